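test_that("the three labeling strategies fire as documented", {
  res <- toy_resources()
  pairs <- tibble::tibble(drug_a = c("dB1", "dA3", "dB2", "dB3"),
                          drug_b = c("dB3", "dB3", "dB3", "dZ9"))
  lab <- label_pairs(pairs, res, toy_classes()[2, ])  # neuro class
  # DDI description "combination is neurotoxic in rats" labels <dB1,dB3>
  expect_true(lab$via_ddi[1] && lab$label[1] == "positive")
  # dB1 is in the neuro SIDER list too
  expect_true(lab$via_sider[1])
  # dB2's toxicity text contains "sedation"
  expect_true(lab$via_toxicity[3] && lab$label[3] == "positive")
  # no list membership, no keyword hit
  expect_equal(as.character(lab$label[4]), "negative")
  expect_false(any(lab$via_sider[4], lab$via_toxicity[4], lab$via_ddi[4]))

  lab_cdt <- label_pairs(pairs, res, toy_classes()[1, ])  # cardio class
  # dA3's toxicity text contains "cardiotoxicity" which the substring
  # keyword "cardiotox" hits
  expect_true(lab_cdt$via_toxicity[2] && lab_cdt$label[2] == "positive")
  # every positive has a recorded provenance
  pos <- lab_cdt$label == "positive"
  expect_true(all((lab_cdt$via_sider | lab_cdt$via_toxicity |
                     lab_cdt$via_ddi)[pos]))
})

test_that("candidate pairs come from two-drug reports, canonicalized", {
  corp <- report_corpus(drugs = list(c("B", "A"), c("A", "B"), "C",
                                     c("C", "D", "E")),
                        reactions = list("r", "r", "r", "r"))
  p <- observed_pairs(corp)
  expect_equal(p, tibble::tibble(drug_a = "A", drug_b = "B"))
  expect_equal(nrow(observed_pairs(corp, reference_drugs = "A")), 0L)
})

test_that("pair features are symmetric elementwise sums", {
  v <- rbind(D1 = c(1, 2), D2 = c(3, 4))
  pr <- tibble::tibble(drug_a = "D1", drug_b = "D2")
  expect_equal(unname(pair_features(v, pr)[1, ]), c(4, 6))
  rp <- tibble::tibble(drug_a = "D2", drug_b = "D1")
  expect_equal(pair_features(v, pr)[1, ], pair_features(v, rp)[1, ],
               ignore_attr = TRUE)
  expect_equal(unname(pair_features(v * 0, pr)[1, ]), c(0, 0))
  expect_error(pair_features(v, tibble::tibble(drug_a = "D1", drug_b = "D9")),
               "D9")
})

test_that("rank-statistic AUROC equals brute-force concordance counting", {
  for (s in 1:50) {
    set.seed(s)
    n <- sample(4:12, 1L)
    scores <- sample(1:6, n, replace = TRUE)  # integer scores force ties
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(pos) || all(pos)) next
    expect_equal(auroc(scores, pos), auroc_brute(scores, pos))
  }
  # hand-checkable 6-point fold
  s6 <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  p6 <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  expect_equal(auroc(s6, p6), 8 / 9)
})

test_that("AUROC respects its exact invariances", {
  set.seed(33)
  scores <- rnorm(40)
  pos <- rep(c(TRUE, FALSE), 20)
  a <- auroc(scores, pos)
  # strictly monotone transforms leave it unchanged
  expect_equal(auroc(exp(scores), pos), a)
  expect_equal(auroc(scores * 3 - 7, pos), a)
  # flipping all labels maps a to 1 - a
  expect_equal(auroc(scores, !pos), 1 - a)
  # independent implementation cross-check
  skip_if_not_installed("pROC")
  expect_equal(a, as.numeric(pROC::auc(pROC::roc(pos, scores, quiet = TRUE,
                                                 direction = "<"))))
})

test_that("folds are stratified and seeded", {
  labels <- factor(rep(c("positive", "negative"), c(30, 70)),
                   levels = c("negative", "positive"))
  f1 <- msgddi:::stratified_folds(labels, 10L, seed = 5L)
  f2 <- msgddi:::stratified_folds(labels, 10L, seed = 5L)
  expect_identical(f1, f2)
  global <- mean(labels == "positive")
  for (k in 1:10) {
    fold_frac <- mean(labels[f1 == k] == "positive")
    expect_lte(abs(fold_frac - global), 1 / sum(f1 == k))
  }
})

test_that("cross-validation is perfect on separable data and null on noise", {
  set.seed(12)
  # separable: positives shifted far away
  n <- 100L
  lab <- tibble::tibble(drug_a = paste0("a", 1:n), drug_b = paste0("b", 1:n),
                        label = factor(rep(c("positive", "negative"), each = n / 2),
                                       levels = c("negative", "positive")))
  X <- matrix(rnorm(n * 4), n, 4)
  X[1:(n / 2), 1] <- X[1:(n / 2), 1] + 50
  cv <- crossval_auroc(X, lab, n_folds = 5L, seed = 2L)
  expect_equal(cv$mean_auroc, 1.0)
  expect_equal(cv$mean_auroc, mean(cv$folds$auroc))
  # ROC points are monotone in both coordinates
  expect_true(all(diff(cv$roc$fpr) >= 0))
  expect_true(all(diff(cv$roc$tpr) >= 0))

  # permuted labels: AUROC concentrates near 1/2
  set.seed(77)
  n2 <- 500L
  X2 <- matrix(rnorm(n2 * 5), n2, 5)
  lab2 <- lab[rep(1:2, n2 / 2), ]
  lab2$label <- factor(sample(rep(c("positive", "negative"), each = n2 / 2)),
                       levels = c("negative", "positive"))
  cv2 <- crossval_auroc(X2, lab2, n_folds = 10L, seed = 9L)
  expect_gte(cv2$mean_auroc, 0.45)
  expect_lte(cv2$mean_auroc, 0.55)
})

test_that("degenerate fold layouts raise advisory errors", {
  lab <- tibble::tibble(drug_a = letters[1:6], drug_b = LETTERS[1:6],
                        label = factor(c("positive", rep("negative", 5)),
                                       levels = c("negative", "positive")))
  X <- matrix(rnorm(12), 6, 2)
  expect_error(crossval_auroc(X, lab, n_folds = 3L, seed = 1L),
               "at least 2 positives")
})

test_that("negative subsampling balances classes deterministically", {
  res <- toy_resources()
  pairs <- tidyr::expand_grid(drug_a = paste0("dA", 1:3),
                              drug_b = paste0("dB", 1:3))
  lab <- label_pairs(pairs, res, toy_classes()[1, ])
  bal1 <- balance_negatives(lab, seed = 4L)
  bal2 <- balance_negatives(lab, seed = 4L)
  expect_identical(bal1, bal2)
  expect_lte(sum(bal1$label == "negative"), sum(bal1$label == "positive"))
})
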