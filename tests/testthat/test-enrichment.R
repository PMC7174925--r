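test_that("cosine similarity obeys its unit identities", {
  expect_equal(cosine_similarity(c(3, -2, 1), c(3, -2, 1)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), 1 / sqrt(2))
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
})

test_that("reaction ranking is sorted, truncated and pair-symmetric", {
  v <- rbind(D1 = c(1, 0, 0), D2 = c(0, 1, 0),
             Rstar = c(1, 1, 0),        # collinear with e(D1) + e(D2)
             Roff = c(1, 0, 1), Rfar = c(-1, -1, 0))
  cands <- c("Rstar", "Roff", "Rfar")
  rk <- rank_reactions(v, "D1", "D2", cands, k = 2L)
  expect_equal(rk$reaction[1], "Rstar")
  expect_equal(rk$cosine[1], 1)
  expect_equal(nrow(rk), 2L)
  expect_true(all(diff(rk$cosine) <= 0))
  # K beyond the candidate count returns everything, still sorted
  rk_all <- rank_reactions(v, "D1", "D2", cands, k = 10L)
  expect_equal(nrow(rk_all), 3L)
  expect_equal(rk_all$reaction[3], "Rfar")
  # order of the pair does not matter
  expect_equal(rank_reactions(v, "D2", "D1", cands, k = 10L), rk_all)
  # exact cosine ties break by token order
  v2 <- rbind(A = c(1, 0), B = c(0, 1), r2 = c(1, 1), r1 = c(2, 2))
  tie <- rank_reactions(v2, "A", "B", c("r2", "r1"), k = 2L)
  expect_equal(tie$reaction, c("r1", "r2"))
  expect_equal(nrow(rank_reactions(v, "D1", "D2", character(0))), 0L)
})

test_that("rankings and validity are invariant to embedding scale", {
  set.seed(14)
  v <- matrix(rnorm(8 * 5), 8, 5,
              dimnames = list(c("D1", "D2", paste0("r", 1:6)), NULL))
  cands <- paste0("r", 1:6)
  soc <- tibble::tibble(reaction = cands,
                        soc_label = rep(c("SOC A", "SOC B"), 3))
  r1 <- rank_reactions(v, "D1", "D2", cands, k = 4L)
  r2 <- rank_reactions(v * 37.5, "D1", "D2", cands, k = 4L)
  expect_equal(r1$reaction, r2$reaction)
  expect_equal(r1$cosine, r2$cosine)
  expect_equal(validate_enrichment(r1, soc, "SOC A"),
               validate_enrichment(r2, soc, "SOC A"))
})

test_that("validity follows the at-least-one SOC rule", {
  soc <- tibble::tibble(reaction = c("r1", "r2", "r3"),
                        soc_label = c("Cardiac disorders", "Other", "Other"))
  ranked <- tibble::tibble(rank = 1:3, reaction = c("r2", "r3", "r1"),
                           cosine = c(0.9, 0.8, 0.7))
  # exactly one match, at the last rank: still valid
  expect_true(validate_enrichment(ranked, soc, "Cardiac disorders"))
  expect_false(validate_enrichment(ranked, soc, "Respiratory disorders"))
  # unmapped reactions never match
  unmapped <- tibble::tibble(rank = 1, reaction = "zz", cosine = 0.5)
  expect_false(validate_enrichment(unmapped, soc, "Cardiac disorders"))
  expect_false(validate_enrichment(ranked[0, ], soc, "Cardiac disorders"))
})

test_that("enlarging the ranking depth never invalidates an enrichment", {
  set.seed(15)
  v <- matrix(rnorm(12 * 6), 12, 6,
              dimnames = list(c("D1", "D2", paste0("r", 1:10)), NULL))
  cands <- paste0("r", 1:10)
  soc <- tibble::tibble(reaction = cands,
                        soc_label = sample(c("S1", "S2"), 10, replace = TRUE))
  for (lab in c("S1", "S2")) {
    prev <- FALSE
    for (k in 1:10) {
      cur <- validate_enrichment(rank_reactions(v, "D1", "D2", cands, k),
                                 soc, lab)
      expect_true(cur >= prev)
      prev <- cur
    }
  }
})

test_that("accuracy pools counts rather than averaging class accuracies", {
  counts <- tibble::tibble(class_name = c("c1", "c2", "c3"),
                           n_ddis = c(10L, 100L, 2L),
                           n_valid = c(9L, 50L, 2L))
  tab <- accuracy_from_counts(counts)
  expect_equal(tab$accuracy[1:3], c(0.9, 0.5, 1.0))
  total <- tab[tab$class_name == "Total", ]
  expect_equal(total$accuracy, 61 / 112)
  expect_false(isTRUE(all.equal(total$accuracy, mean(c(0.9, 0.5, 1.0)))))
  # zero-count class dropped with a warning; zero valid is accuracy 0
  expect_warning(
    tab2 <- accuracy_from_counts(tibble::tibble(
      class_name = c("a", "b"), n_ddis = c(0L, 4L), n_valid = c(0L, 0L))),
    "zero interaction")
  expect_equal(tab2$accuracy, c(0, 0))
})

test_that("enrich_ddis ties ranking, validity and accuracy together", {
  # planted geometry: class reactions collinear with their drug pair
  v <- rbind(D1 = c(1, 0), D2 = c(0, 1),
             E1 = c(-1, 0), E2 = c(0, -1),
             rGood = c(1, 1), rBad = c(-1, -1), rOrth = c(1, -1))
  classes <- tibble::tibble(class_name = "cls", soc_label = "Target SOC",
                            keywords = list("kw"))
  soc <- tibble::tibble(reaction = c("rGood", "rBad", "rOrth"),
                        soc_label = c("Target SOC", "Other", "Other"))
  ddis <- tibble::tibble(drug_a = c("D1", "E1"), drug_b = c("D2", "E2"),
                         description = "kw", class_name = "cls")
  enr <- enrich_ddis(v, ddis, classes, soc, candidates = rownames(v)[5:7],
                     k = 1L)
  expect_equal(enr$valid, c(TRUE, FALSE))
  tab <- accuracy_table(enr)
  expect_equal(tab$accuracy, c(0.5, 0.5))
  expect_error(enrich_ddis(v, dplyr::mutate(ddis, class_name = "nope"),
                           classes, soc, candidates = "rGood"),
               "undefined event class")
})
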