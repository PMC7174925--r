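test_that("bipartite pair enumeration follows the modified context rule", {
  vocab <- build_vocab(report_corpus(
    drugs = list(c("D1", "D2")), reactions = list(c("R1", "R2", "R3"))), 1L)

  p1 <- enumerate_pairs("D1", c("R1", "R2", "R3"), vocab)
  expect_equal(nrow(p1), 6L)  # 3 drug-input + 3 reaction-input pairs
  expect_setequal(p1$target[p1$input == "D1"], c("R1", "R2", "R3"))

  expect_equal(nrow(enumerate_pairs(c("D1", "D2"), character(0), vocab)), 0L)

  p3 <- enumerate_pairs(c("D1", "D2"), c("R1", "R2"), vocab)
  expect_equal(nrow(p3), 8L)  # 2 * |drugs| * |reactions|
  # never a same-side pair
  kind <- stats::setNames(vocab$kind, vocab$token)
  expect_true(all(kind[p3$input] != kind[p3$target]))
  # out-of-vocabulary tokens are dropped silently
  expect_equal(nrow(enumerate_pairs(c("D1", "ZZZ"), "R1", vocab)), 2L)
})

test_that("hierarchical softmax is a normalized distribution", {
  for (s in c(1L, 2L)) {
    m <- random_model(n_tokens = sample(5:64, 1L), dim = 8L, seed = s)
    for (input in m$vocab$token[c(1L, nrow(m$vocab))]) {
      p <- hs_probability(m, m$vocab$token, input)
      expect_true(all(p > 0 & p < 1))
      expect_equal(sum(p), 1, tolerance = 1e-9)
    }
  }
})

test_that("hs_probability matches an independent path-product oracle", {
  m <- random_model(n_tokens = 4L, dim = 6L, seed = 42L)
  for (tgt in m$vocab$token) {
    expect_equal(hs_probability(m, tgt, "d1"), hs_prob_oracle(m, tgt, "d1"),
                 tolerance = 1e-12)
  }
  expect_error(hs_probability(m, "nope", "d1"), "not in vocabulary")
})

test_that("a zero model over two leaves gives probability one half", {
  m <- random_model(n_tokens = 2L, dim = 4L, seed = 1L)
  m$input_vectors[] <- 0
  m$node_vectors[] <- 0
  expect_equal(hs_probability(m, m$vocab$token, m$vocab$token[1]),
               c(0.5, 0.5))
})

test_that("the SGD update implements the analytic HS gradient", {
  # One update at tiny learning rate: (new - old)/alpha must equal the
  # central-difference gradient of log P(target | input).
  m <- random_model(n_tokens = 6L, dim = 5L, seed = 7L)
  fl <- list(path_flat = as.integer(unlist(m$tree$path) - 1L),
             code_flat = as.integer(unlist(m$tree$code)),
             offset = as.integer(c(0L, cumsum(lengths(m$tree$path)))))
  alpha <- 1e-6
  emb0 <- t(m$input_vectors)
  nod0 <- t(m$node_vectors)
  emb <- emb0 + 0; nod <- nod0 + 0  # copies: the C++ core updates in place
  msgddi:::msg_sgd_cpp(emb, nod, pin = 2L, ptg = 4L,
                       fl$path_flat, fl$code_flat, fl$offset,
                       epochs = 1L, alpha0 = alpha, min_alpha = alpha)
  g_emb <- (emb[, 3L] - emb0[, 3L]) / alpha
  target <- m$vocab$token[5L]; input <- m$vocab$token[3L]
  eps <- 1e-5
  g_num <- vapply(seq_len(nrow(emb0)), function(d) {
    mp <- m; mp$input_vectors[input, d] <- mp$input_vectors[input, d] + eps
    mm <- m; mm$input_vectors[input, d] <- mm$input_vectors[input, d] - eps
    (log(hs_probability(mp, target, input)) -
       log(hs_probability(mm, target, input))) / (2 * eps)
  }, numeric(1))
  expect_equal(g_emb, g_num, tolerance = 1e-5)

  # node-vector gradients on the target's path
  path <- m$tree$path[[5L]]
  for (nd in path) {
    g_node <- (nod[, nd] - nod0[, nd]) / alpha
    g_num_n <- vapply(seq_len(nrow(nod0)), function(d) {
      mp <- m; mp$node_vectors[nd, d] <- mp$node_vectors[nd, d] + eps
      mm <- m; mm$node_vectors[nd, d] <- mm$node_vectors[nd, d] - eps
      (log(hs_probability(mp, target, input)) -
         log(hs_probability(mm, target, input))) / (2 * eps)
    }, numeric(1))
    expect_equal(g_node, g_num_n, tolerance = 1e-5)
  }
})

test_that("the compiled trainer matches the pure-R reference exactly", {
  corp <- toy_corpus(n_reports = 12L, seed = 2L)
  ref <- msg_train_reference(corp, dim = 6L, epochs = 3L, seed = 11L)
  m <- msg_train(corp, dim = 6L, epochs = 3L, min_count = 1L, seed = 11L)
  expect_equal(m$input_vectors, ref$input_vectors, tolerance = 1e-12)
  expect_equal(m$node_vectors, ref$node_vectors, tolerance = 1e-12)
})

test_that("training is reproducible and raises the objective", {
  corp <- toy_corpus(n_reports = 40L, seed = 5L)
  m1 <- msg_train(corp, dim = 10L, epochs = 2L, min_count = 1L, seed = 3L)
  m2 <- msg_train(corp, dim = 10L, epochs = 2L, min_count = 1L, seed = 3L)
  expect_identical(m1$input_vectors, m2$input_vectors)

  # objective after epoch 1 beats the untrained model
  m0 <- m1
  set.seed(3L)
  m0$input_vectors <- t(matrix(runif(10 * nrow(m1$vocab), -0.05, 0.05),
                               10, nrow(m1$vocab)))
  rownames(m0$input_vectors) <- m1$vocab$token
  m0$node_vectors[] <- 0
  expect_gt(m1$objective[1], hs_log_likelihood(m0, corp))
  # and hs_log_likelihood agrees with the trainer's own trace
  expect_equal(hs_log_likelihood(m1, corp), m1$objective[2], tolerance = 1e-12)
})

test_that("the objective is non-decreasing over epochs at small alpha", {
  corp <- toy_corpus(n_reports = 30L, seed = 8L)
  ok <- 0L
  for (s in 1:20) {
    m <- msg_train(corp, dim = 8L, epochs = 4L, min_count = 1L, seed = s,
                   alpha0 = 0.005, min_alpha = 1e-5)
    if (all(diff(m$objective) >= -1e-9)) ok <- ok + 1L
  }
  expect_gte(ok / 20, 0.95)
})

test_that("consistent relabeling permutes embeddings without changing them", {
  corp <- toy_corpus(n_reports = 25L, seed = 4L)
  relab <- report_corpus(lapply(corp$drugs, function(x) paste0("x", x)),
                         lapply(corp$reactions, function(x) paste0("x", x)))
  m <- msg_train(corp, dim = 7L, epochs = 2L, min_count = 1L, seed = 6L)
  mr <- msg_train(relab, dim = 7L, epochs = 2L, min_count = 1L, seed = 6L)
  expect_equal(unname(mr$input_vectors[paste0("x", rownames(m$input_vectors)), ]),
               unname(m$input_vectors))
})

test_that("a planted exclusive co-occurrence is recovered by cosine rank", {
  set.seed(11)
  noise_d <- paste0("nd", 1:20)
  noise_r <- paste0("nr", 1:30)
  drugs <- c(lapply(1:200, function(i) c("D", sample(noise_d, 1))),
             lapply(1:200, function(i) sample(noise_d, 2)))
  reacts <- c(lapply(1:200, function(i) unique(c("R", sample(noise_r, 2)))),
              lapply(1:200, function(i) sample(noise_r, 3)))
  m <- msg_train(report_corpus(drugs, reacts), dim = 30L, epochs = 5L,
                 min_count = 1L, seed = 7L)
  v <- m$input_vectors
  cos_r <- cosine_similarity(v["D", ], v["R", ])
  cos_others <- vapply(noise_r, function(r) cosine_similarity(v["D", ], v[r, ]),
                       numeric(1))
  expect_gt(cos_r, stats::quantile(cos_others, 0.95))
})

test_that("degenerate corpora raise informative training errors", {
  corp <- report_corpus(list("A"), list("R"))
  expect_error(msg_train(corp, dim = 4L, min_count = 10L), "min_count")
})
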