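# Independent oracles: every routine here re-derives a quantity by a
# different method than the package (enumeration, brute force, pure-R
# re-implementation) so the two paths check each other.

# Brute-force AUROC: fraction of concordant positive-negative score pairs,
# ties counting one half.
auroc_brute <- function(scores, positive) {
  p <- scores[positive]
  n <- scores[!positive]
  mean(outer(p, n, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Minimal weighted code length over ALL full binary trees with n leaves:
# enumerate every sorted leaf-depth profile, assign large counts to small
# depths.
depth_profiles <- local({
  memo <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- if (n == 1L) list(0) else {
      acc <- list()
      for (l in seq_len(n - 1L)) {
        for (pl in depth_profiles(l)) {
          for (pr in depth_profiles(n - l)) {
            acc[[length(acc) + 1L]] <- sort(c(pl + 1, pr + 1))
          }
        }
      }
      unique(acc)
    }
    memo[[key]] <<- res
    res
  }
})

optimal_code_cost <- function(counts) {
  counts <- sort(counts, decreasing = TRUE)
  min(vapply(depth_profiles(length(counts)),
             function(d) sum(counts * d), numeric(1)))
}

# Path-product recomputation of the hierarchical-softmax probability,
# independent of hs_probability()'s vectorised code path.
hs_prob_oracle <- function(model, target, input) {
  i <- match(target, model$vocab$token)
  path <- model$tree$path[[i]]
  code <- model$tree$code[[i]]
  p <- 1
  for (l in seq_along(path)) {
    x <- sum(model$node_vectors[path[l], ] * model$input_vectors[input, ])
    p <- p * if (code[l] == 0L) 1 / (1 + exp(-x)) else 1 / (1 + exp(x))
  }
  p
}

# Pure-R reference of the SGD trainer: same contract as msg_train() but
# written independently with explicit loops.
msg_train_reference <- function(corpus, dim, epochs, seed, alpha0 = 0.025,
                                min_alpha = 1e-4, min_count = 1L) {
  vocab <- build_vocab(corpus, min_count)
  tree <- build_huffman(vocab)
  pairs <- NULL
  for (ri in seq_len(nrow(corpus))) {
    d <- corpus$drugs[[ri]][corpus$drugs[[ri]] %in% vocab$token]
    r <- corpus$reactions[[ri]][corpus$reactions[[ri]] %in% vocab$token]
    if (length(d) == 0L || length(r) == 0L) next
    pairs <- rbind(pairs,
                   cbind(rep(d, each = length(r)), rep(r, length(d))),
                   cbind(rep(r, each = length(d)), rep(d, length(r))))
  }
  V <- nrow(vocab)
  set.seed(seed)
  emb <- matrix(runif(dim * V, -0.5 / dim, 0.5 / dim), dim, V)
  nodes <- matrix(0, dim, V - 1L)
  idx <- stats::setNames(seq_len(V), vocab$token)
  total <- nrow(pairs) * epochs
  t <- 0
  for (e in seq_len(epochs)) {
    for (p in seq_len(nrow(pairs))) {
      alpha <- max(min_alpha, alpha0 * (1 - t / total))
      t <- t + 1
      j <- idx[[pairs[p, 1]]]
      w <- idx[[pairs[p, 2]]]
      path <- tree$path[[w]]
      code <- tree$code[[w]]
      neu <- numeric(dim)
      for (l in seq_along(path)) {
        x <- sum(nodes[, path[l]] * emb[, j])
        g <- (1 - code[l] - stats::plogis(x)) * alpha
        neu <- neu + g * nodes[, path[l]]
        nodes[, path[l]] <- nodes[, path[l]] + g * emb[, j]
      }
      emb[, j] <- emb[, j] + neu
    }
  }
  out <- t(emb)
  rownames(out) <- vocab$token
  list(input_vectors = out, node_vectors = t(nodes), vocab = vocab)
}

# Brute-force PCA of term rows via eigendecomposition of the covariance.
pca_oracle <- function(X, k) {
  Xc <- sweep(X, 2L, colMeans(X))
  eg <- eigen(crossprod(Xc) / (nrow(X) - 1), symmetric = TRUE)
  scores <- Xc %*% eg$vectors[, seq_len(k), drop = FALSE]
  list(scores = scores, variance = eg$values[seq_len(k)])
}
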