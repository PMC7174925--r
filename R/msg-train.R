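#' Enumerate the bipartite training pairs of one report
#'
#' The modified skip-gram context rule: within a report, the contexts of a
#' drug are all reactions of that report and vice versa — there is no
#' positional window and no drug-drug or reaction-reaction pair. Both
#' directions are emitted, first every (drug, reaction) pair with the drug
#' as input, then every (reaction, drug) pair, each side in report order.
#'
#' @param drugs,reactions Character vectors of one report's tokens.
#' @param vocab An `msg_vocab`; out-of-vocabulary tokens are dropped first.
#' @return A tibble with columns `input` and `target`.
#' @export
enumerate_pairs <- function(drugs, reactions, vocab) {
  d <- drugs[drugs %in% vocab$token]
  r <- reactions[reactions %in% vocab$token]
  if (length(d) == 0L || length(r) == 0L) {
    return(tibble::tibble(input = character(), target = character()))
  }
  dplyr::bind_rows(
    tidyr::expand_grid(input = d, target = r),
    tidyr::expand_grid(input = r, target = d)
  )
}

corpus_pairs <- function(corpus, vocab) {
  keep <- stats::setNames(rep(TRUE, nrow(vocab)), vocab$token)
  rows <- purrr::map2(corpus$drugs, corpus$reactions, function(d, r) {
    d <- d[!is.na(keep[d])]
    r <- r[!is.na(keep[r])]
    nd <- length(d); nr <- length(r)
    if (nd == 0L || nr == 0L) return(NULL)
    # drug-input pairs (report order), then reaction-input pairs
    list(input  = c(rep(d, each = nr), rep(r, each = nd)),
         target = c(rep(r, times = nd), rep(d, times = nr)))
  })
  rows <- rows[!purrr::map_lgl(rows, is.null)]
  tibble::tibble(
    input  = unlist(purrr::map(rows, "input"),  use.names = FALSE) %||% character(),
    target = unlist(purrr::map(rows, "target"), use.names = FALSE) %||% character()
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

flatten_tree <- function(tree) {
  list(path_flat = as.integer(unlist(tree$path) - 1L),
       code_flat = as.integer(unlist(tree$code)),
       offset = as.integer(c(0L, cumsum(lengths(tree$path)))))
}

#' Train the modified skip-gram model
#'
#' Fits drug and reaction embeddings by stochastic gradient ascent on the
#' hierarchical-softmax log-likelihood of the bipartite training pairs (see
#' [enumerate_pairs()]). Updates are applied pair-by-pair in deterministic
#' corpus order; the learning rate decays linearly from `alpha0` to
#' `min_alpha` over all `epochs * n_pairs` updates. Input vectors are
#' initialised uniformly in `[-0.5/dim, 0.5/dim]` from the seeded
#' generator; internal-node vectors start at zero. Two runs with the same
#' corpus and parameters produce identical models.
#'
#' @param corpus A `report_corpus` tibble.
#' @param dim Embedding dimensionality (default 100).
#' @param alpha0 Starting learning rate (default 0.025).
#' @param min_alpha Floor learning rate (default 1e-4).
#' @param epochs Passes over the corpus (default 5).
#' @param min_count Vocabulary frequency threshold (default 10), passed to
#'   [build_vocab()].
#' @param seed Integer seed for the initialisation.
#' @return An object of class `msg_model`: a list with `vocab`, `tree`,
#'   `input_vectors` (tokens x dim matrix, row names are tokens),
#'   `node_vectors`, `params`, and `objective` (mean log-likelihood after
#'   each epoch).
#' @examples
#' corp <- report_corpus(list(c("d1", "d2"), "d1"), list(c("r1", "r2"), "r1"))
#' m <- msg_train(corp, dim = 4, epochs = 2, min_count = 1, seed = 1)
#' tidy(m)
#' @export
msg_train <- function(corpus, dim = 100L, alpha0 = 0.025, min_alpha = 1e-4,
                      epochs = 5L, min_count = 10L, seed = 1L) {
  stopifnot(dim >= 1L, epochs >= 1L, min_alpha > 0, min_alpha <= alpha0)
  vocab <- build_vocab(corpus, min_count = min_count)
  if (nrow(vocab) < 2L) {
    stop("fewer than 2 vocabulary tokens survive min_count = ", min_count,
         "; lower min_count or supply more reports", call. = FALSE)
  }
  tree <- build_huffman(vocab)
  pairs <- corpus_pairs(corpus, vocab)
  if (nrow(pairs) == 0L) {
    stop("no training pairs after vocabulary filtering; ",
         "min_count = ", min_count, " is the likely cause", call. = FALSE)
  }
  idx <- stats::setNames(vocab$index, vocab$token)
  n_tok <- nrow(vocab)
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  emb <- withr_seed(matrix(stats::runif(dim * n_tok, -0.5 / dim, 0.5 / dim),
                           nrow = dim, ncol = n_tok))
  nodes <- matrix(0, nrow = dim, ncol = n_tok - 1L)
  fl <- flatten_tree(tree)
  objective <- msg_sgd_cpp(emb, nodes,
                           as.integer(idx[pairs$input]),
                           as.integer(idx[pairs$target]),
                           fl$path_flat, fl$code_flat, fl$offset,
                           as.integer(epochs), alpha0, min_alpha)
  input_vectors <- t(emb)
  rownames(input_vectors) <- vocab$token
  node_vectors <- t(nodes)
  structure(list(vocab = vocab, tree = tree,
                 input_vectors = input_vectors, node_vectors = node_vectors,
                 params = list(dim = as.integer(dim), alpha0 = alpha0,
                               min_alpha = min_alpha, epochs = as.integer(epochs),
                               min_count = as.integer(min_count),
                               seed = as.integer(seed)),
                 n_pairs = nrow(pairs),
                 objective = as.numeric(objective)),
            class = "msg_model")
}

#' Hierarchical-softmax probability of a target token
#'
#' The probability of `target` given `input` is the product, along the
#' target's root-to-leaf Huffman path, of `sigmoid(x)` for a 0-bit step and
#' `sigmoid(-x)` for a 1-bit step, where `x` is the inner product of the
#' internal node's vector with the input token's vector. Summed over all
#' vocabulary tokens the probabilities telescope to 1.
#'
#' @param model An `msg_model`.
#' @param target Character vector of target tokens.
#' @param input A single input token.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
hs_probability <- function(model, target, input) {
  tok <- model$vocab$token
  unknown <- setdiff(c(target, input), tok)
  if (length(unknown) > 0L) {
    stop("token(s) not in vocabulary: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  ej <- model$input_vectors[input, ]
  x_all <- as.numeric(model$node_vectors %*% ej)
  purrr::map_dbl(target, function(w) {
    i <- match(w, tok)
    path <- model$tree$path[[i]]
    code <- model$tree$code[[i]]
    x <- x_all[path]
    prod(stats::plogis(ifelse(code == 0L, x, -x)))
  })
}

#' Mean hierarchical-softmax log-likelihood of a corpus
#'
#' Evaluates the training objective: the mean over all bipartite training
#' pairs of the log hierarchical-softmax probability of the target given
#' the input, under the model's current vectors.
#'
#' @param model An `msg_model`.
#' @param corpus A `report_corpus`.
#' @return A single number (or `NA` if the corpus yields no pairs).
#' @export
hs_log_likelihood <- function(model, corpus) {
  pairs <- corpus_pairs(corpus, model$vocab)
  if (nrow(pairs) == 0L) return(NA_real_)
  idx <- stats::setNames(model$vocab$index, model$vocab$token)
  fl <- flatten_tree(model$tree)
  hs_mean_loglik_cpp(t(model$input_vectors), t(model$node_vectors),
                     as.integer(idx[pairs$input]),
                     as.integer(idx[pairs$target]),
                     fl$path_flat, fl$code_flat, fl$offset)
}

#' @export
print.msg_model <- function(x, ...) {
  cat("Modified skip-gram model\n")
  cat("  tokens:", nrow(x$vocab),
      sprintf("(%d drugs, %d reactions)", sum(x$vocab$kind == "drug"),
              sum(x$vocab$kind == "reaction")), "\n")
  cat("  dim:", x$params$dim, " epochs:", x$params$epochs,
      " training pairs/epoch:", x$n_pairs, "\n")
  cat("  mean log-likelihood (final epoch):",
      sprintf("%.4f", utils::tail(x$objective, 1L)), "\n")
  invisible(x)
}

#' @describeIn msg_train Per-token tidy summary: token, kind, corpus count,
#'   and the L2 norm of its embedding.
#' @param x An `msg_model`.
#' @param ... Unused.
#' @export
tidy.msg_model <- function(x, ...) {
  x$vocab %>%
    tibble::as_tibble() %>%
    dplyr::mutate(norm = sqrt(rowSums(x$input_vectors^2))) %>%
    dplyr::select("token", "kind", "count", "norm")
}

#' @describeIn msg_train One-row model summary.
#' @export
glance.msg_model <- function(x, ...) {
  tibble::tibble(n_tokens = nrow(x$vocab), dim = x$params$dim,
                 epochs = x$params$epochs, n_pairs = x$n_pairs,
                 mean_loglik = utils::tail(x$objective, 1L))
}
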