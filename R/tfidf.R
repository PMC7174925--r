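#' TF-IDF weight of a term in a report
#'
#' The weight is `(n_ij / report_total) * log(n_reports / doc_freq)` with
#' the natural logarithm, and exactly 0 when the term does not occur in the
#' report. Vectorised over its arguments.
#'
#' @param n_ij Occurrences of the term in the report (0 or 1 under the
#'   set-semantics corpus, but general counts are accepted).
#' @param report_total Total term occurrences in the report.
#' @param n_reports Number of reports in the corpus.
#' @param doc_freq Number of reports containing the term (must be >= 1
#'   wherever `n_ij > 0`).
#' @return Numeric weight(s), >= 0 whenever `doc_freq <= n_reports`.
#' @examples
#' tfidf_weight(3, 10, 100, 10)  # 0.3 * log(10)
#' @export
tfidf_weight <- function(n_ij, report_total, n_reports, doc_freq) {
  args <- vctrs_recycle(n_ij, report_total, n_reports, doc_freq)
  n_ij <- args[[1]]; report_total <- args[[2]]
  n_reports <- args[[3]]; doc_freq <- args[[4]]
  if (any(n_ij > 0 & report_total == 0)) {
    stop("report_total is 0 for a report with a positive term count",
         call. = FALSE)
  }
  if (any(n_ij > 0 & doc_freq < 1)) {
    stop("doc_freq must be >= 1 for terms that occur", call. = FALSE)
  }
  out <- numeric(length(n_ij))
  pos <- n_ij > 0
  out[pos] <- (n_ij[pos] / report_total[pos]) * log(n_reports[pos] / doc_freq[pos])
  out
}

vctrs_recycle <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  lapply(args, rep_len, length.out = n)
}

#' Build the term-by-report TF-IDF co-occurrence matrix
#'
#' Rows are vocabulary terms (drugs and reactions jointly), columns are
#' reports; the entry for a term present in a report is its
#' [tfidf_weight()], otherwise exactly zero. Counts follow set semantics
#' (a term occurs 0 or 1 times per report).
#'
#' @param corpus A `report_corpus`.
#' @param vocab An `msg_vocab` built from the same corpus.
#' @return An object of class `tfidf_matrix`: a list with the sparse
#'   `weights` matrix (terms x reports, `Matrix::dgCMatrix`), `terms`,
#'   `n_reports`, `doc_freq`, and `report_totals`.
#' @export
build_tfidf <- function(corpus, vocab) {
  if (nrow(corpus) == 0L) stop("empty corpus", call. = FALSE)
  n_reports <- nrow(corpus)
  occ <- tibble::tibble(
    report = rep(corpus$report_id,
                 lengths(corpus$drugs) + lengths(corpus$reactions)),
    token  = unlist(purrr::map2(corpus$drugs, corpus$reactions, c))
  ) %>%
    dplyr::filter(.data$token %in% vocab$token)
  report_totals <- occ %>% dplyr::count(.data$report, name = "total")
  totals <- stats::setNames(rep(0L, n_reports), corpus$report_id)
  totals[as.character(report_totals$report)] <- report_totals$total
  doc_freq <- occ %>% dplyr::count(.data$token, name = "df")
  df <- stats::setNames(doc_freq$df, doc_freq$token)
  terms <- vocab$token[vocab$token %in% names(df)]  # doc_freq >= 1 guaranteed
  i <- match(occ$token, terms)
  j <- match(occ$report, corpus$report_id)
  w <- tfidf_weight(1L, totals[j], n_reports, df[occ$token])
  weights <- Matrix::sparseMatrix(i = i, j = j, x = w,
                                  dims = c(length(terms), n_reports),
                                  dimnames = list(terms, as.character(corpus$report_id)))
  structure(list(weights = weights, terms = terms, n_reports = n_reports,
                 doc_freq = df[terms], report_totals = totals),
            class = "tfidf_matrix")
}

#' @export
print.tfidf_matrix <- function(x, ...) {
  cat("TF-IDF co-occurrence matrix:", length(x$terms), "terms x",
      x$n_reports, "reports;",
      sprintf("%.2f%% nonzero\n",
              100 * Matrix::nnzero(x$weights) /
                (length(x$terms) * x$n_reports)))
  invisible(x)
}

#' Reduce TF-IDF term rows to fixed-length features by PCA
#'
#' Projects the centred term rows of the co-occurrence matrix onto the top
#' `k` principal axes. The per-component sign indeterminacy is fixed by
#' making each component's largest-magnitude loading positive, so results
#' are fully deterministic.
#'
#' @param tfidf A `tfidf_matrix`.
#' @param k Output dimensionality, `1 <= k <= min(n_terms, n_reports)`;
#'   defaults to 100 to parallel the default embedding dimension.
#' @return An object of class `reduced_features`: list with `vectors`
#'   (terms x k matrix, terms as row names) and `explained_variance`
#'   (component variances, non-increasing).
#' @export
reduce_pca <- function(tfidf, k = 100L) {
  n_terms <- length(tfidf$terms)
  if (k < 1L || k > min(n_terms, tfidf$n_reports)) {
    stop("k must be between 1 and min(n_terms, n_reports) = ",
         min(n_terms, tfidf$n_reports), call. = FALSE)
  }
  X <- as.matrix(tfidf$weights)
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = k)
  kk <- min(k, ncol(pr$x))
  scores <- pr$x[, seq_len(kk), drop = FALSE]
  rotation <- pr$rotation[, seq_len(kk), drop = FALSE]
  for (j in seq_len(kk)) {
    lead <- which.max(abs(rotation[, j]))
    if (rotation[lead, j] < 0) {
      rotation[, j] <- -rotation[, j]
      scores[, j] <- -scores[, j]
    }
  }
  if (kk < k) {  # rank-deficient tail: pad with exact zero coordinates
    scores <- cbind(scores, matrix(0, nrow(scores), k - kk))
  }
  rownames(scores) <- tfidf$terms
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(vectors = scores,
                 explained_variance = c(pr$sdev^2, rep(0, k))[seq_len(k)],
                 center = pr$center, rotation = rotation, k = k),
            class = "reduced_features")
}
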