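#' Candidate drug pairs observed in two-drug reports
#'
#' The candidate universe for pair classification: every unordered drug
#' pair occurring in a report that lists exactly two drugs, optionally
#' intersected with a reference drug list.
#'
#' @param corpus A `report_corpus`.
#' @param reference_drugs Optional character vector; keep only pairs whose
#'   drugs are both in it.
#' @return A tibble with canonical columns `drug_a < drug_b`, one row per
#'   distinct pair.
#' @export
observed_pairs <- function(corpus, reference_drugs = NULL) {
  two <- corpus %>% dplyr::filter(lengths(.data$drugs) == 2L)
  if (nrow(two) == 0L) {
    return(tibble::tibble(drug_a = character(), drug_b = character()))
  }
  a <- purrr::map_chr(two$drugs, 1L)
  b <- purrr::map_chr(two$drugs, 2L)
  pairs <- canonical_pair(a, b) %>% dplyr::distinct()
  if (!is.null(reference_drugs)) {
    pairs <- pairs %>%
      dplyr::filter(.data$drug_a %in% reference_drugs,
                    .data$drug_b %in% reference_drugs)
  }
  dplyr::arrange(pairs, .data$drug_a, .data$drug_b)
}

keyword_hit <- function(text, keywords) {
  text <- tolower(text)
  Reduce(`|`, lapply(keywords, function(k) stringr::str_detect(text, stringr::fixed(k))),
         accumulate = FALSE, right = FALSE) %||% rep(FALSE, length(text))
}

#' Label drug pairs for an adverse-event class
#'
#' A pair is positive if any of the three reference strategies fires:
#' \describe{
#'   \item{SIDER}{either drug is in the class's drug list;}
#'   \item{Toxicity}{either drug has a toxicity record whose text contains
#'     (case-insensitive substring) any class keyword;}
#'   \item{DDI}{the pair has an interaction record whose description
#'     contains any class keyword.}
#' }
#' All other pairs are negative. The columns `via_sider`, `via_toxicity`
#' and `via_ddi` record which strategies fired, so per-strategy positive
#' counts can be tabulated as well as the union label.
#'
#' @param pairs Tibble of canonical pairs (`drug_a`, `drug_b`), e.g. from
#'   [observed_pairs()].
#' @param resources A `label_resources` object.
#' @param class_name,soc_label,keywords The event-class definition: name,
#'   System Organ Class label, and lowercase keyword vector. A one-row
#'   slice of the tibble from [read_event_classes()] may be passed as
#'   `class_name` instead.
#' @return A tibble of class `labeled_pairs`: `drug_a`, `drug_b`, `label`
#'   (factor positive/negative), `via_sider`, `via_toxicity`, `via_ddi`.
#' @export
label_pairs <- function(pairs, resources, class_name, soc_label = NULL,
                        keywords = NULL) {
  if (is.data.frame(class_name)) {
    stopifnot(nrow(class_name) == 1L)
    soc_label <- class_name$soc_label
    keywords <- class_name$keywords[[1]]
    class_name <- class_name$class_name
  }
  stopifnot(length(keywords) >= 1L)
  keywords <- tolower(keywords)
  class_drugs <- resources$sider_lists %>%
    dplyr::filter(.data$class_name == !!class_name) %>%
    dplyr::pull("drug")
  tox <- resources$toxicity_records
  tox_drugs <- unique(tox$drug[keyword_hit(tox$description, keywords)])
  ddi <- resources$ddi_records
  ddi_pos <- ddi[keyword_hit(ddi$description, keywords), c("drug_a", "drug_b")]
  out <- pairs %>%
    dplyr::mutate(
      via_sider = .data$drug_a %in% class_drugs | .data$drug_b %in% class_drugs,
      via_toxicity = .data$drug_a %in% tox_drugs | .data$drug_b %in% tox_drugs,
      via_ddi = paste(.data$drug_a, .data$drug_b) %in%
        paste(ddi_pos$drug_a, ddi_pos$drug_b),
      label = factor(ifelse(.data$via_sider | .data$via_toxicity | .data$via_ddi,
                            "positive", "negative"),
                     levels = c("negative", "positive"))
    )
  structure(out, event_class = list(class_name = class_name,
                                    soc_label = soc_label, keywords = keywords),
            class = c("labeled_pairs", class(tibble::tibble())))
}

#' Subsample negatives to match the positive count
#'
#' @param labeled A `labeled_pairs` tibble.
#' @param seed Integer seed for the subsample.
#' @return A `labeled_pairs` tibble with equal class counts (all positives
#'   kept) when negatives outnumber positives, unchanged otherwise.
#' @export
balance_negatives <- function(labeled, seed = 1L) {
  pos <- labeled %>% dplyr::filter(.data$label == "positive")
  neg <- labeled %>% dplyr::filter(.data$label == "negative")
  if (nrow(neg) > nrow(pos)) {
    keep <- local({set.seed(seed); sample.int(nrow(neg), nrow(pos))})
    neg <- neg[sort(keep), , drop = FALSE]
  }
  out <- dplyr::bind_rows(pos, neg) %>%
    dplyr::arrange(.data$drug_a, .data$drug_b)
  structure(out, event_class = attr(labeled, "event_class"),
            class = class(labeled))
}

#' Additive drug-pair features
#'
#' A pair's feature vector is the elementwise sum of its two drug
#' embeddings, which is symmetric in pair order.
#'
#' @param vectors Numeric matrix of embeddings, tokens as row names (an
#'   `msg_model`'s `input_vectors`, a `reduced_features`' `vectors`, or the
#'   matrix returned by [read_embeddings()]).
#' @param pairs Tibble with columns `drug_a`, `drug_b`.
#' @return A numeric matrix with one row per pair.
#' @export
pair_features <- function(vectors, pairs) {
  if (inherits(vectors, "msg_model")) vectors <- vectors$input_vectors
  if (inherits(vectors, "reduced_features")) vectors <- vectors$vectors
  missing <- setdiff(unique(c(pairs$drug_a, pairs$drug_b)), rownames(vectors))
  if (length(missing) > 0L) {
    stop("drug(s) missing from the embedding: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  vectors[pairs$drug_a, , drop = FALSE] + vectors[pairs$drug_b, , drop = FALSE]
}

#' AUROC by the rank statistic
#'
#' The probability that a random positive outscores a random negative,
#' computed from average ranks (ties count one half) — the Mann-Whitney
#' form of the area under the ROC curve.
#'
#' @param scores Numeric decision scores.
#' @param labels Logical or factor; `TRUE`/"positive" marks positives.
#' @return A number in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == "positive"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUROC needs at least one positive and one negative", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

stratified_folds <- function(labels, n_folds, seed) {
  pos <- labels == "positive"
  fold <- integer(length(labels))
  set.seed(seed)
  for (cls in list(which(pos), which(!pos))) {
    if (length(cls) < n_folds) {
      stop("a class has fewer members (", length(cls), ") than folds (",
           n_folds, "); use fewer folds or more data", call. = FALSE)
    }
    fold[sample(cls)] <- rep_len(seq_len(n_folds), length(cls))
  }
  fold
}

roc_points <- function(scores, labels) {
  pos <- labels == "positive"
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  tibble::tibble(fpr = c(0, fp / sum(!pos)), tpr = c(0, tp / sum(pos)))
}

#' Stratified cross-validated AUROC of a logistic-regression classifier
#'
#' Splits the labeled pairs into `n_folds` label-stratified folds; for each
#' fold an L2-regularised (ridge) logistic regression is fitted on the
#' remaining folds and scored on the held-out fold. The per-fold AUROC is
#' the rank statistic of [auroc()]; ROC points are computed from the pooled
#' out-of-fold scores. Splits are seeded and reproducible.
#'
#' @param features Numeric matrix, one row per pair (see [pair_features()]).
#' @param labeled A `labeled_pairs` tibble aligned with `features` rows (or
#'   any vector coercible to positive/negative labels).
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param lambda Ridge penalty of the logistic regression (default 0.01).
#' @return An object of class `cv_result`: list with `folds` (tibble of
#'   per-fold AUROC), `mean_auroc`, `roc` (pooled ROC points), `n_folds`,
#'   `seed`, and the out-of-fold `scores`.
#' @export
crossval_auroc <- function(features, labeled, n_folds = 10L, seed = 1L,
                           lambda = 0.01) {
  labels <- if (is.data.frame(labeled)) labeled$label else
    factor(ifelse(as.logical(labeled == "positive" | labeled == TRUE),
                  "positive", "negative"), levels = c("negative", "positive"))
  stopifnot(nrow(features) == length(labels))
  if (sum(labels == "positive") < 2L || sum(labels == "negative") < 2L) {
    stop("need at least 2 positives and 2 negatives", call. = FALSE)
  }
  fold <- stratified_folds(labels, n_folds, seed)
  scores <- numeric(length(labels))
  per_fold <- purrr::map_dbl(seq_len(n_folds), function(k) {
    test <- fold == k
    if (length(unique(labels[test])) < 2L || length(unique(labels[!test])) < 2L) {
      stop("fold ", k, " contains a single class; use fewer folds or more data",
           call. = FALSE)
    }
    fit <- glmnet::glmnet(features[!test, , drop = FALSE], labels[!test],
                          family = "binomial", alpha = 0,
                          lambda = c(10, 1, 0.1, lambda), standardize = FALSE)
    s <- as.numeric(predict(fit, features[test, , drop = FALSE], s = lambda))
    scores[test] <<- s
    auroc(s, labels[test])
  })
  structure(list(folds = tibble::tibble(fold = seq_len(n_folds),
                                        auroc = per_fold),
                 mean_auroc = mean(per_fold),
                 roc = roc_points(scores, labels),
                 n_folds = as.integer(n_folds), seed = as.integer(seed),
                 lambda = lambda, scores = scores,
                 event_class = attr(labeled, "event_class")),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Cross-validated logistic regression (", x$n_folds, "folds )\n")
  cat("  mean AUROC:", sprintf("%.4f", x$mean_auroc),
      " per-fold range:", sprintf("[%.4f, %.4f]", min(x$folds$auroc),
                                  max(x$folds$auroc)), "\n")
  invisible(x)
}

#' @describeIn crossval_auroc Per-fold AUROC as a tibble.
#' @param x A `cv_result`.
#' @param ... Unused.
#' @export
tidy.cv_result <- function(x, ...) x$folds

#' @describeIn crossval_auroc One-row summary (mean AUROC, fold count,
#'   fold-AUROC standard deviation).
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(mean_auroc = x$mean_auroc, n_folds = x$n_folds,
                 sd_auroc = stats::sd(x$folds$auroc), seed = x$seed)
}
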