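#' Cosine similarity
#'
#' `sum(u*v) / (||u|| ||v||)`. Both vectors must be nonzero and of equal
#' length.
#'
#' @param u,v Numeric vectors.
#' @return A number in \[-1, 1\].
#' @export
cosine_similarity <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("cosine is undefined for a zero vector", call. = FALSE)
  }
  sum(u * v) / (nu * nv)
}

#' Rank candidate reactions for a drug pair
#'
#' Scores every candidate reaction by the cosine between its embedding and
#' the additive pair embedding (see [pair_features()]), sorts descending,
#' breaks exact cosine ties by token order, and keeps the top `k`.
#'
#' @param vectors Embedding matrix, tokens as row names (accepts an
#'   `msg_model` or `reduced_features` as in [pair_features()]).
#' @param drug_a,drug_b The drug pair (order irrelevant).
#' @param candidates Character vector of candidate reaction tokens.
#' @param k Ranking depth (default 20).
#' @return A tibble with columns `rank`, `reaction`, `cosine`
#'   (non-increasing), at most `k` rows.
#' @export
rank_reactions <- function(vectors, drug_a, drug_b, candidates, k = 20L) {
  if (inherits(vectors, "msg_model")) vectors <- vectors$input_vectors
  if (inherits(vectors, "reduced_features")) vectors <- vectors$vectors
  if (length(candidates) == 0L) {
    return(tibble::tibble(rank = integer(), reaction = character(),
                          cosine = numeric()))
  }
  missing <- setdiff(c(drug_a, drug_b, candidates), rownames(vectors))
  if (length(missing) > 0L) {
    stop("token(s) missing from the embedding: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  pair_vec <- vectors[drug_a, ] + vectors[drug_b, ]
  cand <- vectors[candidates, , drop = FALSE]
  norms <- sqrt(rowSums(cand^2))
  pn <- sqrt(sum(pair_vec^2))
  if (pn == 0 || any(norms == 0)) {
    stop("cosine is undefined for a zero vector", call. = FALSE)
  }
  cos <- as.numeric(cand %*% pair_vec) / (norms * pn)
  ord <- order(-cos, candidates)
  keep <- utils::head(ord, k)
  tibble::tibble(rank = seq_along(keep), reaction = candidates[keep],
                 cosine = unname(cos[keep]))
}

#' Validate an enrichment ranking against a System Organ Class
#'
#' The enrichment of a drug pair is valid for an event class when at least
#' one ranked reaction maps to the class's SOC label. Reactions absent
#' from the SOC map never match.
#'
#' @param ranked Tibble from [rank_reactions()].
#' @param soc_map Tibble with columns `reaction`, `soc_label`.
#' @param soc_label The event class's SOC label.
#' @return Logical scalar.
#' @export
validate_enrichment <- function(ranked, soc_map, soc_label) {
  if (nrow(ranked) == 0L) return(FALSE)
  socs <- soc_map$soc_label[match(ranked$reaction, soc_map$reaction)]
  any(!is.na(socs) & socs == soc_label)
}

#' Enrich a set of DDI records against their event classes
#'
#' For every interaction record, ranks the candidate reactions by cosine
#' to the pair embedding and flags validity against the record's event
#' class SOC.
#'
#' @param vectors Embedding matrix (or `msg_model`/`reduced_features`).
#' @param ddis Tibble with columns `drug_a`, `drug_b`, `class_name`.
#' @param event_classes Tibble from [read_event_classes()] (columns
#'   `class_name`, `soc_label`, `keywords`).
#' @param soc_map Tibble `reaction`, `soc_label`.
#' @param candidates Candidate reaction tokens; defaults to every token in
#'   the embedding that appears in no `drug_a`/`drug_b` column, i.e. the
#'   caller usually passes the vocabulary's reactions.
#' @param k Ranking depth (default 20).
#' @return A tibble of class `enrichment_result`: one row per (pair,
#'   class) with `drug_a`, `drug_b`, `class_name`, `valid`, and the
#'   list-column `ranked`.
#' @export
enrich_ddis <- function(vectors, ddis, event_classes, soc_map,
                        candidates, k = 20L) {
  if (inherits(vectors, "msg_model")) vectors <- vectors$input_vectors
  if (inherits(vectors, "reduced_features")) vectors <- vectors$vectors
  soc_of <- stats::setNames(event_classes$soc_label, event_classes$class_name)
  unknown <- setdiff(unique(ddis$class_name), names(soc_of))
  if (length(unknown) > 0L) {
    stop("DDI record(s) reference undefined event class(es): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- ddis %>%
    dplyr::mutate(
      ranked = purrr::pmap(list(.data$drug_a, .data$drug_b),
                           ~ rank_reactions(vectors, ..1, ..2, candidates, k)),
      valid = purrr::map2_lgl(.data$ranked, .data$class_name,
                              ~ validate_enrichment(.x, soc_map, soc_of[[.y]]))
    )
  structure(out, k = as.integer(k),
            class = c("enrichment_result", class(tibble::tibble())))
}

#' Per-class enrichment accuracy table
#'
#' Accuracy is the fraction of a class's interaction pairs whose
#' enrichment is valid; the `Total` row pools counts over classes
#' (`sum(n_valid) / sum(n_ddis)`, not the mean of the class accuracies).
#'
#' @param results An `enrichment_result` tibble (needs `class_name` and
#'   `valid` columns).
#' @return A tibble with columns `class_name`, `n_ddis`, `n_valid`,
#'   `accuracy`, ending with the pooled `Total` row.
#' @export
accuracy_table <- function(results) {
  counts <- results %>%
    tibble::as_tibble() %>%
    dplyr::group_by(.data$class_name) %>%
    dplyr::summarise(n_ddis = dplyr::n(), n_valid = sum(.data$valid),
                     .groups = "drop")
  accuracy_from_counts(counts)
}

#' Accuracy table from per-class counts
#'
#' The arithmetic of [accuracy_table()] applied to already-tabulated
#' counts: per-class `accuracy = n_valid / n_ddis` plus a pooled `Total`
#' row. Classes with zero interactions are dropped with a warning.
#'
#' @param counts Tibble with columns `class_name`, `n_ddis`, `n_valid`.
#' @return A tibble with columns `class_name`, `n_ddis`, `n_valid`,
#'   `accuracy` (`Total` last).
#' @examples
#' accuracy_from_counts(tibble::tibble(
#'   class_name = c("A", "B"), n_ddis = c(10, 20), n_valid = c(9, 10)))
#' @export
accuracy_from_counts <- function(counts) {
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("class_name", "n_ddis", "n_valid") %in% names(counts)),
            all(counts$n_valid >= 0), all(counts$n_valid <= counts$n_ddis))
  empty <- counts$n_ddis == 0
  if (any(empty)) {
    warning("dropping class(es) with zero interaction records: ",
            paste(counts$class_name[empty], collapse = ", "), call. = FALSE)
    counts <- counts[!empty, , drop = FALSE]
  }
  dplyr::bind_rows(
    counts %>% dplyr::mutate(accuracy = .data$n_valid / .data$n_ddis),
    tibble::tibble(class_name = "Total",
                   n_ddis = sum(counts$n_ddis),
                   n_valid = sum(counts$n_valid),
                   accuracy = sum(counts$n_valid) / sum(counts$n_ddis))
  )
}
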