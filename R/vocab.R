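#' Build the frequency-filtered vocabulary of a report corpus
#'
#' Token frequency is document frequency: the number of reports containing
#' the token (within-report duplicates were already collapsed on read, so
#' this equals raw multiplicity). Tokens seen in fewer than `min_count`
#' reports are dropped and ignored by all downstream stages. Each retained
#' token records the side of the report it came from (`drug` or
#' `reaction`); a token seen on both sides across the corpus is ambiguous
#' and raises an error. Vocabulary order is order of first appearance,
#' which fixes every later tie-break.
#'
#' @param corpus A `report_corpus` tibble from [read_reports()] or
#'   [report_corpus()].
#' @param min_count Minimum number of reports a token must appear in
#'   (default 10, the threshold used for regulatory-scale corpora).
#' @return A tibble of class `msg_vocab` with columns `token`, `count`,
#'   `kind` and zero-based `index`.
#' @export
build_vocab <- function(corpus, min_count = 10L) {
  stopifnot(min_count >= 1L)
  occ <- dplyr::bind_rows(
    tibble::tibble(token = unlist(corpus$drugs), kind = "drug"),
    tibble::tibble(token = unlist(corpus$reactions), kind = "reaction")
  )
  if (nrow(occ) > 0L) {
    both <- occ %>%
      dplyr::distinct(.data$token, .data$kind) %>%
      dplyr::count(.data$token) %>%
      dplyr::filter(.data$n > 1L)
    if (nrow(both) > 0L) {
      stop("token(s) appear as both drug and reaction across the corpus: ",
           paste(utils::head(both$token, 5L), collapse = ", "), call. = FALSE)
    }
  }
  # first appearance: all drugs of report 1, then its reactions, then report 2, ...
  appearance <- unlist(purrr::map2(corpus$drugs, corpus$reactions, c))
  first_seen <- appearance[!duplicated(appearance)]
  vocab <- occ %>%
    dplyr::count(.data$token, .data$kind, name = "count") %>%
    dplyr::filter(.data$count >= min_count) %>%
    dplyr::arrange(match(.data$token, first_seen)) %>%
    dplyr::mutate(index = seq_len(dplyr::n()) - 1L) %>%
    dplyr::select("token", "count", "kind", "index")
  structure(vocab, min_count = min_count,
            class = c("msg_vocab", class(tibble::tibble())))
}

#' Build the Huffman tree for hierarchical softmax
#'
#' Repeatedly merges the two lowest-count nodes; ties prefer the lower
#' creation index (leaves first, in vocabulary order, then internal nodes
#' in creation order), so the tree is fully deterministic. The first node
#' merged becomes the left (bit 0) child. Codes are prefix-free and
#' minimise the expected code length under the count distribution.
#'
#' @param vocab An `msg_vocab` tibble with at least two tokens.
#' @return A tibble of class `huffman_tree` with columns `token`, `code`
#'   and `path` (list-columns; `path` holds one-based internal-node
#'   indices, root first, aligned with `code` bits). The number of internal
#'   nodes (`n_leaves - 1`) is kept in the `n_internal` attribute.
#' @export
build_huffman <- function(vocab) {
  n <- nrow(vocab)
  if (n < 2L) {
    stop("hierarchical softmax needs a vocabulary of at least 2 tokens",
         call. = FALSE)
  }
  n_nodes <- 2L * n - 1L
  count <- c(as.numeric(vocab$count), rep(NA_real_, n - 1L))
  parent <- integer(n_nodes)
  bit <- integer(n_nodes)
  alive <- c(rep(TRUE, n), rep(FALSE, n - 1L))
  for (m in seq_len(n - 1L)) {
    idx <- which(alive)
    ord <- idx[order(count[idx], idx)]
    left <- ord[1]; right <- ord[2]
    node <- n + m
    count[node] <- count[left] + count[right]
    parent[c(left, right)] <- node
    bit[left] <- 0L; bit[right] <- 1L
    alive[c(left, right)] <- FALSE
    alive[node] <- TRUE
  }
  root <- n_nodes
  codes <- vector("list", n)
  paths <- vector("list", n)
  for (i in seq_len(n)) {
    code <- integer(0)
    path <- integer(0)
    node <- i
    while (node != root) {
      code <- c(bit[node], code)
      path <- c(parent[node] - n, path)  # internal nodes numbered 1..n-1
      node <- parent[node]
    }
    codes[[i]] <- code
    paths[[i]] <- path
  }
  structure(
    tibble::tibble(token = vocab$token, code = codes, path = paths),
    n_internal = n - 1L,
    class = c("huffman_tree", class(tibble::tibble()))
  )
}
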