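#' Read a pipe-delimited adverse-event report corpus
#'
#' Parses the plain-text exchange format for preprocessed adverse-event
#' reports: one report per line, drug concept IDs left of a single `|`,
#' reaction concept IDs right of it, tokens separated by whitespace.
#' Duplicate tokens within a side are collapsed (contexts are sets), order
#' of first appearance is preserved, and blank lines are skipped.
#'
#' @param path Path to the corpus file.
#' @return A tibble of class `report_corpus` with one row per report and
#'   columns `report_id` (line-order integer), `drugs` and `reactions`
#'   (list-columns of character token vectors). The source path is kept in
#'   the `source_path` attribute.
#' @examples
#' f <- tempfile()
#' writeLines(c("1327356 1112807 | 35104086 35304314", "100 | "), f)
#' read_reports(f)
#' @export
read_reports <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) {
    stop("report corpus file does not exist: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*$", lines))
  n_sep <- lengths(regmatches(lines[keep], gregexpr("\\|", lines[keep])))
  bad <- keep[n_sep != 1L]
  if (length(bad) > 0L) {
    stop("malformed report line(s) ", paste(bad, collapse = ", "),
         ": expected exactly one '|' separator", call. = FALSE)
  }
  parse_side <- function(x) setdiff(unique(strsplit(trimws(x), "\\s+")[[1]]), "")
  sides <- strsplit(sub("\\|", "\x01", lines[keep]), "\x01", fixed = TRUE)
  corpus <- tibble::tibble(
    report_id = seq_along(keep),
    drugs     = purrr::map(sides, ~ parse_side(.x[1])),
    reactions = purrr::map(sides, ~ parse_side(if (length(.x) > 1L) .x[2] else ""))
  )
  new_report_corpus(corpus, source_path = path)
}

new_report_corpus <- function(corpus, source_path = NA_character_) {
  corpus <- tibble::as_tibble(corpus)
  stopifnot(all(c("report_id", "drugs", "reactions") %in% names(corpus)))
  structure(corpus,
            source_path = source_path,
            class = c("report_corpus", class(tibble::tibble())))
}

#' Assemble a report corpus from in-memory token sets
#'
#' @param drugs,reactions Lists of character vectors, one element per report.
#'   Within-report duplicates are collapsed, mirroring [read_reports()].
#' @return A `report_corpus` tibble.
#' @export
report_corpus <- function(drugs, reactions) {
  stopifnot(length(drugs) == length(reactions))
  new_report_corpus(tibble::tibble(
    report_id = seq_along(drugs),
    drugs     = purrr::map(drugs, ~ unique(as.character(.x))),
    reactions = purrr::map(reactions, ~ unique(as.character(.x)))
  ))
}

#' Write a report corpus in the pipe-delimited exchange format
#'
#' Inverse of [read_reports()]: re-reading the written file yields
#' identical reports.
#'
#' @param corpus A `report_corpus` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reports <- function(corpus, path) {
  lines <- purrr::map2_chr(
    corpus$drugs, corpus$reactions,
    ~ paste(paste(.x, collapse = " "), "|", paste(.y, collapse = " "))
  )
  writeLines(lines, path)
  invisible(path)
}

canonical_pair <- function(a, b) {
  swap <- a > b
  tibble::tibble(drug_a = ifelse(swap, b, a), drug_b = ifelse(swap, a, b))
}

#' Read drug-drug interaction records
#'
#' Reads a tab-separated file `drug_a<TAB>drug_b<TAB>description`. Pairs are
#' unordered: each is canonicalised by sorting the two IDs, and records with
#' the same canonical pair and case-insensitively equal description collapse
#' to one (mirrored pairs carry the same knowledge once). Records with
#' distinct descriptions are kept separately. Self-pairs are rejected.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `drug_a`, `drug_b` (canonical order) and
#'   `description`.
#' @export
read_ddi_records <- function(path) {
  raw <- read_tsv_fields(path, 3L, "DDI")
  if (nrow(raw) == 0L) {
    return(tibble::tibble(drug_a = character(), drug_b = character(),
                          description = character()))
  }
  names(raw) <- c("drug_a", "drug_b", "description")
  self <- raw$drug_a == raw$drug_b
  if (any(self)) {
    stop("self-interacting DDI record(s) at line(s) ",
         paste(which(self), collapse = ", "), call. = FALSE)
  }
  cp <- canonical_pair(raw$drug_a, raw$drug_b)
  tibble::tibble(drug_a = cp$drug_a, drug_b = cp$drug_b,
                 description = raw$description) %>%
    dplyr::mutate(.dedup_key = tolower(.data$description)) %>%
    dplyr::distinct(.data$drug_a, .data$drug_b, .data$.dedup_key,
                    .keep_all = TRUE) %>%
    dplyr::select("drug_a", "drug_b", "description")
}

read_tsv_fields <- function(path, n_fields, what) {
  if (!file.exists(path)) {
    stop(what, " file does not exist: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0L) {
    return(tibble::as_tibble(matrix(character(), 0, n_fields),
                             .name_repair = ~ paste0("V", seq_len(n_fields))))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < n_fields)
  if (length(short) > 0L) {
    stop("malformed line(s) in ", what, " file ", path, ": ",
         paste(short, collapse = ", "), " (expected ", n_fields,
         " tab-separated fields)", call. = FALSE)
  }
  # extra tabs inside the final free-text field are re-joined
  rows <- purrr::map(parts, function(p) {
    c(p[seq_len(n_fields - 1L)],
      paste(p[n_fields:length(p)], collapse = "\t"))
  })
  tibble::as_tibble(do.call(rbind, rows),
                    .name_repair = ~ paste0("V", seq_len(n_fields)))
}

#' Read the label resources used by the positive-labeling strategies
#'
#' Loads the four side datasets that drive drug-pair labeling and
#' enrichment validation: per-class drug lists (SIDER-style, TSV
#' `class_name<TAB>drug_id`), drug toxicity records (TSV
#' `drug<TAB>description`), DDI records (see [read_ddi_records()]), and the
#' reaction-to-System-Organ-Class map (TSV `reaction_id<TAB>soc_label`).
#' A missing SOC file yields an empty map with a warning, so validation
#' treats every reaction as unmapped rather than failing.
#'
#' @param sider_path,toxicity_path,ddi_path,soc_path File paths.
#' @return A list of class `label_resources` with tibbles `sider_lists`
#'   (`class_name`, `drug`), `toxicity_records` (`drug`, `description`),
#'   `ddi_records`, and `soc_map` (`reaction`, `soc_label`).
#' @export
read_label_resources <- function(sider_path, toxicity_path, ddi_path, soc_path) {
  sider <- read_tsv_fields(sider_path, 2L, "drug-list")
  names(sider) <- c("class_name", "drug")
  tox <- read_tsv_fields(toxicity_path, 2L, "toxicity")
  names(tox) <- c("drug", "description")
  ddi <- read_ddi_records(ddi_path)
  if (file.exists(soc_path)) {
    soc <- read_tsv_fields(soc_path, 2L, "SOC map")
    names(soc) <- c("reaction", "soc_label")
  } else {
    warning("SOC map file not found (", soc_path,
            "); using an empty reaction-to-SOC map", call. = FALSE)
    soc <- tibble::tibble(reaction = character(), soc_label = character())
  }
  label_resources(sider_lists = dplyr::distinct(sider),
                  toxicity_records = tox,
                  ddi_records = ddi,
                  soc_map = dplyr::distinct(soc))
}

#' Construct label resources from in-memory tibbles
#'
#' @param sider_lists Tibble `class_name`, `drug`.
#' @param toxicity_records Tibble `drug`, `description`.
#' @param ddi_records Tibble `drug_a`, `drug_b`, `description`.
#' @param soc_map Tibble `reaction`, `soc_label`.
#' @return A list of class `label_resources`.
#' @export
label_resources <- function(sider_lists, toxicity_records, ddi_records, soc_map) {
  structure(list(sider_lists = tibble::as_tibble(sider_lists),
                 toxicity_records = tibble::as_tibble(toxicity_records),
                 ddi_records = tibble::as_tibble(ddi_records),
                 soc_map = tibble::as_tibble(soc_map)),
            class = "label_resources")
}

#' Read event-class definitions
#'
#' TSV layout: `class_name<TAB>soc_label<TAB>keyword1,keyword2,...`.
#' Keywords are lower-cased; each class must declare at least one.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `class_name`, `soc_label` and the
#'   list-column `keywords`.
#' @export
read_event_classes <- function(path) {
  raw <- read_tsv_fields(path, 3L, "event-class")
  names(raw) <- c("class_name", "soc_label", "keywords")
  out <- raw %>%
    dplyr::mutate(keywords = purrr::map(
      .data$keywords,
      ~ setdiff(trimws(tolower(strsplit(.x, ",", fixed = TRUE)[[1]])), "")))
  if (any(lengths(out$keywords) == 0L)) {
    stop("event class with empty keyword list in ", path, call. = FALSE)
  }
  out
}

#' Write embeddings in the plain-text word-vector format
#'
#' Writes the interoperable text format used by common embedding tooling: a
#' header line `<n_tokens> <dim>` followed by one `<token> <v1> ... <vdim>`
#' line per token, values at 6 decimal places.
#'
#' @param vectors A numeric matrix with one row per token; row names are the
#'   tokens. An [msg_model] may be passed directly (its input vectors are
#'   written).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(vectors, path) {
  if (inherits(vectors, "msg_model")) vectors <- vectors$input_vectors
  stopifnot(is.matrix(vectors), is.numeric(vectors))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(vectors), ncol(vectors)), con)
  if (nrow(vectors) > 0L) {
    body <- paste(rownames(vectors),
                  apply(vectors, 1L, function(v)
                    paste(sprintf("%.6f", v), collapse = " ")))
    writeLines(body, con)
  }
  invisible(path)
}

#' Read embeddings written by [write_embeddings()]
#'
#' @param path Path to the embedding text file.
#' @return A numeric matrix, tokens as row names.
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty embedding file: ", path, call. = FALSE)
  header <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(header) != 2L || anyNA(header)) {
    stop("malformed embedding header in ", path, call. = FALSE)
  }
  n <- header[1]; dim <- header[2]
  body <- lines[-1]
  body <- body[!grepl("^\\s*$", body)]
  if (length(body) != n) {
    stop("embedding file ", path, " declares ", n, " tokens but has ",
         length(body), " vector lines", call. = FALSE)
  }
  if (n == 0L) {
    return(matrix(numeric(), 0L, dim))
  }
  parts <- strsplit(trimws(body), "\\s+")
  if (any(lengths(parts) != dim + 1L)) {
    stop("embedding dimension mismatch in ", path, ": expected ", dim,
         " values per token", call. = FALSE)
  }
  mat <- do.call(rbind, purrr::map(parts, ~ as.numeric(.x[-1])))
  rownames(mat) <- purrr::map_chr(parts, 1L)
  if (anyNA(mat)) stop("non-numeric embedding values in ", path, call. = FALSE)
  mat
}
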