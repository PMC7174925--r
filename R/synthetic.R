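#' Generate a synthetic adverse-event data bundle with planted classes
#'
#' Emulates the statistical structure the pipeline assumes: a handful of
#' adverse-event classes, each with its own drug pool and reaction pool
#' that co-occur in reports, against a background of unrelated drugs and
#' reactions. Every report carries exactly two drugs (mirroring the
#' two-drug report filter applied to regulatory corpora); each drug slot
#' is drawn from the report's class pool with probability `signal`, else
#' from the background pool, and each reaction is independently replaced
#' by a background reaction with probability `noise_rate`. Alongside the
#' corpus the generator emits every side resource the labeling and
#' enrichment stages need — per-class drug lists, toxicity records with a
#' synthetic class keyword embedded in the text, interaction records with
#' keyword-bearing descriptions, a reaction-to-SOC map — plus the ground
#' truth they were derived from. Everything is reproducible from `seed`.
#'
#' @param n_classes Number of planted event classes (default 5).
#' @param drugs_per_class,background_drugs Drug pool sizes (defaults 40, 40).
#' @param reactions_per_class,background_reactions Reaction pool sizes
#'   (defaults 15, 60).
#' @param n_reports Number of reports (default 2000).
#' @param signal Probability that a class report draws a drug slot from its
#'   class pool (default 0.8).
#' @param reactions_per_report Integer range (length-2 vector) of reactions
#'   per report (default `c(2, 4)`).
#' @param noise_rate Per-reaction background substitution probability
#'   (default 0.1).
#' @param ddis_per_class Interaction records emitted per class (default 30).
#' @param toxicity_fraction Fraction of each class's drugs given a
#'   keyword-bearing toxicity record (default 0.5).
#' @param seed Integer seed.
#' @return An object of class `synth_bundle`: list with `corpus`
#'   (`report_corpus`), `resources` (`label_resources`), `event_classes`
#'   (tibble `class_name`, `soc_label`, `keywords`), `ground_truth` (drug
#'   and reaction class assignments and the truly interacting pairs per
#'   class), and `params`.
#' @examples
#' b <- synth_bundle(n_reports = 50, seed = 1)
#' b$corpus
#' @export
synth_bundle <- function(n_classes = 5L, drugs_per_class = 40L,
                         background_drugs = 40L, reactions_per_class = 15L,
                         background_reactions = 60L, n_reports = 2000L,
                         signal = 0.8, reactions_per_report = c(2L, 4L),
                         noise_rate = 0.1, ddis_per_class = 30L,
                         toxicity_fraction = 0.5, seed = 1L) {
  stopifnot(n_classes >= 1L, drugs_per_class >= 2L, background_drugs >= 2L,
            reactions_per_class >= 1L, background_reactions >= 1L,
            n_reports >= 1L, signal >= 0, signal <= 1,
            noise_rate >= 0, noise_rate <= 1,
            length(reactions_per_report) == 2L,
            reactions_per_report[1] >= 1L,
            reactions_per_report[1] <= reactions_per_report[2])
  if (reactions_per_report[2] > reactions_per_class ||
      reactions_per_report[2] > background_reactions) {
    stop("reactions_per_report exceeds a reaction pool size", call. = FALSE)
  }
  if (ddis_per_class > choose(drugs_per_class, 2)) {
    stop("ddis_per_class exceeds the number of distinct class drug pairs",
         call. = FALSE)
  }
  set.seed(seed)

  # token alphabets: numeric-style concept IDs, drugs and reactions disjoint
  n_drugs <- n_classes * drugs_per_class + background_drugs
  n_reacts <- n_classes * reactions_per_class + background_reactions
  drug_ids <- as.character(1000L + seq_len(n_drugs))
  react_ids <- as.character(35000000L + seq_len(n_reacts))
  drug_class <- c(rep(seq_len(n_classes), each = drugs_per_class),
                  rep(0L, background_drugs))
  react_class <- c(rep(seq_len(n_classes), each = reactions_per_class),
                   rep(0L, background_reactions))
  drug_pool <- split(drug_ids, drug_class)    # "0" = background
  react_pool <- split(react_ids, react_class)

  classes <- tibble::tibble(
    class_name = paste0("class", seq_len(n_classes)),
    soc_label = paste0("Class ", seq_len(n_classes), " disorders"),
    keywords = purrr::map(seq_len(n_classes), ~ paste0("class", .x, "tox"))
  )
  background_soc <- "Background disorders"

  # reports
  report_class <- sample(0:n_classes, n_reports, replace = TRUE)
  draw_drugs <- function(cls) {
    pools <- if (cls == 0L) c("0", "0") else
      ifelse(stats::runif(2) < signal, as.character(cls), "0")
    if (pools[1] == pools[2]) {
      sample(drug_pool[[pools[1]]], 2L)
    } else {
      c(sample(drug_pool[[pools[1]]], 1L), sample(drug_pool[[pools[2]]], 1L))
    }
  }
  draw_reactions <- function(cls) {
    n_r <- sample(reactions_per_report[1]:reactions_per_report[2], 1L)
    src <- if (cls == 0L) "0" else as.character(cls)
    r <- sample(react_pool[[src]], n_r)
    swap <- stats::runif(n_r) < noise_rate
    if (any(swap)) {
      r[swap] <- sample(react_pool[["0"]], sum(swap), replace = TRUE)
    }
    unique(r)
  }
  drugs <- purrr::map(report_class, draw_drugs)
  reactions <- purrr::map(report_class, draw_reactions)
  corpus <- new_report_corpus(tibble::tibble(
    report_id = seq_len(n_reports), drugs = drugs, reactions = reactions))

  # side resources derived from the ground truth
  sider <- tibble::tibble(
    class_name = classes$class_name[drug_class[drug_class > 0L]],
    drug = drug_ids[drug_class > 0L])
  tox <- purrr::map_dfr(seq_len(n_classes), function(k) {
    pool <- drug_pool[[as.character(k)]]
    n_tox <- max(1L, round(toxicity_fraction * length(pool)))
    tibble::tibble(
      drug = sort(sample(pool, n_tox)),
      description = paste0("preclinical studies observed ",
                           classes$keywords[[k]], " at high doses"))
  })
  ddi <- purrr::map_dfr(seq_len(n_classes), function(k) {
    pool <- drug_pool[[as.character(k)]]
    all_pairs <- utils::combn(sort(pool), 2L)
    take <- sample(ncol(all_pairs), ddis_per_class)
    tibble::tibble(
      drug_a = all_pairs[1, take], drug_b = all_pairs[2, take],
      description = paste0("coadministration increases the risk of ",
                           classes$keywords[[k]]),
      class_name = classes$class_name[k])
  })
  bg_pairs <- utils::combn(sort(drug_pool[["0"]]), 2L)
  bg_take <- sample(ncol(bg_pairs), min(ddis_per_class, ncol(bg_pairs)))
  ddi_bg <- tibble::tibble(
    drug_a = bg_pairs[1, bg_take], drug_b = bg_pairs[2, bg_take],
    description = "no clinically notable interaction reported",
    class_name = NA_character_)
  ddi_all <- dplyr::bind_rows(ddi, ddi_bg)
  soc <- tibble::tibble(
    reaction = react_ids,
    soc_label = ifelse(react_class > 0L,
                       paste0("Class ", react_class, " disorders"),
                       background_soc))
  resources <- label_resources(
    sider_lists = sider,
    toxicity_records = tox,
    ddi_records = ddi_all %>% dplyr::select("drug_a", "drug_b", "description"),
    soc_map = soc)

  structure(list(
    corpus = corpus,
    resources = resources,
    event_classes = classes,
    ddi_classes = ddi_all,
    ground_truth = list(
      drug_class = stats::setNames(drug_class, drug_ids),
      reaction_class = stats::setNames(react_class, react_ids),
      interacting_pairs = ddi %>% dplyr::select("class_name", "drug_a", "drug_b"),
      report_class = report_class),
    params = list(n_classes = n_classes, drugs_per_class = drugs_per_class,
                  background_drugs = background_drugs,
                  reactions_per_class = reactions_per_class,
                  background_reactions = background_reactions,
                  n_reports = n_reports, signal = signal,
                  reactions_per_report = reactions_per_report,
                  noise_rate = noise_rate, ddis_per_class = ddis_per_class,
                  toxicity_fraction = toxicity_fraction, seed = seed)),
    class = "synth_bundle")
}

#' @export
print.synth_bundle <- function(x, ...) {
  p <- x$params
  cat("Synthetic adverse-event bundle:", p$n_reports, "reports,",
      p$n_classes, "classes\n")
  cat("  signal:", p$signal, " noise_rate:", p$noise_rate,
      " seed:", p$seed, "\n")
  invisible(x)
}

#' Write a synthetic bundle to disk in the exchange formats
#'
#' Emits `reports.txt`, `sider.tsv`, `toxicity.tsv`, `ddi.tsv`, `soc.tsv`
#' and `event_classes.tsv` in exactly the layouts the readers in this
#' package consume, so a generated bundle round-trips through the file
#' interface.
#'
#' @param bundle A `synth_bundle`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(reports = file.path(dir, "reports.txt"),
             sider = file.path(dir, "sider.tsv"),
             toxicity = file.path(dir, "toxicity.tsv"),
             ddi = file.path(dir, "ddi.tsv"),
             soc = file.path(dir, "soc.tsv"),
             event_classes = file.path(dir, "event_classes.tsv"))
  write_reports(bundle$corpus, paths[["reports"]])
  r <- bundle$resources
  writeLines(paste(r$sider_lists$class_name, r$sider_lists$drug, sep = "\t"),
             paths[["sider"]])
  writeLines(paste(r$toxicity_records$drug, r$toxicity_records$description,
                   sep = "\t"), paths[["toxicity"]])
  writeLines(paste(r$ddi_records$drug_a, r$ddi_records$drug_b,
                   r$ddi_records$description, sep = "\t"), paths[["ddi"]])
  writeLines(paste(r$soc_map$reaction, r$soc_map$soc_label, sep = "\t"),
             paths[["soc"]])
  writeLines(paste(bundle$event_classes$class_name,
                   bundle$event_classes$soc_label,
                   purrr::map_chr(bundle$event_classes$keywords,
                                  paste, collapse = ","), sep = "\t"),
             paths[["event_classes"]])
  invisible(paths)
}

#' Per-class positive-resource counts of a bundle
#'
#' Tabulates, by scanning the emitted resources (not the ground truth),
#' how many positive reference records each labeling strategy contributes
#' per class: drugs in the class list, distinct drugs whose toxicity text
#' contains a class keyword, and unique interaction records whose
#' description contains a class keyword.
#'
#' @param bundle A `synth_bundle`.
#' @return A tibble with columns `class_name`, `n_sider_drugs`,
#'   `n_toxicity_drugs`, `n_ddi_pairs`.
#' @export
summarize_bundle <- function(bundle) {
  r <- bundle$resources
  purrr::map_dfr(seq_len(nrow(bundle$event_classes)), function(i) {
    cls <- bundle$event_classes[i, ]
    kw <- cls$keywords[[1]]
    tibble::tibble(
      class_name = cls$class_name,
      n_sider_drugs = sum(r$sider_lists$class_name == cls$class_name),
      n_toxicity_drugs = length(unique(
        r$toxicity_records$drug[keyword_hit(r$toxicity_records$description, kw)])),
      n_ddi_pairs = sum(keyword_hit(r$ddi_records$description, kw)))
  })
}
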