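#' Assign DDI records to event classes by keyword match
#'
#' A DDI record belongs to an event class when its description contains
#' (case-insensitive substring) any of the class's keywords; a record can
#' belong to several classes and unmatched records are dropped.
#'
#' @param ddi_records Tibble `drug_a`, `drug_b`, `description`.
#' @param event_classes Tibble `class_name`, `soc_label`, `keywords`.
#' @return Tibble `drug_a`, `drug_b`, `description`, `class_name`.
#' @export
assign_ddi_classes <- function(ddi_records, event_classes) {
  purrr::map_dfr(seq_len(nrow(event_classes)), function(i) {
    cls <- event_classes[i, ]
    hit <- keyword_hit(ddi_records$description, cls$keywords[[1]])
    ddi_records[hit, , drop = FALSE] %>%
      dplyr::mutate(class_name = cls$class_name)
  })
}

#' Default experiment configuration
#'
#' A flat named list of every knob of [run_pipeline()]. Input paths left
#' empty mean "generate a synthetic bundle" with the `gen_*` parameters;
#' when `reports_path` is set the five companion paths must be set too.
#'
#' @param ... Overrides of the defaults, `key = value`. Unknown keys are
#'   rejected.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    out_dir = tempfile("msgddi_run_"),
    seed = 1L,
    # input files; empty => synthesise
    reports_path = "", sider_path = "", toxicity_path = "", ddi_path = "",
    soc_path = "", event_classes_path = "",
    # generator
    gen_n_reports = 2000L, gen_n_classes = 5L, gen_drugs_per_class = 40L,
    gen_background_drugs = 40L, gen_reactions_per_class = 15L,
    gen_background_reactions = 60L, gen_signal = 0.8, gen_noise_rate = 0.1,
    gen_ddis_per_class = 30L, gen_toxicity_fraction = 0.5,
    # model
    dim = 100L, epochs = 5L, alpha0 = 0.025, min_alpha = 1e-4, min_count = 10L,
    # baseline
    skip_tfidf = FALSE, tfidf_k = 0L,  # 0 => same as dim
    # evaluation
    folds = 10L, lambda = 0.01, balance = TRUE,
    # enrichment
    top_k = 20L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, overrides)
  structure(cfg, class = "pipeline_config")
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value` (comments starting with `#` and blank
#' lines ignored); values are coerced to the type of the corresponding
#' [pipeline_config()] default. Unknown keys are rejected.
#'
#' @param path Path to the config file.
#' @param ... Further overrides applied on top of the file.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[lines != ""]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) < 2L)) {
    stop("malformed config line(s) in ", path, call. = FALSE)
  }
  keys <- trimws(purrr::map_chr(kv, 1L))
  vals <- trimws(purrr::map_chr(kv, ~ paste(.x[-1], collapse = "=")))
  defaults <- pipeline_config()
  parsed <- purrr::map2(keys, vals, function(k, v) {
    proto <- defaults[[k]]
    if (is.null(proto)) return(v)  # caught by pipeline_config()
    switch(class(proto)[1],
           integer = as.integer(v),
           numeric = as.numeric(v),
           logical = as.logical(v),
           v)
  })
  do.call(pipeline_config, c(stats::setNames(parsed, keys), list(...)))
}

fmt6 <- function(x) sprintf("%.6f", x)

write_tsv_plain <- function(df, path) {
  num <- purrr::map_lgl(df, is.double)
  df[num] <- lapply(df[num], fmt6)
  lines <- c(paste(names(df), collapse = "\t"),
             do.call(paste, c(unname(as.list(df)), sep = "\t")))
  writeLines(lines, path)
}

#' Run the full experiment pipeline
#'
#' Executes the workflow end to end: load (or synthesise) the inputs,
#' build the vocabulary, train the modified skip-gram model, build the
#' TF-IDF/PCA baseline, label candidate drug pairs per event class,
#' estimate cross-validated AUROC for both feature sources, enrich the
#' class-assigned DDI records, and tabulate enrichment accuracy. All
#' artifacts (embeddings, per-fold AUROC, ROC points, enrichment rows,
#' accuracy table, resolved configuration, run log) are written under
#' `config$out_dir` with fixed 6-decimal formatting, so two runs with the
#' same configuration and seed produce byte-identical files.
#'
#' @param config A `pipeline_config` list.
#' @param quiet Suppress progress messages (default FALSE).
#' @return Invisibly, a list of class `pipeline_result` with the fitted
#'   objects (`model`, `tfidf_features`, `cv` tibble, `enrichment`,
#'   `accuracy`, `bundle` when synthesised) and `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  say <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message("[msgddi] ", line)
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- inputs ---------------------------------------------------------
  bundle <- NULL
  if (nzchar(config$reports_path)) {
    stage("load-inputs", {
      corpus <- read_reports(config$reports_path)
      resources <- read_label_resources(config$sider_path, config$toxicity_path,
                                        config$ddi_path, config$soc_path)
      event_classes <- read_event_classes(config$event_classes_path)
    })
    say("loaded ", nrow(corpus), " reports from ", config$reports_path)
  } else {
    stage("generate", {
      bundle <- synth_bundle(
        n_classes = config$gen_n_classes,
        drugs_per_class = config$gen_drugs_per_class,
        background_drugs = config$gen_background_drugs,
        reactions_per_class = config$gen_reactions_per_class,
        background_reactions = config$gen_background_reactions,
        n_reports = config$gen_n_reports, signal = config$gen_signal,
        noise_rate = config$gen_noise_rate,
        ddis_per_class = config$gen_ddis_per_class,
        toxicity_fraction = config$gen_toxicity_fraction,
        seed = config$seed)
      corpus <- bundle$corpus
      resources <- bundle$resources
      event_classes <- bundle$event_classes
    })
    say("generated synthetic bundle: ", nrow(corpus), " reports, ",
        config$gen_n_classes, " classes, signal ", config$gen_signal)
  }

  # --- embeddings -----------------------------------------------------
  model <- stage("train-msg", msg_train(
    corpus, dim = config$dim, alpha0 = config$alpha0,
    min_alpha = config$min_alpha, epochs = config$epochs,
    min_count = config$min_count, seed = config$seed))
  say("trained MSG: ", nrow(model$vocab), " tokens, dim ", config$dim,
      ", final mean log-likelihood ", fmt6(utils::tail(model$objective, 1L)))
  write_embeddings(model, file.path(config$out_dir, "msg_embeddings.txt"))
  write_tsv_plain(tibble::as_tibble(model$vocab),
                  file.path(config$out_dir, "vocab.tsv"))

  tfidf_features <- NULL
  if (!config$skip_tfidf) {
    k <- if (config$tfidf_k > 0L) config$tfidf_k else config$dim
    tfidf_features <- stage("train-tfidf", {
      tm <- build_tfidf(corpus, model$vocab)
      reduce_pca(tm, k = min(k, length(tm$terms), tm$n_reports))
    })
    say("built CM-TF-IDF baseline, PCA to ", ncol(tfidf_features$vectors),
        " components")
    write_embeddings(tfidf_features$vectors,
                     file.path(config$out_dir, "tfidf_embeddings.txt"))
  }

  # --- labeling + cross-validation ------------------------------------
  rdl <- intersect(model$vocab$token[model$vocab$kind == "drug"],
                   unique(c(resources$ddi_records$drug_a,
                            resources$ddi_records$drug_b)))
  pairs <- observed_pairs(corpus, reference_drugs = rdl)
  say("candidate universe: ", nrow(pairs), " drug pairs over ",
      length(rdl), " reference drugs")
  sources <- c("MSG", if (!config$skip_tfidf) "CM-TF-IDF")
  cv <- purrr::map_dfr(seq_len(nrow(event_classes)), function(i) {
    cls <- event_classes[i, ]
    labeled <- label_pairs(pairs, resources, cls)
    if (config$balance) {
      labeled <- balance_negatives(labeled, seed = config$seed + 17L)
    }
    purrr::map_dfr(sources, function(src) {
      vecs <- if (src == "MSG") model$input_vectors else tfidf_features$vectors
      res <- stage(paste0("crossval-", cls$class_name, "-", src),
                   crossval_auroc(pair_features(vecs, labeled), labeled,
                                  n_folds = config$folds,
                                  seed = config$seed + 29L,
                                  lambda = config$lambda))
      say("  ", cls$class_name, " / ", src, ": mean AUROC ",
          fmt6(res$mean_auroc), " over ", nrow(labeled), " pairs")
      tibble::tibble(class_name = cls$class_name, feature_source = src,
                     n_pairs = nrow(labeled),
                     n_positive = sum(labeled$label == "positive"),
                     fold = list(res$folds$auroc),
                     mean_auroc = res$mean_auroc,
                     roc = list(res$roc))
    })
  })
  cv_flat <- cv %>%
    tidyr::unnest_longer("fold", values_to = "auroc", indices_to = "fold_id") %>%
    dplyr::select("class_name", "feature_source", "fold_id", "auroc",
                  "mean_auroc")
  write_tsv_plain(cv_flat, file.path(config$out_dir, "cv_results.tsv"))
  roc_flat <- cv %>%
    dplyr::select("class_name", "feature_source", "roc") %>%
    tidyr::unnest("roc")
  write_tsv_plain(roc_flat, file.path(config$out_dir, "roc_points.tsv"))

  # --- enrichment -----------------------------------------------------
  class_ddis <- assign_ddi_classes(resources$ddi_records, event_classes) %>%
    dplyr::filter(.data$drug_a %in% model$vocab$token,
                  .data$drug_b %in% model$vocab$token)
  candidates <- model$vocab$token[model$vocab$kind == "reaction"]
  enrichment <- stage("enrich", enrich_ddis(
    model, class_ddis, event_classes, resources$soc_map,
    candidates = candidates, k = config$top_k))
  accuracy <- accuracy_table(enrichment)
  say("enrichment: ", sum(enrichment$valid), "/", nrow(enrichment),
      " valid; pooled accuracy ",
      fmt6(accuracy$accuracy[accuracy$class_name == "Total"]))
  soc_lookup <- stats::setNames(resources$soc_map$soc_label,
                                resources$soc_map$reaction)
  enrich_flat <- enrichment %>%
    tibble::as_tibble() %>%
    dplyr::select("class_name", "drug_a", "drug_b", "valid", "ranked") %>%
    tidyr::unnest("ranked") %>%
    dplyr::mutate(soc_label = dplyr::coalesce(soc_lookup[.data$reaction], ""))
  write_tsv_plain(enrich_flat, file.path(config$out_dir, "enrichment.tsv"))
  write_tsv_plain(accuracy, file.path(config$out_dir, "accuracy_table.tsv"))

  # --- provenance -----------------------------------------------------
  cfg_lines <- purrr::imap_chr(unclass(config)[order(names(unclass(config)))],
                               ~ paste0(.y, " = ", .x))
  writeLines(cfg_lines, file.path(config$out_dir, "config.txt"))
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))

  invisible(structure(list(model = model, tfidf_features = tfidf_features,
                           cv = cv, enrichment = enrichment,
                           accuracy = accuracy, bundle = bundle,
                           config = config, out_dir = config$out_dir),
                      class = "pipeline_result"))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("msgddi pipeline run:", x$out_dir, "\n")
  print(x$cv %>% dplyr::select("class_name", "feature_source", "mean_auroc"))
  print(x$accuracy)
  invisible(x)
}
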