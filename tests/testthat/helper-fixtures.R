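# In-code fixtures shared across test files.

write_lines_tmp <- function(lines) {
  f <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# A model object with random vectors over a synthetic vocabulary, for
# probability/normalization checks that do not need training.
random_model <- function(n_tokens, dim, seed) {
  set.seed(seed)
  n_drugs <- max(1L, n_tokens %/% 2L)
  vocab <- tibble::tibble(
    token = c(paste0("d", seq_len(n_drugs)),
              paste0("r", seq_len(n_tokens - n_drugs))),
    count = sample(1:50, n_tokens, replace = TRUE),
    kind = rep(c("drug", "reaction"), c(n_drugs, n_tokens - n_drugs)),
    index = seq_len(n_tokens) - 1L
  )
  tree <- build_huffman(vocab)
  iv <- matrix(rnorm(n_tokens * dim), n_tokens, dim,
               dimnames = list(vocab$token, NULL))
  nv <- matrix(rnorm((n_tokens - 1L) * dim), n_tokens - 1L, dim)
  structure(list(vocab = vocab, tree = tree, input_vectors = iv,
                 node_vectors = nv,
                 params = list(dim = dim)),
            class = "msg_model")
}

# Small mixed corpus with two planted drug/reaction groups plus noise.
toy_corpus <- function(n_reports = 40L, seed = 1L) {
  set.seed(seed)
  drugs <- lapply(seq_len(n_reports), function(i) {
    grp <- if (i %% 2L == 0L) c("dA1", "dA2", "dA3") else c("dB1", "dB2", "dB3")
    sample(grp, 2L)
  })
  reactions <- lapply(seq_len(n_reports), function(i) {
    grp <- if (i %% 2L == 0L) c("rA1", "rA2", "rA3") else c("rB1", "rB2", "rB3")
    unique(sample(grp, 2L, replace = TRUE))
  })
  report_corpus(drugs, reactions)
}

toy_resources <- function() {
  label_resources(
    sider_lists = tibble::tibble(class_name = c("cardio", "cardio", "neuro"),
                                 drug = c("dA1", "dA2", "dB1")),
    toxicity_records = tibble::tibble(
      drug = c("dA3", "dB2"),
      description = c("severe cardiotoxicity observed", "mild sedation only")),
    ddi_records = tibble::tibble(
      drug_a = c("dB1", "dA1"), drug_b = c("dB3", "dB1"),
      description = c("combination is neurotoxic in rats",
                      "no interaction known")),
    soc_map = tibble::tibble(
      reaction = c("rA1", "rA2", "rB1", "rB2"),
      soc_label = c("Cardiac disorders", "Cardiac disorders",
                    "Nervous system disorders", "Nervous system disorders")))
}

toy_classes <- function() {
  tibble::tibble(
    class_name = c("cardio", "neuro"),
    soc_label = c("Cardiac disorders", "Nervous system disorders"),
    keywords = list("cardiotox", c("neurotoxic", "sedation")))
}
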