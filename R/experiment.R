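paradigm_specs <- function() {
  list(RCP = list(kind = "RCP"),
       CBP = list(kind = "CBP", virtual_shape = c(3L, 6L)),
       COMB9 = list(kind = "COMB", n = 9L, k = 2L),
       COMB7 = list(kind = "COMB", n = 7L, k = 3L, drop_symbols = TRUE))
}

base_codebook_for <- function(name, grid) {
  sp <- paradigm_specs()[[name]]
  if (is.null(sp)) stop("unknown paradigm: ", name)
  switch(sp$kind,
         RCP = rcp_codebook(grid),
         CBP = cbp_codebook(grid, sp$virtual_shape),
         COMB = comb_codebook(grid, sp$n, sp$k, sp$drop_symbols))
}

#' Experiment configuration
#'
#' Settings for a full simulated study: which paradigms to run, how many
#' synthetic subjects, each subject's per-flash separability d', decoder and
#' timing settings, the corpus, and the session texts (the study design: two
#' 10-character sessions, "THE QUICK " and "BROWN FOX ", spaces typed as
#' `"_"`).
#'
#' @param paradigms Subset of `c("RCP", "CBP", "COMB9", "COMB7")`.
#' @param n_subjects Number of synthetic subjects.
#' @param d_prime Per-subject separability; recycled to `n_subjects`. The
#'   default ladder 0.8..1.6 spans the range of SWLDA separabilities typical
#'   of healthy P300 cohorts, matched across paradigms within subject.
#' @param decoder A [decoder_config()].
#' @param timing A [timing_model()].
#' @param corpus A [corpus_counts()] vector, or `NULL` for the bundled
#'   synthetic corpus.
#' @param session_texts Character vector of texts typed per session.
#' @param n_calib_sessions Calibration sessions per paradigm (default 2).
#' @param calib_sets Flash sets per character during calibration (default 10,
#'   so every character is flashed 20 times under RCP).
#' @param smoothing_floor Language-model smoothing floor.
#' @param seed Integer seed recorded in the outputs.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(paradigms = c("RCP", "CBP", "COMB9"),
                              n_subjects = 10L,
                              d_prime = seq(0.8, 1.6, length.out = n_subjects),
                              decoder = decoder_config(),
                              timing = timing_model(),
                              corpus = NULL,
                              session_texts = c("THE_QUICK_", "BROWN_FOX_"),
                              n_calib_sessions = 2L,
                              calib_sets = 10L,
                              smoothing_floor = 1e-4,
                              seed = 1L) {
  stopifnot(all(paradigms %in% names(paradigm_specs())))
  if (is.null(corpus)) corpus <- read_corpus(
    system.file("extdata", "corpus_synthetic.txt", package = "pfspeller", mustWork = TRUE))
  grid <- make_grid()
  chars <- unique(unlist(strsplit(session_texts, "")))
  if (!all(chars %in% grid$symbols)) stop("session text uses symbols not on the grid")
  structure(list(paradigms = paradigms,
                 n_subjects = as.integer(n_subjects),
                 d_prime = rep_len(d_prime, n_subjects),
                 decoder = decoder, timing = timing,
                 corpus = corpus, grid = grid,
                 session_texts = session_texts,
                 n_calib_sessions = as.integer(n_calib_sessions),
                 calib_sets = as.integer(calib_sets),
                 smoothing_floor = smoothing_floor,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

subject_true_params <- function(config, subject) {
  score_model(mu_a = config$d_prime[subject], sigma_a = 1, mu_n = 0, sigma_n = 1)
}

#' Simulate calibration sessions and fit per-subject score models
#'
#' For each subject and paradigm, simulates `n_calib_sessions` sessions (one
#' session text each, cycled) of labeled flashes at `calib_sets` sets per
#' character and fits the two-Gaussian score model from the pooled flashes.
#'
#' @param config An [experiment_config()].
#' @return List of lists: `calib[[subject]][[paradigm]]` is a fitted
#'   [score_model()]; `attr(,"n_flashes")` records flash counts.
#' @export
run_calibration <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  lapply(seq_len(config$n_subjects), function(subj) {
    true <- subject_true_params(config, subj)
    fits <- lapply(config$paradigms, function(pname) {
      base <- base_codebook_for(pname, config$grid)
      vals <- numeric(0); labs <- logical(0)
      for (sess in seq_len(config$n_calib_sessions)) {
        text <- config$session_texts[(sess - 1L) %% length(config$session_texts) + 1L]
        for (ch in strsplit(text, "")[[1]]) {
          sched <- schedule_session(base, max_sets = config$calib_sets)
          sc <- simulate_scores(sched, ch, true)
          vals <- c(vals, sc$value); labs <- c(labs, sc$attended)
        }
      }
      fit <- fit_score_model(vals, labs)
      attr(fit, "n_flashes") <- length(vals)
      fit
    })
    stats::setNames(fits, config$paradigms)
  })
}

#' Run the online sessions and compute per-subject metrics
#'
#' For each subject and paradigm (order shuffled per subject, as in the study
#' design), decodes every session text with dynamic stopping — scores are
#' generated from the subject's true model, the decoder uses the calibrated
#' estimates — and pools the sessions into one metrics row per
#' subject x paradigm.
#'
#' @param config An [experiment_config()].
#' @param calib Output of [run_calibration()]; `NULL` runs calibration first.
#' @param out_dir Optional directory for a CSV report and JSON-lines decision
#'   logs.
#' @return List with `rows` (data frame subject/paradigm/sr/acc/br/itr),
#'   `report` (an [aggregate_report()]), `decodes` (nested decode objects),
#'   `calib`.
#' @export
run_online <- function(config, calib = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(calib)) calib <- run_calibration(config)
  lm <- build_lm(config$corpus, alphabet = config$grid$symbols,
                 smoothing_floor = config$smoothing_floor)
  set.seed(config$seed + 1L)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, config$n_subjects)
  rows <- list(); decodes <- list()
  for (subj in seq_len(config$n_subjects)) {
    set.seed(subject_seeds[subj])
    true <- subject_true_params(config, subj)
    order_p <- sample(config$paradigms)   # cosmetic randomized test order, logged
    decodes[[subj]] <- list()
    for (pname in order_p) {
      est <- calib[[subj]][[pname]]
      base <- base_codebook_for(pname, config$grid)
      outs <- character(0); sets <- integer(0); dists <- 0L
      runs <- list()
      for (text in config$session_texts) {
        dec <- decode_sequence(text, base, lm, est, config$decoder, gen_params = true)
        outs <- c(outs, dec$output); sets <- c(sets, dec$sets_used)
        dists <- dists + levenshtein(dec$output, text)
        runs[[length(runs) + 1L]] <- dec
      }
      n <- sum(nchar(config$session_texts))
      acc <- max(0, (n - dists) / n)
      sr <- selection_rate(sets, flashes_per_set(base), config$timing, n_chars = n)
      br <- max(0, bit_rate(acc, length(config$grid$symbols)))
      rows[[length(rows) + 1L]] <-
        data.frame(subject = subj, paradigm = pname, test_order = match(pname, order_p),
                   d_prime = config$d_prime[subj],
                   sr = sr, acc = 100 * acc, br = br, itr = br * sr)
      decodes[[subj]][[pname]] <- runs
    }
  }
  rows <- do.call(rbind, rows)
  rows <- rows[order(rows$subject, rows$paradigm), ]
  report <- aggregate_report(rows)
  if (!is.null(out_dir)) write_experiment_outputs(rows, report, decodes, config, out_dir)
  list(rows = rows, report = report, decodes = decodes, calib = calib)
}

#' Full pipeline: calibration then online decoding
#'
#' @inheritParams run_online
#' @return As [run_online()].
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL) {
  run_online(config, calib = run_calibration(config), out_dir = out_dir)
}

write_experiment_outputs <- function(rows, report, decodes, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(rows, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  mean_row <- report$mean
  utils::write.csv(mean_row, file.path(out_dir, "means.csv"), row.names = FALSE)
  jsonlite::write_json(list(seed = config$seed,
                            paradigms = config$paradigms,
                            tests = report$tests),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  log_path <- file.path(out_dir, "decisions.jsonl")
  con <- file(log_path, open = "wt")
  on.exit(close(con))
  for (subj in seq_along(decodes)) for (pname in names(decodes[[subj]]))
    for (dec in decodes[[subj]][[pname]])
      for (d in dec$decisions)
        writeLines(jsonlite::toJSON(c(list(subject = subj, paradigm = pname), d),
                                    auto_unbox = TRUE, digits = NA, null = "null"), con)
  invisible(out_dir)
}

#' Read an experiment configuration file (YAML or JSON)
#'
#' Recognized top-level keys mirror the [experiment_config()] arguments;
#' `decoder` and `timing` sub-maps are passed to their constructors;
#' `corpus` may name a corpus file path.
#'
#' @param path Configuration file.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE)) jsonlite::fromJSON(path)
         else yaml::read_yaml(path)
  bad <- setdiff(names(obj), c("paradigms", "n_subjects", "d_prime", "decoder", "timing",
                               "corpus", "session_texts", "n_calib_sessions",
                               "calib_sets", "smoothing_floor", "seed"))
  if (length(bad)) stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  args <- obj
  if (!is.null(obj$decoder)) args$decoder <- do.call(decoder_config, obj$decoder)
  if (!is.null(obj$timing)) args$timing <- do.call(timing_model, obj$timing)
  if (!is.null(obj$corpus) && is.character(obj$corpus)) args$corpus <- read_corpus(obj$corpus)
  do.call(experiment_config, args)
}
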