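#' Aggregate per-subject metrics into a table-style report
#'
#' Column means per paradigm (the "Mean" row of the published-style tables)
#' plus a Kruskal-Wallis comparison of each metric across paradigms.
#'
#' @param rows Data frame with columns `subject`, `paradigm`, and one column
#'   per metric (default `sr`, `acc`, `itr`).
#' @param metrics Metric column names to aggregate.
#' @return List with `mean` (paradigm x metric data frame) and `tests`
#'   (data frame metric / H / df / p).
#' @export
aggregate_report <- function(rows, metrics = intersect(c("sr", "acc", "itr"), names(rows))) {
  stopifnot(all(c("subject", "paradigm") %in% names(rows)), length(metrics) > 0)
  if (length(unique(rows$subject)) < 2L) stop("need at least 2 subjects")
  means <- stats::aggregate(rows[metrics], by = list(paradigm = rows$paradigm), FUN = mean)
  tests <- do.call(rbind, lapply(metrics, function(m) {
    if (length(unique(rows$paradigm)) < 2L)
      return(data.frame(metric = m, H = NA_real_, df = NA_real_, p = NA_real_))
    kw <- stats::kruskal.test(rows[[m]], factor(rows$paradigm))
    data.frame(metric = m, H = unname(kw$statistic), df = unname(kw$parameter),
               p = kw$p.value)
  }))
  list(mean = means, tests = tests)
}

#' Published per-subject performance tables
#'
#' The per-subject selection rate (characters/minute), accuracy (%) and ITR
#' (bits/minute) tables bundled with the package, in long format
#' (subject, paradigm, sr, acc, itr).
#'
#' @param which `"offline"` or `"online"`.
#' @return Data frame.
#' @export
speller_tables <- function(which = c("offline", "online")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   if (which == "offline") "table2_offline.csv" else "table3_online.csv",
                   package = "pfspeller", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}

#' Attended vs non-attended waveform analysis
#'
#' Given per-subject average attended and non-attended responses, computes
#' grand averages and tests each latency with a paired Wilcoxon signed-rank
#' test across subjects, controlling the false discovery rate with
#' Benjamini-Hochberg.
#'
#' @param attended,nonattended Subjects x time matrices of per-subject
#'   average responses (same dimensions).
#' @param alpha FDR level (default 0.05).
#' @return List with `grand_attended`, `grand_nonattended`, `difference`,
#'   `p` (per-latency raw p), `p_adj` (BH-adjusted), `mask` (logical,
#'   significant latencies), `alpha`.
#' @export
waveform_analysis <- function(attended, nonattended, alpha = 0.05) {
  attended <- as.matrix(attended); nonattended <- as.matrix(nonattended)
  if (!all(dim(attended) == dim(nonattended))) stop("epoch matrices must have equal dimensions")
  if (nrow(attended) < 5L) stop("need average responses from at least 5 subjects")
  p <- vapply(seq_len(ncol(attended)), function(j) {
    d <- attended[, j] - nonattended[, j]
    if (all(d == 0)) return(1)
    suppressWarnings(
      stats::wilcox.test(attended[, j], nonattended[, j], paired = TRUE)$p.value)
  }, numeric(1))
  p_adj <- stats::p.adjust(p, method = "BH")
  list(grand_attended = colMeans(attended),
       grand_nonattended = colMeans(nonattended),
       difference = colMeans(attended) - colMeans(nonattended),
       p = p, p_adj = p_adj, mask = p_adj < alpha, alpha = alpha)
}

#' Average per-subject responses from epoch collections
#'
#' Convenience helper: stacks each subject's mean attended and non-attended
#' epoch into the matrices [waveform_analysis()] expects.
#'
#' @param epoch_list List of [simulate_erp_epochs()] objects, one per subject.
#' @return List with `attended` and `nonattended` subjects x time matrices.
#' @export
subject_averages <- function(epoch_list) {
  att <- do.call(rbind, lapply(epoch_list, function(e) colMeans(e$attended)))
  non <- do.call(rbind, lapply(epoch_list, function(e) colMeans(e$nonattended)))
  list(attended = att, nonattended = non)
}
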