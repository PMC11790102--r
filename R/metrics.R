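#' Position-wise character accuracy
#'
#' Fraction of positions where output and target agree; both strings must
#' have the same length (use [ld_accuracy()] otherwise).
#'
#' @param output,target Strings.
#' @return Fraction in \[0, 1\].
#' @export
char_accuracy <- function(output, target) {
  a <- strsplit(output, "")[[1]]
  b <- strsplit(target, "")[[1]]
  if (length(a) != length(b)) stop("strings differ in length; use ld_accuracy()")
  if (length(b) == 0L) stop("empty target")
  mean(a == b)
}

#' Levenshtein edit distance
#'
#' Minimal number of single-character insertions, deletions and substitutions
#' (unit costs) turning `a` into `b`.
#'
#' @param a,b Strings.
#' @return Integer distance.
#' @export
levenshtein <- function(a, b) {
  as.integer(utils::adist(a, b)[1L, 1L])
}

#' Levenshtein-based typing accuracy
#'
#' `(n - LD(output, target)) / n` with `n` the target length, clamped at 0;
#' reduces to [char_accuracy()] for equal-length substitution-only pairs.
#'
#' @param output,target Strings; target non-empty.
#' @return Fraction in \[0, 1\].
#' @export
ld_accuracy <- function(output, target) {
  n <- nchar(target)
  if (n == 0L) stop("empty target")
  max(0, (n - levenshtein(output, target)) / n)
}

#' Wolpaw bits per selection
#'
#' `BR = log2 N + acc log2 acc + (1 - acc) log2((1 - acc)/(N - 1))`, the
#' uniform-error-model bit rate; continuous at acc = 0 and 1 via
#' `x log x -> 0`.
#'
#' @param acc Single-character accuracy in \[0, 1\].
#' @param n_symbols Alphabet size N (default 36).
#' @return Bits per selection (can be negative below chance level).
#' @export
bit_rate <- function(acc, n_symbols = 36L) {
  if (acc < 0 || acc > 1) stop("acc must be in [0, 1]")
  if (n_symbols < 2L) stop("need at least 2 symbols")
  xlx <- function(x) ifelse(x > 0, x * log2(x), 0)
  log2(n_symbols) + xlx(acc) + ifelse(acc < 1, (1 - acc) * log2((1 - acc) / (n_symbols - 1)), 0)
}

#' General bit rate for an arbitrary confusion model
#'
#' `BR = sum_z p(z) sum_x p(x|z) log2(p(x|z)/p(x))` — the mutual-information
#' form of which [bit_rate()] is the uniform special case.
#'
#' @param p_z Prior over intended symbols (length N, sums to 1).
#' @param p_x_given_z N x N matrix, rows intended `z`, columns selected `x`.
#' @param p_x Marginal over selections (default: implied by `p_z` and the
#'   confusion matrix).
#' @return Bits per selection.
#' @export
bit_rate_general <- function(p_z, p_x_given_z, p_x = drop(p_z %*% p_x_given_z)) {
  stopifnot(abs(sum(p_z) - 1) < 1e-9, all(dim(p_x_given_z) == length(p_z)))
  terms <- p_x_given_z * log2(sweep(p_x_given_z, 2L, p_x, `/`))
  terms[p_x_given_z == 0] <- 0
  sum(p_z * rowSums(terms))
}

#' Stimulus timing model
#'
#' The online presentation timing: 62.5 ms flashes with 62.5 ms ISI (125 ms
#' SOA) and a 3.5 s interval between characters.
#'
#' @param flash_duration,isi,inter_character Durations in seconds.
#' @return Object of class `timing_model` with derived `soa`.
#' @export
timing_model <- function(flash_duration = 0.0625, isi = 0.0625,
                         inter_character = 3.5) {
  structure(list(flash_duration = flash_duration, isi = isi,
                 soa = flash_duration + isi,
                 inter_character = inter_character),
            class = "timing_model")
}

#' Selection rate in characters per minute
#'
#' Reconstructs session time from the per-decision flash-set counts:
#' `sum(sets_used) * flashes_per_set * SOA + n_decisions * inter_character`
#' seconds for `n_chars` typed characters (with predictive spelling a
#' decision can emit several characters, so `n_chars` may exceed the number
#' of decisions).
#'
#' @param sets_used Integer vector, flash sets per decision.
#' @param flashes_per_set Flashes in one complete set (12 RCP, 18 CBP,
#'   n for COMB).
#' @param timing A [timing_model()].
#' @param n_chars Characters produced (default: one per decision).
#' @return Characters per minute.
#' @export
selection_rate <- function(sets_used, flashes_per_set, timing = timing_model(),
                           n_chars = length(sets_used)) {
  total <- sum(sets_used) * flashes_per_set * timing$soa +
    length(sets_used) * timing$inter_character
  60 * n_chars / total
}

#' Information transfer rate
#'
#' `ITR = BR x CPM` in bits per minute; a negative bit rate (accuracy below
#' chance) is clamped to zero with a warning, the standard convention.
#'
#' @param br Bits per selection.
#' @param sr Selections (characters) per minute.
#' @return Bits per minute.
#' @export
itr <- function(br, sr) {
  if (br < 0) {
    warning("negative bit rate clamped to 0")
    br <- 0
  }
  br * sr
}

#' Per-run metrics row
#'
#' Computes the accuracy (Levenshtein-based), selection rate, bit rate and
#' ITR for one decoded session (or pooled sessions).
#'
#' @param output,target Strings (target non-empty).
#' @param sets_used Flash sets per decision.
#' @param flashes_per_set Flashes per set.
#' @param n_symbols Alphabet size for the bit rate.
#' @param timing A [timing_model()].
#' @return One-row data frame with `sr` (chars/min), `acc` (percent), `br`
#'   (bits/selection), `itr` (bits/min).
#' @export
metrics_row <- function(output, target, sets_used, flashes_per_set,
                        n_symbols = 36L, timing = timing_model()) {
  acc <- ld_accuracy(output, target)
  sr <- selection_rate(sets_used, flashes_per_set, timing, n_chars = nchar(target))
  br <- max(0, bit_rate(acc, n_symbols))
  data.frame(sr = sr, acc = 100 * acc, br = br, itr = br * sr)
}
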