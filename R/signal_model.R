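#' Two-Gaussian per-flash score model
#'
#' The generative and likelihood model for per-flash classifier scores: a
#' flash containing the attended character yields a score from
#' N(mu_a, sigma_a^2), any other flash from N(mu_n, sigma_n^2).
#'
#' @param mu_a,sigma_a Attended mean and standard deviation.
#' @param mu_n,sigma_n Non-attended mean and standard deviation.
#' @return Object of class `score_model`.
#' @export
score_model <- function(mu_a = 1, sigma_a = 1, mu_n = 0, sigma_n = 1) {
  if (sigma_a <= 0 || sigma_n <= 0) stop("standard deviations must be positive")
  structure(list(mu_a = mu_a, sigma_a = sigma_a, mu_n = mu_n, sigma_n = sigma_n),
            class = "score_model")
}

#' Separability index of a score model
#'
#' d' = (mu_a - mu_n) / sqrt((sigma_a^2 + sigma_n^2) / 2), the per-flash
#' attended/non-attended separation in pooled-SD units.
#'
#' @param params A [score_model()].
#' @return Numeric d'.
#' @export
d_prime <- function(params) {
  (params$mu_a - params$mu_n) / sqrt((params$sigma_a^2 + params$sigma_n^2) / 2)
}

#' @export
print.score_model <- function(x, ...) {
  cat(sprintf("flash score model: attended N(%.3g, %.3g^2), non-attended N(%.3g, %.3g^2), d' = %.3g\n",
              x$mu_a, x$sigma_a, x$mu_n, x$sigma_n, d_prime(x)))
  invisible(x)
}

#' Gaussian likelihood of a flash score
#'
#' Density of score `y` under the attended or non-attended branch of the
#' score model.
#'
#' @param y Numeric score(s); must be finite.
#' @param params A [score_model()].
#' @param attended Logical: was the hypothesized character in the flash group?
#' @param log Return log density.
#' @return Density (vectorized over `y`).
#' @export
score_likelihood <- function(y, params, attended, log = FALSE) {
  if (any(!is.finite(y))) stop("score must be finite")
  if (attended) stats::dnorm(y, params$mu_a, params$sigma_a, log = log)
  else stats::dnorm(y, params$mu_n, params$sigma_n, log = log)
}

#' Simulate per-flash classifier scores for a target character
#'
#' One score per flash of the schedule, drawn independently from the attended
#' branch when the target is in the flash group and the non-attended branch
#' otherwise (the independence assumption the decoder itself makes).
#'
#' @param schedule A [schedule_session()] `flash_schedule`.
#' @param target Target symbol; must be addressable in every set.
#' @param params Generating [score_model()].
#' @param seed Optional integer seed.
#' @return Data frame with columns `set_index`, `flash_index`, `attended`,
#'   `value`; the schedule is attached as attribute `"schedule"`.
#' @export
simulate_scores <- function(schedule, target, params, seed = NULL) {
  stopifnot(inherits(schedule, "flash_schedule"), inherits(params, "score_model"))
  if (!is.null(seed)) set.seed(seed)
  ok <- vapply(schedule$sets, function(cb) target %in% addressable_symbols(cb), logical(1))
  if (!all(ok)) stop(sprintf("target '%s' is not addressable by the codebook", target))
  rows <- lapply(seq_along(schedule$sets), function(si) {
    cb <- schedule$sets[[si]]
    att <- vapply(cb$groups, function(g) target %in% g, logical(1))
    data.frame(set_index = si, flash_index = seq_along(cb$groups), attended = att)
  })
  df <- do.call(rbind, rows)
  n <- nrow(df)
  df$value <- ifelse(df$attended,
                     stats::rnorm(n, params$mu_a, params$sigma_a),
                     stats::rnorm(n, params$mu_n, params$sigma_n))
  attr(df, "schedule") <- schedule
  attr(df, "target") <- target
  df
}

#' Fit the two-Gaussian score model from labeled flashes
#'
#' Sample means and standard deviations per class.
#'
#' @param values Numeric flash scores.
#' @param attended Logical labels (same length).
#' @return A [score_model()].
#' @export
fit_score_model <- function(values, attended) {
  stopifnot(length(values) == length(attended))
  attended <- as.logical(attended)
  a <- values[attended]; n <- values[!attended]
  if (length(a) < 2L || length(n) < 2L) stop("need at least 2 scores per class")
  sa <- stats::sd(a); sn <- stats::sd(n)
  if (sa == 0 || sn == 0) stop("degenerate class: zero variance")
  score_model(mu_a = mean(a), sigma_a = sa, mu_n = mean(n), sigma_n = sn)
}

# Canonical deflection template: positive peak (default 300 ms) preceded by a
# smaller negativity (default 200 ms); amplitude ratio 2:1.
erp_template <- function(t_ms, peak_latency_ms = 300, neg_latency_ms = 200,
                         peak_amp = 5, neg_amp = -peak_amp / 2,
                         peak_width_ms = 45, neg_width_ms = 35) {
  v <- peak_amp * exp(-(t_ms - peak_latency_ms)^2 / (2 * peak_width_ms^2)) +
    neg_amp * exp(-(t_ms - neg_latency_ms)^2 / (2 * neg_width_ms^2))
  # numerically negligible tails are exactly zero (compact support)
  v[abs(v) < 1e-8 * max(abs(v))] <- 0
  v
}

#' Simulate ERP-like stimulus-locked epochs
#'
#' Attended epochs are Gaussian noise plus a deflection template: a positive
#' peak near `peak_latency_ms` preceded by a negativity of half the amplitude
#' near `neg_latency_ms`. Non-attended epochs are noise only.
#'
#' @param n_attended,n_nonattended Epoch counts.
#' @param peak_latency_ms Positive-peak latency (default 300).
#' @param neg_latency_ms Negativity latency (default 200).
#' @param noise_sd Per-sample noise SD (default 5, template peak is 5).
#' @param sampling_rate Hz (default 256).
#' @param epoch_ms Epoch length in ms post-stimulus (default 800).
#' @param peak_amp Positive-peak amplitude (default 5).
#' @param seed Optional integer seed.
#' @return Object of class `erp_epochs`: list with `attended` and
#'   `nonattended` (epochs x time matrices), `template`, `t_ms`,
#'   `sampling_rate`.
#' @export
simulate_erp_epochs <- function(n_attended, n_nonattended,
                                peak_latency_ms = 300, neg_latency_ms = 200,
                                noise_sd = 5, sampling_rate = 256,
                                epoch_ms = 800, peak_amp = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_t <- floor(epoch_ms * sampling_rate / 1000)
  t_ms <- (seq_len(n_t) - 1L) / sampling_rate * 1000
  if (peak_latency_ms > max(t_ms) || neg_latency_ms > max(t_ms))
    stop("latencies must fall within the epoch")
  tmpl <- erp_template(t_ms, peak_latency_ms, neg_latency_ms, peak_amp = peak_amp)
  att <- matrix(stats::rnorm(n_attended * n_t, 0, noise_sd), n_attended, n_t, byrow = TRUE)
  att <- sweep(att, 2L, tmpl, `+`)
  non <- matrix(stats::rnorm(n_nonattended * n_t, 0, noise_sd), n_nonattended, n_t, byrow = TRUE)
  structure(list(attended = att, nonattended = non,
                 template = tmpl, t_ms = t_ms, sampling_rate = sampling_rate),
            class = "erp_epochs")
}

#' Flatten and decimate epochs into feature vectors
#'
#' Takes every `decim`-th sample of each epoch, the standard dimensionality
#' reduction before stepwise feature selection.
#'
#' @param epochs Epochs x time matrix (or an `erp_epochs` component).
#' @param decim Decimation factor (default 8).
#' @return Feature matrix, one row per epoch.
#' @export
epochs_to_features <- function(epochs, decim = 8L) {
  keep <- seq(1L, ncol(epochs), by = decim)
  m <- epochs[, keep, drop = FALSE]
  colnames(m) <- paste0("f", keep)
  m
}

#' Write / read per-flash scores as CSV
#'
#' Column format: `char_index`, `set_index`, `flash_index`, `value`,
#' `attended` (optional), `members` (flash-group symbols joined with `|`).
#' [read_score_sets()] reconstructs the nested per-decision, per-set structure
#' that [decode_sequence()] and [exact_posterior_oracle()] accept.
#'
#' @param scores A [simulate_scores()] data frame (its schedule attribute
#'   supplies the flash groups).
#' @param path CSV path.
#' @param char_index Decision index recorded in the file.
#' @return `write_scores_csv`: the path, invisibly. `read_score_sets`: a list
#'   (one element per decision) of lists of `list(values, codebook)` per set.
#' @export
write_scores_csv <- function(scores, path, char_index = 1L) {
  sched <- attr(scores, "schedule")
  if (is.null(sched)) stop("scores must carry their schedule attribute")
  members <- vapply(seq_len(nrow(scores)), function(i) {
    cb <- sched$sets[[scores$set_index[i]]]
    paste(cb$groups[[scores$flash_index[i]]], collapse = "|")
  }, character(1))
  df <- data.frame(char_index = char_index,
                   set_index = scores$set_index,
                   flash_index = scores$flash_index,
                   value = scores$value,
                   attended = scores$attended,
                   members = members)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores_csv
#' @param grid The `speller_grid` the flash groups refer to.
#' @export
read_score_sets <- function(path, grid = make_grid()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("char_index", "set_index", "flash_index", "value", "members")
  if (!all(need %in% names(df))) stop("score file lacks columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  lapply(split(df, df$char_index), function(dc) {
    lapply(split(dc, dc$set_index), function(ds) {
      ds <- ds[order(ds$flash_index), ]
      groups <- strsplit(ds$members, "|", fixed = TRUE)
      list(values = ds$value,
           codebook = codebook_from_groups(grid, groups))
    })
  })
}
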