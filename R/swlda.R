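#' Stepwise linear discriminant analysis (SWLDA)
#'
#' Classic P300 calibration: ordinary least squares regression of the class
#' label on epoch features, with forward selection / backward elimination by
#' partial-F significance until no feature enters at `p_enter`, none leaves at
#' `p_remove`, or `max_features` is reached. The fitted weights score new
#' epochs; attended epochs score higher.
#'
#' @param x Feature matrix (rows: epochs; see [epochs_to_features()]).
#' @param y Logical or 0/1 labels (attended?). Both classes must be present.
#' @param p_enter Forward-selection p-value threshold (default 0.10).
#' @param p_remove Backward-elimination p-value threshold (default 0.15).
#' @param max_features Cap on the selected set size (default 60).
#' @return Object of class `swlda_model` with `selected` (feature names),
#'   `weights`, `intercept`.
#' @export
train_swlda <- function(x, y, p_enter = 0.10, p_remove = 0.15, max_features = 60L) {
  x <- as.matrix(x)
  y <- as.numeric(as.logical(y))
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  keep <- apply(x, 2L, stats::sd) > 0          # degenerate features excluded
  x <- x[, keep, drop = FALSE]
  if (ncol(x) == 0L) stop("no non-constant features")
  df <- data.frame(y = y, x, check.names = FALSE)
  candidates <- colnames(x)
  fit <- stats::lm(y ~ 1, data = df)
  selected <- character(0)
  for (iter in seq_len(10L * length(candidates) + 10L)) {
    changed <- FALSE
    # forward step
    pool <- setdiff(candidates, selected)
    if (length(pool) > 0L && length(selected) < max_features) {
      # add1 requires the scope to contain the current model terms as well
      scope <- stats::reformulate(paste0("`", candidates, "`"))
      a1 <- stats::add1(fit, scope = scope, test = "F")
      pv <- a1[["Pr(>F)"]][-1L]
      terms <- rownames(a1)[-1L]
      if (any(is.finite(pv)) && min(pv, na.rm = TRUE) < p_enter) {
        best <- terms[which.min(pv)]
        selected <- c(selected, gsub("`", "", best))
        fit <- stats::lm(stats::reformulate(paste0("`", selected, "`"), response = "y"), data = df)
        changed <- TRUE
      }
    }
    # backward step
    if (length(selected) > 0L) {
      d1 <- stats::drop1(fit, test = "F")
      pv <- d1[["Pr(>F)"]][-1L]
      terms <- gsub("`", "", rownames(d1)[-1L])
      if (any(is.finite(pv)) && max(pv, na.rm = TRUE) > p_remove) {
        worst <- terms[which.max(pv)]
        selected <- setdiff(selected, worst)
        fit <- if (length(selected) > 0L)
          stats::lm(stats::reformulate(paste0("`", selected, "`"), response = "y"), data = df)
        else stats::lm(y ~ 1, data = df)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  cf <- stats::coef(fit)
  structure(list(selected = selected,
                 weights = unname(cf[-1L])[match(selected, gsub("`", "", names(cf)[-1L]))],
                 intercept = unname(cf[1L])),
            class = "swlda_model")
}

#' @export
print.swlda_model <- function(x, ...) {
  cat(sprintf("SWLDA model: %d selected features\n", length(x$selected)))
  invisible(x)
}

#' Score epochs with a fitted SWLDA model
#'
#' @param object A `swlda_model`.
#' @param newdata Feature matrix with the training feature names.
#' @param ... Unused.
#' @return Numeric score per epoch (higher = more attended-like).
#' @export
predict.swlda_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (length(object$selected) == 0L) return(rep(object$intercept, nrow(newdata)))
  missing <- setdiff(object$selected, colnames(newdata))
  if (length(missing)) stop("newdata lacks features: ", paste(missing, collapse = ", "))
  drop(newdata[, object$selected, drop = FALSE] %*% object$weights + object$intercept)
}
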