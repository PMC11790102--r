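#' Default speller alphabet
#'
#' The 36-symbol alphabet of the classic 6x6 speller matrix: the letters A-Z,
#' the digits 1-9, and `"_"` used as the visible word separator (space).
#'
#' @return Character vector of 36 single-character symbols.
#' @export
speller_alphabet <- function() {
  c(LETTERS, as.character(1:9), "_")
}

#' Construct a speller character grid
#'
#' Places `symbols` row-major into an `n_rows` by `n_cols` matrix. The grid is
#' the on-screen layout the user attends to; codebooks are built on top of it.
#' Cells beyond `length(symbols)` are left empty.
#'
#' @param symbols Character vector of distinct single-character symbols.
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @return An object of class `speller_grid` with elements `symbols`,
#'   `n_rows`, `n_cols`, and zero-based `row`/`col` position vectors named by
#'   symbol.
#' @examples
#' g <- make_grid()
#' grid_position(g, "A")  # c(0, 0)
#' @export
make_grid <- function(symbols = speller_alphabet(), n_rows = 6L, n_cols = 6L) {
  symbols <- as.character(symbols)
  if (any(nchar(symbols) != 1L)) stop("grid symbols must be single characters")
  if (anyDuplicated(symbols)) stop("grid symbols must be distinct")
  if (length(symbols) < 1L) stop("grid needs at least one symbol")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) stop("grid dimensions must be positive")
  if (length(symbols) > n_rows * n_cols)
    stop(sprintf("too many symbols: %d > %d cells", length(symbols), n_rows * n_cols))
  idx <- seq_along(symbols) - 1L
  g <- structure(
    list(symbols = symbols,
         n_rows = n_rows, n_cols = n_cols,
         row = stats::setNames(idx %/% n_cols, symbols),
         col = stats::setNames(idx %% n_cols, symbols)),
    class = "speller_grid")
  g
}

#' Read a grid definition file
#'
#' Plain-text format: one row of symbols per line, all lines the same length.
#'
#' @param path Path to the grid file.
#' @return A [make_grid()] object.
#' @export
read_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty grid file")
  widths <- nchar(lines)
  if (length(unique(widths)) != 1L) stop("grid rows must all have the same length")
  make_grid(unlist(strsplit(lines, "")), n_rows = length(lines), n_cols = widths[1L])
}

#' Zero-based (row, col) position of a symbol
#'
#' @param grid A `speller_grid`.
#' @param symbol A symbol on the grid.
#' @return Integer vector `c(row, col)`, zero-based.
#' @export
grid_position <- function(grid, symbol) {
  stopifnot(inherits(grid, "speller_grid"))
  if (!symbol %in% grid$symbols) stop(sprintf("symbol '%s' is not on the grid", symbol))
  c(row = unname(grid$row[symbol]), col = unname(grid$col[symbol]))
}

# 4-neighbourhood adjacency in the real grid (used by the checkerboard checks)
grid_adjacent <- function(grid, a, b) {
  dr <- abs(grid$row[a] - grid$row[b])
  dc <- abs(grid$col[a] - grid$col[b])
  unname((dr + dc) == 1L)
}

#' @export
print.speller_grid <- function(x, ...) {
  cat(sprintf("speller grid: %d symbols on %dx%d\n", length(x$symbols), x$n_rows, x$n_cols))
  m <- matrix("", x$n_rows, x$n_cols)
  m[cbind(x$row + 1L, x$col + 1L)] <- x$symbols
  for (r in seq_len(x$n_rows)) cat(" ", paste(m[r, ], collapse = " "), "\n")
  invisible(x)
}
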