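#' Exact binomial coefficient
#'
#' C(n, k), the number of k-subsets of n flash indices; the capacity of the
#' combinatorial flashing paradigm with n flashes per set and k target flashes.
#'
#' @param n,k Non-negative integers with `k <= n`.
#' @return Exact integer-valued count.
#' @examples
#' binomial_coefficient(7, 3)  # 35
#' binomial_coefficient(9, 2)  # 36
#' @export
binomial_coefficient <- function(n, k) {
  if (length(n) != 1L || length(k) != 1L) stop("n and k must be scalars")
  if (n < 0 || k < 0 || k > n) stop("need 0 <= k <= n")
  round(choose(n, k))
}

#' Relative increase in flashes per set
#'
#' Percentage increase of `new_flashes` over `base_flashes`, rounded to two
#' decimals; used to compare the 12-flash row-column set against the 7- and
#' 9-flash combinatorial sets (71.43% and 33.33%).
#'
#' @param base_flashes Positive baseline flash count.
#' @param new_flashes Flash count being compared.
#' @return Percentage, rounded to 2 decimals.
#' @export
relative_flash_increase <- function(base_flashes, new_flashes) {
  if (base_flashes <= 0) stop("base_flashes must be positive")
  round(100 * (new_flashes - base_flashes) / base_flashes, 2)
}

# Flash-index signature of every symbol: which groups (by position in the set)
# contain it. Returned as a named list of integer vectors.
signatures_from_groups <- function(groups, symbols) {
  sig <- lapply(symbols, function(s) which(vapply(groups, function(g) s %in% g, logical(1))))
  names(sig) <- symbols
  sig[vapply(sig, length, integer(1)) > 0L]
}

new_codebook <- function(paradigm, grid, groups, params = list()) {
  sig <- signatures_from_groups(groups, grid$symbols)
  cb <- structure(
    list(paradigm = paradigm, grid = grid, groups = groups,
         signatures = sig, params = params),
    class = "speller_codebook")
  validate_codebook(cb)
  cb
}

#' Validate codebook invariants
#'
#' Checks that every flash group is a non-empty subset of the grid, that the
#' groups cover all addressable symbols, and that the flash-index signatures
#' are pairwise distinct (so one complete noiseless set identifies every
#' character).
#'
#' @param cb A `speller_codebook`.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_codebook <- function(cb) {
  stopifnot(inherits(cb, "speller_codebook"))
  if (any(vapply(cb$groups, length, integer(1)) == 0L)) stop("empty flash group")
  if (!all(unlist(cb$groups) %in% cb$grid$symbols)) stop("flash group member not on grid")
  keys <- vapply(cb$signatures, function(ix) paste(ix, collapse = ","), character(1))
  if (anyDuplicated(keys)) stop("character signatures are not distinct")
  invisible(TRUE)
}

#' Addressable symbols of a codebook
#'
#' Symbols that appear in at least one flash group (COMB(7,3) on a 36-symbol
#' grid leaves one symbol unaddressable).
#'
#' @param cb A `speller_codebook`.
#' @return Character vector.
#' @export
addressable_symbols <- function(cb) names(cb$signatures)

#' Number of flashes per complete set
#'
#' @param cb A `speller_codebook`.
#' @return Integer group count (12 for RCP on 6x6, 18 for CBP with 3x6 virtual
#'   matrices, n for COMB(n,k)).
#' @export
flashes_per_set <- function(cb) length(cb$groups)

#' Row-column paradigm codebook
#'
#' The classic paradigm: the 6 rows and 6 columns of the matrix flash in
#' random order, 12 flashes per set; every character's signature is its row
#' flash and its column flash.
#'
#' @param grid A fully populated `speller_grid`.
#' @return A `speller_codebook` with `n_rows + n_cols` groups. Uses the
#'   current R random stream for the group order.
#' @export
rcp_codebook <- function(grid) {
  stopifnot(inherits(grid, "speller_grid"))
  if (length(grid$symbols) != grid$n_rows * grid$n_cols)
    stop("RCP requires a fully populated grid")
  rows <- split(grid$symbols, grid$row)
  cols <- split(grid$symbols, grid$col)
  groups <- c(unname(rows), unname(cols))
  groups <- groups[sample.int(length(groups))]
  new_codebook("RCP", grid, groups)
}

#' Checkerboard paradigm codebook
#'
#' Superimposes a checkerboard on the grid so that 4-adjacent characters fall
#' in different parity classes; each class is randomly permuted into its own
#' virtual matrix, and one set flashes the rows of both virtual matrices
#' followed by the columns of both. Rows (and columns) of the two matrices are
#' interleaved so that consecutive flashes come from different classes,
#' guaranteeing both the no-adjacent-flash and the no-double-flash properties.
#'
#' @param grid A `speller_grid`.
#' @param virtual_shape `c(rows, cols)` of each virtual matrix; each parity
#'   class must fit. Default `c(3, 6)` for the 6x6 grid (18 characters per
#'   class), giving 18 flashes per set.
#' @return A `speller_codebook` with groups ordered rows-then-columns.
#' @export
cbp_codebook <- function(grid, virtual_shape = c(3L, 6L)) {
  stopifnot(inherits(grid, "speller_grid"))
  vr <- as.integer(virtual_shape[1L]); vc <- as.integer(virtual_shape[2L])
  parity <- (grid$row + grid$col) %% 2L
  classes <- list(grid$symbols[parity == 0L], grid$symbols[parity == 1L])
  if (any(vapply(classes, length, integer(1)) > vr * vc))
    stop("virtual_shape too small for a parity class")
  place <- function(chars) {
    # random placement into the virtual matrix, row-major over vr*vc cells
    cells <- sample.int(vr * vc, length(chars))
    list(row = (cells - 1L) %/% vc, col = (cells - 1L) %% vc, chars = chars)
  }
  pl <- lapply(classes, place)
  row_groups <- function(p) lapply(seq_len(vr) - 1L, function(r) p$chars[p$row == r])
  col_groups <- function(p) lapply(seq_len(vc) - 1L, function(cc) p$chars[p$col == cc])
  drop_empty <- function(gs) gs[vapply(gs, length, integer(1)) > 0L]
  interleave <- function(a, b) {
    out <- vector("list", length(a) + length(b))
    out[seq_along(a) * 2L - 1L] <- a
    out[seq_along(b) * 2L] <- b
    out
  }
  # randomize order within each block, then interleave the two classes so
  # consecutive groups are always disjoint
  ra <- drop_empty(row_groups(pl[[1L]])); ra <- ra[sample.int(length(ra))]
  rb <- drop_empty(row_groups(pl[[2L]])); rb <- rb[sample.int(length(rb))]
  ca <- drop_empty(col_groups(pl[[1L]])); ca <- ca[sample.int(length(ca))]
  cb2 <- drop_empty(col_groups(pl[[2L]])); cb2 <- cb2[sample.int(length(cb2))]
  groups <- c(interleave(ra, rb), interleave(ca, cb2))
  new_codebook("CBP", grid, groups, params = list(virtual_shape = c(vr, vc)))
}

#' Combinatorial paradigm codebook
#'
#' Each character is assigned a distinct k-subset of the n flash indices
#' (randomly, by default over a random sample of all C(n, k) subsets); flash
#' group i contains every character whose subset includes i, so each set has
#' n flashes and the target flashes k times. C(9, 2) = 36 addresses the full
#' 6x6 grid; C(7, 3) = 35 addresses all but one symbol.
#'
#' @param grid A `speller_grid`.
#' @param n Flashes per set.
#' @param k Target flashes per set.
#' @param drop_symbols Symbols to leave unaddressable when C(n, k) is smaller
#'   than the grid. By default none are dropped and a capacity shortfall is an
#'   error; `TRUE` drops the last symbols in row-major order, as many as
#'   needed (for the default alphabet that is `"_"`, so texts containing
#'   spaces need a different choice).
#' @return A `speller_codebook` with n groups.
#' @export
comb_codebook <- function(grid, n = 9L, k = 2L, drop_symbols = NULL) {
  stopifnot(inherits(grid, "speller_grid"))
  n <- as.integer(n); k <- as.integer(k)
  capacity <- binomial_coefficient(n, k)
  symbols <- grid$symbols
  if (isTRUE(drop_symbols)) {
    short <- max(0L, length(symbols) - capacity)
    drop_symbols <- if (short > 0L) symbols[seq.int(length(symbols) - short + 1L, length(symbols))]
                    else character(0)
  }
  if (is.null(drop_symbols)) drop_symbols <- character(0)
  symbols <- setdiff(symbols, drop_symbols)
  if (capacity < length(symbols))
    stop(sprintf("C(%d,%d) = %d cannot address %d characters", n, k, capacity, length(symbols)))
  subsets <- utils::combn(n, k, simplify = FALSE)
  subsets <- subsets[sample.int(length(subsets), length(symbols))]
  subsets <- subsets[sample.int(length(subsets))]  # random character -> subset assignment
  assign <- stats::setNames(subsets, symbols)
  groups <- lapply(seq_len(n), function(i)
    symbols[vapply(assign, function(s) i %in% s, logical(1))])
  new_codebook("COMB", grid, groups,
               params = list(n = n, k = k, drop_symbols = drop_symbols))
}

# One fresh instantiation of a codebook for the next flash set. RCP keeps the
# character->(row,col) identity and only re-randomizes flash order; CBP and
# COMB re-randomize the virtual placement / subset assignment (configurable
# for COMB via params$reassign = FALSE).
reinstantiate_codebook <- function(cb) {
  switch(cb$paradigm,
    RCP = {
      groups <- cb$groups[sample.int(length(cb$groups))]
      new_codebook("RCP", cb$grid, groups)
    },
    CBP = cbp_codebook(cb$grid, cb$params$virtual_shape),
    COMB = {
      if (isFALSE(cb$params$reassign)) {
        cb
      } else {
        comb_codebook(cb$grid, cb$params$n, cb$params$k, cb$params$drop_symbols)
      }
    },
    stop("unknown paradigm: ", cb$paradigm))
}

#' Generate a flash schedule for one character decision
#'
#' Produces up to `max_sets` independent instantiations of the codebook: RCP
#' re-randomizes the flash order each set, CBP repopulates its virtual
#' matrices, COMB re-draws the character-to-subset assignment (unless the
#' codebook was built with `params$reassign = FALSE`).
#'
#' @param codebook A `speller_codebook`.
#' @param max_sets Maximum number of flash sets (default 10, the dynamic
#'   stopping cap).
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `flash_schedule`: list with `sets` (a list of
#'   codebooks) and `max_sets`.
#' @export
schedule_session <- function(codebook, max_sets = 10L, seed = NULL) {
  stopifnot(inherits(codebook, "speller_codebook"), max_sets >= 1L)
  if (!is.null(seed)) set.seed(seed)
  sets <- vector("list", max_sets)
  sets[[1L]] <- reinstantiate_codebook(codebook)
  if (max_sets > 1L)
    for (i in 2:max_sets) sets[[i]] <- reinstantiate_codebook(codebook)
  structure(list(sets = sets, max_sets = as.integer(max_sets),
                 paradigm = codebook$paradigm),
            class = "flash_schedule")
}

#' Serialize a codebook or schedule to JSON
#'
#' Dump format: list of sets, each a list of flash groups (symbol vectors),
#' plus per-character signatures. Used as a plain-text fixture format.
#'
#' @param x A `speller_codebook` or `flash_schedule`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
codebook_json <- function(x, path = NULL) {
  sets <- if (inherits(x, "flash_schedule")) x$sets else list(x)
  obj <- list(
    paradigm = sets[[1L]]$paradigm,
    sets = lapply(sets, function(cb)
      list(groups = cb$groups,
           signatures = cb$signatures)))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @export
print.speller_codebook <- function(x, ...) {
  cat(sprintf("%s codebook: %d flashes/set, %d addressable characters\n",
              x$paradigm, flashes_per_set(x), length(x$signatures)))
  invisible(x)
}

#' Build a codebook from explicit flash groups
#'
#' For deserialized or hand-specified flash patterns; the usual invariants
#' (distinct signatures, grid membership) are validated.
#'
#' @param grid A `speller_grid`.
#' @param groups List of character vectors of grid symbols.
#' @param paradigm Label stored on the codebook.
#' @return A `speller_codebook`.
#' @export
codebook_from_groups <- function(grid, groups, paradigm = "CUSTOM") {
  new_codebook(paradigm, grid, groups)
}
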