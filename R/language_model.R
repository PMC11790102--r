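#' Word-frequency counts
#'
#' Constructor for corpus counts used to build the prefix automaton. Tokens
#' are upper-cased and non-alphabetic tokens are dropped (the grid types
#' upper-case words separated by `"_"`); duplicate tokens have their counts
#' summed.
#'
#' @param words Character vector of tokens.
#' @param counts Nonnegative frequencies, recycled from 1 if missing.
#' @return Named numeric vector of class `corpus_counts`.
#' @export
corpus_counts <- function(words, counts = rep(1, length(words))) {
  stopifnot(length(words) == length(counts), all(counts >= 0))
  words <- toupper(as.character(words))
  keep <- grepl("^[A-Z]+$", words)
  words <- words[keep]; counts <- as.numeric(counts[keep])
  if (length(words) == 0L) stop("empty corpus")
  agg <- rowsum(counts, words)
  structure(stats::setNames(as.numeric(agg), rownames(agg)), class = "corpus_counts")
}

#' Read a word-frequency corpus file
#'
#' Plain text, UTF-8, `#` comments; either one token per line (count 1 each)
#' or `token<TAB>count`.
#'
#' @param path Path to the corpus file.
#' @return A [corpus_counts()] vector.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty corpus file")
  parts <- strsplit(lines, "\t")
  words <- vapply(parts, `[`, character(1), 1L)
  counts <- vapply(parts, function(p) if (length(p) > 1L) as.numeric(p[2L]) else 1, numeric(1))
  corpus_counts(words, counts)
}

#' Build the word-prefix automaton language model
#'
#' A directed graph with one state per distinct prefix of a corpus word,
#' rooted at the empty string. The raw transition probability from state `s`
#' to `s+c` is `prefix_count(s+c) / prefix_count(s)`; the probability of
#' ending the word (typing the separator and returning to the root) is
#' `word_count(s) / prefix_count(s)`. These raw probabilities are then
#' floor-smoothed over the full grid alphabet and renormalized so that every
#' symbol — including digits never seen in a word corpus — keeps strictly
#' positive probability and any target string remains decodable. Symbols with
#' no prefix-tree successor lead back to the root (a word restart).
#'
#' @param corpus A [corpus_counts()] vector (or plain named numeric vector).
#' @param alphabet Grid alphabet the model must cover; must contain `sep`.
#' @param smoothing_floor Probability floor added to every alphabet symbol
#'   before renormalization (default 1e-4); 0 disables smoothing.
#' @param sep Word-separator symbol (default `"_"`).
#' @return An object of class `speller_lm` with elements `states` (prefix
#'   labels, root first), `alphabet`, `probs` (states x alphabet smoothed
#'   transition matrix), `raw` (pre-smoothing matrix), `succ` (states x
#'   alphabet successor-state index matrix), `is_word`, `root` (index 1).
#' @examples
#' lm <- build_lm(corpus_counts(c("CAR", "CAKE")), smoothing_floor = 0)
#' transition_prob(lm, "CA", "R")  # 0.5
#' @export
build_lm <- function(corpus, alphabet = speller_alphabet(),
                     smoothing_floor = 1e-4, sep = "_") {
  if (is.null(names(corpus)) || length(corpus) == 0L) stop("empty corpus")
  if (!sep %in% alphabet) stop("alphabet must contain the separator symbol")
  words <- names(corpus); counts <- as.numeric(corpus)
  bad <- words[!vapply(words, function(w)
    all(strsplit(w, "")[[1]] %in% setdiff(alphabet, sep)), logical(1))]
  if (length(bad)) stop("corpus words use symbols outside the alphabet: ", bad[1L])

  # every prefix of every word (including "" and the full word), with counts
  lens <- nchar(words)
  pref <- unlist(lapply(seq_along(words), function(i) substring(words[i], 1, 0:lens[i])))
  pcnt <- unlist(lapply(seq_along(words), function(i) rep(counts[i], lens[i] + 1L)))
  agg <- rowsum(pcnt, pref)
  states <- c("", setdiff(sort(rownames(agg)), ""))  # root first, then sorted labels
  # NB: index by match(), not by name — "" never matches as a character subscript
  prefix_count <- stats::setNames(as.numeric(agg)[match(states, rownames(agg))], states)
  word_count <- stats::setNames(rep(0, length(states)), states)
  wc <- rowsum(counts, words)
  word_count[match(rownames(wc), states)] <- as.numeric(wc)

  A <- length(alphabet)
  S <- length(states)
  raw <- matrix(0, S, A, dimnames = list(states, alphabet))
  succ <- matrix(1L, S, A, dimnames = list(states, alphabet))  # default: restart at root
  sep_col <- match(sep, alphabet)
  raw[, sep_col] <- word_count / prefix_count
  if (S > 1L) {
    child <- states[-1L]
    parent <- substring(child, 1L, nchar(child) - 1L)
    pi <- match(parent, states)
    ci <- 2:S
    ch_col <- match(substring(child, nchar(child)), alphabet)
    raw[cbind(pi, ch_col)] <- prefix_count[ci] / prefix_count[pi]
    succ[cbind(pi, ch_col)] <- ci
  }
  probs <- (raw + smoothing_floor) / (1 + smoothing_floor * A)
  structure(
    list(states = states, alphabet = alphabet, sep = sep,
         probs = probs, raw = raw, succ = succ,
         is_word = unname(word_count[states] > 0),
         word_end = unname(raw[, sep_col]),
         prefix_count = prefix_count,
         smoothing_floor = smoothing_floor,
         root = 1L),
    class = "speller_lm")
}

#' Uniform (knowledge-free) language model
#'
#' A single root state with equal probability for every alphabet symbol; every
#' transition returns to the root. Serves as the no-language-model baseline.
#'
#' @param alphabet Grid alphabet.
#' @param sep Word separator.
#' @return A `speller_lm`.
#' @export
uniform_lm <- function(alphabet = speller_alphabet(), sep = "_") {
  A <- length(alphabet)
  probs <- matrix(1 / A, 1, A, dimnames = list("", alphabet))
  structure(
    list(states = "", alphabet = alphabet, sep = sep,
         probs = probs, raw = probs,
         succ = matrix(1L, 1, A, dimnames = list("", alphabet)),
         is_word = FALSE, word_end = 1 / A,
         prefix_count = c(` ` = NA_real_),
         smoothing_floor = 0, root = 1L),
    class = "speller_lm")
}

lm_state_index <- function(lm, state) {
  if (is.numeric(state)) return(as.integer(state))
  i <- match(state, lm$states)
  if (is.na(i)) stop(sprintf("state '%s' not in language model", state))
  i
}

#' Transition probability from a language-model state
#'
#' The (by default smoothed) probability that the next typed symbol is
#' `symbol` given the current prefix state; the word separator carries the
#' word-end (return-to-root) probability.
#'
#' @param lm A `speller_lm`.
#' @param state State label (prefix string) or index.
#' @param symbol Grid symbol, or a vector of symbols.
#' @param smoothed Use the floor-smoothed distribution (default) or the raw
#'   corpus relative frequencies.
#' @return Probability (vectorized over `symbol`).
#' @export
transition_prob <- function(lm, state, symbol, smoothed = TRUE) {
  i <- lm_state_index(lm, state)
  if (!all(symbol %in% lm$alphabet)) stop("symbol outside the grid alphabet")
  m <- if (smoothed) lm$probs else lm$raw
  unname(m[i, symbol])
}

#' Sample the next symbol from a state
#'
#' Draws one symbol from the state's smoothed transition distribution; a
#' word-end (separator) or an off-tree symbol returns to the root.
#'
#' @param lm A `speller_lm`.
#' @param state State label or index.
#' @return List with `symbol`, `state` (successor label), `at_root` (logical:
#'   did the transition return to the root, i.e. end a word).
#' @export
sample_next <- function(lm, state) {
  i <- lm_state_index(lm, state)
  j <- sample.int(length(lm$alphabet), 1L, prob = lm$probs[i, ])
  si <- lm$succ[i, j]
  list(symbol = lm$alphabet[j], state = lm$states[si], at_root = si == lm$root)
}

#' Prior probability of a whole string under the language model
#'
#' Product of transition probabilities walking the automaton from the root,
#' with root restarts at word ends and off-tree symbols.
#'
#' @param lm A `speller_lm`.
#' @param string Character string over the grid alphabet.
#' @param smoothed Use smoothed probabilities (default) or raw.
#' @param log Return the log probability.
#' @return Probability (or log probability).
#' @export
lm_string_prob <- function(lm, string, smoothed = TRUE, log = FALSE) {
  chars <- strsplit(string, "")[[1]]
  m <- if (smoothed) lm$probs else lm$raw
  s <- lm$root
  lp <- 0
  for (ch in chars) {
    j <- match(ch, lm$alphabet)
    if (is.na(j)) stop("symbol outside the grid alphabet: ", ch)
    lp <- lp + log(m[s, j])
    s <- lm$succ[s, j]
  }
  if (log) lp else exp(lp)
}

#' Serialize / load a language model as JSON
#'
#' Plain-text dump of states, alphabet and smoothed transition matrix; used
#' for test fixtures and the CLI.
#'
#' @param lm A `speller_lm`.
#' @param path File path (for `lm_to_json`, `NULL` returns the JSON string).
#' @return `lm_to_json`: JSON string (invisibly when written); `lm_from_json`:
#'   a `speller_lm`.
#' @export
lm_to_json <- function(lm, path = NULL) {
  obj <- list(states = lm$states, alphabet = lm$alphabet, sep = lm$sep,
              smoothing_floor = lm$smoothing_floor,
              probs = unname(lm$probs),      # serialized row-major, one row per state
              raw = unname(lm$raw),
              succ = unname(lm$succ),
              is_word = lm$is_word)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @rdname lm_to_json
#' @export
lm_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  dn <- list(obj$states, obj$alphabet)
  probs <- obj$probs; dimnames(probs) <- dn
  raw <- obj$raw; dimnames(raw) <- dn
  succ <- matrix(as.integer(obj$succ), nrow(probs), ncol(probs), dimnames = dn)
  structure(
    list(states = obj$states, alphabet = obj$alphabet, sep = obj$sep,
         probs = probs, raw = raw, succ = succ,
         is_word = obj$is_word, word_end = unname(raw[, obj$sep]),
         prefix_count = NULL, smoothing_floor = obj$smoothing_floor, root = 1L),
    class = "speller_lm")
}

#' @export
print.speller_lm <- function(x, ...) {
  cat(sprintf("prefix-automaton language model: %d states, %d-symbol alphabet, floor %g\n",
              length(x$states), length(x$alphabet), x$smoothing_floor))
  invisible(x)
}
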