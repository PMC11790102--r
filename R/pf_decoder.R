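#' Decoder configuration
#'
#' Settings of the sequential Monte Carlo decoder: particle count, the
#' dynamic-stopping threshold on the string posterior (0.95 in the online
#' system), the flash-set cap (10), and the predictive-spelling parameters
#' (projection fraction rho, word-selection threshold 0.40, six suggestion
#' slots).
#'
#' @param P Particle count (default 10000).
#' @param p_thresh Stopping threshold on the maximum string posterior.
#' @param max_sets Flash-set cap per character decision.
#' @param rho Fraction of particles projected to word completions.
#' @param word_thresh Posterior threshold for selecting a suggested word.
#' @param k_words Number of word-suggestion slots.
#' @param predictive Enable predictive spelling in [decode_sequence()].
#' @param resample `"multinomial"` (as described: new particles sampled by
#'   weight) or `"systematic"` (lower-variance option).
#' @return Object of class `decoder_config`.
#' @export
decoder_config <- function(P = 10000L, p_thresh = 0.95, max_sets = 10L,
                           rho = 0.5, word_thresh = 0.40, k_words = 6L,
                           predictive = FALSE,
                           resample = c("multinomial", "systematic")) {
  if (P < 1L) stop("P must be at least 1")
  if (p_thresh <= 0 || p_thresh > 1) stop("p_thresh must be in (0, 1]")
  if (max_sets < 1L) stop("max_sets must be at least 1")
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]")
  structure(list(P = as.integer(P), p_thresh = p_thresh,
                 max_sets = as.integer(max_sets), rho = rho,
                 word_thresh = word_thresh, k_words = as.integer(k_words),
                 predictive = predictive, resample = match.arg(resample)),
            class = "decoder_config")
}

#' Initialize the particle set
#'
#' All particles start at the language-model root with empty history and
#' uniform weight 1/P.
#'
#' @param config A [decoder_config()].
#' @param lm A `speller_lm`.
#' @return Object of class `particle_set`: parallel vectors `state` (LM state
#'   index), `hist` (typed string), `cur` (current symbol), `word` (current
#'   word prefix), `root_index` (last decision index at the root), `logw`
#'   (normalized log weights), plus `t` (decision counter) and `P`.
#' @export
init_particles <- function(config, lm) {
  P <- config$P
  structure(list(state = rep(lm$root, P),
                 hist = rep("", P),
                 cur = rep("", P),
                 word = rep("", P),
                 root_index = rep(0L, P),
                 logw = rep(-log(P), P),
                 t = 0L, P = P),
            class = "particle_set")
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# advance one particle-array step given sampled alphabet indices
advance_particles <- function(ps, lm, j) {
  sym <- lm$alphabet[j]
  si <- lm$succ[cbind(ps$state, j)]
  at_root <- si == lm$root
  ps$hist <- paste0(ps$hist, sym)
  ps$cur <- sym
  ps$word <- ifelse(at_root, "", paste0(ps$word, ifelse(sym == lm$sep, "", sym)))
  # a particle completing a word records the word via its history; the word
  # prefix buffer resets at the root
  ps$state <- si
  ps$root_index[at_root] <- ps$t
  ps
}

#' Propose: extend every particle by one sampled symbol
#'
#' Each particle independently samples its next symbol from the language
#' model's (smoothed) transition distribution at its current state; weights
#' are unchanged.
#'
#' @param ps A `particle_set`.
#' @param lm A `speller_lm`.
#' @return Updated `particle_set` with `t` incremented.
#' @export
propose <- function(ps, lm) {
  ps$t <- ps$t + 1L
  A <- length(lm$alphabet)
  j <- integer(ps$P)
  for (s in unique(ps$state)) {
    ix <- which(ps$state == s)
    j[ix] <- sample.int(A, length(ix), replace = TRUE, prob = lm$probs[s, ])
  }
  advance_particles(ps, lm, j)
}

# Per-symbol log likelihood of one complete flash set: for each alphabet
# symbol, sum of attended/non-attended log densities over the set's flashes.
set_symbol_loglik <- function(values, groups, params, alphabet) {
  base <- sum(stats::dnorm(values, params$mu_n, params$sigma_n, log = TRUE))
  delta <- stats::dnorm(values, params$mu_a, params$sigma_a, log = TRUE) -
    stats::dnorm(values, params$mu_n, params$sigma_n, log = TRUE)
  ll <- stats::setNames(rep(base, length(alphabet)), alphabet)
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    ll[g] <- ll[g] + delta[i]
  }
  ll
}

#' Update particle weights with one flash set's scores
#'
#' Multiplies each particle's weight by the likelihood of the observed scores
#' under the particle's current symbol (attended density for flashes whose
#' group contains the symbol, non-attended otherwise), in log space with
#' max-subtraction, then renormalizes.
#'
#' @param ps A `particle_set`.
#' @param scores Numeric vector of per-flash scores for one complete set (in
#'   flash order), or a `simulate_scores()` data frame restricted to one set.
#' @param params The decoder's [score_model()].
#' @param codebook The `speller_codebook` instantiation that produced the
#'   flashes.
#' @return Updated `particle_set` with normalized log weights.
#' @export
update_weights <- function(ps, scores, params, codebook) {
  if (is.data.frame(scores)) {
    scores <- scores[order(scores$flash_index), ]
    values <- scores$value
  } else values <- as.numeric(scores)
  if (length(values) != length(codebook$groups))
    stop("scores must cover exactly one complete flash set")
  ll <- set_symbol_loglik(values, codebook$groups, params, codebook$grid$symbols)
  cur <- ps$cur
  add <- rep(min(ll), length(cur))  # symbols off the grid keep a finite floor
  on <- cur %in% names(ll)
  add[on] <- ll[cur[on]]
  logw <- ps$logw + add
  z <- log_sum_exp(logw)
  if (!is.finite(z)) stop("all particle weights underflowed to zero; scores or parameters are degenerate")
  ps$logw <- logw - z
  ps
}

#' Posterior distribution over output strings
#'
#' Probability of each distinct particle history is the sum of the weights of
#' the particles sharing it.
#'
#' @param ps A `particle_set` with normalized weights.
#' @return Named numeric vector (names: strings), sorted by label, summing
#'   to 1.
#' @export
string_posterior <- function(ps) {
  w <- exp(ps$logw)
  p <- rowsum(w, ps$hist)
  stats::setNames(as.numeric(p), rownames(p))
}

#' Dynamic-stopping rule
#'
#' Stop flashing once the maximum string posterior exceeds `p_thresh` or the
#' number of completed flash sets reaches `max_sets`.
#'
#' @param posterior A [string_posterior()] vector.
#' @param sets_done Completed flash sets for the current character.
#' @param config A [decoder_config()].
#' @return Logical.
#' @export
dynamic_stop_check <- function(posterior, sets_done, config) {
  max(posterior) > config$p_thresh || sets_done >= config$max_sets
}

resample_indices <- function(w, P, scheme) {
  if (scheme == "systematic") {
    u <- (stats::runif(1) + seq_len(P) - 1L) / P
    findInterval(u, cumsum(w) - 1e-12) + 1L
  } else {
    sample.int(length(w), P, replace = TRUE, prob = w)
  }
}

#' Select the MAP string and resample the particles
#'
#' Returns the argmax of the string posterior (ties broken lexicographically)
#' and a new particle set drawn from the current particles by weight, each
#' with uniform weight 1/P.
#'
#' @param ps A `particle_set`.
#' @param config A [decoder_config()].
#' @return List with `selected` (string) and `ps` (resampled `particle_set`).
#' @export
select_and_resample <- function(ps, config = decoder_config(P = ps$P)) {
  post <- string_posterior(ps)
  nm <- names(post)
  selected <- nm[order(-post, nm)][1L]
  w <- exp(ps$logw)
  idx <- resample_indices(w / sum(w), ps$P, config$resample)
  for (f in c("state", "hist", "cur", "word", "root_index")) ps[[f]] <- ps[[f]][idx]
  ps$logw <- rep(-log(ps$P), ps$P)
  list(selected = selected, ps = ps)
}

#' Project particles to complete words (predictive spelling)
#'
#' A fraction `rho` of the particles continues sampling through the language
#' model until the next word end; the posterior over complete words is the
#' normalized weight mass of the projected particles per word. The top
#' `k_words` words are mapped to the last grid cells in row-major order;
#' projected particles mapped to less likely words get weight zero (they are
#' replaced at the next resampling).
#'
#' @param ps A `particle_set`.
#' @param lm A `speller_lm`.
#' @param config A [decoder_config()].
#' @param grid The `speller_grid` (for suggestion-cell placement).
#' @param max_steps Projection step cap per particle.
#' @return List with `words` (named word-probability vector, decreasing),
#'   `suggestions` (data frame word/cell/prob, at most `k_words` rows),
#'   `selected` (top word if its probability exceeds `word_thresh`, else
#'   `NA`), and `ps` (particle set with zeroed off-suggestion projections).
#' @export
project_for_words <- function(ps, lm, config, grid = NULL, max_steps = 25L) {
  n_proj <- round(config$rho * ps$P)
  if (n_proj < 1L) stop("rho too small: no particles projected")
  proj <- sample.int(ps$P, n_proj)
  words <- character(n_proj)
  for (ii in seq_along(proj)) {
    i <- proj[ii]
    s <- ps$state[i]
    word <- ps$word[i]
    steps <- 0L
    while (s != lm$root && steps < max_steps) {
      j <- sample.int(length(lm$alphabet), 1L, prob = lm$probs[s, ])
      sym <- lm$alphabet[j]
      s <- lm$succ[s, j]
      if (sym != lm$sep && s != lm$root) word <- paste0(word, sym)
      else if (sym != lm$sep && s == lm$root) word <- paste0(word, sym)
      steps <- steps + 1L
    }
    words[ii] <- word
  }
  w <- exp(ps$logw[proj])
  wp <- rowsum(w, words)
  word_prob <- sort(stats::setNames(as.numeric(wp) / sum(w), rownames(wp)), decreasing = TRUE)
  top <- utils::head(names(word_prob), config$k_words)
  suggestions <- data.frame(word = top, prob = unname(word_prob[top]))
  if (!is.null(grid)) {
    cells <- utils::tail(grid$symbols, length(top))
    suggestions$cell <- cells
  }
  off <- proj[!(words %in% top)]
  ps$logw[off] <- -Inf
  ps$logw <- ps$logw - log_sum_exp(ps$logw)
  selected <- if (word_prob[1L] > config$word_thresh) names(word_prob)[1L] else NA_character_
  list(words = word_prob, suggestions = suggestions, selected = selected, ps = ps)
}

#' Decode a character sequence with the particle filter
#'
#' The full online loop: for each character decision, propose an extension
#' for every particle, then flash sets (simulating scores for the user's
#' intended character) and update weights until the dynamic-stopping rule
#' fires, then select the MAP string and resample. If the newly selected
#' string disagrees with previously emitted characters, the disagreeing
#' prefix is replaced and logged as a retroactive correction. With
#' `config$predictive = TRUE`, particle projection after each decision can
#' select a complete word (posterior above `word_thresh`), which finishes the
#' current word immediately.
#'
#' @param targets Target text (string over the grid alphabet) the simulated
#'   user attends to, e.g. `"THE_QUICK_"`.
#' @param codebook Base `speller_codebook`; each flash set is a fresh
#'   instantiation of it.
#' @param lm A `speller_lm`.
#' @param params The decoder's [score_model()] (also used to generate scores
#'   unless `gen_params` is given).
#' @param config A [decoder_config()].
#' @param gen_params Optional generating [score_model()] for the simulated
#'   scores (defaults to `params`; letting them differ emulates calibration
#'   error).
#' @param seed Optional integer seed.
#' @param score_sets Optional pre-computed scores: a list (one element per
#'   decision) of lists of `list(values, codebook)` per set; when supplied no
#'   scores are simulated and `targets` only sets the decision count.
#' @return Object of class `speller_decode`: `output`, `target`, `sets_used`,
#'   `posterior_trace` (max posterior at each decision), `corrections`
#'   (data frame), `decisions` (per-decision log), `flashes_per_set`,
#'   `paradigm`, `config`.
#' @export
decode_sequence <- function(targets, codebook, lm, params, config = decoder_config(),
                            gen_params = NULL, seed = NULL, score_sets = NULL) {
  stopifnot(inherits(codebook, "speller_codebook"), inherits(lm, "speller_lm"),
            inherits(params, "score_model"), inherits(config, "decoder_config"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(gen_params)) gen_params <- params
  target_chars <- strsplit(targets, "")[[1]]
  n_chars <- length(target_chars)
  if (is.null(score_sets)) {
    ok <- target_chars %in% addressable_symbols(codebook)
    if (!all(ok)) stop("target contains unaddressable characters: ",
                       paste(unique(target_chars[!ok]), collapse = ""))
  }
  ps <- init_particles(config, lm)
  emitted <- ""
  sets_used <- integer(0)
  posterior_trace <- numeric(0)
  corrections <- list()
  decisions <- list()
  decision <- 0L
  while (nchar(emitted) < n_chars) {
    decision <- decision + 1L
    pos <- nchar(emitted) + 1L
    intent <- target_chars[min(pos, n_chars)]
    ps <- propose(ps, lm)
    sets_done <- 0L
    repeat {
      if (!is.null(score_sets)) {
        st <- score_sets[[decision]][[sets_done + 1L]]
        ps <- update_weights(ps, st$values, params, st$codebook)
      } else {
        cb <- reinstantiate_codebook(codebook)
        att <- vapply(cb$groups, function(g) intent %in% g, logical(1))
        values <- ifelse(att,
                         stats::rnorm(length(att), gen_params$mu_a, gen_params$sigma_a),
                         stats::rnorm(length(att), gen_params$mu_n, gen_params$sigma_n))
        ps <- update_weights(ps, values, params, cb)
      }
      sets_done <- sets_done + 1L
      post <- string_posterior(ps)
      if (dynamic_stop_check(post, sets_done, config)) break
      if (!is.null(score_sets) && sets_done >= length(score_sets[[decision]])) break
    }
    sr <- select_and_resample(ps, config)
    ps <- sr$ps
    selected <- sr$selected
    # retroactive correction: earlier emitted characters replaced on disagreement
    old_prefix <- substr(emitted, 1L, min(nchar(emitted), nchar(selected)))
    new_prefix <- substr(selected, 1L, nchar(old_prefix))
    if (nchar(old_prefix) > 0L && old_prefix != new_prefix) {
      corrections[[length(corrections) + 1L]] <-
        data.frame(decision = decision, old = old_prefix, new = new_prefix)
    }
    emitted <- selected
    sets_used <- c(sets_used, sets_done)
    posterior_trace <- c(posterior_trace, max(post))
    word_selected <- NA_character_
    if (isTRUE(config$predictive) && nchar(emitted) < n_chars) {
      pr <- project_for_words(ps, lm, config, grid = codebook$grid)
      ps <- pr$ps
      if (!is.na(pr$selected) && nchar(pr$selected) > 0L) {
        word_selected <- pr$selected
        # the selected word completes the current word immediately
        before <- sub("[^_]*$", "", emitted)   # everything up to the last word start
        emitted <- paste0(before, word_selected, lm$sep)
        ps$hist <- rep(emitted, ps$P)
        ps$state <- rep(lm$root, ps$P)
        ps$cur <- rep(lm$sep, ps$P)
        ps$word <- rep("", ps$P)
        ps$root_index <- rep(ps$t, ps$P)
        ps$logw <- rep(-log(ps$P), ps$P)
      }
    }
    decisions[[decision]] <- list(decision = decision, intent = intent,
                                  selected = selected, sets_used = sets_done,
                                  max_posterior = max(post),
                                  word_selected = word_selected)
    if (!is.null(score_sets) && decision >= length(score_sets)) break
  }
  structure(
    list(output = emitted,
         target = targets,
         sets_used = sets_used,
         posterior_trace = posterior_trace,
         corrections = if (length(corrections)) do.call(rbind, corrections)
                       else data.frame(decision = integer(0), old = character(0), new = character(0)),
         decisions = decisions,
         flashes_per_set = flashes_per_set(codebook),
         paradigm = codebook$paradigm,
         config = config),
    class = "speller_decode")
}

#' @export
print.speller_decode <- function(x, ...) {
  cat(sprintf("%s decode: '%s' -> '%s'\n", x$paradigm, x$target, x$output))
  cat(sprintf("  decisions: %d, mean sets/decision: %.2f, corrections: %d\n",
              length(x$sets_used), mean(x$sets_used), nrow(x$corrections)))
  invisible(x)
}

#' Exact Bayes posterior over strings (brute-force oracle)
#'
#' Enumerates every string over the language-model alphabet to the given
#' depth and computes the exact posterior: the language-model prior of the
#' string times the product over decisions and flash sets of the two-Gaussian
#' score likelihoods of the string's symbol at that decision. Feasible only on
#' toy instances; guards against enumeration explosion.
#'
#' @param lm A `speller_lm`.
#' @param score_sets List (one element per decision) of lists of
#'   `list(values, codebook)` per flash set, as in [decode_sequence()].
#' @param params A [score_model()].
#' @param depth Number of decisions (string length).
#' @param max_strings Enumeration guard (default 2e5).
#' @return Named probability vector over all `alphabet^depth` strings.
#' @export
exact_posterior_oracle <- function(lm, score_sets, params, depth,
                                   max_strings = 2e5) {
  A <- lm$alphabet
  if (length(A)^depth > max_strings) stop("instance too large for brute-force enumeration")
  grids <- rev(rep(list(A), depth))
  strings <- do.call(paste0, rev(expand.grid(grids, stringsAsFactors = FALSE)))
  # per-decision per-symbol log likelihood
  ll <- lapply(seq_len(depth), function(t) {
    out <- stats::setNames(rep(0, length(A)), A)
    for (st in score_sets[[t]]) {
      l1 <- set_symbol_loglik(st$values, st$codebook$groups, params,
                              st$codebook$grid$symbols)
      out[names(l1)] <- out[names(l1)] + l1
    }
    out
  })
  lp <- vapply(strings, function(s) {
    chars <- strsplit(s, "")[[1]]
    lm_string_prob(lm, s, log = TRUE) +
      sum(vapply(seq_len(depth), function(t) ll[[t]][chars[t]], numeric(1)))
  }, numeric(1))
  lp <- lp - log_sum_exp(lp)
  stats::setNames(exp(lp), strings)
}

#' Particle-filter posterior on fixed scores (for oracle comparison)
#'
#' Runs propose / update / resample on a fixed score record, with no dynamic
#' stopping and no selection, and returns the final posterior over strings —
#' the quantity the brute-force oracle computes exactly.
#'
#' @inheritParams exact_posterior_oracle
#' @param config A [decoder_config()].
#' @param seed Optional integer seed.
#' @return Named probability vector over the strings visited by particles.
#' @export
pf_posterior <- function(lm, score_sets, params, config = decoder_config(),
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ps <- init_particles(config, lm)
  depth <- length(score_sets)
  for (t in seq_len(depth)) {
    ps <- propose(ps, lm)
    for (st in score_sets[[t]]) ps <- update_weights(ps, st$values, params, st$codebook)
    if (t < depth) ps <- select_and_resample(ps, config)$ps
  }
  string_posterior(ps)
}

#' Total variation distance between two string distributions
#'
#' @param p,q Named probability vectors.
#' @return 0.5 * sum |p - q| over the union of names.
#' @export
tv_distance <- function(p, q) {
  nm <- union(names(p), names(q))
  pv <- stats::setNames(rep(0, length(nm)), nm); pv[names(p)] <- p
  qv <- stats::setNames(rep(0, length(nm)), nm); qv[names(q)] <- q
  0.5 * sum(abs(pv - qv))
}
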