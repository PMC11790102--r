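test_that("particles initialize at the root with uniform weight", {
  lm <- toy_lm3()
  ps <- init_particles(decoder_config(P = 4), lm)
  expect_equal(exp(ps$logw), rep(0.25, 4))
  expect_true(all(ps$state == lm$root))
  post <- string_posterior(ps)
  expect_equal(unname(post), 1)         # the empty string carries all the mass
  expect_named(post, "")
  expect_error(decoder_config(P = 0), "at least 1")
})

test_that("proposal samples from the language-model transition distribution", {
  ab <- c(LETTERS, "_")
  chain <- build_lm(corpus_counts("AB"), alphabet = ab, smoothing_floor = 0)
  set.seed(61)
  ps <- propose(init_particles(decoder_config(P = 50), chain), chain)
  expect_true(all(ps$cur == "A"))        # single-support proposal
  expect_true(all(ps$hist == "A"))
  # empirical root frequencies match the smoothed root distribution
  lm <- default_lm()
  set.seed(62)
  big <- propose(init_particles(decoder_config(P = 1e5), lm), lm)
  emp <- table(factor(big$cur, levels = lm$alphabet)) / 1e5
  tv <- 0.5 * sum(abs(as.numeric(emp) - lm$probs[1, ]))
  expect_lt(tv, 0.01)
  # determinism under a fixed seed
  set.seed(63); a <- propose(init_particles(decoder_config(P = 500), lm), lm)
  set.seed(63); b <- propose(init_particles(decoder_config(P = 500), lm), lm)
  expect_identical(a$hist, b$hist)
})

test_that("weight updates implement the per-flash Gaussian likelihood product", {
  # 1x2 toy grid: groups are the row {A,B} and the two singleton columns
  g <- make_grid(c("A", "B"), 1, 2)
  lm <- build_lm(corpus_counts(c("A", "B"), c(1, 1)),
                 alphabet = c("A", "B", "_"), smoothing_floor = 0)
  set.seed(64)
  cb <- rcp_codebook(g)
  params <- score_model(1, 1, 0, 1)
  ps <- propose(init_particles(decoder_config(P = 400), lm), lm)
  y <- c(0.7, -0.3, 1.4)
  ps2 <- update_weights(ps, y, params, cb)
  # hand computation: every flash either contains both or exactly one symbol
  lik <- function(sym) prod(vapply(seq_along(cb$groups), function(i)
    score_likelihood(y[i], params, sym %in% cb$groups[[i]]), numeric(1)))
  # per-particle weight ratio across hypotheses equals the density ratio
  w <- exp(ps2$logw)
  wa <- w[match("A", ps2$cur)]; wb <- w[match("B", ps2$cur)]
  expect_equal(wa / wb, lik("A") / lik("B"), tolerance = 1e-9)
  post <- string_posterior(ps2)
  expect_equal(sum(post), 1, tolerance = 1e-12)
  # uninformative likelihood leaves the weights unchanged
  p0 <- score_model(0.4, 1.1, 0.4, 1.1)
  ps3 <- update_weights(ps, y, p0, cb)
  expect_equal(ps3$logw, ps$logw, tolerance = 1e-12)
  # permuting particle order permutes but does not change normalized weights
  perm <- sample.int(ps$P)
  psp <- ps; for (f in c("state", "hist", "cur", "word", "root_index", "logw"))
    psp[[f]] <- psp[[f]][perm]
  psp2 <- update_weights(psp, y, params, cb)
  expect_equal(psp2$logw, ps2$logw[perm], tolerance = 1e-12)
  # total underflow raises with a diagnostic rather than renormalizing garbage
  dead <- ps; dead$logw <- rep(-Inf, dead$P)
  expect_error(update_weights(dead, y, params, cb), "underflow")
})

test_that("string posterior sums particle weights by history", {
  ps <- structure(list(state = c(1L, 1L, 1L), hist = c("S1", "S1", "S2"),
                       cur = c("1", "1", "2"), word = c("", "", ""),
                       root_index = c(0L, 0L, 0L),
                       logw = log(c(0.5, 0.3, 0.2)), t = 1L, P = 3L),
                  class = "particle_set")
  post <- string_posterior(ps)
  expect_equal(post[["S1"]], 0.8)
  expect_equal(post[["S2"]], 0.2)
  expect_equal(sum(post), 1)
})

test_that("dynamic stopping fires on threshold or set cap", {
  cfg <- decoder_config(p_thresh = 0.95, max_sets = 10)
  expect_true(dynamic_stop_check(c(a = 0.96, b = 0.04), 1, cfg))
  expect_true(dynamic_stop_check(c(a = 0.5, b = 0.5), 10, cfg))
  expect_false(dynamic_stop_check(c(a = 0.5, b = 0.5), 3, cfg))
})

test_that("selection takes the MAP string and resampling follows the weights", {
  lm <- toy_lm3()
  cfg <- decoder_config(P = 4)
  # point-mass posterior: resampled set identical
  ps <- structure(list(state = rep(2L, 4), hist = rep("AB", 4), cur = rep("B", 4),
                       word = rep("AB", 4), root_index = rep(0L, 4),
                       logw = rep(log(0.25), 4), t = 2L, P = 4L),
                  class = "particle_set")
  sr <- select_and_resample(ps, cfg)
  expect_equal(sr$selected, "AB")
  expect_identical(sr$ps$hist, ps$hist)
  # equal-weight maxima break ties lexicographically
  tie <- ps; tie$hist <- c("ZZ", "ZZ", "AA", "AA")
  expect_equal(select_and_resample(tie, cfg)$selected, "AA")
  # multinomial resampling frequencies reflect the weights
  set.seed(65)
  big <- structure(list(state = rep(1L, 3), hist = c("X", "Y", "Z"),
                        cur = c("X", "Y", "Z"), word = c("", "", ""),
                        root_index = c(0L, 0L, 0L),
                        logw = log(c(0.6, 0.3, 0.1)), t = 1L, P = 3L),
                   class = "particle_set")
  # resample P = 1e4 from the three hypotheses
  big$P <- 3L
  draws <- local({
    w <- exp(big$logw)
    idx <- sample.int(3, 1e4, replace = TRUE, prob = w)
    table(factor(big$hist[idx], levels = c("X", "Y", "Z")))
  })
  chi <- stats::chisq.test(as.numeric(draws), p = c(0.6, 0.3, 0.1))
  expect_gt(chi$p.value, 0.01)
})

test_that("particle filter agrees with the exact Bayes posterior on a toy instance", {
  g <- toy_grid4()
  lm <- toy_lm3()
  params <- score_model(1, 1, 0, 1)
  set.seed(66)
  cb <- rcp_codebook(g)
  score_sets <- list(toy_score_set(cb, "A", params, n_sets = 2),
                     toy_score_set(cb, "B", params, n_sets = 2))
  ex <- exact_posterior_oracle(lm, score_sets, params, depth = 2)
  expect_equal(sum(ex), 1, tolerance = 1e-12)
  pf <- pf_posterior(lm, score_sets, params, decoder_config(P = 5000), seed = 67)
  expect_lt(tv_distance(ex, pf), 0.03)
  # uninformative scores: the oracle posterior equals the language-model prior
  p0 <- score_model(0, 1, 0, 1)
  ex0 <- exact_posterior_oracle(lm, score_sets, p0, depth = 2)
  prior <- vapply(names(ex0), function(s) lm_string_prob(lm, s), numeric(1))
  expect_equal(unname(ex0), unname(prior / sum(prior)), tolerance = 1e-9)
  # single character, hand-derivable Bayes update
  one <- list(score_sets[[1]][1])
  ex1 <- exact_posterior_oracle(lm, one, params, depth = 1)
  st <- one[[1]][[1]]
  hand <- vapply(lm$alphabet, function(sym) {
    lm_string_prob(lm, sym) * prod(vapply(seq_along(st$codebook$groups), function(i)
      score_likelihood(st$values[i], params, sym %in% st$codebook$groups[[i]]),
      numeric(1)))
  }, numeric(1))
  hand <- hand / sum(hand)
  expect_equal(ex1[names(hand)], hand, tolerance = 1e-9)
  expect_error(exact_posterior_oracle(default_lm(), list(), score_model(), depth = 5),
               "too large")
})

test_that("uninformative evidence leaves the depth-1 posterior at the prior", {
  lm <- default_lm()
  g <- make_grid()
  set.seed(68)
  cb <- rcp_codebook(g)
  p0 <- score_model(0, 1, 0, 1)
  sets <- list(toy_score_set(cb, "T", p0, n_sets = 1))
  pf <- pf_posterior(lm, sets, p0, decoder_config(P = 2e4), seed = 69)
  root <- stats::setNames(lm$probs[1, ], lm$alphabet)
  expect_lt(tv_distance(pf, root), 0.02)
})

test_that("decoding recovers the target at high separability", {
  lm <- default_lm()
  g <- make_grid()
  set.seed(71)
  cb <- rcp_codebook(g)
  dec <- decode_sequence("THE_QUICK", cb, lm, score_model(5, 1, 0, 1),
                         decoder_config(P = 2000), seed = 72)
  expect_equal(dec$output, "THE_QUICK")
  expect_equal(ld_accuracy(dec$output, "THE_QUICK"), 1)
  expect_lt(stats::median(dec$sets_used), 10)
  expect_length(dec$sets_used, 9)
  expect_equal(dec$flashes_per_set, 12L)
})

test_that("an unreachable threshold forces the flash-set cap on every character", {
  lm <- default_lm()
  set.seed(73)
  cb <- rcp_codebook(make_grid())
  dec <- decode_sequence("THE", cb, lm, score_model(2, 1, 0, 1),
                         decoder_config(P = 500, p_thresh = 1.0, max_sets = 4), seed = 74)
  expect_true(all(dec$sets_used == 4L))
})

test_that("the language model improves decoding over a uniform prior at fixed d'", {
  g <- make_grid()
  lm <- default_lm()
  unif <- uniform_lm(g$symbols)
  text <- strrep("THE_QUICK_BROWN_FOX_", 10)   # 200 characters
  params <- score_model(1, 1, 0, 1)
  cfg <- decoder_config(P = 1000)
  set.seed(75)
  cb <- rcp_codebook(g)
  dec_lm <- decode_sequence(text, cb, lm, params, cfg, seed = 76)
  dec_un <- decode_sequence(text, cb, unif, params, cfg, seed = 76)
  expect_gt(ld_accuracy(dec_lm$output, text), ld_accuracy(dec_un$output, text))
})

test_that("retroactive correction replaces earlier characters and is logged", {
  # two-word model: after weak first-character evidence the decoder may commit
  # to the wrong word start; strong second-character evidence flips it back
  g <- toy_grid4()
  lm <- build_lm(corpus_counts(c("CA", "BB"), c(1, 1)), alphabet = g$symbols,
                 smoothing_floor = 1e-4)
  params <- score_model(2, 1, 0, 1)
  set.seed(77)
  cb <- rcp_codebook(g)
  # char 1: mildly favour B over the true C; char 2: strongly favour A
  mk <- function(target, strength) {
    cbi <- reinstantiate_set(cb)
    att <- vapply(cbi$groups, function(gr) target %in% gr, logical(1))
    list(values = ifelse(att, strength, 0), codebook = cbi)
  }
  score_sets <- list(list(mk("B", 0.8)), list(mk("A", 6)))
  cfg <- decoder_config(P = 5000, p_thresh = 0.999, max_sets = 1)
  dec <- decode_sequence("CA", cb, lm, params, cfg, seed = 78, score_sets = score_sets)
  expect_equal(dec$output, "CA")
  expect_gte(nrow(dec$corrections), 1)
  expect_equal(dec$corrections$old[1], "B")
  expect_equal(dec$corrections$new[1], "C")
})

test_that("word projection distributes mass over completions and respects thresholds", {
  ab <- c(LETTERS, "_")
  one <- build_lm(corpus_counts("CAR"), alphabet = ab, smoothing_floor = 0)
  cfg <- decoder_config(P = 200, rho = 0.5)
  set.seed(79)
  ps <- propose(init_particles(cfg, one), one)     # every particle at "C"
  pr <- project_for_words(ps, one, cfg, grid = make_grid())
  expect_equal(unname(pr$words["CAR"]), 1)          # one-word model: certainty
  expect_equal(pr$selected, "CAR")                  # 1 > 0.40
  expect_lte(nrow(pr$suggestions), 6)
  expect_equal(pr$suggestions$cell[1], "_")         # suggestions take the last cells
  # three equally likely words: no word clears the 0.40 selection threshold
  lm3 <- build_lm(corpus_counts(c("AB", "CD", "EF")), alphabet = ab,
                  smoothing_floor = 0)
  set.seed(80)
  ps3 <- propose(init_particles(decoder_config(P = 3000, rho = 0.5), lm3), lm3)
  pr3 <- project_for_words(ps3, lm3, decoder_config(P = 3000, rho = 0.5),
                           grid = make_grid())
  expect_true(is.na(pr3$selected))
  expect_true(all(abs(pr3$words - 1 / 3) < 0.1))
  # k_words caps the suggestion list
  lm8 <- build_lm(corpus_counts(paste0(LETTERS[1:8], "X")), alphabet = ab,
                  smoothing_floor = 0)
  set.seed(81)
  ps8 <- propose(init_particles(decoder_config(P = 4000, rho = 1), lm8), lm8)
  pr8 <- project_for_words(ps8, lm8, decoder_config(P = 4000, rho = 1, k_words = 6),
                           grid = make_grid())
  expect_equal(nrow(pr8$suggestions), 6)
})

test_that("predictive spelling completes words early", {
  lm <- default_lm()
  g <- make_grid()
  set.seed(82)
  cb <- rcp_codebook(g)
  cfg <- decoder_config(P = 2000, predictive = TRUE, rho = 0.5)
  dec <- decode_sequence("THE_QUICK_", cb, lm, score_model(3, 1, 0, 1), cfg, seed = 83)
  expect_equal(ld_accuracy(dec$output, "THE_QUICK_"), 1)
  # at least one word completion fired, so fewer decisions than characters
  expect_lt(length(dec$sets_used), nchar("THE_QUICK_"))
  words_fired <- vapply(dec$decisions, function(d) !is.na(d$word_selected), logical(1))
  expect_true(any(words_fired))
})
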