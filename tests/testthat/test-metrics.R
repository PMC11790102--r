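test_that("character accuracy counts matching positions", {
  expect_equal(char_accuracy("THE", "THE"), 1)
  expect_equal(char_accuracy("TXE", "THE"), 2 / 3)
  expect_error(char_accuracy("TH", "THE"), "length")
  # a 20-character session pair with one substitution: the table granularity
  out <- paste0("THE_QUICK_", "BROWN_FOY_")
  tgt <- paste0("THE_QUICK_", "BROWN_FOX_")
  expect_equal(char_accuracy(out, tgt), 0.95)
})

test_that("edit distance satisfies the textbook identities and metric axioms", {
  expect_equal(levenshtein("", "ABC"), 3L)
  expect_equal(levenshtein("ABC", "ABC"), 0L)
  expect_equal(levenshtein("KITTEN", "SITTING"), 3L)
  set.seed(91)
  rand_str <- function() paste(sample(c("A", "B", "C"), sample(0:6, 1), replace = TRUE),
                               collapse = "")
  for (i in 1:25) {
    a <- rand_str(); b <- rand_str(); c <- rand_str()
    expect_identical(levenshtein(a, b), levenshtein(b, a))
    expect_lte(levenshtein(a, c), levenshtein(a, b) + levenshtein(b, c))
    expect_gte(levenshtein(a, b), abs(nchar(a) - nchar(b)))
  }
})

test_that("Levenshtein accuracy generalizes positional accuracy", {
  expect_equal(ld_accuracy("THE", "THE"), 1)
  expect_equal(ld_accuracy("THE_QUICKX", strrep("Z", 10)), 0)   # clamped at 0
  expect_equal(ld_accuracy("ABCDEFGHIJX", "ABCDEFGHIJ"), 0.9)   # one insertion, n = 10
  expect_error(ld_accuracy("A", ""), "empty target")
  set.seed(92)
  for (i in 1:25) {
    n <- sample(4:10, 1)
    base <- sample(LETTERS[1:6], n, replace = TRUE)
    k <- sample(0:(n - 1), 1)
    out <- base
    pos <- sample(n, k)
    out[pos] <- sample(c("1", "2", "3", "4", "5", "6", "7", "8", "9"), k)  # fresh symbols
    a <- paste(base, collapse = ""); b <- paste(out, collapse = "")
    # substitution-only pairs: edit distance equals the Hamming distance
    expect_equal(ld_accuracy(b, a), char_accuracy(b, a))
    # in general the edit distance can only be smaller than the Hamming count
    r <- paste(sample(c("A", "B"), n, replace = TRUE), collapse = "")
    expect_gte(ld_accuracy(r, a), char_accuracy(r, a))
  }
})

test_that("Wolpaw bit rate matches its closed forms and is maximal at perfect accuracy", {
  expect_equal(bit_rate(1, 36), log2(36))
  expect_equal(bit_rate(0.98, 36), 4.9259, tolerance = 1e-4)
  accs <- seq(0, 1, by = 0.01)
  brs <- vapply(accs, bit_rate, numeric(1), n_symbols = 36)
  expect_equal(which.max(brs), length(accs))
  expect_true(all(diff(brs[accs >= 1 / 36]) > 0))       # monotone above chance
  expect_lt(abs(bit_rate(1e-12, 36) - bit_rate(0, 36)), 1e-9)  # continuity at 0
  # chance-level accuracy is never better than any accuracy above chance
  expect_true(all(bit_rate(1 / 36, 36) <= brs[accs > 1 / 36]))
  expect_error(bit_rate(1.2, 36))
})

test_that("the general mutual-information bit rate reduces to the uniform form", {
  N <- 36
  for (acc in c(0.5, 0.9, 0.98)) {
    conf <- matrix((1 - acc) / (N - 1), N, N)
    diag(conf) <- acc
    expect_equal(bit_rate_general(rep(1 / N, N), conf), bit_rate(acc, N),
                 tolerance = 1e-9)
  }
})

test_that("selection rate follows the SOA timing arithmetic", {
  tm <- timing_model()
  expect_equal(tm$soa, 0.125)
  # RCP, one set per character: 12 x 0.125 + 3.5 = 5 s per character
  expect_equal(selection_rate(rep(1, 10), 12, tm), 12)
  # COMB(9,2), one set: 9 x 0.125 + 3.5 = 4.625 s
  expect_equal(selection_rate(rep(1, 10), 9, tm), 60 / 4.625, tolerance = 1e-9)
  expect_equal(round(selection_rate(rep(1, 10), 9, tm), 2), 12.97)
  # doubling the flash sets strictly decreases the rate
  expect_lt(selection_rate(rep(2, 10), 12, tm), selection_rate(rep(1, 10), 12, tm))
})

test_that("ITR is the bit rate times the selection rate, clamped at zero", {
  expect_equal(itr(0, 15), 0)
  expect_equal(itr(bit_rate(1, 36), 10) / 10, log2(36))
  expect_warning(v <- itr(-0.5, 10), "clamped")
  expect_equal(v, 0)
  row <- metrics_row("THE_QUICK_", "THE_QUICK_", rep(2, 10), 12)
  expect_equal(row$itr, row$br * row$sr, tolerance = 1e-9)
  expect_equal(row$acc, 100)
})

test_that("aggregation reproduces mean rows and a null comparison", {
  rows <- data.frame(subject = rep(1:5, 3),
                     paradigm = rep(c("RCP", "CBP", "COMB"), each = 5),
                     sr = rep(c(14, 14, 14), each = 5),
                     acc = rep(100, 15),
                     itr = rep(c(70, 70, 70), each = 5))
  rep0 <- aggregate_report(rows)
  expect_true(all(rep0$mean$sr == 14))
  # identical metric values across paradigms: H ~ 0, p ~ 1
  expect_true(all(is.na(rep0$tests$p) | rep0$tests$p > 0.99))
  expect_error(aggregate_report(rows[rows$subject == 1, ]), "at least 2 subjects")
})

test_that("waveform analysis flags the deflection window and controls the null FDR", {
  set.seed(93)
  subj <- lapply(1:10, function(i) simulate_erp_epochs(60, 300, noise_sd = 8))
  av <- subject_averages(subj)
  wa <- waveform_analysis(av$attended, av$nonattended)
  t_ms <- subj[[1]]$t_ms
  peak_window <- which(abs(t_ms - 300) <= 40)
  expect_true(all(wa$mask[peak_window]))          # the positive peak is detected
  expect_gt(sum(wa$mask), 20)
  # null: attended and non-attended generated identically
  subj0 <- lapply(1:10, function(i) simulate_erp_epochs(60, 300, noise_sd = 8, peak_amp = 0))
  av0 <- subject_averages(subj0)
  wa0 <- waveform_analysis(av0$attended, av0$nonattended)
  expect_lte(mean(wa0$mask), 0.05)
  # degenerate noiseless case: the mask is exactly the template support
  subjT <- lapply(1:6, function(i) simulate_erp_epochs(5, 5, noise_sd = 0))
  avT <- subject_averages(subjT)
  waT <- waveform_analysis(avT$attended, avT$nonattended)
  expect_identical(waT$mask, subjT[[1]]$template != 0)
  expect_error(waveform_analysis(av$attended[1:3, ], av$nonattended[1:3, ]),
               "at least 5")
  expect_error(waveform_analysis(av$attended[, 1:10], av$nonattended), "equal dimensions")
})

test_that("the bundled performance tables parse and are internally consistent", {
  off <- speller_tables("offline")
  onl <- speller_tables("online")
  expect_equal(nrow(off), 30)
  expect_equal(nrow(onl), 30)
  expect_setequal(unique(onl$paradigm), c("RCP", "CBP", "COMB"))
  # ITR cells are consistent with BR(acc) x SR up to printed rounding
  br <- vapply(onl$acc / 100, bit_rate, numeric(1), n_symbols = 36)
  expect_lt(stats::median(abs(br * onl$sr - onl$itr)), 0.05)
})
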