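---
title: "Simulating P300 speller typing: paradigms, language models and dynamic stopping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating P300 speller typing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pfspeller)
```

## The problem

A P300 speller presents a 6×6 matrix of characters and flashes groups of them
while the user attends to one target. Flashes containing the target elicit an
event-related potential with a positive deflection roughly 300 ms
post-stimulus; a classifier turns each flash epoch into a scalar score, and a
decoder accumulates scores into a decision. Typing speed depends on three
levers that interact: the *flashing paradigm* (which groups flash, and how
many flashes one complete pass takes), the *prior* over what the user is
typing (a language model), and the *stopping rule* (how much evidence to
collect before committing). This package simulates that full loop so the
levers can be studied separately and jointly, without EEG hardware.

## Flashing paradigms

One *flash set* is a complete pass of a codebook's groups, enough to identify
any character noiselessly; each character's *signature* is the set of flash
indices containing it.

* **Row-column (RCP)** — the 6 rows and 6 columns in random order: 12 flashes
  per set, signatures of size 2. Adjacent characters flash together (rows and
  columns are contiguous), and random order allows immediate repeats of a
  target — the two classic weaknesses (adjacency errors and the "double
  flash" suppression of the second of two stimuli closer than ~500 ms).
* **Checkerboard (CBP)** — the grid is split by checkerboard parity into two
  18-character classes, each randomly placed into a virtual matrix whose rows
  flash first, then columns. Parity guarantees no two 4-adjacent characters
  ever flash together, and interleaving the two classes' rows (and columns)
  makes consecutive groups disjoint, eliminating double flashes — at the cost
  of 18 flashes per set.
* **Combinatorial (COMB)** — every character gets a distinct k-subset of n
  flash indices; group *i* is all characters whose subset contains *i*.
  C(9,2) = 36 addresses the full grid with only 9 flashes per set; C(7,3) = 35
  leaves one grid cell unaddressable.

Design choices where the construction is under-determined:

* The virtual-matrix shape for a 36-character CBP is set to two 3×6 matrices
  (18 flashes per set) and is configurable; any split of 18 characters into a
  virtual matrix needs at least 9 flashes per class.
* Within a CBP set, randomization happens within the row block and within the
  column block, preserving the rows-then-columns structure.
* COMB re-draws the character→subset assignment on every set (configurable
  off via `params$reassign = FALSE`); the figure-style sequential assignment
  is only a didactic special case, and re-randomization averages out
  persistent hard-to-separate character pairs.
* `comb_codebook` treats a capacity shortfall as an error unless the caller
  opts into dropping symbols (`drop_symbols = TRUE` drops the last row-major
  cell — the space in the default alphabet, so COMB(7,3) is not usable for
  texts containing spaces without re-configuring).

## Language model

`build_lm()` constructs a directed prefix automaton: one state per distinct
prefix of a corpus word, rooted at the empty string. The raw transition
probability to the next character is the ratio of prefix counts,
`count(s+c)/count(s)`; the probability of ending a word (typing `"_"`) is
`word_count(s)/count(s)`, and word ends return to the root. These raw
probabilities are exact relative frequencies — the probability of typing a
whole word from the root telescopes to its corpus share.

Because a word corpus contains no digits, raw probabilities would assign exact
zeros to decodable targets. A floor `f` (default 1e-4) is added to every
alphabet symbol and the row renormalized: `p' = (p + f) / (1 + f·A)`. Symbols
with no prefix-tree successor restart at the root. With `f > 0` every string
over the grid alphabet has positive prior, so the decoder can always recover
the truth; with `f = 0` the model is the pure relative-frequency automaton
used in the worked examples. Whether (and how much) the original online
systems smoothed is not documented anywhere we know of; the floor is this
package's choice and only materially affects targets outside the corpus
vocabulary.

The bundled corpus (`inst/extdata/corpus_synthetic.txt`) is a hand-assembled,
~330-word frequency list with realistic relative magnitudes for common English
words — *synthetic*, not an extract of any copyrighted corpus. Any
`token<TAB>count` file can replace it.

## Score model and synthetic signals

Given the target, per-flash classifier scores are modelled as independent
draws from two Gaussians: `N(mu_a, sigma_a²)` when the flash contains the
target, `N(mu_n, sigma_n²)` otherwise. This is both the generator
(`simulate_scores`) and the decoder's likelihood (`score_likelihood`), i.e.
the simulation is well-specified by construction. The separability
`d' = (mu_a − mu_n) / sqrt((sigma_a² + sigma_n²)/2)` is the single knob that
controls difficulty. Defaults `mu_a = 1, mu_n = 0, sigma_a = sigma_n = 1`
(d' = 1) make dynamic stopping terminate in roughly 3–6 sets per character,
the regime online systems operate in. No study reports its fitted score-model
parameters, so these defaults are stated as conventional, not matched to any
dataset.

The epoch generator (`simulate_erp_epochs`) produces 800 ms, 256 Hz epochs:
attended epochs add a deflection template — a positive Gaussian bump at
300 ms preceded by a negativity of half the amplitude at 200 ms — to white
noise; non-attended epochs are noise only. `train_swlda()` runs the classic
calibration: decimate (×8), then stepwise OLS feature selection by partial-F
tests (defaults `p_enter = 0.10`, `p_remove = 0.15`, at most 60 features —
standard values in this literature, configurable), and the resulting scores
on held-out epochs are approximately Gaussian per class, which is what
justifies the two-Gaussian abstraction at the simulation level.

What the generator deliberately does **not** emulate: overlapping epochs at
the 125 ms SOA (scores are independent across flashes by assumption),
artifacts and non-stationarity, channel covariance and montage geometry,
latency jitter across trials, and any paradigm dependence of signal quality —
the last point matters for interpretation (below).

## The particle-filter decoder

Particles carry a language-model state, a typed-string history, the index of
their last root visit, and a weight. One character decision runs:
propose (sample the next character from the prior) → for each flash set,
multiply weights by the per-flash Gaussian likelihood of the particle's
current character (log space with max-subtraction; if an entire set
underflows, that is an error, never a silent renormalization) → stop when the
maximum string posterior exceeds `p_thresh` (0.95, the value online systems
use) or after `max_sets = 10` sets → emit the MAP string (ties broken
lexicographically, for determinism) and resample multinomially
("new particles sampled from the current ones by weight", with systematic
resampling available as a variance-reduced option). Because the emitted
string is the MAP over whole histories, later evidence can rewrite earlier
characters; such retroactive corrections are logged.

Correctness is established against `exact_posterior_oracle()`, a brute-force
enumeration of all strings to a given depth with the exact Bayes posterior:
on a toy 4-symbol grid with a 3-word model, the particle filter at P = 20,000
matches the oracle within total variation 0.02 (typically well under 0.01).
The default particle count P = 10,000 is set by a practical constraint: the
rarest characters the study texts need (e.g. `Q` at a word start, prior
≈ 0.002) must be proposed by several particles, since the proposal is the
prior; at P = 10,000 about 20 particles carry `Q`. Below P ≈ 2,000 particle
impoverishment at rare characters, not weight degeneracy, is the binding
failure mode.

Predictive spelling projects a fraction `rho` (default 0.5; the source
literature does not print its value) of the particles through the model to
the next word end; a word whose projected posterior exceeds 0.40 is selected
immediately and completes the current word, and the top 6 suggestions are
mapped onto the last grid cells. Projected particles on non-suggested words
get zero weight and disappear at the next resampling. We interpret word
selection as terminating the word at once; whether it should instead merely
shortcut the remaining per-character thresholds is ambiguous in the source
description, and the chosen semantics is the simpler and stronger reading.

## Metrics and timing

Accuracy is Levenshtein-based, `(n − LD)/n` clamped at zero, which reduces to
positional accuracy for equal-length substitution-only outputs and stays
meaningful when predictive spelling changes the output length. The Wolpaw bit
rate uses base-2 logarithms and N = 36; negative values (below-chance
accuracy) are clamped to zero with a warning when forming ITR, the standard
convention. The general mutual-information bit rate with a non-uniform
confusion model is provided (`bit_rate_general`) as a utility; no printed
number exercises it.

Selection rate reconstructs time from counts:
`sum(sets) × flashes_per_set × 0.125 s + decisions × 3.5 s`. The real
system's pause bookkeeping is not printed anywhere, so simulated SR is
comparable to published values only in order of magnitude; the package never
asserts SR agreement with printed tables, while the *arithmetic* identities
(e.g. one RCP set per character ⇒ exactly 12.0 characters/min) are exact.

The waveform analysis averages attended and non-attended epochs per subject,
tests each latency with a paired Wilcoxon signed-rank across subjects and
controls the false discovery rate with Benjamini-Hochberg (the FDR variant is
our choice; the method description does not name one). With ten simulated
subjects the exact signed-rank floor is p ≈ 0.002, so single isolated
latencies cannot survive FDR correction — detection relies on the deflection
spanning many samples, which the template does.

## The paradigm-comparison experiment, and what it shows

`run_experiment()` reproduces the study design on synthetic subjects: two
calibration sessions per paradigm (10 characters × 10 sets each, so every
character is flashed 20 times under RCP), score-model fitting from the
labeled flashes, then online decoding of `"THE_QUICK_"` and `"BROWN_FOX_"`
with dynamic stopping, the decoder using the *estimated* parameters while
scores are generated from the true ones. Ten synthetic subjects span
d' = 0.8–1.6, a deliberately heterogeneous but paradigm-matched ladder;
paradigm test order is shuffled per subject and logged.

An important structural result falls out of the simulation, and it is worth
stating precisely. At *matched* per-flash d', all three paradigms deliver the
same evidence per flash set (each character is attended in exactly k = 2
flashes per set, and a typical competitor differs in ~4 flashes), so dynamic
stopping uses statistically the same number of sets and reaches the same
accuracy in all three. The time per set, however, is proportional to the
flashes per set — 12 (RCP), 18 (CBP), 9 (COMB(9,2)) — so the simulated
selection rate and hence ITR order as COMB > RCP > CBP with a relative spread
of roughly 20–45% depending on d' (about 30% at the defaults; run
`scripts/acceptance.R` to recompute it). Matched-d' simulation therefore does
**not** reproduce the empirical finding that the three paradigms perform
equivalently online. The two statements are compatible: equivalence in human
data implies the paradigms do not share a single per-flash d' — CBP's design
goal is precisely to *raise* signal quality (fewer adjacency and double-flash
errors), buying back the time its longer sets cost. The package's assumption
ledger makes that trade explicit and measurable: users can give CBP a higher
per-subject d' than RCP and ask how much is needed for parity. The acceptance
suite keeps the matched-d' invariance check at its stated thresholds, and it
fails by design of the timing arithmetic; the accompanying analysis is this
section.

## Numerical and reproducibility choices

* All weight arithmetic is in log space with max-subtraction; normalization
  checks guard every update.
* MAP ties break lexicographically; resampling is multinomial by default.
* The ERP template zeroes numerically negligible tails so that degenerate
  (noiseless) analyses have exact compact support.
* Low-level generators consume the current R RNG stream; every entry point
  (`schedule_session`, `simulate_scores`, `decode_sequence`,
  `run_experiment`, the CLI, the acceptance script) takes an integer seed,
  and derived sub-seeds stay below 2³¹. Fixed seed ⇒ bit-identical outputs,
  including the CSV reports.
* Problem sizes used by the test suite: oracle comparisons at P = 20,000 on a
  4-symbol grid at depth 2; parameter recovery from 5,000 row-column sets
  (10⁴ attended flashes); codebook invariants over 1,000 regenerations;
  stopping-threshold monotonicity on 200 isolated character decisions per
  threshold at P = 2,000 (with common random numbers the stopping time is
  pathwise monotone in the threshold); the full synthetic study at
  P = 10,000 with 10 subjects.

## Limitations

* The simulation is well-specified (the decoder assumes the true generative
  model); real scores are only approximately Gaussian and not independent at
  a 125 ms SOA, so absolute simulated accuracies are optimistic.
* The timing model omits system pauses beyond the 3.5 s inter-character
  interval; selection rates are order-of-magnitude, not calibrated.
* The language model is word-internal only: no cross-word context beyond the
  root restart, no n-gram or neural continuation.
* Predictive spelling does not simulate the EEG of users attending suggestion
  cells; selection is driven purely by the projected posterior.
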