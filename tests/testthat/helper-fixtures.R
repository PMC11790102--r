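# Shared toy fixtures, all built in code.

toy_grid4 <- function() make_grid(c("A", "B", "C", "_"), 2, 2)

toy_lm3 <- function(floor = 1e-3) {
  # 3-word language model over the 4-symbol toy grid
  build_lm(corpus_counts(c("AB", "AC", "BC"), c(2, 1, 1)),
           alphabet = toy_grid4()$symbols, smoothing_floor = floor)
}

default_corpus <- function() {
  read_corpus(system.file("extdata", "corpus_synthetic.txt", package = "pfspeller"))
}

default_lm <- function() {
  build_lm(default_corpus())
}

# fixed per-flash scores for one set: attended draws for the target's groups
toy_score_set <- function(codebook, target, params, n_sets = 1L) {
  lapply(seq_len(n_sets), function(s) {
    cbi <- reinstantiate_set(codebook)
    att <- vapply(cbi$groups, function(g) target %in% g, logical(1))
    values <- ifelse(att,
                     rnorm(length(att), params$mu_a, params$sigma_a),
                     rnorm(length(att), params$mu_n, params$sigma_n))
    list(values = values, codebook = cbi)
  })
}

reinstantiate_set <- function(cb) getFromNamespace("reinstantiate_codebook", "pfspeller")(cb)

# rank-based AUC (Mann-Whitney statistic)
rank_auc <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels); n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
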