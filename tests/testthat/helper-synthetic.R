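# shared builders for small in-code fixtures

tiny_compounds <- function(ids, truth, n_dereg, cytotoxic = FALSE,
                           buckets = "1x", n_replicates = 3) {
  grid <- expand.grid(compound_id = ids, bucket = buckets,
                      stringsAsFactors = FALSE)
  grid$truth <- rep(truth, length.out = nrow(grid))
  grid$n_deregulated <- rep(n_dereg, length.out = nrow(grid))
  grid$cytotoxic <- rep(cytotoxic, length.out = nrow(grid))
  grid$n_replicates <- n_replicates
  grid
}

# small separable two-class study used by several classifier tests; the
# planted count matches the responsive pool so teratogen signatures overlap
# almost completely, which is what "separable" means for a cross-compound
# classifier
separable_config <- function(seed = 42, n_probe_sets = 1000,
                             n_dereg = 500, noise_sd = 0.1) {
  cmp <- rbind(
    tiny_compounds(sprintf("T%02d", 1:5), "teratogen", n_dereg,
                   buckets = c("1x", "20x")),
    tiny_compounds(sprintf("N%02d", 1:3), "non_teratogen", 0,
                   buckets = c("1x", "20x")))
  simulation_config(cmp, n_probe_sets = n_probe_sets, noise_sd = noise_sd,
                    n_batches = 2, seed = seed)
}

# the default stated-world study is expensive enough to build once per run
default_sim_cache <- new.env(parent = emptyenv())
default_sim <- function(seed = 20260912) {
  key <- as.character(seed)
  if (is.null(default_sim_cache[[key]])) {
    sim <- generate_study(default_simulation_config(seed = seed))
    sim$nd <- normalize_to_controls(sim$study)
    default_sim_cache[[key]] <- sim
  }
  default_sim_cache[[key]]
}

# hand-built score set
make_scores <- function(score, truth, cytotoxic = FALSE, bucket = "20x",
                        kind = "sps") {
  n <- length(score)
  df <- data.frame(
    compound_id = sprintf("C%02d", seq_len(n)), bucket = bucket,
    truth = truth, cytotoxic = rep(cytotoxic, length.out = n),
    score = score, cytotox_assigned = rep(cytotoxic, length.out = n),
    substituted_from_1x = FALSE)
  attr(df, "score_kind") <- kind
  class(df) <- c("score_set", "data.frame")
  df
}

# brute-force pair-count AUC oracle (independent of the rank-based path)
auc_oracle <- function(score, truth) {
  pos <- score[truth == "teratogen"]
  neg <- score[truth != "teratogen"]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# exact hypergeometric upper-tail oracle by enumeration
hyper_tail_oracle <- function(x, K, N, n) {
  js <- x:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# half-up rounding used when comparing against printed two-decimal metrics
round2 <- function(x) floor(x * 100 + 0.5) / 100
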