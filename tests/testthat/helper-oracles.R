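# Independent oracles used across tests.

# Mann-Whitney U computed by pairwise comparison (not ranks); two-sided
# exact p by enumerating every assignment of the pooled sample to group A.
oracle_mww_p <- function(x, y, alternative = "two.sided") {
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  mu <- n1 * n2 / 2
  obs <- u_stat(x, y)
  idx <- utils::combn(n1 + n2, n1)
  us <- apply(idx, 2, function(i) u_stat(pooled[i], pooled[-i]))
  eps <- 1e-9
  switch(alternative,
         two.sided = mean(abs(us - mu) >= abs(obs - mu) - eps),
         less      = mean(us <= obs + eps),
         greater   = mean(us >= obs - eps))
}

# Fisher's exact two-sided p by direct enumeration of all tables with the
# observed margins, using explicit hypergeometric probabilities.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) {
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
  }, numeric(1))
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# small, fast simulation configuration for unit tests (overridable defaults)
tiny_config <- function(seed = 1L, ...) {
  defaults <- list(seed = seed, n_cells_control = 5000, n_cells_treated = 5000,
                   n_control_replicates = 12L, events_per_culture = 800L,
                   events_per_diploid_culture = 1000L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
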