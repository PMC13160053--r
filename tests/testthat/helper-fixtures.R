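# Shared fixtures: all built in code at test time.

# Small neutral library configuration.
neutral_config <- function(n_positions = 6, depth = 2e5, seed = 11,
                           n_replicas = 2, ...) {
  sim_config(n_positions = n_positions, depth_t0 = depth, depth_tf = depth,
             n_replicas = n_replicas, seed = seed,
             dfe = dfe_spec(p_deleterious = 0, p_beneficial = 0), ...)
}

# Hand-built fitness table: one row per (replica, codon) with chosen s,
# variance and P, for tests that need exact control over the calls.
manual_fit <- function(rows) {
  fit <- dplyr::bind_rows(rows)
  defaults <- list(condition = "c1", wt_codon = "AAA", mut_codon = "CCC",
                   wt_aa = "K", mut_aa = "P", class = "missense",
                   sigma2_w = 1e-4)
  for (nm in names(defaults)) {
    if (!nm %in% names(fit)) fit[[nm]] <- defaults[[nm]]
  }
  if (!"p" %in% names(fit)) {
    fit$p <- 2 * pnorm(-abs(fit$s / sqrt(fit$sigma2_w)))
  }
  class(fit) <- c("fitness_table", class(fit))
  fit
}

# Exhaustive sign-enumeration null of the Wilcoxon signed-rank statistic:
# an oracle independent of stats::wilcox.test. Zero differences are
# dropped; requires untied absolute values.
exact_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 16, !anyDuplicated(abs(d)))
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_null <- as.vector(signs %*% rk)
  p_lo <- mean(v_null <= v_obs)
  p_hi <- mean(v_null >= v_obs)
  min(1, 2 * min(p_lo, p_hi))
}
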