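# Condition comparisons: Wilcoxon signed-rank positional shifts,
# codon-pooled t-tests, DFE-shift partitions.

# Two-replica fitness tables with full control over per-codon s values.
two_cond_fit <- function(s_by_codon_a, s_by_codon_b, sigma2 = 1e-4) {
  build <- function(s_map, cond) {
    rows <- lapply(seq_len(nrow(s_map)), function(i) {
      tibble::tibble(condition = cond, replica = s_map$replica[i],
                     position = s_map$position[i],
                     mut_codon = s_map$mut_codon[i],
                     mut_aa = s_map$mut_aa[i],
                     s = s_map$s[i], sigma2_w = sigma2)
    })
    manual_fit(rows)
  }
  list(a = build(s_by_codon_a, "A"), b = build(s_by_codon_b, "B"))
}

test_that("identical conditions give no signed-rank signal", {
  cfg <- neutral_config(n_positions = 4, depth = 5e4, seed = 53)
  fit <- fit_counts(simulate_experiment(cfg)$counts, r = 2^10)
  res <- wilcoxon_positions(fit, fit)
  expect_true(all(is.na(res$p)))        # all paired differences are zero
  expect_false(any(res$significant))
  expect_true(all(res$delta_s == 0))
})

test_that("signed-rank P matches the exhaustive enumeration oracle", {
  # all-negative differences, n = 6: two-sided P = 2/2^6
  d6 <- c(-0.11, -0.23, -0.05, -0.17, -0.29, -0.08)
  expect_equal(exact_signed_rank_p(d6), 2 / 64)
  cases <- withr::with_seed(61, lapply(c(4, 5, 7, 9, 12), function(n) {
    round(runif(n, -1, 1), 3)
  }))
  for (d in cases) {
    d <- d[d != 0 & !duplicated(abs(d))]
    got <- suppressWarnings(wilcox.test(d)$p.value)
    expect_equal(got, exact_signed_rank_p(d), tolerance = 1e-12)
  }
  # and through the package interface: one position, 6 substitutions,
  # condition B uniformly more deleterious
  base <- tibble::tibble(
    replica = rep(1:2, each = 6),
    position = 7L,
    mut_codon = rep(c("TGT", "GAT", "GAA", "TTT", "CAT", "AAA"), 2),
    mut_aa = rep(c("C", "D", "E", "F", "H", "K"), 2),
    s = rep(c(-0.01, 0.02, 0, 0.01, -0.02, 0.005), 2)
  )
  shifted <- base
  shifted$s <- base$s - rep(c(0.11, 0.23, 0.05, 0.17, 0.29, 0.08), 2)
  ff <- two_cond_fit(base, shifted)
  res <- wilcoxon_positions(ff$a, ff$b)
  expect_equal(res$p, 0.03125)
  expect_equal(res$n_pairs, 6L)
  # 0.03125 is the smallest two-sided P six pairs can give: still above
  # the 0.01 landscape threshold, so the flag must stay off
  expect_false(res$significant)
})

test_that("swapping condition labels negates the shift and keeps P", {
  cfg_a <- sim_config(n_positions = 5, depth_t0 = 1e5, depth_tf = 1e5,
                      seed = 67, dfe = dfe_spec(p_deleterious = 0.3))
  lib <- draw_library(cfg_a)
  lib_b <- lib
  lib_b$truth$s_true <- pmax(-1, lib_b$truth$s_true - 0.05 *
                               (lib_b$truth$class != "synonymous" &
                                  lib_b$truth$class != "wt"))
  cfg_b <- sim_config(n_positions = 5, depth_t0 = 1e5, depth_tf = 1e5,
                      seed = 68, dfe = dfe_spec(p_deleterious = 0.3))
  sim_a <- simulate_experiment(cfg_a, condition = "A", library = lib)
  sim_b <- simulate_experiment(cfg_b, condition = "B", library = lib_b)
  fit_a <- fit_counts(sim_a$counts, r = sim_a$fold)
  fit_b <- fit_counts(sim_b$counts, r = sim_b$fold)
  ab <- wilcoxon_positions(fit_a, fit_b)
  ba <- wilcoxon_positions(fit_b, fit_a)
  expect_equal(ab$p, ba$p)
  expect_equal(ab$delta_s, -ba$delta_s)
  tt_ab <- ttest_substitutions(fit_a, fit_b)
  tt_ba <- ttest_substitutions(fit_b, fit_a)
  expect_equal(tt_ab$p, tt_ba$p)
  expect_equal(tt_ab$delta_s, -tt_ba$delta_s)
})

test_that("a planted positional shift is flagged at exactly those positions", {
  cfg <- neutral_config(n_positions = 10, depth = 5e5, seed = 71)
  lib <- draw_library(cfg)
  shifted_lib <- lib
  planted <- c(2L, 5L, 9L)
  mask <- shifted_lib$truth$position %in% planted &
    shifted_lib$truth$class %in% c("missense", "nonsense")
  shifted_lib$truth$s_true[mask] <- -0.1
  cfg_b <- neutral_config(n_positions = 10, depth = 5e5, seed = 72)
  sim_a <- simulate_experiment(cfg, condition = "A", library = lib)
  sim_b <- simulate_experiment(cfg_b, condition = "B", library = shifted_lib)
  fit_a <- fit_counts(sim_a$counts, r = sim_a$fold)
  fit_b <- fit_counts(sim_b$counts, r = sim_b$fold)
  res <- wilcoxon_positions(fit_a, fit_b)
  expect_setequal(res$position[res$significant], planted)
  expect_true(all(res$delta_s[res$position %in% planted] < -0.08))
})

test_that("codon-pooled t-tests use codon x replica samples", {
  # glycine substitution: 4 codons x 2 replicas = 8 measures per condition
  gly <- tidyr::expand_grid(replica = 1:2,
                            mut_codon = c("GGT", "GGC", "GGA", "GGG"))
  gly$position <- 3L
  gly$mut_aa <- "G"
  base_s <- c(-0.02, -0.01, -0.015, -0.025, -0.018, -0.022, -0.012, -0.02)
  a_map <- dplyr::mutate(gly, s = base_s)
  b_map <- dplyr::mutate(gly, s = base_s - 0.1)
  ff <- two_cond_fit(a_map, b_map)
  res <- ttest_substitutions(ff$a, ff$b)
  expect_equal(res$n_a, 8L)
  expect_equal(res$n_b, 8L)
  oracle <- t.test(b_map$s, a_map$s)
  expect_equal(res$t, unname(oracle$statistic))
  expect_equal(res$p, oracle$p.value)
  expect_lt(res$p, 0.01)
  expect_equal(res$delta_s, -0.1)
  # identical sample sets: no shift, P = 1
  same <- ttest_substitutions(ff$a, ff$a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(same$delta_s, 0)
})

test_that("planted 3-sigma substitution shifts are detected with high power", {
  n_sub <- 40
  detect <- withr::with_seed(73, vapply(seq_len(n_sub), function(i) {
    noise_sd <- 0.01
    gly <- tidyr::expand_grid(replica = 1:2,
                              mut_codon = c("GGT", "GGC", "GGA", "GGG"))
    gly$position <- 3L
    gly$mut_aa <- "G"
    a_map <- dplyr::mutate(gly, s = stats::rnorm(8, 0, noise_sd))
    b_map <- dplyr::mutate(gly, s = stats::rnorm(8, -3 * noise_sd, noise_sd))
    ttest_substitutions(manual_fit(list(a_map)), manual_fit(list(b_map)))$p
  }, 0) < 0.01)
  expect_gte(mean(detect), 0.9)
})

test_that("DFE shift partitions split by baseline significance", {
  cfg <- sim_config(n_positions = 8, depth_t0 = 3e5, depth_tf = 3e5,
                    seed = 79,
                    dfe = dfe_spec(p_deleterious = 0.3,
                                   deleterious = list(dist = "uniform",
                                                      min = -0.35,
                                                      max = -0.1)))
  lib <- draw_library(cfg)
  sim_a <- simulate_experiment(cfg, condition = "A", library = lib)
  fit_a <- fit_counts(sim_a$counts, r = sim_a$fold)

  # identical conditions: paired histograms coincide
  same <- dfe_shift_partition(fit_a, fit_a)
  for (part in unique(same$histograms$partition)) {
    h <- same$histograms[same$histograms$partition == part, ]
    expect_equal(h$count[h$condition == "A"], h$count[h$condition == "B"])
  }

  # exacerbate only the baseline-significant subset in condition B
  calls_a <- dual_replica_calls(fit_a)
  sig <- calls_a[calls_a$significant, c("position", "mut_aa")]
  lib_b <- lib
  mask <- paste(lib_b$truth$position, lib_b$truth$mut_aa) %in%
    paste(sig$position, sig$mut_aa)
  lib_b$truth$s_true[mask] <- pmax(-1, lib_b$truth$s_true[mask] - 0.2)
  cfg_b <- sim_config(n_positions = 8, depth_t0 = 3e5, depth_tf = 3e5,
                      seed = 80, dfe = cfg$dfe)
  sim_b <- simulate_experiment(cfg_b, condition = "B", library = lib_b)
  fit_b <- fit_counts(sim_b$counts, r = sim_b$fold)
  res <- dfe_shift_partition(fit_a, fit_b)
  means <- dplyr::summarise(
    dplyr::group_by(res$assignments, baseline_significant),
    shift = mean(s_b - s_a), .groups = "drop")
  shift_sig <- means$shift[means$baseline_significant]
  shift_null <- means$shift[!means$baseline_significant]
  expect_lt(shift_sig, -0.15)
  expect_lt(abs(shift_null), 0.02)
})

test_that("disjoint substitution sets are an error", {
  gly <- tidyr::expand_grid(replica = 1:2, mut_codon = c("GGT", "GGC"))
  gly$position <- 3L
  gly$mut_aa <- "G"
  a_map <- dplyr::mutate(gly, s = -0.01)
  b_map <- dplyr::mutate(gly, position = 4L, s = -0.01)
  ff <- two_cond_fit(a_map, b_map)
  expect_error(dfe_shift_partition(ff$a, ff$b), "share no substitutions")
})
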