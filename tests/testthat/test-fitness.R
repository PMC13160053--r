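# Fitness estimator: enrichment, fitness, variance model, pooling,
# monoculture assay.

test_that("enrichment matches hand-evaluated cases", {
  # symmetric counts: eps = 1 up to the pseudocount (100.5/100.5)
  e <- enrichment(100, 100, 1e6, 1e6, 500, 500)
  expect_equal(e$eps_i, 1)
  expect_equal(e$eps_wt, 1)
  # allele dropping to zero is floored by the pseudocount
  e <- enrichment(100, 0, 1e6, 1e6, 500, 500)
  expect_equal(e$eps_i, 0.5 / 100.5)
  # direct evaluation: 100 -> 50 at equal totals
  e <- enrichment(100, 50, 1e6, 1e6, 500, 500)
  expect_equal(e$eps_i, 50.5 / 100.5, tolerance = 1e-15)
})

test_that("fitness matches hand-evaluated cases to 1e-12", {
  # eps_i = 50.5/100.5, r = 1024, eps_wt = 1
  f <- fitness(50.5 / 100.5, 1, 1024)
  expect_equal(f$w, 0.90071597915728663, tolerance = 1e-12)
  expect_equal(f$s, f$w - 1)
  # identity: eps_i = eps_wt gives exactly w = 1
  expect_identical(fitness(0.37, 0.37, 1024)$w, 1)
  # growth-arrested allele: r*eps_i = 1 makes the numerator vanish
  expect_equal(fitness(1 / 1024, 1, 1024)$w, 0)
})

test_that("degenerate inputs raise explicit errors", {
  expect_error(fitness(-0.1, 1, 1024), "strictly positive")
  expect_error(fitness(0.5, 1 / 1024, 1024), "degenerate reference")
  expect_error(enrichment(10, 10, 100, 100, 0, 5), "reference unobserved")
})

test_that("fitness increases monotonically in the final allele count", {
  c_if <- seq(0, 400, by = 25)
  e <- enrichment(100, c_if, 1e6, 1e6, 500, 500)
  w <- fitness(e$eps_i, e$eps_wt, 1024)$w
  expect_true(all(diff(w) > 0))
})

test_that("the analytic variance matches a binomial resampling oracle", {
  # moderate counts, all >= 50: the delta-method formula should agree
  # with the empirical variance over 10,000 count resamples within 10%
  cT0 <- 2e5; cTf <- 2e5
  c_i0 <- 200; c_if <- 120; c_wt0 <- 5000; c_wtf <- 5200
  r <- 1024
  e <- enrichment(c_i0, c_if, cT0, cTf, c_wt0, c_wtf)
  w0 <- fitness(e$eps_i, e$eps_wt, r)$w
  v <- fitness_variance(c_i0, c_if, cT0, cTf, c_wt0, c_wtf,
                        w0, e$eps_i, e$eps_wt, r)
  n_mc <- 10000
  sim <- withr::with_seed(31, {
    ri0 <- rbinom(n_mc, cT0, c_i0 / cT0)
    rif <- rbinom(n_mc, cTf, c_if / cTf)
    rw0 <- rbinom(n_mc, cT0, c_wt0 / cT0)
    rwf <- rbinom(n_mc, cTf, c_wtf / cTf)
    ee <- enrichment(ri0, rif, cT0, cTf, rw0, rwf)
    fitness(ee$eps_i, ee$eps_wt, r)$w
  })
  expect_lt(abs(v$sigma2_w - var(sim)) / var(sim), 0.10)
})

test_that("the variance formula equals independent delta-method propagation", {
  skip_if_not_installed("pracma")
  # The estimator seen as a function of the four counts; counting noise is
  # binomial per count. Evaluated at the pseudocounted mutant counts the
  # gradient propagation reproduces the closed form to numerical precision.
  cT0 <- 1e6; cTf <- 1e6; r <- 1024
  cases <- list(c(100, 50, 800, 780), c(2000, 2400, 5000, 5100),
                c(60, 55, 1000, 950))
  for (cs in cases) {
    w_of <- function(x) {
      eps_i <- (x[2] * cT0) / (x[1] * cTf)
      eps_wt <- (x[4] * cT0) / (x[3] * cTf)
      log(r * eps_i) / log(r * eps_wt)
    }
    x0 <- c(cs[1] + 0.5, cs[2] + 0.5, cs[3], cs[4])
    g <- pracma::grad(w_of, x0)
    var_c <- x0 * (1 - c(cs[1] / cT0, cs[2] / cTf, cs[3] / cT0, cs[4] / cTf))
    oracle <- sum(g^2 * var_c)
    e <- enrichment(cs[1], cs[2], cT0, cTf, cs[3], cs[4])
    w0 <- fitness(e$eps_i, e$eps_wt, r)$w
    v <- fitness_variance(cs[1], cs[2], cT0, cTf, cs[3], cs[4],
                          w0, e$eps_i, e$eps_wt, r)
    expect_equal(v$sigma2_w, oracle, tolerance = 1e-6)
  }
})

test_that("variance vanishes in the infinite-data limit at fixed ratios", {
  scale <- c(1, 10, 100, 1000)
  v <- vapply(scale, function(k) {
    e <- enrichment(100 * k, 80 * k, 1e4 * k, 1e4 * k, 500 * k, 510 * k)
    w <- fitness(e$eps_i, e$eps_wt, 1024)$w
    fitness_variance(100 * k, 80 * k, 1e4 * k, 1e4 * k, 500 * k, 510 * k,
                     w, e$eps_i, e$eps_wt, 1024)$sigma2_w
  }, 0)
  expect_true(all(diff(v) < 0))
  expect_lt(v[4] / v[1], 1e-2)
})

test_that("inverse-variance pooling matches hand arithmetic", {
  expect_equal(weighted_mean_s(-0.2, 0.01), list(s = -0.2, sigma2 = 0.01,
                                                 n = 1L))
  # equal variances reduce to the arithmetic mean
  expect_equal(weighted_mean_s(c(-0.1, -0.3), c(2, 2))$s, -0.2)
  # sigma2 = (1, 1, 2), s = (0, 0, -0.3): weights (1, 1, 0.5) -> -0.06
  res <- weighted_mean_s(c(0, 0, -0.3), c(1, 1, 2))
  expect_equal(res$s, -0.06)
  expect_equal(res$sigma2, 1 / 2.5)
  # nothing usable -> flagged missing
  expect_true(is.na(weighted_mean_s(c(0.1), c(Inf))$s))
})

test_that("the pooled wild-type class itself has fitness exactly 1", {
  cfg <- neutral_config(n_positions = 4, depth = 5e4, seed = 17)
  sim <- simulate_experiment(cfg)
  counts <- sim$counts[sim$counts$replica == 1, ]
  mut <- counts[counts$position > 0, ]
  syn <- codon_to_aa(mut$mut_codon) == codon_to_aa(mut$wt_codon)
  c_wt0 <- sum(mut$count_t0[syn]); c_wtf <- sum(mut$count_tf[syn])
  e <- enrichment(0, 0, sum(counts$count_t0), sum(counts$count_tf),
                  c_wt0, c_wtf)
  expect_identical(fitness(e$eps_wt, e$eps_wt, sim$fold)$w, 1)
})

test_that("fit_counts recovers neutrality and simulated effects", {
  cfg <- sim_config(n_positions = 8, depth_t0 = 2e5, depth_tf = 2e5,
                    seed = 23, dfe = dfe_spec(p_deleterious = 0.3))
  sim <- simulate_experiment(cfg)
  fit <- fit_counts(sim$counts, r = sim$fold)
  expect_s3_class(fit, "fitness_table")
  expect_identical(nrow(fit), sum(sim$counts$position > 0))
  expect_true(all(fit$s == fit$w - 1))
  expect_true(all(fit$ci_lo <= fit$w & fit$w <= fit$ci_hi))
  expect_true(all(fit$sigma2_w > 0))
  agg <- aggregate_substitutions(fit)
  truth <- dplyr::distinct(
    sim$truth[sim$truth$class %in% c("missense", "nonsense"),
              c("position", "mut_aa", "s_true")])
  m <- dplyr::inner_join(agg, truth, by = c("position", "mut_aa"))
  expect_gt(cor(m$s, m$s_true), 0.95)
})

test_that("monoculture fitness follows the dilution-corrected log growth", {
  wt <- list(O_o = 0.05, O_f = 0.4, d = 8)
  expect_equal(monoculture_fitness(wt, wt)$w, 1)
  # mutant doubles 9 times while wt doubles 10, same dilution and O_o:
  # growth terms 9 ln2 and 10 ln2
  wt10 <- list(O_o = 0.05, O_f = 0.05 * 2^10 / 64, d = 64)
  mut9 <- list(O_o = 0.05, O_f = 0.05 * 2^9 / 64, d = 64)
  expect_equal(monoculture_fitness(mut9, wt10)$w, 0.9)
  # arrested mutant: no net growth at d = 1
  expect_equal(monoculture_fitness(list(O_o = 0.1, O_f = 0.1, d = 1),
                                   wt10)$w, 0)
  expect_error(monoculture_fitness(mut9, list(O_o = 0.1, O_f = 0.1, d = 1)),
               "did not grow")
  expect_error(monoculture_fitness(list(O_o = -1, O_f = 1, d = 1), wt10))
})

test_that("fitness tables survive a TSV round trip", {
  cfg <- neutral_config(n_positions = 3, depth = 2e4, seed = 2)
  fit <- fit_counts(simulate_experiment(cfg)$counts, r = 1024)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fitness(fit, path)
  back <- read_fitness(path)
  expect_equal(back$s, fit$s)
  expect_equal(back$p, fit$p)
})
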