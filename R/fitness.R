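# Fitness estimation from enrichment counts. The estimator measures each
# allele's enrichment over the competition relative to the pooled synonyms
# of the wild-type gene, and converts it to fitness on the scale where the
# wild type is 1 and a fully growth-arrested allele is 0:
#
#   w_i = ln(r * eps_i) / ln(r * eps_wt),   s_i = w_i - 1
#
# with r the measured fold increase in the number of cells during the
# competition. A 0.5 pseudocount is added to mutant allele counts at both
# time points (never to totals or to the pooled wild-type counts) so that
# alleles dropping to zero still yield a fitness value. The variance of w
# is the delta-method propagation of multinomial counting noise through
# the estimator:
#
#   var(w) = w^2 * [ ((1-f_if)/c_if + (1-f_io)/c_io) / ln^2(r eps_i)
#                  + ((1-f_wtf)/c_wtf + (1-f_wto)/c_wto) / ln^2(r eps_wt) ]
#
# where f = c / c_T is the allele frequency. The 1/c terms for mutant
# alleles use the pseudocounted counts (zero-count protection).

PSEUDOCOUNT <- 0.5

#' Allele and wild-type enrichment from counts
#'
#' Enrichment is the ratio of an allele's frequency at the end vs the
#' beginning of the competition. Mutant allele counts receive a 0.5
#' pseudocount at both time points; the pooled wild-type synonym counts do
#' not (the reference must be observed).
#'
#' @param c_i0,c_if allele counts at the start / end.
#' @param c_T0,c_Tf total sequencing counts at the start / end.
#' @param c_wt0,c_wtf pooled wild-type-synonym counts at the start / end.
#' @return List with numeric vectors `eps_i` and `eps_wt`.
#' @export
enrichment <- function(c_i0, c_if, c_T0, c_Tf, c_wt0, c_wtf) {
  # counts arrive as integers; products of count x total overflow 32-bit
  c_i0 <- as.numeric(c_i0); c_if <- as.numeric(c_if)
  c_T0 <- as.numeric(c_T0); c_Tf <- as.numeric(c_Tf)
  c_wt0 <- as.numeric(c_wt0); c_wtf <- as.numeric(c_wtf)
  stopifnot(all(c_T0 > 0), all(c_Tf > 0))
  if (any(c_wt0 == 0) || any(c_wtf == 0)) {
    stop("wild-type synonym reference unobserved at one time point ",
         "(c_wt0 or c_wtf is zero)")
  }
  list(
    eps_i = ((c_if + PSEUDOCOUNT) * c_T0) / ((c_i0 + PSEUDOCOUNT) * c_Tf),
    eps_wt = (c_wtf * c_T0) / (c_wt0 * c_Tf)
  )
}

#' Fitness and selection coefficient from enrichments
#'
#' @param eps_i,eps_wt allele and wild-type enrichment.
#' @param r measured fold increase in cell number over the competition
#'   (defaults to 2^10 for a ten-generation experiment when supplied by
#'   callers).
#' @return List with `w` (fitness) and `s = w - 1`.
#' @export
fitness <- function(eps_i, eps_wt, r) {
  stopifnot(all(r > 0))
  if (any(eps_i <= 0)) stop("eps_i must be strictly positive")
  if (any(abs(log(r * eps_wt)) < 1e-12)) {
    stop("degenerate reference: r * eps_wt = 1, fitness undefined")
  }
  w <- log(r * eps_i) / log(r * eps_wt)
  list(w = w, s = w - 1)
}

#' Delta-method variance, confidence interval and P-value of fitness
#'
#' Propagates multinomial counting noise through the fitness estimator.
#' The two-tailed P-value tests s = 0 with the normal approximation
#' z = s / sigma_w; the confidence interval is `w +/- z_(1-(1-level)/2) *
#' sigma_w`.
#'
#' @inheritParams enrichment
#' @param w fitness values from [fitness()].
#' @param eps_i,eps_wt enrichments from [enrichment()].
#' @param r measured fold increase in cell number.
#' @param level confidence level (default 0.99).
#' @return List with `sigma2_w`, `ci_lo`, `ci_hi`, `p`.
#' @export
fitness_variance <- function(c_i0, c_if, c_T0, c_Tf, c_wt0, c_wtf,
                             w, eps_i, eps_wt, r, level = 0.99) {
  if (any(c_wt0 == 0) || any(c_wtf == 0)) {
    stop("wild-type synonym reference unobserved at one time point")
  }
  c_i0 <- as.numeric(c_i0); c_if <- as.numeric(c_if)
  c_T0 <- as.numeric(c_T0); c_Tf <- as.numeric(c_Tf)
  c_wt0 <- as.numeric(c_wt0); c_wtf <- as.numeric(c_wtf)
  ci0 <- c_i0 + PSEUDOCOUNT
  cif <- c_if + PSEUDOCOUNT
  f_i0 <- c_i0 / c_T0
  f_if <- c_if / c_Tf
  f_wt0 <- c_wt0 / c_T0
  f_wtf <- c_wtf / c_Tf
  sigma2 <- w^2 * (
    ((1 - f_if) / cif + (1 - f_i0) / ci0) / log(r * eps_i)^2 +
      ((1 - f_wtf) / c_wtf + (1 - f_wt0) / c_wt0) / log(r * eps_wt)^2
  )
  sigma <- sqrt(sigma2)
  z <- qnorm(1 - (1 - level) / 2)
  p <- 2 * pnorm(-abs((w - 1) / sigma))
  list(sigma2_w = sigma2, ci_lo = w - z * sigma, ci_hi = w + z * sigma, p = p)
}

#' Fit fitness for every allele of a count table
#'
#' For each (condition, replica) the pooled wild-type synonym reference is
#' assembled from single-codon alleles whose mutant codon encodes the
#' wild-type amino acid, totals are taken over all rows (including the
#' unmutated wild-type class row), and every mutant allele (synonymous ones
#' included) receives fitness, selection coefficient, variance, confidence
#' interval and P-value.
#'
#' @param counts count tibble in the package schema (`condition`,
#'   `replica`, `region`, `position`, `wt_codon`, `mut_codon`, `count_t0`,
#'   `count_tf`; the wild-type class row has `position = 0`).
#' @param r measured fold increase in cell number: a single number, or a
#'   named vector keyed by condition. Use the simulator's realized fold for
#'   simulated data; `2^generations` is the conventional value when only
#'   the generation count is known.
#' @param level confidence level for the interval (default 0.99).
#' @return Tibble of class `fitness_table` with one row per mutant allele:
#'   key columns, `wt_aa`, `mut_aa`, `class`, counts, `eps_i`, `eps_wt`,
#'   `r`, `w`, `s`, `sigma2_w`, `ci_lo`, `ci_hi`, `p`.
#' @export
fit_counts <- function(counts, r, level = 0.99) {
  stopifnot(all(c("condition", "replica", "position", "wt_codon",
                  "mut_codon", "count_t0", "count_tf") %in% names(counts)))
  r_of <- function(cond) {
    if (length(r) == 1 && is.null(names(r))) return(unname(r))
    if (!cond %in% names(r)) stop("no fold increase r given for condition ", cond)
    unname(r[[cond]])
  }
  groups <- dplyr::group_split(dplyr::group_by(counts, .data$condition,
                                               .data$replica))
  out <- lapply(groups, function(g) {
    c_T0 <- sum(g$count_t0)
    c_Tf <- sum(g$count_tf)
    mut <- g[g$position > 0, ]
    mut$wt_aa <- codon_to_aa(mut$wt_codon)
    mut$mut_aa <- codon_to_aa(mut$mut_codon)
    mut$class <- mutation_class(mut$wt_aa, mut$mut_aa)
    syn <- mut$class == "synonymous"
    c_wt0 <- sum(mut$count_t0[syn])
    c_wtf <- sum(mut$count_tf[syn])
    rr <- r_of(g$condition[1])
    eps <- enrichment(mut$count_t0, mut$count_tf, c_T0, c_Tf, c_wt0, c_wtf)
    fit <- fitness(eps$eps_i, eps$eps_wt, rr)
    v <- fitness_variance(mut$count_t0, mut$count_tf, c_T0, c_Tf,
                          c_wt0, c_wtf, fit$w, eps$eps_i, eps$eps_wt, rr,
                          level = level)
    dplyr::mutate(mut, eps_i = eps$eps_i, eps_wt = eps$eps_wt, r = rr,
                  w = fit$w, s = fit$s, sigma2_w = v$sigma2_w,
                  ci_lo = v$ci_lo, ci_hi = v$ci_hi, p = v$p)
  })
  res <- dplyr::bind_rows(out)
  class(res) <- c("fitness_table", class(res))
  res
}

#' Inverse-variance weighted mean of selection coefficients
#'
#' Combines fitness records of one amino-acid substitution across codons
#' and/or replicas. Records with infinite or missing variance are dropped;
#' if none remain the result is flagged missing (`NA`).
#'
#' @param s selection coefficients.
#' @param sigma2 their variances.
#' @return List with `s` (weighted mean), `sigma2` (combined variance,
#'   `1 / sum(1/sigma2)`) and `n` (records used).
#' @export
weighted_mean_s <- function(s, sigma2) {
  keep <- is.finite(s) & is.finite(sigma2) & sigma2 > 0
  s <- s[keep]
  sigma2 <- sigma2[keep]
  if (length(s) == 0) {
    return(list(s = NA_real_, sigma2 = NA_real_, n = 0L))
  }
  wgt <- 1 / sigma2
  list(s = sum(wgt * s) / sum(wgt), sigma2 = 1 / sum(wgt), n = length(s))
}

#' Aggregate allele fitness to amino-acid substitutions
#'
#' Inverse-variance weighted mean selection coefficient per substitution
#' (position x mutant amino acid), either per replica (for the
#' dual-replica significance rule) or across replicas (for landscape
#' matrices and condition comparisons). P-values are recomputed from the
#' combined variance with the normal approximation.
#'
#' @param fit a `fitness_table` from [fit_counts()].
#' @param per_replica keep replicas separate (default `FALSE`).
#' @param classes allele classes to retain before aggregation (default
#'   missense + nonsense: synonymous alleles are the reference, not
#'   substitutions of interest, but can be included).
#' @return Tibble with `condition`, optionally `replica`, `position`,
#'   `wt_aa`, `mut_aa`, `class`, `s`, `sigma2`, `n_records`, `p`.
#' @export
aggregate_substitutions <- function(fit, per_replica = FALSE,
                                    classes = c("missense", "nonsense")) {
  fit <- fit[fit$class %in% classes, ]
  keys <- c("condition", if (per_replica) "replica", "position",
            "wt_aa", "mut_aa", "class")
  grouped <- dplyr::group_by(fit, dplyr::across(dplyr::all_of(keys)))
  out <- dplyr::summarise(
    grouped,
    res = list(weighted_mean_s(.data$s, .data$sigma2_w)),
    .groups = "drop"
  )
  out$s <- vapply(out$res, `[[`, 0, "s")
  out$sigma2 <- vapply(out$res, `[[`, 0, "sigma2")
  out$n_records <- vapply(out$res, `[[`, 0L, "n")
  out$res <- NULL
  out$p <- 2 * pnorm(-abs(out$s / sqrt(out$sigma2)))
  out
}

#' Monoculture fitness from optical-density growth records
#'
#' Relative fitness of a mutant monoculture vs the wild-type culture from
#' start/final optical densities with one mid-assay dilution by factor `d`
#' (the measured final OD is post-dilution, so the realized growth of the
#' culture is `d * O_f / O_o`):
#'
#'   w = ln(d * O_f / O_o)_mut / ln(d * O_f / O_o)_wt
#'
#' @param mut,wt lists or one-row data frames with elements `O_o`, `O_f`,
#'   `d` (dilution factor, >= 1).
#' @return List with `w` and `s = w - 1`.
#' @export
monoculture_fitness <- function(mut, wt) {
  term <- function(x) {
    stopifnot(x$O_o > 0, x$O_f > 0, x$d >= 1)
    log(x$d * x$O_f / x$O_o)
  }
  mu_wt <- term(wt)
  if (mu_wt <= 0) stop("wild-type culture did not grow; fitness undefined")
  w <- term(mut) / mu_wt
  list(w = w, s = w - 1)
}

#' Write / read a fitness table (TSV)
#'
#' @param fit fitness tibble.
#' @param path file path.
#' @export
write_fitness <- function(fit, path) {
  readr::write_tsv(fit, path)
  invisible(path)
}

#' @rdname write_fitness
#' @export
read_fitness <- function(path) {
  res <- readr::read_tsv(path, show_col_types = FALSE)
  class(res) <- c("fitness_table", class(res))
  res
}
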