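# Condition-dependent shifts in fitness effects: per-position Wilcoxon
# signed-rank tests on paired substitution effects, codon-pooled Welch
# t-tests per substitution, and DFE-shift partitions.

# Paired per-substitution weighted-mean s for two conditions at one unit of
# pairing (position x mutant amino acid).
paired_substitutions <- function(fit_a, fit_b) {
  agg_a <- aggregate_substitutions(fit_a, per_replica = FALSE)
  agg_b <- aggregate_substitutions(fit_b, per_replica = FALSE)
  dplyr::inner_join(agg_a, agg_b,
                    by = c("position", "wt_aa", "mut_aa", "class"),
                    suffix = c("_a", "_b"))
}

#' Wilcoxon signed-rank test of a positional fitness shift
#'
#' Tests whether the fitness effects of the substitutions at one position
#' tend to be more (or less) deleterious in condition B than in condition
#' A. Pairs are amino-acid substitutions (weighted-mean selection
#' coefficients across codons and replicas); zero differences are dropped
#' (classic signed-rank convention); the exact null distribution is used
#' for small samples without ties, the normal approximation with
#' continuity correction otherwise.
#'
#' @param fit_a,fit_b `fitness_table`s for the two conditions.
#' @param positions positions to test (default: all shared positions).
#' @param alpha significance threshold for the `significant` flag.
#' @return Tibble with one row per position: `position`, `n_pairs`,
#'   `statistic` (signed-rank V), `p`, `delta_s` (mean of paired
#'   differences, B minus A), `delta_s_weighted` (difference of
#'   position-level weighted means), `significant`. Positions with fewer
#'   than two non-zero pairs have `NA` statistics and are flagged
#'   undefined.
#' @export
wilcoxon_positions <- function(fit_a, fit_b, positions = NULL, alpha = 0.01) {
  paired <- paired_substitutions(fit_a, fit_b)
  if (is.null(positions)) positions <- sort(unique(paired$position))
  rows <- lapply(positions, function(pos) {
    pp <- paired[paired$position == pos, ]
    d <- pp$s_b - pp$s_a
    d <- d[is.finite(d)]
    nz <- d[d != 0]
    if (length(nz) < 2) {
      return(tibble::tibble(position = pos, n_pairs = length(d),
                            statistic = NA_real_, p = NA_real_,
                            delta_s = if (length(d)) mean(d) else NA_real_,
                            delta_s_weighted = NA_real_,
                            significant = FALSE))
    }
    wt <- suppressWarnings(wilcox.test(nz))
    wa <- weighted_mean_s(pp$s_a, pp$sigma2_a)
    wb <- weighted_mean_s(pp$s_b, pp$sigma2_b)
    tibble::tibble(position = pos, n_pairs = length(d),
                   statistic = unname(wt$statistic), p = wt$p.value,
                   delta_s = mean(d), delta_s_weighted = wb$s - wa$s,
                   significant = wt$p.value < alpha)
  })
  dplyr::bind_rows(rows)
}

#' Codon-pooled t-test of a substitution's condition dependence
#'
#' Welch two-sample t-test comparing an amino-acid substitution's fitness
#' between two conditions, treating each codon x replica measurement as one
#' sample (a glycine substitution with four codons and two replicas gives
#' eight measures per condition). Power therefore scales with the codon
#' multiplicity of the substitution.
#'
#' @param fit_a,fit_b `fitness_table`s for the two conditions.
#' @param min_n minimum samples per condition (default 2).
#' @return Tibble with one row per shared substitution: `position`,
#'   `wt_aa`, `mut_aa`, `n_a`, `n_b`, `t`, `df`, `p`, `delta_s` (mean B
#'   minus mean A). Substitutions with too few samples have `NA`
#'   statistics.
#' @export
ttest_substitutions <- function(fit_a, fit_b, min_n = 2) {
  pick <- function(fit) fit[fit$class %in% c("missense", "nonsense"),
                            c("position", "wt_aa", "mut_aa", "s")]
  a <- pick(fit_a)
  b <- pick(fit_b)
  keys <- dplyr::distinct(dplyr::inner_join(
    dplyr::distinct(a[, c("position", "wt_aa", "mut_aa")]),
    dplyr::distinct(b[, c("position", "wt_aa", "mut_aa")]),
    by = c("position", "wt_aa", "mut_aa")
  ))
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sa <- a$s[a$position == k$position & a$mut_aa == k$mut_aa]
    sb <- b$s[b$position == k$position & b$mut_aa == k$mut_aa]
    sa <- sa[is.finite(sa)]
    sb <- sb[is.finite(sb)]
    base <- tibble::tibble(position = k$position, wt_aa = k$wt_aa,
                           mut_aa = k$mut_aa, n_a = length(sa),
                           n_b = length(sb))
    if (length(sa) < min_n || length(sb) < min_n ||
        (stats::sd(sa) == 0 && stats::sd(sb) == 0)) {
      if (length(sa) >= 1 && length(sb) >= 1 &&
          stats::sd(c(sa, sb)) == 0) {
        # identical degenerate samples: no evidence of a shift
        return(dplyr::mutate(base, t = 0, df = NA_real_, p = 1,
                             delta_s = 0))
      }
      return(dplyr::mutate(base, t = NA_real_, df = NA_real_, p = NA_real_,
                           delta_s = mean(sb) - mean(sa)))
    }
    tt <- t.test(sb, sa)
    dplyr::mutate(base, t = unname(tt$statistic),
                  df = unname(tt$parameter), p = tt$p.value,
                  delta_s = mean(sb) - mean(sa))
  })
  dplyr::bind_rows(rows)
}

#' Partitioned DFE shift between two conditions
#'
#' Splits substitutions by whether they were significant under condition A
#' (dual-replica rule) and returns, for each partition, the distribution
#' of fitness effects under both conditions — the display used to ask
#' whether a condition shift exacerbates effects that were already
#' significant, spreads to previously neutral ones, or both.
#'
#' @param fit_a,fit_b `fitness_table`s for the baseline and comparison
#'   condition (same substitutions).
#' @param alpha per-replica significance threshold for the baseline call.
#' @param breaks optional histogram breaks passed to [dfe_summary()].
#' @return List with `assignments` (tibble: substitution keys,
#'   `baseline_significant`, `s_a`, `s_b`) and `histograms` (tibble with
#'   `partition`, `condition`, and histogram bins).
#' @export
dfe_shift_partition <- function(fit_a, fit_b, alpha = 0.01, breaks = NULL) {
  paired <- paired_substitutions(fit_a, fit_b)
  if (nrow(paired) == 0) stop("conditions share no substitutions")
  calls_a <- dual_replica_calls(fit_a, unit = "aa", alpha = alpha)
  paired <- dplyr::left_join(
    paired, calls_a[, c("position", "mut_aa", "significant")],
    by = c("position", "mut_aa")
  )
  paired$baseline_significant <- !is.na(paired$significant) & paired$significant
  if (is.null(breaks)) {
    lo <- floor(min(c(paired$s_a, paired$s_b, -1), na.rm = TRUE) / 0.05) * 0.05
    hi <- ceiling(max(c(paired$s_a, paired$s_b, 0.5), na.rm = TRUE) / 0.05) * 0.05
    breaks <- seq(lo, hi, by = 0.05)
  }
  hists <- list()
  for (part in c(FALSE, TRUE)) {
    sub <- paired[paired$baseline_significant == part, ]
    for (cond in c("a", "b")) {
      s <- if (cond == "a") sub$s_a else sub$s_b
      h <- dfe_summary(s, breaks = breaks)$histogram
      h$partition <- if (part) "baseline_significant" else "baseline_null"
      h$condition <- if (cond == "a") "A" else "B"
      hists[[length(hists) + 1]] <- h
    }
  }
  assignments <- paired[, c("position", "wt_aa", "mut_aa", "class",
                            "baseline_significant", "s_a", "s_b")]
  list(assignments = assignments, histograms = dplyr::bind_rows(hists))
}
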