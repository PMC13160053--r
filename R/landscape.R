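# Landscape-level summaries: dual-replica significance calls, percent
# deleterious, position x amino-acid matrices, DFE summaries and variance
# diagnostics.

#' Protein domain annotation
#'
#' Named intervals over protein positions; an entry may be a single
#' `c(start, end)` interval or a list of intervals (discontinuous domain).
#' Intervals must not overlap across domains.
#'
#' @param ... named intervals, e.g.
#'   `signal = c(1, 25), alpha = c(69, 212), alpha_beta =
#'   list(c(26, 68), c(213, 290))`.
#' @return Object of class `domain_annotation`.
#' @export
domain_annotation <- function(...) {
  doms <- list(...)
  stopifnot(length(doms) > 0, !is.null(names(doms)), all(names(doms) != ""))
  doms <- lapply(doms, function(d) if (is.list(d)) d else list(d))
  all_pos <- unlist(lapply(doms, function(d)
    unlist(lapply(d, function(iv) seq(iv[1], iv[2])))))
  if (anyDuplicated(all_pos)) stop("domain intervals overlap")
  structure(doms, class = "domain_annotation")
}

#' TEM-1 beta-lactamase domain annotation
#'
#' Signal sequence, alpha-domain (residues 69-212) and the discontinuous
#' alpha/beta-domain (residues 26-68 and 213-290).
#'
#' @return A [domain_annotation()].
#' @export
tem1_domains <- function() {
  domain_annotation(signal = c(1, 25), alpha = c(69, 212),
                    alpha_beta = list(c(26, 68), c(213, 290)))
}

#' Read a domain annotation from YAML
#'
#' The YAML maps domain names to `[start, end]` or a list of such pairs.
#'
#' @param path YAML file.
#' @return A [domain_annotation()].
#' @export
read_annotation <- function(path) {
  raw <- yaml::read_yaml(path)
  raw <- lapply(raw, function(d) {
    if (is.list(d)) lapply(d, as.numeric) else as.numeric(d)
  })
  do.call(domain_annotation, raw)
}

#' Domain of each position under an annotation
#'
#' @param annotation a [domain_annotation()].
#' @param position integer positions.
#' @return Character vector of domain names (`NA` outside all domains).
#' @export
domain_of <- function(annotation, position) {
  out <- rep(NA_character_, length(position))
  for (nm in names(annotation)) {
    for (iv in annotation[[nm]]) {
      out[position >= iv[1] & position <= iv[2]] <- nm
    }
  }
  out
}

#' Dual-replica significance calls per mutation
#'
#' Applies the dual-replica criterion: a mutation is called *deleterious*
#' when its selection coefficient is negative and P < `alpha` in each
#' replica separately, and *significant* when P < `alpha` in each replica
#' with a consistent sign. At `unit = "aa"` codons of a substitution are
#' pooled per replica by inverse-variance weighting first; at
#' `unit = "codon"` each codon mutation is called on its own.
#'
#' @param fit a `fitness_table` with at least two replicas.
#' @param unit `"aa"` (default) or `"codon"`.
#' @param classes allele classes entering the calls.
#' @param alpha per-replica significance threshold (default 0.01).
#' @return Tibble with one row per mutation: keys, `n_replicas`,
#'   `defined`, `deleterious`, `significant`, `s_mean` (weighted mean
#'   across replicas), `p_max`.
#' @export
dual_replica_calls <- function(fit, unit = c("aa", "codon"),
                               classes = c("missense", "nonsense"),
                               alpha = 0.01) {
  unit <- match.arg(unit)
  if (unit == "aa") {
    per <- aggregate_substitutions(fit, per_replica = TRUE, classes = classes)
  } else {
    per <- fit[fit$class %in% classes,
               c("condition", "replica", "position", "wt_aa", "mut_aa",
                 "class", "mut_codon", "s", "sigma2_w", "p")]
    names(per)[names(per) == "sigma2_w"] <- "sigma2"
  }
  keys <- c("condition", "position", "wt_aa", "mut_aa", "class",
            if (unit == "codon") "mut_codon")
  n_rep <- length(unique(per$replica))
  if (n_rep < 2) stop("dual-replica calls require at least two replicas")
  grouped <- dplyr::group_by(per, dplyr::across(dplyr::all_of(keys)))
  out <- dplyr::summarise(
    grouped,
    n_replicas = dplyr::n(),
    all_finite = all(is.finite(.data$s)),
    all_sig = all(.data$p < alpha),
    all_neg = all(.data$s < 0),
    all_pos = all(.data$s > 0),
    s_mean = weighted_mean_s(.data$s, .data$sigma2)$s,
    p_max = max(.data$p),
    .groups = "drop"
  )
  out$defined <- out$n_replicas == n_rep & out$all_finite
  out$deleterious <- out$defined & out$all_sig & out$all_neg
  out$significant <- out$defined & out$all_sig & (out$all_neg | out$all_pos)
  out[, c(keys, "n_replicas", "defined", "deleterious", "significant",
          "s_mean", "p_max")]
}

#' Percent of mutations with deleterious fitness effects
#'
#' A mutation counts as deleterious when its selection coefficient is
#' negative and P < `alpha` in both replica experiments. The denominator is
#' every mutation of the requested class with a defined estimate in both
#' replicas. The unit can be amino-acid substitutions (replica-level
#' inverse-variance pooling across codons, default) or individual codon
#' mutations.
#'
#' @param fit a `fitness_table` covering two (or more) replicas of one
#'   condition.
#' @param class_filter `"missense"` (default), `"nonsense"`,
#'   `"synonymous"` or `"all"` (missense + nonsense).
#' @param unit `"aa"` or `"codon"`.
#' @param alpha per-replica significance threshold (default 0.01).
#' @return Percentage (0-100).
#' @export
percent_deleterious <- function(fit, class_filter = "missense",
                                unit = c("aa", "codon"), alpha = 0.01) {
  classes <- switch(class_filter,
    all = c("missense", "nonsense"),
    missense = "missense",
    nonsense = "nonsense",
    synonymous = "synonymous",
    stop("unknown class_filter: ", class_filter)
  )
  calls <- dual_replica_calls(fit, unit = match.arg(unit),
                              classes = classes, alpha = alpha)
  denom <- sum(calls$defined)
  if (denom == 0) stop("no mutation has defined estimates in both replicas")
  100 * sum(calls$deleterious) / denom
}

#' Build a position x amino-acid landscape matrix
#'
#' Weighted-mean selection coefficients per (position, amino acid) across
#' codons and replicas, with a significance mask from the dual-replica rule
#' (P < 0.01 in both replicas and consistent sign) and a missing-data mask.
#' The nonsense (stop) column is included.
#'
#' @param fit a `fitness_table` for one condition with two replicas.
#' @param annotation optional [domain_annotation()].
#' @param alpha per-replica significance threshold.
#' @return Object of class `landscape_matrix`: list with numeric matrix
#'   `s` (positions x 21 amino acids), logical matrices `significant` and
#'   `missing`, `positions`, `aa`, `domain` (per-position labels or `NA`).
#' @export
build_landscape_matrix <- function(fit, annotation = NULL, alpha = 0.01) {
  if (length(unique(fit$condition)) != 1) {
    stop("landscape matrix is built per condition")
  }
  agg <- aggregate_substitutions(fit, per_replica = FALSE)
  calls <- dual_replica_calls(fit, unit = "aa", alpha = alpha)
  agg <- dplyr::left_join(
    agg, calls[, c("position", "mut_aa", "significant")],
    by = c("position", "mut_aa")
  )
  if (anyDuplicated(agg[, c("position", "mut_aa")])) {
    stop("duplicate conflicting substitution keys")
  }
  positions <- sort(unique(fit$position[fit$position > 0]))
  aa <- aa_levels()
  shape <- function(fill) matrix(fill, nrow = length(positions),
                                 ncol = length(aa),
                                 dimnames = list(positions, aa))
  s_mat <- shape(NA_real_)
  sig <- shape(FALSE)
  i <- cbind(match(agg$position, positions), match(agg$mut_aa, aa))
  ok <- complete.cases(i)
  s_mat[i[ok, , drop = FALSE]] <- agg$s[ok]
  sig[i[ok, , drop = FALSE]] <- !is.na(agg$significant[ok]) & agg$significant[ok]
  structure(list(
    s = s_mat, significant = sig, missing = is.na(s_mat),
    positions = positions, aa = aa,
    domain = if (is.null(annotation)) rep(NA_character_, length(positions))
             else domain_of(annotation, positions),
    condition = fit$condition[1]
  ), class = "landscape_matrix")
}

#' Summarise a distribution of fitness effects
#'
#' Histogram over selection coefficients with a fixed bin specification,
#' the mean over all records (significant or not) and the median effect of
#' the significantly deleterious subset.
#'
#' @param s selection coefficients (e.g. per-substitution weighted means).
#' @param deleterious logical mask of significant-deleterious records
#'   (dual-replica rule); used for the median deleterious effect.
#' @param breaks histogram break points (default 0.05-wide bins spanning
#'   the data and at least \[-1, 0.5\]).
#' @return List with `histogram` (tibble `bin_lo`, `bin_mid`, `bin_hi`,
#'   `count`), `mean_s`, `median_deleterious_s` (`NA` if no deleterious
#'   records), `n`.
#' @export
dfe_summary <- function(s, deleterious = NULL, breaks = NULL) {
  s <- s[is.finite(s)]
  if (is.null(breaks)) {
    lo <- floor(min(c(s, -1)) / 0.05) * 0.05
    hi <- ceiling(max(c(s, 0.5)) / 0.05) * 0.05
    breaks <- seq(lo, hi, by = 0.05)
  }
  h <- graphics::hist(s, breaks = breaks, plot = FALSE)
  hist_tbl <- tibble::tibble(bin_lo = head(h$breaks, -1),
                             bin_hi = h$breaks[-1],
                             bin_mid = h$mids, count = h$counts)
  med_del <- if (!is.null(deleterious) && any(deleterious, na.rm = TRUE)) {
    median(s[which(deleterious)])
  } else NA_real_
  list(histogram = hist_tbl, mean_s = mean(s),
       median_deleterious_s = med_del, n = length(s))
}

#' Median per-allele fitness variance
#'
#' Diagnostic for comparing measurement resolution between experiments:
#' the variance depends only on sequencing depth and allele / reference
#' counts, so the median variance tracks effective depth.
#'
#' @param fit a `fitness_table`.
#' @return Median of `sigma2_w`.
#' @export
median_variance <- function(fit) {
  if (nrow(fit) == 0) stop("empty fitness table")
  median(fit$sigma2_w, na.rm = TRUE)
}
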