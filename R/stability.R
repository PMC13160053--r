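# Correlation of fitness effects with externally predicted folding
# stability changes (ddG, kcal/mol; positive = destabilizing). The ddG
# table is consumed, never computed: any structure-based predictor can
# supply it. With deleterious s < 0 and destabilizing ddG > 0, a real
# stability-fitness coupling shows up as a negative Spearman correlation.

#' Read a per-substitution stability prediction table
#'
#' TSV with columns `position`, `wt_aa`, `mut_aa`, `ddg` (kcal/mol,
#' positive = destabilizing).
#'
#' @param path TSV file.
#' @return Tibble with one finite `ddg` per substitution.
#' @export
read_ddg <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    position = readr::col_integer(), wt_aa = readr::col_character(),
    mut_aa = readr::col_character(), ddg = readr::col_double()
  ))
  if (anyDuplicated(tbl[, c("position", "mut_aa")])) {
    stop("duplicate substitutions in ddG table")
  }
  if (any(!is.finite(tbl$ddg))) stop("non-finite ddG values")
  tbl
}

#' Spearman correlation between fitness effects and stability predictions
#'
#' Rank correlation (ties mid-ranked) between per-substitution
#' weighted-mean selection coefficients and predicted ddG, optionally
#' restricted to a domain or position set. Rank correlation is preferred
#' over Pearson because threshold (sigmoidal) stability-fitness coupling
#' is expected, not a linear one. All substitutions with defined estimates
#' enter, not only significant ones; substitutions absent from the ddG
#' table are dropped with a count.
#'
#' @param fit a `fitness_table` (or a pre-aggregated substitution tibble
#'   with `position`, `mut_aa`, `s`).
#' @param ddg stability table from [read_ddg()].
#' @param positions optional positions to keep (e.g. one domain); signal
#'   sequence positions are naturally excluded by the ddG table, which is
#'   only defined on the folded mature protein.
#' @return List with `rho`, `n`, `n_dropped` (fitness substitutions with
#'   no ddG entry).
#' @export
spearman_fitness_stability <- function(fit, ddg, positions = NULL) {
  agg <- if (inherits(fit, "fitness_table")) {
    aggregate_substitutions(fit, per_replica = FALSE, classes = "missense")
  } else fit
  if (!is.null(positions)) agg <- agg[agg$position %in% positions, ]
  merged <- dplyr::inner_join(agg, ddg, by = c("position", "mut_aa"),
                              suffix = c("", "_ddg"))
  merged <- merged[is.finite(merged$s) & is.finite(merged$ddg), ]
  if (nrow(merged) < 3) stop("fewer than 3 overlapping substitutions")
  list(rho = cor(merged$s, merged$ddg, method = "spearman"),
       n = nrow(merged), n_dropped = nrow(agg) - nrow(merged))
}

#' Correlation strength vs frequency of deleterious effects
#'
#' Pairs the absolute stability-fitness correlation of each
#' protein/domain/condition with its percent of deleterious mutations, for
#' the trend display asking whether stability predictions work better
#' where deleterious effects are common. Rows are sorted by frequency then
#' label (deterministic tie-break).
#'
#' @param labels labels of the protein/domain/condition combinations.
#' @param rho Spearman correlations.
#' @param pct_deleterious percent-deleterious values (0-100).
#' @return Tibble sorted by `pct_deleterious`, then `label`, with
#'   `abs_rho`.
#' @export
correlation_vs_frequency <- function(labels, rho, pct_deleterious) {
  stopifnot(length(labels) == length(rho),
            length(rho) == length(pct_deleterious),
            length(rho) >= 1)
  tbl <- tibble::tibble(label = as.character(labels), rho = rho,
                        abs_rho = abs(rho),
                        pct_deleterious = pct_deleterious)
  dplyr::arrange(tbl, .data$pct_deleterious, .data$label)
}
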