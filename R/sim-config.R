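# Configuration objects for the growth-competition forward simulator.

#' Specify a distribution of fitness effects for simulated libraries
#'
#' The simulated DFE is a three-component mixture: a point mass at s = 0
#' (neutral), a deleterious component on \[-1, 0) and a beneficial component
#' on (0, Inf). Synonymous alleles are always neutral regardless of the DFE
#' (they form the wild-type reference class).
#'
#' Supported component distributions, given as
#' `list(dist = <name>, ...parameters)`:
#' * `point`: `value` (the selection coefficient; negated for the
#'   deleterious component if given positive).
#' * `uniform`: `min`, `max` on the s scale (deleterious: both in \[-1, 0\]).
#' * `gamma`: `shape`, `scale`; deleterious draws are `-rgamma(...)`
#'   truncated at -1 (complete growth arrest).
#' * `exponential`: `rate`; beneficial draws are `rexp(...)`.
#'
#' @param p_deleterious probability a (non-synonymous) allele is deleterious.
#' @param deleterious distribution spec for deleterious s (see above).
#' @param p_beneficial probability an allele is beneficial.
#' @param beneficial distribution spec for beneficial s.
#' @return An object of class `dfe_spec`.
#' @export
dfe_spec <- function(p_deleterious = 0.2,
                     deleterious = list(dist = "gamma", shape = 0.6, scale = 0.15),
                     p_beneficial = 0,
                     beneficial = list(dist = "exponential", rate = 100)) {
  stopifnot(p_deleterious >= 0, p_beneficial >= 0,
            p_deleterious + p_beneficial <= 1)
  structure(list(p_deleterious = p_deleterious, deleterious = deleterious,
                 p_beneficial = p_beneficial, beneficial = beneficial),
            class = "dfe_spec")
}

# Draw n selection coefficients from a dfe_spec. Deleterious draws are
# clamped to [-1, 0) (s = -1 is complete growth arrest; death not modelled).
draw_dfe <- function(n, dfe) {
  stopifnot(inherits(dfe, "dfe_spec"))
  u <- runif(n)
  s <- numeric(n)
  del <- u < dfe$p_deleterious
  ben <- u >= dfe$p_deleterious & u < dfe$p_deleterious + dfe$p_beneficial
  if (any(del)) {
    s[del] <- -pmin(1, abs(draw_component(sum(del), dfe$deleterious)))
  }
  if (any(ben)) {
    s[ben] <- abs(draw_component(sum(ben), dfe$beneficial))
  }
  s
}

draw_component <- function(n, comp) {
  switch(comp$dist,
    point = rep(comp$value, n),
    uniform = runif(n, comp$min, comp$max),
    gamma = rgamma(n, shape = comp$shape, scale = comp$scale),
    exponential = rexp(n, rate = comp$rate),
    stop("unknown DFE component distribution: ", comp$dist)
  )
}

#' Configure a growth-competition simulation
#'
#' Describes one site-saturation (NNN) library and its competition: every
#' position of the wild-type sequence is substituted by the 63 non-wild-type
#' codons, the library is spiked with an unmutated wild-type class, grown for
#' `generations` generations of exponential competition, and sequenced to
#' fixed depths at the start and end with multinomial sampling noise.
#'
#' @param n_positions number of codon positions mutagenised.
#' @param wt_codons optional character vector of wild-type codons (length
#'   `n_positions`, no stop codons); randomly generated (seeded) if `NULL`.
#' @param regions either the number of equal-sized regions the positions are
#'   split into (default 3, emulating a multi-amplicon design) or a list of
#'   `c(start, end)` position intervals that must disjointly cover
#'   `1..n_positions`.
#' @param generations generations of exponential growth (default 10).
#' @param r nominal fold increase of a neutral (wild-type) genotype over the
#'   competition; default `2^generations`.
#' @param depth_t0,depth_tf total sequencing counts per replica at the start
#'   and end of the competition.
#' @param n_replicas number of replica experiments (independent multinomial
#'   resamples of the same true composition; default 2).
#' @param wt_mass initial library fraction carrying the unmutated wild-type
#'   gene (0 < wt_mass < 1).
#' @param dfe a [dfe_spec()] for non-synonymous alleles.
#' @param s_unit `"aa"` (default): codons encoding the same amino-acid
#'   substitution share one true selection coefficient, reflecting
#'   protein-level effects; `"codon"`: every codon substitution draws its own.
#' @param bottleneck if `TRUE`, apply one intermediate multinomial resample
#'   (size `bottleneck_size`) at mid-competition, emulating a single dilution
#'   at about five generations. Default off.
#' @param bottleneck_size cells retained at the bottleneck.
#' @param seed integer seed controlling every random draw of the simulation.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_positions,
                       wt_codons = NULL,
                       regions = 3,
                       generations = 10,
                       r = 2^generations,
                       depth_t0 = 1e6,
                       depth_tf = 1e6,
                       n_replicas = 2,
                       wt_mass = 0.05,
                       dfe = dfe_spec(),
                       s_unit = c("aa", "codon"),
                       bottleneck = FALSE,
                       bottleneck_size = 1e8,
                       seed = 1L) {
  s_unit <- match.arg(s_unit)
  stopifnot(n_positions >= 1, depth_t0 > 0, depth_tf > 0, n_replicas >= 1,
            wt_mass > 0, wt_mass < 1, r > 1, generations > 0)
  if (is.numeric(regions) && length(regions) == 1) {
    k <- min(regions, n_positions)
    cut <- floor(seq(0, n_positions, length.out = k + 1))
    regions <- lapply(seq_len(k), function(i) c(cut[i] + 1L, cut[i + 1L]))
  }
  check_regions(regions, n_positions)
  if (!is.null(wt_codons)) {
    stopifnot(length(wt_codons) == n_positions)
    if (any(codon_to_aa(wt_codons) == "*")) {
      stop("wild-type sequence contains a stop codon")
    }
  }
  structure(list(n_positions = as.integer(n_positions), wt_codons = wt_codons,
                 regions = regions, generations = generations, r = r,
                 depth_t0 = depth_t0, depth_tf = depth_tf,
                 n_replicas = as.integer(n_replicas), wt_mass = wt_mass,
                 dfe = dfe, s_unit = s_unit, bottleneck = bottleneck,
                 bottleneck_size = bottleneck_size, seed = as.integer(seed)),
            class = "sim_config")
}

check_regions <- function(regions, n_positions) {
  covered <- integer(0)
  for (rg in regions) {
    stopifnot(length(rg) == 2, rg[1] <= rg[2])
    covered <- c(covered, seq(rg[1], rg[2]))
  }
  if (anyDuplicated(covered) || !setequal(covered, seq_len(n_positions))) {
    stop("regions must disjointly cover positions 1..n_positions")
  }
  invisible(TRUE)
}

# Region label ("r1", "r2", ...) for each position under a config.
region_of_position <- function(config, position) {
  lab <- rep(NA_character_, length(position))
  for (i in seq_along(config$regions)) {
    rg <- config$regions[[i]]
    lab[position >= rg[1] & position <= rg[2]] <- paste0("r", i)
  }
  lab
}
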