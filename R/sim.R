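# Forward simulator of the growth-competition experiment: library
# composition -> exponential selection -> multinomial sequencing counts.
# The simulator carries its ground truth (s_true per allele) so estimator
# recovery can be tested.

#' Draw a site-saturation library with known ground truth
#'
#' Builds one allele per (position, non-wild-type codon) plus a pooled
#' unmutated wild-type class, assigns true selection coefficients from the
#' configured DFE (synonymous alleles and the wild-type class are always
#' neutral: they constitute the reference), and assigns initial frequencies
#' (wild-type class gets `wt_mass`, the rest is spread uniformly over the
#' mutant alleles).
#'
#' @param config a [sim_config()].
#' @return A list of class `sim_truth` with elements
#'   * `truth`: tibble with one row per allele (`region`, `position`,
#'     `wt_codon`, `mut_codon`, `wt_aa`, `mut_aa`, `class`, `s_true`,
#'     `freq0`); the wild-type class row has `position = 0` and codons
#'     `"WT"`.
#'   * `config`, `seed`: the configuration and seed used.
#' @export
draw_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, draw_library_impl(config))
}

draw_library_impl <- function(config) {
  wt_codons <- config$wt_codons %||% random_wt_codons(config$n_positions)
  space <- codon_space()
  if (length(space) == 0) stop("empty codon space")

  pos <- rep(seq_len(config$n_positions), each = length(space) - 1L)
  wt <- wt_codons[pos]
  mut <- unlist(lapply(wt_codons, function(w) setdiff(space, w)),
                use.names = FALSE)
  wt_aa <- codon_to_aa(wt)
  mut_aa <- codon_to_aa(mut)
  cls <- mutation_class(wt_aa, mut_aa)

  s_true <- numeric(length(pos))
  non_syn <- cls != "synonymous"
  if (config$s_unit == "aa") {
    key <- paste(pos, mut_aa)
    uk <- unique(key[non_syn])
    s_map <- setNames(draw_dfe(length(uk), config$dfe), uk)
    s_true[non_syn] <- s_map[key[non_syn]]
  } else {
    s_true[non_syn] <- draw_dfe(sum(non_syn), config$dfe)
  }

  n_mut <- length(pos)
  truth <- tibble::tibble(
    region = c("*", region_of_position(config, pos)),
    position = c(0L, pos),
    wt_codon = c("WT", wt),
    mut_codon = c("WT", mut),
    wt_aa = c("WT", wt_aa),
    mut_aa = c("WT", mut_aa),
    class = c("wt", cls),
    s_true = c(0, s_true),
    freq0 = c(config$wt_mass, rep((1 - config$wt_mass) / n_mut, n_mut))
  )
  if (any(!is.finite(truth$freq0)) || abs(sum(truth$freq0) - 1) > 1e-9) {
    stop("degenerate initial frequency vector")
  }
  structure(list(truth = truth, config = config, seed = config$seed),
            class = "sim_truth")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic selection step of the competition
#'
#' Each allele's abundance is multiplied by `r^(1 + s_true)` (so the
#' wild-type class, s = 0, grows by the nominal fold `r`) and frequencies
#' are renormalised. The realized fold increase in the total number of
#' cells, `sum(freq0 * r^(1 + s))`, is returned alongside: it is the
#' quantity an experimentalist measures as "fold increase in cell number"
#' and is the correct `r` to use in the fitness estimator.
#'
#' @param sim a `sim_truth` from [draw_library()].
#' @return List with `freq_tf` (frequencies after selection, summing to 1)
#'   and `fold` (realized total fold increase).
#' @export
propagate <- function(sim) {
  stopifnot(inherits(sim, "sim_truth"))
  r <- sim$config$r
  s <- sim$truth$s_true
  stopifnot(all(s >= -1), r > 1)
  m <- r^(1 + s)
  unnorm <- sim$truth$freq0 * m
  fold <- sum(unnorm)
  list(freq_tf = unnorm / fold, fold = fold)
}

#' Multinomial sequencing sample of a composition
#'
#' @param freqs frequency vector summing to 1.
#' @param depth total read count to draw.
#' @param seed optional integer seed for this draw.
#' @return Integer vector of counts summing to `depth`.
#' @export
sample_counts <- function(freqs, depth, seed = NULL) {
  if (depth <= 0) stop("depth must be > 0")
  if (abs(sum(freqs) - 1) > 1e-8) stop("freqs must sum to 1")
  draw <- function() as.integer(rmultinom(1, size = depth, prob = freqs))
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

#' Simulate a full growth-competition experiment
#'
#' Runs [draw_library()] (unless a library is supplied), applies selection
#' via [propagate()], and draws independent multinomial sequencing samples
#' at t0 and tf for each replica ("different aliquots of the same library
#' transformation": replicas share the true composition and differ only by
#' sampling). With `config$bottleneck`, one intermediate resample of the
#' mid-competition composition is applied per replica before the remaining
#' generations.
#'
#' @param config a [sim_config()].
#' @param condition condition label stored in the count table.
#' @param library optional `sim_truth` to reuse (e.g. the same library with
#'   altered `s_true` for a second condition).
#' @return List of class `sim_experiment`:
#'   * `counts`: tibble in the package's count-table schema (`condition`,
#'     `replica`, `region`, `position`, `wt_codon`, `mut_codon`,
#'     `count_t0`, `count_tf`); the wild-type class row has `position = 0`.
#'   * `truth`: the allele truth tibble; `fold`: realized fold increase;
#'   * `config`.
#' @export
simulate_experiment <- function(config, condition = "cond1", library = NULL) {
  sim <- library %||% draw_library(config)
  stopifnot(inherits(sim, "sim_truth"))
  withr::with_seed(config$seed + 1000L, {
    prop <- propagate(sim)
    reps <- lapply(seq_len(config$n_replicas), function(k) {
      freq_tf <- prop$freq_tf
      if (isTRUE(config$bottleneck)) {
        # one dilution at ~ half the generations: resample the mid-point
        # composition, then apply the remaining selection
        half <- sqrt(config$r)
        m_half <- half^(1 + sim$truth$s_true)
        mid <- sim$truth$freq0 * m_half
        mid <- mid / sum(mid)
        kept <- as.numeric(rmultinom(1, config$bottleneck_size, mid))
        second <- kept * m_half
        freq_tf <- second / sum(second)
      }
      c0 <- as.integer(rmultinom(1, config$depth_t0, sim$truth$freq0))
      cf <- as.integer(rmultinom(1, config$depth_tf, freq_tf))
      dplyr::mutate(
        sim$truth[, c("region", "position", "wt_codon", "mut_codon")],
        condition = condition, replica = k, count_t0 = c0, count_tf = cf
      )
    })
    counts <- dplyr::bind_rows(reps)[, c("condition", "replica", "region",
                                         "position", "wt_codon", "mut_codon",
                                         "count_t0", "count_tf")]
    structure(list(counts = counts, truth = sim$truth, fold = prop$fold,
                   config = config),
              class = "sim_experiment")
  })
}

#' Write / read the package's count-table schema (TSV)
#'
#' @param counts count tibble as produced by [simulate_experiment()] or
#'   [count_reads()].
#' @param path file path.
#' @return `read_counts()` returns the count tibble; `write_counts()` its
#'   path, invisibly.
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  counts <- suppressWarnings(readr::read_tsv(
    path,
    col_types = readr::cols(
      condition = readr::col_character(),
      replica = readr::col_integer(),
      region = readr::col_character(),
      position = readr::col_integer(),
      wt_codon = readr::col_character(),
      mut_codon = readr::col_character(),
      count_t0 = readr::col_double(),
      count_tf = readr::col_double()
    )
  ))
  req <- c("condition", "replica", "region", "position", "wt_codon",
           "mut_codon", "count_t0", "count_tf")
  missing <- setdiff(req, names(counts))
  if (length(missing)) {
    stop("count table ", path, " is missing columns: ",
         paste(missing, collapse = ", "))
  }
  counts
}

#' Write the simulator's ground truth as TSV
#'
#' @param sim a `sim_truth` or `sim_experiment`.
#' @param path file path.
#' @export
write_truth <- function(sim, path) {
  truth <- if (inherits(sim, "sim_experiment")) sim$truth else sim$truth
  readr::write_tsv(truth, path)
  invisible(path)
}
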