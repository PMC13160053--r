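# Variant counting from merged, trimmed amplicon reads: fixed-window crop,
# per-read quality/identity classification, and aggregation into the count
# table schema. Filters follow the scanning protocol: any base below Q20,
# any N base, or mutations at more than one codon disqualify a read (Q = 20
# itself passes: the rule is "below 20"). Filter precedence is fixed as
# low_quality -> N_base -> multi_codon; precedence only affects how a
# multiply-faulty read is reported, never which reads are kept.

QUALITY_MIN <- 20L

#' Crop reads to a region's fixed window
#'
#' Removes `spec$head_crop` leading bases and keeps the window of
#' `nchar(spec$wt_seq)` bases, mirroring a HEADCROP + CROP trim. Reads too
#' short for the full window are classified `length`-filtered.
#'
#' @param reads read tibble (`id`, `seq`, `qual`).
#' @param spec a [region_spec()].
#' @return The read tibble with cropped `seq`/`qual` and a logical column
#'   `too_short`.
#' @export
crop_reads <- function(reads, spec) {
  stopifnot(inherits(spec, "region_spec"))
  win <- nchar(spec$wt_seq)
  need <- spec$head_crop + win
  too_short <- nchar(reads$seq) < need
  out <- reads
  out$seq <- substr(reads$seq, spec$head_crop + 1L, need)
  out$qual <- substr(reads$qual, spec$head_crop + 1L, need)
  out$too_short <- too_short
  out
}

#' Classify cropped reads against the wild-type window
#'
#' Applies the read filters and, for kept reads, the codon-wise comparison
#' to the wild-type window: zero mutated codons is a wild-type read, exactly
#' one yields a variant call, two or more are filtered.
#'
#' @param cropped output of [crop_reads()].
#' @param spec a [region_spec()].
#' @return Tibble with one row per read: `verdict` (one of `"wt"`,
#'   `"variant"`, `"low_quality"`, `"N_base"`, `"multi_codon"`, `"length"`)
#'   and, for variants, `position`, `wt_codon`, `mut_codon`.
#' @export
classify_reads <- function(cropped, spec) {
  n <- nrow(cropped)
  verdict <- rep(NA_character_, n)
  position <- rep(NA_integer_, n)
  wt_codon <- rep(NA_character_, n)
  mut_codon <- rep(NA_character_, n)
  if (n == 0) {
    return(tibble::tibble(id = character(0), verdict = character(0),
                          position = integer(0), wt_codon = character(0),
                          mut_codon = character(0)))
  }
  verdict[cropped$too_short] <- "length"
  live <- which(is.na(verdict))

  min_q <- vapply(cropped$qual[live],
                  function(q) min(utf8ToInt(q)) - 33L, 0L,
                  USE.NAMES = FALSE)
  low <- live[min_q < QUALITY_MIN]
  verdict[low] <- "low_quality"
  live <- setdiff(live, low)

  has_n <- live[grepl("N", cropped$seq[live], fixed = TRUE)]
  verdict[has_n] <- "N_base"
  live <- setdiff(live, has_n)

  if (length(live)) {
    seqs <- cropped$seq[live]
    mism <- matrix(FALSE, nrow = length(live), ncol = spec$n_codons)
    codons <- matrix("", nrow = length(live), ncol = spec$n_codons)
    for (k in seq_len(spec$n_codons)) {
      off <- (k - 1L) * 3L + 1L
      codons[, k] <- substr(seqs, off, off + 2L)
      mism[, k] <- codons[, k] != spec$wt_codons[k]
    }
    n_mut <- rowSums(mism)
    verdict[live[n_mut == 0]] <- "wt"
    verdict[live[n_mut >= 2]] <- "multi_codon"
    one <- which(n_mut == 1)
    if (length(one)) {
      k_hit <- max.col(mism[one, , drop = FALSE], ties.method = "first")
      idx <- live[one]
      verdict[idx] <- "variant"
      position[idx] <- spec$positions[k_hit]
      wt_codon[idx] <- spec$wt_codons[k_hit]
      mut_codon[idx] <- codons[cbind(one, k_hit)]
    }
  }
  tibble::tibble(id = cropped$id, verdict = verdict, position = position,
                 wt_codon = wt_codon, mut_codon = mut_codon)
}

#' Count variants in a set of merged amplicon reads
#'
#' Runs [crop_reads()] and [classify_reads()] and aggregates kept reads
#' into the package's count-table schema: one row per observed single-codon
#' variant plus one pooled wild-type row (`position = 0`, codons `"WT"`).
#' Kept plus filtered reads always equals the input total.
#'
#' @param reads read tibble (`id`, `seq`, `qual`) or a FASTQ path.
#' @param spec a [region_spec()].
#' @return List of class `count_result`:
#'   * `counts`: tibble (`region`, `position`, `wt_codon`, `mut_codon`,
#'     `count`), sorted by position then codon;
#'   * `report`: named list of totals per verdict class plus `total` and
#'     `kept`;
#'   * `verdicts`: the per-read classification tibble.
#' @export
count_reads <- function(reads, spec) {
  if (is.character(reads)) reads <- read_fastq(reads)
  cls <- classify_reads(crop_reads(reads, spec), spec)
  kept <- cls[cls$verdict %in% c("wt", "variant"), ]
  var_counts <- dplyr::count(
    kept[kept$verdict == "variant", c("position", "wt_codon", "mut_codon")],
    .data$position, .data$wt_codon, .data$mut_codon, name = "count"
  )
  wt_row <- tibble::tibble(position = 0L, wt_codon = "WT", mut_codon = "WT",
                           count = sum(kept$verdict == "wt"))
  counts <- dplyr::bind_rows(wt_row, var_counts)
  counts <- tibble::add_column(counts, region = spec$name, .before = 1)
  counts <- dplyr::arrange(counts, .data$position, .data$mut_codon)
  report <- list(
    total = nrow(cls),
    kept = nrow(kept),
    wt = sum(cls$verdict == "wt"),
    variant = sum(cls$verdict == "variant"),
    filtered_length = sum(cls$verdict == "length"),
    filtered_low_quality = sum(cls$verdict == "low_quality"),
    filtered_N_base = sum(cls$verdict == "N_base"),
    filtered_multi_codon = sum(cls$verdict == "multi_codon")
  )
  structure(list(counts = counts, report = report, verdicts = cls),
            class = "count_result")
}

#' Write a filter report as YAML
#'
#' @param result a `count_result` from [count_reads()].
#' @param path output path.
#' @export
write_filter_report <- function(result, path) {
  yaml::write_yaml(result$report, path)
  invisible(path)
}
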