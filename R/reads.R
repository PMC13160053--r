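# Amplicon read emission (simulator side) and FASTQ I/O. Reads are carried
# in-memory as a tibble (id, seq, qual) with Phred+33 quality strings;
# Biostrings handles the FASTQ format on disk.

#' Define an amplicon region window
#'
#' A region is the fixed window of the merged amplicon read that covers a
#' contiguous run of codons, after a fixed head-crop (adapter/primer bases)
#' has been removed. The window length must be a multiple of 3.
#'
#' @param name region label (matches the count table's `region` column).
#' @param wt_seq wild-type nucleotide sequence of the cropped window.
#' @param start_position protein position of the window's first codon.
#' @param head_crop bases removed from the start of each merged read before
#'   the window.
#' @return Object of class `region_spec`.
#' @export
region_spec <- function(name, wt_seq, start_position, head_crop = 0) {
  wt_seq <- toupper(wt_seq)
  if (nchar(wt_seq) %% 3 != 0) {
    stop("region window length must be a multiple of 3")
  }
  n_codons <- nchar(wt_seq) %/% 3
  structure(list(name = name, wt_seq = wt_seq,
                 start_position = as.integer(start_position),
                 head_crop = as.integer(head_crop),
                 n_codons = n_codons,
                 positions = seq(start_position, length.out = n_codons),
                 wt_codons = substring(wt_seq, seq(1, nchar(wt_seq), 3),
                                       seq(3, nchar(wt_seq), 3))),
            class = "region_spec")
}

# region_spec for one simulated region of a sim_config / sim_truth.
sim_region_spec <- function(sim, region, head_crop = 0) {
  truth <- if (inherits(sim, "sim_truth") || inherits(sim, "sim_experiment"))
    sim$truth else sim
  rows <- truth[truth$region == region & truth$position > 0, ]
  if (nrow(rows) == 0) stop("unknown region: ", region)
  pos <- sort(unique(rows$position))
  wt <- vapply(pos, function(p) rows$wt_codon[rows$position == p][1], "")
  region_spec(region, paste(wt, collapse = ""), pos[1], head_crop = head_crop)
}

#' Emit error-free or fault-injected reads for a set of allele counts
#'
#' Produces one full-region read per count, carrying the allele's codon
#' substitution on the wild-type window (wild-type class rows, position 0,
#' yield unmutated reads). A fixed head flank of length `spec$head_crop` is
#' prepended so the counting stage's crop step is exercised. Fault
#' injection modifies the first `n_inject_*` emitted reads so the counter's
#' filters can be tested with exactly known totals: one base dropped to
#' Q19 (`lowq`), one base replaced by `N` (`n`), or a second codon mutated
#' (`multi`).
#'
#' @param counts tibble with columns `position`, `wt_codon`, `mut_codon`
#'   and `count` (use e.g. `count_tf` renamed); positions must lie in the
#'   region (or be the wild-type class row, `position == 0`).
#' @param spec a [region_spec()].
#' @param base_quality Phred score written on every base (default 37).
#' @param n_inject_lowq,n_inject_n,n_inject_multi number of reads to
#'   corrupt per fault class.
#' @param seed optional seed (only the injected multi-codon choice is
#'   random).
#' @return Tibble with columns `id`, `seq`, `qual`.
#' @export
emit_reads <- function(counts, spec, base_quality = 37,
                       n_inject_lowq = 0, n_inject_n = 0, n_inject_multi = 0,
                       seed = NULL) {
  stopifnot(inherits(spec, "region_spec"))
  ok <- counts$position == 0 | counts$position %in% spec$positions
  if (!all(ok)) {
    stop("allele positions outside region window: ",
         paste(unique(counts$position[!ok]), collapse = ", "))
  }
  build <- function() {
    idx <- rep(seq_len(nrow(counts)), counts$count)
    seqs <- rep(spec$wt_seq, length(idx))
    pos <- counts$position[idx]
    is_var <- pos > 0
    if (any(is_var)) {
      off <- (pos[is_var] - spec$start_position) * 3L + 1L
      substr(seqs[is_var], off, off + 2L) <- counts$mut_codon[idx[is_var]]
      # guard against a mut codon identical to wt (not a variant read)
    }
    qual <- strrep(intToUtf8(base_quality + 33L), nchar(spec$wt_seq))
    quals <- rep(qual, length(idx))

    inject_at <- function(k, n) if (n > 0) seq_len(min(n, length(idx))) + k else integer(0)
    i_low <- inject_at(0, n_inject_lowq)
    i_n <- inject_at(length(i_low), n_inject_n)
    i_multi <- inject_at(length(i_low) + length(i_n), n_inject_multi)
    if (length(i_low)) {
      substr(quals[i_low], 1L, 1L) <- intToUtf8(19L + 33L)
    }
    if (length(i_n)) {
      substr(seqs[i_n], 1L, 1L) <- "N"
    }
    for (i in i_multi) {
      # ensure the read carries mutations at >= 2 codons: add non-wt
      # codons besides the allele's own until two codons differ
      own <- match(pos[i], spec$positions, nomatch = 0L)
      extra <- setdiff(seq_len(spec$n_codons), own)[seq_len(2L - (own > 0))]
      for (k in extra) {
        alt <- setdiff(codon_space(), spec$wt_codons[k])[sample.int(63L, 1L)]
        off <- (k - 1L) * 3L + 1L
        substr(seqs[i], off, off + 2L) <- alt
      }
    }
    head <- strrep("A", spec$head_crop)
    head_q <- strrep(intToUtf8(base_quality + 33L), spec$head_crop)
    tibble::tibble(id = paste0(spec$name, "_read", seq_along(idx)),
                   seq = paste0(head, seqs),
                   qual = paste0(head_q, quals))
  }
  if (is.null(seed)) build() else withr::with_seed(as.integer(seed), build())
}

#' FASTQ input/output (Phred+33)
#'
#' Thin wrappers over Biostrings' FASTQ support converting to/from the
#' package's in-memory read tibble (`id`, `seq`, `qual`).
#'
#' @param reads read tibble.
#' @param path FASTQ file path.
#' @return `read_fastq()` returns a read tibble; `write_fastq()` its path,
#'   invisibly.
#' @export
write_fastq <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(reads$seq)
  names(dna) <- reads$id
  Biostrings::writeXStringSet(dna, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  tibble::tibble(id = names(x), seq = as.character(x),
                 qual = as.character(S4Vectors::mcols(x)$qualities))
}
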