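# Codon-level helpers shared by the simulator, the read counter and the
# fitness layer. Translation uses the standard genetic code from Biostrings.

#' All 64 codons of the NNN mutagenesis space
#'
#' @return Character vector of the 64 DNA codons in a fixed lexicographic
#'   order (the order is part of the package's deterministic behaviour).
#' @export
codon_space <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

#' Translate codons to one-letter amino acids
#'
#' Stop codons translate to `"*"`.
#'
#' @param codon character vector of DNA codons (A/C/G/T, length 3).
#' @return Character vector of one-letter amino-acid codes.
#' @export
codon_to_aa <- function(codon) {
  aa <- unname(Biostrings::GENETIC_CODE[codon])
  if (anyNA(aa)) {
    stop("invalid codon(s): ", paste(unique(codon[is.na(aa)]), collapse = ", "))
  }
  aa
}

#' Classify an amino-acid change
#'
#' @param wt_aa,mut_aa one-letter amino acids of the wild-type and mutant
#'   codon at a position.
#' @return `"synonymous"`, `"missense"` or `"nonsense"` per element.
#' @export
mutation_class <- function(wt_aa, mut_aa) {
  ifelse(mut_aa == "*", "nonsense",
         ifelse(mut_aa == wt_aa, "synonymous", "missense"))
}

#' Amino-acid column order used by landscape matrices
#'
#' Twenty amino acids followed by the stop symbol.
#' @return Character vector of length 21.
#' @export
aa_levels <- function() {
  c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "*")
}

# Random wild-type codon sequence without internal stop codons.
random_wt_codons <- function(n_positions) {
  cods <- setdiff(codon_space(), c("TAA", "TAG", "TGA"))
  sample(cods, n_positions, replace = TRUE)
}
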