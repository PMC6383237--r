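# Codon-level translation helpers built on the standard genetic code.
# Codons containing gaps or ambiguity codes translate to NA: downstream
# scanners decide their treatment (usually "skip and log") rather than guess.

#' Translate a single codon under the standard genetic code
#'
#' @param codon Character scalar of length 3 over `A,C,G,T` (case-insensitive).
#' @return Single amino-acid letter (`"*"` for a stop), or `NA_character_`
#'   when the codon contains a gap or ambiguity code.
#' @examples
#' translate_codon("TGC")  # "C"
#' translate_codon("TGA")  # "*"
#' translate_codon("T-A")  # NA
#' @export
translate_codon <- function(codon) {
  codon <- toupper(codon)
  if (nchar(codon) != 3L || grepl("[^ACGT]", codon)) {
    return(NA_character_)
  }
  unname(Biostrings::GENETIC_CODE[[codon]])
}

#' Translate a gap-free nucleotide string codon by codon
#'
#' Trailing incomplete codons are dropped. Codons with gaps or ambiguity
#' codes become `X`.
#'
#' @param nt Nucleotide string.
#' @return Amino-acid string (stops as `*`).
#' @export
translate_sequence <- function(nt) {
  nt <- toupper(nt)
  n <- nchar(nt) %/% 3L
  if (n == 0L) return("")
  codons <- substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- vapply(codons, function(cd) {
    out <- translate_codon(cd)
    if (is.na(out)) "X" else out
  }, character(1))
  paste(aa, collapse = "")
}

is_stop_codon <- function(codon, stop_set = STANDARD_STOPS) {
  toupper(codon) %in% stop_set
}

# Split a sequence string into a character vector of single residues.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
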