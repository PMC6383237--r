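# Reference-anchored coordinates. Comparative pseudogene work reports every
# lesion in the numbering of a functional reference sequence; two
# conventions coexist in the literature and both are supported:
#   alignment_columns  - every alignment column is numbered, gap columns
#                        included (the convention used when positions are
#                        read off a figure of the full alignment);
#   ungapped_reference - only reference non-gap sites are numbered.
# Codon indices are always over the ungapped reference coding sequence and
# are therefore identical in both modes.

#' Build a coordinate map between alignment columns and reference numbering
#'
#' @param aln A [coding_alignment()].
#' @param mode `"alignment_columns"` (default: positions number every
#'   column, indel columns included) or `"ungapped_reference"` (positions
#'   number reference non-gap sites only).
#' @param coding_start Position of the first coding base in *ungapped
#'   reference* coordinates (default 1: the whole reference is CDS).
#' @return An object of class `coordinate_map` with fields
#'   `column_to_refpos` (NA at reference-gap columns in ungapped mode),
#'   `refpos_to_column`, `codon_columns` (n_codons x 3 matrix of alignment
#'   columns under each reference codon), `ref_codons`, `n_codons`, `mode`.
#' @export
build_coordinate_map <- function(aln,
                                 mode = c("alignment_columns", "ungapped_reference"),
                                 coding_start = 1L) {
  mode <- match.arg(mode)
  ref <- seq_chars(aln_seq(aln, aln$reference_id))
  L <- length(ref)
  non_gap <- which(ref != "-")

  if (mode == "alignment_columns") {
    column_to_refpos <- seq_len(L)
    refpos_to_column <- seq_len(L)
  } else {
    column_to_refpos <- rep(NA_integer_, L)
    column_to_refpos[non_gap] <- seq_along(non_gap)
    refpos_to_column <- non_gap
  }

  if (coding_start < 1L || coding_start > length(non_gap)) {
    ps_error("coding_start outside the ungapped reference", "pseudoscan_range_error")
  }
  coding_cols <- non_gap[coding_start:length(non_gap)]
  n_codons <- length(coding_cols) %/% 3L
  codon_columns <- matrix(coding_cols[seq_len(3L * n_codons)],
                          ncol = 3L, byrow = TRUE)
  ref_codons <- apply(codon_columns, 1L, function(cols) paste(ref[cols], collapse = ""))

  structure(
    list(reference_id = aln$reference_id, mode = mode,
         column_to_refpos = column_to_refpos,
         refpos_to_column = refpos_to_column,
         codon_columns = codon_columns, ref_codons = ref_codons,
         n_codons = n_codons, alignment_length = L,
         coding_start = as.integer(coding_start)),
    class = "coordinate_map"
  )
}

#' Extract the residues of a sequence under a reference codon
#'
#' Returns the three residues of `seq_id` in the alignment columns occupied
#' by the reference's `codon_index`-th codon. Insertion columns between
#' them (reference gaps) are not part of the codon; they are reported
#' separately by [detect_indels()].
#'
#' @param map A [build_coordinate_map()] result.
#' @param aln The [coding_alignment()] the map was built from.
#' @param seq_id Sequence to query.
#' @param codon_index 1-based reference codon index.
#' @return An object of class `codon`: list with `codon_index`,
#'   `nucleotides` (length-3 string, possibly with gaps) and `complete`
#'   (`TRUE` iff gap-free).
#' @export
codon_at <- function(map, aln, seq_id, codon_index) {
  if (length(codon_index) != 1L || codon_index < 1L || codon_index > map$n_codons) {
    ps_error(sprintf("codon_index %s out of range 1..%d",
                     paste(codon_index, collapse = ","), map$n_codons),
             "pseudoscan_range_error")
  }
  s <- seq_chars(aln_seq(aln, seq_id))
  nt <- paste(s[map$codon_columns[codon_index, ]], collapse = "")
  structure(
    list(codon_index = as.integer(codon_index), nucleotides = nt,
         complete = !grepl("-", nt, fixed = TRUE)),
    class = "codon"
  )
}

# Reference position reported for an alignment column, honouring the map's
# numbering mode. For reference-gap columns in ungapped mode, `direction`
# picks the nearest numbered site at/after ("next") or at/before ("prev").
column_ref_position <- function(map, column, direction = c("next", "prev")) {
  direction <- match.arg(direction)
  if (map$mode == "alignment_columns") return(as.integer(column))
  rp <- map$column_to_refpos[column]
  if (!is.na(rp)) return(rp)
  later <- map$column_to_refpos[seq(column, map$alignment_length)]
  earlier <- map$column_to_refpos[seq_len(column)]
  if (direction == "next") {
    hit <- later[!is.na(later)]
    if (length(hit)) hit[1] else length(map$refpos_to_column) + 1L
  } else {
    hit <- earlier[!is.na(earlier)]
    if (length(hit)) hit[length(hit)] else 0L
  }
}

#' @export
print.coordinate_map <- function(x, ...) {
  cat(sprintf("<coordinate_map> reference '%s', mode %s, %d columns, %d codons\n",
              x$reference_id, x$mode, x$alignment_length, x$n_codons))
  invisible(x)
}

#' @export
print.codon <- function(x, ...) {
  cat(sprintf("<codon %d> %s (%s)\n", x$codon_index, x$nucleotides,
              if (x$complete) "complete" else "incomplete"))
  invisible(x)
}

#' @export
as.data.frame.coordinate_map <- function(x, ...) {
  data.frame(column = seq_len(x$alignment_length),
             ref_position = x$column_to_refpos)
}
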