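# Coding alignments: the substrate of every scan. One designated reference
# record anchors coordinates and the reading frame; all other records are
# queried against it.

#' Construct a coding alignment
#'
#' A `coding_alignment` holds equal-length gapped nucleotide sequences plus
#' the id of a designated functional reference. The reference defines the
#' reading frame for every downstream scan; by default it must translate
#' (after gap removal) to an open reading frame ending in a stop codon with
#' no internal stops.
#'
#' Species and allele labels are parsed from sequence ids: a trailing
#' `*<digits>` token denotes an allele (`"O_hoffmanni*2"` is allele `"2"` of
#' species `"O_hoffmanni"`); its absence means a single observed allele.
#'
#' @param sequences Named character vector (or `Biostrings::XStringSet`) of
#'   equal-length aligned sequences over `A,C,G,T,N`, IUPAC ambiguity codes
#'   and `-`. Case-insensitive; normalized to upper case.
#' @param reference_id Id of the reference record.
#' @param species,allele Optional character vectors overriding the labels
#'   parsed from the ids.
#' @param check_reference_orf If `TRUE` (default), validate that the
#'   ungapped reference is a complete ORF ending in a stop codon.
#' @return An object of class `coding_alignment` with elements `seqs`
#'   (named character vector), `meta` (data.frame of id, species, allele),
#'   `reference_id` and `alignment_length`.
#' @seealso [read_alignment()], [build_coordinate_map()], [scan_alignment()]
#' @export
coding_alignment <- function(sequences, reference_id,
                             species = NULL, allele = NULL,
                             check_reference_orf = TRUE) {
  if (inherits(sequences, "XStringSet")) {
    sequences <- as.character(sequences)
  }
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids))) {
    ps_error("all sequences must have non-empty ids", "pseudoscan_alphabet_error")
  }
  if (anyDuplicated(ids)) {
    ps_error(sprintf("duplicate sequence id: '%s'", ids[duplicated(ids)][1]),
             "pseudoscan_alignment_shape_error")
  }
  if (any(!nzchar(sequences))) {
    ps_error("sequences must be non-empty", "pseudoscan_alignment_shape_error")
  }
  sequences <- toupper(sequences)

  bad <- gregexpr(sprintf("[^%s-]", paste(setdiff(ALLOWED_CHARS, "-"), collapse = "")),
                  sequences)
  for (i in seq_along(bad)) {
    pos <- bad[[i]]
    if (pos[1] != -1L) {
      ps_error(sprintf("illegal character '%s' in record '%s' at column %d",
                       substr(sequences[i], pos[1], pos[1]), ids[i], pos[1]),
               "pseudoscan_alphabet_error")
    }
  }

  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    ps_error(sprintf("sequences are not aligned: lengths %s",
                     paste(unique(lens), collapse = ", ")),
             "pseudoscan_alignment_shape_error")
  }
  if (sum(ids == reference_id) != 1L) {
    ps_error(sprintf("reference id '%s' does not name exactly one record", reference_id),
             "pseudoscan_missing_reference_error")
  }

  parsed <- parse_allele_labels(ids)
  meta <- data.frame(
    id = ids,
    species = if (is.null(species)) parsed$species else species,
    allele = if (is.null(allele)) parsed$allele else allele,
    stringsAsFactors = FALSE
  )

  aln <- structure(
    list(seqs = sequences, meta = meta, reference_id = reference_id,
         alignment_length = unname(lens[1])),
    class = "coding_alignment"
  )
  if (check_reference_orf) validate_reference_orf(aln)
  aln
}

# Allele convention: trailing "*<digits>" on the id; the remainder is the
# species token.
parse_allele_labels <- function(ids) {
  m <- regmatches(ids, regexpr("\\*[0-9]+$", ids))
  has <- grepl("\\*[0-9]+$", ids)
  allele <- character(length(ids))
  allele[has] <- sub("^\\*", "", regmatches(ids, regexpr("\\*[0-9]+$", ids)))
  list(species = sub("\\*[0-9]+$", "", ids), allele = allele)
}

validate_reference_orf <- function(aln) {
  ref <- gsub("-", "", aln$seqs[[aln$reference_id]], fixed = TRUE)
  if (nchar(ref) < 6L || nchar(ref) %% 3L != 0L) {
    ps_error(sprintf(
      "ungapped reference '%s' has length %d, not a positive multiple of 3",
      aln$reference_id, nchar(ref)), "pseudoscan_reference_orf_error")
  }
  aa <- translate_sequence(ref)
  n <- nchar(aa)
  if (substr(aa, n, n) != "*") {
    ps_error(sprintf("reference '%s' does not end in a stop codon", aln$reference_id),
             "pseudoscan_reference_orf_error")
  }
  if (grepl("\\*", substr(aa, 1L, n - 1L))) {
    ps_error(sprintf("reference '%s' contains an internal stop codon", aln$reference_id),
             "pseudoscan_reference_orf_error")
  }
  invisible(aln)
}

#' Read an aligned FASTA file into a coding alignment
#'
#' @param path Path to an aligned FASTA file (gaps as `-`). All sequences
#'   must have equal length.
#' @param reference_id Id of the designated functional reference record.
#' @inheritParams coding_alignment
#' @return A [coding_alignment()].
#' @export
read_alignment <- function(path, reference_id, check_reference_orf = TRUE) {
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  # FASTA descriptions may carry trailing comments; the id is the first token.
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  coding_alignment(seqs, reference_id, check_reference_orf = check_reference_orf)
}

#' Write a coding alignment to FASTA
#'
#' @param aln A [coding_alignment()].
#' @param path Output path.
#' @export
write_alignment <- function(aln, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(aln$seqs), path, width = 70L)
  invisible(path)
}

seq_ids <- function(aln) aln$meta$id

aln_seq <- function(aln, seq_id) {
  if (!seq_id %in% names(aln$seqs)) {
    ps_error(sprintf("sequence id '%s' not present in alignment", seq_id),
             "pseudoscan_missing_sequence_error")
  }
  aln$seqs[[seq_id]]
}

#' @export
print.coding_alignment <- function(x, ...) {
  cat(sprintf("<coding_alignment> %d sequences x %d columns (reference: %s)\n",
              nrow(x$meta), x$alignment_length, x$reference_id))
  n_show <- min(nrow(x$meta), 8L)
  for (i in seq_len(n_show)) {
    s <- x$seqs[[i]]
    prev <- if (nchar(s) > 50) paste0(substr(s, 1, 50), "...") else s
    cat(sprintf("  %-24s %s\n", x$meta$id[i], prev))
  }
  if (nrow(x$meta) > n_show) cat(sprintf("  ... and %d more\n", nrow(x$meta) - n_show))
  invisible(x)
}
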