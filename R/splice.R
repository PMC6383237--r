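# Splice-acceptor scanning. An acceptor dinucleotide occurring inside an
# intron, upstream of the annotated 3' end, creates an alternative acceptor
# whose use retains the downstream intron segment in the mature transcript
# (intron retention). If the retained length is a multiple of 3 the reading
# frame is preserved and length/3 amino acids are inserted. Candidates are
# plain motif matches: no strength scoring is attempted.

#' Find candidate splice-acceptor sites in an intron
#'
#' Returns the annotated acceptor (offset 0) plus every occurrence of the
#' acceptor motif whose use would end the intron within `search_window`
#' nucleotides upstream of the annotated 3' end, sorted by offset.
#'
#' Two motif conventions are supported. `side = "intron_terminal"`
#' (default) treats the motif as the last intron bases of the alternative
#' acceptor, the canonical `AG` reading. `side = "exon_initial"` treats the
#' motif as the first bases of the newly created exon segment, matching
#' descriptions of an acceptor-flanking exon-side motif (e.g. a `CA`
#' immediately at an exon start).
#'
#' @param model A [gene_model()].
#' @param intron_index Which intron (1-based).
#' @param search_window Scan depth in nucleotides upstream of the annotated
#'   acceptor; must not exceed the intron length.
#' @param motif Acceptor dinucleotide (default `"AG"`).
#' @param side `"intron_terminal"` or `"exon_initial"` (see above).
#' @return data.frame of class `splice_sites`: `intron_index`,
#'   `position_in_intron` (1-based position of the last intron nucleotide
#'   used by the acceptor), `dinucleotide`, `offset_nt` (0 for the
#'   annotated site), `retained_seq` (intron segment retained when this
#'   acceptor is used).
#' @examples
#' gm <- gene_model("g", rbind(c(1, 9), c(110, 130)),
#'                  introns = paste0(strrep("T", 75), "AG",
#'                                   strrep("C", 19), "AG"))
#' find_acceptor_candidates(gm, 1, search_window = 50)  # offsets 0 and 21
#' @export
find_acceptor_candidates <- function(model, intron_index, search_window,
                                     motif = "AG",
                                     side = c("intron_terminal", "exon_initial")) {
  side <- match.arg(side)
  motif <- toupper(motif)
  if (intron_index < 1L || intron_index > length(model$introns)) {
    ps_error(sprintf("intron %d not present (model has %d)", intron_index,
                     length(model$introns)), "pseudoscan_range_error")
  }
  intron <- model$introns[[intron_index]]
  L <- nchar(intron)
  if (search_window > L) {
    ps_error(sprintf("search window %d exceeds intron length %d", search_window, L),
             "pseudoscan_range_error")
  }
  w <- nchar(motif)

  sites <- data.frame(intron_index = intron_index, position_in_intron = L,
                      dinucleotide = substr(intron, L - w + 1L, L),
                      offset_nt = 0L, retained_seq = "",
                      stringsAsFactors = FALSE)

  # all motif occurrences in the intron
  starts <- integer()
  if (L >= w) {
    hits <- gregexpr(motif, intron, fixed = TRUE)[[1]]
    if (hits[1] != -1L) starts <- as.integer(hits)
  }
  for (p in starts) {
    if (side == "intron_terminal") {
      last_used <- p + w - 1L            # intron ends at the motif's last base
    } else {
      last_used <- p - 1L                # new exon starts at the motif
      if (last_used < 1L) next
    }
    offset <- L - last_used
    if (offset >= 1L && offset <= search_window) {
      sites <- rbind(sites, data.frame(
        intron_index = intron_index, position_in_intron = last_used,
        dinucleotide = if (side == "intron_terminal") motif
                       else substr(intron, last_used - w + 1L, last_used),
        offset_nt = offset,
        retained_seq = substr(intron, last_used + 1L, L),
        stringsAsFactors = FALSE))
    }
  }
  sites <- sites[order(sites$offset_nt), , drop = FALSE]
  sites <- sites[!duplicated(sites$offset_nt), , drop = FALSE]
  rownames(sites) <- NULL
  class(sites) <- c("splice_sites", "data.frame")
  sites
}

#' Predict the intron-retention consequence of an alternative acceptor
#'
#' Use of an acceptor `offset_nt` nucleotides upstream of the annotated
#' site retains exactly that many intron nucleotides in the transcript.
#' The retention is in frame iff the offset is divisible by 3 (the
#' insertion lands at the exon boundary and must not shift the downstream
#' frame); in that case `offset_nt / 3` amino acids are inserted and, when
#' the retained segment is known, its peptide is translated.
#'
#' @param site One row of a [find_acceptor_candidates()] result with
#'   `offset_nt > 0`, or a bare positive offset in nucleotides.
#' @return Object of class `retention_prediction`: list with `inserted_nt`,
#'   `in_frame`, `inserted_aa`, `inserted_peptide` (empty when out of frame
#'   or the segment is unknown).
#' @examples
#' predict_retention(21)  # in frame, 7 amino acids
#' predict_retention(20)  # frameshifting
#' @export
predict_retention <- function(site) {
  if (is.numeric(site)) {
    offset <- as.integer(site)
    retained <- NA_character_
  } else {
    if (is.data.frame(site) && nrow(site) != 1L) {
      ps_error("predict_retention expects a single site", "pseudoscan_range_error")
    }
    offset <- as.integer(site$offset_nt)
    retained <- site$retained_seq
  }
  if (is.na(offset) || offset <= 0L) {
    ps_error("site is the annotated acceptor (offset 0), not an alternative",
             "pseudoscan_not_alternative_error")
  }
  in_frame <- offset %% 3L == 0L
  peptide <- ""
  if (in_frame && !is.na(retained) && nzchar(retained)) {
    peptide <- translate_sequence(retained)
  }
  structure(
    list(inserted_nt = offset, in_frame = in_frame,
         inserted_aa = if (in_frame) offset %/% 3L else 0L,
         inserted_peptide = peptide),
    class = "retention_prediction"
  )
}

#' @export
print.retention_prediction <- function(x, ...) {
  if (x$in_frame) {
    cat(sprintf("<retention> %d nt retained, in frame: +%d aa%s\n",
                x$inserted_nt, x$inserted_aa,
                if (nzchar(x$inserted_peptide)) paste0(" (", x$inserted_peptide, ")") else ""))
  } else {
    cat(sprintf("<retention> %d nt retained, frameshifting\n", x$inserted_nt))
  }
  invisible(x)
}

#' Offset between two species' acceptor positions
#'
#' Absolute difference of two acceptor positions stated in the same
#' coordinate system (the caller guarantees a shared frame).
#'
#' @param pos_species_a,pos_species_b Positive 1-based positions.
#' @return Integer absolute offset in nucleotides.
#' @examples
#' compare_acceptor_positions(28, 49)  # 21
#' @export
compare_acceptor_positions <- function(pos_species_a, pos_species_b) {
  stopifnot(pos_species_a >= 1L, pos_species_b >= 1L)
  abs(as.integer(pos_species_a) - as.integer(pos_species_b))
}
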