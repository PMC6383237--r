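# Lesion detection. Every scan is reference-anchored: the reading frame is
# defined solely by the reference record, and query sequences are examined
# codon-by-codon (stops, motifs, start) or column-by-column (indels) in the
# reference frame. Frameshifted queries are NOT re-translated in their own
# shifted frame: lesions are enumerated independently, as in comparative
# gene-loss annotation.

EVENT_KINDS <- c("premature_stop", "frameshift_indel", "inframe_indel",
                 "motif_substitution", "motif_stop_loss", "start_loss")
DISRUPTING_KINDS <- c("premature_stop", "frameshift_indel", "start_loss",
                      "motif_stop_loss")

#' Create a (possibly empty) disruption-event table
#'
#' Events are plain data frames with columns `seq_id`, `kind`,
#' `ref_position`, `length`, `detail`; all detectors return this shape so
#' results can be combined with `rbind`.
#'
#' @param seq_id,kind,ref_position,length,detail Parallel vectors.
#' @return data.frame of events.
#' @export
disruption_events <- function(seq_id = character(), kind = character(),
                              ref_position = integer(), length = integer(),
                              detail = character()) {
  stopifnot(all(kind %in% EVENT_KINDS))
  data.frame(seq_id = as.character(seq_id), kind = as.character(kind),
             ref_position = as.integer(ref_position),
             length = as.integer(length), detail = as.character(detail),
             stringsAsFactors = FALSE)
}

#' Detect premature stop codons in one sequence
#'
#' Walks every reference codon strictly before the reference's terminal
#' stop. A complete (gap-free, unambiguous) query codon belonging to
#' `stop_set` yields one `premature_stop` event at that codon index.
#' Codons containing gaps or ambiguity codes are skipped, never guessed;
#' their indices are returned in the `skipped` attribute. The terminal stop
#' position itself never yields an event, but a query whose codon there is
#' complete and not a stop is flagged in the `missing_terminal_stop`
#' attribute (a known failure mode of draft database sequences).
#'
#' @param aln A [coding_alignment()].
#' @param map Matching [build_coordinate_map()].
#' @param seq_id Query sequence id.
#' @param stop_set Stop codons to call (default standard genetic code).
#' @return Event data.frame (see [disruption_events()]) with attributes
#'   `skipped` (integer codon indices) and `missing_terminal_stop` (logical).
#' @examples
#' aln <- coding_alignment(
#'   c(ref = "ATGTGCTGCTAA", q = "ATGTGATGCTAA"), "ref")
#' map <- build_coordinate_map(aln)
#' detect_premature_stops(aln, map, "q")  # TGC>TGA at codon 2
#' @export
detect_premature_stops <- function(aln, map, seq_id, stop_set = STANDARD_STOPS) {
  stopifnot(length(stop_set) > 0)
  s <- seq_chars(aln_seq(aln, seq_id))
  n <- map$n_codons
  skipped <- integer()
  hit_idx <- integer(); hit_detail <- character()
  for (i in seq_len(max(n - 1L, 0L))) {
    nt <- paste(s[map$codon_columns[i, ]], collapse = "")
    if (grepl("[^ACGT]", nt)) {
      skipped <- c(skipped, i)
      next
    }
    if (nt %in% stop_set) {
      hit_idx <- c(hit_idx, i)
      hit_detail <- c(hit_detail, paste0(map$ref_codons[i], ">", nt))
    }
  }
  term <- paste(s[map$codon_columns[n, ]], collapse = "")
  missing_term <- !grepl("[^ACGT]", term) && !(term %in% stop_set)
  ev <- disruption_events(seq_id = rep(seq_id, length(hit_idx)),
                          kind = rep("premature_stop", length(hit_idx)),
                          ref_position = hit_idx,
                          length = rep(0L, length(hit_idx)),
                          detail = hit_detail)
  attr(ev, "skipped") <- skipped
  attr(ev, "missing_terminal_stop") <- missing_term
  ev
}

#' Detect start-codon loss
#'
#' If the reference's first codon is `ATG` and the query's codon there is
#' anything else (including gapped), one `start_loss` event is reported.
#'
#' @inheritParams detect_premature_stops
#' @return Event data.frame.
#' @export
detect_start_loss <- function(aln, map, seq_id) {
  if (map$n_codons < 1L || map$ref_codons[1] != "ATG") {
    return(disruption_events())
  }
  obs <- codon_at(map, aln, seq_id, 1L)$nucleotides
  if (obs == "ATG") return(disruption_events())
  disruption_events(seq_id = seq_id, kind = "start_loss", ref_position = 1L,
                    length = 0L, detail = paste0("ATG>", obs))
}

#' Detect insertions and deletions relative to the reference
#'
#' A *deletion* is a maximal run of columns where the query is gapped and
#' the reference is not; an *insertion* is a maximal run where the
#' reference is gapped and the query is not. Columns gapped in both
#' sequences (indels private to third sequences) are transparent: they
#' neither count toward nor break a run. Each run yields one event:
#' `frameshift_indel` when its length is not a multiple of 3, else
#' `inframe_indel`. `ref_position` is the first reference position of the
#' run (deletions) or of the site immediately after it (insertions), in the
#' map's numbering mode. Adjacent runs separated by >= 1 aligned residue
#' are separate events; no net-frame compensation is applied across events,
#' but the cumulative frame offset is reported in the `frame_offset`
#' attribute so compensated pairs remain visible.
#'
#' @inheritParams detect_premature_stops
#' @return Event data.frame with attribute `frame_offset`
#'   (insertions minus deletions, in nucleotides).
#' @export
detect_indels <- function(aln, map, seq_id) {
  ref <- seq_chars(aln_seq(aln, aln$reference_id))
  qry <- seq_chars(aln_seq(aln, seq_id))
  L <- length(ref)

  # per-column state: 0 aligned, 1 deletion, 2 insertion, 3 transparent
  state <- integer(L)
  state[ref != "-" & qry == "-"] <- 1L
  state[ref == "-" & qry != "-"] <- 2L
  state[ref == "-" & qry == "-"] <- 3L

  ev_kind <- character(); ev_pos <- integer(); ev_len <- integer(); ev_detail <- character()
  run_type <- 0L; run_start <- 0L; run_len <- 0L

  close_run <- function() {
    if (run_type == 0L) return()
    if (run_type == 1L) {
      pos <- column_ref_position(map, run_start, "next")
      tag <- "del"
    } else {
      pos <- column_ref_position(map, run_start, "next")
      tag <- "ins"
    }
    ev_kind <<- c(ev_kind, if (run_len %% 3L != 0L) "frameshift_indel" else "inframe_indel")
    ev_pos <<- c(ev_pos, pos)
    ev_len <<- c(ev_len, run_len)
    ev_detail <<- c(ev_detail, paste0(tag, run_len))
    run_type <<- 0L; run_len <<- 0L
  }

  for (col in seq_len(L)) {
    st <- state[col]
    if (st == 3L) next                      # transparent: both gapped
    if (st == 0L) { close_run(); next }     # aligned residue ends any run
    if (st == run_type) {
      run_len <- run_len + 1L
    } else {
      close_run()
      run_type <- st; run_start <- col; run_len <- 1L
    }
  }
  close_run()

  ev <- disruption_events(seq_id = rep(seq_id, length(ev_kind)), kind = ev_kind,
                          ref_position = ev_pos, length = ev_len, detail = ev_detail)
  ins <- sum(ev$length[startsWith(ev$detail, "ins")])
  del <- sum(ev$length[startsWith(ev$detail, "del")])
  attr(ev, "frame_offset") <- ins - del
  ev
}

#' Specify a conserved sequence motif at fixed codon positions
#'
#' @param codon_indices Reference codon indices carrying the motif.
#' @param residues Required amino-acid letters, parallel to `codon_indices`.
#' @param name Motif name (used in reports).
#' @return Object of class `motif_spec`.
#' @examples
#' # the CC chemokine juxtaposed-cysteine motif at mature-protein 53-54
#' motif_spec(c(53, 54), c("C", "C"), name = "CC")
#' @export
motif_spec <- function(codon_indices, residues, name = "motif") {
  codon_indices <- as.integer(codon_indices)
  residues <- toupper(as.character(residues))
  if (length(codon_indices) != length(residues)) {
    ps_error("codon_indices and residues must have equal length",
             "pseudoscan_model_error")
  }
  structure(list(name = name, codon_indices = codon_indices, residues = residues),
            class = "motif_spec")
}

#' Parse a motif spec string of the form "C@53,C@54"
#'
#' @param spec Comma-separated `RESIDUE@CODON` tokens.
#' @param name Motif name.
#' @return A [motif_spec()].
#' @export
parse_motif_spec <- function(spec, name = "motif") {
  toks <- strsplit(trimws(spec), ",", fixed = TRUE)[[1]]
  m <- regmatches(toks, regexec("^([A-Za-z])@([0-9]+)$", trimws(toks)))
  if (any(vapply(m, length, integer(1)) != 3L)) {
    ps_error(sprintf("cannot parse motif spec '%s' (expected e.g. 'C@53,C@54')", spec),
             "pseudoscan_model_error")
  }
  motif_spec(vapply(m, function(x) as.integer(x[3]), integer(1)),
             vapply(m, `[[`, character(1), 2L), name = name)
}

#' Check a conserved motif in one sequence
#'
#' For each motif position: no event when the translated query codon
#' matches the required residue; `motif_stop_loss` when it is a stop codon
#' (the motif residue replaced by a premature stop); otherwise
#' `motif_substitution` with the observed residue in the detail (gapped or
#' ambiguous codons report detail `"gap"`).
#'
#' @inheritParams detect_premature_stops
#' @param spec A [motif_spec()].
#' @param stop_set Stop codons (default standard code).
#' @return Event data.frame.
#' @export
check_motif <- function(aln, map, seq_id, spec, stop_set = STANDARD_STOPS) {
  if (any(spec$codon_indices < 1L | spec$codon_indices > map$n_codons)) {
    ps_error("motif codon index outside the reference coding length",
             "pseudoscan_range_error")
  }
  out <- disruption_events()
  for (k in seq_along(spec$codon_indices)) {
    idx <- spec$codon_indices[k]
    req <- spec$residues[k]
    nt <- codon_at(map, aln, seq_id, idx)$nucleotides
    if (grepl("[^ACGT]", nt)) {
      out <- rbind(out, disruption_events(seq_id, "motif_substitution", idx, 0L, "gap"))
      next
    }
    if (nt %in% stop_set) {
      out <- rbind(out, disruption_events(seq_id, "motif_stop_loss", idx, 0L,
                                          sprintf("%s%d*", req, idx)))
      next
    }
    aa <- translate_codon(nt)
    if (!identical(aa, req)) {
      out <- rbind(out, disruption_events(seq_id, "motif_substitution", idx, 0L,
                                          sprintf("%s%d%s", req, idx, aa)))
    }
  }
  out
}
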