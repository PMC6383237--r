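# Per-allele and per-species functional verdicts. The verdict logic
# mirrors comparative gene-loss annotation practice: a single premature
# stop, frameshift indel or start loss is sufficient for a pseudogene
# call; loss of a required motif residue to a non-stop amino acid is
# reported as impairment, not proof of pseudogenization; in-frame indels
# alone do not disrupt the frame and leave an allele functional (the event
# stays visible in the report).

#' Classify one allele from its event list
#'
#' Verdicts: `pseudogene` iff the events contain at least one of
#' `premature_stop`, `frameshift_indel`, `start_loss` or `motif_stop_loss`
#' (a stop inside a required motif truncates like any other stop);
#' `impaired_motif` iff only motif substitutions (with or without in-frame
#' indels) are present; `functional` otherwise.
#'
#' @param events Event data.frame for a single sequence
#'   (see [disruption_events()]).
#' @param seq_id,species,allele Sequence metadata; `seq_id` defaults to the
#'   one present in `events` (required when `events` is empty).
#' @return Object of class `gene_status`: list with `seq_id`, `species`,
#'   `allele`, `verdict`, `events`.
#' @export
classify_allele <- function(events, seq_id = NULL, species = "", allele = "") {
  ids <- unique(events$seq_id)
  if (length(ids) > 1L) {
    ps_error(sprintf("events belong to multiple sequences: %s",
                     paste(ids, collapse = ", ")),
             "pseudoscan_consistency_error")
  }
  if (is.null(seq_id)) {
    if (length(ids) == 0L) {
      ps_error("seq_id required when the event list is empty",
               "pseudoscan_consistency_error")
    }
    seq_id <- ids
  } else if (length(ids) == 1L && ids != seq_id) {
    ps_error(sprintf("events belong to '%s', not '%s'", ids, seq_id),
             "pseudoscan_consistency_error")
  }
  verdict <- if (any(events$kind %in% DISRUPTING_KINDS)) {
    "pseudogene"
  } else if (any(events$kind == "motif_substitution")) {
    "impaired_motif"
  } else {
    "functional"
  }
  structure(list(seq_id = seq_id, species = species, allele = allele,
                 verdict = verdict, events = events),
            class = "gene_status")
}

#' @export
print.gene_status <- function(x, ...) {
  cat(sprintf("<gene_status> %s (%s%s): %s, %d event(s)\n",
              x$seq_id, x$species,
              if (nzchar(x$allele)) paste0(" allele ", x$allele) else "",
              x$verdict, nrow(x$events)))
  invisible(x)
}

statuses_to_df <- function(statuses) {
  if (is.data.frame(statuses)) return(statuses)
  do.call(rbind, lapply(statuses, function(s) {
    data.frame(seq_id = s$seq_id, species = s$species, allele = s$allele,
               verdict = s$verdict, n_events = nrow(s$events),
               stringsAsFactors = FALSE)
  }))
}

#' Aggregate allele verdicts into per-species verdicts
#'
#' A species is `functional` if at least one allele is functional (a
#' heterozygote with one intact allele still makes protein), `pseudogene`
#' if every allele is a pseudogene, and `impaired` otherwise (all alleles
#' carry motif impairment and/or disruption, none intact).
#'
#' @param statuses List of [classify_allele()] results, or the `statuses`
#'   data.frame of a [scan_alignment()] result.
#' @return data.frame with one row per species: allele count, verdict
#'   counts and the species verdict.
#' @export
summarize_species <- function(statuses) {
  df <- statuses_to_df(statuses)
  if (is.null(df) || nrow(df) == 0L) {
    ps_error("at least one allele status is required", "pseudoscan_consistency_error")
  }
  out <- do.call(rbind, lapply(split(df, df$species), function(d) {
    n_fun <- sum(d$verdict == "functional")
    n_psg <- sum(d$verdict == "pseudogene")
    n_imp <- sum(d$verdict == "impaired_motif")
    verdict <- if (n_fun >= 1L) "functional" else if (n_psg == nrow(d)) "pseudogene" else "impaired"
    data.frame(species = d$species[1], n_alleles = nrow(d),
               n_functional = n_fun, n_pseudogene = n_psg,
               n_impaired_motif = n_imp, verdict = verdict,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$species), , drop = FALSE]
}

#' Run all detectors on one allele
#'
#' Runs start-loss, premature-stop, indel and (optionally) motif detection
#' and classifies the allele. When a premature stop falls on a motif
#' position it is reported once, as the more specific `motif_stop_loss`.
#'
#' @inheritParams detect_premature_stops
#' @param motif Optional [motif_spec()].
#' @return A `gene_status` whose `events` hold all detected lesions;
#'   attribute `notes` carries skipped-codon and missing-terminal-stop
#'   diagnostics, attribute `frame_offset` the cumulative indel offset.
#' @export
scan_allele <- function(aln, map, seq_id, motif = NULL, stop_set = STANDARD_STOPS) {
  stops <- detect_premature_stops(aln, map, seq_id, stop_set)
  indels <- detect_indels(aln, map, seq_id)
  starts <- detect_start_loss(aln, map, seq_id)
  motifs <- if (!is.null(motif)) check_motif(aln, map, seq_id, motif, stop_set)
            else disruption_events()

  # same lesion, one event: prefer motif_stop_loss over premature_stop
  dup <- stops$ref_position %in% motifs$ref_position[motifs$kind == "motif_stop_loss"]
  events <- rbind(starts, stops[!dup, , drop = FALSE], indels, motifs)
  rownames(events) <- NULL
  attr(events, "skipped") <- NULL
  attr(events, "missing_terminal_stop") <- NULL
  attr(events, "frame_offset") <- NULL

  meta <- aln$meta[aln$meta$id == seq_id, ]
  status <- classify_allele(events, seq_id = seq_id,
                            species = meta$species, allele = meta$allele)
  notes <- character()
  if (length(attr(stops, "skipped"))) {
    notes <- c(notes, sprintf("skipped %d gapped/ambiguous codon(s): %s",
                              length(attr(stops, "skipped")),
                              paste(attr(stops, "skipped"), collapse = ",")))
  }
  if (isTRUE(attr(stops, "missing_terminal_stop"))) {
    notes <- c(notes, "missing terminal stop")
  }
  attr(status, "notes") <- notes
  attr(status, "frame_offset") <- attr(indels, "frame_offset")
  status
}

#' Scan every allele of an alignment and aggregate verdicts
#'
#' The high-level entry point of the disruption scan: builds the
#' coordinate map, scans every non-reference record, classifies each
#' allele and summarizes per species.
#'
#' @param aln A [coding_alignment()].
#' @param motif Optional [motif_spec()] (or a spec string accepted by
#'   [parse_motif_spec()]).
#' @param numbering Coordinate mode, see [build_coordinate_map()].
#' @param stop_set Stop codons to call.
#' @param include Sequence ids to scan (default: all but the reference).
#' @return Object of class `scan_result`: list with `events` (all events),
#'   `statuses` (per-allele data.frame), `species` (per-species verdicts),
#'   `notes` (per-allele diagnostics), `frame_offsets`, and the `map`.
#' @examples
#' aln <- coding_alignment(
#'   c(ref  = "ATGTGCTGCGAGTAA",
#'     psg  = "ATGTGATGCGAGTAA",
#'     ok   = "ATGTGCTGCGAGTAA"), "ref")
#' scan_alignment(aln, motif = "C@2,C@3")
#' @export
scan_alignment <- function(aln, motif = NULL,
                           numbering = c("alignment_columns", "ungapped_reference"),
                           stop_set = STANDARD_STOPS,
                           include = NULL) {
  numbering <- match.arg(numbering)
  if (is.character(motif)) motif <- parse_motif_spec(motif)
  map <- build_coordinate_map(aln, mode = numbering)
  ids <- if (is.null(include)) setdiff(seq_ids(aln), aln$reference_id) else include

  statuses <- lapply(ids, function(id) scan_allele(aln, map, id, motif, stop_set))
  events <- do.call(rbind, c(list(disruption_events()),
                             lapply(statuses, `[[`, "events")))
  rownames(events) <- NULL
  notes <- do.call(rbind, lapply(statuses, function(s) {
    ns <- attr(s, "notes")
    if (length(ns) == 0L) return(NULL)
    data.frame(seq_id = s$seq_id, note = ns, stringsAsFactors = FALSE)
  }))
  if (is.null(notes)) notes <- data.frame(seq_id = character(), note = character())
  offsets <- setNames(vapply(statuses, function(s) attr(s, "frame_offset"), integer(1)), ids)

  structure(
    list(events = events, statuses = statuses_to_df(statuses),
         species = summarize_species(statuses), notes = notes,
         frame_offsets = offsets, map = map, allele_statuses = statuses),
    class = "scan_result"
  )
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result> %d allele(s) scanned, %d event(s)\n",
              nrow(x$statuses), nrow(x$events)))
  cat("\nPer-allele verdicts:\n")
  print(x$statuses, row.names = FALSE)
  cat("\nPer-species verdicts:\n")
  print(x$species, row.names = FALSE)
  if (nrow(x$notes)) {
    cat("\nNotes:\n")
    print(x$notes, row.names = FALSE)
  }
  invisible(x)
}
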