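# Report serialization: a greppable TSV is the primary artifact, with a
# JSON mirror for programmatic use and a per-species summary alongside.

report_columns <- c("seq_id", "species", "allele", "kind", "ref_position",
                    "length", "detail")

#' Write a disruption report (TSV + JSON mirror + species summary)
#'
#' Writes one row per event to `path` (tab-separated; columns `seq_id`,
#' `species`, `allele`, `kind`, `ref_position`, `length`, `detail`), a JSON
#' mirror next to it (`<path minus extension>.json`) and a per-species
#' summary (`<path minus extension>_species.tsv`). The TSV round-trips
#' losslessly through [read_report()].
#'
#' @param events Event data.frame ([disruption_events()] shape). Every
#'   `seq_id` must appear in `statuses`.
#' @param statuses List of `gene_status` objects or the `statuses`
#'   data.frame of a [scan_alignment()] result.
#' @param path Output TSV path.
#' @return Invisibly, the three paths written.
#' @export
write_report <- function(events, statuses, path) {
  sdf <- statuses_to_df(statuses)
  missing_ids <- setdiff(unique(events$seq_id), sdf$seq_id)
  if (length(missing_ids)) {
    ps_error(sprintf("events reference sequence ids absent from statuses: %s",
                     paste(missing_ids, collapse = ", ")),
             "pseudoscan_consistency_error")
  }
  idx <- match(events$seq_id, sdf$seq_id)
  tab <- data.frame(seq_id = events$seq_id,
                    species = sdf$species[idx],
                    allele = sdf$allele[idx],
                    kind = events$kind,
                    ref_position = events$ref_position,
                    length = events$length,
                    detail = events$detail,
                    stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) tab <- tab[0, report_columns, drop = FALSE]

  ok <- tryCatch({
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) {
    ps_error(sprintf("cannot write report to '%s'", path), "pseudoscan_io_error")
  }

  base <- tools::file_path_sans_ext(path)
  json_path <- paste0(base, ".json")
  species_path <- paste0(base, "_species.tsv")
  jsonlite::write_json(list(events = tab, statuses = sdf),
                       json_path, auto_unbox = TRUE, digits = NA)
  write.table(summarize_species(sdf), species_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(c(tsv = path, json = json_path, species = species_path))
}

#' Read a disruption report TSV back into an event table
#'
#' Inverse of [write_report()] on the event collection.
#'
#' @param path Path to a report TSV.
#' @return data.frame with the report columns; `species`/`allele` columns
#'   are carried through, so the [disruption_events()] columns are a
#'   subset.
#' @export
read_report <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(seq_id = "character", species = "character",
                                   allele = "character", kind = "character",
                                   ref_position = "integer", length = "integer",
                                   detail = "character"))
  for (cc in names(tab)) {
    if (is.character(tab[[cc]])) tab[[cc]][is.na(tab[[cc]])] <- ""
  }
  tab
}
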