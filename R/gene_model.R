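# Gene models: exon intervals plus intron sequences, the input to the
# splice-acceptor scan. The on-disk format is a small documented key-value
# config (see read_gene_model) rather than GFF because intron *sequences*
# are part of the model.

#' Construct a gene model
#'
#' @param gene_id Gene identifier.
#' @param exons Two-column matrix (or list of length-2 vectors) of 1-based
#'   closed `(start, end)` exon intervals in gene coordinates, strictly
#'   increasing and non-overlapping.
#' @param introns Character vector of intron nucleotide sequences, ordered;
#'   must have `length(exons) - 1` elements.
#' @param coding_start_offset Non-negative offset of the coding start within
#'   the spliced transcript (0 = translation starts at exon 1 base 1).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, exons, introns = character(), coding_start_offset = 0L) {
  if (is.list(exons)) exons <- do.call(rbind, exons)
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) < 1L || any(exons[, "start"] > exons[, "end"]) || any(exons < 1L)) {
    ps_error("exon intervals must be 1-based with start <= end",
             "pseudoscan_model_error")
  }
  if (nrow(exons) > 1L) {
    if (any(diff(exons[, "start"]) <= 0) ||
        any(exons[-1L, "start"] <= exons[-nrow(exons), "end"])) {
      ps_error("exon intervals must be strictly increasing and non-overlapping",
               "pseudoscan_model_error")
    }
  }
  introns <- toupper(as.character(introns))
  if (length(introns) != nrow(exons) - 1L) {
    ps_error(sprintf("gene model with %d exons requires %d introns, got %d",
                     nrow(exons), nrow(exons) - 1L, length(introns)),
             "pseudoscan_model_error")
  }
  if (coding_start_offset < 0L) {
    ps_error("coding_start_offset must be non-negative", "pseudoscan_model_error")
  }
  structure(
    list(gene_id = gene_id, exons = exons, introns = introns,
         coding_start_offset = as.integer(coding_start_offset)),
    class = "gene_model"
  )
}

#' Read a gene model from a plain-text config file
#'
#' Format: one `key value` pair per line, `#` comments allowed. Keys:
#' \describe{
#'   \item{`gene_id <string>`}{required, once}
#'   \item{`exon <start> <end>`}{one line per exon, in order}
#'   \item{`intron <sequence>`}{one line per intron, in order}
#'   \item{`coding_start_offset <int>`}{optional, default 0}
#' }
#'
#' @param path Path to the config file.
#' @return A [gene_model()].
#' @export
read_gene_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "[[:space:]]+")
  key <- vapply(toks, `[[`, character(1), 1L)

  get1 <- function(k, default = NULL) {
    hit <- which(key == k)
    if (length(hit) == 0L) {
      if (is.null(default)) ps_error(sprintf("gene model config missing '%s'", k),
                                     "pseudoscan_model_error")
      return(default)
    }
    toks[[hit[1]]][2L]
  }
  exon_rows <- toks[key == "exon"]
  if (length(exon_rows) == 0L) {
    ps_error("gene model config has no 'exon' lines", "pseudoscan_model_error")
  }
  exons <- t(vapply(exon_rows, function(t) as.integer(t[2:3]), integer(2)))
  introns <- vapply(toks[key == "intron"], `[[`, character(1), 2L)
  gene_model(
    gene_id = get1("gene_id"),
    exons = exons,
    introns = introns,
    coding_start_offset = as.integer(get1("coding_start_offset", "0"))
  )
}

#' Write a gene model config
#'
#' Inverse of [read_gene_model()].
#'
#' @param model A [gene_model()].
#' @param path Output path.
#' @export
write_gene_model <- function(model, path) {
  lines <- c(
    paste("gene_id", model$gene_id),
    paste("coding_start_offset", model$coding_start_offset),
    sprintf("exon %d %d", model$exons[, "start"], model$exons[, "end"]),
    if (length(model$introns)) paste("intron", model$introns)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s: %d exons, %d introns (intron lengths: %s)\n",
              x$gene_id, nrow(x$exons), length(x$introns),
              paste(nchar(x$introns), collapse = ", ")))
  invisible(x)
}
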