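# Tajima's relative-rate test. For two ingroup lineages A and B and an
# outgroup O, sites where exactly one ingroup lineage differs from the
# other two are informative: under equal rates the unique-difference
# counts nA and nB have equal expectation, and
#     chi^2 = (nA - nB)^2 / (nA + nB)
# is approximately chi-square distributed with 1 degree of freedom.
# No continuity correction is applied (the plain statistic).

#' Classify alignment columns of a sequence triple
#'
#' Under complete deletion every column containing a gap or IUPAC
#' ambiguity code in any of the three sequences is excluded; the remaining
#' columns fall into exactly one of five categories: identical in all
#' three, unique to A (`a != b`, `b == o`), unique to B (`b != a`,
#' `a == o`), unique to the outgroup (`o != a`, `a == b`), or all three
#' distinct.
#'
#' @param a,b,outgroup Equal-length aligned sequences: character strings
#'   or single-character vectors.
#' @param deletion_policy `"complete"` or `"pairwise-complete"`. For a
#'   single triple the two coincide (all three bases are needed to
#'   classify a site); they differ in [batch_rrt()], where `"complete"`
#'   masks columns across the whole batch.
#' @return Object of class `site_counts`: `n_sites_used`, `n_unique_a`,
#'   `n_unique_b`, `n_unique_o`, `n_all_different`, `n_identical`.
#' @examples
#' classify_sites("AAAA", "AAAT", "AAAA")  # one site unique to B
#' @export
classify_sites <- function(a, b, outgroup,
                           deletion_policy = c("complete", "pairwise-complete")) {
  deletion_policy <- match.arg(deletion_policy)
  ca <- as_char_vector(a); cb <- as_char_vector(b); co <- as_char_vector(outgroup)
  if (length(ca) != length(cb) || length(cb) != length(co)) {
    ps_error(sprintf("sequences differ in length: %d, %d, %d",
                     length(ca), length(cb), length(co)),
             "pseudoscan_alignment_shape_error")
  }
  keep <- ca %in% DNA_BASES & cb %in% DNA_BASES & co %in% DNA_BASES
  ca <- ca[keep]; cb <- cb[keep]; co <- co[keep]

  ab <- ca == cb; ao <- ca == co; bo <- cb == co
  counts <- list(
    n_sites_used = sum(keep),
    n_unique_a = sum(!ab & bo),
    n_unique_b = sum(!ab & ao),
    n_unique_o = sum(ab & !ao),
    n_all_different = sum(!ab & !ao & !bo),
    n_identical = sum(ab & ao)
  )
  structure(counts, class = "site_counts")
}

as_char_vector <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) x <- seq_chars(x)
  toupper(as.character(x))
}

#' @export
print.site_counts <- function(x, ...) {
  cat(sprintf(paste0("<site_counts> %d sites used: %d identical, ",
                     "%d unique to A, %d unique to B, %d unique to outgroup, ",
                     "%d all different\n"),
              x$n_sites_used, x$n_identical, x$n_unique_a, x$n_unique_b,
              x$n_unique_o, x$n_all_different))
  invisible(x)
}

#' Upper-tail probability of the chi-square distribution
#'
#' @param x Non-negative quantile.
#' @param df Degrees of freedom (default 1).
#' @return `P(X >= x)` for `X ~ chi-square(df)`.
#' @export
chi2_survival <- function(x, df = 1L) {
  if (any(x < 0)) ps_error("chi-square quantile must be non-negative",
                           "pseudoscan_range_error")
  pchisq(x, df = df, lower.tail = FALSE)
}

#' Tajima's relative-rate test from unique-difference counts
#'
#' @param n_unique_a,n_unique_b Numbers of sites where lineage A
#'   (respectively B) differs while the other ingroup lineage matches the
#'   outgroup. Their sum must be positive.
#' @param counts Optional [classify_sites()] result to attach.
#' @param labels Optional named character vector (`taxon_a`, `taxon_b`,
#'   `outgroup`) for reporting.
#' @return Object of class `rrt_result`: `chi_square`,
#'   `degrees_of_freedom` (1), `p_value`, `n_unique_a`, `n_unique_b`, plus
#'   any `counts`/`labels` supplied. Full precision is kept; rounding to
#'   the conventional 2 decimals happens only in the print method.
#' @examples
#' tajima_rrt(11, 69)   # chi-square 42.05, p < 0.01
#' tajima_rrt(18, 10)   # chi-square 2.29, p 0.13
#' @export
tajima_rrt <- function(n_unique_a, n_unique_b, counts = NULL, labels = NULL) {
  nA <- n_unique_a; nB <- n_unique_b
  if (nA < 0 || nB < 0) {
    ps_error("unique-difference counts must be non-negative", "pseudoscan_range_error")
  }
  if (nA + nB == 0) {
    ps_error("test undefined: no unique differences in either lineage (nA + nB == 0)",
             "pseudoscan_undefined_test_error")
  }
  chi2 <- (nA - nB)^2 / (nA + nB)
  structure(
    list(chi_square = chi2, degrees_of_freedom = 1L,
         p_value = chi2_survival(chi2, 1L),
         n_unique_a = nA, n_unique_b = nB,
         counts = counts, labels = labels),
    class = "rrt_result"
  )
}

#' @export
print.rrt_result <- function(x, ...) {
  lab <- if (!is.null(x$labels)) {
    sprintf(" [%s vs %s, outgroup %s]", x$labels[["taxon_a"]],
            x$labels[["taxon_b"]], x$labels[["outgroup"]])
  } else ""
  cat(sprintf("<rrt_result>%s nA = %d, nB = %d, chi-square = %.2f (1 df), p = %s\n",
              lab, x$n_unique_a, x$n_unique_b, x$chi_square,
              if (x$p_value < 0.01) "< 0.01" else sprintf("%.2f", x$p_value)))
  invisible(x)
}

#' Relative-rate test for one triple taken from an alignment
#'
#' @param aln A [coding_alignment()] (or any named list of equal-length
#'   sequences).
#' @param taxon_a,taxon_b,outgroup Sequence ids.
#' @param deletion_policy See [classify_sites()].
#' @return An `rrt_result`.
#' @export
rrt_test <- function(aln, taxon_a, taxon_b, outgroup,
                     deletion_policy = c("complete", "pairwise-complete")) {
  deletion_policy <- match.arg(deletion_policy)
  counts <- classify_sites(aln_seq(aln, taxon_a), aln_seq(aln, taxon_b),
                           aln_seq(aln, outgroup), deletion_policy)
  tajima_rrt(counts$n_unique_a, counts$n_unique_b, counts = counts,
             labels = c(taxon_a = taxon_a, taxon_b = taxon_b, outgroup = outgroup))
}

#' Batch relative-rate tests against a fixed comparator
#'
#' Runs [classify_sites()] + [tajima_rrt()] for one fixed taxon A against
#' each taxon B, with a common outgroup. Under `"complete"` deletion the
#' excluded columns are those gapped or ambiguous in *any* sequence
#' involved in the batch (taxon A, outgroup, or any taxon B), so every row
#' uses the same site set; `"pairwise-complete"` masks per triple.
#'
#' @param aln A [coding_alignment()].
#' @param taxon_a Fixed comparator id.
#' @param taxon_b_list Character vector of taxon B ids.
#' @param outgroup Outgroup id.
#' @param deletion_policy `"complete"` (default) or `"pairwise-complete"`.
#' @return data.frame with one row per taxon B: ids, `n_sites_used`,
#'   `n_unique_a`, `n_unique_b`, `chi_square`, `p_value`.
#' @export
batch_rrt <- function(aln, taxon_a, taxon_b_list, outgroup,
                      deletion_policy = c("complete", "pairwise-complete")) {
  deletion_policy <- match.arg(deletion_policy)
  ids <- c(taxon_a, taxon_b_list, outgroup)
  for (id in ids) aln_seq(aln, id)   # missing-sequence error names the id
  if (length(taxon_b_list) == 0L) {
    return(data.frame(taxon_a = character(), taxon_b = character(),
                      outgroup = character(), n_sites_used = integer(),
                      n_unique_a = integer(), n_unique_b = integer(),
                      chi_square = numeric(), p_value = numeric()))
  }

  seqs <- lapply(setNames(ids, ids), function(id) as_char_vector(aln_seq(aln, id)))
  if (deletion_policy == "complete") {
    valid <- Reduce(`&`, lapply(seqs, function(s) s %in% DNA_BASES))
    seqs <- lapply(seqs, function(s) s[valid])
  }
  out <- lapply(taxon_b_list, function(b) {
    counts <- classify_sites(seqs[[taxon_a]], seqs[[b]], seqs[[outgroup]])
    res <- tajima_rrt(counts$n_unique_a, counts$n_unique_b, counts = counts,
                      labels = c(taxon_a = taxon_a, taxon_b = b, outgroup = outgroup))
    data.frame(taxon_a = taxon_a, taxon_b = b, outgroup = outgroup,
               n_sites_used = counts$n_sites_used,
               n_unique_a = counts$n_unique_a, n_unique_b = counts$n_unique_b,
               chi_square = res$chi_square, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
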