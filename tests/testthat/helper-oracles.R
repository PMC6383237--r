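# Independent brute-force implementations used as oracles. These are
# deliberately naive (per-column loops, no shared code with the package
# internals) so that agreement with the package is informative.

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Naive per-column classification of a sequence triple.
oracle_classify_sites <- function(a, b, o) {
  ca <- chars(toupper(a)); cb <- chars(toupper(b)); co <- chars(toupper(o))
  counts <- c(n_sites_used = 0L, n_unique_a = 0L, n_unique_b = 0L,
              n_unique_o = 0L, n_all_different = 0L, n_identical = 0L)
  for (i in seq_along(ca)) {
    trio <- c(ca[i], cb[i], co[i])
    if (!all(trio %in% c("A", "C", "G", "T"))) next
    counts["n_sites_used"] <- counts["n_sites_used"] + 1L
    if (trio[1] == trio[2] && trio[2] == trio[3]) {
      counts["n_identical"] <- counts["n_identical"] + 1L
    } else if (trio[1] != trio[2] && trio[2] == trio[3]) {
      counts["n_unique_a"] <- counts["n_unique_a"] + 1L
    } else if (trio[2] != trio[1] && trio[1] == trio[3]) {
      counts["n_unique_b"] <- counts["n_unique_b"] + 1L
    } else if (trio[3] != trio[1] && trio[1] == trio[2]) {
      counts["n_unique_o"] <- counts["n_unique_o"] + 1L
    } else {
      counts["n_all_different"] <- counts["n_all_different"] + 1L
    }
  }
  as.list(counts)
}

# Column-walk extraction of the codon of `seq_id` under reference codon k:
# walk reference columns, counting non-gap reference bases; the codon's
# columns are those carrying reference coding bases 3k-2, 3k-1, 3k.
oracle_codon_at <- function(aln, seq_id, k) {
  ref <- chars(aln$seqs[[aln$reference_id]])
  qry <- chars(aln$seqs[[seq_id]])
  want <- c(3L * k - 2L, 3L * k - 1L, 3L * k)
  got <- character(0)
  n_ref <- 0L
  for (col in seq_along(ref)) {
    if (ref[col] != "-") {
      n_ref <- n_ref + 1L
      if (n_ref %in% want) got <- c(got, qry[col])
    }
  }
  paste(got, collapse = "")
}

# Naive premature-stop scan: every complete query codon under reference
# codons 1..(n-1) that is a stop.
oracle_premature_stops <- function(aln, seq_id, stop_set = c("TAA", "TAG", "TGA")) {
  ref_ungapped <- gsub("-", "", aln$seqs[[aln$reference_id]], fixed = TRUE)
  n <- nchar(ref_ungapped) %/% 3L
  hits <- data.frame(ref_position = integer(), detail = character())
  for (k in seq_len(n - 1L)) {
    cd <- oracle_codon_at(aln, seq_id, k)
    if (grepl("[^ACGT]", cd)) next
    if (cd %in% stop_set) {
      ref_cd <- oracle_codon_at(aln, aln$reference_id, k)
      hits <- rbind(hits, data.frame(ref_position = k,
                                     detail = paste0(ref_cd, ">", cd)))
    }
  }
  hits
}

# Naive indel-run scan in ungapped-reference coordinates. Columns gapped
# in both sequences are transparent (skipped entirely); runs are maximal
# stretches of deletion (query gap over reference base) or insertion
# (query base over reference gap) states.
oracle_indels <- function(aln, seq_id) {
  ref <- chars(aln$seqs[[aln$reference_id]])
  qry <- chars(aln$seqs[[seq_id]])
  runs <- data.frame(kind = character(), ref_position = integer(),
                     length = integer(), op = character())
  cur_op <- ""; cur_len <- 0L; cur_pos <- 0L
  n_ref <- 0L
  flush <- function() {
    if (cur_op == "") return()
    kind <- if (cur_len %% 3L != 0L) "frameshift_indel" else "inframe_indel"
    runs <<- rbind(runs, data.frame(kind = kind, ref_position = cur_pos,
                                    length = cur_len, op = cur_op))
    cur_op <<- ""; cur_len <<- 0L
  }
  for (col in seq_along(ref)) {
    r_gap <- ref[col] == "-"; q_gap <- qry[col] == "-"
    if (!r_gap) n_ref_next <- n_ref + 1L else n_ref_next <- n_ref
    if (r_gap && q_gap) { n_ref <- n_ref_next; next }
    op <- if (!r_gap && q_gap) "del" else if (r_gap && !q_gap) "ins" else ""
    if (op == "") {
      flush()
    } else if (op == cur_op) {
      cur_len <- cur_len + 1L
    } else {
      flush()
      cur_op <- op
      cur_len <- 1L
      cur_pos <- if (op == "del") n_ref_next else n_ref + 1L
    }
    n_ref <- n_ref_next
  }
  flush()
  runs
}

# Exhaustive motif-occurrence scan of an intron for the acceptor search.
oracle_acceptor_offsets <- function(intron, window, motif = "AG",
                                    side = "intron_terminal") {
  L <- nchar(intron)
  w <- nchar(motif)
  offsets <- integer()
  for (p in seq_len(L - w + 1L)) {
    if (substr(intron, p, p + w - 1L) != motif) next
    last_used <- if (side == "intron_terminal") p + w - 1L else p - 1L
    if (last_used < 1L) next
    off <- L - last_used
    if (off >= 1L && off <= window) offsets <- c(offsets, off)
  }
  sort(unique(c(0L, offsets)))
}
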