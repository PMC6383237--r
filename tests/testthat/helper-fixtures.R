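# Programmatic fixtures: everything is generated in code at test time.

SENSE_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

# A clean coding sequence: ATG, sense codons, terminal TAA.
make_cds <- function(n_codons, motif_at = NULL, motif_codon = "TGC") {
  codons <- c("ATG", sample(SENSE_CODONS, n_codons - 2L, replace = TRUE), "TAA")
  if (!is.null(motif_at)) codons[motif_at] <- motif_codon
  paste(codons, collapse = "")
}

# Reference plus queries carrying random substitutions, deletions (query
# gap runs) and insertions (columns where the reference and the other
# queries are gapped). Returns a coding_alignment.
random_alignment <- function(n_codons = 12L, n_queries = 2L, p_sub = 0.05,
                             max_dels = 2L, max_ins = 1L, max_indel_len = 7L) {
  ref <- chars(make_cds(n_codons))
  L <- length(ref)
  rows <- list(ref = ref)
  for (q in seq_len(n_queries)) {
    s <- ref
    hit <- which(runif(L) < p_sub)
    if (length(hit)) s[hit] <- sample(c("A", "C", "G", "T"), length(hit), TRUE)
    for (d in seq_len(sample(0:max_dels, 1))) {
      len <- sample.int(max_indel_len, 1)
      start <- sample.int(L - len + 1L, 1)
      s[start:(start + len - 1L)] <- "-"
    }
    rows[[paste0("q", q)]] <- s
  }
  # insertions: each owned by one query, placed after a reference column
  n_ins <- if (max_ins > 0 && n_queries > 0) sample(0:max_ins, 1) else 0L
  if (n_ins > 0L) {
    ins <- data.frame(owner = sample(n_queries, n_ins, replace = TRUE),
                      after = sample(0:L, n_ins, replace = TRUE),
                      len = sample.int(max_indel_len, n_ins, replace = TRUE))
    ins <- ins[order(ins$after), , drop = FALSE]
    out <- lapply(rows, function(x) character(0))
    emit <- function(colset) for (nm in names(rows)) out[[nm]] <<- c(out[[nm]], colset[[nm]])
    for (col in 0:L) {
      if (col > 0L) emit(lapply(rows, `[`, col))
      for (j in which(ins$after == col)) {
        block <- lapply(rows, function(x) rep("-", ins$len[j]))
        block[[paste0("q", ins$owner[j])]] <-
          sample(c("A", "C", "G", "T"), ins$len[j], TRUE)
        emit(block)
      }
    }
    rows <- out
  }
  seqs <- vapply(rows, paste, character(1), collapse = "")
  coding_alignment(seqs, "ref", check_reference_orf = FALSE)
}

# Build an alignment where `query_codons[k]` replaces the reference codon
# at index k (list names are codon indices), for worked-example fixtures.
alignment_with_codons <- function(n_codons, query_codons,
                                  motif_at = NULL, motif_codon = "TGC") {
  ref <- make_cds(n_codons, motif_at = motif_at, motif_codon = motif_codon)
  qry <- chars(ref)
  for (k in names(query_codons)) {
    i <- as.integer(k)
    qry[(3L * i - 2L):(3L * i)] <- chars(query_codons[[k]])
  }
  coding_alignment(c(ref = ref, query = paste(qry, collapse = "")), "ref")
}

# Delete `len` query bases starting at reference position `start`.
alignment_with_deletion <- function(n_codons, start, len) {
  ref <- make_cds(n_codons)
  qry <- chars(ref)
  qry[start:(start + len - 1L)] <- "-"
  coding_alignment(c(ref = ref, query = paste(qry, collapse = "")), "ref")
}

# Insert `len` query bases after reference position `after`.
alignment_with_insertion <- function(n_codons, after, len) {
  ref <- chars(make_cds(n_codons))
  ins <- sample(c("A", "C", "G", "T"), len, TRUE)
  ref_row <- c(ref[seq_len(after)], rep("-", len), ref[-seq_len(after)])
  qry_row <- c(ref[seq_len(after)], ins, ref[-seq_len(after)])
  coding_alignment(c(ref = paste(ref_row, collapse = ""),
                     query = paste(qry_row, collapse = "")), "ref")
}

write_temp_fasta <- function(seqs, path = withr::local_tempfile(fileext = ".fasta",
                                                                .local_envir = parent.frame())) {
  lines <- character(0)
  for (nm in names(seqs)) lines <- c(lines, paste0(">", nm), seqs[[nm]])
  writeLines(lines, path)
  path
}
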