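test_that("aligned FASTA is read with normalized case and parsed allele labels", {
  set.seed(11)
  cds <- tolower(make_cds(20))
  path <- write_temp_fasta(c("O_cuniculus" = cds, "O_hoffmanni*2" = cds,
                             "ref" = cds))
  aln <- read_alignment(path, "ref")
  expect_s3_class(aln, "coding_alignment")
  expect_equal(aln$alignment_length, 60L)
  expect_equal(aln$seqs[["O_cuniculus"]], toupper(cds))

  m <- aln$meta
  expect_equal(m$species[m$id == "O_hoffmanni*2"], "O_hoffmanni")
  expect_equal(m$allele[m$id == "O_hoffmanni*2"], "2")
  expect_equal(m$species[m$id == "O_cuniculus"], "O_cuniculus")
  expect_equal(m$allele[m$id == "O_cuniculus"], "")

  # idempotent under case normalization: re-reading what we write changes nothing
  out <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(aln, out)
  expect_equal(read_alignment(out, "ref")$seqs, aln$seqs)
})

test_that("malformed alignments raise classed errors naming the problem", {
  set.seed(12)
  cds <- make_cds(10)
  path <- write_temp_fasta(c(a = cds, b = substr(cds, 1, nchar(cds) - 1L),
                             ref = cds))
  expect_error(read_alignment(path, "ref"),
               class = "pseudoscan_alignment_shape_error")

  path2 <- write_temp_fasta(c(a = cds, ref = cds))
  expect_error(read_alignment(path2, "nope"),
               class = "pseudoscan_missing_reference_error")

  bad <- cds
  substr(bad, 7, 7) <- "J"
  path3 <- write_temp_fasta(c(a = bad, ref = cds))
  err <- expect_error(read_alignment(path3, "ref"),
                      class = "pseudoscan_alphabet_error")
  expect_match(conditionMessage(err), "'a'")
  expect_match(conditionMessage(err), "column 7")

  # IUPAC ambiguity codes pass through untouched
  amb <- cds
  substr(amb, 7, 7) <- "R"
  path4 <- write_temp_fasta(c(a = amb, ref = cds))
  expect_equal(substr(read_alignment(path4, "ref")$seqs[["a"]], 7, 7), "R")
})

test_that("the reference must be an open reading frame ending in a stop", {
  set.seed(13)
  cds <- make_cds(10)
  no_stop <- paste0(substr(cds, 1, 27), "AAA")
  expect_error(coding_alignment(c(ref = no_stop), "ref"),
               class = "pseudoscan_reference_orf_error")
  internal <- paste0(substr(cds, 1, 12), "TGA", substr(cds, 16, 30))
  expect_error(coding_alignment(c(ref = internal), "ref"),
               class = "pseudoscan_reference_orf_error")
  expect_silent(coding_alignment(c(ref = no_stop), "ref",
                                 check_reference_orf = FALSE))
})

test_that("gene model configs parse and enforce exon/intron consistency", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# three exons, two introns",
               "gene_id CCL16",
               "exon 1 90",
               "exon 91 200",
               "exon 201 320",
               "intron GTAAGTCCCTTTAG",
               "intron GTTTGTAACCAG"), path)
  gm <- read_gene_model(path)
  expect_s3_class(gm, "gene_model")
  expect_equal(nrow(gm$exons), 3L)
  expect_equal(length(gm$introns), 2L)

  expect_error(gene_model("g", rbind(c(1, 90), c(91, 200), c(201, 320)),
                          introns = "GTAG"),
               class = "pseudoscan_model_error")
  expect_error(gene_model("g", rbind(c(1, 90), c(50, 200)), introns = "GTAG"),
               class = "pseudoscan_model_error")

  # write/read round trip
  out <- withr::local_tempfile(fileext = ".txt")
  write_gene_model(gm, out)
  expect_equal(read_gene_model(out), gm)
})

test_that("disruption reports round-trip losslessly through TSV", {
  set.seed(14)
  aln <- alignment_with_codons(60, list(`53` = "TGA"), motif_at = 53)
  res <- scan_alignment(aln)
  expect_equal(res$events$kind, "premature_stop")
  expect_equal(res$events$ref_position, 53L)

  dir <- withr::local_tempdir()
  path <- file.path(dir, "events.tsv")
  paths <- write_report(res$events, res$statuses, path)
  expect_true(all(file.exists(paths)))

  back <- read_report(path)
  expect_equal(back[, names(res$events)], res$events)

  # empty event list: header-only TSV that still round-trips
  empty <- disruption_events()
  path2 <- file.path(dir, "empty.tsv")
  write_report(empty, res$statuses, path2)
  expect_length(readLines(path2), 1L)
  expect_equal(nrow(read_report(path2)), 0L)

  # events naming a sequence absent from the statuses are rejected
  rogue <- disruption_events("ghost", "premature_stop", 5L, 0L, "TGC>TGA")
  expect_error(write_report(rogue, res$statuses, file.path(dir, "x.tsv")),
               class = "pseudoscan_consistency_error")
})
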