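test_that("premature stops are called with reference-anchored codon positions", {
  set.seed(31)
  # TGC -> TGA in the CC motif position, as in the leporid lesion
  aln <- alignment_with_codons(60, list(`53` = "TGA"), motif_at = 53)
  map <- build_coordinate_map(aln)
  ev <- detect_premature_stops(aln, map, "query")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "premature_stop")
  expect_equal(ev$ref_position, 53L)
  expect_equal(ev$detail, "TGC>TGA")

  # GAG (Glu) -> TAG, the pygmy-rabbit style lesion
  aln2 <- alignment_with_codons(40, list(`20` = "TAG"),
                                motif_at = 20, motif_codon = "GAG")
  ev2 <- detect_premature_stops(aln2, build_coordinate_map(aln2), "query")
  expect_equal(ev2$detail, "GAG>TAG")
  expect_equal(ev2$ref_position, 20L)

  # identity: no events of any kind
  aln3 <- alignment_with_codons(30, list())
  map3 <- build_coordinate_map(aln3)
  expect_equal(nrow(detect_premature_stops(aln3, map3, "query")), 0L)
  expect_equal(nrow(detect_indels(aln3, map3, "query")), 0L)
  expect_equal(nrow(detect_start_loss(aln3, map3, "query")), 0L)
})

test_that("gapped or ambiguous codons are skipped and logged, never called", {
  set.seed(32)
  aln <- alignment_with_codons(20, list(`5` = "T-A", `9` = "TRA", `12` = "TGA"))
  ev <- detect_premature_stops(aln, build_coordinate_map(aln), "query")
  expect_equal(ev$ref_position, 12L)
  expect_setequal(attr(ev, "skipped"), c(5L, 9L))
})

test_that("the terminal stop is exempt and its absence is noted", {
  set.seed(33)
  aln <- alignment_with_codons(20, list(`20` = "AAA"))  # terminal TAA mutated away
  ev <- detect_premature_stops(aln, build_coordinate_map(aln), "query")
  expect_equal(nrow(ev), 0L)
  expect_true(attr(ev, "missing_terminal_stop"))

  status <- scan_allele(aln, build_coordinate_map(aln), "query")
  expect_true("missing terminal stop" %in% attr(status, "notes"))
})

test_that("start-codon loss is detected when the reference starts with ATG", {
  set.seed(34)
  aln <- alignment_with_codons(15, list(`1` = "ACG"))
  ev <- detect_start_loss(aln, build_coordinate_map(aln), "query")
  expect_equal(ev$kind, "start_loss")
  expect_equal(ev$detail, "ATG>ACG")
  st <- classify_allele(ev)
  expect_equal(st$verdict, "pseudogene")
})

test_that("indel runs classify by length modulo 3 at the first affected position", {
  set.seed(35)
  cases <- list(list(len = 16L, kind = "frameshift_indel"),
                list(len = 19L, kind = "frameshift_indel"),
                list(len = 20L, kind = "frameshift_indel"),
                list(len = 3L, kind = "inframe_indel"),
                list(len = 21L, kind = "inframe_indel"),
                list(len = 24L, kind = "inframe_indel"))
  for (cs in cases) {
    aln <- alignment_with_deletion(30, start = 10L, len = cs$len)
    ev <- detect_indels(aln, build_coordinate_map(aln), "query")
    expect_equal(ev$kind, cs$kind, info = paste("deletion len", cs$len))
    expect_equal(ev$ref_position, 10L)
    expect_equal(ev$length, cs$len)
    expect_equal(ev$detail, paste0("del", cs$len))

    aln_i <- alignment_with_insertion(30, after = 12L, len = cs$len)
    ev_i <- detect_indels(aln_i, build_coordinate_map(aln_i, "ungapped_reference"),
                          "query")
    expect_equal(ev_i$kind, cs$kind, info = paste("insertion len", cs$len))
    expect_equal(ev_i$ref_position, 13L)
    expect_equal(ev_i$length, cs$len)
  }
})

test_that("indel lengths sum to the ungapped length difference", {
  set.seed(36)
  for (rep in 1:20) {
    aln <- random_alignment(n_codons = 15, n_queries = 2, p_sub = 0.05,
                            max_dels = 3, max_ins = 2)
    map <- build_coordinate_map(aln)
    for (id in setdiff(aln$meta$id, "ref")) {
      ev <- detect_indels(aln, map, id)
      ungapped <- function(s) nchar(gsub("-", "", s, fixed = TRUE))
      diff <- ungapped(aln$seqs[[id]]) - ungapped(aln$seqs[["ref"]])
      expect_equal(attr(ev, "frame_offset"), diff)
      ins <- sum(ev$length[startsWith(ev$detail, "ins")])
      del <- sum(ev$length[startsWith(ev$detail, "del")])
      expect_equal(ins - del, diff)
    }
  }
})

test_that("motif checks distinguish stop loss, substitution and intact sites", {
  set.seed(37)
  cc <- motif_spec(c(53, 54), c("C", "C"), name = "CC")

  aln <- alignment_with_codons(60, list(`53` = "TGA"), motif_at = 53:54)
  ev <- check_motif(aln, build_coordinate_map(aln), "query", cc)
  expect_equal(ev$kind, "motif_stop_loss")
  expect_equal(ev$detail, "C53*")

  aln2 <- alignment_with_codons(60, list(`53` = "AAA"), motif_at = 53:54)
  ev2 <- check_motif(aln2, build_coordinate_map(aln2), "query", cc)
  expect_equal(ev2$kind, "motif_substitution")
  expect_equal(ev2$detail, "C53K")

  aln3 <- alignment_with_codons(60, list(), motif_at = 53:54)
  expect_equal(nrow(check_motif(aln3, build_coordinate_map(aln3), "query", cc)), 0L)

  aln4 <- alignment_with_codons(60, list(`53` = "T-A"), motif_at = 53:54)
  ev4 <- check_motif(aln4, build_coordinate_map(aln4), "query", cc)
  expect_equal(ev4$detail, "gap")

  expect_equal(parse_motif_spec("C@53,C@54")$codon_indices, c(53L, 54L))
  expect_error(parse_motif_spec("C53"), class = "pseudoscan_model_error")
})

test_that("allele verdicts follow the disrupting-event rule exactly", {
  mk <- function(...) disruption_events(seq_id = "x", ...)
  expect_equal(classify_allele(mk(kind = "premature_stop", ref_position = 53,
                                  length = 0, detail = "TGC>TGA"))$verdict,
               "pseudogene")
  expect_equal(classify_allele(disruption_events(), seq_id = "x")$verdict,
               "functional")
  expect_equal(classify_allele(mk(kind = "motif_substitution", ref_position = 53,
                                  length = 0, detail = "C53K"))$verdict,
               "impaired_motif")
  expect_equal(classify_allele(mk(kind = "inframe_indel", ref_position = 343,
                                  length = 24, detail = "ins24"))$verdict,
               "functional")
  expect_equal(classify_allele(mk(kind = "motif_stop_loss", ref_position = 53,
                                  length = 0, detail = "C53*"))$verdict,
               "pseudogene")

  mixed <- rbind(mk(kind = "premature_stop", ref_position = 5, length = 0,
                    detail = "TGC>TGA"),
                 disruption_events("y", "inframe_indel", 9L, 3L, "del3"))
  expect_error(classify_allele(mixed), class = "pseudoscan_consistency_error")

  # property: verdict is pseudogene iff a disrupting kind is present
  set.seed(38)
  kinds <- c("premature_stop", "frameshift_indel", "inframe_indel",
             "motif_substitution", "motif_stop_loss", "start_loss")
  disrupting <- c("premature_stop", "frameshift_indel", "start_loss",
                  "motif_stop_loss")
  for (i in 1:30) {
    ks <- sample(kinds, sample(0:4, 1), replace = TRUE)
    lens <- ifelse(ks == "frameshift_indel", 4L,
                   ifelse(ks == "inframe_indel", 6L, 0L))
    ev <- disruption_events(rep("x", length(ks)), ks,
                            seq_along(ks), lens, rep("d", length(ks)))
    v <- classify_allele(ev, seq_id = "x")$verdict
    expect_equal(v == "pseudogene", any(ks %in% disrupting))
    if (!any(ks %in% disrupting)) {
      expect_equal(v == "impaired_motif", any(ks == "motif_substitution"))
    }
  }
})

test_that("species summaries aggregate allele verdicts as a diploid would", {
  mk_status <- function(id, species, allele, verdict) {
    ev <- if (verdict == "pseudogene") {
      disruption_events(id, "premature_stop", 53L, 0L, "TGC>TGA")
    } else if (verdict == "impaired_motif") {
      disruption_events(id, "motif_substitution", 53L, 0L, "C53K")
    } else disruption_events()
    classify_allele(ev, seq_id = id, species = species, allele = allele)
  }
  statuses <- list(
    mk_status("hoff*1", "hoff", "1", "functional"),
    mk_status("hoff*2", "hoff", "2", "pseudogene"),
    mk_status("rabbit", "rabbit", "", "pseudogene"),
    mk_status("cotton*1", "cotton", "1", "pseudogene"),
    mk_status("cotton*2", "cotton", "2", "impaired_motif"))
  tab <- summarize_species(statuses)
  expect_equal(tab$verdict[tab$species == "hoff"], "functional")
  expect_equal(tab$n_alleles[tab$species == "hoff"], 2L)
  expect_equal(tab$verdict[tab$species == "rabbit"], "pseudogene")
  expect_equal(tab$verdict[tab$species == "cotton"], "impaired")
  expect_error(summarize_species(list()), class = "pseudoscan_consistency_error")
})

test_that("a stop inside the motif is reported once, as motif_stop_loss", {
  set.seed(39)
  aln <- alignment_with_codons(60, list(`53` = "TGA"), motif_at = 53:54)
  res <- scan_alignment(aln, motif = "C@53,C@54")
  at53 <- res$events[res$events$ref_position == 53, ]
  expect_equal(nrow(at53), 1L)
  expect_equal(at53$kind, "motif_stop_loss")
  expect_equal(res$statuses$verdict, "pseudogene")
})

test_that("full scans match the brute-force per-codon/per-column oracle", {
  set.seed(40)
  for (rep in 1:40) {
    aln <- random_alignment(n_codons = sample(8:25, 1), n_queries = 2,
                            p_sub = 0.08, max_dels = 2, max_ins = 1)
    map <- build_coordinate_map(aln, "ungapped_reference")
    for (id in setdiff(aln$meta$id, "ref")) {
      got <- detect_premature_stops(aln, map, id)
      want <- oracle_premature_stops(aln, id)
      expect_equal(got$ref_position, want$ref_position)
      expect_equal(got$detail, want$detail)

      got_i <- detect_indels(aln, map, id)
      want_i <- oracle_indels(aln, id)
      expect_equal(got_i$kind, want_i$kind)
      expect_equal(got_i$ref_position, want_i$ref_position)
      expect_equal(got_i$length, want_i$length)
    }
  }
})
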