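test_that("identical config and seed give byte-identical output", {
  cfg <- glires_preset(seed = 77)
  s1 <- simulate_alignment(cfg)
  s2 <- simulate_alignment(glires_preset(seed = 77))
  expect_identical(s1$alignment$seqs, s2$alignment$seqs)
  expect_identical(s1$truth, s2$truth)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_sim_output(s1, d1); write_sim_output(s2, d2)
  f1 <- file.path(d1, "alignment.fasta"); f2 <- file.path(d2, "alignment.fasta")
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  s3 <- simulate_alignment(glires_preset(seed = 78))
  expect_false(identical(s1$alignment$seqs, s3$alignment$seqs))
})

test_that("noise-free planting changes exactly the planted codon", {
  set.seed(71)
  root <- make_cds(60, motif_at = 53)
  cfg <- sim_config(tree = "(a:0,b:0);", root_sequence = root,
                    planted_events = list(list(branch = "a", kind = "stop_gain",
                                               codon = 53)),
                    seed = 5)
  sim <- simulate_alignment(cfg)
  a <- chars(sim$alignment$seqs[["a"]])
  r <- chars(root)
  diff_sites <- which(a != r)
  expect_true(all(diff_sites %in% (3 * 53 - 2):(3 * 53)))
  expect_true(paste(a[(3 * 53 - 2):(3 * 53)], collapse = "") %in%
                c("TAA", "TAG", "TGA"))
  expect_identical(sim$alignment$seqs[["b"]], root)
  expect_equal(sim$truth$verdicts$expected_verdict[sim$truth$verdicts$leaf == "a"],
               "pseudogene")
  expect_equal(sim$truth$verdicts$expected_verdict[sim$truth$verdicts$leaf == "b"],
               "functional")

  # minimal-change stop with tie broken in codon order: TGC -> TGA
  expect_equal(substr(sim$alignment$seqs[["a"]], 157, 159), "TGA")
})

test_that("planted events are inherited exactly along root-to-leaf paths", {
  set.seed(72)
  root <- make_cds(40)
  cfg <- sim_config(
    tree = "((a:0.01,b:0.01)ab:0.01,(c:0.01,d:0.01)cd:0.01)r;",
    root_sequence = root,
    planted_events = list(
      list(branch = "ab", kind = "indel", op = "deletion",
           position = 10, length = 4),
      list(branch = "c", kind = "stop_gain", codon = 20)),
    seed = 9)
  sim <- simulate_alignment(cfg)
  ev <- sim$truth$events
  expect_setequal(ev$leaf[ev$kind == "indel"], c("a", "b"))
  expect_equal(ev$leaf[ev$kind == "stop_gain"], "c")
  expect_false("d" %in% ev$leaf)
})

test_that("configuration invariants are enforced", {
  set.seed(73)
  root <- make_cds(30)
  expect_error(sim_config("(a:1,b:1);", root,
                          planted_events = list(list(branch = "zz",
                                                     kind = "stop_gain", codon = 5)),
                          seed = 1),
               class = "pseudoscan_config_error")
  expect_error(sim_config("(a:1,b:1);", root,
                          planted_events = list(list(branch = "a",
                                                     kind = "stop_gain", codon = 30)),
                          seed = 1),
               class = "pseudoscan_config_error")
  bad_root <- sub("^ATG", "CCC", root)
  expect_error(sim_config("(a:1,b:1);", bad_root, seed = 1),
               class = "pseudoscan_config_error")
  expect_error(sim_config("(a:1,b:1);", root, rate_multiplier_after_loss = 0.5,
                          seed = 1),
               class = "pseudoscan_config_error")
  expect_error(sim_config("(a:1,b:1);", root),
               class = "pseudoscan_config_error")
})

test_that("K80 substitution kinetics favour transitions as kappa grows", {
  set.seed(74)
  root <- make_cds(600)
  cfg <- sim_config("(a:0.3,b:0);", root, model = "K80", kappa = 10, seed = 11,
                    include_root = TRUE)
  sim <- simulate_alignment(cfg)
  a <- chars(sim$alignment$seqs[["a"]]); r <- chars(root)
  changed <- which(a != r)
  is_transition <- function(x, y) paste0(x, y) %in% c("AG", "GA", "CT", "TC")
  ts <- sum(is_transition(r[changed], a[changed]))
  tv <- length(changed) - ts
  expect_gt(ts, tv)  # with kappa = 10 transitions must dominate

  # transition matrices are proper stochastic matrices
  for (d in c(0.01, 0.1, 1)) {
    for (m in c("JC69", "K80")) {
      P <- pseudoscan:::sub_matrix(d, m, kappa = 4)
      expect_equal(unname(rowSums(P)), rep(1, 4))
      expect_true(all(P >= 0))
    }
  }
})

test_that("the glires preset reproduces the qualitative species pattern", {
  sim <- simulate_alignment(glires_preset(seed = 123))
  scan <- scan_alignment(sim$alignment, motif = sim$config$motif,
                         numbering = "ungapped_reference")
  leporids <- c("eur_rabbit", "hare", "pygmy_rabbit", "cottontail",
                "volcano_rabbit")
  st <- scan$statuses
  expect_true(all(st$verdict[st$seq_id %in% leporids] == "pseudogene"))

  sp <- scan$species
  expect_equal(sp$verdict[sp$species == "hoffmanns_pika"], "functional")
  expect_equal(sp$n_alleles[sp$species == "hoffmanns_pika"], 2L)
})

test_that("pseudogenized lineages reject rate constancy more often than intact ones", {
  set.seed(76)
  seeds <- sample.int(1e6, 200)
  rej <- matrix(FALSE, length(seeds), 2,
                dimnames = list(NULL, c("pseudo", "intact")))
  for (i in seq_along(seeds)) {
    sim <- simulate_alignment(glires_preset(seed = seeds[i]))
    tab <- batch_rrt(sim$alignment, "steppe_pika", c("eur_rabbit", "amer_pika"),
                     "outgroup", deletion_policy = "pairwise-complete")
    rej[i, "pseudo"] <- tab$p_value[tab$taxon_b == "eur_rabbit"] < 0.05
    rej[i, "intact"] <- tab$p_value[tab$taxon_b == "amer_pika"] < 0.05
  }
  expect_gt(mean(rej[, "pseudo"]), mean(rej[, "intact"]))
})
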