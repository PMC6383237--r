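# The Glires-like preset: a fixed simulation configuration emulating the
# pseudogenization pattern reported for CCL16 in lagomorphs — a
# leporid-like clade sharing a stop gain in the CC motif plus
# clade-specific frameshift deletions (16 and 19 nt), a cottontail-like
# sub-branch where the stop is replaced by a lysine and a further 20-nt
# deletion accrues, an intact pika-like sister clade with one
# heterozygous taxon (one intact and one stop-carrying allele), an
# outgroup, and accelerated evolution on pseudogenized branches.

GLIRES_NEWICK <- paste0(
  "(((((eur_rabbit:0.008,hare:0.008)rabbits:0.004,pygmy_rabbit:0.012)",
  "rabbit_core:0.004,(cottontail:0.010,volcano_rabbit:0.010)cottontails:0.006)",
  "leporid:0.030,((amer_pika:0.015,(hoffmanns_pika_A:0.001,hoffmanns_pika_B:0.001)",
  "hoffmanns:0.014)pika_core:0.005,steppe_pika:0.020)pika:0.030)lagomorph:0.020,",
  "outgroup:0.080)root;")

# Deterministic root CDS: 120 codons, Cys-Cys motif at codons 53-54,
# generated from a fixed internal stream so every call returns the same
# sequence without touching the caller's RNG state.
glires_root_sequence <- function(n_codons = 120L) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(1916L)
  sense <- sort(names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"])
  sense <- setdiff(sense, "ATG")  # keep internal ATGs out for a clean start codon
  codons <- c("ATG", sample(sense, n_codons - 2L, replace = TRUE), "TAA")
  codons[53:54] <- "TGC"
  paste(codons, collapse = "")
}

#' Glires-like simulation preset
#'
#' Returns a fixed [sim_config()] on a Glires-like topology (five
#' leporid-like leaves, a pika-like sister clade with a heterozygous
#' taxon, an outgroup) with the planted events described above and
#' post-loss rate acceleration. The preset models the conserved CC motif
#' at codons 53–54 ([motif_spec()] attached to the config).
#'
#' @param seed Simulation seed (default 101).
#' @param substitution_scale Multiplier on every branch length; 0 gives a
#'   noise-free simulation where only the planted events separate the
#'   leaves from the root.
#' @param rate_multiplier Post-loss rate multiplier (default 3).
#' @return A [sim_config()].
#' @examples
#' sim <- simulate_alignment(glires_preset(substitution_scale = 0))
#' scan_alignment(sim$alignment, motif = sim$config$motif)
#' @export
glires_preset <- function(seed = 101L, substitution_scale = 1,
                          rate_multiplier = 3) {
  tree <- ape::read.tree(text = GLIRES_NEWICK)
  tree$edge.length <- tree$edge.length * substitution_scale
  tree$tip.label[tree$tip.label == "hoffmanns_pika_A"] <- "hoffmanns_pika*1"
  tree$tip.label[tree$tip.label == "hoffmanns_pika_B"] <- "hoffmanns_pika*2"

  events <- list(
    list(branch = "leporid", kind = "stop_gain", codon = 53L),
    list(branch = "rabbit_core", kind = "indel", op = "deletion",
         position = 20L, length = 16L),
    list(branch = "cottontails", kind = "indel", op = "deletion",
         position = 25L, length = 19L),
    list(branch = "cottontail", kind = "motif_sub", codon = 53L, residue = "K"),
    list(branch = "cottontail", kind = "indel", op = "deletion",
         position = 170L, length = 20L),
    list(branch = "hoffmanns_pika*2", kind = "stop_gain", codon = 53L)
  )

  sim_config(
    tree = tree,
    root_sequence = glires_root_sequence(),
    model = "JC69",
    planted_events = events,
    rate_multiplier_after_loss = rate_multiplier,
    seed = seed,
    include_root = TRUE,
    reference_id = "ancestor",
    motif = motif_spec(c(53L, 54L), c("C", "C"), name = "CC")
  )
}

#' Compare scan output against a simulation's truth ledger
#'
#' Scans the simulated alignment (ungapped-reference numbering, so event
#' positions are in root coordinates) and matches detected events to the
#' truth ledger. A planted event counts as *recovered* when a detected
#' event of the corresponding kind sits at its position: stop gains match
#' `premature_stop` or `motif_stop_loss` at the planted codon; deletions
#' match an indel event of the planted length at the first deleted
#' position; insertions at the first reference position after the run.
#' Only events flagged `survived` in the truth ledger are expected —
#' substitution noise can legitimately overwrite a planted stop, and a
#' scanner cannot (and should not) report what is no longer in the
#' sequence. Planted motif substitutions are expected only when `motif`
#' covers their codon. At zero substitution noise every planted event
#' survives, and a correct scanner attains precision = recall = 1.
#'
#' @param sim A [simulate_alignment()] result.
#' @param motif Motif spec for the scan (defaults to the config's).
#' @param stop_set Stop codons.
#' @return List with `precision`, `recall`, `recall_disrupting` (stop
#'   gains and frameshift indels only), `n_expected`, `n_detected`,
#'   `n_matched`, the per-event `detail` data.frame, and the `scan`.
#' @export
evaluate_recovery <- function(sim, motif = sim$config$motif,
                              stop_set = STANDARD_STOPS) {
  scan <- scan_alignment(sim$alignment, motif = motif,
                         numbering = "ungapped_reference", stop_set = stop_set)
  truth <- sim$truth$events
  detected <- scan$events

  expected <- truth[truth$survived, , drop = FALSE]
  if (!is.null(motif) && nrow(expected)) {
    keep <- expected$kind != "motif_sub" | expected$position %in% motif$codon_indices
    expected <- expected[keep, , drop = FALSE]
  } else if (is.null(motif) && nrow(expected)) {
    expected <- expected[expected$kind != "motif_sub", , drop = FALSE]
  }

  used <- rep(FALSE, nrow(detected))
  matched <- logical(nrow(expected))
  for (i in seq_len(nrow(expected))) {
    ev <- expected[i, ]
    cand <- !used & detected$seq_id == ev$leaf
    cand <- cand & switch(
      ev$kind,
      stop_gain = detected$kind %in% c("premature_stop", "motif_stop_loss") &
        detected$ref_position == ev$position,
      motif_sub = detected$kind %in% c("motif_substitution", "motif_stop_loss") &
        detected$ref_position == ev$position,
      indel = {
        want_kind <- if (ev$length %% 3L != 0L) "frameshift_indel" else "inframe_indel"
        want_pos <- if (ev$op == "deletion") ev$position else ev$position + 1L
        detected$kind == want_kind & detected$ref_position == want_pos &
          detected$length == ev$length
      })
    hit <- which(cand)
    if (length(hit)) {
      used[hit[1]] <- TRUE
      matched[i] <- TRUE
    }
  }

  disrupting <- expected$kind == "stop_gain" |
    (expected$kind == "indel" & expected$length %% 3L != 0L)
  list(
    precision = if (nrow(detected)) sum(used) / nrow(detected) else 1,
    recall = if (nrow(expected)) mean(matched) else 1,
    recall_disrupting = if (any(disrupting)) mean(matched[disrupting]) else 1,
    n_expected = nrow(expected), n_detected = nrow(detected),
    n_matched = sum(matched),
    detail = cbind(expected, recovered = matched),
    scan = scan
  )
}

# Random sense CDS for calibration runs (consumes the active RNG stream).
random_cds <- function(n_codons) {
  sense <- sort(names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"])
  paste(c("ATG", sample(sense, n_codons - 2L, replace = TRUE), "TAA"),
        collapse = "")
}

#' Rejection rate of the relative-rate test under simulated rate shifts
#'
#' Simulates triples `((A, B), outgroup)` where lineage B evolves at
#' `rate_multiplier` times the rate of A, runs the relative-rate test on
#' each and returns the rejection frequency at level `alpha`. With
#' `rate_multiplier = 1` this measures the test's size (nominally
#' `alpha`); with multipliers > 1 its power, which must be non-decreasing
#' in the multiplier.
#'
#' @param rate_multiplier Rate multiplier on lineage B (>= 1).
#' @param n_replicates Number of simulated triples.
#' @param n_codons Codons per simulated sequence (3 x codons sites).
#' @param branch_length Ingroup terminal branch length
#'   (substitutions/site).
#' @param internal_length,outgroup_length Remaining branch lengths.
#' @param alpha Test level.
#' @param seed Master seed; replicate seeds are drawn from it.
#' @param model,kappa Substitution model.
#' @return List with `rejection_rate`, `n_replicates`, `n_rejected`,
#'   `alpha`, `mean_chi_square`.
#' @export
rrt_calibration <- function(rate_multiplier = 1, n_replicates = 400L,
                            n_codons = 333L, branch_length = 0.05,
                            internal_length = 0.02, outgroup_length = 0.10,
                            alpha = 0.05, seed = 1L,
                            model = "JC69", kappa = 2) {
  set.seed(seed)
  root_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  sim_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  newick <- sprintf("((A:%g,B:%g)ingroup:%g,O:%g)root;",
                    branch_length, branch_length * rate_multiplier,
                    internal_length, outgroup_length)
  rejected <- logical(n_replicates)
  chi2 <- numeric(n_replicates)
  for (i in seq_len(n_replicates)) {
    set.seed(root_seeds[i])
    root <- random_cds(n_codons)
    cfg <- sim_config(tree = newick, root_sequence = root, model = model,
                      kappa = kappa, seed = sim_seeds[i],
                      include_root = FALSE, reference_id = "A")
    sim <- simulate_alignment(cfg)
    counts <- classify_sites(aln_seq(sim$alignment, "A"),
                             aln_seq(sim$alignment, "B"),
                             aln_seq(sim$alignment, "O"))
    if (counts$n_unique_a + counts$n_unique_b == 0L) {
      rejected[i] <- FALSE
      chi2[i] <- 0
    } else {
      res <- tajima_rrt(counts$n_unique_a, counts$n_unique_b)
      rejected[i] <- res$p_value < alpha
      chi2[i] <- res$chi_square
    }
  }
  list(rejection_rate = mean(rejected), n_replicates = n_replicates,
       n_rejected = sum(rejected), alpha = alpha, mean_chi_square = mean(chi2))
}

#' Observed divergence along a single simulated branch
#'
#' Evolves a sequence along one branch and reports the proportion of
#' differing sites, for comparison with the JC69 closed form
#' `(3/4)(1 - exp(-4 d / 3))`.
#'
#' @param branch_length Branch length in substitutions/site.
#' @param n_codons Sequence length in codons.
#' @param seed Seed.
#' @param model,kappa Substitution model.
#' @return List with `observed`, `expected` (JC69 closed form),
#'   `n_sites`, `binomial_se` (standard error of the observed proportion
#'   at the expected value).
#' @export
simulated_divergence <- function(branch_length = 0.1, n_codons = 3334L,
                                 seed = 1L, model = "JC69", kappa = 2) {
  set.seed(seed)
  root <- random_cds(n_codons)
  sim_seed <- sample.int(.Machine$integer.max - 1L, 1L)
  cfg <- sim_config(tree = sprintf("(A:%g,B:0);", branch_length),
                    root_sequence = root, model = model, kappa = kappa,
                    seed = sim_seed, include_root = TRUE, reference_id = "ancestor",
                    constrain_functional = FALSE)
  sim <- simulate_alignment(cfg)
  a <- seq_chars(aln_seq(sim$alignment, "A"))
  r <- seq_chars(aln_seq(sim$alignment, "ancestor"))
  expected <- 0.75 * (1 - exp(-4 * branch_length / 3))
  list(observed = mean(a != r), expected = expected, n_sites = length(r),
       binomial_se = sqrt(expected * (1 - expected) / length(r)))
}
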