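# Seeded coding-sequence evolution along a phylogeny with planted
# pseudogenization events. Substitutions follow JC69 or K80 site-wise;
# indels exist only as planted events, so the emitted alignment is exactly
# gapped and no realignment step (with its own error modes) stands between
# the simulation and the scanners. Branches descending from a loss event
# (a planted stop gain or frame-disrupting indel) evolve at an accelerated
# rate, modelling release from purifying selection; the acceleration
# starts at the midpoint of the branch carrying the event.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a simulation configuration
#'
#' @param tree An `ape::phylo` tree (or newick string) with branch lengths
#'   in expected substitutions/site. Internal nodes that carry planted
#'   events must be labelled.
#' @param root_sequence Coding nucleotide string at the root: length a
#'   multiple of 3, starting `ATG`, ending in a stop, no internal stops.
#' @param model Substitution model, `"JC69"` or `"K80"`.
#' @param kappa Transition/transversion rate ratio for K80.
#' @param planted_events List of events; each a list with `branch` (label
#'   of the child node of the branch) and `kind` plus kind-specific
#'   fields: `stop_gain` (`codon`), `motif_sub` (`codon`, `residue`),
#'   `indel` (`position`, `length`, `op` = `"deletion"`/`"insertion"`,
#'   positions in root coordinates).
#' @param rate_multiplier_after_loss Rate multiplier (>= 1) applied to
#'   lineage segments downstream of a loss event.
#' @param seed Integer seed; the simulation consumes a single seeded
#'   stream in fixed pre-order traversal.
#' @param include_root If `TRUE` (default) the unevolved root sequence is
#'   emitted as a record named `reference_id` and designated the
#'   alignment's functional reference.
#' @param constrain_functional If `TRUE` (default), lineage segments that
#'   have not lost the gene evolve under a minimal purifying-selection
#'   proxy: substitutions that would create or destroy an in-frame stop
#'   codon, alter the start codon, or change the amino acid at a `motif`
#'   position are suppressed (reverted). Post-loss segments evolve free.
#'   Set to `FALSE` for a fully neutral process (e.g. when checking the
#'   substitution engine against its closed form).
#' @param reference_id Name of the reference record (default
#'   `"ancestor"`); when `include_root` is `FALSE` it must name a tip.
#' @param motif Optional [motif_spec()] describing the conserved motif the
#'   simulated gene carries (used by recovery evaluation).
#' @return Object of class `sim_config`.
#' @seealso [simulate_alignment()], [glires_preset()]
#' @export
sim_config <- function(tree, root_sequence, model = c("JC69", "K80"), kappa = 2,
                       planted_events = list(), rate_multiplier_after_loss = 1,
                       seed, include_root = TRUE, reference_id = "ancestor",
                       motif = NULL, constrain_functional = TRUE) {
  model <- match.arg(model)
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!inherits(tree, "phylo")) {
    ps_error("tree must be an ape phylo object or newick string",
             "pseudoscan_config_error")
  }
  tree <- ape::reorder.phylo(tree, "cladewise")
  if (missing(seed) || is.null(seed)) {
    ps_error("a seed is required for simulation", "pseudoscan_config_error")
  }
  root_sequence <- toupper(root_sequence)
  L <- nchar(root_sequence)
  if (L %% 3L != 0L || L < 9L) {
    ps_error("root sequence length must be a multiple of 3 (>= 9)",
             "pseudoscan_config_error")
  }
  aa <- translate_sequence(root_sequence)
  if (substr(root_sequence, 1, 3) != "ATG" ||
      substr(aa, nchar(aa), nchar(aa)) != "*" ||
      grepl("\\*", substr(aa, 1, nchar(aa) - 1L))) {
    ps_error("root sequence must start ATG, end in a stop, and have no internal stops",
             "pseudoscan_config_error")
  }
  if (rate_multiplier_after_loss < 1) {
    ps_error("rate_multiplier_after_loss must be >= 1", "pseudoscan_config_error")
  }

  labels <- node_labels(tree)
  n_codons <- L %/% 3L
  planted_events <- lapply(planted_events, function(ev) {
    if (!ev$branch %in% labels) {
      ps_error(sprintf("planted event on unknown branch '%s'", ev$branch),
               "pseudoscan_config_error")
    }
    kind <- match.arg(ev$kind, c("stop_gain", "motif_sub", "indel"))
    if (kind %in% c("stop_gain", "motif_sub")) {
      if (ev$codon < 1L || ev$codon >= n_codons) {   # terminal stop excluded
        ps_error(sprintf("planted %s codon %d outside coding range 1..%d",
                         kind, ev$codon, n_codons - 1L), "pseudoscan_config_error")
      }
    } else {
      ev$op <- match.arg(ev$op, c("deletion", "insertion"))
      if (ev$position < 1L || ev$length < 1L ||
          (ev$op == "deletion" && ev$position + ev$length - 1L > L) ||
          (ev$op == "insertion" && ev$position > L)) {
        ps_error("planted indel outside the root sequence", "pseudoscan_config_error")
      }
    }
    ev$kind <- kind
    ev
  })

  structure(
    list(tree = tree, root_sequence = root_sequence, model = model,
         kappa = kappa, planted_events = planted_events,
         rate_multiplier_after_loss = rate_multiplier_after_loss,
         seed = as.integer(seed), include_root = include_root,
         reference_id = reference_id, motif = motif,
         constrain_functional = constrain_functional),
    class = "sim_config"
  )
}

node_labels <- function(tree) {
  ntip <- length(tree$tip.label)
  internal <- tree$node.label %||% rep("", tree$Nnode)
  internal[!nzchar(internal)] <- paste0("node", which(!nzchar(internal)) + ntip)
  c(tree$tip.label, internal)
}

# Nucleotide substitution probability matrix for one branch.
sub_matrix <- function(d, model = "JC69", kappa = 2) {
  if (d <= 0) {
    P <- diag(4)
  } else if (model == "JC69") {
    same <- 0.25 + 0.75 * exp(-4 * d / 3)
    P <- matrix((1 - same) / 3, 4, 4)
    diag(P) <- same
  } else {
    beta <- 1 / (kappa + 2)
    alpha <- kappa * beta
    e1 <- exp(-4 * beta * d)
    e2 <- exp(-2 * (alpha + beta) * d)
    p_same <- 0.25 + 0.25 * e1 + 0.5 * e2
    p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
    p_tv <- 0.25 - 0.25 * e1
    P <- matrix(p_tv, 4, 4)
    diag(P) <- p_same
    P[1, 3] <- P[3, 1] <- P[2, 4] <- P[4, 2] <- p_ts   # A<->G, C<->T
  }
  dimnames(P) <- list(DNA_BASES, DNA_BASES)
  P
}

# Evolve residues along one branch segment; gaps are inert.
evolve_residues <- function(res, d, model, kappa) {
  live <- which(res %in% DNA_BASES)
  if (length(live) == 0L || d <= 0) return(list(res = res, n_sub = 0L))
  P <- sub_matrix(d, model, kappa)
  old <- res[live]
  new <- old
  for (b in DNA_BASES) {
    ii <- which(old == b)
    if (length(ii)) {
      new[ii] <- sample(DNA_BASES, length(ii), replace = TRUE, prob = P[b, ])
    }
  }
  res[live] <- new
  list(res = res, n_sub = sum(new != old))
}

hamming_codon <- function(a, b) {
  sum(seq_chars(a) != seq_chars(b))
}

# Minimal nucleotide change from the current codon to a stop codon,
# ties broken by codon order TAA < TAG < TGA.
nearest_stop <- function(codon, stop_set = STANDARD_STOPS) {
  d <- vapply(stop_set, hamming_codon, integer(1), a = codon)
  stop_set[which.min(d)]
}

# Minimal-change codon encoding `residue`, ties broken alphabetically.
nearest_codon_for <- function(codon, residue) {
  cands <- sort(names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == residue])
  if (length(cands) == 0L) {
    ps_error(sprintf("no codon encodes residue '%s'", residue),
             "pseudoscan_config_error")
  }
  d <- vapply(cands, hamming_codon, integer(1), a = codon)
  cands[which.min(d)]
}

# Minimal purifying-selection proxy on functional lineage segments:
# revert any codon (in root-frame coordinates) whose evolved state would
# create or destroy a stop, change the start codon, or change the amino
# acid at a motif position. All other substitutions pass through.
constrain_segment <- function(old_res, new_res, ids, config) {
  L <- nchar(config$root_sequence)
  m <- matrix(match(as.numeric(seq_len(L)), ids), nrow = 3L)
  o <- matrix(old_res[m], nrow = 3L)
  n <- matrix(new_res[m], nrow = 3L)
  oc <- paste0(o[1, ], o[2, ], o[3, ])
  nc <- paste0(n[1, ], n[2, ], n[3, ])
  valid <- !grepl("[^ACGT]", oc) & !grepl("[^ACGT]", nc)
  changed <- valid & oc != nc
  if (!any(changed)) return(new_res)

  stop_flip <- (oc %in% STANDARD_STOPS) != (nc %in% STANDARD_STOPS)
  k <- seq_len(L %/% 3L)
  revert <- changed & (stop_flip | k == 1L)
  if (!is.null(config$motif)) {
    at_motif <- k %in% config$motif$codon_indices
    aa_flip <- rep(FALSE, length(k))
    ii <- which(changed & at_motif)
    if (length(ii)) {
      aa_flip[ii] <- unname(Biostrings::GENETIC_CODE[oc[ii]]) !=
        unname(Biostrings::GENETIC_CODE[nc[ii]])
    }
    revert <- revert | (changed & at_motif & aa_flip)
  }
  if (any(revert)) {
    sites <- as.vector(m[, revert, drop = FALSE])
    new_res[sites] <- old_res[sites]
  }
  new_res
}

# Evolve one branch segment, honouring the functional constraint when the
# lineage still carries an intact gene.
evolve_segment <- function(st, d, config, constrained) {
  old <- st$res
  out <- evolve_residues(old, d, config$model, config$kappa)
  if (constrained && config$constrain_functional && out$n_sub > 0L) {
    out$res <- constrain_segment(old, out$res, st$ids, config)
    out$n_sub <- sum(out$res != old & old %in% DNA_BASES)
  }
  st$res <- out$res
  list(st = st, n_sub = out$n_sub)
}

is_loss_event <- function(ev) {
  ev$kind == "stop_gain" ||
    (ev$kind == "indel" && ev$length %% 3L != 0L)
}

apply_planted_event <- function(st, ev, ev_index) {
  if (ev$kind %in% c("stop_gain", "motif_sub")) {
    sites <- 3L * ev$codon - c(2L, 1L, 0L)
    idx <- match(sites, st$ids)
    if (anyNA(idx) || any(st$res[idx] == "-")) {
      return(st)  # codon removed by an earlier planted deletion; nothing to mutate
    }
    cur <- paste(st$res[idx], collapse = "")
    new <- if (ev$kind == "stop_gain") nearest_stop(cur)
           else nearest_codon_for(cur, toupper(ev$residue))
    st$res[idx] <- seq_chars(new)
  } else if (ev$op == "deletion") {
    idx <- which(st$ids >= ev$position & st$ids <= ev$position + ev$length - 1L)
    st$res[idx] <- "-"
  } else {
    new_ids <- ev$position + seq_len(ev$length) / (ev$length + 1L) + ev_index * 1e-9
    new_res <- sample(DNA_BASES, ev$length, replace = TRUE)
    ids2 <- c(st$ids, new_ids)
    res2 <- c(st$res, new_res)
    ord <- order(ids2)
    st$ids <- ids2[ord]
    st$res <- res2[ord]
  }
  st
}

#' Simulate a coding alignment with planted disruption events
#'
#' Evolves the root sequence along the configured tree (pre-order,
#' single seeded stream), applying each planted event deterministically at
#' the midpoint of its branch and inheriting it in all descendants. The
#' output alignment is exactly gapped from the planted indels.
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_result`: list with
#'   \describe{
#'     \item{`alignment`}{a [coding_alignment()] of the leaf sequences
#'       (plus the unevolved root as reference when configured)}
#'     \item{`truth`}{list of `events` (per-leaf inherited planted events
#'       with a `survived` flag: later substitutions can overwrite a
#'       planted stop or motif change), `verdicts` (per-leaf expected
#'       functional verdict from the surviving events) and
#'       `branch_substitutions` (realized substitution count and effective
#'       length per branch)}
#'     \item{`config`}{the input configuration}
#'   }
#' Identical config (including seed) gives byte-identical output.
#' @export
simulate_alignment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tree <- config$tree
  ntip <- length(tree$tip.label)
  labels <- node_labels(tree)
  root <- ntip + 1L
  L <- nchar(config$root_sequence)
  r_mult <- config$rate_multiplier_after_loss

  ev_branch <- vapply(config$planted_events, `[[`, character(1), "branch")

  states <- vector("list", ntip + tree$Nnode)
  states[[root]] <- list(ids = as.numeric(seq_len(L)),
                         res = seq_chars(config$root_sequence))
  lost <- logical(ntip + tree$Nnode)
  inherited <- vector("list", ntip + tree$Nnode)
  inherited[[root]] <- integer()

  branch_rows <- vector("list", nrow(tree$edge))
  for (i in seq_len(nrow(tree$edge))) {
    par <- tree$edge[i, 1L]
    chd <- tree$edge[i, 2L]
    lab <- labels[chd]
    ev_idx <- which(ev_branch == lab)
    st <- states[[par]]
    rate_in <- if (lost[par]) r_mult else 1
    d <- tree$edge.length[i]
    if (length(ev_idx) == 0L) {
      out <- evolve_segment(st, d * rate_in, config, constrained = !lost[par])
      st <- out$st
      n_sub <- out$n_sub
      eff <- d * rate_in
      lost[chd] <- lost[par]
    } else {
      out1 <- evolve_segment(st, d / 2 * rate_in, config, constrained = !lost[par])
      st <- out1$st
      for (e in ev_idx) st <- apply_planted_event(st, config$planted_events[[e]], e)
      lost[chd] <- lost[par] ||
        any(vapply(config$planted_events[ev_idx], is_loss_event, logical(1)))
      rate_out <- if (lost[chd]) r_mult else 1
      out2 <- evolve_segment(st, d / 2 * rate_out, config, constrained = !lost[chd])
      st <- out2$st
      n_sub <- out1$n_sub + out2$n_sub
      eff <- d / 2 * (rate_in + rate_out)
    }
    states[[chd]] <- st
    inherited[[chd]] <- c(inherited[[par]], ev_idx)
    branch_rows[[i]] <- data.frame(branch = lab, nominal_length = d,
                                   effective_length = eff,
                                   n_substitutions = n_sub,
                                   stringsAsFactors = FALSE)
  }

  # assemble the gapped alignment over the union of site ids
  leaf_states <- states[seq_len(ntip)]
  all_ids <- sort(unique(c(as.numeric(seq_len(L)),
                           unlist(lapply(leaf_states, `[[`, "ids")))))
  build_row <- function(st) {
    res <- rep("-", length(all_ids))
    res[match(st$ids, all_ids)] <- st$res
    paste(res, collapse = "")
  }
  seqs <- vapply(leaf_states, build_row, character(1))
  names(seqs) <- tree$tip.label
  if (config$include_root) {
    seqs <- c(setNames(build_row(states[[root]]), config$reference_id), seqs)
  }
  aln <- coding_alignment(seqs, config$reference_id,
                          check_reference_orf = config$include_root)

  truth <- build_truth(config, tree, labels, states, inherited, ntip)
  truth$branch_substitutions <- do.call(rbind, branch_rows)

  structure(list(alignment = aln, truth = truth, config = config),
            class = "sim_result")
}

# Survival semantics: a planted event "survives" at a leaf when the leaf
# sequence still carries the corresponding lesion -- later substitutions
# can overwrite a planted stop or motif change. A codon carries at most
# one realized lesion, so when several planted codon-level events hit the
# same codon of the same lineage (e.g. a stop gain later replaced by a
# motif substitution), the realized state is attributed to exactly one of
# them: the stop-gain expectation when the codon now is a stop, otherwise
# the motif-substitution expectation. Indels always survive (there is no
# spontaneous indel process). The expected verdict is computed from the
# surviving events.
build_truth <- function(config, tree, labels, states, inherited, ntip) {
  root_aa <- translate_sequence(config$root_sequence)
  all_rows <- list()
  verdict_rows <- list()
  empty <- data.frame(leaf = character(), branch = character(),
                      kind = character(), position = integer(),
                      length = integer(), op = character(),
                      realized = character(), survived = logical(),
                      stringsAsFactors = FALSE)
  for (leaf in seq_len(ntip)) {
    lab <- labels[leaf]
    st <- states[[leaf]]
    rows <- empty
    for (e in inherited[[leaf]]) {
      ev <- config$planted_events[[e]]
      if (ev$kind %in% c("stop_gain", "motif_sub")) {
        sites <- 3L * ev$codon - c(2L, 1L, 0L)
        idx <- match(sites, st$ids)
        codon <- if (anyNA(idx)) "---" else paste(st$res[idx], collapse = "")
        aa <- translate_codon(codon)
        survived <- if (ev$kind == "stop_gain") {
          codon %in% STANDARD_STOPS
        } else {
          !is.na(aa) && aa != substr(root_aa, ev$codon, ev$codon)
        }
        rows <- rbind(rows, data.frame(
          leaf = lab, branch = ev$branch, kind = ev$kind,
          position = ev$codon, length = 0L, op = "", realized = codon,
          survived = survived, stringsAsFactors = FALSE))
      } else {
        rows <- rbind(rows, data.frame(
          leaf = lab, branch = ev$branch, kind = ev$kind,
          position = ev$position, length = ev$length, op = ev$op,
          realized = "", survived = TRUE, stringsAsFactors = FALSE))
      }
    }
    # one realized lesion per codon
    codon_rows <- which(rows$kind %in% c("stop_gain", "motif_sub"))
    for (pos in unique(rows$position[codon_rows])) {
      here <- codon_rows[rows$position[codon_rows] == pos]
      if (sum(rows$survived[here]) <= 1L) next
      is_stop <- rows$realized[here[1]] %in% STANDARD_STOPS
      keep_kind <- if (is_stop) "stop_gain" else "motif_sub"
      keep <- here[rows$kind[here] == keep_kind][1]
      rows$survived[setdiff(here, keep)] <- FALSE
    }

    surv <- rows[rows$survived, , drop = FALSE]
    verdict <- if (any(surv$kind == "stop_gain") ||
                   any(surv$kind == "indel" & surv$length %% 3L != 0L) ||
                   any(surv$kind == "motif_sub" & surv$realized %in% STANDARD_STOPS)) {
      "pseudogene"
    } else if (any(surv$kind == "motif_sub")) {
      "impaired_motif"
    } else "functional"

    all_rows[[leaf]] <- rows
    verdict_rows[[leaf]] <- data.frame(leaf = lab, expected_verdict = verdict,
                                       stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, c(list(empty), all_rows))
  rownames(events) <- NULL
  list(events = events, verdicts = do.call(rbind, verdict_rows))
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d leaves, alignment %d columns, %d planted event instance(s)\n",
              length(x$config$tree$tip.label), x$alignment$alignment_length,
              nrow(x$truth$events)))
  invisible(x)
}

#' Write simulation outputs to a directory
#'
#' Writes `alignment.fasta`, `truth_events.tsv`, `truth_verdicts.tsv`,
#' `branch_substitutions.tsv` and a JSON mirror `truth.json`.
#'
#' @param sim A [simulate_alignment()] result.
#' @param dir Output directory (created if needed).
#' @param force Overwrite existing files.
#' @return Invisibly, the directory.
#' @export
write_sim_output <- function(sim, dir, force = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("alignment.fasta", "truth_events.tsv",
                            "truth_verdicts.tsv", "branch_substitutions.tsv",
                            "truth.json"))
  exists <- file.exists(paths)
  if (any(exists) && !force) {
    ps_error(sprintf("refusing to overwrite %s (use force)",
                     paste(paths[exists], collapse = ", ")),
             "pseudoscan_io_error")
  }
  write_alignment(sim$alignment, paths[1])
  write.table(sim$truth$events, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth$verdicts, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth$branch_substitutions, paths[4], sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, paths[5], auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
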