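---
title: "Detecting coding-sequence decay: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting coding-sequence decay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudoscan)
```

# Scope and model

`pseudoscan` annotates gene loss in orthologous coding alignments. The
analysis is *reference-anchored*: one record — a functional ortholog, often
from a distant species such as human for a rodent/lagomorph data set — is
designated the reference, and it alone defines the reading frame and the
coordinate system. Query sequences are never re-translated in their own
(possibly frameshifted) frame; each lesion is enumerated independently
against the intact frame, which is how comparative gene-loss studies report
their findings and what makes events from different species comparable.

The reference must be a complete open reading frame: after gap removal it
must translate without internal stops and end in a stop codon. Everything
else — queries with stops, gaps, ambiguity codes, missing terminal stops —
is data, not an error.

## Coordinates

Two numbering conventions coexist in the literature and both are
implemented (`build_coordinate_map()`):

* **`alignment_columns`** (default): every column is numbered, gap columns
  included. This is the convention used when positions are read off a
  published alignment figure whose caption says indels are included in the
  numbering, and it is why the package default follows it.
* **`ungapped_reference`**: only reference non-gap sites are numbered;
  useful for interoperability with annotation on the unaligned reference.

Codon indices are always over the ungapped reference coding sequence and so
are identical in both modes. Coordinates are 1-based with closed intervals
throughout, matching the positional language of the field ("position 283",
"from position 343 to 366"). Reverse-strand input and transcript-to-genome
liftover are out of scope: sequences are coding-strand by contract.

## Lesion detection

**Premature stops.** Every reference codon strictly before the terminal
stop is inspected; a complete query codon in the stop set (default
`TAA`/`TAG`/`TGA`, configurable for non-standard codes) yields one event.
Codons containing gaps or ambiguity codes are *skipped and logged*, never
guessed: calling a stop through an alignment gap is the classic false
positive of this analysis. The terminal stop position never yields an
event; a query that has lost its terminal stop is flagged as a note (draft
database sequences show exactly this failure mode).

**Indels.** A deletion is a maximal run of columns where the query is
gapped and the reference is not; an insertion the converse. Columns gapped
in *both* sequences belong to indels private to third sequences and are
transparent — they neither count toward nor break a run. Runs classify by
length modulo 3 (`frameshift_indel` vs `inframe_indel`). Two nearby runs
separated by at least one aligned residue are two events; the package does
not silently cancel a +1/−1 pair into "no net frameshift", because each
lesion is an independent mutational event — but the per-sequence cumulative
frame offset is reported so compensated cases remain visible.

**Motifs.** A `motif_spec` names required residues at reference codon
positions (for CC chemokines, `C@53,C@54`). A stop codon at a motif
position is `motif_stop_loss`; any other mismatch is `motif_substitution`.
When the premature-stop scan and the motif check would report the same
codon, the single more specific `motif_stop_loss` event is kept.

**Verdicts.** An allele is `pseudogene` iff it carries at least one of
`premature_stop`, `frameshift_indel`, `start_loss` or `motif_stop_loss`.
A motif residue replaced by a different amino acid is `impaired_motif`,
deliberately *not* `pseudogene`: a Cys→Lys change very likely impairs
function but is not proof of pseudogenization the way a truncation is, and
the two claims should stay distinguishable in reports. In-frame indels
alone leave an allele `functional` (the event stays visible). At species
level, one functional allele suffices for a `functional` verdict — a
heterozygote still makes protein; all-pseudogene alleles give `pseudogene`;
anything else is `impaired`.

## Splice-acceptor scanning

`find_acceptor_candidates()` scans an intron for occurrences of an acceptor
motif upstream of the annotated 3′ end, within a caller-chosen window. Use
of an acceptor *k* nt upstream retains exactly *k* intron nucleotides in
the transcript; the retention is in frame iff *k* ≡ 0 (mod 3), inserting
*k*/3 residues (`predict_retention()`, which also translates the retained
peptide when the segment is known). Candidates are plain motif matches —
no position-weight matrix or neural scoring; strength prediction is
explicitly out of scope, so absence of a candidate means absence of the
motif, nothing more. Two motif conventions are supported because published
descriptions are sometimes exon-side: `intron_terminal` (the canonical
`AG` ending the intron) and `exon_initial` (a motif, e.g. `CA`, beginning
the new exon segment). The default is the canonical intron-terminal `AG`;
neither reading is hard-coded as the only truth. Frame arithmetic assumes
the insertion lands at the exon boundary without shifting the downstream
frame, which holds when the boundary sits on a codon boundary.

## Tajima's relative-rate test

For aligned sequences A, B and outgroup O, sites are classified under
complete deletion (any column with a gap or IUPAC ambiguity code in any of
the three is dropped — ambiguity codes are treated as missing, never
partially matched, for determinism) into: identical, unique to A, unique
to B, unique to O, all different. With $n_A$ and $n_B$ the unique counts,

$$\chi^2 = \frac{(n_A - n_B)^2}{n_A + n_B}, \qquad \text{df} = 1,$$

tested against the upper tail of $\chi^2_1$. No continuity correction is
applied — the plain statistic reproduces the published worked values
exactly (e.g. $(11-69)^2/80 = 42.05$). Full precision is kept internally;
the conventional two-decimal rounding happens only in the print method.
`batch_rrt()` runs one fixed comparator against many partners; its
`"complete"` policy masks columns across the *whole* batch (every row then
uses the same site set, as multi-sequence complete deletion does), while
`"pairwise-complete"` masks per triple. For a single triple the two
coincide. No multiple-testing correction is applied across rows; raw
p-values are reported. The transition/transversion-partitioned variant of
the test and model-based rate tests are out of scope.

# The simulator

`simulate_alignment()` evolves a root coding sequence along a phylogeny
(`ape` tree, branch lengths in expected substitutions/site) under JC69 or
K80, using the standard closed-form transition probabilities. Design
choices that matter:

* **Indels are planted, never spontaneous.** Deletions blank residues;
  insertions create fresh alignment columns. The emitted alignment is
  therefore *exactly* gapped and no aligner sits between simulation and
  scanner — alignment error is a real confounder in practice, but a test
  harness must not mix it into every test of the detector.
* **Planted events are deterministic.** A stop gain rewrites its codon to
  the nearest stop (ties broken in the fixed order TAA < TAG < TGA,
  echoing single-nucleotide TGC→TGA-style lesions); a motif substitution
  picks the minimal-change codon for the target residue (alphabetical
  tie-break). Events apply at the midpoint of their branch and are
  inherited by all descendants.
* **Post-loss acceleration.** Branch segments downstream of a loss event
  (stop gain or frameshift indel) evolve at `rate_multiplier_after_loss`
  times the base rate, from the event branch's midpoint onward — a simple,
  documented convention for partially constrained branches.
* **A minimal purifying-selection proxy** (`constrain_functional`, default
  on): on segments that still carry an intact gene, substitutions that
  would create or destroy an in-frame stop, change the start codon, or
  change the amino acid at a declared motif position are suppressed. A
  neutral process would sprinkle premature stops into "functional"
  lineages (about 4% of random coding substitutions create stops), making
  every truth comparison meaningless; real functional genes are protected
  by selection, and this is the smallest model of that protection. All
  other sites evolve neutrally. Set it off to verify the raw engine
  against closed forms.
* **Determinism.** One seeded stream, consumed in fixed pre-order
  traversal: identical config and seed give byte-identical FASTA.

## Truth ledger and survival

The simulator emits, per leaf, every inherited planted event with a
`survived` flag and the realized codon: on accelerated (unconstrained)
branches, later substitutions can legitimately overwrite a planted stop.
Recovery (`evaluate_recovery()`) is measured against the *realized* truth —
a scanner cannot, and should not, report a lesion that evolution erased —
and one codon carries at most one realized lesion, so when several planted
codon-level events hit the same codon the realized state is credited to a
single expectation. At zero substitution noise every event survives and a
correct scanner attains precision = recall = 1 against the planted set;
under noise, recall over surviving events stays 1 while precision drops
as accelerated pseudogene lineages accrue genuine new stops (which the
scanner is right to report). Expected verdicts are computed from surviving
events only and do not account for noise-created lesions outside the
planted set; with the selection proxy on, such lesions arise only in
already-pseudogenized lineages, where they cannot change the verdict.

## The Glires-like preset

`glires_preset()` encodes the study design this package is organized
around: a 120-codon root CDS with the CC motif at codons 53–54; a
leporid-like clade (five leaves) sharing a stop gain at codon 53, with
subclade frameshift deletions of 16 nt and 19 nt; a cottontail-like branch
where the stop is replaced by a lysine (`C53K`) and a further 20-nt
deletion accrues; an intact pika-like sister clade containing one
heterozygous taxon (records `hoffmanns_pika*1`, intact, and `*2`, carrying
the codon-53 stop — the `*<digit>` suffix is the package's allele
convention); and an outgroup. Branch lengths total roughly 0.07
substitutions/site root-to-leaf before acceleration — shallow-radiation
values appropriate to a conserved immune gene over this clade's depth —
and the post-loss multiplier defaults to 3, a free parameter chosen to
give a clear but not trivial rate contrast (the underlying study design
yields path-level difference counts, not branch rate estimates, so no
calibrated value exists). `substitution_scale` scales all branch lengths;
0 gives the noise-free planting used for exact recovery checks.

## Calibration checks and problem sizes

Two stochastic checks accompany the unit tests, at sizes chosen to keep
the suite fast while leaving comfortable statistical margins:

* `rrt_calibration()` simulates `((A, B), O)` triples — 333 codons,
  ingroup branches 0.05, outgroup 0.10 substitutions/site — with lineage B
  accelerated by a multiplier. At multiplier 1 the rejection rate at
  α = 0.05 estimates the test's size (asserted within three binomial
  standard errors of 0.05 over 400 replicates); power must be
  non-decreasing over multipliers {1, 2, 4} (150 replicates each).
* `simulated_divergence()` evolves ~10,000 sites along one branch of
  length 0.1 with the selection proxy off and compares the observed
  proportion of differing sites with the JC69 closed form
  $\tfrac{3}{4}(1 - e^{-4d/3})$, within three binomial standard errors.

## What passing these tests does and does not show

The simulator omits real-data complications on purpose: no alignment
error, no spontaneous indels, no rate variation across sites, no base
composition bias, no sequencing error or phasing uncertainty (each FASTA
record is one already-phased allele). Perfect recovery on simulated data
therefore validates the *logic* of the detectors — coordinates, run
bookkeeping, classification rules — not robustness to misalignment. On
real data the dominant error source is the alignment itself; the skipped-
codon log and the transparency rule for third-party gaps are the package's
mitigations, not cures.

# Numerical and degenerate-input conventions

* The relative-rate test is *undefined*, not zero, when $n_A + n_B = 0$; a
  classed error is raised rather than reporting a meaningless pass.
* `chi2_survival()` is the upper tail of `stats::pchisq`; p-values are
  never recomputed through approximations.
* Gapped/ambiguous codons: skipped in stop detection (logged), reported as
  `detail = "gap"` in motif checks, excluded columns in the rate test.
* Ambiguity codes are accepted on input, normalized to upper case, and
  preserved; they are treated as missing wherever a decision would
  otherwise rest on a guess.
* Reports are TSV (greppable, spreadsheet-friendly) with a JSON mirror and
  a per-species summary; the TSV round-trips losslessly through
  `read_report()`.
* The CLI never overwrites outputs without `--force` and returns exit
  status 1 with a diagnostic naming the offending file/record/column on
  validation failure.

# Known limitations

Heterozygote phasing is assumed done upstream. The motif check translates
single codons and cannot see compound lesions spanning motif and frame
(a frameshift running through the motif appears as gap-coded motif events
plus the indel itself). `compare_acceptor_positions()` requires both
positions in one stated coordinate system — it cannot detect a frame
mismatch between species. The simulator's selection proxy protects only
stops, the start codon and declared motif positions; it does not model
synonymous/non-synonymous rate structure, so dN/dS-style inference on its
output would be meaningless (and is out of scope).
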