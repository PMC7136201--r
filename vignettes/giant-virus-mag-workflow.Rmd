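---
title: "Recovering and analysing giant virus MAGs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering and analysing giant virus MAGs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gvpipe)
```

## The problem

Nucleo-Cytoplasmic Large DNA Viruses (NCLDV, the "giant viruses") are
routinely recovered from metagenomes by binning assembled contigs, but the
completeness and contamination checks used for bacterial and archaeal bins
rely on universal single-copy marker sets that do not exist for viruses.
`gvpipe` implements a dedicated workflow for viral bins: marker-based
screening, contig-level decontamination, strain-heterogeneity QC, and the
downstream comparative layer (clade delineation on a marker phylogeny,
average amino acid identity, orthologous-group analytics, and metabolic
gene profiling). External search and inference tools (HMMER, LAST/BLAST,
ProteinOrtho, aligners, tree builders) are consumed through their standard
tabular/Newick outputs; the package never shells out to them.

## Screening and quality control

**Marker screen.** Five protein families are conserved across NCLDV and
essentially absent from cellular genomes: DNA polymerase B (PolB), the
virus-like transcription factor VLTF3, the major capsid protein (MCP), the
A32 packaging ATPase, and the superfamily II helicase (SFII). A bin is
retained when at least 4 of the 5 markers are detected and its total
length exceeds 100 Kbp -- the smallest known NCLDV genome is ~103 Kbp, so
a higher cutoff would bias against small-genome clades. Hits must clear a
per-model bitscore cutoff; calibrated cutoffs are data-dependent, so the
packaged default is a uniform, conservative 30 bits, exposed in
`marker_registry()`. The cutoff comparison is inclusive (a hit exactly at
the cutoff counts), and the 4-of-5 rule does not privilege any particular
marker.

**Split genes.** Marker genes occasionally appear as two protein
fragments (introns, assembly breaks). `merge_split_hits()` merges hits
from distinct proteins against the same model when their model-coordinate
intervals overlap by at most 10 residues ("no sequence overlap", read in
model coordinates, with a small tolerance for alignment jitter), ordering
fragments by model position. Merging is genome-wide rather than
contig-restricted because MAG contigs are unordered fragments of one
genome. Merging can only reduce copy counts, never increase them.

**Decontamination.** Each contig receives a signed score contrasting its
proteins' best hits against virus-specific (VOG-like) and
cellular-specific (Pfam-like) HMMs:
score = mean over proteins of (max viral bitscore − max cellular
bitscore), with a missing side contributing zero. The mean (rather than
the sum) makes the score independent of contig length; only the sign
semantics are fixed by the underlying method, so the aggregation is
isolated in `score_contig()`. A contig is removed as *cellular* when its
score is negative AND fewer than 3 of its proteins hit viral HMMs AND no
top-5 homology hit lands on a known NCLDV protein -- the three conditions
are combined conjunctively, the conservative reading that removes only
multiply-supported contamination (`cellular_combine = "or"` is available).
Independently, a contig is removed as *phage* when any top-5 hit is a
bacteriophage and none is an NCLDV. After decontamination the bin is
re-screened: removals can push a bin below 4 markers or 100 Kbp.

**Strain heterogeneity.** Bins in which two or more of SFII, VLTF3, A32
and PolB occur in multiple (merged) copies are rejected as likely strain
mixtures; exactly one multi-copy marker flags the bin but keeps it. MCP is
ignored entirely because multiple capsid-protein copies are commonplace in
real NCLDV genomes. N50 uses the standard convention: the length at which
the descending cumulative sum first reaches half the total.

## Phylogeny-derived clades

The marker supermatrix concatenates per-marker alignments in the fixed
order PolB, VLTF3, MCP, A32, SFII, padding missing genome x marker cells
with gaps, and `trim_alignment()` drops columns whose non-gap fraction is
below a threshold (default 0.1, boundary inclusive, matching trimAl's
`-gt`). Alignment and tree inference are inputs, not package
responsibilities.

Clade delineation cuts a rooted ultrametric tree at a height *h*:
clusters are the maximal clades whose root height is at most *h*, so every
cluster is monophyletic by construction -- the manual monophyly editing
step of interactive workflows becomes a structural guarantee.
`stretch_ultrametric()` provides a deliberately simple ultrametric
transform (terminal branches extended to equalise root-to-leaf depths);
already-ultrametric chronograms are accepted and validated at a 1e-6
path-length tolerance.

For each height on a grid (default: 100 evenly spaced heights strictly
inside (0, root height)) the Dunn index is computed on cophenetic
distances: minimum between-cluster distance divided by maximum
within-cluster diameter. Degenerate partitions (k < 2, k > n−1, all
diameters zero) are skipped. The index is conventionally *maximised* for
compact, well-separated clusters, and that is the default objective; the
source workflow this package generalises selected the *lowest* index
value, so `objective = "min"` is exposed verbatim rather than silently
corrected -- the conflict between the two directions is real and left
visible to the user. Ties break toward the smaller height.

## AAI and AF

`reciprocal_best_hits()` pairs proteins that are mutually best-scoring
across two directional searches (ties broken by input order, so results
are reproducible); AAI is the mean of the two directional identities over
RBH pairs, and the alignment fraction AF = 100 · n_RBH / min(proteome
sizes). Pairs with AF below 10 are masked to an AAI of 0 for reporting --
with the min-size denominator there is a single AF per pair, which
subsumes "either member below 10". The search backend is pluggable:
`best_hits_from_table()` adapts external tabular searches, while
`best_hits()` computes exact global Needleman--Wunsch alignments
(BLOSUM62, gap open 10, extension 0.5) so that AAI is testable with no
external binary.

## Orthologous-group analytics

`frequency_spectrum()` reports per-OG genome counts, singleton and
annotated fractions as integer percentages. `power_law_alpha()` is the
continuous-approximation MLE alpha = 1 + n / sum(ln(x/xmin)) with fixed
xmin = 1; data-driven xmin selection is out of scope since only a display
fit is needed. The bipartite genome/OG network connects genomes to the
families they encode, restricted to OGs in more than 5 genomes.

Clade-specific enrichment runs a two-sided Mann--Whitney U test of
per-genome copy counts in a clade against all other genomes (normal
approximation with tie and continuity correction, via
`stats::wilcox.test`), for clades with more than 5 members and annotated
OGs present in more than 6 genomes. "Membership" is read as copy counts
-- clade-specific families often expand in copy number -- with a binary
presence/absence mode behind a flag. P-values are Benjamini--Hochberg
corrected across all (clade, OG) tests pooled, and an OG is called
significant at q < 0.01 when the clade mean exceeds the background mean
(the test is two-sided; direction is filtered post hoc). Unannotated OGs
are excluded *before* correction, so only performed tests enter the BH
family.

A caveat the test suite makes explicit: at very small sample sizes the
normal approximation is not uniformly accurate. Against an exhaustive
permutation oracle on instances with n1 + n2 <= 12, deviations of 0.05 to
0.5 occur at mid-range p-values (heavily tied small samples can have an
exact two-sided p of 1.0 where the approximation reports ~0.5). These
deviations sit far from the q < 0.01 decision region -- in the exact-p <=
0.05 tail the worst deviation we measured is ~0.01 -- but an oracle
agreement band of 0.01 over *all* small instances is not attainable with
this estimator, and the corresponding acceptance check is left failing
rather than weakened.

## Metabolic profiling

Pathway definitions ship as editable YAML: glycolysis as 10 steps (HK,
PGI, PFK, ALD, TPI, G3P, PGK, PGM, ENO, PYK), the TCA cycle as 8 steps
with succinate dehydrogenase satisfied by any subunit, the
gluconeogenesis-specific trio (PEPCK, FBP, G6P) and the glyoxylate shunt
(ICL, MS). Completeness counts each step once regardless of copy number.
Whether a multi-subunit enzyme counts as one step is unambiguous for
glycolysis but a choice for the TCA cycle; the any-subunit rule is the
packaged convention. `detect_fusion()` calls a fused-domain protein when
one protein carries both target domains with at most 10 aa of coordinate
overlap (the G3P+PGK architecture); `colocalization()` reports runs of
target genes separated by at most 5 intervening genes, with at least 2
members. Neither tolerance is fixed by the underlying study, so both are
exposed as arguments.

## What the synthetic generator emulates

`generate_bundle()` plays the role of the external search tools and
writes a complete, parseable input bundle plus a `truth.json` of
everything planted. Design choices:

* **Sequences are i.i.d. uniform over residues.** No stage in scope reads
  sequence content except lengths and identities, so compositional
  realism would add nothing to what the tests can show.
* **Hit tables are generated directly.** The generator emits domtblout
  and tabular homology files with planted score distributions, which is
  what makes the pipeline testable without HMMER or LAST.
* **Score model.** Viral proteins draw their best viral bitscore from
  Normal(100, 8); planted cellular contigs draw cellular bitscores from
  Normal(60, 8). The 40-bit separation is comfortably above the 30-bit
  margin at which contaminant removal is exact, and is the regime the
  screening thresholds assume.
* **Bin plans.** Six default bins cover the decision space: full-marker
  pass (with a split PolB and a duplicated MCP), 4-marker pass, 3-marker
  fail, short-bin fail, singly-flagged, and a two-multi-copy reject. One
  phage and one cellular contaminant contig are planted per 8-contig bin.
* **Tree plan.** Three clades of 10 leaves; coalescent subtrees rescaled
  to depth 1 under a root at depth 5, so between-clade separation is five
  times the within-clade depth (at least the 3x ratio at which the sweep
  provably recovers the planted partition for any grid height between the
  two depths).
* **OG plan.** 120 OGs at background presence 0.1; 8 planted families
  present in every member of one clade at one or two copies, emulating
  clade-specific expansions. The copy-number component keeps the planted
  signal decisive for the rank-based test across seeds.
* **AAI plan.** Proteome pairs of 25 x 400 aa at 80% and 50% target
  identity; substitutions are uniform over the 19 alternative residues, so
  at 10,000 positions the realized identity concentrates within about
  +/-1 point of the target.

What the generator does **not** emulate: assembly and binning artefacts,
compositional signal, coverage, chimeric contigs, alignment uncertainty,
or database incompleteness. Passing the planted-truth suites therefore
demonstrates that the decision logic is implemented correctly under its
stated assumptions -- not that those thresholds are optimal for real
metagenomes.

## Problem sizes and determinism

The packaged test and acceptance runs use the default bundle (six bins of
4--8 contigs totalling 80--300 Kbp each, 30 tree leaves, 120 OGs, 25 x 400
aa proteome pairs) and a 2,000+-test null matrix for the type-I suite --
sizes chosen so a complete run takes well under a minute while every
decision branch of the pipeline is exercised. All randomness flows through
one seeded generator scoped with `withr::with_seed()`; identical seed and
configuration produce byte-identical bundles, and no function touches the
global RNG state.

## Known limitations

* Marker cutoffs default to a uniform 30 bits; real deployments should
  calibrate per model against curated reference proteins.
* The ultrametric transform is a simple terminal-branch stretch, not a
  rate-smoothing chronogram method; for published trees, supply a proper
  chronogram and the package will validate and use it unchanged.
* The normal-approximation enrichment p-values are inaccurate in the
  mid-range at very small clade sizes (see above); conclusions at
  q < 0.01 with clades above 5 members are unaffected, but exact tests
  would be preferable for borderline calls.
* AF masking uses the min-proteome denominator; against very incomplete
  MAGs the AF underestimates true genomic overlap.
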