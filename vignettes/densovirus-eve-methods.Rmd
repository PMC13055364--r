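---
title: "Mining and dating endogenous densovirus NS1 elements: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and dating endogenous densovirus NS1 elements: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleodens)
library(dplyr)
```

## The problem

Endogenous viral elements (EVEs) are viral sequences fixed in a host
germline — "molecular fossils" of ancient infection. Densoviruses
(Parvoviridae: Densovirinae; small linear ssDNA genomes) leave a
particularly tractable fossil: NS1, their largest and most conserved
nonstructural protein, carrying an SF3 helicase domain with ATPase and
endonuclease activities. paleodens implements the complete desk-side
workflow for studying such fossils in host genome assemblies: finding
NS1-like ORFs, confirming and cataloguing them, classifying them under
ICTV Parvoviridae demarcation rules, testing their chromosomal
integration via flanking-sequence composition, dating their divergence
with host-calibrated relative-rate trees, scanning for recombination,
and comparing structural domains.

Every stage is exercisable on synthetic assemblies with known ground
truth, so the pipeline's recovery, error rates and statistical
calibration are measurable without any downloads.

## The synthetic study

`simulate_assembly()` emulates the structure of a flatworm-genome EVE
survey: multiple host species, several contigs each, i.i.d. background
sequence, and planted NS1-like ORFs with the field's hallmark
composition — a coding region near 41.84% GC, a dramatically AT-rich
upstream flank (15.52% GC) and a moderate-GC downstream flank, 300 bp
flanks on both sides. Defaults are 10 species x 2 contigs x 100 kb with
30 planted loci, ORFs of 1,947 nt (648-residue proteins), and three
paralog groups.

Generator decisions worth knowing:

* **Lineage divergence.** A coalescent species tree (depth 0.25
  substitutions/site by default) is drawn once per simulation; tip NS1
  proteins evolve from a random root by per-branch Poisson substitution
  counts with uniform replacement residues. Within a species,
  non-paralogous loci get a small extra divergence (0.02 subs/site) so
  they are distinct; the first `n_paralog_groups` species instead carry
  byte-identical copies at all their loci, defining the paralog ground
  truth for deduplication.
* **Placement.** Each species' loci are planted on its first contig;
  the remaining contigs stay virus-free, giving clean negative controls
  for the false-locus rate.
* **Codon choice.** Planted ORFs are back-translated choosing only
  codons that translate identically under the standard code (table 1)
  and the flatworm mitochondrial code (table 9) — i.e. avoiding AAA,
  AGA, AGG and TGA — so the standard-code screening translation and the
  table-9 ORF re-translation both see the planted protein. The terminal
  stop is TAA (a stop in both tables).
* **GC targeting.** Synonymous codons are sampled with weights
  `q^k (1-q)^(3-k)` on their GC count `k`, with `q` solved by root
  finding so the expected coding GC equals the target; the realised
  mean lands within ~0.1 percentage points.
* **Start-anchoring.** An in-frame TAA is written immediately upstream
  of the planted ATG. Without it, an upstream in-frame ATG without an
  intervening stop would occasionally (roughly one locus in eight in
  AT-rich flanks) make the ORF finder report a 5'-extended start, which
  is correct behaviour for the finder but makes exact-coordinate truth
  comparisons ill-posed.
* **What is deliberately unrealistic.** Background is i.i.d. (no
  repeats, isochores or genes), there is no codon-usage realism and no
  element degradation. Passing tests therefore demonstrate the
  pipeline's correctness and calibration, not its robustness to
  pseudogenised or repeat-embedded elements.

## Screening and ORF mining

`search_ns1()` translates every contig in six frames (standard code)
and aligns candidate regions against the NS1 panel with exact
affine-gap Smith-Waterman (BLOSUM62; gap of length *k* costs
11 + *k*). Candidate regions come from a k-mer prefilter: frame/subject
pairs sharing at least two 6-mers, clustered and padded by the subject
length. The prefilter changes nothing on any confirmed locus (the
alignment window always contains the full hit) and keeps a
20 x 100 kb x panel search in minutes; exhaustive full-frame alignment
is available with `prefilter = FALSE`. Significance uses the
Karlin-Altschul expectation `E = K m n exp(-lambda S)` with the
standard gapped-BLOSUM62 parameters (lambda = 0.267, K = 0.041), and
hits with E above 1e-5 are dropped. Overlapping hits (> 50% of the
shorter interval) are merged keeping the higher score, ties breaking
toward the lexicographically smaller subject — one best subject per
locus by default.

`find_orfs()` then predicts ORFs on hit contigs under the flatworm
mitochondrial code (NCBI table 9 — AAA to Asn, AGA/AGG to Ser, TGA to
Trp): every maximal ATG-to-stop segment of at least 702 nt (a ~700 nt
floor rounded up to a codon multiple; the stop codon counts, the
protein excludes it), both strands, the 5'-most ATG per stop-bounded
segment. Contig-edge ORFs without an in-frame stop are excluded. A hit
is assigned to the ORF containing at least 80% of its interval (ties:
longer ORF, then smaller start); hits with no qualifying ORF are
dropped as degraded. Each ORF translation is confirmed against the
panel by local alignment, reporting identity over alignment columns
and subject coverage.

## Catalogue, demarcation and clades

`dedup_identical()` groups byte-identical proteins (paralogous copies)
keeping the lexicographically smallest locus id. Clade-level contrasts
of confirmation identity and coverage use classical one-way ANOVA and
Tukey HSD (no Welch correction), via the standard `aov`/`TukeyHSD`
machinery behind tidy wrappers.

`build_identity_matrix()` aligns all pairs globally (BLOSUM62, gap
opening 10, extension 0.2 — the conventional profile for this
comparison) after excluding proteins shorter than 400 residues, and
scores identity with the p-distance convention of sequence demarcation
tools: dual-gap columns excluded, gap-versus-residue columns counted
as differences (`ignore_gaps = TRUE` for the alternative). Pairwise
alignment (rather than a trimmed MSA) is used because the matrix is a
pairwise-comparison object; `trim_columns()` provides the 50%
consensus-support trimming rule separately for users preparing MSAs.
Display order comes from a midpoint-rooted neighbour-joining tree on
`100 - identity` — presentation plumbing, not an inference.

Demarcation (`classify_pair()`) applies the ICTV Parvoviridae rules to
NS1: same species requires identity > 85% with coverage > 80%; the
genus floor defaults to 35% (the lower end of the published 35-40%
range, surfaced as a parameter); below it, sequences are distinct.
`flag_novel()` marks a sequence under 75% identity to all others as a
candidate new species. Clade labels, when no external phylogeny is
supplied, come from single-linkage clustering of the identity matrix
cut at 55% — a deliberately transparent stand-in for a Bayesian tree,
which is out of scope.

## Flanks and integration evidence

`extract_flanks()` takes 300 bp on each side of a locus, truncated at
contig edges, oriented by the ORF (for minus-strand loci the upstream
flank is the genomic right side, reverse-complemented). GC uses only
unambiguous A/C/G/T in numerator and denominator. `flank_stats()`
contrasts coding-region GC against the locus's own upstream flank with
a paired two-sided t-test — the pairing the integration argument
implies — computed directly so the degenerate all-equal case returns
t = 0, p = 1. Flanks shorter than 50 nt are reported but excluded from
the test (their GC variance is too high to be informative).

## Relative-rate dating

`reltime_heights()` implements the core relative-rate recursion on a
rooted tree with branch lengths, top-down: at each node, a child
lineage's length is its stem branch plus the mean root-to-tip path in
its (already corrected) subtree; children receive relative rates
`r_i = k L_i / sum(L)` and every branch in the child's subtree is
divided by its rate before recursing. On a clock tree all rates are
exactly 1 and heights equal depths. Heights are corrected mean
tip-paths, normalised to root = 1. Confidence intervals and the full
estimator's rate-merging heuristics are not implemented; polytomies
are resolved with zero-length branches. The input tree is expected
from an external ML analysis (newick); the NJ ordering tree from the
identity matrix can serve as a clearly-labelled stand-in inside
`run_pipeline()`.

`exclude_outgroup()` removes the outgroup side of the root from the
timed node set — ingroup rates are not assumed to transfer — keeping
the ingroup MRCA timed. `calibrate_tree()` converts relative heights to
MYA by least squares through the origin over point calibrations
(`scale = sum(t a) / sum(t^2)`), the simplest estimator consistent with
multiple adjusted host divergence times; maximum-age calibrations are
checked post hoc and violations reported.

Accuracy is assessed under clade-wise rate multipliers (three random
subtrees scaled by 2.0, 0.5 and 1.5 on 32-tip coalescent trees): this
is the lineage-rate departure the relative-rate framework models and
corrects; with it, the median node-age relative error stays under 5%.
I.i.d. per-branch rate noise is a different regime that no lineage-rate
method can fully correct at cherry nodes.

## Recombination

Three detectors with permutation significance:

* `maxchi()` — over sites where the parents differ and the recombinant
  matches one of them, the 2x2 chi-square of parent-A/parent-B matches
  in 10-site windows either side of each candidate breakpoint,
  maximised; p by site-order permutation, `(1 + #{perm >= obs}) /
  (n_perm + 1)`.
* `chimaera()` — the same engine on the compacted match vector (sites
  where the recombinant differs from exactly one parent).
* `bootscan_like()` — window-wise p-distances to each candidate with a
  nearest-parent track and persistence-2 switch calls. Significance
  permutes window order, so windows are non-overlapping by default
  (window = step = 100 columns): overlapping windows are serially
  correlated and permuting them is anti-conservative (measured type-I
  error several times nominal), so with step < window the track is
  display-only and the p-value is withheld. The statistic is the
  largest left/right contrast, over split points and candidate pairs,
  of the window-wise distance difference — continuous, so the
  achievable p granularity is set by the permutation count rather than
  by run-length combinatorics.

`scan_triplets()` enumerates all (recombinant, parent-pair) triplets
after collapsing duplicate sequences, Bonferroni-corrects across
triplets x methods (the published "corrected P" without committing to
one tool version's exact correction), and accepts an event only when
at least `consensus_min = 3` methods are individually significant —
with three detectors, unanimity. This is deliberately stricter than a
3-of-7 rule over seven detectors; the four other published detectors
are out of scope. Permutations default to 1,000 and are seed-controlled
(the test suite uses 200, which still resolves the Bonferroni
threshold for a 3-sequence scan: 1/201 x 9 < 0.05).

## Structures

`kabsch_rmsd()` is the closed-form SVD superposition with the
determinant-sign correction (proper rotations only, no outlier
rejection — both "all-Calpha" and band semantics follow from that).
Similarity bands: <= 2.0 A highly similar, 2.0-3.0 A moderately
similar, > 3.0 A significantly divergent. `qc_filter()` applies strict
pTM > 0.5 and ipTM > 0.8 thresholds, retaining (with a message) models
lacking metadata. `screen_domain()` selects residues within 5 A of any
seed and prunes non-seed runs shorter than 3 residues; the default
ATPase-domain anchor is the Walker-A motif (`G-x(4)-G-K-[T/S]`) found
on the model's own sequence, since the spatial screen needs a
sequence-defined anchor and the P-loop is the canonical one. Toy
structure pairs from `make_structure_pair()` record the analytic
expected RMSD `sd * sqrt(3 (1 - 2/n))` (superposition fits six
rigid-body parameters).

## Numerical and design notes

* Alignment scores from the underlying C engine hold fractional gap
  penalties in single precision; tests compare at 1e-5.
* Permutation p-values use the add-one convention and are therefore
  never zero and slightly conservative.
* Problem sizes in the test suite (20 contigs x 100 kb end-to-end; 100
  oracle contigs; 20 x 20 flank replicates with a 400-replicate null;
  100 dating replicates; 200 recombination null replicates at 200
  permutations) were chosen as the smallest sizes at which the
  statistical claims are resolvable with comfortable margins.
* Known limitations: no degraded/pseudogenised EVE handling (no
  frameshift-aware reconstruction), no MSA inference, no Bayesian or ML
  tree estimation, no structure prediction; calibrations and trees are
  inputs.

## A worked micro-example

```{r example, eval = FALSE}
sim <- simulate_assembly(sim_config(
  n_species = 3, contigs_per_species = 2, contig_length = 2e4,
  n_loci = 6, n_paralog_groups = 1, seed = 42
))
loci <- mine_loci(sim$assembly, sim$panel)
dedup_identical(loci)
#> dedup report: 6 input, 5 unique, 1 duplicate group(s)

fs <- flank_stats(extract_flanks(loci, sim$assembly))
glance(fs)
#> t ~ 48 on 5 df, p < 1e-6: the coding region is ~26 GC points above
#> its upstream flank, the integration signature the generator planted.
```
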