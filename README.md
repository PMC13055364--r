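# paleodens

Mining and codivergence analysis of endogenous densovirus NS1 elements
in host genome assemblies.

Densoviruses (Parvoviridae: Densovirinae) are small ssDNA viruses of
invertebrates whose genomes occasionally integrate into host germlines
and persist as endogenous viral elements (EVEs) — "molecular fossils"
of ancient infection. The most durable fossil is NS1, the largest and
most conserved densovirus nonstructural protein (an SF3 helicase with
ATPase and endonuclease activities). paleodens is an R toolkit for
researchers studying such fossils — paleovirologists and parasite
genomicists — covering the whole desk-side workflow:

* **Screening** — six-frame translated homology search of contigs
  against an NS1 protein panel: exact affine-gap Smith–Waterman
  (BLOSUM62) on k-mer-seeded candidate regions, with Karlin–Altschul
  e-values `E = K·m·n·e^(−λS)` and a 1e-5 ceiling, one best subject per
  locus.
* **ORF mining** — ORF prediction under the flatworm mitochondrial
  genetic code (NCBI table 9: AAA→N, AGA/AGG→S, TGA→W), ≥ 702 nt,
  ATG start, both strands; hits assigned to their containing ORF and
  confirmed BLASTP-style against the panel.
* **Catalogue** — deduplication of byte-identical paralogs; clade-level
  identity/coverage statistics by one-way ANOVA with Tukey HSD.
* **Demarcation** — SDT-style pairwise identity matrices (p-distance
  convention: identity = 1 − p, gaps count as differences) and the ICTV
  Parvoviridae rules: same species iff NS1 identity > 85% with
  coverage > 80%; genus floor ≥ 35%; novel-taxon flag below 75%.
* **Integration evidence** — 300 bp flank extraction and the paired
  t-test of coding-region GC against each locus's own upstream flank.
* **Dating** — a relative-rate (RelTime-style) recursion converting
  non-clock branch lengths to relative node times, outgroup excluded
  from timing, calibrated to MYA by least squares through the origin
  over host divergence calibrations.
* **Recombination** — MaxChi, Chimaera and a BootScan-like
  nearest-parent track with permutation significance, Bonferroni
  correction across triplets × methods, and a ≥ 3-method consensus rule.
* **Structures** — Kabsch SVD superposition of Cα models (proper
  rotations only), 5 Å spatial domain screening anchored on the
  Walker-A motif, and RMSD bands (≤ 2 Å highly similar, 2–3 Å
  moderately similar, > 3 Å significantly divergent).

A first-class synthetic-data generator (`simulate_assembly()`) plants
NS1-like ORFs with known coordinates, paralogy, lineage divergence and
the hallmark GC architecture (≈ 41.8% coding, ≈ 15.5% AT-rich upstream
flank), so every stage is testable with ground truth and no downloads.

## Worked example

```r
library(paleodens)

sim  <- simulate_assembly(sim_config(
  n_species = 3, contigs_per_species = 2, contig_length = 2e4,
  n_loci = 6, n_paralog_groups = 1, seed = 42
))
loci <- mine_loci(sim$assembly, sim$panel)
loci[, c("locus_id", "start", "end", "strand",
         "confirm_identity", "confirm_coverage")]
#>   locus_id          start   end strand confirm_identity confirm_coverage
#> 1 species_01_ctg1_1  9255 11202 +                  77.3              100
#> 2 species_01_ctg1_2 13431 15378 +                  77.3              100
#> 3 species_02_ctg1_1  1502  3449 -                  80.6              100
#> ...
```

All six planted loci are recovered with exact coordinates; identity to
the nearest panel reference is ~77–81% at full coverage. Paralogous
copies collapse in the catalogue:

```r
dedup_identical(loci)
#> dedup report: 6 input, 5 unique, 1 duplicate group(s)
```

The integration signature — coding regions ~26 GC points above their
AT-rich upstream flanks — is recovered by the paired test:

```r
fs <- flank_stats(extract_flanks(loci, sim$assembly))
fs
#>   region     n  mean    sd
#> 1 left       6  15.6 2.17
#> 2 ns1        6  41.9 0.792
#> 3 right      6  44.2 1.87
#> paired t (NS1 - left flank): t = 38.973, p = 2.1e-07 (n = 6)
```

and demarcation calls follow the ICTV thresholds:

```r
classify_pair(c(99.6, 60, 25), c(100, 95, 90))$level
#> same_species  same_genus  distinct
```

`run_pipeline(pipeline_config(...))` chains the stages into a run
directory with per-stage TSV/FASTA/newick outputs and a summary JSON;
`autoplot()` methods draw the identity heatmap, clade boxplots, flank
GC contrasts and recombination tracks.

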