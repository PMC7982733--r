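---
title: "Fingerprint genotyping and hybrid inference with tbpfinger"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fingerprint genotyping and hybrid inference with tbpfinger}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbpfinger)
```

## The marker system

Tubulin-based polymorphism (TBP) is a multilocus, codominant PCR
fingerprint.  Every land-plant beta-tubulin gene carries two introns at
fixed positions, flanked by exon sequence conserved enough to design
universal degenerate primer pairs.  A single PCR per intron region
therefore amplifies one fragment per beta-tubulin locus (and per
distinguishable allele), and the fragment length is

    amplicon = intron length + flank constant of the region,

where the flank constant is the exonic sequence between the two primer
3' ends of that region.  For the primer geometry modelled here the
constants are 305 nt (first-intron region) and 232 nt (second-intron
region); they are the single most useful invariant of the system, since
they convert an observed capillary-electrophoresis (CE) peak directly
into an intron length and hence a candidate locus.  Intron-internal
microsatellites (e.g. CTT repeats) generate allelic length ladders
scattered by one repeat unit, plus the familiar stutter artifacts one
to four units below a true allele peak.

In duckweeds (Lemnaceae), where reduced morphology makes species
identification notoriously hard, these profiles separate most species
at a glance and — scored as binary marker matrices at single-nucleotide
CE resolution — resolve clones and, crucially, expose interspecific
hybrids: a hybrid's profile is close to the union of its two parental
profiles, it recovers each parent group's diagnostic (fixed private)
markers, and a diagnostic single-locus assay shows both alleles as a
doublet.

## Pipeline stages

The package implements each stage behind a small functional surface:

1. **Peaks** (`read_peak_table()`, `filter_peaks()`, `flag_stutter()`).
   Fragment-analysis exports are parsed into per-(sample, panel)
   profiles of (size bp, height RFU).  Filtering uses a minimum height
   and a closed size window; the AFLP defaults are 150 RFU and
   50–450 bp.  For CE-TBP no published threshold exists, so the same
   150 RFU default is used and both are configurable.  Stutter flagging
   marks any peak that has a taller peak `k` repeat units above it
   (`k <= 4`, ±0.5 bp size tolerance, strict height inequality); the
   default policy is *flag but keep*, because reproducible stutters
   carry genotype information — exclusion is an option
   (`bin_peaks(use_stutter = FALSE)`), not the default.
2. **Markers** (`bin_peaks()`, `matrix_stats()`,
   `fixed_private_markers()`, `group_mean_loci()`,
   `marker_inflation()`).  Peak sizes are clustered per panel by single
   linkage with a gap tolerance (0.5 bp default for CE-TBP, matching
   single-nucleotide resolution; 1.0 bp is typical for AFLP); each
   cluster becomes a binary marker labelled by its median size.
   Statistics follow the conventions of dominant-marker panel tables:
   TNM (total markers), NMM (monomorphic markers), PP = 100 (TNM −
   NMM)/TNM, per-group mean detected loci (NDL), fixed private markers
   (present in *all* members of one group, absent from *all* others)
   and pairwise percent marker-count inflation.  Printed-table rounding
   is half away from zero.
3. **Phylo** (`binary_distance()`, `p_distance()`,
   `neighbor_joining()`, `upgma()`, `bootstrap_support()`,
   `mantel_test()`, `write_newick()`/`read_newick()`).  All of these
   are implemented in the package rather than delegated, so that their
   conventions are fully specified; ape, vegan and `hclust()` serve as
   independent oracles in the test suite.  Conventions: Jaccard and
   Dice distances ignore joint absences; a pair with no scored markers
   gets distance 0 with a warning.  p-distance supports complete
   deletion (drop any column with a gap/ambiguity in *any* sequence)
   and pairwise deletion.  NJ uses the classic Q-criterion with a
   deterministic tie-break towards the lexicographically lowest leaf
   pair, and clamps negative branch lengths to zero transferring the
   deficit to the sister edge.  UPGMA is size-weighted average linkage
   with heights at half the merge distance.  Bootstrap resamples marker
   columns (or alignment sites) with replacement, 1000 replicates by
   default, and annotates each internal edge of the point tree with the
   percentage of replicates containing the same bipartition (clade for
   rooted UPGMA trees); the customary "show values ≥ 30" is display
   only.  The Mantel test correlates the n(n−1)/2 off-diagonal pairs
   and permutes one matrix's rows/columns jointly, one-tailed,
   `p = (1 + #{r_perm >= r_obs})/(B + 1)` with `B = 999` by default.
4. **In-silico PCR** (`expand_iupac()`, `find_primer_sites()`,
   `predict_amplicons()`, `assign_peaks()`).  Degenerate primers are
   IUPAC strings; site search matches any expansion on either strand
   with a configurable mismatch budget (0 by default; an `N` in the
   subject never matches).  Every (+ forward, − reverse) pair with a
   positive span below a 2000-nt cap (the scored size range of the
   study data tops out below 1300 nt) yields a predicted amplicon;
   nested predictions are flagged.  Peak-to-locus assignment takes the
   nearest prediction within ±3 bp — the largest CE-vs-predicted
   discrepancy observed across the forty annotated locus/region
   reference rows shipped with the package — and re-tests unmatched
   peaks against predictions shifted by whole SSR units (up to 10),
   flagging such matches as allelic variants.  Reported coordinates
   are 1-based inclusive, the R/Bioconductor convention.
5. **Hybrid inference** (`partition_origin()`, `union_coverage()`,
   `diagnostic_genotype()`, `call_hybrid()`).  See below.
6. **Synthetic data** (`make_species_model()`, `derive_clone()`,
   `make_hybrid_clone()`, `simulate_electropherogram()`,
   `simulate_aflp_panel()`, `simulate_tbp_study()`).  See below.

## Operationalizing the hybrid argument

The qualitative hybrid signature — "the profile is an almost perfect
merge of the two parents" — is made explicit with three statistics
computed against two parental clone groups:

* **union coverage**: fraction of the candidate's markers present in
  the union of the two parental reference sets (each reference set is
  the union of member profiles);
* **parental recovery** (per group): fraction of the group's
  *diagnostic* markers — fixed in that group and absent from the other
  — that the candidate carries;
* **marker inflation**: percent excess of the candidate's marker count
  over each parental group mean.

The verdict is `hybrid` iff both recoveries reach 0.8 and coverage
reaches 0.9; `parent_X_like` iff one recovery is ≥ 0.8 and the other
≤ 0.2; otherwise `inconclusive`.  The thresholds are engineering
choices on a qualitative argument: 0.8 tolerates realistic per-marker
dropout (10% leaves expected recovery near 0.9) while staying far from
the ≈ 0 recovery of a non-parent; 0.9 coverage tolerates a handful of
candidate-private markers such as hybrid-specific rearrangement
products.  Inflation is reported but never gates the verdict, because
it is confounded by per-clone marker yield.  Markers monomorphic
between the two parental groups are excluded from diagnostic sets by
construction (they are fixed in both, private to neither) and thus
never contribute to recovery — the report's class counts make this
visible.  A codominant length fingerprint cannot distinguish a
homoploid hybrid (AB) from an allotetraploid (AABB); the report makes
no ploidy claim.

`diagnostic_genotype()` encodes the companion single-locus assay: with
two known allele sizes (463 nt for the A-type allele, 436 nt for the
B-type in the shipped defaults), peak sets are read as AA / BB / AB
(the hybrid doublet) / null with a ±3 bp tolerance.

## What the generator emulates — and what it does not

The synthetic module is first-class, tested code; it exists so that
every downstream stage can be exercised with known truth and no
external data.

`make_species_model()` draws, per species, a set of beta-tubulin locus
templates: three exons, two introns at fixed positions, universal
primer sites embedded verbatim at the exon–intron borders (synthetic
21-mers, *not* the real universal primers, which are not distributed
here), reference intron lengths drawn without collision (so a model's
predicted amplicons are distinct), and a CTT microsatellite inside
intron 1 of a configurable fraction of loci (default 0.5) with an
allele pool of ±2 repeat units around the reference.  Default intron
ranges (80–520 nt region 1, 60–450 nt region 2) put amplicons in the
~350–950 nt span where the real profiles live; locus counts of 4–12
match observed per-clone band counts.  `derive_clone()` realizes
diploid clones and applies allelic InDel variants as whole-repeat-unit
shifts; `make_hybrid_clone()` builds homoploid (one haplotype per
parent) or allotetraploid (both full sets) hybrids, whose marker set is
the union of the contributed haplotypes by construction.

`simulate_electropherogram()` emits one main peak per distinct
predicted amplicon.  The detected size adds a rounded Gaussian error
bounded to ±3 nt that is derived from the *clone's* identity and seed,
not from the call's seed — so replicate amplifications of one clone
agree, mimicking the high repeatability of the real assay (two
independent amplification batches of the study correlate at Mantel
r = 0.95); a separate `replicate_noise_sd` knob exists to degrade
repeatability deliberately.  Heights are log-uniform in 500–30,000 RFU
(the usable dynamic range of a capillary instrument above the noise
floor); stutter peaks appear 1–4 repeat units below SSR-bearing main
peaks with height a Beta(2,5)-distributed fraction of the main peak
capped at 0.6 and shrinking with the offset — always strictly below
their main peak, never above it in size.

`simulate_aflp_panel()` plants a binary matrix with known classes:
shared markers, per-group fixed private markers, within-group
polymorphic markers, optional hybrid rows built as the union of one
random member profile per parent group plus planted hybrid-private
markers, and i.i.d. per-cell dropout applied last as observational
noise.  With zero dropout and no hybrid group the planted fixed-private
counts are recovered exactly by `fixed_private_markers()`; with a
hybrid group present the parental fixed-private counts shrink, exactly
as in real data where the hybrid group shares them.

The generator does **not** emulate: continuous electropherogram traces
(peak lists only), size-standard calibration or allele binning drift,
co-migration of unrelated loci, chromosome-level read data, plastid
markers, or any sequence evolution beyond SSR unit shifts (exons and
intron flanks are fixed within a species).  Passing tests therefore
demonstrate the correctness of the scoring, tree, assignment and
hybrid-inference machinery under the stated noise model — not the
field performance of the wet-lab assay.

## Numerical choices and degenerate inputs

* Binning uses single linkage on the line, so clusters are runs split
  at gaps > tolerance; a cluster spanning more than 5× tolerance
  triggers an over-merge warning.  Tolerance 0 keeps every distinct
  size separate.
* NJ/UPGMA tie-breaks are deterministic (lowest label pair), so fixed
  seeds give bit-identical trees; duplicate taxa form zero-length
  cherries.
* A clone pair with no scored markers (a + b + c = 0) gets distance 0
  with a warning rather than NaN.
* Mantel p is bounded below by 1/(B + 1); permutation comparisons use
  a 1e-12 slack so ties count as ≥.
* `p_distance()` errors when no column survives complete deletion.
* Percentage polymorphism is reported from its definition,
  100 (TNM − NMM)/TNM.  For the shipped study-scale panel table this is
  97.5%; the originally printed "100"/"99.98" values are mutually
  inconsistent and are not reproduced.  Likewise the shipped per-panel
  NDL entries are integers rounded for printing, so group grand means
  are taken from the group NDL totals (60.0, 60.4, 79.4, 56.4 over ten
  panels), which reproduce the printed inflation percentages 41/31/32.

## Problem sizes used by the test suite

The suite favours many small randomized instances over few large ones:
additive/ultrametric tree recovery at n ≤ 8–9 taxa, exhaustive Mantel
enumeration at n = 4 (24 permutations) against 1999 Monte-Carlo draws,
brute-force fixed-private scans on 6-clone matrices, and 500 simulated
hybrid/parent/unrelated trios (two parental triplets, 60 shared + 100
fixed-private markers per parent + 30 group-polymorphic markers, 8
hybrid-private markers, 10% dropout) for verdict recovery.  The
100-per-group diagnostic scale reflects a two-species comparison at the
scale of the reference AFLP panel (1,619 markers across ten primer
combinations with between-group Dice similarities of roughly
0.22–0.29); four-group fixed-private counts such as 44/26 are
necessarily smaller than two-group diagnostic sets and would understate
the available signal.

## Known limitations

* Real CE size calibration can drift systematically with fragment
  length; the ±3 nt assignment tolerance absorbs the observed range
  but is not a calibration model.
* Homoplasy (co-migrating unrelated fragments) is not simulated, so
  binary-distance saturation behaviour is milder in synthetic panels
  than in deep real comparisons.
* The hybrid caller assumes the two parental groups are correctly
  delimited and sampled; with very small or noisy groups the strict
  fixed-private diagnostic definition can empty out — a
  frequency-relaxed alternative is left to the caller by pre-filtering
  markers, and recovery is reported as `NA` when a diagnostic set is
  empty.
* Bootstrap support on dominant binary markers is known to be
  conservative for shallow splits; values are reported unfiltered.
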