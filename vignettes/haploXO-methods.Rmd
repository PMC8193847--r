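---
title: "Methods: SNP-density crossovers, dimorphic TEs and haplotype shuffling"
author: "haploXO"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP-density crossovers, dimorphic TEs and haplotype shuffling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haploXO)
```

## The scientific problem

Phased haplotype assemblies of the human MHC class II region are
mosaics: long blocks inherited essentially intact from a small number
of ancestral haplotypes, exchanged by historical recombination.  When
two present-day haplotypes are aligned, blocks of shared ancestry are
nearly SNP-free (SNP-poor, < 10 SNPs/100 kb), while blocks descending
from different ancestral haplotypes are SNP-dense (SNP-rich,
> 50 SNPs/100 kb).  The junction between a SNP-rich and a SNP-poor
block — operationally, the last identifiable SNP of the rich block —
is a *SNP-density crossover* (XO), a footprint of an ancestral
recombination event.  Alongside XOs, presence/absence (dimorphic)
transposable-element (TE) insertions act as bi-allelic
identity-by-descent markers, and short PRDM9-associated sequence
motifs (`CCTCCCCT`/`AGGGGAGG` activating, `ATCCATG`/`CATGGAT`
suppressing, and the degenerate 13-mer `CCNCCNTNNCCNC`) mark where
meiotic recombination is promoted or inhibited.

haploXO re-implements this comparative analysis as a deterministic,
testable pipeline: pairwise co-linear comparison of ~0.6 Mb haplotype
sequences, SNP extraction with explicit exclusion rules, windowed
density segmentation with XO calling, dimorphic TE genotyping from
RepeatMasker annotations, motif scanning with repeat-overlap
classification, multi-locus haplotype/linkage tabulation, and a
p-distance neighbor-joining phylogeny of allele panels.

## Pairwise comparison of near-identical long sequences

Published analyses of this kind used interactive web aligners; haploXO
replaces them with MUM-style anchoring, standard for near-identical
genomes:

1. **Anchors** (`find_anchors`): maximal exact matches seeded by
   k-mers (default *k* = 31) that occur exactly once in *each*
   sequence and contain no `N`.  Uniqueness in both sequences protects
   against repeat-induced false anchors — more than half of the target
   region is repeats.
2. **Chaining** (`chain_anchors`): the maximum-total-length strictly
   co-linear subset (weighted longest-increasing-subsequence), with
   residual overlaps trimmed.  Inversions are out of scope: a large
   inversion simply surfaces as an unaligned block.
3. **Gap closing** (`close_gaps`): inter-anchor gaps with both sides
   ≤ 5 kb are globally aligned with affine-gap scoring (match +1,
   mismatch −1, gap open −4, extension −1 per position); one-sided
   gaps need no alignment and larger two-sided gaps are labelled
   `unaligned`.  The affine-gap dynamic program itself is delegated to
   `Biostrings::pairwiseAlignment`; the package's own vectorised
   implementation of the same scoring (`align_global`) is kept for
   allele-identity computation and as an internal cross-check.
4. **Variants** (`extract_variants`): mismatched aligned columns
   become SNPs; gap runs become one insertion/deletion record each,
   left-normalised against their local sequence context (the standard
   VCF convention) so that tie-equivalent gap placements yield one
   canonical representation; maximal `N` runs are recorded as `N_run`
   records; unaligned blocks yield a deletion/insertion pair record.
   Indel positions adjacent to tandem repeats remain
   alignment-convention-dependent in principle, which is why the test
   suite compares variant *sets* after normalisation rather than
   asserting gap placement.

All coordinates are 0-based half-open internally; conversions to
1-based inclusive RepeatMasker coordinates happen only at file
boundaries.

## SNP exclusion rules

The source analysis counted SNPs manually, twice, and averaged,
excluding obvious artifacts.  haploXO codifies that judgment as
deterministic rules (`filter_snps`), applied to the variant table:

* **cluster rule** — any sliding 50-nt span containing more than 5
  SNPs excludes *every* SNP in the span (≤ 5 SNPs is kept; the bound
  is strict);
* **proximity rule** — SNPs within 50 bp (inclusive) of an `N` run
  (≥ 5 bp) or a long indel (≥ 100 bp) are excluded;
* **microsatellites** — SNPs inside simple-repeat intervals are
  excluded; intervals come from `Simple_repeat` annotation features
  when an annotation is supplied, otherwise from the internal
  perfect-tandem detector (`detect_simple_repeats`: unit ≤ 6 bp
  spanning ≥ 12 bp, homopolymers ≥ 8 bp);
* **unaligned blocks** — SNPs cannot be called there, and indel and
  `N`-run records are never counted as SNPs.

"Obvious assembly errors" are operationalised as exactly these
enumerable artifact classes; no further heuristic is applied.
Filtering is idempotent.

## Density segmentation and XO calling

Kept SNPs are profiled in 500-nt windows (`density_profile`, the
plotting resolution used for density figures) and segmented
(`classify_segments`) with a 10-kb sliding window stepped at 1 kb.
Windows are labelled rich (> 50 SNPs/100 kb), poor (< 10 SNPs/100 kb)
or intermediate.  Intermediate runs are not a third class — the
two-class description has no third label — so they are absorbed into
the adjacent run with the nearer density (ties to the preceding run);
runs shorter than 20 kb are absorbed into the longer neighbour.  Each
surviving rich/poor boundary is then refined to the exact two-rate
Poisson maximum-likelihood change point over the kept SNP positions of
the two adjacent segments (profile likelihood over every candidate
split).  Final segment labels reflect the realized segment densities,
which guards against window-level noise promoting intermediate-density
spans and makes the rich span monotone non-increasing in `rich_min`.

`call_xos` emits one XO per rich/poor adjacency at the kept SNP inside
the *rich* segment nearest the junction — the "last identifiable SNP"
of the rich block read from the rich side.  Reading the junction from
the poor side is exposed as an option (`side = "poor"`) because the
published phrasing is ambiguous.  `xo_summary` tabulates XO counts per
pair (0/1/2/3/4+), the total, and the number of unique XO sites after
merging positions within 1 kb (the published "unique sites" count
states no radius; 1 kb is this package's choice and a parameter).

With rates of 80 vs ≤ 5 SNPs/100 kb and segments ≥ 50 kb, the ML
change point almost always falls in the SNP gap containing the true
ancestor switch, so the called XO coincides with the true boundary
SNP.  The residual failure mode is a locally SNP-sparse stretch at the
edge of a rich block, which shifts the ML split by a few kb; this is
why recovery is asserted as a ≥ 95% rate rather than exactness.

## Dimorphic TE calling

The published catalog was built by eye from the "periodic positions"
of repeats across RepeatMasker outputs.  haploXO codifies it:

1. `match_annotations` pairs features of two haplotypes by identical
   repeat name and strand.  With a co-linear map, positions are
   projected and paired greedily within `tol` (500 bp).  Without a
   map, pairing is the maximum strictly co-linear chain over all
   same-name candidates (longest increasing subsequence in both
   coordinate orders).  The chain formulation absorbs the arbitrary
   coordinate drift that indels introduce — a running-offset greedy
   scheme was rejected because any indel larger than `tol`
   desynchronises every downstream feature.
2. `call_dimorphic_te` merges unmatched features closer than 200 bp
   into one candidate locus — this is what keeps a composite indel
   (e.g. a 7-kb mosaic annotated as ten family members) a single
   locus — and requires a paired flanking feature on each side within
   10 kb plus a minimum length of 100 bp.
3. `call_dimorphic_panel` runs every haplotype pair and unifies
   candidates whose flank anchors coincide (same flank names, anchor
   positions within 1 kb in a shared coordinate frame), reporting a
   presence/absence matrix.  Elements present in every haplotype are
   monomorphic and yield no call; haplotypes with no evidence either
   way are `NA`.

## Motif scanning and classification

`scan_motifs` matches literal or IUPAC-degenerate patterns
strand-explicitly on the forward strand (each motif and its reverse
complement are separate entries whose hits are never merged), with
overlapping occurrences reported and `N` matching nothing.  Matching
uses `Biostrings::matchPattern(fixed = "subject")`; the test suite
checks it position-by-position against a brute-force scanner.
`classify_motif_overlap` assigns each hit to the overlapping
annotation feature covering the largest part of its span (ties to the
lower-start feature; hits with no overlap are "Non-repeat region").
Plurality overlap was chosen over midpoint assignment because 7–8-mers
can straddle feature edges.  The count matrix (categories × motifs)
has column sums equal to per-motif hit counts by construction.

## Linkage and phylogeny

`tabulate_haplotypes` groups records by their allele-label tuple over
selected loci; `GAP` (unresolvable locus) is an ordinary label, and
records missing a locus are dropped and reported.
`linkage_percentages` gives contingency counts and row percentages,
excluding `GAP` rows.  `assign_allele` labels a query by exact match,
else by best library identity ≥ 99% over ≥ 90% length coverage
("novel"), else `GAP`; the two thresholds are this package's own
choice (the published analysis assigned novel alleles without stating
criteria) and are parameters.

`p_distance_matrix` computes uncorrected p-distances on equal-length
sequences, skipping columns with `-` or `N` in either member of a
pair.  Multiple sequence alignment is out of scope; length-mismatched
alleles fall back to the package's pairwise global aligner.
`neighbor_joining` is a deterministic Saitou–Nei implementation:
Q-criterion minimisation with ties broken toward the
lexicographically smallest taxon pair, negative branch lengths clamped
to zero with the deficit logged.  NJ is exact on additive matrices,
which the tests exploit (random additive trees must be reconstructed
with path-length error ≤ 1e-9, cross-checked against `ape::nj`).

## The simulator and what it does (not) emulate

`simulate_panel` builds haplotype panels as mosaics of ancestral
blocks on a shared base coordinate frame:

* Ancestor sequences differ from an i.i.d.-uniform base sequence at
  rate `branch_divergence − background_divergence` per site, and each
  haplotype adds private substitutions at `background_divergence`, so
  a pair has expected density `2 × branch_divergence` (default
  2 × 4e-4 = 80 SNPs/100 kb) in unshared blocks and
  `2 × background_divergence` (default 4/100 kb) in shared blocks —
  the study's rich/poor regimes.  The residual divergence of shared
  blocks is not published; 2e-5 per branch is a modelling choice
  exposed as a parameter.
* Substitutions are drawn by binomial thinning and never placed inside
  planted motif/TE/noise spans; SNP truth is then computed by *direct
  comparison* of the final sequences, so it is exact by construction
  rather than by bookkeeping of intentions.
* Planted artifacts exercise each filter: SNP clusters (8
  substitutions in 40 bp, violating the >5-in-50-nt rule), `N` runs
  (200 bp), microsatellite tracts (60 bp, written into every
  haplotype, with 2 substitutions planted inside one haplotype) and
  long deletions (1 kb).
* TE presence/absence uses a fixed synthetic library (Alu-, SVA- and
  LTR-sized elements plus a 7-kb mosaic of ten member parts).
  Insertions and deletions give each haplotype its own coordinate
  frame; an explicit monotone map (`map_to_hap`/`map_to_base`) records
  truth in both frames.
* Annotations are emitted directly in the RepeatMasker `.out` dialect
  — planted TEs, microsatellite tracts, and decoy features drawn from
  a small catalog at 1 feature per 1.5 kb, matching the observed
  density of roughly 1200 interspersed repeats per Mb in the region.
  Decoys are shared across haplotypes and double as flank anchors for
  dimorphic-TE calling.
* Planted motif copies are written into every haplotype (inside or
  outside decoy repeats on request), and spurious occurrences of any
  planted pattern are screened out by point mutation, so the motif
  truth set is the complete hit set.

The simulator does **not** emulate: coalescent or recombination-rate
realism (blocks and rates are specified, not evolved), sequencing
error or read data, inversions/duplications, repeat sequence content
(decoy annotations are labels, not homologous sequence), or HLA allele
nomenclature.  Passing tests therefore demonstrate algorithmic
correctness under the stated block/rate model, not performance on real
assemblies with assembly-specific artifacts.

## Problem sizes and numerical choices

The test and acceptance suites run at the study's own scales chosen as
a deliberate compromise: pairwise XO recovery on 50 simulated 600-kb
pairs with 1–4 breakpoints and segments ≥ 50 kb; aligner–oracle
equivalence on 200 random 2-kb pairs at 1% substitutions with up to
two ≤ 50-bp indels; TE recovery on twenty 5-haplotype panels of 300 kb
with 10 planted loci including the 10-member mosaic; NJ on 100 random
additive matrices of 4–10 taxa.  Degenerate inputs are defined
explicitly: a span with no kept SNPs is a single poor segment; `k`
larger than a sequence yields no anchors (not an error); an empty
allele library is an error; fewer than three taxa is an error.

## Known limitations

* XO positions are only as precise as the local SNP supply; a sparse
  stretch at a rich-block edge can displace the ML change point by a
  few kb.
* Dimorphic-TE calling requires flanking shared features within 10 kb;
  a locus in an annotation desert is not callable (tunable via
  `flank_window`).
* The comparator does not call inversions or duplications; such
  regions surface as unaligned blocks and are excluded from SNP
  counting, mirroring the "A" artifact flags of the original density
  plots.
* Identity thresholds for novel-allele assignment, the unique-XO merge
  radius, and the intermediate-density absorption rule are
  package-defined conventions where the publication is silent; all are
  exposed as parameters.
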