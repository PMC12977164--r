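---
title: "tetradiv: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tetradiv: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetradiv)
```

`tetradiv` analyses haplotype divergence in phased autotetraploid
assemblies. This vignette explains the statistical models behind each
stage, the parameters that matter with their defaults and units, what the
synthetic data generator does and does not emulate, and the numerical
choices made where the design was genuinely open. It states no empirical
result that the package's tests do not themselves compute.

## The synthetic tetraploid world

`simulation_config()` / `simulate_tetraploid()` generate an
autotetraploid dataset from one ancestral genome evolved along a fixed
4-branch topology: root → two lineage ancestors → the haplotypes
({H1, H2} and {H3, H4} by default). Branch substitution intensities are
chosen so that the *expected pairwise* SNP density equals the configured
rates:

- `within_lineage_snp_rate` (default 1e-3 substitutions/bp): expected
  H1–H2 and H3–H4 density; each terminal branch carries half.
- `between_lineage_snp_rate` (default 1e-2): expected cross-lineage
  density; each root branch carries (between − within)/2.

SNP counts per branch are Poisson(rate × length) at distinct positions,
so for a chromosome of length L the pairwise truth SNP count is Poisson
with mean rate × L — the property the tests check at 3 SD. InDels are
generated at `indel_fraction` (default 0.1) of the event rate and are
*position-preserving*: they are recorded in the truth tables but not
applied to coordinates, so downstream window densities need no
whole-genome alignment. This substitutes for the alignment step that is
out of scope here.

**Layered divergence.** Divergence is split into two layers that keep the
emitted FASTA, GFF3 and truth CDS-pair tables mutually consistent:

1. *Intergenic* sequence evolves by the uniform per-bp process above; the
   process never touches annotated CDS.
2. *Coding* sequence diverges only at the lineage split, via
   `evolve_cds_pair()` at the configured `target_dS`/`target_dN`
   (defaults 0.02 / 0.005 — the scale of a very recent WGD). Haplotypes
   within a lineage therefore carry identical CDS.

The uniform-rate model is a stand-in, not an inference about any real
genome; the generator's defaults are the stated world of the package's
tests (two lineages an order of magnitude apart in SNP density,
background copy retention 0.913 with 0.984 for a tagged pathway set,
~60% TE coverage, and per-tissue ASE designs whose haplotype-dominant
totals are 2.2/2.4/1.7/1.5% across stem, root, tuber peel, tuber flesh).
The biallelic vs higher-one-allele split within the remaining mass is not
externally constrained; 80% biallelic was fixed once as a realistic
choice for a recently duplicated genome with little expression
divergence.

What the generator does **not** emulate: read-level noise (no FASTQ),
recombination, realistic TE families or nested insertions, coordinate
shifts from InDels, and expression count overdispersion (TPMs are drawn
directly in class-consistent ranges). A green test therefore establishes
correctness of the *analytics* on data with known truth — not robustness
to alignment error or quantification noise.

### Target interpretation in `evolve_cds_pair()`

Targets are substitutions per site *after* Jukes–Cantor correction. The
substitution quota per class is `round(p × sites)` with
p = ¾(1 − exp(−4/3 d)) — the inverse of the JC map. Placing `d × sites`
raw substitutions instead would make the downstream NG86 + JC estimator
overshoot by the correction factor (≈ +16% at d = 0.2), which would
contradict the estimator-recovery property the package tests. At most one
substitution lands per codon, so realized synonymous/nonsynonymous counts
are recovered exactly by diffing the two sequences codon by codon; the
total quota must not exceed the codon count (a `simulation error`
otherwise, as is a positive dS target on a CDS with no synonymous sites).
Proposals that would create a stop codon are rejected.

### Expression margins

`simulate_expression()` draws TPMs at least 10% away from every decision
boundary (expressed means TPM > 2.2 or < 1.8; folds ≤ 1.8 or ≥ 2.2), so
floating-point noise can never reclassify a designed label. Class counts
per tissue use largest-remainder allocation: realized fractions equal the
design exactly at integer granularity, which is what makes the
closed-loop classifier test exact rather than statistical.

## Synteny and retention

`chain_anchors()` forms maximal runs of one-to-one anchors consecutive in
gene rank on both genomes with a consistent orientation (+1/+1 or +1/−1
per step). Ranks are gene-order indices among *all annotated genes* on
the chromosome, so a lost gene on one side breaks the run — exactly the
fragmentation the consolidation rule is meant to heal.

`consolidate_blocks()` merges blocks separated by `< 50` genes **or**
`< 300000` bp. Two open points were resolved as follows:

- *"in either genome"* is read as: the disjunctive gap condition must
  hold in **both** genomes (each genome passes at least one threshold).
  Merging on one genome's proximity alone would bridge large structural
  gaps. The one-genome reading is available via `either = TRUE`.
- Thresholds are strict inequalities exactly as printed; a 50-gene /
  300-kb gap does not merge.

Merging is the transitive closure of the pairwise predicate (union–find),
verified in tests against an independent boolean-closure oracle, and is
idempotent. Only same-orientation blocks merge, preserving collinearity.

`retention_rate()` is the exact ratio polyploid syntenic genes /
(diploid syntenic genes × ploidy); when a polyploid gene hits multiple
blocks it is counted once (distinct gene ids). Per-set rates in
`pathway_retention()` restrict the anchor pairing to a diploid gene-id
set; an empty or disjoint set yields `NA` with a warning, never 0.

## Variant densities and lineage clustering

`window_density()` uses 0-based half-open windows
[i·step, i·step + window); the last partial window is dropped, giving the
closed-form count ⌊(L − w)/s⌋ + 1. Defaults follow the window schemes
typical for this analysis (300 kb for variant density; 200 kb and 500 kb
appear in the same literature for gene density and genome overviews).
With step = window the window sums plus the dropped tail conserve the
total feature count, which is tested as a property.

`cluster_haplotypes()` substitutes UPGMA on SNP+InDel count distances for
maximum-likelihood tree building, which is out of scope: the acceptance
surface is *partition recovery*, not branch lengths. Labels are sorted
before clustering so merge ties resolve deterministically (warned when
all distances are equal); for four haplotypes the k = 2 cut defines the
lineage partition. InDels count as single events regardless of length.
Both raw counts and counts normalised by an aligned length are supported,
since the normalisation used for published heatmaps is generally
unstated.

## Ka/Ks and WGD peaks

`ng86_sites()`/`ng86_differences()` implement the Nei–Gojobori (1986)
counting method: per codon, the synonymous site count is (synonymous
single mutants)/3, with mutants to stops counted nonsynonymous, so
syn + nonsyn = 3 exactly; per codon pair, step counts average over all
orderings of the separating substitutions. Orderings through stop codons
are excluded when a stop-free ordering exists; otherwise (and under
`stop_paths = "include"`) all orderings are averaged with stop-touching
steps counted nonsynonymous. Which convention the field's calculators
apply is rarely documented, hence the flag. Codons containing gaps,
ambiguity codes or stops in either sequence are dropped pairwise
(standard practice); at least 10 comparable codons are required
(configurable).

`kaks_pair()` averages site counts over the two sequences, then corrects
pS and pN with the Jukes–Cantor map. Proportions at or beyond 3/4 yield
`NA` flagged "JC correction domain" — never a fabricated number. Ka/Ks is
undefined when Ks = 0.

`detect_ks_peaks()` estimates a Gaussian KDE on the fixed grid
[0, cutoff] with 0.005 spacing (saturation cutoff 3.0; values above it
stay in the record but not in peak detection). The bandwidth defaults to
Silverman's rule — a stated, overridable default, since no method is
externally fixed. Peaks are local maxima with topographic prominence at
least `min_prominence` (default 0.05) of the maximum density. Two
numerical choices matter here:

- **Edge convention**: a side on which the walk from a peak reaches the
  grid edge without meeting higher terrain does not constrain its
  prominence. Ks distributions are truncated at 0, and a very recent WGD
  puts the dominant mode within one bandwidth of the boundary; under the
  classic edge-bounded convention the shallow dip toward 0 would cap that
  mode's prominence near zero and the most important peak would be
  filtered out.
- **Degenerate samples** (zero variance, where Silverman's rule returns
  0) fall back to a 0.005 bandwidth so an all-identical input still
  yields its single peak at the common value.

A consequence of any prominence convention is that a structureless
(uniform) sample still reports its one broad plateau maximum; the tests
assert that no *additional* spurious structure appears.

`date_event()` is the algebraic map T = Ks/(2μ). μ is
lineage-specific and has no defensible package default, so it must be
supplied; dates produced by phylogenomic dating pipelines are not
reproduced here and are not targets.

## ASE classification

`classify_ase()` applies the printed threshold rules: expressed means
TPM strictly > 2; both expressed and fold < 2 → `biallelic`; both
expressed and fold ≥ 2 → `higher_one_allele`; exactly one expressed →
that haplotype's dominant class; neither → `not_expressed`. The source
rules leave fold exactly 2 unassigned ("less than 2-fold" vs "at least a
2-fold"); assigning it to `higher_one_allele` makes the two rules
partition the space, and the boundary is configurable. Fold is max/min of
the two TPMs (direction kept separately), undefined when either TPM is 0.
Fractions are computed over expressed rows with denominators reported.
Only the TPM rule set is implemented; count-model differential testing
(DESeq2-style FDR filters) is deliberately out of scope, which is why
cross-tissue "significant ASE" gene counts from such hybrid filters are
not targets.

`intersect_ase_sets()` computes all 2^k − 1 exclusive Venn regions on
gene-id sets restricted to the classes of interest (default: the two
dominant classes, i.e. haplotype-specific expression); region counts sum
to the union size by construction and are tested against a set-algebra
oracle. `compare_kaks_by_class()` is a Welch two-sample t-test
(`stats::t.test`, unequal variances), verified against a closed-form
oracle; undefined ratios are excluded with the count reported.

`scan_motif()` is a minimal IUPAC scanner (default motif `ACGTG`, the
ABRE ACGT-core bound by subfamily-A bZIP factors). It reports all
overlapping matches at 0-based positions, with reverse-strand hits mapped
to forward coordinates. It stands in for full cis-element catalogue
scans, which are out of scope.

## TE flank profiles

`flank_te_profile()` computes the TE-covered fraction per window over the
5-kb flanks of a gene (100-bp windows, 10-bp steps → 491 windows per
flank), orienting upstream as the 5′ side of the gene's strand and
excluding the gene body. Overlapping TE annotations are merged by union
before coverage, so nothing is double-counted (tested against a per-base
oracle). The bounded fraction is the primary statistic; the literal
TE:non-TE odds is emitted alongside because it is unbounded (undefined at
full coverage) — which of the two a published figure plots is typically
unstated, so both are available. Flanks truncate at chromosome ends;
truncated windows keep their effective length, and `average_profiles()`
pools covered/effective bases per window position, i.e. truncated windows
are weighted by effective length.

## Pipeline and reproducibility

`run_pipeline()` chains all stages on simulator output with one global
seed; stage-local seeds derive deterministically from it and all internal
seeding save/restores the caller's RNG state. Rerunning the same config
reproduces every deterministic report field byte-identically (tested).
Config files are JSON; YAML support was narrowed out because no YAML
parser is part of the declared dependency environment.

## Known limitations

- The simulator's uniform substitution model has no rate heterogeneity,
  GC bias or hotspots; lineage partition recovery on it is easier than on
  real data.
- Within-lineage haplotypes carry identical CDS, so Hap1–Hap2 coding
  divergence is zero by construction; only the between-lineage CDS layer
  is calibrated.
- `consolidate_blocks()` is O(n²) in block count per chromosome pair —
  fine for desk scale and typical per-chromosome block counts, not tuned
  for megablock inputs.
- NG86 is a counting method; codon-model ML estimators (GY94/YN00) will
  differ on saturated or highly biased pairs and are intentionally not
  provided.
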