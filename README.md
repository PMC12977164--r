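# tetradiv

Haplotype divergence analytics for phased autotetraploid genome assemblies.

Haplotype-resolved assemblies of autopolyploid plants (the motivating system
is a tetraploid yam with four phased haplotypes, Hap1–Hap4, of 20
pseudochromosomes each) raise a recurring set of questions:

- **Lineage structure** — do the four haplotypes fall into two lineages
  (Hap1/Hap2 vs Hap3/Hap4), as pairwise SNP/InDel densities would show?
- **Gene retention** — after whole-genome duplication (WGD), what fraction
  of the expected gene copies survives relative to a diploid relative, and
  are pathway gene sets (e.g. dioscin biosynthesis) preferentially retained?
- **WGD timing** — where do the peaks of the synonymous-divergence (*Ks*)
  distribution of collinear gene pairs sit, and what dates do they imply
  under *Ks* = 2μ*T*?
- **Expression balance** — are homologous alleles expressed evenly
  (biallelic) or is there allele-specific expression (ASE), classified from
  per-allele TPM by threshold rules?
- **TE pressure** — is transposable-element density around genes symmetric
  between haplotypes?

`tetradiv` implements each analysis as a small, tested R API, plus a
synthetic tetraploid data generator with complete truth tables so the whole
pipeline is verifiable at desk scale without any external data.

## Core statistics

- **Synteny and retention**: homolog anchor pairs are chained into
  collinear blocks (maximal runs consecutive in gene rank on both genomes);
  adjacent blocks are consolidated when separated by `< 50` genes or
  `< 300 kb` (strict, both genomes by default). Retention rate =
  polyploid syntenic genes / (diploid syntenic genes × ploidy).
- **Ka/Ks**: the Nei–Gojobori (1986) counting method. Per codon,
  synonymous site counts come from single-mutant enumeration
  (syn + nonsyn = 3 exactly); per codon pair, synonymous/nonsynonymous
  differences average over all substitution orderings, excluding pathways
  through stop codons when a stop-free ordering exists. Rates are
  Jukes–Cantor corrected: *Ks* = −¾ ln(1 − 4/3 · pS).
- **WGD peaks**: Gaussian KDE of the pooled *Ks* values on a 0.005 grid
  over [0, 3], peaks = local maxima with topographic prominence ≥ 5% of
  the maximum density; dating via *T* = *Ks* / (2μ).
- **ASE classes** (per tissue, thresholds TPM > 2 and 2-fold):
  `biallelic`, `higher_one_allele`, `hap1_dominant`, `hap3_dominant`,
  plus `not_expressed`.
- **TE profiles**: TE-covered fraction per 100-bp window sliding by 10 bp
  across the 5-kb flanks of each gene (491 windows per flank), averaged
  over gene sets with effective-length weighting at chromosome ends.

## Worked example

```r
library(tetradiv)

cfg <- simulation_config(seed = 7, n_chromosomes = 1, chrom_length = 100000,
                         n_genes_per_chrom = 50, te_fraction = 0.3)
ds <- simulate_tetraploid(cfg)

divergence_matrix(ds$truth_variants, cfg$haplotypes)$snp_counts
#>      H1   H2   H3   H4
#> H1    0   95 1081 1080
#> H2   95    0 1095 1094
#> H3 1081 1095    0  115
#> H4 1080 1094  115    0
```

Within-lineage pairs (H1–H2: 95 SNPs; H3–H4: 115) are an order of
magnitude closer than between-lineage pairs (~1090), matching the
configured 1e-3 vs 1e-2 substitutions/bp. UPGMA on these counts recovers
the designed partition:

```r
cluster_haplotypes(divergence_matrix(ds$truth_variants, cfg$haplotypes))$partition
#> [[1]] "H1" "H2"
#> [[2]] "H3" "H4"
```

One simulated Hap1–Hap3 CDS pair through the NG86 estimator:

```r
kaks_pair(ds$truth_cds_pairs$seq_a[1], ds$truth_cds_pairs$seq_b[1])
#> NG86 pair: 100 codons | S = 77.00 N = 223.00 | Sd = 2.00 Nd = 1.00
#>   Ks = 0.02643  Ka = 0.004498  Ka/Ks = 0.1701
```

i.e. close to the configured coding divergence (target dS = 0.02,
dN = 0.005) on a 100-codon gene. ASE classification applies the printed
threshold rules directly:

```r
classify_ase(10, 4)
#> $class "higher_one_allele"   $fold 2.5
```

And a retention check at the configured probabilities (0.913 background):

```r
copies <- data.frame(gene_id = rep(sprintf("g%03d", 1:50), each = 4),
                     haplotype = rep(paste0("H", 1:4), 50), pathway = FALSE)
ret <- assign_retention(copies, 0.913, 0.984, seed = 7)
retention_rate(sum(ret$retained), 50, 4)
#> $rate 0.925   $percent 92.5
```

The full pipeline (simulate → synteny → divergence → Ks → ASE → TE
profile) runs in one call and writes a JSON report:

```r
run_pipeline(list(seed = 42, mu = 7e-9), "out/")
```

or from the shell: `Rscript inst/cli/tetradiv.R run --config cfg.json --out out/`.

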