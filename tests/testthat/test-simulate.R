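# synthetic tetraploid generator: configuration, determinism, truth tables

test_that("simulation_config validates its invariants", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(ploidy = 1), "ploidy")
  expect_error(simulation_config(within_lineage_snp_rate = 0.02,
                                 between_lineage_snp_rate = 0.01),
               "within-lineage")
  expect_error(simulation_config(te_fraction = 1.5), "\\[0, 1\\]")
  bad_design <- matrix(0.3, nrow = 4, ncol = 4,
                       dimnames = list(NULL, NULL))
  expect_error(simulation_config(ase_design = bad_design), "sum to 1")
})

test_that("simulate_tetraploid builds the stated structure deterministically", {
  cfg <- simulation_config(seed = 12, n_chromosomes = 2,
                           chrom_length = 50000, n_genes_per_chrom = 10,
                           te_fraction = 0.2)
  ds <- simulate_tetraploid(cfg)
  expect_equal(length(ds$genomes), 4)
  expect_equal(sum(lengths(ds$genomes)), 8)   # 4 haplotypes x 2 chromosomes
  expect_equal(ds$truth_lineages, list(c("H1", "H2"), c("H3", "H4")))
  # genomes are over ACGT and all the declared length
  for (h in names(ds$genomes)) {
    expect_false(any(grepl("[^ACGT]", unclass(ds$genomes[[h]]))))
    expect_true(all(nchar(ds$genomes[[h]]) == 50000))
  }
  # all gene intervals lie within their chromosome
  for (h in names(ds$gene_models)) {
    g <- ds$gene_models[[h]]$genes
    expect_true(all(g$start >= 0 & g$end <= 50000))
  }
  # determinism: same config, byte-identical dataset
  expect_identical(ds, simulate_tetraploid(cfg))
})

test_that("truth SNP counts match Poisson expectations per pair", {
  cfg <- simulation_config(seed = 21, n_chromosomes = 1,
                           chrom_length = 100000, n_genes_per_chrom = 0,
                           te_fraction = 0,
                           within_lineage_snp_rate = 1e-3,
                           between_lineage_snp_rate = 1e-2)
  ds <- simulate_tetraploid(cfg)
  snp <- ds$truth_variants[ds$truth_variants$type == "SNP", ]
  count <- function(a, b) sum(snp$hap_a == a & snp$hap_b == b)
  expect_lt(abs(count("H1", "H2") - 100), 3 * sqrt(100))
  expect_lt(abs(count("H3", "H4") - 100), 3 * sqrt(100))
  for (pr in list(c("H1", "H3"), c("H1", "H4"), c("H2", "H3"),
                  c("H2", "H4"))) {
    expect_lt(abs(count(pr[1], pr[2]) - 1000), 3 * sqrt(1000))
  }
})

test_that("simulated CDS have no internal stops and consistent truth pairs", {
  cfg <- simulation_config(seed = 30, n_chromosomes = 1,
                           chrom_length = 60000, n_genes_per_chrom = 20,
                           te_fraction = 0)
  ds <- simulate_tetraploid(cfg)
  cp <- ds$truth_cds_pairs
  expect_equal(nrow(cp), 20)
  for (i in seq_len(nrow(cp))) {
    for (s in c(cp$seq_a[i], cp$seq_b[i])) {
      aa <- strsplit(as.character(Biostrings::translate(
        Biostrings::DNAString(s))), "")[[1]]
      expect_false(any(aa == "*"))
    }
    # realized counts equal exhaustive diff of the two sequences
    ca <- substring(cp$seq_a[i], seq(1, nchar(cp$seq_a[i]), 3),
                    seq(3, nchar(cp$seq_a[i]), 3))
    cb <- substring(cp$seq_b[i], seq(1, nchar(cp$seq_b[i]), 3),
                    seq(3, nchar(cp$seq_b[i]), 3))
    diff_idx <- which(ca != cb)
    syn <- sum(GENCODE[ca[diff_idx]] == GENCODE[cb[diff_idx]])
    expect_equal(syn, cp$syn_subs[i])
    expect_equal(length(diff_idx) - syn, cp$nonsyn_subs[i])
  }
  # the CDS embedded in the genomes match the truth pair sequences
  g1 <- ds$gene_models$H1$genes
  gid <- g1$gene_id[1]
  anc_id <- sub("^H1_", "", gid)
  chrom_seq <- unclass(ds$genomes$H1)[[g1$chrom[1]]]
  emb <- substr(chrom_seq, g1$start[1] + 1, g1$end[1])
  if (g1$strand[1] == "-") {
    emb <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(emb)))
  }
  expect_equal(emb, cp$seq_a[cp$pair_id == anc_id])
})

test_that("evolve_cds_pair meets targets and refuses impossible ones", {
  cds <- fixture_cds(100, seed = 7)
  same <- evolve_cds_pair(cds, 0, 0, seed = 1)
  expect_equal(same$seq, cds)
  expect_equal(same$syn_subs + same$nonsyn_subs, 0)
  ev <- evolve_cds_pair(cds, 0.1, 0.02, seed = 2)
  aa <- strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(ev$seq))), "")[[1]]
  expect_false(any(aa == "*"))
  # tryptophan-only CDS has zero synonymous sites
  trp <- paste(rep("TGG", 30), collapse = "")
  expect_error(evolve_cds_pair(trp, 0.2, 0, seed = 1), "impossible target")
  expect_error(evolve_cds_pair(cds, 3, 3, seed = 1), "")
})

test_that("assign_retention hits its probabilities", {
  copies <- data.frame(gene_id = rep(paste0("g", 1:1000), each = 4),
                       haplotype = rep(paste0("H", 1:4), 1000),
                       pathway = FALSE)
  all_in <- assign_retention(copies, 1, 1, seed = 1)
  expect_true(all(all_in$retained))
  none <- assign_retention(copies, 0, 0, seed = 1)
  expect_false(any(none$retained))
  some <- assign_retention(copies, 0.9, 0.9, seed = 5)
  p_hat <- mean(some$retained)
  expect_lt(abs(p_hat - 0.9), 3 * sqrt(0.9 * 0.1 / 4000))
  expect_error(assign_retention(copies, 1.2, 0.5, seed = 1), "\\[0, 1\\]")
})

test_that("simulate_expression honours the design with safe margins", {
  design <- matrix(c(0.9, 0.05, 0.03, 0.02), nrow = 1,
                   dimnames = list("stem", NULL))
  sim <- simulate_expression(design, paste0("p", 1:200), seed = 3,
                             tissues = "stem")
  expect_equal(nrow(sim$expression), 400)   # 200 pairs x 2 alleles
  expect_identical(sim$expression,
                   simulate_expression(design, paste0("p", 1:200), seed = 3,
                                       tissues = "stem")$expression)
  # per-label margin guarantees
  wide <- merge(sim$expression[sim$expression$haplotype == "H1",
                               c("gene_id", "tpm")],
                sim$expression[sim$expression$haplotype == "H3",
                               c("gene_id", "tpm")], by = "gene_id")
  names(wide)[2:3] <- c("a", "b")
  wide <- merge(wide, sim$labels, by = "gene_id")
  dom1 <- wide[wide$class == "hap1_dominant", ]
  expect_true(all(dom1$a > 2.2 & dom1$b < 1.8))
  bi <- wide[wide$class == "biallelic", ]
  expect_true(all(bi$a > 2.2 & bi$b > 2.2 &
                    pmax(bi$a, bi$b) / pmin(bi$a, bi$b) <= 1.8))
  hi <- wide[wide$class == "higher_one_allele", ]
  expect_true(all(pmax(hi$a, hi$b) / pmin(hi$a, hi$b) >= 2.2))
  expect_error(simulate_expression(design, character(0), seed = 1),
               "empty gene list")
})

test_that("write_dataset emits the declared files", {
  cfg <- simulation_config(seed = 2, n_chromosomes = 1, chrom_length = 30000,
                           n_genes_per_chrom = 5, te_fraction = 0.1)
  ds <- simulate_tetraploid(cfg)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(all(file.exists(file.path(
    dir, c("H1.fasta", "H4.gff3", "te.bed", "variants.tsv",
           "expression.tsv", "truth.json")))))
})
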