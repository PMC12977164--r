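# TPM normalisation, ASE classifier, Venn intersections, Welch comparison,
# motif scanning

test_that("tpm_from_counts normalises to one million", {
  expect_equal(tpm_from_counts(rep(10, 4), rep(1000, 4)), rep(250000, 4))
  tpm <- tpm_from_counts(c(0, 5, 5), c(100, 100, 200))
  expect_equal(tpm[1], 0)
  expect_equal(sum(tpm), 1e6)
  for (seed in 1:5) {
    x <- withr_seed(seed, list(c = rpois(20, 50), l = sample(200:2000, 20)))
    expect_equal(sum(tpm_from_counts(x$c, x$l)), 1e6, tolerance = 1e-9)
  }
  expect_error(tpm_from_counts(c(0, 0), c(1, 1)), "all counts are zero")
  expect_error(tpm_from_counts(c(1, 2), c(0, 1)), "positive")
})

test_that("classify_ase applies the threshold rules, boundaries included", {
  expect_equal(classify_ase(10, 8)$class, "biallelic")
  expect_equal(classify_ase(10, 8)$fold, 1.25)
  expect_equal(classify_ase(10, 1)$class, "hap1_dominant")
  expect_equal(classify_ase(1, 10)$class, "hap3_dominant")
  expect_equal(classify_ase(10, 4)$class, "higher_one_allele")
  expect_equal(classify_ase(2, 2)$class, "not_expressed")   # strict > 2
  expect_equal(classify_ase(0, 0)$class, "not_expressed")
  expect_equal(classify_ase(6, 3)$class, "higher_one_allele") # fold == 2
  expect_true(is.na(classify_ase(10, 0)$fold))
  expect_error(classify_ase(-1, 2), "negative")
  # total function: every non-negative pair maps to exactly one class
  grid <- expand.grid(a = c(0, 1, 2, 2.0001, 3, 50),
                      b = c(0, 1, 2, 2.0001, 3, 50))
  cls <- mapply(function(a, b) classify_ase(a, b)$class, grid$a, grid$b)
  expect_true(all(cls %in% c("biallelic", "higher_one_allele",
                             "hap1_dominant", "hap3_dominant",
                             "not_expressed")))
})

test_that("classify_matrix recovers designed fractions exactly", {
  design <- matrix(c(0.9, 0.05, 0.03, 0.02), nrow = 1,
                   dimnames = list("stem", NULL))
  sim <- simulate_expression(design, paste0("p", 1:200), seed = 8,
                             tissues = "stem")
  out <- classify_matrix(sim$expression)
  merged <- merge(out$calls, sim$labels, by = c("gene_id", "tissue"))
  expect_equal(merged$class.x, merged$class.y)
  fr <- out$fractions
  expect_equal(fr$fraction[fr$class == "biallelic"], 0.9)
  expect_equal(fr$fraction[fr$class == "hap3_dominant"], 0.02)
  expect_equal(sum(fr$fraction), 1)

  # permutation invariance of the summary
  perm <- withr_seed(2, sim$expression[sample(nrow(sim$expression)), ])
  out2 <- classify_matrix(perm)
  expect_equal(out2$fractions[order(out2$fractions$class), ],
               fr[order(fr$class), ], ignore_attr = TRUE)

  silent <- data.frame(gene_id = "g", tissue = "stem",
                       hap1_tpm = 0, hap3_tpm = 0)
  expect_warning(res0 <- classify_matrix(silent), "fractions undefined")
  expect_true(all(is.na(res0$fractions$fraction)))
  expect_error(classify_matrix(silent[0, ]), "empty")
})

test_that("intersect_ase_sets equals the set-algebra oracle", {
  calls <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    tissue = c("stem", "stem", "root", "root"),
    class = c("hap1_dominant", "biallelic", "hap3_dominant", "biallelic"))
  v <- intersect_ase_sets(calls, tissues = c("stem", "root"))
  expect_equal(unname(v["stem"]), 1)
  expect_equal(unname(v["root"]), 1)
  expect_equal(unname(v["stem&root"]), 0)

  # identical sets: everything in the full intersection
  all4 <- do.call(rbind, lapply(c("a", "b", "c", "d"), function(t) {
    data.frame(gene_id = paste0("g", 1:5), tissue = t,
               class = "hap1_dominant")
  }))
  v4 <- intersect_ase_sets(all4)
  expect_equal(unname(v4["a&b&c&d"]), 5)
  expect_equal(sum(v4), 5)

  expect_error(intersect_ase_sets(calls, tissues = c("stem", "leaf")),
               "unknown tissue")
  expect_error(intersect_ase_sets(calls, tissues = "stem"), ">= 2 tissues")
})

test_that("compare_kaks_by_class matches the closed-form Welch oracle", {
  kaks <- data.frame(gene_id = paste0("g", 1:10),
                     ratio = c(1, 2, 3, 4, 5, 2, 3, 4, 5, 6))
  calls <- data.frame(gene_id = paste0("g", 1:10),
                      class = rep(c("biallelic", "hap1_dominant"), each = 5))
  res <- compare_kaks_by_class(kaks, calls, "biallelic", "hap1_dominant")
  orc <- oracle_welch(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
  expect_equal(res$t, orc$t, tolerance = 1e-10)
  expect_equal(res$p, orc$p, tolerance = 1e-10)

  # identical groups
  same <- compare_kaks_by_class(
    data.frame(gene_id = paste0("g", 1:6), ratio = rep(c(1, 2, 3), 2)),
    data.frame(gene_id = paste0("g", 1:6),
               class = rep(c("x", "y"), each = 3)), "x", "y")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # well-separated simulated groups
  set1 <- withr_seed(5, rnorm(100, 0.2, 0.1))
  set2 <- withr_seed(6, rnorm(100, 0.5, 0.1))
  big <- compare_kaks_by_class(
    data.frame(gene_id = paste0("g", 1:200), ratio = c(set1, set2)),
    data.frame(gene_id = paste0("g", 1:200),
               class = rep(c("biallelic", "hap1_dominant"), each = 100)),
    "biallelic", "hap1_dominant")
  expect_lt(big$p, 1e-6)

  expect_error(compare_kaks_by_class(
    kaks, data.frame(gene_id = "g1", class = "x"), "x", "y"), ">= 3")
})

test_that("scan_motif reports all overlapping IUPAC matches", {
  expect_equal(nrow(scan_motif("", "ACGTG")), 0)
  hit <- scan_motif("AAA", "ANA")
  expect_equal(hit$position, 0)
  # overlapping matches are all reported
  ovl <- scan_motif("ATATAT", "ATA")
  expect_equal(ovl$position, c(0, 2))
  # reverse strand reported against forward coordinates
  rc <- scan_motif("AAACACGTAAA", "ACGTG", both_strands = TRUE)
  expect_equal(rc$strand, "-")
  expect_equal(rc$position, 3)
  expect_error(scan_motif("ACGT", "AZT"), "invalid IUPAC")
  expect_error(scan_motif("ACGU", "ACG"), "non-ACGTN")
})
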