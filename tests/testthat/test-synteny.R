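# anchor chaining, gap-rule consolidation, retention statistics

# build an annotated anchor table from rank pairs on one chromosome pair;
# gene coordinates place gene of rank r at [r*1000, r*1000 + 500)
anchors_from_ranks <- function(ranks_a, ranks_b, n_genes = 40) {
  ga <- fixture_genes(n_genes, "a", "cA", gene_len = 500, gap = 500)
  gb <- fixture_genes(n_genes, "b", "cB", gene_len = 500, gap = 500)
  anc <- data.frame(gene_a = paste0("a", ranks_a),
                    gene_b = paste0("b", ranks_b), similarity = 1)
  annotate_anchors(anc, ga, gb)
}

test_that("chain_anchors produces maximal consistent runs", {
  one <- chain_anchors(anchors_from_ranks(1:5, 1:5))
  expect_equal(nrow(one), 1)
  expect_equal(one$n_anchors, 5)
  expect_equal(one$orientation, "same")

  two <- chain_anchors(anchors_from_ranks(c(1, 2, 3, 4, 5),
                                          c(1, 2, 3, 7, 6)))
  expect_equal(nrow(two), 2)
  expect_equal(two$orientation, c("same", "inverted"))
  expect_equal(two$n_anchors, c(3, 2))

  single <- chain_anchors(anchors_from_ranks(4, 9))
  expect_equal(nrow(single), 1)
  expect_equal(single$n_anchors, 1)

  dup <- anchors_from_ranks(1:3, 1:3)
  dup$gene_a[2] <- dup$gene_a[1]
  expect_error(chain_anchors(dup), "duplicate gene")
})

test_that("best_hit_filter keeps highest-similarity one-to-one pairs", {
  a <- data.frame(gene_a = c("a1", "a1", "a2"),
                  gene_b = c("b1", "b2", "b1"),
                  similarity = c(0.9, 0.95, 0.99))
  f <- best_hit_filter(a)
  expect_equal(nrow(f), 2)
  expect_setequal(paste(f$gene_a, f$gene_b), c("a2 b1", "a1 b2"))
  # deterministic tie-break by lexicographic gene id
  t2 <- data.frame(gene_a = c("a2", "a1"), gene_b = c("b9", "b9"),
                   similarity = 0.5)
  expect_equal(best_hit_filter(t2)$gene_a, "a1")
})

test_that("consolidation respects the strict gap thresholds", {
  # runs separated by 49 genes in both genomes merge (gene condition holds
  # even though the bp gap of ~500 kb exceeds 300 kb)
  gap49 <- chain_anchors(anchors_from_ranks(c(1, 2, 52, 53),
                                            c(1, 2, 52, 53), n_genes = 60))
  expect_equal(nrow(gap49), 2)
  merged <- consolidate_blocks(gap49, max_gene_gap = 50,
                               max_bp_gap = 300000)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$n_anchors, 4)

  # exactly 50 genes and exactly 300 kb: strict < on both, no merge.
  # gene of rank r sits at [(r-1)*1000, (r-1)*1000+500): ranks 2 and 53
  # leave 50 genes between and facing boundaries 51500 - 1500 = 50 kb, so
  # use wide genes to hit exactly 300 kb: construct coordinates directly
  ga <- data.frame(gene_id = paste0("a", 1:60), chrom = "cA",
                   start = (0:59) * 10000, end = (0:59) * 10000 + 500)
  gb <- ga; gb$gene_id <- paste0("b", 1:60); gb$chrom <- "cB"
  anc <- data.frame(gene_a = paste0("a", c(1, 2, 53, 54)),
                    gene_b = paste0("b", c(1, 2, 53, 54)), similarity = 1)
  ann <- annotate_anchors(anc, ga, gb)
  raw <- chain_anchors(ann)
  # gap: 50 genes between rank 2 and 53; bp gap = 520000 - 10500 > 300 kb
  expect_equal(nrow(consolidate_blocks(raw, 50, 300000)), 2)
  # loosening either threshold by one unit merges
  expect_equal(nrow(consolidate_blocks(raw, 51, 300000)), 1)
  expect_error(consolidate_blocks(raw, -1, 300000), "non-negative")
})

test_that("consolidation is idempotent and matches the closure oracle", {
  oracle_consolidate <- function(blocks, max_gene_gap, max_bp_gap) {
    n <- nrow(blocks)
    # independent pairwise predicate straight from the rule
    pred <- function(i, j) {
      b1 <- blocks[i, ]; b2 <- blocks[j, ]
      if (b1$orientation != b2$orientation) return(FALSE)
      gap_ok <- function(lo_max_r, hi_min_r, lo_end, hi_start) {
        genes <- max(hi_min_r - lo_max_r - 1, 0)
        bp <- max(hi_start - lo_end, 0)
        genes < max_gene_gap || bp < max_bp_gap
      }
      a_ok <- if (b1$rank_a_min <= b2$rank_a_min) {
        gap_ok(b1$rank_a_max, b2$rank_a_min, b1$end_a, b2$start_a)
      } else gap_ok(b2$rank_a_max, b1$rank_a_min, b2$end_a, b1$start_a)
      b_ok <- if (b1$rank_b_min <= b2$rank_b_min) {
        gap_ok(b1$rank_b_max, b2$rank_b_min, b1$end_b, b2$start_b)
      } else gap_ok(b2$rank_b_max, b1$rank_b_min, b2$end_b, b1$start_b)
      a_ok && b_ok
    }
    adj <- diag(n) == 1
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && pred(i, j)) adj[i, j] <- TRUE
    }
    # reachability by repeated boolean closure
    repeat {
      nxt <- (adj %*% adj) > 0 | adj
      if (identical(nxt, adj)) break
      adj <- nxt
    }
    comps <- unique(apply(adj, 1, function(r) paste(which(r), collapse = ",")))
    sort(vapply(strsplit(comps, ","), length, integer(1)))
  }

  for (case in 1:30) {
    ranks <- withr_seed(100 + case, {
      n_runs <- sample(2:10, 1)
      starts <- sort(sample(seq(1, 180, by = 3), n_runs))
      unlist(lapply(starts, function(s) s + 0:1))
    })
    ann <- anchors_from_ranks(ranks, ranks, n_genes = 200)
    raw <- chain_anchors(ann)
    cons <- consolidate_blocks(raw, max_gene_gap = 5, max_bp_gap = 4000)
    expect_equal(sort(table_block_sizes(raw, cons)),
                 oracle_consolidate(raw, 5, 4000), info = case)
    again <- consolidate_blocks(cons, max_gene_gap = 5, max_bp_gap = 4000)
    expect_equal(nrow(again), nrow(cons))
    expect_equal(again$n_anchors, cons$n_anchors)
  }
})

test_that("retention_rate computes the exact ratio with guards", {
  expect_equal(retention_rate(400, 100, 4)$rate, 1)
  r <- retention_rate(365, 100, 4)
  expect_equal(r$rate, 0.9125)
  expect_equal(r$percent, 91.2)
  expect_error(retention_rate(10, 0, 4), "undefined statistic")
  expect_error(retention_rate(10, 5, 0), "ploidy")
})

test_that("pathway_retention reports per-set rates and handles edge sets", {
  blocks <- data.frame(orientation = "same", stringsAsFactors = FALSE)
  blocks$genes_a <- I(list(paste0("a", 1:10)))
  blocks$genes_b <- I(list(paste0("b", 1:10)))
  rep_all <- pathway_retention(blocks, list(sub = paste0("a", 1:3)),
                               ploidy = 1)
  expect_equal(rep_all$rate, 1)
  expect_equal(rep_all$per_set$sub, 1)
  expect_warning(
    rep_na <- pathway_retention(blocks, list(gone = "zz"), ploidy = 1),
    "disjoint")
  expect_true(is.na(rep_na$per_set$gone))
})

test_that("retention estimator is unbiased on simulation", {
  truth <- 0.88
  est <- vapply(1:50, function(s) {
    copies <- data.frame(gene_id = rep(paste0("g", 1:200), each = 4),
                         haplotype = rep(paste0("H", 1:4), 200),
                         pathway = FALSE)
    ret <- assign_retention(copies, truth, truth, seed = 4000 + s)
    retention_rate(sum(ret$retained), 200, 4)$rate
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - truth), se)
})
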