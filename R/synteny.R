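# Synteny-block chaining, gap-rule consolidation and gene-retention
# statistics against a diploid relative.

#' Pre-filter anchors to one-to-one best pairs
#'
#' Keeps, per gene on either side, the highest-similarity anchor; ties break
#' by smallest (gene_a, gene_b) lexicographic order, deterministically.
#'
#' @param anchors data.frame gene_a, gene_b, similarity.
#' @return filtered data.frame where each gene appears in one anchor.
#' @export
best_hit_filter <- function(anchors) {
  a <- anchors[order(-anchors$similarity, anchors$gene_a, anchors$gene_b), ,
               drop = FALSE]
  # greedy pass: a row is kept only if neither gene was claimed earlier
  seen_a <- character(0); seen_b <- character(0)
  sel <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    if (!(a$gene_a[i] %in% seen_a) && !(a$gene_b[i] %in% seen_b)) {
      sel[i] <- TRUE
      seen_a <- c(seen_a, a$gene_a[i])
      seen_b <- c(seen_b, a$gene_b[i])
    }
  }
  a[sel, , drop = FALSE]
}

# attach chromosome, rank (gene-order index among all annotated genes on the
# chromosome) and bp span to each anchor side
rank_genes <- function(genes) {
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  genes$rank <- stats::ave(seq_len(nrow(genes)), genes$chrom,
                           FUN = seq_along)
  genes
}

#' Annotate anchors with gene ranks and coordinates
#'
#' @param anchors one-to-one anchor table (gene_a, gene_b).
#' @param genes_a,genes_b gene tables (gene_id, chrom, start, end) for the
#'   two genomes.
#' @return anchor table with chrom/rank/start/end columns for both sides.
#' @export
annotate_anchors <- function(anchors, genes_a, genes_b) {
  if (anyDuplicated(anchors$gene_a) || anyDuplicated(anchors$gene_b)) {
    fail_validation("anchors are not one-to-one; apply best_hit_filter first")
  }
  ra <- rank_genes(genes_a)
  rb <- rank_genes(genes_b)
  ia <- match(anchors$gene_a, ra$gene_id)
  ib <- match(anchors$gene_b, rb$gene_id)
  if (anyNA(ia)) {
    fail_validation("anchor references unknown gene id: ",
                    anchors$gene_a[is.na(ia)][1])
  }
  if (anyNA(ib)) {
    fail_validation("anchor references unknown gene id: ",
                    anchors$gene_b[is.na(ib)][1])
  }
  data.frame(
    gene_a = anchors$gene_a, gene_b = anchors$gene_b,
    chrom_a = ra$chrom[ia], rank_a = ra$rank[ia],
    start_a = ra$start[ia], end_a = ra$end[ia],
    chrom_b = rb$chrom[ib], rank_b = rb$rank[ib],
    start_b = rb$start[ib], end_b = rb$end[ib],
    stringsAsFactors = FALSE
  )
}

#' Chain anchors into raw collinear blocks
#'
#' Within each chromosome pair, maximal runs of anchors consecutive in rank
#' on both genomes with consistent orientation (rank_b strictly +1 per step
#' for `same`, -1 for `inverted`) become blocks; every anchor lands in
#' exactly one block. Single anchors form size-1 blocks with orientation
#' `same`.
#'
#' @param anchors annotated anchors (see [annotate_anchors()]).
#' @return data.frame of blocks: block_id, chrom_a, chrom_b, orientation,
#'   n_anchors, rank/bp spans on both sides, plus an `anchors` list column
#'   of member anchor indices.
#' @export
chain_anchors <- function(anchors) {
  if (anyDuplicated(anchors$gene_a) || anyDuplicated(anchors$gene_b)) {
    fail_validation("duplicate gene in multiple anchors; pre-filter to best pairs")
  }
  blocks <- list()
  for (key in unique(paste(anchors$chrom_a, anchors$chrom_b, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- anchors[anchors$chrom_a == parts[1] & anchors$chrom_b == parts[2], ,
                   drop = FALSE]
    sub <- sub[order(sub$rank_a), , drop = FALSE]
    n <- nrow(sub)
    run_start <- 1L
    dirs <- if (n > 1L) diff(sub$rank_b) else integer(0)
    cons <- if (n > 1L) diff(sub$rank_a) == 1L else logical(0)
    i <- 1L
    while (i <= n) {
      j <- i
      dir <- 0L
      while (j < n && cons[j] && abs(dirs[j]) == 1L &&
             (dir == 0L || dirs[j] == dir)) {
        dir <- dirs[j]
        j <- j + 1L
      }
      blocks[[length(blocks) + 1L]] <- make_block(sub[i:j, , drop = FALSE],
                                                  dir)
      i <- j + 1L
    }
  }
  out <- do.call(rbind, blocks)
  out$block_id <- seq_len(nrow(out))
  out
}

make_block <- function(sub, dir) {
  data.frame(
    chrom_a = sub$chrom_a[1], chrom_b = sub$chrom_b[1],
    orientation = if (dir < 0) "inverted" else "same",
    n_anchors = nrow(sub),
    rank_a_min = min(sub$rank_a), rank_a_max = max(sub$rank_a),
    rank_b_min = min(sub$rank_b), rank_b_max = max(sub$rank_b),
    start_a = min(sub$start_a), end_a = max(sub$end_a),
    start_b = min(sub$start_b), end_b = max(sub$end_b),
    genes_a = I(list(sub$gene_a)), genes_b = I(list(sub$gene_b)),
    stringsAsFactors = FALSE
  )
}

# gap between two blocks on one genome: genes strictly between the runs and
# bp between facing boundaries (0 when the spans overlap)
block_gap <- function(lo_rank_max, hi_rank_min, lo_end, hi_start) {
  genes <- max(hi_rank_min - lo_rank_max - 1L, 0L)
  bp <- max(hi_start - lo_end, 0L)
  c(genes = genes, bp = bp)
}

# pairwise merge predicate: in the required genome(s), the gap must satisfy
# (gene gap < max_gene_gap) OR (bp gap < max_bp_gap); strict inequalities
blocks_mergeable <- function(b1, b2, max_gene_gap, max_bp_gap,
                             either = FALSE) {
  if (b1$chrom_a != b2$chrom_a || b1$chrom_b != b2$chrom_b ||
      b1$orientation != b2$orientation) {
    return(FALSE)
  }
  ord <- if (b1$rank_a_min <= b2$rank_a_min) list(b1, b2) else list(b2, b1)
  ga <- block_gap(ord[[1]]$rank_a_max, ord[[2]]$rank_a_min,
                  ord[[1]]$end_a, ord[[2]]$start_a)
  ordb <- if (b1$rank_b_min <= b2$rank_b_min) list(b1, b2) else list(b2, b1)
  gb <- block_gap(ordb[[1]]$rank_b_max, ordb[[2]]$rank_b_min,
                  ordb[[1]]$end_b, ordb[[2]]$start_b)
  ok_a <- ga[["genes"]] < max_gene_gap || ga[["bp"]] < max_bp_gap
  ok_b <- gb[["genes"]] < max_gene_gap || gb[["bp"]] < max_bp_gap
  if (either) ok_a || ok_b else ok_a && ok_b
}

#' Consolidate collinear blocks by the gap rule
#'
#' Blocks on the same chromosome pair with the same orientation merge when
#' the separating gap passes the disjunctive threshold test (`< max_gene_gap`
#' genes OR `< max_bp_gap` bp) in both genomes (or in at least one, with
#' `either = TRUE`). Merging is applied transitively (connected components
#' of the pairwise predicate); output is sorted by genome-A position.
#' Consolidation is idempotent.
#'
#' @param blocks block table from [chain_anchors()].
#' @param max_gene_gap gene-count threshold (strict `<`, default 50).
#' @param max_bp_gap bp threshold (strict `<`, default 300000).
#' @param either require the gap condition in only one genome.
#' @return consolidated block table.
#' @export
consolidate_blocks <- function(blocks, max_gene_gap = 50,
                               max_bp_gap = 300000, either = FALSE) {
  if (max_gene_gap < 0 || max_bp_gap < 0) {
    fail_validation("gap thresholds must be non-negative")
  }
  n <- nrow(blocks)
  if (n == 0L) return(blocks)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (blocks_mergeable(blocks[i, ], blocks[j, ], max_gene_gap,
                           max_bp_gap, either)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  merged <- lapply(split(seq_len(n), comp), function(idx) {
    sub <- blocks[idx, , drop = FALSE]
    data.frame(
      chrom_a = sub$chrom_a[1], chrom_b = sub$chrom_b[1],
      orientation = sub$orientation[1],
      n_anchors = sum(sub$n_anchors),
      rank_a_min = min(sub$rank_a_min), rank_a_max = max(sub$rank_a_max),
      rank_b_min = min(sub$rank_b_min), rank_b_max = max(sub$rank_b_max),
      start_a = min(sub$start_a), end_a = max(sub$end_a),
      start_b = min(sub$start_b), end_b = max(sub$end_b),
      genes_a = I(list(unlist(sub$genes_a))),
      genes_b = I(list(unlist(sub$genes_b))),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$chrom_a, out$start_a), , drop = FALSE]
  out$block_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Gene retention rate after polyploidy
#'
#' The ratio of polyploid syntenic genes to diploid syntenic genes times
#' ploidy: with full retention a tetraploid carries 4 copies per diploid
#' syntenic gene.
#'
#' @param polyploid_syntenic distinct syntenic gene count in the polyploid.
#' @param diploid_syntenic distinct syntenic gene count in the diploid (> 0).
#' @param ploidy polyploid copy number (>= 1).
#' @return list with `rate` (exact proportion) and `percent` (one decimal).
#' @export
#' @examples
#' retention_rate(365, 100, 4)  # rate 0.9125, percent 91.2
retention_rate <- function(polyploid_syntenic, diploid_syntenic, ploidy) {
  if (ploidy < 1) fail_validation("ploidy must be >= 1")
  if (diploid_syntenic <= 0) {
    fail_validation("undefined statistic: diploid syntenic gene count is 0")
  }
  rate <- polyploid_syntenic / (diploid_syntenic * ploidy)
  list(rate = rate, percent = round(100 * rate, 1))
}

#' Retention report over consolidated blocks, per gene set
#'
#' Counts distinct diploid (side A) and polyploid (side B) gene ids inside
#' the consolidated blocks, overall and restricted to each labelled diploid
#' gene-id set. Empty or block-disjoint sets yield an `NA` rate with a
#' warning rather than zero.
#'
#' @param blocks consolidated blocks carrying `genes_a`/`genes_b` and the
#'   anchor pairing (`pairs` list column not required: pairing is recovered
#'   from the stored member gene vectors, which stay aligned).
#' @param gene_sets named list of diploid gene-id sets (may be empty).
#' @param ploidy polyploid copy number.
#' @return object of class `retention_report`: list with counts, `rate`,
#'   `percent`, `per_set` (named list of rates), `per_set_percent`.
#' @export
pathway_retention <- function(blocks, gene_sets = list(), ploidy = 4) {
  ga <- unlist(blocks$genes_a)
  gb <- unlist(blocks$genes_b)
  dip <- unique(ga)
  poly <- unique(gb)
  overall <- retention_rate(length(poly), length(dip), ploidy)
  per_set <- lapply(gene_sets, function(ids) {
    sel <- ga %in% ids
    dip_s <- unique(ga[sel])
    if (length(dip_s) == 0L) {
      warning("gene set disjoint from syntenic blocks; rate undefined")
      return(NA_real_)
    }
    poly_s <- unique(gb[sel])
    retention_rate(length(poly_s), length(dip_s), ploidy)$rate
  })
  structure(list(
    polyploid_syntenic_genes = length(poly),
    diploid_syntenic_genes = length(dip),
    ploidy = ploidy, rate = overall$rate, percent = overall$percent,
    per_set = per_set,
    per_set_percent = lapply(per_set, function(r) round(100 * r, 1))
  ), class = "retention_report")
}

#' @export
print.retention_report <- function(x, ...) {
  cat(sprintf("retention: %d polyploid / (%d diploid x %d) = %.4f (%.1f%%)\n",
              x$polyploid_syntenic_genes, x$diploid_syntenic_genes,
              x$ploidy, x$rate, x$percent))
  for (nm in names(x$per_set)) {
    cat(sprintf("  set %-12s %.4f\n", nm, x$per_set[[nm]]))
  }
  invisible(x)
}
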