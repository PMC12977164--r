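# Sliding-window variant densities, pairwise divergence matrices and
# distance-based haplotype lineage clustering (UPGMA).

#' Sliding-window feature density
#'
#' Windows are 0-based half-open `[i*step, i*step + window_size)`; the last
#' partial window is dropped, so the number of windows is
#' `floor((L - window_size) / step) + 1`.
#'
#' @param positions 0-based feature positions.
#' @param chrom_length chromosome length (>= window_size).
#' @param window_size window width, bp.
#' @param step step size, bp.
#' @return object of class `window_track`: data.frame with `start`, `end`,
#'   `count`; attributes `window_size`, `step`, `chrom_length`.
#' @export
window_density <- function(positions, chrom_length, window_size, step) {
  if (window_size <= 0 || step <= 0) {
    fail_validation("window_size and step must be positive")
  }
  if (window_size > chrom_length) {
    fail_validation("window_size exceeds chromosome length")
  }
  if (length(positions) && (any(positions < 0) ||
                            any(positions >= chrom_length))) {
    fail_validation("feature positions outside [0, chrom_length)")
  }
  n_win <- (chrom_length - window_size) %/% step + 1L
  starts <- (seq_len(n_win) - 1L) * step
  counts <- vapply(starts, function(s) {
    sum(positions >= s & positions < s + window_size)
  }, numeric(1))
  structure(data.frame(start = starts, end = starts + window_size,
                       count = counts),
            window_size = window_size, step = step,
            chrom_length = chrom_length, class = c("window_track",
                                                   "data.frame"))
}

#' Pairwise haplotype divergence matrices
#'
#' Totals SNP and InDel counts per unordered haplotype pair into symmetric
#' matrices with zero diagonals. InDels count as single events regardless of
#' length.
#'
#' @param variants data.frame with hap_a, hap_b, type (SNP/INS/DEL).
#' @param haplotypes haplotype label vector.
#' @return object of class `divergence_matrix`: list with `labels`,
#'   `snp_counts`, `indel_counts`.
#' @export
divergence_matrix <- function(variants, haplotypes) {
  known <- unique(c(variants$hap_a, variants$hap_b))
  if (length(known) && !all(known %in% haplotypes)) {
    fail_validation("unknown haplotype label: ",
                    known[!known %in% haplotypes][1])
  }
  k <- length(haplotypes)
  snp <- matrix(0, k, k, dimnames = list(haplotypes, haplotypes))
  ind <- snp
  if (nrow(variants)) {
    agg <- stats::aggregate(
      list(n = rep(1L, nrow(variants))),
      by = list(a = variants$hap_a, b = variants$hap_b,
                indel = variants$type != "SNP"),
      FUN = sum)
    for (i in seq_len(nrow(agg))) {
      m <- if (agg$indel[i]) "ind" else "snp"
      if (m == "snp") {
        snp[agg$a[i], agg$b[i]] <- snp[agg$a[i], agg$b[i]] + agg$n[i]
        snp[agg$b[i], agg$a[i]] <- snp[agg$a[i], agg$b[i]]
      } else {
        ind[agg$a[i], agg$b[i]] <- ind[agg$a[i], agg$b[i]] + agg$n[i]
        ind[agg$b[i], agg$a[i]] <- ind[agg$a[i], agg$b[i]]
      }
    }
  }
  structure(list(labels = haplotypes, snp_counts = snp, indel_counts = ind),
            class = "divergence_matrix")
}

#' Cluster haplotypes into lineages by UPGMA
#'
#' Distance between haplotypes is SNP count + InDel count (optionally
#' normalised by aligned length). Labels are sorted lexicographically before
#' clustering so ties resolve deterministically; for four leaves the two
#' first merges define the lineage partition (in general, the k = 2 cut).
#'
#' @param dmat a `divergence_matrix`.
#' @param normalize optional aligned length to divide counts by.
#' @return list with `partition` (list of two label vectors, each sorted,
#'   ordered by first label), `tree` (an `hclust`), `newick` (string).
#' @export
cluster_haplotypes <- function(dmat, normalize = NULL) {
  stopifnot(inherits(dmat, "divergence_matrix"))
  labs <- sort(dmat$labels)
  if (length(labs) < 3L) fail_validation("need >= 3 haplotypes to cluster")
  d <- (dmat$snp_counts + dmat$indel_counts)[labs, labs]
  if (!is.null(normalize)) d <- d / normalize
  if (any(!is.finite(d))) fail_validation("non-finite distances")
  off <- d[upper.tri(d)]
  if (length(unique(off)) == 1L && length(off) > 1L) {
    warning("all pairwise distances equal; tie broken by label order")
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  grp <- stats::cutree(hc, k = 2L)
  partition <- split(names(grp), grp)
  partition <- lapply(partition, sort)
  partition <- partition[order(vapply(partition, `[`, character(1), 1L))]
  names(partition) <- NULL
  phy <- ape::as.phylo(hc)
  list(partition = partition, tree = hc, newick = ape::write.tree(phy))
}
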