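# TE-density profiles over gene flanks: per-window TE fraction across 5-kb
# regions upstream and downstream of each gene, 100-bp windows sliding by
# 10 bp, averaged per gene set.

#' Number of sliding windows per flank
#' @param flank,window,step geometry in bp (window <= flank).
#' @return integer window count, `floor((flank - window)/step) + 1`.
#' @export
n_flank_windows <- function(flank, window, step) {
  if (window > flank) fail_validation("window larger than flank")
  if (window <= 0 || step <= 0) fail_validation("window and step must be > 0")
  (flank - window) %/% step + 1L
}

# merge intervals (0-based half-open data.frame start/end) into their union
merge_intervals <- function(start, end) {
  if (length(start) == 0L) return(list(start = integer(0), end = integer(0)))
  r <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
  list(start = BiocGenerics::start(r) - 1L, end = BiocGenerics::end(r))
}

# TE-covered bases per position over [from, to) as cumulative sums, using
# merged intervals so overlapping annotations are not double counted
flank_coverage <- function(tes, from, to) {
  len <- to - from
  cov <- integer(len)
  m <- merge_intervals(tes$start, tes$end)
  for (i in seq_along(m$start)) {
    s <- max(m$start[i], from)
    e <- min(m$end[i], to)
    if (s < e) cov[(s - from + 1L):(e - from)] <- 1L
  }
  cov
}

#' TE-density profile over one gene's flanks
#'
#' Builds per-window TE fractions over the `flank` bp upstream (5' of the
#' gene's strand) and downstream of the gene body; the gene body itself is
#' excluded. Windows slide from the position farthest from the gene toward
#' it. Overlapping TE annotations are merged before coverage. Flanks are
#' truncated at chromosome ends: each window keeps its effective length and
#' a fraction of `NA` where no sequence exists. Alongside the bounded
#' fraction, the raw TE:non-TE odds is emitted (`Inf` flagged as `NA` when
#' a window is fully covered).
#'
#' @param gene one-row data.frame with chrom, start, end (0-based
#'   half-open), strand.
#' @param tes data.frame of TE intervals on the same chromosome (start,
#'   end, 0-based half-open).
#' @param chrom_length chromosome length, bp.
#' @param flank,window,step profile geometry (defaults 5000/100/10).
#' @return object of class `te_profile`: list with `upstream` and
#'   `downstream` data.frames (offset, covered, effective, fraction, odds),
#'   `geometry`, `n_genes = 1`.
#' @export
flank_te_profile <- function(gene, tes, chrom_length, flank = 5000,
                             window = 100, step = 10) {
  n_win <- n_flank_windows(flank, window, step)
  # windows over one nominal genomic flank [nom_start, nom_start + flank),
  # in genomic left-to-right order; truncated at [0, chrom_length)
  side_windows <- function(nom_start) {
    starts <- nom_start + (seq_len(n_win) - 1L) * step
    covered <- numeric(n_win); effective <- numeric(n_win)
    cov_from <- max(nom_start, 0L)
    cov_to <- min(nom_start + flank, chrom_length)
    cum <- if (cov_to > cov_from) {
      c(0L, cumsum(flank_coverage(tes, cov_from, cov_to)))
    } else 0L
    for (i in seq_len(n_win)) {
      cs <- max(starts[i], cov_from)
      ce <- min(starts[i] + window, cov_to)
      eff <- max(ce - cs, 0L)
      effective[i] <- eff
      covered[i] <- if (eff > 0) {
        cum[ce - cov_from + 1L] - cum[cs - cov_from + 1L]
      } else 0
    }
    data.frame(covered = covered, effective = effective)
  }
  left <- side_windows(gene$start - flank)
  right <- side_windows(gene$end)
  # orient by strand: upstream = 5' side of the gene, windows ordered
  # far -> near the gene; downstream ordered near -> far
  if (gene$strand == "-") {
    upstream <- right[rev(seq_len(n_win)), , drop = FALSE]
    downstream <- left[rev(seq_len(n_win)), , drop = FALSE]
  } else {
    upstream <- left
    downstream <- right
  }
  finish <- function(df, offsets) {
    rownames(df) <- NULL
    df$offset <- offsets
    df$fraction <- ifelse(df$effective > 0, df$covered / df$effective,
                          NA_real_)
    non_te <- df$effective - df$covered
    df$odds <- ifelse(df$effective > 0 & non_te > 0, df$covered / non_te,
                      NA_real_)
    df[, c("offset", "covered", "effective", "fraction", "odds")]
  }
  upstream <- finish(upstream, -flank + (seq_len(n_win) - 1L) * step)
  downstream <- finish(downstream, (seq_len(n_win) - 1L) * step)
  structure(list(upstream = upstream, downstream = downstream,
                 geometry = c(flank = flank, window = window, step = step),
                 n_genes = 1L),
            class = "te_profile")
}

#' Average TE profiles over a gene set
#'
#' Arithmetic mean of per-window TE fraction across genes, weighting
#' truncated windows by their effective lengths (pooled covered / pooled
#' effective bases per window position). All profiles must share geometry.
#'
#' @param profiles non-empty list of `te_profile` objects.
#' @param label gene-set label carried on the result.
#' @return `te_profile` with averaged `fraction` per window and `n_genes`.
#' @export
average_profiles <- function(profiles, label = NA_character_) {
  if (length(profiles) == 0L) fail_validation("no profiles to average")
  geom <- profiles[[1]]$geometry
  same <- vapply(profiles, function(p) identical(p$geometry, geom),
                 logical(1))
  if (!all(same)) fail_validation("mixed window geometries")
  pool <- function(side) {
    cov <- Reduce(`+`, lapply(profiles, function(p) p[[side]]$covered))
    eff <- Reduce(`+`, lapply(profiles, function(p) p[[side]]$effective))
    frac <- ifelse(eff > 0, cov / eff, NA_real_)
    non_te <- eff - cov
    data.frame(offset = profiles[[1]][[side]]$offset, covered = cov,
               effective = eff, fraction = frac,
               odds = ifelse(eff > 0 & non_te > 0, cov / non_te, NA_real_))
  }
  structure(list(upstream = pool("upstream"), downstream = pool("downstream"),
                 geometry = geom, n_genes = length(profiles),
                 label = label),
            class = "te_profile")
}

#' @export
print.te_profile <- function(x, ...) {
  cat(sprintf(
    "TE profile (%s): %d gene(s), %d windows/flank (flank %d, window %d, step %d)\n",
    if (is.null(x$label) || is.na(x$label)) "unnamed" else x$label,
    x$n_genes, nrow(x$upstream), x$geometry[["flank"]],
    x$geometry[["window"]], x$geometry[["step"]]))
  cat(sprintf("  mean upstream fraction: %.3f | downstream: %.3f\n",
              mean(x$upstream$fraction, na.rm = TRUE),
              mean(x$downstream$fraction, na.rm = TRUE)))
  invisible(x)
}
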