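# Allele-specific expression: TPM normalisation, the four-category
# threshold classifier, cross-tissue intersections, Ka/Ks-by-class
# comparison and a minimal IUPAC motif scanner.

#' TPM from read counts
#'
#' `rate_i = counts_i / lengths_i`; `TPM_i = 1e6 * rate_i / sum(rate)`.
#' The result always sums to one million.
#'
#' @param counts non-negative read counts (at least one positive).
#' @param lengths positive effective lengths, bp.
#' @return TPM vector.
#' @export
tpm_from_counts <- function(counts, lengths) {
  if (length(counts) != length(lengths)) {
    fail_validation("counts and lengths differ in length")
  }
  if (any(lengths <= 0)) fail_validation("effective lengths must be positive")
  if (any(counts < 0)) fail_validation("counts must be non-negative")
  if (all(counts == 0)) fail_validation("all counts are zero")
  rate <- counts / lengths
  1e6 * rate / sum(rate)
}

#' Classify one gene's allele expression pattern
#'
#' Threshold rules on per-allele TPM: both alleles at or below
#' `expr_threshold` (strict `>` defines expressed) is `not_expressed`; both
#' expressed with fold (max/min) below `fold_threshold` is `biallelic`;
#' both expressed with fold at or above the threshold is
#' `higher_one_allele`; exactly one expressed is the dominant class of that
#' haplotype. A fold of exactly `fold_threshold` falls in
#' `higher_one_allele` so the two printed rules partition the space.
#'
#' @param hap1_tpm,hap3_tpm per-allele TPM (>= 0).
#' @param expr_threshold expressed means TPM strictly above this (default 2).
#' @param fold_threshold imbalance boundary (default 2).
#' @return list with `class` and `fold` (max/min, `NA` when either TPM is 0).
#' @export
#' @examples
#' classify_ase(10, 8)$class   # biallelic
#' classify_ase(10, 1)$class   # hap1_dominant
classify_ase <- function(hap1_tpm, hap3_tpm, expr_threshold = 2,
                         fold_threshold = 2) {
  if (hap1_tpm < 0 || hap3_tpm < 0) fail_validation("negative TPM")
  e1 <- hap1_tpm > expr_threshold
  e3 <- hap3_tpm > expr_threshold
  fold <- if (hap1_tpm > 0 && hap3_tpm > 0) {
    max(hap1_tpm, hap3_tpm) / min(hap1_tpm, hap3_tpm)
  } else NA_real_
  cls <- if (!e1 && !e3) {
    "not_expressed"
  } else if (e1 && e3) {
    if (fold < fold_threshold) "biallelic" else "higher_one_allele"
  } else if (e1) "hap1_dominant" else "hap3_dominant"
  list(class = cls, fold = fold)
}

#' Classify a full allele-expression table
#'
#' One call per (gene, tissue) row plus per-tissue class fractions over
#' expressed rows (class != not_expressed), with denominators reported.
#' The summary is invariant to row order.
#'
#' @param table data.frame with `gene_id`, `tissue`, `hap1_tpm`, `hap3_tpm`
#'   (wide form), or the long form from [read_expression()] with exactly two
#'   haplotype levels, which is widened internally.
#' @param expr_threshold,fold_threshold see [classify_ase()].
#' @return list with `calls` (data.frame gene_id, tissue, class, fold) and
#'   `fractions` (data.frame tissue, class, fraction, n_expressed).
#' @export
classify_matrix <- function(table, expr_threshold = 2, fold_threshold = 2) {
  if (nrow(table) == 0L) fail_validation("empty expression table")
  if (!"hap1_tpm" %in% names(table)) table <- widen_expression(table)
  calls <- do.call(rbind, lapply(seq_len(nrow(table)), function(i) {
    r <- classify_ase(table$hap1_tpm[i], table$hap3_tpm[i],
                      expr_threshold, fold_threshold)
    data.frame(gene_id = table$gene_id[i], tissue = table$tissue[i],
               class = r$class, fold = r$fold, stringsAsFactors = FALSE)
  }))
  fractions <- do.call(rbind, lapply(unique(calls$tissue), function(t) {
    sub <- calls[calls$tissue == t & calls$class != "not_expressed", ,
                 drop = FALSE]
    if (nrow(sub) == 0L) {
      warning("no expressed genes in tissue ", t, "; fractions undefined")
      return(data.frame(tissue = t, class = ASE_CLASSES,
                        fraction = NA_real_, n_expressed = 0L))
    }
    data.frame(tissue = t, class = ASE_CLASSES,
               fraction = vapply(ASE_CLASSES, function(cl) {
                 mean(sub$class == cl)
               }, numeric(1)),
               n_expressed = nrow(sub), stringsAsFactors = FALSE)
  }))
  rownames(fractions) <- NULL
  list(calls = calls, fractions = fractions)
}

# long (gene_id, haplotype, tissue, tpm) -> wide (gene_id, tissue,
# hap1_tpm, hap3_tpm); haplotype levels map by sorted order
widen_expression <- function(long) {
  need <- c("gene_id", "haplotype", "tissue", "tpm")
  if (!all(need %in% names(long))) {
    fail_validation("expression table must be wide (hap1_tpm/hap3_tpm) or ",
                    "long (gene_id, haplotype, tissue, tpm)")
  }
  haps <- sort(unique(long$haplotype))
  if (length(haps) != 2L) {
    fail_validation("long expression table must have exactly 2 haplotypes")
  }
  a <- long[long$haplotype == haps[1], c("gene_id", "tissue", "tpm")]
  b <- long[long$haplotype == haps[2], c("gene_id", "tissue", "tpm")]
  names(a)[3] <- "hap1_tpm"
  names(b)[3] <- "hap3_tpm"
  merge(a, b, by = c("gene_id", "tissue"))
}

#' Overlap counts of ASE gene sets across tissues
#'
#' Restricts each tissue's calls to `classes_of_interest`, then counts gene
#' ids in every exclusive region of the k-set Venn partition (2^k - 1
#' regions). Region counts sum to the size of the union.
#'
#' @param calls data.frame of calls (gene_id, tissue, class).
#' @param classes_of_interest character vector of classes (default: the two
#'   dominant classes, i.e. haplotype-specific expression).
#' @param tissues tissue labels to use (default: all in `calls`, >= 2).
#' @return named integer vector over regions, names like `"stem"`,
#'   `"stem&root"`.
#' @export
intersect_ase_sets <- function(calls,
                               classes_of_interest = c("hap1_dominant",
                                                       "hap3_dominant"),
                               tissues = NULL) {
  if (is.null(tissues)) tissues <- unique(calls$tissue)
  if (length(tissues) < 2L) fail_validation("need >= 2 tissues")
  if (!all(tissues %in% calls$tissue)) {
    fail_validation("unknown tissue label: ",
                    tissues[!tissues %in% calls$tissue][1])
  }
  sets <- lapply(tissues, function(t) {
    unique(calls$gene_id[calls$tissue == t &
                           calls$class %in% classes_of_interest])
  })
  names(sets) <- tissues
  ids <- unique(unlist(sets))
  member <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  if (length(ids) == 1L) member <- matrix(member, nrow = 1,
                                          dimnames = list(NULL, tissues))
  k <- length(tissues)
  out <- integer(0)
  for (mask in seq_len(2^k - 1L)) {
    in_set <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1L)))
    region <- paste(tissues[in_set], collapse = "&")
    cnt <- if (length(ids)) {
      sum(apply(member, 1L, function(m) all(m == in_set)))
    } else 0L
    out[region] <- cnt
  }
  out
}

#' Compare Ka/Ks between two ASE classes (Welch t-test)
#'
#' Joins per-pair Ka/Ks ratios to calls for one tissue, drops undefined
#' ratios (count reported) and runs a two-sample Welch t-test.
#'
#' @param kaks data.frame with `gene_id` and `ratio`.
#' @param calls data.frame of ASE calls for one tissue.
#' @param class_a,class_b the two classes to compare.
#' @return list with `t`, `p`, `summary` (per-group n/mean/sd),
#'   `n_undefined`.
#' @export
compare_kaks_by_class <- function(kaks, calls, class_a, class_b) {
  pick <- function(cl) {
    ids <- calls$gene_id[calls$class == cl]
    r <- kaks$ratio[kaks$gene_id %in% ids]
    r
  }
  ra <- pick(class_a); rb <- pick(class_b)
  n_undef <- sum(is.na(ra)) + sum(is.na(rb))
  ra <- ra[!is.na(ra)]; rb <- rb[!is.na(rb)]
  if (length(ra) < 3L || length(rb) < 3L) {
    fail_validation("both groups need >= 3 defined Ka/Ks ratios (",
                    length(ra), " vs ", length(rb), ")")
  }
  if (stats::sd(ra) == 0 && stats::sd(rb) == 0 && mean(ra) == mean(rb)) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- stats::t.test(ra, rb, var.equal = FALSE)
  }
  list(
    t = unname(tt$statistic), p = tt$p.value,
    summary = data.frame(
      class = c(class_a, class_b), n = c(length(ra), length(rb)),
      mean = c(mean(ra), mean(rb)), sd = c(stats::sd(ra), stats::sd(rb))),
    n_undefined = n_undef
  )
}

IUPAC_MAP <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
               S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT",
               H = "ACT", V = "ACG", N = "ACGT")

#' Scan a sequence for an IUPAC motif
#'
#' Reports all (possibly overlapping) matches with 0-based positions.
#' With `both_strands`, reverse-strand hits are found by matching the
#' reverse complement of the motif and are reported against forward
#' coordinates. An N in the subject matches only motif N.
#'
#' @param sequence nucleotide string over A/C/G/T/N.
#' @param motif IUPAC pattern (default `"ACGTG"`, the ABRE ACGT-core
#'   element bound by subfamily-A bZIP factors).
#' @param both_strands also scan the reverse strand.
#' @return data.frame with `position` (0-based), `strand`, `match`.
#' @export
scan_motif <- function(sequence, motif = "ACGTG", both_strands = FALSE) {
  sequence <- toupper(sequence)
  motif <- toupper(motif)
  if (grepl("[^ACGTN]", sequence)) {
    fail_validation("sequence contains non-ACGTN characters")
  }
  if (!all(strsplit(motif, "")[[1]] %in% names(IUPAC_MAP))) {
    fail_validation("invalid IUPAC symbol in motif: ", motif)
  }
  hits_one <- function(pat, strand) {
    if (nchar(sequence) < nchar(pat) || nchar(sequence) == 0L) {
      return(NULL)
    }
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat),
                                  Biostrings::DNAString(sequence),
                                  fixed = FALSE)
    if (length(m) == 0L) return(NULL)
    data.frame(position = BiocGenerics::start(m) - 1L, strand = strand,
               match = as.character(m), stringsAsFactors = FALSE)
  }
  out <- hits_one(motif, "+")
  if (both_strands) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(motif)))
    out <- rbind(out, hits_one(rc, "-"))
  }
  if (is.null(out)) {
    return(data.frame(position = integer(0), strand = character(0),
                      match = character(0)))
  }
  out[order(out$position), , drop = FALSE]
}
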