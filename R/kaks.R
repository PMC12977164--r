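# Nei-Gojobori (1986) Ka/Ks estimation, Ks distributions, WGD peak
# detection and Ks = 2*mu*T dating.

BASES <- c("A", "C", "G", "T")

# all 64 codons in fixed A,C,G,T order; translation via the standard code
all_codons <- function() {
  g <- expand.grid(p3 = BASES, p2 = BASES, p1 = BASES,
                   stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

translate_codon <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codon])
}

is_stop_codon <- function(codon) {
  translate_codon(codon) == "*"
}

codon_table <- function() {
  if (is.null(.tetradiv_cache$codons)) {
    codons <- all_codons()
    aa <- translate_codon(codons)
    .tetradiv_cache$codons <- codons
    .tetradiv_cache$aa <- stats::setNames(aa, codons)
  }
  .tetradiv_cache
}

#' Synonymous and nonsynonymous site counts of a codon (NG86)
#'
#' For each of the nine single-nucleotide mutants of the codon, the mutant
#' is synonymous if it encodes the same amino acid; mutants to stop codons
#' count as nonsynonymous. The synonymous site count is the number of
#' synonymous mutants divided by 3; synonymous + nonsynonymous sites = 3
#' exactly for every sense codon.
#'
#' @param codon a 3-letter string over A/C/G/T, not a stop codon.
#' @return named numeric vector `c(syn = ..., nonsyn = ...)`.
#' @export
#' @examples
#' ng86_sites("TTT")  # c(syn = 1/3, nonsyn = 8/3)
ng86_sites <- function(codon) {
  ct <- codon_table()
  validate_codon(codon)
  n_syn <- 0
  aa0 <- ct$aa[[codon]]
  for (pos in 1:3) {
    for (b in BASES) {
      if (substr(codon, pos, pos) == b) next
      mut <- codon
      substr(mut, pos, pos) <- b
      aa1 <- ct$aa[[mut]]
      if (aa1 != "*" && aa1 == aa0) n_syn <- n_syn + 1
    }
  }
  c(syn = n_syn / 3, nonsyn = 3 - n_syn / 3)
}

validate_codon <- function(codon) {
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L) {
    fail_validation("codon must be a single 3-letter string, got: ",
                    deparse(codon))
  }
  if (!all(strsplit(codon, "")[[1]] %in% BASES)) {
    fail_validation("codon contains non-ACGT characters: ", codon)
  }
  if (is_stop_codon(codon)) {
    fail_validation("stop codon not allowed here: ", codon)
  }
  invisible(codon)
}

#' Synonymous and nonsynonymous differences between two codons (NG86)
#'
#' Averages synonymous/nonsynonymous step counts over all orderings of the
#' substitutions separating the codons. Orderings that pass through a stop
#' codon are excluded when at least one stop-free ordering exists
#' (`stop_paths = "exclude"`, the default); with no stop-free ordering, or
#' with `stop_paths = "include"`, all orderings are averaged and any step
#' whose source or target is a stop codon counts as nonsynonymous.
#'
#' @param codon_a,codon_b sense codons over A/C/G/T.
#' @param stop_paths `"exclude"` or `"include"`.
#' @return named numeric vector `c(Sd = ..., Nd = ...)`; `Sd + Nd` equals the
#'   nucleotide Hamming distance whenever no ordering is excluded.
#' @export
#' @examples
#' ng86_differences("TTT", "TTC")  # c(Sd = 1, Nd = 0)
ng86_differences <- function(codon_a, codon_b,
                             stop_paths = c("exclude", "include")) {
  stop_paths <- match.arg(stop_paths)
  validate_codon(codon_a)
  validate_codon(codon_b)
  ct <- codon_table()
  pos <- which(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(c(Sd = 0, Nd = 0))
  perms <- permutations_of(pos)
  step_syn <- function(from, to) {
    a <- ct$aa[[from]]; b <- ct$aa[[to]]
    a != "*" && b != "*" && a == b
  }
  paths <- lapply(perms, function(ord) {
    cur <- codon_a
    sd <- 0; nd <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(codon_b, p, p)
      if (ct$aa[[nxt]] == "*") blocked <- TRUE
      if (step_syn(cur, nxt)) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, blocked = blocked)
  })
  ok <- !vapply(paths, `[[`, logical(1), "blocked")
  use <- if (stop_paths == "exclude" && any(ok)) paths[ok] else paths
  sd <- mean(vapply(use, `[[`, numeric(1), "sd"))
  nd <- mean(vapply(use, `[[`, numeric(1), "nd"))
  c(Sd = sd, Nd = nd)
}

# all orderings of a short vector (k <= 3 here)
permutations_of <- function(x) {
  k <- length(x)
  if (k == 1L) return(list(x))
  out <- list()
  for (i in seq_len(k)) {
    for (rest in permutations_of(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

# lazily built per-codon site table and pairwise difference tables,
# indexed by codon string, one table per stop-path mode
ng86_tables <- function(stop_paths = "exclude") {
  key <- paste0("ng86_", stop_paths)
  if (is.null(.tetradiv_cache[[key]])) {
    ct <- codon_table()
    sense <- ct$codons[ct$aa[ct$codons] != "*"]
    sites <- t(vapply(sense, ng86_sites, numeric(2)))
    n <- length(sense)
    Sd <- matrix(0, n, n, dimnames = list(sense, sense))
    Nd <- matrix(0, n, n, dimnames = list(sense, sense))
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        d <- ng86_differences(sense[i], sense[j], stop_paths = stop_paths)
        Sd[i, j] <- d[["Sd"]]
        Nd[i, j] <- d[["Nd"]]
      }
    }
    .tetradiv_cache[[key]] <- list(sense = sense, sites = sites, Sd = Sd, Nd = Nd)
  }
  .tetradiv_cache[[key]]
}

split_codons <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n %% 3 != 0) fail_validation("sequence length not a multiple of 3: ", n)
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

#' Ka/Ks for one codon-aligned sequence pair (NG86 with JC correction)
#'
#' Codon positions where either sequence carries a gap, an ambiguous base or
#' a stop codon are dropped pairwise. Site counts are averaged over the two
#' sequences; `pS = Sd / S`, `pN = Nd / N`; rates are Jukes-Cantor corrected,
#' `Ks = -3/4 * log(1 - 4/3 * pS)` (same form for Ka). Proportions at or
#' beyond the correction domain (>= 3/4) yield `NA` with a reason flag
#' rather than a fabricated value.
#'
#' @param seq_a,seq_b equal-length codon-aligned sequences (gap `-` allowed,
#'   in codon-sized runs at codon boundaries).
#' @param min_codons minimum comparable codons required (default 10).
#' @param stop_paths pathway handling, see [ng86_differences()].
#' @return object of class `kaks_result`: list with `S_sites`, `N_sites`,
#'   `Sd`, `Nd`, `pS`, `pN`, `Ks`, `Ka`, `ratio`, `n_codons`, `flags`.
#' @export
kaks_pair <- function(seq_a, seq_b, min_codons = 10,
                      stop_paths = c("exclude", "include")) {
  stop_paths <- match.arg(stop_paths)
  if (nchar(seq_a) != nchar(seq_b)) {
    fail_validation("aligned sequences must have equal length")
  }
  ca <- split_codons(seq_a)
  cb <- split_codons(seq_b)
  tab <- ng86_tables(stop_paths)
  usable <- ca %in% tab$sense & cb %in% tab$sense
  ca <- ca[usable]; cb <- cb[usable]
  if (length(ca) < min_codons) {
    fail_validation("fewer than ", min_codons, " comparable codons (",
                    length(ca), ")")
  }
  S <- (sum(tab$sites[ca, "syn"]) + sum(tab$sites[cb, "syn"])) / 2
  N <- (sum(tab$sites[ca, "nonsyn"]) + sum(tab$sites[cb, "nonsyn"])) / 2
  idx <- cbind(match(ca, tab$sense), match(cb, tab$sense))
  Sd <- sum(tab$Sd[idx])
  Nd <- sum(tab$Nd[idx])
  pS <- Sd / S
  pN <- Nd / N
  flags <- character(0)
  jc <- function(p) -0.75 * log(1 - 4 / 3 * p)
  if (pS >= 0.75) {
    Ks <- NA_real_
    flags <- c(flags, "Ks: JC correction domain (pS >= 3/4)")
  } else Ks <- jc(pS)
  if (pN >= 0.75) {
    Ka <- NA_real_
    flags <- c(flags, "Ka: JC correction domain (pN >= 3/4)")
  } else Ka <- jc(pN)
  ratio <- if (is.na(Ka) || is.na(Ks) || Ks == 0) NA_real_ else Ka / Ks
  if (!is.na(Ks) && Ks == 0) flags <- c(flags, "ratio: undefined (Ks = 0)")
  structure(
    list(S_sites = S, N_sites = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
         Ks = Ks, Ka = Ka, ratio = ratio, n_codons = length(ca),
         flags = flags),
    class = "kaks_result"
  )
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf(
    "NG86 pair: %d codons | S = %.2f N = %.2f | Sd = %.2f Nd = %.2f\n",
    x$n_codons, x$S_sites, x$N_sites, x$Sd, x$Nd))
  cat(sprintf("  Ks = %s  Ka = %s  Ka/Ks = %s\n",
              format(x$Ks, digits = 4), format(x$Ka, digits = 4),
              format(x$ratio, digits = 4)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Pool per-pair Ks values into a distribution
#'
#' Collects finite Ks values from a list of aligned pairs (or a numeric
#' vector of precomputed Ks). Values above `saturation_cutoff` are retained
#' in the record but excluded from peak detection (synonymous saturation).
#'
#' @param pairs list of 2-element character vectors (aligned CDS pairs) or a
#'   numeric vector of Ks values.
#' @param saturation_cutoff Ks ceiling for peak detection (default 3).
#' @param ... passed to [kaks_pair()] when `pairs` holds sequences.
#' @return object of class `ks_distribution`: list with `values`, `n_undefined`,
#'   `saturation_cutoff`.
#' @export
ks_distribution <- function(pairs, saturation_cutoff = 3, ...) {
  if (is.numeric(pairs)) {
    ks <- pairs
  } else {
    ks <- vapply(pairs, function(p) {
      r <- kaks_pair(p[[1]], p[[2]], ...)
      if (is.na(r$Ks)) NA_real_ else r$Ks
    }, numeric(1))
  }
  n_undef <- sum(is.na(ks) | !is.finite(ks))
  ks <- ks[!is.na(ks) & is.finite(ks)]
  if (length(ks) == 0L) fail_validation("no defined Ks values")
  if (any(ks < 0)) fail_validation("negative Ks values are invalid")
  structure(list(values = ks, n_undefined = n_undef,
                 saturation_cutoff = saturation_cutoff),
            class = "ks_distribution")
}

#' Detect WGD peaks in a Ks distribution
#'
#' Gaussian kernel density estimated on the grid `[0, saturation_cutoff]`
#' with 0.005 spacing (Silverman's rule bandwidth unless given). Peaks are
#' local maxima whose topographic prominence is at least
#' `min_prominence * max(density)`, returned sorted by location.
#'
#' @param dist a `ks_distribution`.
#' @param bandwidth `"silverman"` or a positive number.
#' @param min_prominence prominence threshold as a fraction of the maximum
#'   density (default 0.05).
#' @param min_values minimum number of usable Ks values (default 30).
#' @return data.frame with columns `location`, `density`, `prominence`
#'   (zero rows, with a warning, when nothing passes).
#' @export
detect_ks_peaks <- function(dist, bandwidth = "silverman",
                            min_prominence = 0.05, min_values = 30) {
  stopifnot(inherits(dist, "ks_distribution"))
  x <- dist$values[dist$values <= dist$saturation_cutoff]
  if (length(x) < min_values) {
    fail_validation("peak detection needs >= ", min_values,
                    " Ks values below the saturation cutoff, got ", length(x))
  }
  if (identical(bandwidth, "silverman")) {
    bw <- tryCatch(stats::bw.nrd0(x), error = function(e) 0)
    # degenerate (near-constant) samples: fall back to a narrow fixed kernel
    if (!is.finite(bw) || bw <= 0) bw <- 0.005
  } else {
    bw <- as.numeric(bandwidth)
    if (!is.finite(bw) || bw <= 0) fail_validation("bandwidth must be > 0")
  }
  grid_n <- round(dist$saturation_cutoff / 0.005) + 1L
  d <- stats::density(x, bw = bw, from = 0, to = dist$saturation_cutoff,
                      n = grid_n)
  peaks <- grid_peaks(d$y, min_prominence = min_prominence)
  if (nrow(peaks) == 0L) {
    warning("no Ks peak passes the prominence threshold")
    return(data.frame(location = numeric(0), density = numeric(0),
                      prominence = numeric(0)))
  }
  out <- data.frame(location = d$x[peaks$idx], density = peaks$height,
                    prominence = peaks$prominence)
  out[order(out$location), , drop = FALSE]
}

# local maxima of a grid signal with topographic prominence; a plateau is
# reported once, at its left edge; grid edges count as maxima when the
# signal falls away inward
grid_peaks <- function(y, min_prominence) {
  n <- length(y)
  cand <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && y[j + 1L] == y[i]) j <- j + 1L
    left <- if (i == 1L) -Inf else y[i - 1L]
    right <- if (j == n) -Inf else y[j + 1L]
    if (y[i] > left && y[i] > right) cand <- c(cand, i)
    i <- j + 1L
  }
  if (length(cand) == 0L) {
    return(data.frame(idx = integer(0), height = numeric(0),
                      prominence = numeric(0)))
  }
  # prominence: height above the higher of the two key saddles, i.e. the
  # lowest point crossed before reaching higher terrain on each side; a
  # side where the walk hits the grid edge without meeting higher terrain
  # does not constrain the peak (boundary-truncated distributions keep
  # their leftmost mode prominent)
  prom <- vapply(cand, function(i) {
    h <- y[i]
    side_min <- function(idx_seq) {
      m <- h
      for (j in idx_seq) {
        if (y[j] > h) return(m)
        m <- min(m, y[j])
      }
      -Inf
    }
    left_min <- if (i > 1L) side_min((i - 1L):1L) else -Inf
    right_min <- if (i < n) side_min((i + 1L):n) else -Inf
    base <- max(left_min, right_min)
    if (!is.finite(base)) h else h - base
  }, numeric(1))
  keep <- prom >= min_prominence * max(y)
  data.frame(idx = cand[keep], height = y[cand[keep]], prominence = prom[keep])
}

#' Date a duplication event from its Ks peak
#'
#' Under a molecular clock, `Ks = 2 * mu * T`, so `T = Ks / (2 * mu)` with
#' `mu` the per-site per-year substitution rate. No default `mu` is shipped:
#' the appropriate rate is lineage-specific and must be supplied.
#'
#' @param ks synonymous divergence at the peak (>= 0).
#' @param mu substitutions/site/year (> 0).
#' @return divergence time in years.
#' @export
#' @examples
#' date_event(0.2, mu = 1e-8)  # 1e7 years
date_event <- function(ks, mu) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0) {
    fail_validation("mu must be a single positive number")
  }
  if (any(ks < 0)) fail_validation("ks must be >= 0")
  ks / (2 * mu)
}
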