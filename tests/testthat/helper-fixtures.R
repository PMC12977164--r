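# shared fixtures and independent oracles, built in code at test time

GENCODE <- Biostrings::GENETIC_CODE
NT <- c("A", "C", "G", "T")
SENSE <- names(GENCODE)[GENCODE != "*"]

# deterministic random CDS over sense codons
fixture_cds <- function(n_codons, seed = 1) {
  withr_seed(seed, paste(sample(SENSE, n_codons, replace = TRUE),
                         collapse = ""))
}

withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# --- independent NG86 oracles (used only by tests) -------------------------

# synonymous site count by direct single-mutant enumeration
oracle_sites <- function(codon) {
  aa0 <- GENCODE[[codon]]
  syn <- 0L
  for (p in 1:3) {
    for (b in setdiff(NT, substr(codon, p, p))) {
      m <- codon
      substr(m, p, p) <- b
      if (GENCODE[[m]] != "*" && GENCODE[[m]] == aa0) syn <- syn + 1L
    }
  }
  c(syn = syn / 3, nonsyn = 3 - syn / 3)
}

# pathway-enumeration oracle for Sd/Nd, Hamming distance <= 3
oracle_differences <- function(a, b, stop_paths = "exclude") {
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  k <- length(pos)
  if (k == 0) return(c(Sd = 0, Nd = 0))
  orders <- if (k == 1) list(pos) else {
    # explicit permutation enumeration, independent of package internals
    perms <- list()
    idx <- seq_len(k)
    rec <- function(prefix, rest) {
      if (!length(rest)) {
        perms[[length(perms) + 1L]] <<- pos[prefix]
      } else {
        for (r in rest) rec(c(prefix, r), setdiff(rest, r))
      }
    }
    rec(integer(0), idx)
    perms
  }
  walk <- function(ord) {
    cur <- a; sd <- 0; nd <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (GENCODE[[nxt]] == "*") blocked <- TRUE
      syn <- GENCODE[[cur]] != "*" && GENCODE[[nxt]] != "*" &&
        GENCODE[[cur]] == GENCODE[[nxt]]
      if (syn) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd, blocked)
  }
  res <- t(vapply(orders, walk, numeric(3)))
  ok <- res[, 3] == 0
  use <- if (stop_paths == "exclude" && any(ok)) res[ok, , drop = FALSE]
         else res
  c(Sd = mean(use[, 1]), Nd = mean(use[, 2]))
}

# closed-form Welch t-test oracle
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# brute-force per-base TE window coverage oracle
oracle_window_coverage <- function(tes, win_start, win_end) {
  if (win_end <= win_start) return(0L)
  covered <- rep(FALSE, win_end - win_start)
  for (i in seq_len(nrow(tes))) {
    s <- max(tes$start[i], win_start)
    e <- min(tes$end[i], win_end)
    if (s < e) covered[(s - win_start + 1):(e - win_start)] <- TRUE
  }
  sum(covered)
}

# component sizes (in raw-block units) induced by a consolidation
table_block_sizes <- function(raw, cons) {
  vapply(seq_len(nrow(cons)), function(i) {
    sum(vapply(seq_len(nrow(raw)), function(j) {
      all(unlist(raw$genes_a[j]) %in% unlist(cons$genes_a[i]))
    }, logical(1)))
  }, integer(1))
}

# small annotated gene table on one chromosome, evenly spaced
fixture_genes <- function(n, prefix, chrom, gene_len = 500, gap = 500) {
  starts <- (seq_len(n) - 1L) * (gene_len + gap)
  data.frame(gene_id = paste0(prefix, seq_len(n)), chrom = chrom,
             start = starts, end = starts + gene_len,
             stringsAsFactors = FALSE)
}
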