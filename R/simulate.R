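# Synthetic autotetraploid dataset generator. Four haplotype genomes derive
# from one ancestral sequence along a fixed 4-branch topology
# (root -> two lineage ancestors -> haplotypes), so within-lineage variant
# density is far below between-lineage density. Divergence is layered:
# intergenic sequence evolves by a uniform per-bp substitution process on
# the branches; coding sequence diverges only at the lineage split, via
# evolve_cds_pair() at the configured dS/dN targets, which keeps genome
# FASTA, annotation and the truth CDS-pair table mutually consistent.

#' Build and validate a simulation configuration
#'
#' Defaults describe the stated world the generator emulates: a tetraploid
#' with two haplotype lineages ({H1,H2} vs {H3,H4}), within-lineage SNP
#' density an order of magnitude below between-lineage, a background
#' gene-copy retention rate of 0.913 with an elevated 0.984 for a tagged
#' pathway gene set, coding divergence at the lineage split of dS = 0.02
#' (the recent-WGD scale) with dN = 0.005, ~60% TE coverage, and per-tissue
#' allele-specific-expression designs whose haplotype-dominant totals are
#' 2.2/2.4/1.7/1.5% across stem, root, tuber peel and tuber flesh.
#'
#' @param seed integer master seed.
#' @param n_chromosomes chromosomes per haplotype.
#' @param chrom_length chromosome length, bp.
#' @param ploidy number of haplotypes (>= 2).
#' @param lineage_pairs list of two character vectors partitioning the
#'   haplotype labels; `NULL` splits H1..Hp in half.
#' @param within_lineage_snp_rate,between_lineage_snp_rate substitutions/bp
#'   between haplotype pairs within / across lineages.
#' @param indel_fraction proportion of variant events that are InDels.
#' @param n_genes_per_chrom genes per chromosome (0 allowed).
#' @param cds_length CDS length per gene, bp, multiple of 3.
#' @param retention_background,retention_pathway per-copy retention
#'   probabilities for background / pathway-tagged genes.
#' @param pathway_gene_fraction proportion of genes tagged as pathway.
#' @param target_dS,target_dN coding divergence (substitutions per
#'   synonymous / nonsynonymous site) between the lineages.
#' @param te_fraction genome proportion covered by TE intervals.
#' @param tissues tissue labels.
#' @param ase_design matrix (tissues x 4) of class proportions over
#'   biallelic, higher_one_allele, hap1_dominant, hap3_dominant; rows must
#'   sum to 1. `NULL` uses the default design described above.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 2L,
                              chrom_length = 500000L,
                              ploidy = 4L,
                              lineage_pairs = NULL,
                              within_lineage_snp_rate = 1e-3,
                              between_lineage_snp_rate = 1e-2,
                              indel_fraction = 0.1,
                              n_genes_per_chrom = 200L,
                              cds_length = 300L,
                              retention_background = 0.913,
                              retention_pathway = 0.984,
                              pathway_gene_fraction = 0.05,
                              target_dS = 0.02,
                              target_dN = 0.005,
                              te_fraction = 0.6,
                              tissues = c("stem", "root", "tuber_peel",
                                          "tuber_flesh"),
                              ase_design = NULL) {
  if (ploidy < 2) fail_validation("ploidy must be >= 2")
  haps <- paste0("H", seq_len(ploidy))
  if (is.null(lineage_pairs)) {
    half <- ceiling(ploidy / 2)
    lineage_pairs <- list(haps[seq_len(half)], haps[-seq_len(half)])
  }
  if (!setequal(unlist(lineage_pairs), haps) ||
      length(unlist(lineage_pairs)) != ploidy) {
    fail_validation("lineage_pairs must partition the haplotype labels")
  }
  probs <- c(within_lineage_snp_rate, between_lineage_snp_rate,
             indel_fraction, retention_background, retention_pathway,
             pathway_gene_fraction, te_fraction)
  if (any(probs < 0 | probs > 1)) {
    fail_validation("all rates/probabilities must lie in [0, 1]")
  }
  if (within_lineage_snp_rate >= between_lineage_snp_rate) {
    fail_validation("within-lineage SNP rate must be below between-lineage")
  }
  if (cds_length %% 3 != 0) fail_validation("cds_length must be a multiple of 3")
  if (n_genes_per_chrom > 0 &&
      chrom_length / n_genes_per_chrom <= cds_length + 2) {
    fail_validation("chromosome too short for requested gene count")
  }
  if (is.null(ase_design)) {
    dom_total <- c(0.022, 0.024, 0.017, 0.015)[seq_along(tissues)]
    if (length(dom_total) < length(tissues)) {
      dom_total <- rep_len(0.02, length(tissues))
    }
    ase_design <- cbind(
      biallelic = 0.80,
      higher_one_allele = 1 - 0.80 - dom_total,
      hap1_dominant = dom_total / 2,
      hap3_dominant = dom_total / 2
    )
    rownames(ase_design) <- tissues
  }
  ase_design <- as.matrix(ase_design)
  if (nrow(ase_design) != length(tissues)) {
    fail_validation("ase_design needs one row per tissue")
  }
  if (any(abs(rowSums(ase_design) - 1) > 1e-9)) {
    fail_validation("ase_design rows must sum to 1")
  }
  if (any(ase_design < 0)) fail_validation("ase_design proportions must be >= 0")
  structure(list(
    seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length), ploidy = as.integer(ploidy),
    haplotypes = haps, lineage_pairs = lineage_pairs,
    within_lineage_snp_rate = within_lineage_snp_rate,
    between_lineage_snp_rate = between_lineage_snp_rate,
    indel_fraction = indel_fraction,
    n_genes_per_chrom = as.integer(n_genes_per_chrom),
    cds_length = as.integer(cds_length),
    retention_background = retention_background,
    retention_pathway = retention_pathway,
    pathway_gene_fraction = pathway_gene_fraction,
    target_dS = target_dS, target_dN = target_dN,
    te_fraction = te_fraction, tissues = tissues, ase_design = ase_design
  ), class = "simulation_config")
}

SENSE_CODONS <- function() {
  ct <- codon_table()
  ct$codons[ct$aa[ct$codons] != "*"]
}

random_cds <- function(n_codons) {
  paste(sample(SENSE_CODONS(), n_codons, replace = TRUE), collapse = "")
}

revcomp_chars <- function(x) rev(chartr("ACGTN", "TGCAN", x))

# inverse Jukes-Cantor: observed proportion that corrects back to d
jc_inverse <- function(d) 0.75 * (1 - exp(-4 / 3 * d))

#' Evolve a coding sequence to target synonymous/nonsynonymous divergence
#'
#' Repeatedly proposes random single-nucleotide changes, classified as
#' synonymous or nonsynonymous against the current codon and rejected when
#' they create a stop codon, until the per-class substitution quotas are
#' met. Targets are substitutions per site after Jukes-Cantor correction:
#' the quota for each class is `round(p * sites)` with
#' `p = 3/4 (1 - exp(-4/3 target))`, so the downstream NG86+JC estimator is
#' centred on the target. At most one substitution lands per codon, which
#' makes the realized counts recoverable exactly by diffing the sequences.
#'
#' @param cds coding sequence (multiple of 3, no internal stops).
#' @param target_dS,target_dN target divergence per synonymous /
#'   nonsynonymous site.
#' @param seed integer seed.
#' @return list with `seq` (mutated CDS), `syn_subs`, `nonsyn_subs`
#'   (realized counts), `S_sites`, `N_sites` of the input.
#' @export
evolve_cds_pair <- function(cds, target_dS, target_dN, seed) {
  codons <- split_codons(cds)
  tab <- ng86_tables()
  if (!all(codons %in% tab$sense)) {
    fail_validation("CDS contains stop or ambiguous codons")
  }
  if (target_dS < 0 || target_dN < 0) fail_validation("targets must be >= 0")
  if (jc_inverse(target_dS) >= 0.75 || jc_inverse(target_dN) >= 0.75) {
    fail_validation("target divergence beyond JC saturation")
  }
  S <- sum(tab$sites[codons, "syn"])
  N <- sum(tab$sites[codons, "nonsyn"])
  if (target_dS > 0 && S == 0) {
    fail_validation("impossible target: no synonymous sites in CDS")
  }
  n_syn <- round(jc_inverse(target_dS) * S)
  n_nonsyn <- round(jc_inverse(target_dN) * N)
  if (n_syn + n_nonsyn > length(codons)) {
    fail_validation("targets require more substitutions than codons ",
                    "(one substitution per codon maximum)")
  }
  ct <- codon_table()
  with_seed(seed, {
    out <- codons
    free <- seq_along(codons)
    got_syn <- 0L
    got_nonsyn <- 0L
    guard <- 0L
    max_iter <- 200L * (n_syn + n_nonsyn) + 10000L
    while ((got_syn < n_syn || got_nonsyn < n_nonsyn)) {
      guard <- guard + 1L
      if (guard > max_iter) {
        fail_validation("substitution targets unreachable after ", max_iter,
                        " proposals")
      }
      ci <- free[sample.int(length(free), 1L)]
      pos <- sample.int(3L, 1L)
      cur <- out[ci]
      alt <- sample(setdiff(BASES, substr(cur, pos, pos)), 1L)
      mut <- cur
      substr(mut, pos, pos) <- alt
      if (ct$aa[[mut]] == "*") next
      syn <- ct$aa[[mut]] == ct$aa[[cur]]
      if (syn && got_syn < n_syn) {
        out[ci] <- mut
        got_syn <- got_syn + 1L
        free <- free[free != ci]
      } else if (!syn && got_nonsyn < n_nonsyn) {
        out[ci] <- mut
        got_nonsyn <- got_nonsyn + 1L
        free <- free[free != ci]
      }
    }
    list(seq = paste(out, collapse = ""), syn_subs = got_syn,
         nonsyn_subs = got_nonsyn, S_sites = S, N_sites = N)
  })
}

#' Assign per-copy retention flags
#'
#' Each gene copy is independently retained with its set-specific
#' probability: `p_pathway` for pathway-tagged genes, `p_background`
#' otherwise.
#'
#' @param gene_copies data.frame with columns `gene_id`, `haplotype` and
#'   logical `pathway`.
#' @param p_background,p_pathway retention probabilities in \[0, 1\].
#' @param seed integer seed.
#' @return the input with a logical `retained` column appended.
#' @export
assign_retention <- function(gene_copies, p_background, p_pathway, seed) {
  if (any(c(p_background, p_pathway) < 0 | c(p_background, p_pathway) > 1)) {
    fail_validation("retention probabilities must lie in [0, 1]")
  }
  p <- ifelse(gene_copies$pathway, p_pathway, p_background)
  with_seed(seed, {
    gene_copies$retained <- stats::rbinom(nrow(gene_copies), 1L, p) == 1L
  })
  gene_copies
}

ASE_CLASSES <- c("biallelic", "higher_one_allele", "hap1_dominant",
                 "hap3_dominant")

# integer allocation of n rows to proportions by largest remainder
largest_remainder <- function(p, n) {
  raw <- p * n
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    add <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

#' Simulate per-allele expression with designed ASE classes
#'
#' Every gene pair is assigned one of the four ASE classes per tissue
#' according to the design proportions (largest-remainder allocation, so
#' realized fractions match the design exactly up to integer granularity).
#' TPM values are drawn to satisfy the class-defining inequalities with a
#' margin of at least `margin` (fractional) away from every threshold
#' boundary, so the classifier recovers the labels without boundary
#' ambiguity.
#'
#' @param design matrix (tissues x 4 classes) of proportions, rows sum to 1.
#' @param pair_ids character vector of paralog-pair gene ids (non-empty).
#' @param seed integer seed.
#' @param tissues tissue labels (default: design rownames).
#' @param alleles two haplotype labels for the allele columns.
#' @param expr_threshold,fold_threshold classifier thresholds.
#' @param margin fractional safety margin from thresholds.
#' @return list with `expression` (data.frame gene_id, haplotype, tissue,
#'   tpm) and `labels` (data.frame gene_id, tissue, class).
#' @export
simulate_expression <- function(design, pair_ids, seed,
                                tissues = rownames(design),
                                alleles = c("H1", "H3"),
                                expr_threshold = 2, fold_threshold = 2,
                                margin = 0.1) {
  if (length(pair_ids) == 0L) fail_validation("empty gene list")
  design <- as.matrix(design)
  if (any(abs(rowSums(design) - 1) > 1e-9)) {
    fail_validation("design rows must sum to 1")
  }
  lo_expr <- expr_threshold * (1 + margin)    # safely expressed
  hi_silent <- expr_threshold * (1 - margin)  # safely not expressed
  fold_lo <- fold_threshold * (1 - margin)    # biallelic fold ceiling
  fold_hi <- fold_threshold * (1 + margin)    # imbalanced fold floor
  n <- length(pair_ids)
  with_seed(seed, {
    expr <- list(); labels <- list()
    for (t in seq_along(tissues)) {
      counts <- largest_remainder(design[t, ], n)
      cls <- rep(ASE_CLASSES, counts)
      cls <- sample(cls)   # decouple class from gene identity
      a <- numeric(n); b <- numeric(n)
      for (i in seq_len(n)) {
        if (cls[i] == "biallelic") {
          base <- stats::runif(1, lo_expr, 50)
          f <- stats::runif(1, 1, fold_lo)
          if (stats::runif(1) < 0.5) { a[i] <- base; b[i] <- base * f }
          else { a[i] <- base * f; b[i] <- base }
        } else if (cls[i] == "higher_one_allele") {
          base <- stats::runif(1, lo_expr, 20)
          f <- stats::runif(1, fold_hi, 8)
          if (stats::runif(1) < 0.5) { a[i] <- base * f; b[i] <- base }
          else { a[i] <- base; b[i] <- base * f }
        } else if (cls[i] == "hap1_dominant") {
          a[i] <- stats::runif(1, lo_expr, 50)
          b[i] <- stats::runif(1, 0, hi_silent)
        } else {
          a[i] <- stats::runif(1, 0, hi_silent)
          b[i] <- stats::runif(1, lo_expr, 50)
        }
      }
      expr[[t]] <- data.frame(
        gene_id = rep(pair_ids, 2L),
        haplotype = rep(alleles, each = n),
        tissue = tissues[t],
        tpm = c(a, b),
        stringsAsFactors = FALSE
      )
      labels[[t]] <- data.frame(gene_id = pair_ids, tissue = tissues[t],
                                class = cls, stringsAsFactors = FALSE)
    }
    list(expression = do.call(rbind, expr), labels = do.call(rbind, labels))
  })
}

#' Simulate a complete phased tetraploid dataset with truth tables
#'
#' Generates one ancestral genome, embeds stop-free CDS for every gene,
#' evolves it along the lineage topology (intergenic substitutions and
#' InDel records on the branches; coding divergence at the lineage split at
#' the configured dS/dN), applies per-copy retention, places TE intervals
#' uniformly, and simulates per-allele expression for paralog pairs between
#' the two lineage-representative haplotypes. Identical configs produce
#' identical datasets.
#'
#' @param config a [simulation_config()].
#' @return object of class `simulated_dataset`: list with `config`,
#'   `genomes` (named list of `genome_set`), `gene_models` (named list of
#'   `gene_annotation`), `ancestral_genes` (diploid-reference annotation
#'   used as the synteny anchor side), `te_intervals`, `truth_variants`,
#'   `truth_cds_pairs`, `expression`, `truth_ase_labels`, `truth_lineages`,
#'   `truth_retention`.
#' @export
simulate_tetraploid <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  haps <- cfg$haplotypes
  L <- cfg$chrom_length
  chrom_names <- sprintf("chr%02d", seq_len(cfg$n_chromosomes))
  with_seed(cfg$seed, {
    # --- ancestral genome with embedded genes -------------------------------
    anc <- list()           # chrom -> char vector
    genes <- list()         # per-chrom gene tables
    cds_seqs <- list()      # ancestral CDS by gene id
    for (ci in seq_along(chrom_names)) {
      v <- sample(BASES, L, replace = TRUE)
      gtab <- NULL
      if (cfg$n_genes_per_chrom > 0) {
        spacing <- L %/% cfg$n_genes_per_chrom
        starts <- (seq_len(cfg$n_genes_per_chrom) - 1L) * spacing +
          sample.int(max(spacing - cfg$cds_length, 1L),
                     cfg$n_genes_per_chrom, replace = TRUE) - 1L
        strand <- sample(c("+", "-"), cfg$n_genes_per_chrom, replace = TRUE)
        ids <- sprintf("g%02d%04d", ci, seq_len(cfg$n_genes_per_chrom))
        for (gi in seq_along(ids)) {
          cds <- random_cds(cfg$cds_length %/% 3L)
          cds_seqs[[ids[gi]]] <- cds
          emb <- strsplit(cds, "")[[1]]
          if (strand[gi] == "-") emb <- revcomp_chars(emb)
          v[(starts[gi] + 1L):(starts[gi] + cfg$cds_length)] <- emb
        }
        gtab <- data.frame(gene_id = ids, chrom = chrom_names[ci],
                           start = starts, end = starts + cfg$cds_length,
                           strand = strand, stringsAsFactors = FALSE)
      }
      anc[[chrom_names[ci]]] <- v
      genes[[ci]] <- gtab
    }
    genes <- do.call(rbind, genes)
    n_genes <- if (is.null(genes)) 0L else nrow(genes)

    # pathway tagging
    if (n_genes > 0) {
      n_path <- round(cfg$pathway_gene_fraction * n_genes)
      path_ids <- if (n_path > 0) sample(genes$gene_id, n_path) else character(0)
      genes$pathway <- genes$gene_id %in% path_ids
    }

    # CDS mask per chromosome: intergenic mutation process must not touch it
    cds_mask <- lapply(chrom_names, function(cn) {
      m <- rep(FALSE, L)
      if (n_genes > 0) {
        g <- genes[genes$chrom == cn, , drop = FALSE]
        for (i in seq_len(nrow(g))) m[(g$start[i] + 1L):g$end[i]] <- TRUE
      }
      m
    })
    names(cds_mask) <- chrom_names

    # --- branch mutation events --------------------------------------------
    lam_w <- cfg$within_lineage_snp_rate / 2
    lam_b <- (cfg$between_lineage_snp_rate - cfg$within_lineage_snp_rate) / 2
    f <- cfg$indel_fraction
    branch_events <- function(rate) {
      lapply(chrom_names, function(cn) {
        inter <- which(!cds_mask[[cn]])
        n_snp <- stats::rpois(1L, rate * L)
        n_ind <- stats::rpois(1L, rate * L * f / (1 - f))
        pos <- sample(inter, min(n_snp, length(inter)))
        ind_pos <- sample(inter, min(n_ind, length(inter)))
        list(snp_pos = pos, indel_pos = sort(ind_pos))
      })
    }
    apply_branch <- function(seqs, ev) {
      for (cn in chrom_names) {
        pos <- ev[[match(cn, chrom_names)]]$snp_pos
        if (length(pos)) {
          cur <- seqs[[cn]][pos]
          alt <- vapply(cur, function(b) sample(setdiff(BASES, b), 1L),
                        character(1))
          seqs[[cn]][pos] <- alt
        }
      }
      seqs
    }
    lineages <- cfg$lineage_pairs
    ev_lineage <- list(branch_events(lam_b), branch_events(lam_b))
    ev_hap <- stats::setNames(
      lapply(haps, function(h) branch_events(lam_w)), haps)

    lin_seq <- list(apply_branch(anc, ev_lineage[[1]]),
                    apply_branch(anc, ev_lineage[[2]]))

    # --- coding divergence at the lineage split ----------------------------
    truth_cds <- NULL
    if (n_genes > 0) {
      evolved <- vector("list", n_genes)
      names(evolved) <- genes$gene_id
      rows <- vector("list", n_genes)
      for (i in seq_len(n_genes)) {
        gid <- genes$gene_id[i]
        ev <- evolve_cds_pair(cds_seqs[[gid]], cfg$target_dS, cfg$target_dN,
                              seed = derive_seed(cfg$seed, 7000L + i))
        evolved[[gid]] <- ev$seq
        rows[[i]] <- data.frame(
          pair_id = gid, seq_a = cds_seqs[[gid]], seq_b = ev$seq,
          syn_subs = ev$syn_subs, nonsyn_subs = ev$nonsyn_subs,
          S_sites = ev$S_sites, N_sites = ev$N_sites,
          stringsAsFactors = FALSE)
        # lineage 2 carries the evolved CDS in its genome
        emb <- strsplit(ev$seq, "")[[1]]
        if (genes$strand[i] == "-") emb <- revcomp_chars(emb)
        cn <- genes$chrom[i]
        lin_seq[[2]][[cn]][(genes$start[i] + 1L):genes$end[i]] <- emb
      }
      truth_cds <- do.call(rbind, rows)
    }

    # --- haplotype genomes -------------------------------------------------
    hap_of_lineage <- function(h) if (h %in% lineages[[1]]) 1L else 2L
    hap_seqs <- stats::setNames(lapply(haps, function(h) {
      apply_branch(lin_seq[[hap_of_lineage(h)]], ev_hap[[h]])
    }), haps)
    genomes <- stats::setNames(lapply(haps, function(h) {
      s <- vapply(hap_seqs[[h]], paste, character(1), collapse = "")
      names(s) <- paste0(h, "_", chrom_names)
      genome_set(s, haplotype = h)
    }), haps)

    # --- truth variants (SNPs by sequence diff; InDels by branch records) --
    pair_idx <- utils::combn(haps, 2L, simplify = FALSE)
    tv <- list()
    for (pr in pair_idx) {
      a <- pr[1]; b <- pr[2]
      for (cn in chrom_names) {
        va <- hap_seqs[[a]][[cn]]; vb <- hap_seqs[[b]][[cn]]
        pos <- which(va != vb)
        if (length(pos)) {
          tv[[length(tv) + 1L]] <- data.frame(
            hap_a = a, hap_b = b, chrom = cn, pos = pos - 1L, type = "SNP",
            ref = va[pos], alt = vb[pos], stringsAsFactors = FALSE)
        }
        # InDels: union of records on the branches separating a and b
        evs <- list(ev_hap[[a]], ev_hap[[b]])
        if (hap_of_lineage(a) != hap_of_lineage(b)) {
          evs <- c(evs, ev_lineage)
        }
        ipos <- sort(unique(unlist(lapply(evs, function(e) {
          e[[match(cn, chrom_names)]]$indel_pos
        }))))
        if (length(ipos)) {
          is_ins <- seq_along(ipos) %% 2L == 1L
          ref <- ifelse(is_ins, va[ipos], paste0(va[ipos], "A"))
          alt <- ifelse(is_ins, paste0(va[ipos], "T"), va[ipos])
          tv[[length(tv) + 1L]] <- data.frame(
            hap_a = a, hap_b = b, chrom = cn, pos = ipos - 1L,
            type = ifelse(is_ins, "INS", "DEL"), ref = ref, alt = alt,
            stringsAsFactors = FALSE)
        }
      }
    }
    truth_variants <- if (length(tv)) do.call(rbind, tv) else
      data.frame(hap_a = character(0), hap_b = character(0),
                 chrom = character(0), pos = integer(0), type = character(0),
                 ref = character(0), alt = character(0))

    # --- retention ---------------------------------------------------------
    truth_retention <- NULL
    gene_models <- stats::setNames(vector("list", length(haps)), haps)
    if (n_genes > 0) {
      copies <- do.call(rbind, lapply(haps, function(h) {
        data.frame(gene_id = genes$gene_id, haplotype = h,
                   pathway = genes$pathway, stringsAsFactors = FALSE)
      }))
      truth_retention <- assign_retention(
        copies, cfg$retention_background, cfg$retention_pathway,
        seed = derive_seed(cfg$seed, 31L))
      for (h in haps) {
        keep <- truth_retention$retained[truth_retention$haplotype == h]
        g <- genes[keep, , drop = FALSE]
        gm <- data.frame(
          gene_id = paste0(h, "_", g$gene_id), haplotype = h,
          chrom = paste0(h, "_", g$chrom), start = g$start, end = g$end,
          strand = g$strand,
          pathway = ifelse(g$pathway, "dioscin", NA_character_),
          stringsAsFactors = FALSE)
        cd <- data.frame(gene_id = gm$gene_id, start = gm$start, end = gm$end,
                         stringsAsFactors = FALSE)
        gene_models[[h]] <- structure(list(genes = gm, cds = cd),
                                      class = "gene_annotation")
      }
    }

    # --- TE intervals ------------------------------------------------------
    te <- list()
    if (cfg$te_fraction > 0) {
      for (h in haps) {
        for (cn in chrom_names) {
          target <- cfg$te_fraction * L
          covered <- 0
          starts <- integer(0); ends <- integer(0)
          while (covered < target) {
            len <- sample(100:1000, 1L)
            s <- sample.int(L - len, 1L) - 1L
            starts <- c(starts, s); ends <- c(ends, s + len)
            covered <- covered + len
          }
          te[[length(te) + 1L]] <- data.frame(
            haplotype = h, chrom = paste0(h, "_", cn), start = starts,
            end = ends,
            te_class = sample(c("LTR/Gypsy", "LTR/Copia", "DNA", "LINE"),
                              length(starts), replace = TRUE),
            stringsAsFactors = FALSE)
        }
      }
    }
    te_intervals <- if (length(te)) do.call(rbind, te) else
      data.frame(haplotype = character(0), chrom = character(0),
                 start = integer(0), end = integer(0),
                 te_class = character(0))

    # --- expression for lineage-representative paralog pairs ---------------
    expression <- NULL; truth_ase <- NULL
    if (n_genes > 0) {
      rep_a <- lineages[[1]][1]; rep_b <- lineages[[2]][1]
      ret_a <- truth_retention$gene_id[truth_retention$haplotype == rep_a &
                                         truth_retention$retained]
      ret_b <- truth_retention$gene_id[truth_retention$haplotype == rep_b &
                                         truth_retention$retained]
      pair_ids <- intersect(ret_a, ret_b)
      if (length(pair_ids)) {
        sim <- simulate_expression(
          cfg$ase_design, pair_ids, seed = derive_seed(cfg$seed, 97L),
          tissues = cfg$tissues, alleles = c(rep_a, rep_b))
        expression <- sim$expression
        truth_ase <- sim$labels
      }
    }

    structure(list(
      config = cfg, genomes = genomes, gene_models = gene_models,
      ancestral_genes = genes, cds_seqs = cds_seqs,
      te_intervals = te_intervals, truth_variants = truth_variants,
      truth_cds_pairs = truth_cds, expression = expression,
      truth_ase_labels = truth_ase, truth_lineages = lineages,
      truth_retention = truth_retention
    ), class = "simulated_dataset")
  })
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("simulated tetraploid dataset: %d haplotypes x %d chrom x %d bp\n",
              cfg$ploidy, cfg$n_chromosomes, cfg$chrom_length))
  cat(sprintf("  genes/chrom: %d | variants: %d | TE intervals: %d\n",
              cfg$n_genes_per_chrom,
              nrow(x$truth_variants), nrow(x$te_intervals)))
  cat("  lineages:", paste(vapply(x$truth_lineages, paste, character(1),
                                  collapse = "+"), collapse = " | "), "\n")
  invisible(x)
}

#' Write a simulated dataset to an output directory
#'
#' Emits per-haplotype FASTA and GFF3, a BED of TE intervals, the variant
#' and expression TSVs, and JSON truth tables.
#'
#' @param dataset a `simulated_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (h in names(dataset$genomes)) {
    write_fasta(dataset$genomes[[h]], file.path(dir, paste0(h, ".fasta")))
    if (!is.null(dataset$gene_models[[h]])) {
      write_gff3(dataset$gene_models[[h]], file.path(dir, paste0(h, ".gff3")))
    }
  }
  if (nrow(dataset$te_intervals)) {
    write_bed(dataset$te_intervals, file.path(dir, "te.bed"))
  }
  write_variants(dataset$truth_variants, file.path(dir, "variants.tsv"))
  if (!is.null(dataset$expression)) {
    write_expression(dataset$expression, file.path(dir, "expression.tsv"))
  }
  truth <- list(
    lineages = dataset$truth_lineages,
    retention = dataset$truth_retention,
    ase_labels = dataset$truth_ase_labels
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
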