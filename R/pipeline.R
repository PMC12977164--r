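# End-to-end orchestration: simulate -> synteny/retention -> divergence ->
# Ks/WGD -> ASE -> TE profile, with a machine-readable JSON report. All
# randomness lives in the simulator; analysis stages are deterministic
# given their inputs. Stage seeds derive from the one config seed.

#' Run the full pipeline on a simulated dataset
#'
#' @param config a [simulation_config()], a list of its arguments, or a
#'   path to a JSON file of them. Extra entries `mu` (substitution rate for
#'   dating, optional), `density_window`/`density_step` (variant density
#'   windows, default 300000), `max_gene_gap`/`max_bp_gap` (consolidation
#'   thresholds) are picked up by the relevant stages.
#' @param out_dir output directory; dataset files and `report.json` are
#'   written there.
#' @param max_kaks_pairs cap on CDS pairs run through the NG86 estimator
#'   (keeps desk-scale runs fast; `Inf` for all pairs).
#' @return the report, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config, out_dir, max_kaks_pairs = 500) {
  opts <- list(mu = NULL, density_window = 300000, density_step = 300000,
               max_gene_gap = 50, max_bp_gap = 300000)
  if (is.character(config)) {
    if (!file.exists(config)) fail_validation("no such config file: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!inherits(config, "simulation_config")) {
    extra <- intersect(names(config), names(opts))
    opts[extra] <- config[extra]
    config <- config[setdiff(names(config), names(opts))]
    config <- do.call(simulation_config, config)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(tool = "tetradiv",
                 version = as.character(utils::packageVersion("tetradiv")),
                 seed = config$seed, config = unclass_config(config),
                 warnings = character(0))
  timings <- list()
  tick <- function() Sys.time()
  stage_log <- function(name) message("[tetradiv] stage: ", name)

  stage_log("simulate")
  t0 <- tick()
  ds <- simulate_tetraploid(config)
  write_dataset(ds, file.path(out_dir, "dataset"))
  timings$simulate <- as.numeric(difftime(tick(), t0, units = "secs"))

  stage_log("synteny")
  t0 <- tick()
  report$retention <- pipeline_synteny(ds, opts$max_gene_gap,
                                       opts$max_bp_gap)
  timings$synteny <- as.numeric(difftime(tick(), t0, units = "secs"))

  stage_log("divergence")
  t0 <- tick()
  report$divergence <- pipeline_divergence(ds, opts$density_window,
                                           opts$density_step, out_dir)
  timings$divergence <- as.numeric(difftime(tick(), t0, units = "secs"))

  stage_log("kaks")
  t0 <- tick()
  report$kaks <- pipeline_kaks(ds, opts$mu, max_kaks_pairs)
  timings$kaks <- as.numeric(difftime(tick(), t0, units = "secs"))

  stage_log("ase")
  t0 <- tick()
  report$ase <- pipeline_ase(ds)
  timings$ase <- as.numeric(difftime(tick(), t0, units = "secs"))

  stage_log("teprofile")
  t0 <- tick()
  report$te_profile <- pipeline_te(ds)
  timings$teprofile <- as.numeric(difftime(tick(), t0, units = "secs"))

  report$timings_sec <- timings
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}

unclass_config <- function(cfg) {
  x <- unclass(cfg)
  x$ase_design <- as.data.frame(x$ase_design)
  x
}

pipeline_synteny <- function(ds, max_gene_gap, max_bp_gap) {
  if (is.null(ds$truth_retention)) return(NULL)
  dip <- ds$ancestral_genes
  blocks_all <- list()
  for (h in names(ds$gene_models)) {
    gm <- ds$gene_models[[h]]$genes
    anchors <- data.frame(gene_a = sub(paste0("^", h, "_"), "", gm$gene_id),
                          gene_b = gm$gene_id, similarity = 1)
    ann <- annotate_anchors(best_hit_filter(anchors), dip, gm)
    raw <- chain_anchors(ann)
    blocks_all[[h]] <- consolidate_blocks(raw, max_gene_gap, max_bp_gap)
  }
  blocks <- do.call(rbind, blocks_all)
  sets <- list(dioscin = dip$gene_id[dip$pathway])
  rep <- pathway_retention(blocks, sets, ploidy = ds$config$ploidy)
  list(rate = rep$rate, percent = rep$percent,
       pathway_rate = rep$per_set$dioscin,
       polyploid_syntenic_genes = rep$polyploid_syntenic_genes,
       diploid_syntenic_genes = rep$diploid_syntenic_genes,
       n_blocks = nrow(blocks))
}

pipeline_divergence <- function(ds, window, step, out_dir) {
  dm <- divergence_matrix(ds$truth_variants, ds$config$haplotypes)
  cl <- cluster_haplotypes(dm)
  # per-pair density tracks for the first chromosome pair, written as TSV
  tracks <- NULL
  if (window <= ds$config$chrom_length) {
    cn <- sprintf("chr%02d", 1L)
    v <- ds$truth_variants
    first <- v[v$chrom == cn & v$type == "SNP", , drop = FALSE]
    tracks <- do.call(rbind, lapply(
      split(first, paste(first$hap_a, first$hap_b)), function(sub) {
        tr <- window_density(sub$pos, ds$config$chrom_length, window, step)
        data.frame(pair = paste0(sub$hap_a[1], "-", sub$hap_b[1]),
                   chrom = cn, start = tr$start, count = tr$count)
      }))
    utils::write.table(tracks, file.path(out_dir, "variant_density.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(snp_counts = as.data.frame(dm$snp_counts),
       indel_counts = as.data.frame(dm$indel_counts),
       lineage_partition = cl$partition, newick = cl$newick)
}

pipeline_kaks <- function(ds, mu, max_pairs) {
  cp <- ds$truth_cds_pairs
  if (is.null(cp) || nrow(cp) == 0L) return(NULL)
  if (nrow(cp) > max_pairs) cp <- cp[seq_len(max_pairs), , drop = FALSE]
  res <- lapply(seq_len(nrow(cp)), function(i) {
    kaks_pair(cp$seq_a[i], cp$seq_b[i])
  })
  ks <- vapply(res, function(r) if (is.na(r$Ks)) NA_real_ else r$Ks,
               numeric(1))
  dist <- ks_distribution(ks[!is.na(ks)])
  peaks <- tryCatch(detect_ks_peaks(dist),
                    error = function(e) data.frame(location = numeric(0)))
  out <- list(n_pairs = nrow(cp), median_ks = stats::median(ks, na.rm = TRUE),
              median_ka = stats::median(
                vapply(res, function(r) r$Ka, numeric(1)), na.rm = TRUE),
              peaks = peaks)
  if (!is.null(mu) && nrow(peaks)) {
    out$dates_years <- date_event(peaks$location, mu)
  }
  out
}

pipeline_ase <- function(ds) {
  if (is.null(ds$expression)) return(NULL)
  cm <- classify_matrix(ds$expression)
  venn <- intersect_ase_sets(cm$calls)
  list(fractions = cm$fractions, venn = as.list(venn),
       n_calls = nrow(cm$calls))
}

pipeline_te <- function(ds) {
  if (nrow(ds$te_intervals) == 0L || is.null(ds$truth_retention)) {
    return(NULL)
  }
  reps <- vapply(ds$truth_lineages, `[`, character(1), 1L)
  out <- list()
  for (h in reps) {
    gm <- ds$gene_models[[h]]$genes
    # cap genes for speed: the profile is a mean, 100 genes is plenty
    gm <- utils::head(gm, 100L)
    tes <- ds$te_intervals[ds$te_intervals$haplotype == h, , drop = FALSE]
    profs <- lapply(seq_len(nrow(gm)), function(i) {
      g <- gm[i, ]
      flank_te_profile(g, tes[tes$chrom == g$chrom, , drop = FALSE],
                       chrom_length = ds$config$chrom_length)
    })
    avg <- average_profiles(profs, label = h)
    out[[h]] <- list(n_genes = avg$n_genes,
                     mean_upstream = mean(avg$upstream$fraction, na.rm = TRUE),
                     mean_downstream = mean(avg$downstream$fraction,
                                            na.rm = TRUE))
  }
  out
}
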