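# Readers/writers for the on-disk formats the pipeline touches: FASTA,
# GFF3 (1-based inclusive), BED (0-based half-open), variant / expression /
# anchor TSVs. Internal coordinates are 0-based half-open everywhere;
# conversion happens at these boundaries. Readers reject malformed records
# instead of coercing.

#' Read a genome sequence set from FASTA
#'
#' Sequences are case-folded to uppercase (soft-masking dropped) and must be
#' over the alphabet A/C/G/T/N. Duplicate ids or illegal characters are
#' format errors naming the offending record.
#'
#' @param path FASTA file.
#' @param haplotype optional haplotype label to attach.
#' @return object of class `genome_set`: named character vector of sequences
#'   with attributes `haplotype` and `lengths`.
#' @export
read_fasta <- function(path, haplotype = NA_character_) {
  if (!file.exists(path)) fail_validation("no such file: ", path)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    return(genome_set(character(0), haplotype))
  }
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  genome_set(seqs, haplotype)
}

#' Construct and validate a genome sequence set
#'
#' @param seqs named character vector of nucleotide sequences.
#' @param haplotype optional label.
#' @return `genome_set` object.
#' @export
genome_set <- function(seqs, haplotype = NA_character_) {
  if (length(seqs)) {
    if (is.null(names(seqs)) || any(names(seqs) == "")) {
      fail_validation("all sequences need ids")
    }
    if (anyDuplicated(names(seqs))) {
      fail_validation("duplicate sequence id: ",
                      names(seqs)[duplicated(names(seqs))][1])
    }
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad)) {
      fail_validation("illegal characters in record '",
                      names(seqs)[bad][1], "'")
    }
  }
  structure(seqs, haplotype = haplotype,
            lengths = stats::setNames(nchar(seqs), names(seqs)),
            class = "genome_set")
}

#' Write a genome sequence set to FASTA
#'
#' @param seqs `genome_set` or named character vector.
#' @param path output file.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  x <- Biostrings::DNAStringSet(as.character(unclass(seqs)))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses gene and CDS features (1-based inclusive coordinates converted to
#' the internal 0-based half-open convention). Validates: start <= end, CDS
#' segments within their gene, summed CDS length a multiple of 3. Pathway
#' tags are read from a `pathway` attribute on gene features.
#'
#' @param path GFF3 file.
#' @param haplotype optional haplotype label to attach to all genes.
#' @return object of class `gene_annotation`: list with `genes` (data.frame
#'   gene_id, haplotype, chrom, start, end, strand, pathway) and `cds`
#'   (data.frame gene_id, start, end), both 0-based half-open.
#' @export
read_gff3 <- function(path, haplotype = NA_character_) {
  if (!file.exists(path)) fail_validation("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  genes <- df[df$type == "gene", , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]
  if (nrow(genes) == 0L) fail_validation("no gene features in ", path)
  gene_id <- as.character(genes$ID)
  pathway <- if ("pathway" %in% names(genes)) {
    as.character(genes$pathway)
  } else rep(NA_character_, nrow(genes))
  out_genes <- data.frame(
    gene_id = gene_id,
    haplotype = haplotype,
    chrom = as.character(genes$seqnames),
    start = genes$start - 1L,      # to 0-based half-open
    end = genes$end,
    strand = as.character(genes$strand),
    pathway = pathway,
    stringsAsFactors = FALSE
  )
  cds_parent <- sub("\\.mRNA.*$", "", as.character(cds$Parent))
  out_cds <- data.frame(
    gene_id = cds_parent,
    start = cds$start - 1L,
    end = cds$end,
    stringsAsFactors = FALSE
  )
  validate_gene_annotation(out_genes, out_cds)
  structure(list(genes = out_genes, cds = out_cds),
            class = "gene_annotation")
}

validate_gene_annotation <- function(genes, cds) {
  if (any(genes$start >= genes$end)) {
    fail_validation("gene with empty/negative span: ",
                    genes$gene_id[genes$start >= genes$end][1])
  }
  if (anyDuplicated(genes$gene_id)) {
    fail_validation("duplicate gene id: ",
                    genes$gene_id[duplicated(genes$gene_id)][1])
  }
  for (gid in unique(cds$gene_id)) {
    seg <- cds[cds$gene_id == gid, , drop = FALSE]
    g <- genes[genes$gene_id == gid, , drop = FALSE]
    if (nrow(g) == 0L) fail_validation("CDS references unknown gene: ", gid)
    if (any(seg$start < g$start | seg$end > g$end)) {
      fail_validation("CDS outside gene span for ", gid)
    }
    seg <- seg[order(seg$start), , drop = FALSE]
    if (nrow(seg) > 1L && any(seg$start[-1L] < seg$end[-nrow(seg)])) {
      fail_validation("overlapping CDS segments for ", gid)
    }
    total <- sum(seg$end - seg$start)
    if (total %% 3 != 0) {
      fail_validation("CDS length of ", gid, " not a multiple of 3 (",
                      total, " bp)")
    }
  }
  invisible(TRUE)
}

#' Write gene models to GFF3
#'
#' @param annotation a `gene_annotation` (0-based half-open internally);
#'   written 1-based inclusive.
#' @param path output file.
#' @param source source column value.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path, source = "tetradiv") {
  genes <- annotation$genes
  cds <- annotation$cds
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    attrs <- paste0("ID=", g$gene_id)
    if (!is.na(g$pathway) && nzchar(g$pathway)) {
      attrs <- paste0(attrs, ";pathway=", g$pathway)
    }
    writeLines(paste(g$chrom, source, "gene", g$start + 1L, g$end, ".",
                     g$strand, ".", attrs, sep = "\t"), con)
    mrna_id <- paste0(g$gene_id, ".mRNA1")
    writeLines(paste(g$chrom, source, "mRNA", g$start + 1L, g$end, ".",
                     g$strand, ".",
                     paste0("ID=", mrna_id, ";Parent=", g$gene_id),
                     sep = "\t"), con)
    seg <- cds[cds$gene_id == g$gene_id, , drop = FALSE]
    for (j in seq_len(nrow(seg))) {
      writeLines(paste(g$chrom, source, "CDS", seg$start[j] + 1L, seg$end[j],
                       ".", g$strand, "0", paste0("ID=", g$gene_id,
                       ".cds", j, ";Parent=", mrna_id), sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Read TE intervals from BED
#'
#' BED is 0-based half-open, matching the internal convention; `start >= end`
#' is rejected. The 4th column (name) is taken as the TE class.
#'
#' @param path BED file.
#' @param haplotype optional haplotype label.
#' @return data.frame with haplotype, chrom, start, end, te_class.
#' @export
read_bed <- function(path, haplotype = NA_character_) {
  if (!file.exists(path)) fail_validation("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(data.frame(haplotype = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      te_class = character(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 3L)) fail_validation("BED line with fewer than 3 fields")
  chrom <- vapply(parts, `[[`, character(1), 1L)
  start <- as.integer(vapply(parts, `[[`, character(1), 2L))
  end <- as.integer(vapply(parts, `[[`, character(1), 3L))
  te_class <- ifelse(ncols >= 4L,
                     vapply(parts, function(p) if (length(p) >= 4L) p[[4L]]
                            else NA_character_, character(1)),
                     NA_character_)
  if (any(is.na(start) | is.na(end))) fail_validation("non-integer BED bounds")
  bad <- start >= end | start < 0
  if (any(bad)) {
    fail_validation("invalid BED interval ", chrom[bad][1], ":",
                    start[bad][1], "-", end[bad][1])
  }
  data.frame(haplotype = haplotype, chrom = chrom, start = start, end = end,
             te_class = te_class, stringsAsFactors = FALSE)
}

#' Write TE intervals to BED
#' @param tes data.frame with chrom, start, end, te_class.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(tes, path) {
  lines <- paste(tes$chrom, tes$start, tes$end,
                 ifelse(is.na(tes$te_class), ".", tes$te_class), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

VARIANT_TYPES <- c("SNP", "INS", "DEL")

#' Read a pairwise variant table (TSV)
#'
#' Columns: hap_a, hap_b, chrom, pos (1-based), type (SNP/INS/DEL), ref, alt.
#' SNPs must have single-base, differing alleles. Positions are converted to
#' 0-based internally.
#'
#' @param path TSV with header.
#' @return data.frame hap_a, hap_b, chrom, pos (0-based), type, ref, alt.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) fail_validation("no such file: ", path)
  v <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("hap_a", "hap_b", "chrom", "pos", "type", "ref", "alt")
  if (!all(need %in% names(v))) {
    fail_validation("variant table must have columns: ",
                    paste(need, collapse = ", "))
  }
  if (!all(v$type %in% VARIANT_TYPES)) {
    fail_validation("unknown variant type: ",
                    v$type[!v$type %in% VARIANT_TYPES][1])
  }
  snp <- v$type == "SNP"
  bad <- snp & (nchar(v$ref) != 1L | nchar(v$alt) != 1L | v$ref == v$alt)
  if (any(bad)) {
    fail_validation("malformed SNP record at ", v$chrom[bad][1], ":",
                    v$pos[bad][1])
  }
  v$pos <- as.integer(v$pos) - 1L
  v
}

#' Write a pairwise variant table (TSV)
#' @param variants data.frame as from [read_variants()] (0-based pos).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path) {
  out <- variants
  out$pos <- out$pos + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-allele expression table (TSV)
#'
#' Columns: gene_id, haplotype, tissue, tpm (>= 0).
#'
#' @param path TSV with header.
#' @param tissues optional declared tissue list; unknown tissues are errors.
#' @return validated data.frame.
#' @export
read_expression <- function(path, tissues = NULL) {
  if (!file.exists(path)) fail_validation("no such file: ", path)
  e <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "haplotype", "tissue", "tpm")
  if (!all(need %in% names(e))) {
    fail_validation("expression table must have columns: ",
                    paste(need, collapse = ", "))
  }
  if (any(!is.finite(e$tpm) | e$tpm < 0)) {
    fail_validation("negative or non-finite TPM values")
  }
  if (!is.null(tissues) && !all(e$tissue %in% tissues)) {
    fail_validation("unknown tissue label: ",
                    e$tissue[!e$tissue %in% tissues][1])
  }
  e
}

#' Write a per-allele expression table (TSV)
#' @param expression data.frame gene_id, haplotype, tissue, tpm.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expression, path) {
  utils::write.table(expression, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a homolog anchor-pair table (TSV)
#'
#' Columns: gene_a, gene_b, similarity. When gene universes are supplied,
#' anchors referencing unknown ids are rejected by name.
#'
#' @param path TSV with header.
#' @param known_a,known_b optional character vectors of valid gene ids.
#' @return data.frame gene_a, gene_b, similarity.
#' @export
read_anchors <- function(path, known_a = NULL, known_b = NULL) {
  if (!file.exists(path)) fail_validation("no such file: ", path)
  a <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "similarity")
  if (!all(need %in% names(a))) {
    fail_validation("anchor table must have columns: ",
                    paste(need, collapse = ", "))
  }
  if (!is.null(known_a) && !all(a$gene_a %in% known_a)) {
    fail_validation("anchor references unknown gene id: ",
                    a$gene_a[!a$gene_a %in% known_a][1])
  }
  if (!is.null(known_b) && !all(a$gene_b %in% known_b)) {
    fail_validation("anchor references unknown gene id: ",
                    a$gene_b[!a$gene_b %in% known_b][1])
  }
  a
}
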