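#' Write simulated data to standard file formats
#'
#' Writes the genome as FASTA, gene models as GFF3 (1-based closed, per the
#' format), fragments as per-sample BED6, the sample sheet and truth table
#' as TSV. Seeded simulations produce byte-identical files.
#'
#' @param sim A `zb_sim`.
#' @param frags Named list of [fragment_set()]s (optional).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_sim <- function(sim, frags = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(sim$genome, fa)
  files <- c(files, fa)
  gff <- file.path(dir, "genes.gff3")
  write_genes_gff3(sim$genes, gff)
  files <- c(files, gff)
  tsv <- file.path(dir, "truth.tsv")
  utils::write.table(sim$truth, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, tsv)
  go <- file.path(dir, "go_annotation.tsv")
  utils::write.table(sim$go, go, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, go)
  if (!is.null(frags)) {
    sheet <- do.call(rbind, lapply(frags, function(fs) data.frame(
      sample_id = fs$sample_id, genotype = fs$genotype, zt = fs$zt,
      replicate = fs$replicate, treatment = fs$treatment,
      file = paste0(fs$sample_id, ".bed"), stringsAsFactors = FALSE)))
    sheet_path <- file.path(dir, "samples.tsv")
    utils::write.table(sheet, sheet_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, sheet_path)
    for (fs in frags) {
      bed <- file.path(dir, paste0(fs$sample_id, ".bed"))
      write_fragments_bed(fs, bed)
      files <- c(files, bed)
    }
  }
  invisible(files)
}

#' Write gene models as GFF3
#'
#' @param genes Gene-model data.frame (0-based half-open columns).
#' @param path Output path.
#' @export
write_genes_gff3 <- function(genes, path) {
  gff_row <- function(type, start0, end0, id, parent = NULL, strand) {
    attrs <- if (is.null(parent)) sprintf("ID=%s", id)
             else sprintf("ID=%s;Parent=%s", id, parent)
    sprintf("chr1\tzeitbind\t%s\t%d\t%d\t.\t%s\t.\t%s",
            type, start0 + 1L, end0, strand, attrs)
  }
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lines <- c(lines,
               gff_row("gene", g$start, g$end, g$gene_id, strand = g$strand),
               gff_row("five_prime_UTR", g$utr5_start, g$utr5_end,
                       paste0(g$gene_id, ".utr5"), g$gene_id, g$strand),
               gff_row("CDS", g$cds_start, g$cds_end,
                       paste0(g$gene_id, ".cds"), g$gene_id, g$strand))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Imports `gene`, `five_prime_UTR` and `CDS` features and converts them to
#' the package's 0-based half-open gene table.
#'
#' @param path GFF3 path.
#' @return Gene-model data.frame as produced by [simulate_genome()].
#' @export
read_gene_models <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_gene_models() requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  gene <- df[df$type == "gene", , drop = FALSE]
  utr <- df[df$type == "five_prime_UTR", , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]
  parent_of <- function(d) vapply(d$Parent, function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  utr_idx <- match(gene$ID, parent_of(utr))
  cds_idx <- match(gene$ID, parent_of(cds))
  strand <- as.character(gene$strand)
  start0 <- gene$start - 1L
  end0 <- gene$end
  data.frame(
    gene_id = gene$ID, chrom = as.character(gene$seqnames), strand = strand,
    start = start0, end = end0,
    tss = ifelse(strand == "+", start0, end0 - 1L),
    tes = ifelse(strand == "+", end0 - 1L, start0),
    utr5_start = utr$start[utr_idx] - 1L, utr5_end = utr$end[utr_idx],
    cds_start = cds$start[cds_idx] - 1L, cds_end = cds$end[cds_idx],
    bump_center = NA_integer_, motif_planted = NA,
    expression_mode = NA_character_, stringsAsFactors = FALSE)
}

#' Write a fragment set as BED6
#'
#' @param fs A [fragment_set()].
#' @param path Output path.
#' @export
write_fragments_bed <- function(fs, path) {
  f <- fs$fragments
  utils::write.table(
    data.frame(f$chrom, f$start, f$end,
               name = sprintf("%s_%d", fs$sample_id, seq_len(nrow(f))),
               score = 0L, strand = f$strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write peaks in a narrowPeak-style BED
#'
#' Columns: chrom, start, end, name, score (`-10 log10 p` capped at 1000),
#' strand, fold enrichment, `-log10 p`, summit offset.
#'
#' @param peaks A `peak_set`.
#' @param path Output path.
#' @export
write_peaks_bed <- function(peaks, path) {
  neglog <- -log10(pmax(peaks$p_value, .Machine$double.xmin))
  utils::write.table(
    data.frame(peaks$chrom, peaks$start, peaks$end,
               name = sprintf("peak_%d", seq_len(nrow(peaks))),
               score = pmin(1000L, as.integer(round(10 * neglog))),
               strand = ".", fold = peaks$fold_enrichment,
               neglog10p = neglog,
               summit_offset = peaks$summit - peaks$start),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal value are collapsed into single intervals.
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  r <- rle(as.numeric(track$values))
  end_bin <- cumsum(r$lengths)
  start_bin <- c(0L, head(end_bin, -1L))
  keep <- r$values != 0
  utils::write.table(
    data.frame(track$chrom, start_bin[keep] * track$bin_size,
               pmin(end_bin[keep] * track$bin_size,
                    length(track$values) * track$bin_size),
               r$values[keep]),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
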