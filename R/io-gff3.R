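# GFF3 gene-model I/O. Gene models travel as a pair of data frames:
#   genes: gene_id, chrom, strand, start, end
#   exons: gene_id, exon_rank, chrom, strand, start, end, phase
# Coordinates are 1-based inclusive (GFF3 convention); exon_rank is the
# 5'->3' order in transcript orientation, so minus-strand exon ranks run in
# decreasing genomic order. phase is the GFF3 CDS phase of each exon.

#' Write gene models to GFF3
#'
#' Emits a gene / mRNA / exon + CDS hierarchy (one transcript per gene; every
#' exon is coding in the package's synthetic gene models) resolvable through
#' `Parent` attributes.
#'
#' @param models A list with `genes` and `exons` data frames (see
#'   \code{\link{read_gff3_gene_models}} for the schema), e.g. a genome bundle
#'   from \code{\link{gen_genome}}.
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_gff3_gene_models <- function(models, path) {
  genes <- models$genes
  exons <- models$exons
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ex <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
    ex <- ex[order(ex$exon_rank), , drop = FALSE]
    tid <- paste0(g$gene_id, ".t1")
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = g$chrom, type = "gene", start = g$start, end = g$end,
      strand = g$strand, phase = NA_integer_, ID = g$gene_id,
      Parent = NA_character_)
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = g$chrom, type = "mRNA", start = g$start, end = g$end,
      strand = g$strand, phase = NA_integer_, ID = tid, Parent = g$gene_id)
    for (j in seq_len(nrow(ex))) {
      e <- ex[j, ]
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = e$chrom, type = "exon", start = e$start, end = e$end,
        strand = e$strand, phase = NA_integer_,
        ID = paste0(tid, ".exon", e$exon_rank), Parent = tid)
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = e$chrom, type = "CDS", start = e$start, end = e$end,
        strand = e$strand, phase = e$phase,
        ID = paste0(tid, ".cds", e$exon_rank), Parent = tid)
    }
  }
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = tab$seqid,
    ranges = IRanges::IRanges(tab$start, tab$end),
    strand = tab$strand)
  S4Vectors::mcols(gr)$type <- tab$type
  S4Vectors::mcols(gr)$ID <- tab$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(tab$Parent), "", tab$Parent)
  S4Vectors::mcols(gr)$phase <- tab$phase
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses a gene / mRNA / exon (+ optional CDS) hierarchy via
#' \code{rtracklayer::import}. Exon chains are returned in transcript
#' orientation (reversed genomic order on the minus strand) and CDS phase is
#' honored when CDS features are present (phase 0 assumed otherwise, with the
#' downstream exon phases derived from cumulative exon length).
#'
#' @param path GFF3 file path.
#' @param seqs Optional `DNAStringSet` of chromosome sequences; when given,
#'   feature coordinates are checked against chromosome bounds.
#' @return A list with `genes` and `exons` data frames (schema above).
#' @export
read_gff3_gene_models <- function(path, seqs = NULL) {
  if (!file.exists(path)) stop_input("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$Parent <- vapply(df$Parent, function(p)
    if (length(p)) as.character(p)[1] else NA_character_, character(1))
  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type == "mRNA", , drop = FALSE]
  exons <- df[df$type == "exon", , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]
  tx2gene <- stats::setNames(mrnas$Parent, mrnas$ID)
  orphan <- !(exons$Parent %in% c(mrnas$ID, genes$ID))
  if (any(orphan))
    stop_input("orphan exon with unresolvable Parent '",
               exons$Parent[orphan][1], "'")
  exons$gene_id <- ifelse(exons$Parent %in% names(tx2gene),
                          unname(tx2gene[exons$Parent]), exons$Parent)
  if (!is.null(seqs)) {
    lens <- stats::setNames(Biostrings::width(seqs),
                            sub("\\s.*$", "", names(seqs)))
    bad <- !(as.character(df$seqnames) %in% names(lens)) |
      df$end > lens[as.character(df$seqnames)] | df$start < 1L
    if (any(bad, na.rm = TRUE))
      stop_input("feature outside chromosome bounds: ",
                 df$ID[which(bad)[1]])
  }
  out_genes <- data.frame(
    gene_id = genes$ID, chrom = as.character(genes$seqnames),
    strand = as.character(genes$strand),
    start = genes$start, end = genes$end, stringsAsFactors = FALSE)
  ex_list <- lapply(split(exons, exons$gene_id), function(e) {
    minus <- e$strand[1] == "-"
    e <- e[order(e$start, decreasing = minus), , drop = FALSE]
    e$exon_rank <- seq_len(nrow(e))
    e
  })
  ex <- do.call(rbind, ex_list)
  # phase: from CDS rows when present, else cumulative exon length
  if (nrow(cds)) {
    key <- paste(ex$gene_id, ex$start, ex$end)
    cds$gene_id <- ifelse(cds$Parent %in% names(tx2gene),
                          unname(tx2gene[cds$Parent]), cds$Parent)
    ckey <- paste(cds$gene_id, cds$start, cds$end)
    ex$phase <- cds$phase[match(key, ckey)]
  } else ex$phase <- NA_integer_
  ex <- ex[order(ex$gene_id, ex$exon_rank), , drop = FALSE]
  for (g in unique(ex$gene_id)) {
    idx <- which(ex$gene_id == g)
    if (anyNA(ex$phase[idx])) {
      lens <- ex$end[idx] - ex$start[idx] + 1L
      cum <- c(0L, cumsum(lens))[seq_along(idx)]
      ex$phase[idx] <- (3L - (cum %% 3L)) %% 3L
    }
  }
  out_exons <- data.frame(
    gene_id = ex$gene_id, exon_rank = ex$exon_rank,
    chrom = as.character(ex$seqnames), strand = as.character(ex$strand),
    start = ex$start, end = ex$end, phase = as.integer(ex$phase),
    stringsAsFactors = FALSE)
  rownames(out_genes) <- rownames(out_exons) <- NULL
  list(genes = out_genes, exons = out_exons)
}
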