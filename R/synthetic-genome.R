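# Synthetic toy genomes and gapped-read junction evidence with ground truth.

SENSE_CODONS <- setdiff(
  as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"), paste0),
                  c("T", "C", "A", "G"), paste0)),
  c("TAA", "TAG", "TGA"))

#' Generate a toy genome with annotated multi-exon genes
#'
#' Builds one synthetic chromosome carrying `n_genes` spliced protein-coding
#' genes on random strands. Each gene's CDS starts with ATG, ends with a stop
#' codon, and is split across exons separated by random introns; the
#' canonical protein is the translation of the annotated exon chain with the
#' terminal stop excluded. Lysine codons are up-weighted so that in-silico
#' LysC digestion yields MS-observable peptides.
#'
#' @param seed Integer seed; identical seeds give byte-identical bundles.
#' @param n_genes Number of genes (>= 1).
#' @param exons_per_gene Length-2 integer range of exons per gene.
#' @param exon_nt,intron_nt Length-2 ranges of exon / intron sizes (nt).
#' @param intergenic_nt Spacer size between gene loci (nt).
#' @param chrom_name Name of the synthetic chromosome.
#' @return A `genome_bundle` list: `seqs` (DNAStringSet), `genes`, `exons`
#'   (data frames, see \code{\link{read_gff3_gene_models}}), `proteins`
#'   (AAStringSet of canonical proteins), `seed`.
#' @export
gen_genome <- function(seed, n_genes = 5L, exons_per_gene = c(3L, 6L),
                       exon_nt = c(24L, 90L), intron_nt = c(50L, 200L),
                       intergenic_nt = 150L, chrom_name = "chrS1") {
  assert_scalar_number(n_genes, "n_genes", lower = 1)
  if (length(exons_per_gene) != 2L || exons_per_gene[1] < 2L ||
      exons_per_gene[1] > exons_per_gene[2])
    stop_config("exons_per_gene must be an increasing range with min >= 2")
  if (length(exon_nt) != 2L || exon_nt[1] < 9L || exon_nt[1] > exon_nt[2])
    stop_config("exon_nt must be an increasing range with min >= 9")
  with_seed(seed, {
    codon_w <- ifelse(SENSE_CODONS %in% c("AAA", "AAG"), 6, 1)
    chrom <- character(0)
    pos <- 0L
    genes <- exons <- list()
    prot <- character(n_genes)
    gene_ids <- sprintf("gene%02d", seq_len(n_genes))
    rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                         replace = TRUE), collapse = "")
    for (gi in seq_len(n_genes)) {
      n_ex <- sample(seq(exons_per_gene[1], exons_per_gene[2]), 1L)
      lens <- sample(seq(exon_nt[1], exon_nt[2]), n_ex, replace = TRUE)
      lens[n_ex] <- lens[n_ex] - sum(lens) %% 3L
      n_cod <- sum(lens) / 3L
      coding <- paste0("ATG",
                       paste(sample(SENSE_CODONS, n_cod - 2L, replace = TRUE,
                                    prob = codon_w), collapse = ""),
                       "TAA")
      prot[gi] <- as.character(Biostrings::translate(
        Biostrings::DNAString(substr(coding, 1L, nchar(coding) - 3L))))
      strand <- sample(c("+", "-"), 1L)
      # transcript-oriented locus: exons interleaved with introns
      ex_seq <- substring(coding, cumsum(c(1L, lens[-n_ex])),
                          cumsum(lens))
      introns <- vapply(seq_len(n_ex - 1L), function(i)
        rand_dna(sample(seq(intron_nt[1], intron_nt[2]), 1L)), character(1))
      parts <- character(2L * n_ex - 1L)
      parts[seq(1L, by = 2L, length.out = n_ex)] <- ex_seq
      if (n_ex > 1L) parts[seq(2L, by = 2L, length.out = n_ex - 1L)] <- introns
      locus_tx <- paste(parts, collapse = "")
      L <- nchar(locus_tx)
      part_len <- nchar(parts)
      tx_start <- cumsum(c(1L, part_len[-length(part_len)]))
      tx_end <- cumsum(part_len)
      ex_idx <- seq(1L, by = 2L, length.out = n_ex)
      spacer <- rand_dna(intergenic_nt)
      chrom <- c(chrom, spacer)
      locus_start <- pos + intergenic_nt + 1L
      pos <- pos + intergenic_nt + L
      if (strand == "+") {
        g_start <- locus_start + tx_start[ex_idx] - 1L
        g_end <- locus_start + tx_end[ex_idx] - 1L
        chrom <- c(chrom, locus_tx)
      } else {
        g_start <- locus_start + (L - tx_end[ex_idx] + 1L) - 1L
        g_end <- locus_start + (L - tx_start[ex_idx] + 1L) - 1L
        chrom <- c(chrom, as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(locus_tx))))
      }
      cum <- c(0L, cumsum(lens))[seq_len(n_ex)]
      exons[[gi]] <- data.frame(
        gene_id = gene_ids[gi], exon_rank = seq_len(n_ex),
        chrom = chrom_name, strand = strand,
        start = g_start, end = g_end,
        phase = (3L - (cum %% 3L)) %% 3L, stringsAsFactors = FALSE)
      genes[[gi]] <- data.frame(
        gene_id = gene_ids[gi], chrom = chrom_name, strand = strand,
        start = min(g_start), end = max(g_end), stringsAsFactors = FALSE)
    }
    chrom <- c(chrom, rand_dna(intergenic_nt))
    seqs <- Biostrings::DNAStringSet(paste(chrom, collapse = ""))
    names(seqs) <- chrom_name
    proteins <- Biostrings::AAStringSet(prot)
    names(proteins) <- gene_ids
    structure(list(seqs = seqs,
                   genes = do.call(rbind, genes),
                   exons = do.call(rbind, exons),
                   proteins = proteins,
                   seed = seed),
              class = "genome_bundle")
  })
}

#' Generate gapped-read junction evidence with ground truth
#'
#' Emits per-read junction evidence for every constitutive (adjacent-exon)
#' junction of a genome bundle and, for a fraction `alt_rate` of genes with
#' at least three exons, an exon-skipping junction that shares a 5' or 3'
#' end with its flanking constitutive junctions (making all three
#' alternative by the shared-end rule). A fraction of junctions is emitted
#' with a single supporting read ("below support"), and some junctions gain
#' an extra read with < 4 nt exonic overlap that must not count as support.
#'
#' @param genome A `genome_bundle` from \code{\link{gen_genome}}.
#' @param alt_rate Fraction of eligible genes given a skip junction, in [0,1].
#' @param depth Supporting reads per junction.
#' @param seed Integer seed.
#' @param low_support_rate Fraction of junctions emitted with 1 read.
#' @param low_overlap_read_rate Fraction of junctions gaining one read with
#'   exonic overlap below 4 nt.
#' @param overlap_nt Range of per-read exonic overlaps (nt) for normal reads.
#' @return A list with `evidence` (chrom, strand, left_end, right_start,
#'   read_id, left_overlap_nt, right_overlap_nt; 1-based inclusive exonic
#'   coordinates) and `truth` (one row per junction: coordinates, gene,
#'   kind constitutive/skip, alternative flag, below_support flag).
#' @export
gen_junction_evidence <- function(genome, alt_rate = 0.5, depth = 5L, seed = 1L,
                                  low_support_rate = 0, low_overlap_read_rate = 0,
                                  overlap_nt = c(4L, 15L)) {
  if (!inherits(genome, "genome_bundle"))
    stop_input("genome must be a genome_bundle")
  if (!is.numeric(alt_rate) || alt_rate < 0 || alt_rate > 1)
    stop_config("alt_rate must be in [0, 1]")
  assert_scalar_number(depth, "depth", lower = 1)
  with_seed(seed, {
    jx <- list()
    for (g in genome$genes$gene_id) {
      ex <- genome$exons[genome$exons$gene_id == g, , drop = FALSE]
      ex <- ex[order(ex$exon_rank), , drop = FALSE]
      n_ex <- nrow(ex)
      minus <- ex$strand[1] == "-"
      jcoord <- function(i, j) { # junction between transcript exons i < j
        if (minus) c(left_end = ex$end[j], right_start = ex$start[i])
        else c(left_end = ex$end[i], right_start = ex$start[j])
      }
      for (i in seq_len(n_ex - 1L)) {
        cc <- jcoord(i, i + 1L)
        jx[[length(jx) + 1L]] <- data.frame(
          chrom = ex$chrom[1], strand = ex$strand[1],
          left_end = cc[["left_end"]], right_start = cc[["right_start"]],
          gene_id = g, kind = "constitutive", stringsAsFactors = FALSE)
      }
      if (n_ex >= 3L && stats::runif(1) < alt_rate) {
        i <- sample(seq_len(n_ex - 2L), 1L)
        cc <- jcoord(i, i + 2L)
        jx[[length(jx) + 1L]] <- data.frame(
          chrom = ex$chrom[1], strand = ex$strand[1],
          left_end = cc[["left_end"]], right_start = cc[["right_start"]],
          gene_id = g, kind = "skip", stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, jx)
    key_l <- paste(truth$chrom, truth$strand, truth$left_end)
    key_r <- paste(truth$chrom, truth$strand, truth$right_start)
    truth$alternative <- (stats::ave(seq_along(key_l), key_l, FUN = length) > 1L) |
      (stats::ave(seq_along(key_r), key_r, FUN = length) > 1L)
    n_reads <- rep(as.integer(depth), nrow(truth))
    n_reads[stats::runif(nrow(truth)) < low_support_rate] <- 1L
    truth$below_support <- n_reads < 2L
    ev <- list()
    rid <- 0L
    for (i in seq_len(nrow(truth))) {
      k <- n_reads[i]
      lo <- sample(seq(overlap_nt[1], overlap_nt[2]), k, replace = TRUE)
      ro <- sample(seq(overlap_nt[1], overlap_nt[2]), k, replace = TRUE)
      if (stats::runif(1) < low_overlap_read_rate) {
        lo <- c(lo, sample(1:3, 1L))
        ro <- c(ro, sample(seq(overlap_nt[1], overlap_nt[2]), 1L))
        k <- k + 1L
      }
      ev[[i]] <- data.frame(
        chrom = truth$chrom[i], strand = truth$strand[i],
        left_end = truth$left_end[i], right_start = truth$right_start[i],
        read_id = sprintf("read%05d", rid + seq_len(k)),
        left_overlap_nt = lo, right_overlap_nt = ro,
        stringsAsFactors = FALSE)
      rid <- rid + k
    }
    rownames(truth) <- NULL
    list(evidence = do.call(rbind, ev), truth = truth)
  })
}

#' Read / write junction evidence TSV
#'
#' The interchange format is a BED-adjacent TSV with one row per supporting
#' read: `chrom`, `strand`, `left_end` (last exonic base of the 5' exon on
#' the + reference axis), `right_start` (first exonic base of the 3' exon),
#' `read_id`, `left_overlap_nt`, `right_overlap_nt`. Coordinates are 1-based
#' inclusive.
#'
#' @param x Evidence data frame.
#' @param path TSV path.
#' @return `read_junction_evidence` returns the data frame;
#'   `write_junction_evidence` returns `path` invisibly.
#' @export
write_junction_evidence <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_junction_evidence
#' @export
read_junction_evidence <- function(path) {
  if (!file.exists(path)) stop_input("evidence file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
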