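# Fixture builders and independent oracles used across the suite.

# hand-built genome bundle from explicit exon sequences (transcript order).
# For minus-strand genes the reverse complement is laid on the chromosome.
make_gene_bundle <- function(exon_seqs, strand = "+", gene_id = "g1",
                             chrom = "c1", intron = 50L, pad = 5L) {
  rc <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  n_ex <- length(exon_seqs)
  introns <- replicate(n_ex - 1L,
                       paste(sample(c("A", "C", "G", "T"), intron,
                                    replace = TRUE), collapse = ""))
  parts <- character(2L * n_ex - 1L)
  parts[seq(1, by = 2, length.out = n_ex)] <- exon_seqs
  if (n_ex > 1L) parts[seq(2, by = 2, length.out = n_ex - 1L)] <- introns
  locus <- paste(parts, collapse = "")
  L <- nchar(locus)
  plen <- nchar(parts)
  tx_start <- cumsum(c(1L, plen[-length(plen)]))
  tx_end <- cumsum(plen)
  ei <- seq(1, by = 2, length.out = n_ex)
  padseq <- paste(rep("T", pad), collapse = "")
  if (strand == "+") {
    chrom_seq <- paste0(padseq, locus, padseq)
    g_start <- pad + tx_start[ei]
    g_end <- pad + tx_end[ei]
  } else {
    chrom_seq <- paste0(padseq, rc(locus), padseq)
    g_start <- pad + (L - tx_end[ei] + 1L)
    g_end <- pad + (L - tx_start[ei] + 1L)
  }
  lens <- nchar(exon_seqs)
  cum <- c(0L, cumsum(lens))[seq_len(n_ex)]
  seqs <- Biostrings::DNAStringSet(chrom_seq)
  names(seqs) <- chrom
  cds <- paste(exon_seqs, collapse = "")
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds), no.init.codon = TRUE))
  aa <- sub("\\*.*$", "", aa)
  prot <- Biostrings::AAStringSet(aa)
  names(prot) <- gene_id
  structure(list(
    seqs = seqs,
    genes = data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                       start = min(g_start), end = max(g_end),
                       stringsAsFactors = FALSE),
    exons = data.frame(gene_id = gene_id, exon_rank = seq_len(n_ex),
                       chrom = chrom, strand = strand,
                       start = g_start, end = g_end,
                       phase = (3L - (cum %% 3L)) %% 3L,
                       stringsAsFactors = FALSE),
    proteins = prot, seed = 0L), class = "genome_bundle")
}

# independent brute-force enumeration of junction-spanning LysC peptides:
# all 3 frames x all (i, j) substrings satisfying the digestion-product
# characterization x span and length filters. Uses its own reverse
# complement and digestion logic.
brute_force_junction_peptides <- function(genome, junctions, params) {
  rc <- function(s)
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  code <- Biostrings::GENETIC_CODE
  out <- character(0)
  jx <- junctions[junctions$alternative, , drop = FALSE]
  for (r in seq_len(nrow(jx))) {
    j <- jx[r, ]
    chrom_seq <- as.character(genome$seqs[[j$chrom]])
    ex <- genome$exons
    li <- which(ex$chrom == j$chrom & ex$strand == j$strand &
                  ex$end == j$left_end)
    ri <- which(ex$chrom == j$chrom & ex$strand == j$strand &
                  ex$start == j$right_start)
    lf_lo <- max(j$left_end - params$flank_nt + 1L,
                 if (length(li)) ex$start[li[1]] else 1L, 1L)
    rf_hi <- min(j$right_start + params$flank_nt - 1L,
                 if (length(ri)) ex$end[ri[1]] else nchar(chrom_seq),
                 nchar(chrom_seq))
    lseq <- substr(chrom_seq, lf_lo, j$left_end)
    rseq <- substr(chrom_seq, j$right_start, rf_hi)
    if (j$strand == "+") {
      ctx <- paste0(lseq, rseq); L <- nchar(lseq)
    } else {
      ctx <- paste0(rc(rseq), rc(lseq)); L <- nchar(rseq)
    }
    for (o in 0:2) {
      n_cod <- (nchar(ctx) - o) %/% 3
      if (n_cod < 1) next
      codons <- substring(ctx, o + 3 * (seq_len(n_cod) - 1) + 1,
                          o + 3 * seq_len(n_cod))
      aa <- unname(code[codons])
      stop_i <- which(aa == "*")
      if (length(stop_i)) aa <- aa[seq_len(stop_i[1] - 1L)]
      na <- length(aa)
      if (!na) next
      for (i in seq_len(na)) for (jj in i:na) {
        # digestion-product characterization: boundaries at K or ends;
        # internal K allowed only when followed by P (retained K|P bond),
        # and at most max_kp of them
        if (i > 1 && aa[i - 1] != "K") next
        if (jj < na && aa[jj] != "K") next
        internal <- seq(i, jj - 1L)
        internal <- internal[aa[internal] == "K"]
        if (any(aa[internal + 1L] != "P")) next
        if (length(internal) > params$max_kp_miscleavage) next
        plen <- jj - i + 1L
        if (plen < params$min_pep_len || plen > params$max_pep_len) next
        # span: first residue fully 5' of junction, last fully 3'
        if (!(o + 3 * i <= L && o + 3 * (jj - 1) + 1 >= L + 1)) next
        out <- c(out, paste(aa[i:jj], collapse = ""))
      }
    }
  }
  sort(unique(out))
}

# Tukey-Kramer adjusted p for one pairwise contrast, straight from the
# studentized range distribution (reference computation for anova_tukey)
reference_tukey_p <- function(y, g, pair) {
  g <- factor(g)
  k <- nlevels(g)
  ns <- tapply(y, g, length)
  ms <- tapply(y, g, mean)
  dfe <- length(y) - k
  mse <- sum((y - ms[g])^2) / dfe
  se <- sqrt(mse / 2 * (1 / ns[pair[1]] + 1 / ns[pair[2]]))
  q <- abs(ms[pair[1]] - ms[pair[2]]) / se
  stats::ptukey(q, k, dfe, lower.tail = FALSE)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
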