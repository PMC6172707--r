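# Junction-spanning peptide extraction, deduplication, and search-database
# assembly.

# transcript-oriented splice context for one junction.
# Returns ctx (character), L (nt on the transcript-5' side of the junction),
# genomic anchor coordinates of the two flanks, and the annotated frame
# offset (NA when the junction is not inside a single annotated gene).
junction_context <- function(genome, chrom, strand, left_end, right_start,
                             flank_nt) {
  chrseq <- genome$seqs[[chrom]]
  if (is.null(chrseq))
    stop_input("unknown chromosome: ", chrom)
  clen <- length(chrseq)
  if (left_end < 1L || right_start > clen || left_end >= right_start)
    stop_input("junction outside genome bounds: ",
               chrom, ":", left_end, "-", right_start)
  ex <- genome$exons
  li <- which(ex$chrom == chrom & ex$strand == strand & ex$end == left_end)
  ri <- which(ex$chrom == chrom & ex$strand == strand &
                ex$start == right_start)
  lf_lo <- left_end - flank_nt + 1L
  rf_hi <- right_start + flank_nt - 1L
  if (length(li)) lf_lo <- max(lf_lo, ex$start[li[1]])
  if (length(ri)) rf_hi <- min(rf_hi, ex$end[ri[1]])
  if (lf_lo < 1L) {
    warning("left flank truncated at chromosome start for ",
            chrom, ":", left_end)
    lf_lo <- 1L
  }
  if (rf_hi > clen) {
    warning("right flank truncated at chromosome end for ",
            chrom, ":", right_start)
    rf_hi <- clen
  }
  lseq <- as.character(Biostrings::subseq(chrseq, lf_lo, left_end))
  rseq <- as.character(Biostrings::subseq(chrseq, right_start, rf_hi))
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  if (strand == "+") {
    ctx <- paste0(lseq, rseq); L <- nchar(lseq)
  } else {
    ctx <- paste0(rc(rseq), rc(lseq)); L <- nchar(rseq)
  }
  # annotated frame: both flanks in exons of the same gene
  ann <- NA_integer_
  if (length(li) && length(ri) &&
      ex$gene_id[li[1]] == ex$gene_id[ri[1]]) {
    gid <- ex$gene_id[li[1]]
    gx <- ex[ex$gene_id == gid, , drop = FALSE]
    gx <- gx[order(gx$exon_rank), , drop = FALSE]
    lens <- gx$end - gx$start + 1L
    if (strand == "+") {
      k <- gx$exon_rank[gx$end == left_end][1]
      cumb <- if (k > 1L) sum(lens[seq_len(k - 1L)]) else 0L
      t0 <- cumb + (lf_lo - gx$start[gx$exon_rank == k] + 1L)
    } else {
      k <- gx$exon_rank[gx$start == right_start][1]
      cumb <- if (k > 1L) sum(lens[seq_len(k - 1L)]) else 0L
      t0 <- cumb + (gx$end[gx$exon_rank == k] - rf_hi + 1L)
    }
    ann <- (3L - ((t0 - 1L) %% 3L)) %% 3L
  }
  list(ctx = ctx, L = L, lf_lo = lf_lo, rf_hi = rf_hi,
       annotated_offset = ann)
}

# translate ctx at frame offset `o`, truncating at the first stop codon
translate_offset <- function(ctx, o) {
  n <- nchar(ctx)
  usable <- ((n - o) %/% 3L) * 3L
  if (usable < 3L) return("")
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(ctx, o + 1L, o + usable)),
    no.init.codon = TRUE))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0L) aa <- substr(aa, 1L, stop_at - 1L)
  aa
}

#' Extract LysC junction-spanning peptides from alternative junctions
#'
#' For each alternative junction, concatenates up to `flank_nt` of exonic
#' sequence ending at `left_end` with up to `flank_nt` starting at
#' `right_start` (strand-aware; both flanks reverse-complemented and swapped
#' for minus-strand junctions, and truncated at exon boundaries when the
#' junction lies in an annotated exon), translates the spliced context in
#' the annotated CDS frame when available (all three frames otherwise, or
#' always when `params$frames == "all3"`), truncates at stop codons, digests
#' with LysC (K|P rule, miscleavage per `params`), and keeps peptides that
#' span the junction with at least one residue fully encoded on each side
#' and length within `[min_pep_len, max_pep_len]`.
#'
#' @param genome A `genome_bundle`.
#' @param junctions Junction data frame carrying an `alternative` column
#'   (from \code{\link{classify_junctions}}); only alternative junctions are
#'   used.
#' @param params A \code{\link{junction_params}} object.
#' @return Data frame of junction peptides: `sequence`, junction
#'   coordinates, `gene_id` (NA for unannotated junctions), `frame`
#'   ("annotated" or the 0/1/2 offset), miscleavage flags, and genomic
#'   spans of the encoding nucleotides on each side of the junction.
#' @export
extract_junction_peptides <- function(genome, junctions,
                                      params = junction_params()) {
  if (!inherits(genome, "genome_bundle"))
    stop_input("genome must be a genome_bundle")
  if (!"alternative" %in% names(junctions))
    stop_input("junctions must be classified first (classify_junctions)")
  jx <- junctions[junctions$alternative, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(jx))) {
    j <- jx[i, ]
    cx <- junction_context(genome, j$chrom, j$strand, j$left_end,
                           j$right_start, params$flank_nt)
    L <- cx$L
    ex <- genome$exons
    li <- which(ex$chrom == j$chrom & ex$strand == j$strand &
                  ex$end == j$left_end)
    ri <- which(ex$chrom == j$chrom & ex$strand == j$strand &
                  ex$start == j$right_start)
    gene_id <- if (length(li) && length(ri) &&
                   ex$gene_id[li[1]] == ex$gene_id[ri[1]])
      ex$gene_id[li[1]] else NA_character_
    if (params$frames == "annotated" && !is.na(cx$annotated_offset)) {
      offsets <- cx$annotated_offset
      labels <- "annotated"
    } else {
      offsets <- 0:2
      labels <- as.character(0:2)
    }
    for (fi in seq_along(offsets)) {
      o <- offsets[fi]
      aa <- translate_offset(cx$ctx, o)
      if (nchar(aa) == 0L) next
      dg <- digest_peptides(aa, "lysc", params$max_kp_miscleavage)
      plen <- dg$end - dg$start + 1L
      spans <- (o + 3L * dg$start) <= L &
        (o + 3L * (dg$end - 1L) + 1L) >= L + 1L
      keep <- spans & plen >= params$min_pep_len & plen <= params$max_pep_len
      if (!any(keep)) next
      dg <- dg[keep, , drop = FALSE]
      a <- o + 3L * (dg$start - 1L) + 1L   # ctx nt span of each peptide
      b <- o + 3L * dg$end
      if (j$strand == "+") {
        ls <- cx$lf_lo + a - 1L
        le <- pmin(j$left_end, cx$lf_lo + b - 1L)
        rs <- j$right_start
        re <- j$right_start + (b - L) - 1L
      } else {
        # ctx 1..L is the genomic-right flank (read downstream to upstream)
        rs <- cx$rf_hi - L + 1L
        re <- cx$rf_hi - a + 1L
        ls <- j$left_end - (b - L) + 1L
        le <- j$left_end
      }
      out[[length(out) + 1L]] <- data.frame(
        sequence = dg$peptide, chrom = j$chrom, strand = j$strand,
        left_end = j$left_end, right_start = j$right_start,
        gene_id = gene_id, frame = labels[fi],
        n_miscleavage = dg$n_miscleavage, miscleaved = dg$miscleaved,
        left_span_start = ls, left_span_end = le,
        right_span_start = rs, right_span_end = re,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(sequence = character(0), chrom = character(0),
                      strand = character(0), left_end = integer(0),
                      right_start = integer(0), gene_id = character(0),
                      frame = character(0), n_miscleavage = integer(0),
                      miscleaved = logical(0), left_span_start = integer(0),
                      left_span_end = integer(0), right_span_start = integer(0),
                      right_span_end = integer(0), stringsAsFactors = FALSE))
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  res
}

#' Deduplicate junction peptides and flag canonical products
#'
#' A peptide sequence arising from two or more distinct genomic loci cannot
#' be attributed to one junction by quantification, so every copy is removed
#' (`multi-locus-duplicate`). Peptides whose exact sequence occurs in the
#' in-silico LysC digest of the canonical proteome are flagged
#' `canonical-duplicate` and removed from the novel set; survivors are
#' `novel`.
#'
#' @param peptides Data frame from \code{\link{extract_junction_peptides}}.
#' @param proteins Canonical proteins (`AAStringSet` or named character).
#' @param max_kp_miscleavage Retained K|P bonds used for the canonical
#'   digest (match the extraction setting).
#' @return `peptides` with a `status` column; the novel set is
#'   `subset(x, status == "novel")`. Filter counts via
#'   \code{\link{filter_log}}.
#' @export
dedupe_and_annotate <- function(peptides, proteins,
                                max_kp_miscleavage = 1L) {
  prot <- as.character(proteins)
  canonical <- unique(unlist(lapply(prot, function(p)
    digest_peptides(p, "lysc", max_kp_miscleavage)$peptide)))
  locus <- paste(peptides$chrom, peptides$strand, peptides$left_end,
                 peptides$right_start)
  n_loci <- vapply(split(locus, peptides$sequence),
                   function(l) length(unique(l)), integer(1))
  multi <- n_loci[peptides$sequence] >= 2L
  canon <- peptides$sequence %in% canonical
  peptides$status <- ifelse(multi, "multi-locus-duplicate",
                            ifelse(canon, "canonical-duplicate", "novel"))
  with_filter_log(peptides, nrow(peptides),
                  sum(peptides$status == "novel"),
                  c(`multi-locus-duplicate` = sum(multi),
                    `canonical-duplicate` = sum(canon & !multi)))
}

#' Write the expanded search database FASTA
#'
#' Canonical entries first, then one entry per novel junction peptide. The
#' novel header grammar is
#' `jxnpep<N>|<gene>|<chrom>:<left_end>-<right_start>(<strand>)|frame=<f>|mc=<n>`.
#'
#' @param canonical Canonical proteome (`AAStringSet` or named character).
#' @param novel Data frame of peptides with `status == "novel"` (rows with
#'   other statuses are ignored).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_search_db <- function(canonical, novel, path) {
  if (length(canonical) == 0L)
    stop_input("canonical set must be non-empty")
  canonical <- Biostrings::AAStringSet(as.character(canonical))
  if ("status" %in% names(novel))
    novel <- novel[novel$status == "novel", , drop = FALSE]
  if (nrow(novel)) {
    hdr <- sprintf("jxnpep%05d|%s|%s:%d-%d(%s)|frame=%s|mc=%d",
                   seq_len(nrow(novel)),
                   ifelse(is.na(novel$gene_id), "unannotated", novel$gene_id),
                   novel$chrom, novel$left_end, novel$right_start,
                   novel$strand, novel$frame, novel$n_miscleavage)
    np <- Biostrings::AAStringSet(novel$sequence)
    names(np) <- hdr
    all <- c(canonical, np)
  } else all <- canonical
  ids <- sub("\\s.*$", "", names(all))
  if (anyDuplicated(ids))
    stop_input("duplicate header ids in search database")
  write_fasta(all, path)
}
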