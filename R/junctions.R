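# Junction summarization and alternative-junction classification.

#' Parameters for junction-peptide database construction
#'
#' Defaults follow the study design this pipeline implements: a junction
#' must be represented by at least 2 gapped reads, a read only counts if
#' both of its exonic overlaps are at least 4 nt, LysC digestion cleaves
#' K|P bonds with at most one retained (miscleaved) K|P bond per peptide,
#' and peptides are kept in the MS-observable 6-50 aa range.
#'
#' @param min_reads Minimum qualifying read support per junction.
#' @param min_overlap_nt Minimum exonic overlap (nt) on both sides for a
#'   read to count as support.
#' @param flank_nt Maximum exonic flank (nt) taken on each side of the
#'   junction for translation; extension stops at exon boundaries.
#' @param frames `"annotated"` (use the annotated CDS frame when the
#'   junction lies in an annotated gene, falling back to 3-frame
#'   translation) or `"all3"` (always translate all three frames).
#' @param min_pep_len,max_pep_len Peptide length bounds (aa).
#' @param max_kp_miscleavage Maximum retained K|P bonds per peptide.
#' @return A `junction_params` list.
#' @export
junction_params <- function(min_reads = 2L, min_overlap_nt = 4L,
                            flank_nt = 120L,
                            frames = c("annotated", "all3"),
                            min_pep_len = 6L, max_pep_len = 50L,
                            max_kp_miscleavage = 1L) {
  frames <- match.arg(frames)
  for (nm in c("min_reads", "min_overlap_nt", "flank_nt", "min_pep_len",
               "max_pep_len", "max_kp_miscleavage"))
    assert_scalar_number(get(nm), nm, lower = 0)
  structure(list(min_reads = as.integer(min_reads),
                 min_overlap_nt = as.integer(min_overlap_nt),
                 flank_nt = as.integer(flank_nt), frames = frames,
                 min_pep_len = as.integer(min_pep_len),
                 max_pep_len = as.integer(max_pep_len),
                 max_kp_miscleavage = as.integer(max_kp_miscleavage)),
            class = "junction_params")
}

#' Summarize per-read junction evidence into supported junctions
#'
#' Merges evidence records by (chrom, strand, left_end, right_start); a read
#' contributes support only when both of its exonic overlaps reach
#' `min_overlap_nt`, and junctions with fewer than `min_reads` qualifying
#' reads are dropped. Malformed records (missing fields, left_end >=
#' right_start) are skipped with a warning and counted in the filter log.
#'
#' @param evidence Data frame as produced by
#'   \code{\link{gen_junction_evidence}} / \code{\link{read_junction_evidence}}.
#' @param params A \code{\link{junction_params}} object.
#' @return Data frame of junctions: chrom, strand, left_end, right_start,
#'   `support` (qualifying reads), `max_min_overlap` (max over qualifying
#'   reads of min(left, right) overlap). Filter counts via
#'   \code{\link{filter_log}}.
#' @export
summarize_junctions <- function(evidence, params = junction_params()) {
  need <- c("chrom", "strand", "left_end", "right_start",
            "left_overlap_nt", "right_overlap_nt")
  if (!all(need %in% names(evidence)))
    stop_input("evidence lacks columns: ",
               paste(setdiff(need, names(evidence)), collapse = ", "))
  n_in <- nrow(evidence)
  malformed <- is.na(evidence$left_end) | is.na(evidence$right_start) |
    !(evidence$strand %in% c("+", "-")) |
    evidence$left_end >= evidence$right_start
  if (any(malformed)) {
    warning(sum(malformed), " malformed evidence record(s) skipped")
    evidence <- evidence[!malformed, , drop = FALSE]
  }
  qualifying <- evidence$left_overlap_nt >= params$min_overlap_nt &
    evidence$right_overlap_nt >= params$min_overlap_nt
  ev <- evidence[qualifying, , drop = FALSE]
  key <- paste(ev$chrom, ev$strand, ev$left_end, ev$right_start, sep = "\r")
  minov <- pmin(ev$left_overlap_nt, ev$right_overlap_nt)
  sup <- tapply(rep(1L, nrow(ev)), key, sum)
  mov <- tapply(minov, key, max)
  parts <- do.call(rbind, strsplit(names(sup), "\r", fixed = TRUE))
  out <- data.frame(chrom = parts[, 1], strand = parts[, 2],
                    left_end = as.integer(parts[, 3]),
                    right_start = as.integer(parts[, 4]),
                    support = as.integer(sup),
                    max_min_overlap = as.integer(mov),
                    stringsAsFactors = FALSE)
  keep <- out$support >= params$min_reads
  dropped_support <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$strand, out$left_end, out$right_start), ,
             drop = FALSE]
  rownames(out) <- NULL
  with_filter_log(out, n_in, nrow(out),
                  c(malformed = sum(malformed),
                    low_overlap_reads = sum(!qualifying),
                    below_min_reads = dropped_support))
}

#' Flag alternative junctions
#'
#' A junction is alternative iff at least one other junction on the same
#' chromosome and strand shares its left (5') end or its right (3') start;
#' all other junctions are singletons/constitutive and are excluded from
#' peptide extraction.
#'
#' @param junctions Data frame from \code{\link{summarize_junctions}}.
#' @return The same data frame with a logical `alternative` column.
#' @export
classify_junctions <- function(junctions) {
  kl <- paste(junctions$chrom, junctions$strand, junctions$left_end)
  kr <- paste(junctions$chrom, junctions$strand, junctions$right_start)
  junctions$alternative <-
    (stats::ave(seq_along(kl), kl, FUN = length) > 1L) |
    (stats::ave(seq_along(kr), kr, FUN = length) > 1L)
  junctions
}
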