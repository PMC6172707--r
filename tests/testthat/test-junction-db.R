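# Junction summarization, classification, digestion, peptide extraction,
# deduplication, and search-database assembly.

evrec <- function(chrom = "c1", strand = "+", le, rs, lo = 10, ro = 10,
                  n = 1) {
  data.frame(chrom = chrom, strand = strand, left_end = le,
             right_start = rs,
             read_id = sprintf("r%03d", seq_len(n)),
             left_overlap_nt = lo, right_overlap_nt = ro,
             stringsAsFactors = FALSE)
}

test_that("junction support requires 2 reads with 4 nt overlap on both sides", {
  # one qualifying read: excluded
  j1 <- summarize_junctions(evrec(le = 100, rs = 500, n = 1))
  expect_equal(nrow(j1), 0L)
  # a read with 3 nt left overlap contributes no support
  ev <- rbind(evrec(le = 100, rs = 500, n = 2),
              evrec(le = 100, rs = 800, lo = 3, n = 2))
  j2 <- summarize_junctions(ev)
  expect_equal(nrow(j2), 1L)
  expect_equal(j2$left_end, 100)
  expect_equal(j2$right_start, 500)
  expect_equal(filter_log(j2)$reasons[["low_overlap_reads"]], 2L)
  # identical coordinates from separate records merge before thresholding
  j3 <- summarize_junctions(rbind(evrec(le = 100, rs = 500, n = 1),
                                  evrec(le = 100, rs = 500, n = 1)))
  expect_equal(nrow(j3), 1L)
  expect_equal(j3$support, 2L)
})

test_that("malformed evidence records are skipped with a warning", {
  ev <- rbind(evrec(le = 100, rs = 500, n = 2),
              evrec(le = 900, rs = 500, n = 1))  # left >= right
  expect_warning(j <- summarize_junctions(ev), "malformed")
  expect_equal(nrow(j), 1L)
})

test_that("raising thresholds never increases the junction count", {
  set.seed(5)
  g <- gen_genome(5, n_genes = 8)
  ev <- gen_junction_evidence(g, alt_rate = 1, depth = 4, seed = 5,
                              low_support_rate = 0.3,
                              low_overlap_read_rate = 0.5,
                              overlap_nt = c(2L, 15L))$evidence
  n_prev <- Inf
  for (mr in 1:4) {
    n <- nrow(summarize_junctions(ev, junction_params(min_reads = mr)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
  n_prev <- Inf
  for (ov in c(2, 4, 8, 12)) {
    n <- nrow(summarize_junctions(ev,
                                  junction_params(min_overlap_nt = ov)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("junctions sharing a left or right end are alternative; lone ones are not", {
  jx <- data.frame(chrom = "c1", strand = "+",
                   left_end = c(100, 100, 300, 1000),
                   right_start = c(500, 800, 500, 2000),
                   support = 5L, max_min_overlap = 10L,
                   stringsAsFactors = FALSE)
  cl <- classify_junctions(jx)
  expect_equal(cl$alternative, c(TRUE, TRUE, TRUE, FALSE))
  lone <- classify_junctions(jx[1, ])
  expect_false(lone$alternative)
})

test_that("LysC digestion cleaves K|P bonds, with miscleaved forms on request", {
  expect_equal(digest_peptides("MAKPLSK", "lysc", 0)$peptide,
               c("MAK", "PLSK"))
  expect_setequal(digest_peptides("MAKPLSK", "lysc", 1)$peptide,
                  c("MAK", "PLSK", "MAKPLSK"))
  # the amyloid-beta tryptic/LysC context: K.LVFFAEDVGSNK.D
  d <- digest_peptides("AKLVFFAEDVGSNKD", "lysc", 0)
  expect_true("LVFFAEDVGSNK" %in% d$peptide)
  # trypsin does not cleave before proline
  expect_equal(digest_peptides("MARPLSK", "trypsin", 0)$peptide, "MARPLSK")
  expect_equal(digest_peptides("MARGLSK", "trypsin", 0)$peptide,
               c("MAR", "GLSK"))
  expect_error(digest_peptides("MA1K"), "position 3")
})

test_that("more allowed miscleavage never yields fewer peptides", {
  set.seed(8)
  seqs <- vapply(1:10, function(i)
    paste(sample(c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "K", "K"),
                 60, replace = TRUE), collapse = ""), character(1))
  for (s in seqs) {
    n_prev <- -1L
    for (mc in 0:3) {
      n <- nrow(digest_peptides(s, "lysc", mc))
      expect_gte(n, n_prev)
      n_prev <- n
    }
  }
})

test_that("junction-spanning peptides include the miscleaved bridge, not the sides", {
  # E1 = MAK codons, E2 skipped, E3 = PLS + stop
  gn <- make_gene_bundle(c("ATGGCTAAG", "GGATCTGAT", "CCTTTATCTTAA"))
  ex <- gn$exons
  jx <- data.frame(chrom = "c1", strand = "+", left_end = ex$end[1],
                   right_start = ex$start[3], alternative = TRUE,
                   stringsAsFactors = FALSE)
  p <- extract_junction_peptides(gn, jx, junction_params(min_pep_len = 3))
  expect_true("MAKPLS" %in% p$sequence)
  expect_true(all(p$miscleaved[p$sequence == "MAKPLS"]))
  expect_false("MAK" %in% p$sequence)
  expect_false("PLS" %in% p$sequence)
  expect_equal(unique(p$frame), "annotated")
})

test_that("a stop codon immediately after the junction suppresses peptides", {
  gn <- make_gene_bundle(c("ATGGCTAAG", "GGATCTGAT", "TAATAATAATAA"))
  ex <- gn$exons
  jx <- data.frame(chrom = "c1", strand = "+", left_end = ex$end[1],
                   right_start = ex$start[3], alternative = TRUE,
                   stringsAsFactors = FALSE)
  p <- extract_junction_peptides(gn, jx, junction_params(min_pep_len = 1))
  expect_equal(nrow(p), 0L)
})

test_that("a minus-strand gene yields the same peptides as its plus-strand twin", {
  exs <- c("ATGGCTAAGCCTAAG", "GGATCTGATAAG", "CCTTTATCTAAGTAA")
  gp <- make_gene_bundle(exs, strand = "+")
  gm <- make_gene_bundle(exs, strand = "-")
  jp <- data.frame(chrom = "c1", strand = "+",
                   left_end = gp$exons$end[1],
                   right_start = gp$exons$start[3], alternative = TRUE,
                   stringsAsFactors = FALSE)
  # on the minus strand the transcript-5' exon is genomically rightmost
  jm <- data.frame(chrom = "c1", strand = "-",
                   left_end = gm$exons$end[3],
                   right_start = gm$exons$start[1], alternative = TRUE,
                   stringsAsFactors = FALSE)
  pars <- junction_params(min_pep_len = 3)
  pp <- extract_junction_peptides(gp, jp, pars)
  pm <- extract_junction_peptides(gm, jm, pars)
  expect_setequal(pp$sequence, pm$sequence)
  expect_gt(nrow(pp), 0L)
})

test_that("extraction matches the brute-force enumeration on a toy genome", {
  pars <- junction_params(frames = "all3")
  for (seed in c(1, 7)) {
    g <- gen_genome(seed, n_genes = 5)
    ev <- gen_junction_evidence(g, alt_rate = 1, depth = 4, seed = seed)
    jx <- classify_junctions(summarize_junctions(ev$evidence, pars))
    mine <- extract_junction_peptides(g, jx, pars)
    oracle <- brute_force_junction_peptides(g, jx, pars)
    expect_setequal(unique(mine$sequence), oracle)
    expect_gt(length(oracle), 0L)
  }
})

test_that("annotated-frame output is a subset of the 3-frame output", {
  g <- gen_genome(11, n_genes = 5)
  ev <- gen_junction_evidence(g, alt_rate = 1, depth = 4, seed = 11)
  jx <- classify_junctions(summarize_junctions(ev$evidence))
  ann <- extract_junction_peptides(g, jx, junction_params())
  all3 <- extract_junction_peptides(g, jx,
                                    junction_params(frames = "all3"))
  expect_true(all(ann$sequence %in% all3$sequence))
})

test_that("every emitted peptide satisfies the junction-spanning predicate", {
  g <- gen_genome(13, n_genes = 6)
  ev <- gen_junction_evidence(g, alt_rate = 1, depth = 4, seed = 13)
  jx <- classify_junctions(summarize_junctions(ev$evidence))
  p <- extract_junction_peptides(g, jx, junction_params(frames = "all3"))
  expect_gt(nrow(p), 0L)
  # at least one full codon on each side of the junction
  expect_true(all(p$left_span_end - p$left_span_start + 1 >= 3))
  expect_true(all(p$right_span_end - p$right_span_start + 1 >= 3))
  expect_true(all(p$left_span_end == p$left_end))
  expect_true(all(p$right_span_start == p$right_start))
  expect_true(all(nchar(p$sequence) >= 6 & nchar(p$sequence) <= 50))
})

test_that("multi-locus and canonical-duplicate peptides are removed from the novel set", {
  peps <- data.frame(
    sequence = c("LLLGGGKAAK", "LLLGGGKAAK", "WWWCCCKDDK", "MAGSDKPRK"),
    chrom = "c1", strand = "+",
    left_end = c(100, 900, 300, 400),
    right_start = c(500, 1200, 700, 800),
    gene_id = NA_character_, frame = "0", n_miscleavage = 0L,
    miscleaved = FALSE, left_span_start = 1, left_span_end = 2,
    right_span_start = 3, right_span_end = 4, stringsAsFactors = FALSE)
  # canonical LysC digest of gA contains the miscleaved form MAGSDKPRK
  canon <- Biostrings::AAStringSet(c(gA = "MMMKMAGSDKPRK"))
  dd <- dedupe_and_annotate(peps, canon, max_kp_miscleavage = 1)
  expect_equal(dd$status,
               c("multi-locus-duplicate", "multi-locus-duplicate",
                 "novel", "canonical-duplicate"))
  expect_equal(filter_log(dd)$n_out, 1L)
})

test_that("search database writing conserves entries and round-trips", {
  g <- gen_genome(1, n_genes = 5)
  ev <- gen_junction_evidence(g, alt_rate = 1, depth = 4, seed = 1)
  jx <- classify_junctions(summarize_junctions(ev$evidence))
  peps <- dedupe_and_annotate(
    extract_junction_peptides(g, jx, junction_params()), g$proteins)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_search_db(g$proteins, peps, path)
  db <- read_fasta(path, alphabet = "aa")
  n_novel <- sum(peps$status == "novel")
  expect_equal(length(db), length(g$proteins) + n_novel)
  expect_identical(unname(as.character(db)[seq_along(g$proteins)]),
                   unname(as.character(g$proteins)))
  # zero novel peptides: output identical to the canonical set
  path0 <- withr::local_tempfile(fileext = ".fasta")
  write_search_db(g$proteins, peps[peps$status != "novel", ], path0)
  expect_equal(length(read_fasta(path0)), length(g$proteins))
  expect_error(write_search_db(Biostrings::AAStringSet(), peps, path),
               "non-empty")
})
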