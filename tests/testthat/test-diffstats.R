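# ANOVA + Tukey, Fisher enrichment, quantifiability, peptide-module
# assignment, cross-network comparison.

test_that("ANOVA and Tukey behave at the reference cases", {
  # identical values: F = 0, p = 1 by convention
  y0 <- matrix(rep(5, 9), 1, dimnames = list("const", NULL))
  g <- rep(c("CT", "AsymAD", "AD"), each = 3)
  r0 <- anova_tukey(y0, g)
  expect_equal(r0$F, 0)
  expect_equal(r0$p, 1)
  # only pairs involving the shifted group are significant
  y1 <- matrix(c(1, 2, 3, 1, 2, 3, 11, 12, 13), 1,
               dimnames = list("shift", NULL))
  r1 <- anova_tukey(y1, factor(g, levels = c("CT", "AsymAD", "AD")))
  expect_lt(r1$p_AD.CT, 0.05)
  expect_lt(r1$p_AD.AsymAD, 0.05)
  expect_gt(r1$p_AsymAD.CT, 0.05)
  expect_equal(r1$diff_AD.CT, 10)
  # pairwise p agrees with a direct studentized-range computation
  set.seed(3)
  y2 <- rnorm(15) + rep(c(0, 0, 1), c(5, 5, 5))
  g2 <- rep(c("a", "b", "c"), each = 5)
  r2 <- anova_tukey(matrix(y2, 1, dimnames = list("f", NULL)), g2)
  expect_equal(r2$p_c.a, unname(reference_tukey_p(y2, g2, c("c", "a"))),
               tolerance = 1e-9)
  expect_equal(r2$p_b.a, unname(reference_tukey_p(y2, g2, c("b", "a"))),
               tolerance = 1e-9)
})

test_that("features without two populated groups are dropped with a report", {
  v <- rbind(ok = c(1, 2, 1.5, 2.5, 3, 3.5),
             thin = c(1, NA, NA, NA, 2, 3))
  g <- rep(c("CT", "AD"), each = 3)
  r <- anova_tukey(v, g)
  expect_equal(r$feature, "ok")
  expect_equal(filter_log(r)$reasons[["insufficient_groups"]], 1L)
})

test_that("ANOVA p matches a permutation null on a small fixture", {
  set.seed(5)
  y <- rnorm(18) + rep(c(0, 0.5, 1), each = 6)
  g <- rep(c("CT", "AsymAD", "AD"), each = 6)
  r <- anova_tukey(matrix(y, 1, dimnames = list("f", NULL)), g)
  fstat <- function(yy) {
    fit <- anova(stats::aov(yy ~ factor(g)))
    fit$`F value`[1]
  }
  f_obs <- fstat(y)
  perm <- replicate(4000, fstat(sample(y)))
  p_perm <- (1 + sum(perm >= f_obs)) / 4001
  expect_lt(abs(r$p - p_perm), 3 * sqrt(p_perm * (1 - p_perm) / 4000) + 5e-4)
})

test_that("one-tailed Fisher p equals exhaustive enumeration for small universes", {
  # background 4, query 2, target 2, overlap 2: p = 1/6
  fe <- fisher_enrichment(c("a", "b"), c("a", "b"), letters[1:4], "one")
  expect_equal(fe$p, 1 / 6)
  # exhaustive check against dhyper enumeration across a grid
  set.seed(7)
  for (i in 1:25) {
    N <- sample(8:60, 1)
    bg <- sprintf("e%02d", seq_len(N))
    q <- sample(bg, sample(1:N, 1))
    t <- sample(bg, sample(1:N, 1))
    a <- length(intersect(q, t))
    # enumeration: sum over all overlaps >= observed
    ks <- max(0, length(q) + length(t) - N):min(length(q), length(t))
    p_enum <- sum(dhyper(ks[ks >= a], length(t), N - length(t), length(q)))
    expect_equal(fisher_enrichment(q, t, bg, "one")$p, p_enum,
                 tolerance = 1e-12)
    # both tails agree with stats::fisher.test
    m <- matrix(c(a, length(q) - a, length(t) - a,
                  N - length(q) - length(t) + a), 2)
    expect_equal(fisher_enrichment(q, t, bg, "one")$p,
                 fisher.test(m, alternative = "greater")$p.value,
                 tolerance = 1e-9)
    expect_equal(fisher_enrichment(q, t, bg, "two")$p,
                 fisher.test(m)$p.value, tolerance = 1e-9)
  }
  # independence on a large balanced table: p near 1
  bg <- sprintf("x%03d", 1:400)
  fe2 <- fisher_enrichment(bg[1:200], bg[seq(1, 400, 2)], bg, "one")
  expect_gt(fe2$p, 0.3)
  expect_error(fisher_enrichment("a", "a", character(0)), "background")
})

test_that("BH adjustment is monotone in rank and bounded by 1", {
  set.seed(9)
  for (i in 1:20) {
    p <- runif(sample(5:50, 1))
    adj <- p.adjust(p, "BH")
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
    expect_true(all(adj <= 1 & adj >= p - 1e-15))
  }
  # family correction inside one fisher_enrichment call
  bg <- sprintf("g%03d", 1:100)
  qs <- list(a = bg[1:20], b = bg[30:45], c = bg[50:70])
  fe <- fisher_enrichment(qs, bg[1:25], bg, "one")
  expect_equal(fe$p_adj, p.adjust(fe$p, "BH"))
})

test_that("quantifiability requires two measurements in two case groups", {
  g <- rep(c("CT", "AsymAD", "AD"), c(3, 2, 2))
  v <- rbind(
    two_two = c(1, 2, NA, NA, NA, 3, 4),    # 2 in CT + 2 in AD
    all_one_group = c(NA, NA, NA, NA, NA, 5, 6),
    ones = c(1, NA, NA, 1, NA, 1, NA))      # 1 value in each group
  keep <- quantifiable_filter(v, g)
  expect_equal(as.character(keep), "two_two")
  expect_equal(filter_log(keep)$reasons[["unquantifiable"]], 2L)
})

test_that("peptides are assigned to the module they track, within missingness limits", {
  set.seed(11)
  n <- 47
  E <- rbind(M1 = rnorm(n), M2 = rnorm(n), M3 = rnorm(n))
  colnames(E) <- sprintf("S%02d", 1:n)
  peps <- rbind(
    exact = E["M3", ],
    noisy2 = E["M2", ] + rnorm(n, 0, 0.3),
    gappy = c(E["M1", 1:21], rep(NA, 26)))
  colnames(peps) <- colnames(E)
  asg <- assign_peptides_to_modules(peps, E, max_missing = 25)
  expect_equal(asg$module[asg$feature == "exact"], "M3")
  expect_equal(asg$kme[asg$feature == "exact"], 1, tolerance = 1e-9)
  expect_equal(asg$module[asg$feature == "noisy2"], "M2")
  expect_true(is.na(asg$module[asg$feature == "gappy"]))   # 26 of 47 missing
  # eigenprotein-plus-noise peptides assign to their source module nearly always
  hits <- replicate(200, {
    y <- E["M2", ] + rnorm(n, 0, 0.3)
    a <- assign_peptides_to_modules(matrix(y, 1, dimnames = list("p", NULL)),
                                    E)
    a$module == "M2"
  })
  expect_gte(mean(hits), 0.95)
})

test_that("module enrichment for junction peptides matches per-module Fisher tests", {
  prot <- setNames(rep(c("M1", "M2", "M3", "grey"), c(30, 25, 20, 25)),
                   sprintf("P%03d", 1:100))
  asg <- data.frame(feature = sprintf("pep%02d", 1:20),
                    module = c(rep("M1", 14), rep("M2", 3), rep("M3", 3)),
                    kme = 0.8, stringsAsFactors = FALSE)
  er <- module_alt_eejxn_enrichment(asg, prot)
  expect_equal(er$set[which.min(er$p)], "M1")
  # agrees with fisher_enrichment called module-by-module
  bg <- c(names(prot), asg$feature)
  fe1 <- fisher_enrichment(c(names(prot)[prot == "M1"],
                             asg$feature[asg$module == "M1"]),
                           asg$feature, bg, "one")
  expect_equal(er$p[er$set == "M1"], fe1$p)
  expect_equal(er$p_adj, p.adjust(er$p, "BH"))
})

test_that("random peptide assignment gives calibrated module enrichment", {
  set.seed(13)
  prot <- setNames(rep(sprintf("M%d", 1:10), each = 30),
                   sprintf("P%03d", 1:300))
  raw_p <- replicate(60, {
    asg <- data.frame(feature = sprintf("pep%02d", 1:40),
                      module = sample(sprintf("M%d", 1:10), 40, TRUE),
                      kme = 0.5, stringsAsFactors = FALSE)
    module_alt_eejxn_enrichment(asg, prot)$p
  })
  expect_lt(abs(mean(raw_p < 0.05) - 0.05), 0.05)
})

test_that("network comparison finds identity, splits, and no false matches", {
  feats <- sprintf("F%03d", 1:120)
  la <- setNames(rep(c("M1", "M2", "M3"), each = 40), feats)
  cmp <- compare_networks(la, la)
  self <- cmp$best_a
  expect_equal(self$module_b, self$module_a)
  expect_true(all(self$p < 1e-10))
  # splitting one module of A into two in B: both halves match it
  lb <- la
  lb[feats[1:20]] <- "M1a"; lb[feats[21:40]] <- "M1b"
  cmp2 <- compare_networks(la, lb)
  bb <- cmp2$best_b
  expect_equal(bb$module_a[bb$module_b %in% c("M1a", "M1b")],
               c("M1", "M1"))
  # independent random labelings: nothing survives BH
  set.seed(15)
  fails <- replicate(40, {
    l1 <- setNames(sample(rep(sprintf("M%d", 1:5), each = 100)),
                   sprintf("G%03d", 1:500))
    l2 <- setNames(sample(rep(sprintf("M%d", 1:5), each = 100)),
                   sprintf("G%03d", 1:500))
    any(compare_networks(l1, l2)$pairs$p_adj < 0.05)
  })
  expect_gte(mean(!fails), 0.95)
  expect_error(compare_networks(setNames("M1", "a"), setNames("M1", "b")),
               "disjoint")
})
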