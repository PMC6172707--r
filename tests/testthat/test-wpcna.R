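# Biweight midcorrelation, soft-threshold selection, TOM, module detection,
# eigenproteins, kME, module-trait correlations.

planted_blocks <- function(n = 47, sizes = rep(40, 5), noise_sd = 0.5,
                           loading = 1, seed = 7, extra_noise = 0) {
  set.seed(seed)
  K <- length(sizes)
  z <- matrix(rnorm(K * n), K, n)
  X <- do.call(rbind, lapply(seq_len(K), function(m)
    t(sapply(seq_len(sizes[m]), function(i)
      loading * z[m, ] + rnorm(n, 0, noise_sd)))))
  if (extra_noise > 0)
    X <- rbind(X, matrix(rnorm(extra_noise * n), extra_noise, n))
  rownames(X) <- sprintf("F%03d", seq_len(nrow(X)))
  list(x = X, truth = rep(c(sprintf("B%d", seq_len(K)), "noise"),
                          c(sizes, extra_noise)), drivers = z)
}

test_that("bicor matches its defining identities and tracks Pearson on clean data", {
  set.seed(1)
  x <- rnorm(47)
  expect_equal(bicor(x, x), 1)
  expect_equal(bicor(x, -x), -1)
  diffs <- replicate(50, {
    a <- rnorm(47); b <- 0.5 * a + rnorm(47)
    abs(bicor(a, b) - cor(a, b))
  })
  expect_lt(mean(diffs), 0.05)
  expect_lt(max(diffs), 0.12)
  # insensitive to a gross outlier, unlike Pearson
  a <- rnorm(47); b <- 0.8 * a + rnorm(47, 0, 0.3)
  a2 <- a; a2[1] <- 50
  expect_lt(abs(bicor(a2, b) - bicor(a, b)), 0.1)
  expect_gt(abs(cor(a2, b) - cor(a, b)), 0.3)
  # too few pairs
  expect_true(is.na(bicor(c(1, 2, 3, NA), c(1, 2, NA, 4))))
  # MAD-zero vector falls back to mean centering (defined result)
  const_ish <- c(rep(0, 30), rnorm(17))
  expect_false(is.na(bicor(const_ish, rnorm(47))))
})

test_that("bicor_all agrees with the pairwise scalar on missing data", {
  set.seed(2)
  X <- matrix(rnorm(8 * 30), 8, 30, dimnames = list(letters[1:8], NULL))
  X[sample(length(X), 30)] <- NA
  R <- bicor_all(X)
  expect_equal(R["a", "c"], bicor(X["a", ], X["c", ]))
  expect_equal(R, t(R))
})

test_that("beta selection returns the lowest power reaching the fit target", {
  # heterogeneous loadings and block sizes over a grey-dominant matrix
  # spread the connectivity distribution as in real proteome networks
  set.seed(42)
  n <- 47
  sizes <- c(40, 28, 22, 17, 13)
  z <- matrix(rnorm(5 * n), 5, n)
  X <- do.call(rbind, lapply(1:5, function(m)
    t(sapply(seq_len(sizes[m]), function(i)
      runif(1, 0.35, 1.2) * z[m, ] + rnorm(n, 0, runif(1, 0.5, 1.5))))))
  X <- rbind(X, matrix(rnorm(180 * n), 180, n))
  rownames(X) <- sprintf("F%03d", seq_len(nrow(X)))
  b <- pick_beta(X)
  tab <- attr(b, "fit_table")
  reached <- tab$power[!is.na(tab$fit) & tab$fit >= 0.80]
  expect_true(length(reached) > 0)
  expect_equal(as.numeric(b), min(reached))
  expect_gte(tab$fit[tab$power == as.numeric(b)], 0.80)
  # degenerate input is rejected
  Xc <- rbind(X[1:5, ], const = rep(1, 47))
  expect_error(pick_beta(Xc), "constant")
})

test_that("beta selection falls back to the fit plateau when the target is unreachable", {
  pb <- planted_blocks(sizes = rep(40, 5), seed = 3)
  expect_message(b <- pick_beta(pb$x, powers = seq(2, 6, 0.5)), "plateau")
  tab <- attr(b, "fit_table")
  expect_true(all(tab$fit < 0.80, na.rm = TRUE))
})

test_that("TOM follows the mean-denominator formula and its limit cases", {
  # three nodes, all pairwise adjacency 0.5 (signed map of r = 0 at beta 1)
  R0 <- diag(3) * 0 + diag(3); R0[R0 == 0] <- 0
  R <- matrix(0, 3, 3); diag(R) <- 1
  at <- adjacency_tom(params = network_params(beta = 1), cor_mat = R)
  expect_equal(at$adjacency[1, 2], 0.5)
  expect_equal(at$tom[1, 2], (0.25 + 0.5) / (1 + 1 - 0.5))
  # perfectly correlated pair in an otherwise empty graph
  R2 <- diag(2); R2[1, 2] <- R2[2, 1] <- 1
  at2 <- adjacency_tom(params = network_params(beta = 6), cor_mat = R2)
  expect_equal(at2$tom[1, 2], 1)
  # perfect anticorrelation maps to zero adjacency in a signed network
  R3 <- diag(2); R3[1, 2] <- R3[2, 1] <- -1
  at3 <- adjacency_tom(params = network_params(beta = 6), cor_mat = R3)
  expect_equal(at3$adjacency[1, 2], 0)
  # general properties on real data
  pb <- planted_blocks(sizes = c(30, 30), seed = 5)
  at4 <- adjacency_tom(pb$x, network_params(beta = 4))
  expect_true(all(at4$tom >= 0 & at4$tom <= 1))
  expect_equal(at4$tom, t(at4$tom))
})

test_that("five planted blocks are recovered with high ARI", {
  pb <- planted_blocks(sizes = rep(40, 5), seed = 7)
  np <- network_params(beta = 4)
  at <- adjacency_tom(pb$x, np)
  lab <- detect_modules(pb$x, at$tom, np)
  expect_gte(ari(lab, pb$truth), 0.9)
  expect_equal(length(setdiff(unique(lab), "grey")), 5L)
  sz <- table(lab[lab != "grey"])
  expect_true(all(sz >= np$min_module_size))
  # labels ordered by size: M1 is the largest
  expect_equal(names(which.max(sz)), "M1")
})

test_that("module labels do not depend on feature input order", {
  pb <- planted_blocks(sizes = c(30, 25, 20), seed = 9)
  np <- network_params(beta = 4)
  at <- adjacency_tom(pb$x, np)
  lab <- detect_modules(pb$x, at$tom, np)
  perm <- sample(nrow(pb$x))
  lab_p <- detect_modules(pb$x[perm, ], at$tom[perm, perm], np)
  expect_identical(lab[names(lab_p)], lab_p)
})

test_that("pure noise yields no spurious truth-matching modules", {
  set.seed(11)
  X <- matrix(rnorm(200 * 47), 200, 47,
              dimnames = list(sprintf("N%03d", 1:200), NULL))
  np <- network_params(beta = 4)
  at <- adjacency_tom(X, np)
  lab <- detect_modules(X, at$tom, np)
  expect_lt(abs(ari(lab, rep(sprintf("B%d", 1:5), each = 40))), 0.05)
})

test_that("modules with eigenprotein correlation above the cut merge; below, they persist", {
  set.seed(13)
  n <- 47
  zz <- rnorm(n)
  z1 <- zz + rnorm(n, 0, 0.15); z2 <- zz + rnorm(n, 0, 0.15)
  X <- rbind(t(sapply(1:25, function(i) z1 + rnorm(n, 0, 0.4))),
             t(sapply(1:25, function(i) z2 + rnorm(n, 0, 0.4))))
  rownames(X) <- sprintf("G%03d", 1:50)
  labels <- setNames(rep(c("M1", "M2"), each = 25), rownames(X))
  ek <- eigenproteins_kme(X, labels)
  expect_gt(cor(ek$eigenproteins[1, ], ek$eigenproteins[2, ]), 0.93)
  merged <- merge_close_modules(X, labels, 0.07)
  expect_equal(length(setdiff(unique(merged), "grey")), 1L)
  # independent drivers stay separate
  z3 <- rnorm(n)
  X2 <- rbind(t(sapply(1:25, function(i) zz + rnorm(n, 0, 0.4))),
              t(sapply(1:25, function(i) z3 + rnorm(n, 0, 0.4))))
  rownames(X2) <- rownames(X)
  kept <- merge_close_modules(X2, labels, 0.07)
  expect_equal(length(setdiff(unique(kept), "grey")), 2L)
})

test_that("eigenproteins are unit-variance first PCs oriented with their members", {
  set.seed(15)
  n <- 47
  # degenerate module: identical features
  prof <- rnorm(n)
  X <- rbind(a = prof, b = prof, c = prof, d = rnorm(n))
  labels <- setNames(c("M1", "M1", "M1", "grey"), rownames(X))
  ek <- eigenproteins_kme(X, labels)
  expect_equal(unname(ek$eigenproteins["M1", ]),
               as.numeric(scale(prof)), tolerance = 1e-9)
  expect_equal(unname(ek$kme[c("a", "b", "c"), "M1"]), rep(1, 3),
               tolerance = 1e-9)
  expect_equal(unname(ek$var_explained["M1"]), 1)
  # uncorrelated feature has small kME
  expect_lt(abs(ek$kme["d", "M1"]), 0.3)
  expect_equal(sd(ek$eigenproteins["M1", ]), 1)
  # eigenprotein explains at least as much member variance as any member
  pb <- planted_blocks(sizes = c(30), seed = 16)
  lab2 <- setNames(rep("M1", 30), rownames(pb$x))
  ek2 <- eigenproteins_kme(pb$x, lab2)
  z <- t(scale(t(pb$x)))
  ep_var <- mean(cor(t(z), ek2$eigenproteins["M1", ])^2)
  best_member <- max(sapply(1:30, function(i)
    mean(cor(t(z), z[i, ])^2, na.rm = TRUE)))
  expect_gte(ep_var + 1e-9, best_member)
})

test_that("missing values are tolerated in eigenprotein computation", {
  pb <- planted_blocks(sizes = c(25, 25), seed = 17)
  X <- pb$x
  X[sample(length(X), round(0.1 * length(X)))] <- NA
  labels <- setNames(rep(c("M1", "M2"), each = 25), rownames(X))
  ek <- eigenproteins_kme(X, labels)
  expect_false(anyNA(ek$eigenproteins))
  expect_gt(mean(ek$kme[1:25, "M1"], na.rm = TRUE), 0.5)
})

test_that("module-trait correlations use the declared estimators", {
  set.seed(19)
  n <- 47
  E <- rbind(M1 = rnorm(n), M2 = rnorm(n))
  colnames(E) <- sprintf("S%02d", 1:n)
  traits <- data.frame(sample_id = colnames(E),
                       CERAD = E["M1", ],        # identical to M1
                       MMSE = round(15 + 7 * E["M2", ]),
                       flat = 1)
  mt <- module_trait_correlation(E, traits)
  r11 <- mt[mt$module == "M1" & mt$trait == "CERAD", ]
  expect_equal(r11$rho, 1, tolerance = 1e-9)
  expect_lt(r11$p, 1e-10)
  expect_equal(r11$method, "bicor")
  expect_equal(mt[mt$module == "M2" & mt$trait == "MMSE", "method"],
               "spearman")
  expect_true(is.na(mt[mt$module == "M1" & mt$trait == "flat", "rho"]))
  # monotone nonlinear relation: Spearman beats bicor
  y <- exp(3 * E["M2", ])
  sp <- suppressWarnings(cor.test(E["M2", ], y, method = "spearman"))
  expect_gt(abs(sp$estimate), abs(bicor(E["M2", ], y)))
})

test_that("eigenprotein-trait p-values are calibrated under the null", {
  set.seed(23)
  n <- 47
  hits <- replicate(300, {
    e <- rnorm(n)
    tr <- rnorm(n)
    cor_p <- function(r) 2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2)
    cor_p(bicor(e, tr)) < 0.05
  })
  expect_lt(abs(mean(hits) - 0.05), 0.035)
})
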