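# Differential abundance (ANOVA + Tukey), enrichment statistics, and
# alt-EEjxn peptide module assignment.

#' One-way ANOVA with Tukey post hoc contrasts per feature
#'
#' For each feature, fits a one-way ANOVA of abundance on group over the
#' available cases and computes Tukey HSD pairwise contrasts (Tukey-Kramer
#' for unequal group sizes) via \code{stats::aov} / \code{stats::TukeyHSD}.
#' Features with fewer than 2 groups having at least `min_per_group`
#' non-missing observations are dropped and reported. A feature with zero
#' within-group variance and equal group means gets p = 1 by convention.
#'
#' @param values Feature-by-sample matrix.
#' @param groups Group label per sample column (coerced to factor; factor
#'   level order defines contrast direction).
#' @param min_per_group Minimum non-missing observations per group for the
#'   group to enter the model.
#' @return Data frame with one row per tested feature: `F`, `p`, per-group
#'   n, and per-pair mean difference (`diff_<A.B>` = mean(A) - mean(B)) and
#'   Tukey-adjusted p (`p_<A.B>`). Dropped features via
#'   \code{\link{filter_log}}.
#' @export
anova_tukey <- function(values, groups, min_per_group = 2L) {
  g_all <- factor(groups)
  lev <- levels(g_all)
  pairs <- utils::combn(lev, 2L)
  pair_id <- paste(pairs[2L, ], pairs[1L, ], sep = "-")   # TukeyHSD order
  pair_col <- gsub("-", ".", pair_id)
  res <- vector("list", nrow(values))
  dropped <- character(0)
  for (f in seq_len(nrow(values))) {
    y <- values[f, ]
    ok <- !is.na(y)
    cnt <- table(g_all[ok])
    use_lev <- names(cnt)[cnt >= min_per_group]
    if (length(use_lev) < 2L) {
      dropped <- c(dropped, rownames(values)[f])
      next
    }
    keep <- ok & g_all %in% use_lev
    d <- data.frame(y = y[keep], g = droplevels(g_all[keep]))
    if (stats::var(d$y) < .Machine$double.eps * max(1, mean(d$y)^2)) {
      # constant feature: zero within-group variance with equal means
      Fv <- 0; pv <- 1
      fit <- NULL
    } else {
      fit <- stats::aov(y ~ g, data = d)
      an <- suppressWarnings(stats::anova(fit))
      Fv <- an$`F value`[1]
      pv <- an$`Pr(>F)`[1]
      if (!is.finite(Fv)) { Fv <- 0; pv <- 1 }
    }
    row <- list(feature = rownames(values)[f], F = Fv, p = pv)
    for (l in lev) row[[paste0("n_", l)]] <-
      as.integer(if (l %in% names(cnt)) cnt[[l]] else 0L)
    tk <- if (is.null(fit)) NULL else
      tryCatch(suppressWarnings(stats::TukeyHSD(fit)$g),
               error = function(e) NULL)
    for (k in seq_along(pair_id)) {
      pid <- pair_id[k]
      if (!is.null(tk) && pid %in% rownames(tk)) {
        row[[paste0("diff_", pair_col[k])]] <- tk[pid, "diff"]
        row[[paste0("p_", pair_col[k])]] <- tk[pid, "p adj"]
      } else {
        row[[paste0("diff_", pair_col[k])]] <- NA_real_
        row[[paste0("p_", pair_col[k])]] <- NA_real_
      }
    }
    res[[f]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  with_filter_log(out, nrow(values), nrow(out),
                  c(insufficient_groups = length(dropped)))
}

# hypergeometric tail probabilities for a 2x2 overlap table
hyper_one_tail <- function(a, q_size, t_size, n_bg) {
  stats::phyper(a - 1L, t_size, n_bg - t_size, q_size, lower.tail = FALSE)
}

hyper_two_tail <- function(a, q_size, t_size, n_bg) {
  kk <- max(0L, q_size + t_size - n_bg):min(q_size, t_size)
  dk <- stats::dhyper(kk, t_size, n_bg - t_size, q_size)
  sum(dk[dk <= stats::dhyper(a, t_size, n_bg - t_size, q_size) *
           (1 + 1e-7)])
}

#' Fisher-exact / hypergeometric set enrichment
#'
#' Tests whether `query` and `target` overlap more than expected among
#' `background`. One-tailed is the hypergeometric upper tail
#' (over-representation); two-tailed sums all hypergeometric outcomes no
#' more probable than the observed one. When `query` is a list, one test
#' per element is run and Benjamini-Hochberg correction is applied across
#' that family.
#'
#' @param query Character vector of ids, or a named list of them.
#' @param target Character vector of target-set ids.
#' @param background Character vector: the test universe (query and target
#'   are intersected with it).
#' @param tail `"one"` or `"two"`.
#' @return Data frame per test: 2x2 counts (`overlap`, `query_only`,
#'   `target_only`, `neither`), `odds_ratio`, `p`, `p_adj`, `tail`.
#' @export
fisher_enrichment <- function(query, target, background,
                              tail = c("one", "two")) {
  tail <- match.arg(tail)
  if (!length(background)) stop_input("empty background")
  background <- unique(background)
  n_bg <- length(background)
  target <- intersect(target, background)
  qlist <- if (is.list(query)) query else list(set = query)
  if (is.null(names(qlist)))
    names(qlist) <- paste0("set", seq_along(qlist))
  rows <- lapply(names(qlist), function(nm) {
    q <- intersect(qlist[[nm]], background)
    a <- length(intersect(q, target))
    b <- length(q) - a
    cc <- length(target) - a
    d <- n_bg - a - b - cc
    p <- if (tail == "one") hyper_one_tail(a, length(q), length(target), n_bg)
         else hyper_two_tail(a, length(q), length(target), n_bg)
    orat <- (a * d) / (b * cc)
    data.frame(set = nm, overlap = a, query_only = b, target_only = cc,
               neither = d, odds_ratio = orat, p = p, tail = tail,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Quantifiability filter for peptides
#'
#' A peptide is quantifiable when at least `min_groups` case groups each
#' contain at least `min_per_group` non-missing measurements.
#'
#' @param values Feature-by-sample matrix.
#' @param groups Group label per sample column.
#' @param min_per_group,min_groups Thresholds (defaults 2 and 2).
#' @return Character vector of retained feature ids; counts via
#'   \code{\link{filter_log}}.
#' @export
quantifiable_filter <- function(values, groups, min_per_group = 2L,
                                min_groups = 2L) {
  g <- factor(groups)
  ok <- apply(values, 1L, function(y) {
    cnt <- table(g[!is.na(y)])
    sum(cnt >= min_per_group) >= min_groups
  })
  out <- rownames(values)[ok]
  with_filter_log(out, nrow(values), length(out),
                  c(unquantifiable = sum(!ok)))
}

#' Assign peptides to network modules by kME
#'
#' Each eligible peptide is correlated (bicor) with every module
#' eigenprotein and assigned to the module with the highest correlation.
#' Peptides with more than `max_missing` missing values (or with too few
#' observations for a correlation) are left unassigned to avoid spurious
#' correlations.
#'
#' @param values Peptide-by-sample matrix (aligned to eigenprotein
#'   columns).
#' @param eigenproteins Module-by-sample matrix from
#'   \code{\link{eigenproteins_kme}}.
#' @param max_missing Maximum missing values per peptide (default 25 of
#'   47).
#' @return Data frame: `feature`, `module` (NA when unassigned), `kme`
#'   (correlation with the assigned module), plus the full kME matrix in
#'   attribute `"kme"`.
#' @export
assign_peptides_to_modules <- function(values, eigenproteins,
                                       max_missing = 25L) {
  mods <- rownames(eigenproteins)
  kme <- matrix(NA_real_, nrow(values), length(mods),
                dimnames = list(rownames(values), mods))
  module <- rep(NA_character_, nrow(values))
  best <- rep(NA_real_, nrow(values))
  for (i in seq_len(nrow(values))) {
    y <- values[i, ]
    if (sum(is.na(y)) > max_missing) next
    kme[i, ] <- vapply(mods, function(m) bicor(y, eigenproteins[m, ]),
                       numeric(1))
    if (all(is.na(kme[i, ]))) next
    j <- which.max(kme[i, ])
    module[i] <- mods[j]
    best[i] <- kme[i, j]
  }
  out <- data.frame(feature = rownames(values), module = module,
                    kme = best, stringsAsFactors = FALSE)
  attr(out, "kme") <- kme
  out
}

#' Module enrichment for alt-EEjxn peptides
#'
#' Tests, per module, whether the module contains more assigned alt-EEjxn
#' peptides than expected given the module's share of the background
#' (module-labeled proteins plus assigned peptides), by one-tailed Fisher
#' exact test with BH correction across modules.
#'
#' @param assignments Data frame from
#'   \code{\link{assign_peptides_to_modules}} (unassigned rows ignored).
#' @param protein_labels Named module assignment of the network proteins
#'   (from \code{\link{detect_modules}}; grey excluded from module sets).
#' @return \code{\link{fisher_enrichment}} result with one row per module.
#' @export
module_alt_eejxn_enrichment <- function(assignments, protein_labels) {
  asg <- assignments[!is.na(assignments$module), , drop = FALSE]
  prot <- names(protein_labels)
  background <- c(prot, asg$feature)
  mods <- sort(unique(c(asg$module,
                        setdiff(unique(protein_labels), "grey"))))
  tests <- lapply(stats::setNames(mods, mods), function(m)
    c(prot[protein_labels == m], asg$feature[asg$module == m]))
  fisher_enrichment(tests, target = asg$feature,
                    background = background, tail = "one")
}

#' Cross-network module overlap
#'
#' Compares two module labelings over a shared feature universe:
#' hypergeometric overlap p-value per module pair on the intersection
#' universe, BH-corrected across all pairs, with each module's best match
#' in the other network reported.
#'
#' @param labels_a,labels_b Named module assignments.
#' @return List: `pairs` (module_a, module_b, overlap, p, p_adj),
#'   `best_a`, `best_b` (per-module best match by smallest p).
#' @export
compare_networks <- function(labels_a, labels_b) {
  universe <- intersect(names(labels_a), names(labels_b))
  if (!length(universe)) stop_input("disjoint feature universes")
  la <- labels_a[universe]; lb <- labels_b[universe]
  mods_a <- setdiff(unique(la), "grey")
  mods_b <- setdiff(unique(lb), "grey")
  n_bg <- length(universe)
  rows <- list()
  for (ma in mods_a) for (mb in mods_b) {
    qa <- universe[la == ma]; tb <- universe[lb == mb]
    a <- length(intersect(qa, tb))
    rows[[length(rows) + 1L]] <- data.frame(
      module_a = ma, module_b = mb, size_a = length(qa),
      size_b = length(tb), overlap = a,
      p = hyper_one_tail(a, length(qa), length(tb), n_bg),
      stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  pairs$p_adj <- stats::p.adjust(pairs$p, method = "BH")
  best <- function(tab, key) {
    do.call(rbind, lapply(split(tab, tab[[key]]), function(t)
      t[which.min(t$p), , drop = FALSE]))
  }
  list(pairs = pairs, best_a = best(pairs, "module_a"),
       best_b = best(pairs, "module_b"))
}
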