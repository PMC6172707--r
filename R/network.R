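# Signed weighted correlation network: soft-threshold selection, topological
# overlap, module detection, eigenproteins, kME, module-trait correlations.

#' Network construction parameters
#'
#' Defaults are the settings this pipeline uses for protein abundance
#' networks: signed adjacency at power 8 chosen as the lowest power
#' reaching scale-free fit R^2 ~ 0.80 in steps of 0.5, biweight
#' midcorrelation, topological overlap with the mean-connectivity
#' denominator, minimum module size 17, module merge at eigenprotein
#' correlation distance 0.07, deep split 2 with a PAM-style kME
#' reassignment stage.
#'
#' @param beta Soft-threshold power.
#' @param beta_step Increment of the candidate power grid.
#' @param target_r2 Scale-free topology fit target.
#' @param signed Use the signed adjacency `((1 + r)/2)^beta`.
#' @param tom_denominator `"mean"` or `"min"` connectivity denominator.
#' @param min_module_size Smallest retained module.
#' @param merge_cut_height Merge modules whose eigenproteins correlate
#'   above `1 - merge_cut_height`.
#' @param deep_split Integer 0-4 controlling the initial tree cut height.
#' @param pam_stage Run the kME-based reassignment stage.
#' @param pam_kme_min Minimum kME at which the PAM stage attaches a grey
#'   (unassigned) feature to a module.
#' @param n_bins Connectivity bins for the scale-free fit.
#' @return A `network_params` list.
#' @export
network_params <- function(beta = 8, beta_step = 0.5, target_r2 = 0.80,
                           signed = TRUE,
                           tom_denominator = c("mean", "min"),
                           min_module_size = 17L, merge_cut_height = 0.07,
                           deep_split = 2L, pam_stage = TRUE,
                           pam_kme_min = 0.3, n_bins = 10L) {
  tom_denominator <- match.arg(tom_denominator)
  assert_scalar_number(beta, "beta", lower = 1e-9)
  assert_scalar_number(target_r2, "target_r2", lower = 1e-9, upper = 1)
  structure(list(beta = beta, beta_step = beta_step, target_r2 = target_r2,
                 signed = isTRUE(signed), tom_denominator = tom_denominator,
                 min_module_size = as.integer(min_module_size),
                 merge_cut_height = merge_cut_height,
                 deep_split = as.integer(deep_split),
                 pam_stage = isTRUE(pam_stage),
                 pam_kme_min = pam_kme_min,
                 n_bins = as.integer(n_bins)),
            class = "network_params")
}

# scale-free topology fit: regression of log10 p(k) on log10 k over
# log-spaced connectivity bins; signed so that a positive value requires a
# negative (power-law) slope
scale_free_fit <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  if (length(unique(k)) < 3L) return(NA_real_)
  br <- 10^seq(log10(min(k)), log10(max(k)), length.out = n_bins + 1L)
  br[1] <- br[1] * (1 - 1e-9); br[length(br)] <- br[length(br)] * (1 + 1e-9)
  bin <- cut(k, br, include.lowest = TRUE)
  pk <- tapply(k, bin, length) / length(k)
  kbar <- tapply(k, bin, mean)
  keep <- !is.na(pk) & pk > 0
  if (sum(keep) < 3L) return(NA_real_)
  fit <- stats::lm(log10(pk[keep]) ~ log10(kbar[keep]))
  r2 <- summary(fit)$r.squared
  -sign(stats::coef(fit)[2]) * r2
}

#' Select the soft-threshold power for a signed network
#'
#' Candidate powers are scanned in `beta_step` increments; for each, the
#' signed adjacency and its connectivity distribution are computed and the
#' scale-free model fit R^2 (signed convention: a positive fit requires a
#' negative slope of log10 p(k) vs log10 k) is evaluated. The lowest power
#' reaching `target_r2` is returned; if none reaches it, the power at the
#' fit plateau (first step improving by less than 0.01) is returned with a
#' message.
#'
#' @param values Feature-by-sample matrix.
#' @param params \code{\link{network_params}}.
#' @param powers Candidate powers (default `seq(2, 20, params$beta_step)`).
#' @return Selected power, with the per-power fit table in attribute
#'   `"fit_table"`.
#' @export
pick_beta <- function(values, params = network_params(), powers = NULL) {
  if (is.null(powers)) powers <- seq(2, 20, by = params$beta_step)
  if (length(powers) < 2L) stop_config("need at least 2 candidate powers")
  sds <- apply(values, 1L, stats::sd, na.rm = TRUE)
  if (any(is.na(sds) | sds == 0))
    stop_input("constant feature(s): ",
               rownames(values)[which(is.na(sds) | sds == 0)[1]])
  R <- bicor_all(values)
  R[is.na(R)] <- 0
  fits <- vapply(powers, function(b) {
    A <- if (params$signed) ((1 + R) / 2)^b else abs(R)^b
    diag(A) <- 0
    scale_free_fit(rowSums(A), params$n_bins)
  }, numeric(1))
  tab <- data.frame(power = powers, fit = fits)
  hit <- which(!is.na(fits) & fits >= params$target_r2)
  if (length(hit)) {
    beta <- powers[hit[1]]
  } else {
    gain <- diff(fits)
    pl <- which(!is.na(gain) & gain < 0.01)
    beta <- if (length(pl)) powers[pl[1] + 1L] else
      powers[which.max(fits)]
    message("no power reached target R^2 = ", params$target_r2,
            "; returning plateau power ", beta)
  }
  attr(beta, "fit_table") <- tab
  beta
}

#' Signed adjacency and topological overlap
#'
#' Adjacency `a_ij = ((1 + bicor_ij)/2)^beta` (signed convention; a pair
#' with bicor -1 gets adjacency 0), self-adjacency excluded. Topological
#' overlap with the mean denominator:
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (mean(k_i, k_j) + 1 - a_ij)` with
#' `k_i = sum_{u != i} a_iu`; `"min"` substitutes `min(k_i, k_j)`.
#'
#' @param values Feature-by-sample matrix.
#' @param params \code{\link{network_params}} (uses `beta`, `signed`,
#'   `tom_denominator`).
#' @param cor_mat Optional precomputed correlation matrix (skips bicor).
#' @return List: `adjacency`, `tom` (both feature x feature, `tom` with
#'   unit diagonal), `beta`.
#' @export
adjacency_tom <- function(values = NULL, params = network_params(),
                          cor_mat = NULL) {
  R <- cor_mat %||% bicor_all(values)
  R[is.na(R)] <- 0
  A <- if (params$signed) ((1 + R) / 2)^params$beta else abs(R)^params$beta
  diag(A) <- 0
  k <- rowSums(A)
  L <- A %*% A
  den <- if (params$tom_denominator == "mean")
    outer(k, k, pmean) else outer(k, k, pmin)
  tom <- (L + A) / (den + 1 - A)
  tom[tom > 1] <- 1
  diag(tom) <- 1
  dimnames(tom) <- dimnames(A)
  list(adjacency = A, tom = tom, beta = params$beta)
}

#' Detect coexpression modules from a topological overlap matrix
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, cut at a
#' `deep_split`-controlled height; clusters below `min_module_size` are
#' dissolved to grey; an optional PAM-like stage reassigns each feature to
#' the module of its highest kME when that exceeds the kME to its current
#' module; finally, modules whose eigenproteins correlate closer than
#' `merge_cut_height` (1 - correlation < cut) are merged. Labels are
#' ordered by size (`M1` largest, ties broken by first feature id); grey
#' collects unassigned features. Features are internally sorted by id
#' before clustering so labels do not depend on input order.
#'
#' @param values Feature-by-sample matrix (used for eigenproteins in the
#'   PAM and merge stages).
#' @param tom Topological overlap matrix from \code{\link{adjacency_tom}}.
#' @param params \code{\link{network_params}}.
#' @return Named character vector feature -> module label.
#' @export
detect_modules <- function(values, tom, params = network_params()) {
  feats <- rownames(values)
  if (length(feats) < params$min_module_size) {
    warning("fewer features than min_module_size; all grey")
    return(stats::setNames(rep("grey", length(feats)), feats))
  }
  ord <- order(feats)
  tom_o <- tom[ord, ord]
  x_o <- values[ord, , drop = FALSE]
  lab <- recursive_cut(tom_o, params)
  lab <- dissolve_small(lab, params$min_module_size)

  if (params$pam_stage && any(lab != 0L)) {
    ek <- eigenproteins_kme(x_o, label_vector(lab, rownames(x_o)))
    kme <- ek$kme
    mods <- colnames(kme)
    cur <- label_vector(lab, rownames(x_o))
    for (i in seq_along(cur)) {
      best <- mods[which.max(kme[i, ])]
      if (cur[i] == "grey") {
        if (kme[i, best] >= params$pam_kme_min) cur[i] <- best
      } else if (kme[i, best] > kme[i, cur[i]]) cur[i] <- best
    }
    lab <- match(cur, mods)
    lab[is.na(lab)] <- 0L
    lab <- dissolve_small(lab, params$min_module_size)
  }

  out <- merge_close_modules(x_o, label_vector(lab, rownames(x_o)),
                             params$merge_cut_height)
  out <- relabel_by_size(out)
  out[feats]
}

#' Merge modules with near-identical eigenproteins
#'
#' Iteratively merges the closest pair of modules while their eigenprotein
#' correlation distance `1 - cor` is below `merge_cut_height`.
#'
#' @param values Feature-by-sample matrix.
#' @param labels Named module assignment (grey allowed).
#' @param merge_cut_height Eigenprotein distance below which modules merge.
#' @return Updated label vector (labels of merged modules collapse into the
#'   first of the pair; call sites relabel by size).
#' @export
merge_close_modules <- function(values, labels, merge_cut_height = 0.07) {
  repeat {
    mods <- setdiff(unique(labels), "grey")
    if (length(mods) < 2L) break
    ek <- eigenproteins_kme(values, labels)
    E <- ek$eigenproteins
    C <- stats::cor(t(E))
    diag(C) <- -Inf
    mx <- which(C == max(C), arr.ind = TRUE)[1, ]
    if (1 - max(C) < merge_cut_height) {
      labels[labels == rownames(E)[mx[2]]] <- rownames(E)[mx[1]]
    } else break
  }
  labels
}

# static cut height: the midpoint of the largest gap between consecutive
# merge heights in the upper part of the height distribution. Cluster-level
# merges sit above a gap separating them from within-cluster joins; cutting
# inside the widest such gap separates the branches. deep_split widens the
# region searched (deeper splits may select a lower gap, giving finer
# clusters).
static_cut_height <- function(heights, deep_split = 2L) {
  h <- sort(heights)
  if (length(h) < 3L) return(max(h) * 0.99)
  frac <- c(0.75, 0.65, 0.50, 0.35, 0.25)[min(deep_split, 4L) + 1L]
  lo <- min(h) + frac * (max(h) - min(h))
  region <- h[h >= lo]
  if (length(region) < 2L) return(max(h) * 0.99)
  gaps <- diff(region)
  i <- which.max(gaps)
  (region[i] + region[i + 1L]) / 2
}

# recursive static cutting: cut the dendrogram inside the widest
# high-region gap, then re-apply to every resulting branch large enough to
# hold two modules. Branch joins sit at heterogeneous heights, so a single
# global cut under-splits; recursion separates each branch at its own
# scale, and the eigenprotein merge stage later re-joins over-splits.
recursive_cut <- function(tom, params) {
  min_size <- params$min_module_size
  n <- nrow(tom)
  lab <- integer(n)
  nxt <- 0L
  assign_cluster <- function(idx) {
    nxt <<- nxt + 1L
    lab[idx] <<- nxt
  }
  split_rec <- function(idx) {
    if (length(idx) < 2L * min_size) {
      assign_cluster(idx)
      return(invisible())
    }
    tree <- stats::hclust(stats::as.dist(1 - tom[idx, idx]),
                          method = "average")
    cut_h <- static_cut_height(tree$height, params$deep_split)
    cl <- stats::cutree(tree, h = cut_h)
    sizes <- table(cl)
    if (sum(sizes >= min_size) < 2L) {
      assign_cluster(idx)
      return(invisible())
    }
    for (c_id in names(sizes)) {
      sub <- idx[cl == as.integer(c_id)]
      if (length(sub) < min_size) lab[sub] <<- 0L else split_rec(sub)
    }
  }
  split_rec(seq_len(n))
  lab
}

# dissolve clusters smaller than min size to 0 (grey)
dissolve_small <- function(lab, min_size) {
  sz <- table(lab[lab != 0L])
  small <- as.integer(names(sz)[sz < min_size])
  lab[lab %in% small] <- 0L
  lab
}

# integer labels -> "M<i>"/"grey" named character vector
label_vector <- function(lab, feats) {
  mods <- sort(setdiff(unique(lab), 0L))
  out <- ifelse(lab == 0L, "grey",
                paste0("M", match(lab, mods)))
  stats::setNames(out, feats)
}

# order module names by decreasing size; ties by first member feature id
relabel_by_size <- function(labels) {
  mods <- setdiff(unique(labels), "grey")
  if (!length(mods)) return(labels)
  sz <- vapply(mods, function(m) sum(labels == m), integer(1))
  first <- vapply(mods, function(m) min(names(labels)[labels == m]),
                  character(1))
  ord <- mods[order(-sz, first)]
  map <- stats::setNames(paste0("M", seq_along(ord)), ord)
  out <- ifelse(labels == "grey", "grey", unname(map[labels]))
  stats::setNames(out, names(labels))
}

#' Module eigenproteins and kME
#'
#' The eigenprotein of a module is the first principal component of its
#' standardized member-by-sample submatrix (missing values are mean-imputed
#' for the decomposition only), scaled to unit variance and sign-oriented
#' so the mean member correlation is non-negative. kME(f, M) is the
#' biweight midcorrelation of feature f with module M's eigenprotein,
#' computed for all features and modules.
#'
#' @param values Feature-by-sample matrix.
#' @param labels Named module assignment from \code{\link{detect_modules}}.
#' @return List: `eigenproteins` (module x sample, unit variance), `kme`
#'   (feature x module), `var_explained` (per module, fraction of member
#'   variance captured).
#' @export
eigenproteins_kme <- function(values, labels) {
  mods <- setdiff(unique(labels), "grey")
  mods <- mods[order(as.integer(sub("^M", "", mods)))]
  if (!length(mods)) stop_input("no non-grey modules")
  E <- matrix(NA_real_, length(mods), ncol(values),
              dimnames = list(mods, colnames(values)))
  ve <- stats::setNames(numeric(length(mods)), mods)
  for (m in mods) {
    sub <- values[names(labels)[labels == m], , drop = FALSE]
    if (sum(colSums(!is.na(sub)) > 0L) < 2L)
      stop_input("module ", m, " has fewer than 2 usable samples")
    z <- t(scale(t(sub)))
    z[!is.finite(z)] <- 0          # mean-impute (0 after standardization)
    sv <- svd(z)
    ep <- sv$v[, 1]
    ep <- drop(scale(ep))
    memb_cor <- suppressWarnings(stats::cor(t(sub), ep,
                                            use = "pairwise.complete.obs"))
    if (mean(memb_cor, na.rm = TRUE) < 0) ep <- -ep
    E[m, ] <- ep
    ve[m] <- sv$d[1]^2 / sum(sv$d^2)
  }
  kme <- matrix(NA_real_, nrow(values), length(mods),
                dimnames = list(rownames(values), mods))
  for (i in seq_len(nrow(values)))
    for (m in seq_along(mods))
      kme[i, m] <- bicor(values[i, ], E[m, ])
  list(eigenproteins = E, kme = kme, var_explained = ve)
}

#' Module-trait correlations
#'
#' Correlates each module eigenprotein with each trait: Spearman for traits
#' listed in `spearman_traits` (cognitive scores such as MMSE, where only
#' monotonicity is meaningful), biweight midcorrelation with a t-based
#' p-value otherwise. Missing trait values are dropped pairwise; constant
#' traits give a missing result.
#'
#' @param eigenproteins Module-by-sample matrix.
#' @param traits Data frame with `sample_id` and numeric trait columns,
#'   aligned to the eigenprotein columns by `sample_id`.
#' @param spearman_traits Trait names correlated by Spearman.
#' @return Long data frame: module, trait, rho, p, n, method.
#' @export
module_trait_correlation <- function(eigenproteins, traits,
                                     spearman_traits = "MMSE") {
  tr <- traits[match(colnames(eigenproteins), traits$sample_id), ,
               drop = FALSE]
  tcols <- setdiff(names(tr), "sample_id")
  out <- list()
  for (m in rownames(eigenproteins)) {
    for (tc in tcols) {
      y <- tr[[tc]]
      x <- eigenproteins[m, ]
      ok <- !is.na(x) & !is.na(y)
      n <- sum(ok)
      if (n < 4L || length(unique(y[ok])) < 2L) {
        rho <- NA_real_; p <- NA_real_
        method <- "none"
      } else if (tc %in% spearman_traits) {
        ct <- suppressWarnings(
          stats::cor.test(x[ok], y[ok], method = "spearman"))
        rho <- unname(ct$estimate); p <- ct$p.value
        method <- "spearman"
      } else {
        rho <- bicor(x[ok], y[ok])
        p <- cor_pvalue(rho, n)
        method <- "bicor"
      }
      out[[length(out) + 1L]] <- data.frame(
        module = m, trait = tc, rho = rho, p = p, n = n,
        method = method, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
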