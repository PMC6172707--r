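# Synthetic multi-batch TMT cohorts with complete ground truth.

TMT10_CHANNELS <- c("126", "127N", "127C", "128N", "128C",
                    "129N", "129C", "130N", "130C", "131")

CELL_TYPES <- c("microglia", "astrocytes", "neurons", "oligodendroglia")

#' Describe a multi-batch TMT cohort design
#'
#' Defaults mirror the study design this pipeline targets: 8 batches of
#' 10-plex TMT, a pooled global internal standard (GIS) in channel 126 of
#' every batch, and 47 samples split control/AsymAD/AD 13/14/20.
#'
#' @param n_batches Number of TMT batches.
#' @param plex Channels per batch.
#' @param gis_channel Reporter channel carrying the GIS.
#' @param groups Named integer vector of samples per diagnosis group.
#' @param missing_rate Fraction of sample measurements set missing (MCAR).
#' @param batch_effect_sd SD (log2 units) of multiplicative feature-by-batch
#'   effects; these cancel exactly in sample/GIS ratios.
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(n_batches = 8L, plex = 10L, gis_channel = "126",
                          groups = c(CT = 13L, AsymAD = 14L, AD = 20L),
                          missing_rate = 0.05, batch_effect_sd = 0.2) {
  assert_scalar_number(n_batches, "n_batches", lower = 1)
  assert_scalar_number(plex, "plex", lower = 2)
  assert_scalar_number(missing_rate, "missing_rate", lower = 0, upper = 1)
  assert_scalar_number(batch_effect_sd, "batch_effect_sd", lower = 0)
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop_config("groups must be a named vector of counts")
  n_samples <- sum(groups)
  if (n_samples > n_batches * (plex - 1L))
    stop_config("design infeasible: ", n_samples, " samples exceed ",
                n_batches, " x ", plex - 1L, " sample channels")
  channels <- if (plex == 10L) TMT10_CHANNELS else
    as.character(seq(126L, length.out = plex))
  if (!gis_channel %in% channels)
    stop_config("gis_channel ", gis_channel, " not among plex channels")
  structure(list(n_batches = as.integer(n_batches), plex = as.integer(plex),
                 gis_channel = gis_channel, channels = channels,
                 groups = groups, n_samples = as.integer(n_samples),
                 missing_rate = missing_rate,
                 batch_effect_sd = batch_effect_sd),
            class = "cohort_design")
}

# reference profile: each marker strongly expressed in its own cell type
make_marker_reference <- function(n_per_type) {
  ids <- unlist(lapply(CELL_TYPES, function(ct)
    sprintf("MK_%s_%02d", substr(ct, 1, 5), seq_len(n_per_type))))
  ref <- matrix(stats::runif(length(ids) * 4L, 0, 5),
                nrow = length(ids), ncol = 4L,
                dimnames = list(ids, CELL_TYPES))
  for (i in seq_along(CELL_TYPES)) {
    rows <- (i - 1L) * n_per_type + seq_len(n_per_type)
    ref[rows, i] <- stats::runif(n_per_type, 80, 120)
  }
  ref
}

# per-sample cell-type weights (rows sum to 1) with AD-dependent composition
make_cell_weights <- function(groups_of_sample, concentration = 120) {
  base <- list(
    CT     = c(microglia = 0.06, astrocytes = 0.16, neurons = 0.48,
               oligodendroglia = 0.30),
    AsymAD = c(microglia = 0.07, astrocytes = 0.18, neurons = 0.42,
               oligodendroglia = 0.33),
    AD     = c(microglia = 0.11, astrocytes = 0.24, neurons = 0.35,
               oligodendroglia = 0.30))
  w <- t(vapply(groups_of_sample, function(g) {
    a <- base[[g]] %||% base[["CT"]]
    x <- stats::rgamma(4L, shape = a * concentration)
    x / sum(x)
  }, numeric(4L)))
  colnames(w) <- CELL_TYPES
  w
}

#' Generate a synthetic cell-type mixture for deconvolution
#'
#' Marker abundances are the linear-scale product of a cell-type reference
#' profile and per-sample weight vectors, plus optional multiplicative
#' log-normal noise, so that marker-based non-negative least-squares
#' recovery is well-posed.
#'
#' @param n_samples Number of samples.
#' @param n_markers_per_type Markers per cell type.
#' @param noise_sd SD of log2-scale noise on marker abundances.
#' @param seed Integer seed.
#' @param groups Optional group label per sample (drives composition).
#' @return List: `mix` (marker x sample linear abundances), `reference`
#'   (marker x 4), `weights` (sample x 4 truth, rows sum to 1).
#' @export
gen_celltype_mixture <- function(n_samples = 47L, n_markers_per_type = 10L,
                                 noise_sd = 0, seed = 1L, groups = NULL) {
  with_seed(seed, {
    if (is.null(groups)) groups <- rep("CT", n_samples)
    ref <- make_marker_reference(n_markers_per_type)
    w <- make_cell_weights(groups)
    rownames(w) <- sprintf("S%02d", seq_len(n_samples))
    mix <- ref %*% t(w)
    if (noise_sd > 0)
      mix <- mix * 2^matrix(stats::rnorm(length(mix), 0, noise_sd),
                            nrow = nrow(mix))
    colnames(mix) <- rownames(w)
    list(mix = mix, reference = ref, weights = w)
  })
}

#' Generate a synthetic multi-batch TMT cohort with ground truth
#'
#' Builds per-batch reporter-intensity matrices for a cohort with planted
#' diagnosis-group effects, covariate (age/sex/PMI) slopes, block-correlated
#' coexpression module structure, marker features carrying a cell-type
#' mixing signal, multiplicative feature-by-batch effects, missing values,
#' and optional PTM-split peptide rows whose intensities sum to the base
#' peptide signal. The GIS channel of every batch carries, per feature, the
#' cohort grand mean (times the batch effect), so sample/GIS ratios cancel
#' batch effects exactly.
#'
#' Intensities are log-normal on the linear scale; all planted effects are
#' additive in log2, matching the downstream log2-ratio analysis. Sex is
#' coded 0/1; age and PMI are uniform over plausible autopsy-cohort ranges.
#'
#' @param design A \code{\link{cohort_design}}.
#' @param seed Integer seed; fixed seed gives identical cohorts.
#' @param n_features Number of non-marker features.
#' @param n_modules,module_size Planted coexpression blocks (first
#'   `n_modules * module_size` features; the rest are unstructured "grey").
#' @param module_cor Target intra-module correlation (loading scale).
#' @param n_markers_per_type Cell-type marker features per cell type
#'   (appended after the `n_features` ordinary features).
#' @param de_frac,de_effect Fraction of features with a planted AD-vs-CT
#'   log2 effect, and the magnitude range it is drawn from (AsymAD gets
#'   half the AD effect).
#' @param cov_frac Fraction of features with planted covariate slopes.
#' @param age_slope_sd,sex_effect_sd,pmi_slope_sd SDs of planted slopes.
#' @param covariate_slopes Optional explicit data frame (feature, age, sex,
#'   pmi) overriding the random covariate plan.
#' @param group_effects Optional explicit data frame (feature, CT, AsymAD,
#'   AD) of planted log2 shifts overriding the random plan.
#' @param ptm_split_fraction Fraction of features emitted as 2-3 modified
#'   forms whose linear intensities sum to the base signal.
#' @param markers_complete Exempt marker features from random missingness
#'   (default TRUE): deconvolution marker panels are defined as features
#'   quantified in every sample, emulating the consistently observed
#'   high-abundance structural markers such panels select.
#' @param noise_sd SD (log2) of measurement noise.
#' @param age_range,pmi_range Uniform ranges for age (years) and PMI (hours).
#' @return A `tmt_cohort` list: `batches` (named list of feature-by-channel
#'   reporter matrices), `channel_map`, `samples`, `traits`, `ptm_map`,
#'   `truth` (planted centered log2 matrix, effect maps, module labels,
#'   cell weights, marker reference), `design`, `seed`.
#' @export
gen_tmt_cohort <- function(design = cohort_design(), seed = 1L,
                           n_features = 200L, n_modules = 5L,
                           module_size = 20L, module_cor = 1,
                           n_markers_per_type = 10L,
                           de_frac = 0.15, de_effect = c(0.5, 1.5),
                           cov_frac = 0.15, age_slope_sd = 0.02,
                           sex_effect_sd = 0.3, pmi_slope_sd = 0.03,
                           covariate_slopes = NULL, group_effects = NULL,
                           ptm_split_fraction = 0, markers_complete = TRUE,
                           noise_sd = 0.2,
                           age_range = c(70, 100), pmi_range = c(4, 20)) {
  if (!inherits(design, "cohort_design"))
    stop_config("design must come from cohort_design()")
  if (n_modules * module_size > n_features)
    stop_config("module plan exceeds n_features")
  with_seed(seed, {
    n <- design$n_samples
    sample_ids <- sprintf("S%02d", seq_len(n))
    group <- rep(names(design$groups), design$groups)
    age <- round(stats::runif(n, age_range[1], age_range[2]), 1)
    sex <- sample(0:1, n, replace = TRUE)
    pmi <- round(stats::runif(n, pmi_range[1], pmi_range[2]), 1)

    feat <- sprintf("P%04d", seq_len(n_features))
    ref <- make_marker_reference(n_markers_per_type)
    markers <- rownames(ref)
    all_feat <- c(feat, markers)

    # module structure on the leading ordinary features
    modules <- stats::setNames(rep("grey", length(all_feat)), all_feat)
    mod_of <- rep(sprintf("M%d", seq_len(n_modules)), each = module_size)
    modules[seq_along(mod_of)] <- mod_of

    # planted group effects (log2)
    ge <- matrix(0, length(all_feat), 3L,
                 dimnames = list(all_feat, c("CT", "AsymAD", "AD")))
    if (is.null(group_effects)) {
      de_idx <- sample(seq_len(n_features), round(de_frac * n_features))
      eff <- stats::runif(length(de_idx), de_effect[1], de_effect[2]) *
        sample(c(-1, 1), length(de_idx), replace = TRUE)
      ge[de_idx, "AD"] <- eff
      ge[de_idx, "AsymAD"] <- eff / 2
    } else {
      ge[group_effects$feature, c("CT", "AsymAD", "AD")] <-
        as.matrix(group_effects[, c("CT", "AsymAD", "AD")])
    }

    # planted covariate slopes
    cs <- matrix(0, length(all_feat), 3L,
                 dimnames = list(all_feat, c("age", "sex", "pmi")))
    if (is.null(covariate_slopes)) {
      cv_idx <- sample(seq_len(n_features), round(cov_frac * n_features))
      cs[cv_idx, "age"] <- stats::rnorm(length(cv_idx), 0, age_slope_sd)
      cs[cv_idx, "sex"] <- stats::rnorm(length(cv_idx), 0, sex_effect_sd)
      cs[cv_idx, "pmi"] <- stats::rnorm(length(cv_idx), 0, pmi_slope_sd)
    } else {
      cs[covariate_slopes$feature, c("age", "sex", "pmi")] <-
        as.matrix(covariate_slopes[, c("age", "sex", "pmi")])
    }

    # expected log2 intensity, ordinary features
    mu <- stats::rnorm(n_features, 14, 1.5)
    x <- matrix(mu, n_features, n, dimnames = list(feat, sample_ids))
    x <- x + ge[feat, group, drop = FALSE]
    x <- x + cs[feat, "age", drop = FALSE] %*% t(age) +
      cs[feat, "sex", drop = FALSE] %*% t(sex) +
      cs[feat, "pmi", drop = FALSE] %*% t(pmi)
    z <- matrix(stats::rnorm(n_modules * n), n_modules, n)
    loading <- stats::runif(length(mod_of), 0.7, 1.3) * module_cor
    for (i in seq_along(mod_of)) {
      m <- as.integer(sub("M", "", mod_of[i]))
      x[i, ] <- x[i, ] + loading[i] * z[m, ]
    }

    # marker features: linear mixture of reference and true weights
    w <- make_cell_weights(group)
    rownames(w) <- sample_ids
    marker_lin <- ref %*% t(w)
    xm <- log2(marker_lin)
    expected <- rbind(x, xm)

    gm <- rowMeans(expected)
    planted <- expected - gm
    noisy <- expected + matrix(stats::rnorm(length(expected), 0, noise_sd),
                               nrow = nrow(expected))

    # sample -> batch/channel assignment, balanced across groups
    ord <- unlist(lapply(split(seq_len(n), group), sample))
    batch_of <- integer(n)
    batch_of[ord] <- rep_len(seq_len(design$n_batches), n)
    s_channels <- setdiff(design$channels, design$gis_channel)
    channel_of <- character(n)
    for (b in seq_len(design$n_batches)) {
      idx <- which(batch_of == b)
      channel_of[idx] <- s_channels[seq_along(idx)]
    }

    # PTM form plan
    n_all <- length(all_feat)
    n_split <- round(ptm_split_fraction * n_all)
    split_idx <- if (n_split > 0) sort(sample(seq_len(n_all), n_split))
                 else integer(0)
    mods_pool <- c("ac", "deam", "ox", "tmt")
    ptm_rows <- lapply(seq_len(n_all), function(i) {
      if (i %in% split_idx) {
        k <- sample(2:3, 1L)
        p <- stats::runif(k); p <- p / sum(p)
        data.frame(row_id = paste0(all_feat[i], "|",
                                   c("", mods_pool)[seq_len(k)]),
                   base_id = all_feat[i],
                   mod = c("", mods_pool)[seq_len(k)],
                   prop = p, stringsAsFactors = FALSE)
      } else {
        data.frame(row_id = all_feat[i], base_id = all_feat[i],
                   mod = "", prop = 1, stringsAsFactors = FALSE)
      }
    })
    ptm_map <- do.call(rbind, ptm_rows)
    ptm_map$row_id <- ifelse(ptm_map$mod == "", ptm_map$base_id,
                             paste0(ptm_map$base_id, "|", ptm_map$mod))
    rownames(ptm_map) <- NULL

    # per-batch reporter matrices
    batches <- list()
    cmap <- list()
    for (b in seq_len(design$n_batches)) {
      idx <- which(batch_of == b)
      e_b <- stats::rnorm(n_all, 0, design$batch_effect_sd)
      lin_s <- 2^(noisy[, idx, drop = FALSE] + e_b)
      lin_g <- 2^(gm + e_b)
      miss <- matrix(stats::runif(length(lin_s)) < design$missing_rate,
                     nrow = n_all)
      if (markers_complete) miss[all_feat %in% markers, ] <- FALSE
      lin_s[miss] <- NA_real_
      base_mat <- cbind(lin_g, lin_s)
      colnames(base_mat) <- c(design$gis_channel, channel_of[idx])
      # expand to PTM form rows
      mat <- base_mat[ptm_map$base_id, , drop = FALSE] * ptm_map$prop
      rownames(mat) <- ptm_map$row_id
      bn <- sprintf("b%02d", b)
      batches[[bn]] <- mat
      cmap[[bn]] <- data.frame(
        batch = bn,
        channel = c(design$gis_channel, channel_of[idx]),
        sample_id = c("GIS", sample_ids[idx]), stringsAsFactors = FALSE)
    }

    samples <- data.frame(sample_id = sample_ids, group = group,
                          age = age, sex = sex, pmi = pmi,
                          batch = sprintf("b%02d", batch_of),
                          channel = channel_of, stringsAsFactors = FALSE)

    # traits tracking pathology and cognition
    gshift <- c(CT = 0, AsymAD = 1, AD = 1.6)[group]
    traits <- data.frame(
      sample_id = sample_ids,
      CERAD = pmin(3, pmax(0, round(gshift * 1.6 + stats::rnorm(n, 0, 0.5)))),
      Braak = pmin(6, pmax(0, round(1 + gshift * 2.4 + stats::rnorm(n, 0, 0.8)))),
      MMSE = pmin(30, pmax(0, round(29 - c(CT = 0, AsymAD = 1, AD = 14)[group] +
                                      stats::rnorm(n, 0, 2)))),
      abeta = round(gshift * 1.5 + stats::rnorm(n, 0, 0.5), 3),
      tau_pT231 = round(gshift * 1.2 + stats::rnorm(n, 0, 0.5), 3),
      stringsAsFactors = FALSE)

    truth <- structure(list(
      planted_log2 = planted,
      grand_mean_log2 = gm,
      true_group_effects = ge,
      true_covariate_effects = cs,
      true_modules = modules,
      true_cell_weights = w,
      marker_reference = ref,
      marker_ids = markers,
      ptm_proportions = ptm_map,
      seed = seed), class = "truth_bundle")

    structure(list(batches = batches,
                   channel_map = do.call(rbind, cmap),
                   samples = samples, traits = traits,
                   ptm_map = ptm_map[, c("row_id", "base_id", "mod")],
                   truth = truth, design = design, seed = seed),
              class = "tmt_cohort")
  })
}
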