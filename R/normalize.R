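# Reporter-ratio normalization: GIS ratios, outlier exclusion, missingness
# filters, PTM-form summation, cross-batch GIS scaling.

#' Normalization parameters
#'
#' Defaults encode the filtering rules of the pipeline: log2 ratios at or
#' beyond +/- log2(100) (~6.64) are extreme outliers and excluded; features
#' with more than 4 of 8 batches lacking a usable GIS value are dropped;
#' per-feature missingness is capped at the largest integer strictly below
#' 50\% of the sample count (23 of 47); peptide-path values below 1 (which
#' would go negative in log2) are removed before transformation.
#'
#' @param outlier_bound Exclusion bound in log2 units. Stored at full
#'   precision `log2(100)`; the rounded 6.64 is accepted for compatibility.
#' @param max_bad_gis_batches Maximum batches with unusable GIS per feature.
#' @param max_missing_protein Maximum missing sample values per feature;
#'   `NULL` means `floor((n_samples - 1) / 2)` computed at filter time.
#' @param max_missing_peptide_kme Missingness cap used when assigning
#'   peptides to modules by kME.
#' @param drop_sub_one Drop linear values below 1 before log2 transform.
#' @return A `normalization_params` list.
#' @export
normalization_params <- function(outlier_bound = log2(100),
                                 max_bad_gis_batches = 4L,
                                 max_missing_protein = NULL,
                                 max_missing_peptide_kme = 25L,
                                 drop_sub_one = TRUE) {
  assert_scalar_number(outlier_bound, "outlier_bound", lower = 1e-12)
  structure(list(outlier_bound = outlier_bound,
                 max_bad_gis_batches = as.integer(max_bad_gis_batches),
                 max_missing_protein = if (is.null(max_missing_protein))
                   NULL else as.integer(max_missing_protein),
                 max_missing_peptide_kme = as.integer(max_missing_peptide_kme),
                 drop_sub_one = isTRUE(drop_sub_one)),
            class = "normalization_params")
}

#' Per-batch log2(sample/GIS) ratios
#'
#' @param batch Feature-by-channel reporter intensity matrix.
#' @param gis_channel Name of the GIS channel column.
#' @return Feature-by-channel matrix of log2(sample/GIS) with the GIS
#'   column removed; missing wherever either intensity is 0 or absent.
#' @export
ratio_to_gis <- function(batch, gis_channel = "126") {
  if (!gis_channel %in% colnames(batch))
    stop_input("GIS channel ", gis_channel, " absent from batch")
  g <- batch[, gis_channel]
  s <- batch[, setdiff(colnames(batch), gis_channel), drop = FALSE]
  bad_g <- is.na(g) | g <= 0
  out <- log2(sweep(s, 1, g, "/"))
  out[bad_g, ] <- NA_real_
  out[is.na(s) | s <= 0] <- NA_real_
  out
}

#' Exclude extreme log2 ratios
#'
#' Entries with |value| >= `outlier_bound` become missing.
#'
#' @param values Numeric matrix of log2 ratios.
#' @param params \code{\link{normalization_params}}.
#' @return The matrix with outliers set missing; count in
#'   \code{\link{filter_log}}.
#' @export
filter_outliers <- function(values, params = normalization_params()) {
  out <- abs(values) >= params$outlier_bound & !is.na(values)
  values[out] <- NA_real_
  with_filter_log(values, length(values), sum(!is.na(values)),
                  c(extreme_outliers = sum(out)))
}

#' Drop features failing GIS-batch or missingness rules
#'
#' A feature is dropped when more than `max_bad_gis_batches` batches lack a
#' usable GIS value for it, or when it has more than `max_missing_protein`
#' missing sample values.
#'
#' @param values Feature-by-sample log2 ratio matrix.
#' @param gis_ok Feature-by-batch logical matrix: GIS usable (positive,
#'   non-missing) for this feature in this batch. `NULL` skips the rule.
#' @param params \code{\link{normalization_params}}.
#' @return Filtered matrix with an exclusion report (feature, reason) in
#'   attribute `"exclusions"` and counts in \code{\link{filter_log}}.
#' @export
filter_features <- function(values, gis_ok = NULL,
                            params = normalization_params()) {
  max_missing <- params$max_missing_protein %||%
    ((ncol(values) - 1L) %/% 2L)
  rn <- rownames(values) %||% as.character(seq_len(nrow(values)))
  reason <- rep(NA_character_, nrow(values))
  if (!is.null(gis_ok)) {
    bad_gis <- rowSums(!gis_ok[rn, , drop = FALSE])
    reason[bad_gis > params$max_bad_gis_batches] <- "bad_gis_batches"
  }
  n_miss <- rowSums(is.na(values))
  reason[is.na(reason) & n_miss > max_missing] <- "too_many_missing"
  keep <- is.na(reason)
  out <- values[keep, , drop = FALSE]
  excl <- data.frame(feature = rn[!keep],
                     reason = reason[!keep], stringsAsFactors = FALSE)
  attr(out, "exclusions") <- excl
  with_filter_log(out, nrow(values), nrow(out),
                  c(table(excl$reason)))
}

# parse "base|mod" row ids into a ptm map; error on unknown modification
PTM_MODS <- c("ac", "deam", "ox", "tmt")

parse_ptm_rownames <- function(row_ids) {
  parts <- strsplit(row_ids, "|", fixed = TRUE)
  bad <- vapply(parts, function(p)
    length(p) > 2L || (length(p) == 2L && !(p[2] %in% PTM_MODS)), logical(1))
  if (any(bad))
    stop_input("unparseable modification string in row '",
               row_ids[bad][1], "'")
  data.frame(row_id = row_ids,
             base_id = vapply(parts, `[`, character(1), 1L),
             mod = vapply(parts, function(p)
               if (length(p) == 2L) p[2] else "", character(1)),
             stringsAsFactors = FALSE)
}

#' Sum post-translationally modified forms of one base peptide
#'
#' All rows sharing a base sequence (modifications stripped) are summed on
#' the linear scale into one row. A form that is missing in a sample is
#' treated as unobserved (available forms are summed); the result is
#' missing only when every form is missing.
#'
#' @param values Linear-scale feature-by-channel (or feature-by-sample)
#'   matrix whose rows are peptide forms.
#' @param ptm_map Data frame (`row_id`, `base_id`) mapping form rows to base
#'   peptides; `NULL` parses row names of the form `base|mod` with `mod`
#'   one of `ac`, `deam`, `ox`, `tmt`.
#' @return Base-peptide-by-column matrix of summed linear abundances.
#' @export
sum_ptm_forms <- function(values, ptm_map = NULL) {
  if (is.null(ptm_map)) ptm_map <- parse_ptm_rownames(rownames(values))
  base <- ptm_map$base_id[match(rownames(values), ptm_map$row_id)]
  if (anyNA(base))
    stop_input("row '", rownames(values)[is.na(base)][1],
               "' absent from ptm_map")
  grp <- factor(base, levels = unique(base))
  obs <- rowsum((!is.na(values)) * 1, grp, reorder = FALSE)
  v <- values; v[is.na(v)] <- 0
  out <- rowsum(v, grp, reorder = FALSE)
  out[obs == 0] <- NA_real_
  out
}

#' Scale linear abundances so batch GIS means agree
#'
#' Each batch is multiplied by (grand mean of the per-batch GIS means) /
#' (that batch's GIS mean), so that after scaling every batch has the same
#' mean GIS abundance. Within-batch ratios between samples are unchanged.
#'
#' @param batches Named list of linear feature-by-channel matrices.
#' @param gis_channel GIS channel name present in every batch.
#' @return List: `batches` (scaled), `factors`, `target`. Batches without a
#'   single usable GIS value are excluded with a warning and listed in
#'   `excluded`.
#' @export
scale_batches <- function(batches, gis_channel = "126") {
  gmeans <- vapply(batches, function(b) {
    if (!gis_channel %in% colnames(b))
      stop_input("GIS channel ", gis_channel, " absent from a batch")
    g <- b[, gis_channel]
    g <- g[!is.na(g) & g > 0]
    if (length(g)) mean(g) else NA_real_
  }, numeric(1))
  excluded <- names(batches)[is.na(gmeans)]
  if (length(excluded)) {
    warning("batch(es) without usable GIS excluded: ",
            paste(excluded, collapse = ", "))
    batches <- batches[!is.na(gmeans)]
    gmeans <- gmeans[!is.na(gmeans)]
  }
  if (!length(batches)) stop_input("no batch with a usable GIS value")
  target <- mean(gmeans)
  factors <- target / gmeans
  scaled <- Map(function(b, f) b * f, batches, factors)
  list(batches = scaled, factors = factors, target = target,
       excluded = excluded)
}

#' Log2-transform linear abundances, dropping sub-one values
#'
#' @param values Linear-scale matrix.
#' @param params \code{\link{normalization_params}}; when `drop_sub_one`,
#'   values below 1 are set missing before the transform (they would
#'   otherwise go negative in log2).
#' @return log2-transformed matrix; removed-value count in
#'   \code{\link{filter_log}}.
#' @export
log2_and_clean <- function(values, params = normalization_params()) {
  sub1 <- !is.na(values) & values < 1
  if (params$drop_sub_one) values[sub1] <- NA_real_
  out <- log2(values)
  with_filter_log(out, length(values), sum(!is.na(out)),
                  c(sub_one_removed = if (params$drop_sub_one) sum(sub1)
                    else 0L))
}

#' Protein-path normalization of a TMT cohort
#'
#' Runs per-batch log2(sample/GIS) ratio computation, extreme-outlier
#' exclusion, and the GIS-batch / missingness feature filters, returning a
#' cross-batch-comparable feature-by-sample abundance matrix.
#'
#' @param cohort A `tmt_cohort` from \code{\link{gen_tmt_cohort}} (or any
#'   list with `batches`, `channel_map`, `samples`, `design`).
#' @param params \code{\link{normalization_params}}.
#' @return List of class `abundance_matrix`: `values` (feature x sample
#'   log2 ratios), `samples` (metadata data frame), `provenance`
#'   (`"protein"`), `gis_ok`, and the per-stage filter logs in `log`.
#' @export
normalize_cohort <- function(cohort, params = normalization_params()) {
  gis <- cohort$design$gis_channel
  rats <- lapply(cohort$batches, ratio_to_gis, gis_channel = gis)
  cm <- cohort$channel_map[cohort$channel_map$sample_id != "GIS", ]
  cols <- list()
  for (bn in names(rats)) {
    m <- cm[cm$batch == bn, ]
    r <- rats[[bn]][, m$channel, drop = FALSE]
    colnames(r) <- m$sample_id
    cols[[bn]] <- r
  }
  feats <- rownames(cols[[1]])
  values <- do.call(cbind, lapply(cols, function(r) r[feats, , drop = FALSE]))
  values <- values[, cohort$samples$sample_id, drop = FALSE]
  values <- filter_outliers(values, params)
  log_out <- filter_log(values)
  gis_ok <- vapply(cohort$batches, function(b) {
    g <- b[feats, gis]
    !is.na(g) & g > 0
  }, logical(length(feats)))
  rownames(gis_ok) <- feats
  values <- filter_features(values, gis_ok, params)
  structure(list(values = unclass_attr(values),
                 samples = cohort$samples, provenance = "protein",
                 gis_ok = gis_ok,
                 log = list(outliers = log_out,
                            features = filter_log(values),
                            exclusions = attr(values, "exclusions"))),
            class = "abundance_matrix")
}

#' Peptide-path normalization of a TMT cohort
#'
#' Sums PTM forms per batch on the linear scale, scales batches so GIS
#' means agree, assembles the sample columns, removes sub-one values and
#' log2-transforms. This is the path used for alt-EEjxn peptide tables,
#' whose within-batch normalized abundances are compared across batches via
#' the GIS mean rather than per-measurement ratios.
#'
#' @inheritParams normalize_cohort
#' @return An `abundance_matrix` with provenance `"alt-EEjxn peptide"`.
#' @export
normalize_peptides <- function(cohort, params = normalization_params()) {
  gis <- cohort$design$gis_channel
  summed <- lapply(cohort$batches, sum_ptm_forms, ptm_map = cohort$ptm_map)
  sc <- scale_batches(summed, gis_channel = gis)
  cm <- cohort$channel_map[cohort$channel_map$sample_id != "GIS", ]
  cols <- list()
  for (bn in names(sc$batches)) {
    m <- cm[cm$batch == bn, ]
    r <- sc$batches[[bn]][, m$channel, drop = FALSE]
    colnames(r) <- m$sample_id
    cols[[bn]] <- r
  }
  feats <- rownames(cols[[1]])
  values <- do.call(cbind, lapply(cols, function(r) r[feats, , drop = FALSE]))
  values <- values[, intersect(cohort$samples$sample_id, colnames(values)),
                   drop = FALSE]
  values <- log2_and_clean(values, params)
  structure(list(values = unclass_attr(values),
                 samples = cohort$samples,
                 provenance = "alt-EEjxn peptide",
                 log = list(log2 = filter_log(values),
                            scale_factors = sc$factors)),
            class = "abundance_matrix")
}

# strip filter-log attributes so `values` is a plain matrix
unclass_attr <- function(x) {
  attr(x, "filter_log") <- NULL
  attr(x, "exclusions") <- NULL
  x
}
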