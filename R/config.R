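# Pipeline configuration, run manifests, and cohort serialization.

#' Default pipeline configuration
#'
#' A single nested document holding every stage's parameters at its
#' documented default (soft-threshold power 8, merge cut 0.07, minimum
#' module size 17, outlier bound log2(100) ~ 6.64, missingness caps 23 and
#' 25, junction support 2 reads at 4 nt overlap, 1000 bootstrap
#' iterations), overridable from a YAML file.
#'
#' @return Nested list of parameter groups.
#' @export
pipeline_defaults <- function() {
  list(seed = 1L,
       design = unclass(cohort_design()),
       junction = unclass(junction_params()),
       normalization = unclass(normalization_params()),
       network = unclass(network_params()),
       regression = unclass(regression_spec()))
}

#' Read a pipeline configuration
#'
#' Loads a YAML document and merges it over \code{\link{pipeline_defaults}}
#' (given keys override defaults; unknown keys are an error).
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Nested configuration list.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- pipeline_defaults()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop_input("config file not found: ", path)
  user <- yaml::read_yaml(path)
  for (k in names(user)) {
    if (!k %in% names(cfg))
      stop_config("unknown configuration key: ", k)
    if (is.list(user[[k]])) {
      bad <- setdiff(names(user[[k]]), names(cfg[[k]]))
      if (length(bad))
        stop_config("unknown configuration key: ", k, "$", bad[1])
      cfg[[k]][names(user[[k]])] <- user[[k]]
    } else cfg[[k]] <- user[[k]]
  }
  cfg
}

#' Write a run manifest
#'
#' Records the configuration, seed, package version, and any stage counts
#' so a run is reproducible from config + seed.
#'
#' @param path Output JSON path.
#' @param config Configuration list used.
#' @param seed Seed used.
#' @param counts Named list/vector of per-stage record counts.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed, counts = list()) {
  manifest <- list(
    package = "tmtsplice",
    version = as.character(utils::packageVersion("tmtsplice")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, counts = counts, config = config)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Write a synthetic cohort to a directory
#'
#' Emits one reporter TSV per batch (feature rows, channel columns), the
#' channel map, sample covariates and traits as TSV, and the truth bundle
#' as JSON.
#'
#' @param cohort A `tmt_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (bn in names(cohort$batches)) {
    b <- data.frame(feature = rownames(cohort$batches[[bn]]),
                    cohort$batches[[bn]], check.names = FALSE)
    utils::write.table(b, file.path(dir, paste0("reporter_", bn, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(cohort$channel_map, file.path(dir, "channel_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$traits, file.path(dir, "traits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  jsonlite::write_json(
    list(planted_log2 = as.data.frame(truth$planted_log2),
         grand_mean_log2 = as.list(truth$grand_mean_log2),
         true_group_effects = as.data.frame(truth$true_group_effects),
         true_covariate_effects = as.data.frame(truth$true_covariate_effects),
         true_modules = as.list(truth$true_modules),
         true_cell_weights = as.data.frame(truth$true_cell_weights),
         marker_reference = as.data.frame(truth$marker_reference),
         seed = truth$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
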