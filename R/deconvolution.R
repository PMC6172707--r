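# Marker-based cell-type deconvolution (digital-sorting style).

#' Collapse feature-level abundances to gene symbols
#'
#' Rows sharing a symbol are averaged per sample over non-missing values
#' (available-case mean); features without a symbol mapping are dropped and
#' reported.
#'
#' @param values Feature-by-sample matrix.
#' @param symbol_map Named character vector feature -> symbol (each feature
#'   maps to at most one symbol; unmapped features may be absent or NA).
#' @return Symbol-by-sample matrix; dropped features via
#'   \code{\link{filter_log}}.
#' @export
collapse_to_symbols <- function(values, symbol_map) {
  sym <- symbol_map[rownames(values)]
  keep <- !is.na(sym)
  v <- values[keep, , drop = FALSE]
  grp <- factor(sym[keep], levels = unique(sym[keep]))
  obs <- rowsum((!is.na(v)) * 1, grp, reorder = FALSE)
  vz <- v; vz[is.na(vz)] <- 0
  out <- rowsum(vz, grp, reorder = FALSE) / obs
  out[obs == 0] <- NA_real_
  with_filter_log(out, nrow(values), nrow(out),
                  c(unmapped = sum(!keep)))
}

#' Estimate per-sample cell-type weights from marker abundances
#'
#' Digital-sorting-style estimation: for each sample, the non-negative
#' least-squares solution of `mixture ~ reference %*% weights` on the
#' linear scale, followed by row normalization to sum 1. Markers with any
#' missing value across samples are excluded first (weights must not be
#' driven by imputation).
#'
#' @param mixture Marker-by-sample matrix of linear-scale abundances, on
#'   the same scale as `reference`.
#' @param reference Marker-by-cell-type matrix of mean abundances in pure
#'   cell populations (microglia, astrocytes, neurons, oligodendroglia).
#' @return Sample-by-cell-type matrix of non-negative weights, rows
#'   summing to 1. Attribute `"markers_used"` records the complete-case
#'   markers employed.
#' @export
estimate_cell_weights <- function(mixture, reference) {
  common <- intersect(rownames(mixture), rownames(reference))
  if (!length(common)) stop_input("no shared markers")
  complete <- common[rowSums(is.na(mixture[common, , drop = FALSE])) == 0L]
  if (!length(complete))
    stop_input("no complete-case markers available")
  R <- as.matrix(reference[complete, , drop = FALSE])
  if (any(colSums(R != 0, na.rm = TRUE) == 0L))
    stop_input("reference column with no signal: ",
               colnames(R)[colSums(R != 0) == 0L][1])
  # each cell type needs at least one complete marker where it dominates
  M <- as.matrix(mixture[complete, , drop = FALSE])
  w <- matrix(NA_real_, ncol(M), ncol(R),
              dimnames = list(colnames(M), colnames(R)))
  for (s in seq_len(ncol(M))) {
    fit <- pracma::lsqnonneg(R, M[, s])
    x <- fit$x
    if (sum(x) <= 0)
      stop_input("infeasible deconvolution for sample ", colnames(M)[s])
    w[s, ] <- x / sum(x)
  }
  attr(w, "markers_used") <- complete
  w
}
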