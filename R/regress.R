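# Bootstrap covariate regression: remove nuisance (age/sex/PMI, cell-type
# weight) components from each feature while retaining the diagnosis-group
# component and the residual. Group is always modeled, never subtracted.

#' Specify a bootstrap covariate regression
#'
#' @param remove Covariate names to model and subtract (columns of the
#'   covariate table, e.g. `c("age", "sex", "pmi")` or cell-type weight
#'   columns).
#' @param retain Name of the retained grouping factor (modeled, never
#'   subtracted).
#' @param n_boot Bootstrap iterations (ordinary nonparametric, cases
#'   resampled with replacement).
#' @param seed Integer seed for the resampling stream.
#' @param aggregation Aggregate bootstrap coefficient estimates by mean or
#'   median.
#' @return A `regression_spec` list.
#' @export
regression_spec <- function(remove = c("age", "sex", "pmi"),
                            retain = "group", n_boot = 1000L, seed = 1L,
                            aggregation = c("mean", "median")) {
  aggregation <- match.arg(aggregation)
  assert_scalar_number(n_boot, "n_boot", lower = 1)
  if (retain %in% remove)
    stop_config("retained term cannot also be removed")
  structure(list(remove = remove, retain = retain,
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 aggregation = aggregation), class = "regression_spec")
}

#' Bootstrap regression of nuisance covariates out of an abundance matrix
#'
#' Per feature, fits `value ~ removed covariates + group` by least squares
#' on the available cases, repeats the fit on `n_boot` case-resamples
#' (redrawing any rank-deficient resample), aggregates the coefficients,
#' and subtracts the removed-covariate components evaluated at covariates
#' centered over that feature's available cases — so each feature's mean is
#' preserved and the group component and residual are retained. Missing
#' values stay missing; features with fewer non-missing observations than
#' (model terms + 2) are left unregressed and flagged.
#'
#' @param values Feature-by-sample matrix (log2 abundances).
#' @param covariates Data frame with one row per sample (in column order of
#'   `values`) holding the removed covariates and the retained group
#'   factor.
#' @param spec A \code{\link{regression_spec}}.
#' @return List: `values` (regressed matrix), `coefficients` (feature x
#'   coefficient matrix of aggregated bootstrap estimates),
#'   `unregressed` (character vector of flagged features), `spec`.
#' @export
bootstrap_regress <- function(values, covariates, spec = regression_spec()) {
  if (nrow(covariates) != ncol(values))
    stop_input("covariates must have one row per sample column")
  if (anyNA(covariates[, c(spec$remove, spec$retain)]))
    stop_input("covariates must be complete for all samples")
  g <- covariates[[spec$retain]]
  if (!is.factor(g)) g <- factor(g, levels = unique(g))
  X_rm <- as.matrix(covariates[, spec$remove, drop = FALSE])
  storage.mode(X_rm) <- "double"
  G <- stats::model.matrix(~g)[, -1, drop = FALSE]
  X <- cbind(`(Intercept)` = 1, X_rm, G)
  p <- ncol(X)
  n_rm <- length(spec$remove)
  rm_idx <- 1L + seq_len(n_rm)
  agg <- if (spec$aggregation == "mean") colMeans else
    function(m) apply(m, 2L, stats::median)

  out <- values
  coefs <- matrix(NA_real_, nrow(values), p,
                  dimnames = list(rownames(values), colnames(X)))
  unregressed <- character(0)
  with_seed(spec$seed, {
    for (f in seq_len(nrow(values))) {
      y <- values[f, ]
      obs <- which(!is.na(y))
      if (length(obs) < p + 2L) {
        unregressed <- c(unregressed, rownames(values)[f])
        next
      }
      Xo <- X[obs, , drop = FALSE]
      yo <- y[obs]
      bmat <- matrix(NA_real_, spec$n_boot, p)
      b <- 1L
      tries <- 0L
      while (b <= spec$n_boot) {
        idx <- sample.int(length(obs), replace = TRUE)
        fit <- stats::.lm.fit(Xo[idx, , drop = FALSE], yo[idx])
        if (fit$rank < p) {        # degenerate resample: redraw
          tries <- tries + 1L
          if (tries > 50L * spec$n_boot)
            stop_input("persistent rank deficiency for feature ",
                       rownames(values)[f])
          next
        }
        bmat[b, ] <- fit$coefficients
        b <- b + 1L
      }
      beta <- agg(bmat)
      coefs[f, ] <- beta
      Xc <- sweep(X_rm[obs, , drop = FALSE], 2L,
                  colMeans(X_rm[obs, , drop = FALSE]))
      out[f, obs] <- yo - drop(Xc %*% beta[rm_idx])
    }
  })
  list(values = out, coefficients = coefs, unregressed = unregressed,
       spec = spec)
}

#' Two-pass regression: cell-type weights, then age/sex/PMI
#'
#' Pass 1 removes the cell-type weight components (the four weights sum to
#' one, so three of the four columns — the same column space once an
#' intercept is present — enter the model); pass 2 removes age, sex and
#' PMI from the pass-1 output. The diagnosis group is modeled and retained
#' in both passes. The fully adjusted matrix serves differential-abundance
#' analysis; the correlation network is built from the covariate-only
#' (\code{\link{bootstrap_regress}}) matrix instead.
#'
#' @param values Feature-by-sample matrix.
#' @param weights Sample-by-cell-type weight matrix from
#'   \code{\link{estimate_cell_weights}} (rows in sample column order).
#' @param covariates Data frame with age, sex, pmi and the group factor.
#' @param spec A \code{\link{regression_spec}}; its `remove` field is
#'   ignored (each pass sets its own), `n_boot`/`seed`/`aggregation` apply
#'   to both passes.
#' @return List: `values` (cell-type- and covariate-adjusted matrix),
#'   `pass1`, `pass2` (full results of each pass).
#' @export
two_pass_regress <- function(values, weights, covariates,
                             spec = regression_spec()) {
  if (nrow(weights) != ncol(values))
    stop_input("weights must have one row per sample column")
  wcols <- colnames(weights)[seq_len(ncol(weights) - 1L)]
  cov1 <- cbind(covariates, as.data.frame(weights))
  spec1 <- regression_spec(remove = wcols, retain = spec$retain,
                           n_boot = spec$n_boot, seed = spec$seed,
                           aggregation = spec$aggregation)
  p1 <- bootstrap_regress(values, cov1, spec1)
  spec2 <- regression_spec(remove = c("age", "sex", "pmi"),
                           retain = spec$retain, n_boot = spec$n_boot,
                           seed = spec$seed + 1L,
                           aggregation = spec$aggregation)
  p2 <- bootstrap_regress(p1$values, covariates, spec2)
  list(values = p2$values, pass1 = p1, pass2 = p2)
}
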