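# Biweight midcorrelation: the outlier-robust similarity measure of the
# coexpression network.

# robust transform of one vector: median-centered, Tukey biweight with the
# standard 9-MAD outlier cutoff; mean-centered (Pearson) when MAD is 0
bicor_transform <- function(x) {
  med <- stats::median(x)
  madx <- stats::median(abs(x - med))
  if (madx == 0) {
    a <- x - mean(x)
    attr(a, "pearson") <- TRUE
    return(a)
  }
  u <- (x - med) / (9 * madx)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  a <- (x - med) * w
  attr(a, "pearson") <- FALSE
  a
}

#' Biweight midcorrelation
#'
#' Robust correlation in [-1, 1] using Tukey biweights with the standard
#' 9-MAD outlier cutoff; observations further than 9 median absolute
#' deviations from the median get zero weight. A vector whose MAD is zero
#' falls back to Pearson (mean) centering for that vector. Computed on
#' pairwise-complete observations; fewer than `min_obs` complete pairs
#' gives `NA`.
#'
#' @param x,y Numeric vectors of equal length (missing values allowed).
#' @param min_obs Minimum paired non-missing observations (default 4).
#' @return The correlation, or `NA_real_`.
#' @export
bicor <- function(x, y, min_obs = 4L) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_obs) return(NA_real_)
  ax <- bicor_transform(x[ok])
  ay <- bicor_transform(y[ok])
  den <- sqrt(sum(ax^2)) * sqrt(sum(ay^2))
  if (den == 0) return(NA_real_)
  max(-1, min(1, sum(ax * ay) / den))
}

#' All-pairs biweight midcorrelation of a feature-by-sample matrix
#'
#' @param values Feature-by-sample matrix; correlations are computed
#'   between feature rows across samples. A complete matrix uses a
#'   vectorized path; matrices with missing values use pairwise-complete
#'   observations per pair.
#' @param min_obs Minimum paired observations per pair.
#' @return Feature-by-feature correlation matrix (unit diagonal). The
#'   number of vectors that used the Pearson (zero-MAD) fallback is in
#'   attribute `"n_pearson_fallback"`.
#' @export
bicor_all <- function(values, min_obs = 4L) {
  p <- nrow(values)
  if (!anyNA(values)) {
    A <- t(apply(values, 1L, bicor_transform))
    nf <- sum(apply(values, 1L, function(r)
      stats::median(abs(r - stats::median(r))) == 0))
    nrm <- sqrt(rowSums(A^2))
    if (any(nrm == 0))
      stop_input("constant feature row: ",
                 rownames(values)[which(nrm == 0)[1]])
    R <- tcrossprod(A / nrm)
    R[R > 1] <- 1; R[R < -1] <- -1
    diag(R) <- 1
    dimnames(R) <- list(rownames(values), rownames(values))
    attr(R, "n_pearson_fallback") <- nf
    return(R)
  }
  R <- matrix(NA_real_, p, p, dimnames = list(rownames(values),
                                              rownames(values)))
  diag(R) <- 1
  for (i in seq_len(p - 1L)) {
    xi <- values[i, ]
    for (j in seq(i + 1L, p)) {
      R[i, j] <- R[j, i] <- bicor(xi, values[j, ], min_obs)
    }
  }
  R
}

# two-sided p-value for a correlation via the t approximation
cor_pvalue <- function(r, n) {
  if (is.na(r) || n < 3L) return(NA_real_)
  r <- max(-1 + 1e-15, min(1 - 1e-15, r))
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), df = n - 2)
}
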