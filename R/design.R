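#' Precision-weighted fixed-effects combination of estimates
#'
#' Combines run-level effect estimates into a session-level estimate by
#' inverse-variance weighting: `beta = sum(b_i/v_i) / sum(1/v_i)` with
#' combined variance `1 / sum(1/v_i)`. With equal variances this is the
#' arithmetic mean; the combined variance is always strictly smaller than
#' the smallest input variance when two or more estimates are combined.
#'
#' @param betas numeric vector of effect estimates.
#' @param variances numeric vector of their (strictly positive) variances.
#' @return list with `beta` and `variance`.
#' @examples
#' fixed_effects_combine(c(2, 4), c(1, 3))  # beta 2.5, variance 0.75
#' @export
fixed_effects_combine <- function(betas, variances) {
  if (length(betas) != length(variances) || length(betas) < 1L) {
    stop("'betas' and 'variances' must have equal length >= 1", call. = FALSE)
  }
  if (any(!is.finite(variances)) || any(variances <= 0)) {
    stop("all variances must be finite and > 0", call. = FALSE)
  }
  w <- 1 / variances
  list(beta = sum(betas * w) / sum(w), variance = 1 / sum(w))
}

#' GLM contrast efficiency of a design matrix
#'
#' The design-dependent precision of a contrast `c` under a GLM with design
#' matrix `X`: `1 / (c (X'X)^{-1} c')`. Larger values mean the contrast is
#' estimated with smaller variance for unit noise. Scaling the design by a
#' factor `a` multiplies the efficiency by `a^2`.
#'
#' @param X numeric design matrix, observations in rows; must have full
#'   column rank.
#' @param contrast numeric contrast weights, one per column of `X`, not all
#'   zero.
#' @return positive scalar efficiency.
#' @export
contrast_efficiency <- function(X, contrast) {
  X <- as.matrix(X)
  contrast <- as.numeric(contrast)
  p <- ncol(X)
  if (length(contrast) != p) {
    stop("contrast length must equal the number of design columns", call. = FALSE)
  }
  if (all(contrast == 0)) stop("contrast must not be all zero", call. = FALSE)
  xtx <- crossprod(X)
  if (qr(xtx)$rank < p) {
    stop("singular design: X is rank-deficient", call. = FALSE)
  }
  as.numeric(1 / (contrast %*% solve(xtx, contrast)))
}

#' Convert a group-level t statistic to Cohen's d
#'
#' `d = t / sqrt(N)` for a one-sample group map from `N` subjects. Used to
#' place group maps from analyses with different numbers of included
#' subjects on a common effect-size scale before thresholding (a t of 3.2
#' at N = 64 corresponds to d = 0.40).
#'
#' @param t t statistic (sign preserved); may be a vector or 3D array.
#' @param n number of subjects, >= 1.
#' @return Cohen's d with the shape of `t`.
#' @export
t_to_cohens_d <- function(t, n) {
  if (length(n) != 1L || !is.finite(n) || n < 1) {
    stop("'n' must be a single integer >= 1", call. = FALSE)
  }
  t / sqrt(n)
}

#' Pearson product-moment correlation
#'
#' Thin wrapper over [stats::cor()] that enforces the preconditions used
#' throughout the package (paired vectors of length >= 3 with nonzero
#' variance) and returns `NA` with a warning for degenerate input instead
#' of erroring, so it can be applied over voxel collections.
#'
#' @param a,b numeric vectors of equal length >= 3.
#' @return correlation in `[-1, 1]`, or `NA` if either input is constant.
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3L) {
    stop("'a' and 'b' must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance input: correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b)
}
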