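#' Intraclass correlation of a subject-by-occasion measurement matrix
#'
#' Estimates the single-measure intraclass correlation coefficient of a
#' complete `n x k` design, together with F-based confidence bounds and the
#' variance components that compose it. Three estimators are available,
#' following the Shrout-Fleiss / McGraw-Wong taxonomy:
#'
#' * `icc_1` — one-way random model ICC(1): occasions are not separated from
#'   noise; uses the pooled within-subject mean square.
#' * `icc_2` — two-way random model ICC(2,1), absolute agreement: occasions
#'   are a random effect, so a systematic occasion shift (additive bias)
#'   lowers the estimate.
#' * `icc_3` — two-way mixed model ICC(3,1), consistency: occasions are
#'   fixed, so additive occasion bias is ignored. For `k = 2` this is
#'   `(MSBS - MSError) / (MSBS + MSError)`, equivalently
#'   \eqn{\sigma^2_r / (\sigma^2_r + \sigma^2_v)} with
#'   \eqn{\sigma^2_r = (MSBS - MSError)/k} the between-subject variance and
#'   \eqn{\sigma^2_v = MSError} the within-subject variance.
#'
#' Negative estimates are returned as-is (no truncation at zero): observed
#' reliabilities slightly below zero are informative and must survive
#' aggregation across voxels. A matrix with (numerically) zero total
#' variance carries no reliability information: the estimate and bounds are
#' `NA` and `degenerate` is `TRUE`, so that downstream voxel maps can
#' propagate the missingness rather than fabricate a 0 or 1.
#'
#' @param m a [measurement_matrix()] or numeric matrix (subjects x occasions).
#' @param icc_type one of `"icc_1"`, `"icc_2"`, `"icc_3"`.
#' @param alpha two-sided confidence level is `1 - alpha`; default `0.05`.
#' @return object of class `icc_estimate`: list with `icc_type`, `estimate`,
#'   `lower`, `upper`, `alpha`, `components` (a list with `sigma2_between`,
#'   `sigma2_within` and, for `icc_2`, `sigma2_measure`), logical flags
#'   `degenerate` and `perfect`, and the underlying `anova` table.
#' @examples
#' # correlation can be perfect while consistency is not:
#' m <- cbind(A = c(1, 3, 6, 9, 12), B = 3 * c(1, 3, 6, 9, 12))
#' icc(m, "icc_3")   # 0.60
#' stats::cor(m)[1, 2]      # 1.0
#' @export
icc <- function(m, icc_type = c("icc_3", "icc_2", "icc_1"), alpha = 0.05) {
  icc_type <- match.arg(icc_type)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  m <- as_measurement_matrix(m)
  tw <- decompose_twoway(m)
  ow <- if (icc_type == "icc_1") decompose_oneway(m) else NULL
  n <- tw$n_subjects
  k <- tw$k_occasions

  res <- icc_from_ms(
    msbs = tw$ms_between_subject,
    msbm = tw$ms_between_measure,
    mse = tw$ms_error,
    msw = if (is.null(ow)) NA_real_ else ow$ms_within,
    ss_total = tw$ss_total,
    scale_sq = mean(m^2),
    n = n, k = k, icc_type = icc_type, alpha = alpha
  )

  components <- list(
    sigma2_between = res$sigma2_between,
    sigma2_within = res$sigma2_within
  )
  if (icc_type == "icc_2") components$sigma2_measure <- res$sigma2_measure

  structure(list(
    icc_type = icc_type,
    estimate = res$estimate,
    lower = res$lower,
    upper = res$upper,
    alpha = alpha,
    components = components,
    degenerate = res$degenerate,
    perfect = res$perfect,
    anova = if (icc_type == "icc_1") ow else tw
  ), class = "icc_estimate")
}

#' F-based confidence interval for an intraclass correlation
#'
#' Two-sided `1 - alpha` bounds computed from F quantiles applied to the
#' ANOVA mean squares (no bootstrap). For `icc_3`,
#' `F = MSBS/MSError` on `(n-1, (n-1)(k-1))` degrees of freedom,
#' `FL = F / qF(1-alpha/2; n-1, (n-1)(k-1))`,
#' `FU = F * qF(1-alpha/2; (n-1)(k-1), n-1)` and each bound is
#' `(F* - 1) / (F* + k - 1)`. `icc_1` is analogous with the pooled
#' within-subject mean square on `n(k-1)` degrees of freedom. `icc_2` uses
#' the McGraw-Wong interval with a Satterthwaite-approximated denominator
#' degrees of freedom.
#'
#' When the residual mean square is zero (perfect consistency) the `icc_3` /
#' `icc_1` interval is `(1, 1)` by convention, and the `icc_2` interval
#' collapses to the point estimate; such results carry `perfect = TRUE` on
#' the corresponding [icc()] object.
#'
#' @param anova a `twoway_anova` (for `icc_2`/`icc_3`) or `oneway_anova`
#'   (for `icc_1`) decomposition.
#' @param icc_type one of `"icc_1"`, `"icc_2"`, `"icc_3"`.
#' @param n,k design size; defaults are taken from the ANOVA object.
#' @param alpha two-sided error rate.
#' @return numeric vector `c(lower, upper)`.
#' @export
icc_confidence_interval <- function(anova, icc_type = c("icc_3", "icc_2", "icc_1"),
                                    n = anova$n_subjects, k = anova$k_occasions,
                                    alpha = 0.05) {
  icc_type <- match.arg(icc_type)
  if (icc_type == "icc_1") {
    if (!inherits(anova, "oneway_anova")) {
      stop("icc_1 bounds require a 'oneway_anova' decomposition", call. = FALSE)
    }
    msw <- anova$ms_within
    msbs <- anova$ms_between_subject
    msbm <- NA_real_
    mse <- NA_real_
  } else {
    if (!inherits(anova, "twoway_anova")) {
      stop(icc_type, " bounds require a 'twoway_anova' decomposition", call. = FALSE)
    }
    msbs <- anova$ms_between_subject
    msbm <- anova$ms_between_measure
    mse <- anova$ms_error
    msw <- NA_real_
  }
  res <- icc_from_ms(msbs, msbm, mse, msw,
                     ss_total = anova$ss_total,
                     scale_sq = max(anova$ss_total, msbs, 1),
                     n = n, k = k, icc_type = icc_type, alpha = alpha)
  c(lower = res$lower, upper = res$upper)
}

# Vectorised engine shared by the scalar and voxel-wise paths: all mean-square
# arguments may be equal-length vectors (one element per voxel).
icc_from_ms <- function(msbs, msbm, mse, msw, ss_total, scale_sq,
                        n, k, icc_type, alpha) {
  nv <- length(msbs)
  msbm <- rep_len(msbm, nv)
  mse <- rep_len(mse, nv)
  msw <- rep_len(msw, nv)
  ss_total <- rep_len(ss_total, nv)
  scale_sq <- rep_len(scale_sq, nv)
  # a voxel with ~zero total variance is uninformative
  degenerate <- ss_total <= 1e-18 * pmax(1, scale_sq) * (n * k)

  resid_ms <- if (icc_type == "icc_1") msw else mse
  perfect <- !degenerate & resid_ms <= 1e-12 * pmax(msbs, 1e-300)

  estimate <- switch(icc_type,
    icc_1 = (msbs - msw) / (msbs + (k - 1) * msw),
    icc_3 = (msbs - mse) / (msbs + (k - 1) * mse),
    icc_2 = (msbs - mse) / (msbs + (k - 1) * mse + k * (msbm - mse) / n)
  )

  lower <- rep(NA_real_, nv)
  upper <- rep(NA_real_, nv)
  ok <- !degenerate & !perfect
  if (any(ok)) {
    ci <- icc_ci_ms(msbs[ok], msbm[ok], mse[ok], msw[ok], estimate[ok],
                    n, k, icc_type, alpha)
    lower[ok] <- ci$lower
    upper[ok] <- ci$upper
  }
  if (any(perfect)) {
    if (icc_type == "icc_2") {
      lower[perfect] <- estimate[perfect]
      upper[perfect] <- estimate[perfect]
    } else {
      lower[perfect] <- 1
      upper[perfect] <- 1
    }
  }
  estimate[degenerate] <- NA_real_

  sigma2_between <- (msbs - mse) / k
  sigma2_within <- mse
  if (icc_type == "icc_1") {
    # one-way model: occasion variation is pooled into noise
    sigma2_between <- (msbs - msw) / k
    sigma2_within <- msw
  }
  sigma2_measure <- if (icc_type == "icc_2") (msbm - mse) / n else NULL
  sigma2_between[degenerate] <- NA_real_
  sigma2_within[degenerate] <- NA_real_
  if (!is.null(sigma2_measure)) sigma2_measure[degenerate] <- NA_real_

  list(estimate = estimate, lower = lower, upper = upper,
       sigma2_between = sigma2_between, sigma2_within = sigma2_within,
       sigma2_measure = sigma2_measure,
       degenerate = degenerate, perfect = perfect)
}

# F-quantile confidence bounds on the mean-square scale (vectorised).
icc_ci_ms <- function(msbs, msbm, mse, msw, est, n, k, icc_type, alpha) {
  p <- 1 - alpha / 2
  if (icc_type == "icc_3") {
    df1 <- n - 1
    df2 <- (n - 1) * (k - 1)
    fobs <- msbs / mse
    fl <- fobs / stats::qf(p, df1, df2)
    fu <- fobs * stats::qf(p, df2, df1)
    lower <- (fl - 1) / (fl + k - 1)
    upper <- (fu - 1) / (fu + k - 1)
  } else if (icc_type == "icc_1") {
    df1 <- n - 1
    df2 <- n * (k - 1)
    fobs <- msbs / msw
    fl <- fobs / stats::qf(p, df1, df2)
    fu <- fobs * stats::qf(p, df2, df1)
    lower <- (fl - 1) / (fl + k - 1)
    upper <- (fu - 1) / (fu + k - 1)
  } else {
    # McGraw-Wong ICC(A,1): Satterthwaite df for the composite denominator
    fj <- msbm / mse
    A <- k * est * fj
    B <- n * (1 + (k - 1) * est) - k * est
    dfe <- (n - 1) * (k - 1)
    v <- dfe * (A + B)^2 / ((n - 1) * A^2 + B^2)
    v[!is.finite(v) | v <= 0] <- dfe  # guard pathological mean squares
    f1 <- stats::qf(p, n - 1, v)
    f2 <- stats::qf(p, v, n - 1)
    lower <- n * (msbs - f1 * mse) /
      (f1 * (k * msbm + (k * n - k - n) * mse) + n * msbs)
    upper <- n * (f2 * msbs - mse) /
      (k * msbm + (k * n - k - n) * mse + n * f2 * msbs)
  }
  # numerical guard: quantile transforms can cross by a few ulp near alpha -> 1
  swap <- !is.na(lower) & !is.na(upper) & lower > upper
  if (any(swap)) {
    tmp <- lower[swap]
    lower[swap] <- upper[swap]
    upper[swap] <- tmp
  }
  list(lower = lower, upper = upper)
}

#' @export
print.icc_estimate <- function(x, ...) {
  lab <- c(icc_1 = "ICC(1)", icc_2 = "ICC(2,1)", icc_3 = "ICC(3,1)")[x$icc_type]
  if (isTRUE(x$degenerate)) {
    cat(lab, ": undefined (zero total variance)\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("%s = %.4f, %d%% CI [%.4f, %.4f]\n", lab, x$estimate,
              round(100 * (1 - x$alpha)), x$lower, x$upper))
  cat(sprintf("  between-subject var = %.4g, within-subject var = %.4g\n",
              x$components$sigma2_between, x$components$sigma2_within))
  if (!is.null(x$components$sigma2_measure)) {
    cat(sprintf("  between-measure var = %.4g\n", x$components$sigma2_measure))
  }
  invisible(x)
}
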