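#' Two-way ANOVA decomposition of a subject-by-occasion matrix
#'
#' Decomposes the total sum of squares of a complete `n x k` measurement
#' matrix into subject, occasion (measure) and residual components — the
#' mean squares that all single-measure ICC estimators are built from:
#' \eqn{MSBS} (between subjects), \eqn{MSBM} (between measures, i.e. the
#' occasion main effect) and \eqn{MSError} (subject-by-occasion residual).
#' Sums of squares use centred deviations to limit floating-point
#' cancellation, and partition the total exactly.
#'
#' @param m a [measurement_matrix()] or numeric matrix, subjects in rows,
#'   occasions in columns.
#' @return object of class `twoway_anova`: list with `ms_between_subject`,
#'   `ms_between_measure`, `ms_error`, the four sums of squares, the degrees
#'   of freedom, and the design size (`n_subjects`, `k_occasions`).
#' @examples
#' m <- cbind(c(1, 3, 6, 9, 12), c(3, 9, 18, 27, 36))
#' decompose_twoway(m)
#' @seealso [decompose_oneway()], [icc()]
#' @export
decompose_twoway <- function(m) {
  m <- as_measurement_matrix(m)
  n <- nrow(m)
  k <- ncol(m)
  grand <- mean(m)
  subj_means <- rowMeans(m)
  occ_means <- colMeans(m)

  ss_total <- sum((m - grand)^2)
  ss_subject <- k * sum((subj_means - grand)^2)
  ss_measure <- n * sum((occ_means - grand)^2)
  ss_error <- sum((m - outer(subj_means, occ_means, `+`) + grand)^2)

  df_subject <- n - 1L
  df_measure <- k - 1L
  df_error <- (n - 1L) * (k - 1L)

  structure(list(
    ms_between_subject = ss_subject / df_subject,
    ms_between_measure = ss_measure / df_measure,
    ms_error = ss_error / df_error,
    ss_total = ss_total,
    ss_subject = ss_subject,
    ss_measure = ss_measure,
    ss_error = ss_error,
    df_subject = df_subject,
    df_measure = df_measure,
    df_error = df_error,
    n_subjects = n,
    k_occasions = k
  ), class = "twoway_anova")
}

#' One-way ANOVA decomposition of a subject-by-occasion matrix
#'
#' One-way (subjects only) decomposition underlying ICC(1): occasion and
#' residual variation are pooled into a single within-subject mean square,
#' `ms_within` with `n(k-1)` degrees of freedom. Equivalently,
#' `ss_within = ss_measure + ss_error` of the two-way fit.
#'
#' @inheritParams decompose_twoway
#' @return object of class `oneway_anova`: list with `ms_between_subject`,
#'   `ms_within`, sums of squares, degrees of freedom and design size.
#' @export
decompose_oneway <- function(m) {
  tw <- decompose_twoway(m)
  n <- tw$n_subjects
  k <- tw$k_occasions
  ss_within <- tw$ss_measure + tw$ss_error
  df_within <- n * (k - 1L)
  structure(list(
    ms_between_subject = tw$ms_between_subject,
    ms_within = ss_within / df_within,
    ss_total = tw$ss_total,
    ss_subject = tw$ss_subject,
    ss_within = ss_within,
    df_subject = tw$df_subject,
    df_within = df_within,
    n_subjects = n,
    k_occasions = k
  ), class = "oneway_anova")
}

#' @export
print.twoway_anova <- function(x, ...) {
  cat("Two-way ANOVA decomposition (", x$n_subjects, " subjects x ",
      x$k_occasions, " occasions)\n", sep = "")
  tab <- data.frame(
    df = c(x$df_subject, x$df_measure, x$df_error),
    SS = c(x$ss_subject, x$ss_measure, x$ss_error),
    MS = c(x$ms_between_subject, x$ms_between_measure, x$ms_error),
    row.names = c("subjects", "occasions", "residual")
  )
  print(tab, ...)
  invisible(x)
}

#' @export
print.oneway_anova <- function(x, ...) {
  cat("One-way ANOVA decomposition (", x$n_subjects, " subjects x ",
      x$k_occasions, " occasions)\n", sep = "")
  tab <- data.frame(
    df = c(x$df_subject, x$df_within),
    SS = c(x$ss_subject, x$ss_within),
    MS = c(x$ms_between_subject, x$ms_within),
    row.names = c("subjects", "within")
  )
  print(tab, ...)
  invisible(x)
}
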