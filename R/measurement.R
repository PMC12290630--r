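#' Construct a complete subject-by-occasion measurement matrix
#'
#' A measurement matrix holds the repeated measurements of one quantity (one
#' voxel's signal, one region's beta, one behavioural score) for `n` subjects
#' across `k` measurement occasions (runs or sessions). The design must be
#' complete: every subject is measured on every occasion and no cell is
#' missing. This is the unit of data every ICC estimator in the package
#' operates on.
#'
#' @param values numeric matrix (or object coercible to one) with one row per
#'   subject and one column per occasion.
#' @param subject_ids optional character vector of subject labels; defaults to
#'   existing rownames or `sub1..subn`.
#' @param occasion_ids optional character vector of occasion labels; defaults
#'   to existing colnames or `occ1..occk`.
#'
#' @return a `measurement_matrix`: a numeric matrix with subject/occasion
#'   dimnames and class attribute.
#' @examples
#' m <- measurement_matrix(cbind(c(1, 3, 6, 9, 12), c(3, 9, 18, 27, 36)))
#' icc(m, "icc_3")
#' @export
measurement_matrix <- function(values, subject_ids = NULL, occasion_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("'values' must be numeric", call. = FALSE)
  }
  n <- nrow(values)
  k <- ncol(values)
  if (n < 2L || k < 2L) {
    stop("invalid design: need at least 2 subjects and 2 occasions (got ",
         n, " x ", k, ")", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("invalid design: measurement matrix must be complete ",
         "(no missing or non-finite cells)", call. = FALSE)
  }
  if (is.null(subject_ids)) {
    subject_ids <- rownames(values)
    if (is.null(subject_ids)) subject_ids <- paste0("sub", seq_len(n))
  }
  if (is.null(occasion_ids)) {
    occasion_ids <- colnames(values)
    if (is.null(occasion_ids)) occasion_ids <- paste0("occ", seq_len(k))
  }
  if (length(subject_ids) != n || length(occasion_ids) != k) {
    stop("label lengths do not match matrix dimensions", call. = FALSE)
  }
  dimnames(values) <- list(subject_ids, occasion_ids)
  class(values) <- c("measurement_matrix", class(values))
  values
}

as_measurement_matrix <- function(m) {
  if (inherits(m, "measurement_matrix")) m else measurement_matrix(m)
}
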