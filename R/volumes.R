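#' Volume set: per-occasion ordered lists of subject 3D volumes
#'
#' The container consumed by all voxel-wise operations. Each measurement
#' occasion (run or session) contributes one ordered list of subject
#' volumes; subject order must be identical across occasions, because
#' volumes are matched by list position, never by filename. All volumes
#' must live on one voxel grid.
#'
#' @param occasions list of length `k >= 2`; each element either a list of
#'   `n` 3D numeric arrays or a 4D array with subjects along the fourth
#'   dimension. All occasions must contain the same number of subjects.
#' @param grid optional grid descriptor as returned by [volume_grid()];
#'   inferred from the first volume when `NULL`.
#' @param subject_ids,occasion_ids optional ordered labels.
#' @return object of class `volume_set`: list with `occasions` (list of 4D
#'   arrays `x * y * z * subject`), `grid`, `subject_ids`, `occasion_ids`.
#' @export
volume_set <- function(occasions, grid = NULL, subject_ids = NULL,
                       occasion_ids = NULL) {
  if (!is.list(occasions) || length(occasions) < 2L) {
    stop("need at least 2 measurement occasions", call. = FALSE)
  }
  k <- length(occasions)
  occasions <- lapply(occasions, normalize_occasion)
  n <- dim(occasions[[1L]])[4L]
  dims <- dim(occasions[[1L]])[1:3]
  for (j in seq_len(k)) {
    dj <- dim(occasions[[j]])
    if (dj[4L] != n) {
      stop("unequal subject counts across occasions: occasion ", j, " has ",
           dj[4L], " subjects, occasion 1 has ", n, call. = FALSE)
    }
    if (!all(dj[1:3] == dims)) {
      stop("grid mismatch: occasion ", j, " volumes are ",
           paste(dj[1:3], collapse = "x"), ", expected ",
           paste(dims, collapse = "x"), call. = FALSE)
    }
  }
  if (n < 2L) stop("need at least 2 subjects", call. = FALSE)
  if (is.null(grid)) grid <- volume_grid(dims)
  if (!all(grid$dims == dims)) {
    stop("grid descriptor does not match volume dimensions", call. = FALSE)
  }
  if (is.null(subject_ids)) subject_ids <- paste0("sub", seq_len(n))
  if (is.null(occasion_ids)) occasion_ids <- paste0("occ", seq_len(k))
  structure(list(occasions = occasions, grid = grid,
                 subject_ids = subject_ids, occasion_ids = occasion_ids),
            class = "volume_set")
}

normalize_occasion <- function(x) {
  if (is.list(x)) {
    dims <- dim(x[[1L]])
    if (length(dims) != 3L) stop("volumes must be 3D arrays", call. = FALSE)
    for (v in x) {
      if (!identical(dim(v), dims)) {
        stop("grid mismatch within an occasion list", call. = FALSE)
      }
    }
    arr <- array(unlist(x, use.names = FALSE), dim = c(dims, length(x)))
    storage.mode(arr) <- "double"
    return(arr)
  }
  x <- unclass(x)
  attributes(x) <- list(dim = dim(x))
  if (length(dim(x)) != 4L) {
    stop("each occasion must be a list of 3D arrays or a 4D array", call. = FALSE)
  }
  storage.mode(x) <- "double"
  x
}

#' Voxel-grid descriptor
#'
#' @param dims integer vector of length 3 (voxels per axis).
#' @param pixdim voxel sizes in mm, length 3.
#' @return list with `dims` and `pixdim`, class `volume_grid`.
#' @export
volume_grid <- function(dims, pixdim = c(1, 1, 1)) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 2L)) {
    stop("'dims' must be 3 integers, each >= 2", call. = FALSE)
  }
  structure(list(dims = dims, pixdim = as.numeric(pixdim)),
            class = "volume_grid")
}

same_grid <- function(a, b, tol = 1e-6) {
  all(a$dims == b$dims) && all(abs(a$pixdim - b$pixdim) < tol)
}

#' Binary brain mask
#'
#' Any nonzero voxel is treated as in-mask (masks are binarized as
#' `value > 0` on construction/load). At least one voxel must be set.
#'
#' @param x 3D numeric or logical array, or a path handled by the caller.
#' @param grid optional [volume_grid()]; inferred from `x` when `NULL`.
#' @return logical 3D array of class `brain_mask` with a `grid` attribute.
#' @export
brain_mask <- function(x, grid = NULL) {
  if (length(dim(x)) != 3L) stop("mask must be a 3D volume", call. = FALSE)
  m <- array(as.numeric(x) > 0, dim = dim(x))
  if (!any(m)) stop("mask is empty: no nonzero voxel", call. = FALSE)
  if (is.null(grid)) grid <- volume_grid(dim(m))
  structure(m, grid = grid, class = c("brain_mask", "array"))
}

vs_n_subjects <- function(vs) dim(vs$occasions[[1L]])[4L]
vs_k_occasions <- function(vs) length(vs$occasions)

# n x V matrix for one occasion (V = all voxels, column-major voxel order)
occasion_matrix <- function(vs, j) {
  a <- vs$occasions[[j]]
  d <- dim(a)
  t(matrix(a, nrow = prod(d[1:3]), ncol = d[4L]))
}

subset_subjects <- function(vs, idx) {
  occ <- lapply(vs$occasions, function(a) a[, , , idx, drop = FALSE])
  volume_set(occ, grid = vs$grid,
             subject_ids = vs$subject_ids[idx],
             occasion_ids = vs$occasion_ids)
}

#' @export
print.volume_set <- function(x, ...) {
  cat("volume_set: ", vs_n_subjects(x), " subjects x ", vs_k_occasions(x),
      " occasions on a ", paste(x$grid$dims, collapse = "x"), " grid\n",
      sep = "")
  invisible(x)
}
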