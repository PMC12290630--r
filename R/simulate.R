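#' Specification for a synthetic subject-by-occasion volume dataset
#'
#' Describes a Gaussian variance-components generative model on a voxel
#' grid: at voxel `v`, subject `i`, occasion `j`,
#' \deqn{y_{ijv} = \mu_v + b_{iv} + s_j + e_{ijv}}
#' with stable subject effects `b_iv ~ N(0, sigma2_between(v))`, noise
#' `e_ijv ~ N(0, sigma2_within(v))` and a fixed additive occasion bias
#' `s_j`. The true consistency ICC at each voxel is therefore
#' `sigma2_between / (sigma2_between + sigma2_within)`, unaffected by the
#' occasion bias (which only lowers the agreement ICC(2,1)).
#'
#' Defaults emulate a small two-session task-fMRI study: 60 subjects, 2
#' occasions, an 8x8x8 grid, unit between- and within-subject variance
#' (true ICC 0.5) and no occasion bias.
#'
#' @param n_subjects,n_occasions design size (`>= 2` each).
#' @param grid_dims 3 integers, each `>= 2`.
#' @param mask_fraction fraction of voxels inside the brain mask, in (0, 1].
#' @param grand_mean scalar or 3D array: the voxel-wise mean signal.
#' @param sigma2_between scalar or 3D array `>= 0`: between-subject variance.
#' @param sigma2_within scalar or 3D array `>= 0`: within-subject variance.
#' @param occasion_bias numeric vector of length `n_occasions`: fixed
#'   additive shift per occasion.
#' @param supra_fraction fraction of in-mask voxels assigned to the
#'   suprathreshold mask of the generated truth bundle.
#' @param smooth_fwhm Gaussian FWHM in voxels for optional spatial
#'   smoothing of the subject-effect and noise fields (0 = independent
#'   voxels). Fields are rescaled so the requested marginal variances are
#'   preserved (approximately, near edges).
#' @param seed integer seed making the dataset reproducible.
#' @return list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_subjects = 60L, n_occasions = 2L,
                            grid_dims = c(8L, 8L, 8L), mask_fraction = 1,
                            grand_mean = 0, sigma2_between = 1,
                            sigma2_within = 1,
                            occasion_bias = rep(0, n_occasions),
                            supra_fraction = 0.25, smooth_fwhm = 0,
                            seed = 1L) {
  grid_dims <- as.integer(grid_dims)
  if (length(grid_dims) != 3L || any(grid_dims < 2L)) {
    stop("'grid_dims' must be 3 integers >= 2", call. = FALSE)
  }
  if (n_subjects < 2L || n_occasions < 2L) {
    stop("need at least 2 subjects and 2 occasions", call. = FALSE)
  }
  if (mask_fraction <= 0 || mask_fraction > 1) {
    stop("'mask_fraction' must be in (0, 1]", call. = FALSE)
  }
  if (length(occasion_bias) != n_occasions) {
    stop("'occasion_bias' must have one entry per occasion", call. = FALSE)
  }
  as_field <- function(x, what) {
    if (length(x) == 1L) x <- array(x, dim = grid_dims)
    if (!all(dim(x) == grid_dims)) {
      stop("'", what, "' must be a scalar or an array on the grid", call. = FALSE)
    }
    x
  }
  s2b <- as_field(sigma2_between, "sigma2_between")
  s2w <- as_field(sigma2_within, "sigma2_within")
  if (any(s2b < 0) || any(s2w < 0)) {
    stop("variances must be >= 0", call. = FALSE)
  }
  structure(list(
    n_subjects = as.integer(n_subjects), n_occasions = as.integer(n_occasions),
    grid_dims = grid_dims, mask_fraction = mask_fraction,
    grand_mean = as_field(grand_mean, "grand_mean"),
    sigma2_between = s2b, sigma2_within = s2w,
    occasion_bias = as.numeric(occasion_bias),
    supra_fraction = supra_fraction, smooth_fwhm = smooth_fwhm,
    seed = as.integer(seed)
  ), class = "simulation_spec")
}

#' Simulate a volume dataset with known variance components
#'
#' Draws a complete subject-by-occasion set of 3D volumes from the model in
#' [simulation_spec()] and packages it with its ground truth: the true
#' voxel-wise consistency-ICC, between-subject variance and within-subject
#' variance maps, the brain mask, and a disjoint supra-/subthreshold mask
#' pair for stratified summaries.
#'
#' @param spec a [simulation_spec()].
#' @return list of class `truth_bundle`: `volumes` (a [volume_set()]),
#'   `mask`, `supra_mask`, `sub_mask` ([brain_mask()]s), `true_icc3`,
#'   `true_bs`, `true_ws` (3D arrays, `NA` outside the mask), and `spec`.
#' @examples
#' tb <- simulate_dataset(simulation_spec(n_subjects = 30, seed = 7))
#' maps <- voxelwise_icc(tb$volumes, tb$mask, "icc_3")
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  dims <- spec$grid_dims
  V <- prod(dims)
  n <- spec$n_subjects
  k <- spec$n_occasions

  withr_seed(spec$seed, {
    n_in <- max(1L, round(spec$mask_fraction * V))
    in_idx <- sort(sample.int(V, n_in))
    mask_arr <- array(0, dim = dims)
    mask_arr[in_idx] <- 1

    sd_b <- sqrt(as.vector(spec$sigma2_between))
    sd_w <- sqrt(as.vector(spec$sigma2_within))
    mu <- as.vector(spec$grand_mean)

    b <- matrix(stats::rnorm(n * V), nrow = n)  # subject effects, unit scale
    if (spec$smooth_fwhm > 0) b <- smooth_rows(b, dims, spec$smooth_fwhm)
    b <- sweep(b, 2L, sd_b, `*`)

    occasions <- vector("list", k)
    for (j in seq_len(k)) {
      e <- matrix(stats::rnorm(n * V), nrow = n)
      if (spec$smooth_fwhm > 0) e <- smooth_rows(e, dims, spec$smooth_fwhm)
      e <- sweep(e, 2L, sd_w, `*`)
      y <- sweep(b + e, 2L, mu, `+`) + spec$occasion_bias[j]
      occasions[[j]] <- array(t(y), dim = c(dims, n))
    }

    masks <- make_masks(dims, supra_fraction = spec$supra_fraction,
                        seed = spec$seed + 1L, within = mask_arr)
  })

  truth <- function(vals) {
    out <- array(NA_real_, dim = dims)
    out[in_idx] <- vals[in_idx]
    out
  }
  s2b <- as.vector(spec$sigma2_between)
  s2w <- as.vector(spec$sigma2_within)
  icc3 <- ifelse(s2b + s2w > 0, s2b / (s2b + s2w), NA_real_)

  structure(list(
    volumes = volume_set(occasions, grid = volume_grid(dims)),
    mask = brain_mask(mask_arr),
    supra_mask = masks$supra,
    sub_mask = masks$sub,
    true_icc3 = truth(icc3),
    true_bs = truth(s2b),
    true_ws = truth(s2w),
    spec = spec
  ), class = "truth_bundle")
}

# separable Gaussian smoothing of each row (a flattened 3D field). Each axis
# pass is a d x d linear operator (replicate padding at the edges); dividing
# by the per-voxel root-sum-of-squared weights restores the marginal
# variance of white noise exactly at every voxel, edges included.
smooth_rows <- function(m, dims, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(seq(-r, r), sd = sigma)
  kern <- kern / sum(kern)
  conv_line <- function(line) {
    padded <- c(rep(line[1L], r), line, rep(line[length(line)], r))
    as.numeric(stats::filter(padded, kern, sides = 2L))[(r + 1L):(r + length(line))]
  }
  smat <- lapply(dims, function(d) {
    vapply(seq_len(d), function(i) conv_line(as.numeric(seq_len(d) == i)),
           numeric(d))  # column i = response to a unit impulse at i
  })
  fac <- lapply(smat, function(S) rowSums(S^2))
  vnorm <- sqrt(array(outer(outer(fac[[1L]], fac[[2L]]), fac[[3L]]), dim = dims))
  t(apply(m, 1L, function(row) {
    a <- array(row, dim = dims)
    a <- apply(a, c(2L, 3L), function(l) smat[[1L]] %*% l)
    a <- aperm(apply(a, c(1L, 3L), function(l) smat[[2L]] %*% l), c(2L, 1L, 3L))
    a <- aperm(apply(a, c(1L, 2L), function(l) smat[[3L]] %*% l), c(2L, 3L, 1L))
    as.vector(a / vnorm)
  }))
}

#' Printed worked-example volume set
#'
#' A 5-subject, 2-occasion volume set in which every in-grid voxel carries
#' the textbook pair A = (1, 3, 6, 9, 12) and B = 3A: occasion means are
#' perfectly correlated (r = 1) yet the consistency ICC(3,1) is 0.60,
#' illustrating that scaling between occasions costs consistency but not
#' correlation.
#'
#' @param grid_dims 3 integers (default 4x4x4).
#' @return a [volume_set()] with n = 5 subjects and k = 2 occasions.
#' @export
worked_example_volumes <- function(grid_dims = c(4L, 4L, 4L)) {
  grid_dims <- as.integer(grid_dims)
  a_vals <- c(1, 3, 6, 9, 12)
  occasions <- list(
    lapply(a_vals, function(v) array(v, dim = grid_dims)),
    lapply(3 * a_vals, function(v) array(v, dim = grid_dims))
  )
  volume_set(occasions, grid = volume_grid(grid_dims),
             subject_ids = paste0("sub", 1:5),
             occasion_ids = c("A", "B"))
}

#' Generate disjoint supra-/subthreshold masks
#'
#' Randomly assigns a fraction of the in-brain voxels to a suprathreshold
#' (task-positive stand-in) mask and the remainder to the subthreshold
#' mask. The two masks are disjoint, nonempty, and together cover the
#' in-brain region. Deterministic given the seed.
#'
#' @param grid_dims 3 integers.
#' @param supra_fraction fraction of in-brain voxels in the supra mask,
#'   strictly between 0 and 1.
#' @param seed integer seed.
#' @param within optional 3D indicator array restricting the in-brain
#'   region (default: whole grid).
#' @return list with [brain_mask()]s `supra` and `sub`.
#' @export
make_masks <- function(grid_dims, supra_fraction = 0.25, seed = 1L,
                       within = NULL) {
  grid_dims <- as.integer(grid_dims)
  if (supra_fraction <= 0 || supra_fraction >= 1) {
    stop("'supra_fraction' must be strictly between 0 and 1", call. = FALSE)
  }
  V <- prod(grid_dims)
  in_idx <- if (is.null(within)) seq_len(V) else which(as.vector(within) > 0)
  n_supra <- round(supra_fraction * length(in_idx))
  if (n_supra < 1L || n_supra >= length(in_idx)) {
    stop("degenerate fraction: both masks must be nonempty", call. = FALSE)
  }
  supra_idx <- withr_seed(seed, sort(sample(in_idx, n_supra)))
  supra <- array(0, dim = grid_dims)
  supra[supra_idx] <- 1
  sub <- array(0, dim = grid_dims)
  sub[setdiff(in_idx, supra_idx)] <- 1
  list(supra = brain_mask(supra), sub = brain_mask(sub))
}

#' @export
print.truth_bundle <- function(x, ...) {
  cat("truth_bundle: ", x$spec$n_subjects, " subjects x ",
      x$spec$n_occasions, " occasions, grid ",
      paste(x$spec$grid_dims, collapse = "x"), ", ",
      sum(x$mask), " in-mask voxels\n", sep = "")
  cat(sprintf("  true ICC(3,1) median %.3f\n",
              stats::median(x$true_icc3, na.rm = TRUE)))
  invisible(x)
}
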