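#' Voxel-wise intraclass correlation maps
#'
#' Applies the scalar ICC estimator [icc()] independently at every in-mask
#' voxel of a [volume_set()], returning labelled 3D maps of the estimate,
#' its F-based confidence bounds, and the variance components: the ICC
#' point estimate, lower bound, upper bound, between-subject variance and
#' within-subject variance (plus the between-measure variance for
#' `icc_2`). Computation is vectorised over voxels but is exactly the
#' per-voxel two-way (or one-way) ANOVA: for any voxel, the map values
#' equal `icc()` run on that voxel's `n x k` measurement matrix.
#'
#' Voxels outside the mask, and in-mask voxels whose measurement matrix has
#' zero total variance (no reliability information), are `NA` in every
#' output map.
#'
#' @param vs a [volume_set()].
#' @param mask a [brain_mask()] on the same grid.
#' @param icc_type one of `"icc_1"`, `"icc_2"`, `"icc_3"`.
#' @param alpha two-sided error rate for the confidence maps.
#' @return object of class `reliability_maps`: list of 3D arrays
#'   `estimate`, `lower`, `upper`, `between_subject_var`,
#'   `within_subject_var` (and `between_measure_var` for `icc_2`), plus
#'   `mask`, `grid`, `icc_type`, `alpha`, `n_subjects`, `k_occasions`.
#' @examples
#' vs <- worked_example_volumes(c(4, 4, 4))
#' mask <- brain_mask(array(1, c(4, 4, 4)))
#' maps <- voxelwise_icc(vs, mask, "icc_3")
#' masked_median(maps$estimate, mask)  # 0.60
#' @export
voxelwise_icc <- function(vs, mask, icc_type = c("icc_3", "icc_2", "icc_1"),
                          alpha = 0.05) {
  icc_type <- match.arg(icc_type)
  stopifnot(inherits(vs, "volume_set"))
  mask <- if (inherits(mask, "brain_mask")) mask else brain_mask(mask)
  if (!same_grid(vs$grid, attr(mask, "grid"))) {
    stop("mask grid does not match the volume set grid", call. = FALSE)
  }
  n <- vs_n_subjects(vs)
  k <- vs_k_occasions(vs)
  sel <- as.vector(mask)

  mats <- lapply(seq_len(k), function(j) occasion_matrix(vs, j)[, sel, drop = FALSE])
  ms <- voxelwise_ms(mats, n, k)
  res <- icc_from_ms(ms$msbs, ms$msbm, ms$mse, ms$msw,
                     ss_total = ms$ss_total, scale_sq = ms$scale_sq,
                     n = n, k = k, icc_type = icc_type, alpha = alpha)

  dims <- vs$grid$dims
  blank <- array(NA_real_, dim = dims)
  fill <- function(v) { out <- blank; out[sel] <- v; out }

  maps <- list(
    estimate = fill(res$estimate),
    lower = fill(res$lower),
    upper = fill(res$upper),
    between_subject_var = fill(res$sigma2_between),
    within_subject_var = fill(res$sigma2_within)
  )
  if (icc_type == "icc_2") {
    maps$between_measure_var <- fill(res$sigma2_measure)
  }
  structure(c(maps, list(mask = mask, grid = vs$grid, icc_type = icc_type,
                         alpha = alpha, n_subjects = n, k_occasions = k)),
            class = "reliability_maps")
}

# Mean squares for every voxel at once. 'mats' is a list of k matrices of
# identical shape n x V (subjects x voxels).
voxelwise_ms <- function(mats, n, k) {
  subj_mean <- Reduce(`+`, mats) / k                 # n x V
  occ_mean <- do.call(rbind, lapply(mats, colMeans)) # k x V
  grand <- colMeans(occ_mean)                        # V

  ss_total <- Reduce(`+`, lapply(mats, function(m) {
    colSums(sweep(m, 2L, grand, `-`)^2)
  }))
  ss_subject <- k * colSums(sweep(subj_mean, 2L, grand, `-`)^2)
  ss_measure <- n * colSums(sweep(occ_mean, 2L, grand, `-`)^2)
  ss_error <- pmax(ss_total - ss_subject - ss_measure, 0)

  scale_sq <- Reduce(`+`, lapply(mats, function(m) colMeans(m^2))) / k

  list(
    msbs = ss_subject / (n - 1),
    msbm = ss_measure / (k - 1),
    mse = ss_error / ((n - 1) * (k - 1)),
    msw = (ss_measure + ss_error) / (n * (k - 1)),
    ss_total = ss_total,
    scale_sq = scale_sq
  )
}

#' Median of a map inside a mask
#'
#' Median over in-mask, non-missing voxels; `NA` voxels (outside-mask or
#' degenerate) are skipped. This is the per-pipeline summary statistic used
#' for stability curves and specification curves.
#'
#' @param map 3D numeric array.
#' @param mask a [brain_mask()] (or 3D array binarized as `> 0`).
#' @return scalar median.
#' @export
masked_median <- function(map, mask) {
  mask <- if (inherits(mask, "brain_mask")) mask else brain_mask(mask)
  if (!all(dim(map) == dim(mask))) {
    stop("map and mask dimensions differ", call. = FALSE)
  }
  vals <- map[as.vector(mask)]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) {
    stop("empty effective mask: no non-missing in-mask voxel", call. = FALSE)
  }
  stats::median(vals)
}

#' @export
print.reliability_maps <- function(x, ...) {
  lab <- c(icc_1 = "ICC(1)", icc_2 = "ICC(2,1)", icc_3 = "ICC(3,1)")[x$icc_type]
  est <- x$estimate[as.vector(x$mask)]
  cat("reliability_maps: voxel-wise ", lab, " over ",
      sum(x$mask), " voxels (", x$n_subjects, " subjects x ",
      x$k_occasions, " occasions)\n", sep = "")
  cat(sprintf("  median estimate %.3f (%d degenerate voxels)\n",
              stats::median(est, na.rm = TRUE), sum(is.na(est))))
  invisible(x)
}
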