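#' Sample-size grid for bootstrap stability curves
#'
#' Defaults follow the standard design for characterising how the median
#' voxel-wise ICC stabilises with sample size: candidate sample sizes 25 to
#' 525 in steps of 50, 100 bootstrap iterations at each size.
#'
#' @param n_values increasing integer sample sizes.
#' @param n_iterations bootstrap iterations per sample size, `>= 1`.
#' @param seed master seed; each `(n, iteration)` cell derives its own
#'   substream from it, so extending the grid never changes earlier draws.
#' @return list of class `stability_grid`.
#' @export
stability_grid <- function(n_values = seq(25L, 525L, by = 50L),
                           n_iterations = 100L, seed = 1L) {
  n_values <- as.integer(n_values)
  if (any(diff(n_values) <= 0L) || any(n_values < 2L)) {
    stop("'n_values' must be increasing integers >= 2", call. = FALSE)
  }
  n_iterations <- as.integer(n_iterations)
  if (n_iterations < 1L) stop("'n_iterations' must be >= 1", call. = FALSE)
  structure(list(n_values = n_values, n_iterations = n_iterations,
                 seed = as.integer(seed)),
            class = "stability_grid")
}

# deterministic per-cell substream seed, independent of grid layout
substream_seed <- function(master, n, iteration) {
  as.integer((as.double(master) %% 2147483647 * 48271 +
                as.double(n) * 100003 + as.double(iteration) * 7919) %%
               2147483629) + 1L
}

#' Bootstrap subsampling stability of median reliability
#'
#' For each candidate sample size `n` and each iteration, draws `n`
#' subjects *with replacement* (the same subjects across all occasions, so
#' within-subject pairing is preserved), recomputes the voxel-wise ICC maps
#' on the resample, and records the masked medians of the estimate,
#' between-subject variance and within-subject variance maps. Summaries per
#' `n` are the mean and the empirical 2.5/97.5 percentile interval across
#' iterations. Deterministic given the grid's master seed.
#'
#' Because sampling is with replacement, a subject drawn twice contributes
#' two identical rows; this slightly deflates the between-subject variance
#' of a resample relative to sampling without replacement.
#'
#' @param vs a [volume_set()] with at least `max(n_values)` subjects.
#' @param mask a [brain_mask()] on the same grid.
#' @param icc_type one of `"icc_1"`, `"icc_2"`, `"icc_3"`.
#' @param grid a [stability_grid()].
#' @param alpha passed to the per-voxel estimator.
#' @return object of class `stability_curve`: list with `draws` (data.frame
#'   `n`, `iteration`, `median_icc`, `median_bs`, `median_ws`) and
#'   `summary` (data.frame `n`, then `mean`/`lower`/`upper` for each of the
#'   three statistics), plus the grid.
#' @export
subsample_stability <- function(vs, mask, icc_type = c("icc_3", "icc_2", "icc_1"),
                                grid = stability_grid(), alpha = 0.05) {
  icc_type <- match.arg(icc_type)
  stopifnot(inherits(vs, "volume_set"), inherits(grid, "stability_grid"))
  mask <- if (inherits(mask, "brain_mask")) mask else brain_mask(mask)
  if (!same_grid(vs$grid, attr(mask, "grid"))) {
    stop("mask grid does not match the volume set grid", call. = FALSE)
  }
  n_avail <- vs_n_subjects(vs)
  if (max(grid$n_values) > n_avail) {
    stop("grid exceeds available subjects: max n is ", max(grid$n_values),
         " but only ", n_avail, " subjects are present", call. = FALSE)
  }
  k <- vs_k_occasions(vs)
  sel <- as.vector(mask)
  mats <- lapply(seq_len(k), function(j) occasion_matrix(vs, j)[, sel, drop = FALSE])

  one_draw <- function(n, iter) {
    seed_i <- substream_seed(grid$seed, n, iter)
    idx <- withr_seed(seed_i, sample.int(n_avail, n, replace = TRUE))
    sub <- lapply(mats, function(m) m[idx, , drop = FALSE])
    ms <- voxelwise_ms(sub, n, k)
    res <- icc_from_ms(ms$msbs, ms$msbm, ms$mse, ms$msw,
                       ss_total = ms$ss_total, scale_sq = ms$scale_sq,
                       n = n, k = k, icc_type = icc_type, alpha = alpha)
    c(median_icc = stats::median(res$estimate, na.rm = TRUE),
      median_bs = stats::median(res$sigma2_between, na.rm = TRUE),
      median_ws = stats::median(res$sigma2_within, na.rm = TRUE))
  }

  draws <- expand.grid(iteration = seq_len(grid$n_iterations),
                       n = grid$n_values)[, 2:1]
  stats_mat <- t(mapply(one_draw, draws$n, draws$iteration))
  draws <- cbind(draws, as.data.frame(stats_mat))
  rownames(draws) <- NULL

  summarize <- function(x) {
    q <- stats::quantile(x, c(0.025, 0.975), names = FALSE, type = 7)
    c(mean = mean(x), lower = q[1L], upper = q[2L])
  }
  summary <- do.call(rbind, lapply(grid$n_values, function(nn) {
    d <- draws[draws$n == nn, ]
    s <- c(n = nn, stats::setNames(summarize(d$median_icc),
                                   c("mean_icc", "lower_icc", "upper_icc")),
           stats::setNames(summarize(d$median_bs),
                           c("mean_bs", "lower_bs", "upper_bs")),
           stats::setNames(summarize(d$median_ws),
                           c("mean_ws", "lower_ws", "upper_ws")))
    as.data.frame(as.list(s))
  }))
  structure(list(draws = draws, summary = summary, grid = grid,
                 icc_type = icc_type),
            class = "stability_curve")
}

# evaluate expr under a local RNG state seeded with 'seed'
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' @export
print.stability_curve <- function(x, ...) {
  cat("stability_curve (", x$icc_type, "): ", length(x$grid$n_values),
      " sample sizes x ", x$grid$n_iterations, " iterations\n", sep = "")
  print(x$summary, ...)
  invisible(x)
}
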