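# Frozen option vocabularies for the analytic-decision grid. Smoothing
# kernels are FWHM in mm (1.5x-3.5x of a 2.4 mm voxel); motion options are
# increasingly stringent nuisance strategies (opt5/opt6 extend opt3/opt4
# with mean-FD subject exclusion and are only present in the full grid);
# model parameterizations and contrasts are the anticipation-phase
# variants of the monetary incentive delay task.
fwhm_levels <- c("3.6", "4.8", "6.0", "7.2", "8.4")
motion_levels_full <- paste0("opt", 1:6)
motion_levels_restricted <- paste0("opt", 1:4)
model_levels <- c("AntMod", "CueMod", "FixMod")
contrast_levels <- c("LgainBase", "LgainNeut", "SgainBase", "SgainNeut")

#' Enumerate the analytic-pipeline grid
#'
#' All combinations of smoothing kernel (5 FWHM levels), motion-correction
#' strategy, model parameterization (3) and task contrast (4). The default
#' motion grid has 4 options, giving `5 * 4 * 3 * 4 = 240` pipelines; the
#' full 6-option motion grid (`full_motion_grid = TRUE`) gives 360.
#'
#' @param full_motion_grid include the two mean-FD exclusion motion options
#'   (opt5, opt6)?
#' @return data.frame with columns `fwhm`, `motion`, `model`, `contrast`
#'   and a unique `pipeline` label, in a deterministic order (fwhm varies
#'   slowest, contrast fastest).
#' @examples
#' nrow(enumerate_pipelines())                        # 240
#' nrow(enumerate_pipelines(full_motion_grid = TRUE)) # 360
#' @export
enumerate_pipelines <- function(full_motion_grid = FALSE) {
  motion <- if (full_motion_grid) motion_levels_full else motion_levels_restricted
  g <- expand.grid(contrast = contrast_levels, model = model_levels,
                   motion = motion, fwhm = fwhm_levels,
                   stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)[, c("fwhm", "motion", "model", "contrast")]
  g <- g[order(match(g$fwhm, fwhm_levels), match(g$motion, motion),
               match(g$model, model_levels), match(g$contrast, contrast_levels)), ]
  rownames(g) <- NULL
  g$pipeline <- pipeline_label(g)
  g
}

pipeline_label <- function(g) {
  paste(g$fwhm, g$motion, g$model, g$contrast, sep = "_")
}

check_vocab <- function(records) {
  bad <- c(
    setdiff(unique(records$fwhm), fwhm_levels),
    setdiff(unique(records$motion), motion_levels_full),
    setdiff(unique(records$model), model_levels),
    setdiff(unique(records$contrast), contrast_levels)
  )
  if (length(bad) > 0L) {
    stop("unknown analytic option(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(records)
}

#' Build a specification curve from per-pipeline estimate records
#'
#' Aggregates one statistic (e.g. the median ICC) across samples for every
#' analytic pipeline and arranges the pipelines in ascending order of the
#' across-sample point estimate — the classic two-panel specification
#' curve: panel A is the ordered estimates with their 95% intervals, panel
#' B is the matrix of analytic decisions that produced each estimate.
#'
#' The across-sample interval is `mean +/- t(0.975, s-1) * SE` over the `s`
#' samples contributing to a pipeline; with a single sample the interval
#' degenerates to the point estimate. Each pipeline is classed against
#' `null_value`: `null_gray` when the interval spans it, otherwise
#' `positive_blue` / `negative_red` by the sign of the estimate relative to
#' the null. Ties in the point estimate are broken lexicographically by
#' pipeline label so the ordering is reproducible.
#'
#' @param records data.frame with columns `sample_id`, `fwhm`, `motion`,
#'   `model`, `contrast`, `statistic`, `value`; all records must share one
#'   statistic.
#' @param null_value reference value for significance classing (0 for ICC
#'   curves).
#' @param conf_level interval coverage (default 0.95).
#' @return object of class `specification_curve`: list with `curve` (one
#'   ordered row per pipeline: options, `estimate`, `lower`, `upper`,
#'   `n_samples`, `significance_class`, `rank`), `panel` (pipeline x
#'   option-level indicator matrix in curve order), `statistic`,
#'   `null_value`.
#' @export
build_specification_curve <- function(records, null_value = 0,
                                      conf_level = 0.95) {
  req <- c("sample_id", "fwhm", "motion", "model", "contrast", "statistic", "value")
  miss <- setdiff(req, names(records))
  if (length(miss) > 0L) {
    stop("records are missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  check_vocab(records)
  if (length(unique(records$statistic)) != 1L) {
    stop("records mix statistics; build one curve per statistic", call. = FALSE)
  }
  records$pipeline <- pipeline_label(records)

  agg <- lapply(split(records, records$pipeline), function(d) {
    s <- nrow(d)
    m <- mean(d$value)
    if (s > 1L) {
      se <- stats::sd(d$value) / sqrt(s)
      tq <- stats::qt(1 - (1 - conf_level) / 2, df = s - 1)
      lo <- m - tq * se
      hi <- m + tq * se
    } else {
      lo <- hi <- m
    }
    data.frame(pipeline = d$pipeline[1L], fwhm = d$fwhm[1L],
               motion = d$motion[1L], model = d$model[1L],
               contrast = d$contrast[1L], estimate = m, lower = lo,
               upper = hi, n_samples = s, stringsAsFactors = FALSE)
  })
  curve <- do.call(rbind, agg)
  curve$significance_class <- ifelse(
    curve$lower <= null_value & curve$upper >= null_value, "null_gray",
    ifelse(curve$estimate > null_value, "positive_blue", "negative_red"))
  curve <- curve[order(curve$estimate, curve$pipeline), ]
  curve$rank <- seq_len(nrow(curve))
  rownames(curve) <- NULL

  levels_all <- c(paste0("fwhm_", fwhm_levels),
                  paste0("motion_", motion_levels_full),
                  paste0("model_", model_levels),
                  paste0("contrast_", contrast_levels))
  panel <- matrix(0L, nrow = nrow(curve), ncol = length(levels_all),
                  dimnames = list(curve$pipeline, levels_all))
  panel[cbind(seq_len(nrow(curve)), match(paste0("fwhm_", curve$fwhm), levels_all))] <- 1L
  panel[cbind(seq_len(nrow(curve)), match(paste0("motion_", curve$motion), levels_all))] <- 1L
  panel[cbind(seq_len(nrow(curve)), match(paste0("model_", curve$model), levels_all))] <- 1L
  panel[cbind(seq_len(nrow(curve)), match(paste0("contrast_", curve$contrast), levels_all))] <- 1L
  panel <- panel[, colSums(panel) > 0L, drop = FALSE]

  structure(list(curve = curve, panel = panel,
                 statistic = records$statistic[1L],
                 null_value = null_value, conf_level = conf_level),
            class = "specification_curve")
}

#' Summarize per-pipeline maps over supra- and subthreshold masks
#'
#' Turns voxel-wise reliability maps (or similarity results) for a set of
#' pipelines into long-format estimate records: for each pipeline, the
#' masked medians of the ICC estimate, between-subject variance and
#' within-subject variance are taken separately over a suprathreshold
#' (task-positive) mask and a disjoint subthreshold mask. Similarity
#' results contribute their coefficient directly.
#'
#' @param results named list, one element per pipeline (names must match
#'   `options$pipeline` or row order), each a `reliability_maps` or
#'   `similarity_result`.
#' @param options data.frame of pipeline options (as from
#'   [enumerate_pipelines()]), one row per element of `results`.
#' @param supra_mask,sub_mask disjoint [brain_mask()]s on the shared grid.
#' @param sample_id label recorded on every emitted record.
#' @return data.frame of records: `sample_id`, options columns, `mask`
#'   (`"supra"`/`"sub"`), `statistic`, `value`.
#' @export
summarize_multiverse <- function(results, options, supra_mask, sub_mask,
                                 sample_id = "sample1") {
  supra_mask <- if (inherits(supra_mask, "brain_mask")) supra_mask else brain_mask(supra_mask)
  sub_mask <- if (inherits(sub_mask, "brain_mask")) sub_mask else brain_mask(sub_mask)
  if (!all(dim(supra_mask) == dim(sub_mask))) {
    stop("masks are not on a shared grid", call. = FALSE)
  }
  if (any(supra_mask & sub_mask)) {
    stop("supra- and subthreshold masks overlap", call. = FALSE)
  }
  if (length(results) != nrow(options)) {
    stop("one options row per result is required", call. = FALSE)
  }
  recs <- list()
  for (i in seq_along(results)) {
    r <- results[[i]]
    opt <- options[i, c("fwhm", "motion", "model", "contrast"), drop = FALSE]
    if (inherits(r, "reliability_maps")) {
      for (mk in c("supra", "sub")) {
        mask <- if (mk == "supra") supra_mask else sub_mask
        recs[[length(recs) + 1L]] <- data.frame(
          sample_id = sample_id, opt, mask = mk,
          statistic = c("median_icc", "median_bs", "median_ws"),
          value = c(masked_median(r$estimate, mask),
                    masked_median(r$between_subject_var, mask),
                    masked_median(r$within_subject_var, mask)),
          row.names = NULL, stringsAsFactors = FALSE)
      }
    } else if (inherits(r, "similarity_result")) {
      recs[[length(recs) + 1L]] <- data.frame(
        sample_id = sample_id, opt, mask = NA_character_,
        statistic = r$metric, value = r$coefficient,
        row.names = NULL, stringsAsFactors = FALSE)
    } else {
      stop("results must be reliability_maps or similarity_result objects",
           call. = FALSE)
    }
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' @export
print.specification_curve <- function(x, ...) {
  cat("specification_curve of ", x$statistic, " over ", nrow(x$curve),
      " pipelines (null = ", x$null_value, ")\n", sep = "")
  cls <- table(x$curve$significance_class)
  cat("  classes:", paste(names(cls), cls, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  estimates %.3f .. %.3f\n", min(x$curve$estimate),
              max(x$curve$estimate)))
  invisible(x)
}
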