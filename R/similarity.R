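#' Binarize a statistical map at a threshold
#'
#' Voxels become 1 where `value > threshold` (strictly greater; only the
#' positive tail is binarized, matching the use of one-sided activation
#' thresholds such as z > 3.1 or Cohen's d > 0.4 on group maps). A
#' threshold of exactly 0 is the "no thresholding" convention: every
#' in-mask voxel becomes 1, so any two maps binarized at 0 over the same
#' mask have similarity 1.
#'
#' @param stat_map 3D numeric array.
#' @param threshold finite scalar `>= 0`.
#' @param mask optional [brain_mask()]; voxels outside it are always 0.
#' @return logical 3D array (class `binary_map`); attribute `empty` flags
#'   an all-zero result.
#' @export
binarize <- function(stat_map, threshold, mask = NULL) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold < 0) {
    stop("'threshold' must be a single finite number >= 0", call. = FALSE)
  }
  if (length(dim(stat_map)) != 3L) stop("'stat_map' must be 3D", call. = FALSE)
  if (threshold == 0) {
    out <- array(TRUE, dim = dim(stat_map))
  } else {
    out <- array(as.numeric(stat_map) > threshold, dim = dim(stat_map))
  }
  if (!is.null(mask)) {
    mask <- if (inherits(mask, "brain_mask")) mask else brain_mask(mask)
    if (!all(dim(mask) == dim(stat_map))) {
      stop("mask and map dimensions differ", call. = FALSE)
    }
    out <- out & mask
  }
  structure(out, empty = !any(out), class = c("binary_map", "array"))
}

#' Similarity between two 3D statistical maps
#'
#' Binary overlap or rank correlation between two maps on a shared grid:
#'
#' * `jaccard` — `|A intersect B| / |A union B|` over binarized maps;
#' * `dice` — `2 |A intersect B| / (|A| + |B|)`;
#' * `spearman` — rank correlation (average ranks for ties) of the
#'   unthresholded in-mask values.
#'
#' For `jaccard`/`dice` a `threshold` is applied via [binarize()] unless
#' both inputs are already binary (logical or 0/1). An empty union, or zero
#' rank variance for `spearman`, yields an `NA` coefficient with a reason.
#'
#' @param img1,img2 3D numeric arrays on the same grid.
#' @param mask optional [brain_mask()].
#' @param threshold binarization threshold for the overlap metrics
#'   (ignored by `spearman`).
#' @param metric one of `"jaccard"`, `"dice"`, `"spearman"`.
#' @param labels length-2 character vector naming the images.
#' @return object of class `similarity_result`: list with `metric`,
#'   `coefficient`, `image_labels`, `threshold_used`, `reason` (NULL unless
#'   the coefficient is undefined).
#' @examples
#' a <- array(rnorm(64), c(4, 4, 4))
#' image_similarity(a, a^3, metric = "spearman")  # 1: monotone transform
#' @export
image_similarity <- function(img1, img2, mask = NULL, threshold = NULL,
                             metric = c("jaccard", "dice", "spearman"),
                             labels = c("img1", "img2")) {
  metric <- match.arg(metric)
  if (!identical(dim(img1), dim(img2))) {
    stop("images are not on a shared grid", call. = FALSE)
  }
  if (!is.null(mask)) {
    mask <- if (inherits(mask, "brain_mask")) mask else brain_mask(mask)
    if (!all(dim(mask) == dim(img1))) {
      stop("mask grid does not match the images", call. = FALSE)
    }
  }
  coefficient <- NA_real_
  reason <- NULL
  threshold_used <- NA_real_

  if (metric == "spearman") {
    sel <- if (is.null(mask)) rep(TRUE, length(img1)) else as.vector(mask)
    a <- as.vector(img1)[sel]
    b <- as.vector(img2)[sel]
    keep <- !is.na(a) & !is.na(b)
    a <- a[keep]; b <- b[keep]
    if (length(a) < 3L || length(unique(a)) < 2L || length(unique(b)) < 2L) {
      reason <- "zero rank variance"
    } else {
      coefficient <- stats::cor(a, b, method = "spearman")
    }
  } else {
    is_binary <- function(x) all(as.numeric(x) %in% c(0, 1))
    if (is.null(threshold)) {
      if (!(is_binary(img1) && is_binary(img2))) {
        stop("overlap metrics need a 'threshold' unless both images are binary",
             call. = FALSE)
      }
      b1 <- array(as.numeric(img1) > 0, dim = dim(img1))
      b2 <- array(as.numeric(img2) > 0, dim = dim(img2))
      if (!is.null(mask)) { b1 <- b1 & mask; b2 <- b2 & mask }
    } else {
      b1 <- binarize(img1, threshold, mask)
      b2 <- binarize(img2, threshold, mask)
      threshold_used <- threshold
    }
    inter <- sum(b1 & b2)
    union <- sum(b1 | b2)
    if (union == 0L) {
      reason <- "empty union"
    } else if (metric == "jaccard") {
      coefficient <- inter / union
    } else {
      coefficient <- 2 * inter / (sum(b1) + sum(b2))
    }
  }
  structure(list(metric = metric, coefficient = coefficient,
                 image_labels = labels, threshold_used = threshold_used,
                 reason = reason),
            class = "similarity_result")
}

#' Pairwise similarity table for a set of labelled maps
#'
#' Computes [image_similarity()] for every unordered pair of `m >= 2`
#' images, giving `choose(m, 2)` rows. Undefined pairs keep their row with
#' an `NA` coefficient and the reason.
#'
#' @param images named list of 3D numeric arrays on a shared grid (names
#'   are the image labels; unnamed lists get `img1..imgm`).
#' @inheritParams image_similarity
#' @return data.frame with columns `image_i`, `image_j`, `metric`,
#'   `coefficient`, `threshold`, `reason`.
#' @export
pairwise_similarity <- function(images, mask = NULL, threshold = NULL,
                                metric = c("jaccard", "dice", "spearman")) {
  metric <- match.arg(metric)
  if (!is.list(images) || length(images) < 2L) {
    stop("need at least 2 images", call. = FALSE)
  }
  if (is.null(names(images)) || any(names(images) == "")) {
    names(images) <- paste0("img", seq_along(images))
  }
  pairs <- utils::combn(names(images), 2L)
  rows <- apply(pairs, 2L, function(p) {
    res <- image_similarity(images[[p[1L]]], images[[p[2L]]], mask = mask,
                            threshold = threshold, metric = metric,
                            labels = p)
    data.frame(image_i = p[1L], image_j = p[2L], metric = metric,
               coefficient = res$coefficient,
               threshold = res$threshold_used,
               reason = if (is.null(res$reason)) NA_character_ else res$reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.similarity_result <- function(x, ...) {
  if (is.na(x$coefficient)) {
    cat(x$metric, " similarity undefined (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("%s(%s, %s) = %.4f", x$metric, x$image_labels[1L],
                x$image_labels[2L], x$coefficient))
    if (!is.na(x$threshold_used)) {
      cat(sprintf(" [threshold %g]", x$threshold_used))
    }
    cat("\n")
  }
  invisible(x)
}
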