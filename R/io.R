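#' Load a volume set from an ordered manifest
#'
#' A manifest makes subject pairing across occasions auditable: it is an
#' explicit ordered table (TSV with header columns `occasion` and `path`,
#' or a named list of character vectors), one row per volume, where row
#' order within each occasion defines subject order. Globbing is
#' deliberately unsupported. All volumes must be readable NIfTI-1 files on
#' one grid.
#'
#' @param manifest path to a TSV file, a data.frame with columns
#'   `occasion` and `path`, or a list of character path vectors (one
#'   element per occasion).
#' @return a [volume_set()].
#' @export
load_volume_set <- function(manifest) {
  if (is.character(manifest) && length(manifest) == 1L) {
    manifest <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  }
  if (is.data.frame(manifest)) {
    if (!all(c("occasion", "path") %in% names(manifest))) {
      stop("manifest needs columns 'occasion' and 'path'", call. = FALSE)
    }
    occ_ids <- unique(manifest$occasion)
    paths <- lapply(occ_ids, function(o) manifest$path[manifest$occasion == o])
    names(paths) <- as.character(occ_ids)
  } else if (is.list(manifest)) {
    paths <- manifest
    if (is.null(names(paths))) names(paths) <- paste0("occ", seq_along(paths))
  } else {
    stop("unsupported manifest type", call. = FALSE)
  }
  if (length(paths) < 2L) {
    stop("manifest must list at least 2 occasions", call. = FALSE)
  }
  lens <- lengths(paths)
  if (any(lens == 0L)) {
    stop("empty occasion list: ", paste(names(paths)[lens == 0L], collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(lens)) != 1L) {
    stop("unequal volume counts across occasions: ",
         paste(names(paths), lens, sep = "=", collapse = ", "), call. = FALSE)
  }
  ref_grid <- NULL
  occasions <- lapply(paths, function(pp) {
    vols <- lapply(pp, function(p) {
      if (!file.exists(p)) stop("unreadable file: ", p, call. = FALSE)
      img <- RNifti::readNifti(p)
      g <- volume_grid(dim(img)[1:3], RNifti::pixdim(img)[1:3])
      if (is.null(ref_grid)) {
        ref_grid <<- g
      } else if (!same_grid(ref_grid, g)) {
        stop("grid mismatch in file: ", p, " (",
             paste(g$dims, collapse = "x"), " vs ",
             paste(ref_grid$dims, collapse = "x"), ")", call. = FALSE)
      }
      array(as.numeric(img), dim = dim(img)[1:3])
    })
    vols
  })
  volume_set(occasions, grid = ref_grid, occasion_ids = names(paths))
}

#' Load a binary brain mask from a NIfTI file
#'
#' Nonzero voxels become in-mask (`value > 0`).
#'
#' @param path NIfTI-1 file.
#' @return a [brain_mask()].
#' @export
load_mask <- function(path) {
  if (!file.exists(path)) stop("unreadable file: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  brain_mask(array(as.numeric(img), dim = dim(img)[1:3]),
             grid = volume_grid(dim(img)[1:3], RNifti::pixdim(img)[1:3]))
}

#' Write a 3D array as NIfTI-1
#'
#' @param map 3D numeric array (`NA` written as `NaN`).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param grid optional [volume_grid()] supplying voxel sizes.
#' @return the path, invisibly.
#' @export
write_volume <- function(map, path, grid = NULL) {
  img <- RNifti::asNifti(map)
  if (!is.null(grid)) {
    RNifti::pixdim(img) <- grid$pixdim
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write reliability maps to a directory
#'
#' One NIfTI file per map (`<prefix>_estimate.nii.gz`, `_lower`, `_upper`,
#' `_bs_var`, `_ws_var`, and `_bm_var` for `icc_2`).
#'
#' @param maps a `reliability_maps` object from [voxelwise_icc()].
#' @param dir output directory (created if missing).
#' @param prefix filename prefix.
#' @return named character vector of written paths, invisibly.
#' @export
write_reliability_maps <- function(maps, dir, prefix = "icc") {
  stopifnot(inherits(maps, "reliability_maps"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  slots <- c(estimate = "estimate", lower = "lower", upper = "upper",
             bs_var = "between_subject_var", ws_var = "within_subject_var")
  if (maps$icc_type == "icc_2") slots <- c(slots, bm_var = "between_measure_var")
  paths <- vapply(names(slots), function(s) {
    p <- file.path(dir, paste0(prefix, "_", s, ".nii.gz"))
    write_volume(maps[[slots[[s]]]], p, maps$grid)
    p
  }, character(1L))
  invisible(paths)
}

#' Write a data frame as UTF-8 TSV
#'
#' Header row included; missing values written as `NA`.
#'
#' @param df data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}
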