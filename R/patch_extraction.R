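# Stage 1: tissue masking, patch-grid generation, hematoxylin filtering.

#' Configuration of the patch-extraction stage
#'
#' @param gray_threshold 8-bit grayscale cutoff; a downsampled pixel is
#'   tissue iff its BT.601 luma is strictly below this value (glass is
#'   brighter than stained tissue). The boundary value itself counts as
#'   background. Default 170.
#' @param min_object_area_px Connected tissue components smaller than
#'   this (in mask-scale pixels) are discarded as debris. Default 64.
#' @param mask_downsample Integer factor by which the slide is
#'   block-averaged before thresholding. Default 32.
#' @param patch_size Side of the square patches in level-0 pixels.
#'   Default 768.
#' @param h_threshold Minimum mean hematoxylin density (see
#'   [hematoxylin_mean()]) for a patch to be considered cell-rich;
#'   patches at or above the threshold are kept. Default 0.017. The
#'   numeric scale is tied to the stain-separation convention of
#'   [rgb_to_hed()]; recalibrate when using a different deconvolution.
#' @param tissue_fraction_min Minimum fraction of a patch footprint that
#'   must be tissue (at mask scale) for the patch to become a candidate.
#'   Default 0.1: permissive, so that boundary tumor tissue survives to
#'   the content-based H-filter.
#' @param read_level Pyramid level (1-based) from which patches are read
#'   for H-filtering; default 1 (full resolution).
#' @return An object of class `til_extraction_config`.
#' @export
extraction_config <- function(gray_threshold = 170,
                              min_object_area_px = 64,
                              mask_downsample = 32L,
                              patch_size = 768L,
                              h_threshold = 0.017,
                              tissue_fraction_min = 0.1,
                              read_level = 1L) {
  if (gray_threshold <= 0 || gray_threshold >= 255)
    til_error("gray_threshold must lie strictly between 0 and 255",
              "til_config_error")
  if (!is_count(mask_downsample) || mask_downsample < 1)
    til_error("mask_downsample must be a positive integer", "til_config_error")
  if (!is_count(patch_size) || patch_size < 1)
    til_error("patch_size must be a positive integer", "til_config_error")
  if (h_threshold < 0)
    til_error("h_threshold must be >= 0", "til_config_error")
  structure(
    list(gray_threshold = gray_threshold,
         min_object_area_px = min_object_area_px,
         mask_downsample = as.integer(mask_downsample),
         patch_size = as.integer(patch_size),
         h_threshold = h_threshold,
         tissue_fraction_min = tissue_fraction_min,
         read_level = as.integer(read_level)),
    class = "til_extraction_config"
  )
}

#' Compute the tissue mask of a slide
#'
#' Block-averages the full-resolution slide by `mask_downsample`,
#' converts to grayscale (BT.601 luma), and thresholds: a mask pixel is
#' tissue iff its luma is strictly below `gray_threshold`. Connected
#' components smaller than `min_object_area_px` are then removed as
#' small tissue outliers and artifacts.
#'
#' @param slide A `til_slide` from [open_slide()].
#' @param cfg An [extraction_config()].
#' @return A list of class `til_mask` with `mask` (logical matrix,
#'   `[y, x]`) and `scale` (the downsample factor relative to level 0).
#' @export
compute_tissue_mask <- function(slide, cfg = extraction_config()) {
  stopifnot(inherits(slide, "til_slide"))
  img <- slide$pages[[1L]]
  lum <- block_mean(luma255(img), cfg$mask_downsample)
  mask <- lum < cfg$gray_threshold
  if (any(mask) && cfg$min_object_area_px > 0) {
    lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
    areas <- tabulate(as.integer(lab))
    small <- which(areas < cfg$min_object_area_px)
    if (length(small) > 0L) mask[matrix(as.integer(lab), nrow(mask)) %in% small] <- FALSE
  }
  structure(list(mask = mask, scale = cfg$mask_downsample), class = "til_mask")
}

#' Generate candidate patches from a tissue mask
#'
#' Lays a non-overlapping grid of `patch_size` squares anchored at
#' (0, 0) over the slide; partial edge patches are dropped. A grid cell
#' becomes a candidate iff the tissue fraction of its footprint in the
#' mask is at least `tissue_fraction_min`. Output is sorted by (y, x).
#'
#' @param mask A `til_mask` from [compute_tissue_mask()].
#' @param slide The `til_slide` the mask was computed from.
#' @param cfg An [extraction_config()].
#' @param slide_id Identifier stored in the patch table (defaults to the
#'   slide's file name without extension).
#' @return A `til_patches` data.frame of candidate patches.
#' @export
mask_to_patch_grid <- function(mask, slide, cfg = extraction_config(),
                               slide_id = NULL) {
  stopifnot(inherits(mask, "til_mask"), inherits(slide, "til_slide"))
  slide_id <- slide_id %||% tools::file_path_sans_ext(basename(slide$path))
  P <- cfg$patch_size
  s <- mask$scale
  M <- mask$mask
  if (slide$width0 < P || slide$height0 < P) return(empty_patch_records())
  xs <- seq.int(0L, slide$width0 - P, by = P)
  ys <- seq.int(0L, slide$height0 - P, by = P)
  keep_x <- integer(0); keep_y <- integer(0)
  for (y in ys) {
    rows <- (y %/% s + 1L):min(nrow(M), (y + P - 1L) %/% s + 1L)
    for (x in xs) {
      cols <- (x %/% s + 1L):min(ncol(M), (x + P - 1L) %/% s + 1L)
      if (mean(M[rows, cols]) >= cfg$tissue_fraction_min) {
        keep_x <- c(keep_x, x); keep_y <- c(keep_y, y)
      }
    }
  }
  patch_records(slide_id, keep_x, keep_y, P)
}

#' Filter candidate patches by mean hematoxylin density
#'
#' Reads each candidate patch at `cfg$read_level`, computes its mean
#' hematoxylin density after stain separation, and keeps exactly the
#' patches whose mean is at or above `cfg$h_threshold`. Kept records
#' store the measured value in `h_mean`; input order is preserved and
#' the output is a subset of the input.
#'
#' @param candidates A `til_patches` data.frame from
#'   [mask_to_patch_grid()].
#' @param slide The `til_slide` the candidates refer to.
#' @param cfg An [extraction_config()].
#' @return The retained `til_patches` subset with `h_mean` filled.
#' @export
h_filter <- function(candidates, slide, cfg = extraction_config()) {
  stopifnot(inherits(slide, "til_slide"))
  n <- nrow(candidates)
  if (n == 0L) return(candidates)
  ds <- slide$downsample[cfg$read_level]
  hm <- vapply(seq_len(n), function(i) {
    P_lvl <- as.integer(candidates$patch_size[i] / ds)
    patch <- read_region(slide, candidates$x[i], candidates$y[i],
                         P_lvl, P_lvl, level = cfg$read_level)
    hematoxylin_mean(patch)
  }, numeric(1))
  candidates$h_mean <- hm
  out <- candidates[hm >= cfg$h_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}
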