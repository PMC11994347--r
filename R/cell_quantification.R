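# Stage 3: nucleus detection, lymphocyte counting, density scoring.
#
# The quantifier is a pluggable contract: any object of class
# "til_quantifier" with a deterministic
#   quantify(patch_rgb, record = NULL)
# returning a data.frame of detections (x, y patch-local 0-based pixel
# centers; cell_kind in {lymphocyte, other}; area_px) can stand in. A
# trained segmentation network (e.g. a HoVer-Net-family model) plugs
# into the same seat through a thin adapter; this package ships a
# classical reference detector and a ground-truth oracle.

new_quantifier <- function(name, quantify, needs_pixels = TRUE) {
  structure(list(name = name, quantify = quantify, needs_pixels = needs_pixels),
            class = "til_quantifier")
}

#' @export
print.til_quantifier <- function(x, ...) {
  cat(sprintf("<til_quantifier> %s\n", x$name)); invisible(x)
}

empty_detections <- function() {
  data.frame(x = numeric(0), y = numeric(0), cell_kind = character(0),
             area_px = numeric(0))
}

#' Parameters of the classical reference nucleus detector
#'
#' Stand-in parameters for a lymphocyte-sized nucleus at roughly
#' 0.25-0.5 um/px; they describe this detector, not any trained model.
#'
#' @param h_od_min Hematoxylin density above which a pixel is nuclear.
#' @param min_area,max_area Connected-component area bounds in pixels;
#'   components outside are discarded.
#' @param lymph_area_max Maximum area of a lymphocyte nucleus (larger
#'   nuclei are classified "other").
#' @param circ_min Minimum circularity `4*pi*A/P^2` for a lymphocyte
#'   (lymphocytes are small and round).
#' @return A list of class `til_detect_params`.
#' @export
detect_params <- function(h_od_min = 0.05, min_area = 20, max_area = 600,
                          lymph_area_max = 250, circ_min = 0.7) {
  structure(list(h_od_min = h_od_min, min_area = min_area, max_area = max_area,
                 lymph_area_max = lymph_area_max, circ_min = circ_min),
            class = "til_detect_params")
}

#' Classical reference nucleus detector
#'
#' Thresholds the hematoxylin channel, labels connected components,
#' discards components with area outside `[min_area, max_area]`, and
#' classifies each remaining component as lymphocyte iff its area is at
#' most `lymph_area_max` and its circularity at least `circ_min`, else
#' "other".
#'
#' @param patch_rgb Numeric array `[h, w, 3]` in `[0, 1]`.
#' @param params A [detect_params()].
#' @return A data.frame of detections: `x`, `y` (patch-local 0-based
#'   centroid coordinates), `cell_kind`, `area_px`.
#' @export
reference_detect <- function(patch_rgb, params = detect_params()) {
  hed <- rgb_to_hed(patch_rgb)
  bin <- matrix(as.numeric(hed[, , 1L] > params$h_od_min),
                dim(patch_rgb)[1L], dim(patch_rgb)[2L])
  lab <- EBImage::bwlabel(bin)
  nlab <- max(lab)
  if (nlab == 0) return(empty_detections())
  shape <- EBImage::computeFeatures.shape(lab)
  mom <- EBImage::computeFeatures.moment(lab)
  area <- shape[, "s.area"]
  perim <- pmax(shape[, "s.perimeter"], 1)
  circ <- pmin(1, 4 * pi * area / perim^2)
  keep <- area >= params$min_area & area <= params$max_area
  if (!any(keep)) return(empty_detections())
  # the label matrix is [y, x], so EBImage's first moment axis is our y
  data.frame(
    x = unname(mom[keep, "m.cy"]) - 1,
    y = unname(mom[keep, "m.cx"]) - 1,
    cell_kind = ifelse(area[keep] <= params$lymph_area_max &
                         circ[keep] >= params$circ_min, "lymphocyte", "other"),
    area_px = unname(area[keep])
  )
}

#' Reference quantifier (classical detector behind the contract)
#'
#' @param params A [detect_params()].
#' @return A `til_quantifier` wrapping [reference_detect()].
#' @export
reference_quantifier <- function(params = detect_params()) {
  new_quantifier(
    "reference",
    function(patch_rgb, record = NULL) reference_detect(patch_rgb, params),
    needs_pixels = TRUE
  )
}

#' Ground-truth oracle quantifier
#'
#' Returns the planted nuclei whose centers lie inside the patch
#' footprint (centroid assignment: a nucleus straddling a patch border
#' belongs to the patch containing its center, so counts partition
#' exactly across a patch grid).
#'
#' @param truth A `til_ground_truth` from [generate_slide()].
#' @param nucleus_radius_px Radii used to report detection areas.
#' @return A `til_quantifier` (does not read pixels).
#' @export
oracle_quantifier <- function(truth,
                              nucleus_radius_px = c(lymphocyte = 6, other = 9)) {
  stopifnot(inherits(truth, "til_ground_truth"))
  nuc <- truth$nuclei
  new_quantifier(
    "oracle",
    function(patch_rgb, record = NULL) {
      if (is.null(record))
        til_error("oracle quantifier needs the patch record", "til_contract_error")
      P <- record$patch_size
      inside <- nuc$x >= record$x & nuc$x < record$x + P &
                nuc$y >= record$y & nuc$y < record$y + P
      sub <- nuc[inside, , drop = FALSE]
      if (nrow(sub) == 0L) return(empty_detections())
      r <- nucleus_radius_px[sub$cell_kind]
      data.frame(x = sub$x - record$x, y = sub$y - record$y,
                 cell_kind = sub$cell_kind, area_px = round(pi * r^2))
    },
    needs_pixels = FALSE
  )
}

#' Per-patch TIL density (cells/mm²)
#'
#' Normalizes a raw lymphocyte count by the physical patch area:
#' `d = c / (patch_size * mpp)^2 * 1e6`, where `patch_size * mpp` is the
#' patch side in microns and the factor 1e6 converts square microns to
#' square millimeters.
#'
#' @param til_count Non-negative count(s) of lymphocytes in the patch.
#' @param patch_size Patch side in pixels.
#' @param mpp Microns per pixel of the slide level the patch was read at.
#' @return Density in cells per square millimeter (vectorized over
#'   `til_count`).
#' @export
#' @examples
#' patch_density(100, 768, 0.25)  # ~2712.67 cells/mm^2
patch_density <- function(til_count, patch_size, mpp) {
  if (!is_pos_scalar(patch_size) || !is_pos_scalar(mpp))
    til_error("patch_size and mpp must be positive", "til_domain_error")
  if (any(til_count < 0))
    til_error("til_count must be non-negative", "til_domain_error")
  til_count / (patch_size * mpp)^2 * 1e6
}

#' Slide-level TIL score
#'
#' The arithmetic mean of the per-patch densities of a slide. A slide
#' with no retained patches has *no score*: an empty input raises a
#' `til_empty_error` rather than returning 0, because 0 would masquerade
#' as "no TILs" when the slide is simply unevaluable.
#'
#' @param densities Numeric vector of per-patch densities (cells/mm²).
#' @return The mean density.
#' @export
slide_score <- function(densities) {
  if (length(densities) == 0L)
    til_error("slide has no retained patches: no score (unevaluable)",
              "til_empty_error")
  mean(densities)
}

#' Patient-level TIL score
#'
#' The mean of the per-slide means over the patient's `k` slides — not
#' the pooled patch mean, so each slide contributes equally regardless
#' of its patch count. Reduces to [slide_score()] when `k = 1`.
#'
#' @param per_slide_densities A list with one numeric vector of patch
#'   densities per slide.
#' @return The patient score.
#' @export
#' @examples
#' patient_score(list(rep(100, 10), 300))  # 200, not the pooled 118.2
patient_score <- function(per_slide_densities) {
  if (length(per_slide_densities) == 0L)
    til_error("patient has no slides: no score", "til_empty_error")
  mean(vapply(per_slide_densities, slide_score, numeric(1)))
}

#' Count lymphocytes and attach densities to patch records
#'
#' Runs the quantifier on every record (preserving order), stores the
#' lymphocyte count `til_count` and the density `d = c/(P*mpp)^2*1e6`,
#' and aggregates the slide-level score.
#'
#' @param records Labeled, prognostically filtered `til_patches`.
#' @param slide The `til_slide` the records refer to.
#' @param quantifier A `til_quantifier`.
#' @return A list with `records` (annotated) and `result`, a
#'   `til_slide_result`: `slide_id`, `n_patches`, `til_score` (`NA` with
#'   `evaluable = FALSE` when no patches remain), and `mpp`.
#' @export
quantify_patches <- function(records, slide, quantifier) {
  stopifnot(inherits(quantifier, "til_quantifier"))
  n <- nrow(records)
  for (i in seq_len(n)) {
    rec <- records[i, ]
    patch <- if (quantifier$needs_pixels)
      read_region(slide, rec$x, rec$y, rec$patch_size, rec$patch_size) else NULL
    det <- tryCatch(
      quantifier$quantify(patch, record = rec),
      error = function(e)
        til_error(sprintf("quantification failed at patch (x=%d, y=%d): %s",
                          rec$x, rec$y, conditionMessage(e)),
                  "til_contract_error"))
    records$til_count[i] <- sum(det$cell_kind == "lymphocyte")
    records$density[i] <- patch_density(records$til_count[i],
                                        rec$patch_size, slide$mpp)
  }
  result <- structure(
    list(
      slide_id = if (n > 0L) records$slide_id[1L]
                 else tools::file_path_sans_ext(basename(slide$path)),
      n_patches = n,
      til_score = if (n > 0L) slide_score(records$density) else NA_real_,
      evaluable = n > 0L,
      mpp = slide$mpp
    ),
    class = "til_slide_result"
  )
  list(records = records, result = result)
}

#' @export
print.til_slide_result <- function(x, ...) {
  cat(sprintf("<til_slide_result> %s: %s (n_patches = %d)\n", x$slide_id,
              if (x$evaluable) sprintf("TIL score %.1f cells/mm^2", x$til_score)
              else "unevaluable (no tumor/stroma patches)",
              x$n_patches))
  invisible(x)
}
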