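# Ruifrok-Johnston color deconvolution into the
# hematoxylin-eosin-DAB (HED) stain space.

# Optical-density stain vectors (rows: H, E, DAB) from Ruifrok & Johnston
# (2001), the standard calibration used by mainstream imaging libraries.
rgb_from_hed_matrix <- matrix(
  c(0.65, 0.70, 0.29,
    0.07, 0.99, 0.11,
    0.27, 0.57, 0.78),
  nrow = 3, byrow = TRUE,
  dimnames = list(c("h", "e", "d"), c("r", "g", "b"))
)
hed_from_rgb_matrix <- solve(rgb_from_hed_matrix)

#' Separate an RGB image into hematoxylin, eosin and DAB stain channels
#'
#' Performs Ruifrok-Johnston color deconvolution: pixel values are mapped
#' to optical density with a logarithm normalized so that an intensity of
#' `1e-6` (practically black) has unit OD, multiplied by the inverse of
#' the standard HED stain matrix, and clipped at zero. A pure-white pixel
#' has zero density in all three stains.
#'
#' The numeric scale follows the convention of mainstream scientific
#' imaging libraries, so thresholds such as the default hematoxylin
#' cutoff of 0.017 in [extraction_config()] are directly comparable.
#'
#' @param img Numeric array `[h, w, 3]` with values in `[0, 1]`.
#' @return Numeric array `[h, w, 3]`: hematoxylin, eosin, DAB densities.
#' @export
#' @examples
#' px <- array(c(70, 40, 110) / 255, c(1, 1, 3))  # dark-violet nucleus
#' rgb_to_hed(px)[1, 1, ]
rgb_to_hed <- function(img) {
  d <- dim(img)
  if (length(d) != 3L || d[3] != 3L)
    til_error("rgb_to_hed() expects an [h, w, 3] RGB array", "til_domain_error")
  m <- matrix(pmax(img, 1e-6), ncol = 3L)
  stains <- (log(m) / log(1e-6)) %*% hed_from_rgb_matrix
  stains[stains < 0] <- 0
  array(stains, d)
}

#' Mean hematoxylin density of a patch
#'
#' The mean of the hematoxylin channel after stain separation; it grows
#' with nuclear content and is the statistic compared against the
#' `h_threshold` of [extraction_config()] by [h_filter()]. Deterministic
#' and invariant to spatial rearrangement of pixels.
#'
#' @param patch_rgb Numeric array `[h, w, 3]` in `[0, 1]`.
#' @return A single non-negative number; exactly 0 for a pure-white patch.
#' @export
#' @examples
#' hematoxylin_mean(array(1, c(4, 4, 3)))  # white glass -> 0
hematoxylin_mean <- function(patch_rgb) {
  mean(rgb_to_hed(patch_rgb)[, , 1L])
}
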