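# Heatmap rendering of per-patch TIL densities.

#' Heatmap rendering options
#'
#' @param clip_max Densities above this value are painted like
#'   `clip_max` itself (default 10000 cells/mm²; extreme outlier patches
#'   would otherwise compress the scale).
#' @param colormap Palette name understood by [grDevices::hcl.colors()].
#' @param overlay_downsample Integer scale of the rendered overlay
#'   relative to level 0; full-resolution overlays are unnecessary for
#'   inspection and expensive.
#' @param alpha Blending weight of the heat color over the tissue.
#' @return A list of class `til_heatmap_spec`.
#' @export
heatmap_spec <- function(clip_max = 10000, colormap = "viridis",
                         overlay_downsample = 32L, alpha = 0.6) {
  if (!is_pos_scalar(clip_max))
    til_error("clip_max must be > 0", "til_config_error")
  if (alpha < 0 || alpha > 1)
    til_error("alpha must lie in [0, 1]", "til_config_error")
  structure(list(clip_max = clip_max, colormap = colormap,
                 overlay_downsample = as.integer(overlay_downsample),
                 alpha = alpha),
            class = "til_heatmap_spec")
}

#' Render a TIL-density heatmap over a slide
#'
#' Downsamples the slide to the overlay scale and alpha-blends each
#' patch footprint with the colormap value of its clipped, normalized
#' density `min(density, clip_max) / clip_max`. Pixels outside retained
#' patch footprints keep the plain downsampled slide. A vertical
#' colorbar spanning 0 to `clip_max` (maximum at the top) is appended on
#' the right, separated by a white gutter.
#'
#' @param slide A `til_slide`.
#' @param records `til_patches` with the `density` column filled.
#' @param spec A [heatmap_spec()].
#' @return An RGB array; `attr(, "body_width")` gives the width of the
#'   slide portion (columns beyond it are the gutter and colorbar), and
#'   `attr(, "clip_max")` the color scale maximum.
#' @export
render_heatmap <- function(slide, records, spec = heatmap_spec()) {
  stopifnot(inherits(slide, "til_slide"))
  if (nrow(records) > 0L && anyNA(records$density))
    til_error("every record must carry a density before rendering",
              "til_contract_error")
  s <- spec$overlay_downsample
  img <- slide$pages[[1L]]
  base <- lapply(1:3, function(k) block_mean(img[, , k], s))
  H <- nrow(base[[1L]]); W <- ncol(base[[1L]])
  pal <- grDevices::hcl.colors(256L, spec$colormap)
  pal_rgb <- grDevices::col2rgb(pal) / 255
  for (i in seq_len(nrow(records))) {
    v <- min(records$density[i], spec$clip_max) / spec$clip_max
    col <- pal_rgb[, 1L + as.integer(round(v * 255))]
    P <- records$patch_size[i]
    rows <- (records$y[i] %/% s + 1L):min(H, (records$y[i] + P - 1L) %/% s + 1L)
    cols <- (records$x[i] %/% s + 1L):min(W, (records$x[i] + P - 1L) %/% s + 1L)
    for (k in 1:3)
      base[[k]][rows, cols] <- (1 - spec$alpha) * base[[k]][rows, cols] +
        spec$alpha * col[k]
  }
  bar_w <- max(4L, W %/% 40L)
  gut_w <- max(2L, bar_w %/% 2L)
  # colorbar: top row = clip_max, bottom row = 0
  bar_idx <- 1L + as.integer(round(rev(seq(0, 1, length.out = H)) * 255))
  out <- array(1, c(H, W + gut_w + bar_w, 3L))
  for (k in 1:3) {
    out[, seq_len(W), k] <- base[[k]]
    out[, (W + gut_w + 1L):(W + gut_w + bar_w), k] <- pal_rgb[k, bar_idx]
  }
  attr(out, "body_width") <- W
  attr(out, "clip_max") <- spec$clip_max
  attr(out, "colormap") <- spec$colormap
  out
}
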