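# Slide access and patch-table I/O.
#
# Slides are flat or multi-page (pyramidal) TIFFs, or flat PNGs. A
# multi-page TIFF is interpreted as a resolution pyramid: page 1 is the
# base level and later pages are progressively downsampled versions of
# it. A flat image is a 1-level pyramid. Images are held in memory as
# numeric [h, w, 3] arrays in [0, 1], which is adequate at the slide
# sizes this package targets (synthetic fixtures and region exports, not
# gigapixel scans).
#
# Microns-per-pixel (mpp) is resolved in this order: explicit override,
# TIFF resolution tags, then a JSON sidecar "<path>.mpp.json" with a
# single field {"mpp": <number>} as written by generate_slide(). The
# tiff package cannot write resolution tags, hence the sidecar.

#' Open a slide image
#'
#' Reads a pyramidal (multi-page) or flat TIFF, or a flat PNG, and
#' returns a slide handle carrying level-0 dimensions, per-level
#' downsample factors, and the microns-per-pixel (mpp) of level 0.
#'
#' @param path Path to a TIFF or PNG image.
#' @param mpp_override Optional positive number; wins over any metadata.
#' @return An object of class `til_slide`: a list with elements `path`,
#'   `width0`, `height0`, `levels`, `downsample` (numeric vector, level 1
#'   = 1.0, strictly increasing), `mpp`, and `pages` (list of pixel
#'   arrays, one per level).
#' @details Levels are indexed from 1 in R; level 1 is the full
#'   resolution ("level 0" in 0-based conventions). If the file carries
#'   no resolution metadata and no sidecar, `mpp_override` is required.
#' @export
#' @seealso [read_region()], [generate_slide()]
open_slide <- function(path, mpp_override = NULL) {
  if (!file.exists(path))
    til_error(sprintf("slide file not found: %s", path), "til_io_error")
  if (!is.null(mpp_override) && !is_pos_scalar(mpp_override))
    til_error("mpp_override must be a positive number", "til_config_error")
  ext <- tolower(tools::file_ext(path))
  meta_mpp <- NULL
  if (ext %in% c("tif", "tiff")) {
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                      error = function(e)
                        til_error(sprintf("cannot read '%s' as TIFF: %s",
                                          path, conditionMessage(e)),
                                  "til_io_error"))
    if (!is.list(pages)) pages <- list(pages)
    a <- attributes(pages[[1L]])
    if (!is.null(a$x.resolution) && is.numeric(a$x.resolution) && a$x.resolution > 0) {
      unit <- a$res.unit %||% "inch"
      um_per_unit <- switch(unit, inch = 25400, cm = 10000, NA_real_)
      if (is.finite(um_per_unit)) meta_mpp <- um_per_unit / a$x.resolution
    }
  } else if (ext == "png") {
    img <- tryCatch(png::readPNG(path),
                    error = function(e)
                      til_error(sprintf("cannot read '%s' as PNG: %s",
                                        path, conditionMessage(e)),
                                "til_io_error"))
    pages <- list(img)
  } else {
    til_error(sprintf("unsupported slide format '.%s' (need TIFF or PNG)", ext),
              "til_io_error")
  }
  pages <- lapply(pages, normalize_page)
  sidecar <- paste0(path, ".mpp.json")
  if (is.null(meta_mpp) && file.exists(sidecar)) {
    sc <- jsonlite::fromJSON(sidecar)
    if (is_pos_scalar(sc$mpp)) meta_mpp <- sc$mpp
  }
  mpp <- mpp_override %||% meta_mpp
  if (is.null(mpp))
    til_error(paste0("no microns-per-pixel (mpp) metadata found for '", path,
                     "'; supply mpp_override"), "til_config_error")
  h0 <- dim(pages[[1L]])[1L]
  w0 <- dim(pages[[1L]])[2L]
  ds <- vapply(pages, function(p) w0 / dim(p)[2L], numeric(1))
  if (any(diff(ds) <= 0))
    til_error("pyramid levels must be strictly decreasing in size", "til_io_error")
  structure(
    list(path = path, width0 = w0, height0 = h0, levels = length(pages),
         downsample = ds, mpp = mpp, pages = pages),
    class = "til_slide"
  )
}

# Coerce a decoded page to a numeric [h, w, 3] array in [0, 1].
normalize_page <- function(p) {
  if (length(dim(p)) == 2L) p <- array(rep(p, 3L), c(dim(p), 3L))
  if (dim(p)[3L] > 3L) p <- p[, , 1:3, drop = FALSE]
  if (dim(p)[3L] != 3L)
    til_error("slide pages must be grayscale or RGB", "til_io_error")
  p
}

#' @export
print.til_slide <- function(x, ...) {
  cat(sprintf("<til_slide> %s\n  level 0: %d x %d px, mpp %.4g um/px, %d level(s)\n",
              x$path, x$width0, x$height0, x$mpp, x$levels))
  invisible(x)
}

#' Read a rectangular region from a slide level
#'
#' Coordinates are given in the level-0 pixel frame (0-based, top-left
#' origin) and mapped to the requested level by its downsample factor;
#' `w` and `h` are the output size in pixels *at that level*.
#'
#' @param slide A `til_slide` from [open_slide()].
#' @param x,y Level-0 coordinates of the region's top-left corner.
#' @param w,h Output width and height in pixels at `level`.
#' @param level Pyramid level, 1-based (1 = full resolution).
#' @return Numeric array `[h, w, 3]` in `[0, 1]`.
#' @export
read_region <- function(slide, x, y, w, h, level = 1L) {
  stopifnot(inherits(slide, "til_slide"))
  if (level < 1L || level > slide$levels)
    til_error(sprintf("level %d out of range (slide has %d)", level, slide$levels),
              "til_bounds_error")
  ds <- slide$downsample[level]
  page <- slide$pages[[level]]
  xl <- floor(x / ds); yl <- floor(y / ds)
  H <- dim(page)[1L]; W <- dim(page)[2L]
  if (x < 0 || y < 0 || xl + w > W || yl + h > H)
    til_error(sprintf(
      "region (x=%s, y=%s, w=%s, h=%s) at level %d exceeds level bounds %dx%d",
      x, y, w, h, level, W, H), "til_bounds_error")
  page[(yl + 1L):(yl + h), (xl + 1L):(xl + w), , drop = FALSE]
}

patch_table_columns <- c("slide_id", "x", "y", "patch_size", "h_mean",
                         "label", "til_count", "density")

#' Construct a patch record table
#'
#' A patch record holds the level-0 top-left coordinate and side length
#' of one square candidate patch, plus annotations accumulated along the
#' pipeline (mean hematoxylin, class label, lymphocyte count, density in
#' cells/mm²). Patches span the half-open square `[x, x+patch_size) x
#' [y, y+patch_size)`.
#'
#' @param slide_id Character scalar or vector.
#' @param x,y Non-negative integer level-0 coordinates.
#' @param patch_size Positive integer side length (pixels).
#' @param h_mean,density Optional numerics (`NA` = not yet computed).
#' @param label Optional labels from [til_classes()].
#' @param til_count Optional non-negative integer counts.
#' @return A `data.frame` of class `til_patches`.
#' @export
patch_records <- function(slide_id, x, y, patch_size,
                          h_mean = NA_real_, label = NA_character_,
                          til_count = NA_integer_, density = NA_real_) {
  n <- max(length(x), length(y))
  df <- data.frame(
    slide_id = rep_len(as.character(slide_id), n),
    x = as.integer(rep_len(x, n)), y = as.integer(rep_len(y, n)),
    patch_size = as.integer(rep_len(patch_size, n)),
    h_mean = rep_len(as.numeric(h_mean), n),
    label = rep_len(as.character(label), n),
    til_count = as.integer(rep_len(til_count, n)),
    density = rep_len(as.numeric(density), n),
    stringsAsFactors = FALSE
  )
  if (n > 0) {
    bad <- !is.na(df$label) & !(df$label %in% til_classes())
    if (any(bad))
      til_error(sprintf("unknown patch label(s): %s",
                        paste(unique(df$label[bad]), collapse = ", ")),
                "til_domain_error")
    if (any(df$x < 0 | df$y < 0 | df$patch_size <= 0))
      til_error("patch coordinates must be >= 0 and patch_size > 0",
                "til_domain_error")
    if (any(!is.na(df$density) & is.na(df$til_count)))
      til_error("density present requires til_count present", "til_domain_error")
  }
  class(df) <- c("til_patches", "data.frame")
  df
}

empty_patch_records <- function(slide_id = character(0)) {
  patch_records(character(0), integer(0), integer(0), integer(0))
}

#' Write / read a patch table as TSV
#'
#' The on-disk format is a tab-separated table with header columns
#' `slide_id, x, y, patch_size, h_mean, label, til_count, density`.
#' Absent (`NA`) fields are serialized as empty strings; reals keep 15
#' significant digits so a write/read round trip is lossless for all
#' practical purposes and bit-exact for integer fields.
#'
#' @param records A `til_patches` data.frame (see [patch_records()]).
#' @param path Output / input file path.
#' @return `write_patch_table()` returns `path` invisibly;
#'   `read_patch_table()` returns a `til_patches` data.frame.
#' @export
write_patch_table <- function(records, path) {
  out <- as.data.frame(records)[, patch_table_columns]
  for (col in c("h_mean", "density"))
    out[[col]] <- ifelse(is.na(out[[col]]), "", sprintf("%.15g", out[[col]]))
  for (col in c("label", "til_count"))
    out[[col]] <- ifelse(is.na(out[[col]]), "", as.character(out[[col]]))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_patch_table
#' @export
read_patch_table <- function(path) {
  if (!file.exists(path))
    til_error(sprintf("patch table not found: %s", path), "til_io_error")
  lines <- readLines(path)
  if (length(lines) == 0L)
    til_error(sprintf("%s:1: empty patch table (missing header)", path),
              "til_parse_error")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  missing <- setdiff(patch_table_columns, header)
  if (length(missing) > 0L)
    til_error(sprintf("%s:1: missing column(s): %s", path,
                      paste(missing, collapse = ", ")), "til_parse_error")
  body <- lines[-1L]
  n <- length(body)
  cells <- strsplit(body, "\t", fixed = TRUE)
  get <- function(row, col) {
    v <- cells[[row]]
    idx <- match(col, header)
    if (idx > length(v)) "" else v[idx]
  }
  num <- function(col, line_of, integer = FALSE) {
    raw <- vapply(seq_len(n), get, character(1), col = col)
    out <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & nzchar(raw) & is.na(out))
    if (length(bad) > 0L)
      til_error(sprintf("%s:%d: cannot parse '%s' in column '%s'",
                        path, bad[1L] + 1L, raw[bad[1L]], col), "til_parse_error")
    out[!nzchar(raw)] <- NA
    if (integer) as.integer(out) else out
  }
  chr <- function(col) {
    raw <- vapply(seq_len(n), get, character(1), col = col)
    raw[!nzchar(raw)] <- NA_character_
    raw
  }
  req <- function(col, vals) {
    bad <- which(is.na(vals))
    if (length(bad) > 0L)
      til_error(sprintf("%s:%d: missing required value in column '%s'",
                        path, bad[1L] + 1L, col), "til_parse_error")
    vals
  }
  if (n == 0L) return(empty_patch_records())
  patch_records(
    slide_id = req("slide_id", chr("slide_id")),
    x = req("x", num("x", integer = TRUE)),
    y = req("y", num("y", integer = TRUE)),
    patch_size = req("patch_size", num("patch_size", integer = TRUE)),
    h_mean = num("h_mean"), label = chr("label"),
    til_count = num("til_count", integer = TRUE), density = num("density")
  )
}
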