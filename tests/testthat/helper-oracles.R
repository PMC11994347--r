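# Independent brute-force oracles and small fixture builders. The
# oracles deliberately share no code with the package implementation.

# Harrell's c by explicit pair enumeration: a pair is comparable iff the
# strictly shorter observed time is an event; tied risks count 0.5.
bf_cindex <- function(time, event, risk) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (time[i] == time[j]) next
      first <- if (time[i] < time[j]) i else j
      other <- if (first == i) j else i
      if (event[first] != 1) next
      den <- den + 1
      if (risk[first] > risk[other]) num <- num + 1
      else if (risk[first] == risk[other]) num <- num + 0.5
    }
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

# One-vs-rest AUC by direct positive-negative pair counting.
bf_auc <- function(score, positive) {
  pos <- which(positive); neg <- which(!positive)
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (score[p] > score[q]) + 0.5 * (score[p] == score[q])
  tot / (length(pos) * length(neg))
}

# Product-limit survival by hand at the distinct observed times.
bf_km <- function(time, event) {
  s <- 1
  out <- numeric(0)
  for (t in sort(unique(time))) {
    at <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / at)
    out <- c(out, s)
  }
  out
}

# A single-region slide covering patch-aligned tissue; returns the
# generated slide object (path + truth + spec).
fixture_slide <- function(width = 512, height = 512, mpp = 1,
                          class = "tumor", lymph = 800, other = 400,
                          seed = 42, ...) {
  sp <- slide_spec(
    width, height, mpp = mpp,
    regions = list(region_rect(0L, 0L, width, height, class)),
    nuclei_density = setNames(list(c(lymphocyte = lymph, other = other)), class),
    seed = seed, ...)
  generate_slide(sp)
}

# Tumor/stroma half-and-half slide with a shared lymphocyte density.
fixture_two_class_slide <- function(width = 1536, height = 1536, mpp = 0.5,
                                    lymph = 1500, other = 500, seed = 42) {
  half <- as.integer(width / 2)
  sp <- slide_spec(
    width, height, mpp = mpp,
    regions = list(region_rect(0L, 0L, half, height, "tumor"),
                   region_rect(half, 0L, width - half, height, "stroma")),
    nuclei_density = list(tumor = c(lymphocyte = lymph, other = other),
                          stroma = c(lymphocyte = lymph, other = other)),
    seed = seed)
  generate_slide(sp)
}

# Uniform-color slide written directly as TIFF (bypasses the generator).
write_flat_slide <- function(rgb255, width = 64, height = 64,
                             path = tempfile(fileext = ".tif"), mpp = NULL) {
  img <- array(rep(rgb255 / 255, each = height * width), c(height, width, 3))
  tiff::writeTIFF(img, path, bits.per.sample = 8L, compression = "LZW")
  if (!is.null(mpp))
    writeLines(jsonlite::toJSON(list(mpp = mpp), auto_unbox = TRUE),
               paste0(path, ".mpp.json"))
  path
}

# Downsample a logical mask by majority coverage (>= 0.5 of the block).
block_fraction_mask <- function(mask, s) {
  ri <- (seq_len(nrow(mask)) - 1L) %/% s + 1L
  ci <- (seq_len(ncol(mask)) - 1L) %/% s + 1L
  sums <- t(rowsum(t(rowsum(mask + 0, ri)), ci))
  cnt <- outer(tabulate(ri), tabulate(ci))
  sums / cnt >= 0.5
}

til_generator_palette <- function() {
  list(background = c(245, 245, 245), tumor = c(210, 91, 218),
       stroma = c(214, 105, 222), necrosis = c(200, 133, 170),
       normal = c(221, 119, 227), lymphocyte = c(70, 40, 110),
       other = c(106, 65, 153))
}
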