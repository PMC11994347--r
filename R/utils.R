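# Internal helpers: classed conditions, image arithmetic, digests.

til_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "til_error", "error", "condition")))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
is_pos_scalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0

# ITU-R BT.601 luma on the 0..255 scale; img is [h, w, 3] in [0, 1].
luma255 <- function(img) {
  255 * (0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
}

# Exact block mean of a matrix with integer factor s; partial edge blocks
# are averaged over the pixels they actually contain.
block_mean <- function(X, s) {
  s <- as.integer(s)
  if (s == 1L) return(X)
  ri <- (seq_len(nrow(X)) - 1L) %/% s + 1L
  ci <- (seq_len(ncol(X)) - 1L) %/% s + 1L
  A <- rowsum(X, ri, reorder = TRUE)
  A <- t(rowsum(t(A), ci, reorder = TRUE))
  A / outer(tabulate(ri), tabulate(ci))
}

# Majority vote over integer blocks (0 = background); used to downsample
# ground-truth label maps. Ties go to the smaller label id (= higher class
# priority, since ids follow til_classes() order).
block_mode <- function(X, s) {
  s <- as.integer(s)
  if (s == 1L) return(X)
  H <- nrow(X); W <- ncol(X)
  ri <- (seq_len(H) - 1L) %/% s + 1L
  ci <- (seq_len(W) - 1L) %/% s + 1L
  vals <- sort(unique(as.vector(X)))
  counts <- lapply(vals, function(v) {
    M <- matrix(as.numeric(X == v), H, W)
    t(rowsum(t(rowsum(M, ri)), ci))
  })
  best <- counts[[1]]
  out <- matrix(vals[1L], nrow(best), ncol(best))
  for (k in seq_along(vals)[-1L]) {
    better <- counts[[k]] > best
    out[better] <- vals[k]
    best[better] <- counts[[k]][better]
  }
  out
}

# Integer offsets of a filled disk of radius r (pixels).
disk_offsets <- function(r) {
  d <- seq.int(-floor(r), floor(r))
  g <- expand.grid(dx = d, dy = d)
  g[g$dx^2 + g$dy^2 <= r^2, , drop = FALSE]
}

# md5 digest of an R object via its canonical JSON rendering.
object_digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"), f)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
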