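# Stage 2: four-class patch classification and prognostic filtering.
#
# The classifier is a pluggable contract: any object of class
# "til_classifier" with a deterministic
#   classify(patch_rgb, record = NULL, mpp = NULL)
# returning list(label = <one of til_classes()>,
#                scores = <named numeric over til_classes(), summing to 1>)
# can stand in. Classifiers that do not need pixel data (the ground-truth
# oracle) set needs_pixels = FALSE so the pipeline can skip patch reads.
# Published CNN weights can be plugged in through the same seat via a
# thin adapter; no training code lives in this package.

new_classifier <- function(name, classify, needs_pixels = TRUE) {
  structure(list(name = name, classify = classify, needs_pixels = needs_pixels),
            class = "til_classifier")
}

#' @export
print.til_classifier <- function(x, ...) {
  cat(sprintf("<til_classifier> %s\n", x$name)); invisible(x)
}

one_hot_scores <- function(label) {
  s <- setNames(numeric(4L), til_classes())
  s[label] <- 1
  s
}

#' Constant classifier (testing aid)
#'
#' Labels every patch with the same class.
#'
#' @param label One of [til_classes()].
#' @return A `til_classifier`.
#' @export
constant_classifier <- function(label = "tumor") {
  stopifnot(label %in% til_classes())
  new_classifier(
    paste0("constant:", label),
    function(patch_rgb, record = NULL, mpp = NULL)
      list(label = label, scores = one_hot_scores(label)),
    needs_pixels = FALSE
  )
}

#' Ground-truth oracle classifier
#'
#' Labels a patch with the majority ground-truth region class under its
#' footprint, mirroring the labeling rule used for hand-annotated patch
#' datasets (the predominant tissue component decides). Ties are broken
#' by the fixed priority tumor > stroma > necrosis > normal. Patches
#' whose footprint contains no region pixels at all fall back to
#' "normal". Scores are the class-area fractions under the footprint.
#'
#' @param truth A `til_ground_truth` from [generate_slide()].
#' @return A `til_classifier` (does not read pixels).
#' @export
oracle_classifier <- function(truth) {
  stopifnot(inherits(truth, "til_ground_truth"))
  map <- truth$region_map
  td <- truth$downsample
  new_classifier(
    "oracle",
    function(patch_rgb, record = NULL, mpp = NULL) {
      if (is.null(record))
        til_error("oracle classifier needs the patch record", "til_contract_error")
      P <- record$patch_size
      rows <- (record$y %/% td + 1L):min(nrow(map), (record$y + P - 1L) %/% td + 1L)
      cols <- (record$x %/% td + 1L):min(ncol(map), (record$x + P - 1L) %/% td + 1L)
      tab <- tabulate(map[rows, cols], nbins = 4L)
      if (sum(tab) == 0L)
        return(list(label = "normal", scores = one_hot_scores("normal")))
      scores <- setNames(tab / sum(tab), til_classes())
      # which.max returns the first maximum; til_classes() order encodes
      # the tie-break priority
      list(label = til_classes()[which.max(tab)], scores = scores)
    },
    needs_pixels = FALSE
  )
}

#' Heuristic reference classifier
#'
#' A fixed-threshold classifier for fixtures without ground truth. It
#' measures the density of nuclear blobs (connected components of the
#' thresholded hematoxylin channel) and the mean eosin density, then
#' applies documented cutoffs: near-acellular patches are necrosis,
#' moderately cellular ones normal lung, and cell-rich patches are split
#' into tumor vs stroma by eosin intensity. The defaults are tuned to
#' the synthetic palette and default planting densities of
#' [slide_spec()]; it makes no claim of matching a trained CNN on real
#' tissue.
#'
#' @param h_od_min Hematoxylin density above which a pixel counts as
#'   nuclear.
#' @param min_blob_px Minimum blob area in pixels.
#' @param necrosis_max_blobs,normal_max_blobs Blob-density cutoffs
#'   (blobs/mm²).
#' @param tumor_eosin_min Mean eosin density separating tumor (above)
#'   from stroma (below) among cell-rich patches.
#' @return A `til_classifier` (reads pixels; requires `mpp`).
#' @export
heuristic_classifier <- function(h_od_min = 0.05, min_blob_px = 10,
                                 necrosis_max_blobs = 150,
                                 normal_max_blobs = 600,
                                 tumor_eosin_min = 0.058) {
  new_classifier(
    "heuristic",
    function(patch_rgb, record = NULL, mpp = NULL) {
      if (is.null(mpp))
        til_error("heuristic classifier needs the slide mpp", "til_contract_error")
      hed <- rgb_to_hed(patch_rgb)
      bin <- matrix(as.numeric(hed[, , 1L] > h_od_min),
                    dim(patch_rgb)[1L], dim(patch_rgb)[2L])
      lab <- EBImage::bwlabel(bin)
      areas <- tabulate(as.integer(lab))
      n_blobs <- sum(areas >= min_blob_px)
      area_mm2 <- prod(dim(patch_rgb)[1:2]) * (mpp / 1000)^2
      blob_density <- n_blobs / area_mm2
      eosin <- mean(hed[, , 2L])
      label <-
        if (blob_density < necrosis_max_blobs) "necrosis"
        else if (blob_density < normal_max_blobs) "normal"
        else if (eosin >= tumor_eosin_min) "tumor"
        else "stroma"
      list(label = label, scores = one_hot_scores(label))
    },
    needs_pixels = TRUE
  )
}

#' Assign class labels to candidate patches
#'
#' Runs the classifier over every record, preserving input order, and
#' fills the `label` column plus per-class score columns
#' (`score_tumor`, ..., `score_normal`).
#'
#' @param records A `til_patches` data.frame (typically the stage-1
#'   output of [h_filter()]).
#' @param slide The `til_slide` the records refer to.
#' @param classifier A `til_classifier`.
#' @return `records` with `label` and score columns filled.
#' @export
classify_patches <- function(records, slide, classifier) {
  stopifnot(inherits(classifier, "til_classifier"))
  n <- nrow(records)
  score_cols <- paste0("score_", til_classes())
  for (sc in score_cols) records[[sc]] <- rep(NA_real_, n)
  if (n == 0L) return(records)
  for (i in seq_len(n)) {
    rec <- records[i, ]
    patch <- if (classifier$needs_pixels)
      read_region(slide, rec$x, rec$y, rec$patch_size, rec$patch_size) else NULL
    res <- tryCatch(
      classifier$classify(patch, record = rec, mpp = slide$mpp),
      error = function(e)
        til_error(sprintf("classification failed at patch (x=%d, y=%d): %s",
                          rec$x, rec$y, conditionMessage(e)),
                  "til_contract_error"))
    if (!res$label %in% til_classes())
      til_error(sprintf("classifier returned unknown label '%s' at patch (x=%d, y=%d)",
                        res$label, rec$x, rec$y), "til_contract_error")
    records$label[i] <- res$label
    records[i, score_cols] <- as.numeric(res$scores[til_classes()])
  }
  records
}

#' Keep only prognostically relevant patches
#'
#' Retains exactly the records labeled tumor or stroma (the classes that
#' carry the lymphocyte infiltrate of interest); necrosis and normal
#' tissue are discarded. Order is preserved.
#'
#' @param records Labeled `til_patches` (every `label` must be filled).
#' @return The retained subset.
#' @export
filter_prognostic <- function(records) {
  if (nrow(records) > 0L && anyNA(records$label))
    til_error("filter_prognostic() requires every record to be labeled",
              "til_contract_error")
  out <- records[records$label %in% prognostic_classes(), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Balanced per-class target count for a test set
#'
#' Clips every class to the size of the least represented one, the usual
#' rule for building a balanced evaluation set.
#'
#' @param per_class_counts Named numeric vector of patch counts.
#' @return The common per-class count (minimum over classes).
#' @export
#' @examples
#' balance_test_set(c(necrosis = 300, stroma = 295, normal = 400, tumor = 500))
balance_test_set <- function(per_class_counts) {
  if (length(per_class_counts) == 0L)
    til_error("balance_test_set() needs at least one class", "til_domain_error")
  min(per_class_counts)
}

#' Seed-controlled balanced subset of labeled patches
#'
#' Samples [balance_test_set()] patches from every class uniformly
#' without replacement, so the resulting index set is class-balanced
#' and reproducible.
#'
#' @param labels Character vector of class labels.
#' @param seed Integer seed.
#' @return Integer indices into `labels`, sorted, with an equal number
#'   per class.
#' @export
balanced_subset <- function(labels, seed = 1L) {
  counts <- table(labels)
  m <- balance_test_set(counts)
  withr::with_seed(as.integer(seed), {
    idx <- unlist(lapply(names(counts), function(cl) {
      pool <- which(labels == cl)
      if (length(pool) == m) pool else sample(pool, m)
    }))
  })
  sort(idx)
}

#' Evaluate a patch classifier against true labels
#'
#' @param true_labels Character vector of true classes.
#' @param predicted_scores Numeric matrix, one row per patch, columns
#'   named (or ordered) as [til_classes()]; each row is a score vector.
#' @return A list with `accuracy` (fraction of argmax-correct
#'   predictions), `auc` (named per-class one-vs-rest AUC by the rank
#'   statistic, `NA` for absent classes), `macro_auc` (their mean), and
#'   `confusion` (rows = true class, columns = predicted).
#' @export
evaluate_classifier <- function(true_labels, predicted_scores) {
  classes <- til_classes()
  predicted_scores <- as.matrix(predicted_scores)
  if (length(true_labels) != nrow(predicted_scores))
    til_error("true_labels and predicted_scores disagree in length",
              "til_domain_error")
  if (!is.null(colnames(predicted_scores)))
    predicted_scores <- predicted_scores[, classes, drop = FALSE]
  pred <- classes[max.col(predicted_scores, ties.method = "first")]
  accuracy <- mean(pred == true_labels)
  auc <- vapply(seq_along(classes), function(k) {
    pos <- true_labels == classes[k]
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0L || n0 == 0L) return(NA_real_)
    r <- rank(predicted_scores[, k])  # average ranks handle score ties
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
  names(auc) <- classes
  confusion <- table(factor(true_labels, classes), factor(pred, classes),
                     dnn = c("true", "predicted"))
  list(accuracy = accuracy, auc = auc, macro_auc = mean(auc, na.rm = TRUE),
       confusion = confusion)
}
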