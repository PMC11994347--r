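# Randomized patch subsampling and the Monte-Carlo stability harness.
#
# Sampling happens after stage-1 extraction and before classification:
# it thins the patch set handed to the expensive model stages. Because
# it is simple random sampling without replacement, the sampled mean
# density is an exactly unbiased estimator of the full-set slide score.

#' Randomly subsample patch records
#'
#' Draws `m = max(1, round(ratio * N))` records uniformly without
#' replacement (base R `round()`, i.e. round-half-to-even) and returns
#' them in their original order. Identical `(records, ratio, seed)`
#' yield an identical subset; the RNG is R's Mersenne-Twister with the
#' current-default "Rejection" sampling kind, seeded locally so the
#' caller's RNG state is untouched.
#'
#' @param records A non-empty `til_patches` data.frame.
#' @param ratio Sampling ratio in `(0, 1]`.
#' @param seed Integer seed.
#' @return The sampled subset, input order preserved.
#' @export
#' @examples
#' # 5% of 7000 stage-1 patches -> 350 per slide
#' max(1, round(0.05 * 7000))
sample_patches <- function(records, ratio, seed) {
  n <- nrow(records)
  if (n == 0L)
    til_error("cannot sample from an empty patch set", "til_empty_error")
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0 || ratio > 1)
    til_error("ratio must lie in (0, 1]", "til_config_error")
  m <- max(1L, as.integer(round(ratio * n)))
  idx <- withr::with_seed(as.integer(seed), sort(sample.int(n, m)))
  out <- records[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Monte-Carlo stability of scores under patch subsampling
#'
#' For each sampling ratio and replicate `r`, subsamples every slide's
#' stage-1 patch set with seed `base_seed + r`, applies the prognostic
#' class filter, recomputes per-patient scores, and (when survival data
#' are supplied) the cohort concordance index of the score, treating
#' higher scores as protective. Reports mean and standard deviation over
#' replicates. Because classification and quantification are
#' deterministic per patch, they are performed once on the full set and
#' the harness resamples the annotated records — numerically identical
#' to rerunning the downstream stages on each subsample, at a fraction
#' of the cost.
#'
#' @param patch_tables Named list (by patient id) of `til_patches`
#'   tables covering the **full** stage-1 candidate set of each slide,
#'   with `label` and `density` already filled.
#' @param ratios Numeric vector of sampling ratios in `(0, 1]`.
#' @param replicates Number of Monte-Carlo replicates per ratio.
#' @param survival Optional data.frame with `patient_id`, `time`,
#'   `event`; enables the c-index columns.
#' @param base_seed Integer; replicate `r` uses seed `base_seed + r`,
#'   so the whole table is reproducible from `base_seed`.
#' @return A data.frame with one row per ratio: `ratio`, `score_mean`
#'   (mean over replicates of the cohort-mean slide score), `score_sd`
#'   (mean over slides of the per-slide score standard deviation across
#'   replicates), and, with survival data, `cindex_mean` and
#'   `cindex_sd`. The per-replicate detail is attached as
#'   `attr(, "replicates")`.
#' @export
monte_carlo_stability <- function(patch_tables, ratios, replicates,
                                  survival = NULL, base_seed = 1L) {
  if (length(ratios) == 0L)
    til_error("ratio list must not be empty", "til_config_error")
  if (!is.null(survival)) {
    if (length(patch_tables) < 2L)
      til_error("survival evaluation needs at least 2 slides", "til_domain_error")
    if (!all(names(patch_tables) %in% survival$patient_id))
      til_error("every patch table must match a survival record",
                "til_domain_error")
  }
  ids <- names(patch_tables)
  n_slides <- length(patch_tables)
  rows <- list(); detail <- list()
  score_mat <- matrix(NA_real_, n_slides, replicates, dimnames = list(ids, NULL))
  for (ratio in ratios) {
    cindex <- rep(NA_real_, replicates)
    for (r in seq_len(replicates)) {
      seed_r <- as.integer(base_seed + r)
      for (j in seq_len(n_slides)) {
        s <- sample_patches(patch_tables[[j]], ratio, seed_r)
        s <- s[s$label %in% prognostic_classes(), , drop = FALSE]
        score_mat[j, r] <- if (nrow(s) > 0L) mean(s$density) else NA_real_
      }
      if (!is.null(survival)) {
        sc <- score_mat[, r]
        ok <- !is.na(sc)
        sv <- survival[match(ids[ok], survival$patient_id), ]
        cindex[r] <- concordance_index(sv$time, sv$event, sc[ok],
                                       direction = "higher_score_lower_risk")
      }
      detail[[length(detail) + 1L]] <- data.frame(
        ratio = ratio, replicate = r,
        cohort_mean_score = mean(score_mat[, r], na.rm = TRUE),
        cindex = cindex[r])
    }
    per_slide_sd <- apply(score_mat, 1L, stats::sd)
    row <- data.frame(
      ratio = ratio,
      score_mean = mean(colMeans(score_mat, na.rm = TRUE)),
      score_sd = mean(per_slide_sd, na.rm = TRUE))
    if (!is.null(survival)) {
      row$cindex_mean <- mean(cindex)
      row$cindex_sd <- stats::sd(cindex)
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  attr(out, "replicates") <- do.call(rbind, detail)
  attr(out, "base_seed") <- base_seed
  out
}
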