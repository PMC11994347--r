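# End-to-end pipeline: extract -> (sample) -> classify -> filter ->
# quantify -> score -> heatmap, with a reproducible run manifest.

#' Run the full TIL-scoring pipeline on one slide
#'
#' Executes tissue masking, patch-grid generation and hematoxylin
#' filtering, optional randomized subsampling of the extracted patch
#' set, classification, prognostic-class filtering, lymphocyte
#' quantification and density scoring, and (when `outdir` is given)
#' heatmap rendering. All stages are deterministic given the inputs and
#' the sampling seed, so identical invocations produce byte-identical
#' artifacts.
#'
#' @param slide_path Path to the slide image.
#' @param classifier A `til_classifier` (see [oracle_classifier()],
#'   [heuristic_classifier()]).
#' @param quantifier A `til_quantifier` (see [oracle_quantifier()],
#'   [reference_quantifier()]).
#' @param config An [extraction_config()].
#' @param sampling Optional `list(ratio =, seed =)`; when supplied, the
#'   stage-1 patch set is subsampled before classification.
#' @param mpp_override Optional mpp when the file has no metadata.
#' @param outdir Optional output directory; when given, writes
#'   `patches.tsv`, `result.json`, `heatmap.png` and `manifest.json`.
#' @param heatmap A [heatmap_spec()].
#' @param slide_id Identifier for outputs (default: file name).
#' @return A list of class `til_pipeline_run`: `result` (the
#'   `til_slide_result`; `til_score` is `NA` with `evaluable = FALSE`
#'   for a slide with no retained tumor/stroma patches), `records`, the
#'   stage-wise `counts` (non-increasing along the pipeline), and
#'   `manifest`.
#' @export
run_pipeline <- function(slide_path, classifier, quantifier,
                         config = extraction_config(), sampling = NULL,
                         mpp_override = NULL, outdir = NULL,
                         heatmap = heatmap_spec(), slide_id = NULL) {
  slide <- open_slide(slide_path, mpp_override = mpp_override)
  slide_id <- slide_id %||% tools::file_path_sans_ext(basename(slide_path))

  mask <- compute_tissue_mask(slide, config)
  grid <- mask_to_patch_grid(mask, slide, config, slide_id = slide_id)
  kept <- h_filter(grid, slide, config)
  counts <- c(grid = nrow(grid), h_filter = nrow(kept))

  if (!is.null(sampling)) {
    if (is.null(sampling$ratio) || is.null(sampling$seed))
      til_error("sampling needs 'ratio' and 'seed'", "til_config_error")
    if (nrow(kept) > 0L)
      kept <- sample_patches(kept, sampling$ratio, sampling$seed)
    counts <- c(counts, sampled = nrow(kept))
  }

  labeled <- classify_patches(kept, slide, classifier)
  prog <- filter_prognostic(labeled)
  counts <- c(counts, classified = nrow(labeled), prognostic = nrow(prog))

  q <- quantify_patches(prog, slide, quantifier)
  counts <- c(counts, quantified = nrow(q$records))

  manifest <- list(
    slide_id = slide_id,
    slide_path = slide_path,
    slide_md5 = unname(tools::md5sum(slide_path)),
    mpp = slide$mpp,
    config = unclass(config),
    config_digest = object_digest(unclass(config)),
    sampling = if (is.null(sampling)) NULL
               else list(ratio = sampling$ratio, seed = sampling$seed),
    classifier = classifier$name,
    quantifier = quantifier$name,
    stage_counts = as.list(counts),
    til_score = q$result$til_score,
    evaluable = q$result$evaluable
  )

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_patch_table(q$records, file.path(outdir, "patches.tsv"))
    jsonlite::write_json(
      list(slide_id = slide_id, n_patches = q$result$n_patches,
           til_score = q$result$til_score, evaluable = q$result$evaluable,
           mpp = slide$mpp, config_digest = manifest$config_digest),
      file.path(outdir, "result.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    hm <- render_heatmap(slide, q$records, heatmap)
    png::writePNG(hm, file.path(outdir, "heatmap.png"))
  }

  structure(list(result = q$result, records = q$records, counts = counts,
                 manifest = manifest),
            class = "til_pipeline_run")
}

#' @export
print.til_pipeline_run <- function(x, ...) {
  print(x$result)
  cat("  stages: ", paste(sprintf("%s=%d", names(x$counts), x$counts),
                          collapse = " -> "), "\n")
  invisible(x)
}
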