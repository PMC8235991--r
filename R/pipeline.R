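#' Default end-to-end pipeline configuration
#'
#' Nested stage parameters for the full run: denoising, segmentation,
#' feature extraction, wrapper selection and classification. All values are
#' overridable via `...` using `stage.key` names (e.g. `denoise.h = 0.2`).
#'
#' @param ... overrides, e.g. `denoise.search_radius = 5`,
#'   `selection.iters = 50`.
#' @return a `run_config` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    image.size = 256L,
    denoise.h = 0.1, denoise.search_radius = 10L,
    denoise.sim_radius = 3L, denoise.kernel_sigma = 1.0,
    segment.se_shape = "square", segment.se_size = 5L,
    segment.connectivity = 8L,
    features.levels = 32L, features.displacement = c(0L, 1L),
    selection.enabled = TRUE,
    selection.iters = 750L, selection.restarts = 20L,
    selection.pop_size = 10L, selection.cv_folds = 5L,
    selection.lambda = 0,
    classify.C = 1, classify.kernel = "rbf",
    classify.train_frac = 0.85, classify.n_seeds = 10L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

process_one_image <- function(path, config) {
  img <- read_pgm(path)
  img <- resize_bilinear(img, config$image.size, config$image.size)
  dp <- denoise_params(h = config$denoise.h,
                       search_radius = config$denoise.search_radius,
                       sim_radius = config$denoise.sim_radius,
                       kernel_sigma = config$denoise.kernel_sigma)
  den <- nlm_filter(img, dp)
  e <- structuring_element(config$segment.se_shape, config$segment.se_size)
  mask <- segment_lesion(den, e, config$segment.connectivity)
  feats <- extract_all(den, mask, levels = config$features.levels,
                       displacement = config$features.displacement)
  list(features = feats, mask = mask)
}

#' Run the full diagnosis pipeline on a manifest of images
#'
#' For each manifest row (`filename,label`, paths relative to the manifest):
#' read, resize, denoise (NLM), segment (Otsu + morphology), extract the 16
#' features. Then evaluate classification under the repeated stratified
#' 85/15 holdout protocol, with wrapper feature selection fitted on each
#' training split only. Failed images are logged and skipped; the run
#' errors if more than 10% fail.
#'
#' Persists under `out_dir`: `features.csv`, per-image masks (`masks/`),
#' `metrics.json`, the effective `config.json`, and `log.txt`.
#'
#' @param manifest path to the manifest CSV.
#' @param config a [default_config()].
#' @param out_dir output directory.
#' @return list with `features` (data.frame), `report` (from
#'   [holdout_protocol()]), `failed` (character vector of failed files).
#' @export
run_pipeline <- function(manifest, config = default_config(),
                         out_dir = tempfile("dermopt_run_")) {
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  stopifnot(all(c("filename", "label") %in% names(man)))
  base <- dirname(manifest)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  logf("pipeline start: %d images, seed %d", nrow(man), config$seed)
  feats <- list(); labels <- character(); failed <- character()
  for (i in seq_len(nrow(man))) {
    path <- file.path(base, man$filename[i])
    t0 <- proc.time()[3]
    res <- tryCatch(process_one_image(path, config), error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, man$filename[i])
      logf("FAIL %s: %s", man$filename[i], conditionMessage(res))
      next
    }
    feats[[length(feats) + 1L]] <- res$features
    labels <- c(labels, man$label[i])
    write_pgm(res$mask, file.path(out_dir, "masks", man$filename[i]))
    logf("ok %s (%.2fs)", man$filename[i], proc.time()[3] - t0)
  }
  if (length(failed) > 0.1 * nrow(man))
    stop(sprintf("pipeline aborted: %d/%d images failed (see %s)",
                 length(failed), nrow(man), log_path))
  fx <- do.call(rbind, feats)
  ftab <- data.frame(fx, label = labels, check.names = FALSE)
  utils::write.csv(ftab, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  data <- labeled_dataset(fx, labels)
  sel_cfg <- if (isTRUE(config$selection.enabled))
    list(iters = config$selection.iters,
         restarts = config$selection.restarts,
         pop_size = config$selection.pop_size,
         cv_folds = config$selection.cv_folds,
         lambda = config$selection.lambda)
  else NULL
  seeds <- config$seed + seq_len(config$classify.n_seeds) - 1L
  report <- holdout_protocol(data, seeds = seeds,
                             train_frac = config$classify.train_frac,
                             selection_cfg = sel_cfg,
                             C = config$classify.C,
                             kernel = config$classify.kernel)
  jsonlite::write_json(list(summary = report$summary,
                            per_seed = report$per_seed,
                            failed = failed),
                       file.path(out_dir, "metrics.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  logf("pipeline done: %d ok, %d failed", length(labels), length(failed))
  list(features = ftab, report = report, failed = failed,
       out_dir = out_dir)
}
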