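#' Synthetic dermoscopy image generator configuration
#'
#' The generator emulates the gross photometry of dermoscopy: a bright
#' skin background (mean 0.75) with low-frequency mottle, a dark roughly
#' elliptical pigmented lesion (mean 0.25), optional dark hair-like
#' curvilinear clutter, and additive Gaussian noise. The class signal is
#' geometric: "cancerous" lesions get an irregular radially perturbed
#' boundary and higher eccentricity, "healthy" nevi are smooth and round.
#'
#' Two presets are shipped: `"easy"` (low noise, no hair; solvable by the
#' Otsu + morphology pipeline) and `"hard"` (triple the noise, hair
#' strokes, weaker shape contrast).
#'
#' @param preset `"easy"` or `"hard"`.
#' @param size image side in pixels (default 256).
#' @param ... named overrides of individual fields.
#' @return a `synth_config` list.
#' @export
synth_config <- function(preset = c("easy", "hard"), size = 256L, ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset, size = as.integer(size),
    bg_mean = 0.75, lesion_mean = 0.25,
    mottle_amp = if (preset == "easy") 0.04 else 0.10,
    noise_sd = if (preset == "easy") 0.05 else 0.15,
    hair_count = if (preset == "easy") 0L else 5L,
    hair_intensity = 0.15,
    # radial boundary perturbation amplitude (relative to radius)
    perturb_cancerous = if (preset == "easy") 0.22 else 0.15,
    perturb_healthy = if (preset == "easy") 0.03 else 0.08,
    # minor/major axis ratio ranges
    ratio_cancerous = c(0.50, 0.72),
    ratio_healthy = c(0.85, 1.00),
    radius_frac = c(0.15, 0.22)   # base radius as fraction of image side
  )
  dots <- list(...)
  stopifnot(all(names(dots) %in% names(cfg)))
  cfg[names(dots)] <- dots
  structure(cfg, class = "synth_config")
}

low_freq_mottle <- function(size, amp) {
  g <- seq(0, 1, length.out = size)
  field <- matrix(0, size, size)
  for (i in 1:3) {
    fr <- stats::runif(2, 1, 4)
    ph <- stats::runif(2, 0, 2 * pi)
    field <- field + outer(sin(2 * pi * fr[1] * g + ph[1]),
                           sin(2 * pi * fr[2] * g + ph[2]))
  }
  amp * field / 3
}

#' Generate one synthetic lesion image with ground truth
#'
#' @param label `"cancerous"` or `"healthy"`.
#' @param seed integer seed; the same `(label, seed, cfg)` triple
#'   regenerates the identical sample.
#' @param cfg a [synth_config()].
#' @return list with `image` ([gray_image()]), `truth_mask` (logical
#'   matrix matching the rendered lesion support exactly), `label`, and
#'   `params` (the generation record).
#' @export
gen_image <- function(label = c("cancerous", "healthy"), seed = 1L,
                      cfg = synth_config()) {
  label <- match.arg(label)
  set.seed(seed)
  s <- cfg$size
  cx <- s / 2 + stats::runif(1, -0.05, 0.05) * s
  cy <- s / 2 + stats::runif(1, -0.05, 0.05) * s
  r0 <- stats::runif(1, cfg$radius_frac[1], cfg$radius_frac[2]) * s
  ratio_rng <- if (label == "cancerous") cfg$ratio_cancerous else cfg$ratio_healthy
  ratio <- stats::runif(1, ratio_rng[1], ratio_rng[2])
  theta <- stats::runif(1, 0, 2 * pi)
  amp <- if (label == "cancerous") cfg$perturb_cancerous else cfg$perturb_healthy
  modes <- 2:6
  fa <- stats::rnorm(length(modes)) / modes
  fb <- stats::rnorm(length(modes)) / modes
  norm <- sqrt(sum(fa^2 + fb^2)) + 1e-12
  fa <- fa / norm; fb <- fb / norm

  row <- matrix(seq_len(s), s, s)
  col <- matrix(seq_len(s), s, s, byrow = TRUE)
  u <- (col - cx) * cos(theta) + (row - cy) * sin(theta)
  v <- -(col - cx) * sin(theta) + (row - cy) * cos(theta)
  a <- r0; b <- r0 * ratio
  rad <- sqrt((u / a)^2 + (v / b)^2)
  phi <- atan2(v / b, u / a)
  pert <- matrix(0, s, s)
  for (m in seq_along(modes))
    pert <- pert + fa[m] * cos(modes[m] * phi) + fb[m] * sin(modes[m] * phi)
  inside <- rad <= 1 + amp * pert

  img <- matrix(cfg$bg_mean, s, s) + low_freq_mottle(s, cfg$mottle_amp)
  lesion_tex <- low_freq_mottle(s, cfg$mottle_amp / 2)
  img[inside] <- cfg$lesion_mean + lesion_tex[inside]
  if (cfg$hair_count > 0) {
    g <- seq_len(s)
    for (h in seq_len(cfg$hair_count)) {
      off <- stats::runif(1, 0.1, 0.9) * s
      ampl <- stats::runif(1, 5, 25)
      per <- stats::runif(1, 40, 150)
      ph <- stats::runif(1, 0, 2 * pi)
      rr <- round(off + ampl * sin(2 * pi * g / per + ph))
      for (thick in 0:1) {
        ok <- rr + thick >= 1 & rr + thick <= s
        img[cbind(rr[ok] + thick, g[ok])] <- cfg$hair_intensity
      }
    }
  }
  img <- img + stats::rnorm(s * s, 0, cfg$noise_sd)
  img <- pmin(pmax(img, 0), 1)
  list(image = gray_image(img), truth_mask = inside, label = label,
       params = list(seed = seed, cfg = cfg, center = c(cx, cy),
                     axes = c(a = a, b = b), theta = theta,
                     fourier = list(a = fa, b = fb), amp = amp))
}

#' Generate a cohort of synthetic images on disk
#'
#' Writes `n` images (balanced labels, alternating) as ASCII PGM plus a
#' `manifest.csv` (`filename,label`) and ground-truth masks under `masks/`.
#'
#' @param n number of images.
#' @param out_dir output directory (created if missing).
#' @param seed master seed; image `i` uses `seed + i`.
#' @param cfg a [synth_config()].
#' @return path of the manifest, invisibly.
#' @export
gen_cohort <- function(n, out_dir, seed = 1L, cfg = synth_config()) {
  dir.create(file.path(out_dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  labels <- rep(c("cancerous", "healthy"), length.out = n)
  rows <- character(n)
  for (i in seq_len(n)) {
    smp <- gen_image(labels[i], seed = as.integer(seed) + i, cfg = cfg)
    fn <- sprintf("img_%03d.pgm", i)
    write_pgm(smp$image, file.path(out_dir, fn))
    write_pgm(smp$truth_mask, file.path(out_dir, "masks", fn))
    rows[i] <- paste(fn, labels[i], sep = ",")
  }
  manifest <- file.path(out_dir, "manifest.csv")
  writeLines(c("filename,label", rows), manifest)
  invisible(manifest)
}

#' Tabular dataset with planted informative features
#'
#' All columns are `N(0, 1)` noise in both classes except the informative
#' ones, which are shifted by `effect` in the cancerous class. Labels are
#' balanced.
#'
#' @param n samples (>= 4), `d` columns.
#' @param d number of feature columns.
#' @param informative column indices carrying the class signal.
#' @param effect mean shift (in sd units) of the informative columns.
#' @param seed integer seed.
#' @return list with `data` (a [labeled_dataset()]), `informative`,
#'   `effect`.
#' @export
gen_tabular <- function(n, d = 16L, informative = 1:3, effect = 3,
                        seed = 1L) {
  stopifnot(n >= 4, all(informative >= 1), all(informative <= d))
  set.seed(seed)
  x <- matrix(stats::rnorm(n * d), n, d)
  labels <- rep(c("cancerous", "healthy"), length.out = n)
  x[labels == "cancerous", informative] <-
    x[labels == "cancerous", informative] + effect
  perm <- sample(n)
  colnames(x) <- sprintf("f%02d", seq_len(d))
  list(data = labeled_dataset(x[perm, , drop = FALSE], labels[perm]),
       informative = sort(as.integer(informative)), effect = effect)
}
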