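#' Non-local means denoising parameters
#'
#' NLM averages pixels weighted by patch similarity rather than spatial
#' proximity. `h` sets the filtering intensity: too small leaves noise,
#' too large blurs structure. Windows are given as radii, so a radius `r`
#' window spans `2r + 1` pixels.
#'
#' @param h smoothing strength, in intensity units (image lives in `[0,1]`).
#' @param search_radius radius of the search window scanned for candidates.
#' @param sim_radius radius of the similarity (patch) window.
#' @param kernel_sigma std. dev. (pixels) of the isotropic Gaussian that
#'   weights the per-pixel terms of the patch distance.
#' @return a `denoise_params` list.
#' @export
denoise_params <- function(h = 0.1, search_radius = 10L, sim_radius = 3L,
                           kernel_sigma = 1.0) {
  stopifnot(h > 0, search_radius >= sim_radius, sim_radius >= 1,
            kernel_sigma > 0)
  structure(list(h = h, search_radius = as.integer(search_radius),
                 sim_radius = as.integer(sim_radius),
                 kernel_sigma = kernel_sigma),
            class = "denoise_params")
}

# Normalised isotropic Gaussian over the (2r+1)^2 patch; weights sum to 1.
gaussian_patch_kernel <- function(sim_radius, kernel_sigma) {
  d <- seq(-sim_radius, sim_radius)
  g1 <- exp(-d^2 / (2 * kernel_sigma^2))
  k <- outer(g1, g1)
  k / sum(k)
}

#' Gaussian-weighted squared patch distance
#'
#' Distance between the similarity patches centred at pixels `i` and `j`:
#' `sum_k w_k (x_ik - x_jk)^2` with `w_k` a normalised Gaussian centred on
#' the patch centre. Borders are handled by symmetric reflection.
#'
#' @param img a [gray_image()].
#' @param i,j pixel indices as `c(row, col)` (1-based).
#' @param params a [denoise_params()].
#' @return nonnegative scalar.
#' @export
patch_distance <- function(img, i, j, params = denoise_params()) {
  stopifnot(is_gray_image(img), length(i) == 2, length(j) == 2)
  k <- gaussian_patch_kernel(params$sim_radius, params$kernel_sigma)
  cpp_patch_distance(as_matrix(img), as.integer(i[1]), as.integer(i[2]),
                     as.integer(j[1]), as.integer(j[2]), k,
                     params$sim_radius)
}

#' Non-local means filter
#'
#' Each output pixel is the normalised weighted average of the pixels in its
#' search window, with weights `exp(-d/h^2)` where `d` is the
#' Gaussian-weighted squared distance between the two similarity patches.
#' The weight normaliser makes the result a convex combination, so output
#' intensities stay within the range of the window.
#'
#' @param img a [gray_image()]; all pixels must be finite.
#' @param params a [denoise_params()].
#' @return denoised [gray_image()].
#' @export
nlm_filter <- function(img, params = denoise_params()) {
  if (!is_gray_image(img)) img <- gray_image(img)
  k <- gaussian_patch_kernel(params$sim_radius, params$kernel_sigma)
  out <- cpp_nlm(as_matrix(img), params$h, params$search_radius,
                 params$sim_radius, k)
  gray_image(out)
}
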