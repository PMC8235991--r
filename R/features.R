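#' Names of the 16 descriptors, in extraction order
#' @export
FEATURE_NAMES <- c("mean", "variance", "std", "contrast", "area",
                   "rectangularity", "elongation", "irregularity_index",
                   "form_factor", "eccentricity", "entropy", "perimeter",
                   "homogeneity", "energy", "correlation", "hu_phi1")

#' First-order intensity statistics over a masked region
#'
#' @param img a [gray_image()].
#' @param mask nonempty binary mask of the same shape.
#' @return named vector `(mean, variance, std)`; variance is the population
#'   variance (1/N normaliser) and `std = sqrt(variance)`.
#' @export
intensity_stats <- function(img, mask) {
  m <- as_mask(mask)
  if (!any(m)) stop("empty mask")
  v <- as_matrix(img)[m]
  mu <- mean(v)
  va <- mean((v - mu)^2)
  c(mean = mu, variance = va, std = sqrt(va))
}

#' Gray-level co-occurrence matrix (GLCM)
#'
#' Joint frequency of quantized intensity pairs at a fixed displacement,
#' restricted to pixel pairs that both fall inside the mask. The matrix is
#' symmetrized (each pair counted in both orders) and normalized to sum 1.
#' Intensities are binned uniformly over the global range `[0, 1]`.
#'
#' @param img a [gray_image()].
#' @param mask binary mask with at least 2 pixels.
#' @param levels number of gray levels (>= 2); 32 by default.
#' @param displacement integer `c(dr, dc)` pixel offset; `(0, 1)` =
#'   horizontal neighbours.
#' @return `levels x levels` normalized matrix.
#' @export
glcm <- function(img, mask, levels = 32L, displacement = c(0L, 1L)) {
  stopifnot(levels >= 2)
  m <- as_mask(mask)
  if (sum(m) < 2) stop("mask must contain at least 2 pixels")
  q <- pmin(floor(as_matrix(img) * levels) + 1L, levels)  # 1..levels
  nr <- nrow(m); nc <- ncol(m)
  dr <- as.integer(displacement[1]); dc <- as.integer(displacement[2])
  r1 <- max(1L, 1L - dr):min(nr, nr - dr)
  c1 <- max(1L, 1L - dc):min(nc, nc - dc)
  if (length(r1) == 0 || length(c1) == 0) stop("displacement exceeds image")
  ok <- m[r1, c1, drop = FALSE] & m[r1 + dr, c1 + dc, drop = FALSE]
  if (!any(ok)) stop("no co-occurring pixel pairs inside the mask")
  a <- q[r1, c1, drop = FALSE][ok]
  b <- q[r1 + dr, c1 + dc, drop = FALSE][ok]
  P <- matrix(0, levels, levels)
  for (t in seq_along(a)) P[a[t], b[t]] <- P[a[t], b[t]] + 1
  P <- P + t(P)
  P / sum(P)
}

#' Haralick-style texture features from a co-occurrence matrix
#'
#' With `P` normalized over level indices `i, j`:
#' contrast `= sum (i-j)^2 P`, entropy `= -sum P log P` (natural log,
#' `0 log 0 := 0`), homogeneity `= sum P / (1 + |i-j|)`, energy
#' `= sum P^2`, correlation `= sum (i-mu_r)(j-mu_c) P / (sigma_r sigma_c)`
#' (0 when either marginal is degenerate).
#'
#' @param P normalized co-occurrence matrix (entries sum to 1).
#' @return named vector of the five texture features.
#' @export
texture_features <- function(P) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P),
            abs(sum(P) - 1) < 1e-8, all(P >= 0))
  L <- nrow(P)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  contrast <- sum((i - j)^2 * P)
  entropy <- -sum(ifelse(P > 0, P * log(P), 0))
  homog <- sum(P / (1 + abs(i - j)))
  energy <- sum(P^2)
  pr <- rowSums(P); pc <- colSums(P)
  mur <- sum(seq_len(L) * pr); muc <- sum(seq_len(L) * pc)
  sr <- sqrt(sum((seq_len(L) - mur)^2 * pr))
  sc <- sqrt(sum((seq_len(L) - muc)^2 * pc))
  corr <- if (sr == 0 || sc == 0) 0 else
    sum((i - mur) * (j - muc) * P) / (sr * sc)
  c(contrast = contrast, entropy = entropy, homogeneity = homog,
    energy = energy, correlation = corr)
}

# second-central-moment ellipse full axis lengths (a >= b) of a mask
region_axes <- function(rc, area) {
  mr <- mean(rc[, 1]); mc <- mean(rc[, 2])
  u20 <- mean((rc[, 1] - mr)^2)
  u02 <- mean((rc[, 2] - mc)^2)
  u11 <- mean((rc[, 1] - mr) * (rc[, 2] - mc))
  tr <- u20 + u02
  det <- u20 * u02 - u11^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc; l2 <- max(tr / 2 - disc, 0)
  c(a = 4 * sqrt(l1), b = 4 * sqrt(l2))
}

#' Geometric descriptors of a binary region
#'
#' Area is the pixel count. Perimeter is the total exposed side length: each
#' region pixel contributes one unit per 4-neighbour that is background (or
#' off-image). Axis lengths `a >= b` are the full axes of the region's
#' second-central-moment ellipse. Derived shapes: rectangularity
#' `area/(a b)`, elongation `2 sqrt(area/pi) / a` (equivalent-circle
#' diameter over major axis), irregularity index `4 pi area / perimeter^2`,
#' form factor `area / a^2`, eccentricity `sqrt(a^2 - b^2)/a`, and the first
#' Hu invariant `phi1 = eta20 + eta02` of the binary region.
#'
#' @param mask binary mask (intended: a single connected region).
#' @return named vector of the eight shape features.
#' @export
shape_features <- function(mask) {
  m <- as_mask(mask)
  area <- sum(m)
  if (area < 1) stop("empty mask")
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  core <- pad[2:(nr + 1), 2:(nc + 1), drop = FALSE]
  exposed <- (core & !pad[1:nr, 2:(nc + 1)]) + (core & !pad[3:(nr + 2), 2:(nc + 1)]) +
    (core & !pad[2:(nr + 1), 1:nc]) + (core & !pad[2:(nr + 1), 3:(nc + 2)])
  perim <- sum(exposed)
  rc <- which(m, arr.ind = TRUE)
  ax <- region_axes(rc, area)
  a <- ax[["a"]]; b <- ax[["b"]]
  rect <- if (a > 0 && b > 0) area / (a * b) else 0
  elong <- if (a > 0) 2 * sqrt(area / pi) / a else 0
  irr <- 4 * pi * area / perim^2
  ff <- if (a > 0) area / a^2 else 0
  ecc <- if (a > 0) sqrt(max(a^2 - b^2, 0)) / a else 0
  # normalized central moments of the binary region: eta_pq = mu_pq / mu00^2
  mr <- mean(rc[, 1]); mc <- mean(rc[, 2])
  mu20 <- sum((rc[, 1] - mr)^2); mu02 <- sum((rc[, 2] - mc)^2)
  phi1 <- (mu20 + mu02) / area^2
  c(area = area, perimeter = perim, rectangularity = rect,
    elongation = elong, irregularity_index = irr, form_factor = ff,
    eccentricity = ecc, hu_phi1 = phi1)
}

#' Extract the full 16-entry feature vector
#'
#' Assembles intensity statistics (over the masked lesion), GLCM texture
#' features and geometric descriptors into the fixed order of
#' [FEATURE_NAMES].
#'
#' @param img a [gray_image()].
#' @param mask nonempty binary lesion mask of the same shape.
#' @param levels,displacement forwarded to [glcm()].
#' @return named numeric vector of length 16, all entries finite.
#' @export
extract_all <- function(img, mask, levels = 32L, displacement = c(0L, 1L)) {
  stopifnot(nrow(img) == nrow(mask), ncol(img) == ncol(mask))
  s <- intensity_stats(img, mask)
  P <- glcm(img, mask, levels = levels, displacement = displacement)
  tx <- texture_features(P)
  sh <- shape_features(mask)
  out <- c(s[["mean"]], s[["variance"]], s[["std"]], tx[["contrast"]],
           sh[["area"]], sh[["rectangularity"]], sh[["elongation"]],
           sh[["irregularity_index"]], sh[["form_factor"]],
           sh[["eccentricity"]], tx[["entropy"]], sh[["perimeter"]],
           tx[["homogeneity"]], tx[["energy"]], tx[["correlation"]],
           sh[["hu_phi1"]])
  names(out) <- FEATURE_NAMES
  if (any(!is.finite(out))) stop("non-finite feature value")
  out
}
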