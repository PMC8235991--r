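#' Structuring element for binary morphology
#'
#' The default is a 5 x 5 all-ones square. An "identity" footprint (the
#' 5-pixel main diagonal) is also available for strict reproducibility of
#' configurations that specify a diagonal element, although it is
#' directionally biased and not recommended.
#'
#' @param shape `"square"`, `"identity"`, or `"cross"` (the 4-connected
#'   plus shape, used by default for hole filling).
#' @param size odd side length.
#' @return a `struct_elem`: binary matrix footprint with offset table.
#' @export
structuring_element <- function(shape = c("square", "identity", "cross"),
                                size = 5L) {
  shape <- match.arg(shape)
  size <- as.integer(size)
  stopifnot(size >= 1, size %% 2L == 1L)
  fp <- switch(shape,
    square = matrix(TRUE, size, size),
    identity = diag(size) > 0,
    cross = {
      mid <- (size + 1L) %/% 2L
      f <- matrix(FALSE, size, size)
      f[mid, ] <- TRUE
      f[, mid] <- TRUE
      f
    })
  structure(list(footprint = fp, shape = shape), class = "struct_elem")
}

se_offsets <- function(e) {
  fp <- e$footprint
  r0 <- (nrow(fp) + 1L) %/% 2L
  idx <- which(fp, arr.ind = TRUE)
  cbind(as.integer(idx[, 1] - r0), as.integer(idx[, 2] - r0))
}

as_mask <- function(x) {
  m <- matrix(as.logical(x != 0), nrow(x), ncol(x))
  m
}

#' Otsu global threshold
#'
#' Selects the intensity threshold `t` (on the image quantized to 256
#' levels) maximizing the between-class variance
#' `sigma_b^2(t) = omega1 omega2 (mu1 - mu2)^2`, which is equivalent to
#' minimizing the within-class variance. A pixel belongs to class 1 when its
#' level is `<= t`. Ties are broken towards the smallest `t`.
#'
#' @param img a [gray_image()] with at least two distinct quantized levels.
#' @return list with elements `t` (0-255), `sigma_b2` (length-256 vector of
#'   the criterion at each candidate threshold), `omega1`, `omega2`, `mu1`,
#'   `mu2` at the chosen threshold, and `total_var`.
#' @export
otsu_threshold <- function(img) {
  q <- quantize256(img)
  h <- tabulate(as.vector(q) + 1L, nbins = 256L)
  if (sum(h > 0) < 2) stop("degenerate histogram")
  p <- h / sum(h)
  lv <- 0:255
  om1 <- cumsum(p)                      # omega1(t): P(level <= t)
  m1c <- cumsum(p * lv)                 # partial first moment
  mu_tot <- m1c[256]
  om2 <- 1 - om1
  mu1 <- ifelse(om1 > 0, m1c / om1, 0)
  mu2 <- ifelse(om2 > 0, (mu_tot - m1c) / om2, 0)
  s_b2 <- ifelse(om1 > 0 & om2 > 0, om1 * om2 * (mu1 - mu2)^2, 0)
  t_opt <- which.max(s_b2) - 1L         # which.max returns first maximizer
  list(t = t_opt, sigma_b2 = s_b2,
       omega1 = om1[t_opt + 1L], omega2 = om2[t_opt + 1L],
       mu1 = mu1[t_opt + 1L], mu2 = mu2[t_opt + 1L],
       total_var = sum(p * (lv - mu_tot)^2))
}

#' Fill interior holes of a binary mask
#'
#' The filled mask is the complement of the background reachable from the
#' image border by iterated conditional dilation
#' `X_k = (X_{k-1} (+) e) n A^c`. The default element is the 3 x 3 cross
#' (4-connected background), the standard hole-filling kernel: an element
#' of radius 2 or more (such as the 5 x 5 square used for opening/closing)
#' would let the background jump across 1-pixel-thick region boundaries and
#' thin-walled holes would never fill.
#'
#' @param mask binary matrix.
#' @param e a [structuring_element()].
#' @return binary mask with interior holes filled (a superset of the input).
#' @export
fill_holes <- function(mask, e = structuring_element("cross", 3L)) {
  m <- as_mask(mask)
  reach <- cpp_border_reach(!m, se_offsets(e))
  m | !reach
}

#' Morphological opening (erosion then dilation)
#'
#' Removes details smaller than the structuring element; anti-extensive.
#' @inheritParams fill_holes
#' @export
morph_open <- function(mask, e = structuring_element()) {
  off <- se_offsets(e)
  cpp_dilate(cpp_erode(as_mask(mask), off), off)
}

#' Morphological closing (dilation then erosion)
#'
#' Bridges narrow gaps and closes small indentations; extensive. The mask
#' is padded by the element radius before the dilation so that closing is
#' computed with infinite-domain semantics (otherwise pixels on the image
#' border could be lost and extensivity would fail).
#' @inheritParams fill_holes
#' @export
morph_close <- function(mask, e = structuring_element()) {
  off <- se_offsets(e)
  m <- as_mask(mask)
  r <- max(abs(off))
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2 * r, nc + 2 * r)
  pad[r + seq_len(nr), r + seq_len(nc)] <- m
  out <- cpp_erode(cpp_dilate(pad, off), off)
  out[r + seq_len(nr), r + seq_len(nc), drop = FALSE]
}

#' Keep the largest connected component
#'
#' @param mask binary matrix.
#' @param connectivity 4 or 8 (default 8, standard for blob extraction).
#' @return binary mask of the largest component (empty mask if input empty).
#' @export
largest_component <- function(mask, connectivity = 8L) {
  m <- as_mask(mask)
  if (!any(m)) return(m)
  lab <- cpp_label(m, as.integer(connectivity))
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

#' Segment a lesion from a denoised image
#'
#' Otsu-thresholds the image, keeps the class with the lower mean intensity
#' as foreground (pigmented lesions are darker than surrounding skin), then
#' applies hole filling, opening and closing in that order, and finally
#' keeps the largest connected component.
#'
#' @param img a denoised [gray_image()].
#' @param e a [structuring_element()].
#' @param connectivity connectivity for the final component filter.
#' @return binary lesion mask (single connected component).
#' @export
segment_lesion <- function(img, e = structuring_element(),
                           connectivity = 8L) {
  th <- otsu_threshold(img)
  q <- quantize256(img)
  below <- q <= th$t
  # foreground = darker class
  fg <- if (th$mu1 <= th$mu2) below else !below
  fg <- fill_holes(fg)                 # 3x3 cross: see ?fill_holes
  fg <- morph_open(fg, e)
  fg <- morph_close(fg, e)
  if (!any(fg)) stop("no lesion found")
  largest_component(fg, connectivity)
}
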