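#' Grayscale image container
#'
#' A `gray_image` is a numeric matrix of intensities in `[0, 1]` (rows =
#' image rows). 8-bit inputs are rescaled by 1/255; RGB arrays are collapsed
#' with the standard luma weights (0.299, 0.587, 0.114) since the whole
#' pipeline is single-channel.
#'
#' @param pixels numeric matrix in `[0,1]`, an integer matrix in `0..255`,
#'   or an `H x W x 3` array (RGB, either scale).
#' @return a `gray_image` (numeric matrix with class attribute).
#' @export
gray_image <- function(pixels) {
  if (is.array(pixels) && length(dim(pixels)) == 3L) {
    if (dim(pixels)[3] != 3L) stop("expected an H x W x 3 RGB array")
    pixels <- 0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
  }
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  pixels <- matrix(as.numeric(pixels), nrow(pixels), ncol(pixels))
  if (any(!is.finite(pixels))) stop("non-finite pixel intensities")
  if (max(pixels) > 1 + 1e-12) pixels <- pixels / 255
  if (min(pixels) < -1e-12 || max(pixels) > 1 + 1e-12)
    stop("intensities outside [0, 1] after rescaling")
  pixels[pixels < 0] <- 0
  pixels[pixels > 1] <- 1
  structure(pixels, class = c("gray_image", "matrix", "array"))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, range [%.3f, %.3f]>\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

is_gray_image <- function(x) inherits(x, "gray_image")

as_matrix <- function(img) {
  m <- unclass(img)
  attr(m, "class") <- NULL
  m
}

#' Quantize an image to 256 uniform intensity levels
#'
#' @param img a [gray_image()].
#' @return integer matrix with values in `0..255`.
#' @export
quantize256 <- function(img) {
  q <- matrix(as.integer(round(as_matrix(img) * 255)), nrow(img), ncol(img))
  q[q < 0L] <- 0L
  q[q > 255L] <- 255L
  q
}

#' Bilinear resize
#'
#' Images are resized on load to a common working size (default 256 x 256)
#' so that geometric features are comparable across acquisitions.
#'
#' @param img a [gray_image()].
#' @param height,width target size in pixels.
#' @return resized [gray_image()].
#' @export
resize_bilinear <- function(img, height = 256L, width = 256L) {
  m <- as_matrix(img)
  nr <- nrow(m); nc <- ncol(m)
  if (nr == height && nc == width) return(gray_image(m))
  # sample at pixel centres of the target grid mapped into the source grid
  ry <- (seq_len(height) - 0.5) * nr / height - 0.5
  rx <- (seq_len(width) - 0.5) * nc / width - 0.5
  ry <- pmin(pmax(ry, 0), nr - 1)
  rx <- pmin(pmax(rx, 0), nc - 1)
  y0 <- pmin(floor(ry), nr - 2); x0 <- pmin(floor(rx), nc - 2)
  fy <- ry - y0; fx <- rx - x0
  i0 <- y0 + 1L; i1 <- i0 + 1L; j0 <- x0 + 1L; j1 <- j0 + 1L
  a <- m[i0, j0, drop = FALSE]; bqq <- m[i1, j0, drop = FALSE]
  cqq <- m[i0, j1, drop = FALSE]; d <- m[i1, j1, drop = FALSE]
  wy <- matrix(fy, height, width); wx <- matrix(fx, height, width, byrow = TRUE)
  out <- a * (1 - wy) * (1 - wx) + bqq * wy * (1 - wx) +
    cqq * (1 - wy) * wx + d * wy * wx
  gray_image(out)
}

#' Read / write plain-text PGM (P2) images
#'
#' The pipeline stores images as ASCII PGM: a portable, text-only format
#' readable by standard image tools. Values are 8-bit (maxval 255).
#'
#' @param path file path.
#' @return [gray_image()] for `read_pgm`.
#' @export
read_pgm <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^#", txt)]
  tok <- scan(text = paste(txt, collapse = " "), what = character(),
              quiet = TRUE)
  if (tok[1] != "P2") stop("only ASCII PGM (P2) supported")
  w <- as.integer(tok[2]); h <- as.integer(tok[3]); maxv <- as.numeric(tok[4])
  vals <- as.numeric(tok[-(1:4)])
  if (length(vals) != w * h) stop("corrupt PGM: wrong pixel count")
  gray_image(matrix(vals / maxv, nrow = h, ncol = w, byrow = TRUE))
}

#' @param img a [gray_image()] or binary mask matrix.
#' @rdname read_pgm
#' @export
write_pgm <- function(img, path) {
  m <- if (is_gray_image(img)) quantize256(img) else {
    m0 <- matrix(as.integer(img != 0), nrow(img), ncol(img))
    m0 * 255L
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), "255"), con)
  apply(m, 1, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}

#' Dice overlap between two binary masks
#'
#' @param a,b binary masks (logical/0-1 matrices of equal shape).
#' @return `2|A n B| / (|A| + |B|)`.
#' @export
dice <- function(a, b) {
  a <- a != 0; b <- b != 0
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}
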