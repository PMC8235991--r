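# Independent brute-force oracles used across the suite. These deliberately
# transcribe the defining formulas as plain loops; they must stay separate
# from the package's fast paths.

reflect1 <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

oracle_patch <- function(m, r, c, sim_r) {
  side <- 2 * sim_r + 1
  o <- matrix(0, side, side)
  for (dr in -sim_r:sim_r)
    for (dc in -sim_r:sim_r)
      o[dr + sim_r + 1, dc + sim_r + 1] <-
        m[reflect1(r + dr, nrow(m)), reflect1(c + dc, ncol(m))]
  o
}

oracle_kernel <- function(sim_r, sigma) {
  d <- -sim_r:sim_r
  k <- outer(exp(-d^2 / (2 * sigma^2)), exp(-d^2 / (2 * sigma^2)))
  k / sum(k)
}

# direct transcription of the NLM weighting equations
oracle_nlm <- function(m, h, search_r, sim_r, sigma) {
  K <- oracle_kernel(sim_r, sigma)
  out <- m * 0
  nr <- nrow(m); nc <- ncol(m)
  for (r in 1:nr) for (c in 1:nc) {
    z <- 0; acc <- 0
    for (r2 in max(1, r - search_r):min(nr, r + search_r)) {
      for (c2 in max(1, c - search_r):min(nc, c + search_r)) {
        d <- sum(K * (oracle_patch(m, r, c, sim_r) -
                        oracle_patch(m, r2, c2, sim_r))^2)
        w <- exp(-d / h^2)
        z <- z + w
        acc <- acc + w * m[r2, c2]
      }
    }
    out[r, c] <- acc / z
  }
  out
}

# exhaustive Otsu: evaluate the between-class variance at all 256 thresholds
oracle_otsu <- function(q) {
  v <- as.vector(q)
  n <- length(v)
  s_b2 <- numeric(256)
  for (t in 0:255) {
    g1 <- v[v <= t]; g2 <- v[v > t]
    if (length(g1) == 0 || length(g2) == 0) next
    w1 <- length(g1) / n; w2 <- length(g2) / n
    s_b2[t + 1] <- w1 * w2 * (mean(g1) - mean(g2))^2
  }
  list(t = which.max(s_b2) - 1L, sigma_b2 = s_b2)
}

# 4-connected flood fill of the background from the border
oracle_fill4 <- function(mask) {
  m <- mask != 0
  nr <- nrow(m); nc <- ncol(m)
  vis <- matrix(FALSE, nr, nc)
  stack <- which((row(m) == 1 | row(m) == nr | col(m) == 1 | col(m) == nc) & !m)
  vis[stack] <- TRUE
  stack <- as.list(stack)
  while (length(stack) > 0) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    r <- (p - 1) %% nr + 1; c <- (p - 1) %/% nr + 1
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
          !m[rr, cc] && !vis[rr, cc]) {
        vis[rr, cc] <- TRUE
        stack[[length(stack) + 1]] <- (cc - 1) * nr + rr
      }
    }
  }
  m | !vis
}

# erosion/dilation by definition (loop over offsets of the footprint)
oracle_erode <- function(mask, fp) {
  m <- mask != 0
  nr <- nrow(m); nc <- ncol(m)
  mid <- (dim(fp) + 1) %/% 2
  out <- matrix(TRUE, nr, nc)
  for (i in seq_len(nrow(fp))) for (j in seq_len(ncol(fp))) {
    if (!fp[i, j]) next
    dr <- i - mid[1]; dc <- j - mid[2]
    shifted <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 - dc):min(nc, nc - dc)
    shifted[rs, cs] <- m[rs + dr, cs + dc]
    out <- out & shifted
  }
  out
}

oracle_dilate <- function(mask, fp) {
  m <- mask != 0
  nr <- nrow(m); nc <- ncol(m)
  mid <- (dim(fp) + 1) %/% 2
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nrow(fp))) for (j in seq_len(ncol(fp))) {
    if (!fp[i, j]) next
    dr <- i - mid[1]; dc <- j - mid[2]
    shifted <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 - dc):min(nc, nc - dc)
    shifted[rs + dr, cs + dc] <- m[rs, cs]
    out <- out | shifted
  }
  out
}

# MCC as the Pearson correlation of the binary label vectors
oracle_mcc <- function(tp, fp, tn, fn) {
  truth <- c(rep(1, tp), rep(0, fp), rep(0, tn), rep(1, fn))
  pred <- c(rep(1, tp), rep(1, fp), rep(0, tn), rep(0, fn))
  if (length(unique(truth)) < 2 || length(unique(pred)) < 2) return(0)
  stats::cor(truth, pred)
}

# render a (possibly rotated) solid ellipse mask
render_ellipse <- function(size, a, b, theta = 0, cx = (size + 1) / 2,
                           cy = (size + 1) / 2) {
  rr <- matrix(seq_len(size), size, size)
  cc <- matrix(seq_len(size), size, size, byrow = TRUE)
  u <- (cc - cx) * cos(theta) + (rr - cy) * sin(theta)
  v <- -(cc - cx) * sin(theta) + (rr - cy) * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

random_mask <- function(nr, nc, p = 0.4) matrix(runif(nr * nc) < p, nr, nc)

as_mat <- function(img) {
  m <- unclass(img)
  attr(m, "class") <- NULL
  m
}
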