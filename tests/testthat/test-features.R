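test_that("intensity_stats matches definitions", {
  img <- gray_image(matrix(0.4, 5, 5))
  mask <- matrix(TRUE, 5, 5)
  expect_equal(unname(intensity_stats(img, mask)), c(0.4, 0, 0))
  m <- matrix(0, 4, 4); m[, 3:4] <- 1
  s <- intensity_stats(gray_image(m), matrix(TRUE, 4, 4))
  expect_equal(unname(s), c(0.5, 0.25, 0.5))
  set.seed(2)
  mm <- matrix(runif(64), 8, 8)
  msk <- random_mask(8, 8)
  s2 <- intensity_stats(gray_image(mm), msk)
  v <- c()
  for (r in 1:8) for (c in 1:8) if (msk[r, c]) v <- c(v, mm[r, c])
  expect_equal(s2[["mean"]], mean(v))
  expect_equal(s2[["variance"]], mean((v - mean(v))^2))
  expect_error(intensity_stats(img, matrix(FALSE, 5, 5)), "empty")
})

test_that("glcm counts co-occurring pairs, symmetrized and normalized", {
  # 2x2 checkerboard, 2 levels, horizontal displacement
  P <- glcm(gray_image(matrix(c(0, 0.9, 0.9, 0), 2, 2)), matrix(TRUE, 2, 2),
            levels = 2, displacement = c(0, 1))
  expect_equal(P[1, 2], 0.5)
  expect_equal(P[2, 1], 0.5)
  expect_equal(P[1, 1] + P[2, 2], 0)
  # constant region: all mass at (c, c)
  Pc <- glcm(gray_image(matrix(0.5, 3, 3)), matrix(TRUE, 3, 3), levels = 4)
  expect_equal(max(Pc), 1)
  expect_equal(sum(Pc), 1)
  # random 6x6 vs pair-enumeration oracle
  set.seed(8)
  m <- matrix(runif(36), 6, 6)
  msk <- random_mask(6, 6, 0.7)
  L <- 4
  P2 <- glcm(gray_image(m), msk, levels = L, displacement = c(1, 0))
  q <- pmin(floor(m * L) + 1, L)
  want <- matrix(0, L, L)
  for (r in 1:5) for (c in 1:6)
    if (msk[r, c] && msk[r + 1, c]) {
      want[q[r, c], q[r + 1, c]] <- want[q[r, c], q[r + 1, c]] + 1
      want[q[r + 1, c], q[r, c]] <- want[q[r + 1, c], q[r, c]] + 1
    }
  expect_equal(P2, want / sum(want))
  expect_error(glcm(gray_image(m), matrix(FALSE, 6, 6), levels = 4),
               "at least 2")
})

test_that("texture_features match their definitions", {
  L <- 5
  P <- diag(L) / L
  tx <- texture_features(P)
  expect_equal(tx[["contrast"]], 0)
  expect_equal(tx[["homogeneity"]], 1)
  expect_equal(tx[["correlation"]], 1)
  # degenerate single-cell matrix
  P1 <- matrix(0, 3, 3); P1[2, 2] <- 1
  t1 <- texture_features(P1)
  expect_equal(t1[["energy"]], 1)
  expect_equal(t1[["entropy"]], 0)
  expect_equal(t1[["correlation"]], 0)
  # random 4x4 vs 16-term hand summation
  set.seed(4)
  Pr <- matrix(runif(16), 4, 4)
  Pr <- Pr / sum(Pr)
  tr <- texture_features(Pr)
  con <- ent <- hom <- ene <- 0
  for (i in 1:4) for (j in 1:4) {
    con <- con + (i - j)^2 * Pr[i, j]
    if (Pr[i, j] > 0) ent <- ent - Pr[i, j] * log(Pr[i, j])
    hom <- hom + Pr[i, j] / (1 + abs(i - j))
    ene <- ene + Pr[i, j]^2
  }
  mur <- sum((1:4) * rowSums(Pr)); muc <- sum((1:4) * colSums(Pr))
  sr <- sqrt(sum((1:4 - mur)^2 * rowSums(Pr)))
  sc <- sqrt(sum((1:4 - muc)^2 * colSums(Pr)))
  cor0 <- 0
  for (i in 1:4) for (j in 1:4)
    cor0 <- cor0 + (i - mur) * (j - muc) * Pr[i, j] / (sr * sc)
  expect_equal(unname(tr), c(con, ent, hom, ene, cor0), tolerance = 1e-12)
})

test_that("shape_features: squares, lines and disks", {
  sq <- matrix(FALSE, 14, 14)
  sq[3:12, 3:12] <- TRUE
  s <- shape_features(sq)
  expect_equal(s[["area"]], 100)
  expect_equal(s[["perimeter"]], 40)
  expect_equal(s[["irregularity_index"]], 4 * pi * 100 / 40^2)
  expect_equal(s[["eccentricity"]], 0)
  line <- matrix(FALSE, 5, 24)
  line[3, 3:22] <- TRUE
  sl <- shape_features(line)
  expect_gte(sl[["eccentricity"]], 0.99)
  expect_lt(sl[["elongation"]], 0.5)
  expect_equal(sl[["rectangularity"]], 0)   # degenerate minor axis
  # discrete disk radius 30: hu_phi1 and irregularity vs brute force
  disk <- render_ellipse(71, 30, 30, cx = 36, cy = 36)
  sd0 <- shape_features(disk)
  rc <- which(disk, arr.ind = TRUE)
  A <- nrow(rc)
  mu20 <- sum((rc[, 1] - mean(rc[, 1]))^2)
  mu02 <- sum((rc[, 2] - mean(rc[, 2]))^2)
  expect_equal(sd0[["hu_phi1"]], (mu20 + mu02) / A^2, tolerance = 1e-12)
  expect_equal(sd0[["hu_phi1"]], 1 / (2 * pi), tolerance = 0.02)
  # perimeter: brute-force exposed-edge count
  per <- 0
  for (i in seq_len(A)) {
    r <- rc[i, 1]; c <- rc[i, 2]
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr < 1 || rr > 71 || cc < 1 || cc > 71 || !disk[rr, cc])
        per <- per + 1
    }
  }
  expect_equal(sd0[["perimeter"]], per)
  # taxicab perimeter of a digital disk is 8R + 4, so the index sits a bit
  # below pi^2/16 (~0.617), far from the continuous-circle value 1
  expect_equal(sd0[["perimeter"]], 8 * 30 + 4)
  expect_equal(sd0[["irregularity_index"]], pi^2 / 16, tolerance = 0.05)
  expect_equal(sd0[["elongation"]], 1, tolerance = 0.02)
})

test_that("shape features are translation invariant; hu_phi1 rotation invariant", {
  ell0 <- render_ellipse(101, 30, 15, theta = 0)
  ell45 <- render_ellipse(101, 30, 15, theta = pi / 4)
  s0 <- shape_features(ell0)
  s45 <- shape_features(ell45)
  expect_equal(s45[["hu_phi1"]], s0[["hu_phi1"]], tolerance = 0.02)
  expect_equal(s45[["eccentricity"]], s0[["eccentricity"]], tolerance = 0.02)
  shifted <- render_ellipse(101, 30, 15, theta = 0, cx = 61, cy = 41)
  ss <- shape_features(shifted)
  for (k in c("area", "rectangularity", "elongation", "form_factor",
              "eccentricity", "hu_phi1", "perimeter"))
    expect_equal(ss[[k]], s0[[k]], tolerance = 1e-12)
})

test_that("extract_all assembles 16 finite features deterministically", {
  set.seed(31)
  s <- gen_image("healthy", seed = 3, cfg = synth_config("easy", size = 64))
  f1 <- extract_all(s$image, s$truth_mask)
  f2 <- extract_all(s$image, s$truth_mask)
  expect_identical(f1, f2)
  expect_identical(names(f1), FEATURE_NAMES)
  expect_true(all(is.finite(f1)))
  expect_equal(f1[["area"]], sum(s$truth_mask))
  expect_gte(f1[["entropy"]], 0)
  expect_gt(f1[["energy"]], 0); expect_lte(f1[["energy"]], 1)
  expect_gt(f1[["homogeneity"]], 0); expect_lte(f1[["homogeneity"]], 1)
})
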