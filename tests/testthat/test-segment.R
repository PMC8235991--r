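test_that("otsu_threshold separates a two-level image and reports identities", {
  m <- matrix(10 / 255, 8, 8)
  m[, 5:8] <- 200 / 255
  th <- otsu_threshold(gray_image(m))
  expect_gte(th$t, 10)
  expect_lte(th$t, 199)
  q <- quantize256(gray_image(m))
  expect_true(all((q <= th$t) == (col(m) <= 4)))
  # smallest maximizer
  expect_equal(th$t, min(which(th$sigma_b2 == max(th$sigma_b2))) - 1L)
  # total variance = within + between at every threshold with two classes
  v <- as.vector(q)
  for (t in c(10, 50, 150, 199)) {
    g1 <- v[v <= t]; g2 <- v[v > t]
    w1 <- length(g1) / length(v); w2 <- 1 - w1
    s_w2 <- w1 * mean((g1 - mean(g1))^2) + w2 * mean((g2 - mean(g2))^2)
    expect_equal(s_w2 + th$sigma_b2[t + 1], th$total_var, tolerance = 1e-9)
  }
  expect_error(otsu_threshold(gray_image(matrix(0.5, 4, 4))),
               "degenerate histogram")
})

test_that("otsu_threshold equals the exhaustive 256-threshold oracle", {
  set.seed(21)
  for (rep in 1:100) {
    m <- matrix(runif(256), 16, 16)
    img <- gray_image(m)
    th <- otsu_threshold(img)
    or <- oracle_otsu(quantize256(img))
    expect_identical(th$t, or$t)
    expect_equal(th$sigma_b2, or$sigma_b2, tolerance = 1e-9)
  }
})

test_that("fill_holes fills rings and matches the flood-fill oracle", {
  ring <- matrix(FALSE, 9, 9)
  ring[3:7, 3:7] <- TRUE
  ring[4:6, 4:6] <- FALSE
  filled <- fill_holes(ring)
  want <- matrix(FALSE, 9, 9)
  want[3:7, 3:7] <- TRUE
  expect_equal(filled, want)
  # no holes: unchanged
  solid <- matrix(FALSE, 9, 9)
  solid[2:5, 2:5] <- TRUE
  expect_equal(fill_holes(solid), solid)
  # two disjoint hollow squares vs oracle
  two <- matrix(FALSE, 15, 15)
  two[2:6, 2:6] <- TRUE; two[3:5, 3:5] <- FALSE
  two[9:14, 8:14] <- TRUE; two[10:13, 9:13] <- FALSE
  expect_equal(fill_holes(two), oracle_fill4(two))
  # random masks: fixpoint of the iteration == flood-fill complement
  set.seed(3)
  for (rep in 1:10) {
    m <- random_mask(12, 12, 0.55)
    f <- fill_holes(m)
    expect_equal(f, oracle_fill4(m))
    expect_true(all(f[m]))              # output superset of input
  }
})

test_that("opening and closing match composition oracles and laws", {
  e3 <- structuring_element("square", 3)
  # isolated pixel removed by opening
  spk <- matrix(FALSE, 7, 7); spk[4, 4] <- TRUE
  expect_false(any(morph_open(spk, e3)))
  # solid square invariant under opening; closing of solid square unchanged
  sq <- matrix(FALSE, 24, 24); sq[3:22, 3:22] <- TRUE
  expect_equal(morph_open(sq, e3), sq)
  expect_equal(morph_close(sq, e3), sq)
  # two blocks bridged by closing
  blocks <- matrix(FALSE, 11, 12)
  blocks[4:8, 2:6] <- TRUE; blocks[4:8, 8:12] <- TRUE
  closed <- morph_close(blocks, e3)
  expect_true(all(closed[4:8, 7]))
  set.seed(9)
  for (e in list(e3, structuring_element("square", 5),
                 structuring_element("identity", 5))) {
    m <- random_mask(15, 15)
    o <- morph_open(m, e)
    cl <- morph_close(m, e)
    fp <- e$footprint
    expect_equal(o, oracle_dilate(oracle_erode(m, fp), fp))
    # compose the primitives on a padded domain (infinite-plane semantics)
    r <- (nrow(fp) - 1) %/% 2
    mp <- matrix(FALSE, 15 + 2 * r, 15 + 2 * r)
    mp[r + 1:15, r + 1:15] <- m
    clp <- oracle_erode(oracle_dilate(mp, fp), fp)
    expect_equal(cl, clp[r + 1:15, r + 1:15, drop = FALSE])
    expect_true(all(m[o]))              # anti-extensive
    expect_true(all(cl[m]))             # extensive
    expect_equal(morph_open(o, e), o)   # idempotent
    expect_equal(morph_close(cl, e), cl)
  }
})

test_that("segment_lesion recovers a dark disk and drops small specks", {
  set.seed(14)
  disk <- render_ellipse(64, 14, 14)
  m <- matrix(0.8, 64, 64)
  m[disk] <- 0.2
  m <- m + rnorm(64 * 64, 0, 0.03)
  img <- gray_image(pmin(pmax(m, 0), 1))
  mask <- segment_lesion(img)
  expect_gte(dice(mask, disk), 0.95)
  lab <- unique(as.vector(mask))
  expect_true(all(lab %in% c(TRUE, FALSE)))
  # add dark specks smaller than the 5x5 element: absent from final mask
  m2 <- matrix(0.8, 64, 64)
  m2[disk] <- 0.2
  m2[5, 5] <- 0.1; m2[10, 55] <- 0.1; m2[58, 6] <- 0.1
  mask2 <- segment_lesion(gray_image(m2))
  expect_false(mask2[5, 5] || mask2[10, 55] || mask2[58, 6])
  expect_gte(dice(mask2, disk), 0.95)
  # single connected component
  expect_equal(max(dermopt:::cpp_label(mask2, 8L)), 1L)
  expect_error(segment_lesion(gray_image(matrix(0.5, 8, 8))),
               "degenerate histogram")
})
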