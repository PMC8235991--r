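test_that("opposite is the bound reflection and an involution", {
  expect_equal(opposite(0.3, 0, 1), 0.7)
  expect_equal(opposite(0.5, 0, 1), 0.5)
  set.seed(12)
  for (rep in 1:20) {
    lo <- runif(4, -5, 0); hi <- runif(4, 1, 5)
    x <- lo + runif(4) * (hi - lo)
    expect_equal(opposite(opposite(x, lo, hi), lo, hi), x, tolerance = 1e-12)
  }
})

test_that("chaos map values and range containment", {
  expect_equal(chaos_step(0), 0)
  expect_equal(chaos_step(1), 0, tolerance = 1e-12)
  expect_equal(chaos_step(0.5, 2.3), 0.575)
  k <- 0.7
  for (i in 1:1000) {
    k <- chaos_step(k, 2.3)
    expect_gte(k, 0)
    expect_lte(k, 0.92)
  }
})

test_that("env_temperature follows the decay formula", {
  cfg <- optimizer_config(dim = 3, lower = 0, upper = 1, m1 = 0, m2 = 0,
                          use_chaos = FALSE)
  out <- env_temperature(c(0.2, 0.5, 0.9), t = 0.3, k = NA, cfg)
  expect_equal(out$temp, c(0.2, 0.5, 0.9))
  # t = 1: the m2 (1-t) term vanishes; verify against hand computation
  cfg2 <- optimizer_config(dim = 1, lower = 0, upper = 1, m1 = 1, m2 = 1,
                           use_chaos = FALSE)
  set.seed(77)
  r <- runif(1)
  set.seed(77)
  out2 <- env_temperature(0.8, t = 1, k = NA, cfg2)
  expect_equal(out2$temp, (1 - r) * 0.8, tolerance = 1e-12)
  # chaos mode consumes the chaotic stream, not the RNG
  cfg3 <- optimizer_config(dim = 1, lower = 0, upper = 1, m1 = 1, m2 = 1,
                           use_chaos = TRUE)
  out3 <- env_temperature(1, t = 0.5, k = 0.5, cfg3)
  k1 <- chaos_step(0.5, 2.3)
  expect_equal(out3$k, k1)
  expect_equal(out3$temp, 1 - (1 + 0.5) * k1, tolerance = 1e-12)
})

test_that("update_position interpolates between old and environment", {
  cfg <- optimizer_config(dim = 1, lower = -10, upper = 10)
  expect_equal(update_position(2, 1, gamma = 0, t = 0.7, cfg), 2)
  expect_equal(update_position(2, 1, gamma = 1e9, t = 1, cfg), 1)
  expect_equal(update_position(2, 1, gamma = 0.5, t = 0.4, cfg),
               1 + exp(-0.2), tolerance = 1e-12)
  # clamped to bounds
  cfg2 <- optimizer_config(dim = 1, lower = 0, upper = 1)
  expect_equal(update_position(0.5, 5, gamma = 1e9, t = 1, cfg2), 1)
})

test_that("component_reset fires with probability pr", {
  cfg0 <- optimizer_config(dim = 3, lower = 0, upper = 1, pr = 0)
  set.seed(1)
  for (rep in 1:20)
    expect_equal(component_reset(c(0.1, 0.2, 0.3), 0.5, 0.5, cfg0),
                 c(0.1, 0.2, 0.3))
  cfg1 <- optimizer_config(dim = 1, lower = -2, upper = 3, pr = 1)
  set.seed(2)
  for (rep in 1:20) {
    out <- component_reset(0.5, 0.5, 0.5, cfg1)
    expect_true(out != 0.5 || isTRUE(all.equal(out, 0.5)))
    expect_gte(out, -2); expect_lte(out, 3)
  }
  cfg <- optimizer_config(dim = 4, lower = 0, upper = 1, pr = 0.3)
  set.seed(3)
  hits <- 0L
  for (rep in 1:10000) {
    out <- component_reset(c(0.37, 0.37, 0.37, 0.37), 0.5, 0.5, cfg)
    if (any(out != 0.37)) hits <- hits + 1L
  }
  expect_equal(hits / 10000, 0.3, tolerance = 0.07)  # 0.3 +/- 0.02 abs
})

test_that("initialization respects bounds, seeds and opposition pairing", {
  cfg <- optimizer_config(dim = 5, lower = 0, upper = 1, pop_size = 8,
                          use_obl = FALSE)
  f <- function(x) sum(x^2)
  set.seed(10); p1 <- mteo_initialize(f, cfg)
  set.seed(10); p2 <- mteo_initialize(f, cfg)
  expect_identical(p1, p2)
  expect_true(all(p1$positions >= 0 & p1$positions <= 1))
  # OBL keeps the better of each (draw, opposite) pair
  cfg2 <- optimizer_config(dim = 3, lower = -1, upper = 1, pop_size = 6,
                           use_obl = TRUE)
  set.seed(11)
  init <- mteo_initialize(f, cfg2)
  for (i in 1:6) {
    op <- opposite(init$positions[i, ], -1, 1)
    expect_lte(init$costs[i], f(op) + 1e-12)
  }
  # hand-stepped transcription for a pop of 4 on a 1-D objective
  cfg3 <- optimizer_config(dim = 1, lower = 0, upper = 2, pop_size = 4,
                           use_obl = TRUE)
  g <- function(x) (x - 0.3)^2
  set.seed(5)
  init3 <- mteo_initialize(g, cfg3)
  set.seed(5)
  delta <- runif(4)
  pos <- 0 + delta * 2
  cost <- (pos - 0.3)^2
  for (i in 1:4) {
    op <- 2 + 0 - pos[i]
    oc <- (op - 0.3)^2
    if (oc < cost[i]) { pos[i] <- op; cost[i] <- oc }
  }
  expect_equal(as.vector(init3$positions), pos, tolerance = 1e-12)
  expect_equal(init3$costs, cost, tolerance = 1e-12)
})

test_that("optimizer errors on non-finite objectives", {
  cfg <- optimizer_config(dim = 2, lower = 0, upper = 1, pop_size = 4,
                          max_iter = 2, seed = 1)
  expect_error(mteo_optimize(function(x) NaN, cfg), "non-finite")
})

test_that("mteo_optimize: convergence, bounds, determinism, monotonicity", {
  f1 <- function(x) sum(x^2)
  cfg <- optimizer_config(dim = 10, lower = -100, upper = 100,
                          pop_size = 100, max_iter = 200, seed = 4)
  res <- mteo_optimize(f1, cfg)
  expect_lt(res$best_cost, 1e-3)
  expect_true(all(diff(res$history) <= 0))
  expect_equal(res$best_cost, min(res$history))
  res2 <- mteo_optimize(f1, cfg)
  expect_identical(res, res2)
  # every evaluated position within bounds (minimum at a bound corner)
  seen_out <- FALSE
  fb <- function(x) {
    if (any(x < -1 - 1e-12) || any(x > 1 + 1e-12)) seen_out <<- TRUE
    sum((x - 1)^2)                      # optimum at the upper corner
  }
  cfgb <- optimizer_config(dim = 3, lower = -1, upper = 1, pop_size = 10,
                           max_iter = 30, seed = 2)
  resb <- mteo_optimize(fb, cfgb)
  expect_false(seen_out)
  expect_true(all(resb$best_position >= -1 & resb$best_position <= 1))
})

test_that("two iterations match a straight-line transcription", {
  f <- function(x) sum(x^2)
  n <- 4; d <- 2; half <- 2
  lower <- rep(-1, d); upper <- rep(1, d)
  cfg <- optimizer_config(dim = d, lower = -1, upper = 1, pop_size = n,
                          max_iter = 2, pr = 0.5, tm_size = 2, seed = 99,
                          use_obl = TRUE, use_chaos = TRUE)
  res <- mteo_optimize(f, cfg)

  # transcription with the same RNG stream, written step by step
  set.seed(99)
  k <- runif(1, 0.5, 0.9)
  pos <- matrix(runif(n * d), n, d)
  pos <- matrix(lower, n, d, byrow = TRUE) +
    pos * matrix(upper - lower, n, d, byrow = TRUE)
  costs <- apply(pos, 1, f)
  for (i in 1:n) {
    op <- upper + lower - pos[i, ]
    if (f(op) < costs[i]) { pos[i, ] <- op; costs[i] <- f(op) }
  }
  ord <- order(costs)
  tmp <- pos[ord[1:2], , drop = FALSE]; tmc <- costs[ord[1:2]]
  best <- tmc[1]; bestp <- tmp[1, ]
  hist <- numeric(2)
  for (it in 1:2) {
    t <- it / 2
    ord <- order(costs, decreasing = TRUE)
    pos[ord[1:2], ] <- tmp; costs[ord[1:2]] <- tmc
    ord <- order(costs)
    pos <- pos[ord, , drop = FALSE]; costs <- costs[ord]
    worst <- costs[n]
    for (i in 1:half) {
      ci <- half + i
      gam <- if (worst == 0) 0 else costs[ci] / worst
      m1 <- as.numeric(runif(1) < 0.5); m2 <- as.numeric(runif(1) < 0.5)
      k <- 2.3 * k^2 * sin(pi * k)
      Te <- (1 - (m1 + m2 * (1 - t)) * k) * pos[i, ]
      cand <- pmin(pmax(Te + (pos[ci, ] - Te) * exp(-gam * t), lower), upper)
      if (runif(1) < 0.5) {
        j <- sample.int(d, 1)
        cand[j] <- lower[j] + runif(1) * (upper[j] - lower[j]) * exp(-gam * t)
        cand <- pmin(pmax(cand, lower), upper)
      }
      cc <- f(cand)
      op <- upper + lower - cand
      if (f(op) < cc) { cand <- op; cc <- f(op) }
      pos[ci, ] <- cand; costs[ci] <- cc
      if (cc < best) { best <- cc; bestp <- cand }
    }
    allp <- rbind(tmp, pos); allc <- c(tmc, costs)
    o2 <- order(allc)[1:2]
    tmp <- allp[o2, , drop = FALSE]; tmc <- allc[o2]
    hist[it] <- best
  }
  expect_equal(res$best_cost, best, tolerance = 1e-12)
  expect_equal(res$best_position, bestp, tolerance = 1e-12)
  expect_equal(res$history, hist, tolerance = 1e-12)
})
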