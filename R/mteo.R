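#' Configuration for the TEO / MTEO optimizer
#'
#' Thermal Exchange Optimization (TEO) evolves a population of "objects"
#' whose positions cool towards paired environment objects following
#' Newton's law of cooling, `T+ = T_e + (T_old - T_e) exp(-gamma t)`. The
#' Modified variant (MTEO) adds opposition-based learning (OBL) and replaces
#' the uniform random factor in the environmental-temperature decay with a
#' sinusoidal chaotic map.
#'
#' @param dim problem dimensionality.
#' @param lower,upper box bounds, scalars or length-`dim` vectors.
#' @param pop_size even population size `n` (the population splits into an
#'   environment half and a cooling half).
#' @param max_iter number of iterations.
#' @param pr probability, per cooling object per iteration, of rewriting one
#'   randomly chosen component (exploration kick). Default 0.05, the typical
#'   setting in the original TEO literature; larger values trade convergence
#'   depth for exploration.
#' @param m1,m2 environmental-temperature control variables. `NULL` (the
#'   default) draws each independently from `{0, 1}` per object per
#'   iteration, the original TEO convention; numeric values fix them.
#' @param chaos_alpha control parameter of the sinusoidal map (default 2.3).
#' @param tm_size thermal-memory size: the number of best-ever solutions
#'   re-injected each iteration over the worst individuals (elitism).
#' @param seed integer RNG seed, or `NULL` to use the current RNG state.
#' @param use_obl enable opposition-based learning (at initialization and
#'   after every position update, greedy keep-better).
#' @param use_chaos use chaotic iterates instead of uniform draws in the
#'   environmental-temperature update.
#' @return an `optimizer_config` list.
#' @export
optimizer_config <- function(dim, lower, upper, pop_size = 30L,
                             max_iter = 100L, pr = 0.05, m1 = NULL, m2 = NULL,
                             chaos_alpha = 2.3, tm_size = 4L, seed = NULL,
                             use_obl = TRUE, use_chaos = TRUE) {
  dim <- as.integer(dim)
  lower <- rep_len(as.numeric(lower), dim)
  upper <- rep_len(as.numeric(upper), dim)
  pop_size <- as.integer(pop_size)
  stopifnot(dim >= 1, all(lower < upper), pop_size >= 2,
            pop_size %% 2L == 0L, max_iter >= 1, pr >= 0, pr <= 1,
            tm_size >= 1, chaos_alpha > 0)
  structure(list(dim = dim, lower = lower, upper = upper,
                 pop_size = pop_size, max_iter = as.integer(max_iter),
                 pr = pr, m1 = m1, m2 = m2, chaos_alpha = chaos_alpha,
                 tm_size = as.integer(tm_size), seed = seed,
                 use_obl = isTRUE(use_obl), use_chaos = isTRUE(use_chaos)),
            class = "optimizer_config")
}

#' Opposite position (opposition-based learning)
#'
#' Componentwise bound reflection `T_hat = T_max + T_min - T`; an
#' involution with the box midpoint as fixed point.
#'
#' @param position numeric vector within the bounds.
#' @param lower,upper bounds (recycled to the position's length).
#' @export
opposite <- function(position, lower, upper) {
  rep_len(upper, length(position)) + rep_len(lower, length(position)) - position
}

#' One step of the sinusoidal chaotic map
#'
#' `k' = alpha * k^2 * sin(pi k)`; with `alpha = 2.3` the iterates stay in
#' `(0, 1)` and behave chaotically, substituting for uniform draws.
#'
#' @param k current value in `[0, 1]`.
#' @param alpha control parameter.
#' @export
chaos_step <- function(k, alpha = 2.3) {
  alpha * k^2 * sin(pi * k)
}

draw_m <- function(m) {
  if (is.null(m)) as.numeric(stats::runif(1) < 0.5) else as.numeric(m)
}

#' Environmental temperature update
#'
#' Scales the paired environment object's position by
#' `1 - (m1 + m2 (1 - t)) r`, where `r` is a uniform draw (TEO) or the next
#' chaotic iterate (MTEO). Draws `m1`, `m2` and `r` from the current RNG /
#' chaotic stream, so the call advances both.
#'
#' @param T_env environment object's position vector.
#' @param t normalized time `iteration / max_iter` in `[0, 1]`.
#' @param k current chaotic value (used and advanced only when
#'   `cfg$use_chaos`).
#' @param cfg an [optimizer_config()].
#' @return list with `temp` (the new environmental temperature vector) and
#'   `k` (the advanced chaotic value).
#' @export
env_temperature <- function(T_env, t, k, cfg) {
  m1 <- draw_m(cfg$m1)
  m2 <- draw_m(cfg$m2)
  if (cfg$use_chaos) {
    k <- chaos_step(k, cfg$chaos_alpha)
    r <- k
  } else {
    r <- stats::runif(1)
  }
  list(temp = (1 - (m1 + m2 * (1 - t)) * r) * T_env, k = k)
}

#' Newton-cooling position update
#'
#' `T+ = T_e + (T_old - T_e) exp(-gamma t)`, clamped to the box.
#'
#' @param T_old cooling object's current position.
#' @param T_e its environmental temperature (from [env_temperature()]).
#' @param gamma cooling coefficient, the object's cost divided by the worst
#'   cost in the population (0 when the worst cost is 0).
#' @param t normalized time.
#' @param cfg an [optimizer_config()].
#' @export
update_position <- function(T_old, T_e, gamma, t, cfg) {
  pmin(pmax(T_e + (T_old - T_e) * cooling_factor(gamma, t), cfg$lower),
       cfg$upper)
}

# exp(-gamma t), with the exponent capped so that negative costs (which can
# make gamma negative and the factor explode) stay finite; the position is
# clamped to the box afterwards in any case.
cooling_factor <- function(gamma, t) {
  exp(-min(max(gamma * t, -50), 700))
}

#' Random single-component reset
#'
#' With probability `cfg$pr`, one uniformly chosen dimension `j` is
#' rewritten as `T_j_min + rnd (T_j_max - T_j_min) exp(-gamma t)`.
#'
#' @inheritParams update_position
#' @param position position vector to (possibly) perturb.
#' @export
component_reset <- function(position, gamma, t, cfg) {
  if (stats::runif(1) < cfg$pr) {
    j <- sample.int(cfg$dim, 1L)
    position[j] <- cfg$lower[j] +
      stats::runif(1) * (cfg$upper[j] - cfg$lower[j]) * cooling_factor(gamma, t)
    position <- pmin(pmax(position, cfg$lower), cfg$upper)
  }
  position
}

eval_cost <- function(objective, x) {
  v <- objective(x)
  if (!is.finite(v))
    stop("objective returned a non-finite value at position (",
         paste(signif(x, 6), collapse = ", "), ")")
  v
}

#' Initialize a TEO / MTEO population
#'
#' Draws `n` positions uniformly in the box (`T_i = T_min + delta
#' (T_max - T_min)`); with OBL each draw is paired with its opposite and the
#' cheaper of the two kept. Consumes the current RNG stream (seed with
#' `set.seed` or run through [mteo_optimize()]).
#'
#' @param objective function mapping a position vector to a finite scalar
#'   cost (minimized).
#' @param cfg an [optimizer_config()].
#' @return list with `positions` (n x dim matrix), `costs`, `n_evals`.
#' @export
mteo_initialize <- function(objective, cfg) {
  n <- cfg$pop_size; d <- cfg$dim
  delta <- matrix(stats::runif(n * d), n, d)
  pos <- matrix(cfg$lower, n, d, byrow = TRUE) +
    delta * matrix(cfg$upper - cfg$lower, n, d, byrow = TRUE)
  costs <- apply(pos, 1, function(x) eval_cost(objective, x))
  n_evals <- n
  if (cfg$use_obl) {
    for (i in seq_len(n)) {
      op <- opposite(pos[i, ], cfg$lower, cfg$upper)
      oc <- eval_cost(objective, op)
      n_evals <- n_evals + 1L
      if (oc < costs[i]) {
        pos[i, ] <- op
        costs[i] <- oc
      }
    }
  }
  list(positions = pos, costs = costs, n_evals = n_evals)
}

#' Run the TEO / MTEO optimizer
#'
#' Full loop: after (optionally opposition-paired) initialization, each
#' iteration re-injects the thermal memory (best-ever archive) over the
#' worst individuals, sorts the population by cost, pairs the best half
#' (environment objects) with the worst half (cooling objects), and moves
#' every cooling object by the Newton-cooling rule with environmental
#' temperature decay, random component reset, and (MTEO) greedy
#' opposition-based reselection. The best-so-far history is non-increasing
#' by construction.
#'
#' @inheritParams mteo_initialize
#' @return list with `best_position`, `best_cost`, `history` (best cost per
#'   iteration), `n_evals`.
#' @export
mteo_optimize <- function(objective, cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$pop_size; d <- cfg$dim
  half <- n %/% 2L
  # seed the chaotic stream inside the map's chaotic basin: iterates started
  # below ~0.37 collapse to the fixed point 0 and the stream degenerates
  k <- if (cfg$use_chaos) stats::runif(1, 0.5, 0.9) else NA_real_
  init <- mteo_initialize(objective, cfg)
  pos <- init$positions; costs <- init$costs; n_evals <- init$n_evals
  tm_k <- min(cfg$tm_size, n - 1L)
  ord <- order(costs)
  tm_pos <- pos[ord[seq_len(tm_k)], , drop = FALSE]
  tm_costs <- costs[ord[seq_len(tm_k)]]
  best_cost <- tm_costs[1]
  best_pos <- tm_pos[1, ]
  history <- numeric(cfg$max_iter)
  for (it in seq_len(cfg$max_iter)) {
    t <- it / cfg$max_iter
    # thermal-memory injection: archive replaces the current worst
    ord <- order(costs, decreasing = TRUE)
    repl <- ord[seq_len(tm_k)]
    pos[repl, ] <- tm_pos
    costs[repl] <- tm_costs
    ord <- order(costs)
    pos <- pos[ord, , drop = FALSE]
    costs <- costs[ord]
    worst <- costs[n]
    for (i in seq_len(half)) {
      ci <- half + i                     # cooling object, paired with env i
      gamma <- if (worst == 0) 0 else costs[ci] / worst
      et <- env_temperature(pos[i, ], t, k, cfg)
      k <- et$k
      cand <- update_position(pos[ci, ], et$temp, gamma, t, cfg)
      cand <- component_reset(cand, gamma, t, cfg)
      cc <- eval_cost(objective, cand)
      n_evals <- n_evals + 1L
      if (cfg$use_obl) {
        op <- opposite(cand, cfg$lower, cfg$upper)
        oc <- eval_cost(objective, op)
        n_evals <- n_evals + 1L
        if (oc < cc) {
          cand <- op
          cc <- oc
        }
      }
      pos[ci, ] <- cand
      costs[ci] <- cc
      if (cc < best_cost) {
        best_cost <- cc
        best_pos <- cand
      }
    }
    # refresh thermal memory with the best of (archive U population)
    all_pos <- rbind(tm_pos, pos)
    all_costs <- c(tm_costs, costs)
    ord <- order(all_costs)[seq_len(tm_k)]
    tm_pos <- all_pos[ord, , drop = FALSE]
    tm_costs <- all_costs[ord]
    history[it] <- best_cost
  }
  list(best_position = best_pos, best_cost = best_cost, history = history,
       n_evals = n_evals)
}

#' @describeIn mteo_optimize plain TEO: the same loop with OBL and the
#'   chaotic map disabled.
#' @export
teo_optimize <- function(objective, cfg) {
  cfg$use_obl <- FALSE
  cfg$use_chaos <- FALSE
  mteo_optimize(objective, cfg)
}
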