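#' Particle swarm configuration
#'
#' Defaults follow the benchmark protocol: 260 particles, an 800-iteration
#' cap, learning factors lambda1 = lambda2 = 2.0. The inertia weight is
#' scheduled linearly from `inertia_start` (0.9) to `inertia_end` (0.4) over
#' the run, a standard choice since no fixed value is prescribed; velocities
#' are clamped to `[-v_max, v_max]` per component (v_max = pi prevents
#' wrap-around aliasing of angle updates).
#'
#' @param swarm_size number of particles (>= 2).
#' @param iters iteration cap for a standalone PSO run.
#' @param lambda1,lambda2 cognitive and social learning factors (>= 0).
#' @param inertia_start,inertia_end endpoints of the linear inertia schedule,
#'   each in (0, 1].
#' @param v_max per-component velocity clamp (radians/iteration).
#' @param seed integer RNG seed, or `NULL` to use the current RNG state.
#' @param scalar_draws if `TRUE`, draw one r1/r2 pair per particle instead of
#'   per dimension (per-dimension is the default and standard).
#' @return a list of class `"pso_config"`.
#' @export
pso_config <- function(swarm_size = 260, iters = 800,
                       lambda1 = 2.0, lambda2 = 2.0,
                       inertia_start = 0.9, inertia_end = 0.4,
                       v_max = pi, seed = NULL, scalar_draws = FALSE) {
  stopifnot(swarm_size >= 2, iters >= 1, lambda1 >= 0, lambda2 >= 0,
            inertia_start > 0, inertia_start <= 1,
            inertia_end > 0, inertia_end <= 1, v_max > 0)
  structure(list(swarm_size = as.integer(swarm_size),
                 iters = as.integer(iters),
                 lambda1 = lambda1, lambda2 = lambda2,
                 inertia_start = inertia_start, inertia_end = inertia_end,
                 v_max = v_max, seed = seed,
                 scalar_draws = isTRUE(scalar_draws)),
            class = "pso_config")
}

#' Inertia weight at a given iteration
#'
#' Linear interpolation from `inertia_start` at iteration 0 to `inertia_end`
#' at the phase cap; monotone non-increasing.
#'
#' @param iteration current iteration (0-based), `0 <= iteration <= cap`.
#' @param config a [pso_config()].
#' @param cap the phase iteration cap (defaults to `config$iters`).
#' @return scalar inertia weight.
#' @export
inertia_at <- function(iteration, config, cap = config$iters) {
  stopifnot(iteration >= 0, iteration <= cap)
  if (cap == 0) return(config$inertia_start)
  config$inertia_start +
    (config$inertia_end - config$inertia_start) * iteration / cap
}

#' Velocity update rule
#'
#' `v' = inertia * v + lambda1 * r1 * (pbest - x) + lambda2 * r2 * (gbest - x)`,
#' clamped component-wise to `[-v_max, v_max]`. All arguments may be vectors
#' (one particle) or conformable matrices (whole swarm, particles in rows).
#'
#' @param velocity,position current velocity and position.
#' @param pbest,gbest personal-best and global-best positions.
#' @param inertia inertia weight.
#' @param lambda1,lambda2 learning factors.
#' @param r1,r2 uniform(0,1) draws, conformable with `position`.
#' @param v_max clamp bound.
#' @return updated velocity.
#' @export
update_velocity <- function(velocity, position, pbest, gbest, inertia,
                            lambda1, lambda2, r1, r2, v_max = pi) {
  if (is.matrix(position) && !is.matrix(gbest))
    gbest <- matrix(gbest, nrow = nrow(position), ncol = ncol(position),
                    byrow = TRUE)
  if (length(velocity) != length(position) || length(pbest) != length(position))
    stop("velocity/position/pbest dimensions disagree", call. = FALSE)
  v <- inertia * velocity + lambda1 * r1 * (pbest - position) +
    lambda2 * r2 * (gbest - position)
  pmin(pmax(v, -v_max), v_max)
}

#' Position update rule
#'
#' `x' = wrap_angle(x + v')`, component-wise; positions always remain in
#' `[-pi, pi)`.
#'
#' @param position current position (vector or matrix).
#' @param velocity updated velocity.
#' @return new position.
#' @export
update_position <- function(position, velocity) {
  out <- wrap_angle(position + velocity)
  if (is.matrix(position)) out <- matrix(out, nrow = nrow(position))
  out
}

#' Initialize a swarm
#'
#' Positions uniform on `[-pi, pi)` per dimension, velocities uniform on
#' `[-v_max/2, v_max/2]`; personal and global bests set from the initial
#' energies. Uses the current RNG state (seed it upstream).
#'
#' @param sequence an [ab_sequence()] (or string), n >= 3.
#' @param config a [pso_config()].
#' @return a list of class `"swarm_state"`: `positions`, `velocities`
#'   (swarm_size x (n-2) matrices), `pbest_pos`, `pbest_e`, `gbest_pos`,
#'   `gbest_e`, `iteration`.
#' @export
init_swarm <- function(sequence, config) {
  s <- as_ab_sequence(sequence)
  n <- length(s)
  if (n < 3L) stop("PSO needs n >= 3", call. = FALSE)
  d <- n - 2L
  m <- config$swarm_size
  pos <- matrix(runif(m * d, -pi, pi), nrow = m)
  vel <- matrix(runif(m * d, -config$v_max / 2, config$v_max / 2), nrow = m)
  e <- energy_fitness_batch(eta_of(s), pos)
  gi <- which.min(e)
  structure(list(positions = pos, velocities = vel,
                 pbest_pos = pos, pbest_e = e,
                 gbest_pos = pos[gi, ], gbest_e = e[gi],
                 iteration = 0L),
            class = "swarm_state")
}

#' One PSO iteration
#'
#' Updates every particle's velocity and position, re-evaluates energies and
#' refreshes the personal and global bests. A particle whose move lands on a
#' diverging conformation (+Inf energy) is resampled uniformly within bounds.
#' The global-best energy never increases. Consumes the current RNG stream.
#'
#' @param swarm a `"swarm_state"` from [init_swarm()].
#' @param sequence the chain being folded.
#' @param config a [pso_config()].
#' @param cap phase iteration cap used by the inertia schedule.
#' @return the updated `"swarm_state"` (iteration counter advanced by 1).
#' @export
pso_step <- function(swarm, sequence, config, cap = config$iters) {
  s <- as_ab_sequence(sequence)
  eta <- eta_of(s)
  m <- nrow(swarm$positions)
  d <- ncol(swarm$positions)
  w <- inertia_at(min(swarm$iteration, cap), config, cap)
  if (config$scalar_draws) {
    r1 <- matrix(runif(m), nrow = m, ncol = d)
    r2 <- matrix(runif(m), nrow = m, ncol = d)
  } else {
    r1 <- matrix(runif(m * d), nrow = m)
    r2 <- matrix(runif(m * d), nrow = m)
  }
  vel <- update_velocity(swarm$velocities, swarm$positions, swarm$pbest_pos,
                         swarm$gbest_pos, w, config$lambda1, config$lambda2,
                         r1, r2, config$v_max)
  pos <- update_position(swarm$positions, vel)
  e <- energy_fitness_batch(eta, pos)
  bad <- which(!is.finite(e))
  if (length(bad) > 0L) {
    pos[bad, ] <- matrix(runif(length(bad) * d, -pi, pi), nrow = length(bad))
    vel[bad, ] <- 0
    e[bad] <- energy_fitness_batch(eta, pos[bad, , drop = FALSE])
  }
  improved <- e < swarm$pbest_e
  swarm$pbest_pos[improved, ] <- pos[improved, , drop = FALSE]
  swarm$pbest_e[improved] <- e[improved]
  gi <- which.min(swarm$pbest_e)
  if (swarm$pbest_e[gi] < swarm$gbest_e) {
    swarm$gbest_e <- swarm$pbest_e[gi]
    swarm$gbest_pos <- swarm$pbest_pos[gi, ]
  }
  swarm$positions <- pos
  swarm$velocities <- vel
  swarm$iteration <- swarm$iteration + 1L
  swarm
}

#' Convergence test on a best-energy trace
#'
#' `TRUE` when the best energy improved by less than `tolerance` over the
#' last `window` recorded iterations, or when the phase iteration budget
#' (`cap`, if finite) is exhausted. Used to trigger the PSO-to-tabu handoff.
#'
#' @param trace numeric vector of best-so-far energies, one per iteration.
#' @param window lookback length in iterations.
#' @param tolerance minimum improvement regarded as progress.
#' @param cap optional phase budget; `length(trace) >= cap` forces `TRUE`.
#' @return logical flag.
#' @export
has_converged <- function(trace, window = 50, tolerance = 1e-4, cap = Inf) {
  stopifnot(length(trace) >= 1)
  if (length(trace) >= cap) return(TRUE)
  if (length(trace) < window) return(FALSE)
  improvement <- trace[length(trace) - window + 1] - trace[length(trace)]
  improvement < tolerance
}

#' Run particle swarm optimization
#'
#' Seeds the RNG (if `config$seed` is set), initializes the swarm and
#' iterates [pso_step()] up to `max_iters` times, optionally stopping early
#' on [has_converged()]. The returned trace holds the global-best energy
#' after each iteration and is monotone non-increasing.
#'
#' @param sequence an [ab_sequence()] (or string), n >= 3.
#' @param config a [pso_config()].
#' @param max_iters iteration budget (defaults to `config$iters`).
#' @param stop_on_converged stop when [has_converged()] fires.
#' @param window,tolerance convergence parameters for the early stop.
#' @return list with `best_position`, `best_energy`, `trace`,
#'   `iterations` (= length of trace) and `swarm` (final state).
#' @export
run_pso <- function(sequence, config = pso_config(),
                    max_iters = config$iters, stop_on_converged = FALSE,
                    window = 50, tolerance = 1e-4) {
  if (!is.null(config$seed)) set.seed(config$seed)
  swarm <- init_swarm(sequence, config)
  trace <- numeric(0)
  for (k in seq_len(max_iters)) {
    swarm <- pso_step(swarm, sequence, config, cap = max_iters)
    trace[k] <- swarm$gbest_e
    if (stop_on_converged && has_converged(trace, window, tolerance))
      break
  }
  list(best_position = swarm$gbest_pos, best_energy = swarm$gbest_e,
       trace = trace, iterations = length(trace), swarm = swarm)
}
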