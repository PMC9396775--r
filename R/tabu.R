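#' Tabu search configuration
#'
#' Defaults follow the benchmark protocol: L = 40 neighborhood solutions per
#' iteration, candidate set size L_C = 6, perturbation scale factor K = 0.93,
#' tabu list length (and tenure) L_T = 8, tabu thresholds E_0 = 0.10 on
#' energy and r_0 = 0.005 on the Euclidean distance between angle vectors.
#'
#' @param L neighbors generated per iteration.
#' @param Lc candidate set size, `1 <= Lc <= L`.
#' @param K perturbation scale factor (> 0).
#' @param Lt tabu list capacity, also used as the tenure.
#' @param E0 energy-closeness threshold of the tabu criterion.
#' @param r0 conformation-distance threshold of the tabu criterion.
#' @param iters iteration cap for a standalone tabu run.
#' @param seed integer RNG seed, or `NULL` to use the current RNG state.
#' @param k_power_mode if `TRUE`, scale the i-th neighbor's step by `K^i`
#'   (i = 0..L-1) instead of the constant `K`; off by default (the plain
#'   reading of the neighborhood rule).
#' @return a list of class `"tabu_config"`.
#' @export
tabu_config <- function(L = 40, Lc = 6, K = 0.93, Lt = 8,
                        E0 = 0.10, r0 = 0.005, iters = 800,
                        seed = NULL, k_power_mode = FALSE) {
  stopifnot(L >= 1, Lc >= 1, Lc <= L, K > 0, Lt >= 1, E0 > 0, r0 > 0,
            iters >= 1)
  structure(list(L = as.integer(L), Lc = as.integer(Lc), K = K,
                 Lt = as.integer(Lt), E0 = E0, r0 = r0,
                 iters = as.integer(iters), seed = seed,
                 k_power_mode = isTRUE(k_power_mode)),
            class = "tabu_config")
}

#' Sign factor of the perturbation
#'
#' +1 when the uniform draw q is below 0.5, otherwise -1 (the boundary
#' q = 0.5 takes the minus branch).
#'
#' @param q a draw in `[0, 1]`. Vectorized.
#' @return +1 or -1 per element.
#' @export
sign_factor <- function(q) {
  if (any(q < 0 | q > 1)) stop("q must lie in [0, 1]", call. = FALSE)
  ifelse(q < 0.5, 1, -1)
}

#' Single-coordinate perturbation
#'
#' The neighborhood move: one chosen bend angle becomes
#' `wrap_angle(x_j + f(q) * pi * Q * K)`; all other coordinates are
#' unchanged. `Q` sets the step magnitude (uniform(0,1) in practice, so the
#' largest step is pi * K), `K` is the scale factor.
#'
#' @param solution numeric angle vector.
#' @param coordinate_index which coordinate to mutate (1-based).
#' @param q sign draw in `[0, 1]`.
#' @param Q magnitude draw in `[0, 1]`.
#' @param K scale factor.
#' @return the neighbor solution.
#' @export
perturb <- function(solution, coordinate_index, q, Q, K = 0.93) {
  if (coordinate_index < 1 || coordinate_index > length(solution))
    stop("coordinate_index out of range", call. = FALSE)
  stopifnot(Q >= 0, Q <= 1)
  out <- solution
  out[coordinate_index] <-
    wrap_angle(solution[coordinate_index] + sign_factor(q) * pi * Q * K)
  out
}

#' Generate the neighborhood of a solution
#'
#' Draws L single-point mutations: for each neighbor a coordinate index is
#' chosen uniformly and (q, Q) are drawn independently uniform(0,1).
#' Consumes the current RNG stream.
#'
#' @param solution numeric angle vector.
#' @param L number of neighbors.
#' @param config a [tabu_config()] (supplies K and `k_power_mode`).
#' @return an L x length(solution) matrix, one neighbor per row.
#' @export
generate_neighbors <- function(solution, L, config = tabu_config()) {
  d <- length(solution)
  idx <- sample.int(d, L, replace = TRUE)
  q <- runif(L)
  Q <- runif(L)
  scale <- if (config$k_power_mode) config$K^(seq_len(L) - 1) else config$K
  out <- matrix(rep(solution, each = L), nrow = L)
  step <- sign_factor(q) * pi * Q * scale
  out[cbind(seq_len(L), idx)] <-
    wrap_angle(solution[idx] + step)
  out
}

#' Select the candidate set
#'
#' The `Lc` lowest-energy neighbors, in ascending energy order; ties are
#' broken by generation index (earlier neighbor wins).
#'
#' @param neighbors neighbor matrix (rows are solutions).
#' @param energies their energies.
#' @param Lc candidate set size.
#' @return list with `solutions` (matrix, ascending energy), `energies`, and
#'   `index` (original generation indices).
#' @export
select_candidates <- function(neighbors, energies, Lc) {
  ord <- order(energies, seq_along(energies))
  take <- ord[seq_len(min(Lc, length(energies)))]
  list(solutions = neighbors[take, , drop = FALSE],
       energies = energies[take], index = take)
}

#' Tabu criterion
#'
#' A candidate z is tabu when some listed solution y is close to it in BOTH
#' energy (`|E(y) - E(z)| <= E0`) and conformation (Euclidean distance
#' `||y - z|| <= r0`). An empty list never tabus.
#'
#' @param candidate angle vector z.
#' @param candidate_energy its energy E(z).
#' @param tabu_list a `"tabu_list"` (see [new_tabu_list()]).
#' @param E0,r0 thresholds.
#' @return logical flag.
#' @export
is_tabu <- function(candidate, candidate_energy, tabu_list,
                    E0 = 0.10, r0 = 0.005) {
  for (entry in tabu_list$entries) {
    if (abs(entry$energy - candidate_energy) <= E0 &&
        sqrt(sum((entry$solution - candidate)^2)) <= r0)
      return(TRUE)
  }
  FALSE
}

#' Aspiration (contempt) criterion
#'
#' A tabu candidate is accepted anyway when it is strictly better than the
#' best solution found so far.
#'
#' @param candidate_energy energy of the tabu candidate.
#' @param best_so_far_energy incumbent best energy.
#' @return logical flag.
#' @export
aspiration_overrides <- function(candidate_energy, best_so_far_energy) {
  stopifnot(is.finite(candidate_energy), is.finite(best_so_far_energy))
  candidate_energy < best_so_far_energy
}

#' Create an empty tabu list
#'
#' @param Lt capacity (and initial tenure of each new entry).
#' @return a list of class `"tabu_list"` with fields `entries` (ordered by
#'   insertion) and `Lt`.
#' @export
new_tabu_list <- function(Lt = 8) {
  structure(list(entries = list(), Lt = as.integer(Lt)), class = "tabu_list")
}

#' Advance the tabu list by one iteration
#'
#' Every existing tenure is decremented first; entries reaching 0 are lifted.
#' The newly accepted solution then joins with full tenure `Lt`; if the list
#' would exceed its capacity the oldest entry is evicted (FIFO).
#'
#' @param tabu_list a `"tabu_list"`.
#' @param accepted_solution angle vector accepted this iteration.
#' @param energy its energy.
#' @return the updated `"tabu_list"`.
#' @export
update_tabu_list <- function(tabu_list, accepted_solution, energy) {
  kept <- list()
  for (entry in tabu_list$entries) {
    entry$tenure <- entry$tenure - 1L
    if (entry$tenure >= 1L) kept[[length(kept) + 1L]] <- entry
  }
  kept[[length(kept) + 1L]] <- list(solution = accepted_solution,
                                    energy = energy,
                                    tenure = tabu_list$Lt)
  while (length(kept) > tabu_list$Lt) kept[[1]] <- NULL
  tabu_list$entries <- kept
  tabu_list
}

#' One tabu search iteration
#'
#' Generates the neighborhood, takes the `Lc` best as candidates and moves to
#' the lowest-energy candidate that is either non-tabu or aspirated (strictly
#' better than the incumbent best). If every candidate is tabu and none
#' aspirates, the lowest-energy candidate is taken anyway (deadlock escape).
#' Neighbors with diverging energy get +Inf fitness and are never selected.
#'
#' @param current current angle vector.
#' @param current_energy its energy.
#' @param best_so_far,best_energy incumbent best solution and energy.
#' @param tabu_list a `"tabu_list"`.
#' @param sequence the chain being folded.
#' @param config a [tabu_config()].
#' @return list with `current`, `current_energy`, `best`, `best_energy`,
#'   `tabu_list`.
#' @export
tabu_step <- function(current, current_energy, best_so_far, best_energy,
                      tabu_list, sequence, config = tabu_config()) {
  eta <- eta_of(as_ab_sequence(sequence))
  nb <- generate_neighbors(current, config$L, config)
  en <- energy_fitness_batch(eta, nb)
  cand <- select_candidates(nb, en, config$Lc)
  chosen <- NULL
  for (k in seq_along(cand$energies)) {
    ek <- cand$energies[k]
    if (!is.finite(ek)) next
    zk <- cand$solutions[k, ]
    if (!is_tabu(zk, ek, tabu_list, config$E0, config$r0) ||
        aspiration_overrides(ek, best_energy)) {
      chosen <- k
      break
    }
  }
  if (is.null(chosen)) {
    finite <- which(is.finite(cand$energies))
    chosen <- if (length(finite) > 0L) finite[1] else NA_integer_
  }
  if (!is.na(chosen)) {
    current <- cand$solutions[chosen, ]
    current_energy <- cand$energies[chosen]
    tabu_list <- update_tabu_list(tabu_list, current, current_energy)
    if (current_energy < best_energy) {
      best_energy <- current_energy
      best_so_far <- current
    }
  }
  list(current = current, current_energy = current_energy,
       best = best_so_far, best_energy = best_energy, tabu_list = tabu_list)
}

#' Run tabu search
#'
#' Iterates [tabu_step()] from `initial_solution` for `max_iters` iterations,
#' recording the best-so-far energy per iteration. Best energy never exceeds
#' the initial solution's energy.
#'
#' @param sequence an [ab_sequence()] (or string), n >= 3.
#' @param initial_solution starting angle vector (length n - 2).
#' @param config a [tabu_config()].
#' @param max_iters iteration budget (defaults to `config$iters`).
#' @return list with `best_position`, `best_energy`, `trace`, `iterations`.
#' @export
run_tabu <- function(sequence, initial_solution, config = tabu_config(),
                     max_iters = config$iters) {
  s <- as_ab_sequence(sequence)
  validate_conformation(initial_solution, length(s))
  if (!is.null(config$seed)) set.seed(config$seed)
  e0 <- energy_fitness(eta_of(s), as.numeric(initial_solution))
  if (!is.finite(e0))
    stop("initial solution has diverging energy", call. = FALSE)
  state <- list(current = as.numeric(initial_solution), current_energy = e0,
                best = as.numeric(initial_solution), best_energy = e0,
                tabu_list = new_tabu_list(config$Lt))
  trace <- numeric(max_iters)
  for (k in seq_len(max_iters)) {
    state <- tabu_step(state$current, state$current_energy, state$best,
                       state$best_energy, state$tabu_list, s, config)
    trace[k] <- state$best_energy
  }
  list(best_position = state$best, best_energy = state$best_energy,
       trace = trace, iterations = max_iters)
}
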