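#' Hybrid driver configuration
#'
#' The hybrid method spends up to `pso_share` of the `total_iters` cap
#' (default 50% of 800) on the particle swarm phase, handing off earlier if
#' the global-best trace stalls ([has_converged()] with `window` and
#' `tolerance`); the tabu phase receives every remaining iteration. Phase
#' seeds are derived deterministically from the master seed so each phase is
#' independently replayable.
#'
#' @param total_iters combined iteration cap (default 800).
#' @param pso PSO settings, a [pso_config()].
#' @param tabu tabu settings, a [tabu_config()].
#' @param pso_share maximum fraction of `total_iters` granted to PSO.
#' @param window,tolerance handoff convergence test parameters.
#' @param seed master seed (integer) or `NULL`.
#' @return a list of class `"hybrid_config"`.
#' @export
hybrid_config <- function(total_iters = 800, pso = pso_config(),
                          tabu = tabu_config(), pso_share = 0.5,
                          window = 50, tolerance = 1e-4, seed = NULL) {
  stopifnot(total_iters >= 2, pso_share > 0, pso_share < 1, window >= 1,
            tolerance > 0)
  structure(list(total_iters = as.integer(total_iters), pso = pso,
                 tabu = tabu, pso_share = pso_share, window = window,
                 tolerance = tolerance, seed = seed),
            class = "hybrid_config")
}

# Deterministic per-phase substreams from one master seed (kept < 2^31).
derive_seed <- function(master, phase) {
  (((as.double(master) %% 2147483647) * 48271) + 7919 * phase) %% 2147483647
}

new_run_result <- function(method, sequence, best_energy, best_position,
                           trace, seed, phase_boundary = NA_integer_,
                           config = NULL) {
  s <- as_ab_sequence(sequence)
  structure(list(
    method = method,
    sequence_id = if (!is.null(attr(s, "id"))) attr(s, "id")
                  else sprintf("n%d", length(s)),
    sequence = as.character(s),
    best_energy = best_energy,
    best_angles = as.numeric(best_position),
    best_coordinates = build_coordinates(best_position),
    trace = as.numeric(trace),
    seed = if (is.null(seed)) NA_integer_ else seed,
    phase_boundary = phase_boundary,
    config = config
  ), class = "ab_run")
}

#' @export
print.ab_run <- function(x, ...) {
  cat(sprintf("<ab_run> %s on %s (n = %d)\n  best energy %.6f after %d iterations%s\n",
              x$method, x$sequence_id, nchar(x$sequence), x$best_energy,
              length(x$trace),
              if (is.na(x$phase_boundary)) ""
              else sprintf(" (PSO phase: %d)", x$phase_boundary)))
  invisible(x)
}

#' Run the hybrid PSO + tabu method
#'
#' Phase one runs the particle swarm until its global-best trace converges or
#' its budget share is spent; the swarm's best conformation then seeds the
#' tabu search, which receives all remaining iterations. The concatenated
#' best-so-far trace is monotone non-increasing and the final best can never
#' be worse than the PSO-phase best.
#'
#' @param sequence an [ab_sequence()] (or string), n >= 3.
#' @param config a [hybrid_config()].
#' @return an `"ab_run"` with method `"hybrid"` and the PSO/tabu phase
#'   boundary recorded.
#' @export
run_hybrid <- function(sequence, config = hybrid_config()) {
  s <- as_ab_sequence(sequence)
  pso_cap <- max(1L, as.integer(floor(config$total_iters * config$pso_share)))
  pso_cfg <- config$pso
  tabu_cfg <- config$tabu
  if (!is.null(config$seed)) {
    pso_cfg$seed <- derive_seed(config$seed, 1)
    tabu_cfg$seed <- derive_seed(config$seed, 2)
  }
  pso <- run_pso(s, pso_cfg, max_iters = pso_cap, stop_on_converged = TRUE,
                 window = config$window, tolerance = config$tolerance)
  tabu_iters <- config$total_iters - pso$iterations
  tb <- run_tabu(s, pso$best_position, tabu_cfg, max_iters = tabu_iters)
  trace <- c(pso$trace, pmin(cummin(tb$trace), pso$best_energy))
  best <- if (tb$best_energy <= pso$best_energy) tb else pso
  new_run_result("hybrid", s, best$best_energy, best$best_position, trace,
                 config$seed, phase_boundary = pso$iterations,
                 config = config)
}

#' Run a single-method baseline
#'
#' Gives the full iteration cap to one method: `"pso"` delegates to
#' [run_pso()]; `"tabu"` starts from a seeded uniform-random conformation and
#' delegates to [run_tabu()].
#'
#' @param sequence an [ab_sequence()] (or string).
#' @param method `"pso"` or `"tabu"`.
#' @param config a [hybrid_config()] (supplies the cap, sub-configs, seed).
#' @return an `"ab_run"` labeled with the method.
#' @export
run_baseline <- function(sequence, method = c("pso", "tabu"),
                         config = hybrid_config()) {
  method <- match.arg(method)
  s <- as_ab_sequence(sequence)
  if (method == "pso") {
    cfg <- config$pso
    if (!is.null(config$seed)) cfg$seed <- derive_seed(config$seed, 1)
    res <- run_pso(s, cfg, max_iters = config$total_iters)
  } else {
    cfg <- config$tabu
    if (!is.null(config$seed)) cfg$seed <- derive_seed(config$seed, 2)
    if (!is.null(cfg$seed)) set.seed(cfg$seed)
    init <- runif(length(s) - 2L, -pi, pi)
    cfg$seed <- NULL  # RNG already seeded; keep one stream for the run
    res <- run_tabu(s, init, cfg, max_iters = config$total_iters)
  }
  new_run_result(method, s, res$best_energy, res$best_position, res$trace,
                 config$seed, config = config)
}

#' Relative improvement on absolute energies
#'
#' `(|E_new| - |E_ref|) / |E_ref| * 100`, the percentage by which the
#' magnitude of the minimum potential energy grew.
#'
#' @param e_new,e_ref energies (typically negative minima).
#' @return percentage (not rounded).
#' @export
relative_improvement <- function(e_new, e_ref) {
  (abs(e_new) - abs(e_ref)) / abs(e_ref) * 100
}

#' Summarize optimization runs into a comparison table
#'
#' Per (sequence, method): the minimum, median and mean best energy over the
#' supplied runs. When hybrid and baseline runs share a sequence, the
#' hybrid's relative improvement over each baseline (on the minima, absolute
#' energies) is appended as `improvement_vs_pso` / `improvement_vs_tabu`.
#'
#' @param results a list of `"ab_run"` objects (>= 1).
#' @return a data.frame, one row per sequence x method.
#' @export
summarize_runs <- function(results) {
  if (length(results) == 0L) stop("no runs supplied", call. = FALSE)
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(sequence_id = r$sequence_id, method = r$method,
               best_energy = r$best_energy, stringsAsFactors = FALSE)
  }))
  out <- do.call(rbind, lapply(split(df, list(df$sequence_id, df$method),
                                     drop = TRUE), function(g) {
    data.frame(sequence_id = g$sequence_id[1], method = g$method[1],
               runs = nrow(g), min_energy = min(g$best_energy),
               median_energy = median(g$best_energy),
               mean_energy = mean(g$best_energy), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out$improvement_vs_pso <- NA_real_
  out$improvement_vs_tabu <- NA_real_
  for (sid in unique(out$sequence_id)) {
    rows <- out$sequence_id == sid
    hyb <- out$min_energy[rows & out$method == "hybrid"]
    if (length(hyb) != 1L) next
    for (base in c("pso", "tabu")) {
      b <- out$min_energy[rows & out$method == base]
      if (length(b) == 1L)
        out[rows & out$method == "hybrid",
            paste0("improvement_vs_", base)] <- relative_improvement(hyb, b)
    }
  }
  out[order(out$sequence_id, out$method), , drop = FALSE]
}
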