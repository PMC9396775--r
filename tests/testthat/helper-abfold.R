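# Shared generators for property-style tests. Everything is built in code;
# no fixture files.

random_ab_string <- function(n) {
  paste(sample(c("A", "B"), n, replace = TRUE), collapse = "")
}

random_instance <- function(n_min = 3, n_max = 20) {
  n <- sample(n_min:n_max, 1)
  list(seq = random_ab_string(n), angles = runif(n - 2, -pi, pi))
}

# Instance with no near-clashing residue pair. The r^-12 wall amplifies
# coordinate rounding by ~12/r, so identities that hold exactly in real
# arithmetic (e.g. chain reversal) are only comparable to ~1e-12 relative
# precision away from the singularity; a min pair distance of 0.2 keeps the
# amplification factor harmless while still sampling tightly folded chains.
random_sane_instance <- function(n_min = 3, n_max = 20, min_dist = 0.2) {
  repeat {
    inst <- random_instance(n_min, n_max)
    if (min(dist(build_coordinates(inst$angles))) >= min_dist) return(inst)
  }
}

# Small, fast configs for optimizer behavior tests (not benchmark quality).
tiny_hybrid_config <- function(seed = 1, total_iters = 60) {
  hybrid_config(total_iters = total_iters,
                pso = pso_config(swarm_size = 20, iters = total_iters,
                                 seed = NULL),
                tabu = tabu_config(iters = total_iters),
                seed = seed)
}
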