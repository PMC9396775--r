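#' Wrap an angle into [-pi, pi)
#'
#' All bend angles live on the half-open interval `[-pi, pi)`; every position
#' update wraps modulo 2*pi. Idempotent; vectorized.
#'
#' @param x finite numeric vector of angles in radians.
#' @return angles congruent to `x` mod 2*pi, each in `[-pi, pi)`.
#' @examples
#' wrap_angle(3 * pi / 2) # -pi/2
#' @export
wrap_angle <- function(x) {
  if (any(!is.finite(x))) stop("angles must be finite", call. = FALSE)
  ((x + pi) %% (2 * pi)) - pi
}

validate_conformation <- function(angles, n = NULL) {
  if (length(angles) == 0L || !is.numeric(angles))
    stop("conformation must be a non-empty numeric vector of bend angles",
         call. = FALSE)
  if (any(!is.finite(angles)))
    stop("conformation contains non-finite angles", call. = FALSE)
  if (!is.null(n) && length(angles) != n - 2L)
    stop(sprintf("conformation has %d angles but sequence of length %d needs %d",
                 length(angles), n, n - 2L), call. = FALSE)
  invisible(angles)
}

#' Realize the planar chain from its bend angles
#'
#' Places the chain with unit bonds: the first residue at the origin, the
#' second at (1, 0); each subsequent bond direction is the previous one
#' rotated by the signed bend angle at the shared residue. The conformation
#' vector holds the n - 2 interior angles alpha_2..alpha_{n-1}.
#'
#' @param conformation numeric vector of n - 2 bend angles (radians).
#' @return an n x 2 numeric matrix of coordinates (columns `x`, `y`).
#' @examples
#' build_coordinates(c(pi / 2, pi / 2)) # unit square
#' @export
build_coordinates <- function(conformation) {
  validate_conformation(conformation)
  theta <- cumsum(c(0, conformation))       # direction of each of n-1 bonds
  x <- cumsum(c(0, cos(theta)))
  y <- cumsum(c(0, sin(theta)))
  cbind(x = x, y = y)
}

#' Nonbonded pair coefficient
#'
#' The polarity-dependent well depth C(eta_i, eta_j) of the nonbonded term:
#' 1 for an AA pair (strong hydrophobic attraction), 1/2 for BB, -1/2 for a
#' mixed AB pair (weak repulsion). Computed as
#' `(1 + eta_i + eta_j + 5 * eta_i * eta_j) / 8`.
#'
#' @param eta_i,eta_j residue polarities, each +1 or -1. Vectorized.
#' @return numeric coefficient(s) in \{1, 1/2, -1/2\}; symmetric in arguments.
#' @export
pair_coefficient <- function(eta_i, eta_j) {
  stopifnot(all(abs(eta_i) == 1), all(abs(eta_j) == 1))
  (1 + eta_i + eta_j + 5 * eta_i * eta_j) / 8
}

#' Backbone (bend) energy
#'
#' Sum over interior residues of (1/4)(1 - cos alpha): zero for the fully
#' extended chain, at most 1/2 per angle.
#'
#' @param conformation numeric vector of bend angles.
#' @return non-negative scalar.
#' @export
backbone_energy <- function(conformation) {
  validate_conformation(conformation)
  sum(0.25 * (1 - cos(conformation)))
}

#' Nonbonded (pairwise) energy
#'
#' Lennard-Jones-like interaction 4 (r^-12 - C r^-6) summed over all residue
#' pairs (i, j) with j >= i + 2, where C is [pair_coefficient()] of the two
#' polarities and r the planar distance. Pairs closer than 1e-6 are a domain
#' error (the potential diverges); optimizers treat such moves as +Inf
#' fitness and reject them.
#'
#' @param sequence an [ab_sequence()] (or string).
#' @param coordinates n x 2 coordinate matrix from [build_coordinates()].
#' @return scalar energy.
#' @export
nonbonded_energy <- function(sequence, coordinates) {
  s <- as_ab_sequence(sequence)
  n <- length(s)
  if (n < 3L) stop("nonbonded energy needs n >= 3", call. = FALSE)
  if (!is.matrix(coordinates) || nrow(coordinates) != n || ncol(coordinates) != 2)
    stop("coordinates must be an n x 2 matrix matching the sequence",
         call. = FALSE)
  eta <- eta_of(s)
  d <- as.matrix(dist(coordinates))
  idx <- which(upper.tri(d) & col(d) >= row(d) + 2, arr.ind = TRUE)
  r <- d[idx]
  if (any(r < 1e-6))
    stop("coincident residues (pair distance < 1e-6): energy diverges",
         call. = FALSE)
  C <- pair_coefficient(eta[idx[, 1]], eta[idx[, 2]])
  sum(4 * (r^-12 - C * r^-6))
}

#' Total model energy of a conformation
#'
#' Evaluates the full potential E = sum E1(alpha_i) + sum E2(r_ij, eta_i,
#' eta_j) through the compiled kernel and returns its decomposition.
#'
#' @param sequence an [ab_sequence()] (or string), length n >= 3.
#' @param conformation numeric vector of n - 2 bend angles.
#' @return a list of class `"energy_breakdown"` with components `backbone`,
#'   `nonbonded` and `total` (total = backbone + nonbonded).
#' @examples
#' total_energy("AAA", 0)$total # -0.0615234375
#' @export
total_energy <- function(sequence, conformation) {
  s <- as_ab_sequence(sequence)
  n <- length(s)
  if (n < 3L) stop("energy evaluation needs n >= 3", call. = FALSE)
  validate_conformation(conformation, n)
  e <- chain_energy_cpp(as.numeric(conformation), eta_of(s))
  if (!is.finite(e[[3]]))
    stop("coincident residues (pair distance < 1e-6): energy diverges",
         call. = FALSE)
  structure(list(backbone = e[[1]], nonbonded = e[[2]], total = e[[3]]),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("backbone : %.10f\nnonbonded: %.10f\ntotal    : %.10f\n",
              x$backbone, x$nonbonded, x$total))
  invisible(x)
}

# Fitness for the optimizers: total energy, +Inf on domain errors (coincident
# points) so such moves are never selected.
energy_fitness <- function(eta, angles) {
  chain_energy_cpp(angles, eta)[[3]]
}

# Batch fitness over rows of a position matrix.
energy_fitness_batch <- function(eta, positions) {
  chain_energy_batch_cpp(positions, eta)
}
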