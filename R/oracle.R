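# Brute-force reference implementations used to validate the production
# energy kernel and the optimizers on tiny chains. Deliberately shares no
# code with the compiled path: geometry, coefficients and sums are literal
# transcriptions with plain loops.

#' Naive reference energy (oracle)
#'
#' Literal double-loop transcription of the model potential: rebuilds the
#' chain point by point, then loops over bend angles and over all pairs
#' (i, j) with j >= i + 2. Exists purely as an independent cross-check of
#' [total_energy()]; do not use it in optimizers (it is slow by design).
#'
#' @param sequence an [ab_sequence()] (or string), n >= 3.
#' @param conformation numeric vector of n - 2 bend angles.
#' @return scalar total energy.
#' @export
naive_energy <- function(sequence, conformation) {
  s <- as_ab_sequence(sequence)
  n <- length(s)
  if (n < 3L) stop("need n >= 3", call. = FALSE)
  if (length(conformation) != n - 2L)
    stop("conformation must have n - 2 angles", call. = FALSE)
  eta <- numeric(n)
  for (i in seq_len(n)) eta[i] <- if (unclass(s)[i] == "A") 1 else -1

  px <- numeric(n); py <- numeric(n)
  px[1] <- 0; py[1] <- 0
  px[2] <- 1; py[2] <- 0
  dir <- 0
  for (k in 3:n) {
    dir <- dir + conformation[k - 2]
    px[k] <- px[k - 1] + cos(dir)
    py[k] <- py[k - 1] + sin(dir)
  }

  e1 <- 0
  for (i in seq_len(n - 2)) e1 <- e1 + (1 / 4) * (1 - cos(conformation[i]))

  e2 <- 0
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      r <- sqrt((px[j] - px[i])^2 + (py[j] - py[i])^2)
      if (r < 1e-6)
        stop("coincident residues: energy diverges", call. = FALSE)
      cij <- (1 + eta[i] + eta[j] + 5 * eta[i] * eta[j]) / 8
      e2 <- e2 + 4 * (r^-12 - cij * r^-6)
    }
  }
  e1 + e2
}

#' Exhaustive grid minimization (oracle)
#'
#' Evaluates [naive_energy()] on the full Cartesian grid
#' `{-pi, -pi + step, ...}` (endpoint pi excluded by the wrap convention) in
#' every angle dimension and returns the grid argmin. Refuses chains longer
#' than 6 residues (dimension > 4) to bound cost. Deterministic.
#'
#' @param sequence an [ab_sequence()] (or string), 3 <= n <= 6.
#' @param step grid spacing in radians (> 0).
#' @return list with `best_energy` and `best_angles`.
#' @export
grid_minimize <- function(sequence, step) {
  s <- as_ab_sequence(sequence)
  n <- length(s)
  if (n > 6L)
    stop("grid_minimize is an oracle for n <= 6 only (cost grows as (2*pi/step)^(n-2))",
         call. = FALSE)
  if (n < 3L) stop("need n >= 3", call. = FALSE)
  stopifnot(step > 0)
  vals <- seq(-pi, pi, by = step)
  vals <- vals[vals < pi - 1e-12]
  d <- n - 2L
  best_e <- Inf
  best_a <- NULL
  idx <- rep(1L, d)
  m <- length(vals)
  repeat {
    a <- vals[idx]
    e <- tryCatch(naive_energy(s, a), error = function(cond) Inf)
    if (is.null(best_a) || e < best_e) {
      best_e <- e
      best_a <- a
    }
    pos <- 1L
    while (pos <= d) {
      idx[pos] <- idx[pos] + 1L
      if (idx[pos] <= m) break
      idx[pos] <- 1L
      pos <- pos + 1L
    }
    if (pos > d) break
  }
  list(best_energy = best_e, best_angles = best_a)
}
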