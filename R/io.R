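# Result serialization (JSON run reports, CSV tables, minimal PDB) and the
# command-line interface.

#' Write / read a JSON run report
#'
#' The report carries everything needed to replay the run: method, sequence,
#' best energy and angles, the per-iteration best-energy trace, the seed and
#' an echo of the configuration. Coordinates are not stored; they are
#' recomputed from the angles on read (they are a pure function of them).
#'
#' @param result an `"ab_run"` from [run_hybrid()] or [run_baseline()].
#' @param path output (input) file path.
#' @return `write_run_report` returns `path` invisibly; `read_run_report`
#'   returns the reconstructed `"ab_run"`.
#' @export
write_run_report <- function(result, path) {
  stopifnot(inherits(result, "ab_run"))
  payload <- list(
    method = result$method,
    sequence_id = result$sequence_id,
    sequence = result$sequence,
    best_energy = result$best_energy,
    best_angles = result$best_angles,
    trace = result$trace,
    seed = result$seed,
    phase_boundary = result$phase_boundary,
    config = strip_config(result$config)
  )
  # 17 significant digits: doubles round-trip exactly, so a replayed run
  # reproduces the trace bit for bit
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       na = "null", pretty = TRUE)
  invisible(path)
}

strip_config <- function(config) {
  if (is.null(config)) return(NULL)
  rapply(unclass(config), f = identity, how = "list")
}

#' @rdname write_run_report
#' @export
read_run_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("method", "sequence", "best_energy", "best_angles", "trace",
                "seed")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0L)
    stop(sprintf("run report %s lacks field(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  cfg <- NULL
  if (!is.null(x$config)) {
    cfg <- hybrid_config(
      total_iters = x$config$total_iters,
      pso = do.call(pso_config, x$config$pso),
      tabu = do.call(tabu_config, x$config$tabu),
      pso_share = x$config$pso_share, window = x$config$window,
      tolerance = x$config$tolerance, seed = x$config$seed)
  }
  new_run_result(x$method, ab_sequence(x$sequence, id = x$sequence_id),
                 x$best_energy, x$best_angles, x$trace, x$seed,
                 phase_boundary = if (is.null(x$phase_boundary))
                   NA_integer_ else x$phase_boundary,
                 config = cfg)
}

#' Export conformations and coordinates as CSV
#'
#' `write_conformation_csv` writes the bend angles with header
#' `index,angle_rad` (index = the interior residue, 2..n-1);
#' `write_coordinates_csv` writes the realized chain with header
#' `index,residue,x,y`.
#'
#' @param conformation numeric vector of bend angles.
#' @param sequence an [ab_sequence()] (or string).
#' @param coordinates n x 2 matrix (defaults to
#'   `build_coordinates(conformation)` where applicable).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_conformation_csv <- function(conformation, path) {
  df <- data.frame(index = seq_along(conformation) + 1L,
                   angle_rad = as.numeric(conformation))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_conformation_csv
#' @export
read_conformation_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("index", "angle_rad") %in% names(df)))
    stop("conformation CSV needs columns index,angle_rad", call. = FALSE)
  as.numeric(df$angle_rad[order(df$index)])
}

#' @rdname write_conformation_csv
#' @export
write_coordinates_csv <- function(sequence, coordinates, path) {
  s <- as_ab_sequence(sequence)
  df <- data.frame(index = seq_len(nrow(coordinates)),
                   residue = as.character(unclass(s)),
                   x = coordinates[, 1], y = coordinates[, 2])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Minimal CA-trace PDB export
#'
#' One CA pseudo-atom per residue on chain A, z = 0, coordinates multiplied
#' by `scale` (model units are dimensionless; scale only affects viewers).
#' A residues are written as ALA, B residues as GLY.
#'
#' @param sequence an [ab_sequence()] (or string).
#' @param coordinates n x 2 matrix.
#' @param path output file.
#' @param scale multiplicative factor applied to coordinates (default 1.0).
#' @return `path`, invisibly.
#' @export
write_pdb_ca <- function(sequence, coordinates, path, scale = 1.0) {
  s <- as_ab_sequence(sequence)
  res <- ifelse(unclass(s) == "A", "ALA", "GLY")
  lines <- vapply(seq_len(nrow(coordinates)), function(i) {
    sprintf("ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, res[i], i, coordinates[i, 1] * scale,
            coordinates[i, 2] * scale, 0)
  }, "")
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Load a run configuration file
#'
#' JSON with optional sections `pso`, `tabu` and top-level hybrid keys
#' (`total_iters`, `pso_share`, `window`, `tolerance`, `seed`). Unknown keys
#' are rejected; omitted keys keep the benchmark defaults.
#'
#' @param path JSON file.
#' @return a [hybrid_config()].
#' @export
load_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  top_ok <- c("pso", "tabu", "total_iters", "pso_share", "window",
              "tolerance", "seed")
  check_keys(names(x), top_ok, "config")
  pso_args <- x$pso %||% list()
  tabu_args <- x$tabu %||% list()
  check_keys(names(pso_args), names(formals(pso_config)), "config$pso")
  check_keys(names(tabu_args), names(formals(tabu_config)), "config$tabu")
  hybrid_config(
    total_iters = x$total_iters %||% 800,
    pso = do.call(pso_config, pso_args),
    tabu = do.call(tabu_config, tabu_args),
    pso_share = x$pso_share %||% 0.5,
    window = x$window %||% 50,
    tolerance = x$tolerance %||% 1e-4,
    seed = x$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_keys <- function(keys, allowed, where) {
  extra <- setdiff(keys, allowed)
  if (length(extra) > 0L)
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(extra, collapse = ", ")), call. = FALSE)
}

# ---- command-line interface -------------------------------------------------

parse_flags <- function(argv) {
  out <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--"))
      stop(sprintf("unexpected argument '%s'", a), call. = FALSE)
    key <- substring(a, 3)
    if (i + 1L <= length(argv) && !startsWith(argv[i + 1L], "--")) {
      out[[key]] <- argv[i + 1L]
      i <- i + 2L
    } else {
      out[[key]] <- TRUE
      i <- i + 1L
    }
  }
  out
}

cli_sequence <- function(flags) {
  if (!is.null(flags$seq)) {
    recs <- read_ab_fasta(flags$seq)
    if (length(recs) > 1L)
      message(sprintf("note: %s has %d records; using the first (%s)",
                      flags$seq, length(recs), names(recs)[1]))
    recs[[1]]
  } else if (!is.null(flags$length)) {
    fibonacci_sequence(as.integer(flags$length))
  } else {
    stop("supply --seq <fasta> or --length <fibonacci length>", call. = FALSE)
  }
}

cli_config <- function(flags) {
  cfg <- if (!is.null(flags$config)) load_run_config(flags$config)
         else hybrid_config()
  if (!is.null(flags$iters)) cfg$total_iters <- as.integer(flags$iters)
  if (!is.null(flags$seed)) cfg$seed <- as.integer(flags$seed)
  cfg
}

#' Command-line entry point
#'
#' Subcommands: `generate` (write a Fibonacci benchmark FASTA), `energy`
#' (evaluate a conformation), `minimize` (run pso/tabu/hybrid and write a
#' JSON report plus coordinate CSV, optionally PDB), `compare` (benchmark
#' table over several seeds) and `oracle` (exhaustive grid minimum for tiny
#' chains). Invoke as `Rscript -e 'abfold::cli_main()' <subcommand> --flags`,
#' or via the installed `exec/abfold` script.
#'
#' @param argv character vector of arguments (default: the command line).
#' @return exit status, invisibly: 0 on success, 2 on validation error.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(argv) == 0L)
      stop("usage: abfold <generate|energy|minimize|compare|oracle> [--flags]",
           call. = FALSE)
    cmd <- argv[1]
    flags <- parse_flags(argv[-1])
    switch(cmd,
      generate = cli_generate(flags),
      energy = cli_energy(flags),
      minimize = cli_minimize(flags),
      compare = cli_compare(flags),
      oracle = cli_oracle(flags),
      stop(sprintf("unknown subcommand '%s'", cmd), call. = FALSE)
    )
    0L
  }, error = function(cond) {
    message("error: ", conditionMessage(cond))
    2L
  })
  invisible(status)
}

cli_generate <- function(flags) {
  if (is.null(flags$length)) stop("generate needs --length", call. = FALSE)
  s <- fibonacci_sequence(as.integer(flags$length))
  if (!is.null(flags$out)) {
    write_ab_fasta(list(s), flags$out)
    cat(sprintf("wrote %s (n = %d)\n", flags$out, length(s)))
  } else {
    cat(sprintf(">%s\n%s\n", attr(s, "id"), as.character(s)))
  }
}

cli_energy <- function(flags) {
  s <- cli_sequence(flags)
  angles <- if (!is.null(flags$angles)) read_conformation_csv(flags$angles)
            else rep(0, length(s) - 2L)
  print(total_energy(s, angles))
}

cli_minimize <- function(flags) {
  s <- cli_sequence(flags)
  method <- flags$method %||% "hybrid"
  cfg <- cli_config(flags)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  res <- if (method == "hybrid") run_hybrid(s, cfg)
         else run_baseline(s, method, cfg)
  prefix <- flags$out %||% sprintf("%s_%s", res$sequence_id, method)
  write_run_report(res, paste0(prefix, ".json"))
  write_coordinates_csv(s, res$best_coordinates, paste0(prefix, "_coords.csv"))
  if (isTRUE(flags$pdb))
    write_pdb_ca(s, res$best_coordinates, paste0(prefix, ".pdb"),
                 scale = as.numeric(flags$scale %||% 1.0))
  cat(sprintf("%s %s best energy %.6f (seed %d)\n", res$sequence_id, method,
              res$best_energy, cfg$seed))
}

cli_compare <- function(flags) {
  s <- cli_sequence(flags)
  cfg <- cli_config(flags)
  n_seeds <- as.integer(flags$seeds %||% 10)
  base_seed <- as.integer(flags$seed %||% 1)
  runs <- list()
  for (k in seq_len(n_seeds)) {
    cfg$seed <- base_seed + k - 1L
    runs[[length(runs) + 1L]] <- run_hybrid(s, cfg)
    runs[[length(runs) + 1L]] <- run_baseline(s, "pso", cfg)
    runs[[length(runs) + 1L]] <- run_baseline(s, "tabu", cfg)
  }
  tab <- summarize_runs(runs)
  if (!is.null(flags$out)) {
    write.csv(tab, flags$out, row.names = FALSE, quote = FALSE)
    cat(sprintf("wrote %s\n", flags$out))
  }
  print(tab)
}

cli_oracle <- function(flags) {
  s <- cli_sequence(flags)
  step <- as.numeric(flags$step %||% 0.01)
  res <- grid_minimize(s, step)
  cat(sprintf("grid minimum %.10f at (%s)\n", res$best_energy,
              paste(sprintf("%.6f", res$best_angles), collapse = ", ")))
}
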