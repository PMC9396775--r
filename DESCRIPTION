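Package: abfold
Title: Protein Structure Prediction in the 2D AB Off-Lattice Model by
    Hybrid Particle Swarm and Tabu Search
Version: 0.1.0
Authors@R:
    person("abfold", "developers", email = "abfold@example.org",
           role = c("aut", "cre"))
Description: Coarse-grained ab initio protein structure prediction on the
    two-dimensional AB off-lattice (toy protein) model. Chains of
    hydrophobic (A) and hydrophilic (B) residues with unit bonds are folded
    by minimizing a Stillinger-type potential (bend-angle backbone term plus
    a Lennard-Jones-like polarity-weighted nonbonded term) over the vector
    of bend angles. Provides a particle swarm optimizer, a tabu search with
    single-coordinate perturbation neighborhoods, energy/distance tabu
    criteria and an aspiration rule, and a hybrid driver in which the
    converged swarm best seeds the tabu refinement. Includes the Fibonacci
    benchmark sequence generator (lengths 13/21/34/55), brute-force
    reference oracles, FASTA/CSV/JSON/PDB input-output and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
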