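# Shared fixtures: tiny in-code structures and random tensors.

random_tensor <- function(pos = c(0, 0, 0)) {
  chi_tensor(pos, stats::rnorm(5, sd = 5))
}

# minimal trans-peptide fragment with ideal planar geometry: two residues,
# the second eligible for amide-proton placement
ideal_dipeptide <- function() {
  structure_model(data.frame(
    chain = "A",
    resno = c(1L, 1L, 1L, 2L, 2L, 2L),
    resid = "ALA",
    elety = c("N", "CA", "C", "N", "CA", "C"),
    # residue 1 backbone, then residue 2 with C1-N2-CA2 all in z = 0 plane
    x = c(-2.0, -1.0, 0.0, 1.33, 2.29, 3.5),
    y = c(1.2, 0.2, 1.0, 0.45, -0.6, 0.0),
    z = c(0, 0, 0, 0, 0, 0),
    stringsAsFactors = FALSE), label = "dipeptide")
}

write_fixture_pdb <- function(path, lines) {
  writeLines(lines, path)
  path
}

three_atom_pdb <- function(path) {
  write_fixture_pdb(path, c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       2.500   2.000   3.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       3.000   3.400   3.250  1.00  0.00           C",
    "END"))
}

two_chain_pdb <- function(path) {
  write_fixture_pdb(path, c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       2.500   2.000   3.000  1.00  0.00           C",
    "ATOM      3  N   GLY B   1       1.000   2.000   9.000  1.00  0.00           N",
    "ATOM      4  CA  GLY B   1       2.500   2.000   9.000  1.00  0.00           C",
    "END"))
}

# exhaustive minimum-cost matching oracle (all permutations)
brute_force_assign <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- NULL; best_val <- Inf
  for (p in perms(seq_len(ncol(cost)))) {
    sel <- p[seq_len(n)]
    val <- sum(cost[cbind(seq_len(n), sel)])
    if (val < best_val) { best_val <- val; best <- sel }
  }
  list(assignment = best, total = best_val)
}

# noise-free single-site synthetic study shared across fit tests
noise_free_study <- function(seed = 42) {
  simulate_study(generator_config(seed = seed, noise_sigma = 0,
                                  omission_fraction_observed = 0))
}
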