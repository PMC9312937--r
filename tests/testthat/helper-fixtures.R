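# Shared fixture builders: tiny hand-written PDB texts for parser contracts
# and helpers around the package's own generators.

fixture_path <- function(name) test_path("fixtures", name)

# Two-residue poly-Ala PDB, 4 backbone atoms per residue, written by hand so
# the parser is not tested against its own writer.
write_two_residue_pdb <- function(path, bfac = c(20, 20)) {
  fmt <- "ATOM  %5d  %-3s ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %s"
  xyz <- list(
    c(0.000, 0.000, 0.000), c(1.458, 0.000, 0.000),
    c(2.009, 1.420, 0.000), c(1.251, 2.390, 0.000),
    c(3.332, 1.536, 0.000), c(4.000, 2.880, 0.100),
    c(5.500, 2.800, 0.150), c(6.150, 3.800, 0.200))
  el <- c("N", "CA", "C", "O", "N", "CA", "C", "O")
  rn <- c(1, 1, 1, 1, 2, 2, 2, 2)
  lines <- vapply(1:8, function(i) {
    sprintf(fmt, i, el[i], rn[i], xyz[[i]][1], xyz[[i]][2], xyz[[i]][3], 1.00,
            bfac[rn[i]], substr(el[i], 1, 1))
  }, "")
  writeLines(c(lines, "END"), path)
  path
}

# Fixture with one CA present in two alternate conformations.
write_altloc_pdb <- function(path) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA AALA A   1       1.458   0.000   0.000  0.60 10.00           C",
    "ATOM      3  CA BALA A   1       1.400   0.100   0.000  0.40 10.00           C",
    "ATOM      4  C   ALA A   1       2.009   1.420   0.000  1.00 10.00           C",
    "ATOM      5  O   ALA A   1       1.251   2.390   0.000  1.00 10.00           O",
    "END")
  writeLines(lines, path)
  path
}

# Small deterministic benchmark used by several test files.
small_benchmark <- function(n = 6, seed = 101,
                            protein_length_range = c(80, 140), ...) {
  simulate_benchmark(synthetic_spec(n_proteins = n, seed = seed,
                                    protein_length_range = protein_length_range,
                                    ...))
}

# Noisy copy of a fragment: fixed-seed isotropic Gaussian displacement.
jitter_coords <- function(x, sigma, seed) {
  set.seed(seed)
  x + matrix(stats::rnorm(length(x), 0, sigma), nrow(x), 3)
}
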