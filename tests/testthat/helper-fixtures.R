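# Shared fixture builders for the test suite. Everything is generated in
# code; nothing is read from disk.

# compact structure builder: one atom per row
atoms_model <- function(..., source_id = "test") {
  df <- tibble::tribble(...)
  defaults <- list(chain = "A", resname = "ALA", atom = "CA", element = "C",
                   ins = "")
  for (nm in names(defaults)) {
    if (!nm %in% names(df)) df[[nm]] <- defaults[[nm]]
  }
  structure_model(df, source_id = source_id)
}

# n-residue single-atom chain at given coordinates (one CA per residue)
point_residues <- function(xyz, chain = "A", resname = "ALA",
                           charge = NULL) {
  df <- tibble::tibble(
    chain = chain, resno = seq_len(nrow(xyz)), resname = resname,
    atom = "CA", element = "C",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  if (!is.null(charge)) df$charge <- charge
  structure_model(df)
}

# minimal hand-written PDB text
pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     alt = " ", element = "C", b = 0) {
  sprintf("ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resname, chain, resno, x, y, z, 1.0, b, element)
}

# a fabricated 2-chain x 5-residue x 4-atom PDB text
two_chain_pdb <- function() {
  lines <- character(0)
  serial <- 0
  for (ch in c("A", "B")) {
    off <- if (ch == "A") 0 else 30
    for (r in 1:5) {
      for (a in c("N", "CA", "C", "O")) {
        serial <- serial + 1
        el <- substr(a, 1, 1)
        lines <- c(lines, pdb_line(serial, a, "GLY", ch, r,
                                   off + r * 4, serial %% 3, 0,
                                   element = el))
      }
    }
  }
  c(lines, "END")
}

# independent exhaustive two-tailed hypergeometric p for the 2x2 table
# [[a, b], [c, d]]: enumerate all tables with the same margins and sum the
# probabilities not exceeding the observed table's
enum_fisher_p <- function(a, b, c_, d) {
  m <- a + b
  n <- c_ + d
  k <- a + c_
  lp <- function(x) {
    lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  }
  xs <- max(0, k - n):min(k, m)
  probs <- exp(vapply(xs, lp, numeric(1)))
  p_obs <- exp(lp(a))
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# analytic exposed area of each of two equal spheres of radius R at
# center distance d (d < 2R): full sphere minus the buried cap
two_sphere_area <- function(R, d) {
  4 * pi * R^2 - 2 * pi * R * (R - d / 2)
}

# small cached docking run shared across tests (built once per test run)
.test_cache <- new.env(parent = emptyenv())
small_toy_run <- function() {
  if (is.null(.test_cache$run)) {
    toy <- make_toy_complex(20, 4, seed = 7)
    run <- dock_pair(toy$receptor, toy$ligand, n_rotations = 60,
                     spacing = 2.0, n_keep = 1500, seed = 7)
    .test_cache$toy <- toy
    .test_cache$run <- run
  }
  list(toy = .test_cache$toy, run = .test_cache$run)
}
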