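# Synthetic fixtures: toy rigid-body complexes with a designed interface,
# variant tables with planted location biases, and the packaged
# interaction-network census.

#' Generate a toy two-body complex with a designed interface
#'
#' Builds two clash-free pseudo-atom bodies (one backbone and one
#' side-chain sphere per residue): each body is a ring of `interface_size`
#' residues facing the partner, continued by a helical stalk pointing away
#' from it. Complementary unit charges decorate a short anchor arc of each
#' ring so that energy rescoring favors near-native poses pivoting about
#' an energetic hot-spot, while the uncharged rim residues are buried more
#' variably across the low-energy poses. The ground-truth
#' interface is verified against the all-atom 10 A contact rule at
#' generation time; generation is deterministic per seed, and the written
#' PDB files are byte-identical across runs.
#'
#' @param n_residues Residues per body.
#' @param interface_size Designed interface size (residues per body); must
#'   be smaller than `n_residues`.
#' @param seed Integer seed (residue identities, stalk geometry jitter).
#' @param gap Backbone-to-backbone separation of the two rings (Angstrom).
#' @param contact_cutoff Contact rule used to verify the ground truth.
#' @return A list: `receptor`, `ligand` ([structure_model()] objects, the
#'   ligand in its bound position), `complex` (the assembled pair),
#'   `truth_receptor`, `truth_ligand` (ground-truth interface residue
#'   keys), `pose` (the designed pose: identity rotation, zero
#'   translation) and `params`.
#' @export
make_toy_complex <- function(n_residues = 30, interface_size = 6, seed = 1,
                             gap = 7, contact_cutoff = 10) {
  if (interface_size >= n_residues) {
    abort("interface_size must be smaller than n_residues")
  }
  if (interface_size < 1) abort("interface_size must be >= 1")
  for (attempt in 0:4) {
    out <- withr::with_seed(seed + 1000L * attempt, {
      .build_toy_complex(n_residues, interface_size, gap)
    })
    truth_r <- interface_residues(out$complex, "A", "B", contact_cutoff)
    truth_l <- interface_residues(out$complex, "B", "A", contact_cutoff)
    clash <- min(.cross_dist(.coords(out$receptor), .coords(out$ligand)))
    ok <- setequal(truth_r, out$design_receptor) &&
      setequal(truth_l, out$design_ligand) && clash >= 3.2
    if (ok) {
      return(list(receptor = out$receptor, ligand = out$ligand,
                  complex = out$complex,
                  truth_receptor = sort(truth_r),
                  truth_ligand = sort(truth_l),
                  pose = list(rotation = diag(3),
                              translation = c(0, 0, 0)),
                  params = list(n_residues = n_residues,
                                interface_size = interface_size,
                                seed = seed, gap = gap,
                                contact_cutoff = contact_cutoff)))
    }
  }
  abort("could not generate a clash-free toy complex with the designed interface")
}

.build_toy_complex <- function(n, k, gap) {
  aa20 <- names(.aa_three_to_one)
  build_body <- function(chain, z_ring_bb, z_ring_sc, stalk_dir,
                         ring_phase, q_ring) {
    r_ring <- max(4.5, k * 4.5 / (2 * pi))
    theta <- 2 * pi * (seq_len(k) - 1) / k + ring_phase
    resnames <- sample(aa20, n, replace = TRUE)
    n_stalk <- n - k
    helix_phase <- runif(1, 0, 2 * pi)
    step <- 100 * pi / 180
    hz <- z_ring_bb + stalk_dir * (6.0 + 1.4 * (seq_len(n_stalk) - 1))
    ha <- helix_phase + step * (seq_len(n_stalk) - 1)
    jit <- function(m) matrix(runif(3 * m, -0.25, 0.25), ncol = 3)
    bb <- rbind(
      cbind(r_ring * cos(theta), r_ring * sin(theta), z_ring_bb),
      cbind(6.0 * cos(ha), 6.0 * sin(ha), hz) + jit(n_stalk))
    sc <- rbind(
      cbind(r_ring * cos(theta), r_ring * sin(theta), z_ring_sc),
      cbind(7.5 * cos(ha), 7.5 * sin(ha), hz) + jit(n_stalk))
    # only a short arc of adjacent ring residues carries charges: an energetic
    # anchor patch (hot-spot) amid cooler rim residues, so low-energy
    # poses pivot about the anchor, bury the rim variably, and the patch
    # extension step is what recovers the full interface
    n_anchor <- min(3L, k)
    charge_sc <- c(rep(q_ring, n_anchor), rep(0, k - n_anchor),
                   rep(0, n_stalk))
    atoms <- tibble(
      chain = chain,
      resno = rep(seq_len(n), each = 2),
      resname = rep(resnames, each = 2),
      atom = rep(c("CA", "CB"), n),
      element = "C",
      x = as.vector(rbind(bb[, 1], sc[, 1])),
      y = as.vector(rbind(bb[, 2], sc[, 2])),
      z = as.vector(rbind(bb[, 3], sc[, 3])),
      charge = as.vector(rbind(rep(0, n), charge_sc)))
    structure_model(atoms, source_id = paste0("toy_", chain))
  }
  receptor <- build_body("A", z_ring_bb = 0, z_ring_sc = 1.5,
                         stalk_dir = -1, ring_phase = 0, q_ring = 1)
  ligand <- build_body("B", z_ring_bb = gap, z_ring_sc = gap - 1.5,
                       stalk_dir = +1, ring_phase = pi / k, q_ring = -1)
  cx <- structure_model(bind_rows(as_tibble(receptor), as_tibble(ligand)),
                        source_id = "toy_complex")
  list(receptor = receptor, ligand = ligand, complex = cx,
       design_receptor = paste0("A:", seq_len(k)),
       design_ligand = paste0("B:", seq_len(k)))
}

#' Write a toy complex to PDB files
#'
#' Writes `receptor.pdb` and `ligand.pdb` (designed charges in the
#' B-factor column) plus `truth.tsv` with the ground-truth interface keys.
#'
#' @param toy Result of [make_toy_complex()].
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_toy_complex <- function(toy, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_structure(toy$receptor, file.path(dir, "receptor.pdb"))
  write_structure(toy$ligand, file.path(dir, "ligand.pdb"))
  truth <- bind_rows(
    tibble(side = "receptor", res_key = toy$truth_receptor),
    tibble(side = "ligand", res_key = toy$truth_ligand))
  readr::write_tsv(truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Generate a variant table with a planted location bias
#'
#' Places disease variants on interface versus non-interface surface
#' residues by independent per-residue Bernoulli draws whose per-residue
#' odds ratio equals `target_or` and whose expected total is `n_disease`;
#' polymorphism and unclassified variants are placed uniformly. The output
#' text parses with [parse_variant_table()].
#'
#' @param residue_labels Tibble with one row per candidate residue:
#'   `accession`, `position`, `label` (`INTERFACE` or
#'   `NON_INTERFACE_SURFACE`), optional `aa` (1-letter wild type;
#'   generated if absent).
#' @param n_disease,n_polymorphism,n_unclassified Expected (disease) or
#'   exact (others) variant counts per category.
#' @param target_or Planted odds ratio of disease variants,
#'   interface versus non-interface surface; must be > 0.
#' @param seed Integer seed.
#' @return A list: `text` (humsavar-dialect lines), `truth` (tibble of
#'   placements with their region), `rates` (the solved per-residue
#'   probabilities).
#' @export
make_variant_fixture <- function(residue_labels, n_disease = 200,
                                 n_polymorphism = 100, n_unclassified = 0,
                                 target_or = 1, seed = 1) {
  if (target_or <= 0) abort("target_or must be > 0")
  labels <- as_tibble(residue_labels)
  if (!"aa" %in% names(labels)) labels$aa <- NA_character_
  ni <- sum(labels$label == "INTERFACE")
  nj <- sum(labels$label == "NON_INTERFACE_SURFACE")
  if (n_disease > 0 && (ni == 0 || nj == 0)) {
    abort("need both interface and non-interface residues to plant an OR")
  }
  p_i <- p_j <- 0
  if (n_disease > 0) {
    # solve N_i p_i + N_j p_j = n_disease with odds(p_i)/odds(p_j) = OR
    expected <- function(lo_j) {
      pj <- stats::plogis(lo_j)
      pi_ <- stats::plogis(lo_j + log(target_or))
      ni * pi_ + nj * pj
    }
    if (expected(20) < n_disease) {
      abort("infeasible target OR for the available residues")
    }
    lo_j <- stats::uniroot(function(x) expected(x) - n_disease,
                           c(-40, 20), tol = 1e-10)$root
    p_j <- stats::plogis(lo_j)
    p_i <- stats::plogis(lo_j + log(target_or))
  }
  withr::with_seed(seed, {
    labels$aa[is.na(labels$aa)] <-
      sample(names(.aa_one_to_three), sum(is.na(labels$aa)), replace = TRUE)
    p <- ifelse(labels$label == "INTERFACE", p_i,
                ifelse(labels$label == "NON_INTERFACE_SURFACE", p_j, 0))
    hit <- runif(nrow(labels)) < p
    disease <- labels[hit, , drop = FALSE]
    pool <- labels
    n_unif <- n_polymorphism + n_unclassified
    if (n_unif > nrow(pool)) {
      abort("more uniform variants requested than available residues")
    }
    unif_idx <- sample(nrow(pool), n_unif)
    poly <- pool[unif_idx[seq_len(n_polymorphism)], , drop = FALSE]
    uncl <- pool[setdiff(unif_idx, unif_idx[seq_len(n_polymorphism)]), ,
                 drop = FALSE]
    placements <- bind_rows(
      disease |> mutate(category = "DISEASE"),
      poly |> mutate(category = "POLYMORPHISM"),
      uncl |> mutate(category = "UNCLASSIFIED"))
    mut <- vapply(placements$aa, function(a) {
      sample(setdiff(names(.aa_one_to_three), a), 1)
    }, character(1))
    placements$mut_aa <- mut
  })
  tok <- c(DISEASE = "Disease", POLYMORPHISM = "Polymorphism",
           UNCLASSIFIED = "Unclassified")
  text <- if (nrow(placements) > 0) {
    sprintf("%-10s %-10s VAR_%06d  p.%s%d%s %-13s %-10s -",
            paste0("G_", placements$accession), placements$accession,
            seq_len(nrow(placements)),
            unname(.aa_one_to_three[placements$aa]), placements$position,
            unname(.aa_one_to_three[placements$mut_aa]),
            unname(tok[placements$category]), "-")
  } else character(0)
  list(text = text, truth = placements,
       rates = c(interface = p_i, non_interface = p_j))
}

.census_data <- list(
  structural = list(
    proteins = 353, proteins_with_snp = 258,
    residues = c(total = 76168, core = 21710, interface = 23779,
                 non_interface = 30679, hotspot = 5918,
                 hotspot_interface = 3673),
    DISEASE = c(total = 832, core = 399, interface = 183,
                non_interface = 250, hotspot_interface = 33),
    POLYMORPHISM = c(total = 499, core = 118, interface = 193,
                     non_interface = 188, hotspot_interface = 46),
    UNCLASSIFIED = c(total = 293, core = 102, interface = 73,
                     non_interface = 118, hotspot_interface = 17)
  ),
  docking = list(
    proteins = 583, proteins_with_snp = 411,
    residues = c(total = 189629, core = 53849, interface = 55031,
                 non_interface = 80749, hotspot = 11839,
                 hotspot_interface = 11839),
    DISEASE = c(total = 1363, core = 609, interface = 370,
                non_interface = 384, hotspot_interface = 74),
    POLYMORPHISM = c(total = 851, core = 231, interface = 221,
                     non_interface = 399, hotspot_interface = 35),
    UNCLASSIFIED = c(total = 401, core = 130, interface = 145,
                     non_interface = 126, hotspot_interface = 47)
  ),
  combined = list(
    proteins = 603, proteins_with_snp = 424,
    residues = c(total = 199846, core = 54936, interface = 68768,
                 non_interface = 76142, hotspot = 16449,
                 hotspot_interface = 14459),
    DISEASE = c(total = 1438, core = 629, interface = 466,
                non_interface = 343, hotspot_interface = 109),
    POLYMORPHISM = c(total = 899, core = 228, interface = 331,
                     non_interface = 340, hotspot_interface = 76),
    UNCLASSIFIED = c(total = 449, core = 146, interface = 178,
                     non_interface = 125, hotspot_interface = 61)
  )
)

#' Packaged interaction-network census
#'
#' Residue and nsSNP location counts for the protein interaction networks
#' of six disease phenotypes, in three evidence contexts: complex
#' structures only (`"structural"`), docking-based interface models only
#' (`"docking"`), and both combined (`"combined"`). These packaged counts
#' drive the enrichment statistics without re-running the full survey; see
#' [census_statistics()].
#'
#' @param context `"structural"`, `"docking"` or `"combined"`.
#' @return A `region_census` tibble (see [region_census()]); attributes
#'   `n_proteins` and `n_proteins_with_snp` carry the protein counts.
#' @examples
#' interaction_census("structural")
#' @export
interaction_census <- function(context = c("structural", "docking",
                                           "combined")) {
  context <- match.arg(context)
  d <- .census_data[[context]]
  rows <- list(tibble(context = context, group = "residues",
                      region = names(d$residues),
                      count = unname(d$residues)))
  for (cat in .variant_categories) {
    rows[[cat]] <- tibble(context = context, group = cat,
                          region = names(d[[cat]]),
                          count = unname(d[[cat]]))
  }
  out <- bind_rows(rows)
  class(out) <- c("region_census", class(out))
  attr(out, "n_proteins") <- d$proteins
  attr(out, "n_proteins_with_snp") <- d$proteins_with_snp
  out
}
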