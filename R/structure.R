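# Structure models: parsing PDB coordinates into a tidy atom table, residue
# bookkeeping, rigid transforms and inter-residue distances.

#' Construct a structure model from an atom table
#'
#' A structure model is a tibble of atoms (one row per non-hydrogen protein
#' atom) with the class `structure_model`. Most users will obtain one from
#' [parse_structure()] or [read_structure()] rather than building it by hand.
#'
#' @param atoms A data frame with columns `chain`, `resno`, `ins`, `resname`,
#'   `atom`, `element`, `x`, `y`, `z` and optionally `charge`. Radii are
#'   looked up from the packaged van der Waals table unless a `radius`
#'   column is present.
#' @param source_id Free-text identifier carried through downstream tables.
#' @return A `structure_model` tibble with additional columns `res_key`
#'   (unique residue identifier `chain:resno[ins]`), `radius` and `charge`.
#' @export
structure_model <- function(atoms, source_id = "structure") {
  atoms <- as_tibble(atoms)
  needed <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("atom table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(atoms) == 0) abort("structure has no atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("non-finite atomic coordinates")
  }
  if (!"ins" %in% names(atoms)) atoms$ins <- ""
  atoms$ins[is.na(atoms$ins)] <- ""
  if (!"charge" %in% names(atoms)) atoms$charge <- NA_real_
  if (!"radius" %in% names(atoms)) {
    atoms$radius <- .vdw_radius_for(atoms$element)
  }
  stopifnot(all(atoms$radius > 0))
  atoms$res_key <- paste0(atoms$chain, ":", atoms$resno, atoms$ins)
  # default coarse charges: residue formal charge on the side-chain
  # representative atom (CB, else CA)
  no_q <- is.na(atoms$charge)
  if (any(no_q)) {
    q <- unname(.residue_charge[atoms$resname])
    q[is.na(q)] <- 0
    rep_atom <- atoms |>
      mutate(.row = dplyr::row_number()) |>
      group_by(.data$res_key) |>
      mutate(.rep = if (any(.data$atom == "CB")) .data$atom == "CB"
             else .data$atom == .data$atom[1]) |>
      ungroup()
    q[!rep_atom$.rep] <- 0
    atoms$charge[no_q] <- q[no_q]
  }
  structure(atoms,
            class = c("structure_model", class(tibble())),
            source_id = source_id)
}

#' @export
print.structure_model <- function(x, ...) {
  cat("# structure_model <", attr(x, "source_id"), ">: ",
      nrow(x), " atoms, ", length(unique(x$res_key)), " residues, chains {",
      paste(sort(unique(x$chain)), collapse = ","), "}\n", sep = "")
  NextMethod()
}

#' Parse PDB-format text into a structure model
#'
#' Reads `ATOM` records (first `MODEL` only), drops hydrogens, `HETATM`
#' records and waters, keeps blank/`A` alternate locations, and maps common
#' non-standard residues to their standard parent (other unknown residues
#' are dropped with a warning). Author numbering is preserved.
#'
#' @param pdb_text Character scalar or vector of PDB lines.
#' @param chain_filter Optional character vector of chain ids to keep.
#' @param source_id Identifier stored on the result.
#' @param charge_from_bfactor If `TRUE`, atomic charges are taken from the
#'   B-factor column (used by the packaged toy-complex fixtures, which store
#'   their designed charges there).
#' @return A [structure_model()].
#' @export
parse_structure <- function(pdb_text, chain_filter = NULL,
                            source_id = "structure",
                            charge_from_bfactor = FALSE) {
  lines <- unlist(strsplit(paste(pdb_text, collapse = "\n"), "\n",
                           fixed = TRUE))
  # first model only
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl) > 0) lines <- lines[seq_len(endmdl[1] - 1)]
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  "
  if (!any(is_atom)) abort("no ATOM records in PDB input")
  atom_lines <- lines[is_atom]
  atom_idx <- which(is_atom)

  num <- function(from, to) {
    suppressWarnings(as.numeric(trimws(substr(atom_lines, from, to))))
  }
  x <- num(31, 38); y <- num(39, 46); z <- num(47, 54)
  bad <- which(is.na(x) | is.na(y) | is.na(z))
  if (length(bad) > 0) {
    abort(paste0("malformed coordinate field in ATOM record at line ",
                 atom_idx[bad[1]], ": '", atom_lines[bad[1]], "'"))
  }
  # delegate record parsing to bio3d, which handles the format's quirks
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  pdb <- NULL
  invisible(utils::capture.output(
    pdb <- suppressWarnings(bio3d::read.pdb(tmp, multi = FALSE,
                                            verbose = FALSE))))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  atoms <- tibble(
    atom = at$elety,
    alt = ifelse(is.na(at$alt), "", at$alt),
    resname = at$resid,
    chain = ifelse(is.na(at$chain), " ", at$chain),
    resno = as.integer(at$resno),
    ins = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    b = at$b,
    element = ifelse(is.na(at$elesy), "", at$elesy)
  )
  # element fallback: first alphabetic character of the atom name
  no_el <- atoms$element == "" | is.na(atoms$element)
  atoms$element[no_el] <-
    substr(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", atoms$atom[no_el])),
           1, 1)

  atoms <- atoms |> filter(.data$alt %in% c("", "A"))
  atoms <- atoms |> filter(!toupper(.data$element) %in% c("H", "D"))
  atoms <- atoms |> filter(!.data$resname %in% c("HOH", "WAT", "DOD"))
  # map non-standard residues to a parent where known, drop the rest
  known <- atoms$resname %in% names(.aa_three_to_one)
  mappable <- !known & atoms$resname %in% names(.aa_parent)
  if (any(mappable)) {
    atoms$resname[mappable] <-
      unname(.aa_parent[atoms$resname[mappable]])
  }
  unknown <- !known & !mappable
  if (any(unknown)) {
    warn(paste0("dropping ", sum(unknown), " atom(s) of non-standard ",
                "residue(s): ",
                paste(unique(atoms$resname[unknown]), collapse = ", ")))
    atoms <- atoms[!unknown, ]
  }
  if (!is.null(chain_filter)) {
    atoms <- atoms |> filter(.data$chain %in% chain_filter)
  }
  if (nrow(atoms) == 0) abort("no atoms left after filtering")
  atoms$charge <- if (charge_from_bfactor) atoms$b else NA_real_
  atoms$alt <- NULL
  atoms$b <- NULL
  structure_model(atoms, source_id = source_id)
}

#' Read a structure model from a PDB file
#'
#' @param path Path to a PDB-format file.
#' @inheritParams parse_structure
#' @return A [structure_model()].
#' @export
read_structure <- function(path, chain_filter = NULL,
                           source_id = NULL, charge_from_bfactor = FALSE) {
  parse_structure(readLines(path, warn = FALSE),
                  chain_filter = chain_filter,
                  source_id = source_id %||% basename(path),
                  charge_from_bfactor = charge_from_bfactor)
}

#' Per-residue summary of a structure model
#'
#' @param structure A [structure_model()].
#' @return A tibble with one row per residue in order of appearance:
#'   `res_key`, `chain`, `resno`, `ins`, `resname`, `n_atoms`.
#' @export
residues <- function(structure) {
  structure |>
    as_tibble() |>
    group_by(.data$res_key) |>
    summarise(chain = .data$chain[1], resno = .data$resno[1],
              ins = .data$ins[1], resname = .data$resname[1],
              n_atoms = dplyr::n(), .groups = "drop") |>
    arrange(match(.data$res_key, unique(structure$res_key)))
}

.coords <- function(structure) {
  cbind(structure$x, structure$y, structure$z)
}

#' Apply a rigid-body transform to a structure
#'
#' The rotation is applied about `center` (the structure centroid by
#' default), then the translation is added: `x' = R (x - c) + c + t`. This
#' is the pose convention used throughout the docking module.
#'
#' @param structure A [structure_model()].
#' @param rotation 3x3 rotation matrix (determinant +1).
#' @param translation Numeric 3-vector in Angstrom.
#' @param center Rotation center; defaults to the atom centroid.
#' @return The transformed `structure_model`.
#' @export
transform_structure <- function(structure, rotation = diag(3),
                                translation = c(0, 0, 0), center = NULL) {
  xyz <- .coords(structure)
  if (is.null(center)) center <- colMeans(xyz)
  new_xyz <- sweep(xyz, 2, center) %*% t(rotation)
  new_xyz <- sweep(new_xyz, 2, center + translation, "+")
  structure$x <- new_xyz[, 1]
  structure$y <- new_xyz[, 2]
  structure$z <- new_xyz[, 3]
  structure
}

#' Minimum inter-residue atomic distance
#'
#' Minimum Euclidean distance over all atom pairs of two residues of the
#' same structure, in Angstrom. Symmetric in its arguments.
#'
#' @param structure A [structure_model()].
#' @param key_a,key_b Residue keys (`chain:resno[ins]`).
#' @return A length-one numeric distance.
#' @export
min_interresidue_distance <- function(structure, key_a, key_b) {
  a <- structure[structure$res_key == key_a, , drop = FALSE]
  b <- structure[structure$res_key == key_b, , drop = FALSE]
  if (nrow(a) == 0) abort(paste0("residue not found: ", key_a))
  if (nrow(b) == 0) abort(paste0("residue not found: ", key_b))
  min(.cross_dist(.coords(a), .coords(b)))
}

# all pairwise distances between two coordinate matrices
.cross_dist <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Write a structure model to PDB format
#'
#' Atomic charges are stored in the B-factor column so that fixture
#' structures round-trip through [parse_structure()] with
#' `charge_from_bfactor = TRUE`. Output is byte-deterministic.
#'
#' @param structure A [structure_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  q <- structure$charge
  q[is.na(q)] <- 0
  name4 <- ifelse(nchar(structure$atom) < 4,
                  sprintf(" %-3s", structure$atom),
                  structure$atom)
  lines <- sprintf(
    "ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(structure)), name4, structure$resname, structure$chain,
    structure$resno, ifelse(structure$ins == "", " ", structure$ins),
    structure$x, structure$y, structure$z, 1.0, q,
    toupper(structure$element))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
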