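# Solvent-accessible surface area: numerical Shrake-Rupley on probe-expanded
# spheres, summed per residue, and normalization to relative ASA.

#' Compute per-residue solvent-accessible surface area
#'
#' Numerical Shrake-Rupley ASA: each atom's probe-expanded sphere is sampled
#' with a deterministic golden-angle point set, points inside any other
#' expanded sphere are discarded, and the exposed fraction is converted to
#' area. Per-atom areas are summed into residues.
#'
#' @param structure A [structure_model()].
#' @param probe_radius Probe radius in Angstrom (water, 1.4 by default).
#' @param n_sphere_points Number of test points per atom.
#' @param reference_table_id Maximum-ASA table used for relative ASA; see
#'   [max_asa_reference()].
#' @return An `asa_profile` tibble, one row per residue, with columns
#'   `res_key`, `chain`, `resno`, `ins`, `resname`, `asa` (absolute, in
#'   squared Angstrom) and `rasa`. The per-atom exposed areas are attached
#'   as attribute `atom_area`; `probe_radius`, `n_sphere_points` and
#'   `reference_table_id` are recorded as attributes.
#' @examples
#' s <- structure_model(tibble::tibble(
#'   chain = "A", resno = 1, resname = "ALA", atom = "CA",
#'   element = "C", x = 0, y = 0, z = 0))
#' compute_asa(s)
#' @export
compute_asa <- function(structure, probe_radius = 1.4,
                        n_sphere_points = 960,
                        reference_table_id = "tien2013_theoretical") {
  if (nrow(structure) == 0) abort("structure has no atoms")
  if (probe_radius <= 0) abort("probe_radius must be > 0")
  areas <- .sr_atom_areas(.coords(structure), structure$radius,
                          probe_radius, as.integer(n_sphere_points))
  prof <- structure |>
    as_tibble() |>
    mutate(.area = areas) |>
    group_by(.data$res_key) |>
    summarise(chain = .data$chain[1], resno = .data$resno[1],
              ins = .data$ins[1], resname = .data$resname[1],
              asa = sum(.data$.area), .groups = "drop") |>
    arrange(match(.data$res_key, unique(structure$res_key)))
  prof$rasa <- relative_asa(prof$asa, prof$resname,
                            table_id = reference_table_id)
  structure(prof,
            class = c("asa_profile", class(tibble())),
            atom_area = areas,
            probe_radius = probe_radius,
            n_sphere_points = as.integer(n_sphere_points),
            reference_table_id = reference_table_id,
            source_id = attr(structure, "source_id"))
}

#' Relative accessible surface area
#'
#' Divides an absolute ASA by the packaged reference maximum for the residue
#' type. Values can slightly exceed 1 for very exposed residues.
#'
#' @param asa Numeric vector of absolute ASA values (squared Angstrom).
#' @param residue_name 3-letter residue codes, recycled against `asa`.
#' @param table_id Reference table, see [max_asa_reference()].
#' @param strict If `TRUE`, an unknown residue name is an error; otherwise
#'   it yields `NA` with a warning.
#' @return Numeric vector of rASA values.
#' @examples
#' relative_asa(64.5, "ALA") # half the ALA reference
#' @export
relative_asa <- function(asa, residue_name,
                         table_id = "tien2013_theoretical",
                         strict = FALSE) {
  if (any(asa < 0, na.rm = TRUE)) abort("negative ASA")
  ref <- .max_asa_reference[[table_id]]
  if (is.null(ref)) abort(paste0("unknown ASA reference table: ", table_id))
  mx <- unname(ref[residue_name])
  if (anyNA(mx)) {
    bad <- unique(residue_name[is.na(mx)])
    msg <- paste0("unknown residue name(s): ", paste(bad, collapse = ", "))
    if (strict) abort(msg)
    warn(paste0(msg, "; returning NA"))
  }
  asa / mx
}
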