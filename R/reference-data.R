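# Packaged reference tables: amino-acid codes, van der Waals radii,
# maximum-ASA normalization values, coarse side-chain charges and atomic
# solvation parameters.

# 3-letter -> 1-letter for the 20 standard amino acids
.aa_three_to_one <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)
.aa_one_to_three <- setNames(names(.aa_three_to_one), .aa_three_to_one)

# common non-standard residues mapped to a standard parent
.aa_parent <- c(
  MSE = "MET", SEC = "CYS", CSO = "CYS", CME = "CYS", OCS = "CYS",
  HSD = "HIS", HSE = "HIS", HSP = "HIS", HIE = "HIS", HID = "HIS",
  HIP = "HIS", MLY = "LYS", KCX = "LYS", LLP = "LYS", PYL = "LYS",
  SEP = "SER", TPO = "THR", PTR = "TYR", PCA = "GLU", CGU = "GLU",
  FME = "MET", MLE = "LEU", SAR = "GLY", AIB = "ALA", DAL = "ALA"
)

# Theoretical maximum ASA per residue type (Gly-X-Gly tripeptide scale,
# Tien et al. 2013), in squared Angstrom. Used to normalize absolute ASA
# into relative ASA; the table id is recorded in every ASA profile.
.max_asa_reference <- list(
  tien2013_theoretical = c(
    ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
    GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
    LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
    SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0
  )
)

# van der Waals radii by element (Angstrom); unknown elements fall back to
# carbon with a warning at parse time.
.vdw_radii <- c(
  C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  H = 1.20, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
  SE = 1.90
)
.vdw_default <- 1.70

# Coarse formal side-chain charges per residue type, placed on the
# side-chain representative atom when no explicit charges are supplied.
.residue_charge <- c(ASP = -1, GLU = -1, LYS = 1, ARG = 1, HIS = 0.5)

# Atomic solvation parameters by element (energy units per squared
# Angstrom); positive for apolar atoms so that burial on complexation is
# favorable, slightly negative for polar atoms.
.solvation_asp <- c(C = 0.018, S = 0.018, N = -0.006, O = -0.006,
                    P = 0.0, H = 0.0)
.asp_default <- 0.0

#' Reference maximum accessible surface areas
#'
#' Returns the packaged maximum-ASA normalization table used to convert
#' absolute solvent-accessible surface areas into relative ASA (rASA).
#'
#' @param table_id Name of the reference set. Currently only
#'   `"tien2013_theoretical"`, the theoretical Gly-X-Gly maxima of Tien et
#'   al. (2013), is packaged.
#' @return A tibble with columns `residue_name` (3-letter code) and
#'   `max_asa` (squared Angstrom).
#' @examples
#' max_asa_reference()
#' @export
max_asa_reference <- function(table_id = "tien2013_theoretical") {
  if (!table_id %in% names(.max_asa_reference)) {
    abort(paste0("unknown ASA reference table: ", table_id))
  }
  ref <- .max_asa_reference[[table_id]]
  tibble(residue_name = names(ref), max_asa = unname(ref))
}

.vdw_radius_for <- function(element) {
  el <- toupper(element)
  r <- unname(.vdw_radii[el])
  miss <- is.na(r)
  if (any(miss)) {
    warn(paste0("unknown element(s) ", paste(unique(el[miss]), collapse = ", "),
                "; using default van der Waals radius ", .vdw_default, " A"))
    r[miss] <- .vdw_default
  }
  r
}

.asp_for <- function(element) {
  a <- unname(.solvation_asp[toupper(element)])
  a[is.na(a)] <- .asp_default
  a
}
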