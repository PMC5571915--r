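# Residue location classification: core / interface / non-interacting
# surface, from unbound-subunit rASA and complex contacts.

.location_levels <- c("CORE", "INTERFACE", "NON_INTERFACE_SURFACE")

#' Classify residues as core, interface or non-interacting surface
#'
#' Residues with average unbound-subunit rASA below `core_cutoff` are
#' `CORE`. Exposed residues with any atom within `contact_cutoff` of any
#' partner-chain atom in any supplied complex are `INTERFACE`; the rest are
#' `NON_INTERFACE_SURFACE`. When several structures of the same protein are
#' supplied, the rASA used for the core decision is the mean over the
#' structures containing the residue, which resolves conflicting
#' buried-versus-exposed outcomes between structures.
#'
#' @param subunit_profiles An `asa_profile` from [compute_asa()] computed on
#'   the isolated (unbound) subunit, or a list of such profiles from
#'   several structures of the same protein. Residues are matched by
#'   `res_key` (author numbering), so the structures must share a
#'   numbering frame (see [build_numbering_map()] to reconcile them).
#' @param partner_structures A list of contact contexts, each a list with
#'   elements `complex` (a [structure_model()] of the assembled complex),
#'   `self_chains` (chains of the classified protein) and `partner_chains`.
#'   May be empty, in which case no residue is labelled `INTERFACE`.
#' @param contact_cutoff Interface distance rule in Angstrom (all atoms).
#' @param core_cutoff rASA threshold below which a residue is buried.
#' @return A `residue_classification` tibble: `res_key`, `chain`, `resno`,
#'   `ins`, `resname`, `asa`, `rasa` (averaged), `min_partner_dist` and
#'   `label` (factor with levels CORE, INTERFACE, NON_INTERFACE_SURFACE).
#' @export
classify_residues <- function(subunit_profiles, partner_structures = list(),
                              contact_cutoff = 10, core_cutoff = 0.1) {
  if (is.data.frame(subunit_profiles)) {
    subunit_profiles <- list(subunit_profiles)
  }
  stopifnot(length(subunit_profiles) > 0)
  prof <- bind_rows(lapply(subunit_profiles, as_tibble)) |>
    group_by(.data$res_key) |>
    summarise(chain = .data$chain[1], resno = .data$resno[1],
              ins = .data$ins[1], resname = .data$resname[1],
              asa = mean(.data$asa), rasa = mean(.data$rasa),
              .groups = "drop")

  min_dist <- rep(Inf, nrow(prof))
  names(min_dist) <- prof$res_key
  for (ctx in partner_structures) {
    cx <- ctx$complex
    self <- cx[cx$chain %in% ctx$self_chains, , drop = FALSE]
    partner <- cx[cx$chain %in% ctx$partner_chains, , drop = FALSE]
    if (nrow(self) == 0 || nrow(partner) == 0) {
      abort("complex context with empty self or partner chain selection")
    }
    self_keys <- unique(self$res_key)
    absent <- setdiff(self_keys, prof$res_key)
    if (length(absent) > 0) {
      abort(paste0("residue(s) in complex but absent from ASA profile: ",
                   paste(absent, collapse = ", ")))
    }
    grp <- match(self$res_key, self_keys) - 1L
    d <- .group_min_dist(.coords(self), grp, length(self_keys),
                         .coords(partner))
    idx <- match(self_keys, prof$res_key)
    min_dist[idx] <- pmin(min_dist[idx], d)
  }

  prof$min_partner_dist <- unname(min_dist)
  prof$label <- factor(
    ifelse(prof$rasa < core_cutoff, "CORE",
           ifelse(prof$min_partner_dist <= contact_cutoff,
                  "INTERFACE", "NON_INTERFACE_SURFACE")),
    levels = .location_levels)
  class(prof) <- c("residue_classification", class(prof))
  prof
}

#' Interface residues of one side of a complex
#'
#' Convenience wrapper around the all-atom distance rule: residues of
#' `self_chains` with any atom within `cutoff` of any `partner_chains`
#' atom.
#'
#' @param complex_structure A [structure_model()] of the assembled complex.
#' @param self_chains,partner_chains Chain id vectors.
#' @param cutoff Contact distance in Angstrom.
#' @return Character vector of residue keys.
#' @export
interface_residues <- function(complex_structure, self_chains,
                               partner_chains, cutoff = 10) {
  self <- complex_structure[complex_structure$chain %in% self_chains, ,
                            drop = FALSE]
  partner <- complex_structure[complex_structure$chain %in% partner_chains, ,
                               drop = FALSE]
  if (nrow(self) == 0 || nrow(partner) == 0) {
    abort("empty chain selection")
  }
  self_keys <- unique(self$res_key)
  grp <- match(self$res_key, self_keys) - 1L
  d <- .group_min_dist(.coords(self), grp, length(self_keys),
                       .coords(partner))
  self_keys[d <= cutoff]
}

#' Write a residue classification table
#'
#' Tab-separated output with one row per residue.
#'
#' @param classification A `residue_classification` from
#'   [classify_residues()].
#' @param path Output file path.
#' @param source_id Identifier written in the first column.
#' @return `path`, invisibly.
#' @export
write_classification <- function(classification, path,
                                 source_id = "structure") {
  out <- classification |>
    as_tibble() |>
    transmute(source_id = source_id, chain = .data$chain,
              residue_number = paste0(.data$resno, .data$ins),
              residue_name = .data$resname,
              asa = sprintf("%.3f", .data$asa),
              rasa = sprintf("%.4f", .data$rasa),
              label = as.character(.data$label))
  readr::write_tsv(out, path)
  invisible(path)
}
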