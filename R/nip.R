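# Normalized interface propensity (NIP): per-residue averaged buried
# surface over the lowest-energy docking poses, normalization, hot-spot
# calls and extension into interface patches.

#' Per-residue ASA across docking poses
#'
#' Computes each residue's accessible surface area in the complex formed by
#' the receptor and the posed ligand, for every pose of a docking run.
#' The exact method recomputes Shrake-Rupley ASA on the assembled pair; the
#' `"contact"` method is a fast approximation that discounts each atom's
#' unbound ASA by a clipped count of partner atoms within probe contact
#' range (useful for screening; the exact method is the reference).
#'
#' @param run A `docking_run` (typically after [select_lowest()]).
#' @param probe_radius,n_sphere_points Shrake-Rupley settings, matching
#'   [compute_asa()].
#' @param burial `"exact"` or `"contact"`.
#' @return A long tibble: `pose_id`, `res_key`, `asa`, covering receptor
#'   and ligand residues (their chain ids must be disjoint).
#' @export
pose_residue_asa <- function(run, probe_radius = 1.4,
                             n_sphere_points = 960,
                             burial = c("exact", "contact")) {
  burial <- match.arg(burial)
  rec <- run$receptor
  lig <- run$ligand
  if (length(intersect(unique(rec$chain), unique(lig$chain))) > 0) {
    abort("receptor and ligand share chain ids; rename chains first")
  }
  rx <- .coords(rec)
  lx0 <- .coords(lig)
  lc <- colMeans(lx0)
  centered <- sweep(lx0, 2, lc)
  keys <- c(rec$res_key, lig$res_key)
  ukeys <- unique(keys)
  grp <- match(keys, ukeys)
  radii <- c(rec$radius, lig$radius)
  rot_cache <- lapply(seq_len(nrow(run$rotations)), function(i) {
    t(.quat_to_mat(run$rotations[i, ]))
  })
  if (burial == "contact") {
    rec_atom_asa <- .sr_atom_areas(rx, rec$radius, probe_radius,
                                   as.integer(n_sphere_points))
    lig_atom_asa <- .sr_atom_areas(lx0, lig$radius, probe_radius,
                                   as.integer(n_sphere_points))
    unbound_atom <- c(rec_atom_asa, lig_atom_asa)
  }
  out <- vector("list", nrow(run$poses))
  for (i in seq_len(nrow(run$poses))) {
    p <- run$poses[i, ]
    lx <- centered %*% rot_cache[[p$rot_id]]
    lx <- sweep(lx, 2, lc + c(p$tx, p$ty, p$tz), "+")
    all_xyz <- rbind(rx, lx)
    if (burial == "exact") {
      areas <- .sr_atom_areas(all_xyz, radii, probe_radius,
                              as.integer(n_sphere_points))
    } else {
      d <- .cross_dist(rx, lx)
      lim <- outer(rec$radius, lig$radius, "+") + 2 * probe_radius
      n_rec <- rowSums(d < lim)
      n_lig <- colSums(d < lim)
      f <- pmin(1, 0.25 * c(n_rec, n_lig))
      areas <- unbound_atom * (1 - f)
    }
    res_asa <- rowsum(areas, grp)
    out[[i]] <- tibble(pose_id = p$pose_id,
                       res_key = ukeys[as.integer(rownames(res_asa))],
                       asa = as.numeric(res_asa))
  }
  bind_rows(out)
}

#' Averaged buried surface (ABS)
#'
#' For each residue, the relative difference between its ASA in the unbound
#' structure and its average ASA over the selected docking poses:
#' `ABS = (ASA_unbound - mean_pose(ASA)) / ASA_unbound`. Residues with zero
#' unbound ASA get ABS 0.
#'
#' @param unbound_asa An `asa_profile` (or tibble with `res_key`, `asa`)
#'   of the isolated subunit.
#' @param pose_asa Long tibble (`pose_id`, `res_key`, `asa`) restricted to
#'   the same residue set, e.g. from [pose_residue_asa()].
#' @return A tibble: `res_key`, `asa_unbound`, `mean_pose_asa`, `abs`.
#' @export
averaged_buried_surface <- function(unbound_asa, pose_asa) {
  if (nrow(pose_asa) == 0) abort("pose ASA list is empty")
  pose_mean <- pose_asa |>
    group_by(.data$res_key) |>
    summarise(mean_pose_asa = mean(.data$asa), .groups = "drop")
  if (!setequal(pose_mean$res_key, unbound_asa$res_key)) {
    abort("residue sets of unbound profile and pose ASA differ")
  }
  unbound_asa |>
    as_tibble() |>
    select("res_key", asa_unbound = "asa") |>
    left_join(pose_mean, by = "res_key") |>
    mutate(abs = ifelse(.data$asa_unbound == 0, 0,
                        (.data$asa_unbound - .data$mean_pose_asa) /
                          .data$asa_unbound))
}

#' Normalize ABS into NIP
#'
#' Per-protein affine normalization mapping the mean ABS to 0 and the
#' maximum ABS to 1: `NIP = (ABS - mean(ABS)) / (max(ABS) - mean(ABS))`.
#' A flat ABS profile yields NIP 0 everywhere.
#'
#' @param abs_profile A tibble with an `abs` column (e.g. from
#'   [averaged_buried_surface()]), or a bare numeric vector of ABS values.
#' @return The tibble with an added `nip` column, or a numeric vector.
#' @export
normalize_nip <- function(abs_profile) {
  if (is.numeric(abs_profile)) {
    return(.nip_values(abs_profile))
  }
  if (nrow(abs_profile) == 0) abort("empty ABS profile")
  abs_profile$nip <- .nip_values(abs_profile$abs)
  abs_profile
}

.nip_values <- function(a) {
  ok <- !is.na(a)
  if (!any(ok)) abort("no ABS values")
  m <- mean(a[ok])
  mx <- max(a[ok])
  out <- rep(NA_real_, length(a))
  out[ok] <- if (mx > m) (a[ok] - m) / (mx - m) else 0
  out
}

#' Predict interface hot-spot residues from NIP
#'
#' Residues with NIP greater than or equal to the cutoff (0.2 by default)
#' are called hot-spots.
#'
#' @param nip A tibble with `res_key` and `nip` columns, or a named numeric
#'   vector of NIP values.
#' @param cutoff NIP threshold, in (-1, 1].
#' @return Character vector of hot-spot residue keys.
#' @export
predict_hotspots <- function(nip, cutoff = 0.2) {
  if (cutoff <= -1 || cutoff > 1) abort("cutoff must be in (-1, 1]")
  if (is.numeric(nip)) {
    keys <- names(nip) %||% as.character(seq_along(nip))
    return(keys[!is.na(nip) & nip >= cutoff])
  }
  nip$res_key[!is.na(nip$nip) & nip$nip >= cutoff]
}

#' Extend a hot-spot set into an interface patch
#'
#' Returns the hot-spots plus every surface residue (rASA strictly above
#' `core_rasa`) whose minimum inter-residue atomic distance to any hot-spot
#' is at most `radius`.
#'
#' @param hotspots Character vector of hot-spot residue keys (must exist in
#'   `structure`).
#' @param structure The subunit [structure_model()].
#' @param rasa An `asa_profile` (or tibble with `res_key`, `rasa`) of the
#'   unbound subunit.
#' @param radius Patch extension distance in Angstrom.
#' @param core_rasa Buried-residue rASA threshold; buried residues are
#'   never added to the patch.
#' @return Character vector of residue keys (the extended patch).
#' @export
extend_patch <- function(hotspots, structure, rasa, radius = 10,
                         core_rasa = 0.1) {
  if (length(hotspots) == 0) return(character(0))
  missing_hs <- setdiff(hotspots, structure$res_key)
  if (length(missing_hs) > 0) {
    abort(paste0("hot-spot residue(s) not in structure: ",
                 paste(missing_hs, collapse = ", ")))
  }
  keys <- unique(structure$res_key)
  grp <- match(structure$res_key, keys) - 1L
  hs_xyz <- .coords(structure[structure$res_key %in% hotspots, ,
                              drop = FALSE])
  d <- .group_min_dist(.coords(structure), grp, length(keys), hs_xyz)
  rasa_tbl <- as_tibble(rasa)[, c("res_key", "rasa")]
  rv <- rasa_tbl$rasa[match(keys, rasa_tbl$res_key)]
  near <- keys[!is.na(rv) & rv > core_rasa & d <= radius]
  union(hotspots, near)
}

#' NIP profile of one docking partner
#'
#' End-to-end per-residue prediction for one side of a rescored docking
#' run: selects the `k` lowest-energy poses, recomputes residue ASA in each
#' pose, forms ABS and NIP, calls hot-spots at the NIP cutoff, and extends
#' the patch to surface residues within `radius` of a hot-spot.
#'
#' @param run A rescored `docking_run` (see [dock_pair()]).
#' @param side `"receptor"` or `"ligand"`: the protein being profiled.
#' @param k Number of lowest-energy poses used.
#' @param cutoff NIP hot-spot threshold.
#' @param radius Patch extension distance (Angstrom).
#' @param core_rasa Buried-residue rASA threshold.
#' @param probe_radius,n_sphere_points ASA settings.
#' @param burial Pose burial method, see [pose_residue_asa()].
#' @return A `nip_profile` tibble: `res_key`, `chain`, `resno`, `ins`,
#'   `resname`, `asa_unbound`, `rasa`, `abs`, `nip`, `hotspot`,
#'   `extended_interface`; attributes record `n_poses_used`, `cutoff`,
#'   `radius` and `side`.
#' @export
nip_profile <- function(run, side = c("receptor", "ligand"), k = 100,
                        cutoff = 0.2, radius = 10, core_rasa = 0.1,
                        probe_radius = 1.4, n_sphere_points = 960,
                        burial = c("exact", "contact")) {
  side <- match.arg(side)
  burial <- match.arg(burial)
  sel <- select_lowest(run, k)
  subunit <- if (side == "receptor") run$receptor else run$ligand
  unbound <- compute_asa(subunit, probe_radius = probe_radius,
                         n_sphere_points = n_sphere_points)
  pose_asa <- pose_residue_asa(sel, probe_radius = probe_radius,
                               n_sphere_points = n_sphere_points,
                               burial = burial) |>
    filter(.data$res_key %in% unbound$res_key)
  abs_tbl <- averaged_buried_surface(unbound, pose_asa)
  abs_tbl <- normalize_nip(abs_tbl)
  hs <- predict_hotspots(abs_tbl, cutoff = cutoff)
  patch <- extend_patch(hs, subunit, unbound, radius = radius,
                        core_rasa = core_rasa)
  prof <- unbound |>
    as_tibble() |>
    select("res_key", "chain", "resno", "ins", "resname", "rasa") |>
    left_join(abs_tbl, by = "res_key") |>
    mutate(hotspot = .data$res_key %in% hs,
           extended_interface = .data$res_key %in% patch) |>
    select("res_key", "chain", "resno", "ins", "resname", "asa_unbound",
           "rasa", "abs", "nip", "hotspot", "extended_interface")
  structure(prof,
            class = c("nip_profile", class(tibble())),
            n_poses_used = nrow(sel$poses),
            cutoff = cutoff, radius = radius, core_rasa = core_rasa,
            side = side, burial = burial)
}

#' Merge NIP profiles of one protein over several docking partners
#'
#' A protein docked against several partners gets one NIP profile per
#' partner; its predicted interface is the union of the partner-specific
#' predictions (a residue is a hot-spot or extended-interface residue if it
#' is one in any profile).
#'
#' @param profiles A list of `nip_profile` objects for the same protein
#'   (matched by `res_key`).
#' @return A tibble with `res_key`, `chain`, `resno`, `ins`, `resname`,
#'   `rasa` (mean over profiles), `nip_max`, and unioned `hotspot` /
#'   `extended_interface` flags; per-partner NIP values are kept in the
#'   long tibble attribute `per_partner`.
#' @export
predict_interface <- function(profiles) {
  if (inherits(profiles, "nip_profile")) profiles <- list(profiles)
  if (length(profiles) == 0) abort("at least one NIP profile required")
  long <- bind_rows(lapply(seq_along(profiles), function(i) {
    as_tibble(profiles[[i]]) |> mutate(partner = i)
  }))
  merged <- long |>
    group_by(.data$res_key) |>
    summarise(chain = .data$chain[1], resno = .data$resno[1],
              ins = .data$ins[1], resname = .data$resname[1],
              rasa = mean(.data$rasa, na.rm = TRUE),
              nip_max = if (all(is.na(.data$nip))) NA_real_
                        else max(.data$nip, na.rm = TRUE),
              hotspot = any(.data$hotspot),
              extended_interface = any(.data$extended_interface),
              .groups = "drop")
  structure(merged,
            class = c("nip_union", class(tibble())),
            per_partner = long)
}

#' Write a NIP profile table
#'
#' Tab-separated per-residue output. Byte-deterministic for a fixed
#' profile.
#'
#' @param profile A `nip_profile` or merged [predict_interface()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_nip_profile <- function(profile, path) {
  tbl <- as_tibble(profile)
  num <- names(tbl)[vapply(tbl, is.double, logical(1))]
  tbl <- tbl |> mutate(across(dplyr::all_of(num), ~ sprintf("%.6f", .x)))
  readr::write_tsv(tbl, path)
  invisible(path)
}
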