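# Rigid-body docking: grid discretization, FFT shape correlation over a
# rotation set, and energy rescoring with electrostatics, van der Waals and
# desolvation terms.

#' Energy scoring parameters
#'
#' Parameters of the pose-rescoring energy function. The total energy is
#' `w_e * electrostatics + w_d * desolvation + w_v * vdw`. Electrostatics is
#' Coulomb with a distance-dependent dielectric `eps(r) = dielectric_slope *
#' r` and a per-pair cap; van der Waals is a 6-12 Lennard-Jones with a
#' per-pair clash cap; desolvation multiplies per-element atomic solvation
#' parameters by an approximate pairwise buried area. All constants are
#' configurable and are recorded in the docking run for reproducibility.
#'
#' @param q_scale Coulomb constant in energy-unit Angstrom per squared
#'   charge (332.0).
#' @param dielectric_slope Slope of the distance-dependent dielectric.
#' @param elec_cap Per-pair cap on the magnitude of the electrostatic term.
#' @param vdw_eps Lennard-Jones well depth.
#' @param vdw_cap Per-pair clash cap on the van der Waals term.
#' @param probe Probe radius used by the pairwise burial approximation.
#' @param desolv_scale Scale of the pairwise burial approximation.
#' @param cutoff Pair distance truncation in Angstrom; beyond it all terms
#'   are zero.
#' @param weights Named vector of term weights (`electrostatics`,
#'   `desolvation`, `vdw`).
#' @return A named list of class `energy_params`.
#' @export
energy_params <- function(q_scale = 332.0, dielectric_slope = 4.0,
                          elec_cap = 1.0, vdw_eps = 0.1, vdw_cap = 1.0,
                          probe = 1.4, desolv_scale = 0.1, cutoff = 12.0,
                          weights = c(electrostatics = 1.0,
                                      desolvation = 1.0, vdw = 0.1)) {
  structure(list(q_scale = q_scale, dielectric_slope = dielectric_slope,
                 elec_cap = elec_cap, vdw_eps = vdw_eps, vdw_cap = vdw_cap,
                 probe = probe, desolv_scale = desolv_scale, cutoff = cutoff,
                 weights = weights),
            class = "energy_params")
}

# unit quaternion -> rotation matrix
.quat_to_mat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Quasi-uniform rotation set
#'
#' Deterministic set of `n` unit quaternions: the identity first, the rest
#' drawn uniformly on SO(3) (Shoemake's method) under the given seed.
#'
#' @param n Number of rotations.
#' @param seed Integer seed controlling the sample.
#' @return A matrix with `n` rows and columns `w, x, y, z`.
#' @export
rotation_set <- function(n, seed = 1) {
  stopifnot(n >= 1)
  qs <- matrix(0, nrow = n, ncol = 4,
               dimnames = list(NULL, c("w", "x", "y", "z")))
  qs[1, ] <- c(1, 0, 0, 0)
  if (n > 1) {
    qs[-1, ] <- withr::with_seed(seed, {
      u1 <- runif(n - 1); u2 <- runif(n - 1); u3 <- runif(n - 1)
      cbind(sqrt(u1) * cos(2 * pi * u3),
            sqrt(1 - u1) * sin(2 * pi * u2),
            sqrt(1 - u1) * cos(2 * pi * u2),
            sqrt(u1) * sin(2 * pi * u3))
    })
  }
  qs
}

#' Discretize a structure onto a shape grid
#'
#' Katchalski-Katzir style discretization on a cubic grid. Cells whose
#' center falls inside any atom's van der Waals sphere are the molecular
#' interior. For a receptor grid the interior gets `interior_penalty` and
#' the shell of thickness `surface_thickness` immediately outside the
#' envelope gets 1, so that a ligand in vdW contact overlaps the shell
#' while penetration overlaps the penalized interior; a ligand grid has
#' value 1 in every interior cell.
#'
#' @param structure A [structure_model()].
#' @param spacing Grid spacing in Angstrom.
#' @param surface_thickness Surface layer thickness in Angstrom.
#' @param role `"receptor"` or `"ligand"`.
#' @param interior_penalty Value of receptor interior cells.
#' @param origin Optional position of the first cell center (3-vector); by
#'   default the grid is fitted to the structure with one cell of margin.
#' @param dims Optional grid dimensions (3 integers).
#' @param max_cells Cell budget; exceeding it is an error suggesting a
#'   larger spacing.
#' @return A `dock_grid`: list with `values` (3D array), `origin`,
#'   `spacing` and `dims`.
#' @export
discretize <- function(structure, spacing, surface_thickness = 1.5,
                       role = c("receptor", "ligand"),
                       interior_penalty = -15, origin = NULL, dims = NULL,
                       max_cells = 8e6) {
  role <- match.arg(role)
  if (nrow(structure) == 0) abort("cannot discretize an empty structure")
  if (spacing <= 0) abort("spacing must be > 0")
  xyz <- .coords(structure)
  rmax <- max(structure$radius)
  pad <- rmax + spacing +
    if (role == "receptor") surface_thickness else 0
  if (is.null(origin) || is.null(dims)) {
    lo <- apply(xyz, 2, min) - pad
    hi <- apply(xyz, 2, max) + pad
    origin <- origin %||% lo
    dims <- dims %||% (floor((hi - origin) / spacing) + 2L)
  }
  dims <- as.integer(dims)
  if (prod(dims) > max_cells) {
    abort(paste0("grid of ", paste(dims, collapse = "x"),
                 " cells exceeds the cell budget (", format(max_cells),
                 "); use a larger spacing"))
  }
  mark <- function(radii) {
    occ <- array(FALSE, dim = dims)
    m <- ceiling(max(radii) / spacing)
    base <- round(sweep(xyz, 2, origin) / spacing) # 0-based nearest cell
    offsets <- as.matrix(expand.grid(dx = -m:m, dy = -m:m, dz = -m:m))
    for (k in seq_len(nrow(offsets))) {
      cell <- sweep(base, 2, offsets[k, ], "+")
      center <- sweep(cell * spacing, 2, origin, "+")
      d2 <- rowSums((center - xyz)^2)
      # a cell is occupied when its center lies inside the sphere; the cell
      # holding the atom center always is (coarse grids)
      inside <- d2 <= radii^2 |
        (offsets[k, 1] == 0 & offsets[k, 2] == 0 & offsets[k, 3] == 0)
      if (!any(inside)) next
      cell <- cell[inside, , drop = FALSE] + 1L # to 1-based indices
      ok <- cell[, 1] >= 1 & cell[, 1] <= dims[1] &
        cell[, 2] >= 1 & cell[, 2] <= dims[2] &
        cell[, 3] >= 1 & cell[, 3] <= dims[3]
      occ[cell[ok, , drop = FALSE]] <- TRUE
    }
    occ
  }
  values <- array(0, dim = dims)
  interior <- mark(structure$radius)
  if (role == "ligand") {
    values[interior] <- 1
  } else {
    shell <- mark(structure$radius + surface_thickness) & !interior
    values[shell] <- 1
    values[interior] <- interior_penalty
  }
  structure(list(values = values, origin = origin, spacing = spacing,
                 dims = dims),
            class = "dock_grid")
}

#' Cross-correlate two shape grids
#'
#' Computes the translational cross-correlation `c[t] = sum_x R[x] L[x-t]`
#' of two grids with identical dimensions, either via the FFT convolution
#' theorem or by direct summation in real space. The two pathways agree
#' exactly on integer-valued grids.
#'
#' @param receptor_grid,ligand_grid `dock_grid` objects with equal `dims`.
#' @param method `"fft"` or `"direct"`.
#' @return A 3D array of correlation scores over cyclic cell shifts.
#' @export
correlate_grids <- function(receptor_grid, ligand_grid,
                            method = c("fft", "direct")) {
  method <- match.arg(method)
  r <- receptor_grid$values
  l <- ligand_grid$values
  if (!identical(dim(r), dim(l))) abort("grid dimensions differ")
  if (method == "fft") {
    cc <- Re(stats::fft(stats::fft(r) * Conj(stats::fft(l)),
                        inverse = TRUE)) / length(r)
    return(cc)
  }
  dims <- dim(r)
  cc <- array(0, dim = dims)
  nz <- which(l != 0, arr.ind = TRUE)
  lv <- l[l != 0]
  for (t1 in 0:(dims[1] - 1)) {
    for (t2 in 0:(dims[2] - 1)) {
      for (t3 in 0:(dims[3] - 1)) {
        i <- ((nz[, 1] - 1 + t1) %% dims[1]) + 1
        j <- ((nz[, 2] - 1 + t2) %% dims[2]) + 1
        k <- ((nz[, 3] - 1 + t3) %% dims[3]) + 1
        cc[t1 + 1, t2 + 1, t3 + 1] <-
          sum(r[cbind(i, j, k)] * lv)
      }
    }
  }
  cc
}

# signed cell shift from a 1-based cyclic index
.signed_shift <- function(idx, n) {
  t <- idx - 1L
  ifelse(t > n / 2, t - n, t)
}

#' Generate rigid-body docking poses by grid shape correlation
#'
#' For each rotation in a quasi-uniform set, the rotated ligand is gridded
#' on the receptor grid frame and the best-correlating translations are
#' located by FFT; the `n_keep` best shape scores over all rotations are
#' kept. Results are deterministic given the seed and configuration.
#'
#' @param receptor,ligand [structure_model()] objects.
#' @param n_rotations Size of the rotation set (identity first).
#' @param spacing Grid spacing in Angstrom.
#' @param n_keep Number of poses kept globally.
#' @param seed Integer seed for the rotation sample.
#' @param surface_thickness Receptor surface layer thickness in Angstrom.
#' @param keep_per_rotation Translations retained per rotation before the
#'   global cut (default: enough to fill `n_keep` with a factor-2 margin).
#' @param interior_penalty Receptor interior cell value.
#' @param max_cells Grid cell budget.
#' @return A `docking_run`: list with `poses` (tibble: `pose_id`, `rot_id`,
#'   quaternion columns, `tx`, `ty`, `tz`, `shape_score`, `rank`),
#'   `rotations`, `receptor`, `ligand` and `params`. Pose translations are
#'   in Angstrom and apply to the ligand after rotation about its centroid
#'   (see [transform_structure()]).
#' @export
generate_poses <- function(receptor, ligand, n_rotations = 150,
                           spacing = 1.5, n_keep = 10000, seed = 1,
                           surface_thickness = 1.5,
                           keep_per_rotation = NULL,
                           interior_penalty = -15, max_cells = 8e6) {
  if (nrow(receptor) == 0 || nrow(ligand) == 0) {
    abort("receptor and ligand must be non-empty")
  }
  keep_per_rotation <- keep_per_rotation %||%
    max(1L, ceiling(2 * n_keep / n_rotations))

  lig_xyz <- .coords(ligand)
  lig_center <- colMeans(lig_xyz)
  lig_half <- max(sqrt(rowSums(sweep(lig_xyz, 2, lig_center)^2))) +
    max(ligand$radius) + spacing

  rec_xyz <- .coords(receptor)
  rec_pad <- max(receptor$radius) + surface_thickness + spacing
  rec_lo <- apply(rec_xyz, 2, min) - rec_pad
  rec_hi <- apply(rec_xyz, 2, max) + rec_pad
  rec_center <- (rec_lo + rec_hi) / 2
  origin <- rec_lo - lig_half - spacing
  extent <- (rec_hi - rec_lo) + 2 * lig_half + 2 * spacing
  dims <- vapply(ceiling(extent / spacing) + 1,
                 function(n) stats::nextn(n, c(2, 3, 5)), numeric(1))
  dims <- as.integer(dims)
  if (prod(dims) > max_cells) {
    abort(paste0("docking grid of ", paste(dims, collapse = "x"),
                 " cells exceeds the cell budget; use a larger spacing"))
  }
  rec_grid <- discretize(receptor, spacing, surface_thickness, "receptor",
                         interior_penalty = interior_penalty,
                         origin = origin, dims = dims,
                         max_cells = max_cells)
  fr <- stats::fft(rec_grid$values)

  quats <- rotation_set(n_rotations, seed = seed)
  pre_shift <- rec_center - lig_center # centers the ligand before search

  res <- vector("list", n_rotations)
  for (ri in seq_len(n_rotations)) {
    rot <- .quat_to_mat(quats[ri, ])
    posed <- transform_structure(ligand, rot, pre_shift,
                                 center = lig_center)
    lig_grid <- discretize(posed, spacing, surface_thickness, "ligand",
                           origin = origin, dims = dims,
                           max_cells = max_cells)
    cc <- Re(stats::fft(fr * Conj(stats::fft(lig_grid$values)),
                        inverse = TRUE)) / prod(dims)
    cc <- round(cc, 6) # integer-valued in exact arithmetic
    ord <- order(-cc)[seq_len(min(keep_per_rotation, length(cc)))]
    sc <- cc[ord]
    pos <- ord[sc > 0]
    sc <- sc[sc > 0]
    if (length(pos) == 0) {
      res[[ri]] <- NULL
      next
    }
    ai <- arrayInd(pos, dims)
    tcell <- cbind(.signed_shift(ai[, 1], dims[1]),
                   .signed_shift(ai[, 2], dims[2]),
                   .signed_shift(ai[, 3], dims[3]))
    res[[ri]] <- tibble(
      rot_id = ri,
      qw = quats[ri, 1], qx = quats[ri, 2], qy = quats[ri, 3],
      qz = quats[ri, 4],
      tx = pre_shift[1] + tcell[, 1] * spacing,
      ty = pre_shift[2] + tcell[, 2] * spacing,
      tz = pre_shift[3] + tcell[, 3] * spacing,
      shape_score = sc)
  }
  poses <- bind_rows(res)
  if (nrow(poses) == 0) abort("no overlapping poses found")
  poses <- poses |>
    mutate(.ord = dplyr::row_number()) |>
    arrange(dplyr::desc(.data$shape_score), .data$.ord) |>
    select(-".ord")
  if (nrow(poses) < n_keep) {
    warn(paste0("only ", nrow(poses), " candidate poses generated (< n_keep = ",
                n_keep, "); returning all"))
  }
  poses <- head(poses, n_keep)
  poses$rank <- seq_len(nrow(poses))
  poses$pose_id <- seq_len(nrow(poses))
  structure(list(
    poses = poses,
    rotations = quats,
    receptor = receptor,
    ligand = ligand,
    params = list(spacing = spacing, n_rotations = n_rotations,
                  n_keep = n_keep, seed = seed,
                  surface_thickness = surface_thickness,
                  interior_penalty = interior_penalty,
                  keep_per_rotation = keep_per_rotation,
                  dims = dims, origin = origin),
    rescored = FALSE
  ), class = "docking_run")
}

# rotation matrix + translation for one row of a pose table
.pose_transform <- function(pose_row) {
  list(rotation = .quat_to_mat(c(pose_row$qw, pose_row$qx, pose_row$qy,
                                 pose_row$qz)),
       translation = c(pose_row$tx, pose_row$ty, pose_row$tz))
}

#' Ligand structure placed in a docking pose
#'
#' @param run A `docking_run`.
#' @param pose_id Pose identifier in `run$poses`.
#' @return The ligand [structure_model()] at the posed position.
#' @export
posed_ligand <- function(run, pose_id) {
  row <- run$poses[run$poses$pose_id == pose_id, , drop = FALSE]
  if (nrow(row) != 1) abort(paste0("no pose with id ", pose_id))
  tr <- .pose_transform(row)
  transform_structure(run$ligand, tr$rotation, tr$translation)
}

#' Score one docking pose
#'
#' Energy of a posed ligand against the receptor: capped Coulomb
#' electrostatics with distance-dependent dielectric, capped 6-12 van der
#' Waals, and desolvation from per-element atomic solvation parameters
#' times an approximate pairwise buried area; all terms truncated at the
#' configured pair-distance cutoff.
#'
#' @param receptor,ligand [structure_model()] objects.
#' @param pose A list with `rotation` (3x3 matrix) and `translation`
#'   (Angstrom 3-vector, applied after rotation about the ligand centroid).
#' @param params An [energy_params()] list.
#' @return A one-row tibble: `electrostatics`, `van_der_waals`,
#'   `desolvation`, `total` (`total` is the weighted sum with the weights
#'   in `params`).
#' @export
score_pose <- function(receptor, ligand, pose, params = energy_params()) {
  posed <- transform_structure(ligand, pose$rotation, pose$translation)
  .score_coords(.coords(receptor), receptor, .coords(posed), posed, params)
}

# pose-invariant pair matrices, reused across poses of a run
.pair_tables <- function(rec, lig) {
  list(qq = outer(rec$charge, lig$charge),
       s = outer(rec$radius, lig$radius, "+"),
       asp_sum = outer(.asp_for(rec$element) * 4 * pi * rec$radius^2,
                       .asp_for(lig$element) * 4 * pi * lig$radius^2, "+"))
}

# numeric c(electrostatics, vdw, desolvation) for one set of ligand coords
.score_components <- function(rx, lx, pt, params) {
  d <- .cross_dist(rx, lx)
  within <- d <= params$cutoff
  if (!any(within)) return(c(0, 0, 0))
  d <- pmax(d[within], 1e-3)
  ele_m <- params$q_scale * pt$qq[within] / (params$dielectric_slope * d^2)
  ele <- sum(pmin(pmax(ele_m, -params$elec_cap), params$elec_cap))
  s <- pt$s[within]
  sr6 <- (s / d)^6
  vdw <- sum(pmin(params$vdw_eps * (sr6^2 - 2 * sr6), params$vdw_cap))
  burial <- pmin(1, pmax(0, (s + 2 * params$probe - d) /
                           (2 * params$probe)))
  des <- -params$desolv_scale * sum(burial * pt$asp_sum[within])
  c(ele, vdw, des)
}

.score_coords <- function(rx, rec, lx, lig, params) {
  comp <- .score_components(rx, lx, .pair_tables(rec, lig), params)
  w <- params$weights
  tibble(electrostatics = comp[1], van_der_waals = comp[2],
         desolvation = comp[3],
         total = w[["electrostatics"]] * comp[1] +
           w[["desolvation"]] * comp[3] + w[["vdw"]] * comp[2])
}

#' Rescore all poses of a docking run
#'
#' Adds energy columns to the pose table and re-ranks by total energy
#' (ascending), breaking ties by shape score (descending) then pose id.
#'
#' @param run A `docking_run` from [generate_poses()].
#' @param params An [energy_params()] list; recorded in the run.
#' @return The rescored `docking_run`.
#' @export
rescore_poses <- function(run, params = energy_params()) {
  rec <- run$receptor
  lig <- run$ligand
  rx <- .coords(rec)
  lx0 <- .coords(lig)
  lc <- colMeans(lx0)
  centered <- sweep(lx0, 2, lc)
  n <- nrow(run$poses)
  ele <- vdw <- des <- numeric(n)
  rot_cache <- lapply(seq_len(nrow(run$rotations)), function(i) {
    t(.quat_to_mat(run$rotations[i, ]))
  })
  pt <- .pair_tables(rec, lig)
  rot_id <- run$poses$rot_id
  txs <- run$poses$tx; tys <- run$poses$ty; tzs <- run$poses$tz
  for (i in seq_len(n)) {
    lx <- centered %*% rot_cache[[rot_id[i]]]
    lx <- sweep(lx, 2, lc + c(txs[i], tys[i], tzs[i]), "+")
    comp <- .score_components(rx, lx, pt, params)
    ele[i] <- comp[1]; vdw[i] <- comp[2]; des[i] <- comp[3]
  }
  w <- params$weights
  tot <- w[["electrostatics"]] * ele + w[["desolvation"]] * des +
    w[["vdw"]] * vdw
  run$poses$electrostatics <- ele
  run$poses$van_der_waals <- vdw
  run$poses$desolvation <- des
  run$poses$total <- tot
  run$poses <- run$poses |>
    arrange(.data$total, dplyr::desc(.data$shape_score), .data$pose_id)
  run$poses$rank <- seq_len(nrow(run$poses))
  run$params$energy <- params
  run$rescored <- TRUE
  run
}

#' Keep the lowest-energy poses of a rescored run
#'
#' @param run A rescored `docking_run`.
#' @param k Number of poses to keep; if fewer are available all are
#'   returned with a warning. Ties in total energy break by shape score
#'   (descending) then pose id.
#' @return The `docking_run` restricted to the `k` lowest-energy poses.
#' @export
select_lowest <- function(run, k = 100) {
  if (!isTRUE(run$rescored)) abort("run has not been rescored")
  poses <- run$poses |>
    arrange(.data$total, dplyr::desc(.data$shape_score), .data$pose_id)
  if (nrow(poses) < k) {
    warn(paste0("only ", nrow(poses), " poses available (< k = ", k, ")"))
    k <- nrow(poses)
  }
  run$poses <- head(poses, k)
  run$poses$rank <- seq_len(k)
  run
}

#' Dock two structures end to end
#'
#' Convenience wrapper: [generate_poses()] then [rescore_poses()].
#'
#' @inheritParams generate_poses
#' @param energy An [energy_params()] list.
#' @param ... Passed to [generate_poses()].
#' @return A rescored `docking_run`.
#' @export
dock_pair <- function(receptor, ligand, n_rotations = 150, spacing = 1.5,
                      n_keep = 2000, seed = 1, energy = energy_params(),
                      ...) {
  run <- generate_poses(receptor, ligand, n_rotations = n_rotations,
                        spacing = spacing, n_keep = n_keep, seed = seed, ...)
  rescore_poses(run, energy)
}

#' @export
print.docking_run <- function(x, ...) {
  cat("# docking_run: ", nrow(x$poses), " poses, ",
      x$params$n_rotations, " rotations, spacing ",
      x$params$spacing, " A", if (isTRUE(x$rescored)) ", rescored" else "",
      "\n", sep = "")
  print(x$poses, ...)
  invisible(x)
}

#' Write a docking run to disk
#'
#' Writes `poses.tsv` (the pose table) and `manifest.json` (all parameters
#' and the seed) into `dir`. Output is byte-deterministic for a fixed run.
#'
#' @param run A `docking_run`.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_docking_run <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  int_cols <- intersect(c("pose_id", "rot_id", "rank"), names(run$poses))
  num_cols <- setdiff(names(run$poses)[vapply(run$poses, is.numeric,
                                              logical(1))], int_cols)
  poses <- run$poses |>
    mutate(across(dplyr::all_of(num_cols), ~ sprintf("%.6f", .x)),
           across(dplyr::all_of(int_cols), ~ sprintf("%d", as.integer(.x))))
  readr::write_tsv(poses, file.path(dir, "poses.tsv"))
  manifest <- run$params
  manifest$rescored <- isTRUE(run$rescored)
  manifest$energy <- unclass(manifest$energy)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(dir, "manifest.json"))
  invisible(dir)
}
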