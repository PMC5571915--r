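# Grid discretization, shape correlation, pose generation and energy
# rescoring.

grid_from <- function(values) {
  structure(list(values = values, origin = c(0, 0, 0), spacing = 1,
                 dims = dim(values)), class = "dock_grid")
}

test_that("discretize marks occupancy as a point-in-sphere test", {
  one <- point_residues(matrix(c(0, 0, 0), ncol = 3))
  g <- discretize(one, spacing = 3.5, role = "ligand")
  expect_equal(sum(g$values != 0), 1)

  # several atoms at finer spacing: compare against brute-force cell
  # enumeration over the whole grid
  set.seed(3)
  xyz <- matrix(rnorm(18, sd = 2.5), ncol = 3)
  s <- point_residues(xyz)
  g <- discretize(s, spacing = 1.0, role = "ligand")
  idx <- as.matrix(expand.grid(i = seq_len(g$dims[1]),
                               j = seq_len(g$dims[2]),
                               k = seq_len(g$dims[3])))
  centers <- sweep((idx - 1) * g$spacing, 2, g$origin, "+")
  base_cells <- round(sweep(xyz, 2, g$origin) / g$spacing) + 1
  occ_oracle <- apply(cbind(idx, centers), 1, function(row) {
    ct <- row[4:6]
    any(sqrt(colSums((t(xyz) - ct)^2)) <= s$radius) ||
      any(base_cells[, 1] == row[1] & base_cells[, 2] == row[2] &
            base_cells[, 3] == row[3])
  })
  expect_equal(as.vector(g$values[idx] != 0), as.vector(occ_oracle))
})

test_that("receptor grids have a penalized interior inside a surface layer", {
  # a solid 5x5x5 block of overlapping atoms has a proper interior
  lat <- as.matrix(expand.grid(x = 0:4, y = 0:4, z = 0:4)) * 1.5
  s <- point_residues(lat)
  g <- discretize(s, spacing = 1.5, role = "receptor")
  expect_true(any(g$values == -15))
  expect_true(any(g$values == 1))
  expect_true(all(g$values %in% c(-15, 0, 1)))
})

test_that("discretization degenerate inputs raise errors", {
  s <- point_residues(matrix(c(0, 0, 0), ncol = 3))
  expect_error(discretize(s, spacing = 0), "spacing")
  expect_error(discretize(s, spacing = 0.01, max_cells = 100), "spacing")
  expect_error(structure_model(tibble::tibble(
    chain = character(), resno = integer(), resname = character(),
    atom = character(), element = character(), x = numeric(),
    y = numeric(), z = numeric())), "no atoms")
})

test_that("FFT and direct-space correlation agree exactly on small grids", {
  set.seed(5)
  for (n in c(4, 8, 16)) {
    r <- array(sample(c(0, 0, 1, -15), n^3, replace = TRUE), dim = rep(n, 3))
    l <- array(sample(c(0, 1), n^3, replace = TRUE), dim = rep(n, 3))
    cf <- correlate_grids(grid_from(r), grid_from(l), method = "fft")
    cd <- correlate_grids(grid_from(r), grid_from(l), method = "direct")
    expect_equal(round(cf, 6), cd, tolerance = 1e-9)
  }
})

test_that("complementary rigid bodies dock at the designed offset", {
  # a block with a pocket, and a peg built at its bound position in the
  # pocket: the designed translation is zero
  full <- as.matrix(expand.grid(i = 0:4, j = 0:4, k = 0:3))
  pocket <- full[, 1] == 2 & full[, 2] == 2 & full[, 3] >= 2
  receptor <- point_residues(full[!pocket, , drop = FALSE] * 3.5)
  ligand <- point_residues(full[pocket, , drop = FALSE] * 3.5, chain = "B")
  run <- generate_poses(receptor, ligand, n_rotations = 1, spacing = 1.0,
                        n_keep = 50, seed = 1)
  top <- run$poses[1, ]
  expect_lte(max(abs(c(top$tx, top$ty, top$tz))), 1.0 + 1e-9)
})

test_that("a single-atom ligand lands adjacent to the receptor surface", {
  rec <- point_residues(matrix(c(0, 0, 0), ncol = 3))
  lig <- point_residues(matrix(c(0, 0, 0), ncol = 3), chain = "B")
  run <- generate_poses(rec, lig, n_rotations = 1, spacing = 1.0,
                        n_keep = 10, seed = 1)
  top <- run$poses[1, ]
  d <- sqrt(top$tx^2 + top$ty^2 + top$tz^2)
  expect_gt(d, 1.5) # outside the penalized envelope
  expect_lt(d, 4.0) # in contact with the surface shell
})

test_that("electrostatics follows the capped distance-dependent dielectric", {
  rec <- point_residues(matrix(c(0, 0, 0), ncol = 3), charge = 1)
  lig <- point_residues(matrix(c(4, 0, 0), ncol = 3), chain = "B",
                        charge = -1)
  pose0 <- list(rotation = diag(3), translation = c(0, 0, 0))
  sc <- score_pose(rec, lig, pose0, energy_params(elec_cap = Inf))
  expect_equal(sc$electrostatics, 332 * (1) * (-1) / (4 * 4 * 4))
  # default cap clamps the same pair to -1
  sc_cap <- score_pose(rec, lig, pose0, energy_params())
  expect_equal(sc_cap$electrostatics, -1)
})

test_that("an infinitely separated pose has zero energy", {
  rec <- point_residues(matrix(c(0, 0, 0), ncol = 3), charge = 1)
  lig <- point_residues(matrix(c(0, 0, 0), ncol = 3), chain = "B",
                        charge = -1)
  sc <- score_pose(rec, lig, list(rotation = diag(3),
                                  translation = c(1e6, 0, 0)))
  expect_equal(sc$electrostatics, 0)
  expect_equal(sc$van_der_waals, 0)
  expect_equal(sc$desolvation, 0)
  expect_equal(sc$total, 0)
})

test_that("clashing pairs contribute the configured vdW cap", {
  rec <- point_residues(matrix(c(0, 0, 0), ncol = 3))
  lig <- point_residues(matrix(c(0.5, 0, 0), ncol = 3), chain = "B")
  p <- energy_params(vdw_cap = 2.5)
  sc <- score_pose(rec, lig, list(rotation = diag(3),
                                  translation = c(0, 0, 0)), p)
  expect_equal(sc$van_der_waals, 2.5)
})

test_that("scores are invariant under a joint rigid transform", {
  toy <- make_toy_complex(12, 3, seed = 6)
  pose <- list(rotation = diag(3), translation = c(1, 2, -1))
  base <- score_pose(toy$receptor, toy$ligand, pose)

  th <- 1.1
  q_rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                  3, byrow = TRUE)
  u <- c(5, -3, 2)
  rec2 <- transform_structure(toy$receptor, q_rot, u)
  lig2 <- transform_structure(toy$ligand, q_rot, u)
  c_r <- colMeans(cbind(toy$receptor$x, toy$receptor$y, toy$receptor$z))
  c_l <- colMeans(cbind(toy$ligand$x, toy$ligand$y, toy$ligand$z))
  pose2 <- list(rotation = q_rot %*% pose$rotation %*% t(q_rot),
                translation = as.vector(q_rot %*% pose$translation +
                                          (q_rot - diag(3)) %*% (c_l - c_r)))
  moved <- score_pose(rec2, lig2, pose2)
  expect_equal(moved$total, base$total, tolerance = 1e-8)
  expect_equal(moved$electrostatics, base$electrostatics, tolerance = 1e-8)
})

test_that("select_lowest keeps the k smallest energies with fixed tie-break", {
  st <- small_toy_run()
  run <- st$run
  # explicit 3-pose example
  mini <- run
  mini$poses <- run$poses[1:3, ]
  mini$poses$total <- c(-5, -7, -1)
  sel <- select_lowest(mini, 2)
  expect_equal(sel$poses$total, c(-7, -5))
  # all-equal energies: first two by (shape desc, pose_id)
  mini$poses$total <- c(0, 0, 0)
  mini$poses$shape_score <- c(3, 9, 9)
  mini$poses$pose_id <- 1:3
  sel <- select_lowest(mini, 2)
  expect_equal(sel$poses$pose_id, c(2, 3))
  # full-sort oracle on many random energies
  big <- run
  set.seed(12)
  big$poses$total <- runif(nrow(big$poses))
  sel <- select_lowest(big, 100)
  expect_equal(sel$poses$total, sort(big$poses$total)[1:100])
  # subset + monotone within output
  expect_true(all(sel$poses$pose_id %in% big$poses$pose_id))
  expect_true(all(diff(sel$poses$total) >= 0))
  expect_warning(select_lowest(mini, 10), "only")
})

test_that("stored totals equal the weighted component sum", {
  st <- small_toy_run()
  w <- st$run$params$energy$weights
  recomputed <- w[["electrostatics"]] * st$run$poses$electrostatics +
    w[["desolvation"]] * st$run$poses$desolvation +
    w[["vdw"]] * st$run$poses$van_der_waals
  expect_equal(st$run$poses$total, recomputed, tolerance = 1e-12)
})

test_that("docking runs are reproducible and serializable", {
  st <- small_toy_run()
  run2 <- dock_pair(st$toy$receptor, st$toy$ligand, n_rotations = 60,
                    spacing = 2.0, n_keep = 1500, seed = 7)
  expect_equal(st$run$poses, run2$poses)
  dir <- withr::local_tempdir()
  write_docking_run(st$run, dir)
  expect_true(file.exists(file.path(dir, "poses.tsv")))
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  expect_equal(manifest$seed, 7)
  expect_equal(manifest$spacing, 2.0)
})
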