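test_that("8-6 Lennard-Jones term matches its closed form", {
  # minimum at contact distance with depth -eps
  expect_equal(vdw_pair_energy(1.5, 1.5, 0.1, 0.1, 3.0), -0.1)
  # zero crossing at sqrt(3)/2 * (r_i + r_j)
  expect_equal(vdw_pair_energy(1.5, 1.5, 0.1, 0.1, sqrt(3) / 2 * 3), 0,
               tolerance = 1e-12)
  # steep repulsion at half contact distance: x = 2 gives 512 * eps
  expect_equal(vdw_pair_energy(1.5, 1.5, 0.1, 0.1, 1.5), 51.2)
  # Berthelot combination: geometric mean of the well depths
  expect_equal(vdw_pair_energy(1, 2, 0.04, 0.25, 3.0), -sqrt(0.04 * 0.25))
})

test_that("LJ shape invariants hold across a parameter sweep", {
  set.seed(5)
  for (k in 1:20) {
    r1 <- runif(1, 0.8, 2.5); r2 <- runif(1, 0.8, 2.5)
    e1 <- runif(1, 0.01, 0.4); e2 <- runif(1, 0.01, 0.4)
    sigma <- r1 + r2
    eps <- sqrt(e1 * e2)
    d <- seq(0.4 * sigma, 4 * sigma, length.out = 1000)
    E <- vdw_pair_energy(r1, r2, e1, e2, d)
    # unique minimum at contact, depth -eps
    expect_lt(abs(d[which.min(E)] - sigma), diff(d)[1])
    expect_lt(abs(vdw_pair_energy(r1, r2, e1, e2, sigma) + eps) / eps, 1e-9)
    # sign: positive below the zero crossing, negative above
    expect_true(all(E[d < sqrt(3) / 2 * sigma - 1e-9] > 0))
    expect_true(all(E[d > sqrt(3) / 2 * sigma + 1e-9] < 0))
    # monotone decay back to zero beyond the minimum
    tail_E <- E[d > sigma]
    expect_true(all(diff(tail_E) > 0))
    expect_lt(abs(tail_E[length(tail_E)]), eps)
  }
})

test_that("Coulomb term reproduces the printed constants and scalings", {
  expect_equal(coulomb_pair_energy(1, 1, 1), 332.0522 / 20, tolerance = 1e-12)
  expect_equal(coulomb_pair_energy(1, -1, 2), -8.301305, tolerance = 1e-9)
  expect_equal(coulomb_pair_energy(0, 0.7, 2.5), 0)
  # proportional to 1/d and to the charge product
  d <- c(1, 2, 4, 8)
  expect_equal(coulomb_pair_energy(1, 1, d) * d, rep(332.0522 / 20, 4))
  expect_equal(coulomb_pair_energy(0.3, -0.5, 2),
               0.3 * -0.5 * coulomb_pair_energy(1, 1, 2))
  # dividing the dielectric by k multiplies the energy by k
  p5 <- scoring_params(dielectric = 5)
  expect_equal(coulomb_pair_energy(1, 1, 2, p5),
               4 * coulomb_pair_energy(1, 1, 2))
})

test_that("pair_energy adds both terms inside the cutoff and is zero beyond", {
  p <- scoring_params()
  ai <- list(charge = 0.4, radius = 1.6, well_depth = 0.12)
  aj <- list(charge = -0.8, radius = 1.5, well_depth = 0.2)
  for (d in c(0.5, 2.9, 7.3, 11.99)) {
    dc <- max(d, p$min_distance)
    expect_equal(pair_energy(ai, aj, d, p),
                 coulomb_pair_energy(ai$charge, aj$charge, dc, p) +
                   vdw_pair_energy(ai$radius, aj$radius, ai$well_depth,
                                   aj$well_depth, dc),
                 tolerance = 1e-12)
  }
  expect_identical(pair_energy(ai, aj, 12.001, p), 0)
  expect_identical(pair_energy(ai, aj, 13, p), 0)
  # zero charges: pure vdW
  a0 <- list(charge = 0, radius = 1.5, well_depth = 0.1)
  expect_equal(pair_energy(a0, a0, 3.0, p),
               vdw_pair_energy(1.5, 1.5, 0.1, 0.1, 3.0))
})

test_that("cell grid 27-cell query is a superset of all in-range points", {
  # two points 11.9 apart see each other; 40 apart do not
  pts <- rbind(c(0, 0, 0), c(11.9, 0, 0))
  g <- build_cell_grid(pts, 12)
  expect_setequal(grid_query(g, pts[1, ]), c(1L, 2L))
  expect_setequal(grid_query(g, pts[2, ]), c(1L, 2L))
  far <- rbind(c(0, 0, 0), c(40, 0, 0))
  gf <- build_cell_grid(far, 12)
  expect_equal(grid_query(gf, far[1, ]), 1L)
  expect_equal(grid_query(gf, far[2, ]), 2L)
  # single point, query at its own location
  g1 <- build_cell_grid(matrix(c(0, 0, 0), ncol = 3), 12)
  expect_equal(grid_query(g1, c(0, 0, 0)), 1L)
  # random clouds: every in-range neighbor is retrieved, each point binned once
  set.seed(8)
  for (k in 1:10) {
    cloud <- matrix(runif(300, -30, 30), ncol = 3)
    cs <- runif(1, 5, 15)
    g <- build_cell_grid(cloud, cs)
    expect_equal(sum(lengths(g$cells)), nrow(cloud))
    probe <- runif(3, -30, 30)
    got <- grid_query(g, probe)
    d <- sqrt(colSums((t(cloud) - probe)^2))
    expect_true(all(which(d <= cs) %in% got))
  }
})

test_that("accelerated intermolecular energy matches brute force and is symmetric", {
  set.seed(21)
  a <- random_mol("a", 200, extent = 18)
  b <- random_mol("b", 300, extent = 18)
  sc <- scene(list(a, b), list(
    rigid_transform(),
    rigid_transform(quat_from_axis_angle_test(rnorm(3), runif(1)), c(8, 2, -3))
  ))
  p <- scoring_params()
  acc <- scene_score(sc, p)$total
  ref <- brute_force_scene_score(sc, p)
  expect_lt(abs(acc - ref) / abs(ref), 1e-9)
  eab <- intermolecular_energy(sc$entries[[1]], sc$entries[[2]], p)
  eba <- intermolecular_energy(sc$entries[[2]], sc$entries[[1]], p)
  expect_lt(abs(eab$energy - eba$energy) / abs(eab$energy), 1e-9)
  expect_equal(eab$energy, eab$vdw + eab$coulomb)
  # separated molecules score exactly zero
  far <- scene(list(a, b), list(rigid_transform(),
                                rigid_transform(translation = c(100, 0, 0))))
  expect_identical(scene_score(far, p)$total, 0)
  # single-pair scene equals pair_energy
  d <- make_diatomic_scene(separation = 2.2)
  expect_equal(scene_score(d$scene, p)$total,
               pair_energy(list(charge = 0, radius = 1.5, well_depth = 0.1),
                           list(charge = 0, radius = 1.5, well_depth = 0.1),
                           2.2, p))
  expect_error(intermolecular_energy(parse_mol2(d$mol2[["A"]]),
                                     parse_mol2(d$mol2[["B"]]), p),
               "parameterized")
})

test_that("scene score is pairwise additive and excludes intramolecular terms", {
  set.seed(31)
  mols <- lapply(1:3, function(i) random_mol(paste0("m", i), 40))
  tfs <- list(rigid_transform(),
              rigid_transform(translation = c(6, 0, 0)),
              rigid_transform(translation = c(0, 7, 0)))
  sc <- scene(mols, tfs)
  p <- scoring_params()
  bd <- scene_score(sc, p)
  pair_sum <- 0
  for (ij in list(c(1, 2), c(1, 3), c(2, 3))) {
    pair_sum <- pair_sum + intermolecular_energy(
      sc$entries[[ij[1]]], sc$entries[[ij[2]]], p)$energy
  }
  expect_lt(abs(bd$total - pair_sum) / abs(pair_sum), 1e-12)
  expect_lt(abs(bd$total - sum(bd$per_pair$energy)) / abs(bd$total), 1e-9)
  expect_lt(abs(bd$total - (bd$vdw_total + bd$coulomb_total)) / abs(bd$total), 1e-9)
  expect_equal(nrow(bd$per_pair), 3L)
  # single molecule scene scores zero
  expect_identical(scene_score(scene(mols[1]), p)$total, 0)
})

test_that("scene score is invariant under a global rigid motion", {
  set.seed(41)
  sc <- make_random_scene(3, 60, box = 18, seed = 41)
  p <- scoring_params()
  ref <- scene_score(sc, p)$total
  for (k in 1:5) {
    g <- random_rigid_transform()
    moved <- sc
    for (id in scene_ids(sc)) {
      moved$entries[[id]]$transform <-
        compose_transforms(g, sc$entries[[id]]$transform)
    }
    expect_lt(abs(scene_score(moved, p)$total - ref) / abs(ref), 1e-6)
  }
})

test_that("scoring parameter validation rejects nonphysical settings", {
  expect_error(scoring_params(cutoff = -1))
  expect_error(scoring_params(dielectric = 0))
  expect_error(scoring_params(min_distance = 1.5))
})
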