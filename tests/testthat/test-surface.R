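test_that("adaptive cell size follows the extents rule with clamps", {
  expect_equal(adaptive_cell_size(c(30, 30, 30)), 0.3)
  expect_equal(adaptive_cell_size(c(60, 45, 30)), 0.45)
  # raw value 0.1 clamps up to the floor
  expect_equal(adaptive_cell_size(c(10, 10, 10)), 0.2)
  # degenerate box clamps to the floor
  expect_equal(adaptive_cell_size(c(0, 0, 0)), 0.2)
  # huge complexes clamp at the ceiling
  expect_equal(adaptive_cell_size(c(300, 300, 300)), 1.5)
  expect_equal(adaptive_cell_size(c(30, 30, 30), min_spacing = 0.5), 0.5)
})

test_that("SES field is negative at atom centers, positive outside, zero near the atom sphere", {
  mol <- one_atom_mol(r = 1.7)
  f <- build_ses_field(mol, probe = 1.4, spacing = 0.2)
  at_center <- function(field, p) {
    idx <- round((p - field$origin) / field$spacing) + 1
    field$values[idx[1], idx[2], idx[3]]
  }
  expect_lt(at_center(f, c(0, 0, 0)), 0)
  # corner of the padded box is far outside
  expect_gt(f$values[1, 1, 1], 0)
  # the zero level set sits near the atom sphere (radius 1.7), not the
  # probe-expanded sphere (3.1): sign flips between 1.6 and 1.8 A
  expect_lt(at_center(f, c(1.6, 0, 0)), 0)
  expect_gt(at_center(f, c(1.8, 0, 0)), 0)
  expect_gt(at_center(f, c(2.6, 0, 0)), 0)
  expect_lt(at_center(f, c(1.2, 0, 0)), 0)
  expect_error(build_ses_field(one_atom_mol(), probe = -1), "probe")
})

test_that("mesh extraction reproduces an analytic sphere within 3% area", {
  f <- sphere_field(R = 2, h = 0.2)
  mesh <- extract_mesh(f, 0)
  true_area <- 4 * pi * 4
  expect_lt(abs(mesh_area(mesh) - true_area) / true_area, 0.03)
  # closed: every edge shared by exactly 2 triangles; sphere topology
  expect_true(mesh_is_closed(mesh))
  expect_equal(mesh_euler(mesh), 2L)
  expect_equal(mesh_components(mesh), 1L)
  # outward orientation: positive enclosed volume near 4/3 pi R^3
  expect_gt(mesh_volume(mesh), 0)
  expect_lt(abs(mesh_volume(mesh) - 4 / 3 * pi * 8) / (4 / 3 * pi * 8), 0.05)
  # constant-positive field has no level set
  f$values[] <- 1
  expect_equal(nrow(extract_mesh(f, 0)$triangles), 0L)
})

test_that("single-atom SES area approaches 4*pi*r^2 and improves with resolution", {
  mol <- one_atom_mol(r = 1.7)
  true_area <- 4 * pi * 1.7^2
  errs <- vapply(c(0.4, 0.2), function(h) {
    mesh <- extract_mesh(build_ses_field(mol, probe = 1.4, spacing = h), 0)
    expect_true(mesh_is_closed(mesh))
    abs(mesh_area(mesh) - true_area) / true_area
  }, numeric(1))
  expect_lt(errs[1], 0.05)
  expect_lt(errs[2], errs[1])
})

test_that("SES component count distinguishes separated from fused atoms", {
  far <- two_atom_mol(20)
  mesh_far <- extract_mesh(build_ses_field(far, 1.4, 0.3), 0)
  expect_equal(mesh_components(mesh_far), 2L)
  fused <- two_atom_mol(1)
  mesh_fused <- extract_mesh(build_ses_field(fused, 1.4, 0.3), 0)
  expect_equal(mesh_components(mesh_fused), 1L)
  expect_true(mesh_is_closed(mesh_fused))
})

test_that("full SES pipeline encloses the atoms and carries charges", {
  mol <- two_atom_mol(2.5, q = c(1, -1))
  mesh <- build_ses_mesh(mol, probe = 1.4, spacing = 0.25)
  expect_true(mesh_is_closed(mesh))
  # both atom centers inside the mesh bounding box with margin
  lo <- apply(mesh$vertices, 2, min); hi <- apply(mesh$vertices, 2, max)
  expect_true(all(lo < -1) && all(hi > 1))
  # charge gradient along the axis: positive pole near atom 1, negative near 2
  xpos <- mesh$vertices[, 1]
  expect_gt(mesh$vertex_charge[which.min(xpos)], 0)
  expect_lt(mesh$vertex_charge[which.max(xpos)], 0)
  # triangle charge is the mean of its vertex charges
  tri <- mesh$triangles
  expect_lt(max(abs(mesh$triangle_charge -
                      (mesh$vertex_charge[tri[, 1]] + mesh$vertex_charge[tri[, 2]] +
                         mesh$vertex_charge[tri[, 3]]) / 3)), 1e-12)
})

test_that("charge mapping handles uniform and zero charge fields", {
  mol <- one_atom_mol(q = -1)
  mesh <- build_ses_mesh(mol, probe = 1.4, spacing = 0.3)
  expect_lt(max(abs(mesh$vertex_charge + 1)), 1e-9)
  expect_lt(max(abs(mesh$triangle_charge + 1)), 1e-9)
  # all-red coloring at the negative saturation point
  expect_true(all(abs(mesh$vertex_color - rep(c(1, 0, 0), each = nrow(mesh$vertex_color))) < 1e-9))
  zero <- one_atom_mol(q = 0)
  mz <- build_ses_mesh(zero, probe = 1.4, spacing = 0.3)
  expect_true(all(mz$vertex_charge == 0))
  expect_true(all(mz$vertex_color == 1))
})

test_that("charge-to-color anchors and interpolation are correct", {
  expect_equal(charge_to_color(0, 1)[1, ], c(r = 1, g = 1, b = 1))
  expect_equal(charge_to_color(-1, 1)[1, ], c(r = 1, g = 0, b = 0))
  expect_equal(charge_to_color(1, 1)[1, ], c(r = 0, g = 0, b = 1))
  expect_equal(charge_to_color(0.5, 1)[1, ], c(r = 0.5, g = 0.5, b = 1))
  expect_equal(charge_to_color(-0.25, 0.5)[1, ], c(r = 1, g = 0.5, b = 0.5))
  # clamping beyond the saturation magnitude
  expect_equal(charge_to_color(-7, 1)[1, ], c(r = 1, g = 0, b = 0))
  expect_equal(charge_to_color(7, 1)[1, ], c(r = 0, g = 0, b = 1))
})

test_that("PLY round-trip preserves geometry, charges and colors", {
  mol <- two_atom_mol(2.5, q = c(0.8, -0.6))
  mesh <- build_ses_mesh(mol, probe = 1.4, spacing = 0.3)
  path <- withr::local_tempfile(fileext = ".ply")
  write_ply(mesh, path)
  back <- read_ply(path)
  expect_equal(nrow(back$vertices), nrow(mesh$vertices))
  expect_equal(back$triangles, mesh$triangles)
  expect_lt(max(abs(back$vertices - mesh$vertices)), 1e-5)
  expect_lt(max(abs(back$vertex_charge - mesh$vertex_charge)), 1e-5)
  expect_lt(max(abs(back$vertex_color - mesh$vertex_color)), 1 / 255)
  # triangle charge rebuilt as the mean of vertex charges
  tri <- back$triangles
  expect_lt(max(abs(back$triangle_charge -
                      (back$vertex_charge[tri[, 1]] + back$vertex_charge[tri[, 2]] +
                         back$vertex_charge[tri[, 3]]) / 3)), 1e-12)
  # OBJ writer emits one v line per vertex and one f line per triangle
  obj <- withr::local_tempfile(fileext = ".obj")
  write_obj(mesh, obj)
  lines <- readLines(obj)
  expect_equal(sum(grepl("^v ", lines)), nrow(mesh$vertices))
  expect_equal(sum(grepl("^f ", lines)), nrow(mesh$triangles))
})
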