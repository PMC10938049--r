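# Fixtures are generated in code; nothing is read from disk.

# A single parameterized atom as a one-molecule fixture.
one_atom_mol <- function(id = "one", r = 1.7, eps = 0.086, q = 0,
                         pos = c(0, 0, 0), element = "C") {
  molecule(id, data.frame(
    serial = 1L, name = element, element = element,
    x = pos[1], y = pos[2], z = pos[3],
    charge = q, radius = r, well_depth = eps,
    stringsAsFactors = FALSE
  ))
}

# Two-atom molecule along x with given separation and charges.
two_atom_mol <- function(sep, q = c(1, -1), r = 1.7, id = "two") {
  molecule(id, data.frame(
    serial = 1:2, name = c("C1", "C2"), element = "C",
    x = c(0, sep), y = 0, z = 0, charge = q,
    radius = r, well_depth = 0.086, stringsAsFactors = FALSE
  ))
}

# Random parameterized molecule (drawn from the current RNG stream).
random_mol <- function(id, n, extent = 10) {
  elements <- sample(c("C", "N", "O", "S", "H", "P"), n, replace = TRUE)
  pars <- lookup_parameters(default_parameter_table(), elements)
  molecule(id, data.frame(
    serial = seq_len(n), name = paste0(elements, seq_len(n)),
    element = elements,
    x = runif(n, -extent / 2, extent / 2),
    y = runif(n, -extent / 2, extent / 2),
    z = runif(n, -extent / 2, extent / 2),
    charge = runif(n, -1, 1),
    radius = pars$radius, well_depth = pars$well_depth,
    stringsAsFactors = FALSE
  ))
}

# Voxel field of an analytic sphere |p| - R on [-ext, ext]^3.
sphere_field <- function(R = 2, h = 0.2, ext = R + 1) {
  ax <- seq(-ext, ext, by = h)
  n <- length(ax)
  g <- expand.grid(x = ax, y = ax, z = ax)
  structure(list(
    origin = rep(-ext, 3), spacing = h, dims = c(n, n, n),
    values = array(sqrt(g$x^2 + g$y^2 + g$z^2) - R, c(n, n, n))
  ), class = "voxel_field")
}

random_rigid_transform <- function() {
  rigid_transform(
    quat_from_axis_angle_test(rnorm(3), runif(1, 0, 2 * pi)),
    runif(3, -10, 10)
  )
}

# Local copy of axis-angle -> quaternion so tests do not rely on package
# internals.
quat_from_axis_angle_test <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}
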