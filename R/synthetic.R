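# Deterministic synthetic fixtures: everything any test needs is
# generated in code, no downloads, fully determined by the seed.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

single_atom_molecule <- function(id, radius, well_depth, charge,
                                 position = c(0, 0, 0), element = "C") {
  molecule(id, data.frame(
    serial = 1L, name = element, element = element,
    x = position[1L], y = position[2L], z = position[3L],
    charge = charge, radius = radius, well_depth = well_depth,
    stringsAsFactors = FALSE
  ))
}

#' Diatomic two-body toy scene
#'
#' Two single-atom molecules `A` (at the origin) and `B` (posed at
#' `separation` along x). With both well depths equal to `eps` and zero
#' charges the scene score is the bare 8-6 Lennard-Jones pair term, with
#' its known minimum `-eps` at `separation = r1 + r2` -- the closed-form
#' anchor used to validate scoring and the pose optimizer.
#'
#' @param r1,r2 Atom radii, Angstrom.
#' @param eps Well depth of both atoms, kcal/mol.
#' @param q1,q2 Partial charges, elementary charge units.
#' @param separation Distance between the atoms, Angstrom.
#' @return A list: `scene` (a [scene()]), `mol2` (named character vector
#'   of the two molecules' mol2 documents).
#' @export
make_diatomic_scene <- function(r1 = 1.5, r2 = 1.5, eps = 0.1,
                                q1 = 0, q2 = 0, separation = 3) {
  stopifnot(separation > 0)
  a <- single_atom_molecule("A", r1, eps, q1)
  b <- single_atom_molecule("B", r2, eps, q2)
  sc <- scene(list(a, b), list(
    rigid_transform(),
    rigid_transform(translation = c(separation, 0, 0))
  ))
  list(
    scene = sc,
    mol2 = c(A = paste(write_mol2(a), collapse = "\n"),
             B = paste(write_mol2(b), collapse = "\n"))
  )
}

random_molecule <- function(id, n_atoms, extent = 10,
                            table = default_parameter_table()) {
  elements <- sample(c("C", "N", "O", "S", "H", "P"), n_atoms, replace = TRUE)
  atoms <- data.frame(
    serial = seq_len(n_atoms),
    name = paste0(elements, seq_len(n_atoms)),
    element = elements,
    x = stats::runif(n_atoms, -extent / 2, extent / 2),
    y = stats::runif(n_atoms, -extent / 2, extent / 2),
    z = stats::runif(n_atoms, -extent / 2, extent / 2),
    charge = stats::runif(n_atoms, -1, 1),
    stringsAsFactors = FALSE
  )
  assign_parameters(molecule(id, atoms), table)
}

#' Random multi-body scene
#'
#' `n_molecules` random atom clouds (elements drawn from C/N/O/S/H/P
#' with packaged parameters, charges uniform in [-1, 1] e, coordinates
#' uniform in a per-molecule cube of edge `molecule_extent`), each posed
#' with a random rotation and a random translation inside a cube of edge
#' `box`. Fully reproducible from `seed`.
#'
#' @param n_molecules Number of molecules (>= 1).
#' @param atoms_per_molecule Atom count per molecule (scalar or vector).
#' @param box Scene cube edge for molecule centers, Angstrom.
#' @param seed Integer seed.
#' @param molecule_extent Per-molecule cloud cube edge, Angstrom.
#' @return A parameterized [scene()].
#' @export
make_random_scene <- function(n_molecules = 3, atoms_per_molecule = 100,
                              box = 30, seed = 1, molecule_extent = 10) {
  stopifnot(n_molecules >= 1)
  atoms_per_molecule <- rep_len(atoms_per_molecule, n_molecules)
  with_seed(seed, {
    mols <- lapply(seq_len(n_molecules), function(i) {
      random_molecule(sprintf("mol%d", i), atoms_per_molecule[i],
                      extent = molecule_extent)
    })
    transforms <- lapply(seq_len(n_molecules), function(i) {
      axis <- stats::rnorm(3L)
      angle <- stats::runif(1L, 0, 2 * pi)
      rigid_transform(quat_from_axis_angle(axis, angle),
                      stats::runif(3L, -box / 2, box / 2))
    })
    scene(mols, transforms)
  })
}

#' Write a molecule as a minimal mol2 fixture
#'
#' Emits a valid mol2 document (MOLECULE + ATOM sections with the charge
#' column) that [parse_mol2()] reads back without loss.
#'
#' @param mol A [molecule()].
#' @param path Output path, or `NULL` to return the document lines.
#' @return `path` invisibly, or the mol2 lines.
#' @export
write_fixture_mol2 <- function(mol, path = NULL) write_mol2(mol, path)

#' Generate a named fixture
#'
#' Convenience dispatcher used by the command line: `"diatomic"` (two
#' single-atom molecules at the Lennard-Jones contact distance),
#' `"random_cloud"` (one random molecule), `"two_body"` (two random
#' molecules 15 A apart).
#'
#' @param kind One of `"diatomic"`, `"random_cloud"`, `"two_body"`.
#' @param seed Integer seed.
#' @param n_atoms Atom count for random kinds.
#' @return A list of [molecule()]s in world coordinates.
#' @export
make_fixture <- function(kind = c("diatomic", "random_cloud", "two_body"),
                         seed = 1, n_atoms = 25) {
  kind <- match.arg(kind)
  with_seed(seed, switch(kind,
    diatomic = {
      d <- make_diatomic_scene()
      lapply(d$scene$entries, function(e) {
        m <- e$molecule
        coords <- apply_transform(atom_coords(m), e$transform)
        m$atoms$x <- coords[, 1L]; m$atoms$y <- coords[, 2L]; m$atoms$z <- coords[, 3L]
        m
      })
    },
    random_cloud = list(random_molecule("cloud", n_atoms)),
    two_body = {
      a <- random_molecule("recA", n_atoms)
      b <- random_molecule("recB", n_atoms)
      b$atoms$x <- b$atoms$x + 15
      list(a, b)
    }
  ))
}
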