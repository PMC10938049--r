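#' Scoring parameters
#'
#' Parameters of the binding score: an 8-6 Lennard-Jones van der Waals
#' term plus Coulomb electrostatics damped by a dielectric constant, both
#' truncated at a hard distance cutoff. Energies are in kcal/mol
#' throughout; `coulomb_constant` is the conversion factor
#' 332.0522 kcal.A/(mol.e^2) that expresses a Coulomb energy between
#' elementary charges at Angstrom separations in kcal/mol.
#'
#' @param cutoff Interaction cutoff, Angstrom. Pairs farther apart
#'   contribute exactly zero. Default 12.
#' @param dielectric Dielectric constant damping the Coulomb term.
#'   Default 20.
#' @param min_distance Clamp floor for interatomic distances, Angstrom
#'   (must lie in (0, 1)). Keeps clashing poses finite in place of the
#'   collision handling an interactive front-end would provide.
#' @param coulomb_constant Units conversion factor, kcal.A/(mol.e^2).
#' @return An object of class `scoring_params`.
#' @export
scoring_params <- function(cutoff = 12, dielectric = 20, min_distance = 0.1,
                           coulomb_constant = 332.0522) {
  stopifnot(cutoff > 0, dielectric > 0, min_distance > 0, min_distance < 1,
            coulomb_constant > 0)
  structure(list(cutoff = cutoff, dielectric = dielectric,
                 min_distance = min_distance,
                 coulomb_constant = coulomb_constant),
            class = "scoring_params")
}

#' 8-6 Lennard-Jones pair energy
#'
#' Soft van der Waals interaction `3*eps*x^8 - 4*eps*x^6` with
#' `x = (r_i + r_j)/d_ij` and `eps = sqrt(eps_i * eps_j)` (Berthelot's
#' geometric-mean combination). The minimum sits at contact,
#' `d = r_i + r_j`, with depth `-eps`; the term crosses zero at
#' `d = sqrt(3)/2 * (r_i + r_j)` and decays to zero at long range.
#' All arguments are vectorized.
#'
#' @param r_i,r_j Atom radii, Angstrom.
#' @param eps_i,eps_j Atom well depths, kcal/mol.
#' @param d_ij Interatomic distance, Angstrom (caller clamps to the
#'   minimum distance).
#' @return Energy, kcal/mol.
#' @export
vdw_pair_energy <- function(r_i, r_j, eps_i, eps_j, d_ij) {
  eps <- sqrt(eps_i * eps_j)
  x2 <- ((r_i + r_j) / d_ij)^2
  x6 <- x2 * x2 * x2
  eps * x6 * (3 * x2 - 4)
}

#' Coulomb pair energy with constant dielectric
#'
#' `coulomb_constant * c_i * c_j / (dielectric * d_ij)`, kcal/mol.
#' Vectorized.
#'
#' @param c_i,c_j Partial charges, elementary charge units.
#' @param d_ij Interatomic distance, Angstrom.
#' @param params A [scoring_params()].
#' @return Energy, kcal/mol.
#' @export
coulomb_pair_energy <- function(c_i, c_j, d_ij, params = scoring_params()) {
  params$coulomb_constant * c_i * c_j / (params$dielectric * d_ij)
}

#' Total pair energy of two parameterized atoms
#'
#' Sum of the Coulomb and 8-6 Lennard-Jones terms when `d_ij` is within
#' the cutoff; exactly zero beyond it. The distance is clamped below at
#' `params$min_distance` (the cutoff test uses the unclamped distance).
#'
#' @param atom_i,atom_j Single-atom records (lists or one-row data
#'   frames) with fields `radius`, `well_depth`, `charge`.
#' @param d_ij Interatomic distance, Angstrom.
#' @param params A [scoring_params()].
#' @return Energy, kcal/mol.
#' @export
pair_energy <- function(atom_i, atom_j, d_ij, params = scoring_params()) {
  if (d_ij > params$cutoff) return(0)
  d <- max(d_ij, params$min_distance)
  coulomb_pair_energy(atom_i$charge, atom_j$charge, d, params) +
    vdw_pair_energy(atom_i$radius, atom_j$radius,
                    atom_i$well_depth, atom_j$well_depth, d)
}

cell_key <- function(ix, iy, iz) paste(ix, iy, iz, sep = "_")

#' Build a uniform cell grid over points
#'
#' Spatial hash with cubic cells of edge `cell_size`: every point is
#' binned into exactly one cell, and all points within `cell_size` of a
#' query location are guaranteed to lie in the 27-cell neighborhood of
#' the query's cell (see [grid_query()]).
#'
#' @param positions Numeric matrix (n x 3), Angstrom.
#' @param cell_size Cell edge, Angstrom; use the interaction cutoff of
#'   the queries the grid will serve.
#' @return An object of class `cell_grid`.
#' @export
build_cell_grid <- function(positions, cell_size) {
  stopifnot(cell_size > 0)
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 3L)
  n <- nrow(positions)
  if (n == 0L) {
    return(structure(list(origin = c(0, 0, 0), cell_size = cell_size,
                          cells = list(), n = 0L), class = "cell_grid"))
  }
  origin <- apply(positions, 2L, min)
  idx <- floor(sweep(positions, 2L, origin, "-") / cell_size)
  keys <- cell_key(idx[, 1L], idx[, 2L], idx[, 3L])
  structure(list(origin = origin, cell_size = cell_size,
                 cells = split(seq_len(n), keys), n = n),
            class = "cell_grid")
}

#' Query the 27-cell neighborhood of a point
#'
#' @param grid A [build_cell_grid()] result.
#' @param point Length-3 location in the grid's frame.
#' @return Integer indices (into the positions the grid was built from)
#'   of all points stored in the query cell and its 26 neighbors -- a
#'   superset of every point within `cell_size` of `point`.
#' @export
grid_query <- function(grid, point) {
  stopifnot(inherits(grid, "cell_grid"), length(point) == 3L)
  if (grid$n == 0L) return(integer(0))
  base <- floor((point - grid$origin) / grid$cell_size)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keys <- cell_key(base[1L] + off[, 1L], base[2L] + off[, 2L], base[3L] + off[, 3L])
  sort(unlist(grid$cells[keys], use.names = FALSE))
}

as_posed <- function(x) {
  if (inherits(x, "molecule")) {
    list(molecule = x, transform = rigid_transform())
  } else if (is.list(x) && !is.null(x$molecule) && !is.null(x$transform)) {
    x
  } else {
    stop("expected a molecule or a scene entry (molecule + transform)")
  }
}

#' Interaction energy between two posed molecules
#'
#' Sums [pair_energy()] over all intermolecular atom pairs within the
#' cutoff, restricting each atom of the first molecule to its
#' neighborhood in the second through a cell grid (cell edge = cutoff,
#' 27-cell stencil). The grid lives in the second molecule's own frame
#' and query points are transformed into that frame, so no grid rebuild
#' is needed when poses change. Symmetric in its arguments up to
#' floating-point summation order.
#'
#' @param mol_a,mol_b Parameterized [molecule()]s (identity pose) or
#'   scene entries carrying a pose.
#' @param params A [scoring_params()].
#' @return A list: `energy` (total, kcal/mol), `vdw`, `coulomb`.
#' @export
intermolecular_energy <- function(mol_a, mol_b, params = scoring_params()) {
  a <- as_posed(mol_a)
  b <- as_posed(mol_b)
  if (!is_parameterized(a$molecule) || !is_parameterized(b$molecule)) {
    stop("molecules must be parameterized (run assign_parameters) before scoring")
  }
  at_a <- a$molecule$atoms
  at_b <- b$molecule$atoms
  # World positions of A, expressed in B's local frame (distances are
  # invariant, and B's grid is built once from its local coordinates).
  world_a <- apply_transform(atom_coords(a$molecule), a$transform)
  probe <- apply_transform(world_a, invert_transform(b$transform))
  local_b <- atom_coords(b$molecule)
  grid <- build_cell_grid(local_b, params$cutoff)

  base <- floor(sweep(probe, 2L, grid$origin, "-") / grid$cell_size)
  groups <- split(seq_len(nrow(probe)),
                  cell_key(base[, 1L], base[, 2L], base[, 3L]))
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  vdw <- 0
  coul <- 0
  for (g in groups) {
    cb <- base[g[1L], ]
    keys <- cell_key(cb[1L] + off[, 1L], cb[2L] + off[, 2L], cb[3L] + off[, 3L])
    cand <- unlist(grid$cells[keys], use.names = FALSE)
    if (length(cand) == 0L) next
    d2 <- outer(rowSums(probe[g, , drop = FALSE]^2),
                rowSums(local_b[cand, , drop = FALSE]^2), "+") -
      2 * probe[g, , drop = FALSE] %*% t(local_b[cand, , drop = FALSE])
    d <- sqrt(pmax(d2, 0))
    within <- which(d <= params$cutoff)
    if (length(within) == 0L) next
    ai <- g[(within - 1L) %% length(g) + 1L]
    bj <- cand[(within - 1L) %/% length(g) + 1L]
    dc <- pmax(d[within], params$min_distance)
    vdw <- vdw + sum(vdw_pair_energy(at_a$radius[ai], at_b$radius[bj],
                                     at_a$well_depth[ai], at_b$well_depth[bj], dc))
    coul <- coul + sum(coulomb_pair_energy(at_a$charge[ai], at_b$charge[bj],
                                           dc, params))
  }
  list(energy = vdw + coul, vdw = vdw, coulomb = coul)
}

#' Score a multi-body scene
#'
#' The binding score of the scene state: [intermolecular_energy()]
#' summed over every unordered molecule pair. Intramolecular terms are
#' excluded (poses are rigid, so they are constant); a single-molecule
#' scene scores zero.
#'
#' @param scene A parameterized [scene()].
#' @param params A [scoring_params()].
#' @return An object of class `score_breakdown`: `total`, `vdw_total`,
#'   `coulomb_total` (kcal/mol) and `per_pair`, a data frame with one row
#'   per molecule pair (`a`, `b`, `vdw`, `coulomb`, `energy`).
#' @export
scene_score <- function(scene, params = scoring_params()) {
  stopifnot(inherits(scene, "scene"))
  ids <- names(scene$entries)
  n <- length(ids)
  rows <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        e <- intermolecular_energy(scene$entries[[i]], scene$entries[[j]], params)
        rows[[length(rows) + 1L]] <- data.frame(
          a = ids[i], b = ids[j], vdw = e$vdw, coulomb = e$coulomb,
          energy = e$energy, stringsAsFactors = FALSE
        )
      }
    }
  }
  per_pair <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(a = character(0), b = character(0), vdw = numeric(0),
               coulomb = numeric(0), energy = numeric(0))
  structure(list(
    total = sum(per_pair$energy),
    vdw_total = sum(per_pair$vdw),
    coulomb_total = sum(per_pair$coulomb),
    per_pair = per_pair
  ), class = "score_breakdown")
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat(sprintf("total:   %12.4f kcal/mol\n", x$total))
  cat(sprintf("vdw:     %12.4f kcal/mol\n", x$vdw_total))
  cat(sprintf("coulomb: %12.4f kcal/mol\n", x$coulomb_total))
  if (nrow(x$per_pair) > 0L) {
    cat("per pair:\n")
    for (k in seq_len(nrow(x$per_pair))) {
      cat(sprintf("  %s : %s  %12.4f kcal/mol\n",
                  x$per_pair$a[k], x$per_pair$b[k], x$per_pair$energy[k]))
    }
  }
  invisible(x)
}

#' Brute-force scene score (verification oracle)
#'
#' Scores the scene with a plain double loop over all intermolecular
#' atom pairs -- no neighbor grid -- applying the identical cutoff and
#' distance clamp. Exists to validate the accelerated path: the two must
#' agree to within floating-point summation error.
#'
#' @param scene A parameterized [scene()].
#' @param params A [scoring_params()].
#' @return Total scene energy, kcal/mol.
#' @export
brute_force_scene_score <- function(scene, params = scoring_params()) {
  stopifnot(inherits(scene, "scene"))
  n <- length(scene$entries)
  if (n < 2L) return(0)
  world <- lapply(scene$entries, function(e) {
    if (!is_parameterized(e$molecule)) {
      stop("molecules must be parameterized before scoring")
    }
    apply_transform(atom_coords(e$molecule), e$transform)
  })
  total <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      ai <- scene$entries[[i]]$molecule$atoms
      aj <- scene$entries[[j]]$molecule$atoms
      pi_ <- world[[i]]
      pj <- world[[j]]
      d2 <- outer(rowSums(pi_^2), rowSums(pj^2), "+") - 2 * pi_ %*% t(pj)
      d <- sqrt(pmax(d2, 0))
      for (k in seq_len(nrow(pi_))) {
        within <- which(d[k, ] <= params$cutoff)
        if (length(within) == 0L) next
        dc <- pmax(d[k, within], params$min_distance)
        total <- total +
          sum(vdw_pair_energy(ai$radius[k], aj$radius[within],
                              ai$well_depth[k], aj$well_depth[within], dc)) +
          sum(coulomb_pair_energy(ai$charge[k], aj$charge[within], dc, params))
      }
    }
  }
  total
}
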