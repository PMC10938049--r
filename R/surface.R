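#' Adaptive voxel spacing from bounding-box extents
#'
#' Empirical resolution rule balancing mesh smoothness against build
#' time: the voxel edge grows with molecule size as
#' `(s_x + s_y + s_z) / 3 * 1e-2` (Angstrom), clamped to
#' `[min_spacing, max_spacing]` so tiny or degenerate boxes still get a
#' usable grid and huge complexes stay tractable.
#'
#' @param bbox_extents Length-3 extents of the atom-center bounding box,
#'   Angstrom.
#' @param min_spacing,max_spacing Clamp bounds, Angstrom.
#' @return Voxel spacing, Angstrom.
#' @export
adaptive_cell_size <- function(bbox_extents, min_spacing = 0.2, max_spacing = 1.5) {
  stopifnot(length(bbox_extents) == 3L, all(bbox_extents >= 0),
            min_spacing > 0, max_spacing >= min_spacing)
  rc <- sum(bbox_extents) / 3 * 1e-2
  min(max(rc, min_spacing), max_spacing)
}

#' Signed voxel field of the Solvent-Excluded Surface
#'
#' Two-pass grid classification of the SES. Pass one marks voxels inside
#' the probe-expanded union of atom spheres (the solvent-accessible
#' interior). Pass two places probe centers on the accessible boundary:
#' boundary voxels are projected radially onto the nearest atom's
#' probe-expanded sphere, and every interior voxel within reach receives
#' the value `probe - distance(nearest probe center)`. The result is
#' negative inside the SES (at an atom center it is at most
#' `-r_atom`), positive in the solvent-carved region and outside, and its
#' zero level set approximates the SES: for an isolated atom of radius
#' `r` the level set is the atom sphere itself, not the expanded one.
#'
#' @param mol A parameterized, posed [molecule()] (coordinates are used
#'   as stored; apply a pose first if needed).
#' @param probe Solvent probe radius, Angstrom (1.4 for water).
#' @param spacing Voxel edge, Angstrom (see [adaptive_cell_size()]).
#' @return An object of class `voxel_field`: `origin`, `spacing`,
#'   `dims`, and a 3-d `values` array. The grid covers the atom-center
#'   bounding box padded by `max(radius) + 2 * probe`.
#' @export
build_ses_field <- function(mol, probe = 1.4, spacing = 0.2) {
  stopifnot(inherits(mol, "molecule"), probe > 0, spacing > 0)
  if (n_atoms(mol) == 0L) stop("cannot build a surface for an empty molecule")
  if (!all(is.finite(mol$atoms$radius))) {
    stop("molecule must be parameterized (atom radii) before surfacing")
  }
  coords <- atom_coords(mol)
  radii <- mol$atoms$radius
  pad <- max(radii) + 2 * probe
  origin <- apply(coords, 2L, min) - pad
  top <- apply(coords, 2L, max) + pad
  dims <- pmax(2L, as.integer(ceiling((top - origin) / spacing)) + 1L)
  axes <- lapply(1:3, function(k) origin[k] + (seq_len(dims[k]) - 1L) * spacing)

  block_range <- function(center, radius) {
    lo <- pmax(1L, as.integer(floor((center - radius - origin) / spacing)) + 1L)
    hi <- pmin(dims, as.integer(ceiling((center + radius - origin) / spacing)) + 1L)
    list(lo = lo, hi = hi)
  }
  local_dist2 <- function(center, rng) {
    dx2 <- (axes[[1L]][rng$lo[1L]:rng$hi[1L]] - center[1L])^2
    dy2 <- (axes[[2L]][rng$lo[2L]:rng$hi[2L]] - center[2L])^2
    dz2 <- (axes[[3L]][rng$lo[3L]:rng$hi[3L]] - center[3L])^2
    outer(outer(dx2, dy2, "+"), dz2, "+")
  }

  # Pass 1: solvent-accessible interior (union of probe-expanded spheres).
  inside <- array(FALSE, dims)
  for (a in seq_len(nrow(coords))) {
    R <- radii[a] + probe
    rng <- block_range(coords[a, ], R)
    blk <- local_dist2(coords[a, ], rng)
    sel <- list(rng$lo[1L]:rng$hi[1L], rng$lo[2L]:rng$hi[2L], rng$lo[3L]:rng$hi[3L])
    inside[sel[[1L]], sel[[2L]], sel[[3L]]] <-
      inside[sel[[1L]], sel[[2L]], sel[[3L]]] | (blk < R * R)
  }

  # Accessible boundary: interior voxels with an exterior 6-neighbor.
  nx <- dims[1L]; ny <- dims[2L]; nz <- dims[3L]
  ext_nb <- array(FALSE, dims)
  ext <- !inside
  ext_nb[-nx, , ] <- ext_nb[-nx, , ] | ext[-1L, , ]
  ext_nb[-1L, , ] <- ext_nb[-1L, , ] | ext[-nx, , ]
  ext_nb[, -ny, ] <- ext_nb[, -ny, ] | ext[, -1L, ]
  ext_nb[, -1L, ] <- ext_nb[, -1L, ] | ext[, -ny, ]
  ext_nb[, , -nz] <- ext_nb[, , -nz] | ext[, , -1L]
  ext_nb[, , -1L] <- ext_nb[, , -1L] | ext[, , -nz]
  bnd <- which(inside & ext_nb)
  if (length(bnd) == 0L) stop("no accessible boundary found; grid too coarse?")

  ijk <- arrayInd(bnd, dims)
  bpts <- cbind(axes[[1L]][ijk[, 1L]], axes[[2L]][ijk[, 2L]], axes[[3L]][ijk[, 3L]])
  # Project each boundary voxel center onto the nearest probe-expanded
  # atom sphere so probe centers sit on the true accessible surface.
  m <- nrow(bpts)
  nat <- nrow(coords)
  best_s <- rep(Inf, m)
  best_a <- rep(1L, m)
  for (a in seq_len(nat)) {
    da <- sqrt((bpts[, 1L] - coords[a, 1L])^2 + (bpts[, 2L] - coords[a, 2L])^2 +
                 (bpts[, 3L] - coords[a, 3L])^2)
    s <- da - (radii[a] + probe)
    upd <- s < best_s
    best_s[upd] <- s[upd]
    best_a[upd] <- a
  }
  ac <- coords[best_a, , drop = FALSE]
  rel <- bpts - ac
  nrm <- sqrt(rowSums(rel^2))
  ok <- nrm > 1e-9
  scale <- (radii[best_a] + probe) / pmax(nrm, 1e-9)
  centers <- ac + rel * scale
  centers <- centers[ok, , drop = FALSE]

  # Pass 2: interior value = probe - distance to nearest probe center.
  # Deep interior keeps a safely negative fill; only voxels within
  # probe + 3*spacing of some probe center need the exact distance (the
  # zero crossing lives there).
  vals <- array(probe, dims)
  vals[inside] <- -3 * spacing
  Ru <- probe + 3 * spacing
  for (p in seq_len(nrow(centers))) {
    rng <- block_range(centers[p, ], Ru)
    blk <- sqrt(local_dist2(centers[p, ], rng))
    sel <- list(rng$lo[1L]:rng$hi[1L], rng$lo[2L]:rng$hi[2L], rng$lo[3L]:rng$hi[3L])
    cur <- vals[sel[[1L]], sel[[2L]], sel[[3L]]]
    ins <- inside[sel[[1L]], sel[[2L]], sel[[3L]]]
    upd <- pmax(cur, probe - blk)
    cur[ins] <- upd[ins]
    vals[sel[[1L]], sel[[2L]], sel[[3L]]] <- cur
  }

  structure(list(origin = origin, spacing = spacing, dims = dims,
                 values = vals), class = "voxel_field")
}

# Kuhn 6-tetrahedron decomposition of the unit cube (corner id bits =
# x + 2y + 4z; all tets share the 0-7 main diagonal, so face diagonals
# match between neighboring cells and the extracted mesh is watertight).
tet_corners <- rbind(
  c(0L, 1L, 3L, 7L),
  c(0L, 1L, 5L, 7L),
  c(0L, 2L, 3L, 7L),
  c(0L, 2L, 6L, 7L),
  c(0L, 4L, 5L, 7L),
  c(0L, 4L, 6L, 7L)
)
tet_flip <- c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE)

# Triangulation of one tetrahedron per sign case. Case id: bit k set
# when local corner k has value < iso ("inside"). Each row of a case
# matrix is a triangle as three edges (corner-index pairs), wound so
# normals point toward the outside region for a positively oriented tet.
tet_case_tris <- local({
  tl <- vector("list", 16L)
  tl[[1L + 1L]] <- rbind(c(1, 2, 1, 3, 1, 4))
  tl[[2L + 1L]] <- rbind(c(2, 1, 2, 4, 2, 3))
  tl[[4L + 1L]] <- rbind(c(3, 1, 3, 2, 3, 4))
  tl[[8L + 1L]] <- rbind(c(4, 1, 4, 3, 4, 2))
  tl[[14L + 1L]] <- rbind(c(1, 2, 1, 4, 1, 3))
  tl[[13L + 1L]] <- rbind(c(2, 1, 2, 3, 2, 4))
  tl[[11L + 1L]] <- rbind(c(3, 1, 3, 4, 3, 2))
  tl[[7L + 1L]] <- rbind(c(4, 1, 4, 2, 4, 3))
  tl[[3L + 1L]] <- rbind(c(1, 3, 1, 4, 2, 4), c(1, 3, 2, 4, 2, 3))
  tl[[5L + 1L]] <- rbind(c(1, 4, 1, 2, 3, 2), c(1, 4, 3, 2, 3, 4))
  tl[[9L + 1L]] <- rbind(c(1, 2, 1, 3, 4, 3), c(1, 2, 4, 3, 4, 2))
  tl[[6L + 1L]] <- rbind(c(2, 1, 2, 4, 3, 4), c(2, 1, 3, 4, 3, 1))
  tl[[10L + 1L]] <- rbind(c(2, 3, 2, 1, 4, 1), c(2, 3, 4, 1, 4, 3))
  tl[[12L + 1L]] <- rbind(c(3, 1, 3, 2, 4, 2), c(3, 1, 4, 2, 4, 1))
  tl
})

empty_mesh <- function() {
  structure(list(
    vertices = matrix(numeric(0), ncol = 3L),
    triangles = matrix(integer(0), ncol = 3L),
    vertex_charge = NULL, triangle_charge = NULL, vertex_color = NULL
  ), class = "surface_mesh")
}

#' Extract the iso-surface of a voxel field as a triangle mesh
#'
#' Marching iso-surface extraction on the voxel grid using the
#' tetrahedral (6-tet Kuhn) decomposition of each cell: every cube is
#' split into six tetrahedra sharing its main diagonal, each tetrahedron
#' is triangulated from the signs of its corner values, and vertices are
#' placed on straddling edges by linear interpolation. Shared edges
#' produce shared vertices, so closed level sets yield watertight meshes
#' with consistent outward orientation (normals point toward values
#' above `iso`).
#'
#' @param field A [build_ses_field()] result (any `voxel_field`).
#' @param iso Iso-value; 0 for the SES.
#' @return A `surface_mesh` with `vertices` (n x 3, Angstrom) and
#'   `triangles` (m x 3 vertex indices); empty when the field does not
#'   straddle `iso`.
#' @export
extract_mesh <- function(field, iso = 0) {
  stopifnot(inherits(field, "voxel_field"))
  vals <- field$values
  if (!all(is.finite(vals))) stop("voxel field must be finite")
  dims <- field$dims
  nx <- dims[1L]; ny <- dims[2L]; nz <- dims[3L]
  inside <- vals < iso
  if (!any(inside) || all(inside)) return(empty_mesh())

  num <- array(0L, dims)
  num[inside] <- 1L
  cx <- seq_len(nx - 1L); cy <- seq_len(ny - 1L); cz <- seq_len(nz - 1L)
  s <- num[cx, cy, cz, drop = FALSE] + num[cx + 1L, cy, cz, drop = FALSE] +
    num[cx, cy + 1L, cz, drop = FALSE] + num[cx + 1L, cy + 1L, cz, drop = FALSE] +
    num[cx, cy, cz + 1L, drop = FALSE] + num[cx + 1L, cy, cz + 1L, drop = FALSE] +
    num[cx, cy + 1L, cz + 1L, drop = FALSE] + num[cx + 1L, cy + 1L, cz + 1L, drop = FALSE]
  act <- which(s > 0L & s < 8L)
  if (length(act) == 0L) return(empty_mesh())
  cell <- arrayInd(act, dims - 1L)

  gindex <- function(ix, iy, iz) ix + (iy - 1L) * nx + (iz - 1L) * (nx * ny)
  corner_g <- lapply(0:7, function(cid) {
    gindex(cell[, 1L] + cid %% 2L,
           cell[, 2L] + (cid %/% 2L) %% 2L,
           cell[, 3L] + cid %/% 4L)
  })

  ea <- list(); eb <- list()  # edge endpoint gids, 3 per triangle
  for (tt in seq_len(6L)) {
    g <- lapply(tet_corners[tt, ] + 1L, function(k) corner_g[[k]])
    ins <- lapply(g, function(gk) inside[gk])
    caseid <- ins[[1L]] + 2L * ins[[2L]] + 4L * ins[[3L]] + 8L * ins[[4L]]
    for (cs in sort(unique(caseid))) {
      tris <- tet_case_tris[[cs + 1L]]
      if (is.null(tris)) next
      rows <- which(caseid == cs)
      for (r in seq_len(nrow(tris))) {
        tr <- tris[r, ]
        if (tet_flip[tt]) tr <- tr[c(1, 2, 5, 6, 3, 4)]
        ea[[length(ea) + 1L]] <- cbind(g[[tr[1L]]][rows], g[[tr[3L]]][rows],
                                       g[[tr[5L]]][rows])
        eb[[length(eb) + 1L]] <- cbind(g[[tr[2L]]][rows], g[[tr[4L]]][rows],
                                       g[[tr[6L]]][rows])
      }
    }
  }
  A <- do.call(rbind, ea)  # n_tri x 3 first endpoints
  B <- do.call(rbind, eb)
  lo <- pmin(A, B); hi <- pmax(A, B)
  key <- lo * (nx * ny * nz + 1) + hi
  ukey <- unique(as.vector(key))
  vid <- matrix(match(key, ukey), ncol = 3L)

  ulo <- ukey %/% (nx * ny * nz + 1)
  uhi <- ukey %% (nx * ny * nz + 1)
  pos_of <- function(g) {
    i <- (g - 1) %% nx + 1
    j <- ((g - 1) %/% nx) %% ny + 1
    k <- (g - 1) %/% (nx * ny) + 1
    cbind(field$origin[1L] + (i - 1) * field$spacing,
          field$origin[2L] + (j - 1) * field$spacing,
          field$origin[3L] + (k - 1) * field$spacing)
  }
  p1 <- pos_of(ulo); p2 <- pos_of(uhi)
  v1 <- vals[ulo]; v2 <- vals[uhi]
  t <- (iso - v1) / (v2 - v1)
  verts <- p1 + t * (p2 - p1)

  structure(list(vertices = verts, triangles = vid,
                 vertex_charge = NULL, triangle_charge = NULL,
                 vertex_color = NULL), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh>: %d vertices, %d triangles%s\n",
              nrow(x$vertices), nrow(x$triangles),
              if (!is.null(x$vertex_charge)) ", charged" else ""))
  invisible(x)
}

#' Map atomic partial charges onto a surface mesh
#'
#' Assigns each vertex the inverse-distance-weighted mean charge of its
#' `k` nearest atoms, then each triangle the mean of its three vertex
#' charges -- a cheap smoothing that renders the molecular electrostatic
#' pattern continuously across the surface. Vertex colors are filled via
#' [charge_to_color()].
#'
#' @param mesh A `surface_mesh`.
#' @param mol The [molecule()] the mesh belongs to (same frame).
#' @param k Number of nearest atoms per vertex (default 8, truncated to
#'   the atom count).
#' @param q_max Charge magnitude mapped to full color saturation;
#'   defaults to the largest absolute atom charge (1 if all zero).
#' @return The mesh with `vertex_charge`, `triangle_charge` and
#'   `vertex_color` set.
#' @export
map_charges <- function(mesh, mol, k = 8L, q_max = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(mol, "molecule"))
  nv <- nrow(mesh$vertices)
  if (nv == 0L) {
    mesh$vertex_charge <- numeric(0)
    mesh$triangle_charge <- numeric(0)
    mesh$vertex_color <- matrix(numeric(0), ncol = 3L)
    return(mesh)
  }
  coords <- atom_coords(mol)
  q <- mol$atoms$charge
  nat <- nrow(coords)
  k <- min(as.integer(k), nat)
  vq <- numeric(nv)
  chunk <- 4000L
  for (start in seq(1L, nv, by = chunk)) {
    idx <- start:min(start + chunk - 1L, nv)
    V <- mesh$vertices[idx, , drop = FALSE]
    d2 <- outer(rowSums(V^2), rowSums(coords^2), "+") - 2 * V %*% t(coords)
    d <- sqrt(pmax(d2, 0))
    if (k < nat) {
      vq[idx] <- vapply(seq_len(nrow(d)), function(r) {
        nn <- order(d[r, ])[seq_len(k)]
        w <- 1 / pmax(d[r, nn], 1e-6)
        sum(w * q[nn]) / sum(w)
      }, numeric(1L))
    } else {
      w <- 1 / pmax(d, 1e-6)
      vq[idx] <- as.numeric((w %*% q) / rowSums(w))
    }
  }
  mesh$vertex_charge <- vq
  tri <- mesh$triangles
  mesh$triangle_charge <- (vq[tri[, 1L]] + vq[tri[, 2L]] + vq[tri[, 3L]]) / 3
  if (is.null(q_max)) {
    q_max <- max(abs(q), 0)
    if (q_max == 0) q_max <- 1
  }
  mesh$vertex_color <- charge_to_color(vq, q_max)
  mesh
}

#' Map a charge to a red-white-blue color
#'
#' The conventional electrostatic-surface coloring: saturated red at
#' `-q_max`, white at zero, saturated blue at `+q_max`, linear in
#' between; charges outside `[-q_max, q_max]` are clamped.
#'
#' @param q Charge(s), elementary charge units.
#' @param q_max Positive saturation magnitude.
#' @return Numeric matrix (n x 3) of RGB values in `[0, 1]`.
#' @export
charge_to_color <- function(q, q_max) {
  stopifnot(q_max > 0)
  f <- pmin(pmax(q / q_max, -1), 1)
  r <- ifelse(f < 0, 1, 1 - f)
  g <- 1 - abs(f)
  b <- ifelse(f < 0, 1 + f, 1)
  cbind(r = r, g = g, b = b)
}

#' Build the charged SES mesh of a molecule
#'
#' Full pipeline: pick the voxel spacing from the bounding box
#' ([adaptive_cell_size()], unless `spacing` is given), build the signed
#' SES field ([build_ses_field()]), extract the zero level set
#' ([extract_mesh()]) and map atomic charges onto it ([map_charges()]).
#'
#' @param mol A parameterized [molecule()].
#' @param probe Solvent probe radius, Angstrom.
#' @param spacing Voxel edge, Angstrom, or `NULL` for the adaptive rule.
#' @param k Nearest-atom count for charge mapping.
#' @return A charged `surface_mesh` enclosing all atom centers.
#' @export
build_ses_mesh <- function(mol, probe = 1.4, spacing = NULL, k = 8L) {
  stopifnot(inherits(mol, "molecule"))
  if (is.null(spacing)) {
    coords <- atom_coords(mol)
    ext <- apply(coords, 2L, max) - apply(coords, 2L, min)
    spacing <- adaptive_cell_size(ext)
  }
  field <- build_ses_field(mol, probe = probe, spacing = spacing)
  mesh <- extract_mesh(field, iso = 0)
  map_charges(mesh, mol, k = k)
}

#' Total area of a triangle mesh
#' @param mesh A `surface_mesh`.
#' @return Area, square Angstrom.
#' @export
mesh_area <- function(mesh) {
  tri <- mesh$triangles
  if (nrow(tri) == 0L) return(0)
  v <- mesh$vertices
  u <- v[tri[, 2L], , drop = FALSE] - v[tri[, 1L], , drop = FALSE]
  w <- v[tri[, 3L], , drop = FALSE] - v[tri[, 1L], , drop = FALSE]
  cx <- u[, 2L] * w[, 3L] - u[, 3L] * w[, 2L]
  cy <- u[, 3L] * w[, 1L] - u[, 1L] * w[, 3L]
  cz <- u[, 1L] * w[, 2L] - u[, 2L] * w[, 1L]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Signed volume enclosed by an oriented mesh
#' @param mesh A closed, outward-oriented `surface_mesh`.
#' @return Volume, cubic Angstrom (positive for outward orientation).
#' @export
mesh_volume <- function(mesh) {
  tri <- mesh$triangles
  if (nrow(tri) == 0L) return(0)
  v <- mesh$vertices
  a <- v[tri[, 1L], , drop = FALSE]
  b <- v[tri[, 2L], , drop = FALSE]
  cc <- v[tri[, 3L], , drop = FALSE]
  sum(a[, 1L] * (b[, 2L] * cc[, 3L] - b[, 3L] * cc[, 2L]) -
        a[, 2L] * (b[, 1L] * cc[, 3L] - b[, 3L] * cc[, 1L]) +
        a[, 3L] * (b[, 1L] * cc[, 2L] - b[, 2L] * cc[, 1L])) / 6
}

mesh_edge_counts <- function(mesh) {
  tri <- mesh$triangles
  e1 <- tri[, c(1L, 2L), drop = FALSE]
  e2 <- tri[, c(2L, 3L), drop = FALSE]
  e3 <- tri[, c(3L, 1L), drop = FALSE]
  e <- rbind(e1, e2, e3)
  key <- pmin(e[, 1L], e[, 2L]) * (nrow(mesh$vertices) + 1) +
    pmax(e[, 1L], e[, 2L])
  table(key)
}

#' Is every mesh edge shared by exactly two triangles?
#' @param mesh A `surface_mesh`.
#' @return `TRUE` for a closed (watertight) mesh.
#' @export
mesh_is_closed <- function(mesh) {
  if (nrow(mesh$triangles) == 0L) return(FALSE)
  all(mesh_edge_counts(mesh) == 2L)
}

#' Number of connected components of a mesh
#' @param mesh A `surface_mesh`.
#' @return Integer component count (0 for an empty mesh).
#' @export
mesh_components <- function(mesh) {
  tri <- mesh$triangles
  if (nrow(tri) == 0L) return(0L)
  g <- igraph::graph_from_edgelist(
    rbind(tri[, 1:2, drop = FALSE], tri[, 2:3, drop = FALSE]),
    directed = FALSE
  )
  used <- unique(as.vector(tri))
  comp <- igraph::components(g)
  length(unique(comp$membership[used]))
}

#' Euler characteristic of a mesh
#' @param mesh A `surface_mesh`.
#' @return `V - E + F` (2 for a single closed sphere-like component).
#' @export
mesh_euler <- function(mesh) {
  if (nrow(mesh$triangles) == 0L) return(0L)
  v <- length(unique(as.vector(mesh$triangles)))
  e <- length(mesh_edge_counts(mesh))
  f <- nrow(mesh$triangles)
  v - e + f
}
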