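#' Write a surface mesh to an ASCII PLY file
#'
#' Vertices carry coordinates, red/green/blue (uchar, from
#' `vertex_color`, white when unset) and a custom float `charge`
#' property (0 when unset); faces are triangles.
#'
#' @param mesh A `surface_mesh`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$triangles)
  col <- mesh$vertex_color
  if (is.null(col) || nrow(col) != nv) col <- matrix(1, nrow = nv, ncol = 3L)
  q <- mesh$vertex_charge
  if (is.null(q) || length(q) != nv) q <- numeric(nv)
  header <- c(
    "ply", "format ascii 1.0",
    "comment softdock SES mesh",
    sprintf("element vertex %d", nv),
    "property float x", "property float y", "property float z",
    "property uchar red", "property uchar green", "property uchar blue",
    "property float charge",
    sprintf("element face %d", nf),
    "property list uchar int vertex_indices",
    "end_header"
  )
  vlines <- sprintf("%.6f %.6f %.6f %d %d %d %.6f",
                    mesh$vertices[, 1L], mesh$vertices[, 2L], mesh$vertices[, 3L],
                    as.integer(round(col[, 1L] * 255)),
                    as.integer(round(col[, 2L] * 255)),
                    as.integer(round(col[, 3L] * 255)), q)
  flines <- sprintf("3 %d %d %d", mesh$triangles[, 1L] - 1L,
                    mesh$triangles[, 2L] - 1L, mesh$triangles[, 3L] - 1L)
  writeLines(c(header, vlines, flines), path)
  invisible(path)
}

#' Read an ASCII PLY file written by [write_ply()]
#'
#' Parses the vertex properties declared in the header (coordinates,
#' optional colors and charge) and the triangle list; `triangle_charge`
#' is recomputed as the mean of the vertex charges.
#'
#' @param path PLY file path.
#' @return A `surface_mesh`.
#' @export
read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || trimws(lines[1L]) != "ply") stop("not a PLY file")
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) stop("PLY parse error: no end_header")
  header <- trimws(lines[seq_len(endh)])
  if (!any(grepl("^format ascii", header))) stop("only ASCII PLY is supported")

  nv <- 0L; nf <- 0L
  vprops <- character(0)
  current <- ""
  for (h in header) {
    f <- strsplit(h, "\\s+")[[1L]]
    if (f[1L] == "element") {
      current <- f[2L]
      if (current == "vertex") nv <- as.integer(f[3L])
      if (current == "face") nf <- as.integer(f[3L])
    } else if (f[1L] == "property" && current == "vertex" && f[2L] != "list") {
      vprops <- c(vprops, f[3L])
    }
  }
  body <- lines[(endh + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf) stop("PLY parse error: truncated body")
  vdat <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                                as.numeric))
  colnames(vdat) <- vprops[seq_len(ncol(vdat))]
  verts <- vdat[, c("x", "y", "z"), drop = FALSE]
  fdat <- do.call(rbind, lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"),
                                as.numeric))
  if (any(fdat[, 1L] != 3)) stop("only triangle faces are supported")
  tri <- matrix(as.integer(fdat[, 2:4]) + 1L, ncol = 3L)

  mesh <- structure(list(vertices = unname(verts), triangles = tri,
                         vertex_charge = NULL, triangle_charge = NULL,
                         vertex_color = NULL), class = "surface_mesh")
  if (all(c("red", "green", "blue") %in% colnames(vdat))) {
    mesh$vertex_color <- cbind(vdat[, "red"], vdat[, "green"], vdat[, "blue"]) / 255
  }
  if ("charge" %in% colnames(vdat)) {
    mesh$vertex_charge <- vdat[, "charge"]
    mesh$triangle_charge <- (mesh$vertex_charge[tri[, 1L]] +
                               mesh$vertex_charge[tri[, 2L]] +
                               mesh$vertex_charge[tri[, 3L]]) / 3
  }
  mesh
}

#' Write mesh geometry to a Wavefront OBJ file
#' @param mesh A `surface_mesh`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  vlines <- sprintf("v %.6f %.6f %.6f", mesh$vertices[, 1L],
                    mesh$vertices[, 2L], mesh$vertices[, 3L])
  flines <- sprintf("f %d %d %d", mesh$triangles[, 1L],
                    mesh$triangles[, 2L], mesh$triangles[, 3L])
  writeLines(c("# softdock SES mesh", vlines, flines), path)
  invisible(path)
}
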