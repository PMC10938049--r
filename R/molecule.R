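#' Construct a molecule
#'
#' A molecule is an ordered collection of atoms with coordinates (Angstrom),
#' partial charges (elementary charge units) and, once
#' [assign_parameters()] has run, per-atom van der Waals radii and well
#' depths. Atom data live in a data frame with columns `serial`, `name`,
#' `element`, `x`, `y`, `z`, `charge`, `radius`, `well_depth`.
#'
#' @param id Molecule identifier (single string).
#' @param atoms Data frame of atoms. Must contain `serial`, `name`,
#'   `element`, `x`, `y`, `z`, `charge`; `radius`/`well_depth` are added as
#'   `NA` when absent and filled by [assign_parameters()].
#' @param source_path Path the molecule was read from, or `""`.
#' @return An object of class `molecule`.
#' @export
molecule <- function(id, atoms, source_path = "") {
  stopifnot(is.character(id), length(id) == 1L, is.data.frame(atoms))
  required <- c("serial", "name", "element", "x", "y", "z", "charge")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atom table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) < 1L) stop("a molecule needs at least one atom")
  if (anyDuplicated(atoms$serial)) stop("atom serials must be unique")
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) stop("atom coordinates must be finite")
  if (!all(is.finite(atoms$charge))) stop("atom charges must be finite")
  if (is.null(atoms$radius)) atoms$radius <- NA_real_
  if (is.null(atoms$well_depth)) atoms$well_depth <- NA_real_
  rownames(atoms) <- NULL
  structure(
    list(id = id, atoms = atoms, source_path = source_path),
    class = "molecule"
  )
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf(
    "<molecule '%s'>: %d atoms, net charge %+0.3f e%s\n",
    x$id, nrow(x$atoms), sum(x$atoms$charge),
    if (all(is.finite(x$atoms$radius))) ", parameterized" else ""
  ))
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol A [molecule()].
#' @return Integer atom count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' Atom coordinates of a molecule
#' @param mol A [molecule()].
#' @return Numeric matrix with one row per atom and columns x, y, z (Angstrom).
#' @export
atom_coords <- function(mol) {
  m <- as.matrix(mol$atoms[, c("x", "y", "z")])
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

is_parameterized <- function(mol) {
  all(is.finite(mol$atoms$radius)) && all(is.finite(mol$atoms$well_depth))
}

#' Load a van der Waals parameter table
#'
#' The table maps an element symbol to a van der Waals radius (Angstrom)
#' and a Lennard-Jones well depth (kcal/mol). A `default` entry makes the
#' lookup total: elements not listed fall back to it. The packaged table
#' (`inst/extdata/vdw_parameters.tsv`) carries Bondi radii and well depths
#' of Amber-like magnitude for C, N, O, S, H, P; it is a documented
#' stand-in, overridable with any file in the same two-column format.
#'
#' @param path Path to a tab-separated file with columns `element`,
#'   `radius`, `well_depth` (comment lines start with `#`). Defaults to the
#'   packaged table.
#' @return An object of class `parameter_table`.
#' @export
read_parameter_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "vdw_parameters.tsv", package = "softdock")
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("element", "radius", "well_depth") %in% names(tab)))
  if (!"default" %in% tab$element) {
    stop("parameter table must contain a 'default' entry")
  }
  if (any(tab$radius <= 0)) stop("all radii must be positive")
  if (any(tab$well_depth < 0)) stop("well depths must be non-negative")
  structure(list(table = tab, path = path), class = "parameter_table")
}

#' Default van der Waals parameter table
#' @return The packaged `parameter_table`.
#' @export
default_parameter_table <- function() read_parameter_table(NULL)

#' Look up an element in a parameter table
#' @param table A `parameter_table`.
#' @param element Character vector of element symbols.
#' @return Data frame with columns `radius`, `well_depth`, one row per query.
#' @export
lookup_parameters <- function(table, element) {
  stopifnot(inherits(table, "parameter_table"))
  tab <- table$table
  idx <- match(toupper(element), toupper(tab$element))
  idx[is.na(idx)] <- match("default", tolower(tab$element))
  data.frame(radius = tab$radius[idx], well_depth = tab$well_depth[idx])
}

#' Assign van der Waals parameters to every atom
#'
#' Fills each atom's `radius` and `well_depth` from the element-keyed
#' table; elements absent from the table receive the table's default entry
#' and trigger a warning. The operation is deterministic and idempotent.
#'
#' @param mol A [molecule()].
#' @param table A `parameter_table`; the packaged table by default.
#' @return The molecule with `radius` and `well_depth` set on every atom.
#' @export
assign_parameters <- function(mol, table = default_parameter_table()) {
  stopifnot(inherits(mol, "molecule"))
  known <- toupper(table$table$element)
  unknown <- setdiff(unique(toupper(mol$atoms$element)), known)
  if (length(unknown) > 0L) {
    warning(sprintf(
      "molecule '%s': unknown element(s) %s assigned default parameters",
      mol$id, paste(unknown, collapse = ", ")
    ))
  }
  pars <- lookup_parameters(table, mol$atoms$element)
  mol$atoms$radius <- pars$radius
  mol$atoms$well_depth <- pars$well_depth
  mol
}
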