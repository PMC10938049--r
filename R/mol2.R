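#' Parse a Tripos mol2 document
#'
#' Reads the `@<TRIPOS>MOLECULE` and `@<TRIPOS>ATOM` sections of a mol2
#' file. Atom records must carry at least nine columns
#' (id, name, x, y, z, type, subst_id, subst_name, charge): partial
#' charges are mandatory input, never recomputed. `BOND`, `SUBSTRUCTURE`
#' and all other sections are skipped. The element symbol is taken from
#' the SYBYL atom type (the part before the first `.`), falling back to
#' the leading letters of the atom name.
#'
#' @param path_or_text Path to a mol2 file, or the document itself as a
#'   character vector (one string, or one element per line).
#' @param id Molecule id; defaults to the name in the MOLECULE section.
#' @return A [molecule()] with `radius`/`well_depth` unset (see
#'   [assign_parameters()]).
#' @export
parse_mol2 <- function(path_or_text, id = NULL) {
  src <- ""
  if (length(path_or_text) == 1L && !grepl("\n", path_or_text) &&
      file.exists(path_or_text)) {
    lines <- readLines(path_or_text, warn = FALSE)
    src <- path_or_text
  } else {
    lines <- unlist(strsplit(path_or_text, "\n", fixed = TRUE))
  }
  sec <- grep("^@<TRIPOS>", lines)
  mol_sec <- grep("^@<TRIPOS>MOLECULE\\s*$", lines)
  atom_sec <- grep("^@<TRIPOS>ATOM\\s*$", lines)
  if (length(mol_sec) == 0L) stop("mol2 format error: missing @<TRIPOS>MOLECULE section")
  if (length(atom_sec) == 0L) stop("mol2 format error: missing @<TRIPOS>ATOM section")
  mol_sec <- mol_sec[1L]
  atom_sec <- atom_sec[1L]
  mol_name <- trimws(lines[mol_sec + 1L])
  if (is.na(mol_name) || mol_name == "") mol_name <- "MOL"

  sec_after <- sec[sec > atom_sec]
  atom_end <- if (length(sec_after) > 0L) min(sec_after) - 1L else length(lines)
  body_idx <- seq(atom_sec + 1L, atom_end)
  body_idx <- body_idx[nzchar(trimws(lines[body_idx]))]
  if (length(body_idx) == 0L) stop("mol2 format error: empty @<TRIPOS>ATOM section")

  fields <- strsplit(trimws(lines[body_idx]), "\\s+")
  ncols <- lengths(fields)
  if (any(ncols < 9L)) {
    bad <- body_idx[which(ncols < 9L)[1L]]
    if (all(ncols >= 8L)) {
      stop(sprintf("mol2: charges required but ATOM record at line %d has no charge column", bad))
    }
    stop(sprintf("mol2 parse error: ATOM record at line %d has %d fields (9 required)",
                 bad, ncols[which(ncols < 9L)[1L]]))
  }
  get_num <- function(k, what) {
    v <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", k)))
    if (anyNA(v)) {
      bad <- body_idx[which(is.na(v))[1L]]
      stop(sprintf("mol2 parse error: non-numeric %s at line %d", what, bad))
    }
    v
  }
  serial <- get_num(1L, "atom id")
  name <- vapply(fields, `[[`, "", 2L)
  x <- get_num(3L, "x coordinate")
  y <- get_num(4L, "y coordinate")
  z <- get_num(5L, "z coordinate")
  type <- vapply(fields, `[[`, "", 6L)
  charge <- get_num(9L, "charge")

  element <- toupper(sub("\\..*$", "", type))
  bad_el <- !grepl("^[A-Z][A-Z]?$", element)
  if (any(bad_el)) {
    fallback <- toupper(sub("[^A-Za-z].*$", "", name[bad_el]))
    fallback <- substr(fallback, 1L, 2L)
    element[bad_el] <- ifelse(nzchar(fallback), fallback, "X")
  }

  molecule(
    id = if (is.null(id)) mol_name else id,
    atoms = data.frame(
      serial = as.integer(serial), name = name, element = element,
      x = x, y = y, z = z, charge = charge,
      stringsAsFactors = FALSE
    ),
    source_path = src
  )
}

# One mol2 MOLECULE+ATOM block for a set of world-frame coordinates.
format_mol2_block <- function(mol, coords) {
  at <- mol$atoms
  n <- nrow(at)
  header <- c(
    "@<TRIPOS>MOLECULE",
    mol$id,
    sprintf("%d 0 0 0 0", n),
    "SMALL",
    "USER_CHARGES"
  )
  rows <- sprintf(
    "%7d %-8s %9.4f %9.4f %9.4f %-7s %3d %-7s %9.4f",
    at$serial, at$name, coords[, 1L], coords[, 2L], coords[, 3L],
    at$element, 1L, mol$id, at$charge
  )
  c(header, "@<TRIPOS>ATOM", rows)
}

# PDB ATOM records for one molecule/chain with world-frame coordinates.
format_pdb_chain <- function(mol, coords, chain, serial_offset) {
  at <- mol$atoms
  n <- nrow(at)
  sprintf(
    "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    (serial_offset + seq_len(n)) %% 100000L,
    substr(at$name, 1L, 4L), "MOL", chain, 1L,
    coords[, 1L], coords[, 2L], coords[, 3L], 0, 0,
    substr(at$element, 1L, 2L)
  )
}

#' Write a posed scene to a structure file
#'
#' Writes every molecule of the scene with its pose applied (coordinates
#' in the shared world frame). mol2 output contains one
#' `@<TRIPOS>MOLECULE` record per molecule; PDB output one chain per
#' molecule (chains A, B, C, ...), occupancy and B-factor zero-filled.
#'
#' @param scene A [scene()].
#' @param format `"mol2"` or `"pdb"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_complex <- function(scene, format = c("mol2", "pdb"), path) {
  stopifnot(inherits(scene, "scene"))
  if (!format[1L] %in% c("mol2", "pdb")) {
    stop(sprintf("unsupported format '%s'; supported formats: mol2, pdb", format[1L]))
  }
  format <- format[1L]
  lines <- character(0)
  offset <- 0L
  for (k in seq_along(scene$entries)) {
    e <- scene$entries[[k]]
    coords <- apply_transform(atom_coords(e$molecule), e$transform)
    if (!all(is.finite(coords))) stop("pose produced non-finite coordinates")
    if (format == "mol2") {
      lines <- c(lines, format_mol2_block(e$molecule, coords))
    } else {
      chain <- LETTERS[(k - 1L) %% 26L + 1L]
      lines <- c(lines, format_pdb_chain(e$molecule, coords, chain, offset), "TER")
      offset <- offset + n_atoms(e$molecule)
    }
  }
  if (format == "pdb") lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' Serialize a single molecule to mol2 text
#'
#' @param mol A [molecule()].
#' @param path Optional output path; when `NULL` the mol2 document is
#'   returned as a character vector of lines.
#' @return `path` invisibly, or the mol2 lines.
#' @export
write_mol2 <- function(mol, path = NULL) {
  stopifnot(inherits(mol, "molecule"))
  lines <- format_mol2_block(mol, atom_coords(mol))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(path)
}
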