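#' Read a PDB-format structure into an atom table
#'
#' Parses the ATOM/HETATM records of a PDB-dialect coordinate file (via
#' [bio3d::read.pdb()]) into one tidy row per atom. Alternate-location
#' duplicates are resolved to the conformer with the highest occupancy
#' (ties broken by file order), so downstream distance calculations see a
#' single copy of every atom.
#'
#' @param source Path to a PDB file, or a character vector of PDB-format
#'   lines (anything containing a newline, or of length > 1, is treated as
#'   literal record text).
#' @param structure_id Label attached to every atom row. Defaults to the
#'   file name without extension, or `"structure"` for literal text.
#'
#' @return A tibble with one row per atom and columns `structure_id`,
#'   `serial`, `atom_name`, `element`, `residue_name`, `chain`,
#'   `residue_seq`, `x`, `y`, `z` (Angstrom), `het` (logical HETATM flag)
#'   and `occupancy`.
#'
#' @details Malformed coordinate fields raise an error naming the offending
#'   line number; an empty file (no ATOM/HETATM records) is an error. Blank
#'   element columns fall back to the residue name for heteroatoms (so bare
#'   `MG`/`MN` records are still recognised as metals) and to the first
#'   letter of the atom name otherwise.
#'
#' @examples
#' pdb_txt <- c(
#'   "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
#'   "HETATM    2 MG    MG A 201       3.000   4.000   0.000  1.00  0.00          MG"
#' )
#' read_pdb(pdb_txt)
#' @export
read_pdb <- function(source, structure_id = NULL) {
  stopifnot(is.character(source), length(source) >= 1)
  is_text <- length(source) > 1 || grepl("\n", source[1]) ||
    grepl("^(ATOM|HETATM|HEADER|REMARK|CRYST1|MODEL|TITLE)", source[1])
  if (is_text) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(unlist(strsplit(source, "\n", fixed = TRUE)), path)
    structure_id <- structure_id %||% "structure"
  } else {
    if (!file.exists(source)) {
      abort(paste0("PDB file not found: ", source))
    }
    path <- source
    structure_id <- structure_id %||% sub("\\.(pdb|ent)$", "", basename(source))
  }

  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) {
    abort(paste0("no ATOM/HETATM records in '", structure_id, "'"))
  }
  validate_coord_fields(lines, which(rec))

  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom

  elem <- toupper(trimws(ifelse(is.na(at$elesy), "", at$elesy)))
  fallback <- ifelse(at$type == "HETATM",
    toupper(trimws(at$resid)),
    toupper(substr(trimws(at$elety), 1, 1))
  )
  elem <- ifelse(elem == "", fallback, elem)

  atoms <- tibble::tibble(
    structure_id = structure_id,
    serial = at$eleno,
    atom_name = trimws(at$elety),
    element = elem,
    residue_name = toupper(trimws(at$resid)),
    chain = ifelse(is.na(at$chain), "", at$chain),
    residue_seq = at$resno,
    x = at$x, y = at$y, z = at$z,
    het = at$type == "HETATM",
    occupancy = ifelse(is.na(at$o), 1, at$o),
    altloc = ifelse(is.na(at$alt), "", at$alt)
  )
  if (anyNA(atoms[c("x", "y", "z")])) {
    abort(paste0("non-finite coordinates in '", structure_id, "'"))
  }
  resolve_altloc(atoms)
}

# Coordinate columns of a PDB record are fixed at 31-38, 39-46, 47-54.
# Errors name the first bad line so truncated/garbled files are diagnosable.
validate_coord_fields <- function(lines, idx) {
  for (i in idx) {
    ln <- lines[i]
    for (cols in list(c(31, 38), c(39, 46), c(47, 54))) {
      fld <- trimws(substr(ln, cols[1], cols[2]))
      if (fld == "" || is.na(suppressWarnings(as.numeric(fld)))) {
        abort(paste0(
          "malformed coordinate field '", fld, "' on line ", i,
          " of PDB input"
        ))
      }
    }
  }
  invisible(TRUE)
}

# Keep, for each (chain, residue, atom name) with alternate locations, the
# conformer of highest occupancy; ties go to the first record in the file.
resolve_altloc <- function(atoms) {
  atoms |>
    dplyr::mutate(.file_order = dplyr::row_number()) |>
    dplyr::group_by(
      .data$chain, .data$residue_seq, .data$residue_name, .data$atom_name
    ) |>
    dplyr::arrange(dplyr::desc(.data$occupancy), .data$.file_order,
      .by_group = TRUE
    ) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.file_order) |>
    dplyr::select(-".file_order", -"altloc")
}

#' Write an atom table as a PDB-format file
#'
#' Serialises a table produced by [read_pdb()] or
#' [generate_site_structures()] back to fixed-column PDB text (via
#' [bio3d::write.pdb()]), so generated fixtures round-trip through
#' [read_pdb()].
#'
#' @param atoms Atom tibble for a single structure (one `structure_id`).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_pdb <- function(atoms, file) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0)
  if (length(unique(atoms$structure_id)) != 1) {
    abort("write_pdb() writes one structure at a time; filter structure_id first")
  }
  xyz <- as.numeric(t(as.matrix(atoms[, c("x", "y", "z")])))
  bio3d::write.pdb(
    pdb = NULL, file = file, xyz = xyz,
    type = ifelse(atoms$het, "HETATM", "ATOM"),
    resno = atoms$residue_seq, resid = atoms$residue_name,
    eleno = atoms$serial, elety = atoms$atom_name,
    chain = atoms$chain, o = atoms$occupancy, b = rep(0, nrow(atoms)),
    elesy = atoms$element
  )
  invisible(file)
}
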