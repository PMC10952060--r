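# structure and trajectory I/O.
# Reading goes through bio3d (fixed-column PDB incl. multi-model, binary DCD);
# writing uses an in-package fixed-column PDB emitter because multi-model
# output is needed for trajectory fixtures.

#' Read a structure from a PDB file
#'
#' ATOM and HETATM records are parsed identically (the systems analysed here
#' mix protein, catalytic iron and lipids). Alternate locations keep altloc
#' "A" or blank and drop the rest. Masses and van der Waals radii are filled
#' from the packaged element table; unknown elements get configurable
#' defaults.
#'
#' @param path PDB file path.
#' @param format currently only `"pdb"`.
#' @param mass_default,vdw_default values for elements not in the table.
#' @return a [structure_model()], atom order as in the file.
#' @export
read_structure <- function(path, format = "pdb",
                           mass_default = 12.0, vdw_default = 1.7) {
  format <- match.arg(format, "pdb")
  if (!file.exists(path))
    stop_loxdyn(paste0("cannot read file: ", path), "loxdyn_io_error")
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop_loxdyn(
      paste0("not parseable as PDB: ", path, " (", conditionMessage(e), ")"),
      "loxdyn_format_error"))
  at <- pdb$atom
  keep <- is.na(at$alt) | at$alt == "" | at$alt == "A"
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L)
    stop_loxdyn(paste0("zero atoms in ", path), "loxdyn_format_error")
  element <- at$elesy
  bad <- is.na(element) | !nzchar(trimws(element))
  element[bad] <- guess_element(at$elety[bad])
  element <- toupper(trimws(element))
  chain <- ifelse(is.na(at$chain), " ", at$chain)
  atoms <- data.frame(
    serial = at$eleno, name = trimws(at$elety), element = element,
    resname = trimws(at$resid), resid = at$resno, chain = chain,
    stringsAsFactors = FALSE)
  structure_model(atoms, cbind(at$x, at$y, at$z),
                  mass_default = mass_default, vdw_default = vdw_default)
}

#' Read a trajectory
#'
#' Accepts multi-model PDB (`.pdb`, one MODEL block per frame — the fixture
#' format) or binary DCD (`.dcd`) via bio3d. Neither format carries times, so
#' times are synthesized as 0, 1, 2, ... frame units unless supplied.
#'
#' @param path trajectory file.
#' @param model the matching [structure_model()] (topology).
#' @param format `"auto"` (by extension), `"pdb"` or `"dcd"`.
#' @param times optional explicit times (ns), strictly increasing.
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, model, format = c("auto", "pdb", "dcd"),
                            times = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd" else "pdb"
  if (!file.exists(path))
    stop_loxdyn(paste0("cannot read file: ", path), "loxdyn_io_error")
  xyz <- if (format == "dcd") {
    unclass(bio3d::read.dcd(path, verbose = FALSE))
  } else {
    pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
    m <- pdb$xyz
    # drop non-kept altloc columns is unnecessary for fixtures (no altlocs in
    # trajectories); bio3d returns all atoms per MODEL
    unclass(m)
  }
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  nfile <- ncol(xyz) / 3L
  if (nfile != n_atoms(model))
    stop_loxdyn(sprintf("trajectory has %d atoms per frame, model has %d",
                        nfile, n_atoms(model)), "loxdyn_shape_error")
  tt <- nrow(xyz)
  frames <- aperm(array(t(xyz), dim = c(3L, nfile, tt)), c(3L, 2L, 1L))
  trajectory(model, frames, times = times)
}

fmt_atom_name <- function(name) {
  # names shorter than 4 characters start in column 14 (PDB convention)
  ifelse(nchar(name) >= 4L, substr(name, 1, 4),
         sprintf(" %-3s", name))
}

.standard_aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

pdb_atom_lines <- function(model, xyz) {
  a <- model$atoms
  rec <- ifelse(a$resname %in% .standard_aa, "ATOM", "HETATM")
  sprintf("%-6s%5d %s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, a$serial %% 100000L, fmt_atom_name(a$name),
          substr(a$resname, 1, 4), a$chain, a$resid,
          xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
          formatC(substr(a$element, 1, 2), width = 2, flag = " "))
}

#' Write a structure to a PDB file
#'
#' Coordinates are written in the fixed 8.3 columns (precision 1e-3
#' Angstrom); re-reading yields identical atom metadata and coordinates
#' within that precision.
#'
#' @param model a [structure_model()].
#' @param path output file.
#' @param format currently only `"pdb"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, format = "pdb") {
  format <- match.arg(format, "pdb")
  lines <- c(pdb_atom_lines(model, model$xyz), "END")
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_loxdyn(paste0("cannot write: ", path), "loxdyn_io_error")
  invisible(path)
}

#' Write a trajectory as a multi-model PDB
#'
#' One MODEL/ENDMDL block per frame; the plain-text fixture format used by
#' the synthetic generator and the test suite.
#'
#' @param traj a [trajectory()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  con <- tryCatch(file(path, "w"), error = function(e)
    stop_loxdyn(paste0("cannot write: ", path), "loxdyn_io_error"))
  on.exit(close(con))
  for (i in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(pdb_atom_lines(traj$model, frame_coords(traj, i)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
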