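#' Construct a static molecular system
#'
#' A `structure_model` holds an ordered atom table and one coordinate set.
#' Atom indices used everywhere else in the package are 1-based positions
#' into this table; residue numbers follow the 1-based PDB convention.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resid`, `chain`, and optionally `mass` (Da), `vdw_radius`
#'   (Angstrom), `charge` (elementary charges). Missing masses/radii are
#'   filled from [element_properties()]; missing charges default to 0.
#' @param xyz numeric N x 3 matrix of coordinates in Angstrom.
#' @param box optional numeric(3) of box lengths in Angstrom.
#' @param mass_default,vdw_default fallbacks for elements absent from the
#'   property table.
#'
#' @return object of class `structure_model`: list with `atoms`, `xyz`, `box`.
#' @export
structure_model <- function(atoms, xyz, box = NULL,
                            mass_default = 12.0, vdw_default = 1.7) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  required <- c("name", "resname", "resid", "chain")
  miss <- setdiff(required, names(atoms))
  if (length(miss))
    stop_loxdyn(paste("atom table lacks columns:", paste(miss, collapse = ", ")),
                "loxdyn_format_error")
  n <- nrow(atoms)
  if (n == 0L) stop_loxdyn("structure has zero atoms", "loxdyn_format_error")
  xyz <- as.matrix(xyz)
  if (!is.numeric(xyz) || ncol(xyz) != 3L || nrow(xyz) != n)
    stop_loxdyn(sprintf("coordinate matrix is %d x %d but %d x 3 atoms expected",
                        nrow(xyz), ncol(xyz), n), "loxdyn_shape_error")
  if (any(!is.finite(xyz)))
    stop_loxdyn("non-finite coordinates", "loxdyn_format_error")
  if (is.null(atoms$serial)) atoms$serial <- seq_len(n)
  if (is.null(atoms$element)) atoms$element <- guess_element(atoms$name)
  if (is.null(atoms$mass)) atoms$mass <- element_mass(atoms$element, mass_default)
  if (is.null(atoms$vdw_radius))
    atoms$vdw_radius <- element_vdw(atoms$element, vdw_default)
  if (is.null(atoms$charge)) atoms$charge <- 0
  if (any(atoms$mass <= 0)) stop_loxdyn("non-positive atom mass", "loxdyn_format_error")
  if (any(atoms$vdw_radius <= 0))
    stop_loxdyn("non-positive vdw radius", "loxdyn_format_error")
  key <- paste(atoms$chain, atoms$resid, atoms$name, sep = "/")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop_loxdyn(paste0("duplicate atom (chain/resid/name): ", dup),
                "loxdyn_format_error")
  }
  rownames(atoms) <- NULL
  dimnames(xyz) <- NULL
  structure(list(atoms = atoms, xyz = xyz, box = box), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d atoms, %d chains (%s)\n",
              nrow(x$atoms), length(unique(x$atoms$chain)),
              paste(sort(unique(x$atoms$chain)), collapse = ", ")))
  invisible(x)
}

#' Number of atoms in a model
#' @param model a [structure_model()].
#' @return integer.
#' @export
n_atoms <- function(model) nrow(model$atoms)

#' Construct a trajectory over a structure model
#'
#' @param model a [structure_model()].
#' @param frames numeric array of dimension T x N x 3 (Angstrom).
#' @param times numeric(T), nanoseconds, strictly increasing. Defaults to
#'   `0, 1, 2, ...` frame units when the source format carries no times.
#'
#' @return object of class `trajectory`: list with `model`, `frames`, `times`.
#' @export
trajectory <- function(model, frames, times = NULL) {
  stopifnot(inherits(model, "structure_model"))
  d <- dim(frames)
  if (length(d) != 3L || d[2] != n_atoms(model) || d[3] != 3L)
    stop_loxdyn(sprintf(
      "frame array is %s but T x %d x 3 expected",
      paste(d, collapse = " x "), n_atoms(model)), "loxdyn_shape_error")
  if (d[1] < 1L) stop_loxdyn("trajectory needs at least one frame", "loxdyn_shape_error")
  if (is.null(times)) times <- as.numeric(seq_len(d[1]) - 1L)
  if (length(times) != d[1] || any(diff(times) <= 0))
    stop_loxdyn("times must match frame count and strictly increase",
                "loxdyn_format_error")
  structure(list(model = model, frames = frames, times = as.numeric(times)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms, t = %.3f..%.3f ns\n",
              dim(x$frames)[1], dim(x$frames)[2],
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()].
#' @return integer.
#' @export
n_frames <- function(traj) dim(traj$frames)[1]

# one frame as an N x 3 matrix
frame_coords <- function(traj, i) {
  if (i < 1L || i > n_frames(traj))
    stop_loxdyn(sprintf("frame index %d outside 1..%d", i, n_frames(traj)),
                "loxdyn_range_error")
  matrix(traj$frames[i, , ], ncol = 3L)
}

#' Create an atom index set
#'
#' Sorted, unique, 1-based atom indices into a model's atom table with an
#' attached label.
#'
#' @param indices integer vector of 1-based atom positions.
#' @param label short text label.
#' @param model optional [structure_model()] for bounds checking.
#' @return integer vector of class `atom_set` with a `label` attribute.
#' @export
atom_set <- function(indices, label = "", model = NULL) {
  idx <- sort(unique(as.integer(indices)))
  if (length(idx) && (idx[1] < 1L))
    stop_loxdyn("atom indices must be >= 1", "loxdyn_range_error")
  if (!is.null(model) && length(idx) && idx[length(idx)] > n_atoms(model))
    stop_loxdyn("atom index exceeds atom count", "loxdyn_range_error")
  structure(idx, label = label, class = c("atom_set", "integer"))
}

#' @export
print.atom_set <- function(x, ...) {
  cat(sprintf("atom_set '%s': %d atoms\n", attr(x, "label") %||% "", length(x)))
  invisible(x)
}
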