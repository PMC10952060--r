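# grid-based substrate-access tunnel detection
#
# The catalytic iron of 15LOX-1 sits at the bottom of a buried channel; the
# finder discretizes space into a clearance grid (distance from each voxel
# center to the nearest atom surface) and extracts the maximin path — the
# 6-connected voxel path from the catalytic site to the protein surface that
# maximizes its minimum clearance. The minimum along that path is the
# bottleneck radius, the limiting width for substrate passage.

#' Clearance grid around a structure
#'
#' The grid covers the atom bounding box plus `margin` on every side; each
#' voxel stores the distance from its center to the nearest atom surface
#' (negative inside an atom).
#'
#' @param model a [structure_model()].
#' @param spacing voxel edge, Angstrom (default 0.8).
#' @param margin padding around the bounding box, Angstrom (default 4.0);
#'   guarantees that grid-boundary voxels are solvent.
#' @param exclude optional [atom_set()] of atoms left out of the occupancy
#'   computation (e.g. the iron used as the seed).
#' @return object of class `clearance_grid`: list with `origin` (center of
#'   voxel `[1,1,1]`), `spacing`, `dims`, `clearance` (array `dims`).
#' @export
occupancy_grid <- function(model, spacing = 0.8, margin = 4.0, exclude = NULL) {
  keep <- setdiff(seq_len(n_atoms(model)), as.integer(exclude %||% integer(0)))
  if (length(keep) == 0L)
    stop_loxdyn("no atoms for occupancy grid", "loxdyn_domain_error")
  if (spacing <= 0) stop_loxdyn("spacing must be positive", "loxdyn_config_error")
  xyz <- model$xyz[keep, , drop = FALSE]
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  cl <- clearance_grid_cpp(xyz, model$atoms$vdw_radius[keep],
                           as.numeric(lo), spacing, dims)
  structure(list(origin = as.numeric(lo), spacing = spacing, dims = dims,
                 clearance = array(cl, dim = dims)),
            class = "clearance_grid")
}

grid_voxel_of <- function(grid, point) {
  v <- as.integer(round((point - grid$origin) / grid$spacing)) + 1L
  if (any(v < 1L) || any(v > grid$dims))
    stop_loxdyn("seed point lies outside the grid", "loxdyn_range_error")
  v
}

grid_centers <- function(grid, lin0) {
  # lin0: 0-based linear voxel indices -> voxel centers
  nx <- grid$dims[1]; ny <- grid$dims[2]
  i <- lin0 %% nx
  j <- (lin0 %/% nx) %% ny
  k <- lin0 %/% (nx * ny)
  cbind(grid$origin[1] + i * grid$spacing,
        grid$origin[2] + j * grid$spacing,
        grid$origin[3] + k * grid$spacing)
}

#' Maximin tunnel path through a clearance grid
#'
#' Among all 6-connected voxel paths from the seed voxel to any
#' grid-boundary voxel whose clearance stays at or above `probe`, returns
#' one maximizing the minimum clearance along the path; ties are broken by
#' fewer steps, then by lexicographic voxel order.
#'
#' @param grid a [occupancy_grid()] result.
#' @param seed numeric(3) seed point, Angstrom (typically the catalytic
#'   iron position); its voxel must have clearance at least `probe`.
#' @param probe probe radius, Angstrom (default 1.4, a water molecule).
#' @return object of class `tunnel_path`: list with `points` (P x 3 voxel
#'   centers from seed to exit), `radii` (clearance per point), `bottleneck`
#'   (minimum of `radii`), `exit_point`, `probe`, `spacing`.
#' @export
find_tunnel <- function(grid, seed, probe = 1.4) {
  stopifnot(inherits(grid, "clearance_grid"))
  v <- grid_voxel_of(grid, seed)
  lin0 <- (v[1] - 1L) + grid$dims[1] * ((v[2] - 1L) + grid$dims[2] * (v[3] - 1L))
  if (grid$clearance[v[1], v[2], v[3]] < probe)
    stop_loxdyn(sprintf("seed voxel is buried (clearance %.2f A < probe %.2f A)",
                        grid$clearance[v[1], v[2], v[3]], probe),
                "loxdyn_seed_buried_error")
  res <- widest_path_cpp(as.numeric(grid$clearance), grid$dims,
                         as.integer(lin0), probe)
  if (!isTRUE(res$found))
    stop_loxdyn(sprintf("no tunnel with clearance >= probe %.2f A", probe),
                "loxdyn_no_tunnel_error")
  lin <- res$path
  radii <- as.numeric(grid$clearance)[lin + 1L]
  pts <- grid_centers(grid, lin)
  structure(list(points = pts, radii = radii, bottleneck = min(radii),
                 exit_point = pts[nrow(pts), ], probe = probe,
                 spacing = grid$spacing),
            class = "tunnel_path")
}

#' @export
print.tunnel_path <- function(x, ...) {
  cat(sprintf("tunnel_path: %d voxels, bottleneck %.2f A (probe %.2f A)\n",
              nrow(x$points), x$bottleneck, x$probe))
  invisible(x)
}

#' Detect the substrate-access tunnel of a structure
#'
#' Builds the clearance grid (excluding the iron itself from the occupancy)
#' and runs the maximin search seeded at the catalytic iron.
#'
#' @param model a [structure_model()].
#' @param fe_selection selection expression or [atom_set()] resolving to
#'   exactly one atom.
#' @param probe,spacing,margin see [find_tunnel()] and [occupancy_grid()].
#' @return a `tunnel_path`.
#' @export
tunnel_from_structure <- function(model, fe_selection = "name FE",
                                  probe = 1.4, spacing = 0.8, margin = 4.0) {
  fe <- if (is.character(fe_selection)) select_atoms(model, fe_selection)
        else atom_set(fe_selection, model = model)
  if (length(fe) != 1L)
    stop_loxdyn(sprintf("iron selection resolves to %d atoms, need exactly 1",
                        length(fe)), "loxdyn_cardinality_error")
  grid <- occupancy_grid(model, spacing = spacing, margin = margin, exclude = fe)
  find_tunnel(grid, model$xyz[as.integer(fe), ], probe = probe)
}

#' Export a tunnel path
#'
#' `write_tunnel_pdb()` writes one HETATM pseudo-atom per path point with
#' the clearance in the B-factor column (convenient for visualization);
#' `write_tunnel_tsv()` writes a table of `x, y, z, clearance`.
#'
#' @param path a `tunnel_path`.
#' @param file output file path.
#' @return `file`, invisibly.
#' @export
write_tunnel_pdb <- function(path, file) {
  stopifnot(inherits(path, "tunnel_path"))
  b <- pmin(path$radii, 99.99)
  lines <- sprintf(
    "HETATM%5d  O   TUN T%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           O",
    seq_len(nrow(path$points)) %% 100000L, seq_len(nrow(path$points)) %% 10000L,
    path$points[, 1], path$points[, 2], path$points[, 3], 1, b)
  writeLines(c(lines, "END"), file)
  invisible(file)
}

#' @rdname write_tunnel_pdb
#' @export
write_tunnel_tsv <- function(path, file) {
  stopifnot(inherits(path, "tunnel_path"))
  df <- data.frame(x = path$points[, 1], y = path$points[, 2],
                   z = path$points[, 3], clearance = path$radii)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
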