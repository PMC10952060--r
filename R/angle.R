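# the domain-opening order parameter theta

#' Partition a model into the three bodies defining the opening angle
#'
#' Holds the atom sets for the 15LOX-1 beta-barrel (PLAT) domain, the
#' 15LOX-1 catalytic domain and the PEBP1 scaffold, plus optional marker
#' sets (catalytic iron, substrate carbons C13/C10, lipids). The three core
#' sets must be pairwise disjoint and non-empty.
#'
#' @param beta_barrel,catalytic_domain,scaffold [atom_set()]s.
#' @param fe,substrate_c13,substrate_c10,lipids optional [atom_set()]s.
#' @return object of class `domain_partition`.
#' @export
domain_partition <- function(beta_barrel, catalytic_domain, scaffold,
                             fe = NULL, substrate_c13 = NULL,
                             substrate_c10 = NULL, lipids = NULL) {
  core <- list(beta_barrel = beta_barrel, catalytic_domain = catalytic_domain,
               scaffold = scaffold)
  for (nm in names(core))
    if (length(core[[nm]]) == 0L)
      stop_loxdyn(paste0("domain set '", nm, "' is empty"), "loxdyn_domain_error")
  pairs <- utils::combn(names(core), 2, simplify = FALSE)
  for (p in pairs)
    if (length(intersect(core[[p[1]]], core[[p[2]]])))
      stop_loxdyn(paste0("domain sets overlap: ", p[1], " and ", p[2]),
                  "loxdyn_domain_error")
  structure(c(core, list(fe = fe, substrate_c13 = substrate_c13,
                         substrate_c10 = substrate_c10, lipids = lipids)),
            class = "domain_partition")
}

# angle (degrees in [0, 180]) at vertex b between b->a and b->c
vertex_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  nu <- vnorm(u); nv <- vnorm(v)
  if (nu < 1e-6 || nv < 1e-6)
    stop_loxdyn("coincident centers of mass: opening angle undefined",
                "loxdyn_degenerate_error")
  cosang <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Opening-angle order parameter per frame
#'
#' For each frame, theta is the angle at the catalytic-domain mass center
#' between the directions to the beta-barrel and scaffold mass centers.
#' It reports the degree of exposure of the catalytic site: larger theta,
#' more open complex. Rigid-motion invariant, so no superposition is
#' applied. Centers are mass-weighted over all atoms of each set by
#' default; set `weighting = "geometric"` for unweighted centroids.
#'
#' @param traj a [trajectory()].
#' @param partition a [domain_partition()].
#' @param vertex which body sits at the angle vertex (default the catalytic
#'   domain, the middle body of the barrel-catalytic-scaffold triple).
#' @param weighting `"mass"` or `"geometric"`.
#' @return object of class `angle_series`: data.frame `(time_ns, theta)`,
#'   theta in degrees within \[0, 180\].
#' @export
opening_angle_series <- function(traj, partition,
                                 vertex = c("catalytic_domain", "beta_barrel",
                                            "scaffold"),
                                 weighting = c("mass", "geometric")) {
  vertex <- match.arg(vertex)
  weighting <- match.arg(weighting)
  stopifnot(inherits(partition, "domain_partition"))
  bodies <- c("beta_barrel", "catalytic_domain", "scaffold")
  ends <- setdiff(bodies, vertex)
  masses <- if (weighting == "mass") traj$model$atoms$mass
            else rep(1, n_atoms(traj$model))
  theta <- vapply(seq_len(n_frames(traj)), function(i) {
    xyz <- frame_coords(traj, i)
    vertex_angle(center_of_mass(xyz, partition[[ends[1]]], masses),
                 center_of_mass(xyz, partition[[vertex]], masses),
                 center_of_mass(xyz, partition[[ends[2]]], masses))
  }, numeric(1))
  out <- data.frame(time_ns = traj$times, theta = theta)
  class(out) <- c("angle_series", "data.frame")
  out
}

#' Shift between two opening-angle series
#'
#' Difference of trailing-window means, `series_b` minus `series_a`;
#' positive values mean opening. Used to quantify, e.g., the increase upon
#' membrane association and the decrease upon substrate binding.
#'
#' @param series_a,series_b `angle_series` objects (or data.frames with a
#'   `theta` column).
#' @param window_fraction trailing fraction of frames averaged (default
#'   0.25).
#' @return shift in degrees.
#' @export
angle_shift <- function(series_a, series_b, window_fraction = 0.25) {
  trail_mean <- function(s) {
    x <- s$theta
    n <- length(x)
    if (n == 0L) stop_loxdyn("empty angle series", "loxdyn_domain_error")
    k <- ceiling(window_fraction * n)
    if (k < 1L) stop_loxdyn("angle-shift window is empty", "loxdyn_domain_error")
    mean(x[(n - k + 1L):n])
  }
  trail_mean(series_b) - trail_mean(series_a)
}
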