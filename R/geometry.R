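# superposition, RMSD triage, centers of mass

#' Mass-weighted center of a set of atoms
#'
#' @param xyz N x 3 frame coordinates (Angstrom).
#' @param set [atom_set()] (1-based indices), non-empty.
#' @param masses atomic masses (Da) for all N atoms, or for the set only.
#' @return numeric(3), Angstrom.
#' @export
center_of_mass <- function(xyz, set, masses) {
  idx <- as.integer(set)
  if (length(idx) == 0L)
    stop_loxdyn("center_of_mass of an empty atom set", "loxdyn_domain_error")
  m <- if (length(masses) == nrow(xyz)) masses[idx] else masses
  if (length(m) != length(idx))
    stop_loxdyn("masses must cover the model or the set", "loxdyn_shape_error")
  colSums(xyz[idx, , drop = FALSE] * m) / sum(m)
}

#' Kabsch superposition
#'
#' Optimal rigid-body fit of `mobile` onto `reference` (both M x 3). The
#' returned rotation is proper (determinant +1) and the RMSD is the global
#' minimum over rigid transforms. Apply as
#' `sweep(mobile, 2, cm) %*% rotation + translation` where `cm` is the
#' (weighted) centroid of `mobile`; `fitted` carries the result.
#'
#' @param reference,mobile M x 3 matrices, M >= 3 non-collinear points.
#' @param weights optional non-negative weights (e.g. masses).
#' @return list with `rotation` (3 x 3), `translation` (numeric(3): the
#'   reference centroid), `rmsd` (Angstrom) and `fitted` (M x 3).
#' @export
kabsch_superpose <- function(reference, mobile, weights = NULL) {
  reference <- as.matrix(reference); mobile <- as.matrix(mobile)
  m <- nrow(reference)
  if (m != nrow(mobile) || ncol(reference) != 3L || ncol(mobile) != 3L)
    stop_loxdyn("reference and mobile must be equal-sized M x 3 matrices",
                "loxdyn_shape_error")
  if (m < 3L)
    stop_loxdyn("need at least 3 points to superpose", "loxdyn_degenerate_error")
  w <- if (is.null(weights)) rep(1, m) else as.numeric(weights)
  w <- w / sum(w)
  cr <- colSums(reference * w)
  cm <- colSums(mobile * w)
  A <- sweep(reference, 2, cr)
  B <- sweep(mobile, 2, cm)
  # collinearity: second singular value of either centered cloud ~ 0
  if (svd(A, nu = 0, nv = 0)$d[2] < 1e-8 || svd(B, nu = 0, nv = 0)$d[2] < 1e-8)
    stop_loxdyn("degenerate geometry: points are collinear", "loxdyn_degenerate_error")
  H <- t(B * w) %*% A
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  fitted <- B %*% R
  fitted <- sweep(fitted, 2, cr, FUN = "+")
  rmsd <- sqrt(sum(w * rowSums((fitted - reference)^2)))
  list(rotation = R, translation = cr, rmsd = rmsd, fitted = fitted)
}

#' RMSD time series against a reference frame
#'
#' Each frame is superposed (Kabsch, unweighted over the given atom set)
#' onto the reference frame before the RMSD is taken.
#'
#' @param traj a [trajectory()].
#' @param set [atom_set()] of atoms entering fit and RMSD (convention:
#'   C-alpha atoms of the protein chains).
#' @param reference_frame 1-based frame index, default first frame.
#' @return object of class `rmsd_series`: data.frame `(time_ns, rmsd)` with
#'   attribute `reference_frame`.
#' @export
rmsd_series <- function(traj, set, reference_frame = 1L) {
  tt <- n_frames(traj)
  if (reference_frame < 1L || reference_frame > tt)
    stop_loxdyn(sprintf("reference frame %d outside 1..%d", reference_frame, tt),
                "loxdyn_range_error")
  idx <- as.integer(set)
  ref <- frame_coords(traj, reference_frame)[idx, , drop = FALSE]
  r <- vapply(seq_len(tt), function(i) {
    kabsch_superpose(ref, frame_coords(traj, i)[idx, , drop = FALSE])$rmsd
  }, numeric(1))
  out <- data.frame(time_ns = traj$times, rmsd = r)
  attr(out, "reference_frame") <- reference_frame
  class(out) <- c("rmsd_series", "data.frame")
  out
}

#' Stability triage of a model from its RMSD series
#'
#' The median RMSD over the trailing `window_fraction` of frames is compared
#' with two thresholds: `stable` if it stays at or below `stable_cut`
#' (default 4.5 Angstrom, the upper edge of the 3-4 Angstrom band typical of
#' stable complex models plus margin), `unstable` at or above
#' `unstable_factor * stable_cut` (default factor 3, mirroring models whose
#' RMSD runs three times higher), otherwise `intermediate`.
#'
#' @param series an `rmsd_series` (or data.frame with an `rmsd` column).
#' @param stable_cut Angstrom.
#' @param unstable_factor multiple of `stable_cut` marking instability.
#' @param window_fraction trailing fraction of frames used.
#' @return list with `label` in `{stable, intermediate, unstable}`,
#'   `median_rmsd` (Angstrom) and `window` (first and last frame index used).
#' @export
classify_stability <- function(series, stable_cut = 4.5, unstable_factor = 3.0,
                               window_fraction = 0.5) {
  r <- series$rmsd
  n <- length(r)
  if (n == 0L) stop_loxdyn("empty RMSD series", "loxdyn_domain_error")
  k <- ceiling(window_fraction * n)
  if (k < 1L) stop_loxdyn("stability window is empty", "loxdyn_domain_error")
  win <- (n - k + 1L):n
  med <- stats::median(r[win])
  label <- if (med >= unstable_factor * stable_cut) "unstable"
           else if (med <= stable_cut) "stable" else "intermediate"
  list(label = label, median_rmsd = med, window = c(win[1], n))
}
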