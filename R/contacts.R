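# interface contact maps and hydrogen-bond statistics

res_key <- function(atoms, idx) {
  paste(atoms$chain[idx], atoms$resid[idx], atoms$resname[idx], sep = ":")
}

# squared cross distances between two coordinate blocks
cross_dist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * (A %*% t(B))
  d2[d2 < 0] <- 0
  d2
}

heavy_subset <- function(model, set) {
  idx <- as.integer(set)
  idx[toupper(model$atoms$element[idx]) != "H"]
}

#' Residue-residue contacts across an interface in one frame
#'
#' A residue pair is in contact when the minimum heavy-atom distance between
#' the two residues is at or below `cutoff` (default 4.5 Angstrom).
#'
#' @param model a [structure_model()].
#' @param set_a,set_b disjoint non-empty [atom_set()]s (e.g. the 15LOX-1 and
#'   PEBP1 chains).
#' @param xyz frame coordinates (N x 3); defaults to the model's own.
#' @param cutoff Angstrom.
#' @return data.frame with columns `chain_a, resid_a, resname_a, chain_b,
#'   resid_b, resname_b, min_distance`, ordered by
#'   `(chain_a, resid_a, chain_b, resid_b)`.
#' @export
contact_map <- function(model, set_a, set_b, xyz = model$xyz, cutoff = 4.5) {
  ia <- as.integer(set_a); ib <- as.integer(set_b)
  if (length(ia) == 0L || length(ib) == 0L)
    stop_loxdyn("contact sets must be non-empty", "loxdyn_domain_error")
  if (length(intersect(ia, ib)))
    stop_loxdyn("contact sets overlap", "loxdyn_domain_error")
  ia <- heavy_subset(model, ia); ib <- heavy_subset(model, ib)
  empty <- data.frame(chain_a = character(0), resid_a = integer(0),
                      resname_a = character(0), chain_b = character(0),
                      resid_b = integer(0), resname_b = character(0),
                      min_distance = numeric(0), stringsAsFactors = FALSE)
  if (length(ia) == 0L || length(ib) == 0L) return(empty)
  d2 <- cross_dist2(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(empty)
  at <- model$atoms
  ka <- res_key(at, ia[hit[, 1]])
  kb <- res_key(at, ib[hit[, 2]])
  dmin <- tapply(sqrt(d2[hit]), paste(ka, kb, sep = "|"), min)
  parts <- strsplit(names(dmin), "|", fixed = TRUE)
  pa <- do.call(rbind, strsplit(vapply(parts, `[`, "", 1), ":", fixed = TRUE))
  pb <- do.call(rbind, strsplit(vapply(parts, `[`, "", 2), ":", fixed = TRUE))
  out <- data.frame(chain_a = pa[, 1], resid_a = as.integer(pa[, 2]),
                    resname_a = pa[, 3], chain_b = pb[, 1],
                    resid_b = as.integer(pb[, 2]), resname_b = pb[, 3],
                    min_distance = as.numeric(dmin), stringsAsFactors = FALSE)
  out <- out[order(out$chain_a, out$resid_a, out$chain_b, out$resid_b), ]
  rownames(out) <- NULL
  out
}

#' Contact frequencies over a trajectory
#'
#' Counts, for every residue pair across the interface, the number of frames
#' in contact. The `normalized` column divides raw counts by the maximum raw
#' count, so the most frequent contact reads 1 (the convention used for
#' normalized contact-count distributions).
#'
#' @inheritParams contact_map
#' @param traj a [trajectory()].
#' @return data.frame with `chain_a, resid_a, resname_a, chain_b, resid_b,
#'   resname_b, raw_count, frequency, normalized`, sorted by decreasing
#'   `raw_count` then residue order.
#' @export
contact_frequency <- function(traj, set_a, set_b, cutoff = 4.5) {
  tt <- n_frames(traj)
  acc <- new.env(parent = emptyenv())
  meta <- new.env(parent = emptyenv())
  for (i in seq_len(tt)) {
    cm <- contact_map(traj$model, set_a, set_b, xyz = frame_coords(traj, i),
                      cutoff = cutoff)
    if (nrow(cm) == 0L) next
    keys <- paste(cm$chain_a, cm$resid_a, cm$resname_a,
                  cm$chain_b, cm$resid_b, cm$resname_b, sep = "|")
    for (j in seq_along(keys)) {
      k <- keys[j]
      acc[[k]] <- (acc[[k]] %||% 0L) + 1L
      if (is.null(meta[[k]])) meta[[k]] <- cm[j, 1:6]
    }
  }
  keys <- ls(acc)
  if (length(keys) == 0L)
    return(data.frame(chain_a = character(0), resid_a = integer(0),
                      resname_a = character(0), chain_b = character(0),
                      resid_b = integer(0), resname_b = character(0),
                      raw_count = integer(0), frequency = numeric(0),
                      normalized = numeric(0), stringsAsFactors = FALSE))
  counts <- vapply(keys, function(k) acc[[k]], integer(1))
  info <- do.call(rbind, lapply(keys, function(k) meta[[k]]))
  out <- cbind(info, data.frame(raw_count = as.integer(counts),
                                frequency = counts / tt,
                                normalized = counts / max(counts)))
  out <- out[order(-out$raw_count, out$chain_a, out$resid_a,
                   out$chain_b, out$resid_b), ]
  rownames(out) <- NULL
  out
}

#' Geometric hydrogen-bond detection in one frame
#'
#' With explicit hydrogens: a bond is recorded when the donor-acceptor
#' distance is at most `d_cut` (default 3.5 Angstrom) and the
#' donor-hydrogen-acceptor angle is at least `angle_cut` (default 140
#' degrees) for some hydrogen bonded to the donor (within 1.2 Angstrom).
#' Without hydrogens in the model, a distance-only criterion applies with
#' `d_cut` defaulting to 3.2 Angstrom.
#'
#' @param model a [structure_model()].
#' @param donor_set,acceptor_set [atom_set()]s; all members must be N or O
#'   atoms (hydrogens are located automatically).
#' @param xyz frame coordinates (N x 3); defaults to the model's own.
#' @param d_cut donor-acceptor distance cutoff, Angstrom; `NULL` picks 3.5
#'   (with hydrogens) or 3.2 (without).
#' @param angle_cut donor-hydrogen-acceptor angle cutoff, degrees.
#' @return data.frame `donor, hydrogen, acceptor` (atom indices; `hydrogen`
#'   NA in distance-only mode), `distance` (Angstrom), `angle` (degrees, NA
#'   in distance-only mode).
#' @export
detect_hbonds <- function(model, donor_set, acceptor_set, xyz = model$xyz,
                          d_cut = NULL, angle_cut = 140) {
  at <- model$atoms
  dn <- as.integer(donor_set); ac <- as.integer(acceptor_set)
  bad <- dn[!toupper(at$element[dn]) %in% c("N", "O")]
  if (length(bad))
    stop_loxdyn(paste0("donor set contains non-N/O atoms: ",
                       paste(utils::head(res_key(at, bad), 5), collapse = ", ")),
                "loxdyn_domain_error")
  ac <- ac[toupper(at$element[ac]) %in% c("N", "O")]
  h_all <- which(toupper(at$element) == "H")
  use_h <- length(h_all) > 0L
  if (is.null(d_cut)) d_cut <- if (use_h) 3.5 else 3.2
  empty <- data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      angle = numeric(0))
  if (length(dn) == 0L || length(ac) == 0L) return(empty)
  d2 <- cross_dist2(xyz[dn, , drop = FALSE], xyz[ac, , drop = FALSE])
  hit <- which(d2 <= d_cut^2, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(empty)
  rows <- list()
  for (j in seq_len(nrow(hit))) {
    di <- dn[hit[j, 1]]; ai <- ac[hit[j, 2]]
    if (di == ai) next
    dist <- sqrt(d2[hit[j, 1], hit[j, 2]])
    if (!use_h) {
      rows[[length(rows) + 1L]] <- data.frame(
        donor = di, hydrogen = NA_integer_, acceptor = ai,
        distance = dist, angle = NA_real_)
      next
    }
    # hydrogens covalently attached to this donor
    hd <- h_all[at$resid[h_all] == at$resid[di] & at$chain[h_all] == at$chain[di]]
    if (length(hd)) {
      dh <- sqrt(rowSums(sweep(xyz[hd, , drop = FALSE], 2, xyz[di, ])^2))
      hd <- hd[dh <= 1.2]
    }
    if (length(hd) == 0L) next
    best <- NA_integer_; best_ang <- -Inf
    for (hi in hd) {
      u <- xyz[di, ] - xyz[hi, ]
      v <- xyz[ai, ] - xyz[hi, ]
      ang <- acos(min(1, max(-1, sum(u * v) / (vnorm(u) * vnorm(v))))) * 180 / pi
      if (ang > best_ang) { best_ang <- ang; best <- hi }
    }
    if (best_ang >= angle_cut)
      rows[[length(rows) + 1L]] <- data.frame(
        donor = di, hydrogen = best, acceptor = ai,
        distance = dist, angle = best_ang)
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Lipid-protein hydrogen-bond reorganization
#'
#' Quantifies, per protein residue, the mean number of hydrogen bonds to
#' lipid head groups over the initial and final stages of a trajectory and
#' their difference. Positive `delta` means bonds gained over the run — the
#' signature of beta-barrel residues anchoring into the bilayer.
#'
#' In models with explicit hydrogens both donor directions
#' (protein-to-lipid and lipid-to-protein) are counted; without hydrogens
#' the symmetric distance-only criterion is used and each N/O pair counts
#' once.
#'
#' @param traj a [trajectory()].
#' @param protein_set [atom_set()] of protein atoms (restricted internally
#'   to N/O).
#' @param lipid_set [atom_set()] of lipid atoms (restricted to N/O).
#' @param initial_window,final_window fractions of frames in \(0, 1\); the
#'   two windows must not overlap.
#' @param d_cut,angle_cut forwarded to [detect_hbonds()].
#' @return data.frame `chain, resid, resname, mean_initial, mean_final,
#'   delta`, one row per protein residue contributing N/O atoms.
#' @export
hbond_reorganization <- function(traj, protein_set, lipid_set,
                                 initial_window = 0.1, final_window = 0.1,
                                 d_cut = NULL, angle_cut = 140) {
  if (initial_window <= 0 || final_window <= 0)
    stop_loxdyn("window fractions must be positive", "loxdyn_config_error")
  if (initial_window + final_window > 1 + 1e-12)
    stop_loxdyn("initial and final windows overlap", "loxdyn_config_error")
  tt <- n_frames(traj)
  ki <- ceiling(initial_window * tt)
  kf <- ceiling(final_window * tt)
  if (ki < 1L || kf < 1L || ki + kf > tt)
    stop_loxdyn("initial and final windows overlap", "loxdyn_config_error")
  at <- traj$model$atoms
  is_no <- toupper(at$element) %in% c("N", "O")
  p <- as.integer(protein_set); p <- p[is_no[p]]
  l <- as.integer(lipid_set);   l <- l[is_no[l]]
  if (length(p) == 0L || length(l) == 0L)
    stop_loxdyn("no N/O atoms in protein or lipid set", "loxdyn_domain_error")
  use_h <- any(toupper(at$element) == "H")
  residues <- unique(res_key(at, p))
  count_frame <- function(i) {
    xyz <- frame_coords(traj, i)
    per_res <- stats::setNames(numeric(length(residues)), residues)
    a <- detect_hbonds(traj$model, atom_set(p), atom_set(l), xyz = xyz,
                       d_cut = d_cut, angle_cut = angle_cut)
    if (nrow(a)) {
      tb <- table(res_key(at, a$donor))
      per_res[names(tb)] <- per_res[names(tb)] + as.numeric(tb)
    }
    if (use_h) {  # lipid-donor direction, attributed to the protein acceptor
      b <- detect_hbonds(traj$model, atom_set(l), atom_set(p), xyz = xyz,
                         d_cut = d_cut, angle_cut = angle_cut)
      if (nrow(b)) {
        tb <- table(res_key(at, b$acceptor))
        per_res[names(tb)] <- per_res[names(tb)] + as.numeric(tb)
      }
    }
    per_res
  }
  acc <- function(frames) {
    m <- vapply(frames, count_frame, numeric(length(residues)))
    if (is.null(dim(m))) m <- matrix(m, nrow = length(residues))
    rowMeans(m)
  }
  mi <- acc(seq_len(ki))
  mf <- acc((tt - kf + 1L):tt)
  parts <- do.call(rbind, strsplit(residues, ":", fixed = TRUE))
  out <- data.frame(chain = parts[, 1], resid = as.integer(parts[, 2]),
                    resname = parts[, 3], mean_initial = mi, mean_final = mf,
                    delta = mf - mi, stringsAsFactors = FALSE)
  out <- out[order(out$chain, out$resid), ]
  rownames(out) <- NULL
  out
}
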