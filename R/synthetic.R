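# deterministic toy complexes and two-state trajectories
#
# The generator emulates the statistical structure the analyses assume — a
# three-body complex (beta-barrel, catalytic domain, scaffold) next to a
# lipid slab, one SAPE-like substrate with labelled C13/C10 carbons, one
# catalytic iron, two-state (closed/open) dynamics — by construction, not by
# physics: angles and distances are imposed by placement so that every
# downstream statistic has a known ground truth. Identical seeds give
# bit-identical output (Mersenne-Twister/Inversion, pinned).

#' Specification of a toy complex
#'
#' Defaults mirror the modelled 15LOX-1/PEBP1 system: a DOPC/DOPE/SAPE
#' bilayer leaflet at 50/30/20 mol%, one substrate with C13 initially ~7.2
#' Angstrom and C10 ~9.0 Angstrom from the catalytic iron.
#'
#' @param atoms_per_domain named integer(3): pseudo-atoms in the
#'   beta-barrel, catalytic domain and scaffold clouds (each >= 3).
#' @param domain_distance Angstrom from the catalytic center to the other
#'   two domain centers.
#' @param theta_initial degrees: closed-state opening angle built into the
#'   static geometry.
#' @param cloud_sd Angstrom: spread of each Gaussian pseudo-atom cloud.
#' @param n_lipids lipids in the slab.
#' @param composition named fractions for DOPC/DOPE/SAPE; must sum to 1.
#' @param substrate logical: include the SAPE substrate + iron markers.
#' @param fe_c13,fe_c10 initial iron-carbon distances, Angstrom.
#' @param carved_channel `NULL`, or `list(direction = numeric(3),
#'   bottleneck = <Angstrom>)`: carve a channel of known bottleneck from the
#'   iron to the surface through a spherical pocket wall.
#' @param seed integer.
#' @return object of class `complex_spec` (a validated list).
#' @export
complex_spec <- function(atoms_per_domain = c(beta_barrel = 120,
                                              catalytic = 240, scaffold = 90),
                         domain_distance = 25, theta_initial = 90,
                         cloud_sd = 2.5, n_lipids = 90,
                         composition = c(DOPC = 0.5, DOPE = 0.3, SAPE = 0.2),
                         substrate = TRUE, fe_c13 = 7.2, fe_c10 = 9.0,
                         carved_channel = NULL, seed = 1L) {
  if (any(atoms_per_domain < 3))
    stop_loxdyn("each domain needs at least 3 atoms", "loxdyn_spec_error")
  if (abs(sum(composition) - 1) > 1e-6)
    stop_loxdyn("lipid composition fractions must sum to 1", "loxdyn_spec_error")
  if (domain_distance <= 2 * cloud_sd)
    stop_loxdyn("domain centers overlap: increase domain_distance",
                "loxdyn_spec_error")
  if (!is.null(carved_channel)) {
    stopifnot(is.list(carved_channel),
              length(carved_channel$direction) == 3L,
              carved_channel$bottleneck > 0)
  }
  structure(list(atoms_per_domain = atoms_per_domain,
                 domain_distance = domain_distance,
                 theta_initial = theta_initial, cloud_sd = cloud_sd,
                 n_lipids = n_lipids, composition = composition,
                 substrate = substrate, fe_c13 = fe_c13, fe_c10 = fe_c10,
                 carved_channel = carved_channel, seed = as.integer(seed)),
            class = "complex_spec")
}

# per-type lipid counts: round(fraction * n) adjusted (largest types absorb
# the rounding residue) so counts sum exactly to n
lipid_counts <- function(n, composition) {
  raw <- composition * n
  counts <- round(raw)
  diff <- n - sum(counts)
  if (diff != 0) {
    ord <- order(raw - floor(raw), decreasing = diff > 0)
    for (i in seq_len(abs(diff))) {
      j <- ord[(i - 1L) %% length(counts) + 1L]
      counts[j] <- counts[j] + sign(diff)
    }
  }
  stats::setNames(as.integer(counts), names(composition))
}

# quasi-uniform points on a sphere (Fibonacci lattice)
fibonacci_sphere <- function(n, radius = 1) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Build a deterministic toy complex
#'
#' Three Gaussian pseudo-atom clouds at the closed-state domain centers, a
#' lipid slab beneath the complex, one substrate with atoms C13/C10, one FE
#' pseudo-atom at the catalytic center, and optionally a carved channel of
#' configured bottleneck radius from the iron to the surface (a spherical
#' pocket wall with a calibrated ring aperture). A manifest records counts,
#' positions, selections and the RNG used.
#'
#' @param spec a [complex_spec()].
#' @return a [structure_model()] with attribute `manifest` (list).
#' @export
build_toy_complex <- function(spec = complex_spec()) {
  stopifnot(inherits(spec, "complex_spec"))
  with_seed(spec$seed, {
    nb <- spec$atoms_per_domain[[1]]
    nc <- spec$atoms_per_domain[[2]]
    ns <- spec$atoms_per_domain[[3]]
    dd <- spec$domain_distance
    th0 <- spec$theta_initial * pi / 180
    com <- list(catalytic = c(0, 0, 0),
                beta_barrel = c(dd, 0, 0),
                scaffold = dd * c(cos(th0), sin(th0), 0))
    cloud <- function(n, center)
      sweep(matrix(stats::rnorm(3 * n, sd = spec$cloud_sd), ncol = 3), 2,
            center, FUN = "+")
    xb <- cloud(nb, com$beta_barrel)
    xc <- cloud(nc, com$catalytic)
    xs <- cloud(ns, com$scaffold)
    fe_pos <- com$catalytic

    atoms <- list(); coords <- list()
    add <- function(name, element, resname, resid, chain, xyz) {
      atoms[[length(atoms) + 1L]] <<- data.frame(
        name = name, element = element, resname = resname, resid = resid,
        chain = chain, stringsAsFactors = FALSE)
      coords[[length(coords) + 1L]] <<- xyz
    }
    # barrel pseudo-residues cycle C/O/N atoms so lipid hydrogen-bond
    # statistics have donors/acceptors to work with
    b_name <- rep(c("CA", "O", "N"), length.out = nb)
    b_elem <- rep(c("C", "O", "N"), length.out = nb)
    add(b_name, b_elem, rep("GLY", nb), seq_len(nb), rep("A", nb), xb)
    add(rep("CA", nc), rep("C", nc), rep("GLY", nc), 200L + seq_len(nc),
        rep("A", nc), xc)
    # scaffold chain P; the pseudo-residue nearest the catalytic center plays
    # the interfacial proline (resid 112, the P112 position)
    s_resid <- seq_len(ns)
    s_resname <- rep("GLY", ns)
    near <- which.min(rowSums(sweep(xs, 2, com$catalytic)^2))
    s_resid[near] <- 112L
    if (ns >= 112L) s_resid[112L] <- near  # swap to keep resids unique
    s_resname[near] <- "PRO"
    add(rep("CA", ns), rep("C", ns), s_resname, s_resid, rep("P", ns), xs)
    add("FE", "FE", "FE", 999L, "A", matrix(fe_pos, 1))

    if (isTRUE(spec$substrate)) {
      u13 <- unit(c(0.3, -0.3, -1))
      u10 <- unit(c(-0.3, 0.3, -1))
      sub <- rbind(fe_pos + u13 * spec$fe_c13,
                   fe_pos + u10 * spec$fe_c10,
                   fe_pos + c(0, 0, -12))
      add(c("C13", "C10", "C1"), rep("C", 3), rep("SAP", 3), rep(1L, 3),
          rep("S", 3), sub)
    }

    counts <- lipid_counts(spec$n_lipids, spec$composition)
    if (spec$n_lipids > 0) {
      side <- ceiling(sqrt(spec$n_lipids))
      gx <- (seq_len(side) - (side + 1) / 2) * 5
      gridxy <- expand.grid(x = gx, y = gx)[seq_len(spec$n_lipids), ]
      jit <- matrix(stats::runif(2 * spec$n_lipids, -0.8, 0.8), ncol = 2)
      types <- rep(names(counts), counts)
      zhead <- -16
      resid0 <- 0L
      for (li in seq_len(spec$n_lipids)) {
        lx <- gridxy$x[li] + jit[li, 1]
        ly <- gridxy$y[li] + jit[li, 2]
        lip <- rbind(c(lx, ly, zhead), c(lx, ly, zhead - 1.5),
                     c(lx, ly, zhead - 3.0), c(lx, ly, zhead - 4.5))
        add(c("O1", "N1", "C1", "C2"), c("O", "N", "C", "C"),
            rep(types[li], 4), rep(resid0 + li, 4), rep("M", 4), lip)
      }
    }

    model_atoms <- do.call(rbind, atoms)
    model_xyz <- do.call(rbind, coords)

    carved <- spec$carved_channel
    if (!is.null(carved)) {
      dir <- unit(carved$direction)
      b <- carved$bottleneck
      r_wall <- 1.7   # carbon vdw radius of the wall pseudo-atoms
      r_shell <- 6.0
      # drop atoms inside the pocket or within the channel cylinder
      rel <- sweep(model_xyz, 2, fe_pos)
      proj <- as.numeric(rel %*% dir)
      perp <- sqrt(pmax(rowSums(rel^2) - proj^2, 0))
      is_fe <- model_atoms$name == "FE"
      drop <- !is_fe & ((sqrt(rowSums(rel^2)) < r_shell + r_wall + 0.5) |
                          (proj > 0 & perp < b + 2.05 + 0.5))
      model_atoms <- model_atoms[!drop, , drop = FALSE]
      model_xyz <- model_xyz[!drop, , drop = FALSE]
      # spherical pocket wall with an aperture around the channel direction
      shell <- fibonacci_sphere(250, r_shell)
      keep <- as.numeric(shell %*% dir) / r_shell < cos(asin(
        min(1, (b + r_wall + 0.6) / r_shell)))
      shell <- sweep(shell[keep, , drop = FALSE], 2, fe_pos, FUN = "+")
      # calibrated ring: clearance on the channel axis at the aperture is
      # exactly the configured bottleneck
      ang <- seq(0, 2 * pi, length.out = 13L)[-13L]
      e1 <- unit(if (abs(dir[1]) < 0.9) pracma_cross(dir, c(1, 0, 0))
                 else pracma_cross(dir, c(0, 1, 0)))
      e2 <- pracma_cross(dir, e1)
      ring <- sweep((b + r_wall) * (outer(cos(ang), e1) + outer(sin(ang), e2)),
                    2, fe_pos + r_shell * dir, FUN = "+")
      nw <- nrow(shell) + nrow(ring)
      wall <- data.frame(name = sprintf("W%d", seq_len(nw)),
                         element = rep("C", nw), resname = rep("WAL", nw),
                         resid = 2000L + seq_len(nw), chain = rep("W", nw),
                         stringsAsFactors = FALSE)
      model_atoms <- rbind(model_atoms, wall)
      model_xyz <- rbind(model_xyz, shell, ring)
    }

    model_atoms$serial <- seq_len(nrow(model_atoms))
    model <- structure_model(model_atoms, model_xyz)
    manifest <- list(
      generator = "loxdyn::build_toy_complex",
      seed = spec$seed, rng = rng_kind_label,
      n_atoms = n_atoms(model),
      n_protein_atoms = nb + nc + ns,
      atoms_per_domain = as.list(stats::setNames(
        as.integer(spec$atoms_per_domain),
        c("beta_barrel", "catalytic", "scaffold"))),
      lipid_counts = as.list(counts),
      n_lipids = spec$n_lipids,
      domain_com = com,
      theta_initial = spec$theta_initial,
      fe_c13 = spec$fe_c13, fe_c10 = spec$fe_c10,
      substrate = spec$substrate,
      carved_channel = if (is.null(carved)) NULL else
        list(direction = as.numeric(unit(carved$direction)),
             bottleneck = carved$bottleneck),
      selections = list(
        beta_barrel = "chain A and resid 1:199",
        catalytic_domain = "chain A and resid 200:998 and not name FE",
        scaffold = "chain P",
        fe = "name FE",
        substrate_c13 = "chain S and name C13",
        substrate_c10 = "chain S and name C10",
        lipids = "chain M"))
    attr(model, "manifest") <- manifest
    model
  })
}

# cross product (kept local; avoids a dependency for one primitive)
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Resolve the domain partition of a toy complex
#'
#' Uses the selection strings recorded in the generator manifest.
#'
#' @param model a model from [build_toy_complex()].
#' @return a [domain_partition()].
#' @export
toy_partition <- function(model) {
  man <- attr(model, "manifest")
  if (is.null(man)) stop_loxdyn("model carries no manifest", "loxdyn_domain_error")
  sel <- man$selections
  grab <- function(nm) {
    s <- select_atoms(model, sel[[nm]])
    if (length(s)) s else NULL
  }
  domain_partition(
    beta_barrel = select_atoms(model, sel$beta_barrel),
    catalytic_domain = select_atoms(model, sel$catalytic_domain),
    scaffold = select_atoms(model, sel$scaffold),
    fe = grab("fe"), substrate_c13 = grab("substrate_c13"),
    substrate_c10 = grab("substrate_c10"), lipids = grab("lipids"))
}

#' Specification of two-state dynamics
#'
#' A closed/open Markov chain driving the opening angle, the iron-carbon
#' distance distributions and optional scripted contacts. Presets:
#' `"membrane"` reproduces the +20 degree opening upon membrane association
#' (90 -> 110 degrees); `"substrate"` the ~-5 degree compaction upon
#' substrate binding (110 -> 105 degrees); `"solution"` never leaves the
#' closed state.
#'
#' @param n_frames frames (>= 2).
#' @param dt ns between frames.
#' @param theta_closed,theta_open state target angles, degrees.
#' @param sigma_theta per-frame angle noise, degrees.
#' @param p_open,p_close per-frame transition probabilities
#'   (closed to open, open to closed).
#' @param fe_c13,fe_c10 per-state `(mean, sd)` Angstrom:
#'   `list(closed = c(mean, sd), open = c(mean, sd))`.
#' @param scripted_contacts `NULL` or list of
#'   `list(chain_a, resid_a, chain_b, resid_b, p_closed, p_open,
#'   contact_dist, apart_dist)`; per frame, residue b is translated to sit
#'   at `contact_dist` (default 3.5 Angstrom) from residue a with the
#'   state's probability, else at `apart_dist` (default 10).
#' @param noise_sigma isotropic positional noise added to every atom,
#'   Angstrom.
#' @param start_state `"closed"` or `"open"`.
#' @param preset `"none"`, `"membrane"`, `"substrate"` or `"solution"`.
#' @param seed integer.
#' @return object of class `dynamics_spec`.
#' @export
dynamics_spec <- function(n_frames = 2000, dt = 0.1,
                          theta_closed = 90, theta_open = 110,
                          sigma_theta = 2, p_open = 0.05, p_close = 0.05,
                          fe_c13 = list(closed = c(7.2, 0.5),
                                        open = c(7.2, 0.5)),
                          fe_c10 = list(closed = c(9.0, 0.5),
                                        open = c(9.0, 0.5)),
                          scripted_contacts = NULL, noise_sigma = 0.08,
                          start_state = c("closed", "open"),
                          preset = c("none", "membrane", "substrate",
                                     "solution"),
                          seed = 1L) {
  preset <- match.arg(preset)
  start_state <- match.arg(start_state)
  if (preset == "membrane") {
    theta_closed <- 90; theta_open <- 110
  } else if (preset == "substrate") {
    theta_closed <- 110; theta_open <- 105
    start_state <- "closed"
    p_open <- 0.05; p_close <- 0
  } else if (preset == "solution") {
    theta_closed <- 90; p_open <- 0; start_state <- "closed"
  }
  if (n_frames < 2) stop_loxdyn("need at least 2 frames", "loxdyn_spec_error")
  if (p_open < 0 || p_open > 1 || p_close < 0 || p_close > 1)
    stop_loxdyn("transition probabilities must lie in [0, 1]", "loxdyn_spec_error")
  for (fc in list(fe_c13, fe_c10))
    if (fc$closed[2] <= 0 || fc$open[2] <= 0)
      stop_loxdyn("distance sds must be positive", "loxdyn_spec_error")
  for (th in c(theta_closed, theta_open))
    if (th - 5 * sigma_theta <= 0 || th + 5 * sigma_theta >= 180)
      stop_loxdyn("state angle targets too close to 0/180 degrees",
                  "loxdyn_spec_error")
  structure(list(n_frames = as.integer(n_frames), dt = dt,
                 theta_closed = theta_closed, theta_open = theta_open,
                 sigma_theta = sigma_theta, p_open = p_open,
                 p_close = p_close, fe_c13 = fe_c13, fe_c10 = fe_c10,
                 scripted_contacts = scripted_contacts,
                 noise_sigma = noise_sigma, start_state = start_state,
                 preset = preset, seed = as.integer(seed)),
            class = "dynamics_spec")
}

#' Simulate a two-state trajectory over a toy complex
#'
#' Per frame, the state follows the closed/open Markov chain; the scaffold
#' and beta-barrel clouds are rigidly counter-rotated about the
#' catalytic-domain mass center so the realized opening angle equals the
#' state target plus `Normal(0, sigma_theta)`; the substrate C13/C10 atoms
#' are placed so their iron distances are draws from the state's
#' `(mean, sd)`; scripted contact residues are translated inside/outside
#' the contact distance; finally isotropic Gaussian noise is added to all
#' atoms. Identical seeds give identical trajectories.
#'
#' @param model a model from [build_toy_complex()].
#' @param dyn a [dynamics_spec()].
#' @return list with `trajectory` (a [trajectory()]), `labels`
#'   (character, `"closed"`/`"open"` per frame), `schedule` (logical
#'   n_frames x n_contacts matrix, or NULL), `dyn`.
#' @export
simulate_two_state_trajectory <- function(model, dyn = dynamics_spec()) {
  stopifnot(inherits(dyn, "dynamics_spec"))
  man <- attr(model, "manifest")
  if (is.null(man))
    stop_loxdyn("model must come from build_toy_complex()", "loxdyn_spec_error")
  part <- toy_partition(model)
  at <- model$atoms
  masses <- at$mass
  base <- model$xyz
  A0 <- center_of_mass(base, part$beta_barrel, masses)
  B0 <- center_of_mass(base, part$catalytic_domain, masses)
  C0 <- center_of_mass(base, part$scaffold, masses)
  theta0 <- vertex_angle(A0, B0, C0)
  axis <- unit(pracma_cross(A0 - B0, C0 - B0))
  ib <- as.integer(part$beta_barrel)
  is <- as.integer(part$scaffold)
  fe_idx <- as.integer(part$fe)
  has_sub <- !is.null(part$substrate_c13) && !is.null(part$substrate_c10)
  if (has_sub) {
    i13 <- as.integer(part$substrate_c13)
    i10 <- as.integer(part$substrate_c10)
    u13 <- unit(base[i13, ] - base[fe_idx, ])
    u10 <- unit(base[i10, ] - base[fe_idx, ])
  }
  sc <- dyn$scripted_contacts
  n_sc <- length(sc %||% list())
  res_idx <- function(chain, resid) which(at$chain == chain & at$resid == resid)

  with_seed(dyn$seed, {
    tt <- dyn$n_frames
    # state path
    labels <- character(tt)
    state <- dyn$start_state
    utrans <- stats::runif(tt)
    for (i in seq_len(tt)) {
      labels[i] <- state
      p <- if (state == "closed") dyn$p_open else dyn$p_close
      if (utrans[i] < p) state <- if (state == "closed") "open" else "closed"
    }
    targets <- ifelse(labels == "open", dyn$theta_open, dyn$theta_closed) +
      stats::rnorm(tt, 0, dyn$sigma_theta)
    targets <- pmin(pmax(targets, 0.5), 179.5)
    d13 <- d10 <- NULL
    if (has_sub) {
      m13 <- vapply(labels, function(s) dyn$fe_c13[[s]][1], numeric(1))
      s13 <- vapply(labels, function(s) dyn$fe_c13[[s]][2], numeric(1))
      m10 <- vapply(labels, function(s) dyn$fe_c10[[s]][1], numeric(1))
      s10 <- vapply(labels, function(s) dyn$fe_c10[[s]][2], numeric(1))
      d13 <- abs(stats::rnorm(tt, m13, s13))
      d10 <- abs(stats::rnorm(tt, m10, s10))
    }
    schedule <- if (n_sc > 0)
      matrix(FALSE, tt, n_sc,
             dimnames = list(NULL, vapply(sc, function(p)
               sprintf("%s:%d|%s:%d", p$chain_a, p$resid_a,
                       p$chain_b, p$resid_b), character(1))))
      else NULL
    if (n_sc > 0) {
      usc <- matrix(stats::runif(tt * n_sc), tt, n_sc)
      for (j in seq_len(n_sc)) {
        pc <- sc[[j]]$p_closed %||% 0
        po <- sc[[j]]$p_open %||% 1
        pj <- ifelse(labels == "closed", pc, po)
        schedule[, j] <- usc[, j] < pj
      }
    }
    n <- n_atoms(model)
    frames <- array(0, dim = c(tt, n, 3))
    noise <- array(stats::rnorm(tt * n * 3, 0, dyn$noise_sigma),
                   dim = c(tt, n, 3))
    for (i in seq_len(tt)) {
      xyz <- base
      delta <- (targets[i] - theta0) * pi / 180
      Rs <- rotation_about_axis(axis, delta / 2)
      Rb <- rotation_about_axis(axis, -delta / 2)
      xyz[is, ] <- sweep(sweep(xyz[is, , drop = FALSE], 2, B0) %*% t(Rs),
                         2, B0, FUN = "+")
      xyz[ib, ] <- sweep(sweep(xyz[ib, , drop = FALSE], 2, B0) %*% t(Rb),
                         2, B0, FUN = "+")
      if (has_sub) {
        xyz[i13, ] <- xyz[fe_idx, ] + u13 * d13[i]
        xyz[i10, ] <- xyz[fe_idx, ] + u10 * d10[i]
      }
      if (n_sc > 0) {
        for (j in seq_len(n_sc)) {
          p <- sc[[j]]
          ia <- res_idx(p$chain_a, p$resid_a)
          iB <- res_idx(p$chain_b, p$resid_b)
          if (length(ia) == 0L || length(iB) == 0L)
            stop_loxdyn("scripted contact names a missing residue",
                        "loxdyn_spec_error")
          dist <- if (schedule[i, j]) p$contact_dist %||% 3.5
                  else p$apart_dist %||% 10
          anchor <- xyz[ia[1], ]
          u <- unit(xyz[iB[1], ] - anchor)
          shift <- (anchor + u * dist) - xyz[iB[1], ]
          xyz[iB, ] <- sweep(xyz[iB, , drop = FALSE], 2, shift, FUN = "+")
        }
      }
      frames[i, , ] <- xyz
    }
    frames <- frames + noise
    traj <- trajectory(model, frames, times = (seq_len(tt) - 1L) * dyn$dt)
    list(trajectory = traj, labels = labels, schedule = schedule, dyn = dyn)
  })
}

#' State-conditional opening-angle shift
#'
#' Difference of the mean opening angle over open-state frames and
#' closed-state frames — the estimator used for parameter recovery against
#' the generator's known state labels.
#'
#' @param series an `angle_series`.
#' @param labels per-frame labels `"closed"`/`"open"`.
#' @return degrees (open minus closed).
#' @export
state_conditional_shift <- function(series, labels) {
  if (nrow(series) != length(labels))
    stop_loxdyn("labels length must match series", "loxdyn_shape_error")
  if (!any(labels == "open") || !any(labels == "closed"))
    stop_loxdyn("need both states present", "loxdyn_domain_error")
  mean(series$theta[labels == "open"]) - mean(series$theta[labels == "closed"])
}

#' Write a fixture directory
#'
#' Writes `toy_complex.pdb`, `traj.pdb` (multi-model), `states.tsv` and
#' `manifest.json`; re-reading reproduces the inputs within PDB precision
#' (1e-3 Angstrom).
#'
#' @param model model from [build_toy_complex()].
#' @param traj a [trajectory()] over it.
#' @param labels per-frame state labels.
#' @param out_dir output directory (created if missing).
#' @return named list of file paths, invisibly.
#' @export
write_fixture <- function(model, traj, labels, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- list(structure = file.path(out_dir, "toy_complex.pdb"),
                trajectory = file.path(out_dir, "traj.pdb"),
                states = file.path(out_dir, "states.tsv"),
                manifest = file.path(out_dir, "manifest.json"))
  write_structure(model, paths$structure)
  write_trajectory(traj, paths$trajectory)
  utils::write.table(data.frame(frame = seq_along(labels), state = labels),
                     paths$states, sep = "\t", quote = FALSE, row.names = FALSE)
  man <- attr(model, "manifest")
  man$n_frames <- n_frames(traj)
  jsonlite::write_json(man, paths$manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
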