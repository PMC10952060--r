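# coarse residue-charge model and screened-Coulomb (Debye-Hueckel) potentials
#
# This is a deliberately coarse characterization of interface electrostatics:
# one formal charge per ionizable residue, linear Debye-Hueckel screening.
# Outputs carry the tag "DH-coarse" and support directional comparisons
# (e.g. whether a Pro->Glu substitution makes an interface patch more
# negative), never absolute Poisson-Boltzmann magnitudes.

#' Bjerrum length
#'
#' Distance at which two elementary charges interact with thermal energy kT:
#' `e^2 / (4 pi eps0 eps_r kB T)`. About 7.1 Angstrom in water at 300 K.
#'
#' @param dielectric relative dielectric constant.
#' @param temperature Kelvin.
#' @return Angstrom.
#' @export
bjerrum_length <- function(dielectric = 78.5, temperature = 300) {
  # e^2/(4 pi eps0 kB) = 1.671010e5 Angstrom * Kelvin
  1.671010e5 / (dielectric * temperature)
}

#' Inverse Debye screening length
#'
#' @inheritParams bjerrum_length
#' @param ionic_strength mol/L of 1:1 electrolyte.
#' @return kappa in 1/Angstrom.
#' @export
debye_kappa <- function(ionic_strength = 0.15, dielectric = 78.5,
                        temperature = 300) {
  lB <- bjerrum_length(dielectric, temperature)
  # number density per Angstrom^3 per mol/L: N_A / 1e27
  sqrt(8 * pi * lB * 6.02214076e-4 * ionic_strength)
}

.charge_sidechain <- list(
  ASP = list(q = -1, atoms = c("CG", "OD1", "OD2")),
  GLU = list(q = -1, atoms = c("CD", "OE1", "OE2")),
  LYS = list(q = +1, atoms = "NZ"),
  ARG = list(q = +1, atoms = c("NH1", "NH2")),
  HIS = list(q = 0, atoms = c("ND1", "NE2")))

.known_neutral <- c("FE", "HOH", "DOPC", "DOPE", "SAPE", "SAP", "TUN", "LIP",
                    "WAL")

#' Assign coarse formal charges to a structure
#'
#' Residue scheme: Asp/Glu carry -1 at the side-chain carboxylate centroid
#' (falling back to the residue centroid when side-chain atoms are absent,
#' as in pseudo-atom models), Lys/Arg carry +1 at the terminal-nitrogen
#' centroid, His carries `his_charge` (default 0: pKa near 6 at
#' physiological pH), all other residues 0. Termini are ignored. Unknown
#' residue codes trigger one warning and get charge 0.
#'
#' @param model a [structure_model()].
#' @param scheme currently only `"residue"`.
#' @param his_charge elementary charges on histidine (e.g. 0.1 to model
#'   partial protonation).
#' @return object of class `charge_set`: data.frame `chain, resid, resname,
#'   charge, x, y, z` with one row per charged site; attribute `scheme`.
#' @export
assign_coarse_charges <- function(model, scheme = "residue", his_charge = 0) {
  scheme <- match.arg(scheme, "residue")
  at <- model$atoms
  key <- paste(at$chain, at$resid, sep = ":")
  rows <- list()
  unknown <- character(0)
  for (k in unique(key)) {
    idx <- which(key == k)
    resname <- at$resname[idx[1]]
    q <- 0
    site_idx <- idx
    if (resname %in% names(.charge_sidechain)) {
      info <- .charge_sidechain[[resname]]
      q <- if (resname == "HIS") his_charge else info$q
      sc <- idx[at$name[idx] %in% info$atoms]
      if (length(sc)) site_idx <- sc
    } else if (!(resname %in% .standard_aa) && !(resname %in% .known_neutral)) {
      unknown <- c(unknown, resname)
    }
    if (q != 0) {
      site <- colMeans(model$xyz[site_idx, , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        chain = at$chain[idx[1]], resid = at$resid[idx[1]], resname = resname,
        charge = q, x = site[1], y = site[2], z = site[3],
        stringsAsFactors = FALSE)
    }
  }
  if (length(unknown))
    warning("unknown residue codes assigned charge 0: ",
            paste(sort(unique(unknown)), collapse = ", "))
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(chain = character(0), resid = integer(0),
                         resname = character(0), charge = numeric(0),
                         x = numeric(0), y = numeric(0), z = numeric(0),
                         stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "scheme") <- scheme
  class(out) <- c("charge_set", "data.frame")
  out
}

#' Screened-Coulomb potential at sample points
#'
#' `phi(r) = sum_i q_i * (l_B / |r - r_i|) * exp(-kappa |r - r_i|)` in kT/e,
#' with Bjerrum length `l_B` and Debye constant `kappa` from the ionic
#' strength. Linear Debye-Hueckel theory — a coarse stand-in for full
#' Poisson-Boltzmann solutions, tagged `"DH-coarse"`.
#'
#' @param charges a `charge_set` (or data.frame with `charge, x, y, z`).
#' @param points K x 3 matrix of evaluation points, Angstrom; no point may
#'   lie within 0.1 Angstrom of a charge site.
#' @param dielectric,ionic_strength,temperature medium parameters.
#' @return object of class `potential_sample`: list with `points`, `phi`
#'   (kT/e), `parameters`, `model = "DH-coarse"`.
#' @export
screened_potential <- function(charges, points, dielectric = 78.5,
                               ionic_strength = 0.15, temperature = 300) {
  points <- matrix(as.numeric(points), ncol = 3L)
  lB <- bjerrum_length(dielectric, temperature)
  kap <- debye_kappa(ionic_strength, dielectric, temperature)
  phi <- numeric(nrow(points))
  if (nrow(charges)) {
    sites <- as.matrix(charges[, c("x", "y", "z")])
    d <- sqrt(cross_dist2(points, sites))
    close <- which(d < 0.1, arr.ind = TRUE)
    if (nrow(close))
      stop_loxdyn(paste0(
        "evaluation point(s) within 0.1 A of charge site(s): point ",
        paste(unique(close[, 1]), collapse = ","), " near site ",
        paste(unique(close[, 2]), collapse = ",")), "loxdyn_singularity_error")
    phi <- as.numeric((lB * exp(-kap * d) / d) %*% charges$charge)
  }
  structure(list(points = points, phi = phi,
                 parameters = list(dielectric = dielectric,
                                   ionic_strength = ionic_strength,
                                   temperature = temperature,
                                   bjerrum_length = lB, kappa = kap),
                 model = "DH-coarse"),
            class = "potential_sample")
}

#' Potential summary over a residue patch
#'
#' Samples `n_points` directions uniformly on a sphere of `shell_radius`
#' around the centroid of the residue set, discards points inside any atom
#' or within 0.1 Angstrom of a charge site, and summarizes the
#' screened-Coulomb potential over the survivors. Deterministic for a given
#' seed.
#'
#' @param model a [structure_model()].
#' @param residue_set non-empty [atom_set()] defining the patch.
#' @param shell_radius Angstrom.
#' @param n_points points sampled on the shell.
#' @param seed integer RNG seed.
#' @param charges optional precomputed `charge_set` (default:
#'   [assign_coarse_charges()] of the model).
#' @inheritParams screened_potential
#' @return list with `mean`, `min`, `max` (kT/e), `n_used`, `parameters`,
#'   `model = "DH-coarse"`.
#' @export
patch_potential_summary <- function(model, residue_set, shell_radius = 5.0,
                                    n_points = 256, seed = 1, charges = NULL,
                                    dielectric = 78.5, ionic_strength = 0.15,
                                    temperature = 300) {
  idx <- as.integer(residue_set)
  if (length(idx) == 0L)
    stop_loxdyn("residue set is empty", "loxdyn_domain_error")
  if (is.null(charges)) charges <- assign_coarse_charges(model)
  centroid <- colMeans(model$xyz[idx, , drop = FALSE])
  dirs <- with_seed(seed, {
    m <- matrix(stats::rnorm(3 * n_points), ncol = 3L)
    m / sqrt(rowSums(m^2))
  })
  pts <- sweep(dirs * shell_radius, 2, centroid, FUN = "+")
  # discard points inside any atom
  d <- sqrt(cross_dist2(pts, model$xyz))
  inside <- rowSums(sweep(d, 2, model$atoms$vdw_radius, "<")) > 0
  pts <- pts[!inside, , drop = FALSE]
  if (nrow(charges)) {
    ds <- sqrt(cross_dist2(pts, as.matrix(charges[, c("x", "y", "z")])))
    pts <- pts[rowSums(ds < 0.1) == 0, , drop = FALSE]
  }
  if (nrow(pts) == 0L)
    stop_loxdyn("all shell points discarded (buried patch)", "loxdyn_geometry_error")
  ps <- screened_potential(charges, pts, dielectric, ionic_strength, temperature)
  list(mean = mean(ps$phi), min = min(ps$phi), max = max(ps$phi),
       n_used = nrow(pts), parameters = ps$parameters, model = "DH-coarse")
}

#' Charge-only point mutation of a residue
#'
#' Replaces the residue name (all atoms of the residue) without touching
#' coordinates — no side-chain rebuild; the mutation changes the coarse
#' charge model only.
#'
#' @param model a [structure_model()].
#' @param chain chain identifier.
#' @param resid residue number (PDB convention).
#' @param new_residue_code 3-letter standard amino-acid code.
#' @return modified [structure_model()].
#' @export
apply_mutation <- function(model, chain, resid, new_residue_code) {
  code <- toupper(new_residue_code)
  if (!(code %in% .standard_aa))
    stop_loxdyn(paste0("unknown residue code: ", new_residue_code),
                "loxdyn_domain_error")
  hit <- model$atoms$chain == chain & model$atoms$resid == resid
  if (!any(hit))
    stop_loxdyn(sprintf("no residue %s:%d in model", chain, resid),
                "loxdyn_domain_error")
  model$atoms$resname[hit] <- code
  model
}

#' Potential change caused by a point mutation
#'
#' `delta_phi = phi(mutant charges) - phi(wild-type charges)` at the given
#' probe points, with coordinates unchanged (charge-only mutation). E.g. a
#' Pro->Glu substitution adds one -1 charge, so `delta_phi < 0` at every
#' finite point.
#'
#' @inheritParams apply_mutation
#' @param probe_points K x 3 matrix, Angstrom.
#' @param his_charge forwarded to [assign_coarse_charges()].
#' @inheritParams screened_potential
#' @return list with `delta` (kT/e per point), `phi_wt`, `phi_mut`,
#'   `parameters`.
#' @export
charge_mutation_delta <- function(model, chain, resid, new_residue_code,
                                  probe_points, his_charge = 0,
                                  dielectric = 78.5, ionic_strength = 0.15,
                                  temperature = 300) {
  mut <- apply_mutation(model, chain, resid, new_residue_code)
  qw <- assign_coarse_charges(model, his_charge = his_charge)
  qm <- assign_coarse_charges(mut, his_charge = his_charge)
  pw <- screened_potential(qw, probe_points, dielectric, ionic_strength, temperature)
  pm <- screened_potential(qm, probe_points, dielectric, ionic_strength, temperature)
  list(delta = pm$phi - pw$phi, phi_wt = pw$phi, phi_mut = pm$phi,
       parameters = pw$parameters)
}
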