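# helper: full side-chain aspartate + lysine peptide with explicit sites
make_charged_peptide <- function() {
  make_model(
    names = c("CA", "CG", "OD1", "OD2", "CA", "NZ", "CA"),
    elements = c("C", "C", "O", "O", "C", "N", "C"),
    resnames = c("ASP", "ASP", "ASP", "ASP", "LYS", "LYS", "GLY"),
    resids = c(1L, 1L, 1L, 1L, 2L, 2L, 3L),
    chains = rep("A", 7),
    xyz = rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0.5, 0), c(2, -0.5, 0),
                c(10, 0, 0), c(12, 0, 0), c(20, 0, 0)))
}

test_that("coarse charges follow the residue scheme with side-chain sites", {
  q <- assign_coarse_charges(make_charged_peptide())
  expect_equal(sum(q$charge), 0)  # one Asp + one Lys
  asp <- q[q$resname == "ASP", ]
  expect_equal(asp$charge, -1)
  expect_equal(c(asp$x, asp$y, asp$z), c(5 / 3, 0, 0))  # CG/OD1/OD2 centroid
  lys <- q[q$resname == "LYS", ]
  expect_equal(lys$charge, 1)
  expect_equal(lys$x, 12)  # NZ site
})

test_that("neutral chains carry no charges and unknown codes warn", {
  m <- make_model(rep("CA", 3), rep("C", 3), rep("GLY", 3), 1:3,
                  rep("A", 3), matrix(rnorm(9), ncol = 3))
  expect_equal(nrow(assign_coarse_charges(m)), 0L)
  m2 <- make_model("CA", "C", "XYZ", 1L, "A", matrix(0, 1, 3))
  expect_warning(assign_coarse_charges(m2), "XYZ")
})

test_that("histidine charge is configurable and defaults to neutral", {
  m <- make_model(c("CA", "ND1", "NE2"), c("C", "N", "N"), rep("HIS", 3),
                  rep(1L, 3), rep("A", 3),
                  rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  expect_equal(nrow(assign_coarse_charges(m)), 0L)
  q <- assign_coarse_charges(m, his_charge = 0.1)
  expect_equal(q$charge, 0.1)
  expect_equal(q$x, 1.5)  # ND1/NE2 centroid
})

test_that("a unit charge at one Bjerrum length gives exactly 1 kT/e unscreened", {
  q <- data.frame(chain = "A", resid = 1L, resname = "LYS", charge = 1,
                  x = 0, y = 0, z = 0)
  lB <- bjerrum_length(78.5, 300)
  ps <- screened_potential(q, matrix(c(lB, 0, 0), 1), ionic_strength = 0)
  expect_equal(ps$phi, 1.0, tolerance = 1e-12)
  expect_identical(ps$model, "DH-coarse")
})

test_that("screened potential matches an independent closed-form evaluation", {
  # closed form coded separately from the implementation
  phi_ref <- function(r, eps, temp, ionic) {
    lB <- 1.671010e5 / (eps * temp)
    kap <- sqrt(8 * pi * lB * 6.02214076e-4 * ionic)
    (lB / r) * exp(-kap * r)
  }
  q <- data.frame(chain = "A", resid = 1L, resname = "ARG", charge = 1,
                  x = 0, y = 0, z = 0)
  ps <- screened_potential(q, matrix(c(10, 0, 0), 1), dielectric = 78.5,
                           ionic_strength = 0.15, temperature = 300)
  expect_equal(ps$phi, phi_ref(10, 78.5, 300, 0.15), tolerance = 1e-9)
  expect_equal(ps$parameters$kappa, sqrt(8 * pi * ps$parameters$bjerrum_length *
                                           6.02214076e-4 * 0.15))
})

test_that("potentials superpose exactly and zero charges give zero field", {
  set.seed(41)
  mk <- function(df) { df }
  qa <- data.frame(chain = "A", resid = 1:3, resname = "ASP", charge = -1,
                   x = rnorm(3), y = rnorm(3), z = rnorm(3))
  qb <- data.frame(chain = "B", resid = 4:5, resname = "LYS", charge = 1,
                   x = rnorm(2) + 5, y = rnorm(2), z = rnorm(2))
  pts <- matrix(rnorm(30, sd = 20), ncol = 3)
  pa <- screened_potential(qa, pts)$phi
  pb <- screened_potential(qb, pts)$phi
  pab <- screened_potential(rbind(qa, qb), pts)$phi
  expect_equal(pab, pa + pb, tolerance = 1e-12)
  q0 <- qa; q0$charge <- 0
  expect_equal(screened_potential(q0, pts)$phi, rep(0, 10))
})

test_that("screening monotonically damps a single-charge potential", {
  q <- data.frame(chain = "A", resid = 1L, resname = "GLU", charge = -1,
                  x = 0, y = 0, z = 0)
  pts <- matrix(c(5, 0, 0, 0, 12, 0, 3, 4, 0), ncol = 3, byrow = TRUE)
  prev <- abs(screened_potential(q, pts, ionic_strength = 0)$phi)
  for (ionic in c(0.01, 0.05, 0.15, 0.5, 1)) {
    cur <- abs(screened_potential(q, pts, ionic_strength = ionic)$phi)
    expect_true(all(cur <= prev + 1e-15))
    prev <- cur
  }
})

test_that("evaluation points on top of charge sites are rejected", {
  q <- data.frame(chain = "A", resid = 1L, resname = "GLU", charge = -1,
                  x = 0, y = 0, z = 0)
  expect_error(screened_potential(q, matrix(c(0.05, 0, 0), 1)),
               class = "loxdyn_singularity_error")
})

test_that("patch summary matches the closed form for a centered charge", {
  m <- make_model("CA", "C", "GLY", 1L, "A", matrix(0, 1, 3), vdw = 1.0)
  q1 <- data.frame(chain = "A", resid = 1L, resname = "ASP", charge = -1,
                   x = 0, y = 0, z = 0)
  s <- patch_potential_summary(m, atom_set(1L), shell_radius = 5,
                               n_points = 128, seed = 3, charges = q1,
                               ionic_strength = 0)
  lB <- bjerrum_length(78.5, 300)
  expect_equal(s$mean, -lB / 5, tolerance = 1e-9)
  expect_equal(s$min, s$max, tolerance = 1e-9)  # all points equidistant
  # neutral model: zero mean
  s0 <- patch_potential_summary(m, atom_set(1L), shell_radius = 5,
                                n_points = 64, seed = 3)
  expect_equal(s0$mean, 0)
  # adding a second negative charge strictly lowers the mean
  q2 <- rbind(q1, data.frame(chain = "A", resid = 2L, resname = "ASP",
                             charge = -1, x = 2, y = 0, z = 0))
  s2 <- patch_potential_summary(m, atom_set(1L), shell_radius = 5,
                                n_points = 128, seed = 3, charges = q2,
                                ionic_strength = 0)
  expect_lt(s2$mean, s$mean)
})

test_that("patch summary is deterministic in its seed", {
  model <- build_toy_complex(complex_spec(seed = 12))
  patch <- select_atoms(model, "chain P and resid 112")
  a <- patch_potential_summary(model, patch, seed = 9)
  b <- patch_potential_summary(model, patch, seed = 9)
  expect_identical(a, b)
})

test_that("charge-only mutations give closed-form potential deltas", {
  m <- make_model(c("CA", "CA"), c("C", "C"), c("PRO", "ALA"), c(1L, 2L),
                  c("P", "P"), rbind(c(0, 0, 0), c(30, 0, 0)))
  pt <- matrix(c(6, 0, 0), 1)
  lB <- bjerrum_length(78.5, 300)
  d <- charge_mutation_delta(m, "P", 1L, "GLU", pt, ionic_strength = 0)
  expect_equal(d$delta, -lB / 6, tolerance = 1e-9)
  expect_equal(charge_mutation_delta(m, "P", 1L, "ALA", pt)$delta, 0)
  masp <- make_model(c("CA", "CA"), c("C", "C"), c("ASP", "GLY"), c(1L, 2L),
                     c("P", "P"), rbind(c(0, 0, 0), c(30, 0, 0)))
  d2 <- charge_mutation_delta(masp, "P", 1L, "ALA", pt, ionic_strength = 0)
  expect_gt(d2$delta, 0)  # removing a -1 charge raises the potential
  expect_error(charge_mutation_delta(m, "P", 1L, "XXX", pt),
               class = "loxdyn_domain_error")
  expect_error(charge_mutation_delta(m, "Q", 7L, "GLU", pt),
               class = "loxdyn_domain_error")
})

test_that("Pro->Glu at the toy interface makes the patch mean more negative", {
  model <- build_toy_complex(complex_spec(seed = 12))
  patch <- select_atoms(model, "chain P and resid 112")
  expect_length(patch, 1L)
  wt <- patch_potential_summary(model, patch, seed = 4)
  mut <- patch_potential_summary(apply_mutation(model, "P", 112L, "GLU"),
                                 patch, seed = 4)
  expect_lt(mut$mean, wt$mean)
})
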