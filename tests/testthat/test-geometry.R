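test_that("center_of_mass is the mass-weighted mean", {
  xyz <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 4, 0))
  expect_equal(center_of_mass(xyz, atom_set(1:2), c(1, 1, 1)), c(1, 0, 0))
  expect_equal(center_of_mass(xyz, atom_set(c(1, 3)), c(1, 3, 3))[2], 3)
  expect_equal(center_of_mass(xyz, atom_set(2L), c(5, 7, 9)), c(2, 0, 0))
  expect_error(center_of_mass(xyz, atom_set(integer(0)), rep(1, 3)),
               class = "loxdyn_domain_error")
})

test_that("kabsch recovers rigid motions exactly", {
  set.seed(1)
  ref <- matrix(rnorm(15), ncol = 3)
  fit <- kabsch_superpose(ref, ref)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)  # 90 deg about z
  mob <- sweep(ref %*% t(Rz), 2, c(3, 4, 0), FUN = "+")
  fit2 <- kabsch_superpose(ref, mob)
  expect_lt(fit2$rmsd, 1e-10)
  expect_equal(det(fit2$rotation), 1, tolerance = 1e-9)
})

test_that("kabsch rejects degenerate geometry", {
  expect_error(kabsch_superpose(matrix(rnorm(6), 2), matrix(rnorm(6), 2)),
               class = "loxdyn_degenerate_error")
  line <- cbind(1:4, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear",
               class = "loxdyn_degenerate_error")
})

test_that("kabsch rmsd is the global minimum (rotation-search oracle)", {
  # independent oracle: coarse axis-angle grid + Nelder-Mead refinement of
  # the best grid point, both over explicit rotations
  oracle_rmsd <- function(ref, mob) {
    cr <- colMeans(ref); cm <- colMeans(mob)
    A <- sweep(ref, 2, cr); B <- sweep(mob, 2, cm)
    rmsd_of <- function(p) {
      ang <- sqrt(sum(p^2))
      R <- if (ang < 1e-12) diag(3) else {
        ax <- p / ang
        K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
        diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
      }
      sqrt(mean(rowSums((B %*% R - A)^2)))
    }
    axes <- rbind(diag(3), -diag(3),
                  matrix(rnorm(3 * 60), ncol = 3))
    axes <- axes / sqrt(rowSums(axes^2))
    angs <- seq(0, pi, length.out = 25)
    best <- c(0, 0, 0); bv <- rmsd_of(best)
    for (i in seq_len(nrow(axes))) for (a in angs) {
      p <- axes[i, ] * a
      v <- rmsd_of(p)
      if (v < bv) { bv <- v; best <- p }
    }
    stats::optim(best, rmsd_of, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 5000))$value
  }
  set.seed(7)
  for (rep in 1:5) {
    np <- sample(4:6, 1)
    ref <- matrix(rnorm(3 * np, sd = 3), ncol = 3)
    mob <- ref
    mob[1, ] <- mob[1, ] + rnorm(3)  # displace one point ~1 A
    motion <- random_rigid_motion()
    mob <- apply_rigid(mob, motion)
    k <- kabsch_superpose(ref, mob)$rmsd
    o <- oracle_rmsd(ref, mob)
    expect_equal(k, o, tolerance = 1e-3)
    expect_lte(k, o + 1e-9)  # never above any explicit rotation
  }
})

test_that("rmsd_series is zero on rigid copies and recovers noise level", {
  set.seed(3)
  n <- 500L
  m <- make_model(rep("CA", n), rep("C", n), rep("GLY", n), seq_len(n),
                  rep("A", n), matrix(rnorm(3 * n, sd = 8), ncol = 3))
  frames <- lapply(1:10, function(i) apply_rigid(m$xyz, random_rigid_motion()))
  tr <- traj_from_frames(m, frames)
  rs <- rmsd_series(tr, atom_set(seq_len(n)), reference_frame = 1L)
  expect_lt(max(rs$rmsd), 1e-8)
  expect_equal(rs$rmsd[1], 0)
  # isotropic sigma = 1 A noise: mean RMSD ~ sqrt(3) within 5 %
  noisy <- lapply(1:30, function(i) m$xyz + matrix(rnorm(3 * n), ncol = 3))
  rs2 <- rmsd_series(traj_from_frames(m, c(list(m$xyz), noisy)),
                     atom_set(seq_len(n)), reference_frame = 1L)
  expect_equal(mean(rs2$rmsd[-1]), sqrt(3), tolerance = 0.05)
  expect_error(rmsd_series(tr, atom_set(seq_len(n)), reference_frame = 99L),
               class = "loxdyn_range_error")
})

test_that("stability triage maps median RMSD bands to labels", {
  mk <- function(level) data.frame(time_ns = 0:99, rmsd = rep(level, 100))
  expect_equal(classify_stability(mk(3.5))$label, "stable")
  expect_equal(classify_stability(mk(6.0))$label, "intermediate")
  expect_equal(classify_stability(mk(13.5))$label, "unstable")
  # boundary: exactly 3 x stable_cut is unstable
  expect_equal(classify_stability(mk(13.5), stable_cut = 4.5,
                                  unstable_factor = 3)$median_rmsd, 13.5)
})

test_that("stability label is monotone under uniformly increased RMSD", {
  set.seed(5)
  rank_of <- c(stable = 1L, intermediate = 2L, unstable = 3L)
  for (rep in 1:20) {
    r <- abs(rnorm(60, mean = runif(1, 1, 15), sd = 2))
    s1 <- data.frame(time_ns = seq_along(r), rmsd = r)
    s2 <- data.frame(time_ns = seq_along(r), rmsd = r + runif(1, 0, 10))
    expect_gte(rank_of[classify_stability(s2)$label],
               rank_of[classify_stability(s1)$label])
  }
})

test_that("opening angle matches closed-form vector geometry", {
  tb <- make_three_body(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0))
  ser <- opening_angle_series(one_frame_traj(tb$model), tb$partition)
  expect_equal(ser$theta, 90, tolerance = 1e-9)
  tb2 <- make_three_body(c(0, 0, 0), c(2, 0, 0), c(4, 0, 0))
  expect_equal(opening_angle_series(one_frame_traj(tb2$model),
                                    tb2$partition)$theta, 180,
               tolerance = 1e-9)
  tb3 <- make_three_body(c(1, 0, 0), c(0, 0, 0), c(1, 1, 0))
  expect_equal(opening_angle_series(one_frame_traj(tb3$model),
                                    tb3$partition)$theta, 45,
               tolerance = 1e-9)
})

test_that("opening angle errors on coincident centers", {
  tb <- make_three_body(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))
  expect_error(opening_angle_series(one_frame_traj(tb$model), tb$partition),
               class = "loxdyn_degenerate_error")
})

test_that("opening angle is rigid-motion invariant", {
  set.seed(9)
  model <- build_toy_complex(complex_spec(
    atoms_per_domain = c(10, 10, 10), n_lipids = 0, substrate = FALSE,
    seed = 4))
  part <- toy_partition(model)
  base <- opening_angle_series(one_frame_traj(model), part)$theta
  for (rep in 1:100) {
    moved <- apply_rigid(model$xyz, random_rigid_motion())
    m2 <- model; m2$xyz <- moved
    th <- opening_angle_series(one_frame_traj(m2), part)$theta
    expect_equal(th, base, tolerance = 1e-9)
  }
})

test_that("angle_shift has the documented sign convention and null", {
  s <- data.frame(time_ns = 0:99, theta = runif(100, 80, 100))
  class(s) <- c("angle_series", "data.frame")
  expect_identical(angle_shift(s, s), 0)
  s2 <- s; s2$theta <- s$theta + 7
  expect_equal(angle_shift(s, s2), 7, tolerance = 1e-12)
  expect_equal(angle_shift(s2, s), -7, tolerance = 1e-12)
})

test_that("substrate-preset dynamics close the complex (negative shift)", {
  model <- build_toy_complex(complex_spec(seed = 6))
  part <- toy_partition(model)
  memb <- simulate_two_state_trajectory(
    model, dynamics_spec(preset = "membrane", n_frames = 400, p_open = 0.05,
                         p_close = 0, seed = 8))
  subs <- simulate_two_state_trajectory(
    model, dynamics_spec(preset = "substrate", n_frames = 400, seed = 8))
  sm <- opening_angle_series(memb$trajectory, part)
  ss <- opening_angle_series(subs$trajectory, part)
  expect_lt(angle_shift(sm, ss), 0)
})
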