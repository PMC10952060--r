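# residues with several atoms each, built explicitly
two_group_model <- function(offsets_a, offsets_b, gap) {
  # group A residues along x < 0, group B at x >= gap
  na <- length(offsets_a); nb <- length(offsets_b)
  xyz <- rbind(
    do.call(rbind, lapply(seq_len(na), function(i)
      sweep(offsets_a[[i]], 2, c(-2 * i, 0, 0), FUN = "+"))),
    do.call(rbind, lapply(seq_len(nb), function(i)
      sweep(offsets_b[[i]], 2, c(gap + 2 * (i - 1), 0, 0), FUN = "+"))))
  counts_a <- vapply(offsets_a, nrow, 1L)
  counts_b <- vapply(offsets_b, nrow, 1L)
  m <- make_model(
    names = c(unlist(lapply(counts_a, function(k) paste0("A", seq_len(k)))),
              unlist(lapply(counts_b, function(k) paste0("B", seq_len(k))))),
    elements = rep("C", sum(counts_a) + sum(counts_b)),
    resnames = rep("GLY", sum(counts_a) + sum(counts_b)),
    resids = c(rep(seq_len(na), counts_a), rep(seq_len(nb), counts_b)),
    chains = c(rep("A", sum(counts_a)), rep("B", sum(counts_b))),
    xyz = xyz)
  list(model = m,
       set_a = atom_set(seq_len(sum(counts_a))),
       set_b = atom_set(sum(counts_a) + seq_len(sum(counts_b))))
}

test_that("contact_map applies the minimum heavy-atom distance criterion", {
  pt <- function(...) matrix(c(...), ncol = 3, byrow = TRUE)
  g <- two_group_model(list(pt(0, 0, 0)), list(pt(0, 0, 0)), gap = 2.0)
  cm <- contact_map(g$model, g$set_a, g$set_b)
  expect_equal(nrow(cm), 1L)
  expect_equal(cm$min_distance, 4.0)  # A1 at x=-2, B1 at x=+2
  g2 <- two_group_model(list(pt(0, 0, 0)), list(pt(0, 0, 0)), gap = 3.0)
  expect_equal(nrow(contact_map(g2$model, g2$set_a, g2$set_b)), 0L)
  expect_error(contact_map(g$model, g$set_a, g$set_a),
               class = "loxdyn_domain_error")
})

test_that("contact_map equals an exhaustive all-residue-pairs oracle", {
  set.seed(21)
  pt <- function(n) matrix(rnorm(3 * n, sd = 2), ncol = 3)
  g <- two_group_model(list(pt(3), pt(2), pt(4)), list(pt(3), pt(2)), gap = 3)
  at <- g$model$atoms
  cutoff <- 4.5
  oracle <- list()
  for (ra in unique(at$resid[as.integer(g$set_a)]))
    for (rb in unique(at$resid[as.integer(g$set_b)])) {
      ia <- intersect(as.integer(g$set_a), which(at$resid == ra))
      ib <- intersect(as.integer(g$set_b), which(at$resid == rb))
      dm <- min(sqrt(outer(rowSums(g$model$xyz[ia, , drop = FALSE]^2),
                           rowSums(g$model$xyz[ib, , drop = FALSE]^2), "+") -
                       2 * g$model$xyz[ia, , drop = FALSE] %*%
                       t(g$model$xyz[ib, , drop = FALSE])))
      if (dm <= cutoff)
        oracle[[length(oracle) + 1L]] <- data.frame(resid_a = ra, resid_b = rb,
                                                    min_distance = dm)
    }
  oracle <- do.call(rbind, oracle)
  oracle <- oracle[order(oracle$resid_a, oracle$resid_b), ]
  cm <- contact_map(g$model, g$set_a, g$set_b, cutoff = cutoff)
  expect_equal(cm$resid_a, oracle$resid_a)
  expect_equal(cm$resid_b, oracle$resid_b)
  expect_equal(cm$min_distance, oracle$min_distance, tolerance = 1e-12)
})

test_that("contact_map is symmetric under swapping the two sets", {
  set.seed(22)
  pt <- function(n) matrix(rnorm(3 * n, sd = 2), ncol = 3)
  g <- two_group_model(list(pt(3), pt(2)), list(pt(2), pt(3)), gap = 2)
  ab <- contact_map(g$model, g$set_a, g$set_b)
  ba <- contact_map(g$model, g$set_b, g$set_a)
  key_ab <- sort(paste(ab$resid_a, ab$resid_b))
  key_ba <- sort(paste(ba$resid_b, ba$resid_a))
  expect_equal(key_ab, key_ba)
  expect_equal(sort(ab$min_distance), sort(ba$min_distance))
})

test_that("enlarging the cutoff never removes a contact pair", {
  set.seed(23)
  pt <- function(n) matrix(rnorm(3 * n, sd = 3), ncol = 3)
  g <- two_group_model(list(pt(3), pt(3), pt(3)), list(pt(3), pt(3)), gap = 4)
  prev <- character(0)
  for (cutoff in c(3, 4.5, 6, 9)) {
    cm <- contact_map(g$model, g$set_a, g$set_b, cutoff = cutoff)
    cur <- paste(cm$resid_a, cm$resid_b)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("contact_frequency normalizes by the maximum raw count", {
  pt <- function(...) matrix(c(...), ncol = 3, byrow = TRUE)
  g <- two_group_model(list(pt(0, 0, 0)), list(pt(0, 0, 0)), gap = 2.0)
  near <- g$model$xyz
  far <- near; far[2, 1] <- far[2, 1] + 10
  tr <- traj_from_frames(g$model, c(rep(list(near), 50), rep(list(far), 50)))
  cf <- contact_frequency(tr, g$set_a, g$set_b)
  expect_equal(nrow(cf), 1L)
  expect_equal(cf$frequency, 0.5)
  expect_equal(cf$normalized, 1.0)  # the only pair anchors the normalization
  expect_equal(cf$raw_count, 50L)
})

test_that("scripted contact frequencies match the generator schedule", {
  model <- build_toy_complex(complex_spec(seed = 31))
  sc <- list(
    list(chain_a = "A", resid_a = 201L, chain_b = "M", resid_b = 1L,
         p_closed = 0.8, p_open = 0.8),
    list(chain_a = "A", resid_a = 210L, chain_b = "M", resid_b = 2L,
         p_closed = 0.16, p_open = 0.16))
  sim <- simulate_two_state_trajectory(
    model, dynamics_spec(n_frames = 100, scripted_contacts = sc, seed = 31))
  cf <- contact_frequency(sim$trajectory,
                          select_atoms(model, "chain A"),
                          select_atoms(model, "chain M"))
  tt <- 100
  for (j in 1:2) {
    row <- cf[cf$resid_a == sc[[j]]$resid_a & cf$resid_b == sc[[j]]$resid_b, ]
    expect_equal(nrow(row), 1L)
    expect_lte(abs(row$frequency - mean(sim$schedule[, j])), 1 / tt)
  }
})

test_that("hydrogen bonds need both distance and angle when hydrogens exist", {
  mk <- function(apos) make_model(
    c("N", "H", "O"), c("N", "H", "O"), c("GLY", "GLY", "HOH"),
    c(1L, 1L, 2L), c("A", "A", "W"),
    rbind(c(0, 0, 0), c(0.98, 0, 0), apos))
  don <- atom_set(1L); acc <- atom_set(3L)
  hb <- detect_hbonds(mk(c(2.9, 0, 0)), don, acc)  # 180 deg, 2.9 A
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$distance, 2.9)
  expect_gte(hb$angle, 140)
  expect_equal(nrow(detect_hbonds(mk(c(3.6, 0, 0)), don, acc)), 0L)  # far
  expect_equal(nrow(detect_hbonds(mk(c(0.98, 2.0, 0)), don, acc)), 0L)  # 90 deg
  expect_error(detect_hbonds(mk(c(2.9, 0, 0)), atom_set(2L), acc),
               "non-N/O", class = "loxdyn_domain_error")
})

test_that("hydrogen-free models use the 3.2 A distance-only criterion", {
  m <- make_model(c("O", "O1"), c("O", "O"), c("GLY", "DOPC"), c(1L, 2L),
                  c("A", "M"), rbind(c(0, 0, 0), c(3.0, 0, 0)))
  hb <- detect_hbonds(m, atom_set(1L), atom_set(2L))
  expect_equal(nrow(hb), 1L)
  expect_true(is.na(hb$hydrogen))
  m$xyz[2, 1] <- 3.4  # beyond 3.2
  expect_equal(nrow(detect_hbonds(m, atom_set(1L), atom_set(2L))), 0L)
})

test_that("detected hbonds are a subset of N/O contacts at the same cutoff", {
  set.seed(24)
  n <- 12L
  m <- make_model(rep(c("N", "O"), n / 2), rep(c("N", "O"), n / 2),
                  rep("GLY", n), seq_len(n),
                  c(rep("A", n / 2), rep("M", n / 2)),
                  matrix(rnorm(3 * n, sd = 2.5), ncol = 3))
  don <- atom_set(seq_len(n / 2)); acc <- atom_set(n / 2 + seq_len(n / 2))
  hb <- detect_hbonds(m, don, acc, d_cut = 3.2)
  cm <- contact_map(m, don, acc, cutoff = 3.2)
  if (nrow(hb)) {
    hb_pairs <- paste(m$atoms$resid[hb$donor], m$atoms$resid[hb$acceptor])
    cm_pairs <- paste(cm$resid_a, cm$resid_b)
    expect_true(all(hb_pairs %in% cm_pairs))
  } else succeed()
})

test_that("hbond_reorganization reports gained and lost bonds with signs", {
  m <- make_model(c("O", "O1"), c("O", "O"), c("SER", "DOPC"), c(1L, 1L),
                  c("A", "M"), rbind(c(0, 0, 0), c(6, 0, 0)))
  prot <- atom_set(1L); lip <- atom_set(2L)
  near <- m$xyz; near[2, 1] <- 2.8
  far <- m$xyz
  gain <- traj_from_frames(m, c(rep(list(far), 5), rep(list(near), 5)))
  tab <- hbond_reorganization(gain, prot, lip, initial_window = 0.5,
                              final_window = 0.5)
  expect_equal(tab$delta, 1.0)
  loss <- traj_from_frames(m, c(rep(list(near), 5), rep(list(far), 5)))
  expect_equal(hbond_reorganization(loss, prot, lip, 0.5, 0.5)$delta, -1.0)
  static <- traj_from_frames(m, rep(list(near), 10))
  expect_equal(hbond_reorganization(static, prot, lip, 0.5, 0.5)$delta, 0)
})

test_that("hbond_reorganization validates its windows", {
  m <- make_model(c("O", "O1"), c("O", "O"), c("SER", "DOPC"), c(1L, 1L),
                  c("A", "M"), rbind(c(0, 0, 0), c(2.8, 0, 0)))
  tr <- traj_from_frames(m, rep(list(m$xyz), 10))
  expect_error(hbond_reorganization(tr, atom_set(1L), atom_set(2L),
                                    initial_window = 0.6, final_window = 0.6),
               class = "loxdyn_config_error")
  expect_error(hbond_reorganization(tr, atom_set(1L), atom_set(2L),
                                    initial_window = 0, final_window = 0.1),
               class = "loxdyn_config_error")
})
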