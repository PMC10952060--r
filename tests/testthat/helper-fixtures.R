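# fixtures built in code; nothing is read from disk except files the tests
# themselves write to tempdir()

# minimal model: atoms placed explicitly, metadata fully controlled
make_model <- function(names, elements, resnames, resids, chains, xyz,
                       vdw = NULL, masses = NULL) {
  atoms <- data.frame(name = names, element = elements, resname = resnames,
                      resid = resids, chain = chains,
                      stringsAsFactors = FALSE)
  if (!is.null(vdw)) atoms$vdw_radius <- vdw
  if (!is.null(masses)) atoms$mass <- masses
  structure_model(atoms, xyz)
}

# three single-atom bodies at given positions; returns model + partition
make_three_body <- function(a, b, c) {
  m <- make_model(c("CA", "CA", "CA"), c("C", "C", "C"),
                  c("GLY", "GLY", "GLY"), 1:3, c("B", "C", "P"),
                  rbind(a, b, c))
  list(model = m,
       partition = domain_partition(
         beta_barrel = atom_set(1L, "A"),
         catalytic_domain = atom_set(2L, "B"),
         scaffold = atom_set(3L, "C")))
}

one_frame_traj <- function(model) {
  trajectory(model, array(model$xyz, dim = c(1L, nrow(model$xyz), 3L)))
}

traj_from_frames <- function(model, frame_list) {
  tt <- length(frame_list)
  fr <- array(0, dim = c(tt, n_atoms(model), 3L))
  for (i in seq_len(tt)) fr[i, , ] <- frame_list[[i]]
  trajectory(model, fr)
}

random_rigid_motion <- function() {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  list(R = R, t = rnorm(3, sd = 10))
}

apply_rigid <- function(xyz, motion) {
  sweep(xyz %*% t(motion$R), 2, motion$t, FUN = "+")
}

# independent maximin oracle: largest clearance threshold at which the seed
# voxel still connects (6-neighborhood) to a boundary voxel, via igraph
# connected components
oracle_bottleneck <- function(clearance, dims, seed_voxel, probe) {
  stopifnot(requireNamespace("igraph", quietly = TRUE))
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  nv <- nx * ny * nz
  idx <- function(i, j, k) i + nx * ((j - 1L) + ny * (k - 1L))
  coords <- expand.grid(i = 1:nx, j = 1:ny, k = 1:nz)
  boundary <- with(coords, i == 1 | j == 1 | k == 1 |
                     i == nx | j == ny | k == nz)
  edges <- NULL
  for (d in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    ok <- coords$i + d[1] <= nx & coords$j + d[2] <= ny & coords$k + d[3] <= nz
    from <- idx(coords$i[ok], coords$j[ok], coords$k[ok])
    to <- idx(coords$i[ok] + d[1], coords$j[ok] + d[2], coords$k[ok] + d[3])
    edges <- rbind(edges, cbind(from, to))
  }
  s <- idx(seed_voxel[1], seed_voxel[2], seed_voxel[3])
  if (clearance[s] < probe) return(NA_real_)
  cand <- sort(unique(clearance[clearance >= probe]), decreasing = TRUE)
  for (thr in cand) {
    if (clearance[s] < thr) next
    keep <- clearance >= thr
    e <- edges[keep[edges[, 1]] & keep[edges[, 2]], , drop = FALSE]
    g <- igraph::graph_from_edgelist(e, directed = FALSE)
    if (length(igraph::V(g)) < nv)
      g <- igraph::add_vertices(g, nv - length(igraph::V(g)))
    comp <- igraph::components(g)$membership
    if (any(boundary & keep & comp == comp[s])) return(thr)
  }
  NA_real_
}

# direct clearance_grid construction for hand-built grids
hand_grid <- function(clearance_array, origin = c(0, 0, 0), spacing = 1) {
  structure(list(origin = origin, spacing = spacing,
                 dims = dim(clearance_array), clearance = clearance_array),
            class = "clearance_grid")
}
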