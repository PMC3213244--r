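# Synthetic inputs: every input type the toolkit consumes can be generated
# here deterministically, so no structure or map download is ever needed for
# building or testing.

#' Cubic lattice point model
#'
#' n_per_side^3 nodes on a cubic lattice; the minimal connected 3-D test
#' geometry for ENM construction (spacing = minimum pairwise distance).
#'
#' @param n_per_side nodes per edge (>= 2).
#' @param spacing lattice constant in Angstrom.
#' @return a `point_model`.
#' @export
make_lattice <- function(n_per_side = 3, spacing = 1) {
  stopifnot(n_per_side >= 2, spacing > 0)
  g <- expand.grid(x = seq_len(n_per_side), y = seq_len(n_per_side),
                   z = seq_len(n_per_side))
  point_model((as.matrix(g) - 1) * spacing,
              labels = sprintf("lat(%d,%d,%d)", g$x, g$y, g$z),
              source = "atoms")
}

#' Toy helical CA trace as a Structure
#'
#' Canonical helix x = r cos(k t), y = r sin(k t), z = rise * t; the
#' defaults (rise 1.5 A, twist 100 degrees, radius 2.3 A) approximate an
#' alpha-helical C-alpha trace. Residues are ALA on chain A with
#' sequential numbering, so the output writes as a toy PDB.
#'
#' @param n_residues number of CA atoms (>= 3).
#' @param rise translation per residue (Angstrom).
#' @param twist rotation per residue (degrees).
#' @param radius helix radius (Angstrom).
#' @param bfactor_profile optional per-residue B-factors; default a smooth
#'   bowl (flexible ends, rigid middle) mimicking real temperature factors.
#' @return an `enm_structure` of CA atoms.
#' @export
make_helix <- function(n_residues = 10, rise = 1.5, twist = 100,
                       radius = 2.3, bfactor_profile = NULL) {
  stopifnot(n_residues >= 3)
  t <- seq_len(n_residues) - 1
  ang <- twist * pi / 180 * t
  if (is.null(bfactor_profile)) {
    mid <- (n_residues + 1) / 2
    bfactor_profile <- 10 + 30 * ((t + 1 - mid) / mid)^2
  }
  structure_new(data.frame(
    serial = seq_len(n_residues), name = "CA", altloc = " ",
    resname = "ALA", chain = "A", resseq = seq_len(n_residues),
    icode = " ",
    x = radius * cos(ang), y = radius * sin(ang), z = rise * t,
    occupancy = 1, bfactor = bfactor_profile, element = "C",
    record = "ATOM", stringsAsFactors = FALSE))
}

#' Two-domain toy structure for hinge-motion tests
#'
#' Two compact lattice blobs joined by a short linker: the simplest
#' geometry with a clean low-frequency hinge mode. All atoms are CA/ALA.
#'
#' @param n_per_domain nodes per cubic domain edge.
#' @param spacing lattice constant (Angstrom).
#' @param gap distance between domain faces (Angstrom).
#' @return an `enm_structure`.
#' @export
make_two_domain <- function(n_per_domain = 3, spacing = 1.8, gap = 2.5) {
  a <- make_lattice(n_per_domain, spacing)$coords
  shift <- (n_per_domain - 1) * spacing + gap
  b <- sweep(a, 2, c(shift, 0, 0), `+`)
  xyz <- rbind(a, b)
  n <- nrow(xyz)
  structure_new(data.frame(
    serial = seq_len(n), name = "CA", altloc = " ", resname = "ALA",
    chain = "A", resseq = seq_len(n), icode = " ",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, bfactor = 15, element = "C", record = "ATOM",
    stringsAsFactors = FALSE))
}

#' Synthetic ensemble deformed along a known direction
#'
#' frame_k = base + amplitude_k * direction + Gaussian noise(sigma). The
#' generative model is a rank-1 deformation, so PCA recovery of
#' `direction` as PC1 is exactly checkable: with sigma = 0 and amplitudes
#' of non-zero variance, PC1 = +/- direction.
#'
#' @param points base `point_model` (N nodes).
#' @param direction 3N-vector, layout (x1, y1, z1, x2, ...); normalized if
#'   not already.
#' @param amplitudes per-frame scalar amplitudes (Angstrom).
#' @param noise_sigma isotropic Gaussian noise s.d. per coordinate
#'   (Angstrom).
#' @param seed RNG seed (mandatory when noise_sigma > 0).
#' @return an `enm_ensemble`.
#' @export
make_mode_ensemble <- function(points, direction, amplitudes,
                               noise_sigma = 0, seed = 1) {
  n <- n_nodes(points)
  stopifnot(length(direction) == 3 * n, length(amplitudes) >= 1,
            noise_sigma >= 0)
  direction <- direction / sqrt(sum(direction^2))
  dmat <- matrix(direction, ncol = 3, byrow = TRUE)
  base <- points_to_structure(points)
  set.seed(seed)
  frames <- lapply(seq_along(amplitudes), function(k) {
    s <- base
    disp <- amplitudes[k] * dmat
    if (noise_sigma > 0)
      disp <- disp + matrix(stats::rnorm(3 * n, sd = noise_sigma), n, 3)
    s$atoms$x <- s$atoms$x + disp[, 1]
    s$atoms$y <- s$atoms$y + disp[, 2]
    s$atoms$z <- s$atoms$z + disp[, 3]
    s$model_id <- k
    s
  })
  ensemble_new(frames)
}

#' Synthetic Gaussian-blob density grid
#'
#' Sum of isotropic Gaussians a_m exp(-|r - c_m|^2 / (2 sigma_m^2))
#' evaluated at voxel centers; emulates a low-resolution density map for
#' the contour-to-points pipeline.
#'
#' @param grid_shape integer(3) voxel counts along (x, y, z).
#' @param voxel_size numeric(3) or scalar, Angstrom per voxel.
#' @param centers M x 3 matrix of blob centers (world Angstrom).
#' @param sigmas length-M Gaussian widths (Angstrom).
#' @param amplitudes length-M peak amplitudes.
#' @param origin world coordinates of voxel (1,1,1) center.
#' @return a `density_grid`.
#' @export
make_blob_map <- function(grid_shape = c(8, 8, 8), voxel_size = 1,
                          centers = matrix(c(4, 4, 4), 1),
                          sigmas = 1.5, amplitudes = 1,
                          origin = c(0, 0, 0)) {
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  centers <- matrix(centers, ncol = 3)
  stopifnot(nrow(centers) == length(sigmas),
            length(sigmas) == length(amplitudes))
  ax <- lapply(1:3, function(a)
    origin[a] + (seq_len(grid_shape[a]) - 1) * voxel_size[a])
  vals <- array(0, dim = grid_shape)
  for (m in seq_len(nrow(centers))) {
    dx2 <- outer(outer((ax[[1]] - centers[m, 1])^2,
                       (ax[[2]] - centers[m, 2])^2, `+`),
                 (ax[[3]] - centers[m, 3])^2, `+`)
    vals <- vals + amplitudes[m] * exp(-dx2 / (2 * sigmas[m]^2))
  }
  density_grid(vals, voxel_size = voxel_size, origin = origin)
}

#' Random connected point cloud for property tests
#'
#' Gaussian point cloud regenerated until the cutoff contact graph is
#' connected (so GNM/ANM zero-mode counts are the theoretical 1 and 6).
#'
#' @param n node count.
#' @param cutoff connectivity cutoff used for the check (Angstrom).
#' @param spread cloud standard deviation (Angstrom).
#' @param seed RNG seed.
#' @return a `point_model`.
#' @export
make_random_cloud <- function(n = 30, cutoff = 7.3, spread = 4, seed = 1) {
  set.seed(seed)
  repeat {
    xyz <- matrix(stats::rnorm(3 * n, sd = spread), n, 3)
    pm <- point_model(xyz, source = "atoms")
    cm <- contact_map_cutoff(pm, cutoff)
    g <- igraph::graph_from_edgelist(cbind(cm$i, cm$j), directed = FALSE)
    if (length(cm$i) > 0 && igraph::vcount(g) == n &&
        igraph::is_connected(g)) return(pm)
  }
}
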