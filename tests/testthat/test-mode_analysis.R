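test_that("solve_modes recovers hand-derived spectra and zero modes", {
  m3 <- path3_gnm_modes()
  expect_equal(m3$values, c(0, 1, 3), tolerance = 1e-12)
  expect_equal(m3$n_zero, 1)
  # GNM zero eigenvector is proportional to all-ones
  expect_equal(abs(m3$vectors[, 1]), rep(1 / sqrt(3), 3), tolerance = 1e-12)
  # connected 3-D ANM: exactly 6 rigid-body zero modes
  lat <- lattice_anm_modes()
  expect_equal(lat$modes$n_zero, 6)
  # orthonormality
  qtq <- t(lat$modes$vectors) %*% lat$modes$vectors
  expect_lt(max(abs(qtq - diag(nrow(qtq)))), 1e-8)
})

test_that("full spectrum reconstructs the stiffness matrix", {
  lat <- lattice_anm_modes()
  h <- build_enm(lat$points, enm_definition("anm", cutoff = 2.6))
  m <- lat$modes
  rec <- m$vectors %*% (t(m$vectors) * m$values)
  hm <- as.matrix(h$matrix)
  expect_lt(norm(rec - hm, "F") / norm(hm, "F"), 1e-6)
})

test_that("pseudo_inverse satisfies the spectral definition and G G+ G = G", {
  m2 <- two_node_gnm_modes()
  expect_equal(pseudo_inverse(m2),
               matrix(c(0.25, -0.25, -0.25, 0.25), 2), tolerance = 1e-12)
  m3 <- path3_gnm_modes()
  gp <- pseudo_inverse(m3)
  expect_equal(diag(gp), c(5, 2, 5) / 9, tolerance = 1e-12)
  g <- m3$vectors %*% (t(m3$vectors) * m3$values)
  expect_lt(max(abs(g %*% gp %*% g - g)), 1e-6)
  # partial mode set = dense pseudo-inverse truncated to those modes
  lat <- lattice_anm_modes()
  h <- build_enm(lat$points, enm_definition("anm", cutoff = 2.6))
  mp <- solve_modes(h, n_modes = 12)
  gp_part <- pseudo_inverse(mp)
  md <- lat$modes
  nz <- 7:12
  gp_trunc <- md$vectors[, nz] %*% (t(md$vectors[, nz]) / md$values[nz])
  expect_equal(gp_part, gp_trunc, tolerance = 1e-8)
})

test_that("mean_square_fluctuations matches the pseudo-inverse diagonal", {
  expect_equal(mean_square_fluctuations(two_node_gnm_modes())$msf,
               c(0.25, 0.25), tolerance = 1e-12)
  msf3 <- mean_square_fluctuations(path3_gnm_modes())$msf
  expect_equal(round(msf3, 4), c(0.5556, 0.2222, 0.5556))
  # palindromic symmetry of the path fixture
  expect_equal(msf3, rev(msf3))
  # ANM MSF invariant under rigid rotation of the input
  pm <- make_random_cloud(12, 7.3, 3, seed = 2)
  msf_a <- mean_square_fluctuations(
    solve_modes(build_enm(pm, enm_definition("anm"))))$msf
  theta <- 1.2
  rot <- matrix(c(cos(theta), -sin(theta), 0, sin(theta), cos(theta), 0,
                  0, 0, 1), 3, byrow = TRUE)
  pm2 <- point_model(pm$coords %*% t(rot))
  msf_b <- mean_square_fluctuations(
    solve_modes(build_enm(pm2, enm_definition("anm"))))$msf
  expect_equal(msf_a, msf_b, tolerance = 1e-8)
})

test_that("internal_distance_fluctuations contracts the covariance", {
  expect_equal(internal_distance_fluctuations(two_node_gnm_modes(),
                                              c(1, 2)), 1)
  expect_equal(internal_distance_fluctuations(path3_gnm_modes(),
                                              c(1, 3)), 2)
  expect_error(internal_distance_fluctuations(path3_gnm_modes(), c(2, 2)),
               "i = j")
  # non-negativity on random connected fixtures
  for (seed in 1:5) {
    pm <- make_random_cloud(10, 7.3, 3, seed = seed)
    m <- solve_modes(build_enm(pm, enm_definition("gnm", cutoff = 7.3)))
    pairs <- t(combn(10, 2))
    expect_true(all(internal_distance_fluctuations(m, pairs) >= -1e-12))
    ma <- solve_modes(build_enm(pm, enm_definition("anm", cutoff = 7.3)))
    expect_true(all(internal_distance_fluctuations(ma, pairs) >= -1e-12))
  }
})

test_that("cross_correlations are normalized, symmetric, bounded", {
  m2 <- two_node_gnm_modes()
  cc <- cross_correlations(m2)
  expect_equal(diag(cc), c(1, 1))
  expect_equal(cc[1, 2], -1)
  lat <- lattice_anm_modes()
  cca <- cross_correlations(lat$modes)
  expect_equal(cca, t(cca), tolerance = 1e-10)
  expect_true(all(cca >= -1 & cca <= 1))
  expect_equal(unname(diag(cca)), rep(1, 27))
})

test_that("adp_tensors and compare_adp behave on oracle cases", {
  expect_error(adp_tensors(path3_gnm_modes()), "anisotropic")
  # two-node x-axis ANM: verify against explicit 6x6 pseudo-inverse
  pm <- point_model(cbind(c(0, 2), 0, 0))
  h <- assemble_anm(contact_map_cutoff(pm, 3), pm$coords)
  m <- solve_modes(h)
  tens <- adp_tensors(m)
  ev <- eigen(as.matrix(h$matrix), symmetric = TRUE)
  keep <- ev$values > 1e-8
  gp <- ev$vectors[, keep, drop = FALSE] %*%
    (t(ev$vectors[, keep, drop = FALSE]) / ev$values[keep])
  expect_equal(tens[[1]], gp[1:3, 1:3], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(tens[[2]], gp[4:6, 4:6], tolerance = 1e-10,
               ignore_attr = TRUE)
  # a set compared with itself: pearson 1, all shape dot products 1
  lat <- lattice_anm_modes()
  tl <- adp_tensors(lat$modes)
  cmp <- compare_adp(tl, tl)
  expect_equal(cmp$pearson, 1, tolerance = 1e-12)
  expect_equal(cmp$scale, 1, tolerance = 1e-12)
  expect_true(all(abs(cmp$dot - 1) < 1e-12))
  # isotropic environment: central node of a symmetric octahedron
  oct <- point_model(rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0),
                           c(0, 1, 0), c(0, -1, 0), c(0, 0, 1),
                           c(0, 0, -1)))
  mo <- solve_modes(build_enm(oct, enm_definition("anm", cutoff = 1.0)))
  to <- adp_tensors(mo)[[1]]
  iso <- diag(3) * to[1, 1]
  expect_equal(sum(to * iso) / sqrt(sum(to^2) * sum(iso^2)), 1,
               tolerance = 1e-8)
})

test_that("collectivity is the exponential displacement entropy", {
  lat <- lattice_anm_modes()
  n <- 27
  # uniform participation: kappa = 1 (build a synthetic uniform mode)
  fake <- lat$modes
  v <- rep(c(1, 0, 0), n); v <- v / sqrt(sum(v^2))
  fake$vectors[, 7] <- v
  expect_equal(collectivity(fake, 7), 1, tolerance = 1e-12)
  # fully localized: kappa = 1/N
  v2 <- rep(0, 3 * n); v2[1] <- 1
  fake$vectors[, 7] <- v2
  expect_equal(collectivity(fake, 7), 1 / n, tolerance = 1e-12)
  # random unit vector vs brute-force formula
  set.seed(3)
  v3 <- rnorm(3 * n); v3 <- v3 / sqrt(sum(v3^2))
  fake$vectors[, 7] <- v3
  u2 <- colSums(matrix(v3^2, nrow = 3)); u2 <- u2 / sum(u2)
  expect_equal(collectivity(fake, 7),
               exp(-sum(u2 * log(u2))) / n, tolerance = 1e-12)
  expect_error(collectivity(lat$modes, 3), "zero mode")
})

test_that("subset_directional_correlation uses mean displacement vectors", {
  lat <- lattice_anm_modes()
  # single subset -> 1x1 matrix [1]
  one <- subset_directional_correlation(lat$modes, 7, list(1:27))
  expect_equal(one, matrix(1, 1, 1), ignore_attr = TRUE)
  # toy hinge: two nodes moving antiparallel along x
  fake <- lat$modes
  v <- rep(0, 81); v[1] <- 1; v[4] <- -1
  fake$vectors[, 7] <- v / sqrt(2)
  cc <- subset_directional_correlation(fake, 7, list(1, 2))
  expect_equal(cc[1, 2], -1, tolerance = 1e-12)
  # symmetric with unit diagonal, entries bounded
  parts <- split(1:27, rep(1:3, each = 9))
  m <- subset_directional_correlation(lat$modes, 8, parts)
  expect_equal(m, t(m), tolerance = 1e-12)
  expect_true(all(m >= -1 & m <= 1))
  expect_error(subset_directional_correlation(lat$modes, 7, list(1:2, 2:3)),
               "disjoint")
  expect_error(subset_directional_correlation(path3_gnm_modes(), 2,
                                              list(1, 2)), "ANM")
})

test_that("bfactor_comparison computes pearson r and the fitted scale", {
  msf <- mean_square_fluctuations(path3_gnm_modes())
  expect_equal(bfactor_comparison(msf, 2 * msf$msf)$pearson, 1)
  expect_equal(bfactor_comparison(msf, -msf$msf + 1)$pearson, -1)
  # length-5 fixture vs textbook formula
  a <- c(0.2, 0.5, 0.9, 0.4, 0.7)
  b <- c(12, 30, 44, 25, 31)
  r <- bfactor_comparison(a, b)
  expect_equal(r$pearson,
               sum((a - mean(a)) * (b - mean(b))) /
                 sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2)),
               tolerance = 1e-12)
  # fitted scale minimizes least squares of B ~ (8 pi^2 / 3) c MSF
  pref <- (8 * pi^2 / 3) * a
  expect_equal(r$scale, sum(pref * b) / sum(pref^2), tolerance = 1e-12)
  expect_error(bfactor_comparison(a, rep(3, 5)), "constant")
})

test_that("mode_animation spans one period at the requested amplitude", {
  lat <- lattice_anm_modes()
  ens <- mode_animation(lat$points, lat$modes, 7, amplitude = 1.5,
                        n_frames = 20)
  expect_length(ens$frames, 20)
  base <- coords(points_to_structure(lat$points))
  disp <- vapply(ens$frames, function(f)
    max(sqrt(rowSums((coords(f) - base)^2))), numeric(1))
  expect_equal(max(disp), 1.5, tolerance = 1e-6)
  # both directions of deformation are visited: projection onto the mode
  v <- lat$modes$vectors[, 7]
  sgn <- vapply(ens$frames, function(f)
    sum(as.numeric(t(coords(f) - base)) * v), numeric(1))
  expect_true(any(sgn > 1e-8) && any(sgn < -1e-8))
  # amplitude 0: all frames identical to the input
  ens0 <- mode_animation(lat$points, lat$modes, 7, amplitude = 0,
                         n_frames = 3)
  for (f in ens0$frames) expect_equal(coords(f), base)
  expect_error(mode_animation(lat$points, lat$modes, 2, 1, 4), "zero mode")
})

test_that("sparse lowest-k modes match the dense decomposition", {
  pm <- make_lattice(4, 1.6)
  h <- build_enm(pm, enm_definition("anm", cutoff = 2.3))
  dense <- solve_modes(h)
  k <- 26
  sp <- solve_modes(h, n_modes = k, method = "sparse_lowest")
  expect_equal(sp$n_zero, 6)
  nz <- 7:k
  expect_lt(max(abs(sp$values[nz] - dense$values[nz]) / dense$values[nz]),
            1e-8)
  # eigenvectors agree within sign where eigenvalues are simple
  gaps <- abs(diff(dense$values))
  for (i in nz) {
    simple <- (i == 1 || gaps[i - 1] > 1e-6) &&
      (i == length(dense$values) || gaps[i] > 1e-6)
    if (simple)
      expect_equal(abs(sum(sp$vectors[, i] * dense$vectors[, i])), 1,
                   tolerance = 1e-6)
  }
})
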