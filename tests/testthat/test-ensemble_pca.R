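test_that("superpose removes rigid transformations exactly", {
  pm <- make_random_cloud(10, 7.3, 3, seed = 5)
  ref <- pm$coords
  ang <- 0.9
  rot <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
                3, byrow = TRUE)
  moved <- ref %*% t(rot) + matrix(c(5, -3, 2), 10, 3, byrow = TRUE)
  sup <- superpose(list(ref, moved), reference = 1)
  expect_lt(sup$rmsd[2], 1e-9)
  # identical frames: zero RMSD
  sup2 <- superpose(list(ref, ref), reference = 1)
  expect_equal(sup2$rmsd, c(0, 0), tolerance = 1e-12)
  # one node displaced by 1 A out of 10 (others fixed, frames pre-centered):
  # the raw RMSD is 1/sqrt(10); the fit can only lower it, and the exact
  # post-fit value is the displacement with its rigid-body (translation +
  # rotation) components projected out -- a closed-form oracle
  # (cloud scaled up so the 1 A displacement is in the linear regime and
  # the first-order projection oracle is exact to tolerance)
  a <- scale(ref * 20, scale = FALSE)
  b <- a; b[1, 1] <- b[1, 1] + 1
  sup3 <- superpose(list(a, b), reference = 1)
  expect_lte(sup3$rmsd[2], 1 / sqrt(10) + 1e-12)
  rigid <- cbind(rep(c(1, 0, 0), 10), rep(c(0, 1, 0), 10),
                 rep(c(0, 0, 1), 10),
                 as.numeric(t(cbind(0, -a[, 3], a[, 2]))),
                 as.numeric(t(cbind(a[, 3], 0, -a[, 1]))),
                 as.numeric(t(cbind(-a[, 2], a[, 1], 0))))
  q <- qr.Q(qr(rigid))
  delta <- rep(0, 30); delta[1] <- 1
  resid <- delta - q %*% (t(q) %*% delta)
  expect_equal(sup3$rmsd[2], sqrt(sum(resid^2) / 10), tolerance = 1e-3)
  # degenerate collinear reference
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(list(line, line), reference = 1), "collinear")
})

test_that("superposition of aligned frames is idempotent", {
  pm <- make_lattice(3, 1.8)
  lat <- lattice_anm_modes()
  ens <- make_mode_ensemble(pm, lat$modes$vectors[, 7],
                            amplitudes = seq(-1, 1, length.out = 6),
                            noise_sigma = 0.1, seed = 9)
  sup <- superpose(ens)
  sup2 <- superpose(sup$coords)
  shift <- max(vapply(seq_along(sup$coords), function(i)
    max(abs(sup$coords[[i]] - sup2$coords[[i]])), numeric(1)))
  expect_lt(shift, 1e-8)
})

test_that("ensemble_pca finds the variance structure", {
  pm <- make_lattice(2, 3)
  base <- pm$coords
  # only node 1's x varies
  frames <- lapply(c(-1, 0, 1), function(a) {
    f <- base; f[1, 1] <- f[1, 1] + a; f
  })
  pca <- ensemble_pca(frames)
  vp <- variance_profile(pca)
  expect_equal(vp$fraction[1], 1, tolerance = 1e-12)
  e1 <- rep(0, 24); e1[1] <- 1
  expect_equal(abs(sum(pca$components[, 1] * e1)), 1, tolerance = 1e-12)
  # rank-1 generative model: PC1 = +/- direction
  set.seed(11)
  v <- rnorm(24); v <- v / sqrt(sum(v^2))
  frames2 <- lapply(seq(-2, 2, length.out = 7), function(a)
    base + matrix(a * v, ncol = 3, byrow = TRUE))
  pca2 <- ensemble_pca(frames2)
  expect_equal(abs(sum(pca2$components[, 1] * v)), 1, tolerance = 1e-10)
  # total variance equals the sum of per-coordinate variances (trace)
  flat <- t(vapply(frames2, function(f) as.numeric(t(f)), numeric(24)))
  expect_equal(pca2$total_variance, sum(apply(flat, 2, var)),
               tolerance = 1e-10)
  expect_error(ensemble_pca(frames2[1]), "at least 2")
  expect_error(ensemble_pca(list(base, base)), "distinct")
})

test_that("variance_profile fractions and cumulative curve", {
  fake <- structure(list(mean = matrix(0, 2, 3),
                         components = diag(6)[, 1:2],
                         variances = c(2, 2), total_variance = 4),
                    class = "pca_result")
  vp <- variance_profile(fake)
  expect_equal(vp$fraction, c(0.5, 0.5))
  expect_equal(vp$cumulative, c(0.5, 1.0))
  fake$total_variance <- 0
  expect_error(variance_profile(fake), "zero total variance")
})

test_that("overlap, cumulative overlap and rmsip obey their definitions", {
  e <- diag(6)
  expect_equal(overlap(e[, 1], e[, 1]), 1)
  expect_equal(overlap(e[, 1], e[, 2]), 0)
  p <- 0.6 * e[, 1] + 0.8 * e[, 2]
  expect_equal(overlap(p, e[, 2]), 0.8)
  expect_warning(overlap(2 * e[, 1], e[, 1]), "renormaliz")
  expect_error(overlap(rep(0, 6), e[, 1]), "zero vector")
  # CO on a complete basis = 1 (Parseval); on partial bases per definition
  set.seed(2)
  u <- rnorm(6); u <- u / sqrt(sum(u^2))
  expect_equal(cumulative_overlap(u, e, 6), 1, tolerance = 1e-12)
  expect_equal(cumulative_overlap(e[, 3], e[, 1:3], 2), 0)
  expect_equal(cumulative_overlap(e[, 3], e[, 1:3], 3), 1)
  expect_equal(cumulative_overlap(p, e, 2), 1, tolerance = 1e-12)
  expect_error(cumulative_overlap(u, e[, 1:3], 5), "exceeds")
  # RMSIP identities
  q <- random_orthonormal(20, 5, seed = 7)
  expect_equal(rmsip(q, q), 1, tolerance = 1e-12)
  expect_equal(rmsip(e[, 1:2], e[, 3:4]), 0)
  # I = 1 reduces to the cumulative overlap
  expect_equal(rmsip(matrix(u, ncol = 1), e, 1, 4),
               cumulative_overlap(u, e, 4), tolerance = 1e-12)
  expect_error(rmsip(q, q, 0, 3), "empty")
})

test_that("overlap metrics are sign-invariant, bounded and monotone", {
  set.seed(13)
  d <- 30
  q <- random_orthonormal(d, 8, seed = 13)
  p <- random_orthonormal(d, 4, seed = 14)
  for (trial in 1:20) {
    flip_q <- q %*% diag(sample(c(-1, 1), 8, replace = TRUE))
    flip_p <- p %*% diag(sample(c(-1, 1), 4, replace = TRUE))
    expect_equal(abs(t(flip_p) %*% flip_q), abs(t(p) %*% q),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(rmsip(flip_p, flip_q), rmsip(p, q), tolerance = 1e-12)
  }
  co <- vapply(1:8, function(k) cumulative_overlap(p[, 1], q, k),
               numeric(1))
  expect_true(all(diff(co) >= -1e-12))          # monotone in k
  expect_true(all(co >= 0 & co <= 1))
  rm_j <- vapply(1:8, function(j) rmsip(p, q, 4, j), numeric(1))
  expect_true(all(diff(rm_j) >= -1e-12))        # monotone in J
  expect_true(all(rm_j >= 0 & rm_j <= 1))
})

test_that("compare_modesets reports overlap structure between models", {
  lat <- lattice_anm_modes()
  rep_self <- compare_modesets(lat$modes, lat$modes)
  expect_equal(rep_self$rmsip, 1, tolerance = 1e-8)
  om <- rep_self$overlap_matrix
  expect_equal(dim(om), c(75, 75))
  expect_true(all(abs(Matrix::diag(om) - 1) < 1e-8))
  # permuted mode order gives the permutation pattern where eigenvalues
  # are simple; use a hand-permuted copy of the same ModeSet
  b <- lat$modes
  perm <- c(8, 7, 9:length(b$values))
  b$values[7:length(b$values)] <- b$values[perm]
  b$vectors[, 7:ncol(b$vectors)] <- b$vectors[, perm]
  rep_perm <- compare_modesets(lat$modes, b)
  expect_equal(rep_perm$overlap_matrix[1, 2], 1, tolerance = 1e-8)
  expect_equal(rep_perm$overlap_matrix[2, 1], 1, tolerance = 1e-8)
  expect_lt(rep_perm$overlap_matrix[1, 1], 1e-6)
  # different parameter choices: well-formed bounded report
  h11 <- build_enm(lat$points, enm_definition("anm", cutoff = 2.2))
  m11 <- solve_modes(h11)
  rep2 <- compare_modesets(lat$modes, m11)
  expect_true(all(rep2$overlap_matrix >= 0 & rep2$overlap_matrix <= 1))
  expect_true(rep2$rmsip >= 0 && rep2$rmsip <= 1)
  # kind and dimension mismatches refused
  expect_error(compare_modesets(lat$modes, path3_gnm_modes()), "kind")
  small <- lattice_anm_modes(2, 1.8, 2.6)
  expect_error(compare_modesets(lat$modes, small$modes), "mismatch")
})

test_that("noise-free mode ensembles are recovered by PCA", {
  lat <- lattice_anm_modes()
  dir7 <- lat$modes$vectors[, 7]
  ens <- make_mode_ensemble(lat$points, dir7,
                            amplitudes = seq(-1.5, 1.5, length.out = 9),
                            noise_sigma = 0, seed = 1)
  sup <- superpose(ens)
  pca <- ensemble_pca(sup$coords)
  expect_gt(overlap(pca$components[, 1], dir7), 0.99)
  rep <- pca_mode_overlap(pca, lat$modes, n_pcs = 1, k_modes = 10)
  expect_gt(rep$cumulative[1], 0.99)
  expect_true(rep$significant[1])
  # graceful degradation with noise: overlap drops but stays dominant
  ens_n <- make_mode_ensemble(lat$points, dir7,
                              amplitudes = seq(-1.5, 1.5, length.out = 9),
                              noise_sigma = 0.05, seed = 2)
  pca_n <- ensemble_pca(superpose(ens_n)$coords)
  o <- overlap(pca_n$components[, 1], dir7)
  expect_gt(o, 0.8)
})
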