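# ---- ModeSet ----------------------------------------------------------------

#' Solve the normal modes of a stiffness matrix
#'
#' Eigen-decomposes the GNM Kirchhoff matrix or ANM Hessian. Eigenvalues
#' (squared vibrational frequencies, in units of the spring constant) are
#' returned ascending with orthonormal eigenvectors as columns. Modes with
#' eigenvalue below `tol * max(eigenvalue)` are flagged as rigid-body zero
#' modes: six for a connected non-collinear ANM, one for a connected GNM.
#' Eigenvector signs are fixed by making the largest-magnitude component
#' positive.
#'
#' The `"sparse_lowest"` method computes only the lowest `n_modes`
#' eigenpairs by shift-invert Lanczos (ARPACK via a sparse Cholesky solve
#' of H + sigma I), matching the dense path on shared modes.
#'
#' @param H a `stiffness_matrix`.
#' @param n_modes `"all"` or an integer k (lowest k modes, including zero
#'   modes).
#' @param method `"dense"` (full LAPACK decomposition) or
#'   `"sparse_lowest"`.
#' @param tol relative zero-mode tolerance (default 1e-8).
#' @return object of class `mode_set` with fields `kind`, `values`,
#'   `vectors`, `n_zero`, `n_nodes`, `coords`, `partial`.
#' @export
solve_modes <- function(H, n_modes = "all",
                        method = c("dense", "sparse_lowest"),
                        tol = 1e-8) {
  stopifnot(inherits(H, "stiffness_matrix"))
  method <- match.arg(method)
  dim_h <- nrow(H$matrix)
  n_nodes <- if (H$kind == "anm") dim_h / 3 else dim_h

  if (method == "dense") {
    eg <- eigen(as.matrix(H$matrix), symmetric = TRUE)
    ord <- order(eg$values)
    values <- eg$values[ord]
    vectors <- eg$vectors[, ord, drop = FALSE]
    partial <- FALSE
    if (!identical(n_modes, "all")) {
      k <- min(as.integer(n_modes), dim_h)
      values <- values[seq_len(k)]
      vectors <- vectors[, seq_len(k), drop = FALSE]
      partial <- k < dim_h
    }
  } else {
    if (identical(n_modes, "all"))
      stop("sparse_lowest requires a finite n_modes < matrix dimension")
    k <- as.integer(n_modes)
    if (k >= dim_h) stop("sparse_lowest requires n_modes < matrix dimension")
    si <- .sparse_lowest_modes(H$matrix, k)
    values <- si$values
    vectors <- si$vectors
    partial <- TRUE
  }
  values[values < 0 & values > -tol * max(abs(values), 1)] <- 0
  # sign convention
  for (c in seq_len(ncol(vectors))) {
    imax <- which.max(abs(vectors[, c]))
    if (vectors[imax, c] < 0) vectors[, c] <- -vectors[, c]
  }
  lam_max <- if (partial) .lambda_max_estimate(H$matrix) else max(values)
  n_zero <- sum(values < tol * max(lam_max, .Machine$double.eps))
  structure(list(kind = H$kind, values = values, vectors = vectors,
                 n_zero = n_zero, n_nodes = n_nodes, coords = H$coords,
                 partial = partial, tol = tol),
            class = "mode_set")
}

# Gershgorin upper bound on the largest eigenvalue (cheap, adequate for the
# relative zero-mode threshold)
.lambda_max_estimate <- function(m) {
  max(Matrix::rowSums(abs(m)))
}

.sparse_lowest_modes <- function(m, k) {
  dim_h <- nrow(m)
  msp <- methods::as(m, "CsparseMatrix")
  sigma <- max(Matrix::diag(msp)) * 1e-6 + 1e-10
  shifted <- msp + Matrix::Diagonal(dim_h, sigma)
  fac <- Matrix::Cholesky(Matrix::forceSymmetric(shifted), LDL = FALSE)
  matvec <- function(x, extra = NULL) {
    as.numeric(Matrix::solve(fac, x, system = "A"))
  }
  res <- igraph::arpack(matvec, sym = TRUE,
                        options = list(n = dim_h, nev = k,
                                       ncv = min(dim_h, max(2 * k + 10, 20)),
                                       which = "LM", maxiter = 10000))
  if (is.null(res$values))
    stop("sparse eigensolver failed to converge")
  mu <- res$values           # eigenvalues of (H + sigma I)^-1, descending
  values <- 1 / mu - sigma   # exact recovery of H's eigenvalues
  vectors <- res$vectors
  if (is.null(dim(vectors))) vectors <- matrix(vectors, ncol = 1)
  ord <- order(values)
  values <- values[ord]
  vectors <- vectors[, ord, drop = FALSE]
  # renormalize (ARPACK vectors are orthonormal already; belt & braces)
  vectors <- sweep(vectors, 2, sqrt(colSums(vectors^2)), `/`)
  list(values = values, vectors = vectors)
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("<ModeSet> %s, %d node(s), %d mode(s) (%d zero)%s\n",
              toupper(x$kind), x$n_nodes, length(x$values), x$n_zero,
              if (x$partial) " [partial]" else ""))
  invisible(x)
}

#' Indices of the non-zero (internal) modes of a ModeSet
#' @param modes a `mode_set`.
#' @return integer vector of column indices into `modes$vectors`.
#' @export
nonzero_modes <- function(modes) {
  seq_along(modes$values)[-seq_len(modes$n_zero)]
}

# ---- pseudo-inverse and covariances ----------------------------------------

#' Spectral pseudo-inverse of the stiffness matrix
#'
#' Gamma^+ = sum over non-zero modes of (1/lambda_i) Q_i Q_i^T -- the mode
#' ranges {2..N} for GNM and {7..3N} for ANM. Proportional to the
#' positional covariance matrix. For a partial mode set the sum is
#' truncated to the available non-zero modes.
#'
#' @param modes a `mode_set`.
#' @return symmetric PSD matrix (N x N for GNM, 3N x 3N for ANM).
#' @export
pseudo_inverse <- function(modes) {
  nz <- nonzero_modes(modes)
  if (length(nz) == 0) stop("all modes are zero modes; nothing to invert")
  q <- modes$vectors[, nz, drop = FALSE]
  lam <- modes$values[nz]
  q %*% (t(q) / lam)
}

#' Mean-square fluctuations per node
#'
#' GNM: MSF_i is the i-th diagonal element of the pseudo-inverse. ANM:
#' MSF_i is the trace of the i-th 3 x 3 diagonal block of the Hessian
#' pseudo-inverse. Values are in raw pseudo-inverse units (k_B T / gamma x
#' Angstrom^2 up to the reporting convention); comparisons with
#' experimental B-factors are scale-invariant.
#'
#' @param modes a `mode_set`.
#' @return object of class `fluctuation_result` with fields `msf`
#'   (numeric, length N) and `kind`.
#' @export
mean_square_fluctuations <- function(modes) {
  nz <- nonzero_modes(modes)
  if (length(nz) == 0) stop("no non-zero modes")
  q <- modes$vectors[, nz, drop = FALSE]
  lam <- modes$values[nz]
  diag_cov <- rowSums(sweep(q^2, 2, lam, `/`))
  msf <- if (modes$kind == "anm") {
    colSums(matrix(diag_cov, nrow = 3))
  } else diag_cov
  structure(list(msf = msf, kind = modes$kind), class = "fluctuation_result")
}

#' @export
print.fluctuation_result <- function(x, ...) {
  cat(sprintf("<FluctuationResult> %d node(s), MSF range [%.4g, %.4g]\n",
              length(x$msf), min(x$msf), max(x$msf)))
  invisible(x)
}

#' Mean-square internal distance fluctuations for node pairs
#'
#' GNM: <Delta d_ij^2> = G_ii + G_jj - 2 G_ij with G the pseudo-inverse.
#' ANM: the same contraction of the 3 x 3 covariance blocks restricted to
#' the inter-node unit vector e_ij: e^T (C_ii + C_jj - 2 C_ij) e. Rigid
#' relative motion gives 0; all outputs are non-negative.
#'
#' @param modes a `mode_set`.
#' @param pairs 2-column integer matrix (or length-2 vector) of node pairs.
#' @return numeric vector, one value per pair.
#' @export
internal_distance_fluctuations <- function(modes, pairs) {
  if (is.vector(pairs)) pairs <- matrix(pairs, ncol = 2, byrow = TRUE)
  stopifnot(ncol(pairs) == 2)
  if (any(pairs[, 1] == pairs[, 2])) stop("pair with i = j is undefined")
  g <- pseudo_inverse(modes)
  if (modes$kind == "gnm") {
    i <- pairs[, 1]; j <- pairs[, 2]
    return(g[cbind(i, i)] + g[cbind(j, j)] - 2 * g[cbind(i, j)])
  }
  xyz <- modes$coords
  if (is.null(xyz)) stop("ANM mode set lacks a coordinate snapshot")
  vapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    bi <- 3 * (i - 1) + 1:3; bj <- 3 * (j - 1) + 1:3
    e <- xyz[j, ] - xyz[i, ]
    e <- e / sqrt(sum(e^2))
    blk <- g[bi, bi] + g[bj, bj] - g[bi, bj] - g[bj, bi]
    max(0, as.numeric(t(e) %*% blk %*% e))
  }, numeric(1))
}

#' Normalized cross-correlations of node motions
#'
#' C_ij = <DR_i . DR_j> / sqrt(<DR_i^2><DR_j^2>), where the covariance
#' <DR_i . DR_j> is the (i, j) element of the GNM pseudo-inverse or the
#' trace of the (i, j) 3 x 3 block of the ANM pseudo-inverse. Diagonal 1;
#' nodes with zero MSF get correlation 0 (logged).
#'
#' @param modes a `mode_set`.
#' @return N x N symmetric matrix with unit diagonal, entries in [-1, 1].
#' @export
cross_correlations <- function(modes) {
  g <- pseudo_inverse(modes)
  n <- modes$n_nodes
  cov <- if (modes$kind == "anm") {
    # trace over 3x3 blocks: sum the three coordinate sub-lattices
    idx <- function(a) seq(a, 3 * n, by = 3)
    g[idx(1), idx(1)] + g[idx(2), idx(2)] + g[idx(3), idx(3)]
  } else g
  s <- sqrt(diag(cov))
  zero <- s <= 0
  if (any(zero)) message(sum(zero), " node(s) with zero MSF; correlations set to 0")
  s[zero] <- 1
  cc <- cov / outer(s, s)
  cc[zero, ] <- 0; cc[, zero] <- 0
  diag(cc)[!zero] <- 1
  pmin(pmax(cc, -1), 1)
}

# ---- anisotropic displacement tensors ---------------------------------------

#' Per-node anisotropic displacement tensors from ANM modes
#'
#' Tensor i is the i-th 3 x 3 diagonal block of the Hessian pseudo-inverse:
#' the model's prediction of the atom's positional covariance, comparable
#' (up to scale) to crystallographic ANISOU tensors.
#'
#' @param modes an ANM `mode_set`.
#' @return list of N symmetric PSD 3 x 3 matrices.
#' @export
adp_tensors <- function(modes) {
  if (modes$kind != "anm") stop("ADP tensors require an anisotropic model (ANM)")
  g <- pseudo_inverse(modes)
  lapply(seq_len(modes$n_nodes), function(i) {
    b <- 3 * (i - 1) + 1:3
    (g[b, b] + t(g[b, b])) / 2
  })
}

#' Compare computed and experimental ADP tensor sets
#'
#' Global agreement: Pearson correlation over the 6 unique tensor elements
#' of every node after a least-squares scaling of the computed set onto the
#' experimental one. Per-node shape agreement: normalized tensor dot
#' product tr(A B) / sqrt(tr(A^2) tr(B^2)), 1 for identical shapes.
#'
#' @param computed list of 3 x 3 tensors (e.g. from [adp_tensors()]).
#' @param experimental list of 3 x 3 tensors (e.g. assembled from ANISOU).
#' @return list with `pearson` (global, scalar), `scale` (fitted
#'   least-squares factor), `dot` (per-node similarity).
#' @export
compare_adp <- function(computed, experimental) {
  stopifnot(length(computed) == length(experimental))
  u6 <- function(m) c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])
  a <- do.call(rbind, lapply(computed, u6))
  b <- do.call(rbind, lapply(experimental, u6))
  scale <- sum(a * b) / sum(a * a)
  pearson <- stats::cor(as.numeric(a * scale), as.numeric(b))
  dot <- vapply(seq_along(computed), function(i) {
    ca <- computed[[i]]; cb <- experimental[[i]]
    den <- sqrt(sum(ca * ca) * sum(cb * cb))
    if (den == 0) return(0)
    sum(ca * cb) / den
  }, numeric(1))
  list(pearson = pearson, scale = scale, dot = dot)
}

#' Assemble experimental ADP tensors from a Structure's ANISOU columns
#'
#' @param structure an `enm_structure` whose atoms carry u11..u23.
#' @param indices atom rows to use (default: all atoms with ANISOU data).
#' @return list of symmetric 3 x 3 U tensors (Angstrom^2).
#' @export
experimental_adp <- function(structure, indices = NULL) {
  at <- structure$atoms
  if (is.null(indices)) indices <- which(!is.na(at$u11))
  if (length(indices) == 0) stop("no ANISOU data in structure")
  lapply(indices, function(i) {
    matrix(c(at$u11[i], at$u12[i], at$u13[i],
             at$u12[i], at$u22[i], at$u23[i],
             at$u13[i], at$u23[i], at$u33[i]), 3, 3)
  })
}

# ---- collectivity and subset correlations -----------------------------------

#' Collectivity of a mode
#'
#' kappa = (1/N) exp(-sum_i u_i^2 ln u_i^2), where u_i^2 is node i's
#' fraction of the mode's squared displacement (fractions sum to 1). The
#' exponential of the displacement entropy: 1/N for motion localized on a
#' single node, 1 for uniform participation.
#'
#' @param modes a `mode_set`.
#' @param mode_index mode column index; must be beyond the zero modes.
#' @return kappa in (0, 1].
#' @export
collectivity <- function(modes, mode_index) {
  if (mode_index <= modes$n_zero)
    stop("mode ", mode_index, " is a rigid-body zero mode")
  v <- modes$vectors[, mode_index]
  u2 <- if (modes$kind == "anm") colSums(matrix(v^2, nrow = 3)) else v^2
  u2 <- u2 / sum(u2)
  nz <- u2 > 0
  entropy <- -sum(u2[nz] * log(u2[nz]))
  exp(entropy) / modes$n_nodes
}

#' Directional correlation between subsets of the structure in one mode
#'
#' For each subset the mean displacement 3-vector in the chosen ANM mode is
#' computed; entry (a, b) is the cosine of the angle between the mean
#' vectors of subsets a and b. Diagonal 1; a subset with zero mean vector
#' yields 0 entries (logged).
#'
#' @param modes an ANM `mode_set`.
#' @param mode_index mode column index beyond the zero modes.
#' @param partition list of disjoint non-empty integer node-index vectors.
#' @return S x S symmetric matrix with unit diagonal, entries in [-1, 1].
#' @export
subset_directional_correlation <- function(modes, mode_index, partition) {
  if (modes$kind != "anm") stop("subset correlations require ANM modes")
  if (mode_index <= modes$n_zero)
    stop("mode ", mode_index, " is a rigid-body zero mode")
  stopifnot(length(partition) >= 1, all(lengths(partition) >= 1))
  all_idx <- unlist(partition)
  if (anyDuplicated(all_idx)) stop("partition subsets are not disjoint")
  v <- matrix(modes$vectors[, mode_index], nrow = 3)
  means <- vapply(partition, function(ix) rowMeans(v[, ix, drop = FALSE]),
                  numeric(3))
  norms <- sqrt(colSums(means^2))
  zero <- norms == 0
  if (any(zero)) message(sum(zero), " subset(s) with zero mean displacement")
  norms[zero] <- 1
  unitv <- sweep(means, 2, norms, `/`)
  cc <- t(unitv) %*% unitv
  cc[zero, ] <- 0; cc[, zero] <- 0
  diag(cc)[!zero] <- 1
  pmin(pmax(cc, -1), 1)
}

# ---- B-factor comparison ----------------------------------------------------

#' Compare computed fluctuations with experimental B-factors
#'
#' Pearson correlation between per-node MSF and experimental B plus the
#' least-squares scale c in B_i ~ (8 pi^2 / 3) c MSF_i (the crystallographic
#' isotropic-B convention). The correlation is invariant to the scale.
#'
#' @param msf a `fluctuation_result` or bare numeric MSF vector.
#' @param experimental_b per-node experimental B-factors (Angstrom^2).
#' @return list with `pearson` and `scale` (c above).
#' @export
bfactor_comparison <- function(msf, experimental_b) {
  m <- if (inherits(msf, "fluctuation_result")) msf$msf else msf
  stopifnot(length(m) == length(experimental_b), length(m) >= 3)
  if (stats::var(experimental_b) == 0)
    stop("experimental B-factor vector is constant")
  pref <- (8 * pi^2 / 3) * m
  list(pearson = stats::cor(m, experimental_b),
       scale = sum(pref * experimental_b) / sum(pref * pref))
}

# ---- animation --------------------------------------------------------------

#' Generate a mode animation as a multi-frame ensemble
#'
#' Frame t (t = 1..n_frames) has coordinates
#' x0 + amplitude * sin(2 pi t / n_frames) * V, with V the chosen ANM mode
#' reshaped to N x 3 and normalized so its largest per-node displacement
#' norm is 1. One full period covers both the negative and positive mode
#' deformations. Write the result with [write_pdb()] to obtain a
#' multi-MODEL animation any molecular viewer can play.
#'
#' @param points `point_model` supplying the rest coordinates.
#' @param modes an ANM `mode_set` on the same nodes.
#' @param mode_index mode column index beyond the zero modes.
#' @param amplitude maximum displacement in Angstrom (>= 0).
#' @param n_frames number of frames (>= 1).
#' @return an `enm_ensemble` of `n_frames` frames.
#' @export
mode_animation <- function(points, modes, mode_index, amplitude = 2,
                           n_frames = 20) {
  if (modes$kind != "anm") stop("animation requires ANM modes")
  if (mode_index <= modes$n_zero)
    stop("mode ", mode_index, " is a rigid-body zero mode")
  stopifnot(amplitude >= 0, n_frames >= 1)
  v <- matrix(modes$vectors[, mode_index], ncol = 3, byrow = TRUE)
  norm_max <- max(sqrt(rowSums(v^2)))
  v <- v / norm_max
  base <- points_to_structure(points)
  frames <- lapply(seq_len(n_frames), function(t) {
    s <- base
    disp <- amplitude * sin(2 * pi * t / n_frames) * v
    s$atoms$x <- s$atoms$x + disp[, 1]
    s$atoms$y <- s$atoms$y + disp[, 2]
    s$atoms$z <- s$atoms$z + disp[, 3]
    s$model_id <- t
    s
  })
  ensemble_new(frames)
}

# ---- CSV export -------------------------------------------------------------

#' Write a per-node result as CSV
#' @param values numeric vector or matrix of per-node values.
#' @param path output path.
#' @param name column name (vector input).
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(values, path, name = "value") {
  if (is.matrix(values)) {
    df <- data.frame(node = seq_len(nrow(values)), values)
  } else {
    df <- data.frame(node = seq_along(values), v = values)
    names(df)[2] <- name
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
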