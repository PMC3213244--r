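# ---- superposition ----------------------------------------------------------

# optimal least-squares rotation mapping xyz (N x 3, centered) onto ref
# (centered) -- Kabsch with proper-rotation correction
.kabsch_rotation <- function(xyz, ref) {
  h <- t(xyz) %*% ref
  sv <- svd(h)
  d <- sign(det(sv$u) * det(sv$v))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

.frame_coords <- function(x) {
  if (inherits(x, "enm_ensemble")) lapply(x$frames, coords)
  else if (is.list(x)) lapply(x, as.matrix)
  else stop("expected an enm_ensemble or list of coordinate matrices")
}

#' Superpose ensemble frames by least-squares rotation
#'
#' Each frame is rigidly rotated and translated to minimize its RMSD to the
#' reference using the Kabsch singular-value-decomposition procedure. With
#' `reference = "iterative_mean"` frames are fitted to the running mean
#' until the mean shifts by less than `tol` Angstrom (max `max_iter`
#' iterations), the usual convention before ensemble PCA; an integer
#' selects a fixed reference frame. The default tolerance is tight enough
#' that re-running `superpose` on aligned frames moves coordinates by less
#' than 1e-8 Angstrom.
#'
#' @param ensemble an `enm_ensemble` with atom correspondence, or a list
#'   of N x 3 coordinate matrices.
#' @param reference frame index, or `"iterative_mean"`.
#' @param tol mean-shift convergence threshold (Angstrom).
#' @param max_iter iteration cap for the iterative-mean fit.
#' @return list with `coords` (aligned N x 3 matrices), `rmsd` (per-frame,
#'   to the final reference), `mean` (reference/mean coordinates),
#'   `iterations`.
#' @export
superpose <- function(ensemble, reference = "iterative_mean",
                      tol = 1e-10, max_iter = 100L) {
  if (inherits(ensemble, "enm_ensemble") && !ensemble$correspondence)
    stop("ensemble frames lack atom correspondence; refusing to superpose")
  frames <- .frame_coords(ensemble)
  n <- nrow(frames[[1]])
  stopifnot(n >= 3)
  if (.is_collinear(frames[[1]]))
    stop("degenerate (collinear) reference coordinates")

  fit_to <- function(frames, ref) {
    refc <- scale(ref, scale = FALSE)
    lapply(frames, function(f) {
      fc <- scale(f, scale = FALSE)
      fc %*% .kabsch_rotation(fc, refc) +
        matrix(colMeans(ref), n, 3, byrow = TRUE)
    })
  }

  iterations <- 1L
  if (identical(reference, "iterative_mean")) {
    aligned <- fit_to(frames, frames[[1]])
    m_prev <- Reduce(`+`, aligned) / length(aligned)
    repeat {
      aligned <- fit_to(aligned, m_prev)
      m <- Reduce(`+`, aligned) / length(aligned)
      shift <- sqrt(max(rowSums((m - m_prev)^2)))
      m_prev <- m
      iterations <- iterations + 1L
      if (shift < tol || iterations >= max_iter) break
    }
    # the iterative-mean fixed point is unique only up to a global rigid
    # transform; anchor the converged system to the input's first frame so
    # the procedure is deterministic and idempotent
    mc <- scale(m_prev, scale = FALSE)
    refc <- scale(frames[[1]], scale = FALSE)
    r0 <- .kabsch_rotation(mc, refc)
    mu_m <- colMeans(m_prev)
    mu_f <- colMeans(frames[[1]])
    reanchor <- function(x)
      (x - matrix(mu_m, n, 3, byrow = TRUE)) %*% r0 +
        matrix(mu_f, n, 3, byrow = TRUE)
    aligned <- lapply(aligned, reanchor)
    ref_final <- reanchor(m_prev)
  } else {
    ref_idx <- as.integer(reference)
    stopifnot(ref_idx >= 1, ref_idx <= length(frames))
    aligned <- fit_to(frames, frames[[ref_idx]])
    ref_final <- frames[[ref_idx]]
  }
  rmsd <- vapply(aligned, function(f)
    sqrt(mean(rowSums((f - ref_final)^2))), numeric(1))
  list(coords = aligned, rmsd = rmsd, mean = ref_final,
       iterations = iterations)
}

.is_collinear <- function(xyz, tol = 1e-9) {
  c0 <- scale(xyz, scale = FALSE)
  s <- svd(c0, nu = 0, nv = 0)$d
  sum(s > tol * max(s, tol)) < 2
}

# ---- PCA --------------------------------------------------------------------

#' Principal component analysis of an aligned ensemble
#'
#' Flattens each frame's deviation from the ensemble mean into a
#' 3N-vector, forms the positional covariance matrix and extracts its
#' principal axes by singular value decomposition. Components are
#' orthonormal 3N-vectors sorted by descending variance; at most
#' min(3N, M - 1) components are non-trivial for M frames. Node weighting
#' is uniform. Coordinate layout matches ANM modes: (x1, y1, z1, x2, ...).
#'
#' @param aligned list of N x 3 aligned coordinate matrices (e.g.
#'   `superpose(...)$coords`) or an aligned `enm_ensemble`.
#' @return object of class `pca_result` with fields `mean` (N x 3),
#'   `components` (3N x k, columns orthonormal), `variances` (descending),
#'   `total_variance`.
#' @export
ensemble_pca <- function(aligned) {
  frames <- .frame_coords(aligned)
  m <- length(frames)
  if (m < 2) stop("PCA requires at least 2 frames")
  flat <- t(vapply(frames, function(f) as.numeric(t(f)),
                   numeric(3 * nrow(frames[[1]]))))
  mu <- colMeans(flat)
  x <- sweep(flat, 2, mu)
  if (max(abs(x)) == 0) stop("fewer than 2 distinct frames")
  sv <- svd(x / sqrt(m - 1), nu = 0)
  k <- min(3 * nrow(frames[[1]]), m - 1)
  variances <- sv$d[seq_len(k)]^2
  comps <- sv$v[, seq_len(k), drop = FALSE]
  for (c in seq_len(ncol(comps))) {       # sign convention as for modes
    imax <- which.max(abs(comps[, c]))
    if (comps[imax, c] < 0) comps[, c] <- -comps[, c]
  }
  structure(list(mean = matrix(mu, ncol = 3, byrow = TRUE),
                 components = comps, variances = variances,
                 total_variance = sum(sv$d^2)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<PCAResult> %d component(s); PC1 explains %.1f%% of variance\n",
              ncol(x$components),
              100 * x$variances[1] / x$total_variance))
  invisible(x)
}

#' Per-component variance fractions and cumulative curve
#'
#' @param pca a `pca_result`.
#' @return list with `fraction` and `cumulative` (non-decreasing to 1 over
#'   all components).
#' @export
variance_profile <- function(pca) {
  if (pca$total_variance <= 0) stop("zero total variance")
  f <- pca$variances / pca$total_variance
  list(fraction = f, cumulative = cumsum(f))
}

# ---- overlap metrics --------------------------------------------------------

.unitize <- function(v, what) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop(what, " is a zero vector")
  if (abs(nv - 1) > 1e-8) {
    warning(what, " was not unit-normalized; renormalizing")
    v <- v / nv
  }
  v
}

#' Overlap between a principal component and a mode
#'
#' The absolute inner product |P . M| of two unit 3N-vectors; signs of
#' modes and PCs are arbitrary, so overlap is sign-invariant and lies in
#' [0, 1].
#'
#' @param p,m numeric vectors of equal length (renormalized with a warning
#'   if not unit length).
#' @return scalar in [0, 1].
#' @export
overlap <- function(p, m) {
  stopifnot(length(p) == length(m))
  p <- .unitize(p, "P"); m <- .unitize(m, "M")
  min(abs(sum(p * m)), 1)
}

#' Cumulative overlap of one PC with the first k modes
#'
#' CO(k) = sqrt(sum_{j=1..k} (P . M_j)^2) over an orthonormal mode set:
#' the fraction of the PC captured within the k-mode subspace.
#' Non-decreasing in k; 1 when the modes span the full space.
#'
#' @param p unit 3N-vector.
#' @param modes matrix of orthonormal mode columns, or a `mode_set` (its
#'   non-zero modes are used).
#' @param k number of leading modes to accumulate.
#' @return scalar in [0, 1].
#' @export
cumulative_overlap <- function(p, modes, k = NULL) {
  q <- .mode_columns(modes)
  if (is.null(k)) k <- ncol(q)
  if (k > ncol(q)) stop("k = ", k, " exceeds available modes (", ncol(q), ")")
  p <- .unitize(p, "P")
  min(sqrt(sum((t(q[, seq_len(k), drop = FALSE]) %*% p)^2)), 1)
}

.mode_columns <- function(modes) {
  if (inherits(modes, "mode_set"))
    modes$vectors[, nonzero_modes(modes), drop = FALSE]
  else as.matrix(modes)
}

#' Root mean square inner product between two subspaces
#'
#' RMSIP(I, J) = sqrt((1/I) sum_{i<=I} sum_{j<=J} (P_i . M_j)^2) for
#' orthonormal sets: how completely the first I PCs are contained in the
#' span of the first J modes. In [0, 1]; 1 when the PC set lies inside the
#' mode span; for I = 1 it reduces to the cumulative overlap.
#'
#' @param pcs matrix of orthonormal PC columns or a `pca_result`.
#' @param modes matrix of orthonormal mode columns or a `mode_set`.
#' @param i_pcs,j_modes subspace sizes I and J (defaults: all columns).
#' @return scalar in [0, 1].
#' @export
rmsip <- function(pcs, modes, i_pcs = NULL, j_modes = NULL) {
  p <- if (inherits(pcs, "pca_result")) pcs$components else as.matrix(pcs)
  q <- .mode_columns(modes)
  if (is.null(i_pcs)) i_pcs <- ncol(p)
  if (is.null(j_modes)) j_modes <- ncol(q)
  if (i_pcs < 1 || j_modes < 1) stop("empty subspace")
  stopifnot(i_pcs <= ncol(p), j_modes <= ncol(q))
  p <- p[, seq_len(i_pcs), drop = FALSE]
  q <- q[, seq_len(j_modes), drop = FALSE]
  ip <- t(p) %*% q
  min(sqrt(sum(ip^2) / i_pcs), 1)
}

# ---- mode set comparison ----------------------------------------------------

#' Compare two mode sets by overlaps and RMSIP
#'
#' Overlap matrix between the non-zero modes of A (rows) and B (columns),
#' cumulative overlap of each A-mode within B's first J modes, and
#' RMSIP(I, J). Significance flags follow the CO > 0.5 convention.
#'
#' @param a,b `mode_set` objects with equal node count and kind.
#' @param i_modes,j_modes subspace sizes for RMSIP (defaults: all shared
#'   non-zero modes).
#' @return object of class `overlap_report` with fields `overlap_matrix`,
#'   `cumulative`, `rmsip`, `significant` (logical, CO > 0.5 per A-mode).
#' @export
compare_modesets <- function(a, b, i_modes = NULL, j_modes = NULL) {
  stopifnot(inherits(a, "mode_set"), inherits(b, "mode_set"))
  if (a$kind != b$kind) stop("mode sets have different kinds (gnm vs anm)")
  if (a$n_nodes != b$n_nodes)
    stop("dimension mismatch: ", a$n_nodes, " vs ", b$n_nodes, " nodes")
  qa <- .mode_columns(a); qb <- .mode_columns(b)
  if (is.null(i_modes)) i_modes <- ncol(qa)
  if (is.null(j_modes)) j_modes <- ncol(qb)
  om <- abs(t(qa) %*% qb)
  co <- sqrt(rowSums(om[, seq_len(j_modes), drop = FALSE]^2))
  structure(list(overlap_matrix = om, cumulative = pmin(co, 1),
                 rmsip = rmsip(qa, qb, i_modes, j_modes),
                 significant = co > 0.5),
            class = "overlap_report")
}

#' Overlap report between PCA components and ENM modes
#'
#' Computes the PC x mode overlap matrix, each PC's cumulative overlap with
#' the first `k_modes` non-zero modes, RMSIP of the two subspaces, and the
#' CO > 0.5 significance flags.
#'
#' @param pca a `pca_result`.
#' @param modes a `mode_set` (non-zero modes are used).
#' @param n_pcs number of leading PCs to report (default all).
#' @param k_modes number of leading modes for CO and RMSIP (default all).
#' @return an `overlap_report`.
#' @export
pca_mode_overlap <- function(pca, modes, n_pcs = NULL, k_modes = NULL) {
  p <- pca$components
  q <- .mode_columns(modes)
  if (is.null(n_pcs)) n_pcs <- ncol(p)
  if (is.null(k_modes)) k_modes <- ncol(q)
  stopifnot(n_pcs <= ncol(p), k_modes <= ncol(q))
  p <- p[, seq_len(n_pcs), drop = FALSE]
  om <- abs(t(p) %*% q)
  co <- sqrt(rowSums(om[, seq_len(k_modes), drop = FALSE]^2))
  structure(list(overlap_matrix = om, cumulative = pmin(co, 1),
                 rmsip = rmsip(p, q, n_pcs, k_modes),
                 significant = co > 0.5),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<OverlapReport> %d x %d overlaps, RMSIP = %.3f, %d significant CO (> 0.5)\n",
              nrow(x$overlap_matrix), ncol(x$overlap_matrix), x$rmsip,
              sum(x$significant)))
  invisible(x)
}
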