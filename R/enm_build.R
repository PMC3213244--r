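# ---- definitions ------------------------------------------------------------

#' Describe an elastic network model
#'
#' Captures the model kind and spring scheme plus every tunable parameter:
#' `cutoff` (interaction cutoff radius r_c, Angstrom; springs of stiffness
#' `gamma` connect node pairs with d_ij <= r_c), `exponent` p for the
#' distance-weighted scheme (k_ij = gamma / d_ij^p over all pairs),
#' `atomic_contact_cutoff` for nearest-neighbor contact assignment on an
#' atomic reference, and `cutoff_pair` (r_atomic, r_coarse) for mixed
#' resolution, where cross-region pairs use the geometric mean
#' sqrt(r_atomic * r_coarse).
#'
#' Defaults: GNM cutoff 7.3 A, ANM cutoff 13 A, gamma 1, exponent 2,
#' atomic contact cutoff 4.5 A.
#'
#' @param kind `"gnm"` or `"anm"`.
#' @param scheme `"cutoff"`, `"weighted"`, `"nearest_neighbor"` or
#'   `"mixed"`.
#' @param cutoff cutoff radius in Angstrom (scheme `"cutoff"`); `NULL`
#'   selects the kind-specific default.
#' @param gamma spring stiffness (arbitrary units, > 0).
#' @param exponent inverse-power exponent p > 0 (scheme `"weighted"`).
#' @param atomic_contact_cutoff heavy-atom contact distance in Angstrom
#'   (scheme `"nearest_neighbor"`).
#' @param cutoff_pair numeric(2): (r_atomic, r_coarse) in Angstrom
#'   (scheme `"mixed"`).
#' @return object of class `enm_definition`.
#' @export
enm_definition <- function(kind = c("anm", "gnm"),
                           scheme = c("cutoff", "weighted",
                                      "nearest_neighbor", "mixed"),
                           cutoff = NULL, gamma = 1, exponent = 2,
                           atomic_contact_cutoff = 4.5,
                           cutoff_pair = NULL) {
  kind <- match.arg(kind)
  scheme <- match.arg(scheme)
  if (is.null(cutoff)) cutoff <- default_cutoff(kind)
  if (is.null(cutoff_pair)) cutoff_pair <- c(cutoff, cutoff)
  stopifnot(cutoff > 0, gamma > 0, exponent > 0,
            atomic_contact_cutoff > 0, all(cutoff_pair > 0),
            length(cutoff_pair) == 2)
  structure(list(kind = kind, scheme = scheme, cutoff = cutoff,
                 gamma = gamma, exponent = exponent,
                 atomic_contact_cutoff = atomic_contact_cutoff,
                 cutoff_pair = as.numeric(cutoff_pair)),
            class = "enm_definition")
}

#' Default interaction cutoff for a model kind
#'
#' 7.3 A for GNM, 13 A for ANM (upper end of the customary 10-13 A band).
#'
#' @param kind `"gnm"` or `"anm"`.
#' @return cutoff radius in Angstrom.
#' @export
default_cutoff <- function(kind = c("anm", "gnm")) {
  switch(match.arg(kind), gnm = 7.3, anm = 13)
}

# ---- ContactMap -------------------------------------------------------------

#' Construct a ContactMap
#'
#' A symmetric spring assignment stored as the upper-triangular pair list
#' (i < j, 1-based) with positive spring constants.
#'
#' @param i,j integer node indices, elementwise i < j.
#' @param k positive spring constants.
#' @param n node count.
#' @return object of class `contact_map`.
#' @export
contact_map <- function(i, j, k, n) {
  i <- as.integer(i); j <- as.integer(j)
  stopifnot(length(i) == length(j), length(i) == length(k),
            all(i >= 1), all(j <= n), all(i < j), all(k > 0))
  ord <- order(i, j)                     # canonical (i, j) ordering
  structure(list(i = i[ord], j = j[ord], k = as.numeric(k)[ord],
                 n = as.integer(n)),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<ContactMap> %d nodes, %d contact(s)\n", x$n, length(x$i)))
  invisible(x)
}

.pairwise_dist_check <- function(xyz) {
  d <- as.matrix(stats::dist(xyz))
  if (any(d[upper.tri(d)] == 0)) stop("coincident nodes (d_ij = 0)")
  d
}

#' Cutoff-based contact map
#'
#' Pair (i, j) receives a spring of stiffness `gamma` iff d_ij <= r_c
#' (inclusive comparison). Uses a cell-list spatial index for large N; the
#' result is identical to the O(N^2) distance scan.
#'
#' @param points a `point_model`.
#' @param cutoff cutoff radius r_c in Angstrom.
#' @param gamma spring stiffness.
#' @return a `contact_map`.
#' @export
contact_map_cutoff <- function(points, cutoff, gamma = 1) {
  stopifnot(inherits(points, "point_model"), cutoff > 0, gamma > 0)
  xyz <- points$coords
  n <- nrow(xyz)
  pairs <- .neighbor_pairs(xyz, cutoff)
  if (nrow(pairs) && any(pairs[, 3] == 0)) stop("coincident nodes (d_ij = 0)")
  if (nrow(pairs) == 0) return(contact_map(integer(0), integer(0), numeric(0), n))
  contact_map(pairs[, 1], pairs[, 2], rep(gamma, nrow(pairs)), n)
}

# all pairs with d <= cutoff via a uniform cell grid; returns (i, j, d), i<j
.neighbor_pairs <- function(xyz, cutoff) {
  n <- nrow(xyz)
  if (n <= 300) {                       # brute force is faster at small n
    d <- as.matrix(stats::dist(xyz))
    sel <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
    out <- cbind(sel[, 1], sel[, 2], d[sel])
    return(out[order(out[, 1], out[, 2]), , drop = FALSE])
  }
  cell <- pmax(cutoff, 1e-8)
  key <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cell)
  ncell <- apply(key, 2, max) + 1L
  cid <- key[, 1] + ncell[1] * (key[, 2] + ncell[2] * key[, 3])
  ord <- order(cid)
  uid <- unique(cid[ord])
  buckets <- split(ord, factor(cid[ord], levels = uid))
  ukey <- key[ord[!duplicated(cid[ord])], , drop = FALSE]
  # half of the 27-cell neighborhood (incl. self) so each pair comes once
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[offs$dz > 0 | (offs$dz == 0 & offs$dy > 0) |
               (offs$dz == 0 & offs$dy == 0 & offs$dx >= 0), ]
  res <- vector("list", nrow(offs))
  for (o in seq_len(nrow(offs))) {
    nk1 <- ukey[, 1] + offs$dx[o]
    nk2 <- ukey[, 2] + offs$dy[o]
    nk3 <- ukey[, 3] + offs$dz[o]
    inb <- nk1 >= 0 & nk1 < ncell[1] & nk2 >= 0 & nk2 < ncell[2] &
      nk3 >= 0 & nk3 < ncell[3]
    nid <- nk1 + ncell[1] * (nk2 + ncell[2] * nk3)
    hit <- match(nid, uid)
    ok <- which(inb & !is.na(hit))
    if (length(ok) == 0) next
    self <- offs$dx[o] == 0 && offs$dy[o] == 0 && offs$dz[o] == 0
    ii <- jj <- vector("list", length(ok))
    for (m in seq_along(ok)) {
      a <- buckets[[ok[m]]]
      if (self) {
        if (length(a) < 2) next
        cmb <- utils::combn(a, 2)
        ii[[m]] <- pmin(cmb[1, ], cmb[2, ]); jj[[m]] <- pmax(cmb[1, ], cmb[2, ])
      } else {
        b <- buckets[[hit[ok[m]]]]
        la <- length(a); lb <- length(b)
        av <- rep(a, times = lb); bv <- rep(b, each = la)
        ii[[m]] <- pmin(av, bv); jj[[m]] <- pmax(av, bv)
      }
    }
    ii <- unlist(ii); jj <- unlist(jj)
    if (length(ii) == 0) next
    dd <- sqrt(rowSums((xyz[ii, , drop = FALSE] - xyz[jj, , drop = FALSE])^2))
    keep <- dd <= cutoff
    res[[o]] <- cbind(ii[keep], jj[keep], dd[keep])
  }
  out <- do.call(rbind, res)
  if (is.null(out)) return(matrix(numeric(0), 0, 3))
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' Distance-weighted contact map (inverse-power springs)
#'
#' Every pair of nodes is in contact with spring constant
#' k_ij = gamma / d_ij^p. With p = 0 this degenerates to a complete
#' uniform-spring graph.
#'
#' @param points a `point_model`.
#' @param gamma spring stiffness scale.
#' @param exponent inverse-power exponent p >= 0.
#' @return a `contact_map` (dense pair list).
#' @export
contact_map_weighted <- function(points, gamma = 1, exponent = 2) {
  stopifnot(inherits(points, "point_model"), gamma > 0, exponent >= 0)
  xyz <- points$coords
  n <- nrow(xyz)
  d <- .pairwise_dist_check(xyz)
  sel <- which(upper.tri(d), arr.ind = TRUE)
  contact_map(sel[, 1], sel[, 2], gamma / d[sel]^exponent, n)
}

#' Nearest-neighbor contact map from an atomic reference
#'
#' The model is coarse-grained (typically one node per residue) but
#' connectivity is decided on the atomic structure: coarse nodes i and j
#' are in contact iff any pair of atoms from their source residues lies
#' within `atomic_cutoff`. Coarse node labels must resolve to residues of
#' `atomic` (format `chain/RESn.../...` as produced by the selection and
#' centroid builders).
#'
#' @param cg_points coarse `point_model` whose labels identify residues.
#' @param atomic the atomic `enm_structure`.
#' @param atomic_cutoff heavy-atom contact distance (Angstrom).
#' @param gamma spring stiffness.
#' @return a `contact_map` over the coarse nodes.
#' @export
contact_map_nearest_neighbor <- function(cg_points, atomic,
                                         atomic_cutoff = 4.5, gamma = 1) {
  stopifnot(inherits(cg_points, "point_model"),
            inherits(atomic, "enm_structure"),
            atomic_cutoff > 0, gamma > 0)
  n <- n_nodes(cg_points)
  at <- atomic$atoms
  rid_atom <- paste(at$chain, at$resseq, at$icode, sep = "|")
  # node label "chain/RESNUMicode/..." -> residue id
  node_rid <- vapply(seq_len(n), function(i) {
    parts <- strsplit(cg_points$labels[i], "/", fixed = TRUE)[[1]]
    if (length(parts) < 2) return(NA_character_)
    chain <- parts[1]
    m <- regmatches(parts[2], regexec("^[A-Za-z']+(-?[0-9]+)([A-Za-z]?)$",
                                      parts[2]))[[1]]
    if (length(m) < 2) return(NA_character_)
    icode <- if (nzchar(m[3])) m[3] else " "
    paste(chain, m[2], icode, sep = "|")
  }, character(1))
  bad <- which(is.na(node_rid) | !(node_rid %in% rid_atom))
  if (length(bad))
    stop("coarse node(s) with no resolvable residue in atomic structure: ",
         paste(cg_points$labels[bad[seq_len(min(3, length(bad)))]],
               collapse = ", "))
  axyz <- as.matrix(at[, c("x", "y", "z")])
  apairs <- .neighbor_pairs(axyz, atomic_cutoff)
  ci <- integer(0); cj <- integer(0)
  if (nrow(apairs)) {
    ra <- match(rid_atom[apairs[, 1]], node_rid)
    rb <- match(rid_atom[apairs[, 2]], node_rid)
    ok <- !is.na(ra) & !is.na(rb) & ra != rb
    if (any(ok)) {
      pi_ <- pmin(ra[ok], rb[ok]); pj_ <- pmax(ra[ok], rb[ok])
      uniq <- !duplicated(cbind(pi_, pj_))
      ci <- pi_[uniq]; cj <- pj_[uniq]
      ord <- order(ci, cj)
      ci <- ci[ord]; cj <- cj[ord]
    }
  }
  contact_map(ci, cj, rep(gamma, length(ci)), n)
}

#' Mixed-resolution contact map with geometric-mean cross cutoff
#'
#' Applies `r_atomic` to atomic-atomic pairs, `r_coarse` to coarse-coarse
#' pairs and sqrt(r_atomic * r_coarse) to cross pairs, using the node
#' resolution tags of the point model.
#'
#' @param points a `point_model` with `"atomic"`/`"coarse"` tags.
#' @param r_atomic cutoff within the atomic region (Angstrom).
#' @param r_coarse cutoff within the coarse region (Angstrom).
#' @param gamma spring stiffness.
#' @return a `contact_map`.
#' @export
contact_map_mixed <- function(points, r_atomic, r_coarse, gamma = 1) {
  stopifnot(inherits(points, "point_model"), r_atomic > 0, r_coarse > 0,
            gamma > 0)
  xyz <- points$coords
  n <- nrow(xyz)
  d <- .pairwise_dist_check(xyz)
  r_cross <- sqrt(r_atomic * r_coarse)
  atomic <- points$tags == "atomic"
  rc <- matrix(r_coarse, n, n)
  rc[atomic, atomic] <- r_atomic
  rc[atomic, !atomic] <- r_cross
  rc[!atomic, atomic] <- r_cross
  sel <- which(upper.tri(d) & d <= rc, arr.ind = TRUE)
  contact_map(sel[, 1], sel[, 2], rep(gamma, nrow(sel)), n)
}

#' Build a contact map according to an ENM definition
#'
#' Dispatches on `definition$scheme`.
#'
#' @param points a `point_model`.
#' @param definition an `enm_definition`.
#' @param atomic atomic `enm_structure`, required for the
#'   `"nearest_neighbor"` scheme.
#' @return a `contact_map`.
#' @export
build_contact_map <- function(points, definition, atomic = NULL) {
  switch(definition$scheme,
    cutoff = contact_map_cutoff(points, definition$cutoff, definition$gamma),
    weighted = contact_map_weighted(points, definition$gamma,
                                    definition$exponent),
    nearest_neighbor = {
      if (is.null(atomic))
        stop("nearest_neighbor scheme requires the atomic structure")
      contact_map_nearest_neighbor(points, atomic,
                                   definition$atomic_contact_cutoff,
                                   definition$gamma)
    },
    mixed = contact_map_mixed(points, definition$cutoff_pair[1],
                              definition$cutoff_pair[2], definition$gamma))
}

# ---- stiffness matrices -----------------------------------------------------

#' Assemble the GNM Kirchhoff (graph Laplacian) matrix
#'
#' Gamma_ij = -k_ij for contacting pairs, 0 otherwise off the diagonal;
#' Gamma_ii = sum of k_ij over contacts of i. The result is symmetric
#' positive semidefinite with zero row sums, stored sparse.
#'
#' @param contacts a `contact_map`.
#' @param coords optional N x 3 coordinate snapshot stored alongside.
#' @param definition optional `enm_definition` recorded for provenance.
#' @return object of class `stiffness_matrix` with `kind = "gnm"`.
#' @export
assemble_gnm <- function(contacts, coords = NULL, definition = NULL) {
  stopifnot(inherits(contacts, "contact_map"), contacts$n >= 2)
  n <- contacts$n
  if (length(contacts$i)) {
    off <- Matrix::sparseMatrix(i = contacts$i, j = contacts$j,
                                x = -contacts$k, dims = c(n, n),
                                symmetric = TRUE)
    diag_vals <- -Matrix::rowSums(off)
    m <- off + Matrix::Diagonal(n, diag_vals)
  } else {
    m <- Matrix::Matrix(0, n, n, sparse = TRUE)
  }
  structure(list(kind = "gnm", matrix = Matrix::forceSymmetric(m),
                 coords = coords, definition = definition),
            class = "stiffness_matrix")
}

#' Assemble the ANM Hessian
#'
#' The 3N x 3N second-derivative matrix of the harmonic potential, built
#' from 3 x 3 super-elements: for a contacting pair with separation vector
#' r_ij and distance d_ij, the off-diagonal block is
#' -(k_ij / d_ij^2) r_ij r_ij^T, and each diagonal block is minus the sum
#' of that node's off-diagonal blocks. Node i occupies rows/cols
#' 3(i-1)+1 .. 3i. Symmetric PSD; annihilates rigid-body motions.
#'
#' @param contacts a `contact_map`.
#' @param coords N x 3 coordinate matrix of the contact map's nodes.
#' @param definition optional `enm_definition` recorded for provenance.
#' @return object of class `stiffness_matrix` with `kind = "anm"`.
#' @export
assemble_anm <- function(contacts, coords, definition = NULL) {
  stopifnot(inherits(contacts, "contact_map"))
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == contacts$n, ncol(coords) == 3)
  n <- contacts$n
  np <- length(contacts$i)
  if (np == 0) {
    m <- Matrix::Matrix(0, 3 * n, 3 * n, sparse = TRUE)
    return(structure(list(kind = "anm", matrix = m, coords = coords,
                          definition = definition),
                     class = "stiffness_matrix"))
  }
  rij <- coords[contacts$j, , drop = FALSE] - coords[contacts$i, , drop = FALSE]
  d2 <- rowSums(rij^2)
  if (any(d2 == 0)) stop("coincident contacting nodes")
  # per-pair 3x3 block entries, scaled
  scale <- contacts$k / d2
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  for (a in 1:3) for (b in 1:3) {
    v <- -scale * rij[, a] * rij[, b]
    ti <- c(ti, 3 * (contacts$i - 1) + a, 3 * (contacts$j - 1) + a)
    tj <- c(tj, 3 * (contacts$j - 1) + b, 3 * (contacts$i - 1) + b)
    tx <- c(tx, v, v)
    # diagonal blocks accumulate the negatives
    ti <- c(ti, 3 * (contacts$i - 1) + a, 3 * (contacts$j - 1) + a)
    tj <- c(tj, 3 * (contacts$i - 1) + b, 3 * (contacts$j - 1) + b)
    tx <- c(tx, -v, -v)
  }
  m <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(3 * n, 3 * n))
  structure(list(kind = "anm", matrix = Matrix::forceSymmetric(m),
                 coords = coords, definition = definition),
            class = "stiffness_matrix")
}

#' @export
print.stiffness_matrix <- function(x, ...) {
  cat(sprintf("<StiffnessMatrix> %s, %d x %d, %d nonzero(s)\n",
              toupper(x$kind), nrow(x$matrix), ncol(x$matrix),
              Matrix::nnzero(x$matrix)))
  invisible(x)
}

#' Build an ENM stiffness matrix in one call
#'
#' Convenience wrapper: contact map per `definition$scheme`, then GNM
#' Kirchhoff or ANM Hessian assembly per `definition$kind`.
#'
#' @param points a `point_model`.
#' @param definition an `enm_definition`.
#' @param atomic atomic structure for the nearest-neighbor scheme.
#' @return a `stiffness_matrix`.
#' @export
build_enm <- function(points, definition = enm_definition(), atomic = NULL) {
  cm <- build_contact_map(points, definition, atomic = atomic)
  if (definition$kind == "gnm")
    assemble_gnm(cm, coords = points$coords, definition = definition)
  else
    assemble_anm(cm, coords = points$coords, definition = definition)
}

# ---- text export ------------------------------------------------------------

#' Write a ContactMap as a 3-column edge list
#'
#' Columns i, j, k_ij with 0-based node indices, tab-separated.
#'
#' @param contacts a `contact_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(contacts, path) {
  df <- data.frame(i = contacts$i - 1L, j = contacts$j - 1L, k = contacts$k)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a StiffnessMatrix in coordinate (triplet) text format
#'
#' Rows: row, col, value (0-based, upper triangle including diagonal).
#'
#' @param H a `stiffness_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stiffness_matrix <- function(H, path) {
  t3 <- as(as(H$matrix, "generalMatrix"), "TsparseMatrix")
  keep <- t3@i <= t3@j
  df <- data.frame(row = t3@i[keep], col = t3@j[keep], value = t3@x[keep])
  df <- df[order(df$row, df$col), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
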