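# ---- PointModel -------------------------------------------------------------

#' Construct a PointModel
#'
#' The set of spatial nodes that define an elastic network: an N x 3
#' coordinate matrix plus per-node provenance labels, a resolution tag
#' (`"atomic"` or `"coarse"`) used by mixed-resolution spring schemes, and
#' optional per-node B-factors carried over from the source atoms.
#'
#' @param coords N x 3 numeric matrix (Angstrom).
#' @param labels character vector of per-node provenance labels.
#' @param tags per-node resolution tag, `"atomic"` or `"coarse"`.
#' @param bfactors optional per-node B-factors (Angstrom^2).
#' @param source one of `"atoms"`, `"centroids"`, `"density"`, `"mixed"`.
#' @return object of class `point_model`.
#' @export
point_model <- function(coords, labels = NULL, tags = "coarse",
                        bfactors = NULL,
                        source = c("atoms", "centroids", "density", "mixed")) {
  source <- match.arg(source)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  stopifnot(ncol(coords) == 3, all(is.finite(coords)))
  n <- nrow(coords)
  if (is.null(labels)) labels <- sprintf("node%d", seq_len(n))
  if (length(tags) == 1) tags <- rep(tags, n)
  stopifnot(length(labels) == n, length(tags) == n,
            all(tags %in% c("atomic", "coarse")))
  if (!is.null(bfactors)) stopifnot(length(bfactors) == n)
  if (n >= 2) {
    dup <- .has_duplicate_rows(coords)
    if (dup) stop("PointModel has exactly coincident nodes")
  }
  structure(list(coords = unname(coords), labels = labels, tags = tags,
                 bfactors = bfactors, source = source),
            class = "point_model")
}

.has_duplicate_rows <- function(m) {
  anyDuplicated(apply(m, 1, paste, collapse = "\r")) > 0
}

#' @export
print.point_model <- function(x, ...) {
  cat(sprintf("<PointModel> %d nodes (source: %s, %d atomic / %d coarse)\n",
              nrow(x$coords), x$source, sum(x$tags == "atomic"),
              sum(x$tags == "coarse")))
  invisible(x)
}

#' Number of nodes in a PointModel
#' @param points a `point_model`.
#' @return integer node count.
#' @export
n_nodes <- function(points) nrow(points$coords)

# ---- selection --------------------------------------------------------------

#' Build an atom selection specification
#'
#' All supplied criteria are combined with logical AND; at least one must be
#' given. Insertion codes are part of residue identity, so `resseq` filters
#' match the file's numbering as-is.
#'
#' @param names atom-name set, e.g. `"CA"`.
#' @param chains chain identifiers to keep.
#' @param resseq residue-number vector (e.g. `5:20`) to keep.
#' @param elements element symbols to keep.
#' @param records record types to keep (`"ATOM"`, `"HETATM"`).
#' @return object of class `selection_spec`.
#' @export
selection_spec <- function(names = NULL, chains = NULL, resseq = NULL,
                           elements = NULL, records = NULL) {
  if (is.null(names) && is.null(chains) && is.null(resseq) &&
      is.null(elements) && is.null(records))
    stop("selection_spec requires at least one non-empty criterion")
  structure(list(names = names, chains = chains, resseq = resseq,
                 elements = elements, records = records),
            class = "selection_spec")
}

#' @export
format.selection_spec <- function(x, ...) {
  parts <- Filter(nzchar, c(
    if (!is.null(x$names)) paste0("name in {", paste(x$names, collapse = ","), "}") else "",
    if (!is.null(x$chains)) paste0("chain in {", paste(x$chains, collapse = ","), "}") else "",
    if (!is.null(x$resseq)) sprintf("resseq in [%d..%d]", min(x$resseq), max(x$resseq)) else "",
    if (!is.null(x$elements)) paste0("element in {", paste(x$elements, collapse = ","), "}") else "",
    if (!is.null(x$records)) paste0("record in {", paste(x$records, collapse = ","), "}") else ""))
  paste(parts, collapse = " & ")
}

.selection_mask <- function(atoms, spec) {
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(spec$names)) keep <- keep & atoms$name %in% spec$names
  if (!is.null(spec$chains)) keep <- keep & atoms$chain %in% spec$chains
  if (!is.null(spec$resseq)) keep <- keep & atoms$resseq %in% spec$resseq
  if (!is.null(spec$elements)) keep <- keep & atoms$element %in% spec$elements
  if (!is.null(spec$records)) keep <- keep & atoms$record %in% spec$records
  keep
}

.atom_labels <- function(atoms) {
  sprintf("%s/%s%d%s/%s", atoms$chain, atoms$resname, atoms$resseq,
          trimws(atoms$icode), atoms$name)
}

#' Select atoms from a Structure as ENM nodes
#'
#' Nodes are exactly the atoms matching every criterion of the spec, in
#' file order, with B-factors copied from the source atoms.
#'
#' @param structure an `enm_structure`.
#' @param spec a `selection_spec`.
#' @param tag resolution tag given to the selected nodes.
#' @return a `point_model` with `source = "atoms"`.
#' @export
select_points <- function(structure, spec, tag = "coarse") {
  stopifnot(inherits(structure, "enm_structure"),
            inherits(spec, "selection_spec"))
  keep <- .selection_mask(structure$atoms, spec)
  if (!any(keep))
    stop("selection matched no atoms: ", format(spec))
  at <- structure$atoms[keep, , drop = FALSE]
  point_model(as.matrix(at[, c("x", "y", "z")]),
              labels = .atom_labels(at), tags = tag,
              bfactors = at$bfactor, source = "atoms")
}

# ---- centroids --------------------------------------------------------------

.BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")
.NUC_SUGAR_ATOMS <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'",
                      "O3'", "C2'", "O2'", "C1'")

#' Centroid (united-atom) coarse-graining
#'
#' Replaces each residue group with a single node at the (optionally
#' mass-weighted) mean of its member atoms. Groupings: `"residue"` (all
#' atoms), `"sidechain"` (all atoms except backbone N/CA/C/O/OXT; residues
#' with no side-chain atoms, such as glycine, fall back to the residue
#' centroid, logged), `"base_and_sugar"` (nucleotides yield two nodes, one
#' for sugar-phosphate atoms, one for base atoms). Node B-factor is the mean
#' of the member B-factors.
#'
#' @param structure an `enm_structure`.
#' @param grouping `"residue"`, `"sidechain"` or `"base_and_sugar"`.
#' @param weighting `"uniform"` or `"mass"` (standard atomic masses by
#'   element).
#' @return a `point_model` with `source = "centroids"`.
#' @export
centroid_points <- function(structure,
                            grouping = c("residue", "sidechain",
                                         "base_and_sugar"),
                            weighting = c("uniform", "mass")) {
  grouping <- match.arg(grouping)
  weighting <- match.arg(weighting)
  at <- structure$atoms
  if (nrow(at) == 0) stop("empty structure")
  gid <- paste(at$chain, at$resseq, at$icode, sep = "|")
  groups <- split(seq_len(nrow(at)), factor(gid, levels = unique(gid)))

  masses <- if (weighting == "mass") .element_mass(at$element, at$name)
            else rep(1, nrow(at))

  res_coords <- list(); res_b <- numeric(0); res_lab <- character(0)
  fallback <- 0L
  for (g in groups) {
    sub <- at[g, , drop = FALSE]
    base_lab <- sprintf("%s/%s%d%s", sub$chain[1], sub$resname[1],
                        sub$resseq[1], trimws(sub$icode[1]))
    members <- switch(grouping,
      residue = list(g),
      sidechain = {
        sc <- g[!(sub$name %in% .BACKBONE_ATOMS)]
        if (length(sc) == 0) { fallback <- fallback + 1L; list(g) }
        else list(sc)
      },
      base_and_sugar = {
        sugar <- g[sub$name %in% .NUC_SUGAR_ATOMS]
        base <- setdiff(g, sugar)
        parts <- list()
        if (length(sugar)) parts <- c(parts, list(sugar))
        if (length(base)) parts <- c(parts, list(base))
        if (length(parts) == 0) { fallback <- fallback + 1L; list(g) }
        else parts
      })
    suffix <- if (grouping == "base_and_sugar" && length(members) == 2)
      c("/sugar", "/base") else rep("", length(members))
    for (mi in seq_along(members)) {
      m <- members[[mi]]
      w <- masses[m] / sum(masses[m])
      res_coords[[length(res_coords) + 1L]] <-
        colSums(as.matrix(at[m, c("x", "y", "z")]) * w)
      res_b <- c(res_b, mean(at$bfactor[m]))
      res_lab <- c(res_lab, paste0(base_lab, suffix[mi]))
    }
  }
  if (fallback > 0)
    message(sprintf("%d residue(s) lacked atoms for grouping '%s'; fell back to residue centroid",
                    fallback, grouping))
  point_model(do.call(rbind, res_coords), labels = res_lab,
              bfactors = res_b, source = "centroids")
}

.element_mass <- function(element, name) {
  tab <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
           S = 32.06, FE = 55.845, ZN = 65.38, MG = 24.305, CA = 40.078)
  el <- toupper(element)
  guess <- toupper(substr(gsub("[^A-Za-z].*", "", name), 1, 1))
  el[!nzchar(el)] <- guess[!nzchar(el)]
  m <- tab[el]
  m[is.na(m)] <- 12.011
  unname(m)
}

# ---- spherical coarse-graining ----------------------------------------------

#' Spherical coarse-graining by greedy radius packing
#'
#' Starting from the seed set, every unretained point within `radius` of a
#' retained point is removed, then the unretained point closest to the
#' retained set (minimum distance over all retained points, ties broken by
#' lowest node index) is added to the retained set. This repeats until no
#' unretained points remain. The result is a maximal radius-packing: every
#' pair of retained points is more than `radius` apart and every removed
#' point is within `radius` of some retained point. Output preserves
#' retention order (seeds first).
#'
#' @param points a `point_model`.
#' @param radius packing radius (Angstrom, > 0).
#' @param seed_indices node indices (1-based) retained unconditionally;
#'   empty defaults to node 1 (logged).
#' @return a `point_model` containing the retained subset.
#' @export
spherical_coarse_grain <- function(points, radius, seed_indices = 1L) {
  stopifnot(inherits(points, "point_model"), radius > 0)
  n <- n_nodes(points)
  if (length(seed_indices) == 0) {
    message("empty seed set; defaulting to node 1")
    seed_indices <- 1L
  }
  seed_indices <- as.integer(seed_indices)
  stopifnot(all(seed_indices >= 1), all(seed_indices <= n))
  xyz <- points$coords

  retained <- unique(seed_indices)
  alive <- setdiff(seq_len(n), retained)
  # min distance from each alive point to the retained set
  mind <- rep(Inf, n)
  if (length(alive)) {
    for (r in retained) {
      d <- sqrt(rowSums((xyz[alive, , drop = FALSE] -
                         matrix(xyz[r, ], length(alive), 3, byrow = TRUE))^2))
      mind[alive] <- pmin(mind[alive], d)
    }
  }
  repeat {
    alive <- alive[mind[alive] > radius]
    if (length(alive) == 0) break
    pick <- alive[which.min(mind[alive])]   # which.min takes first = lowest idx
    retained <- c(retained, pick)
    alive <- setdiff(alive, pick)
    if (length(alive)) {
      d <- sqrt(rowSums((xyz[alive, , drop = FALSE] -
                         matrix(xyz[pick, ], length(alive), 3, byrow = TRUE))^2))
      mind[alive] <- pmin(mind[alive], d)
    }
  }
  point_model(xyz[retained, , drop = FALSE],
              labels = points$labels[retained],
              tags = points$tags[retained],
              bfactors = if (is.null(points$bfactors)) NULL
                         else points$bfactors[retained],
              source = points$source)
}

# ---- density-derived points -------------------------------------------------

#' Convert a density grid to ENM points along a contour
#'
#' Candidate points are the world-coordinate centers of every voxel whose
#' value meets the threshold (filled volume above the contour); the
#' candidates are then spherically coarse-grained at `packing_radius`,
#' seeded at the highest-density voxel. Node labels record the voxel index
#' and density value.
#'
#' @param grid a `density_grid`.
#' @param threshold density contour level; voxels with value >= threshold
#'   become candidates.
#' @param packing_radius spherical coarse-graining radius (Angstrom).
#' @return a `point_model` with `source = "density"`.
#' @export
density_to_points <- function(grid, threshold, packing_radius) {
  stopifnot(inherits(grid, "density_grid"), packing_radius > 0)
  hit <- which(grid$values >= threshold, arr.ind = TRUE)
  if (nrow(hit) == 0)
    stop(sprintf("no voxel above threshold %g (grid max %g)",
                 threshold, max(grid$values)))
  vals <- grid$values[hit]
  world <- sweep((hit - 1) %*% diag(grid$voxel_size), 2, grid$origin, `+`)
  labels <- sprintf("voxel(%d,%d,%d)=%.4g", hit[, 1], hit[, 2], hit[, 3], vals)
  pm <- point_model(world, labels = labels, source = "density")
  seed <- which.max(vals)
  spherical_coarse_grain(pm, radius = packing_radius, seed_indices = seed)
}

# ---- mixed resolution -------------------------------------------------------

#' Build a mixed-resolution point model
#'
#' Atoms matching `detail_spec` enter at full atomic detail (tag
#' `"atomic"`); `coarse_spec` supplies the coarse nodes (tag `"coarse"`,
#' typically a CA selection). The two selections must be disjoint at the
#' residue level. Output order is the atomic block then the coarse block,
#' each in file order.
#'
#' @param structure an `enm_structure`.
#' @param detail_spec `selection_spec` for the region kept at atomic detail.
#' @param coarse_spec `selection_spec` for the coarse representation.
#' @return a `point_model` with `source = "mixed"`.
#' @export
mixed_resolution_model <- function(structure, detail_spec, coarse_spec) {
  at <- structure$atoms
  dmask <- .selection_mask(at, detail_spec)
  cmask <- .selection_mask(at, coarse_spec)
  rid <- paste(at$chain, at$resseq, at$icode, sep = "|")
  both <- intersect(unique(rid[dmask]), unique(rid[cmask]))
  if (length(both))
    stop("residue(s) matched by both detail and coarse specs: ",
         paste(both, collapse = "; "))
  if (!any(cmask) && !any(dmask)) stop("both selections are empty")
  blocks <- list()
  if (any(dmask)) {
    da <- at[dmask, , drop = FALSE]
    blocks$atomic <- list(coords = as.matrix(da[, c("x", "y", "z")]),
                          labels = .atom_labels(da), tags = "atomic",
                          b = da$bfactor)
  }
  if (any(cmask)) {
    ca <- at[cmask, , drop = FALSE]
    blocks$coarse <- list(coords = as.matrix(ca[, c("x", "y", "z")]),
                          labels = .atom_labels(ca), tags = "coarse",
                          b = ca$bfactor)
  }
  coords <- do.call(rbind, lapply(blocks, `[[`, "coords"))
  tags <- unlist(lapply(blocks, function(b) rep(b$tags, nrow(b$coords))))
  point_model(coords,
              labels = unlist(lapply(blocks, `[[`, "labels")),
              tags = unname(tags),
              bfactors = unlist(lapply(blocks, `[[`, "b")),
              source = if (any(dmask) && any(cmask)) "mixed" else "atoms")
}

# ---- export -----------------------------------------------------------------

#' Write a PointModel as a plain-text table
#'
#' Columns: index, x, y, z, tag, label (tab-separated, with header).
#'
#' @param points a `point_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_point_table <- function(points, path) {
  df <- data.frame(index = seq_len(n_nodes(points)),
                   x = points$coords[, 1], y = points$coords[, 2],
                   z = points$coords[, 3], tag = points$tags,
                   label = points$labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert a PointModel to a Structure of CA pseudo-atoms
#'
#' Used to export coarse models to molecular viewers: each node becomes a
#' CA atom of residue ALA, chain A, sequential numbering; node B-factors
#' are carried into the B column when present.
#'
#' @param points a `point_model`.
#' @return an `enm_structure`.
#' @export
points_to_structure <- function(points) {
  n <- n_nodes(points)
  b <- if (is.null(points$bfactors)) rep(0, n) else points$bfactors
  structure_new(data.frame(
    serial = seq_len(n), name = "CA", altloc = " ", resname = "ALA",
    chain = "A", resseq = seq_len(n), icode = " ",
    x = points$coords[, 1], y = points$coords[, 2], z = points$coords[, 3],
    occupancy = 1, bfactor = b, element = "C", record = "ATOM",
    stringsAsFactors = FALSE))
}
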