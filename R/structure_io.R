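# ---- domain types -----------------------------------------------------------

#' Construct a Structure object
#'
#' A `Structure` holds the ordered atom records of one coordinate model:
#' serial, atom name, alternate location, residue name, chain, residue
#' number, insertion code, Cartesian coordinates (Angstrom), occupancy,
#' B-factor (Angstrom^2), element symbol and, when present, the six unique
#' anisotropic displacement tensor elements (U11, U22, U33, U12, U13, U23,
#' Angstrom^2).
#'
#' @param atoms data.frame with columns `serial`, `name`, `altloc`,
#'   `resname`, `chain`, `resseq`, `icode`, `x`, `y`, `z`, `occupancy`,
#'   `bfactor`, `element`, `record`, and optionally `u11` .. `u23`.
#' @param model_id integer model identifier (1 for single-model files).
#' @return object of class `enm_structure`.
#' @export
structure_new <- function(atoms, model_id = 1L) {
  stopifnot(is.data.frame(atoms))
  need <- c("serial", "name", "altloc", "resname", "chain", "resseq",
            "icode", "x", "y", "z", "occupancy", "bfactor", "element",
            "record")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")
  structure(list(atoms = atoms, model_id = as.integer(model_id)),
            class = "enm_structure")
}

#' @export
print.enm_structure <- function(x, ...) {
  cat(sprintf("<Structure> %d atoms, model %d, %d chain(s)\n",
              nrow(x$atoms), x$model_id, length(unique(x$atoms$chain))))
  invisible(x)
}

#' Number of atoms in a Structure
#' @param structure an `enm_structure`.
#' @return integer atom count.
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

#' Atom coordinates of a Structure as an N x 3 matrix
#' @param structure an `enm_structure`.
#' @return numeric matrix with columns x, y, z (Angstrom).
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Construct a StructureEnsemble
#'
#' An ordered collection of Structures (e.g. the MODEL blocks of an NMR
#' entry or frames of a trajectory). The `correspondence` flag is true when
#' every frame has the same atoms (name/resseq/chain) in the same order,
#' which downstream superposition and PCA require.
#'
#' @param frames list of `enm_structure` objects.
#' @return object of class `enm_ensemble`.
#' @export
ensemble_new <- function(frames) {
  stopifnot(length(frames) >= 1,
            all(vapply(frames, inherits, logical(1), "enm_structure")))
  key <- function(s) paste(s$atoms$name, s$atoms$resseq, s$atoms$chain,
                           sep = "|")
  k0 <- key(frames[[1]])
  corr <- all(vapply(frames, function(f) {
    nrow(f$atoms) == length(k0) && all(key(f) == k0)
  }, logical(1)))
  structure(list(frames = frames, correspondence = corr),
            class = "enm_ensemble")
}

#' @export
print.enm_ensemble <- function(x, ...) {
  cat(sprintf("<StructureEnsemble> %d frame(s), %d atoms, correspondence=%s\n",
              length(x$frames), nrow(x$frames[[1]]$atoms),
              x$correspondence))
  invisible(x)
}

#' Construct a DensityGrid
#'
#' A 3-D scalar field on a regular orthogonal grid. Values are stored with
#' the X axis fastest (first array dimension); `axis_order` records the axis
#' permutation of the source file (MAPC/MAPR/MAPS) before normalization.
#'
#' @param values 3-D numeric array, dim = grid sampling along (x, y, z).
#' @param voxel_size length-3 positive numeric, Angstrom per voxel.
#' @param origin length-3 numeric, world coordinates of voxel (1,1,1) center
#'   (Angstrom).
#' @param axis_order integer(3), original fastest-to-slowest axis ids.
#' @return object of class `density_grid`.
#' @export
density_grid <- function(values, voxel_size, origin = c(0, 0, 0),
                         axis_order = 1:3) {
  stopifnot(is.array(values), length(dim(values)) == 3,
            all(dim(values) >= 1),
            length(voxel_size) == 3, all(voxel_size > 0),
            length(origin) == 3)
  structure(list(values = values, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin),
                 axis_order = as.integer(axis_order)),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<DensityGrid> %s voxels, voxel size (%.3g, %.3g, %.3g) A\n",
              paste(dim(x$values), collapse = "x"),
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

# ---- PDB reading ------------------------------------------------------------

# fixed-column field helpers; PDB columns are 1-based inclusive
.substr_num <- function(lines, from, to, what, lineno) {
  raw <- trimws(substr(lines, from, to))
  out <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(out) & nzchar(raw) | !nzchar(raw) & what == "coordinate")
  if (length(bad)) {
    stop(sprintf("malformed %s field at line %d: '%s'", what,
                 lineno[bad[1]], raw[bad[1]]))
  }
  out
}

.parse_atom_lines <- function(lines, lineno) {
  data.frame(
    serial = as.integer(.substr_num(lines, 7, 11, "serial", lineno)),
    name = trimws(substr(lines, 13, 16)),
    altloc = substr(lines, 17, 17),
    resname = trimws(substr(lines, 18, 20)),
    chain = substr(lines, 22, 22),
    resseq = as.integer(.substr_num(lines, 23, 26, "residue number", lineno)),
    icode = substr(lines, 27, 27),
    x = .substr_num(lines, 31, 38, "coordinate", lineno),
    y = .substr_num(lines, 39, 46, "coordinate", lineno),
    z = .substr_num(lines, 47, 54, "coordinate", lineno),
    occupancy = {
      v <- suppressWarnings(as.numeric(trimws(substr(lines, 55, 60))))
      ifelse(is.na(v), 1, v)
    },
    bfactor = {
      v <- suppressWarnings(as.numeric(trimws(substr(lines, 61, 66))))
      ifelse(is.na(v), 0, v)
    },
    element = trimws(substr(lines, 77, 78)),
    record = trimws(substr(lines, 1, 6)),
    stringsAsFactors = FALSE
  )
}

.parse_one_model <- function(lines, lineno, model_id) {
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM") |
    trimws(rec) %in% c("ATOM", "HETATM")
  is_anisou <- trimws(rec) == "ANISOU"
  atoms <- .parse_atom_lines(lines[is_atom], lineno[is_atom])

  # altloc policy: keep blank or 'A', drop others
  drop <- !(atoms$altloc %in% c(" ", "", "A"))
  if (any(drop)) {
    message(sprintf("dropped %d alternate-location atom(s) (kept ' '/'A')",
                    sum(drop)))
    atoms <- atoms[!drop, , drop = FALSE]
  }

  atoms$u11 <- NA_real_; atoms$u22 <- NA_real_; atoms$u33 <- NA_real_
  atoms$u12 <- NA_real_; atoms$u13 <- NA_real_; atoms$u23 <- NA_real_
  if (any(is_anisou)) {
    alines <- lines[is_anisou]
    aser <- as.integer(trimws(substr(alines, 7, 11)))
    # ANISOU integers are U * 1e4 Angstrom^2
    u <- vapply(seq(29, 64, by = 7), function(from) {
      as.numeric(trimws(substr(alines, from, from + 6))) / 1e4
    }, numeric(length(alines)))
    u <- matrix(u, ncol = 6)
    idx <- match(aser, atoms$serial)
    orphan <- is.na(idx)
    if (any(orphan)) {
      warning(sprintf("%d ANISOU record(s) without matching ATOM dropped",
                      sum(orphan)))
    }
    ok <- which(!orphan)
    if (length(ok)) {
      atoms[idx[ok], c("u11", "u22", "u33", "u12", "u13", "u23")] <- u[ok, ]
    }
  }
  rownames(atoms) <- NULL
  structure_new(atoms, model_id = model_id)
}

#' Read a fixed-column PDB file
#'
#' Parses ATOM, HETATM and ANISOU records; HETATM is treated like ATOM.
#' ANISOU integers are interpreted as U x 1e4 Angstrom^2 and rescaled.
#' Alternate locations other than blank or 'A' are dropped (counts logged).
#' Files with MODEL records yield one Structure per model.
#'
#' @param path path to a PDB file.
#' @param model_policy `"first"` returns the first model as an
#'   `enm_structure`; `"all"` returns an `enm_ensemble` over all models.
#' @return `enm_structure` or `enm_ensemble`.
#' @export
read_pdb <- function(path, model_policy = c("first", "all")) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  rec <- trimws(substr(lines, 1, 6))

  model_starts <- which(rec == "MODEL")
  if (length(model_starts) == 0) {
    s <- .parse_one_model(lines, lineno, 1L)
    if (n_atoms(s) == 0) stop("no ATOM/HETATM records in ", path)
    if (model_policy == "all") return(ensemble_new(list(s)))
    return(s)
  }
  model_ends <- which(rec == "ENDMDL")
  frames <- vector("list", length(model_starts))
  for (k in seq_along(model_starts)) {
    from <- model_starts[k] + 1L
    to <- if (k <= length(model_ends)) model_ends[k] - 1L else length(lines)
    sel <- from:to
    mid <- suppressWarnings(as.integer(trimws(substr(lines[model_starts[k]],
                                                     7, 80))))
    if (is.na(mid)) mid <- k
    frames[[k]] <- .parse_one_model(lines[sel], lineno[sel], mid)
  }
  if (model_policy == "first") return(frames[[1]])
  ensemble_new(frames)
}

# ---- PDB writing ------------------------------------------------------------

.format_atom_name <- function(name, element) {
  # standard PDB alignment: 1-2 char element symbols start in column 14
  ifelse(nchar(name) >= 4, substr(name, 1, 4),
         sprintf(" %-3s", name))
}

.atom_line <- function(a, bfac) {
  sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          a$record, a$serial %% 100000L,
          .format_atom_name(a$name, a$element), a$altloc,
          a$resname, a$chain, a$resseq %% 10000L, a$icode,
          a$x, a$y, a$z, a$occupancy, bfac, a$element)
}

.anisou_line <- function(a) {
  sprintf("ANISOU%5d %s%1s%-3s %1s%4d%1s %7d%7d%7d%7d%7d%7d      %2s",
          a$serial %% 100000L, .format_atom_name(a$name, a$element),
          a$altloc, a$resname, a$chain, a$resseq %% 10000L, a$icode,
          round(a$u11 * 1e4), round(a$u22 * 1e4), round(a$u33 * 1e4),
          round(a$u12 * 1e4), round(a$u13 * 1e4), round(a$u23 * 1e4),
          a$element)
}

.write_model_lines <- function(s, bfactor_override = NULL) {
  at <- s$atoms
  if (any(abs(c(at$x, at$y, at$z)) >= 10000))
    stop("coordinate magnitude >= 10000 A breaks fixed PDB columns")
  bfac <- if (is.null(bfactor_override)) at$bfactor else bfactor_override
  out <- character(0)
  has_u <- "u11" %in% names(at) && any(!is.na(at$u11))
  for (i in seq_len(nrow(at))) {
    a <- at[i, ]
    out <- c(out, .atom_line(a, bfac[i]))
    if (has_u && !is.na(a$u11)) out <- c(out, .anisou_line(a))
  }
  out
}

#' Write a Structure or StructureEnsemble to PDB format
#'
#' Multi-frame input is wrapped in MODEL/ENDMDL pairs numbered from 1, the
#' layout molecular viewers use for animations. Coordinates are written at
#' the format's 0.001 A precision and B-factors at 0.01 A^2, so a
#' write/read round trip reproduces them at that precision. Atoms carrying
#' anisotropic U tensors emit ANISOU records.
#'
#' @param x `enm_structure` or `enm_ensemble`.
#' @param path output file path.
#' @param bfactor_override optional numeric vector (length = atom count)
#'   written into the B-factor column of every frame.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path, bfactor_override = NULL) {
  if (inherits(x, "enm_structure")) x <- ensemble_new(list(x))
  stopifnot(inherits(x, "enm_ensemble"))
  na <- nrow(x$frames[[1]]$atoms)
  if (!is.null(bfactor_override) && length(bfactor_override) != na)
    stop("bfactor_override length (", length(bfactor_override),
         ") != atom count (", na, ")")
  multi <- length(x$frames) > 1
  out <- character(0)
  for (k in seq_along(x$frames)) {
    body <- .write_model_lines(x$frames[[k]], bfactor_override)
    if (multi) {
      out <- c(out, sprintf("MODEL     %4d", k), body, "ENDMDL")
    } else {
      out <- c(out, body)
    }
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}

# ---- MRC/CCP4 density maps --------------------------------------------------

#' Read an MRC/CCP4 2014-style density map
#'
#' Supports modes 0 (int8), 1 (int16) and 2 (float32) on orthogonal cells.
#' The data array is normalized so the first array dimension is the
#' crystallographic X axis regardless of the file's MAPC/MAPR/MAPS order;
#' the original order is kept in `axis_order`. Voxel size is cell length
#' divided by grid sampling; the origin is taken from the ORIGIN words when
#' set, else from NXSTART/NYSTART/NZSTART.
#'
#' @param path path to an MRC/CCP4 map file.
#' @return a `density_grid`.
#' @export
read_density_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdr_flt <- readBin(con, "numeric", n = 256, size = 4, endian = "little")
  nc <- hdr_int[1]; nr <- hdr_int[2]; ns <- hdr_int[3]
  mode <- hdr_int[4]
  mxyz <- hdr_int[8:10]
  cella <- hdr_flt[11:13]
  cellb <- hdr_flt[14:16]
  mapc <- hdr_int[17]; mapr <- hdr_int[18]; maps <- hdr_int[19]
  nstart <- hdr_int[5:7]
  origin_words <- hdr_flt[50:52]
  nsymbt <- hdr_int[24]
  if (!(mode %in% c(0L, 1L, 2L)))
    stop("unsupported MRC mode ", mode, " (supported: 0, 1, 2)")
  if (any(abs(cellb - 90) > 1e-3))
    stop("non-orthogonal cell (angles ", paste(round(cellb, 2), collapse = ", "),
         ") is unsupported")
  seek(con, 1024 + nsymbt)
  nvox <- as.numeric(nc) * nr * ns
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = nvox, size = 1,
                             signed = TRUE, endian = "little")),
    "1" = as.numeric(readBin(con, "integer", n = nvox, size = 2,
                             signed = TRUE, endian = "little")),
    "2" = readBin(con, "numeric", n = nvox, size = 4, endian = "little"))
  if (length(vals) != nvox) stop("truncated map data in ", path)
  arr <- array(vals, dim = c(nc, nr, ns))
  # reorder so dim 1 = X, dim 2 = Y, dim 3 = Z
  file_axes <- c(mapc, mapr, maps)          # axis id of each array dim
  perm <- order(file_axes)                  # perm[k] = dim holding axis k
  arr <- aperm(arr, perm)
  voxel <- cella / ifelse(mxyz > 0, mxyz, c(nc, nr, ns)[perm])
  if (any(origin_words != 0)) {
    origin <- origin_words
  } else {
    origin <- nstart[perm] * voxel
  }
  density_grid(arr, voxel_size = voxel, origin = origin,
               axis_order = file_axes)
}

#' Write a DensityGrid as an MRC/CCP4 map (mode 2, float32)
#'
#' Writes X-fastest axis order (MAPC/MAPR/MAPS = 1/2/3) with the grid origin
#' stored in the ORIGIN header words. Output is byte-stable for identical
#' input.
#'
#' @param grid a `density_grid`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_density_map <- function(grid, path) {
  stopifnot(inherits(grid, "density_grid"))
  d <- dim(grid$values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  vals <- as.numeric(grid$values)
  wi(d)                                   # NX NY NZ (columns, rows, sections)
  wi(2L)                                  # MODE 2 = float32
  wi(c(0L, 0L, 0L))                       # NXSTART..
  wi(d)                                   # MX MY MZ
  wf(d * grid$voxel_size)                 # CELLA
  wf(c(90, 90, 90))                       # CELLB
  wi(1:3)                                 # MAPC MAPR MAPS: X fastest
  wf(c(min(vals), max(vals), mean(vals))) # DMIN DMAX DMEAN
  wi(c(1L, 0L))                           # ISPG, NSYMBT
  wi(rep(0L, 25))                         # EXTRA words 25-49
  wf(grid$origin)                         # ORIGIN words 50-52
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  wi(16708L)                              # little-endian machine stamp 0x4144
  wf(stats::sd(vals))                     # RMS
  wi(0L)                                  # NLABL
  writeBin(raw(800), con)                 # labels
  wf(vals)
  invisible(path)
}
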