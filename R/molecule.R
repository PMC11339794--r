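#' Molecular structure container
#'
#' An ordered list of atoms (element symbol + Cartesian position in Angstrom)
#' with an optional total charge. Atom indices are stable 1-based positions.
#'
#' @param elements character vector of element symbols; every element must
#'   have a van der Waals and a covalent radius in `radii`.
#' @param coords numeric matrix with one row per atom and columns x, y, z
#'   (Angstrom).
#' @param name identifier for the structure.
#' @param charge integer total charge (default 0).
#' @param radii `radii_table` used to validate element symbols.
#' @return an object of class `molecule`.
#' @examples
#' m <- molecule("N", matrix(0, 1, 3))
#' n_atoms(m)
#' @export
molecule <- function(elements, coords, name = "", charge = 0L,
                     radii = radii_table()) {
  elements <- as.character(elements)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (length(elements) < 1L) stop("a molecule needs at least one atom")
  if (nrow(coords) != length(elements) || ncol(coords) != 3L)
    stop("coords must be a length(elements) x 3 matrix")
  if (any(!is.finite(coords))) stop("all coordinates must be finite")
  vdw_radius(radii, elements)       # errors on unknown element
  covalent_radius(radii, elements)
  if (length(elements) > 1L) {
    dmin <- min(stats::dist(coords))
    if (dmin < 0.3)
      stop(sprintf("degenerate geometry: atoms closer than 0.3 A (min %.3f A)",
                   dmin))
  }
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(name = as.character(name)[1L], elements = elements,
                 coords = coords, charge = as.integer(charge)),
            class = "molecule")
}

#' @rdname molecule
#' @param x a `molecule`.
#' @export
n_atoms <- function(x) length(x$elements)

#' @export
print.molecule <- function(x, ...) {
  cat("molecule", if (nzchar(x$name)) sQuote(x$name) else "",
      "-", n_atoms(x), "atoms, charge", x$charge, "\n")
  comp <- sort(table(x$elements), decreasing = TRUE)
  cat("  composition:", paste0(names(comp), comp, collapse = " "), "\n")
  invisible(x)
}

#' @export
as.data.frame.molecule <- function(x, ...) {
  data.frame(element = x$elements, x = x$coords[, 1], y = x$coords[, 2],
             z = x$coords[, 3], stringsAsFactors = FALSE)
}

#' Read an XYZ file
#'
#' Standard XYZ convention: first line the atom count, second line a comment
#' (stored as the structure name when `name` is not supplied), then one
#' `element x y z` record per atom, coordinates in Angstrom.
#'
#' @param path file to read.
#' @param name optional structure name overriding the comment line.
#' @param charge total charge to record.
#' @param radii `radii_table` used to validate element symbols.
#' @return a [molecule].
#' @export
read_xyz <- function(path, name = NULL, charge = 0L, radii = radii_table()) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) stop("empty XYZ file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L)
    stop("line 1: malformed atom count ", sQuote(trimws(lines[1L])))
  if (length(lines) < n + 2L)
    stop(sprintf("file has %d lines but the count line promises %d atoms",
                 length(lines), n))
  comment <- if (length(lines) >= 2L) trimws(lines[2L]) else ""
  elements <- character(n)
  coords <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    ln <- i + 2L
    tok <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1L]]
    if (length(tok) < 4L)
      stop(sprintf("line %d: expected 'element x y z', got %s",
                   ln, sQuote(lines[ln])))
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(xyz))
      stop(sprintf("line %d: non-numeric coordinate in %s", ln, sQuote(lines[ln])))
    elements[i] <- tok[1L]
    coords[i, ] <- xyz
  }
  bad <- !elements %in% names(radii$vdw)
  if (any(bad)) {
    ln <- which(bad)[1L] + 2L
    stop(sprintf("line %d: unknown element symbol %s", ln,
                 sQuote(elements[which(bad)[1L]])))
  }
  molecule(elements, coords, name = if (is.null(name)) comment else name,
           charge = charge, radii = radii)
}

#' Write an XYZ file
#'
#' Emits the standard count/comment/records layout with coordinates printed
#' to 6 decimals, so a read/write round trip preserves elements and
#' coordinates within 1e-6 Angstrom.
#'
#' @param mol a [molecule].
#' @param path output file.
#' @export
write_xyz <- function(mol, path) {
  stopifnot(inherits(mol, "molecule"))
  rec <- sprintf("%-3s %14.6f %14.6f %14.6f", mol$elements,
                 mol$coords[, 1], mol$coords[, 2], mol$coords[, 3])
  writeLines(c(as.character(n_atoms(mol)), mol$name, rec), path)
  invisible(path)
}

#' Bonded neighbours of an atom
#'
#' Distance-based bond perception: atoms i and j are bonded when
#' `dist(i, j) <= covalent(i) + covalent(j) + tolerance`. DFT-quality
#' geometries are insensitive to the exact cutoff; 0.4 A is a conventional
#' slack.
#'
#' @param mol a [molecule].
#' @param index 1-based atom index.
#' @param radii `radii_table` supplying covalent radii.
#' @param tolerance slack added to the covalent-radius sum, Angstrom.
#' @return integer vector of neighbour indices sorted by distance ascending.
#' @export
bonded_neighbors <- function(mol, index, radii = radii_table(),
                             tolerance = 0.4) {
  stopifnot(inherits(mol, "molecule"))
  n <- n_atoms(mol)
  if (length(index) != 1L || is.na(index) || index < 1L || index > n)
    stop("index out of range 1..", n)
  d <- sqrt(colSums((t(mol$coords) - mol$coords[index, ])^2))
  cut <- covalent_radius(radii, mol$elements[index]) +
    covalent_radius(radii, mol$elements) + tolerance
  j <- setdiff(which(d <= cut), index)
  j[order(d[j])]
}

#' Atoms connected to a seed atom
#'
#' Breadth-first traversal of the bond graph, optionally with some atoms
#' removed first (e.g. a metal centre, so that only the ligand bound through
#' the seed atom is kept).
#'
#' @inheritParams bonded_neighbors
#' @param seed 1-based index of the starting atom.
#' @param drop indices removed from the graph before traversal.
#' @return sorted integer vector of atom indices, including `seed`.
#' @export
connected_atoms <- function(mol, seed, drop = integer(0),
                            radii = radii_table(), tolerance = 0.4) {
  stopifnot(inherits(mol, "molecule"))
  n <- n_atoms(mol)
  keep <- setdiff(seq_len(n), drop)
  if (!seed %in% keep) stop("seed atom is in the dropped set")
  seen <- logical(n)
  seen[seed] <- TRUE
  frontier <- seed
  while (length(frontier)) {
    nxt <- integer(0)
    for (i in frontier) {
      nb <- bonded_neighbors(mol, i, radii, tolerance)
      nb <- nb[nb %in% keep & !seen[nb]]
      seen[nb] <- TRUE
      nxt <- c(nxt, nb)
    }
    frontier <- nxt
  }
  which(seen)
}
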