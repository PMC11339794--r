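.voxel_centers_1d <- function(radius, mesh) {
  n <- as.integer(ceiling(2 * radius / mesh - 1e-9))
  (seq_len(n) - 0.5) * mesh - radius
}

.quadrant_of <- function(x, y) {
  # NE, NW, SW, SE by sign of (x, y); zeros (possible only for non-default
  # meshes) go to the positive side
  xp <- x >= 0; yp <- y >= 0
  ifelse(xp & yp, "NE", ifelse(!xp & yp, "NW", ifelse(!xp & !yp, "SW", "SE")))
}

.resolve_atoms <- function(mol, include, exclude) {
  idx <- if (is.null(include) || identical(include, "all"))
    seq_len(n_atoms(mol)) else as.integer(include)
  idx <- setdiff(idx, as.integer(exclude))
  if (length(idx) == 0L)
    stop("no atoms left to test: include/exclude leave an empty set")
  sort(idx)
}

#' Percent buried volume on a voxel grid
#'
#' Scans a cubic voxel grid (spacing `mesh`, aligned to the frame axes)
#' covering the probe sphere. A voxel belongs to the sphere iff its centre is
#' within `frame$radius` of the origin; it is buried iff that centre also lies
#' within the scaled van der Waals radius of any included atom. The total is
#' `100 * buried / sphere`; quadrant values use the sign of the voxel-centre
#' (x, y) in the frame, and by the grid registration each quadrant holds
#' exactly a quarter of the sphere voxels, so the quadrant mean equals the
#' total. Voxel membership is a centre test (no partial-volume weighting);
#' at the default 0.1 A mesh the discretization error is below 0.3
#' percentage points.
#'
#' Hydrogens are included by default (set `hydrogens = FALSE` for the older
#' heavy-atom convention). When a metal or other non-ligand atoms are present
#' they should be excluded via `exclude` or by passing only the ligand's
#' indices (see [connected_atoms()]); the donor N is part of the ligand and
#' stays in.
#'
#' @param mol a [molecule].
#' @param frame a [sphere_frame], typically from [amine_frame()].
#' @param radii a [radii_table]; atom radii are `scale * vdw`.
#' @param mesh voxel spacing in Angstrom (default 0.1; must be positive and
#'   not exceed the sphere radius).
#' @param include atom indices to test, or `"all"` (default all atoms).
#' @param exclude atom indices dropped from `include`.
#' @param hydrogens logical; drop all H atoms when `FALSE`.
#' @return an object of class `buried_volume` with fields `total_pct`,
#'   `quadrant_pct` (named NE/NW/SW/SE), `low_pct`, `high_pct`,
#'   `buried_voxels`, `sphere_voxels`, `mesh`, `frame`, `included_atoms`.
#' @export
buried_volume <- function(mol, frame, radii = vbur_radii_table(), mesh = 0.1,
                          include = "all", exclude = integer(0),
                          hydrogens = TRUE) {
  stopifnot(inherits(mol, "molecule"), inherits(frame, "sphere_frame"))
  if (!is.numeric(mesh) || mesh <= 0) stop("mesh must be positive")
  if (mesh > frame$radius) stop("mesh cannot exceed the sphere radius")
  idx <- .resolve_atoms(mol, include, exclude)
  if (!hydrogens) idx <- idx[mol$elements[idx] != "H"]
  if (length(idx) == 0L) stop("no atoms left to test after hydrogen removal")

  R <- frame$radius
  g <- .voxel_centers_1d(R, mesh)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g, KEEP.OUT.ATTRS = FALSE))
  in_sphere <- rowSums(pts^2) <= R^2
  pts <- pts[in_sphere, , drop = FALSE]
  sphere_voxels <- nrow(pts)

  loc <- frame_coords(frame, mol$coords[idx, , drop = FALSE])
  r2 <- scaled_vdw_radius(radii, mol$elements[idx])^2
  buried <- logical(sphere_voxels)
  for (a in seq_along(idx)) {
    togo <- which(!buried)
    if (!length(togo)) break
    d2 <- (pts[togo, 1] - loc[a, 1])^2 + (pts[togo, 2] - loc[a, 2])^2 +
      (pts[togo, 3] - loc[a, 3])^2
    buried[togo[d2 <= r2[a]]] <- TRUE
  }

  quad <- .quadrant_of(pts[, 1], pts[, 2])
  qlev <- c("NE", "NW", "SW", "SE")
  sph_q <- table(factor(quad, levels = qlev))
  bur_q <- table(factor(quad[buried], levels = qlev))
  quadrant_pct <- 100 * as.numeric(bur_q) / as.numeric(sph_q)
  names(quadrant_pct) <- qlev

  structure(list(
    total_pct = 100 * sum(buried) / sphere_voxels,
    quadrant_pct = quadrant_pct,
    low_pct = min(quadrant_pct), high_pct = max(quadrant_pct),
    buried_voxels = sum(buried), sphere_voxels = sphere_voxels,
    quadrant_sphere_voxels = as.numeric(sph_q),
    mesh = mesh, frame = frame, included_atoms = idx
  ), class = "buried_volume")
}

#' @export
print.buried_volume <- function(x, ...) {
  cat(sprintf("%%V_Bur: %.2f (sphere R %.2f A, mesh %.2f A, %d atoms)\n",
              x$total_pct, x$frame$radius, x$mesh, length(x$included_atoms)))
  q <- x$quadrant_pct
  cat(sprintf("  quadrants NE %.2f  NW %.2f  SW %.2f  SE %.2f  (low %.2f, high %.2f)\n",
              q["NE"], q["NW"], q["SW"], q["SE"], x$low_pct, x$high_pct))
  invisible(x)
}

#' Monte-Carlo buried volume
#'
#' Independent cross-check of the voxel engine: uniform rejection sampling in
#' the probe sphere, reporting the buried fraction with its binomial standard
#' error. Shares no code with the grid path beyond coordinate transforms.
#'
#' @inheritParams buried_volume
#' @param n_samples number of points inside the sphere (>= 1e4).
#' @param seed RNG seed; the global RNG state is restored on exit.
#' @return list with `total_pct`, `se_pct` (both percentage points) and
#'   `n_samples`.
#' @export
mc_buried_volume <- function(mol, frame, radii = vbur_radii_table(),
                             n_samples = 1e6, seed = 1L,
                             include = "all", exclude = integer(0),
                             hydrogens = TRUE) {
  stopifnot(inherits(frame, "sphere_frame"))
  if (n_samples < 1e4) stop("n_samples must be at least 1e4")
  idx <- tryCatch(.resolve_atoms(mol, include, exclude), error = function(e) integer(0))
  if (!hydrogens) idx <- idx[mol$elements[idx] != "H"]

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  R <- frame$radius
  n <- as.integer(n_samples)
  # sample uniformly in the ball: direction x radius ~ R * U^(1/3)
  u <- matrix(stats::rnorm(3L * n), ncol = 3L)
  u <- u / sqrt(rowSums(u^2))
  pts <- u * (R * stats::runif(n)^(1 / 3))

  if (length(idx) == 0L)
    return(list(total_pct = 0, se_pct = 0, n_samples = n))

  loc <- frame_coords(frame, mol$coords[idx, , drop = FALSE])
  r2 <- scaled_vdw_radius(radii, mol$elements[idx])^2
  buried <- logical(n)
  for (a in seq_along(idx)) {
    togo <- which(!buried)
    if (!length(togo)) break
    d2 <- (pts[togo, 1] - loc[a, 1])^2 + (pts[togo, 2] - loc[a, 2])^2 +
      (pts[togo, 3] - loc[a, 3])^2
    buried[togo[d2 <= r2[a]]] <- TRUE
  }
  p <- mean(buried)
  list(total_pct = 100 * p, se_pct = 100 * sqrt(p * (1 - p) / n), n_samples = n)
}

#' Topographic steric map
#'
#' For every (x, y) column of the voxel grid that intersects the probe
#' sphere, the height of the ligand's buried surface toward the probe:
#' `z_top = max z` over buried voxel centres in the column, with sentinel
#' `-radius` for columns containing no buried voxel. Columns outside the
#' sphere's equatorial disc are `NA`. Summing the per-column buried counts
#' reproduces the buried-voxel count of [buried_volume()] exactly.
#'
#' @inheritParams buried_volume
#' @return an object of class `steric_map`: `x`, `y` (grid-line coordinates),
#'   `z_top` (matrix, Angstrom relative to the frame origin), `mesh`,
#'   `buried_voxels`, `frame`.
#' @export
steric_map <- function(mol, frame, radii = vbur_radii_table(), mesh = 0.1,
                       include = "all", exclude = integer(0),
                       hydrogens = TRUE) {
  stopifnot(inherits(mol, "molecule"), inherits(frame, "sphere_frame"))
  if (!is.numeric(mesh) || mesh <= 0) stop("mesh must be positive")
  if (mesh > frame$radius) stop("mesh cannot exceed the sphere radius")
  idx <- .resolve_atoms(mol, include, exclude)
  if (!hydrogens) idx <- idx[mol$elements[idx] != "H"]

  R <- frame$radius
  g <- .voxel_centers_1d(R, mesh)
  nd <- length(g)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g, KEEP.OUT.ATTRS = FALSE))
  in_sphere <- rowSums(pts^2) <= R^2

  loc <- frame_coords(frame, mol$coords[idx, , drop = FALSE])
  r2 <- scaled_vdw_radius(radii, mol$elements[idx])^2
  keep <- which(in_sphere)
  sub <- pts[keep, , drop = FALSE]
  buried <- logical(length(keep))
  for (a in seq_along(idx)) {
    togo <- which(!buried)
    if (!length(togo)) break
    d2 <- (sub[togo, 1] - loc[a, 1])^2 + (sub[togo, 2] - loc[a, 2])^2 +
      (sub[togo, 3] - loc[a, 3])^2
    buried[togo[d2 <= r2[a]]] <- TRUE
  }

  ix <- ((keep - 1L) %% nd) + 1L
  iy <- ((keep - 1L) %/% nd) %% nd + 1L
  col_id <- (iy - 1L) * nd + ix
  z_top <- matrix(NA_real_, nd, nd)
  has_col <- unique(col_id)
  z_top[has_col] <- -R
  if (any(buried)) {
    zb <- sub[buried, 3]
    cb <- col_id[buried]
    mx <- tapply(zb, cb, max)
    z_top[as.integer(names(mx))] <- as.numeric(mx)
  }
  structure(list(x = g, y = g, z_top = z_top, mesh = mesh,
                 buried_voxels = sum(buried), frame = frame),
            class = "steric_map")
}

#' @export
print.steric_map <- function(x, ...) {
  cat(sprintf("steric_map: %d x %d grid, mesh %.2f A, %d buried voxels\n",
              length(x$x), length(x$y), x$mesh, x$buried_voxels))
  invisible(x)
}

#' @export
plot.steric_map <- function(x, levels = pretty(c(-x$frame$radius, x$frame$radius), 12),
                            ...) {
  z <- x$z_top
  graphics::filled.contour(
    x$x, x$y, z, levels = levels,
    color.palette = function(n) grDevices::hcl.colors(n, "Blue-Red 3"),
    xlab = "x (A)", ylab = "y (A)",
    plot.axes = {
      graphics::axis(1); graphics::axis(2)
      graphics::contour(x$x, x$y, z, add = TRUE, lwd = 0.5)
    }, ...)
  invisible(x)
}

#' @export
as.data.frame.steric_map <- function(x, ...) {
  df <- expand.grid(x = x$x, y = x$y, KEEP.OUT.ATTRS = FALSE)
  df$z_top <- as.vector(x$z_top)
  df[!is.na(df$z_top), , drop = FALSE]
}

#' One-call %V_Bur for an amine ligand
#'
#' Convenience wrapper: builds the frame with [amine_frame()], restricts the
#' atom set to the ligand connected to the donor N (metal removed from the
#' bond graph first when given), and runs [buried_volume()].
#'
#' @inheritParams amine_frame
#' @inheritParams buried_volume
#' @export
amine_vbur <- function(mol, n_index, metal_index = NULL,
                       radii = vbur_radii_table(), offset = 2.0, radius = 3.5,
                       mesh = 0.1, hydrogens = TRUE, x_ref_index = NULL,
                       tolerance = 0.4) {
  fr <- amine_frame(mol, n_index, metal_index, radii, offset, radius,
                    x_ref_index, tolerance)
  lig <- connected_atoms(mol, n_index, drop = metal_index, radii = radii,
                         tolerance = tolerance)
  buried_volume(mol, fr, radii, mesh = mesh, include = lig,
                hydrogens = hydrogens)
}
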