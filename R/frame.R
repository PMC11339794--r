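.unit <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) stop("cannot normalize a zero vector")
  v / nv
}

#' Least-squares plane through a set of points
#'
#' Exact plane for 3 points; for more, the total-least-squares plane obtained
#' from the eigendecomposition of the 3x3 covariance of the centred points
#' (normal = eigenvector of the smallest eigenvalue).
#'
#' @param points numeric matrix, >= 3 rows, columns x, y, z.
#' @return list with `normal` (unit vector) and `centroid`.
#' @export
fit_plane <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("need at least 3 points to fit a plane")
  ctr <- colMeans(points)
  cen <- sweep(points, 2L, ctr)
  cv <- crossprod(cen)
  ev <- eigen(cv, symmetric = TRUE)
  # collinear points: two vanishing eigenvalues
  if (ev$values[2L] < 1e-10 * max(ev$values[1L], 1e-12))
    stop("points are collinear or coincident; plane is undefined")
  list(normal = .unit(ev$vectors[, 3L]), centroid = ctr)
}

#' Sphere reference frame
#'
#' The coordinate system every buried-volume and steric-map computation runs
#' in: an origin (the probe-sphere centre), a right-handed orthonormal triad
#' and the sphere radius. For amine ligands the origin sits on the z axis at
#' `offset` Angstrom from the donor nitrogen, where the metal would be.
#'
#' @param origin sphere centre, length-3 numeric (Angstrom).
#' @param z_axis,x_axis unit vectors; `y = z x x` is derived. Must be
#'   orthogonal within 1e-8.
#' @param radius sphere radius in Angstrom (default 3.5).
#' @param offset distance from the donor atom to the origin (Angstrom).
#' @param n_position position of the donor atom the frame was built from
#'   (optional; used to validate `offset`).
#' @return an object of class `sphere_frame`.
#' @export
sphere_frame <- function(origin, z_axis, x_axis, radius = 3.5, offset = 2.0,
                         n_position = NULL) {
  origin <- as.numeric(origin); z <- .unit(as.numeric(z_axis))
  x <- as.numeric(x_axis)
  x <- .unit(x - sum(x * z) * z)   # enforce orthogonality exactly
  if (abs(sum(as.numeric(x_axis) * z)) > 1e-6)
    warning("x_axis had a sizeable z component; projected out")
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])  # y = z x x gives right-handed x,y,z
  if (!is.numeric(radius) || radius <= 0) stop("radius must be positive")
  if (!is.null(n_position)) {
    d <- sqrt(sum((origin - n_position)^2))
    if (abs(d - offset) > 1e-8)
      stop(sprintf("|origin - N| = %.10f differs from offset %.10f", d, offset))
  }
  structure(list(origin = origin, x_axis = x, y_axis = y, z_axis = z,
                 radius = radius, offset = offset,
                 n_position = n_position),
            class = "sphere_frame")
}

#' @export
print.sphere_frame <- function(x, ...) {
  cat(sprintf("sphere_frame: radius %.2f A, offset %.2f A\n", x$radius, x$offset))
  cat(sprintf("  origin (%.3f, %.3f, %.3f)\n", x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  z axis (%.3f, %.3f, %.3f)\n", x$z_axis[1], x$z_axis[2], x$z_axis[3]))
  invisible(x)
}

# coordinates of points (rows) in the local frame
frame_coords <- function(frame, pts) {
  pts <- sweep(as.matrix(pts), 2L, frame$origin)
  pts %*% cbind(frame$x_axis, frame$y_axis, frame$z_axis)
}

#' Build the probe-sphere frame of an amine
#'
#' Places the sphere centre on the axis of the nitrogen lone pair, `offset`
#' Angstrom from N (2.0 A by default, the typical amine-metal bond length).
#' The z axis is perpendicular to the best plane of the three N-bound
#' substituents; when a metal index is supplied the sign points toward the
#' metal, otherwise toward the half-space away from the substituent centroid
#' (the face a metal would bind). The x axis is the in-plane projection of
#' the first (lowest-index, or `x_ref_index`) substituent direction; quadrant
#' values depend on this convention, the total does not.
#'
#' For an essentially planar amine (out-of-plane height of N below
#' `planar_tol`) the "away from the substituents" sign is ill-posed: both
#' sides are evaluated with a quick buried-volume pass and the less hindered
#' one is kept, with a warning.
#'
#' @param mol a [molecule].
#' @param n_index 1-based index of the donor nitrogen.
#' @param metal_index optional 1-based index of a coordinated metal atom;
#'   excluded from the three substituents and used to sign the z axis.
#' @param radii a [radii_table].
#' @param offset,radius frame geometry in Angstrom.
#' @param x_ref_index optional substituent index defining the x axis.
#' @param tolerance bond-perception slack (Angstrom), see
#'   [bonded_neighbors()].
#' @param planar_tol out-of-plane height (Angstrom) below which the free-amine
#'   z sign is resolved by the smaller-%V_Bur tie-break.
#' @return a [sphere_frame].
#' @export
amine_frame <- function(mol, n_index, metal_index = NULL,
                        radii = vbur_radii_table(), offset = 2.0, radius = 3.5,
                        x_ref_index = NULL, tolerance = 0.4,
                        planar_tol = 0.05) {
  stopifnot(inherits(mol, "molecule"))
  if (mol$elements[n_index] != "N")
    stop("atom ", n_index, " is ", mol$elements[n_index], ", not N")
  nb <- bonded_neighbors(mol, n_index, radii, tolerance)
  if (!is.null(metal_index)) nb <- setdiff(nb, metal_index)
  if (length(nb) != 3L)
    stop("nitrogen must have exactly 3 non-metal bonded neighbors, found ",
         length(nb))
  sub <- sort(nb)
  pl <- fit_plane(mol$coords[sub, , drop = FALSE])
  npos <- mol$coords[n_index, ]
  z <- pl$normal
  if (!is.null(metal_index)) {
    vm <- mol$coords[metal_index, ] - npos
    z <- .unit(vm)            # physical metal-N bond direction
  } else {
    away <- npos - pl$centroid
    h <- sum(away * z)        # signed out-of-plane height of N
    if (abs(h) >= planar_tol) {
      if (h < 0) z <- -z
    } else {
      # near-planar: probe both faces, keep the less hindered one
      cand <- lapply(list(z, -z), function(zz) {
        fr <- .raw_frame(npos, zz, mol$coords[sub[1L], ], offset, radius)
        bv <- buried_volume(mol, fr, radii, mesh = 0.2)
        list(frame = fr, total = bv$total_pct)
      })
      pick <- if (cand[[1L]]$total <= cand[[2L]]$total) 1L else 2L
      warning(sprintf(paste("near-planar nitrogen (|h| = %.3f A):",
                            "z sign chosen by smaller %%V_Bur (%.1f vs %.1f)"),
                      abs(h), cand[[pick]]$total, cand[[3L - pick]]$total))
      z <- if (pick == 1L) z else -z
    }
  }
  xref <- if (is.null(x_ref_index)) sub[1L] else x_ref_index
  .raw_frame(npos, z, mol$coords[xref, ], offset, radius)
}

.raw_frame <- function(npos, z, xref_pos, offset, radius) {
  v <- xref_pos - npos
  x <- v - sum(v * z) * z
  if (sqrt(sum(x^2)) < 1e-8)
    stop("x reference atom lies on the z axis; pick another with x_ref_index")
  sphere_frame(origin = npos + offset * z, z_axis = z, x_axis = .unit(x),
               radius = radius, offset = offset, n_position = npos)
}
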