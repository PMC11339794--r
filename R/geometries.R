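#' Idealized reference geometries
#'
#' Synthetic stand-in geometries built from standard experimental structural
#' parameters, for benchmarking the steric descriptors without any external
#' coordinate files. They are idealized constructions, not optimized
#' quantum-chemical geometries.
#'
#' * `ref_nh3()`: ammonia, N-H 1.012 A, H-N-H 106.7 deg.
#' * `ref_nme3()`: trimethylamine, N-C 1.451 A, C-N-C 110.9 deg, idealized
#'   methyls (C-H 1.09 A, tetrahedral).
#' * `ref_net3()`: triethylamine, N-C 1.466 A, C-N-C 111 deg, idealized
#'   ethyls in the reference rotamer of [build_amine()]. NB: the real
#'   molecule is conformationally flexible, so this single rotamer is only
#'   indicative.
#' * `ref_pyridine()`: pyridine, planar ring from the standard
#'   microwave-derived bond lengths and angles (N-C 1.338 A, C2-C3 1.394 A,
#'   C3-C4 1.392 A, C-N-C 116.9 deg), in the z = 0 plane with N at the
#'   origin and the ring along +y.
#'
#' @return a [molecule].
#' @name reference_geometries
NULL

# height of the apex above the base plane for three equal bonds of length l
# with inter-bond angle theta
.pyramid_height <- function(l, theta) {
  h2 <- l^2 * (1 + 2 * cos(theta)) / 3
  if (h2 < 0) h2 <- 0
  sqrt(h2)
}

#' @rdname reference_geometries
#' @export
ref_nh3 <- function() {
  h <- .pyramid_height(1.012, 106.7 * pi / 180)
  build_amine(c("H", "H", "H"), pyramid_height = h, nh_bond = 1.012,
              name = "NH3 (idealized)")
}

#' @rdname reference_geometries
#' @export
ref_nme3 <- function() {
  h <- .pyramid_height(1.451, 110.9 * pi / 180)
  build_amine(c("Me", "Me", "Me"), pyramid_height = h, cn_bond = 1.451,
              name = "NMe3 (idealized)")
}

#' @rdname reference_geometries
#' @export
ref_net3 <- function() {
  h <- .pyramid_height(1.466, 111.0 * pi / 180)
  build_amine(c("Et", "Et", "Et"), pyramid_height = h, cn_bond = 1.466,
              name = "NEt3 (idealized, single rotamer)")
}

#' @rdname reference_geometries
#' @export
ref_pyridine <- function() {
  xy <- rbind(
    N  = c(0.000000, 0.000000),
    C2 = c(1.140222, 0.700098),
    C3 = c(1.194950, 2.093024),
    C4 = c(0.000000, 2.806997),
    C5 = c(-1.194950, 2.093024),
    C6 = c(-1.140222, 0.700098),
    H2 = c(2.078254, 0.150858),
    H3 = c(2.147196, 2.608889),
    H4 = c(0.000000, 3.887997),
    H5 = c(-2.147196, 2.608889),
    H6 = c(-2.078254, 0.150858))
  molecule(sub("[0-9]", "", rownames(xy)), cbind(xy, 0),
           name = "pyridine (idealized)")
}

#' Probe frame for an aromatic (2-coordinate) nitrogen
#'
#' Planar N-heterocycles bind metals through the in-plane lone pair, so the
#' 3-substituent frame of [amine_frame()] does not apply. Here the z axis
#' points from the midpoint of the two ring neighbours through N (the lone
#' pair / metal direction, in the ring plane) and the x axis is the ring
#' normal.
#'
#' @inheritParams amine_frame
#' @export
ring_n_frame <- function(mol, n_index, radii = radii_table(), offset = 2.0,
                         radius = 3.5, tolerance = 0.4) {
  nb <- bonded_neighbors(mol, n_index, radii, tolerance)
  if (length(nb) != 2L)
    stop("ring_n_frame expects a 2-coordinate nitrogen, found ", length(nb),
         " neighbours")
  npos <- mol$coords[n_index, ]
  mid <- colMeans(mol$coords[nb, , drop = FALSE])
  z <- .unit(npos - mid)
  normal <- .unit(.cross3(mol$coords[nb[1L], ] - npos,
                          mol$coords[nb[2L], ] - npos))
  sphere_frame(origin = npos + offset * z, z_axis = z, x_axis = normal,
               radius = radius, offset = offset, n_position = npos)
}
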