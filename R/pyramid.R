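#' Nitrogen pyramidalization index
#'
#' Scalar measure of how far a 3-coordinate nitrogen deviates from planarity:
#' exactly 0 when N lies in the plane of its three substituents, growing
#' monotonically with out-of-plane displacement, invariant under rigid motions
#' and substituent relabeling.
#'
#' Strategies:
#' \describe{
#'   \item{`"oop-distance"` (default)}{perpendicular distance (Angstrom) of N
#'     from the plane through its three bonded substituents. An idealized
#'     trialkylamine (N-C 1.47 A, C-N-C 111 deg) scores ~0.45 A and ammonia
#'     (N-H 1.012 A, H-N-H 106.7 deg) ~0.38 A, so the conventional 0.450
#'     regime boundary between flattened and sp3-like amines is in Angstrom
#'     on this scale.}
#'   \item{`"angle-deficit"`}{360 minus the sum of the three substituent
#'     bond angles at N, in degrees (0 for planar, ~31 deg for sp3).}
#' }
#'
#' @param mol a [molecule].
#' @param n_index 1-based index of the nitrogen (or any 3-coordinate centre).
#' @param strategy `"oop-distance"` or `"angle-deficit"`.
#' @param metal_index optional metal atom excluded from the substituents.
#' @param radii a [radii_table] for bond perception.
#' @param tolerance bond-perception slack (Angstrom).
#' @return object of class `pyramidalization` with fields `index`, `n_index`,
#'   `substituent_indices`, `strategy`.
#' @export
pyramidalization <- function(mol, n_index,
                             strategy = c("oop-distance", "angle-deficit"),
                             metal_index = NULL, radii = radii_table(),
                             tolerance = 0.4) {
  stopifnot(inherits(mol, "molecule"))
  strategy <- match.arg(strategy)
  nb <- bonded_neighbors(mol, n_index, radii, tolerance)
  if (!is.null(metal_index)) nb <- setdiff(nb, metal_index)
  if (length(nb) == 2L) {
    # 2-coordinate (aromatic ring) nitrogen: no pyramid is defined and the
    # centre is planar by convention, so the index is exactly zero
    return(structure(list(index = 0, n_index = n_index,
                          substituent_indices = sort(nb),
                          strategy = match.arg(strategy)),
                     class = "pyramidalization"))
  }
  if (length(nb) != 3L)
    stop("pyramidalization needs exactly 3 bonded substituents, found ",
         length(nb))
  sub <- sort(nb)
  npos <- mol$coords[n_index, ]
  p <- mol$coords[sub, , drop = FALSE]

  idx <- switch(strategy,
    "oop-distance" = {
      normal <- .unit(.cross3(p[2, ] - p[1, ], p[3, ] - p[1, ]))
      abs(sum((npos - p[1, ]) * normal))
    },
    "angle-deficit" = {
      ang <- function(a, b) {
        u <- p[a, ] - npos; v <- p[b, ] - npos
        acos(min(1, max(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
      }
      360 - (ang(1, 2) + ang(1, 3) + ang(2, 3)) * 180 / pi
    })
  # tiny negative angle-deficits from roundoff on exactly planar input
  if (abs(idx) < 1e-10) idx <- 0
  if (idx < 0) idx <- 0
  structure(list(index = idx, n_index = n_index, substituent_indices = sub,
                 strategy = strategy),
            class = "pyramidalization")
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.pyramidalization <- function(x, ...) {
  unit <- if (x$strategy == "oop-distance") "A" else "deg"
  cat(sprintf("pyramidalization (%s): %.4f %s at atom %d (substituents %s)\n",
              x$strategy, x$index, unit, x$n_index,
              paste(x$substituent_indices, collapse = ", ")))
  invisible(x)
}
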