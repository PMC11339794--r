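#' Longest C-N bond at a nitrogen
#'
#' Maximum bonded N-C distance in Angstrom; an error when the nitrogen has no
#' carbon neighbour.
#'
#' @inheritParams pyramidalization
#' @export
longest_cn_bond <- function(mol, n_index, radii = radii_table(),
                            tolerance = 0.4) {
  nb <- bonded_neighbors(mol, n_index, radii, tolerance)
  cc <- nb[mol$elements[nb] == "C"]
  if (length(cc) == 0L)
    stop("atom ", n_index, " has no bonded carbon neighbour")
  d <- sqrt(colSums((t(mol$coords[cc, , drop = FALSE]) -
                       mol$coords[n_index, ])^2))
  max(d)
}

.sphere_points <- function(n) {
  # golden-spiral quasi-uniform points on the unit sphere
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Van der Waals molecular surface area
#'
#' Shrake-Rupley-style point sampling: each atom carries a quasi-uniform
#' point shell at its scaled vdW radius (plus probe); points inside any other
#' atom's sphere are culled, and the exposed fraction times the sphere area
#' is summed over atoms. With `probe = 0` this is the bare scaled-vdW
#' molecular surface.
#'
#' @param mol a [molecule].
#' @param radii a [radii_table] (radii are `scale * vdw + probe`).
#' @param probe probe radius in Angstrom (default 0).
#' @param mesh target point spacing on each atomic sphere, Angstrom; the
#'   point count per atom is `4*pi*r^2 / mesh^2` (capped at 2e4).
#' @return area in Angstrom^2.
#' @export
molecular_area <- function(mol, radii = radii_table(), probe = 0, mesh = 0.1) {
  stopifnot(inherits(mol, "molecule"))
  r <- scaled_vdw_radius(radii, mol$elements) + probe
  n <- n_atoms(mol)
  total <- 0
  for (i in seq_len(n)) {
    npts <- min(2e4, max(200L, ceiling(4 * pi * r[i]^2 / mesh^2)))
    pts <- .sphere_points(npts) * r[i]
    pts <- sweep(pts, 2L, mol$coords[i, ], "+")
    exposed <- rep(TRUE, npts)
    for (j in seq_len(n)) {
      if (j == i) next
      d_ij <- sqrt(sum((mol$coords[i, ] - mol$coords[j, ])^2))
      if (d_ij >= r[i] + r[j]) next
      keep <- which(exposed)
      if (!length(keep)) break
      d2 <- (pts[keep, 1] - mol$coords[j, 1])^2 +
        (pts[keep, 2] - mol$coords[j, 2])^2 +
        (pts[keep, 3] - mol$coords[j, 3])^2
      exposed[keep[d2 < r[j]^2]] <- FALSE
    }
    total <- total + 4 * pi * r[i]^2 * mean(exposed)
  }
  total
}

#' Bundled reference table of amine energies and %V_Bur
#'
#' Loads the packaged transcription of the published benchmark table for 43
#' hindered tertiary amines plus NH3, NMe3, NEt3 and pyridine: protonation
#' Gibbs energies (free proton and acetic-acid routes) and ligand-exchange
#' Gibbs energies on AuCl(PMe3), Pd(PMe3)2 and PdCl2(PMe3) (all kcal/mol;
#' DFT-derived benchmark values taken here as input data), and the total
#' %V_Bur of the amine. Species for which a bound structure could not be
#' located are `NA`.
#'
#' @return data.frame with columns `amine_id`, `dg_h_free`, `dg_h_acoh`,
#'   `dg_au`, `dg_pd0`, `dg_pd2`, `vbur_total`.
#' @export
load_reference_table <- function() {
  path <- system.file("extdata", "amines_reference_table.csv",
                      package = "hindamine", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(amine_id = "character"))
  df
}

#' Assemble a descriptor table from geometries and external columns
#'
#' For every amine in the manifest, computes geometry-derived descriptors
#' from whichever XYZ files exist and joins externally computed
#' quantum-chemical columns (E(LUMO), Mayer bond orders, pKa, NPA charge,
#' hardness, response energies, ...). QM columns are inputs, never
#' recomputed. Unresolvable cells stay `NA`; a provenance attribute records
#' the source of every filled cell.
#'
#' Roles and the columns they fill:
#' \describe{
#'   \item{`amine`}{`vbur_total`, `vbur_low`, `vbur_high`, `pyramidalization`,
#'     `longest_cn`, `molecular_area`.}
#'   \item{`ammonium`}{`vbur_total_ammonium`, `vbur_low_ammonium`,
#'     `vbur_high_ammonium`, `d_n_h` (N-H+ bond); the frame z axis points
#'     from N toward the acquired proton and the proton counts as part of
#'     the ammonium.}
#'   \item{`au_complex`}{`d_au_n`; ligand %V_Bur columns are only taken from
#'     the `amine` entry.}
#'   \item{`pd0_complex`, `pd2_complex`}{`pyramidalization_pd` (from the
#'     Pd-bound geometry), `d_pd_n`.}
#' }
#'
#' @param manifest data.frame with columns `amine_id`, `role` (one of
#'   amine/ammonium/au_complex/pd0_complex/pd2_complex), `path` (XYZ file),
#'   `n_index` (1-based donor N index) and optional `metal_index`.
#' @param external optional data.frame (or CSV path) keyed by `amine_id`;
#'   all other columns must be numeric and are joined as-is.
#' @param radii a [radii_table] (default: the buried-volume convention,
#'   [vbur_radii_table()]).
#' @param mesh voxel mesh for %V_Bur, Angstrom.
#' @param offset,radius frame geometry, Angstrom.
#' @return data.frame, one row per `amine_id`, with attribute `"provenance"`.
#' @export
assemble_table <- function(manifest, external = NULL,
                           radii = vbur_radii_table(), mesh = 0.1,
                           offset = 2.0, radius = 3.5) {
  need <- c("amine_id", "role", "path", "n_index")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(manifest[c("amine_id", "role")]))
    stop("duplicate amine_id/role pair in manifest")
  ok_roles <- c("amine", "ammonium", "au_complex", "pd0_complex", "pd2_complex")
  if (!all(manifest$role %in% ok_roles))
    stop("unknown role(s): ",
         paste(setdiff(manifest$role, ok_roles), collapse = ", "))

  ids <- unique(manifest$amine_id)
  out <- data.frame(amine_id = ids, stringsAsFactors = FALSE)
  prov <- list()
  note <- function(id, col, src) prov[[length(prov) + 1L]] <<-
    data.frame(amine_id = id, column = col, source = src,
               stringsAsFactors = FALSE)
  set <- function(id, col, val, src) {
    if (!col %in% names(out)) out[[col]] <<- NA_real_
    out[out$amine_id == id, col] <<- val
    note(id, col, src)
  }

  for (k in seq_len(nrow(manifest))) {
    row <- manifest[k, ]
    mol <- read_xyz(row$path, radii = radii)
    ni <- as.integer(row$n_index)
    mi <- if ("metal_index" %in% names(manifest) && !is.na(row$metal_index))
      as.integer(row$metal_index) else NULL
    src <- row$path
    if (row$role == "amine") {
      bv <- amine_vbur(mol, ni, radii = radii, mesh = mesh,
                       offset = offset, radius = radius)
      set(row$amine_id, "vbur_total", bv$total_pct, src)
      set(row$amine_id, "vbur_low", bv$low_pct, src)
      set(row$amine_id, "vbur_high", bv$high_pct, src)
      set(row$amine_id, "pyramidalization",
          pyramidalization(mol, ni, radii = radii)$index, src)
      cn <- tryCatch(longest_cn_bond(mol, ni, radii), error = function(e) NA_real_)
      if (!is.na(cn)) set(row$amine_id, "longest_cn", cn, src)
      set(row$amine_id, "molecular_area", molecular_area(mol, radii), src)
    } else if (row$role == "ammonium") {
      nb <- bonded_neighbors(mol, ni, radii)
      hs <- nb[mol$elements[nb] == "H"]
      if (length(hs) >= 1L) {
        if (length(hs) > 1L)
          warning(row$amine_id, ": several N-H bonds in ammonium; using shortest")
        dnh <- min(sqrt(colSums((t(mol$coords[hs, , drop = FALSE]) -
                                   mol$coords[ni, ])^2)))
        set(row$amine_id, "d_n_h", dnh, src)
        proton <- hs[which.min(sqrt(colSums((t(mol$coords[hs, , drop = FALSE]) -
                                               mol$coords[ni, ])^2)))]
        # frame z points toward the proton; the proton stays in the ligand set
        fr <- amine_frame(mol, ni, metal_index = proton, radii = radii,
                          offset = offset, radius = radius)
        bv <- buried_volume(mol, fr, radii, mesh = mesh, include = "all")
        set(row$amine_id, "vbur_total_ammonium", bv$total_pct, src)
        set(row$amine_id, "vbur_low_ammonium", bv$low_pct, src)
        set(row$amine_id, "vbur_high_ammonium", bv$high_pct, src)
      } else {
        warning(row$amine_id, ": ammonium geometry has no N-H bond; skipped")
      }
    } else {
      metal <- if (row$role == "au_complex") "Au" else "Pd"
      mi2 <- if (!is.null(mi)) mi else which(mol$elements == metal)[1L]
      if (is.na(mi2)) {
        warning(row$amine_id, ": no ", metal, " atom found in ", src)
        next
      }
      dmn <- sqrt(sum((mol$coords[mi2, ] - mol$coords[ni, ])^2))
      set(row$amine_id, if (metal == "Au") "d_au_n" else "d_pd_n", dmn, src)
      if (metal == "Pd")
        set(row$amine_id, "pyramidalization_pd",
            pyramidalization(mol, ni, metal_index = mi2, radii = radii)$index,
            src)
    }
  }

  if (!is.null(external)) {
    ext <- if (is.character(external))
      utils::read.csv(external, stringsAsFactors = FALSE,
                      colClasses = c(amine_id = "character")) else external
    if (!"amine_id" %in% names(ext)) stop("external table needs amine_id")
    if (anyDuplicated(ext$amine_id)) stop("duplicate amine_id in external table")
    for (col in setdiff(names(ext), "amine_id")) {
      if (!is.numeric(ext[[col]]))
        stop("external column ", sQuote(col), " has non-numeric cells")
      m <- match(out$amine_id, ext$amine_id)
      hit <- which(!is.na(m) & !is.na(ext[[col]][m]))
      if (!col %in% names(out)) out[[col]] <- NA_real_
      out[hit, col] <- ext[[col]][m[hit]]
      for (id in out$amine_id[hit]) note(id, col, "external")
    }
  }

  attr(out, "provenance") <- do.call(rbind, prov)
  out
}
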