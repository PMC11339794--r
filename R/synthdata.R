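.TET <- acos(-1 / 3)          # 109.471 deg
.CC <- 1.54                   # idealized sp3 C-C, Angstrom
.CH <- 1.09                   # idealized C-H, Angstrom

# atoms of a substituent group, recursively: `axis` is the unit vector from
# the parent atom to the group's anchor, `pos` the anchor position. Child
# directions make the tetrahedral angle with the bond back to the parent;
# `phase` sets their azimuth around the axis, measured from the projection of
# the global +z (so phase 0 tilts children toward the probe side).
.place_group <- function(template, pos, axis, phase) {
  e3 <- axis
  ref <- c(0, 0, 1)
  e1 <- ref - sum(ref * e3) * e3
  if (sqrt(sum(e1^2)) < 1e-6) e1 <- c(1, 0, 0) - e3[1] * e3
  e1 <- .unit(e1)
  e2 <- .cross3(e3, e1)
  child_dir <- function(az) {
    s <- sin(pi - .TET); cz <- cos(pi - .TET)
    .unit(s * (cos(az) * e1 + sin(az) * e2) + cz * e3)
  }
  kids <- function(templates, lens, az) {
    el <- character(0); xyz <- NULL
    for (k in seq_along(templates)) {
      d <- child_dir(az[k])
      p <- pos + lens[k] * d
      if (templates[k] == "H") {
        el <- c(el, "H"); xyz <- rbind(xyz, p)
      } else {
        g <- .place_group(templates[k], p, d, phase)
        el <- c(el, g$elements); xyz <- rbind(xyz, g$coords)
      }
    }
    list(elements = el, coords = xyz)
  }
  az <- phase + c(0, 2 * pi / 3, 4 * pi / 3)
  out <- switch(template,
    H = list(elements = character(0), coords = NULL),
    Me = kids(c("H", "H", "H"), rep(.CH, 3), az),
    Et = kids(c("Me", "H", "H"), c(.CC, .CH, .CH), az),
    iPr = kids(c("Me", "Me", "H"), c(.CC, .CC, .CH), az),
    tBu = kids(c("Me", "Me", "Me"), rep(.CC, 3), az),
    Ad = kids(c("Et", "Et", "Et"), rep(.CC, 3), az),
    stop("unknown substituent template ", sQuote(template)))
  anchor_el <- if (template == "H") "H" else "C"
  list(elements = c(anchor_el, out$elements),
       coords = rbind(pos, out$coords))
}

#' Build a synthetic trisubstituted amine
#'
#' Idealized NR3 geometry: the donor N sits `pyramid_height` Angstrom above
#' the plane of three substituent anchor atoms placed with 3-fold symmetry at
#' `cn_bond` Angstrom from N. Substituent internal geometry uses idealized
#' sp3 templates (tetrahedral angles, C-C 1.54 A, C-H 1.09 A); realism beyond
#' steric bulk is not a goal. By construction the default ("oop-distance")
#' pyramidalization index of the result equals `pyramid_height` exactly.
#'
#' @param substituents three template labels among `"H"`, `"Me"`, `"Et"`,
#'   `"iPr"`, `"tBu"`, `"Ad"` (an adamantyl-like branched blob).
#' @param pyramid_height out-of-plane height of N, Angstrom (0 = planar);
#'   must be smaller than `cn_bond`.
#' @param cn_bond N-C anchor bond length, Angstrom (default 1.47).
#' @param nh_bond N-H bond length used for `"H"` substituents, Angstrom.
#' @param seed optional integer; seeds small azimuthal twists of the
#'   substituents so different seeds give different rotamers. Deterministic
#'   for a given seed; `NULL` gives the untwisted reference rotamer.
#' @param name structure name.
#' @return a [molecule] with N as atom 1 and the three anchors as atoms
#'   2..4 (further atoms follow each substituent).
#' @export
build_amine <- function(substituents, pyramid_height, cn_bond = 1.47,
                        nh_bond = 1.01, seed = NULL, name = NULL) {
  if (length(substituents) != 3L)
    stop("exactly three substituent templates are required")
  if (!is.numeric(pyramid_height) || pyramid_height < 0)
    stop("pyramid_height must be >= 0")
  anchor_len <- ifelse(substituents == "H", nh_bond, cn_bond)
  if (pyramid_height >= min(anchor_len))
    stop("pyramid_height must be smaller than every N-anchor bond length")
  # canonical clash-free rotamer per template (azimuth of the first branch
  # from the +z projection): ethyls sit tangentially (propeller), branched
  # groups tilt their first branches toward the probe face, which is how
  # increasing substituent bulk actually crowds a binding site
  phase0 <- c(H = 0, Me = pi / 3, Et = pi / 2, iPr = pi / 6, tBu = pi / 6,
              Ad = pi / 4)
  bad <- setdiff(substituents, names(phase0))
  if (length(bad)) stop("unknown substituent template ", sQuote(bad[1L]))
  twists <- unname(phase0[substituents])
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(as.integer(seed))
    twists <- twists + stats::runif(3, -pi / 6, pi / 6)
  }
  h <- pyramid_height
  az <- pi / 2 + c(0, 2 * pi / 3, 4 * pi / 3)
  npos <- c(0, 0, h)
  elements <- "N"
  coords <- rbind(npos)
  group_of <- integer(0)
  for (k in 1:3) {
    rho <- sqrt(anchor_len[k]^2 - h^2)
    anchor <- c(rho * cos(az[k]), rho * sin(az[k]), 0)
    axis <- .unit(anchor - npos)
    g <- .place_group(substituents[k], anchor, axis, phase = twists[k])
    elements <- c(elements, g$elements)
    coords <- rbind(coords, g$coords)
    group_of <- c(group_of, rep(k, length(g$elements)))
  }
  # inter-substituent clash guard
  gidx <- c(0L, group_of)  # N is group 0
  if (nrow(coords) > 2L) {
    d <- as.matrix(stats::dist(coords))
    diff_grp <- outer(gidx, gidx, "!=") & upper.tri(d)
    if (any(d[diff_grp] < 0.8))
      stop(sprintf(paste("substituents clash (closest contact %.2f A < 0.8 A);",
                         "use smaller templates or a larger pyramid_height"),
                   min(d[diff_grp])))
  }
  if (is.null(name))
    name <- sprintf("N(%s) h=%.3f", paste(substituents, collapse = ","), h)
  molecule(elements, coords, name = name)
}

#' Random synthetic amines
#'
#' Draws `n` amines with substituents sampled from H/Me/Et/iPr and pyramid
#' heights uniform on 0.15-0.48 A, for oracle-equivalence and invariance
#' testing. Deterministic under `seed`.
#'
#' @param n number of amines.
#' @param seed integer seed.
#' @param templates pool to sample substituents from.
#' @return list of [molecule]s.
#' @export
random_amines <- function(n, seed = 1L,
                          templates = c("H", "Me", "Et", "iPr")) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  lapply(seq_len(n), function(i) {
    repeat {
      sub <- sample(templates, 3L, replace = TRUE)
      h <- stats::runif(1, 0.15, 0.48)
      m <- tryCatch(build_amine(sub, h, seed = sample.int(1e6, 1)),
                    error = function(e) NULL)
      if (!is.null(m)) return(m)
    }
  })
}

#' Simulate a descriptor table with a planted linear response
#'
#' Candidate columns are drawn independently and uniformly on per-column
#' ranges whose defaults emulate the spread of the bundled reference data
#' (%V_Bur-like descriptors on 15-70). The response is
#' `intercept + sum(coef * active columns) + N(0, noise_sd)` (kcal/mol-like
#' scale); candidate cells are then masked missing at `missing_rate`,
#' mirroring the "not located" gaps of real tables. Optional decoy columns
#' are drawn correlated with an existing column.
#'
#' @param n_rows rows to simulate.
#' @param n_candidates number of candidate columns (named `x1`, `x2`, ...).
#' @param active named numeric vector of true coefficients; names must be
#'   candidate columns.
#' @param intercept true intercept.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param missing_rate fraction of candidate cells masked to `NA` (0 <= r < 1).
#' @param ranges list of `c(min, max)` per candidate (recycled).
#' @param decoys optional named list: `list(d1 = list(of = "x1", rho = 0.8))`
#'   adds column `d1` with correlation about `rho` to `x1`.
#' @param seed integer seed (global RNG state restored on exit).
#' @return list with `table` (data.frame, response column `y`) and `truth`
#'   (the generating parameters).
#' @export
simulate_table <- function(n_rows = 50, n_candidates = 8,
                           active = c(x1 = 2.5, x2 = -1.0), intercept = 3,
                           noise_sd = 1, missing_rate = 0,
                           ranges = list(c(15, 70)), decoys = NULL,
                           seed = 1L) {
  stopifnot(noise_sd >= 0, missing_rate >= 0, missing_rate < 1)
  if (!all(names(active) %in% paste0("x", seq_len(n_candidates))))
    stop("active names must be among the candidate columns")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  ranges <- rep(ranges, length.out = n_candidates)
  tab <- as.data.frame(lapply(seq_len(n_candidates), function(j)
    stats::runif(n_rows, ranges[[j]][1], ranges[[j]][2])))
  names(tab) <- paste0("x", seq_len(n_candidates))
  if (!is.null(decoys)) {
    for (nm in names(decoys)) {
      d <- decoys[[nm]]
      base <- tab[[d$of]]
      z <- (base - mean(base)) / stats::sd(base)
      mix <- d$rho * z + sqrt(1 - d$rho^2) * stats::rnorm(n_rows)
      tab[[nm]] <- mean(base) + stats::sd(base) * mix
    }
  }
  y <- intercept + as.matrix(tab[names(active)]) %*% active +
    stats::rnorm(n_rows, 0, noise_sd)
  tab$y <- drop(y)
  if (missing_rate > 0) {
    cand <- setdiff(names(tab), "y")
    for (cl in cand) {
      mask <- stats::runif(n_rows) < missing_rate
      tab[[cl]][mask] <- NA_real_
    }
  }
  list(table = tab,
       truth = list(active = active, intercept = intercept,
                    noise_sd = noise_sd, missing_rate = missing_rate,
                    seed = seed))
}
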