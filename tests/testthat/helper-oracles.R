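# independent oracles used across tests; deliberately naive implementations

# all-pairs bond detection by direct distance comparison
brute_neighbors <- function(mol, i, radii = radii_table(), tol = 0.4) {
  out <- integer(0)
  for (j in seq_len(n_atoms(mol))) {
    if (j == i) next
    d <- sqrt(sum((mol$coords[i, ] - mol$coords[j, ])^2))
    if (d <= covalent_radius(radii, mol$elements[i]) +
        covalent_radius(radii, mol$elements[j]) + tol)
      out <- c(out, j)
  }
  out
}

# normal-equations OLS, no lm machinery
brute_ols <- function(x, y) {
  X <- cbind(1, as.matrix(x))
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fitted <- drop(X %*% beta)
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(intercept = beta[1], coefficients = beta[-1],
       r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else 0,
       rmse = sqrt(ss_res / length(y)))
}

# exhaustive re-enumeration of best subsets, independent of screen_models
brute_best_per_size <- function(table, response, candidates, max_vars) {
  best <- list()
  for (size in seq_len(max_vars)) {
    combos <- utils::combn(sort(candidates), size, simplify = FALSE)
    top <- NULL
    for (vars in combos) {
      ok <- stats::complete.cases(table[c(response, vars)])
      if (sum(ok) < size + 2) next
      f <- brute_ols(table[ok, vars, drop = FALSE], table[[response]][ok])
      if (is.null(top) || f$r2 > top$r2 + 1e-12)
        top <- list(vars = vars, r2 = f$r2)
    }
    best[[size]] <- top
  }
  best
}

# rigid motion: random rotation (from QR of a gaussian matrix) + translation
rigid_motion <- function(mol, seed = 1) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  t0 <- rnorm(3, sd = 5)
  molecule(mol$elements, mol$coords %*% Q +
             matrix(t0, n_atoms(mol), 3, byrow = TRUE), name = mol$name)
}

write_tmp_xyz <- function(mol) {
  f <- tempfile(fileext = ".xyz")
  write_xyz(mol, f)
  f
}
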