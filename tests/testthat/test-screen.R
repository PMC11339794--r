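test_that("fit_ols is exact on noiseless data and matches normal equations", {
  set.seed(1)
  x <- cbind(x1 = runif(30, 15, 70), x2 = runif(30, -5, 5))
  y <- 2.5 * x[, 1] - 1.0 * x[, 2] + 3
  f <- fit_ols(x, y)
  expect_equal(unname(f$coefficients), c(2.5, -1.0), tolerance = 1e-10)
  expect_equal(f$intercept, 3, tolerance = 1e-8)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  expect_equal(f$rmse, 0, tolerance = 1e-8)

  yn <- y + rnorm(30, sd = 4)
  f2 <- fit_ols(x, yn)
  o <- brute_ols(x, yn)
  expect_equal(unname(f2$coefficients), unname(o$coefficients), tolerance = 1e-9)
  expect_equal(f2$intercept, unname(o$intercept), tolerance = 1e-9)
  expect_equal(f2$r2, o$r2, tolerance = 1e-12)
  expect_equal(f2$rmse, o$rmse, tolerance = 1e-12)
  # r2 equals the squared Pearson correlation of fitted vs observed
  expect_equal(f2$r2, cor(f2$fitted, yn)^2, tolerance = 1e-10)
  # predict/residuals/coef methods are consistent
  expect_equal(predict(f2, as.data.frame(x)), f2$fitted, tolerance = 1e-12)
  expect_equal(yn - f2$fitted, residuals(f2), tolerance = 1e-12)
  expect_length(coef(f2), 3L)
})

test_that("degenerate designs are guarded", {
  x <- cbind(x1 = 1:10)
  expect_equal(fit_ols(x, rep(5, 10))$r2, 0)          # constant response
  expect_equal(unname(fit_ols(x, rep(5, 10))$coefficients), 0,
               tolerance = 1e-12)
  xx <- cbind(a = 1:10, b = 2 * (1:10))
  expect_error(fit_ols(xx, rnorm(10)), "collinear.*b")
  expect_error(fit_ols(cbind(x1 = 1:2), rnorm(2)), "n >= p \\+ 2")
  expect_error(fit_ols(cbind(x1 = c(1, 2, NA, 4, 5)), rnorm(5)), "complete")
})

test_that("a planted model is recovered within three standard errors", {
  sim <- simulate_table(n_rows = 200, active = c(x1 = 2.5, x2 = -1.0),
                        intercept = 3, noise_sd = 1, seed = 42)
  f <- fit_ols(sim$table[c("x1", "x2")], sim$table$y)
  # standard errors from the independent lm cross-check
  lmf <- lm(y ~ x1 + x2, data = sim$table)
  se <- coef(summary(lmf))[, "Std. Error"]
  expect_lt(abs(f$intercept - 3), 3 * se["(Intercept)"])
  expect_lt(abs(f$coefficients["x1"] - 2.5), 3 * se["x1"])
  expect_lt(abs(f$coefficients["x2"] + 1.0), 3 * se["x2"])
  expect_equal(unname(coef(lmf)), unname(coef(f)), tolerance = 1e-9)
})

test_that("r2 is invariant to affine rescaling of a candidate column", {
  sim <- simulate_table(n_rows = 60, active = c(x1 = 1.5, x3 = -0.7),
                        noise_sd = 2, seed = 9)
  t1 <- sim$table
  f1 <- fit_ols(t1[c("x1", "x3")], t1$y)
  t2 <- t1
  t2$x1 <- 10 * t2$x1 - 4      # affine rescale
  f2 <- fit_ols(t2[c("x1", "x3")], t2$y)
  expect_equal(f2$r2, f1$r2, tolerance = 1e-10)
  expect_equal(f2$coefficients[["x1"]], f1$coefficients[["x1"]] / 10,
               tolerance = 1e-10)
})

test_that("the exhaustive screen enumerates every subset and matches brute force", {
  sim <- simulate_table(n_rows = 60, n_candidates = 6,
                        active = c(x3 = 2.0), noise_sd = 3, seed = 31)
  sc <- screen_models(sim$table, "y", max_vars = 3)
  k <- 6
  expect_equal(sc$n_subsets, choose(k, 1) + choose(k, 2) + choose(k, 3))
  expect_equal(sum(sc$results$size == 1), choose(k, 1))
  expect_equal(sum(sc$results$size == 3), choose(k, 3))
  # a lone driver tops the 1-variable ranking
  expect_equal(sc$best[["1"]]$variables, "x3")
  bb <- brute_best_per_size(sim$table, "y", paste0("x", 1:6), 3)
  for (s in 1:3) {
    expect_setequal(sc$best[[as.character(s)]]$variables, bb[[s]]$vars)
    expect_equal(sc$best[[as.character(s)]]$r2, bb[[s]]$r2, tolerance = 1e-10)
  }
  # single candidate, single size: identical to a direct fit
  sc1 <- screen_models(sim$table, "y", candidates = "x3", max_vars = 1)
  f <- fit_ols(sim$table["x3"], sim$table$y)
  expect_equal(sc1$best[["1"]]$r2, f$r2, tolerance = 1e-12)
})

test_that("listwise deletion is per evaluated subset", {
  sim <- simulate_table(n_rows = 80, n_candidates = 4,
                        active = c(x1 = 1), noise_sd = 1,
                        missing_rate = 0.2, seed = 77)
  sc <- screen_models(sim$table, "y", max_vars = 2)
  res <- sc$results
  for (i in seq_len(nrow(res))) {
    vars <- strsplit(res$variables[i], " \\+ ")[[1]]
    expect_equal(res$n[i],
                 sum(stats::complete.cases(sim$table[c("y", vars)])))
  }
})

test_that("robustness transforms behave as specified", {
  tab <- data.frame(x = 1:3, y = c(-3, 2, -1))
  clip <- apply_robustness(tab, "y", "clip_negative_to_zero")
  expect_equal(clip$y, c(0, 2, 0))
  expect_equal(clip$x, 1:3)
  drop <- apply_robustness(tab, "y", "drop_negative")
  expect_equal(drop$y, 2)
  expect_equal(nrow(drop), 1L)
  # NA responses are preserved, not treated as negative
  tab$y[2] <- NA
  expect_equal(apply_robustness(tab, "y", "drop_negative")$y, NA_real_)

  # screening under both modes on a constructed negative-barrier table
  sim <- simulate_table(n_rows = 50, active = c(x1 = 0.8), intercept = -30,
                        noise_sd = 2, seed = 5)
  expect_lt(min(sim$table$y), 0)
  sc_clip <- screen_models(sim$table, "y", candidates = "x1", max_vars = 1,
                           robustness = "clip_negative_to_zero")
  sc_drop <- screen_models(sim$table, "y", candidates = "x1", max_vars = 1,
                           robustness = "drop_negative")
  expect_equal(sc_clip$best[["1"]]$n, 50L)
  expect_equal(sc_drop$best[["1"]]$n, sum(sim$table$y >= 0))
})

test_that("the subgroup filter is strict and drops rows missing the column", {
  tab <- data.frame(pyramidalization = c(0.3, 0.45, 0.4500001, 0.6, 0.7, NA),
                    x1 = c(1, 2, 3, 4, 5, 6) * 1.0,
                    y = c(1.1, 2.2, 2.9, 4.2, 5.0, 6.1))
  sc <- screen_models(tab, "y", candidates = "x1", max_vars = 1,
                      filter = "pyramidalization > 0.450")
  expect_equal(sc$best[["1"]]$n, 3L)   # 0.450 itself is excluded (strict), NA dropped
  expect_error(screen_models(tab, "y", candidates = "x1",
                             filter = "pyramidalization >= 0.45"),
               "filter must look like")
})

test_that("true active pairs dominate the 2-variable ranking across 100 tables", {
  hits <- 0L
  for (s in 1:100) {
    sim <- simulate_table(n_rows = 50, n_candidates = 8,
                          active = c(x2 = 1.2, x5 = -0.9), intercept = 5,
                          noise_sd = 6, seed = 1000 + s)
    sc <- screen_models(sim$table, "y", max_vars = 2)
    if (identical(sort(sc$best[["2"]]$variables), c("x2", "x5")))
      hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("a correlated decoy degrades but does not usually displace the truth", {
  hits <- 0L
  for (s in 1:40) {
    sim <- simulate_table(n_rows = 50, n_candidates = 6,
                          active = c(x1 = 1.2, x4 = -0.9), intercept = 5,
                          noise_sd = 6,
                          decoys = list(d1 = list(of = "x1", rho = 0.8)),
                          seed = 300 + s)
    sc <- screen_models(sim$table, "y", max_vars = 2)
    if (identical(sort(sc$best[["2"]]$variables), c("x1", "x4")))
      hits <- hits + 1L
  }
  expect_gt(hits, 20L)   # majority of seeds
})

test_that("screen_report emits a ledger that round-trips through CSV", {
  tab <- load_reference_table()
  out <- tempfile()
  led <- screen_report(tab, responses = c("dg_au", "dg_pd2"),
                       candidates = "vbur_total", max_vars = 1,
                       out_dir = out)
  expect_true(all(c("response", "filter", "robustness", "size", "n",
                    "variables", "coefficients", "intercept", "r2", "rmse",
                    "subsets_searched") %in% names(led)))
  expect_equal(nrow(led), 2L)
  expect_equal(led$n[led$response == "dg_pd2"], 16L)
  back <- utils::read.csv(file.path(out, "screen_ledger.csv"),
                          stringsAsFactors = FALSE)
  expect_equal(back$r2, led$r2, tolerance = 1e-12)
  expect_equal(back$variables, led$variables)
})
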