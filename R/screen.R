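#' Ordinary least squares fit of a descriptor subset
#'
#' OLS with intercept via `stats::lm.fit`. `r2 = 1 - SS_res/SS_tot`, which for
#' OLS with intercept equals the squared Pearson correlation of fitted vs
#' observed (the usual convention when quoting best-subset R^2). When the
#' response is constant (`SS_tot = 0`) `r2` is defined as 0. `rmse` uses
#' denominator n; the unbiased variant (`rmse_unbiased`, denominator
#' n - p - 1) is also carried since conventions differ.
#'
#' @param x numeric matrix or data.frame of descriptors (columns = variables).
#' @param y numeric response vector.
#' @param varnames optional variable names overriding `colnames(x)`.
#' @return object of class `model_fit`: `variables`, `coefficients` (one per
#'   variable), `intercept`, `r2`, `rmse`, `rmse_unbiased`, `n`, `fitted`,
#'   `residuals`.
#' @export
fit_ols <- function(x, y, varnames = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stop("x and y disagree on n")
  if (is.null(varnames)) varnames <- colnames(x)
  if (is.null(varnames)) varnames <- paste0("x", seq_len(ncol(x)))
  n <- length(y); p <- ncol(x)
  if (n < p + 2L) stop(sprintf("need n >= p + 2 (n = %d, p = %d)", n, p))
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("fit_ols requires complete, finite rows (apply listwise deletion first)")
  X <- cbind(`(Intercept)` = 1, x)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- setdiff(colnames(X), colnames(X)[qrX$pivot[seq_len(qrX$rank)]])
    stop("rank-deficient design; collinear column(s): ",
         paste(drop, collapse = ", "))
  }
  fit <- stats::lm.fit(X, y)
  res <- fit$residuals
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot <= 0) 0 else 1 - ss_res / ss_tot
  r2 <- min(1, max(0, r2))
  structure(list(
    variables = varnames,
    coefficients = stats::setNames(unname(fit$coefficients[-1L]), varnames),
    intercept = unname(fit$coefficients[1L]),
    r2 = r2,
    rmse = sqrt(ss_res / n),
    rmse_unbiased = if (n > p + 1L) sqrt(ss_res / (n - p - 1L)) else NA_real_,
    n = n, fitted = unname(fit$fitted.values), residuals = unname(res)
  ), class = "model_fit")
}

#' @export
print.model_fit <- function(x, digits = 4, ...) {
  cat(sprintf("model_fit: %d variable(s), n = %d, R2 = %.3f, RMSE = %.3f\n",
              length(x$variables), x$n, x$r2, x$rmse))
  co <- c(x$coefficients, `(Intercept)` = x$intercept)
  print(round(co, digits))
  invisible(x)
}

#' @export
predict.model_fit <- function(object, newdata, ...) {
  nd <- as.data.frame(newdata)
  miss <- setdiff(object$variables, names(nd))
  if (length(miss)) stop("newdata lacks column(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(nd[object$variables])
  drop(X %*% object$coefficients) + object$intercept
}

#' @export
residuals.model_fit <- function(object, ...) object$residuals

#' @export
coef.model_fit <- function(object, ...)
  c(`(Intercept)` = object$intercept, object$coefficients)

#' Robustness transforms of a response column
#'
#' `"clip_negative_to_zero"` maps negative response values to 0;
#' `"drop_negative"` removes those rows. Everything else is untouched.
#' `NA` responses are never considered negative.
#'
#' @param table data.frame.
#' @param response response column name.
#' @param mode `"clip_negative_to_zero"` or `"drop_negative"`.
#' @export
apply_robustness <- function(table, response,
                             mode = c("clip_negative_to_zero",
                                      "drop_negative")) {
  mode <- match.arg(mode)
  y <- table[[response]]
  if (is.null(y)) stop("no column ", sQuote(response))
  neg <- !is.na(y) & y < 0
  if (mode == "clip_negative_to_zero") {
    table[[response]][neg] <- 0
    table
  } else {
    table[!neg, , drop = FALSE]
  }
}

.parse_filter <- function(filter) {
  # "col > value" (strict); also accepts list(column=, threshold=)
  if (is.null(filter)) return(NULL)
  if (is.list(filter)) return(list(column = filter$column,
                                   threshold = as.numeric(filter$threshold)))
  m <- regmatches(filter, regexec("^\\s*([^ >]+)\\s*>\\s*([-0-9.eE+]+)\\s*$",
                                  filter))[[1L]]
  if (length(m) != 3L)
    stop("filter must look like 'column > value' (strict), got ", sQuote(filter))
  list(column = m[2L], threshold = as.numeric(m[3L]))
}

#' Exhaustive best-subset multilinear screen
#'
#' Enumerates all candidate-descriptor subsets of size 1..`max_vars`, applies
#' listwise deletion per evaluated subset (rows missing the response or any
#' descriptor in that subset are dropped, so each fit uses the maximum
#' available n), fits OLS with intercept, and ranks the fits of each size by
#' R^2 descending (ties: fewer variables, then lexicographic variable names).
#' An optional strict `column > threshold` filter restricts the rows first
#' (rows with the filter column missing are excluded), and a robustness mode
#' transforms the response before screening.
#'
#' Subsets whose post-deletion n falls below p + 2 or whose design is
#' rank-deficient are recorded with `NA` fit statistics rather than silently
#' dropped. No multiple-testing correction is applied: the output records the
#' number of subsets searched so selection effects can be judged.
#'
#' @param table data.frame of descriptors and responses.
#' @param response response column name (must not be a candidate).
#' @param candidates character vector of candidate descriptor columns, or
#'   `"all-numeric"` for every numeric column except the response.
#' @param max_vars largest subset size, 1..3.
#' @param filter optional strict filter, e.g. `"pyramidalization > 0.450"`.
#' @param robustness `"none"`, `"clip_negative_to_zero"` or `"drop_negative"`.
#' @param top_k ranked fits kept per size (default all).
#' @return object of class `model_screen`: `results` (data.frame, one row per
#'   evaluated subset, ranked within size), `best` (list of the top
#'   `model_fit` per size), plus the resolved configuration.
#' @export
screen_models <- function(table, response, candidates = "all-numeric",
                          max_vars = 3, filter = NULL, robustness = "none",
                          top_k = Inf) {
  stopifnot(is.data.frame(table))
  if (!response %in% names(table)) stop("no response column ", sQuote(response))
  if (identical(candidates, "all-numeric"))
    candidates <- setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                          response)
  candidates <- unique(as.character(candidates))
  if (length(candidates) == 0L) stop("no candidate columns")
  if (response %in% candidates) stop("response cannot be a candidate")
  miss <- setdiff(candidates, names(table))
  if (length(miss)) stop("candidate column(s) absent: ", paste(miss, collapse = ", "))
  if (!is.numeric(max_vars) || max_vars < 1 || max_vars > 3)
    stop("max_vars must be 1, 2 or 3")
  max_vars <- as.integer(max_vars)

  if (robustness != "none") table <- apply_robustness(table, response, robustness)
  flt <- .parse_filter(filter)
  if (!is.null(flt)) {
    if (!flt$column %in% names(table)) stop("filter column absent: ", flt$column)
    keep <- !is.na(table[[flt$column]]) & table[[flt$column]] > flt$threshold
    table <- table[keep, , drop = FALSE]
  }

  rows <- list(); best <- list(); any_ok <- FALSE
  n_evaluated <- 0L
  for (size in seq_len(min(max_vars, length(candidates)))) {
    subsets <- utils::combn(sort(candidates), size, simplify = FALSE)
    recs <- lapply(subsets, function(vars) {
      ok <- stats::complete.cases(table[c(response, vars)])
      n_ok <- sum(ok)
      fit <- if (n_ok >= size + 2L)
        tryCatch(fit_ols(table[ok, vars, drop = FALSE], table[[response]][ok],
                         varnames = vars),
                 error = function(e) NULL) else NULL
      data.frame(
        size = size, variables = paste(vars, collapse = " + "),
        n = n_ok,
        r2 = if (is.null(fit)) NA_real_ else fit$r2,
        rmse = if (is.null(fit)) NA_real_ else fit$rmse,
        rmse_unbiased = if (is.null(fit)) NA_real_ else fit$rmse_unbiased,
        coefficients = if (is.null(fit)) NA_character_ else
          paste(sprintf("%.6g", fit$coefficients), collapse = "; "),
        intercept = if (is.null(fit)) NA_real_ else fit$intercept,
        stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, recs)
    ord <- order(-ifelse(is.na(df$r2), -Inf, df$r2), df$variables)
    df <- df[ord, , drop = FALSE]
    df$rank <- seq_len(nrow(df))
    rownames(df) <- NULL
    n_evaluated <- n_evaluated + nrow(df)
    if (is.finite(top_k)) df <- df[seq_len(min(top_k, nrow(df))), , drop = FALSE]
    rows[[size]] <- df
    top_vars <- strsplit(df$variables[1L], " \\+ ")[[1L]]
    if (!is.na(df$r2[1L])) {
      ok <- stats::complete.cases(table[c(response, top_vars)])
      best[[as.character(size)]] <-
        fit_ols(table[ok, top_vars, drop = FALSE], table[[response]][ok],
                varnames = top_vars)
      any_ok <- TRUE
    }
  }
  if (!any_ok)
    stop("no evaluated subset satisfied n >= p + 2 after filtering/deletion")
  structure(list(results = do.call(rbind, rows), best = best,
                 response = response, candidates = sort(candidates),
                 max_vars = max_vars, filter = filter,
                 robustness = robustness,
                 n_subsets = n_evaluated),
            class = "model_screen")
}

#' @export
print.model_screen <- function(x, ...) {
  cat(sprintf("model_screen: response %s, %d candidates, sizes 1..%d (%s%s)\n",
              sQuote(x$response), length(x$candidates), x$max_vars,
              if (is.null(x$filter)) "no filter" else x$filter,
              if (x$robustness == "none") "" else paste0(", ", x$robustness)))
  cat(sprintf("  %d subsets evaluated\n", x$n_subsets))
  for (s in names(x$best)) {
    b <- x$best[[s]]
    cat(sprintf("  best %s-variable: %s  (n = %d, R2 = %.3f, RMSE = %.3f)\n",
                s, paste(b$variables, collapse = " + "), b$n, b$r2, b$rmse))
  }
  invisible(x)
}

#' @export
summary.model_screen <- function(object, top = 5L, ...) {
  res <- object$results
  out <- do.call(rbind, lapply(split(res, res$size), utils::head, top))
  rownames(out) <- NULL
  out
}

#' @export
plot.model_screen <- function(x, size = max(as.integer(names(x$best))), ...) {
  b <- x$best[[as.character(size)]]
  if (is.null(b)) stop("no best fit of size ", size)
  obs <- b$fitted + b$residuals
  graphics::plot(b$fitted, obs, xlab = "modelled", ylab = "computed",
                 main = sprintf("%s ~ %s (R2 = %.3f)", x$response,
                                paste(b$variables, collapse = " + "), b$r2),
                 ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Run a grid of screens and emit a summary ledger
#'
#' Screens every response against the candidate pool, with and without the
#' pyramidalization-style filter, and (for responses named in
#' `robust_responses`) with the two robustness variants. Returns the
#' benchmark-table-shaped ledger (response, filter, robustness, size, n,
#' variables, coefficients, intercept, r2, rmse) of the best fit per size of
#' every screen, optionally written to CSV together with observed-vs-predicted
#' data for the best model of each screen.
#'
#' @param table descriptor data.frame.
#' @param responses character vector of response columns.
#' @param candidates candidate columns or `"all-numeric"` (resolved once,
#'   excluding all responses).
#' @param max_vars largest subset size.
#' @param filter optional strict filter string applied in the filtered pass
#'   (e.g. `"pyramidalization > 0.450"`); `NULL` to skip the filtered pass.
#' @param robust_responses responses additionally screened under the two
#'   robustness modes (unfiltered).
#' @param out_dir optional directory for `screen_ledger.csv` and per-screen
#'   observed-vs-predicted CSVs.
#' @return the ledger data.frame (invisibly carries the `model_screen`
#'   objects as attribute `"screens"`).
#' @export
screen_report <- function(table, responses, candidates = "all-numeric",
                          max_vars = 3, filter = NULL,
                          robust_responses = character(0), out_dir = NULL) {
  if (identical(candidates, "all-numeric"))
    candidates <- setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                          responses)
  runs <- list()
  for (resp in responses) {
    runs[[paste0(resp, "|none|none")]] <-
      list(resp = resp, filter = NULL, rob = "none")
    if (!is.null(filter))
      runs[[paste0(resp, "|", filter, "|none")]] <-
        list(resp = resp, filter = filter, rob = "none")
    if (resp %in% robust_responses)
      for (rb in c("clip_negative_to_zero", "drop_negative"))
        runs[[paste0(resp, "|none|", rb)]] <-
          list(resp = resp, filter = NULL, rob = rb)
  }
  ledger <- list(); screens <- list()
  for (nm in names(runs)) {
    r <- runs[[nm]]
    sc <- tryCatch(
      screen_models(table, r$resp, candidates, max_vars = max_vars,
                    filter = r$filter, robustness = r$rob),
      error = function(e) NULL)
    if (is.null(sc)) next
    screens[[nm]] <- sc
    for (s in names(sc$best)) {
      b <- sc$best[[s]]
      ledger[[length(ledger) + 1L]] <- data.frame(
        response = r$resp,
        filter = if (is.null(r$filter)) "" else r$filter,
        robustness = r$rob, size = as.integer(s), n = b$n,
        variables = paste(b$variables, collapse = " + "),
        coefficients = paste(sprintf("%.6g", b$coefficients), collapse = "; "),
        intercept = b$intercept, r2 = b$r2, rmse = b$rmse,
        rmse_unbiased = b$rmse_unbiased,
        subsets_searched = sc$n_subsets,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(ledger)) stop("no screen could be evaluated")
  out <- do.call(rbind, ledger)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(out_dir, "screen_ledger.csv"),
                     row.names = FALSE)
    for (nm in names(screens)) {
      sc <- screens[[nm]]
      b <- sc$best[[length(sc$best)]]
      ovp <- data.frame(modelled = b$fitted, computed = b$fitted + b$residuals)
      fn <- paste0("ovp_", gsub("[^A-Za-z0-9._-]+", "_", nm), ".csv")
      utils::write.csv(ovp, file.path(out_dir, fn), row.names = FALSE)
    }
  }
  attr(out, "screens") <- screens
  out
}
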