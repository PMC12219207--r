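#' Pearson correlation with pairwise complete-case deletion
#'
#' @param x,y numeric vectors of equal length; pairs with a missing value in
#'   either are dropped.
#' @return The sample Pearson correlation, with the number of complete pairs
#'   attached as attribute `n`.
#' @export
pearson_correlation <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 3L) stop("undefined correlation: fewer than 3 complete pairs")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    stop("undefined correlation: zero variance after pairwise deletion")
  structure(stats::cor(x[ok], y[ok]), n = n)
}

#' Property-index correlation screening
#'
#' Computes the Pearson correlation of every physicochemical property with
#' every topological index under pairwise complete-case deletion, the
#' screening step that motivates which indices enter the regression models.
#'
#' @param it index table as from [load_index_table()].
#' @param pt property table as from [load_property_table()].
#' @return A properties x indices numeric matrix of correlations, with the
#'   matrix of per-cell complete-pair counts as attribute `n`.
#' @examples
#' r <- correlation_table(load_index_table(), load_property_table())
#' round(r["P", "H"], 3)
#' @export
correlation_table <- function(it, pt) {
  stopifnot(identical(it$drug, pt$drug))
  props <- setdiff(names(pt), "drug")
  idx <- intersect(index_ids(), names(it))
  r <- matrix(NA_real_, length(props), length(idx),
              dimnames = list(props, idx))
  nm <- r
  for (p in props) for (i in idx) {
    ri <- pearson_correlation(pt[[p]], it[[i]])
    r[p, i] <- ri
    nm[p, i] <- attr(ri, "n")
  }
  attr(r, "n") <- nm
  r
}

#' Construct a regression model specification
#'
#' @param id integer model identifier.
#' @param response property id (column of the property table).
#' @param regressors character vector of index ids.
#' @param intercept,coefficients optional published values, kept for
#'   comparison reports.
#' @param stats optional named list of published fit statistics.
#' @return A `model_spec` object.
#' @export
model_spec <- function(id, response, regressors, intercept = NA_real_,
                       coefficients = NULL, stats = NULL) {
  stopifnot(all(regressors %in% index_ids()))
  structure(list(id = id, response = response, regressors = regressors,
                 intercept = intercept,
                 coefficients = coefficients, stats = stats),
            class = "model_spec")
}

#' Fit an enter-method multiple linear regression
#'
#' Ordinary least squares of a property on a fixed set of topological indices,
#' all regressors entered simultaneously and retained regardless of
#' significance (the "enter" method). Rows with a missing response are
#' dropped (listwise deletion on the response only; the index table is
#' complete by construction).
#'
#' @param pt property table (columns `drug` and the response).
#' @param it index table (columns `drug` and the regressors).
#' @param spec a [model_spec()].
#' @return A `qspr_fit`: list with the `spec`, `intercept`, `coefficients`
#'   (named by regressor), `rows` (drug names used), `fitted`, `residuals`,
#'   `n`, `k` and the underlying `lm` object.
#' @export
fit_mlr <- function(pt, it, spec) {
  stopifnot(inherits(spec, "model_spec"),
            identical(it$drug, pt$drug),
            spec$response %in% names(pt),
            all(spec$regressors %in% names(it)))
  y <- pt[[spec$response]]
  keep <- !is.na(y)
  X <- as.matrix(it[keep, spec$regressors, drop = FALSE])
  if (anyNA(X)) stop("regressor table has missing values")
  n <- sum(keep); k <- length(spec$regressors)
  if (n <= k + 1L)
    stop("n = ", n, " rows is too few for ", k, " regressors plus intercept")
  qrX <- qr(cbind(1, X))
  if (qrX$rank < k + 1L) {
    kept <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- c("(Intercept)", colnames(X))[setdiff(seq_len(k + 1L), kept)]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  dat <- data.frame(.y = y[keep], X, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = dat)
  co <- stats::coef(fit)
  structure(list(spec = spec,
                 intercept = unname(co[1L]),
                 coefficients = stats::setNames(unname(co[-1L]), spec$regressors),
                 rows = pt$drug[keep],
                 fitted = stats::setNames(unname(stats::fitted(fit)), pt$drug[keep]),
                 residuals = stats::setNames(unname(stats::resid(fit)), pt$drug[keep]),
                 n = n, k = k, lm = fit),
            class = "qspr_fit")
}

#' @export
print.qspr_fit <- function(x, ...) {
  cat(sprintf("qspr_fit: %s ~ %s (n = %d)\n", x$spec$response,
              paste(x$spec$regressors, collapse = " + "), x$n))
  print(round(c("(Intercept)" = x$intercept, x$coefficients), 4))
  invisible(x)
}

#' Summary statistics of a fitted QSPR model
#'
#' Computes the statistics reported with the published models: `n`, multiple
#' correlation `r` (positive root of R-squared), `R2`, standard error
#' `SE = sqrt(SSE/(n-k-1))`, Fisher statistic
#' `F = (R2/k) / ((1-R2)/(n-k-1))`, root mean square error
#' `RMSE = sqrt(SSE/n)` and the upper-tail F probability `p`. The `RMSE`
#' denominator `n` (rather than the residual degrees of freedom used by `SE`)
#' is the convention that reproduces every published (SE, RMSE, n) triple for
#' the ten-regressor models.
#'
#' @param f a `qspr_fit` from [fit_mlr()].
#' @return Named list with `n`, `r`, `R2`, `SE`, `F`, `RMSE`, `p`.
#' @export
fit_statistics <- function(f) {
  stopifnot(inherits(f, "qspr_fit"))
  n <- f$n; k <- f$k
  if (n <= k + 1L) stop("too few rows for fit statistics")
  sse <- sum(f$residuals^2)
  y <- f$fitted + f$residuals
  sst <- sum((y - mean(y))^2)
  R2 <- 1 - sse / sst
  Fstat <- (R2 / k) / ((1 - R2) / (n - k - 1))
  list(n = n, r = sqrt(R2), R2 = R2,
       SE = sqrt(sse / (n - k - 1)),
       F = Fstat,
       RMSE = sqrt(sse / n),
       p = stats::pf(Fstat, k, n - k - 1, lower.tail = FALSE))
}

#' Predict a property for every drug from a fitted model
#'
#' Uses the full-precision refit coefficients (not the rounded published
#' ones) and produces predictions for all rows of the index table, including
#' drugs excluded from fitting because their response is missing.
#'
#' @param object a `qspr_fit`.
#' @param it index table with the model's regressors (defaults to the table
#'   used implicitly via `newdata = NULL` is not supported; pass the table).
#' @param ... unused.
#' @return Named numeric vector of predictions, one per drug in `it`.
#' @export
predict.qspr_fit <- function(object, it, ...) {
  X <- as.matrix(it[, object$spec$regressors, drop = FALSE])
  stats::setNames(drop(object$intercept + X %*% object$coefficients), it$drug)
}

#' Refit all published models and compare with the printed statistics
#'
#' Refits each published model specification on the packaged tables and
#' tabulates recomputed versus printed fit statistics with absolute
#' deviations.
#'
#' @param pt,it,specs the fixture tables and model specs; default to the
#'   packaged ones.
#' @return List with `fits` (list of `qspr_fit`), `statistics` (list of
#'   [fit_statistics()] results) and `comparison` (long data frame with
#'   columns `model`, `response`, `statistic`, `printed`, `recomputed`,
#'   `abs_deviation`).
#' @export
reproduce_models <- function(pt = load_property_table(),
                             it = load_index_table(),
                             specs = load_model_specs()) {
  fits <- lapply(specs, fit_mlr, pt = pt, it = it)
  sts <- lapply(fits, fit_statistics)
  rows <- list()
  for (nm in names(specs)) {
    printed <- specs[[nm]]$stats
    rec <- sts[[nm]]
    for (s in c("n", "r", "R2", "SE", "F", "RMSE", "p")) {
      rows[[length(rows) + 1L]] <- data.frame(
        model = specs[[nm]]$id, response = specs[[nm]]$response, statistic = s,
        printed = as.numeric(printed[[s]]), recomputed = as.numeric(rec[[s]]),
        abs_deviation = abs(as.numeric(printed[[s]]) - as.numeric(rec[[s]])))
    }
  }
  list(fits = fits, statistics = sts, comparison = do.call(rbind, rows))
}
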