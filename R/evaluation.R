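#' Coefficient of determination and mean absolute error
#'
#' `r_squared()` is the coefficient of determination about the mean of
#' the true ages, `1 - SS_res / SS_tot` (not the squared Pearson
#' correlation, which is reported separately in CV summaries). `mae()` is
#' the mean absolute residual in years.
#'
#' @param true,predicted Numeric vectors of equal length.
#' @return A single number.
#' @export
r_squared <- function(true, predicted) {
  stopifnot(length(true) == length(predicted))
  ok <- is.finite(true) & is.finite(predicted)
  1 - sum((predicted[ok] - true[ok])^2) / sum((true[ok] - mean(true[ok]))^2)
}

#' @rdname r_squared
#' @export
mae <- function(true, predicted) {
  stopifnot(length(true) == length(predicted))
  ok <- is.finite(true) & is.finite(predicted)
  mean(abs(predicted[ok] - true[ok]))
}

#' k-fold cross-validated age prediction
#'
#' Samples are partitioned into `k` seeded random folds with sizes
#' differing by at most one; for each fold the reference — including the
#' Spearman site ranking — is re-fit strictly on the other folds'
#' samples, and the held-out samples are predicted. Re-ranking inside
#' every fold is what keeps site selection leakage-free. Fold assignment
#' is keyed to sorted sample IDs, so the report is identical whatever
#' order the samples arrive in.
#'
#' @param x A `meth_matrix` with ages.
#' @param k Number of folds (default 10); `k = n` gives leave-one-out.
#' @param tau,trend_kind,grid,eps,min_site_coverage Passed to
#'   [construct_reference()].
#' @param n_sites Site budget for both training retention and prediction
#'   (default 8).
#' @param seed Seed for the fold partition.
#' @return A `cv_report`: per-sample predictions and residuals
#'   (`tidy()`), summary metrics (`glance()`): coefficient of
#'   determination, squared Pearson correlation, MAE, and the Spearman
#'   correlation of residuals with age, plus the residual LOWESS trend
#'   ([residual_bias()]).
#' @export
kfold_cross_validate <- function(x, k = 10, tau = 0.7, n_sites = 8,
                                 trend_kind = c("lowess", "linear"),
                                 grid = age_grid(), eps = 1e-6,
                                 min_site_coverage = 5, seed = 1L) {
  stopifnot(inherits(x, "meth_matrix"))
  trend_kind <- match.arg(trend_kind)
  k <- assert_count(k, "k", lower = 2L)
  n <- length(x$samples)
  if (n < k) abort("Need at least k samples for k folds.")

  ord <- order(x$samples, method = "radix")
  sorted_ids <- x$samples[ord]
  folds <- withr::with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  fold_of <- setNames(folds, sorted_ids)

  rows <- purrr::map_dfr(seq_len(k), function(f) {
    test_ids <- sorted_ids[fold_of == f]
    train_idx <- which(!x$samples %in% test_ids)
    train <- subset_matrix(x, train_idx)
    ref <- construct_reference(
      train, tau = tau, n_sites = Inf, trend_kind = trend_kind,
      grid = grid, eps = eps, min_site_coverage = min_site_coverage
    )
    preds <- predict_age(sample_counts(x, test_ids), ref, n_sites)
    preds$fold <- f
    preds
  })
  age_of <- setNames(x$ages, x$samples)
  rows$true_age <- unname(age_of[rows$sample_id])
  rows$residual <- rows$mle_age - rows$true_age
  rows <- dplyr::arrange(rows, .data$sample_id)
  structure(
    list(
      samples = rows[, c("sample_id", "fold", "true_age", "mle_age",
                         "residual", "n_sites_used", "note")],
      k = k, tau = tau, n_sites = n_sites, trend_kind = trend_kind,
      grid = grid, seed = seed
    ),
    class = "cv_report"
  )
}

subset_matrix <- function(x, idx) {
  new_meth_matrix(
    sites = x$sites, samples = x$samples[idx], ages = x$ages[idx],
    meth = x$meth[, idx, drop = FALSE], cov = x$cov[, idx, drop = FALSE]
  )
}

#' @export
print.cv_report <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<cv_report> %d-fold CV, %s trend, top %d sites: R2 = %.3f, MAE = %.2f yr, residual-age Spearman = %.3f\n",
    x$k, x$trend_kind, x$n_sites, g$r_squared, g$mae,
    g$residual_age_spearman
  ))
  invisible(x)
}

#' @param x A `cv_report`.
#' @param ... Unused.
#' @describeIn kfold_cross_validate Per-sample prediction table.
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) tibble::as_tibble(x$samples)

#' @describeIn kfold_cross_validate One-row metric summary.
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  s <- x$samples
  ok <- is.finite(s$mle_age)
  bias <- residual_bias(x)
  tibble::tibble(
    n = nrow(s), n_predicted = sum(ok), k = x$k,
    trend_kind = x$trend_kind, n_sites = x$n_sites, tau = x$tau,
    r_squared = r_squared(s$true_age, s$mle_age),
    pearson_r2 = cor(s$true_age[ok], s$mle_age[ok])^2,
    mae = mae(s$true_age, s$mle_age),
    residual_age_spearman = bias$residual_age_spearman
  )
}

#' Residual-bias analysis of cross-validated predictions
#'
#' A clock is interpretable as an "age acceleration" readout only if its
#' residuals (predicted - true) carry no age trend. This fits a LOWESS
#' curve (default tau 0.9) to residual versus true age and reports the
#' Spearman correlation of residuals with age as a scalar bias measure.
#' Constant residuals have no defined rank correlation; they are reported
#' as 0 with `constant_residuals = TRUE`.
#'
#' @param report A `cv_report`, or a data frame with `true_age` and
#'   `residual` columns (e.g. an externally produced prediction table).
#' @param tau_resid LOWESS neighbourhood fraction for the residual trend.
#' @return List with `trend` (tibble: `age`, `residual_trend` on the
#'   distinct true ages), `residual_age_spearman`, and
#'   `constant_residuals`.
#' @export
residual_bias <- function(report, tau_resid = 0.9) {
  s <- if (inherits(report, "cv_report")) report$samples else report
  if (!all(c("true_age", "residual") %in% names(s))) {
    abort("`report` must have columns true_age and residual.")
  }
  ok <- is.finite(s$residual)
  age <- s$true_age[ok]
  res <- s$residual[ok]
  constant <- length(unique(res)) < 2L
  rho <- if (constant) 0 else spearman_rho(age, res)
  fit <- lowess_fit(age, res, tau = tau_resid)
  o <- order(age)
  list(
    trend = tibble::tibble(age = age[o], residual_trend = fit[o]),
    residual_age_spearman = rho,
    constant_residuals = constant
  )
}

#' Compare trend kinds and site budgets under identical folds
#'
#' Runs [kfold_cross_validate()] for each combination of `trend_kinds`
#' and `n_sites_values` using the same seed (hence identical fold
#' partitions) and tabulates the summary metrics side by side.
#'
#' @inheritParams kfold_cross_validate
#' @param trend_kinds Character vector among `"lowess"`, `"linear"`.
#' @param n_sites_values Integer vector of site budgets.
#' @return List with `summary` (one row per configuration) and `reports`
#'   (named list of `cv_report`s).
#' @export
compare_trend_kinds <- function(x, k = 10, tau = 0.7,
                                trend_kinds = c("lowess", "linear"),
                                n_sites_values = 8, grid = age_grid(),
                                eps = 1e-6, min_site_coverage = 5,
                                seed = 1L) {
  configs <- expand.grid(trend_kind = trend_kinds,
                         n_sites = n_sites_values,
                         stringsAsFactors = FALSE)
  reports <- purrr::pmap(configs, function(trend_kind, n_sites) {
    kfold_cross_validate(
      x, k = k, tau = tau, n_sites = n_sites, trend_kind = trend_kind,
      grid = grid, eps = eps, min_site_coverage = min_site_coverage,
      seed = seed
    )
  })
  names(reports) <- paste0(configs$trend_kind, "_", configs$n_sites)
  list(
    summary = purrr::map_dfr(reports, glance),
    reports = reports
  )
}
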