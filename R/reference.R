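#' Discrete candidate-age grid
#'
#' The likelihood is evaluated on integer ages from `grid_min` to
#' `grid_max` in steps of 1 year (default 1-100).
#'
#' @param grid_min,grid_max Grid bounds in years; `grid_min >= 0`.
#' @return Numeric vector of grid ages.
#' @export
age_grid <- function(grid_min = 1, grid_max = 100) {
  assert_scalar_number(grid_min, "grid_min", lower = 0)
  assert_scalar_number(grid_max, "grid_max", lower = grid_min + 1)
  seq(grid_min, grid_max, by = 1)
}

#' Locally weighted scatterplot smoothing (LOWESS)
#'
#' Classic robust LOWESS: for each target point the nearest
#' `ceiling(tau * N)` points by distance in `x` receive tricube weights
#' `(1 - (d/dmax)^3)^3` and a weighted least-squares line is evaluated at
#' the target. Bisquare robustifying reweighting is then applied `iters`
#' times to downweight outliers. `tau` is the neighbourhood fraction: the
#' share of the data entering each local fit, larger values giving
#' smoother curves.
#'
#' @param x,y Numeric vectors of equal length; `x` needs >= 5 distinct
#'   values.
#' @param tau Neighbourhood fraction in (0, 1].
#' @param iters Number of robustifying iterations (default 3).
#' @return Fitted value at each `x`, in input order.
#' @export
lowess_fit <- function(x, y, tau = 0.7, iters = 3) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("`x` and `y` must be finite.")
  }
  assert_scalar_number(tau, "tau", 0, 1, open_lower = TRUE)
  n <- length(x)
  if (length(unique(x)) < 5L) {
    abort("LOWESS needs at least 5 distinct x values.")
  }
  if (diff(range(x)) == 0) abort("All x values are identical.")
  k <- ceiling(tau * n)
  if (k < 2L) {
    abort("Local window has fewer than 2 points; increase tau or add data.")
  }

  # tricube kernel weights of the k nearest neighbours of each target
  nbr_idx <- vector("list", n)
  nbr_w <- vector("list", n)
  for (i in seq_len(n)) {
    d <- abs(x - x[i])
    idx <- order(d)[seq_len(k)]
    dmax <- d[idx[k]]
    w <- if (dmax > 0) (1 - pmin(d[idx] / dmax, 1)^3)^3 else rep(1, k)
    nbr_idx[[i]] <- idx
    nbr_w[[i]] <- w
  }

  rw <- rep(1, n)
  fitted <- numeric(n)
  for (it in seq_len(iters + 1L)) {
    for (i in seq_len(n)) {
      idx <- nbr_idx[[i]]
      w <- nbr_w[[i]] * rw[idx]
      fitted[i] <- wls_at(x[idx], y[idx], w, x[i])
    }
    if (it > iters) break
    res <- y - fitted
    s <- median(abs(res))
    if (s == 0) break
    rw <- pmax(1 - (res / (6 * s))^2, 0)^2
  }
  if (!all(is.finite(fitted))) {
    abort("LOWESS produced non-finite fits; increase tau or add data.")
  }
  fitted
}

# Weighted least-squares line through (x, y) with weights w, evaluated at
# x0; falls back to the weighted mean when the local x spread degenerates.
wls_at <- function(x, y, w, x0) {
  sw <- sum(w)
  if (sw <= 0) return(mean(y))
  xbar <- sum(w * x) / sw
  ybar <- sum(w * y) / sw
  sxx <- sum(w * (x - xbar)^2)
  if (sxx <= .Machine$double.eps * sw * max(x^2, 1)) return(ybar)
  ybar + sum(w * (x - xbar) * (y - ybar)) / sxx * (x0 - xbar)
}

#' Evaluate fitted trend values on the age grid
#'
#' Linear interpolation between fitted values inside the training age
#' range, constant (nearest-value) extrapolation outside it, then clipping
#' into `[eps, 1 - eps]` so the binomial log-likelihood stays finite.
#' Duplicate training ages are averaged before interpolation.
#'
#' @param x Training ages.
#' @param fitted Fitted methylation values at `x`.
#' @param grid Age grid from [age_grid()].
#' @param eps Clip epsilon.
#' @return Expected methylation probability per grid age.
#' @export
trend_on_grid <- function(x, fitted, grid, eps = 1e-6) {
  assert_scalar_number(eps, "eps", 0, 0.5, open_lower = TRUE, open_upper = TRUE)
  p <- approx(x, fitted, xout = grid, rule = 2, ties = mean)$y
  clip01(p, eps)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked data (ties receive mean ranks);
#' robust to any monotone nonlinearity in the methylation-age trend, which
#' is why sites are scored with it.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    abort("`x` and `y` must have equal length >= 3.")
  }
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    abort("Spearman correlation is undefined for a constant vector.")
  }
  cor(x, y, method = "spearman")
}

#' Ordinary least-squares methylation-age trend
#'
#' The linear baseline reference: `meth = a * age + b` fit by OLS. Used as
#' `trend_kind = "linear"` inside the same binomial likelihood engine.
#'
#' @param x Ages; `y` methylation fractions. At least 3 points with
#'   non-degenerate `x`.
#' @return Named vector `c(slope, intercept)`.
#' @export
linear_trend <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    abort("Need at least 3 (age, methylation) points.")
  }
  if (diff(range(x)) == 0) abort("All x values are identical.")
  xbar <- mean(x)
  slope <- sum((x - xbar) * (y - mean(y))) / sum((x - xbar)^2)
  c(slope = slope, intercept = mean(y) - slope * xbar)
}

#' Train a per-site methylation-age reference model
#'
#' For every site: per-sample methylation fractions `meth/total` are
#' computed from samples with coverage at least `min_site_coverage` at
#' that site; a trend (LOWESS or OLS line) is fit against age and
#' evaluated on the age grid; the Spearman correlation of fraction with
#' age scores the site. Sites are ranked by descending `|rho|` (ties
#' broken by site key) and the top `n_sites` are kept. Sites with fewer
#' than 5 usable samples, or with constant fractions or ages, are skipped
#' with a warning.
#'
#' @param x A `meth_matrix` with at least 2 distinct ages.
#' @param tau LOWESS neighbourhood fraction (default 0.7).
#' @param n_sites Number of top-ranked sites to retain (default all).
#' @param trend_kind `"lowess"` or `"linear"`.
#' @param grid Age grid (default [age_grid()], 1-100).
#' @param eps Probability clip epsilon (default 1e-6).
#' @param min_site_coverage Minimum per-cell coverage for a sample to
#'   enter a site's trend fit (default 5).
#' @return An `age_reference`: per-site expected methylation on the grid
#'   plus Spearman scores, with [tidy.age_reference()] /
#'   [glance.age_reference()] / [autoplot.age_reference()] methods.
#' @export
construct_reference <- function(x, tau = 0.7, n_sites = Inf,
                                trend_kind = c("lowess", "linear"),
                                grid = age_grid(), eps = 1e-6,
                                min_site_coverage = 5) {
  stopifnot(inherits(x, "meth_matrix"))
  trend_kind <- match.arg(trend_kind)
  min_site_coverage <- assert_count(min_site_coverage, "min_site_coverage", 1L)
  assert_scalar_number(tau, "tau", 0, 1, open_lower = TRUE)
  if (length(unique(x$ages)) < 2L) {
    abort("Training needs at least 2 samples with distinct ages.")
  }
  validate_grid(grid)

  n_site_total <- nrow(x$sites)
  rho <- rep(NA_real_, n_site_total)
  n_used <- integer(n_site_total)
  probs <- matrix(NA_real_, n_site_total, length(grid))
  skipped <- character(0)
  for (i in seq_len(n_site_total)) {
    use <- x$cov[i, ] >= min_site_coverage
    if (sum(use) < 5L) {
      skipped <- c(skipped, rownames(x$cov)[i])
      next
    }
    ages_i <- x$ages[use]
    frac_i <- x$meth[i, use] / x$cov[i, use]
    if (length(unique(ages_i)) < 5L || length(unique(frac_i)) < 2L ||
        length(unique(ages_i)) < 2L) {
      skipped <- c(skipped, rownames(x$cov)[i])
      next
    }
    rho[i] <- spearman_rho(ages_i, frac_i)
    n_used[i] <- sum(use)
    fit <- if (trend_kind == "lowess") {
      lowess_fit(ages_i, frac_i, tau = tau)
    } else {
      ab <- linear_trend(ages_i, frac_i)
      ab["slope"] * ages_i + ab["intercept"]
    }
    probs[i, ] <- trend_on_grid(ages_i, fit, grid, eps)
  }
  if (length(skipped)) {
    inform(sprintf(
      "Skipped %d site(s) with < 5 usable samples or constant data.",
      length(skipped)
    ))
  }
  scorable <- which(!is.na(rho))
  if (!length(scorable)) abort("No scorable sites; check coverage filters.")
  keys <- site_key(x$sites$chrom, x$sites$pos)
  ord <- scorable[order(-abs(rho[scorable]), keys[scorable], method = "radix")]
  if (is.finite(n_sites)) {
    n_sites <- assert_count(n_sites, "n_sites", 1L)
    if (n_sites > length(ord)) {
      warn(sprintf(
        "Requested %d sites but only %d are scorable; returning all.",
        n_sites, length(ord)
      ))
    }
    ord <- head(ord, n_sites)
  }
  structure(
    list(
      grid = grid,
      sites = tibble::tibble(
        chrom = x$sites$chrom[ord], pos = x$sites$pos[ord],
        rho = rho[ord], n_train = n_used[ord]
      ),
      probs = probs[ord, , drop = FALSE],
      tau = tau, eps = eps, trend_kind = trend_kind,
      n_samples = length(x$samples)
    ),
    class = "age_reference"
  )
}

validate_grid <- function(grid) {
  if (length(grid) < 2L || any(diff(grid) != 1) || grid[1] < 0) {
    abort("`grid` must be increasing ages with step exactly 1 and min >= 0.")
  }
  invisible(grid)
}

#' @export
print.age_reference <- function(x, ...) {
  cat(sprintf(
    "<age_reference> %s trends at %d CpG sites, grid %g-%g yr (tau = %g, trained on %d samples)\n",
    x$trend_kind, nrow(x$sites), min(x$grid), max(x$grid), x$tau, x$n_samples
  ))
  invisible(x)
}

#' Tidy and summarise a trained reference model
#'
#' `tidy()` returns the per-site trend table in rank order (one row per
#' site x grid age in `long = TRUE` form); `glance()` returns a one-row
#' model summary.
#'
#' @param x An `age_reference`.
#' @param long Return one row per site x grid age (default) or one row
#'   per site without the curve.
#' @param ... Unused.
#' @method tidy age_reference
#' @export
tidy.age_reference <- function(x, long = TRUE, ...) {
  per_site <- dplyr::mutate(x$sites, rank = dplyr::row_number())
  if (!long) return(per_site)
  curves <- tibble::tibble(
    rank = rep(per_site$rank, each = length(x$grid)),
    age = rep(x$grid, nrow(per_site)),
    expected_meth = as.vector(t(x$probs))
  )
  dplyr::left_join(per_site, curves, by = "rank")
}

#' @rdname tidy.age_reference
#' @method glance age_reference
#' @export
glance.age_reference <- function(x, ...) {
  tibble::tibble(
    n_sites = nrow(x$sites), trend_kind = x$trend_kind, tau = x$tau,
    eps = x$eps, grid_min = min(x$grid), grid_max = max(x$grid),
    n_samples = x$n_samples, max_abs_rho = max(abs(x$sites$rho))
  )
}

reference_format_version <- "methage-reference-v1"

#' Save / load a reference model as TSV
#'
#' Plain-text serialisation: `#`-prefixed metadata header (format version,
#' tau, eps, grid, trend kind, training size) followed by one row per site
#' with its key, Spearman rho, training count and expected methylation at
#' each grid age. Round trips losslessly; [load_reference()] rejects files
#' with an unknown version tag. Gzip-transparent.
#'
#' @param x An `age_reference`.
#' @param path Output path (`.tsv` or `.tsv.gz`).
#' @export
save_reference <- function(x, path) {
  stopifnot(inherits(x, "age_reference"))
  meta <- c(
    paste0("#version=", reference_format_version),
    sprintf("#tau=%s", format(x$tau, digits = 15)),
    sprintf("#eps=%s", format(x$eps, digits = 15)),
    sprintf("#grid_min=%g", min(x$grid)),
    sprintf("#grid_max=%g", max(x$grid)),
    paste0("#trend_kind=", x$trend_kind),
    sprintf("#n_samples=%d", x$n_samples)
  )
  header <- paste(c("site", "rho", "n_train",
                    paste0("age_", x$grid)), collapse = "\t")
  rows <- paste(
    site_key(x$sites$chrom, x$sites$pos),
    format(x$sites$rho, digits = 17),
    x$sites$n_train,
    apply(x$probs, 1, function(p) paste(format(p, digits = 17),
                                        collapse = "\t")),
    sep = "\t"
  )
  readr::write_lines(c(meta, header, gsub(" ", "", rows)), path)
  invisible(path)
}

#' @rdname save_reference
#' @export
load_reference <- function(path) {
  lines <- readr::read_lines(path)
  meta_lines <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  kv <- strsplit(sub("^#", "", meta_lines), "=", fixed = TRUE)
  meta <- setNames(vapply(kv, `[[`, character(1), 2),
                   vapply(kv, `[[`, character(1), 1))
  if (!identical(unname(meta["version"]), reference_format_version)) {
    abort(sprintf(
      "%s: unsupported reference format version '%s' (expected '%s').",
      path, meta["version"], reference_format_version
    ))
  }
  grid <- age_grid(as.numeric(meta["grid_min"]), as.numeric(meta["grid_max"]))
  if (length(body) < 2L) abort(sprintf("%s: no site rows.", path))
  parts <- strsplit(body[-1], "\t", fixed = TRUE)
  if (any(lengths(parts) != 3L + length(grid))) {
    abort(sprintf("%s: site rows do not match the grid length.", path))
  }
  keys <- vapply(parts, `[[`, character(1), 1)
  probs <- t(vapply(parts, function(r) as.numeric(r[-(1:3)]),
                    numeric(length(grid))))
  structure(
    list(
      grid = grid,
      sites = tibble::tibble(
        chrom = sub(":[0-9]+$", "", keys),
        pos = as.integer(sub("^.*:", "", keys)),
        rho = as.numeric(vapply(parts, `[[`, character(1), 2)),
        n_train = as.integer(vapply(parts, `[[`, character(1), 3))
      ),
      probs = probs,
      tau = as.numeric(meta["tau"]), eps = as.numeric(meta["eps"]),
      trend_kind = unname(meta["trend_kind"]),
      n_samples = as.integer(meta["n_samples"])
    ),
    class = "age_reference"
  )
}
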