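#' Simulate a synthetic sample from the reference at a given age
#'
#' Parametric-bootstrap draw: for every reference site covered by the
#' real sample (restricted to the prediction's site budget), a new
#' methylated count is drawn as `Binomial(n, p_site(at_age))` keeping the
#' real sample's per-site coverage `n`. Reproducible under `seed`.
#'
#' @param counts One sample's tidy count table.
#' @param reference An `age_reference`.
#' @param at_age A grid age at which to simulate.
#' @param n_sites Site budget (default 8).
#' @param seed Integer seed.
#' @param sim_from Draw counts from the reference trend at `at_age`
#'   (`"trend"`, default) or from the sample's own observed fractions
#'   (`"observed"`), clipped away from 0/1 by the reference's epsilon.
#' @return A tidy count table with the same sites/coverages and simulated
#'   methylated counts; `sample_id` is suffixed with `"_sim"`.
#' @export
simulate_sample <- function(counts, reference, at_age, n_sites = 8,
                            seed = 1L, sim_from = c("trend", "observed")) {
  sim_from <- match.arg(sim_from)
  prof <- profile_loglik(counts, reference, n_sites)
  gi <- match(at_age, reference$grid)
  if (is.na(gi)) abort("`at_age` must be one of the reference grid ages.")
  idx <- match(
    site_key(prof$sites$chrom, prof$sites$pos),
    site_key(reference$sites$chrom, reference$sites$pos)
  )
  p <- if (sim_from == "trend") {
    reference$probs[idx, gi]
  } else {
    clip01(prof$sites$meth / prof$sites$total, reference$eps)
  }
  n <- prof$sites$total
  x_star <- withr::with_seed(seed, rbinom(length(n), n, p))
  tibble::tibble(
    sample_id = paste0(prof$sample_id, "_sim"),
    chrom = prof$sites$chrom, pos = prof$sites$pos,
    meth = as.integer(x_star), total = n
  )
}

#' Simulation-based uncertainty bounds for one sample's age estimate
#'
#' The sample's maximum-likelihood age is computed, then `n_sims`
#' synthetic samples are generated at that age ([simulate_sample()]) and
#' re-predicted. The 25th and 75th percentiles of the simulated ages
#' (linear interpolation between order statistics, `quantile` type 7)
#' give the lower and upper IQR bounds. Each sample draws its own RNG
#' substream from `seed` and its id, so batch order does not affect
#' results.
#'
#' @inheritParams simulate_sample
#' @param n_sims Number of synthetic samples (default 100; >= 4).
#' @param seed Master seed.
#' @return An `age_uncertainty` with fields `sample_id`, `point_age`,
#'   `lower_iqr`, `upper_iqr`, `simulated_ages`, `seed`; `tidy()` gives a
#'   one-row tibble including the interval width.
#' @export
estimate_uncertainty <- function(counts, reference, n_sites = 8,
                                 n_sims = 100, seed = 1L,
                                 sim_from = c("trend", "observed")) {
  sim_from <- match.arg(sim_from)
  n_sims <- assert_count(n_sims, "n_sims", lower = 4L)
  prof <- profile_loglik(counts, reference, n_sites)
  base_seed <- derive_seed(seed, prof$sample_id)
  sims <- vapply(seq_len(n_sims), function(s) {
    sim <- simulate_sample(counts, reference, prof$mle_age, n_sites,
                           seed = (base_seed + s) %% 2147483562L + 1L,
                           sim_from = sim_from)
    profile_loglik(sim, reference, n_sites)$mle_age
  }, numeric(1))
  q <- unname(quantile(sims, c(0.25, 0.75), type = 7))
  structure(
    list(sample_id = prof$sample_id, point_age = prof$mle_age,
         lower_iqr = q[1], upper_iqr = q[2],
         simulated_ages = sims, seed = seed),
    class = "age_uncertainty"
  )
}

#' @export
print.age_uncertainty <- function(x, ...) {
  cat(sprintf(
    "<age_uncertainty> sample %s: %g yr, IQR [%g, %g] (%d simulations)\n",
    x$sample_id, x$point_age, x$lower_iqr, x$upper_iqr,
    length(x$simulated_ages)
  ))
  invisible(x)
}

#' @param x An `age_uncertainty`.
#' @param ... Unused.
#' @describeIn estimate_uncertainty One-row tibble with the point age,
#'   IQR bounds and width.
#' @method tidy age_uncertainty
#' @export
tidy.age_uncertainty <- function(x, ...) {
  tibble::tibble(
    sample_id = x$sample_id, point_age = x$point_age,
    lower_iqr = x$lower_iqr, upper_iqr = x$upper_iqr,
    width = x$upper_iqr - x$lower_iqr, n_sims = length(x$simulated_ages)
  )
}

#' Uncertainty bounds for a batch of samples
#'
#' @inheritParams estimate_uncertainty
#' @param counts Tidy count table, possibly many samples.
#' @return Tibble with one row per sample (see [tidy.age_uncertainty()]).
#' @export
estimate_uncertainty_batch <- function(counts, reference, n_sites = 8,
                                       n_sims = 100, seed = 1L) {
  validate_counts(counts)
  purrr::map_dfr(split(counts, counts$sample_id), function(df) {
    tidy(estimate_uncertainty(df, reference, n_sites, n_sims, seed))
  })
}

#' Mean interquartile width over a set of uncertainty estimates
#'
#' The cohort-level uncertainty summary: the arithmetic mean of
#' `upper_iqr - lower_iqr` across samples.
#'
#' @param estimates A list of `age_uncertainty` objects, or a tibble from
#'   [estimate_uncertainty_batch()] with `lower_iqr`/`upper_iqr` columns.
#' @return A single number (years).
#' @export
mean_iqr_width <- function(estimates) {
  if (is.data.frame(estimates)) {
    return(mean(estimates$upper_iqr - estimates$lower_iqr))
  }
  widths <- vapply(estimates, function(e) {
    stopifnot(inherits(e, "age_uncertainty"))
    e$upper_iqr - e$lower_iqr
  }, numeric(1))
  mean(widths)
}
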