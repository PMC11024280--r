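#' Binomial log probability mass
#'
#' Log of the probability of observing `x` methylated reads among `n`
#' reads when the true methylation level is `p`:
#' `log C(n, x) + x log p + (n - x) log(1 - p)`, with the combinatorial
#' term computed via log-gamma. `p` must lie strictly inside (0, 1) — the
#' reference curves are clipped upstream, so a boundary `p` here indicates
#' a missed clip and errors loudly.
#'
#' @param x Methylated (cytosine) read count, `0 <= x <= n`.
#' @param n Total read count, `>= 1`.
#' @param p Methylation probability strictly in (0, 1). Vectorised over
#'   all three arguments.
#' @return Log-probability (numeric).
#' @export
binomial_logpmf <- function(x, n, p) {
  if (any(p <= 0) || any(p >= 1)) {
    abort("`p` must lie strictly inside (0, 1); clip the trend first.")
  }
  if (any(x < 0) || any(x > n) || any(n < 1)) {
    abort("Counts must satisfy 0 <= x <= n and n >= 1.")
  }
  lgamma(n + 1) - lgamma(x + 1) - lgamma(n - x + 1) +
    x * log(p) + (n - x) * log1p(-p)
}

#' Age log-likelihood profile for one sample
#'
#' The top `n_sites` reference sites are intersected with the sample's
#' covered sites — intersection first, then truncation, preserving the
#' reference's rank order, so the requested site budget is met even when
#' the sample misses some top-ranked sites. At every grid age the
#' per-site binomial log-probabilities of the observed counts are summed
#' (the log-sum replaces the product of site probabilities to avoid
#' underflow); the grid age maximising this sum is the maximum-likelihood
#' epigenetic age. Ties are broken toward the youngest age. Sites with
#' zero coverage in the sample are skipped, never imputed.
#'
#' @param counts Tidy count table for a single sample (columns
#'   `sample_id`, `chrom`, `pos`, `meth`, `total`).
#' @param reference An `age_reference` from [construct_reference()].
#' @param n_sites Site budget (default 8).
#' @return An `age_likelihood`: the profile (`tidy()` gives one row per
#'   grid age with `loglik` and a flat-prior normalised `posterior`), the
#'   `mle_age`, and the sites used.
#' @export
profile_loglik <- function(counts, reference, n_sites = 8) {
  validate_counts(counts)
  stopifnot(inherits(reference, "age_reference"))
  n_sites <- assert_count(n_sites, "n_sites", 1L)
  if (length(unique(counts$sample_id)) != 1L) {
    abort("`counts` must contain exactly one sample; see predict_age() for batches.")
  }
  counts <- counts[counts$total > 0L, ]
  ref_keys <- site_key(reference$sites$chrom, reference$sites$pos)
  hit <- match(ref_keys, site_key(counts$chrom, counts$pos))
  use <- which(!is.na(hit))            # reference rank order
  if (!length(use)) {
    abort("No informative sites shared with the reference.")
  }
  use <- head(use, n_sites)
  xi <- counts$meth[hit[use]]
  ni <- counts$total[hit[use]]
  p <- reference$probs[use, , drop = FALSE]     # sites x grid ages
  const <- lgamma(ni + 1) - lgamma(xi + 1) - lgamma(ni - xi + 1)
  ll <- colSums(xi * log(p) + (ni - xi) * log1p(-p)) + sum(const)
  mle_idx <- which.max(ll)             # which.max takes the first maximum,
  structure(                           # i.e. the youngest tied age
    list(
      grid = reference$grid,
      loglik = unname(ll),
      mle_age = reference$grid[mle_idx],
      sample_id = counts$sample_id[1],
      sites = tibble::tibble(
        chrom = reference$sites$chrom[use],
        pos = reference$sites$pos[use],
        meth = xi, total = ni
      )
    ),
    class = "age_likelihood"
  )
}

#' @export
print.age_likelihood <- function(x, ...) {
  cat(sprintf(
    "<age_likelihood> sample %s: mle_age = %g yr from %d sites (grid %g-%g)\n",
    x$sample_id, x$mle_age, nrow(x$sites), min(x$grid), max(x$grid)
  ))
  invisible(x)
}

#' @param x An `age_likelihood`.
#' @param ... Unused.
#' @describeIn profile_loglik One row per grid age with the raw
#'   log-likelihood and the flat-prior posterior (softmax over the grid,
#'   for plotting).
#' @method tidy age_likelihood
#' @export
tidy.age_likelihood <- function(x, ...) {
  m <- max(x$loglik)
  w <- exp(x$loglik - m)
  tibble::tibble(
    age = x$grid, loglik = x$loglik, posterior = w / sum(w)
  )
}

#' @describeIn profile_loglik One-row summary (sample, MLE age, sites
#'   used, log-likelihood at the maximum).
#' @method glance age_likelihood
#' @export
glance.age_likelihood <- function(x, ...) {
  tibble::tibble(
    sample_id = x$sample_id, mle_age = x$mle_age,
    n_sites_used = nrow(x$sites), max_loglik = max(x$loglik)
  )
}

#' Predict epigenetic age for a batch of samples
#'
#' Runs [profile_loglik()] per sample and collects the maximum-likelihood
#' ages. A sample that fails (e.g. shares no site with the reference)
#' yields a row with `NA` age and the error message rather than aborting
#' the batch.
#'
#' @param counts Tidy count table; may hold many samples.
#' @param reference An `age_reference`.
#' @param n_sites Site budget per sample (default 8).
#' @return Tibble with one row per sample: `sample_id`, `mle_age`,
#'   `n_sites_used`, `note` (`NA` on success, else the failure message).
#' @export
predict_age <- function(counts, reference, n_sites = 8) {
  validate_counts(counts)
  purrr::map_dfr(split(counts, counts$sample_id), function(df) {
    res <- tryCatch(profile_loglik(df, reference, n_sites),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      tibble::tibble(sample_id = df$sample_id[1], mle_age = NA_real_,
                     n_sites_used = 0L, note = res)
    } else {
      tibble::tibble(sample_id = res$sample_id, mle_age = res$mle_age,
                     n_sites_used = nrow(res$sites), note = NA_character_)
    }
  })
}

#' Fraction-matching baseline age predictor
#'
#' A deliberately simple non-likelihood baseline used in the downsampling
#' robustness analysis: the predicted age minimises the sum of squared
#' differences between observed methylation fractions and the reference
#' curves. With `missing = "zero"`, reference sites absent from the
#' sample are imputed as fraction 0 (the failure mode of weighted-sum
#' clocks on sparse data); with `missing = "skip"` they are dropped.
#'
#' @inheritParams predict_age
#' @param missing How to treat reference sites with no coverage in a
#'   sample: `"skip"` or `"zero"`.
#' @return Tibble with `sample_id`, `pred_age`, `n_sites_used`.
#' @export
predict_age_fraction <- function(counts, reference, n_sites = 8,
                                 missing = c("skip", "zero")) {
  missing <- match.arg(missing)
  validate_counts(counts)
  n_sites <- assert_count(n_sites, "n_sites", 1L)
  top <- head(seq_len(nrow(reference$sites)), n_sites)
  ref_keys <- site_key(reference$sites$chrom[top], reference$sites$pos[top])
  p <- reference$probs[top, , drop = FALSE]
  purrr::map_dfr(split(counts, counts$sample_id), function(df) {
    sid <- df$sample_id[1]
    df <- df[df$total > 0L, ]
    hit <- match(ref_keys, site_key(df$chrom, df$pos))
    frac <- df$meth[hit] / df$total[hit]
    if (missing == "zero") {
      frac[is.na(frac)] <- 0
      use <- seq_along(frac)
    } else {
      use <- which(!is.na(frac))
    }
    if (!length(use)) {
      return(tibble::tibble(sample_id = sid,
                            pred_age = NA_real_, n_sites_used = 0L))
    }
    sse <- colSums((frac[use] - p[use, , drop = FALSE])^2)
    tibble::tibble(
      sample_id = sid,
      pred_age = reference$grid[which.min(sse)],
      n_sites_used = length(use)
    )
  })
}
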