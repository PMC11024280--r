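#' Specify a per-site methylation-age trend for simulation
#'
#' Trend families used by the cohort generator, covering the shapes seen
#' at age-associated CpGs: saturating exponentials (rapid change early in
#' life that decelerates with age), logistic transitions, straight lines
#' and flat (age-independent) sites.
#'
#' * `saturating_exp`: `m(a) = m0 + direction * amplitude * (1 - exp(-rate * a))`
#' * `logistic`: `m(a) = m0 + direction * amplitude / (1 + exp(-rate * (a - midpoint)))`
#' * `linear`: `m(a) = m0 + direction * amplitude * a / 100`
#' * `flat`: `m(a) = m0`
#'
#' all clipped into `[0, 1]`.
#'
#' @param kind Trend family.
#' @param m0 Baseline methylation level in `[0, 1]`.
#' @param amplitude Total change over the age span (>= 0).
#' @param rate Rate constant per year (> 0; ignored for linear/flat).
#' @param direction +1 (gains methylation with age) or -1 (loses).
#' @param midpoint Logistic midpoint age (years).
#' @return A `trend_spec` (callable on an age vector via [trend_value()]).
#' @export
trend_spec <- function(kind = c("saturating_exp", "logistic", "linear", "flat"),
                       m0 = 0.2, amplitude = 0.5, rate = 0.05,
                       direction = 1, midpoint = 40) {
  kind <- match.arg(kind)
  assert_scalar_number(m0, "m0", 0, 1)
  assert_scalar_number(amplitude, "amplitude", lower = 0)
  assert_scalar_number(rate, "rate", lower = 0, open_lower = TRUE)
  if (!direction %in% c(-1, 1)) abort("`direction` must be +1 or -1.")
  spec <- structure(
    list(kind = kind, m0 = m0, amplitude = amplitude, rate = rate,
         direction = direction, midpoint = midpoint),
    class = "trend_spec"
  )
  m <- trend_value(spec, 1:100, clip = FALSE)
  if (all(m < 0) || all(m > 1)) {
    abort("Infeasible trend: m(a) lies outside [0, 1] at every age.")
  }
  spec
}

#' Evaluate a simulation trend at given ages
#'
#' @param spec A `trend_spec`.
#' @param ages Ages in years.
#' @param clip Clip the result into `[0, 1]` (default TRUE).
#' @return Methylation level per age.
#' @export
trend_value <- function(spec, ages, clip = TRUE) {
  stopifnot(inherits(spec, "trend_spec"))
  m <- switch(spec$kind,
    saturating_exp = spec$m0 +
      spec$direction * spec$amplitude * (1 - exp(-spec$rate * ages)),
    logistic = spec$m0 +
      spec$direction * spec$amplitude /
        (1 + exp(-spec$rate * (ages - spec$midpoint))),
    linear = spec$m0 + spec$direction * spec$amplitude * ages / 100,
    flat = rep(spec$m0, length(ages))
  )
  if (clip) pmin(pmax(m, 0), 1) else m
}

#' Specify a synthetic bisulfite cohort
#'
#' Defaults describe the package's standard simulation study: 300
#' subjects with ages uniform on 1-90 years, 30 age-informative CpGs with
#' saturating-exponential trends plus 30 age-independent noise CpGs,
#' fixed 100x coverage and Gaussian per-sample jitter (sd 0.03) on the
#' trend probability.
#'
#' @param n_samples Number of subjects.
#' @param age_min,age_max Uniform age range (years); ignored when `ages`
#'   is given.
#' @param ages Optional explicit age vector (length `n_samples`).
#' @param n_signal_sites Age-associated CpGs.
#' @param n_noise_sites Age-independent CpGs with `p ~ U(0.05, 0.95)`.
#' @param coverage Fixed per-cell read depth, or with
#'   `coverage_model = "poisson"` the Poisson mean (truncated >= 1).
#' @param coverage_model `"fixed"` or `"poisson"`.
#' @param noise_sd SD of Gaussian jitter added to the trend probability
#'   per sample x site before clipping (the per-subject biological
#'   scatter around the population trend).
#' @param overdispersion Optional beta-binomial stress test: when > 0,
#'   the effective `p` is drawn from `Beta` with mean at the trend value
#'   and this "spread" parameter `rho` (larger = more overdispersed).
#' @param seed Integer seed; the cohort is fully reproducible from the
#'   spec.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 300, age_min = 1, age_max = 90,
                        ages = NULL, n_signal_sites = 30,
                        n_noise_sites = 30, coverage = 100,
                        coverage_model = c("fixed", "poisson"),
                        noise_sd = 0.03, overdispersion = 0, seed = 1L) {
  coverage_model <- match.arg(coverage_model)
  n_samples <- assert_count(n_samples, "n_samples", 1L)
  assert_count(n_signal_sites, "n_signal_sites", 0L)
  assert_count(n_noise_sites, "n_noise_sites", 0L)
  if (n_signal_sites + n_noise_sites < 1L) {
    abort("The cohort needs at least one site.")
  }
  assert_count(coverage, "coverage", 1L)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  assert_scalar_number(overdispersion, "overdispersion", 0, 1)
  if (!is.null(ages) && length(ages) != n_samples) {
    abort("`ages` must have length n_samples.")
  }
  structure(
    list(n_samples = n_samples, age_min = age_min, age_max = age_max,
         ages = ages, n_signal_sites = as.integer(n_signal_sites),
         n_noise_sites = as.integer(n_noise_sites),
         coverage = as.integer(coverage), coverage_model = coverage_model,
         noise_sd = noise_sd, overdispersion = overdispersion,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Random realistic signal trends: saturating exponentials with baselines
# near one boundary, moving toward the middle, at rates that saturate
# over decades.
random_trends <- function(n) {
  lapply(seq_len(n), function(i) {
    dir <- sample(c(1, -1), 1)
    trend_spec(
      kind = "saturating_exp",
      m0 = if (dir == 1) runif(1, 0.05, 0.3) else runif(1, 0.7, 0.95),
      amplitude = runif(1, 0.3, 0.6),
      rate = runif(1, 0.02, 0.08),
      direction = dir
    )
  })
}

#' Generate a synthetic bisulfite cohort
#'
#' Emulates the data-generating process the estimator assumes: each
#' signal site follows its trend plus per-subject Gaussian jitter; noise
#' sites have an age-independent level drawn once per site from
#' `U(0.05, 0.95)`; observed methylated counts are
#' `Binomial(coverage, p)`. Fully reproducible from `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param trends Optional list of `trend_spec` (length
#'   `n_signal_sites`); by default saturating-exponential trends with
#'   randomised parameters are drawn under the spec seed.
#' @return A `meth_matrix` with attributes `truth` (tibble: site, kind,
#'   noise level) and `trends` (the trend list). Signal sites are named
#'   `chrS:...`, noise sites `chrN:...`.
#' @export
generate_cohort <- function(spec, trends = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    ages <- spec$ages %||% runif(spec$n_samples, spec$age_min, spec$age_max)
    trends <- trends %||% random_trends(spec$n_signal_sites)
    if (length(trends) != spec$n_signal_sites) {
      abort("`trends` must have length n_signal_sites.")
    }
    ns <- spec$n_signal_sites
    nn <- spec$n_noise_sites
    n_sites <- ns + nn
    samples <- sprintf("S%03d", seq_len(spec$n_samples))
    sites <- tibble::tibble(
      chrom = c(rep("chrN", nn), rep("chrS", ns)),
      pos = c(seq_len(nn) * 100L, seq_len(ns) * 100L)
    )
    # probability matrix sites x samples
    p <- matrix(0, n_sites, spec$n_samples)
    noise_levels <- runif(nn, 0.05, 0.95)
    for (i in seq_len(nn)) p[i, ] <- noise_levels[i]
    for (i in seq_len(ns)) p[nn + i, ] <- trend_value(trends[[i]], ages)
    if (spec$noise_sd > 0) {
      p <- p + matrix(rnorm(length(p), 0, spec$noise_sd), nrow(p))
    }
    p <- pmin(pmax(p, 0), 1)
    if (spec$overdispersion > 0) {
      # beta-binomial stress test: p* ~ Beta with mean p, ICC rho
      rho <- spec$overdispersion
      shape_tot <- (1 - rho) / rho
      a <- pmax(p * shape_tot, 1e-8)
      b <- pmax((1 - p) * shape_tot, 1e-8)
      p <- matrix(stats::rbeta(length(p), a, b), nrow(p))
    }
    cov <- if (spec$coverage_model == "fixed") {
      matrix(spec$coverage, n_sites, spec$n_samples)
    } else {
      matrix(pmax(rpois(n_sites * spec$n_samples, spec$coverage), 1L),
             n_sites)
    }
    meth <- matrix(rbinom(length(p), as.vector(cov), as.vector(p)),
                   n_sites)
    ord <- site_order(sites$chrom, sites$pos)
    m <- new_meth_matrix(
      sites = sites[ord, ], samples = samples, ages = ages,
      meth = meth[ord, , drop = FALSE],
      cov = matrix(as.integer(cov), n_sites)[ord, , drop = FALSE]
    )
    truth <- tibble::tibble(
      chrom = sites$chrom, pos = sites$pos,
      kind = c(rep("noise", nn),
               vapply(trends, function(t) t$kind, character(1))),
      level = c(noise_levels, rep(NA_real_, ns))
    )
    attr(m, "truth") <- truth[ord, ]
    attr(m, "trends") <- trends
    m
  })
}

#' Randomly downsample sequencing reads
#'
#' Thins a sample (or every sample of a matrix) to a target total read
#' count by multivariate-hypergeometric sampling without replacement from
#' the pooled per-site methylated/unmethylated read population — the
#' analogue of sequencing the same library at lower depth. Sites whose
#' coverage reaches zero become missing observations (coverage 0), never
#' methylation-fraction 0.
#'
#' @param x A tidy count table (thinned per sample) or a `meth_matrix`
#'   (thinned per sample column).
#' @param target_total_reads Reads to keep per sample; if it meets or
#'   exceeds a sample's total, that sample is returned unchanged with a
#'   warning.
#' @param seed Integer seed.
#' @return Same type as `x`.
#' @export
downsample_counts <- function(x, target_total_reads, seed = 1L) {
  assert_count(target_total_reads, "target_total_reads", 0L)
  if (inherits(x, "meth_matrix")) {
    out <- x
    for (j in seq_along(x$samples)) {
      thin <- thin_reads(x$meth[, j], x$cov[, j], target_total_reads,
                         derive_seed(seed, x$samples[j]))
      out$meth[, j] <- thin$meth
      out$cov[, j] <- thin$cov
    }
    return(out)
  }
  validate_counts(x)
  purrr::map_dfr(split(x, x$sample_id), function(df) {
    thin <- thin_reads(df$meth, df$total, target_total_reads,
                       derive_seed(seed, df$sample_id[1]))
    df$meth <- thin$meth
    df$total <- thin$cov
    df
  })
}

# Sequential-conditional multivariate hypergeometric draw over the
# 2 * n_sites read categories (methylated / unmethylated per site).
thin_reads <- function(meth, cov, target, seed) {
  total <- sum(cov)
  if (target >= total) {
    if (target > total) {
      warn(sprintf(
        "target_total_reads (%d) exceeds available reads (%d); returning input unchanged.",
        target, total
      ))
    }
    return(list(meth = meth, cov = cov))
  }
  cats <- c(meth, cov - meth)          # category sizes
  drawn <- integer(length(cats))
  withr::with_seed(seed, {
    remaining <- total
    need <- as.integer(target)
    for (i in seq_along(cats)) {
      if (need == 0L) break
      remaining <- remaining - cats[i]
      drawn[i] <- rhyper(1, cats[i], remaining, need)
      need <- need - drawn[i]
    }
  })
  k <- length(meth)
  new_meth <- drawn[seq_len(k)]
  new_cov <- new_meth + drawn[k + seq_len(k)]
  list(meth = as.integer(new_meth), cov = as.integer(new_cov))
}
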