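test_that("binomial log-pmf boundary forms, symmetry and input policing", {
  n <- c(1, 7, 30, 200)
  p <- c(0.01, 0.4, 0.97)
  for (ni in n) for (pi in p) {
    expect_equal(binomial_logpmf(0, ni, pi), ni * log(1 - pi))
    expect_equal(binomial_logpmf(ni, ni, pi), ni * log(pi))
  }
  grid <- expand.grid(x = 0:6, n = 6, p = c(0.2, 0.5, 0.77))
  expect_equal(
    binomial_logpmf(grid$x, grid$n, grid$p),
    binomial_logpmf(grid$n - grid$x, grid$n, 1 - grid$p)
  )
  # independent cross-check against the distribution in base R
  expect_equal(binomial_logpmf(grid$x, grid$n, grid$p),
               dbinom(grid$x, grid$n, grid$p, log = TRUE))
  expect_error(binomial_logpmf(1, 4, 0), "strictly inside")
  expect_error(binomial_logpmf(1, 4, 1), "strictly inside")
  expect_error(binomial_logpmf(5, 4, 0.5), "0 <= x <= n")
})

test_that("profile equals a brute-force enumerated product of site pmfs", {
  # <= 3 sites, small grid: enumerate C(n,x) p^x q^(n-x) with integer
  # factorials, take the product across sites, then log.
  ref <- monotone_reference(n_extra = 2, grid = age_grid(1, 5))
  counts <- counts_tbl("s", "chr1", c(100L, 200L, 300L),
                       c(3, 1, 4), c(6, 2, 9))
  prof <- profile_loglik(counts, ref, n_sites = 3)
  brute <- vapply(seq_along(ref$grid), function(g) {
    pr <- 1
    for (i in 1:3) {
      x <- counts$meth[i]; n <- counts$total[i]; p <- ref$probs[i, g]
      pr <- pr * (factorial(n) / (factorial(x) * factorial(n - x))) *
        p^x * (1 - p)^(n - x)
    }
    log(pr)
  }, numeric(1))
  expect_equal(prof$loglik, brute, tolerance = 1e-12)
})

test_that("a sample lying exactly on a monotone trend is mapped to its age", {
  ref <- monotone_reference(function(a) 0.1 + 0.8 * (a / 100))
  for (a_star in c(5, 40, 80)) {
    p <- 0.1 + 0.8 * a_star / 100
    counts <- counts_tbl("s", "chr1", 100L, round(p * 50), 50L)
    # n chosen so x/n lands exactly on the trend at a_star
    stopifnot(abs(counts$meth - p * 50) < 1e-9)
    prof <- profile_loglik(counts, ref, n_sites = 1)
    expect_equal(prof$mle_age, a_star)
  }
})

test_that("log-sum structure: duplicates double, constants shift, order is irrelevant", {
  ref <- monotone_reference(n_extra = 3)
  counts <- counts_tbl("s", "chr1", c(100L, 200L, 300L, 400L),
                       c(20, 10, 15, 9), c(40, 30, 30, 30))
  prof <- profile_loglik(counts, ref, n_sites = 4)
  # shuffling observation rows changes nothing
  prof_shuf <- profile_loglik(counts[c(3, 1, 4, 2), ], ref, n_sites = 4)
  expect_equal(prof$loglik, prof_shuf$loglik)
  # restricting to the single informative site, then adding flat sites,
  # shifts the profile by a constant and leaves the argmax alone
  prof1 <- profile_loglik(counts[1, ], ref, n_sites = 1)
  shift <- prof$loglik - prof1$loglik
  expect_equal(max(shift) - min(shift), 0, tolerance = 1e-9)
  expect_equal(prof$mle_age, prof1$mle_age)
  # a duplicated observation set doubles the log-likelihood
  ref1 <- monotone_reference()
  dup_ref <- ref1
  dup_ref$sites <- dplyr::bind_rows(ref1$sites,
                                    dplyr::mutate(ref1$sites, pos = 999L))
  dup_ref$probs <- rbind(ref1$probs, ref1$probs)
  dup_counts <- counts_tbl("s", "chr1", c(100L, 999L), c(20, 20), c(40, 40))
  p2 <- profile_loglik(dup_counts, dup_ref, n_sites = 2)
  p1 <- profile_loglik(dup_counts[1, ], dup_ref, n_sites = 1)
  expect_equal(p2$loglik, 2 * p1$loglik)
  expect_equal(p2$mle_age, p1$mle_age)
})

test_that("flat trends give a constant profile resolved to the youngest age", {
  ref <- monotone_reference(function(a) rep(0.4, length(a)))
  counts <- counts_tbl("s", "chr1", 100L, 12L, 30L)
  prof <- profile_loglik(counts, ref, n_sites = 1)
  expect_equal(diff(range(prof$loglik)), 0)
  expect_equal(prof$mle_age, min(ref$grid))
})

test_that("intersection precedes truncation so the site budget is met", {
  ref <- monotone_reference(n_extra = 5)  # 6 ranked sites
  # sample misses the top 2 sites but covers ranks 3..6
  counts <- counts_tbl("s", "chr1", c(300L, 400L, 500L, 600L),
                       c(5, 5, 5, 5), c(10, 10, 10, 10))
  prof <- profile_loglik(counts, ref, n_sites = 3)
  expect_equal(nrow(prof$sites), 3L)
  expect_equal(prof$sites$pos, c(300L, 400L, 500L))  # reference rank order
})

test_that("zero-coverage and disjoint samples error informatively", {
  ref <- monotone_reference()
  expect_error(
    profile_loglik(counts_tbl("s", "chr9", 1L, 0L, 5L), ref),
    "No informative sites"
  )
  expect_error(
    profile_loglik(counts_tbl("s", "chr1", 100L, 0L, 0L), ref),
    "No informative sites"
  )
})

test_that("batch prediction equals per-sample calls and survives failures", {
  ref <- monotone_reference(n_extra = 1)
  batch <- dplyr::bind_rows(
    counts_tbl("a", "chr1", c(100L, 200L), c(10, 5), c(20, 20)),
    counts_tbl("b", "chr1", 100L, 18L, 20L),
    counts_tbl("c", "chr9", 5L, 3L, 10L)   # shares no reference site
  )
  preds <- predict_age(batch, ref, n_sites = 2)
  expect_equal(nrow(preds), 3L)
  expect_equal(sum(is.na(preds$mle_age)), 1L)
  expect_match(preds$note[preds$sample_id == "c"], "No informative sites")
  single <- profile_loglik(batch[batch$sample_id == "a", ], ref, 2)
  expect_equal(preds$mle_age[preds$sample_id == "a"], single$mle_age)
})

test_that("the likelihood concentrates with coverage on model-generated data", {
  ref <- monotone_reference(function(a) 0.05 + 0.9 * (a / 100)^0.7)
  a_star <- 35
  p <- ref$probs[1, ref$grid == a_star]
  med_err <- vapply(c(10, 100, 1000), function(n) {
    set.seed(1000 + n)
    errs <- vapply(1:60, function(r) {
      counts <- counts_tbl("s", "chr1", 100L, rbinom(1, n, p), n)
      abs(profile_loglik(counts, ref, 1)$mle_age - a_star)
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) <= 0))
  expect_lte(med_err[3], 1)
})
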