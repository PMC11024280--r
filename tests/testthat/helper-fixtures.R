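# Shared fixtures: tiny call files, hand-built count tables, and a
# monotone synthetic reference with known trends.

`%||%` <- function(a, b) if (is.null(a)) b else a

site_key <- function(chrom, pos) paste0(chrom, ":", pos)

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

cgmap_fixture <- function() {
  # 3 CG lines (one with zero coverage, dropped) + 2 non-CG lines
  write_lines_tmp(c(
    "chr1\tC\t1000\tCG\tCG\t0.800000\t8\t10",
    "chr1\tC\t1500\tCHG\tCA\t0.000000\t0\t5",
    "chr2\tC\t500\tCG\tCG\t0.500000\t5\t10",
    "chr2\tC\t800\tCHH\tCT\t0.100000\t1\t10",
    "chr2\tC\t900\tCG\tCG\t0.000000\t0\t0"
  ), ".cgmap")
}

counts_tbl <- function(sample_id, chrom, pos, meth, total) {
  tibble::tibble(sample_id = sample_id, chrom = chrom, pos = pos,
                 meth = as.integer(meth), total = as.integer(total))
}

# A reference whose single-site trends are strictly monotone and known in
# closed form, built directly (no training), for identifiability tests.
monotone_reference <- function(p_fun = function(a) 0.1 + 0.8 * (a / 100),
                               n_extra = 0, grid = age_grid(),
                               eps = 1e-6) {
  n_sites <- 1 + n_extra
  probs <- matrix(NA_real_, n_sites, length(grid))
  probs[1, ] <- pmin(pmax(p_fun(grid), eps), 1 - eps)
  if (n_extra > 0) {
    for (i in seq_len(n_extra)) probs[1 + i, ] <- 0.3 + 0.002 * i
  }
  structure(
    list(
      grid = grid,
      sites = tibble::tibble(
        chrom = "chr1", pos = 100L * seq_len(n_sites),
        rho = seq(0.9, by = -0.01, length.out = n_sites),
        n_train = rep(50L, n_sites)
      ),
      probs = probs, tau = 0.7, eps = eps, trend_kind = "lowess",
      n_samples = 50L
    ),
    class = "age_reference"
  )
}

# Small trained cohort shared by several slow-ish tests (built once).
shared_cohort <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      m <<- generate_cohort(cohort_spec(
        n_samples = 80, n_signal_sites = 12, n_noise_sites = 8,
        coverage = 100, noise_sd = 0.03, seed = 424L
      ))
    }
    m
  }
})

# Brute-force LOWESS oracle: explicit per-point loop building the weight
# vector and solving the 2x2 weighted normal equations, independent of
# the package's vectorised path.
lowess_oracle <- function(x, y, tau, iters = 3) {
  n <- length(x)
  k <- ceiling(tau * n)
  rw <- rep(1, n)
  fit <- numeric(n)
  for (pass in seq_len(iters + 1)) {
    for (i in seq_len(n)) {
      d <- abs(x - x[i])
      idx <- order(d)[1:k]
      dmax <- d[idx[k]]
      w <- if (dmax > 0) (1 - pmin(d[idx] / dmax, 1)^3)^3 else rep(1, k)
      w <- w * rw[idx]
      X <- cbind(1, x[idx])
      A <- t(X) %*% (w * X)
      b <- t(X) %*% (w * y[idx])
      if (abs(det(A)) > 1e-12 * max(A)^2) {
        beta <- solve(A, b)
        fit[i] <- beta[1] + beta[2] * x[i]
      } else {
        fit[i] <- sum(w * y[idx]) / sum(w)
      }
    }
    if (pass > iters) break
    r <- y - fit
    s <- median(abs(r))
    if (s == 0) break
    rw <- pmax(1 - (r / (6 * s))^2, 0)^2
  }
  fit
}
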