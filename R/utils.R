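# Internal helpers shared across modules.

clip01 <- function(p, eps) pmin(pmax(p, eps), 1 - eps)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Scalar checks ---------------------------------------------------------

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` must lie in %s%s, %s%s (got %g).", name,
      if (open_lower) "(" else "[", format(lower),
      format(upper), if (open_upper) ")" else "]", x
    ))
  }
  invisible(x)
}

assert_count <- function(x, name, lower = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != trunc(x) || x < lower) {
    abort(sprintf("`%s` must be an integer >= %d.", name, lower))
  }
  invisible(as.integer(x))
}

# Deterministic per-sample RNG substreams -------------------------------
#
# Batch results must not depend on the order samples are processed, so each
# sample gets a seed derived from the master seed and its own id.  A small
# explicit string hash keeps this reproducible across platforms.

derive_seed <- function(master_seed, sample_id) {
  h <- 0
  for (b in utf8ToInt(as.character(sample_id))) {
    h <- (h * 31 + b) %% 2147483563
  }
  as.integer((h + as.numeric(master_seed) %% 2147483563) %% 2147483563) + 1L
}

# Tidy sample-count tables ----------------------------------------------

counts_cols <- c("sample_id", "chrom", "pos", "meth", "total")

validate_counts <- function(counts, arg = "counts") {
  if (!is.data.frame(counts)) {
    abort(sprintf("`%s` must be a data frame of per-site read counts.", arg))
  }
  missing_cols <- setdiff(counts_cols, names(counts))
  if (length(missing_cols)) {
    abort(sprintf(
      "`%s` is missing column(s): %s.", arg,
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (any(counts$meth > counts$total)) {
    abort(sprintf("`%s` has rows with methylated count > total coverage.", arg))
  }
  if (any(counts$meth < 0L) || any(counts$total < 0L)) {
    abort(sprintf("`%s` has negative read counts.", arg))
  }
  dup <- duplicated(counts[, c("sample_id", "chrom", "pos")])
  if (any(dup)) {
    abort(sprintf(
      "`%s` has duplicate (sample_id, chrom, pos) records, e.g. %s:%s in sample %s.",
      arg, counts$chrom[dup][1], counts$pos[dup][1], counts$sample_id[dup][1]
    ))
  }
  invisible(counts)
}

site_key <- function(chrom, pos) paste0(chrom, ":", pos)

# (chromosome, position) lexicographic-numeric site order
site_order <- function(chrom, pos) order(chrom, pos, method = "radix")
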