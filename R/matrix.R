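#' Assemble a cohort count matrix from per-sample call tables
#'
#' Takes the union of CpG sites across samples and keeps those where at
#' least a fraction `min_sample_fraction` of samples reach coverage
#' `min_coverage`. Cells below `min_coverage` at a surviving site keep
#' their observed counts; a site a sample never covered is stored as
#' coverage 0 (missing), never as methylation 0. Site order is
#' (chromosome, position), lexicographic in chromosome and numeric in
#' position, so the result is deterministic whatever the input order.
#'
#' @param counts Tidy count table (columns `sample_id`, `chrom`, `pos`,
#'   `meth`, `total`), e.g. several [read_cgmap()] results row-bound.
#' @param ages Data frame with columns `sample_id` and `age` (years),
#'   covering every sample in `counts`.
#' @param min_coverage Minimum reads for a cell to count as covered in the
#'   site filter (>= 1).
#' @param min_sample_fraction Minimum fraction of samples that must be
#'   covered for a site to be retained, in `[0, 1]`.
#' @return A `meth_matrix`: sites x samples methylated-count and coverage
#'   grids plus per-sample ages. See [tidy.meth_matrix()].
#' @export
aggregate_matrix <- function(counts, ages, min_coverage = 5,
                             min_sample_fraction = 0.8) {
  validate_counts(counts)
  min_coverage <- assert_count(min_coverage, "min_coverage", lower = 1L)
  assert_scalar_number(min_sample_fraction, "min_sample_fraction", 0, 1)
  if (!is.data.frame(ages) || !all(c("sample_id", "age") %in% names(ages))) {
    abort("`ages` must be a data frame with columns sample_id and age.")
  }
  samples <- sort(unique(counts$sample_id))
  missing_age <- setdiff(samples, ages$sample_id)
  if (length(missing_age)) {
    abort(sprintf(
      "No age provided for sample(s): %s.",
      paste(missing_age, collapse = ", ")
    ))
  }
  age_of <- setNames(as.numeric(ages$age), ages$sample_id)
  if (anyNA(age_of[samples]) || any(age_of[samples] < 0)) {
    abort("Ages must be non-negative numbers for every sample.")
  }

  sites <- dplyr::distinct(counts, .data$chrom, .data$pos)
  sites <- sites[site_order(sites$chrom, sites$pos), ]
  si <- match(site_key(counts$chrom, counts$pos),
              site_key(sites$chrom, sites$pos))
  sj <- match(counts$sample_id, samples)

  meth <- matrix(0L, nrow(sites), length(samples))
  cov <- matrix(0L, nrow(sites), length(samples))
  meth[cbind(si, sj)] <- as.integer(counts$meth)
  cov[cbind(si, sj)] <- as.integer(counts$total)

  covered_frac <- rowMeans(cov >= min_coverage)
  keep <- covered_frac >= min_sample_fraction
  if (!any(keep)) {
    abort(sprintf(
      paste0("Empty matrix: no site is covered >= %dx in at least %.0f%% ",
             "of samples."), min_coverage, 100 * min_sample_fraction
    ))
  }
  new_meth_matrix(
    sites = sites[keep, , drop = FALSE],
    samples = samples,
    ages = unname(age_of[samples]),
    meth = meth[keep, , drop = FALSE],
    cov = cov[keep, , drop = FALSE]
  )
}

new_meth_matrix <- function(sites, samples, ages, meth, cov) {
  stopifnot(
    nrow(meth) == nrow(sites), ncol(meth) == length(samples),
    all(dim(meth) == dim(cov)), length(ages) == length(samples),
    all(meth <= cov), all(meth >= 0L)
  )
  sites <- tibble::as_tibble(sites)
  rownames(meth) <- rownames(cov) <- site_key(sites$chrom, sites$pos)
  colnames(meth) <- colnames(cov) <- samples
  structure(
    list(sites = sites, samples = samples, ages = as.numeric(ages),
         meth = meth, cov = cov),
    class = "meth_matrix"
  )
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf(
    "<meth_matrix> %d CpG sites x %d samples (ages %.1f-%.1f yr, %.1f%% cells covered)\n",
    nrow(x$sites), length(x$samples), min(x$ages), max(x$ages),
    100 * mean(x$cov > 0)
  ))
  invisible(x)
}

#' @export
dim.meth_matrix <- function(x) c(nrow(x$sites), length(x$samples))

#' Tidy a count matrix into a long observation table
#'
#' One row per observed (coverage > 0) site x sample cell, with the
#' sample's chronological age attached. Cells with zero coverage are
#' missing observations and are not emitted.
#'
#' @param x A `meth_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `sample_id`, `chrom`, `pos`, `meth`,
#'   `total`, `age`.
#' @method tidy meth_matrix
#' @export
tidy.meth_matrix <- function(x, ...) {
  obs <- which(x$cov > 0L, arr.ind = TRUE)
  out <- tibble::tibble(
    sample_id = x$samples[obs[, 2]],
    chrom = x$sites$chrom[obs[, 1]],
    pos = x$sites$pos[obs[, 1]],
    meth = x$meth[obs],
    total = x$cov[obs],
    age = x$ages[obs[, 2]]
  )
  dplyr::arrange(out, .data$sample_id, .data$chrom, .data$pos)
}

#' Extract one or more samples' counts from a matrix
#'
#' @param x A `meth_matrix`.
#' @param sample_ids Samples to extract (default: all).
#' @return Tidy count table (no `age` column), suitable for
#'   [profile_loglik()] / [predict_age()].
#' @export
sample_counts <- function(x, sample_ids = NULL) {
  stopifnot(inherits(x, "meth_matrix"))
  sample_ids <- sample_ids %||% x$samples
  missing <- setdiff(sample_ids, x$samples)
  if (length(missing)) {
    abort(sprintf("Sample(s) not in matrix: %s.",
                  paste(missing, collapse = ", ")))
  }
  out <- tidy(x)[, counts_cols]
  out[out$sample_id %in% sample_ids, ]
}

#' Write / read a cohort count matrix as TSV
#'
#' The matrix file has a header row of sample IDs and one row per site:
#' the `chrom:pos` key followed by `meth/total` cells (`0/0` marks a
#' missing cell). Ages go to a two-column sidecar TSV. The round trip is
#' lossless for counts, ages and site keys. Both files may be gzipped.
#'
#' @param x A `meth_matrix`.
#' @param path Matrix TSV path.
#' @param ages_path Sidecar ages TSV path; defaults to `path` with an
#'   `.ages.tsv` suffix appended.
#' @return `write_matrix()` returns `path` invisibly; `read_matrix()`
#'   returns a `meth_matrix`.
#' @export
write_matrix <- function(x, path, ages_path = paste0(path, ".ages.tsv")) {
  stopifnot(inherits(x, "meth_matrix"))
  cells <- matrix(paste0(x$meth, "/", x$cov), nrow = nrow(x$meth))
  header <- paste(c("site", x$samples), collapse = "\t")
  rows <- paste(site_key(x$sites$chrom, x$sites$pos),
                apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  readr::write_lines(c(header, rows), path)
  readr::write_lines(
    c("sample_id\tage", paste(x$samples, format(x$ages, digits = 15),
                              sep = "\t")),
    ages_path
  )
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path, ages_path = paste0(path, ".ages.tsv")) {
  lines <- readr::read_lines(path)
  if (length(lines) < 2L) abort(sprintf("%s: no site rows found.", path))
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  samples <- header[-1]
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  if (any(lengths(body) != length(header))) {
    abort(sprintf("%s: ragged rows do not match the header.", path))
  }
  keys <- vapply(body, `[[`, character(1), 1)
  chrom <- sub(":[0-9]+$", "", keys)
  pos <- as.integer(sub("^.*:", "", keys))
  cells <- t(vapply(body, function(r) r[-1], character(length(samples))))
  if (length(samples) == 1L) cells <- matrix(cells, ncol = 1L)
  meth <- matrix(as.integer(sub("/.*$", "", cells)), nrow = length(keys))
  cov <- matrix(as.integer(sub("^.*/", "", cells)), nrow = length(keys))
  if (anyNA(meth) || anyNA(cov)) {
    abort(sprintf("%s: malformed meth/total cell.", path))
  }
  ages_df <- readr::read_tsv(ages_path, col_types = readr::cols(
    sample_id = readr::col_character(), age = readr::col_double()
  ))
  age_of <- setNames(ages_df$age, ages_df$sample_id)
  if (anyNA(age_of[samples])) {
    abort(sprintf("%s: missing age for some samples.", ages_path))
  }
  new_meth_matrix(
    sites = tibble::tibble(chrom = chrom, pos = pos),
    samples = samples, ages = unname(age_of[samples]),
    meth = meth, cov = cov
  )
}
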