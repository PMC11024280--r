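#' Read a CGmap methylation call file
#'
#' Parses a tab-separated CGmap file (BSBolt dialect) into a tidy per-site
#' count table. CGmap columns are: chromosome, observed nucleotide (C/G),
#' 1-based position of the cytosine, context (CG/CHG/CHH), dinucleotide
#' context, methylation fraction, methylated-read count, total-read count.
#' Only CpG-context records are retained; the methylation-fraction column is
#' ignored because the read counts are authoritative. Records with zero
#' total coverage are dropped. Gzipped files are read transparently.
#'
#' @param path Path to a CGmap file (optionally gzipped).
#' @param sample_id Sample identifier for the returned rows; defaults to the
#'   file name stripped of `.cgmap`/`.tsv`/`.txt`/`.gz` extensions.
#' @return A tibble with columns `sample_id`, `chrom`, `pos`, `meth`
#'   (methylated/cytosine read count), `total` (all reads covering the
#'   site), one row per retained CpG, and attribute `source_path`.
#' @seealso [read_bismark_cov()], [aggregate_matrix()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".cgmap")
#' writeLines(c("chr1\tC\t1000\tCG\tCG\t0.8\t8\t10",
#'              "chr1\tC\t1200\tCHH\tCA\t0.0\t0\t5"), f)
#' read_cgmap(f)
read_cgmap <- function(path, sample_id = NULL) {
  fields <- read_call_file(path, n_cols = 8L)
  ctx <- fields[[4]]
  keep <- ctx == "CG"
  meth <- parse_count_col(fields[[7]], "methylated-read count", path, keep)
  total <- parse_count_col(fields[[8]], "total-read count", path, keep)
  bad <- which(keep & meth > total)
  if (length(bad)) {
    abort(sprintf(
      "%s line %d: methylated count (%d) exceeds total coverage (%d).",
      path, bad[1], meth[bad[1]], total[bad[1]]
    ))
  }
  keep <- keep & total > 0L
  if (!any(keep)) {
    abort(sprintf("%s: no CpG records with coverage after filtering.", path))
  }
  pos <- parse_count_col(fields[[3]], "position", path, keep)
  out <- tibble::tibble(
    sample_id = sample_id %||% strip_ext(path),
    chrom = fields[[1]][keep],
    pos = pos[keep],
    meth = meth[keep],
    total = total[keep]
  )
  validate_counts(out)
  attr(out, "source_path") <- path
  out
}

#' Read a Bismark coverage file
#'
#' Parses the six-column Bismark coverage format: chromosome, start, end,
#' methylation percent, methylated-read count, unmethylated-read count.
#' Total coverage is the sum of the two count columns; the percent column
#' is ignored. The start column is taken as the 1-based cytosine position.
#'
#' @inheritParams read_cgmap
#' @return A tibble in the same shape as [read_cgmap()].
#' @export
read_bismark_cov <- function(path, sample_id = NULL) {
  fields <- read_call_file(path, n_cols = 6L)
  all_keep <- rep(TRUE, length(fields[[1]]))
  meth <- parse_count_col(fields[[5]], "methylated-read count", path, all_keep)
  unmeth <- parse_count_col(fields[[6]], "unmethylated-read count", path, all_keep)
  pos <- parse_count_col(fields[[2]], "start position", path, all_keep)
  total <- meth + unmeth
  keep <- total > 0L
  if (!any(keep)) {
    abort(sprintf("%s: no CpG records with coverage after filtering.", path))
  }
  out <- tibble::tibble(
    sample_id = sample_id %||% strip_ext(path),
    chrom = fields[[1]][keep],
    pos = pos[keep],
    meth = meth[keep],
    total = total[keep]
  )
  validate_counts(out)
  attr(out, "source_path") <- path
  out
}

#' Write per-sample methylation calls to CGmap or Bismark coverage files
#'
#' Serialises a tidy count table (one or more samples) to one file per
#' sample. CGmap output recomputes the fraction column as `meth/total`
#' rounded to 6 decimals; rows with `total == 0` are not written (a site
#' with no reads is simply absent from a call file).
#'
#' @param counts A data frame with columns `sample_id`, `chrom`, `pos`,
#'   `meth`, `total`.
#' @param dir Output directory (created if needed).
#' @param format `"cgmap"` or `"bismark"`.
#' @param gzip Compress the output files.
#' @return Invisibly, a named character vector of written paths.
#' @export
write_call_files <- function(counts, dir, format = c("cgmap", "bismark"),
                             gzip = FALSE) {
  format <- match.arg(format)
  validate_counts(counts)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- paste0(if (format == "cgmap") ".cgmap" else ".cov",
                if (gzip) ".gz" else "")
  paths <- vapply(split(counts, counts$sample_id), function(df) {
    df <- df[df$total > 0L, ]
    df <- df[site_order(df$chrom, df$pos), ]
    path <- file.path(dir, paste0(df$sample_id[1], ext))
    lines <- if (format == "cgmap") {
      paste(df$chrom, "C", df$pos, "CG", "CG",
            sprintf("%.6f", df$meth / df$total), df$meth, df$total,
            sep = "\t")
    } else {
      paste(df$chrom, df$pos, df$pos,
            sprintf("%.6f", 100 * df$meth / df$total),
            df$meth, df$total - df$meth, sep = "\t")
    }
    con <- if (gzip) gzfile(path, "w") else file(path, "w")
    writeLines(lines, con)
    close(con)
    path
  }, character(1))
  invisible(paths)
}

# -- internal parsing helpers -------------------------------------------

strip_ext <- function(path) {
  sub("\\.(cgmap|cov|tsv|txt)?(\\.gz)?$", "", basename(path))
}

# Split a call file into columns, enforcing a uniform column count and
# reporting 1-based line numbers on malformed input.
read_call_file <- function(path, n_cols) {
  if (!file.exists(path)) {
    abort(sprintf("Cannot read '%s': no such file.", path))
  }
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    abort(sprintf("%s: file is empty (I/O produced no records).", path))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != n_cols)
  if (length(bad)) {
    abort(sprintf(
      "%s line %d: expected %d tab-separated fields, found %d.",
      path, bad[1], n_cols, nf[bad[1]]
    ))
  }
  lapply(seq_len(n_cols), function(j) {
    vapply(parts, `[[`, character(1), j)
  })
}

parse_count_col <- function(x, what, path, relevant) {
  bad <- which(relevant & !grepl("^[0-9]+$", x))
  if (length(bad)) {
    abort(sprintf(
      "%s line %d: %s '%s' is not a non-negative integer.",
      path, bad[1], what, x[bad[1]]
    ))
  }
  out <- rep(NA_integer_, length(x))
  out[relevant] <- as.integer(x[relevant])
  out
}
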