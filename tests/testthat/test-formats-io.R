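test_that("CGmap parsing maps fields, filters non-CpG context and zero coverage", {
  counts <- read_cgmap(cgmap_fixture(), sample_id = "s1")
  # 3 CG lines in the file, one with total 0 -> 2 observations survive
  expect_equal(nrow(counts), 2L)
  expect_equal(counts$chrom, c("chr1", "chr2"))
  expect_equal(counts$pos, c(1000L, 500L))
  expect_equal(counts$meth, c(8L, 5L))
  expect_equal(counts$total, c(10L, 10L))
  expect_true(all(counts$sample_id == "s1"))
})

test_that("CGmap reader rejects malformed input with the offending line number", {
  short <- write_lines_tmp(c("chr1\tC\t1000\tCG\tCG\t0.8\t8\t10",
                             "chr1\tC\t2000\tCG\tCG"), ".cgmap")
  expect_error(read_cgmap(short), "line 2.*expected 8")
  noninteger <- write_lines_tmp("chr1\tC\t1000\tCG\tCG\t0.8\tx\t10", ".cgmap")
  expect_error(read_cgmap(noninteger), "line 1.*not a non-negative integer")
  inverted <- write_lines_tmp("chr1\tC\t1000\tCG\tCG\t0.8\t12\t10", ".cgmap")
  expect_error(read_cgmap(inverted), "line 1.*exceeds total")
  onlychh <- write_lines_tmp("chr1\tC\t1000\tCHH\tCA\t0.8\t8\t10", ".cgmap")
  expect_error(read_cgmap(onlychh), "no CpG records")
  expect_error(read_cgmap(tempfile()), "no such file")
})

test_that("Bismark coverage parsing sums count columns and keeps start as position", {
  cov <- write_lines_tmp(c(
    "chr2\t500\t500\t50.0\t5\t5",
    "chr2\t501\t501\t0.0\t0\t7",
    "chr1\t900\t900\t100.0\t4\t0",
    "chr3\t10\t10\t25.0\t1\t3"
  ), ".cov")
  counts <- read_bismark_cov(cov, sample_id = "b1")
  expect_equal(nrow(counts), 4L)
  expect_equal(counts$pos[1], 500L)
  expect_equal(counts$meth, c(5L, 0L, 4L, 1L))
  expect_equal(counts$total, c(10L, 7L, 4L, 4L))
})

test_that("the same calls expressed in the two formats parse identically", {
  counts <- read_cgmap(cgmap_fixture(), sample_id = "s")
  dir <- tempfile()
  write_call_files(counts, dir, format = "bismark")
  via_bismark <- read_bismark_cov(file.path(dir, "s.cov"), sample_id = "s")
  expect_equal(
    as.data.frame(dplyr::arrange(counts, chrom, pos)),
    as.data.frame(via_bismark),
    ignore_attr = TRUE
  )
})

test_that("CGmap round trip reproduces counts and the x/n fraction column", {
  counts <- read_cgmap(cgmap_fixture(), sample_id = "s")
  dir <- tempfile()
  path <- write_call_files(counts, dir, format = "cgmap", gzip = TRUE)
  again <- read_cgmap(path[["s"]], sample_id = "s")
  expect_equal(as.data.frame(dplyr::arrange(counts, chrom, pos)),
               as.data.frame(again), ignore_attr = TRUE)
  # fraction column is x/n to 6 decimals
  line1 <- strsplit(readr::read_lines(path[["s"]])[1], "\t")[[1]]
  expect_equal(as.numeric(line1[6]),
               round(as.integer(line1[7]) / as.integer(line1[8]), 6))
})

test_that("matrix aggregation applies the coverage/sample-fraction site filter", {
  # 4 samples x 6 sites with a designed coverage pattern at min_coverage 5:
  #   siteA covered in 4/4, siteB 3/4, siteC 2/4, siteD 1/4, siteE 0/4
  #   (always present but below threshold), siteF 4/4.
  cov_pattern <- list(
    A = c(10, 10, 10, 10), B = c(10, 10, 10, 2), C = c(5, 5, 0, 0),
    D = c(9, 0, 0, 0), E = c(4, 4, 4, 4), F = c(5, 5, 5, 5)
  )
  counts <- purrr::imap_dfr(cov_pattern, function(cv, site) {
    keep <- cv > 0
    counts_tbl(paste0("s", 1:4)[keep], "chr1",
               match(site, names(cov_pattern)) * 10L,
               floor(cv / 2)[keep], cv[keep])
  })
  ages <- tibble::tibble(sample_id = paste0("s", 1:4), age = c(10, 20, 30, 40))

  m75 <- aggregate_matrix(counts, ages, min_coverage = 5,
                          min_sample_fraction = 0.75)
  expect_equal(rownames(m75$meth), c("chr1:10", "chr1:20", "chr1:60"))
  # cells below min_coverage at surviving sites keep observed counts
  expect_equal(m75$cov["chr1:20", "s4"], 2)

  m_all <- aggregate_matrix(counts, ages, min_coverage = 5,
                            min_sample_fraction = 0)
  expect_equal(nrow(m_all$sites), 6L)
  expect_error(
    aggregate_matrix(counts, ages, min_coverage = 11,
                     min_sample_fraction = 0.5),
    "Empty matrix"
  )
  expect_error(
    aggregate_matrix(counts, ages[1:3, ], min_coverage = 5,
                     min_sample_fraction = 0),
    "s4"
  )
})

test_that("aggregation is deterministic in site order and never exceeds coverage", {
  m <- shared_cohort()
  counts <- tidy(m)[, c("sample_id", "chrom", "pos", "meth", "total")]
  ages <- tibble::tibble(sample_id = m$samples, age = m$ages)
  shuffled <- counts[sample(nrow(counts)), ]
  a1 <- aggregate_matrix(counts, ages, 1, 0)
  a2 <- aggregate_matrix(shuffled, ages, 1, 0)
  expect_identical(rownames(a1$meth), rownames(a2$meth))
  expect_identical(a1$meth, a2$meth)
  expect_true(all(a1$meth <= a1$cov))
})

test_that("count-matrix TSV round trip is lossless including missing cells", {
  counts <- counts_tbl(
    rep(c("s1", "s2"), each = 2),
    rep("chr1", 4), c(10L, 20L, 10L, 30L), c(3, 0, 5, 2), c(9, 4, 9, 2)
  )
  ages <- tibble::tibble(sample_id = c("s1", "s2"), age = c(31.5, 62))
  m <- aggregate_matrix(counts, ages, min_coverage = 1,
                        min_sample_fraction = 0)
  path <- tempfile(fileext = ".tsv")
  write_matrix(m, path)
  m2 <- read_matrix(path)
  expect_identical(unname(m$meth), unname(m2$meth))
  expect_identical(unname(m$cov), unname(m2$cov))
  expect_equal(m$ages, m2$ages)
  expect_equal(m$sites, m2$sites)
  # a missing cell stays coverage 0, not methylation-fraction 0
  expect_equal(m2$cov["chr1:20", "s2"], 0)
  expect_equal(m2$cov["chr1:30", "s1"], 0)
})

test_that("hand-written 2x2 matrix TSV parses to the expected counts", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("site\ta\tb", "chr1:5\t3/10\t0/0", "chr2:7\t1/2\t9/9"), path)
  writeLines(c("sample_id\tage", "a\t40", "b\t70"),
             paste0(path, ".ages.tsv"))
  m <- read_matrix(path)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m$meth["chr1:5", "a"], 3)
  expect_equal(m$cov["chr1:5", "b"], 0)
  expect_equal(m$ages, c(40, 70))
})
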