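test_that("bedGraph dialect parses counts and intervals", {
  f <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines("chr1\t100\t102\t50.00\t5\t5", f)
  ct <- read_coverage(c(sampleA = f), dialect = "bedgraph_panel")
  expect_equal(site_ids(ct), "chr1-100-102")
  expect_equal(unname(ct$meth[1, 1]), 5L)
  expect_equal(unname(ct$total[1, 1]), 10L)
})

test_that("empty files give empty tables and malformed lines error", {
  f <- withr::local_tempfile(fileext = ".bedgraph")
  file.create(f)
  ct <- read_coverage(c(s1 = f), dialect = "bedgraph_panel")
  expect_equal(nrow(ct$sites), 0)

  bad <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines("chr1\t100\t102\t50.00\t12\t-20", bad)
  expect_error(read_coverage(c(s1 = bad), dialect = "bedgraph_panel"),
               "malformed")
})

test_that("bedMethyl strands collapse onto the forward CpG and counts sum", {
  f <- withr::local_tempfile(fileext = ".bedmethyl")
  writeLines(c(
    "chr1\t100\t102\tm\t8\t+\t100\t102\t255,0,0\t8\t75.00\t6\t2",
    "chr1\t101\t103\tm\t4\t-\t101\t103\t255,0,0\t4\t50.00\t2\t2",
    "chr1\t200\t202\tm\t10\t+\t200\t202\t255,0,0\t10\t10.00\t1\t9"),
    f)
  ct <- read_coverage(c(s1 = f), dialect = "bedmethyl_long_read")
  expect_equal(site_ids(ct), c("chr1-100-102", "chr1-200-202"))
  expect_equal(unname(ct$meth[, 1]), c(6L + 2L, 1L))
  expect_equal(unname(ct$total[, 1]), c(8L + 4L, 10L))
})

test_that("write -> read round trip preserves counts; canonical files are byte-stable", {
  sim <- simulate_coverage(4, 30, mean_depth = 20, seed = 5)
  for (dialect in c("bedgraph_panel", "bedmethyl_long_read")) {
    d1 <- withr::local_tempdir()
    paths <- write_coverage(sim$coverage, d1, dialect = dialect)
    back <- read_coverage(paths, dialect = dialect)
    expect_equal(back$meth, sim$coverage$meth, ignore_attr = TRUE)
    expect_equal(back$total, sim$coverage$total, ignore_attr = TRUE)
    ## canonical round trip is byte-identical
    d2 <- withr::local_tempdir()
    paths2 <- write_coverage(back, d2, dialect = dialect)
    for (s in seq_along(paths)) {
      expect_identical(readLines(paths2[s]), readLines(paths[s]))
    }
  }
})

## A fully hand-enumerable 5-site x 46-sample toy. Sites (rows):
##   s1: depth 20 everywhere             -> survives everything
##   s2: depth 1 everywhere              -> all entries masked at step 1
##   s3: depth 20 but only in 39 samples (0 elsewhere; masked) -> fails step 4
##   s4: depth 500 everywhere            -> removed as high coverage (step 2)
##   s5: depth 20 everywhere, inside the SNP mask -> removed at step 3
toy_coverage <- function() {
  n <- 46
  total <- rbind(rep(20L, n),
                 rep(1L, n),
                 c(rep(20L, 39), rep(0L, n - 39)),
                 rep(500L, n),
                 rep(20L, n))
  meth <- matrix(10L, 5, n)
  meth <- pmin(meth, total)
  sites <- data.frame(chrom = "chr1",
                      start = c(100L, 200L, 300L, 400L, 500L),
                      end = c(102L, 202L, 302L, 402L, 502L))
  coverage_table(sites, meth, total, sprintf("s%02d", 1:n),
                 platform = "short_read_panel")
}

test_that("filter audit matches hand enumeration on the 46-sample toy", {
  ct <- toy_coverage()
  mask <- data.frame(chrom = "chr1", start = 500L, end = 501L)
  res <- apply_filters(ct, filter_policy(min_doc = 2,
                                         high_coverage_quantile = 0.99,
                                         snp_mask = mask,
                                         min_samples = 40,
                                         min_reads_platform = 10))
  ## step 1: s2 fully masked and removed           (1 removed, 4 left)
  ## step 2: mean DoCs {20, ~20(39 obs), 500, 20}; 0.99 quantile of the 4
  ##         values < 500 only for s4              (1 removed, 3 left)
  ## step 3: SNP mask hits s5                      (1 removed, 2 left)
  ## step 4: s3 has 39 < 40 well-covered samples   (1 removed, 1 left)
  expect_equal(res$audit$sites_removed, c(1L, 1L, 1L, 1L))
  expect_equal(res$audit$sites_remaining, c(4L, 3L, 2L, 1L))
  expect_equal(site_ids(res$coverage), "chr1-100-102")
  ## conservation: removals + survivors = input count
  expect_equal(sum(res$audit$sites_removed) +
                 nrow(res$coverage$sites), 5L)
})

test_that("snp mask covering all sites removes everything at step 3", {
  ct <- toy_coverage()
  mask <- data.frame(chrom = "chr1", start = 0L, end = 1000L)
  res <- apply_filters(ct, filter_policy(snp_mask = mask, min_samples = 40))
  step3 <- res$audit[res$audit$step == "snp_mask", ]
  expect_equal(step3$sites_remaining, 0L)
  expect_equal(nrow(res$coverage$sites), 0L)
})

test_that("constant coverage: ties at the quantile survive (documented rule)", {
  n <- 46
  total <- matrix(20L, 10, n)
  meth <- matrix(5L, 10, n)
  sites <- data.frame(chrom = "chr1", start = seq(100L, 1000L, by = 100L))
  sites$end <- sites$start + 2L
  ct <- coverage_table(sites, meth, total, sprintf("s%02d", 1:n))
  res <- apply_filters(ct, filter_policy(min_samples = 40))
  expect_equal(res$audit$sites_removed, rep(0L, 4))
  expect_equal(nrow(res$coverage$sites), 10L)
})

test_that("survivor count is monotone in min_samples and min_reads", {
  sim <- simulate_coverage(46, 150, mean_depth = 12, seed = 31)
  surv <- function(ms, mr) {
    nrow(apply_filters(sim$coverage,
                       filter_policy(min_samples = ms,
                                     min_reads_platform = mr))$coverage$sites)
  }
  for (mr in c(5, 10)) {
    s <- vapply(c(10, 20, 30, 40), surv, numeric(1), mr = mr)
    expect_true(all(diff(s) <= 0))
  }
  for (ms in c(10, 30)) {
    s <- vapply(c(2, 5, 10, 15), function(mr) surv(ms, mr), numeric(1))
    expect_true(all(diff(s) <= 0))
  }
})

test_that("policy validation and fraction computation", {
  sim <- simulate_coverage(10, 20, mean_depth = 10, seed = 3)
  expect_error(apply_filters(sim$coverage, filter_policy(min_samples = 40)),
               "exceeds sample count")

  sites <- data.frame(chrom = "chr1", start = c(10L, 20L), end = c(12L, 22L))
  ct <- coverage_table(sites,
                       meth = matrix(c(5L, 0L, 10L, NA), 2, 2),
                       total = matrix(c(10L, 7L, 10L, NA), 2, 2),
                       samples = c("a", "b"))
  fr <- methylation_fraction(ct)
  expect_equal(fr["a", ], c(`chr1-10-12` = 0.5, `chr1-20-22` = 0))
  expect_equal(unname(fr["b", 1]), 1)
  expect_true(is.na(fr["b", 2]))
  expect_error(coverage_table(sites, matrix(5L, 2, 2), matrix(4L, 2, 2),
                              c("a", "b")),
               "methylated")
})
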