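# Text and SAM ingestion, coverage filtering, bedGraph export.

test_that("text reader parses the example table and derives counts", {
  m <- read_methylation_text(example_calls_path())
  d <- as.data.frame(m)
  expect_equal(nrow(d), 6L)
  # strand letters F/R map to +/-
  expect_setequal(unique(d$strand), c("-", "+"))
  r <- d[d$start == 9849022, ]
  expect_equal(r$chrom, "chr21")
  expect_equal(r$strand, "+")
  expect_equal(r$n_meth, 90L)
  expect_equal(r$n_unmeth, 34L)
  # counts always reproduce the parsed coverage column exactly
  raw <- read.delim(example_calls_path())
  raw <- raw[order(raw$chr, raw$base), ]
  expect_identical(unname(unit_coverage(m)), as.integer(raw$coverage))
  # and percent methylation reproduces freqC/freqT to two decimals
  pct <- percent_methylation(d$n_meth, d$n_unmeth)
  expect_equal(pct, raw$freqC, tolerance = 1e-12)
  expect_equal(round(100 - pct, 2), raw$freqT, tolerance = 1e-12)
})

test_that("text reader validates structure and frequencies", {
  hdr <- "chrBase\tchr\tbase\tstrand\tcoverage\tfreqC\tfreqT"
  f <- withr::local_tempfile(fileext = ".txt")

  writeLines(hdr, f)
  m <- read_methylation_text(f)
  expect_s3_class(m, "methylome")
  expect_equal(n_units(m), 0L)

  writeLines(c(hdr, "chr1.5\tchr1\t5\tF\t10\t60\t50"), f)
  expect_error(read_methylation_text(f), "freqC \\+ freqT")

  writeLines(c(hdr, "chr1.5\tchr1\t5\tF\t10\t50"), f)
  expect_error(read_methylation_text(f), "line 2")

  writeLines(c(hdr, "chr1.5\tchr1\t5\tF\t10\t50\t50",
               "chr1.5\tchr1\t5\tF\t12\t25\t75"), f)
  expect_error(read_methylation_text(f), "duplicate")

  writeLines(c(hdr, "chr1.5\tchr1\t5\tQ\t10\t50\t50"), f)
  expect_error(read_methylation_text(f), "strand")
})

test_that("text dialect round-trips coverage and frequencies", {
  sim <- simulate_methylomes(sim_spec(n_sites = 200, seed = 11))
  m <- sim$samples[[1]]
  f <- withr::local_tempfile(fileext = ".txt")
  write_methylation_text(m, f)
  m2 <- read_methylation_text(f, sample_id = m$sample_id)
  expect_identical(unit_coverage(m2), unit_coverage(m))
  p1 <- percent_methylation(m$data$n_meth, m$data$n_unmeth)
  p2 <- percent_methylation(m2$data$n_meth, m2$data$n_unmeth)
  expect_true(max(abs(p1 - p2)) <= 0.01)
})

test_that("SAM reader applies quality and coverage filters", {
  sam <- withr::local_tempfile(fileext = ".sam")
  sites <- data.frame(
    chrom = "chr1",
    pos = c(100L, 250L, 400L),
    strand = c("+", "-", "+"),
    n_meth = c(3L, 5L, 4L),
    n_unmeth = c(9L, 7L, 5L),       # site 3: coverage 9 < 10 -> dropped
    n_meth_lowq = c(0L, 1L, 0L))    # one quality-19 call -> excluded
  res <- simulate_sam(sam, sites, low_quality = 19L)
  m <- read_bismark_sam(sam, filter_policy(10L, 20L))
  d <- as.data.frame(m)
  expect_equal(nrow(d), 2L)                 # coverage-9 site absent
  expect_equal(d$start, c(100L, 250L))
  expect_equal(d$n_meth, c(3L, 5L))
  expect_equal(d$n_unmeth, c(9L, 7L))       # low-quality call not counted
  expect_equal(d$strand, c("+", "-"))
  expect_equal(percent_methylation(d$n_meth[1], d$n_unmeth[1]), 25)
})

test_that("SAM reader is invariant to read order and skips unmapped", {
  sam <- withr::local_tempfile(fileext = ".sam")
  sites <- data.frame(chrom = c("chr1", "chr2"), pos = c(50L, 80L),
                      strand = "+", n_meth = c(6L, 12L),
                      n_unmeth = c(6L, 2L))
  simulate_sam(sam, sites, n_unmapped = 2L)
  expect_message(m1 <- read_bismark_sam(sam), "unmapped")

  lines <- readLines(sam)
  is_hdr <- startsWith(lines, "@")
  set.seed(99)
  shuffled <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(lines[is_hdr], sample(lines[!is_hdr])), shuffled)
  m2 <- suppressMessages(read_bismark_sam(shuffled))
  expect_identical(m1$data, m2$data)
})

test_that("coverage filter drops low and clips high coverage", {
  m <- mk_methylome(c(10L, 20L, 30L), c(4L, 5L, 60L), c(5L, 5L, 64L))
  f <- filter_by_coverage(m, filter_policy(min_coverage = 10))
  expect_equal(unname(unit_coverage(f)), c(10L, 124L))

  e <- filter_by_coverage(mk_methylome(integer(0), integer(0),
                                       integer(0)))
  expect_equal(n_units(e), 0L)

  # upper percentile cut equals a brute-force filter
  sim <- simulate_methylomes(sim_spec(n_sites = 1000, seed = 5,
                                      clonal_fraction = 0.01))
  m <- sim$samples[[1]]
  pol <- filter_policy(min_coverage = 1, high_coverage_percentile = 99.9)
  got <- filter_by_coverage(m, pol)
  cut <- quantile(unit_coverage(m), 0.999, names = FALSE)
  expected <- m$data[unit_coverage(m) <= cut, ]
  rownames(expected) <- NULL
  expect_identical(got$data, expected)

  # idempotence of the coverage floor
  p10 <- filter_policy(min_coverage = 10)
  once <- filter_by_coverage(m, p10)
  expect_identical(filter_by_coverage(once, p10)$data, once$data)
})

test_that("bedGraph export uses 0-based half-open coordinates", {
  d <- data.frame(chrom = c("chr21", "chr1"), start = c(9849022L, 500L),
                  end = c(9849022L, 500L), strand = "+",
                  pvalue = c(1e-8, 1e-8), qvalue = c(1e-6, 1e-6),
                  meth.diff = c(30, -41.5))
  f <- withr::local_tempfile(fileext = ".bedgraph")

  write_bedgraph(d, f, track = "hyper")
  lines <- readLines(f)
  expect_match(lines[1], "^track type=bedGraph")
  expect_equal(lines[-1], "chr21 9849021 9849022 30")

  write_bedgraph(d, f, track = "hypo")
  expect_equal(readLines(f)[-1], "chr1 499 500 -41.5")

  # empty table and empty sign class: header only
  write_bedgraph(d[0, ], f, track = "all")
  expect_length(readLines(f), 1L)
  write_bedgraph(d[d$meth.diff > 0, ], f, track = "hypo")
  expect_length(readLines(f), 1L)
})
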