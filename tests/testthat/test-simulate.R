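test_that("make_itd_allele duplicates the segment head-to-tail", {
  ref <- load_reference("AAACCCGGG")
  expect_equal(make_itd_allele(ref, itd_spec(3, 3)), "AAACCCCCCGGG")
  expect_error(itd_spec(3, 0))
  expect_error(make_itd_allele(ref, itd_spec(7, 5)), "beyond")

  big <- synthetic_reference()
  for (L in c(6L, 21L, 126L, 244L)) {
    allele <- make_itd_allele(big, itd_spec(100, L))
    expect_equal(nchar(allele), 600L + L)
    # both copies present back to back
    seg <- substr(big$sequence, 101, 100 + L)
    expect_equal(substr(allele, 101, 100 + 2 * L), paste0(seg, seg))
  }
})

test_that("injected point changes land only in the second copy", {
  ref <- synthetic_reference()
  allele <- make_itd_allele(ref, itd_spec(100, 30, extra_mismatches = 2))
  expect_equal(substr(allele, 1, 130), substr(ref$sequence, 1, 130))
  second <- substr(allele, 131, 160)
  seg <- substr(ref$sequence, 101, 130)
  diff <- sum(strsplit(second, "")[[1L]] != strsplit(seg, "")[[1L]])
  expect_equal(diff, 2L)
  expect_equal(substr(allele, 161, 630), substr(ref$sequence, 131, 600))
})

test_that("count-exact mixtures emit exactly the requested counts", {
  ref <- synthetic_reference()
  reads <- simulate_reads(ref, list(itd_spec(300, 21), "WT"),
                          counts = c(67L, 33L))
  expect_equal(nrow(reads), 100L)
  truth <- sim_truth(reads)
  expect_equal(truth$n_reads, c(67L, 33L))
  expect_equal(truth$fraction, c(0.67, 0.33))
  # error-free single-end reads from one allele are identical
  expect_equal(length(unique(reads$bases)), 2L)

  wt <- simulate_reads(ref, list("WT"), counts = 100L)
  expect_equal(length(unique(wt$bases)), 1L)
  o <- (600 - 250) %/% 2
  expect_equal(wt$bases[1L], substr(ref$sequence, o + 1, o + 250))
})

test_that("identical seeds give identical reads and FASTQ bytes", {
  ref <- synthetic_reference()
  mk <- function() {
    simulate_reads(ref, list(itd_spec(300, 21), "WT"),
                   fractions = c(0.4, 0.6), total_reads = 500L,
                   error_rate = 0.005, seed = 77L)
  }
  r1 <- mk()
  r2 <- mk()
  expect_identical(r1$bases, r2$bases)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(r1, f1)
  write_fastq(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # and a different seed changes the reads
  r3 <- simulate_reads(ref, list(itd_spec(300, 21), "WT"),
                       fractions = c(0.4, 0.6), total_reads = 500L,
                       error_rate = 0.005, seed = 78L)
  expect_false(identical(r1$bases, r3$bases))
})

test_that("paired mode reads both allele ends in opposite orientation", {
  ref <- synthetic_reference()
  reads <- simulate_reads(ref, list("WT"), counts = 3L, paired = TRUE)
  expect_equal(nrow(reads), 6L)
  expect_equal(sort(unique(reads$mate)), c(1L, 2L))
  m1 <- reads$bases[reads$mate == 1L][1L]
  m2 <- reads$bases[reads$mate == 2L][1L]
  expect_equal(m1, substr(ref$sequence, 1, 250))
  expect_equal(reverse_complement(m2), substr(ref$sequence, 351, 600))
})

test_that("dilution series follows the expected VAF ladder", {
  ref <- synthetic_reference()
  dil <- simulate_dilution_series(ref, itd_spec(300, 21), start_vaf = 0.67,
                                  dilution_factor = 10, n_steps = 5,
                                  reads_per_step = 100000L, seed = 5L,
                                  count_exact = TRUE)
  expect_equal(dil$truth$expected_vaf,
               0.67 / 10^(0:4))
  expect_equal(length(dil$samples), 5L)
  # count-exact construction matches the rounded expectation
  expect_equal(dil$truth$constructed_vaf,
               round(0.67 / 10^(0:4) * 1e5) / 1e5)

  flat <- simulate_dilution_series(ref, itd_spec(300, 21), start_vaf = 0.5,
                                   dilution_factor = 1, n_steps = 3,
                                   reads_per_step = 100L, seed = 5L,
                                   count_exact = TRUE)
  expect_equal(flat$truth$expected_vaf, rep(0.5, 3))
  expect_warning(
    simulate_dilution_series(ref, itd_spec(300, 21), start_vaf = 0.1,
                             dilution_factor = 10, n_steps = 4,
                             reads_per_step = 100L, seed = 5L,
                             count_exact = TRUE),
    "below one read"
  )
})

test_that("linearity R^2 matches direct computation", {
  exact <- linearity_r2(c(0.1, 0.2, 0.4), c(0.1, 0.2, 0.4))
  expect_equal(exact$r_squared, 1)
  scaled <- linearity_r2(c(0.1, 0.2, 0.4), 2 * c(0.1, 0.2, 0.4))
  expect_equal(scaled$r_squared, 1)
  expect_equal(scaled$slope, 2)

  set.seed(91)
  x <- c(0.67, 0.067, 0.0067, 6.7e-4)
  y <- x * (1 + rnorm(4, sd = 0.02))
  fit <- linearity_r2(x, y)
  # independent arithmetic: R^2 = 1 - SSE/SST for the OLS line
  b <- cov(x, y) / var(x)
  a <- mean(y) - b * mean(x)
  r2 <- 1 - sum((y - a - b * x)^2) / sum((y - mean(y))^2)
  expect_equal(fit$r_squared, r2, tolerance = 1e-12)
  expect_error(linearity_r2(0.1, 0.1))

  g <- glance(fit)
  expect_equal(g$r_squared, fit$r_squared)
  td <- tidy(fit)
  expect_equal(nrow(td), 4L)
  expect_equal(td$measured - td$residual, td$fitted)
})

test_that("full-pipeline parameter recovery and determinism", {
  ref <- synthetic_reference()
  cfg <- itd_config()
  # same mixture twice: identical clone tables
  mk <- function() {
    reads <- simulate_reads(ref, list(itd_spec(300, 21), "WT"),
                            fractions = c(0.3, 0.7), total_reads = 400L,
                            error_rate = 0.002, seed = 13L)
    detect_itds(reads = reads, reference = ref, config = cfg)$clones
  }
  expect_identical(mk(), mk())
})

test_that("WT-only simulations with errors never produce ITD calls", {
  ref <- synthetic_reference()
  for (seed in 1:10) {
    reads <- simulate_reads(ref, list("WT"), counts = 800L,
                            error_rate = 0.01, seed = seed)
    res <- detect_itds(reads = reads, reference = ref)
    expect_equal(nrow(res$clones), 0L, info = paste("seed", seed))
  }
})
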