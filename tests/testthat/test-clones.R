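mk_call <- function(sequence, length_estimate, ref_pos, trailing = FALSE,
                    uid = 1L, count = 1L, seg_start = 0L,
                    seg_end = nchar(sequence)) {
  tibble::tibble(sequence = sequence, insert_length = nchar(sequence),
                 ref_pos = ref_pos, read_offset = 0L, trailing = trailing,
                 length_estimate = length_estimate,
                 exact_length = !trailing,
                 tandem_start = ref_pos - length_estimate,
                 tandem_end = ref_pos, mismatches_in_tandem = 0L,
                 seg_start = seg_start, seg_end = seg_end, uid = uid,
                 count = count)
}

test_that("merge_calls merges identical calls and splits length mismatches", {
  cfg <- itd_config()
  seq21 <- random_dna_fixed(21, seed = 61)
  two <- dplyr::bind_rows(mk_call(seq21, 21L, 30L, uid = 1L, count = 5L),
                          mk_call(seq21, 21L, 30L, uid = 2L, count = 3L))
  out <- merge_calls(two, cfg)
  expect_equal(nrow(out), 1L)
  expect_equal(out$supporting_reads, 8L)
  expect_equal(out$supporting_unique, 2L)

  seq24 <- random_dna_fixed(24, seed = 62)
  mixed <- dplyr::bind_rows(mk_call(seq21, 21L, 30L),
                            mk_call(seq24, 24L, 30L, uid = 2L))
  expect_equal(nrow(merge_calls(mixed, cfg)), 2L)
})

test_that("trailing estimates within 3 bp merge; beyond do not", {
  cfg <- itd_config()
  seg <- random_dna_fixed(40, seed = 63)
  # two trailing calls at the same site, estimates 125 and 126, and the
  # sequenced portions are both prefixes of the same segment
  a <- mk_call(substr(seg, 1, 30), 125L, 300L, trailing = TRUE, uid = 1L,
               count = 4L)
  b <- mk_call(substr(seg, 1, 25), 126L, 300L, trailing = TRUE, uid = 2L,
               count = 2L)
  out <- merge_calls(dplyr::bind_rows(a, b), cfg)
  expect_equal(nrow(out), 1L)
  expect_equal(out$supporting_reads, 6L)
  expect_equal(out$consensus_insert, substr(seg, 1, 30))  # most supported

  c2 <- mk_call(substr(seg, 1, 25), 131L, 300L, trailing = TRUE, uid = 3L)
  expect_equal(nrow(merge_calls(dplyr::bind_rows(a, c2), cfg)), 2L)
})

test_that("merge_calls never merges across evidence classes by default", {
  cfg <- itd_config()
  seq21 <- random_dna_fixed(21, seed = 64)
  a <- mk_call(seq21, 21L, 300L, trailing = FALSE, uid = 1L)
  b <- mk_call(seq21, 21L, 300L, trailing = TRUE, uid = 2L)
  expect_equal(nrow(merge_calls(dplyr::bind_rows(a, b), cfg)), 2L)
  allow <- itd_config(merge_trailing_with_exact = TRUE)
  expect_equal(nrow(merge_calls(dplyr::bind_rows(a, b), allow)), 1L)
})

test_that("merge_calls respects sequence disagreement over the overlap", {
  cfg <- itd_config()
  seq21 <- random_dna_fixed(21, seed = 65)
  other <- paste0(substr(seq21, 1, 10),
                  chartr("ACGT", "CGTA", substr(seq21, 11, 11)),
                  substr(seq21, 12, 21))
  a <- mk_call(seq21, 21L, 300L)
  b <- mk_call(other, 21L, 300L, uid = 2L)
  expect_equal(nrow(merge_calls(dplyr::bind_rows(a, b), cfg)), 2L)
  # output clone count never exceeds input call count
  expect_lte(nrow(merge_calls(dplyr::bind_rows(a, a, b), cfg)), 3L)
})

test_that("coverage counts site-spanning reads, with boundary rules", {
  cfg <- itd_config()
  aln <- tibble::tibble(
    bases = c("x", "y", "z"),
    count = c(100L, 7L, 3L),
    ref_start = c(0L, 0L, 120L),
    ref_end = c(250L, 120L, 300L),
    passed = TRUE
  )
  # interior position spanned by all full reads
  expect_equal(compute_coverage(aln, 60L, 600L), 107L)
  # reads ending exactly at ref_pos are not spanning (no base after)
  expect_equal(compute_coverage(aln, 120L, 600L), 100L)
  # but ITD-supporting reads at that site are counted via support_uids
  expect_equal(compute_coverage(aln, 120L, 600L, support_uids = c(2L, 3L)),
               110L)
  # reference start boundary uses the single flanking base
  expect_equal(compute_coverage(aln, 0L, 600L), 107L)

  # brute-force per-read span check on a random mixture
  set.seed(66)
  starts <- sample(0:200, 50, replace = TRUE)
  ends <- starts + sample(50:250, 50, replace = TRUE)
  counts <- sample(1:5, 50, replace = TRUE)
  aln2 <- tibble::tibble(bases = "b", count = counts, ref_start = starts,
                         ref_end = pmin(ends, 450L), passed = TRUE)
  pos <- 210L
  manual <- sum(counts[starts <= pos - 1L & pmin(ends, 450L) >= pos + 1L])
  expect_equal(compute_coverage(aln2, pos, 450L), manual)
})

test_that("VAF arithmetic matches its definition", {
  expect_equal(compute_vaf(67000, 100000), 0.67)
  expect_equal(compute_vaf(0, 1000), 0)
  expect_equal(compute_vaf(67, 1e6), 6.7e-5)
  expect_error(compute_vaf(10, 5))
})

test_that("VAF and AR conversions are mutually inverse", {
  expect_equal(vaf_to_ar(0.5), 1)
  expect_equal(ar_to_vaf(0), 0)
  expect_equal(vaf_to_ar(1 / 3), 0.5)
  expect_equal(vaf_to_ar(1), Inf)
  v <- seq(0, 0.99, by = 0.01)
  expect_equal(ar_to_vaf(vaf_to_ar(v)), v, tolerance = 1e-12)
  a <- c(0, 0.1, 0.5, 1, 2, 10)
  expect_equal(vaf_to_ar(ar_to_vaf(a)), a, tolerance = 1e-12)
})

test_that("clone filtering applies the support threshold with an audit", {
  cfg <- itd_config()  # min 2 supporting reads
  clones <- tibble::tibble(
    consensus_insert = c("A", "B", "C"),
    length_estimate = 21L, exact_length = TRUE, ref_pos = 300L,
    trailing = FALSE,
    supporting_reads = c(1L, 2L, 20L),
    supporting_unique = 1L, support_mate1 = c(1L, 2L, 20L),
    support_mate2 = 0L, uids = list(1L, 2L, 3L),
    coverage = 300000L, vaf = c(1, 2, 20) / 300000
  )
  out <- apply_filters(clones, cfg)
  expect_equal(out$consensus_insert, c("B", "C"))
  audit <- clone_audit(out)
  expect_equal(audit$consensus_insert, "A")
  expect_equal(audit$reason, "support")
  # no VAF floor: 20 of 300,000 is retained
  expect_true("C" %in% out$consensus_insert)
  empty <- apply_filters(clones[0, ], cfg)
  expect_equal(nrow(empty), 0L)
})

test_that("track_clones categorises trajectories and partitions cleanly", {
  clone_row <- function(seq, len, pos, vaf, trailing = FALSE) {
    tibble::tibble(consensus_insert = seq, length_estimate = len,
                   exact_length = !trailing, ref_pos = pos,
                   trailing = trailing, vaf = vaf)
  }
  s1 <- random_dna_fixed(21, seed = 71)
  s2 <- random_dna_fixed(33, seed = 72)
  s3 <- random_dna_fixed(15, seed = 73)
  dx <- dplyr::bind_rows(clone_row(s1, 21L, 300L, 0.40),
                         clone_row(s2, 33L, 150L, 0.10))
  cy2 <- clone_row(s1, 21L, 300L, 0.002)
  rl <- dplyr::bind_rows(clone_row(s1, 21L, 300L, 0.30),
                         clone_row(s3, 15L, 200L, 0.05))
  traj <- track_clones(list(dx, cy2, rl), labels = c("dx", "cy2", "rl"))

  per_clone <- unique(traj[, c("clone_id", "consensus_insert", "category")])
  expect_equal(nrow(per_clone), 3L)
  expect_equal(per_clone$category[per_clone$consensus_insert == s1],
               "persisting")
  expect_equal(per_clone$category[per_clone$consensus_insert == s2], "lost")
  expect_equal(per_clone$category[per_clone$consensus_insert == s3],
               "gained")
  # categories partition the matched clones
  expect_equal(sum(table(per_clone$category)), nrow(per_clone))

  # persisting clone has VAFs at dx and rl, detected at cy2 here too
  s1_traj <- traj[traj$consensus_insert == s1, ]
  expect_equal(s1_traj$vaf[s1_traj$timepoint == "dx"], 0.40)
  expect_equal(s1_traj$vaf[s1_traj$timepoint == "rl"], 0.30)
  # undetected timepoints are NA
  s2_traj <- traj[traj$consensus_insert == s2, ]
  expect_true(is.na(s2_traj$vaf[s2_traj$timepoint == "rl"]))
  expect_error(track_clones(list(dx)), "length")
})

test_that("sample summaries reconcile stage counts", {
  ref <- synthetic_reference()
  wt <- simulate_reads(ref, list("WT"), counts = 200L)
  res <- detect_itds(reads = wt, reference = ref)
  s <- summarize_sample(res)
  expect_equal(s$n_clones, 0L)
  expect_equal(s$reads_in, 200L)
  expect_lte(s$reads_qc, s$reads_in)
  expect_lte(s$reads_aligned, s$reads_qc)
  expect_lte(s$itd_supporting_reads, s$reads_aligned)

  mixed <- simulate_reads(ref, list(itd_spec(200, 21), itd_spec(400, 33),
                                    "WT"),
                          counts = c(100L, 50L, 850L), offset = 190L)
  res2 <- detect_itds(reads = mixed, reference = ref)
  s2 <- summarize_sample(res2)
  expect_equal(s2$n_clones, 2L)
  # summed VAF of multiple clones, as plotted in total-burden views
  expect_equal(s2$total_vaf, sum(res2$clones$vaf))
})
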