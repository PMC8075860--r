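align_tbl <- function(bases, ref, cfg = itd_config()) {
  align_reads(collapse_unique(reads_tbl(bases)), ref, cfg)
}

test_that("extract_inserts finds gap runs and applies the length floor", {
  cfg <- itd_config()
  ref <- load_reference(random_dna_fixed(200, seed = 44))

  # identity alignment: no candidates
  aln <- align_tbl(ref$sequence, ref, cfg)
  expect_equal(nrow(extract_inserts(aln, cfg)), 0L)

  # 21 bp duplication: exactly one internal candidate of length 21
  aln21 <- align_tbl(make_itd_allele(ref, itd_spec(80, 21)), ref, cfg)
  cand <- extract_inserts(aln21, cfg)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$insert_length, 21L)
  expect_equal(cand$end, "internal")
  expect_false(cand$trailing)

  # 5 bp duplication: the gap run exists but is below the floor
  aln5 <- align_tbl(make_itd_allele(ref, itd_spec(80, 5)), ref, cfg)
  expect_equal(nrow(extract_inserts(aln5, cfg)), 0L)
  expect_equal(nrow(extract_inserts(aln5,
                                    itd_config(min_insert_length = 5))), 1L)
})

test_that("trailing classification follows read-end abutment", {
  # 21 bp insert centred in a 250 bp read
  expect_false(classify_trailing(115L, 21L, 250L))
  # 126 bp insert reaching the 3' read end
  expect_true(classify_trailing(124L, 126L, 250L))
  # 198 bp insert at the read end
  expect_true(classify_trailing(52L, 198L, 250L))
  # insert at the very start
  expect_true(classify_trailing(0L, 30L, 250L))
})

test_that("find_tandem verifies adjacency and rejects non-tandem inserts", {
  cfg <- itd_config()
  ref <- load_reference(random_dna_fixed(300, seed = 55))

  # insert identical to the 21 bases immediately upstream of ref_pos
  ins <- substr(ref$sequence, 100, 120)
  cand <- tibble::tibble(uid = 1L, sequence = ins, insert_length = 21L,
                         ref_pos = 120L, read_offset = 50L,
                         trailing = FALSE, end = "internal")
  call <- find_tandem(cand, ref, cfg)
  site <- canonical_dup_site(ref, 99, 21)   # left-aligned representation
  expect_equal(call$tandem_start, site - 21L)
  expect_equal(call$tandem_end, site)
  expect_equal(call$ref_pos, site)
  expect_equal(call$mismatches_in_tandem, 0L)
  expect_true(call$exact_length)
  # brute-force window scan confirms the match is unique
  mm <- vapply(0:(300 - 21), function(w) {
    sum(strsplit(ins, "")[[1L]] !=
          strsplit(substr(ref$sequence, w + 1, w + 21), "")[[1L]])
  }, numeric(1))
  expect_equal(which(mm == 0) - 1L, 99L)

  # random insert absent from the reference
  cand$sequence <- "TTTTTTTTTTGGGGGGGGGGA"
  expect_null(find_tandem(cand, ref, cfg))

  # insert matching a window 50 bp away from ref_pos: non-adjacent
  cand$sequence <- substr(ref$sequence, 30, 50)
  expect_null(find_tandem(cand, ref, cfg))
})

test_that("find_tandem canonicalises downstream-copy placements", {
  cfg <- itd_config()
  ref <- load_reference(random_dna_fixed(300, seed = 56))
  ins <- substr(ref$sequence, 101, 121)   # segment [100, 121)
  # aligner placed the gap before the wild-type copy (downstream window)
  cand <- tibble::tibble(uid = 1L, sequence = ins, insert_length = 21L,
                         ref_pos = 100L, read_offset = 60L,
                         trailing = FALSE, end = "internal")
  call <- find_tandem(cand, ref, cfg)
  expect_equal(call$ref_pos, 121L)        # canonical upstream representation
  expect_equal(c(call$tandem_start, call$tandem_end), c(100L, 121L))
})

test_that("tandem mismatch tolerance is enforced", {
  cfg <- itd_config()   # 10% tolerance
  ref <- load_reference(random_dna_fixed(300, seed = 57))
  seg <- substr(ref$sequence, 101, 140)   # 40 bp: tolerate 4 mismatches
  mutate_at <- function(s, pos) {
    ch <- strsplit(s, "")[[1L]]
    ch[pos] <- chartr("ACGT", "CGTA", ch[pos])
    paste(ch, collapse = "")
  }
  cand <- tibble::tibble(uid = 1L, sequence = mutate_at(seg, c(5, 15, 25, 35)),
                         insert_length = 40L, ref_pos = 140L,
                         read_offset = 50L, trailing = FALSE,
                         end = "internal")
  call <- find_tandem(cand, ref, cfg)
  expect_equal(call$mismatches_in_tandem, 4L)
  expect_lte(call$mismatches_in_tandem / call$length_estimate,
             cfg$tandem_max_mismatch_fraction)

  cand$sequence <- mutate_at(seg, c(5, 10, 15, 20, 25))  # 5 > 4: rejected
  expect_null(find_tandem(cand, ref, cfg))
})

test_that("trailing length estimation uses the copy offset", {
  cfg <- itd_config()
  ref <- load_reference(random_dna_fixed(400, seed = 58))
  # sequenced portion = first 30 bases of a segment that starts 90 bp
  # upstream of the insertion position
  portion <- substr(ref$sequence, 111, 140)   # window starts at 110 (0-based)
  cand <- tibble::tibble(uid = 1L, sequence = portion, insert_length = 30L,
                         ref_pos = 200L, read_offset = 220L,
                         trailing = TRUE, end = "3p")
  est <- estimate_trailing_length(cand, ref, cfg)
  expect_equal(est$length_estimate, 90L)
  expect_false(est$exact)
  call <- find_tandem(cand, ref, cfg)
  expect_equal(c(call$tandem_start, call$tandem_end), c(110L, 200L))
  expect_equal(c(call$seg_start, call$seg_end), c(0L, 30L))
})

test_that("simulate -> detect round-trips exact length and site", {
  cfg <- itd_config()
  ref <- synthetic_reference()
  for (L in c(6L, 12L, 33L, 60L, 100L)) {
    for (d in c(150L, 300L, 350L)) {
      reads <- simulate_reads(ref, list(itd_spec(d, L), "WT"),
                              counts = c(30L, 30L))
      clones <- detect_itds(reads = reads, reference = ref,
                            config = cfg)$clones
      expect_equal(nrow(clones), 1L, info = sprintf("L=%d d=%d", L, d))
      expect_equal(clones$length_estimate, L)
      expect_equal(clones$ref_pos, canonical_dup_site(ref, d, L))
      expect_false(clones$trailing)
      expect_true(clones$exact_length)
      expect_equal(clones$vaf, 0.5)
    }
  }
})

test_that("simulate -> detect recovers trailing lengths within 3 bp", {
  cfg <- itd_config()
  ref <- synthetic_reference()
  for (L in c(130L, 160L, 200L, 240L)) {
    reads <- simulate_reads(ref, list(itd_spec(250L, L), "WT"),
                            counts = c(30L, 30L))
    clones <- detect_itds(reads = reads, reference = ref,
                          config = cfg)$clones
    expect_equal(nrow(clones), 1L, info = sprintf("L=%d", L))
    expect_lte(abs(clones$length_estimate - L), 3L)
    expect_true(clones$trailing)
    expect_false(clones$exact_length)
  }
})

test_that("adding WT-only reads does not change the extracted inserts", {
  cfg <- itd_config()
  ref <- synthetic_reference()
  itd_reads <- simulate_reads(ref, list(itd_spec(300, 21)), counts = 5L)
  mixed <- simulate_reads(ref, list(itd_spec(300, 21), "WT"),
                          counts = c(5L, 50L))
  cand1 <- extract_inserts(align_tbl(itd_reads$bases, ref, cfg), cfg)
  cand2 <- extract_inserts(align_tbl(mixed$bases, ref, cfg), cfg)
  cols <- c("sequence", "insert_length", "ref_pos", "read_offset",
            "trailing", "end")
  expect_equal(cand1[, cols], cand2[, cols])
})
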