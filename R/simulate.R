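#' Specify a simulated internal tandem duplication
#'
#' @param dup_start 0-based reference position where the duplicated
#'   segment begins.
#' @param dup_length Length of the duplicated segment in bp (>= 1).
#' @param extra_mismatches Number of point changes injected into the
#'   second (inserted) copy, emulating ITDs that carry point mutations
#'   (default 0). Positions and substitutions are deterministic.
#' @return An `itd_sim_spec` object.
#' @examples
#' itd_spec(300, 21)
#' @export
itd_spec <- function(dup_start, dup_length, extra_mismatches = 0L) {
  spec <- list(dup_start = as.integer(dup_start),
               dup_length = as.integer(dup_length),
               extra_mismatches = as.integer(extra_mismatches))
  stopifnot(spec$dup_start >= 0L, spec$dup_length >= 1L,
            spec$extra_mismatches >= 0L,
            spec$extra_mismatches <= spec$dup_length)
  structure(spec, class = "itd_sim_spec")
}

next_base <- function(b) {
  c(A = "C", C = "G", G = "T", T = "A")[b]
}

#' Construct an ITD-bearing allele sequence
#'
#' Duplicates the reference segment `[dup_start, dup_start + dup_length)`
#' immediately after itself (head-to-tail), the mutation model of an
#' internal tandem duplication. Optional point changes are applied to the
#' second copy only, at deterministic evenly spaced positions.
#'
#' @param ref An `itd_reference`.
#' @param spec An [itd_spec()].
#' @return The allele sequence; its length is
#'   `nchar(ref$sequence) + dup_length`.
#' @examples
#' make_itd_allele(load_reference("AAACCCGGG"), itd_spec(3, 3))
#' @export
make_itd_allele <- function(ref, spec) {
  ref <- as_itd_reference(ref)
  stopifnot(inherits(spec, "itd_sim_spec"))
  n <- nchar(ref$sequence)
  j <- spec$dup_start + spec$dup_length
  if (j > n) {
    stop("Duplication [", spec$dup_start, ", ", j,
         ") extends beyond the ", n, " bp reference.", call. = FALSE)
  }
  seg <- substr(ref$sequence, spec$dup_start + 1L, j)
  if (spec$extra_mismatches > 0L) {
    chars <- strsplit(seg, "", fixed = TRUE)[[1L]]
    pos <- unique(pmax(1L, floor(spec$dup_length *
                                   seq_len(spec$extra_mismatches) /
                                   (spec$extra_mismatches + 1L))))
    chars[pos] <- next_base(chars[pos])
    seg <- paste(chars, collapse = "")
  }
  paste0(substr(ref$sequence, 1L, j), seg,
         substr(ref$sequence, j + 1L, n))
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

inject_errors <- function(bases, error_rate) {
  if (error_rate <= 0) return(bases)
  lens <- nchar(bases)
  n_err <- stats::rbinom(length(bases), lens, error_rate)
  hit <- which(n_err > 0L)
  for (i in hit) {
    chars <- strsplit(bases[i], "", fixed = TRUE)[[1L]]
    pos <- sample.int(lens[i], n_err[i])
    for (p in pos) {
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
    }
    bases[i] <- paste(chars, collapse = "")
  }
  bases
}

#' Simulate amplicon reads from a mixture of alleles
#'
#' Emulates deep amplicon sequencing of a mixture of wild-type and
#' ITD-bearing alleles. In single-end mode (the default) every read
#' starts at a common reference offset chosen so that reads span the
#' (first) duplication's insertion site -- so the constructed read
#' fraction of each ITD allele is exactly its expected VAF. In paired
#' mode each fragment yields a mate-1 read from the allele's 5' end and
#' a reverse-complemented mate-2 read from its 3' end.
#'
#' Counts can be given exactly (`counts`; deterministic mixtures for
#' validation experiments) or drawn by sampling each read's allele of
#' origin from `fractions`. Per-base substitution errors are applied at
#' `error_rate` under `seed`; the same specification and seed always
#' yield identical reads. Qualities are constant Phred `phred`.
#'
#' @param ref An `itd_reference`.
#' @param alleles List of alleles: [itd_spec()] objects and/or the string
#'   `"WT"`.
#' @param counts Integer vector, one exact read (or fragment) count per
#'   allele. Mutually exclusive with `fractions`.
#' @param fractions Numeric mixing fractions per allele (summing to 1);
#'   requires `total_reads`.
#' @param total_reads Total reads when sampling from `fractions`.
#' @param read_length Read length in bp (default 250).
#' @param paired Emit mate pairs instead of single-end reads.
#' @param offset Single-end start offset (0-based reference coordinate);
#'   default centres the first duplication's insertion site in the read,
#'   clamped to the amplicon.
#' @param error_rate Per-base substitution error probability (default 0).
#' @param seed Integer seed for error injection and allele sampling.
#' @param phred Constant base quality (default 37).
#' @param sample Sample name used in read ids.
#' @return A reads tibble (`read_id`, `bases`, `quality`, `mate`) with a
#'   `"truth"` attribute tibble (`allele`, `dup_start`, `dup_length`,
#'   `n_reads`, `fraction`); retrieve it with [sim_truth()].
#' @export
simulate_reads <- function(ref, alleles, counts = NULL, fractions = NULL,
                           total_reads = NULL, read_length = 250L,
                           paired = FALSE, offset = NULL, error_rate = 0,
                           seed = NULL, phred = 37L, sample = "sim") {
  ref <- as_itd_reference(ref)
  stopifnot(is.list(alleles), length(alleles) >= 1L)
  is_wt <- vapply(alleles, function(a) identical(a, "WT"), logical(1))
  stopifnot(all(is_wt | vapply(alleles, inherits, logical(1),
                               "itd_sim_spec")))
  if (is.null(counts) == is.null(fractions)) {
    stop("Give exactly one of `counts` (count-exact) or `fractions`.",
         call. = FALSE)
  }
  read_length <- as.integer(read_length)
  ref_len <- nchar(ref$sequence)
  if (read_length > ref_len) {
    stop("`read_length` exceeds the reference length.", call. = FALSE)
  }
  seqs <- vapply(alleles, function(a) {
    if (identical(a, "WT")) ref$sequence else make_itd_allele(ref, a)
  }, character(1))
  names(seqs) <- vapply(seq_along(alleles), function(k) {
    if (is_wt[k]) "WT" else paste0("ITD", k)
  }, character(1))

  with_seed(seed, {
    if (is.null(counts)) {
      stopifnot(!is.null(total_reads), length(fractions) == length(alleles),
                abs(sum(fractions) - 1) < 1e-8)
      origin <- sample.int(length(alleles), total_reads, replace = TRUE,
                           prob = fractions)
      counts <- tabulate(origin, nbins = length(alleles))
    } else {
      stopifnot(length(counts) == length(alleles), all(counts >= 0))
      counts <- as.integer(counts)
    }

    first_itd <- which(!is_wt)[1L]
    rows <- vector("list", length(alleles))
    for (k in seq_along(alleles)) {
      if (counts[k] == 0L) next
      allele_seq <- unname(seqs[k])
      if (paired) {
        m1 <- substr(allele_seq, 1L, read_length)
        m2 <- reverse_complement(substr(allele_seq,
                                        nchar(allele_seq) - read_length + 1L,
                                        nchar(allele_seq)))
        bases <- rep(c(m1, m2), counts[k])
        mate <- rep(c(1L, 2L), counts[k])
      } else {
        o <- offset
        if (is.null(o)) {
          if (is.na(first_itd)) {
            o <- (ref_len - read_length) %/% 2L
          } else {
            site <- alleles[[first_itd]]$dup_start +
              alleles[[first_itd]]$dup_length
            o <- max(0L, min(site - read_length %/% 2L,
                             ref_len - read_length))
          }
        }
        o <- as.integer(o)
        if (o < 0L || o + read_length > nchar(allele_seq)) {
          stop("Read window [", o, ", ", o + read_length,
               ") does not fit allele '", names(seqs)[k], "'.",
               call. = FALSE)
        }
        bases <- rep(substr(allele_seq, o + 1L, o + read_length), counts[k])
        mate <- rep(1L, counts[k] * 1L)
      }
      rows[[k]] <- tibble::tibble(
        allele = names(seqs)[k], bases = bases, mate = mate
      )
    }
    reads <- dplyr::bind_rows(rows)
    if (nrow(reads) > 0L) {
      reads$bases <- inject_errors(reads$bases, error_rate)
    }
    qual <- strrep(intToUtf8(phred + 33L), read_length)
    out <- tibble::tibble(
      read_id = sprintf("%s_%s_%07d", sample, reads$allele,
                        seq_len(max(nrow(reads), 0L))),
      bases = reads$bases,
      quality = rep(qual, nrow(reads)),
      mate = reads$mate
    )
    total <- sum(counts) * (if (paired) 2L else 1L)
    truth <- tibble::tibble(
      allele = names(seqs),
      dup_start = vapply(alleles, function(a) {
        if (identical(a, "WT")) NA_integer_ else a$dup_start
      }, integer(1)),
      dup_length = vapply(alleles, function(a) {
        if (identical(a, "WT")) NA_integer_ else a$dup_length
      }, integer(1)),
      n_reads = counts * (if (paired) 2L else 1L),
      fraction = if (total > 0L) counts * (if (paired) 2L else 1L) / total
                 else rep(0, length(counts))
    )
    attr(out, "truth") <- truth
    out
  })
}

#' Truth table of a simulated sample
#'
#' @param reads A reads tibble from [simulate_reads()].
#' @return The `"truth"` attribute tibble.
#' @export
sim_truth <- function(reads) {
  attr(reads, "truth", exact = TRUE)
}

#' Simulate a serial dilution series
#'
#' Emulates the classic sensitivity experiment: DNA of an ITD-positive
#' specimen serially diluted in ITD-negative DNA, sequenced at each step.
#' Step k has expected VAF `start_vaf / dilution_factor^(k-1)`. In
#' count-exact mode the ITD read count at each step is the rounded
#' expectation (so the constructed fraction is deterministic); otherwise
#' each read's allele of origin is sampled, adding binomial noise as in a
#' real dilution.
#'
#' @param ref An `itd_reference`.
#' @param spec An [itd_spec()] for the diluted ITD.
#' @param start_vaf Expected VAF of the undiluted sample (default 0.67).
#' @param dilution_factor Fold-dilution per step (default 10).
#' @param n_steps Number of samples including the undiluted one.
#' @param reads_per_step Reads per sample.
#' @param read_length Read length (default 250).
#' @param error_rate Per-base substitution error rate (default 0).
#' @param seed Integer seed.
#' @param count_exact Use exact rounded counts instead of sampling.
#' @return A list with `samples` (named list of reads tibbles) and
#'   `truth` (tibble: `sample`, `step`, `expected_vaf`,
#'   `constructed_vaf`, `n_reads`, `dup_start`, `dup_length`).
#' @export
simulate_dilution_series <- function(ref, spec, start_vaf = 0.67,
                                     dilution_factor = 10, n_steps = 5,
                                     reads_per_step = 300000L,
                                     read_length = 250L, error_rate = 0,
                                     seed = 1L, count_exact = FALSE) {
  ref <- as_itd_reference(ref)
  stopifnot(inherits(spec, "itd_sim_spec"), start_vaf > 0, start_vaf < 1,
            dilution_factor >= 1, n_steps >= 1)
  expected <- start_vaf / dilution_factor^(seq_len(n_steps) - 1L)
  if (min(expected) * reads_per_step < 1) {
    warning("Expected ITD support below one read at the most diluted ",
            "step; detection there is not expected.", call. = FALSE)
  }
  samples <- vector("list", n_steps)
  constructed <- numeric(n_steps)
  names(samples) <- sprintf("dilution_%02d", seq_len(n_steps))
  for (k in seq_len(n_steps)) {
    if (count_exact) {
      n_itd <- as.integer(round(expected[k] * reads_per_step))
      reads <- simulate_reads(
        ref, list(spec, "WT"), counts = c(n_itd, reads_per_step - n_itd),
        read_length = read_length, error_rate = error_rate,
        seed = seed + k, sample = names(samples)[k]
      )
    } else {
      reads <- simulate_reads(
        ref, list(spec, "WT"),
        fractions = c(expected[k], 1 - expected[k]),
        total_reads = reads_per_step, read_length = read_length,
        error_rate = error_rate, seed = seed + k,
        sample = names(samples)[k]
      )
    }
    samples[[k]] <- reads
    tr <- sim_truth(reads)
    constructed[k] <- tr$fraction[1L]
  }
  list(
    samples = samples,
    truth = tibble::tibble(
      sample = names(samples), step = seq_len(n_steps),
      expected_vaf = expected, constructed_vaf = constructed,
      n_reads = as.integer(reads_per_step),
      dup_start = spec$dup_start, dup_length = spec$dup_length
    )
  )
}

#' Linearity of measured versus expected VAF
#'
#' Ordinary least-squares fit of measured on expected VAF across a
#' dilution (or other truth) series, summarised by the coefficient of
#' determination R-squared. R-squared is 1 for any perfect linear
#' relation (linearity, not identity); the slope indicates quantitative
#' accuracy.
#'
#' @param expected Expected (true) VAFs.
#' @param measured Measured (pipeline) VAFs.
#' @return An `itd_linearity` object with elements `r_squared`, `slope`,
#'   `intercept`, `n` and `data` (a tibble of the pairs). Supports
#'   [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @examples
#' linearity_r2(c(0.1, 0.2, 0.4), c(0.11, 0.19, 0.41))$r_squared
#' @export
linearity_r2 <- function(expected, measured) {
  stopifnot(length(expected) == length(measured), length(expected) >= 2L)
  fit <- stats::lm(measured ~ expected,
                   data = data.frame(expected = expected,
                                     measured = measured))
  structure(
    list(
      r_squared = suppressWarnings(summary(fit))$r.squared,
      slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      n = length(expected),
      data = tibble::tibble(expected = expected, measured = measured)
    ),
    class = "itd_linearity"
  )
}

#' @export
print.itd_linearity <- function(x, ...) {
  cat("<itd_linearity> n = ", x$n,
      ", R^2 = ", format(x$r_squared, digits = 6),
      ", slope = ", format(x$slope, digits = 4),
      ", intercept = ", format(x$intercept, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Run the caller across a dilution series and evaluate linearity
#'
#' Convenience wrapper: calls ITDs in every sample of a
#' [simulate_dilution_series()] result, takes as the measured VAF the
#' clone matching the simulated duplication (site within the merge
#' tolerance and compatible length; 0 when undetected), and fits
#' [linearity_r2()].
#'
#' @param dilution Result of [simulate_dilution_series()].
#' @param ref An `itd_reference`.
#' @param config An [itd_config()].
#' @return A list with `results` (tibble: `sample`, `expected_vaf`,
#'   `measured_vaf`, `detected`) and `linearity` (an `itd_linearity`).
#' @export
evaluate_dilution <- function(dilution, ref, config = itd_config()) {
  ref <- as_itd_reference(ref)
  truth <- dilution$truth
  measured <- numeric(nrow(truth))
  detected <- logical(nrow(truth))
  for (k in seq_len(nrow(truth))) {
    res <- detect_itds(reads = dilution$samples[[k]], reference = ref,
                       config = config, sample = truth$sample[k])
    clones <- res$clones
    site <- canonical_dup_site(ref, truth$dup_start[k], truth$dup_length[k])
    hit <- which(
      abs(clones$ref_pos - site) <= config$merge_site_tolerance &
        (ifelse(clones$exact_length,
                clones$length_estimate == truth$dup_length[k],
                abs(clones$length_estimate - truth$dup_length[k]) <= 3L))
    )
    if (length(hit) > 0L) {
      detected[k] <- TRUE
      measured[k] <- max(clones$vaf[hit])
    }
  }
  list(
    results = tibble::tibble(sample = truth$sample,
                             expected_vaf = truth$expected_vaf,
                             measured_vaf = measured,
                             detected = detected),
    linearity = linearity_r2(truth$expected_vaf, measured)
  )
}
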