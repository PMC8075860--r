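#' Detect and quantify ITDs in one sample
#'
#' Runs the full calling pipeline: quality filtering, mate orientation,
#' unique-sequence collapsing, semi-global alignment against the
#' wild-type amplicon, insert extraction, tandem verification, clone
#' merging, quantification (supporting reads, site coverage, VAF, AR)
#' and filtering. Every step is deterministic: the same reads, reference
#' and configuration always produce identical output.
#'
#' @param reads A reads tibble (`read_id`, `bases`, `quality`, `mate`),
#'   e.g. from [simulate_reads()]; alternatively give FASTQ paths via
#'   `r1`/`r2`.
#' @param r1,r2 FASTQ paths (mate 2 optional), used when `reads` is
#'   `NULL`.
#' @param reference An `itd_reference`, or a FASTA path / sequence string.
#' @param config An [itd_config()].
#' @param sample Sample label written into the output tables.
#' @return An `itd_result` object: a list with
#'   \describe{
#'     \item{clones}{filtered clone tibble, one row per reported ITD
#'       clone (columns `sample`, `consensus_insert`, `length_estimate`,
#'       `exact_length`, `ref_pos`, `annotation`, `trailing`,
#'       `supporting_reads`, `supporting_unique`, `coverage`, `vaf`,
#'       `ar`), sorted by descending support;}
#'     \item{non_itd}{insertions that found no wild-type tandem;}
#'     \item{audit}{clones removed by [apply_filters()], with reasons;}
#'     \item{summary}{one-row stage-count summary (see
#'       [summarize_sample()]);}
#'     \item{alignments}{per-unique-read alignment tibble.}
#'   }
#'   Supports [generics::tidy()] (clone table) and [generics::glance()]
#'   (summary row).
#' @examples
#' ref <- synthetic_reference()
#' reads <- simulate_reads(ref, list(itd_spec(300, 21), "WT"),
#'                         counts = c(670, 330))
#' res <- detect_itds(reads = reads, reference = ref)
#' res$clones[, c("length_estimate", "vaf")]
#' @export
detect_itds <- function(reads = NULL, r1 = NULL, r2 = NULL, reference,
                        config = itd_config(), sample = "sample1") {
  ref <- as_itd_reference(reference)
  if (is.null(reads)) {
    if (is.null(r1)) stop("Give `reads` or `r1`.", call. = FALSE)
    reads <- read_fastq(r1, r2)
  }
  n_in <- nrow(reads)
  qc <- quality_filter(reads, config$min_mean_quality)
  fstats <- filter_stats(qc)
  uniq <- collapse_unique(orient_mates(qc))
  aln <- align_reads(uniq, ref, config)
  n_aligned <- sum(aln$count[aln$passed])

  cand <- extract_inserts(aln, config)
  verified <- verify_tandems(cand, ref, config)
  calls <- verified$calls
  if (nrow(calls) > 0L) {
    calls$count <- aln$count[calls$uid]
    calls$n_mate1 <- aln$n_mate1[calls$uid]
    calls$n_mate2 <- aln$n_mate2[calls$uid]
  }
  clones <- merge_calls(calls, config)

  ref_len <- nchar(ref$sequence)
  if (nrow(clones) > 0L) {
    clones$coverage <- vapply(seq_len(nrow(clones)), function(i) {
      compute_coverage(aln, clones$ref_pos[i], ref_len,
                       support_uids = clones$uids[[i]])
    }, numeric(1))
    clones$vaf <- compute_vaf(clones$supporting_reads, clones$coverage)
    clones$ar <- vaf_to_ar(clones$vaf)
    clones$annotation <- annotate_position(ref, clones$ref_pos)
  } else {
    clones$coverage <- numeric(0)
    clones$vaf <- numeric(0)
    clones$ar <- numeric(0)
    clones$annotation <- character(0)
  }
  mate_cov <- NULL
  if (any(uniq$n_mate2 > 0L) && nrow(clones) > 0L) {
    mate_cov <- c(mate1 = sum(aln$count[aln$passed & aln$n_mate1 > 0L]),
                  mate2 = sum(aln$count[aln$passed & aln$n_mate2 > 0L]))
  }
  clones <- apply_filters(clones, config, mate_coverage = mate_cov)
  audit <- clone_audit(clones)

  clone_cols <- c("sample", "consensus_insert", "length_estimate",
                  "exact_length", "ref_pos", "annotation", "trailing",
                  "supporting_reads", "supporting_unique", "coverage",
                  "vaf", "ar")
  finish <- function(tbl) {
    tbl$sample <- rep(sample, nrow(tbl))
    tbl[, clone_cols, drop = FALSE]
  }
  uids_kept <- clones$uids
  clones_out <- finish(clones)
  audit_out <- finish(audit)
  audit_out$reason <- audit$reason

  non_itd <- verified$non_itd
  if (nrow(non_itd) > 0L) {
    non_itd$count <- aln$count[non_itd$uid]
    non_itd <- non_itd |>
      dplyr::summarise(supporting_reads = sum(.data$count),
                       supporting_unique = dplyr::n(),
                       .by = c("sequence", "insert_length", "ref_pos",
                               "trailing")) |>
      dplyr::arrange(dplyr::desc(.data$supporting_reads), .data$sequence)
  } else {
    non_itd <- tibble::tibble(sequence = character(),
                              insert_length = integer(),
                              ref_pos = integer(), trailing = logical(),
                              supporting_reads = integer(),
                              supporting_unique = integer())
  }
  non_itd$sample <- rep(sample, nrow(non_itd))

  itd_supporting <- if (length(uids_kept) > 0L) {
    sum(aln$count[sort(unique(unlist(uids_kept)))])
  } else 0L

  summary <- tibble::tibble(
    sample = sample,
    reads_in = n_in,
    reads_qc = fstats$reads_out,
    removed_n = fstats$removed_n,
    removed_quality = fstats$removed_quality,
    unique_sequences = nrow(uniq),
    reads_aligned = n_aligned,
    itd_supporting_reads = itd_supporting,
    n_clones = nrow(clones_out),
    total_vaf = sum(clones_out$vaf)
  )

  structure(
    list(clones = clones_out, non_itd = non_itd, audit = audit_out,
         summary = summary, alignments = aln, sample = sample,
         config = config, reference_name = ref$name),
    class = "itd_result"
  )
}

#' @export
print.itd_result <- function(x, ...) {
  cat("<itd_result> sample '", x$sample, "' vs reference '",
      x$reference_name, "'\n", sep = "")
  s <- x$summary
  cat("  reads: ", s$reads_in, " in, ", s$reads_qc, " after QC, ",
      s$reads_aligned, " aligned, ", s$itd_supporting_reads,
      " ITD-supporting\n", sep = "")
  cat("  clones reported: ", s$n_clones, "\n", sep = "")
  if (nrow(x$clones) > 0L) {
    print(x$clones[, c("length_estimate", "exact_length", "ref_pos",
                       "trailing", "supporting_reads", "coverage",
                       "vaf", "ar")])
  }
  invisible(x)
}

#' Summarise a sample's pipeline run
#'
#' Stage counts (reads in, QC-passed, unique, aligned, ITD-supporting),
#' clone count and the summed VAF of all reported clones (the quantity
#' plotted when following total ITD burden over time).
#'
#' @param result An `itd_result`.
#' @return A one-row tibble.
#' @export
summarize_sample <- function(result) {
  stopifnot(inherits(result, "itd_result"))
  result$summary
}

fmt_table <- function(tbl, digits = 6L) {
  for (col in names(tbl)) {
    if (is.double(tbl[[col]])) {
      tbl[[col]] <- formatC(tbl[[col]], digits = digits, format = "g")
    }
  }
  tbl
}

#' Write the fixed-format result tables
#'
#' Writes four tab-separated tables into `dir`:
#' `<sample>_clones.tsv` (one row per reported clone, fixed column
#' order: sample, consensus_insert, length_estimate, exact_length,
#' ref_pos, annotation, trailing, supporting_reads, supporting_unique,
#' coverage, vaf, ar), `<sample>_non_itd.tsv` (insertions without a
#' wild-type tandem), `<sample>_filtered.tsv` (removed clones with
#' reasons) and `<sample>_summary.tsv`. Floating-point values are
#' printed with 6 significant digits.
#'
#' @param result An `itd_result`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of written paths, invisibly.
#' @export
write_itd_tables <- function(result, dir) {
  stopifnot(inherits(result, "itd_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- list(clones = result$clones, non_itd = result$non_itd,
                 filtered = result$audit, summary = result$summary)
  paths <- character(0)
  for (nm in names(tables)) {
    path <- file.path(dir, paste0(result$sample, "_", nm, ".tsv"))
    utils::write.table(fmt_table(tables[[nm]]), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths[nm] <- path
  }
  invisible(paths)
}

#' Dump alignments of ITD-supporting reads as text
#'
#' For each reported clone, renders the alignment of every supporting
#' unique read in the three-row match/mismatch/gap notation (see
#' [render_alignment()]).
#'
#' @param result An `itd_result`.
#' @param width Wrap width.
#' @return A character vector of display lines, invisibly printed.
#' @export
render_supporting_alignments <- function(result, width = 60L) {
  stopifnot(inherits(result, "itd_result"))
  aln <- result$alignments
  cand <- extract_inserts(aln, result$config)
  out <- character(0)
  for (i in unique(cand$uid)) {
    out <- c(out,
             sprintf("# unique read %d (count %d, score %g)",
                     i, aln$count[i], aln$score[i]),
             render_alignment(as.list(aln[i, ]), width = width), "")
  }
  out
}
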