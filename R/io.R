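#' Read amplicon FASTQ files into a reads table
#'
#' Reads one (single-end) or two (paired-end) FASTQ files, plain or
#' gzip-compressed, Phred+33 encoded. Each record becomes one row; the
#' `mate` column records the file of origin.
#'
#' @param path1 FASTQ path for single-end reads or mate 1.
#' @param path2 Optional FASTQ path for mate 2.
#' @return A tibble with columns `read_id`, `bases`, `quality` (Phred+33
#'   string) and `mate` (1 or 2).
#' @seealso [phred_scores()] to decode quality strings to integers.
#' @export
read_fastq <- function(path1, path2 = NULL) {
  out <- read_fastq_one(path1, mate = 1L)
  if (!is.null(path2)) {
    out <- dplyr::bind_rows(out, read_fastq_one(path2, mate = 2L))
  }
  out
}

read_fastq_one <- function(path, mate) {
  if (!file.exists(path)) {
    stop("FASTQ file '", path, "' does not exist.", call. = FALSE)
  }
  set <- tryCatch(
    suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path)),
    error = function(e) {
      stop("Failed to parse FASTQ file '", path, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  if (length(set) == 0L) {
    return(tibble::tibble(read_id = character(), bases = character(),
                          quality = character(), mate = integer()))
  }
  bases <- as.character(set)
  qual <- as.character(Biostrings::quality(set))
  ids <- names(set)
  if (is.null(ids)) ids <- paste0("read", seq_along(bases))
  bad <- which(nchar(bases) != nchar(qual) | nchar(bases) == 0L)
  if (length(bad) > 0L) {
    stop("FASTQ record '", ids[bad[1L]], "' in '", path,
         "': sequence and quality lengths differ (or are empty).",
         call. = FALSE)
  }
  tibble::tibble(read_id = unname(ids), bases = unname(bases),
                 quality = unname(qual), mate = rep(mate, length(bases)))
}

#' Write a reads table to FASTQ
#'
#' Inverse of [read_fastq()]: writes Phred+33 FASTQ, one file per mate.
#'
#' @param reads A reads tibble (`read_id`, `bases`, `quality`, `mate`).
#' @param path1 Output path for mate-1 / single-end reads.
#' @param path2 Output path for mate-2 reads; required when `reads`
#'   contains mate 2.
#' @param compress Write gzip-compressed output (default from file
#'   extension `.gz`).
#' @return Character vector of written paths, invisibly.
#' @export
write_fastq <- function(reads, path1, path2 = NULL,
                        compress = grepl("\\.gz$", path1)) {
  stopifnot(all(c("read_id", "bases", "quality", "mate") %in% names(reads)))
  write_one <- function(tbl, path) {
    set <- Biostrings::DNAStringSet(tbl$bases)
    names(set) <- tbl$read_id
    Biostrings::writeXStringSet(set, path, format = "fastq",
                                qualities = Biostrings::BStringSet(tbl$quality),
                                compress = compress)
    path
  }
  m2 <- reads$mate == 2L
  paths <- write_one(reads[!m2, , drop = FALSE], path1)
  if (any(m2)) {
    if (is.null(path2)) {
      stop("`reads` contains mate-2 reads but `path2` was not given.",
           call. = FALSE)
    }
    paths <- c(paths, write_one(reads[m2, , drop = FALSE], path2))
  }
  invisible(paths)
}

#' Decode Phred+33 quality strings
#'
#' @param quality Character vector of Phred+33 quality strings.
#' @return A list of integer vectors of per-base Phred scores.
#' @examples
#' phred_scores("II!")
#' @export
phred_scores <- function(quality) {
  lapply(quality, function(q) utf8ToInt(q) - 33L)
}

#' Reverse-complement DNA strings
#'
#' @param bases Character vector over A/C/G/T/N.
#' @return The reverse-complemented strings; `N` maps to `N`.
#' @examples
#' reverse_complement("ATCG")
#' @export
reverse_complement <- function(bases) {
  if (length(bases) == 0L) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(bases)))
}

#' Filter reads on mean base quality and ambiguous bases
#'
#' Retains reads whose mean Phred score is at least `min_mean_quality`
#' (boundary inclusive) and that contain no `N`: an `N` inside a putative
#' insert cannot be verified against the reference, so such reads are
#' dropped entirely. Filter statistics are attached as the
#' `"filter_stats"` attribute and retrievable with [filter_stats()].
#'
#' @param reads A reads tibble from [read_fastq()].
#' @param min_mean_quality Minimum mean Phred score (default 25).
#' @return The filtered reads tibble.
#' @export
quality_filter <- function(reads, min_mean_quality = 25) {
  n_in <- nrow(reads)
  if (n_in == 0L) {
    out <- reads
    has_n <- logical(0)
    low_q <- logical(0)
  } else {
    has_n <- grepl("N", reads$bases, fixed = TRUE)
    # deep amplicon data repeats quality strings heavily; score each
    # distinct string once
    uq <- unique(reads$quality)
    qs <- Biostrings::PhredQuality(uq)
    mean_uq <- BiocGenerics::mean(methods::as(qs, "IntegerList"))
    mean_q <- mean_uq[match(reads$quality, uq)]
    low_q <- !has_n & mean_q < min_mean_quality
    out <- reads[!has_n & !low_q, , drop = FALSE]
  }
  stats <- tibble::tibble(
    reads_in = n_in,
    removed_n = sum(has_n),
    removed_quality = sum(low_q),
    reads_out = nrow(out)
  )
  attr(out, "filter_stats") <- stats
  out
}

#' Retrieve filter statistics attached by [quality_filter()]
#'
#' @param reads A reads tibble returned by [quality_filter()].
#' @return A one-row tibble of counts, or `NULL` if absent.
#' @export
filter_stats <- function(reads) {
  attr(reads, "filter_stats", exact = TRUE)
}

#' Orient all reads to the reference strand
#'
#' Mate-2 reads sequence the opposite strand of the amplicon; this
#' reverse-complements them so every read is in reference orientation
#' before unique-sequence collapsing. Mate provenance is kept.
#'
#' @param reads A reads tibble.
#' @return The reads tibble with mate-2 `bases` reverse-complemented and
#'   `quality` reversed.
#' @export
orient_mates <- function(reads) {
  m2 <- which(reads$mate == 2L)
  if (length(m2) > 0L) {
    reads$bases[m2] <- reverse_complement(reads$bases[m2])
    reads$quality[m2] <- vapply(reads$quality[m2], function(q) {
      intToUtf8(rev(utf8ToInt(q)))
    }, character(1), USE.NAMES = FALSE)
  }
  reads
}

#' Collapse reads to unique sequences with multiplicities
#'
#' One row per distinct read sequence, with its total multiplicity and the
#' per-mate breakdown. Aligning each distinct sequence once and weighting
#' results by `count` is what makes deep amplicon samples (millions of
#' reads, few distinct sequences) tractable. Output is ordered by
#' descending count, ties broken lexicographically by sequence, so the
#' result is independent of input order.
#'
#' @param reads A reads tibble (mate 2 already oriented, see
#'   [orient_mates()]).
#' @return A tibble with columns `bases`, `count`, `n_mate1`, `n_mate2`.
#' @export
collapse_unique <- function(reads) {
  if (nrow(reads) == 0L) {
    return(tibble::tibble(bases = character(), count = integer(),
                          n_mate1 = integer(), n_mate2 = integer()))
  }
  reads |>
    dplyr::summarise(
      count = dplyr::n(),
      n_mate1 = sum(.data$mate == 1L),
      n_mate2 = sum(.data$mate == 2L),
      .by = "bases"
    ) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$bases)
}
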