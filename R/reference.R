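#' Load a wild-type amplicon reference
#'
#' Reads the wild-type reference amplicon either from a single-record FASTA
#' file or from a bare sequence string. The sequence is uppercased and
#' whitespace-stripped; only the unambiguous bases A/C/G/T are accepted
#' (an `N` in the reference would make any putative insert unverifiable,
#' so ambiguous references are rejected outright).
#'
#' @param x Path to a single-record FASTA file, or a raw DNA string.
#' @param name Label for the reference; defaults to the FASTA header (or
#'   `"reference"` for bare strings).
#' @param annotation Optional annotation table: a data frame with columns
#'   `position` (0-based reference position) and `label` (external
#'   coordinate, e.g. a transcript position or protein codon). When
#'   supplied it must cover every reference position exactly once.
#' @return An `itd_reference` object: a list with elements `name`,
#'   `sequence` (uppercase character scalar) and `annotation` (a tibble or
#'   `NULL`).
#' @examples
#' ref <- load_reference("ACGTACGTACGT")
#' ref$sequence
#' @export
load_reference <- function(x, name = NULL, annotation = NULL) {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  looks_like_path <- !grepl("^[ACGTNacgtn \t\r\n]*$", x) || file.exists(x)
  if (file.exists(x)) {
    set <- Biostrings::readDNAStringSet(x)
    if (length(set) == 0L) {
      stop("FASTA file '", x, "' contains no sequence records.", call. = FALSE)
    }
    if (length(set) > 1L) {
      stop("FASTA file '", x, "' contains ", length(set),
           " records; the reference must be a single amplicon.", call. = FALSE)
    }
    seq <- toupper(as.character(set[[1L]]))
    if (is.null(name)) name <- names(set)[1L]
  } else if (looks_like_path) {
    stop("'", x, "' is neither an existing file nor a DNA sequence.",
         call. = FALSE)
  } else {
    seq <- toupper(gsub("[ \t\r\n]", "", x))
    if (is.null(name)) name <- "reference"
  }
  if (!nzchar(seq)) {
    stop("Reference sequence is empty.", call. = FALSE)
  }
  bad <- unique(strsplit(gsub("[ACGT]", "", seq), "")[[1L]])
  if (length(bad) > 0L) {
    stop("Reference contains invalid characters: ",
         paste(bad, collapse = ", "),
         " (only A/C/G/T are allowed; N is not permitted in the reference).",
         call. = FALSE)
  }
  ann <- NULL
  if (!is.null(annotation)) {
    ann <- tibble::as_tibble(annotation)
    if (!all(c("position", "label") %in% names(ann))) {
      stop("`annotation` must have columns 'position' and 'label'.",
           call. = FALSE)
    }
    if (!identical(sort(as.integer(ann$position)),
                   seq_len(nchar(seq)) - 1L)) {
      stop("`annotation` must cover every 0-based reference position ",
           "exactly once.", call. = FALSE)
    }
  }
  structure(list(name = name, sequence = seq, annotation = ann),
            class = "itd_reference")
}

#' @export
print.itd_reference <- function(x, ...) {
  cat("<itd_reference> ", x$name, ": ", nchar(x$sequence), " bp",
      if (!is.null(x$annotation)) " (annotated)", "\n", sep = "")
  invisible(x)
}

#' Write a reference amplicon to FASTA
#'
#' @param ref An `itd_reference`.
#' @param path Output file path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(ref, path, width = 60L) {
  stopifnot(inherits(ref, "itd_reference"))
  n <- nchar(ref$sequence)
  starts <- seq(1L, n, by = width)
  writeLines(c(paste0(">", ref$name),
               substring(ref$sequence, starts, pmin(starts + width - 1L, n))),
             path)
  invisible(path)
}

#' Packaged synthetic amplicon reference
#'
#' Returns the 600 bp synthetic amplicon shipped with the package. The
#' sequence is a fixed, seeded random sequence -- not a real gene -- so the
#' package is fully self-contained for simulation and testing; analyses of
#' real data should supply the actual sequenced amplicon via
#' [load_reference()].
#'
#' @return An `itd_reference` of length 600 bp.
#' @export
synthetic_reference <- function() {
  load_reference(system.file("extdata", "synthetic_amplicon.fasta",
                             package = "tandup"))
}

#' Maximum detectable ITD length for a given read length
#'
#' An internal tandem duplication is only called when the inserted copy is
#' seen alongside at least `min_insert_length` anchoring bases of the same
#' read, so the longest detectable insert is
#' `read_length - min_insert_length`. With 250 bp reads and the default
#' 6 bp minimum insert this gives 244 bp; longer duplications cannot be
#' recovered from a single read.
#'
#' @param read_length Read length in bp.
#' @param min_insert_length Minimum insert length in bp (default 6).
#' @return The maximum detectable duplication length in bp.
#' @examples
#' max_detectable_itd_length(250, 6)
#' @export
max_detectable_itd_length <- function(read_length, min_insert_length = 6L) {
  stopifnot(is.numeric(read_length), is.numeric(min_insert_length),
            min_insert_length >= 1)
  if (read_length < min_insert_length) {
    stop("`read_length` (", read_length, ") must be at least ",
         "`min_insert_length` (", min_insert_length, ").", call. = FALSE)
  }
  as.integer(read_length - min_insert_length)
}

#' Pipeline run parameters
#'
#' Collects all tunable parameters of the ITD calling pipeline with their
#' defaults. Every value is a knob; the defaults are this package's own
#' choices and are documented per argument.
#'
#' @param min_insert_length Minimum insert length (bp) for an ITD candidate;
#'   shorter insertions are never called (default 6).
#' @param read_length Expected read length hint in bp (default 250). Used by
#'   the score filter and trailing classification; per-read lengths are
#'   taken from the data.
#' @param min_mean_quality Minimum mean per-read Phred quality (default 25).
#' @param match Match reward (default 5).
#' @param mismatch Mismatch penalty, negative (default -15). The harsh
#'   penalty prevents the unsequenced-side tail of a trailing ITD from
#'   being absorbed into a spurious gap/match mosaic instead of being
#'   left as a free end overhang.
#' @param gap_open Cost of opening a gap, positive (default 29). A gap of
#'   length L costs `gap_open + (L - 1) * gap_extend`; with the defaults
#'   any insert costs a flat 29, just below the `match * min_insert_length`
#'   reward of the minimum anchor, so a true tandem-duplication insert
#'   with at least the minimum anchoring flank always beats end-clipping,
#'   whatever its length.
#' @param gap_extend Cost per additional gapped base (default 0). A zero
#'   extension cost keeps arbitrarily long tandem-duplication inserts in
#'   one contiguous gap run instead of scattering or truncating them.
#' @param min_score_fraction Alignments scoring below
#'   `min_score_fraction * read_length * match` are discarded as off-target
#'   (default 0.5).
#' @param tandem_max_mismatch_fraction Maximum mismatch fraction tolerated
#'   between an insert and its wild-type tandem copy (default 0.1), allowing
#'   ITDs that carry point mutations or non-templated junction bases.
#' @param min_supporting_reads Minimum supporting reads per reported clone
#'   (default 2). There is no VAF floor by default.
#' @param merge_site_tolerance Maximum difference (bp) between insertion
#'   sites merged into one clone, and the slack allowed when testing tandem
#'   adjacency (default 2).
#' @param require_both_mates For paired-end data, require each clone to be
#'   supported by both mates when both cover the site (default `FALSE`).
#' @param merge_trailing_with_exact Allow trailing and non-trailing calls at
#'   compatible sites to merge into one clone (default `FALSE`; they are
#'   different evidence classes).
#' @param fast_max_mismatch Reads whose best ungapped placement on the
#'   reference has at most this many mismatches are aligned by the
#'   seed-and-extend fast path; anything else goes through the full affine
#'   dynamic program (default 2).
#' @return An `itd_config` object (a validated named list).
#' @examples
#' cfg <- itd_config(min_insert_length = 9)
#' cfg$min_insert_length
#' @export
itd_config <- function(min_insert_length = 6L,
                       read_length = 250L,
                       min_mean_quality = 25,
                       match = 5,
                       mismatch = -15,
                       gap_open = 29,
                       gap_extend = 0,
                       min_score_fraction = 0.5,
                       tandem_max_mismatch_fraction = 0.1,
                       min_supporting_reads = 2L,
                       merge_site_tolerance = 2L,
                       require_both_mates = FALSE,
                       merge_trailing_with_exact = FALSE,
                       fast_max_mismatch = 2L) {
  cfg <- list(
    min_insert_length = as.integer(min_insert_length),
    read_length = as.integer(read_length),
    min_mean_quality = as.numeric(min_mean_quality),
    match = as.numeric(match),
    mismatch = as.numeric(mismatch),
    gap_open = as.numeric(gap_open),
    gap_extend = as.numeric(gap_extend),
    min_score_fraction = as.numeric(min_score_fraction),
    tandem_max_mismatch_fraction = as.numeric(tandem_max_mismatch_fraction),
    min_supporting_reads = as.integer(min_supporting_reads),
    merge_site_tolerance = as.integer(merge_site_tolerance),
    require_both_mates = isTRUE(require_both_mates),
    merge_trailing_with_exact = isTRUE(merge_trailing_with_exact),
    fast_max_mismatch = as.integer(fast_max_mismatch)
  )
  stopifnot(cfg$min_insert_length >= 1L,
            cfg$read_length >= cfg$min_insert_length,
            cfg$match > 0, cfg$mismatch <= 0,
            cfg$gap_open >= 0, cfg$gap_extend >= 0,
            cfg$min_score_fraction >= 0, cfg$min_score_fraction <= 1,
            cfg$tandem_max_mismatch_fraction >= 0,
            cfg$tandem_max_mismatch_fraction <= 1,
            cfg$min_supporting_reads >= 0L,
            cfg$merge_site_tolerance >= 0L,
            cfg$fast_max_mismatch >= 0L)
  structure(cfg, class = "itd_config")
}

#' @export
print.itd_config <- function(x, ...) {
  cat("<itd_config>\n")
  for (nm in names(x)) cat("  ", nm, " = ", format(x[[nm]]), "\n", sep = "")
  invisible(x)
}

as_itd_reference <- function(ref) {
  if (inherits(ref, "itd_reference")) return(ref)
  load_reference(ref)
}

annotate_position <- function(ref, pos) {
  if (is.null(ref$annotation)) return(rep(NA_character_, length(pos)))
  idx <- match(pos, ref$annotation$position)
  as.character(ref$annotation$label[idx])
}
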