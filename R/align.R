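#' Semi-global alignment of reads against the amplicon
#'
#' Reads are aligned to the reference with free end gaps on both sequences
#' (the read may map anywhere inside the amplicon, and trailing read
#' sequence may overhang unaligned) and affine gap penalties: a gap of
#' length L costs `gap_open + (L - 1) * gap_extend`. Higher scores are
#' better. The low extension cost makes a true tandem-duplication insert
#' emerge as one contiguous gap run in the reference row rather than as
#' scattered short gaps.
#'
#' @name alignment
NULL

substitution_matrix <- function(cfg) {
  Biostrings::nucleotideSubstitutionMatrix(match = cfg$match,
                                           mismatch = cfg$mismatch,
                                           baseOnly = TRUE)
}

#' Align one read semi-globally to the reference
#'
#' Computes the optimal-score alignment under the affine-gap scheme of
#' `config`, with end gaps free on both the read and the reference. This
#' is the exact dynamic program; the pipeline itself short-circuits
#' near-reference reads through a seed-and-extend fast path (see
#' [align_reads()]).
#'
#' @param read A DNA string (A/C/G/T).
#' @param ref An `itd_reference` (or sequence coercible to one).
#' @param config An [itd_config()].
#' @return A `pairwise_alignment` object: a list with gapped `read_row`
#'   and `ref_row` over the aligned region, `score`, 0-based half-open
#'   spans `ref_start`/`ref_end` (reference) and `read_start`/`read_end`
#'   (read), and `read_length`.
#' @examples
#' ref <- load_reference("ACGTACGTACGTACGTACGT")
#' align_semi_global(ref$sequence, ref)$score
#' @export
align_semi_global <- function(read, ref, config = itd_config()) {
  stopifnot(is.character(read), length(read) == 1L, nzchar(read))
  ref <- as_itd_reference(ref)
  tbl <- dp_align_set(read, ref$sequence, config)
  aln <- c(as.list(tbl[1L, ]), list(read = read, read_length = nchar(read)))
  structure(aln, class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment> score ", format(x$score),
      ", ref [", x$ref_start, ", ", x$ref_end, ")",
      ", read [", x$read_start, ", ", x$read_end, ") of ",
      x$read_length, " bp\n", sep = "")
  cat(render_alignment(x), sep = "\n")
  invisible(x)
}

# Full affine-gap dynamic program over a character vector of reads,
# via Biostrings. Free end gaps on both sequences are realised as local
# alignment: unalignable read ends (e.g. the junction-crossing tail of a
# trailing ITD) are clipped instead of forcing the alignment to a
# sequence boundary. Gap convention: Biostrings charges gapOpening +
# L * gapExtension for a length-L gap, so gapOpening is set to
# gap_open - gap_extend to realise gap_open + (L - 1) * gap_extend.
dp_align_set <- function(reads, ref_seq, cfg) {
  if (length(reads) == 0L) return(empty_alignment_tbl())
  if (any(grepl("[^ACGT]", reads))) {
    stop("Reads must contain only A/C/G/T at alignment ",
         "(N-containing reads are removed by quality_filter()).",
         call. = FALSE)
  }
  alns <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(reads),
    Biostrings::DNAString(ref_seq),
    substitutionMatrix = substitution_matrix(cfg),
    gapOpening = cfg$gap_open - cfg$gap_extend,
    gapExtension = cfg$gap_extend,
    type = "local"
  )
  pat <- Biostrings::pattern(alns)
  sub <- Biostrings::subject(alns)
  tibble::tibble(
    score = Biostrings::score(alns),
    ref_start = BiocGenerics::start(sub) - 1L,
    ref_end = BiocGenerics::end(sub),
    read_start = BiocGenerics::start(pat) - 1L,
    read_end = BiocGenerics::end(pat),
    read_row = as.character(pat),
    ref_row = as.character(sub),
    method = "dp"
  )
}

empty_alignment_tbl <- function() {
  tibble::tibble(score = numeric(), ref_start = integer(),
                 ref_end = integer(), read_start = integer(),
                 read_end = integer(), read_row = character(),
                 ref_row = character(), method = character())
}

# Hash of all k-mers of the reference; k-mers occurring more than once
# are dropped so a seed hit implies a unique candidate placement.
kmer_index <- function(ref_seq, k = 25L) {
  n <- nchar(ref_seq)
  if (n < k) return(list(k = k, kmers = character(), pos0 = integer()))
  starts <- seq_len(n - k + 1L)
  kmers <- substring(ref_seq, starts, starts + k - 1L)
  keep <- !(duplicated(kmers) | duplicated(kmers, fromLast = TRUE))
  list(k = k, kmers = kmers[keep], pos0 = starts[keep] - 1L)
}

# Optimal free end-clipping of an ungapped placement: given 0-based
# mismatch positions within the read, choose how many leading/trailing
# mismatches to clip so the aligned segment score is maximal.
best_clip <- function(mm_pos, len, match, mismatch) {
  k <- length(mm_pos)
  best <- NULL
  for (a in 0:k) {
    for (b in 0:(k - a)) {
      start <- if (a == 0L) 0L else mm_pos[a] + 1L
      end <- if (b == 0L) len else mm_pos[k - b + 1L]
      if (end <= start) next
      inner <- k - a - b
      sc <- match * (end - start - inner) + mismatch * inner
      if (is.null(best) || sc > best$score) {
        best <- list(read_start = start, read_end = end, score = sc,
                     n_mismatch = inner)
      }
    }
  }
  best
}

# Seed-based read placement. Three unique k-mer seeds (read start,
# middle, end) are looked up in the reference index; each hit implies a
# placement diagonal (reference offset minus read offset).
#
# * One diagonal: the read is reference-like; accept the (end-clipped)
#   ungapped placement when it has at most cfg$fast_max_mismatch
#   mismatches (with the default scoring such a placement beats any
#   gapped alternative, so this is score-equivalent to the full DP).
# * Two diagonals, tail upstream of head: the signature of a tandem
#   duplication. The duplication length is the diagonal difference --
#   exact by construction, immune to the spurious-island gap chaining
#   an unconstrained optimal alignment can fall into on the random-like
#   tail of a trailing read. The optimal junction split is found by a
#   vectorised scan, and the read is emitted either as a single-gap-run
#   alignment (insert fully contained) or as a clipped alignment whose
#   overhang carries the trailing insert.
# * Anything else (no seeds, three diagonals, deletion-like offsets,
#   out-of-range placements) falls through to the full dynamic program.
#
# Returns a tibble with one row per read and a `fast_ok` flag; rows with
# fast_ok == FALSE must be realigned by dp_align_set().
fast_place <- function(reads, ref_seq, cfg, index = NULL) {
  n <- length(reads)
  if (is.null(index)) index <- kmer_index(ref_seq)
  k <- index$k
  lens <- nchar(reads)
  ref_len <- nchar(ref_seq)

  diag <- matrix(NA_integer_, nrow = n, ncol = 3L)
  eligible <- which(lens >= k)
  if (length(eligible) > 0L && length(index$kmers) > 0L) {
    for (w in 1:3) {
      spos0 <- switch(w,
                      rep(0L, length(eligible)),
                      pmax(0L, lens[eligible] %/% 2L - k %/% 2L),
                      lens[eligible] - k)
      seeds <- substring(reads[eligible], spos0 + 1L, spos0 + k)
      hit <- match(seeds, index$kmers)
      found <- !is.na(hit)
      diag[eligible[found], w] <- index$pos0[hit[found]] - spos0[found]
    }
  }

  out <- tibble::tibble(
    score = rep(NA_real_, n), ref_start = rep(NA_integer_, n),
    ref_end = rep(NA_integer_, n), read_start = rep(NA_integer_, n),
    read_end = rep(NA_integer_, n), read_row = rep(NA_character_, n),
    ref_row = rep(NA_character_, n), method = rep("dp", n),
    fast_ok = rep(FALSE, n)
  )

  n_diag <- apply(diag, 1L, function(d) length(unique(d[!is.na(d)])))

  # --- single-diagonal reads: ungapped with optimal end clipping -------
  one <- which(n_diag == 1L)
  if (length(one) > 0L) {
    off1 <- apply(diag[one, , drop = FALSE], 1L, function(d) {
      d[!is.na(d)][1L]
    })
    valid <- off1 >= 0L & off1 + lens[one] <= ref_len
    one <- one[valid]
    off1 <- off1[valid]
    grp <- split(seq_along(one), list(off1, lens[one]), drop = TRUE)
    grp <- unlist(lapply(grp, function(g) {
      split(g, ceiling(seq_along(g) / 5000L))  # bound matrix size
    }), recursive = FALSE, use.names = FALSE)
    for (g in grp) {
      off <- off1[g[1L]]
      len <- lens[one[g[1L]]]
      window <- substr(ref_seq, off + 1L, off + len)
      wchars <- strsplit(window, "", fixed = TRUE)[[1L]]
      rchars <- matrix(unlist(strsplit(reads[one[g]], "", fixed = TRUE),
                              use.names = FALSE),
                       nrow = len)
      mm <- rchars != wchars
      ok <- which(colSums(mm) <= cfg$fast_max_mismatch)
      for (ii in ok) {
        i <- one[g[ii]]
        clip <- best_clip(which(mm[, ii]) - 1L, len, cfg$match,
                          cfg$mismatch)
        out$score[i] <- clip$score
        out$read_start[i] <- clip$read_start
        out$read_end[i] <- clip$read_end
        out$ref_start[i] <- off + clip$read_start
        out$ref_end[i] <- off + clip$read_end
        out$read_row[i] <- substr(reads[i], clip$read_start + 1L,
                                  clip$read_end)
        out$ref_row[i] <- substr(ref_seq, off + clip$read_start + 1L,
                                 off + clip$read_end)
        out$method[i] <- "fast"
        out$fast_ok[i] <- TRUE
      }
    }
  }

  # --- two-diagonal reads: duplication signature -----------------------
  two <- which(n_diag == 2L)
  for (i in two) {
    d <- diag[i, ]
    known <- which(!is.na(d))
    o_h <- d[known[1L]]                 # earliest seed: head diagonal
    o_t <- d[known[length(known)]]      # latest seed: tail diagonal
    if (length(known) == 3L && d[2L] != o_h && d[2L] != o_t) next
    D <- o_t - o_h
    if (D >= 0L) next                   # deletion-like: leave to the DP
    len <- lens[i]
    L <- -D
    if (o_t < 0L || o_h + len > ref_len) next
    rchars <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
    head_ref <- strsplit(substr(ref_seq, o_h + 1L, o_h + len), "",
                         fixed = TRUE)[[1L]]
    tail_ref <- strsplit(substr(ref_seq, o_t + 1L, o_t + len), "",
                         fixed = TRUE)[[1L]]
    head_sc <- ifelse(rchars == head_ref, cfg$match, cfg$mismatch)
    tail_sc <- ifelse(rchars == tail_ref, cfg$match, cfg$mismatch)
    H <- c(0, cumsum(head_sc))                 # H[c+1]: head over [0, c)
    Tsuf <- rev(c(0, cumsum(rev(tail_sc))))    # Tsuf[j+1]: tail over [j, len)
    # option 1: internal insert of length L after split c
    int_best <- -Inf
    int_c <- NA_integer_
    if (len > L) {
      cs <- 0:(len - L)
      sc_int <- H[cs + 1L] + Tsuf[cs + L + 1L] - cfg$gap_open -
        (L - 1L) * cfg$gap_extend
      int_best <- max(sc_int)
      int_c <- cs[which.max(sc_int)]
    }
    # option 2: head only, tail clipped (trailing insert in the overhang)
    sc_tr <- H
    tr_best <- max(sc_tr)
    tr_c <- (0:len)[which.max(sc_tr)]
    # option 3: whole read on the tail diagonal (head seed spurious)
    tail_best <- Tsuf[1L]
    best <- max(int_best, tr_best, tail_best)
    if (best == int_best) {
      c0 <- int_c
      out$score[i] <- int_best
      out$ref_start[i] <- o_h
      out$ref_end[i] <- o_h + len - L
      out$read_start[i] <- 0L
      out$read_end[i] <- len
      out$read_row[i] <- reads[i]
      out$ref_row[i] <- paste0(substr(ref_seq, o_h + 1L, o_h + c0),
                               strrep("-", L),
                               substr(ref_seq, o_t + c0 + L + 1L,
                                      o_t + len))
    } else if (best == tr_best) {
      c0 <- tr_c
      if (c0 == 0L) next                # nothing aligns: leave to the DP
      out$score[i] <- tr_best
      out$ref_start[i] <- o_h
      out$ref_end[i] <- o_h + c0
      out$read_start[i] <- 0L
      out$read_end[i] <- c0
      out$read_row[i] <- substr(reads[i], 1L, c0)
      out$ref_row[i] <- substr(ref_seq, o_h + 1L, o_h + c0)
    } else {
      out$score[i] <- tail_best
      out$ref_start[i] <- o_t
      out$ref_end[i] <- o_t + len
      out$read_start[i] <- 0L
      out$read_end[i] <- len
      out$read_row[i] <- reads[i]
      out$ref_row[i] <- substr(ref_seq, o_t + 1L, o_t + len)
    }
    out$method[i] <- "seed"
    out$fast_ok[i] <- TRUE
  }
  out
}

#' Align unique reads to the reference
#'
#' Aligns every unique read sequence once (results are weighted by
#' `count` downstream). Reads are first placed by unique k-mer seeds:
#' reference-like reads resolve to one placement diagonal and are scored
#' ungapped; reads carrying a tandem duplication resolve to two
#' diagonals whose difference is the duplication length, yielding either
#' a single-gap-run alignment or a clipped alignment with the trailing
#' insert in the overhang. Reads the seeds cannot place unambiguously
#' fall back to the full affine-gap dynamic program
#' ([align_semi_global()]). Alignments scoring below
#' `min_score_fraction * read_length * match` are flagged as failed
#' (off-target or garbage reads).
#'
#' @param unique_reads Tibble from [collapse_unique()] (columns `bases`,
#'   `count`, ...), or any tibble with a `bases` column.
#' @param ref An `itd_reference`.
#' @param config An [itd_config()].
#' @return The input tibble with alignment columns added: `score`,
#'   0-based half-open `ref_start`/`ref_end` and `read_start`/`read_end`,
#'   gapped `read_row`/`ref_row` over the aligned region, `method`
#'   (`"fast"` or `"dp"`) and `passed` (score filter).
#' @export
align_reads <- function(unique_reads, ref, config = itd_config()) {
  ref <- as_itd_reference(ref)
  reads <- unique_reads$bases
  fast <- fast_place(reads, ref$sequence, config)
  todo <- which(!fast$fast_ok)
  if (length(todo) > 0L) {
    dp <- dp_align_set(reads[todo], ref$sequence, config)
    for (col in names(dp)) fast[[col]][todo] <- dp[[col]]
  }
  fast$fast_ok <- NULL
  out <- dplyr::bind_cols(unique_reads, fast)
  out$passed <- passes_score_filter(out$score, nchar(reads), config)
  out
}

#' Alignment score filter
#'
#' An alignment passes when its score reaches at least
#' `min_score_fraction` of the maximum achievable score for the read
#' (`read_length * match`); the boundary is inclusive. Note that bases in
#' free end overhangs contribute nothing, so with the default fraction of
#' 0.5 a trailing-ITD read keeps support as long as its anchored portion
#' covers at least half the read.
#'
#' @param score Alignment score(s).
#' @param read_length Read length(s) in bp.
#' @param config An [itd_config()].
#' @return Logical vector.
#' @export
passes_score_filter <- function(score, read_length, config = itd_config()) {
  score >= config$min_score_fraction * read_length * config$match
}

#' Render an alignment as text
#'
#' Produces the classic three-row display: read row, connector row
#' (`|` for a match, `.` for a mismatch, blank opposite a gap) and
#' reference row, wrapped at `width` columns. Gaps are written as `-` in
#' the sequence rows. When an ITD call is supplied, a marker row flags
#' insert columns with `I` and wild-type tandem columns with `T`.
#'
#' @param aln A `pairwise_alignment` or one row of [align_reads()] output
#'   (as a list).
#' @param itd Optional one-row ITD call (from [find_tandem()] /
#'   [detect_itds()]) whose `read_offset`, `insert_length`, `tandem_start`
#'   and `tandem_end` refer to this read.
#' @param width Wrap width in columns (default 60).
#' @return Character vector of display lines.
#' @export
render_alignment <- function(aln, itd = NULL, width = 60L) {
  read_chars <- strsplit(aln$read_row, "", fixed = TRUE)[[1L]]
  ref_chars <- strsplit(aln$ref_row, "", fixed = TRUE)[[1L]]
  stopifnot(length(read_chars) == length(ref_chars))
  conn <- ifelse(read_chars == "-" | ref_chars == "-", " ",
                 ifelse(read_chars == ref_chars, "|", "."))
  marker <- NULL
  if (!is.null(itd)) {
    marker <- rep(" ", length(conn))
    read_pos <- cumsum(read_chars != "-") - 1L + aln$read_start
    ref_pos <- cumsum(ref_chars != "-") - 1L + aln$ref_start
    ins <- ref_chars == "-" &
      read_pos >= itd$read_offset &
      read_pos < itd$read_offset + itd$insert_length
    # trailing inserts live in the unaligned overhang; mark in-row part only
    marker[ins] <- "I"
    tand <- read_chars != "-" & ref_chars != "-" &
      ref_pos >= itd$tandem_start & ref_pos < itd$tandem_end
    marker[tand] <- ifelse(marker[tand] == "I", "I", "T")
  }
  n <- length(conn)
  out <- character(0)
  for (s in seq(1L, n, by = width)) {
    e <- min(s + width - 1L, n)
    block <- c(
      if (!is.null(marker)) paste(marker[s:e], collapse = ""),
      paste(read_chars[s:e], collapse = ""),
      paste(conn[s:e], collapse = ""),
      paste(ref_chars[s:e], collapse = ""),
      ""
    )
    out <- c(out, block)
  }
  out[-length(out)]
}
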