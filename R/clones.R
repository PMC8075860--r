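#' Clone-level aggregation and quantification
#'
#' Per-read ITD calls are merged into clones, quantified against
#' site-spanning coverage, filtered, and optionally tracked across
#' serial samples.
#'
#' @name clones
NULL

# Pairwise mergeability of two ITD calls. Both must belong to the same
# evidence class (trailing vs non-trailing) unless configured otherwise;
# non-trailing lengths must match exactly, trailing estimates within 3 bp;
# insertion sites within merge_site_tolerance; and the sequenced portions
# must be identical wherever they overlap. Portions are compared anchored
# at the duplication end they were sequenced from (a 3' overhang is a
# prefix of the insert, a 5' overhang a suffix), so two trailing calls
# whose length *estimates* differ by a base still compare their actual
# sequenced bases.
calls_compatible <- function(a, b, config) {
  if (isTRUE(a$trailing) != isTRUE(b$trailing) &&
      !config$merge_trailing_with_exact) {
    return(FALSE)
  }
  both_exact <- !isTRUE(a$trailing) && !isTRUE(b$trailing)
  len_ok <- if (both_exact) {
    a$length_estimate == b$length_estimate
  } else {
    abs(a$length_estimate - b$length_estimate) <= 3L
  }
  if (!len_ok) return(FALSE)
  if (abs(a$ref_pos - b$ref_pos) > config$merge_site_tolerance) return(FALSE)
  xa <- a$seg_end - a$seg_start
  xb <- b$seg_end - b$seg_start
  a_start <- a$seg_start == 0L          # prefix-anchored portion
  b_start <- b$seg_start == 0L
  a_end <- a$seg_end == a$length_estimate  # suffix-anchored portion
  b_end <- b$seg_end == b$length_estimate
  if (a_start && b_start) {
    o <- min(xa, xb)
    return(identical(substr(a$sequence, 1L, o), substr(b$sequence, 1L, o)))
  }
  if (a_end && b_end) {
    o <- min(xa, xb)
    return(identical(substr(a$sequence, xa - o + 1L, xa),
                     substr(b$sequence, xb - o + 1L, xb)))
  }
  # opposite anchors: overlap only if the portions together exceed the
  # (least constraining) length estimate
  est <- max(a$length_estimate, b$length_estimate)
  o <- xa + xb - est
  if (o <= 0L) return(TRUE)            # disjoint: nothing to contradict
  if (a_start) {
    sa <- substr(a$sequence, est - xb + 1L, xa)
    sb <- substr(b$sequence, 1L, o)
  } else {
    sa <- substr(a$sequence, 1L, o)
    sb <- substr(b$sequence, est - xa + 1L, xb)
  }
  identical(sa, sb)
}

union_find_groups <- function(n, compatible) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        if (compatible(i, j)) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Merge per-read ITD calls into clones
#'
#' Calls are merged by transitive closure over a pairwise rule: same
#' evidence class, identical length (non-trailing) or estimates within
#' 3 bp (trailing), insertion sites within `merge_site_tolerance`, and
#' identical insert sequence over the overlap of the sequenced portions.
#' The consensus insert is the most-supported call's sequence (ties
#' broken lexicographically). This delineates separate ITD clones within
#' one sample so each can be monitored on its own.
#'
#' @param calls ITD call tibble from [verify_tandems()], augmented with a
#'   `count` column (read multiplicity of the supporting unique read) and
#'   optionally `n_mate1`/`n_mate2`.
#' @param config An [itd_config()].
#' @return An unquantified clone tibble, sorted by descending support:
#'   `consensus_insert`, `length_estimate`, `exact_length`, `ref_pos`,
#'   `trailing`, `supporting_reads`, `supporting_unique`,
#'   `support_mate1`, `support_mate2`, `uids` (list of supporting
#'   alignment row indices).
#' @export
merge_calls <- function(calls, config = itd_config()) {
  if (nrow(calls) == 0L) {
    return(tibble::tibble(consensus_insert = character(),
                          length_estimate = integer(),
                          exact_length = logical(), ref_pos = integer(),
                          trailing = logical(), supporting_reads = integer(),
                          supporting_unique = integer(),
                          support_mate1 = integer(),
                          support_mate2 = integer(), uids = list()))
  }
  if (!"count" %in% names(calls)) calls$count <- 1L
  if (!"n_mate1" %in% names(calls)) calls$n_mate1 <- calls$count
  if (!"n_mate2" %in% names(calls)) calls$n_mate2 <- 0L
  # identical calls (same geometry and sequence) merge trivially; collapse
  # them first so the pairwise closure only visits distinct calls
  agg <- calls |>
    dplyr::summarise(
      count = sum(.data$count),
      n_mate1 = sum(.data$n_mate1),
      n_mate2 = sum(.data$n_mate2),
      uids = list(unique(.data$uid)),
      .by = c("sequence", "length_estimate", "exact_length", "ref_pos",
              "trailing", "seg_start", "seg_end")
    )
  n <- nrow(agg)
  ord_pairs <- function(i, j) {
    # cheap vector pre-rejects before the string comparison
    if (agg$trailing[i] != agg$trailing[j] &&
        !config$merge_trailing_with_exact) return(FALSE)
    calls_compatible(lapply(agg, `[`, i)[names(agg) != "uids"],
                     lapply(agg, `[`, j)[names(agg) != "uids"], config)
  }
  grp <- union_find_groups(n, function(i, j) {
    if (abs(agg$ref_pos[i] - agg$ref_pos[j]) > config$merge_site_tolerance)
      return(FALSE)
    if (abs(agg$length_estimate[i] - agg$length_estimate[j]) > 3L)
      return(FALSE)
    ord_pairs(i, j)
  })
  agg$.group <- grp
  agg |>
    dplyr::group_by(.data$.group) |>
    dplyr::group_map(function(g, key) {
      rep_i <- order(-g$count, g$sequence)[1L]
      tibble::tibble(
        consensus_insert = g$sequence[rep_i],
        length_estimate = g$length_estimate[rep_i],
        exact_length = g$exact_length[rep_i],
        ref_pos = g$ref_pos[rep_i],
        trailing = g$trailing[rep_i],
        supporting_reads = sum(g$count),
        supporting_unique = length(unique(unlist(g$uids))),
        support_mate1 = sum(g$n_mate1),
        support_mate2 = sum(g$n_mate2),
        uids = list(unique(unlist(g$uids)))
      )
    }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(dplyr::desc(.data$supporting_reads),
                   .data$consensus_insert)
}

#' Reads covering an insertion site
#'
#' Counts reads whose alignment spans both reference bases flanking the
#' insertion position (`ref[ref_pos - 1]` and `ref[ref_pos]`); at the
#' reference boundaries the single existing flanking base is used.
#' Supporting reads of a clone at this site always span it by
#' construction (a trailing read's aligned region ends exactly at the
#' site), so their alignment row indices can be passed via `support_uids`
#' to be counted regardless of the span rule.
#'
#' @param alignments Alignment tibble from [align_reads()] (rows failing
#'   the score filter are ignored).
#' @param ref_pos 0-based insertion position.
#' @param ref_length Reference length in bp.
#' @param support_uids Optional integer row indices of ITD-supporting
#'   alignments.
#' @return Total read count (sum of `count`) covering the site.
#' @export
compute_coverage <- function(alignments, ref_pos, ref_length,
                             support_uids = integer()) {
  stopifnot(ref_pos >= 0L, ref_pos <= ref_length)
  left_ok <- alignments$ref_start <= (if (ref_pos > 0L) ref_pos - 1L
                                      else ref_pos)
  right_ok <- alignments$ref_end >= (if (ref_pos < ref_length) ref_pos + 1L
                                     else ref_pos)
  spans <- alignments$passed & left_ok & right_ok
  spans[support_uids] <- TRUE
  sum(alignments$count[spans])
}

#' Variant allele frequency
#'
#' @param supporting_reads Reads supporting the ITD at the site.
#' @param coverage Reads covering the site.
#' @return `supporting_reads / coverage`.
#' @examples
#' compute_vaf(67000, 100000)
#' @export
compute_vaf <- function(supporting_reads, coverage) {
  stopifnot(all(coverage > 0), all(supporting_reads >= 0),
            all(supporting_reads <= coverage))
  supporting_reads / coverage
}

#' Convert between VAF and allelic ratio
#'
#' Fragment analysis conventionally reports the mutant-to-wild-type
#' allelic ratio AR; sequencing reports the variant allele frequency
#' VAF. The two are related by `AR = VAF / (1 - VAF)` and
#' `VAF = AR / (1 + AR)`; the functions are mutually inverse. A VAF of
#' exactly 1 maps to `Inf`.
#'
#' @param vaf Fraction in \[0, 1\].
#' @param ar Nonnegative allelic ratio.
#' @return The converted value(s).
#' @examples
#' vaf_to_ar(0.5)
#' ar_to_vaf(1)
#' @export
vaf_to_ar <- function(vaf) {
  stopifnot(all(vaf >= 0 & vaf <= 1))
  ifelse(vaf == 1, Inf, vaf / (1 - vaf))
}

#' @rdname vaf_to_ar
#' @export
ar_to_vaf <- function(ar) {
  stopifnot(all(ar >= 0))
  ifelse(is.infinite(ar), 1, ar / (1 + ar))
}

#' Filter quantified clones
#'
#' Retains clones with at least `min_supporting_reads` supporting reads.
#' When `require_both_mates` is set and the sample is paired-end with
#' both mates covering the insertion site, support from both mates is
#' required. There is no VAF floor by default. Removed clones are
#' recorded, with reasons, in the `"audit"` attribute (see
#' [clone_audit()]).
#'
#' @param clones Quantified clone tibble.
#' @param config An [itd_config()].
#' @param mate_coverage Optional named vector `c(mate1 = , mate2 = )` of
#'   site-covering read counts per mate, used for the both-mates rule.
#' @return The retained clones, with an `"audit"` attribute.
#' @export
apply_filters <- function(clones, config = itd_config(),
                          mate_coverage = NULL) {
  reason <- rep(NA_character_, nrow(clones))
  low <- clones$supporting_reads < config$min_supporting_reads
  reason[low] <- "support"
  if (config$require_both_mates && !is.null(mate_coverage) &&
      all(mate_coverage > 0)) {
    one_sided <- clones$support_mate1 == 0L | clones$support_mate2 == 0L
    reason[is.na(reason) & one_sided] <- "single_mate"
  }
  keep <- is.na(reason)
  audit <- clones[!keep, , drop = FALSE]
  audit$reason <- reason[!keep]
  out <- clones[keep, , drop = FALSE]
  attr(out, "audit") <- audit
  out
}

#' Audit table of filtered clones
#'
#' @param clones A clone tibble returned by [apply_filters()].
#' @return The removed clones with a `reason` column.
#' @export
clone_audit <- function(clones) {
  attr(clones, "audit", exact = TRUE)
}

#' Track ITD clones across serial samples
#'
#' Matches clones across samples using exactly the within-sample merge
#' rule (no looser cross-sample tolerance, so clone identity cannot
#' drift along an MRD series), then categorises each matched clone:
#' `persisting` (present at the first and last timepoints, e.g.
#' diagnosis and relapse), `lost` (first only), `gained` (last only),
#' `transient` (intermediate timepoints only).
#'
#' @param samples List of clone tibbles (as produced by [detect_itds()];
#'   must contain the call-geometry columns `consensus_insert`,
#'   `length_estimate`, `ref_pos`, `trailing`, `exact_length` and `vaf`),
#'   ordered by time.
#' @param labels Timepoint labels (default `names(samples)` or
#'   `t1, t2, ...`).
#' @param config An [itd_config()].
#' @return A long trajectory tibble: one row per clone and timepoint,
#'   with `clone_id`, `consensus_insert`, `length_estimate`, `ref_pos`,
#'   `trailing`, `category`, `timepoint` (ordered factor) and `vaf`
#'   (`NA` where undetected).
#' @export
track_clones <- function(samples, labels = NULL, config = itd_config()) {
  stopifnot(is.list(samples), length(samples) >= 2L)
  if (is.null(labels)) {
    labels <- names(samples)
    if (is.null(labels)) labels <- paste0("t", seq_along(samples))
  }
  stopifnot(length(labels) == length(samples))
  all_calls <- dplyr::bind_rows(
    lapply(seq_along(samples), function(k) {
      s <- tibble::as_tibble(samples[[k]])
      if (nrow(s) == 0L) return(NULL)
      tibble::tibble(
        sample_index = k,
        sequence = s$consensus_insert,
        length_estimate = s$length_estimate,
        ref_pos = s$ref_pos,
        trailing = s$trailing,
        seg_start = 0L,
        seg_end = nchar(s$consensus_insert),
        vaf = s$vaf
      )
    })
  )
  tp_levels <- labels
  if (is.null(all_calls) || nrow(all_calls) == 0L) {
    return(tibble::tibble(clone_id = integer(), consensus_insert = character(),
                          length_estimate = integer(), ref_pos = integer(),
                          trailing = logical(), category = character(),
                          timepoint = factor(character(), levels = tp_levels),
                          vaf = numeric()))
  }
  rows <- split(all_calls, seq_len(nrow(all_calls)))
  grp <- union_find_groups(nrow(all_calls), function(i, j) {
    calls_compatible(rows[[i]], rows[[j]], config)
  })
  all_calls$clone_id <- match(grp, unique(grp))
  n_tp <- length(samples)
  per_clone <- all_calls |>
    dplyr::summarise(
      consensus_insert = .data$sequence[1L],
      length_estimate = .data$length_estimate[1L],
      ref_pos = .data$ref_pos[1L],
      trailing = .data$trailing[1L],
      at_first = any(.data$sample_index == 1L),
      at_last = any(.data$sample_index == n_tp),
      .by = "clone_id"
    ) |>
    dplyr::mutate(category = dplyr::case_when(
      .data$at_first & .data$at_last ~ "persisting",
      .data$at_first ~ "lost",
      .data$at_last ~ "gained",
      TRUE ~ "transient"
    ))
  grid <- tidyr::expand_grid(clone_id = per_clone$clone_id,
                             sample_index = seq_len(n_tp))
  grid |>
    dplyr::left_join(
      all_calls |>
        dplyr::summarise(vaf = sum(.data$vaf),
                         .by = c("clone_id", "sample_index")),
      by = c("clone_id", "sample_index")
    ) |>
    dplyr::left_join(
      per_clone[, c("clone_id", "consensus_insert", "length_estimate",
                    "ref_pos", "trailing", "category")],
      by = "clone_id"
    ) |>
    dplyr::mutate(timepoint = factor(labels[.data$sample_index],
                                     levels = tp_levels)) |>
    dplyr::select("clone_id", "consensus_insert", "length_estimate",
                  "ref_pos", "trailing", "category", "timepoint", "vaf") |>
    dplyr::arrange(.data$clone_id, .data$timepoint)
}
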