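# Brute-force affine-gap local alignment (Gotoh three-state DP with a
# zero floor), written independently of the package's alignment path.
# A gap of length L costs gap_open + (L - 1) * gap_extend.
oracle_local_score <- function(read, ref, config = itd_config()) {
  a <- strsplit(read, "", fixed = TRUE)[[1L]]
  b <- strsplit(ref, "", fixed = TRUE)[[1L]]
  n <- length(a)
  m <- length(b)
  open <- config$gap_open
  ext <- config$gap_extend
  H <- matrix(0, n + 1L, m + 1L)   # match/mismatch state (0-floored)
  E <- matrix(-Inf, n + 1L, m + 1L) # gap in reference row (read insertion)
  F <- matrix(-Inf, n + 1L, m + 1L) # gap in read row (deletion)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (a[i] == b[j]) config$match else config$mismatch
      E[i + 1L, j + 1L] <- max(H[i, j + 1L] - open, E[i, j + 1L] - ext)
      F[i + 1L, j + 1L] <- max(H[i + 1L, j] - open, F[i + 1L, j] - ext)
      H[i + 1L, j + 1L] <- max(0,
                               H[i, j] + s,
                               E[i, j] + s,
                               F[i, j] + s)
      best <- max(best, H[i + 1L, j + 1L], E[i + 1L, j + 1L],
                  F[i + 1L, j + 1L])
    }
  }
  best
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# reproducible sequence without touching the caller's RNG stream
random_dna_fixed <- function(n, seed) {
  withr::with_seed(seed, random_dna(n))
}

# quick reads tibble around bare sequences (constant Q37)
reads_tbl <- function(bases, mate = 1L) {
  tibble::tibble(
    read_id = sprintf("r%03d", seq_along(bases)),
    bases = bases,
    quality = strrep("F", nchar(bases)),
    mate = rep(mate, length.out = length(bases))
  )
}
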