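# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (explicit loops, no shared code with the package
# internals they check).

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# oracle: all windows of |motif| bases with <= k mismatches, by direct
# character comparison
oracle_motif_scan <- function(bases, motif, k = 0L) {
  bs <- strsplit(bases, "")[[1L]]
  ms <- strsplit(motif, "")[[1L]]
  m <- length(ms)
  n <- length(bs) - m + 1L
  if (n < 1L) return(integer(0L))
  starts <- integer(0L)
  for (i in seq_len(n)) {
    mm <- sum(bs[i:(i + m - 1L)] != ms)
    if (mm <= k) starts <- c(starts, i)
  }
  starts
}

# oracle: greedy left-to-right non-overlapping scan for the two DBT motifs
oracle_dbt_scan <- function(bases, k = 1L) {
  s1 <- oracle_motif_scan(bases, dbt_motifs()[["type1"]], k)
  s2 <- oracle_motif_scan(bases, dbt_motifs()[["type2"]], k)
  cand <- data.frame(start = c(s1, s2),
                     type = c(rep(1L, length(s1)), rep(2L, length(s2))))
  if (!nrow(cand)) return(cand)
  # prefer the fewer-mismatch motif at equal starts, matching the scanner
  mm_of <- function(st, ty) {
    motif <- dbt_motifs()[[ty]]
    sum(strsplit(substr(bases, st, st + 23L), "")[[1L]] !=
          strsplit(motif, "")[[1L]])
  }
  cand$mm <- mapply(function(s, t) mm_of(s, c("type1", "type2")[t]),
                    cand$start, cand$type)
  cand <- cand[order(cand$start, cand$mm, cand$type), ]
  out <- cand[0, ]
  last_end <- 0L
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] > last_end) {
      out <- rbind(out, cand[i, ])
      last_end <- cand$start[i] + 23L
    }
  }
  out
}

# oracle: per-base sliding-window-mean quality labels recomputed with
# explicit loops (window starting at each base, clipped; boundary refined
# at the per-base threshold crossing)
oracle_quality_labels <- function(quals, window, min_q) {
  n <- length(quals)
  lab <- character(n)
  for (i in seq_len(n)) {
    w <- quals[i:min(n, i + window - 1L)]
    lab[i] <- if (mean(w) >= min_q) "high" else "low"
  }
  lab
}

expect_tiles <- function(segments, len) {
  expect_equal(segments$start[1L], 1L)
  expect_equal(segments$end[nrow(segments)], len)
  if (nrow(segments) > 1L) {
    expect_equal(segments$start[-1L], segments$end[-nrow(segments)] + 1L)
  }
}

test_protocol <- function() default_protocol()

# minimal element-hit tibble for context tests
hit_stub <- function(start, end, label = "vector", strand = "+") {
  n <- length(start)
  tibble::tibble(label = rep_len(label, n), start = as.integer(start),
                 end = as.integer(end), strand = rep_len(strand, n),
                 kind = "vector", mismatches = 0L,
                 matched = as.double(end - start + 1L),
                 matched_fraction = 1, vstart = NA_integer_,
                 vend = NA_integer_)
}
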