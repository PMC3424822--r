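# Atomic terminus-component detection: quality segmentation, motif scans,
# poly-tail runs, vector local alignments, and flank context labels.
# All intervals are 1-based inclusive.

hit_rows <- function(label, start, end, strand, kind, mismatches, matched,
                     vstart = NA_integer_, vend = NA_integer_) {
  n <- length(start)
  start <- as.integer(start); end <- as.integer(end)
  tibble::new_tibble(list(
    label = rep_len(label, n), start = start, end = end,
    strand = rep_len(strand, n), kind = rep_len(kind, n),
    mismatches = as.integer(mismatches), matched = as.double(matched),
    matched_fraction = as.double(matched) / (end - start + 1L),
    vstart = as.integer(rep_len(vstart, n)),
    vend = as.integer(rep_len(vend, n))), nrow = n)
}

empty_hits <- function() {
  hit_rows(character(0L), integer(0L), integer(0L), character(0L),
           character(0L), integer(0L), double(0L))
}

#' Segment a read into high- and low-quality regions
#'
#' Sliding-window mean phred segmentation: a window of `window` bases whose
#' mean quality reaches `min_q` marks its start base high quality; maximal
#' same-label runs are merged and each high/low boundary is then refined to
#' the exact base where the per-base quality crosses `min_q`, so clean
#' quality transitions segment exactly at the transition point. A read
#' without qualities is a single all-high segment.
#'
#' @param quals Integer vector of per-base phred scores, or `NULL`.
#' @param len Read length in bases (required when `quals` is `NULL`).
#' @param window Sliding window width (bases).
#' @param min_q Mean phred threshold for "high" quality.
#' @return A tibble of ordered, non-overlapping segments (`start`, `end`,
#'   `label` in `high`/`low`) that jointly cover the read.
#' @export
segment_quality <- function(quals, len = length(quals), window = 20L, min_q = 16) {
  if (window < 1L) stop_validation("window must be >= 1")
  if (is.null(quals) || !length(quals)) {
    if (len < 1L) return(tibble(start = integer(), end = integer(), label = character()))
    return(tibble(start = 1L, end = as.integer(len), label = "high"))
  }
  if (!is.null(len) && len != length(quals)) {
    stop_validation("quality/base length mismatch (%d vs %d)", length(quals), len)
  }
  n <- length(quals)
  w <- min(window, n)
  # mean of the window starting at each base (trailing windows clipped)
  cs <- cumsum(c(0, quals))
  starts <- seq_len(n)
  wend <- pmin(starts + w - 1L, n)
  means <- (cs[wend + 1L] - cs[starts]) / (wend - starts + 1L)
  lab <- ifelse(means >= min_q, "high", "low")
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  seg <- tibble(start = c(1L, utils::head(ends, -1L) + 1L),
                end = as.integer(ends), label = r$values)
  # refine each boundary to the per-base crossing
  if (nrow(seg) > 1L) {
    for (i in seq_len(nrow(seg) - 1L)) {
      b <- seg$end[i]  # last base of segment i under the window labelling
      if (seg$label[i] == "high") {
        while (b < n && quals[b + 1L] >= min_q) b <- b + 1L
        while (b > seg$start[i] && quals[b] < min_q) b <- b - 1L
      } else {
        while (b < n && quals[b + 1L] < min_q) b <- b + 1L
        while (b > seg$start[i] && quals[b] >= min_q) b <- b - 1L
      }
      seg$end[i] <- b
      seg$start[i + 1L] <- b + 1L
    }
    seg <- seg[seg$end >= seg$start, , drop = FALSE]
    # merge adjacent same-label segments created by refinement
    keep <- c(TRUE, seg$label[-1L] != seg$label[-nrow(seg)])
    grp <- cumsum(keep)
    seg <- tibble(start = as.integer(tapply(seg$start, grp, min)),
                  end = as.integer(tapply(seg$end, grp, max)),
                  label = seg$label[keep])
  }
  seg$start <- as.integer(seg$start); seg$end <- as.integer(seg$end)
  seg
}

#' Find all occurrences of a short motif, allowing mismatches
#'
#' Reports every window of `nchar(motif)` bases with at most `max_mismatch`
#' substitutions, sorted by start (a fixed-width Hamming scan, delegated to
#' `Biostrings::matchPattern`).
#'
#' @param bases DNA string to scan.
#' @param motif DNA motif (length >= 1).
#' @param max_mismatch Maximum substitutions allowed (< motif length).
#' @param label Optional label for the hits (defaults to the motif).
#' @return An element-hit tibble.
#' @export
find_motif_hits <- function(bases, motif, max_mismatch = 0L, label = motif) {
  if (!nzchar(motif)) stop_validation("empty motif")
  m <- nchar(motif)
  if (max_mismatch >= m) stop_validation("max_mismatch must be < motif length")
  L <- nchar(bases)
  if (L < m) return(empty_hits())
  # vectorized windowed Hamming scan: one pass per motif position
  x <- utf8ToInt(bases)
  mo <- utf8ToInt(motif)
  n <- L - m + 1L
  mm <- integer(n)
  for (j in seq_len(m)) {
    mm <- mm + (x[j:(n + j - 1L)] != mo[j])
  }
  st <- which(mm <= max_mismatch)
  if (!length(st)) return(empty_hits())
  kind <- if (m >= 8L) "adapter" else "enzyme_site"
  hit_rows(label, st, st + m - 1L, "+", kind, mm[st], m - mm[st])
}

#' Find poly(A)/poly(T) tails
#'
#' Maximal runs of a single base, tolerating interior impurities up to
#' `max_impurity` of the run length; runs shorter than `min_len` are
#' dropped. Disjoint tails are all reported (abnormal reads can carry
#' several poly(A) fragments).
#'
#' @param bases DNA string.
#' @param base `"A"` or `"T"`.
#' @param min_len Minimum reported run length.
#' @param max_impurity Maximum fraction of interior non-`base` positions.
#' @return An element-hit tibble with label `polyA`/`polyT`.
#' @export
find_poly_tail <- function(bases, base, min_len = 8L, max_impurity = 0.1) {
  stopifnot(base %in% c("A", "T"))
  if (min_len < 2L) stop_validation("min_len must be >= 2")
  x <- utf8ToInt(bases) == utf8ToInt(base)
  if (!any(x)) return(empty_hits())
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rs <- starts[r$values]; re <- ends[r$values]
  # merge pure runs across single-base interior impurities while the total
  # impurity stays within budget (scattered single miscalls, not gaps)
  if (length(rs) > 1L) {
    ms <- rs[1L]; me <- re[1L]
    for (i in 2L:length(rs)) {
      k <- length(ms)
      gap <- rs[i] - me[k] - 1L
      span <- re[i] - ms[k] + 1L
      impure <- span - sum(x[ms[k]:re[i]])
      if (gap == 1L && impure <= floor(max_impurity * span)) {
        me[k] <- re[i]
      } else {
        ms <- c(ms, rs[i]); me <- c(me, re[i])
      }
    }
    rs <- ms; re <- me
  }
  keep <- re - rs + 1L >= min_len
  rs <- rs[keep]; re <- re[keep]
  if (!length(rs)) return(empty_hits())
  matched <- vapply(seq_along(rs), function(i) sum(x[rs[i]:re[i]]), integer(1L))
  hit_rows(paste0("poly", base), rs, re, "+", "poly_tail",
           (re - rs + 1L) - matched, matched)
}

# ---- vector local alignments -------------------------------------------

VEC_SEED_K <- 12L

# memoised k-mer index of a vector sequence (both strands)
vector_index <- local({
  cache <- new.env(parent = emptyenv())
  function(vector_seq) {
    key <- paste0("v", nchar(vector_seq), "_",
                  substr(vector_seq, 1L, 40L),
                  substr(vector_seq, nchar(vector_seq) - 39L, nchar(vector_seq)))
    if (!is.null(cache[[key]])) return(cache[[key]])
    k <- VEC_SEED_K
    kmers_of <- function(s) {
      n <- nchar(s) - k + 1L
      substring(s, 1:n, k:nchar(s))
    }
    idx <- list(seq = vector_seq, rcseq = rc(vector_seq),
                fwd = kmers_of(vector_seq))
    idx$rev <- kmers_of(idx$rcseq)
    cache[[key]] <- idx
    idx
  }
})

# ungapped two-sided extension of a diagonal seed block; +1 match / -3
# mismatch X-drop, returns the maximal-scoring extension
extend_diag <- function(rch, sch, r1, r2, s1, s2) {
  n_r <- length(rch); n_s <- length(sch)
  # left
  m <- min(r1, s1) - 1L
  if (m > 0L) {
    cmp <- rch[(r1 - 1L):(r1 - m)] == sch[(s1 - 1L):(s1 - m)]
    sc <- cumsum(ifelse(cmp, 1L, -3L))
    best <- which.max(sc)
    if (sc[best] > 0L) { r1 <- r1 - best; s1 <- s1 - best }
  }
  # right
  m <- min(n_r - r2, n_s - s2)
  if (m > 0L) {
    cmp <- rch[(r2 + 1L):(r2 + m)] == sch[(s2 + 1L):(s2 + m)]
    sc <- cumsum(ifelse(cmp, 1L, -3L))
    best <- which.max(sc)
    if (sc[best] > 0L) { r2 <- r2 + best; s2 <- s2 + best }
  }
  c(r1, r2, s1, s2)
}

#' Locate cloning-vector fragments in a read
#'
#' Seed-and-extend local matching of the read against both strands of the
#' vector: exact 12-mer seeds are grouped by alignment diagonal, extended
#' without gaps (gapped candidates are refined with a banded local
#' alignment), and reported when the aligned block reaches `min_len` bases
#' at `min_identity`. Hits carry the matching vector interval and strand.
#'
#' @param bases Read DNA string.
#' @param vector_seq Vector DNA string (or an `est_protocol`).
#' @param min_len Minimum aligned length.
#' @param min_identity Minimum identity of the aligned block.
#' @return An element-hit tibble (kind `vector`), with `vstart`/`vend` in
#'   vector coordinates and `strand` `"+"`/`"-"`.
#' @export
find_vector_hits <- function(bases, vector_seq, min_len = 20L, min_identity = 0.94) {
  if (inherits(vector_seq, "est_protocol")) vector_seq <- vector_seq$vector_seq
  if (nchar(vector_seq) < min_len) stop_validation("vector shorter than min_len")
  L <- nchar(bases)
  if (L < VEC_SEED_K) return(empty_hits())
  idx <- vector_index(vector_seq)
  rkm <- substring(bases, 1:(L - VEC_SEED_K + 1L), VEC_SEED_K:L)
  rch <- strsplit(bases, "", fixed = TRUE)[[1L]]
  out <- list()
  for (strand in c("+", "-")) {
    subj <- if (strand == "+") idx$seq else idx$rcseq
    km <- if (strand == "+") idx$fwd else idx$rev
    seeds <- seed_pairs(rkm, km)
    if (!nrow(seeds)) next
    sch <- strsplit(subj, "", fixed = TRUE)[[1L]]
    hits <- extend_seed_groups(seeds, rch, sch, bases, subj,
                               min_len, min_identity)
    if (!is.null(hits) && nrow(hits)) {
      hits$strand <- strand
      out[[strand]] <- hits
    }
  }
  if (!length(out)) return(empty_hits())
  h <- dplyr::bind_rows(out)
  # map subject coords to vector coords for '-' hits
  V <- nchar(vector_seq)
  neg <- h$strand == "-"
  vs <- ifelse(neg, V - h$send + 1L, h$sstart)
  ve <- ifelse(neg, V - h$sstart + 1L, h$send)
  res <- hit_rows("vector", h$rstart, h$rend, "+", "vector",
                  h$mismatches, h$matched)
  res$strand <- h$strand
  res$vstart <- as.integer(vs); res$vend <- as.integer(ve)
  res <- res[order(res$start, res$end), , drop = FALSE]
  dedupe_contained(res)
}

seed_pairs <- function(read_kmers, subj_kmers) {
  # all (read pos, subject pos) pairs sharing a k-mer
  m <- match(read_kmers, subj_kmers)
  first <- which(!is.na(m))
  if (!length(first)) return(data.frame(rpos = integer(), spos = integer()))
  # duplicated subject k-mers: expand via split lookup only when needed
  dup <- anyDuplicated(subj_kmers) > 0L
  if (!dup) return(data.frame(rpos = first, spos = m[first]))
  pos_list <- split(seq_along(subj_kmers), subj_kmers)
  res_r <- integer(0L); res_s <- integer(0L)
  for (i in first) {
    sp <- pos_list[[read_kmers[i]]]
    res_r <- c(res_r, rep.int(i, length(sp)))
    res_s <- c(res_s, sp)
  }
  data.frame(rpos = res_r, spos = res_s)
}

extend_seed_groups <- function(seeds, rch, sch, bases, subj, min_len, min_identity) {
  k <- VEC_SEED_K
  seeds$diag <- seeds$rpos - seeds$spos
  seeds <- seeds[order(seeds$diag, seeds$rpos), , drop = FALSE]
  # group seeds with nearby diagonals and read gaps
  grp <- cumsum(c(TRUE, diff(seeds$diag) > 4L |
                    abs(diff(seeds$rpos)) > 60L))
  res <- list()
  for (g in split(seeds, grp)) {
    r1 <- min(g$rpos); r2 <- max(g$rpos) + k - 1L
    s1 <- min(g$spos); s2 <- max(g$spos) + k - 1L
    if (length(unique(g$diag)) == 1L) {
      e <- extend_diag(rch, sch, r1, r2, s1, s2)
      seg_r <- rch[e[1L]:e[2L]]; seg_s <- sch[e[3L]:e[4L]]
      mm <- sum(seg_r != seg_s)
      len <- e[2L] - e[1L] + 1L
      if (len >= min_len && (len - mm) / len >= min_identity) {
        res[[length(res) + 1L]] <- data.frame(
          rstart = e[1L], rend = e[2L], sstart = e[3L], send = e[4L],
          mismatches = mm, matched = len - mm)
      }
    } else {
      # indel candidate: refine with a local alignment on padded substrings
      pr1 <- max(1L, r1 - 25L); pr2 <- min(length(rch), r2 + 25L)
      ps1 <- max(1L, s1 - 25L); ps2 <- min(length(sch), s2 + 25L)
      al <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(substr(bases, pr1, pr2)),
        Biostrings::DNAString(substr(subj, ps1, ps2)),
        type = "local")
      len <- Biostrings::nchar(al)
      matched <- Biostrings::nmatch(al)
      if (len >= min_len && matched / len >= min_identity) {
        pat <- Biostrings::pattern(al); sub <- Biostrings::subject(al)
        res[[length(res) + 1L]] <- data.frame(
          rstart = pr1 + Biostrings::start(pat) - 1L,
          rend = pr1 + Biostrings::end(pat) - 1L,
          sstart = ps1 + Biostrings::start(sub) - 1L,
          send = ps1 + Biostrings::end(sub) - 1L,
          mismatches = as.integer(len - matched), matched = matched)
      }
    }
  }
  if (!length(res)) return(NULL)
  dplyr::bind_rows(res)
}

# drop hits whose read interval is contained in another hit of the same strand
dedupe_contained <- function(h) {
  if (nrow(h) < 2L) return(h)
  keep <- rep(TRUE, nrow(h))
  for (i in seq_len(nrow(h))) {
    for (j in seq_len(nrow(h))) {
      if (i != j && keep[i] && keep[j] && h$strand[i] == h$strand[j] &&
          h$start[j] <= h$start[i] && h$end[j] >= h$end[i] &&
          (h$end[j] - h$start[j]) > (h$end[i] - h$start[i])) {
        keep[i] <- FALSE
      }
    }
  }
  h[keep, , drop = FALSE]
}

#' Classify the context of a read interval
#'
#' Labels an interval by its dominant content: `V` if at least half of it is
#' covered by vector alignments, else `N`; `H` if at least half lies in
#' high-quality segments, else `L`. Returns the combined four-way label used
#' in terminus context scoring (`HV`, `LV`, `HN`, `LN`).
#'
#' @param start,end Interval on the read (1-based inclusive).
#' @param vector_hits Element-hit tibble from [find_vector_hits()].
#' @param segments Quality segments from [segment_quality()].
#' @return One of `"HV"`, `"LV"`, `"HN"`, `"LN"`.
#' @export
classify_context <- function(start, end, vector_hits, segments) {
  if (end < start) stop_validation("empty interval")
  len <- end - start + 1L
  vcov <- interval_coverage(start, end, vector_hits$start, vector_hits$end)
  hseg <- segments[segments$label == "high", , drop = FALSE]
  hcov <- interval_coverage(start, end, hseg$start, hseg$end)
  paste0(if (hcov >= len / 2) "H" else "L",
         if (vcov >= len / 2) "V" else "N")
}

interval_coverage <- function(start, end, hs, he) {
  if (!length(hs)) return(0L)
  cov <- rep(FALSE, end - start + 1L)
  for (i in seq_along(hs)) {
    a <- max(start, hs[i]); b <- min(end, he[i])
    if (a <= b) cov[(a - start + 1L):(b - start + 1L)] <- TRUE
  }
  sum(cov)
}

# ---- full element scan for one read ------------------------------------

# derive vector-border (VF1/VF2, sense and rc) element hits from vector
# alignments; mapping assumes collinearity within a hit (indels shift the
# border by at most the hit's indel count)
vf_element_hits <- function(vector_hits, protocol, min_overlap = 15L) {
  if (!nrow(vector_hits)) return(empty_hits())
  out <- list()
  borders <- list(VF1 = protocol$vf1, VF2 = protocol$vf2)
  for (i in seq_len(nrow(vector_hits))) {
    h <- vector_hits[i, ]
    for (b in names(borders)) {
      iv <- borders[[b]]
      a <- max(h$vstart, iv[1L]); z <- min(h$vend, iv[2L])
      if (z - a + 1L < min_overlap) next
      if (h$strand == "+") {
        rs <- h$start + (a - h$vstart); re <- h$start + (z - h$vstart)
        lab <- b
      } else {
        rs <- h$start + (h$vend - z); re <- h$start + (h$vend - a)
        lab <- paste0(b, "rc")
      }
      frac <- h$matched_fraction
      out[[length(out) + 1L]] <- hit_rows(
        lab, rs, re, h$strand, "vector_border",
        round((1 - frac) * (re - rs + 1L)), round(frac * (re - rs + 1L)),
        a, z)
    }
  }
  if (!length(out)) return(empty_hits())
  dplyr::bind_rows(out)
}

# context-restricted rescue of degraded enzyme sites: 1-mismatch hits are
# accepted only when flanked on both sides (within gap_tol) by another
# detected element or by vector alignment
rescue_enzyme_hits <- function(bases, exact_hits, neighbors, vector_hits,
                               motifs, gap_tol = 2L, max_mismatch = 1L) {
  if (max_mismatch < 1L) return(empty_hits())
  out <- list()
  near <- function(s, e) {
    # wholly inside a vector alignment counts as flanked on both sides
    if (nrow(vector_hits) &&
        any(vector_hits$start <= s & vector_hits$end >= e)) {
      return(TRUE)
    }
    lft <- any(neighbors$end >= s - 1L - gap_tol & neighbors$end <= s + 1L) ||
      (nrow(vector_hits) &&
         any(vector_hits$end >= s - 1L - gap_tol & vector_hits$end <= s + 1L))
    rgt <- any(neighbors$start >= e - 1L & neighbors$start <= e + 1L + gap_tol) ||
      (nrow(vector_hits) &&
         any(vector_hits$start >= e - 1L & vector_hits$start <= e + 1L + gap_tol))
    lft && rgt
  }
  for (lab in names(motifs)) {
    m <- motifs[[lab]]
    cand <- find_motif_hits(bases, m, max_mismatch = max_mismatch, label = lab)
    cand <- cand[cand$mismatches > 0L, , drop = FALSE]
    if (!nrow(cand)) next
    ex <- exact_hits[exact_hits$label == lab, , drop = FALSE]
    keep <- vapply(seq_len(nrow(cand)), function(i) {
      # skip candidates overlapping an exact hit of the same motif
      if (nrow(ex) && any(pmin(ex$end, cand$end[i]) >= pmax(ex$start, cand$start[i]))) {
        return(FALSE)
      }
      near(cand$start[i], cand$end[i])
    }, logical(1L))
    out[[lab]] <- cand[keep, , drop = FALSE]
  }
  if (!length(out)) return(empty_hits())
  dplyr::bind_rows(out)
}

# all element hits for one read under one protocol + parameter set
detect_read_elements <- function(bases, protocol, params) {
  p <- params
  vec_hits <- find_vector_hits(bases, protocol$vector_seq,
                               min_len = p$vector_min_len,
                               min_identity = p$vector_min_identity)
  vf <- vf_element_hits(vec_hits, protocol, min_overlap = p$vf_min_overlap)
  enz <- dplyr::bind_rows(
    find_motif_hits(bases, protocol$enzyme1, p$enzyme_max_mismatch, "EcoRI"),
    find_motif_hits(bases, protocol$enzyme2, p$enzyme_max_mismatch, "XhoI"))
  ad <- dplyr::bind_rows(
    find_motif_hits(bases, protocol$adapter_sense, p$adapter_max_mismatch,
                    "Adapter1"),
    find_motif_hits(bases, protocol$adapter_antisense, p$adapter_max_mismatch,
                    "Adapter1rc"))
  poly <- dplyr::bind_rows(
    find_poly_tail(bases, "A", p$poly_min_len, p$poly_max_impurity),
    find_poly_tail(bases, "T", p$poly_min_len, p$poly_max_impurity))
  neighbors <- dplyr::bind_rows(vf, ad, poly)
  rescued <- if (p$enzyme_rescue_mismatch > 0L) {
    rescue_enzyme_hits(bases, enz, neighbors, vec_hits,
                       stats::setNames(list(protocol$enzyme1, protocol$enzyme2),
                                       c("EcoRI", "XhoI")),
                       gap_tol = p$max_gap, max_mismatch = p$enzyme_rescue_mismatch)
  } else empty_hits()
  elements <- dplyr::bind_rows(vf, enz, rescued, ad, poly)
  elements <- elements[order(elements$start, elements$end), , drop = FALSE]
  list(vector_hits = vec_hits, elements = elements)
}
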