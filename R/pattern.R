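# Terminus assembly, Eq.-style confidence scoring, pattern-string
# construction, and reasonable-pair selection.

empty_termini <- function() {
  tibble(def_name = character(), family = character(),
         start = integer(), end = integer(),
         n_elements = integer(), a_count = integer(),
         matched = double(),
         a_score = double(), b_score = double(), c_score = double(),
         confidence = double(), components = list())
}

#' Assemble terminus instances from element hits
#'
#' Chains adjacent element hits (component gaps within `max_gap` bases;
#' small overlaps from alignment jitter are tolerated) into every terminus
#' definition of the protocol whose element order they match. Single-base
#' components (the replaced-site G/C of the `3TSS-4`/`5TNS-4` variants) are
#' matched directly against the read. Overlapping variants at one locus are
#' all produced; disambiguation happens after scoring.
#'
#' @param hits Element-hit tibble (sorted by start), e.g. the `elements`
#'   part of an internal element scan.
#' @param protocol An `est_protocol`.
#' @param max_gap Maximum gap between consecutive components.
#' @param bases The read sequence (needed for single-base components).
#' @return An (unscored) terminus-hit tibble.
#' @export
assemble_termini <- function(hits, protocol, max_gap = 2L, bases = NULL) {
  if (!nrow(hits)) return(empty_termini())
  h_label <- hits$label; h_start <- hits$start
  h_end <- hits$end; h_matched <- hits$matched
  acc <- list(def_name = character(0L), family = character(0L),
              start = integer(0L), end = integer(0L),
              n_elements = integer(0L), a_count = integer(0L),
              matched = double(0L))
  comp_idx <- list()
  for (def in protocol$termini) {
    labels <- vapply(def$elements, `[[`, character(1L), "label")
    kinds <- vapply(def$elements, `[[`, character(1L), "kind")
    starts <- which(h_label == labels[1L])
    for (s in starts) {
      idx <- s
      cur_end <- h_end[s]
      ok <- TRUE
      extra_matched <- 0
      if (length(labels) > 1L) {
        for (j in 2L:length(labels)) {
          if (kinds[j] == "single_base") {
            b <- if (is.null(bases)) "" else substr(bases, cur_end + 1L, cur_end + 1L)
            if (b != def$elements[[j]]$motif) { ok <- FALSE; break }
            cur_end <- cur_end + 1L
            extra_matched <- extra_matched + 1
            next
          }
          cand <- which(h_label == labels[j] &
                          h_start >= cur_end - 1L &
                          h_start <= cur_end + 1L + max_gap)
          if (!length(cand)) { ok <- FALSE; break }
          # prefer the snuggest fit, then the longest hit
          gaps <- h_start[cand] - cur_end - 1L
          cand <- cand[order(abs(gaps), -(h_end[cand] - h_start[cand]))]
          idx <- c(idx, cand[1L])
          cur_end <- max(cur_end, h_end[cand[1L]])
        }
      }
      if (!ok) next
      k <- length(acc$def_name) + 1L
      acc$def_name[k] <- def$name
      acc$family[k] <- def$family
      acc$start[k] <- h_start[s]
      acc$end[k] <- as.integer(cur_end)
      acc$n_elements[k] <- length(def$elements)
      acc$a_count[k] <- def$a_count
      acc$matched[k] <- sum(h_matched[idx]) + extra_matched
      comp_idx[[k]] <- idx
    }
  }
  n <- length(acc$def_name)
  if (!n) return(empty_termini())
  t <- tibble::new_tibble(c(acc, list(
    a_score = rep(NA_real_, n), b_score = rep(NA_real_, n),
    c_score = rep(NA_real_, n), confidence = rep(NA_real_, n),
    components = lapply(comp_idx, function(i) hits[i, , drop = FALSE]))),
    nrow = n)
  t <- t[!duplicated(t[, c("def_name", "start", "end")]), , drop = FALSE]
  t[order(t$start, t$end, t$def_name), , drop = FALSE]
}

#' Score one flank context against its expectation
#'
#' The context sub-score of a terminus compares each flank with what the
#' library-construction protocol predicts there: an observed context that
#' matches the expectation scores 100; a low-quality mismatch scores 50
#' (sequencing quality may simply have hidden the expected content); a
#' high-quality mismatch scores 0.
#'
#' @param context Observed context label (`HV`, `LV`, `HN`, `LN`).
#' @param expected Expected content: `"vector"` or `"insert"` (non-vector).
#' @return 100, 50 or 0.
#' @export
context_score <- function(context, expected) {
  stopifnot(context %in% c("HV", "LV", "HN", "LN"),
            expected %in% c("vector", "insert"))
  is_vector <- substr(context, 2L, 2L) == "V"
  matches <- (expected == "vector") == is_vector
  if (matches) return(100)
  if (substr(context, 1L, 1L) == "L") 50 else 0
}

#' Confidence score of a detected terminus
#'
#' Combines three sub-scores as a weighted sum: the completeness score
#' (A, fraction of the family's canonical components present in this
#' variant), the flank-context score (B, mean of [context_score()] over the
#' two flanks; flanks beyond the read edge are neutral), and the base-match
#' score (C, matched bases over terminus length).
#'
#' @param hit One terminus-hit row (from [assemble_termini()]).
#' @param upstream_ctx,downstream_ctx Observed flank context labels
#'   (`HV`/`LV`/`HN`/`LN`), or `NA` at a read edge.
#' @param weights Sub-score weights (non-negative, sum 1).
#' @param protocol Protocol supplying the family's canonical component
#'   count.
#' @return A list with `a_score`, `b_score`, `c_score`, `confidence`.
#' @export
score_terminus <- function(hit, upstream_ctx, downstream_ctx,
                           weights = c(1, 1, 1) / 3,
                           protocol = default_protocol()) {
  check_weights(weights)
  fam_counts <- vapply(protocol$termini, `[[`, integer(1L), "a_count")
  fams <- vapply(protocol$termini, `[[`, character(1L), "family")
  canon <- max(fam_counts[fams == hit$family])
  a <- 100 * hit$a_count / canon
  def <- protocol$termini[[hit$def_name]]
  bs <- c(
    if (is.na(upstream_ctx)) 100 else context_score(upstream_ctx, def$expected_upstream),
    if (is.na(downstream_ctx)) 100 else context_score(downstream_ctx, def$expected_downstream))
  b <- mean(bs)
  len <- hit$end - hit$start + 1L
  cc <- 100 * min(1, hit$matched / len)
  conf <- sum(weights * c(a, b, cc))
  list(a_score = a, b_score = b, c_score = cc, confidence = conf)
}

# score every terminus hit of a read. Flank windows are clipped at the
# nearest non-overlapping terminus candidate: an abutting *other* terminus
# is neither vector nor insert context, so it must not leak into the B
# score — but a competing variant at the same locus keeps the full flank
# (its own missing components are evidence against it).
score_termini <- function(termini, vector_hits, segments, read_len,
                          protocol, params) {
  if (!nrow(termini)) return(termini)
  for (i in seq_len(nrow(termini))) {
    disjoint <- termini$end < termini$start[i] | termini$start > termini$end[i]
    cs <- termini$start[disjoint]; ce <- termini$end[disjoint]
    us <- max(1L, termini$start[i] - params$flank_len)
    ue <- termini$start[i] - 1L
    blk <- ce[ce < termini$start[i] & ce >= us]
    if (length(blk)) us <- max(blk) + 1L
    up <- if (ue < us) NA_character_ else classify_context(us, ue, vector_hits, segments)
    ds <- termini$end[i] + 1L
    de <- min(read_len, termini$end[i] + params$flank_len)
    blk <- cs[cs > termini$end[i] & cs <= de]
    if (length(blk)) de <- min(blk) - 1L
    dn <- if (de < ds) NA_character_ else classify_context(ds, de, vector_hits, segments)
    sc <- score_terminus(termini[i, ], up, dn, params$weights, protocol)
    termini$a_score[i] <- sc$a_score
    termini$b_score[i] <- sc$b_score
    termini$c_score[i] <- sc$c_score
    termini$confidence[i] <- sc$confidence
  }
  termini
}

#' Resolve overlapping terminus variants
#'
#' Where several scored variants claim overlapping read intervals (a full
#' terminus always co-occurs with its sub-variants), only the
#' highest-confidence hit is kept; ties break to the larger completeness
#' score, then to the leftmost-longest interval, then lexicographically by
#' name, so the result is deterministic.
#'
#' @param termini Scored terminus-hit tibble.
#' @return The non-overlapping subset, ordered by start.
#' @export
disambiguate <- function(termini) {
  if (nrow(termini) < 2L) return(termini)
  # a same-family hit contained in a fuller variant is a fragment of it:
  # completeness marks the authentic terminus, so drop the fragment first
  frag <- vapply(seq_len(nrow(termini)), function(i) {
    any(termini$family == termini$family[i] &
          termini$a_count > termini$a_count[i] &
          termini$start <= termini$start[i] &
          termini$end >= termini$end[i])
  }, logical(1L))
  termini <- termini[!frag, , drop = FALSE]
  if (nrow(termini) < 2L) return(termini)
  ord <- order(-termini$confidence, -termini$a_score, termini$start,
               -(termini$end - termini$start), termini$def_name)
  kept <- integer(0L)
  for (i in ord) {
    clash <- any(termini$start[kept] <= termini$end[i] &
                   termini$end[kept] >= termini$start[i])
    if (!clash) kept <- c(kept, i)
  }
  res <- termini[sort(kept), , drop = FALSE]
  res[order(res$start), , drop = FALSE]
}

# ---- pattern strings ---------------------------------------------------

#' Build the terminus pattern of a read
#'
#' Tiles the read left to right: each disambiguated terminus emits its name;
#' every maximal inter-terminus region emits `V` or `N` context tokens by
#' vector coverage (sub-regions alternate where vector alignments start or
#' stop; slivers shorter than `min_context_len` merge into their
#' neighbour), each refinable to `HV`/`LV`/`HN`/`LN`. The canonical text
#' rendering joins tokens with commas.
#'
#' @param read_len Read length.
#' @param termini Disambiguated terminus hits.
#' @param vector_hits Vector alignments of the read.
#' @param segments Quality segments.
#' @param min_context_len See [est_params()].
#' @return An `est_pattern`: list with `tokens` (tibble: `token`, `type`,
#'   `start`, `end`, `refined`, `vstart`, `vend`) and `rendering`.
#' @export
build_pattern <- function(read_len, termini, vector_hits, segments,
                          min_context_len = 5L) {
  if (nrow(termini) > 1L) {
    if (any(termini$start[-1L] <= termini$end[-nrow(termini)])) {
      stop("overlapping termini after disambiguation") # internal contract
    }
  }
  toks <- list()
  emit_context <- function(s, e) {
    if (e < s || (e - s + 1L) < min_context_len) return(NULL)
    cov <- rep(FALSE, e - s + 1L)
    if (nrow(vector_hits)) {
      for (i in seq_len(nrow(vector_hits))) {
        a <- max(s, vector_hits$start[i]); b <- min(e, vector_hits$end[i])
        if (a <= b) cov[(a - s + 1L):(b - s + 1L)] <- TRUE
      }
    }
    r <- rle(cov)
    # merge sub-min_context_len slivers into their larger neighbour
    while (length(r$lengths) > 1L && any(r$lengths < min_context_len)) {
      i <- which.min(r$lengths)
      r$values[i] <- if (i == 1L) r$values[2L] else r$values[i - 1L]
      r <- rle(inverse.rle(r))
    }
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    lapply(seq_along(r$values), function(i) {
      a <- s + starts[i] - 1L; b <- s + ends[i] - 1L
      refined <- classify_context(a, b, vector_hits, segments)
      # dominant vector interval backing a V token (for RECA-F checks)
      vs <- NA_integer_; ve <- NA_integer_
      if (r$values[i] && nrow(vector_hits)) {
        ov <- pmin(vector_hits$end, b) - pmax(vector_hits$start, a) + 1L
        j <- which.max(ov)
        vs <- vector_hits$vstart[j]; ve <- vector_hits$vend[j]
      }
      tibble(token = if (r$values[i]) "V" else "N", type = "context",
             start = a, end = b, refined = refined, vstart = vs, vend = ve)
    })
  }
  pos <- 1L
  if (nrow(termini)) {
    for (i in seq_len(nrow(termini))) {
      toks <- c(toks, emit_context(pos, termini$start[i] - 1L))
      toks <- c(toks, list(tibble(
        token = termini$def_name[i], type = "terminus",
        start = termini$start[i], end = termini$end[i],
        refined = NA_character_, vstart = NA_integer_, vend = NA_integer_)))
      pos <- termini$end[i] + 1L
    }
  }
  toks <- c(toks, emit_context(pos, read_len))
  tokens <- if (length(toks)) dplyr::bind_rows(toks) else
    tibble(token = "N", type = "context", start = 1L,
           end = as.integer(read_len), refined = "HN",
           vstart = NA_integer_, vend = NA_integer_)
  if (!nrow(tokens)) {
    tokens <- tibble(token = "N", type = "context", start = 1L,
                     end = as.integer(read_len), refined = "HN",
                     vstart = NA_integer_, vend = NA_integer_)
  }
  structure(list(tokens = tokens,
                 rendering = paste(tokens$token, collapse = ",")),
            class = "est_pattern")
}

#' @export
print.est_pattern <- function(x, ...) {
  cat("<est_pattern>", x$rendering, "\n")
  invisible(x)
}

#' Render a pattern as its canonical comma-joined text
#' @param pattern An `est_pattern`.
#' @return A string like `"5TSS,N,3TSS"`.
#' @export
render_pattern <- function(pattern) pattern$rendering

# ---- reasonable pairs --------------------------------------------------

#' Enumerate reasonable terminus pairs
#'
#' For a designated 5' read, every (5TSS-family, 3TSS-family) pair with the
#' 5' member upstream; for a 3' read, every (5TNS-family, 3TNS-family) pair
#' likewise. Pairs closer than `min_separation` bases cannot contain a cDNA
#' insert and are excluded.
#'
#' @param termini Disambiguated, scored terminus hits of one read.
#' @param direction `"5'"`, `"3'"` or `"unknown"`.
#' @param min_separation Minimum bases between the paired termini.
#' @return A tibble of pairs (`left_idx`, `right_idx`, names, `separation`,
#'   `cumulative_confidence`), empty with a warning for unknown direction.
#' @export
find_reasonable_pairs <- function(termini, direction, min_separation = 200L) {
  empty <- tibble(left_idx = integer(), right_idx = integer(),
                  left = character(), right = character(),
                  separation = integer(), cumulative_confidence = double())
  if (!direction %in% c("5'", "3'")) {
    warn("unknown read direction: no reasonable pairs")
    return(empty)
  }
  fams <- if (direction == "5'") c("5TSS", "3TSS") else c("5TNS", "3TNS")
  li <- which(termini$family == fams[1L])
  ri <- which(termini$family == fams[2L])
  if (!length(li) || !length(ri)) return(empty)
  grid <- expand.grid(l = li, r = ri)
  sep <- termini$start[grid$r] - termini$end[grid$l] - 1L
  ok <- termini$end[grid$l] < termini$start[grid$r] & sep >= min_separation
  grid <- grid[ok, , drop = FALSE]
  if (!nrow(grid)) return(empty)
  tibble(left_idx = grid$l, right_idx = grid$r,
         left = termini$def_name[grid$l], right = termini$def_name[grid$r],
         separation = as.integer(sep[ok]),
         cumulative_confidence = termini$confidence[grid$l] +
           termini$confidence[grid$r])
}

#' Select the best reasonable pair
#'
#' The pair with the highest cumulative confidence; ties break to the
#' larger separation, then to the leftmost pair.
#'
#' @param pairs Tibble from [find_reasonable_pairs()].
#' @return A one-row tibble, or `NULL` when no pair exists.
#' @export
select_best_pair <- function(pairs) {
  if (!nrow(pairs)) return(NULL)
  ord <- order(-pairs$cumulative_confidence, -pairs$separation,
               pairs$left_idx, pairs$right_idx)
  pairs[ord[1L], , drop = FALSE]
}
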