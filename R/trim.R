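# Per-read pipeline orchestration, clean-insert extraction and summaries.

#' Extract the bona fide clean insert
#'
#' Starts at the inner edge of the left terminus and ends at the inner edge
#' of the right terminus (or, for the single-terminus fallback, at the read
#' boundary on the insert side). Double-termini adapter spans inside the
#' interval are excised (keeping the longest surviving piece), then both
#' ends shrink past any overlapping vector alignment and any low-quality
#' segment. Intervals shorter than `min_clean_len` are rejected.
#'
#' @param span Integer `c(start, end)`: the raw inter-termini interval.
#' @param segments Quality segments of the read.
#' @param vector_hits Vector alignments of the read.
#' @param dbt_hits DBT hits to excise (may be empty).
#' @param min_clean_len Minimum surviving length.
#' @return A list: `interval` (`c(start, end)`) on success or `NULL` plus a
#'   `reason` string on rejection.
#' @export
extract_clean_insert <- function(span, segments, vector_hits,
                                 dbt_hits = NULL, min_clean_len = 100L) {
  if (span[2L] < span[1L]) return(list(interval = NULL, reason = "degenerate pair"))
  pieces <- list(span)
  if (!is.null(dbt_hits) && nrow(dbt_hits)) {
    pieces <- subtract_intervals(span, dbt_hits$start, dbt_hits$end)
    if (!length(pieces)) return(list(interval = NULL, reason = "insert too short"))
    lens <- vapply(pieces, function(p) p[2L] - p[1L] + 1L, integer(1L))
    pieces <- pieces[which.max(lens)]
  }
  iv <- pieces[[1L]]
  lows <- segments[segments$label == "low", , drop = FALSE]
  shrink <- function(iv) {
    repeat {
      moved <- FALSE
      for (h in list(vector_hits, lows)) {
        if (!nrow(h)) next
        # left edge
        cover <- h$start <= iv[1L] & h$end >= iv[1L]
        if (any(cover)) { iv[1L] <- max(h$end[cover]) + 1L; moved <- TRUE }
        cover <- h$start <= iv[2L] & h$end >= iv[2L]
        if (any(cover)) { iv[2L] <- min(h$start[cover]) - 1L; moved <- TRUE }
        if (iv[2L] < iv[1L]) return(iv)
      }
      if (!moved) return(iv)
    }
  }
  iv <- shrink(iv)
  if (iv[2L] - iv[1L] + 1L < min_clean_len) {
    return(list(interval = NULL, reason = "insert too short"))
  }
  list(interval = as.integer(iv), reason = NA_character_)
}

subtract_intervals <- function(span, hs, he) {
  pieces <- list()
  pos <- span[1L]
  ord <- order(hs)
  for (i in ord) {
    a <- max(hs[i], span[1L]); b <- min(he[i], span[2L])
    if (b < a) next
    if (a > pos) pieces[[length(pieces) + 1L]] <- c(pos, a - 1L)
    pos <- max(pos, b + 1L)
  }
  if (pos <= span[2L]) pieces[[length(pieces) + 1L]] <- c(pos, span[2L])
  pieces
}

#' Process one raw EST read through the full pipeline
#'
#' Runs quality segmentation, element detection, terminus assembly +
#' scoring + disambiguation, pattern construction, DBT detection and
#' RECA/case/direction classification, then decides the outcome: reads
#' with a RECA call or a chimeric DBT are filtered; an internal DBT is
#' excised before trimming; otherwise the best reasonable terminus pair
#' (or, if enabled, a single direction-consistent terminus) delimits the
#' insert, which is quality- and vector-trimmed. Reads with no detected
#' terminus are emitted clean-untrimmed (quality/vector trimming only)
#' with a warning category rather than silently dropped.
#'
#' @param id Read name.
#' @param bases Read DNA string.
#' @param quals Integer phred vector or `NULL`.
#' @param direction `"5'"`, `"3'"` or `"unknown"`.
#' @param protocol An `est_protocol`.
#' @param params An [est_params()] list.
#' @return A one-row report tibble (see [process_reads()]) with attached
#'   list-columns `termini`, `tokens` and `dbt`.
#' @export
process_read <- function(id, bases, quals = NULL, direction = "unknown",
                         protocol = default_protocol(), params = est_params()) {
  res <- tryCatch(
    process_read_impl(id, bases, quals, direction, protocol, params),
    estclean_validation_error = function(e) {
      report_row(id = id, direction = direction, pattern = NA_character_,
                 primary_call = NA_character_, secondary = character(0L),
                 outcome = "filtered", clean = NULL,
                 reason = paste("invalid input:", conditionMessage(e)),
                 warning = NA_character_, termini = empty_termini(),
                 tokens = NULL, dbt = NULL, pair = NULL)
    })
  res
}

report_row <- function(id, direction, pattern, primary_call, secondary,
                       outcome, clean, reason, warning, termini, tokens,
                       dbt, pair) {
  tibble(
    id = id, direction = direction, pattern = pattern,
    primary_call = primary_call,
    secondary_calls = paste(secondary, collapse = ";"),
    outcome = outcome,
    clean_start = if (is.null(clean)) NA_integer_ else clean[1L],
    clean_end = if (is.null(clean)) NA_integer_ else clean[2L],
    rejection_reason = reason,
    warning = warning,
    n_termini = nrow(termini),
    n_dbt = if (is.null(dbt)) 0L else nrow(dbt),
    best_pair = if (is.null(pair)) NA_character_ else
      paste(pair$left, pair$right, sep = "|"),
    cumulative_confidence = if (is.null(pair)) NA_real_ else
      pair$cumulative_confidence,
    termini = list(termini),
    tokens = list(tokens),
    dbt = list(dbt)
  )
}

process_read_impl <- function(id, bases, quals, direction, protocol, params) {
  if (!is.character(bases) || length(bases) != 1L || !nzchar(bases) ||
      grepl("[^ACGTN]", bases)) {
    stop_validation("read '%s': bases must be a non-empty ACGTN string", id)
  }
  L <- nchar(bases)
  segments <- segment_quality(quals, len = L, window = params$window,
                              min_q = params$min_q)
  dbt <- detect_dbt(bases, max_mismatch = params$dbt_max_mismatch)
  det <- detect_read_elements(bases, protocol, params)
  termini <- assemble_termini(det$elements, protocol, params$max_gap, bases)
  termini <- drop_dbt_internal_termini(termini, dbt)
  termini <- score_termini(termini, det$vector_hits, segments, L,
                           protocol, params)
  termini <- disambiguate(termini)
  pattern <- build_pattern(L, termini, det$vector_hits, segments,
                           params$min_context_len)
  calls <- classify_read_calls(pattern, termini, dbt, direction, protocol)

  finish <- function(outcome, clean = NULL, reason = NA_character_,
                     warning = NA_character_, pair = NULL) {
    report_row(id, direction, pattern$rendering, calls$primary,
               calls$secondary, outcome, clean, reason, warning,
               termini, pattern$tokens, dbt, pair)
  }

  if (!is.na(calls$primary) &&
      (startsWith(calls$primary, "RECA") || calls$primary == "DBT-chimera")) {
    return(finish("filtered", reason = calls$primary))
  }
  if (nrow(termini) == 0L) {
    ext <- extract_clean_insert(c(1L, L), segments, det$vector_hits,
                                dbt, params$min_clean_len)
    if (is.null(ext$interval)) {
      return(finish("filtered", reason = "no usable terminus"))
    }
    return(finish("clean", clean = ext$interval,
                  warning = "quality-only-no-terminus"))
  }
  pairs <- suppressWarnings(
    find_reasonable_pairs(termini, direction, params$min_separation))
  best <- select_best_pair(pairs)
  if (!is.null(best)) {
    span <- c(termini$end[best$left_idx] + 1L,
              termini$start[best$right_idx] - 1L)
    ext <- extract_clean_insert(span, segments, det$vector_hits, dbt,
                                params$min_clean_len)
    if (is.null(ext$interval)) return(finish("filtered", reason = ext$reason))
    return(finish("clean", clean = ext$interval, pair = best))
  }
  if (!direction %in% c("5'", "3'")) {
    return(finish("filtered", reason = "unknown direction"))
  }
  # single-terminus fallback: exactly one terminus, family consistent with
  # the designated direction
  own <- if (direction == "5'") c("5TSS", "3TSS") else c("5TNS", "3TNS")
  if (params$fallback && nrow(termini) == 1L && termini$family %in% own) {
    fam <- termini$family
    span <- if (fam %in% c("5TSS", "5TNS")) {
      c(termini$end[1L] + 1L, L)            # insert downstream of a 5' terminus
    } else {
      c(1L, termini$start[1L] - 1L)         # insert upstream of a 3' terminus
    }
    ext <- extract_clean_insert(span, segments, det$vector_hits, dbt,
                                params$min_clean_len)
    if (is.null(ext$interval)) return(finish("filtered", reason = ext$reason))
    return(finish("clean", clean = ext$interval))
  }
  finish("filtered", reason = "no usable terminus")
}

#' Process a table of reads
#'
#' The main pipeline verb: takes the read tibble produced by
#' [read_est_fasta()] or [generate_dataset()] and returns one report row
#' per read.
#'
#' @param reads Tibble with columns `id`, `direction`, `bases` and
#'   optionally list-column `quals`.
#' @param protocol An `est_protocol`.
#' @param params An [est_params()] list.
#' @return A report tibble: `id`, `direction`, `pattern` (comma-joined
#'   tokens), `primary_call`, `secondary_calls`, `outcome`
#'   (`clean`/`filtered`), `clean_start`/`clean_end` (1-based inclusive),
#'   `rejection_reason`, `warning`, hit counts, and list-columns `termini`,
#'   `tokens`, `dbt` with the full per-read evidence.
#' @export
process_reads <- function(reads, protocol = default_protocol(),
                          params = est_params()) {
  stopifnot(all(c("id", "bases", "direction") %in% names(reads)))
  if (nrow(reads) == 0L) {
    out <- report_row("x", "unknown", NA_character_, NA_character_,
                      character(0L), "filtered", NULL, NA_character_,
                      NA_character_, empty_termini(), NULL, NULL,
                      NULL)[0L, ]
    class(out) <- c("est_report", class(out))
    return(out)
  }
  has_quals <- "quals" %in% names(reads)
  rows <- lapply(seq_len(nrow(reads)), function(i) {
    process_read(reads$id[i], reads$bases[i],
                 if (has_quals) reads$quals[[i]] else NULL,
                 reads$direction[i], protocol, params)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("est_report", class(out))
  out
}

#' Summarize a report table
#'
#' Per-category tallies in the style of the classic EST-cleanup summary
#' tables: counts and percentages by pattern rendering, by frequent
#' abnormal case, by RECA type and by DBT category, plus overall totals
#' and the fraction of reads with detectable termini.
#'
#' @param reports A report tibble from [process_reads()].
#' @return An `est_summary` list of tibbles (`totals`, `by_pattern`,
#'   `by_case`, `by_reca`, `by_dbt`, `by_outcome`).
#' @export
summarize_reports <- function(reports) {
  n <- nrow(reports)
  pct <- function(k) if (n == 0L) 0 else round(100 * k / n, 2)
  tally <- function(x, what) {
    x <- x[!is.na(x)]
    if (!length(x)) {
      return(tibble(!!what := character(), n = integer(), pct = double()))
    }
    t <- sort(table(x), decreasing = TRUE)
    tibble(!!what := names(t), n = as.integer(t), pct = pct(as.integer(t)))
  }
  primary <- reports$primary_call
  totals <- tibble(
    n_reads = n,
    n_with_termini = sum(reports$n_termini > 0L),
    pct_with_termini = pct(sum(reports$n_termini > 0L)),
    n_clean = sum(reports$outcome == "clean"),
    n_filtered = sum(reports$outcome == "filtered"),
    n_abnormal = sum(!is.na(primary)),
    pct_abnormal = pct(sum(!is.na(primary)))
  )
  structure(list(
    totals = totals,
    by_pattern = tally(reports$pattern, "pattern"),
    by_case = tally(primary[startsWith(primary %||% "", "CASE")], "case"),
    by_reca = tally(primary[startsWith(primary %||% "", "RECA")], "reca_type"),
    by_dbt = tally(primary[startsWith(primary %||% "", "DBT")], "dbt"),
    by_outcome = tally(reports$outcome, "outcome")
  ), class = "est_summary")
}

#' @export
print.est_summary <- function(x, ...) {
  cat("<est_summary>\n")
  print(as.data.frame(x$totals))
  cat("\nTop patterns:\n")
  print(utils::head(as.data.frame(x$by_pattern), 10L))
  if (nrow(x$by_reca)) { cat("\nRECA types:\n"); print(as.data.frame(x$by_reca)) }
  if (nrow(x$by_case)) { cat("\nFrequent cases:\n"); print(as.data.frame(x$by_case)) }
  if (nrow(x$by_dbt)) { cat("\nDBT:\n"); print(as.data.frame(x$by_dbt)) }
  invisible(x)
}

#' Extract trimmed clean sequences from a report
#'
#' @param reports Report tibble from [process_reads()].
#' @param reads The read tibble the report was computed from.
#' @return Tibble `id`, `bases` with only the clean, trimmed inserts.
#' @export
clean_sequences <- function(reports, reads) {
  ok <- reports$outcome == "clean" & !is.na(reports$clean_start)
  idx <- match(reports$id[ok], reads$id)
  tibble(id = reports$id[ok],
         bases = substr(reads$bases[idx], reports$clean_start[ok],
                        reports$clean_end[ok]))
}
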