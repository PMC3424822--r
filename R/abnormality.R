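# RECA, frequent-abnormal-case and double-termini-adapter classification.

#' Double-termini adapter motifs
#'
#' The two concatenation forms of the palindromic double-termini adapter
#' (DBT): type 1 is adapter(antisense) + G + AATTC + adapter(sense), type 2
#' is AATTC + adapter(sense) + adapter(antisense) + G. Both are 24 bases;
#' the type-1 motif is its own reverse complement.
#'
#' @return Named character vector with elements `type1` and `type2`.
#' @export
dbt_motifs <- function() {
  c(type1 = "CCTCGTGCCGAATTCGGCACGAGG",
    type2 = "AATTCGGCACGAGGCCTCGTGCCG")
}

#' Detect double-termini adapters
#'
#' Scans left to right for non-overlapping occurrences of the two 24-base
#' DBT motifs (allowing `max_mismatch` substitutions). Directly consecutive
#' hits are assigned increasing `repetition_index` within their run —
#' single, double and triple repetitions all occur in real libraries.
#'
#' @param bases Read DNA string.
#' @param max_mismatch Substitutions tolerated per motif occurrence.
#' @param max_gap Maximum gap between members of one repetition run.
#' @return Tibble with `start`, `end`, `dbt_type` (1 or 2),
#'   `repetition_index`.
#' @export
detect_dbt <- function(bases, max_mismatch = 1L, max_gap = 0L) {
  motifs <- dbt_motifs()
  h1 <- find_motif_hits(bases, motifs[["type1"]], max_mismatch, "DBT1")
  h1$dbt_type <- rep(1L, nrow(h1))
  h2 <- find_motif_hits(bases, motifs[["type2"]], max_mismatch, "DBT2")
  h2$dbt_type <- rep(2L, nrow(h2))
  cand <- dplyr::bind_rows(h1, h2)
  out <- tibble(start = integer(), end = integer(), dbt_type = integer(),
                repetition_index = integer())
  if (!nrow(cand)) return(out)
  cand <- cand[order(cand$start, cand$mismatches, cand$dbt_type), , drop = FALSE]
  # greedy left-to-right non-overlapping selection
  sel <- integer(0L)
  last_end <- 0L
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] > last_end) {
      sel <- c(sel, i)
      last_end <- cand$end[i]
    }
  }
  h <- cand[sel, , drop = FALSE]
  rep_idx <- integer(nrow(h))
  rep_idx[1L] <- 1L
  if (nrow(h) > 1L) {
    for (i in 2L:nrow(h)) {
      gap <- h$start[i] - h$end[i - 1L] - 1L
      rep_idx[i] <- if (gap <= max_gap) rep_idx[i - 1L] + 1L else 1L
    }
  }
  tibble(start = h$start, end = h$end, dbt_type = h$dbt_type,
         repetition_index = rep_idx)
}

# ---- RECA --------------------------------------------------------------

# direction-specific pattern templates (exact token sequences)
reca_templates <- function() {
  list(
    "RECA-A1" = list(`5'` = "N,3TNS-1,V,3TSS-2",      `3'` = "5TNS-2,V,5TSS-1,N"),
    "RECA-A2" = list(`5'` = "5TSS,N,V,3TSS-2",        `3'` = "5TNS-2,V,N,3TNS"),
    "RECA-A3" = list(`5'` = "5TSS,3TNS-1,V,3TSS-2",   `3'` = "5TNS-2,V,5TSS-1,3TNS"),
    "RECA-B1" = list(`5'` = "5TSS-2,V,5TNS-1,N",      `3'` = "N,3TSS-1,V,3TNS-2"),
    "RECA-B2" = list(`5'` = "5TSS-2,V,N,3TSS",        `3'` = "5TNS,N,V,3TNS-2"),
    "RECA-C"  = list(`5'` = "5TSS-2,V,3TSS-2",        `3'` = "5TNS-2,V,3TNS-2"),
    "RECA-D"  = list(`5'` = "N,3TNS-1,V,5TNS-1,N",    `3'` = "N,3TSS-1,V,5TSS-1,N"),
    "RECA-E"  = list(`5'` = "N,V,3TSS-2",             `3'` = "5TNS-2,V,N"),
    "RECA-F"  = list(`5'` = "V,N",                    `3'` = "N,V")
  )
}

#' Classify restriction enzyme cutting abnormalities (RECA)
#'
#' Matches the read's pattern rendering against the direction-specific RECA
#' signature templates (types A1-A3, B1-B2, C, D, E, F). Quality refinement
#' is ignored: a `V` token matches whether the vector lies in a high- or
#' low-quality region. The deliberately generic type-F signature (`V,N` /
#' `N,V`) additionally requires the vector alignment behind the `V` token to
#' fall near the EcoRI-side cloning border (type F is EcoRI cutting the
#' vector at a wrong site, so the retained vector flanks that border).
#' A pattern that matches no template but still shows the RECA hallmark —
#' a vector token strictly between two termini — is returned as
#' `RECA-other`.
#'
#' @param pattern An `est_pattern`.
#' @param direction `"5'"` or `"3'"`.
#' @param protocol Protocol providing the cloning-border coordinates.
#' @param f_window Distance (bases) around the EcoRI border within which a
#'   type-F vector alignment must fall.
#' @return A category string (`"RECA-A1"` ... `"RECA-F"`, `"RECA-other"`)
#'   or `NA` if the pattern is not a RECA.
#' @export
classify_reca <- function(pattern, direction, protocol = default_protocol(),
                          f_window = 200L) {
  if (!direction %in% c("5'", "3'")) return(NA_character_)
  rend <- pattern$rendering
  for (ty in names(reca_templates())) {
    tpl <- reca_templates()[[ty]][[direction]]
    if (identical(rend, tpl)) {
      if (ty == "RECA-F" && !reca_f_supported(pattern, direction, protocol,
                                              f_window)) {
        next
      }
      return(ty)
    }
  }
  # hallmark: retained vector strictly between two detected termini
  tok <- pattern$tokens
  vpos <- which(tok$token == "V")
  for (v in vpos) {
    before <- any(tok$type[seq_len(v - 1L)] == "terminus")
    after <- v < nrow(tok) && any(tok$type[(v + 1L):nrow(tok)] == "terminus")
    if (before && after) return("RECA-other")
  }
  NA_character_
}

reca_f_supported <- function(pattern, direction, protocol, f_window) {
  tok <- pattern$tokens
  v <- if (direction == "5'") which(tok$token == "V")[1L] else
    utils::tail(which(tok$token == "V"), 1L)
  if (!length(v) || is.na(tok$vstart[v])) return(FALSE)
  win <- c(protocol$vf1[1L] - f_window,
           protocol$vf1[2L] + nchar(protocol$enzyme1) + f_window)
  tok$vstart[v] <= win[2L] && tok$vend[v] >= win[1L]
}

# ---- frequent abnormal cases -------------------------------------------

# templates as regexes over the comma-joined rendering; "(N,)?" encodes the
# optional leading non-vector context, CASE-1 repeats poly(A)-only termini
case_templates <- function() {
  list(
    "CASE-1" = list(dir = "5'", re = "^N(,3TSS-3,N)+$"),
    "CASE-2" = list(dir = "3'", re = "^(N,)?5TNS-4,N$"),
    "CASE-3" = list(dir = "3'", re = "^(N,)?5TNS-5,N$"),
    "CASE-4" = list(dir = "5'", re = "^N,3TSS-5,V$"),
    "CASE-5" = list(dir = "5'", re = "^N,5TNS-1,N$"),
    "CASE-6" = list(dir = "3'", re = "^5TNS-2,N$"),
    "CASE-7" = list(dir = "5'", re = "^N,3TSS-5,N$"),
    "CASE-8" = list(dir = "5'", re = "^N,3TSS-4,V$")
  )
}

#' Classify a pattern as one of the frequent abnormal cases
#'
#' Matches the read's pattern rendering against the eight most frequent
#' abnormal terminus patterns (e.g. case 1: one or more bare poly(A)
#' fragments in a 5' read; case 2: the XhoI site replaced by a single C
#' between VF2' and the poly(T) tail in a 3' read). The optional leading
#' `N` of cases 2-3 and the case-1 repetition are honoured.
#'
#' @param pattern An `est_pattern`.
#' @param direction `"5'"` or `"3'"`.
#' @return `"CASE-1"` ... `"CASE-8"`, or `NA`.
#' @export
classify_case <- function(pattern, direction) {
  for (id in names(case_templates())) {
    tpl <- case_templates()[[id]]
    if (identical(direction, tpl$dir) && grepl(tpl$re, pattern$rendering)) {
      return(id)
    }
  }
  NA_character_
}

#' Detect a designated-direction conflict
#'
#' A designated 5' read whose only detected termini belong to the
#' non-sense-strand families (5TNS/3TNS) — or a 3' read with only
#' sense-strand termini — carries the other direction's terminal structure
#' and is flagged.
#'
#' @param termini Disambiguated terminus hits of the read.
#' @param direction `"5'"` or `"3'"`.
#' @return `"direction-conflict"` or `NA`.
#' @export
detect_direction_conflict <- function(termini, direction) {
  if (!nrow(termini) || !direction %in% c("5'", "3'")) return(NA_character_)
  fams <- unique(termini$family)
  own <- if (direction == "5'") c("5TSS", "3TSS") else c("5TNS", "3TNS")
  if (!any(fams %in% own)) "direction-conflict" else NA_character_
}

#' Resolve double-termini adapters into internal vs chimeric
#'
#' A DBT lying strictly inside a valid 5TNS ... 3TNS span of a designated 3'
#' read is a concatenated-adapter artifact, not a chimera: the insert is
#' recoverable by excising the DBT (`DBT-internal`). Any other DBT
#' configuration joins unrelated fragments and the read is flagged
#' `DBT-chimera`. Consecutive repetitions count as one call covering the
#' whole run.
#'
#' @param termini Disambiguated terminus hits.
#' @param dbt_hits Tibble from [detect_dbt()] (at least one row).
#' @param direction Designated read direction.
#' @return `"DBT-internal"` or `"DBT-chimera"`.
#' @export
resolve_dbt <- function(termini, dbt_hits, direction) {
  stopifnot(nrow(dbt_hits) >= 1L)
  if (identical(direction, "3'") && nrow(termini)) {
    left <- termini$end[termini$family == "5TNS"]
    right <- termini$start[termini$family == "3TNS"]
    if (length(left) && length(right)) {
      l <- min(left); r <- max(right)
      if (all(dbt_hits$start > l & dbt_hits$end < r)) return("DBT-internal")
    }
  }
  "DBT-chimera"
}

# suppress termini fully contained in a DBT hit: the adapter/enzyme
# components of the DBT itself would otherwise masquerade as termini
drop_dbt_internal_termini <- function(termini, dbt_hits) {
  if (!nrow(termini) || !nrow(dbt_hits)) return(termini)
  contained <- vapply(seq_len(nrow(termini)), function(i) {
    any(dbt_hits$start <= termini$start[i] & dbt_hits$end >= termini$end[i])
  }, logical(1L))
  termini[!contained, , drop = FALSE]
}

# precedence RECA > DBT > CASE > direction-conflict; one primary call plus
# secondary annotations
classify_read_calls <- function(pattern, termini, dbt_hits, direction,
                                protocol, f_window = 200L) {
  reca <- classify_reca(pattern, direction, protocol, f_window)
  dbt <- if (nrow(dbt_hits)) resolve_dbt(termini, dbt_hits, direction) else NA_character_
  case <- classify_case(pattern, direction)
  conflict <- detect_direction_conflict(termini, direction)
  ordered <- c(reca, dbt, case, conflict)
  ordered <- ordered[!is.na(ordered)]
  list(primary = if (length(ordered)) ordered[1L] else NA_character_,
       secondary = if (length(ordered) > 1L) ordered[-1L] else character(0L))
}
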