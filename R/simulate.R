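# Synthetic raw Sanger EST generator: every supported construct layout with
# full ground truth (segment map, true clean interval, expected call).

POLY_LEN <- 20L

# random insert DNA additionally free of any 12-mer shared with the
# protocol's vector (either strand): a shared seed could otherwise produce
# a chance local alignment and blur the planted truth
clean_insert_dna <- function(n, protocol) {
  seq <- clean_random_dna(n)
  k <- VEC_SEED_K
  if (n < k) return(seq)
  idx <- vector_index(protocol$vector_seq)
  bases <- c("A", "C", "G", "T")
  for (iter in 1:50) {
    km <- substring(seq, 1:(n - k + 1L), k:n)
    hit_pos <- which(km %in% idx$fwd | km %in% idx$rev)
    if (!length(hit_pos)) {
      # substitutions may have re-created a forbidden motif or poly run
      ok <- TRUE
      for (m in forbidden_motifs()) {
        if (grepl(m, seq, fixed = TRUE)) { ok <- FALSE; break }
      }
      if (ok && (nrow(find_poly_tail(seq, "A")) ||
                 nrow(find_poly_tail(seq, "T")))) ok <- FALSE
      if (ok) break
      seq <- clean_random_dna_repair(seq)
      next
    }
    for (i in hit_pos) {
      mid <- i + k %/% 2L
      cur <- substr(seq, mid, mid)
      substr(seq, mid, mid) <- sample(setdiff(bases, cur), 1L)
    }
  }
  seq
}

#' Supported synthetic construct layouts
#'
#' The default dataset mix: the expected construct in both read directions,
#' one read direction per RECA type, the two chimeric DBT concatenation
#' types plus the internal-DBT rescue layout, and the four headline
#' frequent abnormal cases. [make_construct()] additionally supports both
#' directions for every RECA type and all eight cases.
#'
#' @return Tibble with columns `layout`, `direction`, `expected_call`
#'   (`NA` = no abnormality) and `has_clean` (whether the layout contains a
#'   recoverable insert).
#' @export
est_layouts <- function() {
  tibble(
    layout = c("expected", "expected",
               "RECA-A1", "RECA-A2", "RECA-A3", "RECA-B1", "RECA-B2",
               "RECA-C", "RECA-D", "RECA-E", "RECA-F",
               "DBT1-chimera", "DBT2-chimera", "DBT-internal",
               "CASE-1", "CASE-2", "CASE-5", "CASE-8"),
    direction = c("5'", "3'",
                  "5'", "5'", "5'", "3'", "3'", "5'", "5'", "3'", "5'",
                  "5'", "5'", "3'",
                  "5'", "3'", "5'", "5'"),
    expected_call = c(NA, NA,
                      "RECA-A1", "RECA-A2", "RECA-A3", "RECA-B1", "RECA-B2",
                      "RECA-C", "RECA-D", "RECA-E", "RECA-F",
                      "DBT-chimera", "DBT-chimera", "DBT-internal",
                      "CASE-1", "CASE-2", "CASE-5", "CASE-8"),
    has_clean = c(TRUE, TRUE,
                  FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                  FALSE, FALSE, FALSE, TRUE,
                  FALSE, TRUE, FALSE, TRUE)
  )
}

# expected primary call for any (layout, direction)
layout_expected_call <- function(layout) {
  if (layout == "expected") return(NA_character_)
  if (layout %in% c("DBT1-chimera", "DBT2-chimera")) return("DBT-chimera")
  layout
}

#' Build one synthetic construct
#'
#' Concatenates protocol elements, random cDNA inserts and (for abnormal
#' layouts) retained vector, spacers or double-termini adapters according
#' to the requested construct layout, and records the exact segment map and
#' the true clean-insert interval. Inserts are uniform random DNA (GC 0.45)
#' free of enzyme/adapter motifs and 8-base homopolymer runs, so planted
#' truth stays unambiguous. Uses the current RNG state; seed via
#' [withr::with_seed()] or [generate_dataset()].
#'
#' @param layout One of the layouts of [est_layouts()] (plus `CASE-3`,
#'   `CASE-4`, `CASE-6`, `CASE-7`).
#' @param direction `"5'"` or `"3'"`; both are valid for `expected` and
#'   RECA layouts, the remaining layouts fix their direction.
#' @param protocol An `est_protocol`.
#' @param insert_length Length (bases) of the primary cDNA insert.
#' @return List with `bases`, `direction`, `segments` (tibble `label`,
#'   `start`, `end` tiling the read), `clean` (`c(start, end)` or `NULL`)
#'   and `expected_call`.
#' @export
make_construct <- function(layout, direction = NULL,
                           protocol = default_protocol(),
                           insert_length = 400L) {
  p <- protocol
  vf1 <- protocol_piece(p, "vf1"); vf2 <- protocol_piece(p, "vf2")
  stuffer <- protocol_piece(p, "stuffer")
  arm2 <- substr(protocol_piece(p, "right_arm"), 1L, 100L)
  E1 <- p$enzyme1; E2 <- p$enzyme2
  AD <- p$adapter_sense; ADr <- p$adapter_antisense
  pA <- strrep("A", POLY_LEN); pT <- strrep("T", POLY_LEN)
  stuf_tail <- substr(stuffer, nchar(stuffer) - 149L, nchar(stuffer))
  # vector retained by a wrong-site EcoRI cut: ends just inside VF1, well
  # upstream of the (uncut) recognition site, so no border element remains
  vec_f <- substr(p$vector_seq, p$vf1[1L] - 100L, p$vf1[1L] + 10L)
  dbt1 <- unname(dbt_motifs()["type1"]); dbt2 <- unname(dbt_motifs()["type2"])
  ins <- function(n = insert_length) clean_insert_dna(n, p)
  spacer <- function() clean_insert_dna(sample(3:15, 1L), p)
  junk2 <- max(150L, as.integer(round(insert_length * 0.6)))

  seg <- function(...) {
    # ... = alternating label, seq
    args <- list(...)
    labs <- unlist(args[seq(1L, length(args), 2L)])
    seqs <- unlist(args[seq(2L, length(args), 2L)])
    keep <- nzchar(seqs)
    tibble(label = labs[keep], seq = seqs[keep])
  }
  fixed_dir <- c("DBT1-chimera" = "5'", "DBT2-chimera" = "5'",
                 "DBT-internal" = "3'",
                 "CASE-1" = "5'", "CASE-2" = "3'", "CASE-3" = "3'",
                 "CASE-4" = "5'", "CASE-5" = "5'", "CASE-6" = "3'",
                 "CASE-7" = "5'", "CASE-8" = "5'")
  if (layout %in% names(fixed_dir)) {
    if (!is.null(direction) && direction != fixed_dir[[layout]]) {
      stop_validation("layout %s is defined for %s reads only",
                      layout, fixed_dir[[layout]])
    }
    direction <- fixed_dir[[layout]]
  }
  if (is.null(direction)) direction <- "5'"
  if (!direction %in% c("5'", "3'")) stop_validation("bad direction")
  d5 <- direction == "5'"

  x <- switch(layout,
    "expected" = if (d5) {
      seg("VF1", vf1, "EcoRI", E1, "Adapter1", AD, "insert", ins(),
          "polyA", pA, "XhoI", E2, "VF2", vf2)
    } else {
      seg("VF2rc", rc(vf2), "XhoI", E2, "polyT", pT, "insert", ins(),
          "Adapter1rc", ADr, "EcoRI", E1, "VF1rc", rc(vf1))
    },
    "RECA-A1" = if (d5) {
      seg("junk", ins(junk2), "Adapter1rc", ADr, "EcoRI", E1,
          "vector", stuffer, "XhoI", E2, "VF2", vf2)
    } else {
      seg("VF2rc", rc(vf2), "XhoI", E2, "vector", rc(stuffer),
          "EcoRI", E1, "Adapter1", AD, "junk", ins(junk2))
    },
    "RECA-A2" = if (d5) {
      seg("VF1", vf1, "EcoRI", E1, "Adapter1", AD, "junk", ins(),
          "spacer", spacer(), "vector", stuffer, "XhoI", E2, "VF2", vf2)
    } else {
      seg("VF2rc", rc(vf2), "XhoI", E2, "vector", rc(stuffer),
          "spacer", spacer(), "junk", ins(), "Adapter1rc", ADr,
          "EcoRI", E1, "VF1rc", rc(vf1))
    },
    "RECA-A3" = if (d5) {
      seg("VF1", vf1, "EcoRI", E1, "Adapter1", AD, "Adapter1rc", ADr,
          "EcoRI", E1, "vector", stuffer, "XhoI", E2, "VF2", vf2)
    } else {
      seg("VF2rc", rc(vf2), "XhoI", E2, "vector", rc(stuffer),
          "EcoRI", E1, "Adapter1", AD, "Adapter1rc", ADr, "EcoRI", E1,
          "VF1rc", rc(vf1))
    },
    "RECA-B1" = if (d5) {
      seg("VF1", vf1, "EcoRI", E1, "vector", stuffer, "XhoI", E2,
          "polyT", pT, "junk", ins(junk2))
    } else {
      seg("junk", ins(junk2), "polyA", pA, "XhoI", E2,
          "vector", rc(stuffer), "EcoRI", E1, "VF1rc", rc(vf1))
    },
    "RECA-B2" = if (d5) {
      seg("VF1", vf1, "EcoRI", E1, "vector", stuffer, "spacer", spacer(),
          "junk", ins(), "polyA", pA, "XhoI", E2, "VF2", vf2)
    } else {
      seg("VF2rc", rc(vf2), "XhoI", E2, "polyT", pT, "junk", ins(),
          "spacer", spacer(), "vector", rc(stuffer), "EcoRI", E1,
          "VF1rc", rc(vf1))
    },
    "RECA-C" = if (d5) {
      seg("VF1", vf1, "EcoRI", E1, "vector", stuffer, "XhoI", E2, "VF2", vf2)
    } else {
      seg("VF2rc", rc(vf2), "XhoI", E2, "vector", rc(stuffer),
          "EcoRI", E1, "VF1rc", rc(vf1))
    },
    "RECA-D" = if (d5) {
      seg("junk", ins(junk2), "Adapter1rc", ADr, "EcoRI", E1,
          "vector", stuffer, "XhoI", E2, "polyT", pT, "junk", ins(junk2))
    } else {
      seg("junk", ins(junk2), "polyA", pA, "XhoI", E2, "vector", stuffer,
          "EcoRI", E1, "Adapter1", AD, "junk", ins(junk2))
    },
    "RECA-E" = if (d5) {
      seg("junk", ins(), "vector", stuf_tail, "XhoI", E2, "VF2", vf2)
    } else {
      seg("VF2rc", rc(vf2), "XhoI", E2, "vector", rc(stuf_tail),
          "junk", ins())
    },
    "RECA-F" = if (d5) {
      seg("vector", vec_f, "junk", ins())
    } else {
      seg("junk", ins(), "vector", rc(vec_f))
    },
    "DBT1-chimera" = seg("VF1", vf1, "EcoRI", E1, "Adapter1", AD,
                         "junk", ins(junk2), "DBT", dbt1, "junk", ins(junk2)),
    "DBT2-chimera" = seg("VF1", vf1, "EcoRI", E1, "Adapter1", AD,
                         "junk", ins(junk2), "DBT", dbt2, "junk", ins(junk2)),
    "DBT-internal" = seg("VF2rc", rc(vf2), "XhoI", E2, "polyT", pT,
                         "insert", ins(), "DBT", dbt1, "Adapter1rc", ADr,
                         "EcoRI", E1, "VF1rc", rc(vf1)),
    "CASE-1" = seg("junk", ins(200L), "polyA", pA, "junk", ins(200L),
                   "polyA", pA, "junk", ins(150L)),
    "CASE-2" = seg("junk", if (stats::runif(1L) < 0.5) ins(100L) else "",
                   "VF2rc", rc(vf2), "C", "C", "polyT", pT, "insert", ins()),
    "CASE-3" = seg("junk", if (stats::runif(1L) < 0.5) ins(100L) else "",
                   "VF2rc", rc(vf2), "insert", ins()),
    "CASE-4" = seg("insert", ins(), "VF2", vf2, "vector", arm2),
    "CASE-5" = seg("junk", ins(250L), "XhoI", E2, "polyT", pT,
                   "junk", ins(250L)),
    "CASE-6" = seg("VF2rc", rc(vf2), "XhoI", E2, "insert", ins()),
    "CASE-7" = seg("insert", ins(), "VF2", vf2, "junk", ins(150L)),
    "CASE-8" = seg("insert", ins(), "polyA", pA, "G", "G", "VF2", vf2,
                   "vector", arm2),
    stop_validation("unknown layout '%s'", layout)
  )
  # junction guards: a random segment abutting a planted poly tail must not
  # carry the tail base at the junction, or the tail boundary would blur
  guard <- function(s, b, side) {
    sub <- if (b == "A") "C" else "G"
    n <- nchar(s)
    idx <- if (side == "tail") seq(max(1L, n - 1L), n) else seq_len(min(2L, n))
    for (i in idx) if (substr(s, i, i) == b) substr(s, i, i) <- sub
    s
  }
  rnd <- c("insert", "junk", "spacer")
  for (j in which(x$label %in% c("polyA", "polyT"))) {
    b <- if (x$label[j] == "polyA") "A" else "T"
    if (j > 1L && x$label[j - 1L] %in% rnd) {
      x$seq[j - 1L] <- guard(x$seq[j - 1L], b, "tail")
    }
    if (j < nrow(x) && x$label[j + 1L] %in% rnd) {
      x$seq[j + 1L] <- guard(x$seq[j + 1L], b, "head")
    }
  }
  lens <- nchar(x$seq)
  ends <- cumsum(lens)
  segments <- tibble(label = x$label,
                     start = as.integer(ends - lens + 1L),
                     end = as.integer(ends))
  bases <- repair_unplanted_runs(paste(x$seq, collapse = ""), segments)
  bases <- repair_vector_bleed(bases, segments, p)
  clean <- NULL
  ci <- which(segments$label == "insert")
  if (length(ci) == 1L) clean <- c(segments$start[ci], segments$end[ci])
  list(bases = bases, direction = direction,
       segments = segments, clean = clean,
       expected_call = layout_expected_call(layout))
}

# a local alignment seeded in a planted vector segment can extend a few
# chance-matching bases into an abutting random segment; re-scan the
# finished read and break any such bleed so context tokens stay exactly as
# planted
repair_vector_bleed <- function(bases, segments, protocol) {
  rnd <- segments[segments$label %in% c("insert", "junk", "spacer"), ,
                  drop = FALSE]
  if (!nrow(rnd)) return(bases)
  other <- c(A = "C", C = "A", G = "T", T = "G")
  for (iter in 1:10) {
    hits <- find_vector_hits(bases, protocol$vector_seq)
    changed <- FALSE
    for (i in seq_len(nrow(hits))) {
      for (j in seq_len(nrow(rnd))) {
        a <- max(hits$start[i], rnd$start[j])
        b <- min(hits$end[i], rnd$end[j])
        if (b - a + 1L < 3L) next
        mid <- (a + b) %/% 2L
        substr(bases, mid, mid) <- other[[substr(bases, mid, mid)]]
        changed <- TRUE
      }
    }
    if (!changed) break
    bases <- repair_unplanted_runs(bases, segments)
  }
  bases
}

# per-segment cleaning cannot see runs assembled across junctions of random
# segments: disrupt any detected poly run that is not exactly a planted
# tail, substituting inside the random segment it crosses
repair_unplanted_runs <- function(bases, segments) {
  rnd <- segments$label %in% c("insert", "junk", "spacer")
  in_any <- function(pos, segs) {
    if (!nrow(segs)) return(rep(FALSE, length(pos)))
    out <- rep(FALSE, length(pos))
    for (i in seq_len(nrow(segs))) {
      out <- out | (pos >= segs$start[i] & pos <= segs$end[i])
    }
    out
  }
  for (iter in 1:20) {
    changed <- FALSE
    for (b in c("A", "T")) {
      planted <- segments[segments$label == paste0("poly", b), , drop = FALSE]
      hits <- find_poly_tail(bases, b)
      for (i in seq_len(nrow(hits))) {
        if (nrow(planted) && any(planted$start == hits$start[i] &
                                   planted$end == hits$end[i])) next
        pos <- hits$start[i]:hits$end[i]
        pos <- pos[!in_any(pos, planted) & in_any(pos, segments[rnd, ])]
        pos <- pos[substring(bases, pos, pos) == b]
        if (!length(pos)) next
        mid <- pos[ceiling(length(pos) / 2L)]
        substr(bases, mid, mid) <- if (b == "A") "C" else "G"
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  bases
}

#' Sanger-style quality profile
#'
#' Per-base phred values emulating a Sanger read: a short low ramp at the
#' start, a high plateau, and a slowly decaying tail. The defaults never
#' cross the low-quality threshold within realistic read lengths, so the
#' profile shapes scores without hiding planted truth; tests exercise the
#' low-quality machinery with explicit quality vectors.
#'
#' @param len Read length.
#' @param q_start,q_plateau Phred at the first base / on the plateau.
#' @param ramp Bases over which quality ramps up.
#' @param decay_from Base position where the tail decay starts.
#' @param decay_rate Phred lost per base in the tail.
#' @param floor Minimum phred.
#' @return Integer vector of length `len`.
#' @export
sanger_quality_profile <- function(len, q_start = 20, q_plateau = 40,
                                   ramp = 12L, decay_from = 500L,
                                   decay_rate = 0.03, floor = 12) {
  i <- seq_len(len)
  q <- rep(q_plateau, len)
  r <- i <= ramp
  q[r] <- q_start + (q_plateau - q_start) * (i[r] - 1L) / ramp
  d <- i > decay_from
  q[d] <- pmax(floor, q_plateau - decay_rate * (i[d] - decay_from))
  as.integer(round(q))
}

#' Add sequencing noise to a synthetic read
#'
#' Applies per-base substitutions and indels at the given rates and
#' generates a quality vector from the profile; ground-truth intervals are
#' shifted through any indels. Uses the current RNG state.
#'
#' @param bases Read DNA string.
#' @param sub_rate,indel_rate Per-base substitution / indel probabilities
#'   (each in `[0, 0.2]`).
#' @param profile Function `(len) -> phred vector`;
#'   default [sanger_quality_profile()].
#' @param truth Optional list with `segments` (tibble) and `clean`
#'   (interval) to be coordinate-shifted through indels.
#' @return List: `bases`, `quals`, `error_positions` (original-coordinate
#'   substitution sites), `n_insertions`, `n_deletions`, and the shifted
#'   `truth`.
#' @export
add_noise <- function(bases, sub_rate = 0, indel_rate = 0,
                      profile = sanger_quality_profile, truth = NULL) {
  if (sub_rate < 0 || sub_rate > 0.2 || indel_rate < 0 || indel_rate > 0.2) {
    stop_validation("noise rates must lie in [0, 0.2]")
  }
  ch <- strsplit(bases, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
  subs <- integer(0L)
  if (sub_rate > 0) {
    subs <- which(stats::runif(n) < sub_rate)
    for (i in subs) {
      opts <- strsplit(alt[[ch[i]]], "")[[1L]]
      ch[i] <- opts[sample.int(3L, 1L)]
    }
  }
  ins_n <- 0L; del_n <- 0L
  shift_at <- rep(0L, n + 1L)  # coordinate shift applying to original pos i
  if (indel_rate > 0) {
    ev <- which(stats::runif(n) < indel_rate)
    pieces <- as.list(ch)
    for (i in ev) {
      if (stats::runif(1L) < 0.5) {
        pieces[[i]] <- ""                               # deletion
        del_n <- del_n + 1L
        shift_at[(i + 1L):(n + 1L)] <- shift_at[(i + 1L):(n + 1L)] - 1L
      } else {
        pieces[[i]] <- paste0(sample(c("A", "C", "G", "T"), 1L), pieces[[i]])
        ins_n <- ins_n + 1L
        shift_at[i:(n + 1L)] <- shift_at[i:(n + 1L)] + 1L
      }
    }
    out <- paste(unlist(pieces), collapse = "")
  } else {
    out <- paste(ch, collapse = "")
  }
  if (!is.null(truth)) {
    mapc <- function(pos) as.integer(pos + shift_at[pmin(pos, n + 1L)])
    truth$segments$start <- mapc(truth$segments$start)
    truth$segments$end <- mapc(truth$segments$end)
    if (!is.null(truth$clean)) truth$clean <- mapc(truth$clean)
  }
  list(bases = out, quals = profile(nchar(out)),
       error_positions = subs, n_insertions = ins_n, n_deletions = del_n,
       truth = truth)
}

#' Generate a synthetic EST dataset with ground truth
#'
#' Draws `n` reads from the layout mix, applies the noise model, and
#' (optionally) writes standard multi-FASTA, QUAL and a truth TSV. Fully
#' deterministic for a given seed.
#'
#' @param n Number of reads.
#' @param proportions Named numeric summing to 1; names are
#'   `"layout@direction"` keys such as `"expected@5'"` or plain layout
#'   names (direction then defaults per [est_layouts()]). Default: equal
#'   proportions over the 18-layout default mix.
#' @param insert_length Primary insert length.
#' @param sub_rate,indel_rate Noise rates, see [add_noise()].
#' @param seed Integer seed (RNG state is restored afterwards).
#' @param dir Output directory; when given, writes `reads.fasta`,
#'   `reads.qual` and `truth.tsv` there.
#' @param protocol An `est_protocol`.
#' @return List with `reads` (tibble `id`, `direction`, `bases`, `quals`)
#'   and `truth` (tibble `id`, `layout`, `direction`, `expected_call`,
#'   `clean_start`, `clean_end`, list-column `segments`), plus `paths` when
#'   `dir` was given.
#' @export
generate_dataset <- function(n, proportions = NULL, insert_length = 400L,
                             sub_rate = 0, indel_rate = 0, seed = 1L,
                             dir = NULL, protocol = default_protocol()) {
  mix <- est_layouts()
  if (is.null(proportions)) {
    proportions <- stats::setNames(rep(1 / nrow(mix), nrow(mix)),
                                   paste0(mix$layout, "@", mix$direction))
  }
  if (abs(sum(proportions) - 1) > 1e-6) {
    stop_validation("proportions must sum to 1 (got %.4f)", sum(proportions))
  }
  keys <- names(proportions)
  if (is.null(keys) || any(!nzchar(keys))) {
    stop_validation("proportions must be named by layout")
  }
  parse_key <- function(k) {
    if (grepl("@", k, fixed = TRUE)) {
      parts <- strsplit(k, "@", fixed = TRUE)[[1L]]
      list(layout = parts[1L], direction = parts[2L])
    } else {
      row <- mix[mix$layout == k, , drop = FALSE]
      list(layout = k,
           direction = if (nrow(row)) row$direction[1L] else NULL)
    }
  }
  withr::with_seed(seed, {
    picks <- sample(seq_along(proportions), n, replace = TRUE,
                    prob = proportions)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      k <- parse_key(keys[picks[i]])
      cons <- make_construct(k$layout, k$direction, protocol, insert_length)
      noisy <- add_noise(cons$bases, sub_rate, indel_rate,
                         truth = list(segments = cons$segments,
                                      clean = cons$clean))
      tag <- if (cons$direction == "5'") "g1" else "b1"
      id <- sprintf("%s_%05d.%s_S", gsub("[^A-Za-z0-9]", "", k$layout), i, tag)
      rows[[i]] <- list(
        read = tibble(id = id, direction = cons$direction,
                      bases = noisy$bases, quals = list(noisy$quals)),
        truth = tibble(id = id, layout = k$layout,
                       direction = cons$direction,
                       expected_call = cons$expected_call,
                       clean_start = if (is.null(noisy$truth$clean))
                         NA_integer_ else noisy$truth$clean[1L],
                       clean_end = if (is.null(noisy$truth$clean))
                         NA_integer_ else noisy$truth$clean[2L],
                       segments = list(noisy$truth$segments)))
    }
  })
  reads <- dplyr::bind_rows(lapply(rows, `[[`, "read"))
  truth <- dplyr::bind_rows(lapply(rows, `[[`, "truth"))
  out <- list(reads = reads, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(fasta = file.path(dir, "reads.fasta"),
                  qual = file.path(dir, "reads.qual"),
                  truth = file.path(dir, "truth.tsv"))
    write_fasta(reads$bases, reads$id, paths$fasta)
    write_qual(reads$quals, reads$id, paths$qual)
    write_tsv(truth[, setdiff(names(truth), "segments")], paths$truth)
    out$paths <- paths
  }
  out
}
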