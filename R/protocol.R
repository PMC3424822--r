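#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

# validation error helper: these become exit code 2 in the CLI
stop_validation <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "estclean_validation_error")
}

#' Reverse-complement a DNA sequence
#'
#' Standard Watson-Crick reverse complement over the alphabet `A,C,G,T,N`.
#' Antisense terminus layouts (e.g. the 3' read forms of the cloning-site
#' borders) are reverse-complement mirrors of their sense counterparts, so
#' this primitive is used throughout the protocol model.
#'
#' @param seq A single DNA string over `A,C,G,T,N` (uppercase).
#' @return The reverse complement, same length, same alphabet.
#' @examples
#' reverse_complement("GGCACGAGG")  # "CCTCGTGCC"
#' reverse_complement("GAATTC")     # palindromic EcoRI site
#' @export
reverse_complement <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop_validation("`seq` must be a single DNA string")
  }
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L) {
    stop_validation("non-DNA character '%s' at position %d",
                    substr(seq, bad, bad), bad)
  }
  comp <- chartr("ACGTN", "TGCAN", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

# fast internal variant, input assumed validated
rc <- function(seq) {
  vapply(seq, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
          collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# ---- terminus definitions ----------------------------------------------

# element constructor. kind in {vector_border, enzyme_site, adapter,
# poly_tail, single_base}; motif for poly_tail/single_base is the single base.
seq_element <- function(kind, label, motif) {
  stopifnot(kind %in% c("vector_border", "enzyme_site", "adapter",
                        "poly_tail", "single_base"))
  if (!nzchar(motif) || grepl("[^ACGT]", motif)) {
    stop_validation("element '%s': motif must be non-empty uppercase DNA", label)
  }
  if (kind %in% c("poly_tail", "single_base") && nchar(motif) != 1L) {
    stop_validation("element '%s': %s motif must be a single base", label, kind)
  }
  list(kind = kind, label = label, motif = motif)
}

terminus_def <- function(name, family, elements) {
  stopifnot(family %in% c("5TSS", "3TSS", "5TNS", "3TNS"), length(elements) >= 1L)
  # single-base stand-ins (the G/C of 3TSS-4/5TNS-4) do not count toward
  # completeness, so each family keeps a unique maximal (canonical) definition
  a_count <- sum(vapply(elements, function(e) e$kind != "single_base", logical(1L)))
  # vector-facing side by family: 5' termini expect vector upstream, insert
  # downstream; 3' termini the reverse
  upstream <- if (family %in% c("5TSS", "5TNS")) "vector" else "insert"
  list(name = name, family = family, elements = elements,
       a_count = a_count,
       expected_upstream = upstream,
       expected_downstream = if (upstream == "vector") "insert" else "vector")
}

# the element table of the default EcoRI/XhoI protocol; X' (rc) forms carry
# an "rc" suffix in their labels
default_terminus_table <- function(enzyme1, enzyme2, adapter_sense, adapter_antisense) {
  E1  <- function() seq_element("enzyme_site", "EcoRI", enzyme1)
  E2  <- function() seq_element("enzyme_site", "XhoI", enzyme2)
  AD  <- function() seq_element("adapter", "Adapter1", adapter_sense)
  ADr <- function() seq_element("adapter", "Adapter1rc", adapter_antisense)
  VF1  <- function() seq_element("vector_border", "VF1", "A")   # motif placeholder,
  VF2  <- function() seq_element("vector_border", "VF2", "A")   # real seq comes from
  VF1r <- function() seq_element("vector_border", "VF1rc", "A") # the vector itself
  VF2r <- function() seq_element("vector_border", "VF2rc", "A")
  pA  <- function() seq_element("poly_tail", "polyA", "A")
  pT  <- function() seq_element("poly_tail", "polyT", "T")
  G1  <- function() seq_element("single_base", "G", "G")
  C1  <- function() seq_element("single_base", "C", "C")

  defs <- list(
    terminus_def("5TSS",   "5TSS", list(VF1(), E1(), AD())),
    terminus_def("5TSS-1", "5TSS", list(E1(), AD())),
    terminus_def("5TSS-2", "5TSS", list(VF1(), E1())),
    terminus_def("3TSS",   "3TSS", list(pA(), E2(), VF2())),
    terminus_def("3TSS-1", "3TSS", list(pA(), E2())),
    terminus_def("3TSS-2", "3TSS", list(E2(), VF2())),
    terminus_def("3TSS-3", "3TSS", list(pA())),
    terminus_def("3TSS-4", "3TSS", list(pA(), G1(), VF2())),
    terminus_def("3TSS-5", "3TSS", list(VF2())),
    terminus_def("5TNS",   "5TNS", list(VF2r(), E2(), pT())),
    terminus_def("5TNS-1", "5TNS", list(E2(), pT())),
    terminus_def("5TNS-2", "5TNS", list(VF2r(), E2())),
    terminus_def("5TNS-3", "5TNS", list(pT())),
    terminus_def("5TNS-4", "5TNS", list(VF2r(), C1(), pT())),
    terminus_def("5TNS-5", "5TNS", list(VF2r())),
    terminus_def("3TNS",   "3TNS", list(ADr(), E1(), VF1r())),
    terminus_def("3TNS-1", "3TNS", list(ADr(), E1())),
    terminus_def("3TNS-2", "3TNS", list(E1(), VF1r())),
    terminus_def("3TNS-5", "3TNS", list(VF1r()))
  )
  stats::setNames(defs, vapply(defs, `[[`, character(1L), "name"))
}

# ---- bundled synthetic vector ------------------------------------------

# deterministic random DNA free of every diagnostic motif (enzyme sites,
# adapters, 8-base homopolymer runs), so planted elements stay unambiguous
forbidden_motifs <- function() {
  c("GAATTC", "CTCGAG", "GGCACGAGG", "CCTCGTGCC",
    strrep("A", 8L), strrep("T", 8L), strrep("C", 8L), strrep("G", 8L))
}

clean_random_dna <- function(n, gc = 0.45) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seq <- paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
  clean_random_dna_repair(seq)
}

# disrupt forbidden motifs and detectable poly runs in an existing sequence
clean_random_dna_repair <- function(seq) {
  bases <- c("A", "C", "G", "T")
  for (iter in 1:50) {
    hit <- FALSE
    for (m in forbidden_motifs()) {
      pos <- gregexpr(m, seq, fixed = TRUE)[[1L]]
      if (pos[1L] > 0L) {
        hit <- TRUE
        mid <- pos + nchar(m) %/% 2L
        for (i in mid) {
          cur <- substr(seq, i, i)
          substr(seq, i, i) <- sample(setdiff(bases, cur), 1L)
        }
      }
    }
    # also disrupt any detectable (impurity-tolerant) poly run, replacing
    # the middle base that actually carries the run base
    for (b in c("A", "T")) {
      runs <- find_poly_tail(seq, b)
      if (nrow(runs)) {
        hit <- TRUE
        for (i in seq_len(nrow(runs))) {
          span <- runs$start[i]:runs$end[i]
          is_b <- span[substring(seq, span, span) == b]
          mid <- is_b[ceiling(length(is_b) / 2L)]
          substr(seq, mid, mid) <- if (b == "A") "C" else "G"
        }
      }
    }
    if (!hit) break
  }
  seq
}

# 2.7 kb pBluescript-like stand-in with a directional EcoRI/XhoI cloning site.
# Synthetic: the real vector sequence is not bundled; users supply theirs via
# load_protocol(). Layout: arm - VF1(50) - GAATTC - stuffer(300) - CTCGAG -
# VF2(50) - arm.
demo_vector <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    parts <- withr::with_seed(104729L, list(
      left    = clean_random_dna(1150L),
      vf1     = clean_random_dna(50L),
      stuffer = clean_random_dna(300L),
      vf2     = clean_random_dna(50L),
      right   = clean_random_dna(1150L)
    ))
    # VF2 must not start with A: a leading A would let a poly(A)/(T) tail
    # planted against the border absorb it and blur the planted boundary
    if (startsWith(parts$vf2, "A")) {
      parts$vf2 <- paste0("C", substring(parts$vf2, 2L))
    }
    seq <- paste0(parts$left, parts$vf1, "GAATTC", parts$stuffer,
                  "CTCGAG", parts$vf2, parts$right)
    # junction-spanning motif check (segment-internal ones already excluded)
    for (m in forbidden_motifs()[1:4]) {
      pos <- gregexpr(m, seq, fixed = TRUE)[[1L]]
      pos <- pos[pos > 0L]
      expected <- c(GAATTC = 1201L, CTCGAG = 1507L)[m]
      if (!all(pos %in% expected)) {
        stop("internal error: stray motif in bundled vector") # nocov
      }
    }
    cache <<- list(seq = seq,
                   vf1 = c(1151L, 1200L), vf2 = c(1513L, 1562L),
                   enzyme1_at = c(1201L, 1206L), enzyme2_at = c(1507L, 1512L))
    cache
  }
})

# ---- ProtocolSpec ------------------------------------------------------

new_protocol <- function(vector_seq, vf1, vf2, enzyme1, enzyme2,
                         adapter_sense, adapter_antisense,
                         direction_rules, termini = NULL, name = "default") {
  for (m in c(enzyme1, enzyme2, adapter_sense, adapter_antisense, vector_seq)) {
    bad <- regexpr("[^ACGT]", m)
    if (bad > 0L) {
      stop_validation("non-DNA character '%s' at position %d",
                      substr(m, bad, bad), bad)
    }
  }
  V <- nchar(vector_seq)
  if (any(c(vf1, vf2) < 1L) || any(c(vf1, vf2) > V)) {
    stop_validation("VF intervals must lie within the vector (length %d)", V)
  }
  if (vf1[2L] >= vf2[1L]) stop_validation("vf1 must precede vf2")
  termini <- termini %||%
    default_terminus_table(enzyme1, enzyme2, adapter_sense, adapter_antisense)
  nms <- vapply(termini, `[[`, character(1L), "name")
  if (anyDuplicated(nms)) stop_validation("duplicate terminus names")
  structure(list(
    name = name,
    vector_seq = vector_seq,
    vf1 = as.integer(vf1), vf2 = as.integer(vf2),
    enzyme1 = enzyme1, enzyme2 = enzyme2,
    adapter_sense = adapter_sense, adapter_antisense = adapter_antisense,
    termini = termini,
    direction_rules = direction_rules
  ), class = "est_protocol")
}

#' The default EcoRI/XhoI directional-cloning protocol
#'
#' Builds the protocol used throughout: a pBluescript-like synthetic vector
#' (bundled stand-in, 2.7 kb) with a directional EcoRI (`GAATTC`) / XhoI
#' (`CTCGAG`) cloning site, the 9-mer adapter `GGCACGAGG` (sense) /
#' `CCTCGTGCC` (antisense), 50-base vector borders `VF1`/`VF2` flanking the
#' cloning sites, and the full expanded terminus variant table for the four
#' canonical termini `5TSS`, `3TSS`, `5TNS`, `3TNS` and their sub-categories
#' (e.g. `3TSS-1` = poly(A) + XhoI, `5TNS-4` = VF2' + C + poly(T)).
#'
#' Read-name direction rules default to the Sanger plate convention:
#' names containing `.g1` are 5' reads, `.b1` are 3' reads.
#'
#' @return An object of class `est_protocol`.
#' @examples
#' p <- default_protocol()
#' terminus_table(p)
#' @export
default_protocol <- function() {
  dv <- demo_vector()
  new_protocol(
    vector_seq = dv$seq, vf1 = dv$vf1, vf2 = dv$vf2,
    enzyme1 = "GAATTC", enzyme2 = "CTCGAG",
    adapter_sense = "GGCACGAGG", adapter_antisense = "CCTCGTGCC",
    direction_rules = tibble(pattern = c("\\.g1", "\\.b1"),
                             direction = c("5'", "3'"))
  )
}

#' Tabular view of a protocol's terminus definitions
#'
#' @param protocol An `est_protocol`.
#' @return A tibble with one row per terminus definition: name, family,
#'   element count and the comma-joined element labels.
#' @export
terminus_table <- function(protocol) {
  stopifnot(inherits(protocol, "est_protocol"))
  defs <- unname(protocol$termini)
  tibble(
    name = vapply(defs, `[[`, character(1L), "name"),
    family = vapply(defs, `[[`, character(1L), "family"),
    n_elements = vapply(defs, function(d) length(d$elements), integer(1L)),
    elements = vapply(defs, function(d)
      paste(vapply(d$elements, `[[`, character(1L), "label"), collapse = "+"),
      character(1L))
  )
}

#' @export
print.est_protocol <- function(x, ...) {
  cat(sprintf("<est_protocol '%s'>\n", x$name))
  cat(sprintf("  vector: %d bp; VF1 %d-%d, VF2 %d-%d\n", nchar(x$vector_seq),
              x$vf1[1L], x$vf1[2L], x$vf2[1L], x$vf2[2L]))
  cat(sprintf("  enzyme1 %s, enzyme2 %s, adapter %s/%s\n", x$enzyme1,
              x$enzyme2, x$adapter_sense, x$adapter_antisense))
  cat(sprintf("  %d terminus definitions\n", length(x$termini)))
  invisible(x)
}

#' Load a protocol from a YAML configuration
#'
#' The configuration describes a cDNA library-construction protocol: the
#' plasmid vector (inline string or FASTA path), the 1-based inclusive
#' coordinates of the left/right cloning-site borders (`vf1`, `vf2`), the two
#' restriction-enzyme recognition motifs, the adapter, and the read-name
#' direction rules. The terminus variant table is auto-expanded from these
#' fields exactly as in [default_protocol()].
#'
#' @param path Path to a YAML file, or `NULL` if `text` is given.
#' @param text YAML text (alternative to `path`).
#' @return An `est_protocol`.
#' @export
load_protocol <- function(path = NULL, text = NULL) {
  cfg <- tryCatch(
    if (is.null(text)) yaml::read_yaml(path) else yaml::yaml.load(text),
    error = function(e) stop_validation("cannot parse protocol config: %s",
                                        conditionMessage(e)))
  need <- c("vector", "vf1", "vf2", "enzyme1", "enzyme2", "adapter_sense")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop_validation("protocol config missing field(s): %s",
                                    paste(miss, collapse = ", "))
  vec <- cfg$vector
  if (file.exists(vec) && !grepl("^[ACGTN]+$", vec)) {
    vec <- as.character(Biostrings::readDNAStringSet(vec)[[1L]])
  }
  vec <- toupper(gsub("\\s", "", vec))
  anti <- cfg$adapter_antisense %||% reverse_complement(cfg$adapter_sense)
  rules <- if (is.null(cfg$direction_rules)) {
    tibble(pattern = c("\\.g1", "\\.b1"), direction = c("5'", "3'"))
  } else {
    tibble(pattern = vapply(cfg$direction_rules, `[[`, character(1L), "pattern"),
           direction = vapply(cfg$direction_rules, `[[`, character(1L), "direction"))
  }
  if (!all(rules$direction %in% c("5'", "3'"))) {
    stop_validation("direction rules must map to \"5'\" or \"3'\"")
  }
  new_protocol(
    vector_seq = vec,
    vf1 = unlist(cfg$vf1), vf2 = unlist(cfg$vf2),
    enzyme1 = toupper(cfg$enzyme1), enzyme2 = toupper(cfg$enzyme2),
    adapter_sense = toupper(cfg$adapter_sense),
    adapter_antisense = toupper(anti),
    direction_rules = rules,
    name = cfg$name %||% "custom"
  )
}

#' Assign designated read directions from read names
#'
#' Applies a protocol's direction rules (regular expressions over read names)
#' to classify each read as a designated 5' or 3' read; names matching no
#' rule get direction `"unknown"`.
#'
#' @param ids Character vector of read names.
#' @param protocol An `est_protocol`.
#' @return Character vector of `"5'"`, `"3'"` or `"unknown"`.
#' @export
designate_direction <- function(ids, protocol) {
  out <- rep("unknown", length(ids))
  for (i in seq_len(nrow(protocol$direction_rules))) {
    hit <- grepl(protocol$direction_rules$pattern[i], ids) & out == "unknown"
    out[hit] <- protocol$direction_rules$direction[i]
  }
  out
}

# vector-border read intervals for a protocol, used by the simulator
protocol_piece <- function(protocol, what) {
  v <- protocol$vector_seq
  switch(what,
    vf1     = substr(v, protocol$vf1[1L], protocol$vf1[2L]),
    vf2     = substr(v, protocol$vf2[1L], protocol$vf2[2L]),
    stuffer = substr(v, protocol$vf1[2L] + nchar(protocol$enzyme1) + 1L,
                        protocol$vf2[1L] - nchar(protocol$enzyme2) - 1L),
    left_arm  = substr(v, max(1L, protocol$vf1[1L] - 1150L), protocol$vf1[1L] - 1L),
    right_arm = substr(v, protocol$vf2[2L] + 1L,
                          min(nchar(v), protocol$vf2[2L] + 1150L)),
    stop("unknown piece ", what))
}
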