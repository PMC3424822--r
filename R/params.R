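#' Pipeline parameters
#'
#' Bundles every tunable threshold of the detection/scoring/trimming
#' pipeline, with the package defaults. All coordinates are bases; quality
#' thresholds are phred scores.
#'
#' @param window,min_q Quality segmentation: sliding-window width and mean
#'   phred threshold (see [segment_quality()]).
#' @param poly_min_len,poly_max_impurity Poly-tail run length and interior
#'   impurity tolerance (see [find_poly_tail()]).
#' @param vector_min_len,vector_min_identity Vector local-alignment
#'   acceptance thresholds (see [find_vector_hits()]).
#' @param enzyme_max_mismatch Mismatches allowed in the *global* enzyme-site
#'   scan (6-mers; default exact).
#' @param enzyme_rescue_mismatch Mismatches allowed for enzyme sites that
#'   are flanked on both sides by other detected terminus elements; 0
#'   disables the rescue pass.
#' @param adapter_max_mismatch Mismatches allowed for the 9-mer adapters.
#' @param dbt_max_mismatch Mismatches allowed in the 24-base double-termini
#'   adapter scan.
#' @param max_gap Maximum gap (bases) between consecutive components of one
#'   terminus.
#' @param weights Length-3 weights of the completeness (A), context (B) and
#'   base-match (C) sub-scores in the confidence score; must be
#'   non-negative and sum to 1.
#' @param min_separation Minimum bases between the two termini of a
#'   reasonable pair (the cDNA insert must fit between them).
#' @param min_clean_len Minimum surviving clean-insert length after
#'   trimming.
#' @param flank_len Flank window used for terminus context (B) scoring.
#' @param min_context_len Shortest inter-terminus region emitted as its own
#'   V/N pattern token; shorter slivers merge into their neighbour.
#' @param vf_min_overlap Minimum overlap (bases) between a vector alignment
#'   and a cloning-site border for a VF1/VF2 element call.
#' @param fallback Trim from a single direction-consistent terminus when no
#'   reasonable pair exists.
#' @return A list of class `est_params`.
#' @export
est_params <- function(window = 20L, min_q = 16,
                       poly_min_len = 8L, poly_max_impurity = 0.1,
                       vector_min_len = 20L, vector_min_identity = 0.94,
                       enzyme_max_mismatch = 0L, enzyme_rescue_mismatch = 1L,
                       adapter_max_mismatch = 1L, dbt_max_mismatch = 1L,
                       max_gap = 2L, weights = c(1, 1, 1) / 3,
                       min_separation = 200L, min_clean_len = 100L,
                       flank_len = 20L, min_context_len = 5L,
                       vf_min_overlap = 15L, fallback = TRUE) {
  check_weights(weights)
  if (window < 1L) stop_validation("window must be >= 1")
  if (poly_min_len < 2L) stop_validation("poly_min_len must be >= 2")
  if (min_separation < 0L || min_clean_len < 1L) {
    stop_validation("min_separation/min_clean_len out of range")
  }
  structure(list(
    window = as.integer(window), min_q = min_q,
    poly_min_len = as.integer(poly_min_len),
    poly_max_impurity = poly_max_impurity,
    vector_min_len = as.integer(vector_min_len),
    vector_min_identity = vector_min_identity,
    enzyme_max_mismatch = as.integer(enzyme_max_mismatch),
    enzyme_rescue_mismatch = as.integer(enzyme_rescue_mismatch),
    adapter_max_mismatch = as.integer(adapter_max_mismatch),
    dbt_max_mismatch = as.integer(dbt_max_mismatch),
    max_gap = as.integer(max_gap), weights = weights,
    min_separation = as.integer(min_separation),
    min_clean_len = as.integer(min_clean_len),
    flank_len = as.integer(flank_len),
    min_context_len = as.integer(min_context_len),
    vf_min_overlap = as.integer(vf_min_overlap),
    fallback = isTRUE(fallback)
  ), class = "est_params")
}

check_weights <- function(weights) {
  if (length(weights) != 3L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9) {
    stop_validation("weights must be 3 non-negative values summing to 1")
  }
  invisible(weights)
}
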