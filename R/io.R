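# FASTA/QUAL input and tabular output.

#' Read raw EST reads from FASTA (with optional paired QUAL)
#'
#' Loads a multi-record FASTA of raw Sanger reads, optionally pairs it with a
#' classic `.qual` file (FASTA-style headers, whitespace-separated per-base
#' phred scores, ids matched to the FASTA), and designates each read's
#' direction from the protocol's read-name rules.
#'
#' @param fasta Path to the FASTA file.
#' @param qual Optional path to the paired QUAL file.
#' @param protocol An `est_protocol`; used only for direction rules.
#' @return A tibble with columns `id`, `direction`, `bases`, and list-column
#'   `quals` (integer vectors, `NULL` when no QUAL was supplied).
#' @export
read_est_fasta <- function(fasta, qual = NULL, protocol = default_protocol()) {
  if (!file.exists(fasta)) stop_validation("FASTA file not found: %s", fasta)
  seqs <- tryCatch(Biostrings::readDNAStringSet(fasta),
                   error = function(e) stop_validation(
                     "malformed FASTA '%s': %s", fasta, conditionMessage(e)))
  ids <- sub("\\s.*$", "", names(seqs))
  reads <- tibble(
    id = ids,
    direction = designate_direction(ids, protocol),
    bases = unname(toupper(as.character(seqs))),
    quals = vector("list", length(seqs))
  )
  if (!is.null(qual)) {
    qv <- read_qual(qual)
    idx <- match(reads$id, names(qv))
    if (anyNA(idx)) {
      stop_validation("QUAL file missing record(s): %s",
                      paste(utils::head(reads$id[is.na(idx)], 3L), collapse = ", "))
    }
    reads$quals <- unname(qv[idx])
    bad <- which(lengths(reads$quals) != nchar(reads$bases))
    if (length(bad)) {
      stop_validation("QUAL/FASTA length mismatch for read '%s' (%d vs %d)",
                      reads$id[bad[1L]], lengths(reads$quals)[bad[1L]],
                      nchar(reads$bases)[bad[1L]])
    }
  }
  reads
}

# .qual files are FASTA-like but hold integers; no installed reader handles
# them, so parse by hand
read_qual <- function(path) {
  if (!file.exists(path)) stop_validation("QUAL file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop_validation("no records in QUAL file %s", path)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  starts <- hdr + 1L
  ends <- c(hdr[-1L] - 1L, length(lines))
  out <- lapply(seq_along(hdr), function(i) {
    if (starts[i] > ends[i]) return(integer(0L))
    txt <- paste(lines[starts[i]:ends[i]], collapse = " ")
    v <- suppressWarnings(as.integer(strsplit(trimws(txt), "\\s+")[[1L]]))
    if (anyNA(v)) stop_validation("non-integer quality value in record '%s'", ids[i])
    v
  })
  stats::setNames(out, ids)
}

write_qual <- function(quals, ids, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(ids)) {
    writeLines(paste0(">", ids[i]), con)
    q <- quals[[i]]
    chunks <- split(q, ceiling(seq_along(q) / 30L))
    writeLines(vapply(chunks, paste, character(1L), collapse = " "), con)
  }
  invisible(path)
}

write_fasta <- function(bases, ids, path) {
  x <- Biostrings::DNAStringSet(bases)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  # flatten list columns for serialization
  for (j in seq_along(df)) {
    if (is.list(df[[j]])) {
      df[[j]] <- vapply(df[[j]], function(x)
        paste(unlist(x), collapse = ";"), character(1L))
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
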