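test_that("quality segmentation handles uniform and missing qualities", {
  s <- segment_quality(rep(40L, 500L))
  expect_equal(nrow(s), 1L)
  expect_equal(c(s$start, s$end, s$label), c("1", "500", "high"))
  s2 <- segment_quality(NULL, len = 120L)
  expect_equal(s2$label, "high")
  expect_equal(s2$end, 120L)
  expect_error(segment_quality(rep(40L, 10L), len = 12L),
               class = "estclean_validation_error")
})

test_that("a sharp quality drop segments exactly at the transition", {
  q <- c(rep(40L, 300L), rep(5L, 200L))
  s <- segment_quality(q, window = 20L, min_q = 16)
  expect_equal(s$label, c("high", "low"))
  expect_equal(s$end, c(300L, 500L))
  expect_tiles(s, 500L)
  # interior low islands are recovered too
  q2 <- c(rep(40L, 100L), rep(6L, 60L), rep(40L, 100L))
  s2 <- segment_quality(q2)
  expect_equal(s2$label, c("high", "low", "high"))
  expect_equal(s2$start[2L], 101L)
  expect_equal(s2$end[2L], 160L)
})

test_that("quality segments always partition the read (property)", {
  withr::with_seed(42L, {
    for (i in 1:30) {
      n <- sample(30:400, 1L)
      q <- sample(0:45, n, replace = TRUE)
      s <- segment_quality(q)
      expect_tiles(s, n)
      # merging adjacent same-label segments is idempotent
      expect_false(any(s$label[-1L] == s$label[-nrow(s)]))
    }
  })
})

test_that("motif scan equals the brute-force Hamming oracle (property)", {
  motifs <- c("GAATTC", "CTCGAG", "GGCACGAGG", "CCTCGTGCC")
  withr::with_seed(7L, {
    for (i in 1:40) {
      n <- sample(50:600, 1L)
      s <- random_dna(n)
      # plant a motif (sometimes corrupted) to guarantee non-trivial cases
      m <- sample(motifs, 1L)
      pos <- sample(n - nchar(m), 1L)
      substr(s, pos, pos + nchar(m) - 1L) <- m
      k <- sample(0:2, 1L)
      hits <- find_motif_hits(s, m, max_mismatch = k)
      expect_equal(hits$start, oracle_motif_scan(s, m, k))
      expect_true(all(hits$end - hits$start + 1L == nchar(m)))
      expect_true(all(hits$matched_fraction > 0 & hits$matched_fraction <= 1))
    }
  })
  expect_equal(find_motif_hits("TTGAATTCAA", "GAATTC")$start, 3L)
  expect_error(find_motif_hits("ACGT", ""), class = "estclean_validation_error")
})

test_that("one-mismatch adapter hits report the matched fraction", {
  s <- paste0("TTTT", "GGCACGAGG", "TTTT")
  substr(s, 8L, 8L) <- "T"  # corrupt one adapter base
  h <- find_motif_hits(s, "GGCACGAGG", max_mismatch = 1L)
  expect_equal(nrow(h), 1L)
  expect_equal(h$mismatches, 1L)
  expect_equal(h$matched_fraction, 8 / 9)
})

test_that("poly-tail runs respect length and impurity rules", {
  expect_equal(find_poly_tail("CCAAAAAAAAGG", "A")$start, 3L)
  expect_equal(find_poly_tail("CCAAAAAAAAGG", "A")$end, 10L)
  expect_equal(nrow(find_poly_tail("AAAAAAA", "A")), 0L)  # 7 < min_len
  # 12 As broken by one interior G merge into a single 13-base run
  h <- find_poly_tail("AAAAAAGAAAAAA", "A")
  expect_equal(nrow(h), 1L)
  expect_equal(c(h$start, h$end), c(1L, 13L))
  expect_equal(h$mismatches, 1L)
  # two separated tails are both reported
  s <- paste0(strrep("A", 10L), strrep("C", 20L), strrep("A", 9L))
  expect_equal(nrow(find_poly_tail(s, "A")), 2L)
})

test_that("vector hits find planted fragments on both strands", {
  p <- test_protocol()
  vf2 <- substr(p$vector_seq, p$vf2[1L], p$vf2[2L])
  withr::with_seed(11L, {
    read <- paste0(random_dna(150), vf2, random_dna(150))
  })
  h <- find_vector_hits(read, p$vector_seq)
  expect_equal(nrow(h), 1L)
  expect_equal(h$strand, "+")
  expect_true(h$start <= 151L && h$end >= 200L)
  expect_equal(h$matched_fraction, 1.0)
  # reverse-complementing the read mirrors the hit coordinates
  rcread <- reverse_complement(read)
  h2 <- find_vector_hits(rcread, p$vector_seq)
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$strand, "-")
  expect_equal(h2$start, nchar(read) - h$end + 1L)
  expect_equal(h2$end, nchar(read) - h$start + 1L)
  expect_equal(c(h2$vstart, h2$vend), c(h$vstart, h$vend))
})

test_that("vector hits tolerate scattered mismatches and survive indels", {
  p <- test_protocol()
  frag <- substr(p$vector_seq, 301L, 420L)
  substr(frag, 40L, 40L) <- "A"; substr(frag, 41L, 41L) <- "A"
  withr::with_seed(3L, read <- paste0(random_dna(100), frag, random_dna(100)))
  h <- find_vector_hits(read, p$vector_seq)
  expect_equal(nrow(h), 1L)
  expect_gte(h$end - h$start + 1L, 100L)
  # a deletion splits the diagonal; the banded refinement bridges it
  frag2 <- paste0(substr(frag, 1L, 60L), substr(frag, 62L, 120L))
  withr::with_seed(4L, read2 <- paste0(random_dna(80), frag2, random_dna(80)))
  h2 <- find_vector_hits(read2, p$vector_seq)
  expect_gte(sum(h2$end - h2$start + 1L), 100L)
})

test_that("random reads produce no vector hits at default thresholds", {
  p <- test_protocol()
  withr::with_seed(20260927L, {
    n_hits <- 0L
    for (i in 1:1000) {
      r <- random_dna(500L)
      n_hits <- n_hits + nrow(find_vector_hits(r, p$vector_seq))
    }
  })
  expect_equal(n_hits, 0L)
})

test_that("context labels follow the majority-coverage rules", {
  segs <- tibble::tibble(start = c(1L, 101L), end = c(100L, 200L),
                         label = c("high", "low"))
  vh <- hit_stub(start = 40L, end = 160L)
  expect_equal(classify_context(50L, 60L, vh, segs), "HV")
  expect_equal(classify_context(1L, 20L, vh, segs), "HN")
  expect_equal(classify_context(150L, 200L, vh, segs), "LN")  # 11/51 vector
  expect_equal(classify_context(120L, 160L, vh, segs), "LV")
  expect_error(classify_context(10L, 5L, vh, segs),
               class = "estclean_validation_error")
})
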