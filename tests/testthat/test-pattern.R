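# helpers building constructed reads through the detection front end
scan_read <- function(bases, p = test_protocol(), params = est_params()) {
  det <- estclean:::detect_read_elements(bases, p, params)
  segs <- segment_quality(NULL, len = nchar(bases))
  t <- assemble_termini(det$elements, p, params$max_gap, bases)
  t <- estclean:::score_termini(t, det$vector_hits, segs, nchar(bases),
                                p, params)
  list(termini = t, det = det, segs = segs, len = nchar(bases))
}

test_that("terminus assembly produces a full 3TSS locus with sub-variants", {
  p <- test_protocol()
  vf2 <- substr(p$vector_seq, p$vf2[1L], p$vf2[2L])
  read <- withr::with_seed(5L, paste0(
    random_dna(99), "C", strrep("A", 20L), "CTCGAG", vf2))
  sc <- scan_read(read)
  expect_setequal(
    intersect(sc$termini$def_name,
              c("3TSS", "3TSS-1", "3TSS-2", "3TSS-3", "3TSS-5")),
    c("3TSS", "3TSS-1", "3TSS-2", "3TSS-3", "3TSS-5"))
  d <- disambiguate(sc$termini)
  expect_equal(d$def_name, "3TSS")  # the canonical survives disambiguation
  expect_equal(c(d$start, d$end), c(101L, 176L))
})

test_that("the replaced-site variant 5TNS-4 assembles via its single base", {
  p <- test_protocol()
  vf2rc <- reverse_complement(substr(p$vector_seq, p$vf2[1L], p$vf2[2L]))
  read <- withr::with_seed(6L, paste0(vf2rc, "C", strrep("T", 20L),
                                      random_dna(150)))
  d <- disambiguate(scan_read(read)$termini)
  expect_equal(d$def_name, "5TNS-4")
  expect_equal(c(d$start, d$end), c(1L, 71L))
})

test_that("a bare enzyme site is not a terminus", {
  read <- withr::with_seed(8L, paste0(random_dna(100), "CTCGAG",
                                      random_dna(100)))
  sc <- scan_read(read)
  expect_equal(nrow(sc$termini), 0L)
})

test_that("sub-scores follow the stated contract", {
  p <- test_protocol()
  # context score: vector / low-quality non-vector / high-quality non-vector
  expect_equal(context_score("HV", "vector"), 100)
  expect_equal(context_score("LV", "vector"), 100)
  expect_equal(context_score("LN", "vector"), 50)
  expect_equal(context_score("HN", "vector"), 0)
  expect_equal(context_score("HN", "insert"), 100)
  expect_equal(context_score("HV", "insert"), 0)
  expect_equal(context_score("LV", "insert"), 50)

  # completeness ordering within the 5TNS family
  a_of <- function(name) {
    hit <- list(def_name = name, family = "5TNS",
                a_count = p$termini[[name]]$a_count, start = 1L, end = 10L,
                matched = 10)
    score_terminus(hit, NA, NA, protocol = p)$a_score
  }
  expect_gt(a_of("5TNS"), a_of("5TNS-1"))
  expect_equal(a_of("5TNS-1"), a_of("5TNS-2"))
  expect_gt(a_of("5TNS-2"), a_of("5TNS-3"))

  # canonical full-score case
  hit <- list(def_name = "5TNS", family = "5TNS", a_count = 3L,
              start = 1L, end = 76L, matched = 76)
  s <- score_terminus(hit, "HV", "HN", protocol = p)
  expect_equal(unlist(s), c(a_score = 100, b_score = 100, c_score = 100,
                            confidence = 100))
  # 2/3 elements, one flank at 50, perfect bases, equal weights
  hit2 <- list(def_name = "5TNS-1", family = "5TNS", a_count = 2L,
               start = 1L, end = 26L, matched = 26)
  s2 <- score_terminus(hit2, "LN", "HV", protocol = p)  # 50 and 0 -> b = 25
  expect_equal(s2$a_score, 200 / 3)
  s3 <- score_terminus(hit2, "LN", "LV", protocol = p)  # 50 and 50
  expect_equal(s3$b_score, 50)
  expect_equal(s3$confidence, (200 / 3 + 50 + 100) / 3, tolerance = 1e-12)
  expect_equal(round(s3$confidence, 2), 72.22)
})

test_that("confidence is linear in the weights and bounded", {
  p <- test_protocol()
  hit <- list(def_name = "5TNS-1", family = "5TNS", a_count = 2L,
              start = 1L, end = 26L, matched = 24)
  subs <- unlist(score_terminus(hit, "LN", "HN", protocol = p))[1:3]
  withr::with_seed(99L, {
    for (i in 1:20) {
      w <- stats::runif(3); w <- w / sum(w)
      s <- score_terminus(hit, "LN", "HN", weights = w, protocol = p)
      expect_equal(s$confidence, sum(w * subs), tolerance = 1e-9)
      expect_true(s$confidence >= 0 && s$confidence <= 100)
    }
  })
  expect_error(score_terminus(hit, "LN", "HN", weights = c(0.5, 0.5, 0.5)),
               class = "estclean_validation_error")
})

test_that("disambiguation keeps the stronger hit and is deterministic", {
  t <- estclean:::empty_termini()
  row <- function(name, fam, s, e, a_count, conf) {
    tibble::tibble(def_name = name, family = fam, start = s, end = e,
                   n_elements = a_count, a_count = a_count, matched = 1,
                   a_score = conf, b_score = conf, c_score = conf,
                   confidence = conf, components = list(NULL))
  }
  t <- rbind(row("3TNS", "3TNS", 100L, 130L, 3L, 95),
             row("3TNS-5", "3TNS", 105L, 130L, 1L, 60))
  expect_equal(disambiguate(t)$def_name, "3TNS")
  # disjoint hits are untouched
  t2 <- rbind(row("5TSS", "5TSS", 1L, 60L, 3L, 90),
              row("3TSS", "3TSS", 400L, 470L, 3L, 90))
  expect_equal(nrow(disambiguate(t2)), 2L)
  # exact ties resolve to the earlier start, reproducibly
  t3 <- rbind(row("5TNS-1", "5TNS", 50L, 80L, 2L, 70),
              row("3TSS-1", "3TSS", 52L, 82L, 2L, 70))
  expect_equal(disambiguate(t3)$def_name, "5TNS-1")
  expect_equal(disambiguate(t3[2:1, ])$def_name, "5TNS-1")
})

test_that("pattern strings tile the read with terminus and context tokens", {
  p <- test_protocol()
  # two bare poly(A) fragments -> N,3TSS-3,N,3TSS-3,N
  read <- withr::with_seed(12L, {
    j <- make_construct("CASE-1", protocol = p)
    j$bases
  })
  sc <- scan_read(read)
  pat <- build_pattern(nchar(read), disambiguate(sc$termini),
                       sc$det$vector_hits, sc$segs)
  expect_equal(render_pattern(pat), "N,3TSS-3,N,3TSS-3,N")
  expect_tiles(pat$tokens[, c("start", "end")], nchar(read))
  # no hits at all -> single N token
  r2 <- withr::with_seed(13L, random_dna(150))
  sc2 <- scan_read(r2)
  pat2 <- build_pattern(150L, disambiguate(sc2$termini),
                        sc2$det$vector_hits, sc2$segs)
  expect_equal(render_pattern(pat2), "N")
})

test_that("patterns of mirrored reads mirror token by token", {
  p <- test_protocol()
  fam_swap <- c("5TSS" = "3TNS", "3TNS" = "5TSS",
                "3TSS" = "5TNS", "5TNS" = "3TSS")
  pattern_of <- function(bases) {
    sc <- scan_read(bases, p)
    render_pattern(build_pattern(nchar(bases), disambiguate(sc$termini),
                                 sc$det$vector_hits, sc$segs))
  }
  mirror_tokens <- function(pat) {
    toks <- rev(strsplit(pat, ",")[[1L]])
    vapply(toks, function(tk) {
      if (tk %in% c("V", "N")) return(tk)
      fam <- sub("^([35]T[NS]S).*$", "\\1", tk)
      sub(fam, fam_swap[[fam]], tk, fixed = TRUE)
    }, character(1L), USE.NAMES = FALSE)
  }
  withr::with_seed(21L, {
    for (layout in c("expected", "RECA-C", "RECA-B1")) {
      cons <- make_construct(layout, "5'", protocol = p)
      fwd <- pattern_of(cons$bases)
      rev_ <- pattern_of(reverse_complement(cons$bases))
      expect_equal(strsplit(rev_, ",")[[1L]], mirror_tokens(fwd),
                   info = layout)
    }
  })
})

test_that("reasonable pairs respect direction, order and separation", {
  mk <- function(name, fam, s, e, conf = 80) {
    tibble::tibble(def_name = name, family = fam, start = s, end = e,
                   n_elements = 2L, a_count = 2L, matched = 1,
                   a_score = conf, b_score = conf, c_score = conf,
                   confidence = conf, components = list(NULL))
  }
  t <- rbind(mk("5TSS", "5TSS", 10L, 75L), mk("3TSS", "3TSS", 600L, 680L))
  pr <- find_reasonable_pairs(t, "5'")
  expect_equal(nrow(pr), 1L)
  expect_equal(pr$separation, 524L)
  # too close to contain an insert
  t2 <- rbind(mk("5TSS", "5TSS", 10L, 75L), mk("3TSS", "3TSS", 150L, 220L))
  expect_equal(nrow(find_reasonable_pairs(t2, "5'")), 0L)
  # wrong order on a 3' read
  t3 <- rbind(mk("3TNS", "3TNS", 10L, 80L), mk("5TNS", "5TNS", 500L, 570L))
  expect_equal(nrow(find_reasonable_pairs(t3, "3'")), 0L)
  expect_warning(find_reasonable_pairs(t, "unknown"), "unknown")
})

test_that("pair separation boundary sits exactly at the minimum", {
  mk <- function(s, e, fam, name) {
    tibble::tibble(def_name = name, family = fam, start = s, end = e,
                   n_elements = 2L, a_count = 2L, matched = 1, a_score = 80,
                   b_score = 80, c_score = 80, confidence = 80,
                   components = list(NULL))
  }
  left <- mk(1L, 60L, "5TSS", "5TSS")
  # separation = right_start - left_end - 1
  at <- function(sep) rbind(left, mk(60L + sep + 1L, 60L + sep + 80L,
                                     "3TSS", "3TSS"))
  expect_equal(nrow(find_reasonable_pairs(at(199L), "5'")), 0L)
  expect_equal(nrow(find_reasonable_pairs(at(200L), "5'")), 1L)
})

test_that("best-pair selection equals exhaustive enumeration (property)", {
  withr::with_seed(31L, {
    for (rep_i in 1:200) {
      k <- sample(2:6, 1L)
      fams <- sample(c("5TSS", "3TSS"), k, replace = TRUE)
      starts <- sort(sample(1:900, k))
      t <- tibble::tibble(
        def_name = paste0(fams, "-x", seq_len(k)), family = fams,
        start = as.integer(starts), end = as.integer(starts + 30L),
        n_elements = 2L, a_count = 2L, matched = 1,
        a_score = 50, b_score = 50, c_score = 50,
        confidence = round(stats::runif(k, 40, 100), 4),
        components = replicate(k, NULL, simplify = FALSE))
      pairs <- find_reasonable_pairs(t, "5'")
      best <- select_best_pair(pairs)
      # oracle: enumerate all index pairs directly
      best_val <- -Inf
      for (i in seq_len(k)) for (j in seq_len(k)) {
        if (t$family[i] == "5TSS" && t$family[j] == "3TSS" &&
            t$end[i] < t$start[j] &&
            (t$start[j] - t$end[i] - 1L) >= 200L) {
          best_val <- max(best_val, t$confidence[i] + t$confidence[j])
        }
      }
      if (is.null(best)) {
        expect_identical(best_val, -Inf)
      } else {
        expect_equal(best$cumulative_confidence, best_val)
        expect_gte(best$separation, 200L)
      }
    }
  })
})
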