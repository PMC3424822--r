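test_that("the type-1 DBT motif is its own reverse complement", {
  m <- dbt_motifs()
  expect_equal(reverse_complement(m[["type1"]]), m[["type1"]])
  expect_equal(nchar(m), c(type1 = 24L, type2 = 24L))
})

test_that("DBT detection finds both concatenation types and repetitions", {
  m <- dbt_motifs()
  r1 <- withr::with_seed(1L, paste0(random_dna(80), m[["type1"]],
                                    random_dna(80)))
  h1 <- detect_dbt(r1)
  expect_equal(nrow(h1), 1L)
  expect_equal(h1$dbt_type, 1L)
  expect_equal(h1$start, 81L)
  r2 <- withr::with_seed(2L, paste0(random_dna(50), m[["type2"]],
                                    random_dna(50)))
  expect_equal(detect_dbt(r2)$dbt_type, 2L)
  # a triple direct repetition indexes 1..3
  r3 <- paste0("TTTT", strrep(m[["type1"]], 3L), "GGGG")
  h3 <- detect_dbt(r3)
  expect_equal(h3$repetition_index, 1:3)
  # reverse-complementing maps type-1 hits onto type-1 hits
  h4 <- detect_dbt(reverse_complement(r1))
  expect_equal(h4$dbt_type, 1L)
  expect_equal(h4$start, nchar(r1) - h1$end + 1L)
})

test_that("DBT scan equals the brute-force oracle on random reads", {
  m <- dbt_motifs()
  withr::with_seed(17L, {
    for (i in 1:50) {
      r <- random_dna(sample(100:400, 1L))
      if (stats::runif(1) < 0.8) {
        ins <- sample(m, 1L)
        at <- sample(nchar(r) - 30L, 1L)
        r <- paste0(substr(r, 1L, at), ins, substr(r, at + 1L, nchar(r)))
      }
      got <- detect_dbt(r)
      want <- oracle_dbt_scan(r)
      expect_equal(got$start, want$start)
      expect_equal(got$dbt_type, want$type)
    }
  })
})

test_that("RECA templates classify their own synthetic constructs (18x)", {
  p <- test_protocol()
  withr::with_seed(77L, {
    for (ty in paste0("RECA-", c("A1", "A2", "A3", "B1", "B2",
                                 "C", "D", "E", "F"))) {
      for (d in c("5'", "3'")) {
        cons <- make_construct(ty, d, p)
        rep <- process_read("t", cons$bases, NULL, d, p)
        expect_equal(rep$primary_call, ty, info = paste(ty, d))
        expect_equal(rep$outcome, "filtered", info = paste(ty, d))
      }
    }
  })
})

test_that("RECA classification works from pattern renderings directly", {
  p <- test_protocol()
  fake_pattern <- function(rendering) {
    toks <- strsplit(rendering, ",")[[1L]]
    structure(list(
      tokens = tibble::tibble(
        token = toks,
        type = ifelse(toks %in% c("V", "N"), "context", "terminus"),
        start = seq_along(toks) * 100L,
        end = seq_along(toks) * 100L + 99L,
        refined = NA_character_, vstart = NA_integer_, vend = NA_integer_),
      rendering = rendering), class = "est_pattern")
  }
  expect_equal(classify_reca(fake_pattern("5TSS-2,V,3TSS-2"), "5'", p),
               "RECA-C")
  expect_equal(classify_reca(fake_pattern("N,3TNS-1,V,3TSS-2"), "5'", p),
               "RECA-A1")
  expect_true(is.na(classify_reca(fake_pattern("5TSS,N,3TSS,V"), "5'", p)))
  # vector between two termini without a template -> RECA-other
  expect_equal(classify_reca(fake_pattern("3TSS-1,V,5TNS-1"), "5'", p),
               "RECA-other")
})

test_that("frequent abnormal cases match their signature templates", {
  fp <- function(rendering) structure(
    list(tokens = NULL, rendering = rendering), class = "est_pattern")
  expect_equal(classify_case(fp("N,3TSS-3,N,3TSS-3,N"), "5'"), "CASE-1")
  expect_equal(classify_case(fp("N,3TSS-3,N"), "5'"), "CASE-1")
  expect_equal(classify_case(fp("5TNS-4,N"), "3'"), "CASE-2")
  expect_equal(classify_case(fp("N,5TNS-4,N"), "3'"), "CASE-2")
  expect_equal(classify_case(fp("N,3TSS-4,V"), "5'"), "CASE-8")
  expect_true(is.na(classify_case(fp("N,3TSS-4,V"), "3'")))
  expect_true(is.na(classify_case(fp("5TSS,N,3TSS"), "5'")))
})

test_that("all eight case layouts round-trip through the pipeline", {
  p <- test_protocol()
  withr::with_seed(41L, {
    for (cs in paste0("CASE-", 1:8)) {
      cons <- make_construct(cs, protocol = p)
      rep <- process_read("t", cons$bases, NULL, cons$direction, p)
      expect_equal(rep$primary_call, cs, info = cs)
    }
  })
})

test_that("direction conflicts are flagged but yield to stronger calls", {
  p <- test_protocol()
  withr::with_seed(43L, {
    cons <- make_construct("CASE-5", protocol = p)  # 5' read, 5TNS-1 only
    rep <- process_read("t", cons$bases, NULL, "5'", p)
    expect_equal(rep$primary_call, "CASE-5")
    expect_match(rep$secondary_calls, "direction-conflict")
    # a 3' RECA-B1 read contains sense termini; RECA takes precedence
    cons2 <- make_construct("RECA-B1", "3'", p)
    rep2 <- process_read("t", cons2$bases, NULL, "3'", p)
    expect_equal(rep2$primary_call, "RECA-B1")
    expect_false(grepl("direction-conflict", rep2$secondary_calls))
    # a normal 5' read is not flagged
    cons3 <- make_construct("expected", "5'", p)
    rep3 <- process_read("t", cons3$bases, NULL, "5'", p)
    expect_true(is.na(rep3$primary_call))
  })
})

test_that("DBTs resolve to internal only inside a 5TNS..3TNS span", {
  p <- test_protocol()
  withr::with_seed(47L, {
    cons <- make_construct("DBT-internal", protocol = p)
    rep <- process_read("t", cons$bases, NULL, "3'", p)
    expect_equal(rep$primary_call, "DBT-internal")
    expect_equal(rep$outcome, "clean")
    cons2 <- make_construct("DBT1-chimera", protocol = p)
    rep2 <- process_read("t", cons2$bases, NULL, "5'", p)
    expect_equal(rep2$primary_call, "DBT-chimera")
    expect_equal(rep2$outcome, "filtered")
  })
  # repetition runs stay one call group
  m <- dbt_motifs()
  hits <- detect_dbt(paste0("AAAA", strrep(m[["type1"]], 3L), "CCCC"))
  expect_equal(max(hits$repetition_index), 3L)
  t0 <- estclean:::empty_termini()
  expect_equal(resolve_dbt(t0, hits, "5'"), "DBT-chimera")
})

test_that("no synthetic single-layout read receives two RECA categories", {
  p <- test_protocol()
  withr::with_seed(53L, {
    for (ty in paste0("RECA-", c("A1", "B2", "C", "E", "F"))) {
      cons <- make_construct(ty, "5'", p)
      rep <- process_read("t", cons$bases, NULL, "5'", p)
      all_calls <- c(rep$primary_call,
                     strsplit(rep$secondary_calls, ";")[[1L]])
      expect_equal(sum(grepl("^RECA", all_calls)), 1L, info = ty)
    }
  })
})
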