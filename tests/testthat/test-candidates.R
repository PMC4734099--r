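make_tss <- function(position, strand, replicon = "c1", category = "unknown",
                     reads = c(100L, 0L, 0L, 0L)) {
  tb <- tibble::tibble(replicon_id = replicon, position = as.integer(position),
                       strand = strand, category = category)
  for (i in seq_along(tss_libraries())) tb[[tss_libraries()[i]]] <- reads[i]
  tb
}

make_terms <- function(lo, hi, strand, replicon = "c1", score = 90) {
  tibble::tibble(replicon_id = replicon,
                 terminator_id = paste0(replicon, ":T", seq_along(lo)),
                 strand = strand, hairpin_lo = as.integer(lo),
                 hairpin_hi = as.integer(hi), tail = NA_character_,
                 score = score)
}

genes1 <- tibble::tibble(replicon_id = "c1", start = 1150L, end = 1250L,
                         strand = "+", locus_tag = "g1")

test_that("TSS classification follows position and orientation", {
  # vacuous gene set
  expect_equal(classify_tss(make_tss(1000, "+"), genes1[0, ]), "nTSS")
  # 150 nt upstream of a same-strand gene start -> gTSS; 300 nt -> nTSS
  expect_equal(classify_tss(make_tss(1000, "+"), genes1), "gTSS")
  g2 <- dplyr::mutate(genes1, start = 1300L, end = 1400L)
  expect_equal(classify_tss(make_tss(1000, "+"), g2), "nTSS")
  # exhaustive distance scan around the 200 nt cutoff
  for (d in c(1, 50, 200, 201, 400)) {
    got <- classify_tss(make_tss(1150 - d, "+"), genes1)
    expect_equal(got, if (d <= 200) "gTSS" else "nTSS", info = paste("d =", d))
  }
  # inside a same-strand gene (boundaries inclusive) -> iTSS
  expect_equal(classify_tss(make_tss(1150, "+"), genes1), "iTSS")
  expect_equal(classify_tss(make_tss(1250, "+"), genes1), "iTSS")
  # inside an opposite-strand gene -> aTSS (excluded from candidates)
  expect_equal(classify_tss(make_tss(1200, "-"), genes1), "aTSS")
  # minus-strand TSS upstream of a minus-strand gene (its start = end coord)
  g3 <- dplyr::mutate(genes1, strand = "-")
  expect_equal(classify_tss(make_tss(1350, "-"), g3), "gTSS")
  expect_equal(classify_tss(make_tss(1500, "-"), g3), "nTSS")
})

test_that("orphan-TSS filtering uses the maximum per-library read count", {
  t1 <- make_tss(500, "-", category = "nTSS", reads = c(4L, 1L, 1L, 2L))
  expect_equal(nrow(filter_ntss(t1, genes1)), 0)
  expect_equal(nrow(filter_ntss(t1, genes1, pipeline_params(min_reads = 4))), 1)
  t2 <- make_tss(500, "-", category = "nTSS", reads = c(0L, 0L, 0L, 50L))
  expect_equal(nrow(filter_ntss(t2, genes1)), 1)
  # stored non-nTSS categories are excluded without reclassification
  t3 <- make_tss(500, "-", category = "iTSS", reads = c(100L, 0L, 0L, 0L))
  expect_equal(nrow(filter_ntss(t3, genes1)), 0)
  # unknown categories are classified on the fly
  t4 <- make_tss(1200, "+", category = "unknown")
  expect_equal(nrow(filter_ntss(t4, genes1)), 0)  # internal
  t5 <- make_tss(700, "+", category = "unknown")
  expect_equal(nrow(filter_ntss(t5, genes1)), 1)
})

test_that("pairing keeps the shortest in-window segment per TSS", {
  set.seed(41)
  reps <- tibble::tibble(id = "c1", sequence = random_seq(1000),
                         length = 1000L, circular = FALSE)
  tss <- make_tss(101, "+", category = "nTSS")
  terms <- make_terms(lo = c(111, 181, 401, 461), hi = c(130, 200, 420, 480),
                      strand = "+")
  seg <- pair_segments(tss, terms, reps)
  # lengths 30/100/320/380; the window keeps 100 and 320; shortest wins
  expect_equal(nrow(seg), 1)
  expect_equal(seg$length_nt, 100L)
  expect_equal(seg$hairpin_hi, 200L)
  expect_equal(seg$id, "101f")
  expect_equal(seg$sequence, substr(reps$sequence, 101, 200))
  # no terminator downstream -> no segment
  seg2 <- pair_segments(make_tss(900, "+", category = "nTSS"), terms, reps)
  expect_equal(nrow(seg2), 0)
})

test_that("window boundaries are inclusive exactly at 45 and 350", {
  set.seed(42)
  reps <- tibble::tibble(id = "c1", sequence = random_seq(2000),
                         length = 2000L, circular = FALSE)
  for (len in c(44L, 45L, 350L, 351L)) {
    tss <- make_tss(100, "+", category = "nTSS")
    terms <- make_terms(lo = 100 + len - 20, hi = 100 + len - 1, strand = "+")
    n <- nrow(pair_segments(tss, terms, reps))
    expect_equal(n, as.integer(len >= 45 && len <= 350),
                 info = paste("len =", len))
  }
})

test_that("several TSSs may share one terminator; each TSS keeps one segment", {
  set.seed(43)
  reps <- tibble::tibble(id = "c1", sequence = random_seq(1000),
                         length = 1000L, circular = FALSE)
  tss <- dplyr::bind_rows(make_tss(101, "+", category = "nTSS"),
                          make_tss(151, "+", category = "nTSS"))
  terms <- make_terms(lo = 281, hi = 300, strand = "+")
  seg <- pair_segments(tss, terms, reps)
  expect_equal(nrow(seg), 2)
  expect_equal(unique(seg$terminator_id), "c1:T1")
  expect_equal(sort(seg$length_nt), c(150L, 200L))
})

test_that("pairing equals the brute-force oracle on random instances", {
  set.seed(44)
  reps <- tibble::tibble(id = "c1", sequence = random_seq(5000),
                         length = 5000L, circular = FALSE)
  for (case in 1:25) {
    n_t <- sample(1:20, 1); n_m <- sample(1:20, 1)
    tss <- dplyr::bind_rows(lapply(seq_len(n_t), function(i)
      make_tss(sample(4000, 1), sample(c("+", "-"), 1), category = "nTSS")))
    lo <- sample(4500, n_m)
    terms <- make_terms(lo = lo, hi = lo + sample(15:30, n_m, TRUE),
                        strand = sample(c("+", "-"), n_m, TRUE),
                        score = sample(80:100, n_m, TRUE))
    got <- pair_segments(tss, terms, reps)
    want <- oracle_pairing(tss, terms)
    expect_equal(nrow(got), nrow(want), info = paste("case", case))
    if (nrow(want) == 0) next
    want_key <- sort(paste(tss$position[want$tss_row],
                           tss$strand[want$tss_row], want$length_nt))
    got_key <- sort(paste(got$tss_position, got$strand, got$length_nt))
    expect_equal(got_key, want_key, info = paste("case", case))
  }
})

test_that("emitted sequences re-locate to their recorded coordinates", {
  set.seed(45)
  reps <- tibble::tibble(id = "c1", sequence = random_seq(3000),
                         length = 3000L, circular = FALSE)
  tss <- dplyr::bind_rows(make_tss(200, "+", category = "nTSS"),
                          make_tss(1500, "-", category = "nTSS"))
  terms <- make_terms(lo = c(361, 1301), hi = c(380, 1320),
                      strand = c("+", "-"))
  seg <- pair_segments(tss, terms, reps)
  expect_equal(nrow(seg), 2)
  for (i in seq_len(nrow(seg))) {
    lo <- if (seg$strand[i] == "+") seg$tss_position[i] else seg$hairpin_lo[i]
    hi <- if (seg$strand[i] == "+") seg$hairpin_hi[i] else seg$tss_position[i]
    raw <- substr(reps$sequence, lo, hi)
    if (seg$strand[i] == "-") {
      raw <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(raw)))
    }
    expect_equal(seg$sequence[i], raw)
    expect_equal(nchar(seg$sequence[i]), seg$length_nt[i])
  }
})

test_that("first-terminator-then-window variant is available behind a flag", {
  set.seed(46)
  reps <- tibble::tibble(id = "c1", sequence = random_seq(1000),
                         length = 1000L, circular = FALSE)
  tss <- make_tss(101, "+", category = "nTSS")
  # nearest terminator gives a 30 nt (sub-window) segment
  terms <- make_terms(lo = c(111, 181), hi = c(130, 200), strand = "+")
  default <- pair_segments(tss, terms, reps)
  expect_equal(default$length_nt, 100L)
  strict <- pair_segments(tss, terms, reps,
                          pipeline_params(shortest_after_window = FALSE))
  expect_equal(nrow(strict), 0)
})

test_that("replicon mismatches raise consistency errors", {
  reps <- tibble::tibble(id = "c1", sequence = strrep("A", 100),
                         length = 100L, circular = FALSE)
  tss <- make_tss(10, "+", replicon = "cX", category = "nTSS")
  terms <- make_terms(lo = 50, hi = 70, strand = "+")
  expect_error(pair_segments(tss, terms, reps),
               class = "srnaflow_consistency_error")
})
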