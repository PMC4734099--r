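test_that("FASTA reading normalizes ids, case and ambiguous characters", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">r1", "acgt"), f)
  reps <- read_fasta(f)
  expect_equal(reps$id, "r1")
  expect_equal(reps$sequence, "ACGT")

  writeLines(c(">r1 some description", "ACGTN", ">r2", "GG"), f)
  reps <- read_fasta(f)
  expect_equal(reps$id, c("r1", "r2"))
  expect_equal(reps$sequence, c("ACGTN", "GG"))

  writeLines(c(">rx", "ACGRYSWacgt"), f)
  expect_equal(read_fasta(f)$sequence, "ACGNNNNACGT")

  writeLines(character(), f)
  expect_error(read_fasta(f), class = "srnaflow_format_error")
  writeLines(c(">a", "ACGT", ">a", "GGGG"), f)
  expect_error(read_fasta(f), "duplicate.*a", class = "srnaflow_format_error")
})

test_that("FASTA write/read round-trips a multi-replicon genome", {
  set.seed(11)
  reps <- tibble::tibble(id = c("c1", "c2", "c3"),
                         sequence = vapply(c(101, 250, 77), random_seq,
                                           character(1)),
                         length = c(101L, 250L, 77L), circular = FALSE)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(reps, f)
  back <- read_fasta(f)
  expect_equal(back$sequence, reps$sequence)
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("TSS tables parse by header name with normalization and defaults", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste("replicon", "position", "strand", "category",
                     paste(tss_libraries(), collapse = "\t"), sep = "\t"),
               "chr\t4547237\tr\tnTSS\t4\t1\t1\t2"), f)
  tss <- read_tss_table(f)
  expect_equal(tss$position, 4547237L)
  expect_equal(tss$strand, "-")
  expect_equal(tss$category, "nTSS")
  expect_equal(sum(tss$wt_nh4, tss$wt_n8h, tss$hetr_nh4, tss$hetr_n8h), 8)

  # empty data section under a valid header
  writeLines(paste(c("replicon", "position", "strand"), collapse = "\t"), f)
  expect_equal(nrow(read_tss_table(f)), 0)
})

test_that("TSS parsing is insensitive to column order", {
  set.seed(21)
  n <- 10
  d <- tibble::tibble(replicon = "c1", position = sample.int(5000, n),
                      strand = sample(c("+", "-"), n, TRUE),
                      category = sample(c("nTSS", "unknown"), n, TRUE),
                      wt_nh4 = sample.int(50, n), wt_n8h = sample.int(50, n),
                      hetr_nh4 = sample.int(50, n),
                      hetr_n8h = sample.int(50, n))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(d, f1)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(d[, sample(ncol(d))], f2)
  expect_equal(read_tss_table(f2), read_tss_table(f1))
})

test_that("TSS format errors carry line numbers and reject bad strands", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("replicon\tposition\tstrand", "c1\t10\t+", "c1\tx2\t+"), f)
  expect_error(read_tss_table(f), "line 3", class = "srnaflow_format_error")
  writeLines(c("replicon\tposition\tstrand", "c1\t10\t?"), f)
  expect_error(read_tss_table(f), class = "srnaflow_format_error")
})

test_that("TransTermHP reports parse TERM lines under sequence headers", {
  f <- withr::local_tempfile(fileext = ".tt")
  writeLines(c("SEQUENCE r1 (length 5000)",
               "  TERM 1   1200 - 1228 + G  96  -12.3 -4.2",
               "  TERM 2   2410 - 2380 - F  88  -10.1 -3.9",
               "SEQUENCE r2",
               "  TERM 1    300 - 321  + G  91  -11.0 -4.0"), f)
  tt <- read_transterm(f)
  expect_equal(nrow(tt), 3)
  expect_equal(tt$replicon_id, c("r1", "r1", "r2"))
  expect_equal(tt$hairpin_lo[1], 1200L)
  expect_equal(tt$hairpin_hi[1], 1228L)
  expect_equal(tt$strand, c("+", "-", "+"))
  # minus-strand coordinates printed high-to-low are normalized
  expect_true(all(tt$hairpin_lo <= tt$hairpin_hi))
  expect_equal(tt$hairpin_lo[2], 2380L)
  expect_equal(tt$score, c(96, 88, 91))

  writeLines(c("SEQUENCE r1", "nothing here"), f)
  expect_equal(nrow(read_transterm(f)), 0)
  writeLines("  TERM 1 10 - 30 + G 90 -1 -1", f)
  expect_error(read_transterm(f), class = "srnaflow_format_error")
  writeLines(c("SEQUENCE r1", "  TERM 1 ab - 30 + G 90 -1 -1"), f)
  expect_error(read_transterm(f), class = "srnaflow_format_error")
})

test_that("transterm writer round-trips through the parser", {
  set.seed(5)
  reps <- tibble::tibble(id = "c1", sequence = random_seq(2000),
                         length = 2000L, circular = FALSE)
  tt <- tibble::tibble(replicon_id = "c1",
                       terminator_id = c("c1:T1", "c1:T2"),
                       strand = c("+", "-"),
                       hairpin_lo = c(100L, 900L), hairpin_hi = c(125L, 930L),
                       tail = NA_character_, score = c(96, 88))
  f <- withr::local_tempfile()
  write_transterm(tt, f)
  back <- read_transterm(f)
  expect_equal(back$hairpin_lo, tt$hairpin_lo)
  expect_equal(back$hairpin_hi, tt$hairpin_hi)
  expect_equal(back$strand, tt$strand)
  # tails come from the genome, 3' of the hairpin in transcript orientation
  withtails <- add_terminator_tails(back, reps)
  expect_equal(withtails$tail[1], substr(reps$sequence, 126, 135))
  expect_equal(withtails$tail[2],
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(reps$sequence, 890, 899)))))
})

test_that("BLAST tabular hits normalize coordinates and drop unknown queries", {
  f <- withr::local_tempfile(fileext = ".tsv")
  rows <- c(
    "q1\tctgA\t100.00\t60\t0\t0\t1\t60\t501\t560\t1e-20\t120",
    "q1\tctgB\t95.00\t40\t2\t0\t5\t44\t900\t861\t1e-10\t80",
    "q2\tctgA\t90.00\t30\t3\t0\t1\t30\t10\t39\t1e-5\t50",
    "q2\tctgC\t88.00\t25\t3\t0\t1\t25\t70\t46\t1e-4\t40",
    "ghost\tctgA\t99.00\t50\t0\t0\t1\t50\t1\t50\t1e-9\t90")
  writeLines(rows, f)
  qlen <- c(q1 = 60L, q2 = 80L)
  expect_warning(h <- read_blast_tab(f, qlen), "1 hit")
  expect_equal(nrow(h), 4)
  expect_equal(h$identity_pct[1], 100)
  expect_equal(h$aligned_len[1], 60L)
  expect_true(all(h$s_lo <= h$s_hi))
  expect_equal(h$subject_strand, c("+", "-", "+", "-"))
  expect_equal(h$s_lo[2], 861L)

  writeLines("q1\tctgA\t100\t60", f)
  expect_error(read_blast_tab(f, qlen), "line 1",
               class = "srnaflow_format_error")
})

test_that("result writers keep BED (0-based) and GFF3 (1-based) consistent", {
  set.seed(31)
  reps <- tibble::tibble(id = "c1", sequence = random_seq(1000),
                         length = 1000L, circular = FALSE)
  seg <- tibble::tibble(
    id = c("101f", "400r"), replicon_id = "c1", strand = c("+", "-"),
    tss_position = c(101L, 400L), hairpin_lo = c(180L, 320L),
    hairpin_hi = c(200L, 341L), length_nt = c(100L, 81L),
    sequence = c(substr(reps$sequence, 101, 200),
                 as.character(Biostrings::reverseComplement(
                   Biostrings::DNAString(substr(reps$sequence, 320, 400))))),
    terminator_id = c("t1", "t2"), term_score = c(96, 90),
    wt_nh4 = c(2000L, 5L), wt_n8h = c(10L, 5L), hetr_nh4 = c(1L, 5L),
    hetr_n8h = c(0L, 5L), reads_total = c(2011, 20))
  out <- withr::local_tempdir()
  write_outputs(seg, out_dir = out)
  bed <- read.table(file.path(out, "candidates.bed"), sep = "\t")
  gff <- read.table(file.path(out, "candidates.gff3"), sep = "\t")
  # forward candidate: BED start 100, end 200; GFF 101..200
  expect_equal(bed$V2[bed$V4 == "101f"], 100)
  expect_equal(bed$V3[bed$V4 == "101f"], 200)
  expect_equal(gff$V4, bed$V2 + 1)
  expect_equal(gff$V5, bed$V3)
  expect_true(all(gff$V3 == "ncRNA"))
  # reads capped at 1000 in the BED score
  expect_equal(sort(bed$V5), c(20, 1000))
  res <- readr::read_tsv(file.path(out, "results.tsv"),
                         show_col_types = FALSE)
  expect_equal(res$id, c("101f", "400r"))
  expect_identical(res$sequence, seg$sequence)
})

test_that("results matrix columns are sorted by descending homolog totals", {
  genomes <- tibble::tibble(genome_id = c("gA", "gB", "gC"),
                            contig_id = paste0(c("gA", "gB", "gC"), "_1"),
                            sequence = strrep("A", 50))
  panel <- genome_panel(genomes, clade = "gA")
  prof <- structure(list(
    profiles = tibble::tibble(query_id = c("x1", "x2", "x3"),
                              homologs_total = c(5L, 9L, 2L),
                              homologs_clade = c(1L, 1L, 0L),
                              clade_exclusive = FALSE),
    presence = tidyr::expand_grid(query_id = c("x1", "x2", "x3"),
                                  genome_id = c("gA", "gB", "gC")) |>
      dplyr::mutate(present = 1L),
    panel_genomes = panel$genome_ids, clade = panel$clade,
    reference_id = NULL, query_lengths = c(x1 = 10L, x2 = 10L, x3 = 10L)),
    class = "conservation_profiles")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_presence_matrix(prof, f, decreasing = TRUE)
  m <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(names(m), c("genome_id", "x2", "x1", "x3"))
  expect_equal(m$genome_id, c("gA", "gB", "gC"))
})

test_that("candidate ids regenerate from coordinates and parse back", {
  expect_equal(candidate_id(c(4547237L, 56433L), c("-", "+")),
               c("4547237r", "56433f"))
  back <- parse_candidate_id(c("4547237r", "56433f"))
  expect_equal(back$position, c(4547237L, 56433L))
  expect_equal(back$strand, c("-", "+"))
  expect_error(parse_candidate_id("56433x"), class = "srnaflow_format_error")
})
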