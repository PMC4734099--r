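plant_in <- function(bg, insert, at, rc = FALSE) {
  if (rc) insert <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(insert)))
  substr(bg, at, at + nchar(insert) - 1L) <- insert
  bg
}

mutate_rate <- function(seq, rate, seed) {
  set.seed(seed)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  paste(chars, collapse = "")
}

test_that("seed-and-extend finds an exact planted query with full identity", {
  set.seed(71)
  q <- random_seq(80)
  subj <- plant_in(random_seq(3000), q, 1200)
  h <- seed_extend_search(q, subj)
  expect_gte(nrow(h), 1)
  expect_equal(h$s_lo[1], 1200L)
  expect_equal(h$s_hi[1], 1279L)
  expect_equal(h$identity_pct[1], 100)
  expect_equal(h$aligned_len[1], 80L)
  expect_equal(h$subject_strand[1], "+")
  # minus-strand plant is found with subject coordinates on the forward strand
  subj2 <- plant_in(random_seq(3000), q, 800, rc = TRUE)
  h2 <- seed_extend_search(q, subj2)
  expect_equal(h2$subject_strand[1], "-")
  expect_equal(h2$s_lo[1], 800L)
  expect_error(seed_extend_search("ACGT", subj),
               class = "srnaflow_usage_error")
})

test_that("a 10% diverged plant is recovered near the DP optimum", {
  set.seed(42)
  q <- random_seq(150)
  copy <- mutate_rate(q, 0.10, seed = 142)
  subj <- paste0(random_seq(120), copy, random_seq(120))
  h <- seed_extend_search(q, subj)
  expect_gte(nrow(h), 1)
  best <- h[1, ]
  expect_gte(best$aligned_len, 0.8 * nchar(q))
  expect_lt(abs(best$identity_pct - 90), 5)
})

test_that("no spurious 35%-coverage hit arises from random subjects", {
  bad <- 0L
  for (s in 1:40) {
    set.seed(1100 + s)
    q <- random_seq(100)
    subj <- random_seq(10000)
    h <- seed_extend_search(q, subj)
    if (nrow(h) > 0 && any(h$aligned_len >= ceiling(0.35 * nchar(q)))) {
      bad <- bad + 1L
    }
  }
  expect_equal(bad, 0L)
})

make_panel <- function(n, clade_n, queries, carriers, seed, rate = 0,
                       bg_len = 2500) {
  set.seed(seed)
  ids <- sprintf("p%02d", seq_len(n))
  rows <- lapply(seq_along(ids), function(g) {
    bg <- random_seq(bg_len)
    at <- 200L
    for (qi in seq_along(queries)) {
      if (!ids[g] %in% carriers[[qi]]) next
      copy <- if (rate > 0) mutate_rate(queries[qi], rate,
                                        seed = seed * 100 + g * 10 + qi)
              else queries[qi]
      bg <- plant_in(bg, copy, at, rc = runif(1) < 0.5)
      at <- at + nchar(copy) + 150L
    }
    tibble::tibble(genome_id = ids[g], contig_id = paste0(ids[g], "_1"),
                   sequence = bg)
  })
  genome_panel(dplyr::bind_rows(rows), clade = ids[seq_len(clade_n)])
}

test_that("homolog counting recovers planted carrier sets exactly", {
  set.seed(72)
  queries <- tibble::tibble(id = c("q1", "q2"),
                            sequence = c(random_seq(90), random_seq(120)))
  carriers <- list(sprintf("p%02d", 1:5), sprintf("p%02d", c(2, 7, 9)))
  panel <- make_panel(10, 4, queries$sequence, carriers, seed = 73)
  prof <- count_homologs(queries, panel)
  pt <- tidy(prof)
  expect_equal(pt$homologs_total, c(5L, 3L))
  expect_equal(pt$homologs_clade, c(4L, 1L))
  expect_equal(pt$clade_exclusive, c(FALSE, FALSE))
  # presence invariants
  expect_true(all(pt$homologs_clade <= pt$homologs_total))
  expect_true(all(pt$homologs_total <= length(panel$genome_ids)))
})

test_that("an empty panel yields all-zero profiles", {
  queries <- tibble::tibble(id = "q1", sequence = strrep("ACGT", 20))
  empty <- genome_panel(tibble::tibble(genome_id = character(),
                                       contig_id = character(),
                                       sequence = character()))
  prof <- count_homologs(queries, empty)
  expect_equal(tidy(prof)$homologs_total, 0L)
  expect_false(tidy(prof)$clade_exclusive)
})

test_that("the reference genome always counts positive for its own queries", {
  set.seed(74)
  queries <- tibble::tibble(id = "q1", sequence = random_seq(100))
  panel <- make_panel(4, 2, queries$sequence, list(character(0)), seed = 75)
  panel_ref <- genome_panel(panel$genomes, clade = panel$clade,
                            reference_id = "p01")
  expect_equal(tidy(count_homologs(queries, panel))$homologs_total, 0L)
  expect_equal(tidy(count_homologs(queries, panel_ref))$homologs_total, 1L)
})

test_that("imported BLAST hits honor coverage and e-value rules", {
  queries <- tibble::tibble(id = "q1", sequence = strrep("ACGT", 25))  # 100 nt
  genomes <- tibble::tibble(genome_id = c("gA", "gB", "gC"),
                            contig_id = c("cA", "cB", "cC"),
                            sequence = strrep("A", 200))
  panel <- genome_panel(genomes, clade = "gA")
  hits <- tibble::tibble(
    query_id = "q1", genome_id = c("gA", "gB", "gC"),
    contig_id = c("cA", "cB", "cC"),
    s_lo = 1L, s_hi = 50L, subject_strand = "+",
    identity_pct = 95, aligned_len = c(35L, 34L, 80L),
    evalue = c(0.001, 0.001, 100))
  prof <- count_homologs(queries, panel, hits = hits)
  # 35 = ceiling(0.35*100) passes; 34 fails coverage; e-value 100 fails
  expect_equal(tidy(prof)$homologs_total, 1L)
  pres <- prof$presence
  expect_equal(pres$present[pres$genome_id == "gA"], 1L)
  expect_equal(sum(pres$present), 1L)
})

test_that("builtin calls equal the alignment-oracle calls at moderate
           divergence", {
  set.seed(76)
  queries <- tibble::tibble(id = c("q1", "q2"),
                            sequence = c(random_seq(100), random_seq(160)))
  carriers <- list(sprintf("p%02d", c(1, 3, 5)), sprintf("p%02d", c(2, 3, 6)))
  panel <- make_panel(6, 3, queries$sequence, carriers, seed = 77, rate = 0.12)
  prof <- count_homologs(queries, panel)
  for (qi in 1:2) {
    for (g in panel$genome_ids) {
      want <- oracle_genome_positive(
        queries$sequence[qi],
        panel$genomes$sequence[panel$genomes$genome_id == g])
      got <- prof$presence$present[prof$presence$query_id == queries$id[qi] &
                                     prof$presence$genome_id == g] == 1L
      expect_equal(got, want, info = paste(queries$id[qi], g))
    }
  }
})

test_that("homolog counts rise monotonically as the coverage bar drops", {
  set.seed(78)
  queries <- tibble::tibble(id = "q1", sequence = random_seq(120))
  carriers <- list(sprintf("p%02d", 1:6))
  panel <- make_panel(8, 4, queries$sequence, carriers, seed = 79, rate = 0.15)
  prev <- -1L
  for (cov in c(0.35, 0.30, 0.25, 0.20)) {
    n <- tidy(count_homologs(queries, panel,
                             pipeline_params(min_query_coverage = cov)))$homologs_total
    expect_gte(n, prev)
    prev <- n
  }
})

test_that("clade-exclusive table uses 'more than 10' and the map 'at least 10'", {
  mk_prof <- function(df, genomes, clade) {
    pres <- tidyr::expand_grid(query_id = df$query_id, genome_id = genomes)
    pres$present <- 0L
    structure(list(profiles = df, presence = pres, panel_genomes = genomes,
                   clade = clade, reference_id = NULL,
                   query_lengths = setNames(rep(100L, nrow(df)), df$query_id)),
              class = "conservation_profiles")
  }
  genomes <- sprintf("g%02d", 1:20)
  clade <- genomes[1:15]
  df <- tibble::tibble(
    query_id = c("a", "b", "c", "d"),
    homologs_total = c(13L, 11L, 10L, 12L),
    homologs_clade = c(12L, 11L, 10L, 12L),
    clade_exclusive = c(FALSE, TRUE, TRUE, TRUE))
  prof <- mk_prof(df, genomes, clade)
  tab <- clade_exclusive_table(prof)
  # 12+1 non-clade hit -> excluded; 11 clade-only -> in; 10 clade-only -> out
  expect_equal(tab$query_id, c("d", "b"))
  tab10 <- clade_exclusive_table(prof, pipeline_params(table_min_homologs = 10))
  expect_equal(tab10$query_id, c("d", "b", "c"))
  # display map keeps >= 10 and sorts ascending, most conserved rightmost
  m <- build_matrix(prof, min_homologs = 10)
  expect_equal(colnames(m), c("c", "b", "d", "a"))
  expect_equal(rownames(m), genomes)
  m0 <- build_matrix(prof, min_homologs = 14)
  expect_equal(ncol(m0), 0)
})
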