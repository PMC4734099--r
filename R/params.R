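#' Pipeline parameters
#'
#' Tunable parameters of the sRNA prediction pipeline. Defaults reflect the
#' study conditions the pipeline was designed for: orphan TSSs supported by
#' at least 8 dRNA-Seq reads in some library, a transcript size window of
#' 45-350 nt (terminator hairpin included, poly-U tail excluded), a homology
#' positive-hit rule requiring an alignment covering at least 35% of the
#' query, and two conservation display thresholds ("more than 10" homologs
#' for the clade-exclusive table, "at least 10" for the presence map).
#'
#' @param min_reads Minimum dRNA-Seq read count (maximum over libraries)
#'   supporting a TSS.
#' @param ntss_distance Minimum distance (nt) from a TSS to the nearest
#'   downstream same-strand gene start for the TSS to count as intergenic
#'   (orphan); TSSs at most this far upstream of a gene start are
#'   gene-associated (gTSS).
#' @param min_len,max_len Candidate transcript length window in nt,
#'   inclusive, measured from the TSS through the terminator hairpin.
#' @param min_query_coverage Minimum fraction of the query length that a
#'   homology hit must cover to mark a genome positive.
#' @param max_evalue Maximum e-value for imported BLAST hits (the built-in
#'   search backend is score-thresholded and ignores this).
#' @param map_min_homologs Minimum total homolog count for a candidate to
#'   appear as a column of the presence/absence matrix ("at least 10").
#' @param table_min_homologs Minimum in-clade homolog count for the
#'   clade-exclusive table ("more than 10", i.e. 11).
#' @param reads_similarity_factor Read totals within this factor of the
#'   family maximum count as "similar" when choosing a representative.
#' @param orf_alpha Significance level for the small-ORF permutation test.
#' @param min_alignment_seqs Minimum number of rows an alignment must have
#'   before small ORFs are scanned ("more than three sequences").
#' @param shortest_after_window If `TRUE` (default) the size window is
#'   applied before the per-TSS shortest-segment rule; if `FALSE` the first
#'   terminator downstream wins and the window is applied afterwards.
#' @return A named list of class `pipeline_params`.
#' @export
pipeline_params <- function(min_reads = 8L,
                            ntss_distance = 200L,
                            min_len = 45L,
                            max_len = 350L,
                            min_query_coverage = 0.35,
                            max_evalue = 10,
                            map_min_homologs = 10L,
                            table_min_homologs = 11L,
                            reads_similarity_factor = 2.0,
                            orf_alpha = 0.05,
                            min_alignment_seqs = 4L,
                            shortest_after_window = TRUE) {
  p <- list(
    min_reads = as.integer(min_reads),
    ntss_distance = as.integer(ntss_distance),
    min_len = as.integer(min_len),
    max_len = as.integer(max_len),
    min_query_coverage = as.numeric(min_query_coverage),
    max_evalue = as.numeric(max_evalue),
    map_min_homologs = as.integer(map_min_homologs),
    table_min_homologs = as.integer(table_min_homologs),
    reads_similarity_factor = as.numeric(reads_similarity_factor),
    orf_alpha = as.numeric(orf_alpha),
    min_alignment_seqs = as.integer(min_alignment_seqs),
    shortest_after_window = isTRUE(shortest_after_window)
  )
  if (p$min_len <= 0 || p$min_len > p$max_len) {
    abort_usage("min_len must satisfy 0 < min_len <= max_len")
  }
  if (p$min_query_coverage <= 0 || p$min_query_coverage > 1) {
    abort_usage("min_query_coverage must lie in (0, 1]")
  }
  if (p$min_reads < 1) abort_usage("min_reads must be >= 1")
  if (p$reads_similarity_factor < 1) {
    abort_usage("reads_similarity_factor must be >= 1")
  }
  structure(p, class = "pipeline_params")
}

#' Built-in terminator scan parameters
#'
#' Parameters of the stand-in Rho-independent terminator detector used when
#' no external terminator prediction is supplied. The detector looks for a
#' perfect (mismatch-free) RNA hairpin stem followed by a uridine-rich tail;
#' pairs score GC = 3, AU = 2, GU = 1 (on the DNA: G-C, A-T, G-T).
#'
#' @param stem_min,stem_max Stem length bounds in bp.
#' @param loop_min,loop_max Loop length bounds in nt.
#' @param pair_scores Named numeric vector of per-pair scores (`GC`, `AU`,
#'   `GU`).
#' @param min_hairpin_score Minimum summed pair score.
#' @param tail_window Number of nt 3' of the hairpin inspected for the tail.
#' @param min_tail_u Minimum number of T's (U's on the transcript) in the
#'   tail window.
#' @param require_u_at Tail positions of which at least one must be a T.
#' @return A named list of class `term_scan_params`.
#' @export
term_scan_params <- function(stem_min = 4L, stem_max = 18L,
                             loop_min = 3L, loop_max = 10L,
                             pair_scores = c(GC = 3, AU = 2, GU = 1),
                             min_hairpin_score = 12,
                             tail_window = 7L,
                             min_tail_u = 4L,
                             require_u_at = c(1L, 2L)) {
  p <- list(
    stem_min = as.integer(stem_min), stem_max = as.integer(stem_max),
    loop_min = as.integer(loop_min), loop_max = as.integer(loop_max),
    pair_scores = pair_scores,
    min_hairpin_score = as.numeric(min_hairpin_score),
    tail_window = as.integer(tail_window),
    min_tail_u = as.integer(min_tail_u),
    require_u_at = as.integer(require_u_at)
  )
  if (p$stem_min < 3L) abort_usage("stem_min must be >= 3")
  if (p$loop_min < 3L) abort_usage("loop_min must be >= 3")
  if (p$min_tail_u > p$tail_window) {
    abort_usage("min_tail_u must be <= tail_window")
  }
  if (!all(c("GC", "AU", "GU") %in% names(p$pair_scores))) {
    abort_usage("pair_scores must name GC, AU and GU")
  }
  structure(p, class = "term_scan_params")
}

#' Sequence-family similarity parameters
#'
#' Criterion under which two candidate sequences count as near-identical
#' copies: a best local alignment (match +1, mismatch -1, gap -2) with
#' identity at least `min_identity` covering at least
#' `min_coverage_of_shorter` of the shorter sequence.
#'
#' @param min_identity Minimum identity fraction over aligned columns.
#' @param min_coverage_of_shorter Minimum fraction of the shorter sequence
#'   included in the local alignment.
#' @param match,mismatch,gap Local alignment scores.
#' @return A named list of class `similarity_params`.
#' @export
similarity_params <- function(min_identity = 0.95,
                              min_coverage_of_shorter = 0.90,
                              match = 1, mismatch = -1, gap = -2) {
  p <- list(
    min_identity = as.numeric(min_identity),
    min_coverage_of_shorter = as.numeric(min_coverage_of_shorter),
    match = as.numeric(match), mismatch = as.numeric(mismatch),
    gap = as.numeric(gap)
  )
  if (p$min_identity <= 0 || p$min_identity > 1 ||
      p$min_coverage_of_shorter <= 0 || p$min_coverage_of_shorter > 1) {
    abort_usage("similarity thresholds must lie in (0, 1]")
  }
  structure(p, class = "similarity_params")
}

#' Built-in homology search parameters
#'
#' Seed-and-extend local search: exact k-mer seeds on both subject strands
#' with ungapped X-drop extension (match +1, mismatch -2).
#'
#' @param k Seed length (exact-match k-mer).
#' @param x_drop Extension stops when the running score falls this far below
#'   the best score seen.
#' @param match,mismatch Per-column extension scores.
#' @return A named list of class `seed_search_params`.
#' @export
seed_search_params <- function(k = 11L, x_drop = 12, match = 1, mismatch = -2) {
  p <- list(k = as.integer(k), x_drop = as.numeric(x_drop),
            match = as.numeric(match), mismatch = as.numeric(mismatch))
  if (p$k < 4L) abort_usage("seed length k must be >= 4")
  structure(p, class = "seed_search_params")
}
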