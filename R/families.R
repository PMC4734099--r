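## Collapse near-identical candidate copies and TSS clusters sharing a
## terminator into families (connected components of a similarity graph),
## then pick one representative per family by read support with a
## homolog-count tie-break.

#' Local-alignment similarity between two sequences
#'
#' Best local alignment under match +1, mismatch -1, linear gap -2 (N never
#' matches). Identity is matches over aligned columns; coverage is the
#' number of aligned residues of the shorter sequence over its length.
#'
#' @param a,b DNA strings.
#' @param sim A [similarity_params()] list.
#' @return A list with `identity`, `coverage`, `score` and `similar` (both
#'   thresholds passed).
#' @export
pairwise_similarity <- function(a, b, sim = similarity_params()) {
  if (!nzchar(a) || !nzchar(b)) abort_usage("sequences must be non-empty")
  r <- batch_similarity(a, b, sim)
  list(identity = r$identity, coverage = r$coverage, score = r$score,
       similar = r$similar)
}

## Vectorized core: many patterns against one subject in a single
## pairwiseAlignment call (the call overhead dominates single-pair use).
batch_similarity <- function(patterns, subject, sim = similarity_params()) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(patterns), subject, type = "local",
    substitutionMatrix = dna_submat(sim$match, sim$mismatch),
    gapOpening = 0, gapExtension = -sim$gap)
  sc <- Biostrings::score(aln)
  nm <- Biostrings::nmatch(aln)
  p <- Biostrings::pattern(aln); s <- Biostrings::subject(aln)
  p_used <- BiocGenerics::end(p) - BiocGenerics::start(p) + 1L
  s_used <- BiocGenerics::end(s) - BiocGenerics::start(s) + 1L
  # alignment width incl. gaps = pattern residues + gap columns in pattern
  ncols <- p_used + Biostrings::nindel(aln)@deletion[, 2]
  shorter_is_p <- nchar(patterns) <= nchar(subject)
  used <- ifelse(shorter_is_p, p_used, s_used)
  short_len <- pmin(nchar(patterns), nchar(subject))
  pos <- sc > 0
  identity <- ifelse(pos, nm / ncols, 0)
  coverage <- ifelse(pos, used / short_len, 0)
  list(identity = identity, coverage = coverage, score = sc,
       similar = identity >= sim$min_identity &
         coverage >= sim$min_coverage_of_shorter)
}

#' Group candidate segments into families
#'
#' Builds an undirected graph over segments with an edge when either the
#' two sequences pass both similarity thresholds (near-identical genomic
#' copies) or the two segments share a terminator (several TSSs feeding one
#' terminator). Families are the connected components (single linkage), so
#' the two collapses compose into one partition. Family ids are assigned in
#' order of each family's smallest member id.
#'
#' @param segments Candidate segment tibble (see [pair_segments()]).
#' @param sim A [similarity_params()] list.
#' @return A tibble with one row per segment: `family_id`, `member_id`.
#' @export
cluster_families <- function(segments, sim = similarity_params()) {
  n <- nrow(segments)
  if (n == 0) return(tibble(family_id = integer(), member_id = character()))
  ids <- segments$id
  edges <- list(); ne <- 0L
  if (n > 1) {
    for (j in 2:n) {
      prev <- seq_len(j - 1)
      shared <- !is.na(segments$terminator_id[j]) &
        segments$terminator_id[prev] == segments$terminator_id[j]
      shared[is.na(shared)] <- FALSE
      similar <- batch_similarity(segments$sequence[prev],
                                  segments$sequence[j], sim)$similar
      for (i in prev[shared | similar]) {
        ne <- ne + 1L
        edges[[ne]] <- c(i, j)
      }
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (ne > 0) {
    g <- igraph::add_edges(g, unlist(edges[seq_len(ne)]))
  }
  comp <- igraph::components(g)$membership
  # deterministic ids: order components by their smallest member id
  key <- parse_candidate_id(ids)
  ord_key <- order(key$position, key$strand)
  rank_of <- integer(max(comp))
  seen <- 0L
  for (i in ord_key) {
    if (rank_of[comp[i]] == 0L) {
      seen <- seen + 1L
      rank_of[comp[i]] <- seen
    }
  }
  tibble(family_id = rank_of[comp], member_id = ids)
}

#' Choose the representative member of each family
#'
#' Within a family, members whose total read count is within
#' `reads_similarity_factor` of the maximum form the "similar" set; among
#' them the member with the most homologs wins (TSS strength first, but a
#' clearly better-conserved copy among comparably supported TSSs is
#' preferred). Remaining ties go to higher reads, then the
#' lexicographically smallest id.
#'
#' @param families Family tibble from [cluster_families()].
#' @param segments Candidate segment tibble (for read counts).
#' @param profiles A [count_homologs()] result, or `NULL` (all homolog
#'   counts treated as zero).
#' @param params A [pipeline_params()] list.
#' @return A tibble with one row per family: `family_id`,
#'   `representative_id`, `n_members`.
#' @export
select_representative <- function(families, segments, profiles = NULL,
                                  params = pipeline_params()) {
  if (nrow(families) == 0) {
    return(tibble(family_id = integer(), representative_id = character(),
                  n_members = integer()))
  }
  reads <- setNames(segments$reads_total, segments$id)
  hom <- setNames(rep(0L, nrow(segments)), segments$id)
  if (!is.null(profiles)) {
    pt <- tidy_profiles(profiles)
    hom[pt$query_id] <- pt$homologs_total
  }
  pick_rep <- function(member_ids) {
    r <- reads[member_ids]
    similar <- member_ids[r >= max(r) / params$reads_similarity_factor]
    h <- hom[similar]
    best_h <- similar[h == max(h)]
    r2 <- reads[best_h]
    best <- best_h[r2 == max(r2)]
    sort(best)[1]
  }
  out <- dplyr::summarise(
    dplyr::group_by(families, family_id),
    representative_id = pick_rep(member_id),
    n_members = dplyr::n(), .groups = "drop")
  dplyr::arrange(out, family_id)
}
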