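## Conservation profiling: a built-in seed-and-extend nucleotide search (or
## imported BLAST tabular hits) against a genome panel; a genome counts as
## carrying a homolog when at least one hit covers >= min_query_coverage of
## the query. Presence is binary per genome; multi-contig assemblies are
## searched contig by contig.

#' Construct a genome panel
#'
#' @param genomes A tibble with columns `genome_id`, `contig_id`,
#'   `sequence`.
#' @param clade Character vector of genome ids forming the focal clade
#'   (e.g. heterocystous strains).
#' @param reference_id Genome id of the reference the queries came from, if
#'   it is part of the panel (its own queries then always count positive),
#'   or `NULL` when the reference is not in the panel.
#' @return An object of class `genome_panel`.
#' @export
genome_panel <- function(genomes, clade = character(), reference_id = NULL) {
  stopifnot(all(c("genome_id", "contig_id", "sequence") %in% names(genomes)))
  ids <- unique(genomes$genome_id)
  bad <- setdiff(clade, ids)
  if (length(bad)) {
    abort_usage(sprintf("clade genome(s) not in panel: %s",
                        paste(bad, collapse = ", ")))
  }
  if (!is.null(reference_id) && !reference_id %in% ids) {
    abort_usage(sprintf("reference genome %s not in panel", reference_id))
  }
  genomes$sequence <- clean_dna(genomes$sequence)
  structure(list(genomes = genomes, genome_ids = ids,
                 clade = unique(clade), reference_id = reference_id),
            class = "genome_panel")
}

#' Read a genome panel from a directory of FASTA files
#'
#' Each `.fasta`/`.fa`/`.fna` file is one genome; the genome id is the file
#' stem and each FASTA record is one contig.
#'
#' @param dir Directory of FASTA files.
#' @param clade_file Optional text file with one clade genome id per line.
#' @param reference_id See [genome_panel()].
#' @return A `genome_panel` object (panel order = sorted file names).
#' @export
read_genome_panel <- function(dir, clade_file = NULL, reference_id = NULL) {
  files <- sort(list.files(dir, pattern = "\\.(fasta|fa|fna)$",
                           full.names = TRUE))
  if (length(files) == 0) {
    abort_usage(sprintf("no FASTA files found in panel directory %s", dir))
  }
  genomes <- dplyr::bind_rows(lapply(files, function(f) {
    reps <- read_fasta(f)
    tibble(genome_id = sub("\\.(fasta|fa|fna)$", "", basename(f)),
           contig_id = reps$id, sequence = reps$sequence)
  }))
  clade <- character()
  if (!is.null(clade_file)) {
    clade <- trimws(readLines(clade_file, warn = FALSE))
    clade <- clade[nzchar(clade)]
  }
  genome_panel(genomes, clade = clade, reference_id = reference_id)
}

#' @export
print.genome_panel <- function(x, ...) {
  cat(sprintf("<genome_panel> %d genomes (%d contigs), clade of %d%s\n",
              length(x$genome_ids), nrow(x$genomes), length(x$clade),
              if (is.null(x$reference_id)) "" else
                sprintf(", reference %s", x$reference_id)))
  invisible(x)
}

## Ungapped X-drop extension along one diagonal. Returns c(lo, hi, score,
## matches) in 1..length(m) coordinates of the logical match vector m, or
## NULL if the seed region is invalid.
extend_xdrop <- function(m, seed_lo, seed_hi, match, mismatch, x_drop) {
  step <- ifelse(m, match, mismatch)
  # right extension
  hi <- seed_hi
  if (seed_hi < length(step)) {
    cs <- cumsum(step[(seed_hi + 1L):length(step)])
    run_max <- cummax(c(0, cs))
    drop_at <- which(run_max[-1] - cs > x_drop)
    lim <- if (length(drop_at)) drop_at[1] else length(cs)
    best <- if (lim >= 1) which.max(cs[seq_len(lim)]) else 0L
    if (best > 0 && cs[best] > 0) hi <- seed_hi + best
  }
  lo <- seed_lo
  if (seed_lo > 1L) {
    cs <- cumsum(rev(step[seq_len(seed_lo - 1L)]))
    run_max <- cummax(c(0, cs))
    drop_at <- which(run_max[-1] - cs > x_drop)
    lim <- if (length(drop_at)) drop_at[1] else length(cs)
    best <- if (lim >= 1) which.max(cs[seq_len(lim)]) else 0L
    if (best > 0 && cs[best] > 0) lo <- seed_lo - best
  }
  mm <- m[lo:hi]
  n_match <- sum(mm)
  c(lo = lo, hi = hi,
    score = n_match * match + (length(mm) - n_match) * mismatch,
    matches = n_match)
}

seed_positions <- function(chars, k) {
  n <- length(chars) - k + 1L
  if (n < 1) return(character(0))
  kmers <- substring(paste(chars, collapse = ""), seq_len(n),
                     seq_len(n) + k - 1L)
  kmers[grepl("N", kmers, fixed = TRUE)] <- NA_character_
  kmers
}

## Precomputed per-strand subject data, reusable across queries.
index_subject <- function(subject, k) {
  subject <- clean_dna(subject)
  lapply(setNames(c("+", "-"), c("+", "-")), function(strand) {
    subj <- if (strand == "+") subject else revcomp(subject)
    sc <- strsplit(subj, "", fixed = TRUE)[[1]]
    if (length(sc) < k) return(NULL)
    s_kmers <- seed_positions(sc, k)
    list(sc = sc, sl = length(sc),
         index = split(seq_along(s_kmers), s_kmers))
  })
}

#' Built-in local homology search (seed and extend)
#'
#' Exact k-mer seeds on both subject strands followed by ungapped extension
#' in both directions with X-drop termination (match +1, mismatch -2; N
#' never matches). Overlapping hits on a strand are merged keeping the
#' higher score. Subject coordinates refer to the forward subject strand.
#'
#' @param query Query DNA string (length at least `k`).
#' @param subject Subject DNA string.
#' @param params A [seed_search_params()] list.
#' @param subject_index Optional precomputed index from an internal call;
#'   lets one subject serve many queries without re-indexing.
#' @return A tibble sorted by descending score: `s_lo`, `s_hi`, `q_lo`,
#'   `q_hi`, `subject_strand`, `identity_pct`, `aligned_len`, `score`.
#' @export
seed_extend_search <- function(query, subject, params = seed_search_params(),
                               subject_index = NULL) {
  p <- params
  query <- clean_dna(query)
  if (nchar(query) < p$k) {
    abort_usage(sprintf("query (%d nt) shorter than seed length k = %d",
                        nchar(query), p$k))
  }
  qc <- strsplit(query, "", fixed = TRUE)[[1]]
  ql <- length(qc)
  q_kmers <- seed_positions(qc, p$k)
  if (is.null(subject_index)) subject_index <- index_subject(subject, p$k)
  out <- list(); n_out <- 0L
  for (strand in c("+", "-")) {
    sd <- subject_index[[strand]]
    if (is.null(sd)) next
    sc <- sd$sc
    sl <- sd$sl
    s_index <- sd$index
    hits_d <- new.env(parent = emptyenv())  # best covered range per diagonal
    strand_hits <- list(); nh <- 0L
    for (qi in seq_along(q_kmers)) {
      km <- q_kmers[qi]
      if (is.na(km)) next
      spos <- s_index[[km]]
      if (is.null(spos)) next
      for (sj in spos) {
        d <- sj - qi
        covered <- get0(as.character(d), envir = hits_d)
        if (!is.null(covered) && qi >= covered[1] && qi + p$k - 1L <= covered[2]) next
        # valid extent of this diagonal: 1 <= q <= ql and 1 <= q + d <= sl
        q_from <- max(1L, 1L - d)
        q_to <- min(ql, sl - d)
        m <- qc[q_from:q_to] == sc[(q_from:q_to) + d] &
          qc[q_from:q_to] != "N"
        ext <- extend_xdrop(m, qi - q_from + 1L, qi + p$k - 1L - q_from + 1L,
                            p$match, p$mismatch, p$x_drop)
        q_lo <- ext[["lo"]] + q_from - 1L
        q_hi <- ext[["hi"]] + q_from - 1L
        assign(as.character(d), c(q_lo, q_hi), envir = hits_d)
        nh <- nh + 1L
        strand_hits[[nh]] <- c(q_lo = q_lo, q_hi = q_hi,
                               s_lo = q_lo + d, s_hi = q_hi + d,
                               score = ext[["score"]],
                               matches = ext[["matches"]])
      }
    }
    if (nh == 0) next
    h <- tibble::as_tibble(do.call(rbind, strand_hits[seq_len(nh)]))
    h <- h[!duplicated(h[, c("q_lo", "q_hi", "s_lo", "s_hi")]), , drop = FALSE]
    # merge overlapping subject intervals, best score first
    h <- h[order(-h$score, h$s_lo, h$q_lo), , drop = FALSE]
    keep <- logical(nrow(h)); kl <- integer(0); kh <- integer(0)
    for (i in seq_len(nrow(h))) {
      if (!any(h$s_lo[i] <= kh & h$s_hi[i] >= kl)) {
        keep[i] <- TRUE
        kl <- c(kl, h$s_lo[i]); kh <- c(kh, h$s_hi[i])
      }
    }
    h <- h[keep, , drop = FALSE]
    if (strand == "-") {
      tmp <- sl - h$s_hi + 1L
      h$s_hi <- sl - h$s_lo + 1L
      h$s_lo <- tmp
    }
    h$subject_strand <- strand
    n_out <- n_out + 1L
    out[[n_out]] <- h
  }
  if (n_out == 0) {
    return(tibble(s_lo = integer(), s_hi = integer(), q_lo = integer(),
                  q_hi = integer(), subject_strand = character(),
                  identity_pct = numeric(), aligned_len = integer(),
                  score = numeric()))
  }
  h <- dplyr::bind_rows(out)
  h$aligned_len <- as.integer(h$q_hi - h$q_lo + 1L)
  h$identity_pct <- 100 * h$matches / h$aligned_len
  h <- h[order(-h$score, h$subject_strand, h$s_lo), , drop = FALSE]
  tibble(s_lo = as.integer(h$s_lo), s_hi = as.integer(h$s_hi),
         q_lo = as.integer(h$q_lo), q_hi = as.integer(h$q_hi),
         subject_strand = h$subject_strand,
         identity_pct = h$identity_pct, aligned_len = h$aligned_len,
         score = h$score)
}

#' Profile candidate conservation across a genome panel
#'
#' A genome is positive for a query when at least one hit spans
#' `ceiling(min_query_coverage x query length)` of the query (and, for
#' imported BLAST hits, passes the e-value cutoff). The reference genome,
#' if present in the panel, always counts positive for its own queries.
#'
#' @param queries A tibble with columns `id` and `sequence` (e.g. candidate
#'   segments).
#' @param panel A [genome_panel()].
#' @param params A [pipeline_params()] list.
#' @param hits Optional imported hit tibble from [read_blast_tab()]; when
#'   supplied the built-in search is skipped.
#' @param search A [seed_search_params()] list for the built-in backend.
#' @return An object of class `conservation_profiles`: per-query summary
#'   (`tidy()`), long-form presence, and the per-genome hits.
#' @export
count_homologs <- function(queries, panel, params = pipeline_params(),
                           hits = NULL, search = seed_search_params()) {
  stopifnot(inherits(panel, "genome_panel"))
  qids <- queries$id
  qlen <- setNames(nchar(queries$sequence), qids)
  need <- setNames(as.integer(ceiling(params$min_query_coverage * qlen)), qids)
  if (is.null(hits)) {
    hit_rows <- list(); nh <- 0L
    for (gi in seq_len(nrow(panel$genomes))) {
      idx <- index_subject(panel$genomes$sequence[gi], search$k)
      for (qi in seq_along(qids)) {
        h <- seed_extend_search(queries$sequence[qi],
                                panel$genomes$sequence[gi], search,
                                subject_index = idx)
        if (nrow(h) == 0) next
        h$query_id <- qids[qi]
        h$genome_id <- panel$genomes$genome_id[gi]
        h$contig_id <- panel$genomes$contig_id[gi]
        h$evalue <- 0
        nh <- nh + 1L
        hit_rows[[nh]] <- h
      }
    }
    hits <- if (nh) dplyr::bind_rows(hit_rows) else
      tibble(query_id = character(), genome_id = character(),
             contig_id = character(), s_lo = integer(), s_hi = integer(),
             subject_strand = character(), identity_pct = numeric(),
             aligned_len = integer(), evalue = numeric())
    evalue_ok <- rep(TRUE, nrow(hits))
  } else {
    evalue_ok <- hits$evalue <= params$max_evalue
  }
  pos <- hits[evalue_ok & hits$aligned_len >= need[hits$query_id], ,
              drop = FALSE]
  pos <- pos[pos$genome_id %in% panel$genome_ids, , drop = FALSE]

  grid <- tidyr::expand_grid(query_id = qids, genome_id = panel$genome_ids)
  present_keys <- unique(paste(pos$query_id, pos$genome_id, sep = "\r"))
  grid$present <- as.integer(
    paste(grid$query_id, grid$genome_id, sep = "\r") %in% present_keys)
  if (!is.null(panel$reference_id)) {
    grid$present[grid$genome_id == panel$reference_id] <- 1L
  }
  in_clade <- grid$genome_id %in% panel$clade
  summary <- dplyr::summarise(
    dplyr::group_by(grid, query_id),
    homologs_total = sum(present),
    homologs_clade = sum(present[genome_id %in% panel$clade]),
    .groups = "drop")
  summary <- summary[match(qids, summary$query_id), , drop = FALSE]
  summary$query_id <- qids                       # empty panel: no grid rows
  summary$homologs_total[is.na(summary$homologs_total)] <- 0L
  summary$homologs_clade[is.na(summary$homologs_clade)] <- 0L
  summary$clade_exclusive <- summary$homologs_total > 0 &
    summary$homologs_total == summary$homologs_clade
  structure(list(profiles = summary, presence = grid, hits = hits,
                 panel_genomes = panel$genome_ids, clade = panel$clade,
                 reference_id = panel$reference_id,
                 query_lengths = qlen),
            class = "conservation_profiles")
}

tidy_profiles <- function(profiles) {
  if (inherits(profiles, "conservation_profiles")) return(profiles$profiles)
  stopifnot(is.data.frame(profiles),
            all(c("query_id", "homologs_total") %in% names(profiles)))
  profiles
}

#' @export
print.conservation_profiles <- function(x, ...) {
  cat(sprintf("<conservation_profiles> %d queries x %d genomes (clade of %d)\n",
              nrow(x$profiles), length(x$panel_genomes), length(x$clade)))
  print(x$profiles, ...)
  invisible(x)
}

#' Clade-exclusive candidate table
#'
#' Keeps candidates whose homologs occur only in clade genomes and which
#' have more than `table_min_homologs - 1` in-clade homologs ("more than
#' 10" at the defaults), sorted by descending in-clade count, then id.
#'
#' @param profiles A [count_homologs()] result (or its `tidy()` tibble).
#' @param params A [pipeline_params()] list.
#' @return Filtered, sorted profile tibble.
#' @export
clade_exclusive_table <- function(profiles, params = pipeline_params()) {
  pt <- tidy_profiles(profiles)
  pt <- pt[pt$clade_exclusive & pt$homologs_clade >= params$table_min_homologs, ,
           drop = FALSE]
  pt[order(-pt$homologs_clade, pt$query_id), , drop = FALSE]
}

#' Presence/absence matrix
#'
#' Rows are panel genomes in panel order; columns are candidates with at
#' least `min_homologs` homologs. With `decreasing = FALSE` (the display
#' map convention) columns are sorted ascending by total homolog count so
#' the most conserved candidates sit rightmost.
#'
#' @param profiles A [count_homologs()] result.
#' @param min_homologs Display threshold on total homolog count.
#' @param decreasing Column sort direction.
#' @return A binary integer matrix, genomes x candidates.
#' @export
build_matrix <- function(profiles, min_homologs = 10L, decreasing = FALSE) {
  stopifnot(inherits(profiles, "conservation_profiles"))
  pt <- profiles$profiles
  keep <- pt[pt$homologs_total >= min_homologs, , drop = FALSE]
  ord <- order(if (decreasing) -keep$homologs_total else keep$homologs_total,
               keep$query_id)
  keep <- keep[ord, , drop = FALSE]
  m <- matrix(0L, nrow = length(profiles$panel_genomes),
              ncol = nrow(keep),
              dimnames = list(profiles$panel_genomes, keep$query_id))
  if (nrow(keep) > 0) {
    pres <- profiles$presence[profiles$presence$query_id %in% keep$query_id, ]
    m[cbind(match(pres$genome_id, rownames(m)),
            match(pres$query_id, colnames(m)))] <- as.integer(pres$present)
  }
  m
}

#' Extract homolog sequences for a query
#'
#' Returns, for each positive genome, the best hit's subject sequence in
#' query orientation — the input rows for the homolog multiple alignment.
#'
#' @param query_id Candidate id.
#' @param profiles A [count_homologs()] result (built-in backend, so hits
#'   carry subject coordinates).
#' @param panel The [genome_panel()] the profiles were computed on.
#' @param params A [pipeline_params()] list.
#' @return A tibble with columns `genome_id`, `sequence`.
#' @export
homolog_sequences <- function(query_id, profiles, panel,
                              params = pipeline_params()) {
  stopifnot(inherits(profiles, "conservation_profiles"))
  qlen <- profiles$query_lengths[[query_id]]
  if (is.null(qlen)) abort_consistency(sprintf("unknown query id %s", query_id))
  need <- as.integer(ceiling(params$min_query_coverage * qlen))
  h <- profiles$hits
  h <- h[h$query_id == query_id & h$aligned_len >= need, , drop = FALSE]
  if (nrow(h) == 0) return(tibble(genome_id = character(), sequence = character()))
  h <- h[order(-h$score), , drop = FALSE]
  h <- h[!duplicated(h$genome_id), , drop = FALSE]
  seqs <- character(nrow(h))
  for (i in seq_len(nrow(h))) {
    contig <- panel$genomes$sequence[panel$genomes$genome_id == h$genome_id[i] &
                                       panel$genomes$contig_id == h$contig_id[i]]
    seqs[i] <- extract_transcript(contig[1], h$s_lo[i], h$s_hi[i],
                                  h$subject_strand[i])
  }
  tibble(genome_id = h$genome_id, sequence = seqs)
}
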