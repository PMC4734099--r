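## Orchestration: the full prediction pipeline (filter orphan TSSs -> pair
## with terminators -> optional conservation -> families -> representatives
## -> outputs) with stage counts as first-class results, because the
## method's headline numbers are exactly such counts.

resolve_replicons <- function(genome) {
  if (is.character(genome)) read_fasta(genome) else genome
}

#' Run the sRNA prediction pipeline
#'
#' @param genome Replicon tibble or path to a genome FASTA.
#' @param tss TSS tibble or path to a TSS table.
#' @param genes Gene tibble, path to GFF3/TSV annotation, or `NULL`.
#' @param terminators Terminator tibble, path to a TransTermHP report, or
#'   `NULL` to run the built-in detector.
#' @param panel Optional [genome_panel()] (or panel directory path) for
#'   conservation profiling.
#' @param clade_file,reference_id Passed to [read_genome_panel()] when
#'   `panel` is a path.
#' @param params A [pipeline_params()] list.
#' @param sim_search A [seed_search_params()] list for the built-in
#'   homology backend.
#' @param term_params A [term_scan_params()] list for the built-in
#'   terminator detector.
#' @param hits Optional imported BLAST hit tibble (see [read_blast_tab()]);
#'   used instead of the built-in homology backend.
#' @param out_dir Optional output directory; when given, result files and a
#'   machine-readable run summary are written there.
#' @return An object of class `srna_result` with components `segments`,
#'   `families`, `representatives`, `profiles`, `summary`, `params`.
#' @export
run_predict <- function(genome, tss, genes = NULL, terminators = NULL,
                        panel = NULL, clade_file = NULL, reference_id = NULL,
                        params = pipeline_params(),
                        sim_search = seed_search_params(),
                        term_params = term_scan_params(),
                        hits = NULL, out_dir = NULL) {
  replicons <- resolve_replicons(genome)
  if (is.character(tss)) tss <- read_tss_table(tss)
  if (is.character(genes)) genes <- read_genes(genes)
  if (is.null(terminators)) {
    terminators <- predict_terminators(replicons, term_params)
  } else if (is.character(terminators)) {
    terminators <- add_terminator_tails(read_transterm(terminators), replicons)
  }
  if (is.character(panel)) {
    panel <- read_genome_panel(panel, clade_file = clade_file,
                               reference_id = reference_id)
  }

  ntss <- filter_ntss(tss, genes, params)
  segments <- pair_segments(ntss, terminators, replicons, params)
  profiles <- NULL
  if (!is.null(panel) || !is.null(hits)) {
    if (is.null(panel)) abort_usage("imported hits require a genome panel")
    profiles <- count_homologs(
      dplyr::select(segments, id, sequence), panel, params,
      hits = hits, search = sim_search)
  }
  families <- cluster_families(segments)
  reps <- select_representative(families, segments, profiles, params)
  segments <- dplyr::left_join(segments,
                               dplyr::rename(families, id = member_id),
                               by = "id")
  representatives <- dplyr::inner_join(
    dplyr::rename(reps, id = representative_id), segments,
    by = c("id", "family_id"))
  representatives <- representatives[order(representatives$family_id), ]

  summary <- tibble(
    n_tss_in = nrow(tss),
    n_ntss = nrow(ntss),
    n_terminators_in = nrow(terminators),
    n_segments = nrow(segments),
    n_distinct_terminators = dplyr::n_distinct(segments$terminator_id),
    n_families = max(0L, nrow(reps)),
    n_entries = max(0L, nrow(reps)))

  res <- structure(list(segments = segments, families = families,
                        representatives = representatives,
                        profiles = profiles, summary = summary,
                        params = params, replicons = replicons),
                   class = "srna_result")
  if (!is.null(out_dir)) {
    write_result_files(res, out_dir)
  }
  res
}

write_result_files <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_outputs(res$segments, res$profiles, orfs = res$orfs, out_dir = out_dir)
  readr::write_tsv(res$representatives,
                   file.path(out_dir, "representatives.tsv"), progress = FALSE)
  if (!is.null(res$profiles)) {
    readr::write_tsv(tidy_profiles(res$profiles),
                     file.path(out_dir, "profiles.tsv"), progress = FALSE)
    ct <- clade_exclusive_table(res$profiles, res$params)
    readr::write_tsv(ct, file.path(out_dir, "clade_exclusive.tsv"),
                     progress = FALSE)
  }
  meta <- list(tool = "srnaflow",
               version = as.character(utils::packageVersion("srnaflow")),
               params = unclass(res$params),
               summary = as.list(res$summary))
  jsonlite::write_json(meta, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.srna_result <- function(x, ...) {
  s <- x$summary
  cat("<srna_result>\n")
  cat(sprintf("  TSSs in: %d; orphan (nTSS) kept: %d\n", s$n_tss_in, s$n_ntss))
  cat(sprintf("  segments: %d over %d distinct terminators\n",
              s$n_segments, s$n_distinct_terminators))
  cat(sprintf("  families/entries: %d\n", s$n_families))
  if (!is.null(x$profiles)) {
    cat(sprintf("  conservation: %d-genome panel\n",
                length(x$profiles$panel_genomes)))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the prediction result
#'
#' One row per non-redundant entry (family representative), with family
#' size and, when available, conservation counts.
#'
#' @param x An `srna_result`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy srna_result
#' @export
tidy.srna_result <- function(x, ...) {
  out <- x$representatives
  if (!is.null(x$profiles)) {
    out <- dplyr::left_join(
      out, dplyr::rename(tidy_profiles(x$profiles), id = query_id),
      by = "id")
  }
  dplyr::select(out, family_id, id, replicon_id, strand, tss_position,
                hairpin_lo, hairpin_hi, length_nt, reads_total, n_members,
                dplyr::any_of(c("homologs_total", "homologs_clade",
                                "clade_exclusive")), sequence)
}

#' Stage counts of a prediction run
#'
#' @param x An `srna_result`.
#' @param ... Unused.
#' @return A one-row tibble of stage counts.
#' @method glance srna_result
#' @export
glance.srna_result <- function(x, ...) x$summary

#' @method tidy conservation_profiles
#' @export
tidy.conservation_profiles <- function(x, ...) x$profiles

#' @method glance conservation_profiles
#' @export
glance.conservation_profiles <- function(x, ...) {
  tibble(n_queries = nrow(x$profiles),
         n_genomes = length(x$panel_genomes),
         n_clade = length(x$clade),
         mean_homologs = mean(x$profiles$homologs_total),
         n_clade_exclusive = sum(x$profiles$clade_exclusive))
}

#' Scan representative candidates for conserved small ORFs
#'
#' For every representative with enough homologs to form an alignment of at
#' least `min_alignment_seqs` rows (query + best hit per positive genome),
#' aligns the set with [center_star_align()] and scans it with
#' [scan_conserved_orfs()].
#'
#' @param result An `srna_result` with conservation profiles computed by
#'   the built-in backend.
#' @param panel The [genome_panel()] used for the profiles.
#' @param min_aa,max_aa,B,seed Passed to [scan_conserved_orfs()].
#' @return A tibble of ORF calls with a `candidate_id` column.
#' @export
run_orfs <- function(result, panel, min_aa = 10L, max_aa = 60L, B = 1000L,
                     seed = NULL) {
  stopifnot(inherits(result, "srna_result"))
  if (is.null(result$profiles)) {
    abort_usage("run_orfs needs conservation profiles; run with a panel first")
  }
  params <- result$params
  out <- list()
  for (i in seq_len(nrow(result$representatives))) {
    cid <- result$representatives$id[i]
    hom <- homolog_sequences(cid, result$profiles, panel, params)
    if (nrow(hom) + 1L < params$min_alignment_seqs) next
    seqs <- tibble(sequence_id = c(cid, hom$genome_id),
                   sequence = c(result$representatives$sequence[i],
                                hom$sequence))
    msa <- center_star_align(seqs, reference = 1L)
    calls <- scan_conserved_orfs(msa, min_aa = min_aa, max_aa = max_aa,
                                 B = B, seed = seed, params = params)
    if (nrow(calls)) {
      calls$candidate_id <- cid
      out[[length(out) + 1L]] <- calls
    }
  }
  if (!length(out)) {
    res <- empty_orf_calls()
    res$candidate_id <- character()
    return(res)
  }
  dplyr::relocate(dplyr::bind_rows(out), candidate_id)
}

#' Read a plain key=value run configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Values are
#' coerced to numbers or logicals where possible, and comma-separated
#' values become vectors.
#'
#' @param path Config file path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_usage(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) abort_usage(sprintf("malformed config line: %s", ln))
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) {
      out[[key]] <- num
    } else if (all(toupper(parts) %in% c("TRUE", "FALSE"))) {
      out[[key]] <- as.logical(toupper(parts))
    } else {
      out[[key]] <- if (length(parts) == 1) val else parts
    }
  }
  out
}

#' Write a run configuration file
#'
#' @param config Named list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  flat <- vapply(config, function(v) paste(v, collapse = ","), character(1))
  write_lines_nl(sprintf("%s = %s", names(flat), flat), path)
}
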