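## Writers. FASTA/TSV writers round-trip byte-identically with their readers;
## BED6 is the single 0-based half-open surface, GFF3 stays 1-based inclusive.

#' Write a replicon table as FASTA
#'
#' @param replicons Replicon tibble (see [read_fasta()]).
#' @param path Output path.
#' @param width Line width for wrapped sequence.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(replicons, path, width = 70L) {
  set <- Biostrings::DNAStringSet(setNames(replicons$sequence, replicons$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Write a TSS table
#'
#' @param tss TSS tibble (see [read_tss_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tss_table <- function(tss, path) {
  header <- paste(c("replicon", "position", "strand", "category",
                    tss_libraries()), collapse = "\t")
  reads <- sapply(tss_libraries(), function(lib) {
    if (lib %in% names(tss)) as.integer(tss[[lib]]) else rep(0L, nrow(tss))
  })
  if (nrow(tss) == 0) return(write_lines_nl(header, path))
  reads <- matrix(reads, nrow = nrow(tss))
  body <- paste(tss$replicon_id, tss$position, tss$strand,
                if ("category" %in% names(tss)) tss$category else "unknown",
                apply(reads, 1, paste, collapse = "\t"), sep = "\t")
  write_lines_nl(c(header, body), path)
}

#' Write terminator calls in the TransTermHP text dialect
#'
#' One `SEQUENCE` header per replicon followed by its `TERM` lines.
#' Minus-strand hairpin coordinates are printed high-to-low, as TransTermHP
#' does; [read_transterm()] normalizes them back.
#'
#' @param terminators Terminator tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transterm <- function(terminators, path) {
  lines <- character()
  for (rep_id in unique(terminators$replicon_id)) {
    sub <- terminators[terminators$replicon_id == rep_id, ]
    lines <- c(lines, sprintf("SEQUENCE %s", rep_id))
    c1 <- ifelse(sub$strand == "+", sub$hairpin_lo, sub$hairpin_hi)
    c2 <- ifelse(sub$strand == "+", sub$hairpin_hi, sub$hairpin_lo)
    lines <- c(lines, sprintf("  TERM %d %6d - %-6d %s G %6.0f  -10.0 -5.0",
                              seq_len(nrow(sub)), c1, c2, sub$strand,
                              sub$score))
  }
  write_lines_nl(lines, path)
}

segment_genomic_bounds <- function(segments) {
  fwd <- segments$strand == "+"
  tibble(
    lo = ifelse(fwd, segments$tss_position, segments$hairpin_lo),
    hi = ifelse(fwd, segments$hairpin_hi, segments$tss_position)
  )
}

#' Write pipeline result files
#'
#' Writes, under `out_dir`:
#' * `results.tsv` — one row per candidate segment with coordinates,
#'   sequence, per-library read counts and (when supplied) family,
#'   conservation and small-ORF annotation;
#' * `candidates.bed` — BED6 (0-based half-open; score = total reads capped
#'   at 1000; name = candidate id);
#' * `candidates.gff3` — GFF3 (1-based inclusive, type `ncRNA`);
#' * `presence_matrix.tsv` — genomes x candidates presence/absence, columns
#'   sorted by descending total homolog count (when profiles are supplied).
#'
#' @param segments Candidate segment tibble (see [pair_segments()]),
#'   optionally carrying a `family_id` column.
#' @param profiles A [count_homologs()] result, or `NULL`.
#' @param orfs A [scan_conserved_orfs()]-style tibble with a `candidate_id`
#'   column, or `NULL`.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_outputs <- function(segments, profiles = NULL, orfs = NULL, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  known <- segments$id
  prof_tab <- NULL
  if (!is.null(profiles)) {
    prof_tab <- tidy_profiles(profiles)
    bad <- setdiff(prof_tab$query_id, known)
    if (length(bad)) {
      abort_consistency(sprintf("profile(s) for unknown candidate id: %s",
                                paste(head(bad, 5), collapse = ", ")))
    }
  }
  if (!is.null(orfs) && nrow(orfs) > 0) {
    bad <- setdiff(unique(orfs$candidate_id), known)
    if (length(bad)) {
      abort_consistency(sprintf("ORF call(s) for unknown candidate id: %s",
                                paste(head(bad, 5), collapse = ", ")))
    }
  }

  res <- segments
  if (!"family_id" %in% names(res)) res$family_id <- NA_integer_
  if (is.null(prof_tab)) {
    res$homologs_total <- NA_integer_
    res$homologs_clade <- NA_integer_
    res$clade_exclusive <- NA
  } else {
    res <- dplyr::left_join(
      res,
      dplyr::select(prof_tab, id = query_id, homologs_total, homologs_clade,
                    clade_exclusive),
      by = "id")
  }
  res$orf <- if (is.null(orfs) || nrow(orfs) == 0) FALSE else
    res$id %in% orfs$candidate_id[orfs$p_value < 1]
  cols <- c("id", "replicon_id", "strand", "tss_position", "hairpin_lo",
            "hairpin_hi", "length_nt", "sequence", tss_libraries(),
            "family_id", "homologs_total", "homologs_clade",
            "clade_exclusive", "orf")
  res_path <- file.path(out_dir, "results.tsv")
  readr::write_tsv(dplyr::select(res, dplyr::all_of(cols)), res_path,
                   progress = FALSE)

  bed_path <- file.path(out_dir, "candidates.bed")
  gff_path <- file.path(out_dir, "candidates.gff3")
  if (nrow(segments) > 0) {
    b <- segment_genomic_bounds(segments)
    total_reads <- rowSums(as.matrix(segments[, tss_libraries()]))
    gr <- GenomicRanges::GRanges(
      seqnames = segments$replicon_id,
      ranges = IRanges::IRanges(start = b$lo, end = b$hi),
      strand = segments$strand)
    gr$name <- segments$id
    gr$score <- pmin(as.numeric(total_reads), 1000)
    rtracklayer::export(gr, bed_path, format = "BED")
    gr$type <- "ncRNA"
    gr$ID <- segments$id
    rtracklayer::export(gr, gff_path, format = "GFF3")
  } else {
    write_lines_nl(character(), bed_path)
    write_lines_nl("##gff-version 3", gff_path)
  }

  written <- c(results = res_path, bed = bed_path, gff3 = gff_path)
  if (!is.null(profiles)) {
    mat_path <- file.path(out_dir, "presence_matrix.tsv")
    write_presence_matrix(profiles, mat_path, decreasing = TRUE)
    written <- c(written, matrix = mat_path)
  }
  invisible(written)
}

#' Write a presence/absence matrix TSV
#'
#' Genomes as rows (panel order), candidates as columns sorted by total
#' homolog count.
#'
#' @param profiles A [count_homologs()] result.
#' @param path Output path.
#' @param decreasing Sort columns by descending (`TRUE`, results file) or
#'   ascending (`FALSE`, display map convention) homolog totals.
#' @param min_homologs Keep only candidates with at least this many homologs.
#' @return `path`, invisibly.
#' @export
write_presence_matrix <- function(profiles, path, decreasing = TRUE,
                                  min_homologs = 0L) {
  m <- build_matrix(profiles, min_homologs = min_homologs,
                    decreasing = decreasing)
  df <- tibble::as_tibble(m, rownames = "genome_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
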