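## Readers for the external formats the pipeline consumes. All coordinates
## are normalized to 1-based inclusive with strands in {+,-}; BED output is
## the only 0-based surface.

#' dRNA-Seq library labels
#'
#' The four sequencing libraries of the TSS dataset: wild type and the
#' heterocyst-regulator (hetR) mutant, each grown on ammonium or after 8 h of
#' nitrogen step-down.
#'
#' @return Character vector of the four library column names.
#' @export
tss_libraries <- function() c("wt_nh4", "wt_n8h", "hetr_nh4", "hetr_n8h")

#' Read a genome FASTA into a replicon table
#'
#' One row per FASTA record. The header token before the first whitespace is
#' used as the replicon id; sequences are uppercased and characters outside
#' `{A,C,G,T,N}` are mapped to `N`.
#'
#' @param path Path to a FASTA file with at least one record.
#' @param circular Logical, recycled; whether replicons are circular.
#'   Origin-spanning candidate segments are never formed either way.
#' @return A tibble with columns `id`, `sequence`, `length`, `circular`.
#' @export
read_fasta <- function(path, circular = FALSE) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) abort_format(sprintf(
                    "not a readable FASTA file: %s (%s)", path, conditionMessage(e))))
  if (length(set) == 0) abort_format(sprintf("empty FASTA file: %s", path))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort_format(sprintf("duplicate replicon id in %s: %s", path,
                         ids[duplicated(ids)][1]))
  }
  seqs <- clean_dna(as.character(set))
  tibble(id = ids, sequence = unname(seqs), length = nchar(seqs),
         circular = rep_len(as.logical(circular), length(ids)))
}

#' Read a TSS table
#'
#' Tab-separated with a header naming at least `replicon`, `position` and
#' `strand`; `category` and the four read-count columns
#' (`r tss_libraries()`) are matched by name in any column order. Strands
#' accept `+`, `-`, `f`, `r`. A missing category column (or empty value)
#' yields `"unknown"`; missing read counts yield 0.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `replicon_id`, `position`, `strand`,
#'   `category` and one integer column per library.
#' @export
read_tss_table <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE, na = character())
  need <- c("replicon", "position", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort_format(sprintf("TSS table %s lacks column(s): %s", path,
                         paste(miss, collapse = ", ")))
  }
  n <- nrow(df)
  line_no <- seq_len(n) + 1L  # header is line 1
  pos <- suppressWarnings(as.integer(df$position))
  bad <- which(is.na(pos) | suppressWarnings(as.numeric(df$position)) != pos)
  if (length(bad)) {
    abort_format(sprintf("non-integer TSS position at line %d of %s",
                         line_no[bad[1]], path))
  }
  strand <- tryCatch(normalize_strand(df$strand), error = function(e) {
    abort_format(sprintf("invalid strand in TSS table %s: %s", path,
                         conditionMessage(e)))
  })
  category <- if ("category" %in% names(df)) df$category else rep("", n)
  category[!category %in% c("nTSS", "gTSS", "iTSS", "aTSS")] <- "unknown"
  reads <- lapply(tss_libraries(), function(lib) {
    if (!lib %in% names(df)) return(rep(0L, n))
    raw <- df[[lib]]
    raw[raw == ""] <- "0"
    v <- suppressWarnings(as.integer(raw))
    bad <- which(is.na(v) | as.numeric(raw) != v | v < 0)
    if (length(bad)) {
      abort_format(sprintf("non-integer read count (%s) at line %d of %s",
                           lib, line_no[bad[1]], path))
    }
    v
  })
  names(reads) <- tss_libraries()
  out <- tibble(replicon_id = df$replicon, position = pos, strand = strand,
                category = category)
  dplyr::bind_cols(out, tibble::as_tibble(reads))
}

#' Read TransTermHP terminator predictions
#'
#' Parses the plain-text TransTermHP report. Only lines whose first token is
#' `TERM` are read as calls; each call is assigned to the replicon named by
#' the preceding `SEQUENCE` header line. Hairpin coordinates are normalized
#' so `hairpin_lo <= hairpin_hi` regardless of printed order (minus-strand
#' terminators are printed high-to-low).
#'
#' @param path Path to the TransTermHP output file.
#' @return A tibble with columns `replicon_id`, `terminator_id`, `strand`,
#'   `hairpin_lo`, `hairpin_hi`, `tail`, `score`. `tail` is `NA` until
#'   filled from the genome with [add_terminator_tails()].
#' @export
read_transterm <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  current <- NA_character_
  rows <- vector("list", length(lines))
  nrow_out <- 0L
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(toks) == 0 || toks[1] == "") next
    if (toks[1] == "SEQUENCE") {
      if (length(toks) < 2) {
        abort_format(sprintf("SEQUENCE header without an id at line %d of %s",
                             i, path))
      }
      current <- toks[2]
    } else if (toks[1] == "TERM") {
      if (is.na(current)) {
        abort_format(sprintf(
          "TERM line before any SEQUENCE header at line %d of %s", i, path))
      }
      if (length(toks) < 8) {
        abort_format(sprintf("truncated TERM line at line %d of %s", i, path))
      }
      c1 <- suppressWarnings(as.integer(toks[3]))
      c2 <- suppressWarnings(as.integer(toks[5]))
      if (is.na(c1) || is.na(c2)) {
        abort_format(sprintf("non-numeric TERM coordinates at line %d of %s",
                             i, path))
      }
      strand <- tryCatch(normalize_strand(toks[6]), error = function(e) {
        abort_format(sprintf("invalid TERM strand at line %d of %s", i, path))
      })
      score <- suppressWarnings(as.numeric(toks[8]))
      nrow_out <- nrow_out + 1L
      rows[[nrow_out]] <- tibble(
        replicon_id = current,
        terminator_id = paste0(current, ":", toks[2]),
        strand = strand,
        hairpin_lo = min(c1, c2), hairpin_hi = max(c1, c2),
        tail = NA_character_,
        score = if (is.na(score)) 0 else score
      )
    }
  }
  if (nrow_out == 0) return(empty_terminators())
  dplyr::bind_rows(rows[seq_len(nrow_out)])
}

empty_terminators <- function() {
  tibble(replicon_id = character(), terminator_id = character(),
         strand = character(), hairpin_lo = integer(), hairpin_hi = integer(),
         tail = character(), score = numeric())
}

#' Fill terminator tails from the genome
#'
#' The poly-U tail is not part of the printed terminator coordinates; this
#' reads the `n` nucleotides immediately 3' of the hairpin, in transcript
#' orientation, from the replicon sequence (clipped at the replicon end).
#'
#' @param terminators Terminator tibble (see [read_transterm()]).
#' @param replicons Replicon tibble (see [read_fasta()]).
#' @param n Tail length to extract.
#' @return The terminator tibble with the `tail` column filled.
#' @export
add_terminator_tails <- function(terminators, replicons, n = 10L) {
  if (nrow(terminators) == 0) return(terminators)
  lens <- setNames(replicons$length, replicons$id)
  seqs <- setNames(replicons$sequence, replicons$id)
  missing <- setdiff(unique(terminators$replicon_id), names(seqs))
  if (length(missing)) {
    abort_consistency(sprintf("terminator replicon(s) absent from genome: %s",
                              paste(missing, collapse = ", ")))
  }
  L <- lens[terminators$replicon_id]
  fwd <- terminators$strand == "+"
  lo <- ifelse(fwd, pmin(terminators$hairpin_hi + 1L, L + 1L),
               pmax(terminators$hairpin_lo - n, 1L))
  hi <- ifelse(fwd, pmin(terminators$hairpin_hi + n, L),
               pmax(terminators$hairpin_lo - 1L, 0L))
  tail <- character(nrow(terminators))
  ok <- lo <= hi
  tail[ok] <- extract_transcript(seqs[terminators$replicon_id[ok]],
                                 lo[ok], hi[ok], terminators$strand[ok])
  terminators$tail <- tail
  terminators
}

#' Read gene annotation
#'
#' Accepts GFF3 (via rtracklayer) or a simple tab-separated table with
#' columns `replicon`, `start`, `end`, `strand`, `locus_tag`.
#'
#' @param path Path to the annotation file.
#' @param format `"auto"` (by extension), `"gff3"` or `"tsv"`.
#' @return A tibble with columns `replicon_id`, `start`, `end`, `strand`,
#'   `locus_tag`, sorted by replicon and start.
#' @export
read_genes <- function(path, format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    types <- as.character(gr$type)
    keep <- if (any(types == "gene")) types == "gene" else types == "CDS"
    gr <- gr[keep]
    tag <- gr$locus_tag %||% gr$ID %||% paste0("gene", seq_along(gr))
    tag[is.na(tag)] <- paste0("gene", which(is.na(tag)))
    out <- tibble(
      replicon_id = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      locus_tag = as.character(tag)
    )
    if (any(!out$strand %in% c("+", "-"))) {
      abort_format(sprintf("unstranded gene feature(s) in %s", path))
    }
  } else {
    df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
    need <- c("replicon", "start", "end", "strand", "locus_tag")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      abort_format(sprintf("gene table %s lacks column(s): %s", path,
                           paste(miss, collapse = ", ")))
    }
    out <- tibble(
      replicon_id = df$replicon,
      start = as.integer(df$start), end = as.integer(df$end),
      strand = normalize_strand(df$strand), locus_tag = df$locus_tag
    )
    if (anyNA(out$start) || anyNA(out$end)) {
      abort_format(sprintf("non-integer gene coordinates in %s", path))
    }
  }
  if (any(out$start > out$end)) {
    abort_format(sprintf("gene with start > end in %s", path))
  }
  dplyr::arrange(out, replicon_id, start)
}

#' Read BLAST tabular homology hits
#'
#' Parses the standard 12-column tabular alignment format (`qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore`).
#' Subject coordinates are normalized ascending with the original orientation
#' kept in `subject_strand`. Rows whose query is absent from `query_lengths`
#' are dropped with one warning giving the count.
#'
#' @param path Path to the tabular file (no header).
#' @param query_lengths Named integer vector of query lengths; names are the
#'   admissible query ids.
#' @param genome_map Optional named character vector mapping subject sequence
#'   ids (`sseqid`) to genome ids; unmapped subjects keep their `sseqid` as
#'   genome id.
#' @return A tibble with columns `query_id`, `genome_id`, `contig_id`,
#'   `s_lo`, `s_hi`, `subject_strand`, `identity_pct`, `aligned_len`,
#'   `evalue`.
#' @export
read_blast_tab <- function(path, query_lengths, genome_map = NULL) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(query_id = character(), genome_id = character(),
                  contig_id = character(), s_lo = integer(), s_hi = integer(),
                  subject_strand = character(), identity_pct = numeric(),
                  aligned_len = integer(), evalue = numeric()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L)) {
    abort_format(sprintf(
      "expected 12 tab-separated columns, found %d at line %d of %s",
      nf[nf != 12L][1], which(nf != 12L)[1], path))
  }
  m <- do.call(rbind, parts)
  sstart <- as.integer(m[, 9]); send <- as.integer(m[, 10])
  out <- tibble(
    query_id = m[, 1],
    contig_id = m[, 2],
    identity_pct = as.numeric(m[, 3]),
    aligned_len = as.integer(m[, 4]),
    s_lo = pmin(sstart, send), s_hi = pmax(sstart, send),
    subject_strand = ifelse(sstart <= send, "+", "-"),
    evalue = as.numeric(m[, 11])
  )
  out$genome_id <- out$contig_id
  if (!is.null(genome_map)) {
    mapped <- genome_map[out$contig_id]
    out$genome_id <- ifelse(is.na(mapped), out$contig_id, unname(mapped))
  }
  unknown <- !out$query_id %in% names(query_lengths)
  if (any(unknown)) {
    warn(sprintf("dropped %d hit(s) with unknown query id in %s",
                 sum(unknown), path))
    out <- out[!unknown, ]
  }
  dplyr::select(out, query_id, genome_id, contig_id, s_lo, s_hi,
                subject_strand, identity_pct, aligned_len, evalue)
}
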