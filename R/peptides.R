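## Conserved small-ORF detection inside homolog sets: a center-star multiple
## aligner (stand-in for an external aligner) and a permutation test on the
## synonymous-position bias of substitutions — protein-coding regions tolerate
## substitutions preferentially at the third codon position.

#' Center-star multiple alignment
#'
#' The center is the sequence maximizing the summed count of shared
#' distinct 6-mers with all others; every other sequence is aligned to the
#' center by global alignment (match +1, mismatch -1, linear gap -2) and
#' the pairwise alignments are merged under once-a-gap-always-a-gap.
#'
#' @param sequences A tibble with columns `sequence_id` and `sequence` (or
#'   a named character vector).
#' @param reference Which row is the query sRNA (index or id); recorded as
#'   the alignment's reference row.
#' @return An object of class `srna_msa`: `rows` (tibble `sequence_id`,
#'   `aligned`), `reference_row`, `center_row`.
#' @export
center_star_align <- function(sequences, reference = 1L) {
  if (is.character(sequences)) {
    sequences <- tibble(
      sequence_id = names(sequences) %||% paste0("seq", seq_along(sequences)),
      sequence = unname(sequences))
  }
  n <- nrow(sequences)
  if (n < 2) abort_usage("center_star_align needs at least 2 sequences")
  seqs <- clean_dna(sequences$sequence)
  ids <- sequences$sequence_id
  if (is.character(reference)) reference <- match(reference, ids)
  if (is.na(reference) || reference < 1 || reference > n) {
    abort_usage("reference row not found")
  }

  kmer_sets <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < 6) return(character(0))
    unique(substring(s, 1:(L - 5), 6:L))
  })
  shared <- vapply(seq_len(n), function(i) {
    sum(vapply(seq_len(n)[-i], function(j) {
      length(intersect(kmer_sets[[i]], kmer_sets[[j]]))
    }, numeric(1)))
  }, numeric(1))
  center <- which.max(shared)  # first maximum: deterministic

  Lc <- nchar(seqs[center])
  sub_mat <- dna_submat(1, -1)
  # per-row: chars at each center position (or "-") and insertions between
  pos_chars <- vector("list", n)
  ins_list <- vector("list", n)   # each: list of length Lc+1 (slots 0..Lc)
  master_ins <- integer(Lc + 1L)
  for (r in seq_len(n)) {
    if (r == center) {
      pos_chars[[r]] <- strsplit(seqs[center], "", fixed = TRUE)[[1]]
      ins_list[[r]] <- rep(list(""), Lc + 1L)
      next
    }
    aln <- Biostrings::pairwiseAlignment(
      seqs[center], seqs[r], type = "global",
      substitutionMatrix = sub_mat, gapOpening = 0, gapExtension = 2)
    pc <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sc <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    chars <- rep("-", Lc)
    ins <- rep(list(""), Lc + 1L)
    cpos <- 0L
    for (col in seq_along(pc)) {
      if (pc[col] == "-") {
        ins[[cpos + 1L]] <- paste0(ins[[cpos + 1L]], sc[col])
      } else {
        cpos <- cpos + 1L
        chars[cpos] <- sc[col]
      }
    }
    pos_chars[[r]] <- chars
    ins_list[[r]] <- ins
    master_ins <- pmax(master_ins, nchar(unlist(ins)))
  }

  pad <- function(s, w) paste0(s, strrep("-", w - nchar(s)))
  aligned <- vapply(seq_len(n), function(r) {
    parts <- character(2L * Lc + 1L)
    ins <- ins_list[[r]]
    for (cpos in 0:Lc) {
      parts[2L * cpos + 1L] <- pad(ins[[cpos + 1L]], master_ins[cpos + 1L])
      if (cpos < Lc) parts[2L * cpos + 2L] <- pos_chars[[r]][cpos + 1L]
    }
    paste(parts, collapse = "")
  }, character(1))

  structure(list(rows = tibble(sequence_id = ids, aligned = aligned),
                 reference_row = reference, center_row = center),
            class = "srna_msa")
}

#' @export
print.srna_msa <- function(x, ...) {
  cat(sprintf("<srna_msa> %d rows x %d columns (reference row %d)\n",
              nrow(x$rows), nchar(x$rows$aligned[1]), x$reference_row))
  invisible(x)
}

#' Read an aligned FASTA as an MSA
#'
#' Bypass for an externally produced multiple alignment.
#'
#' @param path Aligned FASTA (equal-width rows, `-` gaps).
#' @param reference Reference row index or id.
#' @return An `srna_msa` object.
#' @export
read_msa <- function(path, reference = 1L) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) < 2) abort_format("alignment must have at least 2 rows")
  rows <- toupper(as.character(set))
  if (length(unique(nchar(rows))) != 1) {
    abort_format("alignment rows differ in width")
  }
  ids <- sub("\\s.*$", "", names(set))
  if (is.character(reference)) reference <- match(reference, ids)
  structure(list(rows = tibble(sequence_id = ids, aligned = unname(rows)),
                 reference_row = as.integer(reference), center_row = NA_integer_),
            class = "srna_msa")
}

orf_codon_tables <- function() {
  list(starts = c("ATG", "GTG"), stops = c("TAA", "TAG", "TGA"))
}

## Enumerate candidate ORFs on an ungapped reference sequence.
enumerate_orfs <- function(ref, min_aa, max_aa) {
  ct <- orf_codon_tables()
  L <- nchar(ref)
  if (L < 6) return(NULL)
  codON <- substring(ref, 1:(L - 2), 3:L)
  starts <- which(codON %in% ct$starts)
  out <- list(); n_out <- 0L
  for (s in starts) {
    in_frame <- seq(s, L - 2, by = 3)
    stop_i <- in_frame[codON[in_frame] %in% ct$stops]
    stop_i <- stop_i[stop_i > s]
    if (length(stop_i) == 0) next
    st <- stop_i[1]
    pep <- (st - s) / 3                 # codons before the stop
    if (pep < min_aa || pep > max_aa) next
    n_out <- n_out + 1L
    out[[n_out]] <- tibble(orf_start = s, orf_end = st + 2L,
                           start_codon = codON[s], stop_codon = codON[st],
                           peptide_len = as.integer(pep))
  }
  if (n_out == 0) return(NULL)
  dplyr::bind_rows(out)
}

## Shine-Dalgarno-like hexamer (<=1 mismatch to AGGAGG) wholly within
## 4-13 nt upstream of the start codon.
has_rbs <- function(ref, orf_start) {
  win_lo <- orf_start - 13L
  win_hi <- orf_start - 4L
  if (win_hi - 5L < 1L) return(FALSE)
  win_lo <- max(1L, win_lo)
  motif <- strsplit("AGGAGG", "")[[1]]
  for (u in win_lo:(win_hi - 5L)) {
    hex <- strsplit(substr(ref, u, u + 5L), "")[[1]]
    if (sum(hex != motif) <= 1L) return(TRUE)
  }
  FALSE
}

#' Scan a homolog alignment for conserved small ORFs
#'
#' Enumerates ORFs on the de-gapped reference row (start ATG/GTG, first
#' in-frame stop, peptide length in `[min_aa, max_aa]`). For each ORF,
#' substitutions of the other rows relative to the reference are counted by
#' codon position (alignment columns where either row has a gap or an
#' ambiguous base are skipped), giving counts `n1`, `n2`, `n3` and the
#' coding score `S = n3 / (n1 + n2 + n3)`. The null distribution of `S` is
#' obtained by shuffling the column order within the ORF span `B` times;
#' `p = (1 + #\{S_perm >= S_obs\}) / (B + 1)`. ORFs with fewer than 5
#' substitutions are reported as conserved but untestable (`p = 1`).
#'
#' @param msa An `srna_msa` with at least `min_alignment_seqs` rows.
#' @param min_aa,max_aa Peptide length bounds (codons before the stop).
#' @param B Number of permutations.
#' @param seed Optional integer seed for the permutations.
#' @param params A [pipeline_params()] list (`orf_alpha`,
#'   `min_alignment_seqs`).
#' @return A tibble with one row per ORF: reference coordinates, codons,
#'   `peptide_len`, `rbs_present`, `intact_fraction`, `n1`..`n3`,
#'   `coding_score`, `p_value` and `positive` (`p < orf_alpha`).
#' @export
scan_conserved_orfs <- function(msa, min_aa = 10L, max_aa = 60L, B = 1000L,
                                seed = NULL, params = pipeline_params()) {
  stopifnot(inherits(msa, "srna_msa"))
  nrows <- nrow(msa$rows)
  if (nrows < params$min_alignment_seqs) {
    abort_usage(sprintf("alignment has %d rows; at least %d required",
                        nrows, params$min_alignment_seqs))
  }
  rows <- lapply(msa$rows$aligned, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  ref_row <- rows[[msa$reference_row]]
  ref_cols <- which(ref_row != "-")
  ref <- paste(ref_row[ref_cols], collapse = "")
  orfs <- enumerate_orfs(ref, min_aa, max_aa)
  if (is.null(orfs)) return(empty_orf_calls())
  ct <- orf_codon_tables()
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }

  res <- vector("list", nrow(orfs))
  for (k in seq_len(nrow(orfs))) {
    o <- orfs[k, ]
    span_ref_pos <- o$orf_start:o$orf_end
    span_cols <- ref_cols[span_ref_pos]
    codon_pos <- ((span_ref_pos - o$orf_start) %% 3L) + 1L
    # per-column substitution totals over non-reference rows
    subs <- integer(length(span_cols))
    other <- setdiff(seq_len(nrows), msa$reference_row)
    for (r in other) {
      rc <- rows[[r]][span_cols]
      ok <- rc %in% c("A", "C", "G", "T") &
        ref_row[span_cols] %in% c("A", "C", "G", "T")
      subs <- subs + as.integer(ok & rc != ref_row[span_cols])
    }
    n_by_pos <- vapply(1:3, function(p) sum(subs[codon_pos == p]), integer(1))
    total <- sum(n_by_pos)
    if (total >= 5L) {
      s_obs <- n_by_pos[3] / total
      s_perm <- vapply(seq_len(B), function(b) {
        pp <- sample(codon_pos)
        sum(subs[pp == 3L]) / total
      }, numeric(1))
      p_val <- (1 + sum(s_perm >= s_obs)) / (B + 1)
    } else {
      s_obs <- NA_real_
      p_val <- 1
    }
    # intact rows: aligned start codon and an in-frame stop downstream
    intact <- vapply(other, function(r) {
      start_chars <- rows[[r]][ref_cols[o$orf_start:(o$orf_start + 2L)]]
      if (any(start_chars == "-")) return(FALSE)
      if (!paste(start_chars, collapse = "") %in% ct$starts) return(FALSE)
      after <- rows[[r]][seq(ref_cols[o$orf_start], length(ref_row))]
      rseq <- paste(after[after != "-"], collapse = "")
      Lr <- nchar(rseq)
      if (Lr < 6) return(FALSE)
      cods <- substring(rseq, seq(1, Lr - 2, by = 3), seq(3, Lr, by = 3))
      any(cods[-1] %in% ct$stops)
    }, logical(1))
    res[[k]] <- tibble(
      orf_start = o$orf_start, orf_end = o$orf_end,
      start_codon = o$start_codon, stop_codon = o$stop_codon,
      peptide_len = o$peptide_len,
      rbs_present = has_rbs(ref, o$orf_start),
      intact_fraction = (sum(intact) + 1) / nrows,  # reference is intact
      n1 = n_by_pos[1], n2 = n_by_pos[2], n3 = n_by_pos[3],
      coding_score = s_obs, p_value = p_val,
      positive = p_val < params$orf_alpha)
  }
  dplyr::bind_rows(res)
}

empty_orf_calls <- function() {
  tibble(orf_start = integer(), orf_end = integer(),
         start_codon = character(), stop_codon = character(),
         peptide_len = integer(), rbs_present = logical(),
         intact_fraction = numeric(), n1 = integer(), n2 = integer(),
         n3 = integer(), coding_score = numeric(), p_value = numeric(),
         positive = logical())
}
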