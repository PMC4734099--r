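## Pipeline core: classify TSSs against the annotation, keep supported
## orphan (intergenic) TSSs, and pair each with same-strand downstream
## intrinsic terminators under the transcript size window, keeping the
## shortest surviving segment per TSS (transcription likely stops at the
## first terminator encountered).

#' Classify TSSs against a gene annotation
#'
#' A TSS inside a same-strand gene is internal (`iTSS`); inside an
#' opposite-strand gene, antisense (`aTSS`); at most `ntss_distance` nt
#' upstream (in transcript orientation) of a same-strand gene start,
#' gene-associated (`gTSS`); anything else is an orphan/intergenic `nTSS`.
#' Gene boundaries count as inside (`start <= pos <= end`).
#'
#' @param tss TSS tibble (see [read_tss_table()]).
#' @param genes Gene tibble (see [read_genes()]); may be empty.
#' @param params A [pipeline_params()] list.
#' @return Character vector of categories, one per TSS row.
#' @export
classify_tss <- function(tss, genes, params = pipeline_params()) {
  n <- nrow(tss)
  out <- rep("nTSS", n)
  if (n == 0 || is.null(genes) || nrow(genes) == 0) return(out)
  for (rep_id in unique(tss$replicon_id)) {
    ti <- which(tss$replicon_id == rep_id)
    g <- genes[genes$replicon_id == rep_id, ]
    if (nrow(g) == 0) next
    pos <- tss$position[ti]
    str <- tss$strand[ti]
    same <- outer(str, g$strand, "==")
    within <- outer(pos, g$start, ">=") & outer(pos, g$end, "<=")
    i_tss <- rowSums(within & same) > 0
    a_tss <- rowSums(within & !same) > 0
    # distance to a same-strand gene start, transcript orientation
    d_fwd <- outer(g$start, pos, "-")        # genes x tss, + strand
    d_rev <- outer(pos, g$end, "-")          # tss x genes, - strand
    up_fwd <- t(d_fwd) >= 1 & t(d_fwd) <= params$ntss_distance &
      same & matrix(str == "+", length(ti), nrow(g))
    up_rev <- d_rev >= 1 & d_rev <= params$ntss_distance &
      same & matrix(str == "-", length(ti), nrow(g))
    g_tss <- rowSums(up_fwd | up_rev) > 0
    cls <- rep("nTSS", length(ti))
    cls[g_tss] <- "gTSS"
    cls[a_tss] <- "aTSS"
    cls[i_tss] <- "iTSS"
    out[ti] <- cls
  }
  out
}

#' Keep supported orphan TSSs
#'
#' Keeps TSSs whose stored category is `nTSS` (or, when the category is
#' `unknown`, which [classify_tss()] calls `nTSS`) and whose maximum
#' single-library read count is at least `min_reads`. Input order is
#' preserved.
#'
#' @param tss TSS tibble.
#' @param genes Gene tibble used to classify `unknown` categories.
#' @param params A [pipeline_params()] list.
#' @return The filtered TSS tibble with `category` resolved.
#' @export
filter_ntss <- function(tss, genes = NULL, params = pipeline_params()) {
  if (nrow(tss) == 0) return(tss)
  cat <- tss$category %||% rep("unknown", nrow(tss))
  unknown <- cat == "unknown"
  if (any(unknown)) {
    cat[unknown] <- classify_tss(tss[unknown, , drop = FALSE], genes, params)
  }
  libs <- intersect(tss_libraries(), names(tss))
  reads_max <- if (length(libs)) {
    do.call(pmax, c(unname(as.list(tss[, libs])), list(0L)))
  } else rep(0L, nrow(tss))
  tss$category <- cat
  tss[cat == "nTSS" & reads_max >= params$min_reads, , drop = FALSE]
}

#' Pair orphan TSSs with downstream terminators
#'
#' For each TSS, same-strand terminators on the same replicon whose hairpin
#' lies entirely downstream in transcript orientation define putative
#' transcripts from the TSS through the hairpin (poly-U tail excluded).
#' Lengths outside `[min_len, max_len]` are discarded and, among a TSS's
#' surviving pairings, only the shortest segment is kept (ties: higher
#' terminator score, then smaller hairpin span). Several TSSs may share one
#' terminator. With `shortest_after_window = FALSE` the nearest terminator
#' wins before the window is applied.
#'
#' @param ntss Filtered TSS tibble (see [filter_ntss()]).
#' @param terminators Terminator tibble.
#' @param replicons Replicon tibble; sequences are extracted from it
#'   (reverse-complemented on the minus strand).
#' @param params A [pipeline_params()] list.
#' @return A candidate segment tibble: `id`, `replicon_id`, `strand`,
#'   `tss_position`, `hairpin_lo`, `hairpin_hi`, `length_nt`, `sequence`,
#'   the four library read counts, `reads_total`, `terminator_id` and
#'   `term_score`, sorted by replicon and TSS position.
#' @export
pair_segments <- function(ntss, terminators, replicons,
                          params = pipeline_params()) {
  missing <- setdiff(unique(ntss$replicon_id), replicons$id)
  if (length(missing)) {
    abort_consistency(sprintf("TSS replicon(s) absent from genome: %s",
                              paste(missing, collapse = ", ")))
  }
  if (nrow(ntss) == 0 || nrow(terminators) == 0) return(empty_segments())
  if (!"terminator_id" %in% names(terminators)) {
    terminators$terminator_id <- paste0(terminators$replicon_id, ":",
                                        terminators$hairpin_lo, "-",
                                        terminators$hairpin_hi,
                                        terminators$strand)
  }
  lens <- setNames(replicons$length, replicons$id)
  bad <- ntss$position < 1 | ntss$position > lens[ntss$replicon_id]
  if (any(bad)) {
    abort_consistency(sprintf("TSS position outside replicon: %s:%d",
                              ntss$replicon_id[which(bad)[1]],
                              ntss$position[which(bad)[1]]))
  }

  tss <- ntss
  tss$.tss_row <- seq_len(nrow(tss))
  joined <- dplyr::inner_join(
    tss, dplyr::rename(terminators, term_score = score),
    by = c("replicon_id", "strand"), relationship = "many-to-many")
  fwd <- joined$strand == "+"
  downstream <- ifelse(fwd, joined$hairpin_lo >= joined$position,
                       joined$hairpin_hi <= joined$position)
  joined <- joined[downstream, , drop = FALSE]
  joined$length_nt <- ifelse(joined$strand == "+",
                             joined$hairpin_hi - joined$position + 1L,
                             joined$position - joined$hairpin_lo + 1L)
  in_window <- joined$length_nt >= params$min_len &
    joined$length_nt <= params$max_len
  pick_shortest <- function(d) {
    d[order(d$length_nt, -d$term_score, d$hairpin_hi - d$hairpin_lo), ,
      drop = FALSE][1, , drop = FALSE]
  }
  if (params$shortest_after_window) {
    joined <- joined[in_window, , drop = FALSE]
    if (nrow(joined) == 0) return(empty_segments())
    best <- dplyr::group_modify(dplyr::group_by(joined, .data$.tss_row),
                                ~ pick_shortest(.x))
  } else {
    if (nrow(joined) == 0) return(empty_segments())
    best <- dplyr::group_modify(dplyr::group_by(joined, .data$.tss_row),
                                ~ pick_shortest(.x))
    best <- best[best$length_nt >= params$min_len &
                   best$length_nt <= params$max_len, , drop = FALSE]
  }
  best <- dplyr::ungroup(best)
  if (nrow(best) == 0) return(empty_segments())

  seqs <- setNames(replicons$sequence, replicons$id)
  b_fwd <- best$strand == "+"
  lo <- ifelse(b_fwd, best$position, best$hairpin_lo)
  hi <- ifelse(b_fwd, best$hairpin_hi, best$position)
  out <- tibble(
    id = candidate_id(best$position, best$strand),
    replicon_id = best$replicon_id,
    strand = best$strand,
    tss_position = best$position,
    hairpin_lo = best$hairpin_lo,
    hairpin_hi = best$hairpin_hi,
    length_nt = best$length_nt,
    sequence = extract_transcript(seqs[best$replicon_id], lo, hi, best$strand),
    terminator_id = best$terminator_id,
    term_score = best$term_score
  )
  for (lib in tss_libraries()) {
    out[[lib]] <- if (lib %in% names(best)) best[[lib]] else rep(0L, nrow(out))
  }
  out$reads_total <- rowSums(as.matrix(out[, tss_libraries()]))
  out[order(out$replicon_id, out$tss_position, out$strand), , drop = FALSE]
}

empty_segments <- function() {
  out <- tibble(id = character(), replicon_id = character(),
                strand = character(), tss_position = integer(),
                hairpin_lo = integer(), hairpin_hi = integer(),
                length_nt = integer(), sequence = character(),
                terminator_id = character(), term_score = numeric())
  for (lib in tss_libraries()) out[[lib]] <- integer()
  out$reads_total <- numeric()
  out
}
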