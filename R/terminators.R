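## Stand-in detector for Rho-independent (intrinsic) terminators: a perfect
## (mismatch-free) hairpin stem scored per closing pair (G-C = 3, A-T = 2,
## G-T = 1 on the DNA) followed by a uridine-rich tail. It exists so the
## pipeline runs with zero external tools; an external TransTermHP report,
## when available, is read with read_transterm() instead.

pair_score_matrix <- function(pair_scores) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(0, 5, 5, dimnames = list(b, b))
  m["G", "C"] <- m["C", "G"] <- pair_scores[["GC"]]
  m["A", "T"] <- m["T", "A"] <- pair_scores[["AU"]]
  m["G", "T"] <- m["T", "G"] <- pair_scores[["GU"]]
  m
}

## Scan one strand of a sequence; returns hairpins in that strand's own
## coordinates. Vectorized over genome positions: for each loop length, stems
## are grown pair by pair, keeping a running score per putative inner pair.
scan_strand_hairpins <- function(seq, p) {
  L <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  code <- match(chars, c("A", "C", "G", "T", "N"))
  code[is.na(code)] <- 5L
  sm <- pair_score_matrix(p$pair_scores)
  t_cum <- cumsum(chars == "T")
  out <- list(); n_out <- 0L

  gaps <- (p$loop_min + 1L):(p$loop_max + 1L + 2L * (p$stem_max - 1L))
  psc <- lapply(setNames(gaps, gaps), function(g) {
    n <- L - g
    if (n < 1) return(numeric(0))
    idx <- seq_len(n)
    sm[cbind(code[idx], code[idx + g])]
  })

  for (l in p$loop_min:p$loop_max) {
    cum <- NULL
    for (t in 0:(p$stem_max - 1L)) {
      g <- l + 1L + 2L * t
      v <- psc[[as.character(g)]]
      if (length(v) == 0) break
      if (t == 0L) {
        cum <- ifelse(v > 0, v, NA_real_)        # indexed by inner 5' pos q
      } else {
        nq <- length(cum)
        if (nq < t + 1L) break
        add <- rep(NA_real_, nq)
        # pair t sits at (q - t, q + l + 1 + t): score psc[[g]][q - t]
        qs <- (t + 1L):nq
        vv <- v[qs - t]                          # out-of-range -> NA
        vv[!is.na(vv) & vv <= 0] <- NA_real_
        add[qs] <- vv[seq_along(qs)]
        cum <- cum + add
      }
      s <- t + 1L
      if (s < p$stem_min) next
      q <- which(!is.na(cum) & cum >= p$min_hairpin_score)
      if (length(q) == 0) next
      lo <- q - s + 1L
      hi <- q + l + s
      keep <- lo >= 1L & hi + p$tail_window <= L
      if (!any(keep)) next
      q <- q[keep]; lo <- lo[keep]; hi <- hi[keep]
      n_u <- t_cum[hi + p$tail_window] - t_cum[hi]
      u_pos_ok <- rep(FALSE, length(hi))
      for (rp in p$require_u_at) {
        u_pos_ok <- u_pos_ok | chars[hi + rp] == "T"
      }
      keep <- n_u >= p$min_tail_u & u_pos_ok
      if (!any(keep)) next
      n_out <- n_out + 1L
      out[[n_out]] <- tibble(hairpin_lo = lo[keep], hairpin_hi = hi[keep],
                             stem_len = s, score = cum[q][keep])
    }
  }
  if (n_out == 0) {
    return(tibble(hairpin_lo = integer(), hairpin_hi = integer(),
                  stem_len = integer(), score = numeric()))
  }
  dplyr::bind_rows(out)
}

## Greedy overlap resolution: highest hairpin score, then longest stem, then
## smallest hairpin_lo.
resolve_overlaps <- function(calls) {
  if (nrow(calls) <= 1) return(calls)
  calls <- calls[order(-calls$score, -calls$stem_len, calls$hairpin_lo), ]
  kept_lo <- integer(0); kept_hi <- integer(0)
  keep <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    lo <- calls$hairpin_lo[i]; hi <- calls$hairpin_hi[i]
    if (!any(lo <= kept_hi & hi >= kept_lo)) {
      keep[i] <- TRUE
      kept_lo <- c(kept_lo, lo); kept_hi <- c(kept_hi, hi)
    }
  }
  calls[keep, ]
}

#' Predict Rho-independent terminators (built-in detector)
#'
#' Scans both strands of each replicon for a perfect hairpin stem of
#' `stem_min`-`stem_max` bp (pairs from G-C, A-T, G-T only; no mismatches or
#' bulges) around a `loop_min`-`loop_max` nt loop, reaching a summed pair
#' score of at least `min_hairpin_score`, immediately followed in transcript
#' orientation by a tail window containing at least `min_tail_u` T's with a T
#' at tail position 1 or 2. Overlapping calls on a strand are resolved by
#' highest hairpin score, then longest stem, then smallest `hairpin_lo`.
#'
#' @param replicons Replicon tibble (see [read_fasta()]).
#' @param params A [term_scan_params()] list.
#' @return A terminator tibble (columns as [read_transterm()], tails filled
#'   from the genome), sorted by replicon, `hairpin_lo` and strand.
#' @export
predict_terminators <- function(replicons, params = term_scan_params()) {
  p <- params
  min_len <- 2L * p$stem_min + p$loop_min + p$tail_window
  res <- list()
  for (i in seq_len(nrow(replicons))) {
    seq <- replicons$sequence[i]
    L <- nchar(seq)
    if (L < min_len) {
      abort_usage(sprintf("replicon %s shorter than the minimum scannable length %d",
                          replicons$id[i], min_len))
    }
    fwd <- resolve_overlaps(scan_strand_hairpins(seq, p))
    fwd$strand <- rep("+", nrow(fwd))
    rev <- resolve_overlaps(scan_strand_hairpins(revcomp(seq), p))
    if (nrow(rev) > 0) {
      tmp <- L - rev$hairpin_hi + 1L
      rev$hairpin_hi <- L - rev$hairpin_lo + 1L
      rev$hairpin_lo <- tmp
    }
    rev$strand <- rep("-", nrow(rev))
    both <- dplyr::bind_rows(fwd, rev)
    if (nrow(both) == 0) next
    both$replicon_id <- replicons$id[i]
    res[[length(res) + 1L]] <- both
  }
  if (length(res) == 0) return(empty_terminators())
  out <- dplyr::bind_rows(res)
  out <- out[order(out$replicon_id, out$hairpin_lo, out$strand), ]
  out$terminator_id <- paste0(out$replicon_id, ":T",
                              stats::ave(seq_len(nrow(out)), out$replicon_id,
                                         FUN = seq_along))
  out$tail <- NA_character_
  out <- dplyr::select(out, replicon_id, terminator_id, strand, hairpin_lo,
                       hairpin_hi, tail, score)
  add_terminator_tails(out, replicons)
}
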