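# Independent oracles used across the suite: plain quadratic dynamic
# programming, exhaustive enumeration, and brute-force graph closure. These
# deliberately do not share code with the package internals.

random_seq <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# Quadratic local-alignment DP (match/mismatch/linear gap), with a
# deterministic traceback (diagonal > up > left) from the best cell.
oracle_local_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  jj <- seq_len(m)
  g <- -gap
  for (i in seq_len(n)) {
    s <- ifelse(B == A[i] & A[i] != "N", match, mismatch)
    base <- pmax(0, H[i, jj] + s, H[i, jj + 1] + gap)
    # linear gaps: a run of horizontal moves collapses to one jump, so the
    # whole row is cummax(base + g*k) - g*j
    H[i + 1, jj + 1] <- cummax(base + g * jj) - g * jj
  }
  best <- max(H)
  if (best <= 0) {
    return(list(score = 0, identity = 0, coverage = 0))
  }
  bidx <- which(H == best, arr.ind = TRUE)[1, ]
  bi <- bidx[1] - 1L; bj <- bidx[2] - 1L
  # traceback
  i <- bi; j <- bj
  matches <- 0L; cols <- 0L; a_used <- 0L; b_used <- 0L
  while (i > 0 && j > 0 && H[i + 1, j + 1] > 0) {
    s <- if (A[i] == B[j] && A[i] != "N") match else mismatch
    if (H[i + 1, j + 1] == H[i, j] + s) {
      matches <- matches + (A[i] == B[j] && A[i] != "N")
      cols <- cols + 1L; a_used <- a_used + 1L; b_used <- b_used + 1L
      i <- i - 1L; j <- j - 1L
    } else if (H[i + 1, j + 1] == H[i, j + 1] + gap) {
      cols <- cols + 1L; a_used <- a_used + 1L
      i <- i - 1L
    } else {
      cols <- cols + 1L; b_used <- b_used + 1L
      j <- j - 1L
    }
  }
  short_len <- min(n, m)
  short_used <- if (n <= m) a_used else b_used
  list(score = best, identity = matches / cols,
       coverage = short_used / short_len)
}

# Exhaustive hairpin enumeration: every (position, stem, loop) window with a
# perfect stem, score threshold and U-tail rule.
oracle_hairpins <- function(seq, p = term_scan_params()) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  pair_sc <- function(x, y) {
    if ((x == "G" && y == "C") || (x == "C" && y == "G")) return(p$pair_scores[["GC"]])
    if ((x == "A" && y == "T") || (x == "T" && y == "A")) return(p$pair_scores[["AU"]])
    if ((x == "G" && y == "T") || (x == "T" && y == "G")) return(p$pair_scores[["GU"]])
    0
  }
  out <- list()
  for (lo in seq_len(L)) {
    for (s in p$stem_min:p$stem_max) {
      for (l in p$loop_min:p$loop_max) {
        hi <- lo + 2 * s + l - 1
        if (hi + p$tail_window > L) next
        sc <- 0; ok <- TRUE
        for (k in 0:(s - 1)) {
          v <- pair_sc(chars[lo + k], chars[hi - k])
          if (v <= 0) { ok <- FALSE; break }
          sc <- sc + v
        }
        if (!ok || sc < p$min_hairpin_score) next
        tail <- chars[(hi + 1):(hi + p$tail_window)]
        if (sum(tail == "T") < p$min_tail_u) next
        if (!any(tail[p$require_u_at] == "T")) next
        out[[length(out) + 1]] <- data.frame(hairpin_lo = lo, hairpin_hi = hi,
                                             stem_len = s, score = sc)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(hairpin_lo = integer(), hairpin_hi = integer(),
                      stem_len = integer(), score = numeric()))
  }
  do.call(rbind, out)
}

# Brute-force TSS x terminator pairing: enumerate every pair, filter by
# downstream placement and the size window, then keep each TSS's shortest
# segment (ties: higher terminator score, then smaller hairpin span).
oracle_pairing <- function(tss, terms, params = pipeline_params()) {
  res <- list()
  for (i in seq_len(nrow(tss))) {
    cand <- list()
    for (j in seq_len(nrow(terms))) {
      if (tss$replicon_id[i] != terms$replicon_id[j]) next
      if (tss$strand[i] != terms$strand[j]) next
      if (tss$strand[i] == "+") {
        if (terms$hairpin_lo[j] < tss$position[i]) next
        len <- terms$hairpin_hi[j] - tss$position[i] + 1
      } else {
        if (terms$hairpin_hi[j] > tss$position[i]) next
        len <- tss$position[i] - terms$hairpin_lo[j] + 1
      }
      if (len < params$min_len || len > params$max_len) next
      cand[[length(cand) + 1]] <- data.frame(
        tss_row = i, term_row = j, length_nt = len,
        score = terms$score[j],
        span = terms$hairpin_hi[j] - terms$hairpin_lo[j])
    }
    if (!length(cand)) next
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand$length_nt, -cand$score, cand$span), ]
    res[[length(res) + 1]] <- cand[1, ]
  }
  if (!length(res)) {
    return(data.frame(tss_row = integer(), term_row = integer(),
                      length_nt = integer()))
  }
  do.call(rbind, res)
}

# Brute-force connected components by repeated closure over an edge list.
oracle_components <- function(n, edges) {
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (e in edges) {
      m <- min(comp[e[1]], comp[e[2]])
      if (comp[e[1]] != m || comp[e[2]] != m) {
        comp[comp == comp[e[1]]] <- m
        comp[comp == comp[e[2]]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# Oracle local search for the homology backend: optimal local alignment
# (independent C implementation) on both subject strands; a genome is
# positive when the best alignment spans enough of the query.
oracle_genome_positive <- function(query, contigs, min_cov = 0.35) {
  need <- ceiling(min_cov * nchar(query))
  mat <- matrix(-2, 5, 5, dimnames = list(c("A","C","G","T","N"),
                                          c("A","C","G","T","N")))
  diag(mat)[1:4] <- 1
  for (ctg in contigs) {
    for (s in c(ctg, as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(ctg))))) {
      aln <- Biostrings::pairwiseAlignment(query, s, type = "local",
                                           substitutionMatrix = mat,
                                           gapOpening = 4, gapExtension = 2)
      if (Biostrings::score(aln) <= 0) next
      used <- nchar(gsub("-", "", as.character(Biostrings::alignedPattern(aln))))
      if (used >= need) return(TRUE)
    }
  }
  FALSE
}

# Small deterministic synthetic fixture used by several files.
tiny_sim <- function(seed, ...) {
  args <- list(seed = seed, n_replicons = 1L, replicon_length = 14000L,
               n_planted_srnas = 3L, n_decoy_tss = 6L,
               n_decoy_terminators = 4L, n_decoy_genes = 4L, panel_size = 6L,
               clade_size = 3L, panel_genome_length = 3000L)
  do.call(sim_params, utils::modifyList(args, list(...)))
}
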