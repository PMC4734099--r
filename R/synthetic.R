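## Synthetic datasets with known ground truth: multi-replicon genomes with
## decoy genes, planted TSSs (with per-library read counts), planted
## stem-loop + U-tail terminators, homolog copies across a genome panel at a
## controlled per-site substitution rate, and an optional planted small ORF
## with synonymous-biased substitutions. Every emitted file uses exactly the
## formats the readers consume.

#' Simulation parameters
#'
#' Defaults emulate the study conditions at desk scale: a small
#' multi-replicon genome (chromosome-plus-plasmid flavor, 41% GC as typical
#' for heterocystous cyanobacteria), planted sRNA loci inside the 45-350 nt
#' window with strong hairpin terminators and U7 tails, decoy TSSs that
#' individually exercise each filter (sub-threshold reads, genic position,
#' no terminator in range), and a genome panel with a designated clade and
#' substitution-only homolog divergence.
#'
#' @param seed Integer seed; the whole dataset is a pure function of it.
#' @param n_replicons,replicon_length Genome shape (nt per replicon).
#' @param gc_fraction Background GC content.
#' @param n_planted_srnas Number of planted sRNA loci.
#' @param planted_length_range Transcript length range (within 45-350).
#' @param n_decoy_tss Decoy TSSs, split over the three decoy classes.
#' @param n_decoy_terminators Decoy terminators (hairpin + tail embedded,
#'   not linked to any supported TSS).
#' @param n_decoy_genes Decoy genes (300-900 nt) for the annotation.
#' @param panel_size,clade_size Genome panel shape.
#' @param panel_genome_length Background length of each panel genome.
#' @param homolog_mutation_rate Per-site substitution probability applied
#'   to planted homolog copies (0-0.3; no indels).
#' @param fraction_clade_exclusive Fraction of planted loci whose homologs
#'   are planted only in clade genomes.
#' @param plant_orf Plant a small ORF (with RBS) in the first locus, with
#'   synonymous-biased substitutions in its homolog copies.
#' @param orf_aa Peptide length range (codons before the stop).
#' @return A named list of class `sim_params`.
#' @export
sim_params <- function(seed = 1L,
                       n_replicons = 2L,
                       replicon_length = 25000L,
                       gc_fraction = 0.41,
                       n_planted_srnas = 8L,
                       planted_length_range = c(45L, 350L),
                       n_decoy_tss = 12L,
                       n_decoy_terminators = 10L,
                       n_decoy_genes = 12L,
                       panel_size = 12L,
                       clade_size = 6L,
                       panel_genome_length = 6000L,
                       homolog_mutation_rate = 0.05,
                       fraction_clade_exclusive = 0.4,
                       plant_orf = TRUE,
                       orf_aa = c(15L, 30L)) {
  p <- list(seed = as.integer(seed), n_replicons = as.integer(n_replicons),
            replicon_length = as.integer(replicon_length),
            gc_fraction = as.numeric(gc_fraction),
            n_planted_srnas = as.integer(n_planted_srnas),
            planted_length_range = as.integer(planted_length_range),
            n_decoy_tss = as.integer(n_decoy_tss),
            n_decoy_terminators = as.integer(n_decoy_terminators),
            n_decoy_genes = as.integer(n_decoy_genes),
            panel_size = as.integer(panel_size),
            clade_size = as.integer(clade_size),
            panel_genome_length = as.integer(panel_genome_length),
            homolog_mutation_rate = as.numeric(homolog_mutation_rate),
            fraction_clade_exclusive = as.numeric(fraction_clade_exclusive),
            plant_orf = isTRUE(plant_orf), orf_aa = as.integer(orf_aa))
  if (p$planted_length_range[1] < 45L || p$planted_length_range[2] > 350L ||
      p$planted_length_range[1] > p$planted_length_range[2]) {
    abort_usage("planted_length_range must lie within [45, 350]")
  }
  if (p$homolog_mutation_rate < 0 || p$homolog_mutation_rate > 0.3) {
    abort_usage("homolog_mutation_rate must lie in [0, 0.3]")
  }
  if (p$clade_size > p$panel_size) {
    abort_usage("clade_size must be <= panel_size")
  }
  structure(p, class = "sim_params")
}

with_preserved_rng <- function(code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

## A planted hairpin: 8 bp all-G/C stem (pair score 24), 4 nt loop, U7 tail.
make_hairpin <- function() {
  stem <- paste(sample(c("G", "C"), 8, replace = TRUE), collapse = "")
  loop <- paste(sample(c("A", "C", "T"), 4, replace = TRUE), collapse = "")
  list(hairpin = paste0(stem, loop, revcomp(stem)), tail = strrep("T", 7))
}

## Random sense (non-stop) codon.
sense_codons <- function() {
  all3 <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                            c("A","C","G","T")), 1, paste, collapse = "")
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

## Substitution-only mutation; within an ORF span, third codon positions
## mutate preferentially (never into a stop) and the start/stop codons are
## left intact.
mutate_copy <- function(seq, rate, orf_span = NULL) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(chars)
  rate_vec <- rep(rate, L)
  if (!is.null(orf_span)) {
    pos <- orf_span[1]:orf_span[2]
    cp <- ((pos - orf_span[1]) %% 3L) + 1L
    rate_vec[pos[cp %in% c(1L, 2L)]] <- rate / 5
    rate_vec[pos[cp == 3L]] <- min(2.5 * rate, 0.5)
    rate_vec[orf_span[1]:(orf_span[1] + 2L)] <- 0           # start codon
    rate_vec[(orf_span[2] - 2L):orf_span[2]] <- 0           # stop codon
  }
  hit <- which(runif(L) < rate_vec)
  for (i in hit) {
    alt <- setdiff(c("A", "C", "G", "T"), chars[i])
    chars[i] <- sample(alt, 1)
    if (!is.null(orf_span) && i >= orf_span[1] && i <= orf_span[2]) {
      c0 <- orf_span[1] + 3L * ((i - orf_span[1]) %/% 3L)
      codon <- paste(chars[c0:(c0 + 2L)], collapse = "")
      if (codon %in% c("TAA", "TAG", "TGA")) {
        chars[i] <- substr(seq, i, i)  # revert premature stop
      }
    }
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic dataset with ground truth
#'
#' Writes, under `out_dir`: `genome.fasta`, `genes.gff3`, `tss.tsv`,
#' `terminators.txt` (TransTermHP dialect), `panel/<genome>.fasta` files,
#' `clade.txt` and `truth.tsv`. Placement is blockwise with at least 400 nt
#' between elements, so planted loci stay intergenic, decoy "no-terminator"
#' TSSs really have no terminator within the size window, and no decoy
#' terminator can shadow a planted one. Fully reproducible from the seed;
#' infeasible placements fail before any file is written.
#'
#' @param p A [sim_params()] list.
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with the in-memory dataset: `replicons`,
#'   `genes`, `tss`, `terminators`, `panel`, `truth`, `files`.
#' @export
simulate_dataset <- function(p = sim_params(), out_dir) {
  stopifnot(inherits(p, "sim_params"))
  ds <- with_preserved_rng({
    set.seed(p$seed)
    build_synthetic(p)
  })
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  panel_dir <- file.path(out_dir, "panel")
  dir.create(panel_dir, showWarnings = FALSE)
  files <- c(
    genome = file.path(out_dir, "genome.fasta"),
    genes = file.path(out_dir, "genes.gff3"),
    tss = file.path(out_dir, "tss.tsv"),
    terminators = file.path(out_dir, "terminators.txt"),
    clade = file.path(out_dir, "clade.txt"),
    truth = file.path(out_dir, "truth.tsv"))
  write_fasta(ds$replicons, files[["genome"]])
  gff <- c("##gff-version 3",
           sprintf("%s\tsrnaflow_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s;locus_tag=%s",
                   ds$genes$replicon_id, ds$genes$start, ds$genes$end,
                   ds$genes$strand, ds$genes$locus_tag, ds$genes$locus_tag))
  write_lines_nl(if (nrow(ds$genes)) gff else gff[1], files[["genes"]])
  write_tss_table(ds$tss, files[["tss"]])
  write_transterm(ds$terminators, files[["terminators"]])
  write_lines_nl(ds$panel$clade, files[["clade"]])
  readr::write_tsv(ds$truth, files[["truth"]], progress = FALSE)
  for (g in unique(ds$panel$genomes$genome_id)) {
    sub <- ds$panel$genomes[ds$panel$genomes$genome_id == g, ]
    write_fasta(tibble(id = sub$contig_id, sequence = sub$sequence),
                file.path(panel_dir, paste0(g, ".fasta")))
  }
  ds$files <- c(files, panel = panel_dir)
  invisible(ds)
}

build_synthetic <- function(p) {
  libs <- tss_libraries()
  n_sub <- ceiling(p$n_decoy_tss / 3)
  n_genic <- if (p$n_decoy_genes > 0) floor(p$n_decoy_tss / 3) else 0L
  n_noterm <- p$n_decoy_tss - n_sub - n_genic

  orf_aa <- if (p$plant_orf) sample(p$orf_aa[1]:p$orf_aa[2], 1) else NA_integer_

  ## --- element construction (sequence blocks) -------------------------
  elements <- list()
  add <- function(el) elements[[length(elements) + 1L]] <<- el
  for (i in seq_len(p$n_planted_srnas)) {
    L <- sample(p$planted_length_range[1]:p$planted_length_range[2], 1)
    strand <- sample(c("+", "-"), 1)
    hp <- make_hairpin()
    orf <- NULL
    body_len <- L - nchar(hp$hairpin)
    if (p$plant_orf && i == 1L) {
      need <- 2L + 6L + 5L + 3L * (orf_aa + 1L)          # pad+RBS+spacer+ORF
      body_len <- max(body_len, need + 3L)
      L <- body_len + nchar(hp$hairpin)
      orf_nt <- 3L * (orf_aa + 1L)
      codons <- c("ATG", sample(sense_codons(), orf_aa - 1L, replace = TRUE),
                  "TAA")
      body <- paste0(random_dna(2L, p$gc_fraction), "AGGAGG",
                     random_dna(5L, p$gc_fraction),
                     paste(codons, collapse = ""),
                     random_dna(body_len - 13L - orf_nt, p$gc_fraction))
      orf <- c(start = 14L, end = 13L + orf_nt)          # transcript coords
    } else {
      body <- random_dna(body_len, p$gc_fraction)
    }
    transcript <- paste0(body, hp$hairpin)
    add(list(kind = "srna", strand = strand, transcript = transcript,
             tail = hp$tail, L = nchar(transcript), orf = orf,
             block = if (strand == "+") paste0(transcript, hp$tail) else
               revcomp(paste0(transcript, hp$tail))))
  }
  for (i in seq_len(p$n_decoy_genes)) {
    len <- sample(300:900, 1)
    add(list(kind = "gene", strand = sample(c("+", "-"), 1),
             block = random_dna(len, p$gc_fraction), len = len))
  }
  for (i in seq_len(p$n_decoy_terminators)) {
    hp <- make_hairpin()
    strand <- sample(c("+", "-"), 1)
    blk <- paste0(hp$hairpin, hp$tail)
    add(list(kind = "decoy_term", strand = strand,
             block = if (strand == "+") blk else revcomp(blk),
             hp_len = nchar(hp$hairpin)))
  }
  for (i in seq_len(n_sub)) {
    hp <- make_hairpin()
    strand <- sample(c("+", "-"), 1)
    body <- random_dna(80, p$gc_fraction)
    blk <- paste0(body, hp$hairpin, hp$tail)
    add(list(kind = "sub_tss", strand = strand,
             block = if (strand == "+") blk else revcomp(blk),
             body_len = 80L, hp_len = nchar(hp$hairpin)))
  }
  for (i in seq_len(n_noterm)) {
    add(list(kind = "noterm_tss", strand = sample(c("+", "-"), 1),
             block = random_dna(1, p$gc_fraction)))
  }

  ## --- placement -------------------------------------------------------
  elements <- elements[sample(length(elements))]
  rep_ids <- sprintf("chr%02d", seq_len(p$n_replicons))
  assignment <- sort(rep_len(seq_len(p$n_replicons), length(elements)))
  assignment <- assignment[sample(length(assignment))]
  placed <- vector("list", length(elements))
  cursor <- setNames(rep(0L, p$n_replicons), rep_ids)
  for (e in seq_along(elements)) {
    rid <- rep_ids[assignment[e]]
    gap <- 400L + sample(0:200, 1)
    start <- cursor[[rid]] + gap + 1L
    end <- start + nchar(elements[[e]]$block) - 1L
    cursor[[rid]] <- end
    placed[[e]] <- list(replicon = rid, start = start, end = end)
  }
  if (any(cursor + 400L > p$replicon_length)) {
    abort_usage(sprintf(
      "replicon_length %d too small for the requested elements (need >= %d)",
      p$replicon_length, max(cursor) + 400L))
  }
  replicons <- tibble(id = rep_ids, sequence = vapply(rep_ids, function(r)
    random_dna(p$replicon_length, p$gc_fraction), character(1)),
    length = p$replicon_length, circular = FALSE)
  for (e in seq_along(elements)) {
    pl <- placed[[e]]
    i <- match(pl$replicon, replicons$id)
    s <- replicons$sequence[i]
    substr(s, pl$start, pl$end) <- elements[[e]]$block
    replicons$sequence[i] <- s
  }

  ## --- per-element records ---------------------------------------------
  genes <- list(); tss <- list(); terms <- list(); truth <- list()
  high_reads <- function() {
    r <- rpois(4, lambda = c(120, 400, 60, 40))
    r[sample(4, 1)] <- r[sample(4, 1)] + 60L   # guarantee a strong library
    as.integer(r)
  }
  gi <- 0L
  for (e in seq_along(elements)) {
    el <- elements[[e]]
    pl <- placed[[e]]
    if (el$kind == "srna") {
      if (el$strand == "+") {
        tss_pos <- pl$start
        hp_hi <- pl$start + el$L - 1L
        hp_lo <- hp_hi - 19L
      } else {
        tss_pos <- pl$end                    # 5' end; genomic tail is 5' of block
        hp_lo <- pl$start + 7L
        hp_hi <- hp_lo + 19L
      }
      tss[[length(tss) + 1L]] <- c(list(replicon_id = pl$replicon,
                                        position = tss_pos, strand = el$strand,
                                        category = "unknown"),
                                   setNames(as.list(high_reads()), libs))
      terms[[length(terms) + 1L]] <- tibble(
        replicon_id = pl$replicon, strand = el$strand,
        hairpin_lo = hp_lo, hairpin_hi = hp_hi, score = 100)
      truth[[length(truth) + 1L]] <- tibble(
        srna_id = candidate_id(tss_pos, el$strand),
        replicon_id = pl$replicon, strand = el$strand,
        tss_position = tss_pos, hairpin_lo = hp_lo, hairpin_hi = hp_hi,
        length_nt = el$L, transcript = el$transcript,
        orf_start = if (is.null(el$orf)) NA_integer_ else el$orf[["start"]],
        orf_end = if (is.null(el$orf)) NA_integer_ else el$orf[["end"]])
    } else if (el$kind == "gene") {
      gi <- gi + 1L
      genes[[gi]] <- tibble(replicon_id = pl$replicon, start = pl$start,
                            end = pl$end, strand = el$strand,
                            locus_tag = sprintf("dec%03d", gi))
    } else if (el$kind == "decoy_term") {
      hp <- if (el$strand == "+") c(pl$start, pl$start + el$hp_len - 1L) else
        c(pl$end - el$hp_len + 1L, pl$end)
      terms[[length(terms) + 1L]] <- tibble(
        replicon_id = pl$replicon, strand = el$strand,
        hairpin_lo = hp[1], hairpin_hi = hp[2], score = 85)
    } else if (el$kind == "sub_tss") {
      if (el$strand == "+") {
        tss_pos <- pl$start
        hp_lo <- pl$start + el$body_len
        hp_hi <- hp_lo + el$hp_len - 1L
      } else {
        tss_pos <- pl$end
        hp_lo <- pl$start + 7L
        hp_hi <- hp_lo + el$hp_len - 1L
      }
      tss[[length(tss) + 1L]] <- c(list(replicon_id = pl$replicon,
                                        position = tss_pos, strand = el$strand,
                                        category = "unknown"),
                                   setNames(as.list(sample(0:7, 4, TRUE)), libs))
      terms[[length(terms) + 1L]] <- tibble(
        replicon_id = pl$replicon, strand = el$strand,
        hairpin_lo = hp_lo, hairpin_hi = hp_hi, score = 90)
    } else if (el$kind == "noterm_tss") {
      tss[[length(tss) + 1L]] <- c(list(replicon_id = pl$replicon,
                                        position = pl$start, strand = el$strand,
                                        category = "unknown"),
                                   setNames(as.list(high_reads()), libs))
    }
  }
  genes <- if (length(genes)) dplyr::bind_rows(genes) else
    tibble(replicon_id = character(), start = integer(), end = integer(),
           strand = character(), locus_tag = character())
  ## genic decoy TSSs sit inside decoy genes (same strand -> iTSS)
  for (i in seq_len(n_genic)) {
    g <- genes[sample(nrow(genes), 1), ]
    pos <- sample((g$start + 10L):(g$end - 10L), 1)
    tss[[length(tss) + 1L]] <- c(list(replicon_id = g$replicon_id,
                                      position = pos, strand = g$strand,
                                      category = "unknown"),
                                 setNames(as.list(high_reads()), libs))
  }
  tss <- dplyr::bind_rows(lapply(tss, tibble::as_tibble))
  tss <- tss[sample(nrow(tss)), ]
  terminators <- dplyr::bind_rows(terms)
  terminators <- terminators[order(terminators$replicon_id,
                                   terminators$hairpin_lo), ]
  terminators$terminator_id <- paste0(terminators$replicon_id, ":T",
                                      seq_len(nrow(terminators)))
  terminators$tail <- NA_character_
  terminators <- dplyr::select(terminators, replicon_id, terminator_id,
                               strand, hairpin_lo, hairpin_hi, tail, score)
  terminators <- add_terminator_tails(terminators, replicons)
  truth <- dplyr::bind_rows(truth)

  ## --- homolog panel ----------------------------------------------------
  genome_ids <- sprintf("g%02d", seq_len(p$panel_size))
  clade <- genome_ids[seq_len(p$clade_size)]
  n_excl <- round(p$fraction_clade_exclusive * nrow(truth))
  excl <- rep(FALSE, nrow(truth))
  if (n_excl > 0 && nrow(truth) > 0) {
    excl[sample(nrow(truth), min(n_excl, nrow(truth)))] <- TRUE
  }
  draw_k <- function(lo, hi) if (lo >= hi) hi else sample(lo:hi, 1)
  carriers <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    if (excl[i]) {
      k <- draw_k(min(2L, p$clade_size), p$clade_size)
      carriers[[i]] <- sort(sample(clade, min(k, length(clade))))
    } else {
      k <- draw_k(min(3L, p$panel_size), p$panel_size)
      cand <- sort(sample(genome_ids, k))
      if (p$clade_size < p$panel_size && all(cand %in% clade)) {
        cand <- sort(c(cand[-1], sample(setdiff(genome_ids, clade), 1)))
      }
      carriers[[i]] <- cand
    }
  }
  truth$carriers <- vapply(carriers, paste, character(1), collapse = ",")
  truth$n_carriers <- lengths(carriers)
  truth$clade_exclusive <- excl

  panel_rows <- list()
  for (g in genome_ids) {
    bg <- random_dna(p$panel_genome_length, p$gc_fraction)
    inserts <- which(vapply(carriers, function(cc) g %in% cc, logical(1)))
    cur <- 0L
    for (i in inserts) {
      span <- if (!is.na(truth$orf_start[i]))
        c(truth$orf_start[i], truth$orf_end[i]) else NULL
      copy <- mutate_copy(truth$transcript[i], p$homolog_mutation_rate, span)
      if (sample(c(TRUE, FALSE), 1)) copy <- revcomp(copy)
      at <- cur + 150L + sample(0:50, 1)
      if (at + nchar(copy) > nchar(bg)) {
        bg <- paste0(bg, random_dna(at + nchar(copy) - nchar(bg) + 200L,
                                    p$gc_fraction))
      }
      substr(bg, at + 1L, at + nchar(copy)) <- copy
      cur <- at + nchar(copy)
    }
    panel_rows[[g]] <- tibble(genome_id = g, contig_id = paste0(g, "_c1"),
                              sequence = bg)
  }
  panel <- genome_panel(dplyr::bind_rows(panel_rows), clade = clade)

  list(replicons = replicons, genes = genes, tss = tss,
       terminators = terminators, panel = panel, truth = truth)
}

#' Mirror a dataset (reverse complement + coordinate flip)
#'
#' Reverse-complements every replicon and flips all coordinates and strands
#' of the TSS, gene and terminator tables. A correct pipeline produces
#' mirrored segments with identical transcript sequences on the mirrored
#' dataset.
#'
#' @param replicons,tss,genes,terminators Dataset tables.
#' @return A list with the four mirrored tables.
#' @export
mirror_dataset <- function(replicons, tss = NULL, genes = NULL,
                           terminators = NULL) {
  L <- setNames(replicons$length, replicons$id)
  flip <- function(pos, rep_id) L[rep_id] - pos + 1L
  out <- list()
  rc <- replicons
  rc$sequence <- revcomp(rc$sequence)
  out$replicons <- rc
  if (!is.null(tss)) {
    t2 <- tss
    t2$position <- unname(flip(tss$position, tss$replicon_id))
    t2$strand <- ifelse(tss$strand == "+", "-", "+")
    out$tss <- t2
  }
  if (!is.null(genes)) {
    g2 <- genes
    g2$start <- unname(flip(genes$end, genes$replicon_id))
    g2$end <- unname(flip(genes$start, genes$replicon_id))
    g2$strand <- ifelse(genes$strand == "+", "-", "+")
    out$genes <- g2
  }
  if (!is.null(terminators)) {
    tm <- terminators
    tm$hairpin_lo <- unname(flip(terminators$hairpin_hi,
                                 terminators$replicon_id))
    tm$hairpin_hi <- unname(flip(terminators$hairpin_lo,
                                 terminators$replicon_id))
    tm$strand <- ifelse(terminators$strand == "+", "-", "+")
    out$terminators <- tm
  }
  out
}

#' Score predictions against the planted truth
#'
#' A planted locus is recovered when a same-strand predicted segment
#' overlaps it with Jaccard index at least `min_jaccard` on genomic
#' coordinates. Precision is the fraction of predictions matching some
#' planted locus; recall the fraction of planted loci recovered. When
#' conservation profiles are supplied, the homolog-count error is the mean
#' absolute difference between each recovered locus's predicted total
#' homolog count and its true carrier count.
#'
#' @param truth Truth tibble from [simulate_dataset()].
#' @param segments Predicted candidate segments.
#' @param profiles Optional [count_homologs()] result.
#' @param min_jaccard Overlap threshold.
#' @return A one-row tibble: `precision`, `recall`, `homolog_count_error`,
#'   `n_truth`, `n_predictions`.
#' @export
evaluate_predictions <- function(truth, segments, profiles = NULL,
                                 min_jaccard = 0.8) {
  if (nrow(truth) == 0) {
    return(tibble(precision = if (nrow(segments) == 0) 1 else 0,
                  recall = 1, homolog_count_error = NA_real_,
                  n_truth = 0L, n_predictions = nrow(segments)))
  }
  bounds <- function(tss, lo, hi, strand) {
    tibble(lo = ifelse(strand == "+", tss, lo),
           hi = ifelse(strand == "+", hi, tss))
  }
  tb <- bounds(truth$tss_position, truth$hairpin_lo, truth$hairpin_hi,
               truth$strand)
  pb <- bounds(segments$tss_position, segments$hairpin_lo,
               segments$hairpin_hi, segments$strand)
  n_t <- nrow(truth); n_p <- nrow(segments)
  matched_t <- rep(FALSE, n_t)
  matched_p <- rep(FALSE, n_p)
  best_pred <- rep(NA_integer_, n_t)
  for (i in seq_len(n_t)) {
    same <- which(segments$replicon_id == truth$replicon_id[i] &
                    segments$strand == truth$strand[i])
    if (!length(same)) next
    inter <- pmax(0L, pmin(tb$hi[i], pb$hi[same]) -
                    pmax(tb$lo[i], pb$lo[same]) + 1L)
    uni <- (tb$hi[i] - tb$lo[i] + 1L) + (pb$hi[same] - pb$lo[same] + 1L) - inter
    jac <- inter / uni
    ok <- jac >= min_jaccard
    if (any(ok)) {
      matched_t[i] <- TRUE
      matched_p[same[ok]] <- TRUE
      best_pred[i] <- same[ok][which.max(jac[ok])]
    }
  }
  hom_err <- NA_real_
  if (!is.null(profiles) && any(matched_t)) {
    pt <- tidy_profiles(profiles)
    hom <- setNames(pt$homologs_total, pt$query_id)
    ids <- segments$id[best_pred[matched_t]]
    pred_h <- hom[ids]
    pred_h[is.na(pred_h)] <- 0L
    hom_err <- mean(abs(pred_h - truth$n_carriers[matched_t]))
  }
  tibble(precision = if (n_p == 0) 1 else sum(matched_p) / n_p,
         recall = if (n_t == 0) 1 else sum(matched_t) / n_t,
         homolog_count_error = hom_err,
         n_truth = n_t, n_predictions = n_p)
}
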