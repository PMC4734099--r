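## Internal helpers: conditions, strands, coordinates, sequences.

abort_format <- function(msg, ...) {
  abort(msg, class = c("srnaflow_format_error", "srnaflow_error"), ...)
}

abort_usage <- function(msg, ...) {
  abort(msg, class = c("srnaflow_usage_error", "srnaflow_error"), ...)
}

abort_consistency <- function(msg, ...) {
  abort(msg, class = c("srnaflow_consistency_error", "srnaflow_error"), ...)
}

#' Normalize strand labels
#'
#' Accepts `+`/`-` as well as the `f`/`r` suffix letters used in candidate
#' identifiers and returns `+`/`-`.
#'
#' @param x Character vector of strand labels (`+`, `-`, `f`, `r`).
#' @return Character vector over `{+,-}`.
#' @export
normalize_strand <- function(x) {
  out <- dplyr::case_match(as.character(x),
    c("+", "f", "F") ~ "+",
    c("-", "r", "R", "−") ~ "-",
    .default = NA_character_
  )
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    abort_format(sprintf("invalid strand label(s): %s", paste(bad, collapse = ", ")))
  }
  out
}

#' Build and parse candidate identifiers
#'
#' Candidates are identified by the 1-based TSS position followed by `f`
#' (forward) or `r` (reverse), e.g. `"4547237r"`. Identifiers are always
#' regenerated from coordinates; `parse_candidate_id()` is the single
#' explicit inverse.
#'
#' @param position Integer vector of 1-based TSS positions.
#' @param strand Character vector over `{+,-}`.
#' @return `candidate_id()`: character vector of ids. `parse_candidate_id()`:
#'   a tibble with columns `position` and `strand`.
#' @export
candidate_id <- function(position, strand) {
  paste0(position, ifelse(normalize_strand(strand) == "+", "f", "r"))
}

#' @param id Character vector of candidate ids.
#' @rdname candidate_id
#' @export
parse_candidate_id <- function(id) {
  ok <- grepl("^[0-9]+[fr]$", id)
  if (!all(ok)) {
    abort_format(sprintf("malformed candidate id(s): %s",
                         paste(unique(id[!ok]), collapse = ", ")))
  }
  tibble(
    position = as.integer(sub("[fr]$", "", id)),
    strand = ifelse(endsWith(id, "f"), "+", "-")
  )
}

## Reverse complement of plain character DNA (keeps N).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Uppercase and map everything outside {A,C,G,T,N} to N.
clean_dna <- function(x) {
  x <- toupper(x)
  gsub("[^ACGTN]", "N", x)
}

## Extract a transcript-oriented subsequence: [lo, hi] on + strand,
## reverse complement of [lo, hi] on - strand.
extract_transcript <- function(sequence, lo, hi, strand) {
  stopifnot(all(lo >= 1), all(hi <= nchar(sequence)), all(lo <= hi))
  s <- substr(rep(sequence, length.out = length(lo)), lo, hi)
  minus <- strand == "-"
  if (any(minus)) s[minus] <- revcomp(s[minus])
  unname(s)
}

## Deterministic uniform integer in [1, n] vectors via sample.int.
## (Plain wrappers so all randomness is easy to audit.)
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

## Substitution matrix over {A,C,G,T,N}: match on ACGT, everything else
## (including N-N) scores `mismatch`. N never matches.
dna_submat <- function(match = 1L, mismatch = -1L) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(b, b))
  diag(m)[1:4] <- match
  m
}

## End every written text file with a trailing newline.
write_lines_nl <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, sep = "\n")
  invisible(path)
}
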