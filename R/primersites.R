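# Primer binding-site location on both strands.
#
# Coordinates are 0-based half-open on the stored (plus) strand everywhere in
# this package; human-readable reports convert to 1-based inclusive.

#' Locate primer binding sites in a sequence
#'
#' Scans every window on both strands and reports those whose IUPAC
#' set-intersection mismatch count is at most `max_mismatch`.  For a
#' minus-strand hit the primer is matched against the reverse complement of
#' the window, and `three_prime_pos` is the plus-strand coordinate of the
#' template base paired with the primer's 3'-terminal base (`end - 1` for a
#' plus-strand hit, `start` for a minus-strand hit).
#'
#' @param seq template sequence (`degen_seq` or character).
#' @param primer primer sequence (`degen_seq` or character; IUPAC allowed).
#' @param max_mismatch maximum tolerated mismatch count (default 2).
#' @return data.frame with columns `seq_id`, `start`, `end`, `strand`
#'   (`"+"`/`"-"`), `mismatches`, `three_prime_pos`, sorted by
#'   (`start`, strand).  Zero rows when nothing is found or the primer is
#'   longer than the sequence.
#' @examples
#' find_primer_sites("TTTCCAGCAGCTGCGGTAATTCCAAA", "CCAGCASCYGCGGTAATTCC", 0)
#' @export
find_primer_sites <- function(seq, primer, max_mismatch = 2L) {
  mm_all <- .window_mismatches(seq, primer)
  L <- seq_length(primer)
  sid <- if (inherits(seq, "degen_seq")) seq$id else ""
  empty <- data.frame(
    seq_id = character(), start = integer(), end = integer(),
    strand = character(), mismatches = integer(),
    three_prime_pos = integer(), stringsAsFactors = FALSE
  )
  if (is.null(mm_all)) return(empty)
  hits <- list(empty)
  for (str in c("+", "-")) {
    mm <- mm_all[[str]]
    keep <- which(mm <= max_mismatch)
    if (length(keep) == 0L) next
    start <- keep - 1L
    hits[[length(hits) + 1L]] <- data.frame(
      seq_id = sid, start = start, end = start + L, strand = str,
      mismatches = mm[keep],
      three_prime_pos = if (str == "+") start + L - 1L else start,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Per-offset mismatch counts on both strands; NULL when primer longer than
# sequence.  Gap-free matching: gaps are stripped from the template first.
.window_mismatches <- function(seq, primer) {
  res <- gsub("-", "", residues(seq), fixed = TRUE)
  smask <- .iupac_mask(res)
  pmask <- .iupac_mask(primer)
  n <- length(smask)
  L <- length(pmask)
  if (L == 0L) stop("empty primer", call. = FALSE)
  if (L > n) return(NULL)
  rcmask <- .iupac_mask(reverse_complement(residues(primer)))
  n_win <- n - L + 1L
  mm_p <- integer(n_win)
  mm_m <- integer(n_win)
  for (i in seq_len(n_win)) {
    w <- smask[i:(i + L - 1L)]
    mm_p[i] <- sum(bitwAnd(w, pmask) == 0L)
    mm_m[i] <- sum(bitwAnd(w, rcmask) == 0L)
  }
  list(`+` = mm_p, `-` = mm_m)
}

#' Best primer site in a sequence regardless of threshold
#'
#' Returns the minimum-mismatch window over both strands (ties broken by
#' start, then plus strand first).  Used to report per-sequence best
#' mismatch counts when a design run finds no admissible site.
#'
#' @inheritParams find_primer_sites
#' @return one-row data.frame as in [find_primer_sites()], or zero rows when
#'   the primer is longer than the sequence.
#' @export
best_primer_site <- function(seq, primer) {
  mm_all <- .window_mismatches(seq, primer)
  if (is.null(mm_all)) {
    return(data.frame(
      seq_id = character(), start = integer(), end = integer(),
      strand = character(), mismatches = integer(),
      three_prime_pos = integer(), stringsAsFactors = FALSE
    ))
  }
  best <- min(mm_all[["+"]], mm_all[["-"]])
  out <- find_primer_sites(seq, primer, max_mismatch = best)
  out[1L, , drop = FALSE]
}
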