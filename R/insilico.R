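# In-silico PCR, nested PCR and clamp blocking prediction.

#' Predict amplicons for a primer pair on one template
#'
#' Every properly oriented pair of primer binding sites within `max_len`
#' yields a prediction; the amplicon span runs from the forward site start
#' through the reverse site end, primers included.  Both template
#' orientations are handled: a `"sense"` product has the forward primer on
#' the plus strand, an `"antisense"` product has it on the minus strand
#' (the template was stored reverse-complemented).
#'
#' @param seq template (`degen_seq` or character).
#' @param fwd,rev primer sequences (IUPAC allowed).
#' @param max_mismatch per-primer mismatch tolerance.
#' @param max_len maximum amplicon length (primers included).
#' @param trim_tail optional integer: match only the 3'-terminal
#'   `trim_tail` bases of each primer (for primers printed with sequencing
#'   adapter tails).
#' @return data.frame with one prediction per row: `seq_id`, `orientation`,
#'   forward/reverse site coordinates and mismatch counts, and the
#'   plus-strand `start`, `end`, `length` of the amplicon.
#' @export
insilico_pcr <- function(seq, fwd, rev, max_mismatch = 2L, max_len = 2000L,
                         trim_tail = NULL) {
  fwd <- .trim_primer(fwd, trim_tail)
  rev <- .trim_primer(rev, trim_tail)
  f_sites <- find_primer_sites(seq, fwd, max_mismatch)
  r_sites <- find_primer_sites(seq, rev, max_mismatch)
  sid <- if (inherits(seq, "degen_seq")) seq$id else ""
  rows <- list(.empty_amplicons())
  add <- function(fs, rs, orientation) {
    data.frame(
      seq_id = sid, orientation = orientation,
      fwd_start = fs$start, fwd_end = fs$end, fwd_strand = fs$strand,
      fwd_mismatches = fs$mismatches,
      rev_start = rs$start, rev_end = rs$end, rev_strand = rs$strand,
      rev_mismatches = rs$mismatches,
      start = min(fs$start, rs$start), end = max(fs$end, rs$end),
      length = max(fs$end, rs$end) - min(fs$start, rs$start),
      stringsAsFactors = FALSE
    )
  }
  for (i in seq_len(nrow(f_sites))) {
    fs <- f_sites[i, ]
    for (j in seq_len(nrow(r_sites))) {
      rs <- r_sites[j, ]
      if (fs$strand == "+" && rs$strand == "-" && rs$start >= fs$end &&
          rs$end - fs$start <= max_len) {
        rows[[length(rows) + 1L]] <- add(fs, rs, "sense")
      } else if (fs$strand == "-" && rs$strand == "+" &&
                 fs$start >= rs$end && fs$end - rs$start <= max_len) {
        rows[[length(rows) + 1L]] <- add(fs, rs, "antisense")
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_amplicons <- function() {
  data.frame(seq_id = character(), orientation = character(),
             fwd_start = integer(), fwd_end = integer(),
             fwd_strand = character(), fwd_mismatches = integer(),
             rev_start = integer(), rev_end = integer(),
             rev_strand = character(), rev_mismatches = integer(),
             start = integer(), end = integer(), length = integer(),
             stringsAsFactors = FALSE)
}

.trim_primer <- function(primer, trim_tail) {
  res <- residues(primer)
  if (is.null(trim_tail)) return(res)
  trim_tail <- as.integer(trim_tail)
  stopifnot(trim_tail >= 1L)
  if (trim_tail >= nchar(res)) return(res)
  substr(res, nchar(res) - trim_tail + 1L, nchar(res))
}

#' Predict nested PCR amplicons
#'
#' The outer pair is matched on the whole template; inner primers are then
#' matched only within first-round amplicon spans, so nesting can only
#' restrict the prediction set.  Reported coordinates refer to the inner
#' amplicon on the original template.
#'
#' @inheritParams insilico_pcr
#' @param outer_fwd,outer_rev,inner_fwd,inner_rev primer sequences.
#' @return data.frame as in [insilico_pcr()], with one extra column
#'   `outer_start` giving the enclosing first-round span start.
#' @export
nested_pcr <- function(seq, outer_fwd, outer_rev, inner_fwd, inner_rev,
                       max_mismatch = 2L, max_len = 2000L,
                       trim_tail = NULL) {
  outer <- insilico_pcr(seq, outer_fwd, outer_rev, max_mismatch, max_len)
  res <- residues(seq)
  sid <- if (inherits(seq, "degen_seq")) seq$id else ""
  rows <- list(cbind(.empty_amplicons(),
                     data.frame(outer_start = integer())))
  for (i in seq_len(nrow(outer))) {
    o <- outer[i, ]
    sub <- substr(res, o$start + 1L, o$end)
    inner <- insilico_pcr(degen_seq(sub, id = sid), inner_fwd, inner_rev,
                          max_mismatch, max_len, trim_tail = trim_tail)
    if (nrow(inner) == 0L) next
    for (cc in c("fwd_start", "fwd_end", "rev_start", "rev_end",
                 "start", "end")) {
      inner[[cc]] <- inner[[cc]] + o$start
    }
    inner$outer_start <- o$start
    rows[[length(rows) + 1L]] <- inner
  }
  out <- do.call(rbind, rows)
  out <- unique(out)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate amplicon predictions with clamp blocking
#'
#' A prediction is blocked when some window of the template inside the
#' amplicon span (both strands searched) matches the blocker with at most
#' `max_block_mismatch` incompatible positions.  `block_mismatches` records
#' the best window's count.  Blocking is evaluated irrespective of overlap
#' with a primer site (the arrest mechanism is not assumed).
#'
#' @param seq the template the predictions refer to.
#' @param predictions data.frame from [insilico_pcr()] / [nested_pcr()].
#' @param blocker clamp sequence (IUPAC allowed).
#' @param max_block_mismatch mismatch tolerance for blocking (default 1:
#'   a single mismatch to a 16-mer clamp is assumed still blocking).
#' @return `predictions` with logical `blocked` and integer
#'   `block_mismatches` columns appended.
#' @export
blocking_prediction <- function(seq, predictions, blocker,
                                max_block_mismatch = 1L) {
  res <- residues(seq)
  blocked <- logical(nrow(predictions))
  best <- integer(nrow(predictions))
  for (i in seq_len(nrow(predictions))) {
    p <- predictions[i, ]
    sub <- substr(res, p$start + 1L, p$end)
    mm <- .window_mismatches(sub, blocker)
    best[i] <- if (is.null(mm)) NA_integer_ else min(mm[["+"]], mm[["-"]])
    blocked[i] <- !is.na(best[i]) && best[i] <= max_block_mismatch
  }
  predictions$blocked <- blocked
  predictions$block_mismatches <- best
  predictions
}

#' Per-taxon amplification and blocking coverage of a community
#'
#' Partitions each taxon's sequences into `amplifiable` (at least one
#' predicted amplicon, none blocked), `blocked` (amplifiable but every
#' amplicon carries a blocker match at or under the threshold) and
#' `no_site` (no predicted amplicon).  Proportions sum to 1 per taxon.
#'
#' @param seqs list of [degen_seq] templates.
#' @param taxa character vector of taxon labels, one per template.
#' @param fwd,rev primer pair.
#' @param blocker optional clamp; `NULL` disables blocking.
#' @param max_mismatch,max_len,trim_tail as in [insilico_pcr()].
#' @param max_block_mismatch as in [blocking_prediction()].
#' @return data.frame with one row per taxon: counts and proportions of the
#'   three classes.
#' @export
community_coverage <- function(seqs, taxa, fwd, rev, blocker = NULL,
                               max_mismatch = 2L, max_len = 2000L,
                               max_block_mismatch = 1L, trim_tail = NULL) {
  stopifnot(length(seqs) == length(taxa), length(taxa) > 0L)
  class_of <- character(length(seqs))
  for (i in seq_along(seqs)) {
    pred <- insilico_pcr(seqs[[i]], fwd, rev, max_mismatch, max_len,
                         trim_tail = trim_tail)
    if (nrow(pred) == 0L) {
      class_of[i] <- "no_site"
    } else if (is.null(blocker)) {
      class_of[i] <- "amplifiable"
    } else {
      pred <- blocking_prediction(seqs[[i]], pred, blocker,
                                  max_block_mismatch)
      class_of[i] <- if (all(pred$blocked)) "blocked" else "amplifiable"
    }
  }
  taxa <- as.character(taxa)
  lv <- sort(unique(taxa))
  out <- do.call(rbind, lapply(lv, function(tx) {
    cls <- class_of[taxa == tx]
    n <- length(cls)
    data.frame(taxon = tx, n = n,
               amplifiable = sum(cls == "amplifiable"),
               blocked = sum(cls == "blocked"),
               no_site = sum(cls == "no_site"),
               p_amplifiable = sum(cls == "amplifiable") / n,
               p_blocked = sum(cls == "blocked") / n,
               p_no_site = sum(cls == "no_site") / n,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
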