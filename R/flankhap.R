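# Primer-flank extraction, haplotype collapsing and conservation profiling.
#
# These three operations replace a median-joining network step: the design
# pipeline only needs (a) how many distinct flanking haplotypes the host
# family carries and (b) which columns are conserved, which collapsing and
# per-column profiling deliver directly.

#' Extract the region flanking a primer binding site
#'
#' Returns the `flank_len` residues adjacent to the site on the requested
#' side, reported 5'-to-3' on the primer's strand.  `side = "outside"` is the
#' region beyond the primer's 3' end (the extension direction);
#' `side = "inside"` is the region behind the primer's 5' end.  When the
#' requested region runs off the end of the sequence it is truncated, a
#' warning is raised and the result carries `attr(x, "partial") = TRUE`.
#'
#' @param seq template sequence (`degen_seq` or character, plus strand).
#' @param site one-row data.frame (or list) with `start`, `end`, `strand`
#'   as produced by [find_primer_sites()].
#' @param flank_len number of residues to extract.
#' @param side `"outside"` (3' side) or `"inside"` (5' side).
#' @return [degen_seq] on the primer's strand, with attribute `partial`.
#' @export
extract_flank <- function(seq, site, flank_len,
                          side = c("outside", "inside")) {
  side <- match.arg(side)
  stopifnot(flank_len >= 0L)
  res <- residues(seq)
  n <- nchar(res)
  start <- as.integer(site$start)
  end <- as.integer(site$end)
  strand <- as.character(site$strand)
  # plus-strand half-open interval of the requested flank
  if (strand == "+") {
    iv <- if (side == "outside") c(end, end + flank_len)
          else c(start - flank_len, start)
  } else {
    iv <- if (side == "outside") c(start - flank_len, start)
          else c(end, end + flank_len)
  }
  clipped <- c(max(iv[1L], 0L), min(iv[2L], n))
  partial <- !identical(iv, clipped)
  if (partial) {
    warning(sprintf(
      "flank [%d,%d) truncated to [%d,%d) on a %d-nt sequence",
      iv[1L], iv[2L], clipped[1L], clipped[2L], n), call. = FALSE)
  }
  s <- if (clipped[2L] > clipped[1L]) {
    substr(res, clipped[1L] + 1L, clipped[2L])
  } else ""
  if (strand == "-") s <- reverse_complement(s)
  sid <- if (inherits(seq, "degen_seq")) seq$id else ""
  out <- if (nzchar(s)) degen_seq(s, id = sid) else {
    structure(list(residues = "", id = sid, is_aligned = FALSE),
              class = "degen_seq")
  }
  attr(out, "partial") <- partial
  out
}

#' Collapse equal-length flanking sequences into haplotypes
#'
#' @param flanks list of `degen_seq` (or character vector), all equal length.
#' @param group label for the source group (e.g. `"ixodid"`).
#' @return object of class `haplotype_summary`: list with `haplotypes`
#'   (named integer counts, ordered by descending count then
#'   lexicographically), `n_sequences`, `n_haplotypes`, `source_group`.
#' @examples
#' collapse_haplotypes(c("AAT", "AAT", "ATT"), group = "demo")
#' @export
collapse_haplotypes <- function(flanks, group = "") {
  strings <- if (is.character(flanks)) flanks
             else vapply(flanks, residues, character(1L))
  if (length(strings) == 0L) {
    return(structure(list(haplotypes = integer(0), n_sequences = 0L,
                          n_haplotypes = 0L, source_group = group),
                     class = "haplotype_summary"))
  }
  if (length(unique(nchar(strings))) != 1L) {
    stop("flanking sequences must all have equal length", call. = FALSE)
  }
  tab <- table(strings)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  ord <- order(-counts, names(counts))
  counts <- counts[ord]
  structure(
    list(haplotypes = counts, n_sequences = length(strings),
         n_haplotypes = length(counts), source_group = group),
    class = "haplotype_summary"
  )
}

#' @export
print.haplotype_summary <- function(x, ...) {
  cat(sprintf("<haplotype_summary> group '%s': %d sequence(s), %d haplotype(s)\n",
              x$source_group, x$n_sequences, x$n_haplotypes))
  for (i in seq_along(x$haplotypes)) {
    cat(sprintf("  %s  n=%d\n", names(x$haplotypes)[i], x$haplotypes[i]))
  }
  invisible(x)
}

#' Per-column conservation profile and degenerate consensus
#'
#' For each alignment column, records the union of observed bases and emits
#' the minimal IUPAC code covering it.  Degenerate input codes contribute
#' their whole expansion set.  Columns where any sequence carries `N` (or a
#' gap) are wildcard-flagged: the union is taken over the remaining
#' informative residues and the column is excluded from polymorphism
#' counting, but downstream design treats such columns as unverifiable.
#'
#' @param flanks list of `degen_seq` (or character vector), equal lengths.
#' @return object of class `conservation_profile`: list with
#'   `column_masks` (integer base-set masks), `wildcard` (logical per
#'   column), `consensus` ([degen_seq]), `degeneracy` (count of
#'   non-concrete, non-wildcard columns) and `n_sequences`.
#' @examples
#' conservation_profile(c("AA", "AT"))  # consensus "AW", degeneracy 1
#' @export
conservation_profile <- function(flanks) {
  strings <- if (is.character(flanks)) flanks
             else vapply(flanks, residues, character(1L))
  if (length(strings) == 0L) {
    stop("conservation_profile requires at least one sequence", call. = FALSE)
  }
  if (length(unique(nchar(strings))) != 1L) {
    stop("sequences must all have equal length", call. = FALSE)
  }
  L <- nchar(strings[[1L]])
  mat <- do.call(rbind, lapply(strings, function(s) {
    .iupac_mask(s, allow_gap = TRUE)
  }))
  chmat <- do.call(rbind, lapply(strings, function(s) {
    .iupac_chars(s, allow_gap = TRUE)
  }))
  column_masks <- integer(L)
  wildcard <- logical(L)
  for (j in seq_len(L)) {
    col_ch <- chmat[, j]
    wild <- col_ch == "N" | col_ch == "-"
    wildcard[j] <- any(wild)
    informative <- mat[!wild, j]
    column_masks[j] <- if (length(informative) > 0L) {
      Reduce(bitwOr, informative)
    } else 15L  # all-N column: no information, full ambiguity
  }
  consensus <- paste(.mask_to_code(column_masks), collapse = "")
  degeneracy <- sum(!.mask_to_code(column_masks) %in% .CONCRETE & !wildcard)
  structure(
    list(column_masks = column_masks, wildcard = wildcard,
         consensus = degen_seq(consensus, id = "consensus"),
         degeneracy = degeneracy, n_sequences = length(strings)),
    class = "conservation_profile"
  )
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf(
    "<conservation_profile> %d column(s), %d sequence(s)\n  consensus: %s\n  degeneracy: %d%s\n",
    length(x$column_masks), x$n_sequences, residues(x$consensus),
    x$degeneracy,
    if (any(x$wildcard)) sprintf("  (wildcard columns: %s)",
                                 paste(which(x$wildcard), collapse = ","))
    else ""))
  invisible(x)
}

#' Write a haplotype report as TSV
#'
#' Columns: `group`, `haplotype`, `count`, `frequency`.
#'
#' @param summaries a `haplotype_summary` or list of them.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_haplotype_report <- function(summaries, path) {
  if (inherits(summaries, "haplotype_summary")) summaries <- list(summaries)
  rows <- do.call(rbind, lapply(summaries, function(s) {
    if (s$n_sequences == 0L) return(NULL)
    data.frame(group = s$source_group, haplotype = names(s$haplotypes),
               count = unname(s$haplotypes),
               frequency = unname(s$haplotypes) / s$n_sequences,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
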