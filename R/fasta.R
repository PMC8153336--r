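# FASTA input/output, plain and aligned, via Biostrings.

#' Read a FASTA file into a list of degenerate sequences
#'
#' Residues are upper-cased on input.  When `aligned = TRUE` all records must
#' have equal length and may contain the gap character `-`.
#'
#' @param path path to a FASTA file.
#' @param aligned logical; input is a pre-computed multiple alignment.
#' @return list of [degen_seq] objects (possibly empty).
#' @export
read_fasta <- function(path, aligned = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("FASTA file not found: '%s'", path), call. = FALSE)
  }
  if (file.size(path) == 0L) return(list())
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) {
      stop(sprintf("malformed FASTA '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  strings <- toupper(as.character(set))
  ids <- names(set)
  if (is.null(ids)) ids <- rep("", length(strings))
  if (aligned && length(strings) > 1L) {
    w <- nchar(strings)
    if (length(unique(w)) != 1L) {
      off <- ids[w != w[1L]][1L]
      stop(sprintf(
        "aligned FASTA '%s' has unequal record lengths (first offender: '%s')",
        path, off), call. = FALSE)
    }
  }
  out <- vector("list", length(strings))
  for (i in seq_along(strings)) {
    res <- strings[[i]]
    if (!aligned) res <- gsub("-", "", res, fixed = TRUE)
    out[[i]] <- tryCatch(
      degen_seq(res, id = ids[[i]], is_aligned = aligned),
      error = function(e) {
        stop(sprintf("record '%s' in '%s': %s", ids[[i]], path,
                     conditionMessage(e)), call. = FALSE)
      }
    )
  }
  out
}

#' Write degenerate sequences to a FASTA file
#'
#' @param seqs list of [degen_seq] (or character vector, optionally named).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) {
    ids <- names(seqs)
    if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
    strings <- unname(seqs)
  } else {
    strings <- vapply(seqs, residues, character(1L))
    ids <- vapply(seqs, function(s) {
      if (inherits(s, "degen_seq") && nzchar(s$id)) s$id else ""
    }, character(1L))
    ids[!nzchar(ids)] <- paste0("seq", which(!nzchar(ids)))
  }
  set <- Biostrings::DNAStringSet(strings)
  names(set) <- ids
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}
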