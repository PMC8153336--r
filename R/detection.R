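# Detection grids: per-sample x per-method sets of detected taxon codes.

#' Code book for apicomplexan genus detection grids
#'
#' @return named character vector mapping code to taxon name.
#' @export
apicomplexa_code_book <- function() {
  c(G = "Gregarina (order Eugregarinorida)",
    A = "Amoebogregarina (order Eugregarinorida)",
    Cr = "Cryptosporidium (order Eucoccidiorida)",
    T = "Theileria (order Piroplasmida)",
    N = "unclassified (phylum) Apicomplexa",
    EU = "unclassified order Eugregarinorida",
    Co = "unclassified family Colpodellidae (order Colpodellida)")
}

#' Path to the bundled apicomplexan detection grid
#'
#' A per-tick-sample, per-PCR-method grid of detected apicomplexan genus
#' codes from a 17-tick blocking-assay sequencing comparison; cells hold
#' comma-separated codes from [apicomplexa_code_book()] or `-` for none.
#'
#' @return file path of the TSV.
#' @export
apicomplexa_detection_file <- function() {
  system.file("extdata", "apicomplexa_detection_grid.tsv",
              package = "clampdesign", mustWork = TRUE)
}

#' Read a detection grid TSV
#'
#' First column identifies the sample; remaining columns are methods whose
#' cells hold comma-separated detection codes (or `-`/empty for none).
#'
#' @param path TSV file path.
#' @param code_book named vector of admissible codes (names are the codes).
#' @return object of class `detection_table`: list with `samples`,
#'   `methods` and `codes` (list-matrix of character vectors), plus the
#'   code book.
#' @export
read_detection_grid <- function(path, code_book = apicomplexa_code_book()) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          comment.char = "#")
  samples <- df[[1L]]
  methods <- names(df)[-1L]
  codes <- vector("list", nrow(df) * length(methods))
  dim(codes) <- c(nrow(df), length(methods))
  dimnames(codes) <- list(samples, methods)
  for (i in seq_len(nrow(df))) {
    for (j in seq_along(methods)) {
      cell <- trimws(df[i, j + 1L])
      entry <- if (cell == "" || cell == "-") character() else {
        trimws(strsplit(cell, ",", fixed = TRUE)[[1L]])
      }
      bad <- setdiff(entry, names(code_book))
      if (length(bad) > 0L) {
        stop(sprintf("unknown detection code(s) %s in sample '%s', method '%s'",
                     paste(sQuote(bad), collapse = ", "), samples[i],
                     methods[j]), call. = FALSE)
      }
      codes[[i, j]] <- entry
    }
  }
  structure(list(samples = samples, methods = methods, codes = codes,
                 code_book = code_book),
            class = "detection_table")
}

#' @export
print.detection_table <- function(x, ...) {
  cat(sprintf("<detection_table> %d sample(s) x %d method(s), %d code(s)\n",
              length(x$samples), length(x$methods), length(x$code_book)))
  invisible(x)
}

#' Per-code count of samples with at least one detection
#'
#' For each code in the code book, counts the distinct samples in which the
#' code appears in at least one method column.  Invariant under permutation
#' of the method columns.
#'
#' @param dt a `detection_table` from [read_detection_grid()].
#' @return named integer vector over all codes of the code book.
#' @export
detection_summary <- function(dt) {
  codes <- names(dt$code_book)
  out <- stats::setNames(integer(length(codes)), codes)
  for (cd in codes) {
    hit <- vapply(seq_along(dt$samples), function(i) {
      any(vapply(seq_along(dt$methods), function(j) {
        cd %in% dt$codes[[i, j]]
      }, logical(1L)))
    }, logical(1L))
    out[[cd]] <- sum(hit)
  }
  out
}
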