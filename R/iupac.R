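# IUPAC degenerate-base arithmetic.
#
# Every code is represented internally as a 4-bit mask over {A, C, G, T}
# (A = 1, C = 2, G = 4, T = 8).  Two codes are compatible iff their masks
# intersect; complementation reverses the bit order.  The gap character "-"
# carries the empty mask and is incompatible with everything by default.

.IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
  V = 7L, H = 11L, D = 13L, B = 14L, N = 15L,
  `-` = 0L
)

.MASK_TO_CODE <- local({
  out <- character(16L)
  out[.IUPAC_MASK + 1L] <- names(.IUPAC_MASK)
  out
})

.IUPAC_COMP <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N",
  `-` = "-"
)

.CONCRETE <- c("A", "C", "G", "T")

#' Split a sequence into validated IUPAC residues
#'
#' @param x character scalar (or `degen_seq`) to split.
#' @param allow_gap logical; permit the alignment gap character `-`.
#' @return character vector of single residues, upper-cased.
#' @keywords internal
#' @noRd
.iupac_chars <- function(x, allow_gap = FALSE) {
  x <- residues(x)
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  ok <- names(.IUPAC_MASK)
  if (!allow_gap) ok <- setdiff(ok, "-")
  bad <- setdiff(unique(chars), ok)
  if (length(bad) > 0L) {
    stop("non-IUPAC residue(s): ", paste(sQuote(bad), collapse = ", "),
         call. = FALSE)
  }
  chars
}

.iupac_mask <- function(x, allow_gap = FALSE) {
  unname(.IUPAC_MASK[.iupac_chars(x, allow_gap = allow_gap)])
}

#' Degenerate DNA sequence
#'
#' A light container for an IUPAC DNA string with an identifier and an
#' alignment flag.  The gap character `-` is permitted only when
#' `is_aligned = TRUE`.  Most operations in the package also accept a bare
#' character scalar wherever a `degen_seq` is expected.
#'
#' @param residues character scalar over the IUPAC DNA alphabet
#'   (`A C G T R Y S W K M B D H V N`, plus `-` when aligned).
#' @param id free-text identifier.
#' @param is_aligned logical; whether the record is a column-aligned slice.
#' @return An object of class `degen_seq`.
#' @examples
#' s <- degen_seq("GATCAAWGAAAACATT", id = "TickB")
#' reverse_complement(s)
#' @export
degen_seq <- function(residues, id = "", is_aligned = FALSE) {
  stopifnot(is.character(residues), length(residues) == 1L, !is.na(residues))
  chars <- .iupac_chars(residues, allow_gap = is_aligned)
  structure(
    list(residues = paste(chars, collapse = ""), id = as.character(id),
         is_aligned = isTRUE(is_aligned)),
    class = "degen_seq"
  )
}

#' Extract the residue string of a sequence
#'
#' @param x a `degen_seq` or character scalar.
#' @return character scalar of residues.
#' @export
residues <- function(x) {
  if (inherits(x, "degen_seq")) x$residues else as.character(x)
}

#' @export
print.degen_seq <- function(x, ...) {
  cat(sprintf("<degen_seq> %s%s (%d nt)\n",
              if (nzchar(x$id)) paste0(x$id, ": ") else "",
              x$residues, nchar(x$residues)))
  invisible(x)
}

#' @export
as.character.degen_seq <- function(x, ...) x$residues

#' Sequence length in residues
#'
#' @param x a `degen_seq` or character scalar.
#' @return integer length.
#' @export
seq_length <- function(x) nchar(residues(x))

#' Reverse complement of an IUPAC string
#'
#' Degenerate codes are complemented set-wise (R to Y, S to S, W to W,
#' K to M, B to V, D to H, N to N); applying the operation twice returns the
#' identical residue string.
#'
#' @param x a `degen_seq` or character scalar.
#' @return object of the same type as the input.
#' @examples
#' reverse_complement("ACTTTCGTTCTTGATYRA")
#' @export
reverse_complement <- function(x) {
  chars <- .iupac_chars(x, allow_gap = inherits(x, "degen_seq") && x$is_aligned)
  rc <- paste(rev(unname(.IUPAC_COMP[chars])), collapse = "")
  if (inherits(x, "degen_seq")) {
    degen_seq(rc, id = x$id, is_aligned = x$is_aligned)
  } else {
    rc
  }
}

#' Are two IUPAC residues compatible?
#'
#' Compatibility is set intersection of the codes' expansions: `W` and `A`
#' are compatible because W = \{A, T\}; `W` and `G` are not.  The relation is
#' symmetric.  Gaps are incompatible with everything (including other gaps)
#' unless `gap_compatible = TRUE`.
#'
#' @param a,b single IUPAC residues (vectorized elementwise).
#' @param gap_compatible logical; treat `-` vs `-` and `-` vs base as a match.
#' @return logical vector.
#' @export
iupac_compatible <- function(a, b, gap_compatible = FALSE) {
  ma <- .iupac_mask(paste(a, collapse = ""), allow_gap = TRUE)
  mb <- .iupac_mask(paste(b, collapse = ""), allow_gap = TRUE)
  if (length(ma) != length(mb)) {
    stop("residue vectors differ in length", call. = FALSE)
  }
  out <- bitwAnd(ma, mb) > 0L
  if (gap_compatible) out[ma == 0L | mb == 0L] <- TRUE
  out
}

#' Count incompatible positions between two equal-length sequences
#'
#' Positions are mismatches when the two codes' expansion sets are disjoint,
#' so a degenerate consensus position (e.g. `W`) matches either allele it
#' covers.
#'
#' @param query,window sequences of equal length (`degen_seq` or character).
#' @return non-negative integer count of incompatible positions.
#' @examples
#' count_mismatches("GATCAAWGAAAACATT", "GATCAATGAAAACATT") # 0
#' count_mismatches("GATCAAWGAAAACATT", "GATCAACGAAAACATT") # 1
#' @export
count_mismatches <- function(query, window) {
  mq <- .iupac_mask(query, allow_gap = TRUE)
  mw <- .iupac_mask(window, allow_gap = TRUE)
  if (length(mq) != length(mw)) {
    stop(sprintf("length mismatch: query %d vs window %d",
                 length(mq), length(mw)), call. = FALSE)
  }
  sum(bitwAnd(mq, mw) == 0L)
}

#' Expand a degenerate sequence into its concrete variants
#'
#' @param x a `degen_seq` or character scalar (no gaps).
#' @param max_expansions cap on the number of concrete variants.
#' @return character vector of concrete ACGT strings.
#' @export
expand_degenerate <- function(x, max_expansions = 64L) {
  chars <- .iupac_chars(x)
  sets <- lapply(chars, function(ch) {
    m <- .IUPAC_MASK[[ch]]
    .CONCRETE[bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L]
  })
  n_exp <- prod(lengths(sets))
  if (n_exp > max_expansions) {
    stop(sprintf("degenerate expansion of %d variants exceeds cap %d",
                 n_exp, max_expansions), call. = FALSE)
  }
  if (length(sets) == 0L) return("")
  grid <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
  apply(grid[, rev(seq_along(sets)), drop = FALSE], 1L, paste, collapse = "")
}

#' Number of non-concrete positions in a sequence
#'
#' @param x a `degen_seq` or character scalar.
#' @return integer count of positions whose code is not one of A, C, G, T.
#' @export
degeneracy_count <- function(x) {
  sum(!.iupac_chars(x, allow_gap = TRUE) %in% .CONCRETE)
}

#' Pyrimidine fraction of a concrete sequence
#'
#' @param x concrete ACGT sequence.
#' @return fraction of residues that are C or T.
#' @export
pyrimidine_fraction <- function(x) {
  chars <- .iupac_chars(x)
  bad <- setdiff(unique(chars), .CONCRETE)
  if (length(bad) > 0L) {
    stop("pyrimidine_fraction requires a concrete sequence; expand first",
         call. = FALSE)
  }
  mean(chars %in% c("C", "T"))
}

# Minimal IUPAC code covering a bitmask union of observed bases.
.mask_to_code <- function(mask) .MASK_TO_CODE[mask + 1L]
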