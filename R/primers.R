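# Standard oligo sets used throughout 18S rDNA V4 eukaryote metabarcoding
# and non-metazoan nested PCR, plus the tick 18S clamp they gave rise to.

#' Universal 18S V4 eukaryote primer pair (TAReuk)
#'
#' @return named list with `fwd` (TAReuk454FWD1, `CCAGCASCYGCGGTAATTCC`)
#'   and `rev` (TAReukREV3, `ACTTTCGTTCTTGATYRA`).
#' @export
tareuk_primers <- function() {
  list(fwd = "CCAGCASCYGCGGTAATTCC", rev = "ACTTTCGTTCTTGATYRA")
}

#' Non-metazoan nested 18S primer scheme (UNonMet)
#'
#' The inner pair is printed with sequencing adapter tails; pass
#' `trim_tail` to [insilico_pcr()] to match only genomic 3' bases.
#'
#' @return named list with `outer_fwd` (EUK581F), `outer_rev` (EUK1134R),
#'   `inner_fwd` (E572F, with adapter tail) and `inner_rev` (E1009R, with
#'   adapter tail).  EUK572F/18S-EUK1009R in some protocol write-ups refer
#'   to the same oligos as E572F/E1009R.
#' @export
unonmet_primers <- function() {
  list(outer_fwd = "GTGCCAGCAGCCGCG",
       outer_rev = "TTTAAGTTTCAGCCTTGCG",
       inner_fwd = "CCATCTCATCCCTGCGTGTCTCCGACTCAG",
       inner_rev = "CCTATCCCCTGTGTGCCTTGGCAGTCTCAG")
}

#' Tick 18S rDNA blocker (TickB) clamp sequence
#'
#' The 16-mer clamp placed across the TAReukREV3 3' end; the `W` absorbs an
#' A/T polymorphism among tick sequences.
#'
#' @return character scalar `GATCAAWGAAAACATT`.
#' @export
tickb_blocker <- function() "GATCAAWGAAAACATT"
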