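# Shared template builders for tests.

# Assemble a plus-strand template with planted forward site and a
# reverse-primer-strand region (primer instance + downstream extension).
build_template <- function(left, fwd, interior, rev_region, right) {
  paste0(left, fwd, interior, reverse_complement(rev_region), right)
}

# The synthetic fixture primers, re-stated here so tests do not reach into
# package internals.
FIX_FWD <- "CCAGCAGCTGCGGTAATTCC"
FIX_REV <- "ACTCAGCGAGGAGGGAGG"
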