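---
title: "Designing host-blocking clamps and evaluating host depletion"
author: "clampdesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing host-blocking clamps and evaluating host depletion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clampdesign)
```

## The problem

Amplicon surveys of eukaryotic microbiomes in host-derived samples are
routinely swamped by the host's own 18S rDNA: in an arthropod such as a
tick, the host gene vastly outnumbers the 18S copies of the protists,
fungi and other microeukaryotes of interest, so universal-primer PCR
returns libraries that are almost entirely host reads.  One remedy is a
*blocker* (clamp) oligonucleotide — an unextendable artificial nucleic
acid such as a peptide nucleic acid (PNA) or locked nucleic acid (LNA) —
that hybridizes to a host-specific segment near a universal primer's 3'
end and suppresses amplification of the host template while sparing
everything else.

`clampdesign` implements the computational side of that strategy:
selecting the clamp site, screening candidates thermodynamically,
predicting in silico which community members a primer/clamp scheme
amplifies or blocks, and computing the statistics used to judge a
host-depletion experiment afterwards.

## The selection procedure

Candidate clamp windows are enumerated around the 3' end of a universal
primer (for 18S V4 work, typically the reverse primer) and screened under
four criteria:

1. **Host identity.** The window's degenerate consensus must match every
   host sequence with zero mismatches.  Host polymorphism is absorbed
   into IUPAC degeneracy (an A/T column becomes `W`) up to
   `max_degeneracy` positions (default 2), rather than disqualifying the
   window outright — a clamp synthesized with a degenerate position
   hybridizes to either allele.  Windows overlapping a *wildcard* column
   (any host carrying `N` or a gap there) fail this criterion: identity
   cannot be verified at such a column and the consensus there is not
   meaningfully synthesizable.
2. **Exclusion mismatches.** The minimum mismatch count over the
   *exclusion set* — the sequences the clamp must spare, e.g.
   apicomplexan parasites amplified by the same universal primers — must
   reach `min_exclusion_mismatch` (default 3).  The minimum, not the
   mean: the clamp has to spare the hardest-to-distinguish target.
3. **Melting temperature.** The configured Tm estimate of the consensus
   must reach `tm_min` (default 70 °C).
4. **Self-complementarity.** The maximum antiparallel self-pairing score
   (default cap 8) and the longest hairpin stem with a loop of at least
   three residues (default cap 4) must stay below their caps.  The
   thresholds are configurable because "low self-complementarity" has no
   universal number; the defaults reject candidates that could dimerize
   or fold at the clamp's working concentration.

All four flags are recorded for every window, including failing ones, so
a report always explains *why* a window was rejected.

### Coordinates and offsets

Clamp windows live on the primer's strand and are anchored at the
primer's 3'-terminal base (relative coordinate r = 0).  A window of
length L placed with `offset_downstream = d` covers r in [d − L, d − 1]:
`offset_upstream = L − d` counts the bases strictly 5' of the 3'-end
position, and the 3'-end base itself belongs to the downstream count, so
the two offsets always sum to the window length.  The classical prose
idiom ("11 bp upstream and 6 bp downstream of the primer's 3' end" for a
16-mer) counts the 3'-terminal base on both sides and therefore sums to
L + 1; reports emit both forms, and machine-readable output always uses
the exact convention.  Internally all template coordinates are 0-based
half-open on the plus strand with strand recorded explicitly;
human-readable TSV output converts to 1-based inclusive and says so in a
`coord_system` header line.

The profiled search region defaults to 27 bases upstream through 6 bases
downstream of the 3'-end base.  Window lengths default to 14–18 and
downstream offsets to 0–10; windows are only enumerated where they fit
inside the profiled region, so under the defaults the effective
downstream offset range is 0–6.  Widen `flank_downstream` to use the full
offset range.

## Thermodynamic models

No single published model covers DNA, PNA and LNA clamps at once, so the
package composes three citable pieces, all user-overridable through
`thermo_params()`:

* **DNA/DNA duplex Tm** uses the unified nearest-neighbor parameter set
  (ΔH in kcal/mol and ΔS in cal/mol/K per stacked dimer, plus per-terminus
  initiation and a symmetry term), the duplex equation
  Tm = ΔH / (ΔS + R ln(C_T/x)) − 273.15, and the entropic salt correction
  ΔS += 0.368 (n − 1) ln[Na⁺].  Defaults: 50 mmol/L monovalent salt and a
  total oligo concentration of 2 µmol/L, the concentration of a 50 pmol
  clamp dose in a 25 µL PCR.
* **PNA/DNA Tm** uses the published linear regression on the
  nearest-neighbor DNA Tm, the pyrimidine fraction of the clamp strand
  and the length:
  Tm(PNA) = 20.79 + 0.83 · Tm(DNA) − 26.13 · f_pyr + 0.44 · L.
* **LNA substitutions** add a per-position increment to the DNA Tm
  (default 4 °C per substituted base, the midpoint of the commonly
  reported 2–8 °C span, configurable per base).

Degenerate consensus sequences are expanded into their concrete variants
and aggregated under a policy; the default `min` is the conservative
bound, so a degenerate clamp passes the Tm criterion only if *every*
variant does.

The design step thresholds the PNA estimate by default (`tm_metric`
in `design_config()`), since the clamp chemistry of record here is a
PNA, and the report names the thresholded estimate.  One consequence of
choosing the conservative regression deserves emphasis: AT-rich natural
clamp sites score well below vendor PNA calculators.  The 16-mer tick
clamp `GATCAAWGAAAACATT` evaluates to roughly 61 °C here, below the
70 °C default that vendor tools would report it as clearing.  Users
reproducing a historical design against an AT-rich site should either
lower `tm_min` or threshold the LNA estimate; the packaged default keeps
the conservative bound and says so in its reports.

## In-silico amplification and blocking

`insilico_pcr()` pairs every properly oriented forward/reverse binding
site within a length cap, in both template orientations.  `nested_pcr()`
matches inner primers only within first-round amplicon spans, so nesting
can only restrict predictions.  Primers printed with sequencing adapter
tails (30-mers) will not match natural templates; `trim_tail` matches
only the 3'-terminal bases, and the command-line tool warns when a primer
exceeds 25 nt.

`blocking_prediction()` marks an amplicon blocked when any window inside
it (either strand) matches the clamp with at most `max_block_mismatch`
incompatible positions.  The default tolerance is 1: the experimental
contrast that motivates the model is between a perfect clamp match
(blocked) and a 3-mismatch relative (amplified), so a single mismatch to
a 16-mer clamp is assumed still blocking and two or more not.  Blocking
is evaluated regardless of whether the clamp overlaps a primer site — no
assumption is made about elongation-arrest versus competitive-annealing
mechanisms, because the positional requirement differs between
chemistries and is rarely known.

## Downstream statistics

Given a sample × taxon count table with per-sample method labels and a
control (no-clamp) library for every host individual:

* the **non-host read proportion** of a sample is the fraction of reads
  whose lineage does not start with the host-lineage prefix;
* the **enrichment value** of a method for one individual divides the
  method's non-host proportion by the matched control's.  When the
  control contains only host reads the ratio is undefined; the sample is
  flagged and excluded from summaries rather than propagated as an
  infinity;
* **pairwise proportion tests** compare methods by the 2×2 chi-square
  test of equal proportions with Yates continuity correction and
  Bonferroni adjustment (min(1, m·p) over the m evaluable pairs).  Reads
  are pooled within method for the test; whether pooling or per-sample
  testing is the right aggregation is genuinely open, so
  `nontick_read_counts()` exposes both aggregations, labelled, and the
  per-sample route feeds mixed-model analyses outside this package's
  scope;
* **alpha diversity** is Shannon entropy (natural log — the base is a
  convention and is stated here), observed variant counts, and Faith's
  phylogenetic diversity.  Faith's PD uses the rooted convention by
  default (the path from the spanning subtree to the root is included,
  `include_root = TRUE`); basal polytomies are resolved with zero-length
  edges before computation, which leaves every branch-length sum
  unchanged;
* **relative intensity** normalizes dose–response fluorescence
  measurements within each replicate trial to that trial's no-clamp
  control (control = 1.0 by construction), then summarises across
  trials;
* **top-taxa rankings** exclude lineages by an explicit prefix list
  (e.g. the host lineage and an `unclassified` lineage), never by string
  heuristics, and break abundance ties lexicographically so output is
  reproducible.

## The synthetic-data generator

Every pipeline stage is testable without downloads because
`fixture_spec()` plants ground truth:

* `make_host_family()` builds a host family sharing one random backbone
  (uniform base composition, hence 50% GC) with exact forward and reverse
  primer sites, exactly one polymorphic A/T column downstream of the
  reverse primer's 3' end partitioning the family into two haplotypes
  (4 + 2 of 6 by default), and one host carrying a planted `N` just
  upstream of the clamp window — the kind of ambiguity real archive
  records contain, and the reason criterion 1 refuses wildcard columns.
* `make_exclusion_seq()` is the same backbone with substitutions at
  exactly three planted coordinates spanning the clamp window (two of
  them inside the primer footprint, where real parasite relatives also
  diverge slightly; the site stays locatable at ≤ 2 primer mismatches).
* The planted clamp site itself is **synthetic and GC-balanced** (the
  clamp strand is purine-rich, ~60% GC).  This is deliberate: under the
  conservative PNA regression an AT-rich natural site cannot clear the
  70 °C default, so a generator that "planted" such a site would plant an
  inadmissible design.  The synthetic site exercises all four criteria at
  their defaults; the trade-off is that the fixture's thermodynamics are
  friendlier than the tick V4 site's.
* `make_count_table()` generates one sample per individual per method
  (six methods, 17 individuals, 100 000 reads per sample by default) with
  per-method target non-host proportions of 0.03%, 3.24%, 5.75%, 1.53%,
  3.18% and 1.37% for the control, PNA and LNA clamps under two
  purification regimes, and nested non-metazoan PCR respectively —
  the medians reported for the experiment this generator emulates.  A
  lognormal per-individual effect (sdlog 0.6) scales all of an
  individual's methods jointly, so each sample's planted enrichment is
  exactly the ratio of method proportions.  Published per-sample
  enrichment medians are *not* simultaneously plantable with the
  proportion medians under any ratio-preserving individual effect; the
  generator plants the proportions and lets enrichment follow.  One
  individual's control carries zero non-host reads to exercise the
  exclusion rule.

What the generator does **not** emulate: sequencing error, chimeras,
taxonomic misassignment, 18S copy-number variation among taxa, length
polymorphism in the V4 region, multiple primer-binding sites per genome,
or non-specific long products.  Passing tests therefore demonstrate that
the algorithms are correct on their stated contracts — not that a clamp
designed on archive sequences will behave quantitatively as predicted in
a real PCR, where chemistry, dose and cycling conditions dominate.

## Numerical choices and degenerate inputs

* Degenerate expansion is capped (64 variants) and errors loudly rather
  than silently truncating; candidate windows can accumulate at most
  `max_degeneracy` degenerate positions anyway.
* Ranking is lexicographic — passing first, then descending exclusion
  mismatches, descending Tm margin, ascending self-complementarity,
  ascending degeneracy, ascending window start — and uses a stable sort,
  so fully tied candidates keep input order and the output is invariant
  under host shuffling.
* `extract_flank()` truncates out-of-bounds regions with a warning and a
  `partial` flag instead of failing, because archive records are often
  shorter than the requested flank; the design step, by contrast,
  requires the full profiled region and skips sequences that cannot
  provide it.
* Empty exclusion sets make criterion 2 *not-evaluable* (and the
  candidate non-passing) rather than vacuously true: a clamp that was
  never checked against off-targets should not be reported as admissible.
* The primer-location mismatch tolerance when anchoring the search
  region defaults to 2 — a toolkit choice, stated here because archive
  mining needs some tolerance and no canonical value exists.

## Known limitations

The Tm layer is deliberately simple: no Mg²⁺ correction beyond a
monovalent-equivalent input, no secondary-structure partition function,
no heteroduplex ΔG profile, and an additive LNA model that ignores
sequence context.  The blocking predictor is binary with a mismatch
threshold; it does not model dose–response or polymerase kinetics.
Multiple sequence alignment is out of scope — aligned input is accepted,
not produced.  These boundaries match the package's role: choosing and
screening candidate clamps and evaluating depletion experiments, with
wet-lab validation as the final arbiter.
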