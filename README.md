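# clampdesign

Host-blocking clamp oligonucleotide design and host-depletion amplicon
statistics, in R.

## The problem

Amplicon surveys of eukaryotic microbiomes in host-derived samples —
protists and fungi inside ticks being the motivating case — are swamped
by the host's own 18S rDNA: with universal V4 primers, nearly every read
is host.  A *blocker* (clamp) oligonucleotide, typically a peptide
nucleic acid (PNA) or locked nucleic acid (LNA), hybridizes to a
host-specific segment spanning a universal primer's 3' end and
suppresses host amplification while sparing other eukaryotes.

`clampdesign` is for researchers building or evaluating such schemes.
It covers:

* **Clamp site selection** (`design_blockers()`): candidate windows of
  length *L* placed with *u* bases strictly 5' of the primer's
  3'-terminal base and *d* bases downstream of it (*u* + *d* = *L*) are
  screened under four criteria —
  1. zero mismatches against every host sequence, with host polymorphism
     absorbed into IUPAC degeneracy (an A/T column becomes `W`) up to a
     cap;
  2. a minimum mismatch count (default ≥ 3) against every *exclusion*
     sequence the clamp must spare (e.g. apicomplexan parasites);
  3. a melting-temperature threshold (default T_m ≥ 70 °C), with DNA T_m
     from the unified nearest-neighbor model,
     T_m = ΔH° / (ΔS° + R ln(C_T/x)) − 273.15 with
     ΔS° += 0.368 (n−1) ln[Na⁺], and PNA T_m from the published
     regression 20.79 + 0.83·T_m(DNA) − 26.13·f_pyr + 0.44·L;
  4. low self-complementarity (antiparallel self-pairing and hairpin-stem
     caps).
* **In-silico PCR** (`insilico_pcr()`, `nested_pcr()`,
  `blocking_prediction()`, `community_coverage()`): degenerate
  IUPAC-aware primer matching on both strands, nested schemes, and
  per-taxon amplified/blocked/no-site partitions.
* **Depletion statistics** (`enrichment_table()`, `pairwise_prop_test()`,
  `alpha_diversity()`, `faith_pd()`, `relative_intensity()`,
  `top_taxa()`, `detection_summary()`): non-host read proportions,
  per-individual enrichment values with the undefined-control exclusion
  rule, Bonferroni-corrected pairwise proportion tests, Shannon/Faith's
  PD/observed-variant diversity, dose–response normalization, and
  detection grids.
* **A deterministic synthetic-data generator** (`fixture_spec()`,
  `make_host_family()`, `make_exclusion_seq()`, `make_count_table()`)
  planting ground truth for every step.

## Worked example

Design a clamp against a synthetic host family (six tick-like sequences
in two haplotypes, one A/T polymorphism) while sparing an
apicomplexan-like relative carrying three planted mismatches:

```r
library(clampdesign)

spec      <- fixture_spec(seed = 1)
hosts     <- make_host_family(spec)
exclusion <- make_exclusion_seq(spec)
design    <- design_blockers(hosts, list(exclusion), spec$rev_primer)
design
#> <blocker_design> 6 host(s), 1 exclusion sequence(s); 35 window(s) scored, 1 passing
#>   top candidate: 5'-GAGGAGGGAGGGCWGG-3' (16 nt, clamp strand)
#>     placement: 11 bp upstream / 6 bp downstream of the primer 3' end
#>     (prose idiom counting the 3'-terminal base on both sides; exact offsets 10+6 = 16 nt)
#>     exclusion mismatches >= 3 | Tm(pna) 72.7 C | selfcomp 4 | degeneracy 1 | PASS
```

The one passing 16-mer is the planted window: `W` marks the host A/T
polymorphism the clamp absorbs, every host matches with zero mismatches,
the spared relative carries 3, and the conservative (minimum over
degenerate expansions) PNA T_m clears 70 °C.

Summarise a detection grid and a depletion experiment:

```r
detection_summary(read_detection_grid(apicomplexa_detection_file()))
#>  G  A Cr  T  N EU Co
#>  3  1  1  1  1  1  1

gen <- make_count_table(spec)
enr <- enrichment_table(gen$table, gen$truth$host_prefix)
print(enrichment_summary(enr), digits = 3)
#>           method  n n_excluded median_p_nontick median_enrichment
#> 1     pna_ampure 16          1           0.0301             107.7
#> 2 pna_sizeselect 16          1           0.0534             191.2
#> 3     lna_ampure 16          1           0.0142              50.9
#> 4 lna_sizeselect 16          1           0.0295             105.8
#> 5            unm 16          1           0.0127              45.6
```

Reading the numbers: the Gregarina code (`G`) appears in 3 of 17
samples and six other apicomplexan codes in exactly one sample each; in
the generated count table the PNA clamp with size selection raises the
median non-host read fraction from 0.03% (control) to ~5%, a ~190-fold
median per-individual enrichment, and the one individual whose control
contained only host reads is excluded (`n_excluded`) rather than
producing an undefined ratio.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/clampdesign.R design --host hosts.fasta \
    --exclude targets.fasta --primer ACTTTCGTTCTTGATYRA \
    --min-exclusion-mm 3 --tm-min 70 --out candidates.tsv
```

(subcommands `design`, `amplify`, `stats`, `fixtures`).

## Vignette

`vignettes/clamp-design.Rmd` documents the model choices in detail: the
coordinate and offset conventions, the three thermodynamic models and
their defaults, the blocking-tolerance rationale, what the synthetic
generator does and does not emulate, and known limitations.
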