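# Deterministic synthetic-data generator with planted ground truth.
#
# The generator emulates the input structure of a clamp-design study: a host
# (tick-like) 18S family sharing a backbone with limited, planted
# polymorphism around a universal reverse primer; an exclusion
# (apicomplexan-like) relative carrying exactly three planted mismatches in
# the clamp window; community templates for in-silico PCR; and per-method
# count tables mirroring a blocking-assay sequencing comparison.
#
# The planted reverse primer and clamp site are synthetic: the clamp window
# is GC-balanced with a purine-rich clamp strand so that the planted window
# is admissible under the default four selection criteria (including the
# conservative PNA Tm threshold), which an AT-rich natural site would not
# clear under the same estimator.  See the methods vignette.

.FIX_FWD_PRIMER <- "CCAGCAGCTGCGGTAATTCC"  # concrete V4 forward instance
.FIX_REV_PRIMER <- "ACTCAGCGAGGAGGGAGG"    # synthetic 18-mer reverse primer
.FIX_REV_EXT <- "GCAGG"                    # r = 1..5 beyond the 3' end

#' Specification for the synthetic fixture family
#'
#' A single integer seed governs all randomness; identical specs produce
#' byte-identical outputs.  Relative coordinates `r` are anchored at the
#' reverse primer's 3'-end base (r = 0), negative upstream (into the
#' primer), positive downstream (beyond the 3' end); the planted clamp
#' window spans r = -10..5.
#'
#' @param seed integer seed.
#' @param n_host number of host sequences.
#' @param haplotype_counts integer vector of per-haplotype sequence counts
#'   (sums to `n_host`; its length is the number of planted haplotypes).
#' @param polymorphic_r relative coordinate of the planted polymorphic
#'   column (must lie downstream of the primer so the flanking-haplotype
#'   analysis sees it).
#' @param polymorphic_alleles bases of the planted alleles (one per
#'   haplotype).
#' @param exclusion_mismatch_r relative coordinates of the planted
#'   exclusion mismatches.
#' @param wildcard_host index of the host carrying a planted `N` (GenBank
#'   records routinely do), or `NULL` for none.
#' @param wildcard_r relative coordinate of the planted `N`.
#' @param interior_len length of the random amplicon interior.
#' @param flank_len length of the random flanks outside the primer pair.
#' @param n_ticks,methods,total_reads,tick_sdlog,zero_control_tick
#'   count-table block: number of host individuals; named vector of
#'   per-method target non-host read proportions (the control first);
#'   reads per sample; lognormal sd of the per-individual effect; whether
#'   one individual's control carries zero non-host reads (to exercise the
#'   enrichment exclusion rule).
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L,
                         n_host = 6L,
                         haplotype_counts = c(4L, 2L),
                         polymorphic_r = 3L,
                         polymorphic_alleles = c("A", "T"),
                         exclusion_mismatch_r = c(-10L, -3L, 5L),
                         wildcard_host = 1L,
                         wildcard_r = -11L,
                         interior_len = 150L,
                         flank_len = 40L,
                         n_ticks = 17L,
                         methods = c(control = 0.0003,
                                     pna_ampure = 0.0324,
                                     pna_sizeselect = 0.0575,
                                     lna_ampure = 0.0153,
                                     lna_sizeselect = 0.0318,
                                     unm = 0.0137),
                         total_reads = 100000L,
                         tick_sdlog = 0.6,
                         zero_control_tick = TRUE) {
  stopifnot(sum(haplotype_counts) == n_host,
            length(haplotype_counts) <= n_host,
            length(polymorphic_alleles) == length(haplotype_counts),
            all(polymorphic_alleles %in% c("A", "C", "G", "T")),
            polymorphic_r >= 1L, polymorphic_r <= nchar(.FIX_REV_EXT),
            all(exclusion_mismatch_r >= -nchar(.FIX_REV_PRIMER) + 1L),
            all(exclusion_mismatch_r <= nchar(.FIX_REV_EXT)),
            interior_len >= 41L, flank_len >= 20L,
            all(methods > 0 | names(methods) == "control"),
            total_reads >= 1000L)
  if (!"control" %in% names(methods)) {
    stop("methods must include a 'control' entry", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), n_host = as.integer(n_host),
         haplotype_counts = as.integer(haplotype_counts),
         polymorphic_r = as.integer(polymorphic_r),
         polymorphic_alleles = polymorphic_alleles,
         exclusion_mismatch_r = as.integer(exclusion_mismatch_r),
         wildcard_host = if (is.null(wildcard_host)) NULL
                         else as.integer(wildcard_host),
         wildcard_r = as.integer(wildcard_r),
         interior_len = as.integer(interior_len),
         flank_len = as.integer(flank_len),
         fwd_primer = .FIX_FWD_PRIMER, rev_primer = .FIX_REV_PRIMER,
         rev_ext = .FIX_REV_EXT,
         n_ticks = as.integer(n_ticks), methods = methods,
         total_reads = as.integer(total_reads), tick_sdlog = tick_sdlog,
         zero_control_tick = isTRUE(zero_control_tick)),
    class = "fixture_spec"
  )
}

.random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Shared random backbone pieces for one spec (deterministic in the seed).
.fixture_backbone <- function(spec) {
  withr::with_seed(spec$seed, {
    list(left = .random_bases(spec$flank_len),
         interior = .random_bases(spec$interior_len),
         right = .random_bases(spec$flank_len))
  })
}

# Reverse-primer-strand instance (primer + downstream extension) for one
# haplotype, optionally with a planted N.
.rev_region_instance <- function(spec, hap, with_wildcard = FALSE) {
  primer <- spec$rev_primer
  ext <- spec$rev_ext
  substr(ext, spec$polymorphic_r, spec$polymorphic_r) <-
    spec$polymorphic_alleles[hap]
  if (with_wildcard) {
    pos <- spec$wildcard_r + nchar(primer)  # r -> 1-based primer index
    if (pos >= 1L && pos <= nchar(primer)) {
      substr(primer, pos, pos) <- "N"
    } else {
      pos_ext <- spec$wildcard_r
      if (pos_ext >= 1L && pos_ext <= nchar(ext)) {
        substr(ext, pos_ext, pos_ext) <- "N"
      }
    }
  }
  paste0(primer, ext)
}

.assemble_template <- function(backbone, spec, rev_region) {
  paste0(backbone$left, spec$fwd_primer, backbone$interior,
         reverse_complement(rev_region), backbone$right)
}

#' Generate the planted host sequence family
#'
#' All hosts share one random backbone; they differ only at the planted
#' polymorphic column (partitioning the family into the specified
#' haplotypes) and, for the designated host, a planted `N`.  Both primer
#' sites are embedded exactly.
#'
#' @param spec a [fixture_spec()].
#' @return list of [degen_seq] with a `truth` attribute recording the
#'   planted clamp window, polymorphism and haplotype assignment.
#' @export
make_host_family <- function(spec = fixture_spec()) {
  backbone <- .fixture_backbone(spec)
  hap_of <- rep(seq_along(spec$haplotype_counts), spec$haplotype_counts)
  out <- vector("list", spec$n_host)
  for (i in seq_len(spec$n_host)) {
    wc <- !is.null(spec$wildcard_host) && i == spec$wildcard_host
    region <- .rev_region_instance(spec, hap_of[i], with_wildcard = wc)
    out[[i]] <- degen_seq(.assemble_template(backbone, spec, region),
                          id = sprintf("host_%02d", i))
  }
  attr(out, "truth") <- fixture_truth(spec)
  attr(out, "haplotype") <- hap_of
  out
}

#' Generate the planted exclusion (spared) sequence
#'
#' The host backbone with substitutions at exactly the planted relative
#' coordinates; each substitution is guaranteed incompatible with the host
#' consensus at that column.  Substitutions inside the primer footprint are
#' permitted by default (the exclusion taxon's primer region may diverge
#' slightly, as long as the site stays locatable).
#'
#' @param spec a [fixture_spec()].
#' @param allow_primer_overlap logical; when `FALSE`, planted positions
#'   falling inside the primer binding site raise an error.
#' @return a [degen_seq] named `exclusion_01`.
#' @export
make_exclusion_seq <- function(spec = fixture_spec(),
                               allow_primer_overlap = TRUE) {
  primer_len <- nchar(spec$rev_primer)
  inside <- spec$exclusion_mismatch_r <= 0L
  if (any(inside) && !allow_primer_overlap) {
    stop("planted exclusion mismatch position(s) ",
         paste(spec$exclusion_mismatch_r[inside], collapse = ", "),
         " fall inside the primer binding site", call. = FALSE)
  }
  backbone <- .fixture_backbone(spec)
  region <- .rev_region_instance(spec, hap = 1L, with_wildcard = FALSE)
  for (r in spec$exclusion_mismatch_r) {
    pos <- r + primer_len  # 1-based index into primer + ext
    host_base <- substr(region, pos, pos)
    # any base incompatible with the host consensus column works; the
    # consensus at planted-mismatch columns is concrete by construction
    sub <- switch(host_base, A = "C", C = "T", G = "T", T = "G", "C")
    if (r == spec$polymorphic_r) {
      # polymorphic column: pick a base outside the planted allele set
      sub <- setdiff(c("A", "C", "G", "T"),
                     c(spec$polymorphic_alleles))[1L]
    }
    substr(region, pos, pos) <- sub
  }
  degen_seq(.assemble_template(backbone, spec, region), id = "exclusion_01")
}

#' Planted ground truth of a fixture specification
#'
#' @param spec a [fixture_spec()].
#' @return list with the planted clamp-window consensus (clamp strand,
#'   r = -10..5), its offsets, the polymorphic column and the exclusion
#'   mismatch coordinates.
#' @export
fixture_truth <- function(spec = fixture_spec()) {
  primer_len <- nchar(spec$rev_primer)
  region <- paste0(spec$rev_primer, spec$rev_ext)
  consensus <- region
  pos <- spec$polymorphic_r + primer_len
  code <- .mask_to_code(Reduce(bitwOr,
                               .IUPAC_MASK[spec$polymorphic_alleles]))
  substr(consensus, pos, pos) <- code
  window <- substr(consensus, primer_len - 10L, primer_len + 5L)
  list(
    window_consensus = window,
    window_r_start = -10L, window_r_end = 5L,
    offset_upstream = 10L, offset_downstream = 6L,
    polymorphic_r = spec$polymorphic_r,
    polymorphic_window_pos = spec$polymorphic_r + 11L,
    polymorphic_code = code,
    exclusion_mismatch_r = spec$exclusion_mismatch_r,
    n_haplotypes = length(spec$haplotype_counts),
    fwd_primer = spec$fwd_primer, rev_primer = spec$rev_primer
  )
}

#' Generate a labelled community for in-silico PCR
#'
#' Hosts (taxon `"tick"`), the exclusion relative (taxon `"apicomplexa"`),
#' amplifiable non-host templates whose clamp window diverges well beyond
#' the blocking tolerance (taxon `"other_eukaryote"`), and templates with
#' no reverse-primer site at all (taxon `"no_site"`).
#'
#' @param spec a [fixture_spec()].
#' @param n_other number of divergent amplifiable templates.
#' @param n_nosite number of templates lacking the reverse primer site.
#' @return list with `seqs` (list of [degen_seq]) and `taxa` (character).
#' @export
make_community <- function(spec = fixture_spec(), n_other = 3L,
                           n_nosite = 2L) {
  hosts <- make_host_family(spec)
  excl <- make_exclusion_seq(spec)
  backbone <- .fixture_backbone(spec)
  primer_len <- nchar(spec$rev_primer)
  seqs <- c(hosts, list(excl))
  taxa <- c(rep("tick", length(hosts)), "apicomplexa")
  # divergent amplifiable templates: 4 clamp-window substitutions, two of
  # them inside the primer (still locatable at <= 2 mismatches)
  divergent_r <- c(-6L, -1L, 1L, 4L)
  withr::with_seed(spec$seed + 1L, {
    for (k in seq_len(n_other)) {
      region <- .rev_region_instance(spec, hap = 1L)
      for (r in divergent_r) {
        pos <- r + primer_len
        host_base <- substr(region, pos, pos)
        substr(region, pos, pos) <-
          switch(host_base, A = "G", C = "A", G = "T", T = "C", "G")
      }
      seqs[[length(seqs) + 1L]] <-
        degen_seq(.assemble_template(backbone, spec, region),
                  id = sprintf("other_%02d", k))
      taxa <- c(taxa, "other_eukaryote")
    }
    for (k in seq_len(n_nosite)) {
      tmpl <- paste0(backbone$left, spec$fwd_primer, backbone$interior,
                     .random_bases(primer_len + nchar(spec$rev_ext)),
                     backbone$right)
      seqs[[length(seqs) + 1L]] <-
        degen_seq(tmpl, id = sprintf("nosite_%02d", k))
      taxa <- c(taxa, "no_site")
    }
  })
  list(seqs = seqs, taxa = taxa)
}

.FIX_HOST_LINEAGE <-
  "Eukaryota;Opisthokonta;Metazoa;Arthropoda;Arachnida;Ixodida;Ixodidae"

.FIX_NONHOST_LINEAGES <- c(
  "Eukaryota;Opisthokonta;Fungi;Ascomycota;Ascochyta",
  "Eukaryota;Opisthokonta;Fungi;Ascomycota;Cladosporium",
  "Eukaryota;Opisthokonta;Fungi;Ascomycota;Aspergillus",
  "Eukaryota;Opisthokonta;Fungi;Basidiomycota;Papiliotrema",
  "Eukaryota;Archaeplastida;Chloroplastida;Charophyta;Capsicum",
  "Eukaryota;SAR;Alveolata;Apicomplexa;Gregarina",
  "Eukaryota;SAR;Alveolata;Ciliophora;Mykophagophrys",
  "Eukaryota;SAR;Alveolata;Ciliophora;Colpoda",
  "Eukaryota;SAR;Rhizaria;Cercozoa;Heteromita",
  "Eukaryota;unclassified"
)

#' Generate a per-method community count table with planted proportions
#'
#' Every host individual receives one sample per method.  The per-sample
#' target non-host proportion is the method's proportion scaled by a
#' lognormal per-individual effect shared across that individual's
#' methods, so the planted enrichment value of each method over its control
#' is the ratio of the method proportions.  Realized integer counts equal
#' the target to within 1/total.  When `zero_control_tick` is set, one
#' individual's control sample carries only host reads, exercising the
#' enrichment exclusion rule.
#'
#' @param spec a [fixture_spec()].
#' @return list with `table` (a [community_count_table()]) and `truth`
#'   (data.frame of per-sample target proportions plus `host_prefix` and
#'   the per-method planted enrichment).
#' @export
make_count_table <- function(spec = fixture_spec()) {
  methods <- spec$methods
  n_taxa <- length(.FIX_NONHOST_LINEAGES)
  taxa <- c(.FIX_HOST_LINEAGE, .FIX_NONHOST_LINEAGES)
  weights <- (n_taxa:1)  # fixed, skewed non-host composition
  weights <- weights / sum(weights)
  withr::with_seed(spec$seed + 2L, {
    tick_ids <- sprintf("tick_%02d", seq_len(spec$n_ticks))
    effect <- exp(stats::rnorm(spec$n_ticks, 0, spec$tick_sdlog))
    zero_tick <- if (spec$zero_control_tick) {
      tick_ids[min(13L, spec$n_ticks)]
    } else NA_character_
    rows <- list()
    truth <- list()
    for (t in seq_len(spec$n_ticks)) {
      for (m in names(methods)) {
        target <- min(0.9, methods[[m]] * effect[t])
        if (!is.na(zero_tick) && tick_ids[t] == zero_tick &&
            m == "control") {
          target <- 0
        }
        nontick <- as.integer(round(target * spec$total_reads))
        host <- spec$total_reads - nontick
        split <- if (nontick > 0L) {
          as.integer(stats::rmultinom(1L, nontick, weights))
        } else integer(n_taxa)
        sample_id <- sprintf("%s_%s", tick_ids[t], m)
        rows[[sample_id]] <- c(host, split)
        truth[[sample_id]] <- data.frame(
          sample = sample_id, tick_id = tick_ids[t], method = m,
          target_p = target, total = spec$total_reads,
          stringsAsFactors = FALSE)
      }
    }
  })
  counts <- do.call(rbind, rows)
  colnames(counts) <- taxa
  truth_df <- do.call(rbind, unname(truth))
  meta <- truth_df[, c("sample", "tick_id", "method")]
  ct <- community_count_table(counts, meta, control_method = "control")
  planted_enrichment <-
    methods[setdiff(names(methods), "control")] / methods[["control"]]
  list(table = ct,
       truth = list(samples = truth_df, host_prefix = .FIX_HOST_LINEAGE,
                    planted_enrichment = planted_enrichment,
                    zero_control_tick = zero_tick))
}
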