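# Blocker (clamp) candidate enumeration, criterion filtering and ranking.
#
# Coordinate idiom: candidate windows live on the primer's strand and are
# anchored at the primer's 3'-terminal base.  Relative coordinate r = 0 is
# the 3'-end base itself; r < 0 runs back toward the primer 5' end
# ("upstream"); r > 0 runs in the extension direction beyond the 3' end
# ("downstream").  A window of length L with offset_downstream = d covers
# r in [d - L, d - 1]; offset_upstream = L - d counts the bases strictly 5'
# of the 3'-end position, so the 3'-end base belongs to the downstream
# count and offsets always sum to the window length.  (The classical prose
# idiom counts the 3'-end base on both sides; reports emit both forms.)

#' Design configuration for blocker candidate screening
#'
#' @param window_length_range integer `c(min, max)` clamp lengths.
#' @param offset_downstream_range integer `c(min, max)` bases beyond the
#'   primer 3' end (the 3'-end base counts as downstream base 1).
#' @param min_exclusion_mismatch criterion 2 threshold: minimum mismatches
#'   against every exclusion (spared) sequence.
#' @param tm_min criterion 3 threshold in degrees C.
#' @param tm_metric which estimate is thresholded: `"pna"` (default; the
#'   clamp is a PNA), `"dna"` or `"lna"`.
#' @param max_degeneracy criterion 1 cap on degenerate consensus positions.
#' @param selfcomp_max,hairpin_max criterion 4 thresholds.
#' @param flank_upstream,flank_downstream extent of the profiled search
#'   region around the primer 3' end (bases).
#' @param primer_max_mismatch tolerance when locating the primer in host and
#'   exclusion sequences.
#' @param degenerate_policy Tm aggregation over consensus expansions.
#' @param lna_positions optional 1-based LNA substitution positions used
#'   when `tm_metric = "lna"` (default: all positions substituted).
#' @return object of class `design_config`.
#' @export
design_config <- function(window_length_range = c(14L, 18L),
                          offset_downstream_range = c(0L, 10L),
                          min_exclusion_mismatch = 3L,
                          tm_min = 70,
                          tm_metric = c("pna", "dna", "lna"),
                          max_degeneracy = 2L,
                          selfcomp_max = 8L,
                          hairpin_max = 4L,
                          flank_upstream = 27L,
                          flank_downstream = 6L,
                          primer_max_mismatch = 2L,
                          degenerate_policy = c("min", "max", "mean"),
                          lna_positions = NULL) {
  tm_metric <- match.arg(tm_metric)
  degenerate_policy <- match.arg(degenerate_policy)
  stopifnot(length(window_length_range) == 2L,
            window_length_range[1L] <= window_length_range[2L],
            window_length_range[1L] >= 1L,
            length(offset_downstream_range) == 2L,
            offset_downstream_range[1L] <= offset_downstream_range[2L],
            offset_downstream_range[1L] >= 0L,
            min_exclusion_mismatch >= 1L,
            flank_upstream >= 1L, flank_downstream >= 0L)
  structure(
    list(window_length_range = as.integer(window_length_range),
         offset_downstream_range = as.integer(offset_downstream_range),
         min_exclusion_mismatch = as.integer(min_exclusion_mismatch),
         tm_min = tm_min, tm_metric = tm_metric,
         max_degeneracy = as.integer(max_degeneracy),
         selfcomp_max = as.integer(selfcomp_max),
         hairpin_max = as.integer(hairpin_max),
         flank_upstream = as.integer(flank_upstream),
         flank_downstream = as.integer(flank_downstream),
         primer_max_mismatch = as.integer(primer_max_mismatch),
         degenerate_policy = degenerate_policy,
         lna_positions = lna_positions),
    class = "design_config"
  )
}

#' Enumerate candidate clamp windows over an anchored profile
#'
#' Emits every (length, downstream offset) combination allowed by the
#' configuration that fits inside the profiled region.  The profile must
#' span `flank_upstream` columns before and `flank_downstream` columns after
#' the primer 3'-end base; column `flank_upstream + 1` is r = 0.
#'
#' @param profile a [conservation_profile()] over the search region.
#' @param config a [design_config()].
#' @return data.frame with one window per row: `length`,
#'   `offset_downstream`, `offset_upstream`, `r_start`, `r_end` (inclusive
#'   relative coordinates) and `col_start`, `col_end` (1-based profile
#'   columns), ordered by (`r_start`, `length`).
#' @export
enumerate_windows <- function(profile, config = design_config()) {
  n_col <- length(profile$column_masks)
  up <- config$flank_upstream
  down <- config$flank_downstream
  if (n_col < up + down) {
    stop(sprintf("profile spans %d columns but the search region needs %d",
                 n_col, up + down), call. = FALSE)
  }
  lens <- config$window_length_range[1L]:config$window_length_range[2L]
  offs <- config$offset_downstream_range[1L]:config$offset_downstream_range[2L]
  rows <- list()
  for (L in lens) {
    for (d in offs) {
      r_start <- d - L
      r_end <- d - 1L
      if (r_start < -up || r_end > down - 1L) next
      rows[[length(rows) + 1L]] <- data.frame(
        length = L, offset_downstream = d, offset_upstream = L - d,
        r_start = r_start, r_end = r_end,
        col_start = r_start + up + 1L, col_end = r_end + up + 1L)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(length = integer(), offset_downstream = integer(),
                      offset_upstream = integer(), r_start = integer(),
                      r_end = integer(), col_start = integer(),
                      col_end = integer()))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$r_start, out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Evaluate the four selection criteria for one enumerated window.
# host_regions / exclusion_regions: character vectors of the full profiled
# region (primer strand, 5'->3') per sequence.
.evaluate_window <- function(window, profile, host_regions,
                             exclusion_regions, thermo, config) {
  cs <- window$col_start
  ce <- window$col_end
  consensus <- substr(residues(profile$consensus), cs, ce)
  wildcard <- any(profile$wildcard[cs:ce])
  deg <- degeneracy_count(consensus)
  host_mm <- vapply(host_regions, function(r) {
    count_mismatches(consensus, substr(r, cs, ce))
  }, integer(1L))
  host_max_mm <- max(host_mm)
  crit1 <- !wildcard && host_max_mm == 0L && deg <= config$max_degeneracy

  if (length(exclusion_regions) == 0L) {
    excl_min_mm <- NA_integer_
    crit2 <- NA
  } else {
    excl_mm <- vapply(exclusion_regions, function(r) {
      count_mismatches(consensus, substr(r, cs, ce))
    }, integer(1L))
    excl_min_mm <- min(excl_mm)
    crit2 <- excl_min_mm >= config$min_exclusion_mismatch
  }

  tm <- tryCatch({
    lna_pos <- config$lna_positions
    if (config$tm_metric == "lna" && is.null(lna_pos)) {
      lna_pos <- seq_len(nchar(consensus))
    }
    tm_estimate(consensus, params = thermo,
                policy = config$degenerate_policy, lna_positions = lna_pos)
  }, error = function(e) NULL)
  if (is.null(tm)) {
    tm_dna <- tm_pna <- tm_lna <- tm_val <- NA_real_
    crit3 <- FALSE
  } else {
    tm_dna <- tm$tm_dna
    tm_pna <- tm$tm_pna
    tm_lna <- tm$tm_lna
    tm_val <- switch(config$tm_metric, dna = tm_dna, pna = tm_pna,
                     lna = tm_lna)
    crit3 <- !is.na(tm_val) && tm_val >= config$tm_min
  }

  sc <- self_complementarity(consensus)
  crit4 <- sc$score <= config$selfcomp_max && sc$hairpin <= config$hairpin_max

  pass <- isTRUE(crit1) && isTRUE(crit2) && isTRUE(crit3) && isTRUE(crit4)
  data.frame(
    sequence = consensus, length = window$length,
    offset_upstream = window$offset_upstream,
    offset_downstream = window$offset_downstream,
    r_start = window$r_start, r_end = window$r_end,
    host_max_mismatch = host_max_mm, exclusion_min_mismatch = excl_min_mm,
    degeneracy = deg, wildcard = wildcard,
    tm_dna = tm_dna, tm_pna = tm_pna, tm_lna = tm_lna,
    tm_metric_value = tm_val, selfcomp = sc$score, hairpin = sc$hairpin,
    crit1_host_identity = crit1, crit2_exclusion = crit2,
    crit3_tm = crit3, crit4_selfcomp = crit4, pass = pass,
    stringsAsFactors = FALSE
  )
}

#' Score enumerated windows against the four selection criteria
#'
#' Criterion 1: the degenerate host consensus matches every host sequence
#' with zero mismatches, carries at most `max_degeneracy` degenerate
#' positions, and spans no wildcard-flagged (N/gap) column.  Criterion 2:
#' the minimum mismatch count over the exclusion set is at least
#' `min_exclusion_mismatch` (reported as not-evaluable when the exclusion
#' set is empty).  Criterion 3: the configured Tm estimate reaches
#' `tm_min`.  Criterion 4: self-complementarity and hairpin stem at or
#' below their caps.  All four flags are recorded even when failing.
#'
#' @param windows data.frame from [enumerate_windows()].
#' @param profile the host [conservation_profile()] the windows index into.
#' @param host_regions character vector, per-host profiled region
#'   (primer strand, 5'->3').
#' @param exclusion_regions character vector for the exclusion set
#'   (may be empty).
#' @param thermo a [thermo_params()].
#' @param config a [design_config()].
#' @return data.frame of candidates with per-criterion flags, one row per
#'   window.
#' @export
apply_criteria <- function(windows, profile, host_regions,
                           exclusion_regions = character(),
                           thermo = thermo_params(),
                           config = design_config()) {
  if (nrow(windows) == 0L) {
    stop("no candidate windows to evaluate", call. = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(windows)), function(i) {
    .evaluate_window(windows[i, ], profile, host_regions,
                     exclusion_regions, thermo, config)
  }))
  rownames(out) <- NULL
  out
}

#' Rank scored blocker candidates
#'
#' Passing candidates come first; within each group the stable sort order is
#' descending exclusion mismatch count, descending Tm margin over `tm_min`,
#' ascending self-complementarity, ascending degeneracy, ascending window
#' start offset.  `rank_score` is a monotone composite of the same keys kept
#' for reporting; the ordering itself is lexicographic on the keys.
#'
#' @param candidates data.frame from [apply_criteria()].
#' @param config the [design_config()] used for scoring (for `tm_min`).
#' @return the same data.frame, reordered, with `rank` and `rank_score`
#'   columns added.
#' @export
rank_candidates <- function(candidates, config = design_config()) {
  if (nrow(candidates) == 0L) return(candidates)
  excl <- ifelse(is.na(candidates$exclusion_min_mismatch), -1L,
                 candidates$exclusion_min_mismatch)
  margin <- ifelse(is.na(candidates$tm_metric_value), -Inf,
                   candidates$tm_metric_value - config$tm_min)
  ord <- order(!candidates$pass, -excl, -margin, candidates$selfcomp,
               candidates$degeneracy, candidates$r_start)
  out <- candidates[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$rank_score <- excl[ord] * 1e3 +
    ifelse(is.finite(margin[ord]), margin[ord], -1e3) -
    0.01 * out$selfcomp - 0.1 * out$degeneracy
  rownames(out) <- NULL
  out
}

#' Design blocker (clamp) candidates around a primer's 3' end
#'
#' End-to-end composition: locate the primer in every host and exclusion
#' sequence, profile the host search region on the primer's strand, and
#' enumerate, score and rank candidate windows.  Candidates are reported
#' 5'-to-3' on the primer's strand (the clamp orientation, complementary to
#' the extension template); the plus-strand window is recoverable from the
#' reported coordinates.
#'
#' @param hosts host sequences: FASTA path or list of [degen_seq] (the
#'   templates the clamp must block).
#' @param exclusions exclusion sequences the clamp must spare: FASTA path,
#'   list of [degen_seq], or `NULL`.
#' @param primer the universal primer whose 3' end anchors the search
#'   (`degen_seq` or character).
#' @param thermo a [thermo_params()].
#' @param config a [design_config()].
#' @return object of class `blocker_design`: list with ranked `candidates`,
#'   the host `profile`, per-sequence `host_sites`/`exclusion_sites`, the
#'   `primer`, `config` and input sizes.
#' @export
design_blockers <- function(hosts, exclusions = NULL, primer,
                            thermo = thermo_params(),
                            config = design_config()) {
  if (is.character(hosts) && length(hosts) == 1L && file.exists(hosts)) {
    hosts <- read_fasta(hosts)
  }
  if (is.character(exclusions) && length(exclusions) == 1L &&
      file.exists(exclusions)) {
    exclusions <- read_fasta(exclusions)
  }
  if (is.null(exclusions)) exclusions <- list()
  if (length(hosts) == 0L) stop("no host sequences", call. = FALSE)

  host_loc <- lapply(hosts, .locate_region, primer = primer, config = config)
  missing <- vapply(host_loc, is.null, logical(1L))
  if (any(missing)) {
    best <- vapply(hosts[missing], function(s) {
      b <- best_primer_site(s, primer)
      if (nrow(b) == 0L) NA_integer_ else b$mismatches
    }, integer(1L))
    ids <- vapply(hosts[missing], function(s) s$id, character(1L))
    stop(sprintf(
      "no admissible primer site (<= %d mismatches, full search region) in host(s): %s",
      config$primer_max_mismatch,
      paste(sprintf("%s (best %s mismatches)", ids, best), collapse = "; ")),
      call. = FALSE)
  }
  excl_loc <- lapply(exclusions, .locate_region, primer = primer,
                     config = config)
  excl_keep <- !vapply(excl_loc, is.null, logical(1L))
  if (length(exclusions) > 0L && !all(excl_keep)) {
    warning(sprintf(
      "%d exclusion sequence(s) without a locatable primer site were dropped",
      sum(!excl_keep)), call. = FALSE)
  }
  excl_loc <- excl_loc[excl_keep]

  host_regions <- vapply(host_loc, `[[`, character(1L), "region")
  excl_regions <- vapply(excl_loc, `[[`, character(1L), "region")
  profile <- conservation_profile(host_regions)
  windows <- enumerate_windows(profile, config)
  candidates <- apply_criteria(windows, profile, host_regions, excl_regions,
                               thermo, config)
  candidates <- rank_candidates(candidates, config)

  structure(
    list(candidates = candidates, profile = profile,
         primer = residues(primer), config = config,
         host_sites = do.call(rbind, lapply(host_loc, `[[`, "site")),
         exclusion_sites = if (length(excl_loc) > 0L) {
           do.call(rbind, lapply(excl_loc, `[[`, "site"))
         } else NULL,
         n_host = length(hosts), n_exclusion = length(excl_loc)),
    class = "blocker_design"
  )
}

# Locate the best primer site in one sequence and extract the profiled
# search region on the primer strand; NULL when no site within tolerance or
# the region runs off the sequence.
.locate_region <- function(seq, primer, config) {
  sites <- find_primer_sites(seq, primer,
                             max_mismatch = config$primer_max_mismatch)
  if (nrow(sites) == 0L) return(NULL)
  site <- sites[order(sites$mismatches, sites$start), ][1L, , drop = FALSE]
  res <- residues(seq)
  n <- nchar(res)
  up <- config$flank_upstream
  down <- config$flank_downstream
  L <- site$end - site$start
  if (site$strand == "+") {
    # r = 0 at plus position end - 1; region r in [-up, down - 1]
    a <- site$end - 1L - up
    b <- site$end - 1L + down - 1L
    if (a < 0L || b >= n) return(NULL)
    region <- substr(res, a + 1L, b + 1L)
  } else {
    # r = 0 at plus position start; r increases toward lower plus coords
    a <- site$start - (down - 1L)
    b <- site$start + up
    if (a < 0L || b >= n) return(NULL)
    region <- reverse_complement(substr(res, a + 1L, b + 1L))
  }
  list(site = site, region = region)
}

#' @export
print.blocker_design <- function(x, ...) {
  cand <- x$candidates
  n_pass <- sum(cand$pass)
  cat(sprintf(
    "<blocker_design> %d host(s), %d exclusion sequence(s); %d window(s) scored, %d passing\n",
    x$n_host, x$n_exclusion, nrow(cand), n_pass))
  if (nrow(cand) > 0L) {
    top <- cand[1L, ]
    cat(sprintf("  top candidate: 5'-%s-3' (%d nt, clamp strand)\n",
                top$sequence, top$length))
    cat(sprintf(
      "    placement: %d bp upstream / %d bp downstream of the primer 3' end\n",
      top$offset_upstream + 1L, top$offset_downstream))
    cat("    (prose idiom counting the 3'-terminal base on both sides;",
        sprintf("exact offsets %d+%d = %d nt)\n", top$offset_upstream,
                top$offset_downstream, top$length))
    cat(sprintf(
      "    exclusion mismatches >= %s | Tm(%s) %.1f C | selfcomp %d | degeneracy %d | %s\n",
      top$exclusion_min_mismatch, x$config$tm_metric, top$tm_metric_value,
      top$selfcomp, top$degeneracy,
      if (top$pass) "PASS" else "fails >= 1 criterion"))
  }
  invisible(x)
}

#' Write a candidate report as TSV
#'
#' One candidate per row with 0/1 criterion flags.  Offsets are relative to
#' the primer 3' end under the convention stated in the header line;
#' coordinates are 1-based inclusive.
#'
#' @param design a `blocker_design`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_candidate_report <- function(design, path) {
  cand <- design$candidates
  out <- cand
  for (fl in c("crit1_host_identity", "crit2_exclusion", "crit3_tm",
               "crit4_selfcomp", "pass", "wildcard")) {
    out[[fl]] <- as.integer(out[[fl]])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# coord_system: offsets relative to the primer 3'-end base (r = 0, counted as downstream base 1); windows 5'->3' on the primer strand",
    sprintf("# tm_metric: %s; tm_min: %s; degenerate_policy: %s",
            design$config$tm_metric, design$config$tm_min,
            design$config$degenerate_policy)), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
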