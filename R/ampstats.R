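# Downstream statistics on taxonomy-annotated count tables: non-host read
# proportions, per-individual enrichment, pairwise proportion tests, alpha
# diversity, intensity normalization, detection and top-taxa summaries.

#' Sample-by-taxon community count table
#'
#' @param counts integer matrix, samples in rows (rownames = sample IDs),
#'   taxa in columns (colnames = semicolon-delimited lineage strings).
#' @param meta data.frame with columns `sample`, `tick_id` (the host
#'   individual the library came from) and `method` (PCR/purification
#'   method label); one row per sample.
#' @param control_method label of the no-blocker reference method.
#' @return object of class `community_count_table`.
#' @export
community_count_table <- function(counts, meta, control_method = "control") {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  need <- c("sample", "tick_id", "method")
  if (!all(need %in% names(meta))) {
    stop("meta must have columns sample, tick_id, method", call. = FALSE)
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!setequal(rownames(counts), meta$sample) ||
      nrow(meta) != nrow(counts)) {
    stop("rownames(counts) must match meta$sample", call. = FALSE)
  }
  counts <- counts[meta$sample, , drop = FALSE]
  non_ctrl <- meta$method != control_method
  ctrl_ticks <- meta$tick_id[meta$method == control_method]
  orphan <- setdiff(unique(meta$tick_id[non_ctrl]), ctrl_ticks)
  if (length(orphan) > 0L) {
    stop("tick individual(s) without a control sample: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  structure(list(counts = counts, meta = meta,
                 control_method = control_method),
            class = "community_count_table")
}

#' @export
print.community_count_table <- function(x, ...) {
  cat(sprintf(
    "<community_count_table> %d sample(s) x %d taxa, %d method(s), control = '%s'\n",
    nrow(x$counts), ncol(x$counts), length(unique(x$meta$method)),
    x$control_method))
  invisible(x)
}

#' Proportion of non-host reads in one sample
#'
#' `(eukaryote reads not matching the host lineage prefix) / (all reads)`.
#' Taxa are matched by lineage-prefix: a taxon is host when its lineage
#' string starts with `host_prefix`.
#'
#' @param counts named numeric vector of per-taxon reads for one sample
#'   (names = lineage strings).
#' @param host_prefix lineage prefix identifying the host taxon.
#' @return fraction in `[0, 1]`, or `NA` when the sample has zero reads.
#' @export
nontick_proportion <- function(counts, host_prefix) {
  total <- sum(counts)
  if (total == 0) return(NA_real_)
  host <- startsWith(names(counts), host_prefix)
  sum(counts[!host]) / total
}

#' Non-host read enrichment value
#'
#' Ratio of a method's non-host read proportion to the matched control's.
#' When the control proportion is zero the value is undefined and the
#' sample must be excluded from summaries rather than propagated.
#'
#' @param p_method,p_control non-host proportions for the same individual.
#' @return numeric ratio, `NA` when `p_control` is 0 or `NA` (vectorized).
#' @export
enrichment_value <- function(p_method, p_control) {
  out <- ifelse(!is.na(p_control) & p_control > 0, p_method / p_control,
                NA_real_)
  unname(out)
}

#' Per-sample non-host proportions and enrichment report
#'
#' Computes, for every sample, the non-host read proportion; for every
#' non-control sample, the enrichment over the same individual's control.
#' Samples whose control has zero non-host reads (or zero reads) are
#' flagged `excluded` with a reason and must be dropped from summaries.
#'
#' @param ct a [community_count_table()].
#' @param host_prefix lineage prefix identifying the host taxon.
#' @return data.frame with columns `sample`, `tick_id`, `method`,
#'   `p_nontick`, `p_control`, `enrichment`, `excluded`, `reason`.
#' @export
enrichment_table <- function(ct, host_prefix) {
  meta <- ct$meta
  p <- vapply(meta$sample, function(s) {
    nontick_proportion(ct$counts[s, ], host_prefix)
  }, numeric(1L))
  ctrl <- meta$sample[meta$method == ct$control_method]
  names(ctrl) <- meta$tick_id[meta$method == ct$control_method]
  out <- data.frame(
    sample = meta$sample, tick_id = meta$tick_id, method = meta$method,
    p_nontick = unname(p), p_control = NA_real_, enrichment = NA_real_,
    excluded = FALSE, reason = "", stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(out))) {
    if (out$method[i] == ct$control_method) next
    pc <- p[[ctrl[[as.character(out$tick_id[i])]]]]
    out$p_control[i] <- pc
    if (is.na(pc)) {
      out$excluded[i] <- TRUE
      out$reason[i] <- "control sample has zero reads"
    } else if (pc == 0) {
      out$excluded[i] <- TRUE
      out$reason[i] <- "only host reads detected in the control method"
    } else {
      out$enrichment[i] <- enrichment_value(out$p_nontick[i], pc)
    }
  }
  out
}

#' Per-method median enrichment summary
#'
#' Medians are taken over non-excluded, non-control samples only.
#'
#' @param enr data.frame from [enrichment_table()].
#' @param control_method label to drop from the summary.
#' @return data.frame with `method`, `n`, `n_excluded`,
#'   `median_p_nontick`, `median_enrichment`.
#' @export
enrichment_summary <- function(enr, control_method = "control") {
  methods <- setdiff(unique(enr$method), control_method)
  out <- do.call(rbind, lapply(methods, function(m) {
    rows <- enr[enr$method == m, ]
    keep <- rows[!rows$excluded, ]
    data.frame(method = m, n = nrow(keep), n_excluded = sum(rows$excluded),
               median_p_nontick = stats::median(keep$p_nontick),
               median_enrichment = stats::median(keep$enrichment),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Non-host read counts aggregated per method or per sample
#'
#' The pairwise proportion test needs success/total counts; this helper
#' exposes both aggregations and labels them, since pooling reads across
#' samples within a method and testing per-sample proportions answer
#' different questions.
#'
#' @param ct a [community_count_table()].
#' @param host_prefix lineage prefix identifying the host taxon.
#' @param per `"method"` (reads pooled within method) or `"sample"`.
#' @return data.frame with `successes` (non-host reads) and `totals`
#'   columns, keyed by method or sample; carries attribute
#'   `aggregation`.
#' @export
nontick_read_counts <- function(ct, host_prefix,
                                per = c("method", "sample")) {
  per <- match.arg(per)
  host <- startsWith(colnames(ct$counts), host_prefix)
  nh <- rowSums(ct$counts[, !host, drop = FALSE])
  tot <- rowSums(ct$counts)
  if (per == "sample") {
    out <- data.frame(sample = ct$meta$sample, method = ct$meta$method,
                      successes = unname(nh), totals = unname(tot),
                      stringsAsFactors = FALSE)
  } else {
    methods <- unique(ct$meta$method)
    out <- do.call(rbind, lapply(methods, function(m) {
      idx <- ct$meta$method == m
      data.frame(method = m, successes = sum(nh[idx]),
                 totals = sum(tot[idx]), stringsAsFactors = FALSE)
    }))
  }
  rownames(out) <- NULL
  attr(out, "aggregation") <- per
  out
}

#' Pairwise tests of equal proportions with Bonferroni correction
#'
#' Each pair of groups is compared by the 2x2 chi-square test of equal
#' proportions (Yates continuity correction by default, mirroring the
#' base-R pairwise proportion test); the Bonferroni-adjusted p-value is
#' `min(1, m p)` with `m` the number of evaluable pairs.  Groups with a
#' zero total are flagged not-evaluable (`NA` rows/columns).
#'
#' @param successes,totals named numeric vectors (same names, same order).
#' @param correction `"bonferroni"` or `"none"`.
#' @param yates logical; apply the continuity correction.
#' @return symmetric matrix of corrected p-values (`NA` diagonal), with
#'   attributes `uncorrected` (matrix) and `correction`.
#' @export
pairwise_prop_test <- function(successes, totals,
                               correction = c("bonferroni", "none"),
                               yates = TRUE) {
  correction <- match.arg(correction)
  k <- length(successes)
  stopifnot(length(totals) == k, all(totals >= successes),
            all(successes >= 0))
  nms <- names(successes)
  if (is.null(nms)) nms <- paste0("group", seq_len(k))
  raw <- matrix(NA_real_, k, k, dimnames = list(nms, nms))
  pairs <- utils::combn(k, 2L)
  pvals <- rep(NA_real_, ncol(pairs))
  for (idx in seq_len(ncol(pairs))) {
    i <- pairs[1L, idx]; j <- pairs[2L, idx]
    if (totals[i] == 0 || totals[j] == 0) next
    pvals[idx] <- suppressWarnings(
      stats::prop.test(c(successes[i], successes[j]),
                       c(totals[i], totals[j]), correct = yates)$p.value)
  }
  for (idx in seq_len(ncol(pairs))) {
    raw[pairs[1L, idx], pairs[2L, idx]] <- pvals[idx]
    raw[pairs[2L, idx], pairs[1L, idx]] <- pvals[idx]
  }
  adj <- raw
  if (correction == "bonferroni") {
    m <- sum(!is.na(pvals))
    adj[] <- pmin(1, raw * m)
  }
  attr(adj, "uncorrected") <- raw
  attr(adj, "correction") <- correction
  adj
}

#' Shannon diversity of one sample
#'
#' `-sum(p_i ln p_i)` over taxa with nonzero counts (natural log).
#'
#' @param counts numeric vector of per-taxon reads.
#' @return Shannon index, `NA` when the sample has zero reads.
#' @export
shannon <- function(counts) {
  if (sum(counts) == 0) return(NA_real_)
  unname(vegan::diversity(counts, index = "shannon"))
}

#' Number of observed sequence variants in one sample
#'
#' @param counts numeric vector of per-taxon reads.
#' @return integer count of taxa with reads.
#' @export
observed_asvs <- function(counts) {
  sum(counts > 0)
}

#' Faith's phylogenetic diversity
#'
#' Total branch length of the minimal subtree connecting the present tips;
#' when `include_root = TRUE` (the rooted-PD convention, the default) the
#' path from the spanning subtree up to the root is included.
#'
#' @param present_taxa character vector of present tip labels.
#' @param tree rooted `phylo` tree with branch lengths.
#' @param include_root logical; include the root path.
#' @return Faith's PD (0 for an empty set).
#' @export
faith_pd <- function(present_taxa, tree, include_root = TRUE) {
  present_taxa <- unique(as.character(present_taxa))
  if (length(present_taxa) == 0L) return(0)
  unknown <- setdiff(present_taxa, tree$tip.label)
  if (length(unknown) > 0L) {
    stop("tip label(s) not in tree: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!ape::is.rooted(tree)) {
    # basal polytomies are resolved with zero-length edges, which leaves
    # every spanning-subtree branch-length sum unchanged
    tree <- ape::multi2di(tree, random = FALSE)
  }
  samp <- matrix(as.integer(tree$tip.label %in% present_taxa), nrow = 1L,
                 dimnames = list("s", tree$tip.label))
  res <- picante::pd(samp, tree, include.root = include_root)
  unname(res$PD[1L])
}

#' Alpha-diversity summary per sample
#'
#' @param ct a [community_count_table()].
#' @param tree optional `phylo` whose tip labels are taxa of `ct`; adds
#'   Faith's PD.
#' @param include_root as in [faith_pd()].
#' @return data.frame with `sample`, `method`, `shannon`,
#'   `observed_asvs` and (when a tree is given) `faith_pd`.
#' @export
alpha_diversity <- function(ct, tree = NULL, include_root = TRUE) {
  out <- data.frame(
    sample = ct$meta$sample, method = ct$meta$method,
    shannon = apply(ct$counts, 1L, shannon),
    observed_asvs = apply(ct$counts, 1L, observed_asvs),
    stringsAsFactors = FALSE
  )
  if (!is.null(tree)) {
    out$faith_pd <- vapply(seq_len(nrow(ct$counts)), function(i) {
      present <- colnames(ct$counts)[ct$counts[i, ] > 0]
      present <- intersect(present, tree$tip.label)
      faith_pd(present, tree, include_root)
    }, numeric(1L))
  }
  rownames(out) <- NULL
  out
}

#' Relative fluorescence intensity normalized to a per-trial control
#'
#' Within each replicate trial, every dose's measurement is divided by that
#' trial's control (no-blocker) measurement, so the control sits at 1.0 by
#' construction; per-dose mean and standard deviation are then taken over
#' trials.
#'
#' @param values data.frame with columns `trial`, `dose`, `value`.
#' @param control_dose the dose label of the no-blocker control.
#' @return data.frame with `dose`, `n`, `mean_relative`, `sd_relative`.
#' @export
relative_intensity <- function(values, control_dose = "0") {
  need <- c("trial", "dose", "value")
  if (!all(need %in% names(values))) {
    stop("values must have columns trial, dose, value", call. = FALSE)
  }
  values$dose <- as.character(values$dose)
  trials <- unique(values$trial)
  rel <- do.call(rbind, lapply(trials, function(tr) {
    v <- values[values$trial == tr, ]
    ctrl <- v$value[v$dose == control_dose]
    if (length(ctrl) != 1L || is.na(ctrl) || ctrl <= 0) {
      stop(sprintf("trial '%s' lacks a positive control measurement", tr),
           call. = FALSE)
    }
    v$relative <- v$value / ctrl
    v
  }))
  doses <- unique(values$dose)
  out <- do.call(rbind, lapply(doses, function(d) {
    r <- rel$relative[rel$dose == d]
    data.frame(dose = d, n = length(r), mean_relative = mean(r),
               sd_relative = stats::sd(r), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Top taxa by relative abundance, with exclusions
#'
#' Taxa whose lineage starts with any excluded prefix are removed; the rest
#' are sorted by descending abundance with ties broken lexicographically.
#'
#' @param abundances named numeric vector (names = lineage strings).
#' @param n number of taxa to keep.
#' @param exclude character vector of lineage prefixes to drop (e.g. the
#'   host lineage and an explicit unclassified-eukaryote lineage).
#' @return data.frame with `taxon` and `abundance`, at most `n` rows.
#' @export
top_taxa <- function(abundances, n = 10L, exclude = character()) {
  stopifnot(all(abundances >= 0))
  keep <- rep(TRUE, length(abundances))
  for (pre in exclude) {
    keep <- keep & !startsWith(names(abundances), pre)
  }
  ab <- abundances[keep]
  ord <- order(-ab, names(ab))
  ab <- ab[ord][seq_len(min(n, length(ab)))]
  data.frame(taxon = names(ab), abundance = unname(ab),
             stringsAsFactors = FALSE)
}
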