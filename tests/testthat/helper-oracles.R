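# Independent brute-force oracles, written as literal transcriptions that
# share no code with the package implementation.

ORC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"), `-` = character()
)

ORC_COMP <- c(A = "T", C = "G", G = "C", T = "A")

orc_chars <- function(s) strsplit(toupper(s), "", fixed = TRUE)[[1L]]

orc_compat <- function(a, b) {
  length(intersect(ORC_EXPANSION[[a]], ORC_EXPANSION[[b]])) > 0L
}

orc_revcomp <- function(s) {
  chars <- orc_chars(s)
  out <- vapply(rev(chars), function(ch) {
    set <- ORC_EXPANSION[[ch]]
    comp_set <- sort(unname(ORC_COMP[set]))
    hit <- vapply(names(ORC_EXPANSION), function(code) {
      identical(sort(ORC_EXPANSION[[code]]), comp_set)
    }, logical(1L))
    names(ORC_EXPANSION)[hit][1L]
  }, character(1L))
  paste(out, collapse = "")
}

orc_count_mm <- function(a, b) {
  ca <- orc_chars(a); cb <- orc_chars(b)
  stopifnot(length(ca) == length(cb))
  n <- 0L
  for (i in seq_along(ca)) if (!orc_compat(ca[i], cb[i])) n <- n + 1L
  n
}

# every window on both strands with mismatches <= max_mm
orc_find_sites <- function(seq, primer, max_mm) {
  s <- orc_chars(seq)
  L <- nchar(primer)
  n <- length(s)
  hits <- list()
  if (L <= n) {
    rc <- orc_revcomp(primer)
    for (i in 0:(n - L)) {
      win <- paste(s[(i + 1):(i + L)], collapse = "")
      mm_p <- orc_count_mm(primer, win)
      if (mm_p <= max_mm) {
        hits[[length(hits) + 1L]] <- data.frame(
          start = i, end = i + L, strand = "+", mismatches = mm_p,
          three_prime_pos = i + L - 1L)
      }
      mm_m <- orc_count_mm(rc, win)
      if (mm_m <= max_mm) {
        hits[[length(hits) + 1L]] <- data.frame(
          start = i, end = i + L, strand = "-", mismatches = mm_m,
          three_prime_pos = i)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), mismatches = integer(),
                      three_prime_pos = integer()))
  }
  out <- do.call(rbind, hits)
  out[order(out$start, out$strand), , drop = FALSE]
}

# exhaustive antiparallel self-alignment pairing count plus best hairpin
orc_selfcomp <- function(s, loop_min = 3L) {
  ch <- orc_chars(s)
  n <- length(ch)
  can_pair <- function(i, j) {
    any(outer(ORC_EXPANSION[[ch[i]]], ORC_EXPANSION[[ch[j]]],
              function(x, y) ORC_COMP[x] == y))
  }
  best <- 0L
  for (shift in (-(n - 1L)):(n - 1L)) {
    cnt <- 0L
    for (i in 1:n) {
      j <- n + 1L - i + shift
      if (j >= 1L && j <= n && can_pair(i, j)) cnt <- cnt + 1L
    }
    best <- max(best, cnt)
  }
  hp <- 0L
  for (i in 1:n) {
    for (j in 1:n) {
      if (j - i - 1L < loop_min) next
      k <- 0L
      while (i - k >= 1L && j + k <= n && can_pair(i - k, j + k)) {
        k <- k + 1L
      }
      hp <- max(hp, k)
    }
  }
  list(score = best, hairpin = hp)
}

# second literal transcription of the unified nearest-neighbor Tm (all 16
# dimers written out, expected-count salt correction, duplex equation)
ORC_NN_DH <- c(
  AA = -7.9, AC = -8.4, AG = -7.8, AT = -7.2,
  CA = -8.5, CC = -8.0, CG = -10.6, CT = -7.8,
  GA = -8.2, GC = -9.8, GG = -8.0, GT = -8.4,
  TA = -7.2, TC = -8.2, TG = -8.5, TT = -7.9)
ORC_NN_DS <- c(
  AA = -22.2, AC = -22.4, AG = -21.0, AT = -20.4,
  CA = -22.7, CC = -19.9, CG = -27.2, CT = -21.0,
  GA = -22.2, GC = -24.4, GG = -19.9, GT = -22.4,
  TA = -21.3, TC = -22.2, TG = -22.7, TT = -22.2)

orc_tm_nn <- function(s, na_molar = 0.05, ct_molar = 2e-6) {
  ch <- orc_chars(s)
  n <- length(ch)
  dh <- 0; ds <- 0
  for (i in 1:(n - 1L)) {
    dim <- paste0(ch[i], ch[i + 1L])
    dh <- dh + ORC_NN_DH[[dim]]
    ds <- ds + ORC_NN_DS[[dim]]
  }
  for (pos in c(1L, n)) {
    if (ch[pos] == "A" || ch[pos] == "T") {
      dh <- dh + 2.3; ds <- ds + 4.1
    } else {
      dh <- dh + 0.1; ds <- ds - 2.8
    }
  }
  palindrome <- identical(paste(ch, collapse = ""), orc_revcomp(
    paste(ch, collapse = "")))
  x <- if (palindrome) 1 else 4
  if (palindrome) ds <- ds - 1.4
  ds <- ds + 0.368 * (n - 1L) * log(na_molar)
  dh * 1000 / (ds + 1.987 * log(ct_molar / x)) - 273.15
}

# literal Pearson chi-square on the 2x2 table with continuity correction,
# mirroring the classical equal-proportions test
orc_prop_p <- function(x1, n1, x2, n2, yates = TRUE) {
  obs <- matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2L, byrow = TRUE)
  N <- sum(obs)
  expd <- outer(rowSums(obs), colSums(obs)) / N
  corr <- if (yates) min(0.5, abs(obs[1, 1] - expd[1, 1])) else 0
  chi <- sum((abs(obs - expd) - corr)^2 / expd)
  stats::pchisq(chi, df = 1L, lower.tail = FALSE)
}

# naive edge-marking Faith's PD: union of root paths of the present tips
orc_faith_pd <- function(tips, tree) {
  if (length(tips) == 0L) return(0)
  tip_idx <- match(tips, tree$tip.label)
  parent_of <- integer(max(tree$edge))
  len_of <- numeric(max(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    parent_of[tree$edge[e, 2L]] <- tree$edge[e, 1L]
    len_of[tree$edge[e, 2L]] <- tree$edge.length[e]
  }
  root <- length(tree$tip.label) + 1L
  marked <- logical(max(tree$edge))
  for (t in tip_idx) {
    node <- t
    while (node != root) {
      marked[node] <- TRUE
      node <- parent_of[node]
    }
  }
  sum(len_of[marked])
}

# brute-force in-silico PCR: every properly oriented site pair within max_len
orc_insilico <- function(seq, fwd, rev, max_mm, max_len) {
  fs <- orc_find_sites(seq, fwd, max_mm)
  rs <- orc_find_sites(seq, rev, max_mm)
  out <- list()
  for (i in seq_len(nrow(fs))) {
    for (j in seq_len(nrow(rs))) {
      f <- fs[i, ]; r <- rs[j, ]
      ok_sense <- f$strand == "+" && r$strand == "-" &&
        r$start >= f$end && r$end - f$start <= max_len
      ok_anti <- f$strand == "-" && r$strand == "+" &&
        f$start >= r$end && f$end - r$start <= max_len
      if (ok_sense || ok_anti) {
        out[[length(out) + 1L]] <- data.frame(
          start = min(f$start, r$start), end = max(f$end, r$end))
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(), end = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$end), , drop = FALSE]
}

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# expand a degenerate string into all concrete variants (recursive)
orc_expand_seq <- function(s) {
  ch <- orc_chars(s)
  out <- ""
  for (c0 in ch) {
    out <- as.vector(outer(out, ORC_EXPANSION[[c0]], paste0))
  }
  out
}

# minimal IUPAC code whose expansion equals the given base set
orc_minimal_code <- function(bases) {
  bases <- sort(unique(bases))
  for (code in names(ORC_EXPANSION)) {
    if (identical(sort(ORC_EXPANSION[[code]]), bases)) return(code)
  }
  stop("no code for base set")
}

orc_pna_tm <- function(concrete) {
  ch <- orc_chars(concrete)
  fpyr <- mean(ch %in% c("C", "T"))
  20.79 + 0.83 * orc_tm_nn(concrete) - 26.13 * fpyr + 0.44 * length(ch)
}

# brute-force window enumeration + four-criterion filter over host and
# exclusion regions (strings on the primer strand spanning the profiled
# region); mirrors the design contract with fully independent arithmetic
orc_design_filter <- function(host_regions, excl_regions, up, down,
                              lens, offs, min_excl_mm = 3L, tm_min = 70,
                              max_deg = 2L, selfcomp_max = 8L,
                              hairpin_max = 4L) {
  n_col <- up + down
  host_mat <- do.call(rbind, lapply(host_regions, orc_chars))
  out <- list()
  for (L in lens) {
    for (d in offs) {
      r_start <- d - L; r_end <- d - 1L
      if (r_start < -up || r_end > down - 1L) next
      cols <- (r_start + up + 1L):(r_end + up + 1L)
      cons <- character(length(cols))
      wild <- FALSE
      for (k in seq_along(cols)) {
        obs <- host_mat[, cols[k]]
        if (any(obs == "N" | obs == "-")) wild <- TRUE
        obs_bases <- unique(unlist(ORC_EXPANSION[obs[obs != "N" & obs != "-"]]))
        cons[k] <- orc_minimal_code(obs_bases)
      }
      cons_str <- paste(cons, collapse = "")
      deg <- sum(!cons %in% c("A", "C", "G", "T"))
      host_mm <- max(vapply(host_regions, function(h) {
        orc_count_mm(cons_str, substr(h, min(cols), max(cols)))
      }, integer(1L)))
      crit1 <- !wild && host_mm == 0L && deg <= max_deg
      excl_mm <- if (length(excl_regions) == 0L) NA_integer_ else {
        min(vapply(excl_regions, function(e) {
          orc_count_mm(cons_str, substr(e, min(cols), max(cols)))
        }, integer(1L)))
      }
      crit2 <- if (is.na(excl_mm)) NA else excl_mm >= min_excl_mm
      tm_pna <- min(vapply(orc_expand_seq(cons_str), orc_pna_tm,
                           numeric(1L)))
      crit3 <- tm_pna >= tm_min
      sc <- orc_selfcomp(cons_str)
      crit4 <- sc$score <= selfcomp_max && sc$hairpin <= hairpin_max
      out[[length(out) + 1L]] <- data.frame(
        length = L, offset_downstream = d, sequence = cons_str,
        host_max_mismatch = host_mm, exclusion_min_mismatch = excl_mm,
        degeneracy = deg,
        pass = isTRUE(crit1) && isTRUE(crit2) && isTRUE(crit3) &&
          isTRUE(crit4),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
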