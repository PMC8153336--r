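# Melting-temperature estimation and self-complementarity screening.
#
# DNA/DNA duplex Tm uses the unified nearest-neighbor parameter set
# (SantaLucia 1998) with the entropic monovalent-salt correction
# dS += 0.368 * (n - 1) * ln[Na+].  PNA/DNA Tm uses the published linear
# regression on the nearest-neighbor DNA Tm, pyrimidine fraction and length
# (Giesen et al. 1998).  LNA substitutions are modelled as additive
# per-position increments.  All coefficients live in `thermo_params()` and
# are user-overridable.

.NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
            CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
.NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
            CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)
.R_GAS <- 1.987  # cal / (mol K)

#' Thermodynamic parameter set
#'
#' Bundles the nearest-neighbor dimer table (kcal/mol enthalpies, cal/mol/K
#' entropies, keyed on the 10 unique Watson-Crick dimers), initiation terms,
#' solution conditions, the four PNA regression coefficients and the
#' per-base LNA Tm increments.
#'
#' @param nn_dh,nn_ds named numeric vectors over the 10 unique dimers.
#' @param init_at,init_gc per-terminus initiation `c(dH, dS)` for A/T and
#'   G/C terminal base pairs.
#' @param sym_ds entropy penalty applied to self-complementary duplexes.
#' @param monovalent_salt monovalent cation concentration (mol/L).
#' @param oligo_conc total oligo strand concentration (mol/L).  The default
#'   2e-6 corresponds to a 50 pmol clamp dose in a 25 uL PCR.
#' @param pna_coeffs numeric `c(intercept, tm_slope, fpyr, length)` of the
#'   PNA/DNA regression.
#' @param lna_increments named numeric Tm gain (degrees C) per LNA
#'   substitution, by base.
#' @return object of class `thermo_params`.
#' @export
thermo_params <- function(nn_dh = .NN_DH, nn_ds = .NN_DS,
                          init_at = c(dH = 2.3, dS = 4.1),
                          init_gc = c(dH = 0.1, dS = -2.8),
                          sym_ds = -1.4,
                          monovalent_salt = 0.05,
                          oligo_conc = 2e-6,
                          pna_coeffs = c(intercept = 20.79, tm_slope = 0.83,
                                         fpyr = -26.13, length = 0.44),
                          lna_increments = c(A = 4, C = 4, G = 4, T = 4)) {
  need <- names(.NN_DH)
  if (!all(need %in% names(nn_dh)) || !all(need %in% names(nn_ds))) {
    stop("nearest-neighbor table must contain all 10 unique dimers",
         call. = FALSE)
  }
  if (!is.numeric(monovalent_salt) || monovalent_salt <= 0) {
    stop("monovalent_salt must be > 0", call. = FALSE)
  }
  if (!is.numeric(oligo_conc) || oligo_conc <= 0) {
    stop("oligo_conc must be > 0", call. = FALSE)
  }
  if (length(pna_coeffs) != 4L) {
    stop("pna_coeffs must have 4 entries", call. = FALSE)
  }
  if (!all(c("A", "C", "G", "T") %in% names(lna_increments))) {
    stop("lna_increments must name all four bases", call. = FALSE)
  }
  structure(
    list(nn_dh = nn_dh, nn_ds = nn_ds, init_at = init_at, init_gc = init_gc,
         sym_ds = sym_ds, monovalent_salt = monovalent_salt,
         oligo_conc = oligo_conc, pna_coeffs = pna_coeffs,
         lna_increments = lna_increments),
    class = "thermo_params"
  )
}

# Dimer lookup with reverse-complement fallback (e.g. TT -> AA).
.nn_entry <- function(dimers, tab) {
  out <- tab[dimers]
  miss <- is.na(out)
  if (any(miss)) {
    out[miss] <- tab[vapply(dimers[miss], function(d) {
      reverse_complement(d)
    }, character(1L))]
  }
  unname(out)
}

# Tm of one concrete duplex, degrees C.
.tm_nn_concrete <- function(s, params) {
  chars <- .iupac_chars(s)
  n <- length(chars)
  dimers <- paste0(chars[-n], chars[-1L])
  dH <- sum(.nn_entry(dimers, params$nn_dh))
  dS <- sum(.nn_entry(dimers, params$nn_ds))
  for (term in chars[c(1L, n)]) {
    if (term %in% c("A", "T")) {
      dH <- dH + params$init_at[["dH"]]; dS <- dS + params$init_at[["dS"]]
    } else {
      dH <- dH + params$init_gc[["dH"]]; dS <- dS + params$init_gc[["dS"]]
    }
  }
  self_comp <- identical(s, reverse_complement(s))
  x <- 4
  if (self_comp) {
    dS <- dS + params$sym_ds
    x <- 1
  }
  dS <- dS + 0.368 * (n - 1) * log(params$monovalent_salt)
  1000 * dH / (dS + .R_GAS * log(params$oligo_conc / x)) - 273.15
}

.aggregate_policy <- function(values, policy) {
  switch(policy, min = min(values), max = max(values), mean = mean(values))
}

#' Nearest-neighbor DNA duplex melting temperature
#'
#' Computes `Tm = dH / (dS + R ln(C_T / x)) - 273.15` with the salt-corrected
#' entropy.  Degenerate sequences are expanded into their concrete variants
#' and aggregated under `policy` (default `"min"`, the conservative bound:
#' a degenerate clamp passes a threshold only if every variant does).
#'
#' @param s sequence (`degen_seq` or character), length >= 8.
#' @param params a [thermo_params()] object.
#' @param policy aggregation over degenerate expansions:
#'   `"min"`, `"max"` or `"mean"`.
#' @return melting temperature in degrees C.
#' @export
tm_nearest_neighbor <- function(s, params = thermo_params(),
                                policy = c("min", "max", "mean")) {
  policy <- match.arg(policy)
  if (seq_length(s) < 8L) {
    stop("nearest-neighbor Tm is unreliable below 8 nt", call. = FALSE)
  }
  variants <- expand_degenerate(s)
  .aggregate_policy(
    vapply(variants, .tm_nn_concrete, numeric(1L), params = params), policy)
}

#' PNA/DNA duplex melting temperature from the linear regression
#'
#' `Tm_PNA = c0 + c1 * Tm_DNA + c2 * f_pyr + c3 * length` with the
#' coefficients in `params$pna_coeffs`.
#'
#' @param tm_dna nearest-neighbor DNA/DNA Tm in degrees C.
#' @param length oligo length in bases (> 0).
#' @param pyrimidine_fraction fraction of C/T residues, in `[0, 1]`.
#' @param params a [thermo_params()] object.
#' @return estimated PNA/DNA Tm in degrees C.
#' @export
tm_pna_estimate <- function(tm_dna, length, pyrimidine_fraction,
                            params = thermo_params()) {
  if (length <= 0L) stop("length must be positive", call. = FALSE)
  if (pyrimidine_fraction < 0 || pyrimidine_fraction > 1) {
    stop("pyrimidine_fraction must lie in [0, 1]", call. = FALSE)
  }
  co <- unname(params$pna_coeffs)
  co[1L] + co[2L] * tm_dna + co[3L] * pyrimidine_fraction + co[4L] * length
}

#' LNA-substituted oligo melting temperature
#'
#' Adds the per-base increments in `params$lna_increments` for each
#' LNA-substituted position to the nearest-neighbor DNA Tm.  Positions are
#' 1-based indices into the sequence.
#'
#' @param s sequence (`degen_seq` or character).
#' @param lna_positions integer vector of substituted positions (1-based).
#' @param params a [thermo_params()] object.
#' @param policy aggregation over degenerate expansions.
#' @return estimated Tm in degrees C.
#' @export
tm_lna_estimate <- function(s, lna_positions, params = thermo_params(),
                            policy = c("min", "max", "mean")) {
  policy <- match.arg(policy)
  n <- seq_length(s)
  lna_positions <- as.integer(lna_positions)
  if (length(lna_positions) > 0L &&
      (any(lna_positions < 1L) || any(lna_positions > n))) {
    stop("lna_positions out of range", call. = FALSE)
  }
  variants <- expand_degenerate(s)
  vals <- vapply(variants, function(v) {
    chars <- .iupac_chars(v)
    .tm_nn_concrete(v, params) +
      sum(params$lna_increments[chars[lna_positions]])
  }, numeric(1L))
  .aggregate_policy(vals, policy)
}

#' Joint Tm estimate for a clamp candidate
#'
#' Convenience wrapper computing, per concrete expansion, the DNA
#' nearest-neighbor Tm, the PNA regression Tm (using that expansion's own
#' pyrimidine fraction) and, when `lna_positions` is given, the LNA
#' estimate; each is then aggregated under `policy`.
#'
#' @inheritParams tm_lna_estimate
#' @param lna_positions optional integer vector; `NULL` leaves `tm_lna` NA.
#' @return object of class `tm_estimate`: list with `tm_dna`, `tm_pna`,
#'   `tm_lna`, `method`, `degenerate_policy`.
#' @export
tm_estimate <- function(s, params = thermo_params(),
                        policy = c("min", "max", "mean"),
                        lna_positions = NULL) {
  policy <- match.arg(policy)
  n <- seq_length(s)
  if (n < 8L) stop("nearest-neighbor Tm is unreliable below 8 nt",
                   call. = FALSE)
  variants <- expand_degenerate(s)
  dna <- vapply(variants, .tm_nn_concrete, numeric(1L), params = params)
  pna <- vapply(seq_along(variants), function(i) {
    tm_pna_estimate(dna[i], n, pyrimidine_fraction(variants[i]), params)
  }, numeric(1L))
  lna <- if (is.null(lna_positions)) NA_real_ else {
    tm_lna_estimate(s, lna_positions, params, policy)
  }
  structure(
    list(tm_dna = .aggregate_policy(dna, policy),
         tm_pna = .aggregate_policy(pna, policy),
         tm_lna = lna,
         method = "nn_unified + pna_regression",
         degenerate_policy = policy),
    class = "tm_estimate"
  )
}

#' @export
print.tm_estimate <- function(x, ...) {
  cat(sprintf(
    "<tm_estimate> dna %.1f C | pna %.1f C | lna %s (policy %s)\n",
    x$tm_dna, x$tm_pna,
    if (is.na(x$tm_lna)) "-" else sprintf("%.1f C", x$tm_lna),
    x$degenerate_policy))
  invisible(x)
}

#' Self-complementarity and hairpin score
#'
#' `score` is the maximum number of complementary pairings over all
#' antiparallel ungapped alignments of the sequence against a second copy of
#' itself (every offset).  `hairpin` is the longest stem of an internal fold
#' whose loop spans at least `loop_min` unpaired residues.  Degenerate codes
#' pair optimistically: a position can pair if any expansion of one code
#' complements any expansion of the other.
#'
#' @param s sequence (`degen_seq` or character), length >= 2.
#' @param loop_min minimum hairpin loop length (default 3).
#' @return list with integer elements `score` and `hairpin`.
#' @examples
#' self_complementarity("ACGT")  # perfect palindrome: score 4
#' @export
self_complementarity <- function(s, loop_min = 3L) {
  chars <- .iupac_chars(s)
  n <- length(chars)
  if (n < 2L) stop("sequence too short to score", call. = FALSE)
  m <- unname(.IUPAC_MASK[chars])
  cm <- unname(.IUPAC_MASK[.IUPAC_COMP[chars]])
  # pair[i, j]: can residue i pair with residue j (antiparallel)?
  pair <- outer(m, cm, function(a, b) bitwAnd(a, b) > 0L)
  score <- 0L
  for (cc in 0:(2L * n - 2L)) {
    i <- max(0L, cc - n + 1L):min(n - 1L, cc)
    j <- cc - i
    score <- max(score, sum(pair[cbind(i + 1L, j + 1L)]))
  }
  hairpin <- 0L
  if (n >= loop_min + 2L) {
    for (i in 1:(n - loop_min - 1L)) {
      for (j in (i + loop_min + 1L):n) {
        k <- 0L
        while (i - k >= 1L && j + k <= n &&
               (j + k) - (i - k) - 1L >= loop_min &&
               pair[i - k, j + k]) {
          k <- k + 1L
        }
        hairpin <- max(hairpin, k)
      }
    }
  }
  list(score = as.integer(score), hairpin = as.integer(hairpin))
}
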