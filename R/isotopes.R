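# Aggregated (unit-mass) isotopologue envelopes at arbitrary 15N enrichment.
#
# An envelope is the distribution of a molecule's isotopologues aggregated
# by nominal-mass offset from the monoisotopic peak M. For a heavy peptide,
# M is the all-15N species and incomplete labeling produces satellite peaks
# at M-1, M-2, ... (one, two, ... residual 14N in label positions). At
# Orbitrap resolutions the 13C/15N/2H fine structure within a nominal-mass
# bin is not resolved, so each bin carries an intensity-weighted centroid
# mass rather than resolved fine structure.

# Internal distribution representation: list(offset0 = integer offset of the
# first bin, ab = abundances, wm = abundance-weighted sum of mass excess
# relative to the molecule's monoisotopic species).
.dist_one <- function(offsets, ab, dm) {
  o <- seq(min(offsets), max(offsets))
  a <- numeric(length(o))
  w <- numeric(length(o))
  a[offsets - min(offsets) + 1] <- ab
  w[offsets - min(offsets) + 1] <- ab * dm
  list(offset0 = min(offsets), ab = a, wm = w)
}

.dist_point <- function() .dist_one(0L, 1, 0)

# Convolve two offset distributions, tracking weighted mass excess.
.dist_conv <- function(d1, d2, trunc = 1e-12) {
  n1 <- length(d1$ab); n2 <- length(d2$ab)
  ab <- numeric(n1 + n2 - 1)
  wm <- numeric(n1 + n2 - 1)
  for (i in seq_len(n1)) {
    if (d1$ab[i] == 0 && d1$wm[i] == 0) next
    j <- i:(i + n2 - 1)
    ab[j] <- ab[j] + d1$ab[i] * d2$ab
    # E[m1 + m2] weighting: a1*w2 + w1*a2
    wm[j] <- wm[j] + d1$ab[i] * d2$wm + d1$wm[i] * d2$ab
  }
  off0 <- d1$offset0 + d2$offset0
  keep <- which(ab > trunc)
  if (length(keep)) {
    lo <- min(keep); hi <- max(keep)
    ab <- ab[lo:hi]; wm <- wm[lo:hi]; off0 <- off0 + lo - 1L
  }
  list(offset0 = as.integer(off0), ab = ab, wm = wm)
}

# dist^n by binary exponentiation.
.dist_pow <- function(d, n, trunc = 1e-12) {
  out <- .dist_point()
  while (n > 0) {
    if (n %% 2 == 1) out <- .dist_conv(out, d, trunc)
    d <- .dist_conv(d, d, trunc)
    n <- n %/% 2
  }
  out
}

# Single-atom offset distributions relative to the molecule's monoisotopic
# (lightest / all-15N-labeled) species.
.atom_dists <- function(p) {
  iso <- element_isotopes()
  mono <- .mono_masses()
  out <- list()
  for (el in unique(iso$element)) {
    sub <- iso[iso$element == el, ]
    sub <- sub[order(sub$mass), ]
    off <- as.integer(round(sub$mass - sub$mass[1]))
    out[[el]] <- .dist_one(off, sub$abundance, sub$mass - sub$mass[1])
  }
  # labeled nitrogen: monoisotopic species has 15N; a residual 14N sits one
  # nominal mass below, with probability (1 - p)
  dN <- .mass_15N() - mono[["N"]]
  out[["N_labeled"]] <- .dist_one(c(-1L, 0L), c(1 - p, p), c(-dN, 0))
  out
}

.envelope_dist <- function(comp, p, trunc = 1e-12) {
  atoms <- .atom_dists(p)
  d <- .dist_point()
  for (el in names(comp$counts)) {
    n <- comp$counts[[el]]
    if (n == 0) next
    if (el == "N") {
      if (comp$n_unlabeled_N > 0)
        d <- .dist_conv(d, .dist_pow(atoms[["N"]], comp$n_unlabeled_N, trunc),
                        trunc)
      if (comp$n_labeled_N > 0)
        d <- .dist_conv(d, .dist_pow(atoms[["N_labeled"]], comp$n_labeled_N,
                                     trunc), trunc)
    } else {
      d <- .dist_conv(d, .dist_pow(atoms[[el]], n, trunc), trunc)
    }
  }
  d
}

.dist_to_envelope <- function(d, comp, p) {
  offsets <- d$offset0 + seq_along(d$ab) - 1L
  ab <- d$ab
  # truncate to the most abundant bins until cumulative >= 1 - 1e-6,
  # keeping a contiguous offset range, then renormalize
  ord <- order(ab, decreasing = TRUE)
  ncum <- which(cumsum(ab[ord]) >= 1 - 1e-6)[1]
  if (is.na(ncum)) ncum <- length(ab)
  kept <- sort(ord[seq_len(ncum)])
  lo <- min(kept); hi <- max(kept)
  offsets <- offsets[lo:hi]
  centroid_dm <- d$wm[lo:hi] / d$ab[lo:hi]
  ab <- ab[lo:hi] / sum(ab[lo:hi])
  mono <- monoisotopic_mass(comp)
  z <- max(1L, comp$charge)
  structure(
    data.frame(offset = offsets,
               abundance = ab,
               mz = (mono + centroid_dm) / z),
    class = c("isotope_envelope", "data.frame"),
    enrichment = p, charge = comp$charge,
    monoisotopic_mass = mono)
}

#' Theoretical isotope envelope at a given 15N enrichment
#'
#' Computes the aggregated nominal-mass isotopologue distribution of a
#' composition: natural-abundance polynomial convolution over C, H, O, S and
#' unlabeled nitrogens, convolved with a Binomial(`n_labeled_N`, `p`)
#' distribution over the labeled nitrogen positions. Offsets are relative
#' to the monoisotopic species (all-15N for a heavy composition), so
#' incomplete labeling appears as satellite peaks at negative offsets.
#'
#' A light-channel composition has `n_labeled_N = 0`, so its envelope is the
#' plain natural-abundance distribution and `p` has no effect.
#'
#' @param comp An `elemental_composition`.
#' @param p 15N incorporation fraction in `[0, 1]`.
#' @param normalize `"sum"` (abundances sum to 1, default) or `"max"`
#'   (largest peak = 100, the display convention of isotope-plot tools).
#' @return An `isotope_envelope` data frame with columns `offset`,
#'   `abundance`, `mz`, and attributes `enrichment`, `charge`,
#'   `monoisotopic_mass`.
#' @export
envelope <- function(comp, p = 1.0, normalize = c("sum", "max")) {
  stopifnot(inherits(comp, "elemental_composition"))
  normalize <- match.arg(normalize)
  if (!is.finite(p) || p < 0 || p > 1)
    stop("enrichment p must lie in [0, 1]")
  env <- .dist_to_envelope(.envelope_dist(comp, p), comp, p)
  if (normalize == "max") env$abundance <- 100 * env$abundance / max(env$abundance)
  env
}

#' Exact brute-force envelope (test oracle)
#'
#' Enumerates every isotopologue of a small composition atom by atom,
#' aggregating exact masses, then bins by nominal-mass offset. Exponential
#' in atom count, so restricted to tiny molecules; serves as the
#' independent correctness oracle for [envelope()].
#'
#' @inheritParams envelope
#' @param max_atoms Enumeration bound (default 12 atoms).
#' @return An `isotope_envelope` data frame.
#' @export
brute_force_envelope <- function(comp, p = 1.0, max_atoms = 12L) {
  stopifnot(inherits(comp, "elemental_composition"))
  if (!is.finite(p) || p < 0 || p > 1) stop("enrichment p must lie in [0, 1]")
  n_atoms <- sum(comp$counts)
  if (n_atoms > max_atoms)
    stop("composition has ", n_atoms, " atoms; enumeration bound is ",
         max_atoms)
  iso <- element_isotopes()
  mono <- .mono_masses()
  # per-atom isotope choices: (probability, exact mass excess vs mono species)
  atom_choices <- list()
  for (el in names(comp$counts)) {
    n <- comp$counts[[el]]
    if (n == 0) next
    sub <- iso[iso$element == el, ]
    sub <- sub[order(sub$mass), ]
    nat <- list(prob = sub$abundance, dm = sub$mass - sub$mass[1])
    if (el == "N") {
      lab <- list(prob = c(1 - p, p),
                  dm = c(mono[["N"]] - .mass_15N(), 0))
      atom_choices <- c(atom_choices,
                        rep(list(nat), comp$n_unlabeled_N),
                        rep(list(lab), comp$n_labeled_N))
    } else {
      atom_choices <- c(atom_choices, rep(list(nat), n))
    }
  }
  # exact joint distribution over (rounded) exact masses
  states <- data.frame(prob = 1, dm = 0)
  for (ch in atom_choices) {
    prob <- as.vector(outer(ch$prob, states$prob))
    dm <- as.vector(outer(ch$dm, states$dm, `+`))
    key <- round(dm, 9)
    agg <- rowsum(prob, key)
    states <- data.frame(prob = as.vector(agg),
                         dm = as.numeric(rownames(agg)))
  }
  offs <- as.integer(round(states$dm))
  ab <- rowsum(states$prob, offs)
  wm <- rowsum(states$prob * states$dm, offs)
  offsets <- as.integer(rownames(ab))
  o <- order(offsets)
  d <- list(offset0 = min(offsets),
            ab = as.vector(ab)[o], wm = as.vector(wm)[o])
  # fill gaps so the contiguous representation holds
  full <- .dist_one(offsets[o], as.vector(ab)[o], 0)
  full$wm <- numeric(length(full$ab))
  full$wm[offsets[o] - full$offset0 + 1] <- as.vector(wm)[o]
  .dist_to_envelope(full, comp, p)
}

#' Fraction of the isotope cluster in the monoisotopic peak
#'
#' The share of a peptide's total isotope-cluster abundance carried by the
#' monoisotopic peak M at the stated enrichment. Dividing a measured M
#' intensity by this fraction scales it up to the whole envelope, which is
#' how satellite-peak abundance lost to incomplete labeling is restored
#' before ratio calculation.
#'
#' @inheritParams envelope
#' @return Fraction in `(0, 1]`.
#' @export
fraction_in_mono <- function(comp, p = 1.0) {
  env <- envelope(comp, p)
  f <- env$abundance[env$offset == 0]
  if (!length(f)) 0 else f
}

#' M-1 / M satellite ratio of a heavy envelope
#'
#' The abundance ratio of the first satellite peak (one residual 14N) to the
#' monoisotopic all-15N peak. Strictly decreasing in the enrichment `p`, so
#' an observed ratio pins down the labeling efficiency.
#'
#' @inheritParams envelope
#' @return Non-negative ratio.
#' @export
m1_over_m <- function(comp, p) {
  if (comp$n_labeled_N < 1)
    stop("M-1/M requires a heavy composition (n_labeled_N >= 1)")
  env <- envelope(comp, p)
  m <- env$abundance[env$offset == 0]
  m1 <- env$abundance[env$offset == -1]
  if (!length(m) || m == 0) stop("degenerate composition: no abundance at M")
  if (!length(m1)) m1 <- 0
  m1 / m
}
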