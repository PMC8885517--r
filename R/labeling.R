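# Labeling-efficiency estimation from observed heavy-peptide clusters.
#
# The M-1/M satellite ratio of a heavy peptide is strictly decreasing in the
# 15N incorporation fraction p, so each observed cluster can be inverted for
# p by bisection; the experiment-level efficiency is the mean over peptides
# (labeling within one experiment is close to constant, so examining a
# handful of peptides from different proteins suffices).

.EFF_LOWER <- 0.5
.EFF_UPPER <- 0.9999

#' Invert an observed M-1/M ratio to a labeling efficiency
#'
#' Finds the enrichment `p` whose theoretical satellite ratio matches the
#' observed one, by bisection on `[0.5, 0.9999]` to `|dp| < 1e-5`.
#' Enrichments below 50% put heavy and light clusters into overlap, where
#' this workflow does not apply, so observations outside the bracket are
#' clamped to its ends with a warning.
#'
#' @param observed_m1_over_m Observed M-1/M abundance ratio (>= 0).
#' @param comp Heavy-channel `elemental_composition` of the peptide.
#' @param tol Bisection tolerance on p.
#' @return Estimated enrichment fraction.
#' @export
invert_efficiency <- function(observed_m1_over_m, comp, tol = 1e-5) {
  if (!is.finite(observed_m1_over_m) || observed_m1_over_m < 0)
    stop("observed M-1/M ratio must be a finite non-negative number")
  lo <- .EFF_LOWER; hi <- .EFF_UPPER
  r_lo <- m1_over_m(comp, lo)   # large ratio at low p
  r_hi <- m1_over_m(comp, hi)
  if (observed_m1_over_m >= r_lo) {
    warning("observed M-1/M ratio implies enrichment below ", lo,
            "; clamped to ", lo)
    return(lo)
  }
  if (observed_m1_over_m <= r_hi) {
    warning("observed M-1/M ratio implies enrichment above ", hi,
            "; clamped to ", hi)
    return(hi)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (m1_over_m(comp, mid) > observed_m1_over_m) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Estimate experiment-wide labeling efficiency
#'
#' Inverts each observed heavy cluster's M-1/M ratio and averages the
#' per-peptide estimates. Peptides with monoisotopic mass below `max_mass`
#' (default 1500 Da) are preferred: for small peptides the monoisotopic peak
#' is the tallest in the cluster and the satellite ratio is measured most
#' reliably. The standard deviation is reported so heterogeneous labeling
#' (which violates the constant-efficiency assumption) can be detected.
#'
#' @param clusters A list of cluster measurements, each a list with elements
#'   `id` (character), `comp` (heavy `elemental_composition`) and
#'   `m1_over_m` (observed ratio).
#' @param max_mass Preferred-mass cutoff in Da; peptides above it are used
#'   only if none fall below. `NULL` disables the filter.
#' @return An `efficiency_estimate`: list with `p_hat` (mean), `sd`,
#'   `n_peptides` and `per_peptide` (data frame of id, mass, observed ratio,
#'   inverted p).
#' @export
estimate_experiment_efficiency <- function(clusters, max_mass = 1500) {
  if (!length(clusters)) stop("no clusters supplied")
  masses <- vapply(clusters, function(cl) monoisotopic_mass(cl$comp),
                   numeric(1))
  use <- rep(TRUE, length(clusters))
  if (!is.null(max_mass) && any(masses < max_mass)) use <- masses < max_mass
  p <- vapply(clusters[use], function(cl)
    invert_efficiency(cl$m1_over_m, cl$comp), numeric(1))
  ids <- vapply(clusters[use], function(cl)
    if (is.null(cl$id)) NA_character_ else as.character(cl$id), character(1))
  per <- data.frame(id = ids, mass = masses[use],
                    observed_m1_over_m = vapply(clusters[use],
                                                `[[`, numeric(1), "m1_over_m"),
                    p = p, stringsAsFactors = FALSE)
  structure(list(p_hat = mean(p),
                 sd = if (length(p) > 1) stats::sd(p) else NA_real_,
                 n_peptides = length(p),
                 per_peptide = per),
            class = "efficiency_estimate")
}

#' Estimate labeling efficiency directly from MS1 spectra
#'
#' For each heavy-channel identification, averages the MS1 scans around the
#' identifying retention time, measures the M and M-1 peaks of the heavy
#' cluster and inverts the observed satellite ratio. This automates the
#' manual measure-the-peaks procedure: no image measurement, the ratio is
#' read straight off the averaged spectrum.
#'
#' @param ids Identification table ([read_id_table()] format); only heavy
#'   (15N search) non-decoy rows are used.
#' @param scans An `ms1_scans` object.
#' @param window,resolution Averaging window and match resolution, as in
#'   [average_scans()].
#' @param max_mass Passed to [estimate_experiment_efficiency()].
#' @param p_ref Reference enrichment used to predict the M-1 centroid
#'   position (the centroid moves by well under the match tolerance across
#'   the 0.9-0.999 range, so any plausible value works).
#' @return An `efficiency_estimate`.
#' @export
estimate_efficiency_from_spectra <- function(ids, scans, window = c(-5, 15),
                                             resolution = 240000,
                                             max_mass = 1500, p_ref = 0.97) {
  sel <- ids$channel == "heavy" & !ids$decoy
  if (!any(sel)) stop("no heavy-channel identifications in the ID table")
  ids <- ids[sel, , drop = FALSE]
  clusters <- list()
  for (i in seq_len(nrow(ids))) {
    comp <- build_composition(peptide_ion(ids$sequence[i],
                                          ids$modifications[i],
                                          ids$charge[i], "heavy"))
    env <- envelope(comp, p_ref)
    slice <- average_scans(scans, ids$rt[i], window, resolution)
    m <- match_peak(slice, env$mz[env$offset == 0], resolution)$intensity
    m1mz <- env$mz[env$offset == -1]
    m1 <- if (length(m1mz)) match_peak(slice, m1mz, resolution)$intensity else 0
    if (m <= 0) next  # no signal at M: cluster unusable
    clusters[[length(clusters) + 1]] <-
      list(id = sprintf("%s/%d", ids$sequence[i], ids$charge[i]),
           comp = comp, m1_over_m = m1 / m)
  }
  if (!length(clusters))
    stop("no heavy cluster had measurable monoisotopic signal")
  estimate_experiment_efficiency(clusters, max_mass = max_mass)
}

#' @export
print.efficiency_estimate <- function(x, ...) {
  cat(sprintf("Labeling efficiency: %.4f (SD %.4f, n = %d peptides)\n",
              x$p_hat, x$sd, x$n_peptides))
  invisible(x)
}
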