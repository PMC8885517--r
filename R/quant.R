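# Per-peptide pair quantification: measure both channels' monoisotopic
# peaks from the same averaged MS1 slice, scale each by its
# fraction-in-monoisotopic-peak (so satellite abundance lost to incomplete
# labeling is restored), report the L/H ratio and per-channel cosine
# similarity quality scores.

#' Quantification run configuration
#'
#' Bundles the parameters of a quantification run. Defaults follow the
#' workflow's recommended settings: an asymmetric -5/+15 s RT averaging
#' window, a 240,000 matching resolution, intensity (peak height) mode, and
#' a cosine-similarity flagging threshold of 0.9 (flag only, nothing is
#' removed).
#'
#' @param p Labeling efficiency (15N enrichment fraction), as determined in
#'   the efficiency-estimation step.
#' @param window RT averaging window offsets in seconds.
#' @param resolution MS1 resolution used for matching and clustering.
#' @param mode `"intensity"` (mean peak height over the window) or `"area"`
#'   (trapezoidal integral of per-scan heights).
#' @param cs_threshold Pairs with a channel CS score below this are flagged.
#' @return A `run_config` list.
#' @export
run_config <- function(p, window = c(-5, 15), resolution = 240000,
                       mode = c("intensity", "area"), cs_threshold = 0.9) {
  mode <- match.arg(mode)
  if (!is.finite(p) || p <= 0 || p > 1) stop("labeling efficiency p must lie in (0, 1]")
  if (length(window) != 2 || window[2] <= window[1])
    stop("window must be c(before, after) with after > before")
  structure(list(p = p, window = as.numeric(window),
                 resolution = resolution, mode = mode,
                 cs_threshold = cs_threshold),
            class = "run_config")
}

#' Efficiency-corrected channel abundance
#'
#' Divides a measured monoisotopic intensity (or area) by the theoretical
#' fraction of the isotope cluster present in the monoisotopic peak, scaling
#' the measurement up to the whole envelope. For a heavy peptide under
#' incomplete labeling this restores the abundance sitting in the M-1, M-2,
#' ... satellites; without it heavy abundances are systematically
#' underestimated and L/H ratios biased high.
#'
#' @param measured Measured monoisotopic value (>= 0).
#' @param f_M Fraction of the envelope in the monoisotopic peak, in (0, 1].
#' @return Corrected abundance.
#' @export
corrected_abundance <- function(measured, f_M) {
  if (!is.finite(f_M) || f_M <= 0 || f_M > 1)
    stop("fraction in monoisotopic peak must lie in (0, 1]")
  measured / f_M
}

#' Cosine-similarity isotope-pattern score
#'
#' Cosine similarity between the observed and theoretical M, M+1, M+2
#' intensity vectors: 1.0 is a perfect pattern match, 0.0 orthogonal. The
#' score is scale-invariant, so it judges pattern shape, not abundance. The
#' theoretical vector must come from the enrichment-aware envelope — low
#' labeling efficiency changes the pattern substantially, and scoring
#' against a fully-labeled pattern would flag correctly-measured peptides.
#' A contaminated peak (co-eluting interference) distorts the pattern and
#' lowers the score.
#'
#' @param observed Length-3 non-negative vector (M, M+1, M+2 measured).
#' @param theoretical Length-3 non-negative vector from [envelope()].
#' @return Score in `[0, 1]`, or `NA` if the observed vector is all zero
#'   (no signal: undefined, deliberately distinct from a bad match of 0).
#' @export
cs_score <- function(observed, theoretical) {
  if (length(observed) != 3 || length(theoretical) != 3)
    stop("CS score compares the M, M+1, M+2 peaks: vectors of length 3")
  if (any(observed < 0) || any(theoretical < 0))
    stop("CS vectors must be non-negative")
  if (all(observed == 0)) return(NA_real_)
  if (all(theoretical == 0)) stop("theoretical pattern is all zero")
  s <- sum(observed * theoretical) /
    sqrt(sum(observed^2) * sum(theoretical^2))
  # proportional vectors must score exactly 1; guard the last-ulp wobble of
  # the square root before clamping into [0, 1]
  if (s > 1 - 1e-12) s <- 1
  min(max(s, 0), 1)
}

# Measure the observed cluster vector of one channel at the envelope's
# offsets. Intensity mode reads the averaged slice; area mode integrates
# per-scan heights.
.measure_cluster <- function(slice, scans, env, rt_center, config) {
  vapply(seq_len(nrow(env)), function(i) {
    if (config$mode == "area")
      peak_area(scans, env$mz[i], rt_center, config$window, config$resolution)
    else
      match_peak(slice, env$mz[i], config$resolution)$intensity
  }, numeric(1))
}

#' Quantify one light/heavy peptide pair
#'
#' Given one identification (from either search channel), derives the
#' counterpart ion, measures both channels' isotope clusters from the same
#' averaged MS1 slice, corrects each channel's monoisotopic measurement by
#' its fraction-in-mono, and reports the L/H ratio with per-channel CS
#' scores. Identification of a single channel is sufficient; if one channel
#' has no signal the ratio is the `Inf` / `0` sentinel (the one-sided case —
#' e.g. bait-IP proteins absent from the control — is retained, never
#' dropped). Low-CS pairs are flagged, never deleted.
#'
#' @param id One identification record (one row of [read_id_table()] as a
#'   list or one-row data frame).
#' @param scans An `ms1_scans` object.
#' @param config A [run_config()].
#' @return A `peptide_quant` list: identification fields plus `light_mono`,
#'   `heavy_mono`, `f_light`, `f_heavy`, `light_corrected`,
#'   `heavy_corrected`, `ratio` (L/H; `Inf`, `0` or `NA` sentinels),
#'   `cs_light`, `cs_heavy`, `flag_cs`, `intensity_sum`, observed cluster
#'   vectors and their offsets.
#' @export
quantify_pair <- function(id, scans, config) {
  id <- as.list(id)
  ion_id <- peptide_ion(id$sequence, id$modifications, id$charge, id$channel)
  ion_cp <- counterpart(ion_id)
  light_ion <- if (ion_id$channel == "light") ion_id else ion_cp
  heavy_ion <- if (ion_id$channel == "heavy") ion_id else ion_cp
  comp_l <- build_composition(light_ion)
  comp_h <- build_composition(heavy_ion)
  env_l <- envelope(comp_l, config$p)
  env_h <- envelope(comp_h, config$p)
  slice <- average_scans(scans, id$rt, config$window, config$resolution)
  obs_l <- .measure_cluster(slice, scans, env_l, id$rt, config)
  obs_h <- .measure_cluster(slice, scans, env_h, id$rt, config)
  f_l <- fraction_in_mono(comp_l, config$p)
  f_h <- fraction_in_mono(comp_h, config$p)
  mono_l <- obs_l[env_l$offset == 0]
  mono_h <- obs_h[env_h$offset == 0]
  cor_l <- corrected_abundance(mono_l, f_l)
  cor_h <- corrected_abundance(mono_h, f_h)
  ratio <- if (cor_l > 0 && cor_h > 0) cor_l / cor_h
           else if (cor_l > 0) Inf
           else if (cor_h > 0) 0
           else NA_real_
  cs3 <- function(obs, env) {
    sel <- match(0:2, env$offset)
    o <- ifelse(is.na(sel), 0, obs[sel])
    t <- ifelse(is.na(sel), 0, env$abundance[sel])
    cs_score(o, t)
  }
  cs_l <- cs3(obs_l, env_l)
  cs_h <- cs3(obs_h, env_h)
  flag <- (is.na(cs_l) | cs_l < config$cs_threshold) |
          (is.na(cs_h) | cs_h < config$cs_threshold)
  structure(list(
    sequence = id$sequence, modifications = id$modifications,
    charge = id$charge, rt = id$rt, accession = id$accession,
    channel = id$channel, file = id$file,
    light_mono = mono_l, heavy_mono = mono_h,
    f_light = f_l, f_heavy = f_h,
    light_corrected = cor_l, heavy_corrected = cor_h,
    ratio = ratio, cs_light = cs_l, cs_heavy = cs_h,
    flag_cs = flag,
    # CS is least reliable at low signal; the summed observed intensity lets
    # consumers down-weight weak patterns
    intensity_sum = sum(obs_l) + sum(obs_h),
    cluster_light = obs_l, cluster_heavy = obs_h,
    offsets_light = env_l$offset, offsets_heavy = env_h$offset),
    class = "peptide_quant")
}

#' Quantify all identified pairs in an experiment
#'
#' Deduplicates identifications to one quantification per (sequence,
#' modifications, charge, file) — when both channels were identified
#' independently, the higher-score identification anchors the RT window —
#' then runs [quantify_pair()] over the remainder.
#'
#' @param ids Identification table from [read_id_table()] (decoy rows are
#'   excluded from quantification).
#' @param scans An `ms1_scans` object.
#' @param config A [run_config()].
#' @return A `quant_table` data frame, one row per quantified pair.
#' @export
quantify_experiment <- function(ids, scans, config) {
  ids <- ids[!ids$decoy, , drop = FALSE]
  if (!nrow(ids)) stop("no target identifications to quantify")
  key <- paste(ids$sequence, ids$modifications, ids$charge, ids$file,
               sep = "\r")
  ids <- ids[order(key, -ids$score), , drop = FALSE]
  ids <- ids[!duplicated(paste(ids$sequence, ids$modifications, ids$charge,
                               ids$file, sep = "\r")), , drop = FALSE]
  rows <- lapply(seq_len(nrow(ids)), function(i)
    quantify_pair(ids[i, ], scans, config))
  scalar <- c("sequence", "modifications", "charge", "rt", "accession",
              "channel", "file", "light_mono", "heavy_mono", "f_light",
              "f_heavy", "light_corrected", "heavy_corrected", "ratio",
              "cs_light", "cs_heavy", "flag_cs", "intensity_sum")
  out <- as.data.frame(lapply(stats::setNames(scalar, scalar), function(f)
    unlist(lapply(rows, `[[`, f))), stringsAsFactors = FALSE)
  class(out) <- c("quant_table", "data.frame")
  attr(out, "config") <- unclass(config)
  out
}
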