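# MS1 spectrum access: mzML reading (via mzR), retention-time window
# averaging, and resolution-based peak matching with a strict zero-noise
# contract (an absent peak contributes exactly 0; nothing is imputed from
# local noise).

#' Read MS1 scans from an mzML file
#'
#' Loads all MS-level-1 scans with retention times normalized to seconds.
#' Data must be centroided: quantification matches discrete peak centroids,
#' so profile-mode spectra are rejected with a pointer to re-export
#' (e.g. msconvert with peak picking) rather than silently mis-measured.
#'
#' @param path Path to an mzML file.
#' @return An `ms1_scans` object: list of scans, each `list(rt, peaks)` with
#'   `peaks` a two-column matrix (`mz`, `intensity`), sorted by rt.
#' @export
read_ms1 <- function(path) {
  if (!file.exists(path)) stop("mzML file not found: ", path)
  f <- mzR::openMSfile(path)
  on.exit(mzR::close(f))
  hdr <- mzR::header(f)
  ms1 <- which(hdr$msLevel == 1L)
  if (!length(ms1)) stop("no MS1 scans in ", path)
  cen <- hdr$centroided[ms1]
  if (any(!is.na(cen) & !cen))
    stop("profile-mode MS1 spectra in ", path,
         "; centroid the data first (e.g. msconvert peakPicking)")
  scans <- lapply(ms1, function(i) {
    pk <- mzR::peaks(f, i)
    colnames(pk) <- c("mz", "intensity")
    list(rt = hdr$retentionTime[i], peaks = pk)
  })
  scans <- scans[order(vapply(scans, `[[`, numeric(1), "rt"))]
  structure(scans, class = "ms1_scans")
}

.fwhm <- function(mz, resolution) mz / resolution

#' Average MS1 scans over a retention-time window
#'
#' Pools the centroided peaks of every MS1 scan inside
#' `[rt_center + window[1], rt_center + window[2]]` and clusters them on the
#' m/z axis with the same FWHM/2 tolerance used for peak matching. Each
#' cluster's intensity is the summed intensity divided by the number of
#' scans in the window (the mean across all window scans, so a peak present
#' in half the scans averages to half its height); its m/z is the
#' intensity-weighted centroid.
#'
#' The default window is asymmetric (-5 s / +15 s around the identifying
#' MS2 scan): chromatographic peaks are ~30 s wide, and a narrow window
#' nearly always contains the elution apex while limiting exposure to
#' co-eluting interference.
#'
#' @param scans An `ms1_scans` object (or list of `list(rt, peaks)`).
#' @param rt_center Window center in seconds (typically the MS2 scan rt).
#' @param window Numeric length-2 offset vector in seconds, default `c(-5, 15)`.
#' @param resolution Instrument resolution used for m/z clustering.
#' @return A `spectrum_slice`: list with `peaks` (mz/intensity matrix),
#'   `rt_window`, `n_scans_averaged`.
#' @export
average_scans <- function(scans, rt_center, window = c(-5, 15),
                          resolution = 240000) {
  rts <- vapply(scans, `[[`, numeric(1), "rt")
  lo <- rt_center + window[1]; hi <- rt_center + window[2]
  inside <- which(rts >= lo & rts <= hi)
  if (!length(inside))
    stop(sprintf("no MS1 scans in RT window [%.1f, %.1f] s", lo, hi))
  pooled <- do.call(rbind, lapply(scans[inside], `[[`, "peaks"))
  o <- order(pooled[, "mz"])
  mz <- pooled[o, "mz"]; int <- pooled[o, "intensity"]
  # cluster: break wherever the gap to the previous peak exceeds FWHM/2
  brk <- c(TRUE, diff(mz) > .fwhm(mz[-1], resolution) / 2)
  grp <- cumsum(brk)
  sum_int <- rowsum(int, grp)
  wmz <- rowsum(int * mz, grp) / ifelse(sum_int > 0, sum_int, 1)
  n <- length(inside)
  peaks <- cbind(mz = as.vector(wmz), intensity = as.vector(sum_int) / n)
  peaks <- peaks[peaks[, "intensity"] > 0, , drop = FALSE]
  structure(list(peaks = peaks, rt_window = c(lo, hi),
                 n_scans_averaged = n),
            class = "spectrum_slice")
}

#' Match a target m/z in a spectrum slice
#'
#' Finds the peak nearest to `target_mz` within half the FWHM implied by
#' the stated resolution (`FWHM = target_mz / resolution`). Ties on distance
#' break toward the higher-intensity peak. An absent peak yields a zeroed
#' measurement — intensity exactly 0, never an imputed noise floor — which
#' is a valid result, not an error.
#'
#' @param slice A `spectrum_slice` (or any list with a `peaks` matrix).
#' @param target_mz Expected centroid m/z.
#' @param resolution Instrument resolution (default 240000; a high setting
#'   gives a tight match tolerance and more consistent quantification).
#' @return A `peak_measurement`: list with `target_mz`, `matched_mz`
#'   (NA if absent), `intensity` (0 if absent) and `ppm_error` (NA if absent).
#' @export
match_peak <- function(slice, target_mz, resolution = 240000) {
  stopifnot(resolution > 0)
  tol <- .fwhm(target_mz, resolution) / 2
  pk <- slice$peaks
  absent <- list(target_mz = target_mz, matched_mz = NA_real_,
                 intensity = 0, ppm_error = NA_real_)
  if (is.null(pk) || !nrow(pk)) return(structure(absent, class = "peak_measurement"))
  d <- abs(pk[, "mz"] - target_mz)
  cand <- which(d <= tol)
  if (!length(cand)) return(structure(absent, class = "peak_measurement"))
  dmin <- min(d[cand])
  best <- cand[d[cand] <= dmin + 1e-12]
  if (length(best) > 1) best <- best[which.max(pk[best, "intensity"])]
  mz_best <- unname(pk[best, "mz"])
  structure(list(target_mz = target_mz,
                 matched_mz = mz_best,
                 intensity = unname(pk[best, "intensity"]),
                 ppm_error = (mz_best - target_mz) / target_mz * 1e6),
            class = "peak_measurement")
}

# Per-scan matched heights of a target m/z across an RT window; used for
# trapezoidal peak areas.
.scan_trace <- function(scans, target_mz, rt_center, window, resolution) {
  rts <- vapply(scans, `[[`, numeric(1), "rt")
  inside <- which(rts >= rt_center + window[1] & rts <= rt_center + window[2])
  h <- vapply(inside, function(i) {
    match_peak(list(peaks = scans[[i]]$peaks), target_mz, resolution)$intensity
  }, numeric(1))
  list(rt = rts[inside], height = h)
}

#' Trapezoidal peak area over the RT window
#'
#' Integrates the per-scan matched heights of a target m/z across the
#' averaging window (trapezoid rule, units intensity x seconds). Scans where
#' the peak is absent contribute exactly zero.
#'
#' @inheritParams average_scans
#' @param target_mz Expected centroid m/z.
#' @return Non-negative area.
#' @export
peak_area <- function(scans, target_mz, rt_center, window = c(-5, 15),
                      resolution = 240000) {
  tr <- .scan_trace(scans, target_mz, rt_center, window, resolution)
  if (length(tr$rt) < 2) return(sum(tr$height))
  sum(diff(tr$rt) * (utils::head(tr$height, -1) + utils::tail(tr$height, -1)) / 2)
}

.ID_COLUMNS <- c("sequence", "modifications", "charge", "rt", "accession",
                 "channel", "score", "decoy", "file")

#' Read a peptide-identification table
#'
#' Reads the TSV exported from the identification stage: one row per
#' peptide-spectrum match with columns `sequence`, `modifications`
#' (`name@position;...`, empty for none), `charge`, `rt` (seconds, of the
#' identifying MS2 scan), `accession`, `channel` (`14N`/`light` or
#' `15N`/`heavy` — which search identified it), `score`, `decoy`
#' (TRUE/FALSE) and `file`. Schema violations report the offending row and
#' column.
#'
#' @param path Path to a TSV file with one header line.
#' @return A data frame of validated identification records, with `channel`
#'   normalized to `light`/`heavy`.
#' @export
read_id_table <- function(path) {
  if (!file.exists(path)) stop("ID table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL,
                           colClasses = "character")
  missing_cols <- setdiff(.ID_COLUMNS, names(tab))
  if (length(missing_cols))
    stop("ID table missing column(s): ", paste(missing_cols, collapse = ", "))
  chan <- c("14N" = "light", light = "light", L = "light",
            "15N" = "heavy", heavy = "heavy", H = "heavy")
  bad <- which(!tab$channel %in% names(chan))
  if (length(bad))
    stop("row ", bad[1], ", column 'channel': unknown value '",
         tab$channel[bad[1]], "' (expected 14N/light or 15N/heavy)")
  tab$channel <- unname(chan[tab$channel])
  tab$charge <- suppressWarnings(as.integer(tab$charge))
  if (anyNA(tab$charge))
    stop("row ", which(is.na(tab$charge))[1],
         ", column 'charge': not an integer")
  tab$rt <- suppressWarnings(as.numeric(tab$rt))
  if (anyNA(tab$rt) || any(tab$rt < 0))
    stop("row ", which(is.na(tab$rt) | tab$rt < 0)[1],
         ", column 'rt': must be a non-negative number of seconds")
  tab$score <- suppressWarnings(as.numeric(tab$score))
  tab$decoy <- tab$decoy %in% c("TRUE", "true", "1", "T")
  tab$modifications[is.na(tab$modifications)] <- ""
  tab
}
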