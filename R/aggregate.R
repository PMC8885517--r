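# Protein-level statistics: log-space median and quartiles of peptide L/H
# ratios, mixing-ratio normalization, and per-channel target-decoy FDR.

#' Protein-level ratio statistics
#'
#' Compiles peptide L/H ratios into per-protein quartiles: the log of each
#' finite ratio is taken, Q1/median/Q3 of the logs computed (linear
#' interpolation between order statistics), and the results back-transformed
#' to linear ratios. The output is identical for any log base (a monotone
#' transform commutes with quantiles). The median is preferred over the mean
#' because occasional outlier peptide ratios — interference, mis-assigned
#' monoisotopic peaks — skew a mean badly but leave a median intact; a tight
#' Q1–Q3 range signals a reliable quantification.
#'
#' Sentinel ratios (`Inf` from a missing heavy channel, `0` from a missing
#' light channel, `NA`) cannot enter log-space statistics and are excluded
#' from them by default; their counts are reported so one-sided proteins
#' remain visible. A protein with no finite ratio is reported with `NA`
#' statistics rather than dropped.
#'
#' @param quants A `quant_table` from [quantify_experiment()].
#' @param use_flagged Include CS-flagged peptides in the statistics
#'   (default TRUE: flags are advisory, nothing is auto-removed).
#' @param iqr_flag_fold Flag proteins whose Q3/Q1 exceeds this fold spread.
#' @return A `protein_table` data frame: `accession`, `n_peptides`,
#'   `n_infinite`, `n_zero`, `q1`, `median`, `q3`, `intensity_sum`,
#'   `flag_wide_iqr`.
#' @export
protein_stats <- function(quants, use_flagged = TRUE, iqr_flag_fold = 2) {
  q <- quants
  if (!use_flagged) q <- q[!q$flag_cs, , drop = FALSE]
  if (!nrow(q)) stop("no peptide quantifications to aggregate")
  out <- do.call(rbind, lapply(split(q, q$accession), function(g) {
    r <- g$ratio
    finite <- r[is.finite(r) & r > 0]
    if (length(finite)) {
      qs <- 10^stats::quantile(log10(finite), c(0.25, 0.5, 0.75),
                               names = FALSE, type = 7)
    } else qs <- rep(NA_real_, 3)
    data.frame(accession = g$accession[1],
               n_peptides = length(finite),
               n_infinite = sum(is.infinite(r)),
               n_zero = sum(!is.na(r) & r == 0),
               q1 = qs[1], median = qs[2], q3 = qs[3],
               intensity_sum = sum(g$intensity_sum),
               flag_wide_iqr = is.finite(qs[1]) &&
                 qs[3] / qs[1] > iqr_flag_fold,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("protein_table", "data.frame")
  out
}

#' Normalize protein ratios for unequal sample mixing
#'
#' Light and heavy samples are rarely mixed at exactly 1:1, so protein
#' ratios carry a global mixing factor. The factor is estimated as the
#' median of the median ratios of the `top_n` most abundant quantified
#' proteins (default 100) — most proteins do not change, and the abundant
#' ones are quantified most precisely — and divided out of every protein's
#' quartiles. Alternatively a set of housekeeping accessions assumed
#' unchanged can define the factor.
#'
#' @param proteins A `protein_table` from [protein_stats()].
#' @param top_n Number of most-abundant proteins defining the factor.
#' @param rank_by Abundance metric for "top": `"intensity"` (summed cluster
#'   intensity over both channels) or `"n_peptides"`.
#' @param housekeeping Optional character vector of accessions; if given,
#'   the factor is the median of those proteins' medians instead.
#' @return The `protein_table` with `normalized_median`, `normalized_q1`,
#'   `normalized_q3` columns added and attribute `normalization_factor`.
#' @export
normalize_proteins <- function(proteins, top_n = 100,
                               rank_by = c("intensity", "n_peptides"),
                               housekeeping = NULL) {
  if (!nrow(proteins)) stop("empty protein table")
  rank_by <- match.arg(rank_by)
  has_med <- is.finite(proteins$median)
  if (!is.null(housekeeping)) {
    sel <- has_med & proteins$accession %in% housekeeping
    if (!any(sel)) stop("no quantified housekeeping proteins found")
  } else {
    cand <- which(has_med)
    if (length(cand) < top_n)
      warning("only ", length(cand), " quantified proteins; using all for ",
              "normalization (top_n = ", top_n, ")")
    metric <- switch(rank_by, intensity = proteins$intensity_sum,
                     n_peptides = proteins$n_peptides)
    sel <- cand[order(metric[cand], decreasing = TRUE)]
    sel <- sel[seq_len(min(top_n, length(sel)))]
  }
  factor <- stats::median(proteins$median[sel])
  proteins$normalized_q1 <- proteins$q1 / factor
  proteins$normalized_median <- proteins$median / factor
  proteins$normalized_q3 <- proteins$q3 / factor
  attr(proteins, "normalization_factor") <- factor
  proteins
}

#' Per-channel target-decoy FDR
#'
#' After a combined search is thresholded, the target and decoy matches of
#' the 14N and 15N searches are parsed separately and each channel's FDR
#' estimated as decoys/targets. 15N labeling gives residues non-standard
#' masses, so channel-wise FDR can differ from the combined figure.
#'
#' @param ids Identification table with `channel` and `decoy` columns.
#' @return A data frame: `channel`, `n_target`, `n_decoy`, `fdr_percent`
#'   (NA when a channel has no targets).
#' @export
fdr_split <- function(ids) {
  if (!all(c("channel", "decoy") %in% names(ids)))
    stop("ID table must have 'channel' and 'decoy' columns")
  out <- do.call(rbind, lapply(split(ids, ids$channel), function(g) {
    nt <- sum(!g$decoy); nd <- sum(g$decoy)
    data.frame(channel = g$channel[1], n_target = nt, n_decoy = nd,
               fdr_percent = if (nt > 0) 100 * nd / nt else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
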