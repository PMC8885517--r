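# Quantification cache and report writers. The cache is a versioned JSON
# document holding every peptide quantification and the run configuration —
# everything needed to regenerate the reports without re-opening the mzML,
# so reports come back in seconds instead of re-running hours of spectrum
# extraction.

.CACHE_SCHEMA <- "silia-cache-1"

# TSV-friendly, stable numeric formatting shared by both report paths so a
# cache-regenerated report is byte-identical to the original.
.fmt_num <- function(x) {
  out <- ifelse(is.na(x), "NA",
         ifelse(is.infinite(x) & x > 0, "Inf",
         ifelse(is.infinite(x), "-Inf", sprintf("%.6g", x))))
  out
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], .fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Write the peptide-level report
#'
#' One row per quantified pair: identification fields, corrected channel
#' abundances, L/H ratio, per-channel CS scores and flags.
#'
#' @param quants A `quant_table`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_peptide_report <- function(quants, path) {
  cols <- c("sequence", "modifications", "charge", "rt", "channel",
            "accession", "file", "light_corrected", "heavy_corrected",
            "ratio", "cs_light", "cs_heavy", "flag_cs", "intensity_sum")
  .write_tsv(as.data.frame(quants)[cols], path)
}

#' Write the protein-level report
#'
#' One row per protein: peptide counts (finite / one-sided), Q1, median and
#' Q3 of the L/H ratios, normalized values when present, and flags.
#'
#' @param proteins A `protein_table` (optionally normalized).
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_protein_report <- function(proteins, path) {
  .write_tsv(as.data.frame(proteins), path)
}

#' Write the quantification cache
#'
#' @param quants A `quant_table` from [quantify_experiment()].
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_cache <- function(quants, path) {
  q <- as.data.frame(quants)
  # JSON has no Inf/NaN literals; sentinel ratios travel as strings
  q$ratio <- as.character(q$ratio)
  doc <- list(schema_version = .CACHE_SCHEMA,
              config = attr(quants, "config"),
              quants = q)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = FALSE)
  invisible(path)
}

#' Read a quantification cache
#'
#' @param path Cache JSON path.
#' @return A `quant_table` with the run config attached, as written by
#'   [write_cache()]. A cache from a different schema version errors.
#' @export
read_cache <- function(path) {
  if (!file.exists(path)) stop("cache file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$schema_version) || doc$schema_version != .CACHE_SCHEMA)
    stop("cache schema version mismatch: found '", doc$schema_version,
         "', expected '", .CACHE_SCHEMA, "'")
  q <- doc$quants
  q$ratio <- as.numeric(q$ratio)
  class(q) <- c("quant_table", "data.frame")
  attr(q, "config") <- doc$config
  q
}

#' Regenerate reports from a cache
#'
#' Rebuilds the peptide and protein reports (and normalization) purely from
#' the cached quantifications; the mzML is never reopened.
#'
#' @param cache_path Cache JSON path.
#' @param out_prefix Prefix for `<prefix>_peptides.tsv` and
#'   `<prefix>_proteins.tsv`.
#' @param top_n,rank_by,housekeeping Passed to [normalize_proteins()].
#' @return Character vector of the two report paths, invisibly.
#' @export
regenerate_reports <- function(cache_path, out_prefix, top_n = 100,
                               rank_by = "intensity", housekeeping = NULL) {
  quants <- read_cache(cache_path)
  pep <- paste0(out_prefix, "_peptides.tsv")
  prot <- paste0(out_prefix, "_proteins.tsv")
  write_peptide_report(quants, pep)
  proteins <- protein_stats(quants)
  proteins <- normalize_proteins(proteins, top_n = top_n, rank_by = rank_by,
                                 housekeeping = housekeeping)
  write_protein_report(proteins, prot)
  invisible(c(peptides = pep, proteins = prot))
}
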