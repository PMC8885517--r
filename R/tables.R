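#' @keywords internal
"_PACKAGE"

# Bundled physical-constant and chemistry tables. All three are plain TSV
# under inst/extdata so users can inspect or extend them; they are loaded
# once per session into this cache.
.silia_tables <- new.env(parent = emptyenv())

.load_table <- function(name) {
  if (!is.null(.silia_tables[[name]])) return(.silia_tables[[name]])
  path <- system.file("extdata", paste0(name, ".tsv"), package = "silia",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  .silia_tables[[name]] <- tab
  tab
}

#' Element isotope masses and natural abundances
#'
#' One row per stable isotope of the elements that occur in unmodified and
#' modified peptides (C, H, N, O, S), ordered by mass within each element.
#' Masses are monoisotopic atomic masses in Da; abundances are natural
#' relative abundances summing to 1 per element.
#'
#' @return A data frame with columns `element`, `mass`, `abundance`.
#' @export
element_isotopes <- function() .load_table("elements")

#' Amino-acid residue elemental formulas
#'
#' Residue (water-subtracted) formulas for the 20 standard amino acids.
#' The `N` column doubles as the 15N label multiplicity of each residue in
#' a metabolic-labeling search: every residue nitrogen is labeled.
#'
#' @return A data frame with columns `residue`, `C`, `H`, `N`, `O`, `S`.
#' @export
residue_formulas <- function() .load_table("residues")

#' Supported peptide modifications
#'
#' Elemental deltas for the modifications supported in the identification
#' tables. `labeled_dN` is the change in the number of *labelable* nitrogen
#' positions: carbamidomethyl adds a nitrogen that always stays 14N (the
#' modification is introduced chemically after extraction, so its nitrogen
#' never sees the 15N medium), hence `labeled_dN = 0` while `N = 1`;
#' pyroglutamate formation and N-terminal Met loss each remove one residue
#' (labelable) nitrogen.
#'
#' Combination modifications (e.g. `Met-loss+Acetyl`) are expressed by
#' joining names with `+`.
#'
#' @return A data frame with columns `name`, `C`, `H`, `N`, `O`, `S`,
#'   `labeled_dN`.
#' @export
modification_deltas <- function() .load_table("modifications")

# Monoisotopic (lightest-isotope) mass per element, plus labeled-15N mass.
.mono_masses <- function() {
  iso <- element_isotopes()
  vapply(split(iso$mass, iso$element), min, numeric(1))
}

.mass_15N <- function() {
  iso <- element_isotopes()
  max(iso$mass[iso$element == "N"])
}

.PROTON_MASS <- 1.00727646688
.ELECTRON_MASS <- 0.00054857990

# Natural 15N abundance, used for unlabeled nitrogens and the light channel.
.natural_15N <- function() {
  iso <- element_isotopes()
  n <- iso[iso$element == "N", ]
  n$abundance[which.max(n$mass)]
}
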