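# Peptide elemental compositions and monoisotopic masses under the
# metabolic-labeling scheme: in the heavy channel every residue nitrogen is
# a 15N label position, while modification-introduced nitrogens (e.g. the
# carbamidomethyl amide) always carry natural-abundance nitrogen.

#' Construct an elemental composition
#'
#' An `elemental_composition` holds integer atom counts per element together
#' with the split of the nitrogen count into labeled (subject to 15N
#' enrichment) and unlabeled (always natural abundance) positions, and the
#' number of charge-carrier protons. Charge protons are included in the `H`
#' count, so the printed formula of a singly protonated peptide matches the
#' convention of displaying the ion formula (e.g. H82 for an ion whose
#' neutral form has 81 hydrogens).
#'
#' @param counts Named non-negative integer vector of atom counts
#'   (names are element symbols; C, H, N, O, S supported).
#' @param n_labeled_N Number of nitrogen positions subject to 15N labeling.
#' @param n_unlabeled_N Number of nitrogens fixed at natural abundance.
#' @param charge Number of charge-carrier protons (already included in `H`).
#' @return An object of class `elemental_composition`.
#' @export
elemental_composition <- function(counts, n_labeled_N = 0L,
                                  n_unlabeled_N = counts[["N"]] - n_labeled_N,
                                  charge = 0L) {
  counts <- counts[counts != 0 | names(counts) %in% c("C", "H", "N", "O", "S")]
  if (any(counts < 0)) stop("negative atom count in composition")
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("composition counts must be a named vector")
  n_tot <- if ("N" %in% names(counts)) counts[["N"]] else 0L
  if (n_labeled_N < 0 || n_unlabeled_N < 0 ||
      n_labeled_N + n_unlabeled_N != n_tot)
    stop("labeled + unlabeled nitrogen must equal the total N count")
  structure(list(counts = as.integer(round(counts)) |>
                   stats::setNames(names(counts)),
                 n_labeled_N = as.integer(n_labeled_N),
                 n_unlabeled_N = as.integer(n_unlabeled_N),
                 charge = as.integer(charge)),
            class = "elemental_composition")
}

#' @export
print.elemental_composition <- function(x, ...) {
  cc <- x$counts[x$counts > 0]
  cat(paste0(names(cc), cc, collapse = " "),
      sprintf(" [15N positions: %d labeled, %d unlabeled; charge %d+]\n",
              x$n_labeled_N, x$n_unlabeled_N, x$charge))
  invisible(x)
}

#' Element-wise composition arithmetic
#'
#' @param a,b `elemental_composition` objects.
#' @return An `elemental_composition`; subtraction errors if any count would
#'   go negative.
#' @export
comp_add <- function(a, b) {
  els <- union(names(a$counts), names(b$counts))
  ca <- stats::setNames(integer(length(els)), els)
  ca[names(a$counts)] <- a$counts
  cb <- stats::setNames(integer(length(els)), els)
  cb[names(b$counts)] <- b$counts
  elemental_composition(ca + cb,
                        n_labeled_N = a$n_labeled_N + b$n_labeled_N,
                        n_unlabeled_N = a$n_unlabeled_N + b$n_unlabeled_N,
                        charge = a$charge + b$charge)
}

#' @rdname comp_add
#' @export
comp_subtract <- function(a, b) {
  els <- union(names(a$counts), names(b$counts))
  ca <- stats::setNames(integer(length(els)), els)
  ca[names(a$counts)] <- a$counts
  cb <- stats::setNames(integer(length(els)), els)
  cb[names(b$counts)] <- b$counts
  elemental_composition(ca - cb,
                        n_labeled_N = a$n_labeled_N - b$n_labeled_N,
                        n_unlabeled_N = a$n_unlabeled_N - b$n_unlabeled_N,
                        charge = a$charge - b$charge)
}

#' Construct a peptide ion
#'
#' @param sequence Amino-acid string over the 20 standard one-letter codes.
#' @param modifications Modification string, `name@position` terms separated
#'   by `;`. Positions are 1-based residue indices or the keywords `Nterm` /
#'   `Cterm`. Combination modifications join names with `+`
#'   (e.g. `"Met-loss+Acetyl@Nterm"`). Empty string or `NA` means none.
#' @param charge Integer charge state (>= 0; 0 = neutral molecule).
#' @param channel `"light"` (14N growth) or `"heavy"` (15N growth).
#' @return An object of class `peptide_ion`.
#' @export
peptide_ion <- function(sequence, modifications = "", charge = 1L,
                        channel = c("light", "heavy")) {
  channel <- match.arg(channel)
  sequence <- toupper(sequence)
  aa <- strsplit(sequence, "")[[1]]
  known <- residue_formulas()$residue
  bad <- setdiff(aa, known)
  if (length(bad))
    stop("unknown residue code(s): ", paste(unique(bad), collapse = ", "))
  if (charge < 0) stop("charge must be >= 0")
  mods <- parse_modifications(modifications, nchar(sequence))
  structure(list(sequence = sequence, modifications = mods,
                 charge = as.integer(charge), channel = channel),
            class = "peptide_ion")
}

#' Parse a modification string
#'
#' @param spec Modification string (see [peptide_ion()]).
#' @param seq_length Peptide length, for validating positions.
#' @return A data frame with columns `name` and `position` (character:
#'   a digit string, `"Nterm"` or `"Cterm"`); zero rows if none.
#' @export
parse_modifications <- function(spec, seq_length) {
  if (is.null(spec) || is.na(spec) || !nzchar(trimws(spec)))
    return(data.frame(name = character(), position = character(),
                      stringsAsFactors = FALSE))
  terms <- trimws(strsplit(spec, ";", fixed = TRUE)[[1]])
  terms <- terms[nzchar(terms)]
  parts <- strsplit(terms, "@", fixed = TRUE)
  if (any(lengths(parts) != 2))
    stop("modification terms must be 'name@position': ",
         paste(terms[lengths(parts) != 2], collapse = "; "))
  name <- trimws(vapply(parts, `[[`, "", 1))
  pos <- trimws(vapply(parts, `[[`, "", 2))
  known <- modification_deltas()$name
  comps <- strsplit(name, "+", fixed = TRUE)
  bad <- setdiff(unlist(comps), known)
  if (length(bad))
    stop("unknown modification(s): ", paste(unique(bad), collapse = ", "),
         ". Supported: ", paste(known, collapse = ", "))
  numeric_pos <- grepl("^[0-9]+$", pos)
  bad_pos <- !numeric_pos & !pos %in% c("Nterm", "Cterm")
  if (any(bad_pos))
    stop("invalid modification position(s): ",
         paste(pos[bad_pos], collapse = ", "))
  idx <- suppressWarnings(as.integer(pos[numeric_pos]))
  if (any(idx < 1 | idx > seq_length))
    stop("modification position outside sequence (length ", seq_length, ")")
  data.frame(name = name, position = pos, stringsAsFactors = FALSE)
}

#' Nitrogen count (15N label multiplicity) of a residue
#'
#' Every residue nitrogen is a label position in metabolic 15N labeling, so
#' the number of nitrogens in a residue's formula equals its 15N label
#' multiplicity: 1 for most residues, 2 for K/N/Q/W, 3 for H, 4 for R.
#'
#' @param amino_acid One-letter residue code (vectorized).
#' @return Integer nitrogen count(s).
#' @export
residue_nitrogens <- function(amino_acid) {
  res <- residue_formulas()
  i <- match(toupper(amino_acid), res$residue)
  if (anyNA(i))
    stop("unknown residue code(s): ",
         paste(unique(amino_acid[is.na(i)]), collapse = ", "))
  as.integer(res$N[i])
}

.mod_total_delta <- function(mods) {
  tab <- modification_deltas()
  els <- c("C", "H", "N", "O", "S")
  delta <- stats::setNames(integer(5), els)
  labeled_dN <- 0L
  for (nm in mods$name) {
    for (part in strsplit(nm, "+", fixed = TRUE)[[1]]) {
      row <- tab[tab$name == part, ]
      delta <- delta + unlist(row[els])
      labeled_dN <- labeled_dN + row$labeled_dN
    }
  }
  list(delta = delta, labeled_dN = as.integer(labeled_dN))
}

#' Elemental composition of a peptide ion
#'
#' Sums residue formulas, one water, modification deltas and the
#' charge-carrier protons. For the heavy channel, `n_labeled_N` counts the
#' residue nitrogens (adjusted by label-removing modifications such as
#' pyroglutamate formation); modification-introduced nitrogens are counted
#' as unlabeled. For the light channel `n_labeled_N` is 0.
#'
#' @param ion A [peptide_ion()].
#' @return An `elemental_composition`.
#' @export
build_composition <- function(ion) {
  stopifnot(inherits(ion, "peptide_ion"))
  res <- residue_formulas()
  els <- c("C", "H", "N", "O", "S")
  aa <- strsplit(ion$sequence, "")[[1]]
  i <- match(aa, res$residue)
  counts <- stats::setNames(
    vapply(els, function(e) sum(res[[e]][i]), numeric(1)), els)
  counts["H"] <- counts["H"] + 2 + ion$charge  # water + charge protons
  counts["O"] <- counts["O"] + 1
  residue_N <- counts[["N"]]
  md <- .mod_total_delta(ion$modifications)
  counts <- counts + md$delta
  if (any(counts < 0))
    stop("modifications remove more atoms than the peptide has")
  labeled_if_heavy <- residue_N + md$labeled_dN
  n_lab <- if (ion$channel == "heavy") labeled_if_heavy else 0L
  elemental_composition(counts, n_labeled_N = n_lab,
                        n_unlabeled_N = counts[["N"]] - n_lab,
                        charge = ion$charge)
}

#' Monoisotopic mass of a composition
#'
#' Sum of lightest-isotope masses with each labeled nitrogen counted at the
#' 15N mass, minus one electron mass per charge proton (the `H` count
#' includes charge protons as whole hydrogen atoms). For a heavy composition
#' this is the mass of the all-15N species, the monoisotopic peak M of the
#' heavy isotope cluster.
#'
#' @param comp An `elemental_composition`.
#' @return Mass in Da.
#' @export
monoisotopic_mass <- function(comp) {
  stopifnot(inherits(comp, "elemental_composition"))
  mono <- .mono_masses()
  unknown <- setdiff(names(comp$counts)[comp$counts > 0], names(mono))
  if (length(unknown))
    stop("no isotope data for element(s): ", paste(unknown, collapse = ", "))
  m <- sum(comp$counts * mono[names(comp$counts)])
  # charge carriers are bare protons: swap each charge-accounting H atom
  # for the proton mass (removes the electron and its binding energy)
  m + comp$n_labeled_N * (.mass_15N() - mono[["N"]]) -
    comp$charge * (mono[["H"]] - .PROTON_MASS)
}

#' Mass-to-charge ratio of a composition
#'
#' @param comp An `elemental_composition` with `charge >= 1`.
#' @return Monoisotopic m/z.
#' @export
mono_mz <- function(comp) {
  if (comp$charge < 1) stop("m/z requires charge >= 1")
  monoisotopic_mass(comp) / comp$charge
}

#' Labeling counterpart of a peptide ion
#'
#' Same sequence, modifications and charge with the channel flipped; an
#' involution. The counterpart of an identified light peptide is the heavy
#' ion expected at `n_labeled_N * (m(15N) - m(14N)) / z` above it.
#'
#' @param ion A [peptide_ion()].
#' @return A `peptide_ion` in the opposite channel.
#' @export
counterpart <- function(ion) {
  stopifnot(inherits(ion, "peptide_ion"))
  ion$channel <- if (ion$channel == "light") "heavy" else "light"
  ion
}
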