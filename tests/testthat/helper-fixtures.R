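# Fixtures built in code: random small compositions for the enumeration
# oracle, random tryptic-like peptides, and the worked-example ion.

fig2_ion <- function(channel = "heavy", charge = 1L)
  peptide_ion("VALEACVQAR", "Carbamidomethyl@6", charge, channel)

# random composition with at most `max_atoms` atoms (for the brute-force
# oracle); labeled/unlabeled nitrogen split drawn at random
random_small_comp <- function(max_atoms = 12) {
  repeat {
    n <- sample(0:3, 5, replace = TRUE)
    names(n) <- c("C", "H", "N", "O", "S")
    if (sum(n) >= 1 && sum(n) <= max_atoms) break
  }
  n_lab <- if (n[["N"]] > 0) sample(0:n[["N"]], 1) else 0L
  elemental_composition(n, n_labeled_N = n_lab)
}

random_tryptic <- function(len = NULL) {
  if (is.null(len)) len <- sample(7:15, 1)
  res <- setdiff(residue_formulas()$residue, c("K", "R"))
  paste0(paste(sample(res, len - 1, replace = TRUE), collapse = ""),
         sample(c("K", "R"), 1))
}

random_peptide_comp <- function(channel = "heavy") {
  build_composition(peptide_ion(random_tryptic(), "", sample(1:3, 1), channel))
}
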