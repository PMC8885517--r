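# silia

Relative protein quantification for **¹⁵N metabolic labeling** experiments.

In whole-organism ¹⁵N labeling (SILIA — stable-isotope labeling *in*
Arabidopsis, and equivalently in algae or other organisms grown on
¹⁵N salts), one sample grows on natural-abundance nitrogen (light) and the
other on ¹⁵N (heavy), the samples are mixed at harvest, and every peptide
appears in MS¹ as a light/heavy pair separated by one ¹⁵N mass shift per
nitrogen atom. Unlike SILAC, *every* residue nitrogen is labeled, so the
pair spacing varies per peptide and — crucially — labeling is rarely
complete: at enrichment *p* < 1 the heavy isotope cluster grows satellite
peaks at M−1, M−2, … (molecules with one, two, … residual ¹⁴N), and a
quantification that reads only the monoisotopic peak systematically
underestimates the heavy channel.

`silia` implements the complete quantification stage for such data:

- **Isotope envelopes at arbitrary enrichment.** The aggregated
  nominal-mass isotopologue distribution of a peptide is the
  natural-abundance convolution over C, H, O, S and unlabeled N, convolved
  with a Binomial(*n*<sub>N</sub>, *p*) over the labeled nitrogens. An exact
  enumeration oracle backs the fast polynomial-convolution implementation.
- **Labeling-efficiency estimation.** The satellite ratio M−1/M of a heavy
  peptide is strictly decreasing in *p*; `silia` measures it from averaged
  MS¹ spectra and inverts it by bisection, averaging over peptides
  (preferring *m* < 1500 Da) to give the experiment-wide efficiency.
- **Efficiency-corrected L/H ratios.** Each channel's measured monoisotopic
  intensity is divided by its theoretical fraction-in-mono
  *f*<sub>M</sub>(*p*), restoring the satellite abundance before the ratio
  L/H is formed. Identification of either channel suffices; one-sided pairs
  keep `Inf`/`0` sentinels instead of being discarded.
- **Cosine-similarity (CS) quality scores.** Observed vs theoretical
  M, M+1, M+2 patterns, per channel, enrichment-aware; 1.0 = perfect match.
  Contaminated (co-eluting) peaks score low and are flagged, never deleted.
- **Protein-level statistics.** Q1/median/Q3 of peptide ratios computed in
  log space and back-transformed; top-100-protein median normalization for
  imperfect mixing; per-channel (¹⁴N vs ¹⁵N search) target-decoy FDR.
- **A ground-truth simulator** producing mzML + identification tables for
  paired clusters at known ratios, enrichment, noise, co-eluting
  interference and missing-channel proteins.

## Worked example

```r
library(silia)

ion  <- peptide_ion("VALEACVQAR", "Carbamidomethyl@6", charge = 1, channel = "heavy")
comp <- build_composition(ion)
comp
#> C46 H82 N15 O15 S1  [15N positions: 14 labeled, 1 unlabeled; charge 1+]
```

The carbamidomethyl nitrogen is introduced chemically after extraction, so
it never carries the label: 15 nitrogens split as 14 labeled + 1 unlabeled.
The satellite ratio falls steeply with enrichment, which is what makes it a
usable efficiency probe:

```r
sprintf("M-1/M at 95%%: %.3f  97%%: %.3f  99%%: %.3f",
        m1_over_m(comp, 0.95), m1_over_m(comp, 0.97), m1_over_m(comp, 0.99))
#> "M-1/M at 95%: 0.610  97%: 0.386  99%: 0.136"
```

Estimating efficiency from ten simulated noisy heavy clusters generated at
*p* = 0.97:

```r
est <- estimate_experiment_efficiency(sim_heavy_clusters(n = 10, p = 0.97,
                                                         noise_cv = 0.01, seed = 42))
est
#> Labeling efficiency: 0.9700 (SD 0.0005, n = 10 peptides)
```

The same operations from the shell (`exec/silia` is installed with the
package):

```sh
silia isotope --sequence VALEACVQAR --mods Carbamidomethyl@6 \
      --charge 1 --enrichment 0.97
# offset  mz          rel_abundance
# -1      1129.54510  38.60
#  0      1130.54279  100.00
#  1      1131.54541  49.82
#  ...
silia simulate --out simdir --seed 4 --ratio 2 --efficiency 0.96
silia quantify --mzml simdir/sim.mzML --ids simdir/ids.tsv \
      --efficiency 0.96 --out run        # reports + JSON cache + manifest
silia report --cache run_cache.json --out rerun   # no mzML needed
```

End-to-end on simulated data, protein medians recover the configured 2:1
mix to better than 1%; the `run_proteins.tsv` report carries accession,
peptide counts, Q1/median/Q3, normalized median and flags.

## Scope

`silia` consumes centroided mzML plus a peptide-identification table
exported from an upstream search engine; the MS² database search itself,
decoy construction and protein inference are out of scope. Studies with
deliberately low/partial incorporation (protein turnover), where heavy and
light clusters overlap, are outside the model's validity and are not
deconvolved — see the methods vignette (`vignettes/methods.Rmd`).
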