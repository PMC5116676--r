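---
title: "Typing and identifying intact glycopeptides from HCD spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typing and identifying intact glycopeptides from HCD spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycotyper)
```

## The problem

Beam-type HCD fragmentation of an intact glycopeptide cleaves both the
peptide backbone and the glycosidic bonds. A single MS/MS spectrum
therefore mixes three ion families: singly charged b/y backbone
fragments, Y ions (the intact peptide retaining zero or more glycan
residues), and low-mass oxonium ions — protonated mono- and
disaccharide fragments such as HexNAc⁺ at m/z 204.0867. The oxonium
region is diagnostic twice over: its mere presence flags a glycopeptide
spectrum, and the *relative* intensities of the individual oxonium ions
differ systematically between N- and O-linked glycopeptides. N-glycans
(built on a GlcNAc₂Man₃ core, often branched) give relatively strong
hexose ions (145, 163, 325) and a strong HexHexNAc ion at 366, while
mucin-type O-glycans (GalNAc-initiated, often sialylated) give a high
186/204 ratio and strong Neu5Ac ions at 274/292. `glycotyper` exploits
this to (i) classify each glycopeptide spectrum as N- or O-linked
before database search and (ii) identify the (peptide, glycan
composition) pair behind each spectrum.

## Spectrum screening and features

A spectrum qualifies as oxonium-ion containing when at least 2 of the
10 diagnostic ions (nominal m/z 138, 145, 163, 168, 186, 204, 274, 292,
325, 366) fall among its top 5% most intense peaks, with 204 mandatory;
complex-background (serum-type) searches relax the window to the top
10%. Before any measurement the bottom 10% of peaks are removed as
low-quality. Counting rules are deterministic: the bottom fraction uses
`floor`, the top fraction uses `ceiling` (so a nonzero fraction always
retains a peak), and intensity ties are broken by m/z so results never
depend on input order.

The classifier input is the vector of the nine oxonium intensities
normalized by the intensity at 204 — the one oxonium ion present in
essentially every glycopeptide spectrum. Normalized ratios are
dimensionless, which makes the features transferable across instruments
and vendor intensity units; they are used untransformed (a `log1p`
option exists for numerical experiments). Ion matching uses the exact
monoisotopic m/z of each ion (computed from elemental composition, not
the nominal integer) at the 20 ppm MS2 tolerance; when several peaks
fall in a window the most intense one is taken, which is robust to
noise splinters.

## The classification model

With two classes, multinomial logistic regression reduces to a binomial
logit: $\Pr(\text{O} \mid x) = \sigma(w^\top x + b)$ over the 9 ratios,
fit by maximum likelihood (IRLS, tolerance 1e-8, up to 500 iterations).
A spectrum is called O-linked when the probability is at least 0.5
(boundary ties go to O — arbitrary but deterministic), and the reported
probability of the assigned class quantifies how deep in the gray zone
a call is. On clean, well-separated training data the unpenalized MLE
does not exist (perfect separation); the fit then falls back to a ridge
penalty of strength 1e-4 (intercept unpenalized), which leaves
non-separated fits essentially unchanged while keeping coefficients
finite. Per-feature significance is assessed with Wald tests from the
inverse observed information; note that under (near-)separation Wald
statistics degenerate (the Hauck–Donner effect), so significance is
only interpretable where the classes overlap. Model evaluation uses
stratified 10-fold cross-validation with pooled out-of-fold
predictions; the scheme is recorded in the report since "cross
validated" alone underdetermines it. Class imbalance is left
unweighted.

## Identification and scoring

Peptide databases come from in-silico tryptic digestion (cleavage after
K/R except before P, up to 2 missed cleavages, up to 2 variable Met
oxidations, fixed carbamidomethyl-Cys from iodoacetamide alkylation,
default length window 5–70). N-glycan pairings require the peptide to
carry an N-sequon (N-X-[S/T/C/V], X ≠ P); O-glycan pairings require an
S or T. Candidates are all pairs whose peptide-plus-glycan monoisotopic
mass matches the neutral precursor mass within 10 ppm.

Each candidate is scored with a modified Morpheus score: the number of
distinct matched theoretical ions (b, y, and the Y series — the peptide
with every sub-composition of the glycan, capped at 400) plus the
fraction of spectrum intensity explained by the matched peaks, with all
oxonium intensity excluded from both numerator and denominator so that
the oxonium-rich spectra of N-glycopeptides are not favored. Each
theoretical ion matches its nearest in-tolerance peak and each peak
contributes its intensity once, preventing double counting. The
integer and fractional parts are recoverable from the score
(`floor(score)` is the matched-ion count). For peptides shorter than
11 residues a matched intact-peptide (Y-series) ion is mandatory;
serum mode disables this rule. Met oxidations are placed on the first
methionines — the data here never localize oxidation, and a
deterministic placement keeps ion series reproducible.

Error control uses a shuffle decoy: all target peptide sequences are
concatenated, the pooled amino acids are shuffled with a seeded RNG,
and the shuffled string is cut back into peptides with exactly the
target length multiset, so the decoy pool conserves the target's
amino-acid composition and length distribution. Only the best GPSM per
spectrum enters the FDR sweep (ties: decoy over target — conservative —
then smaller glycan, then lexicographic peptide). The sweep accepts the
largest prefix of the descending score list with
`#decoy / max(#target, 1) <= 0.01`.

Conventional mode searches every oxonium spectrum against both glycan
spaces; pre-classification mode first calls the classifier and searches
only the assigned space, halving the searched space per spectrum.
Training-set curation for the classifier keeps only FDR-accepted GPSMs
on peptides overlapping known glycosites, with intensity coverage ≥ 10%
and total spectrum intensity ≥ 5×10⁵, and excludes O-linked GPSMs whose
peptide carries an N-sequon (whose class label would be ambiguous).

## The synthetic generator

`generate_dataset()` provides ground-truth spectra so every stage is
testable without external data. Each spectrum contains the 10 oxonium
ions at exact m/z with class-conditional 204-normalized ratios drawn
log-normally (log-normal for positivity and the heavy right tail
typical of ion intensities), a random subset of b/y ions, a Y ladder
built by adding one glycan residue at a time, uniform-m/z noise peaks
with exponential intensities, Gaussian ppm-scale m/z jitter (default
5 ppm), and a precursor consistent with the peptide + glycan mass at
charge 2–3. The default ratio medians encode the qualitative N/O
contrasts described above (O: 186/204 ≈ 0.9, Neu5Ac ions 0.5–0.6,
366 ≈ 0.15; N: 186/204 ≈ 0.12, hexose ions ≈ 0.2, 366 ≈ 0.5) and are
synthetic settings chosen once as plausible values, not measurements.
The default class split (872 N / 527 O) mirrors a realistic curated
training set. The peptide and glycan pools are invented tryptic-like
sequences and common composition classes.

What the generator does *not* emulate: physical fragmentation
propensities (mobile proton, glycan rearrangement), isotope envelopes,
co-isolation, and the correlation structure of real oxonium ratios
(each ratio is drawn independently). Passing tests therefore
demonstrate the correctness of the algorithms under controlled
conditions, not instrument-level performance: in particular the default
classes are nearly separable, so classification accuracies on synthetic
data sit at or near 100% rather than at the high-90s values seen on
real spectra. Under 5 ppm jitter a rare spectrum (≈4σ event) loses its
204 reference peak outside the 20 ppm window; such spectra are
unclassifiable by construction and are dropped from the feature table,
exactly as the oxonium filter would drop them in a real pipeline.

## Numerical and design choices

* Masses are computed from elemental compositions (CODATA atomic
  masses); oxonium m/z are residue mass + 1.007276 minus water losses.
  No deisotoping and no ±1 Da precursor correction are attempted.
* Decoy generation shuffles the whole concatenated database (per-pool,
  not per-protein) — the strongest reproducible reading of
  "lengths similar to the target peptides" is the exact length
  multiset.
* Sequon positions are reported 1-based, as R indexes strings.
* The "bottom 10%" of peaks is read as a count of peaks, not
  cumulative intensity.
* Model files are JSON with 17-significant-digit numbers, which
  round-trips IEEE doubles exactly.

## Problem sizes used in validation

The test-suite and acceptance computations run at deliberately modest
scale: the classifier study uses the full 1,399-spectrum (872/527)
synthetic dataset; permutation-null and parameter-recovery checks use
1,000–5,000 rows per fit; FDR calibration uses 10–20 replicate searches
of 500 spectra each against a ~13-peptide × 12-composition database;
noiseless end-to-end recovery uses 80–120 spectra. These sizes give
stable statistics (binomial standard errors well inside the asserted
bounds) while keeping a full run in minutes on one core.

## Worked example

```{r example, eval = FALSE}
cfg <- generator_config(seed = 1)
d <- generate_dataset(cfg)                       # 872 N + 527 O spectra
report <- cross_validate(d$features, d$labels, k_folds = 10, seed = 1)
report

model <- train_classifier(d$features, d$labels, seed = 1)
dbs <- synth_search_databases(cfg)
res <- run_search(d$spectra, dbs,
                  search_config(mode = "preclassify"), model = model)
res$summary
```

## Limitations

Only glycan *compositions* (HexNAc/Hex/Fuc/Neu5Ac counts) are modeled —
no topology, linkage or branch information, so structure-dependent
effects (e.g. the branch-count dependence of the 366 ion) are out of
reach. Only two glycosylation classes are separated; O-GlcNAc versus
mucin-type O-glycosylation is not distinguished. ETD/EThcD spectra,
glycosite localization within multi-site peptides, and vendor raw file
reading are out of scope.
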