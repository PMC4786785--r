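---
title: "From plate screens to mutability landscapes: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From plate screens to mutability landscapes: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutscape)
```

## The screen this package models

4-oxalocrotonate tautomerase (4-OT) is a hexameric enzyme of 62-residue
subunits whose N-terminal proline makes it a promiscuous catalyst of
Michael-type carbon–carbon bond formation. A site-saturation collection of
1,040 single mutants — at least 15 of the 19 possible substitutions at every
position from Ile-2 to Arg-62, with the catalytic Pro-1 left untouched —
was screened in plates for three things: how much soluble protein each
variant makes, how active it is relative to wild type, and which product
enantiomer it prefers. `mutscape` implements that entire data-analysis
chain as tested, reusable code, and pairs it with a synthetic-data module
that generates every raw input the chain consumes, so the whole pipeline
can be exercised, and its error budget measured, without any instrument.

The package is organised as an analysis workflow: the numbered scripts
under `analysis/` are thin narrative drivers; every computation they
perform lives in package functions that the test suite and the acceptance
script call directly.

## Expression: densitometric calibration

Each gel carries calibration lanes loaded with 0.5, 1, 2.5 and 5 µg of
purified wild-type enzyme. `fit_calibration()` fits ordinary least squares
of band intensity on load with a *free intercept*: Coomassie background
staining gives an empty lane nonzero intensity, and forcing the line
through zero would bias every back-calculated concentration.
`quantify_lane()` inverts the line and rescales by the CFE-equivalent
volume loaded (default 1 µl, mirroring a 2 µl extract diluted 1:10 with
half the mixture loaded). Two semantics matter:

* **Per-gel isolation.** A calibration curve is applied only to sample
  lanes of the same gel (`quantify_gel()` enforces this by `gel_id`);
  staining intensity is not comparable across gels.
* **Detection limit.** Concentrations under 0.5 mg ml⁻¹ are flagged
  `below_lod`; negative regression inversions clip to zero and are
  flagged. In per-substitution averages (`substitution_averages()`),
  below-limit cells enter as zero — they are a floor category, not
  missing data.

## Activity: initial rates, background, and plate-wise normalization

Progress curves are UV absorbance of the depleting substrate. The
synthetic generator uses a two-phase model — linear depletion until the
substrate is exhausted, then flat — rather than a first-order decay,
because the analysis only ever consumes the initial linear section and
the two-phase form makes the ground-truth slope exact (a first-order mode
exists for robustness checks). Noise is homoscedastic Gaussian on
absorbance, the simplest model that exercises every estimator; its
magnitude (default 0.003 AU) is a configuration knob, since the
instrument noise of the original screen is not published.

`initial_rate()` selects the linear section with a sliding window:

* Candidate points are restricted to the early region in which at most
  20% of the initial signal has been lost (`max_fraction_depleted`), so
  the window can never reach the plateau.
* The window length is **half the admissible span**, floored at
  `min_points` (default 7). Slow traces are therefore fitted over many
  points (precision where the slope is shallow), while fast traces stay
  inside their short linear phase.
* Among all placements the highest-R² window wins; exact ties go to the
  earliest window, which makes noise-free recovery exact.

Rates convert to µM min⁻¹ through an extinction coefficient and optical
path length that are deliberately *configuration, not constants*: the
screen's values are not published, and relative activities are invariant
to them because the conversion cancels in the wild-type ratio (verified
to 1×10⁻¹² in the tests). Duplicate variant wells are pointwise-averaged
into one curve before fitting; the mean initial rate of the empty-vector
wells on the same plate is subtracted from every other well; specific
activity is units per mg of enzyme using the gel-derived concentration;
and each plate is normalized by the arithmetic mean of its own wild-type
wells (a median switch exists). Controls never cross plates. Wells whose
corrected rate is ≤ 0 are marked `zero_activity` rather than given
negative values; wells whose expression was under the detection limit are
marked `below_lod` regardless of rate, because units-per-mg is undefined
there.

## Enantioselectivity: peak integration and ratio arithmetic

The four stereoisomers of the 2-ethyl γ-nitroaldehyde product separate on
a chiral column; the generator models them as four Gaussians on a flat
baseline. `detect_and_integrate()` estimates the baseline as the 5th
percentile of the signal (matching the generator's flat baseline; real
dialects can pass a numeric level), detects local maxima above a
prominence threshold, and integrates trapezoidally out to 0.1% of apex
height or the valley towards a neighbouring peak. Peaks are assigned to
stereoisomers purely by retention-time window (`default_rt_windows()`);
the windows are configuration because the original column's retention
times live in unavailable supplementary material, and the defaults close
the loop with the generator. The syn enantiomers carry absolute labels
(2R3S, 2S3R — assignable via reference standards); the anti enantiomers
are labelled by elution order only, and the package never invents their
configurations.

`compute_dr_er()` reports d.r. = syn:anti over the total area and e.r. =
2R3S:2S3R within syn, both as pairs summing to 100, stored at full
precision and printed as integers (table style). A chromatogram whose
total area falls under `min_total_area` is flagged
`insufficient_signal` — too little product for an adequate UV signal —
and enters the landscape as a state, not a number. An inversion
(`find_inversions()`) is a valued cell whose *majority* syn enantiomer
differs from wild type's; exactly 50:50 has no majority and is never an
inversion.

## Landscapes

`assemble_landscape()` builds the 20 × 61 matrix (amino-acid rows,
positions 2–62; Pro-1 is excluded because its mutants were never in the
collection). Every cell carries exactly one state — `wild_type`,
`absent`, `below_lod`, `zero_activity`, `insufficient_signal` or
`value` — and the states always tile the full grid. Wild-type cells of a
relative-activity landscape carry 1 by construction. The long-form CSV is
the canonical artifact (values serialized at 17 significant digits so the
round trip is bit-exact); heatmaps are presentation, not data, and the
published figure's colour breakpoints are deliberately not
reverse-engineered.

## Library design and additivity

`expand_codon()` enumerates a degenerate IUPAC triplet through the
standard genetic code; the tests check it against an independent
translation of all 15³ triplets. Stop codons are excluded from
protein-variant counts but reported, since NNK encodes the amber stop —
that is what reconciles codon-level truth with a 5 × 4 × 20 × 4 = 1,600
member focused library. `coverage()` keeps full precision (1,040 of
61 × 19 = 89.7%) next to the rounded report value (90%).
`predict_combined()` multiplies single-mutant folds (log-additivity) and
`predict_combined_er()` adds log-odds shifts of the enantiomer ratio;
both are explicitly heuristics and tag their output with the model name.

## Preparative stoichiometry

Molar masses come from an embedded IUPAC atomic-weight table and formulas
derived from the products' IUPAC names. Yields are linear in isolated
mass and inverse-linear in volume; an optional contaminant weight
fraction (e.g. 6% w/w unreacted nitroalkene detected by NMR) is removed
before conversion. Printed masses, mmol and percent values occasionally
disagree in the last digit because the printed inputs are themselves
rounded (a mass given as "9 mg" supports only ±0.5 mg); the tests
therefore compare at the printed precision plus the propagated rounding
of the mass. One such inconsistency in the source data — a footnote
giving 1.4 mol% where 29.4 µM on 2 mM computes to 1.47 — is reported as
computed, not resolved.

## What the synthetic data does and does not establish

The generator reproduces the screen's *structure*: duplicate wells,
per-plate controls, calibration lanes on every gel, two-phase kinetics,
four-Gaussian chromatograms, a detection limit, and planted ground-truth
effects taken from the published single-mutant results (e.g. a 3.5-fold
variant, an inverting mutant at 7:93). Its defaults are chosen once:
expression lognormal around 2 mg ml⁻¹, relative activity lognormal with
a mild detrimental bias and 5% dead variants, stereo fractions perturbed
on the log scale around the wild-type product distribution (d.r. 91:9,
e.r. 57:43). It does **not** model enzyme mechanism, hexamer
dissociation, pH effects, heteroscedastic or drifting instrument noise,
gel-lane distortions, or overlapping chromatogram peaks. Passing
round-trip tests therefore shows the *analysis* is correct and
well-conditioned at realistic noise levels — not that real instruments
are this kind. Problem sizes in the tests and acceptance checks (single
plates, one chromatogram, a 61-variant end-to-end run) are chosen as the
smallest sets that exercise every code path; the `analysis/` drivers run
the full 1,040-variant campaign.

## Worked example

```{r example, eval = FALSE}
ref <- load_reference()
collection <- make_collection(ref, min_per_position = 15, total = 1040,
                              seed = 1)
coverage(collection)$rounded
#> [1] 90

spec <- assay_michael_butanal()
variant <- collection[collection$variant_id == "A33D", ]
truth <- make_truth(variant, seed = 2, rel_overrides = c(A33D = 3.5))
plate <- simulate_plate(variant, truth, spec, seed = 17)
expr <- data.frame(variant_id = "A33D", conc_mg_ml = truth$true_conc,
                   below_lod = FALSE)
rec <- analyze_plate(plate, spec, expr)
rec$relative[which(rec$variant_id == "A33D")]
#> [1] 3.504479
```
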