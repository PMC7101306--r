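---
title: "Colour-block encoding of clinical data for RA classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colour-block encoding of clinical data for RA classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratda)
```

## The problem and the idea

Rheumatoid arthritis (RA) has no single diagnostic marker. Rheumatologists
integrate joint symptoms, examination findings, ultrasound synovitis
scores, serology and acute-phase reactants into a holistic judgement, and
many treated patients never satisfy the 2010 ACR/EULAR classification
criteria. `ratda` implements a published pipeline that makes this
integration machine-learnable by *drawing* each patient: every clinical
variable is discretized into an ordered colour (green < yellow < orange <
red) and painted into a fixed position on an 871 x 494 pixel canvas, so
that one patient becomes one colour-block image and an image classifier
can be trained to label the image RA or nonRA.

The canvas holds two bilaterally symmetrical hand panels of fifteen
cruciform (plus-shaped) joint blocks each — wrist, MCP1-5, PIP2-5, the
thumb IP, and DIP2-5 — and fourteen clinical squares. Each cruciform block
has five sub-squares: patient-reported symptom (a), examined tenderness
(b), examined swelling (c), and the OMERACT semi-quantitative ultrasound
grayscale (d) and power Doppler (e) scores, both 0-3.

## Discretization rules

`default_rules()` reproduces the published cutoffs exactly: RF 15/30
IU/mL, ACPA 4.5 U/mL, ESR 10/20 mm/h, symptom onset 42 days, CRP 0.3
mg/dL, ANA titre 40/80 vs 160, MMP-3 120 ng/mL, WBC 4000/8000 /uL, body
temperature 37.5/38 deg C, both VAS 10/50, male = yellow / female = red,
and the cruciform channels (flags green/red; ultrasound 0 = green, 1 =
yellow, 2 = orange, 3 = red). Three boundary questions are not settled by
the printed rules and are resolved here as package policy:

* **Cutoff membership.** Every `a~b` band is interpreted as `[a, b)`:
  a value equal to a cutoff takes the severer colour, consistent with the
  `30 <= red` style in which upper bounds are printed.
* **MMP-3.** The printed rule (`yellow < 120, 121 <= red`) leaves 120-121
  open; we use yellow for values up to 120 inclusive, red above 120.
* **ANA.** Only the anchors 0, 40, 80 and >= 160 are printed; intermediate
  titres interpolate (green below 40, yellow in [40, 160), red at and
  above 160), and an ultrasound score of 0, absent from the printed table,
  renders green like the other negative findings.

`discretize_field()` is total over each field's domain and monotone in
severity for every numeric field; both properties are enforced by tests
over dense domain grids.

## Layout and palette

The source fixes the canvas size, the block inventory and the sub-square
labels, but publishes the exact pixel geometry only as a figure. The
shipped `default_layout()` is therefore an explicit, versioned stand-in,
not a claim about the original pixels: 26 px sub-squares arranged a-top /
b-left / c-centre / d-right / e-bottom (mirrored on the left hand), the
left panel a pixel-exact horizontal mirror of the right, and the fourteen
60 px clinical squares in two rows of seven below the panels. Layouts and
rule sets serialize to versioned YAML so a render is a pure, byte-stable
function of (record, rules, palette, layout).

Colours are likewise named but not specified numerically in the source.
The default palette — green (0,176,80), yellow (255,255,0), orange
(255,140,0), red (255,0,0), white background, grey for missing values —
keeps every pair of colours at least 100 apart in Euclidean RGB distance
so that `decode_tda()` can invert a render unambiguously: each block's
centre-region mean colour is assigned to the nearest palette colour, and
anything farther than half the minimum palette distance from every colour
(for example, a masked or empty block) is an explicit error. The orange
was darkened from the common (255,165,0) to honour the 100-distance
guarantee against yellow. `decode(render(r)) = discretize(r)` over
randomized records is the encoder's central tested invariant.

## Synthetic cohorts

The study's patient data were never deposited, so all experiments here run
on seeded synthetic cohorts that emulate the published class-conditional
summaries: the learning profile (252 RA / 785 nonRA after augmentation)
and the testing profile (10 RA / 40 nonRA). For each continuous laboratory
value the published median and range are bridged to a samplable
distribution by `fit_marginal()`: a log-normal truncated to the printed
range, with the log-mean solved numerically so the *truncated* median
equals the printed median (labs are nonnegative and right-skewed; RA RF
spans 0-2265 IU/mL with median 68). Symptom onset is printed as median
plus quartile range, not min-max, so it is fitted through the quartiles
and truncated at six times the upper quartile. Fields whose median sits on
the range minimum (e.g. nonRA ACPA, median 0) become zero-inflated
mixtures so the empirical median is still exact. ANA is sampled on the
discrete titre ladder (0, 40, 80, ...), body temperature — printed as a
range only — as a symmetric Beta(2,2) over that range, and categorical
fields as Bernoulli draws at the printed count ratios.

Two components are *not* derivable from the source and are shipped as
clearly marked invented defaults:

* The RA learning-profile ACPA median is blank in the source (only the
  range 0-3519 is printed). It is modelled as a mixture of a seronegative
  mass below the 4.5 U/mL positivity cutoff (weight 0.3) and a positive
  log-normal component with median 150 U/mL — chosen so the cohort
  contains ACPA-negative RA, which the original system classified
  correctly and which any faithful emulation must include.
* Per-joint involvement probabilities are not reported at all. The
  defaults encode the textbook contrast the study population implies:
  RA as symmetric wrist/MCP/PIP synovitis with active Doppler signal
  (bilateral sharing 0.7), nonRA as DIP-dominant, osteoarthritis-like
  involvement (sharing 0.3) — the nonRA diagnoses were dominated by
  osteoarthritis. A bilateral "sharing" event copies one sampled finding
  to both sides, so a symmetry coefficient of 1 forces identical hands.

A scalar `separation` knob interpolates, at the patient level, between the
two class profiles (1 = published profiles, 0 = both classes drawn from
the nonRA profile), which is how the no-signal and robustness experiments
are constructed, and `joints_only_profile()` equalizes everything except
the joint patterns for the ablation experiment.

What passing tests on these cohorts shows — and does not show: they
demonstrate that the *pipeline* (encoding, augmentation, training,
selection, metrics) behaves as specified and can extract class signal
whose marginals match the published tables. They cannot certify the
published clinical accuracies (96-98%, kappa 0.79-0.87), because the
synthetic generator assumes conditional independence between laboratory
values given the class and invents the joint-pattern parameters; real
patients are almost certainly harder.

## Augmentation

The original learning set was expanded 1-to-6 (RA) and 1-to-5 (nonRA) by
one rheumatologist manually editing each record under the rule that edits
"could not affect the original diagnosis". Those edits are unknowable, so
`perturb_record()` substitutes an explicit stochastic proxy: multiplicative
log-normal jitter (sd 0.1) on the laboratory values, small additive jitter
on VAS and temperature, rare flag flips and joint-channel toggles — under
a hard guard that at most 4 fields may change their colour category, each
by at most 1 level of its own category scale, and that the categories of
protected fields (ACPA and RF, the diagnosis-critical serology) never
change. The guard reverts offending fields rather than rejecting whole
clones, so expansion counts are exact: 42 + 157 originals become exactly
252 + 785 = 1037. "Diagnosis-preserving" is thus operationalized as a
category-drift bound, not a clinical re-adjudication — a software
substitute for clinical judgement, stated as such.

## Classifier and training protocol

The published protocol fine-tunes a pretrained 8-layer CNN by replacing
its final fully connected and classification layers for two classes
(learning rate 0.001, at most 10 epochs, validation about once per epoch,
fresh random 80/20 stratified splits, five independent trials, and
selection of the trial with the best *test* accuracy). `ratda` keeps that
protocol but treats the backbone as pluggable — the protocol, not the
particular network, is the contract — and ships a default that is fully
self-contained and bit-reproducible, with no external weight artefacts:

* `small_cnn` (default) is a small convolutional network trained from
  scratch in-package: one 3x3 valid convolution with 8 filters, ReLU, 2x2
  max-pooling, and a dense softmax layer. Colour-block images are nearly
  piecewise-constant, so this capacity is ample. The optimizer is Adam at
  the protocol's learning rate 0.001 with batch size 32 (optimizer and
  batch size are unstated in the source; these are package defaults
  recorded in `training_config()`). Gradients are exact (verified against
  numerical differentiation in tests) and seeded runs are bit-reproducible.
* `pretrained_transfer` reproduces the final-layer-replacement recipe over
  any locally available feature extractor: only a new softmax head is
  trained.

Inputs are nearest-neighbour downscaled to 40 x 40 (a package choice, not
the published 227 x 227 network input): nearest-neighbour sampling keeps
every pixel an exact palette colour, and because every block in the
default layout is at least 26 px in its narrow dimension while 40 x 40
sampling of the 871 x 494 canvas probes every ~22 x ~12 px, every block is
guaranteed to contribute at least one input pixel. This keeps the default
five-trial protocol at roughly two minutes on one CPU at the study sizes
used in the tests (about 1560 augmented learning images from 300
originals, 50 test images).

Two protocol details deserve emphasis. First, learning/test disjointness
is enforced by patient id, never assumed. Second, selecting the best of
five trials *by test accuracy* means the test set participates in model
selection; this replicates the source protocol faithfully and is flagged
in the returned objects rather than silently corrected.

## Evaluation

`confusion()`, `prf_accuracy()` (RA is the positive class; report values
are rounded half-up to integer percent, exact fractions retained;
zero-denominator metrics are reported as undefined, never as zero) and
`cohens_kappa()` ((p_o - p_e)/(1 - p_e), defined as 1 when both raters are
constant and identical) reproduce the published worked example: the
confusion matrix (10, 0, 1, 39) gives precision 91%, recall 100%, accuracy
98%, and kappa 0.940 against the truth labels. `ablation_report()` rebuilds
the two-image experiment (joint blocks only vs clinical squares only), and
`counterfactual_probe()` the single-field switching experiment: render a
record twice, once with one field replaced, and ask whether the predicted
label flips.

## Numerical choices and degenerate inputs

* Marginal fitting solves the truncated-median equation by `uniroot` at
  tolerance 1e-10; degenerate ranges (min = max) are point masses;
  medians at the range minimum are zero-inflated mixtures.
* Splits allocate `round(fraction * n)` validation cases across classes by
  largest remainder, so stratification is exact at any size.
* Trial selection breaks ties toward the lowest trial index.
* Pooling ties in the CNN route gradient to the first maximal slot.
* Validation never raises on structurally complete records; it reports.
  Missing values are rejected by default and rendered grey only under the
  explicit permissive policy.

## Known limitations

* The default layout and palette are stand-ins for geometry the source
  publishes only graphically; both are versioned and configurable.
* The synthetic cohorts ignore between-lab correlations (beyond the class)
  and longitudinal structure; they are a test harness, not a patient
  simulator.
* The augmentation proxy bounds *encoded* drift; it cannot re-create a
  rheumatologist's editing style.
* Only the fingers and wrist are encoded; inflammation elsewhere is
  invisible to the system, as in the source design.
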