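---
title: "Geometric quantification of mouse facial expressions: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric quantification of mouse facial expressions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facemetrics)
```

## The measurement model

Rodent facial expression is conventionally scored with ordinal grimace
scales (0/1/2 per action unit), which are coarse and observer-dependent.
`facemetrics` instead treats the profile face as a small landmark
configuration — thirteen named points around the eye, ear, snout and
mouth — and summarizes it with seven continuous parameters, each a pure
ratio of distances or an angle. Because similarity transforms of the
plane (translation, rotation, uniform scaling, reflection) preserve
distance ratios and unsigned angles, the parameters are by construction
independent of camera placement, zoom and animal size, and of whether a
left or right profile was filmed. This invariance is not an empirical
claim but an algebraic property, and the test suite exercises it to
1e-9 over random landmark sets and random similarity transforms.

The seven definitions (see `?compute_parameters` for formulas):
eye opening (1 for a circular eye, shrinking with lid closure), ear
opening (pavilion width over length; smaller when the ear is held high
on the head), ear angle (ear axis against the skull-fixed
eye-corner-to-ear-orifice axis; ~90° for a straight ear), ear position
(ear displacement normalized by a rigid skull distance), snout position
(snout aperture angle; smaller = pointier), mouth position (lower-lip
advance normalized by snout-to-eye distance) and face inclination (the
eye-corner angle between the lower snout and the ear orifice, minus
90°, negative toward a convex profile).

Two definitional choices were genuinely open. The "corner of the eye"
anchoring face inclination is fixed to the posterior corner
(`eye_back`), the corner adjacent to the ear orifice on a profile view.
The reference axis for ear angle is `eye_back → ear_orifice`: both
endpoints are skull-fixed, so whole-head tilt cancels out of the ear
measurement. Absolute values of the ratio parameters depend on such
anchor choices; directions of change and all invariances do not, and
the directions are what the downstream statistics consume.

Degenerate geometry (two required landmarks closer than
`epsilon_coincident`, default 1e-9 of the eye-to-ear-orifice distance so
the threshold is itself zoom-free) raises an error rather than returning
a silent zero: a zero leaking into a per-animal average would corrupt
every downstream contrast. The two ratios whose numerator may
legitimately vanish (ear position with the ear base at the eye corner,
mouth position with the lip at the snout tip) only guard their
denominators. `compute_parameters(partial = TRUE)` returns per-parameter
`ok`/`missing`/`degenerate` status instead of aborting, which is how
frame tables with incomplete pose-estimation output are processed.

## From frames to inference

**Units.** All analyzable frames of one animal under one condition are
averaged into a single unit, so animals contributing many frames do not
dominate. Frames flagged for confounding behaviors (licking,
scratching) are excluded first; for tastant conditions only frames
within the closed 5-s window after a tasting event are kept (the window
includes both endpoints — the boundary convention is fixed here for
determinism).

**Proportional change.** Each stimulus unit is normalized by the same
animal's baseline unit, `(stimulus - baseline)/baseline`. An exactly
zero baseline yields `NA` ("undefined") rather than infinity; this
occurs for ratios that can reach zero, such as a fully closed eye.

**Response profiles.** Per parameter, a two-sided one-sample t test of
the proportional changes against zero, Bonferroni-corrected by the
number of comparisons `m` made in the experiment. `m` is an
experiment-level design input, not inferred from the table.

**ANOVA battery.** One-way ANOVAs with Tukey HSD compare conditions
when subject repetition is not modeled. Two-way designs use Type II
sums of squares when fully between-subjects (the default for unbalanced
data; the choice is recorded in the result's `ss_type`). When one
factor is within-subject, the univariate repeated-measures table is
computed through the multivariate-model route with a
Greenhouse–Geisser sphericity correction; the correction produces the
fractional degrees of freedom reported, and a two-level repeated factor
has epsilon = 1 identically. Post hoc policy: Tukey on main effects
(for the within factor, via the studentized range on the
within-subject error mean square; for the between factor, on
per-subject means), and Sidak-adjusted cell comparisons only when the
interaction is significant. Temporal formalin analyses use a
within-subject one-way ANOVA followed by Dunnett comparisons of each
post-injection bin against the pooled baseline; Dunnett adjusted
p-values are integrated numerically from the equicorrelated (rho = 1/2)
multivariate t distribution on the within-subject error, not read from
tables, and are cross-checked in the tests against an independent
implementation (multcomp) to ~1e-3, the accuracy of the numerical
integration.

**Reliability.** Inter-observer agreement is ICC(2,1): two-way random
effects, absolute agreement, single measure — the appropriate form when
every observer measures every frame and absolute values matter. It is
computed from the two-way mean-square decomposition with
McGraw–Wong F-based confidence bounds, and tested to 1e-9 against an
`aov`-based variance-component oracle.

**Formalin binning.** The 30-min pre-injection phase is averaged into
one reference bin; the 30-min post-injection phase is split into six
half-open 5-min bins `[start, end)`. Half-open bins make the partition
exact: a frame at exactly 5.0 min belongs to bin 2, and the tests
assert that no frame is lost or double-counted. The derived `early`
phase is the first post-injection bin, `late` pools minutes 20–30.

## Structure of the parameter landscape

PCA is performed on standardized variables (correlation matrix) by
default because the parameters mix degrees and dimensionless ratios;
`scale. = FALSE` gives the covariance variant. The contribution of
variable j to component k is the squared unit-norm loading in percent,
so contributions per component sum to 100.

Component retention uses Horn's parallel analysis: observed eigenvalues
are compared against eigenvalues of Monte-Carlo standard-normal
datasets of the same size (default 1000 iterations, seeded). Two
choices here differ from the most naive formulation, both for
calibration reasons verified by simulation. First, the Monte-Carlo
reference is a high centile (0.99) of the random eigenvalue
distribution rather than its mean: under an independent-noise null the
top observed eigenvalue fluctuates around the random mean, so a mean
reference retains a spurious first component in roughly half of all
datasets, while the 0.99-centile reference keeps false retention near
1% (the mean variant remains available as `adjustment = "mean"`).
Second, retention counts the leading run of adjusted eigenvalues above
1 and stops at the first failure, as a later component cannot be more
credible than an already-rejected earlier one; counting all components
above 1 would again inflate false retention roughly sevenfold. With
these choices, planted two-factor data (n = 200, loadings 0.8) are
recovered as exactly two components in 100% of 100 seeds and iid noise
yields zero components in 98%.

The 2-D embedding uses UMAP (via `uwot`) with Euclidean distances, 15
neighbors and minimum distance 0.1, run directly on raw absolute
parameter values. Raw values mean that degree-valued parameters
dominate the metric; this caveat is recorded in the result metadata,
and the choice is deliberate — the embedding characterizes the units as
measured, not a rescaled abstraction. Embeddings are seed-reproducible
(single-threaded optimization under a fixed seed).

## The synthetic-face simulator

The simulator emulates the experimental designs the statistics are
meant for: a baseline phase followed by stimulus phases, 4–6 clear
profile frames drawn per animal per condition (about five usable frames
per unit), per-individual random effects, per-frame measurement noise,
camera similarity jitter and random behavioral exclusions; a schedule
override reproduces the formalin design (one frame per minute over
30 + 30 min, 60 frames per animal).

Two effect mechanisms exist because inverting all seven parameters at
once in landmark space is over-constrained. The *landmark* mechanism
realizes a condition effect as a geometric deformation of a fixed
template face — rotate the ear tip about its base midpoint for ear
angle, scale the lid separation for eye opening, and so on — and each
deformation changes its target parameter by exactly the requested
delta (additive degrees for angles, multiplicative for ratios),
verified to 1e-9. It is used for geometry-level validation, including
the guarantee that per-frame camera jitter never moves any parameter.
The *parameter* mechanism applies effects, animal effects and frame
noise directly to the seven parameter values and is used for
statistical power and calibration studies. Noise magnitudes are
expressed as fractions of the template value (defaults: 5% between
animals, 3% between frames); true inter-frame noise of manual
measurement is unknown, so these defaults are stated in every
simulation's ground-truth record and should be treated as assumptions,
not estimates. An optional per-landmark pixel noise term emulates
placement error in the landmark mechanism.

Because animal-level effects multiply both the baseline and the
stimulus value of the same animal, they largely cancel in proportional
changes — exactly the reason the proportional-change normalization is
used on real animals.

What passing simulations do and do not show: they demonstrate that the
pipeline recovers effects that exist in its own generative model
(Gaussian noise, exchangeable frames, exact landmark placement up to
isotropic jitter). Real data add non-Gaussian measurement error,
temporally correlated frames within a session, asymmetric faces viewed
from one side, and out-of-plane head rotation, none of which the
simulator models beyond the foreshortening construction used in the
ear-opening tests.

## Numerical choices and problem sizes

Angles are computed with the two-argument arctangent of cross and dot
products, which is stable near 0° and 180° where the arc-cosine form
loses precision; the suite still checks agreement with an independent
arc-cosine oracle at 1e-9 over 1000 random configurations. Studentized
range and Dunnett probabilities are evaluated numerically (`ptukey`,
`mvtnorm::pmvt` with 1e-6 integration tolerance). Determinism contracts
are bitwise for the simulator and the Monte-Carlo analyses under a
fixed seed.

The shipped validation suites use desk-scale problem sizes chosen to
estimate the relevant rates with useful precision: 500 null replicates
(binomial SE ~1%) and 100 effect replicates for response-profile
calibration and power, 100 seeds per parallel-analysis scenario, and
10-animal formalin simulations. These sizes are the package's own
validation design.

## Known limitations

Absolute parameter values are anchor-dependent and not comparable
across landmarking conventions; only directions, invariances and
within-animal normalized changes transfer. Facial asymmetry is
invisible in single-profile views. Pose estimation itself, video
decoding and event detection (tasting, grooming) are out of scope: the
package consumes landmark tables, long-format CSV or the
three-header-row pose-estimation dialect, and event times come from the
run configuration.
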