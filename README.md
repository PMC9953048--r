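# facemetrics

Quantification of mouse facial expressions from profile landmarks.

Grimace-scale scoring of rodent facial expression is ordinal and
observer-dependent. `facemetrics` implements a fully geometric
alternative: thirteen easily visualizable points on the mouse profile
(eye corners and lids, ear tip/base/orifice, nose, snout, mouth, lip)
are reduced to **seven facial parameters** — each a pure ratio or angle,
and therefore invariant to camera translation, rotation, zoom and
left/right mirroring:

| parameter | definition | reading |
|---|---|---|
| eye opening | d(eye_top, eye_bottom) / d(eye_front, eye_back) | 1 = perfectly round eye; smaller = narrowed |
| ear opening | ear base width / d(base midpoint, ear_tip) | near 1 = deployed pavilion; smaller = ear held high |
| ear angle | angle(ear axis, eye_back→ear_orifice axis), degrees | ~90 = straight ear; smaller = tilted |
| ear position | d(eye_back, ear_base_front) / d(eye_back, ear_orifice) | larger = ear further back |
| snout position | angle at snout_tip between nose_top and lower_snout, degrees | smaller = pointier snout |
| mouth position | d(snout_tip, lower_lip) / d(snout_tip, eye_back) | smaller = lower lip brought forward |
| face inclination | angle at eye_back between lower_snout and ear_orifice, minus 90° | smaller = more convex profile |

On top of the geometry the package provides the full analysis pipeline:
frame selection (behavioral exclusions; the closed 5-s post-tasting
window for tastants), averaging of frames into per-individual
per-condition *units*, proportional change from baseline
((stimulus − baseline)/baseline), response profiles (one-sample t tests
with Bonferroni correction), the ANOVA battery (one-way + Tukey HSD,
two-way between or mixed designs with Greenhouse–Geisser correction,
repeated-measures with Dunnett comparisons against baseline via the
multivariate t distribution), inter-observer reliability as ICC(2,1),
formalin-test temporal binning (30-min baseline reference + six 5-min
bins, early/late phases), PCA with per-variable contributions, Horn's
parallel analysis, and a seeded 2-D UMAP embedding of units. A
synthetic-face simulator with exact ground truth (template + invertible
deformations + camera jitter) makes every stage testable without animal
data.

## Worked example

Simulate a petting-like experiment in which the stimulus raises ear
position by 20% and opens the eye by 10%, then recover those effects:

```r
library(facemetrics)

design <- simulation_design(n_animals = 30,
                            conditions = c("baseline", "petting"),
                            frame_sd = 0.03, seed = 42)
sim    <- simulate_experiment(design,
            effects = list(petting = list(ear_position = 1.20,
                                          eye_opening  = 1.10)))
units   <- unit_average(sim$frames)
changes <- proportional_change(units)
response_profile(changes, "petting", m = 7)
```

```
         parameter  n   mean_change           t df        p_raw        p_adj m
1      eye_opening 30  9.798036e-02 19.42618077 29 3.608368e-18 2.525857e-17 7
2      ear_opening 30 -3.849698e-03 -1.22190743 29 2.315823e-01 1.000000e+00 7
3        ear_angle 30  4.895566e-05  0.01458083 29 9.884664e-01 1.000000e+00 7
4     ear_position 30  2.016411e-01 54.08947885 29 1.125610e-30 7.879271e-30 7
5   snout_position 30  4.155879e-03  1.16203920 29 2.546942e-01 1.000000e+00 7
6   mouth_position 30 -1.488926e-03 -0.43836163 29 6.643724e-01 1.000000e+00 7
7 face_inclination 30 -1.837506e-03 -0.43359074 29 6.677941e-01 1.000000e+00 7
```

The two injected parameters are recovered near their true proportional
changes (+0.10 and +0.20) with Bonferroni-significant one-sample t
statistics of the correct sign; the five uninjected parameters stay at
chance. The geometry itself is exact: computing the seven parameters on
the built-in template after an arbitrary rotation/zoom/translation
reproduces the original values to better than 1e-9.

A shell interface over the same functions ships in
`inst/cli/facemetrics` (subcommands `simulate`, `measure`, `aggregate`,
`profile`, `anova`, `icc`, `embed`); every run writes a JSON manifest
recording versions, seeds and input fingerprints.

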