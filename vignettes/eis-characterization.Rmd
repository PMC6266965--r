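---
title: "Characterizing microelectrode impedance spectra: models, rules, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing microelectrode impedance spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eismea)
```

## The measurement and the problem

Electrochemical impedance spectroscopy (EIS) of an implanted microelectrode
sweeps a small sinusoidal signal across frequency — here 1 Hz to 1 MHz at 5
points per decade, 31 frequencies per spectrum — and records the complex
impedance of each electrode site against a reference in the surrounding
tissue. A single 1 kHz reading, the conventional quick check, cannot separate
an aging-but-functional site from a broken lead: very different physical
states can produce similar 1 kHz magnitudes. The shape of the whole
magnitude/phase spectrum can.

`eismea` implements a rule-based classifier that sorts each spectrum into one
of four failure-mode categories, an equivalent-circuit fit that turns each
spectrum into four physically interpretable parameters, longitudinal
analytics over weekly measurement sessions, an SVM benchmark of the
classifier, and a synthetic cohort simulator so that the entire pipeline is
testable without access to any animal data.

## The circuit model

The core model is a Randles equivalent circuit with a constant phase element
(CPE): the access (solution) resistance $R_S$ in series with the parallel
combination of the charge-transfer resistance $R_E$ and the CPE,

$$Z_{CPE}(w) = \frac{1}{Q (jw)^n}, \qquad
  Z(w) = R_S + \frac{R_E}{1 + R_E Q (jw)^n},$$

where $Q$ (S s$^n$) sets the CPE magnitude and $n \in [0,1]$ interpolates
between a resistor ($n = 0$) and an ideal capacitor ($n = 1$). The principal
complex branch is used, so the CPE phase is exactly $-90 n$ degrees.

**Frequency convention.** Whether $w$ denotes ordinary frequency $f$ (Hz) or
angular frequency $2\pi f$ is a genuine ambiguity of the CPE literature; the
two conventions rescale $Q$ by $(2\pi)^n$ and leave $R_E$, $n$, $R_S$
unchanged. This package maps grid frequencies directly, $w = f$. The choice
was forced by internal consistency: the packaged archetype library stores
published group-mean parameters, and only under the $w = f$ reading do the
reconstructed hockey-stick spectra satisfy the hockey-stick phase rule
(under $w = 2\pi f$ the low-frequency mean phase of the in-vivo hockey-stick
reconstruction lands at $-37^\circ$, outside the $(-80, -40)$ band the rule
requires). Fitting and simulation use the same convention throughout, so
parameter recovery is exact either way; `angular = TRUE` is available on the
forward model for sensitivity checks.

**Extended elements.** Two degradation pathways extend the circuit, each in
parallel with the whole Randles branch: a parasitic shunt resistance $R_p$
(encapsulation damage or a lead break: a mostly-real leakage path that caps
the low-frequency magnitude and produces the ski-slope plateau) and a
dielectric coupling capacitance $C_d$ (insulation degradation: a capacitive
path that collapses the phase toward $-90^\circ$ at high frequency and, on
top of a hockey-stick circuit, creates the inverted-U phase with an interior
maximum near 1 kHz). With $R_p = \infty$ and $C_d = 0$ the extension reduces
*exactly* to the Randles form — an identity the test suite asserts. The
parallel-with-the-whole-branch topology is a package design choice: the
source material draws both pathways without equations, and this placement is
the simplest one that reproduces both morphologies.

## The classification rules

Seven band statistics are extracted per spectrum: the mean magnitude and mean
phase below 100 Hz (strict), the phase maxima over the closed bands
100 Hz–50 kHz and 100 Hz–10 kHz, the mean phase above 10 kHz and above
50 kHz (strict), and the maximum absolute phase difference between successive
grid frequencies. Band-edge conventions (strict below, closed inside) were
fixed so that the 100 Hz point belongs to the interior bands and not to the
low band.

The rules, with all thresholds strict and exposed as configuration
(`eis_rules()`):

* **outlier** first: mean low-frequency magnitude above $10^8\,\Omega$
  (platinum) or $2 \times 10^9\,\Omega$ (iridium oxide) — an
  open-circuit-like failure;
* **hockey-stick** (iridium-oxide arrays only): mean $|Z|_{<100\,Hz} <
  8\times10^6\,\Omega$, mean phase below 100 Hz inside $(-80, -40)^\circ$,
  phase maximum over 100 Hz–50 kHz above $-30^\circ$, and a phase swing
  $|{\max \varphi_{100\,Hz-10\,kHz} - \overline{\varphi}_{<100\,Hz}}| >
  25^\circ$;
* **ski-slope**: mean phase above 10 kHz below $-80^\circ$, *or* all of:
  mean phase below 100 Hz above $-35^\circ$, mean phase above 50 kHz below
  $-70^\circ$, and a successive-frequency phase step exceeding $25^\circ$ in
  absolute value;
* **mixed** is the default.

Three choices here were genuinely open and are fixed as follows. The
evaluation order (outlier, hockey-stick, ski-slope, mixed) is not stated by
the rules themselves; outlier must run first because its magnitudes satisfy
neither shape rule's intent, and the hockey-stick/ski-slope order is
practically irrelevant because hockey-stick's magnitude gate empties the
overlap. The phase-slope statistic is compared via absolute value: for a
decreasing sigmoid the signed successive difference is negative, and a signed
reading of the ski-slope slope condition could never fire. The ski-slope rule
is written for iridium-oxide arrays but is also applied to platinum arrays —
reclassifications of platinum sites into ski-slope do occur in practice — and
such labels carry a low-confidence note. A manual-override ledger
(`apply_overrides()`) mirrors the supervised-correction workflow and reports
the fraction of labels changed.

## The fitting protocol

`fit_randles()` fits the Randles/CPE model to the real and imaginary parts of
the spectrum at frequencies up to 10 kHz (inclusive); higher frequencies are
excluded because the dielectric roll-off of aging electrodes is outside the
fitted model. Residuals are modulus-weighted — both parts divided by $|Z|$ —
so that frequencies spanning five decades of magnitude contribute uniformly;
unit weighting is available for sensitivity checks. Initial values are
$R_E = 6\times10^7\,\Omega$, $Q = 5\times10^{-7}$, $n = 0.8$, and $R_S$ from
the real part of the impedance at 10 kHz; bounds are $R_E \in [10^4,
10^{11}]\,\Omega$, $Q \in [10^{-15}, 10^{-5}]$, $n \in [0, 1]$, $R_S \in
[10, 10^{12}]\,\Omega$ (the last in place of an unbounded $R_S$).

Numerically, $R_E$, $Q$ and $R_S$ are optimized in $\log_{10}$ space (they
span many decades) and the box bounds are enforced by a smooth sine
reparameterization inside a Levenberg–Marquardt solver. Projected-bound
updates were tried first and stall on a hard wall when parameters trade off —
for open-circuit-like spectra the optimizer would pin $R_S$ at its lower
bound away from the global optimum. A small family of deterministic starts
(the protocol start plus data-driven starts that read the CPE exponent off
the low-frequency phase and, after subtracting the estimated CPE, the access
resistance off the top of the fit window) makes recovery of noiseless
spectra numerically exact (fit cost below $10^{-12}$, parameters within
0.5%) across the whole archetype library and the random-parameter round
trips in the test suite; the search exits early once a numerically exact
optimum (cost below $10^{-18}$) is found, so nominal spectra pay for one
solver run only. Estimates that end within $10^{-3}$ of a bound (on the
internal scale) are flagged in `at_bound`; charge-transfer resistances pinned
at $10^{11}\,\Omega$ are expected for failed sites and should not be read
quantitatively. $R_E$ is identifiable only when it saturates the branch
inside the measured band (roughly $R_E Q\, w_{min}^n < 10$); the tests
assert its recovery only there.

## Longitudinal analytics

Sessions are categorical and ordered: in-vitro baseline, ~1 h post-op, then
weekly from week 2 (`session_rank()` maps them to $-1, 0, w$). Analytics
include the 1 kHz magnitude (exact grid sample when present; log-log
interpolation otherwise, since spectra are locally near power-law), the
phase-peak frequency `f_peak()` (grid argmax, ties to the lowest frequency —
no sub-grid refinement, because the measured grid is what shifts), category
population tables whose per-session counts plus an `unmeasured` column always
sum to the roster (whole-array failures appear as unmeasured), and group-wise
aggregation that emits mean and SEM (sample sd over $\sqrt{count}$) only when
more than three channels populate a cell. Area and unit conversions for
comparing CPE parameters across electrode geometries
(`scale_areal_admittance()`, `scale_access_resistance()`,
`convert_q_units()`) round out the module.

Inferential statistics (ANOVA, Kruskal–Wallis, signed-rank comparisons) are
deliberately not re-implemented; users can feed the exported tables to
`stats::aov`, `stats::kruskal.test` and friends.

## The synthetic cohort and what it does (not) show

`archetype_library()` packages one circuit per array-type × category ×
condition combination, with the four Randles fields set to the published
group-mean fits. Three kinds of entries are package choices, marked with
provenance `"chosen"`:

* ski-slope archetypes carry $R_p = 10^8\,\Omega$ (the observed plateau
  range) and $C_d = 2\,nF$, sized so the reconstructed spectrum satisfies the
  ski-slope phase rule;
* the iridium-oxide mixed in-vivo archetype carries $R_p = 10^6\,\Omega$,
  representing moderate Faradaic leakage at aged sites. This is needed
  because a pure Randles reconstruction from that row's means reaches the
  access-resistance plateau inside the 100 Hz–50 kHz band and would satisfy
  the hockey-stick rules — the group means inherit an $R_S$ that the actual
  mixed spectra (which never show a plateau) do not support;
* the outlier archetypes carry a chosen CPE magnitude ($10^{-11}$ iridium
  oxide, $10^{-10}$ platinum) instead of the published outlier-group means.
  The published means average a small number of highly skewed, bound-pinned
  fits and reconstruct to low-frequency magnitudes far below the outlier
  thresholds; physically, an open-circuit failure couples through a tiny
  capacitance, which is what the chosen values encode.

With these choices the library satisfies *label closure*: every archetype,
simulated noiselessly on the default grid, is classified as its own category.
Measurement noise is log-normal on magnitude (standard deviation in decades,
preserving positivity) and additive Gaussian on phase, independent — the
simplest law with the right support; the defaults used in the robustness
tests (0.05 decades, 3°) represent a generous session-to-session measurement
scatter. The default cohort mirrors the study structure: five iridium-oxide
and six platinum 16-channel arrays over 13 sessions, with scripted
trajectories encoding the reported failure narratives (a whole-array
ski-slope switch at week 8 followed by loss of the array; an early
hockey-stick to mixed conversion; platinum arrays turning outlier en masse;
stable platinum arrays).

What passing tests show: the rules, fits and analytics are mutually
consistent and robust to substantial measurement noise *on spectra generated
by the package's own circuit model*. What they do not show: performance on
real spectra, whose within-category variability (channel-to-channel parameter
spread, drift, correlated noise, instrument artifacts) the point-mass
archetypes do not emulate. Published classification accuracy on the original
data is context, not something this package can reproduce, since no dataset
was released.

## The SVM benchmark

`crossval_gaussian_svm()` reproduces the machine-learning comparison: one
row per (spectrum, frequency) with predictors $\log_{10} f$,
$\log_{10}|Z|$, phase, channel and session ordinal; a radial-kernel SVM
(one-vs-one) with kernel scale $\sqrt{P}/4$ ($P = 5$ predictors), the
convention the "fine Gaussian" preset denotes; features standardized with
training-fold statistics; stratified seeded 5-fold cross-validation (a
grouped-by-spectrum fold option guards against row-level leakage, which the
row-level default deliberately mirrors rather than corrects). The SMO
stopping tolerance defaults to 0.01 — looser than the solver's generic
0.001 — because predicted classes depend on the sign of the decision
function, not the final duality gap, while training time on tens of
thousands of near-duplicate rows does. On the noiseless default cohort
(~68,000 rows) the acceptance suite asserts an overall cross-validated
accuracy of at least 95% with a valid confusion matrix.

## Problem sizes and reproducibility

The test suite exercises: the full default cohort (2,192 spectra) for
simulation, classification and the SVM benchmark; 100 random-parameter fit
round trips plus the ten archetypes for the fitter; 1,000 noisy spectra for
classification robustness; and 1,000 random feature vectors against a
brute-force rule oracle. All randomness flows from explicit seeds; CLI runs
(`run_cli()`) record the seed and options in a JSON manifest next to every
output, and identical configuration plus seed reproduces outputs byte for
byte.

## Known limitations

* Archetypes are point masses at group means; no within-category parameter
  dispersion is simulated.
* Category transitions are scripted, not mechanistic; the simulator makes no
  claim about degradation dynamics.
* The extended circuit is simulation-only; fitting always uses the Randles
  form (as in the source protocol), so shunt/dielectric parameters are never
  estimated from data.
* No Warburg/diffusion element and no inductive artifacts; spectra outside
  the passive RC repertoire will fit poorly and should be screened by the
  classifier first.
* The 1 kHz interpolation and the `f_peak` tie rule are extensions needed
  for grids other than the default; on the default grid they reduce to the
  raw sample and the plain argmax.
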