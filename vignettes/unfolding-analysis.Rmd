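---
title: "Methods: denaturation thermodynamics and 15N relaxation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: denaturation thermodynamics and 15N relaxation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unfoldnmr)
```

unfoldnmr implements the quantitative core of a chemical-denaturation study
of a small protein followed by optical spectroscopy and solution NMR: how a
βγ-crystallin-like, predominantly β-sheet protein loses its fold as guanidine
hydrochloride (GdmCl) is titrated in, and what residual structure and motion
survive in the denatured states. This vignette documents the models, their
assumptions, the tunable parameters, and the numerical choices, in the order
the pipeline applies them.

## Two-state denaturation thermodynamics

Optical melting curves — CD ellipticity at 218 nm or tryptophan fluorescence
at 331 nm versus denaturant concentration $D$ — are fitted to the two-state
(folded ⇌ unfolded) model with a linear free-energy dependence on denaturant:

$$Y(D) = \frac{s_n + s_d\,K(D)}{1 + K(D)}, \qquad
  K(D) = \exp\!\left[-\frac{g_1 - m_1 D}{R T}\right]$$

with native/denatured baseline signals $s_n, s_d$, free-energy change $g_1$
(kcal/mol), m-value $m_1$ (kcal mol$^{-1}$ M$^{-1}$) and
$R = 1.987$ cal K$^{-1}$ mol$^{-1}$. The transition midpoint is $g_1/m_1$.
Assumptions: exactly two thermodynamic states populated, $\Delta G$ linear in
$D$ over the fitted range, and baselines flat (a sloping-baseline variant is
available via `sloping_baselines = TRUE` but off by default, since flat
baselines are the minimal model consistent with constant folded/denatured
signals). CD and fluorescence curves are fitted independently; no global
multi-probe fit is attempted.

`fit_two_state()` uses Levenberg–Marquardt least squares. Starting values are
data-driven — baselines from the means of the concentration terciles, the
midpoint from the half-signal crossing, and $m_1$ by inverting the central
finite-difference slope $dY/dD|_{mid} = (s_d - s_n)m_1/(4RT)$ — with five
deterministically scaled restarts of $m_1$ on failure, so the fit needs no
random starts. A curve whose signal range is indistinguishable from zero
raises "no transition detected" rather than returning a degenerate fit. The
midpoint error uses the delta method on $(g_1, m_1)$ with their covariance.

GdmCl concentrations prepared by weight are checked refractometrically;
`gdmcl_from_refractive_index()` converts a refractive-index increment to
molarity with the Nozaki (1972) cubic calibration, monotone over its
calibrated domain [0, 0.12].

## Relaxation rates and the heteronuclear NOE

$^{15}$N $R_1$ (inversion recovery) and $R_2$ (CPMG) are extracted per
residue from peak-height decays $I(t) = A + B e^{-Rt}$. The offset $A$ — the
steady-state intensity at $t = \infty$ — is kept free for inversion recovery,
where magnetization recovers toward thermal equilibrium, and fixed at zero
for CPMG, where transverse magnetization decays completely. The delay
schedules embedded as defaults (11 inversion-recovery delays from 10 to
1100 ms, 10 CPMG delays from 10 to 190 ms, three of each recorded twice)
match common practice for proteins of this size; duplicated delays provide a
direct noise estimate via the pooled replicate SD
(`duplicate_delay_error()`). The intensity-error hierarchy is: explicit
per-point errors, then duplicate-delay pooled SD, then post-hoc residual SD —
the best information available, applied deterministically.

The heteronuclear NOE is the ratio $I_{sat}/I_{eq}$ of peak intensities with
and without proton saturation; its error propagates the RMS background noise
of the two spectra. Negative NOEs are meaningful (sub-nanosecond flexibility,
typically chain termini) and are never clipped.

## Reduced spectral density mapping

With data at a single field, the motional information in $(R_1, R_2, NOE)$
is summarized model-independently by three spectral density values. The
package uses the reduced mapping with a single effective high frequency
$0.87\,\omega_H$:

$$\sigma_{NH} = R_1 (NOE - 1)\frac{\gamma_N}{\gamma_H}, \qquad
  J(\omega_H) = \frac{4\sigma_{NH}}{5 d^2}$$
$$J(\omega_N) = \frac{R_1 - \tfrac{7}{4} d^2 J(\omega_H)}{\tfrac{3}{4} d^2 + c^2}, \qquad
  J(0) = \frac{R_2 - \left(\tfrac{3}{8}d^2 + \tfrac{c^2}{2}\right) J(\omega_N)
         - \tfrac{13}{8} d^2 J(\omega_H)}{\tfrac{d^2}{2} + \tfrac{2 c^2}{3}}$$

with the dipolar constant $d^2 = 1.35 \times 10^9$ (rad/s)$^2$ and the
$^{15}$N CSA constant $c^2 = 1.25 \times 10^9$ or $2.25 \times 10^9$
(rad/s)$^2$ at 600- and 800-MHz-class fields ($c^2$ scales with field
squared in between). $\gamma_N/\gamma_H = -0.10136$ is carried with its sign
so that $NOE < 1$ gives $\sigma_{NH} > 0$. The mapping is linear in the
observables, so `back_calculate_rates()` is its exact inverse and the
round-trip identity is enforced in the tests to $10^{-10}$ relative — this
isolates correctness of the implementation from any convention ambiguity in
the printed constants. Errors propagate first-order through the Jacobian
with respect to $(R_1, R_2, NOE)$, treating the three as independent.
Negative mapped $J$ values, which noise can produce, are flagged, not
rejected.

The only approximation is the single effective high frequency: on rates
generated from the full five-frequency expressions the mapped $J(0)$ agrees
with the analytic value to well under 5% for tumbling times in the
nanosecond range (checked in the test suite).

## Correlation times from the J–J regression

Across residues, $J(\omega)$ at the two nonzero frequencies correlates
linearly with $J(0)$: $J(\omega_{N,H}) = \alpha J(0) + \beta$. Substituting
a single-Lorentzian spectral density into this relation yields a cubic in
the correlation time $\tau_c$:

$$2\alpha\omega^2\tau_c^3 + 5\beta\omega^2\tau_c^2 + 2(\alpha - 1)\tau_c + 5\beta = 0.$$

`correlation_times()` solves it with $\omega$ in rad/ns and $\beta$ in
ns/rad, so the roots emerge in ns without $10^9$ scale factors. All three
roots are reported; real positive roots are labelled by timescale — chemical
exchange (≥ 100 ns as seen by this equation, i.e. the ms–µs regime),
overall tumbling (1–100 ns), internal motion (< 1 ns) — and complex or
non-positive roots are nonphysical (printed as "IM"). The band edges
operationalize the qualitative ms-to-µs / sub-ns / ps language of the
field and are configurable. Because the coefficients are real, complex
roots must come in conjugate pairs; a solved set never contains exactly one
complex root, and the solver is checked against an independent
companion-matrix oracle to $10^{-9}$ relative on a thousand random
coefficient draws, including the degenerate families $\alpha = 0$ (the
cubic collapses to a quadratic; the third root is reported absent) and
$\beta = 0$ ($\tau_c = 0$ is factored out exactly rather than left to
numerical noise).

Conformational exchange is screened with $R_2 R_1$ and $R_2/R_1$; a residue
is flagged when its ratio exceeds the condition mean by more than one SD.
The one-SD default is a reproducible operationalization of the usual
"distinctly higher ratio" criterion and is exposed as a parameter.

## Residue-level propensity calls

* **Secondary chemical shifts.** $(\Delta C^\alpha - \Delta C^\beta)$
  against the embedded Wishart (1995) random-coil table; positive runs
  suggest helix, negative strand. Glycine (no $C^\beta$) contributes
  $\Delta C^\alpha$ alone and is flagged rather than dropped, keeping
  profiles dense. A custom random-coil table can be supplied; absolute
  values depend on that choice, so only the sign/segment structure is
  treated as meaningful.
* **$^3J(H^N\!-\!H^\alpha)$ classes.** Helical below 5.5 Hz (α-helix and
  PP$_\parallel$ both fall in the 4.0–5.5 Hz band), coil 5.5–8.0 Hz
  inclusive, strand above 8 Hz; thresholds configurable.
  `summarize_structure_fractions()` turns classes into percentages.
* **Temperature coefficients.** Amide-proton shift versus temperature
  (default schedule 15–36 °C in 3 °C steps, converted to K at parse time)
  fitted by least squares; slopes more positive than −4.5 ppb/K (strict
  inequality, configurable) class the amide as hydrogen-bond protected.
* **AABUF.** Per-residue average area buried upon folding from the Rose
  (1985) scale, smoothed with a nine-residue centered moving average. At
  the termini the window shrinks to the available neighbors so every
  residue keeps a value (full-length profiles), rather than trimming four
  residues per end.
* **HSQC intensities.** Normalized per condition by the median observed
  intensity — robust to the handful of exchange-broadened outliers that a
  mean would follow; missing peaks (broadened beyond detection) stay
  missing rather than becoming zeros.
* **Sequential NOEs.** Assigned cross-peak pairs are filtered to
  $d_{NN}(i, i+1)$ contacts and collapsed into maximal contiguous runs, the
  signature of transiently helical stretches.

## Synthetic data: what it emulates, and what it does not

Every analysis stage has a paired seeded generator (`simulate_*`), so the
pipeline is testable end-to-end without measured data:
single-exponential decays at the embedded delay schedules; two-state melts
(default grid 0–6 M at 0.2 M, 31 points); shift tables with planted
helix/strand segments (offsets +2.6/−0.4 and −1.4/+1.0 ppm on
C$^\alpha$/C$^\beta$ — generator conventions of typical literature
magnitude, not measured values); linear temperature series on the 8-point
schedule; and relaxation triples from a two-timescale (model-free) spectral
density with known $\tau_m$, $S^2$, $\tau_e$, assembled through the full
five-frequency rate expressions so the reduced mapping is genuinely
approximated, not trivially inverted. Noise defaults are 1% relative on
intensities, 0.02 ppm absolute on shifts, and 2% relative on optical
signals — plausible experimental magnitudes, all configurable. A fixed seed
gives bit-identical output.

What passing these tests shows is that the estimators invert the models
they assume, at realistic noise, and that the algebraic stages are exact.
What it cannot show: the generators have no peak overlap, no assignment
errors, no baseline drift, no correlated noise between $R_1$ and $R_2$, and
no deviation from single-exponential or two-state behavior — so agreement
on synthetic data does not certify accuracy on spectra that violate those
assumptions.

The bundled `m_crystallin_synthetic.fasta` is an 85-residue *synthetic*
stand-in sequence (the deposited sequence is not redistributed here): the
residue identities at every position named in the published literature on
this protein — including Gln 84, Ile 85 and three prolines — are honored,
and the file is used only to exercise sequence plumbing and AABUF
profiling.

## Problem sizes and determinism

The stochastic recovery checks use 100 seeded two-state fits, 200 seeded
decay fits and 100 seeded regression sets — enough for stable medians with
seconds-scale runtime. Deterministic checks (cubic roots, mapping round
trips, oracle comparisons) use 1,000-point sweeps. All seeds are explicit;
reruns are byte-identical.

## Known limitations

* Single-field reduced mapping only; no Lipari–Szabo model-free fitting of
  $S^2$/$\tau_e$/$R_{ex}$ per residue, and no field-dependent $R_{ex}$
  decomposition.
* Two-state melts only: no three-state or global linear-extrapolation fits
  across probes.
* Mono-exponential decays only: no CPMG relaxation-dispersion analysis.
* The pipeline starts at peak heights and chemical shifts; no spectral
  processing, peak picking, or resonance assignment.
* The NMR-STAR reader covers the assigned-chemical-shift loop only
  (duplicate atom entries: last wins, with a warning); there is no
  NMR-STAR writer.
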