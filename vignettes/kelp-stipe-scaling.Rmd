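---
title: "Methods: tensile mechanics, allometric scaling and the juvenile-adult breakpoint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tensile mechanics, allometric scaling and the juvenile-adult breakpoint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kelpmech)
```

`kelpmech` turns two kinds of raw measurements on bull kelp
(*Nereocystis luetkeana*) — tensile pulls of stipes to failure, and
morphometric tables spanning juvenile and adult life stages — into a
scaling analysis: material properties per specimen, standard major axis
(SMA) regressions of each property against stipe length with a
classification against geometric null slopes, and a segmented-regression
estimate of where bulb-vs-stipe scaling switches from juvenile isometry to
adult allometry. This vignette records the models, the numerical choices,
and what the synthetic validation does and does not establish.

## 1. From force-extension records to material properties

A tensile record holds samples $(x_j, F_j)$ of crosshead extension (mm) and
force (N), nominally at 100 Hz with the crosshead rising at
50.8 mm min$^{-1}$, plus the initial stipe length $L_0$ (mm) and the
fracture surface area $A$ (mm$^2$) measured at the break.

**Baseline.** The force trace is tared by the first sample's force and
floored at zero; the strain origin is the first sample. Taring by the first
sample (rather than an average of several early samples) keeps the
extraction exact on records that start at zero load: any average over a
rising toe is strictly positive and would bias every stress-derived
quantity. No toe trimming is applied — the failure criterion and the
windowed modulus estimate are already insensitive to the toe.

**Failure detection.** Failure is the first sample $i$ with
$F_i \le (1 - d)\,\max_{k \le i} F_k$, with drop fraction $d = 0.5$ by
default. Two guards make this robust to load-cell noise without touching
the recorded values:

* a centred median filter (width 5 samples) is applied to the force trace
  *for detection only*;
* the running peak must exceed an absolute floor (`min_peak`, default
  0.1 N) before a drop can qualify — in the toe region the running maximum
  is itself noise-sized, and a relative criterion alone would fire on the
  first downward wiggle. The floor is absolute rather than relative to the
  global maximum so that samples recorded after the break can never alter
  the detected failure.

$F_{fail}$ is defined as the running-maximum force at the failure sample,
i.e. the peak preceding the qualifying drop; with this convention
$F_{fail} = F_{max}$ by construction, and both are reported.

**Properties.** Let $p = \arg\max_{k \le i} F_k$ be the peak-force sample.
All integrals and the failure strain use $p$ as their endpoint: the energy
absorbed *before* catastrophic failure is the quantity of mechanical
interest, and the drop itself is not integrated. With
$\sigma = F/A$ and $\varepsilon = (x - x_1)/L_0$:

* $W_{fail} = \int_0^{x_p} F\,dx$ (trapezoidal, N·mm $\times 10^{-3}$ → J);
* $\sigma_{max} = F_{max}/A$ (N/mm$^2$ $\times 10^6$ → Pa);
* $\varepsilon_{fail} = \varepsilon_p$ (dimensionless);
* toughness $= \int_0^{\varepsilon_p} \sigma\,d\varepsilon$
  (Pa $\times 10^{-6}$ → MJ m$^{-3}$);
* Young's modulus $E$ = the *maximum* over all contiguous windows of $w$
  samples in $[1, p]$ of the OLS slope of $\sigma$ on $\varepsilon$ — the
  tangent modulus of the stiffest part of the curve, which a compliant toe
  cannot contaminate. Default $w = \max(5, \lceil 0.1\,p \rceil)$: wide
  enough to average instrument noise, narrow enough to stay inside the
  linear region. The rolling slopes are computed from centred cumulative
  sums, so the estimator is $O(n)$ and exact (to rounding) on linear data.

Because the work and toughness integrals share bounds and the unit algebra
is exact, every record satisfies the identity
$\text{toughness} \times A \times L_0 \times 10^{-3} = W_{fail}$
to machine precision; the test suite asserts it at $10^{-9}$ relative.

Specimens flagged as clamp or cradle failures are excluded from property
extraction but retained in the exclusions log, so specimen counts are
conserved: every tensile input appears exactly once in the properties table
or the exclusions table.

## 2. Scaling regressions and classification

Allometric relationships are fitted on $\log_{10}$-transformed variables
(slope, CI and $R^2$ are invariant to the log base and to unit changes; the
base only moves intercepts). The SMA slope is
$b = \mathrm{sign}(r)\, s_y / s_x$ with intercept
$\bar y - b \bar x$, and the analytic $(1-\alpha)$ CI is
$b\,(\sqrt{B + 1} \pm \sqrt{B})$ with
$B = F_{1-\alpha;\,1,\,n-2}\,(1 - r^2)/(n - 2)$, bounds ordered so the
interval is valid for negative slopes. SMA is the right Model II choice
here because both axes are field measurements with comparable error. Two
numerical details: $1 - r^2$ is snapped to zero when below $10^{-12}$ (on
exactly collinear data rounding in the correlation otherwise leaves a
spurious $\sim 10^{-8}$-wide CI), and an $|r| < 10^{-12}$ correlation
raises an "ambiguous sign" error rather than guessing the slope's sign.

Strain at failure is dimensionless, so it is regressed *raw* against
$\log_{10}$ stipe length by OLS with a $t$-based CI — the magnitude of its
reported intercept (≈ 0.7, a plausible raw strain) indicates the response
was not log-transformed in this regression.

The default table fits nine regressions against $\log_{10}$ stipe length
(cm): bulb width for adults and for juveniles (null slope 1), break surface
area and failure force (null 2), work to failure (null 3), and modulus,
maximum stress, toughness (SMA) and strain at failure (OLS) against null 0.
Classification is purely CI-based: null inside the CI → isometric
(or "independent" for null 0); CI entirely above → positive allometry;
entirely below → negative allometry. Widening the CI (smaller $\alpha$) can
therefore never move a classification *away* from the null — a property the
tests check. Life-stage subsets use stipe length, juveniles $< 40$ cm and
adults $> 200$ cm; specimens between the thresholds enter only the pooled
breakpoint fit. Missing values are dropped listwise per regression with a
logged count, and a failed regression poisons only its own row of the
table.

## 3. The isometry-allometry breakpoint

The pooled $\log_{10}$ bulb-vs-stipe data are fitted with a continuous
two-segment model with breakpoint $\psi$, by iterative linearization: at
the current $\psi$, regress $y$ on
$\{1,\ x,\ (x - \psi)_+,\ -\mathbf{1}[x > \psi]\}$ and update
$\psi \leftarrow \psi + \hat\gamma/\hat\beta$, where $\hat\beta$ is the
slope-change coefficient and $\hat\gamma$ the indicator coefficient. Steps
that would increase the SSE are halved (up to 10 times); iteration stops
when $\psi$ moves less than `tol` ($10^{-8}$), when the SSE stalls, or at
100 iterations (returning the best iterate flagged non-converged). At the
solution, $SE(\psi) = SE(\hat\gamma)/|\hat\beta|$, and the breakpoint is
reported on the measurement scale as $10^{\psi}$ cm with the delta-method
SE $\ln(10)\,10^{\psi}\,SE(\psi)$ — the SE is estimated on the log scale,
where the model is linear, and transformed, rather than estimated on the
raw scale. $\psi$ is constrained to the interval between the second
smallest and second largest $x$ so both segments keep at least two points.

**Starting value.** The SSE profile in $\psi$ is only piecewise smooth
(its form changes each time $\psi$ crosses a data point), and with a gap
between the juvenile and adult size ranges it has multiple local minima. A
fixed start such as the median strands the iteration in a non-global local
minimum on a material fraction of datasets. The default start therefore
scans the SSE at the midpoints between consecutive distinct $x$ values
together with a 64-point uniform grid (wide gaps in $x$ hold basins whose
minimum sits far from the midpoint), and the iteration is refined from the
five best candidates, keeping the lowest-SSE solution. With this start the
fit matches a 10,000-point brute-force grid search (`grid_breakpoint`, the
independent oracle) to within one grid step on every one of 250 simulated
study-design datasets.

One breakpoint only: the biology under study is a single juvenile→adult
transition, and multi-breakpoint search is out of scope, as are existence
tests (Davies-type) for the breakpoint.

## 4. Synthetic data and what the validation shows

The generators encode the study conditions the pipeline targets, chosen
once and fixed:

* **Morphometrics** (`simulate_morphometrics`): 22 juveniles drawn
  log-uniformly on 2.1–36.1 cm and 27 adults on 200–3000 cm — the juvenile
  collection range, and an adult range starting at the maturity threshold —
  with $\log_{10}$ bulb width following a continuous two-segment law,
  slopes 1.19 (juvenile) and 0.70 (adult) around a 33.2 cm breakpoint, and
  Gaussian noise (sd 0.08) on the log scale, i.e. multiplicative biological
  variation. The intercept default ($-0.3$, log$_{10}$ mm at 1 cm) gives a
  realistic ≈ 8 mm bulb on a 10 cm stipe; reported intercepts depend on
  this unit convention and are not comparable across unit choices.
* **Tensile curves** (`simulate_tensile_test`): a quadratic toe over
  $[0, t\,\varepsilon_{fail}]$ joined $C^1$ to a linear region of slope
  $E$ reaching $\sigma_{max}$ at $\varepsilon_{fail}$, then a collapse to
  10% of peak force; additive Gaussian force noise (instrument noise).
  Geometry makes $(E, \sigma_{max}, \varepsilon_{fail}, t)$ redundant —
  $\sigma_{max} = E\,\varepsilon_{fail}\,(1 - t/2)$ — so any three may be
  given and the fourth is derived; inconsistent combinations raise an error
  rather than silently rescaling. Defaults ($E = 4$ MPa,
  $\varepsilon_{fail} = 0.45$, $t = 0.2$, hence
  $\sigma_{max} = 1.62$ MPa; noise sd 0.02 N ≈ 0.6% of the 3.24 N peak)
  sit at the magnitudes a mid-sized juvenile stipe implies.
* **Study-level coupling** (`simulate_study`): per-juvenile fracture area
  and modulus follow size power laws (exponents 0.66 and $-1.23$) with
  size-independent strain at failure, so the biomechanical regressions see
  realistic structure; adults carry morphometrics only, mirroring a design
  in which drift-collected adults are not mechanically tested.

What passing tests establish: exact noiseless round trips through every
stage (machine precision), the energy identity on every record, the SMA
closed-form identities ($|b_{SMA}| = |b_{OLS}|/|r|$, swap symmetry
$b_{xy} = 1/b_{yx}$, log-base invariance) against independent `lm()`
routes, 95% CI coverage of 93–94% over 1,000 simulated juvenile samples
(inside the 95 ± 3% band; the small deficit is the expected SMA bias when
noise sits mainly on $y$), analytic-vs-bootstrap CI agreement within
Monte-Carlo and small-sample error, grid-oracle agreement for the
breakpoint, median property-recovery errors under 2% at instrument-level
noise, and a median recovered breakpoint within one simulated SE of the
generating 33.2 cm.

What they do not establish: real stipes are viscoelastic, strain-rate
sensitive, and fail by crack growth from damage; the generator's idealized
curve family cannot represent, e.g., strain hardening, so it ties
$\sigma_{max}$ to $E\,\varepsilon_{fail}$ and cannot simultaneously
reproduce a *falling* modulus and a *rising* maximum stress with size, as
field data can show. The generators validate the estimators, not the
biology; field noise levels and size distributions will differ from the
placeholder defaults.

## 5. Problem sizes, determinism and limitations

The validation experiments run at deliberate sizes — 1,000 replicates for
CI coverage, 500 for breakpoint recovery, 100 tensile recoveries, 50
datasets against a 10,000-point grid — chosen so the whole suite completes
in about half a minute while leaving Monte-Carlo error well inside each
acceptance band. All generators take explicit seeds and are fully
deterministic given one; the pipeline itself is deterministic given inputs
and configuration, and `write_report()` emits byte-identical files (17
significant digits, so CSV round trips preserve doubles exactly).

Known limitations: engineering (conventional) strain only, no true-strain
or cyclic/viscoelastic analysis; a single breakpoint; no permutation
p-values for the SMA fits (classification is CI-based); fracture surface
area is an input, not measured from images; and the SMA slope is biased
upward by $1/|r|$ when variation is predominantly in $y$ — on such data the
OLS route is the better estimator, which is why the dimensionless strain at
failure uses it.
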