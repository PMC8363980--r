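# kelpmech

Biomechanics and allometric scaling of bull kelp (*Nereocystis luetkeana*)
stipes.

Bull kelp is an annual, canopy-forming kelp: every year juvenile sporophytes
must grow from the relatively calm benthos up into the water column, where
drag regimes are far harsher. Whether the stipe's morphology and material
properties change along that journey is a scaling question: does the bulb
keep pace with the stipe (isometry), and do strength, stiffness, toughness
and extensibility stay constant as stipes lengthen? `kelpmech` implements
the full analysis pipeline for answering it from two kinds of raw data:

* **tensile test records** — force–extension time series from pulling a
  stipe to failure (nominally 100 Hz sampling, 50.8 mm min⁻¹ crosshead),
  plus the initial stipe length L₀ and the fracture surface area SA;
* **morphometric tables** — stipe length, bulb width and stipe widths per
  specimen, across juvenile (< 40 cm) and adult (> 200 cm) life stages.

## What it computes

**Material properties** (`extract_properties`). Failure is detected as the
first sample whose force drops to half the running peak; properties are then
F_max, F_fail, work to failure W_fail = ∫F dx, stress σ = F/SA, conventional
strain ε = ΔL/L₀, extensibility ε_fail, maximum stress σ_max, Young's
modulus E (the steepest windowed tangent slope of the σ–ε curve) and
toughness ∫σ dε. Units are fixed: mm, N, mm² in; J, Pa, MJ m⁻³ out, so that
`toughness × SA × L₀ = W_fail` holds exactly.

**Allometric scaling** (`sma_fit`, `ols_fit`, `run_scaling_table`). Log–log
relationships are fitted by standard major axis (Model II) regression,
appropriate when both variables carry error:

    b = sign(r) · s_y / s_x,   CI: b·(√(B+1) ± √B),
    B = F(1−α; 1, n−2) · (1−r²)/(n−2)

Each slope is compared with its geometric null: 1 for bulb width vs stipe
length, 2 for areas and forces, 3 for work (volume), 0 for true material
properties. A null slope outside the 95% CI means positive or negative
allometry; inside means isometry (or size-independence when the null is 0).
Extensibility, being dimensionless, is fitted by OLS.

**Breakpoint** (`segmented_fit`). The transition from juvenile isometry to
adult allometry is estimated by segmented regression with iterative
linearization: regress y on {1, x, (x−ψ)₊, −1[x>ψ]} and update
ψ ← ψ + γ̂/β̂ until convergence, with SE(ψ) = SE(γ̂)/|β̂| and a delta-method
back-transform to cm. A brute-force grid search (`grid_breakpoint`) serves
as an independent oracle.

**Synthetic data** (`simulate_morphometrics`, `simulate_tensile_test`,
`simulate_study`) generate seeded datasets with known ground truth — a
two-segment bulb-vs-stipe power law (slopes 1.19/0.70, breakpoint 33.2 cm)
and toe + linear-elastic tensile curves with a catastrophic force drop — so
every stage of the pipeline is testable without field data.

## Worked example

```r
library(kelpmech)
study  <- simulate_study(seed = 7)      # 22 juveniles + 27 adults, known truth
report <- run_full_analysis(study$morphometrics, study$tensile_records)
report
#> Kelp stipe scaling analysis
#>   22 specimens with material properties, 0 excluded
#>   Scaling table:
#>               regression h0 method  n   slope  ci_low ci_high     classification
#>      bulb_vs_stipe_adult  1    SMA 27  0.7077  0.6432  0.7787 negative_allometry
#>   bulb_vs_stipe_juvenile  1    SMA 22  1.1991  1.1149  1.2896 positive_allometry
#>      break_area_vs_stipe  2    SMA 22  0.7107  0.5935  0.8512 negative_allometry
#>  youngs_modulus_vs_stipe  0    SMA 22 -1.2131 -1.2956 -1.1358 negative_allometry
#>       sigma_max_vs_stipe  0    SMA 22 -1.2240 -1.3119 -1.1420 negative_allometry
#>    epsilon_fail_vs_stipe  0    OLS 22 -0.0199 -0.0627  0.0228        independent
#>       toughness_vs_stipe  0    SMA 22 -1.2594 -1.3721 -1.1560 negative_allometry
#>          F_fail_vs_stipe  2    SMA 22 -0.6320 -0.7881 -0.5069 negative_allometry
#>          W_fail_vs_stipe  3    SMA 22  0.5250  0.3969  0.6945 negative_allometry
#>   Breakpoint: 35.0 cm (SE 10.2 cm)
```

Reading this: adult bulbs lengthen more slowly than stipes (slope 0.71
against a null of 1 → negative allometry) while juvenile bulbs keep pace or
better (1.20); the generating modulus exponent (−1.23) is recovered with a
CI that excludes 0; strain at failure shows no size trend; and the segmented
fit places the isometry→allometry transition at 35 cm, within one standard
error of the generating 33.2 cm breakpoint. Per-specimen properties are in
`report$properties`, exclusions (clamp/cradle failures, undetectable drops)
in `report$exclusions`, and `write_report(report, dir)` serializes
everything deterministically.

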