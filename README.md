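# rtdcontrol

Residence-time-distribution (RTD) modeling and control-strategy toolkit
for a three-unit continuous direct-compression line: two in-series
powder blenders feeding a tablet-press feed frame.

In continuous drug-product manufacturing, a feeder disturbance reaches
the tablets later, smeared and attenuated by the mixing along the line.
`rtdcontrol` quantifies that smearing and turns it into a control
strategy, for process modelers and control engineers working on
continuous direct compression:

* **Unit RTD models.** Each blending unit is a plug-flow delay θ
  followed by two equal stirred tanks (τ each):
  `E(t) = (t−θ) e^{−(t−θ)/τ} / τ²` for `t ≥ θ`, with mean
  `MRT = θ + 2τ`. Units compose by convolution.
* **Joint fitting with sequential deconvolution.** Impulse-experiment
  traces are normalized to densities and fitted jointly across
  operating conditions with one τ per condition and a single shared
  ratio `R = τ/θ` per unit, in the only feasible order for an in-series
  line: Blender 2 → Blender 1 → feed frame, threading fitted kernels
  downstream (`fit_unit_joint()`, `deconvolution_sequence()`).
* **Empirical MRT surfaces.** `MRT = A/ṁ + B/β + C/(ṁβ) + D` for the
  blenders and `MRT = E/ṁ² + D` for the feed frame, fitted by
  inverse-ε weighted closed-form least squares (`fit_empirical()`,
  `predict_mrt()`).
* **Prediction and control.** Downstream tablet concentration from 1 s
  feeder data (`predict_downstream()`), disturbance dampability funnel
  maps (`funnel_region()`), RMSEP validation (`rmsep()`,
  `gen_step_validation()`), and statistically tightened rejection
  limits `85 + z√(RMSEP² + σ_w²)` / `115 − z√(RMSEP² + σ_w²)`
  (`rejection_limits()`).
* **Synthetic campaigns.** Because no experimental curves are
  distributed, a first-class generator simulates tracer-impulse
  campaigns and step-change validation runs with configurable
  measurement noise (`gen_campaign()`, `gen_impulse()`).

## Worked example

Simulate Blender 2 impulse experiments at all 12 studied conditions
(4 mass flows × 3 impeller speeds, 2 %LC NIR noise), refit them
jointly, and build a control kernel at the 50 kg/h center point:

```r
library(rtdcontrol)

ff <- reference_constants()$feedframe
predict_mrt(ff, operating_condition(50))
#> [1] 82.86

design <- campaign_design()
b2_pulses <- gen_campaign(design[design$target_unit == "blender2", ],
                          noise = noise_model(nir_sigma = 2), seed = 1)
fit <- fit_unit_joint(b2_pulses, control = fit_control(n_starts = 4))
fit
#> <unit_fit_result> blender2: 12 conditions, shared R = 0.379 (eps 0.0027), SSE = 0.02084
#>    mass_flow speed tau_tank  theta    mrt eps_tau eps_mrt
#> 1         15   150   48.549 128.11 225.21 0.51454  2.5506
#> 2         15   210   29.537  77.94 137.01 0.26156  1.3310
#> ...
#> 12        90   300    6.875  18.14  31.89 0.04371  0.2394

kern <- build_system_kernel(
  params_from_mrt_r(74.5, reference_r("blender1")),
  params_from_mrt_r(55.4, reference_r("blender2")),
  rtd_params_at(operating_condition(50), ff, reference_r("feedframe")))
kern
#> <system_kernel> MRT 212.8 s on 1089 x 1 s grid (unit MRTs: 74.5 + 55.4 + 82.86)

max_outlet_deviation(kern, disturbance_spec(amplitude = 30, duration = 50))
#> [1] 10.78711

rejection_limits(6, sigma_weight = 0)
#> <rejection_limits> [94.870, 105.130] %LC (RMSEP 6, sigma_w 0, z 1.645)
```

Reading the numbers: the recovered shared ratio 0.379 says Blender 2 is
transport-dominated (delay ≈ 2.6× the tank time); the fitted MRTs fall
from ~225 s at 15 kg/h / 150 rpm to ~32 s at 90 kg/h / 300 rpm, and the
generating values (e.g. 224, 137, 85.2 s at 15 kg/h) sit within the
reported ε of the estimates. At 50 kg/h the full line averages ~213 s
of residence; a ±30 %LC feeder upset lasting 50 s would still reach the
tablets at ~10.8 %LC peak deviation, outside a 95–105 band — useful
dampability at this throughput requires shorter upsets or smaller
amplitudes. With the 6 %LC validation acceptance criterion and no
tablet-weight variance, in-process rejection tightens from 85/115 to
94.87/105.13 %LC.

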