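# ctmar — metal artifact reduction for fan-beam CT

Metal implants block diagnostic X-rays almost completely, so the sinogram
samples whose rays cross an implant (the *metal trace* `T_M`) carry
essentially no information and reconstruct into severe streak artifacts.
`ctmar` implements and compares three sinogram-completion corrections for
2-D fan-beam CT, together with the full polychromatic simulation pipeline
needed to evaluate them quantitatively:

* **LIN** — linear interpolation across every trace run, per view;
* **NMAR** — normalized MAR: interpolate `p0 / R(prior)` across the trace,
  then multiply the prior projection back (threshold-based and
  segmentation-based prior builders included);
* the **multi-prior method** — the package's core. The pre-corrected image
  `f_k` is partitioned into `N` intensity tiers by *recursive active
  contour* (RAC) segmentation: repeated Chan–Vese minimization of

  ```
  F(phi) = ∫ (I − c1)² H(phi) + (I − c2)² (1 − H(phi)) + mu |D H(phi)|
  ```

  where after each round the background is replaced by the minimum of the
  foreground, so `N` adapts to the object's complexity (`mu = 0.1`). The
  tiers' forward projections `beta_j = R(I_j)` form a sinogram basis and

  ```
  d = argmin_{d >= 0} ‖p0 − Σ d_j beta_j‖_{T_M^c} + alpha ‖∇p0 − Σ d_j ∇beta_j‖_{∂T_M}
  ```

  is solved by Nelder–Mead (`alpha = 0.1`). The trace is replaced by
  `Σ d_j beta_j + delta_hat`, where `delta_hat` interpolates the residual
  `delta = p0 − Σ d_j beta_j` across the trace — so the corrected sinogram
  equals the measurement exactly off the trace. The loop repeats, stopping
  when `‖delta‖` falls below 10% of its first value or stops improving.

Simulation support: a phantom library (Shepp-Logan variant with two gold
inserts, jaw-like and abdomen-like phantoms), an ICRU-44-style attenuation
table, a filtered 120 kVp tungsten spectrum model, Beer–Lambert
polychromatic projection with Poisson noise, fan-beam FBP, and MSE / ROI
standard-deviation evaluation against a metal-free beam-hardening-bearing
reference.

## Worked example

The end-to-end comparison (simulate → segment metal → correct with every
method → score against the metal-free reference):

```r
library(ctmar)
report <- run_study(study_config())   # three phantoms, six methods, seed 1
print(report)
```

```
<experiment_report> MSE (HU^2, metal excluded):
           phantom uncorrected    lin nmar_th nmar_seg_s nmar_seg_e proposed
 shepp_logan_metal     4853236 8904.9   23748     8359.0     8331.1   8351.1
          jaw_like     4945582 5274.5   27912     1404.7     1001.2    991.4
      abdomen_like     3988313  927.6    1991      733.4      742.9    746.4
```

Reading the table: uncorrected images are destroyed by the implants (MSE in
the millions of HU²); plain interpolation (LIN) recovers most of the image;
a poor threshold prior makes NMAR *worse* than LIN; good RAC priors help
substantially; and on the complex jaw phantom — multiple bone objects,
hence strong beam hardening — the multi-prior method with residual
compensation is the best of all methods. On the simple Shepp-Logan variant
it is statistically tied with NMAR using the same prior, which is the
theoretically expected behaviour. The RAC segmentation chose `N = 3`, `3`
and `4` priors for the three phantoms; the fitted coefficients are
interpretable region attenuations, e.g. for the Shepp-Logan variant
`d = (0.023, 0.039, 0.062) /mm` — soft tissue, bright tissue tier, bone:

```r
signif(report$detail$shepp_logan_metal$results$proposed$d, 3)
#> [1] 0.0234 0.0394 0.0616
```

Single steps are exposed individually (`polychromatic_sinogram()`,
`fbp_reconstruct()`, `segment_metal()`, `metal_trace()`, `rac_segment()`,
`lin_mar()`, `nmar()`, `proposed_mar()`); a thin command-line wrapper with
`simulate` / `run` / `eval` subcommands lives in `inst/cli/mar.R`.

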