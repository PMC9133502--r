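# petkern

Dynamic PET kernel reconstruction and lp-ntPET kinetic modeling workbench.

Transient changes in endogenous neurotransmitter levels (for example a
dopamine release after a challenge) show up in dynamic PET as a dip in the
tracer time activity curve of receptor-rich regions. The linear parametric
neurotransmitter PET (lp-ntPET) model detects and times that dip by
extending the reference-tissue model with a time-varying efflux term:

    C_T(t) = R1·C_R(t) + k2·∫C_R − k2a·∫C_T − γ·∫C_T·h_i ,

with a gamma-variate response h_i(t) of onset t_d, peak t_p and skewness α,
fitted by non-negative least squares over an exhaustive grid of 2,394
response shapes. Whether the fitted activation magnitude γ (min⁻¹) and its
timing are usable depends heavily on the noise in the reconstructed dynamic
frames. petkern exists to study exactly that: it simulates a 2D rat-brain
phantom scan with known kinetics, Poisson counting noise and photon
attenuation, reconstructs it with

* **IFR** — independent-frame MLEM,
* **IFR+HYPR** — MLEM followed by highly constrained backprojection
  denoising, and
* **Kernel** — spatiotemporal kernel expectation-maximization with
  data-derived spatial (9×9 window, 0.8 threshold, 48 nearest neighbours)
  and temporal (15-frame window) kernel matrices,

then fits lp-ntPET regionally and voxel-wise, computes activation response
profiles ARP(t) = 100·γ·h(t)/k2a, parametric maps with γ t-statistics,
ABC credible intervals, and seeded Monte-Carlo comparisons (COV, bias,
paired rest-vs-active tests) across reconstruction arms. It is aimed at
preclinical PET methodologists evaluating reconstruction and denoising
choices for neurotransmitter-release studies.

## Worked example

Simulate the phantom at 40 million counts, reconstruct, and fit the active
region:

```r
library(petkern)

setup  <- sim_setup()                      # phantom + TACs + system model
counts <- sample_poisson_counts(
            forward_project_frames(setup$truth, setup$sys, setup$framing, 4e7),
            seed = 1)
imgs   <- reconstruct_arms(counts, setup, arms = "kernel", n_iter = 300)

C_R <- region_tac_extract(imgs$kernel, setup$masks$reference)
tac <- region_tac_extract(imgs$kernel, setup$masks$active)
fit <- fit_lpntpet(tac, C_R)
fit
#> <lpntpet_fit> (nonneg gamma)
#>   R1 = 1.0107  k2 = 0.3374 min^-1  k2a = 0.0484 min^-1
#>   gamma = 0.0196 min^-1  (t_d = 19.0, t_p = 23.5, alpha = 0.5)
#>   SSE = 0.0001666  SE(gamma) = 0.001381  gamma/SE = 14.186
```

The fitted onset (19 min) lands within one grid step of the simulated
20-min challenge; γ/k2a ≈ 0.40 is the activation magnitude relative to
baseline efflux, so the ARP peaks near 40% of baseline at t_p. The
noise-free fit of the same phantom gives k2a = 0.0523, γ = 0.0186,
t_d = 20.5 — the anchor used for the bias columns of
`run_simulation_experiment()` summaries. `autoplot(fit)`,
`compute_arp(fit)`, `fit_parametric_maps()` and `abc_sample(fit)` continue
from here; `vignettes/methods.Rmd` documents every model and convention.

A thin CLI over the same functions lives in `inst/cli/petkern.R`
(subcommands `simulate`, `fit`, `abc`, `evaluate`).

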