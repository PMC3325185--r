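# invadosim

Kinetic modelling of MT1-MMP turnover and extracellular-matrix (ECM)
degradation at invadopodia.

Invasive cancer cells degrade the ECM at invadopodia, membrane protrusions
where the membrane-anchored protease MT1-MMP concentrates. Surface MT1-MMP is
rapidly inhibited by TIMP-2 and internalized, so sustained proteolysis
depends on continuous vesicle-mediated delivery. `invadosim` is for
quantitative cell biologists and modellers who want to (i) extract turnover
kinetics from FRAP measurements of surface proteins, (ii) simulate the
MT1-MMP/TIMP-2/proMMP-2 activation network with ECM proteolysis, well-mixed
or in 3D, and (iii) screen in-silico interventions that slow the turnover or
cut the supply of the protease.

## The models

**FRAP decomposition.** Recovery curves are exponential mixtures
`F(t) = P − Σᵢ aᵢ·exp(−t/τᵢ)` fitted by bounded multi-start
Levenberg–Marquardt with a semi-log curve-peeling cross-check and AICc model
selection. The reference control kinetics are τ = 26.0 s and 259 s with
amplitudes 40.7% and 17.5% of pre-bleach and a 41.8% non-recovering level;
blocking lysosomal delivery (bafilomycin) leaves a single 49.0 s component.

**Two-pool turnover model.** Surface MT1-MMP splits into pool D (constant
insertion flux `C_D`, density-dependent internalization `k_D`) and pool X
(docking-site-limited insertion `k_X·(M_S − M_X)`, constant internalization
`C_X`). The fluorescent content recovers as a double exponential with time
constants `1/k_D` and `1/k_X`; bafilomycin is `k_X = 0`. The fitted fast
constant gives an internalization rate of `60/26.0 = 2.31 min⁻¹`.

**Reaction network.** Species and mass-action reactions are generated from
binding rules — M14 dimerization, TIMP-2 on the catalytic site, proMMP-2 on a
bound TIMP-2, activation of proMMP-2 at the quadruple complex
M14·M14·T2·M2, inactivation of MMP-2 by TIMP-2, and ECM binding/cleavage by
T2-free M14 (`k_fn11p`) and active MMP-2 (`k_fn2p`) — with insertion and
internalization per pool and a monomer-conservation self-check on every
reaction. Deterministic integration uses a compiled fixed-step RK4 scheme;
the spatial variant adds explicit no-flux diffusion on a voxel grid inside
the same scheme. Readouts: ECM remaining, degradation rate (µM/s),
half-degradation time τ_h, inactivated (fully TIMP-2-occupied) MT1-MMP.

**Interventions.** `apply_reduction()` divides turnover rates and/or the
vesicular supply by a reduction factor; degradation efficacy is `1/τ_h`
normalized to control, and `synergy_index()` compares the combined
intervention against the multiplicative (Bliss) null.

## Worked example

```r
library(invadosim)

# 20 noisy control traces (0-330 s), averaged and decomposed
ds  <- generate_dataset(20, "control", noise = noise_spec(2, 42L))
fit <- fit_exponential_mixture(mean_trace(ds), 2)
fit
#> Exponential-mixture FRAP fit (2 components)
#>   tau[1] = 26.81 s   amp[1] = 42.01 %
#>   tau[2] = 321.6 s   amp[2] = 17.86 %
#>   plateau = 59.62 %  (non-recovering 40.38 %)
#>   rss = 21.66, converged = TRUE
```

The fast pool turns over with a ~27 s time constant (the generating truth is
26.0 s); the slow constant is recovered near 322 s — with a 330 s
acquisition window its sampling error is large (about 21% even for an
optimal estimator), which the package's statistical tests account for by
checking medians over replicated experiments.

```r
# turnover model reconstructed from the fit; bafilomycin = k_X frozen at 0
p <- params_from_fit(fit_exponential_mixture(generate_control_trace(), 2))
round(c(k_D_per_min = p$k_D * 60, k_X = p$k_X, plateau_D = p$C_D / p$k_D), 4)
#>  k_D_per_min        k_X   plateau_D
#>       2.3077     0.0039     40.7000

# control ECM degradation at 180 nM TIMP-2 and factor-10 interventions
sc  <- invadopodium_scenario()        # calibrated-default rate table
eff <- efficacy_curve(sc, factors = c(1, 10), dt = 0.05)
eff[eff$factor == 10, c("mode", "tau_half_s", "efficacy")]
#>       mode tau_half_s   efficacy
#> 2 turnover   579.7366 0.28053067
#> 4     conc  1100.7247 0.14775166
#> 6     both  6407.7154 0.02538095
synergy_index(eff, 10)
#> [1] 0.6123436
```

Half of the ECM is degraded in about 163 s under control conditions; a
tenfold reduction of the turnover rate alone slows that to 580 s (28% of the
control efficacy), cutting the vesicular supply tenfold slows it to 1101 s,
and doing both at once slows it to 6408 s — a 2.5% residual efficacy, far
below the 4.1% a multiplicative combination of the single interventions
would predict. The synergy index of 0.61 quantifies that
super-multiplicative inhibition, the model's central prediction.

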