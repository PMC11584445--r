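# coxplosive

Stochastic modelling of microfailure accumulation in loaded cortical bone,
as observed by acoustic emission (AE).

When a rib is bent to fracture, microcracks form and grow at random sites
in the bone microstructure; each one radiates an ultrasonic burst that an
AE sensor records as one event. Event arrivals accelerate with strain until
an avalanche of microfailures becomes the macroscopic fracture. This
package implements an explosive, doubly stochastic ("coxplosive") renewal
process for that phenomenology, the per-specimen estimation machinery, a
synthetic-cohort generator, and the cohort-level statistics that relate the
fitted parameters to donor age and body-mass index (BMI).

## The model

The process is indexed by tensile strain ε, not time. After the *k*-th
microfailure, the strain increment to the next one is exponential with a
geometrically growing hazard:

    Δε_k ~ Exp(λ_k),   λ_k = λ α^(−k+1),   0 < α < 1,   λ > 0.

Consequences, all in closed form:

* expected increments shrink geometrically, `E(Δε_k) = α^(k−1)/λ` — a
  New-Better-than-Used-in-Expectation damage process;
* the deterioration rate `β = −ln α > 0` is constant per event;
* the process is **explosive**: infinitely many events accumulate before
  the finite strain ε∞, with `E(ε∞) = μ∞ = 1/((1−α)λ)` — the model's
  expected fracture strain;
* segment expectations `μ_{i,j} = (α^i − α^j)/((1−α)λ)` are additive and
  telescope to μ∞.

Per specimen, `(α, λ)` are estimated by minimizing the expectation-matching
penalty

    Φ(α,λ) = [μ∞ − ε*_n]² + Σ_{k=1..n−1} [μ_{k,k+1} − (ε*_{k+1} − ε*_k)]²,

and the AE event energies above a threshold E_m follow a Pareto law
`P(E' ≤ E) = 1 − (E_m/E)^ν`, fitted by the Hill maximum-likelihood closed
form. Cohort-level structure (Spearman matrix, standardized PCA, the
regression of the leading "degradation" component on age and BMI) is
computed by `cohort_report()`.

## Worked example

```r
library(coxplosive)

p <- coxplosive_params(alpha = 0.9, lambda = 50)
p
#> Coxplosive process parameters
#>   alpha  = 0.9   (rate ratio)
#>   lambda = 50   (1/strain)
#>   beta   = 0.1054   (deterioration rate, -log alpha)
#>   E(total strain) = 0.2
```

`alpha = 0.9` means each microfailure multiplies the hazard by 1/0.9; with
`lambda = 50 /strain` the first event is expected around strain 0.02 and
the whole avalanche completes, on average, at strain `μ∞ = 0.2`.

```r
sim <- simulate_coxplosive(p, seed = 7)
sim
#> Coxplosive realization: 211 events, total strain 0.229663 (increment_underflow)
#>   alpha = 0.9, lambda = 50, E(total) = 0.2

fit <- fit_coxplosive(sim$cum_strains)
summary(fit)
#> Explosive microfailure process fit
#>
#>   events (N_AE)                 211
#>   max strain (last event)       0.2297
#>   alpha (rate ratio)            0.8749
#>   lambda (1/strain)             34.62
#>   beta = -log(alpha)            0.1336
#>   E(total strain)               0.2309
#>   penalty at optimum            0.001571
#>   converged                     TRUE
```

The fit recovers the rate ratio to about 0.03 and pins the expected total
strain (0.2309) to the realized fracture strain (0.2297); `plot(fit)` draws
the observed event-count staircase with simulated overlays.

A full synthetic study — 15 specimens with realistic age/BMI structure,
friction filtering, per-specimen fits, cohort statistics — is one call:

```r
out <- run_pipeline(cohort_config(), seed = 1)
out$report
#> Cohort report: 15 specimens
#>   PC1 variance fraction: 66.8%
#>   PC1 = -20.705 + 0.222 * age + 0.281 * BMI  (r^2 = 0.965)
#>   E(total strain) vs eps_max: Pearson r = 1.000
#>   correlation sign pattern: 8 of 8 conditions hold
```

The report carries the 7×7 Spearman matrix with p-values, the PCA variance
fractions and loadings, the PC1 ~ age + BMI regression, and the agreement
between fitted `E(ε∞)` and observed `ε_max`. At the realistic cohort size
of 15 the individual correlations are noisy; on 200-specimen cohorts the
expected qualitative pattern (α, λ, N_AE rising with the degradation axis;
ν and ε_max falling; PC1 dominant) appears in essentially every cohort.

Event tables are plain CSV (`strain,energy,channel`), metadata is
`specimen_id,age,bmi`, so real AE data in the same layout can be fitted
with `fit_cohort("data_dir/")`; per-specimen result records round-trip
through `write_specimen_records()`/`read_specimen_records()` at full float
precision.

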