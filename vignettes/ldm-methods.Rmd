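---
title: "Estimating plasmid conjugation rates from transconjugant-free cocultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating plasmid conjugation rates from transconjugant-free cocultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldmrate)
```

## The model

A well-mixed mating assay contains donors (plasmid-bearing), recipients
(plasmid-free) and transconjugants (recipients that acquired the plasmid),
with densities $D_t$, $R_t$, $T_t$ in cfu/ml. Populations grow
exponentially and plasmid transfer follows mass action:

$$\frac{dD}{dt} = \psi_D D, \qquad
  \frac{dR}{dt} = \psi_R R - \gamma_D D R - \gamma_T T R, \qquad
  \frac{dT}{dt} = \psi_T T + \gamma_D D R + \gamma_T T R.$$

The $\psi$ parameters are per-capita growth rates (1/hr) and the $\gamma$
parameters are conjugation rates (ml cell$^{-1}$ hr$^{-1}$): $\gamma_D$ for
donor-to-recipient transfer, $\gamma_T$ for transconjugant-to-recipient
transfer. Units are fixed package-wide: hours, cfu/ml, ml cell$^{-1}$
hr$^{-1}$.

The classic end-point ("SIM") estimator assumes all growth and conjugation
rates are equal and reads the conjugation rate off the final densities:

$$\hat\gamma_D^{\mathrm{SIM}}
  = \psi \, \ln\!\Big(1 + \frac{T_{\tilde t}}{R_{\tilde t}}
    \frac{N_{\tilde t}}{D_{\tilde t}}\Big) \frac{1}{N_{\tilde t} - N_0},$$

with $N = D + R + T$ and $\psi$ the realized total-population growth rate
$\ln(N_{\tilde t}/N_0)/\tilde t$. When transconjugants conjugate faster
than donors ($\gamma_T \gg \gamma_D$) — common when donor and recipient are
different species — the transconjugant count is dominated by
transconjugant-to-recipient chains and the SIM estimate inflates over time.

The estimator at the heart of this package avoids $T_{\tilde t}$
altogether. Because a coculture starts with no transconjugants, the first
transconjugant must arise from a donor-to-recipient event, which occurs at
rate $\gamma_D D_t R_t$. Treating that first event as an inhomogeneous
Poisson process with exponentially growing hosts gives the probability that
a culture is still transconjugant-free at time $\tilde t$:

$$p_0(\tilde t) = \exp\Big\{-\frac{\gamma_D D_0 R_0}{\psi_D + \psi_R}
  \big(e^{(\psi_D+\psi_R)\tilde t} - 1\big)\Big\},$$

the same logic by which Luria and Delbrück inferred mutation rates from
mutant-free cultures; conjugation behaves like mutation of a "wild type" of
size $D_0 R_0$ growing at $\psi_D + \psi_R$ (`ld_mutation_rate()` makes the
mapping explicit). Solving for $\gamma_D$ gives the parametric form
(`ldm_parametric()`), and substituting realized growth rates
$\ln(D_{\tilde t}/D_0)/\tilde t$ and $\ln(R_{\tilde t}/R_0)/\tilde t$ gives
the laboratory form (`ldm_endpoint()`):

$$\hat\gamma_D^{\mathrm{LDM}}
  = \frac{f\,[-\ln \hat p_0(\tilde t)]\,
    \big(\ln D_{\tilde t} R_{\tilde t} - \ln D_0 R_0\big)}
    {\tilde t\,\big(D_{\tilde t} R_{\tilde t} - D_0 R_0\big)},$$

where $\hat p_0$ is the fraction of parallel cocultures without
transconjugants and $f$ is the reciprocal of the coculture volume in ml
(100 µl wells give $f = 10$). The two forms are algebraically identical
under the realized-rate substitution — a property the test suite enforces
to pin down the placement of $\tilde t$, which typeset renderings of the
end-point formula leave ambiguous. Because only the *first*
donor-to-recipient event matters, the estimate is unbiased by $\gamma_T$,
$\psi_T$, or anything else that happens after $t^*$.

## Assumptions, and where they are encoded

* Donors and recipients grow exponentially at constant rates, and the loss
  of recipients to conversion is negligible ($\gamma_D D_t \ll \psi_R$).
  `ode_solve()` nevertheless integrates the full equations including
  recipient loss, so the approximation error is itself measurable.
* Transconjugants are initially absent ($T_0 = 0$); `p0_analytic()` and the
  samplers refuse inocula violating this.
* A single transconjugant cell founds a detectable (turbid) lineage under
  selection. Establishment failure is not modelled; the estimators expose a
  multiplicative hook for such corrections but default to none.
* No segregational plasmid loss, cell death, or resource limitation.

## Simulation engines

`gillespie_run()` is an exact stochastic simulation over the five
reactions (three divisions, two conjugation channels, with recipients
decremented on conversion), implemented in C++ and driven by R's RNG so
that `set.seed()` governs every draw. It records counts on a requested
sample grid, the first donor-to-recipient event time $t^*$, and stops at
`t_max` or at a total-count cap (default $10^9$, the usual end of a batch
assay). Because it walks every event it refuses configurations whose
expected event count exceeds $10^8$.

`hybrid_run()` is this package's fast companion engine, consistent with the
estimator's own assumptions: hosts follow their closed forms while the
transconjugant count is an explicit pure-birth path — immigration at
$\gamma_D D_t R_t$ (first draw taken by inverting $p_0$, so $t^*$ is exact
by construction) and per-capita birth $\psi_T + \gamma_T R_t$, simulated by
thinning with a piecewise-constant majorant refreshed every event or 0.1 hr
(host densities grow exponentially, so a global bound would be wasteful).
The test suite checks the two engines against each other and against the
analytic $p_0$ (Kolmogorov–Smirnov at $\alpha = 0.01$).

Volume is handled by converting densities to counts ($X = x V$) and scaling
conjugation propensities by $1/V$; the default 1-ml volume makes counts and
densities coincide. Ensembles (`run_ensemble()`) derive per-run seeds from
one master seed and are bitwise reproducible.

## The simulation study

`batch_design()` encodes how ensembles become estimate distributions: each
disjoint block of 100 runs yields one LDM estimate ($\hat p_0$ from the
block, densities from one seeded-randomly designated run, $f = 1/V$) and
the same designated run yields one SIM estimate — so 10,000 populations
give 100 estimates of each kind. Incubation times are chosen per parameter
setting and per method: the LDM time is the mean observed $t^*$
(`choose_t_ldm()`; the probability of transconjugant-free wells must be
away from 0 and 1, which happens in a window flanking the mean first-event
time), while the SIM time is where the ensemble's mean transconjugant count
first reaches 50 (`choose_t_sim()`, linearly interpolated between sample
times) — enough transconjugants to measure, hence necessarily later than
the LDM window. `incubation_sweep()` profiles both estimators on a 30-min
grid and flags, per method, grid times where fewer than 90% of estimates
are finite and nonzero; the flagging is per method because the two valid
windows differ. `parameter_sweep()` re-runs the study along a growth-rate
axis ($\psi_D = \psi_T$ varied, modelling plasmid cost or benefit) or a
conjugation axis ($\gamma_T$ varied). Summaries follow boxplot conventions:
type-7 quantiles (the interpolation rule is fixed and documented here
because several conventions exist), whiskers at 1.5 IQR clipped to the data
range, zeros retained and counted, invalid estimates counted but excluded
from the numbers. `compare_estimates()` applies Welch's t-test on log10
values, excluding (and counting) zeros.

At the reference setting used throughout the tests —
$\psi_D=\psi_R=\psi_T=1$, $\gamma_D=\gamma_T=10^{-6}$, $D_0=R_0=10^2$,
$T_0=0$ — the mean first-event time is about 2.4 hr and batched LDM
estimates recover $\gamma_D$ (the acceptance script recomputes the
geometric mean from 10,000 exact simulations). These inoculum and rate
values are deliberately small so that exact simulation of tens of
thousands of assays is cheap; they are not typical laboratory values,
and conclusions at realistic scales rest on the analytic results, not on
these simulations.

One empirical caveat this machinery makes visible: with
$\gamma_T = 100\,\gamma_D$, the SIM median at the mean-T-reaches-50
incubation time is only mildly inflated, because at that point the
transconjugant-driven flux $\gamma_T T R$ has not yet overtaken the donor
flux $\gamma_D D R$; the inflation grows steeply at later incubation
times. The direction of the bias (SIM above truth, LDM on it) is stable;
its magnitude depends strongly on when the assay is read.

## The plate layer

`plate_data` mirrors a 96-well LDM assay: 84 coculture wells scored
turbid/nonturbid after selection, three density wells sampled at both ends
of the incubation (`cfu_density()` converts colony counts via
count × dilution / volume; per-well densities are averaged on the linear
scale), and control wells — donor, recipient and transconjugant
monocultures plus post-incubation donor–recipient mixes — whose expected
states `validate_controls()` checks (failures leave the estimate
computable but flagged untrusted). `plate_ldm_estimate()` combines
$\hat p_0$, the densities, $\tilde t$ and $f$ through `ldm_endpoint()`;
one plate yields one estimate.

`generate_plate_fixture()` simulates such a plate: turbidity is Bernoulli
with success $1 - p_0(\tilde t)$ computed with the whole-well hazard
(halving the well volume raises the transconjugant-free probability — a
tested monotonicity), and colony counts are Poisson around the
deterministic expectations, the standard noise model for plate counts (the
choice is a convention; no claim is made about real plating error
structure). Auto-dilution targets at most ~300 expected colonies and the
generator refuses plates whose expected counts exceed $10^4$ (unreadable).
The generator reproduces exactly from its seed. What passing end-to-end
tests show is that the pipeline is internally consistent — parsing,
density arithmetic, $\hat p_0$, volume correction and estimator algebra
invert the generating model with small bias. They do not validate the
biological assumptions themselves (establishment, constant growth,
selection fidelity), which only the plate controls and a pre-assay can
address for a real system.

## Numerical choices

* $\psi_D + \psi_R = 0$ in $p_0$ and the estimators uses the analytic
  limit; for $|s\,t| < 10^{-8}$ the factor $(e^{st}-1)/s$ is evaluated by a
  second-order series to avoid cancellation.
* ODE integration: `deSolve::lsoda`, rtol $10^{-10}$, atol $10^{-10}$
  cfu/ml. The tight absolute tolerance is needed for the closed-form
  cross-checks at $10^{-8}$ relative accuracy.
* `mean_tstar_analytic()` integrates the survival function by adaptive
  quadrature, truncated where $p_0 < 10^{-12}$.
* Precision of $-\ln \hat p_0$ degrades as $\varepsilon/\Lambda$ when
  $\hat p_0 \to 1$; exact-inverse tests therefore assert at $10^{-7}$
  relative rather than machine epsilon on extreme inputs.
* $\hat p_0 = 0$ (all wells turbid) is an invalid estimate with a reason
  code; $\hat p_0 = 1$ is a valid zero. Both carry machine-readable
  reasons so sweeps can count them, mirroring the finite-and-nonzero
  filtering rule.
* Gillespie paths are exact at their sample times; off-grid states are
  interpolated geometrically (exact in expectation under exponential
  growth). Hybrid paths are exact everywhere via stored jump times.

## Problem sizes

The default test suite simulates 1,000–10,000 populations per check and
1,000 synthetic plates, completing in well under a minute for the unit
tests; `scripts/acceptance.R` re-runs the full 10,000-population recovery
study, the heterogeneity cell and the plate study from scratch. Full-scale
sweeps (10,000 populations per cell across eight-point parameter grids)
use the same code paths via `parameter_sweep()` and scale linearly.

## Limitations

No resource dynamics (Monod growth, stationary phase), no segregational
loss, no establishment-probability correction, no tau-leaping, and no
spatial structure. The supplementary-style alternative estimators (ASM,
TDR and relatives) are out of scope. The hybrid engine assumes
$T_0 = 0$ and ignores recipient depletion, so it should not be used where
conversions are a substantial fraction of the recipient population.
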