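---
title: "The confined flexible-chain model of thin-filament regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The confined flexible-chain model of thin-filament regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfcsim)
```

## The model

Striated-muscle contraction is switched on and off by calcium through the
azimuthal position of tropomyosin on the actin filament. `cfcsim` treats the
end-to-end linked tropomyosin–troponin (Tm–Tn) assembly on one strand of the
actin double helix as a single elastically homogeneous *continuous flexible
chain* (CFC) confined in a harmonic angular well on the actin surface. The
energy of a chain configuration $\phi(s)$ along the strand is

$$E\{\phi\} = \int_0^L \left[\tfrac{\kappa}{2}\,\phi''(s)^2 +
\tfrac{\alpha}{2}\,\phi(s)^2\right]\mathrm{d}s,$$

where $\kappa$ (pN nm$^4$) is the angular bending stiffness per unit length
and $\alpha$ (pN) the curvature of the confining well. The well minimum is
the *closed* angle $\phi_o = 0$. Actin-bound troponin-I (TnI) pins the chain
at the *blocked* angle $\phi_- < 0$; a strongly bound (isomerized) myosin-S1
pins it at the *open* angle $\phi_+ > 0$. Between pins the minimum-energy
(equally, thermal-mean) path satisfies
$(\mathrm{d}^4/\mathrm{d}s^4 + 4\xi^4)\,\phi = 0$ with
$\xi = (\alpha/4\kappa)^{1/4}$; $1/\xi$ is the persistence length of the
confined chain and sets the size of the cooperative unit (a kink spans
roughly $2/\xi$). Thermal fluctuations about the mean are Gaussian with a
free-chain standard deviation $\sigma_o = (k_BT/8\kappa\xi^3)^{1/2}$,
zero at every pin.

Because chain motion is fast compared with binding kinetics, the chain
regulates rates through the fraction of time it spends past a threshold
angle. With local mean $\bar\phi_i$ and SD $\sigma_i$ at site $i$:

* TnI rebinding: $r_I = \tfrac12\,\mathrm{erfc}[(\bar\phi_i - \phi_-)/
  (\sqrt2\,\sigma_i)]$, applied as $k_I = (r_I/r_I^o)\,k_I^o$;
* weak myosin binding ($\phi \ge \phi_o$): $r_{M1}$, with closed-state
  normalizer $r_{M1}^o = \tfrac12$, applied as
  $k_{M1} = (r_{M1}/r_{M1}^o)\,k_{M1}^o\,[M]$;
* weak-to-strong isomerization ($\phi \ge \phi_+$): $r_{M2}$, normalized by
  $r_{M2}^o = \tfrac12\,\mathrm{erfc}[\phi_+/(\sqrt2\,\sigma_o)]$.

Weak binding is further slowed by the empirical crowding factor
$\delta = 1 - 0.82\,(n_{AM}/n_A)$ and by myosin depletion
$[M] = [M_{tot}] - f[A_{tot}]$. TnI detachment $k_{-I}$ depends only on
calcium; $K_B = k_{-I}/k_I^o$ is the single calcium-dependent quantity, and
fitting it to stopped-flow transients at each calcium level yields the
sigmoidal $K_B$–pCa relationship whose steepness is summarized by a Hill
coefficient.

## Parameters

| symbol | meaning | default | units |
|---|---|---|---|
| $\phi_-$ | TnI pinning angle | $-25$ | deg |
| $\phi_+$ | myosin-imposed displacement | $10$ | deg |
| $\kappa$ | chain bending stiffness | $2.0\times10^4$ | pN nm$^4$ |
| $1/\xi$ | confined persistence length | $22.2$ | nm |
| $\sigma_o$ | free-chain angular SD | $29.7$ | deg |
| $\alpha$ | confining potential strength | $0.341$ | pN |
| $k_{M1}^o$ | weak binding rate | $4.2\times10^6$ | M$^{-1}$s$^{-1}$ |
| $k_{-M1}$ | weak detachment rate | $20$ | s$^{-1}$ |
| $k_{M2}^o$ | isomerization rate | $500$ | s$^{-1}$ |
| $k_{-M2}$ | reverse isomerization | $5$ | s$^{-1}$ |
| $k_I^o$ | TnI binding rate | $100$ | s$^{-1}$ |
| $k_{-I}$ | TnI detachment (high Ca$^{2+}$) | $\sim1200$ | s$^{-1}$ |

The derivation chain is implemented in `derive_chain_stiffness()`
($\kappa = L_{p,TmTn} k_BT \cdot R^2$ with $R = 4.5$ nm),
`derive_sigma_free()` ($\sigma_o$ from the 20 % blocked fraction of the
free chain), `derive_xi()` and `derive_alpha()`. Two numerical choices are
worth stating:

* **Thermal energy.** The published table is internally consistent only for
  $k_BT \approx 3.95$ pN nm ($\kappa_{TmTn}/L_{p,TmTn} = 987/250$), while
  the stated experimental temperature (20 °C) gives 4.045 pN nm. We default
  to `kBT = 4.045` and accept 1–5 % deviations from the printed derived
  values (`default_params()` checks the identities at 5 %); `kBT` is
  configurable everywhere.
* **Angles** are degrees at every interface and radians inside all energy
  and variance arithmetic; $\phi_o$ is fixed at 0 and offsets are not
  supported.

## The chain solver

`chain_solution()` discretizes the energy on a uniform grid (default
spacing $h = 5.5/4$ nm, $\xi h \approx 0.06$) with central differences for
$\phi''$ and natural free ends, and minimizes it subject to equality
constraints at pin nodes. The operator is pentadiagonal and positive
definite; means come from a banded constrained solve and variances from
$k_BT\,\mathrm{diag}(K_{ff}^{-1})$ via banded LDL$^\mathsf{T}$ factorization
with the Takahashi recurrences (exact on the band). Against closed forms,
the single-pin mean profile $\phi_p e^{-\xi s}(\cos\xi s + \sin\xi s)$ is
matched to $<0.5$ % for $s \le 4/\xi$ and the free-chain SD to $<1$ %
(second-order convergence in $h$).

Two physical points the implementation makes explicit:

* **Free ends are soft.** With natural boundary conditions the thermal SD
  at a chain end is about twice $\sigma_o$ (end compliance of a beam on an
  elastic foundation is four times the bulk value). $\sigma \le \sigma_o$
  therefore holds only in the interior, more than $\sim 6/\xi$ from an end;
  end sites of a 700-monomer strand are a negligible fraction.
* **Point pins do not decouple segments.** The operator is fourth order, so
  value-only constraints leak slope and curvature across a pin. A two-pin
  "pair" solve with free tails reproduces the global solution only when
  other pins are farther than $\sim 1/\xi$; at dense TnI spacing (7 sites
  $\approx 0.4/\xi$ apart) its mean deviates by up to $\sim 12$ % of
  $|\phi_-|$. The whole-chain solve is therefore the single source of truth
  here, including inside the engine.

`update_chain_solution()` recomputes only a window around changed pins.
Clamping two *adjacent* nodes at a window edge block-separates the
pentadiagonal operator, so the windowed mean equals the full re-solve
exactly given the clamped values; window sizes ($23/\xi$ for the mean, an
$11/\xi$ margin for the variance) keep the neglected exponential tails
below $10^{-8}$.

## The Monte Carlo engine

`run_transient()` simulates an ensemble of independent strands (two per
filament) with the fixed-timestep two-drawing scheme: at each step one
uniform draw per regulatory site decides TnI detachment/rebinding
($p_{-I} = k_{-I}\Delta t$, $p_I = (r_I/r_I^o) k_I^o \Delta t$, rebinding
forbidden while any myosin occupies the same monomer), then one draw per
actin site decides FREE↔WEAK↔STRONG transitions
($p_{M1} = \delta\,(r_{M1}/r_{M1}^o) k_{M1}^o [M] \Delta t$, etc.; strong
myosin must reverse-isomerize before detaching). Ensemble tallies
($f$, $n_{AM}$, $[M]$) refresh once per step. The compiled engine keeps a
per-strand chain field and refreshes it after every pin change with the
windowed solver above (window 32 sites, variance margin 14 sites, leak
$<10^{-3}\sigma_o$); after thousands of stochastic events the engine's
chain state still matches an exact re-solve to $\sim10^{-6}$ deg in the
mean and $\sim10^{-3}$ deg in the SD.

Numerical and design choices:

* $\Delta t = 10^{-5}$ s by default. A hard error is raised only if a
  probability bin can exceed 1, a warning above 0.05 — at high calcium
  $k_{-I}\Delta t \approx 0.012$ exceeds the ideal $k\Delta t \le 10^{-3}$
  regime, which is the published operating point; $\Delta t$ is
  configurable and a halving test confirms transients change by less than
  Monte Carlo error.
* Draws are made for **every** site each step, whether or not a transition
  is possible. This fixes the random-number stream alignment so that
  common-random-number fitting sees a smooth objective in $k_{-I}$.
* One seedable `xoshiro256**` stream per run, fixed iteration order
  (strand, then site): identical configuration and seed give bit-identical
  transients.
* Initialization: all sites free, all TnI bound, then `burn_in` (default
  0.5 s) of TnI-only dynamics before myosin becomes available, emulating
  pre-equilibration at a set calcium level before mixing.
* Probabilities within a drawing pass use the chain state from the start of
  the pass; the chain is refreshed between the two drawings.

## Observation and fitting

The comparison quantity is the fraction of sites *not* strongly bound
(`frac_not_R`), the proxy for normalized pyrene fluorescence.
`fit_tni_off()` minimizes the SSE between an observed trace and the
simulated trace over $\log_{10} k_{-I}$, with affine scale/offset nuisance
parameters profiled out in closed form — experimental normalization
conventions (min–max or initial-value) are unknown, and the affine profile
covers both. A coarse log-spaced scan brackets the minimum (refining
toward an edge a few times before declaring failure), then Brent search
finishes; a near-flat objective (high-calcium insensitivity) raises a
warning. `hill_fit()` fits the four-parameter log-logistic
$K_B(\mathrm{[Ca]})$ sigmoid — the functional form is our choice; only the
Hill coefficient is compared with published values.

`xi_sensitivity()` scales $1/\xi$ holding $\alpha$ fixed and re-deriving
$\kappa$. This is a deliberate choice between two readings of "change the
persistence length with other parameters unchanged": since
$\xi = (\alpha/4\kappa)^{1/4}$, either $\kappa$ or $\alpha$ must move with
$\xi$. At fixed $\alpha$, $\sigma_o = (k_BT\,\xi/2\alpha)^{1/2}$ *shrinks*
as $1/\xi$ grows — a stiffer, longer-range chain fluctuates less and
suppresses binding at low and intermediate calcium, which is the mechanism
the sensitivity analysis probes. At fixed $\kappa$, $\sigma_o$ instead
grows as $\xi^{-3/2}$ and the longer pinning range is almost exactly
offset by the larger fluctuations (measured: a 20 % increase in $1/\xi$
shifts the half-decay time by $\sim$2 % instead of $\sim$11 %), so that
convention probes nearly nothing.

## Synthetic data

The stopped-flow records behind the published fits are not deposited, so
`make_synthetic_transient()` generates the study conditions: a simulated
transient at a known $K_B$, min–max normalized, plus i.i.d. Gaussian noise
of SD 0.01 (a realistic photometric noise floor for a normalized
stopped-flow trace). Concentrations follow the published conditions —
excess actin 2.5 μM actin / 0.25 μM S1 with 2000 strands, excess myosin
0.5 μM / 5.0 μM with 200 strands — and recovery experiments in the test
suite use $K_B \in \{0.12, 0.47, 11.89\}$, the fitted values reported at
pCa 8.9/6.2/4.6. What passing recovery shows is that the *procedure* is
unbiased and precise under the model's own noise; it cannot certify the
published $K_B$ or Hill values, which derive from the undeposited
experimental data. Synthetic traces also lack instrument artifacts
(mixing dead time, drift, correlated noise).

## Problem sizes

Simulation sizes in the tests are scaled to single-CPU runs as the
package's own study design: the mass-action limit check uses 2000 strands
of 700 sites at $\Delta t = 2.5\,\mu$s over 35 ms; recovery fits use
350-site strands, 500-strand truth ensembles with 1 % noise and 150-strand
fitting ensembles at $\Delta t = 20\,\mu$s over 0.3 s (excess myosin) and
100 strands at $\Delta t = 50\,\mu$s over 2 s (excess actin); qualitative
checks (clustering, $1/\xi$ sensitivity, decay ordering) use 200 strands.
Filament length does not affect the conclusions, consistent with the
published observation, which is why 350-site strands are used where
throughput matters.

## Known limitations

* No allosteric TnC–Ca$^{2+}$ scheme: calcium enters only through
  $k_{-I}$.
* No strain-dependent TnI detachment; no interaction between the two
  chains of one filament; weakly bound myosin does not bias the chain
  solution (only the same-monomer rebinding prohibition is modeled).
* The crowding factor is an empirical stand-in for diffusion-limited
  slowing near saturated filaments, not a mechanistic steric model.
* The two-drawing scheme need not satisfy detailed balance exactly; the
  unregulated limits (all weights → 1) do recover mass-action kinetics,
  which is the regime the tests certify.
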