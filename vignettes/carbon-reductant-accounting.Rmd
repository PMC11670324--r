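---
title: "Carbon and reductant accounting in anoxic microcosms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carbon and reductant accounting in anoxic microcosms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anoxbal)
```

This vignette documents the scientific model behind `anoxbal`, the
conventions it commits to where several were defensible, and what its
verification on simulated data does and does not establish about real
incubations.

## Degree-of-reduction stoichiometry

The package's central primitive converts a net concentration change of a
compound into carbon and electron-equivalent units. The carbon factor is the
C count of the molecular formula. The reductant factor is the generalised
degree of reduction

$$\gamma = 4\,n_C + 1\,n_H - 2\,n_O - 3\,n_N,$$

the electron equivalents released per molecule on complete oxidation to CO~2~,
H~2~O and NH~3~. Two conventions are fixed, and fixed deliberately:

* **Neutral acid forms.** Organic acids enter as protonated formulas
  (acetic acid C~2~H~4~O~2~, formic CH~2~O~2~, propionic C~3~H~6~O~2~). The degree of
  reduction of an anion needs a charge term; under the neutral convention
  the standard factor pairs — 8/32 for N-acetylglucosamine, 1/2 formate,
  2/12 ethanol, 2/8 acetate, 3/14 propionate, 1/8 methane, 1/0 CO~2~ —
  fall out of the formula alone. `check_reaction_balance()` therefore also
  balances H and O without tracking protons or water of neutralisation
  separately: reactions are written between neutral species.

* **NH~3~ nitrogen reference.** With nitrogen referenced to ammonia
  (weight −3), the amino sugar's factor is 32; an NO~3~^−^ or N~2~ reference
  would give different values. Only the NH~3~ reference reproduces the
  standard amino-sugar factor, so no alternative reference is offered —
  silently switchable reference states are a classic source of
  irreproducible electron budgets.

Sulfur and phosphorus compounds, charged-species accounting and isotopes
are out of scope. A negative $\gamma$ (an oxidant such as O~2~) warns but
never aborts: hard errors are reserved for malformed input.

## Net turnover and closure

For a time frame the pipeline is differencing → matched-control subtraction
→ factor conversion → closure statistics. Choices made where practice
varies:

* **Replicates are averaged at each timepoint first**, then differenced;
  incubation studies report means of replicate flasks, and for means the
  order of averaging and differencing is immaterial. A `per_replicate`
  policy is retained because the two orders differ for standard errors. The
  package deliberately does not claim any particular uncertainty model
  beyond quadrature combination of endpoint standard errors.

* **Control matching is keyed on inhibitor status.** An unsupplemented
  control with methanogenesis inhibited (BES) is a different baseline from
  one without; subtracting across that boundary mixes two different
  endogenous product spectra, so a BES mismatch is an error, not a warning.

* **Unsampled frame boundaries are linearly interpolated** between the
  bracketing sampling days, with a warning; exact-match mode is available.
  Sampling every 1–2 days makes boundary misses routine, and linear
  interpolation is the weakest assumption that keeps frame additivity
  (Δ(0→4) + Δ(4→10) = Δ(0→10) whenever the boundary days are sampled).

* **Recovery above 100 % is reported as-is** with an `exceeds_100` flag.
  Measured budgets genuinely can over-close — endogenous sources
  mobilised by the treatment, or correlated analytical bias — and clipping
  would hide exactly the observation that matters. A frame with no net
  consumption has an *undefined* ratio (flag, not a number), never a
  division by zero.

* CO~2~ is one lumped pool; carbonate speciation is not modelled.

## Closed-chamber fluxes

The flux estimator is an ordinary least-squares slope of mixing ratio
against time, converted to areal units through the moles of air in the
chamber: $F = b\,PV/(RTA)$. No curvature correction (HMR-style) is applied:
over the short deployments the estimator targets (four points in 0–3 h)
linear accumulation is the appropriate default, and negative slopes
(uptake) are reported unchanged. Defaults are 293.15 K and 101.325 kPa,
both configurable.

Two slurry unit conversions are provided. Headspace volume-percent converts
to mmol per litre of slurry by the ideal gas law over the configured flask
geometry. The μM → μmol g⁻¹ dry weight divisor is a **configured constant**
(default 10.5, appropriate to 1:10 peat slurries): it is a property of the
soil's dry-weight density in the slurry, and deriving it from flask
geometry alone is not possible, so the package treats it — like the
commonly quoted 8 vol% H~2~ ≙ 8.4 mmol L⁻¹ equivalence — as configuration
rather than pretending to derive it.

## The synthetic microcosm simulator

The simulator exists so that every accounting stage can be checked against
bookkept ground truth. It integrates first-order kinetics over an element-
and electron-balanced reaction library:

| reaction | stoichiometry | k (d⁻¹) | lag (d) | BES-sensitive |
|---|---|---|---|---|
| primary NAG fermentation | C₈H₁₅NO₆ + 3 H₂O → 2 acetate + ethanol + formate + CO₂ + H₂ + NH₃ | 1.6 | 0 | no |
| formate methanogenesis | 4 HCOOH → CH₄ + 3 CO₂ + 2 H₂O | 0.8 | 2 | yes |
| hydrogenotrophic methanogenesis | 4 H₂ + CO₂ → CH₄ + 2 H₂O | 1.0 | 2 | yes |
| syntrophic ethanol oxidation | C₂H₅OH + H₂O → acetate + 2 H₂ | 0.6 | 2 | yes |
| hydrogenotrophic acetogenesis | 4 H₂ + 2 CO₂ → acetate + 2 H₂O | 0.1 | 0 | no |
| aceticlastic methanogenesis | CH₃COOH → CH₄ + CO₂ | 0.02 | 4 | yes |
| methylotrophic methanogenesis | 4 CH₃OH → 3 CH₄ + CO₂ + 2 H₂O | 0.3 | 2 | yes |

The primary fermentation stoichiometry is the unique small-integer solution
that routes an amino sugar's 8 C and 32 e⁻ into the observed product set
(acetate, ethanol, formate, CO₂, H₂, plus the amine nitrogen as NH₃).
Rate constants and lags are not fitted to any dataset — none is deposited —
they are chosen once so that the default scenario shows the canonical
succession of a 500 μM amino-sugar pulse: substrate exhausted within ~4
days, transient ethanol/formate maxima before day 4, methanogenesis
dominating days 4–10. The lags stand in for the enrichment delay of the
methanogenic guild; Monod kinetics, population dynamics and thermodynamic
feedback (H₂ partial-pressure control of syntrophy) are deliberately out of
scope.

Design choices worth flagging:

* **Syntrophic ethanol oxidation is marked BES-sensitive** although it
  produces no methane itself. Thermodynamically it proceeds only when a
  hydrogenotrophic partner keeps H₂ low; with methanogens inhibited and no
  H₂-pressure feedback in the model, flagging the syntrophic step as
  inhibited is the simplest faithful proxy, and it is what produces the
  experimentally observed signature of larger transient ethanol pools under
  BES. All CH₄-producing reactions are BES-sensitive by construction.

* **Endogenous background CO₂** is released at a constant rate
  (default 200 μM d⁻¹) from an explicitly tracked reservoir pool carried as
  CO₂-equivalent carbon ($\gamma = 0$). Peat mineralisation in situ runs on
  unresolved electron acceptors that the model does not represent;
  carrying the reservoir as already-oxidised carbon keeps the simulator's
  conservation guarantee exact without inventing an acceptor. Matched
  treatment/control subtraction removes this background exactly, because no
  reaction rate depends on the CO₂ concentration.

* **The unmeasured sink** diverts a fraction *s* of each reaction's
  substrate carbon and electrons into a bookkept sink pool instead of the
  products. Total C and e⁻ over *all* pools (sink included) remain
  conserved; the *measured* budget under a single-reaction scenario closes
  at exactly 100·(1−s) %, which is what makes *s* a controlled stand-in for
  the real phenomenon of products nobody measured.

* **Measured analytes** default to the set a typical HPLC + GC workflow
  quantifies (amino sugar, acetate, formate, ethanol, propionate, CO₂,
  CH₄); H₂ is tracked in the truth but not "measured", mirroring the common
  situation that reliable H₂ series are unavailable. Propionate is measured
  but has no producing reaction by default — its sources in peat are
  largely endogenous and stoichiometrically unresolved, so inventing one
  seemed worse than reporting a flat series.

* **Noise** is additive Gaussian per observation, truncated at zero.
  Nothing heteroscedastic is claimed; published incubation data report
  means ± SE only, which cannot constrain a richer error model. The default
  5 μM is ~1 % of the standard supplement.

## Numerical choices

Integration is fixed-step classical Runge–Kutta (RK4, step 0.01 d, via
`deSolve`), with sampling days spliced into the step grid. A fixed-step
explicit scheme is enough because all rates are first-order with constants
of order 1 d⁻¹ (step × rate ≈ 0.016 ≪ stability limit), and it makes runs
bit-reproducible across platforms in a way adaptive steppers are not. Total
carbon and electrons are linear invariants of the exact derivative, so any
Runge–Kutta preserves them to round-off — conservation drift over 10
simulated days is ~10⁻¹⁵ relative, and the test suite enforces ≤ 10⁻⁶.

A pool dipping below −10⁻⁶ × the state scale aborts the run with an
integrator error; concentrations are never silently clipped. (First-order
kinetics in the limiting substrate cannot drive that substrate negative,
but a co-substrate can be exhausted if a scenario under-provisions it — the
error names the remedy.) Reaction balance uses an absolute residual
tolerance of 10⁻⁹ to admit rational coefficients; formula atom counts are
integers only. All stochastic entry points require an explicit seed and are
reproducible byte-for-byte; `simulate_experiment()` derives per-treatment
seeds from the master seed so treatments are independent but jointly
reproducible.

Problem sizes throughout the package's own verification are deliberately
small — triplicate 10-day incubations at eight sampling days, thousand-fold
replication only for the scalar chamber-flux estimator — chosen as the
smallest sizes at which the statistical properties under test are
informative.

## What passing tests show, and what they do not

The simulator emulates the *designs* of amino-sugar and
methanogenic-substrate experiments (500 μM NAG ± 20 mM BES; 1 mM formate /
acetate / methanol; 8 vol% H₂ + 2 vol% CO₂ ≙ 8.4 / 2.1 mmol L⁻¹ slurry) and
the qualitative product successions those designs elicit. It does not
emulate microbial growth, inhibition kinetics beyond on/off BES, pH or
temperature effects, dissolved/gaseous partitioning (all pools are
slurry-equivalent μM), or the true endogenous respiratory network of peat.
Consequently, a green suite establishes that the *accounting* is correct —
factors derive from formulas, budgets close when they must, the sink is
attributed quantitatively, the flux estimator is unbiased and exact in the
noiseless limit — not that any particular field soil behaves like the
default scenario. On real data the package's outputs are only as closed as
the analyte coverage of the instrument park; that is precisely what the
recovery ratio is for.
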