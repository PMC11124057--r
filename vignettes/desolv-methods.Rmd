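---
title: "Modelling drug solubility in DES-water systems: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling drug solubility in DES-water systems: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(desolv)
```

# The problem

Deep eutectic solvents (DESs) — mixtures of a hydrogen-bond acceptor (HBA,
here choline chloride or betaine) and a donor (HBD, here a polyol) that are
liquid well below the melting points of their components — are attractive,
tunable solubilisers for poorly water-soluble drugs such as ibuprofen and
ketoprofen. Screening the composition space (which HBA, which HBD, what molar
ratio, how much water) experimentally is laborious: already 2 acceptors x 6
donors x 3 ratios gives 36 neat systems before any water dilution or
temperature variation. `desolv` implements a hybrid workflow: physically
motivated descriptors derived from screening-charge (sigma) profiles, a
solid-liquid-equilibrium (SLE) solubility baseline from fusion data, and a
machine-learned correction trained on measured solubility records, together
with the data-reduction steps that turn raw UV absorbance measurements into
mole-fraction solubility records.

# Sigma-profiles and sigma-potentials

A sigma-profile $p(\sigma)$ is the histogram of a molecule's COSMO
screening-charge density over its surface, expressed as surface area per bin
on the canonical grid of 61 points covering $\sigma \in [-0.03, +0.03]$
e/&Aring;&sup2; in steps of 0.001. All profiles in this package live on that
grid ([`sigma_grid()`]); CSV profiles are validated on load.

The solvent-side descriptor is the *sigma-potential* $\mu_S(\sigma)$ — the
affinity of liquid $S$ for surface of polarity $\sigma$. It is
temperature-dependent, which is why it (and not the temperature-independent
sigma-profile) is used as the descriptor family. `sigma_potential()` solves
the standard simplified COSMO-RS segment self-consistency

$$\ln\Gamma_S(\sigma) = -\ln \sum_{\sigma'} p_S(\sigma')\,\Gamma_S(\sigma')\,
  \exp\!\left[-\frac{W(\sigma,\sigma')}{RT}\right], \qquad
  \mu_S(\sigma) = \frac{RT\,\ln\Gamma_S(\sigma)}{a_\mathrm{eff}}$$

with the exchange energy
$W(\sigma,\sigma') = \tfrac{\alpha'}{2}(\sigma+\sigma')^2 +
c_\mathrm{hb}\,\max(0, \sigma_\mathrm{acc}-\sigma_\mathrm{hb})\,
\min(0, \sigma_\mathrm{don}+\sigma_\mathrm{hb})$
combining the electrostatic misfit and hydrogen-bond terms. The constants
(`cosmo_constants()`: $\alpha'$ = 68897 kJ &Aring;⁴/(mol e&sup2;),
$c_\mathrm{hb}$ = 358067 kJ &Aring;⁴/(mol e&sup2;),
$\sigma_\mathrm{hb}$ = 0.0084 e/&Aring;&sup2;, $a_\mathrm{eff}$ = 7.5
&Aring;&sup2;) are the widely published open COSMO-SAC parameterisation
converted to kJ; they are versioned configuration, not fitted quantities.
This engine reproduces the *structure* of commercial COSMO-RS descriptors —
even potentials for neutral surfaces, deep hydrogen-bond wells beyond
$\pm\sigma_\mathrm{hb}$, temperature dependence — without the commercial
parametrisation, which is exactly what the downstream statistical pipeline
needs. No claim is made that absolute values match any particular commercial
release.

Numerics: the self-consistency is solved by damped fixed-point iteration in
$\ln\Gamma$ (damping 0.5, tolerance $10^{-10}$ on the max-abs update, at most
10000 iterations; non-convergence is an error reporting the final residual).
The damping and log-space iteration make the solve robust for profiles with
strong hydrogen-bond donors, where the undamped map converges slowly or
oscillates. The solver is cross-checked in the test suite against an
independently coded brute-force successive-substitution oracle on toy
profiles, agreeing to better than $10^{-8}$ kJ/(mol &Aring;&sup2;).

For multicomponent solvents, `mixture_potential()` linearly combines the
*pure-component sigma-potentials* weighted by solute-free mole fractions.
This follows the stated descriptor convention ("the sigma-potential weighted
by the solute-free mole fraction"); the physically stricter alternative —
mixing the profiles and re-solving the self-consistency for the mixed liquid
— is available as `method = "profile"` for comparison. For descriptor
purposes the two differ only mildly and the linear rule keeps the descriptor
an explicit function of the component potentials.

DES composition convention: an HBA:HBD ratio 1:$k$ contributes solute-free
fractions $(1/(1+k),\ k/(1+k))$ within the DES; water enters through
$x^*_\mathrm{DES}$, the solute-free DES mole fraction of the aqueous mixture;
all fractions are renormalised to sum to one. Choline chloride is treated as
a single (ion-pair) component since no ion-resolved treatment is available at
this level.

The per-record descriptor is the *relative* sigma-potential
$\Delta\mu(\sigma) = \mu_\mathrm{solute}(\sigma) -
\mu_\mathrm{solvent}(\sigma)$ at the record's temperature
(`relative_potential()`), which vanishes identically when solute and solvent
coincide.

# SLE solubility from fusion data

The first descriptor is a computed solubility. Ideal solubility comes from
the Schr&ouml;der-van Laar equation using the melting temperature $T_m$ and
fusion enthalpy $\Delta H_m$,

$$\ln x_\mathrm{id}(T) = -\frac{\Delta H_m}{R}\Big(\frac{1}{T} -
\frac{1}{T_m}\Big) + \frac{\Delta C_p}{R}\Big(\frac{T_m}{T} - 1 -
\ln\frac{T_m}{T}\Big),$$

with the heat-capacity term included only when $\Delta C_p$ is supplied (the
study compounds use the two-parameter form; the package ships their
literature-mean fusion data: ibuprofen $T_m$ = 348.64 K, $\Delta H_m$ = 26.69
kJ/mol; ketoprofen 367.99 K, 25.52 kJ/mol; flurbiprofen 387.34 K, 27.86
kJ/mol). At 298.15 K this gives $x_\mathrm{id} \approx 0.210$ for ibuprofen
and $\approx 0.142$ for ketoprofen.

Saturation solves $\ln(x\,\gamma(x,T)) = \ln x_\mathrm{id}(T)$ *fully*, by a
bracketed root solve in $\ln x$ on $(0, 1]$ (`solve_sle()`), rather than by
successive substitution $x \leftarrow x_\mathrm{id}/\gamma(x)$ — the
substitution map oscillates for highly soluble cases (steep $\gamma$ near
saturation), which the test suite demonstrates explicitly. Three activity
models satisfy the solver contract: ideal ($\gamma \equiv 1$), constant, and
a COSMO-RS-style model in which $\ln\gamma$ is the solute's sigma-potential
(residual) chemical potential in the saturated mixture minus that in its own
pure liquid; the combinatorial contribution is neglected, a documented
simplification. The constant-$\gamma$ identity $x_\mathrm{sat} =
x_\mathrm{id}/c$ is verified to $10^{-10}$.

# Descriptor selection

For each sigma grid point and each of two record subsets — conventional
(non-DES) solvents and DES systems — the package computes the $R^2$ of a
univariate ordinary-least-squares regression of $\log_{10} x_\mathrm{exp}$ on
$\Delta\mu(\sigma)$ (`r2_profile()`). A point is retained when $R^2 > 0.4$ in
*either* subset, with a strict inequality at the boundary
(`select_sigma_points()`). Two open choices were resolved as follows: the
response is the decadal logarithm (solubilities span orders of magnitude and
downstream accuracy is quoted in log units; a linear-scale flag exists), and
the regression is univariate OLS per point, the simplest reading of a
per-sigma $R^2$. The feature table (`build_feature_table()`) is then: the
decadal log of the SLE-computed solubility first, the selected
$\Delta\mu(\sigma)$ values in grid order, and the temperature. Removing the
computed-solubility descriptor measurably degrades held-out accuracy on
synthetic data, echoing its role as the anchor descriptor.

# Model selection and the ensemble

*Splitting.* Records are shuffled with a seed and split 70/15/15 into
training, test and validation sets. The hold-out counts use ceilings taken
sequentially — $n_\mathrm{test} = \lceil 0.15\,n \rceil$, then
$n_\mathrm{val} = \lceil 0.15/0.85 \cdot (n - n_\mathrm{test}) \rceil$ — the
convention of common Python splitters, which maps 581 records to exactly
(406, 88, 87), whereas a single largest-remainder apportionment would give
(407, 87, 87). Stratification (by solute or solvent class) is not applied;
plain seeded shuffling keeps the three subsets exchangeable.

*Scoring.* Each candidate is scored by `custom_score()`: cross-validated MAE
plus $\lambda$ times a learning-curve-analysis (LCA) penalty, where the
penalty is the mean validation MAE at the largest learning-curve training
size plus the train/validation gap there. During tuning the learning curve
uses two points (50% and 100% of the data); the final chosen model is audited
with a 20-point curve over the same range. The relative weighting of
accuracy and generalisability is genuinely open; $\lambda = 1$ with an MAE
base is this package's documented default, and the score returns its breakdown
(`base_error`, `lca_penalty`, `total`) for auditability. The penalty makes a
memorising model score strictly worse than an equally accurate regularised
one, which is its purpose.

*Search.* `tune_models()` minimises the custom score with a tree-structured
Parzen estimator (`tpe_minimize()`): uniform warm-up trials, then per
dimension a good/bad split at the 25% score quantile and candidates scored by
the Parzen density ratio. The sampler handles uniform, log-uniform, integer
and categorical dimensions and is fully deterministic under a seed. The
model zoo is a representative subset of three families — the multi-layer
perceptron (the family the final model belongs to), ridge regression and a
random forest — rather than a full zoo of dozens of regressor types; the
machinery is family-agnostic. Desk scale is 100 trials; a full-scale search
would run thousands with identical machinery.

*The network.* `train_network()` implements the multi-layer perceptron with
arbitrary hidden layers, ReLU activation and an L-BFGS solver (analytic
backpropagation gradients, Glorot initialisation, biases unpenalised,
objective $\tfrac12 \mathrm{MSE} + \tfrac{\alpha}{2n}\sum\lVert W\rVert^2$).
The default `network_spec()` is the tuned COX-inhibitor architecture shipped
with the package: hidden layers (64, 17, 45, 54, 18, 14, 45, 61),
$\alpha = 0.045$ (an alternative L2 value of 0.024 circulates for this
model; both are accepted configuration, with 0.045 — the tuned
hyperparameter — as the default). `max_iter` defaults to a desk-scale 10000;
much larger caps (~9 x 10^5) are accepted for full-scale training. Features
are z-score standardised on the training split only — standard practice for
L-BFGS-trained networks. Gradients are verified against finite differences
in the tests.

*Ensembling.* `build_ensemble()` minimises validation RMSD over the weight
simplex (softmax reparameterisation, BFGS, multi-start from the best member
and from equal weights), removes members contributing less than 1%,
renormalises and re-optimises. Members with identical validation predictions
are degenerate, and their weight is shared equally — the documented
tie-break. When one model dominates, the procedure naturally collapses to
single-model selection, which is also how predictions for new compounds
should be read: the ensemble *is* the best individual model whenever pruning
leaves one member. Predictions for analogs require fusion data; compounds
without it are skipped with a warning rather than silently imputed, because
the SLE descriptor cannot be formed.

# Experimental data reduction

`fit_calibration()` fits absorbance vs concentration by OLS and reports
LOD $= 3.3\,s/\mathrm{slope}$ and LOQ $= 10\,s/\mathrm{slope}$ with $s$ the
residual standard deviation. The 3.3/10 convention (ICH) is adopted: it is
the standard for UV assays, and the LOQ/LOD ratios quoted for ibuprofen and
ketoprofen calibrations (0.00698/0.00233 and 0.00156/0.00052 mg/mL, both
3.00 at the printed precision) are consistent with $10/3.3 \approx 3.03$.
`absorbance_to_mole_fraction()` converts a reading to a saturation mole
fraction using the measured density: the curve gives the saturated
concentration $C$ (mg/mL), 1 mL of solution weighs $1000\rho$ mg, the
solvent mass $1000\rho - C$ is apportioned among components by solute-free
mole fractions, and moles follow from the registered molar masses (computed
from molecular formulas, not tabulated). Replicates (conventionally three per
system) are aggregated as mean and sample SD.
`cosolvency_analysis()` reports the optimal DES-water composition as the
argmax *on the measured grid* (no interpolation, matching how optimal
compositions like $x^*_\mathrm{DES} = 0.9$ or 0.8 are quoted) and classifies
a curve as "apparent cosolvency" only when the maximum strictly exceeds the
neat-DES value, ties breaking toward the neat DES.

# The synthetic-data generator

Measured DES solubility datasets of this kind are typically available only
on request, so `desolv` ships a generator that emulates their structure and
makes every stage testable offline:

- **Sigma-profiles** (`gen_sigma_profiles()`): Gaussian-mixture area
  distributions with archetypes for apolar drug-like solutes (&ge;80% of
  area within $|\sigma| \le 0.005$, reflecting the mostly apolar character
  of these drugs), HBA salts (strong positive-sigma anion surface), polyol
  donors (donor hydrogens at negative sigma), moderately polar conventional
  solvents, and water; total areas fall in a realistic 100-400
  &Aring;&sup2; range.
- **Fusion data** (`gen_fusion()`): melting points 330-430 K, fusion
  enthalpies 18-32 kJ/mol, the range typical of small-molecule APIs.
- **Solubility surface** (`gen_solubility_dataset()`): $\log_{10} x =
  \log_{10} x_\mathrm{id} + \sum_i \beta_i z_i + q(z_1^2 - 1) +
  \varepsilon$, where $z_i$ are standardised relative potentials at planted
  grid indices (defaults $\sigma = -0.015, 0, +0.015$ with effects 0.7, 0.5,
  0.4 dex/SD and a mild quadratic 0.15), and $\varepsilon$ is Gaussian with
  SD 0.1 dex — typical inter-laboratory solubility scatter. With all effects
  zero the surface reduces exactly to ideal solubility. 600 records over
  DES-water sweeps and conventional solvents at three temperatures are the
  desk-scale study conditions.
- **Selection fixture** (`gen_selection_fixture()`): relative potentials
  that are i.i.d. noise at non-planted points and share a latent component
  with the response at planted points (marginal $R^2 \approx 0.8$). Exact
  index recovery is only a well-posed property in this independent-noise
  setting: profile-derived potentials are smooth in sigma, so signal
  planted at one point legitimately bleeds into its neighbours there.
- **Calibration series and cosolvency curves** mirror the wet-lab
  structure (11 levels over 0.0126-0.0504 mg/mL; unimodal composition
  curves with a controlled peak).

What the generator does *not* emulate: real sigma-profiles from quantum
chemistry, correlated measurement error across temperatures, solvate or
polymorph effects, and the literature-curation quirks of a heterogeneous
dataset. Passing tests therefore demonstrate that the pipeline recovers a
known signal of realistic shape and size under realistic noise — not that it
reproduces any particular laboratory's numbers.

Because the synthetic truth is anchored on ideal solubility, the pipeline's
desk-scale configuration computes the SLE descriptor with the ideal activity
model (`pipeline_config(activity_model = "ideal")`), keeping the descriptor
set consistent with the generator; the COSMO-RS activity model is the
default for real-data featurisation (`build_feature_table()`).

# Problem sizes and budgets

The shipped defaults are desk-scale: 600 synthetic records, 100 tuning
trials, 3-fold cross-validation, two-point learning curves during tuning, a
20-point final curve, and MLP iteration caps of 150 (tuning) / 2000 (final
refit). These sizes were chosen so a full end-to-end fit completes in about
two minutes on a single CPU while leaving every algorithmic component
identical to the full-scale protocol; all of them are plain configuration.

# Known limitations

- The sigma-potential engine is a simplified parameterisation; absolute
  activity coefficients (and hence absolute computed solubilities) carry the
  model's bias. The pipeline uses them as *descriptors*, which tolerates
  systematic bias by design.
- Melting data are required for every solute; that is inherent to the SLE
  descriptor and mirrored by the explicit skip-with-warning behaviour in
  prediction.
- The TPE implementation is a compact re-creation of the published sampler
  idea, not a bit-for-bit port of any optimisation library.
- Subset labels (DES vs non-DES) are taken from the input records; binary
  conventional-solvent mixtures count as non-DES.
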