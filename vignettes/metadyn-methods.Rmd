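---
title: "Dynamic metabolome drug profiling with metadyn: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic metabolome drug profiling with metadyn: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metadyn)
```

# Scope

`metadyn` analyses untargeted flow-injection time-of-flight mass spectrometry
(FIA-TOFMS) profiles of adherent mammalian cell lines sampled over a drug
time course. It covers five computational stages — accurate-mass ion
annotation, normalization-free estimation of per-cell metabolite abundances,
dynamic fold-change statistics, drug-fingerprint extraction with metabolite-set
enrichment, and growth/GI50 estimation — plus a minimal kinetic model of CoA
homeostasis that rationalizes dichloroacetate (DCA) toxicity, and a synthetic
data generator that provides ground truth for every stage. Raw spectral
processing (alignment, centroiding), image segmentation for confluence, and
absolute quantification are out of scope: centroided ion m/z values, cell
numbers and confluences are inputs.

# Ion annotation

Negative-mode electrospray of flow-injected extracts is modelled as
deprotonation only: each candidate metabolite contributes one expected ion at
its neutral monoisotopic mass minus the proton mass (1.007276467 Da, i.e. the
H atom minus the electron; using the H-atom mass instead would shift every
expected m/z by ~0.5 mDa, a fifth of the matching tolerance). Monoisotopic
masses are sums of bundled NIST most-abundant-isotope masses
(`element_masses`, 17 elements). Because the extraction solvent contains
phenylhydrazine, α-keto acids are additionally represented by their
phenylhydrazone (+C6H8N2 −H2O, a constant shift of 90.0581836 Da); the keto
flag is a per-metabolite input rather than a hard-coded compound list.
Measured ions are matched within an inclusive absolute tolerance (default
0.003 amu) by binary search; each ion reports the best match (smallest
absolute mass error, ties broken by lexicographic metabolite id for
deterministic output) and all matches in tolerance. Without chromatography,
isobaric metabolites are genuinely indistinguishable — `all_matches` preserves
the ambiguity while downstream stages use the single best match.

```{r}
deprotonated_mz(monoisotopic_mass("C3H9NO3S"))  # lock-mass compound, HOT
```

# The steady-state intensity model

In unperturbed exponentially growing cells, intracellular concentrations are
constant, so the measured intensity of ion $i$ in cell line $j$ scales with
the extracted cell number $N_c$:

$$ I_{j,i} = \alpha_{j,i} \cdot N_c + \beta_i $$

with $\alpha_{j,i}$ the per-cell abundance (up to an unknown
instrument-response factor, hence "relative" abundance) and $\beta_i$ a
background offset shared across cell lines, because the MS background does
not depend on the cell type. All lines are fitted jointly per ion by ordinary
least squares on a design with one $N_c$ column per line plus a common
intercept. Each coefficient gets a p-value from the F statistic for the
hypothesis that it is zero (identical to the squared t statistic for a single
coefficient). An (ion, line) pair is *reliable* when $\hat\alpha > 0$ and
$p \le 0.001$; ions reliable in no line are flagged as background or
below-detection and excluded downstream. The coefficient of variation of a
reliable estimate is reported as $\mathrm{SE}(\hat\alpha)/\hat\alpha$ — the
regression-based reading of estimate precision; a replicate-based CV would
also be computable but is not what the fit summarizes.

Choices that matter:

* **Confluence window.** Cell numbers derived from bright-field images are
  unreliable above ~80% confluence and cells start deviating from metabolic
  steady state, so samples above `max_confluence = 0.80` (inclusive boundary
  kept) are excluded from baseline fitting only — treated samples are never
  filtered, since the model is applied to them, not fitted on them.
* **No weighting.** Plain least squares on the linear intensity scale, no
  heteroscedasticity correction or imputation; missing intensities are
  dropped per ion. Multiplicative MS noise therefore inflates
  $\hat\alpha,\hat\beta$ by a factor $\sqrt{1+\mathrm{CV}^2}$ (~1.1% at CV
  15%), which cancels in fold-change ratios up to ~0.016 log2 units.
* **Degenerate designs.** A rank-deficient design (e.g. constant $N_c$
  everywhere) yields NA for non-estimable coefficients rather than a failure;
  all-missing ions are skipped.

Per-sample abundances $(I-\hat\beta)/N_c$ feed a classical one-way ANOVA
across cell lines with Benjamini–Hochberg correction across ions, flagging
metabolites whose baseline levels differ between lines.

# Dynamic fold-changes

After drug exposure the measured intensity is compared with the intensity the
*unperturbed* model predicts at the observed cell number:

$$ \mathrm{FC}_{t,i}^{D,j} = \log_2 \frac{I_{t,i}^{D,j}}
   {\hat\alpha_{j,i} N_{j,t} + \hat\beta_i} $$

computed per replicate, averaged on the log2 scale, and tested with a
two-sided one-sample t-test of the replicate values against zero (the
`two-sample` mode instead Welch-tests treated against time-matched untreated
wells when those are measured). Replicates with non-positive intensity or
baseline are dropped rather than pseudo-counted — the fitted $\beta$ already
absorbs the detector floor. All-zero replicate sets return $p = 1$ by the
zero-statistic convention.

**Documented limitation.** The uncertainty of $\hat\alpha, \hat\beta$ is not
propagated into the t-test. Under the generator's default world
(CV 15%, 3 replicates) the pure measurement floor of the mean log2
fold-change is 0.124 log2 units; baseline estimation error adds ~0.09 in
quadrature, and makes the nominal 5% test mildly anti-conservative (~8–9%
observed type-I at $p<0.05$). The test-suite calibration criteria therefore
fit the baseline on noiseless steady-state data, isolating the estimator
being calibrated; with real data the p-values should be read as ranking
scores near the detection limit.

# Drug fingerprints and enrichment

Per ion and cell line, the time point with maximal $|\mathrm{FC}|$ is located
and its *signed* value kept (the text definition "maximum absolute fold
change" is implemented signed because the volcano display plots signed
medians; an absolute mode is a flag). Ions are summarized across lines by

* `median_max_fc` — median of the per-line signed maxima,
* `combined_p` — the product of per-line minimal p-values. This product is
  **not** a calibrated p-value (minima of dependent tests, multiplied); it is
  used exactly as intended: a ranking/selection score,
* `sd_max_fc` — sample standard deviation (n−1) of the per-line maxima.

The *conserved* fingerprint keeps ions with $|\mathrm{median}| \ge 1$ log2
and combined score $\le 10^{-10}$ (both inclusive, following the written
methods over the figure legend's strict inequality); the *variable*
fingerprint keeps ions with $\mathrm{SD} \ge 1.5$. Selected ions are mapped
to metabolites via their best-match annotation (ambiguous isobars count
once) and tested against pathway sets with the upper-tail hypergeometric
test; the universe defaults to all reliable annotated ions and is
configurable, since the published analysis does not state it. Correction is
Benjamini–Hochberg by default; Storey q-values (π₀ by λ-grid spline
smoothing) are available and fall back to BH with a warning below 100 tests,
where π₀ is not estimable.

# Growth rates and GI50

Growth rates are log-linear regression slopes of confluence on time
(replicates pooled, points above 80% confluence or at zero excluded) — an
exponential fit with stable estimation. Inhibition at dose $d$ is
$1 - r(d)/r(0)$; values outside $[0,1]$ (death, stimulation) are retained.
The dose–inhibition curve is fitted on the log10-dose scale with the
two-parameter Hill form

$$ \mathrm{inh}(d) = \frac{1}{1 + (\mathrm{GI}_{50}/d)^h} $$

whose asymptotes are pinned to 0 and 1 (the published curve form is unstated;
a four-parameter logistic is available behind `four_param = TRUE`). Dose 0
only defines the untreated rate. Fits flag extrapolation (0.5 outside the
observed inhibition range), low confidence (observed inhibitions not spanning
[0.2, 0.8]) and flat no-inhibition data (where the sigmoid location is
unidentifiable and GI50 is NA rather than an arbitrary number). `nls` with a
`scaleOffset` (so exact fits converge) is tried first, then a Nelder–Mead
least-squares fallback.

# The CoA homeostasis model

Two Michaelis–Menten-type reactions couple CoA biosynthesis and biomass
production:

$$ v_{\mathrm{CoA}} = \frac{v_{\mathrm{CoA,max}}}{\max(\mathrm{HoPan}, 1)}
   \left( \frac{[\mathrm{DCA}]}{[\mathrm{DCA}] + K_{\mathrm{DCA}}} + 1 \right), \qquad
   v_{\mathrm{biomass}} = v_{\mathrm{biomass,max}}
   \frac{[\mathrm{CoA}]}{[\mathrm{CoA}] + K_{\mathrm{CoA}}
   \left(1 + [\mathrm{CoA}]^3 / K_i\right)} $$

DCA saturably activates biosynthesis (factor in (1, 2)); hopantenate (HoPan)
divides the maximal biosynthesis flux, applied only for concentrations above
1 because dividing by a sub-unit concentration would spuriously *activate*
the inhibited reaction (HoPan = 0 means untreated). The cubic term encodes
ultrasensitive growth inhibition by high CoA: $v_{\mathrm{biomass}}$ rises to
an interior maximum at $[\mathrm{CoA}]^* = (K_i/2)^{1/3}$ and collapses as
CoA accumulates. Defaults are the published simulation set
($v_{\mathrm{biomass,max}}=1$, $K_{\mathrm{CoA}}=0.01$, $K_i=1$ in
concentration³ units as the rate law implies, $v_{\mathrm{CoA,max}}=0.45$,
$[\mathrm{CoA}]_0=10$, treated $[\mathrm{DCA}]=0.01$, $[\mathrm{HoPan}]=5$).
$K_{\mathrm{DCA}}$ is not part of that set; the default 0.01 (equal to the
DCA dose, activation factor 1.5) is a config knob.

The state equations are a declared reconstruction (the published model
structure is not printed): $d[\mathrm{CoA}]/dt = v_{\mathrm{CoA}} - c \cdot
v_{\mathrm{biomass}}$ with stoichiometric coupling $c = 1$ (CoA is directly
consumed to form biomass), and $dB/dt = v_{\mathrm{biomass}} B$ for a
confluence-like readout. Exogenous CoA is modelled purely as a higher initial
condition. Integration uses a Dormand–Prince 5(4) adaptive scheme (rtol 1e-8,
atol 1e-10, CoA clamped at 0) validated against a fixed-step RK4 oracle;
`t_end = 250` lets the untreated system settle within 1e-4 of its fixed point
and the DCA runaway exceed ten times the initial CoA pool.

This reconstruction reproduces all qualitative behaviours: untreated cells
relax to a balanced fixed point ($v_{\mathrm{biomass}} \to 0.45$); DCA tips
the balance so CoA accumulates without bound and growth collapses (*runaway*);
HoPan drains CoA through the $v_{\mathrm{biomass}}$ maximum — a transient
growth benefit — before biosynthesis becomes limiting (*biphasic*); HoPan
added to DCA restores early-time growth above the DCA-alone trajectory.
"Early time" means $t \le 10$ model-time units here: beyond $t \approx 22$
the HoPan arm has drained its CoA pool and its growth rate falls below the
still-declining DCA arm, so the comparison is meaningful only in the first
phase. The regime classifier uses 20% relative margins (biphasic requires a
transient at least 20% above and an endpoint at least 20% below the initial
rate) because *every* trajectory that drains from $[\mathrm{CoA}]_0 = 10$
passes the interior maximum — with exact inequalities the untreated system
would be labelled biphasic too, which contradicts its behaviour (a monotone
relaxation to a stable balance).

# The synthetic world

The generator emulates exactly the structure the pipeline assumes:
$I = (\alpha_{\mathrm{line}} N + \beta)\, 2^{\mathrm{fc_{true}}}\,
e^{\varepsilon}$ with lognormal noise ($\sigma^2 = \log(1+\mathrm{CV}^2)$,
multiplicative because MS intensity error scales with signal), per-line
exponential cell growth, and Hill-type dose-dependent growth inhibition for
confluence curves. Defaults mirror the study design: 5 cell lines, 3
replicates, sampling at 0/24/48/72/96 h, CV 15%, 9-dose grids. Per-cell
abundances are drawn as a per-ion base level (log-uniform over [0.5, 50]
intensity/cell) modulated per line by a log-uniform factor in [0.5, 2]:
metabolite levels differ between cell lines by a few fold, not by orders of
magnitude — drawing lines independently would let one line dominate the
pooled residual of the unweighted fit and mask the others' coefficients, a
failure mode real data does not show at this scale. Seeding densities
(1.5–4×10⁴ cells), growth rates (0.015–0.03 h⁻¹) and a 10⁶-cell carrying
capacity keep baseline confluence below 0.8, so the stated world and the fit
window coincide.

What a green test does **not** establish: the generator has no batch or
drift structure, no missing-value mechanism, no isobaric collisions, no
in-source fragments, and its noise is exactly lognormal — real FIA data
violate all of these to some degree. Recovery results are statements about
the estimators under the assumed model, not about instrument performance.

# Numerical choices

* Inclusive thresholds everywhere a boundary is stated (tolerance ≤ 0.003,
  confluence ≤ 0.80 kept, p ≤ 0.001, |FC| ≥ 1, combined ≤ 1e-10, SD ≥ 1.5).
* OLS via pivoted QR; batched one-design solve when the intensity matrix is
  complete, per-ion fits otherwise; both paths verified equal.
* Annotation ties at identical |mass error| resolved by metabolite id.
* t-tests with zero variance: p = 1 when the mean is 0, p = 0 otherwise.
* GI50 start values from linear interpolation of the 50% crossing on
  log10-dose.
* All generators accept a seed and restore the RNG state afterwards; fixed
  inputs give byte-identical pipeline outputs.

# Known limitations

Baseline uncertainty is not propagated into fold-change tests (above);
`combined_p` is a score, not a p-value; α contains an unknown scaling factor,
so abundances are relative and cross-metabolite comparisons are invalid;
pool changes are not fluxes; the kinetic model is qualitative — its units are
arbitrary and its coupling is a reconstruction, so only regime-level
statements are supported.
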