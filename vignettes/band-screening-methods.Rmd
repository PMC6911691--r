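---
title: "Band screening and inversion modelling of wastewater spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Band screening and inversion modelling of wastewater spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specwq)
```

## The problem

Wastewater carries dissolved and suspended constituents — oxidizable
organic matter (measured as COD and BOD), ammonia nitrogen, dissolved
solids, hardness ions, alkalinity — that modulate its visible–near-infrared
reflectance weakly and over broad, overlapping spectral regions. A
laboratory spectrum has ~2,000 usable 1-nm bands but a campaign rarely has
more than ~100 samples, so full-band regression sits deep in the
small-n-large-p regime: adjacent bands are nearly collinear, most bands are
redundant, and adding dimensions degrades a model fitted on limited samples
(the Hughes phenomenon). `specwq` implements an explicit, inspectable
band-screening stage between pretreatment and modelling, and two inversion
regressors to use on the screened bands.

## Pretreatment

Three steps, in this order:

1. **Margin trimming** removes the noisy grid edges; the defaults keep
   400–2,400 nm, turning a 350–2,500 nm instrument grid into 2,001 bands.
2. **Savitzky–Golay smoothing** (polynomial order 2, window 5) replaces
   each value by a local least-squares quadratic fit; the interior kernel
   is (−3, 12, 17, 12, −3)/35. Edges are mirror-padded so the grid is not
   shortened. A consequence worth knowing: mirror padding preserves
   constants everywhere but reproduces higher-degree polynomials exactly
   only at interior bands — the mirrored continuation of a quadratic is not
   that quadratic. We preferred an unshortened grid over exact polynomial
   pass-through at the two outermost bands per side.
3. **SNV** standardises each spectrum to mean 0, sd 1 (sample sd, `ddof`
   configurable), cancelling per-sample multiplicative scatter exactly and
   baseline offsets additively.

Trimming precedes smoothing so the filter never sees the discarded noisy
margins; smoothing precedes SNV because SNV rescales whatever noise is
left.

## Gray correlation degree

For a parameter's concentration sequence $x_0(t)$ over samples and band
$i$'s reflectance sequence $x_i(t)$, both are first made dimensionless by
the averaging operator $x \mapsto x/\bar{x}$. With
$\Delta_i(t) = |x_0(t) - x_i(t)|$, the relational coefficient and degree
are

$$\xi_i(t) = \frac{\Delta_{\min} + \rho\,\Delta_{\max}}
                 {\Delta_i(t) + \rho\,\Delta_{\max}},
\qquad \gamma_i = \frac{1}{m}\sum_t \xi_i(t),$$

with discrimination coefficient $\rho = 0.5$ (the conventional value,
exposed in `gc_config()`). Bands with $\gamma > 0.5$ are retained.

**The extrema scope is a genuine design fork.** Taking
$\Delta_{\min}/\Delta_{\max}$ globally over all bands and samples
(classical Deng analysis, the default) makes $\gamma$ comparable across
bands, and its argmax reliably identifies the band whose normalised
sequence best matches the concentrations. But SNV data has an intrinsic
pathology here: the mean SNV spectrum has zero mean across bands, so some
band's across-sample mean passes through zero, the averaging operator
explodes there, $\Delta_{\max}$ inflates, and all other $\gamma$ compress
towards 1 — on synthetic data the $\gamma > 0.5$ rule then retains nearly
every band. The per-band scope (`extrema_scope = "per-band"`) bounds
$\gamma$ in $(\rho/(1+\rho), 1] = (1/3, 1]$ and yields the score
distributions typically reported for this method on SNV spectra, but it is
scale-invariant in $\Delta$, so its argmax reflects the *shape* of the
mismatch distribution rather than its size and tends to sit at a
structure-driven band shared by all parameters. We default to the global
scope because ranking fidelity is what the downstream selection uses, and
document that the GC *mask* is only discriminating when the score
distribution is well spread.

GC localisation also has a physical limit: an analyte whose relative
concentration span is small (TDS at 317–351 mg/L and TH at
1.09–1.17 mmol/L in the emulated campaign, ±5% and ±3%) moves the
spectrum by less than the structural variation between samples, and no
rescaling can recover its feature position. The package's property tests
therefore assert centre localisation for the strongly varying analytes
(COD, BOD, NH₃-N, TA) only.

## VIP

From a NIPALS PLSR with unit-norm weight vectors $W_h$ and per-component
explained response variance $Rd(Y; t_h)$,

$$\mathrm{VIP}_j = \sqrt{\frac{p \sum_{h=1}^m Rd(Y;t_h)\, W_{hj}^2}
                             {\sum_{h=1}^m Rd(Y;t_h)}}.$$

Because each $W_h$ has unit norm, $\sum_j \mathrm{VIP}_j^2 = p$: the mean
squared score is 1, a variable of average explanatory power scores exactly
1, and the conventional VIP > 1 retention rule follows. The component
count $m$ defaults to the minimiser of 10-fold cross-validated RMSE
(folds assigned deterministically by cycling sample indices, so screening
is reproducible without a seed).

## Set-pair fusion

The GC and VIP selections are fused as the two sets of a set pair. With
$n$ bands, identity/discrepancy/opposite counts $s, f, p$ give degrees
$S + F + P = 1$ and the connection number

$$\mu = S + F \cdot I + P \cdot J, \qquad I = \frac{S - P}{S + P},
\qquad J = -1,$$

then relative memberships $v_i = 1/N + \mu_i/N$ and weights
$W_i = v_i / \sum v$. How $s, f, p$ are counted for two continuous score
sets is not canonical; the package's convention is asymmetric, from each
method's viewpoint against the other: identity = bands both select,
opposite = bands the other selects but this method rejects, discrepancy =
the rest. A method that contradicts its partner on many bands is thereby
down-weighted. The fused score is $W_{gc}\gamma_i + W_{vip}\mathrm{VIP}_i$
with selection threshold $W_{gc}\cdot 0.5 + W_{vip}\cdot 1$ — a
weight-blend of the two methods' own thresholds, so either degenerate
weight vector collapses the fusion onto the corresponding single method
exactly. The fused score is monotone in each input score at fixed weights.

## Kennard–Stone split

Calibration samples are chosen by deterministic max–min selection on
Euclidean distances over the full-band SNV spectra: seed with the most
distant pair, then repeatedly add the sample maximising its minimum
distance to the selected set; ties break to the lowest original row index.
The calibration share is 2/3 with half-up rounding (87 samples → 58/29).
The split runs once per dataset, not per parameter, and screening by
default uses all samples (matching how published score tables are
computed); `screen_on = "calibration"` avoids validation leakage at the
cost of comparability.

## Inversion models

**PLSR (NIPALS).** Chosen over SIMPLS because VIP needs the unit-norm
weights $W$ directly. Components deflate $X$; $Rd(Y;t_h)$ is stored per
component. With the maximal component count the fit reproduces multiple
linear regression; with one band it is ordinary least squares — both serve
as independent cross-checks in the tests. Predicting the mean calibration
spectrum returns the mean calibration response (centring algebra).

**ELM.** A single hidden layer of logistic-sigmoid neurons with weights
and biases drawn uniformly on $[-1, 1]$ from a mandatory, recorded seed;
output weights are the minimum-norm least-squares solution via SVD
pseudoinverse (exact interpolation once the hidden size reaches the sample
count). Two numerical choices matter at spectral dimensionality:
inputs are standardised to zero mean/unit variance, and pre-activations
are scaled by $1/\sqrt{p}$ — without that fan-in normalisation the sum of
~2,000 standardised inputs saturates every sigmoid and the network cannot
learn. Neurons are drawn sequentially, so nested hidden sizes under one
seed share their leading neurons and training error is non-increasing in
the hidden size. The default hidden size is chosen by 5-fold
cross-validated RMSE over {5, 10, 20, 40, 80}.

## Evaluation

$R^2$ is the squared Pearson correlation of observed and predicted values
(the convention of chemometric calibration reporting; the $1 -
\mathrm{SSE}/\mathrm{SST}$ definition is available via `method = "ss"` and
differs whenever predictions are biased). RPD divides the validation
standard deviation (sample sd by default; `ddof` configurable) by RMSEP
and is banded poor ≤ 1.5 < satisfactory ≤ 2 < good ≤ 2.5 < very good ≤ 3 <
excellent. Robustness is $R^2_p / R^2_c$; this ratio definition reproduces
the "robust" columns of published PLSR/ELM comparison tables for this
workflow to ±0.002 in 45 of 48 cells, ±0.004 in one (consistent with a
ratio computed before rounding), with two cells inconsistent with their
own printed $R^2$ values — the regression test records all three
exceptions explicitly.

## The synthetic generator

`generate_spectra()` emulates a dilution-design sewage campaign: 87
samples on a 400–2,400 nm 1-nm grid; reflectance = gentle polynomial
baseline − Σ (concentration × Gaussian absorption feature), then
per-sample multiplicative scatter (U(0.95, 1.05)) and additive Gaussian
noise (sd 0.002, about 1% of the absorption signal range). The six default
analytes follow the emulated campaign's concentration spans (COD 20–425,
BOD 3.1–86, NH₃-N 0–34.85, TDS 317–351, TA 101–252 mg/L; TH
1.09–1.17 mmol/L) with features near 460, 760, 820, 990, 1200 and
1650 nm; the primary analyte's concentrations are snapped to a 5 mg/L
dilution grid. Concentrations are drawn independently per analyte — a real
dilution series co-varies all constituents, so the generator is *easier*
for band attribution than real sewage; passing screening tests here shows
the machinery localises planted structure, not that it untangles fully
collinear chemistry. The baseline is kept gentle (range ≈ 0.016) so
static baseline offsets do not drown the concentration signal after SNV.

Two more honest caveats. First, with zero noise and no scatter the raw
spectra are exactly linear in concentrations and PLSR with one component
per analyte recovers them exactly (validation $R^2 = 1$ to $10^{-6}$); the
SNV step divides by a per-sample sd and is mildly nonlinear, so the same
experiment *after* full preprocessing gives $R^2 \approx 0.985$, not 1 —
exactness is therefore asserted on the linear signal. Second, the
generator does not model water's real absorption bands, temperature
effects, or instrument artefacts; it is a correctness instrument, not a
radiative-transfer simulation.

## Problem sizes and determinism

The shipped tests run the full default scene (87 × 2,001 bands) for the
acceptance-style checks and a reduced scene (60 × 351 bands, three
analytes) for unit tests; the complete suite finishes in well under a
minute. All randomness flows through explicit seeds: the generator and the
ELM restore the caller's RNG state, cross-validation folds are
deterministic, and pipeline reruns with the same configuration are
byte-identical. Degenerate inputs fail loudly and early: constant spectra
in SNV (named per sample), constant bands in Pearson screening (flagged,
r set to 0), zero-mean sequences in the averaging operator, empty band
selections, and hyperparameters exceeding what the sample count supports.
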