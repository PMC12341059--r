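---
title: "Models and methods behind bksingle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bksingle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bksingle)
```

This vignette is the package's own account of its models, numerical
choices and limitations. It states no empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## The gating model

Channel gating is a continuous-time Markov chain over a small set of
kinetic states, each labelled closed or open. Transition rates depend on
membrane potential as

$$k(V) = k_0 \, e^{V / V_e},$$

with $k_0$ the rate at 0 mV (s⁻¹) and $V_e$ the signed e-fold voltage
(mV); $V_e = \infty$ gives a voltage-independent rate. All voltages in the
package are membrane potentials — any pipette-potential sign convention is
the caller's responsibility and is never applied internally.

The default topology is the linear three-state chain
$C_2 \rightleftharpoons C_1 \rightleftharpoons O$. It is the minimal
scheme whose aggregate closed-time distribution has exactly two
exponential components and whose open-time distribution has one, matching
the structure the dwell-fitting stage assumes (single-component open fits,
two-component closed fits). Voltage dependence sits on the
$C_1 \rightarrow O$ and $O \rightarrow C_1$ rates.

The preset parameters were fixed once, from these constraints:

* **wt** — stationary open probability below 0.01 at +60 mV and above 0.1
  at +140 mV, so that activation begins above about +80 mV, the behaviour
  of BK channels in fibroblast cell-attached patches at endogenous
  (~100 nM) cytosolic Ca²⁺. The fast closed component at +120 mV is
  ≈ 0.05 ms, in the range reported for such recordings.
* **n999s** — a gain-of-function regime produced by faster
  closed→open transitions (both $C_2 \rightarrow C_1$ occupancy and the
  $C_1 \rightarrow O$ rate are raised), shortening closed sojourns and
  left-shifting activation at unchanged conductance.
* **e656a** — a gain-of-function regime produced by slowing
  $O \rightarrow C_1$, lengthening open sojourns; in study-like pipelines
  this preset is paired with a reduced channel count per patch.
* **two_state** — a voltage-independent $C \rightleftharpoons O$ scheme
  with 10 ms mean sojourns and Po = 0.5 at every voltage. It exists for
  conductance assays: measuring the unitary current–voltage relation
  requires resolvable openings at *every* protocol voltage, which a
  voltage-gated scheme cannot supply below its activation range. The
  unitary conductance being recovered is a property of the open pore, not
  of gating, so this substitution does not touch the quantity under test.

Calcium is not an explicit variable: recordings of this kind are made at a
fixed endogenous Ca²⁺, and its effect is folded into the effective rate
constants. Paxilline block is modelled as all channels pinned closed
(`paxilline_block = TRUE`), which is how the pharmacological identity
control manifests in analysed records (NPo = 0 at every voltage).

Two analytic oracles accompany the simulator and anchor the tests:
`mean_dwell()` (mean sojourn = 1/Σ outgoing rates), `stationary_po()`
(stationary distribution of the generator), and `dwell_spectrum()`
(eigenvalues of the closed-class sub-generator give the closed-time
constants). The Gillespie sampler is checked against all three.

## Sweep rendering

The unitary current is ohmic, $i = \gamma (V - V_{rev})/1000$ pA with
$\gamma$ in pS; the default reversal potential is 0 mV (near-symmetric K⁺
on both sides of the patch), and no rectification is modelled. Per-sample
current is (number of open channels) × $i$ plus Gaussian noise of SD
`noise_sd` (default 1 pA), then filtered.

The low-pass filter is a zero-phase Gaussian FIR with
$\sigma = 0.1325/f_c$ — the standard smoothing-filter idealization used in
single-channel analysis. Being symmetric it shifts no dwell boundaries,
and it is consistent with the dead-time bound used downstream,
$T_d = 0.179/f_c$ (≈ 30 µs at the default 6 kHz).

## Idealization

Levels are found from the all-points amplitude histogram: local maxima
subject to a prominence floor (5 % of the tallest peak) and a minimum
separation, with three-point parabolic refinement of the peak positions
(the bin width would otherwise quantise amplitudes). The baseline is the
lowest-amplitude peak along the driving-force direction; the unitary
amplitude is the median spacing of consecutive peaks; levels are assumed
equally spaced. The default bin width is half the trace's robust noise SD
(floor 0.05 pA), and the default peak separation is max(4 bins, 2.5 pA).

Detection thresholds sit at 50 % of the unitary amplitude:
$\theta_k = \text{baseline} + (k - \tfrac12)\,\Delta i$. A sample's level
is the number of thresholds below it; runs become events; events shorter
than the dead time are merged into the longer adjacent event (shortest
first, edge events exempt — they are boundary-truncated, not brief). No
hysteresis is applied, matching plain half-amplitude analysis.

For sweeps below the reversal potential the open-channel current is
inward (negative), so detection and idealization operate on the
driving-force-rectified trace and unitary currents are reported signed.
Sweeps within 10 mV of reversal carry no resolvable amplitude and are
skipped rather than imputed.

## NPo, N, Po, slope conductance

NPo is the level-weighted time fraction $\sum_k k\,t_k/T$ and is checked
in the tests against per-sample brute force (the two are equal by
construction up to quantisation). The channel count N is the maximum
simultaneous open level observed at the top two protocol voltages, where
open probability is maximal; this standard stacking estimate undercounts
when per-channel Po is low, which is why it is evaluated only at the
highest voltages. Po = NPo/N, clipped to [0, 1]. The slope conductance is
an unweighted OLS line through the signed unitary I–V points inside
−40..+100 mV (≥ 3 points required), reported in pS.

## Dwell-time fitting

Dwell histograms use constant-width bins in $\log_{10} t$ (default 10 per
decade). In log time an exponential density with constant $\tau$ becomes

$$g(x) = A \exp\left[(x - \ln\tau) - e^{x - \ln\tau}\right],
\qquad x = \ln t,$$

whose maximum is exactly at $t = \tau$ — the reason the transform is used.
The fitted component is this transformed exponential, not a literal
log-normal: the peak-at-τ property is the defining behaviour of these
histograms, and the transformed exponential is the density that actually
has it. A least-squares fit on the binned counts estimates
$(\ln\tau, A)$; open fits use one component, closed fits two, initialised
at the most prominent histogram maxima (ties toward smaller τ), reported
with $\tau_1 < \tau_2$ and weights $A_i/\sum A_j$. When the second
component collapses (weight < 1 % or $\tau_2 \approx \tau_1$) the result
is flagged effectively single-component, falling back to the one-peak fit
if the two-component optimisation is singular. Fits on fewer than 50
dwells attach a warning.

No missed-event (dead-time) correction is applied to the fitted
constants. The consequence is visible and deliberate: closures shorter
than $T_d$ merge into flanking openings, so apparent open times from
idealized data are burst-like and can sit well above the generating
scheme's mean open sojourn when a fast closed component lies near the dead
time. Recovery tests that target the fitting stage itself therefore
generate dwells directly from the exponential mixture; recovery through
the full idealization chain is validated for quantities (total open time,
slope conductance, NPo) that the dead time does not bias.

## Allele-expression module

The pileup counter consumes per-read base calls (simulated, from a plain
TSV, or via `Rsamtools` for BAM/SAM) and applies per-base quality floors
(default Q20 for base and mapping quality — the position-level analogue of
read-level Q20 truncation used in sequencing QC). `N` calls never count;
depth equals retained calls. Allele imbalance is tested against the
heterozygous expectation 0.5 with the exact two-sided binomial test
restricted to ref+alt calls, and the 95 % interval is Clopper–Pearson
(exact, hence conservative: empirical coverage runs at or above 95 %).
Coordinates are 1-based; strand is ignored. No reference-bias correction
is applied.

## The statistics ladder

Normality is assessed per group with Shapiro–Wilk at α = 0.05; any
rejection — or any group too small to test (n < 3) or degenerate
(constant) — routes the comparison nonparametric. The parametric route is
one-way ANOVA with Bonferroni-adjusted pairwise Welch t tests (Tukey HSD
as an option); the nonparametric route is Kruskal–Wallis with Dunn's
pairwise z comparisons (tie-corrected, Bonferroni-style adjustment, as in
common statistics software). Both post-hoc conventions appear in practice,
which is why the parametric family is selectable. With exactly two groups
the ladder collapses to the Welch t test or the exact Mann–Whitney test.

Activation curves are compared per voltage with two-sided Mann–Whitney
tests and Holm adjustment across voltages (Šidák available); Holm is
uniformly more powerful than Bonferroni under the same assumptions.
Voltages with n < 3 in either group are skipped and recorded. At the
small group sizes typical of per-voltage curve comparisons the exact
Mann–Whitney p-values are discrete, which makes the Holm-adjusted
procedure strictly conservative: its family-wise error under the null
falls below — often far below — the nominal 0.05, as the replicated null
simulation in the acceptance suite demonstrates.

## Problem sizes and determinism

All simulations are seed-deterministic: a recording is a pure function of
(scheme, config), and `run_pipeline()` derives per-patch seeds from its
master seed, so identical runs are byte-identical down to the JSON
summary. The test suite and the acceptance script use 3 s sweeps
(protocol-faithful runs use 15 s), 20 seeds per recovery estimate,
10⁴-dwell samples for dwell-fit recovery, and 500 replicates for the
null family-wise-error check; these sizes put Monte-Carlo error well
inside each check's tolerance.

## Known limitations

* Threshold idealization, not hidden-Markov inference: no missed-event
  correction, no baseline drift handling beyond a constant baseline, no
  sub-conductance states.
* The stacking estimate of N is biased downward at low Po.
* The gating presets are effective models — no explicit Ca²⁺-dependent
  allosteric gating, no β/γ regulatory subunits, no capacitive or seal
  artifacts; passing recovery tests on these synthetic recordings shows
  the analysis chain is correct, not that real fibroblast data are this
  clean.
* ABF/ATF instrument files are not read; recordings enter as
  package-native CSV + JSON bundles or in-memory objects.
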