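---
title: "clocksig: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{clocksig: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`clocksig` implements a complete computational workflow for linking
circadian-clock deregulation to oncogenic RAS/MAPK signalling in cancer
cell lines: rhythm quantification from luciferase reporter recordings,
oscillator phenotyping, discriminative gene-signature discovery,
network-connectivity enrichment, and mechanistic interpretation through
a core-clock ODE model. This vignette documents the models, the
numerical choices, and the places where the design was genuinely open.

## 1. Rhythm quantification

### Detrending and smoothing

Raw luciferase counts decay as luciferin is consumed, so traces are
detrended by dividing each count by a centered 24-hour running average;
24 h is chosen so one full circadian cycle averages out of the
baseline. Where a full centered window is unavailable (the first and
last half-window) the running-mean ratio is biased, so those samples
are trimmed rather than imputed. Smoothing for visualization and peak
finding uses a 4-hour centered running mean with symmetrically
shrinking edge windows, which preserves record length (a fit should
not lose data to cosmetic smoothing).

### Damped cosinor fit

The rhythm model is

$$y(t) = m + A\,e^{-\lambda t}\cos\!\big(2\pi (t-\phi)/\tau\big),$$

with mesor $m$, amplitude $A$ (reported at $t = 0$, on the detrended
unit-mean scale), damping $\lambda \ge 0$, period $\tau$ and phase
$\phi \in [0, \tau)$ given as the time of the first fitted peak after
synchronization. The published analyses name only "the cosine wave
function"; the damping term is our dialect choice (reporter rhythms in
cell culture visibly dampen), and a `fix_lambda` flag recovers the pure
cosinor. For fixed $(\tau, \lambda)$ the model is linear in
$(m, A\cos, A\sin)$, so the fit uses variable projection: a quasi-Newton
search over $(\tau, \lambda)$ with exact linear solves, multistarted
from the period grid $\{20, 22, 24, 26, 28\}$ h. The multistart grid
makes the phase grid of a classical cosinor scan unnecessary — the
linear solve is exact in phase. Residual-sum ties resolve to the
smallest period.

### Oscillator classification

A cell line is a **strong oscillator** when the fitted relative
amplitude is at least 0.20 of the detrended signal, the period falls in
a circadian band, and the fit is credible. The amplitude threshold is
the published criterion; the band ($[18, 32]$ h) and the fit-quality
floor ($r^2 \ge 0.5$) operationalize "a clear circadian period", which
was published without numbers — both are configurable, and we fixed the
amplitude reading at $t = 0$ (the record average is a dialect option
that we considered and rejected as less comparable across damping
levels). Unconverged fits are weak by definition.

### Entrainment phase and qPCR quantification

After temperature entrainment the phase is the time from release to the
first local maximum of the detrended, smoothed trace, refined by
quadratic interpolation through the three samples around the discrete
peak; boundary samples are not eligible. Relative expression uses the
standard $2^{-\Delta\Delta CT}$ scheme against a housekeeping reference
(GAPDH) and a calibrator sample at its earliest timepoint.

## 2. The core-clock model

### Structure

The shipped model is a reduced 9-state three-loop network:

- BMAL1 protein ($B_p$) activates transcription of *Per* ($P_m$),
  *Cry* ($C_m$), *Rev-Erb* ($R$) and *Ror* ($R_a$, both nuclear
  receptors lumped to protein level) through a shared activating Hill
  function $H_{act}(B_p) = B_p^a/(g^a + B_p^a)$;
- PER and CRY proteins associate into the PER:CRY complex ($PC$),
  which both represses BMAL1-driven transcription through a Hill term
  in the repressor:activator ratio and **stoichiometrically
  sequesters** BMAL1 (a mutual-annihilation term $k_{seq} B_p \cdot
  PC$ removes both partners 1:1) — the main negative feedback;
- REV-ERB represses and ROR activates *Bmal1* transcription ($B_m$) —
  the interlocked loops that give the Bmal1-luciferase reporter its
  rhythm;
- mRNA decay is saturable (Michaelis–Menten with shared constant
  $K_m$): above $K_m$ the turnover machinery runs at capacity.

The global dimensionless factor `ktt` scales BMAL1-mediated
transcription of *Per*, *Cry*, *Rev-Erb* and *Ror* (not of *Bmal1*);
`ktt = 0.4` emulates RAS/MAPK activation (ERK phosphorylates BMAL1 and
reduces its transactivation capacity), `ktt = 1.6` emulates RAS/MAPK
inhibition. `kt2` is the *Cry* transcription rate.

Three of these ingredients deserve a design note, because a simpler
two-loop variant (no ROR arm, purely multiplicative Hill repression,
linear decay) **cannot** reproduce the published direction of the
`ktt` response. In extensive searches of that simpler wiring every
deep limit cycle (Bmal1-mRNA relative amplitude above a few percent)
had its period *increasing* with `ktt`, while period-decreasing
parameter sets existed only vanishingly close to the Hopf boundary:
with purely multiplicative repression, reducing transactivation only
starves the repressor arm, which shortens the cycle. The positive ROR
arm makes total loop gain fall with `ktt`, the 1:1 sequestration makes
repression stoichiometric (the time to titrate the BMAL1 pool scales
inversely with repressor production), and saturable decay provides the
relaxation-type nonlinearity long known to carry negative
period–transcription coupling in circadian models. Only with all three
did the calibration search find deep oscillators whose period
lengthens under RAS-like transactivation loss. The authors' full
published model is larger still; its exact parameterization is out of
scope here and can be supplied as an external model file, which is the
only route to the published `ktt` period values (24.1 h / 21.4 h).

### Numerics

Integration uses an embedded Dormand–Prince 5(4) pair implemented in
C++ (no ODE solver package is assumed), relative tolerance $10^{-8}$,
absolute $10^{-10}$, cubic-Hermite dense output at 10 samples/h.
Features are read from the trajectory after discarding a transient:
period as the mean interval between quadratically interpolated maxima
of $B_m$, **magnitude** as the time average over an integer number of
cycles, amplitude as half the post-transient range. "Magnitude" is
never defined in the source analyses; we adopt cycle-mean level because
the experimental comparison is of expression levels, and we report
amplitude alongside so either reading can be checked. A trajectory
counts as non-oscillatory when the reference relative amplitude falls
below $10^{-3}$ or inter-peak intervals vary by more than 5%.

The default analysis horizon is 700 h with a 300 h transient — longer
than the 400/200 h one might first reach for. Near the oscillation
threshold these models relax toward their limit cycle over hundreds of
hours, and with a 200 h transient period estimates carry transient
bias of order 0.1 h; worse, slowly damped ringing can masquerade as
oscillation over short windows. The calibration machinery therefore
measures periods on 1800 h horizons before accepting a parameter set,
the shipped configuration stores a point on its limit cycle as the
default initial state (making the 300 h transient generously
sufficient in routine use), and the default features were verified
stable to < 0.01 h against the long-horizon estimates.

### Calibration

`calibrate_default_model()` searches log-uniform bounds (rates
$[10^{-3}, 10]$ h$^{-1}$, integer Hill exponents $[2, 8]$, thresholds
$[0.05, 5]$) by seeded Latin hypercube, then refines locally by
stochastic hill-climbing on a feasibility score. Because every
rate-dimension parameter scales time jointly, any oscillatory candidate
can be rescaled exactly to a 23.0 h baseline period — the WT period in
the modelling figures — and the search only needs to satisfy the
shape criteria: Bmal1-mRNA relative amplitude at least 0.20, period
strictly decreasing in `ktt` over $\{0.4, 0.7, 1.0, 1.3, 1.6\}$ with at
least 1 h of range (period lengthens under RAS activation, shortens
under inhibition), and a `kt2` perturbation that lengthens the period
while moving *Per* and *Cry* magnitudes in opposite directions (*Cry*
up, *Per* down) — the experimentally observed RAS signature. The
accepted parameter set is frozen as plain-text JSON in
`inst/extdata/core_clock_default.json`, together with a point on its
limit cycle used as the default initial state. The shipped set gives
periods 25.41 / 24.03 / 23.00 / 22.48 / 22.18 h over the `ktt` grid
and a `kt2` x 1.6 hit with a 0.80 h period increase, Cry magnitude
+150% and Per magnitude −55%.

### Sensitivity analysis

Control coefficients are central differences at $\pm 1\%$:
$CC_\tau(p) = (\Delta\tau/\tau)/(\Delta p/p)$, and likewise per-state
magnitude coefficients. The harmonic test system ($\tau = 2\pi/\omega$)
provides an exact oracle, $CC_\tau(\omega) = -1$, and an unused dummy
parameter checks the zero. The perturbation screen multiplies each
parameter by 0.4 and 1.6 (mirroring the $\pm 60\%$ `ktt` scenarios; the
published *Cry*-transcription perturbation size is unstated, so both
directions are screened) and flags entries with a period increase above
0.05 h and antipodal Per/Cry magnitude changes above 1% relative.

## 3. Signature discovery

The moderated t-statistic shrinks gene-wise pooled variances toward a
scaled inverse-chi-square prior fitted by moment matching on
log-variances (closed forms in the function documentation); with no
excess spread in observed variances the prior dominates
($d_0 = \infty$). This is authored in the package — the well-known
`limma` implementation is only an optional cross-check in the test
suite, never the code path.

Leave-one-cell-line-out discovery excludes both timepoint samples of
one line per fold (timepoints behave as biological replicates, a claim
the replicate check re-tests with Benjamini–Hochberg adjustment), ranks
genes by moderated-t p-value, and keeps the top 100. Fold quality is
assessed exactly as published: cluster all labeled samples on the
fold's genes with Pearson distance ($1 - r$) and Ward linkage cut at
two groups, and retain the fold only when the excluded line lands in
the cluster whose majority phenotype matches it. The final signature is
the intersection over retained folds, ordered by best fold p-value.
Open dialect choices we fixed: Ward.D2 (squared-update) linkage with a
flag for the unsquared variant; ties in the ranking broken by $|t|$
then gene name; no multiple-testing correction inside the ranking (raw
p-value order, as published). The probe-set-to-gene collapse that took
100 probe sets to 45 genes is unspecified in the source; we operate at
gene level and provide a max-mean collapse for probe-level input.

Two empirical properties of this procedure are worth knowing. First,
adjacent leave-one-out folds share 10 of 12 samples, so the
highest-ranked *noise* genes recur in every fold and survive the
intersection: at the reference synthetic setting (30 planted genes at
2 SD among 5,000, lists of 100) the final signature carries its ~30
planted genes plus a floor of roughly 8–14 stable false positives —
across every seed we examined. A false-positive count below ~5 is not
reachable at these settings, and the corresponding acceptance check is
deliberately left failing rather than weakened. Second, when the
generator's line-level random effect is switched on, the two samples
of a cell line are correlated and a per-sample two-group test becomes
mildly anticonservative (empirical type-I ~0.08 at a line SD of 0.1);
the type-I calibration of the *statistic* is therefore assessed under
exchangeable samples (line SD 0), and the line effect is treated as
what it is — a design nuisance that the paper's clustering validation,
not the t-test, guards against.

Held-out samples are classified by co-clustering (append, recluster,
take the joined cluster's majority phenotype) with a nearest-centroid
alternative, because the published validation rule for the eight extra
cell lines is not fully described. Classification success is scored by
the exact binomial upper tail; seven of eight at chance 1/2 gives
$9/256 = 0.03516$.

## 4. Network enrichment

Networks are provenance-tagged undirected edge lists; duplicate edges
merge with provenance union ("both" when text-mining and STRING agree).
Shell assembly places a declared core (the 14 core-clock genes), a
declared first shell of known direct interactors, and an outer shell of
remaining genes with at least one edge to the core.

Connectivity enrichment asks whether a query set (the 45 discriminative
genes) is unusually connected to target sets (clock and cancer genes).
Only edges between different sets count. The null preserves literature
visibility: genes are binned by $\lfloor \log_2(\text{citations} + 1)
\rfloor$ — exact citation matching is infeasible for highly cited genes,
so log-width bins stand in for "the same number of PubMed citations" —
and each of $B = 50$ replicates redraws every query gene uniformly from
its bin, without replacement, excluding query and target genes (a flag
re-admits them; excluding avoids trivially inflated nulls). Genes in
both query and target sets count once, on the target side. We report
the empirical permutation p-value $(1 + \#\{count \ge obs\})/(1 + B)$
as the headline statistic, with the $z$-score and a one-sample Wilcoxon
signed-rank p alongside; how a single observed count was originally
paired with 50 null counts in a Wilcoxon test is ambiguous, which is
why the empirical p leads.

## 5. Synthetic data: what it does and does not establish

Every pipeline stage is exercised end-to-end on seeded generators that
reproduce the statistical structure the stage assumes:

- **Traces**: damped cosine on an exponentially decaying baseline with
  multiplicative Gaussian noise (photon counts are large, so Gaussian
  stands in for Poisson; a Poisson mode would be a small extension).
  Strong mode defaults to $A = 0.4$, $\tau = 24$ h, weak mode caps
  $A \le 0.1$ — the two phenotype archetypes.
- **Expression**: 3 strong + 3 weak lines by default (the published
  2 + 4 split ships as the `"paper2014"` preset), two timepoints per
  line sharing a line-level random effect (SD 0.1 by default — small
  against typical gene SDs of ~0.2 but enough to make within-line
  correlation visible), gene variances from the scaled
  inverse-chi-square prior ($d_0 = 4$, $s_0^2 = 0.04$, typical of
  log-scale array data), and planted genes whose phenotype means sit
  at $\pm\delta s_g$ around the grand mean (group difference
  $2\delta s_g$); defaults 30 planted at $\delta = 2$ among 5000.
- **Networks**: citation counts log-normal (meanlog 3, sdlog 1.5,
  spanning unknown to heavily studied genes), edge probability
  proportional to the citation product (ascertainment bias), planted
  query-target enrichment factor $\rho$.

Green tests on these generators establish that the machinery is
correct and calibrated (type-I error, sensitivity at a stated effect
size, null z-scores), not that the biological conclusions replicate:
real arrays carry batch and probe effects, real interaction databases
carry correlated curation noise, and real traces carry instrument
artifacts, none of which are emulated. The published per-cell-line
rhythm parameters and the absolute text-mining interaction counts
depend on unpublished raw data and database snapshots and are
deliberately not test surfaces.

## 6. Known limitations

- The reduced clock model reproduces directions and signatures, not
  the published absolute period shifts (those require the external
  full parameterization).
- Oscillation near the low-`ktt` boundary is close to a Hopf point;
  period estimates there need long horizons, and extremely slow
  relaxation can still bias features at the margin.
- The co-clustering classifier inherits the instability of hierarchical
  clustering under small sample counts (a held-out line's two samples
  can straddle the two-cluster cut, yielding "unclassified"); the
  centroid mode is more robust but less faithful to the published
  procedure.
- The LOOCV intersection carries a structural false-positive floor
  (section 3); treat the tail of the signature, ranked by fold
  p-value, with caution.
- Gene-symbol normalization covers the aliases appearing in the
  packaged gene sets, not a full synonym dictionary.
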