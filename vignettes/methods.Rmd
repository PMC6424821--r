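---
title: "Methods: assembly detection, cell-type classification and cross-region timing in hpcnac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assembly detection, cell-type classification and cross-region timing in hpcnac}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hpcnac` re-implements, as a tested and reusable chain, the ensemble
electrophysiology analyses used to study how hippocampal CA1 pyramidal cells
(PYRs) coordinate nucleus accumbens (NAc) populations during spatial
appetitive behavior: detection and cross-session tracking of co-activation
assemblies, waveform-based classification of striatal units, theta-controlled
cross-region spike-timing analysis, ensemble-to-ensemble spike-count
prediction, and place-preference scoring. Because no public recordings
accompany that experimental design, the package ships a synthetic-session
generator with complete ground truth; every stage is validated by recovery of
known structure rather than by comparison to archived data.

This vignette is the package's methodological account: the models, the
tunable parameters and their defaults, the numerical choices, and the known
limitations — including what passing the synthetic benchmarks does and does
not establish about real recordings.

## Assembly detection

Spike trains of simultaneously recorded PYRs are counted in 25-ms half-open
bins and each neuron's count vector is standardized to zero mean and unit
variance (population SD), so high-rate neurons cannot dominate. Writing the
standardized matrix as $Z$ (neurons $\times$ bins), the neuron correlation
matrix is $C = ZZ^\top/B$. The number of *significant co-activation
patterns* is the number of eigenvalues of $C$ above the Marcenko–Pastur
upper bound for independent unit-variance data,

$$\lambda_{\max} = \left(1 + \sqrt{N/B}\right)^2 ,$$

with $N$ retained neurons and $B$ bins. The bound requires $B > N$;
zero-variance neurons are excluded before standardization and re-inserted as
zero weights when patterns are aligned across sessions.

Patterns themselves are extracted by fastICA run on the data projected into
the top-$n$ principal subspace ($n$ = the significant count), deflation
mode, with a seeded random orthogonal starting rotation and up to three
restarts on non-convergence. Each independent component is back-projected to
neuron space, unit-normalized, and sign-fixed so its largest-magnitude entry
is positive. A pattern's *members* are the neurons whose weight exceeds the
weight mean by more than two weight SDs. This 2-SD rule presumes members are
a minority of the population: with, say, 5 members among 20 neurons the
member weights themselves inflate the SD and the rule returns an empty set.
The recovery benchmarks therefore use populations of 30–50 neurons with 5–6
members per assembly.

Activation strength tracks a pattern in continuous time: each spike train is
convolved with a Gaussian kernel, sampled on a uniform grid, standardized
over the analysis interval, and scored as the quadratic form
$A(t) = z(t)^\top P\, z(t)$, where $P$ is the outer product of the weight
vector with its diagonal set to zero — so a single neuron firing alone
contributes exactly nothing, only co-activation does. *Activations* are
local maxima of $A(t)$ above $R_{\mathrm{THRES}} = 5$, at least one
detection bin (25 ms) apart. Two patterns are compared by the similarity
index $|w_a \cdot w_b|$ (sign-invariant by construction); sets of patterns
from different sessions are matched one-to-one by the Hungarian assignment
maximizing total similarity.

Defaults and why:

* `bin_width = 0.025` s — the detection timescale of interest.
* `kernel_sd = 0.025 / sqrt(12)` (≈ 7.2 ms) — matches the variance of the
  25-ms detection boxcar, so the continuous trace and the binned detector
  see co-activation at the same scale. Configurable.
* strength grid `step = 0.001` s — comfortably below the kernel width;
  evaluating at the raw 20-kHz acquisition rate changes nothing but cost.
* `r_thres = 5` — the detection threshold on the quadratic form.

Two empirical properties of this detector are worth knowing. First,
*oscillatory comodulation counts as structure*: a population phase-locked to
a common theta rhythm with random preferred phases carries a rank-two
(sine/cosine) covariance component, and the eigenvalue count reports exactly
two extra patterns above the embedded assemblies (a test asserts this).
The recovery benchmarks therefore run with theta and place modulation
disabled so that the embedded assemblies are the only co-activation
structure; on modulated data the count is interpretable only as "assemblies
plus oscillatory components". Second, at $R_{\mathrm{THRES}} = 5$ the
quadratic form's heavy (chi-square-like) tail produces roughly 0.5–1
spurious peaks per second on structureless standardized data, essentially
independent of firing rate; recovery of embedded event *rates* is therefore
asserted on peaks matched to ground-truth event times, and the
activation-rate maps should be read as relative, not absolute, rates.

## Synthetic sessions

The generator emulates the statistical structure the analyses assume,
without pretending to be a biophysical simulation:

* **PYRs** are inhomogeneous Poisson, rate-modulated by a von Mises factor
  of theta phase (concentration per class; PYR default $\kappa = 0.8$) and
  optionally by a Gaussian place field (width 10 cm, depth 0.3) over the
  trajectory; the modulation is normalized so each neuron's marginal rate
  equals its configured rate exactly, making Poisson rate checks sharp.
* **Assemblies** are lists of member neurons with an event rate (events/s)
  and a participation probability; at each event every member independently
  emits one extra spike, jittered uniformly within one 25-ms window — the
  least-informative choice consistent with bin-scale co-activation.
* **Monosynaptic coupling** (PYR→FSI, PYR→MSN): after each presynaptic
  spike the target fires with the configured transmission probability at
  the configured latency, plus 0.3 ms Gaussian jitter — producing the
  3–8 ms cross-correlogram peak the timing analyses test for.
* **Feedforward inhibition** (FSI→MSN) is a multiplicative rate dip: each
  FSI spike scales the target MSN rate by $e^{-s}$, recovering with a
  10-ms exponential — sufficient to reproduce a population rate decrease,
  not a conductance model.
* **Light epochs** multiply the targeted neurons' rates by a suppression
  factor (0 silences completely), applied both to the Poisson rate and, by
  thinning, to event- and coupling-driven spikes.
* **Theta phase** is generated analytically (constant nominal frequency,
  default 8 Hz, with a few percent per-cycle length jitter) and exported as
  exact cycle boundaries, so cycle detection can be bypassed or validated
  against truth.
* **Position** is sampled at 25 Hz over two 46-cm square enclosures joined
  by an 8 × 7 cm bridge. Enclosure visits follow a deterministic
  alternating bout schedule sized so the dwell fraction equals the
  configured preference (randomness lives in the within-enclosure reflected
  walk); this makes the preference score a sharp closed-form check rather
  than a bout-level random variable.
* **Waveform banks** are built from parametric biphasic templates (negative
  trough, two positive flanking peaks with small undershoots) whose zero
  crossings are analytically placed, so the three classification features
  are exact by construction before jitter. The class `separation` parameter
  is the per-feature RMS standardized centroid offset of the *closest*
  class pair (so the closest pair sits at `separation * sqrt(3)` jitter SDs
  in the 3-D feature space); FSI templates are narrowest, TAN broadest.

Reproducibility: one master seed per session; every neuron, assembly,
coupling and stage draws from an independent substream keyed on a label, so
adding neurons or assemblies never perturbs existing spike trains.

What the generator does *not* emulate: spike-sorting artifacts and unit
contamination, nonstationary rates and behavioral state changes, bursting
and refractory structure, volume-conducted LFP, or correlated noise between
waveform features. Passing the benchmarks shows the algorithms recover the
structure they target under clean conditions at realistic scale — not that
they are robust to every pathology of real tetrode data.

## Cell-type classification

A unit's mean waveform (40 kHz, trough at $t=0$, highest-amplitude channel)
is parameterized by the duration of its first peak — trough to the *second*
zero intercept on the left, i.e. the far edge of the positive lobe
preceding the trough — the duration of the second peak (same, rightward),
and spike symmetry, the first peak's amplitude over the summed peak
amplitudes. Crossings are located by linear interpolation; all three
features are invariant to amplitude rescaling. Units lacking the required
crossings raise a typed error and are left unclassified.

Features are z-scaled and partitioned by k-means ($k=3$, 25 seeded
restarts). Because clustering returns anonymous clusters, names are
assigned by physiology: the briefest-spike cluster is FSI; of the remaining
two, the lower-firing is MSN and the other TAN. The partition is
cross-checked with DBSCAN and Ward hierarchical clustering, with pairwise
adjusted Rand indices reported. DBSCAN's epsilon comes from the knee of the
4-NN distance curve; `min_pts` is 8 at typical unit counts (suppressing
density bridges between adjacent clusters) and shrinks to 4 below 100
units, and DBSCAN noise points are attached to their nearest clustered
point so the agreement indices compare full partitions. Ward linkage is
used for the hierarchical check because average linkage frequently isolates
a single outlier as a "cluster" at $k=3$, which says nothing about the
class structure.

Opto-tagging uses a 0.2-ms peri-pulse histogram: a unit is tagged when any
bin in (0, 8] ms exceeds the baseline ([-50, 0) ms) mean by more than 3
baseline SDs, with the baseline SD floored at the binomial SD of half a
spike over the pulse count so silent baselines cannot self-tag; the window
and multiplier bracket reported 3.2–8 ms monosynaptic offsets and are
configurable.

## Cross-region spike timing

Cross-correlograms bin target-spike lags around each reference spike
(default ±200 ms, 1-ms bins) and normalize by the reference count, giving a
discharge probability per bin. Population correlograms either average
per-pair probabilities (default) or pool spikes; both are exposed because
published population correlograms rarely say which was used.

The central null model is the *theta-phase-preserving shift surrogate*:
every reference spike is moved to an independently chosen random valid
theta cycle, at the time within that cycle with the same phase (inverse of
the cycle's linear phase map). Surrogates exactly preserve the spike count
and the phase multiset, destroying only sub-cycle timing — so any
correlogram feature surviving them reflects fine-timescale coupling, not
shared rhythm. Per-bin bands are the 0.5%/99.5% surrogate quantiles. For
*detection* over the 3.2–8 ms monosynaptic window, the package uses a
simultaneous (global) band — the 99.5% quantile of the per-surrogate
maximum over the window — because the pointwise band tested at ~5 bins has
a family-wise false-positive rate of 2.5–4%, which would fail the intended
≤ 2% calibration by construction; the global band measures ≤ 1% while
keeping full power against a 4-ms, 0.2-efficacy coupling.

Theta cycles come either from an analytic phase channel (boundaries at
phase-zero crossings, exact) or from a raw LFP trace (3rd-order Butterworth
band-pass, forward-backward, instantaneous phase from the FFT analytic
signal). LFP-derived boundary estimates drop the first and last cycle
(filter and Hilbert edge transients) and are accurate to sample precision;
cycles outside 83–250 ms are flagged and excluded from surrogate and
cycle-binning use.

Light responsiveness is scored per unit as
$(r_{\mathrm{ON}} - r_{\mathrm{OFF}})/(r_{\mathrm{ON}} + r_{\mathrm{OFF}})$,
with the same formula between flanking OFF epochs as a control; a
suppression factor $s$ in the generator predicts the score
$(s-1)/(s+1)$ in closed form. Score distributions are summarized by a
Gaussian kernel density with Silverman bandwidth clipped to [0.02, 0.2] on
the score scale, renormalized over the evaluation grid. Theta modulation
depth is the Rayleigh vector length, which for von Mises phases with
concentration $\kappa$ converges to $I_1(\kappa)/I_0(\kappa)$.

Slice-physiology kinetics: events are deflections exceeding the
pre-stimulus baseline mean by 2 baseline SDs; amplitude is peak minus
baseline, duration is between threshold crossings, rise time is between
the 20% and 80% amplitude crossings (linear interpolation), and the
paired-pulse ratio is the second amplitude over the first. Note that the
2-SD criterion applied to a pure-noise trace will, by definition, flag
~2% of samples; it is meaningful only on averaged traces where the
stimulus-locked deflection dominates.

## Ensemble prediction

Observations are theta cycles: each neuron's activity is its spike count in
each retained cycle. A target MSN is modeled as
$\mathrm{MSN}_j(\theta) = \beta_0 + \sum_i \beta_i\, x_i(\theta) + \varepsilon$
over the PYR population. The written model is linear in parameters with an
additive error, so the default family is Gaussian with identity link
(ordinary least squares, matching the normal-equations solution to 1e-8); a
log-link Poisson family is available. "GLM" alone does not pin the family,
and with per-cycle counts of order one the two give nearly identical
rankings. Predictors are raw per-PYR counts by default; a PCA compression
of the predictor matrix is implemented but off by default — the notation in
the source model is ambiguous between "pyramidal cell $i$" and "principal
component $i$", and both readings are provided rather than resolved.
Rank-deficient designs fall back to a small-penalty ridge solution with a
message. Accuracy is the Pearson correlation between observed and predicted
counts across cycles, invariant to affine rescaling of predictions;
zero-variance cases return `NA` with a message.

## Behavior

The place-preference score is
$(t_{\mathrm{target}} - t_{\mathrm{other}})/(t_{\mathrm{target}} + t_{\mathrm{other}})$
over dwell times in the two enclosures. Bridge and out-of-mask samples are
excluded from the denominator — the two-enclosure formula read literally;
whether the original analysis excluded bridge time is not stated, and this
choice changes scores by at most the bridge dwell fraction. Tracking gaps
up to 0.5 s are linearly interpolated, longer gaps dropped. Occupancy maps
are dwell seconds per spatial bin and conserve total duration to one frame
interval; event (poke) counts are split by enclosure mask.

## Validation scale

The bundled checks run at desk scale on one CPU: null calibration on 100
populations of 30 neurons × 20,000 bins; recovery of 5 six-member
assemblies (participation 0.8, 1 event/s) in 20-minute, 50-PYR sessions
over 20 seeds; 100 coupled and 100 uncoupled PYR–FSI pairs at 200
surrogates each (the band construction is quantile-based, so 200 suffices
for the global band; per-bin bands at the 0.5% level are better estimated
with the full 1000); ensemble-model recovery at 10,000 cycles and
cross-session discrimination over 50 seeds. The numbers these checks print
are recomputed from scratch by `scripts/acceptance.R`.

## Known limitations

* The Marcenko–Pastur count reports *any* bin-scale comodulation:
  oscillation, slow rate co-drift and place-field overlap all contribute
  patterns. On real data the count is an upper bound on "assemblies" in the
  co-firing sense.
* The 2-SD member rule is undefined when a pattern's support is a large
  fraction of the population.
* $R_{\mathrm{THRES}} = 5$ admits a background of spurious activations
  (~0.5–1/s) from the quadratic form's tail; activation-rate comparisons
  should be within-pattern and relative.
* Whole-interval standardization redistributes variance: suppressing
  neurons during part of a session inflates their standardized activity
  elsewhere, so light effects on assembly strength must be compared within
  matched epochs (the pipeline reports per-condition means for this
  reason).
* DBSCAN cannot resolve classes with fewer members than `min_pts`; at very
  small unit counts only k-means and the hierarchical check are
  informative.
* The GLM's cross-session accuracy contrast assumes stable unit identity
  across sessions, which spike-sorting drift violates in real data.
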