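---
title: "Muscle synergy analysis of gait: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Muscle synergy analysis of gait: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitsynergy)
```

## The model

`gaitsynergy` analyses walking sEMG under the synchronous muscle synergy
model: the nonnegative envelope matrix \(M\) (muscles \(\times\) time) is
approximated by a product \(M \approx W H\), where the columns of \(W\)
(one per synergy) hold time-invariant, nonnegative spatial weights — how
much each muscle participates in a synergy — and the rows of \(H\) hold the
nonnegative time activation coefficients with which the central nervous
system recruits each synergy across the gait cycle. Goodness of
reconstruction is measured by the global, uncentered variance accounted
for,

\[
\mathrm{VAF} = 1 - \frac{\lVert M - W H \rVert_F^2}{\lVert M \rVert_F^2},
\]

which is also the model-order selection statistic: the number of synergies
for a subject is the smallest \(N_{syn}\) whose VAF exceeds 0.90, and a
group's order is the ceiling of the mean subject order. VAF is deliberately
uncentered (no envelope mean removal); this is the dominant convention in
the synergy literature, and centering would break the nonnegativity that
NNMF relies on.

## The processing chain

1. **Band-pass filtering** (35–450 Hz, Butterworth, 4th-order prototype).
   Filtering is zero-phase (forward–backward cascade of second-order
   sections). The choice of zero phase is deliberate: envelope timing feeds
   phase-resolved statistics downstream, and a causal filter would delay
   every event by a frequency-dependent lag. Because no DSP package is
   assumed, the design (bilinear transform with pre-warping) and the
   filtering are implemented in the package; `freq_response()` exposes the
   designed transfer function so tests can use the design itself as the
   oracle for the implementation.
2. **Envelope estimation.** The default is a moving-RMS with a 100 ms
   window (`fixed_rms`), which is deterministic and easily verified against
   a brute-force sliding window. An `adaptive_rms` variant chooses, per
   sample, a window from a 25–400 ms dyadic ladder by minimizing an
   estimated bias\(^2\) + variance criterion (bias estimated against the
   shortest window; variance of an \(N\)-sample RMS approximated by
   \(\mathrm{RMS}^2/2N\)). This implements the *intent* of adaptive
   envelope estimators — long windows where the amplitude is stationary,
   short ones where it changes — without reproducing any specific published
   algorithm's internals. All acceptance-level analyses use `fixed_rms`.
3. **Stride segmentation and sub-phases.** Gait events (heel strikes and
   toe offs of both limbs) define four contiguous, half-open sub-phases per
   stride: DS1 (reference heel strike to contralateral toe off), single
   Stance, DS2 (contralateral heel strike to reference toe off), and Swing.
4. **Amplitude normalization.** Each muscle's envelope is divided by the
   median across strides of its per-stride peak, so a typical stride peaks
   at 1 for every muscle. Normalization is per muscle; applying it twice is
   a no-op (the second divisor is 1).
5. **Time normalization.** Each sub-phase is linearly resampled to a fixed
   block (DS1 20, Stance 80, DS2 20, Swing 80 samples) giving a 200-point
   cycle. The printed inclusive sample ranges found in parts of the
   literature ("0–20, 21–100, 101–120, 121–200") sum to 201 and cannot all
   be inclusive; the package adopts the equivalent half-open 0-based
   convention [0,20), [20,100), [100,120), [120,200). **Synergy extraction
   always runs on the envelopes *before* time normalization**; only the
   activation coefficients are time-normalized afterwards, so phase
   duration differences cannot leak into the factorization.

## Extraction, ordering, cross-validation

**NNMF.** Both factors are fitted by multiplicative (Lee–Seung) updates of
the squared Frobenius error, the family matching the fixed-\(W\)
reconstruction rule used in cross-validation. Each of 20 restarts draws
uniform nonnegative initial factors with half of each column suppressed to
a negligible seed value (`1e-6`). Exact zeros are *not* used for the sparse
start: zeros are absorbing under multiplicative updates, so a wrongly
zeroed entry could never be repaired and the factorization would stall far
below the attainable VAF — an effect we observed directly. Iteration stops
when the VAF improvement falls below `1e-5`. Denominators are floored at
`1e-12`.

**Order selection.** Orders are scanned upward with each order warm-started
from the previous solution plus one random component; this makes the VAF
curve monotone non-decreasing by construction, which independent restarts
alone do not guarantee. When the mean subject order is an exact integer the
group rule returns that integer (the ceiling), a case that cannot be
distinguished from the usual "next larger integer" phrasing when means are
fractional.

**Ordering and averaging.** Subject synergies are matched to a reference by
the one-to-one assignment maximizing total cosine similarity — an exact
branch-and-bound assignment, not a greedy pass, with lowest-index
preference on exact ties; tests verify agreement with exhaustive
permutation search up to \(N_{syn} = 5\). Group-average synergy vectors are
entrywise means of the ordered sets, renormalized to unit columns. The
reference group defaults to controls at self-selected speed, so any
speed-related differences surface in the activation coefficients rather
than in the spatial weights.

**Cross-validation.** Whether a fixed reference set \(W_{ctrl}\) explains a
subject's data is tested by non-negative reconstruction: \(H\) is fitted by
`H <- H * (W'M) / (W'WH)` with \(W\) frozen. As printed in parts of the
literature this update omits the leading multiplicative factor
\(H_{a\mu}\); taken literally that is not a convergent iteration, so the
package implements the standard multiplicative rule and treats the printed
form as a typographical omission. The null distribution comes from
reconstructions with within-column shuffles of \(W_{ctrl}\) (the weight
multiset per synergy is preserved, the muscle assignment destroyed);
`n_shuffles` is configurable (default 1000, minimum 20) and the threshold
is the 95th percentile with the linear-interpolation definition, neither of
which is standardized in the literature.

## Phase statistics

Per-phase activity is the sum of the 200-point profile over the phase
blocks. The center of activity (CoA) maps the cycle onto the circle
(360° = one cycle, sample \(t\) at \(360 t/200\) degrees) and returns the
direction of the circular resultant \(\sum_t H_t e^{i\theta_t}\). A zero
resultant (all-zero or perfectly uniform profile) raises an error rather
than returning an arbitrary angle. Group differences are tested per
(synergy, sub-phase) cell by a tie-corrected Kruskal–Wallis test; when
every observation in a cell is tied there is no rank information and the
cell is reported as \(H = 0, p = 1\). Post-hoc comparisons default to
pairwise two-sided Mann–Whitney tests with Bonferroni multiplication by the
number of pairs; Dunn's \(z\)-based procedure is available via
`posthoc = "dunn"` (the literature rarely states which was used; both are
provided). Equivalence of synergy counts across groups uses the
Freeman–Halton extension of Fisher's exact test, implemented by full
enumeration of tables with the observed margins (desk-scale margins make
enumeration exact and cheap); tests verify agreement with
`stats::fisher.test` and with a margin-preserving permutation null.

## The synthetic world

Because clinical gait sEMG is not redistributable, every stage is verified
against a generator with known ground truth. The packaged template has 12
muscles and 4 synergies reflecting the canonical functional groupings of
level walking: knee extensors + gluteus medius (weight acceptance, early
stance), calf muscles (propulsion, late stance), TFL with minor
knee-extensor/TA/PL contributions (weight acceptance and leg swing), and
hamstrings + TA (late-swing deceleration). Activations are periodic
Gaussian bumps locked to the gait-cycle fraction (wrapped at the cycle
boundary so late-swing activity continues into the next stride's first
samples).

Generator defaults state a realistic desk-scale study: 12 subjects per
group, 8 strides each (about what a short walkway yields), stride duration
1.2 ± 0.1 s, sub-phases at 12/38/12/38% of the cycle (consistent with the
20/80/20/80 resampling blocks), 1000 Hz sampling, 20 dB per-channel SNR,
and a subject-level weight perturbation SD of 0.05 (rectified and
renormalized). Noise is additive Gaussian on the envelopes, clamped at
zero — the simplest model preserving the nonnegativity NNMF assumes. In
`raw` mode each envelope amplitude-modulates an independent band-limited
(35–450 Hz) unit-RMS Gaussian carrier, the standard surrogate in EMG
simulation, so the filter + envelope chain can be exercised end to end.

Two design points deserve emphasis:

* **Bump geometry is part of the stated world.** Amplitudes and widths were
  chosen so that, *after* per-muscle amplitude normalization, each synergy
  carries a distinct and non-negligible share of signal energy. This
  matters because normalization equalizes muscle peaks, making a synergy's
  post-normalization energy scale with its bump width and the number of
  muscles it dominates rather than with its raw amplitude. With
  well-separated supports the rank-3 fit plateaus near VAF 0.88 while the
  rank-4 fit reaches ≈ 0.995 at 20 dB SNR, so the 90% criterion recovers
  the generative order; a template with strongly overlapping bumps (e.g.
  coincident early-stance activity in two synergies) would *not* be
  identifiable by a variance criterion, which is a property of the method,
  not a bug in the generator.
* **The `tf_like` preset injects a known effect**: the calf synergy's
  stance bump is widened (×1.8) and flanked by bumps centred in the two
  double-support phases, and the hamstrings synergy gains a bump at the
  contralateral heel strike — mimicking the prolonged calf activity and
  additional hamstrings activity reported for trans-femoral prosthetic
  gait. The injected DS2 surplus is verified in tests against direct
  integration of the added bumps.

What a green test does **not** establish: the generator has no motor-unit
physiology, no electrode crosstalk, no nonstationary noise, no
biomechanics; inter-subject variability is a single isotropic perturbation.
Green tests establish that the *pipeline* recovers what it is designed to
recover from data obeying its model assumptions — they say nothing about
clinical sensitivity on real recordings.

## Numerical choices and degenerate inputs

* NNMF / NNR stop on VAF improvement `< 1e-5` (configurable); denominators
  floored at `1e-12`; all-zero input matrices, zero synergy columns, zero
  envelope muscles, and zero circular resultants raise errors rather than
  returning conventions.
* Zero-phase filtering uses odd-reflection padding (500 samples by default)
  so start-up transients decay inside the padding.
* Descriptive statistics round half-up (half away from zero), the usual
  presentation convention; base R's round-half-even would disagree on
  exact .5 boundaries.
* Seeds: every stochastic routine takes an explicit `seed` and restores the
  caller's RNG state; cohorts, extractions, and full pipeline runs are pure
  functions of their inputs.

## Known limitations

* The adaptive envelope estimator implements a stated intent, not a
  specific published algorithm; analyses meant to be deterministic should
  use `fixed_rms`.
* The exact synergy-count test enumerates all tables with the observed
  margins; this is exact and fast for desk-scale group sizes (tens of
  subjects, 3 × 3 tables) but not intended for large margins.
* `run_pipeline()` requires the same muscle montage across all subjects
  and groups; no channel matching or imputation is attempted.
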