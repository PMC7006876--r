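---
title: "Spatiotemporal connectome analysis: models, measures, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal connectome analysis: models, measures, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stconnectome)
```

## The analysis in one paragraph

Resting-state BOLD activity, reduced to one time series per cortical region,
is binarized into a point process: a region is *active* at a frame when its
z-scored signal exceeds +2 SD. Active (region, frame) cells become the nodes
of a multilayer graph; two cells are linked when the regions are connected in
a structural white-matter template and the frames coincide or are successive
(a region active at two successive frames is also linked to itself). The
weakly connected components (CCs) of this graph are the unit of analysis:
transient patterns of coactivation spreading along anatomical connections.
Each CC is scored by its **System Diversity** (SD) — the entropy of the
distribution of its unique regions over the seven canonical functional
systems (VIS, SM, DA, VA, LIM, FP, DM) — and a set of CCs is scored by its
**Spatiotemporal Diversity** (STD), built from the mean pairwise cosine
similarity between the CCs' l2-normalized spatial activation vectors. Group
contrasts (children vs. adults) are evaluated by permutation of CC group
labels, at the global scale, per functional system (with Benjamini–Hochberg
correction across the seven systems), and per region (nodal maps). Finally,
multilayer edges are classified by physical length (short < 20 mm,
long > 42 mm) and by system membership (intra/inter), and each subject's
relative edge usage is correlated with age, with mean framewise displacement
as a nuisance.

## Definitions and conventions

**Point process.** Per region, z = (x − mean)/SD over the retained frames
(the first four frames are dropped first; motion censoring acts later, on
components, so it does not enter the z-scoring). A cell is active iff
z > threshold, strictly, positive tail only: an event is a significant
*peak* of BOLD activity. Deflations below −2 SD are not events; an
`"absolute"` mode is available for |z| analyses. The strict inequality is a
measure-zero choice in continuous data but is fixed for reproducibility.

**SD.** For a CC with p_f unique regions in system f and P = p/Σp,
SD = −Σ P_f log P_f, natural logarithm (a `base` argument is provided;
only relative comparisons matter). SD ∈ [0, log 7]: 0 when one system is
recruited, log 7 for a uniform spread over all seven. Only *unique* regions
count — how long a region stays active does not change SD.

**STD.** For CCs n, m with unit-normalized activation vectors x̄, the
similarity is cos(x̄_n, x̄_m) ∈ [0, 1] (vectors are non-negative), and
STD over an index set is the mean over unordered distinct pairs. Two
conventions are emitted: `std_sim` (the mean similarity itself) and
`std_div = 1 − std_sim`, under which *higher values mean a more
heterogeneous pattern repertoire*. All interpretation in this package uses
the diversity convention (`std_div`, the default in group tests); since
1 − x is a monotone relabeling, two-sided permutation p-values are identical
under either convention (this is asserted by a test), so the choice affects
only the sign language of reported differences.

**Scales.** Global: all CCs of a group. Functional system f: CCs whose
unique-region fraction in f is at least 20% (inclusive — "at least" — and
deliberately consistent with SD's unique-region convention); a CC may
qualify for several systems. Nodal r: CCs containing region r at any frame.

**Permutation tests.** The permutation unit is the CC, not the subject:
group labels are reassigned over the pooled CC list preserving group sizes.
This matches the framework's group-level construction (all subjects of a
group concatenated), but it means within-subject dependence between CCs is
not respected by the null — a caveat discussed under *Limitations*. STD
permutations are evaluated by submatrix averaging of the precomputed
similarity matrix (one BLAS multiply for all permutations), never by
re-embedding; p-values use the +1-corrected estimator
p = (1 + #extreme)/(1 + n_perm), which cannot return zero and gives
min p ≈ 0.001 at 1,000 permutations. For small groups an exhaustive mode
enumerates all reassignments and returns the exact fraction. At the system
scale the one-tailed direction defaults to the direction of the observed
global difference; this is configurable because the alternative's direction
is an analysis choice.

**Motion.** FD is the Power convention: sum of absolute frame-to-frame
translation changes plus 50 mm times the sum of absolute rotation changes.
Frames are flagged when FD > 0.4 mm *or* DVARS > 25 (strict; OR is the
conservative combination of the two criteria). Subjects with more than 10%
of their frames flagged — counted over the full run, before the four-frame
drop, i.e. relative to total scanning time — are excluded. Scrubbing is
component-wise: any CC touching a flagged frame is discarded entirely, so
activity that spread from a corrupted frame into neighbouring frames is
removed with it. DVARS is accepted precomputed; a region-level
RMS-of-differences surrogate would not be equivalent to the voxel-level
definition and is therefore not used in the pipeline.

**Edge usage.** Every inter-regional multilayer edge instance of the kept
CCs is counted (same-frame and cross-frame alike; same-region continuity
edges carry no physical length and are excluded). Instances, not unique
structural edges, are counted because the multilayer graph's edges *are*
instances; a unique-per-CC variant is a straightforward aggregation of the
per-instance table. Fractions are per subject (relative usage), so subjects
with different amounts of activity are comparable. Length classes are
strict: short < 20 mm, long > 42 mm, mid in between, with the ±5 mm
sensitivity sweep recomputing the correlation at each shifted threshold.
Consensus templates keep edges present in at least 50% of subjects
(inclusive), with the mean length over possessing subjects (median by flag).

## The synthetic cohort generator

The package replaces restricted clinical MRI data with a generative model
whose parameters *are* the study conditions. Defaults
(`sim_config()`): 40 subjects, 100 regions, 200 frames at TR 2.4 s, ages
uniform on [6, 33] years with the children/adults cut at 18 (the cut is an
argument, since group membership is an input of the analysis, never
inferred).

**Geometry and structure.** Seven spatially clustered systems (regions
scattered with 8 mm SD around system centres in a 60 mm box) and a
structural template whose edge probability decays exponentially with
centroid distance (length scale 30 mm), scaled so the mean edge probability
equals the configured density (0.06) and degenerating to the complete graph
at density 1. Distance-dependent wiring is what makes the spatial
clustering of systems *topologically* real: short edges are predominantly
intra-system, as in cortex, so the short-range/intra-system confound that
any edge-length analysis faces in real data is present in simulation. Edge
lengths are Euclidean centroid distances and span both classification
thresholds (2–75 mm at the default geometry).

**Events.** BOLD is unit-variance Gaussian noise plus planted coactivation
events. An event seeds a region and performs a random walk along template
edges for a geometric number of steps (mean 8), each step crossing system
boundaries with probability `mixing(age)`, preferring long (> 42 mm) edges
with probability `long_range_pref(age)`, and advancing one frame with
probability 1/2. Event cells receive +4 noise-SD of signal, chosen in
z-units so threshold survival is controlled analytically (a cell needs
z > 2 after z-scoring; 4 SD leaves headroom for the mean/SD inflation that
the events themselves cause). Motion spikes (FD and DVARS pushed strictly
above their thresholds) occur at 2% of frames; baseline FD and DVARS are
clipped below the thresholds so a spike-free subject is never flagged.

**Repertoire.** Recurring patterns are drawn from a cohort-level pool of 24
canonical patterns — shared across subjects, as canonical resting-state
coactivation patterns are — ranked from most integrative/long-range
(generated with the oldest-age parameter values, with a fixed step count so
the core patterns are stable, large assemblies) down to most local. A
subject's dictionary is the first `repertoire_size(age)` patterns (24 at
age 6, 5 at age 33): maturation prunes the repertoire toward the
integrative core. The probability that an event re-uses a dictionary
pattern rather than walking afresh is tied to consolidation,
`reuse_prob · (1 − K/(pool+1))` with K the dictionary size — children
(K = 24) explore almost exclusively novel patterns, adults (K = 5) mostly
re-instantiate the shared core. This one mechanism carries all three
planted effects coherently: adults' events are more cross-system (higher
SD), concentrated on few shared patterns (higher mutual similarity, lower
`std_div`), and routed through long-range edges (higher long-edge usage).

**Null mode.** `effects = FALSE` replaces the age-dependent parameters by
their midpoint constants and empties the pattern pool. With no dictionary,
pooled CCs are exchangeable at the CC level across groups, which is the
regime in which the CC-label permutation test is exactly valid — the
type-I calibration experiment uses this mode. (With dictionaries active,
CCs from one subject share patterns and are not independent; see
*Limitations*.)

**What the generator does not emulate.** No haemodynamic response
convolution, no voxel-level structure, no tractography error model, no
disconnected coactivations (the framework's core assumption is that
coactivation spreads along structural edges, so the generator plants only
such events), and no realistic spatial autocorrelation of noise. Passing
tests therefore demonstrate that the *pipeline* recovers planted structure
of the stated kinds at realistic problem sizes — not that real
developmental data would show these effects.

## Problem sizes used by the packaged experiments

The packaged calibration experiment uses 200 null cohorts of 12 subjects,
60 regions, 80 frames (density 0.12 so small templates stay connected) with
200 permutations per test — sizes chosen to make a 200-replicate calibration
a routine desk computation while keeping ≥ 2 subjects per group
essentially always. The effect-recovery experiment uses 50 cohorts at the
full default conditions (40 subjects, 100 regions, 200 frames). The
acceptance script runs the default cohort once with 1,000 permutations, the
analysis-grade setting.

## Numerical and degenerate-input choices

- Zero-variance regions abort point-process construction with the region
  named: a constant series signals broken input, not a quiet region.
- STD over fewer than two components is `NA` with a warning, and nodal maps
  mark regions touched by fewer than two CCs as undefined; cross-group map
  agreement correlates jointly defined regions only and requires at least 3.
- Component IDs are assigned by sorted traversal (first frame, then first
  region), never by hash order; all outputs are deterministic functions of
  (cohort, parameters, seed), which the byte-identity test asserts.
- Isolated active cells are dropped by default (`min_nodes = 2`: a CC must
  contain at least one edge); whether singletons count as CCs is exposed as
  a parameter because the convention is not universal.
- Same-region temporal continuity edges are included by default (without
  them a region's sustained activation fragments into per-frame pieces) and
  can be disabled.
- Ties at every stated threshold are resolved as written: z > 2 strict,
  FD/DVARS flags strict, the 10% exclusion strict (> 0.10), the 20% system
  rule and the 50% consensus rule inclusive, and the 20/42 mm length classes
  strict on both sides.
- Pearson p-values for age trends use the t transform (n − 2 df; n − 3
  after partialing out FD by the first-order partial-correlation formula).

## Limitations

- **CC-level permutation.** Reassigning CC labels treats CCs as
  exchangeable units. When subjects differ (and they do, by construction,
  in the effects-on cohorts — and in real data), CCs cluster within
  subjects, and the CC-label null understates that dependence. The
  calibration experiment is therefore run in the null mode where CC-level
  exchangeability actually holds; a subject-level permutation would be the
  conservative alternative and is deliberately out of scope here, since the
  analysis is defined at the CC level.
- **STD direction.** The printed STD formula is a mean *similarity*, while
  its interpretation (higher = more heterogeneous) reads as a
  *dissimilarity*. Both are reported; tests and reported differences use
  `std_div`. No p-value can depend on the choice.
- The generator's event walks are a stand-in: no claim is made that they
  model BOLD dynamics beyond carrying the stated statistical structure
  (threshold-surviving coactivations propagating on the template, with
  controllable mixing, reuse, and length preference).
- Template lengths in simulation are Euclidean; real fiber lengths exceed
  Euclidean distance, so absolute threshold placements (20/42 mm) should be
  read against the simulated geometry, not cortex.
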