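---
title: "Methods: morphometry, imaging quantification and the extinction circuit model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphometry, imaging quantification and the extinction circuit model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbex)
```

`mbex` implements the quantitative backbone of a *Drosophila*
memory-extinction study: morphometry of EM-traced mushroom-body output
neurons (MBONs), synapse-placement statistics, calcium-imaging
quantification, T-maze behavioral metrics and protocols, and a
compartmentalized circuit model in which extinction is a *parallel opposing
memory* written by reward-coding dopaminergic neurons (DANs). This vignette
records the methods, the tunable parameters and the design decisions —
especially the places where the underlying biology constrains only the sign
structure and a concrete quantitative choice had to be made.

## 1. Skeleton morphometry

Neuron skeletons are rooted trees of 3-D nodes in nanometres (the
convention of whole-brain EM volumes), exchanged as 7-column SWC with
parent `-1` marking the root; `unit_scale` converts micron-valued files on
the way in. Edge lengths are straight-line Euclidean distances between
consecutive nodes — no spline smoothing — so total cable length and all
geodesic (along-the-arbor) distances are sums of segment lengths.
`validate_skeleton()` reports duplicate ids, unresolved parents, multiple
roots, and nodes unreachable from the root (cycles or detached
components); the readers fail fast with the offending line.

**Strahler order** is computed leaves-up: a leaf has order 1, a parent
takes the maximum child order, incremented when at least two children
attain it. It is invariant under child permutation and edge subdivision,
which the tests assert on random trees against a naive recursive oracle.

**Dendritic root.** Anatomically, the dendritic root is the point where
the main neurite splits into proximal dendrites and distal axon. A
manually annotated node (tag `"dendritic_root"`) always wins — in practice
this point is tagged during reconstruction. When no tag exists,
`find_dendritic_root()` infers it from synapse flow: for each branch node
and each of its child subtrees, the separation score is the larger of
(postsynapses inside + presynapses outside) and (presynapses inside +
postsynapses outside), normalized by all sites; the branch node with the
best-separating child wins, ties broken toward the smallest `node_id`. For
a neuron whose inputs lie below one child and whose outputs lie elsewhere
the score reaches 1 exactly at the anatomical branch point; the generator
recovery test requires ≥ 99% recovery over seeded instances.

**Axonlets** are distal neurites that originate *inside* the dendritic
field yet carry exclusively presynaptic sites. The field is
operationalized as the nodes below the dendritic root whose own subtree
still contains at least one postsynapse — excluding the dendritic root
itself, so the main axon (also a child of the root) never qualifies. An
axonlet is then a maximal child subtree of a field node with ≥ 1 synaptic
site, all presynaptic; each is reported with cable length (including its
attachment segment) and presynapse count.

## 2. Synapse-placement statistics

`distance_profile()` assigns each synapse of a class its geodesic distance
to the dendritic root — postsynaptic node for input classes, presynaptic
node for outputs. Distances are absolute nanometres; a field-relative
normalization was considered and rejected as the default because arbor
extents are part of the comparison between neurons.

**Unimodal vs bimodal.** `fit_distance_distribution()` fits one- and
two-component Gaussian mixtures by EM and selects by BIC
(`-2 logL + p log n`). The EM is deterministic: component means initialize
at the 25th/75th percentiles, sds at half the pooled sd, weights equal.
Because distances are realized on a discrete node grid, duplicated values
occur, and an unconstrained two-component fit can collapse one component
onto a point mass (a likelihood singularity). Component sds are therefore
floored at 5% of the pooled sd — far below any genuine component sd in
these data, but enough to remove the singularity. Sample-size guard:
`n >= 10`; zero-variance samples are rejected.

**Localization comparison** uses a two-sided rank-sum (Mann-Whitney) test
plus the signed median difference; with one observation per side the
p-value is 1 by convention. The test is the natural distribution-free
choice for comparing placement depth between synapse classes.

**Synapse-count bounds.** Consensus tracing finds 99.8% of presynapses and
91.7% of postsynapses, with a 2.2% postsynaptic false-positive rate
(presynaptic false positives negligible). For a found count $F$:

$$\mathrm{lower} = F\,(1 - 0.022), \qquad
  \mathrm{upper} = F\,\bigl(1 + (1 - 0.917)(1 - 0.022)\bigr),$$

both rounded half-away-from-zero to one decimal. The lower bound removes
expected false positives; the upper bound adds the expected number of
missed true synapses, itself discounted by the false-positive rate. This
parameterization reproduces all six published bound values from found
counts 17, 16 and 47.

**Dendrograms.** `layout_dendrogram()` flattens an arbor for display:
depth encodes topological (not metric) distance from the root, leaves
spread along x in file order with parents centred over children, and the
layout's edge set is isomorphic to the skeleton's. Synapse marks travel
with their nodes so input/output classes can be coloured.

## 3. Imaging quantification

Traces are raw fluorescence sampled at 5.92 Hz (the acquisition rate of
the 256×256 two-photon recordings this emulates). Two baseline conventions
are supported, matching the two experiment types: `"pre_odor_2s"` (mean F
over the 2 s ending at odor onset, recomputed per stimulus) and
`"first_9s"` (mean F over the first 9 s of the recording, used for
optogenetic connectivity tests). Baselines must be positive.

The odor response is the trapezoidal integral of F/F₀ over the 5-s odor
window on the native grid. The onset snaps to the nearest sample; because
5 s is not a whole number of sample periods (29.6 at 5.92 Hz), the window
edges are linearly interpolated so every trial integrates exactly the same
duration — without this the integral loses up to one sample period, a ~2%
bias for fast-rising responses. The integrand defaults to F/F₀ (so a flat
trace integrates to the window length); the baseline-subtracted ΔF/F₀
integral is available via `integrand = "dff"`, and under it a planted 30%
CS+ depression appears directly as a ~0.7 normalized CS+/CS− ratio.

Per fly and trial, CS+ and CS− AUCs are divided by the novel-odor (IAA)
AUC, removing between-fly response-magnitude variance. Flies whose novel
AUC falls below ε (default 10⁻⁶ of the largest AUC magnitude, which also
catches negative values) cannot be normalized and are excluded with a
warning. Cohorts are tested with `paired_group_test()`: Shapiro-Wilk on
the paired differences at α = 0.05 gates a paired t test (normal) vs a
Wilcoxon matched-pairs signed-rank test (otherwise). All-zero differences
return the degenerate p = 1. The optogenetic comparison contrasts mean
ΔF/F₀ in the 1 s before vs 1 s after stimulation onset with a paired t
test across preparations.

## 4. Behavior and protocols

The performance index is (flies in CS+ arm − flies in CS− arm)/total;
non-choosers count toward the total by default (the denominator is "total
flies"), with `include_nonchoosers = FALSE` available. One experimental
sample averages two reciprocally trained groups. Group statistics follow
the field's convention: two groups → unpaired two-sided t test (pooled
variance); three or more → one-way ANOVA with Tukey's HSD. Every group
needs n ≥ 3.

`build_protocol()` expands phase specs into a deterministic event table.
The standard training trial is 1 min of CS+ with twelve 90 V shocks at 5-s
intervals, the first 1.2 s after odor onset (so the train ends at 56.2 s),
then 45 s of air and 1 min of CS−. The 1.2-s first-shock delay is stated
for under-the-microscope training and applied generally (configurable).
The inter-trial interval of re-exposure phases is measured end-to-start,
so two 1-min trials at 15-min ITI start 16 min apart. Shock trains that
overrun the odor window and overlapping odor epochs are rejected.
Temperature shifts are annotations only — no kinetics. Timelines
serialize to JSON and round-trip.

## 5. The extinction circuit model

The model is rate-based with discrete trials: no spiking, no time
constants, one plasticity update per trial. Four output channels read a
binary KC pattern through per-compartment weight vectors initialized at 1:
γ1pedc (MVP2, approach), γ5 (M6, avoidance), β′2 (M4β′, avoidance) and a
lumped second approach channel. Dendritic drive is the *mean* weight over
the odor's active KCs, so a naive network responds identically to every
odor — the balanced configuration that promotes no directed behavior.

The EM placement result is encoded as the *form* of MVP2's feedforward
inhibition: onto M6, whose MVP2 inputs sit at the root of the dendritic
tree, inhibition is divisive (shunting): m6_axon = m6_dend / (1 + g·MVP2);
onto M4β′, whose MVP2 inputs are distal boutons, it is subtractive:
m4_axon = max(0, m4_dend − s·MVP2). This is an interpretive encoding — the
anatomy motivates, but does not measure, these forms. The γ5 DAN drive is
dan_gain·(m6_axon + m4_axon): the network's own avoidance output is the
extinction teaching signal. Valence is approach minus avoidance drive, and
the model PI for an odor pair is (V₊ − V₋)/(|V₊| + |V₋| + ε).

Training pairs the CS+ with PPL1 DAN activity, depressing CS+-active KC
weights in γ1pedc and the other approach channel by η_train. Each
unreinforced CS+ re-exposure computes the recurrent γ5 DAN drive from the
*current* M4/M6 axonal response; above `dan_threshold` (and unblocked) it
depresses the CS+-active KC weights in γ5 only — M4β′ weights are never
touched during extinction, matching the observation that the β′2 response
is unchanged. Plasticity is multiplicative with a floor:
w ← max(w_min, w(1 − η)); weights stay in [w_min, 1] and odors that share
no active KCs with the CS+ are invariant across the whole protocol.

**Parameters are model choices, not measurements.** The biology fixes a
table of inequalities (which responses are depressed, disinhibited or
unchanged after each phase), not magnitudes. Defaults: N = 200 KCs, 15
active per odor (7.5% sparseness, protocol odors disjoint); η_train = 0.2
(one training trial yields a clear but unsaturated memory); g_shunt = 0.5,
s_sub = 0.3 (inhibition strong enough that releasing it visibly
disinhibits both avoidance MBONs); dan_gain = 1; dan_threshold = 1.42,
which sits strictly between the naive recurrent drive (≈ 1.367) and the
post-training drive (≈ 1.474), so only a trained, disinhibited network
recruits extinction; w_min = 0.05. The extinction rate η_ext is
*calibrated at construction*: after training, the M6 shunt release lets
the CS+ response exceed the CS− response by the factor
(1 + g)/(1 + g(1 − η_train)); η_ext is chosen so that the default two
re-exposure trials shrink the CS+ dendritic drive by exactly that factor,
returning the M6 axonal CS+ response to the CS− level (the re-equalization
seen physiologically). With the defaults η_ext ≈ 0.034.

Under these defaults the full sign table holds: after training MVP2(CS+)
is depressed, M6 dendrites unchanged, both avoidance axons disinhibited;
after extinction MVP2 depression persists, M6 dendrites are depressed, the
M6 axonal responses re-equalize (within 5%), M4β′ disinhibition persists;
behaviorally PI_trained < PI_extinguished < 0, blocking γ5 DANs during
re-exposure leaves PI at the trained value, blocking M4/M6 output removes
the teaching signal (reducing extinction to nothing in this deterministic
model), and retraining restores at least the trained avoidance. Extinction
is partial and monotone in trial count; the model makes no claim about
trial *spacing*, which it does not represent.

## 6. Synthetic data: what it emulates and what it does not

The generators exist so every analysis stage can be validated against
planted ground truth without access to raw recordings; all are
deterministic given their seed, restore the ambient RNG state, and emit
sidecars sufficient to score recovery.

**Skeletons** (`gen_skeleton()`): a main neurite runs from the soma to the
planted dendritic root, where primary dendrites (default 4) and axon
branches (default 2) emerge as chains with short side twigs; segment
lengths are Gaussian (default 300 ± 60 nm, floored at 10% of the mean).
Synapse classes are planted by sampling target geodesic distances from the
requested law (uniform, Gaussian, bimodal Gaussian) and snapping each to
the nearest-distance node of the right domain — so planted distances are
geodesic, matching the analysis target, with realized-vs-target error
bounded by the local node spacing. Out-of-reach targets are resampled with
a summary warning and fail after 100 attempts. The morphology is
deliberately simple: no tortuosity, taper, or spine-like twigs, so passing
recovery tests demonstrates correctness of the analysis chain, not realism
of fly neurons.

**Imaging cohorts** (`gen_imaging_cohort()`): each fly sees CS+, CS− and a
novel odor for 5 s each with 30 s of air between, sampled at 5.92 Hz.
Responses follow a difference-of-exponentials kernel (rise 0.3 s, decay
4 s, peak-normalized) scaled by baseline (100 a.u.), peak ΔF/F₀ (0.8), a
per-fly lognormal amplitude factor (sdlog 0.2) and the planted CS+
multiplier; noise is additive Gaussian on F (sd 3 a.u.). Two deliberate
idealizations keep the noise-free, effect-free cohort *exactly*
symmetric (a property the tests assert): the kernel has finite support
(the 25-s air remainder), so responses never bleed into the next epoch's
baseline, and epoch onsets snap to the acquisition grid so every epoch
samples the kernel in phase. Photobleaching, motion, GCaMP nonlinearity
and trial-order effects are absent — conclusions about those require real
data.

**T-maze cohorts** (`gen_tmaze_cohort()`): each fly independently picks
the CS+ arm with probability (1 + PI)/2, giving an unbiased observed PI
with the binomial standard error √(1 − PI²)/√n.

## 7. Problem sizes and numerical conventions

The validation studies run at fixed sizes chosen to make the recovery
rates statistically meaningful while keeping a full check fast on a single
core: 1,000 random trees (≤ 200 nodes) for the tree-algorithm oracles;
200 skeleton instances with n = 500 planted distances (5 sd separation
for the bimodal half) for mixture selection; 100 imaging cohorts of 15
flies for sign recovery plus 1,000 for the null error rate; 1,000 groups
of 100 flies for the T-maze calibration. Ties break toward the smallest
node id everywhere; reported bounds round half-away-from-zero to one
decimal; the mixture EM stops at a relative log-likelihood change of 1e-8
or 500 iterations.

## Known limitations

* Dendritic-root inference assumes a single dominant input/output
  separation; neurons with mixed or multi-focal fields need the manual tag.
* The bound formula treats detection errors as independent and
  proportional; it is a reconstruction that matches the published values,
  not a derived estimator with stated variance.
* The circuit model is a sign-structure model: magnitudes, trial-spacing
  effects, spontaneous recovery and appetitive-memory extinction are out
  of scope.
* The imaging pipeline quantifies manually segmented ROI traces; no
  segmentation, registration or spike inference is provided.
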