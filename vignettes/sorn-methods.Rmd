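---
title: "Deterministic self-organizing recurrent networks: model, protocols and analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deterministic self-organizing recurrent networks: model, protocols and analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`sornsim` simulates a self-organizing recurrent network (SORN) of binary
McCulloch–Pitts threshold units: $N^E$ excitatory and $N^I = 0.2\,N^E$
inhibitory neurons updated synchronously in discrete time,

$$x(t+1) = \Theta\!\left(W^{EE}x(t) - W^{EI}y(t) + W^{EU}u(t) - T^E(t)\right),
\qquad
y(t+1) = \Theta\!\left(W^{IE}x(t+1) - T^I\right),$$

where $\Theta$ is the elementwise Heaviside function (a strictly positive
activation spikes; an activation of exactly zero does not — the boundary
convention is arbitrary but fixed, and only affects measure-zero
configurations).  $u(t)$ is a one-hot symbolic input; each letter drives a
pool of $N^U = 10$ excitatory units with weight $w^{in} = 0.5$.  Inputs do
not reach the inhibitory population: the inhibitory input matrix that
appears in the update equation in some formulations is never specified and
is taken to be zero here, so inhibition is driven purely by the fresh
excitatory state.  The model is fully deterministic; all variability in its
behaviour originates from the stimulus sequence and from the unobserved
internal state.

Three plasticity rules shape the excitatory recurrence:

* **STDP** (rate $\eta_{STDP} = 10^{-3}$): an existing synapse $W_{ij}$ is
  strengthened when a spike in $i$ directly follows a spike in $j$ and
  weakened for the reverse order.  Updated weights are clipped at zero
  ("excitatory" semantics); with `pruneZeroWeights` a weight driven to zero
  is removed from the synapse set.
* **Synaptic normalization** (every plastic step): each weight moves 10%
  of the way towards
  $W_{ij} / \bigl(\tfrac12\sum_k W_{ik} + \tfrac12\sum_k W_{kj}\bigr)$,
  pulling all incoming *and* outgoing weight sums towards one (pre- plus
  postsynaptic normalization, the "conservation of axonal arbor").  A
  doubly-normalized matrix is a fixed point; entries whose combined
  in/out sum is zero are necessarily zero and are left unchanged rather
  than divided by zero.
* **Intrinsic plasticity** (rate $\eta_{IP} = 10^{-3}$): each excitatory
  threshold follows $T^E \leftarrow T^E + \eta_{IP}(x - H_{IP})$ towards a
  per-neuron target rate drawn once from $(0.09, 0.11)$.  The slight
  heterogeneity of targets discourages repetitive global patterns.
  Thresholds are unbounded; negative excursions self-correct because a
  negative threshold forces the neuron to fire, which raises the threshold
  again.

Within a step the order of operations is: state update, then STDP
(including structural changes), then synaptic normalization, then intrinsic
plasticity.  The source the model derives from does not state the order;
this is the order of the SORN lineage it cites, and all micro-oracle tests
assert the single-rule updates independently of it.

**Structural plasticity.** With probability `structuralRate` (default 0.1)
per plastic step one random non-autapse position is probed and, if empty, a
new synapse of weight `structuralInit` (0.001) is created.  Together with
pruning this lets the *connection fraction* move during learning, as the
weight-fluctuation variant of the SORN describes; the mechanism is
config-exposed and can be disabled for ablations.  In our measurements the
two-word state-space analyses are essentially insensitive to this choice.

**Initialization.** $W^{EE}$ is sparse (directed connection probability
$p^{EE} = 0.1$, no autapses) with entries drawn uniformly from $[0,1]$ and
then iterated through synaptic normalization until all nonzero row and
column sums are within `snTol` of one.  $W^{EI}$ and $W^{IE}$ are dense,
uniform, and exactly row-scaled so that each excitatory unit receives total
inhibitory weight one and each inhibitory unit receives total excitatory
weight one.  Thresholds are evenly spaced across $(0, T^E_{max})$ and
$(0, T^I_{max})$ — implemented as the midpoints of an even partition — and
assigned to neurons in randomly permuted order, so that threshold rank is
uncorrelated with input-pool membership.  The initial excitatory state is
sampled with per-neuron probability equal to its initial threshold;
inhibitory units start silent.

$T^I_{max}$ trades inhibitory resolution against dynamic range: 0.35 for
continuously stimulated tasks, 1 for the trial-structured inference task,
where the onset transient needs head-room and the active inhibitory
fraction then tracks the active excitatory fraction.

**Determinism and seeds.** With `noiseSd = 0` a phase trajectory is
bit-reproducible from its seed.  A master seed is split into named child
streams (topology, thresholds, stimulus order, cue draws, per-phase
structural/shuffle randomness, analysis subsampling) so that, for example,
the stimulus sequence does not change when the topology seed does.  The
phase runner is compiled (Rcpp/Armadillo); the exported single-step
operations `sornStep()`, `applyStdp()`, `applySynapticNormalization()` and
`applyIp()` are an independent pure-R reference implementation, and the
test suite asserts bit-exact agreement of the two over a plastic run.

**Optional noise.** `noiseSd > 0` adds independent Gaussian perturbations
to the excitatory pre-threshold activations and tracks how many spikes flip
relative to the noiseless update, so that noise levels can be dosed as a
fraction of activity.

## Stimulation protocols

All experiments share a three-phase schedule: *self-organization*
($T_{plastic} = 50000$ steps, all plasticity active), *training*
($T_{train} = 20000$, STDP and structural changes frozen, IP active to keep
the mean rate stable), and *testing* ($T_{test} = 50000$).  At the end of
each phase the excitatory state vector is shuffled by a uniform random
permutation across neurons.  Words are drawn i.i.d. according to their
priors (immediate repetitions allowed), their letters presented one per
step, followed by a blank run: none for the continuous-stimulation tasks,
a fixed 10 steps for sequence recognition, and 10–15 steps (uniform) for
the trial-structured inference task, whose test trials use the fixed delay
of 10 plus 0–5 extra steps.

The four presets of `runExperiment()`:

* **random_letters** — ten letters, spontaneous testing phase; basic spike
  and weight statistics.
* **sequence_recognition** — training on "ABCD" (or on all 24 permutations
  as control), a spontaneous "sleep" period (length $T_{train}$; the source
  protocol does not state it), then separate tests on "ABCD", "DCBA",
  "A_CD" and "E_CD", each started from the same post-sleep state.  The
  "sequence magnitude" is the mean firing rate over the four word steps of
  the *stimulus-driven* subpopulation (all input pools of the task
  alphabet, fixed across conditions).  This choice is deliberate: the
  experiment the task emulates records from sensory-driven neurons, and in
  the model the homeostatic loop pins the *whole-population* rate so well
  that the trained-order effect (clearly present in the driven pools) is
  cancelled at the population level by recurrent inhibition.  The blank
  step inside "A_CD"/"E_CD" presents no input.
* **sequence_priors** — continuous random alternation of "ABCD"/"EFGH" at
  configurable priors; evoked activity recorded in training, spontaneous
  activity in testing.
* **inference** — "AXXX"/"BXXX" with disjoint A/B pools and
  $T^I_{max} = 1$; the testing phase presents ambiguous cues
  ("A/B XXX _ …") with $f_A \times 10$ units drawn fresh each trial from
  the A pool and the rest from the B pool, cycling the ambiguity grid in
  random order.

## Readouts and decisions

The decision readout is two least-squares linear regressions (bias
appended, pseudoinverse solve) from the excitatory state at the first blank
after the mask to indicator targets for cue A and cue B.  "At the first
blank" follows the simultaneous state/input indexing of the update
equations: the decision state is the state present when the blank is shown,
i.e. the state evoked by the final mask letter.  (Using the state one step
later instead measurably degrades the readout — the recurrent dynamics have
had one extra input-free step to wash out the cue — and the resulting
flatter decision curves are fitted systematically worse by the
noisy-channel model family.)  States at letter
steps enter as 0-target samples; samples are taken from the end of
training, balanced per letter, and each classifier sees equally many
positive and negative examples regardless of the prior (majority classes
are subsampled uniformly).  The decision is the argmax of the two readouts,
with exact ties resolved to "A" (documented, deterministic).

Evoked-activity prediction fits, per post-onset offset, one pooled
least-squares map from {per-condition indicators, pre-stimulus state, bias}
to the evoked state, and reports the mean per-trial Pearson correlation
between prediction and truth.  A single pooled regression (rather than one
per condition) is used deliberately: with roughly 270 trials per ambiguity
class and ~200 regressors, per-condition fits are saturated at every
offset and cannot show the decay of predictability; pooled over ~3000
trials the regression is well-determined, reproduces the identity at
offset zero, and decays as the spontaneous state's influence fades.  The
baseline permutes pre-stimulus states across trials within condition,
keeping the condition and bias regressors, so it retains the
stimulus-locked average response but loses the trial link.  Decision
prediction trains a separate readout per (ambiguity class, offset) on half
the trials and reports held-out agreement with the network's decisions;
classes with fewer than 10 trials are excluded.

## Spike statistics

ISIs and their per-neuron CV are computed from spontaneous recordings
(neurons with fewer than 10 intervals excluded); the exponential ISI fit
discards intervals of at most 2 steps, below which the discrete dynamics
deviate from the exponential regime.  The Fano factor uses a causal 5-step
sliding window; with target rates near 0.1 this gives 0.5 spikes per bin.
Means and variances are taken over trials per neuron, condition and
offset, and the population FF at an offset is the weighted regression
slope of variance on mean across neurons with weights inversely
proportional to the asymptotic variance of the variance estimate
($\propto \mathrm{mean}^2/n_{trials}$) — under which the slope reduces to
the mean variance-to-mean ratio.  Offsets whose window is truncated by the
trial start are flagged and excluded from mean matching.

**Mean matching.** Windowed mean counts are binned per offset, the
greatest common distribution (per-bin minimum across offsets) is formed,
and points are discarded at random per offset until every histogram equals
it; the FF is recomputed on the survivors and averaged over 10 discard
randomizations.  The bin width is not stated in the analysis the procedure
follows; the default here is 0.005 counts, on the order of the resolution
$1/n_{trials}$ at which a trial-averaged mean is defined, i.e. the
matching is nearly exact.  At this granularity the procedure discards
roughly 60% of the points on inference-task data — comparable to the
"about two thirds" the original analysis reports — while the mean-matched
FF drop at onset survives.  A coarse bin (0.2 counts) leaves the matched
FF essentially equal to the raw one because the model's homeostatically
pinned rates concentrate all means in one or two bins.

## State-space geometry

Hamming distance is the metric throughout (the states are binary).  PCA is
fit on the last 2500 evoked states of the training phase (mean-centered,
unscaled); spontaneous states from the end of the testing phase are
projected into the same subspace.  The nonmetric MDS embeds the pooled
150+150+150 sample of spontaneous, time-shuffled-spontaneous and evoked
states by minimizing Kruskal's normalized stress-1; exact duplicate states
are collapsed before the fit (zero dissimilarities are inadmissible) and
restored as coincident points.  The KL divergence between evoked and
spontaneous pattern distributions subsamples 16 units (more than 24 is
refused — the pattern space grows as $2^n$), counts patterns with an
add-one prior so the divergence stays finite, and handles never-observed
patterns in closed form (their contribution is exactly zero for
equal-length recordings).  Pattern dictionaries take the last 2500
non-blank training states, balance letters to the least frequent one
(keeping the most recent states), and label spontaneous states by the
nearest evoked state, with ties resolved to the alphabetically first
letter, then the earliest dictionary entry.

The SVD transition prediction treats the learned dynamics as
$x(t+1) = W^{EE} x(t)$: each singular triplet maps $v_i$ to
$\sigma_i u_i$, both vectors are matched to letters by the maximum dot
product with the labelled evoked states — evaluating the two sign
orientations of the pair jointly and keeping the better, which makes the
assignment invariant to the SVD's sign ambiguity — and $\sigma_i$
accumulates onto the corresponding letter transition before row
normalization.

## The noisy-channel reference model

The probabilistic reference model treats each of the 10 input units per
cue as an independent binary channel with reliabilities $\theta_1$
(stimulus transmitted) and $\theta_0$ (non-stimulus transmitted), a Naive
Bayes classifier on the channel outputs, and a learned prior $p(A)$.  The
posterior given evidence counts is computed in log space; the evidence
counts under an ambiguous cue are exact convolutions of two binomials, and
the decision curve $p(A \mid f_A)$ is the exact expectation over the
$11 \times 11$ count pairs — sampling is used only as a test oracle.
Fitting to measured decision curves is an exhaustive grid search over
$\theta_1, \theta_0 \in \{0.05, \dots, 0.95\}$ minimizing the unweighted
sum over curves of the mean squared deviation (trial counts do not enter
the objective).  Note the exact non-identifiability
$(\theta_1, \theta_0) \to (1-\theta_0, 1-\theta_1)$ (and the cue-relabelling
copy): up to four grid points produce identical curves, so ties are
resolved towards larger $\theta_1$, then larger $\theta_0$, selecting the
representative with a mostly-faithful stimulus channel.  Ambiguity
fractions that are not multiples of $1/N^U$ are refused rather than
rounded.

## Problem sizes and what the tests show

The packaged checks run the full network ($N^E = 200$) at the standard
phase lengths.  The decision-curve fit uses the nine training priors
$\{0.1, \dots, 0.9\}$; because the channel-model error surface is nearly
flat along the trade-off between $\theta_1$ and $\theta_0$, the grid
argmin is sensitive to realization noise, and we use 10–15 realizations
per prior for the full-plasticity condition (the reference procedure
averages 20) and 5 for the far less variable IP-only condition; a
realization-bootstrap of the fit shows its mode stabilizing only once the
per-prior average pools about ten realizations.  Variability quenching and the prediction suite use 10
realizations of the 0.1-prior inference task; sequence recognition uses 20
realizations per condition at reduced phase lengths (20000/10000/10000) —
the effect is present at this scale and the reduction keeps the suite
affordable; the KL comparison uses 30000-step evoked/spontaneous
recordings with 16 subsampled units rather than the full 750000 steps, a
proportional scale-down with the same add-one prior.

Because every input is synthetic and symbolic, passing tests demonstrate
the internal consistency of the dynamics, plasticity and analyses and the
reproduction of the qualitative phenomena (variability quenching,
spontaneous/evoked alignment, prior learning, sampling-like decision
curves) — they say nothing about fits to any particular biological
dataset.

Known limitations, measured honestly under the standard conditions:

* The first three evoked principal components capture 33–42% of the
  evoked variance in the two-word task at $T_{plastic} = 50000$ depending
  on the realization, with typical values around 34% — insensitive to the
  structural-plasticity and pruning variants and identical for centered,
  uncentered and pooled variance accounting.  The share rises with longer
  self-organization (about 39% at 150000 steps for a realization that
  starts near 34%), approaching the 40–50% range reported for this family
  of models, but typically stays below it at the standard phase length.
* Fano factors sit at or slightly below 1 outside onset transients; the
  model has no slow latent modulators, so values above 1 are not expected.
* The readout-decision curves at extreme priors (0.1, 0.9) occasionally
  saturate — networks that overlearn the frequent word barely ever sample
  the rare one — which inflates realization variance there; all
  realizations are reported, none excluded.
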