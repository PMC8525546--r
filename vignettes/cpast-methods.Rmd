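---
title: "Simulating culturally patterned attention: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating culturally patterned attention: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpast)
```

`cpast` simulates a visual forager under discrete-state active inference and
asks how the statistical structure of decorated artefacts is absorbed into
the forager's generative model — its *culturally patterned attention style*
(C-PAST) — and how that absorbed structure changes performance in a later
categorisation task. This vignette documents the model, every tunable that
matters, the numerical conventions, and the design decisions that were
genuinely open, so that a reader can judge exactly what the simulations do
and do not show.

## The generative process: synthetic vase decorations

The environment is a binary pigment grid (default 30 x 30 = 900 locations,
row-major 0-based indexing) decorated with up to four motif types of
increasing verticality: a horizontal line, an oblique descending below the
line, an oblique ascending above it, and a vertical segment below the lower
obliques. Complexity levels 0-3 are cumulative: level *c* carries motifs
0..*c*. Each motif is a 5-cell stencil tiled four times across its band with
a 2-cell gap; bands are separated by two blank rows. The exact stencil
geometry is a package choice (any layout with the same qualitative
verticality ordering would do); it is parameterised (`band_row`, `seg_len`,
`n_reps`) and fully deterministic, so every stimulus is reproducible by
construction. Grids too small to host a stencil raise an error naming it:
with 5-cell stencils in four stacked bands the default layout needs at least
a 30-row grid around the default band row.

What the generator emulates: graded decoration complexity as *number and
verticality of motif types*, with equal pigment mass per motif so that
complexity is not confounded with pigment density. What it does not emulate:
curved vessel geometry, photographic texture, motif variation within a type,
or natural scenes. Passing tests therefore show that the inference-learning
loop responds to compositional structure of this kind; they say nothing
about real eye-tracking data.

## The agent

The agent's two-level generative model is held in a `hierarchical_model`:

* `A1` (level-1 likelihood) is deterministic and **remapped** after every
  saccade from the 3 x 3 patch around the new gaze position
  (`remap_likelihood()`): the agent only ever represents its immediate
  surroundings. Off-grid patch positions observe no pigment
  deterministically — the simplest contract that preserves nine local states
  everywhere, including edges.
* `A2` (level-2 likelihood) maps each motif to its normalised pigment map
  P(location | motif); it is exact knowledge of the motif layouts. The motif
  state space matches the vase: a complexity-*c* decoration gives a
  (*c*+1)-dimensional motif space. The C-PAST entropy measure sums over the
  motifs of the decoration, so the measure's range grows with the number of
  motifs — that growth is part of what "more complex artefact, more complex
  model" means here. (A fixed four-motif space was considered and rejected:
  its never-evidenced uniform columns dominate the entropy and invert the
  complexity ordering.)
* `B1` is deterministic: a saccade lands where it aims.
* `B2`, the motif-transition matrix, is the only learned object. It is the
  column-normalisation of a Dirichlet count matrix initialised at
  `dirichlet_seed` (default 1) per entry plus a **sticky diagonal**
  (`b2_persistence`, default 2, i.e. 3 pseudo-counts on the diagonal):
  decorations are spatially continuous, so a gaze dwelling on a decoration
  is a priori more likely to stay within a motif between updates than to
  switch. Without this prior the one-step transition prediction flips its
  favoured motif every cycle (a self-amplifying two-cycle oscillation), and
  the learned matrices carry no persistence structure at all.
* `C` holds log-preferences over outcomes, pigment +4 / no-pigment −4
  (softmax-normalised before use). Only the difference matters; ±4 makes a
  background saccade cost about 8 nats of risk, strong but finite.

### Inference and the 4:1 cycle

Each timestep the agent saccades, observes one pigment outcome, and performs
level-1 inference over the remapped patch (exact Bayes with a uniform local
prior — beliefs about local states do not persist across remaps because the
remap redefines the state space). After every fourth timestep the four
(location, outcome) pairs are combined into one level-2 update:
`q2 ∝ [∏ P(outcome | motif)] × (B2 · q2_prev)`, followed by one Dirichlet
update at `learning_rate` (default 1). A 100-timestep episode therefore
performs exactly 25 level-2 updates and grows the count mass by exactly 25 —
a conservation law the test suite asserts.

The motif-conditioned outcome probability of a cell is 1 on the motif's own
cells and a floor `epsilon` (default 1e-3) elsewhere; the floor prevents
zero-evidence dead ends under deterministic likelihoods and sets the scale
of "implausible but not impossible" throughout the package.

### Action selection

Every grid location is a candidate (`saccade_limit` defaults to unlimited; a
Chebyshev radius can be configured). Candidates are scored by the
single-step expected free energy

> G = w_risk · KL[predicted outcome ‖ softmax(C)]
>   + w_ambiguity · E[outcome entropy]
>   − w_novelty · E[Dirichlet information gain on B2]

with unit weights by default. The prediction uses the one-step propagated
belief `B2 · q2`; the novelty term scores the expected KL between the B2
Dirichlet before and after the transition the move would evidence, so
rarely-evidenced transitions attract the gaze.

The action is drawn from the softmax policy posterior
`q(π) ∝ exp(−G / policy_temperature)` (default temperature 0.5);
`temperature = 0` gives hard greedy argmin with uniform tie-breaking. The
softmax is the deliberate default: with a hard argmin, the first
infinitesimal tilt of B2 collapses the entire candidate set onto a single
motif and the agent locks there for the rest of the episode at every
complexity level — no complexity effect of any kind can exist in that
regime. Temperature 0.5 keeps saccades strongly pigment-seeking (background
cells cost ~8 nats, i.e. odds of roughly e^16 per cell against) while
letting comparably attractive motifs compete. Larger temperatures (≥ 1)
wash out the complexity ordering of the gazed-region area; smaller ones
(≤ 0.25) reintroduce lock-in.

## Summary statistics

* **Vertical index**: `(h·n_vert − w·n_horiz) / (h·n_vert + w·n_horiz)`,
  where `h`, `w` are the bounding box of the *visited* cells (a fixed
  display size would make them constants) and saccades are classified by
  dominant displacement, with exact diagonals and zero-moves excluded so
  nothing is double-counted. The denominator's second term uses the
  horizontal count; the variant with the vertical count in both terms — an
  evident transcription slip, since it cannot normalise horizontal-dominant
  paths — is kept behind `denominator = "printed"` for comparison.
* **C-PAST entropy**: per-column Shannon entropy of `B2` in nats
  (0·log 0 = 0), summed over columns. Natural logarithms are used everywhere
  (entropies, preferences, expected free energy).

## The categorisation task

The transfer experiment freezes a learned `B2` and uses it as the prior of a
single-level categorisation model. The five shapes are the four motifs as
5 x 5 masks plus an aversive "+" that is never a correct answer; cues are
cut-outs — the part of a shape mask visible through one of nine occlusion
windows. A cut-out is compatible with every shape showing the same visible
cells through the same window, which makes some cues uniquely identifying
and others genuinely ambiguous (the centre cell alone is consistent with all
shapes). Each trial: one blank-display propagation of the carried belief
through the transferred matrix (the prior), a deterministic
compatibility likelihood with the `epsilon` floor, and an argmax decision
with a fixed −8 log-penalty on "+" so that a real shape is always committed
to; ties break uniformly at random. Beliefs carry across trials — with a
per-trial reset the transferred transitions would be inert.

Two design choices here were genuinely open and deserve scrutiny:

* **Embedding.** The learned (*c*+1)-dimensional block is embedded into the
  five-shape space with the `epsilon` floor on never-experienced *rows*, and
  never-experienced *columns* filled with the agent's marginal next-motif
  expectation. A floor-only column would renormalise to uniform, silently
  handing the least-trained agent a maximally dispersed — i.e. near-optimal —
  prior; the marginal fill instead encodes that an agent trained on few
  motifs keeps expecting the motifs it knows.
* **The cue series.** For any single cue, the expected hit rate is
  1/|compatible set| for *every* prior when the true shape is uniform within
  the compatible set — only temporal structure lets a transferred prior
  matter. The predetermined series therefore follows the decoration's own
  *band-reading grammar*: reading the full vase band by band, each motif is
  encountered in runs of four (its tiled repetitions) before the next band,
  giving self-transition probability 3/4 and the remainder to the band
  successor. Persistence is exactly the structure foraging agents learn
  about the motifs they visited, so categorisation accuracy reflects how
  much of the artefact's grammar the training exposure covered. Independent
  uniform truths (provably no ordering) and radius-based spatial adjacency
  chains (hub-dominated, rewarding low-complexity agents) were examined and
  rejected; `motif_transition_grammar()` remains available for the latter.

## Reproducibility and problem sizes

All stochasticity — softmax action draws and tie-breaks, series generation,
decision ties — flows through R's session RNG seeded once per episode, trial
run or series, so every result is a pure function of (inputs, config, seed),
and the command-level outputs are byte-identical across reruns. The sweep
sizes used by the test suite and the acceptance script are 20 training seeds
per complexity level, 20 series seeds and 100 trials per categorisation run
(1600 runs), which keeps the full comparison around a minute on one CPU
while the orderings of interest are stable across disjoint seed sets.

```{r, eval = FALSE}
rep <- cmd_reproduce(cpast_config(), seeds = 1:20, series_seeds = 1:20,
                     out_dir = tempdir())
rep$summary    # mean ± sd of Vi, C-PAST entropy, hit rate per complexity
rep$verdicts   # the three monotonicity checks
```

## Known limitations

* The agent is greedy (one-step lookahead); multi-step policies might
  produce qualitatively different scanpaths.
* The stencil geometry, preference magnitude, Dirichlet seed, persistence
  prior, policy temperature and EFE weights are not identified by any data;
  they were fixed once, for the reasons given above, and are all exposed in
  the configuration. The complexity orderings reported by `cmd_reproduce()`
  are claims about this calibrated regime, not about all of parameter space.
* Scanpaths are heuristics of attention allocation on a discrete grid; no
  claim is made about fixation durations, saccade kinematics, or fit to
  human eye-tracking recordings.
* The categorisation result depends on the cue series carrying the
  decoration's succession statistics; under structureless cue sequences,
  transferred priors cannot matter in principle (see above), and the
  package makes that regime available for inspection rather than hiding it.
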