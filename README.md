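# cpast

Active-inference simulation of culturally patterned visual attention.

## The problem

Do the decorated artefacts we grow up around shape *how* we look at the
world, and does that acquired way of looking change performance on later
tasks? `cpast` addresses this question in silico for pottery decoration. A
discrete-state active-inference agent forages over synthetic vase
decorations of four graded complexity levels (a horizontal pigment line, to
which obliques below, obliques above, and vertical segments are cumulatively
added). While foraging it learns how the decoration's motifs succeed one
another; the learned motif-transition matrix is its *culturally patterned
attention style* (C-PAST). The package then measures how that attention
style transfers to a cut-out categorisation task.

It is intended for computational cognitive scientists and cognitive
archaeologists who want a small, fully reproducible pipeline linking
artefact complexity, simulated gaze behaviour and downstream task
performance.

## The model

The agent carries a two-level hierarchical generative model over a 30 x 30
(900-location) grid:

* **Level 1** — hidden states are the 9 locations of the 3 x 3 patch around
  the gaze; outcomes are pigment / no-pigment. The likelihood `A1` is
  deterministic and is *remapped* from the environment after every saccade
  (the remapping trick), so the agent never holds a global scene model.
* **Level 2** — hidden states are motifs; `A2` maps each motif *m* to its
  normalised pigment map P(location | m). The column-stochastic transition
  matrix `B2` is the only learned object: after every four level-1 cycles
  one level-2 posterior `q2` is inferred from the four pigment observations
  and the Dirichlet counts are updated with the outer product
  `q2_now ⊗ q2_prev`.
* **Action** — each saccade is scored by the single-step expected free
  energy `G = risk + ambiguity − novelty` (preference KL, expected outcome
  entropy, Dirichlet information gain) and drawn from the softmax policy
  posterior `q(π) ∝ exp(−G / temperature)`.

Two summary statistics phenotype the result of a 100-timestep episode:

* the **vertical index** of the scanpath,
  `Vi = (h·n_vert − w·n_horiz) / (h·n_vert + w·n_horiz)` with `h`, `w` the
  gazed-region bounding box, in [−1, 1];
* the **C-PAST entropy** `H[B2] = −Σ_i Σ_j B2_ij log B2_ij` (nats, summed
  per column), 0 for deterministic transition knowledge, `N·log N` for a
  fully dispersed one.

In the categorisation task the learned `B2` is frozen, embedded into a
five-shape space (the four motifs plus an aversive "+" that is never
correct), and used as the prior over a predetermined series of 100 partially
occluded cut-out cues; performance is the **hit rate**.

## Worked example

```r
library(cpast)

vase <- build_vase(3)           # full-complexity decoration
vase
#> <vase_stimulus> complexity 3, 30 x 30 grid, 80 pigment cells, motifs {0, 1, 2, 3}

ep <- run_episode(vase, cpast_config(), seed = 1)
ep
#> <episode_result> complexity 3, seed 1: 100 saccades (3 vertical, 77 horizontal)
#>   gazed region 15 x 26, Vi = -0.9560, C-PAST entropy = 4.2421 nats

round(ep$learned_B2, 3)
#>       from_m0 from_m1 from_m2 from_m3
#> to_m0    0.48   0.034   0.148    0.16
#> to_m1    0.18   0.895   0.241    0.18
#> to_m2    0.18   0.038   0.463    0.18
#> to_m3    0.16   0.034   0.148    0.48
```

The learned matrix keeps substantial mass on every transition the agent
experienced — its dispersion (4.24 nats of a 5.55-nat maximum) *is* the
complexity-3 attention style. A complexity-0 agent learns a 1 x 1 matrix
(entropy 0) instead. Transferring both to the same cut-out series:

```r
series <- generate_cutout_series(shape_library(), length = 100, seed = 1)
run_experiment2(ep$learned_B2, series, cpast_config(), seed = 1)$hit_rate
#> [1] 0.83
naive <- run_episode(build_vase(0), cpast_config(), seed = 1)
run_experiment2(naive$learned_B2, series, cpast_config(), seed = 1)$hit_rate
#> [1] 0.36
```

The richer attention style more than doubles categorisation accuracy: the
complexity-0 agent keeps predicting the one motif it knows and systematically
misses ambiguous cues, while the complexity-3 agent's dispersed prior keeps
every shape plausible and its learned persistence structure matches how cues
actually succeed one another.

The full comparison (means ± sd of Vi, C-PAST entropy and hit rate over 20
seeds per complexity level, with monotonicity verdicts) is one call:

```r
rep <- cmd_reproduce(cpast_config(), seeds = 1:20, series_seeds = 1:20,
                     out_dir = "out")
```

or from a shell, via the bundled CLI:

```sh
Rscript inst/cli/cpast.R forage --complexity 3 --seed 1 --out out
Rscript inst/cli/cpast.R categorise --b2 out/forage_c3_s1_b2.csv --out out
Rscript inst/cli/cpast.R reproduce --seeds 20 --out out
```

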