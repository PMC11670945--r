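---
title: "Simulating IPD tournaments and profiling their winners"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating IPD tournaments and profiling their winners}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipdsim)
```

## The model

The Iterated Prisoner's Dilemma (IPD) is a repeated two-player game in
which both players simultaneously choose to cooperate (`C`) or defect
(`D`) each turn, remembering all prior interactions. Per-turn payoffs
are `R` for mutual cooperation, `P` for mutual defection, and `T`
(temptation) / `S` (sucker) for unilateral defection, with
`T > R > P > S` and `2R > T + S`. The package defaults to the standard
values `R = 3, P = 1, T = 5, S = 0` (`payoff_matrix()`).

Four tournament mechanics are supported, all round-robin with `k`
repetitions:

* **standard** — every match lasts exactly `n` turns;
* **noisy** — additionally, each player's action is flipped each turn
  with probability `p_n` *before* it is played and recorded;
* **probabilistic ending** — instead of a fixed `n`, each match ends
  after every turn with probability `p_e`, so lengths are geometric
  with mean `1 / p_e`;
* **noisy probabilistic ending** — both `p_n` and `p_e`.

Two modelling conventions deserve emphasis because the verbal
definitions of noise admit more than one reading:

1. **Strategies observe realized (post-noise) actions, including their
   own.** This is the standard noisy-IPD convention, and the only
   reading under which a flipped action affects the shared history both
   players react to. Noise applies uniformly to every turn, including
   the first.
2. **Probabilistic-ending lengths are sampled up-front** from the
   geometric law, independently per match. This is equivalent in
   distribution to stopping round by round and simpler to log. A
   `length_cap` (default 10,000 turns) guards against tiny `p_e`; the
   trial sampler draws `p_e` from `(0, 1]` because a match with
   `p_e = 0` would never end.

## Scoring and the result summary

`run_tournament()` plays every unordered pair once per repetition. A
player's score in one repetition is its mean per-turn payoff averaged
over its `N - 1` matches against distinct opponents; the reported
`median_score` is the median of those per-repetition scores over the
`k` repetitions, and ranks (0 = winner) are assigned by descending
median, ties broken by lexicographic name so rankings are
deterministic. A `rank_by = "mean"` switch ranks by the mean over
repetitions instead.

Self-pairs are played by default (`self_play = TRUE`) and pooled into
the behavioral statistics, but they are *never* counted towards
scores, wins, or ranks; `self_play = FALSE` skips them entirely. The
`wins` column reports mean match wins per repetition; drawn matches
count for neither player.

Behavioral statistics pool raw counts over all matches and
repetitions rather than averaging per-match rates — matches of
geometric length carry unequal numbers of rounds, and pooling preserves
the "rate" semantics: the cooperation rating `C_r` is total cooperative
plays over total plays; `initial_C` the fraction of matches opened with
`C`; the state rates the occupancy of `CC`, `CD`, `DC`, `DD` (focal
action first); and the conditional cooperation rates `s -> C` the
probability of cooperating in the round after joint state `s`. A
conditional rate whose state was never visited with a successor round
is reported missing (`NA`), never 0.

## The strategy catalog

`ipd_catalog()` registers canonical strategies, each with classifier
metadata (stochastic; makes use of the game payoffs; makes use of the
number of turns; memory size). The exact rules implemented:

* **Cooperator / Defector** — unconditionally `C` / `D`.
* **Alternator** — `C` first, then the opposite of its own previous
  (realized) action.
* **Random** — `C` with probability 1/2 every turn.
* **Tit For Tat (TFT)** — `C` first, then the opponent's previous
  action.
* **Suspicious Tit For Tat** — `D` first, then TFT.
* **Tit For 2 Tats** — defects only after two consecutive opponent
  defections.
* **Two Tits For Tat** — defects if the opponent defected in either of
  the last two rounds.
* **Generous Tit For Tat** — TFT, but after an opponent defection it
  still cooperates with probability
  `g = min(1 - (T - R)/(R - S), (R - P)/(T - P))`, the standard
  generosity level; `g = 1/3` at the default payoffs.
* **Grudger** — cooperates until the opponent's first defection, then
  defects forever.
* **Spiteful Tit For Tat** — TFT until the opponent defects twice
  consecutively, then defects forever.
* **Fool Me Once** — forgives a single defection; defects forever once
  the opponent has defected twice in total.
* **Win-Stay Lose-Shift (Pavlov)** — `C` first; cooperates exactly when
  both players played the same action last round.
* **Gradual** — punishes the opponent's *k*-th defection with *k*
  consecutive defections, then enters a calming state of two
  cooperations. The literature contains variants of the punishment
  counter; here the count is the opponent's total defections at the
  moment punishment begins, and defections during punishment or calming
  enlarge only the *next* punishment.
* **Adaptive Tit For Tat** — keeps an exponentially smoothed estimate
  `w` of the opponent's cooperation (`w <- (1 - theta) w + theta
  1[opponent played C]`, `w` starting at 1/2) and cooperates while
  `w >= 1/2`. `theta = 0.5` by default, configurable; the first move is
  `C`.
* **Omega TFT** — TFT plus deadlock breaking: after `deadlock`
  (default 3) successive disagreement rounds it cooperates to break a
  `CD`/`DC` cycle; an opponent-randomness score (incremented when the
  opponent's action changes and when the players disagree) reaching
  `randomness` (default 8) switches it to permanent defection. The
  strategy is named without parameters in the literature; both
  thresholds are configurable.
* **Prober** — opens `D, C, C`; if the opponent cooperated on turns 2
  and 3 it defects forever, otherwise it plays TFT.
* **BackStabber** — forgives the first three opponent defections and
  defects forever on the fourth; when the number of turns is known it
  also unconditionally defects in the last two rounds
  (`makes_use_of_length = TRUE`).
* **ZD-Extort-2 / ZD-GTFT-2** — memory-one strategies with cooperation
  vectors `(8/9, 1/2, 1/3, 0)` and `(1, 1/8, 1, 1/4)`.
* **Meta Majority / Meta Winner** — ensembles over a team (default:
  TFT, Pavlov, Grudger, Cooperator, Defector) that play the majority
  proposal (ties towards `C`) or the proposal of the member whose
  hypothetical cumulative payoff against the opponent's realized
  actions is highest (earliest member on ties).

Named trained strategies from the literature (evolved automata, neural
networks, particle-swarm lookups, and similar) are *not* re-implemented:
their exact weights are not published in citable form here. Instead the
generic families — `memory_one_strategy()`, `fsm_strategy()`,
`lookup_strategy()`, `meta_majority()`, `meta_winner()` — provide the
machinery to express such rules, and `read_strategy_config()` loads
them from a validated YAML schema (see
`inst/extdata/example-strategies.yaml`).

Stochastic strategies draw through the match RNG stream, so a seeded
match — and hence a seeded tournament or campaign — is fully
reproducible. Child seeds derive deterministically from the master seed
and the (repetition, pair) indices, making results independent of
execution order.

## Features

For every (trial, tournament type, strategy) the package derives the
feature record used in the statistical layer (`summary_features()`,
`trial_features()`):

* **Normalized rank** `r = R / (N - 1)`: 0 is the winner, 1 last
  place, comparable across tournament sizes. Overall performance of a
  strategy is the median of `r` across the tournaments it entered.
* **Cooperation aggregates** `C_max`, `C_min`, `C_mean`, `C_median`
  over the tournament's cooperation ratings, and each strategy's ratios
  `C_r / C_max`, `C_min / C_r`, `C_r / C_median`, `C_r / C_mean`. A
  ratio with a zero denominator is missing, never infinite.
* **Memory usage** `min(memory_size / n, 1)`, with infinite-memory
  strategies at 1; undefined for probabilistic-ending tournaments,
  where `n` is not a meaningful quantity.
* **SSE to the zero-determinant family** (below).

### The SSE measure

Zero-determinant (ZD) strategies are memory-one strategies that enforce
a linear relation between the players' long-run payoffs; the
extortionate ones guarantee themselves at least a `chi`-multiple of the
opponent's surplus over the punishment payoff. Writing a memory-one
cooperation vector `p = (p_CC, p_CD, p_DC, p_DD)` in tilde coordinates
`p~ = (p_CC - 1, p_CD - 1, p_DC, p_DD)`, the extortionate family is

```
p~ = phi * ( (S_x - P) - chi * (S_y - P) ),
```

with `S_x = (R, S, T, P)` and `S_y = (R, T, S, P)` the two players'
stage payoffs over the states `CC, CD, DC, DD`. `sse_to_zd()` solves
the two-parameter least-squares projection of an observed `p~` onto
`a * u - b * v` (with `u = S_x - P`, `v = S_y - P`, `a = phi`,
`b = phi * chi`) and reports the residual sum of squared errors: 0
means the observed behavior is exactly ZD. Tit For Tat's vector
`(1, 0, 1, 0)` lies in the family (`a = b = 0.2` at default payoffs);
an unconditional cooperator is far from it (SSE > 1).

Numerical choices:

* The fit is constrained to the cone `a, b >= 0` — the extortionate
  side of the family — via an exact active-set solve of the 2x2 normal
  equations; degenerate inputs land on the cone boundary rather than
  erroring. `constrained = FALSE` exposes the unconstrained solution.
* The tabulated range of the measure is `[0, 1]`, but the raw residual
  is not intrinsically bounded by 1; the fit therefore reports the raw
  residual (`sse`) plus a clipped variant (`sse_clipped = min(sse, 1)`).
  All package analyses use the raw value, which agrees at 0 for exact
  ZD behavior.
* The `p` fed to the fit is the strategy's pooled conditional
  cooperation vector — its observed memory-one shadow. States never
  visited carry no information; their rates are imputed at the neutral
  value 0.5 and the row is flagged `sse_imputed`.

The test suite checks the analytic fit against an exhaustive
grid-search oracle over `(a, b)` and verifies parameter recovery
(`phi`, `chi`) on exactly constructed family members.

## Randomized trials and campaigns

`sample_trial()` draws one trial configuration — a tournament size `N`,
`N` distinct strategies, `k`, `n`, `p_n`, `p_e`, each uniform over its
range — and `run_trial()` executes the four tournament types on the
same players with the same `k`. The full-study ranges
(`trial_ranges()`: `N` in `[3, 195]` clipped to the catalog size, `k`
in `[10, 100]`, `n` in `[1, 200]`, `p_n` in `[0, 1]`, `p_e` in
`(0, 1]`) are the defaults for the sampler; `run_campaign()` defaults
to the desk-scale profile `desk_ranges()` (`N` in `[3, 8]`, `k` in
`[2, 4]`, `n` in `[5, 40]`, `p_e` in `(0.1, 1]`), which keeps an
interactive smoke run in the seconds range while exercising every code
path. Campaigns stream `trials.csv` and `features.csv` to disk, record
completed trials in a manifest, and can resume after interruption with
results identical to an uninterrupted run.

High-noise tournaments are hard to interpret — with `p_n` near 1 most
realized actions are the opposite of what the strategy chose — so
analyses typically restrict to `p_n <= 0.1` and `p_e <= 0.1`; under
uniform sampling about 10% of trials satisfy each restriction, which
the acceptance suite verifies at the 11,400-trial scale (sampling
only; no tournaments are run at that scale here).

## The statistical layer

* `correlate_features()` reports Spearman rank correlations of each
  feature with the normalized rank and the median score, per tournament
  type. Ties receive average ranks (the standard convention) and
  missing values are pairwise-deleted; a feature that is constant or
  undefined for a type yields no row.
* `fit_rank_regression()` fits, per type, an ordinary least-squares
  model of `r` (or the median score) on that type's feature list with
  an intercept. The default per-type lists keep a common core
  (conditional cooperation rates, SSE, cooperation aggregates and
  ratios, `k`) and add only the parameters defined for the type: `n`
  and memory usage where the length is fixed, `p_n` where there is
  noise, `p_e` where the ending is probabilistic. Highly collinear
  ratio features (`C_r`, `C_r / C_max`) are left out of the default
  design; a rank-deficient design is an error naming the collinear
  columns rather than a silently dropped coefficient.
* `winner_profiles()` filters the rank-0 rows and summarizes the
  distributions of the winner's `C_r`, `C_r / C_mean`, SSE, and four
  conditional cooperation rates per type; `autoplot()` draws the
  histograms.

## The synthetic feature generator

`generate_feature_table()` realizes feature tables with the campaign
schema but *known* structure, so the statistical layer can be validated
without running tournaments: rate-type features are drawn from a
Beta(2, 2) marginal (interior-concentrated, which keeps ratio
denominators away from 0), tournament aggregates and ratio features are
recomputed from the generated cooperation ratings so every block is
internally consistent, and the normalized rank follows the planted
linear model `r = clip(intercept + sum(beta_i x_i) + eps, 0, 1)` with
Gaussian noise. Integer ranks are assigned in the order of `r` within
each block.

Two caveats. The clipping to `[0, 1]` is a mild misspecification of
the linear model; the default intercept, coefficients, and `sigma`
keep the linear predictor well inside the interval so that fewer than
1% of rows clip, and the recovery tests hold at ordinary
least-squares accuracy. And the generator makes no attempt to emulate
the dependence structure of real tournaments — rows within a block are
exchangeable apart from the shared aggregates, whereas real strategies
in one tournament interact. Passing recovery tests therefore validates
the *analysis code*, not any claim about real tournament data.

## Problem sizes and limitations

The shipped tests run tournaments of 3–8 strategies with up to a few
repetitions and matches of tens of turns, 10,000-draw distributional
checks, a 100-vector grid-oracle comparison for the SSE fit, a
100-replication coverage simulation for the regression, and an
11,400-draw sampler check — sizes chosen so the whole suite completes
in about two minutes on one core while still exercising every
contract. Campaigns at the full study scale (hundreds of strategies,
tens of thousands of tournaments) use exactly the same code paths via
`trial_ranges()` and a larger `n_trials`; only wall-clock time
separates the two.

The catalog is a representative, fully specified subset of the
published strategy space; conclusions about *which* strategy wins in a
given environment depend on the opponent pool and do not transfer from
a 22-strategy catalog to larger corpora. The package's purpose is the
mechanics: a reproducible engine, summary, feature, and analysis
pipeline into which any further strategies — including user-supplied
rule tables for published trained strategies — can be dropped.
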