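---
title: "Adaptive puzzle-game training: models, simulator and analysis choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive puzzle-game training: models, simulator and analysis choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(puzzletrain)
```

puzzletrain is a desk-scale re-creation of a tablet-based cognitive-training
system: two casual puzzle games (match-3 and numberlink) whose difficulty is
adjusted between days by a data-driven service, plus the performance metrics
and small-trial statistics used to evaluate such an intervention. Human
participants are replaced by synthetic players, so the whole loop — board
generation, play, time prediction, level decisions, metrics, analysis — runs
end to end in code. This vignette explains the models, the defaults and why
they are what they are, and what the simulation can and cannot show.

## The difficulty model

Both games are parameterized by a square board size $s \in [4, 8]$ and a
number of unique game objects $g \in [4, 8]$ (gem types in match-3, colored
endpoint pairs in numberlink). The 25 $(s, g)$ combinations are arranged on a
single **difficulty ladder** ordered lexicographically by $(s, g)$:

$$\mathrm{index} = 5(s - 4) + (g - 4) + 1 .$$

Board growth dominates perceived difficulty — a $5\times5$ board with 4
objects is harder than a $4\times4$ with 8 — and this order matches the usual
introductory progression ($4\times4$, then $5\times5$, then $6\times6$), so
all object counts at one size precede the next size.

## The adaptation rule

After a solved level the service receives the measured solving time $t_m$ and
compares it with a predicted time $t_p$ for that level. The **level
predictor** is the piecewise rule

$$
f(t_m, t_p) =
\begin{cases}
-1 & t_m > t_p + c\,\sigma \\
+1 & t_m < t_p - c\,\sigma \\
\;\;0 & \text{otherwise,}
\end{cases}
$$

with $-1$ = retreat one level, $+1$ = advance one level. $c \in (0, 1)$ is a
dimensionless band constant and $\sigma$ is the standard deviation of the
solving times of all games played at that difficulty level in the data set.
The inequalities are strict: a time exactly on a band edge stays. Two
properties follow directly and are enforced by tests: the rule is symmetric
around $t_p$, and widening the band (larger $c$) never converts a "stay" into
a move.

Decisions move the level index by one step, clamped at both ladder ends.

**Defaults and their rationale.**

| Parameter | Default | Units | Why |
|---|---|---|---|
| `c` | 0.5 | — | The rule only constrains $c$ to $(0,1)$; the midpoint gives a band of one SD total width. |
| `sigma_floor` | 2 | s | Lower bound for the fallback band width. |
| `min_attempts_for_sigma` | 3 | attempts | Below this, the sample SD at a level is too unstable to trust. |
| per-game cap | 600 | s/day | Ten minutes per game per day. |
| daily cap | 1200 | s/day | Twenty minutes of training per day. |
| schedule | 8 weeks × 3 sessions | — | The intervention phase length and minimum weekly frequency. |

**$\sigma$ fallback.** With fewer than 3 attempts at a level,
$\sigma = \max(2\,\mathrm{s},\, 0.2\,t_p)$. A freshly reached level would
otherwise have $\sigma = 0$ (or `NA`) and a zero-width band, making the
trajectory thrash on every attempt. $\sigma$ is pooled per game per level
across participants — the most literal reading of "all the games played on
the given difficulty level in the data set".

**Unsolved levels.** The decision rule is defined for solved levels. A level
that hits the 600 s per-game cap is recorded with $t_m = 600$ s and a forced
$-1$; an attempt cut short merely because the day's remaining budget ran out
is logged as a timeout event with no decision at all, since the player did
not fail the level.

## The time predictor

$t_p$ comes from a regressor fitted on pooled attempt records with the
feature set (board size, object count, ladder index, session index,
participant's running mean time). Three candidate families are fitted —
ordinary least squares, a k-nearest-mean regressor ($k = 5$, standardized
features), and an equal-weight committee of the two (a voting-regressor
analogue) — and the candidate with the highest **adjusted $R^2$ on the
training data**,

$$\bar R^2 = 1 - (1 - R^2)\frac{n - 1}{n - p - 1},$$

is selected ($p = 5$ features for every candidate; ties keep the earlier
candidate, with the linear family listed first). On noiseless data linear in
the level index the linear candidate attains $\bar R^2 = 1$ exactly and is
always selected, which the tests exploit as an oracle.

Predictions are clamped below at 1 s, and a level outside the fitted range
raises an extrapolation warning. Refitting happens *nightly* (after each
simulated session), matching a service that updates the next day's level from
the previous day's play; each refit uses the most recent 600 attempts per
game, which bounds the $O(n^2)$ k-nearest-mean training pass while keeping
months of play in view.

Before any model exists the service uses a bootstrap predictor: the pooled
mean time at the level once three observations exist, otherwise the baseline
curve $20 + 15\,(\mathrm{index} - 1)$ s.

One consequence of the running-mean feature is deliberate and worth knowing:
it partially *personalizes* $t_p$, so a uniformly fast player is not pushed
upward indefinitely — at equilibrium their band centers on their own pace,
and further ascent comes from practice gains and from fitting more attempts
into the capped sessions. Skill ordering is therefore recovered in rank (the
closed-loop test checks exactly that), not as a deterministic mapping from
skill to final level.

## Initial placement

The starting level uses the pretest variables MoCA (global cognition, 0–30),
TMT-A (selective attention, seconds) and SMT (visuoconstructive maze,
seconds). The composite is the mean of the standardized triplet
$(-\mathrm{TMT\!-\!A}, -\mathrm{SMT}, \mathrm{MoCA})$ against a reference
population (the embedded 12-participant table by default); the composite's
empirical quantile maps to the lowest index of the corresponding ladder
quintile (indices 1, 6, 11, 16, 21). Better pretests therefore start weakly
higher, the best start at level 21, and placement is monotone in the
composite — the property the tests check. The mapping itself (which
variables, how combined) is a package choice: only the variables are given by
the instrument set, not their weighting. TMT-B is carried in the records but
not used in the composite, as it duplicates TMT-A's attention signal with
much heavier tails.

## The puzzle engines

**Match-3.** Boards are integer matrices of gem codes with 1-based (row,
col) coordinates, row 1 at the top, gravity toward higher rows. Generation
fills cells row-major, resampling any code that would complete a run of three
with its two left or two upper neighbours, then requires at least one valid
swap (whole-board resample otherwise, capped at 1000 tries — for $g \ge 4$
rejection is rare). Matches are maximal runs $\ge 3$; runs longer than three
are one descriptor; a cell in both a row and a column run is reported in
both and cleared once. Cascades repeat remove → gravity → refill until
quiescent, with refill drawn uniformly from the gem alphabet under the
caller's seed, so replays are bit-identical. A match-3 *level* is defined as
clearing a quota of $10g$ gems — the tablet's completion rule is not
documented, and a quota scaling with the alphabet keeps level durations
comparable across the ladder.

**Numberlink.** A puzzle is solved by joining each colored endpoint pair
with orthogonal paths that are cell-disjoint and jointly cover every cell.
The generator draws a random Hamiltonian path (serpentine start, randomized
by backbite moves) and cuts it into exactly $g$ segments; segment termini
become the endpoint pairs and the segments are the witness solution. This
construction guarantees a full-fill solvable puzzle with the exact pair count
on every draw, with no rejection loop. Minimum segment length is 3 cells,
relaxed to 2 when $s^2 < 3g$ (a $4\times4$ board cannot hold 7–8 pairs of 3
cells). Solution uniqueness is *not* enforced — uniqueness testing is NP-hard
in general — but `count_solutions()` provides exhaustive counting for small
test boards. The solver is depth-first with a fixed neighbour order and three
sound pruning rules (current target reachable through free cells; pending
pairs mutually reachable; no orphan free region), returns a distinguishable
"unknown" when its node budget is exhausted, and its output always validates.

## The synthetic players

A player is (skill, learning rate, noise SD, seed) and solves a level in

$$t_m = \big(20 + 15\,(\mathrm{index} - 1)\big)\cdot \mathrm{skill}\cdot
(1 - \mathrm{lr})^{\,\mathrm{session} - 1}\cdot e^{\varepsilon},
\qquad \varepsilon \sim N(0, \mathrm{noise\_sd}^2).$$

Multiplicative lognormal noise and an exponential practice curve are the
standard response-time choices: times are positive and right-skewed, and
practice gains are proportional. Population priors are skill
$\sim \mathrm{LogNormal}(0, 0.25)$, learning rate $\sim U(0, 0.04)$, noise SD
$\sim U(0.1, 0.3)$ — a factor-of-two spread in speed, up to 4% per-session
gains, and 10–30% time variability, plausible for healthy adults on casual
puzzles. Both games share a player's profile.

What the simulator emulates: times growing with difficulty, shrinking with
practice, varying lognormally within and across players; schedule caps; and
the full request loop against the service. What it does not: fatigue within
a session, day-to-day mood, dropout and adherence, game-specific strategies,
or any cognitive mechanism (attention, working memory) behind the times.
Passing closed-loop tests therefore show that the *adaptation machinery*
behaves as designed under realistic time statistics — not that the
intervention would produce the human outcomes, which are outside what any
simulation of this kind can establish.

## Trial analysis

The 12-participant characteristics table and the IMI / NASA-TLX subscale
tables ship as CSV fixtures with column checksums. Summaries are mean and
sample SD ($n-1$; the printed SDs of the source tables match the sample
convention), rounded half-up to two decimals only at the report layer. The
statistics mirror a small crossover analysis: Shapiro-Wilk normality, paired
$t$, one-way within-subject ANOVA ($F = MS_\mathrm{wave}/MS_\mathrm{error}$,
$df = (k-1),\,(k-1)(n-1)$; no sphericity correction by default at $n = 12$,
Greenhouse-Geisser behind a flag), and Pearson correlation. The
within-subject $F$ and the improvement slope are computed from closed-form
sums of squares in the package and cross-checked in the tests against
`aov()`/`lm()`; the classical tests wrap their `stats` implementations and
are cross-checked against transliterated references (AS R94 for
Shapiro-Wilk).

Metrics follow fixed conventions: the improvement slope is the OLS slope of
per-session time against the session index (robust to irregular play days),
negative = improvement; match-3 "target search time" is level duration per
match made; items are gems cleared (match-3, via the quota) or path cells
(numberlink, $s^2$ by the full-fill rule). Note that under *successful*
adaptation the at-level search-time slope is expectedly near zero — the
service raises difficulty precisely to keep times in band — so progress shows
up in the level trajectory rather than in raw times.

## Problem sizes and determinism

Every randomized operation is a pure function of its inputs and a seed;
nested simulations derive child seeds from a master seed, so logs, CSVs and
boards are byte-reproducible. The shipped checks use 100 generated boards
per game across the size bands, 50 solver round-trips at $5\times5$, 1000
random decision-rule cases, 12 training players and 20 evaluation players
over 24 sessions — sizes chosen to exercise every band of the ladder while
keeping a full run of the suite and the acceptance script in the minutes
range on a laptop.

## Known limitations

- The closed loop's skill-to-final-level rank correlation is positive by
  construction but, at 20 players, its significance varies with the master
  seed (the running-mean feature absorbs part of the skill signal).
- Generated numberlink puzzles need not have unique solutions, and path
  aesthetics (no lateral self-touch) are not enforced.
- The match-3 level-completion quota and the initial-placement mapping are
  package choices where the original system's rules are undocumented.
- Mid- and post-wave human outcomes cannot be recomputed from the shipped
  tables; only the pretest summaries and the questionnaire orderings are
  reproducible, and the package makes no claim about human efficacy.
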