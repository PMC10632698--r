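# puzzletrain

An R toolkit for **adaptive puzzle-game cognitive training** at desk scale.
It re-creates, in code, a tablet-based training system for healthy adults and
older people: two casual puzzle games whose difficulty adapts between days to
the player's measured performance, together with the metrics and small-trial
statistics used to evaluate such an intervention. Human participants are
replaced by a synthetic-player simulator, so the entire loop — board
generation, play, solving-time prediction, level decisions, session logs,
analysis — runs end to end without any external data.

It is aimed at researchers prototyping dynamic difficulty adjustment (DDA)
for cognitive interventions, and at anyone who needs reproducible puzzle
generators and a transparent reference implementation of the adaptation rule.

## The model in brief

Difficulty is a 25-level ladder over board size `s ∈ [4,8]` and object count
`g ∈ [4,8]` (`index = 5(s−4) + (g−4) + 1`). After each solved level the
service compares the measured solving time `t_m` with a model-predicted time
`t_p`:

```
f(t_m, t_p) = −1  if t_m > t_p + c·σ     (retreat one level)
              +1  if t_m < t_p − c·σ     (advance one level)
               0  otherwise              (stay)
```

where `c ∈ (0,1)` (default 0.5) and `σ` is the SD of all games played at
that level in the data set. `t_p` comes from the best of several candidate
regressors — selected by **adjusted R² on the training data**,
`1 − (1−R²)(n−1)/(n−p−1)` — over the features (board size, object count,
level index, session index, participant's running mean time). Initial
placement maps a pretest composite (MoCA, TMT-A, SMT) to a ladder quintile.

The two engines: **match-3** (swap adjacent gems to align ≥3, with full
remove/gravity/refill cascades) and **numberlink** (join colored endpoint
pairs with cell-disjoint paths covering every cell; generated puzzles carry a
full-fill witness solution by construction, and a pruned backtracking solver
verifies them).

## Worked example

```r
library(puzzletrain)

# a playable 4x4 match-3 board (matchless, at least one valid swap)
generate_board(difficulty_level(4, 4, index = 1), seed = 1)
#> <gem_grid> 4x4, 4 gem types
#> 1 4 3 1
#> 2 1 3 3
#> 2 2 1 3
#> 1 1 2 2

# a 5x5 numberlink puzzle with 5 pairs (letters are endpoints)
cat(format_puzzle(generate_puzzle(difficulty_level(5, 5, index = 7), seed = 3)$puzzle))
#> . . B . .
#> B A C . C
#> A . . . D
#> . . D E .
#> . . E . .

# the level decision: 41 s against a 50 s prediction, sigma 8 s, c = 0.5
decide_next_level(t_m = 41, t_p = 50, sigma = 8, c = 0.5)
#> [1] 1        # 41 < 50 - 4: advance one level

# initial placement from pretest scores (median-ish profile -> mid ladder)
srv <- adaptive_service()
put_initial_level(srv, "numberlink", "P01",
                  pretest_scores(moca = 28, tmt_a = 30, tmt_b = 70, smt = 15))
#> $level_index
#> [1] 11

# pretest summary cells recomputed from the embedded participant table
pretest_summary()[, c("measure", "mean_2dp", "sd_2dp")]
#>   measure mean_2dp sd_2dp
#> 1     age    58.92  10.28
#> 2    moca    27.58   2.07
#> 3   tmt_a    32.25  10.96
#> 4   tmt_b    91.83  63.43
#> 5     smt    19.17   8.59
```

The decision `1` means the player solved the level more than `c·σ` faster
than predicted, so the next day's puzzle moves one ladder step up. The
summary block reproduces the published pretest cells of the embedded
12-participant table (the MoCA SD prints as 2.07 here; the source table's
2.06 is a truncation of 2.0652).

A full simulated intervention (12 players, 8 weeks × 3 sessions, both games,
nightly model refits) with session logs, per-participant metrics and level
trajectories:

```r
res <- cli_simulate(run_config(n_players = 12, seed = 1, out_dir = "out"))
head(res$trajectories)   # level index per participant/game/session
```

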