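---
title: "Module-bank planning over navigation maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Module-bank planning over navigation maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(navbank)
```

## The model

navbank simulates the planning subsystem of a brain-inspired cognitive
architecture built around *navigation maps*: small 3-D grids of cells (by
default 6×6×1, a functional model of a neocortical minicolumn's
representation) whose cells hold sensory features, links to other maps, and
operational *tags*. Planning proceeds in three stages:

1. **Tagging.** A scene is mapped into the Module A navigation map; an
   instruction such as "go to all objects and go back" triggers the
   `goto()` primitive, which places an `<all>` marker on every destination
   cell and a `<back>` marker on the start cell.
2. **Replication.** The tagged map is broadcast to a bank of B duplicated
   Navigation Module B slots. Slot n = 0 is reserved (it keeps a copy of
   the instruction and, during planning, the running-minimum TempMap);
   slot n = 1 plans deterministically; slots n = 2..B−1 plan with
   randomness injected.
3. **Selection.** Each slot builds a closed tour over the tagged cells by
   the `small_plan()` primitive; the slot with the smallest total distance
   wins (ties to the lowest n) and its tour is emitted as a `move()`
   sequence: destinations re-tagged `<1>, <2>, ...`, the start `<0>`.

`small_plan()` is randomized nearest-neighbour construction. At every
decision point the remaining destinations are sorted by distance from the
current location (ties to the lower location index) and one is drawn from
a probability rule; the destination list is rebuilt and the probabilities
renormalized after every visit. Two rules are provided:

* **Position-weighted** (the architecture's default): the rank-x candidate
  of m has probability
  $p_x = \dfrac{(m - x + 1)^{w}}{\sum_{j=1}^{m} (m - j + 1)^{w}}$,
  independent of the distance magnitudes. With m = 5 and the default
  weight w = 4 this is [64, 26, 8, 2, 0.1]%. Any $w \ge 10$ collapses the
  rule to deterministic nearest-neighbour, which is how the deterministic
  slot is expressed internally ($w = 30$).
* **Value-weighted** (the comparison rule): candidate weights are the
  reciprocals of each distance's excess over the minimum, floored at 1,
  then normalized. Distances [12, 13, 44] give [49, 49, 2]%; [12, 42, 44]
  give [94, 3.1, 2.9]%.

Selection is roulette-wheel: the first rank whose cumulative probability
exceeds a uniform draw in [0, 1).

Planning treats distance entries as unitless magnitudes; a
`distance_table` is a symmetric matrix with zero diagonal, validated at
construction, and the `units` field is annotation only.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `weight` | 4 | randomness sharpness of the position rule; 1–2 near-uniform, ≥ 10 deterministic |
| `B` | 1024 | bank size; usable modules are B − 2 randomized + 1 deterministic (n = 0 reserved) |
| `runs` | 100 | independent episodes per experiment variant |
| `K` | 1024 | TempMap slots per module; only the reserved slot's running minimum is used |

The bank sizes follow the 1K/4K/16K convention (1024/4096/16384 slots,
n = 0 reserved). The weight default of 4 sits in the mid-range a weight
sweep identifies as best: weights 1–2 are too random to respect local
structure, weights above 9 remove the exploration that lets some module
beat plain nearest-neighbour.

## The worked example

```{r toy}
ts <- toy_scene()
bank <- load_instruction("go to all objects and go back",
                         module_bank(ts$map, B = 1024))
pg <- parse_goto(bank)
pg$location_count
bank <- broadcast(pg$bank)
set.seed(1)
br <- run_bank(bank, ts$distances)
br$best_plan$total_distance
table(br$per_module_totals)
```

The deterministic slot follows 25 + 22 + 20 + 42 = 109 cm; the only other
tour classes are 100 cm and 119 cm, and with a thousand randomized modules
the 100 cm optimum is found essentially always. `brute_force_shortest()`
(Held-Karp dynamic programming, exact to 16 locations) confirms 100 cm.

## The 13-city study

The 13-city mileage table (`cities13()`, from the Google OR-Tools routing
examples) has exact optimum 7,293 and nearest-neighbour total 8,131 from
the home city. `run_experiment()` repeats best-of-bank episodes and
summarizes them against the oracle:

```{r study, eval = FALSE}
dt <- cities13()
run_experiment(experiment_config("bank-position", bank_size = 1024,
                                 runs = 100, master_seed = 102), dt)
```

The package's full replication (100 runs per variant, run in the test
suite at bank sizes up to 16,384) yields, on this table: single randomized
module mean ≈ 10,550; 1K bank ≈ 7,490 (sd ≈ 150); 4K ≈ 7,335; 16K ≈
7,297 (sd ≈ 7) with ~45% of runs exactly optimal; value-weighted 1K
≈ 7,536. Bank size improves results monotonically and the Welch one-tailed
tests for bank-vs-single and 4K-vs-1K are significant far below 0.001.
These match the published account of this architecture qualitatively in
every direction; several means differ from the published ones by more
than sampling error, however, and the published fraction-optimal sequence
(1%, 27%, 67% for 1K/4K/16K) is not attainable by any scheme in which
modules draw independently from the printed probability rule: 27% at 4K
implies about 7.5% at 1K, not 1%. We therefore treat the printed
per-variant distributions as approximate and keep the implementation
exactly as the formulas and worked examples specify.

## Numerical and design choices

* **Determinism.** Destination sorting and best-module selection break
  ties toward the lower index, making the deterministic branch fully
  reproducible (the constant 8,131 requires this).
* **Randomness.** All draws come from R's seeded RNG. Per experiment run a
  child seed is drawn from the master-seeded stream; within a run the
  randomized modules consume one pre-generated uniform per destination
  decision, laid out one row per module. The compiled kernel is a pure
  function of the distance table and the draw matrix, and the test suite
  asserts exact agreement between the kernel and the pure-R constructor on
  shared draws.
* **Arithmetic.** Position weights are computed in doubles; the largest
  exponentials actually evaluated are $12^{9}$ (exact in a double), since
  weights of 10 or more short-circuit to the deterministic rule before any
  large power is formed.
* **Parallelism.** The bank's parallel modules are simulated sequentially
  within a run. For scene planning (`run_bank()`) the per-slot map copies
  are materialized; the experiment harness works directly on the shared
  distance table, where thousands of identical map copies would add
  nothing.
* **TempMap persistence.** TempMap contents are cleared per planning
  episode; only the reserved slot's running minimum is carried within an
  episode.
* **`<back>` semantics.** The `<back>`-tagged start is the forced final
  leg, never an ordinary destination, matching the `<0>` tag semantics of
  the move sequence.
* **Single destinations.** With one tagged destination the bank is
  bypassed and a direct out-and-back move is emitted.

## What the fixture generator does and does not emulate

`random_distance_table()` produces seeded symmetric integer matrices
(optionally metric-repaired by shortest-path closure), and the test
helpers build random grid scenes from them. These emulate the *outcome* of
the architecture's perception stage — a tagged map plus a distance
relation — not its mechanisms: no sensory feature binding, no fuzzy
instruction matching, no map linking. Passing tests therefore demonstrate
the planning subsystem's behaviour on well-formed symmetric inputs; they
say nothing about robustness to perceptual noise, asymmetric travel costs
(explicitly unsupported), or instances large enough that the exact oracle
(≤ 16 locations) cannot certify optimality.

## Known limitations

* Tour construction only; no 2-opt or other improvement heuristics.
* Instructions are matched by exact lowercase tokens; only the `go`
  action word (with `all`/`back` and named-feature destinations) is
  implemented.
* Distances must be symmetric with zero tolerance.
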