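# navbank

Planning with a bank of duplicated navigation modules.

`navbank` simulates the planning subsystem of a brain-inspired cognitive
architecture for researchers studying how simple innate procedures,
massively duplicated, yield capable behaviour. A sensory scene is mapped
onto a *navigation map* — a small grid of cells carrying object features
and operational tags. An instruction such as `"go to all objects and go
back"` triggers the `goto()` primitive, which tags every destination cell
`<all>` and the start cell `<back>`. The tagged map is then broadcast to a
bank of B duplicated planning modules (slot n = 0 reserved for the
instruction copy, slot n = 1 deterministic, slots n ≥ 2 randomized); each
module builds a closed tour with the `small_plan()` primitive and the
shortest tour across the bank is executed as a `move()` sequence.

`small_plan()` is randomized nearest-neighbour construction: at each
decision point the m remaining destinations are sorted by distance and the
rank-x candidate is selected with probability

    p_x = (m - x + 1)^w / Σ_j (m - j + 1)^w        (position-weighted)

with weight w = 4 by default; any w ≥ 10 collapses to plain deterministic
nearest-neighbour. An alternative *value-weighted* rule uses normalized
reciprocals of each distance's excess over the minimum. Best-of-bank
selection makes the architecture a multi-restart stochastic greedy tour
builder, and the package includes the exact Held-Karp oracle and a Monte
Carlo harness (with Welch one-tailed t-tests) for the comparative study of
bank sizes and weighting rules on symmetric distance tables.

## Worked example

The built-in three-object scene: start at (0,0,0), white sphere (2,2,0),
black sphere (3,0,0), white block (4,2,0), distances in cm.

```r
library(navbank)
ts <- toy_scene()
bank <- load_instruction("go to all objects and go back",
                         module_bank(ts$map, B = 1024))
pg <- parse_goto(bank)     # tags 3 <all> cells and the <back> start
bank <- broadcast(pg$bank)
set.seed(1)
br <- run_bank(bank, ts$distances)
br
#> <bank_result: best module n = 5, total 100 over 1023 modules>
move_sequence(br$best_plan)
#>      id tag
#> 1 3,0,0   1
#> 2 4,2,0   2
#> 3 2,2,0   3
#> 4 0,0,0   0
```

The deterministic slot n = 1 follows pure nearest-neighbour for a
25 + 22 + 20 + 42 = 109 cm tour; a randomized module finds the 100 cm
optimum (here in the black-sphere-first direction) and wins the bank.
The move sequence visits the `<1>`, `<2>`, `<3>` tags in order and returns
to the `<0>`-tagged start.

On the bundled 13-city mileage table:

```r
dt <- cities13()
tour_totals(dt, 1, 1, "deterministic-nn")$best_total
#> [1] 8131
brute_force_shortest(dt, 1)$total
#> [1] 7293
run_experiment(experiment_config("bank-position", bank_size = 1024,
                                 runs = 20, master_seed = 102), dt)
#> <experiment_result: bank-position (B = 1024), 20 runs>
#>   mean 7472.9, sd 174.1, optimum 7293, fraction optimal 0.1
```

A single deterministic module is stuck at 8,131 miles; a 1K bank averages
about 7,470–7,490, and larger banks (`bank_size = 4096` or `16384`)
approach the 7,293-mile optimum, reaching it in a growing fraction of
runs. See the methods vignette (`vignettes/module-bank-planning.Rmd`) for
the model, parameter meanings, and the full replication discussion.

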