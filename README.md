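# tpgsim

Agent-based simulation of **temporal partitioning congestion games**:
settings where a population must coordinate *when* to use a shared
resource whose per-slot capacity is limited, so crowding imposes a purely
pecuniary externality. The canonical instance implemented here is a
"blossom game": a nature reserve flowers for 19 days with per-day abundance
`K(d) = min(d, 20 - d)`, and 2000 heterogeneous visitors each pick a day or
stay home. For whom: behavioural ecologists, social scientists and
modellers studying El Farol-type coordination, common-pool congestion, and
temporal niche partitioning.

## The model

Visitor `i` has preference `m_i ~ U[1, 3]`. If `n(d)` visitors choose day
`d`, each receives

```
u_i = m_i K(d) / n(d)   if m_i K(d) / n(d) >= z      (z = 0.1)
u_i = -c                otherwise                    (c = 1)
u_i = 0                 for staying home
```

Dynamics are satisficing with stochastic exploration: positive-utility
agents repeat their choice; others stay home with probability `1 - p` and
otherwise explore — a bloom-weighted random day in the **local**-knowledge
condition, or a best response to last season's published attendance in the
**global**-knowledge condition. Learning multiplies `p` by `L` (default
0.5) after every strictly negative season. The 2×2 information-by-learning
design, population turnover, a typed **bat waterhole** variant with
same-type affinity (`u = (z / n) (n_same / n)`, threshold 1, roost pays 0),
and a static Nash toolkit (verification, greedy preference-ordered
construction, exhaustive enumeration) are all included.

## Worked example

```r
library(tpgsim)
cfg <- game_config(info_mode = "global", seed = 42)   # reference conditions
res <- run_game(cfg)
diagnose(res, window = 20)
```

```
<convergence_report> strong=FALSE, weak_trend=0.0766
  mean visitor utility (late): 0.1885
  mean preference: visitors 2.351 vs home 1.469
```

Read: with global information *and* learning the game is near equilibrium
after 100 seasons — late-season visitors average utility +0.19 (crowds sit
just under capacity), the rate of behavioural change has fallen to ~8% of
its early value (changer fraction 0.182 in seasons 1–10 vs 0.0085 in
90–100), and the visitor pool is preference-sorted: agents who still visit
value the experience markedly more (mean `m` 2.35) than those parked at
home (1.47) — the winner-takes-all character of the equilibria. Setting
`learning_L = 1` instead yields permanent oscillation with negative mean
visitor utility; `info_mode = "local"` with learning gives only weak
convergence; `turnover_fraction = 0.1` destroys convergence again.

```r
res_bat <- run_bat_game(bat_config(n_bats = 500, seed = 1))
slot_dominance(final_slot_types(res_bat))   # one type per slot, mostly
```

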