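# ktdrank

Identify influential spreaders in undirected networks with the **KTD
score** — a k-shell decomposition refined by a global **iteration factor**
and node **degree**, then aggregated over **neighbor** influences — plus the
full evaluation stack used in the influential-spreader literature.

## Who this is for

Network scientists and epidemic modellers who need (a) a node-influence
ranking that is nearly as cheap as plain k-shell but far more
discriminating, and (b) the standard apparatus for judging any such
ranking: the monotonicity index, CCDF / rank-frequency summaries, a
discrete-time SIR simulator providing per-node spreading power as ground
truth, the mean-field epidemic threshold, Kendall rank agreement, and
degree / betweenness / closeness / k-shell baselines.

## The score

K-shell peeling proceeds shell by shell; every simultaneous removal pass
increments a *global* round counter `IT` that never resets between shells
(`ITmax` = total rounds). With `deg` the original degrees:

```
C_i = KS_i + (IT_i / ITmax) * (deg_i / degmax)        (direct influence)
E_i = C_i + sum over neighbors j of C_j               (KTD score)
```

The refinement term lies in (0, 1], so shell order is never violated; the
neighbor sum separates nodes that agree in all of `KS`, `IT`, `deg`.

## Worked example

```r
library(ktdrank)
g <- karate_graph()          # bundled 34-node Zachary karate club

network_summary(g)
#> network: N=34 E=78  k=4.59  d=2.41  c=0.57  Ksmax=4  beta_th=0.129

sm <- ktd_score(g)
head(sort(sm$scores, decreasing = TRUE), 5)
#>        1       34        3       33        2
#> 56.69748 54.88235 43.70588 41.86555 38.01681

to_ranking(sm)
#> ranking [KTD]: 34 nodes in 27 dense rank levels
monotonicity(sm)             # 0.9542

compare_methods(g, c("KTD", "dc", "cc", "ks"),
                sir_config(beta = 0.15, gamma = 1, reps = 200, seed = 42))
#> method comparison vs SIR (beta=0.15, gamma=1, reps=200)
#>  method monotonicity  tau_a  tau_b
#>     KTD       0.9542 0.6809 0.6902
#>      dc       0.7079 0.6292 0.6872
#>      cc       0.8993 0.6417 0.6601
#>      ks       0.4958 0.5276 0.6299
```

Reading the output: the karate club has mean degree 4.59, four k-shells and
epidemic threshold 0.129. Plain k-shell resolves the 34 nodes into only 4
levels (monotonicity 0.50); KTD resolves them into 27 levels (0.9542) and
its ranking agrees best with the SIR spreading-power ground truth (highest
Kendall tau). Nodes 1 and 34 — the two club factions' hubs — top the
ranking.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/ktd.R summary  inst/extdata/karate.edgelist
Rscript inst/cli/ktd.R rank     inst/extdata/karate.edgelist --method KTD
Rscript inst/cli/ktd.R evaluate inst/extdata/karate.edgelist --beta 0.15 --seed 42
```

See `vignettes/ktd-methods.Rmd` for the model, the SIR conventions, tie
handling, and design rationale.

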