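# boolsig

Asynchronous Boolean dynamics and structural analysis of signaling
networks, built around a complete logical model of survival signaling in
T cell large granular lymphocyte (T-LGL) leukemia — a blood cancer in
which cytotoxic T cells escape activation-induced cell death.

A Boolean network assigns every component $v_i$ a state in $\{0, 1\}$ and
a transfer function $v_i^* = f_i(v_{i_1}, \dots, v_{i_k})$ written with
AND/OR/NOT. Under the **general asynchronous** update (one random node per
step) the dynamics is a nondeterministic state transition graph whose
terminal strongly-connected components are the attractors — here a
*normal* fixed point (programmed cell death fires) and a *T-LGL* fixed
point (survival signaling locks death out). The package implements:

* a parser, exact simplifier and OR-of-ANDs canonicalizer for the
  `Node* = expr` rule dialect;
* two-step network reduction: logical steady state analysis (iterative
  constant propagation from frozen inputs, attractor-safe) and simple
  mediator elimination (fixed-point preserving), with back-substitution of
  reduced attractors;
* exact GA state-transition-graph analysis: attractors, exclusive basins
  of attraction by graph reachability, and absorption probabilities of
  the associated Markov chain;
* expanded-network structural analysis: complementary (`~X`) and composite
  (AND) vertices, cascading deletion, simple-path counting in compiled
  code, and importance values
  $I_v = 1 - N_{SP}(G_{\Delta v}) / N_{SP}(G_{exp})$;
* systematic in-silico knockout / over-expression screening with
  trap-subcube (stable-motif-style) attractor detection, and the
  structural-vs-dynamic sensitivity/specificity comparison;
* a seeded random Boolean network generator and classic motifs for
  property-based testing.

The three published T-LGL rule tables ship as plain-text fixtures:
`tlgl60` (60 nodes, 142 regulatory edges, six frozen sources), `tlgl18`
(the non-stabilizing sub-network) and `tlgl6` (the reduced core).

## Worked example

```r
library(boolsig)

net <- load_tlgl("tlgl6")
fixed_points(net)
#> [1] "000001" "110000"

stg <- build_stg(net)
basin_partition(stg)
#> # A tibble: 2 × 6
#>   attractor class       attractor_state n_members n_exclusive percent
#>       <int> <chr>       <chr>               <int>       <int>   <dbl>
#> 1         1 fixed-point 000001                  1          36   56.2
#> 2         2 fixed-point 110000                  1           3    4.69
#> overlap region: 25 states (39.06%)
```

Reading: with digits ordered S1P, FLIP, Fas, Ceramide, DISC, Apoptosis,
the network has exactly two fixed points. `000001` is the normal outcome
(Apoptosis ON, everything else OFF); 36 of the 64 states (56%) can reach
no other attractor. `110000` is the disease state (S1P and FLIP ON, death
pathway silent) with a 3-state (5%) exclusive basin; the remaining 25
states can still go either way, and `absorption_probabilities(stg)` gives
their exact commitment. Screening the full network,

```r
scan <- perturbation_scan(load_tlgl("tlgl60"))
table(scan$outcome)
#>  normal    both disease
#>      15      32       2
```

identifies the 15 single-node interventions (e.g. STAT3 or SPHK1 knockout,
Ceramide over-expression) that abolish the disease attractor entirely —
the model's candidate therapeutic targets — and the two (FasT, FasL) whose
loss locks the disease in. `expand_network()` / `importance_scan()`
reproduce the same ranking from network structure alone.

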