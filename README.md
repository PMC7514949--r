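# actualcause

Quantitative **actual causation** ("what caused *what*?") for discrete
dynamical causal networks — logic-gate circuits, small artificial neural
networks, Boolean models of gene regulation, voting rules — anywhere a system
is described by per-node mechanisms and you want to explain one concrete state
transition rather than the system's average behaviour.

Given a two-slice causal network (each node at time *t* has a conditional
probability table over its inputs at *t−1*) and one realized transition
*v*<sub>t−1</sub> ≺ *v*<sub>t</sub>, the package:

- computes **cause and effect repertoires**: interventional distributions
  π(Y<sub>t</sub> | x<sub>t−1</sub>) and π(X<sub>t−1</sub> | y<sub>t</sub>)
  obtained with the do-operator and *causal marginalization* (every variable
  outside the occurrence is averaged uniformly over all of its states, and
  joint repertoires are products of per-node repertoires, which discounts
  common-input correlations);
- scores links in bits: cause/effect information
  ρ = log₂ π(state | occurrence) / π(state), and **integrated** cause/effect
  information α = log₂ π(state | occurrence) / π(state)<sub>MIP</sub>, where
  the MIP is the partition of the occurrence (with its purview) that loses the
  least information;
- applies **exclusion and minimality**: the actual cause (or effect) of an
  occurrence is the minimal candidate sub-state with maximal α — possibly
  indeterminate between tied, non-nested candidates, possibly absent;
- assembles the **causal account**: every irreducible occurrence of either
  slice with its actual cause/effect and strength, plus the account-level
  irreducibility *A* (minimum over bipartitions of the transition's variables
  of the summed strength of links crossing the cut).

Closed-form predictions for linear threshold units and
disjunction-of-conjunction gates, plus a literal brute-force repertoire
implementation, are included as independent cross-checks and are tested
against the engine exhaustively.

## Worked example

The classic "prisoner" disjunction-of-conjunctions: D fires if A loads the gun
*and* B shoots, or if C does both alone — `D = (A ∧ B) ∨ C`. What caused
`{D=1}` when `ABC = 101`?

```r
library(actualcause)

fx  <- paper_example("doc")       # network D = (A AND B) OR C, transition 101 > 1
acc <- causal_account(fx$network, fx$transition)
tidy(acc)
#> # A tibble: 3 × 7
#>   direction occurrence order alpha candidates n_candidates indeterminate
#>   <chr>     <chr>      <int> <dbl> <chr>             <int> <lgl>
#> 1 effect    {A=1}          1 0.263 {D=1}                 1 FALSE
#> 2 effect    {C=1}          1 0.678 {D=1}                 1 FALSE
#> 3 cause     {D=1}          1 0.678 {C=1}                 1 FALSE
```

Both `{A=1}` and `{C=1}` have the actual *effect* `{D=1}` (they raise its
probability: 0.263 and 0.678 bits), but the one actual *cause* of `{D=1}` is
`{C=1}` — the maximally irreducible candidate at α = 0.678 bits. `{B=0}` plays
no causal role, so the account as a whole is reducible:

```r
glance(acc)
#> # A tibble: 1 × 6
#>   n_links n_effect_links n_cause_links total_alpha max_alpha     A
#> 1       3              2             1        1.62     0.678     0
```

Repertoires are tibbles (and `autoplot()`-able):

```r
cause_repertoire(fx$network, c(D = 1), c("A", "B", "C"))
#> <cause repertoire> pi(A,B,C | {D=1})
#> # A tibble: 8 × 4
#>       A     B     C  prob
#> 1     0     0     0   0
#> 2     1     0     0   0
#> 3     0     1     0   0
#> 4     1     1     0   0.2
#> 5     0     0     1   0.2
#> ...
```

`list_examples()` names all bundled networks (overdetermination, prevention,
majority gates with and without background conditions, a ternary 7-voter
plurality, a noisy copy gate, a toy image classifier, ...). Networks can also
be built directly with `build_network()` + `make_gate_mechanism()` or loaded
from JSON with `read_network_spec()`; `exec/actualcause` exposes
`analyze` / `alpha` / `repertoire` / `fixtures` commands on the shell.

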