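---
title: "Quantifying actual causation in discrete causal networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying actual causation in discrete causal networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actualcause)
```

## The problem

Knowing a system's full mechanism and watching a transition happen does not by
itself say *what caused what*. When an OR gate fires with both inputs on, was
one input the cause, both separately, or the pair jointly? Contingency-based
counterfactual tests give unstable answers across such cases because they fix
the "other" variables at one arbitrary state. This package implements a fully
quantitative alternative: all counterfactual states are weighed at once, and
causal claims are scored in bits.

## The model

A **dynamical causal network** here is two time slices of discrete variables
(states `0..cardinality-1`). Each post-slice node has a mechanism: a
conditional probability table over its pre-slice inputs. There are no
within-slice edges, so post nodes are conditionally independent given the full
pre-state and the transition probability factorizes over mechanisms
(`transition_probability()`). A **transition** is a realized pair of full
states with positive interventional probability; an **occurrence** is any
sub-state of either slice, fixed at the values it actually took.

Five principles organize the analysis:

1. **Realization** — only occurrences inside a possible transition are
   analyzed (`validate_transition()` enforces p > 0).
2. **Composition** — every subset of either slice is a candidate occurrence;
   multi-variate ("high-order") occurrences can have their own causes and
   effects.
3. **Information** — an occurrence must raise the probability of its cause or
   effect. The *effect repertoire* π(Y<sub>t</sub> | x<sub>t−1</sub>)
   intervenes on the occurrence and averages every other pre-slice variable
   uniformly over its states (**causal marginalization**); the joint
   repertoire is the product of per-node repertoires, which removes
   correlations that are due to common inputs rather than to the occurrence.
   The *cause repertoire* is the Bayes inversion with a uniform prior,
   multiplied pointwise across occurrence nodes and renormalized. Cause/effect
   information is ρ = log₂ π(actual state | occurrence) / π(actual state).
4. **Integration** — a high-order occurrence must beat its parts. Every
   partition of the occurrence (with each purview variable assigned to a part
   or left unconstrained, plus the full cut) yields a partitioned repertoire;
   the **minimum-information partition** (MIP) loses the least, and
   α = ρ − ρ<sub>MIP</sub> is the link's integrated information. For singleton
   occurrences the full cut is the only partition, so α = ρ.
5. **Exclusion** — an occurrence has at most one actual cause (effect): the
   candidate maximizing α, with a **minimality** condition that removes
   supersets of equally strong candidates. Ties between non-nested candidates
   are reported as genuinely *indeterminate*, never broken arbitrarily.

The **causal account** (`causal_account()`) collects every link in both
directions. Cause links and effect links are genuinely asymmetric: in the
bundled `or_and_system` example the second-order occurrence at *t* has an
irreducible cause, but the corresponding pre-slice occurrence has no joint
effect.

```{r}
fx <- paper_example("or_and_system")
tidy(causal_account(fx$network, fx$transition))
```

## Account-level irreducibility

Beyond single links, `account_irreducibility()` asks whether the *transition
as a whole* decomposes. The measure used here is a documented design choice of
this package (the framework defines the idea; a concrete formula for it was
left open): A is the minimum over bipartitions of the pooled pre+post
variables of the summed α of the links whose variable span crosses the cut.
This reproduces the reference behaviour — A = 0 exactly when some variable
plays no causal role (the prevention example) or the transition splits into
causally unlinked sub-transitions (the independent OR/AND example), and A > 0
for integrated transitions. When a link's cause or effect is indeterminate,
its span uses the union of the tied candidates, the conservative reading.

## Tunable parameters

- `max_vars` (`causal_account()`, default 12 variables total): the analysis is
  exhaustive over subsets and partitions, which is the point — the framework
  is exact, not approximate — so a guard rejects larger networks with a clear
  error instead of running without bound.
- Probability tolerance 1e-9: mechanism rows must sum to 1 this tightly, and
  every repertoire is checked against it in the tests.
- α tie tolerance 1e-8 bits: used for maximum ties, minimality, and
  indeterminacy. All worked-example values are logarithms of small rational
  ratios, so genuine distinctions sit far above this threshold; the tolerance
  only absorbs floating-point noise.
- Gate constructors (`make_gate_mechanism()`) always expand to full tables;
  named gates are conveniences, and multi-valued variables take the same code
  path as binary ones.

## Numerical choices

All repertoire arithmetic stays in linear probability space (the state spaces
are tiny, so underflow is not a concern); logarithms appear only when
information is reported, always base 2. Joint states are enumerated with the
first-listed variable varying fastest, which fixes row order in every table
and serialized repertoire. The MIP search exploits the fact that a partitioned
repertoire's value at the actual state is a product of per-part scalars: the
search precomputes those scalars per (occurrence block, purview subset) pair
and scores every partition by multiplication. A test verifies this against
the explicit `partitioned_repertoire()` vectors partition by partition.
Degenerate inputs are handled by convention: the empty occurrence yields the
unconstrained repertoire (uniform on the cause side), π(∅) = 1, and
information involving an empty side is 0, which floors α<sub>max</sub> at 0.
When several partitions tie as MIP, any minimizer may be reported; α itself is
unique, and only α carries meaning in the tests.

## Background conditions

`condition_on_background()` pins exogenous pre-slice variables and *removes*
them: mechanism tables are restricted to consistent rows, and no
counterfactuals over pinned variables are considered afterwards. Removal
(rather than keeping the variables pinned in place) makes it impossible for
any later computation to marginalize over them accidentally. Conditioning the
idle voter of the four-input majority example preserves the link structure
while strictly increasing every α — pinned context concentrates causal
strength on the remaining variables.

## Closed-form oracles and what the tests show

For two gate families the actual causes and effects are known in closed form,
and the package ships them as independent predictors:

- `ltu_predict()` — a linear threshold unit that fired has as actual cause a
  k-subset of its on-inputs (indeterminate when over-determined), and an
  all-on occurrence of at most k inputs has the unit as its actual effect. A
  unit in the off state behaves like the complementary unit with threshold
  n − k + 1 on the zeros (the complement of "at least k ones" under this
  package's ≥ threshold convention).
- `doc_predict()` — for a disjunction of conjunctions that fired, the actual
  cause is a fully satisfied conjunction (indeterminate among several); an
  all-on occurrence has the gate as its actual effect unless it *strictly*
  contains a complete conjunction, which over-determines the output and makes
  the link reducible. In the off state, causes take exactly one 0-input per
  conjunction and effects at most one.

The suite checks the engine against these predictions exhaustively for every
threshold unit with n ≤ 6 inputs (all k, all realizable states, all
occurrences) and every conjunction-size composition summing to ≤ 6, both
output states. A literal brute-force repertoire (`brute_force_repertoire()`,
no factorization shortcuts, distributions read off the full joint transition
table) is compared to the engine on every bundled network at 1e-12. These
sizes cover the regime where exhaustive verification is possible; they are the
package's own choice of verification depth, and nothing in the engine is
specific to them.

What passing these tests shows: the implementation computes the framework's
quantities exactly on deterministic and probabilistic, binary and multi-valued
networks of desk scale. What it does not show: anything about approximation
quality on large systems — there is none; the guard refuses them — or about
networks whose mechanisms are mis-specified. The analysis is only as good as
the mechanism tables supplied.

## Bundled example networks

`paper_example()` reconstructs the reference cases programmatically:
overdetermination (`disjunction`), conjunction, the XNOR bi-conditional,
prevention, four-input majority with and without a pinned voter, the
disjunction of conjunctions with and without background, a non-linear voting
rule, a seven-voter three-candidate plurality (multi-valued, with ties going
to "no winner"), the noisy copy, a three-detector toy classifier, a double
bi-conditional, an independent-inputs OR/AND pair, and an AND/XOR pair on
common inputs. Two inferred details are worth flagging: the noisy-copy noise
level is set to p(follow input) = 0.9, the value consistent with its reported
causal strength of log₂(0.9/0.5) ≈ 0.848 bits; and the AND/XOR example uses
the self-consistent post-state (AND, XOR) = (1, 0) for inputs (1, 1). The
`random_network()` generator (seeded, RNG-state preserving) supplies
additional property-test instances; it emulates the same class of systems —
random logic gates or random normalized tables over a fixed variable set —
and nothing about real data.

## Known limitations

- Single-step transitions only; causal chains across several updates (and
  with them questions of transitivity and pre-emption) are out of scope.
- Occurrences that *lower* the probability of a candidate get negative ρ/α in
  diagnostic tables but never form links; "preventative" causation is not
  quantified.
- Exhaustive enumeration limits practical use to roughly a dozen variables;
  there is deliberately no approximate mode.
- Mechanisms must be given exactly (full interventional tables); the package
  does not learn them from observations.
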