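---
title: "Entropy-based variability metrics for passing networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-based variability metrics for passing networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(passentropy)
```

## The model

A passing record is a weighted digraph: `w[i, j]` completed passes from
node (player) `i` to node `j`, collected in a square non-negative matrix
`W` with total weight `L`. Everything in this package derives from three
probability objects:

* the sender shares `p[i] = s[i] / L`, where `s[i]` is row `i`'s sum
  (out-strength);
* the receiver shares `q[i] = t[i] / L`, where `t[i]` is column `i`'s sum
  (in-strength);
* the Markov transition matrix `M[i, j] = w[i, j] / s[i]`, the
  conditional distribution of player `i`'s next pass target.

Equivalently, `w[i, j] / L` is the joint distribution of a
transmitter–receiver pair `(X, Y)`; `p` and `q` are its marginals and the
rows of `M` its conditionals `P(Y | X = i)`.

The metric family, all in log base 2 (bits):

| quantity | formula | interpretation |
|---|---|---|
| `R_out(i)` | `p[i] * H(M[i, ])` | node rate of passing |
| `R_in(i)`  | see variants below | node rate of reception |
| `IndR_*`   | rate `/ log2 n` | bounded [0, 1] index |
| `RN_out`, `RN_in` | sums of node rates | network rates |
| `EN_out`, `EN_in` | `H(p)`, `H(q)` | total (marginal) entropies |
| `CN_out` | `EN_out - RN_in` | capacity of passing (signed) |
| `CN_in`  | `EN_in - RN_out` | capacity of reception |
| `IndCN_*` | `abs(CN) / log2 n` | capacity index |

`H` is Shannon entropy. `R_out(i)` weighs how unpredictable a player's
target choice is (`H(M[i, ])`) by how much of the game flows through
them (`p[i]`), so a player who passes rarely contributes little
variability no matter how eclectic those few passes are.

## Assumptions and scope

The weights are assumed to be counts (or non-negative reals — every
metric is invariant under `W -> c W`) of *completed* directed
interactions; failed passes and possession-ending events are simply not
part of the record. Under the default `"sports"` validation profile the
diagonal must be zero (no self-passes); a `"general"` profile admits
self-loops, for which all formulas remain well defined. The package does
not compute degree/closeness/betweenness-style centralities, stationary
distributions, or significance tests of metric differences.

## The two reception variants

The reception metrics come from substituting `w[i, j] -> w[j, i]` and
`m[i, j] -> m[j, i]` in the passing formulas. That substitution is
ambiguous: does `m[j, i]` denote an entry of the transition matrix of
`W`, or of the transition matrix of `t(W)`? Both readings are
implemented and every reception-side function takes a `variant`
argument:

* **`"literal"`** (default): `R_in(i) = -q[i] * sum_j m[j, i] log2 m[j, i]`
  with `M` the row-stochastic matrix of `W`. Columns of `M` are not
  distributions, so `RN_in` is not a conditional entropy and
  `CN_out = EN_out - RN_in` is a *signed* quantity: it goes negative
  when reception-side variability outweighs the sender-marginal entropy,
  i.e. when a team's passing patterns are more stable than its reception
  patterns. The single-broadcaster star (`canonical_fixtures()$star_out_5`)
  is the minimal example: `EN_out = 0`, literal `RN_in = 0.5`, so
  `CN_out = -0.5`.
* **`"conditional"`**: row-normalize `t(W)` first, so each `R_in(i)` uses
  a genuine conditional distribution `P(X | Y = i)`. Then
  `RN_in = H(X|Y)` and `CN_out = EN_out - H(X|Y) = I(X;Y) >= 0`, the
  textbook mutual information of the transmitter–receiver pair.

The literal reading is the default because only it can produce negative
passing capacities, which are a meaningful, interpretable outcome of the
model (stability asymmetry between passing and receiving); the
conditional reading is provided because it is the information-theoretic
limit case and a useful non-negative cross-check.

One identity worth knowing when reading reports: `RN_out` is *always*
`H(Y|X)` (it is the `p`-weighted average of row entropies), so
`CN_in = EN_in - RN_out = I(X;Y)` under **both** variants. Only the
out-capacity distinguishes them. Consequently `CN_in >= 0` always, while
literal `CN_out` may have either sign, and the report records which
variant produced it.

## Numerical choices

* `0 * log2(0) = 0` everywhere; nodes with zero out-strength (a player
  who never passed — e.g. a goalkeeper in some systems, or a very late
  substitute) get an all-zero transition row, are flagged in
  `defined_rows`, and contribute exactly 0 to every entropy sum. This
  keeps all metrics finite without dropping nodes.
* `n` in every `log2 n` denominator is the dimension of the supplied
  matrix, never the number of active nodes. Including or excluding
  substitutes therefore changes every index, deliberately: the index
  measures variability relative to the squad actually fielded.
* Matrix powers (`k_step()`) use iterated multiplication — `k` is small
  in this domain and this avoids complex-arithmetic edge cases of
  eigendecompositions. `propagate()` warns with the lost mass when the
  walk can fall into a zero-out-strength node.
* All computation is in double precision with no rounding before
  serialization (reports store 15 significant digits); internal
  consistency identities (`RN = Σ R`, `CN = EN − RN`, `Ind = value /
  log2 n`) hold exactly, and the test suite compares against a
  loop-based brute-force oracle at 1e-12 absolute.
* The absolute value in the capacity index applies to the index only;
  `CN_out`/`CN_in` themselves are reported signed.

## The synthetic generator

`simulate_pass_network()` emulates a single-match squad pass matrix:
default `n = 14` nodes (11 starters + 3 substitutes) and
`total_passes = 500`, matching the scale of real elite-match records
(a few hundred completed passes, squads of 11–14 once substitutes are
counted). Sender activity is drawn from (or supplied as) a probability
vector — near-zero entries emulate goalkeepers and late substitutes —
and each sender's receiver preferences are an independent symmetric
Dirichlet draw over the other `n − 1` nodes; passes are then allocated
by a single multinomial. A Dirichlet-multinomial was chosen over
independent Poisson counts because the `concentration` parameter
(default 1, uniform on the simplex) cleanly interpolates spiky
(`concentration << 1`, a few dominant arcs, low variability indexes) to
uniform (`concentration >> 1`, indexes approaching 1) passing structure —
precisely the axis these metrics measure. A single integer seed governs
all randomness; the draw leaves the caller's RNG state untouched and the
generator records its algorithm version, parameters and seed in a
`generator` attribute.

What the generator does **not** emulate: temporal structure within a
match (substitution windows, score effects), tactical-formation
geometry, pass failure, or dependence between a sender's activity and
their target preferences. Tests passing on synthetic data therefore
validate the *mathematics* of the metrics on match-scaled inputs, not
any claim about real teams.

`simulate_pass_sequence()` complements this by sampling the Markov chain
itself: aggregating a long walk recovers the transition proportions, and
the test suite checks at 30,000 steps that empirical transition
frequencies land within 0.02 and the network indexes within 0.05 of
their closed forms on the uniform complete 4-node digraph.

## Problem sizes used in the checks

The test suite runs the brute-force oracle against the implementation on
200 random graphs with `n` between 3 and 12 (both variants, mixed dense
and sparse), a bound-and-identity sweep over 1,000 random graphs, exact
closed-form checks on uniform complete digraphs with
`n ∈ {3, 4, 8, 16}`, and one 30,000-step chain-sampling check — about a
minute end to end. These sizes cover the regime the metrics are designed
for (team-sport squads) with ample margin; all formulas are `O(n^2)` per
network, so much larger graphs pose no difficulty beyond test runtime.

## Known limitations

* The literal reception rate is not guaranteed by construction to stay
  below `log2 n` for adversarial weight patterns; across the 1,000-graph
  property sweep all indexes stay in [0, 1], but the bound is proved
  only for the conditional variant.
* Reports are per-network snapshots; rolling-window dynamics within a
  match are out of scope.
* The CSV reader expects the labelled square layout it writes; the
  edge-list importer covers the common alternative, but no GraphML/GEXF
  export is provided.
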