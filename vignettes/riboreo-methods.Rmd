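---
title: "Methods: assembly-order chronologies and genetic code imprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assembly-order chronologies and genetic code imprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboreo)
```

## The model

Both ribosomal subunits assemble in a reproducible order: experimentally
determined assembly maps state which proteins must already be bound before
another can join the particle. Under the recapitulation hypothesis, this
binding order mirrors the order in which the proteins were recruited during
the evolution of the ribosome, before the last universal common ancestor.
Because the genetic code was still expanding during that era, each protein's
universally conserved positions should carry an imprint of the code at its
recruitment time — a usage bias relative to positions conserved only within
one domain of life, which evolved later under an essentially complete code.

riboreo turns this premise into a pipeline:

1. **Rules → orders.** An assembly map becomes a partial order; its linear
   extensions are the *permitted linear evolutionary orders* (PLEOs). For a
   rule set with prerequisite sets $\mathrm{pre}(j)$, the count of
   extensions is computed exactly by dynamic programming over
   downward-closed subsets $S$: $f(S) = \sum_{j \in S,\,
   \mathrm{pre}(j) \subseteq S \setminus j} f(S \setminus j)$, in
   $O(2^n n)$ time. The same tables give exact position probabilities and an
   exactly-uniform sampler over extensions (each sequential choice weighted
   by the number of permitted completions).
2. **Orders → chronology.** Compiling orders (exhaustively, exactly, or by
   sampling) yields the REO matrix $P_{ij}$, the probability that protein
   $j$ occupies chronology position $i$. It is doubly stochastic by
   construction. Proteins believed to have undergone non-orthologous
   displacement (LSU: L15, L16; SSU: S6, S16, S18, S20) are carried through
   the ordering, then deleted from every underlying order with the
   remaining proteins closing ranks — they shape the chronology but get
   zero weight in usage averaging.
3. **Chronology → usage profile.** With per-protein usage rates
   $r^U_{jA} = U_{jA}/U_{jT}$ and $r^D_{jA} = D_{jA}/D_{jT}$ at universal
   and domain-specific conserved positions, the position profile is the
   probability-weighted mean difference
   $D_{iA} = \sum_j P_{ij}\,(r^U_{jA} - r^D_{jA})$, with weighted standard
   error $SE_{iA} = \big(\sum_j P_{ij}^2\,\mathrm{Var}_j[A]\big)^{1/2}$,
   $\mathrm{Var}_j[A] = r^U(1-r^U)/U_{jT} + r^D(1-r^D)/D_{jT}$. The
   expected value of $D_{iA}$ under a finished code is 0, and the
   rate-difference profile sums to 0 over amino acids at every position.
4. **Two profiles → alignment.** Pairwise position distances
   $\mathrm{RMSD}(i_L, i_S) = \big(\tfrac1{20}\sum_A (D_{i_L A} -
   D_{i_S A})^2\big)^{1/2}$ fill an LSU × SSU matrix. A background matrix —
   the average over replicates in which intact per-protein $(U, D)$ count
   pairs are permuted across proteins within each subunit — removes the
   structure the model itself induces (adjacent positions share proteins;
   terminal positions average fewer proteins), and is subtracted to give
   the residual matrix. Constrained monotone random walks (down, right,
   diagonal; no right-after-down or down-after-right; start on the first
   row/column, stop on first arrival at the last row/column; score = mean
   residual over visited cells) explore the residual matrix; the top 5%/1%
   best-scoring walks give a path-frequency landscape, and the single best
   walk (or a ridge summary of the landscape) gives a discrete chronology
   alignment.
5. **Alignment → statistics.** Per amino acid, congruence between the two
   chronologies is $Z_c = (D_L - D_S)/\sqrt{SE_L^2 + SE_S^2}$ at each
   aligned position, combined by a weighted Z-transform
   $Z_w = \sum_c w_c Z_c / \sqrt{\sum_c w_c^2}$ with
   $w_c = 1/(SE_{L,c}^2 + SE_{S,c}^2)$; convergence toward modern usage is
   the endpoint score $Z_V = |D_{\mathrm{last}}|/SE_{\mathrm{last}} -
   |D_{\mathrm{first}}|/SE_{\mathrm{first}}$. Thresholds follow the
   conventional quantiles: congruent if $|Z_c| < 1.282$, convergent if
   $Z_V < -1$, divergent if $Z_V > 1$.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| conservation threshold | 0.90 | minimum ancestral-state probability at *both* root-flanking nodes (inclusive) for a site to count as conserved |
| delta variant | `rate_difference` | per-protein usage contrast; `count_quotient` gives the literal count-difference quotient $(U_{jA}-D_{jA})/(U_{jT}-D_{jT})$ |
| background reps | 10000 | permutation replicates averaged into the background matrix |
| walks | 10^6 | random walks through the residual matrix (a 10^7 flag-level value reproduces heavier searches; convergence is declared when independent half-samples give the same best path) |
| q levels | 0.05, 0.01 | best-scoring fractions mapped into landscapes |
| congruence threshold | 1.282 | one-tailed 0.10 normal quantile applied to $|Z_c|$ |
| convergence threshold | 1.0 | on $Z_V$, in SE units |

## Design choices in ambiguous territory

* **Weighted-usage formula.** The verbal description of the position
  profile admits two readings: a difference of usage *rates* or a quotient
  of count differences. The rate difference is the default because it alone
  satisfies the stated expectation $U_c - D_c = 0$ for a finished code and
  is well defined when $U_{jT} = D_{jT}$; the count quotient is retained as
  an option and the choice is recorded in output metadata.
* **Weighted standard error.** The exact SE formula used historically for
  this analysis is not published; we use the standard weighted-mean SE with
  binomial per-protein variances (above). Empirically this yields
  per-position $Z_c$ with unit variance under drift-free synthetic worlds
  (observed sd 1.01), i.e. the per-position test is well calibrated.
* **Sampling distribution of random PLEOs.** The heuristic order generator
  used historically is unspecified. The default sampler is exactly uniform
  over linear extensions (the defensible null); a "frontier" sampler that
  picks uniformly among currently bindable proteins (non-uniform over
  extensions) is kept for sensitivity analysis.
* **Walk termination.** Walks end the moment they occupy any cell of the
  last row or column; whether an edge-crawl continuation was intended is
  not decidable from the rules as stated, and immediate termination is the
  reading that keeps all pairings exclusive. Consequently on a $1 \times n$
  matrix every walk is its start cell.
* **Tie-breaking.** Enumeration emits extensions in lexicographic label
  order; best-walk selection breaks score ties by walk generation index;
  `order()`'s stable sort makes landscape selection deterministic.
* **Conserved in both domains, different identities.** Such sites
  contribute to *both* domains' D sets (they are conserved at either root
  but demonstrably not in the common ancestor). This is our reading of the
  subtraction rule and is flagged here rather than buried in code.
* **Alignment condensation.** How a path landscape is condensed to the
  discrete alignment is not specified historically; the default is the
  single best-scoring walk, with a ridge-based extraction (per-row argmax
  of coverage, made monotone) as an alternative. Neither is claimed to
  equal any previously published condensation.
* **Enumeration cap.** `enumerate_pleos()` materialises orders in memory;
  its default cap is 10^6 orders (the limit is an argument, and the exact
  DP covers counting and probabilities without enumeration at any size up
  to the subset-DP limit of 24 proteins).
* **Protein-exclusion sensitivity.** Analyses omitting one protein (e.g.
  the S7 sensitivity check on early SSU alanine usage) are composed with
  `remove_excluded(reo, rs, drop = "S7")` before `delta_profile()`, rather
  than by a bespoke option downstream.

## The synthetic world generator

`simulate_world()` creates two subunit analogues with known ground truth:
a code-expansion schedule (consensus addition order, Gly/Ala/Asp early
through Met/Trp late; baseline frequencies near average modern protein
composition), protein recruitment at unit time steps with the LSU analogue
leading by `lag` steps, a dependency DAG drawn edge-wise from earlier to
later proteins, and U/D count tables. A protein recruited at time $t$ draws
its U positions from a multinomial with weights
$b_A \exp(-\mathrm{drift} \cdot e^{-(t - a_A)/\tau})$ for amino acids
already added at time $a_A \le t$ and weight 0 for amino acids not yet in
the code; D positions always draw from the modern baseline $b_A$. With
`drift = 0` the mask is dropped entirely and U and D are drawn from the
same distribution: an exact null. A step-function variant of this
recruitment-to-bias link was considered; the exponential decay is the
default because code imprints plausibly fade gradually as usage equilibrates.

Calibrated default: `dep_density = 0.20`, chosen so the median permitted
fraction of orders for a 15-protein analogue (~1e-5) matches the
selectivity scale of the bundled LSU rule set (30,298,800 of 15!,
i.e. 2.3e-5). `profiles_from_world()` additionally emits two-node ancestral
probability profiles per domain (true conserved sites at probability
$1-\mathrm{noise}$, decoys at 0.5) so the conserved-position calling and
classification stages can be exercised end to end.

What the generator does *not* emulate: phylogenetic correlation between
proteins, alignment error, site-rate heterogeneity, reconstruction
uncertainty correlated across sites, or any sequence-level process. Passing
tests on synthetic worlds therefore demonstrate the statistical machinery
under the model's own assumptions, not robustness to real-data violations
of them.

## Numerical notes

* Counts are exact in double precision below $2^{53}$; the subset DP is
  limited to 24 proteins (memory $2^n$ doubles).
* REO matrices satisfy unit row and column sums to within 1e-12; the
  rate-difference profile sums to zero over amino acids to within 1e-12.
* All randomness flows through R's RNG; every stochastic stage takes or
  records a seed, and `run_pipeline()` reruns byte-identically from the
  same configuration.
* Degenerate cells (zero combined variance with equal deltas) count as
  trivially congruent but are excluded from the weighted Z combination;
  endpoint convergence scores are NA when an endpoint SE is zero.

## Known limitations

Two calibration facts about the published statistics, established with the
package's own synthetic nulls, deserve emphasis:

* **The one-sample Z on matrix summaries is approximate.** The permutation
  distribution of the residual-matrix variance is right-skewed, so the
  normal-approximation p of `structure_test()` is not uniform under a true
  null (a Kolmogorov–Smirnov test over 500 drift-free worlds rejects),
  while the rank-based permutation p over the same replicates is uniform
  (KS p ≈ 0.6). `structure_test()` therefore reports both; the empirical p
  is the better-calibrated quantity, and the Z-based p is retained as the
  published form.
* **The weighted Z-transform assumes independent positions.** Adjacent
  chronology positions weight largely the same proteins, so their $Z_c$
  are strongly positively correlated (next-neighbour correlation ~0.8 at
  realistic map selectivity). The combined $Z_w$ consequently has null
  variance well above 1, and its per-amino-acid type-I error at nominal
  0.05 is ~0.3 in drift-free worlds. Per-position congruence counts and
  $Z_c$ themselves are well calibrated; overall $p(Z_w)$ values should be
  read as anticonservative.

Problem sizes used by the test-suite experiments (chosen to estimate each
property precisely at desk scale): 500 drift-free worlds for calibration
checks, 20 seeded worlds at the default 15+18-protein scale for
lag-recovery, 10^5–10^6 walks for landscape and optimality checks, and
exhaustive brute-force oracles on DAGs with up to 8 proteins and matrices
up to 4 × 4.
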