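---
title: "Drug cocktail networks: models, null hypotheses and prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug cocktail networks: models, null hypotheses and prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcpred)
```

## The scientific problem

Effective drug combinations — cocktails of two or more agents that achieve
better efficacy or fewer side effects than their components — are rare
finds among an enormous space of possible pairings. Curated databases of
known effective combinations can be recast as a **drug cocktail network**:
drugs are nodes and an edge joins two drugs that occur together in an
effective combination (combinations of more than two drugs are split into
all pairwise edges). Two empirical regularities make this network useful
for prediction:

1. combined drugs tend to have **similar therapeutic effects**, as encoded
   by their ATC classification codes, far beyond what degree-matched
   random networks show; and
2. two drugs that **share many combination partners** are far more likely
   to form an effective combination themselves.

`dcpred` implements the full chain: therapeutic similarity, network
topology, a degree-preserving null model, the shared-neighbour ranking
statistic, ROC evaluation, and target-protein proximity on a
protein–protein interaction (PPI) network — plus synthetic-data
generators so the whole pipeline is testable without any external
database.

## Therapeutic similarity from ATC codes

The WHO Anatomical Therapeutic Chemical (ATC) system assigns each drug one
or more 7-character codes with five nested levels (prefix widths 1, 3, 4,
5, 7; e.g. `C03AA03` is level-1 `C`, level-2 `C03`, …). For a drug $d$,
let $\mathrm{ATC}_k(d)$ be the set of distinct level-$k$ prefixes over all
its codes. The level-$k$ similarity of two drugs is the Jaccard index

$$S_k(d_1, d_2) = \frac{|\mathrm{ATC}_k(d_1) \cap \mathrm{ATC}_k(d_2)|}
                       {|\mathrm{ATC}_k(d_1) \cup \mathrm{ATC}_k(d_2)|},$$

and the **therapeutic similarity** is the mean over the first $n$ levels,

$$TS(d_1, d_2) = \frac{1}{n} \sum_{k=1}^{n} S_k(d_1, d_2).$$

The default is $n = 3$: level 5 identifies the chemical substance itself,
so almost no drug *pair* agrees there and deeper levels mostly dilute the
score. Drugs may carry several codes; we read the set notation literally
and take the Jaccard over the deduplicated prefix sets, the only
interpretation consistent with multi-code drugs. Since every $S_k$ is a
ratio of small integers, $TS$ values are exact rationals; tests compare
them at an absolute tolerance of $10^{-12}$.

```{r ts-example}
therapeutic_similarity(c("A01AB02", "C03AA03"), "C03BB01")  # (1/2 + 1/2 + 0)/3
```

Drugs without any ATC code cannot be scored and are rejected at load time;
malformed codes raise a line-numbered error rather than being skipped
silently.

## Network topology

`build_cocktail_network()` splits each $k$-member combination into
$\binom{k}{2}$ unordered pairs, discards non-effective records and
combinations with unannotated members (all counted in an exclusion
report), and collapses duplicate pairs, so the result is always a simple
graph. Descriptors follow the conventions of scale-free network analysis:

- `degree_distribution_table()` gives the empirical $P(k)$;
- `fit_power_law()` fits $P(k) \propto c\,k^{-\alpha}$; the default
  estimator is ordinary least squares on the $(\log_{10} k, \log_{10}
  P(k))$ points, matching how such distributions are usually displayed. A
  discrete maximum-likelihood estimate is available via `method = "mle"`.
  On sampled graphs the raw log–log points are dominated by tail bins
  holding a single node; the `min_count` argument floors those bins
  (our generator tests use `min_count = 5`), while on noiseless grids OLS
  recovers $\alpha$ to $10^{-6}$.
- **star drugs** are drugs with at least two neighbours; **hub drugs**
  have more than six (implemented as degree $\ge 7$; the threshold is an
  argument, since analyses sometimes restrict hubs further, e.g. to those
  with target annotations).
- `star_neighbor_ts_profile()` reports the fraction of star–neighbour
  edges with $TS > 0$. "Has therapeutic similarity" is interpreted as
  $TS > 0$ at $n = 3$ — the complement of drug pairs with totally
  disjoint ATC classifications. Because an edge between two star drugs
  can be counted per-edge or once per (star, neighbour) ordered pair, and
  either convention is defensible, both fractions are returned.
- `neighbor_pair_effective_fraction()` sweeps a TS threshold over pairs
  of drugs sharing a star neighbour (each pair counted once however many
  stars it shares) and reports the fraction already combined — the
  empirical signal behind the predictor.

Analyses run on the full network by default. Restricting to the union of
the largest components is supported (`top_components` argument) but not
the default, because the shared-neighbour statistic's worked values are
consistent with the full node count (see below).

## The rewiring null model

To ask whether combined drugs are *more* similar than chance, the
network-level mean edge TS is compared against degree-preserving
randomisations: repeated double-edge swaps that keep every node's degree
while shuffling partners, rejecting swaps that would create self-loops or
parallel edges. The attempted-swap budget is `ceiling(swap_factor * |E|)`
with `swap_factor = 10`, a standard mixing heuristic; graphs admitting no
valid swap (a triangle, a single edge) are returned unchanged with a
warning. The empirical p-value is

$$p = \frac{\#\{\text{replicates with mean } TS \ge \text{observed}\}}{R},$$

with ties counted toward the numerator — the conservative convention; the
looser "strictly larger" reading changes nothing when the observed value
is extreme. Per "ATC code level" $k$ the package defaults to recomputing
$TS$ with $n = k$ (mean over levels $1..k$); `agg = "single"` instead
uses $S_k$ alone. Both are exposed because either reading of "similarity
at level $k$" is defensible; the significance verdict on assortative
networks is the same.

Per-component ATC class enrichment uses the one-sided hypergeometric tail
(drug counts per level-1 class in the component vs the universe) with
Benjamini–Hochberg adjustment across classes. No particular test is
canonical for such count tables, so raw per-class frequencies are also
emitted and the table can be rebuilt without any test at all. A drug
carrying several level-1 codes counts once toward each class.

All randomness flows from one user-supplied seed; replicate $i$ uses
`seed + i`, so runs are reproducible and individually re-derivable.

## The shared-neighbour statistic and the DCPred models

Suppose the network has $N$ drugs and a candidate pair has $n_1$ and
$n_2$ neighbours with $m$ in common. The probability of that overlap
arising if neighbourhoods were random subsets is

$$P(m, n_1, n_2, N) =
  \frac{\binom{N}{m}\binom{N-m}{n_1-m}\binom{N-n_1}{n_2-m}}
       {\binom{N}{n_1}\binom{N}{n_2}}
  \;=\; \frac{\binom{n_1}{m}\binom{N-n_1}{n_2-m}}{\binom{N}{n_2}},$$

the hypergeometric point probability of exactly $m$ overlaps — the two
forms are algebraically identical. It is computed on the log scale via
`lchoose`, is exactly symmetric in $(n_1, n_2)$, strictly decreasing in
$m$, and sums to 1 over $m$ (Vandermonde). We implement the *point*
probability as printed; in the worked reference values $m = \min(n_1,
n_2)$, where point and upper tail coincide, so the two readings cannot be
distinguished there — the upper tail is available as `tail = TRUE`.

```{r eq4}
shared_neighbor_pvalue(2, 2, 2, 215)
```

Candidates are pairs of network drugs with similar ATC codes ($TS > 0$,
threshold exposed as `ts_min`):

- **DCPred1**: no degree filter, ranked by descending TS;
- **DCPred2 / DCPred3**: both drugs need $\ge 2$ / $\ge 3$ neighbours,
  ranked by ascending p-value.

Ties are broken by descending TS, then lexicographic pair id, giving a
deterministic total order invariant to input row order. Known edges stay
in the candidate set (they are the evaluation positives), and by default
a pair's own edge is *not* removed from its endpoints' neighbourhoods —
the statistic scores known combinations exactly as novel ones. Because
that choice is optimistic when evaluating on the known edges themselves,
`exclude_pair_edge = TRUE` and `holdout_evaluation()` (mask a fraction of
edges, score without them, recover them) provide the honest alternatives.
$N$ defaults to the loaded network's node count.

## Evaluation

`roc_auc()` sweeps all score thresholds; tied scores cross together
(grouped, not broken), and the trapezoid area then equals the
tie-corrected rank-sum statistic — the probability that a random positive
outscores a random negative, ties counting half; the suite asserts the
identity to $10^{-9}$ and cross-checks against an independent ROC
implementation. `threshold_metrics()` tabulates sensitivity, specificity
and accuracy at every rank cutoff.

## Target proximity on a PPI network

`load_ppi()` reads STRING-style scored edges and keeps interactions with
score $\ge 700$ (the conventional high-confidence cutoff; "below 700" is
what gets removed, so the boundary is inclusive). The distance between
two drugs' target sets is the minimum unweighted shortest-path length
over cross pairs — the usual convention for drug–target proximity; 0 iff
the sets intersect within the graph; `Inf` is the unreachable sentinel
(never an arbitrary large number). A mean-over-cross-pairs variant is
available, and `proximity_comparison()` emits both full distance
distributions (hub↔partner vs hub↔similar-non-partner) along with their
medians, since a pooled per-protein reading of "shortest distances" is
also plausible. `localization_tally()` fractions a drug set's targets
over cellular-localization classes, with unannotated targets counted
separately rather than dropped.

## What the synthetic generator emulates — and what it does not

`generate_drugs()` samples 1–3 level-5 codes per drug from a synthetic
ATC hierarchy with the real level structure (prefix widths 1/3/4/5/7) but
a fabricated level-1 alphabet (`E, F, I, K, O, Q, …`) disjoint from the
real one, so fixtures can never collide with real codes.
`generate_cocktail_network()` draws endpoints with weights $w_i \propto
i^{-1/(\gamma-1)}$ (static scale-free model, target exponent $\gamma$),
resamples the second endpoint among class-sharing drugs with probability
`ts_assortativity`, and closes triangles between similar co-neighbours of
a shared partner — planting exactly the two regularities the analyses
detect. A fraction of true pairs is withheld and returned as evaluation
positives. `generate_ppi()` builds a Watts–Strogatz small-world protein
graph and pulls combination partners' targets within two hops with
configurable probability.

Defaults are fixed at the regime of curated combination data: 500 drugs,
mean degree 2.2 (a few hundred drugs joined by a comparable number of
effective pairs), six therapeutic classes, assortativity 0.8, degree
exponent 2.1, 10% planted positives, status mix roughly 40/33/28%
approved/clinical/preclinical, and 5% non-effective decoy records for the
loaders to discard. What the generator does **not** emulate: real ATC
code multiplicity patterns, dosage effects, database curation biases,
literature lag, or target annotation sparsity. Passing tests therefore
demonstrate that the machinery detects the planted structure at realistic
sizes — not that any particular real-world AUC is reproduced. On these
defaults the shared-neighbour ranking (DCPred2-style) recovers planted
positives with median AUC around 0.8 across seeds and clearly beats the
TS-only ranking, mirroring the qualitative model ordering on real data;
the real-data AUCs themselves depend on the curated database and are out
of desk scope.

## Numerical and design choices

- Binomial coefficients via `lchoose`; probabilities exponentiated once,
  stable far beyond the sizes seen here.
- TS matrices via sparse level-incidence cross-products; exact ratios of
  integers, no floating accumulation across pairs.
- Degenerate inputs: empty networks, edgeless graphs, unrewirable graphs,
  single-class enrichments and empty candidate sets all raise or warn
  explicitly rather than returning silent zeros.
- Deterministic tie-breaks everywhere a total order is promised
  (component ordering, candidate ranking).
- Problem sizes in the test-suite: property loops use graphs of 6–40
  nodes against brute-force oracles; generator-level checks use 200–2000
  drugs; the null-model significance check uses 200 replicates at 500
  drugs and the planted benchmark 5 seeds at 500 drugs — sizes at which
  every stochastic property is comfortably separated from its threshold.

## Known limitations

- The statistic treats neighbourhoods as exchangeable random subsets; it
  ignores degree-correlation structure beyond $n_1, n_2$.
- Scoring known edges without exclusion is optimistic (see
  `holdout_evaluation()`).
- Only pairwise combinations are scored; higher-order cocktails enter
  only through pair-splitting.
- The OLS power-law fit is a descriptive summary, not a rigorous
  heavy-tail test; use `method = "mle"` and dedicated model comparison if
  the exponent matters substantively.
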