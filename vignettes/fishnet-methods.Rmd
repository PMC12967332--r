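---
title: "Methods: network-module gene prioritization with permutation-based significance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-module gene prioritization with permutation-based significance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishnetr)
```

## The model and its assumptions

`fishnetr` prioritizes genes from gene-level association P-values by asking
whether genes with low P-values cluster in network modules and share
biological functions. The statistical premise is that, under the global
null, the assignment of P-value *ranks* to genes is exchangeable: a gene's
rank carries no information about which module it sits in or which
annotation terms it carries. Every significance statement in the package is
relative to that exchangeable-rank null.

Three consequences follow. First, only ranks matter: all inference is
invariant under strictly monotone transformations of the P-values, which
protects against miscalibrated or inflated input P-values (at the cost of
ignoring their absolute scale). Second, modules are treated purely as gene
sets — internal connectivity is never used — so any biologically coherent
gene collection can stand in for network modules. Third, the premise fails
by construction when the module structure was estimated from the same data
that produced the P-values (e.g. co-expression modules and expression-trait
association from one cohort); the rank-reversal diagnostic below exists to
detect exactly that failure.

## Stage 1: module enrichment

P-values are rank-transformed: the gene at rank $r$ of $N$ (ascending $p$,
ties broken by ascending gene id) receives the empirical quantile
$\tilde p_r = r/(N+1)$ and the score
$\chi^2_r = F^{-1}_{\chi^2_1}(1 - \tilde p_r)$. The $r/(N+1)$ convention
keeps $\tilde p$ strictly inside $(0,1)$ for every rank, so all scores are
finite; conventions differing by $O(1/N)$ change nothing detectable at
realistic $N$. A module with $k$ scored member genes (genes outside the
score table are dropped; $k$ is the intersection size) is scored by
$T = \sum \chi^2$ over its members.

The null distribution of $T$ is the distribution of the sum of $k$ values
drawn without replacement from the fixed grid
$\{\chi^2_1, \dots, \chi^2_N\}$. The package computes its upper tail two
ways, switching on the universe size (`exact_n_max`, default 100):

* **Exactly**, for $N \le$ `exact_n_max`, by dynamic programming over the
  score grid discretized to $2^{18}$ bins (counting, for every module size,
  the subsets whose integerized sum reaches the observed one). The grid
  resolution bounds the sum error at about $k \cdot 2^{-19}$ of the largest
  attainable sum, far below any tolerance used in testing. One table serves
  every module and every permutation, because the grid depends only on $N$.
  For $k > N/2$ the complement sum is used, and a whole-universe module has
  a constant statistic, hence $p = 1$.
* **By the $\chi^2_k$ upper tail**, for larger universes. As $N$ grows the
  finite grid's mean approaches 1 and the without-replacement correction
  vanishes, so the permutation null converges to $\chi^2_k$; at
  genome scale the two are numerically indistinguishable, and the tail
  approximation errs on the conservative side where it matters (small
  module P-values). The exact branch exists because at small $N$ the
  lumpy, bounded permutation distribution visibly departs from $\chi^2_k$
  (absolute errors up to ~0.08 at $N \le 50$), which would defeat
  small-universe validation against shuffle oracles.

Modules with fewer than `min_module_size` (default 3; singletons and pairs
make the module notion vacuous) scored genes are skipped, and Bonferroni
correction divides by the number of modules actually tested. A module is
significant when its adjusted P-value is at most `alpha_module`
(default 0.05).

## Stage 2: term over-representation

Within each significant module, annotation terms are tested with the
hypergeometric upper tail $P(X \ge k_{\text{overlap}})$, drawing the
module's universe-restricted size from a reference universe. The universe
defaults to scored genes carrying at least one annotation
(`universe = "annotated"`), the usual reference-set choice for
over-representation analysis; `"all"` uses every scored gene. Terms
overlapping the module in fewer than `min_overlap` genes (default 2 — one
shared gene cannot evidence a *shared* function) are not tested.
Benjamini–Hochberg adjustment runs across the terms tested for that module,
with enrichment at `ora_fdr_threshold` (default 0.05).

Redundant terms (GO-style annotation sets overlap heavily) are removed by a
deterministic greedy filter: terms are visited by ascending P-value and
kept only if their overlap-gene Jaccard similarity with every kept term is
below `jaccard_threshold` (default 0.5). A randomized exemplar-clustering
filter would serve the same purpose — cutting the multiple-testing burden —
but the greedy rule is order-free, reproducible, never drops the most
significant term, and shrinks monotonically as the threshold tightens.

A gene is a *candidate* ($A_0$) when it lies in a significant module and in
the overlap set of one of that module's kept enriched terms.

## Stage 3: permutation-based acceptance

Because stage 1 uses only ranks, permuting the rank assignment is
equivalent to permuting the P-values. The package draws $M$ (default 200)
uniform rank permutations, recomputing candidates each time
($A_1, \dots, A_M$). Term enrichment depends only on a module's fixed
member set, so per-module ORA is computed once and cached; permutations
only change which modules are significant. Permutation $i$ runs under child
seed $(seed + 48271\,i) \bmod (2^{31}-1)$, making the ensemble independent
of execution order.

With $B_j$ the observed top-$j$ gene set (always from the unpermuted
P-values) and $C_{ij} = A_i \cap B_j$, the rank-filter search starts at
$j = \operatorname{round}(0.05N)$ (round half away from zero, floored at
`j_min`) and accepts when

$$\mathrm{FDR}_j = \frac{\overline{|C_{1j}|, \dots, |C_{Mj}|}}{|C_{0j}|}
\le 0.05 \quad\text{and}\quad \mathrm{quantile}_j \ge 0.99,$$

else reduces $j$ by `j_step` (default 10) until it drops below `j_min`
(default 10). Two guard conventions are deliberate: when $|C_{0j}| = 0$ the
FDR is undefined and the criteria fail (rather than passing vacuously), and
the quantile counts only permutations *strictly* below the observed count,
so ties count against acceptance. Both make the empty or unremarkable
candidate set fail, which is the conservative direction.

The module-filter alternative keeps all of $A_i$ but restricts the
generating modules to Bonferroni-adjusted P-values at most $t$, with $t$
descending through `module_p_schedule`. The schedule defaults to geometric
halving from 0.1 down to about $10^{-6}$ — a choice the method's
description leaves open beyond "increasingly stringent"; halving gives
uniform steps on the log scale and a bounded trace length, and the schedule
is a plain numeric vector for users who want another. Candidate sets are
nested in $t$, so the search stops early once the observed set is empty.
`simple` mode applies the top-5% filter once with no permutations, for
quick exploration.

The acceptance thresholds warn outside FDR 0.01–0.10 and quantile
0.80–0.99, the ranges over which the method is known to be insensitive; the
package's own robustness test confirms, on the planted fixture, an
identical gene set across that grid and across $M \in \{200, 1000\}$.

## Diagnostics and evaluation

`rank_reversal_diagnostic()` reverses the ranking (rank $r$ receives the
P-value of rank $N+1-r$; an involution preserving the P multiset) and
counts significant modules. Genes that are *not* associated with the trait
hold the top reversed ranks, so under the model assumption the count is 0;
a positive count flags score–module dependency. Reversing ranks rather
than mapping $p \mapsto 1-p$ keeps the diagnostic inside the rank-only
world of the rest of the pipeline — downstream results could not
distinguish the two anyway. `module_p_histogram()` exposes the companion
signature: excess raw module P-value mass near 1.

`evaluate_replication()` scores a discovery run against a replication
cohort: a hit *replicates* when its replication P-value passes that
cohort's own Bonferroni threshold ($0.05/N_{\text{rep}}$ by default), and
*reproduces* when the same (gene, network, algorithm, trait) quad is found
by a replication-cohort run. The two notions are computed independently;
genes missing from the replication universe count as non-replicated and
are listed.

## What the synthetic generator does and does not emulate

`simulate_fishnet_data()` produces the study conditions used throughout the
tests: 1000 genes, 50 modules of 10–30 genes partitioning the universe
(largest modules shrunk deterministically when a sampled partition
overflows), 30 random annotation terms of 10–50 genes, background
$p \sim U(0,1)$, and optionally planted 20-gene modules with
$p \sim \mathrm{Beta}(0.1, 1)$ — the standard spike model for non-null
P-values — plus one aligned annotation term (coverage `annotation_alignment`,
default 1, with 10 decoy genes). `simulate_dependent_pair()` instead draws
each module's P-values around a shared center,
$p \sim \mathrm{Beta}(1+\kappa c, 1+\kappa(1-c))$ with $\kappa = 50$ and
centers near 1 (5 modules), near 0 (5 modules), or uniform; $\kappa = 0$
recovers the independent fixture exactly.

These fixtures emulate the *statistical* structure the method assumes or is
meant to detect — uniform null ranks, rank-concentrated signal confined to
a module, within-module P correlation with a U-shaped module P histogram.
They do not emulate linkage disequilibrium, correlated gene-level
statistics from shared SNPs or co-expression, overlapping module
hierarchies, or the term-size and annotation-depth distributions of real
GO. Passing tests therefore demonstrate correctness and calibration of the
algorithmic machinery under its own model, not performance on any real
cohort: with dependent gene-level statistics the module P-values are no
longer exchangeable-rank-calibrated, which is precisely what the
rank-reversal diagnostic is for.

Fixture sizes were chosen so a full permutation run ($N = 1000$, 50
modules, $M = 200$) completes in well under a second, making the repeated
designs in the test suite (100 null runs, 20 planted runs, 200 diagnostic
runs) a few minutes of desk-scale compute.

## Numerical and degenerate-input conventions

* Ties in P are broken by ascending gene id everywhere (ranking, top-$j$),
  trading randomized tie-handling for bit-reproducibility; the convention
  is recorded in each run summary.
* $p = 0$ is rejected on input ($(0,1]$ is enforced); computed module
  P-values are floored at the smallest positive double.
* Modules disjoint from the score universe or below the size floor are
  skipped and named in the `skipped` attribute, not errors; zero testable
  modules is an error.
* An empty candidate set short-circuits the search (no permutation
  intersections can change it) and returns `accepted = FALSE`.
* All file outputs are plain TSV/YAML with sorted, semicolon-joined set
  columns, so identical runs produce byte-identical tables.

## Limitations

Inter-gene correlation within modules is not modeled at scoring time (the
sum-of-$\chi^2$ treats member ranks as exchangeable draws), GO structure is
flat (no DAG propagation), and the exact output gene lists of any given
external tool chain are not reproduced — equivalence is at the level of the
described mechanism. Replication evaluation is per discovery–replication
pair; aggregation across many pairs is left to scripting.
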