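---
title: "Robustness of host–microbiome metabolic predictions: methods"
author: "symbioscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robustness of host-microbiome metabolic predictions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symbioscope)
```

## The problem

Genome-scale draft metabolic networks are reconstructed from genome
annotations, and different annotation pipelines produce different gene and
enzyme calls for the same genome. When such networks feed downstream
community analyses — which metabolites can a host–bacteria consortium
produce, and which minimal set of bacteria suffices to produce them? — the
choice of annotation pipeline becomes a hidden experimental factor.
`symbioscope` implements the complete chain of such an analysis together
with a synthetic-data generator that emulates several pipelines observing
the same strains, so every stage can be exercised and validated end to end
without external genome data.

## The producibility model

All reasoning is *stoichiometry-free*. A reaction is a pair of compound
sets (reactants, products) with a reversibility flag; coefficients,
kinetics and organism abundances are ignored. Given a set of seed
compounds $S$ (the culture medium) and a reaction set $R$, the **scope**
$\Sigma(R, S)$ is the least fixpoint of

> a compound is producible iff it is a seed, or it is a product of a
> reaction direction whose substrates are all producible,

with a reversible reaction contributing both directions. This is the
classical network-expansion semantics. Two consequences worth noting:

* a compound appearing on both sides of one direction cannot bootstrap
  itself — all substrates of the direction must be producible *before* its
  products are added;
* the fixpoint is order-independent and monotone in both seeds and
  reactions.

`compute_scope()` implements this as a worklist fixpoint with per-rule
unmet-substrate counters (linear in total substrate occurrences per wave);
the deliberately naive repeat-until-stable loop survives in the test suite
as the independent oracle.

The **added value** of a symbiont community for a host is
$(\Sigma(H \cup B, S) \cap \mathrm{compounds}(H)) \setminus \Sigma(H, S)$:
host metabolites that become producible only through bacterial
cooperation. Pooling all reactions ("soup" semantics) deliberately ignores
exchange costs. The restriction to host compounds reflects the question
being asked (what does the *host* gain?); `host_restrict = FALSE` exposes
the unrestricted variant for sensitivity analyses, since community-level
reports may also count bacterial compounds.

## Minimal community selection

Given achievable targets, `minimal_community()` finds the smallest number
of symbionts whose pooled networks (with the host) cover all targets, and
`enumerate_minimal_communities()` lists *every* optimum plus their union —
the set of strains appearing in at least one optimal community, the
quantity used to compare pipelines. The solver:

1. computes a greedy cover (most newly-producible targets per added
   strain, ties lexicographic) as an upper bound;
2. searches subset sizes $k = 0, 1, \dots$ exhaustively, so the first size
   with a cover is provably minimal;
3. prunes, before running any fixpoint, subsets that cannot even *emit*
   some required target as a reaction product — a sound necessary
   condition;
4. re-verifies every candidate with the scope fixpoint itself; no cached
   approximation is trusted.

Witness order is lexicographic by sorted strain ids, so runs are
reproducible where an answer-set or MILP solver would return an arbitrary
optimum. Enumeration stores at most `cap` (default 10,000) optima; beyond
that the list is flagged truncated, while the union is still accumulated
over all optima encountered. `cross_pipeline_scope()` scores a *fixed*
community against another pipeline's reconstruction of the same strains,
enabling the interchangeability comparison in `run_full_analysis()`.

## Network quality metrics

* **Dead-end** metabolites are produced by some reaction direction and
  consumed by none; **orphans** are the mirror image. Both percentages use
  the same denominator — all network compounds before currency removal —
  so they are directly comparable.
* The **SCC ratio** is the size of the largest strongly connected
  component of the directed metabolite graph divided by its node count,
  computed after removing 23 ubiquitous currency metabolites (water,
  proton, ATP, NAD(P)(H), coenzyme A, ...). The default table matches both
  the English names and MetaCyc-style ids, exact-string, because compound
  namespaces are database-specific. The denominator is taken *after*
  currency removal; `denominator = "pre"` divides by the full compound
  count instead, since either convention is defensible and the choice
  matters when comparing against other reports.

SCC computation is delegated to `igraph`; the test suite checks it
against a pairwise-reachability (Warshall) oracle.

## Cross-pipeline statistics

Comparisons run on the reaction presence/absence matrix over all
(strain, pipeline) instances.

* **Bray–Curtis** on presence/absence reduces to the Sørensen form
  $1 - 2|A \cap B|/(|A|+|B|)$, defined as 0 when both rows are empty.
* **ANOSIM** uses Clarke's statistic with mid-ranks for ties,
  $R = (\bar r_{between} - \bar r_{within})/(M/2)$, $M = n(n-1)/2$, and a
  label-permutation p-value $(1 + \#\{R^\ast \ge R\})/(1 + n_{perm})$ —
  the +1 convention never reports $p = 0$. `exact = TRUE` enumerates all
  distinct label arrangements for small $n$. Phylum and pipeline are
  tested as two independent one-factor models on the same matrix (the
  alternative — stratified tests — answers a different question and is
  out of scope).
* **NMDS** minimizes Kruskal stress-1 by alternating isotonic regression
  of configuration distances on the dissimilarity order with a Guttman
  (majorization) update, guarded by step halving so the recorded stress
  trace is non-increasing; defaults: `tol = 1e-6`, `max_iter = 300`,
  `n_starts = 20` (one classical-scaling start, the rest random), all
  seeded. The embedding is centred and principal-axis rotated; stress is
  invariant to rigid motion.
* **UpSet exclusive cells** count reactions present in exactly a given
  pipeline subset, where "present in a pipeline" means found in at least
  one of its strain networks; the cells partition the reaction union.
* **EC over-representation** tests each (category, pipeline) cell against
  $X \sim \mathrm{Binomial}(N_c, 1/P)$ with a one-sided (greater) exact
  tail and Bonferroni correction over all tested cells. The
  percent-over-representation baseline is the mean of the *other*
  pipelines, which is what makes an "$\infty$" (category predicted by one
  pipeline only) representable; a grand-mean baseline cannot produce it.
  The test is one-sided because over-representation is the reported
  direction; the underlying tail function is two-sided-capable.
* **Deviation summaries**: per genome, percent deviation from the
  cross-pipeline mean; one-way ANOVA across pipelines treating each
  genome as a replicate, with Tukey HSD pairwise contrasts
  (`stats::aov` + `stats::TukeyHSD`).

## The synthetic generator

The generator emulates the *structure* such a study assumes, not its
scale: 4 phyla × 5 strains observed by 5 pipelines (the study it mirrors
used 81 strains from 4 phyla and 5 pipelines; desk-scale replication of
that corpus is impossible, so all validation is property-based).

* **Universe** — `n_pathways = 40` linear chains of
  `pathway_length = 5` reactions (~10% reversible), a scaled-down
  caricature of MetaCyc topology: chains yield nontrivial scopes,
  dead-ends (chain terminals), orphans and, through reversible segments,
  SCCs. With probability `cross_link_prob = 0.2` a pathway starts at an
  earlier pathway's terminal, so it consumes upstream output and is inert
  without it. Every reaction belongs to exactly one pathway and carries a
  synthetic EC number from a fixed 20-category list.
* **Strains** — each phylum owns a core of
  `phylum_core_fraction = 0.35` of the pathways shared by its strains;
  each strain adds `strain_private_fraction = 0.05` of the universe as
  private repertoire. Phylum cores are what make within-phylum reaction
  content far more similar than between-phylum content.
* **Pipelines** — five profiles with sensitivities 0.98/0.96/0.94/0.92/
  0.90 and false-positive rates 2/3/5/6/8 decoys per strain, drawn from a
  pipeline-exclusive pool of 8 decoy reactions. Decoys attach a fresh
  pipeline-private compound to a real compound: they inflate network size
  and dead-end counts but cannot open shortcuts to targets, mirroring the
  empirical finding that pipeline-specific reactions are low-confidence.
  The small pool makes pipeline-characteristic false positives recur
  across strains of the same pipeline — without this recurrence the
  simulated pipeline effect is far weaker than the annotation-tool effect
  observed on real data, and the generator would fail its own structure
  contract (phylum dominant, pipeline detectable: both ANOSIM factors
  significant with $R_{phylum} > R_{pipeline}$).
* **Host and medium** — the host consumes the terminals of
  `host_pathway_count = 6` bacterial pathways it does not carry, each
  feeding a host-internal metabolite, and autonomously runs 3 other
  pathways. Seeds are the genuinely initial compounds (sources no
  universe reaction produces). Targets — the consumed terminals plus the
  host-internal products — are verified at generation time: unproducible
  by the host alone, producible with all true networks pooled.
* **Observation RNG** — one stream per (strain, pipeline) derived from
  the master seed by stable string hashing, so adding a pipeline never
  perturbs the others and identical config + seed gives byte-identical
  SBML. A `coupled_sampling` mode shares one uniform per
  (strain, reaction) across pipelines, making observed networks nested by
  sensitivity when false positives are off — used for monotonicity tests.
* **Planted optima** — `plant_minimal_community(k)` makes each of `k`
  designated strains the exclusive carrier of one indispensable target
  pathway, so the unique minimum cover is exactly those strains;
  uniqueness is proved by exhaustive enumeration (with the sound emission
  prune) before the instance is returned whenever the strain count is at
  most 12.

What the generator does *not* emulate: sequence-level noise, realistic
MetaCyc pathway topology (branching, cycles beyond reversibility,
compound reuse across pathways), annotation-pipeline internals, or
incomplete gene associations. Passing tests therefore demonstrate
correctness of the algorithms and recoverability of planted structure,
not performance on real reconstructions.

## Numerical and design choices

* Reversible reactions are stored once and expanded to two directed rules
  only inside scope/graph computations, so reaction counts match SBML
  counts.
* Compound identity is exact string equality of SBML species ids; no
  cross-namespace reconciliation. Boundary species get no special
  treatment — the medium file is the sole seed source.
* Gene associations are sets (no AND/OR logic); SBML I/O accepts both a
  `GENE_ASSOCIATION:` notes line and fbc gene-product associations, and
  writes both.
* Stoichiometric coefficients ≠ 1 are read and discarded, not errors.
* ANOSIM permutations default to 9999 in `anosim()`;
  `run_full_analysis()` uses 999 to keep full-study reruns interactive.
* NMDS declares convergence when the relative stress improvement drops
  below `tol`; if a Guttman step cannot improve stress even after eight
  halvings the iteration stops, which keeps the trace monotone.

## Problem sizes used in validation

The test suite validates: the scope fixpoint against the naive oracle on
200 random instances (≤ 40 reactions, ≤ 30 compounds); community
selection against exhaustive subset enumeration on 100 random host +
symbiont instances (≤ 12 symbionts); planted-community recovery for
$k \in \{3,4,5,6\}$ × 50 seeds on 12-strain instances; structure recovery
(both ANOSIM factors significant at $p < 0.01$, phylum dominant) on 20
replicate default datasets with 999 permutations; plus closed-form,
partition, monotonicity and round-trip properties throughout. These sizes
keep a full run to a few minutes on one CPU while leaving the brute-force
oracles genuinely exhaustive.

## A worked run

```{r example, eval = FALSE}
inst <- generate_instance(generator_config(rng_seed = 1))
bundle <- run_full_analysis(inst, permutations = 999, seed = 1)
bundle            # per-pipeline scope / community sizes, ANOSIM summary
write_report_bundle(bundle, "report")
```

## Known limitations

* The exhaustive optimality proof is exponential in community size; it is
  intended for study-scale pools (tens of strains, small optima), not
  hundreds of symbionts.
* Bray–Curtis/ANOSIM operate on presence/absence only; abundance-weighted
  variants are out of scope.
* The EC enrichment assumes counts are comparable across pipelines (same
  strain set per pipeline); partially missing strains should be dropped
  before counting.
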