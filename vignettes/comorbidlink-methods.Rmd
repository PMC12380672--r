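---
title: "Methods: population-scaled comorbidity modeling and literature-based gene overlap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-scaled comorbidity modeling and literature-based gene overlap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbidlink)
```

This vignette explains the statistical model behind each stage of the
pipeline, the assumptions it rests on, the parameters worth knowing
about, and the design choices made where more than one defensible
option existed.

## The co-occurrence model

The starting point is an *all-case* clinical cohort: every record is a
patient with the outcome disease (here HNSCC), with the comorbid
exposure (diabetes mellitus) recorded per patient. Within a sex stratum
the cohort yields the proportion

$$\hat p = \frac{\#\{\text{cases with DM}\}}{\#\{\text{cases}\}},$$

which `conditional_probability()` reports. A caveat worth stating
plainly: this quantity is a DM proportion *among cases*. Field reports
sometimes label it P(outcome | exposure); the package computes exactly
the ratio above and uses it as the observed conditional co-occurrence
rate seeding the population model, without arbitrating the label.

`build_population_table()` scales $\hat p$ to a population of size $N$
(default $10^7$ per stratum) with exposure prevalence $\pi$ (default
0.069) and stratum-specific outcome incidence $\lambda$. The allocation
is deterministic expected counts:

- outcome margin $M_\text{out} = \operatorname{round}(N\lambda)$,
- exposure margin $M_\text{exp} = \operatorname{round}(N\pi)$,
- joint cell $a = \operatorname{round}(\hat p \, M_\text{out})$,
- $b = M_\text{exp} - a$, $c = M_\text{out} - a$, $d = N - a - b - c$.

Anchoring the joint cell to the *outcome margin* is the allocation that
makes the table internally consistent with both margins and with the
observed case composition, and it is the one that reproduces published
population-scaled tables cell for cell. The textbook factorization
$P(\text{both}) = P(\text{DM}) \times P(\text{outcome}\mid\text{DM})$
with $\hat p$ plugged in for the conditional term does *not* produce a
consistent table here (it would allocate $N\pi\hat p \approx 126{,}615$
joint cases against an outcome margin of 1,520), because $\hat p$ is a
case-composition proportion, not a population conditional; we document
this and use the margin-anchored allocation. Parameters implying a
negative cell raise an error rather than being clipped, so margin
conservation is an invariant, not a hope.

A *multinomial* mode (`method = "multinomial"`) draws one seeded
multinomial sample of $N$ individuals from the implied cell
probabilities for users who want a literal simulation; the default is
the deterministic expectation because the analysis targets are expected
counts.

On the resulting table, `odds_ratio()` ($ad/bc$), `relative_risk()`
($\tfrac{a/(a+b)}{c/(c+d)}$) and `fisher_exact()` quantify the
association. Two numerical points:

- **Cells are coerced to double before products.** $a d$ at population
  scale overflows 32-bit integers.
- **Fisher's test runs in log space.** The conditional null is
  hypergeometric with the table's margins; point probabilities for
  $N = 10^7$ tables underflow doubles, so all pmf evaluations use
  `dhyper(log = TRUE)` and tail sums use log-sum-exp. The two-sided
  p-value follows the point-probability ("minlike") convention — the
  sum over tables whose point probability is at most the observed
  one, with a relative tie tolerance of $10^{-7}$ — which is the
  dominant convention in mainstream statistical software and the one
  consistent with published magnitudes for these tables
  (`stats::fisher.test` uses it too, but cannot be asked for the
  log-scale evaluation needed here; the test suite uses it as an
  independent cross-check at moderate sizes, and exact
  `choose()`-based enumeration at small sizes).

When the outcome is rare ($\lambda < 10^{-3}$), $b \approx a+b$ and
$d \approx c+d$, so OR $\approx$ RR; the test suite asserts agreement
within 2% in that regime, which is why published tables can show
identical OR and RR at two decimals.

The Haldane–Anscombe 0.5 continuity correction is available but only on
explicit request; none of the reference tables need it.

## The literature association statistic

For a gene–disease pair, the inputs are $n_p$ (positive-polarity
findings) and $N$ (polarity-adjusted observations). `abm_pvalue()`
computes the upper-tail binomial probability
$P(X \ge n_p)$, $X \sim \text{Binomial}(N, p_0)$, via the survival
function `pbinom(n_p - 1, N, p_0, lower.tail = FALSE)` — never
$1 - \text{cdf}$, which loses all precision in small tails.

**The null proportion $p_0$ is an assumption.** The package defaults to
$p_0 = 0.5$ — polarity at chance — because the literature-curation
pipelines that produce such counts rarely publish their null. Users
whose pipeline implies a different null must set it; every significance
count downstream depends on it.

`score_associations()` applies Benjamini–Hochberg correction **within
each disease**: the FDR family is the set of genes tested for one
disease, which is the reading consistent with separately sized
significant-gene lists per disease. q-values are computed for all rows
and filtering is a view (`keep_all = TRUE` returns everything);
`bh_fdr()` delegates to `stats::p.adjust(method = "BH")`. Regulation
sign is a majority vote over polarity-labeled references, with ties
reported as `mixed` rather than forced.

## Overlap enrichment

`overlap_fisher()` tests two gene sets against a finite universe. The
universe size is a required argument: substituting $|A \cup B|$
silently would change the "neither" cell and therefore every statistic.
The default test is one-sided (greater), which is the enrichment
convention: for the published significant-set row (195 × 124 sets,
overlap 9, universe 19,924) the one-sided p is $3.69 \times 10^{-6}$,
matching the printed value, while the two-sided minlike p differs —
that agreement is what pinned the convention. Gene symbols are
uppercased before matching, since literature sources mix case for
lncRNA symbols. P-values below the double range are displayed as the
bound `< 4.95e-319`. Degenerate tables where one set contains the
other (a zero off-diagonal cell) report `Inf` for the OR rather than
erroring: the enrichment direction is still well defined.

## Network topology and centrality

Directed regulatory networks at the scale of interest (tens of nodes)
need conventions more than algorithms; the package fixes these:

- density $m / (n(n-1))$;
- average path length and diameter over *reachable* ordered pairs only,
  so a weakly connected digraph still has finite metrics;
- clustering on the **undirected projection** (average local
  coefficient, degree-<2 nodes contributing 0) — with directed triad
  definitions, the high clustering values reported for small dense
  regulatory modules are simply not attainable;
- degree centralities normalized by $n-1$ (the convention under which
  published top in-degree values are expressible as $k/8$ in a 9-node
  network), betweenness over directed shortest paths normalized by
  $(n-1)(n-2)$, eigenvector centrality on the undirected projection
  scaled to max-norm 1;
- hub genes by unweighted mean rank across the four centralities
  (rank 1 = highest, ties share mean rank), lexicographic tie-break.

Graph routines are delegated to igraph; the test suite holds them to an
independent oracle that exhaustively enumerates all simple paths on
digraphs with up to 8 nodes, so the conventions above are verified
rather than assumed. Published per-gene centralities for the reference
9-gene module are *not* regression targets: its 29-edge list was never
published, so only density (a function of $n$ and $m$ alone) is
checked at that scale.

## Cross-disease path assembly

`assemble_paths()` intersects two significant signed edge sets on the
gene symbol and flags concordance (same sign in both diseases). The
output is deliberately modest: a gene-alphabetical table and
JSON/TSV/Graphviz serializations that carry a hypothesis-generating
disclaimer. No causal scoring is computed — the statistic that would
justify it does not exist in these inputs. Genes significant in both
diseases but lacking polarity evidence are left to the association
table (`score_associations()` output) rather than drawn as paths.

## The synthetic-data generators

The generators exist so that every stage has realistic, structured
input under a fixed seed; all take a mandatory seed and restore the
caller's RNG state.

- `generate_cohort()` defaults to the reference cohort's shape: 728
  patients, 692/728 male, per-sex DM probabilities 127/692 and 5/36,
  ages truncated-normal with mean 61.1, sd 10.4 on [14, 91] (the
  observed range), TNM stages sampled with the reference frequency
  tables as weights. The sex split is deterministic
  (`round(n × proportion)`) so published stratum sizes round-trip
  exactly; DM status is the random element, as it is the quantity whose
  sampling variability matters downstream. The published baseline table
  contains internal inconsistencies (its sex and DM totals disagree
  with the stratum counts used in the co-occurrence analysis); the
  generator follows the stratum counts and uses the stage table only
  as sampling weights.
- `generate_literature()` draws $n_\text{pos} \sim
  \text{Binomial}(N, p)$ with $p = p_0$ for nulls and $p = p_\text{true}$
  for a `frac_true` fraction of genes, returning truth labels so type-I
  error and power are measurable. What it does *not* model: publication
  bias, correlated evidence between related genes, or heavy-tailed
  per-gene reference counts — passing calibration here shows the
  statistic is correct under its own null, not that real literature
  satisfies that null.
- `generate_network()` draws exactly $m$ distinct ordered non-self
  pairs uniformly (or Erdős–Rényi by probability); real regulatory
  networks are not uniform, so these nets validate metric conventions,
  not biology.
- `generate_gene_sets()` can force an exact intersection size, which
  lets tests rebuild published overlap quadruples as genuine member
  sets.

## Problem sizes and numerical settings

The test suite uses: exhaustive-enumeration oracles on digraphs up to
$n = 8$ (100 random graphs) and on Fisher tables up to $N = 40$;
binomial-tail oracles up to $N = 1000$; a 10,000-gene null panel with
$N \in [100, 300]$ for type-I calibration (expected realized level
0.043 — slightly conservative because the test is discrete); 5,000
hypergeometric replicates for overlap calibration; 1,000 random
parameter draws for margin conservation. These sizes give stable
verdicts in well under a minute per suite file. Tolerances: $10^{-12}$
relative against brute-force oracles, $10^{-7}$ against
`fisher.test` (whose internal tie handling differs in the last digits).

## Known limitations

- The co-occurrence model standardizes one observed proportion against
  population rates; it does not adjust for age, smoking, alcohol, HPV
  status, or any covariate, and inherits any selection bias of the
  source cohort (e.g. a heavily male surgical cohort).
- $p_0$ misspecification in the literature statistic shifts every
  p-value monotonically; conclusions about *counts* of significant
  genes are sensitive to it even when rankings are not.
- Overlap enrichment treats genes as exchangeable; study-bias-aware
  nulls (popular genes appear in both lists more often) are out of
  scope.
- Path assembly is set intersection with sign bookkeeping — evidence
  synthesis, not causal inference.
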