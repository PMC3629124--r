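---
title: "Deriving stage-specific signatures of totipotency and pluripotency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving stage-specific signatures of totipotency and pluripotency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemsig)
```

## The problem

Human pre-implantation development passes through three reference states that
can be profiled transcriptionally: totipotent single blastomeres of day-3
embryos, the pluripotent inner cell mass (ICM) of the blastocyst, and human
embryonic stem cell (hESC) lines adapted to culture. `stemsig` derives, from a
genes-by-samples expression matrix over these three groups, the gene signature
specific to each state — a totipotency signature (TS), an in-vivo pluripotency
signature (IVVPS) and an in-vitro pluripotency signature (IVTPS) — restricted
to a curated "undifferentiation network signature" (UNS): a seed list of known
undifferentiation markers expanded with genes that interact heavily with it.

The design this implements is extremely unbalanced (the default emulated
design is 41 blastomeres, 2 ICMs, 5 hESC lines), which is why the differential
expression core uses empirical-Bayes variance moderation rather than gene-wise
t-tests: with 45 residual degrees of freedom pooled across genes, even the
two-sample ICM group yields usable statistics.

## Pipeline and models

### Preprocessing

Raw scanner intensities, when supplied, are background-corrected with the
normexp convolution model: an observed intensity is $X = B + S$ with
$B \sim N(\mu, \sigma^2)$ background and $S \sim \mathrm{Exp}(\alpha)$ signal.
`normexp_fit()` maximizes the convolution likelihood by BFGS over
$(\mu, \log\sigma, \log\alpha)$ from method-of-moments starting values;
`normexp_adjust()` returns the closed-form posterior mean
$E[S \mid X = x] = m + \sigma\,\phi(m/\sigma)/\Phi(m/\sigma)$ with
$m = x - \mu - \sigma^2/\alpha$, evaluated on the log scale so the
Mills ratio stays finite far into the background tail. The result is strictly
positive and monotone in $x$, so corrected intensities can always be
log2-transformed. Because the main simulator generates log2-scale data
directly, the pipeline treats normexp as an optional first step
(`run_all(normexp = TRUE)`), exercised against raw-scale draws from
`simulate_raw_intensities()`.

Quantile normalization maps every sample column onto the across-sample mean
of order statistics. Ties within a column receive the mean of the target
values their rank span covers — a deterministic, permutation-invariant rule;
on tie-free data the operation is idempotent and equalizes column
distributions exactly.

PCA treats samples as observations and genes as variables, with gene-wise
centering and no unit-variance scaling (the standard convention for
log-expression data; scaling would let the many near-constant background
genes drown the signal). Explained-variance fractions are eigenvalues over
their total. Running PCA on all genes and again restricted to the UNS
(`pca_expr(exprs, uns)`) shows the concentration of stage signal in the UNS
as a larger PC1 fraction.

### Moderated differential expression

For each gene a one-way three-group model gives group means and a pooled
residual variance $s^2_g$ on $d_g = N - 3$ degrees of freedom. The
empirical-Bayes layer assumes $1/\sigma^2_g \sim \chi^2_{d_0}/(d_0 s_0^2)$
and estimates $(d_0, s_0^2)$ by moment matching on $\log s^2_g$: the excess
of the empirical variance of $e_g = \log s^2_g - \psi(d_g/2) + \log(d_g/2)$
over $\psi'(d_g/2)$ is inverted through the trigamma function (Newton
iteration) to give $d_0$, and the mean equation gives $s_0^2$. Moment
matching was chosen over full maximum likelihood because it is closed-form,
deterministic and the field-standard estimator for this model. Degenerate
inputs are handled explicitly: genes with $s^2_g = 0$ are excluded from
prior estimation but still shrunk; zero excess dispersion yields
$d_0 = \infty$ with the prior set to the geometric mean of the observed
variances, so identical variances give a posterior equal to the common value.

The moderated statistic for a pairwise contrast is
$t_g = (\bar{y}_A - \bar{y}_B)/(\tilde{s}_g\sqrt{1/n_A + 1/n_B})$ with
$\tilde{s}^2_g = (d_0 s_0^2 + d_g s^2_g)/(d_0 + d_g)$, referred to a
$t$ distribution on $d_0 + d_g$ degrees of freedom. The three contrasts
(hESC−blastomere, hESC−ICM, ICM−blastomere) are each BH-adjusted across
genes. Significance for downstream clustering uses BH-adjusted p < 0.05 by
default; the threshold can be applied to raw p instead
(`significance_config(use_adjusted = FALSE)`) since published analyses of
this kind sometimes report the raw-scale cutoff — adjusted is the default
as the defensible reading when both an FDR procedure and a 0.05 cutoff are
stated together.

### UNS construction

`select_connectors()` expands the curated seed list: a network node outside
the seed list becomes a connector when it has at least `k_min = 15` distinct
seed-list interaction partners, counted on the simple undirected graph —
duplicate edges, self-loops and edge-type labels do not affect the count.
Distinct-neighbor degree on the simple graph is the standard reading of
"interaction partners"; the threshold is inclusive. Raising `k_min` can only
shrink the connector set, and selection is idempotent. Seed genes absent
from the network remain in the UNS (curation outranks network coverage).

### Cluster assignment

Each UNS gene is assigned to one of seven clusters from its significant
contrasts: clusters 1/2 are blastomere-specific up/down (TS), 3/4 ICM
(IVVPS), 5/6 hESC (IVTPS), and 7 collects genes with no significant
difference. The decision rule had to resolve a genuine ambiguity: a gene can
be significant in only one contrast, which involves two cell types. The rule
implemented scores each cell type by the number of significant contrasts it
participates in; the top scorer owns the gene, with ties broken by the
larger absolute deviation of the cell type's mean from the pooled
(sample-weighted) mean of the remaining samples. If the owner's significant
contrasts imply conflicting directions (for example up versus blastomeres
but down versus ICMs), the gene is flagged ambiguous and parked in cluster 7
rather than forced into a signature — the six signature clusters admit only
consistent directions. A `strict` mode requires both of the owner's
contrasts to be significant, for users who prefer the conservative reading.
Direction is the sign of the owner mean minus the pooled-others mean;
percentages in summaries are rounded to the nearest integer, matching how
such tables are conventionally reported.

### Network statistics and enrichment

Signature subnetworks are induced subgraphs that keep isolated members (so
"unbound" genes are visible); degree reports break each gene's neighbors
down by their primary compartment attribute (nucleus, cytoplasm, plasma
membrane, extracellular space, with an `unspecified` bucket), and the
compartment counts always partition the neighbor set. Genes carrying
multiple localizations are represented by a primary compartment only; counts
use the primary. Untyped edges load as `functional`, and an edge labelled
both `physical` and `biochemical` collapses to `both`. Export targets SIF
plus an attribute table, or GraphML.

Enrichment is the exact hypergeometric (Fisher) over-representation test:
$p = P(X \ge k)$ for $X \sim \mathrm{Hypergeom}(N, K, n)$, with
under-representation available by flag; only over-representation is flagged
by default since that is what such signature comparisons report.
Fine-grained annotations are first rolled up to a GO-slim vocabulary by
true-path propagation through the (acyclic) ancestor map; terms reaching no
slim ancestor are reported, not silently dropped. The comparison battery
runs UNS versus the gene universe and each signature versus the universe at
a strict $\alpha = 0.005$ (these comparisons produce very many enriched
terms, so a restrictive level is the informative one), and each signature
versus the UNS and versus each other signature at $\alpha = 0.1$ (these are
close comparisons where even suggestive enrichment is worth flagging).
BH adjustment is applied within each comparison family, since each
query/background pair is its own testing problem. The "genome" background is
the gene universe of the expression matrix — the array-universe convention —
keeping the analysis self-contained. For signature-versus-signature
comparisons the background is the union of the two signatures, so the exact
test's query-within-background requirement holds.

## The synthetic-data generator

`sim_config()` encodes the emulated study: 41/2/5 samples, a 2000-gene
universe, a 191-gene seed list, 75 planted connectors, and planted
signatures of 61 (17 up / 44 down), 21 (17 up / 4 down) and 107 (83 up /
24 down) genes — the 107 split follows the reported ~78% up-regulated
share. Planted genes get a log2 shift of `effect_size` (default 3.0) in
their owning group; residuals are i.i.d. Gaussian with `noise_sd = 0.5` on
the log2 scale, a realistic residual spread for normalized log2 array data.
The effect default is deliberately large relative to the noise
(6 noise s.d.) because the two-sample ICM group caps detectable effects;
recovery claims are made under that detectability condition and a null mode
(`effect_size = 0`) exercises calibration. The ICM group stays at n = 2
precisely to stress the variance-shrinkage path.

The network generator wires every planted connector to at least 15 distinct
seed genes and every background gene to at most 14, so connector selection
at the threshold separates exactly; typed edges and compartment attributes
are sampled for realism. The annotation generator builds a 33-term slim
vocabulary with three children per slim term and plants one child term in a
chosen signature at annotation probability `p_in = 0.6` against a
`p_out = 0.08` background.

What the generator does *not* emulate: probe-level artifacts (spatial
effects, dye bias), correlated gene modules, heavy-tailed or
intensity-dependent noise, multi-compartment localization, and annotation
structure beyond a two-level ontology. Passing recovery tests therefore
demonstrates that the pipeline's logic is correct under its own model
assumptions, not that real arrays of this design would yield these recovery
rates.

Gene identifiers are synthetic (`G000001`...) with an alias slot so
well-known marker names (POU5F1, NANOG, ...) can be injected into fixtures
without depending on annotation databases.

## Numerical choices

- Normexp likelihood and posterior mean use `pnorm(log.p = TRUE)` /
  `dnorm(log = TRUE)` throughout; the fit is parameterized in
  $\log\sigma, \log\alpha$ to keep the optimizer unconstrained.
- Trigamma inversion runs Newton on the monotone convex map with asymptotic
  starts for extreme arguments; convergence tolerance 1e-8 relative.
- Quantile-normalization tie spans are computed from min- and max-ranks with
  a cumulative-sum lookup, avoiding an $O(n^2)$ scan.
- Exact-test tails are computed by `phyper`, never by summing floating-point
  point masses in the implementation; enumeration appears only as a test
  oracle.
- All simulators restore the caller's RNG state and are parameterized by a
  single integer seed; the three generators decorrelate by fixed offsets
  from it.

The test suite runs the unit tiers on a reduced design (18 samples,
400 genes) and the deep checks at the full emulated design (48 samples,
2000 genes, five replicate seeds for recovery; 50 000 draws for normexp
recovery; 5000 genes for hyperparameter recovery) — sizes chosen so the
statistical claims are sharp at conventional tolerances.

## Known limitations

- The assignment rule's tie-break depends on group sizes through the pooled
  mean; with extreme imbalance a single-contrast gene's attribution can be
  sensitive to the larger group.
- The empirical-Bayes estimator assumes a common $d_g$ across genes (true
  for complete designs); missing values are not supported.
- The slim rollup assumes the ancestor map is acyclic and does not check for
  cycles; a cyclic map would loop the closure walk's frontier to exhaustion
  but with wasted work.
- Enrichment treats annotations as flat sets after rollup; term-term
  dependence (shared genes between slim terms) is not modeled in the
  adjustment, which is the standard practice this mirrors.

## A worked run

```{r, eval = FALSE}
cfg <- sim_config(rng_seed = 42)
run <- run_simulation_study(cfg)
run$uns                 # seed/connector/UNS sizes
run$report              # seven-cluster table
signature_recovery(run) # planted-membership recovery
run$enrichment$flagged  # over-represented slim terms per comparison
```
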