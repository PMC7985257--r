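---
title: "Methods: nestedness, null models and specialization in plant-AM fungal networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nestedness, null models and specialization in plant-AM fungal networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestweb)
options(nestweb.quiet = TRUE)
```

# The scientific question

Herbaceous plants host communities of arbuscular mycorrhizal (AM) fungi in
their roots. Aggregating sequencing reads per host species turns a
sample-by-OTU count table into a bipartite interaction matrix — hosts in
rows, fungal OTUs in columns — and the structure of that matrix carries
ecological signal. Two structural axes matter here:

* **Nestedness**: do specialists interact with subsets of the partners of
  generalists? Nested networks are considered robust to species loss.
* **Specialization / segregation**: how strongly does each species deviate
  from using partners in proportion to their availability, and do partner
  sets repel each other (checkerboards)?

The package implements the full measurement stack for a two-site
(e.g. rural vs urban) comparison of such networks, plus a synthetic
generator so that every stage is testable end to end without sequencing
data.

# From reads to a network

The preprocessing chain mirrors standard practice for amplicon data:

1. **Rare-cluster filtering** (`filter_rare_otus`): OTUs with summed reads
   strictly below a proportion of the grand total (default `1e-6`, i.e.
   0.0001%) are removed as probable sequencing-error clusters. The
   threshold uses the *grand* total over all samples, and strict
   inequality, so the operation is idempotent.
2. **Low-depth exclusion** (`exclude_low_depth_samples`): samples whose
   target-taxon yield is below the rarefaction depth carry no usable
   community signal and are dropped before rarefaction. The exclusion
   threshold and the rarefaction depth are deliberately separate
   configuration values.
3. **Rarefaction** (`rarefy_table`): each sample is subsampled without
   replacement (multivariate hypergeometric) to a common depth — the
   default 4,227 reads reflects a realistic minimum yield for root AM
   fungal libraries. One draw is taken per sample; the seed is explicit
   and the draw is reproducible.
4. **Aggregation** (`aggregate_to_network`): replicate plot samples are
   pooled (summed) within host species at one site; OTUs absent from the
   site are dropped. Summing, rather than averaging, matches the
   convention of building quantitative interaction matrices from pooled
   libraries; a `"mean"` option is exposed for users who prefer per-plot
   averages.

# Nestedness: NODF, max-NODF, NODFc

`nodf()` scores every unordered pair of rows and of columns. For one pair,
let `MT_hi >= MT_lo` be the marginal totals. The pair contributes its
*paired overlap* — the percentage of the lower-marginal member's presences
also held by the higher-marginal member — but **only when the marginals
differ strictly** (the "decreasing fill" rule); ties contribute zero. NODF
is the mean over all `m(m-1)/2 + n(n-1)/2` pairs, 0–100. Under this
convention a strict staircase scores exactly 100 and a checkerboard 0,
which is how the implementation is anchored in tests; the tie rule also
explains why nearly-full matrices score *low* even though they contain
many overlapping pairs.

Raw NODF is well known to depend on size and connectance, so the package
also provides the corrected index

`NODFc = NODF / max(NODF) / (C * ln S)`,

with `C = fill/(m n)` the connectance, `S = sqrt(m n)` the geometric-mean
richness, and `max(NODF)` the maximum achievable NODF over binary matrices
with the same dimensions and number of links and no empty row or column.
The logarithm is natural by default; the base is a configuration knob
since published applications are not always explicit about it.

`max_nodf()` solves the inner optimization:

* instances with `m * n <= 16` cells are solved by exhaustive enumeration;
* larger instances start from a left-packed nested staircase template and
  hill-climb with random single-cell moves (empty rows/columns are never
  created). Later restarts randomize the template and perturb it away from
  the staircase, because at minimal fill the template is unique and the
  staircase is not always the optimal shape. Plateau moves are accepted
  with probability 0.25 so the search can traverse tie regions; the best
  visited state is returned.

The default budget is 10 restarts of 5,000 moves. Restart seeds are
derived deterministically from the user seed, and a larger budget explores
a superset of the smaller budget's trajectory, so the returned value is
monotone in the budget at fixed seed — a property the tests assert. The
pipeline uses a reduced budget (4 restarts x 2,000 moves) because on the
8 x 81 networks it analyses the search is within ~0.3 NODF units of the
large-budget value at a quarter of the cost.

# Null models and standardized effects

Three randomization schemes are implemented behind one testing interface
(`null_test`):

* **EE** (`ee_null`): the observed number of presences is scattered
  uniformly over all cells. Fill is preserved exactly; empty rows or
  columns may occur and are legal in replicates (pairs involving an empty
  line simply contribute zero to NODF). Rejecting such replicates would
  bias the null upward.
* **FF** (`ff_null`): each cell is an independent Bernoulli draw with
  `p_ij = (P_i / C + P_j / R) / 2`, the mean of the row and column
  incidence proportions. `sum(p_ij)` equals the observed fill
  analytically, so fill is preserved in expectation while marginal
  structure is respected probabilistically.
* **swap-web** (`swap_web_null`): quantitative randomization preserving
  row sums, column sums *and* the number of realized links exactly, via
  marginal-conditioned random tables adjusted by connectance-changing 2x2
  transfers. The heavy lifting is vegan's C implementation
  (`quasiswap_count`); matrices without checkerboard units (perfectly
  nested or full binary views), which that implementation refuses, are
  handled by an in-package fallback that implements the same
  draw-then-adjust construction in R.

Empirical P-values use the add-one convention
`P = (#{null >= obs} + 1) / (reps + 1)`: a finite ensemble can never
produce P = 0, and the resulting test is exactly calibrated under
exchangeability (the type-I test in the acceptance suite verifies the
0.05-level rejection rate on null-generated matrices). The standardized
effect size is `z = (obs - mean(null)) / sd(null)`; when the null has zero
variance, z is reported as the explicit undefined marker `NA` with a
warning — never as 0 — while P is still computed from counts. Replicate
defaults are 999; the classic ANINHADO-style 50-replicate variant is a
configuration choice, not a different code path.

Per-link and per-species tests (`link_zscores`, `dprime_zscores`) compare
each observed cell weight (or each species' d') with its distribution over
a swap-web ensemble; `|z| > 1.96` and `|z| > 2.576` (strict inequalities)
flag the 0.05 and 0.01 levels. No multiple-testing correction is applied
at the link level, matching common practice for these network link maps;
the report carries an explicit note, and users can correct the emitted z
matrix themselves if they prefer.

# Specialization: d' and H2'

Species-level specialization d' is the Kullback-Leibler divergence of a
species' partner-use distribution `p'` from partner availability `q`
(partner marginals over the grand total), rescaled to `[0, 1]` by its
achievable extremes at the species' integer total:

* `d_max = ln(1 / min q)` is analytic: the most specialized achievable
  allocation is a point mass on the least-available partner (the maximum
  of a convex function over the integer simplex sits at a vertex).
* `d_min` is the minimum of the divergence over integer reallocations of
  the species' total. Because the objective is *separable convex* on the
  integer simplex, largest-remainder rounding of the continuous optimum
  (`a = A q`) followed by single-unit exchange descent terminates at the
  global minimum — no random restarts are needed, which is why the
  implementation uses an exact descent rather than a restart heuristic.
  An exhaustive enumeration path (`method = "exact"`) exists for small
  totals and is used to validate the descent in tests.

A species with a single interaction (or a one-partner network) has
coinciding extremes; d' is then reported as the undefined marker `NA`
with a warning, since the index carries no information there.

Availabilities `q` are always computed from the site-level matrix being
analysed, not pooled across sites, so each site's d' values are
self-contained.

Network-level H2' standardizes the two-dimensional Shannon entropy `H2` of
the interaction frequencies between its extremes at fixed marginals:
`H2' = (H2_max - H2) / (H2_max - H2_min)`. The extremes are genuine
integer optimization problems over the transportation polytope:

* `H2_max` (most generalized): largest-remainder rounding of the
  independence table `r c' / T` repaired to exact margins, then
  entropy-increasing 2x2 unit moves. Entropy is concave along any cycle,
  so unit moves suffice directionally; on small matrices the search runs
  exhaustive improving-move sweeps to a clean pass.
* `H2_min` (most specialized): greedy concentrated filling (repeatedly
  pair the largest remaining row with the largest remaining column) with
  randomized pairings across 100 restarts, then entropy-decreasing moves
  including full 2x2 transfers. Entropy minimization is non-convex, hence
  the restarts; the randomized pairing matters because the strict greedy
  can pair the largest row with the "wrong" column and strand the search.

Instances whose margin-constrained table space is small are solved
exactly by enumeration, and the search path is validated against
exhaustive enumeration in the acceptance tests. If the heuristics ever
overshoot (H2' outside `[0, 1]`), the value is clamped with a logged
warning rather than silently.

The C-score (`c_score`) counts checkerboard units between species pairs on
one margin: `CU = (r_i - S_ij)(r_j - S_ij)`, normalized per pair by
`r_i * r_j` and averaged. Among the published normalizations this is the
one with the clean `[0, 1]` range and the right endpoints — any nested
matrix scores exactly 0 (one factor vanishes for every pair) and the 2x2
identity scores 1 — which is why it was chosen; the choice matters when
comparing absolute C-score values across studies. Checkerboards are
defined on presences, so the C-score is computed on the binary view.

# The synthetic two-site generator

`synthetic_config()` defines a community of `n_hosts = 8` hosts and
`n_fungi = 81` fungal OTUs with `plots_per_host = 5` replicate samples of
`reads_per_sample = 4227` reads each — the scale of a realistic two-site
root-sequencing study, and the scale at which all full-size tests run.
Each host's preference over fungi has three structured components and one
noise component:

* a shared geometric rank-abundance backbone `exp(-lambda * rank)`
  (steeper `lambda` → presences concentrate on leading fungi → decaying
  fungal marginals, the raw material of nestedness);
* host-specific steepness multipliers spread by `breadth` (narrow hosts
  sample prefixes of what broad hosts sample, giving deterministically
  nested rows; `breadth = 0` collapses all hosts onto one shared vector);
* a host-private specialist component weighted by
  `gamma / (1 + gamma)` (private fungi assigned round-robin), which
  raises d', H2' and between-host Bray-Curtis dissimilarity;
* ranking noise `epsilon`: each host's preference *ranking* is an
  interpolation between the shared ranking and host-private uniform
  random scores. This contaminates the alignment between hosts — the
  actual source of cross-host nestedness — while leaving each host's
  profile shape, and hence matrix fill, essentially unchanged. At
  `epsilon = 1` host rankings are independent.

The noise knob was designed this way deliberately: contaminating the
preference *mass* with a uniform floor instead would saturate fill at
this sequencing depth (a 1% uniform floor already implies ~5 expected
reads in every cell), and NODF would respond to the fill change, not to
the loss of structure. With ranking noise, mean NODF falls and the
C-score rises monotonically in `epsilon` — opposite directions, as
segregation replaces nesting — and both responses are asserted as rank
correlations in the test suite.

Reads are drawn multinomially per plot (no overdispersion; a
Dirichlet-multinomial knob is future work and deliberately absent so that
parameter-recovery tests are not confounded). Identical seeds give
byte-identical outputs.

Two presets encode the study regimes:

* `rural_config()`: `lambda = 20, gamma = 1, epsilon = 0.05, breadth = 1`
  — sparse, strongly nested incidence, specialist-enriched, divergent
  hosts;
* `urban_config()`: `lambda = 10, gamma = 0.1, epsilon = 0.05,
  breadth = 0.25` — denser, flatter, generalist-enriched, convergent
  hosts.

These values were fixed once from a response-surface exploration of the
generator and are not tuned per analysis. Under them, the rural-like
network is significantly nested against EE nulls while the urban-like one
is not, urban NODF sits below rural NODF, urban connectance above rural,
and d', H2', C-score and between-host dissimilarity are all higher in the
rural-like regime — the full qualitative contrast the pipeline is meant
to detect.

Two honest caveats about what the generator does *not* show. First,
multinomial sampling at finite depth caps achievable NODF around 65–75:
the occupancy transition zone scales with the decay rate, so "perfect"
nestedness (NODF near 100) is unattainable for any `lambda`; tests
therefore assert *strong and significant* nestedness, not near-perfect
scores. Second, the specialization knob lowers NODF only on sparse
(steep-`lambda`) baselines; on dense baselines extra private mass
*raises* NODF by breaking marginal ties. Direction-of-effect tests
condition on the sparse regime, where the contrast of interest lives.
Passing tests on synthetic data demonstrate that the measurement stack
recovers planted structure of realistic size and effect strength; they do
not certify behavior under real-data features the generator omits
(overdispersion, plot-level spatial structure, taxonomic error).

# Diversity and the host-convergence comparison

Alpha diversity (`sample_diversity`) uses natural logarithms throughout:
Shannon `H = -sum p ln p`, Simpson `D = 1 - sum p^2`, Pielou
`E = H / ln S` (undefined marker for single-species samples), and Faith's
PD as the branch-length sum of the minimal rooted subtree spanning the
present tips (root-inclusive, via picante). Diversity is computed on
rarefied counts — filter, exclude, rarefy, then measure.

Host convergence is measured by Bray-Curtis dissimilarity
`BC = sum|x - y| / sum(x + y)` between aggregated per-host abundance
vectors (the network rows). Computing BC from the aggregated vectors
rather than from per-sample vectors is a documented default — the
site-level network is the object under study — and the per-sample route
remains available by calling `bray_curtis` on any vectors of interest.
The cross-site comparison pairs the `m(m-1)/2` host-pair dissimilarities
across sites and applies a classical paired t test; BC is not a metric
(no triangle inequality), which is irrelevant for this paired comparison
but worth remembering before feeding the matrices to methods that assume
metricity.

# Numerical conventions

* **Undefined-marker policy**: any mathematically undefined quantity
  (Pielou at S = 1, BC of two zero vectors, z at zero null variance, d'
  at coinciding extremes, NODFc of a full matrix) returns `NA` plus a
  warning. Nothing is silently coerced to 0.
* **Seeds**: one global seed fans out to stage-specific child seeds via a
  fixed integer map, so rarefaction, each null ensemble and the optimizer
  are independently reproducible; all derived seeds stay below 2^31.
* **Strictness**: the rare-OTU threshold, the decreasing-fill rule and
  the 1.96/2.576 significance cuts are all strict inequalities.
* **Problem sizes**: unit tests run on reduced communities (4-8 hosts,
  10-60 fungi, hundreds of reads); the acceptance suite runs the
  full-scale defaults (8 x 81, 4,227 reads x 5 plots, 50 study
  replicates, 999-replicate nulls in the acceptance script). These sizes
  are the package's documented reference conditions.

# Known limitations

* The max-NODF search is exact only for `m * n <= 16`; beyond that it is
  a stochastic lower-bound maximizer (tests assert it dominates sampled
  matrices and is budget-monotone).
* H2_min is a heuristic for large matrices; its quality is validated
  exhaustively only on small instances.
* Weighted nestedness variants, other nestedness indices (temperature,
  spectral radius), modularity and robustness simulations are out of
  scope, as are mixed-model analyses of diversity and the
  Adonis/ANOSIM/MRPP family, which standard packages already provide.
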