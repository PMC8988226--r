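---
title: "Methods: co-occurrence network analysis of paired urogenital microbiomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occurrence network analysis of paired urogenital microbiomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and model

`urogenet` analyses genus-level 16S rRNA count tables from two paired body
sites (vagina and bladder) across two cohorts (cases and controls). The
analysis has five stages:

1. **Preprocessing.** Rarefaction without replacement to a fixed depth per
   site (defaults 15,000 reads for vaginal and 2,500 for bladder samples),
   an abundance filter keeping genera that *strictly exceed* 5% relative
   abundance in at least one sample, and frequency-based contaminant
   screening against DNA concentration.
2. **Diversity.** Observed genera, inverse Simpson, Pielou evenness;
   Bray-Curtis and (un)weighted UniFrac distances; PCoA; PERMANOVA with
   sequential sums of squares, covariates first and the cohort term last.
3. **Community-state typing.** Ward.D2 hierarchical clustering of the
   weighted UniFrac matrix, cut at the number of clusters `k` in 2..6 that
   maximizes the mean silhouette width, plus Fisher-type association tests
   between cluster membership and categorical covariates.
4. **Co-occurrence networks.** SparCC correlations per cohort x site, an
   edge threshold from a permutation null computed on the pooled site
   table, networks over positive supra-threshold correlations only,
   map-equation (InfoMap-style) community detection, weighted modularity,
   normalized connectance, betweenness-centrality keystone screening at a
   0.10 cutoff, and per-focal-taxon neighbour tables.
5. **Overlap.** Shared genus sets between the two sites per cohort, Venn
   counts, and per-genus median percent relative abundance by site grouped
   by phylum.

## SparCC

Counts are compositional: only relative information survives sequencing,
so Pearson correlations on proportions are biased. SparCC works on
log-ratio variances. With fractions $f_i$ drawn from a per-sample
Dirichlet posterior (unit pseudocount), the variation matrix is
$t_{ij} = \mathrm{Var}\,\log(f_i/f_j)$. Under sparsity the approximation
$t_{ij} \approx \omega_i^2 + \omega_j^2$ identifies the basis log-variances
$\omega_i^2$ through the linear system with matrix $(D-2)I + \mathbf{1}$,
and correlations follow as
$\rho_{ij} = (\omega_i^2 + \omega_j^2 - t_{ij}) / (2\omega_i\omega_j)$,
clamped to $[-1, 1]$.

Numerical choices:

* **Exclusion.** The sparsity assumption is protected by iteratively
  excluding the strongest pair with $|\rho| > 0.1$ from the system (one
  pair per iteration, up to 10 iterations), re-solving after each
  exclusion. A pair is not excluded if doing so would leave a taxon with
  fewer than two remaining partners (the system would become singular).
* **Aggregation.** The returned matrix is the element-wise *median* over
  20 inner resamples: a robustness choice, insensitive to the occasional
  degenerate resample.
* **Degeneracy.** Basis variances are floored at $10^{-12}$ before taking
  square roots; if the linear system is singular the diagonal
  approximation $\omega_i^2 = \sum_j t_{ij} / M_{ii}$ is used.

## Permutation-null threshold

Each of 1,000 trials (100 in the documented fast mode used by CI and the
pipeline tests) permutes every genus column independently across samples —
destroying all between-genus association while preserving each genus's
marginal distribution — and refits SparCC. All off-diagonal correlations
are pooled into a single null distribution, and the edge threshold is its
empirical 95th percentile (`tail = 0.05`). A pooled rather than per-pair
null is used: with $D$ genera a trial yields $D(D-1)/2$ null values, so
the pooled quantile is stable at modest trial counts, and the published
description speaks of a single null distribution per site. The threshold
is computed on the pooled site table (cases and controls together), with
the per-cohort option available by simply passing a subset table.

## Map equation and community detection

For an undirected weighted network with total edge weight $W$, a random
walker visits node $i$ at rate $p_i = s_i/2W$ ($s_i$ = strength). For a
partition into modules $m$ with exit rates
$q_m = (\text{boundary weight})_m / 2W$, the two-level codelength is

$$L = q\,H(Q) + \sum_m p_m^{\circlearrowright} H(P_m),\qquad
q = \sum_m q_m,\quad p_m^{\circlearrowright} = q_m + \sum_{i \in m} p_i.$$

`detect_communities()` minimizes $L$ greedily: single-node moves to
neighbouring modules while improvements exist, then merges of adjacent
modules, repeated to convergence, with the best of 10 seeded restarts
returned. On graphs of up to 8 nodes the optimizer attains the exhaustive
global minimum in at least 95 of 100 random graphs (acceptance test); on
larger graphs it is a heuristic, like all map-equation optimizers.
Modularity is reported for the detected partition — the published tables
print one modularity per network without naming the partition, so tying it
to the map-equation partition is this package's documented choice.

## Betweenness and keystones

Betweenness uses the *unweighted* topology. Correlation magnitude is a
similarity; feeding it to a shortest-path algorithm as a cost would invert
its meaning, and no weighting scheme is stated in the source analysis.
Brandes' accumulation algorithm is used, normalized by $(N-1)(N-2)/2$.
Keystone candidates are taxa with normalized betweenness strictly above
0.10, a cutoff chosen in the motivating study because ~90% of observed
values fell below it.

## Contaminant screening

For each genus present in at least 5 samples, two one-parameter models of
log relative abundance are fit on the presence samples: a contaminant
model linear in log DNA concentration with slope fixed at $-1$, and a
constant-frequency null. The score is
$\mathrm{pf}(\mathrm{RSS}_{contam}/\mathrm{RSS}_{null},\, n-1,\, n-1)$ —
small when the inverse-concentration signature fits well. Genera scoring
below the threshold (0.3 bladder, 0.5 vaginal, following the published
values) are removed. Below 5 presence samples the two models are not
distinguishable, so such genera are left unscored and retained. The score
is invariant to rescaling all concentrations by a positive constant. Note
that 0.5 is an aggressive threshold: under the null the score concentrates
near 0.5, so residents are removed at a non-trivial rate when the
concentration spread is small relative to biological variance — visible in
the synthetic study as a few false removals.

## The synthetic world

`simulate_counts()` draws latent log-basis abundances from a multivariate
normal with a *planted* correlation matrix, exponentiates, normalizes, and
samples counts multinomially at log-normal depths. This matches the
generative assumptions under which SparCC's basis correlations are
identified, which is exactly what makes recovery tests interpretable: a
planted pair at $\rho = 0.8$ ($D = 50$, $n = 100$) must be recovered
within $\pm 0.15$ on average.

Design choices that are part of the stated world (not tuning knobs):

* **Study shape.** 20 cases / 30 controls, two sites, 66 vaginal and 131
  bladder genera, mirroring the motivating study's counts.
* **Dominance.** "Dominated" samples give *Lactobacillus* a log-mean shift
  of +8 (median relative abundance ~0.7); "diverse" samples draw from the
  common heavy-tailed pool. Vaginal product use raises the probability of
  the dominated state; menopause lowers it in the bladder.
* **Dispersion.** Per-sample log-normal dispersion 2.3 with taxon-level
  base unevenness sd 0.5. The heavy tail is what lets most of a
  131-genus pool exceed the 5% filter somewhere, as real genus tables do.
* **Depths.** Log-normal around 45,000 (vaginal) and 20,000 with sdlog 0.9
  (bladder), so a few bladder samples fall below the 2,500 rarefaction
  depth and exercise the drop-and-report path.
* **Contaminants.** Expected relative abundance proportional to 1/DNA
  concentration with multiplicative log-normal noise, the signature the
  frequency classifier detects.
* **Hub design.** The nominal "hub correlated at 0.6 with 8 otherwise
  independent leaves" matrix is *not* positive semidefinite (its smallest
  eigenvalue is $1 - 0.6\sqrt{8} \approx -0.70$; with mutually
  uncorrelated leaves the feasible maximum is $1/\sqrt{8} \approx 0.35$).
  `hub_correlation()` therefore projects the nominal matrix to the nearest
  correlation matrix (eigenvalue clipping + unit-diagonal rescaling),
  giving realized hub-leaf $\approx 0.40$ and leaf-leaf $\approx 0.04$.
  The hub-recovery acceptance test runs on this projected, feasible world.

What the generator does **not** emulate: read-level error, chimeras,
taxonomy misassignment, cohort-dependent genus pools (the two cohorts
share one pool per site, so cross-site overlap differs between cohorts
only through sampling), and phylogenetic signal in abundances (the tree is
random, so UniFrac structure comes only from the dominance contrast). A
green test therefore establishes correctness of the statistical machinery
on data satisfying the model's assumptions — not robustness to upstream
artifacts.

## Other numerical decisions

* **Ward.D2** is implemented by the Lance-Williams recursion on squared
  dissimilarities with square-rooted merge heights; the published text
  mentions both "ward.D2" and "complete linkage", and `ward.D2` (the
  quoted `hclust` method name) is taken as operative.
* **Silhouette ties** across `k` break toward smaller `k` (parsimony).
* **Fisher r x c tables** beyond 2 x 2 use the same point-probability rule
  estimated by seeded Monte Carlo over `r2dtable` draws (default 1e5).
* **Weighted UniFrac** defaults to the normalized variant (the common
  implementation default); the flag is explicit because the source
  analysis does not say.
* **PERMANOVA** uses sequential sums of squares with the adjusted term
  (cohort) last, 999 permutations by default; the published analysis does
  not state its permutation count or covariate order, so these defaults
  are documented rather than asserted as the original ones.
* **Preprocessing order.** Whether contaminant screening preceded or
  followed the abundance filter is unstated in the source; the pipeline
  default is filter-then-decontam with `decontam_first = TRUE` available.
* **Seed fan-out.** The pipeline derives per-stage seeds as
  `(seed * 7919 + stage_index * 104729) mod (2^31 - 1)`, so any stage
  rerun in isolation with its derived seed reproduces the full run.

## Known limitations

Permutation thresholds at 1,000 trials dominate runtime (the fast mode
trades threshold precision for speed; the pooled null makes this cheap in
accuracy terms). The map-equation optimizer and betweenness are exact-ish
only at the scales tested. Published headline numbers (e.g. thresholds
0.23/0.22, silhouettes 0.63/0.50, Table 4/7 centrality values) require the
deposited sequencing cohort and are out of scope for desk-scale
verification; the connectance and Fisher worked examples in
`tests/testthat/test-acceptance.R` are the values recomputable from
printed inputs alone.
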