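---
title: "Classifying cultivar collections with nuclear and chloroplast SSRs"
author: "ssrpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying cultivar collections with nuclear and chloroplast SSRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Collections of clonally propagated tree cultivars — chestnut is the motivating
case — accumulate three kinds of uncertainty over decades of exchange between
orchards and genebanks: the same clone circulates under several names
(*synonyms*), the origin of hybrid selections is forgotten, and the geographic
structure of the founding material is unknown. Codominant nuclear
microsatellites (SSRs, scored as integer fragment sizes, both alleles of a
diploid observed) plus a handful of haploid, maternally inherited chloroplast
SSRs are the standard instrument for all three questions.

`ssrpipe` implements the classical three-step workflow as composable,
seed-reproducible functions:

1. **identity** — find synonym groups, deduplicate, quantify the panel's
   discrimination power (probability of identity);
2. **relationship** — Bayesian admixture clustering of the unique genotypes,
   exclusion parentage for hybrid cultivars, seed/pollen role assignment from
   chloroplast haplotypes;
3. **structure** — admixture within one species' cultivars, per-group
   diversity statistics, principal coordinate analysis.

A synthetic-data generator with complete ground truth
(`simulate_dataset()`) stands in for real collection data, so every stage of
the pipeline is testable end to end.

```{r, eval = FALSE}
library(ssrpipe)
sim <- simulate_dataset(sim_config(seed = 1))
report <- run_pipeline(sim$gm, out_dir = "run1", seed = 1)
```

# Data model

A `genotype_matrix` holds individuals (cultivar name + group code) against a
nuclear panel (unordered diploid allele-size pairs, stored low-allele-first)
and a chloroplast panel (haploid calls). A call with either half missing is
treated as wholly missing. Allele identity is exact integer equality of
fragment sizes; the package does no binning, which matches how collection
studies publish their genotype tables. Two text dialects are supported by
`read_genotypes()`/`write_genotypes()`: a plain tabular layout
(`name,group,<locus>_1,<locus>_2,...,<cploci>`) and the GenAlEx codominant
layout, with `0`/empty as the missing code in both. Group codes are data, not
an enum; the twelve codes of the default generator layout (`J_KA`, `J_TA`,
`J_OJ`, `KOR`, `HYB`, `C_SJ`, `C_IO`, `C_HE`, `C_SH`, `C_JI`, `C_AN`,
`C_OR`) are only a default vocabulary.

# Synonym detection and probability of identity

Two cultivars are synonymous when their genotypes agree at every nuclear
locus at which **both** are typed (`max_mismatch = 0`; a tolerance can be
set). Missing-data handling follows the usual clonal-identification
convention: loci untyped in either member are ignored, and an individual
typed at fewer than half the loci is flagged and never matched — too little
information to call it a clone of anything. Synonymy is closed transitively;
each group's representative is its first occurrence in input order, which
makes deduplication deterministic without favouring any particular name.

Internally, complete multilocus genotypes are grouped by hashing (linear
time); only individuals with missing calls, or scans with a nonzero
tolerance, fall back to pairwise comparison. The test suite holds this
equal to an all-pairs union-find oracle on hundreds of random matrices with
planted clones.

The discrimination power of the panel is the probability of identity: the
chance that two individuals drawn from a Hardy–Weinberg population share a
single-locus genotype,

$$PI = \sum_i p_i^4 + \sum_{i<j} (2 p_i p_j)^2 = 2 a_2^2 - a_4,
\qquad a_k = \sum_i p_i^k,$$

multiplied across independent loci for the panel (`pi_panel()`). The naive
(Paetkau) form is the default and headline statistic; the small-sample
bias-corrected variant (Waits, Luikart & Taberlet 2001) is available via
`unbiased = TRUE`. Note that the correction is unbiased when its sample size
is counted in *gene copies*; the package uses `n_genes` accordingly (a
Monte-Carlo bias check guided this choice).

# Chloroplast haplotypes

Cultivars with the identical combination of alleles at **all** chloroplast
loci carry the same haplotype; an individual with any missing chloroplast
call is left unassigned rather than fuzzily matched, because the defining
rule is exact. Labels `HAP1, HAP2, ...` are assigned by decreasing frequency
with first-occurrence tie-break — a deterministic rule — and a reference map
lets users pin an established labelling (novel tuples then continue the
numbering). `haplotype_table()` produces the group-by-haplotype count table.
Because the chloroplast is maternally inherited in *Castanea*, an
offspring's haplotype identifies its seed parent among candidates — the
lever used in role assignment below.

# The admixture model

`run_admixture()` is a Gibbs sampler for the classical admixture model with
the *independent* allele-frequency prior and no origin information (the
model popularised by Structure; Pritchard, Stephens & Donnelly 2000). For
individual $i$, gene copy $c$ at locus $l$:

$$z_{icl} \sim \mathrm{Categorical}(q_i), \qquad
  x_{icl} \mid z_{icl}=k \sim \mathrm{Categorical}(p_{kl}),$$
$$p_{kl} \sim \mathrm{Dirichlet}(\lambda, \ldots, \lambda), \qquad
  q_i \sim \mathrm{Dirichlet}(\alpha, \ldots, \alpha),$$

with one $\alpha$ shared across clusters under a Uniform$(0,
\alpha_{\max})$ hyperprior. Each sweep samples all $z$ from their
conditionals $\propto q_{ik}\, p_{k,l,a}$, then $p_{kl}$ from
Dirichlet($\lambda$ + assigned counts), then $q_i$ from Dirichlet($\alpha$ +
assigned copy counts), then updates $\alpha$ by a Normal random-walk
Metropolis step. Missing copies are skipped in every count. Defaults follow
the canonical implementation of this model: $\lambda = 1$, $\alpha$
initialised at 1, $\alpha_{\max} = 10$, proposal sd 0.025.

Design choices worth stating explicitly:

* **Posterior means, not MAP**, define the reported membership matrix Q and
  frequency simplices P — memberships are continuous quantities, as in the
  familiar bar plots.
* **Label switching** is handled after the fact: `align_runs()` permutes
  replicate runs onto the first run's labelling by exhaustive search over
  the $K!$ column permutations ($K \le 8$ keeps this trivial), minimising
  $\sum |Q - Q_{\mathrm{ref}}|$. The chain itself stays exact, with no
  identifiability constraint.
* **Model evidence** is estimated from the post-burn-in log-likelihood trace
  as $\widehat{\ln P(D)} = \bar L - \mathrm{var}(L)/2$, the harmonic-style
  estimator traditionally paired with this model. The trace records the
  complete-data log-likelihood given the current $(Z, P)$; a test recomputes
  it from the final sweep's state and requires agreement to $10^{-8}$.
* **Two run profiles** ship as named configurations: `"desk"` (20,000
  post-burn-in sweeps, 2,000 burn-in, 3 replicates), which the package's own
  validation uses, and `"full"` (1,000,000 / 100,000, 10 replicates)
  matching the traditional long-run protocol. On well-separated pools the
  desk profile is already stable to ±0.01 in Q between replicates.
* **Convergence diagnostics** are deliberately limited to trace inspection
  and replicate concordance after alignment.
* The sampler core is C++ (Rcpp), drawing all randomness through R's RNG,
  so a seed makes runs bit-identical.

## Choosing K: the Evanno criterion

`evanno_delta_k()` implements the second-difference criterion

$$\Delta K = \frac{\mathrm{mean}_r\,\bigl|L_r(K-1) - 2L_r(K) +
L_r(K+1)\bigr|}{\mathrm{sd}_r\, L_r(K)}$$

over replicate evidence estimates. A K whose replicates have zero standard
deviation is *flagged* as undefined, never silently 0 or infinite. Because
the second difference needs both neighbours, $\Delta K$ exists only for
interior K of the scanned range: a scan that should be able to conclude
"K = 2" must include K = 1. `admixture_scan()` therefore takes an explicit
contiguous range (e.g. `1:5`) and derives per-run seeds from one base seed.

## Membership classes

For K = 2, `classify_membership()` applies the conventional thresholds:
first-cluster membership above 0.8 is cluster-1-dominant, below 0.2
cluster-2-dominant, anything between (boundaries included) admixed. A
membership of 0.78 is admixed — deliberately inclusive at the boundary.

# Exclusion parentage

A candidate parent is excluded at a locus where it shares no allele with the
child (both typed); a candidate pair is excluded at a locus where the
child's two alleles cannot be drawn one from each parent (all four phase
assignments fail). Following long-standing practice, one discrepant locus is
tolerated (`tol = 1`) to absorb genotyping errors, null alleles and
mutation; the tolerance applies to both the pairwise and the trio counts,
since the convention is stated in the literature for parent–offspring
relationships generally. Loci with a missing call in any member of a comparison are
excluded from that comparison, not counted as mismatches. Self-pairs are
excluded by default (chestnut is self-incompatible) but can be enabled.

When several candidate pairs survive, all are reported ranked by
incompatibility count — the package deliberately adds no likelihood-based
disambiguation, as exclusion is the published method. Seed and pollen roles
come from chloroplast haplotypes (`assign_roles()`): the parent matching the
child's haplotype is the seed parent; both-match or neither-match is
ambiguous; a single-parent hypothesis gets a role only when decisive. With
31 polymorphic loci, random non-parents survive the `tol = 1` screen at
well under 5% (a property the acceptance tests measure).

# Group diversity

Per group with at least `min_group_size` members (default 9, i.e. "more
than 8"):

* $H_O$ — fraction of typed individuals heterozygous, averaged over loci;
* $H_E = 1 - \sum_i p_i^2$ (Nei), optionally with the $2n/(2n-1)$
  small-sample correction (off by default, matching the convention of the
  standard desktop tools);
* $F = (H_E - H_O)/H_E$ per locus, monomorphic loci excluded. The headline
  F is the **mean of per-locus ratios**, not the pooled ratio of means —
  the convention of the standard desktop tools, whose printed F values are
  reproduced by per-locus averaging rather than by the ratio of the printed
  mean heterozygosities. Both forms are returned.
* AR — rarefaction allelic richness: the expected number of distinct
  alleles among $g = 2 n_{\mathrm{ref}}$ gene copies drawn without
  replacement (El Mousadik & Petit 1996; Hurlbert 1971),
  $$AR = \sum_i \left[ 1 - \binom{N - N_i}{g} \middle/ \binom{N}{g}
  \right].$$
  `n_ref` is counted in diploid individuals — the default 9 gives
  $g = 18$ gene copies, the natural floor when the smallest qualifying
  group has exactly 9 members. Binomial coefficients are evaluated in log
  space; loci with fewer than $g$ typed copies are excluded with a warning.

# Ordination

`squared_distance()` implements the Smouse–Peakall squared distance for
codominant data, the metric behind the "covariance-standardized" PCoA of
the familiar desktop pipeline. Writing a single-locus genotype as its
allele-count vector $x$ (entries summing to 2), the per-locus contribution
is $\tfrac12\sum_i (x_i - y_i)^2$, equivalently the genotype-pair pattern
$d^2(ii,ii) = d^2(ij,ij) = 0$, $d^2(ii,ij) = d^2(ij,ik) = 1$,
$d^2(ij,kl) = 2$, $d^2(ii,jk) = 3$, $d^2(ii,jj) = 4$. Distances sum over
co-typed loci; when missing data thin a pair's loci the sum is rescaled by
(total loci / co-typed loci) — a declared choice, since desktop tools
interpolate instead in some modes. A pair with no co-typed locus is an
error, not a guess.

`pcoa()` is classical scaling: Gower double-centering of $-\tfrac12 D^2$,
eigendecomposition, coordinates $v_k\sqrt{\lambda_k}$ for positive
eigenvalues. Negative eigenvalues (possible under missing-data rescaling)
are reported but excluded from coordinates and from variance percentages,
which are computed over the positive spectrum and sum to 100. Axis signs
follow a deterministic convention (first non-negligible loading positive)
so replicate outputs are comparable.

# The synthetic-data generator

`simulate_dataset()` emulates the statistical structure the analysis
assumes, with complete ground truth:

* **Two ancestral gene pools** diverged by the Balding–Nichols
  construction: per locus, an ancestral frequency vector $p$ from a
  symmetric Dirichlet(1), then pool frequencies from
  Dirichlet$(p\,(1-F)/F)$. One parameter $F$ (default 0.2) controls
  separability — the quantity the admixture recovery tests exercise —
  without simulating drift generation by generation.
* **Groups** with fixed ancestry: the default layout has 12 groups
  totalling 200 individuals (14/21/25/6/18/27/5/13/25/10/9/27), four
  pool-1 groups, seven pool-2 groups and one 18-member F1 hybrid group,
  mirroring a realistic collection's shape.
* **Pedigreed hybrids**: F1s are recorded crosses between random members of
  the two pools (seed side chosen at random); each offspring inherits one
  uniformly chosen allele per locus from each parent and the seed parent's
  chloroplast haplotype. First backcrosses (F1 × pool 1) are available.
* **Chloroplast pools**: pool 1 draws from {HAP1 0.95, HAP2 0.05}, pool 2
  from {HAP3 0.55, HAP4 0.35, HAP5 0.05, HAP6 0.05} — the skewed,
  pool-diagnostic distribution typical of cultivated germplasm, with two
  dominant and several rare haplotypes.
* **Artifacts** (`inject_artifacts()`): clones appended under derived names
  (default 30, planted only in pool-2 groups, where duplicate names
  historically accumulate), per-call missingness (default 1%), and ±2
  allele-size-shift errors (default 0.2%) on a 2-unit allele ladder so
  shifted alleles stay in-ladder. Every change is logged.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: null alleles and allele dropout, stutter or
binning ambiguity, linkage between loci, isolation-by-distance within
pools, homonyms, and any coalescent-realistic site-frequency structure.
The generator answers "does the machinery recover known structure", not
"how will a specific collection behave".

# Validation scale and numerical choices

The package validates itself (testthat suite plus
`scripts/acceptance.R`) at the scale the workflow targets: 31 nuclear
loci with 4–8 alleles, pools of 50 pure individuals plus 18 F1s at
$F = 0.2$ for admixture recovery (20,000-sweep desk profile, Q RMSE
below 0.1 required), a K = 1..5 scan with 3 replicates and 4,000-sweep
chains for the Evanno ordering, 200 random 100-individual matrices for
the synonym oracle, and 100,000-draw Monte-Carlo rarefaction for the AR
oracle. Degenerate cases have declared behaviour rather than accidents:
an all-missing locus is excluded with a warning everywhere; zero
between-replicate variance flags ΔK as undefined; a Monte-Carlo band
tighter than one draw's resolution is floored at that resolution; an
under-typed individual is flagged out of synonym matching; Dirichlet
draws are floored at 10⁻¹⁰⁰ so log-densities stay finite.

# Limitations

* Exclusion parentage reports all surviving hypotheses; it cannot rank
  competing pairs probabilistically (no LOD scores) and assumes candidate
  panels are genotyped on the same ladder as the children.
* The admixture model here is the independent-frequency variant only — no
  correlated frequencies, linkage model, or location priors.
* PI assumes Hardy–Weinberg and locus independence; in structured or inbred
  collections the true match probability is higher than the product form.
* The evidence estimator $\bar L - \mathrm{var}(L)/2$ is known to be rough;
  it is used only comparatively, inside the ΔK criterion, never as an
  absolute model probability.
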