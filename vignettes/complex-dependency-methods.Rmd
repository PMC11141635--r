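---
title: "Methods: complex-level selective dependency analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: complex-level selective dependency analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(complexdep)
```

## The problem

Genome-wide CRISPR knockout screens assign every gene in every screened
cell line a *gene effect* (Chronos/CERES-style) score: roughly 0 when the
knockout is neutral, around −1 for common-essential genes, and below
−0.3 where knockout measurably impairs growth. A *selective* dependency
is a gene — or, more interestingly, a whole protein complex — whose
scores are systematically more negative in a biologically defined
subgroup of lines (here, a MYCN-amplified neuroblastoma-like subgroup)
than in all other lines. Complex-level analysis matters because a
coactivator complex can be a coherent therapeutic target even when no
single subunit is the strongest individual hit.

`complexdep` implements the full screen-arm pipeline (differential
dependency → complex enrichment → per-line metagene scores), a
rule-based MYCN amplification-status classifier, a paralog-redundancy
screen, and the bespoke parts of spike-in calibrated ChIP-seq region
quantification. A seeded synthetic generator supplies inputs with the
statistical structure each stage assumes, so every claim the package
makes is testable offline.

## Differential dependency: the moderated t

For a gene $g$ with $n_{in}$ subgroup and $n_{out}$ background lines
(missing values removed per gene per group), the pooled residual
variance $s_g^2$ on $d_g = n_{in} + n_{out} - 2$ df is shrunk toward a
prior:

$$\tilde{s}_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g}, \qquad
  t_g = \frac{\bar{x}_{in} - \bar{x}_{out}}
             {\tilde{s}_g \sqrt{1/n_{in} + 1/n_{out}}}$$

on $d_0 + d_g$ df. The prior $(d_0, s_0^2)$ is estimated across genes by
method of moments on $\log s_g^2$: the expectation and variance of the
log of a scaled chi-square variable are linear in digamma/trigamma of
the half-dfs, so matching the observed mean and spread of
$e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$ and inverting the
trigamma function yields closed-form estimates. Two finite-sample
conventions follow the standard empirical-Bayes linear-model
implementation and are verified against it in the test suite to
$\sim 10^{-10}$: when the observed spread of $\log s^2$ is no larger
than the residual df alone explains, $d_0 = \infty$ with
$s_0^2 = \mathrm{mean}(s^2)$; and the total df is capped at the pooled
residual df, since the prior is estimated from the same genes. Setting
`d0 = 0` recovers the classical pooled two-sample t exactly.

Degenerate inputs are reported, never silently dropped: zero variance
with zero effect gives $t = 0, p = 1$; zero variance with nonzero effect
gives a p at the smallest representable double and a
`zero_variance_nonzero_effect` flag; groups reduced below two values by
missingness are emitted with `NA` statistics and a reason.

## Preranked enrichment

Genes are ranked descending by the moderated t (ties broken
lexicographically by identifier, so rankings are deterministic). For a
set $S$ in a ranked list of $N$ genes with scores $s_j$ and weight
exponent $p$ (default 1, the weighted scheme; 0 gives the classic KS
statistic), the running sum adds $|s_j|^p / \sum_{S}|s|^p$ at in-set
positions and subtracts $1/(N - |S|)$ elsewhere; the enrichment score
ES is the signed extremum. The null is gene-label permutation: random
sets of identical size drawn from the ranked universe under an explicit
seed, shared across sets of the same size. NES divides ES by the mean
same-sign permutation ES; the nominal p is the one-sided frequency of
same-sign permutation ESs at least as extreme; the FDR follows the
global ratio-of-tails scheme on NES, with Benjamini–Hochberg on the
nominal p available (`fdr_method = "bh"`) and preferable when `n_perm`
is small. Sets with no same-sign permutations get `NA`, not 0. The
conventional hit filter (|NES| ≥ 1.3, p ≤ 0.05, FDR ≤ 0.25) is exposed
as `significant_enrichments()` and never hard-coded, since volcano-style
displays often use a plain p cutoff instead.

The implementation is checked three ways: an exhaustive brute-force
running-sum oracle over all subsets of size ≤ 4 of lists of length
≤ 12, the independent `fgsea` statistic on larger random instances, and
exact permutation enumeration on 6-gene toys against the Monte-Carlo
null at 10,000 draws. One numerical knife edge is documented: when the
running sum attains $+m$ and $-m$ with equal magnitude, the signed
winner depends on floating-point summation order; only the magnitude is
stable there.

## ssGSEA metagene scores and z-scores

Per sample, genes are ranked descending and the set score is the *sum*
over all list positions of the difference between the weighted in-set
empirical CDF (weights $r^\alpha$ on average ranks, $\alpha = 0.25$)
and the uniform out-of-set CDF — an integral, not an extremum, so
coordinated moderate depletion of a complex's members accumulates.
Scores are range-normalized over the whole set × sample matrix by
default. Complex-level dependency z-scores are obtained by
standardizing each set across samples (sample sd, $n-1$); which samples
form the reference axis is the caller's choice, since the score is
relative by construction. Constant rows yield all-zero z-scores with a
warning rather than dividing by zero.

## MYCN status classifier

Evidence per line: copy number on the $\log_2(\mathrm{CN}/2+1)$ scale,
expression as $\log_2(\mathrm{TPM}+1)$, and any literature-reported
status. Four rules fire in order: (1) cn ≥ 3 → amplified, or
inconsistent if reported not-amplified; (2) medium cn in $[1.10, 3)$
with expression ≥ 5 or a reported amplification → amplified; (3) medium
cn with expression < 3 or reported not-amplified → not-amplified;
(4) cn < 1.10 with expression ≥ 5 and reported not-amplified →
inconsistent. Anything else is *undetermined*: the evidence gap
(medium cn, expression in [3, 5), no report) is reported as such rather
than guessed, because a curation step outside this package's scope is
what resolves it in practice. Boundary conventions are explicit: the
medium interval is half-open so rules 1 and 2 are disjoint, cn = 3
belongs to rule 1, and expression = 5 satisfies the high-expression
bound. A line with expression ≥ 5 but reported not-amplified at medium
cn satisfies both rule 2 and rule 3; rule order resolves it (amplified)
and a warning flags the conflict, since the source phrasing ("and/or")
does not.

## Paralog-redundancy screen

Lines dependent on an anchor gene are selected by a strict score
threshold (default < −0.3). Across those lines, a query gene's
dependency is correlated with every expressed gene's expression
(expressed = maximum $\log_2(\mathrm{TPM}+1) \ge 1$, a filter that can
be disabled): Pearson r, $t = r\sqrt{n-2}/\sqrt{1-r^2}$, two-sided
t-distribution p, BH q. A redundant paralog appears as the strongest
correlation with a positive sign — dependency deepens (more negative)
where the partner's expression is low. The slope F-test for a single
gene pair is algebraically $t^2$ on $(1, n-2)$ df and is verified
against the standard linear-model fit; a constant response returns
slope 0, F 0, p 1 by convention.

## Spike-in ChIP quantification

Scale factors are the cross-sample mean of exogenous (dm6) spike-in
read totals divided by each sample's total, so scaled spike-in totals
are all exactly the pre-scaling mean — an invariant the tests assert
identically, not approximately. Peak curation drops regions with
$\log_2(\mathrm{AUC}+1)$ below 13 in the calling sample (the boundary
value 8191, whose transform is exactly 13, is retained) and regions
overlapping a blacklist interval by ≥ 1 bp; curation is idempotent and
its removal bookkeeping sums to input − output. Condition peak sets are
merged as interval unions with abutting intervals coalesced
(half-open coordinates throughout, so intervals sharing only a boundary
point do merge, while blacklist overlap requires a shared base).

Differential regions combine two gates: an effect-size gate on the
difference of per-condition means of $\log_2(\mathrm{AUC}+1)$
(|delta| ≥ 1.5 — the log scale is the only reading under which a fixed
cutoff is scale-free, and deltas are computed after spike-in scaling
when factors are supplied), and a significance gate (p ≤ 0.10) from a
likelihood-ratio test on read counts under a negative-binomial model
with a common dispersion estimated across regions by method of moments.
A common (not per-region) dispersion is a deliberate simplification of
the tagwise/trended GLM machinery of dedicated count packages: with the
handful of replicates typical of ChIP designs, per-region dispersions
are noise, and the common estimate keeps the test tractable and
transparent. For small designs an exact group-relabeling permutation of
the LRT statistic is available (`method = "permutation"`); on a
zero-noise 3v3 fixture it yields p = 2/20 = 0.10 exactly, which the
tests use as an oracle for the NB path's classification. Regions with
zero counts everywhere are `not_significant` with p = 1.

## The synthetic generator

`generate_screen()` draws per-gene Gaussian scores around the class
center (−1 for the configured common-essential genes, 0 otherwise,
sd 0.2), shifts embedded complex members by −Δ in the target subgroup,
links one paralog pair's dependency to its partner's expression
(`dep_A = slope · (expr_B − mean) + noise`, positive slope so low
partner expression deepens the score), and attaches per-line MYCN
evidence spanning all four classifier regimes including the exact
boundary values 1.10, 3 and 5. Defaults are the package's study
conditions: 1000 genes, 200 common-essential, 100 lines with a 20-line
subgroup, one embedded 8-gene complex at Δ = 0.6, 30 decoy sets of size
5–15, paralog slope 0.25. The score sd of 0.2 is an arbitrary but
realistic choice (public releases do not publish a single dispersion);
it puts the false-dependency rate of a null gene at
$\Phi(-1.5) \approx 6.7\%$ per line, which the tests check. Decoy sets
are drawn from non-essential genes *excluding* embedded members, so
recovery tests compare the embedded complex against true negatives.
Everything is driven by one integer seed through a locally scoped
Mersenne-Twister generator (inversion normals), so equal configurations
produce byte-identical bundles and the caller's RNG state is never
disturbed.

What the generator does not emulate — and what passing tests therefore
do not show about real screens: guide-level count noise and the score
fitting itself, copy-number artifacts, correlated off-target effects,
lineage-specific expression programs, heavy-tailed score outliers, and
batch structure between screening projects. Recovery rates measured
here are upper bounds on what identically parameterized real data would
give.

Problem sizes in the shipped tests are chosen to make every
distributional check stable yet quick: recovery uses 20 replicates of a
500-gene × 100-line screen with 200 permutations per set size; null
calibration uses 2000 genes; the permutation-oracle fixtures use 3v3
designs where the relabeling null is exact.

## Known limitations

- The NB dispersion is common across regions; strongly heteroskedastic
  signal (e.g. promoters vs broad domains in one table) would be better
  served by the trended estimators of dedicated count packages.
- The GSEA FDR uses the global same-sign NES ratio; at very small
  `n_perm` it is coarse, which is why `fdr_method = "bh"` exists.
- The classifier is deliberately conservative: it never resolves the
  evidence gap without a report, so `undetermined` calls are expected
  on sparse annotations.
- Matrices are dense in memory; genome × biobank-scale inputs should be
  subset before loading.
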