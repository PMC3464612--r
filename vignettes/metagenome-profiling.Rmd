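---
title: "Metagenome profiling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metagenome profiling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The profiling idea

A *metagenome profile* is the vector of read counts obtained by aligning a
sample's untargeted shotgun reads against an arbitrary reference contig
collection: with $n$ contigs in the reference, each sample becomes a point
in $\mathbb{N}^n$. Nothing about the reference needs to be annotated, and
the reference need not even come from the same host species — it is only an
alignment target. Samples are then compared through their profiles:
hierarchically clustered, decomposed into variance components, or tested
contig by contig between groups. This vignette explains the models behind
each stage, the tunable parameters and their defaults, and the design
choices that were genuinely open.

```{r}
library(metaprof)
```

## Read quality control

Reads are trimmed from the 3' end one base at a time, recomputing the mean
Phred score after each removal, until the mean is *strictly above*
`min_mean_quality` (default 20); reads whose surviving prefix is shorter
than `min_length` (default 50 bases) are discarded. Equivalently, the kept
read is the longest prefix with mean quality above the threshold. Two
details are conventions rather than forced choices and are therefore part
of the documented contract:

* *strictness* — a read whose best prefix averages exactly 20.0 is
  discarded ("above" is read literally);
* *direction* — bases are removed from the 3' end only, because quality
  degrades toward the end of the read on the short-read platforms this
  workflow targets. No per-window or adapter logic is attempted
  (`fastp` and friends exist for that); this stage reproduces the simple
  mean-quality accounting, including percent-of-reads and
  percent-of-basepairs retained.

Qualities are Phred+33 by default; a configurable `offset` covers legacy
+64 data. Paired reads are filtered independently — no mate rescue.

## Counting and normalisation

Each mapped, *primary* alignment record with `mapq >= min_mapq` (default 0,
i.e. whatever the aligner reported) increments exactly one contig;
secondary and supplementary records never count, so the column sums equal
the number of qualifying reads. Unmapped records still count toward the
library total, which is what makes "percent aligned" meaningful. Reads are
counted per end by default; `count_pairs = TRUE` counts a pair once if
either end maps, since published tallies are sometimes by read and
sometimes by pair.

Library sizes are equalised before distance computations. The default is
`head_subsample()` — take the first $N$ records of each alignment stream —
matching the historical practice of extracting the first $N$ reads per
library; `downsample_matrix()` offers seeded multivariate-hypergeometric
rarefaction for files whose record order is confounded with anything.
Each sample draws from its own RNG substream (derived from the seed and
the sample id), so one sample's draw is independent of which other samples
are present.

Contigs with a total of fewer than `min_total = 10` reads across samples
are dropped before model fitting (`filter_min_reads()`); zero-count
contigs are *retained* in the matrix itself because presence/absence
tallies need them.

## Distances and clustering

Two dissimilarities are supported on the normalised matrix:

* **Canberra** for counts:
  $d(x,y) = \sum_i |x_i - y_i| / (|x_i| + |y_i|)$, with terms where
  $x_i = y_i = 0$ omitted. Each term lies in $[0,1]$, which makes the
  distance sensitive to proportional change in rare contigs — appropriate
  when most of the signal sits in low-abundance features. Note a subtle
  and easily missed discrepancy: `stats::dist(method = "canberra")`
  *rescales* the sum by `n/n_used` when zero–zero terms are omitted.
  `profile_dist()` implements the plain omitted sum by default and offers
  `rescale = TRUE` to reproduce `stats::dist` exactly.
* **binary** for presence/absence: the fraction of mismatched positions
  among positions present in at least one sample (identical to
  `stats::dist(method = "binary")`).

Clustering is agglomerative Ward via the Lance–Williams recurrence applied
to the dissimilarities as given (`"ward.D"`, the historical default;
`"ward.D2"` squares them first). Merge heights are recorded exactly as
produced — `ward.D` on raw dissimilarities can in pathological cases
produce non-monotone heights, and silently reordering them would misstate
the tree. Delegating to `stats::hclust` means tie-breaking among equal
minimum distances follows `hclust`'s deterministic rule; on count-derived
distances ties have measure zero.

## Multiscale bootstrap support

Ordinary bootstrap support (BP) for a dendrogram edge is the fraction of
replicates — contigs resampled with replacement, samples fixed — in which
the same leaf set reappears as an edge. BP is known to be biased as a
p-value; the multiscale bootstrap corrects it by resampling to *different
sizes* $n' = r\,n$ over a grid of ratios (default $r = 0.5, 0.6, \dots,
1.4$, `B = 1000` replicates per scale) and extrapolating.

With $\sigma_r = \sqrt{1/r}$ and $z_r = \Phi^{-1}(1 - \mathrm{BP}_r)$, the
signed-distance/curvature model

$$ z = v\,/\sigma + c\,\sigma $$

is fitted by weighted least squares with weights
$B\,\phi(z_r)^2 / (\mathrm{BP}_r(1-\mathrm{BP}_r))$, and

$$ \mathrm{AU} = 1 - \Phi(v - c), \qquad
   \mathrm{BP}_{\text{fit}} = 1 - \Phi(v + c). $$

Here $v$ (on $1/\sigma = \sqrt{r}$) is the signed distance to the cluster
boundary and $c$ the boundary curvature; a strongly supported edge has a
large negative $v$ and AU near 1. Sign conventions differ across
write-ups, so this one is part of the contract, and `fit_au()` is
calibration-tested: for BP curves generated exactly from known $(v, c)$,
the fit recovers both to $10^{-6}$ and, with $c = 0$, AU equals the fitted
BP. Numerical guards: frequencies are clipped to $[1/2B,\, 1 - 1/2B]$
before the probit transform; an edge recovered in no (every) replicate at
every scale is reported as AU $= 0$ ($1$) with `fit_ok = FALSE`. Whether
"1000 iterations" means per scale or in total is ambiguous in common
usage; here `B` is per scale, the convention of the reference
implementation of the method.

Edge identity is exact leaf-set equality — no partial credit for nearly
matching clades.

## Variance components

The crossed random-effects model for the long count table is

$$ Y_{ijk} = \mu + \mathrm{unit}_i + \mathrm{contig}_j + \mathrm{animal}_k
   + e_{ijk}, $$

where the *unit* is the rumen sampling position (top/bottom/mix) or the
sample type (rumen fluid/faeces), and all three factors are random with a
single fixed mean. The response is the raw count with Gaussian errors.
That is statistically crude for counts — heteroscedastic, skewed — but it
is the model this analysis tradition uses, so it is the default and its
crudeness is documented rather than papered over; `log1p = TRUE` offers a
variance-stabilised alternative. Percent-of-total for each component is
$\hat\sigma^2_f / \sum_g \hat\sigma^2_g \times 100$ with all four
components (including residual) in the denominator, so the percent column
sums to 100.

Estimation is REML via `lme4`, with one extra step: the profiled REML
criterion is flat enough near its optimum that off-the-shelf convergence
leaves variance components accurate only to about $10^{-5}$ relative. For
`precision = "high"`, Newton steps on a Richardson-extrapolated
finite-difference gradient of the profiled deviance polish the optimum
until, on balanced designs, the REML estimates agree with the closed-form
ANOVA (expected-mean-squares) estimators — implemented independently in
`anova_varcomp_balanced()` as $\hat\sigma^2_f = (MS_f - MS_E)\,a_f/N$ —
to better than $10^{-6}$ relative. The ANOVA estimator truncates negative
solutions at zero and flags them; agreement is only claimed for interior
solutions, where the two estimators coincide theoretically.

Each factor's significance comes from a REML likelihood-ratio test against
the model without that factor, referred to the boundary-corrected mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ (the null value $\sigma^2 = 0$ sits
on the boundary of the parameter space). The test is conservative; its
type-I error is verified to stay at or below nominal by simulation. Stars
in the printed table follow `***` = p < 0.001.

## Two-group comparisons

For a two-group design (e.g. rumen fluid vs faeces), `overlap_summary()`
classifies every contig with any reads as unique to one group or shared —
presence being a positive group total on the *raw* counts. Per-contig
differential representation uses Student's equal-variance t-tests on the
*normalised* matrix (Welch by flag); whether published analyses of this
kind used raw or normalised counts is typically unstated, and normalised
is the defensible default since library size is a nuisance. Degenerate
contigs are resolved by convention: zero variance with equal means gives
p = 1, zero variance with unequal means gives p = 0 with a flag.

The empirical FDR at threshold $\alpha$ is
$$ \mathrm{FDR} = 100 \cdot \min(1,\ m\alpha/k)\ \%, $$
with $m$ the number of tested contigs (all contigs with any reads — the
sum of the unique/unique/shared classes) and $k$ the number significant.
This expected-false-positives-over-observed-significant construction is
the only formula consistent with all the published FDR values this
package reconstructs; Benjamini–Hochberg (`fdr_bh()`) is available as the
modern alternative. One reconstructed cell disagrees with its source by
0.1 percentage point (9.95% rounds to 10.0, printed as 9.9); the printed
inputs admit no rounding rule that reproduces every cell, and the
discrepancy is recorded in the test suite rather than hidden.

`correlation_compare()` correlates every profile of one group with every
profile of the other (Pearson by default, Spearman by flag) and tests
same-animal against different-animal pairs with a two-sample t-test —
the "does the faecal profile predict the rumen profile of the same
animal" question.

## Depth sufficiency

`depth_series()` replays the clustering at increasing head-subsampled
depths; `group_purity()` asks whether each group (e.g. each animal's
samples) forms an exact clade and with what minimal AU; and
`minimal_adequate_depth()` reports the first depth at which all groups are
monophyletic with AU at least `au_threshold` (default 0.95). "Samples
separate by animal" is a qualitative judgement in the source tradition;
exact monophyly plus an AU threshold is this package's operationalisation
of it. Head subsampling (not random rarefaction) is used, matching how
the libraries are normalised.

## The synthetic-community generator

`sim_params()` defines the generative model used as ground truth
everywhere: log-abundance of contig $j$ in the sample from animal $k$,
unit $i$ is

$$ \log a_{j(ik)} = b_j + A_{jk} + U_{ji} + \varepsilon, $$

with $b_j \sim N(\mu_b, \sigma_b^2)$ the baseline (log-normal community),
$A$ and $U$ the animal and unit effects, and everything softmax-normalised
to a probability vector from which reads are drawn multinomially at a
fixed depth. Defaults emulate the repeat-sampling study design: 3 animals
× 3 rumen positions × 200 contigs, $\sigma_b = 1.5$ (contig effects
dominate, as they do in real profiles), $\sigma_A = 0.3$,
$\sigma_U = 0.05$ (host effect well above position effect), residual
log-noise $0.1$, and 50,000 reads per sample. The depth default is chosen
so multinomial sampling noise (count CV $\approx \sqrt{200/50000} = 0.06$)
sits below the residual log-noise, as it does in real libraries of
millions of reads; at much lower depths sampling noise competes with the
planted effects and clade support genuinely degrades — which is precisely
the behaviour the depth-sufficiency analysis measures. The `"faeces"`
preset switches to 7 animals × 2 sample types with
$\sigma_U = 0.6 \gg \sigma_A = 0.1$, mirroring the observation that sample
type dwarfs host animal in the two-site comparison.

Because every sample's counts are normalised to the same depth, a planted
animal effect moves counts *within* the profile but cannot move a sample's
mean count — the crossed model's animal *main effect* is structurally zero
under the default generator. Real libraries differ: animals differ in
what fraction of their reads align at all. `aligned_frac < 1` adds an
unaligned compartment subject to the same animal/unit effects, so aligned
totals vary by animal and the mixed model has a real main effect to find;
the variance-ordering checks use `aligned_frac = 0.05`, the scale of real
alignment rates to a same-environment reference.

`simulate_reads()` emits actual FASTQ (qualities around Q35 with 3' decay,
so the trimmer has nontrivial work) plus a truth SAM recording each read's
source contig, which lets the whole read-level pipeline be tested without
any external data: counting the truth alignments must reproduce the
planted count matrix exactly. The generator deliberately omits indels,
chimeras, platform error profiles and paired-end insert modelling — tests
passing on it demonstrate the *statistical* machinery, not robustness to
alignment artefacts.

## Problem sizes used in validation

The shipped validation suite runs at desk scale, chosen to exercise every
code path with tight Monte-Carlo bounds: distance/linkage oracles on 100
random matrices (up to 7 samples, exhaustive Lance–Williams replay);
variance-component recovery on 200 balanced datasets of 5 animals × 3
units × 200 contigs with planted components $(4, 1, 9, 1)$; LRT size on
500 null replicates; t-test calibration on $10^4$ null contigs and an FDR
check against the realised false-discovery proportion on $2 \times 10^4$
contigs with 2% planted signal; and end-to-end read-level and count-level
pipelines with planted clades. Published quantities whose inputs are fully
printed (the two-group FDR table and the sample-type/animal variance
ratios) are reconstructed exactly; quantities that would require the
original sequencing libraries (retention percentages, alignment rates,
observed tree topologies) are validated in distribution on synthetic data
instead.

## Known limitations

* The Gaussian-on-counts variance model inherits every caveat of its
  tradition; use `log1p` (or a proper count GLMM outside this package) for
  inference you intend to defend.
* AU values are extrapolations; with small `B` or few informative scales
  the (v, c) fit can be poor — `fit_ok` and the per-scale counts are
  exposed so this is inspectable.
* `ward.D` on raw (unsquared) dissimilarities is kept for fidelity to the
  historical default, not because it is the better-behaved variant.
* Edge identity is exact leaf-set equality, so AU for a clade says nothing
  about nearly identical clades.
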