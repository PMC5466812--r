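---
title: "Methods: ecophylogenetics of paired DNA/RNA microbiomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ecophylogenetics of paired DNA/RNA microbiomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Amplicon surveys of a host-associated microbiome sequenced from co-extracted
DNA and RNA observe two views of the same community: the DNA fraction
records who is there, the RNA (cDNA) fraction records who is transcribing
ribosomal RNA, a proxy for metabolic activity. Given per-sample,
per-fraction OTU count tables and a phylogeny over the OTUs, `ecophylo`
answers three questions:

1. How diverse is each community, and how small is the core shared by all
   hosts?
2. Are co-occurring OTUs phylogenetically clustered relative to a null
   expectation (host filtering), or overdispersed (competitive exclusion)?
3. Does relative activity — the mean expression ratio — carry phylogenetic
   signal, i.e., are related OTUs similarly active?

All user-facing functions take a tidy table first and return tibbles, so
stages chain with the pipe; every stochastic step takes an explicit integer
seed and is bit-reproducible.

## The mean expression ratio

For OTU $i$, let $RA_{RNA,is}$ and $RA_{DNA,is}$ be its relative abundances
in the RNA and DNA fractions of sample $s$, and let $n_i$ be the number of
samples in which the OTU appears in the DNA and/or RNA fraction. With
$\overline{RA} = \sum_s RA_{is} / n_i$ taken over exactly those $n_i$
samples (zeros in the other fraction of a supporting sample are real
observations and stay in the mean),

$$\mathrm{ratio}_i =
  \frac{\overline{RA}_{RNA,i}}{\overline{RA}_{RNA,i} +
        \overline{RA}_{DNA,i}} \in [0, 1].$$

The boundary cases are identities, not approximations: an OTU never seen in
RNA has ratio 0, never seen in DNA ratio 1, and exactly mirrored mean
relative abundances give 0.5. The ratio is invariant to fraction-wide
sequencing-depth rescaling because relative abundances cancel depth.

**Standard error.** The construction of the per-OTU SE is genuinely open:
sampling variability could be summarized from the $n_i$ per-sample ratios
$r_{is} = RA_{RNA,is}/(RA_{RNA,is}+RA_{DNA,is})$, or propagated from the
two fraction means. We default to the per-sample-ratio SEM
($\mathrm{sd}(r_{is})/\sqrt{n_i}$) as the most direct reading of
"standard errors over the samples", and expose a first-order delta-method
alternative (`se_method = "delta"`). Both are validated against the
empirical sampling sd under a fixed generative process. OTUs supported by a
single sample have no sample-to-sample SE; because the measurement-error
signal statistic needs finite SEs everywhere, these receive the median SE
of the multi-sample OTUs (flagged in the output, policy configurable via
`n1_se`).

## Community phylogenetic structure

For each sample × fraction community we compute the mean pairwise distance
(MPD) and the mean nearest taxon distance (MNTD) on the patristic distance
matrix, then standardize against a tip-shuffle null: tip labels are
permuted across the phylogeny while community membership, richness,
occupancy and abundances are held fixed. For a single community this is
equivalent to drawing random equally sized communities from the OTU pool.
With 999 permutations plus the observation (a 1,000-permutation test),

$$SES = \frac{\mathrm{obs} - \overline{\mathrm{null}}}{\mathrm{sd}(\mathrm{null})},
\qquad p = \frac{\#\{\mathrm{null} \le \mathrm{obs}\} + 1}{n_{perm} + 1}.$$

The p-value is lower-tailed by default because clustering is the working
hypothesis; a two-tailed option exists. Metrics are presence/absence
(unweighted) by default — the null's fixed-abundance rationale presumes
abundance-free metrics — with abundance-weighted variants available.

Design choices worth stating:

- **Pool definition.** The OTU pool is the union of OTUs across all samples
  and both fractions (`pool = "all"`); the per-fraction pool variant
  (`pool = "by_fraction"`) is the robustness check. An intersection reading
  of the pool would make observed community sizes impossible, so union it
  is.
- **Null validity.** The tip-shuffle null holds abundance patterns fixed,
  which inflates type I error if abundance itself carries phylogenetic
  signal. `structure_table()` therefore computes Blomberg's K on per-OTU
  total abundance up front and warns when it is significant.
- **Degeneracy.** A community equal to the whole pool is shuffle-invariant:
  the null sd is 0, SES is reported as 0 and the row flagged degenerate
  rather than dropped. Communities with fewer than two members are likewise
  flagged, never silently removed.

## Phylogenetic signal: K and Kse

Blomberg's K compares the observed partitioning of trait variance on the
tree with its Brownian-motion (BM) expectation. With the phylogenetic GLS
mean $\hat a = (1'C^{-1}x)/(1'C^{-1}1)$ over the tree's variance–covariance
matrix $C$,

$$K = \frac{(MSE_0/MSE)_{\mathrm{obs}}}
           {\left[\mathrm{tr}(C) - n/(1'C^{-1}1)\right]/(n-1)},$$

where $MSE_0$ is the ordinary mean squared deviation from $\hat a$ and
$MSE$ its $C^{-1}$-weighted counterpart. $K = 1$ matches BM; on a star
phylogeny ($C \propto I$) the statistic is identically 1 for any
non-constant trait, a useful exactness check. K is invariant to affine
trait transformations and to uniform branch-length scaling.

**Measurement error (Kse).** A trait estimated from finitely many samples
is observed with error, which attenuates K. The Kse variant adopts the
observation model $x \sim N(\hat a 1,\; \sigma^2 C + \mathrm{diag}(se^2))$:
the BM rate $\sigma^2$ is estimated by maximum likelihood (profile over
$\log\sigma^2$, GLS mean profiled out; Cholesky solves with a
$10^{-10}\,\mathrm{tr}(C)/n$ jitter retry), and K is then computed with
$C^* = \hat\sigma^2 C + \mathrm{diag}(se^2)$ in place of $C$. Because K is
scale-invariant in $C$, all-zero SEs reduce Kse to plain K exactly. When
the fitted tree variance is negligible against the measurement variance
(ratio below $10^{-3}$) the result is flagged `se_dominated`: the signal is
unidentifiable, not merely weak. The simpler moment plug-in correction was
considered and rejected: it can go negative and has no likelihood
interpretation.

**Significance.** Following the contrast-based formulation, the test
statistic is the variance (mean square) of the phylogenetically independent
contrasts — small when relatives are similar — and the null shuffles trait
values across tips; $p$ is the lower-tail permutation probability. The
statistic is the contrast variance, not K itself, and the test is one-tailed
toward low variance. Under exchangeable (white-noise) traits the test is
exact by symmetry, which the calibration suite verifies.

## Diversity and core

Hill numbers $^qD = (\sum p_i^q)^{1/(1-q)}$ give the alpha-diversity
profile, with richness, exp-Shannon and inverse Simpson at $q = 0, 1, 2$
($q = 1$ via the Shannon limit, $0\log 0 = 0$). Chao1 uses the
bias-corrected form $S_{obs} + F_1(F_1-1)/(2(F_2+1))$ throughout so that
zero doubletons never divide by zero. Bray–Curtis dissimilarity applies the
square-root transform and Wisconsin double standardization (species maxima
first, then sample totals — the ordination convention) before the distance;
the downstream NMDS/Procrustes ordination itself is out of scope.
Rarefaction is a single seeded draw without replacement to a fixed depth
(1,288 reads in the emulated study); under-depth columns are reported and
excluded, never padded. The paired DNA-vs-RNA comparison defaults to the
paired t-test with a signed-rank alternative: the design pairs both
fractions of the same plant, so the paired (signed-rank) test, not the
two-sample rank-sum test, is the coherent nonparametric choice.

The core microbiome is computed on the full (unrarefied) table: `"DNA"` and
`"RNA"` cores require presence in that fraction of every sample, `"both"`
requires presence in both fractions of every sample — equal to the
intersection of the two single-fraction cores. The sampling-effort curve
redraws uniform k-subsets of samples (1,000 resamples per k by default) and
reports mean ± sd of the core size.

## The synthetic-data generator

The generator is first-class, tested code: it produces data with exactly
the statistical structure the analyses assume, so every downstream claim is
checkable without sequencing data. Its defaults state the emulated world:

- **Tree.** Pure-birth (Yule) trees; birth–death would add parameters
  without changing any tested property.
- **Samples.** 19 hosts, the population size of the emulated study; two
  fractions; two technical replicates per fraction (independent multinomial
  draws from the same latent composition, feeding the replicate-consensus
  filter).
- **Latent abundances.** Log-normal (meanlog 0, sdlog 1.5), reproducing the
  observed dominance structure in which a handful of OTUs carries a large
  share of reads. No generative model is stated in the emulated study;
  this is a calibration choice, made once.
- **Activity.** A latent trait simulated under BM (or white noise) on the
  tree, mapped through the logistic function to an activity in $[0,1]$.
  DNA reads are multinomial at composition $\mathrm{abundance} \times
  (1-\mathrm{activity})$, RNA reads at $\mathrm{abundance} \times
  \mathrm{activity}$: the estimated mean expression ratio is then a
  monotone estimator of activity, exact at both boundaries. (Weighting only
  the RNA side would leave the DNA composition activity-free but makes the
  activity-one boundary ill-defined; the symmetric weighting keeps both
  boundary identities exact.)
- **Assembly.** `random` draws tips uniformly; `filtered` draws from within
  one non-root clade (failing loudly when none is large enough, except in
  the vacuous full-pool case); `overdispersed` uses greedy max-min distance
  selection — deterministic given the seed, and sufficient to produce
  positive SES.

What the generator does *not* emulate: nucleotide sequences, PCR and
chimera artifacts, taxonomy, or any real effect sizes — the emulated
clustering and signal strengths are calibration choices. A green
calibration test therefore establishes that the machinery is correct and
well-calibrated under its stated model, not that real root microbiomes
match that model.

## Numerical policies

- Zero-length branches are lifted by $10^{-8} \times$ tree depth and
  polytomies resolved to zero-length bifurcations before contrasts.
- Ties in the greedy max-min selection are broken by a seeded uniform draw.
- Permutation p-values use the add-one convention and can never be 0.
- All stage seeds are derived deterministically from one master seed and
  recorded in the pipeline's JSON run manifest.

## Known limitations

- Kse's exact published implementations vary in their treatment of the
  error model; validation here is property-based (reduction at zero SE,
  BM calibration, attenuation correction, planted-signal recovery), not a
  value-for-value match against any published table.
- The mean expression ratio is a proxy: rRNA content, growth and activity
  are not interchangeable, and the package deliberately reports the ratio
  without interpreting it further.
- Compositional effects of relative abundances (one OTU's activity changes
  every other OTU's RNA relative abundance) are inherited from the trait
  definition, not corrected.
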