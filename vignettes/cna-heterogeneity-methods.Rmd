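---
title: "Methods: allelic-imbalance CNA calling in heterogeneous samples"
author: "subcloneCNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allelic-imbalance CNA calling in heterogeneous samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subcloneCNA)
```

# The model

A heterogeneous sample is a mixture of homogeneous components — a stromal
(normal diploid) component and one or more tumor subclones — with mixing
coefficients $x_i \ge 0$, $\sum_i x_i = 1$. At locus $j$ an aggregate assay
measures the weighted averages of the components' integer allele copy
numbers,

$$\bar a_j = \sum_i x_i\, a_{ji}, \qquad \bar b_j = \sum_i x_i\, b_{ji},$$

implemented by `mix_signals()`. These are re-expressed in the conventional
SNP-array coordinates (`to_profile()`):

$$\beta_j = \frac{\bar b_j}{\bar a_j + \bar b_j}, \qquad
  \rho_j = \frac{\bar a_j + \bar b_j}{2}, \qquad
  \log R_j = \log_2 \rho_j .$$

A normal diploid locus has $\rho = 1$, $\log R = 0$ and
$\beta \in \{0, \tfrac12, 1\}$. Loci with zero total signal take
$\beta = \tfrac12$ by convention — a homozygous deletion should not
masquerade as allelic imbalance; its evidence lives entirely in $\rho = 0$
— and $\log R$ is left undefined there.

## Why status, not copy number

Recovering the $a_{ji}, b_{ji}, x_i$ from $(\bar a, \bar b)$ is
underdetermined once three or more components are mixed. Even restricted to
binary per-allele profiles over $s$ loci, the candidate space has $2^s - 1$
profiles per allele channel while only $s + 1$ independent equations are
available, and `enumerate_demixings()` shows by exhaustive search that a
three-component aggregate admits multiple exact reconstructions while a
two-component mixture with independent measurements is unique. The package
therefore aims only at the aberration *status* of the dominant aberrant
component per locus: gain, loss, or normal.

# The M-measure

Aberrations in a fraction of cells displace heterozygous-SNP $\beta$ from
$\tfrac12$. The per-SNP imbalance function is

$$f(\beta) = \sin^2(2\pi\beta),$$

a product of trigonometric functions chosen for two properties: it vanishes
*with zero slope* at the three normal-state values $\{0, \tfrac12, 1\}$, so
its mean under noise of amplitude $\sigma$ is $O(\sigma^2)$ rather than
$O(\sigma)$, and it rises steeply away from them, reaching 1 at
$\beta = \tfrac14, \tfrac34$. (The non-flat alternative
$|\sin 2\pi\beta|$ is available as `imbalance_abs_sin`; its windowed mean
under realistic BAF noise sits near the default decision cutoff, which is
exactly the failure mode the flat choice avoids. The function is an
injectable argument everywhere.)

## Windowing

The M-measure of a SNP is the mean of $f(\beta)$ over the $W = 20$
informative SNPs nearest to it, where *informative* means
$\beta \in (\delta, 1 - \delta)$ with $\delta = 0.1$: loci on the
homozygous outer bands carry no imbalance information. Windowing over the
informative subsequence — rather than over $W$ consecutive array SNPs — is
what makes $W = 20$ a robust estimate: at the ~9.5% heterozygosity of a
germline genome, 20 consecutive SNPs contain only about two informative
ones (and none at all in 12% of windows), so a raw-SNP window would leave
the score dominated by sampling noise and bounded far below its nominal
range. Non-informative SNPs inherit the score of their nearest informative
neighbor; edge windows shrink symmetrically. The price is resolution: the
window spans roughly $W / 0.095 \approx 200$ loci of physical distance in a
germline-typical region, acceptable for the 1,000-locus aberrations this
design targets (focal-event sensitivity is a non-goal).

## Three-state classification

`classify_cna()` labels a SNP aberrant when

* its M-measure exceeds `m_cutoff` (default 0.1), **or**
* the one-sided $z$-test of its windowed mean $\log R$ against 0 rejects at
  `logr_alpha` (default 0.01), with the noise scale taken as the global
  median absolute deviation of $\log R$ (floored at $10^{-12}$ so noiseless
  input remains decodable).

The second gate exists because the M-measure is structurally blind to
hemizygous deletions carried by the majority of cells: there the
heterozygous $\beta$ collapses onto the homozygous bands and only the
depressed $\rho$ remains. Aberrant SNPs are then labeled **loss** when the
windowed mean $\log R$ is below `-logr_tolerance`, **gain** when above
`+logr_tolerance` (default 0.05), and **normal** otherwise — a copy-neutral
imbalance is not a copy-number event. The 0.05 default is about five
standard errors of the windowed $\log R$ mean at the simulator's reference
noise level and half the $\log R$ shift of a one-copy event in a ~30%
subclone, i.e. comfortably above noise and below the smallest effect of
interest. For zero-$\rho$ loci the windowed statistics use
$\log_2 \max(\rho, 2^{-10})$.

## Parameters at a glance

| parameter        | default | meaning                                            |
|------------------|---------|----------------------------------------------------|
| `window`         | 20      | informative SNPs per M-measure window              |
| `m_cutoff`       | 0.1     | M-measure aberrance threshold                      |
| `logr_alpha`     | 0.01    | level of the one-sided depressed-$\log R$ test     |
| `logr_tolerance` | 0.05    | $\log R$ band treated as "no total-DNA evidence"   |
| `hom_delta`      | 0.1     | homozygous-band half width excluded from windows   |

# The 3SMM decoder

`viterbi_3smm()` decodes the maximum-a-posteriori path of a three-state
HMM (normal / deletion / duplication segments) whose per-SNP observation is
the pair (M-measure, windowed mean $\log R$), modeled per state as
independent Gaussians. `fit_hmm_from_truth()` estimates transitions from
the empirical state bigrams of a simulated truth track (add-one smoothing)
and emissions from the per-state observation moments (standard deviations
floored at $10^{-4}$) — the best-case parameterization available in a
simulation. Ties are broken toward `normal`, making decoding
deterministic; the generic `viterbi_decode()` is exported and is checked
against exhaustive path enumeration in the tests. In the simulated
benchmarks the decoder performs on par with plain thresholding — the
accuracy loss at high stromal content comes from the vanishing signal, not
from the absence of segmental smoothing — which is why thresholding is the
default.

# Stromal mixing-coefficient inference

For a binary stroma/tumor mixture, a deletion locus with aggregate copy
number $\bar c = 2\rho < 2$ satisfies $\bar c = 2x + m(1 - x)$ with
$m \in \{0, 1\}$ the integer tumor copy number, giving two candidates
$x = (\bar c - m)/(2 - m)$ per locus. One $x$ must hold across all loci
simultaneously, so `infer_mixing_coefficient()` pools both candidates from
every deletion locus, discards values outside $[0, 1]$, and takes the mode
of a histogram with 0.01-wide bins *centered on multiples of the bin
width* — centering matters because noiseless candidates are exact grid
values and edge-aligned bins would split their mass across two bins by
floating-point accident. Ties go to the bin with the smaller within-bin
variance. Each locus then receives the $m$ whose candidate is nearer the
mode.

Known limitation: when only one deletion kind is available the system is
genuinely ambiguous — $\bar c = 1.9$ is explained exactly by both
$(x = 0.95, m = 0)$ and $(x = 0.9, m = 1)$ — so the mode rule needs both
hemizygous and homozygous deletion loci in the input. With
classifier-derived loss calls this occurs at extreme stromal content
($\alpha \gtrsim 0.95$), where the hemizygous $\log R$ shift falls inside
the tolerance band.

# The simulator

`simulate_mixture()` reproduces the validation design the classifier is
benchmarked on:

* **Germline**: two binary haplotypes over `n_loci` (default 10,000) loci;
  each locus heterozygous with probability 0.095, otherwise AA or BB with
  equal probability.
* **Aberrations**: four kinds — homozygous deletion, hemizygous deletion,
  one-copy gain, two-copy gain — each spanning 1,000 loci (roughly 20 Mbp
  at array density), separated by 1,000 normal loci. Hemizygous deletions
  and gains act on one parental haplotype chosen by a seeded coin *per
  block*, so each block produces a coherent split $\beta$ band rather than
  per-locus salt-and-pepper.
* **Mixing**: coefficients $(\alpha, 1-\alpha)$ for one subclone or
  $(\alpha, \tfrac{2(1-\alpha)}{3}, \tfrac{1-\alpha}{3})$ for two. With two
  subclones the second subclone's block grid is shifted by half a block
  with the aberration kinds in reversed order, so every overlap pairs a
  deletion with a duplication and each kind also occurs alone — the
  aggregate realizes the aberration combinations while no kind conflicts
  within a subclone.
* **Truth**: each locus is labeled by the aberration sign of the covering
  aberrant component with the largest coefficient; normal elsewhere.
* **Noise**: zero-mean Gaussian noise is added independently to the
  aggregate A and B channels *before* the $\beta/\rho$ transform, inducing
  the correlated $\beta$/$\log R$ noise real arrays show. The default SNR
  of 30 is interpreted as an amplitude ratio, `sd = rms(channel)/snr`,
  giving a BAF band width of about 0.02 — the scale of Illumina-class
  arrays; a power-ratio reading (`snr_scale = "power"`) is also available
  but produces bands several times wider than the instruments this
  emulates. Negative noisy signals are clamped at zero to preserve the
  non-negativity of allele quantities.

What the simulator deliberately omits: recombination and phasing realism,
GC waves, probe-specific bias, and copy-neutral LOH. Passing benchmarks on
these mixtures therefore demonstrates robustness to *mixture dilution and
channel noise*, not to array artifacts; on real data the wave and bias
structure of a platform will add errors the simulation cannot show.

# Evaluation

`auc_roc_three_class()` scores a call track by the unweighted mean over the
three classes of the per-class balanced accuracy
$\tfrac12(\mathrm{TP}/\mathrm{P} + \mathrm{TN}/\mathrm{N})$ — the area
under the ROC curve at the operative point of a thresholdless classifier.
A class absent from the truth contributes 1 via the $0/0 \to 1$
convention, so perfect calls on aberration-free data score 1 rather than
being penalized. `run_mixture_experiment()` drives replicated simulations
over a grid of stromal coefficients for any set of caller plugins
(`caller_mmeasure()`, `caller_3smm()`, `caller_oracle()`, or any
`function(profile, truth)`), recording per-replicate scores and surviving
caller failures.

Problem sizes used in the shipped checks: the headline benchmark runs 20
replicates per $\alpha \in \{0.1, \ldots, 0.5\}$ at 10,000 loci (the
scripted run completes in seconds); module tests use 500–2,000-locus
layouts with proportionally shortened blocks.

# RNA-seq within-exon imbalance

At sufficient depth, per-nucleotide allelic imbalance in RNA-seq carries
the same mixture information: a somatic variant carried by a subset of
subclones shows an alt-allele fraction equal to the summed abundance of its
carriers, while allele-specific expression or expression-level differences
shift whole exons, not single sites. `score_sites()` keeps sites with at
least 100 supporting reads and scores
$0.5 - |0.5 - \#B/(\#A + \#B)|$ with an exact binomial (Clopper–Pearson)
95% interval on the alt fraction. `detect_exon_fluctuation()` emits a call
for every within-exon pair of passing sites whose intervals are disjoint —
a deliberately descriptive criterion mirroring a confidence-interval
display; a Fisher-exact mode with Benjamini–Hochberg correction across all
pairs is available behind `method = "fisher"`. Pairs closer than the read
length (default 50 bp, configurable) are flagged, since a focal CNA shared
by all subclones would move both sites of such a pair together. All
within-exon pairs are tested and adjacency is recorded in the output, so
both the "consecutive sites" and the "all pairs" readings are recoverable.
`generate_rnaseq_fixture()` plants known carrier sets and fractions for
calibration: with disjoint 95% intervals as the criterion, the false-call
rate on truly balanced pairs is well below 5%, and planted fractions are
covered by the site intervals at the nominal rate.

# Numerical and degenerate-input choices

* Validation failures signal a `subcloneCNA_validation` condition; the CLI
  maps them to exit code 1 (runtime errors to 2).
* All randomness flows through R's session RNG; every stochastic entry
  point takes a `seed` argument (`NULL` = current stream), and identical
  seeds give bit-identical outputs.
* Coordinates are 0-based half-open internally and in BED output, 1-based
  in signal TSVs (array convention).
* Viterbi ties, mode-histogram ties and hemizygous/homozygous assignment
  ties are all broken deterministically (toward `normal`, the
  lower-variance bin, and $m = 1$ respectively).
* `m_measure` on a profile without informative SNPs returns all zeros; the
  depressed-$\log R$ test alone then drives classification.
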