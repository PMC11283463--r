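---
title: "Quantifying mutation scars at AID break clusters: models and methods"
author: "abcdPCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mutation scars at AID break clusters: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abcdPCR)
```

## The problem

Activation-induced cytidine deaminase (AID) is the B-cell mutator behind
somatic hypermutation and class switching. Off target, it deaminates
cytosines in WRC/RCG contexts (IUPAC: W = A/T, R = A/G) inside focal
20–600 bp "AID break clusters" (ABCs) near genes such as *CRLF2* and *BCL2*,
leaving behind NHEJ repair scars — small indels and C→T transitions — that
cluster at and near CpG dinucleotides. Quantifying that scar load from
genomic DNA is useful both as a genome-instability readout and as a candidate
risk marker for CRLF2-rearranged leukemias.

`abcdPCR` implements the analysis side of a multiplexed *drop-off* digital
PCR (dPCR) assay for these regions, together with per-position indel
profiling of aligned amplicon-sequencing reads. Several TaqMan probes tile an
ABC amplicon: drop-off probes sit directly on mutable CpG/AID-motif sites,
and one reference probe sits where no AID target or break has been mapped.
A mutation under a probe abolishes its binding, so a scarred template
produces an amplicon that lights the reference channel but not the mutated
probe's channel. The package classifies chambers, converts negative-chamber
fractions into absolute concentrations, quantifies the drop-off product per
probe, and compares conditions.

Because bench data require an instrument and genomic DNA, everything here is
driven by a synthetic-data generator that forward-simulates the assay with
known truth. All empirical statements in this vignette are the quantities the
package's own test suite and `scripts/acceptance.R` recompute.

## Partition statistics

A reaction of volume $NV$ is split into $N$ chambers of volume $V$. Template
molecules at bulk concentration $c$ (copies/µL) land in chambers
independently, so the occupying count per chamber is Poisson with mean
$\lambda = cV$ and

$$\Pr(\text{chamber negative}) = e^{-\lambda}, \qquad
  \hat\lambda = -\ln\frac{n_{\mathrm{neg}}}{n}, \qquad
  \hat c = \hat\lambda / V .$$

Defaults follow the assay's operating point: $N = 20{,}000$ chambers and
$V = 4.5\times10^{-4}$ µL. The partition volume itself is not published for
the instrument; we derive it transparently as a 9 µL reaction split over
20,000 chambers, and it is user-configurable everywhere. "Copies/µL" always
refers to the pre-partition bulk reaction.

**Confidence intervals.** The negative fraction is a binomial proportion; we
put a Wilson interval on it and map the endpoints through the monotone
transform $-\ln(\cdot)/V$ (the upper bound on the negative fraction becomes
the lower concentration bound). Wilson was chosen over Wald for its behaviour
at extreme fractions; over 500 simulated runs at the default scale the
transformed interval covers the truth at essentially the nominal 95%
(asserted at ≥ 93% in the test suite to leave Monte Carlo slack). Degenerate
cases are explicit: a fully negative channel returns a zero estimate with a
one-sided upper bound; a channel with fewer than 0.5% negative chambers is
outside the assay's dynamic range and raises a saturation error that reports
the detectable lower bound rather than an unstable number.

## Drop-off estimators

Let $R$ be the reference channel and $P$ a drop-off probe. Templates intact
at $P$ light both channels; templates scarred under $P$ light $R$ only.

**Difference estimator (default).** Each channel's marginal concentration is
inverted separately and

$$\widehat{\mathrm{drop}}(P) = \hat c_R - \hat c_P .$$

The two negative fractions come from the same chambers and are strongly
correlated; the interval uses the delta method with the covariance estimated
from the observed joint negativity counts:
$\widehat{\mathrm{Cov}}(\hat p_R,\hat p_P) = (p_{RP} - p_R p_P)/n$, where
$p_{RP}$ is the both-negative fraction. This correlation roughly halves the
variance relative to treating the channels as independent runs. The default
matches how per-probe copies/µL panels are usually reported (per-probe
marginals); which rule a vendor's software applies internally is not public,
so neither estimator is claimed to replicate it.

**Joint (subset-lattice) estimator.** The positivity patterns carry more
information than the marginals. Model every channel subset $T$ as a molecule
class "intact exactly on $T$" with intensity $\lambda_T$. A chamber is
negative on a channel set $S$ iff it contains no molecule of any class
intersecting $S$:

$$\Pr(\text{negative on } S) = \exp\!\Big(-\sum_{T \cap S \neq \emptyset} \lambda_T\Big)
  \;\Rightarrow\; \Lambda_S = -\ln f_{\mathrm{neg},S} .$$

With $G(U) = \Lambda_{\text{all}} - \Lambda_{U^{c}}$ (the total intensity of
classes contained in $U$), Möbius inversion over the subset lattice recovers
$\lambda_T = \sum_{U \subseteq T} (-1)^{|T|-|U|} G(U)$, and
$\mathrm{drop}(P)$ sums the classes intact on $R$ but not on $P$. Because the
map from the $2^K$ pattern frequencies to the $2^K{-}1$ class intensities is
a smooth bijection, this moment estimator is also the multinomial maximum
likelihood estimator of the saturated class model — the test suite verifies
both the equivalence to a brute-force likelihood fit ($K=2$) and to a direct
linear solve of the pattern equations ($K=2,3$), and the conservation
identity $\sum_T \hat\lambda_T = -\ln(\text{all-negative fraction})$ holds
exactly by construction. Intervals come from the delta method on the
multinomial pattern covariance. Sampling noise can push individual class
estimates slightly negative; they are reported as-is with an
`inconsistent-pattern` flag, never clamped, so bias diagnostics stay honest.
A subset with no negative chambers makes its $\Lambda_S$ infinite and raises
a named saturated-pattern error.

On two-class simulations the two estimators agree within combined sampling
uncertainty; the difference estimator is the default and the joint estimator
is the pattern-level alternative.

## Chamber classification

Per channel, fluorescence is thresholded. Fixed thresholds are always
accepted for reproducibility. Auto-thresholding performs a one-dimensional
two-cluster $k$-means split (deterministically initialised at the 1% and 99%
quantiles) and cuts at the midpoint of the two centers. A channel is declared
unseparable when the centers are closer than twice the pooled within-cluster
spread, with "pooled" taken in quadrature, $\sqrt{s_1^2+s_2^2}$. That
calibration is deliberate: a 2-means split of a *single* Gaussian cloud
yields centers about $1.6\sigma$ apart with cluster spreads of $0.6\sigma$
each, which fails this bound (an all-positive or all-negative channel is thus
flagged rather than silently split), while two genuinely separated
fluorescence clusters clear it by a wide margin. A summed or averaged
within-cluster spread would make the bound unreachable at any 2-means
optimum.

## Group comparison

Replicate-level drop-off concentrations are compared with Welch tests
(two-condition design), or each drop-off probe against the reference probe
with a Dunnett-style many-to-one adjustment: the adjusted $p$ for contrast
$j$ is $\Pr(\max_i |Z_i| \ge |t_j|)$ under a multivariate normal whose
correlation is induced by the shared reference replicates, evaluated by
seeded Monte Carlo (50,000 draws by default; Bonferroni fallback if the
correlation matrix is not positive definite). Using normal rather than $t$
tails is slightly liberal at very small replicate counts; the test suite
pins the procedure against an independent multivariate-normal integration.
Reports carry group means ± SEM, the convention of the assay's figure
legends. Groups with a single replicate yield descriptive output flagged
`no-test`.

## The synthetic assay

`simulatePartitionRun()` is the forward model of the inference above:
per-chamber class counts are independent Poisson draws, channel occupancy is
the union over classes intact on that channel, and fluorescence is a
two-component Gaussian mixture per channel, independent across channels
given occupancy (negatives at 1.0 ± 0.3 a.u., positives at 6.0 ± 0.6 a.u. by
default — well separated, as the real 2-D chamber scatters are visually
bimodal; no fluorescence model is published, so the mixture is the simplest
shape consistent with those plots). Occupancy maps to positivity
deterministically by default; an optional per-molecule dropout rate exists
(default 0) for robustness experiments. What the generator deliberately does
*not* model: PCR efficiency/kinetics, optical crosstalk between channels,
rain (intermediate fluorescence), or translocation junctions. Passing tests
therefore validate the estimators under ideal partition statistics, not the
instrument's optics.

`simulateAmpliconReads()` emits SAM-style alignment records over an ABC
region, one independent template molecule per read. Per molecule: one
context C→T substitution (G→A on the minus strand) with probability
`substitutionRate`, placed on a WRC/RCG/CpG cytosine; one indel with
probability `indelRate`, placed by the CpG-proximity kernel — with
probability `cpgKernel` (default 0.70) the indel midpoint falls within
`cpgWindow` (default 8) bp of a CpG, with exact-CpG positions upweighted by
`atCpgBias` (default 1.3). Those defaults encode the published breakpoint
geometry of ABCs (70% of events within 8 bp of a CpG, 30% more likely
directly at one) as a model default, not as a reproduced result. Deletions
dominate (`deletionFraction` 0.8) and lengths are
$1+\mathrm{Geom}(p{=}0.6)$, i.e. mostly 1–2 nt NHEJ scars. Sequencing errors
hit matched bases at `errorRate`; optional library-prep artifact indels are
injected uniformly inside a configured homopolymer range, independently of
the AID model, and flagged in the truth table. An indel that would overrun
the read's reference span is resampled within its kernel branch (so the
0.70 calibration is preserved exactly) with a hard cap of 10 retries.

Conventions shared between the generator and the profiler, so truth tables
and profiles are comparable without tolerance: insertions attach to the
reference base on their left; deleted positions count toward depth (a
deletion is an observation of that position); event midpoints (deletion
midpoint, insertion attachment base) define CpG proximity.

## Indel profiling

`profileFromAlignments()` walks each read's CIGAR: `M/=/X` advance both
coordinates and add depth, with mismatches above the base-quality floor
(default Q20) counted as substitutions; `D` adds depth and a deletion count
at every deleted position; `I` adds one insertion at the left flanking base;
secondary/supplementary alignments and reads below the mapping-quality floor
are skipped. Indel and substitution tracks are kept distinct — per-bp
"change" bars at ABCs are dominated by indels, and mixing in substitutions
would blur the artifact analysis. On simulated reads the profile equals the
generator truth table exactly; counting is deterministic, so no tolerance is
involved. Positions inside single-nucleotide runs of ≥ 5 nt are flagged as
homopolymer artifact territory (amplicon libraries produce standalone indel
peaks in A/T runs that are not AID-derived), and
`cpgProximitySummary(..., excludeArtifacts = TRUE)` removes flagged events
before computing CpG-proximity fractions; with artifacts injected only
inside a run, exclusion recovers the configured kernel while the naive
summary is biased, and the suite asserts that ordering. No statistical peak
caller is provided: published per-bp profiles identify peaks visually, so
peaks are reported descriptively.

There is no realignment or left-normalisation of indels beyond the
attachment convention, no genotype calling, and no paired-end merging; the
exact counting rules behind commercial amplicon pipelines are unpublished,
so only internal consistency and truth-table equality are asserted, never
third-party bar heights.

## Motif scanning and panel validation

`scanCpG()` scans the plus strand only (CpG is its own reverse complement);
`scanAidMotifs()` scans both strands for WRC, RCG, WGCW and the CAC/CACA
cryptic-RSS core, reporting minus-strand hits at their plus-strand offset
with the match in motif orientation. `N` never matches (conservative
calling). The published affinity ordering among WGCW/WRC/RCG is
typographically ambiguous in its source, so the three patterns are unranked
classes here. CRYPTIC_RSS reports the maximal match per start (CACA when
present, else CAC) because no merging rule is published; per-start maximal
matching is reproducible. All scanners are checked exactly against
regex-free exhaustive enumerators on random sequences.

Panels load from YAML with 1-based inclusive genomic coordinates (so printed
browser coordinates paste directly); everything internal is 0-based
half-open. Validation is eager: exactly one reference probe, all windows
inside the region, and a reference window free of CpGs — a reference probe
over a mutable site would silently deflate every drop-off estimate.

The bundled region/panel (`inst/extdata/`, `syntheticAbcRegion()`) is a
labelled synthetic stand-in: a seeded 660-nt sequence with eight embedded
CpG islands in AID context, an A-run and a T-run mimicking artifact-prone
homopolymers, and a background scrubbed of stray CpGs so the proximity
kernel has a clean proximal/non-proximal split. The published probe windows
live in a supplement that is not redistributed; the synthetic windows are
placeholders with the same geometry (three drop-off probes on the first
three CpGs, one reference probe on a CpG-free, homopolymer-free stretch).

## Problem sizes and determinism

Simulation-backed checks in the test suite and acceptance script use the
full 20,000-chamber scale for single-run statements, 50–500 replicates for
coverage/bias/recovery statements (estimator properties use the
occupancy-only fast path `simulateCalls()`, which skips the fluorescence
layer), 100 random sequences for scanner oracles, and 1,000–10,000 reads or
events for profiler and kernel statements. Every stochastic component takes
an explicit seed, private RNG streams restore the caller's `.Random.seed`,
and pipeline stages write manifests with input/output hashes and the seeds
used, so any run is reproducible from its manifest alone.

## Known limitations

* The fluorescence model has no rain, drift or crosstalk; auto-thresholding
  on real exports may need fixed thresholds from instrument software.
* The joint estimator's saturated class model estimates $2^K - 1$
  intensities from $2^K - 1$ free frequencies; with many channels and few
  chambers its per-class variance is large, and patterns with zero negative
  chambers stop it entirely.
* Normal-tail Dunnett adjustment is mildly anti-conservative below ~4
  replicates per group.
* The mutation model places at most one AID indel and one AID substitution
  per molecule; heavily scarred templates (multiple independent hits) are
  outside its scope, consistent with the low per-molecule hit rates the
  assay targets.
* Restriction-digest accessibility steps (e.g. AvrII) change which templates
  amplify, not the partition math; they belong in sample metadata.
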