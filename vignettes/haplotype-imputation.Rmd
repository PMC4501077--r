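---
title: "Genotype calling and imputation from allele read depths"
author: "HapDepth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype calling and imputation from allele read depths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HapDepth)
```

## The problem

Low-coverage sequencing observes each site of a diploid genome a random,
small number of times. At a biallelic site the data for one individual
reduce to a pair of allele depths $(n_A, n_B)$ — counts of reads
supporting the reference A and alternate B alleles. With no sequencing
error, observing both alleles proves a heterozygote, but one-sided
observations are ambiguous: $n_A = 4, n_B = 0$ arises from an AA
homozygote, or from an AB heterozygote with probability
$0.5^4 = 0.0625$. A pair with $n_A = n_B = 0$ is a missing observation.
Calling genotypes site-by-site therefore loses exactly the information —
haplotype sharing across a population — that makes imputation work.

HapDepth treats each individual's genotype as the sum of two haplotypes
drawn from a shared, frequency-sorted library of probability tracks, and
pushes the read counts directly into those tracks by Bayes' rule. Array
genotypes enter the same machinery as pseudo read counts, so genotype
calling from sequence and imputation from SNP arrays happen in one pass
over the population.

## The model

Given a per-read error rate $e$ (`errate`), the read-count likelihoods
are binomial:

$$P(n_A, n_B \mid AA) = C\,(1-e)^{n_A} e^{n_B},\quad
  P(n_A, n_B \mid BB) = C\,e^{n_A} (1-e)^{n_B},\quad
  P(n_A, n_B \mid AB) = C\,0.5^{\,n_A+n_B},$$

with $C = \binom{n_A+n_B}{n_A}$ a shared constant that cancels from every
ratio and posterior. Writing $p_1 = P(h_1 = A)$ and $p_2 = P(h_2 = A)$
for the two haplotypes of the focal individual, the probability of the
observation given one haplotype allele is

$$P(n_A, n_B \mid h_1 = A) = p_2 P(\cdot \mid AA) + (1 - p_2) P(\cdot \mid AB),$$

and unconditionally

$$P(n_A, n_B) = p_1 p_2 P(\cdot \mid AA) + (1-p_1)(1-p_2) P(\cdot \mid BB)
  + (p_1 + p_2 - 2 p_1 p_2) P(\cdot \mid AB).$$

The posterior allele probabilities of the two haplotypes follow from
Bayes' rule (`posteriorPairUpdate()`); they are written back into the
library so that the next individual carrying either haplotype starts
from the updated state. Linkage information thus accumulates in the
haplotype list itself rather than in an explicit hidden Markov model,
which is what makes the search fast.

### Haplotype selection

Individuals are processed from oldest to youngest. For each window of
sites, a candidate H1 is scored by the product over observed loci of
$P(s \mid H1)/P(s)$, where the candidate track's per-site probability is
used directly (no rounding to hard alleles) and the denominator
substitutes the population frequency $p$ for both haplotypes. A
candidate is accepted when the joint ratio exceeds $1/n$ ($n$ = observed
loci in the window); the scan over a candidate stops — and the candidate
is discarded — as soon as the *running* product falls below $1/n$, which
is what keeps long windows cheap. H2 is scored conditionally on H1 with
the relaxed threshold $1/(n(1 + n/100))$ and must be a distinct track.
Known parental and grandparental tracks are tried first; if nothing
qualifies, a new haplotype is admitted with prior probabilities equal to
the site frequencies (for array-called loci, seeded with the complement
of H1). After every population pass, site frequencies are re-estimated
as the usage-weighted mean of track posteriors and the library is
resorted by descending usage.

A note on the discard rule: it is applied to the running product rather
than to single-locus ratios alone. A single-locus dip below $1/n$ is a
special case of the running rule (the product starts at 1), and the
running form is both the computational point of the rule and the reason
candidate scans terminate after a handful of loci at high depth.

### Window ladder

Windows are tiled at a ladder of lengths from `maxLen` (default 20,000
variants) down by factors of 4 to `minLen` (default 100), with
`itersPerStep` (default 6) population passes at each length. Long
windows discover long shared segments in strongly related individuals;
short windows rescue recombinants. The ladder runs long-to-short so that
haplotype discovery precedes fine-grained correction, and final calls
come from the shortest length, where within-window crossovers are
rarest. Crossovers are otherwise handled implicitly: H1/H2 are selected
independently per window.

### Genotype calls

At call time the two assigned tracks give a genotype prior
($P(AA) = q_1 q_2$, etc.) that is combined with the individual's own
read likelihoods; the call is the posterior argmax with ties broken
toward the heterozygote, the dosage is the posterior expected count of A
alleles, and a call is missing when the posterior is essentially
uniform. Track probabilities saturate towards 0/1 as evidence
accumulates, but a track can be *locally* wrong for an individual — most
commonly across a crossover breakpoint inside a window — so the prior
entering the call is floored at `priorFloor` (default $10^{-3}$). The
cap means roughly ten error-free reads can override a saturated wrong
prior, while genuinely ambiguous one-sided heterozygotes (whose
conditional read count is about half the mean depth) are still rescued
by a correct prior. Selection and updating are unaffected by the floor.

### Frequency initialization and zeroing

Site frequencies start from simple pooled allele counts. A site whose
total minor-allele reads are at or below the expectation under the read
error rate ($e \times$ total reads) carries no evidence of polymorphism;
such sites are flagged once at initialization and their frequencies are
pinned to 0 or 1 after every re-estimation. With $e = 0$ this only
affects sites with no minor reads at all. This makes variant selection
somewhat automatic when monomorphic or near-monomorphic sites are left
in the input.

### Numerical choices

* Haplotype probabilities are clamped to $[10^{-6}, 1 - 10^{-6}]$ inside
  every update: read errors make no observation strictly impossible, and
  the clamp keeps denominators positive even at `errate = 0`.
* Likelihoods for piles deeper than 30 reads are evaluated in log space;
  the compiled engine and the R reference use the same expressions so
  that both engines produce bit-identical trajectories.
* Posteriors are clipped to $[0, 1]$ after division to absorb one-ulp
  overshoots.
* Ties in the usage resort preserve insertion order; ties in the call
  argmax go to the heterozygote.
* The binomial coefficient is carried in `readLikelihoods()` by default
  but all selection and updating paths use coefficient-free likelihoods;
  tests assert that every ratio is invariant to the choice.

## The simulator

`simulateDataset()` generates the study design end to end: a
discrete-generation pedigree with heavy sire usage
(`simulatePedigree()`), founder haplotypes with linkage disequilibrium,
gene drop with Poisson (Haldane, no-interference) recombination
(`geneDrop()`), Poisson read depths with per-read error
(`sampleReads()`), and array genotypes with genotyping error 0.001 at a
chip subset, optionally embedded into the sequenced individuals' data as
depth-32 pseudo counts.

Design choices worth knowing:

* **Founder frequencies.** Sequence variants draw
  $p = 0.5 + \mathrm{sign}(u - 0.5)\sqrt{|u - 0.5|/2}$ from uniform $u$,
  a density $4|p - 0.5|$ concentrated near 0 and 1, so 36% of variants
  have MAF below 0.1; chip markers draw plain uniform frequencies. An
  alternative scaled form of the transform, with range
  $[0.457, 0.957]$, is available via `literal = TRUE`.
* **Founder LD.** Haplotypes are thresholded latent Gaussian AR(1)
  processes (copula autocorrelation 0.98 by default): marginals match
  the site frequencies exactly and adjacent sites are strongly
  correlated, which is the feature the chip-design filter
  (`selectArrayMarkers()`) needs. No attempt is made to match a specific
  empirical LD decay curve.
* **Array errors** are single-step genotype swaps
  (AA $\leftrightarrow$ AB $\leftrightarrow$ BB) at rate 0.001.
* **Scale.** The desk-scale defaults are 20,000 sites on a 100 cM map
  with a 400-marker chip (2% of sites, the same proportion as a 600K
  array on a one-million-SNV chromosome). Note that per *window* the
  desk-scale map is 50 times denser in centimorgans per variant than a
  full-scale chromosome, so within-window crossovers — and the
  boundary effects they cause — are substantially more frequent here
  than at full scale. Accuracies in calling-dominated regimes (high
  depth) transfer well; imputation accuracy for array-only individuals
  is *not* comparable to full-scale values because the desk chip has
  only 400 markers to anchor on.

What passing tests on simulator output do and do not show: they verify
the estimator under its own generative assumptions (biallelic sites,
independent Poisson depths, symmetric read errors, known pedigree). Real
data violate several of these — depth is correlated with GC content and
mappability, errors are not symmetric, pedigrees contain mistakes — and
nothing here quantifies robustness to those violations.

## Evaluation

`percentCorrect()` scores called against true genotypes across all loci,
counting missing calls as incorrect (a diagnostic non-missing-only mode
exists). `centeredCorrelation()` subtracts twice the reference-allele
frequency from both dosages and truth and computes the pooled
uncentered correlation $\sum xy / \sqrt{\sum x^2 \sum y^2}$; the
frequency centering replaces mean centering, so monomorphic loci
contribute exactly zero to numerator and denominator and per-locus
averaging (a stricter, low-MAF-weighted metric) is deliberately not
used. `mafBinnedCorrelation()` restricts the same statistic to MAF bins
(default 10 equal bins over (0, 0.5]), and `runGrid()` sweeps a design
grid (depth x error x population x HD embedding), recording per-cell
failures without aborting the grid.

## A small worked run

```{r example}
sim <- simulateDataset(SimConfig(nSeq = 20, nArray = 5, nSites = 300,
                                 chipSize = 30, meanDepth = 8,
                                 errate = 0.01, nGenerations = 3,
                                 nSires = 3, seed = 11))
sim
calls <- runPipeline(sim, SegmentPlan(300, minLen = 50, maxLen = 300,
                                      itersPerStep = 3),
                     ModelConfig(errate = 0.01))
evaluateCalls(calls, sim)
```

## Problem sizes used by the automated checks

The package's acceptance checks run the pipeline at 500 individuals by
20,000 sites (the desk-scale design above) with the default window
ladder, which takes on the order of one to two minutes per run on a
single core; the remaining test suite uses populations of 6-40
individuals and 40-600 sites so that property checks stay in the
seconds range. These sizes are the package's chosen desk scale for the
study design, with the chip kept at 2% of sites.

## Known limitations

* Only biallelic sites; additional observed alleles must be removed or
  recoded as errors upstream.
* Per-read base qualities are not used; one global `errate` (plus the
  array pseudo-count error) covers all reads.
* No explicit recombination model inside windows; crossovers surface
  only through the window ladder.
* The admission threshold for new haplotypes reuses the 1/n selection
  threshold; no cap is placed on library size per segment.
* Incremental runs (`augmentPipeline()`) treat the imported library as a
  frozen reference panel: new individuals are assigned tracks but do not
  update them, which keeps previous calls bit-identical at the cost of
  ignoring the new information.
* Two-stage density-ladder imputation (low-density array to HD to
  sequence) is out of scope.
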