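---
title: "Pedigree reconstruction from non-invasive genetic monitoring data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree reconstruction from non-invasive genetic monitoring data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wolfped)
```

## The problem

Territorial carnivores such as grey wolves are monitored largely through
the material they leave behind: scats, hair, urine in snow, the
occasional carcass. Microsatellite genotypes from such samples identify
individuals and, across years, reveal the pedigree — who founded each
pack, who inherited or usurped a breeding position, where immigrants
arrived, and whether inbreeding is occurring. Two properties of the data
make this hard. First, faecal DNA is dilute and degraded, so genotypes
carry two error classes: *allelic dropout* (E1), where one allele of a
heterozygote fails to amplify and the locus is scored as a homozygote,
and *stochastic miscall* (E2), where an allele is read as a different
allele. Second, sampling is opportunistic: many animals — especially
parents of the earliest cohorts — are never sampled, and almost nothing
is known about ages. `wolfped` implements a complete, testable pipeline
for this setting.

## Consensus genotypes and individual identification

Each sample is amplified in three independent PCRs per locus. A
heterozygous genotype is accepted when the same heterozygote is observed
in at least two replicates of the triplicate; a homozygote only when all
three replicates show the identical homozygote. A locus failing both
rules triggers a second triplicate, judged on its own (a configuration
switch pools all six replicates instead); a locus unresolved after six
replicates is treated as missing. The sequential reading mirrors the
laboratory workflow: the second series of three replicates is a fresh
attempt, not additional evidence mixed into the first.

Samples are clustered into individuals by pairwise genotype matching:
at most two mismatching alleles in total, at most one at any single
locus, and at least eight loci typed in both genotypes before any call
is made (below that the comparison is a no-call). Two mismatches
concentrated at one locus (A/B vs C/D) are *not* a match under the
default rule — a single-locus double discrepancy is more likely a
different animal than two independent errors at one locus. Matches are
edges of a graph; connected components are individuals; components held
together only by transitivity (some internal pair fails the rule) are
flagged `AMBIGUOUS` for review rather than split, since the correct
split is rarely identifiable automatically. With 17 loci at the
moderate diversity of a recolonising population this rule occasionally
merges full siblings whose genotypes differ by two alleles or fewer;
the synthetic-recovery results below include the cost of such merges.

## The genotyping-error model

The generative observation model has two stages. For a true
heterozygote, with probability E1 one of the two alleles (chosen
uniformly) drops, leaving an apparent homozygote; homozygotes are
unaffected. Then each apparent allele copy is independently misread
with probability E2, the replacement drawn from the locus' other
alleles proportional to their population frequency (a uniform option
exists). E2 is per allele copy, not per genotype — the choice is
declared here because the literature uses both conventions — and the
model is isolated behind `observation_distribution()` so an alternative
can be swapped in. Null alleles, contamination and stutter are out of
scope.

## Parentage likelihood and the pedigree sampler

For an offspring with observed multilocus genotype and a candidate
parent pair, the likelihood integrates over true genotypes:
the offspring contributes the observation density of its observed
genotype given each true genotype; each sampled candidate parent enters
through the posterior of its true genotype given its own observation
(Hardy-Weinberg prior times observation density, normalised); an
UNSAMPLED parent is integrated over Hardy-Weinberg directly. Loci
untyped in the offspring contribute a factor of one. The conditional
form keeps sampled and unsampled candidates on one scale.

The sampler is a Gibbs sweep over offspring: each (dam, sire) pair is
drawn from its full conditional, the product of the pair likelihood and
categorical prior weights `1/(n + N)` per sampled candidate and
`N/(n + N)` for the UNSAMPLED category, where `N` is the current
unsampled population size of that sex. Draws that would create a cycle
(the offspring an ancestor of its own parent) are removed from the
conditional's support and redrawn, which enforces legality exactly.
`N` for each sex follows a broad lognormal prior — meanlog `log(7)` for
males and `log(2)` for females, sdlog 0.5, reflecting male-biased
long-distance immigration — and is updated by random-walk
Metropolis-Hastings on the log scale, with the step size tuned during
burn-in into a 30--50% acceptance window. Chains are thinned every 2
iterations. Individuals are swept in reverse detection order, so
later-observed animals are fitted as offspring first; with no explicit
age data this ordering (plus initialisation at all-UNSAMPLED) is what
orients parent-offspring links. Candidate parents are pre-filtered: a
candidate mismatching the offspring (no shared allele) at more than 4
loci is excluded, as are wrong-sex candidates, candidates known to have
died before the offspring's cohort, and candidates below the minimum
breeding age of 2 years where cohorts are known.

The sweep is compiled (Rcpp). Because the prior weights take only two
values per role, the dam marginal is computed from precomputed row sums
in O(candidates) per offspring, which is what makes the protocol's
replicated chains practical on one CPU.

Correctness is established against brute force: on small instances the
posterior pair frequencies are compared with exact enumeration of every
jointly legal configuration weighted by likelihood times prior, and
with the likelihood switched off the unsampled-size chains reproduce
their lognormal priors (Kolmogorov--Smirnov).

## The staged protocol

Estimation proceeds in six steps, each a pure function of its inputs,
configuration and seed:

1. **Preliminary pedigree** — one chain of 20,000 iterations (burn-in
   2,000) at fixed literature rates E1 = 0.04, E2 = 0.022.
2. **Error-rate estimation** — per locus, Metropolis-Hastings under
   Beta(4, 100) (E1) and Beta(2, 100) (E2) priors, initialised at 0.1.
   The likelihood combines replicate concordance (all replicates of all
   samples of an individual share one latent genotype) with Mendelian
   priors from the >90%-confidence links of step 1. Faecal samples
   carry the estimated rates; tissue/secretion samples are too few to
   estimate and use constants (defaults 0.01/0.005).
3. **Possible breeders** — 20 chains of 25,000 iterations; an
   individual assigned in at least 5% of parentages across the pooled
   modal pedigrees (denominator: offspring count per parental role per
   run) becomes a possible breeder. The per-run alternative is a
   configuration switch.
4. **Main fits** — 20 chains of 30,000 iterations with candidates
   restricted to possible breeders.
5. **Averaging** — per offspring, each pair's support is averaged over
   the 20 modal pedigrees with absent-in-run counting as zero (a
   present-only option exists); the best mean wins, ties broken toward
   UNSAMPLED (the conservative direction: no false sampled-parent
   link), then lexicographically.
6. **Consistency checks** — birth years are inferred from first
   detections (litter members are assumed first detected in their birth
   year; founders stay undetermined unless a known age at death pins
   them), and the pedigree is scanned for anachronisms (parent younger
   than 2 at the offspring's birth), medium-confidence (0.70--0.80)
   pairs with a single offspring (wolf pairs produce litters, so such
   pairs are suspect), and two litters in one territory-year. Flags are
   reports, not automatic edits: changes go through
   `apply_corrections()` with an explicit ledger (reason codes
   `ANACHRONISM`, `SINGLE_OFFSPRING_PAIR`, `TERRITORY_CONFLICT`,
   `CONFIRMED`), and edits that would make the pedigree illegal are
   rejected.

Confidence vocabulary throughout: *confident* >0.80, *high* >0.90,
*very high* >0.95, *medium* 0.70--0.80.

## The synthetic population

The generator emulates the study system rather than any particular
dataset: territories settled gradually (establishment lags 0, 1, 2, 3
years across 4 packs over 7 breeding years), a single breeding pair per
territory producing at most one Poisson(4) litter per year, annual
adult mortality 0.15, vacancies refilled by inheritance from the natal
pack (probability 0.3), female-biased local dispersal (0.3), and
male-biased immigration (0.5; immigrants carry UNSAMPLED parents), with
parent-offspring pairings barred. The detection layer observes each
individual-year with probability 0.7, draws a negative-binomial number
of samples per detected individual (mean 4, size 5, truncated at one —
most individuals yield a handful of samples, a few up to a dozen),
makes 93% of samples faecal,
and generates triplicate replicate PCR observations through the error
model (per-replicate amplification failure 0.05) with the
second-triplicate escalation. Allele frequencies come from a
constructed 17-locus panel whose per-locus expected heterozygosities
span roughly 0.2--0.8 with mean 0.58 (2--9 alleles per locus,
Dirichlet draws accepted against per-locus targets). These defaults
reproduce the *scale* of the study system (~80--90 detected
individuals, ~7 breeding pairs); none of them is an estimate of any
real population, and the demographic defaults not fixed by the study
conditions were chosen once on plausibility grounds.

What the generator deliberately does not model: genotyping artefacts
beyond dropout/miscall (stutter, null alleles, contamination),
spatially explicit dispersal, uncertainty in species assignment, and
multi-population structure in the allele frequencies. Passing recovery
tests on this generator therefore demonstrates the statistical
machinery under the declared error model, not robustness to every
pathology of real faecal genotyping.

## Numerical choices and problem sizes

Pair likelihoods are precomputed per offspring as matrices over
(dam, sire) candidates and rescaled per offspring before
exponentiation; zero likelihoods are floored at 1e-300 before logging.
The allele-frequency inbreeding estimator maximises the per-individual
likelihood on F ∈ [0, 1] by golden-section search (tolerance 1e-6) with
explicit endpoint checks; it is a generic maximum-likelihood stand-in,
deliberately simple, and its population mean is not comparable across
software without checking the estimator in use. Frequency tables must
sum to one per locus within 1e-9; novel alleles are added at frequency
0.005 ("low", unquantified in field practice) and renormalised.

The marker-panel power experiment simulates genotypes on the fitted
(or true) pedigree at panel sizes from 5 to twice the panel, refits
steps 3--5 and scores confident (>0.80) and correct assignments. By
design the power fits can reuse the main analysis' possible-breeder
set — the same restriction the study itself carried into its
simulations — because re-identifying breeders from a single noisy
simulated genotype set intermittently drops true parents of small
litters and floods the score with confident-but-wrong UNSAMPLED
assignments; re-running step 3 per data set remains available.

The test suite runs the protocol at reduced chain sizes — 10 runs of
10,000 iterations for the breeder-identification and main stages, and
5 runs of 5,000 iterations inside the panel-power experiment with 3
replicates per panel size — chosen so the full suite completes in tens
of minutes on one CPU while leaving the qualitative behaviour
(confident recovery above 75% of slots, false positives among confident
assignments below 2%, a panel-power rise from 5 to 17 loci far beyond
its standard error) stable under the fixed seeds. The package defaults
remain the full settings listed above.

## Known limitations

Sibship versus parentage remains partially confounded when one parent
is unsampled and no temporal information orients the link (both
relationships have r = 0.5); the detection-order sweep mitigates but
cannot resolve this. The matching rule can merge full siblings at
moderate panel diversity (flag review of `AMBIGUOUS` components is the
defence). Error rates estimated from per-sample replicates are
conservative when applied to consensus genotypes built from several
samples, which lowers assignment confidence more than accuracy — the
main reason recovery is limited by confidence rather than correctness.
The breeder-restriction threshold trades dimensionality against the
risk of orphaning offspring of rarely-assigned true breeders; both the
threshold and its denominator convention are configuration options.
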