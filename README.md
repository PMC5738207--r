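# wolfped

Individual-based genetic monitoring of wolf populations from
non-invasively collected samples (scats, hair, urine, opportunistic
tissue), for wildlife geneticists and managers who need to know *who is
breeding with whom* in a recolonising population without ever handling an
animal.

Faecal DNA is dilute and degraded, so the raw material is noisy: alleles
drop out, genotypes get miscalled, many animals are never sampled, and
there is almost no age information. `wolfped` implements the full
analytical chain that turns replicate-PCR microsatellite calls into a
multigenerational pedigree with calibrated confidence:

1. **Consensus genotyping** from triplicate PCRs (heterozygote accepted
   when seen in two replicates, homozygote when identical in all three;
   a second triplicate on failure, missing after six replicates).
2. **Individual identification** by multilocus genotype matching (at most
   two mismatching alleles, at most one per locus) and graph clustering.
3. **A two-stage genotyping-error model**: allelic dropout at rate E1
   turns heterozygotes into apparent homozygotes; each allele copy is
   independently miscalled at rate E2 into another allele of the locus,
   frequency-weighted.
4. **Bayesian pedigree reconstruction**: Gibbs sampling over per-offspring
   (dam, sire) assignments. A pair's full-conditional weight is

   `P(dam = d, sire = s | ...) ∝ L(g_o | g_d, g_s) · w(d) · w(s)`

   where `L` integrates the observed trio genotypes over true genotypes
   under the error model and Mendelian transmission, and the categorical
   prior weights are `w(candidate) = 1/(n + N)` and
   `w(UNSAMPLED) = N/(n + N)` for `n` enumerated candidates and `N` the
   current unsampled population size of that sex. `N` gets a lognormal
   prior (males: meanlog log 7; females: meanlog log 2; sdlog 0.5) and
   random-walk Metropolis-Hastings updates tuned to a 30--50% acceptance
   rate; pedigree legality (acyclicity) is enforced at every iteration.
5. **The staged estimation protocol**: preliminary fit at fixed rates
   (E1 = 0.04, E2 = 0.022) → per-locus error-rate estimation under
   Beta(4, 100)/Beta(2, 100) priors against the >90%-confidence links →
   possible-breeder identification from 20 replicate fits (≥5% of
   parentages) → 20 restricted main fits → averaging of modal pedigrees →
   biological consistency checks (minimum breeding age 2, one litter per
   territory-year) and a documented corrections ledger.
6. **Pedigree statistics**: kinship φ, inbreeding F = φ(dam, sire),
   relatedness r = 2φ/√((1+F_a)(1+F_b)), expected heterozygosity, and a
   maximum-likelihood allele-frequency inbreeding estimator.
7. **Marker-panel power simulation**: genotypes simulated on a known
   pedigree at panel sizes 5--34, refitted (protocol steps 3--5) and
   scored as confident (>80% support) and correct.
8. **A synthetic wolf-population generator** (packs, alpha pairs, annual
   litters, inheritance/dispersal/immigration, detection and sampling)
   with full ground truth, used throughout the tests.

## Worked example

```r
library(wolfped)

# a synthetic study: 4 territories settled over 7 breeding years,
# 17 microsatellites at panel H_E ~ 0.58, faecal E1 = 0.04, E2 = 0.022
truth <- simulate_truth(seed = 20260901)
truth
#> <wolfped_truth> 86 detected individuals (of 95), 318 samples, 17982 replicate rows

inp    <- truth_to_inputs(truth)        # consensus calls + identification
freqs  <- augment_frequencies(truth$freqs, inp$genotypes)
proto  <- run_protocol(inp$individuals, inp$genotypes, freqs,
                       replicates = truth$replicates,
                       membership = inp$membership,
                       metadata   = truth$samples,
                       detections = inp$detections,
                       config = protocol_config(
                         step3 = list(runs = 10, iterations = 10000,
                                      burn_in = 1000,
                                      breeder_threshold = 0.05,
                                      aggregation = "pooled"),
                         step4 = list(runs = 10, iterations = 10000,
                                      burn_in = 1000)),
                       seed = 2026)

glance(proto)
#> # A tibble: 1 × 7
#>    both only_mother only_father neither n_individuals n_breeders n_flags
#>      80           0           0       5            85         11      23

# score against the generating pedigree (undetected parents count as
# outside the sampled set)
truth_ped <- subset(truth$pedigree, id %in% proto$main_pedigree$id)
known <- c(proto$main_pedigree$id, NA, "UNSAMPLED")
truth_ped$dam[!(truth_ped$dam %in% known)]   <- "UNSAMPLED"
truth_ped$sire[!(truth_ped$sire %in% known)] <- "UNSAMPLED"
evaluate_assignments(proto$main_pedigree, truth_ped, threshold = 0.8)
#> # A tibble: 1 × 5
#>   n_assignable n_confident n_confident_correct n_correct fp_fraction
#>          170         160                 157       167      0.0188
```

Read: of the 170 parent slots (mother and father of 85 identified
individuals), 160 were assigned with >80% support and 157 of those name
the true parent — 92% of all slots confidently *and* correctly resolved,
with 1.9% of confident assignments wrong. `autoplot(proto)` shows the
confidence histogram; `tidy(proto)` returns the pedigree as a tibble.

Pedigree arithmetic on the fitted (or any) pedigree:

```r
relatedness(tidy(proto)[c("id", "dam", "sire")], "W001", "W039")
inbreeding_coefficient(tidy(proto)[c("id", "dam", "sire")])
```

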