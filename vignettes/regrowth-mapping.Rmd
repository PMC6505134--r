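---
title: "Mapping dominant complementary regrowth loci in maize-teosinte F2 populations"
author: "regrowqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping dominant complementary regrowth loci in maize-teosinte F2 populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regrowqtl)
```

## The scientific problem

Perennial teosinte *Zea diploperennis* regrows from basal axillary buds after
flowering and senescence; annual maize does not. In F2 intercross populations
between the two, regrowth segregates as a binary trait (R = regrew, NR = did
not). `regrowqtl` provides the three analysis layers such a study needs:

1. **Segregation modelling.** Under complementary dominant epistasis over
   $k$ unlinked loci — at least one *Z. diploperennis* (Zd) allele required at
   *every* locus — the expected F2 regrowth fraction is $(3/4)^k$: 3:1 for
   one locus, 9:7 for two, 27:37 for three. `gof_test()` scores observed R/NR
   counts against each model by a two-class Pearson $\chi^2$ with one degree
   of freedom and no continuity correction; `best_fit_model()` picks the
   largest p-value, breaking ties toward the simpler model.
2. **SNP filtration.** GBS genotype matrices (plants $\times$ biallelic SNPs
   coded AA = homozygous Zd, AB = heterozygous, BB = homozygous maize) pass
   through a four-stage cascade: site coverage/minor-allele-frequency
   filters; removal of sites missing in more than 20% of plants with
   heterozygote imputation of the remaining gaps; a model-constrained
   contingency $\chi^2$ filter; and collapsing of 100-bp clusters of SNPs
   that share one haplotype.
3. **Genome scan.** A binary-trait single-locus scan: HMM conditional
   genotype probabilities on a $\le$ 1 cM grid with a genotyping-error
   allowance, EM estimation of the genotype-specific penetrances
   $\pi = (\pi_{AA}, \pi_{AB}, \pi_{BB})$, LOD profiles, genome-wide
   permutation thresholds and first/last-significant-SNP interval calling.

A seeded simulator (`simulate_f2_population()`, `simulate_backcross()`)
generates F2 and backcross populations with GBS-like noise under the same
two-locus model, so every stage is testable end to end without any external
data.

## The model-constrained SNP filter

The third filtration stage is the package's most model-specific step. For a
marker fully linked to one of the two complementary loci, combining the F2
1 AA : 2 AB : 1 BB segregation at the linked locus with the independent 3:1
dominance at the other locus gives the conditional genotype distributions

$$P(\mathrm{AA},\mathrm{AB},\mathrm{BB} \mid R) = (1/3,\ 2/3,\ 0), \qquad
  P(\mathrm{AA},\mathrm{AB},\mathrm{BB} \mid NR) = (1/7,\ 2/7,\ 4/7).$$

```{r cond}
conditional_genotype_probs("R")
conditional_genotype_probs("NR")
```

Observed six-cell counts (R/NR $\times$ AA/AB/BB) are compared with the
counts expected from these distributions; the statistic is summed over cells
with positive expectation and a SNP is kept iff $\chi^2 < 9.49$, the upper
5% point of $\chi^2_4$. Two numerical choices deserve comment:

* **Empty expected cells.** $E(\mathrm{BB} \mid R) = 0$, so the Pearson term
  is undefined there. We take the limit: a zero-expectation cell contributes
  nothing when its observed count is zero and forces rejection (statistic
  $+\infty$) when it is occupied. A single BB regrowth plant is enough to
  reject perfect linkage, which is exactly the model's prediction.
* **Degrees of freedom.** The critical value belongs to df = 4 (six cells
  minus the two subpopulation-total constraints), not the df = 2 a generic
  independence test would use. The df = 4 convention is what the published
  critical value 9.49 implies, and we keep the whole filter consistent with
  it.

The conditional probabilities are carried as integer numerators over
denominators 9 and 7, so expected counts downstream are free of repeating-
decimal drift; marginalizing them over the 9:7 phenotype prior returns the
unconditional 1:2:1 exactly, which the test suite checks in integer
arithmetic.

Interpretation note for the missingness stage: "more than 20%" is read
strictly (a site missing in exactly 20% of plants survives), and cluster
membership in stage 4 requires genotype identity across *all* plants, with
the 100-bp window anchored at the cluster's first member. On the worked
examples both the anchored and chained-gap readings of the window give the
same clusters; we fixed the anchored reading.

## The genome scan

### Genotype probabilities

Genotypes along a chromosome follow a three-state hidden Markov chain with
stationary distribution 1/4 : 1/2 : 1/4 and transition probabilities built
from the Haldane recombination fraction $r = (1 - e^{-2d/100})/2$ of each
interval via two independent meioses. Emissions allow genotyping error
$\varepsilon$ (default $10^{-4}$): the observed call is right with
probability $1 - \varepsilon$ and each wrong call has probability
$\varepsilon/2$. This symmetric error model is simpler than the richer
genotyping-error models some HMM implementations use; it is documented and
fixed. Missing calls are uninformative, so an isolated missing marker
returns the prior. Pseudomarkers are inserted evenly inside marker intervals
so no gap exceeds `step` (default 1 cM); they carry no observation and are
excluded from interval endpoints, which are defined by real SNP positions.

### Physical-to-genetic coupling

The scan is driven by physical bp positions; no genetic map is assumed to be
available. The default convention is 1 cM/Mbp (`build_genetic_map()`,
`physical_1cM_per_Mbp` mode), declared rather than estimated, and the
simulator uses the same coupling so simulated data are directly consumable.
An `em_estimated` mode estimates adjacent-pair recombination fractions by
the classic F2 EM (the double heterozygote's phase is the latent variable)
and is used in the tests to validate the simulator against Haldane's map
function. LOD thresholds are map- and data-dependent, so thresholds from
other datasets and other bp-to-cM conventions are not comparable.

### EM and the LOD

At each grid position the alternative model is the mixture
$\ell_1 = \sum_i \log \sum_g w_{ig}\, \pi_g^{y_i} (1-\pi_g)^{1-y_i}$,
maximized over the penetrances by EM; the null has one common penetrance
whose MLE is the phenotype mean, and $\mathrm{LOD} = (\ell_1 - \ell_0)/\ln 10$.
Numerical guards: penetrances start at the $w$-weighted phenotype mean
clamped to $[10^{-3}, 1-10^{-3}]$, are clamped to $[10^{-12}, 1-10^{-12}]$
during iterations (no $\log 0$), and iteration stops when the log-likelihood
improves by less than `em_tolerance` (default $10^{-8}$, at most
`em_max_iter` = 1000 iterations). The EM ascent property makes a LOD below
$-10^{-6}$ impossible; the implementation treats one as an internal error. A
constant phenotype saturates both models and yields an identically zero
profile.

### Permutation thresholds and intervals

Phenotype labels are permuted across plants with genotypes fixed; each
replicate reruns the full EM scan and records its genome-wide maximum LOD.
The threshold is the order statistic $\lceil (1-\alpha) n \rceil$ of the
sorted maxima — no interpolation, so the value is reproducible across
platforms. The permutations rerun the exact EM model rather than any faster
approximation. Intervals are called per chromosome as the closed bp span
from the first to the last real SNP at or above the threshold, with the
peak at the maximal-LOD SNP (leftmost on ties).

## The simulator and what it does (not) emulate

`simulate_f2_population()` builds fully inbred parents (Zd = AA everywhere,
maize = BB), a uniformly heterozygous F1, and F2 plants from two independent
F1 gametes. Meiosis has no crossover interference (crossover counts Poisson
with mean = map length in Morgans, positions uniform), matching the scan's
Haldane assumption. The phenotype is R iff every causal locus carries a Zd
allele; misclassification is applied next (default direction R scored as NR,
`misclassification_delta`, motivated by dormancy at scoring time; the
reverse direction defaults to zero); GBS noise is applied last.

Default study conditions, chosen once for realism and kept fixed:

* **Genome**: ten chromosomes with approximate maize physical lengths
  (301-151 Mbp) at the 1 cM/Mbp coupling; 50 uniformly placed markers per
  chromosome by default.
* **Causal model**: two loci on chromosomes 2 and 7 (at 33.0 Mbp and
  4.3 Mbp, mirroring the mapped regrowth loci), complementary dominant.
* **Missingness**: per-site rates drawn from Beta(1, 9) (mean 10%) — GBS
  depth varies by locus, not by plant, so missingness is a site property.
* **Genotyping error**: $10^{-4}$ per call, the same order as the scan's
  error allowance.
* **Transmission distortion**: off by default; optionally a locus with
  transmission probability $\beta \neq 0.5$ of the maize allele,
  implemented by rejection sampling of whole gametes so linkage is
  preserved.

The simulator does **not** model read-level data (no FASTQ, no allele
depths), linked selection, interference, time-dependent dormancy (the static
`misclassification_delta` stands in for it), or F3 and later generations.
Passing tests on these simulations therefore demonstrate correctness of the
statistical machinery under the stated genetic model — not robustness to
every artifact of real GBS data.

## Validation experiments

Three experiment functions re-run the whole pipeline at fixed, documented
problem sizes (chosen to keep a full validation run in the tens of minutes
on one CPU):

* `parameter_recovery_experiment()` — 20 seeded replicates of n = 200
  plants, 500 markers over the 10 default chromosomes, no phenotype
  misclassification, default GBS noise, 200-replicate permutation
  thresholds. Success means significant intervals on exactly the two
  planted chromosomes with peaks within 10 cM of the planted loci; the
  acceptance suite requires at least 90% success.
* `type1_calibration_experiment()` — 200 scaled-down null replicates
  (n = 100, two 80 cM chromosomes, 20 markers each, 100 permutations);
  phenotypes are permuted so genotype and phenotype are independent, and
  the rate at which a dataset's own maximum LOD exceeds its own threshold
  is compared with $\alpha = 0.05$ within three binomial standard
  deviations.
* `filter_enrichment_experiment()` — 20 replicates; model-filter survivors
  are tested for enrichment within 10 cM of the planted loci by a pooled
  one-sided Fisher exact test.

## Data conventions and degenerate inputs

* Coordinates are 1-based physical bp; intervals are closed
  `[start_bp, end_bp]`.
* The on-disk genotype coding is 1 = AA, 2 = BB, 3 = AB (note 3 = het — a
  trap for arithmetic on codes, which is why the internal vocabulary is the
  ordered {AA, AB, BB, missing} instead and the file coding lives only at
  the IO boundary). Phenotypes: 1 = R, 2 = NR, or the literal strings.
* The minimal VCF dialect is biallelic GT-only; allele orientation (which
  parent is REF) is declared by the caller, never guessed; multi-allelic
  records are rejected.
* Genotypes and phenotypes are joined by an explicit inner join with logged
  drops — mirroring a real study in which only a subset of phenotyped
  plants yields usable SNP calls.
* Chromosome ordering follows first appearance (numeric labels sort
  numerically), so chromosome "10" never sorts between "1" and "2".
* Unknown genotype tokens are parse errors naming row and column; empty
  phenotype files yield an empty table with a warning; a filter stage that
  removes every marker short-circuits the scan with an explicit note rather
  than failing.

## Known limitations

* The conditional-distribution machinery behind the model filter is derived
  for the two-locus (9:7) case only; other k are rejected explicitly.
* Segregation models with modifier loci or penetrance-adjusted ratios are
  out of scope; the goodness-of-fit layer tests the pure $(3/4)^k$ family.
* The scan is strictly single-locus: no multi-QTL models, covariates, or
  epistasis scans.
* Published LOD thresholds from real datasets cannot be reproduced here:
  they depend on the realized marker set and the (unpublished) bp-to-cM
  convention of the original analysis. The package instead validates its
  scan by parameter recovery and type-I calibration on simulated data.
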