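---
title: "Models and methods behind wisentpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind wisentpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wisentpanel)
```

`wisentpanel` implements a reduced-SNP-panel workflow for the European
bison, a species whose entire global population descends from 12
founders managed in two breeding lines (lowland, LL, from 7 founders;
lowland-Caucasian, LC, from those 7 plus 5 more including one
Caucasian bull). This vignette explains each model, the tunable
parameters, the synthetic-data generator the package validates itself
against, and the design decisions taken where the methodology was
genuinely open.

## Consensus calling from replicated genotypes

Non-invasive samples yield degraded DNA, so each sample is genotyped in
replicates (default minimum 3; invasive reference samples may be single
runs). Per autosomal marker the replicate tally `(nAA, nAB, nBB)` over
called replicates is collapsed by fixed precedence:

1. nothing called → No Call;
2. a heterozygote seen and *both* opposite homozygotes at least twice →
   heterozygous;
3. all three genotype classes present → heterozygous;
4. heterozygote count at least the larger homozygote count (and > 0) →
   heterozygous (an equal homozygote/heterozygote split is
   heterozygous);
5. strict majority → that genotype;
6. only the two homozygotes, tied → No Call.

The scoring protocol defines these rules but not their order; we apply
the most specific heterozygote-forcing rules first. Any other order
breaks at least one of the rules on some tally, and the package asserts
the whole precedence on every tally up to six replicates in its test
suite. Monotonicity holds: appending a replicate that equals the
current (correct) consensus never changes it.

**Error decomposition.** Every replicate call is compared with its
consensus where both are non-missing. At a heterozygous consensus a
homozygous replicate is an allelic dropout (ADO); a replicate carrying
an allele absent from the consensus is a false allele (FA). On a
biallelic panel the two are mutually exclusive, so genotyping-error
events GE = ADO + FA exactly. Rates are reported twice:

* *marginally* — events divided by all comparisons, so the GE rate is
  the sum of the ADO and FA rates; and
* *conditionally* — ADO events per heterozygous-consensus comparison
  and FA events per homozygous-consensus comparison, which are the
  per-event probabilities of the error model and what the generator's
  `pAdo`/`pFa` parameters mean.

Loci with a marginal GE rate above `geThreshold` (default 0.05, i.e.
5%) are flagged for exclusion. The threshold is configurable because
published protocols are inconsistent about its scale; 5% retains a
well-clustering marker with a ~2% error rate while removing unusable
assays.

**Sex determination** uses the single gonosomal marker with a
Y-diagnostic cluster: an individual is male if more than half of its
called replicates carry Y, female below half, undetermined on an exact
tie or with no data. Majority voting (rather than "any Y means male")
is used because the observed failure modes of such markers — a female
with 4 of 6 spurious Y calls becoming a false-positive male, and 3 of 6
being undeterminable — are exactly majority-with-tie semantics.

## Individual discrimination

Per biallelic locus with allele frequencies $p, q$:

$$\mathrm{PID}_l = p^4 + q^4 + (2pq)^2, \qquad
\mathrm{PIDsib}_l = \tfrac14 + \tfrac12(p^2+q^2) +
\tfrac12 (p^2+q^2)^2 - \tfrac14 (p^4+q^4).$$

Loci are ranked by descending expected heterozygosity and the products
accumulated in log space (beyond ~30 loci the cumulative values
underflow double precision otherwise). `pidCurves()` reports the locus
count at which each curve first drops below a threshold, default
$10^{-4}$, the conventional bound for natural populations. Pairwise
allele mismatches are counted over loci called in both individuals;
repeated samples of one individual are grouped at `maxMismatch = 3`,
far below the minimum between-individual mismatch the panel produces
(~10–20 loci on synthetic data, 17 on real panels of this kind).

## Parentage

Full-likelihood sibship reconstruction is out of scope; instead each
pair is scored by

* **exclusions** — loci where the two genotypes are opposing
  homozygotes, impossible for parent and offspring barring error; and
* **LOD** — per locus
  $\log_{10} \frac{(1-\varepsilon) T(g_o \mid g_c) +
  \varepsilon P_{HW}(g_o)}{P_{HW}(g_o)}$, where $T$ is the single-parent
  Mendelian transition probability with the unknown parent drawn from
  Hardy–Weinberg and $\varepsilon = 10^{-4}$ reflects the reliability of
  consensus genotypes built from triplicates.

A candidate passes with exclusions ≤ 1 and LOD > 0. One tolerated
exclusion means a single mis-scored locus cannot veto a true parent at
$\varepsilon = 10^{-4}$ over 63 loci. With $\varepsilon = 0$ the rule
reduces exactly to pure exclusion (LOD $= -\infty$ iff an exclusion
exists), asserted by enumeration in the tests. Orientation
(who is parent, who is offspring) is genetically undetermined and
reported as such; candidates are pooled by sex, exact LOD ties among
passing candidates are flagged ambiguous, and the family network keeps
the best passing candidate per pool. Against a supplied pedigree,
expected links are labeled verified / not-verified / not-testable and
extra assignments novel.

## Marker selection

The selection workflow first removes every individual whose sire and
dam are both genotyped (keeping maximal allele variation while removing
first-degree redundancy — on a completely genotyped pedigree this
leaves the founders). On the filtered set:

* **HWE**: χ² goodness-of-fit with 1 df per locus (exact mid-p variant
  available), familywise α = 0.05 with Bonferroni correction. The
  α and the LD threshold are not dictated by any published protocol;
  both are surfaced as parameters.
* **LD**: composite R² — squared Pearson correlation of 0/1/2 dosage
  vectors over individuals called at both loci (data are unphased, so
  no haplotype EM) — with greedy pruning at R² > 0.8, removing the
  locus with the higher mean R² from each violating pair.
* **Line subset**: per-locus Nei-style
  $F_{ST} = (H_T - H_S)/H_T$ from the two lines' allele frequencies
  with unweighted group means, thresholded at 0.075. Weir–Cockerham
  θ is available as an option; the default matches the
  spreadsheet-tool convention under which the 0.075 threshold was
  calibrated.
* **Private alleles**: alleles with nonzero count in exactly one line.

## Breeding-line assignment

Two deliberately different methods are run and combined:

* `mlCluster()` — classification EM under a Hardy–Weinberg-within-
  cluster likelihood: hard assignment in the E-step, maximum-likelihood
  cluster allele frequencies in the M-step, 20 multi-starts (k-means on
  dosage plus random restarts) under a deterministic seed schedule.
  The classification log-likelihood is non-decreasing and asserted so.
  **BIC** is computed from the equal-proportion *mixture*
  log-likelihood at the fitted frequencies with $\nu = K \times L$ free
  parameters: the classification log-likelihood itself is
  optimistically biased (each individual contributes its best-fitting
  cluster) and in calibration runs on the two-line design (FST 0.1, 18
  loci) it selected K = 3–4 in most runs, whereas the mixture
  likelihood selects K = 2 essentially always.
* `bayesAssign()` — supervised leave-one-out assignment: per line,
  posterior-predictive genotype probabilities under a Beta(1, 1) prior
  on allele frequencies estimated from that line's reference
  genotypes excluding the focal individual. This replaces full MCMC
  admixture clustering, defensible because the management use case (two
  predefined lines with reference individuals) is supervised in
  practice.

`decideLines()` assigns a line only when both methods give it at least
60% probability, otherwise the individual is unassigned with a
below-threshold or method-conflict flag. F1 hybrids of the two lines
sit near 50/50 and fail the dual rule at several times the purebred
rate in simulation — mirroring their intended treatment in management.

## Cross-species detection

Individuals (focal and non-target taxa) are gated at an 80% call rate
over the autosomal loci; excluded taxa are listed, not silently
dropped. Pairwise squared codominant distances (0 identical, 1
homozygote–heterozygote, 4 opposite homozygotes — squared dosage
differences) are summed over shared called loci and rescaled by
total/shared locus count (unbiased under missing-at-random; no
genotypes are imputed). The matrix is double-centered and
eigendecomposed; negative eigenvalues are reported rather than hidden,
and coordinates reproduce every Euclidean-embeddable distance to 1e-8
(asserted in tests).

## Diversity: molecular and pedigree

Per locus and line: $H_O$, Nei's unbiased
$\hat h = \frac{2n}{2n-1}(1 - \sum p_i^2)$; $H_S$ is the unweighted
mean of $\hat h$ over lines and $H_T = 1 - \sum \bar p_i^2$ from
unweighted mean frequencies (Nei–Chesser small-sample correction
available, off by default to match the plain definitions). F-statistics
come in the two averaging modes spreadsheets commonly disagree on —
the arithmetic mean of per-locus values, and values recomputed from
locus-averaged H's; in the latter mode
$(1-F_{IT}) = (1-F_{IS})(1-F_{ST})$ holds to machine precision.
Allelic richness is rarefied to the smallest line's gene-copy count per
locus. Standard errors are jackknife-over-loci.

Pedigree analytics use the tabular kinship recursion
($f_{ii} = \tfrac12(1 + f_{\text{sire},\text{dam}})$, unknown parents
treated as unique non-inbred founders). Gene diversity is computed two
ways: $1 - \overline f$ over all ordered pairs of living individuals
*including self-pairs* — the convention under which the closed form and
the gene-drop estimator target the same quantity — and by gene drop
(default 1000 iterations, unique founder alleles transmitted by
Mendelian sampling). Pedigree F-statistics use mean inbreeding, mean
within-line coancestry (self-pairs excluded) and overall mean
coancestry with unweighted group means; group-size weighting
conventions differ between studbook tools, so the choice is stated in
the output metadata.

## The synthetic-data generator

`simulatePopulation()` emulates the study system: 12 founders, 7
seeding line A, discrete generations of random within-line mating
(Poisson(3) offspring per female, exact 1:1 offspring sex ratio), and
one-directional gene flow — with probability `migration` (default
0.05) a line-B female is sired by a line-A male, never the reverse.
Founder allele frequencies are Beta(2, 2) per marker (a panel selected
for polymorphism is enriched for intermediate frequencies); descendants
are produced by Mendelian gene dropping, cross-species markers are
fixed in the focal species, and the sex marker follows the recorded
sex. `observeReplicates()` applies, independently per replicate call:
No Call with probability 0.076 (non-invasive; 0.02 invasive, tuned so
expected call rates are ~92.4% and ~98%), allele dropout of a
heterozygote with 0.016, and a spurious second allele on a homozygote
with 0.003; at the sex marker the FA mechanism produces spurious Y
calls in females and ADO drops the Y in males. Error events are
independent across calls — published error profiles report only
marginal rates, so independence is the minimal model; the event log is
retained so estimators are scored against exact truth, not just rates.

What the generator does *not* emulate: overlapping generations and
non-random mate choice, correlated (sample-quality-driven) error and
missingness, linkage (the real panel was filtered to unlinked loci),
and ascertainment bias of the marker discovery process. Passing tests
therefore demonstrate correctness of the estimators under the stated
error model, not robustness to structured noise in field data.

## Numerical choices and problem sizes

PID products, clustering likelihoods and LOD scores accumulate in log
space. EM stops when the classification log-likelihood improves by
less than 1e-10 (100 iterations cap, non-convergence flagged); empty
clusters retain their previous frequencies for the iteration. Ties:
het-count ties in consensus go heterozygous (rule 4), opposing-homozygote
ties go No Call, exact LOD ties among passing parentage candidates are
ambiguous, and cluster labels are aligned to lines through labeled
anchors (an error if none exist). The validation suite runs at desk
scale, chosen to keep the whole suite under a minute while leaving the
statistical assertions well-powered: populations of ~150–350
individuals over 3–6 generations, 63–96 markers, 100 seeded clustering
runs, 50 random pedigrees for the gene-drop/kinship cross-check, and
20000-iteration gene-drop oracles for kinship spot checks.
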