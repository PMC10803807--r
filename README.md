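# wisentpanel

Genetic assessment of the European bison (*Bos bonasus*) — a species
rebuilt from only 12 founders and managed in two breeding lines (the
lowland line LL and the lowland-Caucasian line LC) — relies on a reduced
96-SNP panel that works with non-invasive samples such as dung, hair and
urine. `wisentpanel` implements the full analysis workflow behind such a
panel for conservation geneticists and studbook managers:

* **Consensus genotyping from replicates.** Non-invasive samples are
  genotyped in ≥ 3 replicates; per-marker consensus follows fixed
  precedence rules (majority voting with heterozygote-forcing rules,
  e.g. an equal homozygote/heterozygote split is called heterozygous,
  opposing homozygotes at 50:50 yield no call).
* **Error decomposition.** Each replicate is compared against the
  consensus: a homozygous replicate at a heterozygous consensus is an
  allelic dropout (ADO), a replicate showing an allele absent from the
  consensus is a false allele (FA); genotyping error GE = ADO + FA.
  High-error loci are flagged (GE rate > 5% by default).
* **Sex determination** by majority vote over the Y-associated marker
  cluster (> 1/2 Y-bearing replicates → male; exactly 1/2 →
  undetermined).
* **Individual discrimination.** Probability of identity, cumulated
  over loci ranked by expected heterozygosity,
  `PID_l = Σ p_i⁴ + Σ_{i<j} (2 p_i p_j)²` and its full-sibling analogue
  `PIDsib_l = 1/4 + (1/2) Σ p_i² + (1/2)(Σ p_i²)² − (1/4) Σ p_i⁴`,
  plus pairwise allele-mismatch matching of repeated samples.
* **Parentage.** Mendelian exclusion (opposing homozygotes) combined
  with a pairwise likelihood-ratio (LOD) test,
  `P(g_o | parent) = (1−ε) T(g_o | g_c) + ε P_HW(g_o)` with per-locus
  error rate ε = 10⁻⁴, and family-network assembly with
  pedigree-concordance labels.
* **Marker subset selection.** Hardy–Weinberg χ² testing, composite LD
  (dosage R²) pruning, per-locus Nei F_ST ranking between the lines
  (line subset at F_ST ≥ 0.075) and private-allele detection, on a
  first-degree-relative-filtered individual set.
* **Breeding-line assignment** with two independent methods —
  classification-EM maximum-likelihood clustering (BIC over K) and
  supervised leave-one-out Bayesian allele-frequency assignment — and
  the dual rule: a line is assigned only if *both* methods give it
  ≥ 60% probability.
* **Cross-species detection**: 80% call-rate gating and principal
  coordinates analysis of codominant squared distances (0/1/4 per
  locus).
* **Diversity**: molecular heterozygosities, F-statistics under two
  averaging modes, rarefied allelic richness; pedigree kinship (tabular
  method), inbreeding, gene diversity by kinship closed form and by
  gene drop, founder contributions, and pedigree F-statistics — so
  molecular and studbook-based estimates can be laid side by side.

A first-class synthetic-data module (`simConfig()`,
`simulatePopulation()`, `observeReplicates()`,
`makeNontargetGenotypes()`) emulates the study system — a 12-founder
bottleneck, 7 founders seeding line A, one-directional gene flow, and a
replicate error model with ADO 1.6%, FA 0.3% and a ~92.4% non-invasive
call rate — so the entire pipeline is testable without any external
data.

## Worked example

```r
library(wisentpanel)

cfg   <- simConfig(seed = 42)          # study-condition defaults
truth <- simulatePopulation(cfg)
truth$pedigree
#> Pedigree: 508 individuals (12 founders, 508 alive)

rcs <- observeReplicates(truth, cfg)   # 3 noisy replicates per sample
gm  <- consensusGenotypes(rcs,
  lines = setNames(pedRecords(truth$pedigree)$line,
                   pedRecords(truth$pedigree)$id))

er <- estimateErrorRates(rcs)
round(100 * er$overall[c("adoRateHet", "faRateHom", "geRate")], 2)
#> adoRateHet  faRateHom     geRate
#>       1.61       0.26       0.70

curve <- pidCurves(gm)
attr(curve, "lociToThreshold")
#>    pid pidsib
#>     10     18

dv <- molecularDiversity(gm)
dv$fstats
#>   statistic perLocusMean  perLocusSE   fromMeanH fromMeanHSE
#> 1      F_IS -0.008397075 0.008179561 -0.01117136 0.008867125
#> 2      F_ST  0.072901535 0.014339802  0.07906316 0.017210677
#> 3      F_IT  0.066082310 0.015676106  0.06877504 0.018504111

gd <- geneDiversity(truth$pedigree, iterations = 1000, seed = 1)
c(GD_kinship = gd$gdKinship, GD_genedrop = gd$gdGeneDrop)
#>  GD_kinship GD_genedrop
#>   0.8840795   0.8847670
```

Reading the output: the estimated conditional error rates recover the
generating profile (ADO 1.6% per heterozygous replicate call, FA 0.3%
per homozygous call); cumulative PID drops below the conventional 10⁻⁴
threshold after 10 loci and PIDsib after 18, i.e. the panel can
distinguish individuals, even full siblings, with a comfortable margin;
F_IS near zero reflects random mating within lines while F_ST ≈ 0.07
carries the between-line differentiation; and the two pedigree
gene-diversity estimators (closed-form mean kinship vs 1000 gene-drop
iterations) agree to three decimals.

Real data enter through `readCallTable()` (long or wide replicate call
tables), `readPedigree()` (studbook-style CSV) and leave through
`writeGenotypeMatrix()` (native CSV, PLINK PED/MAP, gzipped VCF v4.2).

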