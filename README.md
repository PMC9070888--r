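# sexhet

Discovery and functional characterization of **sex-heterogeneous SNPs**
("sex-het" SNPs) — autosomal variants whose estimated effects on
quantitative traits differ between females and males beyond sampling error —
from sex-stratified GWAS summary statistics.

Most complex traits and diseases show sex differences that the sex
chromosomes do not explain. One way to get at autosomal contributions is to
scan female- and male-stratified GWAS of biometric traits for variants with
sexually dimorphic effects, and then ask whether those variants play an
outsized role elsewhere: in disease association signal, in constrained
genes, in developmental gene sets, and in regulatory/QTL maps. `sexhet`
implements that whole workflow for analysts working from summary statistics,
including the permutation machinery needed to separate "this SNP set is
trait-associated" from "this SNP set is *sex-heterogeneous*".

## The statistics at the core

For each SNP and trait, with stratified estimates (&beta;<sub>F</sub>,
SE<sub>F</sub>) and (&beta;<sub>M</sub>, SE<sub>M</sub>):

* **Cochran's Q** (two strata, 1 df):
  Q = (&beta;<sub>F</sub> &minus; &beta;<sub>M</sub>)² / (SE<sub>F</sub>² + SE<sub>M</sub>²),
  with P<sub>Q</sub> from the upper &chi;²₁ tail. Trait-specific sex-het
  SNPs satisfy P<sub>Q</sub> &lt; 5&times;10⁻⁸ and MAF &ge; 0.1%.
* **Heterogeneity Z-score**:
  Z<sub>het</sub> = (&beta;<sub>F</sub> &minus; &beta;<sub>M</sub>) / &radic;(SE<sub>F</sub>² + SE<sub>M</sub>²),
  converted to the effect scale for meta-analysis by
  &beta;<sub>het</sub> = Z<sub>het</sub> / &radic;(2p(1&minus;p)(n + Z<sub>het</sub>²)) and
  SE<sub>het</sub> = 1 / &radic;(2p(1&minus;p)(n + Z<sub>het</sub>²)),
  where p is the allele frequency and n the total sample size.
* **Cross-trait meta-analysis**: fixed-effects (inverse-variance) pooling of
  the signed &beta;<sub>het</sub> across traits (sign = which sex has the
  larger absolute marginal effect), with an optional correlated
  fixed-effects (Lin–Sullivan) correction for overlapping samples.
* **LD clumping**: greedy selection by ascending best P<sub>Q</sub> keeping
  SNPs pairwise below r² = 0.2 yields the independent sex-het catalog.
* **Matched permutation nulls**: sets of sex-homogeneous SNPs matched to the
  catalog on MAF (&plusmn;0.001 for MAF &lt; 0.01, else &plusmn;0.02) and on
  combined-sex marginal-effect rank (&plusmn;75 positions), excluding LD
  neighbors (r² &gt; 0.2) of catalog SNPs. Any enrichment statistic gets an
  empirical p-value empP = (1 + #{null &ge; observed}) / (N + 1).
* **Enrichment / ORA**: percent of catalog SNPs with disease p &lt; 0.05
  versus the 5% null (1-df goodness of fit) with empP; SNP-set and interval
  overlaps (meQTL, predicted-eQTL, regulatory annotations); nearest-gene
  annotation (&le;25 kb rule), pLI constraint checks, and Fisher-exact
  gene-set overrepresentation with fold enrichment FE = observed/expected,
  BH-FDR and permutation-calibrated empP.

A synthetic-data generator (`simConfig()`, `simulateSumstats()`,
`simulateDisease()`, `simulateAnnotations()`) emulates every input with
planted ground truth, so the pipeline is fully testable without downloads.

## Worked example

A two-trait synthetic genome with 20,000 SNPs and 80 planted sex-het SNPs,
through discovery, clumping, matching and disease enrichment:

```r
library(sexhet)
options(sexhet.verbose = FALSE)

cfg <- simConfig(nSnps = 20000, nTraits = 2, sexhetFrac = 0.004, seed = 7)
sim <- simulateSumstats(cfg)
paired  <- lapply(sim$sumstats, function(tr) harmonizePair(tr$female, tr$male))
hetList <- lapply(paired, hetStats)
sapply(hetList, function(h) genomicInflation(chisq = h$q_stat))
#>   trait1   trait2
#> 1.084906 1.023624

meta       <- metaFixedTable(hetList)
candidates <- combineUniMulti(hetList, meta)
ann        <- simulateAnnotations(cfg, sim$truth)
(catalog   <- clumpSnps(candidates, ann$ld))
#> SexHetCatalog: 65 independent tag SNPs (r2 < 0.2)
#>      snp_id chrom     pos         maf     best_p_q leading_trait     direction
#> 1 rs0006664  chr2 2504500 0.055326030 1.029923e-17        trait2   male_driven
#> 2 rs0019314  chr4 6479500 0.282562808 5.108437e-16        trait1   male_driven
#> ...

table(tbl(catalog)$direction)
#> female_driven   male_driven
#>            28            37

index  <- buildMatchingIndex(paired[[1]], catalog, ann$ld)
nulls  <- sampleMatchedSets(index, nSets = 100, seed = 7)
disease <- simulateDisease(cfg, sim$truth, scenario = "pleiotropic")
signalEnrichment(catalog, disease, nullSets = nulls)
#> EnrichmentResult: n_overlap=65 observed=10.77% expected=5.00% chi2P=0.0328 empP=0.0099
```

Reading: the genomic inflation of the Q statistic is near 1 (the scan is
calibrated); 65 independent sex-het tags are recovered, split roughly evenly
between female- and male-driven effects; 10.8% of them associate with the
simulated pleiotropic disease at p &lt; 0.05 against the 5% expectation, and
the matched-null empirical p (0.0099, i.e. above all 100 null sets) shows
the excess is specific to sex-heterogeneity, not to trait association or
allele frequency.

`runPipeline()` executes the same stages (plus gene annotation, ORA,
regulatory and QTL overlaps) from a single YAML-able config and writes TSV
outputs with a reproducibility manifest.

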