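---
title: "Methods: sex-heterogeneity discovery and matched-null enrichment"
author: "sexhet package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-heterogeneity discovery and matched-null enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexhet)
options(sexhet.verbose = FALSE)
```

# The model

`sexhet` works entirely from summary statistics. For SNP $i$ and one trait,
the female and male strata provide effect estimates
$\hat\beta_F \sim N(\beta_F, SE_F^2)$ and
$\hat\beta_M \sim N(\beta_M, SE_M^2)$, assumed independent between strata
(different individuals) but correlated across nearby SNPs through LD. The
target of inference is the contrast $\beta_F - \beta_M$.

**Per-trait test.** With two strata, Cochran's heterogeneity statistic
reduces to
$Q = (\hat\beta_F - \hat\beta_M)^2 / (SE_F^2 + SE_M^2) \sim \chi^2_1$
under homogeneity, and is exactly the square of the signed heterogeneity
Z-score $Z_{het} = (\hat\beta_F - \hat\beta_M)/\sqrt{SE_F^2 + SE_M^2}$.
The package enforces this identity ($Q = Z_{het}^2$ and
$P_Q = 2\Phi(-|Z_{het}|)$ to $10^{-12}$ relative tolerance) rather than
computing the two through different code paths. A consequence worth noting:
within a trait, the ranks of $P_Q$ and of the $|Z_{het}|$ p-values are
identical by construction, so any rank correlation below 1 between the two
can only arise from differences in upstream extraction, never from the
statistics themselves.

**Effect-scale conversion.** Cross-trait meta-analysis consumes effects and
standard errors, so $Z_{het}$ is converted by
$\beta_{het} = Z_{het}/\sqrt{2p(1-p)(n + Z_{het}^2)}$,
$SE_{het} = 1/\sqrt{2p(1-p)(n + Z_{het}^2)}$, with $p$ the allele frequency
and $n$ the total (F+M) sample size. The conversion preserves
$\beta_{het}/SE_{het} = Z_{het}$ exactly. For $p$ we use the minor allele
frequency of the harmonized pair (computed from the female stratum): it is
symmetric in allele labeling and is the same quantity used downstream for
matching.

**Direction and mechanism.** A SNP is *female-driven* iff
$|\beta_F| > |\beta_M|$ (ties, which have measure zero on real data, go to
*male-driven* deterministically and are logged). Mechanisms are classified
at a per-sex nominal level $\alpha = 0.05$ (the level is a tunable
argument): *one-sex-only* (exactly one stratum nominal),
*opposite-direction* (both nominal, discordant signs),
*magnitude-difference* (both nominal, concordant signs); SNPs nominal in
neither stratum are left unclassified.

**Genomic inflation.** $\lambda = \mathrm{median}(\chi^2)/0.4549364$.
Conversion from p-values supports log-space input (`log.p = TRUE`) so
p-values below the double underflow threshold (~1e-308) remain usable.

# Multi-trait meta-analysis

Signed inputs $s_i = \pm|\beta_{het}|$ carry the direction (positive =
female-driven). Fixed-effects pooling uses inverse-variance weights;
with a trait-correlation matrix $R$ the correlated fixed-effects
(Lin–Sullivan) estimate is used, with covariance
$\Sigma_{jk} = R_{jk} SE_j SE_k$:
$\hat\beta = (1'\Sigma^{-1}b)/(1'\Sigma^{-1}1)$,
$SE = (1'\Sigma^{-1}1)^{-1/2}$. SNPs missing in some traits are pooled over
the available traits (recorded as `n_traits_contributing`); a singular
covariance falls back to the uncorrected estimate with a warning.

$R$ is estimated as the Pearson correlation of the signed inputs over SNPs
where both traits sit in a null band $|z| < 1$ (the conventional device to
exclude true signals). Two caveats we document because they matter in
practice:

* **Truncation attenuation.** Restricting a bivariate normal to the unit
  square shrinks its correlation substantially (true 0.5 becomes ~0.18).
  With heavily overlapping samples the default band therefore
  under-corrects; `estimateOverlapCorr(nullBand = ...)` accepts a wider
  band, and the package's own calibration tests use `nullBand = 4`, which
  keeps >99.99% of null mass while still excluding genome-wide signals.
* **Sign-product mixture.** Because the input sign is "which sex dominates"
  rather than the sign of $Z_{het}$, the signed null inputs of two
  overlapping traits form a mixture of $+\rho$ and $-\rho$ correlation
  components. Even with the correlation estimated perfectly, the corrected
  test is near-nominal rather than exact (analytically, type-I error 0.057
  at 50% sample overlap versus 0.0695 uncorrected and 0.05 nominal). The
  tests assert this honest behavior.

Candidates are the union of univariate discoveries
($P_Q < 5\times10^{-8}$, MAF $\ge$ 0.001 per trait) and meta-analysis
discoveries (same thresholds on $P_{meta}$, MAF re-checked on the
largest-sample contributing trait), each tagged `univariate_only`,
`multivariate_only` or `both`, and each carrying the leading trait (minimum
per-trait $P_Q$) and its `best_p_q`.

# LD clumping

Greedy selection by ascending `best_p_q` (ties broken by chromosome,
position, SNP id, for full determinism), keeping a SNP iff $r^2 < 0.2$
against every SNP already kept. Clumping is genome-wide; the LD provider
defines cross-chromosome $r^2$ as 0, and no distance window is applied
(a window can be emulated by the LD provider itself). SNPs absent from the
LD reference are kept as independent with a logged count.

One property often assumed of clumping is *threshold monotonicity* (a
higher $r^2$ threshold never shrinks the kept set). It is false for greedy
clumping in general: a newly admitted SNP can displace two SNPs it is
correlated with (e.g. best SNP A, $r^2(A,B)=0.5$,
$r^2(B,C)=r^2(B,D)=0.9$, all other pairs 0.1: threshold 0.2 keeps
$\{A,C,D\}$, threshold 0.6 keeps $\{A,B\}$). Under block-diagonal
exchangeable LD — the structure the synthetic generator produces —
monotonicity does hold, and that is where the test suite asserts it.

# Matched permutation nulls

The empirical calibration layer asks: would an equally trait-associated,
equally common, but sex-*homogeneous* SNP set show the same enrichment?
Pool SNPs are ranked by the combined-sex marginal effect (inverse-variance
meta of the female and male betas of the leading trait; signed betas, with
SNP id as the deterministic tie-break). Eligible nulls are pool SNPs that
are not in the catalog, not in LD ($r^2>0.2$) with it, and (optionally)
inside a restriction set such as the predicted-eQTL map. For each catalog
entry a null is drawn uniformly among eligible SNPs within both tolerances:

* MAF: $\pm 0.001$ if catalog MAF < 0.01, else $\pm 0.02$; a catalog MAF of
  exactly 0.01 uses the wider rule (the boundary case is otherwise
  undefined).
* rank: $\pm 75$ positions.

Draws are without replacement within a set; across sets reuse is allowed.
Entries with no candidate double both tolerances up to three times, then
fall back to the nearest eligible neighbor by MAF; every relaxation is
recorded in the set's metadata (and counted in the run log). At desk-scale
pool sizes the joint window is genuinely empty for some entries — notably
common SNPs at extreme marginal-effect ranks, whose rank neighbors are
rare SNPs (raw effect noise scales with SE, hence with $1/\sqrt{maf}$) —
so the relax-and-flag path is part of the contract, not an error path.
Per-set RNG streams are derived deterministically from one master seed, so
any single set can be regenerated in isolation.

Empirical p-values use the add-one rank formula
$empP = (1 + \#\{null \ge obs\})/(N+1)$ (mirrored for depletion), so the
smallest attainable value with 1,000 sets is $1/1001$ and the enrichment
and depletion p-values of one statistic sum to at least $1 + 1/(N+1)$.

# Enrichment and overrepresentation

* **Association signal**: among catalog SNPs present in a disease/trait
  table, the percent with $p < \alpha$ ($\alpha = 0.05$) is compared to
  $100\alpha$ by the 1-df chi-square goodness-of-fit on counts (exact
  binomial available for small overlaps), and to the matched nulls for
  empP. The expected count is $\alpha \times$ overlap, exactly.
  Female-/male-driven subset comparisons use a 2x2 chi-square and report
  the subset percent ratio.
* **SNP-set overlaps** (meQTL at caller-chosen significance, e.g.
  $p < 10^{-14}$; predicted-eQTL maps): percent of catalog in the target
  set, with unique item counts (CpG probes, eGenes; a SNP counts once
  regardless of multiplicity) and per-SNP item ranges; empP for both the
  percent and the item count. Tissue filters (e.g. brain-only or
  brain-excluded) are arguments, not separate code paths.
* **Interval overlaps**: SNP positions are 1-based; BED input is 0-based
  half-open and converted on read. Both enrichment and depletion empP are
  reported per annotation, since regulatory categories are frequently
  depleted in sex-het SNPs.
* **Conditional predicted-eQTL enrichment**: the disease-signal test is
  recomputed on the catalog ∩ Pr-eQTL subset against nulls drawn only from
  sex-homogeneous Pr-eQTL SNPs (the matching index is rebuilt with the
  restriction), which distinguishes "sex-het SNPs are enriched because they
  are expression-regulating" from a genuinely sex-het-specific excess.
* **Gene annotation**: genic classes by containment with priority
  splicing > UTR > exonic > intronic; splice sites are ±2 bp around
  internal exon boundaries; a genic SNP without exon structure is
  intronic. Intergenic SNPs take the nearest gene within 25 kb (gene-body
  anchor, strand-ignorant; both the anchor and the cutoff are arguments),
  else no gene. The second flanking gene is reported only for the
  distance-ratio diagnostic that motivates the 25 kb cutoff. Constraint
  checks compare the pLI > 0.9 and pLI < 0.1 fractions of the mapped list
  to user-supplied reference proportions by exact binomial tests (the
  reference is an input; no database is bundled).
* **ORA**: expected count $= n_{ref} \cdot |list| / |universe|$, fold
  enrichment $FE = n_{obs}/n_{exp}$, two-sided Fisher exact p (one-tailed
  via an argument), BH-FDR across sets, and the permutation layer: FE is
  recomputed for gene lists derived from each matched null set by the same
  annotation rule, and empP is the rank of the observed FE (upper tail for
  overrepresented sets, lower for underrepresented). The universe defaults
  to the genes of the GMT collection; genes absent from the universe are
  dropped from the list before testing.

# The synthetic-data generator

`simConfig()` fixes the study conditions; defaults are chosen once to
mirror the scale and structure of the reference analysis: 100,000 SNPs on
4 chromosomes, 3 traits, stratum sizes 170,000 females / 150,000 males,
MAF spectrum $0.001 + 0.499\,\mathrm{Beta}(0.8, 3)$ (common-variant-heavy
with a realistic rare tail), exchangeable LD blocks of 20 SNPs at
$r^2 = 0.5$, planted sex-het fraction 0.003 (at most one per LD block, so
each planted signal is its own clump) with standardized effect differences
$|\Delta\beta|/SE_\Delta \in \{4,5,6\}$, a mechanism mix of
0.668/0.326/0.006 (one-sex / opposite / magnitude — the proportions
observed in the reference catalog), 1% sex-shared trait associations,
disease pleiotropy on 10% of sex-het SNPs at mean $|Z| = 3$, predicted-eQTL
membership 17% with a 1.28-fold sex-het excess, meQTL membership 5% with a
1.16-fold excess, 50 regulatory annotations at 10% coverage, and a bimodal
pLI mixture (20% constrained).

Standard errors are analytic, $SE = 1/\sqrt{2\,maf(1-maf)\,n}$, rather than
derived from simulated genotypes; observed effects are truth plus Gaussian
noise whose within-block correlation equals $\sqrt{r^2}$ (the LD
correlation of genotypes), which is what clumping and matching actually
exercise. The generator therefore emulates: stratified sampling noise, LD
block structure, planted heterogeneity of all three mechanisms, pleiotropic
disease signal, and annotation membership excesses. It deliberately does
**not** emulate: realistic human LD decay, population stratification,
imputation error, allele-frequency differences between strata, or
winner's-curse effects of upstream selection. Passing tests demonstrate the
statistical machinery is correct and calibrated under the stated model;
they do not certify behavior under confounding that the model excludes.

All generators are deterministic given the master seed and restore the
caller's RNG state.

# Numerical and design choices

* Strand-ambiguous SNPs (A/T, C/G) are dropped in harmonization:
  orientation is unresolvable from summary data. Allele-mismatched SNPs
  are dropped (no strand-complement rescue is attempted).
* $\chi^2$-from-p conversion accepts log p-values to avoid underflow;
  simulated p-values are floored at the smallest positive double.
* All orderings that affect output (clumping, ranking, leading-trait
  selection) carry deterministic tie-breaks.
* Degenerate inputs error early with informative messages: empty female ∩
  male intersection, zero disease overlap, empty gene lists, chromosome
  name mismatches (listing the unmatched names), pools smaller than the
  catalog, too few restricted nulls for the conditional analysis.
* Problem sizes in the test suite are the package's chosen desk-scale
  conditions: the discovery-recovery experiment runs the full 100,000-SNP,
  3-trait scenario; the matched-null audit samples 1,000 sets over a
  20,000-SNP pool; null calibration averages 1,000 replicate disease tables
  against a 2,320-SNP catalog; the two-layer ORA experiment uses ten
  replicates of a 20,000-gene universe with 600-SNP catalogs and 100
  permutations.

# Known limitations

* Exactly two strata; random-effects heterogeneity models are out of scope.
* The overlap correction inherits the null-band estimator's attenuation and
  the sign-mixture near-nominality discussed above.
* Gene annotation is intentionally minimal (gene-body containment plus the
  25 kb rule), not a re-implementation of a transcript-aware annotator.
* The matched-null sampler matches marginals (MAF, effect rank), not joint
  covariate distributions; propensity or Mahalanobis matching is a
  non-goal.

# A compact end-to-end run

```{r example, eval = FALSE}
cfg <- simConfig(nSnps = 20000, nTraits = 2, sexhetFrac = 0.004, seed = 7)
sim <- simulateSumstats(cfg)
paired  <- lapply(sim$sumstats, function(tr) harmonizePair(tr$female, tr$male))
hetList <- lapply(paired, hetStats)
meta    <- metaFixedTable(hetList)
ann     <- simulateAnnotations(cfg, sim$truth)
catalog <- clumpSnps(combineUniMulti(hetList, meta), ann$ld)
index   <- buildMatchingIndex(paired[[1]], catalog, ann$ld)
nulls   <- sampleMatchedSets(index, nSets = 100, seed = 7)
disease <- simulateDisease(cfg, sim$truth, scenario = "pleiotropic")
signalEnrichment(catalog, disease, nullSets = nulls)
```

`runPipeline()` wraps the same stages behind a single configuration and
writes TSV outputs plus a manifest with config hash, seeds, per-file
checksums and stage timings.
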