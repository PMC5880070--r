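---
title: "Methods: from de-regressed proofs to network-enriched genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from de-regressed proofs to network-enriched genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`dystnet` implements a complete analysis chain for dissecting and
predicting calving difficulty (dystocia) and related traits in dairy
cattle: national-evaluation PTAs are de-regressed into independent
pseudo-phenotypes, single-trait Bayes-B regressions estimate marker
effects, co-association across six traits is condensed into an
association weight matrix (AWM) over genes, the PCIT algorithm extracts
a gene network, and the network feeds back into genomic prediction
through modified relationship matrices evaluated under
pedigree-clustered cross-validation. This vignette records the models,
the tunable parameters and the design decisions, in that order of the
pipeline.

## The six traits

Two calving-difficulty components (direct, DCD, and maternal, MCD),
gestation length (GL), and three conformation ("type") traits linked to
feto-pelvic disproportion: stature (STAT), strength (STR) and rump
width (RW). The functional group is {DCD, MCD, GL}; the type group is
{STAT, STR, RW}. Criteria for "relevant" markers in the AWM refer to
these groups.

## De-regression

A bull's PTA is a shrunken blend of its parent average (PA) and its own
(mostly progeny) information. Using each trait's heritability proxy
`h2`, the module recovers the effective information contents of the PA
and of the bull's own records from the pair (PTA reliability, PA
reliability) by inverting the 2x2 mixed-model equations of the
PA/animal pair (numerator relationships 0.5/1), then removes the PA
contribution and the shrinkage. The de-regressed PTA (dPTA) carries a
reliability `r2_d = zz_i / (zz_i + lambda)` with
`lambda = (1 - h2)/h2`, and an association weight

```
w = (1 - h2) / ((c + (1 - r2_d)/r2_d) * h2),    c = 0.5
```

used as an inverse residual-variance weight downstream. When the PA is
missing it is rebuilt from whichever of three ancestor combinations is
available: `0.5*sire + 0.25*MGS + 0.25*AYB`, `0.5*sire + 0.5*AYB`, or
`0.25*MGS + 0.75*AYB` (MGS = maternal grandsire PTA, AYB = birth-cohort
mean PTA). Records keep their dPTA only if `r2_d > 0.2` (strict; the
boundary rule is an argument), and a bull is kept only with
pseudo-phenotypes on all six traits, to avoid an animal-trait
confounding effect.

Two quantities the upstream evaluations do not provide are arguments
with documented defaults rather than estimates: the per-trait `h2`
proxies (0.1 for the calving traits, 0.5 for GL, 0.4 for type — typical
magnitudes for these trait families) and the PA reliability when absent
(0.25; a parent average cannot exceed 0.5). Which reliability enters the
weight (PTA vs dPTA) is likewise not fixed by convention; the dPTA
reliability is used because `w` weights the de-regressed record.

## Bayes-B marker association

Per breed and trait, `y = 1*mu + sum_i Z_i g_i + e` with de-regressed
weights on the residual, `Var(e_i) = sigma_e^2 / w_i`. Each marker is
absent from the model with prior probability `pi = 0.9` and otherwise
carries its own variance with a scaled inverse chi-square prior. Scale
parameters use `S = sigma^2 (nu - 2)/nu` with `(nu = 4, sigma^2 = 5)`
for the marker variance and `(nu = 10, sigma^2 = 3)` for the residual —
the residual's degrees of freedom and the scale rule are stated
separately in the source conventions and are reconciled this way as a
documented choice. Default chains are 40,000 samples with 5,000
burn-in; posterior summaries are stable well below that on the problem
sizes used here (a robustness test compares two chain lengths and
requires correlation above 0.99 of the posterior-mean effects).

The sampler scans each locus with a partially collapsed update:
variance from its full conditional, then the inclusion indicator with
the effect integrated out, then the effect. Posterior mean effects
`abar` average over all post-burn-in iterations including the zeros —
this is what makes the per-marker variance proportions comparable —
and the per-SNP share of marker-explained variance is

```
PV_g[j] = 2 p_j (1 - p_j) abar_j^2 / sum_k 2 p_k (1 - p_k) abar_k^2 .
```

Markers at or above the 75th percentile of a trait's PV_g are flagged
significant (the top 25%; ties at the threshold are all kept and the
count reported). QC before the GWAS removes markers with minor allele
frequency below 5% or call rate below 90% (both strict) and
mean-imputes surviving missing codes.

## From SNPs to genes to a network

A marker maps to every gene whose interval (1-based inclusive
coordinates throughout, no strand logic) extended by 2,500 bp contains
it; the distance is measured from the gene boundary, not the TSS. A
marker is *relevant* if significant (a) in all six traits, (b) in all
functional traits, or (c) in all type traits. Genes hit by several
relevant markers keep the one with the largest PV_g averaged over the
six traits ("one SNP to one gene"), ties broken by genomic order;
relevant markers with no gene stay as their own rows only under
criterion (a). The AWM holds the z-score-standardized `abar` per trait,
standardized over AWM rows with the population (n-denominator) SD —
the matrix itself is the analysis object, so its rows are the natural
standardization set. Signs are preserved; co-association is signed.

PCIT then tests every row pair: for each trio (x, y, z) the three
first-order partial correlations are computed, the trio tolerance is
the mean of the partial/direct ratios, and the edge x–y dies if some z
makes it weaker than the tolerance-scaled strength of both legs. The
elimination test compares direct correlations, which is the published
form of the algorithm; a `compare = "partial"` mode is available
because with six-point profiles the distinction matters in edge cases
(under the published rule, an edge whose correlation exactly equals the
product of two strong legs is retained; the partial mode removes it).
Surviving edges are weighted by the direct row correlation, and the
network is trimmed to `|r| >= 0.98` — the absolute value, since with
six trait columns a strong negative co-association is as informative as
a positive one (a signed-only mode is flag-gated).

Across-breed analysis intersects the breed networks' gene sets. The
chance level of an intersection is assessed exactly: when sets of the
observed sizes are drawn uniformly without replacement from a universe
of `N` genes (default: the genes mapped from the SNP panel), the
running intersection size is a Markov chain with hypergeometric
transitions, so the exact tail probability is a chain of hypergeometric
convolutions, evaluated in log space to survive p-values below 1e-300.
The two-set case collapses to the hypergeometric tail. Degree
distributions are checked against a discrete power law (maximum
likelihood tail fit, cutoff by KS minimization) through
`igraph::fit_power_law`; its p-value refinement is stochastic, so the
wrapper pins an internal seed to keep repeated calls identical.

## Network-enriched prediction

Six relationship matrices on the QC'd panel (VanRaden method 1,
`G = MM'/(2*sum p(1-p))`, centering frequencies from the analyzed
training bulls): BASE (all markers), TOP25 (markers in the top PV_g
quartile for at least three of six traits) and its complement BOT75,
NET (the AWM source markers) and its complement FREE, and CONN,
`G = Z D Z'` with `Z` centered-and-scaled network-marker genotypes and
`D` carrying 1 on the diagonal and the trimmed network's edge weights
off-diagonal. The AWM itself is genes x traits and cannot be `D`; the
network-derived correlation structure is the implemented reading, with
a flag to use the untrimmed PCIT correlations instead. An indefinite
`D` is projected to the nearest PSD matrix (eigenvalue clipping,
diagonal restored; the repair distance is recorded) because an
indefinite kernel breaks the sampler. CONN is then rescaled by the
allele-frequency-free route: an affine map matching its mean diagonal
and mean off-diagonal to BASE.

Models 1–7 combine these kernels (1 BASE; 2 TOP25; 3 TOP25+BOT75;
4 NET; 5 NET+FREE; 6 CONN; 7 CONN+FREE) in a Bayesian GBLUP with the
de-regression weights on the residual (an `--unweighted` analogue is a
single argument). The sampler reparameterizes each kernel through its
eigendecomposition — one decomposition per kernel per fold — and
single-site-samples the rotated coefficients; variance components get
scaled inverse chi-square priors with df 5 and scales from an even 50%
heritability split across kernels. Default prediction chains are
20,000/5,000. Masked bulls enter with residual weight 0: they
contribute no likelihood but receive genetic-value predictions
`mu + sum_k g_k`.

Cross-validation uses four folds built by k-means on the rows of the
pedigree A-matrix (tabular method), keeping relatives together; k-means
on A-rows is the documented default where the clustering representation
was an open choice, with the fold seed an argument. Within each
training set the entire discovery chain — GWAS, marker partitions, AWM,
PCIT, D, every G — is rebuilt from training bulls only, including the
centering allele frequencies, so validation phenotypes cannot leak into
any discovery statistic (a canary test plants an extreme validation
phenotype and requires bit-identical training GWAS output). Accuracy is
the plain Pearson correlation between predicted and masked dPTA,
reported as mean (SE) over folds; folds with fewer than three usable
validation records are skipped with a warning.

## The synthetic populations

`simulate_population()` generates what the analysis assumes: unrelated
founder sires, paternal half-sib progeny via Mendelian gene-drop
(founders in Hardy–Weinberg proportions at frequencies uniform in
`maf_range`; each dam is composed of a maternal-grandsire gamete and a
population gamete so MGS ties are genetically real), sparse pleiotropic
marker effects (a marker is causal with probability `1 - pi_qtl`,
default matching the GWAS prior at 0.9), and six correlated traits.
Effects are recolored in TBV space so the realized genetic correlations
and per-trait TBV variances match the configuration exactly, not only
in expectation — with a few hundred QTL the sampling noise of a purely
stochastic draw would otherwise dominate the calibration.

Evaluations mimic real PTAs as information blends: for each progeny
bull, a PA information source (around the true parent average from the
sire's and dam's breeding values) and an own-information source around
TBV/2 are combined through the same 2x2 mixed-model equations the
de-regression inverts, with the two information contents solved so the
blend's squared correlation with TBV/2 equals the bull's drawn
reliability (uniform in `reliability_range`; the published per-breed
tables show trait- and breed-specific reliabilities, and a uniform draw
is the simplest emulation). The emitted PA reliability uses the joint
convention, so de-regressing a simulated record recovers the pure
own-information source exactly — by construction, de-regression on
synthetic data removes precisely the PA blend it is supposed to remove.
The birth-cohort mean PTA is the plain mean of the cohort's PTAs. One
progeny generation is simulated; founders default to linkage
equilibrium, with an optional founder haplotype-block mode
(`ld_blocks`) that induces block LD, since network and GWAS behaviour
under LD is of interest but no LD model is prescribed. Genes are placed
so a configurable fraction of markers lies within 2,500 bp of a gene
(exact at 0 and 1, approximate between); QTL intervals cover a
configurable fraction of each chromosome.

What the simulator does not emulate: recombination maps and
multi-generation drift or selection, breed divergence, genotyping-chip
ascertainment, and the long-range LD of real cattle genomes. Passing
tests therefore demonstrate the correctness and internal consistency of
the chain, not real-data effect sizes; in particular, synthetic
prediction accuracies are not comparable to published real-data
accuracies.

## Numerical choices and degenerate inputs

- Information contents and variances are guarded: reliabilities are
  clamped away from 0, 1 (and 0.5 for a PA); records whose own
  information content is non-positive are excluded with a reason, not
  silently transformed.
- The percentile retention keeps the `floor(m/4)`-th largest value as
  threshold and everything tied with it; all-equal inputs retain all
  markers.
- PCIT skips trios containing a zero or unit-magnitude correlation
  (undefined ratio or partial); 2-node inputs return all nonzero pairs
  with a warning.
- The exact intersection test runs entirely in log space; the multi-set
  recursion caps its support at the second-largest set size.
- Kernel eigenvalues below 1e-10 of the maximum are dropped from the
  GBLUP reparameterization, which also absorbs the small negative
  eigenvalues an affinely rescaled CONN can carry.
- A-matrix construction topologically sorts the pedigree and names the
  animals involved when it finds a cycle.

## Problem sizes in the shipped tests

The test suite exercises the chain at deliberately compact sizes chosen
as the smallest instances where each property is meaningful: GWAS
recovery at 300 bulls x 1,000 markers with 20 QTL over ten seeds,
calibration at 2,000 bulls, the oracle comparisons at 25–50
individuals, and one full pipeline demo at 500 progeny bulls x 2,000
markers running all seven models under 4-fold cross-validation with
shortened (but documented) chains. The defaults of every function
remain the full-scale settings quoted above.
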