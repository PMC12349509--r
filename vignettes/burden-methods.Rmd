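---
title: "Estimating deleterious mutation burden in conserved germplasm: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating deleterious mutation burden in conserved germplasm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germburden)
```

## The problem

Seed genebanks conserve germplasm for decades. Two processes change its
genetic makeup along the way: mutations arise (in cold storage and at every
regeneration, when stored seed is grown out to produce fresh seed), and
selection plus drift act at each regeneration bottleneck. For a selfing crop
such as soybean, regeneration has a characteristic signature. Selfing halves
heterozygosity each generation, and the homozygotes it creates expose
recessive deleterious alleles to viability selection, which removes them
("purging"). Deleterious alleles that remain heterozygous largely escape
this filter. The expectation, then, is that mutation burden accumulated
under conservation should be carried mainly in the heterozygous state, with
the homozygous component held down by purging — unless an allele is already
fixed within an accession, in which case no within-family selection can
touch it.

`germburden` implements the full measurement chain for that question and a
generative simulator of the conservation process, so every stage can be
tested against datasets with known truth.

## Measurement chain

### Genotype filtering

Input is a multi-sample VCF. Filtering keeps biallelic SNPs, drops sites
with quality below `min_qual` (default 20), marks genotype calls with depth
below `min_dp` (default 10) as missing, and by default requires a complete
genotype matrix (any site with a remaining missing call is dropped). These
defaults correspond to the common
`--max-alleles 2 --min-alleles 2 --minDP 10 --minQ 20 --max-missing 1`
recipe. A joint filter does not define an order, but a ledger does: each
dropped site is attributed to the first rule it fails, in the fixed order
indel → multi-allelic → quality → missing call. The order affects only the
ledger's per-rule attribution, never which sites survive. Half calls
(`./1`), calls beyond the biallelic diploid vocabulary, and — conservatively
— calls with no depth information at all are treated as missing.

### Deleterious classification

A SNP is classified deleterious when two independent lines of evidence
agree: a damaging functional prediction (SIFT score ≤ `sift_max`, default
0.05, confident calls only) and evolutionary constraint at the site (GERP++
rejected-substitution score strictly positive). The SIFT threshold is
inclusive, following the convention that a score of 0.05 *or less* is
damaging; the RS threshold is exclusive, since only a positive score marks a
site with fewer substitutions than expected. Variants missing either score
are never deleterious. Severity is binned on RS: weak below 1, mild on the
closed interval [1, 3], high above 3. Both boundary conventions are exposed
as arguments (`bin_severity(rs, low, high)`), because published usage
varies between "1–3" and "3 or higher" phrasings; the closed-interval
reading keeps the three bins an exact partition.

"Deleterious" here means deleterious to gene function as predicted by these
scores — not necessarily to whole-plant fitness.

### Burden estimators

Let `L` be the number of deleterious loci in the analysis run (the global
count, not per-sample: the matrix is complete by construction). For one
sample with `n_het` heterozygous and `n_hom` homozygous deleterious loci,

$$B_{het} = \frac{n_{het}}{2L}, \qquad
  B_{hom} = \frac{2\,n_{hom}}{2L}, \qquad
  B_{tot} = \frac{n_{het} + 2\,n_{hom}}{2L},$$

i.e. deleterious allele copies per potentially deleterious allele slot. The
decomposition $B_{tot} = B_{het} + B_{hom}$ is exact, and the suite asserts
it to machine precision. The deleterious allele is operationalized as the
alternate allele of the scored substitution; no outgroup polarization is
attempted, and the convention can be overridden per site through
`deleterious_allele`. Loci fixed for the deleterious allele stay in `L`
(they add the same constant to every sample's $B_{hom}$) and are flagged by
the MAF spectrum so they can be reported separately.

### Expression and RIN

From a TPM matrix restricted to genes associated with the deleterious loci,
two per-sample estimates are derived: the expressed gene count and the mean
TPM over that sample's expressed genes. "Expressed" means TPM strictly
above `tpm_floor`, default 0 — a presence/absence notion; no published
cutoff exists for this step, so the floor is a visible knob rather than a
hidden constant. A sample with no expressed gene gets an undefined mean,
not zero. RIN (RNA integrity number, 1–10) enters as a covariate measured
per sample; biologically it proxies RNA degradation and hence seed aging
since the last regeneration.

### Association battery

All associations are simple ordinary-least-squares regressions with
two-sided t tests on the slope, reported per test at α = 0.05 with a
"marginal" band at 0.05 ≤ p < 0.10. The battery is three blocks: the 3
burden estimators against the 3 conservation covariates (years since
acquisition, years since last regeneration, regeneration cycles), all 15
unordered pairs of the six per-sample estimates, and the 3 expression/RIN
estimates against the 3 covariates — 33 tests. No multiple-testing
correction enters the significance labels, matching per-test reporting
practice for this design; a Benjamini–Hochberg column is emitted alongside
as a labeled extension for readers who want it. Differences among countries
of origin use classic equal-variance one-way ANOVA, restricted to groups
with at least `min_group_n` (default 3) accessions; the groups actually
used are always reported, since any group-size rule is a judgment call.
Two-cohort comparisons (e.g. seed- versus leaf-derived estimates of the
same accessions) regress one cohort on the other over the shared samples.

## The simulator

### Generative model

Each accession is a single selfing lineage tracked at `n_del_sites`
potential deleterious sites with genotypes coded 0/1/2 (copies of the
deleterious allele). Time runs in years from acquisition to the assay year.

* **Standing variation.** Per site, a deleterious-allele frequency is drawn
  from a zero-inflated Beta (mass `p_zero = 0.30` at zero, Beta(0.5, 9)
  otherwise; mean frequency ≈ 0.037), then spread into genotypes with
  inbreeding coefficient `f = 0.95` — accessions of a selfer are nearly
  homozygous, so standing load is mostly homozygous and per-accession
  independent of the conservation covariates. One site ships fixed for the
  deleterious allele in every accession.
* **Storage mutation.** Each remaining reference allele copy mutates to the
  deleterious state with probability `mu_storage` per year, irreversibly.
* **Regeneration.** At each scheduled regeneration the stored genotype is
  selfed: Mendelian transmission per site, gamete mutation at `mu_regen`
  per allele copy (regeneration is a sexual generation, so it carries its
  own mutation input), and viability selection weighting offspring
  genotypes $1 : 1-hs : 1-s$. Selection is applied *relative to the
  within-family baseline*: a site at which the parent is homozygous
  segregates no viability variance among its selfed offspring, so
  accession-fixed alleles — however harmful — cannot be purged by
  regeneration. This is what makes fixed load a permanent floor under
  $B_{hom}$ while segregating homozygotes are removed.
* **Single-seed descent.** The next stored genotype is one surviving seed.
  Because viability is multiplicative over independent sites, the
  distribution of a surviving seed factorizes per site, and the simulator
  samples that conditional directly — exactly equivalent to drawing
  `n_regen` survivors by rejection and picking one uniformly, but without
  the rejection loop. A pooled mode (`mode = "pooled"`) keeps `n_regen`
  explicit plants with per-seed rejection sampling (capped at `reject_cap`,
  breach is an error, not silent truncation) for experiments where
  within-accession variation matters.

Sites are unlinked; the burden statistics are single-site tallies, so free
recombination loses nothing. Decoy SNPs (neutral sites with an L-shaped
frequency spectrum, a 2.3% invariant-heterozygous fraction, and
tolerated/low-confidence/score-free annotations) are emitted alongside so
the classifier has realistic negatives, and the annotation model draws
deleterious-site RS scores from the 7.7/81.1/11.2% weak/mild/high mixture.

### Covariates and their confounding

Acquisition calendar years are uniform on 1972–2004 (so accession age spans
18–50 years at the 2022 reference), regeneration cycles rise with accession
age at about one cycle per 3.2 years with Gaussian noise (clamped to 0–10),
and years since the last regeneration are drawn from 4–25 independently of
the cycle count. The age–cycles confounding is deliberate: in a genebank,
older accessions *have* been regenerated more, and that correlation is part
of the signal structure the association battery faces.

### Expression, RIN and their links to burden

RIN declines with years since last regeneration
(`rin = 8.8 − 0.077·y_last`, Gaussian noise 0.25, clamped to [1, 10]) and
slightly with total burden. The expressed gene count falls with total
burden and rises with RIN and accession age; mean TPM rises with total
burden and years since last regeneration and falls with the expressed
count. These coefficients fix the signs of the pairwise associations the
battery should recover (burden negatively associated with expressed genes
and RIN; count and mean expression negatively related; RIN positively
related to count). The TPM matrix realizes the counts through a panel of
175 deleterious-associated genes of which 119 are expressed in every
sample, with popularity-weighted inclusion of the rest and per-sample
rescaling so the realized mean TPM matches the model.

### Default parameters

| parameter | default | units | why |
|---|---|---|---|
| `n_samples` | 190 | accessions | collection size of the motivating design |
| `n_del_sites` | 588 | sites | deleterious-locus count of the motivating design |
| `mu_storage` | 2e-4 | per allele per year | desk-scale; inflated far above real per-site rates so ~0.2 heterozygous mutations arise per accession-year over 588 sites |
| `mu_regen` | 5e-3 | per allele per regeneration | desk-scale; ~6 new heterozygous sites per regeneration event |
| `s` | 0.98 | — | strong purging of segregating homozygotes |
| `h` | 0.05 | — | nearly recessive: heterozygotes mostly escape selection |
| `background` | p₀ = 0.3, Beta(0.5, 9), f = 0.95 | — | standing, mostly homozygous load giving mean `b_hom` ≈ 0.036 |

Real per-generation point-mutation rates are on the order of 1e-8 per site;
at 588 sites nothing would ever happen in a simulated collection of this
size. The mutation rates are therefore calibration knobs chosen to place
the simulated burden means near the empirical scale (total ≈ 0.05,
heterozygous ≈ 0.014, homozygous ≈ 0.038) and to give the association tests
measurable signal; they carry no claim of realism, and the truth record
makes every run auditable.

### What the generator does and does not emulate

It emulates: complete biallelic genotype matrices with L-shaped frequency
spectra, invariant-heterozygous and fixed sites, SIFT/RS score mixtures
with decoys and low-confidence calls, covariate ranges with realistic
confounding, and expression/RIN structure tied to burden. It does not
emulate: sequencing reads or genotyping error (the emitted VCF is clean
unless filter fodder is requested), linkage, outcrossing, per-seed
within-accession heterogeneity in single-seed mode, shared demography
across accessions (each is an independent lineage), or any real soybean
locus. Passing the recovery checks therefore shows the pipeline's
statistics behave correctly under the assumed generative process — it is
not evidence about any real collection.

## Numerical and design choices

* **Degenerate regressions.** A constant predictor is an error ("degenerate
  predictor"); a constant response gives slope 0, R² = 0 and p = 1 rather
  than NaN. A perfect fit reports p = 0 on a zero standard error.
* **Zero between-group variance.** One-way ANOVA on identical group means
  returns F = 0, p = 1 by definition instead of 0/0.
* **Empty classifications.** An empty deleterious set is a defined outcome
  of classification, but burden computation on it is an explicit error
  ("no deleterious loci"), and the pipeline halts there by stage name.
* **Zero surviving sites** after filtering is a warning plus an empty
  variant set, not an exception, so ledgers can still be inspected.
* **Severity of an intersected set** is taken from the first set, with
  disagreements listed in an attribute rather than resolved silently.
* **Determinism.** A dataset is a pure function of its `sim_config`
  (including `seed`); the generator seeds R's RNG itself.
* **Null configurations.** Turning mutation off (`mu_storage = mu_regen =
  0`) is not by itself a null for the slope tests: standing heterozygosity
  still decays by half per regeneration, a real (negative) association. The
  true null used in the tests also sets `f = 1`, leaving no standing
  heterozygosity to decay.

## Problem sizes used by the test suite

The suite checks the estimator against a literal allele-counting oracle at
1000 sites × 600 samples, calibrates the regression and ANOVA type-I error
on 10,000 Monte-Carlo null replicates each (observed rates within ±0.01 of
0.05), verifies the neutral selfing halving law on 10,000 single-generation
replicates, and runs 50 replicate default collections for the recovery
checks: the heterozygous and total burden slopes on regeneration cycles are
recovered as significantly positive in ≥ 90% of replicates, while the
homozygous slope stays non-significant in a majority (about 80% at these
defaults — the purging leak of roughly 0.1 surviving new homozygote per
regeneration occasionally reaches significance, which is a property of the
strong-but-finite `s = 0.98` default, not a defect of the test).

## Known limitations

Burden is estimated per deleterious locus without ancestral-state
polarization, so reference-genome bias folds into the alternate-is-derived
convention. The country ANOVA mechanics are implemented, but any particular
group-selection rule (which origins enter the test) is a reporting choice
the caller controls. The pairwise battery reports per-test significance;
with 33 tests, a handful of false positives per run is expected by
construction. The simulator's single-seed mode represents an accession by
one genotype, which matches a one-seed-per-accession assay but understates
within-accession variance for anything else; use the pooled mode for that.
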