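---
title: "Family-based screening of FMR1 CGG repeat expansions: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based screening of FMR1 CGG repeat expansions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmrscreen)
library(dplyr)
```

## The problem

The CGG trinucleotide repeat in the 5' UTR of *FMR1* on the X chromosome
expands pathologically: normal alleles span roughly 5–40 repeat units,
41–54 is the gray zone, 55–200 the premutation range, and alleles beyond
200 repeats cause Fragile X Syndrome. Premutation carriers (about 1 in
300 females, 1 in 900 males in the general population) are
phenotypically unaffected by FXS but at risk for FXTAS/FXPOI, and
premutation alleles are unstable on transmission. Modern repeat
genotypers (ExpansionHunter and kin) estimate these repeat lengths from
short-read WGS, which makes population-scale carrier screening and
family-based transmission analysis possible — but the estimates carry a
characteristic error mode: reads from similar repeats elsewhere in the
genome ("off-target" reads) occasionally inflate a call far above the
true length, and the bootstrap confidence intervals broaden with repeat
length.

`fmrscreen` implements the full analysis layer of such a screen for
simplex-ASD-style trio/quad cohorts: range classification, sex-aware IO
for repeat calls and pedigrees, X-linked transmission and de novo
inference, and the cohort statistics (prevalence, burden, HWE,
concordance). Because the individual-level cohorts this kind of study
uses are access-restricted, the package also ships a synthetic-cohort
generator with known ground truth so that every stage is testable.

## Range classification

`classify_allele()` partitions lengths by three inclusive upper
thresholds held in a `locus_catalog()` (defaults 40/54/200): normal
$\le 40 <$ gray $\le 54 <$ premutation $\le 200 <$ full. Both boundary
conventions circulate in the literature for the full-mutation cutoff
("200 or more" versus ">200"); we follow the premutation definition
55–200 inclusive, so 200 is a premutation and 201 is full. All
thresholds live in the catalog and are overridable; nothing is
hard-coded. Lengths below 5 repeats have no class of their own anywhere
in this analysis and classify as normal with a warning.

An individual's carrier status follows the longer allele
(`classify_genotypes()`). Two flags matter downstream:
`is_premutation_carrier` (an allele in 55–200 exactly) and
`is_expanded` (an allele at or beyond 55). Screening decisions —
which samples to re-evaluate, which families count as carrier families,
prevalence numerators — use `is_expanded`, because a screen cannot and
should not exclude a full-range call from follow-up; this also matches
how published screens count rare off-target calls above 200 among their
"predicted premutation carriers".

## IO and ploidy

Repeat calls enter as ExpansionHunter-style JSON (`read_eh_json()`),
repeat-count VCF with `REPCN`/`REPCI` per-sample fields
(`read_eh_vcf()`), or PCR result tables (`read_pcr_table()`); pedigrees
as 6-column PED (`read_pedigree()`). All readers normalize to one tidy
genotype tibble: alleles sorted ascending, males hemizygous (one allele
at a chrX locus), females with two, optional per-allele confidence
bounds, and an explicit no-call representation (`NA` alleles) for
samples the genotyper skipped — no-calls stay in the table so that
"processed" versus "genotyped" denominators remain distinguishable, but
they never enter percentages. Ploidy/sex consistency is enforced at
parse time; repeat counts are the only coordinates used anywhere, so no
0/1-based genome-coordinate issues arise.

## Transmission inference

For each analysis-ready family (both parents genotyped),
`call_transmissions()` assigns every offspring allele a parental origin
by minimum absolute repeat-length difference. A son's single X is
matched against the mother's two alleles only — father-to-son
transmission of an X-linked allele is impossible, and the pipeline
treats that as a structural assertion, not an empirical finding. A
daughter's two alleles are split one-paternal/one-maternal by whichever
of the two possible assignments minimizes the total absolute
difference.

The matching deliberately has no hard cutoff. Published family data
show parent/offspring length scatter of 10–20 units for expanded
alleles under WGS genotyping, so a cutoff would silently drop real
transmissions; instead a `poor_match` flag marks assignments with
`|delta|` above a tolerance (default 5 repeat units, configurable) and
`ambiguous_match` marks ties. Categories follow the offspring's own
observed allele class:

* premutation transmitted — offspring and assigned parental allele both
  at/above the premutation range;
* de novo — offspring at/above, assigned parental allele below (both
  parents must be genotyped, since the de novo call is a
  pedigree-exclusion argument);
* normal from carrier parent — offspring below the premutation range
  while the transmitting parent carries an expanded allele (this is the
  "non-inheriting offspring" row of the published accounting; a
  contraction from an expanded parental allele lands here with a
  `contraction` flag);
* plain normal transmission otherwise.

A son whose expanded allele matches only his father's expanded allele
is flagged `x_linkage_violation` and reported but never counted — such
a call indicates a genotyping or pedigree error, not a transmission.

`summarize_transmissions()` restricts to families with at least one
expanded-allele member, tabulates the 20 report rows (mother/father ×
four offspring roles × premutation/normal, plus four de novo rows) and
uses the number of genotyped offspring in those carrier families as the
percentage denominator.

### Identifiability

Minimum-distance matching cannot always recover the true event. The
instructive case (which the synthetic generator does produce, rarely):
a mother carrying both a premutation allele and a gray-zone allele
whose gray allele expands de novo past 55 in one transmission. The
offspring's allele then lies nearer the mother's premutation allele
than its true source, and any distance-based matcher counts a
premutation transmission (flagged `poor_match`) where the truth is a de
novo expansion. This is a limit of the observable data, not of the
implementation; with transmission instability switched off, recovery of
origins, categories and counts is exact, and the test suite asserts
precisely that split (exact recovery under stable transmission; count
recovery up to such collisions otherwise).

## Cohort statistics

* **Prevalence** (`summarize_prevalence()`): per-role processed /
  genotyped / carriers / percent, with pooled male- and female-offspring
  rows. Percentages always use genotyped (not processed) denominators.
* **Burden** (`fisher_burden()`): probands versus unaffected siblings,
  sex-stratified, on carrier counts of individuals — not allele counts.
  With hemizygous males, X-linked allele and carrier counts coincide;
  for females we verified that carrier-based tables reproduce all six
  published odds ratios of the reference analyses, so carriers are the
  counting unit throughout and this is worth stating prominently. The
  p-value is the two-sided Fisher exact probability (delegated to
  `stats::fisher.test`); the reported OR is the sample cross-product
  `ad/bc`, the conventional companion to the exact test (the
  conditional-MLE OR that `fisher.test` itself reports differs in the
  second decimal and is not what published tables print).
* **HWE QC** (`hwe_female_chi2()`): Pearson goodness-of-fit of female
  genotypes (non-carrier / heterozygous / homozygous carrier) against
  Hardy–Weinberg proportions at the estimated expanded-allele
  frequency. Observed female carriers are taken as heterozygous unless
  homozygous genotypes are present — no homozygous premutation female
  has been reported in the screens this reproduces. The `df` used for
  the p-value defaults to 2, the convention of the reference analyses
  (it reproduces their printed p-values); the textbook test with an
  estimated frequency uses 1 df, offered via `df = 1`. Note the
  statistic's sampling expectation under the null is 1 either way —
  the simulation-based test of this package asserts mean χ² ≈ 1 across
  seeds, since the frequency is estimated from the same counts.
* **Two-cohort comparison** (`compare_prevalence()`): the same exact
  test on carriers/totals of two cohorts, e.g. case-cohort mothers
  versus an external reference panel.
* **Parental-age Z-test** (`parental_age_ztest()`): two-sample Z on
  means with pooled standard error, for comparing parents of de novo
  versus transmitting families.
* **Concordance** (`callset_concordance()`): two call sets on the same
  samples compared by longer-allele class, with per-set expanded-carrier
  counts and per-sample discordance.

`run_full_analysis()` chains these stages and implements the dual-mode
re-evaluation rule used by off-target-aware screens: samples flagged
under the primary (off-target) calls are re-classified from the
confirmatory (region-only) calls before final classification. The rule
can only downgrade or confirm a flag — the final carrier list is
provably a subset of the primary flagged list — mirroring how
restricting to on-locus reads reduces overestimation.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure of the ASD
family cohorts this analysis targets, with every random quantity under
one integer seed (fixed seed ⇒ byte-identical output):

* **Families**: `n_families` nuclear families, 78% quads / 22% trios;
  probands male with probability 0.87, siblings 0.47 — the role counts
  of the published cohorts imply exactly this asymmetry, which is why a
  single offspring sex ratio is not used.
* **Founder alleles**: i.i.d. from a discrete mixture with modes at 29
  and 30 repeats (the overwhelmingly most frequent genotypes in
  published family tables), minor normal modes at 20–40, a thin uniform
  gray band (total weight 2%) and a uniform premutation tail on 55–120
  with weight 0.8% — giving ~0.8% male and ~1.6% female expected
  founder carrier prevalence, the order observed in case-family parents
  (`expected_carrier_prevalence()` returns the closed form).
* **Transmission**: sons draw one maternal allele uniformly; daughters
  receive the paternal allele plus one maternal allele. Each
  transmission mutates with probability increasing in the parental
  allele class (0.2% normal, 4% gray, 20% premutation — published
  screens report no quantitative instability model, so these are
  plumbing-scale placeholders chosen once to make de novo events rare
  but present, a few per several thousand families, echoing the ~3% de
  novo share among carrier-family offspring); steps are mostly +1..+3
  with occasional larger jumps and rare contractions.
* **Measurement**: mode `none` passes truth through; `eh_offtarget`
  inflates alleles with probability increasing in true length (0.2% /
  5% / 50% by class) by a positive step drawn from a decreasing-weight
  distribution up to 120 units, emulating the documented off-target
  failure mode where a normal allele is called deep in the premutation
  range; `eh_region_only` applies the same shape shrunk by 0.3.
  Inflation is non-negative by construction, so flagged carriers can
  only exceed true carriers. CI half-widths grow linearly with measured
  length (slope 0.15 per unit above 30), reproducing the reported
  broadening of bootstrap intervals. No-calls thin samples at 0.2%,
  matching the ~99.8% genotyping rates of real screens.

What the generator does **not** emulate: AGG interruptions, somatic
mosaicism, read-level data, maternal-age effects on expansion risk, and
any correlation structure between families. Tests passing on synthetic
cohorts therefore validate the pipeline's bookkeeping and statistics,
not the biological realism of any instability parameter.

## Numerical and design choices

* Range boundaries are closed on both ends as printed; the 200/201
  boundary decision is recorded above.
* Allele normalization sorts ascending everywhere; printed short/long
  genotype order is preserved on output (`Y/23` male notation).
* Fisher p-values use the standard "sum of tables at most as probable"
  two-sided rule; the test suite checks them against an exhaustive
  hypergeometric enumeration over all 2×2 tables with total ≤ 25.
* Degenerate inputs: zero margins give p = 1 with a flagged OR (`Inf`,
  `0`, or `NaN` from the cross-product); empty transmission summaries
  report zero percentages with `percent_defined = FALSE`; a role with
  zero genotyped samples reports `NA` percent.
* Tie-breaks in origin assignment are deterministic (paternal side
  prefers the allele nearer the father, then the shorter allele) and
  always flagged, so reruns are reproducible.
* Problem sizes in the test suite (up to 5,000 families for recovery
  properties, 50 seeds for the HWE sampling check, exhaustive Fisher
  sweep to total 25) were chosen as the smallest sizes at which the
  binomial/χ² approximations and rare-event counts are informative.

## Worked example

```{r example, eval = FALSE}
library(fmrscreen)

cohort <- simulate_cohort(cohort_config(n_families = 500, seed = 42,
                                        measurement_mode = "eh_offtarget"))
report <- run_full_analysis(cohort$observed, cohort$pedigree,
                            cohort_id = "synthetic-demo")
report$prevalence
glance(report$transmission)
report$burden

# published-count reproduction
fisher_burden(13, 2042, 8, 897)          # male probands vs male siblings
hwe_female_chi2(59, 0, 3694)             # pooled female carriers
```

## Known limitations

* The transmission matcher is distance-based and model-free; it cannot
  distinguish a large transmission drift from a de novo expansion when
  a carrier parent offers a closer match (see *Identifiability*).
* HWE with very rare alleles has a near-empty homozygote class; the χ²
  approximation is then anti-conservative in the tail, which is
  acceptable for its QC role here but not for formal inference.
* External-reference comparisons (`compare_prevalence()`) provide the
  machinery only; reference-panel carrier counts must be supplied.
* Single locus per run; multi-locus catalogs are read but analyses are
  per-locus.
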