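---
title: "Pedigree-based rare-variant prioritization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree-based rare-variant prioritization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedscreen)
library(dplyr)
```

## The analysis problem

A multiplex family segregating a mood disorder — nine affected members
across three generations, thirteen unaffected, five spouses who married
into the family — is exome-sequenced, and the analyst wants the small set
of variants most plausibly driving the phenotype. Two observations shape
the model. First, an unaffected father of two affected sons sits on the
transmission path, so the inheritance model must be dominant with
*incomplete penetrance*: carriers are usually, not always, affected.
Second, the disease allele entered with the blood line, so a variant
carried by any marry-in cannot be the family's causal allele.

`pedscreen` turns those assumptions into a deterministic pipeline:
pedigree role classification, a three-stage filter cascade, and a
multiplicative priority score. A companion module implements the
expression statistics used to validate a candidate gene downstream, and a
gene-dropping simulator generates full synthetic datasets so the whole
path is testable.

## Pedigree roles

`classify_roles()` partitions members into affected, unaffected blood
members, and marry-ins. A *marry-in* is a founder (no parents in the
pedigree) all of whose co-parents are non-founders: someone who joined an
established blood line by marriage. The members of a founding couple are
each other's co-parents and both founders, so they are classified as
blood, never as marry-ins — including in the degenerate childless-couple
pedigree. Members with unknown phenotype take part in no filter
predicate: they are neither required carriers nor excluders. This is
deliberately conservative — an unknown phenotype should not be able to
kill or rescue a candidate.

An *obligate carrier* is inferred by transmission logic
(`infer_obligate_carriers()`): an unaffected blood parent of an affected
child, whose co-parent for that child is a marry-in, must carry the
allele, because under the within-family assumption it cannot have entered
through the marry-in. The rule is automatic but unionable with an
explicit override list, since in practice analysts sometimes designate a
carrier on external evidence rather than structure. On the packaged
family template the rule yields exactly one obligate carrier, A03, the
unaffected father of affected sons A17 and A18.

The packaged 22-member template (`pedigree_template()`) is one consistent
realization of the role structure described above; the true family's full
parent–child graph is not public, so the template is documented as
illustrative, not genealogical.

## The filter cascade

Each stage takes and returns a variant tibble and attaches a
count-conserving report (`filter_reports()`); rejection reasons are
assigned as the *first* failing criterion in a documented order, so
reports are deterministic.

**Site QC** (`qc_filter()`) applies five hard filters with the
conventional exome thresholds: RMS mapping quality ≥ 30, mapping-quality-
zero reads ≤ 4, site depth ≥ 5, QUAL ≥ 50, phred-scaled strand bias
≤ 10. Boundaries are inclusive on the passing side, following the strict
inequalities of the underlying hard-filter convention ("remove if
MQ < 30", so MQ = 30 survives). One wording quirk deserves a note: stated
literally, an MQ0 *removal* rule of "< 4" would discard the cleanest
sites; the package implements the standard remove-if-MQ0-exceeds-4 rule
and keeps the literal inversion available behind `mq0_literal = TRUE` for
comparison. Records missing a QC field are rejected with their own reason
by default (`missing = "pass"` opts out).

**Function and prevalence** (`functional_filter()`) removes synonymous
variants, variants with allele frequency above 5% in *any* reference
database (absent frequencies count as zero — an unobserved variant is not
evidence of commonness), variants with no carrier at all, and variants
whose carrier-sample support is weak: depth of coverage below 6× or
variant allele fraction ("mutation ratio", alt reads / depth) below 30%.
Depth and allele fraction are averaged over carrier samples by default;
`aggregate = "min"` makes every carrier pass individually, the stricter
reading, since the source convention does not specify per-sample versus
aggregate.

**Segregation** (`segregation_filter()`) applies two predicates in
sequence, reported separately: (1) every affected member and obligate
carrier is a called carrier; (2) no marry-in is a called carrier. Missing
genotypes are handled asymmetrically, conservative in each predicate's
required direction: an uncalled required sample *fails* sharing (it
cannot be confirmed to share), while an uncalled marry-in does *not*
exclude (only a confirmed carrier does). `missing_as_compatible = TRUE`
relaxes the first predicate for low-coverage call sets.

The real study's intermediate counts (≈10⁵ called variants narrowing to a
few dozen candidates) depend on raw data that is not distributable;
correctness here is instead established by property: on every simulated
dataset the survivor set must equal an independent brute-force
re-evaluation of the predicates, and every report must conserve
`input = output + rejected`.

## The priority score

Candidates surviving the cascade are ranked by the product of three
component scores (`prioritize_variants()`), each in (0, 1]:

* **Annotation** — loss-of-function or predicted-damaging 1.0, other
  nonsynonymous 0.8, synonymous or noncoding 0.01. An unknown class maps
  to the lowest score with a warning rather than an error, so one odd
  annotation cannot abort a run.
* **Population** — a tier on the variant's maximum frequency across
  databases: absent from dbSNP 1.0; present without a recorded frequency
  0.6; below 0.001 → 0.2; otherwise 0.02. Tiering is independent of the
  upstream 5% prevalence filter, so frequencies above 5% still score
  (lowest tier) if the filter was loosened. The 0.001 boundary is
  inferred from the observed score spectra of the reference candidate
  table and is configurable.
* **Dominant segregation** — `0.1^a × 0.8^u`, where `a` counts affected
  non-carriers and `u` unaffected blood-member carriers. Obligate
  carriers are exempt from the `u` penalty: under incomplete penetrance
  an unaffected obligate carrier carrying the allele is the *expected*
  configuration, and penalizing it would make a perfectly segregating
  variant unable to score 1. This exemption is the module's central
  modeling commitment. Missing genotypes contribute no penalty in either
  direction. The defaults 0.1 and 0.8 reproduce the factorization
  pattern (`0.8^u × 0.1^a`) observable in the reference score table and
  are both configuration knobs.

Alongside, a **null-sharing statistic** `(1/2)^m` is reported, where `m`
counts blood-member carriers among non-founders — the probability that
`m` informative Mendelian transmissions would all deliver the allele by
chance. Founders and marry-ins are uninformative and excluded from `m`.

Scores combine by product — the combination the reference table's
arithmetic forces — and ties are broken by higher population score, then
chromosome and position, so output order is reproducible. A shipped
26-row reference table (`reference_candidate_scores()`) pins the
arithmetic as a regression fixture: for every row the recomputed product
matches the published overall score to its printed three significant
figures (a 0.5% relative tolerance absorbs the rounding of printed
components).

## Expression-validation statistics

The pooled (equal-variance) two-sample t-test is the default because it,
and not the Welch variant, reproduces all three published mouse
ventral-dentate-gyrus t-statistics (−3.216, 4.946, −2.055) to three
decimals when recomputed from the published group means, SDs and sample
sizes; Welch and paired variants sit behind flags. `t_test_summary()`
computes directly from (mean, sd, n) triples; `t_test_raw()` computes the
group moments and calls the identical formula, and the two routes agree
to machine precision — a tested invariant, with `stats::t.test()` as an
independent oracle on the raw route. Signs follow first-group-minus-
second-group; the published signs are reproduced by documented group
ordering. The human blood-expression comparisons are checked only as
tolerance bands (±0.05): their published t-values (3.652, 2.131) are not
exactly recoverable from summaries printed to two decimals (recomputation
gives ≈3.64, ≈2.15), which is consistent with rounding. The
before/after-treatment comparison is implemented as a two-sample test by
default, matching the stated analysis, with the paired alternative behind
a flag.

Normality screening uses the one-sample Kolmogorov–Smirnov test against a
normal with the sample mean and SD and the uncorrected asymptotic p —
the convention of the desktop statistics packages this emulates. With
estimated parameters that p is conservative (it under-rejects), which is
acceptable for a screen that gates a t-test; the Lilliefors-corrected
version (via the nortest package) is available with `lilliefors = TRUE`.
Zero-variance input is an error, not a silent p of 1.

Relative qPCR quantification uses the comparative-Ct method:
ΔΔCt = (Ct_target − Ct_ref)_sample − (Ct_target − Ct_ref)_calibrator and
fold change 2^−ΔΔCt, with replicate Ct rows averaged before
differencing. The method assumes ~100% amplification efficiency;
efficiency-corrected models are out of scope.

## The synthetic-data generator

`simulate_pedigree_dataset()` performs gene-dropping on a pedigree
template: founder genotypes for each background variant are drawn under
Hardy–Weinberg equilibrium at that variant's frequency, and each child
receives one allele from each parent with probability `g/2` — exactly
Mendelian transmission. The causal variant is planted heterozygous in one
lineal founder and in *no other founder*, making it family-private by
construction: it can never enter through a marry-in, which is the
segregation model's core premise. Affection is then assigned
Bernoulli(`penetrance`) to true carriers and Bernoulli(`phenocopy`)
otherwise, so the realized affected set varies across replicates the way
incomplete penetrance implies.

Defaults are the study regime the package targets:

| parameter | default | rationale |
|---|---|---|
| pedigree | 22-member template | 9 affected, 5 marry-ins, obligate-carrier configuration |
| `penetrance` | 0.9 | high but incomplete dominant model |
| `phenocopy` | 0 | affected non-carriers not part of the base model |
| `mean_depth` | 70× (Poisson) | within the 46–80× per-sample exome coverage regime |
| `seq_error` | 0.005 | keeps hom/het allele-fraction distributions well separated at 70× |
| `background_af` | Uniform(0.01, 0.5) | spans rare-to-common founder variation |
| `region_probs` | whole-exome call-set composition (~49% exonic, ~30% intronic) | background annotation mix |
| `genotype_error`, `missing_rate` | 0 | noise is opt-in per experiment |
| `qc_violation_rate` | 0.1 | gives the QC stage work to do |

Read-level evidence is simulated per call: depth ~ Poisson(λ), alt reads
~ Binomial(depth, p) with p = `seq_error`, 0.5, or 1 − `seq_error` by
true genotype. Genotype *calls* — not reads — are then corrupted: with
probability `genotype_error` a call is replaced by one of the other two
genotypes, and with probability `missing_rate` it is erased. The truth
record retains the true genotype matrix and both corruption masks, so any
downstream expectation can be recomputed by brute force. A fixed seed
fully determines the dataset, to the byte, through `write_vcf()`/
`write_ped()`.

What the simulator does *not* emulate: linkage disequilibrium between
background variants (variants are independent), population demography,
batch effects in coverage, and read-level artifacts (no FASTQ). Passing
tests on simulated data therefore demonstrate the pipeline's logic —
predicate correctness, score arithmetic, determinism, recovery of a
planted signal — not robustness to the full messiness of real exomes.

`simulate_expression()` draws independent normal group samples; its
`exact_moments` mode affinely rescales each group so sample mean and SD
equal the specification exactly, which reconstructs raw datasets
consistent with published summary statistics (and, piped into
`t_test_raw()`, reproduces the summary-based t exactly).

## Numerical and design choices

* Coordinates are 1-based inclusive (VCF convention); a one-base
  `start;end` locus notation maps to a single-position SNV.
* A *carrier* holds at least one alt allele; zygosity is never used by
  the filters, matching the sharing logic they implement.
* Multi-allelic sites are split into one record per ALT allele on read;
  the total count of (site, allele) pairs is conserved.
* Annotation is consumed, not computed: the VCF contract is a strict
  INFO schema (`GENE`, `REGION`, `CSQCLASS`, `MQ`, `MQ0`, `DP`, `FS`,
  `AF_<database>`, dbSNP id in the ID column) mirroring upstream
  annotation output. Computing annotations is out of scope.
* Reading goes through vcfR; writing is a schema-faithful serializer so
  that read∘write∘read is the identity on retained fields — a tested
  invariant.
* Scores multiply to full floating precision; no rounding happens before
  ranking. Reported tables round for display only.
* All analysis paths are seed-free and deterministic; randomness lives
  exclusively in the simulator and is governed by one integer seed.

## Problem sizes used in the test suite

The shipped tests run the cascade-versus-brute-force comparison on 200
seeded datasets of 30 background variants plus the planted causal variant
across 22 samples, the noiseless recovery check on 100 replicates of 60
background variants (the planted variant must survive every stage in all
of them and rank first in at least 95%), the null-calibration of the
pooled t on 10,000 two-group replicates (empirical type-I error must lie
in [0.04, 0.06] at α = 0.05), and Hardy–Weinberg/composition checks on
500- and ~21,000-record draws. These sizes give the binomial bounds used
by the assertions reasonable power while keeping a full run at a few
minutes on one core.

## Known limitations

* Only the dominant model is implemented; recessive and compound-
  heterozygous filters, X-linked and mitochondrial inheritance, de novo
  detection and CNVs are out of scope.
* The population-tier boundaries (0.001; the 5% prevalence cut) are
  inferred and configurable, not canonical.
* Per-variant segregation scores from the original analysis cannot be
  reproduced end-to-end without the underlying per-sample genotypes;
  what is pinned is the scoring law and the component→overall
  arithmetic.
* The qPCR model ignores amplification-efficiency differences between
  target and reference genes.
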