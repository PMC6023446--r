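---
title: "Screening DMET genotype tables: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening DMET genotype tables: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmetscreen)
```

dmetscreen takes one genotype-call table (probes × samples, diploid calls or
`NoCall`), a two-class phenotype assignment and optional per-sample OS/PFS
annotations, and runs three screens in one execution: per-probe Fisher exact
association testing with multiple-testing correction and Hardy–Weinberg
testing, Fisher-filtered class-association rule mining via FP-Growth, and
per-probe Kaplan–Meier/log-rank survival screening. This vignette records
the statistical model behind each stage, the tunable parameters, and the
design decisions taken where more than one reasonable convention exists.

## Input model and preprocessing

A genotype call is an unordered pair of allele symbols; `"G/A"` and `"A/G"`
are the same genotype. Calls are therefore canonicalized on input (alleles
sorted under a fixed C-locale order), half-calls and unrecognised strings
are demoted to missing and reported, and `NoCall` is the single missing
value. The genotype table defines the sample universe; class and survival
files are intersected against it (extras dropped with a warning) because a
clinical annotation for an un-genotyped sample cannot enter any screen. An
empty class after intersection is an error.

Preprocessing removes probes that cannot contribute to any downstream
analysis: probes whose NoCall fraction exceeds `max_nocall_fraction`
(default 0.1 — a probe failing in more than ~10% of samples is usually a
probe-level assay failure) and, by default, monomorphic probes (fewer than
two distinct genotypes among called samples), which carry no contrast for
association, mining or stratification. A probe failing both checks is
reported once, with excess-NoCall taking precedence. Filtering is
idempotent and order-preserving. The per-probe genotype-category counts
(NoCall included) are exposed as the distribution matrix behind the
heat-map view; computation and rendering are deliberately separated, the
matrix being the contract.

## Association screen

For each probe and each genotype category *g* observed among class-assigned,
called samples, the screen forms the presence/absence table
(a, b, c, d) = (#A with *g*, #A without, #B with, #B without), excluding
NoCall samples per probe rather than listwise (per-probe exclusion keeps
every other probe's full sample size). The two-sided Fisher exact p-value
uses the point-probability definition: the sum of hypergeometric
probabilities of all tables with the observed margins whose point
probability is at most that of the observed table, with a relative
tolerance of 1e-7 for probability ties (the same convention as
`stats::fisher.test`, which the test suite uses as an independent oracle;
the package's own implementation exists so the tie convention and
vectorisation over hundreds of thousands of tables are under its control).
Odds ratios are plain cross-products with the 0-cell → 0/∞ convention.

Two decisions deserve emphasis:

* **Test family.** The screen tests one 2×2 table per observed genotype
  category, not one r×2 table per probe, and corrects the *entire*
  (probe × genotype) family together. For a biallelic probe this
  deliberately includes complementary rows (the (6,0,0,6) and (0,6,6,0)
  tables of the worked example) — each row answers "is carrying *g*
  associated", which is what a reader of the ranked output sees. The run
  manifest records `correction_family: probe x genotype` so the family size
  is never ambiguous. An r×2 Freeman–Halton mode is out of scope.
* **Correctors.** `bonferroni` (min(1, m·p)) and `fdr`
  (Benjamini–Hochberg step-up) via `stats::p.adjust`; `none` is the
  identity. Ranking is by adjusted p, ties broken by raw p, then probe and
  genotype, so output order is total and reproducible.

The Hardy–Weinberg test is the classical 1-df χ² goodness-of-fit of the
(hom-major, het, hom-minor) counts against n·(p², 2pq, q²) with allele
frequencies estimated from the same data. It applies only to biallelic
probes; monomorphic or >2-allele probes are flagged not-applicable rather
than failing, since DMET arrays do include tri-allelic and indel probes.

## Rule mining

Mining operates on transactions: one per class-assigned sample, containing
one `probe=genotype` item per called probe plus exactly one class item.
Before mining, the *Fisher filter* retains only probes whose minimum raw
Fisher p across categories is ≤ `fisher_filter` (default 0.05). This filter
is intentionally independent of the corrected association screen — it is a
search-space reduction device with its own threshold, not a significance
claim — which is why it uses raw p-values.

Frequent itemsets come from an FP-Growth implementation: single-item
support scan, infrequent items dropped, remaining items totally ordered by
support descending with lexicographic tie-break, transactions compressed
into an FP-tree (shared prefixes collapse; a header table chains the nodes
of each item), and recursive conditional-pattern-base mining with a
single-path shortcut. The fixed item order makes the tree, and hence the
output, independent of transaction order. Supports are exact counts over
*all* transactions, not per class — with unbalanced classes a per-class
basis would change which rules survive, so the choice is recorded in the
run manifest. The test suite proves the miner equal to brute-force subset
enumeration on hundreds of random instances.

Rules are generated only from frequent itemsets containing exactly one
class item: antecedent = the genotype items (never a class item),
consequent = the class, confidence = supp(itemset)/supp(antecedent), both
taken from exact mined supports (the antecedent is a subset of a frequent
itemset and therefore itself frequent). Rules are split by consequent class
and ranked by confidence, then support, then antecedent — the two per-class
ranked lists mirror how class-association results are read. Defaults
`min_support = 0.2` and `min_confidence = 0.8` are conventional
starting points for cohort-scale rule mining and are mandatory-overridable
at the CLI; there is no single right value, and the package treats them as
study parameters. Lift/conviction and redundancy pruning beyond the
class-consequent constraint are out of scope.

## Survival screen

For each probe and genotype category, carriers (group 1) are compared with
all other called samples (group 2), separately for OS and PFS. The log-rank
statistic is the standard hypergeometric-moment form: at each distinct
pooled event time, E₁ⱼ = n₁ⱼdⱼ/nⱼ and
Vⱼ = dⱼ(n₁ⱼ/nⱼ)(1−n₁ⱼ/nⱼ)(nⱼ−dⱼ)/(nⱼ−1) (skipped when nⱼ = 1);
χ² = (ΣO₁ⱼ−ΣE₁ⱼ)²/ΣVⱼ with 1 df. Kaplan–Meier curves use the product-limit
estimator with the events-before-censorings convention at tied times;
medians follow the "smallest event time with S(t) ≤ 0.5" convention (with a
1e-12 numerical guard on the product). The hazard ratio is the model-free
(O₁/E₁)/(O₂/E₂) — it accompanies a curve display, and fitting a Cox model
per (probe, genotype) pair would claim more than the screen intends.

Design decisions:

* **Comparisons per probe.** For a probe with exactly two observed
  categories, "category vs rest" defines the same partition twice; only the
  lexicographically first category is emitted. With ≥3 categories every
  category-vs-rest split is a distinct comparison and all are emitted. A
  carrier-vs-noncarrier allele mode is a possible extension, not currently
  implemented.
* **Ranking and multiplicity.** Results are ranked by raw log-rank p
  (ties: χ² descending, then probe) — the screen is an exploratory ranking
  device. A clearly-labelled BH-adjusted column `p_bh` is added for users
  who want error control, but it does not drive the ranking.
* **Skips.** Comparisons with an empty group or zero pooled events are
  skipped; a missing survival annotation skips the whole stage, recorded in
  the manifest. The statistic here is the standard log-rank test; no
  area-under-curve summary is computed.

## Engine

The stage graph is load → preprocess → {survival screens} ∥ {Fisher + HWE →
rule mining}. The two analysis branches are independent: each stage runs
under its own error handler, so a failure in one branch is recorded in the
manifest while the other branch completes. Parallelism is provided by a
deterministic `parallel_map` (forked workers, results in input order,
pool bounded by the available cores): per-probe chunks inside the screens
and the two branches at the top level. Because every analysis stage is
deterministic, outputs are byte-identical for any worker count — the suite
asserts this on the full CSV bundle. The stage graph is static; all
interactive choices (class assignment, thresholds) are configuration
parameters, which is what makes runs reproducible and testable. A single
integer seed drives the only stochastic component, the synthetic-data
generator.

Outputs are plain CSVs (`fisher_results.csv`, `hwe_results.csv`,
`rules_<class>.csv`, `survival_OS.csv`/`survival_PFS.csv`, per-curve
step-coordinate files for comparisons with p ≤ α, the heat-map matrix and
the preprocessing report) plus `run_manifest.json` echoing the
configuration, per-stage status and per-file row counts. Wall times appear
only in the manifest, keeping the CSVs byte-stable.

## Synthetic data: what it emulates, and what it does not

`simulate_dataset()` draws background probes as independent biallelic SNPs
under Hardy–Weinberg proportions with minor-allele frequency uniform on
[0.1, 0.5] — DMET probes target ascertained polymorphic pharmacogenomic
variants, so a 0.1 floor keeping all three genotype classes represented at
cohort sizes around 100 is a reasonable background. Defaults: 100 samples,
200 probes, even class split, 2% NoCalls, exponential survival with
baseline hazard 0.1 per time unit and 30% expected censoring. Censoring is
independent uniform on (0, b) with b solved (by `uniroot`) from
E[e^{-hC}] = (1−e^{-hb})/(hb) = target rate at the baseline hazard;
progression times are an independent exponential race against death, so
PFS ≤ OS by construction.

Planted effects define the ground truth: association probes are drawn at a
stated genotype frequency per class; rule effects first draw the antecedent
genotypes (carriage frequency 0.7 per antecedent probe) and then assign
carriers the target class with the stated probability, so the planted
rule's population confidence is that probability; survival effects multiply
the carrier hazard by the stated ratio. Everything is reproducible from one
seed.

What the generator does **not** emulate — and hence what green tests do not
establish about real DMET data: linkage disequilibrium between probes
(probes are independent), population stratification and relatedness,
probe-specific NoCall patterns (missingness is uniform), allele-specific
assay chemistry, non-exponential hazards, and informative censoring.
Calibration results under this null transfer to real data only to the
extent those assumptions hold.

## Numerical choices and validation scale

* Fisher ties: point probabilities compared with relative tolerance 1e-7;
  the exhaustive sweep of all 2×2 tables with N ≤ 30 agrees with direct
  hypergeometric enumeration to 1e-10.
* Support thresholds: count ≥ n·minsup − 1e-9 guards binary-float
  round-off in proportions such as 2/3; confidence comparisons use a 1e-12
  slack in the same spirit. Medians use S(t) ≤ 0.5 + 1e-12.
* Sorting everywhere uses radix (C-locale) order so rankings do not depend
  on the session locale.
* Degenerate inputs are contracts, not crashes: all-zero contingency tables
  and empty groups are errors; monomorphic probes are skips or
  not-applicable flags; an empty filtered table or rule set is legal and
  flagged.

The validation suite runs at deliberately chosen sizes: the null
calibration of the association screen uses 500 simulated null cohorts of
200 probes × 100 samples (family-wise false-positive rate under Bonferroni
bounded by 0.05 plus two binomial standard errors — Fisher is conservative,
so the observed rate sits well below the nominal level); survival-screen
uniformity pools the raw p-values of 20 null cohorts into one
Kolmogorov–Smirnov check at the 1% level. Two caveats make that KS check
approximate by nature: all comparisons within a cohort share the same
survival times (the pooled p-values are dependent), and small carrier
groups make the 1-df χ² reference itself approximate, so mild deviations
from uniformity are expected at large pooled sizes. Planted-effect
recovery uses 100 replicates each at the effect sizes stated in the README;
the miner is checked against brute-force enumeration on 200 random
transaction sets over ≤ 12 items.

## Known limitations

Only the tabular genotype-call export is supported (no CEL/CHP parsing);
annotation of hits against external SNP databases is out of scope; the
association screen has no r×2 mode; survival screening offers no Cox
adjustment for covariates and no confidence bands; rule mining reports
support/confidence only. The per-probe screens treat probes as independent
— with strong LD the effective number of tests is smaller than the
Bonferroni family size, making the correction conservative.
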