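---
title: "Disproportionality screening of spontaneous adverse-event reports with pvscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality screening of spontaneous adverse-event reports with pvscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvscreen)
```

## The problem

Spontaneous reporting systems (FAERS, VigiBase) collect voluntarily submitted
suspected adverse drug reaction reports. They have no denominator: we observe
how often a (drug, event) pair is *reported*, not how often it *occurs*.
Signal detection therefore asks a relative question — is event $y$ reported
disproportionately often with drug $x$, compared with how often $y$ is
reported with every other drug? All of the statistics in this package are
functions of the fourfold table

|              | target event | other events | total |
|--------------|--------------|--------------|-------|
| target drug  | $a$          | $b$          | $a+b$ |
| other drugs  | $c$          | $d$          | $c+d$ |

built per preferred term (PT), optionally rolled up to system organ classes
(SOC) through a user-supplied PT→SOC mapping (MedDRA is licensed and is never
shipped; the hierarchy is a two-column file).

## Counting unit

The default counting unit is the **event record**: one distinct (report, PT)
pair, so a report listing three PTs contributes three records and $a+b$ is
the exposure's total event-record count. This is forced by internal
consistency of published signal tables of this kind: reconstructing their
strongest row from its printed ROR and chi-square requires $a+b$ to equal the
*event* total (e.g. 2,245), not the report total (1,235). `unit = "report"`
is available, where a report contributes at most one count per cell;
cell-wise it can never exceed the record unit. Duplicate reaction rows for
the same PT within one report always count once.

## The five statistics

For a table $(a, b, c, d)$ with $N = a+b+c+d$:

* **ROR** $= ad/bc$, with lognormal 95% CI
  $\exp(\ln \mathrm{ROR} \pm 1.96\sqrt{1/a + 1/b + 1/c + 1/d})$.
  Signal: $a \ge 3$ and CI lower limit $> 1$.
* **PRR** $= \frac{a/(a+b)}{c/(c+d)}$, CI via
  $\sqrt{1/a - 1/(a+b) + 1/c - 1/(c+d)}$, and the companion chi-square
  $(ad-bc)^2 N / [(a+b)(a+c)(c+d)(b+d)]$ (no continuity correction).
  Signal: $a \ge 3$ and CI lower limit $> 1$.
* **MHRA criterion**: $\mathrm{PRR} \ge 2$, $\chi^2 \ge 4$, $a \ge 3$. The
  published sources rarely restate these constants; they are the conventional
  criterion and are configurable.
* **BCPNN information component** $\mathrm{IC} = \log_2 \frac{aN}{(a+b)(a+c)}$,
  with the closed-form posterior moments $E(\mathrm{IC})$ and
  $V(\mathrm{IC})$ under priors $\gamma_{11} = \alpha_1 = \beta_1 = 1$,
  $\alpha = \beta = 2$ and the dependence prior $\gamma$ derived so the prior
  IC expectation is zero. Signal: $E(\mathrm{IC}) - 2\sqrt{V(\mathrm{IC})} > 0$
  (the "IC025" bound). The printed IC point estimates in the motivating
  tables equal the raw $\log_2$ ratio while the parenthesized bounds match
  $E - 2\sqrt{V}$; both are exposed, and flags use the latter.
* **EBGM**, here defined exactly as published: the crude relative reporting
  ratio $aN/[(a+c)(a+b)]$ with the same lognormal SE as the ROR;
  $\mathrm{EBGM05}$ is the interval's lower limit. Signal:
  $\mathrm{EBGM05} > 2$. Note this is *not* the full gamma-Poisson mixture
  (MGPS) posterior mean — we implement the formula the source analysis
  defines while keeping the field's name. Consequently
  $\mathrm{IC} = \log_2(\mathrm{EBGM})$ identically, which the test suite
  asserts to 1e-12 and which reproduces the printed IC values (e.g.
  $\log_2 260.33 = 8.02$).

A PT is a **positive signal** when a configurable boolean rule over the five
per-method flags holds; the default `"ror & prr"` is the most conservative
literal reading of "combined application of ROR and PRR". No multiplicity
correction is applied (none is applied in the practice this mirrors); the
number of PTs tested is reported so users can judge the multiple-testing
burden themselves.

### Numerical choices

* Zero cells make ROR/PRR/EBGM intervals undefined; the default returns an
  undefined-statistic code (which always flags `FALSE`) rather than a number.
  An optional Haldane–Anscombe $+0.5$ correction is available behind
  `threshold_config(continuity = TRUE)`. Screens with the conventional
  $a \ge 3$ floor never meet a zero $a$; zero $c$ can occur for PTs unique to
  the drug and is surfaced, not silently patched.
* All cells are coerced to double before arithmetic (the chi-square
  denominator overflows 32-bit integers at realistic database sizes).
* $z$ is fixed at 1.96 to match the printed interval formulas, configurable.
* Presentation rounding (half-up, 2 decimals) happens only at TSV
  serialization; comparisons and flags always use full precision.
* Ranking is by ROR point estimate, ties by $a$ descending then PT ascending;
  rows with undefined ROR sort last. This makes screen output byte-stable
  under permutation of the input rows.

## Reconstructing published rows

Published signal tables print $a$, the ROR with CI, PRR with CI, chi-square,
IC (IC025) and EBGM (EBGM05) — but not $c$ and $d$. Because the ROR fixes
$d/c$ and the chi-square is strictly monotone in the comparator scale,
`reconstruct_table()` recovers the full table numerically from
$(a,\ a+b,\ \mathrm{ROR},\ \chi^2)$ alone. `replay_counts()` then emits a
minimal `report_store` realizing those cells — aggregated pseudo-records
carry large comparator cells as weights, so a $d \approx 5.5\times 10^7$ row
replays in a handful of rows rather than 55 million. The acceptance script
drives exactly this path and reproduces the printed CI lower limits and the
IC025 bound of the strongest row to their printed precision.

## Deduplication

The dedup rule is not stated in the motivating analysis; we adopt FAERS
practice: (i) keep the highest case version per report id (ties: latest
receipt date), then (ii) collapse reports with identical content 5-tuple
(sex, age, drug-name set, PT set, receipt date), keeping the smallest report
id. The rule is idempotent and never increases the report count. No
probabilistic record linkage is attempted.

## Stratified screens, time to onset, co-administration

Sex and age strata (`18–44`, `45–64`, `≥65`, plus `<18`; boundaries
inclusive) restrict *both* margins of the table before construction, so each
stratum is a self-contained disproportionality analysis; reports with
unknown sex or age are excluded from the corresponding strata but kept
overall. Because the source's sex comparison is ambiguous between
within-stratum disproportionality and a female-vs-male contrast, both are
provided: `stratified_screen()` (primary) and `sex_contrast()` (secondary,
female vs male within the exposure's own reports).

Time to onset is onset date minus the exposure's earliest therapy start,
per reaction; negative differences are implausible and are excluded but
counted; unknown dates propagate as unknown and are never imputed. The
median is the lower median; the per-sex cumulative curves are empirical CDFs
among known-delay records — spontaneous reports carry no risk set, so no
censoring-adjusted estimator is attempted.

Co-administration screens treat the pair (base drug + partner) as a
composite exposure against all other reports, reusing the identical metric
machinery, and annotate each PT with whether the base drug alone also flags
it; a combination-positive, base-negative PT is a candidate interaction
signal. No observed-vs-expected interaction contrast (e.g. Ω shrinkage) is
attempted; the comparator choice (all other reports, including base-only) is
a design decision the source leaves unstated.

## The synthetic reporting database

`generate_reports()` emulates a spontaneous reporting database so that every
pipeline stage is testable without proprietary extracts. Its defaults are
the stated conditions of the motivating analysis:

* 1,235 target-drug reports; background scaled to 2×10⁵ records (the real
  background is 10⁶–10⁷; we scale down for desk-speed and say so — margins
  enter the statistics only through $c/(c+d)$, which is scale-stable),
* reactions per report $1 + \mathrm{Poisson}(0.8)$ (so the target's ~1,235
  reports carry ~2,245 event records, matching the published ratio),
* female:male 3.02:1 among known sex. The source prints "male-to-female
  3.02:1" while stating females dominate; the ratio label is taken as
  inverted and the simulator uses female:male = 3.02:1 (female fraction
  0.751),
* 49.7% missing age; ages Normal(46, 15) truncated to [1, 95] (MS onset in
  the 30s plus reporting lag; a choice, stated once here),
* 42.11% missing onset timing; onset delay geometric with median 5 days,
* 18.3% serious; region mix dominated by the Americas; 2% exact-duplicate
  reports (duplicate rate chosen, not published),
* co-administered partner drugs with decreasing inclusion probabilities led
  by the published most-frequent partners.

Signals are injected multiplicatively: a target report draws each reaction
PT with probability proportional to (background probability × RR), with
sex-, age-, and partner-restricted variants. Renormalization means very
large RRs on common PTs saturate (a draw probability cannot exceed 1), so
the default catalog gives signal PTs realistically *rare* background
probabilities; the manifest records the truth (injected RR, expected and
realized cells) for every PT. Realized EBGM estimates the injected RR only
in the rare-event regime ($a \ll a + c$): strong signals self-dilute the
comparator margin otherwise, which is a property of the statistics, not of
the generator.

What a green test does establish: the counting, statistics, thresholds,
stratification, dedup and missingness machinery behave exactly as specified
on a database whose ground truth is known. What it does not establish: the
published headline counts (52 PT signals, 20 SOCs, 24 five-method-concordant
PTs) — those require the proprietary FAERS/VigiAccess extracts and are out
of scope by design; the generator also makes no attempt to model reporting
dynamics over calendar time (Weber effects and the like).

## Worked example

```{r example, eval = FALSE}
cfg <- synthetic_config(seed = 7)
sim <- generate_reports(cfg)
store <- deduplicate(sim$store)
hier <- as_hierarchy(cfg$pt_catalog[, c("pt", "soc")])
res <- screen_pt(store, "ublituximab", hier)
res
concordance(res)
tto_summary(store, "ublituximab")
```

## Known limitations

* EBGM is the published crude ratio, not an empirical-Bayes shrinkage
  estimator; for sparse cells it is anti-conservative relative to true MGPS.
* The exact-content dedup rule can collapse genuinely distinct reports that
  coincide on all five key fields; at realistic catalog and background-drug
  diversity this is rare (and such collapses are arguably true duplicates
  from the rule's point of view), but the synthetic manifest tracks injected
  pairs separately so the effect is measurable.
* The FAERS ASCII reader maps country codes to coarse regions with a small
  built-in table and treats absence from the OUTC table as non-serious;
  partial dates resolve to the first day of their period.
* Stratified screens inherit all the biases of spontaneous reports
  (no denominators, reporting fashion, confounding by indication); nothing
  here supports causal inference.
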