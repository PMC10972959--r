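---
title: "Disproportionality signal detection on spontaneous-report data"
author: "faersignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection on spontaneous-report data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous adverse-event reporting databases such as the FDA Adverse
Event Reporting System (FAERS) collect voluntary reports of suspected
drug-event pairs. They have no denominator — nobody knows how many
patients took a drug without an event being reported — so absolute risks
cannot be estimated. What can be estimated is *disproportionality*:
whether an event is reported more often with a given drug than the same
event is reported with all other drugs in the database. faersignal
implements this screening workflow end to end for a single target drug
(its defaults describe a lurbinectedin cohort, a second-line treatment
for metastatic small-cell lung cancer approved in June 2020, but every
setting is configurable).

The unit of analysis is the *report*. Each report carries one or more
MedDRA preferred terms (PTs), which roll up to system organ classes
(SOCs) through a two-level dictionary. For a target drug and one event,
the database collapses to a 2x2 table:

|              | event          | other events | total |
|--------------|----------------|--------------|-------|
| target drug  | $a$            | $b$          | $a+b$ |
| other drugs  | $c$            | $d$          | $c+d$ |
| total        | $a+c$          | $b+d$        | $N$   |

## The four algorithms and the consensus rule

Four statistics are computed per event, each with its conventional
signal standard:

* **ROR** (reporting odds ratio): $\mathrm{ROR} = ad/bc$, with the Woolf
  log-normal interval
  $\exp\{\ln \mathrm{ROR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d}\}$.
  Signal: lower 95% bound $> 1$ and $a \ge 2$.
* **PRR** (proportional reporting ratio):
  $\mathrm{PRR} = \frac{a/(a+b)}{c/(c+d)}$, paired with the Pearson
  chi-square $\chi^2 = \sum (O-E)^2/E$ (no continuity correction),
  computed in the algebraically identical closed form
  $N(ad-bc)^2 / \{(a+b)(c+d)(a+c)(b+d)\}$.
  Signal: $\chi^2 \ge 4$, $\mathrm{PRR} \ge 2$, $a \ge 3$.
* **EBGM** (here the *unshrunk* relative reporting ratio):
  $\mathrm{EBGM} = aN / \{(a+b)(a+c)\}$, with a log-normal lower bound
  $\mathrm{EBGM}_{05} = \exp\{\ln\mathrm{EBGM} - 1.645\,
  \sqrt{1/a+1/b+1/c+1/d}\}$. Signal: $\mathrm{EBGM}_{05} > 2$.
* **IC** (information component): $\mathrm{IC} = \log_2 \mathrm{EBGM}$,
  an exact identity that holds to machine precision in the
  implementation and is enforced by tests. Signal: $\mathrm{IC}_{025} >
  0$ and $a > 0$.

A *consensus signal* is an event satisfying all four standards
simultaneously. The conjunction is strictly more specific than any
single algorithm; the package's null-calibration suite checks this
empirically on generated data.

Two deliberate departures from the wider literature, both documented
rather than hidden:

* No empirical-Bayes gamma-mixture shrinkage is fitted. The screening
  convention implemented here uses the raw relative reporting ratio
  under the EBGM name; at the report counts where consensus decisions
  are actually made the shrunk and unshrunk values nearly coincide
  (published screening tables show EBGM tracking PRR to two decimals),
  and a full MGPS posterior is out of scope.
* The IC interval has no universally printed formula. The default mode
  is the Norén closed-form approximation
  $\mathrm{IC}_{025} = \mathrm{IC} - 3.3(a+0.5)^{-1/2} -
  2(a+0.5)^{-3/4}$. A diagnostic worth knowing: several published
  screening tables print an IC-to-IC$_{025}$ gap that is *constant*
  across rows at 1.67 ($\approx 1.96 \times \log_2 e \times 0.59$,
  i.e. a fixed-variance normal bound); we verified this constancy on
  such a table and therefore provide `ic025_mode = "fixed_offset"`
  with `ic025_delta = 1.67` for replicating that style of report.
  Replication work should use the fixed offset; new analyses the
  Norén form.

### Undefined statistics and zero cells

Every formula above is undefined when a cell is zero. The default
policy flags the statistic as undefined (`NA`) and fails its criterion
— a statistic is never silently reported as 0 or 1. A Haldane
correction (+0.5 on all four cells of affected tables) is available via
`dispro_config(zero_cell = "haldane")` for users who prefer defined
estimates at the cost of bias; it is off by default because the
screening thresholds were calibrated for raw cells.

### The counting unit

The 2x2 unit defaults to the report: a report contributes at most once
to an event even if duplicate PT rows (or, at SOC level, several PTs of
one SOC) appear, and $a+b$ is the number of target reports. This
reproduces the "cases" semantics of published screening tables. Because
source texts rarely state the unit, a report-by-PT-pair unit
(`unit = "pair"`, margins counted over reaction rows) is also
implemented; at PT level the two differ only in margins, at SOC level
also in $a$.

## Deduplication

FAERS accumulates several versions of one case across quarterly files.
The FDA-recommended recipe is implemented: within each CASEID keep the
version with the latest FDA_DT; a missing date loses to any present
date; remaining ties go to the highest PRIMARYID, compared as
zero-padded numeric strings. The published phrasing of the tie-break
("the highest primary drug") is ambiguous, so the rule is exposed as
`tie_break` and an alternative lowest-PRIMARYID reading can be swapped
in; the result is order-invariant and idempotent either way, which the
test suite checks by permutation.

## Descriptive profiling

`summarize_clinical()` tabulates sex, age (converted to years from YR /
MON / DY / DEC / WK codes; bins 18–64, 65–85, >85 inclusive, everything
else Unknown), report year from FDA_DT, country (a configurable list
plus "Others"), reporter occupation, and outcomes. One convention
matters and is easy to get wrong: outcome percentages use the **total
number of outcome entries**, not reports, as denominator, because a
report may carry several outcomes; a report with no outcome row
contributes one Unknown entry. The bundled `fixture_table6()` cohort
(511 reports, 729 outcome entries) exists precisely to pin this
arithmetic: 145 deaths / 729 entries = 19.9%.

Percentages are rounded half-up to one decimal, matching how such
tables are printed; full precision never leaves the internals, so this
only affects display and golden-value comparisons.

## Time to onset

Onset is the day difference between the event date and the *earliest*
day-resolution therapy start of the matched target drug on the same
report (whether the clock should instead start at the therapy episode
linked to the reaction is unknowable from typical sources; earliest
start is the default reading). Partial dates (YYYY or YYYYMM) are kept
for year-level descriptives but excluded from day arithmetic; negative
differences are dropped and counted. Quartiles use linear interpolation
between order statistics at the $(n+1)p$ plotting positions
(`quantile type 6`): for a 3-point sample $\{8, 25, 64\}$ this reports
the conventional IQR 8–64, where R's default type 7 would report
16.5–44.5. The rule is exposed as `quantile_type`.

## Subgroup re-analysis and confounding checks

`restricted_screen()` narrows the comparison universe to reports (any
drug) carrying given indications and re-screens inside it, so the
comparator population shares the indication case-mix of the target
cohort. The comparator is "all other drugs" by default;
`comparator = "named"` further restricts the universe to target plus a
named comparator drug, covering both readings of "comparative analysis
with topotecan and other drugs". Free-text indications are normalized
with a small synonym map (e.g. "Small cell lung cancer (SCLC)" folds to
"SMALL CELL LUNG CANCER").

Confounding checks are counting audits, not causal adjustments:
`cooccurrence()` counts reports carrying two PTs simultaneously, and
`concomitant_audit()` lists the distinct co-reported non-target drugs
on reports carrying a PT — an empty listing is evidence the event is
not driven by a co-medication. `per_indication_validation()` confirms a
candidate signal only when consensus holds in *every* indication
stratum; a stratum with no target reports is "not evaluable" and blocks
confirmation, the conservative reading.

## The synthetic-report generator

`synth_generate()` emits the six FAERS-dialect tables plus the PT-SOC
dictionary and a ground-truth manifest. What it emulates:

* multi-table cases keyed by report ID, with duplicate case versions
  (shared CASEID, earlier FDA_DT, identical content) at a configurable
  rate, so deduplication is exercised realistically;
* drug entries with marginal inclusion probabilities and per-drug role
  distributions (the target drug defaults to always primary suspect);
* per-PT independent event draws, with at least one reaction per report
  (empty reports are redrawn, as FAERS reports always carry a
  reaction); injected associations multiply the event probability by
  $\lambda$ on reports carrying the drug, capped at 1 with the capping
  recorded in the manifest;
* therapy start dates uniform over the study window (2020-06-15 to
  2023-09-30 by default), log-normal onset (median 25 days, log-sd
  1.54, which puts the quartile ratio near the 8-to-64-day spread
  reported for the motivating cohort), event date = anchor start +
  onset, receipt date after a reporting delay;
* per-field missingness, outcome multiplicity, per-drug indication
  distributions.

What it does **not** emulate: real FAERS marginal distributions of
drugs and PTs, correlated event co-occurrence (beyond what injected
signals induce), free-text noise beyond form suffixes, country- or
time-varying reporting behaviour. Passing the calibration and recovery
suites therefore shows the *statistics and plumbing* are right, not
that real-data confounding (channeling, stimulated reporting,
duplicates across different CASEIDs) is handled — those are analytic
limitations of disproportionality itself.

All randomness flows from one seeded generator with a documented stream
order, so snapshots are byte-identical across runs of the same seed.

## Validation suites and problem sizes

The test suite runs entirely on generated or in-code data, at sizes
chosen to keep the full run near a minute while leaving the statistical
checks well-powered:

* *Null calibration*: 20 seeds of 10,000 reports x 200 PTs with no
  injected signal and a 5% target cohort. The consensus fraction must
  not exceed any single algorithm's flag fraction, and the median ROR /
  PRR / EBGM (IC) over estimable events must center on 1 (0).
  Estimable means expected target count $\ge 5$, selected on the
  ancillary database-wide margin $(a+c) \cdot (a+b) / N$ — selecting on
  the realized $a$ itself would condition on the noise and bias the
  medians upward.
* *Recovery*: 20 seeds of 50,000 reports with a $\lambda = 4$
  association injected at a ~1% background term (expected $a \approx
  25$–30): the Woolf 95% CI must cover 4 in at least 18 of 20 seeds.
  With $\lambda = 8$, consensus must fire in at least 19 of 20. (The
  injected multiplier acts on the probability, so the true ROR is
  slightly above $\lambda$; the coverage check tolerates this.)
* *Oracle equivalence*: on 1,000 random tables with cells in
  $[1, 10^4]$, the closed-form chi-square matches the cellwise
  $\sum(O-E)^2/E$ to $10^{-9}$ relative tolerance, and ROR / PRR / EBGM
  match direct arithmetic.
* *Exact golden values*: the 511-report fixture reproduces its printed
  descriptive percentages, and dedup / determinism contracts are
  checked on adversarial fixtures.

## Known limitations

* Disproportionality measures reporting, not risk; no causal claim
  survives it. The package deliberately stops at counting audits for
  confounding.
* The simplified two-level PT-SOC dictionary stands in for the licensed
  MedDRA hierarchy; unmapped PTs route to a sentinel SOC with a
  warning rather than being dropped.
* The EBGM lower bound uses a log-normal approximation with Woolf
  variance, which approximately reproduces published magnitudes but is
  not the posterior quantile a shrinkage fit would give; exact
  replication of published EBGM$_{05}$ values is not claimed.
* LAERS-era (pre-2012) layouts and the XML distribution are not
  parsed.
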