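---
title: "Objective performance indicators from console kinematics: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Objective performance indicators from console kinematics: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opikin)
```

## The problem

Robotic surgical consoles record the positions of the hand controllers and
instrument tips continuously, together with event streams marking when a
surgeon is actively driving ("following") versus clutched or idle. From
these streams one can compute *objective performance indicators* (OPIs) —
quantitative, rater-free measures of how a surgeon moves — and ask whether
they separate experienced surgeons from trainees, step by step, in a real
operation such as robotic Roux-en-Y gastric bypass (r-RYGB).

`opikin` implements that analysis end to end:

1. **Case bundles** (`read_case_bundle()`): plain-text kinematic, activity,
   segment and roster tables on a shared clock.
2. **Step ontology** (`build_step_windows()`): raw annotation labels mapped
   onto eight canonical r-RYGB steps, with subtask merging and exclusion
   rules.
3. **OPI engine** (`compute_step_opis()`): per (case, step, operator)
   metrics.
4. **Cohort statistics** (`build_comparison_table()`): normality-gated
   two-group tests per step and metric.
5. **Synthetic generator** (`simulate_cohorts()`): seeded case bundles with
   programmable per-step effects, providing ground truth for every metric.

## The metrics

For a step with analysis windows $W$ (a disjoint union of half-open time
intervals) and per-scope activity interval sets $A_{\text{console}}$,
$A_{\text{dom}}$, $A_{\text{nondom}}$:

* **Total task duration** $T = |W|$ and **active console time**
  $T_a = |A_{\text{console}} \cap W|$, with the percentage $100\,T_a/T$;
  per-hand analogues use the hand-scope interval sets.
* **Instrument path length** $L_h = \sum_i \lVert x_{i+1} - x_{i} \rVert$
  over consecutive tip samples of hand $h$ inside $A_h \cap W$, never
  accumulating across an interval boundary.
* **Speed** $v_h = L_h / |A_h \cap W|$ — defined during active time, so
  $v_h \times \text{active time} = L_h$ holds exactly by construction.
* **Bimanual dexterity** $L_{\text{dom}} / L_{\text{nondom}}$; values above
  1 mean greater dominant-hand travel.
* **Workspace volume** $V$: the convex hull volume of the pooled both-hand
  tip positions inside $A_{\text{console}} \cap W$, reported raw, per second
  of active console time ($V/T_a$), and per centimeter of summed path length
  ($V/(L_{\text{dom}}+L_{\text{nondom}})$). Two normalizations are carried
  because workspace volume grows with both time and travel; a finding that
  survives both denominators is not an artifact of either.
* **Console sensitivity** $L_h^{\text{tip}} / L_h^{\text{wrist}}$: the
  master-slave motion scaling, a per-case consistency diagnostic rather
  than a skill metric.

Undefined values (zero denominators) propagate as `NA`, never as 0 or
infinity, so group statistics drop them per case instead of absorbing a
spurious value.

### Design choices in the engine

* *Convex hull for "space occupied".* No algorithm is canonical for the
  total volume swept by instruments; the convex hull is the simplest
  defensible reading, is rotation/translation invariant, and admits an
  independent Monte-Carlo inclusion check (used in the tests). The hull is
  computed by an incremental algorithm in C++; degenerate clouds
  (collinear/coplanar, or fewer than four points) report zero volume with a
  note. Both hands are pooled by default (`opi_config(pool_hands_workspace)`
  exposes the per-hand alternative).
* *Path length restricted to active intervals.* Speed is defined during
  active console time; restricting the summation to active intervals makes
  the speed-time-distance identity exact. The unrestricted full-window path
  length is also reported (`pathlength_window_*_cm`) for sensitivity
  analyses.
* *Half-open intervals.* All spans are `[start, end)`, making union and
  intersection durations exact with no boundary double counting.
* *Derived hand activity.* When a recording carries only console-scope
  activity, per-hand activity is derived as the spans where that hand's
  controller wrist moves faster than 0.05 cm/s over a 0.1 s window
  (configurable), intersected with console-active time.
* *Dominance.* All operators in the motivating setting were right-hand
  dominant; streams are labeled `dominant`/`nondominant` directly and the
  roster records handedness so left-dominant operators are representable.

## The step ontology

The eight canonical steps, in procedure order: dissection, creation of
gastric pouch, measurement, division of mesentery, staple anastomosis,
enterotomy closure, defect closure, hand-sewn anastomosis. The shipped
`ontology.yaml` seeds a synonym lexicon (annotation teams differ in raw
labels) and an exclusion list for rare side tasks (e.g. leak test,
concurrent hiatal hernia repair). Unknown labels are dropped with a
warning — a value-level outcome, not an error, so one stray label never
aborts a batch.

Two policy decisions were genuinely open:

* *Revisited steps.* Annotations can contain several episodes of one step.
  All windows of a step within a case are pooled into one analysis unit,
  matching an analysis that treats steps as single rows per case; the
  windows are kept as separate spans so no idle bridge time is counted.
* *Cross-step overlap.* The ontology is linear, so a segment that starts
  inside an earlier-starting segment of a different step is truncated at
  the earlier segment's end, with a warning.

Steps lacking instrument-tip data for either hand inside their windows are
omitted, mirroring the exclusion of steps without both console streams.

## Cohort statistics

The unit of analysis is the **case**: for each step and metric, each case
contributes one value per role group (averaging in the rare event that two
same-group operators share a step in one case). Per (step, metric) cell:

* **Normality gate**: Shapiro-Wilk at $\alpha = 0.05$ in *each* group; both
  must pass for the parametric path. The gating test is not dictated by the
  motivating analysis; Shapiro-Wilk is the conventional choice at these
  per-step case counts. Constant groups are treated as non-normal.
* **Parametric path**: two-sided independent Student t-test (equal
  variances; Welch via `welch = TRUE`), summaries as mean (95% t-based CI).
* **Nonparametric path**: two-sided Mann-Whitney U — exact when both groups
  have at most 8 tie-free cases, else the normal approximation with
  continuity and tie correction — summaries as median [IQR].
* $p < 0.05$ is flagged significant. **No multiple-testing correction** is
  applied by default, mirroring a raw-p-value report across the
  step-by-metric grid; `p_adjust = "BH"` turns on a Benjamini-Hochberg mode.
* Comparisons with fewer than 3 non-missing values in a group are skipped
  with a logged reason; two all-identical groups give $p = 1$ by convention.

Cases are treated as independent replicates; surgeon-level clustering
(several cases per operator) is a known limitation of this design and is
not modeled.

## The synthetic generator

Clinical console recordings are proprietary, so the generator is a
first-class module: it emulates exactly the sufficient statistics the OPIs
measure, not surgical realism.

* **Motion model**: a stationary damped Langevin process (stochastic
  harmonic oscillator, reversion time-constant 1 s) with separately
  controllable positional spread `workspace_sigma_cm` and target speed.
  Velocity is continuous, so sampled path length converges with sampling
  rate; a position-level random walk would not have that property. After
  simulation the active-time increments are rescaled once so realized path
  length equals target speed x active time; the raw realized speed is
  already within a few percent, so the spread is barely perturbed.
* **Activity**: alternating exponential active/idle bouts (mean active bout
  8 s; idle mean set by the duty cycle). Fragmented activity exercises the
  interval algebra, and the exponential/memoryless construction makes the
  occupancy expectation equal the duty cycle exactly.
* **Hands**: per-hand duty cycles and speeds; the dominant hand's travel is
  multiplied by `dominance_scale`; the wrist stream is the tip stream
  contracted by `1/motion_scale` about its centroid.
* **Between-case variability**: per-(case, step) lognormal jitter
  (sd 0.08 on the log scale) on speeds, duty cycles and spread — roughly a
  coefficient of variation of 8%, a realistic case-to-case spread for motion
  metrics and the variance the cohort statistics operate on.
* **Seeding**: every stream derives its substream seed from (master seed,
  cohort, case index, step, hand), so bundles are byte-identical under a
  fixed master seed and adding cases never perturbs existing ones.

What the generator does **not** emulate: autocorrelated surgeon behavior
across steps, learning curves within a trainee, camera/clutch events, case
complexity, or anatomically structured motion. Passing tests therefore
demonstrate that the *pipeline* measures what it claims on data with known
truth — not that any particular clinical effect generalizes.

### The study-effects preset

`preset_study_effects()` encodes the six direction-of-effect findings of
the motivating comparison (attending vs trainee) as generator profiles:
higher attending dexterity and non-dominant speed in dissection, lower
attending non-dominant speed and higher active time in pouch creation, and
higher active time with a more confined workspace in hand-sewn anastomosis.
The five remaining steps have identical profiles and act as negative
controls. Signs follow the reported pattern; magnitudes are the package's
own scaled-down choices, sized by a variance budget: with 20 cases per
cohort, 8% case jitter, and bout-sampling noise contributing roughly
5-13% CV to active-time-derived metrics at these step durations, each
programmed gap is set to at least ~3 pooled standard deviations so that a
two-sided test at $\alpha = 0.05$ detects it with high probability while
the null steps stay at the nominal false-positive rate. The dissection
step carries the dexterity effect, whose variance is dominated by the
active-time ratio; it gets the longest duration (median 90 s) for that
reason.

### Problem sizes

Replication studies run at desk scale by design: preset steps last tens of
seconds (not the tens of minutes of a real case) at 20-25 Hz sampling, 20
cases per cohort for effect recovery (100 replicates), 15 + 15 cases for
null calibration (1000 replicates), and 60 pooled single-step cases of
600 s for parameter recovery. These sizes keep a full validation run in
minutes while leaving every estimate's Monte-Carlo error well inside the
margins being tested.

### Parameter recovery estimators

Recovery checks pool replicate cases as ratios of totals (total path length
over total active time, total dominant over total non-dominant path
length). A mean of per-case ratios would be biased upward by the sampling
variance of the random denominator (Jensen's inequality) — measurably so
for dexterity, whose denominator carries the non-dominant hand's
bout-sampling noise; ratios of totals are consistent and tighter.

## Numerical notes

* Bundle text serializes numerics with 17 significant digits; reading back
  reproduces doubles exactly.
* Hull visibility tests use an epsilon scaled to the cloud diameter
  (`1e-12 x diameter` base, inflated by face normal magnitude), which keeps
  near-coplanar clouds stable; hull volumes match an independent
  implementation to ~1e-14 relative error in tests.
* p-values in rendered tables print to three decimals with values below
  0.001 shown as `<0.001`; the numeric value is preserved in a parallel
  column.
* The Mann-Whitney exact path is enumerable: at 5 vs 5 with complete
  separation the two-sided exact p is 2/252 = 0.0079, which the test suite
  verifies against a full enumeration of all 252 rank assignments.

## Known limitations

* Convex-hull workspace volume is sensitive to isolated excursions (a
  single reach inflates the hull); an alpha-shape alternative would be less
  so but has a free parameter the motivating description gives no basis to
  set.
* The statistics treat cases as exchangeable within cohorts; operator
  identity is recorded and a mixed-effects extension would be the natural
  next step.
* Per-hand active time has no universal operational definition; when hand
  scopes are not recorded, the wrist-speed threshold stands in and its
  threshold is a tunable.

## A minimal session

```{r example, eval = FALSE}
cfg <- preset_study_effects(n_cases_per_cohort = 20, seed = 1)
run <- run_cohort_comparison(cfg)          # simulate + OPIs + comparison
head(run$table[run$table$significant,
               c("step", "metric", "p_value", "test_used")])
write_opi_table(run$table, "comparison.csv")
```
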