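---
title: "Touchscreen cognitive-testing pipeline: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Touchscreen cognitive-testing pipeline: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tscog)
```

# Overview

`tscog` implements an analysis pipeline for high-throughput rodent
touchscreen cognitive testing across three tasks: the five-choice serial
reaction time task (5-CSRTT, sustained attention), pairwise visual
discrimination (PD, discrimination learning and reversal flexibility) and
paired-associates learning (PAL, object–location memory). The unit of data
is one XML event log per mouse per session. The pipeline stages are:
parse → quality control → behavioural measures → mixed-design statistics →
longitudinal clustering, plus a cohort simulator that provides ground truth
for every end-to-end claim.

This vignette documents the scientific content of each stage: the measures
and their exact definitions, the QC rules and their tunable thresholds, the
statistical models and their assumptions, the clustering procedure, what
the simulator emulates, and the numerical conventions the package fixes.

# Session files and the data model

A `session_record` holds subject metadata (ID, strain, genotype, sex, age
in months with the derived testing interval 3–6 / 7–10 / 11–13 months,
site, housing, light cycle), the task/schedule context, and the ordered
trial events. Each trial has an outcome — `correct`, `incorrect`,
`omission` (no response within stimulus presentation plus the limited
hold), or `premature` (touch during the variable delay before stimulus
onset) — a correction-trial flag, the stimulus window and duration, the
correct-touch and reward-collection latencies (present exactly on correct
trials), and a perseverative-response count (repeat touches of a previously
rewarded window).

The parser is deliberately *lenient* and the QC stage *strict*: a missing
required field becomes a `missing:<field>` annotation on the record rather
than an error, so that policy (flag, fix, or discard) lives in one place.
Only malformed XML and wrong-kind values (a non-numeric latency) abort
parsing. The writer is deterministic — fixed element order, ISO-8601
dates, seconds with exactly three decimals — so identical records always
serialise to identical bytes and `parse(write(r))` reproduces `r`. Event
logs from other acquisition systems can be adapted by an element-name
mapping table (`element_map`) without touching the parser.

# Automated quality control

Five rules cover the failure modes that occur in practice:

* `SCHEMA_MISSING` (fixable when a correction supplies the field) — a
  required field absent from the file.
* `BAD_ANIMAL_ID` (fixable) — the recorded animal is not on the study
  roster, typically an ID typed incorrectly at the chamber; supplying the
  right ID in the fixes table repairs the file (disposition `fixed`).
* `DUPLICATE_SESSION` (fatal) — a software failure at session start
  followed by a restart yields two files for the same mouse, day, task and
  schedule. Within such a group the record with the most non-correction
  trials is kept (ties: longer duration, then lexicographically smallest
  file reference); all others are flagged.
* `INCOMPLETE_SESSION` (fatal) — the signature of an early software
  failure: fewer than 10 non-correction trials **and** under 10 minutes.
  Both thresholds are configurable; requiring both avoids discarding
  legitimately short-but-slow sessions.
* `VALUE_OUT_OF_RANGE` (fatal) — negative latencies, more non-correction
  trials than the task maximum (50 for 5-CSRTT, 30 for PD, 36 for PAL), or
  a 5-CSRTT probe stimulus duration outside {1.5, 1.0, 0.8, 0.6} s. This
  rule is fatal because no ID-style correction can repair a measured
  value.

A batch report partitions files into `pass` / `fixed` / `discarded`
(`n_total = n_pass + n_fixed + n_discarded` always) and reports the
percentage of files carrying at least one flag, rounded to one decimal,
together with its complement.

## Extreme-outlier filtering of temporal features

Latencies are non-negative and right-skewed, so outlier filtering is
one-sided: a value is an extreme outlier when it exceeds
**Q3 + 3·IQR**. Quartiles use linear interpolation of order statistics at
`h = (n−1)p` (the `type = 7` convention), which must be fixed for
reproducibility since different conventions move the fence. The multiplier
3 targets *extreme* outliers only (the conventional mild-outlier fence is
1.5). Thresholds are computed per task over the pooled correct-trial
latencies of the whole clean batch — pooling across genotypes avoids
masking a genotype effect by group-specific fences — and flagged trials
are excluded from latency means but never removed from raw storage
(`mean_*_raw_s` columns retain the unmasked means for audit). With fewer
than four values the mask is suppressed with a warning, as quartiles of
tiny samples are unstable.

# Behavioural measures

All counts are over non-correction trials:

* **Accuracy (%)** = 100·correct/(correct + incorrect). Omissions and
  premature responses never enter the accuracy denominator. When no
  responded trials exist, accuracy is *absent*, not zero.
* **Omissions (%)** = 100·omissions/(correct + incorrect + omissions).
  Premature trials are excluded from this denominator because a premature
  response aborts the trial before the stimulus is ever presented, so no
  omission was possible on that trial.
* **Premature responses** and **perseverative responses** are reported as
  per-session counts.
* **Correct-touch** and **reward-collection latency**: arithmetic means
  over correct trials surviving the batch outlier mask.
* **Correction trials** (PD/PAL: the forced repetitions after an incorrect
  choice) are counted separately and never enter the trial count, so
  appending them leaves accuracy unchanged.

Aggregations:

* **Probe pairs (5-CSRTT)** — each reduced stimulus duration is tested on
  two consecutive days; measures are analysed as the pair mean. A lone
  session passes through with a completeness warning; three or more at one
  duration is an error (duplicates should have been resolved upstream).
* **Vigilance blocks** — performance across consecutive 10-trial blocks
  within a session (a full 50-trial session gives 5 blocks). A final
  partial block is retained and marked, so block counts always sum to the
  session counts.
* **Session bins (PAL)** — 45 daily sessions binned in fives ("week 1" =
  sessions 1–5, …, 9 bins), averaging each measure within the bin.
* **Sessions to criterion** — the first run of `k` consecutive sessions
  each strictly exceeding the accuracy floor, strictly below the omission
  ceiling and inside the trial range (e.g. >80 %, <20 %, 30–50 trials,
  three days for 5-CSRTT training; the PD form 24/30 correct two days
  running is the same rule with a 30-trial range and run length 2).
  Strictness at the boundary follows the criterion's "greater than"
  wording: a session at exactly 80.0 % breaks the run. Animals not
  reaching criterion within the 30-session cap are eliminated. The
  completed-trials test uses non-correction trials only.

# Mixed-design (split-plot) statistics

The genotype question — does the transgenic line differ from wildtype on a
measure repeated over stimulus durations or session bins? — is the classic
one-between × one-within design. With `a` between levels of sizes `n_j`,
`b` within levels and `N` subjects:

$$SS_{A} = b\sum_j n_j(\bar y_{j}-\bar y)^2, \qquad
  SS_{subj(A)} = b\sum_s(\bar y_s-\bar y)^2 - SS_A,$$
$$SS_{B} = \sum_l N(\bar y_{l}-\bar y)^2, \qquad
  SS_{AB} = SS_{cells}-SS_A-SS_B, \qquad
  SS_{err} = SS_{tot}-SS_{betw.subj}-SS_B-SS_{AB}.$$

`F_A = MS_A/MS_{subj(A)}` on `(a−1, N−a)` df tests the between factor
against subject-to-subject variation; the within factor and the
interaction are tested against the within-subjects error on
`(b−1, (N−a)(b−1))` and `((a−1)(b−1), (N−a)(b−1))` df. Design choices:

* Unequal group sizes are allowed (real cohorts shrink over a longitudinal
  study); the group-size-weighted decomposition above is used.
* Within-subject data must be complete — subjects with missing cells are
  an error and must be dropped explicitly beforehand. No imputation, no
  mixed-model machinery.
* No sphericity correction is applied; with more than two within levels
  the within-factor p-values assume sphericity. This is a known
  limitation.
* A zero error mean square (degenerate, noise-free data) reports an
  infinite F with p = 0 and a warning rather than failing.

Bonferroni post-hoc comparisons test the between-group difference at each
within level with `t = Δ\bar y/\sqrt{MS_{pooled}(1/n_1+1/n_2)}`, where
`MS_pooled` pools the subjects-within-groups and within-error terms —
the classical error term for a between comparison at a fixed within
level — and raw p-values are multiplied by the number of comparisons
(capped at 1).

**Effect calls.** A measure is called only when the genotype main effect
or the interaction reaches α = 0.05 (default). The symbol encodes the
*direction of change* of the transgenic marginal mean (up = higher,
down = lower); whether a change is an impairment is a property of the
measure (higher accuracy is better, higher omissions worse), carried in a
separate polarity field rather than baked into the symbol. This keeps an
increase in premature responding (`up`) distinguishable from an
improvement without the call logic guessing clinical meaning.

**Fisher's exact test** for genotype × performance-group tables uses the
two-sided point-probability method: the p-value sums the probabilities of
all tables with the observed margins whose multivariate hypergeometric
probability does not exceed the observed one (relative tolerance ~1e-7
for floating-point ties). All-zero columns admit a single allocation and
cannot change the enumeration, so they are dropped before testing; a
zero row (or fewer than two non-empty columns) leaves no contrast and
returns p = 1 with a degeneracy flag. **Benjamini–Hochberg** step-up
adjustment is applied across all strata of one analysis family.

# Longitudinal k-means clustering

Each observation is one animal at one testing interval — intervals are
treated as *independent observations*, which lets an animal change group
across ages (group migration being the interesting signal in a
progressive disease model). An observation's data is a T×V matrix:
timepoints are the 4 probe stimulus durations (5-CSRTT), the 9 session
bins (PAL) or the 10 reversal sessions (PD); variables default to
accuracy, omissions, premature and perseverative counts and the two
latencies (5-CSRTT), configurable per task.

Numerical choices, each a config knob since no single convention is
canonical for trajectory k-means:

* **Standardisation**: each variable is z-scored by its overall mean and
  SD across all cells of all observations, so a variable measured in
  seconds cannot dominate one measured in percent. A zero-variance
  variable is an error naming the variable.
* **Distance**: Euclidean over all T×V cells (equivalent to flattening
  each matrix to a vector).
* **Algorithm**: Lloyd iterations; each restart draws k distinct
  observations as initial centroids under a seeded generator; an emptied
  cluster is re-seeded with the observation farthest from its current
  centroid; iteration stops when assignments stabilise (or at 100
  iterations). Best of 20 restarts by within-cluster SS. Identical seeds
  give identical results; the caller's RNG state is untouched.
* **Complete cases only**: observations with any missing cell are
  excluded and listed.

**k = 3 always.** Three groups are used across all tasks for
cross-domain consistency; the within-SS by k ("elbow") can be inspected
but never auto-selects k. Clusters are unlabelled by construction, so
they are renamed *post hoc* by overall performance: centroids are ordered
on the mean of a primary variable (default accuracy, higher-is-better;
polarity configurable, e.g. omissions lower-is-better) into **high /
mid / low** performers, with configurable secondary tie-breakers.

Genotype differences in membership are then tested per (strain, sex,
age-bin) stratum — sexes and ages are deliberately separate strata so sex
and age effects are not conflated with genotype — via the 2×3 genotype ×
label table, with BH correction across the strata of the task.

# The cohort simulator

Real multi-site corpora are not redistributable, so the simulator is the
package's source of ground truth. Its generative model per trial:
premature with probability `p_pre`; otherwise omission with `p_om`;
otherwise a response, correct with probability
`plogis(β0 + β1·d)` at stimulus duration `d` — accuracy rising in
stimulus duration is the defining feature of 5-CSRTT probe data, and the
logistic form is the simplest monotone choice (`β1 ≥ 0` enforced).
Correct trials draw log-normal latencies (rounded to the 3-decimal
serialised precision so simulated records round-trip exactly) and
Poisson perseveration counts. PD/PAL incorrect trials are followed by
correction trials repeating until a simulated correct choice, capped at
25 repeats to bound session length.

Default study conditions follow the reference design: per strain,
2 genotypes × 2 sexes × 2 sites, three testing intervals (4, 8 and 12
months), and for 5-CSRTT a probe plan of two sessions at each of
1.5/1.0/0.8/0.6 s with duration order counterbalanced across mice by
seeded shuffle. Wildtype defaults (`p_pre` 0.06, `p_om` 0.12, β0 = 0.3,
β1 = 1.4, median touch latency 1 s) put accuracy near 92 % at 1.5 s
falling to ~76 % at 0.6 s with omissions in the low teens — the typical
healthy-mouse operating range; the transgenic default shifts β0 by −0.6
and omissions up by 5 points, a mild attentional impairment. Three
performance presets (`high`/`mid`/`low`) plant recoverable cluster
structure: they differ in accuracy, omissions, latencies, and premature
responding (elevated in `mid`), mirroring the qualitative profiles that
separate performance groups in real data.

`inject_defects()` corrupts a batch with the three emulated failure
modes (duplicate restart file with under half the trials, off-roster
animal ID, truncation below the incomplete-session thresholds) at
configurable rates, at most one defect per file, and returns an exact
truth log; QC on such a batch must flag exactly the truth-log files.

**What the simulator does not emulate** — and hence what passing tests do
not show about real data: learning dynamics within or across sessions
(training phases appear only as sessions-to-criterion counts),
within-session fatigue (an optional per-block accuracy decrement exists
but is off by default), inter-site variability beyond the site label,
correlated latencies within a session, and attrition. Recovery of planted
clusters therefore demonstrates the correctness of the clustering
machinery, not that real cohorts contain three groups.

# Verification strategy and problem sizes

Every statistical operation is checked against an independent oracle
implemented from the defining formula: quartiles against direct order-
statistic interpolation; the outlier mask against brute force on 500
random vectors; the ANOVA against both the hand-computed toy
decomposition and `aov()` Error-stratum fits, with SS conservation on 500
random balanced designs; Fisher's test against a recursive full
enumeration on 200 random 2×3 tables; BH against the step-up formula;
k-means against an exhaustive partition search (90 partitions of 6
observations into 3 non-empty groups) and `stats::kmeans` on separated
data. End-to-end: planted-preset recovery uses cohorts of 60 animals (20
per preset, 8 probe sessions each) across 10 seeds, QC truth-log
agreement uses 100-file batches at 5 % defect rates across 10 seeds, and
the membership tests are calibrated on 50 genotype-balanced null
simulations (6 strata × 20 observations). These sizes keep the full
suite fast while leaving each check statistically meaningful.

# Known limitations

* The ANOVA assumes sphericity and complete within-subject data; studies
  with heavy dropout need a mixed-model treatment out of scope here.
* The incomplete-session thresholds (10 trials / 10 min) are pragmatic
  defaults, not estimated from data.
* The IQR fence is computed pooled per task; if one genotype dominated
  the upper latency tail, pooling could shade group means slightly.
* Whether re-adjusted BH values are idempotent is sometimes assumed in
  pipelines; they are not, and `tscog` applies the adjustment exactly
  once per analysis family.
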