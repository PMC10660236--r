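---
title: "The weekly coaching-message engine: model, rules, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The weekly coaching-message engine: model, rules, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weeklycoach)
```

## What the engine does

In behavioral weight-loss (BWL) programs, participants self-weigh daily,
log dietary intake, and wear an activity tracker; a weekly tailored
"coaching message" summarizes their data and gives feedback matched to
their situation. `weeklycoach` implements such a messaging system as a
reusable engine: weekly aggregation of daily self-monitoring records into
tailoring variables, multi-stage constraint-aware selection of message
components from externalized message banks, and rendering of the delivered
text — plus a synthetic-cohort simulator so the entire pipeline runs with
no participant data.

A delivered message has three components:

1. a **summary box** of the week's data (weight trend, calories, monitoring,
   activity), rendered with fixed rounding rules;
2. **weight feedback** selected by criteria over the week's weight pattern,
   with first-time milestone congratulations and a self-weigh reminder on
   zero-weigh weeks; and
3. **behavioral feedback** built in stages — a *theme* (tone), a *parent*
   subcomponent addressing exactly one behavioral prescription, and
   optionally a domain-matched *targeted* sentence (reinforcement or a
   strategy suggestion).

## The weekly tailoring variables

`aggregate_week()` reduces one 7-day window to:

| variable | definition | absent when |
|---|---|---|
| `weight_change` | this window's reduced weigh-in minus last window's | either side missing |
| `weight_category` | LOSS < −0.4 lbs; MAINTENANCE in [−0.4, +0.4]; GAIN > +0.4 | change absent → UNKNOWN |
| `cum_pct_change` | 100 × (this week's weigh-in − baseline)/baseline | no weigh-in this week |
| `days_self_weighed` | days with a weight record | — |
| `mvpa_minutes` | weekly sum of tracker activity minutes | — |
| `activity_tracking_days` | days with recorded minutes > 0 | — |
| `avg_calorie_intake` | mean over logged days | no logged days |
| `days_in/above/below_range` | split of logged days against the target range | — |
| `app_used` | any app open in the window | — |

The target calorie range runs from 300 kcal below the participant's daily
goal to the goal, both bounds inclusive. Days *below* the range are treated
as likely underreporting, so dietary-monitoring adherence
(`monitoring_days`) counts only within-or-above days.

Windows are anchored to the program start date, not calendar weeks, because
"week 1" — the baseline-weight week — is the program's reference point.
Weekly weight reduction uses the **last** weigh-in of each window by
default: it matches the semantics of a weekly check-in, and is robust to
sparse weighing. It is swappable per profile (`weight_reduction:
last|mean`) since either convention is defensible. The trailing trend
(`trailing3_net_change`) covers the 3 weeks *prior to last week*, read here
as week indices k−4..k−2; the alternative reading (k−3..k−1) would overlap
the "past week" variable, which argues for ours. Missing trailing weeks are
skipped; if all three are absent the trend is absent.

Milestones fire at cumulative changes of ≤ −5% and ≤ −10% exactly (no
tolerance, computed before display rounding), each at most once per
participant; the history records them permanently.

## The criteria language and message banks

All content is configuration in a YAML bank file (`bank_schema: 1`;
JSON accepted). Weight and parent messages carry **conjunctions** of simple
criteria (`LT LE EQ GE GT IN BETWEEN PRESENT ABSENT`) over the weekly
variables, two derived labels (`cum_band`, `trailing3_summary`), and
profile fields. Disjunction is expressed as multiple bank entries — that
keeps matching auditable and lets coverage be checked exhaustively.
Comparisons against absent values are false (not errors), so sparse weeks
fall through to low-data entries. Unknown variable names fail at load time,
never at match time.

Load-time validation enforces everything the selection rules rely on: ≥ 2
weight messages per distinct criteria set *and* per reachable signature, ≥ 2
positively weighted themes per progress tier (otherwise the
no-consecutive-theme rule is unsatisfiable), exactly one behavioral domain
per parent, an always-matching fallback parent per theme, a targeted message
for every (domain, type) pair, and digit-free rescue check-in texts.

`check_coverage()` proves the fallback guarantee over a documented
discretized grid: each count at 0/1/4/7, weight category at all four values,
cumulative change at its band boundaries and absent, seven calorie-day
split patterns, optional fields present and absent — roughly 1.3 × 10^5
states. Matching over the grid is vectorized; the test suite checks it
against an exhaustive double loop on a subsample.

Shipped-bank choices. The deployed system's banks are not public, so the
default bank is original content: 22 weight messages (≥ 2 per signature
cell), 4 themes with author-chosen tier weights, 20 parents, 20 targeted
messages. Fallback parents use the *empty* criteria set rather than an
"opened the app" criterion — an app-use condition would leave
no-engagement states uncovered. Each theme ships two fallbacks in
different domains, so the no-consecutive-domain exclusion can never empty
the candidate pool and the audited last-resort repeat is structurally
unreachable with this bank.

## Selection rules

**Weight feedback.** Zero-weigh weeks get the reminder text instead. The
habituation key is the signature (weight category, trailing-trend summary,
cumulative-change band, intent); the default bands are ≤ −10, (−10, −5],
(−5, −2], (−2, 0], > 0 percent, overridable in the bank. Among matching
messages, only the **most specific** criteria sets (maximum criterion
count) are candidates, so a message written for an exact situation outranks
a generic same-category one. Ids already sent at the signature are
excluded; when all have been sent, the least-recently-sent id is reused —
LRU maximizes spacing between repeats and is deterministic.

**Theme.** The progress tier is DECLINING if the past week was a gain or
the trailing net change exceeds +0.4 lbs; IMPROVING if the past week was a
loss and the trailing change is below −0.4 lbs; otherwise FLAT (unknown
data included). Tier weights live in the bank so real deployment
probabilities can be dropped in. Last week's theme is zeroed out and the
rest renormalized before a categorical draw.

**Parent.** Criteria-matching parents of the theme, minus last week's
domain; if empty, the theme's fallbacks outside that domain; if even that
is empty (not reachable with the shipped bank), the repeat is permitted and
flagged in the audit — a message must always be deliverable. Ties break
uniformly.

**Targeted.** Authored per parent in its `targeted_slot` field
(NONE / REINFORCEMENT / STRATEGY); drawn uniformly from entries matching
the parent's domain and the slot type.

**Rescue mode** replaces everything with a neutral check-in drawn in
rotation, exposing no aggregated data; bank validation guarantees the texts
contain no numerals. Behavioral feedback *is* still generated on zero-weigh
weeks — only the weight component is replaced — with weight-dependent
criteria evaluating against absent values.

## Randomness and reproducibility

Every random decision draws from an isolated stream (`coach_rng()`), seeded
per participant-week as the 32-bit FNV-1a hash of
`"<global_seed>:<participant_id>:<week_index>"` folded into [1, 2^31 − 1].
Results are therefore independent of cohort iteration order, and the whole
pipeline is a pure function of (inputs, seed); the engine never touches the
caller's `.Random.seed`. Each stage logs candidates, exclusions with
reasons, the uniform draw, and the chosen id into the message's audit
record.

## Rendering

The summary box is eight labeled lines in fixed order (weight → calories →
monitoring → activity). Percents show one decimal, kcal and minutes as
integers, rounding half away from zero; absent data render as fixed
phrases ("no weigh-ins this week", "no dietary records"), never as 0.
Message templates may embed `{placeholder}` tokens from a whitelist of
summary counts and goals only — so behavioral texts cannot leak weight
values — and an unresolved placeholder is an error naming the message.

## The synthetic cohort

`simulate_participant()` draws daily weight as linear drift plus IID
Gaussian noise (day *d*, 1-based: `start + drift·d/7 + N(0, sd)`), observed
on Bernoulli weigh-in days; calories and activity minutes are truncated
Gaussians on Bernoulli logging/wear days. The model is deliberately
non-physiological — no autocorrelation, plateaus, or water-weight dynamics —
it is the simplest process that exercises every weight category, band, and
milestone path. Passing tests therefore demonstrate rule correctness, not
realism of behavior change. Default adherence (`p_weigh` 0.8, `p_log` 0.7,
`p_wear` 0.85) reflects the moderately adherent participants such programs
typically see; effect sizes span losing (−1.5 lbs/wk) through regaining
(+0.6 lbs/wk) in the test cohorts.

Named scenarios (`make_scenario()`) pin down edge cases deterministically —
e.g. `milestone_cross` (noise-free −1 lb/week from 200 lbs crosses 5% = 10
lbs exactly at week 10, given the ≤ convention), `regainer` (a gain week
with mixed trailing weeks and net gain since baseline), `underreporter`
(most logged days below range). Each scenario's property is asserted by
re-measuring through `aggregate_week()`, not by construction.

`run_trial()` threads histories over a cohort and emits message logs, a
JSONL audit corpus, and a report (theme/domain transition matrices — whose
zero diagonals *are* the anti-repetition constraints — milestone events,
fallback counts). The verification sizes used by the test suite are 10^3
random weeks against a naive re-count oracle, 100 participants × 52 weeks
for the constraint scan, and 10^4 draws per distributional check.

## Known limitations

- Criteria are conjunctions only; complex logic requires multiple entries.
- The shipped theme weights and tier definition are package defaults, not
  calibrated values; deployments should supply their own bank.
- Intraday weigh-in reduction is out of scope: upstream data must provide
  one value per day (first-of-day by convention).
- The simulator's weight process has no autocorrelation and its adherence
  processes are independent across behaviors, unlike real participants.
- Scheduling is limited to a manifest timestamp (noon on the intervention
  day); delivery itself is out of scope.
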