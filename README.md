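# weeklycoach

Tailored weekly coaching messages for digital behavioral weight-loss
interventions.

Behavioral weight-loss (BWL) programs prescribe daily self-weighing, dietary
logging against a target calorie range, and physical activity tracked by a
wearable. Digital arms of such programs replace some human-counseling weeks
with an automated weekly "coaching message" tailored to the participant's
own data. `weeklycoach` implements that messaging system as a reusable,
fully auditable rule engine for intervention researchers and mHealth
developers: it is the machinery that turns a week of raw self-monitoring
records into the message a participant reads.

The engine has four parts:

- **Weekly aggregation** — daily records (date, morning weight in lbs,
  logged kcal, activity minutes, app-open flag) reduce to the weekly
  tailoring variables: past-week weight change Δw, categorized as loss
  (Δw < −0.4 lbs), maintenance (−0.4 ≤ Δw ≤ 0.4), or gain (Δw > 0.4);
  cumulative percent change from baseline; days self-weighed; weekly MVPA
  minutes and activity-tracking days; average intake; and the split of
  logged days within / above / below the target range
  (goal − 300 kcal, goal), where below-range days are treated as likely
  underreporting. First-time milestones fire at ≤ −5% and ≤ −10%.
- **Message banks** — all content lives in a versioned YAML file; weight and
  behavioral messages carry criteria (conjunctions over the weekly
  variables) and are validated at load, including an exhaustive proof that
  every state on a documented grid matches at least one parent message per
  theme.
- **Constraint-aware selection** — weight feedback avoids habituation
  (never the same message at the same criteria signature until alternatives
  are exhausted, then least-recently-used); behavioral feedback picks a
  theme probabilistically by progress tier (never the same theme two weeks
  running), a parent subcomponent addressing exactly one behavioral domain
  (never the same domain two weeks running), and optionally a
  domain-matched targeted sentence. Every stage logs candidates,
  exclusions, and draws to an audit record, and the pipeline is a pure
  function of (inputs, seed).
- **Synthetic cohort** — a drifting-noisy-weight / Bernoulli-adherence
  simulator and named scenario fixtures so the whole system runs and is
  testable without participant data.

## Worked example

```r
library(weeklycoach)

bank <- load_bank(default_bank_path())
sc   <- make_scenario("steady_loser")   # 12 weeks, drifting -1.2 lbs/week

h <- new_history()
for (k in 1:6) {
  res <- compose_week(sc$records, week_window(sc$profile$program_start, k),
                      sc$profile, h, bank,
                      derive_seed(42, sc$profile$participant_id, k))
  h <- res$history
}
cat(render_message(res$message))
```

prints the week-6 message:

```
Weight change: -3.5% since baseline
Past week: lost weight
Average calorie intake: 1630 kcal/day
Target calorie range: 1500-1800 kcal
Days in calorie range: 5 of 7
MVPA minutes: 182
Activity tracking days: 6 of 7
Weekly activity goal: 150 minutes

Your weight went down this past week - nice work! Take a moment to notice
what went well, because those are the habits worth protecting.

Your target calorie range of 1500-1800 kcal is there to make day-to-day
decisions simpler. Keeping meals inside it most days is what steady
progress looks like.
```

The first block is the summary box computed from the raw records (the
participant is down 3.5% from baseline and lost weight this past week, ate
an average of 1630 kcal/day with 5 of 7 logged days inside the 1500–1800
kcal target range, and logged 182 activity minutes against a 150-minute
goal). The second block is the weight feedback selected for the
loss-week signature; the third is the behavioral feedback. The message's
`$audit` field records why: tier `IMPROVING`, theme `steady_habits` drawn
at u = 0.226 after excluding last week's theme, parent `sh_fallback_cal`
drawn uniformly among 4 eligible candidates.

`run_trial()` scales this over a cohort and writes message logs, a JSONL
audit corpus, and a report whose theme/domain transition matrices have zero
diagonals — the anti-repetition constraints made visible. The same engine
is scriptable from a shell via `inst/cli/coach.R`
(`simulate` / `run` / `trial` / `validate-bank` subcommands).

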