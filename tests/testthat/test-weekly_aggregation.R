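test_that("calorie range runs from 300 kcal below the goal to the goal", {
  expect_equal(compute_calorie_range(1800), c(low = 1500, high = 1800))
  expect_equal(compute_calorie_range(300), c(low = 0, high = 300))
  expect_equal(compute_calorie_range(2500), c(low = 2200, high = 2500))
  expect_error(compute_calorie_range(299), ">= 300")
})

test_that("weight-change categories have boundaries exactly at +/-0.4 lbs", {
  expect_equal(categorize_weight_change(-0.5), "LOSS")
  expect_equal(categorize_weight_change(-0.4), "MAINTENANCE")
  expect_equal(categorize_weight_change(0.4), "MAINTENANCE")
  expect_equal(categorize_weight_change(0.0), "MAINTENANCE")
  expect_equal(categorize_weight_change(0.41), "GAIN")
  expect_equal(categorize_weight_change(NA), "UNKNOWN")
  # partition: every real delta lands in exactly one category
  deltas <- c(seq(-5, 5, by = 0.01), -0.4 - 1e-9, 0.4 + 1e-9)
  cats <- vapply(deltas, categorize_weight_change, character(1))
  expect_true(all(cats %in% c("LOSS", "MAINTENANCE", "GAIN")))
  expect_equal(cats[deltas < -0.4], rep("LOSS", sum(deltas < -0.4)))
  expect_equal(cats[deltas > 0.4], rep("GAIN", sum(deltas > 0.4)))
  expect_equal(cats[deltas >= -0.4 & deltas <= 0.4],
               rep("MAINTENANCE", sum(deltas >= -0.4 & deltas <= 0.4)))
})

test_that("an all-empty week aggregates to zero counts and absent optionals", {
  p <- test_profile()
  w <- week_window(p$program_start, 1L)
  v <- aggregate_week(validate_daily_records(NULL), w, p)
  expect_equal(v$days_self_weighed, 0L)
  expect_equal(v$mvpa_minutes, 0)
  expect_equal(v$activity_tracking_days, 0L)
  expect_true(is.na(v$avg_calorie_intake))
  expect_true(is.na(v$weight_change))
  expect_equal(v$weight_category, "UNKNOWN")
  expect_equal(v$days_in_range + v$days_above_range + v$days_below_range, 0L)
  expect_false(v$app_used)
})

test_that("weekly weight change uses last weigh-ins of adjacent windows", {
  p <- test_profile()
  rec <- validate_daily_records(data.frame(
    date = c("2023-01-02", "2023-01-08", "2023-01-09", "2023-01-12"),
    weight_lbs = c(201, 200, 202, 199.5),  # prev window last = 200
    calories_kcal = NA, mvpa_minutes = NA, app_opened = FALSE
  ))
  v1 <- aggregate_week(rec, week_window(p$program_start, 1L), p)
  v2 <- aggregate_week(rec, week_window(p$program_start, 2L), p, list(v1))
  expect_equal(v2$weight_change, -0.5)
  expect_equal(v2$weight_category, "LOSS")
  expect_equal(v2$cum_pct_change, 100 * (199.5 - 200) / 200)
})

test_that("aggregation agrees with the naive re-count oracle on random weeks", {
  p <- test_profile()
  for (s in 1:300) {
    rec <- validate_daily_records(random_records(s, n_weeks = 1L))
    w <- week_window(p$program_start, 1L)
    expect_week_equal(aggregate_week(rec, w, p), oracle_aggregate(rec, w, p))
  }
})

test_that("multi-week aggregation with history matches the oracle", {
  p <- test_profile()
  for (s in 1:40) {
    rec <- validate_daily_records(random_records(1000 + s, n_weeks = 6L))
    prior <- list()
    for (k in 1:6) {
      w <- week_window(p$program_start, k)
      got <- aggregate_week(rec, w, p, prior)
      expect_week_equal(got, oracle_aggregate(rec, w, p, prior))
      prior <- c(prior, list(got))
    }
  }
})

test_that("calorie-day split conserves the logged-day count and is monotone", {
  p <- test_profile()
  w <- week_window(p$program_start, 1L)
  for (s in 1:200) {
    rec <- validate_daily_records(random_records(500 + s))
    v <- aggregate_week(rec, w, p)
    n_logged <- sum(!is.na(rec$calories_kcal[rec$date >= w$start_date &
                                               rec$date <= w$end_date]))
    expect_equal(v$days_in_range + v$days_above_range + v$days_below_range,
                 as.integer(n_logged))
    expect_equal(v$monitoring_days, v$days_in_range + v$days_above_range)

    # adding one in-range day never decreases days_in_range / monitoring_days
    free <- setdiff(seq(w$start_date, w$end_date, by = "day"), rec$date)
    if (length(free)) {
      extra <- rbind(rec, data.frame(date = as.Date(free[1], origin = "1970-01-01"),
                                     weight_lbs = NA, calories_kcal = 1650,
                                     mvpa_minutes = NA, app_opened = FALSE))
      v2 <- aggregate_week(validate_daily_records(extra), w, p)
      expect_gte(v2$days_in_range, v$days_in_range)
      expect_gte(v2$monitoring_days, v$monitoring_days)
    }
  }
})

test_that("trailing trend summarizes weeks k-4..k-2, skipping absent entries", {
  p <- test_profile()
  rec <- validate_daily_records(data.frame(
    date = p$program_start + seq(0, 7 * 6 - 1),
    weight_lbs = rep(c(200, 200.5, 199.8, 200.9, 200.6, 201.4), each = 7),
    calories_kcal = NA, mvpa_minutes = NA, app_opened = FALSE
  ))
  prior <- list()
  for (k in 1:6) {
    v <- aggregate_week(rec, week_window(p$program_start, k), p, prior)
    prior <- c(prior, list(v))
  }
  # week 6 trailing window = weeks 2..4: +0.5, -0.7, +1.1
  expect_equal(prior[[6]]$trailing3_net_change, 0.5 - 0.7 + 1.1)
  expect_equal(prior[[6]]$trailing3_categories, c("GAIN", "LOSS", "GAIN"))
  # week 2 trailing window reaches back before week 1: no data
  expect_true(is.na(prior[[2]]$trailing3_net_change))
  # week 3 trailing window = week 1 only, whose change is absent
  expect_true(is.na(prior[[3]]$trailing3_net_change))
  expect_equal(prior[[3]]$trailing3_categories, "UNKNOWN")
})

test_that("misaligned windows and gappy week indices are rejected", {
  p <- test_profile()
  rec <- validate_daily_records(NULL)
  bad <- week_window(p$program_start + 1, 1L)
  expect_error(aggregate_week(rec, bad, p), "aligned")
  w3 <- week_window(p$program_start, 3L)
  v1 <- aggregate_week(rec, week_window(p$program_start, 1L), p)
  expect_error(aggregate_week(rec, w3, p, list(v1)), "contiguous")
  expect_error(aggregate_week(rec, w3, p, list()), "contiguous")
})

test_that("milestones fire at -5 and -10 percent, each only once", {
  h <- new_history()
  expect_equal(detect_milestones(-5.2, h), "FIVE_PCT")
  expect_equal(detect_milestones(-4.9999, h), character())
  expect_equal(detect_milestones(-5, h), "FIVE_PCT")  # <= convention, exact
  expect_equal(detect_milestones(-12, h), c("FIVE_PCT", "TEN_PCT"))
  h$milestones_reached <- "FIVE_PCT"
  expect_equal(detect_milestones(-5.2, h), character())
  expect_equal(detect_milestones(-12, h), "TEN_PCT")
  # brute force over a threshold grid: fired set must be exactly the
  # first-time thresholds crossed
  for (cum in seq(-0.1, -15, by = -0.1)) {
    fresh <- new_history()
    got <- detect_milestones(cum, fresh)
    want <- as.character(c(if (cum <= -5) "FIVE_PCT", if (cum <= -10) "TEN_PCT"))
    expect_identical(got, want, label = paste("cum =", cum))
  }
})

test_that("milestones fire at most once per kind over a whole trajectory", {
  sc <- make_scenario("milestone_cross")
  bank <- default_bank()
  h <- new_history()
  fired <- character()
  for (k in seq_len(sc$n_weeks)) {
    res <- compose_week(sc$records, week_window(sc$profile$program_start, k),
                        sc$profile, h, bank, derive_seed(5, "m", k))
    h <- res$history
    fired <- c(fired, res$message$weight_component$milestones)
  }
  expect_equal(sum(fired == "FIVE_PCT"), 1L)
  expect_lte(sum(fired == "TEN_PCT"), 1L)
})

test_that("weekly variables tabulate one row per week", {
  sc <- make_scenario("steady_loser")
  prior <- list()
  for (k in 1:5) {
    prior <- c(prior, list(aggregate_week(sc$records,
                                          week_window(sc$profile$program_start, k),
                                          sc$profile, prior)))
  }
  tab <- weekly_variables_table(prior)
  expect_equal(nrow(tab), 5L)
  expect_equal(tab$week_index, 1:5)
  expect_true("days_in_range" %in% names(tab))
})
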