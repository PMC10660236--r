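# Test helpers: independent oracles and random fixture generators.
#
# The oracles here are deliberately written as naive, literal re-counts /
# brute-force evaluators, independent of the package's implementation paths.

test_profile <- function(id = "p1", baseline = 200, goal = 1800,
                         activity_goal = 150, intent = "LOSE",
                         rescue = FALSE, start = as.Date("2023-01-02")) {
  participant_profile(id, baseline_weight = baseline, calorie_goal = goal,
                      activity_goal = activity_goal, intent = intent,
                      rescue_mode = rescue, program_start = start)
}

# Naive day-by-day re-count of every weekly variable, straight off the rows.
oracle_aggregate <- function(records, window, profile, prior_weeks = list()) {
  days <- seq(window$start_date, window$end_date, by = "day")
  weights <- c(); n_weigh <- 0L; mvpa_total <- 0; track_days <- 0L
  cals <- c(); app <- FALSE
  for (d in seq_along(days)) {
    row <- records[records$date == days[d], , drop = FALSE]
    if (nrow(row) == 0) next
    if (!is.na(row$weight_lbs)) {
      n_weigh <- n_weigh + 1L
      weights <- c(weights, row$weight_lbs)
    }
    if (!is.na(row$mvpa_minutes)) {
      mvpa_total <- mvpa_total + row$mvpa_minutes
      if (row$mvpa_minutes > 0) track_days <- track_days + 1L
    }
    if (!is.na(row$calories_kcal)) cals <- c(cals, row$calories_kcal)
    if (isTRUE(row$app_opened)) app <- TRUE
  }
  low <- profile$calorie_goal - 300
  high <- profile$calorie_goal
  d_in <- 0L; d_above <- 0L; d_below <- 0L
  for (cc in cals) {
    if (cc < low) d_below <- d_below + 1L
    else if (cc > high) d_above <- d_above + 1L
    else d_in <- d_in + 1L
  }

  # previous-window weigh-ins, re-collected naively
  prev_days <- seq(window$start_date - 7, window$start_date - 1, by = "day")
  prev_weights <- c()
  if (window$week_index > 1) {
    for (d in seq_along(prev_days)) {
      row <- records[records$date == prev_days[d], , drop = FALSE]
      if (nrow(row) == 1 && !is.na(row$weight_lbs)) {
        prev_weights <- c(prev_weights, row$weight_lbs)
      }
    }
  }
  w_this <- if (length(weights)) weights[length(weights)] else NA_real_
  w_prev <- if (length(prev_weights)) prev_weights[length(prev_weights)] else NA_real_
  wc <- if (is.na(w_this) || is.na(w_prev)) NA_real_ else w_this - w_prev
  cat_of <- function(x) {
    if (is.na(x)) "UNKNOWN"
    else if (x < -0.4) "LOSS"
    else if (x > 0.4) "GAIN"
    else "MAINTENANCE"
  }

  k <- window$week_index
  tr_net <- NA_real_; tr_cats <- character(); any_tr <- FALSE
  for (j in (k - 4):(k - 2)) {
    if (j >= 1 && j <= length(prior_weeks)) {
      pw <- prior_weeks[[j]]
      tr_cats <- c(tr_cats, pw$weight_category)
      if (!is.na(pw$weight_change)) {
        tr_net <- if (is.na(tr_net)) pw$weight_change else tr_net + pw$weight_change
        any_tr <- TRUE
      }
    }
  }
  if (!any_tr) tr_net <- NA_real_

  list(
    week_index = k,
    weight_change = wc,
    weight_category = cat_of(wc),
    cum_pct_change = if (is.na(w_this)) NA_real_ else
      100 * (w_this - profile$baseline_weight) / profile$baseline_weight,
    days_self_weighed = n_weigh,
    mvpa_minutes = mvpa_total,
    activity_tracking_days = track_days,
    avg_calorie_intake = if (length(cals)) sum(cals) / length(cals) else NA_real_,
    days_in_range = d_in,
    days_above_range = d_above,
    days_below_range = d_below,
    monitoring_days = d_in + d_above,
    app_used = app,
    trailing3_net_change = tr_net,
    trailing3_categories = tr_cats
  )
}

expect_week_equal <- function(got, want) {
  for (f in names(want)) {
    expect_equal(got[[f]], want[[f]], tolerance = 1e-12,
                 ignore_attr = TRUE, label = paste0("field ", f))
  }
}

# Random one-week records with random missing-data patterns; also returns a
# random multi-week context when n_weeks > 1.
random_records <- function(seed, start = as.Date("2023-01-02"), n_weeks = 1L) {
  set.seed(seed)
  n <- 7L * n_weeks
  keep <- runif(n) < 0.85   # some days have no row at all
  df <- data.frame(
    date = start + seq_len(n) - 1L,
    weight_lbs = ifelse(runif(n) < 0.6, round(runif(n, 140, 260), 1), NA_real_),
    calories_kcal = ifelse(runif(n) < 0.65, round(runif(n, 900, 2600)), NA_real_),
    mvpa_minutes = ifelse(runif(n) < 0.7, round(runif(n, 0, 90)), NA_real_),
    app_opened = runif(n) < 0.3
  )
  df[keep, , drop = FALSE]
}

# Brute-force single-criterion evaluator (independent of match_criteria).
brute_eval_one <- function(cr, state) {
  v <- state[[cr$variable]]
  absent <- is.null(v) || length(v) != 1 || is.na(v)
  if (cr$op == "PRESENT") return(!absent)
  if (cr$op == "ABSENT") return(absent)
  if (absent) return(FALSE)
  if (cr$op == "LT") return(v < cr$value)
  if (cr$op == "LE") return(v <= cr$value)
  if (cr$op == "EQ") return(v == cr$value)
  if (cr$op == "GE") return(v >= cr$value)
  if (cr$op == "GT") return(v > cr$value)
  if (cr$op == "IN") return(any(unlist(cr$value) == v))
  if (cr$op == "BETWEEN") {
    pair <- unlist(cr$value)
    return(v >= pair[1] && v <= pair[2])
  }
  stop("bad op in oracle")
}

brute_match <- function(criteria, state) {
  res <- TRUE
  for (cr in criteria) res <- res && brute_eval_one(cr, state)
  res
}

# Random selection state covering all field kinds the criteria language sees.
random_state <- function(seed) {
  set.seed(seed)
  cats <- c("LOSS", "MAINTENANCE", "GAIN", "UNKNOWN")
  list(
    week_index = sample(1:52, 1),
    weight_change = if (runif(1) < 0.2) NA_real_ else round(runif(1, -3, 3), 2),
    weight_category = sample(cats, 1),
    cum_pct_change = if (runif(1) < 0.2) NA_real_ else round(runif(1, -15, 5), 2),
    days_self_weighed = sample(0:7, 1),
    mvpa_minutes = sample(0:400, 1),
    activity_tracking_days = sample(0:7, 1),
    avg_calorie_intake = if (runif(1) < 0.25) NA_real_ else round(runif(1, 900, 2600)),
    days_in_range = sample(0:4, 1),
    days_above_range = sample(0:2, 1),
    days_below_range = sample(0:2, 1),
    monitoring_days = sample(0:6, 1),
    app_used = runif(1) < 0.5,
    trailing3_net_change = if (runif(1) < 0.3) NA_real_ else round(runif(1, -4, 4), 2),
    trailing3_summary = sample(c("GAIN", "MIXED_GAIN", "LOSS", "MIXED_LOSS", "FLAT", "NONE"), 1),
    cum_band = sample(c("LE_NEG10", "NEG10_NEG5", "NEG5_NEG2", "NEG2_0", "GT_0", "NONE"), 1),
    intent = sample(c("LOSE", "MAINTAIN"), 1),
    calorie_goal = sample(c(1500, 1800, 2100), 1),
    activity_goal = sample(c(100, 150, 200), 1)
  )
}

random_criterion <- function(state) {
  vars_num <- c("days_self_weighed", "mvpa_minutes", "cum_pct_change",
                "monitoring_days", "trailing3_net_change", "days_in_range")
  vars_cat <- c("weight_category", "intent", "cum_band", "trailing3_summary")
  if (runif(1) < 0.5) {
    v <- sample(vars_num, 1)
    op <- sample(c("LT", "LE", "GE", "GT", "BETWEEN", "PRESENT", "ABSENT"), 1)
    val <- switch(op,
      BETWEEN = sort(round(runif(2, -5, 10), 1)),
      round(runif(1, -5, 10), 1))
    list(variable = v, op = op, value = val)
  } else {
    v <- sample(vars_cat, 1)
    op <- sample(c("EQ", "IN"), 1)
    pool <- switch(v,
      weight_category = c("LOSS", "MAINTENANCE", "GAIN", "UNKNOWN"),
      intent = c("LOSE", "MAINTAIN"),
      cum_band = c("LE_NEG10", "NEG10_NEG5", "NEG5_NEG2", "NEG2_0", "GT_0", "NONE"),
      trailing3_summary = c("GAIN", "MIXED_GAIN", "LOSS", "MIXED_LOSS", "FLAT", "NONE"))
    val <- if (op == "IN") sample(pool, sample(seq_len(min(3, length(pool))), 1)) else sample(pool, 1)
    list(variable = v, op = op, value = val)
  }
}

# Load the default bank once per test session.
default_bank <- local({
  bank <- NULL
  function() {
    if (is.null(bank)) bank <<- load_bank(default_bank_path())
    bank
  }
})

default_bank_raw <- function() yaml::read_yaml(default_bank_path())

# Tiny valid-by-construction bank object for stage-level unit tests
# (bypasses file validation on purpose; only the fields the stage uses).
stub_bank <- function(themes = NULL, parents = NULL, targeted = NULL,
                      weight = NULL) {
  b <- default_bank()
  if (!is.null(themes)) b$themes <- themes
  if (!is.null(parents)) b$parent_messages <- parents
  if (!is.null(targeted)) b$targeted_messages <- targeted
  if (!is.null(weight)) b$weight_messages <- weight
  b
}

make_theme <- function(id, declining, flat, improving) {
  list(id = id, label = id, tone = "",
       weights = list(DECLINING = declining, FLAT = flat, IMPROVING = improving))
}

make_parent <- function(id, theme_id, domain, criteria = list(),
                        slot = "NONE", fallback = FALSE,
                        text = "placeholder body.") {
  list(id = id, theme_id = theme_id, domain = domain, criteria = criteria,
       targeted_slot = slot, is_fallback = fallback, text = text)
}

# History after composing weeks 1..n for a scenario.
new_history_through <- function(sc, bank, n, global_seed = 1) {
  h <- new_history()
  for (k in seq_len(n)) {
    h <- compose_week(sc$records, week_window(sc$profile$program_start, k),
                      sc$profile, h, bank,
                      derive_seed(global_seed, sc$profile$participant_id, k))$history
  }
  h
}

# A plain FULL-pipeline state for stage tests.
plain_state <- function(...) {
  st <- list(
    week_index = 5L, weight_change = -0.6, weight_category = "LOSS",
    cum_pct_change = -2.5, days_self_weighed = 6L, mvpa_minutes = 120,
    activity_tracking_days = 5L, avg_calorie_intake = 1650,
    days_in_range = 4L, days_above_range = 1L, days_below_range = 1L,
    monitoring_days = 5L, app_used = TRUE, trailing3_net_change = -1.2,
    trailing3_summary = "LOSS", cum_band = "NEG5_NEG2", intent = "LOSE",
    calorie_goal = 1800, activity_goal = 150
  )
  mods <- list(...)
  for (nm in names(mods)) st[[nm]] <- mods[[nm]]
  st
}
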