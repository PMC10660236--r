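#' Weekly aggregation of self-monitoring data
#'
#' Turns a participant's daily records into the eight weekly tailoring
#' variables the coaching messages reference: past-week weight change (and
#' its loss / maintenance / gain category), cumulative percent weight change
#' from baseline, days self-weighed, weekly MVPA minutes, activity-tracking
#' days, average calorie intake, days within / above / below the target
#' calorie range, and app use. Days below the calorie range are treated as
#' likely underreporting, so dietary-monitoring adherence
#' (\code{monitoring_days}) counts only within-or-above days.
#'
#' @name weekly_aggregation
NULL

#' Target calorie range for a daily calorie goal
#'
#' The target range runs from 300 kcal below the participant's selected goal
#' up to the goal itself; a day is "in range" when
#' \code{low <= calories <= high} (both bounds inclusive).
#'
#' @param calorie_goal Daily calorie goal (kcal), at least 300.
#' @return Named numeric vector \code{c(low =, high =)}.
#' @export
#' @examples
#' compute_calorie_range(1800)  # c(low = 1500, high = 1800)
compute_calorie_range <- function(calorie_goal) {
  if (!is.numeric(calorie_goal) || length(calorie_goal) != 1L ||
      is.na(calorie_goal) || calorie_goal < 300) {
    stop("calorie_goal must be a single number >= 300")
  }
  c(low = calorie_goal - 300, high = calorie_goal)
}

#' Categorize a weekly weight change
#'
#' Loss below −0.4 lbs, maintenance from −0.4 to +0.4 lbs inclusive, gain
#' above +0.4 lbs; a missing change is \code{"UNKNOWN"}.
#'
#' @param delta Weight change over the past week in lbs, or \code{NA}.
#' @return One of \code{"LOSS"}, \code{"MAINTENANCE"}, \code{"GAIN"},
#'   \code{"UNKNOWN"}.
#' @export
categorize_weight_change <- function(delta) {
  if (length(delta) != 1L) stop("delta must be a single value")
  if (is.na(delta)) return("UNKNOWN")
  if (delta < -0.4) return("LOSS")
  if (delta > 0.4) return("GAIN")
  "MAINTENANCE"
}

#' Construct the window for one program week
#'
#' Week \code{k} covers the 7 days from \code{program_start + 7(k-1)} to
#' \code{program_start + 7k - 1}; windows are anchored to the program start,
#' not to calendar weeks.
#'
#' @param program_start Date of the first day of program week 1.
#' @param week_index Program week, 1-based.
#' @return A list with \code{start_date}, \code{end_date}, \code{week_index}.
#' @export
week_window <- function(program_start, week_index) {
  week_index <- as.integer(week_index)
  if (is.na(week_index) || week_index < 1L) stop("week_index must be >= 1")
  start <- as.Date(program_start) + 7L * (week_index - 1L)
  list(start_date = start, end_date = start + 6L, week_index = week_index)
}

# last (or mean) weigh-in within [start, end]; NA if none
reduce_weigh_ins <- function(records, start, end, how = "last") {
  sub <- records[records$date >= start & records$date <= end &
                   !is.na(records$weight_lbs), , drop = FALSE]
  if (nrow(sub) == 0L) return(NA_real_)
  if (how == "mean") mean(sub$weight_lbs) else sub$weight_lbs[which.max(sub$date)]
}

#' Compute the weekly tailoring variables for one program week
#'
#' @param records Validated daily-records data frame for the participant
#'   (may span the whole program; only the relevant windows are used).
#' @param window A [week_window()] aligned to \code{profile$program_start}.
#' @param profile A [participant_profile()].
#' @param prior_weeks List of weekly-variables lists for weeks
#'   \code{1..k-1} in order (may be empty for week 1); indices must be
#'   contiguous even when a week had no data.
#' @return A named list of weekly variables (see package docs); optional
#'   quantities are \code{NA} when the underlying data are absent.
#' @details Weekly weight change is the reduced weigh-in of this window minus
#'   that of the previous window (reduction per
#'   \code{profile$weight_reduction}, default last weigh-in); it is absent if
#'   either side is missing. Cumulative percent change uses this week's
#'   reduced weigh-in against the baseline weight. The trailing trend
#'   (\code{trailing3_net_change}, \code{trailing3_categories}) summarizes
#'   the 3 weeks prior to last week, i.e. weeks \code{k-4..k-2}, skipping
#'   absent entries.
#' @export
aggregate_week <- function(records, window, profile, prior_weeks = list()) {
  k <- window$week_index
  expected_start <- as.Date(profile$program_start) + 7L * (k - 1L)
  if (window$start_date != expected_start ||
      window$end_date != expected_start + 6L) {
    stop("window is not aligned to the program-start week grid")
  }
  if (length(prior_weeks)) {
    idx <- vapply(prior_weeks, function(w) as.integer(w$week_index), integer(1))
    if (!identical(idx, seq_len(k - 1L))) {
      stop("prior_weeks must cover weeks 1..k-1 contiguously")
    }
  } else if (k > 1L) {
    stop("prior_weeks must cover weeks 1..k-1 contiguously")
  }

  inwin <- records[records$date >= window$start_date &
                     records$date <= window$end_date, , drop = FALSE]

  how <- profile$weight_reduction
  w_this <- reduce_weigh_ins(records, window$start_date, window$end_date, how)
  w_prev <- if (k > 1L) {
    reduce_weigh_ins(records, window$start_date - 7L, window$start_date - 1L, how)
  } else NA_real_
  weight_change <- if (is.na(w_this) || is.na(w_prev)) NA_real_ else w_this - w_prev

  days_self_weighed <- sum(!is.na(inwin$weight_lbs))
  mvpa_minutes <- sum(inwin$mvpa_minutes, na.rm = TRUE)
  activity_tracking_days <- sum(!is.na(inwin$mvpa_minutes) & inwin$mvpa_minutes > 0)

  cal <- inwin$calories_kcal[!is.na(inwin$calories_kcal)]
  rng_cal <- compute_calorie_range(profile$calorie_goal)
  days_in <- sum(cal >= rng_cal["low"] & cal <= rng_cal["high"])
  days_above <- sum(cal > rng_cal["high"])
  days_below <- sum(cal < rng_cal["low"])
  avg_cal <- if (length(cal)) mean(cal) else NA_real_

  cum_pct <- if (is.na(w_this)) NA_real_ else
    100 * (w_this - profile$baseline_weight) / profile$baseline_weight

  trail_idx <- (k - 4L):(k - 2L)
  trail_idx <- trail_idx[trail_idx >= 1L]
  trail <- prior_weeks[trail_idx]
  trail_changes <- vapply(trail, function(w) as.numeric(w$weight_change), numeric(1))
  trail_cats <- vapply(trail, function(w) as.character(w$weight_category), character(1))
  net <- if (length(trail_changes) && any(!is.na(trail_changes))) {
    sum(trail_changes, na.rm = TRUE)
  } else NA_real_

  list(
    week_index = as.integer(k),
    weight_change = weight_change,
    weight_category = categorize_weight_change(weight_change),
    cum_pct_change = cum_pct,
    days_self_weighed = as.integer(days_self_weighed),
    mvpa_minutes = as.numeric(mvpa_minutes),
    activity_tracking_days = as.integer(activity_tracking_days),
    avg_calorie_intake = avg_cal,
    days_in_range = as.integer(days_in),
    days_above_range = as.integer(days_above),
    days_below_range = as.integer(days_below),
    monitoring_days = as.integer(days_in + days_above),
    app_used = any(inwin$app_opened, na.rm = TRUE),
    trailing3_net_change = net,
    trailing3_categories = trail_cats
  )
}

#' Detect first-time weight-loss milestones
#'
#' Milestones fire at 5% and 10% cumulative weight loss, each at most once
#' per participant: a week with \code{cum_pct_change <= -5} yields
#' \code{"FIVE_PCT"} unless it is already in \code{history$milestones_reached},
#' and likewise \code{"TEN_PCT"} at \code{<= -10}. A single week can yield
#' both. Recording fired milestones into the history is the caller's job
#' (done by [compose_week()]).
#'
#' @param cum_pct_change Cumulative percent weight change (negative = loss).
#' @param history A \code{coach_history}.
#' @return Character vector of newly reached milestones (possibly empty).
#' @export
detect_milestones <- function(cum_pct_change, history) {
  if (is.na(cum_pct_change)) return(character())
  out <- character()
  if (cum_pct_change <= -5 && !("FIVE_PCT" %in% history$milestones_reached)) {
    out <- c(out, "FIVE_PCT")
  }
  if (cum_pct_change <= -10 && !("TEN_PCT" %in% history$milestones_reached)) {
    out <- c(out, "TEN_PCT")
  }
  out
}

#' Tabulate weekly variables for audit export
#'
#' @param weekly_list List of weekly-variables lists (one per week).
#' @return A data frame with one row per week;
#'   \code{trailing3_categories} is collapsed to a comma-separated string.
#' @export
weekly_variables_table <- function(weekly_list) {
  rows <- lapply(weekly_list, function(w) {
    w$trailing3_categories <- paste(w$trailing3_categories, collapse = ",")
    as.data.frame(w, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
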