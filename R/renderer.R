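#' Rendering the weekly coaching message
#'
#' The delivered message is plain text: a labeled summary box (weight,
#' calories, monitoring, activity — in that order), a blank line, the weight
#' feedback (milestone congratulations first when one fired), a blank line,
#' and the behavioral feedback with any targeted sentence appended. Percents
#' are shown to 1 decimal and kcal/minutes as integers, rounding half away
#' from zero; absent data render as fixed placeholder phrases, never as 0.
#'
#' @name renderer
NULL

# round half away from zero (display convention; base round() is half-even)
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

fmt_pct <- function(x) sprintf("%+.1f%%", round_half_away(x, 1))
fmt_int <- function(x) sprintf("%d", as.integer(round_half_away(x, 0)))

NO_WEIGH_TEXT <- "no weigh-ins this week"
NO_DIET_TEXT <- "no dietary records"

STATUS_WORDS <- c(LOSS = "lost weight", GAIN = "gained weight",
                  MAINTENANCE = "maintained weight", UNKNOWN = "no weigh-ins")

#' Render the summary box
#'
#' One labeled line per field, fixed order; every displayed number equals the
#' underlying weekly variable after the documented rounding, and absent
#' quantities render as their placeholder strings.
#'
#' @param vars Weekly variables from [aggregate_week()].
#' @param profile A [participant_profile()].
#' @return A single string (lines joined with newlines).
#' @export
render_summary_box <- function(vars, profile) {
  rng <- compute_calorie_range(profile$calorie_goal)
  weight_line <- if (is.na(vars$cum_pct_change)) NO_WEIGH_TEXT else
    paste0(fmt_pct(vars$cum_pct_change), " since baseline")
  cal_line <- if (is.na(vars$avg_calorie_intake)) NO_DIET_TEXT else
    paste0(fmt_int(vars$avg_calorie_intake), " kcal/day")
  lines <- c(
    paste0("Weight change: ", weight_line),
    paste0("Past week: ", STATUS_WORDS[[vars$weight_category]]),
    paste0("Average calorie intake: ", cal_line),
    paste0("Target calorie range: ", fmt_int(rng["low"]), "-",
           fmt_int(rng["high"]), " kcal"),
    paste0("Days in calorie range: ", vars$days_in_range, " of 7"),
    paste0("MVPA minutes: ", fmt_int(vars$mvpa_minutes)),
    paste0("Activity tracking days: ", vars$activity_tracking_days, " of 7"),
    paste0("Weekly activity goal: ", fmt_int(profile$activity_goal), " minutes")
  )
  paste(lines, collapse = "\n")
}

# fields message templates may reference with {placeholder}; summary-box
# variables and goals only, so behavioral texts can never leak weight values
# beyond what the summary already shows
placeholder_values <- function(vars, profile) {
  rng <- compute_calorie_range(profile$calorie_goal)
  list(
    week_index = as.character(vars$week_index),
    days_self_weighed = as.character(vars$days_self_weighed),
    days_in_range = as.character(vars$days_in_range),
    monitoring_days = as.character(vars$monitoring_days),
    mvpa_minutes = fmt_int(vars$mvpa_minutes),
    activity_tracking_days = as.character(vars$activity_tracking_days),
    calorie_low = fmt_int(rng["low"]),
    calorie_high = fmt_int(rng["high"]),
    calorie_goal = fmt_int(profile$calorie_goal),
    activity_goal = fmt_int(profile$activity_goal)
  )
}

#' Substitute whitelisted placeholders into a message template
#'
#' Templates may embed \code{{placeholder}} tokens for summary-box counts and
#' goals (e.g. \code{{days_in_range}}, \code{{activity_goal}}). Any token
#' left unresolved is an error naming the placeholder and the message id.
#'
#' @param text Template string.
#' @param vars Weekly variables.
#' @param profile A [participant_profile()].
#' @param message_id Id used in error messages.
#' @return The substituted string.
#' @export
substitute_placeholders <- function(text, vars, profile, message_id = "<unknown>") {
  vals <- placeholder_values(vars, profile)
  for (nm in names(vals)) {
    text <- gsub(paste0("{", nm, "}"), vals[[nm]], text, fixed = TRUE)
  }
  left <- regmatches(text, regexpr("\\{[A-Za-z0-9_]+\\}", text))
  if (length(left) && nzchar(left)) {
    stop("unresolved placeholder ", left, " in message ", message_id)
  }
  text
}

#' Render an assembled coaching message to delivery text
#'
#' @param msg A \code{coach_message} from [compose_week()].
#' @return A single string: for a full message, summary box + blank line +
#'   weight component + blank line + behavioral component; for a rescue
#'   check-in, the check-in text alone.
#' @export
render_message <- function(msg) {
  if (msg$kind == "RESCUE_CHECKIN") {
    return(msg$checkin_text)
  }
  paste(msg$summary_box, "", msg$weight_component$text, "",
        msg$behavioral_component$text, sep = "\n")
}

#' @export
print.coach_message <- function(x, ...) {
  cat(render_message(x), "\n")
  invisible(x)
}

#' Build a delivery manifest entry
#'
#' Messages are delivered at noon local time on the participant's scheduled
#' intervention day (taken as the last day of the program week).
#'
#' @param msg A \code{coach_message}.
#' @param profile A [participant_profile()].
#' @return A list with \code{participant_id}, \code{scheduled_datetime}
#'   (\code{"YYYY-MM-DD 12:00"}), and \code{text}.
#' @export
delivery_manifest <- function(msg, profile) {
  day <- as.Date(profile$program_start) + 7L * msg$week_index - 1L
  list(participant_id = profile$participant_id,
       scheduled_datetime = paste(format(day, "%Y-%m-%d"), "12:00"),
       text = render_message(msg))
}
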