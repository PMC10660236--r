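#' Shared data types: daily records, profiles, histories
#'
#' The engine works on four kinds of object:
#' \itemize{
#'   \item daily records — a data frame, one row per calendar day, columns
#'     \code{date}, \code{weight_lbs}, \code{calories_kcal},
#'     \code{mvpa_minutes}, \code{app_opened}; \code{NA} means the
#'     observation is absent (no weigh-in, no dietary log, tracker not worn).
#'   \item a participant profile (see [participant_profile()]).
#'   \item weekly tailoring variables (see [aggregate_week()]).
#'   \item a participant history (see [new_history()]), the memory the
#'     anti-repetition and milestone rules need between weeks.
#' }
#' Units are pounds and kilocalories throughout; unit conversion belongs in a
#' pre-processor, not here.
#'
#' @name domain_model
NULL

DAILY_COLS <- c("date", "weight_lbs", "calories_kcal", "mvpa_minutes", "app_opened")

WEIGHT_CATEGORIES <- c("LOSS", "MAINTENANCE", "GAIN", "UNKNOWN")
DOMAINS <- c("SELF_WEIGHING", "DIETARY_MONITORING", "CALORIE_INTAKE",
             "PHYSICAL_ACTIVITY", "APP_USE")
TARGETED_TYPES <- c("REINFORCEMENT", "STRATEGY")
MILESTONES <- c("FIVE_PCT", "TEN_PCT")
INTENTS <- c("LOSE", "MAINTAIN")
TIERS <- c("DECLINING", "FLAT", "IMPROVING")

#' Validate a table of daily self-monitoring records
#'
#' Checks ranges, de-duplicates identical rows, and rejects (never repairs)
#' violations: a weight outside (50, 1000) lbs, calories outside
#' \code{[0, 20000]} kcal, negative activity minutes, or two rows for the
#' same date with conflicting values all raise an error naming the offending
#' field or date.
#'
#' @param records Data frame with columns \code{date} (Date or ISO-8601
#'   string), \code{weight_lbs}, \code{calories_kcal}, \code{mvpa_minutes}
#'   (numeric, \code{NA} = absent) and \code{app_opened} (logical,
#'   \code{NA} treated as \code{FALSE}).
#' @return The validated data frame, date-sorted, one row per date.
#' @export
validate_daily_records <- function(records) {
  if (is.null(records) || nrow(as.data.frame(records)) == 0L) {
    out <- data.frame(date = as.Date(character()), weight_lbs = numeric(),
                      calories_kcal = numeric(), mvpa_minutes = numeric(),
                      app_opened = logical())
    return(out)
  }
  records <- as.data.frame(records)
  missing <- setdiff(DAILY_COLS, names(records))
  if (length(missing)) {
    stop("daily records missing column(s): ", paste(missing, collapse = ", "))
  }
  records <- records[DAILY_COLS]
  records$date <- as.Date(records$date)
  if (anyNA(records$date)) stop("daily records contain unparseable dates")
  for (col in c("weight_lbs", "calories_kcal", "mvpa_minutes")) {
    records[[col]] <- as.numeric(records[[col]])
  }
  records$app_opened <- as.logical(records$app_opened)
  records$app_opened[is.na(records$app_opened)] <- FALSE

  bad_w <- which(!is.na(records$weight_lbs) &
                   (records$weight_lbs <= 50 | records$weight_lbs >= 1000))
  if (length(bad_w)) {
    stop(sprintf("invalid weight %.1f lbs on %s (must be in (50, 1000))",
                 records$weight_lbs[bad_w[1]], records$date[bad_w[1]]))
  }
  bad_c <- which(!is.na(records$calories_kcal) &
                   (records$calories_kcal < 0 | records$calories_kcal > 20000))
  if (length(bad_c)) {
    stop(sprintf("invalid calories %.0f kcal on %s (must be in [0, 20000])",
                 records$calories_kcal[bad_c[1]], records$date[bad_c[1]]))
  }
  bad_m <- which(!is.na(records$mvpa_minutes) & records$mvpa_minutes < 0)
  if (length(bad_m)) {
    stop(sprintf("invalid mvpa_minutes %.1f on %s (must be >= 0)",
                 records$mvpa_minutes[bad_m[1]], records$date[bad_m[1]]))
  }

  records <- unique(records)
  dup <- records$date[duplicated(records$date)]
  if (length(dup)) {
    stop("conflicting duplicate records for date ", format(dup[1]))
  }
  records <- records[order(records$date), , drop = FALSE]
  rownames(records) <- NULL
  records
}

#' Read daily records from delimited text
#'
#' Expects header \code{date,weight_lbs,calories_kcal,mvpa_minutes,app_opened}
#' with ISO-8601 dates; an empty cell means the observation is absent.
#'
#' @param path Path to a CSV file.
#' @return A validated daily-records data frame.
#' @export
read_daily_records <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(date = "character"))
  validate_daily_records(raw)
}

#' Write daily records as CSV
#' @param records Validated daily-records data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_daily_records <- function(records, path) {
  out <- records
  out$date <- format(out$date, "%Y-%m-%d")
  out$app_opened <- tolower(as.character(out$app_opened))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Construct a participant profile
#'
#' @param participant_id Opaque identifier string.
#' @param baseline_weight Body weight (lbs) measured in program week 1.
#' @param calorie_goal Upper bound of the daily target calorie range
#'   (kcal/day); the range runs from 300 kcal below the goal to the goal.
#' @param activity_goal Weekly moderate-to-vigorous activity target (minutes).
#' @param intent \code{"LOSE"} or \code{"MAINTAIN"}.
#' @param rescue_mode If \code{TRUE}, coaching is paused and a neutral
#'   check-in message is sent instead.
#' @param program_start Date of the first day of program week 1.
#' @param weight_reduction How multiple weigh-ins in a week are reduced to
#'   one value when computing weekly change: \code{"last"} (default) or
#'   \code{"mean"}.
#' @return An object of class \code{coach_profile}.
#' @export
participant_profile <- function(participant_id, baseline_weight, calorie_goal,
                                activity_goal, intent = "LOSE",
                                rescue_mode = FALSE,
                                program_start = as.Date("2023-01-02"),
                                weight_reduction = "last") {
  stopifnot(is.character(participant_id), nchar(participant_id) > 0)
  if (!is.numeric(baseline_weight) || baseline_weight <= 0) {
    stop("baseline_weight must be > 0")
  }
  if (!is.numeric(calorie_goal) || calorie_goal < 300) {
    stop("calorie_goal must be >= 300 kcal/day")
  }
  if (!is.numeric(activity_goal) || activity_goal < 0) {
    stop("activity_goal must be >= 0 minutes/week")
  }
  intent <- match.arg(intent, INTENTS)
  weight_reduction <- match.arg(weight_reduction, c("last", "mean"))
  structure(list(
    participant_id = participant_id,
    baseline_weight = as.numeric(baseline_weight),
    calorie_goal = as.numeric(calorie_goal),
    activity_goal = as.numeric(activity_goal),
    intent = intent,
    rescue_mode = isTRUE(rescue_mode),
    program_start = as.Date(program_start),
    weight_reduction = weight_reduction
  ), class = "coach_profile")
}

#' Read a participant profile from YAML or JSON
#' @param path Path to a \code{.yaml}/\code{.yml} or \code{.json} file whose
#'   keys are the [participant_profile()] arguments.
#' @return A \code{coach_profile}.
#' @export
read_profile <- function(path) {
  lst <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(participant_profile, lst[intersect(names(lst), names(formals(participant_profile)))])
}

#' Write a participant profile to YAML
#' @param profile A \code{coach_profile}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_profile <- function(profile, path) {
  lst <- unclass(profile)
  lst$program_start <- format(lst$program_start, "%Y-%m-%d")
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Create an empty participant history
#'
#' The history is the per-participant memory consulted by the habituation
#' rules: which weight messages were already sent at each criteria signature,
#' last week's theme and behavioral domain, which milestones have fired, and
#' append-only logs of weekly variables and message audits.
#'
#' @return An object of class \code{coach_history}.
#' @export
new_history <- function() {
  structure(list(
    sent_weight = list(),        # signature -> character vector, send order
    last_theme = NA_character_,
    last_parent_domain = NA_character_,
    milestones_reached = character(),
    rescue_count = 0L,
    weekly_log = list(),
    messages_log = list()
  ), class = "coach_history")
}

#' Serialize / restore a participant history as JSON
#'
#' @param history A \code{coach_history}.
#' @param path Output path.
#' @return \code{path} invisibly (write) or a \code{coach_history} (read).
#' @export
write_history <- function(history, path) {
  jsonlite::write_json(unclass(history), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_history
#' @export
read_history <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = FALSE)
  h <- new_history()
  h$sent_weight <- lapply(lst$sent_weight, function(x) unlist(x, use.names = FALSE))
  h$last_theme <- if (is.null(lst$last_theme)) NA_character_ else lst$last_theme
  h$last_parent_domain <- if (is.null(lst$last_parent_domain)) NA_character_ else lst$last_parent_domain
  h$milestones_reached <- unlist(lst$milestones_reached, use.names = FALSE)
  if (is.null(h$milestones_reached)) h$milestones_reached <- character()
  h$rescue_count <- as.integer(lst$rescue_count %||% 0L)
  h$weekly_log <- lapply(lst$weekly_log, restore_weekly)
  h$messages_log <- lst$messages_log
  h
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# jsonlite turns NA into null and vectors into lists; undo for weekly vars
restore_weekly <- function(lst) {
  num1 <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  chr1 <- function(x) if (is.null(x)) NA_character_ else as.character(x)
  list(
    week_index = as.integer(lst$week_index),
    weight_change = num1(lst$weight_change),
    weight_category = chr1(lst$weight_category),
    cum_pct_change = num1(lst$cum_pct_change),
    days_self_weighed = as.integer(lst$days_self_weighed),
    mvpa_minutes = as.numeric(lst$mvpa_minutes),
    activity_tracking_days = as.integer(lst$activity_tracking_days),
    avg_calorie_intake = num1(lst$avg_calorie_intake),
    days_in_range = as.integer(lst$days_in_range),
    days_above_range = as.integer(lst$days_above_range),
    days_below_range = as.integer(lst$days_below_range),
    monitoring_days = as.integer(lst$monitoring_days),
    app_used = isTRUE(lst$app_used),
    trailing3_net_change = num1(lst$trailing3_net_change),
    trailing3_categories = as.character(unlist(lst$trailing3_categories, use.names = FALSE))
  )
}
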