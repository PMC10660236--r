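#' Synthetic cohort simulation and trial running
#'
#' Generates synthetic daily self-monitoring trajectories so the whole
#' engine can run and be tested without participant data. Daily weight is a
#' linear drift plus IID Gaussian noise (deliberately non-physiological: the
#' simplest process that exercises every weight category and milestone
#' path); weigh-ins, dietary logs and tracker wear are daily Bernoulli
#' events; calorie intake and activity minutes are truncated Gaussians.
#'
#' @name synthetic_cohort
NULL

#' Trajectory parameters for one synthetic participant
#'
#' @param n_weeks Number of program weeks to simulate (>= 1).
#' @param start_weight Starting body weight, lbs.
#' @param weekly_drift Average weight change, lbs/week (negative = losing).
#' @param day_noise_sd Day-to-day weight noise SD, lbs.
#' @param p_weigh,p_log,p_wear Daily Bernoulli probabilities of self-weighing,
#'   logging food, and wearing the activity tracker.
#' @param calorie_mean,calorie_sd Daily logged intake distribution, kcal.
#' @param mvpa_mean,mvpa_sd Activity minutes per worn day.
#' @param p_app_open Probability of opening the app on any given day.
#' @param seed Integer seed.
#' @param program_start Date of the first simulated day.
#' @return A validated parameter list of class \code{coach_traj_params}.
#' @export
trajectory_params <- function(n_weeks = 12L, start_weight = 200,
                              weekly_drift = -0.5, day_noise_sd = 1,
                              p_weigh = 0.8, p_log = 0.7, p_wear = 0.85,
                              calorie_mean = 1700, calorie_sd = 250,
                              mvpa_mean = 25, mvpa_sd = 15,
                              p_app_open = 0.3, seed = 1L,
                              program_start = as.Date("2023-01-02")) {
  probs <- c(p_weigh = p_weigh, p_log = p_log, p_wear = p_wear,
             p_app_open = p_app_open)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (day_noise_sd < 0 || calorie_sd < 0 || mvpa_sd < 0) stop("sds must be >= 0")
  if (n_weeks < 1) stop("n_weeks must be >= 1")
  if (start_weight <= 50) stop("start_weight must exceed 50 lbs")
  structure(list(
    n_weeks = as.integer(n_weeks), start_weight = start_weight,
    weekly_drift = weekly_drift, day_noise_sd = day_noise_sd,
    p_weigh = p_weigh, p_log = p_log, p_wear = p_wear,
    calorie_mean = calorie_mean, calorie_sd = calorie_sd,
    mvpa_mean = mvpa_mean, mvpa_sd = mvpa_sd,
    p_app_open = p_app_open, seed = as.integer(seed),
    program_start = as.Date(program_start)
  ), class = "coach_traj_params")
}

#' Simulate one participant's daily records
#'
#' Day \code{d} (1-based) has latent weight
#' \code{start_weight + weekly_drift * d / 7 + N(0, day_noise_sd)}, observed
#' only on Bernoulli(\code{p_weigh}) days; calories are
#' \code{max(0, N(calorie_mean, calorie_sd))} on Bernoulli(\code{p_log})
#' days; activity minutes \code{max(0, N(mvpa_mean, mvpa_sd))} on
#' Bernoulli(\code{p_wear}) days. Deterministic given \code{params$seed}.
#'
#' @param params A [trajectory_params()].
#' @return A validated daily-records data frame of \code{7 * n_weeks} rows.
#' @export
simulate_participant <- function(params) {
  if (!inherits(params, "coach_traj_params")) params <- do.call(trajectory_params, params)
  n_days <- 7L * params$n_weeks
  with_seed(params$seed, {
    d <- seq_len(n_days)   # 1-based: day 7k has k full weeks of drift
    latent <- params$start_weight + params$weekly_drift * d / 7 +
      stats::rnorm(n_days, 0, params$day_noise_sd)
    weigh <- stats::runif(n_days) < params$p_weigh
    log_day <- stats::runif(n_days) < params$p_log
    wear <- stats::runif(n_days) < params$p_wear
    app <- stats::runif(n_days) < params$p_app_open
    cals <- pmax(0, stats::rnorm(n_days, params$calorie_mean, params$calorie_sd))
    mvpa <- pmax(0, stats::rnorm(n_days, params$mvpa_mean, params$mvpa_sd))
    records <- data.frame(
      date = params$program_start + d - 1L,
      weight_lbs = ifelse(weigh, latent, NA_real_),
      calories_kcal = ifelse(log_day, round(cals), NA_real_),
      mvpa_minutes = ifelse(wear, round(mvpa), NA_real_),
      app_opened = app
    )
    validate_daily_records(records)
  })
}

SCENARIOS <- c("steady_loser", "plateau", "regainer", "underreporter",
               "no_weigh_week", "milestone_cross", "perfect_adherence",
               "rescue")

#' Deterministic named scenario fixtures
#'
#' Each scenario is a (records, profile) pair with a defining property that
#' holds when re-measured through [aggregate_week()]: \code{steady_loser}
#' (consistent loss), \code{plateau} (flat weight), \code{regainer} (a gain
#' week with mixed gains/losses and net gain over the trailing window, net
#' gain since baseline), \code{underreporter} (most logged days below the
#' calorie range), \code{no_weigh_week} (week 3 has zero weigh-ins),
#' \code{milestone_cross} (noise-free −1 lb/week from 200 lbs: the 5%
#' milestone falls in week 10), \code{perfect_adherence} (all adherence
#' probabilities 1), \code{rescue} (profile has rescue mode on).
#'
#' @param name One of the scenario names above.
#' @return List with \code{records}, \code{profile}, \code{n_weeks}.
#' @export
make_scenario <- function(name) {
  if (!name %in% SCENARIOS) {
    stop("unknown scenario '", name, "'; valid names: ",
         paste(SCENARIOS, collapse = ", "))
  }
  start <- as.Date("2023-01-02")
  prof <- function(id, w0 = 200, rescue = FALSE) {
    participant_profile(id, baseline_weight = w0, calorie_goal = 1800,
                        activity_goal = 150, intent = "LOSE",
                        rescue_mode = rescue, program_start = start)
  }
  if (name == "steady_loser") {
    p <- trajectory_params(n_weeks = 12L, start_weight = 200,
                           weekly_drift = -1.2, day_noise_sd = 0.3,
                           p_weigh = 0.95, p_log = 0.9, p_wear = 0.9,
                           calorie_mean = 1650, calorie_sd = 120,
                           mvpa_mean = 30, seed = 101L, program_start = start)
    return(list(records = simulate_participant(p), profile = prof("steady_loser"),
                n_weeks = 12L))
  }
  if (name == "plateau") {
    p <- trajectory_params(n_weeks = 12L, start_weight = 200,
                           weekly_drift = 0, day_noise_sd = 0.25,
                           p_weigh = 0.9, p_log = 0.8, p_wear = 0.8,
                           seed = 102L, program_start = start)
    return(list(records = simulate_participant(p), profile = prof("plateau"),
                n_weeks = 12L))
  }
  if (name == "regainer") {
    # hand-built weekly endpoint weights: week 6 shows a past-week gain,
    # mixed gains/losses with net gain over weeks 2..4, and net gain since
    # baseline (the signature of the trouble-with-trajectory weight message)
    wk_weights <- c(200.0, 200.5, 199.8, 200.9, 200.6, 201.4)
    rows <- lapply(seq_along(wk_weights), function(k) {
      day <- start + 7L * (k - 1L) + 6L  # one weigh-in, last day of week
      data.frame(date = c(day - 1L, day),
                 weight_lbs = c(NA, wk_weights[k]),
                 calories_kcal = c(1700, 1850),
                 mvpa_minutes = c(20, 0),
                 app_opened = c(TRUE, FALSE))
    })
    rec <- validate_daily_records(do.call(rbind, rows))
    return(list(records = rec, profile = prof("regainer"), n_weeks = 6L))
  }
  if (name == "underreporter") {
    # logs most days, but far below the 1500-1800 range on most of them
    days <- seq(start, start + 7L * 8L - 1L, by = "day")
    d <- seq_along(days) - 1L
    cals <- ifelse(d %% 7 == 0, 1650, 1100)  # 1 in-range day, 6 below, weekly
    rec <- validate_daily_records(data.frame(
      date = days,
      weight_lbs = ifelse(d %% 2 == 0, 200 - 0.05 * d / 7, NA),
      calories_kcal = cals,
      mvpa_minutes = 15,
      app_opened = d %% 7 == 3
    ))
    return(list(records = rec, profile = prof("underreporter"), n_weeks = 8L))
  }
  if (name == "no_weigh_week") {
    days <- seq(start, start + 7L * 6L - 1L, by = "day")
    d <- seq_along(days) - 1L
    in_week3 <- d >= 14 & d <= 20
    rec <- validate_daily_records(data.frame(
      date = days,
      weight_lbs = ifelse(in_week3, NA, 199 - 0.3 * d / 7),
      calories_kcal = 1700,
      mvpa_minutes = 25,
      app_opened = TRUE
    ))
    return(list(records = rec, profile = prof("no_weigh_week"), n_weeks = 6L))
  }
  if (name == "milestone_cross") {
    p <- trajectory_params(n_weeks = 14L, start_weight = 200,
                           weekly_drift = -1, day_noise_sd = 0,
                           p_weigh = 1, p_log = 1, p_wear = 1,
                           calorie_mean = 1650, calorie_sd = 0,
                           mvpa_mean = 25, mvpa_sd = 0,
                           p_app_open = 1, seed = 103L, program_start = start)
    return(list(records = simulate_participant(p), profile = prof("milestone_cross"),
                n_weeks = 14L))
  }
  if (name == "perfect_adherence") {
    p <- trajectory_params(n_weeks = 12L, start_weight = 190,
                           weekly_drift = -0.8, day_noise_sd = 0.4,
                           p_weigh = 1, p_log = 1, p_wear = 1,
                           calorie_mean = 1600, calorie_sd = 100,
                           mvpa_mean = 35, p_app_open = 1, seed = 104L,
                           program_start = start)
    return(list(records = simulate_participant(p),
                profile = prof("perfect_adherence", 190), n_weeks = 12L))
  }
  # rescue
  p <- trajectory_params(n_weeks = 8L, seed = 105L, program_start = start)
  list(records = simulate_participant(p),
       profile = prof("rescue", rescue = TRUE), n_weeks = 8L)
}

#' Run the weekly coaching pipeline over a cohort
#'
#' Iterates week by week for each participant, threading the history, and
#' collects rendered messages, the per-stage audit corpus, and a cohort
#' report (theme-transition matrix, domain-transition matrix, milestone
#' events, fallback and last-resort counts). Per-week RNG streams are seeded
#' from \code{hash(global_seed, participant_id, week_index)}, so results are
#' independent of iteration order and fully reproducible.
#'
#' @param cohort List of \code{list(profile =, records =)} entries.
#' @param bank A \code{coach_bank}.
#' @param n_weeks Number of program weeks to run.
#' @param global_seed Integer seed for the whole run.
#' @return A list of class \code{coach_trial} with \code{messages} (data
#'   frame: participant_id, week_index, kind, theme_id, domain, text),
#'   \code{audits} (list of per-participant-week audit records),
#'   \code{histories}, and \code{report}.
#' @export
run_trial <- function(cohort, bank, n_weeks, global_seed = 42L) {
  msg_rows <- list()
  audits <- list()
  histories <- list()
  errors <- list()

  theme_ids <- vapply(bank$themes, function(t) t$id, character(1))
  theme_trans <- matrix(0L, length(theme_ids), length(theme_ids),
                        dimnames = list(theme_ids, theme_ids))
  domain_trans <- matrix(0L, length(DOMAINS), length(DOMAINS),
                         dimnames = list(DOMAINS, DOMAINS))
  milestone_events <- list()
  n_fallback_weight <- 0L
  n_lru_reuse <- 0L
  n_domain_last_resort <- 0L

  for (entry in cohort) {
    profile <- entry$profile
    pid <- profile$participant_id
    history <- new_history()
    prev_theme <- NA_character_
    prev_domain <- NA_character_
    for (k in seq_len(n_weeks)) {
      window <- week_window(profile$program_start, k)
      seed_k <- derive_seed(global_seed, pid, k)
      res <- tryCatch(
        compose_week(entry$records, window, profile, history, bank, seed_k),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        errors[[length(errors) + 1L]] <- list(participant_id = pid,
                                              week_index = k,
                                              message = conditionMessage(res))
        next
      }
      history <- res$history
      msg <- res$message
      audits[[length(audits) + 1L]] <- list(
        participant_id = pid, week_index = k, kind = msg$kind,
        audit = msg$audit
      )
      if (msg$kind == "FULL") {
        th <- msg$behavioral_component$theme_id
        dom <- msg$behavioral_component$domain
        if (!is.na(prev_theme)) theme_trans[prev_theme, th] <- theme_trans[prev_theme, th] + 1L
        if (!is.na(prev_domain)) domain_trans[prev_domain, dom] <- domain_trans[prev_domain, dom] + 1L
        prev_theme <- th
        prev_domain <- dom
        for (ms in msg$weight_component$milestones) {
          milestone_events[[length(milestone_events) + 1L]] <-
            list(participant_id = pid, week_index = k, milestone = ms)
        }
        wa <- msg$audit$stages[[1]]
        if (identical(wa$note, "no-weigh fallback: self-weigh reminder")) {
          n_fallback_weight <- n_fallback_weight + 1L
        }
        if (identical(wa$note, "signature exhausted: least-recently-sent reuse")) {
          n_lru_reuse <- n_lru_reuse + 1L
        }
        pa <- msg$audit$stages[[3]]
        if (identical(pa$note, "last-resort domain repeat permitted")) {
          n_domain_last_resort <- n_domain_last_resort + 1L
        }
        msg_rows[[length(msg_rows) + 1L]] <- data.frame(
          participant_id = pid, week_index = k, kind = "FULL",
          theme_id = th, domain = dom, text = render_message(msg),
          stringsAsFactors = FALSE
        )
      } else {
        msg_rows[[length(msg_rows) + 1L]] <- data.frame(
          participant_id = pid, week_index = k, kind = "RESCUE_CHECKIN",
          theme_id = NA_character_, domain = NA_character_,
          text = render_message(msg), stringsAsFactors = FALSE
        )
      }
    }
    histories[[pid]] <- history
  }

  structure(list(
    messages = do.call(rbind, msg_rows),
    audits = audits,
    histories = histories,
    errors = errors,
    report = list(
      theme_transitions = theme_trans,
      domain_transitions = domain_trans,
      milestone_events = milestone_events,
      n_no_weigh_reminders = n_fallback_weight,
      n_lru_reuse = n_lru_reuse,
      n_domain_last_resort = n_domain_last_resort
    )
  ), class = "coach_trial")
}

#' Write trial outputs to disk
#'
#' Writes \code{messages.csv}, \code{audits.jsonl} (one JSON object per
#' participant-week), and \code{report.json} into \code{dir}.
#'
#' @param trial A \code{coach_trial} from [run_trial()].
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(trial$messages, file.path(dir, "messages.csv"),
                   row.names = FALSE)
  con <- file(file.path(dir, "audits.jsonl"), "w")
  on.exit(close(con))
  for (a in trial$audits) {
    writeLines(jsonlite::toJSON(a, auto_unbox = TRUE, digits = NA,
                                null = "null", na = "null"), con)
  }
  rep <- trial$report
  rep$theme_transitions <- as.data.frame(as.table(rep$theme_transitions))
  rep$domain_transitions <- as.data.frame(as.table(rep$domain_transitions))
  jsonlite::write_json(rep, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(dir)
}
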