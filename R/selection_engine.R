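#' Multi-stage weekly message selection
#'
#' One coaching message per participant-week is assembled in stages:
#' weight feedback (criteria-matched, habituation-avoiding, with first-time
#' milestone congratulations and a self-weigh reminder on zero-weigh weeks),
#' then behavioral feedback via theme (probabilistic by progress tier, never
#' the same theme twice in a row), parent subcomponent (criteria-matched,
#' never the same behavioral domain two weeks in a row), and optionally a
#' domain-matched targeted-feedback sentence. Every stage records its
#' candidates, exclusions, random draw, and choice in a structured audit, and
#' the whole pipeline is a pure function of (inputs, seed).
#'
#' @name selection_engine
NULL

#' Derive the progress tier driving theme probabilities
#'
#' \code{DECLINING} when the past week was a gain or the trailing 3-week net
#' change exceeds +0.4 lbs; \code{IMPROVING} when the past week was a loss
#' and the trailing net change is below −0.4 lbs; otherwise \code{FLAT}
#' (including weeks with unknown weight data).
#'
#' @param state A [selection_state()].
#' @return One of \code{"DECLINING"}, \code{"FLAT"}, \code{"IMPROVING"}.
#' @export
derive_progress_tier <- function(state) {
  net <- state$trailing3_net_change
  if (identical(state$weight_category, "GAIN") || (!is.na(net) && net > 0.4)) {
    return("DECLINING")
  }
  if (identical(state$weight_category, "LOSS") && !is.na(net) && net < -0.4) {
    return("IMPROVING")
  }
  "FLAT"
}

# (weight_category, trailing3_summary, cum_band, intent) key for habituation
weight_signature <- function(state) {
  paste(state$weight_category, state$trailing3_summary, state$cum_band,
        state$intent, sep = "|")
}

audit_stage <- function(stage, candidates, excluded, draw, chosen, note = NULL) {
  list(stage = stage, candidates = candidates, excluded = excluded,
       draw = draw, chosen = chosen, note = note)
}

#' Select the weight-feedback component
#'
#' Zero weigh-in weeks get the bank's self-weigh reminder instead of weight
#' feedback. Otherwise the candidates are the weight messages whose criteria
#' match the state; ids already sent at this criteria signature are excluded
#' so repeat encounters with the same situation get a different message each
#' time; when the signature's bank is exhausted the least-recently-sent id is
#' reused (deterministically). First-time 5% / 10% milestone texts are
#' prepended. The caller (not this function) writes fired milestones and the
#' sent id back into the history; both are returned.
#'
#' @param state A [selection_state()].
#' @param history A \code{coach_history}.
#' @param bank A \code{coach_bank}.
#' @param rng A [coach_rng()] stream.
#' @return List with \code{text}, \code{message_id} (\code{NA} for the
#'   reminder), \code{milestones}, \code{signature}, and \code{audit}.
#' @export
select_weight_feedback <- function(state, history, bank, rng) {
  milestones <- if (is.na(state$cum_pct_change)) character() else
    detect_milestones(state$cum_pct_change, history)
  pre <- paste(unlist(bank$milestone_texts[milestones]), collapse = " ")

  if (state$days_self_weighed == 0L) {
    aud <- audit_stage("weight", character(), list(), NA_real_, NA_character_,
                       note = "no-weigh fallback: self-weigh reminder")
    return(list(text = bank$no_weigh_reminder, message_id = NA_character_,
                milestones = milestones, signature = NA_character_, audit = aud))
  }

  sig <- weight_signature(state)
  cand <- Filter(function(m) match_criteria(m$criteria, state), bank$weight_messages)
  if (!length(cand)) {
    stop("no weight message matches signature ", sig,
         " (bank coverage violation)")
  }
  # most-specific criteria set wins: a message written for this exact
  # situation outranks a generic fallback for the same category
  nc <- vapply(cand, function(m) length(m$criteria), integer(1))
  cand <- cand[nc == max(nc)]
  cand_ids <- vapply(cand, function(m) m$id, character(1))
  sent <- history$sent_weight[[sig]] %||% character()
  fresh <- setdiff(cand_ids, sent)
  excluded <- lapply(intersect(cand_ids, sent), function(id) {
    list(id = id, reason = "already-sent")
  })

  if (length(fresh)) {
    u <- rng$unif(1)
    chosen <- fresh[sample_weighted(rep(1, length(fresh)), u)]
    note <- NULL
  } else {
    # exhausted: reuse the id whose last send is oldest (LRU), deterministic
    last_pos <- vapply(cand_ids, function(id) max(which(sent == id)), numeric(1))
    chosen <- cand_ids[which.min(last_pos)]
    u <- NA_real_
    note <- "signature exhausted: least-recently-sent reuse"
  }
  msg <- cand[[which(cand_ids == chosen)]]
  text <- if (nzchar(pre)) paste(pre, msg$text) else msg$text
  aud <- audit_stage("weight", cand_ids, excluded, u, chosen, note = note)
  list(text = text, message_id = chosen, milestones = milestones,
       signature = sig, audit = aud)
}

#' Select the behavioral-feedback theme
#'
#' Each theme carries a selection weight per progress tier; last week's theme
#' is zeroed out, the remaining weights renormalized, and a theme drawn
#' categorically.
#'
#' @inheritParams select_weight_feedback
#' @param tier A progress tier from [derive_progress_tier()].
#' @return List with \code{theme_id} and \code{audit}.
#' @export
select_theme <- function(tier, history, bank, rng) {
  ids <- vapply(bank$themes, function(t) t$id, character(1))
  w <- vapply(bank$themes, function(t) as.numeric(t$weights[[tier]] %||% 0), numeric(1))
  excluded <- list()
  if (!is.na(history$last_theme)) {
    drop <- which(ids == history$last_theme & w > 0)
    if (length(drop)) {
      excluded <- list(list(id = history$last_theme, reason = "consecutive-theme"))
    }
    w[ids == history$last_theme] <- 0
  }
  if (sum(w) <= 0) stop("all theme weights zero for tier ", tier)
  u <- rng$unif(1)
  chosen <- ids[sample_weighted(w, u)]
  list(theme_id = chosen,
       audit = audit_stage("theme", ids[w > 0], excluded, u, chosen,
                           note = paste0("tier=", tier)))
}

#' Select the parent behavioral subcomponent
#'
#' Candidates are the chosen theme's parent messages whose criteria match the
#' state, minus those in last week's behavioral domain. If that exclusion
#' empties the set, the theme's fallback parents outside the excluded domain
#' are used; if even those are empty the domain repeat is permitted and
#' flagged in the audit. Ties break uniformly at random.
#'
#' @inheritParams select_weight_feedback
#' @param theme_id Chosen theme id.
#' @return List with \code{parent} (the bank entry) and \code{audit}.
#' @export
select_parent <- function(state, theme_id, history, bank, rng) {
  parents <- Filter(function(m) m$theme_id == theme_id, bank$parent_messages)
  match <- Filter(function(m) match_criteria(m$criteria, state), parents)
  ids <- vapply(match, function(m) m$id, character(1))
  doms <- vapply(match, function(m) m$domain, character(1))
  excluded <- Filter(function(m) !match_criteria(m$criteria, state), parents)
  excluded <- lapply(excluded, function(m) list(id = m$id, reason = "criteria-fail"))

  note <- NULL
  keep <- rep(TRUE, length(match))
  if (!is.na(history$last_parent_domain)) {
    keep <- doms != history$last_parent_domain
    excluded <- c(excluded, lapply(ids[!keep], function(id) {
      list(id = id, reason = "domain-repeat")
    }))
  }
  pool <- match[keep]
  if (!length(pool)) {
    fb <- Filter(function(m) isTRUE(m$is_fallback) &&
                   m$domain != history$last_parent_domain, parents)
    if (length(fb)) {
      pool <- fb
      note <- "domain exclusion emptied candidates: fallback pool used"
    } else {
      pool <- match
      note <- "last-resort domain repeat permitted"
    }
  }
  if (!length(pool)) {
    stop("no parent message eligible for theme ", theme_id,
         " (bank coverage violation); state: ",
         paste(names(state), unlist(lapply(state, format)), sep = "=", collapse = " "))
  }
  u <- rng$unif(1)
  chosen <- pool[[sample_weighted(rep(1, length(pool)), u)]]
  list(parent = chosen,
       audit = audit_stage("parent", vapply(pool, function(m) m$id, character(1)),
                           excluded, u, chosen$id, note = note))
}

#' Select the targeted-feedback subcomponent
#'
#' A parent whose \code{targeted_slot} is \code{NONE} gets no targeted
#' feedback; otherwise one message is drawn uniformly from the targeted bank
#' entries matching the parent's behavioral domain and the slot's type
#' (reinforcement or strategy suggestion).
#'
#' @inheritParams select_weight_feedback
#' @param parent A parent message entry from [select_parent()].
#' @return List with \code{targeted} (bank entry or \code{NULL}) and
#'   \code{audit}.
#' @export
select_targeted <- function(parent, bank, rng) {
  if (parent$targeted_slot == "NONE") {
    return(list(targeted = NULL,
                audit = audit_stage("targeted", character(), list(), NA_real_,
                                    NA_character_, note = "slot NONE")))
  }
  cand <- Filter(function(m) m$domain == parent$domain &&
                   m$type == parent$targeted_slot, bank$targeted_messages)
  if (!length(cand)) {
    stop("no targeted message for (", parent$domain, ", ",
         parent$targeted_slot, ")")
  }
  u <- rng$unif(1)
  chosen <- cand[[sample_weighted(rep(1, length(cand)), u)]]
  list(targeted = chosen,
       audit = audit_stage("targeted", vapply(cand, function(m) m$id, character(1)),
                           list(), u, chosen$id))
}

#' Compose one weekly coaching message
#'
#' Runs the full pipeline for one participant-week: rescue-mode gate, weekly
#' aggregation, weight feedback, progress tier, theme, parent, targeted
#' feedback, and template substitution — returning the assembled message
#' (with complete audit) and the updated history. With
#' \code{profile$rescue_mode} the coaching content is replaced by a neutral
#' check-in drawn in rotation from the bank's check-in texts; no aggregated
#' data are exposed. The result is a pure function of (inputs, seed).
#'
#' @param records Validated daily records for the participant.
#' @param window A [week_window()].
#' @param profile A [participant_profile()].
#' @param history A \code{coach_history}.
#' @param bank A \code{coach_bank}.
#' @param seed Integer seed for this participant-week (see [derive_seed()]).
#' @return List with \code{message} (class \code{coach_message}) and
#'   \code{history} (updated).
#' @export
compose_week <- function(records, window, profile, history, bank, seed) {
  rng <- coach_rng(seed)
  k <- window$week_index

  if (isTRUE(profile$rescue_mode)) {
    texts <- bank$rescue_checkin_texts
    idx <- (history$rescue_count %% length(texts)) + 1L
    msg <- structure(list(
      week_index = k, kind = "RESCUE_CHECKIN",
      summary_box = NULL, weight_component = NULL, behavioral_component = NULL,
      checkin_text = texts[[idx]],
      audit = list(seed = seed, stages = list(
        audit_stage("rescue", as.character(seq_along(texts)), list(), NA_real_,
                    as.character(idx), note = "rescue mode: coaching disabled")
      ))
    ), class = "coach_message")
    history$rescue_count <- history$rescue_count + 1L
    history$messages_log <- c(history$messages_log,
                              list(list(week_index = k, kind = "RESCUE_CHECKIN")))
    return(list(message = msg, history = history))
  }

  vars <- aggregate_week(records, window, profile, history$weekly_log)
  state <- selection_state(vars, profile, bank$cum_pct_bands)

  wf <- select_weight_feedback(state, history, bank, rng)
  tier <- derive_progress_tier(state)
  th <- select_theme(tier, history, bank, rng)
  pa <- select_parent(state, th$theme_id, history, bank, rng)
  tg <- select_targeted(pa$parent, bank, rng)

  behav_text <- substitute_placeholders(pa$parent$text, vars, profile, pa$parent$id)
  if (!is.null(tg$targeted)) {
    behav_text <- paste(behav_text,
                        substitute_placeholders(tg$targeted$text, vars, profile,
                                                tg$targeted$id))
  }
  weight_text <- if (!is.na(wf$message_id) || nzchar(wf$text)) {
    substitute_placeholders(wf$text, vars, profile,
                            wf$message_id %||% "no_weigh_reminder")
  } else wf$text

  msg <- structure(list(
    week_index = k, kind = "FULL",
    vars = vars,
    profile_snapshot = list(calorie_goal = profile$calorie_goal,
                            activity_goal = profile$activity_goal),
    summary_box = render_summary_box(vars, profile),
    weight_component = list(text = weight_text, message_id = wf$message_id,
                            milestones = wf$milestones),
    behavioral_component = list(text = behav_text, theme_id = th$theme_id,
                                parent_id = pa$parent$id,
                                domain = pa$parent$domain,
                                targeted_id = if (is.null(tg$targeted)) NA_character_ else tg$targeted$id),
    audit = list(seed = seed, tier = tier,
                 stages = list(wf$audit, th$audit, pa$audit, tg$audit))
  ), class = "coach_message")

  # thread history: milestones, habituation memory, logs
  history$milestones_reached <- union(history$milestones_reached, wf$milestones)
  if (!is.na(wf$signature) && !is.na(wf$message_id)) {
    history$sent_weight[[wf$signature]] <-
      c(history$sent_weight[[wf$signature]] %||% character(), wf$message_id)
  }
  history$last_theme <- th$theme_id
  history$last_parent_domain <- pa$parent$domain
  history$weekly_log <- c(history$weekly_log, list(vars))
  history$messages_log <- c(history$messages_log, list(list(
    week_index = k, kind = "FULL", weight_id = wf$message_id,
    theme_id = th$theme_id, parent_id = pa$parent$id,
    domain = pa$parent$domain, milestones = wf$milestones
  )))
  list(message = msg, history = history)
}
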