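#' Message banks and the criteria language
#'
#' Message content is configuration, not code: every message the engine can
#' send lives in a YAML (or JSON) bank file. Each weight-feedback and parent
#' message carries a list of criteria — conjunctions of simple comparisons
#' over the weekly tailoring variables and profile fields — and the engine
#' selects among the messages whose criteria the participant's current state
#' satisfies. Disjunction is expressed by listing several bank entries, which
#' keeps matching auditable and coverage exhaustively checkable.
#'
#' Criterion operators: \code{LT, LE, EQ, GE, GT, IN, BETWEEN} (inclusive
#' pair), \code{PRESENT, ABSENT}. A comparison against an absent value (other
#' than \code{PRESENT}/\code{ABSENT}) evaluates to \code{FALSE}, so sparse
#' data weeks fall through to low-data fallbacks instead of erroring.
#'
#' @name message_bank
NULL

CRITERIA_OPS <- c("LT", "LE", "EQ", "GE", "GT", "IN", "BETWEEN", "PRESENT", "ABSENT")

# fields a criterion may reference: weekly variables, derived summaries,
# and profile fields
STATE_FIELDS <- c(
  "week_index", "weight_change", "weight_category", "cum_pct_change",
  "days_self_weighed", "mvpa_minutes", "activity_tracking_days",
  "avg_calorie_intake", "days_in_range", "days_above_range",
  "days_below_range", "monitoring_days", "app_used",
  "trailing3_net_change", "trailing3_summary", "cum_band",
  "intent", "calorie_goal", "activity_goal"
)

DEFAULT_CUM_BANDS <- list(
  list(label = "LE_NEG10", upper = -10),
  list(label = "NEG10_NEG5", upper = -5),
  list(label = "NEG5_NEG2", upper = -2),
  list(label = "NEG2_0", upper = 0),
  list(label = "GT_0", upper = Inf)
)

#' Band label for a cumulative percent change
#'
#' Default bands (upper bounds inclusive): \code{<= -10} → \code{LE_NEG10},
#' \code{(-10, -5]} → \code{NEG10_NEG5}, \code{(-5, -2]} → \code{NEG5_NEG2},
#' \code{(-2, 0]} → \code{NEG2_0}, \code{> 0} → \code{GT_0}; \code{NA} →
#' \code{"NONE"}. A bank may override the bands via its
#' \code{cum_pct_bands} entry.
#'
#' @param cum_pct_change Percent change (negative = loss) or \code{NA}.
#' @param bands Band definition list (label, upper).
#' @return Band label string.
#' @export
cum_band <- function(cum_pct_change, bands = DEFAULT_CUM_BANDS) {
  if (is.na(cum_pct_change)) return("NONE")
  for (b in bands) if (cum_pct_change <= b$upper) return(b$label)
  bands[[length(bands)]]$label
}

#' Summarize the trailing 3-week weight trend
#'
#' Collapses the net change and weekly categories over the 3 weeks prior to
#' last week into one label: \code{GAIN} / \code{MIXED_GAIN} (net gain
#' > 0.4 lbs, without / with a loss week among them), \code{LOSS} /
#' \code{MIXED_LOSS} (net loss < −0.4 lbs), \code{FLAT} (net within ±0.4),
#' or \code{NONE} when no trailing data exist.
#'
#' @param net Net lbs change over the trailing window, or \code{NA}.
#' @param categories Character vector of the trailing weekly categories.
#' @return Summary label.
#' @export
trailing3_summary <- function(net, categories = character()) {
  if (is.na(net)) return("NONE")
  if (net > 0.4) {
    return(if ("LOSS" %in% categories) "MIXED_GAIN" else "GAIN")
  }
  if (net < -0.4) {
    return(if ("GAIN" %in% categories) "MIXED_LOSS" else "LOSS")
  }
  "FLAT"
}

#' Build the flat matching state for one participant-week
#'
#' Merges the weekly variables with the profile fields criteria may
#' reference and adds the derived \code{cum_band} and
#' \code{trailing3_summary} labels.
#'
#' @param vars Weekly variables from [aggregate_week()].
#' @param profile A [participant_profile()].
#' @param bands Cumulative-percent band definitions.
#' @return Named list keyed by the criteria-visible field names.
#' @export
selection_state <- function(vars, profile, bands = DEFAULT_CUM_BANDS) {
  st <- vars[setdiff(names(vars), "trailing3_categories")]
  st$trailing3_summary <- trailing3_summary(vars$trailing3_net_change,
                                            vars$trailing3_categories)
  st$cum_band <- cum_band(vars$cum_pct_change, bands)
  st$intent <- profile$intent
  st$calorie_goal <- profile$calorie_goal
  st$activity_goal <- profile$activity_goal
  st
}

match_one <- function(cr, state) {
  val <- state[[cr$variable]]
  if (cr$op == "PRESENT") return(!is.null(val) && length(val) == 1L && !is.na(val))
  if (cr$op == "ABSENT") return(is.null(val) || length(val) != 1L || is.na(val))
  if (is.null(val) || length(val) != 1L || is.na(val)) return(FALSE)
  switch(cr$op,
    LT = val < cr$value,
    LE = val <= cr$value,
    EQ = val == cr$value,
    GE = val >= cr$value,
    GT = val > cr$value,
    IN = val %in% unlist(cr$value),
    BETWEEN = {
      v <- unlist(cr$value)
      val >= v[1] && val <= v[2]
    },
    stop("unknown criterion op: ", cr$op)
  )
}

#' Evaluate a conjunction of criteria against a state
#'
#' @param criteria List of criteria, each
#'   \code{list(variable =, op =, value =)}; the empty list matches any state.
#' @param state A [selection_state()].
#' @return \code{TRUE} iff every criterion holds.
#' @export
match_criteria <- function(criteria, state) {
  for (cr in criteria) if (!isTRUE(match_one(cr, state))) return(FALSE)
  TRUE
}

# vectorized evaluation over a grid data frame (used by check_coverage);
# semantics identical to match_criteria row by row
match_criteria_grid <- function(criteria, grid) {
  ok <- rep(TRUE, nrow(grid))
  for (cr in criteria) {
    val <- grid[[cr$variable]]
    hit <- switch(cr$op,
      PRESENT = !is.na(val),
      ABSENT = is.na(val),
      LT = !is.na(val) & val < cr$value,
      LE = !is.na(val) & val <= cr$value,
      EQ = !is.na(val) & val == cr$value,
      GE = !is.na(val) & val >= cr$value,
      GT = !is.na(val) & val > cr$value,
      IN = !is.na(val) & val %in% unlist(cr$value),
      BETWEEN = {
        v <- unlist(cr$value)
        !is.na(val) & val >= v[1] & val <= v[2]
      },
      stop("unknown criterion op: ", cr$op)
    )
    ok <- ok & hit
  }
  ok
}

validate_criteria <- function(criteria, where) {
  for (cr in criteria) {
    if (is.null(cr$variable) || !cr$variable %in% STATE_FIELDS) {
      stop(where, ": unknown criterion variable '", cr$variable %||% "<missing>", "'")
    }
    if (is.null(cr$op) || !cr$op %in% CRITERIA_OPS) {
      stop(where, ": unknown criterion op '", cr$op %||% "<missing>", "'")
    }
    if (cr$op == "BETWEEN") {
      v <- unlist(cr$value)
      if (length(v) != 2L || v[1] > v[2]) {
        stop(where, ": BETWEEN value must be an ordered pair")
      }
    } else if (!cr$op %in% c("PRESENT", "ABSENT") && is.null(cr$value)) {
      stop(where, ": criterion op ", cr$op, " requires a value")
    }
  }
  criteria
}

canonical_criteria <- function(criteria) {
  if (!length(criteria)) return("<always>")
  parts <- vapply(criteria, function(cr) {
    paste(cr$variable, cr$op, paste(unlist(cr$value), collapse = ","))
  }, character(1))
  paste(sort(parts), collapse = ";")
}

#' Load and validate a message bank
#'
#' Reads a YAML or JSON bank file and enforces every structural invariant the
#' selection rules rely on:
#' \itemize{
#'   \item unique ids within each collection; referenced theme ids exist;
#'   \item at least 2 weight messages per distinct criteria set, and at
#'     least 2 matching weight messages for every reachable criteria
#'     signature, so "a different message each time" is honorable;
#'   \item for every progress tier, at least 2 themes with positive weight,
#'     so the no-consecutive-theme rule is always satisfiable;
#'   \item each parent message addresses exactly one behavioral domain; every
#'     theme has at least one always-matching fallback parent;
#'   \item at least one targeted message per (domain, type) pair;
#'   \item both milestone texts, a no-weigh reminder, and at least one
#'     rescue check-in text (check-ins must not contain digits, since they
#'     may never reference progress).
#' }
#'
#' @param path Path to the bank file; the package default bank is at
#'   \code{system.file("extdata", "default_bank.yaml", package = "weeklycoach")}.
#' @return An object of class \code{coach_bank}.
#' @export
load_bank <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  validate_bank(raw, path)
}

#' @rdname load_bank
#' @param raw A bank structure already parsed from YAML/JSON.
#' @param path Label used in error messages.
#' @export
validate_bank <- function(raw, path = "<bank>") {
  fail <- function(...) stop(path, ": ", ..., call. = FALSE)
  if (is.null(raw$bank_schema) || raw$bank_schema != 1) {
    fail("bank_schema must be 1")
  }
  for (sec in c("weight_messages", "themes", "parent_messages",
                "targeted_messages", "milestone_texts", "no_weigh_reminder",
                "rescue_checkin_texts")) {
    if (is.null(raw[[sec]])) fail("missing section '", sec, "'")
  }

  # weight messages
  wm_ids <- vapply(raw$weight_messages, function(m) m$id %||% "", character(1))
  if (anyDuplicated(wm_ids)) fail("duplicate weight message id: ", wm_ids[duplicated(wm_ids)][1])
  for (m in raw$weight_messages) {
    m$criteria <- m$criteria %||% list()
    validate_criteria(m$criteria, paste0("weight_messages/", m$id))
    if (is.null(m$text)) fail("weight_messages/", m$id, ": missing text")
  }
  sig <- vapply(raw$weight_messages, function(m) canonical_criteria(m$criteria %||% list()), character(1))
  per_sig <- table(sig)
  if (any(per_sig < 2)) {
    fail("weight message criteria set '", names(per_sig)[per_sig < 2][1],
         "' has fewer than 2 messages (habituation rule unsatisfiable)")
  }

  # themes
  th_ids <- vapply(raw$themes, function(t) t$id %||% "", character(1))
  if (anyDuplicated(th_ids)) fail("duplicate theme id: ", th_ids[duplicated(th_ids)][1])
  for (tier in TIERS) {
    w <- vapply(raw$themes, function(t) as.numeric(t$weights[[tier]] %||% 0), numeric(1))
    if (any(w < 0)) fail("theme weights must be non-negative (tier ", tier, ")")
    if (sum(w > 0) < 2) {
      fail("tier ", tier, ": fewer than 2 themes with positive weight ",
           "(no-consecutive-repeat unsatisfiable)")
    }
  }

  # parent messages
  pm_ids <- vapply(raw$parent_messages, function(m) m$id %||% "", character(1))
  if (anyDuplicated(pm_ids)) fail("duplicate parent message id: ", pm_ids[duplicated(pm_ids)][1])
  for (m in raw$parent_messages) {
    where <- paste0("parent_messages/", m$id)
    if (is.null(m$theme_id) || !m$theme_id %in% th_ids) {
      fail(where, ": dangling theme_id '", m$theme_id %||% "<missing>", "'")
    }
    if (is.null(m$domain) || length(m$domain) != 1L || !m$domain %in% DOMAINS) {
      fail(where, ": domain must be exactly one of ", paste(DOMAINS, collapse = ", "))
    }
    slot <- m$targeted_slot %||% "NONE"
    if (!slot %in% c("NONE", TARGETED_TYPES)) fail(where, ": bad targeted_slot '", slot, "'")
    validate_criteria(m$criteria %||% list(), where)
    if (is.null(m$text)) fail(where, ": missing text")
  }
  for (tid in th_ids) {
    fb <- Filter(function(m) m$theme_id == tid && isTRUE(m$is_fallback), raw$parent_messages)
    if (!length(fb)) fail("theme '", tid, "' has no fallback parent message")
  }

  # targeted messages
  tg_ids <- vapply(raw$targeted_messages, function(m) m$id %||% "", character(1))
  if (anyDuplicated(tg_ids)) fail("duplicate targeted message id: ", tg_ids[duplicated(tg_ids)][1])
  for (m in raw$targeted_messages) {
    where <- paste0("targeted_messages/", m$id)
    if (is.null(m$domain) || !m$domain %in% DOMAINS) fail(where, ": bad domain")
    if (is.null(m$type) || !m$type %in% TARGETED_TYPES) fail(where, ": bad type")
    if (is.null(m$text)) fail(where, ": missing text")
  }
  have <- paste(vapply(raw$targeted_messages, function(m) m$domain, character(1)),
                vapply(raw$targeted_messages, function(m) m$type, character(1)))
  for (dom in DOMAINS) for (ty in TARGETED_TYPES) {
    if (!paste(dom, ty) %in% have) {
      fail("no targeted message for (", dom, ", ", ty, ")")
    }
  }

  # fixed texts
  for (ms in MILESTONES) {
    if (is.null(raw$milestone_texts[[ms]])) fail("missing milestone text ", ms)
  }
  if (!length(raw$rescue_checkin_texts)) fail("rescue_checkin_texts is empty")
  for (tx in raw$rescue_checkin_texts) {
    if (grepl("[0-9]", tx)) fail("rescue check-in text contains a numeral")
  }

  bands <- if (is.null(raw$cum_pct_bands)) DEFAULT_CUM_BANDS else {
    lapply(raw$cum_pct_bands, function(b) {
      list(label = b$label, upper = if (is.character(b$upper) || is.null(b$upper)) Inf else as.numeric(b$upper))
    })
  }

  bank <- structure(list(
    weight_messages = lapply(raw$weight_messages, function(m) {
      m$criteria <- m$criteria %||% list(); m
    }),
    themes = raw$themes,
    parent_messages = lapply(raw$parent_messages, function(m) {
      m$criteria <- m$criteria %||% list()
      m$targeted_slot <- m$targeted_slot %||% "NONE"
      m$is_fallback <- isTRUE(m$is_fallback)
      m
    }),
    targeted_messages = raw$targeted_messages,
    milestone_texts = raw$milestone_texts,
    no_weigh_reminder = raw$no_weigh_reminder,
    rescue_checkin_texts = unlist(raw$rescue_checkin_texts),
    cum_pct_bands = bands
  ), class = "coach_bank")

  # every reachable weight signature must have >= 2 matching weight messages
  # at the highest matching specificity (selection keeps only those)
  wgrid <- weight_signature_grid(bank)
  for (i in seq_len(nrow(wgrid))) {
    st <- as.list(wgrid[i, ])
    hits <- Filter(function(m) match_criteria(m$criteria, st), bank$weight_messages)
    n <- if (length(hits)) {
      ncs <- vapply(hits, function(m) length(m$criteria), integer(1))
      sum(ncs == max(ncs))
    } else 0L
    if (n < 2) {
      fail("weight signature (", paste(unlist(st), collapse = ", "),
           ") matches only ", n, " weight message(s)")
    }
  }
  bank
}

# all reachable (weight_category, trailing3_summary, cum_band, intent) cells;
# UNKNOWN category only occurs with days_self_weighed > 0 (else the reminder
# replaces weight feedback), and cum_band NONE iff no weigh-in this week,
# which forces category UNKNOWN
weight_signature_grid <- function(bank) {
  labels <- vapply(bank$cum_pct_bands, function(b) b$label, character(1))
  g <- expand.grid(
    weight_category = WEIGHT_CATEGORIES,
    trailing3_summary = c("GAIN", "MIXED_GAIN", "LOSS", "MIXED_LOSS", "FLAT", "NONE"),
    cum_band = labels,
    intent = INTENTS,
    stringsAsFactors = FALSE
  )
  g
}

#' Default state grid for coverage checking
#'
#' A discretized grid over the fields parent-message criteria may reference:
#' each count at 0 / 1 / 4 / 7, weight category at all four values (with a
#' representative change), cumulative percent change at the band boundaries
#' and absent, calorie-day splits spanning within / above / below patterns,
#' and each optional field present and absent. Calorie-range day counts are
#' expressed relative to a 1800 kcal goal profile.
#'
#' @return A data frame, one row per grid state, columns = criteria fields.
#' @export
coverage_state_grid <- function() {
  cal_patterns <- list(
    c(0L, 0L, 0L), c(1L, 0L, 0L), c(4L, 2L, 1L), c(7L, 0L, 0L),
    c(0L, 4L, 0L), c(0L, 0L, 4L), c(2L, 2L, 3L)
  )
  base <- expand.grid(
    weight_change = c(-1, 0, 1, NA),
    cum_pct_change = c(-12, -7, -3.5, -1, 2, NA),
    days_self_weighed = c(0L, 1L, 4L, 7L),
    mvpa_minutes = c(0, 30, 150),
    activity_tracking_days = c(0L, 1L, 4L, 7L),
    cal_pattern = seq_along(cal_patterns),
    app_used = c(TRUE, FALSE),
    trailing3_net_change = c(-2, 0, 2, NA),
    intent = INTENTS,
    stringsAsFactors = FALSE
  )
  base$weight_category <- vapply(base$weight_change, categorize_weight_change, character(1))
  base$days_in_range <- vapply(cal_patterns, `[`, integer(1), 1)[base$cal_pattern]
  base$days_above_range <- vapply(cal_patterns, `[`, integer(1), 2)[base$cal_pattern]
  base$days_below_range <- vapply(cal_patterns, `[`, integer(1), 3)[base$cal_pattern]
  base$monitoring_days <- base$days_in_range + base$days_above_range
  logged <- base$days_in_range + base$days_above_range + base$days_below_range
  base$avg_calorie_intake <- ifelse(logged > 0, 1600, NA_real_)
  base$cum_band <- vapply(base$cum_pct_change, cum_band, character(1))
  base$trailing3_summary <- mapply(function(net, wc) {
    trailing3_summary(net, if (identical(wc, "LOSS")) "LOSS" else "GAIN")
  }, base$trailing3_net_change, base$weight_category)
  base$week_index <- 6L
  base$calorie_goal <- 1800
  base$activity_goal <- 150
  base$cal_pattern <- NULL
  base
}

#' Check fallback coverage of a bank over a state grid
#'
#' For every theme and every grid state there must be at least one parent
#' message whose criteria the state satisfies; the shipped default bank must
#' pass this over the full [coverage_state_grid()]. Also reports messages no
#' grid state can reach.
#'
#' @param bank A \code{coach_bank}.
#' @param state_grid Data frame of states (default [coverage_state_grid()]).
#' @return A list with \code{n_states}, \code{uncovered} (data frame of
#'   theme_id + state row index), and \code{unreachable} (parent message ids
#'   matched by no grid state).
#' @export
check_coverage <- function(bank, state_grid = coverage_state_grid()) {
  th_ids <- vapply(bank$themes, function(t) t$id, character(1))
  match_mat <- vapply(bank$parent_messages, function(m) {
    match_criteria_grid(m$criteria, state_grid)
  }, logical(nrow(state_grid)))
  if (is.null(dim(match_mat))) match_mat <- matrix(match_mat, nrow = nrow(state_grid))
  pm_theme <- vapply(bank$parent_messages, function(m) m$theme_id, character(1))
  pm_ids <- vapply(bank$parent_messages, function(m) m$id, character(1))

  uncovered <- list()
  for (tid in th_ids) {
    cols <- which(pm_theme == tid)
    covered <- if (length(cols) == 1L) match_mat[, cols] else rowSums(match_mat[, cols, drop = FALSE]) > 0
    bad <- which(!covered)
    if (length(bad)) {
      uncovered[[tid]] <- data.frame(theme_id = tid, state_row = bad,
                                     stringsAsFactors = FALSE)
    }
  }
  uncovered <- if (length(uncovered)) do.call(rbind, uncovered) else
    data.frame(theme_id = character(), state_row = integer())
  rownames(uncovered) <- NULL
  unreachable <- pm_ids[colSums(match_mat) == 0]
  list(n_states = nrow(state_grid), uncovered = uncovered,
       unreachable = unreachable)
}

#' Path to the bundled default message bank
#' @return File path string.
#' @export
default_bank_path <- function() {
  system.file("extdata", "default_bank.yaml", package = "weeklycoach")
}
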