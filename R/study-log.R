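#' Event constructors for the study log
#'
#' A study log records four event types per participant, mirroring the
#' daily app cycle: an evening `set` event (behaviors chosen for the next
#' day), the next evening's `review` event (which selected behaviors were
#' performed, plus any ad-hoc extras), a daily `mood` observation (nine
#' 0-100 visual-analog items), and a daily `weight` observation (kg,
#' recorded on waking).
#'
#' @param user_id Character participant id.
#' @param timestamp POSIXct or ISO-8601 string (UTC).
#' @param selected Character vector of chosen arm ids (non-empty, unique).
#' @param performed Named logical vector over the selected set.
#' @param extras Character vector of additionally performed arm ids,
#'   disjoint from `selected`.
#' @param items Numeric vector of exactly nine values in \[0, 100\].
#' @param weight_kg Positive body weight in kilograms.
#' @return A list with a `type` field, suitable for [study_log()].
#' @name study_events
NULL

#' @rdname study_events
#' @export
set_event <- function(user_id, timestamp, selected) {
  if (length(selected) == 0L) stop("set event needs a non-empty selection")
  if (anyDuplicated(selected)) stop("duplicate arm_id in selection")
  list(type = "set", user_id = user_id, timestamp = as_ts_chr(timestamp),
       selected = as.character(selected))
}

#' @rdname study_events
#' @export
review_event <- function(user_id, timestamp, performed, extras = character()) {
  stopifnot(is.logical(performed))
  if (length(performed) > 0L && is.null(names(performed)))
    stop("performed must be a named logical vector")
  if (length(intersect(names(performed), extras)) > 0L)
    stop("extras must be disjoint from the selected set")
  list(type = "review", user_id = user_id, timestamp = as_ts_chr(timestamp),
       performed = performed, extras = as.character(extras))
}

#' @rdname study_events
#' @export
mood_observation <- function(user_id, timestamp, items) {
  if (length(items) != 9L)
    stop("mood observation needs exactly 9 items, got ", length(items))
  if (any(!is.finite(items)) || any(items < 0 | items > 100))
    stop("mood items must lie in [0, 100]")
  list(type = "mood", user_id = user_id, timestamp = as_ts_chr(timestamp),
       items = as.numeric(items))
}

#' @rdname study_events
#' @export
weight_observation <- function(user_id, timestamp, weight_kg) {
  if (!is.numeric(weight_kg) || length(weight_kg) != 1L || !(weight_kg > 0))
    stop("weight_kg must be a positive number")
  list(type = "weight", user_id = user_id, timestamp = as_ts_chr(timestamp),
       weight_kg = as.numeric(weight_kg))
}

as_ts_chr <- function(timestamp) {
  if (inherits(timestamp, "POSIXt")) return(fmt_ts(timestamp))
  parse_ts(timestamp) # validates
  as.character(timestamp)
}

#' Assemble a study log
#'
#' @param users List of per-user metadata lists; each needs `user_id` and
#'   `seed` (the user's bandit stream seed), and may carry baseline
#'   covariates (`sex`, `bmi_start`, `psych_comorbidity`) and a behavior
#'   `catalog` (list of `arm_id` / `label` / `source` entries, `source` one
#'   of `"predefined"` or `"user_created"`).
#' @param events List of events from the [study_events] constructors.
#' @param tz Timezone used for calendar-day boundaries (default UTC).
#' @return An object of class `study_log`.
#' @export
study_log <- function(users, events = list(), tz = "UTC") {
  log <- structure(list(header = list(tz = tz, users = users),
                        events = events),
                   class = "study_log")
  validate_study_log(log)
  log
}

#' Validate a study log
#'
#' Checks header/user metadata, event well-formedness (timestamps, mood
#' item counts and ranges, non-empty unique selections, positive weights),
#' that every event's user appears in the header, and that catalogs have
#' unique arm ids.
#'
#' @param log A [study_log()].
#' @return The log, invisibly; signals an error on the first violation.
#' @export
validate_study_log <- function(log) {
  stopifnot(inherits(log, "study_log"))
  users <- log$header$users
  uids <- vapply(users, `[[`, "", "user_id")
  if (anyDuplicated(uids)) stop("duplicate user_id in header")
  for (u in users) {
    if (is.null(u$seed)) stop("user ", u$user_id, " lacks an RNG seed")
    cat_ids <- vapply(u$catalog %||% list(), `[[`, "", "arm_id")
    if (anyDuplicated(cat_ids))
      stop("duplicate arm_id in catalog of user ", u$user_id)
  }
  for (ev in log$events) {
    if (!ev$type %in% c("set", "review", "mood", "weight"))
      stop("unknown event type: ", ev$type)
    if (!ev$user_id %in% uids)
      stop("event references unknown user: ", ev$user_id)
    parse_ts(ev$timestamp)
    switch(ev$type,
      set = {
        if (length(ev$selected) == 0L || anyDuplicated(ev$selected))
          stop("malformed set event for ", ev$user_id, " at ", ev$timestamp)
      },
      review = {
        if (length(ev$performed) > 0L && is.null(names(ev$performed)))
          stop("review without named performed map at ", ev$timestamp)
        if (length(intersect(names(ev$performed), ev$extras)) > 0L)
          stop("extras overlap selected set at ", ev$timestamp)
      },
      mood = {
        if (length(ev$items) != 9L || any(ev$items < 0 | ev$items > 100))
          stop("malformed mood observation at ", ev$timestamp)
      },
      weight = {
        if (!(ev$weight_kg > 0)) stop("non-positive weight at ", ev$timestamp)
      })
  }
  invisible(log)
}

#' Read and write study logs as JSON Lines
#'
#' One JSON object per line: a `header` line (timezone plus per-user
#' metadata including each user's bandit RNG seed), followed by `set`,
#' `review`, `mood`, and `weight` events with ISO-8601 timestamps.
#' `parse(write(log))` is the identity.
#'
#' @param log A [study_log()].
#' @param path File path.
#' @return `write_event_log()` returns `path` invisibly;
#'   `read_event_log()` returns a validated `study_log`.
#' @export
write_event_log <- function(log, path) {
  validate_study_log(log)
  hdr <- c(list(type = "header"), log$header)
  lines <- c(
    as.character(jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA)),
    vapply(log$events, function(ev) {
      if (ev$type == "review") {
        ev$performed <- as.list(ev$performed)
        if (length(ev$extras) == 0L) ev$extras <- character()
      }
      as.character(jsonlite::toJSON(ev, auto_unbox = TRUE, digits = NA))
    }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty event log: ", path)
  hdr <- jsonlite::fromJSON(lines[1], simplifyDataFrame = FALSE)
  if (!identical(hdr$type, "header")) stop("first line must be the header")
  hdr$type <- NULL
  events <- lapply(lines[-1], function(l) {
    ev <- jsonlite::fromJSON(l, simplifyDataFrame = FALSE)
    switch(ev$type,
      set = set_event(ev$user_id, ev$timestamp, unlist(ev$selected)),
      review = review_event(
        ev$user_id, ev$timestamp,
        performed = if (length(ev$performed) == 0L)
          stats::setNames(logical(0), character(0))
        else unlist(ev$performed),
        extras = as.character(unlist(ev$extras))),
      mood = mood_observation(ev$user_id, ev$timestamp, unlist(ev$items)),
      weight = weight_observation(ev$user_id, ev$timestamp, ev$weight_kg),
      stop("unknown event type: ", ev$type))
  })
  study_log(users = hdr$users, events = events, tz = hdr$tz %||% "UTC")
}

#' Pair review events with their preceding set events
#'
#' Each review is matched to the most recent prior set event of the same
#' user whose gap lies strictly inside (12, 36) hours. Pairing is
#' one-to-one: reviews are processed in time order, so when two reviews
#' fall inside one set's window the earlier review claims it and the later
#' is dropped. Unmatched events are counted in the attached drop report.
#' The daily outcome `Y` is the number of preselected behaviors actually
#' performed plus the number of extras.
#'
#' @param log A [study_log()].
#' @return A data frame with one row per paired record: `user_id`,
#'   `set_time`, `review_time`, `gap_hours`, `day_index` and `week_index`
#'   (relative to the user's first set event), `Y`, and list-columns
#'   `performed` (named logical) and `extras`. The attribute `drop_report`
#'   counts `unmatched_reviews` and `unmatched_sets`.
#' @export
pair_set_review <- function(log) {
  validate_study_log(log)
  rows <- list()
  dropped_reviews <- 0L
  dropped_sets <- 0L
  uids <- vapply(log$header$users, `[[`, "", "user_id")
  for (uid in uids) {
    evs <- Filter(function(e) e$user_id == uid, log$events)
    sets <- Filter(function(e) e$type == "set", evs)
    reviews <- Filter(function(e) e$type == "review", evs)
    if (length(sets) == 0L) {
      dropped_reviews <- dropped_reviews + length(reviews)
      next
    }
    set_t <- parse_ts(vapply(sets, `[[`, "", "timestamp"))
    sets <- sets[order(set_t)]; set_t <- sort(set_t)
    rev_t <- parse_ts(vapply(reviews, `[[`, "", "timestamp"))
    reviews <- reviews[order(rev_t)]; rev_t <- sort(rev_t)
    start_day <- as.Date(calendar_day(set_t[1], log$header$tz))
    claimed <- rep(FALSE, length(sets))
    for (i in seq_along(reviews)) {
      gaps <- as.numeric(difftime(rev_t[i], set_t, units = "hours"))
      ok <- which(gaps > 12 & gaps < 36 & !claimed)
      if (length(ok) == 0L) {
        dropped_reviews <- dropped_reviews + 1L
        next
      }
      j <- ok[length(ok)] # most recent prior admissible set
      sel <- sets[[j]]$selected
      perf <- reviews[[i]]$performed
      if (!all(names(perf) %in% sel))
        stop("malformed log: review at ", reviews[[i]]$timestamp,
             " reports behaviors outside its matched selection")
      claimed[j] <- TRUE
      day_idx <- as.integer(
        as.Date(calendar_day(set_t[j], log$header$tz)) - start_day) + 1L
      rows[[length(rows) + 1L]] <- list(
        user_id = uid,
        set_time = fmt_ts(set_t[j]),
        review_time = fmt_ts(rev_t[i]),
        gap_hours = gaps[j],
        day_index = day_idx,
        week_index = (day_idx - 1L) %/% 7L + 1L,
        Y = compute_daily_outcome(perf, reviews[[i]]$extras),
        performed = perf,
        extras = reviews[[i]]$extras)
    }
    dropped_sets <- dropped_sets + sum(!claimed)
  }
  out <- if (length(rows) == 0L) {
    data.frame(user_id = character(), set_time = character(),
               review_time = character(), gap_hours = numeric(),
               day_index = integer(), week_index = integer(), Y = integer())
  } else {
    df <- data.frame(
      user_id = vapply(rows, `[[`, "", "user_id"),
      set_time = vapply(rows, `[[`, "", "set_time"),
      review_time = vapply(rows, `[[`, "", "review_time"),
      gap_hours = vapply(rows, `[[`, 0, "gap_hours"),
      day_index = vapply(rows, `[[`, 0L, "day_index"),
      week_index = vapply(rows, `[[`, 0L, "week_index"),
      Y = vapply(rows, `[[`, 0L, "Y"),
      row.names = NULL)
    df$performed <- lapply(rows, `[[`, "performed")
    df$extras <- lapply(rows, `[[`, "extras")
    df
  }
  attr(out, "drop_report") <- list(unmatched_reviews = dropped_reviews,
                                   unmatched_sets = dropped_sets)
  out
}

#' Daily behavior outcome
#'
#' The outcome modeled in the longitudinal analysis: the number of
#' preselected behaviors actually performed plus the number of additional
#' behaviors logged at review.
#'
#' @param performed Named logical vector over the selected set.
#' @param extras Character vector of extra behaviors.
#' @return A non-negative integer.
#' @export
compute_daily_outcome <- function(performed, extras = character()) {
  stopifnot(is.logical(performed), is.character(extras))
  as.integer(sum(performed) + length(extras))
}

#' Default assignment of the nine mood items to subscales
#'
#' The mood instrument's nine 0-100 visual-analog items split evenly into
#' depression, anxiety, and positive-affect subscales. The assignment is
#' configurable because deployments may order items differently; positive
#' affect is reported as its own subscale, never reverse-scored.
#'
#' @return Named list of three integer index triplets.
#' @export
default_mood_mapping <- function() {
  list(depression = 1:3, anxiety = 4:6, positive_affect = 7:9)
}

#' Score a mood observation into subscales
#'
#' Each subscale is the mean of its three assigned items divided by 100,
#' giving values on \[0, 1\] as used in the longitudinal model.
#'
#' @param items Numeric vector of nine values in \[0, 100\] (or a mood
#'   event from [mood_observation()]).
#' @param mapping Item-to-subscale assignment, see [default_mood_mapping()].
#' @return Named numeric vector `c(depression, anxiety, positive_affect)`.
#' @examples
#' score_mood(c(20, 40, 60, rep(0, 6)))
#' @export
score_mood <- function(items, mapping = default_mood_mapping()) {
  if (is.list(items) && identical(items$type, "mood")) items <- items$items
  if (length(items) != 9L) stop("expected 9 mood items, got ", length(items))
  if (any(!is.finite(items)) || any(items < 0 | items > 100))
    stop("mood items must lie in [0, 100]")
  idx <- sort(unlist(mapping, use.names = FALSE))
  if (!identical(idx, 1:9) ||
      !setequal(names(mapping), c("depression", "anxiety", "positive_affect")) ||
      any(lengths(mapping) != 3L))
    stop("mapping must assign each of the 9 items to exactly one of the 3 subscales")
  vapply(mapping[c("depression", "anxiety", "positive_affect")],
         function(i) mean(items[i]) / 100, 0)
}

#' Per-user app use rate
#'
#' The percentage of scheduled study days on which a behavior review was
#' recorded: `100 * distinct review days / scheduled_days`, reported to one
#' decimal. Calendar days use the log's timezone.
#'
#' @param log A [study_log()].
#' @param scheduled_days Scheduled study days per user; a single number
#'   (default 28) or a named vector by user id for per-user denominators.
#' @return Named numeric vector of percentages (one decimal) by user.
#' @export
compute_use_rate <- function(log, scheduled_days = 28) {
  validate_study_log(log)
  uids <- vapply(log$header$users, `[[`, "", "user_id")
  sched <- if (length(scheduled_days) == 1L && is.null(names(scheduled_days)))
    stats::setNames(rep(scheduled_days, length(uids)), uids)
  else scheduled_days[uids]
  if (any(!is.finite(sched)) || any(sched < 1))
    stop("scheduled_days must be >= 1 for every user")
  out <- stats::setNames(numeric(length(uids)), uids)
  for (uid in uids) {
    revs <- Filter(function(e) e$type == "review" && e$user_id == uid,
                   log$events)
    days <- unique(calendar_day(parse_ts(vapply(revs, `[[`, "", "timestamp")),
                                log$header$tz))
    if (length(days) > sched[uid])
      stop("log error: user ", uid, " has ", length(days),
           " recorded days but only ", sched[uid], " scheduled")
    out[uid] <- round(100 * length(days) / sched[uid], 1)
  }
  out
}

#' Weight change covariates at a time point
#'
#' Uses the latest weight observation strictly before `at`. The baseline
#' delta is relative to the user's first observation; the previous delta is
#' relative to the next-most-recent observation (NA and flagged when only
#' one prior observation exists — such records are dropped from models that
#' need it rather than imputed).
#'
#' @param times POSIXct (or ISO-8601 character) observation times.
#' @param weights Numeric weights (kg), same length as `times`.
#' @param at Time point of interest.
#' @return List with `delta_baseline`, `delta_previous`, and
#'   `missing_previous`.
#' @export
weight_deltas <- function(times, weights, at) {
  if (is.character(times)) times <- parse_ts(times)
  if (is.character(at)) at <- parse_ts(at)
  stopifnot(length(times) == length(weights))
  ord <- order(times)
  times <- times[ord]; weights <- weights[ord]
  prior <- which(times < at)
  if (length(prior) == 0L)
    stop("missing covariate: no weight observation before ", fmt_ts(at))
  k <- prior[length(prior)]
  list(delta_baseline = weights[k] - weights[1],
       delta_previous = if (k >= 2L) weights[k] - weights[k - 1L] else NA_real_,
       missing_previous = k < 2L)
}

#' Build the analysis-ready long table
#'
#' Joins paired set/review records with the latest mood observation in the
#' preceding `mood_window_hours`, weight-change covariates at review time,
#' and the header's baseline covariates (`sex`, BMI centered at 35,
#' psychiatric comorbidity). Records without a mood observation in the
#' window are dropped (counted in the attached drop report); missing
#' weight covariates are left NA for complete-case handling downstream.
#'
#' @param log A [study_log()].
#' @param mood_window_hours Width of the look-back window for mood
#'   (default 24 h).
#' @param mapping Mood item-to-subscale assignment.
#' @return Data frame with columns `user_id`, `day`, `week`, `Y`,
#'   `depression`, `anxiety`, `positive_affect`, `delta_weight_baseline`,
#'   `delta_weight_previous`, `sex`, `bmi_centered`, `psych_comorbidity`.
#' @export
build_analysis_table <- function(log, mood_window_hours = 24,
                                 mapping = default_mood_mapping()) {
  paired <- pair_set_review(log)
  users <- log$header$users
  names(users) <- vapply(users, `[[`, "", "user_id")
  no_mood <- 0L
  rows <- vector("list", nrow(paired))
  for (i in seq_len(nrow(paired))) {
    uid <- paired$user_id[i]
    rt <- parse_ts(paired$review_time[i])
    moods <- Filter(function(e) e$type == "mood" && e$user_id == uid,
                    log$events)
    mt <- parse_ts(vapply(moods, `[[`, "", "timestamp"))
    in_win <- which(mt < rt &
                      as.numeric(difftime(rt, mt, units = "hours")) <=
                      mood_window_hours)
    if (length(in_win) == 0L) {
      no_mood <- no_mood + 1L
      next
    }
    sub <- score_mood(moods[[in_win[which.max(mt[in_win])]]], mapping)
    wobs <- Filter(function(e) e$type == "weight" && e$user_id == uid,
                   log$events)
    dw <- if (length(wobs) > 0L &&
              any(parse_ts(vapply(wobs, `[[`, "", "timestamp")) < rt)) {
      weight_deltas(vapply(wobs, `[[`, "", "timestamp"),
                    vapply(wobs, `[[`, 0, "weight_kg"), rt)
    } else list(delta_baseline = NA_real_, delta_previous = NA_real_)
    u <- users[[uid]]
    rows[[i]] <- data.frame(
      user_id = uid,
      day = paired$day_index[i],
      week = paired$week_index[i],
      Y = paired$Y[i],
      depression = unname(sub["depression"]),
      anxiety = unname(sub["anxiety"]),
      positive_affect = unname(sub["positive_affect"]),
      delta_weight_baseline = dw$delta_baseline,
      delta_weight_previous = dw$delta_previous,
      sex = u$sex %||% NA_character_,
      bmi_centered = (u$bmi_start %||% NA_real_) - 35,
      psych_comorbidity = as.numeric(u$psych_comorbidity %||% NA),
      row.names = NULL)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) out <- data.frame()
  attr(out, "drop_report") <- c(attr(paired, "drop_report"),
                                list(no_mood_in_window = no_mood))
  out
}
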