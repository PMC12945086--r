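#' Create a behavior arm
#'
#' One selectable daily behavior, tracked as a beta-Bernoulli bandit arm.
#' `n_selected` counts the times the behavior was chosen and subsequently
#' reviewed; `n_completed` counts the times it was actually performed. Under
#' a uniform prior the completion probability has posterior
#' Beta(`n_completed + 1`, `n_selected - n_completed + 1`).
#'
#' @param arm_id Character scalar identifying the behavior.
#' @param n_selected Number of reviewed selections (N >= 0).
#' @param n_completed Number of completions (0 <= a <= N).
#' @return An object of class `behavior_arm`.
#' @examples
#' behavior_arm("walk_30min")
#' behavior_arm("no_snacks", n_selected = 5, n_completed = 3)
#' @export
behavior_arm <- function(arm_id, n_selected = 0L, n_completed = 0L) {
  stopifnot(is.character(arm_id), length(arm_id) == 1L, nzchar(arm_id))
  arm <- structure(
    list(arm_id = arm_id,
         n_selected = as.integer(n_selected),
         n_completed = as.integer(n_completed)),
    class = "behavior_arm")
  validate_arm(arm)
  arm
}

validate_arm <- function(arm) {
  if (!is_count(arm$n_selected) || !is_count(arm$n_completed) ||
      arm$n_completed > arm$n_selected) {
    stop("corrupted arm state for '", arm$arm_id,
         "': need 0 <= n_completed <= n_selected, got a = ",
         arm$n_completed, ", N = ", arm$n_selected)
  }
  invisible(arm)
}

#' Beta posterior parameters of an arm
#'
#' Shape parameters of the posterior over the arm's completion probability:
#' with `N` reviewed selections and `a` completions, the normalized density
#' proportional to `theta^a * (1 - theta)^(N - a)` is Beta(a + 1, N - a + 1),
#' i.e. a uniform Beta(1, 1) prior updated by `a` successes and `N - a`
#' failures.
#'
#' @param arm A [behavior_arm()].
#' @return Named numeric vector `c(alpha =, beta =)`.
#' @examples
#' posterior_params(behavior_arm("x"))                      # c(1, 1)
#' posterior_params(behavior_arm("x", 5, 3))                # c(4, 3)
#' @export
posterior_params <- function(arm) {
  validate_arm(arm)
  c(alpha = arm$n_completed + 1,
    beta = arm$n_selected - arm$n_completed + 1)
}

#' Posterior mean completion probability of an arm
#'
#' Equals `(a + 1) / (N + 2)`; converges to the empirical completion rate
#' `a / N` as reviews accumulate.
#'
#' @inheritParams posterior_params
#' @return A value in (0, 1).
#' @export
posterior_mean <- function(arm) {
  p <- posterior_params(arm)
  unname(p["alpha"] / (p["alpha"] + p["beta"]))
}

#' Sample completion-probability scores from an arm's posterior
#'
#' Draws from the Beta(a + 1, N - a + 1) posterior using the current R
#' random stream (seed with [set.seed()] for reproducibility, or use
#' [rank_behaviors()] whose draws come from the bandit state's own stream).
#'
#' @inheritParams posterior_params
#' @param n Number of draws.
#' @return Numeric vector of `n` values in (0, 1).
#' @export
sample_theta <- function(arm, n = 1L) {
  p <- posterior_params(arm)
  stats::rbeta(n, p["alpha"], p["beta"])
}

#' Create a per-user bandit state
#'
#' Each participant has an independent model trained only on their own
#' review history: a catalog of [behavior_arm()]s plus a named random
#' stream (seed and draw counter) so ranking sequences are bit-for-bit
#' reproducible.
#'
#' @param user_id Character scalar.
#' @param arms List of [behavior_arm()]s (or character vector of arm ids,
#'   which are registered fresh with the uniform prior).
#' @param seed Integer seed of the user's random stream.
#' @return An object of class `bandit_state`.
#' @export
bandit_state <- function(user_id, arms, seed) {
  stopifnot(is.character(user_id), length(user_id) == 1L)
  if (is.character(arms)) arms <- lapply(arms, behavior_arm)
  stopifnot(is.list(arms), length(arms) >= 0)
  for (a in arms) {
    if (!inherits(a, "behavior_arm")) stop("arms must be behavior_arm objects")
    validate_arm(a)
  }
  ids <- vapply(arms, `[[`, "", "arm_id")
  if (anyDuplicated(ids)) stop("duplicate arm_id in catalog: ",
                               ids[duplicated(ids)][1])
  names(arms) <- ids
  structure(
    list(user_id = user_id, arms = arms,
         seed = as.integer(seed), draw_count = 0L),
    class = "bandit_state")
}

#' Register a new behavior in a user's catalog
#'
#' User-created items enter with the same uniform prior as predefined ones
#' (N = 0, a = 0).
#'
#' @param state A [bandit_state()].
#' @param arm_id Character id of the new behavior.
#' @return The updated state.
#' @export
register_arm <- function(state, arm_id) {
  stopifnot(inherits(state, "bandit_state"))
  if (arm_id %in% names(state$arms))
    stop("arm_id already in catalog: ", arm_id)
  state$arms[[arm_id]] <- behavior_arm(arm_id)
  state
}

#' Rank the behavior catalog by Thompson sampling
#'
#' Draws one fresh score per arm from its beta posterior and sorts the full
#' catalog by score, descending — easily achievable behaviors rise to the
#' top as data accumulate, while rarely tried behaviors keep large sampling
#' variance and continue to be explored. Score ties are broken by
#' lexicographic `arm_id`. Each call consumes one tick of the state's
#' random stream; the caller's RNG is untouched.
#'
#' @param state A [bandit_state()] with at least one arm.
#' @param timestamp Time of the draw (defaults to now).
#' @return A list with `suggestion` (class `ranked_suggestion`: a data frame
#'   of `arm_id` and sampled `theta` in ranked order, the `timestamp`, and
#'   the `draw_index`) and `state` (the input state with its stream
#'   advanced).
#' @examples
#' st <- bandit_state("u1", c("walk", "no_snacks"), seed = 42)
#' out <- rank_behaviors(st)
#' out$suggestion$ranking
#' @export
rank_behaviors <- function(state, timestamp = Sys.time()) {
  stopifnot(inherits(state, "bandit_state"))
  if (length(state$arms) == 0L)
    stop("empty catalog: cannot rank a user with no behavior arms")
  for (a in state$arms) validate_arm(a)
  ids <- names(state$arms)
  alpha <- vapply(state$arms, function(a) a$n_completed + 1, 0)
  beta <- vapply(state$arms, function(a) a$n_selected - a$n_completed + 1, 0)
  call_seed <- derive_seed(state$seed, state$draw_count)
  theta <- with_local_seed(call_seed, function()
    stats::rbeta(length(ids), alpha, beta))
  ord <- order(-theta, ids)
  suggestion <- structure(
    list(ranking = data.frame(arm_id = ids[ord], theta = theta[ord],
                              row.names = NULL),
         timestamp = fmt_ts(timestamp),
         draw_index = state$draw_count),
    class = "ranked_suggestion")
  state$draw_count <- state$draw_count + 1L
  list(suggestion = suggestion, state = state)
}

#' Record one reviewed selection on an arm
#'
#' Increments the selection counter, and the completion counter when the
#' behavior was performed. Counters only ever increase; the posterior mean
#' rises after a completion and falls after an incompletion.
#'
#' @inheritParams posterior_params
#' @param completed Logical: was the behavior performed?
#' @return The updated arm.
#' @export
update_arm <- function(arm, completed) {
  validate_arm(arm)
  stopifnot(is.logical(completed), length(completed) == 1L, !is.na(completed))
  arm$n_selected <- arm$n_selected + 1L
  if (completed) arm$n_completed <- arm$n_completed + 1L
  arm
}

#' Apply one evening review to a user's bandit state
#'
#' Every preselected behavior's arm is updated with its performed flag.
#' Ad-hoc extra behaviors logged at review time update their arms (as
#' selected-and-completed) only when `include_extras = TRUE`; by default
#' they are kept out of the counters, since a selection count means "times
#' the user chose the item the evening before". Arms not referenced are
#' unchanged.
#'
#' @param state A [bandit_state()].
#' @param performed Named logical vector: the selected arm ids and whether
#'   each was performed.
#' @param extras Character vector of additionally performed arm ids.
#' @param include_extras Should extras update their arms? Default `FALSE`.
#' @return The updated state.
#' @export
apply_review <- function(state, performed, extras = character(),
                         include_extras = FALSE) {
  stopifnot(inherits(state, "bandit_state"),
            is.logical(performed), !is.null(names(performed)) || length(performed) == 0L,
            is.character(extras))
  touched <- c(names(performed), if (include_extras) extras)
  unknown <- setdiff(touched, names(state$arms))
  if (length(unknown) > 0L)
    stop("catalog mismatch: unknown arm_id(s) ", paste(unknown, collapse = ", "),
         " (register user-created behaviors first)")
  for (id in names(performed)) {
    state$arms[[id]] <- update_arm(state$arms[[id]], unname(performed[id]))
  }
  if (include_extras) {
    for (id in extras) {
      state$arms[[id]] <- update_arm(state$arms[[id]], TRUE)
    }
  }
  state
}

#' Serialize / restore a bandit state as JSON
#'
#' The state (user id, per-arm counters, stream seed and draw counter)
#' round-trips losslessly, so a recommender can be checkpointed between
#' evenings.
#'
#' @param state A [bandit_state()].
#' @param path File path.
#' @return `write_bandit_state()` returns `path` invisibly;
#'   `read_bandit_state()` returns the restored `bandit_state`.
#' @export
write_bandit_state <- function(state, path) {
  stopifnot(inherits(state, "bandit_state"))
  obj <- list(
    user_id = state$user_id,
    seed = state$seed,
    draw_count = state$draw_count,
    arms = lapply(unname(state$arms), function(a)
      list(arm_id = a$arm_id, n_selected = a$n_selected,
           n_completed = a$n_completed)))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname write_bandit_state
#' @export
read_bandit_state <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                            simplifyDataFrame = FALSE)
  arms <- lapply(obj$arms, function(a)
    behavior_arm(a$arm_id, a$n_selected, a$n_completed))
  state <- bandit_state(obj$user_id, arms, obj$seed)
  state$draw_count <- as.integer(obj$draw_count)
  state
}

#' @export
print.bandit_state <- function(x, ...) {
  cat("<bandit_state> user", x$user_id, "-", length(x$arms), "arms, draw",
      x$draw_count, "\n")
  for (a in x$arms) {
    cat(sprintf("  %-20s N=%3d a=%3d  E[theta]=%.3f\n", a$arm_id,
                a$n_selected, a$n_completed, posterior_mean(a)))
  }
  invisible(x)
}

#' @export
print.ranked_suggestion <- function(x, ...) {
  cat("<ranked_suggestion> at", x$timestamp, "(draw", x$draw_index, ")\n")
  print(x$ranking, ...)
  invisible(x)
}
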