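#' Simulation parameters for a synthetic study cohort
#'
#' Defaults emulate the study conditions: 20 participants followed for 28
#' days, a 20-item behavior catalog with latent per-behavior completion
#' probabilities drawn from Beta(2, 2), daily mood following a clamped
#' AR(1) on \[0, 1\] per subscale, behavior completion modulated on the
#' logit scale by same-day depressive mood, ~5% of review days missing
#' (calibrating simulated use rates to the mid-90s), daily weight as a
#' linear drift plus Gaussian noise, and a 30% psychiatric-comorbidity
#' rate.
#'
#' @param n_participants Cohort size.
#' @param n_days Study length in days.
#' @param catalog_size Number of predefined behaviors.
#' @param true_completion_probs Optional numeric vector of latent
#'   completion probabilities (recycled/truncated to `catalog_size`); when
#'   `NULL` each participant's probabilities are drawn from
#'   `Beta(completion_prob_shape[1], completion_prob_shape[2])`.
#' @param completion_prob_shape Beta shapes of the completion-probability
#'   law.
#' @param mood_ar1 Per-subscale `c(mean, ar, sd)` of the clamped AR(1)
#'   mood process on \[0, 1\].
#' @param depression_effect Logit-scale coefficient of same-day depressive
#'   mood on behavior completion (negative: worse mood, fewer completions).
#' @param selection_attention `c(p1, decay)`: a simulated user selects the
#'   behavior displayed at rank r with probability `p1 * decay^(r-1)`
#'   (at least one is always selected), giving ~3 selections per evening
#'   at the defaults.
#' @param extra_prob Probability of logging one ad-hoc extra behavior at a
#'   review.
#' @param missing_review_prob Probability a review day is skipped.
#' @param weight_baseline `c(mean, sd, min)` of the baseline weight law (kg).
#' @param weight_drift Mean daily weight change (kg/day).
#' @param weight_noise_sd SD of daily weight noise (kg).
#' @param bmi_baseline `c(mean, sd, min)` of the baseline BMI law.
#' @param psych_comorbidity_prob Probability of psychiatric comorbidity.
#' @param female_prob Probability a participant is female.
#' @param start_date First study date (ISO `YYYY-MM-DD`).
#' @param seed Master seed; every participant's stream is derived from it.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_participants = 20L,
                       n_days = 28L,
                       catalog_size = 20L,
                       true_completion_probs = NULL,
                       completion_prob_shape = c(2, 2),
                       mood_ar1 = list(
                         depression = c(mean = 0.30, ar = 0.6, sd = 0.08),
                         anxiety = c(mean = 0.30, ar = 0.6, sd = 0.08),
                         positive_affect = c(mean = 0.55, ar = 0.6, sd = 0.10)),
                       depression_effect = -1.5,
                       selection_attention = c(p1 = 0.9, decay = 0.7),
                       extra_prob = 0.1,
                       missing_review_prob = 0.05,
                       weight_baseline = c(mean = 95, sd = 15, min = 60),
                       weight_drift = -0.08,
                       weight_noise_sd = 0.3,
                       bmi_baseline = c(mean = 35, sd = 5, min = 27),
                       psych_comorbidity_prob = 0.3,
                       female_prob = 0.55,
                       start_date = "2026-01-05",
                       seed = 1L) {
  p <- structure(as.list(environment()), class = "sim_params")
  stopifnot(p$n_participants >= 1, p$n_days >= 1, p$catalog_size >= 1,
            p$missing_review_prob >= 0, p$missing_review_prob <= 1,
            p$extra_prob >= 0, p$extra_prob <= 1,
            p$psych_comorbidity_prob >= 0, p$psych_comorbidity_prob <= 1,
            p$female_prob >= 0, p$female_prob <= 1)
  if (!is.null(p$true_completion_probs)) {
    stopifnot(all(p$true_completion_probs >= 0),
              all(p$true_completion_probs <= 1))
  }
  p
}

clamp01 <- function(x) pmin(1, pmax(0, x))

# Clamped AR(1) path on [0, 1]: x_t = mean + ar * (x_{t-1} - mean) + noise.
ar1_path <- function(n, mean, ar, sd) {
  x <- numeric(n)
  x[1] <- clamp01(mean + stats::rnorm(1, 0, sd / sqrt(max(1 - ar^2, 1e-8))))
  for (t in seq_len(n)[-1]) {
    x[t] <- clamp01(mean + ar * (x[t - 1] - mean) + stats::rnorm(1, 0, sd))
  }
  x
}

#' Simulate a synthetic study cohort
#'
#' Generates a complete event log for `n_participants` over `n_days`,
#' reproducing the app's daily cycle: each evening the per-user Thompson
#' sampler ranks the catalog and the simulated user selects the top-ranked
#' behaviors under a rank-decaying attention law; the next evening a
#' review records per-behavior Bernoulli completion, with the completion
#' probability of behavior k on day t equal to
#' `plogis(qlogis(p_k) + depression_effect * depression_t)`. Reviews are
#' skipped with `missing_review_prob` (skipped selections never update the
#' bandit). Mood (nine 0-100 items) and weight are recorded daily. The
#' same seed always yields a byte-identical log.
#'
#' @param params A [sim_params()].
#' @return A validated [study_log()].
#' @export
simulate_cohort <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  start <- as.POSIXct(paste0(params$start_date, "T00:00:00"),
                      format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  arm_ids <- sprintf("b%02d", seq_len(params$catalog_size))
  catalog <- lapply(arm_ids, function(id)
    list(arm_id = id, label = paste("behavior", id), source = "predefined"))
  users <- list()
  events <- list()
  for (u in seq_len(params$n_participants)) {
    uid <- sprintf("u%02d", u)
    user_seed <- derive_seed(params$seed, u)
    ev <- with_local_seed(user_seed, function()
      simulate_participant(uid, user_seed, params, start, arm_ids))
    users[[u]] <- c(list(user_id = uid, seed = user_seed), ev$meta,
                    list(catalog = catalog))
    events <- c(events, ev$events)
  }
  ts <- vapply(events, `[[`, "", "timestamp")
  events <- events[order(ts, vapply(events, `[[`, "", "user_id"),
                         vapply(events, `[[`, "", "type"),
                         method = "radix")]
  study_log(users = users, events = events, tz = "UTC")
}

simulate_participant <- function(uid, user_seed, params, start, arm_ids) {
  K <- length(arm_ids)
  p_k <- if (is.null(params$true_completion_probs)) {
    stats::rbeta(K, params$completion_prob_shape[1],
                 params$completion_prob_shape[2])
  } else rep_len(params$true_completion_probs, K)
  psych <- stats::runif(1) < params$psych_comorbidity_prob
  sex <- if (stats::runif(1) < params$female_prob) "female" else "male"
  wb <- params$weight_baseline
  weight0 <- max(wb["min"], stats::rnorm(1, wb["mean"], wb["sd"]))
  bb <- params$bmi_baseline
  bmi0 <- max(bb["min"], stats::rnorm(1, bb["mean"], bb["sd"]))
  mood <- lapply(params$mood_ar1, function(m)
    ar1_path(params$n_days, m["mean"], m["ar"], m["sd"]))
  miss <- stats::runif(params$n_days) < params$missing_review_prob

  state <- bandit_state(uid, arm_ids, seed = derive_seed(user_seed, 9001L))
  events <- list()
  add <- function(e) events[[length(events) + 1L]] <<- e

  select_from <- function(ranking) {
    att <- params$selection_attention
    pick <- stats::runif(nrow(ranking)) <
      att["p1"] * att["decay"]^(seq_len(nrow(ranking)) - 1)
    sel <- ranking$arm_id[pick]
    if (length(sel) == 0L) sel <- ranking$arm_id[1]
    sel
  }

  # evening of day 0: first selection for day 1
  out <- rank_behaviors(state, start + 20.5 * 3600)
  state <- out$state
  selected <- select_from(out$suggestion$ranking)
  add(set_event(uid, start + 20.5 * 3600, selected))

  for (t in seq_len(params$n_days)) {
    day0 <- start + (t - 1) * 86400 # midnight starting day t... day t runs [day0+24h, day0+48h)
    day_t <- start + t * 86400
    add(weight_observation(
      uid, day_t + 7 * 3600,
      round(weight0 + params$weight_drift * t +
              stats::rnorm(1, 0, params$weight_noise_sd), 2)))
    items <- round(clamp01(c(
      mood$depression[t] + stats::rnorm(3, 0, 0.05),
      mood$anxiety[t] + stats::rnorm(3, 0, 0.05),
      mood$positive_affect[t] + stats::rnorm(3, 0, 0.05))) * 100)
    add(mood_observation(uid, day_t + 10 * 3600, items))

    review_time <- day_t + 20 * 3600
    if (!miss[t]) {
      prob <- clamp01(stats::plogis(
        stats::qlogis(pmin(pmax(p_k, 1e-6), 1 - 1e-6)) +
          params$depression_effect * mood$depression[t]))
      idx <- match(selected, arm_ids)
      performed <- stats::setNames(
        stats::runif(length(selected)) < prob[idx], selected)
      extras <- character()
      if (stats::runif(1) < params$extra_prob) {
        pool <- setdiff(arm_ids, selected)
        if (length(pool) > 0L) extras <- sample(pool, 1)
      }
      add(review_event(uid, review_time, performed, extras))
      state <- apply_review(state, performed, extras, include_extras = FALSE)
    }
    if (t < params$n_days) {
      set_time <- day_t + 20.5 * 3600
      out <- rank_behaviors(state, set_time)
      state <- out$state
      selected <- select_from(out$suggestion$ranking)
      add(set_event(uid, set_time, selected))
    }
  }
  list(events = events,
       meta = list(sex = sex, bmi_start = round(bmi0, 1),
                   weight_start = round(weight0, 1),
                   psych_comorbidity = psych))
}

#' Generating parameters for the two-level longitudinal model
#'
#' Direct generator for the mixed-model recovery harness. The outcome for
#' participant i at observation j follows
#' `Y_ij = Pi0_i + Pi1_i * Depression_ij + eps_ij` with
#' `Pi0_i = gamma00 + zeta0_i` and
#' `Pi1_i = gamma10 + gamma11 * Psych_i + zeta1_i`, where `zeta0`, `zeta1`
#' are independent normal random effects and `eps` is residual noise.
#' Default fixed effects are the study-scale values (4.45, -1.88, 1.59);
#' variance components are set so fixed-effect standard errors at
#' 20 x 22 observations resemble the reported interval widths.
#'
#' @param gamma00 Fixed intercept.
#' @param gamma10 Fixed depression slope.
#' @param gamma11 Depression-by-psychiatric-comorbidity interaction.
#' @param sd_zeta0,sd_zeta1,sd_eps Random-intercept, random-slope, and
#'   residual SDs (all >= 0).
#' @param n_participants,obs_per_participant Sampling shape.
#' @param depression_shape Beta shapes of the depression law on \[0, 1\].
#' @param psych_prob Psychiatric-comorbidity probability.
#' @param female_prob Probability a participant is female (covariate only).
#' @param seed Seed.
#' @return An object of class `lmm_gen_params`.
#' @export
lmm_gen_params <- function(gamma00 = 4.45, gamma10 = -1.88, gamma11 = 1.59,
                           sd_zeta0 = 2.0, sd_zeta1 = 1.0, sd_eps = 2.2,
                           n_participants = 20L, obs_per_participant = 22L,
                           depression_shape = c(2, 5), psych_prob = 0.3,
                           female_prob = 0.55, seed = 1L) {
  p <- structure(as.list(environment()), class = "lmm_gen_params")
  stopifnot(p$sd_zeta0 >= 0, p$sd_zeta1 >= 0, p$sd_eps >= 0,
            p$n_participants >= 1, p$obs_per_participant >= 1)
  p
}

#' Generate an analysis-ready table directly from the two-level model
#'
#' Unlike [simulate_cohort()], which emulates the full app mechanics, this
#' generator draws the outcome exactly from the two-level equations, so
#' parameter recovery tests the fitted model against its own generating
#' process. Candidate predictors not in the generating model (anxiety,
#' positive affect, weight deltas, week, sex, centered BMI) are included
#' as null covariates for model-selection experiments. `depression` can be
#' fixed by passing a degenerate law via `depression_shape = NULL` and the
#' `fixed_depression` argument.
#'
#' @param params An [lmm_gen_params()].
#' @param fixed_depression Optional scalar: use this constant depression
#'   value for every observation instead of the Beta law.
#' @return Data frame matching the [build_analysis_table()] schema.
#' @export
generate_lmm_dataset <- function(params = lmm_gen_params(),
                                 fixed_depression = NULL) {
  stopifnot(inherits(params, "lmm_gen_params"))
  with_local_seed(params$seed, function() {
    n <- params$n_participants
    m <- params$obs_per_participant
    uid <- sprintf("u%02d", seq_len(n))
    zeta0 <- stats::rnorm(n, 0, params$sd_zeta0)
    zeta1 <- stats::rnorm(n, 0, params$sd_zeta1)
    psych <- as.numeric(stats::runif(n) < params$psych_prob)
    sex <- ifelse(stats::runif(n) < params$female_prob, "female", "male")
    bmi_c <- stats::rnorm(n, 0, 5)
    rows <- lapply(seq_len(n), function(i) {
      dep <- if (!is.null(fixed_depression)) rep(fixed_depression, m)
      else stats::rbeta(m, params$depression_shape[1],
                        params$depression_shape[2])
      pi0 <- params$gamma00 + zeta0[i]
      pi1 <- params$gamma10 + params$gamma11 * psych[i] + zeta1[i]
      eps <- stats::rnorm(m, 0, params$sd_eps)
      data.frame(
        user_id = uid[i],
        day = seq_len(m),
        week = (seq_len(m) - 1L) %/% 7L + 1L,
        Y = pi0 + pi1 * dep + eps,
        depression = dep,
        anxiety = stats::rbeta(m, 2, 5),
        positive_affect = stats::rbeta(m, 3, 3),
        delta_weight_baseline = cumsum(stats::rnorm(m, -0.08, 0.3)),
        delta_weight_previous = stats::rnorm(m, -0.08, 0.3),
        sex = sex[i],
        bmi_centered = bmi_c[i],
        psych_comorbidity = psych[i],
        row.names = NULL)
    })
    do.call(rbind, rows)
  })
}

#' Run one bandit interaction episode
#'
#' Evaluation harness for the recommender: at each round the policy ranks
#' the arms (Thompson sampling from the running posteriors, or a uniform
#' random permutation), the top-ranked arm is selected, completion is
#' Bernoulli in the arm's true probability, and the review updates the
#' posterior. Instantaneous regret is `max(true_probs) - true_prob(selected)`.
#'
#' @param true_probs Named (or unnamed) vector of true completion
#'   probabilities, one per arm.
#' @param n_rounds Number of rounds (>= 1).
#' @param policy `"thompson"` or `"uniform_random"`.
#' @param seed Seed; the whole trajectory is reproducible from it.
#' @return An object of class `bandit_trajectory`: list with `rounds`
#'   (data frame of `round`, `selected`, `completed`, `regret`,
#'   `cum_regret`), `rankings` (n_rounds x n_arms character matrix of
#'   ranked arm ids), `policy`, and `true_probs`.
#' @export
run_bandit_episode <- function(true_probs, n_rounds,
                               policy = c("thompson", "uniform_random"),
                               seed = 1L) {
  policy <- match.arg(policy)
  stopifnot(length(true_probs) >= 1L, n_rounds >= 1L,
            all(true_probs >= 0), all(true_probs <= 1))
  ids <- names(true_probs) %||% sprintf("arm%02d", seq_along(true_probs))
  if (is.null(names(true_probs))) names(true_probs) <- ids
  state <- bandit_state("sim", ids, seed = derive_seed(seed, 1L))
  best <- max(true_probs)
  with_local_seed(derive_seed(seed, 2L), function() {
    sel <- character(n_rounds)
    comp <- logical(n_rounds)
    regret <- numeric(n_rounds)
    rankings <- matrix("", n_rounds, length(ids))
    for (r in seq_len(n_rounds)) {
      ranked <- if (policy == "thompson") {
        out <- rank_behaviors(state)
        state <<- out$state
        out$suggestion$ranking$arm_id
      } else {
        sample(ids)
      }
      rankings[r, ] <- ranked
      sel[r] <- ranked[1]
      comp[r] <- stats::runif(1) < true_probs[sel[r]]
      regret[r] <- best - true_probs[sel[r]]
      state <<- apply_review(state,
                             stats::setNames(comp[r], sel[r]))
    }
    structure(
      list(rounds = data.frame(round = seq_len(n_rounds), selected = sel,
                               completed = comp, regret = regret,
                               cum_regret = cumsum(regret)),
           rankings = rankings, policy = policy, true_probs = true_probs,
           final_state = state),
      class = "bandit_trajectory")
  })
}

#' Suggestion diversity within a window of rounds
#'
#' Operationalizes the "monotony" phenomenon reported by app users: as the
#' sampler converges, the same few behaviors dominate the top of the
#' screen. Counts the distinct arms appearing among the top `top_k`
#' displayed positions across a window of rounds; comparing an early
#' window with a late one quantifies convergence-induced monotony.
#'
#' @param trajectory A [run_bandit_episode()] result.
#' @param window_days Window length in rounds.
#' @param position `"first"` or `"last"` window of the trajectory.
#' @param top_k Number of top display positions considered (default 3).
#' @return Integer count of distinct arms.
#' @export
suggestion_diversity <- function(trajectory, window_days,
                                 position = c("last", "first"), top_k = 3L) {
  position <- match.arg(position)
  stopifnot(inherits(trajectory, "bandit_trajectory"))
  n <- nrow(trajectory$rankings)
  if (window_days > n)
    stop("window_days (", window_days, ") exceeds trajectory length (", n, ")")
  rows <- if (position == "first") seq_len(window_days)
  else seq(n - window_days + 1L, n)
  k <- min(top_k, ncol(trajectory$rankings))
  length(unique(as.vector(trajectory$rankings[rows, seq_len(k), drop = FALSE])))
}
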