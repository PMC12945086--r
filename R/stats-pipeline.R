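#' Wilcoxon signed-rank test for paired pre/post measurements
#'
#' Two-sided test of paired differences (`post - pre`). Zero differences
#' are dropped and the effective sample size reported. The exact path
#' computes the full null distribution of the positive-rank sum `W+` by
#' convolution over sign assignments of the (tie-averaged) ranks —
#' equivalent to enumerating all `2^n` sign patterns — and is used when
#' `mode = "exact"`, or under `mode = "auto"` when `n_effective <= 25`
#' with no tied absolute differences. Otherwise the normal approximation
#' with continuity and tie corrections is used. All-zero differences give
#' a degenerate result (p = 1, flagged), not an error.
#'
#' @param pre,post Equal-length numeric vectors of paired measurements.
#' @param mode One of `"auto"`, `"exact"`, `"approx"`.
#' @return An object of class `wilcoxon_result`: `statistic` (W+),
#'   `p_value`, `n_effective`, `method`, `degenerate`.
#' @examples
#' wilcoxon_signed_rank(c(5, 6, 7, 8, 9, 10), c(6, 7, 8, 9, 10, 12))
#' @export
wilcoxon_signed_rank <- function(pre, post, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(pre), is.numeric(post), length(pre) == length(post),
            length(pre) >= 2L)
  d <- post - pre
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(structure(list(statistic = NA_real_, p_value = 1,
                          n_effective = 0L, method = "degenerate",
                          degenerate = TRUE),
                     class = "wilcoxon_result"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  has_ties <- anyDuplicated(abs(d)) > 0L
  exact <- mode == "exact" || (mode == "auto" && n <= 25L && !has_ties)
  if (exact) {
    p <- signed_rank_exact_p(r, W)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tab^3 - tab) / 48
    z <- W - mu
    z <- z - sign(z) * 0.5 # continuity correction
    z <- z / sqrt(sigma2)
    p <- min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
    method <- "normal approximation"
  }
  structure(list(statistic = W, p_value = p, n_effective = n,
                 method = method, degenerate = FALSE),
            class = "wilcoxon_result")
}

# Exact two-sided p for the signed-rank sum via convolution: the null
# distribution assigns each rank its sign independently with prob 1/2.
# Ranks are doubled so tie-averaged (half-integer) ranks stay integral.
signed_rank_exact_p <- function(ranks, W) {
  s <- as.integer(round(2 * ranks))
  total <- sum(s)
  probs <- c(1, numeric(total)) # index i <-> doubled rank-sum i - 1
  for (si in s) {
    shifted <- c(numeric(si), probs[seq_len(total + 1 - si)])
    probs <- (probs + shifted) / 2
  }
  w2 <- as.integer(round(2 * W))
  p_le <- sum(probs[seq_len(w2 + 1)])
  p_ge <- sum(probs[seq(w2 + 1, total + 1)])
  min(1, 2 * min(p_le, p_ge))
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat("Wilcoxon signed rank (", x$method, ")\n", sep = "")
  cat("  W+ =", x$statistic, " n_effective =", x$n_effective,
      " p =", format.pval(x$p_value, digits = 4), "\n")
  if (x$degenerate) cat("  degenerate: all paired differences are zero\n")
  invisible(x)
}

lmm_level1_vocab <- c("depression", "anxiety", "positive_affect",
                      "delta_weight_baseline", "delta_weight_previous",
                      "week")
lmm_level2_vocab <- c("sex", "bmi_centered", "psych_comorbidity")

#' Specify a two-level linear mixed-effects model
#'
#' Level-1 (within-person) fixed effects act on daily observations;
#' level-2 (between-person) fixed effects act on the person-level
#' intercept; cross-level interactions let a level-2 variable moderate a
#' level-1 slope — e.g. the depression-by-psychiatric-comorbidity term
#' corresponds to the comorbidity entering the slope equation, and is
#' admissible whenever the level-1 variable is included (the level-2 main
#' effect is optional, matching a slope-only moderation). Random effects
#' always include the person intercept and may add a per-person
#' depression slope, with the intercept-slope correlation estimated.
#' Estimation is by maximum likelihood so AIC is comparable across
#' fixed-effect structures.
#'
#' @param level1_fixed Subset of `depression`, `anxiety`,
#'   `positive_affect`, `delta_weight_baseline`, `delta_weight_previous`,
#'   `week`.
#' @param level2_fixed Subset of `sex`, `bmi_centered`,
#'   `psych_comorbidity`.
#' @param cross_level_interactions List of `c(level1, level2)` pairs.
#' @param random_effects `"intercept"` or
#'   `c("intercept", "depression_slope")`.
#' @return An object of class `lmm_spec`.
#' @export
lmm_spec <- function(level1_fixed = "depression",
                     level2_fixed = character(),
                     cross_level_interactions =
                       list(c("depression", "psych_comorbidity")),
                     random_effects = c("intercept", "depression_slope")) {
  stopifnot(all(level1_fixed %in% lmm_level1_vocab),
            all(level2_fixed %in% lmm_level2_vocab),
            "intercept" %in% random_effects,
            all(random_effects %in% c("intercept", "depression_slope")))
  for (pair in cross_level_interactions) {
    if (length(pair) != 2L || !pair[1] %in% lmm_level1_vocab ||
        !pair[2] %in% lmm_level2_vocab)
      stop("interactions must be (level-1, level-2) pairs from the model vocabulary")
    if (!pair[1] %in% level1_fixed)
      stop("interaction ", pair[1], ":", pair[2],
           " requires the level-1 main effect '", pair[1], "'")
  }
  if ("depression_slope" %in% random_effects &&
      !"depression" %in% level1_fixed)
    stop("a random depression slope requires depression among the level-1 fixed effects")
  structure(list(level1_fixed = level1_fixed,
                 level2_fixed = level2_fixed,
                 cross_level_interactions = cross_level_interactions,
                 random_effects = random_effects),
            class = "lmm_spec")
}

spec_formula <- function(spec) {
  fixed <- c("1", spec$level1_fixed, spec$level2_fixed,
             vapply(spec$cross_level_interactions,
                    function(p) paste(p, collapse = ":"), ""))
  re <- if ("depression_slope" %in% spec$random_effects)
    "(1 + depression | user_id)" else "(1 | user_id)"
  stats::as.formula(paste("Y ~", paste(c(fixed, re), collapse = " + ")))
}

spec_id <- function(spec) {
  paste0("L1{", paste(sort(spec$level1_fixed), collapse = ","),
         "} L2{", paste(sort(spec$level2_fixed), collapse = ","),
         "} X{", paste(sort(vapply(spec$cross_level_interactions,
                                   function(p) paste(p, collapse = ":"), "")),
                       collapse = ","),
         "} R{", paste(sort(spec$random_effects), collapse = ","), "}")
}

#' Fit a two-level linear mixed-effects model
#'
#' Fits the specified model by maximum likelihood with [lme4::lmer()],
#' after complete-case filtering on the variables the spec uses (records
#' lacking a weight covariate are excluded from models that include it; no
#' imputation). Fixed-effect 95% confidence intervals and p-values are
#' Wald. Non-convergence and singular fits are flagged, never silent;
#' a rank-deficient fixed-effect design is an error naming the collinear
#' columns.
#'
#' @param table Analysis-ready long table ([build_analysis_table()] or
#'   [generate_lmm_dataset()] schema) with columns `Y` and `user_id`.
#' @param spec An [lmm_spec()].
#' @return An object of class `lmm_fit`: `coefficients` (term, estimate,
#'   se, ci_lower, ci_upper, p_value), `varcomp` (sd_intercept, sd_slope,
#'   cor_intercept_slope, sd_residual), `aic`, `logLik`, `converged`,
#'   `singular`, `n_obs`, `n_groups`, `spec`, `formula`.
#' @export
fit_lmm <- function(table, spec = lmm_spec()) {
  stopifnot(is.data.frame(table), inherits(spec, "lmm_spec"),
            all(c("Y", "user_id") %in% names(table)))
  vars <- unique(c("Y", "user_id", spec$level1_fixed, spec$level2_fixed,
                   unlist(spec$cross_level_interactions)))
  missing_cols <- setdiff(vars, names(table))
  if (length(missing_cols) > 0L)
    stop("table lacks required columns: ", paste(missing_cols, collapse = ", "))
  dat <- table[stats::complete.cases(table[vars]), vars, drop = FALSE]
  if (nrow(dat) == 0L) stop("no complete cases for the requested model")
  fml <- spec_formula(spec)
  fixed_fml <- lme4::nobars(fml)
  mm <- stats::model.matrix(fixed_fml, dat)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_mm$pivot[seq(qr_mm$rank + 1L, ncol(mm))]]
    stop("rank-deficient fixed-effect design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  msgs <- character()
  fit <- tryCatch(
    withCallingHandlers(
      lme4::lmer(fml, data = dat, REML = FALSE),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        msgs <<- c(msgs, conditionMessage(m))
        invokeRestart("muffleMessage")
      }),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(coefficients = NULL, varcomp = NULL,
                          aic = NA_real_, logLik = NA_real_,
                          converged = FALSE, singular = NA,
                          messages = conditionMessage(fit),
                          n_obs = nrow(dat),
                          n_groups = length(unique(dat$user_id)),
                          spec = spec, formula = fml),
                     class = "lmm_fit"))
  }
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- est / se
  coefs <- data.frame(
    term = names(est), estimate = unname(est), se = unname(se),
    ci_lower = unname(est - stats::qnorm(0.975) * se),
    ci_upper = unname(est + stats::qnorm(0.975) * se),
    p_value = unname(2 * stats::pnorm(-abs(z))),
    row.names = NULL)
  vc <- lme4::VarCorr(fit)$user_id
  sds <- attr(vc, "stddev")
  corr <- attr(vc, "correlation")
  varcomp <- list(
    sd_intercept = unname(sds["(Intercept)"]),
    sd_slope = if ("depression" %in% names(sds)) unname(sds["depression"])
               else NA_real_,
    cor_intercept_slope = if (!is.null(corr) && "depression" %in% rownames(corr))
      unname(corr["(Intercept)", "depression"]) else NA_real_,
    sd_residual = stats::sigma(fit))
  # Gradient-based convergence checks are meaningless in the perfect-fit
  # limit (residual variance ~ 0), where the estimates are exact.
  converged <- !any(grepl("failed to converge|convergence code",
                          msgs, ignore.case = TRUE)) ||
    varcomp$sd_residual < 1e-8
  structure(list(coefficients = coefs, varcomp = varcomp,
                 aic = stats::AIC(fit), logLik = as.numeric(stats::logLik(fit)),
                 df = attr(stats::logLik(fit), "df"),
                 converged = converged, singular = lme4::isSingular(fit),
                 messages = msgs,
                 n_obs = nrow(dat), n_groups = length(unique(dat$user_id)),
                 spec = spec, formula = fml),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Linear mixed-effects fit (ML):", deparse(x$formula), "\n")
  if (!x$converged) cat("  ** did not converge **\n")
  if (isTRUE(x$singular)) cat("  (singular fit)\n")
  if (!is.null(x$coefficients)) {
    print(within(x$coefficients, {
      estimate <- round(estimate, 3); se <- round(se, 3)
      ci_lower <- round(ci_lower, 3); ci_upper <- round(ci_upper, 3)
      p_value <- signif(p_value, 3)
    }), row.names = FALSE)
    cat(sprintf("  AIC %.1f | n_obs %d, n_groups %d\n",
                x$aic, x$n_obs, x$n_groups))
  }
  invisible(x)
}

#' Exhaustive AIC model selection over candidate predictors
#'
#' Enumerates every admissible combination: all subsets of the level-1 and
#' level-2 candidates, all subsets of the candidate cross-level
#' interactions whose level-1 member is included, and each random-effect
#' option. Each model is fit by ML and ranked by AIC; among converged
#' models, ties are broken by fewer parameters, then lexicographic spec
#' id.
#'
#' @param table Analysis-ready long table.
#' @param level1_candidates,level2_candidates Character vectors from the
#'   [lmm_spec()] vocabularies.
#' @param interaction_candidates List of `c(level1, level2)` pairs.
#' @param random_candidates List of random-effect sets to try.
#' @return A list with `best_spec`, `best_fit`, and `ranking` (data frame
#'   of spec id, parameter count, AIC, convergence flag, ordered best
#'   first).
#' @export
select_model_aic <- function(table,
                             level1_candidates = c("depression", "anxiety",
                                                   "positive_affect", "week"),
                             level2_candidates = "psych_comorbidity",
                             interaction_candidates =
                               list(c("depression", "psych_comorbidity")),
                             random_candidates = list(
                               "intercept",
                               c("intercept", "depression_slope"))) {
  subsets <- function(x) {
    if (length(x) == 0L) return(list(character()))
    unlist(lapply(0:length(x), function(k)
      if (k == 0L) list(character())
      else apply(utils::combn(x, k), 2, identity, simplify = FALSE)),
      recursive = FALSE)
  }
  specs <- list()
  for (l1 in subsets(level1_candidates)) {
    for (l2 in subsets(level2_candidates)) {
      admissible <- Filter(function(p) p[1] %in% l1, interaction_candidates)
      for (ix in subsets_of_pairs(admissible)) {
        for (re in random_candidates) {
          if ("depression_slope" %in% re && !"depression" %in% l1) next
          specs[[length(specs) + 1L]] <- lmm_spec(
            level1_fixed = l1, level2_fixed = l2,
            cross_level_interactions = ix, random_effects = re)
        }
      }
    }
  }
  fits <- lapply(specs, function(s) {
    tryCatch(fit_lmm(table, s), error = function(e)
      structure(list(coefficients = NULL, aic = NA_real_, df = NA_real_,
                     converged = FALSE, messages = conditionMessage(e),
                     spec = s),
                class = "lmm_fit"))
  })
  ranking <- data.frame(
    spec_id = vapply(specs, spec_id, ""),
    n_par = vapply(fits, function(f) f$df %||% NA_integer_, 0),
    aic = vapply(fits, `[[`, 0, "aic"),
    converged = vapply(fits, `[[`, TRUE, "converged"),
    row.names = NULL)
  ok <- which(ranking$converged & is.finite(ranking$aic))
  if (length(ok) == 0L)
    stop("no candidate model converged; diagnostics: ",
         paste(unique(unlist(lapply(fits, `[[`, "messages"))), collapse = "; "))
  ord <- order(!ranking$converged, ranking$aic, ranking$n_par, ranking$spec_id)
  best_i <- ok[order(ranking$aic[ok], ranking$n_par[ok], ranking$spec_id[ok])][1]
  list(best_spec = specs[[best_i]], best_fit = fits[[best_i]],
       ranking = ranking[ord, , drop = FALSE])
}

subsets_of_pairs <- function(pairs) {
  if (length(pairs) == 0L) return(list(list()))
  out <- list(list())
  for (p in pairs) {
    out <- c(out, lapply(out, function(s) c(s, list(p))))
  }
  out
}

#' Parameter-recovery harness for the two-level model
#'
#' Generates `n_reps` datasets from the two-level equations, fits the
#' given model spec to each, and reports per-coefficient bias, RMSE, and
#' 95% CI coverage against the generating values. Non-converged replicates
#' are excluded and counted.
#'
#' @param gen An [lmm_gen_params()] (its `seed` is overridden per
#'   replicate, derived from `seed`).
#' @param spec An [lmm_spec()] matching the generator structure.
#' @param n_reps Number of replicates.
#' @param seed Master seed.
#' @return An object of class `recovery_report`: data frame `coefficients`
#'   with generating value, mean estimate, bias, RMSE, and coverage per
#'   fixed effect, plus `n_reps`, `n_converged`, `seed`.
#' @export
recover_parameters <- function(gen = lmm_gen_params(), spec = lmm_spec(),
                               n_reps = 200L, seed = 1L) {
  stopifnot(inherits(gen, "lmm_gen_params"), inherits(spec, "lmm_spec"))
  truth <- c("(Intercept)" = gen$gamma00, depression = gen$gamma10)
  if (any(vapply(spec$cross_level_interactions, function(p)
    identical(p, c("depression", "psych_comorbidity")), TRUE)))
    truth["depression:psych_comorbidity"] <- gen$gamma11
  est <- cover <- matrix(NA_real_, n_reps, length(truth),
                         dimnames = list(NULL, names(truth)))
  n_conv <- 0L
  for (r in seq_len(n_reps)) {
    g <- gen
    g$seed <- derive_seed(seed, r)
    # a replicate can draw a degenerate design (e.g. no comorbid
    # participants, leaving the interaction column zero); it is excluded
    # and counted like any other non-converged replicate
    fit <- tryCatch(fit_lmm(generate_lmm_dataset(g), spec),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged || is.null(fit$coefficients)) next
    n_conv <- n_conv + 1L
    cf <- fit$coefficients
    for (term in names(truth)) {
      i <- match(term, cf$term)
      if (is.na(i)) next
      est[r, term] <- cf$estimate[i]
      cover[r, term] <- truth[term] >= cf$ci_lower[i] &
        truth[term] <= cf$ci_upper[i]
    }
  }
  coefs <- data.frame(
    term = names(truth),
    generating = unname(truth),
    mean_estimate = colMeans(est, na.rm = TRUE),
    bias = colMeans(est, na.rm = TRUE) - unname(truth),
    rmse = sqrt(colMeans(sweep(est, 2, truth)^2, na.rm = TRUE)),
    coverage = colMeans(cover, na.rm = TRUE),
    row.names = NULL)
  structure(list(coefficients = coefs, n_reps = n_reps,
                 n_converged = n_conv, seed = seed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter recovery over", x$n_converged, "of", x$n_reps,
      "converged replicates (seed", paste0(x$seed, ")\n"))
  print(within(x$coefficients, {
    mean_estimate <- round(mean_estimate, 3); bias <- round(bias, 3)
    rmse <- round(rmse, 3); coverage <- round(coverage, 3)
  }), row.names = FALSE)
  invisible(x)
}

#' Feasibility summary of a study log
#'
#' Per-user app use rates with their median, range, mean, and SD (midpoint
#' convention for even-length medians, SD flagged undefined for a single
#' user), plus the median and range of the number of distinct behaviors
#' each user performed (preselected-and-done or logged as extras).
#'
#' @param log A [study_log()].
#' @param scheduled_days Denominator passed to [compute_use_rate()].
#' @return An object of class `feasibility_summary`.
#' @export
summarize_feasibility <- function(log, scheduled_days = 28) {
  validate_study_log(log)
  if (length(log$events) == 0L) stop("empty log: nothing to summarize")
  rates <- compute_use_rate(log, scheduled_days)
  uids <- names(rates)
  distinct <- vapply(uids, function(uid) {
    revs <- Filter(function(e) e$type == "review" && e$user_id == uid,
                   log$events)
    done <- unlist(lapply(revs, function(e)
      c(names(e$performed)[e$performed], e$extras)))
    length(unique(done))
  }, 0L)
  structure(list(
    use_rates = rates,
    use_rate_median = stats::median(rates),
    use_rate_range = range(rates),
    use_rate_mean = mean(rates),
    use_rate_sd = if (length(rates) >= 2L) stats::sd(rates) else NA_real_,
    distinct_behaviors_median = stats::median(distinct),
    distinct_behaviors_range = range(distinct),
    n_users = length(rates)),
    class = "feasibility_summary")
}

#' @export
print.feasibility_summary <- function(x, ...) {
  cat("Feasibility over", x$n_users, "users\n")
  cat(sprintf("  use rate: median %.1f%% (range %.1f-%.1f), mean %.1f%% (SD %s)\n",
              x$use_rate_median, x$use_rate_range[1], x$use_rate_range[2],
              x$use_rate_mean,
              if (is.na(x$use_rate_sd)) "undefined"
              else sprintf("%.1f", x$use_rate_sd)))
  cat(sprintf("  distinct behaviors performed: median %s (range %d-%d)\n",
              format(x$distinct_behaviors_median),
              x$distinct_behaviors_range[1], x$distinct_behaviors_range[2]))
  invisible(x)
}
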