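test_that("exact signed-rank p matches brute-force sign enumeration", {
  # all-positive differences at n = 6: two-sided p = 2/64
  w <- wilcoxon_signed_rank(1:6, 1:6 + seq(0.5, 3, by = 0.5))
  expect_identical(w$method, "exact")
  expect_equal(w$p_value, 2 / 64)
  expect_identical(w$n_effective, 6L)

  set.seed(51)
  for (rep in 1:30) {
    n <- sample(2:10, 1)
    pre <- rnorm(n)
    post <- pre + rnorm(n)
    if (rep %% 3 == 0) { # force tied absolute differences
      post <- pre + sample(c(-1, 1, 2, -2), n, replace = TRUE)
    }
    res <- wilcoxon_signed_rank(pre, post, mode = "exact")
    expect_equal(res$p_value, brute_force_signed_rank_p(post - pre),
                 tolerance = 1e-12,
                 label = sprintf("exact p (rep %d, n %d)", rep, n))
  }
})

test_that("signed-rank agrees with the reference implementation", {
  set.seed(52)
  # untied, exact path
  pre <- rnorm(15); post <- pre + rnorm(15)
  ours <- wilcoxon_signed_rank(pre, post)
  ref <- stats::wilcox.test(post, pre, paired = TRUE, exact = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(unname(ours$statistic), unname(ref$statistic))

  # ties => normal approximation with continuity + tie correction
  pre2 <- rep(c(10, 12, 14), 10)
  post2 <- pre2 + rep(c(1, -2, 2, 1, -1), 6)
  ours2 <- wilcoxon_signed_rank(pre2, post2)
  expect_identical(ours2$method, "normal approximation")
  ref2 <- suppressWarnings(
    stats::wilcox.test(post2, pre2, paired = TRUE, correct = TRUE))
  expect_equal(ours2$p_value, ref2$p.value, tolerance = 1e-12)
})

test_that("identical pre and post measurements give a degenerate result", {
  w <- wilcoxon_signed_rank(c(3, 4, 5), c(3, 4, 5))
  expect_true(w$degenerate)
  expect_identical(w$p_value, 1)
  expect_identical(w$n_effective, 0L)
})

test_that("noise-free data is recovered exactly by the mixed model", {
  g <- lmm_gen_params(sd_zeta0 = 0, sd_zeta1 = 0, sd_eps = 0,
                      psych_prob = 0.4, seed = 3)
  fit <- fit_lmm(generate_lmm_dataset(g))
  expect_true(fit$converged)
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(est[["(Intercept)"]], 4.45, tolerance = 1e-6)
  expect_equal(est[["depression"]], -1.88, tolerance = 1e-6)
  expect_equal(est[["depression:psych_comorbidity"]], 1.59, tolerance = 1e-6)
})

test_that("the fit is invariant to row order and user relabeling", {
  d <- generate_lmm_dataset(lmm_gen_params(seed = 17))
  fit <- fit_lmm(d)
  set.seed(1)
  d2 <- d[sample(nrow(d)), ]
  fit2 <- fit_lmm(d2)
  expect_equal(fit2$coefficients$estimate, fit$coefficients$estimate,
               tolerance = 1e-6)
  expect_equal(fit2$aic, fit$aic, tolerance = 1e-6)
  d3 <- d
  d3$user_id <- paste0("participant_", match(d$user_id, unique(d$user_id)))
  fit3 <- fit_lmm(d3)
  expect_equal(fit3$coefficients$estimate, fit$coefficients$estimate,
               tolerance = 1e-6)
})

test_that("degenerate designs are flagged or rejected with diagnostics", {
  d <- generate_lmm_dataset(lmm_gen_params(seed = 4))
  one <- d[d$user_id == "u01", ]
  fit1 <- fit_lmm(one, lmm_spec(cross_level_interactions = list()))
  expect_false(fit1$converged && !isTRUE(fit1$singular))

  d$dep_copy <- d$depression
  expect_error(fit_lmm(d, lmm_spec()), NA) # unrelated column is harmless
  d$anxiety <- d$depression
  expect_error(
    fit_lmm(d, lmm_spec(level1_fixed = c("depression", "anxiety"),
                        cross_level_interactions = list())),
    "rank-deficient")

  expect_error(lmm_spec(level1_fixed = "anxiety"),
               "requires the level-1 main effect")
  expect_error(lmm_spec(level1_fixed = "anxiety",
                        cross_level_interactions = list(),
                        random_effects = c("intercept", "depression_slope")),
               "random depression slope")
})

test_that("AIC selection finds the generating structure and breaks ties", {
  set.seed(61)
  hits <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    d <- generate_lmm_dataset(
      lmm_gen_params(gamma11 = 0, sd_zeta1 = 0, seed = 6000 + r))
    sel <- select_model_aic(d, level1_candidates = "depression",
                            level2_candidates = character(),
                            interaction_candidates = list(),
                            random_candidates = list("intercept"))
    if ("depression" %in% sel$best_spec$level1_fixed) hits <- hits + 1L
  }
  expect_gt(hits, n_rep / 2) # strong generating effect is selected

  # null data: the intercept-only model wins a plurality
  null_hits <- 0L
  for (r in seq_len(n_rep)) {
    d <- generate_lmm_dataset(
      lmm_gen_params(gamma10 = 0, gamma11 = 0, sd_zeta1 = 0,
                     seed = 7000 + r))
    sel <- select_model_aic(d, level1_candidates = "depression",
                            level2_candidates = character(),
                            interaction_candidates = list(),
                            random_candidates = list("intercept"))
    if (length(sel$best_spec$level1_fixed) == 0L) null_hits <- null_hits + 1L
  }
  expect_gt(null_hits, n_rep / 2)

  # duplicated candidates tie exactly; the tie-break is deterministic
  d <- generate_lmm_dataset(lmm_gen_params(seed = 5))
  sel_dup <- select_model_aic(d, level1_candidates = "depression",
                              level2_candidates = character(),
                              interaction_candidates = list(),
                              random_candidates = list("intercept", "intercept"))
  sel_dup2 <- select_model_aic(d, level1_candidates = "depression",
                               level2_candidates = character(),
                               interaction_candidates = list(),
                               random_candidates = list("intercept", "intercept"))
  expect_identical(sel_dup$best_fit$coefficients, sel_dup2$best_fit$coefficients)
  # and among equal-AIC models the smaller one is preferred
  expect_lte(sel_dup$ranking$n_par[1], max(sel_dup$ranking$n_par))
})

test_that("parameter recovery is unbiased in the noise-free limit and seeded", {
  g0 <- lmm_gen_params(sd_zeta0 = 0, sd_zeta1 = 0, sd_eps = 0,
                       psych_prob = 0.4)
  rep0 <- recover_parameters(g0, n_reps = 5, seed = 2)
  expect_identical(rep0$n_converged, 5L)
  expect_true(all(abs(rep0$coefficients$bias) < 1e-6))

  r1 <- recover_parameters(n_reps = 5, seed = 9)
  r2 <- recover_parameters(n_reps = 5, seed = 9)
  expect_identical(r1$coefficients, r2$coefficients)
})

test_that("feasibility summaries use median, range, mean, SD conventions", {
  day_reviews <- function(days, uid)
    lapply(days, function(d)
      review_event(uid, sprintf("2026-01-%02dT20:00:00", d),
                   setNames(TRUE, paste0("b", d %% 3 + 1))))
  users <- lapply(sprintf("u%02d", 1:3), function(u) list(user_id = u, seed = 1L))
  # rates 80 / 90 / 100 under a 10-day schedule
  log <- study_log(users, c(day_reviews(1:8, "u01"),
                            day_reviews(1:9, "u02"),
                            day_reviews(1:10, "u03")))
  fs <- summarize_feasibility(log, scheduled_days = 10)
  expect_identical(fs$use_rate_median, 90)
  expect_identical(fs$use_rate_range, c(80, 100))
  expect_identical(fs$use_rate_mean, 90)
  expect_identical(fs$distinct_behaviors_range[2], 3L)

  # single user: every statistic collapses to that rate, SD undefined
  log1 <- study_log(users[1], day_reviews(1:8, "u01"))
  fs1 <- summarize_feasibility(log1, scheduled_days = 10)
  expect_identical(fs1$use_rate_median, 80)
  expect_identical(fs1$use_rate_mean, 80)
  expect_true(is.na(fs1$use_rate_sd))

  expect_error(summarize_feasibility(study_log(users[1], list())), "empty log")
})
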