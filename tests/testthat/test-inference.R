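test_that("candidate enumeration covers all subsets including intercept-only", {
  cand <- enumerate_candidates()
  expect_equal(nrow(cand), 8)
  expect_equal(cand$label[1], "1")
  expect_equal(sum(lengths(cand$terms) == 3), 1)

  expect_equal(nrow(enumerate_candidates("population")), 2)
  expect_equal(nrow(enumerate_candidates(character(0))), 1)
})

test_that("AICc reproduces the published worked examples and the closed form", {
  expect_equal(round(aicc(-567.47, k = 4, n = 633), 2), 1143.00)
  expect_equal(round(aicc(-536.35, k = 6, n = 787), 2), 1084.81)
  expect_equal(aicc(0, k = 1, n = 100), 2 + 4 / 98)
  expect_error(aicc(0, k = 10, n = 11), "undefined")
})

test_that("delta-AICc and Akaike weights match printed values and symmetries", {
  pub <- published_selection_tables()
  for (blk in split(pub, paste(pub$response, pub$measure))) {
    w <- akaike_weights(min(blk$AICc) + blk$delta)
    expect_equal(w$delta, blk$delta, tolerance = 1e-9)
    expect_equal(round(w$weight, 2), blk$weight)
    expect_equal(sum(w$weight), 1, tolerance = 1e-9)
  }
  expect_equal(akaike_weights(5)$weight, 1)
  expect_equal(akaike_weights(c(3, 3))$weight, c(0.5, 0.5))
  # adding a constant to all AICc (equivalently loglik) changes nothing
  a <- c(100, 101.3, 104)
  expect_equal(akaike_weights(a), akaike_weights(a + 57.3))
  # AICc converges to AIC for large n
  expect_lt(abs(aicc(-500, 5, 1e6) - (2 * 500 + 10)), 1e-3)
})

test_that("the delta < 2 retention rule keeps exactly the published bold rows", {
  pub <- published_selection_tables()
  t2a <- pub[pub$response == "timescale" & pub$measure == "absolute", ]
  kept <- retained_set(t2a$delta)
  expect_equal(sum(kept), 5)
  expect_equal(max(t2a$delta[kept]), 1.78)
  expect_equal(min(t2a$delta[!kept]), 2.26)
})

test_that("candidate fitting matches degenerate-case closed forms", {
  set.seed(33)
  # balanced binary outcome, no birth-year structure: logit intercept ~ 0
  d <- tibble::tibble(
    dominant_scale_binary = rep(c(0L, 1L), 50),
    birth_year = factor(rep(2000:2009, each = 10)),
    population = factor("A"), sex = factor("female"),
    mean_individual_clutch = 8
  )
  f <- fit_candidate(d, "dominant_scale_binary", family = "binomial")
  expect_lt(abs(unname(lme4::fixef(f$fit)[1])), 1e-3)
  expect_lt(unname(unlist(lme4::VarCorr(f$fit))), 1e-3)

  # gaussian with exactly zero between-birth-year variance (the same
  # residual pattern repeats in every year): fixed effects equal OLS
  block <- tibble::tibble(
    amplitude_long = exp(0.5 + 0.3 * ((1:20) %% 2) +
                           0.4 * scale(rnorm(20))[, 1]),
    population = factor(rep(c("A", "B"), each = 10)),
    sex = factor(rep(c("female", "male"), 10))
  )
  d2 <- dplyr::bind_rows(lapply(2000:2009, function(y)
    dplyr::mutate(block, birth_year = factor(y, levels = 2000:2009))))
  d2$mean_individual_clutch <- 8
  f2 <- fit_candidate(d2, "amplitude_long", terms = c("population", "sex"),
                      family = "gaussian", transform = "log")
  expect_lt(unname(unlist(lme4::VarCorr(f2$fit)))[1], 1e-3)
  ols <- stats::lm(log(amplitude_long) ~ population + sex, data = d2)
  expect_equal(unname(lme4::fixef(f2$fit)), unname(stats::coef(ols)),
               tolerance = 1e-5)

  # zero amplitudes must be dropped before a log fit
  d3 <- d2
  d3$amplitude_long[1] <- 0
  expect_error(fit_candidate(d3, "amplitude_long", family = "gaussian",
                             transform = "log"), "drop_zero")
  dz <- drop_zero_amplitudes(d3, "amplitude_long")
  expect_equal(dz$n_dropped, 1L)
  expect_equal(nrow(dz$data), nrow(d2) - 1)
})

test_that("logistic fixed effects are recovered from a known generating model", {
  set.seed(91)
  n <- 2000
  b_pop <- 1.0
  b_sex <- -0.5
  sd_year <- sqrt(0.1)
  pop <- factor(sample(c("A", "B"), n, TRUE))
  sex <- factor(sample(c("female", "male"), n, TRUE))
  year <- factor(sample(2000:2014, n, TRUE))
  u <- rnorm(nlevels(year), 0, sd_year)
  eta <- 0.2 + b_pop * (pop == "B") + b_sex * (sex == "male") +
    u[as.integer(year)]
  d <- tibble::tibble(
    dominant_scale_binary = rbinom(n, 1, stats::plogis(eta)),
    population = pop, sex = sex, birth_year = year,
    mean_individual_clutch = 8
  )
  f <- fit_candidate(d, "dominant_scale_binary",
                     terms = c("population", "sex"), family = "binomial")
  est <- lme4::fixef(f$fit)
  se <- sqrt(diag(as.matrix(stats::vcov(f$fit))))
  expect_lt(abs(est[["populationB"]] - b_pop), 3 * se[2])
  expect_lt(abs(est[["sexmale"]] - b_sex), 3 * se[3])
})

test_that("model selection ranks, weights and averages the candidate set", {
  sim <- simulate_study(list(pop_preset("fast"), pop_preset("slow")),
                        n_per_pop = 150, seed = 21)
  prep <- prepare_series(sim$records)
  cls <- ric_classify_cohort(prep$series, "absolute")
  at <- analysis_table(cls)
  sel <- model_selection(at, "dominant_scale_binary", family = "binomial")
  expect_equal(nrow(sel$table), 8)
  expect_equal(sel$table$delta[1], 0)
  expect_equal(sum(sel$table$weight), 1, tolerance = 1e-9)
  expect_true(sel$table$retained[1])
  expect_true(all(diff(sel$table$AICc) >= 0))
  expect_equal(sel$table$AICc,
               -2 * sel$table$logLik + 2 * sel$table$df +
                 2 * sel$table$df * (sel$table$df + 1) /
                   (sel$n_obs - sel$table$df - 1),
               tolerance = 1e-9)

  avg <- average_models(sel)
  expect_true("(Intercept)" %in% avg$term)
  expect_true(all(is.finite(avg$estimate)))

  # averaging identical coefficients returns them unchanged (convexity)
  sel2 <- sel
  sel2$table$retained <- c(TRUE, TRUE, rep(FALSE, 6))
  b1 <- lme4::fixef(sel2$fits[[1]]$fit)[["(Intercept)"]]
  b2 <- lme4::fixef(sel2$fits[[2]]$fit)[["(Intercept)"]]
  avg2 <- average_models(sel2)
  got <- avg2$estimate[avg2$term == "(Intercept)"]
  expect_true(got >= min(b1, b2) - 1e-12 && got <= max(b1, b2) + 1e-12)

  # single-candidate selection: weight 1, average = own coefficients
  sel1 <- model_selection(at, "dominant_scale_binary", family = "binomial",
                          fixed_pool = character(0))
  expect_equal(sel1$table$weight, 1)
  avg1 <- average_models(sel1)
  expect_equal(avg1$estimate,
               unname(lme4::fixef(sel1$fits[[1]]$fit)))
})

test_that("full-averaging shrinks terms missing from some retained models", {
  sim <- simulate_study(list(pop_preset("fast"), pop_preset("slow")),
                        n_per_pop = 120, seed = 8)
  prep <- prepare_series(sim$records)
  at <- analysis_table(ric_classify_cohort(prep$series, "absolute"))
  sel <- model_selection(at, "dominant_scale_binary", family = "binomial")
  cond <- average_models(sel, method = "conditional")
  full <- average_models(sel, method = "full")
  for (tm in setdiff(cond$term, "(Intercept)")) {
    nc <- cond$n_models[cond$term == tm]
    if (nc < sum(sel$table$retained)) {
      expect_lte(abs(full$estimate[full$term == tm]),
                 abs(cond$estimate[cond$term == tm]) + 1e-12)
    }
  }
})

test_that("marginal means back-transform to the response scale", {
  set.seed(14)
  # intercept-only logistic model with balanced outcome: EMM ~ 0.5
  d <- tibble::tibble(
    dominant_scale_binary = rep(c(0L, 1L), 60),
    birth_year = factor(rep(2000:2009, each = 12)),  # balanced within year
    population = factor(rep(c("A", "B"), 60)),
    sex = factor("female"), mean_individual_clutch = 8
  )
  f <- fit_candidate(d, "dominant_scale_binary", family = "binomial")
  mm <- ric_marginal_means(f, "population")
  expect_equal(mm$level, "overall")
  expect_match(mm$note[1], "not in model")
  expect_equal(mm$estimate, 0.5, tolerance = 1e-6)

  # gaussian log-scale model: EMMs equal hand-computed inverse-link values
  n <- 400
  pop <- factor(rep(c("A", "B"), each = n / 2))
  sex <- factor(rep(c("female", "male"), n / 2))
  y <- exp(0.2 + 0.6 * (pop == "B") - 0.3 * (sex == "male") +
             rnorm(n, 0, 0.3))
  d2 <- tibble::tibble(amplitude_long = y, population = pop, sex = sex,
                       mean_individual_clutch = 8,
                       birth_year = factor(rep(2000:2009, 40)))
  f2 <- fit_candidate(d2, "amplitude_long", terms = c("population", "sex"),
                      family = "gaussian", transform = "log")
  mm2 <- ric_marginal_means(f2, "population")
  b <- lme4::fixef(f2$fit)
  hand_a <- exp(b[["(Intercept)"]] + 0.5 * b[["sexmale"]])
  hand_b <- exp(b[["(Intercept)"]] + b[["populationB"]] +
                  0.5 * b[["sexmale"]])
  expect_equal(mm2$estimate[mm2$level == "A"], unname(hand_a),
               tolerance = 1e-6)
  expect_equal(mm2$estimate[mm2$level == "B"], unname(hand_b),
               tolerance = 1e-6)
  expect_true(all(mm2$se > 0))
})

test_that("analysis table extracts scale-specific amplitudes and the binary response", {
  recs <- dplyr::bind_rows(
    # dominant long (lambda 6, A 3) + secondary short (lambda 2, A 1)
    toy_series_records("mix", 2001:2006,
                       round(8 + 1.5 * cos(2 * pi * (0:5) / 6) +
                               0.5 * cos(pi * (0:5)))),
    # pure alternation: short only
    toy_series_records("alt", 2001:2004, c(7, 9, 7, 9))
  )
  cls <- ric_classify_cohort(build_series(recs)$series, "absolute")
  at <- analysis_table(cls, ref_sex = "female")
  mix <- at[at$individual_id == "mix", ]
  expect_equal(mix$dominant_scale_binary, 1L)
  expect_false(is.na(mix$amplitude_long))
  expect_false(is.na(mix$amplitude_short))
  expect_gt(mix$amplitude_long, mix$amplitude_short)
  alt <- at[at$individual_id == "alt", ]
  expect_equal(alt$dominant_scale_binary, 0L)
  expect_equal(alt$amplitude_short, 2, tolerance = 1e-9)
  expect_true(is.na(alt$amplitude_long))
  expect_equal(levels(at$sex)[1], "female")
})
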