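test_that("noise-free scores are interpolated exactly", {
  sc <- simulate_scores(n = 150,
                        beta = c(age = 2e-4, sex = 1e-3, decade = 5e-4,
                                 hurricane_yn = 2e-3),
                        sigma_matriline = 0, sigma_resid = 0, seed = 2)
  fit <- suppressWarnings(suppressMessages(fa_lmm(sc, "hurricane_yn")))
  est <- fit$coefficients$estimate
  names(est) <- fit$coefficients$term
  expect_equal(est[["(Intercept)"]], 0.015, tolerance = 1e-6)
  expect_equal(est[["age_at_death"]], 2e-4, tolerance = 1e-6)
  expect_equal(est[["sexM"]], 1e-3, tolerance = 1e-6)
  expect_equal(est[["decade_trend"]], 5e-4, tolerance = 1e-6)
  expect_equal(est[["hurricane_ynyes"]], 2e-3, tolerance = 1e-6)
})

test_that("with zero matriline variance the fixed effects agree with OLS", {
  sc <- simulate_scores(n = 200, beta = c(hurricane_yn = 1e-3),
                        sigma_matriline = 0, sigma_resid = 0.004, seed = 4)
  fit <- fa_lmm(sc, "hurricane_yn")
  ols <- lm(fa_score ~ age_at_death + sex +
              I((decade_of_birth - 1950) / 10) +
              I(n_hurricanes > 0), data = sc)
  expect_equal(unname(fit$coefficients$estimate),
               unname(coef(ols)), tolerance = 1e-4)
  # t = estimate / SE must hold exactly in the reported table
  expect_equal(fit$coefficients$t_value,
               fit$coefficients$estimate / fit$coefficients$std_error,
               tolerance = 1e-9)
})

test_that("estimates are invariant to relabeling matrilines and row order", {
  sc <- simulate_scores(n = 150, beta = c(sex = 1e-3), seed = 6)
  f1 <- fa_lmm(sc, "hurricane_yn")
  sc2 <- sc[sample(nrow(sc)), ]
  sc2$matriline <- factor(paste0("zz_", as.character(sc2$matriline)))
  f2 <- fa_lmm(sc2, "hurricane_yn")
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-8)
  expect_equal(unname(f1$varcomp), unname(f2$varcomp), tolerance = 1e-6)
})

test_that("reported Satterthwaite df are fractional and bounded by n", {
  sc <- simulate_scores(n = 150, seed = 8, sigma_matriline = 0.002)
  fit <- fa_lmm(sc, "hurricane_yn")
  expect_true(all(fit$coefficients$df > 0))
  expect_true(all(fit$coefficients$df <= fit$n_obs))
})

test_that("degenerate model inputs raise informative errors", {
  sc <- simulate_scores(n = 60, seed = 10)
  one_sex <- sc[sc$sex == "F", ]
  expect_error(fa_lmm(one_sex, "none"), "'sex'")
  sc$matriline <- "only_one"
  expect_error(fa_lmm(sc, "none"), "matriline")
  tiny <- simulate_scores(n = 60, seed = 12)[1:4, ]
  expect_error(fa_lmm(tiny, "none"), "fewer observations|single observed")
  exposed_leak <- simulate_scores(n = 60, seed = 13)
  expect_error(fa_lmm(exposed_leak, "age_at_hurricane"), "subset")
})

test_that("the four-model suite applies the subsetting rules", {
  sc <- simulate_scores(n = 275, seed = 14)
  suite <- fa_model_suite(sc)
  expect_named(suite, c("model1", "model2", "model3", "model4"))
  expect_equal(suite$model1$n_obs, 275)
  expect_equal(suite$model2$n_obs, 174)   # never-exposed subset
  expect_equal(suite$model3$n_obs, 275)
  expect_equal(suite$model4$n_obs, 101)   # exposed subset
  expect_equal(suite$model2$hurricane_term, "none")
  # model 3 reports separate rows for 1 and 2 hurricanes
  expect_true(all(c("n_hurricanes1", "n_hurricanes2") %in%
                    suite$model3$coefficients$term))
  # model 4 contrasts juvenile and adult against the fetal reference
  expect_true(all(c("age_at_hurricanejuvenile", "age_at_hurricaneadult") %in%
                    suite$model4$coefficients$term))
})

test_that("post hoc Tukey contrasts carry Holm-adjusted p-values obeying the
           closed form", {
  sc <- simulate_scores(n = 275, beta = c(juvenile = -6e-3, adult = -7e-3),
                        seed = 16)
  suite <- fa_model_suite(sc)
  ctr <- posthoc_holm(suite$model4, "age_at_hurricane")
  expect_equal(nrow(ctr), 3)  # fetal-juvenile, fetal-adult, juvenile-adult
  # Holm closed form: adjusted_(i) = max_{j<=i} min(1, (m-j+1) p_(j))
  ord <- order(ctr$p_raw)
  m <- nrow(ctr)
  adj <- cummax(pmin(1, (m - seq_len(m) + 1) * ctr$p_raw[ord]))
  expect_equal(ctr$p_holm[ord], adj, tolerance = 1e-12)
  expect_true(all(ctr$p_holm >= ctr$p_raw - 1e-15))
  # the two fetal contrasts carry the large injected offsets
  fetal_rows <- grepl("fetal", ctr$contrast)
  expect_true(all(ctr$p_holm[fetal_rows] < 0.05))
  expect_error(posthoc_holm(suite$model2, "age_at_hurricane"), "not a term")
})

test_that("a single level shifted by a large offset drives only its own
           contrasts", {
  sc <- simulate_scores(n = 275, beta = c(juvenile = 0.02), seed = 18)
  suite <- fa_model_suite(sc)
  ctr <- posthoc_holm(suite$model4, "age_at_hurricane")
  juv <- grepl("juvenile", ctr$contrast)
  expect_true(all(ctr$p_holm[juv] < 0.01))
  expect_true(all(ctr$p_holm[!juv] > 0.05))
})

test_that("power simulation saturates at huge effects and stays near alpha
           at zero effect", {
  pw <- power_simulation(effect_grid_pct = c(0, 300), n_sims = 40,
                         alpha = 0.05, seed = 3, n = 150)
  expect_true(all(pw$power >= 0 & pw$power <= 1))
  # effect of 300% of the mean is ~11 residual SDs: certain detection
  expect_equal(pw$power[2], 1)
  # null power within 2 Monte-Carlo SEs of alpha (binomial SE at n=40)
  expect_lt(abs(pw$power[1] - 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 40))
  expect_equal(attr(pw, "detectable"), 300)
})
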