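test_that("templates are symmetric, midline-on-plane and non-degenerate", {
  for (seedling in c(1, 7, 19)) {
    tmpl <- make_template(13, 8, geometry_seed = seedling)
    sc <- sim_scheme(13, 8)
    expect_equal(nrow(tmpl), 34)
    expect_matrix_equal(reflect_relabel(tmpl, sc), tmpl, tol = 1e-12)
    expect_equal(tmpl[sc$midline, 1], rep(0, 8))
    expect_gt(centroid_size(tmpl), 0)
  }
})

test_that("simulation is reproducible from its seed alone", {
  p <- sim_params(n = 6, r = 2, p = 3, u = 2, seed = 77)
  d1 <- simulate_dataset(p)
  d2 <- simulate_dataset(p)
  expect_identical(lapply(d1$configs, `[[`, "coords"),
                   lapply(d2$configs, `[[`, "coords"))
  expect_identical(d1$metadata, d2$metadata)
  d3 <- simulate_dataset(sim_params(n = 6, r = 2, p = 3, u = 2, seed = 78))
  expect_false(identical(d1$configs[[1]]$coords, d3$configs[[1]]$coords))
})

test_that("generator subspaces are exact eigen-spaces of reflect_relabel", {
  sc <- sim_scheme(4, 3)
  set.seed(8)
  for (i in 1:10) {
    s <- fluctasym:::sym_deviation(sc, 1)
    a <- fluctasym:::asym_deviation(sc, 1)
    expect_identical(reflect_relabel(s, sc), s)
    expect_identical(reflect_relabel(a, sc), -a)
    expect_lt(abs(sum(s * a)), 1e-12)
  }
})

test_that("subspace ranks match the pre-alignment dimension counts", {
  sc <- sim_scheme(3, 2)
  set.seed(12)
  m <- 60
  sym_draws <- t(vapply(seq_len(m), function(i)
    as.vector(fluctasym:::sym_deviation(sc, 1)), numeric(24)))
  asym_draws <- t(vapply(seq_len(m), function(i)
    as.vector(fluctasym:::asym_deviation(sc, 1)), numeric(24)))
  # 3p + 2u = 13 symmetric directions, 3p + u = 11 asymmetric, of 3(2p+u)=24
  expect_equal(qr(sym_draws)$rank, 13)
  expect_equal(qr(asym_draws)$rank, 11)
})

test_that("zero digitizing error makes replicates identical up to the
           nuisance transform and kills the error stratum", {
  ds <- simulate_dataset(sim_params(n = 6, r = 2, p = 3, u = 2,
                                    sigma_err = 0, seed = 15))
  fit <- procrustes_fa(ds)
  expect_lt(fit$anova$ss[4], 1e-12)
  # pre-transform equality shows through superimposition
  expect_lt(max(abs(fit$sym[, , 1] - fit$sym[, , 2])), 1e-9)
})

test_that("null generator (no FA, no DA) gives near-zero scores and a
           calibrated side effect", {
  ds <- simulate_dataset(sim_params(n = 10, r = 2, p = 3, u = 2,
                                    sigma_fa = 0, da_magnitude = 0,
                                    seed = 29))
  fit <- procrustes_fa(ds)
  # all asymmetry is digitizing noise: the score noise floor is about
  # sqrt(d_asym / r) * sigma_err = sqrt(8 / 2) * 0.0027 = 0.0054
  expect_lt(mean(fit$scores$fa_score), 0.01)
  expect_gt(fit$anova$p[2], 1e-6)  # side effect no longer overwhelming
})

test_that("metadata mirrors the study composition and maturity rule", {
  p <- sim_params(n = 275, seed = 3)
  set.seed(3)
  md <- read_metadata(fluctasym:::simulate_metadata(p))
  expect_equal(nrow(md), 275)
  expect_equal(sum(md$n_hurricanes > 0), 101)
  expect_equal(as.vector(table(md$age_at_hurricane))[1:3], c(10, 50, 41))
  # individuals exposed as adults died after skeletal maturity
  ad <- md[md$age_at_hurricane == "adult", ]
  expect_true(all(maturity_class(ad$age_at_death, as.character(ad$sex))
                  == "adult"))
})

test_that("score-level generator recovers its own coefficients exactly when
           noise-free", {
  sc <- simulate_scores(n = 120, beta = c(age = 2e-4, sex = 1e-3),
                        sigma_matriline = 0, sigma_resid = 0, seed = 1)
  # deterministic scores: a plain linear model reproduces the coefficients
  fit <- lm(fa_score ~ age_at_death + I(sex == "M"), data = sc)
  expect_equal(unname(coef(fit)), c(0.015, 2e-4, 1e-3), tolerance = 1e-10)
})
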