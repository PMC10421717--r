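test_that("symmetric and asymmetric components are exactly orthogonal and
           satisfy the Pythagorean decomposition", {
  ds <- small_dataset(n = 8, r = 2, p = 3, u = 2, seed = 13)
  fit <- procrustes_fa(ds)
  nr <- dim(fit$sym)[3]
  for (j in seq_len(nr)) {
    s <- fit$sym[, , j]; a <- fit$asym[, , j]
    # direct inner product between the two components
    expect_lt(abs(sum(s * a)), 1e-9)
    total <- s + a  # aligned original minus consensus
    expect_lt(abs(sum(s^2) + sum(a^2) - sum(total^2)) /
                max(sum(total^2), 1e-300), 1e-9)
  }
})

test_that("components live in the reflection-invariant / anti-invariant
           subspaces", {
  ds <- small_dataset(n = 6, r = 2, p = 3, u = 2, seed = 17)
  fit <- procrustes_fa(ds)
  sc <- ds$scheme
  expect_matrix_equal(reflect_relabel(fit$consensus, sc), fit$consensus,
                      tol = 1e-6)
  for (j in seq_len(dim(fit$sym)[3])) {
    expect_matrix_equal(reflect_relabel(fit$sym[, , j], sc), fit$sym[, , j],
                        tol = 1e-9)
    expect_matrix_equal(reflect_relabel(fit$asym[, , j], sc),
                        -fit$asym[, , j], tol = 1e-9)
  }
})

test_that("a mirror-symmetric configuration has zero asymmetric component", {
  sc <- sim_scheme(3, 2)
  tmpl <- make_template(3, 2, geometry_seed = 8)
  # two identical symmetric specimens (plus replicates) => asymmetry 0
  configs <- list()
  for (i in 1:2) for (j in 1:2)
    configs[[length(configs) + 1]] <-
      landmark_config(paste0("s", i), j, tmpl * (1 + 0.1 * i), sc)
  fit <- procrustes_fa(fa_dataset(configs, NULL, sc))
  expect_lt(max(abs(fit$asym)), 1e-9)
  expect_true(all(fit$scores$fa_score < 1e-9))
})

test_that("known symmetric/asymmetric perturbations are recovered", {
  sc <- sim_scheme(3, 2)
  tmpl <- make_template(3, 2, geometry_seed = 4)
  set.seed(99)
  # draws in the two generator subspaces (exact eigen-spaces of
  # reflect_relabel) with small magnitude, no noise
  s_vec <- local({set.seed(1); fluctasym:::sym_deviation(sc, 2e-4)})
  a_vec <- local({set.seed(2); fluctasym:::asym_deviation(sc, 2e-4)})
  configs <- list()
  for (i in 1:3) for (j in 1:2) {
    shape <- tmpl + (i - 2) * s_vec + (i - 2) * a_vec
    configs[[length(configs) + 1]] <-
      landmark_config(paste0("s", i), j, shape, sc)
  }
  fit <- procrustes_fa(fa_dataset(configs, NULL, sc))
  # individual 1 and 3 carry opposite asymmetries, individual 2 none:
  # recovered asymmetric components must mirror that structure
  ids <- fit$obs$specimen_id
  a1 <- fit$asym[, , which(ids == "s1")[1]]
  a2 <- fit$asym[, , which(ids == "s2")[1]]
  a3 <- fit$asym[, , which(ids == "s3")[1]]
  expect_lt(max(abs(a2)), 1e-6)
  expect_matrix_equal(a1, -a3, tol = 1e-6)
  # the recovered magnitude equals the injected vector after projecting
  # out the similarity directions absorbed by superimposition
  # (translations, scale, infinitesimal rotations of the template)
  expect_equal(sqrt(sum(a3^2)), proj_norm(a_vec, tmpl), tolerance = 5e-3)
})

test_that("FA scores: hand-set asymmetries give direct norms", {
  # three individuals with asymmetric components 0, +v, -v and DA = 0:
  # scores must be (0, ||v*||, ||v*||), where v* is v with the similarity
  # directions that superimposition absorbs projected out; built through
  # the full pipeline with replicate-identical, noise-free shapes
  sc <- sim_scheme(3, 2)
  tmpl <- make_template(3, 2, geometry_seed = 4)
  a_vec <- local({set.seed(2); fluctasym:::asym_deviation(sc, 4e-4)})
  configs <- list()
  shapes <- list(tmpl, tmpl + a_vec, tmpl - a_vec)
  for (i in 1:3) for (j in 1:2)
    configs[[length(configs) + 1]] <-
      landmark_config(paste0("s", i), j, shapes[[i]], sc)
  fit <- procrustes_fa(fa_dataset(configs, NULL, sc))
  v <- proj_norm(a_vec, tmpl)
  sco <- fit$scores[match(c("s1", "s2", "s3"), fit$scores$specimen_id), ]
  expect_equal(sco$fa_score, c(0, v, v), tolerance = 5e-3)
})

test_that("with no FA and no digitizing error all FA scores vanish", {
  ds <- simulate_dataset(sim_params(n = 8, r = 2, p = 3, u = 2,
                                    sigma_fa = 0, sigma_err = 0,
                                    da_magnitude = 0, seed = 23))
  fit <- procrustes_fa(ds)
  expect_true(all(fit$scores$fa_score < 1e-9))
})

test_that("doubling all asymmetric deviations doubles FA scores within 1%", {
  p1 <- sim_params(n = 10, r = 2, p = 3, u = 2, seed = 31)
  p2 <- sim_params(n = 10, r = 2, p = 3, u = 2, seed = 31,
                   sigma_fa = 2 * p1$sigma_fa,
                   da_magnitude = 2 * p1$da_magnitude,
                   sigma_err = 0)
  p1 <- sim_params(n = 10, r = 2, p = 3, u = 2, seed = 31, sigma_err = 0)
  s1 <- procrustes_fa(simulate_dataset(p1))$scores
  s2 <- procrustes_fa(simulate_dataset(p2))$scores
  expect_equal(s2$fa_score / s1$fa_score, rep(2, 10), tolerance = 0.01)
})

test_that("pipeline outputs are invariant to fresh rigid motions and
           scalings of every input configuration", {
  ds <- small_dataset(n = 8, r = 2, p = 3, u = 2, seed = 37)
  fit1 <- procrustes_fa(ds)
  set.seed(101)
  jiggled <- ds
  jiggled$configs <- lapply(ds$configs, function(cf) {
    cf$coords <- apply_transform(cf$coords, random_rotation(),
                                 runif(3, -10, 10), exp(runif(1, -0.7, 0.7)))
    cf
  })
  fit2 <- procrustes_fa(jiggled)
  expect_equal(fit2$scores$fa_score, fit1$scores$fa_score, tolerance = 1e-6)
  expect_equal(fit2$anova$ss, fit1$anova$ss, tolerance = 1e-6)
})

test_that("single-replicate data is rejected with a clear message", {
  ds <- small_dataset(n = 5, r = 2, seed = 3)
  singles <- Filter(function(cf) cf$replicate_id == 1L, ds$configs)
  ds1 <- fa_dataset(singles, ds$metadata, ds$scheme)
  expect_error(procrustes_fa(ds1), "measurement error")
})
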