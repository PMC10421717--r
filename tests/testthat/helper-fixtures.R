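# shared fixtures: small schemes and datasets built in code

# 2 bilateral pairs + 1 midline point
toy_scheme <- function() {
  landmark_scheme(pairs = rbind(c(1L, 3L), c(2L, 4L)), midline = 5L)
}

# a small but non-trivial simulated dataset
small_dataset <- function(n = 10, r = 2, p = 3, u = 2, seed = 11, ...) {
  simulate_dataset(sim_params(n = n, r = r, p = p, u = u, seed = seed, ...))
}

# metadata table mirroring the study composition at arbitrary n
study_metadata <- function(n = 275, seed = 5) {
  simulate_scores(n = n, seed = seed)
}

expect_matrix_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(a - b)), tol)
}

# norm of a perturbation after projecting out the similarity directions
# (3 translations, uniform scaling, 3 infinitesimal rotations) at a
# template shape; direct linear algebra, independent of the GPA code
proj_norm <- function(dev, tmpl) {
  k <- nrow(tmpl)
  j1 <- rbind(c(0, 0, 0), c(0, 0, -1), c(0, 1, 0))
  j2 <- rbind(c(0, 0, 1), c(0, 0, 0), c(-1, 0, 0))
  j3 <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 0))
  basis <- cbind(
    as.vector(matrix(rep(c(1, 0, 0), each = k), k)),
    as.vector(matrix(rep(c(0, 1, 0), each = k), k)),
    as.vector(matrix(rep(c(0, 0, 1), each = k), k)),
    as.vector(tmpl),
    as.vector(tmpl %*% t(j1)),
    as.vector(tmpl %*% t(j2)),
    as.vector(tmpl %*% t(j3))
  )
  q <- qr.Q(qr(basis))
  v <- as.vector(dev)
  sqrt(sum((v - q %*% crossprod(q, v))^2))
}
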