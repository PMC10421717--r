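#' Simulation parameters for synthetic cranial landmark data
#'
#' Bundles every knob of the landmark-data generator. The generator mimics
#' the statistical structure a replicate-digitized bilateral landmark study
#' assumes: individual symmetric shape variation, a fixed population-wide
#' directional asymmetry, individual-specific fluctuating asymmetry
#' (optionally inflated in exposure groups), and per-digitization
#' measurement error, each injected in the appropriate shape subspace of a
#' symmetric template, followed by an arbitrary rigid motion and scaling of
#' every configuration.
#'
#' Default magnitudes are calibrated so that, at the default study design
#' (275 individuals, 2 replicates, 13 pairs + 8 midline landmarks), the
#' Procrustes ANOVA strata occupy roughly 91 / 0.3 / 3.6 / 5 percent of the
#' total variation and the mean FA score is about 0.015 — the regime typical
#' of replicate-digitized cranial data.
#'
#' @param n individuals.
#' @param r replicate digitizations per individual.
#' @param p,u bilateral pairs / midline landmarks.
#' @param sigma_sym SD of individual symmetric deviations (per drawn
#'   coordinate, shape units).
#' @param da_magnitude Procrustes norm of the fixed directional-asymmetry
#'   vector.
#' @param sigma_fa SD of individual fluctuating-asymmetry deviations.
#' @param sigma_err SD of per-replicate, per-coordinate digitizing noise.
#' @param kappa named positive multipliers of `sigma_fa` per
#'   exposure group (`fetal`, `juvenile`, `adult`); 1 = no inflation.
#' @param exposure_counts named integer vector of exposed-group sizes
#'   (`fetal`, `juvenile`, `adult`); the remaining `n - sum` individuals are
#'   unexposed. Defaults scale the study composition 10/50/41 of 275.
#' @param n_matrilines number of maternal lineages in the metadata.
#' @param seed RNG seed; the same seed reproduces the dataset exactly.
#' @return list of class `"sim_params"`.
#' @export
sim_params <- function(n = 275L, r = 2L, p = 13L, u = 8L,
                       sigma_sym = 0.008, da_magnitude = 0.0046,
                       sigma_fa = 0.001, sigma_err = 0.0027,
                       kappa = c(fetal = 1, juvenile = 1, adult = 1),
                       exposure_counts = NULL,
                       n_matrilines = 20L, seed = 1L) {
  n <- as.integer(n); r <- as.integer(r)
  if (is.null(exposure_counts)) {
    exposure_counts <- c(fetal = round(n * 10 / 275),
                         juvenile = round(n * 50 / 275),
                         adult = round(n * 41 / 275))
  }
  exposure_counts <- exposure_counts[c("fetal", "juvenile", "adult")]
  stopifnot(all(c("fetal", "juvenile", "adult") %in% names(kappa)),
            all(kappa > 0),
            sigma_sym >= 0, sigma_fa >= 0, sigma_err >= 0,
            da_magnitude >= 0,
            sum(exposure_counts) <= n)
  structure(list(n = n, r = r, p = as.integer(p), u = as.integer(u),
                 sigma_sym = sigma_sym, da_magnitude = da_magnitude,
                 sigma_fa = sigma_fa, sigma_err = sigma_err,
                 kappa = kappa, exposure_counts = exposure_counts,
                 n_matrilines = as.integer(n_matrilines),
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Landmark scheme used by the simulator
#'
#' Left landmarks occupy indices `1..p`, right landmarks `p+1..2p`, midline
#' landmarks `2p+1..2p+u`.
#'
#' @param p,u pairs / midline counts.
#' @return a [landmark_scheme()].
#' @export
sim_scheme <- function(p, u) {
  landmark_scheme(pairs = cbind(seq_len(p), p + seq_len(p)),
                  midline = if (u > 0) 2L * p + seq_len(u) else integer(0))
}

#' Build a symmetric template shape
#'
#' Random non-degenerate 3D template with exact mirror symmetry about the
#' plane x = 0: right-side points are drawn with x > 0 and reflected to
#' make their left partners; midline points sit exactly on x = 0. The
#' template is centered and scaled to unit centroid size.
#'
#' @param p,u pairs / midline counts.
#' @param geometry_seed seed controlling the template draw.
#' @return `(2p+u) x 3` coordinate matrix in [sim_scheme()] order.
#' @export
make_template <- function(p, u, geometry_seed = 1L) {
  stopifnot(p >= 1L)
  set.seed(geometry_seed)
  for (attempt in 1:50) {
    right <- cbind(stats::runif(p, 0.3, 1),
                   stats::runif(p, -1, 1), stats::runif(p, -1, 1))
    left <- right
    left[, 1] <- -left[, 1]
    mid <- if (u > 0) cbind(0, stats::runif(u, -1, 1),
                            stats::runif(u, -1, 1)) else NULL
    tmpl <- rbind(left, right, mid)
    cc <- sweep(tmpl, 2, colMeans(tmpl))
    # require a genuinely 3D, non-degenerate spread
    if (qr(cc)$rank == 3L && min(svd(cc)$d) > 1e-3)
      return(cc / sqrt(sum(cc^2)))
  }
  stop("failed to draw a non-degenerate template in 50 attempts")
}

# one draw in the symmetric subspace: pairs get (a,b,c)/(-a,b,c),
# midline gets (0,b,c); per-coordinate SD = sigma
sym_deviation <- function(scheme, sigma) {
  k <- scheme$n_landmarks
  d <- matrix(0, k, 3L)
  if (sigma <= 0) return(d)
  for (i in seq_len(nrow(scheme$pairs))) {
    abc <- stats::rnorm(3, 0, sigma)
    d[scheme$pairs[i, 1], ] <- abc
    d[scheme$pairs[i, 2], ] <- c(-abc[1], abc[2], abc[3])
  }
  for (m in scheme$midline)
    d[m, ] <- c(0, stats::rnorm(2, 0, sigma))
  d
}

# one draw in the asymmetric subspace: pairs get (a,b,c)/(a,-b,-c),
# midline gets (a,0,0)
asym_deviation <- function(scheme, sigma) {
  k <- scheme$n_landmarks
  d <- matrix(0, k, 3L)
  if (sigma <= 0) return(d)
  for (i in seq_len(nrow(scheme$pairs))) {
    abc <- stats::rnorm(3, 0, sigma)
    d[scheme$pairs[i, 1], ] <- abc
    d[scheme$pairs[i, 2], ] <- c(abc[1], -abc[2], -abc[3])
  }
  for (m in scheme$midline)
    d[m, ] <- c(stats::rnorm(1, 0, sigma), 0, 0)
  d
}

#' Random proper 3D rotation
#' @param n ignored; one rotation per call.
#' @return 3 x 3 orthonormal matrix with determinant +1.
#' @export
random_rotation <- function(n = 1) {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Apply a rigid motion plus scaling to a configuration
#'
#' @param coords landmark matrix.
#' @param rotation 3 x 3 proper rotation.
#' @param translation length-3 vector.
#' @param scale positive scalar.
#' @return transformed coordinates.
#' @export
apply_transform <- function(coords, rotation = diag(3),
                            translation = c(0, 0, 0), scale = 1) {
  stopifnot(scale > 0)
  sweep(scale * (coords %*% rotation), 2, -translation)
}

# draws one random nuisance transform (rotation, translation, scale)
random_transform <- function() {
  list(rotation = random_rotation(),
       translation = stats::runif(3, -5, 5),
       scale = exp(stats::runif(1, log(0.5), log(2))))
}

# specimen metadata mirroring the study's composition: sexes ~154F/121M,
# exposed 101 (10 fetal / 50 juvenile / 41 adult; 78 one hurricane, 23 two),
# ages 0.75-31 y, birth decades 1950-2000, maternal lineages
simulate_metadata <- function(params) {
  n <- params$n
  ec <- params$exposure_counts
  n_exposed <- sum(ec)
  exposure <- c(rep("fetal", ec[["fetal"]]),
                rep("juvenile", ec[["juvenile"]]),
                rep("adult", ec[["adult"]]),
                rep("none", n - n_exposed))
  ids <- sprintf("S%03d", seq_len(n))
  # sex composition follows the study: exposed ~64F/37M, unexposed ~90F/84M
  sex <- character(n)
  exp_idx <- which(exposure != "none")
  sex[exp_idx] <- sample(rep(c("F", "M"),
                             times = round(c(64, 37) / 101 * length(exp_idx)))[
                               seq_along(exp_idx)])
  un_idx <- which(exposure == "none")
  sex[un_idx] <- sample(rep(c("F", "M"),
                            times = round(c(90, 84) / 174 * length(un_idx)))[
                              seq_along(un_idx)])
  sex[!nzchar(sex)] <- sample(c("F", "M"), sum(!nzchar(sex)), replace = TRUE)
  n_h <- integer(n)
  if (length(exp_idx)) {
    two <- sample(exp_idx, round(23 / 101 * length(exp_idx)))
    n_h[exp_idx] <- 1L
    n_h[two] <- 2L
  }
  age <- round(stats::runif(n, 0.75, 31), 1)
  # individuals exposed as adults must have lived past skeletal maturity
  adult_idx <- which(exposure == "adult")
  if (length(adult_idx)) {
    mat_age <- ifelse(sex[adult_idx] == "M", 8, 15)
    age[adult_idx] <- pmax(age[adult_idx], mat_age + stats::runif(length(adult_idx), 0.5, 5))
  }
  data.frame(
    specimen_id = ids, sex = sex, age_at_death = pmin(age, 31),
    decade_of_birth = sample(seq(1950L, 2000L, 10L), n, replace = TRUE),
    matriline = paste0("mat", sample(params$n_matrilines, n, replace = TRUE)),
    n_hurricanes = n_h, age_at_hurricane = exposure,
    stringsAsFactors = FALSE
  )
}

#' Skeletal maturity class from age and sex
#'
#' Juvenile below skeletal maturity (8 years in males, 15 years in
#' females), adult otherwise.
#'
#' @param age age in years.
#' @param sex `"F"` or `"M"`.
#' @return character vector, `"juvenile"` or `"adult"`.
#' @export
maturity_class <- function(age, sex) {
  ifelse(age < ifelse(sex == "M", 8, 15), "juvenile", "adult")
}

#' Simulate a replicate-digitized landmark dataset
#'
#' Per individual, a symmetric deviation and an individual-specific
#' asymmetric (FA) deviation are drawn in the symmetric and asymmetric
#' subspaces of the template; the fixed directional-asymmetry vector is
#' added; each replicate then receives independent coordinate-wise
#' digitizing noise, and every configuration finally receives its own
#' random rotation, translation and scaling (which superimposition must
#' undo). FA deviations of individuals exposed in group `g` are scaled by
#' `kappa[g]`.
#'
#' @param params a [sim_params()] object.
#' @return an [fa_dataset()] with metadata.
#' @examples
#' ds <- simulate_dataset(sim_params(n = 10, r = 2, p = 3, u = 2, seed = 7))
#' ds
#' @export
simulate_dataset <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  scheme <- sim_scheme(params$p, params$u)
  template <- make_template(params$p, params$u,
                            geometry_seed = params$seed + 1000L)
  set.seed(params$seed + 2000L)
  da_dir <- asym_deviation(scheme, 1)
  da <- if (params$da_magnitude > 0)
    da_dir / sqrt(sum(da_dir^2)) * params$da_magnitude
  else matrix(0, scheme$n_landmarks, 3L)
  set.seed(params$seed + 3000L)
  metadata <- simulate_metadata(params)
  configs <- vector("list", params$n * params$r)
  idx <- 0L
  for (i in seq_len(params$n)) {
    grp <- metadata$age_at_hurricane[i]
    kap <- if (grp %in% names(params$kappa)) params$kappa[[grp]] else 1
    s_i <- sym_deviation(scheme, params$sigma_sym)
    a_i <- asym_deviation(scheme, params$sigma_fa * kap)
    true_shape <- template + s_i + a_i + da
    for (j in seq_len(params$r)) {
      noisy <- true_shape +
        matrix(stats::rnorm(3 * scheme$n_landmarks, 0, params$sigma_err),
               scheme$n_landmarks, 3L)
      tr <- random_transform()
      idx <- idx + 1L
      configs[[idx]] <- landmark_config(
        metadata$specimen_id[i], j,
        apply_transform(noisy, tr$rotation, tr$translation, tr$scale),
        scheme)
    }
  }
  fa_dataset(configs, metadata, scheme)
}

#' Simulate FA scores directly at the score level
#'
#' Bypasses landmark geometry: generates specimen metadata and draws FA
#' scores from a linear model
#' `score = intercept + X beta + matriline intercept + residual`, the
#' generating counterpart of the mixed models fitted downstream. Useful for
#' fast calibration and power studies of the modelling stage alone.
#'
#' @param n individuals.
#' @param beta named numeric vector of fixed effects on the score scale;
#'   allowed names: `age` (per year), `sex` (M vs F), `decade` (per decade
#'   index from 1950), `hurricane_yn` (exposed vs not), `n_hurricanes1`,
#'   `n_hurricanes2`, `juvenile`, `adult` (age-at-hurricane levels vs
#'   fetal). Missing names mean 0.
#' @param intercept baseline mean FA score.
#' @param sigma_matriline SD of the matriline random intercept.
#' @param sigma_resid residual SD. Defaults match the score summary typical
#'   of replicate-digitized cranial FA data (mean 0.015, SD 0.004).
#' @param n_matrilines,exposure_counts,seed as in [sim_params()].
#' @return data.frame of scores joined to metadata (columns of
#'   [read_metadata()] plus `fa_score`).
#' @export
simulate_scores <- function(n = 275L, beta = numeric(0), intercept = 0.015,
                            sigma_matriline = 0.001, sigma_resid = 0.004,
                            n_matrilines = 20L, exposure_counts = NULL,
                            seed = 1L) {
  params <- sim_params(n = n, n_matrilines = n_matrilines,
                       exposure_counts = exposure_counts, seed = seed)
  set.seed(seed)
  md <- simulate_metadata(params)
  md <- read_metadata(md)
  b <- function(nm) if (nm %in% names(beta)) beta[[nm]] else 0
  decade_idx <- (md$decade_of_birth - 1950) / 10
  mu <- intercept +
    b("age") * md$age_at_death +
    b("sex") * (md$sex == "M") +
    b("decade") * decade_idx +
    b("hurricane_yn") * md$hurricane_experienced +
    b("n_hurricanes1") * (md$n_hurricanes == 1L) +
    b("n_hurricanes2") * (md$n_hurricanes == 2L) +
    b("juvenile") * (md$age_at_hurricane == "juvenile") +
    b("adult") * (md$age_at_hurricane == "adult")
  mat_eff <- stats::rnorm(nlevels(md$matriline), 0, sigma_matriline)
  md$fa_score <- mu + mat_eff[as.integer(md$matriline)] +
    stats::rnorm(n, 0, sigma_resid)
  md
}
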