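#' Fit an object-symmetry Procrustes asymmetry model
#'
#' The central fitting function. Every configuration in the dataset is
#' paired with its reflected-relabeled mirror; the `2 n r` shapes enter a
#' single generalized Procrustes superimposition, after which each
#' observation is split into a symmetric component (the average of the
#' aligned original and mirror, relative to the consensus) and an
#' asymmetric component (half their difference). The mean asymmetric
#' component over all observations is the directional-asymmetry (DA)
#' vector; the per-individual Procrustes FA score is the Procrustes norm of
#' the individual's replicate-averaged asymmetry after subtracting DA. A
#' replicate-based Procrustes ANOVA decomposes the total squared variation
#' into individual, side (DA), individual-by-side (FA) and measurement
#' error strata.
#'
#' @param dataset an [fa_dataset()] (or a list of [landmark_config()]
#'   objects plus `scheme`).
#' @param scheme landmark scheme; taken from `dataset` when omitted.
#' @param tol,max_iter GPA convergence controls, see [gpa()].
#' @return object of class `"procrustes_fa"`: a list with
#'   \describe{
#'     \item{consensus}{unit-size symmetric mean shape (k x 3).}
#'     \item{sym, asym}{k x 3 x (n r) arrays of per-observation symmetric
#'       and asymmetric deviations from the consensus.}
#'     \item{da_vector}{k x 3 directional-asymmetry matrix.}
#'     \item{anova}{[procrustes_anova_table()] of the four strata.}
#'     \item{scores}{per-individual FA score table (see [fa_scores()]).}
#'     \item{obs}{data.frame mapping array slices to (specimen, replicate).}
#'     \item{design, scheme, gpa_iterations}{bookkeeping.}
#'   }
#' @examples
#' ds <- simulate_dataset(sim_params(n = 12, r = 2, p = 3, u = 2, seed = 1))
#' fit <- procrustes_fa(ds)
#' fit
#' head(fa_scores(fit))
#' @export
procrustes_fa <- function(dataset, scheme = NULL, tol = 1e-10,
                          max_iter = 100L) {
  if (inherits(dataset, "fa_dataset")) {
    scheme <- dataset$scheme
    configs <- dataset$configs
  } else {
    if (is.null(scheme)) stop("scheme is required when not passing an fa_dataset")
    configs <- dataset
    dataset <- fa_dataset(configs, metadata = NULL, scheme = scheme)
    configs <- dataset$configs
  }
  if (dataset$r < 2L)
    stop("r = ", dataset$r, ": at least 2 replicate digitizations per ",
         "specimen are required to separate FA from measurement error")
  nr <- length(configs)
  originals <- lapply(configs, `[[`, "coords")
  mirrors <- lapply(originals, reflect_relabel, scheme = scheme)
  fit <- gpa(c(originals, mirrors), scheme = scheme, tol = tol,
             max_iter = max_iter)
  k <- scheme$n_landmarks
  sym <- array(0, c(k, 3L, nr))
  asym <- array(0, c(k, 3L, nr))
  for (j in seq_len(nr)) {
    o <- fit$aligned[[j]]
    m <- fit$aligned[[nr + j]]
    sym[, , j] <- (o + m) / 2 - fit$consensus
    asym[, , j] <- (o - m) / 2
  }
  ids <- vapply(configs, `[[`, character(1), "specimen_id")
  reps <- vapply(configs, `[[`, integer(1), "replicate_id")
  obs <- data.frame(specimen_id = ids, replicate_id = reps,
                    stringsAsFactors = FALSE)
  design <- c(n = dataset$n, r = dataset$r,
              p = n_pairs(scheme), u = n_midline(scheme))
  anova <- procrustes_anova_from_components(sym, asym, ids, design)
  da <- apply(asym, c(1, 2), mean)
  uid <- unique(ids)
  score <- vapply(uid, function(id) {
    masym <- apply(asym[, , ids == id, drop = FALSE], c(1, 2), mean)
    sqrt(sum((masym - da)^2))
  }, numeric(1))
  da_proj <- vapply(uid, function(id) {
    masym <- apply(asym[, , ids == id, drop = FALSE], c(1, 2), mean)
    sum(masym * da)
  }, numeric(1))
  scores <- data.frame(specimen_id = uid, fa_score = unname(score),
                       da_projection = unname(da_proj),
                       stringsAsFactors = FALSE)
  structure(
    list(consensus = fit$consensus, sym = sym, asym = asym,
         da_vector = da, anova = anova, scores = scores, obs = obs,
         design = design, scheme = scheme,
         metadata = dataset$metadata,
         gpa_iterations = fit$iterations, gpa_rms_change = fit$rms_change),
    class = "procrustes_fa"
  )
}

#' Extract per-individual Procrustes FA scores
#'
#' @param fit a fitted [procrustes_fa()] object.
#' @param with_metadata join specimen metadata (if the dataset carried any).
#' @return data.frame with `specimen_id`, `fa_score` (Procrustes distance
#'   units), `da_projection`, and metadata columns if requested.
#' @export
fa_scores <- function(fit, with_metadata = FALSE) {
  stopifnot(inherits(fit, "procrustes_fa"))
  sc <- fit$scores
  if (with_metadata) {
    if (is.null(fit$metadata))
      stop("the fitted dataset carried no specimen metadata")
    sc <- merge(sc, fit$metadata, by = "specimen_id", sort = FALSE)
  }
  sc
}

#' Summary statistics of a set of FA scores
#'
#' @param scores numeric vector of FA scores, or a data.frame with an
#'   `fa_score` column (e.g. from [fa_scores()]).
#' @return named numeric vector `(mean, median, sd, n)`.
#' @export
fa_score_summary <- function(scores) {
  if (is.data.frame(scores)) scores <- scores$fa_score
  scores <- as.numeric(scores)
  c(mean = mean(scores), median = stats::median(scores),
    sd = stats::sd(scores), n = length(scores))
}

#' @export
print.procrustes_fa <- function(x, ...) {
  d <- x$design
  cat("Object-symmetry Procrustes asymmetry fit\n")
  cat("  ", d[["n"]], "individuals x", d[["r"]], "replicates,",
      x$scheme$n_landmarks, "landmarks (p =", d[["p"]], ", u =",
      d[["u"]], ")\n")
  cat("  GPA converged in", x$gpa_iterations, "iterations (rms change",
      format(x$gpa_rms_change, digits = 3), ")\n")
  s <- fa_score_summary(x$scores)
  cat("  FA scores: mean", format(s[["mean"]], digits = 3),
      " median", format(s[["median"]], digits = 3),
      " sd", format(s[["sd"]], digits = 3), "\n")
  cat("  DA magnitude:", format(sqrt(sum(x$da_vector^2)), digits = 3), "\n")
  invisible(x)
}

#' @export
summary.procrustes_fa <- function(object, ...) {
  structure(list(fit = object), class = "summary.procrustes_fa")
}

#' @export
print.summary.procrustes_fa <- function(x, ...) {
  print(x$fit)
  cat("\n")
  print(x$fit$anova)
  invisible(x)
}

#' @export
coef.procrustes_fa <- function(object, ...) {
  stats::setNames(object$scores$fa_score, object$scores$specimen_id)
}

#' Plot method: FA score distribution
#'
#' Histogram of per-individual Procrustes FA scores with the sample mean
#' marked, in the style conventional for FA studies.
#'
#' @param x a [procrustes_fa()] fit.
#' @param ... passed to [graphics::hist()].
#' @export
plot.procrustes_fa <- function(x, ...) {
  sc <- x$scores$fa_score
  graphics::hist(sc, main = "Procrustes FA scores",
                 xlab = "FA score (Procrustes distance)", ...)
  graphics::abline(v = mean(sc), lty = 2)
  invisible(x)
}
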