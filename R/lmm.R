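#' Fit a linear mixed-effect model of FA scores
#'
#' FA score is modelled against age at death (years, continuous), sex
#' (reference female), decade of birth (a single linear trend per decade
#' index from 1950) and at most one hurricane-related term, with a
#' matriline random intercept. Fitting is by REML via lmerTest, so fixed
#' effects carry Satterthwaite-approximated (fractional) denominator
#' degrees of freedom.
#'
#' @param data data.frame of FA scores joined to specimen metadata (e.g.
#'   from [fa_scores()] with `with_metadata = TRUE`, or
#'   [simulate_scores()]). Required columns: `fa_score`, `age_at_death`,
#'   `sex`, `decade_of_birth`, `matriline`, plus the hurricane columns when
#'   used.
#' @param hurricane_term one of `"none"`, `"hurricane_yn"`,
#'   `"n_hurricanes"` (categorical, reference 0) or `"age_at_hurricane"`
#'   (categorical fetal/juvenile/adult, reference fetal; requires an
#'   exposed-only subset).
#' @param reml fit by REML (default) or ML.
#' @return object of class `"fa_lmm"`: list with `model` (the lmerTest
#'   fit), `coefficients` (data.frame: term, estimate, std_error, df,
#'   t_value, p_value), `varcomp` (matriline and residual variances),
#'   `reml_criterion`, `n_obs`, `n_groups`, `singular` (TRUE when the
#'   matriline variance hit its zero boundary), `hurricane_term`.
#' @export
fa_lmm <- function(data, hurricane_term = c("none", "hurricane_yn",
                                            "n_hurricanes",
                                            "age_at_hurricane"),
                   reml = TRUE) {
  hurricane_term <- match.arg(hurricane_term)
  need <- c("fa_score", "age_at_death", "sex", "decade_of_birth",
            "matriline")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("data is missing columns: ", paste(miss, collapse = ", "))
  d <- data
  d$sex <- factor(d$sex, levels = c("F", "M"))
  d$decade_trend <- (d$decade_of_birth - 1950) / 10
  d$matriline <- factor(d$matriline)
  rhs <- "age_at_death + sex + decade_trend"
  if (hurricane_term == "hurricane_yn") {
    d$hurricane_yn <- factor(ifelse(d$n_hurricanes > 0, "yes", "no"),
                             levels = c("no", "yes"))
    rhs <- paste(rhs, "+ hurricane_yn")
  } else if (hurricane_term == "n_hurricanes") {
    d$n_hurricanes <- factor(d$n_hurricanes, levels = 0:2)
    d$n_hurricanes <- droplevels(d$n_hurricanes)
    rhs <- paste(rhs, "+ n_hurricanes")
  } else if (hurricane_term == "age_at_hurricane") {
    if (any(d$age_at_hurricane == "none"))
      stop("age_at_hurricane models require the hurricane-exposed subset ",
           "(rows with age_at_hurricane == 'none' present)")
    d$age_at_hurricane <- factor(as.character(d$age_at_hurricane),
                                 levels = c("fetal", "juvenile", "adult"))
    d$age_at_hurricane <- droplevels(d$age_at_hurricane)
    rhs <- paste(rhs, "+ age_at_hurricane")
  }
  # reject degenerate categorical terms up front, naming the offender
  for (v in c("sex", "hurricane_yn", "n_hurricanes", "age_at_hurricane")) {
    if (v %in% all.vars(stats::as.formula(paste("~", rhs))) &&
        is.factor(d[[v]]) && nlevels(droplevels(d[[v]])) < 2L)
      stop("fixed effect '", v, "' has a single observed level")
  }
  if (nlevels(droplevels(d$matriline)) < 2L)
    stop("need at least 2 matrilines for the random intercept")
  form <- stats::as.formula(paste("fa_score ~", rhs, "+ (1 | matriline)"))
  n_par <- ncol(stats::model.matrix(
    stats::as.formula(paste("~", rhs)), d))
  if (nrow(d) <= n_par)
    stop("fewer observations (", nrow(d), ") than fixed-effect parameters (",
         n_par, ")")
  # zero-boundary matriline variance is legitimate here (clamped at 0 and
  # flagged via `singular`); keep lme4 from messaging about it in bulk runs
  ctrl <- lme4::lmerControl(
    check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4))
  fit <- lmerTest::lmer(form, data = d, REML = reml, control = ctrl)
  ct <- as.data.frame(summary(fit)$coefficients)
  names(ct) <- c("estimate", "std_error", "df", "t_value", "p_value")
  ct <- cbind(term = rownames(ct), ct, stringsAsFactors = FALSE)
  rownames(ct) <- NULL
  vc <- as.data.frame(lme4::VarCorr(fit))
  mat_var <- vc$vcov[vc$grp == "matriline"]
  res_var <- vc$vcov[vc$grp == "Residual"]
  structure(list(
    model = fit, coefficients = ct,
    varcomp = c(matriline = mat_var, residual = res_var),
    reml_criterion = as.numeric(lme4::REMLcrit(fit)),
    n_obs = nrow(d), n_groups = nlevels(droplevels(d$matriline)),
    singular = lme4::isSingular(fit),
    hurricane_term = hurricane_term, data = d
  ), class = "fa_lmm")
}

#' @export
print.fa_lmm <- function(x, ...) {
  cat("FA mixed model (REML, Satterthwaite df): fa_score ~ age + sex + ",
      "decade", if (x$hurricane_term != "none") paste0(" + ", x$hurricane_term),
      " + (1 | matriline)\n", sep = "")
  cat("  n =", x$n_obs, "individuals,", x$n_groups, "matrilines\n")
  if (x$singular)
    cat("  note: matriline variance estimated at the zero boundary\n")
  ct <- x$coefficients
  ct$estimate <- formatC(ct$estimate, digits = 5, format = "f")
  ct$std_error <- formatC(ct$std_error, digits = 5, format = "f")
  ct$df <- formatC(ct$df, digits = 1, format = "f")
  ct$t_value <- formatC(ct$t_value, digits = 3, format = "f")
  ct$p_value <- formatC(ct$p_value, digits = 3, format = "f")
  print(ct, row.names = FALSE)
  cat("  variance components: matriline",
      format(x$varcomp[["matriline"]], digits = 3),
      ", residual", format(x$varcomp[["residual"]], digits = 3), "\n")
  invisible(x)
}

#' @export
coef.fa_lmm <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Run the four-model FA suite
#'
#' The standard model battery for hurricane-exposure analyses of FA:
#' \describe{
#'   \item{model1}{all individuals; hurricane experienced yes/no.}
#'   \item{model2}{never-exposed subset; demographic terms only.}
#'   \item{model3}{all individuals; number of hurricanes (0/1/2,
#'     categorical).}
#'   \item{model4}{exposed subset; developmental stage at hurricane
#'     (fetal/juvenile/adult, reference fetal).}
#' }
#' All four share age, sex and decade-of-birth fixed effects and the
#' matriline random intercept.
#'
#' @param scores data.frame of FA scores joined to metadata.
#' @return named list of [fa_lmm()] fits, class `"fa_lmm_suite"`.
#' @export
fa_model_suite <- function(scores) {
  if (!"hurricane_experienced" %in% names(scores))
    scores$hurricane_experienced <- scores$n_hurricanes > 0
  never <- scores[!scores$hurricane_experienced, , drop = FALSE]
  exposed <- scores[scores$hurricane_experienced, , drop = FALSE]
  if (!nrow(never)) stop("empty never-exposed subset")
  if (!nrow(exposed)) stop("empty exposed subset")
  out <- list(
    model1 = fa_lmm(scores, "hurricane_yn"),
    model2 = fa_lmm(never, "none"),
    model3 = fa_lmm(scores, "n_hurricanes"),
    model4 = fa_lmm(exposed, "age_at_hurricane")
  )
  class(out) <- "fa_lmm_suite"
  out
}

#' @export
print.fa_lmm_suite <- function(x, ...) {
  labels <- c(model1 = "Model 1: all individuals, hurricane Y/N",
              model2 = "Model 2: never-exposed subset",
              model3 = "Model 3: all individuals, number of hurricanes",
              model4 = "Model 4: exposed subset, age at hurricane")
  for (nm in names(x)) {
    cat("==", labels[[nm]], "==\n")
    print(x[[nm]])
    cat("\n")
  }
  invisible(x)
}

#' Tukey pairwise contrasts with Holm correction
#'
#' All pairwise contrasts of a categorical fixed effect from a fitted FA
#' mixed model, with z statistics from the estimated coefficient
#' covariance and step-down Bonferroni-Holm adjustment of the two-sided
#' p-values across the contrast family.
#'
#' @param fit an [fa_lmm()] object whose model contains `factor`.
#' @param factor name of the categorical fixed effect (default
#'   `"age_at_hurricane"`).
#' @return data.frame of class `"fa_contrasts"`: `contrast, estimate,
#'   std_error, z_value, p_raw, p_holm`.
#' @export
posthoc_holm <- function(fit, factor = "age_at_hurricane") {
  stopifnot(inherits(fit, "fa_lmm"))
  if (!factor %in% all.vars(stats::formula(fit$model)))
    stop("factor '", factor, "' is not a term of the fitted model")
  linfct <- list("Tukey")
  names(linfct) <- factor
  gl <- multcomp::glht(fit$model, linfct = do.call(multcomp::mcp, linfct))
  sm <- summary(gl, test = multcomp::adjusted("none"))
  est <- as.numeric(sm$test$coefficients)
  se <- as.numeric(sm$test$sigma)
  z <- as.numeric(sm$test$tstat)
  p_raw <- as.numeric(sm$test$pvalues)
  out <- data.frame(
    contrast = names(sm$test$coefficients),
    estimate = est, std_error = se, z_value = z,
    p_raw = p_raw, p_holm = stats::p.adjust(p_raw, method = "holm"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("fa_contrasts", "data.frame")
  out
}

#' @export
print.fa_contrasts <- function(x, ...) {
  cat("Tukey pairwise contrasts, Holm-adjusted\n")
  y <- as.data.frame(x)
  y$estimate <- formatC(y$estimate, digits = 5, format = "f")
  y$std_error <- formatC(y$std_error, digits = 5, format = "f")
  y$z_value <- formatC(y$z_value, digits = 3, format = "f")
  y$p_raw <- formatC(y$p_raw, digits = 4, format = "f")
  y$p_holm <- formatC(y$p_holm, digits = 4, format = "f")
  print(y, row.names = FALSE)
  invisible(x)
}

#' Simulation-based power analysis for FA mixed models
#'
#' For each effect size on the grid (expressed as percent change in the
#' mean FA score), repeatedly simulates score data with the effect
#' injected, refits the mixed model, and records the proportion of
#' simulations in which the target term is significant at `alpha`. By
#' default the simulation draws score-level data via [simulate_scores()]
#' and tests the binary hurricane term; a custom `simulator` (a
#' `function(seed, effect_pct)` returning a single p-value) substitutes any
#' other pipeline, e.g. a full landmark-level re-analysis.
#'
#' @param effect_grid_pct numeric vector of percent changes in mean FA.
#' @param n_sims simulations per grid point.
#' @param alpha significance level.
#' @param seed base RNG seed; simulation `s` of grid point `g` uses
#'   deterministic offsets of it.
#' @param n,intercept,sigma_matriline,sigma_resid,n_matrilines passed to
#'   [simulate_scores()] for the default simulator.
#' @param term which fixed effect carries the injected effect in the
#'   default simulator (`"hurricane_yn"`).
#' @param target_power power level reported against (conventionally 0.8).
#' @param simulator optional `function(seed, effect_pct) -> p-value`.
#' @return data.frame of class `"fa_power"`: `effect_pct, power, mc_se,
#'   n_sims`; attributes `alpha`, `target_power`, `detectable` (smallest
#'   grid effect reaching `target_power`, NA if none).
#' @export
power_simulation <- function(effect_grid_pct, n_sims = 200L, alpha = 0.05,
                             seed = 1L, n = 275L, intercept = 0.015,
                             sigma_matriline = 0.001, sigma_resid = 0.004,
                             n_matrilines = 20L, term = "hurricane_yn",
                             target_power = 0.8, simulator = NULL) {
  stopifnot(n_sims >= 1L, alpha > 0, alpha < 1)
  if (is.null(simulator)) {
    simulator <- function(sim_seed, effect_pct) {
      beta <- stats::setNames(effect_pct / 100 * intercept, term)
      sc <- simulate_scores(n = n, beta = beta, intercept = intercept,
                            sigma_matriline = sigma_matriline,
                            sigma_resid = sigma_resid,
                            n_matrilines = n_matrilines, seed = sim_seed)
      f <- fa_lmm(sc, hurricane_term = term)
      rows <- grepl(term, f$coefficients$term)
      min(f$coefficients$p_value[rows])
    }
  }
  res <- lapply(seq_along(effect_grid_pct), function(g) {
    pvals <- vapply(seq_len(n_sims), function(s) {
      simulator(seed + 10000L * g + s, effect_grid_pct[g])
    }, numeric(1))
    pow <- mean(pvals < alpha)
    c(power = pow, mc_se = sqrt(pow * (1 - pow) / n_sims))
  })
  out <- data.frame(effect_pct = effect_grid_pct,
                    power = vapply(res, `[[`, numeric(1), "power"),
                    mc_se = vapply(res, `[[`, numeric(1), "mc_se"),
                    n_sims = n_sims)
  attr(out, "alpha") <- alpha
  attr(out, "target_power") <- target_power
  reached <- out$effect_pct[out$power >= target_power]
  attr(out, "detectable") <- if (length(reached)) min(reached) else NA_real_
  class(out) <- c("fa_power", "data.frame")
  out
}

#' @export
print.fa_power <- function(x, ...) {
  cat("Simulated power (alpha =", attr(x, "alpha"), ",",
      x$n_sims[1], "simulations per point)\n")
  print(as.data.frame(x), row.names = FALSE)
  det <- attr(x, "detectable")
  if (!is.na(det))
    cat("smallest grid effect reaching", attr(x, "target_power"),
        "power:", det, "% change in mean FA\n")
  else
    cat("no grid effect reached", attr(x, "target_power"), "power\n")
  invisible(x)
}

#' @export
plot.fa_power <- function(x, ...) {
  graphics::plot(x$effect_pct, x$power, type = "b", ylim = c(0, 1),
                 xlab = "effect size (% change in mean FA)",
                 ylab = "power", ...)
  graphics::abline(h = attr(x, "target_power"), lty = 2)
  invisible(x)
}
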