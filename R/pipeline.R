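#' Run the full FA analysis pipeline
#'
#' Orchestrates load (or simulate) -> object-symmetry superimposition ->
#' symmetric/asymmetric decomposition -> Procrustes ANOVA -> FA scores ->
#' mixed-model suite -> post hoc contrasts -> power analysis, writing every
#' stage's table to `out_dir` together with a manifest that makes the run
#' reproducible (seed, configuration hash, package version).
#'
#' @param config a named list, or the path to a YAML file holding one.
#'   Recognized fields:
#'   \describe{
#'     \item{scenario}{list of [sim_params()] arguments for a synthetic
#'       run (mutually exclusive with `input`).}
#'     \item{input}{list with `landmarks` (dir/file), `metadata` (CSV) and
#'       optionally `scheme = "macaque"` for real data.}
#'     \item{seed}{integer; overrides the scenario seed.}
#'     \item{alpha}{significance level (default 0.05).}
#'     \item{models}{logical, fit the four-model suite (default TRUE when
#'       metadata is present).}
#'     \item{posthoc}{logical, Tukey/Holm contrasts on model 4.}
#'     \item{power}{list with `effect_grid_pct`, `n_sims` to run the power
#'       stage; omit to skip.}
#'     \item{out_dir}{output directory.}
#'   }
#' @return (invisibly) list with the fitted objects and the output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- normalize_yaml(yaml::read_yaml(config))
  if (!is.null(config$scenario) && !is.null(config$input))
    stop("config must set exactly one of 'scenario' (simulation) or 'input'")
  if (is.null(config$scenario) && is.null(config$input))
    stop("config must set one of 'scenario' or 'input'")
  alpha <- if (is.null(config$alpha)) 0.05 else config$alpha
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  out_dir <- if (is.null(config$out_dir)) "fa_run" else config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L

  if (!is.null(config$scenario)) {
    sc_args <- config$scenario
    sc_args$seed <- seed
    params <- do.call(sim_params, sc_args)
    ds <- simulate_dataset(params)
  } else {
    scheme <- if (identical(config$input$scheme, "macaque") ||
                  is.null(config$input$scheme))
      macaque_cranial_scheme()
    else do.call(landmark_scheme, config$input$scheme)
    ds <- load_dataset(config$input$landmarks, config$input$metadata,
                       scheme, quiet = TRUE)
  }
  message("pipeline: n = ", ds$n, ", r = ", ds$r,
          ", p = ", n_pairs(ds$scheme), ", u = ", n_midline(ds$scheme))

  fit <- procrustes_fa(ds)
  message("GPA converged in ", fit$gpa_iterations, " iterations")
  utils::write.csv(as.data.frame(fit$anova),
                   file.path(out_dir, "anova_table.csv"), row.names = FALSE)
  scores <- fa_scores(fit, with_metadata = !is.null(ds$metadata))
  utils::write.csv(scores, file.path(out_dir, "fa_scores.csv"),
                   row.names = FALSE)

  suite <- NULL; contrasts <- NULL; power <- NULL
  do_models <- if (is.null(config$models)) !is.null(ds$metadata)
  else isTRUE(config$models)
  if (do_models) {
    suite <- fa_model_suite(scores)
    lmm_tab <- do.call(rbind, lapply(names(suite), function(nm) {
      cbind(model = nm, suite[[nm]]$coefficients)
    }))
    utils::write.csv(lmm_tab, file.path(out_dir, "lmm_results.csv"),
                     row.names = FALSE)
    if (isTRUE(config$posthoc) || is.null(config$posthoc)) {
      contrasts <- posthoc_holm(suite$model4, "age_at_hurricane")
      utils::write.csv(as.data.frame(contrasts),
                       file.path(out_dir, "contrasts.csv"),
                       row.names = FALSE)
    }
  }
  if (!is.null(config$power)) {
    pw <- config$power
    power <- power_simulation(
      effect_grid_pct = pw$effect_grid_pct,
      n_sims = if (is.null(pw$n_sims)) 200L else pw$n_sims,
      alpha = alpha, seed = seed, n = ds$n)
    utils::write.csv(as.data.frame(power),
                     file.path(out_dir, "power.csv"), row.names = FALSE)
  }

  manifest <- list(
    seed = seed, alpha = alpha,
    config_hash = config_hash(config),
    design = as.list(fit$design),
    package_version = as.character(utils::packageVersion("fluctasym")),
    stages = c("superimpose", "anova", "scores",
               if (do_models) "lmm",
               if (!is.null(contrasts)) "posthoc",
               if (!is.null(power)) "power"),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(fit = fit, scores = scores, suite = suite,
                 contrasts = contrasts, power = power,
                 out_dir = out_dir, manifest = manifest))
}

# YAML 1.1 parses bare keys y/n/yes/no as booleans; restore the intended
# short field names (we only ever use "n")
normalize_yaml <- function(x) {
  if (!is.list(x)) return(x)
  nm <- names(x)
  if (!is.null(nm)) {
    nm[nm == "FALSE"] <- "n"
    names(x) <- nm
  }
  lapply(x, normalize_yaml)
}

# stable md5 of the configuration, computed over its canonical JSON form
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config[order(names(config))], tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

#' Summarize a completed pipeline run as Markdown
#'
#' @param out_dir directory written by [run_pipeline()].
#' @param file optional path to write the summary to.
#' @return the Markdown text, invisibly (printed when `file` is NULL).
#' @export
report <- function(out_dir, file = NULL) {
  need <- file.path(out_dir, c("anova_table.csv", "fa_scores.csv",
                               "manifest.json"))
  for (f in need)
    if (!file.exists(f)) stop("missing run artifact: ", f)
  manifest <- jsonlite::read_json(file.path(out_dir, "manifest.json"))
  anova <- utils::read.csv(file.path(out_dir, "anova_table.csv"))
  scores <- utils::read.csv(file.path(out_dir, "fa_scores.csv"))
  md <- c(
    "# FA pipeline report", "",
    sprintf("Seed %s, config hash `%s`.", manifest$seed,
            manifest$config_hash), "",
    "## Procrustes ANOVA", "",
    "| Effect | df | SS | MS | F | p | % var |",
    "|---|---|---|---|---|---|---|",
    vapply(seq_len(nrow(anova)), function(i) {
      sprintf("| %s | %s | %.8f | %.10f | %s | %s | %.2f%% |",
              anova$effect[i], format(anova$df[i], big.mark = ","),
              anova$ss[i], anova$ms[i],
              ifelse(is.na(anova$f[i]), "", sprintf("%.2f", anova$f[i])),
              ifelse(is.na(anova$p[i]), "",
                     ifelse(anova$p[i] < 0.001, "<.001",
                            sprintf("%.3f", anova$p[i]))),
              anova$pct_var[i])
    }, character(1)), "",
    sprintf("Percent variation sums to %.2f.", sum(anova$pct_var)), "",
    "## FA scores", "",
    sprintf("n = %d individuals; mean %.4f, median %.4f, sd %.4f.",
            nrow(scores), mean(scores$fa_score),
            stats::median(scores$fa_score), stats::sd(scores$fa_score)), ""
  )
  lmm_path <- file.path(out_dir, "lmm_results.csv")
  if (file.exists(lmm_path)) {
    lmm <- utils::read.csv(lmm_path)
    md <- c(md, "## Mixed-model suite", "",
            "| Model | Term | Estimate | SE | df | t | p |",
            "|---|---|---|---|---|---|---|",
            vapply(seq_len(nrow(lmm)), function(i) {
              sprintf("| %s | %s | %.5f | %.5f | %.1f | %.3f | %.3f |",
                      lmm$model[i], lmm$term[i], lmm$estimate[i],
                      lmm$std_error[i], lmm$df[i], lmm$t_value[i],
                      lmm$p_value[i])
            }, character(1)), "")
  }
  ctr_path <- file.path(out_dir, "contrasts.csv")
  if (file.exists(ctr_path)) {
    ctr <- utils::read.csv(ctr_path)
    md <- c(md, "## Post hoc contrasts (Tukey, Holm-adjusted)", "",
            "| Contrast | Estimate | SE | z | raw p | Holm p |",
            "|---|---|---|---|---|---|",
            vapply(seq_len(nrow(ctr)), function(i) {
              sprintf("| %s | %.5f | %.5f | %.3f | %.4f | %.4f |",
                      ctr$contrast[i], ctr$estimate[i], ctr$std_error[i],
                      ctr$z_value[i], ctr$p_raw[i], ctr$p_holm[i])
            }, character(1)), "")
  }
  pow_path <- file.path(out_dir, "power.csv")
  if (file.exists(pow_path)) {
    pow <- utils::read.csv(pow_path)
    md <- c(md, "## Power curve", "",
            "| Effect (% change in mean FA) | Power | MC SE |",
            "|---|---|---|",
            vapply(seq_len(nrow(pow)), function(i) {
              sprintf("| %.1f | %.3f | %.3f |", pow$effect_pct[i],
                      pow$power[i], pow$mc_se[i])
            }, character(1)), "")
  } else {
    md <- c(md, "_Power stage was not run._", "")
  }
  text <- paste(md, collapse = "\n")
  if (!is.null(file)) {
    writeLines(text, file)
    return(invisible(text))
  }
  cat(text, "\n")
  invisible(text)
}
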