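#' Procrustes ANOVA degrees of freedom for 3D object symmetry
#'
#' Closed-form design degrees of freedom for the two-factor (individual,
#' side) Procrustes ANOVA with replicate digitizations. With `p` bilateral
#' pairs and `u` midline landmarks in 3D, the symmetric shape subspace has
#' `d_sym = 3p + 2u - 4` dimensions and the asymmetric subspace
#' `d_asym = 3p + u - 3`; then
#' \deqn{df_{ind} = (n-1) d_{sym}, \quad df_{side} = d_{asym},}
#' \deqn{df_{ind \times side} = (n-1) d_{asym}, \quad
#'       df_{err} = (r-1) n (d_{sym} + d_{asym}).}
#'
#' @param n number of individuals (>= 2).
#' @param r replicate digitizations per individual; must be >= 2 for the
#'   error stratum to exist (with a single digitization FA cannot be
#'   separated from measurement error).
#' @param p number of bilateral landmark pairs.
#' @param u number of midline landmarks.
#' @return named integer vector `(individual, side, individual_x_side,
#'   error)`.
#' @examples
#' anova_dfs(275, 2, 13, 8)  # 13974, 44, 12056, 26125
#' @export
anova_dfs <- function(n, r, p, u) {
  n <- as.integer(n); r <- as.integer(r)
  if (n < 2L) stop("need at least 2 individuals")
  if (r < 2L)
    stop("r = ", r, ": with fewer than 2 replicate digitizations the ",
         "error stratum is empty and FA cannot be separated from ",
         "measurement error")
  d <- symmetry_dims(p, u)
  c(individual = (n - 1L) * d[["sym"]],
    side = d[["asym"]],
    individual_x_side = (n - 1L) * d[["asym"]],
    error = (r - 1L) * n * (d[["sym"]] + d[["asym"]]))
}

#' Build a Procrustes ANOVA table from sums of squares
#'
#' Given the four Procrustes sums of squares and their degrees of freedom,
#' computes mean squares, F ratios, parametric p-values (Goodall-style F
#' tests at the Procrustes df) and percent variation (SS shares). The error
#' strata follow the replicate design: individual and side are tested over
#' the individual-by-side mean square, individual-by-side over measurement
#' error.
#'
#' @param ss numeric vector of sums of squares in the order individual,
#'   side, individual x side, error.
#' @param df integer vector of matching degrees of freedom.
#' @param design optional named list/vector `(n, r, p, u)` recorded in the
#'   result.
#' @return data.frame of class `"procrustes_anova"` with columns
#'   `effect, df, ss, ms, f, p, pct_var`.
#' @export
procrustes_anova_table <- function(ss, df, design = NULL) {
  stopifnot(length(ss) == 4L, length(df) == 4L, all(df >= 1))
  ms <- ss / df
  f <- c(ms[1] / ms[3], ms[2] / ms[3], ms[3] / ms[4], NA_real_)
  p <- c(stats::pf(f[1], df[1], df[3], lower.tail = FALSE),
         stats::pf(f[2], df[2], df[3], lower.tail = FALSE),
         stats::pf(f[3], df[3], df[4], lower.tail = FALSE),
         NA_real_)
  total <- sum(ss)
  if (total <= 0) {
    warning("total Procrustes SS is zero; the decomposition is degenerate ",
            "and p-values are undefined")
    p[] <- NA_real_
    pct <- rep(NA_real_, 4L)
  } else {
    pct <- percent_variation(ss)
  }
  out <- data.frame(
    effect = c("individual", "side", "individual_x_side", "error"),
    df = as.integer(df), ss = ss, ms = ms, f = f, p = p, pct_var = pct,
    stringsAsFactors = FALSE
  )
  attr(out, "design") <- design
  class(out) <- c("procrustes_anova", "data.frame")
  out
}

#' Percent variation from Procrustes sums of squares
#'
#' Each effect's share of the total sum of squares, in percent. (The shares
#' of the summed squared Procrustes deviations — not mean squares — are what
#' reproduce the conventional percent-variation column of published
#' Procrustes ANOVA tables.)
#'
#' @param ss numeric vector of sums of squares (or a `"procrustes_anova"`
#'   table, whose `ss` column is used).
#' @return numeric vector summing to 100.
#' @export
percent_variation <- function(ss) {
  if (inherits(ss, "procrustes_anova")) ss <- ss$ss
  if (sum(ss) <= 0) stop("total SS must be positive")
  100 * ss / sum(ss)
}

#' @export
print.procrustes_anova <- function(x, ...) {
  cat("Procrustes ANOVA (object symmetry)\n")
  des <- attr(x, "design")
  if (!is.null(des))
    cat("  design: n =", des[["n"]], " r =", des[["r"]],
        " p =", des[["p"]], " u =", des[["u"]], "\n")
  tab <- data.frame(
    Effect = c("Individual", "Side (DA)", "Individual x Side (FA)", "Error"),
    df = format(x$df, big.mark = ","),
    SS = formatC(x$ss, digits = 8, format = "f"),
    MS = formatC(x$ms, digits = 10, format = "f"),
    F = ifelse(is.na(x$f), "", formatC(x$f, digits = 2, format = "f")),
    p = ifelse(is.na(x$p), "",
               ifelse(x$p < 0.001, "<.001",
                      formatC(x$p, digits = 3, format = "f"))),
    `pct var` = paste0(formatC(x$pct_var, digits = 2, format = "f"), "%"),
    check.names = FALSE
  )
  print(tab, row.names = FALSE)
  invisible(x)
}

# Procrustes ANOVA from a symmetry decomposition.
# sym, asym: k x 3 x (n*r) arrays of per-observation components;
# ids: specimen of each observation slice.
procrustes_anova_from_components <- function(sym, asym, ids, design) {
  n <- design[["n"]]; r <- design[["r"]]
  uid <- unique(ids)
  stopifnot(length(uid) == n, dim(sym)[3] == n * r)
  da <- apply(asym, c(1, 2), mean)
  ss_ind <- 0; ss_int <- 0; ss_err <- 0
  for (id in uid) {
    sl <- which(ids == id)
    msym <- apply(sym[, , sl, drop = FALSE], c(1, 2), mean)
    masym <- apply(asym[, , sl, drop = FALSE], c(1, 2), mean)
    ss_ind <- ss_ind + r * sum(msym^2)
    ss_int <- ss_int + r * sum((masym - da)^2)
    for (j in sl)
      ss_err <- ss_err + sum((sym[, , j] - msym)^2) +
        sum((asym[, , j] - masym)^2)
  }
  ss_side <- n * r * sum(da^2)
  df <- anova_dfs(n, r, design[["p"]], design[["u"]])
  procrustes_anova_table(c(ss_ind, ss_side, ss_int, ss_err), df,
                         design = design)
}
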