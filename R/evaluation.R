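#' Paired simulated-vs-observed series
#'
#' @param x observed values
#' @param y simulated values
#' @param variable label
#' @return object of class `paired_series`
#' @export
paired_series <- function(x, y, variable = "variable") {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 data pairs")
  structure(list(x = as.numeric(x), y = as.numeric(y), variable = variable),
            class = "paired_series")
}

#' Evaluate simulated against observed values
#'
#' The standard crop-model agreement statistics for a simulated (Y) vs
#' observed (X) series: ordinary least-squares intercept (alpha) and slope
#' (beta) of Y on X, squared Pearson correlation (r2), a two-sample t-test
#' p-value (Welch's unequal-variance test by default, optionally paired),
#' the normalized root mean square error
#' `RMSEn = 100 * sqrt(mean((Y - X)^2)) / mean(X)` (percent of the observed
#' mean), and the Nash-Sutcliffe model efficiency
#' `Meff = 1 - sum((X - Y)^2) / sum((X - mean(X))^2)`.
#'
#' @param pairs a [paired_series()], or observed vector if `y` given
#' @param y simulated vector (when `pairs` is the observed vector)
#' @param t_test "welch" (two-sample, unequal variance) or "paired"
#' @return object of class `eval_report` with fields alpha, beta, r2, p_t,
#'   rmse_n (percent), m_eff, n, variable
#' @export
evaluate <- function(pairs, y = NULL, t_test = c("welch", "paired")) {
  t_test <- match.arg(t_test)
  if (!inherits(pairs, "paired_series")) pairs <- paired_series(pairs, y)
  x <- pairs$x; yv <- pairs$y; n <- length(x)
  xbar <- mean(x)
  if (xbar == 0) stop("observed mean is zero: RMSEn undefined")
  if (stats::var(x) == 0) stop("observed values have zero variance: r2 and Meff undefined")
  # closed-form OLS of Y on X
  beta <- sum((x - xbar) * (yv - mean(yv))) / sum((x - xbar)^2)
  alpha <- mean(yv) - beta * xbar
  # r2 undefined (0/0 in the sum formula) when the simulation is constant
  r2 <- if (stats::var(yv) == 0) NA_real_ else stats::cor(x, yv)^2
  rmse_n <- 100 * sqrt(sum((yv - x)^2) / n) / xbar
  m_eff <- 1 - sum((x - yv)^2) / sum((x - xbar)^2)
  p_t <- if (t_test == "welch") {
    if (stats::var(yv) == 0 && stats::var(x) == 0) 1
    else stats::t.test(yv, x, var.equal = FALSE)$p.value
  } else {
    if (all(yv == x)) 1 else stats::t.test(yv, x, paired = TRUE)$p.value
  }
  structure(list(alpha = alpha, beta = beta,
                 r2 = r2, p_t = p_t, rmse_n = rmse_n, m_eff = m_eff,
                 n = n, variable = pairs$variable),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s (n = %d)\n", x$variable, x$n))
  cat(sprintf("  alpha %.3f  beta %.3f  r2 %.3f  P(t) %.3f  RMSEn %.2f%%  Meff %.3f\n",
              x$alpha, x$beta, x$r2, x$p_t, x$rmse_n, x$m_eff))
  invisible(x)
}

#' Flag an evaluation report against the ideal-agreement criteria
#'
#' The model is considered to represent the observations well when beta, r2
#' and Meff are near 1, alpha and RMSEn near 0, and P(t) > 0.05.
#'
#' @param report an [evaluate()] result
#' @param tol_one tolerance around 1 for beta, r2, Meff
#' @param tol_alpha absolute tolerance for alpha (in units of the observed
#'   mean)
#' @param tol_rmsen RMSEn threshold, percent
#' @return named logical vector of pass flags
#' @export
interpret <- function(report, tol_one = 0.2, tol_alpha = 0.2, tol_rmsen = 25) {
  stopifnot(inherits(report, "eval_report"))
  c(beta = abs(report$beta - 1) <= tol_one,
    r2 = report$r2 >= 1 - tol_one,
    m_eff = report$m_eff >= 1 - tol_one,
    alpha = abs(report$alpha) <= tol_alpha,
    rmse_n = report$rmse_n <= tol_rmsen,
    p_t = report$p_t > 0.05)
}

#' Recover the drought tolerance factor by grid search
#'
#' Re-simulates a drought scenario over a DTF grid and picks the value whose
#' biomass trajectory is closest (sum of squared differences on sampled days)
#' to the supplied observations. This is the single-parameter calibration
#' used to check that DTF is identifiable from biomass under noise.
#'
#' @param obs data frame with columns `dae` and `wagt` (observed biomass)
#' @param cfg the [sim_config()] of the scenario (its cultivar's dtf is
#'   ignored)
#' @param grid DTF candidate values
#' @param production production level passed to [run_season()] (a drought
#'   calibration normally uses "water_limited" so DTF is the only active
#'   stress parameter)
#' @return object of class `dtf_fit`: list with `dtf`, `sse` (named vector
#'   over the grid)
#' @export
fit_dtf <- function(obs, cfg, grid = 1:10, production = "actual") {
  sse <- vapply(grid, function(dtf) {
    cfg$cultivar$dtf <- dtf
    sim <- run_season(cfg, production = production)
    idx <- match(obs$dae, sim$daily$dae)
    if (anyNA(idx)) return(Inf)
    sum((sim$daily$wagt[idx] - obs$wagt)^2)
  }, numeric(1))
  names(sse) <- grid
  structure(list(dtf = grid[which.min(sse)], sse = sse), class = "dtf_fit")
}

#' @export
print.dtf_fit <- function(x, ...) {
  cat("<dtf_fit> best DTF:", x$dtf, "\n")
  invisible(x)
}
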