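# Fast refit used inside Monte-Carlo resampling and simulation loops:
# 1-D minimisation of the profile SSR over pKa (coarse grid + golden
# section), with (a, b) solved linearly at each pKa. Same least-squares
# objective as fit_curve, orders of magnitude faster.
fast_fit_pka <- function(ph, csp, lo, hi, b_sign = 0) {
  grid <- seq(lo, hi, by = 0.1)
  ssr <- vapply(grid, function(p) profile_ssr(ph, csp, p, b_sign)$ssr,
                numeric(1))
  i <- which.min(ssr)
  a <- grid[max(1, i - 1)]
  b <- grid[min(length(grid), i + 1)]
  opt <- optimize(function(p) profile_ssr(ph, csp, p, b_sign)$ssr,
                  interval = c(a, b), tol = 1e-6)
  pr <- profile_ssr(ph, csp, opt$minimum, b_sign)
  list(pka = opt$minimum, a = pr$a, b = pr$b, ssr = pr$ssr,
       converged = opt$minimum > lo + 1e-3 && opt$minimum < hi - 1e-3 && pr$b != 0)
}

#' Monte-Carlo error estimate for the fitted pKa
#'
#' Estimates the standard deviation of the fitted pKa by parametric
#' resampling: the residual SD of the best fit,
#' \eqn{\sqrt{SSR/(n-3)}}, sets the noise level; \code{n_rep} synthetic
#' curves are drawn as best-fit model + Gaussian noise on the observed pH
#' grid and refitted; \code{mc_sd} is the sample SD of the refitted pKa
#' over converging replicates. Replicates that fail to converge are
#' dropped (count reported; a warning is raised above 20\%).
#'
#' @param curve the fitted \code{\link{titration_curve}}.
#' @param fit the \code{\link{fit_curve}} result (must have converged).
#' @param n_rep number of synthetic curves (default 1000).
#' @param seed RNG seed; fixed seed gives reproducible \code{mc_sd}.
#' @return the \code{hh_fit} with \code{mc_sd} and \code{mc_n_fail}
#'   filled in.
#' @export
mc_errors <- function(curve, fit, n_rep = 1000, seed = NULL) {
  stopifnot(inherits(fit, "hh_fit"))
  if (!fit$converged) stop("mc_errors requires a converged fit")
  if (!is.null(seed)) set.seed(seed)
  ph <- fit$ph
  yhat <- hh_model(ph, fit$pka, fit$a, fit$b)
  sdres <- fit$residual_sd
  lo <- min(ph) - 1
  hi <- max(ph) + 1
  if (sdres == 0) {
    fit$mc_sd <- 0
    fit$mc_n_fail <- 0L
    return(fit)
  }
  pkas <- rep(NA_real_, n_rep)
  for (r in seq_len(n_rep)) {
    ystar <- yhat + rnorm(length(ph), 0, sdres)
    ff <- fast_fit_pka(ph, ystar, lo, hi, fit$b_sign)
    if (ff$converged) pkas[r] <- ff$pka
  }
  n_fail <- sum(is.na(pkas))
  if (n_fail > 0.2 * n_rep) {
    warning(sprintf("%d/%d Monte-Carlo replicates failed to converge",
                    n_fail, n_rep))
  }
  fit$mc_sd <- sd(pkas, na.rm = TRUE)
  fit$mc_n_fail <- as.integer(n_fail)
  fit
}

#' F-statistic confidence interval for the fitted pKa
#'
#' Profile-likelihood interval for one parameter of a nonlinear
#' least-squares fit: the SSR is profiled over pKa (re-optimising the
#' offset and amplitude at each fixed pKa, a linear subproblem) and the
#' interval collects all pKa with
#' \deqn{SSR(pK_a) \le SSR_{min}\,\left(1 + \frac{F_{1,\,n-3;\,level}}{n-3}\right).}
#' Endpoints are located by bisection to 0.005 pKa units. A side whose
#' endpoint is not bracketed within the sampled pH range +/- 2 units is
#' reported at that search edge and flagged unbounded.
#'
#' @inheritParams mc_errors
#' @param level confidence level (default 0.95).
#' @return the \code{hh_fit} with \code{ci95} (and \code{ci_flags})
#'   filled in.
#' @export
fstat_ci <- function(curve, fit, level = 0.95) {
  stopifnot(inherits(fit, "hh_fit"))
  if (!fit$converged) stop("fstat_ci requires a converged fit")
  ph <- fit$ph
  csp <- fit$csp
  n <- fit$n
  stopifnot(n > 3)
  ssr_min <- min(fit$ssr, profile_ssr(ph, csp, fit$pka, fit$b_sign)$ssr)
  thr <- ssr_min * (1 + qf(level, 1, n - 3) / (n - 3))
  # excess over threshold; < 0 inside the confidence region
  f <- function(p) profile_ssr(ph, csp, p, fit$b_sign)$ssr - thr

  search_lo <- min(ph) - 2
  search_hi <- max(ph) + 2
  flags <- character(0)

  find_edge <- function(from, to) {
    # march from the estimate toward `to` until the region is exited
    step <- 0.1 * sign(to - from)
    p_in <- from
    p <- from + step
    while (sign(to - p) == sign(step) && f(p) <= 0) {
      p_in <- p
      p <- p + step
    }
    if (sign(to - p) != sign(step)) {
      if (f(to) <= 0) return(list(edge = to, open = TRUE))
      p <- to
    }
    a <- p_in; b <- p  # f(a) <= 0 < f(b)
    while (abs(b - a) > 0.005) {
      m <- (a + b) / 2
      if (f(m) <= 0) a <- m else b <- m
    }
    list(edge = (a + b) / 2, open = FALSE)
  }

  lo <- find_edge(fit$pka, search_lo)
  hi <- find_edge(fit$pka, search_hi)
  if (lo$open) flags <- c(flags, "unbounded_low")
  if (hi$open) flags <- c(flags, "unbounded_high")

  fit$ci95 <- c(min(lo$edge, fit$pka), max(hi$edge, fit$pka))
  fit$ci_flags <- flags
  fit
}
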