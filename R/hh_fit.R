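#' Modified Henderson-Hasselbalch model for CSP titration curves
#'
#' \deqn{CSP(x) = b - \frac{b}{1 + 10^{x - pK_a}} + a}
#' where \eqn{x} is the pH, \eqn{a} the offset of the curve (Hz), \eqn{b}
#' its amplitude (Hz) and \eqn{pK_a} the ionization constant. The curve is
#' sigmoidal, running from \eqn{a} at low pH to \eqn{a + b} at high pH,
#' with midpoint \eqn{a + b/2} at \eqn{x = pK_a}.
#'
#' @param x pH value(s).
#' @param pka ionization constant.
#' @param a offset in Hz.
#' @param b amplitude in Hz.
#' @return CSP in Hz.
#' @examples
#' hh_model(7.4, pka = 6.5, a = 0, b = 100)  # 88.8 Hz
#' @export
hh_model <- function(x, pka, a, b) {
  b - b / (1 + 10^(x - pka)) + a
}

# deprotonated-fraction regressor: hh_model = a + b * hh_g(x, pka)
hh_g <- function(x, pka) 1 - 1 / (1 + 10^(x - pka))

# at fixed pKa the model is linear in (a, b): solve by least squares.
# b_sign = +1/-1 clamps the amplitude to that sign (orientation
# constraint); 0 leaves it free.
profile_ssr <- function(ph, csp, pka, b_sign = 0) {
  g <- hh_g(ph, pka)
  n <- length(g)
  sg <- sum(g); sgg <- sum(g * g)
  sy <- sum(csp); sgy <- sum(g * csp)
  det <- n * sgg - sg * sg
  if (det <= 1e-12 * max(n * sgg, 1)) { # degenerate design (g ~ constant)
    a <- sy / n; b <- 0
  } else {
    b <- (n * sgy - sg * sy) / det
    if (b_sign != 0 && sign(b) == -b_sign) {
      a <- sy / n; b <- 0
    } else {
      a <- (sy - b * sg) / n
    }
  }
  r <- csp - (a + b * g)
  list(ssr = sum(r * r), a = a, b = b)
}

# orientation of a CSP curve: +1 when it rises with pH (low-pH reference),
# -1 when it falls toward the high-pH reference
curve_orientation <- function(ph, csp) {
  n <- length(ph)
  lo <- csp[seq_len(ceiling(n / 2))]
  hi <- csp[seq(floor(n / 2) + 1, n)]
  s <- sign(mean(hi) - mean(lo))
  if (s == 0) 1 else s
}

#' Fit a titration curve to the Henderson-Hasselbalch model
#'
#' Least-squares fit of \code{\link{hh_model}} to a CSP-versus-pH curve.
#' Starting values: \code{a0} is the CSP at the pH extreme nearest the
#' reference point, \code{b0} the CSP range, and \code{pka0} the pH where
#' the curve crosses half-range (linear interpolation). The pKa is bounded
#' to \code{[min(ph) - 1, max(ph) + 1]}; a fit whose pKa lands on a
#' bound, or whose amplitude is not resolved above the residual noise
#' (|b| < 2 residual SD, an unidentifiable pKa), is reported with
#' \code{converged = FALSE}. Estimates within 0.3 pH
#' units of the sampled range edge carry \code{boundary_flag = TRUE},
#' signalling an incompletely sampled transition.
#'
#' @param curve a \code{\link{titration_curve}} (or any data frame with
#'   \code{ph} and \code{csp} columns), n >= 4.
#' @param constrain_b constrain the sign of the amplitude \code{b} to the
#'   curve's orientation (default TRUE). CSPs are magnitudes, so a curve
#'   referenced at the high-pH end falls with pH (\code{b < 0}) and one
#'   referenced at the low-pH end rises (\code{b > 0}); the constraint
#'   rules out sign-flipped fits.
#' @return an \code{hh_fit} object with elements \code{pka}, \code{a},
#'   \code{b}, \code{residual_sd}, \code{ssr}, \code{n}, \code{converged},
#'   \code{boundary_flag}; \code{mc_sd} and \code{ci95} are NA until
#'   filled in by \code{\link{mc_errors}} / \code{\link{fstat_ci}}.
#' @seealso \code{\link{fit_titration}} for the one-call wrapper.
#' @export
fit_curve <- function(curve, constrain_b = TRUE) {
  ph <- curve$ph
  csp <- curve$csp
  stopifnot(all(is.finite(ph)), all(is.finite(csp)))
  n <- length(ph)
  if (n < 4) stop("insufficient data: need >= 4 points to fit 3 parameters, got ", n)
  if (diff(range(ph)) <= 0) stop("pH span must be positive")
  if (sd(csp) == 0) stop("degenerate fit: CSP has zero variance")

  ord <- order(ph)
  ph <- ph[ord]; csp <- csp[ord]
  lo_pka <- min(ph) - 1
  hi_pka <- max(ph) + 1
  b_sign <- if (constrain_b) curve_orientation(ph, csp) else 0

  # a is the low-pH plateau of the model, a + b the high-pH plateau
  a0 <- csp[1]
  b0 <- csp[n] - csp[1]
  half <- (max(csp) + min(csp)) / 2
  cross <- which(diff(sign(csp - half)) != 0)
  pka0 <- if (length(cross) > 0) {
    i <- cross[1]
    ph[i] + (half - csp[i]) * (ph[i + 1] - ph[i]) / (csp[i + 1] - csp[i])
  } else {
    mean(range(ph))
  }
  pka0 <- min(max(pka0, lo_pka + 1e-3), hi_pka - 1e-3)

  dat <- data.frame(x = ph, y = csp)
  lower <- c(pka = lo_pka, a = -Inf, b = if (b_sign > 0) 0 else -Inf)
  upper <- c(pka = hi_pka, a = Inf, b = if (b_sign < 0) 0 else Inf)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ hh_model(x, pka, a, b), data = dat,
                      start = c(pka = pka0, a = a0, b = b0),
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  if (is.null(fit)) {
    # fall back to 1-D profile over pKa with linear (a, b) at each value
    opt <- optimize(function(p) profile_ssr(ph, csp, p, b_sign)$ssr,
                    interval = c(lo_pka, hi_pka))
    pr <- profile_ssr(ph, csp, opt$minimum, b_sign)
    est <- c(pka = opt$minimum, a = pr$a, b = pr$b)
    ssr <- pr$ssr
    minimiser_ok <- TRUE
  } else {
    est <- coef(fit)[c("pka", "a", "b")]
    ssr <- sum(residuals(fit)^2)
    minimiser_ok <- fit$convInfo$isConv
  }

  at_bound <- est["pka"] <= lo_pka + 1e-6 || est["pka"] >= hi_pka - 1e-6
  ssr0 <- ssr
  resid_sd <- sqrt(ssr0 / (n - 3))
  # pKa is unidentifiable when the amplitude is not resolved above noise
  identifiable <- abs(est["b"]) >= 2 * resid_sd
  converged <- isTRUE(minimiser_ok) && !at_bound && identifiable
  boundary_flag <- est["pka"] < min(ph) + 0.3 || est["pka"] > max(ph) - 0.3

  structure(
    list(pka = unname(est["pka"]), a = unname(est["a"]), b = unname(est["b"]),
         ssr = ssr, residual_sd = sqrt(ssr / (n - 3)), n = n,
         converged = converged, boundary_flag = unname(boundary_flag),
         mc_sd = NA_real_, ci95 = c(NA_real_, NA_real_),
         ci_flags = character(0), mc_n_fail = NA_integer_,
         constrain_b = constrain_b, b_sign = b_sign,
         residue = attr(curve, "residue"),
         ph = ph, csp = csp),
    class = "hh_fit")
}

#' @export
print.hh_fit <- function(x, ...) {
  lab <- if (is.null(x$residue)) "curve" else x$residue
  cat(sprintf("<hh_fit> %s: pKa = %.2f", lab, x$pka))
  if (is.finite(x$mc_sd)) cat(sprintf(" +/- %.2f", x$mc_sd))
  if (all(is.finite(x$ci95))) cat(sprintf(" [%.2f-%.2f]", x$ci95[1], x$ci95[2]))
  cat(sprintf("\n  a = %.1f Hz, b = %.1f Hz, residual SD = %.2f Hz, n = %d\n",
              x$a, x$b, x$residual_sd, x$n))
  if (!x$converged) cat("  WARNING: fit did not converge (or pKa at bound)\n")
  if (x$boundary_flag) cat("  note: pKa within 0.3 units of the sampled pH range edge\n")
  if (length(x$ci_flags)) cat("  CI flags:", paste(x$ci_flags, collapse = ", "), "\n")
  invisible(x)
}

#' Fitted values and residuals of an hh_fit
#' @param object an \code{hh_fit}.
#' @param ... unused.
#' @export
fitted.hh_fit <- function(object, ...) {
  hh_model(object$ph, object$pka, object$a, object$b)
}

#' @rdname fitted.hh_fit
#' @export
residuals.hh_fit <- function(object, ...) {
  object$csp - fitted(object)
}

#' Fit, Monte-Carlo error and F-statistic CI in one call
#'
#' Runs \code{\link{fit_curve}}, \code{\link{mc_errors}} and
#' \code{\link{fstat_ci}} and returns the completed \code{hh_fit}.
#'
#' @inheritParams fit_curve
#' @param n_mc Monte-Carlo replicates (default 1000).
#' @param seed RNG seed for the Monte-Carlo resampling.
#' @param level confidence level for the F-statistic interval.
#' @return an \code{hh_fit} with \code{mc_sd} and \code{ci95} filled in.
#' @export
fit_titration <- function(curve, constrain_b = TRUE, n_mc = 1000,
                          seed = NULL, level = 0.95) {
  fit <- fit_curve(curve, constrain_b = constrain_b)
  if (fit$converged) {
    fit <- mc_errors(curve, fit, n_rep = n_mc, seed = seed)
    fit <- fstat_ci(curve, fit, level = level)
  }
  fit
}
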