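# Weighted r-squared with the degenerate-data conventions used throughout:
# r2 = 1 when the weighted residual sum of squares is (numerically) zero,
# otherwise 1 - ss_res / ss_tot with ss_tot floored at 1e-12 so constant
# curves do not divide by zero.
weighted_r2 <- function(y, mu, w) {
  ss_res <- sum(w * (y - mu)^2)
  ybar <- sum(w * y) / sum(w)
  ss_tot <- sum(w * (y - ybar)^2)
  r2 <- if (ss_res <= 1e-12) 1 else 1 - ss_res / max(ss_tot, 1e-12)
  list(r_squared = r2, ss_res = ss_res, ss_tot = ss_tot)
}

new_fit <- function(model, coefficients, r2, converged, n_bins) {
  structure(
    list(model = model, coefficients = coefficients,
         r_squared = r2$r_squared, ss_res = r2$ss_res, ss_tot = r2$ss_tot,
         converged = converged, n_bins = n_bins),
    class = "acq_fit"
  )
}

curve_points <- function(curve) {
  nz <- curve$counted > 0L
  list(x = curve$bin_centre[nz], y = curve$probability[nz],
       w = as.numeric(curve$counted[nz]), n = sum(nz))
}

#' Weighted linear fit to an acquisition curve
#'
#' Exact closed-form weighted least squares of per-bin adoption probability
#' on bin centre, weights = per-bin counted totals.
#'
#' @param curve An [build_curve()] result with at least 2 nonempty bins.
#' @return Class `acq_fit` with `coefficients = c(intercept, slope)` and a
#'   count-weighted `r_squared`.
#' @export
fit_linear <- function(curve) {
  p <- curve_points(curve)
  if (p$n < 2L) stop("underdetermined fit: need >= 2 nonempty bins")
  sw <- sum(p$w)
  xb <- sum(p$w * p$x) / sw
  yb <- sum(p$w * p$y) / sw
  sxx <- sum(p$w * (p$x - xb)^2)
  slope <- sum(p$w * (p$x - xb) * (p$y - yb)) / sxx
  intercept <- yb - slope * xb
  mu <- intercept + slope * p$x
  new_fit("linear", c(intercept = intercept, slope = slope),
          weighted_r2(p$y, mu, p$w), TRUE, p$n)
}

#' Weighted sigmoid fit to an acquisition curve
#'
#' Nonlinear weighted least squares of one of two sigmoid forms:
#' \describe{
#'   \item{logistic2}{`y = 1 / (1 + exp(-(a + b x)))` — two parameters,
#'     deliberately matching the linear model's complexity so a raw
#'     r-squared comparison is fair. Fitted by BFGS from multiple starts
#'     (gain b in ±1, ±5, ±20, plus a logit-regression start); the best
#'     converged start is kept.}
#'   \item{freq_bias}{`y = x^theta / (x^theta + (1-x)^theta)` — the
#'     one-parameter frequency-bias curve with fixed endpoints; `theta = 1`
#'     is the neutral identity. Fitted by 1-D optimization of log(theta).}
#' }
#'
#' @param curve An acquisition curve with >= 3 (`logistic2`) or >= 2
#'   (`freq_bias`) nonempty bins.
#' @param form `"logistic2"` or `"freq_bias"`.
#' @return Class `acq_fit`; `converged = FALSE` flags an optimizer failure
#'   (such fits are excluded from comparisons).
#' @export
fit_sigmoid <- function(curve, form = c("logistic2", "freq_bias")) {
  form <- match.arg(form)
  p <- curve_points(curve)
  min_bins <- if (form == "logistic2") 3L else 2L
  if (p$n < min_bins) {
    stop("underdetermined fit: need >= ", min_bins, " nonempty bins")
  }
  if (form == "logistic2") {
    fn <- function(par) {
      mu <- stats::plogis(par[1] + par[2] * p$x)
      sum(p$w * (p$y - mu)^2)
    }
    gr <- function(par) {
      mu <- stats::plogis(par[1] + par[2] * p$x)
      d <- -2 * p$w * (p$y - mu) * mu * (1 - mu)
      c(sum(d), sum(d * p$x))
    }
    starts <- lapply(c(-20, -5, -1, 1, 5, 20), function(b) c(-b / 2, b))
    yc <- pmin(pmax(p$y, 1e-3), 1 - 1e-3)
    lg <- stats::lm.wfit(cbind(1, p$x), stats::qlogis(yc), p$w)
    starts <- c(starts, list(unname(lg$coefficients)))
    best <- NULL
    conv <- FALSE
    for (s in starts) {
      res <- tryCatch(
        stats::optim(s, fn, gr, method = "BFGS",
                     control = list(maxit = 500)),
        error = function(e) NULL
      )
      if (is.null(res) || !is.finite(res$value)) next
      ok <- res$convergence == 0L
      if (is.null(best) || (ok && !conv) ||
          (ok == conv && res$value < best$value)) {
        if (ok >= conv) { best <- res; conv <- ok }
      }
    }
    if (is.null(best)) {
      return(new_fit("logistic2", c(a = NA_real_, b = NA_real_),
                     list(r_squared = NA_real_, ss_res = NA_real_,
                          ss_tot = NA_real_), FALSE, p$n))
    }
    mu <- stats::plogis(best$par[1] + best$par[2] * p$x)
    new_fit("logistic2", c(a = best$par[1], b = best$par[2]),
            weighted_r2(p$y, mu, p$w), conv, p$n)
  } else {
    fb <- function(x, theta) {
      num <- x^theta
      num / (num + (1 - x)^theta)
    }
    fn <- function(lt) sum(p$w * (p$y - fb(p$x, exp(lt)))^2)
    opt <- stats::optimize(fn, c(-7, 7))
    theta <- exp(opt$minimum)
    mu <- fb(p$x, theta)
    new_fit("freq_bias", c(theta = theta),
            weighted_r2(p$y, mu, p$w), TRUE, p$n)
  }
}

#' Linear-versus-sigmoid fit comparison
#'
#' Fits both models to the same curve and compares their count-weighted
#' r-squared values. `relative_fit = r2_linear - r2_sigmoid`; the sigmoid is
#' declared better only when `relative_fit < -tie_tol` (ties resolve toward
#' the linear null shape, conservatively not inferring conformity). If the
#' sigmoid fit fails or cannot be attempted, the comparison is reported
#' linear-only with `sigmoid_ok = FALSE` and a warning.
#'
#' @param curve An acquisition curve.
#' @param sigmoid_form Passed to [fit_sigmoid()].
#' @param tie_tol Tie tolerance on `relative_fit` (default 1e-6).
#' @return Class `fit_comparison`: list with `linear`, `sigmoid` (possibly
#'   `NULL`), `relative_fit`, `better` ("linear"/"sigmoid"), `sigmoid_ok`.
#' @export
compare_fits <- function(curve, sigmoid_form = "logistic2",
                         tie_tol = 1e-6) {
  lin <- fit_linear(curve)
  sig <- tryCatch(fit_sigmoid(curve, sigmoid_form),
                  error = function(e) NULL)
  if (is.null(sig) || !sig$converged) {
    warning("sigmoid fit unavailable; reporting linear-only comparison")
    return(structure(
      list(linear = lin, sigmoid = sig, relative_fit = NA_real_,
           better = "linear", sigmoid_ok = FALSE),
      class = "fit_comparison"
    ))
  }
  rel <- lin$r_squared - sig$r_squared
  structure(
    list(linear = lin, sigmoid = sig, relative_fit = rel,
         better = if (rel < -tie_tol) "sigmoid" else "linear",
         sigmoid_ok = TRUE),
    class = "fit_comparison"
  )
}

#' @export
print.acq_fit <- function(x, ...) {
  cat("<acq_fit>", x$model, "|",
      paste(names(x$coefficients),
            format(x$coefficients, digits = 4), sep = "=", collapse = " "),
      "| r2 =", format(x$r_squared, digits = 4),
      if (!x$converged) "| NOT CONVERGED" else "", "\n")
  invisible(x)
}

#' @export
print.fit_comparison <- function(x, ...) {
  cat("<fit_comparison> better:", x$better,
      "| r2 linear =", format(x$linear$r_squared, digits = 4),
      if (x$sigmoid_ok) {
        paste("| r2 sigmoid =", format(x$sigmoid$r_squared, digits = 4),
              "| relative_fit =", format(x$relative_fit, digits = 4))
      } else "| sigmoid unavailable", "\n")
  invisible(x)
}
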