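#' Boltzmann sigmoid of transition pressure against pH
#'
#' The liquid-expanded / liquid-condensed transition pressure of a titratable
#' lipid follows a four-parameter Boltzmann sigmoid in subphase pH,
#' `pi_T(pH) = A2 + (A1 - A2) / (1 + exp((pH - x0) / dx))`:
#' `A1` is the acidic (fully protonated) plateau, `A2` the alkaline plateau,
#' `x0` the inflection pH and `dx` the width. For this model the pH of
#' maximal slope — the operational pKa — is exactly `x0`.
#'
#' @param ph pH values.
#' @param A1,A2 Acidic and alkaline plateau pressures in mN/m.
#' @param x0 Inflection pH.
#' @param dx Width in pH units, > 0.
#' @return Transition pressure(s) in mN/m.
#' @examples
#' boltzmann_sigmoid(7, A1 = 4.5, A2 = 24.4, x0 = 5.4, dx = 0.83)
#' @export
boltzmann_sigmoid <- function(ph, A1, A2, x0, dx) {
  A2 + (A1 - A2) / (1 + exp((ph - x0) / dx))
}

#' Validate a transition-pressure titration curve
#'
#' @param data A data frame with columns `ph` and `transition_pressure`
#'   (mN/m), one row per subphase pH.
#' @return A `transition_curve` tibble, sorted by pH.
#' @export
transition_curve <- function(data) {
  data <- as_tibble(data)
  req <- c("ph", "transition_pressure")
  if (!all(req %in% names(data))) {
    abort("`data` needs columns `ph` and `transition_pressure`.")
  }
  if (nrow(data) < 5L) abort("A transition curve needs at least 5 points.")
  if (any(data$ph < 0) || any(data$ph > 14)) abort("`ph` must lie in [0, 14].")
  out <- arrange(data[req], .data$ph)
  class(out) <- c("transition_curve", class(out))
  out
}

#' Fit the Boltzmann sigmoid to a titration curve
#'
#' Least-squares fit of `pi_T(pH) = A2 + (A1 - A2)/(1 + exp((pH - x0)/dx))`
#' by Levenberg-Marquardt. Starting values are taken from the data (plateaus
#' from the extremes, `x0` from the half-rise crossing, `dx` from the
#' 25-75% rise span) and `dx` is box-constrained to `[0.05, 5]` pH units.
#' The pKa is reported as the pH of maximal absolute slope of the fitted
#' curve, which for this model equals the fitted `x0`.
#'
#' @param curve A data frame with columns `ph` and `transition_pressure`, or
#'   a [transition_curve()].
#' @param init Optional named list overriding any of the starting values
#'   `A1`, `A2`, `x0`, `dx`.
#' @return An object of class `sigmoid_fit`: a list with elements
#'   `A1`, `A2`, `x0`, `dx` (mN/m, mN/m, pH, pH), `pka`, `sigma`
#'   (residual sd), `converged`, `n`, `data` and the underlying `nls` fit.
#' @seealso [dissociation_degree()], [tidy.sigmoid_fit()]
#' @examples
#' pts <- make_transition_points(
#'   list(A1 = 4.5, A2 = 24.4, x0 = 5.4, dx = 0.83),
#'   ph_grid = seq(3, 9, by = 0.5), noise_sd = 0, seed = 1
#' )
#' fit <- fit_sigmoid(pts)
#' fit$pka
#' @export
fit_sigmoid <- function(curve, init = NULL) {
  curve <- transition_curve(curve)
  y <- curve$transition_pressure
  x <- curve$ph

  rng <- range(y)
  if (diff(rng) < 1e-8 * max(1, abs(mean(y)))) {
    abort("Degenerate titration curve: transition pressure does not vary with pH.")
  }

  start <- sigmoid_start(x, y)
  if (!is.null(init)) {
    bad <- setdiff(names(init), c("A1", "A2", "x0", "dx"))
    if (length(bad)) abort(paste0("Unknown init parameter(s): ", toString(bad)))
    start[names(init)] <- init
  }

  fit <- minpack.lm::nlsLM(
    transition_pressure ~ boltzmann_sigmoid(ph, A1, A2, x0, dx),
    data = curve,
    start = start,
    lower = c(A1 = -Inf, A2 = -Inf, x0 = min(x) - 2, dx = 0.05),
    upper = c(A1 = Inf, A2 = Inf, x0 = max(x) + 2, dx = 5),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )

  cf <- coef(fit)
  if (abs(cf[["A2"]] - cf[["A1"]]) < 1e-6) {
    abort("Degenerate sigmoid: fitted plateaus coincide (A1 = A2).")
  }
  at_bound <- cf[["dx"]] <= 0.05 + 1e-10 || cf[["dx"]] >= 5 - 1e-10
  if (at_bound) {
    warn("Fitted width `dx` is pinned at its bound; the pKa is unreliable.")
  }

  structure(
    list(
      A1 = cf[["A1"]], A2 = cf[["A2"]], x0 = cf[["x0"]], dx = cf[["dx"]],
      pka = cf[["x0"]],
      sigma = sqrt(sum(stats::resid(fit)^2) / max(1, length(y) - 4)),
      converged = fit$convInfo$isConv && !at_bound,
      n = length(y),
      data = curve,
      fit = fit
    ),
    class = "sigmoid_fit"
  )
}

# data-driven starting values for the four sigmoid parameters
sigmoid_start <- function(x, y) {
  increasing <- stats::cor(x, y) >= 0
  lo <- min(y); hi <- max(y)
  A1 <- if (increasing) lo else hi   # acidic plateau
  A2 <- if (increasing) hi else lo
  mid <- (lo + hi) / 2
  x0 <- stats::approx(y, x, xout = mid, ties = mean)$y
  if (!is.finite(x0)) x0 <- stats::median(x)
  q <- stats::approx(y, x, xout = lo + c(0.25, 0.75) * (hi - lo), ties = mean)$y
  # 25-75% rise of a logistic spans 2*log(3)*dx
  dx <- abs(diff(q)) / (2 * log(3))
  if (!is.finite(dx) || dx <= 0) dx <- diff(range(x)) / 6
  list(A1 = A1, A2 = A2, x0 = x0, dx = min(max(dx, 0.05), 5))
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat("<sigmoid_fit> pi_T(pH) = A2 + (A1 - A2)/(1 + exp((pH - x0)/dx))\n")
  cat(sprintf("  A1 = %.4g mN/m, A2 = %.4g mN/m, x0 = %.4g, dx = %.4g\n",
              x$A1, x$A2, x$x0, x$dx))
  cat(sprintf("  pKa = %.4g (pH of maximal slope), residual sd = %.3g mN/m, n = %d\n",
              x$pka, x$sigma, x$n))
  invisible(x)
}

#' Evaluate a fitted sigmoid
#'
#' @param object A `sigmoid_fit`.
#' @param newdata Optional data frame with a `ph` column; defaults to the
#'   fitted data.
#' @param ... Unused.
#' @return Predicted transition pressures in mN/m.
#' @export
predict.sigmoid_fit <- function(object, newdata = NULL, ...) {
  ph <- if (is.null(newdata)) object$data$ph else newdata$ph
  boltzmann_sigmoid(ph, object$A1, object$A2, object$x0, object$dx)
}

#' Dissociation degree of the titratable head group
#'
#' The deprotonated fraction read off the transition-pressure sigmoid as its
#' normalised rise, `alpha(pH) = (pi_T(pH) - A1) / (A2 - A1)`, which for the
#' Boltzmann model reduces to the logistic `1 / (1 + exp(-(pH - x0)/dx))`.
#' It is monotone increasing in pH, equals 1/2 at the pKa and is clamped to
#' `[0, 1]`.
#'
#' @param fit A converged [fit_sigmoid()] object, or a named list with
#'   elements `x0` and `dx`.
#' @param ph pH value(s).
#' @return Dissociation degree(s) in `[0, 1]`.
#' @examples
#' dissociation_degree(list(x0 = 5.4, dx = 0.83), 7)   # about 0.873
#' @export
dissociation_degree <- function(fit, ph) {
  if (inherits(fit, "sigmoid_fit") && !isTRUE(fit$converged)) {
    abort("`fit` did not converge; dissociation degree undefined.")
  }
  if (is.null(fit$x0) || is.null(fit$dx)) {
    abort("`fit` must provide `x0` and `dx`.")
  }
  pmin(pmax(stats::plogis((ph - fit$x0) / fit$dx), 0), 1)
}

#' @describeIn fit_sigmoid One row per parameter with `term` and `estimate`.
#' @param x A `sigmoid_fit`.
#' @param ... Unused.
#' @export
tidy.sigmoid_fit <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble(
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    std.error = cf[, "Std. Error"],
    statistic = cf[, "t value"],
    p.value = cf[, "Pr(>|t|)"]
  )
}

#' @describeIn fit_sigmoid One-row model summary with `pka`, `sigma`,
#'   `converged`, `n`.
#' @export
glance.sigmoid_fit <- function(x, ...) {
  tibble(pka = x$pka, A1 = x$A1, A2 = x$A2, dx = x$dx,
         sigma = x$sigma, converged = x$converged, n = x$n)
}
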