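#' Classify a trajectory as converged or oscillatory
#'
#' Operationalises the stable/oscillatory dichotomy of delay-driven immune
#' dynamics: on the post-transient window (the last `1 - transient` fraction
#' of the trajectory) each compartment's relative amplitude
#' \eqn{(\max - \min)/\mathrm{scale}} is measured, where the scale is the
#' window mean of the compartment (floored at `1e-6` of the largest
#' compartment mean, so compartments decaying to zero report amplitude
#' zero rather than 0/0 noise).
#'
#' Classification: `converged` when every relative amplitude is below
#' `eps_conv`; `oscillatory` when the virus-component amplitude is at least
#' `eps_osc` *and* is not decaying (the amplitude over the last quarter of
#' the window is at least 80% of that over the preceding quarter);
#' `undecided` otherwise.  The dominant period is the median spacing of
#' successive virus-component peaks in the window.
#'
#' @param traj a `"viral_trajectory"`.
#' @param transient fraction of the trajectory discarded as transient.
#' @param eps_conv,eps_osc relative-amplitude thresholds separating damped
#'   from sustained motion.
#' @return Object of class `"oscillation_report"`: per-variable relative
#'   `amplitudes`, `period` (NA unless oscillatory), `classification`.
#' @export
detect_oscillation <- function(traj, transient = 0.7, eps_conv = 1e-3,
                               eps_osc = 1e-2) {
  stopifnot(transient > 0, transient < 1)
  n <- nrow(traj$states)
  i0 <- max(1L, floor(n * transient))
  W <- traj$states[i0:n, , drop = FALSE]
  tw <- traj$times[i0:n]

  means <- colMeans(W)
  floor_scale <- 1e-6 * max(abs(means), 1e-300)
  scales <- pmax(abs(means), floor_scale)
  amps <- apply(W, 2, function(col) diff(range(col))) / scales

  # amplitude trend: last quarter vs the one before
  nq <- nrow(W) %/% 4
  ampq <- function(block) diff(range(block))
  v <- W[, "v"]
  a_prev <- ampq(v[(nrow(W) - 2 * nq + 1):(nrow(W) - nq)])
  a_last <- ampq(v[(nrow(W) - nq + 1):nrow(W)])
  sustained <- a_last >= 0.8 * a_prev

  period <- NA_real_
  classification <- if (all(amps < eps_conv)) "converged"
  else if (amps[["v"]] >= eps_osc && sustained) "oscillatory"
  else "undecided"

  if (classification == "oscillatory") {
    pk <- which(diff(sign(diff(v))) == -2) + 1
    if (length(pk) >= 3) period <- stats::median(diff(tw[pk]))
  }

  structure(list(amplitudes = amps, period = period,
                 classification = classification,
                 window = c(tw[1], tw[length(tw)])),
            class = "oscillation_report")
}

#' @export
print.oscillation_report <- function(x, ...) {
  cat("Oscillation report (window [", format(x$window[1]), ", ",
      format(x$window[2]), "]): ", x$classification, "\n", sep = "")
  cat("  relative amplitudes: ",
      paste(names(x$amplitudes), format(x$amplitudes, digits = 3),
            sep = " = ", collapse = ", "), "\n", sep = "")
  if (!is.na(x$period))
    cat("  dominant period: ", format(x$period, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Sweep the immune-response delay for stability switches
#'
#' Integrates the model once per value of \eqn{\tau_3}, classifies each
#' trajectory with [detect_oscillation()], and reports the grid intervals
#' where the classification changes (the numerically observed stability
#' switches / Hopf bifurcation windows).  All other parameters, the
#' history, the horizon and the step are held fixed across the sweep, so a
#' rerun is bit-identical.
#'
#' @param model a [viral_model()]; its own `tau3` is ignored.
#' @param tau3 sorted nonnegative grid of immune-delay values.
#' @param t_end,h integration horizon and step (passed to
#'   [simulate.viral_model()]).
#' @param history history passed to the integrator; default is the
#'   \eqn{\tau_3 = 0} regime equilibrium perturbed by +10%.
#' @param ... further arguments for [detect_oscillation()].
#' @return Object of class `"tau3_scan"`: a data frame (`tau3`, per-variable
#'   amplitudes, `period`, `classification`) plus `switches`, the grid
#'   intervals over which the classification changes.
#' @examples
#' \donttest{
#' scan_tau3(example_model(17), tau3 = c(0.2, 2), t_end = 1500, h = 0.02)
#' }
#' @export
scan_tau3 <- function(model, tau3, t_end = 3000, h = 0.01, history = NULL,
                      ...) {
  stopifnot(is.numeric(tau3), !is.unsorted(tau3), all(tau3 >= 0))
  if (is.null(history)) history <- default_history_state(set_tau3(model, 0))
  rows <- lapply(tau3, function(t3) {
    m <- set_tau3(model, t3)
    rep <- tryCatch({
      tr <- stats::simulate(m, t_end = t_end, h = h, history = history)
      detect_oscillation(tr, ...)
    }, error = function(e) {
      warning("tau3 = ", t3, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(rep))
      return(data.frame(tau3 = t3, amplitude_x = NA, amplitude_y = NA,
                        amplitude_v = NA, amplitude_z = NA, amplitude_w = NA,
                        period = NA, classification = "error"))
    data.frame(tau3 = t3,
               amplitude_x = rep$amplitudes[["x"]],
               amplitude_y = rep$amplitudes[["y"]],
               amplitude_v = rep$amplitudes[["v"]],
               amplitude_z = rep$amplitudes[["z"]],
               amplitude_w = rep$amplitudes[["w"]],
               period = rep$period,
               classification = rep$classification)
  })
  grid <- do.call(rbind, rows)
  chg <- which(grid$classification[-1] != grid$classification[-nrow(grid)])
  switches <- if (length(chg))
    data.frame(tau3_lo = grid$tau3[chg], tau3_hi = grid$tau3[chg + 1],
               from = grid$classification[chg],
               to = grid$classification[chg + 1])
  else data.frame(tau3_lo = numeric(0), tau3_hi = numeric(0),
                  from = character(0), to = character(0))
  structure(list(grid = grid, switches = switches,
                 t_end = t_end, h = h, history = history),
            class = "tau3_scan")
}

#' @export
print.tau3_scan <- function(x, ...) {
  cat("Immune-delay sweep (t_end = ", format(x$t_end), ", h = ",
      format(x$h), "):\n", sep = "")
  print(x$grid, row.names = FALSE)
  if (nrow(x$switches)) {
    cat("classification switches:\n")
    print(x$switches, row.names = FALSE)
  } else cat("no classification switches on the grid\n")
  invisible(x)
}

# H(xi) = xi - 1 - log(xi) >= 0, = 0 iff xi = 1: the Volterra-type distance
# used throughout the Lyapunov functionals
lyap_H <- function(xi) {
  if (any(xi <= 0)) stop("H(xi) requires xi > 0")
  xi - 1 - log(xi)
}

# composite Simpson on [t - tau, t] through the dense interpolant;
# integrand fn maps a state matrix (rows = times) to values
delay_integral <- function(traj, t, tau, fn, h_max) {
  if (tau == 0) return(0)
  nseg <- max(2, 2 * ceiling(tau / (2 * h_max)))
  ts <- seq(t - tau, t, length.out = nseg + 1)
  vals <- fn(dense_eval(traj, ts))
  hseg <- tau / nseg
  w <- rep(c(2, 4), length.out = nseg - 1)
  hseg / 3 * (vals[1] + vals[nseg + 1] + sum(w * vals[2:nseg]))
}

#' Evaluate a Lyapunov functional along a trajectory
#'
#' Numerically evaluates one of the five trajectory functionals whose decay
#' certifies global stability of the corresponding equilibrium:
#' `V1` (infection-free E0), `V2` (immune-free E1), `V3` (antibody-only E2),
#' `V4` (CTL-only E3, \eqn{\tau_3 = 0}), `V5` (coexistence E4,
#' \eqn{\tau_3 = 0}).  Each functional combines Volterra-type distances
#' \eqn{H(\xi) = \xi - 1 - \ln\xi} of the state to the reference
#' equilibrium with delay-window integrals over \eqn{[t - \tau_i, t]},
#' evaluated by composite Simpson quadrature on the dense interpolant (node
#' spacing at most the integration step).  Within its regime the value is
#' nonnegative and nonincreasing along solutions.
#'
#' @param model a [viral_model()].
#' @param traj a `"viral_trajectory"` of that model covering
#'   \eqn{[t - \tau, t]}.
#' @param t evaluation time(s), \eqn{\ge 0}.
#' @param functional one of `"V1"`..`"V5"`.
#' @param eq optional precomputed reference `"viral_equilibrium"` (E0 for
#'   V1, E1 for V2, ... E4 for V5); solved from the model if missing.
#' @return Object(s) of class `"lyapunov_value"`: functional id, time,
#'   value, and a central finite-difference estimate of \eqn{dV/dt} (NA at
#'   the trajectory ends).  For vector `t` a data frame.
#' @export
lyapunov_functional <- function(model, traj, t,
                                functional = c("V1", "V2", "V3", "V4", "V5"),
                                eq = NULL) {
  functional <- match.arg(functional)
  lab <- c(V1 = "E0", V2 = "E1", V3 = "E2", V4 = "E3", V5 = "E4")[functional]
  if (is.null(eq)) eq <- solve_equilibrium(model, lab)
  if (!eq$exists)
    stop("reference equilibrium ", lab, " of ", functional,
         " does not exist for this model")
  if (length(t) > 1) {
    rows <- lapply(t, function(tt)
      as.data.frame(unclass(
        lyapunov_functional(model, traj, tt, functional, eq)
      )[c("functional", "t", "value", "dVdt")]))
    return(do.call(rbind, rows))
  }
  Tend <- traj$times[length(traj$times)]
  if (t < 0 || t > Tend) stop("t outside trajectory domain")
  val <- lyap_eval(model, traj, t, functional, eq)
  dt <- 2 * traj$h
  dVdt <- if (t - dt >= 0 && t + dt <= Tend)
    (lyap_eval(model, traj, t + dt, functional, eq) -
       lyap_eval(model, traj, t - dt, functional, eq)) / (2 * dt)
  else NA_real_
  structure(list(functional = functional, t = t, value = val, dVdt = dVdt,
                 equilibrium = eq$label),
            class = "lyapunov_value")
}

#' @export
print.lyapunov_value <- function(x, ...) {
  cat(sprintf("%s(t = %g) = %.8g", x$functional, x$t, x$value))
  if (!is.na(x$dVdt)) cat(sprintf("   dV/dt ~ %.3e", x$dVdt))
  cat("\n")
  invisible(x)
}

lyap_eval <- function(model, traj, t, functional, eq) {
  rr <- model$rates
  g <- model$removals
  f <- model$incidence$f
  taus <- model$delays
  em1 <- exp(rr$m1 * taus[["tau1"]])
  em2 <- exp(rr$m2 * taus[["tau2"]])
  st <- drop(dense_eval(traj, t))
  x <- st[["x"]]; y <- st[["y"]]; v <- st[["v"]]
  z <- st[["z"]]; w <- st[["w"]]
  hq <- traj$h

  # Goh-Volterra bracket  int_{ue}^{u} (1 - K(ue)/K(theta)) dtheta >= 0,
  # vanishing iff u = ue; K is a monotone kernel evaluated in closed form
  bracket <- function(u, ue, Kfun) {
    if (u <= 0 && ue > 0)
      stop("domain error: state hit zero where a positive ratio is required")
    if (u == ue) return(0)
    u - ue - stats::integrate(function(th) Kfun(ue) / Kfun(th), ue, u,
                              rel.tol = 1e-10, abs.tol = 0)$value
  }

  if (functional == "V1") {
    fv0 <- function(xx) model$incidence$fv(xx, 0)
    xbar <- eq$state[["x"]]
    term_x <- x - xbar - stats::integrate(function(th) fv0(xbar) / fv0(th),
                                          xbar, x, rel.tol = 1e-10,
                                          abs.tol = 0)$value
    I1 <- delay_integral(traj, t, taus[["tau1"]],
                         function(S) f(S[, "x"], S[, "v"]), hq)
    I2 <- delay_integral(traj, t, taus[["tau2"]],
                         function(S) g$g1$g(S[, "y"]), hq)
    I3 <- delay_integral(traj, t, taus[["tau3"]],
                         function(S) g$g1$g(S[, "y"]) * g$g4$g(S[, "z"]), hq)
    return(term_x + em1 * y + rr$a * em1 * em2 / rr$k * v +
             rr$p * em1 / rr$c * z + I1 + rr$a * em1 * I2 + rr$p * em1 * I3 +
             rr$a * rr$q * em1 * em2 / (rr$k * rr$r) * w)
  }

  es <- eq$state
  xe <- es[["x"]]; ye <- es[["y"]]; ve <- es[["v"]]
  ze <- es[["z"]]; we <- es[["w"]]
  fe <- f(xe, ve)
  term_x <- bracket(x, xe, function(th) f(th, ve))
  term_y <- bracket(y, ye, g$g1$g)
  term_v <- bracket(v, ve, g$g2$g)
  Ix <- delay_integral(traj, t, taus[["tau1"]],
                       function(S) lyap_H(f(S[, "x"], S[, "v"]) / fe), hq)
  Iy <- delay_integral(traj, t, taus[["tau2"]],
                       function(S) lyap_H(g$g1$g(S[, "y"]) / g$g1$g(ye)), hq)
  Izw <- function() delay_integral(traj, t, taus[["tau3"]],
                                   function(S) g$g1$g(S[, "y"]) *
                                     g$g4$g(S[, "z"]), hq)

  if (functional == "V2") {
    return(term_x + em1 * term_y + rr$a * em1 * em2 / rr$k * term_v +
             rr$p * em1 / rr$c * z +
             rr$a * rr$q * em1 * em2 / (rr$k * rr$r) * w +
             fe * Ix + rr$p * em1 * Izw() + rr$a * em1 * g$g1$g(ye) * Iy)
  }
  if (functional == "V3") {
    cv <- fe / (g$g2$g(ve) * (rr$u + rr$q * g$g3$g(we)))
    cw <- rr$q * cv / rr$r
    term_w <- bracket(w, we, g$g3$g)
    return(term_x + em1 * term_y + cv * term_v + rr$p * em1 / rr$c * z +
             cw * term_w + fe * Ix + fe * Iy + rr$p * em1 * Izw())
  }
  if (functional == "V4") {
    cv <- fe / (g$g2$g(ve) * rr$u)
    cw <- rr$q * cv / rr$r
    term_z <- bracket(z, ze, g$g4$g)
    return(term_x + em1 * term_y + cv * term_v +
             rr$p * em1 / rr$c * term_z + cw * w + fe * Ix + fe * Iy)
  }
  # V5
  cv <- fe / (g$g2$g(ve) * (rr$u + rr$q * g$g3$g(we)))
  cw <- rr$q * cv / rr$r
  term_z <- bracket(z, ze, g$g4$g)
  term_w <- bracket(w, we, g$g3$g)
  term_x + em1 * term_y + cv * term_v + rr$p * em1 / rr$c * term_z +
    cw * term_w + fe * Ix + fe * Iy
}
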