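#' Construct a delayed within-host viral infection model
#'
#' Assembles the five-compartment model
#' \deqn{x' = s(x) - f(x, v)}
#' \deqn{y' = e^{-m_1\tau_1} f(x_{\tau_1}, v_{\tau_1}) - a g_1(y) - p g_1(y) g_4(z)}
#' \deqn{v' = k e^{-m_2\tau_2} g_1(y_{\tau_2}) - u g_2(v) - q g_2(v) g_3(w)}
#' \deqn{z' = c g_1(y_{\tau_3}) g_4(z_{\tau_3}) - b g_4(z)}
#' \deqn{w' = r g_2(v) g_3(w) - h g_3(w)}
#' for uninfected target cells \eqn{x}, infected cells \eqn{y}, free virus
#' \eqn{v}, CTLs \eqn{z} and antibodies \eqn{w}, with intracellular delay
#' \eqn{\tau_1}, virus maturation delay \eqn{\tau_2} and immune-response delay
#' \eqn{\tau_3}.  The factors \eqn{e^{-m_1\tau_1}} and \eqn{e^{-m_2\tau_2}}
#' are the probabilities of surviving the corresponding delay period.
#' Time and concentration units are abstract: any consistent choice works,
#' and all rates are per unit time.
#'
#' @param growth a [growth_form()].
#' @param incidence an [incidence_form()].
#' @param removals a single [removal_form()] (applied to all four removal
#'   slots) or a list of four, ordered \eqn{g_1} (infected cells),
#'   \eqn{g_2} (virus), \eqn{g_3} (antibodies), \eqn{g_4} (CTLs).
#' @param rates named list or vector with strictly positive entries
#'   `a` (infected-cell death), `b` (CTL death), `c` (CTL activation),
#'   `k` (virus production), `u` (virus clearance), `p` (CTL killing),
#'   `q` (antibody neutralisation), `r` (antibody activation),
#'   `h` (antibody death), `m1`, `m2` (delay-survival decay exponents).
#' @param delays named vector `c(tau1 = , tau2 = , tau3 = )`, all \eqn{\ge 0}.
#' @return An object of class `"viral_model"`.
#' @seealso [validate_assumptions()], [reproduction_numbers()],
#'   [equilibria()], [simulate.viral_model()]
#' @examples
#' mod <- viral_model(
#'   growth = growth_form("linear", lambda = 10, d = 0.01),
#'   incidence = incidence_form("bilinear", beta = 0.002),
#'   rates = list(a = 0.5, b = 0.15, c = 0.1, k = 0.4, u = 3, p = 1,
#'                q = 1, r = 1.5, h = 0.5, m1 = 0.01, m2 = 0.01),
#'   delays = c(tau1 = 1, tau2 = 2, tau3 = 0)
#' )
#' mod
#' @export
viral_model <- function(growth, incidence, removals = removal_form("identity"),
                        rates, delays = c(tau1 = 0, tau2 = 0, tau3 = 0)) {
  stopifnot(inherits(growth, "growth_form"),
            inherits(incidence, "incidence_form"))
  if (inherits(removals, "removal_form"))
    removals <- list(removals, removals, removals, removals)
  if (!is.list(removals) || length(removals) != 4 ||
      !all(vapply(removals, inherits, logical(1), "removal_form")))
    stop("`removals` must be one removal_form or a list of four")
  names(removals) <- paste0("g", 1:4)

  rates <- as.list(rates)
  rate_names <- c("a", "b", "c", "k", "u", "p", "q", "r", "h", "m1", "m2")
  miss <- setdiff(rate_names, names(rates))
  if (length(miss))
    stop("missing rate(s): ", paste(miss, collapse = ", "))
  extra <- setdiff(names(rates), rate_names)
  if (length(extra))
    stop("unknown rate(s): ", paste(extra, collapse = ", "))
  rates <- rates[rate_names]
  bad <- rate_names[!vapply(rates, function(v)
    is.numeric(v) && length(v) == 1 && is.finite(v) && v > 0, logical(1))]
  if (length(bad))
    stop("rates must be strictly positive finite scalars; offending: ",
         paste(bad, collapse = ", "))

  delays <- unlist(delays)
  dmiss <- setdiff(c("tau1", "tau2", "tau3"), names(delays))
  if (length(dmiss))
    stop("missing delay(s): ", paste(dmiss, collapse = ", "))
  delays <- delays[c("tau1", "tau2", "tau3")]
  if (any(!is.finite(delays)) || any(delays < 0))
    stop("delays must be finite and >= 0")

  mod <- structure(
    list(growth = growth, incidence = incidence, removals = removals,
         rates = lapply(rates, as.numeric), delays = delays),
    class = "viral_model"
  )
  mod
}

# survival factors e^{-m1 tau1}, e^{-m2 tau2}
survival_factors <- function(model) {
  with(model$rates, c(
    e1 = exp(-m1 * model$delays[["tau1"]]),
    e2 = exp(-m2 * model$delays[["tau2"]])
  ))
}

#' Right-hand side of the delayed model
#'
#' Evaluates the five time derivatives given the current state and the three
#' delayed states.  With all four arguments equal this is the stationarity
#' residual: it vanishes exactly at an equilibrium.
#'
#' @param model a [viral_model()].
#' @param state numeric 5-vector `(x, y, v, z, w)`, all entries \eqn{\ge 0}.
#' @param lag1,lag2,lag3 the 5-vector states at times \eqn{t - \tau_1},
#'   \eqn{t - \tau_2}, \eqn{t - \tau_3}; default to `state`.
#' @return Named numeric 5-vector of derivatives.
#' @export
viral_rhs <- function(model, state, lag1 = state, lag2 = state, lag3 = state) {
  for (s in list(state, lag1, lag2, lag3)) {
    if (length(s) != 5 || any(!is.finite(s)))
      stop("states must be finite 5-vectors")
    if (any(s < 0)) stop("negative state entry: states must be >= 0")
  }
  sf <- survival_factors(model)
  g <- model$removals
  rr <- model$rates
  f <- model$incidence$f
  c(
    x = model$growth$s(state[1]) - f(state[1], state[3]),
    y = sf[["e1"]] * f(lag1[1], lag1[3]) -
      rr$a * g$g1$g(state[2]) - rr$p * g$g1$g(state[2]) * g$g4$g(state[4]),
    v = rr$k * sf[["e2"]] * g$g1$g(lag2[2]) -
      rr$u * g$g2$g(state[3]) - rr$q * g$g2$g(state[3]) * g$g3$g(state[5]),
    z = rr$c * g$g1$g(lag3[2]) * g$g4$g(lag3[4]) - rr$b * g$g4$g(state[4]),
    w = rr$r * g$g2$g(state[3]) * g$g3$g(state[5]) - rr$h * g$g3$g(state[5])
  )
}

#' Incidence partial derivatives
#'
#' Returns \eqn{\partial f/\partial x} and \eqn{\partial f/\partial v} at a
#' point, using the form's analytic partials when available and
#' Richardson-extrapolated central differences otherwise.  The slope
#' \eqn{\partial f(\bar x, 0)/\partial v} is the ingredient of the basic
#' reproduction number.
#'
#' @param model a [viral_model()].
#' @param x,v nonnegative coordinates.
#' @return Named vector `c(fx = , fv = )`.
#' @export
incidence_partials <- function(model, x, v) {
  if (any(c(x, v) < 0)) stop("x and v must be >= 0")
  c(fx = model$incidence$fx(x, v), fv = model$incidence$fv(x, v))
}

#' Validate the structural assumptions of the model
#'
#' Checks, on a dense grid of the positive orthant, the four structural
#' assumptions under which the theory holds:
#' \describe{
#'   \item{H1}{\eqn{s} has a unique positive root \eqn{\bar x} with
#'     \eqn{s'(\bar x) < 0}, \eqn{s > 0} below it and \eqn{s < 0} above it.}
#'   \item{H2}{\eqn{f(x, 0) = f(0, v) = 0} exactly; \eqn{f > 0} on the open
#'     positive quadrant; both partials \eqn{\ge 0}; the slope
#'     \eqn{\partial f(x,0)/\partial v} nondecreasing in \eqn{x}.}
#'   \item{H3}{each \eqn{g_i} has \eqn{g_i(0) = 0}, \eqn{g_i'(0) = 1}
#'     (enforced at machine precision), is strictly increasing, and
#'     dominates a linear function \eqn{k_i \xi} with \eqn{k_i > 0}.}
#'   \item{H4}{\eqn{f(x, v)/g_2(v)} nonincreasing in \eqn{v}.}
#' }
#' The check is grid-based, not symbolic: the assumptions are transcendental
#' inequalities and a dense grid with violation reporting is the testable
#' contract.  A pass certifies the assumptions on the sampled box
#' \eqn{(0, 2\bar x] \times (0, v_{max}]} only.
#'
#' @param model a [viral_model()].
#' @param nx,nv grid resolution per axis (at least 100).
#' @param v_max upper end of the virus grid (model units).
#' @return An object of class `"assumption_report"`: per-assumption pass flag
#'   plus the first violating coordinates and inequality, and `all_pass`.
#' @examples
#' validate_assumptions(example_model(18))
#' @export
validate_assumptions <- function(model, nx = 120, nv = 120, v_max = 100) {
  if (nx < 100 || nv < 100)
    stop("grid must have at least 100 points per axis")
  checks <- list()
  fail <- function(assumption, what, at) {
    list(assumption = assumption, pass = FALSE, violation = what, at = at)
  }
  ok <- function(assumption) list(assumption = assumption, pass = TRUE)
  finite_or_stop <- function(vals, fname, pts) {
    bad <- which(!is.finite(vals))
    if (length(bad))
      stop("non-finite value of ", fname, " at ",
           paste(format(pts[bad[1], ]), collapse = ", "))
  }

  # H1 ------------------------------------------------------------------
  xbar <- tryCatch(find_xbar(model), error = function(e) NULL)
  if (is.null(xbar)) {
    checks$H1 <- fail("H1", "s has no positive root with s' < 0", NA)
  } else {
    xs <- seq_len(nx) / nx * 2 * xbar
    sv <- model$growth$s(xs)
    finite_or_stop(sv, "s(x)", cbind(x = xs))
    below <- xs < xbar * (1 - 1e-10)
    above <- xs > xbar * (1 + 1e-10)
    if (any(sv[below] <= 0)) {
      i <- which(below & sv <= 0)[1]
      checks$H1 <- fail("H1", "s(x) <= 0 below xbar", c(x = xs[i]))
    } else if (any(sv[above] >= 0)) {
      i <- which(above & sv >= 0)[1]
      checks$H1 <- fail("H1", "s(x) >= 0 above xbar", c(x = xs[i]))
    } else if (model$growth$sp(xbar) >= 0) {
      checks$H1 <- fail("H1", "s'(xbar) >= 0", c(x = xbar))
    } else checks$H1 <- ok("H1")
  }
  if (is.null(xbar)) xbar <- v_max # fallback grid scale for remaining checks

  xs <- seq_len(nx) / nx * 2 * xbar
  vs <- seq_len(nv) / nv * v_max
  f <- model$incidence$f

  # H2 ------------------------------------------------------------------
  checks$H2 <- local({
    fx0 <- f(xs, 0)
    f0v <- f(0, vs)
    finite_or_stop(fx0, "f(x, 0)", cbind(x = xs))
    finite_or_stop(f0v, "f(0, v)", cbind(v = vs))
    if (any(fx0 != 0)) {
      i <- which(fx0 != 0)[1]
      return(fail("H2", "f(x, 0) != 0", c(x = xs[i], v = 0)))
    }
    if (any(f0v != 0)) {
      i <- which(f0v != 0)[1]
      return(fail("H2", "f(0, v) != 0", c(x = 0, v = vs[i])))
    }
    for (v in vs) {
      fv_ <- f(xs, v)
      finite_or_stop(fv_, "f(x, v)", cbind(x = xs, v = v))
      if (any(fv_ <= 0)) {
        i <- which(fv_ <= 0)[1]
        return(fail("H2", "f(x, v) <= 0", c(x = xs[i], v = v)))
      }
      dfx <- model$incidence$fx(xs, v)
      dfv <- model$incidence$fv(xs, v)
      if (any(dfx < -1e-10)) {
        i <- which(dfx < -1e-10)[1]
        return(fail("H2", "df/dx < 0", c(x = xs[i], v = v)))
      }
      if (any(dfv < -1e-10)) {
        i <- which(dfv < -1e-10)[1]
        return(fail("H2", "df/dv < 0", c(x = xs[i], v = v)))
      }
    }
    slope0 <- model$incidence$fv(xs, 0)
    if (any(diff(slope0) < -1e-10 * max(abs(slope0)))) {
      i <- which(diff(slope0) < -1e-10 * max(abs(slope0)))[1]
      return(fail("H2", "df(x, 0)/dv decreasing in x", c(x = xs[i + 1])))
    }
    ok("H2")
  })

  # H3 ------------------------------------------------------------------
  checks$H3 <- local({
    xi <- seq_len(max(nx, nv)) / max(nx, nv) * max(2 * xbar, v_max)
    for (i in 1:4) {
      gi <- model$removals[[i]]
      gv <- gi$g(xi)
      finite_or_stop(gv, paste0("g", i), cbind(xi = xi))
      if (gi$g(0) != 0)
        return(fail("H3", paste0("g", i, "(0) != 0"), c(xi = 0)))
      if (any(diff(c(0, gv)) <= 0)) {
        j <- which(diff(c(0, gv)) <= 0)[1]
        return(fail("H3", paste0("g", i, " not strictly increasing"),
                    c(xi = xi[j])))
      }
      if (abs(gi$gp(0) - 1) > 1e-12)
        return(fail("H3", paste0("g", i, "'(0) != 1"), c(xi = 0)))
      ki <- min(gv / xi)
      if (!is.finite(ki) || ki <= 0)
        return(fail("H3", paste0("no positive k with g", i, "(xi) >= k*xi"),
                    c(xi = xi[which.min(gv / xi)])))
    }
    ok("H3")
  })

  # H4 ------------------------------------------------------------------
  checks$H4 <- local({
    g2 <- model$removals$g2$g
    for (x in xs) {
      ratio <- f(x, vs) / g2(vs)
      finite_or_stop(ratio, "f/g2", cbind(x = x, v = vs))
      tol <- 1e-10 * max(abs(ratio))
      if (any(diff(ratio) > tol)) {
        j <- which(diff(ratio) > tol)[1]
        return(fail("H4", "f(x, v)/g2(v) increasing in v",
                    c(x = x, v = vs[j + 1])))
      }
    }
    ok("H4")
  })

  structure(
    list(checks = checks,
         all_pass = all(vapply(checks, `[[`, logical(1), "pass")),
         grid = list(nx = nx, nv = nv, x_max = 2 * xbar, v_max = v_max)),
    class = "assumption_report"
  )
}

#' @export
print.assumption_report <- function(x, ...) {
  cat("Model assumption check (grid ", x$grid$nx, " x ", x$grid$nv,
      ", x <= ", format(x$grid$x_max, digits = 6),
      ", v <= ", format(x$grid$v_max, digits = 6), ")\n", sep = "")
  for (ch in x$checks) {
    if (ch$pass) {
      cat("  ", ch$assumption, ": pass\n", sep = "")
    } else {
      cat("  ", ch$assumption, ": FAIL - ", ch$violation, " at (",
          paste(names(ch$at), format(ch$at, digits = 6),
                sep = " = ", collapse = ", "), ")\n", sep = "")
    }
  }
  invisible(x)
}

#' @export
print.viral_model <- function(x, ...) {
  cat("Delayed within-host viral infection model\n")
  cat("  growth:    ", x$growth$form, " (",
      paste(names(x$growth$params), unlist(x$growth$params),
            sep = " = ", collapse = ", "), ")\n", sep = "")
  cat("  incidence: ", x$incidence$form, " (",
      paste(names(x$incidence$params), unlist(x$incidence$params),
            sep = " = ", collapse = ", "), ")\n", sep = "")
  cat("  removals:  ",
      paste(vapply(x$removals, `[[`, character(1), "form"), collapse = ", "),
      "\n", sep = "")
  cat("  rates:     ",
      paste(names(x$rates), format(unlist(x$rates)),
            sep = " = ", collapse = ", "), "\n", sep = "")
  cat("  delays:    ",
      paste(names(x$delays), format(x$delays),
            sep = " = ", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
coef.viral_model <- function(object, ...) {
  c(unlist(object$rates), object$delays)
}

#' Replace the immune-response delay
#'
#' Convenience helper returning a copy of the model with `tau3` replaced,
#' used when sweeping the immune delay.
#'
#' @param model a [viral_model()].
#' @param tau3 new immune-response delay (\eqn{\ge 0}).
#' @return The modified model.
#' @export
set_tau3 <- function(model, tau3) {
  stopifnot(is.numeric(tau3), length(tau3) == 1, is.finite(tau3), tau3 >= 0)
  model$delays[["tau3"]] <- tau3
  model
}

#' @export
summary.viral_model <- function(object, ...) {
  th <- reproduction_numbers(object)
  eq <- equilibria(object)
  structure(list(model = object, thresholds = th, equilibria = eq,
                 regime = classify_regime(object)),
            class = "summary.viral_model")
}

#' @export
print.summary.viral_model <- function(x, ...) {
  print(x$model)
  cat("\n")
  print(x$thresholds)
  cat("\nEquilibria:\n")
  for (e in x$equilibria) print(e)
  cat("\nRegime: ", x$regime$label, "\n", sep = "")
  invisible(x)
}
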