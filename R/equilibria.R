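#' Uninfected steady state of the target-cell pool
#'
#' Finds \eqn{\bar x > 0}, the unique positive root of the growth law
#' \eqn{s}, by bracket expansion and Brent's method, then checks
#' \eqn{s'(\bar x) < 0}.
#'
#' @param model a [viral_model()].
#' @return The scalar \eqn{\bar x}.
#' @export
find_xbar <- function(model) {
  s <- model$growth$s
  lo <- 1e-12
  if (s(lo) <= 0) stop("no uninfected steady state: s(0+) <= 0")
  hi <- 1
  for (i in 1:200) {
    if (s(hi) < 0) break
    hi <- 2 * hi
  }
  if (s(hi) >= 0)
    stop("no uninfected steady state: s(x) has no sign change on (0, ",
         format(hi), "]")
  xbar <- stats::uniroot(s, c(lo, hi), tol = 1e-14 * hi)$root
  # polish with a Newton step for full relative accuracy
  xbar <- xbar - s(xbar) / model$growth$sp(xbar)
  if (model$growth$sp(xbar) >= 0)
    stop("s'(xbar) >= 0: growth law violates H1 at its root")
  xbar
}

# Root of phi(x) = s(x) - f(x, v_fixed) on (0, xbar). Under H1-H2 phi is
# decreasing with phi(0) > 0 > phi(xbar), so the bracketed root is unique.
solve_x_at_v <- function(model, v_fixed, xbar) {
  phi <- function(x) model$growth$s(x) - model$incidence$f(x, v_fixed)
  eps <- 1e-9 * xbar
  if (phi(eps) <= 0 || phi(xbar) >= 0)
    stop("bracketing failed for s(x) = f(x, v): phi(", format(eps), ") = ",
         format(phi(eps)), ", phi(xbar) = ", format(phi(xbar)))
  stats::uniroot(phi, c(eps, xbar), tol = 1e-12 * xbar)$root
}

equilibrium_obj <- function(model, label, state, exists) {
  state <- stats::setNames(as.numeric(state), c("x", "y", "v", "z", "w"))
  res <- if (exists)
    max(abs(viral_rhs(model, pmax(state, 0)))) else NA_real_
  structure(list(label = label, state = state, exists = exists,
                 residual = res),
            class = "viral_equilibrium")
}

#' @export
print.viral_equilibrium <- function(x, ...) {
  if (x$exists) {
    cat(sprintf("  %s: (%s)  residual %.2e\n", x$label,
                paste(format(x$state, digits = 7), collapse = ", "),
                x$residual))
  } else {
    cat(sprintf("  %s: does not exist\n", x$label))
  }
  invisible(x)
}

#' Reproduction numbers of the delayed infection model
#'
#' Computes the five dimensionless threshold quantities:
#' \describe{
#'   \item{R0}{basic reproduction number for viral infection,
#'     \eqn{R_0 = k e^{-m_1\tau_1 - m_2\tau_2} \partial f(\bar x, 0)/\partial v / (a u)};
#'     gates whether infection can take off at all.}
#'   \item{R1}{antibody response reproductive number,
#'     \eqn{R_1 = k e^{-m_1\tau_1 - m_2\tau_2} f(x_2, v_2)/(a u\, g_2(v_2))};
#'     gates establishment of the antibody-only equilibrium
#'     (\eqn{w_2 = g_3^{-1}(u (R_1 - 1)/q) > 0} exactly when \eqn{R_1 > 1}).}
#'   \item{R2}{CTL immune response reproductive number,
#'     \eqn{R_2 = k e^{-m_1\tau_1 - m_2\tau_2} f(x_3, v_3)/(a u\, g_2(v_3))};
#'     gates establishment of the CTL-only equilibrium.}
#'   \item{R3}{CTL immune competition reproductive number,
#'     \eqn{R_3 = c e^{-m_1\tau_1} f(x_4, v_4)/(a b)}.}
#'   \item{R4}{antibody competition reproductive number,
#'     \eqn{R_4 = k e^{-m_2\tau_2} g_1(y_4)/(u\, g_2(v_4))}, which for
#'     identity removals reduces to \eqn{k b r e^{-m_2\tau_2}/(u c h)}.}
#' }
#' Whenever defined, \eqn{R_1 < R_0} and \eqn{R_2 < R_0}.
#'
#' @param model a [viral_model()].
#' @return Object of class `"threshold_set"`: named numbers `R0..R4` plus
#'   per-value `defined` flags.
#' @examples
#' reproduction_numbers(example_model(17))
#' @export
reproduction_numbers <- function(model) {
  rr <- model$rates
  sf <- survival_factors(model)
  g <- model$removals
  f <- model$incidence$f
  xbar <- find_xbar(model)
  defined <- c(R0 = TRUE, R1 = FALSE, R2 = FALSE, R3 = FALSE, R4 = FALSE)

  R0 <- rr$k * sf[["e1"]] * sf[["e2"]] / (rr$a * rr$u) *
    model$incidence$fv(xbar, 0)

  R1 <- R2 <- R3 <- R4 <- NA_real_
  # antibody-only pieces: v2 = g2^{-1}(h/r), x2 from s(x) = f(x, v2)
  p2 <- tryCatch({
    v2 <- g$g2$ginv(rr$h / rr$r)
    x2 <- solve_x_at_v(model, v2, xbar)
    list(v2 = v2, x2 = x2)
  }, error = function(e) NULL)
  if (!is.null(p2)) {
    R1 <- rr$k * sf[["e1"]] * sf[["e2"]] * f(p2$x2, p2$v2) /
      (rr$a * rr$u * g$g2$g(p2$v2))
    defined["R1"] <- TRUE
  }
  # CTL-only pieces: y3 = g1^{-1}(b/c), v3 = g2^{-1}(b k e^{-m2 tau2}/(c u))
  p3 <- tryCatch({
    v3 <- g$g2$ginv(rr$b * rr$k * sf[["e2"]] / (rr$c * rr$u))
    x3 <- solve_x_at_v(model, v3, xbar)
    list(v3 = v3, x3 = x3)
  }, error = function(e) NULL)
  if (!is.null(p3)) {
    R2 <- rr$k * sf[["e1"]] * sf[["e2"]] * f(p3$x3, p3$v3) /
      (rr$a * rr$u * g$g2$g(p3$v3))
    defined["R2"] <- TRUE
  }
  # coexistence pieces: y4 = g1^{-1}(b/c), v4 = g2^{-1}(h/r)
  p4 <- tryCatch({
    y4 <- g$g1$ginv(rr$b / rr$c)
    v4 <- g$g2$ginv(rr$h / rr$r)
    x4 <- solve_x_at_v(model, v4, xbar)
    list(y4 = y4, v4 = v4, x4 = x4)
  }, error = function(e) NULL)
  if (!is.null(p4)) {
    R3 <- rr$c * sf[["e1"]] * f(p4$x4, p4$v4) / (rr$a * rr$b)
    R4 <- rr$k * sf[["e2"]] * g$g1$g(p4$y4) / (rr$u * g$g2$g(p4$v4))
    defined["R3"] <- defined["R4"] <- TRUE
  }

  structure(list(R0 = R0, R1 = R1, R2 = R2, R3 = R3, R4 = R4,
                 defined = defined, xbar = xbar),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("Reproduction numbers (xbar = ", format(x$xbar, digits = 7), "):\n",
      sep = "")
  for (nm in c("R0", "R1", "R2", "R3", "R4")) {
    if (x$defined[[nm]]) {
      cat(sprintf("  %s = %.6g\n", nm, x[[nm]]))
    } else {
      cat(sprintf("  %s: undefined\n", nm))
    }
  }
  invisible(x)
}

#' Solve a single equilibrium of the model
#'
#' Solves the stationarity system for one of the five labelled equilibria by
#' the threshold constructions: each boundary component is pinned by an
#' inverse removal function and the remaining cell component by a bracketed
#' root on \eqn{(0, \bar x)}.
#'
#' \describe{
#'   \item{E0}{infection-free \eqn{(\bar x, 0, 0, 0, 0)}; always exists.}
#'   \item{E1}{immune-free \eqn{(x_1, y_1, v_1, 0, 0)}; exists iff
#'     \eqn{R_0 > 1}.}
#'   \item{E2}{antibody-only \eqn{(x_2, y_2, v_2, 0, w_2)}; exists iff
#'     \eqn{R_1 > 1}.}
#'   \item{E3}{CTL-only \eqn{(x_3, y_3, v_3, z_3, 0)}; exists iff
#'     \eqn{R_2 > 1}.}
#'   \item{E4}{coexistence \eqn{(x_4, y_4, v_4, z_4, w_4)}; exists iff
#'     \eqn{R_3 > 1} and \eqn{R_4 > 1}.}
#' }
#' Threshold equalities (an R exactly 1) are classified as nonexistence of
#' the corresponding interior component.
#'
#' @param model a [viral_model()].
#' @param label one of `"E0"`, `"E1"`, `"E2"`, `"E3"`, `"E4"`.
#' @return Object of class `"viral_equilibrium"`: label, named state
#'   `(x, y, v, z, w)`, `exists` flag, and the stationarity residual
#'   (max norm).
#' @examples
#' solve_equilibrium(example_model(17), "E3")
#' @export
solve_equilibrium <- function(model, label = c("E0", "E1", "E2", "E3", "E4")) {
  label <- match.arg(label)
  rr <- model$rates
  sf <- survival_factors(model)
  g <- model$removals
  f <- model$incidence$f
  xbar <- find_xbar(model)
  th <- reproduction_numbers(model)

  if (label == "E0")
    return(equilibrium_obj(model, "E0", c(xbar, 0, 0, 0, 0), TRUE))

  if (label == "E1") {
    if (!(th$R0 > 1))
      return(equilibrium_obj(model, "E1", rep(NA_real_, 5), FALSE))
    x1 <- solve_E1_x(model, xbar)
    aue <- rr$a * rr$u / (sf[["e1"]] * sf[["e2"]])
    v1 <- g$g2$ginv(rr$k * model$growth$s(x1) / aue)
    y1 <- g$g1$ginv(rr$u * g$g2$g(v1) / (rr$k * sf[["e2"]]))
    return(equilibrium_obj(model, "E1", c(x1, y1, v1, 0, 0), TRUE))
  }

  if (label == "E2") {
    if (!(isTRUE(th$defined[["R1"]]) && th$R1 > 1))
      return(equilibrium_obj(model, "E2", rep(NA_real_, 5), FALSE))
    v2 <- g$g2$ginv(rr$h / rr$r)
    x2 <- solve_x_at_v(model, v2, xbar)
    y2 <- g$g1$ginv(sf[["e1"]] * f(x2, v2) / rr$a)
    w2 <- g$g3$ginv(rr$u * (th$R1 - 1) / rr$q)
    return(equilibrium_obj(model, "E2", c(x2, y2, v2, 0, w2), TRUE))
  }

  if (label == "E3") {
    if (!(isTRUE(th$defined[["R2"]]) && th$R2 > 1))
      return(equilibrium_obj(model, "E3", rep(NA_real_, 5), FALSE))
    y3 <- g$g1$ginv(rr$b / rr$c)
    v3 <- g$g2$ginv(rr$b * rr$k * sf[["e2"]] / (rr$c * rr$u))
    x3 <- solve_x_at_v(model, v3, xbar)
    z3 <- g$g4$ginv(rr$a * (th$R2 - 1) / rr$p)
    return(equilibrium_obj(model, "E3", c(x3, y3, v3, z3, 0), TRUE))
  }

  # E4
  if (!(isTRUE(th$defined[["R3"]]) && th$R3 > 1 && th$R4 > 1))
    return(equilibrium_obj(model, "E4", rep(NA_real_, 5), FALSE))
  y4 <- g$g1$ginv(rr$b / rr$c)
  v4 <- g$g2$ginv(rr$h / rr$r)
  x4 <- solve_x_at_v(model, v4, xbar)
  z4 <- g$g4$ginv(rr$a * (th$R3 - 1) / rr$p)
  w4 <- g$g3$ginv(rr$u * (th$R4 - 1) / rr$q)
  equilibrium_obj(model, "E4", c(x4, y4, v4, z4, w4), TRUE)
}

# Interior root of G(x) = f(x, phi(x)) - s(x) on (0, xbar), where
# phi(x) = g2^{-1}(k s(x) e^{-m1 tau1 - m2 tau2} / (a u)).  G(0) < 0 and,
# when R0 > 1, G > 0 just left of xbar (G(xbar) = 0 with G'(xbar) < 0),
# so a sign change is bracketed strictly inside (0, xbar).
solve_E1_x <- function(model, xbar) {
  rr <- model$rates
  sf <- survival_factors(model)
  g2 <- model$removals$g2
  aue <- rr$a * rr$u / (sf[["e1"]] * sf[["e2"]])
  G <- function(x) {
    v <- g2$ginv(pmax(rr$k * model$growth$s(x) / aue, 0))
    model$incidence$f(x, v) - model$growth$s(x)
  }
  eps <- 1e-9 * xbar
  hi <- xbar * (1 - 1e-6)
  for (i in 1:40) {
    if (G(hi) > 0) break
    hi <- xbar - (xbar - hi) / 4
  }
  if (G(eps) >= 0 || G(hi) <= 0)
    stop("bracketing failed for the immune-free equilibrium: G(",
         format(eps), ") = ", format(G(eps)), ", G(", format(hi), ") = ",
         format(G(hi)))
  stats::uniroot(G, c(eps, hi), tol = 1e-12 * xbar)$root
}

#' All equilibria of the model
#'
#' @param model a [viral_model()].
#' @return Named list of five `"viral_equilibrium"` objects (`E0`..`E4`).
#' @export
equilibria <- function(model) {
  out <- lapply(c("E0", "E1", "E2", "E3", "E4"), solve_equilibrium,
                model = model)
  names(out) <- vapply(out, `[[`, character(1), "label")
  out
}

#' Classify the global-stability regime
#'
#' Maps the reproduction numbers to the globally stable equilibrium
#' guaranteed by the threshold theory:
#' \itemize{
#'   \item \eqn{R_0 \le 1}: infection-free E0 stable (any delays);
#'   \item \eqn{R_0 > 1}, \eqn{R_1 \le 1}, \eqn{R_2 \le 1}: immune-free E1
#'     stable (any delays);
#'   \item \eqn{R_1 > 1}, \eqn{R_3 \le 1}: antibody-only E2 stable (any
#'     delays);
#'   \item \eqn{R_2 > 1}, \eqn{R_4 \le 1} and \eqn{\tau_3 = 0}: CTL-only E3
#'     stable;
#'   \item \eqn{R_3 > 1}, \eqn{R_4 > 1} and \eqn{\tau_3 = 0}: coexistence E4
#'     stable.
#' }
#' The E3/E4 statements require \eqn{\tau_3 = 0}; for \eqn{\tau_3 > 0} those
#' corners return `"indeterminate"` (stability switches and Hopf bifurcations
#' can occur and must be assessed numerically, see [scan_tau3()]).  If the
#' satisfied conditions select no regime, or more than one, the label is
#' `"indeterminate"` and the satisfied conditions are listed.
#'
#' @param model a [viral_model()].
#' @param thresholds optionally a precomputed [reproduction_numbers()] set.
#' @return List with `label` (e.g. `"E3-stable"` or `"indeterminate"`),
#'   `satisfied` (character vector of threshold conditions that hold) and the
#'   `thresholds` used.
#' @export
classify_regime <- function(model, thresholds = NULL) {
  th <- thresholds %||% reproduction_numbers(model)
  tau3 <- model$delays[["tau3"]]
  defined <- function(nm) isTRUE(th$defined[[nm]])
  conds <- character(0)
  if (th$R0 <= 1) conds <- c(conds, "R0<=1") else conds <- c(conds, "R0>1")
  for (nm in c("R1", "R2", "R3", "R4")) if (defined(nm))
    conds <- c(conds, paste0(nm, if (th[[nm]] > 1) ">1" else "<=1"))

  match_lab <- character(0)
  if (th$R0 <= 1) match_lab <- c(match_lab, "E0-stable")
  if (th$R0 > 1 && defined("R1") && defined("R2") &&
      th$R1 <= 1 && th$R2 <= 1) match_lab <- c(match_lab, "E1-stable")
  if (defined("R1") && defined("R3") && th$R1 > 1 && th$R3 <= 1)
    match_lab <- c(match_lab, "E2-stable")
  if (defined("R2") && defined("R4") && th$R2 > 1 && th$R4 <= 1 && tau3 == 0)
    match_lab <- c(match_lab, "E3-stable")
  if (defined("R3") && defined("R4") && th$R3 > 1 && th$R4 > 1 && tau3 == 0)
    match_lab <- c(match_lab, "E4-stable")

  label <- if (length(match_lab) == 1) match_lab else "indeterminate"
  list(label = label, matches = match_lab, satisfied = conds,
       thresholds = th)
}
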