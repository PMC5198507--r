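#' Target-cell growth laws
#'
#' Constructs a growth function \eqn{s(x)} describing production and natural
#' turnover of uninfected target cells.  The model requires a unique carrying
#' state \eqn{\bar x > 0} with \eqn{s(\bar x) = 0} and \eqn{s'(\bar x) < 0}:
#' below \eqn{\bar x} the healthy-cell pool grows, above it it shrinks.
#'
#' Registered forms:
#' \describe{
#'   \item{`"linear"`}{\eqn{s(x) = \lambda - d x}; parameters `lambda`, `d`.}
#'   \item{`"logistic"`}{\eqn{s(x) = \lambda - d x + r_1 x (1 - x/K)};
#'     parameters `lambda`, `d`, `r1`, `K`.  Constant influx plus logistic
#'     proliferation of target cells.}
#'   \item{`"custom"`}{user-supplied `s` and its derivative `sp` (plugin hook;
#'     such models use the plain-R integrator path).}
#' }
#'
#' @param form form label, one of `"linear"`, `"logistic"`, `"custom"`.
#' @param ... named numeric parameters of the form (see above), or for
#'   `"custom"` the functions `s` and `sp`.
#' @return An object of class `"growth_form"`: a list with the form label, the
#'   parameter map and vectorised functions `s(x)` (cells/time) and `sp(x)`
#'   (its derivative).
#' @examples
#' g <- growth_form("logistic", lambda = 10, d = 0.01, r1 = 0.6, K = 500)
#' g$s(100)
#' @export
growth_form <- function(form = c("linear", "logistic", "custom"), ...) {
  form <- match.arg(form)
  args <- list(...)
  out <- switch(form,
    linear = {
      p <- need_params(args, c("lambda", "d"), "growth 'linear'")
      list(
        s = function(x) p$lambda - p$d * x,
        sp = function(x) rep(-p$d, length(x)),
        code = 1L, par = c(p$lambda, p$d), params = p
      )
    },
    logistic = {
      p <- need_params(args, c("lambda", "d", "r1", "K"), "growth 'logistic'")
      list(
        s = function(x) p$lambda - p$d * x + p$r1 * x * (1 - x / p$K),
        sp = function(x) -p$d + p$r1 * (1 - 2 * x / p$K),
        code = 2L, par = c(p$lambda, p$d, p$r1, p$K), params = p
      )
    },
    custom = {
      if (!is.function(args$s)) stop("growth 'custom' needs a function `s`")
      sp <- args$sp
      if (is.null(sp)) sp <- function(x) num_deriv(args$s, x)
      list(s = args$s, sp = sp, code = NA_integer_, par = numeric(0),
           params = args[!vapply(args, is.function, logical(1))])
    }
  )
  out$form <- form
  class(out) <- "growth_form"
  out
}

#' Incidence functions
#'
#' Constructs the incidence function \eqn{f(x, v)}: the rate at which
#' susceptible cells \eqn{x} are newly infected by free virus \eqn{v}.  All
#' registered forms vanish when either argument is zero and are nondecreasing
#' in both arguments on the biologically relevant range.
#'
#' Registered forms:
#' \describe{
#'   \item{`"bilinear"`}{\eqn{\beta x v}; parameter `beta`.}
#'   \item{`"saturated"`}{\eqn{\beta x v / (1 + b v)}; parameters `beta`, `b`.}
#'   \item{`"holling2"`}{\eqn{\beta x v / (1 + a x)}; parameters `beta`, `a`.}
#'   \item{`"crowley_martin"`}{\eqn{\beta x v / (1 + a x + b v + n x v)};
#'     parameters `beta`, `a`, `b` and optionally `n` (defaults to `a*b`,
#'     the Crowley-Martin cross term; `n = 0` gives Beddington-DeAngelis).}
#'   \item{`"beddington_deangelis"`}{alias for `"crowley_martin"` with
#'     `n` defaulting to 0.}
#'   \item{`"exp_shift"`}{\eqn{\beta x ((v - b_1) e^{-c_1 v} + b_1)};
#'     parameters `beta`, `b1`, `c1`.  A saturating-then-declining viral
#'     activity law; its slope in `v` is positive for
#'     \eqn{v < 1/c_1 + b_1}.}
#'   \item{`"custom"`}{user-supplied value function `fn(x, v)` and
#'     optionally analytic partials `fx`, `fv` (otherwise
#'     Richardson-extrapolated central differences).}
#' }
#'
#' @param form form label (see above).
#' @param ... named numeric parameters, or functions for `"custom"`.
#' @return An object of class `"incidence_form"`: form label, parameter map
#'   and vectorised `f(x, v)`, `fx(x, v)`, `fv(x, v)`.
#' @examples
#' f <- incidence_form("crowley_martin", beta = 0.25, a = 0.01, b = 0.01)
#' f$fv(1000, 0) # slope in v at v = 0
#' @export
incidence_form <- function(form = c("bilinear", "saturated", "holling2",
                                    "crowley_martin", "beddington_deangelis",
                                    "exp_shift", "custom"), ...) {
  form <- match.arg(form)
  args <- list(...)
  out <- switch(form,
    bilinear = {
      p <- need_params(args, "beta", "incidence 'bilinear'")
      list(
        f = function(x, v) p$beta * x * v,
        fx = function(x, v) p$beta * v,
        fv = function(x, v) p$beta * x,
        code = 1L, par = c(p$beta, 0, 0, 0), params = p
      )
    },
    saturated = {
      p <- need_params(args, c("beta", "b"), "incidence 'saturated'")
      list(
        f = function(x, v) p$beta * x * v / (1 + p$b * v),
        fx = function(x, v) p$beta * v / (1 + p$b * v),
        fv = function(x, v) p$beta * x / (1 + p$b * v)^2,
        code = 2L, par = c(p$beta, p$b, 0, 0), params = p
      )
    },
    holling2 = {
      p <- need_params(args, c("beta", "a"), "incidence 'holling2'")
      list(
        f = function(x, v) p$beta * x * v / (1 + p$a * x),
        fx = function(x, v) p$beta * v / (1 + p$a * x)^2,
        fv = function(x, v) p$beta * x / (1 + p$a * x),
        code = 3L, par = c(p$beta, p$a, 0, 0), params = p
      )
    },
    crowley_martin = ,
    beddington_deangelis = {
      p <- need_params(args, c("beta", "a", "b"),
                       paste0("incidence '", form, "'"), optional = "n")
      if (is.null(p$n))
        p$n <- if (form == "crowley_martin") p$a * p$b else 0
      den <- function(x, v) 1 + p$a * x + p$b * v + p$n * x * v
      list(
        f = function(x, v) p$beta * x * v / den(x, v),
        fx = function(x, v) p$beta * v * (1 + p$b * v) / den(x, v)^2,
        fv = function(x, v) p$beta * x * (1 + p$a * x) / den(x, v)^2,
        code = 4L, par = c(p$beta, p$a, p$b, p$n), params = p
      )
    },
    exp_shift = {
      p <- need_params(args, c("beta", "b1", "c1"), "incidence 'exp_shift'")
      act <- function(v) (v - p$b1) * exp(-p$c1 * v) + p$b1
      list(
        f = function(x, v) p$beta * x * act(v),
        fx = function(x, v) p$beta * act(v) + 0 * x,
        fv = function(x, v)
          p$beta * x * exp(-p$c1 * v) * (1 - p$c1 * (v - p$b1)),
        code = 5L, par = c(p$beta, p$b1, p$c1, 0), params = p
      )
    },
    custom = {
      # the value function is `fn` (not `f`, which R's partial argument
      # matching would capture into `form`)
      if (!is.function(args$fn))
        stop("incidence 'custom' needs a function `fn`")
      f <- args$fn
      fx <- args$fx %||% function(x, v) num_deriv(function(t) f(t, v), x)
      fv <- args$fv %||% function(x, v) num_deriv(function(t) f(x, t), v)
      list(f = f, fx = fx, fv = fv, code = NA_integer_, par = numeric(0),
           params = args[!vapply(args, is.function, logical(1))])
    }
  )
  out$form <- form
  class(out) <- "incidence_form"
  out
}

#' Removal functions
#'
#' Constructs one of the state-dependent removal functions \eqn{g_i(\xi)}
#' (losses of infected cells, virus, antibodies and CTLs scale as
#' \eqn{a g_1(y)}, \eqn{u g_2(v)}, \eqn{h g_3(w)}, \eqn{b g_4(z)}).  Removal
#' functions are normalised: \eqn{g_i(0) = 0}, \eqn{g_i'(0) = 1}, strictly
#' increasing, and bounded below by a linear function \eqn{k_i \xi}.
#'
#' Registered forms:
#' \describe{
#'   \item{`"identity"`}{\eqn{g(\xi) = \xi} (the classical linear clearance).}
#'   \item{`"power_affine"`}{\eqn{g(\xi) = \xi (1 + \epsilon \xi)};
#'     parameter `eps` \eqn{\ge 0}: clearance accelerating with density.}
#'   \item{`"custom"`}{user-supplied `g`, `gp` and optionally `ginv`
#'     (otherwise a monotone bracketed inverse is used).}
#' }
#'
#' @param form form label.
#' @param ... named numeric parameters, or functions for `"custom"`.
#' @return An object of class `"removal_form"`: form label, parameter map and
#'   vectorised `g(xi)`, `gp(xi)` (derivative) and `ginv(eta)` (inverse).
#' @examples
#' g <- removal_form("power_affine", eps = 0.05)
#' g$ginv(g$g(3)) # inverse round trip
#' @export
removal_form <- function(form = c("identity", "power_affine", "custom"), ...) {
  form <- match.arg(form)
  args <- list(...)
  out <- switch(form,
    identity = list(
      g = function(xi) xi,
      gp = function(xi) rep(1, length(xi)),
      ginv = function(eta) eta,
      code = 1L, par = 0, params = list()
    ),
    power_affine = {
      p <- need_params(args, "eps", "removal 'power_affine'")
      if (p$eps < 0) stop("removal 'power_affine': eps must be >= 0")
      list(
        g = function(xi) xi * (1 + p$eps * xi),
        gp = function(xi) 1 + 2 * p$eps * xi,
        ginv = function(eta) {
          if (p$eps == 0) return(eta)
          (-1 + sqrt(1 + 4 * p$eps * eta)) / (2 * p$eps)
        },
        code = 2L, par = p$eps, params = p
      )
    },
    custom = {
      if (!is.function(args$g) || !is.function(args$gp))
        stop("removal 'custom' needs functions `g` and `gp`")
      ginv <- args$ginv %||% function(eta) monotone_inverse(args$g, eta)
      list(g = args$g, gp = args$gp, ginv = ginv, code = NA_integer_,
           par = numeric(0),
           params = args[!vapply(args, is.function, logical(1))])
    }
  )
  out$form <- form
  class(out) <- "removal_form"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

need_params <- function(args, required, where, optional = character(0)) {
  fns <- vapply(args, is.function, logical(1))
  args <- args[!fns]
  miss <- setdiff(required, names(args))
  if (length(miss))
    stop(where, ": missing parameter(s) ", paste(miss, collapse = ", "))
  extra <- setdiff(names(args), c(required, optional))
  if (length(extra))
    stop(where, ": unknown parameter(s) ", paste(extra, collapse = ", "))
  bad <- names(args)[!vapply(args, function(p)
    is.numeric(p) && length(p) == 1 && is.finite(p), logical(1))]
  if (length(bad))
    stop(where, ": parameter(s) not finite scalars: ",
         paste(bad, collapse = ", "))
  args
}

# Richardson-extrapolated central difference, used for custom forms lacking
# analytic derivatives.
num_deriv <- function(fn, x) {
  h <- 1e-4 * (1 + abs(x))
  d1 <- (fn(x + h) - fn(x - h)) / (2 * h)
  d2 <- (fn(x + h / 2) - fn(x - h / 2)) / h
  (4 * d2 - d1) / 3
}

# Monotone inverse on [0, Inf): expand the bracket until g(upper) straddles
# the target, then bisect to 1e-12 relative accuracy.
monotone_inverse <- function(g, eta) {
  vapply(eta, function(e) {
    if (e < 0) stop("monotone_inverse: negative target")
    if (e == 0) return(0)
    upper <- 1
    for (i in 1:120) {
      if (g(upper) >= e) break
      upper <- 2 * upper
    }
    if (g(upper) < e) stop("monotone_inverse: bracket expansion failed")
    stats::uniroot(function(xi) g(xi) - e, c(0, upper),
                   tol = 1e-12 * max(1, upper))$root
  }, numeric(1))
}
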