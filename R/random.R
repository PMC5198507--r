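#' Draw a random admissible model, optionally targeting a regime
#'
#' Generates a model satisfying the structural assumptions, with rates drawn
#' around the scales of the worked examples, and (optionally) rescales the
#' infection and immune-activation rates so that the reproduction numbers
#' place it in a requested global-stability regime.  Used by the package's
#' property checks; randomness flows through R's RNG, so `set.seed()` makes
#' draws reproducible.
#'
#' Regime targeting exploits the threshold structure: \eqn{R_0} is linear in
#' the incidence scale \eqn{\beta}; \eqn{R_3} is linear in the CTL
#' activation rate \eqn{c}; raising \eqn{c} lowers \eqn{v_3} and so raises
#' \eqn{R_2}; raising the antibody activation rate \eqn{r} lowers \eqn{v_2}
#' (resp. \eqn{v_4}) and so raises \eqn{R_1} (resp. \eqn{R_4}).  Thresholds
#' are pushed to at most 0.8 (for "\eqn{\le 1}" clauses) or at least 1.25
#' (for "\eqn{> 1}" clauses) so that sampled models sit away from the
#' bifurcation boundaries; draws whose final classification disagrees with
#' the target are rejected and redrawn.
#'
#' @param regime `"any"` or one of `"E0"`, `"E1"`, `"E2"`, `"E3"`, `"E4"`
#'   (the equilibrium that should be the stable regime; E3/E4 imply
#'   \eqn{\tau_3 = 0}).
#' @param nonlinear_removals probability that \eqn{g_2} is the
#'   `power_affine` form rather than identity.
#' @param max_tries rejection-sampling cap.
#' @return A [viral_model()].
#' @examples
#' set.seed(1)
#' classify_regime(random_viral_model("E1"))$label
#' @export
random_viral_model <- function(regime = c("any", "E0", "E1", "E2", "E3", "E4"),
                               nonlinear_removals = 0, max_tries = 50) {
  regime <- match.arg(regime)
  runifs <- function(lo, hi) stats::runif(1, lo, hi)
  for (try in seq_len(max_tries)) {
    iform <- sample(c("bilinear", "saturated", "holling2", "crowley_martin"),
                    1)
    beta <- runifs(0.1, 0.5)
    incid <- switch(iform,
      bilinear = incidence_form("bilinear", beta = beta),
      saturated = incidence_form("saturated", beta = beta,
                                 b = runifs(0.005, 0.05)),
      holling2 = incidence_form("holling2", beta = beta,
                                a = runifs(0.005, 0.02)),
      crowley_martin = incidence_form("crowley_martin", beta = beta,
                                      a = runifs(0.005, 0.02),
                                      b = runifs(0.005, 0.05))
    )
    growth <- growth_form("linear", lambda = runifs(5, 15),
                          d = runifs(0.005, 0.02))
    g2 <- if (stats::runif(1) < nonlinear_removals)
      removal_form("power_affine", eps = runifs(0.001, 0.02))
    else removal_form("identity")
    removals <- list(removal_form("identity"), g2,
                     removal_form("identity"), removal_form("identity"))
    rates <- list(a = runifs(0.3, 0.8), b = runifs(0.1, 0.2),
                  c = runifs(0.05, 0.2), k = runifs(0.2, 0.6),
                  u = runifs(1, 4), p = runifs(0.5, 2), q = runifs(0.5, 2),
                  r = runifs(0.5, 2), h = runifs(0.1, 1),
                  m1 = runifs(0.005, 0.02), m2 = runifs(0.005, 0.02))
    # positive delays floored at 0.5: shorter ones are dynamically
    # indistinguishable at these time scales but force tiny integrator steps
    delays <- c(tau1 = runifs(0.5, 4), tau2 = runifs(0.5, 6),
                tau3 = if (regime %in% c("E3", "E4")) 0 else runifs(0.5, 3))
    mod <- viral_model(growth, incid, removals, rates, delays)

    mod <- tryCatch(target_regime(mod, regime), error = function(e) NULL)
    if (is.null(mod)) next
    lab <- tryCatch(classify_regime(mod)$label, error = function(e) "err")
    if (regime == "any") {
      if (lab != "err") return(mod)
    } else if (lab == paste0(regime, "-stable")) return(mod)
  }
  stop("could not draw an admissible model for regime ", regime, " in ",
       max_tries, " tries")
}

# rescale beta (R0), c (R2/R3) and r (R1/R4) toward the requested regime
target_regime <- function(mod, regime) {
  scale_rate <- function(mod, nm, fac) {
    if (nm == "beta") {
      mod$incidence <- do.call(incidence_form, c(
        list(form = mod$incidence$form),
        utils::modifyList(mod$incidence$params,
                          list(beta = mod$incidence$params$beta * fac))))
    } else mod$rates[[nm]] <- mod$rates[[nm]] * fac
    mod
  }
  th <- function(mod) reproduction_numbers(mod)
  push <- function(mod, nm, Rname, up, lim = 40) {
    # multiplicative line search on rate nm until threshold crosses its gate
    for (i in seq_len(lim)) {
      R <- th(mod)[[Rname]]
      if (!is.finite(R)) stop("threshold undefined")
      if (up && R >= 1.25) return(mod)
      if (!up && R <= 0.8) return(mod)
      mod <- scale_rate(mod, nm, if (up) 1.6 else 0.6)
    }
    stop("regime targeting failed on ", Rname)
  }
  if (regime == "any") return(mod)
  if (regime == "E0") {
    R0 <- th(mod)$R0
    return(scale_rate(mod, "beta", stats::runif(1, 0.2, 0.8) / R0))
  }
  # all infected regimes need R0 comfortably above 1
  R0 <- th(mod)$R0
  if (R0 < 6) mod <- scale_rate(mod, "beta", 6 / R0)
  if (regime == "E1") {
    mod <- push(mod, "c", "R2", up = FALSE)
    mod <- push(mod, "r", "R1", up = FALSE)
  } else if (regime == "E2") {
    mod <- push(mod, "r", "R1", up = TRUE)
    R3 <- th(mod)$R3
    mod <- scale_rate(mod, "c", min(0.8 / R3, 1))
  } else if (regime == "E3") {
    mod <- push(mod, "c", "R2", up = TRUE)
    mod <- push(mod, "r", "R4", up = FALSE)
  } else if (regime == "E4") {
    # R3 and R4 are coupled through v4 = g2^{-1}(h/r) and y4 = g1^{-1}(b/c):
    # alternate the two rescalings until both gates clear
    for (i in 1:12) {
      t4 <- th(mod)
      if (t4$R3 >= 1.25 && t4$R4 >= 1.25) break
      if (t4$R3 < 1.25) mod <- scale_rate(mod, "c", 1.5 / t4$R3)
      t4 <- th(mod)
      if (t4$R4 < 1.25) mod <- scale_rate(mod, "r", 1.6)
    }
  }
  mod
}
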