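# shared builders and small oracles for the test suite

base_rates <- function(...) {
  utils::modifyList(
    list(a = 0.5, b = 0.15, c = 0.1, k = 0.4, u = 3, p = 1, q = 1,
         r = 1.5, h = 0.5, m1 = 0.01, m2 = 0.01),
    list(...)
  )
}

bilinear_model <- function(beta = 0.002, lambda = 10, d = 0.01,
                           delays = c(tau1 = 1, tau2 = 2, tau3 = 0), ...) {
  viral_model(
    growth = growth_form("linear", lambda = lambda, d = d),
    incidence = incidence_form("bilinear", beta = beta),
    rates = base_rates(...),
    delays = delays
  )
}

rel_err <- function(got, want) abs(got - want) / abs(want)

# exact method-of-steps solution of y'(t) = -y(t - 1), y = 1 on [-1, 0]:
# on [n, n + 1] the solution is a degree-(n + 1) polynomial obtained by
# integrating the previous segment
scalar_dde_exact <- function(t) {
  # polynomial coefficients per segment in the local variable s = t - n
  segs <- list(c(1)) # y = 1 on [-1, 0]
  endv <- 1
  for (n in 1:(ceiling(max(t)) + 1)) {
    prev <- segs[[n]]
    anti <- -prev / seq_along(prev) # antiderivative of -y(t-1)
    segs[[n + 1]] <- c(endv, anti)
    endv <- sum(segs[[n + 1]])
  }
  vapply(t, function(tt) {
    if (tt <= 0) return(1)
    n <- min(floor(tt), length(segs) - 2)
    s <- tt - n
    sum(segs[[n + 2]] * s^(seq_along(segs[[n + 2]]) - 1))
  }, numeric(1))
}

random_positive_history <- function(eq_state) {
  pmax(eq_state * stats::runif(5, 0.5, 1.5), 0.01)
}
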