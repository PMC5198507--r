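test_that("the scalar delayed-decay problem is solved exactly on aligned grids", {
  # y'(t) = -y(t - 1), constant history 1: piecewise-polynomial solution,
  # exact for the one-step scheme while the local degree stays <= 3
  sol <- dde_solve(function(t, y, ylag) -ylag[[1]], history = 1, delays = 1,
                   t_end = 2, h = 0.05)
  expect_equal(sol$states[sol$times == 1], 0, tolerance = 1e-13)
  expect_equal(sol$states[sol$times == 2], -0.5, tolerance = 1e-13)
})

test_that("step size above a quarter of the smallest delay is rejected", {
  expect_error(dde_solve(function(t, y, ylag) -ylag[[1]], 1, 1, 2, h = 0.3),
               "min positive delay")
  expect_error(simulate(example_model(18, tau3 = 0.1), t_end = 10, h = 0.05),
               "min positive delay")
})

test_that("an equilibrium history is a fixed point of the integrator", {
  m17 <- example_model(17)
  e3 <- solve_equilibrium(m17, "E3")
  tr <- simulate(m17, t_end = 500, h = 0.05, history = e3$state)
  expect_lt(max(abs(sweep(tr$states, 2, e3$state))), 1e-6)
})

test_that("trajectories relax to the CTL-only equilibrium in its regime", {
  m17 <- example_model(17)
  e3 <- solve_equilibrium(m17, "E3")
  tr <- simulate(m17, t_end = 3000, h = 0.05,
                 history = c(400, 2, 0.5, 10, 0.1))
  final <- tr$states[nrow(tr$states), ]
  expect_lt(max(abs(final - e3$state) / (1 + abs(e3$state))), 1e-3)
  # halving the step does not move the endpoint
  tr2 <- simulate(m17, t_end = 3000, h = 0.025,
                  history = c(400, 2, 0.5, 10, 0.1))
  expect_lt(max(abs(final - tr2$states[nrow(tr2$states), ]) /
                  (1 + abs(final))), 1e-6)
})

test_that("compiled and plain-R integration paths coincide", {
  m18 <- example_model(18)
  h <- 0.25
  fast <- suppressWarnings(simulate(m18, t_end = 60, h = h,
                                    history = c(900, 2, 1, 0.3, 1)))
  # wrap the incidence as a custom form to force the R path
  cm <- m18$incidence
  slow_mod <- viral_model(
    m18$growth,
    incidence_form("custom", fn = cm$f, fx = cm$fx, fv = cm$fv),
    m18$removals, m18$rates, m18$delays
  )
  slow <- suppressWarnings(simulate(slow_mod, t_end = 60, h = h,
                                    history = c(900, 2, 1, 0.3, 1)))
  expect_equal(slow$method, "rk4-R")
  expect_equal(fast$method, "rk4-compiled")
  expect_lt(max(abs(fast$states - slow$states)), 1e-9)
})

test_that("the integrator agrees with an independent adaptive DDE solver", {
  skip_if_not_installed("deSolve")
  m18 <- example_model(18)
  hist0 <- c(900, 2, 1, 0.3, 1)
  tr <- simulate(m18, t_end = 100, h = 0.02, history = hist0)
  derivs <- function(t, y, parms) {
    lag1 <- if (t > 5) deSolve::lagvalue(t - 5) else hist0
    lag2 <- if (t > 8) deSolve::lagvalue(t - 8) else hist0
    list(viral_rhs(m18, pmax(y, 0), pmax(lag1, 0), pmax(lag2, 0),
                   pmax(y, 0)))
  }
  ref <- deSolve::dede(y = hist0, times = c(0, 50, 100), func = derivs,
                       parms = NULL, atol = 1e-10, rtol = 1e-10)
  for (ti in c(50, 100)) {
    ours <- tr$states[tr$times == ti, ]
    theirs <- ref[ref[, 1] == ti, 2:6]
    expect_lt(max(abs(ours - theirs) / (1 + abs(theirs))), 1e-6)
  }
})

test_that("dense output is exact at nodes, reproduces linears, and converges at order four", {
  sol <- dde_solve(function(t, y, ylag) -ylag[[1]], history = 1, delays = 1,
                   t_end = 6, h = 0.1)
  # node exactness
  idx <- c(5, 17, 31)
  expect_equal(drop(dense_eval(sol, sol$times[idx])),
               sol$states[idx], tolerance = 0)
  # a linear trajectory is reproduced exactly between nodes
  lin <- dde_solve(function(t, y, ylag) 2, history = 1, delays = 1,
                   t_end = 2, h = 0.25)
  ts <- c(0.1, 0.33, 1.87)
  expect_equal(drop(dense_eval(lin, ts)), 1 + 2 * ts, tolerance = 1e-13)
  # empirical convergence order of the dense solution >= 3.5
  hs <- c(0.1, 0.05, 0.025, 0.0125)
  errs <- vapply(hs, function(h) {
    s <- dde_solve(function(t, y, ylag) -ylag[[1]], history = 1, delays = 1,
                   t_end = 6, h = h)
    tq <- seq(0.5, 5.5, by = 0.375) # off-node query points
    max(abs(drop(dense_eval(s, tq)) - scalar_dde_exact(tq)))
  }, numeric(1))
  slopes <- log2(errs[-length(errs)] / errs[-1])
  expect_gte(min(slopes), 3.5)
})

test_that("solutions stay positive and ultimately bounded for random admissible models", {
  set.seed(77)
  for (i in 1:8) {
    mod <- random_viral_model("any")
    eqs <- equilibria(mod)
    xb <- find_xbar(mod)
    hist0 <- pmax(c(xb, 5, 5, 1, 1) * runif(5, 0.2, 2), 0.01)
    tr <- suppressWarnings(simulate(mod, t_end = 1000, h = 0.05,
                                    history = hist0))
    expect_gt(min(tr$states), -1e-8)
    # a-priori scale: the target-cell pool cannot exceed its carrying state
    # once transients fade, and every compartment stays desk-bounded
    expect_lt(max(tr$states), 10 * max(xb, hist0, 50))
  }
})

test_that("histories can be general functions of time", {
  m <- bilinear_model(beta = 0.002, delays = c(tau1 = 1, tau2 = 2, tau3 = 0))
  histf <- function(t) c(900 + 10 * t, 2 * exp(t), 1, 0.5, 0.5)
  tr <- simulate(m, t_end = 10, h = 0.05, history = histf)
  expect_equal(unname(tr$states[1, ]), histf(0), tolerance = 1e-12)
  expect_equal(unname(drop(dense_eval(tr, -0.5))), histf(-0.5),
               tolerance = 1e-12)
  expect_true(all(is.finite(tr$states)))
})
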