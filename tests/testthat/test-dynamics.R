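make_synthetic_traj <- function(states, h) {
  # wrap a precomputed state matrix as a trajectory (finite-difference
  # derivatives are good enough for classification tests)
  n <- nrow(states)
  derivs <- rbind(diff(states) / h, 0)
  structure(list(times = (0:(n - 1)) * h, states = states, derivs = derivs,
                 h = h, tau = 0, history = function(t) states[1, ],
                 method = "synthetic"),
            class = "viral_trajectory")
}

test_that("a constant trajectory is classified as converged with zero amplitudes", {
  st <- matrix(rep(c(500, 2, 1, 0.5, 0.2), each = 2001), ncol = 5)
  colnames(st) <- c("x", "y", "v", "z", "w")
  rep <- detect_oscillation(make_synthetic_traj(st, 0.5))
  expect_equal(rep$classification, "converged")
  expect_true(all(rep$amplitudes == 0))
})

test_that("a sustained sinusoid on the virus channel is oscillatory with the right period", {
  h <- 0.05
  tt <- seq(0, 400, by = h)
  st <- cbind(x = rep(500, length(tt)), y = rep(2, length(tt)),
              v = 1 + 0.5 * sin(tt), z = rep(0.5, length(tt)),
              w = rep(0.2, length(tt)))
  rep <- detect_oscillation(make_synthetic_traj(st, h))
  expect_equal(rep$classification, "oscillatory")
  expect_equal(rep$period, 2 * pi, tolerance = 0.02)
})

test_that("a decaying ring-down is not classified as sustained oscillation", {
  h <- 0.05
  tt <- seq(0, 400, by = h)
  st <- cbind(x = rep(500, length(tt)), y = rep(2, length(tt)),
              v = 1 + exp(-0.02 * tt) * sin(tt), z = rep(0.5, length(tt)),
              w = rep(0.2, length(tt)))
  rep <- detect_oscillation(make_synthetic_traj(st, h))
  expect_true(rep$classification %in% c("undecided", "converged"))
})

test_that("the immune-delay sweep finds the benchmark stability switch", {
  # desk-scale check of the first switch window; the full published pattern
  # is exercised by the acceptance suite
  sc <- scan_tau3(example_model(17), c(0.2, 2), t_end = 1500, h = 0.02)
  expect_equal(sc$grid$classification, c("converged", "oscillatory"))
  expect_equal(nrow(sc$switches), 1)
  expect_equal(sc$switches$tau3_lo, 0.2)
  # rerunning reproduces the classifications bit-identically
  sc2 <- scan_tau3(example_model(17), c(0.2, 2), t_end = 1500, h = 0.02)
  expect_identical(sc$grid, sc2$grid)
})

test_that("a tau3 = 0 CTL-regime model yields a single converged point", {
  sc <- scan_tau3(example_model(17), 0, t_end = 1500, h = 0.02)
  expect_equal(sc$grid$classification, "converged")
  expect_equal(nrow(sc$switches), 0)
})

test_that("the Volterra distance H has its closed-form values", {
  expect_equal(viraldelay:::lyap_H(1), 0)
  expect_equal(viraldelay:::lyap_H(exp(1)), exp(1) - 2)
  expect_error(viraldelay:::lyap_H(0), "xi > 0")
  xi <- c(0.02, 0.5, 3, 40)
  expect_true(all(viraldelay:::lyap_H(xi) >= 0))
})

test_that("the immune-free functional vanishes on its pinned equilibrium", {
  m18 <- example_model(18)
  e1 <- solve_equilibrium(m18, "E1")
  tr <- simulate(m18, t_end = 60, h = 0.25, history = e1$state)
  lv <- lyapunov_functional(m18, tr, 30, "V2")
  expect_equal(lv$value, 0, tolerance = 1e-9)
  expect_equal(lv$dVdt, 0, tolerance = 1e-9)
})

test_that("the infection-free functional decays no faster than its proof bound allows", {
  # in the subthreshold regime dV1/dt <= (a u e^{m1 tau1 + m2 tau2}/k)
  # g2(v) (R0 - 1) <= 0
  set.seed(13)
  mod <- random_viral_model("E0")
  th <- reproduction_numbers(mod)
  tr <- simulate(mod, t_end = 400, h = 0.05,
                 history = c(find_xbar(mod) * 0.5, 3, 2, 0.5, 0.5))
  ts <- seq(20, 380, length.out = 50)
  lv <- lyapunov_functional(mod, tr, ts, "V1")
  expect_true(all(lv$dVdt <= 1e-6))
  bound <- with(mod$rates, a * u * exp(m1 * mod$delays[["tau1"]] +
                                         m2 * mod$delays[["tau2"]]) / k) *
    mod$removals$g2$g(dense_eval(tr, ts)[, "v"]) * (th$R0 - 1)
  expect_true(all(lv$dVdt <= bound + 1e-6 * (1 + abs(bound))))
})

test_that("each Lyapunov functional is nonnegative and nonincreasing in its regime", {
  set.seed(29)
  cases <- list(
    list(fun = "V1", mod = random_viral_model("E0")),
    list(fun = "V2", mod = random_viral_model("E1")),
    list(fun = "V3", mod = random_viral_model("E2")),
    list(fun = "V4", mod = example_model(17)),
    list(fun = "V5", mod = example_model(18))
  )
  for (cs in cases) {
    mod <- cs$mod
    lab <- c(V1 = "E0", V2 = "E1", V3 = "E2", V4 = "E3", V5 = "E4")[cs$fun]
    eq <- solve_equilibrium(mod, lab)
    hist0 <- pmax(eq$state * 1.4, 0.05)
    tr <- simulate(mod, t_end = 500, h = 0.05, history = hist0)
    ts <- seq(25, 475, by = 25)
    lv <- lyapunov_functional(mod, tr, ts, cs$fun)
    expect_true(all(lv$value >= 0), label = cs$fun)
    expect_true(all(diff(lv$value) <= 1e-6 * (1 + lv$value[-1])),
                label = paste(cs$fun, "nonincreasing"))
  }
})
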