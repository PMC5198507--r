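test_that("the uninfected steady state solves s(x) = 0 with negative slope", {
  # linear growth: xbar = lambda / d exactly
  expect_equal(find_xbar(bilinear_model(lambda = 10, d = 0.01)), 1000,
               tolerance = 1e-12)
  # logistic growth: positive root of 10 + 0.59 x - 0.0012 x^2
  mod17 <- example_model(17)
  xbar_quad <- (0.59 + sqrt(0.59^2 + 4 * 0.0012 * 10)) / (2 * 0.0012)
  expect_equal(find_xbar(mod17), xbar_quad, tolerance = 1e-12)
  # degenerate logistic (r1 = 0) reduces to lambda / d
  mod0 <- viral_model(
    growth_form("logistic", lambda = 10, d = 0.01, r1 = 0, K = 500),
    incidence_form("bilinear", beta = 0.001),
    rates = base_rates(), delays = c(tau1 = 0, tau2 = 0, tau3 = 0)
  )
  expect_equal(find_xbar(mod0), 1000, tolerance = 1e-12)
})

test_that("R0 matches its closed form", {
  # hand evaluation for the coexistence benchmark
  m18 <- example_model(18)
  expect_equal(reproduction_numbers(m18)$R0,
               0.4 * exp(-0.13) / (0.5 * 3) * 250 / 11, tolerance = 1e-12)
  # zero transport delays: survival factor exactly 1
  m <- bilinear_model(beta = 0.002, delays = c(tau1 = 0, tau2 = 0, tau3 = 0))
  expect_equal(reproduction_numbers(m)$R0, 0.4 * 0.002 * 1000 / (0.5 * 3),
               tolerance = 1e-12)
  # bilinear closed form with delays
  m2 <- bilinear_model(beta = 0.002, delays = c(tau1 = 2, tau2 = 3, tau3 = 0))
  expect_equal(reproduction_numbers(m2)$R0,
               0.4 * 0.002 * 1000 * exp(-0.01 * 2 - 0.01 * 3) / (0.5 * 3),
               tolerance = 1e-12)
})

test_that("the immune-free equilibrium exists iff infection can invade", {
  m17 <- example_model(17)
  e1 <- solve_equilibrium(m17, "E1")
  expect_true(e1$exists)
  expect_lt(e1$residual, 1e-8 * (1 + max(abs(e1$state))))
  expect_true(all(e1$state[c("z", "w")] == 0))
  # scale the incidence so R0 = 0.5: no infected equilibrium
  th <- reproduction_numbers(m17)
  weak <- viral_model(
    m17$growth,
    incidence_form("exp_shift", beta = 0.3 * 0.5 / th$R0, b1 = 0.01,
                   c1 = 0.01),
    m17$removals, m17$rates, m17$delays
  )
  expect_equal(reproduction_numbers(weak)$R0, 0.5, tolerance = 1e-10)
  expect_false(solve_equilibrium(weak, "E1")$exists)
  expect_equal(classify_regime(weak)$label, "E0-stable")
})

test_that("the immune-free cell component is the unique sign change on (0, xbar)", {
  # dense scan of G(x) = f(x, phi(x)) - s(x): exactly one sign change,
  # at the root the solver returns
  m18 <- example_model(18)
  xbar <- find_xbar(m18)
  e1 <- solve_equilibrium(m18, "E1")
  sf <- exp(-0.01 * 5 - 0.01 * 8)
  aue <- 0.5 * 3 / sf
  G <- function(x) {
    v <- pmax(m18$rates$k * m18$growth$s(x) / aue, 0)
    m18$incidence$f(x, v) - m18$growth$s(x)
  }
  xs <- seq(xbar * 1e-4, xbar * (1 - 1e-6), length.out = 1e4)
  sgn <- sign(G(xs))
  flips <- which(diff(sgn) != 0)
  expect_length(flips, 1)
  expect_lt(abs(xs[flips] - e1$state[["x"]]), xbar * 1e-3)
})

test_that("antibody-only equilibrium: pinned virus level and Lemma-5 sign relation", {
  m17 <- example_model(17)
  e2 <- solve_equilibrium(m17, "E2")
  # identity removals: v2 = h / r exactly
  expect_equal(e2$state[["v"]], 1 / 1.5, tolerance = 1e-12)
  expect_true(e2$state[["z"]] == 0)
  set.seed(11)
  for (i in 1:12) {
    mod <- random_viral_model("any")
    th <- reproduction_numbers(mod)
    if (!(th$R0 > 1) || !isTRUE(th$defined[["R1"]])) next
    e1 <- solve_equilibrium(mod, "E1")
    v2 <- mod$removals$g2$ginv(mod$rates$h / mod$rates$r)
    x2 <- tryCatch(
      uniroot(function(x) mod$growth$s(x) - mod$incidence$f(x, v2),
              c(1e-6, find_xbar(mod)), tol = 1e-12)$root,
      error = function(e) NULL)
    if (is.null(x2)) next
    s125 <- c(sign(x2 - e1$state[["x"]]), sign(e1$state[["v"]] - v2),
              sign(th$R1 - 1))
    expect_true(all(s125 == s125[1]))
  }
})

test_that("R1 below one suppresses the antibody-only equilibrium", {
  set.seed(3)
  mod <- random_viral_model("E1") # targets R1 <= 0.8, R2 <= 0.8
  th <- reproduction_numbers(mod)
  expect_lte(th$R1, 1)
  e2 <- solve_equilibrium(mod, "E2")
  expect_false(e2$exists)
  expect_true(all(is.na(e2$state)))
})

test_that("CTL-only equilibrium reproduces the benchmark values", {
  m17 <- example_model(17)
  th <- reproduction_numbers(m17)
  e3 <- solve_equilibrium(m17, "E3")
  expect_equal(e3$state[["y"]], 1.5, tolerance = 1e-12)
  expect_equal(e3$state[["v"]], 0.1902, tolerance = 1e-3)
  expect_equal(e3$state[["x"]], 462.1965, tolerance = 1e-3)
  expect_equal(th$R2, 34.4139, tolerance = 1e-3)
  # identity removals and tau2 = 0: v3 = b k / (c u) exactly
  m <- bilinear_model(beta = 0.01, delays = c(tau1 = 1, tau2 = 0, tau3 = 0))
  e3b <- solve_equilibrium(m, "E3")
  if (e3b$exists)
    expect_equal(e3b$state[["v"]], 0.15 * 0.4 / (0.1 * 3), tolerance = 1e-12)
})

test_that("Lemma-6 sign relation links E3 to the immune-free equilibrium", {
  set.seed(19)
  done <- 0
  for (i in 1:40) {
    mod <- random_viral_model("any")
    th <- reproduction_numbers(mod)
    if (!(th$R0 > 1) || !isTRUE(th$defined[["R2"]])) next
    e1 <- tryCatch(solve_equilibrium(mod, "E1"), error = function(e) NULL)
    if (is.null(e1) || !e1$exists) next
    g <- mod$removals
    sf <- exp(-mod$rates$m1 * mod$delays[["tau1"]] -
                mod$rates$m2 * mod$delays[["tau2"]])
    y3 <- g$g1$ginv(mod$rates$b / mod$rates$c)
    v3 <- g$g2$ginv(mod$rates$b * mod$rates$k *
                      exp(-mod$rates$m2 * mod$delays[["tau2"]]) /
                      (mod$rates$c * mod$rates$u))
    x3 <- tryCatch(
      uniroot(function(x) mod$growth$s(x) - mod$incidence$f(x, v3),
              c(1e-9, find_xbar(mod)), tol = 1e-12)$root,
      error = function(e) NULL)
    if (is.null(x3)) next
    s <- c(sign(x3 - e1$state[["x"]]), sign(e1$state[["v"]] - v3),
           sign(e1$state[["y"]] - y3), sign(th$R2 - 1))
    expect_true(all(s == s[1]))
    done <- done + 1
    if (done >= 20) break
  }
  expect_gte(done, 10)
})

test_that("coexistence equilibrium matches the benchmark and its gates", {
  m18 <- example_model(18)
  th <- reproduction_numbers(m18)
  e4 <- solve_equilibrium(m18, "E4")
  expect_equal(th$R3, 1.891, tolerance = 1e-3)
  expect_equal(th$R4, 2.769, tolerance = 1e-3)
  expect_equal(e4$state[["z"]], 0.4456, tolerance = 2e-3)
  expect_equal(e4$state[["y"]], 1.5, tolerance = 1e-12)
  # identity removals pin v4 = h/r and y4 = b/c exactly
  expect_equal(e4$state[["v"]], 0.1 / 1.5, tolerance = 1e-12)
  # the CTL-dominated benchmark has R4 < 1: no coexistence
  m17 <- example_model(17)
  expect_equal(reproduction_numbers(m17)$R4, 0.2854, tolerance = 1e-3)
  expect_false(solve_equilibrium(m17, "E4")$exists)
})

test_that("regime classification follows the threshold theorems", {
  expect_equal(classify_regime(example_model(17))$label, "E3-stable")
  expect_equal(classify_regime(example_model(18))$label, "E4-stable")
  # tau3 > 0 leaves the CTL/coexistence corners open
  expect_equal(classify_regime(example_model(17, tau3 = 2))$label,
               "indeterminate")
})

test_that("whenever defined, R1 and R2 stay below R0", {
  set.seed(101)
  n_checked <- 0
  for (i in 1:100) {
    mod <- random_viral_model("any", nonlinear_removals = 0.3)
    th <- reproduction_numbers(mod)
    if (isTRUE(th$defined[["R1"]])) {
      expect_lt(th$R1, th$R0)
      n_checked <- n_checked + 1
    }
    if (isTRUE(th$defined[["R2"]])) expect_lt(th$R2, th$R0)
  }
  expect_gte(n_checked, 50)
})

test_that("raising the intracellular delay never raises R0", {
  set.seed(5)
  mod <- random_viral_model("any")
  taus <- seq(0, 10, by = 0.5)
  R0s <- vapply(taus, function(t1) {
    mod$delays[["tau1"]] <- t1
    reproduction_numbers(mod)$R0
  }, numeric(1))
  expect_true(all(diff(R0s) <= 0))
})

test_that("each equilibrium cell component is a unique sign change of its defining function", {
  for (w in c(17, 18)) {
    mod <- example_model(w)
    xbar <- find_xbar(mod)
    xs <- seq(xbar * 1e-4, xbar * (1 - 1e-7), length.out = 1e4)
    for (lab in c("E2", "E3", "E4")) {
      eq <- solve_equilibrium(mod, lab)
      if (!eq$exists) next
      Fx <- mod$growth$s(xs) - mod$incidence$f(xs, eq$state[["v"]])
      flips <- which(diff(sign(Fx)) != 0)
      expect_length(flips, 1)
      expect_lt(abs(xs[flips] - eq$state[["x"]]), 1e-3 * xbar)
    }
  }
})
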