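test_that("the infection-free viral factor at lambda = 0 equals au(1 - R0)", {
  for (mod in list(example_model(17), example_model(18),
                   bilinear_model(beta = 0.002))) {
    th <- reproduction_numbers(mod)
    L <- viraldelay:::linearization_at(mod, solve_equilibrium(mod, "E0"))
    sf <- viraldelay:::survival_factors(mod)
    f0 <- mod$rates$a * mod$rates$u -
      mod$rates$k * L$fv * sf[["e1"]] * sf[["e2"]]
    expect_equal(f0, mod$rates$a * mod$rates$u * (1 - th$R0),
                 tolerance = 1e-10)
  }
  # coexistence benchmark: f(0) = 1.5 (1 - R0) < 0
  m18 <- example_model(18)
  th <- reproduction_numbers(m18)
  expect_lt(1.5 * (1 - th$R0), 0)
})

test_that("factored characteristic forms agree with the 5x5 determinant", {
  set.seed(23)
  lams <- complex(real = runif(25, -2, 2), imaginary = runif(25, -5, 5))
  m17 <- example_model(17, tau3 = 0.5)
  m18 <- example_model(18, tau3 = 0.5)
  cases <- list(list(m17, "E0"), list(m17, "E1"), list(m17, "E2"),
                list(m17, "E3"), list(m18, "E0"), list(m18, "E1"),
                list(m18, "E2"), list(m18, "E3"), list(m18, "E4"))
  for (cs in cases) {
    eq <- solve_equilibrium(cs[[1]], cs[[2]])
    if (!eq$exists) next
    full <- characteristic_at(cs[[1]], eq, lams, method = "determinant")
    if (cs[[2]] == "E4") {
      expect_error(characteristic_at(cs[[1]], eq, lams[1],
                                     method = "factored"), "factored")
      next
    }
    fact <- characteristic_at(cs[[1]], eq, lams, method = "factored")
    expect_lt(max(Mod(full - fact) / (1 + Mod(full))), 1e-8)
  }
})

test_that("at zero delays the characteristic function is the Jacobian characteristic polynomial", {
  mod <- bilinear_model(beta = 0.01, delays = c(tau1 = 0, tau2 = 0,
                                                tau3 = 0))
  eq <- solve_equilibrium(mod, "E1")
  expect_true(eq$exists)
  J <- with(viraldelay:::delayed_jacobians(mod, eq), J0 + J1 + J2 + J3)
  ev <- eigen(J, only.values = TRUE)$values
  lams <- complex(real = c(-1, 0.3, 0.2, 1), imaginary = c(0, 0.5, -2, 1))
  for (l in lams) {
    want <- prod(l - ev)
    got <- characteristic_at(mod, eq, l)
    expect_lt(Mod(got - want) / (1 + Mod(want)), 1e-8)
  }
})

test_that("delay-free infection-free roots obey the quadratic formula", {
  mod <- bilinear_model(beta = 0.002, delays = c(tau1 = 0, tau2 = 0,
                                                 tau3 = 0))
  th <- reproduction_numbers(mod)
  a <- mod$rates$a
  u <- mod$rates$u
  disc <- (a + u)^2 - 4 * a * u * (1 - th$R0)
  roots_quad <- (-(a + u) + c(1, -1) * sqrt(disc)) / 2
  eq <- solve_equilibrium(mod, "E0")
  for (r in roots_quad)
    expect_lt(Mod(characteristic_at(mod, eq, r + 0i)), 1e-8)
})

test_that("analytic instability certificates fire exactly when the clauses do", {
  # CTL-dominated benchmark: R4 < 1, no antibody-driven root at E3
  m17 <- example_model(17)
  expect_equal(nrow(analytic_unstable_roots(m17, solve_equilibrium(m17, "E3"))),
               0)
  # coexistence benchmark at E3: R4 > 1 gives lambda* = r g2(v3) - h > 0,
  # and Delta(lambda*) = 0 on the scalar antibody factor
  m18 <- example_model(18)
  e3 <- solve_equilibrium(m18, "E3")
  ar <- analytic_unstable_roots(m18, e3)
  expect_equal(ar$root, 1.5 * e3$state[["v"]] - 0.1, tolerance = 1e-12)
  expect_gt(ar$root, 0)
  expect_lt(Mod(characteristic_at(m18, e3, ar$root + 0i)), 1e-6 *
              Mod(characteristic_at(m18, e3, ar$root + 1 + 0i)))
  # immune-free equilibrium with both responses viable: two certificates
  e1 <- solve_equilibrium(m18, "E1")
  ar1 <- analytic_unstable_roots(m18, e1)
  expect_setequal(ar1$factor, c("antibody factor", "CTL factor"))
  expect_true(all(ar1$root > 0))
})

test_that("rightmost-root verdicts agree with the stability theorems", {
  # the regime equilibrium is locally stable ...
  m17 <- example_model(17)
  m18 <- example_model(18)
  expect_equal(rightmost_root(m17, solve_equilibrium(m17, "E3"))$verdict,
               "stable")
  expect_equal(rightmost_root(m18, solve_equilibrium(m18, "E4"))$verdict,
               "stable")
  # ... and the superseded ones are unstable
  expect_equal(rightmost_root(m18, solve_equilibrium(m18, "E0"))$verdict,
               "unstable")
  expect_equal(rightmost_root(m18, solve_equilibrium(m18, "E1"))$verdict,
               "unstable")
  expect_equal(rightmost_root(m18, solve_equilibrium(m18, "E3"))$verdict,
               "unstable")
  # subthreshold model: infection-free state stable with delays present
  weak <- bilinear_model(beta = 1e-5, delays = c(tau1 = 1, tau2 = 1,
                                                 tau3 = 0))
  expect_lt(reproduction_numbers(weak)$R0, 1)
  rep <- rightmost_root(weak, solve_equilibrium(weak, "E0"))
  expect_equal(rep$verdict, "stable")
  expect_identical(rep$n_unstable, 0)
})

test_that("random-model verdicts match the regime classification", {
  set.seed(31)
  for (regime in c("E0", "E1", "E2")) {
    for (rep_i in 1:2) {
      mod <- random_viral_model(regime)
      eq <- solve_equilibrium(mod, regime)
      expect_equal(rightmost_root(mod, eq)$verdict, "stable",
                   label = paste("regime", regime))
    }
  }
  for (regime in c("E3", "E4")) {
    mod <- random_viral_model(regime)
    eq <- solve_equilibrium(mod, regime)
    expect_equal(rightmost_root(mod, eq)$verdict, "stable",
                 label = paste("regime", regime))
  }
  # instability clause: an E3-regime model pushed into R4 > 1 territory
  mod <- random_viral_model("E4")
  e3 <- solve_equilibrium(mod, "E3")
  if (e3$exists)
    expect_equal(rightmost_root(mod, e3)$verdict, "unstable")
})
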