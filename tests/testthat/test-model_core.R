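test_that("transform to natural scale follows log-normal / logit-normal laws", {
  pop <- ref_pop()
  psi0 <- transform_to_natural(pop, rep(0, 4))
  expect_equal(unlist(psi0),
               c(r = pop$r_pop, psa0 = pop$psa0_pop, eps = pop$eps_pop,
                 tesc = pop$tesc_pop))
  # log-normal shift doubles the rate, leaves the rest untouched
  psi2 <- transform_to_natural(pop, c(log(2), 0, 0, 0))
  expect_equal(psi2$r, 2 * pop$r_pop)
  expect_equal(psi2[c("psa0", "eps", "tesc")], psi0[c("psa0", "eps", "tesc")])
  # logit-normal keeps effectiveness inside (0, 1) however large the shift
  psi_hi <- transform_to_natural(pop, c(0, 0, 10, 0))
  expect_gt(psi_hi$eps, 0.99)
  expect_lt(psi_hi$eps, 1)
  expect_error(transform_to_natural(pop, c(0, 0, NA, 0)), "finite")
})

test_that("transform is a bijection between eta-space and psi-space", {
  pop <- ref_pop()
  set.seed(101)
  for (i in 1:25) {
    eta <- rnorm(4, sd = c(0.098, 1.57, 1.34, 0.64))
    back <- transform_to_eta(pop, transform_to_natural(pop, eta))
    expect_equal(back, eta, tolerance = 1e-10)
  }
})

test_that("PSA curve starts at PSA0, stays positive and is continuous at the escape kink", {
  pop <- ref_pop()
  set.seed(102)
  for (i in 1:1000) {
    eta <- rnorm(4, sd = c(0.098, 1.57, 1.34, 0.64))
    psi <- transform_to_natural(pop, eta)
    expect_identical(psa_value(0, psi), psi$psa0)
    # branch agreement at the kink: evaluate the post-escape branch at
    # exactly tesc through its own closed form and compare with the
    # on-treatment value there
    p_esc <- psa_value(psi$tesc, psi)
    c1 <- psi$r * (1 - psi$eps) - 0.046
    c2 <- psi$r - 0.046
    a2 <- 0.23 * psi$psa0 / (c2 + 0.23)
    right <- a2 * exp(c2 * psi$tesc - psi$r * psi$eps * psi$tesc) +
      (p_esc - a2 * exp(c1 * psi$tesc))
    expect_lt(abs(right - p_esc), 1e-10 * max(psi$psa0, p_esc))
    tt <- c(1, 50, psi$tesc, psi$tesc + 1, 500, 2000)
    expect_true(all(psa_value(tt, psi) > 0))
  }
})

test_that("PSA at 21 days under reference parameters matches an independent ODE solve", {
  # the biexponential is the solution of the cell/PSA system
  #   N' = (rho(t) - d) N,  P' = delta (N - P),  N(0) = P(0) = PSA0
  # with rho = r(1-eps) on treatment and r after the escape time
  skip_if_not_installed("deSolve")
  pop <- ref_pop()
  psi <- ref_psi(pop)
  rhs <- function(t, state, parms) {
    rho <- if (t <= psi$tesc) psi$r * (1 - psi$eps) else psi$r
    list(c(state[1] * (rho - pop$d_fixed),
           pop$delta_elim_fixed * (state[1] - state[2])))
  }
  sol <- deSolve::lsoda(c(N = psi$psa0, P = psi$psa0), seq(0, 300, by = 1),
                        rhs, NULL, rtol = 1e-10, atol = 1e-10)
  ode_p <- sol[sol[, "time"] %in% c(21, 100, 300), "P"]
  expect_equal(psa_value(c(21, 100, 300), psi), unname(ode_p),
               tolerance = 1e-6)
  expect_equal(psa_value(21, psi), 62.2, tolerance = 1e-3)
})

test_that("removable singularities are evaluated by their analytic limits", {
  # with the reference constants (delta > d) the denominators never vanish,
  # but the code must stay continuous for arbitrary rate configurations
  d <- 0.4; delta <- 0.23
  # after escape: r - d + delta = 0
  base <- list(psa0 = 60, eps = 0.4, tesc = 80)
  p_exact <- structure(c(list(r = d - delta), base), class = "psa_psi")
  p_near <- structure(c(list(r = (d - delta) * (1 + 1e-9)), base),
                      class = "psa_psi")
  tt <- c(10, 79, 81, 200, 400)
  expect_true(all(is.finite(psa_value(tt, p_exact, d, delta))))
  expect_equal(psa_value(tt, p_exact, d, delta),
               psa_value(tt, p_near, d, delta), tolerance = 1e-6)
  expect_equal(psa_deriv(tt, p_exact, d, delta),
               psa_deriv(tt, p_near, d, delta), tolerance = 1e-5)
  # on treatment: r(1-eps) - d + delta = 0
  q_exact <- structure(list(r = 0.34, psa0 = 60, eps = 0.5, tesc = 120),
                       class = "psa_psi")
  q_near <- q_exact; q_near$eps <- 0.5 * (1 + 1e-9)
  expect_equal(psa_value(tt, q_exact, d, delta),
               psa_value(tt, q_near, d, delta), tolerance = 1e-6)
})

test_that("log-scale observation mean is log(PSA+1) and monotone in PSA", {
  pop <- ref_pop()
  psi <- ref_psi(pop)
  expect_equal(log_psa(0, psi), log(pop$psa0_pop + 1))
  expect_equal(log(74.9), 4.316, tolerance = 1e-3)
  tt <- seq(0, 400, by = 5)
  p <- psa_value(tt, psi)
  expect_identical(order(log_psa(tt, psi)), order(p))
})

test_that("log-PSA slope matches central finite differences away from the kink", {
  pop <- ref_pop()
  psi <- ref_psi(pop)
  h <- 1e-4
  for (t in c(5, 50, 120, 160, 400)) {
    fd <- (log_psa(t + h, psi) - log_psa(t - h, psi)) / (2 * h)
    expect_equal(log_psa_slope(t, psi), fd, tolerance = 1e-5)
  }
  set.seed(103)
  for (i in 1:50) {
    psi_r <- transform_to_natural(pop, rnorm(4, sd = c(0.098, 1.57, 1.34, 0.64)))
    t <- runif(1, 1, 600)
    if (abs(t - psi_r$tesc) < 1) next
    fd <- (log_psa(t + h, psi_r) - log_psa(t - h, psi_r)) / (2 * h)
    expect_equal(log_psa_slope(t, psi_r), fd, tolerance = 1e-5)
  }
})

test_that("slope is zero at the nadir and negative at t=0 when treatment wins", {
  pop <- ref_pop()
  psi <- ref_psi(pop)
  # reference kinetics decline at start: r(1-eps) < d
  expect_lt(psi$r * (1 - psi$eps), pop$d_fixed)
  expect_lt(log_psa_slope(1e-6, psi), 0)
  # PSA declines throughout treatment, so the nadir sits after the escape
  # time where regrowth takes over; the slope vanishes there
  nadir <- optimize(function(t) psa_value(t, psi),
                    c(psi$tesc, 2000), tol = 1e-9)$minimum
  expect_gt(nadir, psi$tesc)
  expect_equal(log_psa_slope(nadir, psi), 0, tolerance = 1e-6)
  # on-treatment continuity check at the reference draw itself
  expect_lt(abs(psa_value(psi$tesc, psi) -
                  psa_value(psi$tesc * (1 + 1e-14), psi)),
            1e-10 * psi$psa0)
})

test_that("area under log(PSA+1) matches adaptive quadrature and trivial cases", {
  pop <- ref_pop()
  psi <- ref_psi(pop)
  expect_identical(log_psa_area(0, psi), 0)
  for (t in c(50, 100, 138, 250, 600)) {
    ref <- integrate(function(u) log1p(psa_value(u, psi)), 0, t,
                     rel.tol = 1e-10)$value
    expect_equal(log_psa_area(t, psi), ref, tolerance = 1e-6)
  }
  # flat trajectory: eps = 0 and r = d gives constant PSA, area = t*log(PSA0+1)
  flat <- structure(list(r = pop$d_fixed, psa0 = 40, eps = 1e-12, tesc = 1e6),
                    class = "psa_psi")
  expect_equal(log_psa_area(200, flat), 200 * log1p(40), tolerance = 1e-6)
})
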