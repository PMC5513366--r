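test_that("Kaplan-Meier product-limit estimator on toy data", {
  km <- km_curve(c(2, 3, 5, 7), c(1, 0, 1, 1))
  expect_equal(km_eval(km, 5), (3 / 4) * (1 / 2))        # hand product-limit
  expect_equal(km_eval(km, 1.9), 1)
  expect_equal(km_eval(km, 5, left = TRUE), 3 / 4)       # left-continuity
  # no censoring: empirical survival function
  tt <- c(1, 4, 6, 9)
  km2 <- km_curve(tt, rep(1, 4))
  for (u in c(0.5, 1, 3, 8, 10))
    expect_equal(km_eval(km2, u), mean(tt > u))
  # all censored: flat at 1
  km3 <- km_curve(tt, rep(0, 4))
  expect_equal(km_eval(km3, 10), 1)
})

test_that("IPCW weights: uncensored data weight 1, in-window censoring weights 0", {
  sr <- data.frame(time_days = c(100, 150, 250, 400, 500), event = 1L)
  G <- km_curve(sr$time_days, 1L - sr$event)
  w <- ipcw_weights(50, 200, sr, G)
  expect_equal(w, rep(1, 5))
  sr2 <- sr; sr2$event <- c(1L, 0L, 1L, 0L, 1L)
  G2 <- km_curve(sr2$time_days, 1L - sr2$event)
  w2 <- ipcw_weights(50, 200, sr2, G2)
  expect_equal(w2[2], 0)                 # censored inside (50, 250]
  expect_true(all(w2[-2] > 0))
})

test_that("IPCW weights match a hand computation on a 6-subject cohort", {
  # censoring times: 150 (subject 2); G(u) drops from 1 to 4/5 after 150
  sr <- data.frame(time_days = c(100, 150, 200, 300, 450, 500),
                   event = c(1L, 0L, 1L, 1L, 0L, 1L))
  G <- km_curve(sr$time_days, 1L - sr$event)
  s <- 50; t <- 300
  w <- ipcw_weights(s, t, sr, G)
  # G(s) = 1; cases die at 100 (G(100-)=1), 200 and 300 (G- = 4/5)
  # controls have T > 350: G(350-) = 4/5
  expect_equal(w, c(1, 0, 5 / 4, 5 / 4, 5 / 4, 5 / 4))
})

test_that("dummy predictor identities hold exactly without censoring", {
  set.seed(61)
  sr <- data.frame(time_days = rexp(40, 1 / 400) + 1, event = 1L)
  G <- km_curve(sr$time_days, 1L - sr$event)
  s <- 100; t <- 300
  w <- ipcw_weights(s, t, sr[sr$time_days > s, ], G)
  at <- sr[sr$time_days > s, ]
  pi_half <- rep(0.5, nrow(at))
  expect_identical(auc_ipcw(s, t, pi_half, at, w), 0.5)
  expect_identical(brier_ipcw(s, t, pi_half, at, w), 0.25)
})

test_that("AUC is 1 under perfect separation and NA without cases or controls", {
  sr <- data.frame(time_days = c(150, 180, 500, 600), event = c(1, 1, 1, 1))
  G <- km_curve(sr$time_days, 1 - sr$event)
  w <- ipcw_weights(100, 300, sr, G)
  expect_equal(auc_ipcw(100, 300, c(0.9, 0.8, 0.2, 0.1), sr, w), 1)
  expect_equal(auc_ipcw(100, 300, c(0.1, 0.2, 0.8, 0.9), sr, w), 0)
  sr_none <- data.frame(time_days = c(500, 600), event = c(1, 1))
  G2 <- km_curve(sr_none$time_days, 1 - sr_none$event)
  w2 <- ipcw_weights(100, 300, sr_none, G2)
  expect_true(is.na(auc_ipcw(100, 300, c(0.5, 0.6), sr_none, w2)))
})

test_that("IPCW AUC and Brier match exhaustive enumeration on random small cohorts", {
  set.seed(62)
  for (rep in 1:60) {
    n <- sample(3:8, 1)
    T_obs <- round(rexp(n, 1 / 300) + 10)
    delta <- rbinom(n, 1, 0.7)
    pi_hat <- round(runif(n), 2)          # rounding forces occasional ties
    s <- 0; t <- sample(c(100, 250, 400), 1)
    at <- T_obs > s
    if (sum(at) < 2) next
    sr <- data.frame(time_days = T_obs[at], event = as.integer(delta[at]))
    G <- km_curve(sr$time_days, 1L - sr$event)
    w <- suppressMessages(ipcw_weights(s, t, sr, G))
    ref <- oracle_small_metrics(s, t, T_obs, delta, pi_hat)
    got_auc <- auc_ipcw(s, t, pi_hat[at], sr, w)
    if (!any(is.na(w))) {
      expect_equal(got_auc, ref$auc, tolerance = 1e-12)
      expect_equal(brier_ipcw(s, t, pi_hat[at], sr, w), ref$bs,
                   tolerance = 1e-12)
    }
  }
})

test_that("without censoring the estimators equal their complete-data versions", {
  set.seed(63)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    T_obs <- round(rexp(n, 1 / 300) + 10)
    pi_hat <- runif(n)
    s <- 20; t <- 250
    at <- T_obs > s
    if (sum(at) < 2) next
    sr <- data.frame(time_days = T_obs[at], event = 1L)
    G <- km_curve(sr$time_days, 1L - sr$event)
    w <- ipcw_weights(s, t, sr, G)
    case <- sr$time_days <= s + t
    if (!any(case) || all(case)) next
    # plain cumulative/dynamic AUC and mean squared error
    pairs <- outer(pi_hat[at][case], pi_hat[at][!case],
                   function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(auc_ipcw(s, t, pi_hat[at], sr, w), mean(pairs))
    expect_equal(brier_ipcw(s, t, pi_hat[at], sr, w),
                 mean((as.numeric(case) - pi_hat[at])^2))
  }
})

test_that("AUC is invariant under strictly monotone transforms of the predictions", {
  set.seed(64)
  sr <- data.frame(time_days = round(rexp(8, 1 / 300) + 10),
                   event = rbinom(8, 1, 0.8))
  G <- km_curve(sr$time_days, 1L - sr$event)
  pi_hat <- runif(8)
  w <- ipcw_weights(0, 250, sr, G)
  a1 <- auc_ipcw(0, 250, pi_hat, sr, w)
  a2 <- auc_ipcw(0, 250, qlogis(pi_hat / 2 + 0.25), sr, w)
  expect_equal(a1, a2)
})

test_that("Brier score is minimised over constants at the IPCW event proportion", {
  set.seed(65)
  sr <- data.frame(time_days = round(rexp(12, 1 / 300) + 10),
                   event = rbinom(12, 1, 0.8))
  sr <- sr[sr$time_days > 30, ]
  G <- km_curve(sr$time_days, 1L - sr$event)
  w <- ipcw_weights(30, 250, sr, G)
  cand <- seq(0, 1, by = 0.005)
  bs_c <- vapply(cand, function(p)
    brier_ipcw(30, 250, rep(p, nrow(sr)), sr, w), numeric(1))
  case <- sr$time_days > 30 & sr$time_days <= 280 & sr$event == 1
  p_star <- sum(w * case) / sum(w)
  expect_equal(cand[which.min(bs_c)], p_star, tolerance = 0.006)
})

test_that("scaled Brier score sign identities", {
  sr <- data.frame(time_days = c(100, 200, 400, 700), event = 1L)
  km_ref <- km_curve(sr$time_days, sr$event)
  G <- km_curve(sr$time_days, 1L - sr$event)
  s <- 50; t <- 300
  w <- ipcw_weights(s, t, sr, G)
  pi_km <- 1 - km_eval(km_ref, s + t) / km_eval(km_ref, s)
  bs_km <- brier_ipcw(s, t, rep(pi_km, 4), sr, w)
  expect_equal(scaled_brier(s, t, bs_km, km_ref, sr, w), 0)
  expect_equal(scaled_brier(s, t, 0, km_ref, sr, w), 1)
  expect_lt(scaled_brier(s, t, bs_km * 1.5, km_ref, sr, w), 0)
})

test_that("coverage evaluation: infinitely wide bands cover, wrong point bands do not", {
  pop <- ref_pop()
  psi <- ref_psi(pop)
  grid <- c(100, 200)
  wide <- data.frame(time_days = 300 + grid, median = 0, lo = -Inf, hi = Inf)
  rk_wide <- list(summary = data.frame(t_days = grid, pi_median = 0.5,
                                       pi_lo = 0, pi_hi = 1))
  cov1 <- coverage_eval(list(wide), list(rk_wide), list(psi), pop,
                        s = 300, grid = grid)
  expect_equal(cov1$cov_psa, c(1, 1))
  expect_equal(cov1$cov_risk, c(1, 1))
  wrong <- data.frame(time_days = 300 + grid, median = 99, lo = 99, hi = 99)
  rk_wrong <- list(summary = data.frame(t_days = grid, pi_median = 0.99,
                                        pi_lo = 0.99, pi_hi = 0.99))
  cov0 <- coverage_eval(list(wrong), list(rk_wrong), list(psi), pop,
                        s = 300, grid = grid)
  expect_equal(cov0$cov_psa, c(0, 0))
  expect_equal(cov0$cov_risk, c(0, 0))
})
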