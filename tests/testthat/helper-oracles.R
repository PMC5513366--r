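# Shared fixtures and independent oracles used across test files.

ref_pop <- function(...) pop_params(...)

ref_psi <- function(pop = ref_pop()) transform_to_natural(pop, rep(0, 4))

# Independent vectorised-over-particles evaluation of the biexponential
# curve, written directly from the closed form (no package code), used by
# the importance-sampling oracle.
oracle_psa_particles <- function(t, r, p0, eps, tesc, d = 0.046, delta = 0.23) {
  c1 <- r * (1 - eps) - d
  c2 <- r - d
  a1 <- delta * p0 / (c1 + delta)
  pre <- t <= tesc
  out <- a1 * exp(c1 * t) + (p0 - a1) * exp(-delta * t)
  if (any(!pre)) {
    pesc <- a1 * exp(c1 * tesc) + (p0 - a1) * exp(-delta * tesc)
    a2 <- delta * p0 / (c2 + delta)
    post <- a2 * exp(c2 * t - r * eps * tesc) +
      (pesc - a2 * exp(c1 * tesc)) * exp(-delta * (t - tesc))
    out[!pre] <- post[!pre]
  }
  out
}

# Importance sampling from the prior: posterior moments and an effective
# sample size, for a subject with observations (times, y) and landmark s.
# Everything is recomputed from scratch with plain vector arithmetic and a
# dense Simpson cumulative hazard, independent of the package's quadrature.
oracle_is_posterior <- function(times, y, s, pop, n_particles = 1e6,
                                seed = 424243) {
  set.seed(seed)
  om <- c(pop$omega_r, pop$omega_psa0, pop$omega_eps, pop$omega_tesc)
  eta <- matrix(rnorm(n_particles * 4), n_particles) *
    matrix(om, n_particles, 4, byrow = TRUE)
  r <- exp(log(pop$r_pop) + eta[, 1])
  p0 <- exp(log(pop$psa0_pop) + eta[, 2])
  eps <- plogis(qlogis(pop$eps_pop) + eta[, 3])
  te <- exp(log(pop$tesc_pop) + eta[, 4])
  ll <- 0
  for (j in seq_along(times))
    ll <- ll + dnorm(y[j],
                     log1p(oracle_psa_particles(times[j], r, p0, eps, te,
                                                pop$d_fixed,
                                                pop$delta_elim_fixed)),
                     pop$sigma, log = TRUE)
  if (s > 0) {
    ngrid <- 201L                       # Simpson rule on [0, s]
    u <- seq(0, s, length.out = ngrid)
    wS <- c(1, rep(c(4, 2), (ngrid - 3) / 2), 4, 1) * (u[2] - u[1]) / 3
    H <- 0
    for (q in 2:ngrid) {                # skip u=0 (baseline finite: k>1)
      h0 <- (pop$k_w / pop$lambda_w) * (u[q] / pop$lambda_w)^(pop$k_w - 1)
      f <- log1p(oracle_psa_particles(u[q], r, p0, eps, te,
                                      pop$d_fixed, pop$delta_elim_fixed))
      H <- H + wS[q] * h0 * exp(pop$beta_link * f)
    }
    ll <- ll - H
  }
  w <- exp(ll - max(ll))
  wn <- w / sum(w)
  est <- colSums(wn * eta)
  ess <- 1 / sum(wn^2)
  se <- sqrt(colSums(wn^2 * sweep(eta, 2, est)^2))
  list(mean = est, se = se, ess = ess, eta = eta, wn = wn)
}

# Exhaustive-enumeration IPCW AUC and Brier score for tiny cohorts,
# written straight from the published estimator definitions (explicit
# double loop, hand-rolled censoring Kaplan-Meier); the same
# administrative-boundary and left-continuity conventions as the package
# are part of the definition being checked.
oracle_small_metrics <- function(s, t, T_obs, delta, pi_hat) {
  at <- T_obs > s
  T_obs <- T_obs[at]; delta <- delta[at]; pi_hat <- pi_hat[at]
  n <- length(T_obs)
  # censoring KM, left-continuous evaluation
  G <- function(u, left = TRUE) {
    tt <- sort(unique(T_obs))
    surv <- 1
    for (v in tt) {
      if ((left && v >= u) || (!left && v > u)) break
      nrisk <- sum(T_obs >= v)
      ncens <- sum(T_obs == v & delta == 0)
      surv <- surv * (1 - ncens / nrisk)
    }
    surv
  }
  G_s <- G(s, left = FALSE)
  case <- T_obs > s & T_obs <= s + t & delta == 1
  ctrl <- T_obs > s + t | (T_obs == s + t & delta == 0)
  W <- numeric(n)
  W[ctrl] <- G_s / G(s + t)
  W[case] <- G_s / vapply(T_obs[case], G, numeric(1))
  num <- 0; den <- 0
  for (i in which(case)) for (j in which(ctrl)) {
    cmp <- if (pi_hat[i] > pi_hat[j]) 1 else if (pi_hat[i] == pi_hat[j]) 0.5 else 0
    num <- num + cmp * W[i] * W[j]
    den <- den + W[i] * W[j]
  }
  auc <- if (den > 0) num / den else NA_real_
  bs <- sum(W * (as.numeric(case) - pi_hat)^2) / n
  list(auc = auc, bs = bs)
}

# landmark container for hand-built subjects
toy_landmark <- function(times, y, s, id = 1L) {
  structure(list(subject_id = id, s = s, times = times, y = y),
            class = "psa_landmark")
}
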