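# Time-dependent predictive-accuracy metrics under right censoring.
#
# At landmark s and horizon t, cases are subjects dying in (s, s+t] and
# controls are subjects event-free beyond s+t (cumulative sensitivity /
# dynamic specificity). Censoring is handled by inverse probability of
# censoring weighting (IPCW) with the Kaplan-Meier estimator G of the
# censoring-time survival. Conventions fixed here:
#   - G is evaluated left-continuously (at u-), the convention of the
#     estimators this implements: a subject's own censoring event never
#     deflates its weight, and with purely administrative censoring at the
#     end of follow-up all weights inside the window are exactly 1.
#   - a subject censored at exactly s+t is a control: its status at s+t is
#     known (alive), which matters only when the horizon end coincides with
#     the administrative censoring date.
#   - tied predictions contribute 1/2 to the AUC numerator, so a constant
#     predictor scores exactly 0.5.

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator, as a step function that can be evaluated
#' right-continuously (the usual survival curve) or left-continuously (the
#' IPCW convention for censoring weights).
#'
#' @param times follow-up times (> 0).
#' @param events event indicators (1 = event). For a censoring-time curve
#'   pass \code{1 - delta}.
#' @return Object of class \code{"psa_km"}: sorted jump \code{times},
#'   post-jump \code{surv} values, and the input size \code{n}.
#' @examples
#' km <- km_curve(c(2, 3, 5, 7), c(1, 0, 1, 1))
#' km_eval(km, 5)   # 0.375
#' @export
km_curve <- function(times, events) {
  stopifnot(length(times) == length(events), all(times > 0))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(list(times = fit$time, surv = fit$surv, n = length(times)),
            class = "psa_km")
}

#' @rdname km_curve
#' @param km a \code{"psa_km"} curve.
#' @param u evaluation time(s).
#' @param left if TRUE evaluate the left-continuous version S(u-).
#' @export
km_eval <- function(km, u, left = FALSE) {
  vapply(u, function(ui) {
    idx <- if (left) which(km$times < ui) else which(km$times <= ui)
    if (length(idx) == 0L) 1 else km$surv[max(idx)]
  }, numeric(1))
}

# classify the at-risk subjects of one (s, t) window; times/events are the
# full survival table, already restricted to T > s by the caller
window_status <- function(T_obs, delta, s, t) {
  case <- T_obs > s & T_obs <= s + t & delta == 1L
  control <- T_obs > s + t | (T_obs == s + t & delta == 0L)
  list(case = case, control = control)
}

#' IPCW weights for one landmark/horizon window
#'
#' Weights for the at-risk subjects (follow-up beyond s): controls get
#' \code{1 / G((s+t)- | s)}, cases \code{1 / G(T- | s)}, subjects censored
#' inside the window get 0, with \code{G(u|s) = G(u)/G(s)} the conditional
#' censoring survival. Subjects whose required G value is 0 are excluded
#' (weight \code{NA}) with a message.
#'
#' @param s landmark (days); @param t horizon (days).
#' @param survival_records data.frame with \code{time_days} and \code{event}
#'   for the subjects at risk at s.
#' @param G_hat censoring Kaplan-Meier curve from \code{\link{km_curve}}
#'   (computed on the full cohort with indicator \code{1 - event}).
#' @return numeric weight vector aligned with \code{survival_records}.
#' @export
ipcw_weights <- function(s, t, survival_records, G_hat) {
  T_obs <- survival_records$time_days
  delta <- survival_records$event
  if (any(T_obs <= s)) stop("all subjects must be at risk at s", call. = FALSE)
  st <- window_status(T_obs, delta, s, t)
  G_s <- km_eval(G_hat, s, left = FALSE)
  w <- numeric(length(T_obs))
  if (any(st$control)) {
    G_end <- km_eval(G_hat, s + t, left = TRUE) / G_s
    w[st$control] <- if (G_end > 0) 1 / G_end else NA_real_
  }
  if (any(st$case)) {
    G_Ti <- km_eval(G_hat, T_obs[st$case], left = TRUE) / G_s
    w[st$case] <- ifelse(G_Ti > 0, 1 / G_Ti, NA_real_)
  }
  n_bad <- sum(is.na(w))
  if (n_bad > 0L)
    message(n_bad, " subject(s) dropped: censoring survival 0 at a required time")
  w
}

#' Time-dependent AUC with IPCW
#'
#' Weighted probability that a case (death in (s, s+t]) has a higher
#' predicted conditional death probability than a control (event-free
#' beyond s+t); tied predictions count 1/2.
#'
#' @param s,t landmark and horizon (days).
#' @param pi_hat point predictions (Monte Carlo medians of the conditional
#'   death probability) for the at-risk subjects.
#' @param survival_records survival table aligned with \code{pi_hat}.
#' @param weights IPCW weights from \code{\link{ipcw_weights}}.
#' @return AUC in [0, 1], or \code{NA} when there is no weighted case or no
#'   weighted control.
#' @export
auc_ipcw <- function(s, t, pi_hat, survival_records, weights) {
  st <- window_status(survival_records$time_days, survival_records$event, s, t)
  keep <- !is.na(weights)
  case <- st$case & keep
  ctrl <- st$control & keep
  if (!any(case) || !any(ctrl)) return(NA_real_)
  pc <- pi_hat[case]; wc <- weights[case]
  pk <- pi_hat[ctrl]; wk <- weights[ctrl]
  cmp <- outer(pc, pk, function(a, b) (a > b) + 0.5 * (a == b))
  ww <- outer(wc, wk)
  sum(cmp * ww) / sum(ww)
}

#' Time-dependent Brier score with IPCW
#'
#' Mean weighted squared difference between window death status and the
#' predicted conditional death probability; the denominator is the number
#' of subjects at risk at s, not the weight sum.
#'
#' @inheritParams auc_ipcw
#' @return Brier score (>= 0).
#' @export
brier_ipcw <- function(s, t, pi_hat, survival_records, weights) {
  st <- window_status(survival_records$time_days, survival_records$event, s, t)
  keep <- !is.na(weights)
  D <- as.numeric(st$case)
  sum(weights[keep] * (D[keep] - pi_hat[keep])^2) / nrow(survival_records)
}

#' Scaled Brier score
#'
#' Relative improvement of the model Brier score over the Brier score of
#' the marginal Kaplan-Meier prediction
#' \code{pi_KM(s+t|s) = 1 - S_KM(s+t)/S_KM(s)} from a reference cohort
#' (the evaluated cohort itself in the simulation experiments, a training
#' cohort for external data).
#'
#' @inheritParams auc_ipcw
#' @param bs model Brier score at (s, t).
#' @param km_ref reference event-time Kaplan-Meier curve
#'   (\code{\link{km_curve}} with the death indicator).
#' @return \code{(BS_KM - BS)/BS_KM}, at most 1; \code{NA} if BS_KM is 0.
#' @export
scaled_brier <- function(s, t, bs, km_ref, survival_records, weights) {
  S_s <- km_eval(km_ref, s)
  S_st <- km_eval(km_ref, s + t)
  if (S_s <= 0) return(NA_real_)
  pi_km <- 1 - S_st / S_s
  bs_km <- brier_ipcw(s, t, rep(pi_km, nrow(survival_records)),
                      survival_records, weights)
  if (bs_km == 0) return(NA_real_)
  (bs_km - bs) / bs_km
}

#' Coverage of the Monte Carlo 95% prediction intervals against truth
#'
#' For simulated cohorts only: per horizon, the proportion of at-risk
#' subjects whose true noise-free log(PSA+1) value and whose true
#' conditional death probability (both computed from the simulated
#' subject-level parameters) fall inside the corresponding 2.5--97.5%
#' Monte Carlo band, together with the exact binomial 95% envelope around
#' the nominal level given the number at risk.
#'
#' @param traj_bands list (one per at-risk subject) of
#'   \code{\link{predict_trajectory}} frames evaluated at \code{s + grid}.
#' @param risk_bands list (one per at-risk subject) of \code{"psa_risk"}
#'   summaries over \code{grid}.
#' @param truth_psi list of true natural-scale parameter sets, aligned.
#' @param pop population parameters.
#' @param s landmark (days).
#' @param grid horizon lengths (days).
#' @param nominal nominal coverage level (default 0.95).
#' @param n_nodes quadrature accuracy for the true conditional death
#'   probability (default 64: truth is computed more accurately than the
#'   8-node inference it judges).
#' @return data.frame with one row per horizon: \code{t_days},
#'   \code{cov_psa}, \code{cov_risk}, \code{n_at_risk}, \code{env_lo},
#'   \code{env_hi} (exact binomial envelope around \code{nominal}).
#' @export
coverage_eval <- function(traj_bands, risk_bands, truth_psi, pop, s, grid,
                          nominal = 0.95, n_nodes = 64L) {
  n <- length(truth_psi)
  stopifnot(length(traj_bands) == n, length(risk_bands) == n)
  in_psa <- matrix(FALSE, n, length(grid))
  in_risk <- matrix(FALSE, n, length(grid))
  for (i in seq_len(n)) {
    psi <- truth_psi[[i]]
    b_true <- log_psa(s + grid, psi, pop$d_fixed, pop$delta_elim_fixed)
    tb <- traj_bands[[i]]
    in_psa[i, ] <- b_true >= tb$lo & b_true <= tb$hi
    pi_true <- conditional_death_prob(s, grid, psi, pop, n_nodes)
    rb <- risk_bands[[i]]$summary
    in_risk[i, ] <- pi_true >= rb$pi_lo & pi_true <= rb$pi_hi
  }
  env <- stats::qbinom(c(0.025, 0.975), n, nominal) / n
  data.frame(t_days = grid,
             cov_psa = colMeans(in_psa),
             cov_risk = colMeans(in_risk),
             n_at_risk = n,
             env_lo = env[1L], env_hi = env[2L])
}
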