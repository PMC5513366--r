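# Individual dynamic prediction. Given PSA measurements of one subject up
# to a landmark time s (and the fact that the subject is alive at s), the
# random effects are sampled from their posterior
#   p(eta | X > s, Y(s)) ~ [prod_j p(y_j | eta)] * S(s | g(mu, eta)) * p(eta)
# with the population parameters treated as known. Each retained draw is
# mapped to natural-scale parameters, a predicted PSA curve and a
# conditional death probability; medians and 2.5/97.5% Monte Carlo
# percentiles give point predictions and 95% prediction intervals.
#
# The sampler is an adaptive random-walk Metropolis chain whose proposal
# covariance is tuned during warmup (Haario-style empirical covariance with
# a Robbins-Monro global-scale adaptation towards 30% acceptance). The
# sampler is a contract, not a fixture: any sampler reproducing the prior
# for a data-free subject and matching importance-sampling posterior means
# on toy subjects is admissible; the chain here passes both checks.

#' Assemble the data of one subject up to a landmark
#'
#' @param cohort a \code{"psa_cohort"} or a list with \code{longitudinal}
#'   (needs \code{subject_id}, \code{time_days}, \code{y}) and
#'   \code{survival} (needs \code{subject_id}, \code{time_days}) tables.
#' @param subject_id the subject.
#' @param s landmark time (days). The subject must still be at risk at s
#'   (follow-up time exceeds s); only measurements at or before s are kept,
#'   which may be none.
#' @return list of class \code{"psa_landmark"} with \code{subject_id},
#'   \code{s}, \code{times}, \code{y}.
#' @export
landmark_dataset <- function(cohort, subject_id, s) {
  surv <- cohort$survival
  row <- surv[surv$subject_id == subject_id, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown subject_id", call. = FALSE)
  if (row$time_days <= s && !(s == 0 && row$time_days > 0))
    stop("subject is not at risk at the landmark", call. = FALSE)
  long <- cohort$longitudinal
  rec <- long[long$subject_id == subject_id & long$time_days <= s, ,
              drop = FALSE]
  structure(list(subject_id = subject_id, s = s,
                 times = rec$time_days, y = rec$y),
            class = "psa_landmark")
}

#' Unnormalised posterior log-density of the random effects
#'
#' Sum of the Gaussian log-likelihood of the observed log(PSA+1) values,
#' the log survival probability to the landmark (8-node quadrature), and
#' the Gaussian prior of the random effects.
#'
#' @param eta numeric 4-vector of random effects.
#' @param landmark_data a \code{\link{landmark_dataset}}.
#' @param pop population parameters.
#' @param n_nodes quadrature nodes for the survival term.
#' @return log-density (unnormalised); \code{-Inf} for any draw whose
#'   intermediate quantities are not finite.
#' @export
posterior_log_density <- function(eta, landmark_data, pop, n_nodes = 8L) {
  f <- make_posterior_logdens(landmark_data, pop, n_nodes)
  f(eta)
}

# closure used in the sampling hot loop
make_posterior_logdens <- function(landmark_data, pop, n_nodes = 8L) {
  times <- landmark_data$times
  y <- landmark_data$y
  s <- landmark_data$s
  om <- omega_vec(pop)
  sigma <- pop$sigma
  d <- pop$d_fixed; delta <- pop$delta_elim_fixed
  has_obs <- length(times) > 0L
  function(eta) {
    if (!all(is.finite(eta))) return(-Inf)
    psi <- transform_to_natural(pop, eta)
    lp <- sum(stats::dnorm(eta, 0, om, log = TRUE))
    if (has_obs) {
      mu <- log1p(psa_value(times, psi, d, delta))
      lp <- lp + sum(stats::dnorm(y, mu, sigma, log = TRUE))
    }
    if (s > 0) lp <- lp - cumulative_hazard(s, psi, pop, n_nodes)
    if (!is.finite(lp)) return(-Inf)
    lp
  }
}

#' Sample random effects from their landmark posterior
#'
#' Adaptive random-walk Metropolis targeting the landmark posterior of the
#' random effects. Warmup iterations adapt the proposal (empirical
#' covariance plus a global scale tuned towards 30% acceptance) and are
#' discarded; the frozen chain is then thinned so that exactly \code{L}
#' draws are retained.
#'
#' @param landmark_data a \code{\link{landmark_dataset}}.
#' @param pop population parameters.
#' @param L number of retained Monte Carlo draws (default 200).
#' @param warmup warmup iterations (default 1000).
#' @param thin post-warmup thinning interval (default 15, at which the retained draws of the random-walk chain are nearly independent).
#' @param seed optional integer seed; fixing it makes the draw matrix
#'   reproducible.
#' @param n_nodes quadrature nodes for the survival term.
#' @return Object of class \code{"psa_posterior"}: \code{s}, \code{draws}
#'   (L x 4 matrix), \code{accept_rate}, \code{flagged} (TRUE when the
#'   post-warmup acceptance rate leaves the 5--60% band, with a warning).
#' @export
sample_posterior <- function(landmark_data, pop, L = 200L, warmup = 1000L,
                             thin = 15L, seed = NULL, n_nodes = 8L) {
  stopifnot(L >= 1L, warmup >= 0L, thin >= 1L)
  if (!is.null(seed)) set.seed(seed)
  logdens <- make_posterior_logdens(landmark_data, pop, n_nodes)
  om <- omega_vec(pop)

  eta <- rep(0, 4)
  lp <- logdens(eta)
  # proposal state: Cholesky of the covariance, global log-scale
  chol_prop <- diag(0.5 * om)
  log_scale <- 0
  m_run <- rep(0, 4); c_run <- diag(om^2); n_run <- 0
  target_acc <- 0.3

  n_keep <- 0L
  draws <- matrix(NA_real_, nrow = L, ncol = 4L,
                  dimnames = list(NULL, c("eta_r", "eta_psa0", "eta_eps",
                                          "eta_tesc")))
  acc_post <- 0L
  total <- warmup + L * thin
  for (it in seq_len(total)) {
    prop <- eta + exp(log_scale) * drop(stats::rnorm(4) %*% chol_prop)
    lp_prop <- logdens(prop)
    if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
      eta <- prop; lp <- lp_prop
      accepted <- TRUE
    } else accepted <- FALSE

    if (it <= warmup) {
      # Robbins-Monro on the global scale
      log_scale <- log_scale + (as.numeric(accepted) - target_acc) / it^0.6
      # running covariance for the proposal shape
      n_run <- n_run + 1
      dlt <- eta - m_run
      m_run <- m_run + dlt / n_run
      c_run <- c_run * (n_run - 1) / n_run + tcrossprod(dlt, eta - m_run) / n_run
      if (it >= 100L && it %% 25L == 0L) {
        sig <- (2.38^2 / 4) * (c_run + diag(1e-10, 4))
        ch <- tryCatch(chol(sig), error = function(e) NULL)
        if (!is.null(ch)) chol_prop <- ch
      }
    } else {
      if (accepted) acc_post <- acc_post + 1L
      k <- it - warmup
      if (k %% thin == 0L) {
        n_keep <- n_keep + 1L
        draws[n_keep, ] <- eta
      }
    }
  }
  acc_rate <- acc_post / (L * thin)
  flagged <- acc_rate < 0.05 || acc_rate > 0.60
  if (flagged)
    warning(sprintf("post-warmup acceptance rate %.2f outside [0.05, 0.60]; treat draws with caution",
                    acc_rate), call. = FALSE)
  structure(list(s = landmark_data$s, subject_id = landmark_data$subject_id,
                 draws = draws, accept_rate = acc_rate, flagged = flagged,
                 L = L, warmup = warmup, thin = thin),
            class = "psa_posterior")
}

#' @export
print.psa_posterior <- function(x, ...) {
  cat(sprintf("Posterior draws: subject %s, landmark %.0f d, L=%d, acceptance %.2f%s\n",
              format(x$subject_id), x$s, nrow(x$draws), x$accept_rate,
              if (isTRUE(x$flagged)) " [flagged]" else ""))
  invisible(x)
}

#' Monte Carlo prediction of the PSA trajectory
#'
#' Maps each posterior draw to its noise-free log(PSA+1) curve and returns
#' the pointwise median and the 2.5/97.5% percentiles.
#'
#' @param draws a \code{"psa_posterior"} (or bare L x 4 matrix).
#' @param pop population parameters.
#' @param grid evaluation times (days, >= 0).
#' @return data.frame \code{time_days}, \code{median}, \code{lo}, \code{hi}
#'   on the log(PSA+1) scale.
#' @export
predict_trajectory <- function(draws, pop, grid) {
  eta_mat <- if (inherits(draws, "psa_posterior")) draws$draws else draws
  curves <- t(apply(eta_mat, 1L, function(eta) {
    log_psa(grid, transform_to_natural(pop, eta),
            pop$d_fixed, pop$delta_elim_fixed)
  }))
  if (length(grid) == 1L) curves <- matrix(curves, ncol = 1L)
  qs <- apply(curves, 2L, stats::quantile, probs = c(0.5, 0.025, 0.975),
              names = FALSE)
  data.frame(time_days = grid, median = qs[1L, ], lo = qs[2L, ], hi = qs[3L, ])
}

#' Monte Carlo prediction of the conditional death probability
#'
#' For every posterior draw, the probability of death in \code{(s, s+t]}
#' given survival to the landmark \code{s} is computed over the horizon
#' grid; the point prediction is the Monte Carlo median and the bands are
#' the 2.5/97.5% percentiles. Draws whose survival at the landmark
#' underflows to zero are dropped (their count is reported).
#'
#' @param draws a \code{"psa_posterior"} (or bare L x 4 matrix).
#' @param pop population parameters.
#' @param s landmark time (days).
#' @param grid horizon lengths t (days, > 0).
#' @param n_nodes quadrature node count.
#' @return list of class \code{"psa_risk"}: \code{summary} (data.frame
#'   \code{t_days}, \code{pi_median}, \code{pi_lo}, \code{pi_hi}),
#'   \code{pi_draws} (retained draws x horizons matrix), \code{n_dropped}.
#' @export
predict_risk <- function(draws, pop, s, grid, n_nodes = 8L) {
  eta_mat <- if (inherits(draws, "psa_posterior")) draws$draws else draws
  L <- nrow(eta_mat)
  pi_mat <- matrix(NA_real_, nrow = L, ncol = length(grid))
  ok <- logical(L)
  for (l in seq_len(L)) {
    psi <- transform_to_natural(pop, eta_mat[l, ])
    pl <- tryCatch(conditional_death_prob(s, grid, psi, pop, n_nodes),
                   error = function(e) NULL)
    if (!is.null(pl)) { pi_mat[l, ] <- pl; ok[l] <- TRUE }
  }
  n_dropped <- sum(!ok)
  if (n_dropped > 0L)
    message(n_dropped, " degenerate draw(s) with zero landmark survival dropped")
  pi_mat <- pi_mat[ok, , drop = FALSE]
  if (nrow(pi_mat) == 0L) stop("no usable posterior draws", call. = FALSE)
  qs <- apply(pi_mat, 2L, stats::quantile, probs = c(0.5, 0.025, 0.975),
              names = FALSE)
  structure(list(summary = data.frame(t_days = grid, pi_median = qs[1L, ],
                                      pi_lo = qs[2L, ], pi_hi = qs[3L, ]),
                 pi_draws = pi_mat, s = s, n_dropped = n_dropped),
            class = "psa_risk")
}
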