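# Cohort simulator: the study-design engine of the simulation experiments.
# PSA is sampled every 3 weeks from treatment start until death or 30
# months, whichever comes first; death times are drawn by inverting the
# subject-specific survival function (64-node quadrature, so the simulated
# truth is more accurate than the 8-node inference machinery it is used to
# test); censoring is administrative only, at the end of follow-up.

#' Simulation design
#'
#' @param n_subjects number of subjects to simulate.
#' @param visit_interval days between scheduled PSA measurements (default 21,
#'   i.e. every 3 weeks).
#' @param max_followup length of follow-up in days (default 913, i.e. 30
#'   months at 30.4375 days/month rounded to whole days).
#' @param admin_censor administrative censoring time (days); defaults to the
#'   end of follow-up. Death is the only other exit: no dropout mechanism is
#'   simulated.
#' @param seed integer seed making the cohort reproducible.
#' @return A validated list of class \code{"psa_design"}.
#' @export
design_spec <- function(n_subjects, visit_interval = 21, max_followup = 913,
                        admin_censor = max_followup, seed = 1L) {
  stopifnot(n_subjects >= 1, visit_interval > 0, max_followup > 0,
            admin_censor > 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 visit_interval = visit_interval,
                 max_followup = max_followup,
                 admin_censor = admin_censor,
                 seed = as.integer(seed)),
            class = "psa_design")
}

#' Draw random effects from the population distribution
#'
#' @param pop population parameters.
#' @param n number of subjects.
#' @param seed optional integer seed.
#' @return An \code{n x 4} matrix of independent Gaussian random effects with
#'   mean zero and the diagonal covariance implied by the omegas.
#' @export
draw_random_effects <- function(pop, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  om <- omega_vec(pop)
  eta <- matrix(stats::rnorm(n * 4L), nrow = n) *
    matrix(om, nrow = n, ncol = 4L, byrow = TRUE)
  colnames(eta) <- c("eta_r", "eta_psa0", "eta_eps", "eta_tesc")
  eta
}

#' Simulate a death time by inverting the survival function
#'
#' Solves \code{survival_prob(X) = u} for a uniform deviate \code{u} by
#' bracketed root finding on the high-accuracy (64-node) cumulative hazard,
#' to within 1e-6 in survival probability.
#'
#' @param psi natural-scale kinetic parameters.
#' @param pop population parameters.
#' @param u uniform deviate in (0, 1).
#' @param n_nodes quadrature accuracy used for the truth (default 64).
#' @param max_time search bound in days; if survival at the bound still
#'   exceeds \code{u} the subject outlives the bound and \code{Inf} is
#'   returned (censored downstream).
#' @return death time in days, or \code{Inf}.
#' @export
simulate_event_time <- function(psi, pop, u, n_nodes = 64L, max_time = 1e5) {
  stopifnot(u > 0, u < 1)
  target <- -log(u)                       # solve H(X) = -log(u)
  if (cumulative_hazard(max_time, psi, pop, n_nodes) < target) return(Inf)
  f <- function(x) cumulative_hazard(x, psi, pop, n_nodes) - target
  stats::uniroot(f, lower = 1e-8, upper = max_time, tol = 1e-9)$root
}

#' Simulate the PSA measurement series of one subject
#'
#' Visits every \code{visit_interval} days from baseline (t = 0, always
#' measured) until death or the end of follow-up; a measurement cannot
#' postdate death. Observations are the noise-free log(PSA+1) curve plus
#' Gaussian error with SD \code{pop$sigma}.
#'
#' @param psi natural-scale kinetic parameters.
#' @param pop population parameters.
#' @param design a \code{\link{design_spec}}.
#' @param x_true the subject's (possibly unobserved) death time in days.
#' @return data.frame with columns \code{time_days} and \code{y}
#'   (observed log(PSA+1)).
#' @export
simulate_longitudinal <- function(psi, pop, design, x_true = Inf) {
  t_end <- min(x_true, design$max_followup)
  times <- seq(0, t_end, by = design$visit_interval)
  mu <- log_psa(times, psi, pop$d_fixed, pop$delta_elim_fixed)
  y <- mu + stats::rnorm(length(times), 0, pop$sigma)
  data.frame(time_days = times, y = y)
}

#' Simulate a full cohort from the joint model
#'
#' Draws random effects, death times and PSA series for every subject.
#' Observable tables (longitudinal and survival) carry nothing derived from
#' the simulation truth; the truth block (random effects, natural-scale
#' parameters and uncensored death times) is kept in a separate element so
#' that prediction code can be run on the observables alone while coverage
#' evaluation retains access to the truth.
#'
#' @param pop population parameters.
#' @param design a \code{\link{design_spec}}; its \code{seed} fixes the
#'   whole cohort.
#' @return An object of class \code{"psa_cohort"}: list with
#'   \describe{
#'     \item{longitudinal}{data.frame \code{subject_id}, \code{time_days},
#'       \code{psa_ng_ml}, \code{y} (= log(PSA+1) as observed)}
#'     \item{survival}{data.frame \code{subject_id}, \code{time_days}
#'       (min of death and censoring), \code{event} (1 = death observed)}
#'     \item{truth}{data.frame \code{subject_id}, \code{r}, \code{psa0},
#'       \code{eps}, \code{tesc}, \code{x_true_days} and the four random
#'       effects}
#'   }
#' @examples
#' coh <- simulate_cohort(pop_params(), design_spec(5, seed = 42))
#' table(coh$survival$event)
#' @export
simulate_cohort <- function(pop, design) {
  set.seed(design$seed)
  n <- design$n_subjects
  eta <- draw_random_effects(pop, n)
  u <- stats::runif(n)
  long_list <- vector("list", n)
  surv <- data.frame(subject_id = seq_len(n), time_days = NA_real_,
                     event = NA_integer_)
  truth <- data.frame(subject_id = seq_len(n), r = NA_real_, psa0 = NA_real_,
                      eps = NA_real_, tesc = NA_real_, x_true_days = NA_real_)
  for (i in seq_len(n)) {
    psi <- transform_to_natural(pop, eta[i, ])
    x_true <- simulate_event_time(psi, pop, u[i])
    rec <- simulate_longitudinal(psi, pop, design, x_true)
    long_list[[i]] <- data.frame(subject_id = i, rec)
    surv$time_days[i] <- min(x_true, design$admin_censor)
    surv$event[i] <- as.integer(x_true <= design$admin_censor)
    truth[i, c("r", "psa0", "eps", "tesc")] <- unlist(psi)
    truth$x_true_days[i] <- x_true
  }
  long <- do.call(rbind, long_list)
  long$psa_ng_ml <- expm1(long$y)
  long <- long[, c("subject_id", "time_days", "psa_ng_ml", "y")]
  truth <- cbind(truth, as.data.frame(eta))
  structure(list(longitudinal = long, survival = surv, truth = truth,
                 pop = pop, design = design),
            class = "psa_cohort")
}

#' @export
print.psa_cohort <- function(x, ...) {
  cat(sprintf("Simulated mCRPC cohort: %d subjects, %d PSA measurements, %d deaths\n",
              nrow(x$survival), nrow(x$longitudinal), sum(x$survival$event)))
  invisible(x)
}
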