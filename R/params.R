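#' Population parameters of the PSA-survival joint model
#'
#' Container for the fixed effects of the biexponential PSA model, the
#' standard deviations of the subject-level random effects, the residual
#' error on the log(PSA+1) scale, the Weibull baseline hazard and the
#' PSA-hazard link. Defaults are the reference estimates of the
#' current-PSA joint model fitted to a 400-patient mCRPC training cohort;
#' the tumour-cell elimination rate \code{d} and the blood PSA elimination
#' rate \code{delta_elim} are fixed constants (half-lives of 15 and about
#' 3 days respectively), never estimated.
#'
#' @param r_pop population proliferation rate of prostatic cells (day^-1).
#' @param psa0_pop population PSA level at treatment initiation (ng/mL).
#' @param eps_pop population treatment effectiveness, in (0, 1).
#' @param tesc_pop population escape time (days): time at which treatment
#'   loses its effect and PSA regrowth resumes.
#' @param d_fixed elimination rate of prostatic cells (day^-1), fixed.
#' @param delta_elim_fixed elimination rate of PSA from blood (day^-1), fixed.
#' @param omega_r,omega_psa0,omega_eps,omega_tesc standard deviations of the
#'   random effects on the transformed (log or logit) scale.
#' @param sigma residual standard deviation of observed log(PSA+1).
#' @param lambda_w Weibull baseline scale (days).
#' @param k_w Weibull baseline shape (unitless).
#' @param beta_link coefficient linking the PSA feature to the log hazard.
#' @param link_type one of \code{"none"}, \code{"current"}, \code{"slope"},
#'   \code{"auc"}: the feature of the true log(PSA+1) trajectory that enters
#'   the hazard multiplicatively through \code{exp(beta_link * f(t))}.
#'
#' @return An object of class \code{"psa_pop"} (a validated list).
#' @examples
#' pop <- pop_params()                  # reference current-PSA model
#' pop_null <- pop_params(link_type = "none", lambda_w = 885, k_w = 1.52)
#' @export
pop_params <- function(r_pop = 0.054, psa0_pop = 73.9, eps_pop = 0.34,
                       tesc_pop = 138,
                       d_fixed = 0.046, delta_elim_fixed = 0.23,
                       omega_r = 0.098, omega_psa0 = 1.57,
                       omega_eps = 1.34, omega_tesc = 0.64,
                       sigma = 0.38,
                       lambda_w = 3800, k_w = 1.19,
                       beta_link = 0.32, link_type = "current") {
  pop <- list(r_pop = r_pop, psa0_pop = psa0_pop, eps_pop = eps_pop,
              tesc_pop = tesc_pop, d_fixed = d_fixed,
              delta_elim_fixed = delta_elim_fixed,
              omega_r = omega_r, omega_psa0 = omega_psa0,
              omega_eps = omega_eps, omega_tesc = omega_tesc,
              sigma = sigma, lambda_w = lambda_w, k_w = k_w,
              beta_link = beta_link, link_type = link_type)
  validate_pop(pop)
  class(pop) <- "psa_pop"
  pop
}

validate_pop <- function(pop) {
  pos <- c("r_pop", "psa0_pop", "tesc_pop", "omega_r", "omega_psa0",
           "omega_eps", "omega_tesc", "sigma", "lambda_w", "k_w")
  for (nm in pos) {
    v <- pop[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single strictly positive number", nm),
           call. = FALSE)
  }
  # omegas of zero are useful for degenerate tests; allow >= 0 there instead
  if (!is.numeric(pop$eps_pop) || pop$eps_pop <= 0 || pop$eps_pop >= 1)
    stop("'eps_pop' must lie in the open interval (0, 1)", call. = FALSE)
  for (nm in c("d_fixed", "delta_elim_fixed", "beta_link")) {
    v <- pop[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
  }
  if (!pop$link_type %in% c("none", "current", "slope", "auc"))
    stop("'link_type' must be one of \"none\", \"current\", \"slope\", \"auc\"",
         call. = FALSE)
  invisible(pop)
}

#' @export
print.psa_pop <- function(x, ...) {
  cat("PSA-survival joint model population parameters\n")
  cat(sprintf("  kinetics: r=%.4g /day, PSA0=%.4g ng/mL, eps=%.3g, Tesc=%.4g d\n",
              x$r_pop, x$psa0_pop, x$eps_pop, x$tesc_pop))
  cat(sprintf("  fixed:    d=%.3g /day, delta=%.3g /day\n",
              x$d_fixed, x$delta_elim_fixed))
  cat(sprintf("  omegas:   (%.3g, %.3g, %.3g, %.3g); sigma=%.3g\n",
              x$omega_r, x$omega_psa0, x$omega_eps, x$omega_tesc, x$sigma))
  cat(sprintf("  survival: Weibull(lambda=%.4g d, k=%.3g), link=%s, beta=%.4g\n",
              x$lambda_w, x$k_w, x$link_type, x$beta_link))
  invisible(x)
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Map random effects to subject-level kinetic parameters
#'
#' The transformation g: the proliferation rate, baseline PSA and escape
#' time are log-normal around their population values, the treatment
#' effectiveness is logit-normal, so any real 4-vector of random effects
#' maps to a valid parameter set.
#'
#' @param pop a \code{\link{pop_params}} object.
#' @param eta numeric 4-vector of random effects
#'   \code{(eta_r, eta_psa0, eta_eps, eta_tesc)} on the transformed scale.
#' @return A list of class \code{"psa_psi"} with elements \code{r},
#'   \code{psa0}, \code{eps}, \code{tesc} on the natural scale.
#' @examples
#' transform_to_natural(pop_params(), c(0, 0, 0, 0))
#' @export
transform_to_natural <- function(pop, eta) {
  stopifnot(length(eta) == 4L)
  if (!all(is.finite(eta))) stop("random effects must be finite", call. = FALSE)
  psi <- list(r    = exp(log(pop$r_pop) + eta[[1L]]),
              psa0 = exp(log(pop$psa0_pop) + eta[[2L]]),
              eps  = inv_logit(logit(pop$eps_pop) + eta[[3L]]),
              tesc = exp(log(pop$tesc_pop) + eta[[4L]]))
  class(psi) <- "psa_psi"
  psi
}

#' Recover random effects from natural-scale parameters
#'
#' Inverse of \code{\link{transform_to_natural}}.
#'
#' @inheritParams transform_to_natural
#' @param psi a natural-scale parameter list with \code{r}, \code{psa0},
#'   \code{eps}, \code{tesc}.
#' @return numeric 4-vector of random effects.
#' @export
transform_to_eta <- function(pop, psi) {
  c(log(psi$r) - log(pop$r_pop),
    log(psi$psa0) - log(pop$psa0_pop),
    logit(psi$eps) - logit(pop$eps_pop),
    log(psi$tesc) - log(pop$tesc_pop))
}

omega_vec <- function(pop) {
  c(pop$omega_r, pop$omega_psa0, pop$omega_eps, pop$omega_tesc)
}
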