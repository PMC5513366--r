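# Biexponential PSA kinetics under chemotherapy with treatment escape.
#
# Before the escape time tesc, prostatic-cell proliferation is inhibited
# by a factor (1 - eps); after tesc the drug no longer acts and growth
# resumes at full rate r. PSA is produced by the cells and eliminated from
# blood at rate delta, giving a piecewise sum of two exponentials in each
# regime. Rate shorthand used below:
#   c1 = r(1 - eps) - d   (net cell growth on treatment)
#   c2 = r - d            (net cell growth after escape)
# Denominators c1 + delta and c2 + delta can vanish for extreme random
# effects; the removable singularity is evaluated by its analytic limit
# (a term of the form delta * PSA0 * t * exp(-delta t)).

.SING_GUARD <- 1e-10

#' True PSA concentration at time t
#'
#' Closed-form biexponential PSA trajectory: decline under treatment up to
#' the escape time, regrowth afterwards, continuous at the kink.
#'
#' @param t time(s) since treatment initiation (days), vectorised.
#' @param psi natural-scale kinetic parameters (see
#'   \code{\link{transform_to_natural}}).
#' @param d prostatic-cell elimination rate (day^-1).
#' @param delta blood PSA elimination rate (day^-1).
#' @return PSA concentration (ng/mL), strictly positive, same length as
#'   \code{t}; \code{psa_value(0, psi) == psi$psa0} exactly.
#' @examples
#' psi <- transform_to_natural(pop_params(), c(0, 0, 0, 0))
#' psa_value(c(0, 21, 138, 300), psi)
#' @export
psa_value <- function(t, psi, d = 0.046, delta = 0.23) {
  if (any(t < 0)) stop("'t' must be nonnegative", call. = FALSE)
  r <- psi$r; psa0 <- psi$psa0; eps <- psi$eps; tesc <- psi$tesc
  c1 <- r * (1 - eps) - d
  c2 <- r - d
  out <- numeric(length(t))

  pre <- t <= tesc
  if (any(pre)) out[pre] <- .psa_branch(t[pre], psa0, c1, delta)
  if (any(!pre)) {
    tp <- t[!pre]
    p_esc <- .psa_branch(tesc, psa0, c1, delta)
    den2 <- c2 + delta
    if (abs(den2) >= .SING_GUARD) {
      a2 <- delta * psa0 / den2
      # growth term exponent c2*t - r*eps*tesc equals c1*tesc at t = tesc
      out[!pre] <- a2 * exp(c2 * tp - r * eps * tesc) +
        (p_esc - a2 * exp(c1 * tesc)) * exp(-delta * (tp - tesc))
    } else {
      # c2 -> -delta: limit delta*PSA0*(t - tesc)*exp(-delta t - r eps tesc)
      out[!pre] <- delta * psa0 * (tp - tesc) * exp(-delta * tp - r * eps * tesc) +
        p_esc * exp(-delta * (tp - tesc))
    }
  }
  out
}

# on-treatment branch (also used for the value at tesc)
.psa_branch <- function(t, psa0, c1, delta) {
  den <- c1 + delta
  if (abs(den) >= .SING_GUARD) {
    a1 <- delta * psa0 / den
    a1 * exp(c1 * t) + (psa0 - a1) * exp(-delta * t)
  } else {
    delta * psa0 * t * exp(-delta * t) + psa0 * exp(-delta * t)
  }
}

#' @rdname psa_value
#' @details \code{psa_deriv} returns the time derivative of the PSA
#'   trajectory (ng/mL/day); at the escape-time kink the left derivative
#'   is used.
#' @export
psa_deriv <- function(t, psi, d = 0.046, delta = 0.23) {
  if (any(t < 0)) stop("'t' must be nonnegative", call. = FALSE)
  r <- psi$r; psa0 <- psi$psa0; eps <- psi$eps; tesc <- psi$tesc
  c1 <- r * (1 - eps) - d
  c2 <- r - d
  out <- numeric(length(t))

  pre <- t <= tesc
  if (any(pre)) {
    tt <- t[pre]
    den <- c1 + delta
    if (abs(den) >= .SING_GUARD) {
      a1 <- delta * psa0 / den
      out[pre] <- a1 * c1 * exp(c1 * tt) - delta * (psa0 - a1) * exp(-delta * tt)
    } else {
      out[pre] <- -delta^2 * psa0 * tt * exp(-delta * tt)
    }
  }
  if (any(!pre)) {
    tp <- t[!pre]
    p_esc <- .psa_branch(tesc, psa0, c1, delta)
    den2 <- c2 + delta
    if (abs(den2) >= .SING_GUARD) {
      a2 <- delta * psa0 / den2
      out[!pre] <- a2 * c2 * exp(c2 * tp - r * eps * tesc) -
        delta * (p_esc - a2 * exp(c1 * tesc)) * exp(-delta * (tp - tesc))
    } else {
      out[!pre] <- delta * psa0 * exp(-delta * tp - r * eps * tesc) *
        (1 - delta * (tp - tesc)) -
        delta * p_esc * exp(-delta * (tp - tesc))
    }
  }
  out
}

#' Log-scale PSA observation mean and hazard-link features
#'
#' The observation model measures \code{y = log(PSA + 1)} with additive
#' Gaussian error; \code{log_psa} is its noise-free mean. \code{log_psa_slope}
#' is the time derivative of that curve and \code{log_psa_area} its running
#' integral; each is a candidate feature linking the PSA kinetics to the
#' hazard of death.
#'
#' @inheritParams psa_value
#' @return \code{log_psa}: unitless log-scale values; \code{log_psa_slope}:
#'   day^-1; \code{log_psa_area}: days (integral of a unitless curve).
#' @export
log_psa <- function(t, psi, d = 0.046, delta = 0.23) {
  log1p(psa_value(t, psi, d, delta))
}

#' @rdname log_psa
#' @export
log_psa_slope <- function(t, psi, d = 0.046, delta = 0.23) {
  psa_deriv(t, psi, d, delta) / (psa_value(t, psi, d, delta) + 1)
}

#' @rdname log_psa
#' @param n_nodes number of Gauss-Legendre nodes per integration panel;
#'   panels are split at the escape time so the kink is never spanned.
#' @export
log_psa_area <- function(t, psi, d = 0.046, delta = 0.23, n_nodes = 16L) {
  vapply(t, function(ti) {
    if (ti == 0) return(0)
    if (ti <= psi$tesc) {
      gl_integrate(function(u) log1p(psa_value(u, psi, d, delta)), 0, ti, n_nodes)
    } else {
      gl_integrate(function(u) log1p(psa_value(u, psi, d, delta)), 0, psi$tesc,
                   n_nodes) +
        gl_integrate(function(u) log1p(psa_value(u, psi, d, delta)), psi$tesc,
                     ti, n_nodes)
    }
  }, numeric(1))
}
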