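# Configuration, CSV I/O and the simulate -> predict -> evaluate pipeline.
# All files and all internal computation use days; months exist only at
# the user surface and convert at 30.4375 days per month (365.25/12),
# rounded to whole days when laying out landmark/horizon grids.

#' Convert months to days
#'
#' @param m months.
#' @param round round to whole days (used for landmark/horizon grids so
#'   that grid ends line up with the administrative censoring date).
#' @return days at 30.4375 days/month.
#' @export
months_to_days <- function(m, round = FALSE) {
  d <- m * 365.25 / 12
  if (round) round(d) else d
}

#' Write / read a cohort as plain CSV
#'
#' \code{write_cohort} writes \code{longitudinal.csv} (subject_id,
#' time_days, psa_ng_ml), \code{survival.csv} (subject_id, time_days,
#' event) and, when the cohort carries simulation truth,
#' \code{truth.csv}. \code{read_cohort} reads them back, recomputing the
#' observation-scale column \code{y = log(PSA + 1)}; the truth file is
#' only read when \code{with_truth = TRUE}, so evaluation code must opt
#' in explicitly.
#'
#' @param cohort a \code{"psa_cohort"} or compatible list.
#' @param dir directory for the CSV files.
#' @return \code{read_cohort}: a list of class \code{"psa_cohort"}.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  long <- cohort$longitudinal[, c("subject_id", "time_days", "psa_ng_ml")]
  utils::write.csv(long, file.path(dir, "longitudinal.csv"), row.names = FALSE)
  utils::write.csv(cohort$survival, file.path(dir, "survival.csv"),
                   row.names = FALSE)
  if (!is.null(cohort$truth))
    utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @param dir directory containing the CSV files.
#' @param with_truth also load \code{truth.csv} if present.
#' @export
read_cohort <- function(dir, with_truth = FALSE) {
  long <- utils::read.csv(file.path(dir, "longitudinal.csv"))
  surv <- utils::read.csv(file.path(dir, "survival.csv"))
  for (col in c("subject_id", "time_days", "psa_ng_ml"))
    if (!col %in% names(long))
      stop("longitudinal.csv lacks column '", col, "'", call. = FALSE)
  for (col in c("subject_id", "time_days", "event"))
    if (!col %in% names(surv))
      stop("survival.csv lacks column '", col, "'", call. = FALSE)
  bad <- which(!is.finite(long$time_days) | long$time_days < 0)
  if (length(bad))
    stop("longitudinal.csv: invalid time at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(long$psa_ng_ml) | long$psa_ng_ml <= -1)
  if (length(bad))
    stop("longitudinal.csv: invalid PSA at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  if (any(surv$time_days <= 0) || !all(surv$event %in% c(0, 1)))
    stop("survival.csv: times must be positive and event in {0,1}",
         call. = FALSE)
  orphan <- setdiff(unique(long$subject_id), surv$subject_id)
  if (length(orphan))
    stop("subject(s) in longitudinal.csv missing from survival.csv: ",
         paste(utils::head(orphan, 5L), collapse = ", "), call. = FALSE)
  long$y <- log1p(long$psa_ng_ml)
  out <- list(longitudinal = long, survival = surv)
  if (with_truth && file.exists(file.path(dir, "truth.csv")))
    out$truth <- utils::read.csv(file.path(dir, "truth.csv"))
  structure(out, class = "psa_cohort")
}

.config_defaults <- function() {
  list(
    population = as.list(formals(pop_params)),
    design = list(n_subjects = 200L, visit_interval = 21, max_followup = 913,
                  admin_censor = 913),
    landmarks_months = c(0, 6, 12, 18),
    horizons_months = seq(2, 18, by = 0.5),
    L = 200L, warmup = 1000L, thin = 15L,
    seed = 1L
  )
}

#' Load and validate an experiment configuration
#'
#' YAML (or JSON) configuration with blocks \code{population},
#' \code{design} and top-level keys \code{landmarks_months},
#' \code{horizons_months}, \code{L}, \code{warmup}, \code{thin},
#' \code{seed}. Missing keys take the documented defaults (the reference
#' current-PSA model and the 200-subject, 30-month design); unknown keys
#' are rejected by name.
#'
#' @param path path to the configuration file; an empty or absent block
#'   means "all defaults".
#' @return Validated config list of class \code{"psa_config"}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  as_psa_config(raw)
}

#' @rdname load_config
#' @param x a named list with the same structure as the file contents.
#' @export
as_psa_config <- function(x = list()) {
  def <- .config_defaults()
  unknown <- setdiff(names(x), names(def))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(def, x)
  for (blk in c("population", "design")) {
    extra <- setdiff(names(cfg[[blk]]), names(def[[blk]]))
    if (length(extra))
      stop("unknown key(s) in '", blk, "': ", paste(extra, collapse = ", "),
           call. = FALSE)
  }
  cfg$pop <- do.call(pop_params, cfg$population)       # validates fields
  cfg$population <- cfg$pop[names(.config_defaults()$population)]
  class(cfg) <- "psa_config"
  cfg
}

# deterministic per-subject, per-landmark stream below 2^31
.subject_seed <- function(base, s_idx, subject_id) {
  as.integer((base + 7919 * s_idx + subject_id) %% 2147483647L)
}

#' Run the full simulation experiment
#'
#' Simulates a cohort from the configured joint model, then for every
#' landmark draws the posterior of each at-risk subject's random effects,
#' predicts the conditional death probability over the horizon grid and
#' the PSA trajectory at the corresponding calendar times, and evaluates
#' time-dependent AUC, Brier score, scaled Brier score (reference: the
#' cohort's own Kaplan-Meier curve) and, from the retained simulation
#' truth, the coverage of the 95% prediction intervals. Horizons that
#' would extend past the administrative censoring date are skipped for
#' the metrics (no observable controls exist there).
#'
#' @param config a \code{"psa_config"} (see \code{\link{load_config}} /
#'   \code{\link{as_psa_config}}).
#' @param progress print one line per landmark.
#' @return list with \code{metrics} (s_months, t_months, auc, bs, sbs,
#'   n_at_risk, n_events), \code{coverage} (one block per landmark),
#'   \code{predictions} (per-subject medians), \code{cohort}, and a
#'   \code{manifest} of seeds and settings.
#' @export
run_experiment <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "psa_config"))
  pop <- config$pop
  design <- do.call(design_spec, c(config$design, list(seed = config$seed)))
  cohort <- simulate_cohort(pop, design)
  surv <- cohort$survival
  G_hat <- km_curve(surv$time_days, 1L - surv$event)
  km_ref <- km_curve(surv$time_days, surv$event)

  metrics <- list(); cov_list <- list(); preds <- list()
  for (s_idx in seq_along(config$landmarks_months)) {
    s_m <- config$landmarks_months[s_idx]
    s_d <- months_to_days(s_m, round = TRUE)
    t_m_all <- config$horizons_months
    t_d_all <- months_to_days(t_m_all, round = TRUE)
    ok_t <- s_d + t_d_all <= design$admin_censor
    t_m <- t_m_all[ok_t]; t_d <- t_d_all[ok_t]
    if (!length(t_d)) next
    at_risk <- surv$subject_id[surv$time_days > s_d]
    if (progress)
      message(sprintf("landmark %g months: %d subjects at risk", s_m,
                      length(at_risk)))
    if (!length(at_risk)) {
      metrics[[length(metrics) + 1L]] <-
        data.frame(s_months = s_m, t_months = t_m, auc = NA_real_,
                   bs = NA_real_, sbs = NA_real_, n_at_risk = 0L,
                   n_events = 0L)
      next
    }
    traj_bands <- vector("list", length(at_risk))
    risk_bands <- vector("list", length(at_risk))
    pi_hat <- matrix(NA_real_, length(at_risk), length(t_d))
    for (j in seq_along(at_risk)) {
      id <- at_risk[j]
      ld <- landmark_dataset(cohort, id, s_d)
      post <- sample_posterior(ld, pop, L = config$L, warmup = config$warmup,
                               thin = config$thin,
                               seed = .subject_seed(config$seed, s_idx, id))
      risk_bands[[j]] <- predict_risk(post, pop, s_d, t_d)
      traj_bands[[j]] <- predict_trajectory(post, pop, s_d + t_d)
      pi_hat[j, ] <- risk_bands[[j]]$summary$pi_median
    }
    sr <- surv[match(at_risk, surv$subject_id), , drop = FALSE]
    rows <- lapply(seq_along(t_d), function(k) {
      w <- ipcw_weights(s_d, t_d[k], sr, G_hat)
      bs <- brier_ipcw(s_d, t_d[k], pi_hat[, k], sr, w)
      data.frame(s_months = s_m, t_months = t_m[k],
                 auc = auc_ipcw(s_d, t_d[k], pi_hat[, k], sr, w),
                 bs = bs,
                 sbs = scaled_brier(s_d, t_d[k], bs, km_ref, sr, w),
                 n_at_risk = nrow(sr),
                 n_events = sum(sr$time_days > s_d &
                                  sr$time_days <= s_d + t_d[k] &
                                  sr$event == 1L))
    })
    metrics[[length(metrics) + 1L]] <- do.call(rbind, rows)
    truth_psi <- lapply(at_risk, function(id) {
      tr <- cohort$truth[cohort$truth$subject_id == id, ]
      structure(list(r = tr$r, psa0 = tr$psa0, eps = tr$eps, tesc = tr$tesc),
                class = "psa_psi")
    })
    cov <- coverage_eval(traj_bands, risk_bands, truth_psi, pop, s_d, t_d)
    cov$s_months <- s_m
    cov$t_months <- t_m
    cov_list[[length(cov_list) + 1L]] <- cov
    preds[[length(preds) + 1L]] <-
      data.frame(subject_id = rep(at_risk, each = length(t_d)),
                 s_days = s_d, t_days = rep(t_d, length(at_risk)),
                 pi_median = as.vector(t(pi_hat)))
  }
  list(metrics = do.call(rbind, metrics),
       coverage = do.call(rbind, cov_list),
       predictions = do.call(rbind, preds),
       cohort = cohort,
       manifest = list(seed = config$seed, L = config$L,
                       warmup = config$warmup, thin = config$thin,
                       n_subjects = design$n_subjects,
                       landmarks_months = config$landmarks_months,
                       horizons_months = config$horizons_months))
}
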