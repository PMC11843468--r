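#' @name stage_models
#' @title Early- versus late-foundress-stage mixed models
#'
#' @description
#' Two models compare foraging between the early foundress stage (solo
#' brood care, larvae in the nest) and the late stage (around worker
#' emergence), with a per-queen random intercept to absorb consistent
#' individual differences:
#'
#' * duration — a linear mixed model on the natural log of trip duration,
#'   stage as the fixed effect ([fit_duration_model()]);
#' * frequency — a negative-binomial generalized linear mixed model on
#'   daily trip counts, stage as the fixed effect, mean/dispersion
#'   parameterization (variance \eqn{\mu + \mu^2/\theta})
#'   ([fit_frequency_model()]).
#'
#' Stage enters with EARLY as the reference level, so the reported
#' coefficient is the LATE-minus-EARLY contrast; its p-value is a Wald
#' test. Both fits are checked for overdispersion with
#' [check_overdispersion()].
NULL

new_stage_model_result <- function(model_type, fit, estimate, se, p_value,
                                   ranef_var, n_obs, n_queens,
                                   overdispersion, dispersion = NA_real_) {
  out <- list(model_type = model_type, term = "stageLATE",
              estimate = estimate, se = se, p_value = p_value,
              ranef_var = ranef_var, n_obs = n_obs, n_queens = n_queens,
              overdispersion = overdispersion, dispersion = dispersion,
              fit = fit)
  stopifnot(p_value >= 0, p_value <= 1,
            n_queens == length(unique(stats::model.frame(fit)$queen_id)))
  class(out) <- "stage_model_result"
  out
}

check_stage_input <- function(df, value_col) {
  stopifnot(all(c("queen_id", "stage", value_col) %in% names(df)))
  if (nrow(df) == 0) stop("empty input", call. = FALSE)
  if (!all(df$stage %in% c("EARLY", "LATE"))) {
    stop("stage must be EARLY or LATE", call. = FALSE)
  }
  if (length(unique(df$queen_id)) < 2) {
    stop("need at least 2 queens: a per-queen random intercept is ",
         "inestimable from one queen", call. = FALSE)
  }
  if (length(unique(df$stage)) < 2) {
    stop("both stages must be present", call. = FALSE)
  }
  df$stage <- factor(df$stage, levels = c("EARLY", "LATE"))
  df$queen_id <- factor(df$queen_id)
  df
}

#' Linear mixed model on log trip duration
#'
#' Fits `log(duration) ~ stage + (1 | queen)` by REML. The response is the
#' natural log of trip duration; the stage coefficient is the LATE-EARLY
#' difference in mean log duration (a multiplicative effect on the
#' original scale), tested with a Wald normal test.
#'
#' @param staged_trips Data.frame with `queen_id`, `stage`
#'   (`EARLY`/`LATE`) and `duration_s` (positive; seconds), as produced by
#'   [stage_subsets()]`$trips`.
#' @return A `stage_model_result`: stage estimate and SE (log scale),
#'   Wald p-value, random-intercept variance, sample sizes, overdispersion
#'   statistic, and the underlying [lme4::lmer()] fit in `$fit`.
#' @export
fit_duration_model <- function(staged_trips) {
  df <- check_stage_input(staged_trips, "duration_s")
  if (any(df$duration_s <= 0)) stop("durations must be > 0", call. = FALSE)
  df$log_duration <- log(df$duration_s)
  if (stats::var(df$log_duration) == 0) {
    stop("degenerate fit: all durations identical (zero residual variance)",
         call. = FALSE)
  }
  fit <- lme4::lmer(log_duration ~ stage + (1 | queen_id), data = df,
                    REML = TRUE)
  ct <- stats::coef(summary(fit))
  est <- ct["stageLATE", "Estimate"]
  se <- ct["stageLATE", "Std. Error"]
  p <- 2 * stats::pnorm(-abs(est / se))
  vc <- as.data.frame(lme4::VarCorr(fit))
  ranef_var <- vc$vcov[vc$grp == "queen_id"][1]
  new_stage_model_result("duration_lmm", fit, est, se, p, ranef_var,
                         nrow(df), nlevels(df$queen_id),
                         check_overdispersion(fit))
}

#' Negative-binomial mixed model on daily trip counts
#'
#' Fits `count ~ stage + (1 | queen)` with a negative-binomial conditional
#' distribution (log link, variance \eqn{\mu + \mu^2/\theta}), maximum
#' likelihood with a Laplace approximation for the random effect. The
#' stage coefficient is the log rate ratio of LATE to EARLY daily trips.
#'
#' @param staged_counts Data.frame with `queen_id`, `stage` and `n_trips`
#'   (non-negative integers, one row per queen-day), as produced by
#'   [stage_subsets()]`$daily`.
#' @return A `stage_model_result`; `$dispersion` holds the estimated
#'   \eqn{\theta} and `$fit` the underlying [glmmTMB::glmmTMB()] fit.
#' @export
fit_frequency_model <- function(staged_counts) {
  df <- check_stage_input(staged_counts, "n_trips")
  if (any(df$n_trips < 0) || any(df$n_trips != round(df$n_trips))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (all(df$n_trips == 0)) {
    stop("degenerate fit: all counts are zero", call. = FALSE)
  }
  fit <- glmmTMB::glmmTMB(n_trips ~ stage + (1 | queen_id), data = df,
                          family = glmmTMB::nbinom2())
  ct <- stats::coef(summary(fit))$cond
  est <- ct["stageLATE", "Estimate"]
  se <- ct["stageLATE", "Std. Error"]
  p <- ct["stageLATE", "Pr(>|z|)"]
  if (!is.finite(se) || !is.finite(p)) {
    stop("degenerate fit: the stage coefficient's uncertainty could not be ",
         "estimated (non-positive-definite Hessian, often from too little ",
         "count variation)", call. = FALSE)
  }
  vc <- glmmTMB::VarCorr(fit)$cond$queen_id
  ranef_var <- as.numeric(vc[1, 1])
  new_stage_model_result("frequency_nb_glmm", fit, est, se, p, ranef_var,
                         nrow(df), nlevels(df$queen_id),
                         check_overdispersion(fit),
                         dispersion = stats::sigma(fit))
}

#' Pearson overdispersion check
#'
#' Sum of squared Pearson residuals over residual degrees of freedom.
#' Values near 1 indicate the fitted mean-variance relationship is
#' adequate; values well above 1 (flagged beyond 1.5) indicate residual
#' clustering the model does not capture.
#'
#' @param fit A fitted model from [fit_duration_model()],
#'   [fit_frequency_model()] (their `$fit`), or any model with Pearson
#'   residuals and `df.residual()`.
#' @return The statistic, with attribute `flagged` (`TRUE` above 1.5).
#' @export
check_overdispersion <- function(fit) {
  if (inherits(fit, "stage_model_result")) fit <- fit$fit
  r <- stats::residuals(fit, type = "pearson")
  if (length(r) == 0) stop("empty model: no residuals", call. = FALSE)
  df_res <- stats::df.residual(fit)
  if (is.na(df_res) || df_res <= 0) {
    stop("no residual degrees of freedom", call. = FALSE)
  }
  stat <- sum(r^2) / df_res
  attr(stat, "flagged") <- stat > 1.5
  stat
}

#' @export
print.stage_model_result <- function(x, ...) {
  lab <- if (x$model_type == "duration_lmm") {
    "LMM on log trip duration"
  } else {
    "NB GLMM on daily trip counts"
  }
  cat(lab, "\n")
  cat(sprintf("  stage (LATE - EARLY): %.4f +/- %.4f, Wald p = %.4g\n",
              x$estimate, x$se, x$p_value))
  cat(sprintf("  random intercept variance (queen): %.4f\n", x$ranef_var))
  if (!is.na(x$dispersion)) {
    cat(sprintf("  NB dispersion theta: %.3f\n", x$dispersion))
  }
  cat(sprintf("  n = %d observations, %d queens; overdispersion = %.3f%s\n",
              x$n_obs, x$n_queens, x$overdispersion,
              if (isTRUE(attr(x$overdispersion, "flagged"))) " (flagged)" else ""))
  invisible(x)
}

#' One-call stage comparison
#'
#' Convenience wrapper: labels trips and daily counts by foundress stage
#' with [stage_subsets()] and fits both stage models.
#'
#' @param trips Retained trips from [infer_trips()].
#' @param queens Queen metadata from [read_queens()].
#' @param config A [pipeline_config()].
#' @return List with `duration` and `frequency` (`stage_model_result`s)
#'   and `subsets` (the [stage_subsets()] output).
#' @export
compare_stages <- function(trips, queens, config = pipeline_config()) {
  ss <- stage_subsets(trips, queens, config)
  list(duration = fit_duration_model(ss$trips),
       frequency = fit_frequency_model(ss$daily),
       subsets = ss)
}
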