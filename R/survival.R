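#' Kaplan-Meier product-limit estimate
#'
#' Wrapper around `survival::survfit` returning a tidy step function. At tied
#' times, events precede censorings.
#'
#' @param time non-negative follow-up times.
#' @param event 0/1 event indicators.
#' @return a tibble of class `km_fit` with `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0L) stop("empty survival input", call. = FALSE)
  if (any(time < 0)) stop("times must be non-negative", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                        n_event = fit$n.event, n_censor = fit$n.censor,
                        survival = fit$surv)
  class(out) <- c("km_fit", class(out))
  out
}

#' Log-rank test
#'
#' Standard (O - E)^2 / V chi-square test on g - 1 degrees of freedom via
#' `survival::survdiff`. If no events occur at all, the test is vacuous and
#' `chi2 = 0, p = 1` is returned with a message.
#'
#' @param time,event as in [km_estimate()].
#' @param groups group labels (>= 2 groups).
#' @return tibble with `chi2`, `df`, `p`.
#' @export
logrank_test <- function(time, event, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (sum(event) == 0) {
    message("no events: log-rank p set to 1 by convention")
    return(tibble::tibble(chi2 = 0, df = nlevels(droplevels(groups)) - 1L, p = 1))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ groups)
  df <- length(sd$n) - 1L
  tibble::tibble(chi2 = unname(sd$chisq), df = df,
                 p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards regression
#'
#' Newton-Raphson maximization of the Breslow partial likelihood via
#' `survival::coxph` (tolerance 1e-8, up to 50 iterations); standard error
#' from the observed information, two-sided Wald p. Non-convergence or a
#' monotone likelihood (coefficient running to infinity) is flagged in the
#' `converged` column rather than returned silently.
#'
#' @param time,event as in [km_estimate()].
#' @param covariate numeric covariate, non-constant.
#' @return one-row tibble: `beta`, `hr`, `se`, `z`, `p`, `n_events`,
#'   `converged`.
#' @export
cox_univariate <- function(time, event, covariate) {
  if (sum(event) < 2) stop("need at least 2 events", call. = FALSE)
  if (stats::sd(covariate) == 0) stop("covariate is constant", call. = FALSE)
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ covariate,
                    ties = "breslow",
                    control = survival::coxph.control(eps = 1e-8,
                                                      iter.max = 50L)),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(fit$var)))
  z <- beta / se
  tibble::tibble(
    beta = beta, hr = exp(beta), se = se, z = z,
    p = 2 * stats::pnorm(-abs(z)),
    n_events = sum(event),
    converged = !flagged && is.finite(beta)
  )
}

# standardized two-group log-rank statistic (O - E) / sqrt(V) for the split
# high = score > cutoff; Breslow-style: events precede censorings at ties
logrank_z <- function(time, event, high) {
  et <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in et) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & high)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & high)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (v <= 0) return(0)
  o_minus_e / sqrt(v)
}

#' Maximally selected rank-statistic cutpoint
#'
#' Scans every distinct score value that leaves at least `ceiling(minprop * n)`
#' samples on each side, computes the standardized two-group log-rank
#' statistic for the split `score > cutoff`, and returns the cutoff with the
#' largest absolute statistic (ties break toward the smaller cutoff). This is
#' the surv-cutpoint / maximally-selected-rank-statistic dichotomization; the
#' reported statistic is not corrected for the selection, so a log-rank test
#' on the chosen split is optimistically biased.
#'
#' @param time,event as in [km_estimate()].
#' @param score continuous per-sample marker.
#' @param minprop minimum fraction of samples in either group.
#' @return one-row tibble of class `cutpoint_result`: `cutoff`, `statistic`
#'   (absolute standardized log-rank), `n_high`, `n_low`, `minprop`.
#' @export
max_rank_cutpoint <- function(time, event, score, minprop = 0.1) {
  n <- length(score)
  if (n < 10L) stop("need at least 10 samples", call. = FALSE)
  if (sum(event) < 2) stop("need at least 2 events", call. = FALSE)
  min_n <- ceiling(minprop * n)
  cand <- sort(unique(score))
  ok <- vapply(cand, function(c) {
    nh <- sum(score > c)
    nh >= min_n && (n - nh) >= min_n
  }, logical(1L))
  cand <- cand[ok]
  if (length(cand) == 0L) stop("no admissible split under minprop", call. = FALSE)
  zs <- vapply(cand, function(c) abs(logrank_z(time, event, score > c)),
               numeric(1L))
  best <- cand[which.max(zs)]  # which.max picks the first = smallest cutoff
  out <- tibble::tibble(cutoff = best, statistic = max(zs),
                        n_high = sum(score > best), n_low = sum(score <= best),
                        minprop = minprop)
  class(out) <- c("cutpoint_result", class(out))
  out
}

#' Kaplan-Meier plot
#'
#' @param object a `km_fit` from [km_estimate()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.km_fit <- function(object, ...) {
  df <- dplyr::bind_rows(tibble::tibble(time = 0, survival = 1),
                         object[, c("time", "survival")])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability",
                  title = "Kaplan-Meier estimate") +
    ggplot2::theme_minimal()
}
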