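## Cluster-outcome association: follow-up truncation, Kaplan-Meier and
## log-rank comparison, Cox proportional hazards (Efron ties) and Harrell's
## concordance. Estimation is delegated to the survival package; this module
## fixes the conventions (3-year truncation, reference cluster, risk score
## for the c-statistic) used throughout the pipeline.

#' Truncate follow-up at a horizon
#'
#' Observations with time beyond the horizon are administratively censored
#' at the horizon (event flag set to 0); an event exactly at the horizon is
#' retained. Applies to every `time_*`/`event_*` column pair, or to columns
#' named `time`/`event`.
#'
#' @param outcomes Outcome data frame.
#' @param horizon Truncation time in the time unit of the table (default 3).
#' @return The truncated table.
#' @export
truncate_followup <- function(outcomes, horizon = 3) {
  if (horizon <= 0) abort("`horizon` must be positive")
  time_cols <- grep("^time(_|$)", names(outcomes), value = TRUE)
  if (!length(time_cols)) abort("no time/event columns found")
  for (tc in time_cols) {
    ec <- sub("^time", "event", tc)
    if (!ec %in% names(outcomes))
      abort(sprintf("missing event column `%s` for `%s`", ec, tc))
    over <- outcomes[[tc]] > horizon
    outcomes[[ec]][over] <- 0L
    outcomes[[tc]][over] <- horizon
  }
  outcomes
}

#' Kaplan-Meier curves and log-rank comparison across clusters
#'
#' @param data Data frame holding the time, event and group columns.
#' @param time,event,group Column names (strings).
#' @return A list of class `hfc_km`: `curves` (tidy step-function tibble),
#'   `chisq`, `df`, `p_value`, `n`, `events`.
#' @export
km_logrank <- function(data, time = "time", event = "event",
                       group = "cluster") {
  tt <- data[[time]]; ev <- data[[event]]; g <- factor(data[[group]])
  keep <- !is.na(tt) & !is.na(ev) & !is.na(g)
  tt <- tt[keep]; ev <- ev[keep]; g <- droplevels(g[keep])
  if (any(table(g) == 0L)) {
    warn("empty group(s) dropped")
    g <- droplevels(g)
  }
  if (nlevels(g) < 2L) abort("log-rank needs at least 2 non-empty groups")
  fit <- survival::survfit(survival::Surv(tt, ev) ~ g)
  sm <- summary(fit, censored = TRUE)
  curves <- tibble(
    group = sub("^g=", "", as.character(sm$strata)),
    time = sm$time, n_risk = sm$n.risk, n_event = sm$n.event,
    survival = sm$surv, lower = sm$lower, upper = sm$upper)
  sd <- survival::survdiff(survival::Surv(tt, ev) ~ g)
  df <- nlevels(g) - 1L
  structure(list(curves = curves, chisq = unname(sd$chisq), df = df,
                 p_value = pchisq(sd$chisq, df, lower.tail = FALSE),
                 n = length(tt), events = sum(ev)),
            class = "hfc_km")
}

#' @export
print.hfc_km <- function(x, ...) {
  cat(sprintf("<hfc_km> %d samples, %d events; log-rank chi2 = %.3f (df %d), p = %.3g\n",
              x$n, x$events, x$chisq, x$df, x$p_value))
  invisible(x)
}

#' @export
autoplot.hfc_km <- function(object, ...) {
  ggplot(object$curves, aes(x = .data$time, y = .data$survival,
                            colour = .data$group)) +
    geom_step(linewidth = 0.8) +
    labs(x = "time (years)", y = "event-free survival", colour = "cluster") +
    theme_minimal()
}

#' Cox proportional-hazards association
#'
#' Partial-likelihood estimation with the Efron approximation for tied
#' event times. Cluster covariates enter as dummies against a declared
#' reference cluster; continuous covariates can be standardized so hazard
#' ratios are per standard deviation increase.
#'
#' @param data Data frame with the time/event columns and covariates.
#' @param time,event Column names.
#' @param cluster Optional cluster column name (coded as factor/integer).
#' @param reference Reference cluster level (default: first level).
#' @param covariates Optional character vector of additional covariate
#'   columns (e.g. age and sex for protein benchmarking models).
#' @param standardize Standardize continuous covariates to unit SD
#'   (default TRUE).
#' @return An object of class `hfc_cox`: `terms` (tibble of HR, 95% CI,
#'   Wald p per term), `c_statistic` (Harrell's C of the model's linear
#'   predictor), `n`, `events`, and the underlying `survival::coxph` fit.
#' @export
cox_fit <- function(data, time = "time", event = "event", cluster = NULL,
                    reference = NULL, covariates = NULL,
                    standardize = TRUE) {
  df <- as.data.frame(data)
  used <- c(time, event, cluster, covariates)
  miss <- setdiff(used, names(df))
  if (length(miss)) abort(sprintf("missing column(s): %s",
                                  paste(miss, collapse = ", ")))
  df <- df[complete.cases(df[, used, drop = FALSE]), used, drop = FALSE]
  if (sum(df[[event]]) < 1) abort("no events in the data")
  terms <- character()
  if (!is.null(cluster)) {
    f <- factor(df[[cluster]])
    if (nlevels(f) < 2L) abort("cluster covariate needs >= 2 levels")
    if (!is.null(reference)) f <- stats::relevel(f, ref = as.character(reference))
    df[[cluster]] <- f
    terms <- cluster
  }
  for (v in covariates %||% character()) {
    if (standardize && is.numeric(df[[v]]) && length(unique(df[[v]])) > 2L)
      df[[v]] <- as.numeric(scale(df[[v]]))
    terms <- c(terms, v)
  }
  if (!length(terms)) abort("no covariates supplied")
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time, ", ", event, ") ~ ",
    paste(terms, collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = df, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be infinite", conditionMessage(w)))
        abort(sprintf("Cox fit unstable (%s); check covariates: %s",
                      conditionMessage(w), paste(terms, collapse = ", ")))
      suppressWarnings(survival::coxph(fml, data = df, ties = "efron"))
    })
  s <- summary(fit)
  co <- s$coefficients
  term_tab <- tibble(
    term = rownames(co),
    estimate = co[, "coef"], hr = exp(co[, "coef"]),
    std_error = co[, "se(coef)"],
    conf_low = exp(co[, "coef"] - qnorm(0.975) * co[, "se(coef)"]),
    conf_high = exp(co[, "coef"] + qnorm(0.975) * co[, "se(coef)"]),
    p_value = co[, "Pr(>|z|)"])
  lp <- unname(fit$linear.predictors)
  structure(list(terms = term_tab,
                 c_statistic = concordance_index(df[[time]], df[[event]], lp),
                 n = nrow(df), events = sum(df[[event]]),
                 reference = if (!is.null(cluster)) levels(df[[cluster]])[1]
                 else NA_character_,
                 fit = fit),
            class = "hfc_cox")
}

#' @export
print.hfc_cox <- function(x, ...) {
  cat(sprintf("<hfc_cox> n = %d, events = %d, c-statistic = %.3f (reference %s)\n",
              x$n, x$events, x$c_statistic, x$reference))
  print(x$terms)
  invisible(x)
}

#' @export
tidy.hfc_cox <- function(x, ...) x$terms

#' @export
glance.hfc_cox <- function(x, ...) {
  tibble(n = x$n, events = x$events, c_statistic = x$c_statistic,
         reference = x$reference, loglik = as.numeric(stats::logLik(x$fit)))
}

#' Harrell's concordance index
#'
#' Probability, over usable pairs (the shorter observed time is an event),
#' that the sample with the higher risk score fails earlier; score ties
#' count one half.
#'
#' @param time,event Observed times and event flags.
#' @param score Risk scores (higher = higher risk, e.g. a Cox linear
#'   predictor).
#' @return Harrell's C in `[0, 1]`.
#' @export
concordance_index <- function(time, event, score) {
  keep <- !is.na(time) & !is.na(event) & !is.na(score)
  time <- time[keep]; event <- event[keep]; score <- score[keep]
  cf <- survival::concordance(survival::Surv(time, event) ~ score,
                              reverse = TRUE)
  usable <- sum(cf$count[c("concordant", "discordant", "tied.x")])
  if (usable == 0) abort("no usable pairs for concordance")
  unname(cf$concordance)
}

#' Associate cluster assignments with every endpoint
#'
#' For each endpoint: 3-year truncation, Kaplan-Meier + log-rank, Cox hazard
#' ratios against the reference cluster, and the c-statistic of the Cox
#' linear predictor. The reference cluster defaults to the cluster with the
#' lowest crude event rate across endpoints (the slowly progressing
#' cluster), and is configurable.
#'
#' @param assignments Data frame with `sample_id` and `class`.
#' @param outcomes Outcome table (`sample_id`, `time_*`/`event_*` columns).
#' @param endpoints Endpoint names; default = all present.
#' @param horizon Truncation horizon in years (3).
#' @param reference Reference cluster; `NULL` picks the lowest-event-rate
#'   cluster.
#' @return An object of class `hfc_assoc`: `results` (tidy per-endpoint,
#'   per-cluster HR tibble), `km` (list of `hfc_km`), `reference`.
#' @export
run_association <- function(assignments, outcomes, endpoints = NULL,
                            horizon = 3, reference = NULL) {
  if (length(unique(assignments$class)) < 2L)
    abort("cluster assignment has a single class; no contrast to estimate")
  time_cols <- grep("^time_", names(outcomes), value = TRUE)
  found <- sub("^time_", "", time_cols)
  endpoints <- endpoints %||% found
  missing_ep <- setdiff(endpoints, found)
  if (length(missing_ep))
    abort(sprintf("endpoint column(s) absent: %s",
                  paste(missing_ep, collapse = ", ")))
  dat <- dplyr::inner_join(assignments, outcomes, by = "sample_id")
  dat <- truncate_followup(dat, horizon)

  if (is.null(reference)) {
    ev_cols <- paste0("event_", endpoints)
    rate <- tapply(rowMeans(as.matrix(dat[, ev_cols, drop = FALSE])),
                   dat$class, mean)
    reference <- names(rate)[which.min(rate)]
  }

  km <- list(); rows <- list()
  for (ep in endpoints) {
    tc <- paste0("time_", ep); ec <- paste0("event_", ep)
    k <- km_logrank(dat, tc, ec, "class")
    km[[ep]] <- k
    cx <- cox_fit(dat, tc, ec, cluster = "class", reference = reference)
    rows[[ep]] <- dplyr::mutate(
      cx$terms, endpoint = ep,
      cluster = sub("^class", "", .data$term),
      logrank_chisq = k$chisq, logrank_p = k$p_value,
      c_statistic = cx$c_statistic, n = cx$n, events = cx$events,
      .before = 1)
  }
  structure(list(results = dplyr::bind_rows(rows), km = km,
                 reference = reference, horizon = horizon),
            class = "hfc_assoc")
}

#' @export
print.hfc_assoc <- function(x, ...) {
  cat(sprintf("<hfc_assoc> reference cluster %s, %d endpoint(s)\n",
              x$reference, length(x$km)))
  print(dplyr::select(x$results, "endpoint", "cluster", "hr", "conf_low",
                      "conf_high", "p_value", "c_statistic"))
  invisible(x)
}

#' @export
tidy.hfc_assoc <- function(x, ...) x$results

#' @export
autoplot.hfc_assoc <- function(object, ...) {
  ggplot(object$results, aes(x = .data$hr, y = .data$cluster)) +
    geom_point() +
    geom_errorbarh(aes(xmin = .data$conf_low, xmax = .data$conf_high),
                   height = 0.2) +
    geom_vline(xintercept = 1, linetype = "dashed") +
    facet_wrap(~endpoint) +
    labs(x = "hazard ratio (log scale)", y = "cluster vs reference") +
    ggplot2::scale_x_log10() +
    theme_minimal()
}
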