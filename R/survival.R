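#' Kaplan-Meier curves per group
#'
#' Product-limit estimator for each group, with the median survival defined as
#' the smallest observed time at which the curve drops to 0.5 or below
#' (undefined, `NA`, when the curve never reaches 0.5).
#'
#' @param clin Clinical tibble (`sample`, `time_months`, `event`, ...).
#' @param group Tibble (`sample`, `label`); every group needs at least one
#'   subject after alignment. Omit to fit a single pooled curve.
#' @return An object of class `emt_km`: list with `curves` (tibble `label`,
#'   `time`, `n_risk`, `n_event`, `n_censor`, `surv`) and `medians` (tibble
#'   `label`, `n`, `events`, `median_months`).
#' @examples
#' clin <- tibble::tibble(sample = letters[1:4], time_months = 1:4, event = 1L)
#' km_fit(clin)$curves$surv   # 0.75 0.50 0.25 0.00
#' @export
km_fit <- function(clin, group = NULL) {
  clin <- validate_clinical(clin)
  if (!nrow(clin)) abort("empty clinical table", class = "emtlnc_validation_error")
  d <- km_data(clin, group)
  fit <- survival::survfit(survival::Surv(time_months, event) ~ label,
                           data = d)
  curves <- survfit_tibble(fit, levels = unique(d$label))
  medians <- curves |>
    group_by(.data$label) |>
    summarise(
      median_months = if (any(.data$surv <= 0.5))
        min(.data$time[.data$surv <= 0.5]) else NA_real_,
      .groups = "drop"
    ) |>
    left_join(
      d |> group_by(.data$label) |>
        summarise(n = dplyr::n(), events = sum(.data$event), .groups = "drop"),
      by = "label"
    ) |>
    select("label", "n", "events", "median_months")
  structure(list(curves = curves, medians = medians), class = "emt_km")
}

km_data <- function(clin, group) {
  if (is.null(group)) {
    d <- clin
    d$label <- "all"
  } else {
    stopifnot(all(c("sample", "label") %in% names(group)))
    d <- dplyr::inner_join(clin, as_tibble(group), by = "sample")
    lost <- setdiff(unique(group$label), unique(d$label))
    if (length(lost)) {
      abort(paste("group(s) without subjects:", paste(lost, collapse = ", ")),
            class = "emtlnc_validation_error")
    }
  }
  d$label <- as.character(d$label)
  d
}

survfit_tibble <- function(fit, levels) {
  s <- summary(fit, censored = TRUE)
  strata <- if (is.null(s$strata)) rep(levels[1], length(s$time)) else
    sub("^label=", "", as.character(s$strata))
  tibble(label = strata, time = s$time, n_risk = s$n.risk,
         n_event = s$n.event, n_censor = s$n.censor, surv = s$surv)
}

#' Log-rank (Mantel-Cox) test across groups
#'
#' @inheritParams km_fit
#' @param group Tibble (`sample`, `label`) defining at least two groups.
#' @return Tibble with `chisq`, `df`, `p.value`.
#' @export
logrank_test <- function(clin, group) {
  clin <- validate_clinical(clin)
  d <- km_data(clin, group)
  if (length(unique(d$label)) < 2) {
    abort("log-rank needs at least two groups", class = "emtlnc_validation_error")
  }
  if (sum(d$event) < 1) {
    abort("log-rank needs at least one event", class = "emtlnc_validation_error")
  }
  sd <- survival::survdiff(survival::Surv(time_months, event) ~ label, data = d)
  df <- length(sd$n) - 1
  tibble(chisq = unname(sd$chisq), df = df,
         p.value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards regression
#'
#' Partial-likelihood fit with Efron tie handling. In multivariate mode all
#' covariates enter one model; in univariate mode each covariate is fitted
#' alone (as in per-covariate hazard-ratio tables). Rows with missing values
#' in the covariates of a model are dropped and counted.
#'
#' @param clin Clinical tibble that also contains the covariate columns (join
#'   an EMT score table in first if needed).
#' @param covariates Character vector of covariate column names. Ordered
#'   factors (stage) are encoded as their integer level (ordinal coding).
#' @param univariate Fit one model per covariate instead of a joint model.
#' @return An object of class `emt_cox`: list with `results` tibble (`term`,
#'   `estimate`, `hazard_ratio`, `conf.low`, `conf.high`, `p.value`, `n`,
#'   `n_event`) and the underlying `coxph` fits.
#' @export
cox_fit <- function(clin, covariates, univariate = FALSE) {
  clin <- validate_clinical(clin)
  absent <- setdiff(covariates, names(clin))
  if (length(absent)) {
    abort(paste("covariate(s) absent:", paste(absent, collapse = ", ")),
          class = "emtlnc_validation_error")
  }
  if (sum(clin$event, na.rm = TRUE) < 1) {
    abort("no events in clinical table", class = "emtlnc_validation_error")
  }
  d <- clin
  for (cv in covariates) {
    if (is.ordered(d[[cv]])) d[[cv]] <- as.integer(d[[cv]])
    if (is.character(d[[cv]])) d[[cv]] <- factor(d[[cv]])
    if (is.numeric(d[[cv]]) && var(d[[cv]], na.rm = TRUE) == 0) {
      abort(paste0("covariate '", cv, "' is constant"),
            class = "emtlnc_fit_error")
    }
  }
  sets <- if (univariate) as.list(covariates) else list(covariates)
  fits <- lapply(sets, function(cvs) {
    keep <- complete.cases(d[, c("time_months", "event", cvs)])
    dropped <- sum(!keep)
    if (dropped) {
      inform(sprintf("dropping %d row(s) with missing covariates for model {%s}",
                     dropped, paste(cvs, collapse = ", ")))
    }
    dd <- d[keep, , drop = FALSE]
    fml <- stats::reformulate(cvs,
                              response = "survival::Surv(time_months, event)")
    fit <- survival::coxph(fml, data = dd, ties = "efron")
    if (any(!is.finite(coef(fit)))) {
      abort("Cox fit did not converge to finite coefficients",
            class = "emtlnc_fit_error")
    }
    fit
  })
  results <- purrr::map_dfr(fits, function(fit) {
    sm <- summary(fit)
    tibble(
      term = rownames(sm$coefficients),
      estimate = sm$coefficients[, "coef"],
      hazard_ratio = sm$coefficients[, "exp(coef)"],
      conf.low = sm$conf.int[, "lower .95"],
      conf.high = sm$conf.int[, "upper .95"],
      p.value = sm$coefficients[, "Pr(>|z|)"],
      n = sm$n,
      n_event = sm$nevent
    )
  })
  structure(list(results = results, fits = fits, univariate = univariate),
            class = "emt_cox")
}

#' @export
print.emt_km <- function(x, ...) {
  cat("Kaplan-Meier fit,", nrow(x$medians), "group(s)\n")
  print(x$medians)
  invisible(x)
}

#' @export
print.emt_cox <- function(x, ...) {
  cat("Cox proportional-hazards fit (",
      if (x$univariate) "univariate per covariate" else "multivariate",
      ")\n", sep = "")
  print(x$results)
  invisible(x)
}

#' Tidy a Kaplan-Meier fit into its survival curve table
#' @param x An `emt_km` object.
#' @param ... Unused.
#' @return Tibble of step-curve points per group.
#' @export
tidy.emt_km <- function(x, ...) x$curves

#' Per-group summary of a Kaplan-Meier fit
#' @param x An `emt_km` object.
#' @param ... Unused.
#' @return Tibble with group sizes, event counts and median survival.
#' @export
glance.emt_km <- function(x, ...) x$medians

#' Tidy a Cox fit into a per-term coefficient table
#' @param x An `emt_cox` object.
#' @param ... Unused.
#' @return Tibble with coefficient, hazard ratio, confidence bounds, p-value.
#' @export
tidy.emt_cox <- function(x, ...) x$results

#' One-row summary per Cox model
#' @param x An `emt_cox` object.
#' @param ... Unused.
#' @return Tibble with n, events, concordance and likelihood-ratio p.
#' @export
glance.emt_cox <- function(x, ...) {
  purrr::map_dfr(x$fits, function(fit) {
    sm <- summary(fit)
    tibble(n = sm$n, n_event = sm$nevent,
           concordance = unname(sm$concordance["C"]),
           logtest_p = unname(sm$logtest["pvalue"]))
  })
}

#' Median split of a numeric marker for high/low survival comparison
#'
#' @param scores Tibble (`sample`, `score`) or any per-sample numeric column.
#' @param q Split quantile (default 0.5, a median split).
#' @return Tibble (`sample`, `label`) with labels `"low"` / `"high"`.
#' @export
split_high_low <- function(scores, q = 0.5) {
  stopifnot(all(c("sample", "score") %in% names(scores)))
  cut_at <- quantile(scores$score, q, names = FALSE)
  tibble(sample = scores$sample,
         label = ifelse(scores$score > cut_at, "high", "low"))
}
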