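#' Split patients into high/low expression groups at the cohort mean
#'
#' High means strictly greater than the mean of the supplied values (ties
#' fall to low), the standard dichotomization for expression-based risk
#' groups. The mean is computed over the patients in the survival table.
#'
#' @param expr numeric expression vector over patients.
#' @return factor with levels \code{low}, \code{high}.
#' @export
dichotomizeByMean <- function(expr) {
  if (length(expr) < 2) stop("need >= 2 patients to dichotomize")
  if (length(unique(expr)) == 1L)
    stop("expression is constant; cannot form high/low groups")
  g <- factor(ifelse(expr > mean(expr), "high", "low"),
              levels = c("low", "high"))
  if (any(table(g) == 0))
    stop("dichotomization produced an empty group")
  g
}

#' Two-group log-rank test with Kaplan-Meier curves
#'
#' @param groups two-level factor (e.g. from [dichotomizeByMean()]).
#' @param times,events follow-up times and event indicators (1 = observed).
#' @return list with \code{chi2}, \code{p} (1 df), \code{km} (the
#'   \code{survival::survfit} step functions per group) and \code{n} per
#'   group.
#' @export
kmLogrank <- function(groups, times, events) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) != 2) stop("kmLogrank needs exactly two groups")
  if (sum(events) < 1) stop("kmLogrank needs at least one observed event")
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       km = survival::survfit(survival::Surv(times, events) ~ groups),
       n = table(groups))
}

.coxRow <- function(fit, var) {
  s <- summary(fit)
  i <- grep(paste0("^", var), rownames(s$coefficients))[1]
  co <- s$coefficients[i, ]
  ci <- s$conf.int[i, ]
  converged <- is.finite(co[["coef"]]) && abs(co[["coef"]]) < 15
  data.frame(
    variable = var, HR = unname(ci[["exp(coef)"]]),
    ci_low = if (converged) unname(ci[["lower .95"]]) else 0,
    ci_high = if (converged) unname(ci[["upper .95"]]) else Inf,
    p = unname(co[["Pr(>|z|)"]]),
    converged = converged,
    stringsAsFactors = FALSE
  )
}

#' Univariate Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Efron tie handling; reports the hazard ratio
#' (per unit for numeric variables, high vs low for two-level factors) with
#' Wald 95 percent CI and p-value. Monotone-likelihood non-convergence is
#' flagged with an infinite-bound CI rather than an error.
#'
#' @param variable numeric or two-level factor per patient.
#' @param times,events follow-up times and event indicators.
#' @param name label for the output row.
#' @return one-row data.frame: variable, HR, ci_low, ci_high, p, n_high,
#'   n_low (NA for numeric variables), converged.
#' @export
coxUnivariate <- function(variable, times, events, name = "variable") {
  if (length(unique(variable[!is.na(variable)])) < 2)
    stop("variable '", name, "' is constant")
  if (sum(events) < 10)
    warning("fewer than 10 events; Cox estimates will be unstable")
  df <- data.frame(time = times, event = events, v = variable)
  df <- df[stats::complete.cases(df), ]
  fit <- survival::coxph(survival::Surv(time, event) ~ v, data = df,
                         ties = "efron")
  out <- .coxRow(fit, "v")
  out$variable <- name
  if (is.factor(variable) || is.character(variable)) {
    tab <- table(df$v)
    out$n_high <- unname(tab[length(tab)])
    out$n_low <- unname(tab[1])
  } else {
    out$n_high <- NA_integer_; out$n_low <- NA_integer_
  }
  out
}

#' Multivariate Cox proportional-hazards fit
#'
#' Joint fit over several variables with Efron ties, giving each variable's
#' adjusted HR, CI and p. With \code{screen = TRUE} variables are first
#' filtered to those significant (p < \code{screenAlpha}) in univariate
#' fits, mirroring the usual two-stage clinical workflow. Collinear inputs
#' raise an error naming the offending pair. Complete cases only.
#'
#' @param variables named list (or data.frame) of per-patient covariates.
#' @param times,events follow-up times and event indicators.
#' @param screen filter to univariate-significant variables first.
#' @param screenAlpha univariate screening level (default 0.05).
#' @return data.frame with one row per fitted variable (columns as in
#'   [coxUnivariate()], without group sizes).
#' @export
coxMultivariate <- function(variables, times, events, screen = TRUE,
                            screenAlpha = 0.05) {
  variables <- as.data.frame(variables, optional = TRUE)
  if (screen) {
    keep <- vapply(names(variables), function(nm) {
      coxUnivariate(variables[[nm]], times, events, name = nm)$p <
        screenAlpha
    }, logical(1))
    if (!any(keep))
      stop("no variable passes univariate screening at p < ", screenAlpha)
    variables <- variables[, keep, drop = FALSE]
  }
  num <- as.data.frame(lapply(variables, function(v)
    if (is.numeric(v)) v else as.numeric(factor(v))))
  cc <- stats::complete.cases(num, times, events)
  if (ncol(num) > 1) {
    cors <- stats::cor(num[cc, , drop = FALSE])
    diag(cors) <- 0
    if (any(abs(cors) > 0.999)) {
      idx <- which(abs(cors) > 0.999, arr.ind = TRUE)[1, ]
      stop("collinear variables: ", colnames(cors)[idx[1]], " and ",
           colnames(cors)[idx[2]])
    }
  }
  df <- cbind(data.frame(time = times[cc], event = events[cc]),
              variables[cc, , drop = FALSE])
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(names(variables), collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  out <- do.call(rbind, lapply(names(variables), function(nm)
    .coxRow(fit, nm)))
  rownames(out) <- NULL
  out
}

#' Prognostic evaluation of a gene panel on a survival table
#'
#' For each gene: dichotomize patients at the cohort mean, run the log-rank
#' test, and fit a univariate Cox model on the high/low group.
#'
#' @param survTable data.frame as produced by [simulateSurvival()] (or read
#'   from a clinical TSV): columns time, event plus one column per gene.
#' @param genes gene columns to evaluate.
#' @return data.frame with one row per gene: variable, HR (high vs low),
#'   ci_low, ci_high, p (Cox Wald), logrank_p, n_high, n_low.
#' @export
survivalScreen <- function(survTable, genes) {
  missing <- setdiff(genes, colnames(survTable))
  if (length(missing))
    stop("gene(s) absent from survival table: ",
         paste(missing, collapse = ", "))
  rows <- lapply(genes, function(g) {
    grp <- dichotomizeByMean(survTable[[g]])
    lr <- kmLogrank(grp, survTable$time, survTable$event)
    cx <- coxUnivariate(grp, survTable$time, survTable$event, name = g)
    cx$logrank_p <- lr$p
    cx
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
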