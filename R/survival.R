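# Survival analysis: Kaplan-Meier curves, log-rank comparisons (overall and
# pairwise) and multivariate Cox proportional-hazards fits. Estimation is
# delegated to the survival package (product-limit, score test, Efron ties);
# this module shapes inputs/outputs for the subtype workflow.

#' Kaplan-Meier product-limit estimate
#'
#' @param times positive event/censoring times.
#' @param events 0/1 event indicators (1 = disease-specific death).
#' @return data.frame step function \code{(time, n_risk, n_event, survival)}.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) stop("empty input")
  if (any(times <= 0)) stop("survival times must be > 0")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             survival = fit$surv)
}

#' Log-rank test across groups
#'
#' Standard observed-minus-expected statistic over the pooled event times,
#' df = number of groups - 1. With no events anywhere the test is undefined;
#' p = 1 is returned with a warning.
#'
#' @param times,events as in \code{\link{km_estimate}}.
#' @param groups grouping vector.
#' @return \code{list(chi2, df, p)}.
#' @export
logrank <- function(times, events, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 non-empty groups")
  if (sum(events) == 0) {
    warning("no events in any group; log-rank undefined, p = 1")
    return(list(chi2 = 0, df = nlevels(groups) - 1, p = 1))
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(sd$n) - 1
  list(chi2 = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Pairwise log-rank tests between subtypes
#'
#' Raw pairwise p-values (matching the usual pairwise reporting style), with
#' a BH-adjusted column alongside.
#'
#' @inheritParams logrank
#' @return data.frame \code{(group1, group2, chi2, p, q)}.
#' @export
pairwise_logrank <- function(times, events, groups) {
  groups <- factor(groups)
  gl <- levels(groups)
  pr <- t(utils::combn(gl, 2))
  res <- apply(pr, 1, function(g) {
    sel <- groups %in% g
    lr <- logrank(times[sel], events[sel], droplevels(groups[sel]))
    c(lr$chi2, lr$p)
  })
  data.frame(group1 = pr[, 1], group2 = pr[, 2], chi2 = res[1, ],
             p = res[2, ], q = stats::p.adjust(res[2, ], method = "BH"),
             stringsAsFactors = FALSE)
}

#' Multivariate Cox proportional-hazards fit
#'
#' Partial likelihood maximized with Efron tie handling; Wald confidence
#' intervals and p-values per covariate. The design matrix is checked for
#' rank deficiency (e.g. duplicated columns) before fitting.
#'
#' @param covariates data.frame or matrix of covariates. Factors are
#'   expanded to treatment-coded indicators (first level = reference).
#' @param times,events as in \code{\link{km_estimate}}.
#' @return data.frame \code{(term, beta, hr, lower95, upper95, p)}.
#' @export
cox_fit <- function(covariates, times, events) {
  covariates <- as.data.frame(covariates)
  mm <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
  if (qr(mm)$rank < ncol(mm))
    stop("covariate matrix is rank deficient (collinear or duplicated columns)")
  d <- data.frame(mm, check.names = TRUE)
  d$.time <- times; d$.event <- events
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(sprintf("`%s`", colnames(mm)), collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = d, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be infinite", conditionMessage(w))) {
        warning("possible separation or non-convergence in Cox fit: ",
                conditionMessage(w))
        suppressWarnings(survival::coxph(fml, data = d, ties = "efron"))
      } else {
        warning(w)
        suppressWarnings(survival::coxph(fml, data = d, ties = "efron"))
      }
    })
  s <- summary(fit)
  data.frame(term = rownames(s$coefficients),
             beta = s$coefficients[, "coef"],
             hr = s$coefficients[, "exp(coef)"],
             lower95 = s$conf.int[, "lower .95"],
             upper95 = s$conf.int[, "upper .95"],
             p = s$coefficients[, "Pr(>|z|)"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Subtype survival analysis for one compartment
#'
#' Convenience wrapper: KM per subtype, overall and pairwise log-rank, and a
#' multivariate Cox model with a one-vs-rest indicator for each non-reference
#' subtype plus UICC stage (reference: largest subtype, stage I).
#'
#' @param assignment data.frame \code{(sample_id, subtype)}.
#' @param clinical clinical table.
#' @param per_subtype if TRUE (default), fit one Cox model per subtype
#'   (indicator + stage); if FALSE, one model with all indicators jointly.
#' @return \code{list(km, logrank, pairwise, cox)}.
#' @export
subtype_survival <- function(assignment, clinical, per_subtype = TRUE) {
  cl <- clinical[match(assignment$sample_id, clinical$patient_id), ]
  keep <- !is.na(cl$time)
  cl <- cl[keep, ]; subtype <- factor(assignment$subtype[keep])
  km <- lapply(split(seq_along(subtype), subtype), function(i)
    km_estimate(cl$time[i], cl$event[i]))
  lr <- logrank(cl$time, cl$event, subtype)
  pw <- pairwise_logrank(cl$time, cl$event, subtype)
  stage <- factor(as.character(cl$uicc), levels = UICC_LEVELS)
  cox <- if (per_subtype) {
    do.call(rbind, lapply(levels(subtype), function(s) {
      cov <- data.frame(subtype = as.numeric(subtype == s), uicc = stage)
      res <- cox_fit(cov, cl$time, cl$event)
      res$term <- sub("^subtype$", s, res$term)
      res$model <- s
      res
    }))
  } else {
    ref <- names(sort(table(subtype), decreasing = TRUE))[1]
    cov <- data.frame(subtype = stats::relevel(subtype, ref), uicc = stage)
    cox_fit(cov, cl$time, cl$event)
  }
  list(km = km, logrank = lr, pairwise = pw, cox = cox)
}
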