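#' Kaplan-Meier estimate
#'
#' Product-limit survival curve with the median survival time defined as
#' the earliest time at which the curve drops to 0.5 or below (undefined if
#' never reached).
#'
#' @param surv_table Tibble with `sample_id`, `time`, `event`.
#' @return Object of class `km_curve`: list with `steps` (tibble `time`,
#'   `n_risk`, `n_event`, `surv`), `median`, `n`, `events`. Has [tidy()] and
#'   [glance()] methods and an [ggplot2::autoplot()] method.
#' @export
km_estimate <- function(surv_table) {
  surv_table <- validate_survival_table(surv_table)
  if (sum(surv_table$event) == 0) {
    warn("no events observed; survival curve is flat at 1 and median undefined")
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = surv_table)
  steps <- tibble(time = fit$time, n_risk = fit$n.risk,
                  n_event = fit$n.event, surv = fit$surv)
  med <- steps$time[steps$surv <= 0.5]
  out <- list(steps = steps,
              median = if (length(med)) min(med) else NA_real_,
              n = nrow(surv_table), events = sum(surv_table$event))
  class(out) <- "km_curve"
  out
}

#' @export
tidy.km_curve <- function(x, ...) x$steps

#' @export
glance.km_curve <- function(x, ...) {
  tibble(n = x$n, events = x$events, median_survival = x$median)
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d subjects, %d events, median survival %s\n",
              x$n, x$events,
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Log-rank test between two groups
#'
#' Standard observed-minus-expected statistic with hypergeometric variance,
#' one degree of freedom.
#'
#' @param group_a,group_b Survival tibbles (`sample_id`, `time`, `event`).
#' @return Tibble with `chisq`, `p_value`, `n_a`, `n_b`.
#' @export
logrank_test <- function(group_a, group_b) {
  if (!nrow(group_a) || !nrow(group_b)) abort("both groups must be non-empty")
  df <- bind_rows(mutate(as_tibble(group_a), .group = "a"),
                  mutate(as_tibble(group_b), .group = "b"))
  if (sum(df$event) == 0) abort("no events in either group")
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ .group, data = df)
  tibble(chisq = sd_fit$chisq,
         p_value = pchisq(sd_fit$chisq, df = 1, lower.tail = FALSE),
         n_a = nrow(group_a), n_b = nrow(group_b))
}

#' Univariate Cox proportional-hazards regression
#'
#' Partial-likelihood fit with Efron tie handling; the hazard ratio is
#' `exp(beta)` with a Wald 95% confidence interval and p-value.
#'
#' @param surv_table Tibble with `sample_id`, `time`, `event` and the
#'   covariate column.
#' @param covariate Name of the covariate column.
#' @return Tibble: `covariate`, `beta`, `se`, `hr`, `ci_lower`, `ci_upper`,
#'   `p_value`, `n`, `events`, `converged`.
#' @export
cox_univariate <- function(surv_table, covariate) {
  surv_table <- validate_survival_table(surv_table)
  x <- surv_table[[covariate]]
  if (is.null(x)) abort(sprintf("no column '%s' in survival table", covariate))
  if (!all(is.finite(x))) abort("covariate must be finite")
  if (length(unique(x)) < 2) abort("constant covariate")
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(surv_table$time, surv_table$event) ~ x,
                    ties = "efron"),
    warning = function(w) invokeRestart("muffleWarning"))
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(fit$var)))
  converged <- is.finite(beta) && is.finite(se) && abs(beta) < 20
  if (!converged) {
    warn(sprintf("Cox fit for '%s' did not converge (monotone likelihood / infinite HR)",
                 covariate))
  }
  tibble(covariate = covariate, beta = beta, se = se,
         hr = exp(beta),
         ci_lower = exp(beta - 1.96 * se), ci_upper = exp(beta + 1.96 * se),
         p_value = 2 * pnorm(-abs(beta / se)),
         n = nrow(surv_table), events = sum(surv_table$event),
         converged = converged)
}

#' Screen genes for association with poor prognosis
#'
#' For each gene: a univariate Cox fit of survival on its expression; genes
#' with hazard ratio > 1 and Wald p < 0.05 are kept. Kept genes are then
#' stratified at their median expression (ties to "low") and the high/low
#' groups compared with a log-rank test.
#'
#' @param expr Genes x samples expression matrix.
#' @param surv_table Survival tibble; sample overlap with the matrix must be
#'   >= 10.
#' @param genes Genes to screen (default: all matrix genes).
#' @param hr_min,p_max Selection thresholds.
#' @return Tibble with one row per screened gene: the Cox columns plus
#'   `kept` and, for kept genes, `logrank_chisq`, `logrank_p`.
#' @export
prognosis_screen <- function(expr, surv_table, genes = rownames(expr),
                             hr_min = 1, p_max = 0.05) {
  surv_table <- validate_survival_table(surv_table)
  common <- intersect(colnames(expr), surv_table$sample_id)
  if (length(common) < 10) abort("fewer than 10 samples shared between matrix and survival table")
  st <- surv_table[match(common, surv_table$sample_id), ]
  genes <- intersect(genes, rownames(expr))
  res <- purrr::map(genes, function(g) {
    stg <- mutate(st, expr = expr[g, common])
    cx <- cox_univariate(stg, "expr")
    cx$covariate <- g
    cx
  }) |> bind_rows() |> rename(gene = "covariate")
  res <- mutate(res, kept = .data$hr > hr_min & .data$p_value < p_max & .data$converged)
  res$logrank_chisq <- NA_real_
  res$logrank_p <- NA_real_
  for (g in res$gene[res$kept]) {
    x <- expr[g, common]
    grp <- ifelse(x > median(x), "high", "low")
    if (length(unique(grp)) < 2) next
    lr <- logrank_test(st[grp == "high", ], st[grp == "low", ])
    res$logrank_chisq[res$gene == g] <- lr$chisq
    res$logrank_p[res$gene == g] <- lr$p_value
  }
  res
}
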