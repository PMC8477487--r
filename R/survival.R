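#' Construct a SurvivalTable
#'
#' @param sample_ids character sample identifiers.
#' @param time non-negative follow-up times.
#' @param event 0/1 event indicators (1 = event observed).
#' @param group per-sample group label.
#' @return a \linkS4class{SurvivalTable}.
#' @export
survivalTable <- function(sample_ids, time, event, group) {
  new("SurvivalTable", sample_ids = as.character(sample_ids),
      time = as.numeric(time), event = as.numeric(event),
      group = rep(as.character(group), length.out = length(sample_ids)))
}

#' @describeIn survivalTable the table as a data.frame.
#' @param table a \linkS4class{SurvivalTable}.
#' @export
asSurvivalFrame <- function(table) {
  data.frame(sample_id = table@sample_ids, time = table@time,
             event = table@event, group = table@group,
             stringsAsFactors = FALSE)
}

setMethod("show", "SurvivalTable", function(object) {
  cat("SurvivalTable:", length(object@sample_ids), "subjects,",
      sum(object@event), "events; groups:",
      paste(names(table(object@group)), table(object@group),
            sep = ":", collapse = ", "), "\n")
})

#' Kaplan-Meier survival curve for one group
#'
#' Product-limit estimator with right censoring handled by the standard
#' risk-set construction; simultaneous events at a time point are treated
#' as occurring together. The curve starts at 1 and is non-increasing.
#'
#' @param table a \linkS4class{SurvivalTable}.
#' @param group the group label to estimate (default: all subjects).
#' @return data.frame with columns \code{time}, \code{n_risk},
#'   \code{n_event} and \code{survival} (one row per observed time).
#' @export
kmCurve <- function(table, group = NULL) {
  df <- asSurvivalFrame(table)
  if (!is.null(group)) {
    df <- df[df$group == group, ]
    if (!nrow(df)) stop("no subjects in group '", group, "'")
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = df)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             survival = fit$surv)
}

#' Log-rank test and Mantel-Haenszel hazard ratio for two groups
#'
#' Mantel-Haenszel log-rank statistic over the pooled event times (via
#' \code{survival::survdiff}), with the hazard ratio in O/E form,
#' \deqn{HR = \frac{O_1 / E_1}{O_2 / E_2},}
#' where group 1 is the comparison group and group 2 the reference, and a
#' log-scale 95\% confidence interval using variance
#' \eqn{1/E_1 + 1/E_2}. The p-value is from the chi-square distribution
#' with 1 degree of freedom. Simultaneous events share a risk-set table,
#' matching the KM convention.
#'
#' @param table a \linkS4class{SurvivalTable} with exactly two groups and
#'   at least one event.
#' @param reference the reference (denominator) group; default is the
#'   alphabetically first group label.
#' @return list with \code{chisq}, \code{p_value}, \code{hazard_ratio},
#'   \code{ci_lower}, \code{ci_upper}, \code{observed} and
#'   \code{expected} (both named by group).
#' @export
logrankHr <- function(table, reference = NULL) {
  df <- asSurvivalFrame(table)
  groups <- sort(unique(df$group))
  if (length(groups) != 2)
    stop("log-rank comparison requires exactly 2 groups, got ",
         length(groups))
  if (sum(df$event) < 1)
    stop("log-rank undefined with zero observed events")
  if (is.null(reference)) reference <- groups[1]
  if (!reference %in% groups) stop("unknown reference group: ", reference)
  comparison <- setdiff(groups, reference)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  obs <- setNames(sd$obs, sub("^group=", "", names(sd$n)))
  expd <- setNames(sd$exp, sub("^group=", "", names(sd$n)))
  if (any(expd == 0))
    stop("a group has zero expected events; log-rank undefined")
  hr <- (obs[comparison] / expd[comparison]) /
    (obs[reference] / expd[reference])
  se_log <- sqrt(1 / expd[comparison] + 1 / expd[reference])
  list(chisq = unname(sd$chisq),
       p_value = unname(pchisq(sd$chisq, df = 1, lower.tail = FALSE)),
       hazard_ratio = unname(hr),
       ci_lower = unname(exp(log(hr) - 1.96 * se_log)),
       ci_upper = unname(exp(log(hr) + 1.96 * se_log)),
       observed = obs, expected = expd)
}
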