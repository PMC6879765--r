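#' Split patients at the median of an expression vector
#'
#' Partitions patients into bottom and top strata at the median expression
#' value. Values exactly at the median go to the bottom stratum, which makes
#' the split deterministic and independent of input order.
#'
#' @param expr Tibble with `patient_id` and `value` (one expression value
#'   per patient), or a named numeric vector.
#' @return Tibble `patient_id`, `value`, `stratum` (`"bottom"`/`"top"`).
#' @export
median_split <- function(expr) {
  if (is.numeric(expr) && !is.null(names(expr))) {
    expr <- tibble::tibble(patient_id = names(expr), value = unname(expr))
  }
  expr <- tibble::as_tibble(expr)
  if (nrow(expr) < 2) abort("need at least 2 patients to split")
  med <- median(expr$value)
  if (all(expr$value == expr$value[1])) {
    abort("constant expression: no median split possible")
  }
  expr$stratum <- ifelse(expr$value <= med, "bottom", "top")
  if (length(unique(expr$stratum)) < 2) {
    abort("degenerate split: all values on one side of the median")
  }
  expr
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator for one stratum: censored subjects leave the risk
#' set without producing a step.
#'
#' @param time Follow-up times (days, non-negative).
#' @param event Logical/0-1 event indicators (`TRUE` = death observed).
#' @return Tibble with one row per distinct event/censoring time: `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`.
#' @export
km_estimate <- function(time, event) {
  if (any(time < 0, na.rm = TRUE)) abort("negative survival times")
  if (length(time) == 0) abort("empty stratum")
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1)
  tibble::tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                 n_censor = fit$n.censor, survival = fit$surv)
}

#' Two-group log-rank test
#'
#' @param time Follow-up times.
#' @param event Event indicators.
#' @param group Two-level grouping vector.
#' @return Tibble `statistic` (chi-squared, 1 df), `df`, `p_value`.
#' @export
logrank_test <- function(time, event, group) {
  if (any(time < 0, na.rm = TRUE)) abort("negative survival times")
  group <- factor(group)
  if (nlevels(group) != 2) abort("exactly two strata required")
  ev <- as.integer(event)
  if (sum(ev) == 0) abort("no events in either stratum")
  if (any(tapply(ev, group, sum) == 0)) {
    warn("a stratum has no events; the log-rank test may be degenerate")
  }
  sd_fit <- survival::survdiff(survival::Surv(time, ev) ~ group)
  df <- length(sd_fit$n) - 1
  tibble::tibble(statistic = sd_fit$chisq, df = df,
                 p_value = pchisq(sd_fit$chisq, df, lower.tail = FALSE))
}

# administrative truncation at a follow-up horizon: later times are censored
# at the horizon
truncate_followup <- function(time, event, horizon_days) {
  over <- !is.na(time) & time > horizon_days
  event[over] <- FALSE
  time[over] <- horizon_days
  list(time = time, event = event)
}

#' Survival stratified by TP53 status
#'
#' Kaplan-Meier curves and a log-rank comparison for wild-type versus
#' TP53-mutant patients, with follow-up truncated at a horizon. Patients
#' with unknown status are excluded.
#'
#' @param clinical Clinical tibble with `tp53_status`, `os_time` (days),
#'   `os_event`.
#' @param horizon_years Follow-up horizon, default 14 years.
#' @return Object of class `xd_survfit`: `curves` (per-stratum KM tibble),
#'   `test` (log-rank tibble), `strata_n` (named sizes).
#' @export
survival_by_tp53 <- function(clinical, horizon_years = 14) {
  d <- dplyr::filter(clinical, .data$tp53_status %in% c("wt", "mutant"),
                     !is.na(.data$os_time), !is.na(.data$os_event))
  if (nrow(d) == 0) abort("no patients with known TP53 status and follow-up")
  tr <- truncate_followup(d$os_time, d$os_event, horizon_years * 365)
  d$os_time <- tr$time; d$os_event <- tr$event
  curves <- dplyr::bind_rows(lapply(split(d, d$tp53_status), function(s) {
    km <- km_estimate(s$os_time, s$os_event)
    km$stratum <- s$tp53_status[1]
    km
  }))
  structure(list(curves = curves,
                 test = logrank_test(d$os_time, d$os_event, d$tp53_status),
                 strata_n = table(d$tp53_status)),
            class = "xd_survfit")
}

#' Survival stratified by top/bottom median expression of a gene
#'
#' Splits patients of each cancer type at the median expression of one gene
#' ([median_split()]), estimates Kaplan-Meier curves for the top and bottom
#' strata and compares them with a log-rank test. By default runs within
#' each cancer type separately (expression scales are cancer-specific);
#' `by_cancer = FALSE` pools all patients. Restrict to a TP53 context with
#' `tp53`.
#'
#' @param clinical Clinical tibble.
#' @param expression Matrix (genes x samples) of expression values (e.g.
#'   CPM), columns named by patient.
#' @param gene Gene symbol to stratify on.
#' @param horizon_years Follow-up horizon, default 10 years.
#' @param tp53 Optional TP53 context filter: `"wt"`, `"mutant"` or `NULL`
#'   (no filter).
#' @param by_cancer Split within each cancer type, default `TRUE`.
#' @return Tibble with one row per analysed cohort: `cancer_type`, `n`,
#'   `statistic`, `df`, `p_value`, plus a `curves` list-column of KM
#'   tibbles.
#' @export
survival_by_expression <- function(clinical, expression, gene,
                                   horizon_years = 10, tp53 = "wt",
                                   by_cancer = TRUE) {
  if (!gene %in% rownames(expression)) abort(paste0("gene not in matrix: ", gene))
  d <- dplyr::filter(clinical, !is.na(.data$os_time), !is.na(.data$os_event),
                     .data$patient_id %in% colnames(expression))
  if (!is.null(tp53)) d <- dplyr::filter(d, .data$tp53_status == tp53)
  if (nrow(d) == 0) abort("no patients left after filtering")
  groups <- if (by_cancer) split(d, d$cancer_type) else list(pooled = d)
  out <- lapply(names(groups), function(ct) {
    s <- groups[[ct]]
    if (nrow(s) < 4) return(NULL)
    sp <- median_split(tibble::tibble(
      patient_id = s$patient_id,
      value = expression[gene, s$patient_id]))
    s <- dplyr::inner_join(s, sp, by = "patient_id")
    tr <- truncate_followup(s$os_time, s$os_event, horizon_years * 365)
    s$os_time <- tr$time; s$os_event <- tr$event
    if (sum(s$os_event) == 0) return(NULL)
    lr <- logrank_test(s$os_time, s$os_event, s$stratum)
    curves <- dplyr::bind_rows(lapply(split(s, s$stratum), function(g) {
      km <- km_estimate(g$os_time, g$os_event)
      km$stratum <- g$stratum[1]
      km
    }))
    tibble::tibble(cancer_type = ct, n = nrow(s),
                   statistic = lr$statistic, df = lr$df,
                   p_value = lr$p_value, curves = list(curves))
  })
  dplyr::bind_rows(out)
}

#' @export
print.xd_survfit <- function(x, ...) {
  cat("<xd_survfit> strata:",
      paste(names(x$strata_n), x$strata_n, sep = "=", collapse = ", "),
      "| log-rank p =", signif(x$test$p_value, 3), "\n")
  invisible(x)
}

#' @rdname survival_by_tp53
#' @param x An `xd_survfit` object.
#' @param ... Unused.
#' @export
tidy.xd_survfit <- function(x, ...) x$curves

#' @rdname survival_by_tp53
#' @export
glance.xd_survfit <- function(x, ...) {
  tibble::tibble(statistic = x$test$statistic, df = x$test$df,
                 p_value = x$test$p_value,
                 n = sum(x$strata_n))
}
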