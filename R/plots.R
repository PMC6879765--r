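#' Kaplan-Meier step curves
#'
#' @param object An `xd_survfit` from [survival_by_tp53()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.xd_survfit <- function(object, ...) {
  d <- dplyr::bind_rows(lapply(split(object$curves, object$curves$stratum),
                               function(s) {
    tibble::tibble(time = c(0, s$time), survival = c(1, s$survival),
                   stratum = s$stratum[1])
  }))
  ggplot2::ggplot(d, ggplot2::aes(.data$time / 365, .data$survival,
                                  colour = .data$stratum)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Years", y = "Overall survival", colour = NULL,
                  subtitle = paste0("log-rank p = ",
                                    signif(object$test$p_value, 3))) +
    ggplot2::theme_minimal()
}

#' Love plot of covariate balance before/after weighting
#'
#' @param object An `xd_propensity` from [balance_loop()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.xd_propensity <- function(object, ...) {
  d <- tidyr::pivot_longer(object$balance, c("smd_before", "smd_after"),
                           names_to = "stage", values_to = "smd")
  d$stage <- factor(d$stage, c("smd_before", "smd_after"),
                    c("before", "after"))
  ggplot2::ggplot(d, ggplot2::aes(abs(.data$smd), .data$covariate,
                                  colour = .data$stage)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$smd_threshold, linetype = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$cancer_type)) +
    ggplot2::labs(x = "|SMD|", y = NULL, colour = "weighting") +
    ggplot2::theme_minimal()
}

#' Volcano plot of per-gene NEM sex-disparity tests
#'
#' Relative NEM incidence (log2 female/male weighted NEM proportion) against
#' significance, designated-set genes highlighted.
#'
#' @param tests An `xd_gene_tests` tibble from [gene_nem_tests()].
#' @param gene_set Optional character vector of designated-set genes.
#' @return A ggplot object.
#' @export
plot_volcano <- function(tests, gene_set = NULL) {
  d <- dplyr::filter(tests, .data$testable, is.finite(.data$log2_fm))
  d$in_set <- if (is.null(gene_set)) FALSE else d$gene %in% gene_set
  ggplot2::ggplot(d, ggplot2::aes(.data$log2_fm, .data$neg_log10_p,
                                  colour = .data$in_set,
                                  shape = .data$significant)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17)) +
    ggplot2::labs(x = "log2 ratio (F/M) of NEM proportion",
                  y = "-log10(p)", colour = "designated set",
                  shape = "adj p <= 0.05") +
    ggplot2::theme_minimal()
}

#' RMAF distribution by sex
#'
#' @param records An `xd_rmaf` tibble from [rmaf_table()].
#' @return A ggplot object (boxplot of gene-level RMAF by sex).
#' @export
plot_rmaf_distribution <- function(records) {
  d <- dplyr::filter(records, .data$selected, !is.na(.data$rmaf))
  ggplot2::ggplot(d, ggplot2::aes(.data$sex, .data$rmaf, fill = .data$sex)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.3) +
    ggplot2::scale_fill_manual(values = c(female = "#e8638c",
                                          male = "#4e79c4"), guide = "none") +
    ggplot2::labs(x = NULL, y = "RMAF") +
    ggplot2::theme_minimal()
}
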