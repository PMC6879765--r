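#' Pearson chi-squared statistic on a weighted 2x2 table
#'
#' Cells are sums of per-patient analysis weights rather than raw counts, so
#' no continuity correction is applied (half-unit corrections are undefined
#' for non-integer cells). With unit weights the statistic reduces exactly
#' to the textbook chi-squared.
#'
#' @param tab 2x2 numeric matrix of weighted cell totals.
#' @return List with `statistic`, `df` (1), `p_value`, `expected`.
#' @export
weighted_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0)) {
    abort("tab must be a non-negative 2x2 matrix")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("zero marginal row/column: table is untestable")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  list(statistic = stat, df = 1L,
       p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       expected = expected)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement
#' (delegates to [stats::p.adjust()]).
#'
#' @param p P-values in `[0, 1]`.
#' @return Adjusted p-values of the same length.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Signed chi-score
#'
#' The signed square root of a 1-df chi-squared statistic: positive when the
#' (weighted) NEM proportion is larger in females than males, negative
#' otherwise. Under the per-gene null these scores are asymptotically
#' standard normal.
#'
#' @param statistic Chi-squared statistic(s), 1 df.
#' @param nem_prop_f,nem_prop_m Weighted NEM proportions by sex.
#' @return Signed score(s).
#' @export
chi_score <- function(statistic, nem_prop_f, nem_prop_m) {
  ifelse(nem_prop_f > nem_prop_m, 1, -1) * sqrt(statistic)
}

#' Per-gene weighted chi-squared NEM tests
#'
#' For every gene with classified (NEM or EM) mutation records in both
#' sexes, tests the null of no association between patient sex and the
#' expression status of the gene's mutations, on a 2x2 table whose cells
#' are sums of propensity matching weights. Genes with mutations in only
#' one sex, or with a zero weighted margin, are marked untestable and
#' excluded from the Benjamini-Hochberg family.
#'
#' @param records `xd_rmaf` records ([rmaf_table()]); only selected records
#'   with status NEM or EM enter (intermediates are excluded from both
#'   classes).
#' @param weights Weights tibble with `patient_id` and `w` (e.g.
#'   `balance_loop(...)$weights`); missing patients default to weight 1.
#' @return Tibble of class `xd_gene_tests`, one row per gene: weighted cell
#'   totals (`w_nem_f`, `w_em_f`, `w_nem_m`, `w_em_m`), unweighted counts
#'   (`n_nem_f`, `n_nem_m`), `chi2_stat`, `p_value`, `adj_p`, `chi_score`,
#'   `log2_fm` (log2 ratio of weighted female vs male NEM proportion),
#'   `neg_log10_p`, `testable`, `significant` (`adj_p <= 0.05`).
#' @export
gene_nem_tests <- function(records, weights = NULL) {
  live <- dplyr::filter(records, .data$selected,
                        .data$status %in% c("NEM", "EM"))
  if (nrow(live) == 0) abort("no NEM/EM records to test")
  if (is.null(weights)) {
    live$w <- 1
  } else {
    live <- dplyr::left_join(live,
                             dplyr::select(weights, "patient_id", "w"),
                             by = "patient_id")
    live$w[is.na(live$w)] <- 1
  }
  per_gene <- dplyr::summarise(
    dplyr::group_by(live, .data$gene),
    w_nem_f = sum(.data$w[.data$status == "NEM" & .data$sex == "female"]),
    w_em_f = sum(.data$w[.data$status == "EM" & .data$sex == "female"]),
    w_nem_m = sum(.data$w[.data$status == "NEM" & .data$sex == "male"]),
    w_em_m = sum(.data$w[.data$status == "EM" & .data$sex == "male"]),
    n_nem_f = sum(.data$status == "NEM" & .data$sex == "female"),
    n_nem_m = sum(.data$status == "NEM" & .data$sex == "male"),
    n_f = sum(.data$sex == "female"),
    n_m = sum(.data$sex == "male"),
    .groups = "drop")

  wf <- per_gene$w_nem_f + per_gene$w_em_f
  wm <- per_gene$w_nem_m + per_gene$w_em_m
  w_nem <- per_gene$w_nem_f + per_gene$w_nem_m
  w_em <- per_gene$w_em_f + per_gene$w_em_m
  per_gene$testable <- per_gene$n_f > 0 & per_gene$n_m > 0 &
    wf > 0 & wm > 0 & w_nem > 0 & w_em > 0

  stat <- rep(NA_real_, nrow(per_gene))
  for (i in which(per_gene$testable)) {
    tab <- matrix(c(per_gene$w_nem_f[i], per_gene$w_em_f[i],
                    per_gene$w_nem_m[i], per_gene$w_em_m[i]),
                  nrow = 2, byrow = TRUE)
    stat[i] <- weighted_chi2(tab)$statistic
  }
  per_gene$chi2_stat <- stat
  per_gene$p_value <- pchisq(stat, 1, lower.tail = FALSE)
  per_gene$adj_p <- NA_real_
  per_gene$adj_p[per_gene$testable] <- bh_adjust(per_gene$p_value[per_gene$testable])
  prop_f <- per_gene$w_nem_f / wf
  prop_m <- per_gene$w_nem_m / wm
  per_gene$chi_score <- chi_score(per_gene$chi2_stat, prop_f, prop_m)
  per_gene$log2_fm <- log2(prop_f / prop_m)
  per_gene$neg_log10_p <- -log10(per_gene$p_value)
  per_gene$significant <- !is.na(per_gene$adj_p) & per_gene$adj_p <= 0.05
  class(per_gene) <- c("xd_gene_tests", class(per_gene))
  per_gene
}

#' Compare chi-scores of a gene set against the remaining genes
#'
#' Two-sided Wilcoxon rank-sum test on the signed chi-scores of a designated
#' gene set versus all other (X-chromosome) genes, asking whether the set's
#' sex-disparity signal is shifted relative to the background.
#'
#' @param chi_scores Numeric vector of signed chi-scores.
#' @param in_set Logical vector, `TRUE` for designated-set genes.
#' @return Tibble with `n_set`, `n_rest`, `statistic`, `p_value`.
#' @export
set_vs_rest <- function(chi_scores, in_set) {
  keep <- is.finite(chi_scores)
  chi_scores <- chi_scores[keep]; in_set <- in_set[keep]
  if (sum(in_set) == 0 || sum(!in_set) == 0) {
    abort("both the set and the rest must be non-empty")
  }
  wt <- suppressWarnings(wilcox.test(chi_scores[in_set], chi_scores[!in_set],
                                     alternative = "two.sided", exact = FALSE))
  tibble::tibble(n_set = sum(in_set), n_rest = sum(!in_set),
                 statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Per-patient mutation counts for a burden model
#'
#' @param mutations Mutation tibble (class-filtered as appropriate).
#' @param clinical Clinical tibble; every patient appears in the output,
#'   with zero counts where no mutation passes the scope.
#' @param scope `"genome_minus_Y"` (all chromosomes but Y), `"X_only"`, or
#'   `"gene_set"` (restrict to `gene_set`).
#' @param gene_set Character vector of genes, required for
#'   `scope = "gene_set"`.
#' @return Tibble `patient_id`, `sex`, `cancer_type`, `n_mut`.
#' @export
mutation_burden <- function(mutations, clinical,
                            scope = c("genome_minus_Y", "X_only", "gene_set"),
                            gene_set = NULL) {
  scope <- match.arg(scope)
  mut <- switch(scope,
                genome_minus_Y = dplyr::filter(mutations, .data$chrom != "Y"),
                X_only = dplyr::filter(mutations, .data$chrom == "X"),
                gene_set = {
                  if (is.null(gene_set)) abort("gene_set required for scope = 'gene_set'")
                  dplyr::filter(mutations, .data$chrom == "X",
                                .data$gene %in% gene_set)
                })
  counts <- dplyr::count(mut, .data$patient_id, name = "n_mut")
  out <- dplyr::left_join(dplyr::select(clinical, "patient_id", "sex",
                                        "cancer_type"),
                          counts, by = "patient_id")
  out$n_mut[is.na(out$n_mut)] <- 0L
  out
}

#' Poisson log-linear mutation-burden model
#'
#' Weighted Poisson regression of per-patient mutation counts on sex. The
#' reported rate ratio is female versus male (`exp` of the sex coefficient,
#' male reference) with a Wald 95% confidence interval.
#'
#' @param burden Tibble from [mutation_burden()] (columns `patient_id`,
#'   `sex`, `n_mut`).
#' @param weights Optional weights tibble (`patient_id`, `w`); omitted means
#'   unweighted.
#' @param scope Label carried through to the result.
#' @return Object of class `xd_burden`: `rate_ratio`, `ci95`, `p_value`,
#'   `scope`, `n`, and the fitted `model`.
#' @export
burden_model <- function(burden, weights = NULL, scope = "genome_minus_Y") {
  if (length(unique(burden$sex)) < 2) abort("both sexes required for a rate ratio")
  if (all(burden$n_mut == 0)) abort("all mutation counts are zero")
  d <- burden
  d$sex <- factor(d$sex, levels = c("male", "female"))
  if (!is.null(weights)) {
    d <- dplyr::left_join(d, dplyr::select(weights, "patient_id", "w"),
                          by = "patient_id")
    d$w[is.na(d$w)] <- 1
  } else {
    d$w <- 1
  }
  fit <- suppressWarnings(glm(n_mut ~ sex, data = d, family = poisson(),
                              weights = d$w))
  beta <- coef(fit)[["sexfemale"]]
  se <- sqrt(diag(stats::vcov(fit)))[["sexfemale"]]
  z <- beta / se
  structure(list(rate_ratio = exp(beta),
                 ci95 = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
                 p_value = 2 * pnorm(-abs(z)),
                 scope = scope, n = nrow(d), model = fit),
            class = "xd_burden")
}

#' @export
print.xd_burden <- function(x, ...) {
  cat("<xd_burden> scope ", x$scope, ": female/male rate ratio ",
      signif(x$rate_ratio, 4), " (95% CI ", signif(x$ci95[1], 4), "-",
      signif(x$ci95[2], 4), "), n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' @rdname burden_model
#' @param x An `xd_burden` object.
#' @param ... Unused.
#' @export
tidy.xd_burden <- function(x, ...) {
  tibble::tibble(term = "sexfemale", estimate = x$rate_ratio,
                 conf.low = x$ci95[1], conf.high = x$ci95[2],
                 p.value = x$p_value)
}

#' @rdname burden_model
#' @export
glance.xd_burden <- function(x, ...) {
  tibble::tibble(rate_ratio = x$rate_ratio, conf.low = x$ci95[1],
                 conf.high = x$ci95[2], p.value = x$p_value,
                 scope = x$scope, nobs = x$n)
}

#' Logit-scale sex comparison of RMAF values
#'
#' Linear model of `logit(RMAF)` on sex with cancer-type adjustment, RMAF
#' clipped to `[eps, 1 - eps]` so boundary values (fully silenced or fully
#' expressed mutations) remain finite. A negative female coefficient means
#' female mutations are less expressed.
#'
#' @param records `xd_rmaf` records; selected, non-discarded rows are used.
#' @param eps Clipping bound, default 0.01.
#' @return Tibble with the female coefficient: `estimate`, `std_error`,
#'   `p_value`, `n`.
#' @export
rmaf_sex_compare <- function(records, eps = 0.01) {
  d <- dplyr::filter(records, .data$selected, !is.na(.data$rmaf))
  if (nrow(d) == 0) abort("no RMAF values to compare")
  d$y <- qlogis(pmin(pmax(d$rmaf, eps), 1 - eps))
  d$sex <- factor(d$sex, levels = c("male", "female"))
  fml <- if (length(unique(d$cancer_type)) > 1) y ~ sex + cancer_type else y ~ sex
  fit <- lm(fml, data = d)
  sm <- suppressWarnings(summary(fit))$coefficients["sexfemale", ]
  tibble::tibble(estimate = sm[["Estimate"]], std_error = sm[["Std. Error"]],
                 p_value = sm[["Pr(>|t|)"]], n = nrow(d))
}

#' Correlation between gene size and NEM count
#'
#' Pearson correlation testing whether non-expressed mutations accumulate
#' simply as a function of gene length (the random-inactivation expectation
#' under uniform mutation placement).
#'
#' @param gene_lengths,nem_counts Numeric vectors, matched by position, at
#'   least 3 genes.
#' @return Tibble `r`, `p_value`, `n`; `r` is `NA` when either vector has
#'   zero variance.
#' @export
size_nem_correlation <- function(gene_lengths, nem_counts) {
  if (length(gene_lengths) != length(nem_counts) || length(gene_lengths) < 3) {
    abort("need at least 3 matched genes")
  }
  if (sd(gene_lengths) == 0 || sd(nem_counts) == 0) {
    return(tibble::tibble(r = NA_real_, p_value = NA_real_,
                          n = length(gene_lengths)))
  }
  ct <- cor.test(gene_lengths, nem_counts, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(gene_lengths))
}
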