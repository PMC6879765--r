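#' Matching weights from propensity scores
#'
#' The matching-weight scheme emulates 1:1 matching while keeping every
#' subject: with `e` the estimated probability of being male given
#' covariates, a male patient receives `min(e, 1-e) / e` and a female
#' patient `min(e, 1-e) / (1-e)`. Weights are bounded by 1 and equal 1
#' exactly when `e = 0.5`.
#'
#' @param e Propensity scores in (0, 1).
#' @param sex `"female"` / `"male"` per patient.
#' @return Numeric weights in (0, 1].
#' @export
matching_weights <- function(e, sex) {
  if (any(e <= 0 | e >= 1)) abort("propensity scores must lie strictly in (0, 1)")
  pr_observed <- ifelse(sex == "male", e, 1 - e)
  pmin(e, 1 - e) / pr_observed
}

# build the model frame: missing categoricals become an explicit level,
# missing ages are median-imputed
prep_covariates <- function(df, covariates) {
  for (cv in covariates) {
    x <- df[[cv]]
    if (is.numeric(x)) {
      x[is.na(x)] <- median(x, na.rm = TRUE)
    } else {
      x <- as.character(x)
      x[is.na(x) | x == ""] <- "(missing)"
      x <- factor(x)
    }
    df[[cv]] <- x
  }
  df
}

fit_ps_model <- function(df, formula) {
  fit <- suppressWarnings(glm(formula, data = df, family = binomial()))
  e <- fitted(fit)
  y <- df$is_male
  # complete separation: the linear predictor classifies the sexes perfectly
  if (sum(y) > 0 && sum(1 - y) > 0 && min(e[y == 1]) > max(e[y == 0])) {
    abort(paste0("propensity model separates the sexes completely; ",
                 "remove a covariate or coarsen its levels"))
  }
  # individual pinned scores are tolerable (their matching weight -> 0);
  # clamp so downstream ratios stay finite
  pmin(pmax(e, 1e-6), 1 - 1e-6)
}

#' Fit sex propensity scores by logistic regression
#'
#' Models the probability of being male given the clinical covariates,
#' separately within each cancer type (cohort composition differs by
#' disease). Missing categorical values form an explicit `"(missing)"`
#' level; missing ages are median-imputed within the cancer.
#'
#' @param clinical Clinical tibble.
#' @param covariates Covariate column names, default
#'   `c("age", "race", "smoking", "stage")`.
#' @return Tibble `patient_id`, `cancer_type`, `sex`, `e`.
#' @export
fit_propensity <- function(clinical,
                           covariates = c("age", "race", "smoking", "stage")) {
  missing_cov <- setdiff(covariates, names(clinical))
  if (length(missing_cov) > 0) {
    abort(paste0("covariate(s) not in clinical table: ",
                 paste(missing_cov, collapse = ", ")))
  }
  fml <- stats::as.formula(paste("is_male ~", paste(covariates, collapse = " + ")))
  res <- lapply(split(clinical, clinical$cancer_type), function(d) {
    if (min(table(factor(d$sex, sex_levels))) < 2) {
      abort("need at least 2 patients of each sex per cancer type")
    }
    d <- prep_covariates(d, covariates)
    d$is_male <- as.integer(d$sex == "male")
    keep <- covariates[vapply(covariates, function(cv)
      is.numeric(d[[cv]]) || nlevels(d[[cv]]) > 1, logical(1))]
    f <- if (length(keep) > 0) {
      stats::as.formula(paste("is_male ~", paste(keep, collapse = " + ")))
    } else stats::as.formula("is_male ~ 1")
    tibble::tibble(patient_id = d$patient_id, cancer_type = d$cancer_type,
                   sex = d$sex, e = unname(fit_ps_model(d, f)))
  })
  dplyr::bind_rows(res)
}

#' Weighted standardized mean difference
#'
#' `(weighted mean in males - weighted mean in females) / pooled unweighted
#' SD`, the conventional covariate-balance diagnostic. A covariate with zero
#' pooled SD is balanced by definition (SMD 0). Factors are one-hot encoded
#' and the largest absolute level-wise SMD is returned.
#'
#' @param x Covariate vector (numeric or categorical).
#' @param sex `"female"` / `"male"` per observation.
#' @param weights Analysis weights, default unweighted.
#' @return A single SMD (signed for numeric covariates; for categoricals the
#'   level-wise SMD of largest magnitude).
#' @export
smd <- function(x, sex, weights = rep(1, length(x))) {
  if (!is.numeric(x)) {
    lv <- levels(factor(x))
    if (length(lv) < 2) return(0)
    smds <- vapply(lv, function(l) smd(as.numeric(x == l), sex, weights),
                   numeric(1))
    return(smds[which.max(abs(smds))])
  }
  m <- sex == "male"
  s_pool <- sqrt((var(x[m]) + var(x[!m])) / 2)
  if (!is.finite(s_pool) || s_pool == 0) return(0)
  wm <- sum(weights[m] * x[m]) / sum(weights[m])
  wf <- sum(weights[!m] * x[!m]) / sum(weights[!m])
  (wm - wf) / s_pool
}

balance_rows <- function(df, covariates, w_before, w_after) {
  rows <- list()
  for (cv in covariates) {
    x <- df[[cv]]
    rows[[cv]] <- tibble::tibble(
      covariate = cv,
      smd_before = smd(x, df$sex, w_before),
      smd_after = smd(x, df$sex, w_after))
    if (is.numeric(x)) {
      # second-moment balance: mean balance alone cannot see variance-only
      # (nonlinear) confounding
      rows[[paste0(cv, "^2")]] <- tibble::tibble(
        covariate = paste0(cv, "^2"),
        smd_before = smd(x^2, df$sex, w_before),
        smd_after = smd(x^2, df$sex, w_after))
    }
  }
  dplyr::bind_rows(rows)
}

# formula for a given iteration: 1 = main effects; 2 adds squares of
# unbalanced numeric covariates; >= 3 also adds pairwise interactions
# involving any unbalanced covariate
iteration_formula <- function(covariates, unbalanced, iteration, numeric_cov) {
  terms <- covariates
  bad <- intersect(sub("\\^2$", "", unbalanced), covariates)
  if (iteration >= 2) {
    sq <- intersect(bad, numeric_cov)
    if (iteration >= 4) sq <- numeric_cov
    if (length(sq) > 0) terms <- c(terms, paste0("I(", sq, "^2)"))
  }
  if (iteration >= 3 && length(bad) > 0) {
    pairs <- expand.grid(a = bad, b = covariates, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$a != pairs$b, ]
    key <- apply(pairs, 1, function(r) paste(sort(r), collapse = ":"))
    terms <- c(terms, unique(key))
  }
  stats::as.formula(paste("is_male ~", paste(unique(terms), collapse = " + ")))
}

#' Propensity balance loop
#'
#' Fits the sex-propensity model, derives matching weights, and checks the
#' weighted standardized mean difference of every covariate (plus the square
#' of each numeric covariate). If any |SMD| is at or above the threshold,
#' the model is revised — iteration 2 adds squared terms for the unbalanced
#' numeric covariates, iteration 3 adds pairwise interactions involving
#' unbalanced covariates, iteration 4 adds all squared terms — and the check
#' repeats, up to `max_iter` rounds per cancer type. Failure to balance is
#' flagged in the report, never silent.
#'
#' @param clinical Clinical tibble.
#' @param covariates Covariate names, default
#'   `c("age", "race", "smoking", "stage")`.
#' @param max_iter Maximum revision rounds, default 5.
#' @param smd_threshold Balance criterion, default 0.1 on |SMD|.
#' @return A list of class `xd_propensity`: `weights` (tibble `patient_id`,
#'   `cancer_type`, `sex`, `e`, `w`, `iteration`), `balance` (tibble
#'   `cancer_type`, `covariate`, `smd_before`, `smd_after`, `balanced`),
#'   and `converged` (logical, all cancers balanced).
#' @export
balance_loop <- function(clinical,
                         covariates = c("age", "race", "smoking", "stage"),
                         max_iter = 5, smd_threshold = 0.1) {
  if (max_iter < 1) abort("max_iter must be at least 1")
  res_w <- list(); res_b <- list()
  for (ct in unique(clinical$cancer_type)) {
    d <- prep_covariates(dplyr::filter(clinical, .data$cancer_type == ct),
                         covariates)
    d$is_male <- as.integer(d$sex == "male")
    numeric_cov <- covariates[vapply(covariates, function(cv)
      is.numeric(d[[cv]]), logical(1))]
    usable <- covariates[vapply(covariates, function(cv)
      is.numeric(d[[cv]]) || nlevels(factor(d[[cv]])) > 1, logical(1))]
    w1 <- rep(1, nrow(d))
    unbalanced <- character(0)
    for (it in seq_len(max_iter)) {
      f <- iteration_formula(usable, unbalanced, it, numeric_cov)
      # a revision that overfits to separation keeps the previous model
      e_try <- tryCatch(fit_ps_model(d, f), error = function(cnd) cnd)
      if (rlang::is_condition(e_try)) {
        if (it == 1) {
          # main-effects model separates (small stratum / perfect
          # predictor): back off covariates from the end until it fits
          for (k in rev(seq_len(length(usable) - 1))) {
            f <- iteration_formula(usable[seq_len(k)], character(0), 1,
                                   numeric_cov)
            e_try <- tryCatch(fit_ps_model(d, f), error = function(cnd) cnd)
            if (!rlang::is_condition(e_try)) break
          }
          if (rlang::is_condition(e_try)) {
            e_try <- rep(mean(d$is_male), nrow(d))
          }
          e <- e_try
          w <- matching_weights(e, d$sex)
          bal <- balance_rows(d, usable, w1, w)
          unbalanced <- bal$covariate[abs(bal$smd_after) >= smd_threshold]
          if (length(unbalanced) == 0) break else next
        }
        it <- it - 1
        break
      }
      e <- e_try
      w <- matching_weights(e, d$sex)
      bal <- balance_rows(d, usable, w1, w)
      unbalanced <- bal$covariate[abs(bal$smd_after) >= smd_threshold]
      if (length(unbalanced) == 0 || it == max_iter) break
    }
    res_w[[ct]] <- tibble::tibble(patient_id = d$patient_id, cancer_type = ct,
                                  sex = d$sex, e = unname(e), w = unname(w),
                                  iteration = it)
    bal$cancer_type <- ct
    bal$balanced <- abs(bal$smd_after) < smd_threshold
    res_b[[ct]] <- dplyr::select(bal, "cancer_type", "covariate",
                                 "smd_before", "smd_after", "balanced")
  }
  balance <- dplyr::bind_rows(res_b)
  out <- structure(list(weights = dplyr::bind_rows(res_w),
                        balance = balance,
                        converged = all(balance$balanced),
                        smd_threshold = smd_threshold),
                   class = "xd_propensity")
  if (!out$converged) {
    warn(paste0("covariates not balanced after the revision loop: ",
                paste(unique(balance$covariate[!balance$balanced]),
                      collapse = ", ")))
  }
  out
}

#' @export
print.xd_propensity <- function(x, ...) {
  cat("<xd_propensity> ", nrow(x$weights), " patients, ",
      length(unique(x$weights$cancer_type)), " cancer type(s); ",
      if (x$converged) "all covariates balanced" else "NOT balanced",
      " (|SMD| < ", x$smd_threshold, ")\n", sep = "")
  invisible(x)
}

#' @rdname balance_loop
#' @param x An `xd_propensity` object.
#' @param ... Unused.
#' @export
tidy.xd_propensity <- function(x, ...) x$weights

#' @rdname balance_loop
#' @export
glance.xd_propensity <- function(x, ...) {
  tibble::tibble(n = nrow(x$weights),
                 n_cancer_types = length(unique(x$weights$cancer_type)),
                 max_abs_smd = max(abs(x$balance$smd_after)),
                 converged = x$converged)
}
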