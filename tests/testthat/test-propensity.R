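confounded_clinical <- function(n = 400, seed = 17, nonlinear = FALSE) {
  withr::with_seed(seed, {
    if (nonlinear) {
      # purely quadratic confounding: sex probability depends on (age-63)^2,
      # so first moments agree but second moments do not
      age <- rnorm(n, 63, 12)
      male <- runif(n) < stats::plogis(0.025 * (age - 63)^2 - 2.2)
      sex <- ifelse(male, "male", "female")
    } else {
      sex <- rep(c("female", "male"), each = n / 2)
      male <- sex == "male"
      age <- rnorm(n, 63 + 4 * male, 9)
    }
    smoking <- ifelse(runif(n) < ifelse(male, 0.6, 0.3), "ever", "never")
    tibble::tibble(
      patient_id = sprintf("C%04d", seq_len(n)), sex = sex,
      cancer_type = "TST", age = age, race = "white", smoking = smoking,
      stage = sample(c("I", "II", "III"), n, replace = TRUE),
      tp53_status = "wt", os_time = NA_real_, os_event = NA)
  })
}

test_that("matching weights follow the min(e, 1-e) scheme and its bounds", {
  expect_equal(matching_weights(0.5, "male"), 1)
  expect_equal(matching_weights(0.5, "female"), 1)
  expect_equal(matching_weights(0.8, "male"), 0.25)
  expect_equal(matching_weights(0.8, "female"), 1)
  expect_error(matching_weights(1, "male"), "strictly")

  e <- runif(500, 0.01, 0.99)
  w_m <- matching_weights(e, rep("male", 500))
  w_f <- matching_weights(e, rep("female", 500))
  expect_true(all(w_m <= 1 & w_f <= 1 & w_m > 0 & w_f > 0))
  # both sexes attain the bound together only at e = 0.5
  expect_true(all(!(w_m == 1 & w_f == 1) | e == 0.5))
  expect_equal(pmin(w_m, w_f), pmin(e, 1 - e) / pmax(e, 1 - e))
  # relabeling the sexes maps e -> 1-e and leaves each weight unchanged
  expect_equal(matching_weights(1 - e, rep("female", 500)), w_m)
})

test_that("SMD matches hand arithmetic and handles degenerate covariates", {
  x <- c(1, 2, 3, 4, 5, 6)
  sex <- rep(c("male", "female"), each = 3)
  w <- rep(1, 6)
  # hand: mean_M = 2, mean_F = 5, pooled sd = sqrt((1 + 1)/2) = 1
  expect_equal(smd(x, sex, w), -3)
  expect_equal(smd(rep(2, 6), sex, w), 0)
  expect_equal(smd(x, sex, c(0.5, 1, 0.5, 1, 0.5, 1)),
               ((0.5 * 1 + 2 + 0.5 * 3) / 2 - (1 * 4 + 0.5 * 5 + 6) / 2.5) / 1)
  expect_equal(smd(c("a", "a", "a", "a", "a", "a"), sex, w), 0)
})

test_that("propensity fit recovers a null and a known confounding slope", {
  cl <- confounded_clinical(600, seed = 71)
  cl$age <- rnorm(600, 63, 9)          # break the age link
  cl$smoking <- sample(cl$smoking)     # and the smoking link
  ps <- fit_propensity(cl)
  expect_true(all(ps$e > 0 & ps$e < 1))
  expect_lt(max(abs(ps$e - 0.5)), 0.2)
  expect_equal(mean(ps$e), 0.5, tolerance = 0.02)

  withr::local_seed(72)
  n <- 2000
  age <- rnorm(n, 63, 9)
  slope <- 0.08
  male <- runif(n) < stats::plogis(slope * (age - 63))
  cl2 <- tibble::tibble(patient_id = sprintf("S%04d", 1:n),
                        sex = ifelse(male, "male", "female"),
                        cancer_type = "TST", age = age, race = "white",
                        smoking = "never", stage = "I",
                        tp53_status = "wt", os_time = NA_real_, os_event = NA)
  fit <- glm(I(sex == "male") ~ age, data = cl2, family = binomial())
  ci <- suppressMessages(stats::confint(fit, "age"))
  expect_true(ci[1] <= slope && slope <= ci[2])
  # and the package's per-cancer fit produces the same scores
  ps2 <- fit_propensity(cl2, covariates = "age")
  expect_equal(ps2$e[order(ps2$patient_id)],
               unname(fitted(fit)[order(cl2$patient_id)]), tolerance = 1e-8)
})

test_that("an already balanced cohort converges at the first iteration", {
  cl <- confounded_clinical(400, seed = 41)
  cl$age <- rnorm(400, 63, 9)
  cl$smoking <- sample(cl$smoking)
  bl <- balance_loop(cl)
  expect_true(bl$converged)
  expect_true(all(bl$weights$iteration == 1))
  expect_lt(max(abs(bl$balance$smd_after)), 0.1)
})

test_that("confounded covariates are balanced by the loop", {
  bl <- balance_loop(confounded_clinical(800, seed = 43))
  expect_true(bl$converged)
  expect_lt(max(abs(bl$balance$smd_after)), 0.1)
  # and the raw cohort really was imbalanced
  expect_gt(max(abs(bl$balance$smd_before)), 0.3)
})

test_that("quadratic age confounding needs the squared-term revision", {
  cl <- confounded_clinical(1200, seed = 47, nonlinear = TRUE)
  bl <- balance_loop(cl)
  age2 <- bl$balance[bl$balance$covariate == "age^2", ]
  expect_gt(abs(age2$smd_before), 0.1)   # first moments alone can't see it
  expect_true(all(bl$weights$iteration >= 2))
  expect_true(age2$balanced)
  expect_true(bl$converged)
})

test_that("complete separation raises an actionable error", {
  cl <- toy_clinical()
  cl$age <- ifelse(cl$sex == "male", 80, 40)  # age classifies sex perfectly
  expect_error(fit_propensity(cl, covariates = "age"), "separates")
})

test_that("a cohort that cannot balance is flagged, not hidden", {
  withr::local_seed(53)
  n <- 60
  # age nearly determines sex: no weighting can balance it
  age <- c(rnorm(n / 2, 45, 2), rnorm(n / 2, 80, 2))
  cl <- tibble::tibble(patient_id = sprintf("U%03d", 1:n),
                       sex = rep(c("female", "male"), each = n / 2),
                       cancer_type = "TST", age = age, race = "white",
                       smoking = "never", stage = "I", tp53_status = "wt",
                       os_time = NA_real_, os_event = NA)
  expect_warning(bl <- balance_loop(cl, covariates = "age", max_iter = 3),
                 "not balanced")
  expect_false(bl$converged)
  expect_true("age" %in% bl$balance$covariate[!bl$balance$balanced])
})

test_that("tidy and glance expose weights and balance summaries", {
  bl <- balance_loop(confounded_clinical(400, seed = 59))
  td <- tidy(bl)
  expect_true(all(c("patient_id", "e", "w", "iteration") %in% names(td)))
  expect_true(all(td$w <= 1))
  gl <- glance(bl)
  expect_equal(gl$n, 400)
})
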