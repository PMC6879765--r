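# quick NEM/EM record builder: one gene, independent Bernoulli NEM states
mk_records <- function(gene, n_f, n_m, p_f, p_m, rng_offset = 0) {
  sex <- c(rep("female", n_f), rep("male", n_m))
  nem <- runif(n_f + n_m) < ifelse(sex == "female", p_f, p_m)
  tibble::tibble(
    patient_id = sprintf("P%s%04d", gene, seq_along(sex) + rng_offset),
    gene = gene, chrom = "X", pos = seq_along(sex), sex = sex,
    cancer_type = "TST", total_reads = 50,
    rmaf = ifelse(nem, 0, 1), rule = "pileup",
    status = ifelse(nem, "NEM", "EM"), selected = TRUE)
}

test_that("the weighted chi-squared reduces to the textbook statistic at unit weights", {
  tab <- matrix(c(12, 5, 7, 14), 2)
  ours <- weighted_chi2(tab)
  ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)

  flat <- weighted_chi2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_error(weighted_chi2(matrix(c(0, 0, 5, 5), 2)), "marginal")
})

test_that("BH adjustment matches the step-up procedure by hand", {
  expect_equal(bh_adjust(0.02), 0.02)
  # hand: sorted p (0.01, 0.02, 0.03) * 3/(1,2,3) = (0.03, 0.03, 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(rep(1, 4)), rep(1, 4))
  expect_error(bh_adjust(1.5), "0, 1")
})

test_that("chi-scores carry the female-vs-male NEM sign convention", {
  expect_equal(chi_score(4, 0.8, 0.2), 2)
  expect_equal(chi_score(9, 0.1, 0.6), -3)
  rec <- withr::with_seed(7, dplyr::bind_rows(mk_records("GA", 40, 40, 0.9, 0.1),
                                              mk_records("GB", 40, 40, 0.1, 0.9)))
  tests <- gene_nem_tests(rec)
  expect_equal(tests$chi_score^2, tests$chi2_stat, tolerance = 1e-12)
  expect_gt(tests$chi_score[tests$gene == "GA"], 0)
  expect_lt(tests$chi_score[tests$gene == "GB"], 0)
  # swapping sex labels flips every score
  swapped <- dplyr::mutate(rec, sex = ifelse(sex == "female", "male", "female"))
  tests_sw <- gene_nem_tests(swapped)
  expect_equal(tests_sw$chi_score, -tests$chi_score)
  expect_equal(tests_sw$chi2_stat, tests$chi2_stat)
})

test_that("single-sex and zero-margin genes are untestable and leave the BH family", {
  withr::local_seed(3)
  one_sex <- mk_records("GC", 10, 0, 0.5, 0.5)
  all_nem <- dplyr::mutate(mk_records("GD", 10, 10, 0.5, 0.5),
                           rmaf = 0, status = "NEM")
  rec <- dplyr::bind_rows(one_sex, all_nem, mk_records("GE", 20, 20, 0.9, 0.1))
  tests <- gene_nem_tests(rec)
  expect_false(tests$testable[tests$gene == "GC"])
  expect_false(tests$testable[tests$gene == "GD"])
  expect_true(tests$testable[tests$gene == "GE"])
  expect_true(is.na(tests$adj_p[tests$gene == "GC"]))
})

test_that("intermediate-status records enter neither NEM nor EM cells", {
  rec <- withr::with_seed(5, mk_records("GF", 20, 20, 0.5, 0.5))
  with_inter <- dplyr::bind_rows(
    rec, dplyr::mutate(mk_records("GF", 8, 8, 0, 0, rng_offset = 500),
                       rmaf = 0.5, status = "intermediate"))
  expect_equal(gene_nem_tests(with_inter)$chi2_stat,
               gene_nem_tests(rec)$chi2_stat)
})

test_that("the set-vs-rest Wilcoxon detects a shifted gene set and is label-symmetric", {
  withr::local_seed(11)
  scores <- c(rnorm(50, 2), rnorm(500))
  in_set <- c(rep(TRUE, 50), rep(FALSE, 500))
  shifted <- set_vs_rest(scores, in_set)
  expect_lt(shifted$p_value, 0.01)
  expect_equal(set_vs_rest(scores, !in_set)$p_value, shifted$p_value)

  same <- set_vs_rest(c(rnorm(200), rnorm(200) * 0 + rnorm(200)),
                      rep(c(TRUE, FALSE), c(200, 400)))
  expect_gt(same$p_value, 0.01)
  expect_error(set_vs_rest(scores, rep(FALSE, 550)), "non-empty")
})

test_that("the Poisson burden model recovers rates and covers the null", {
  withr::local_seed(13)
  mk_burden <- function(rate_f, rate_m, n) tibble::tibble(
    patient_id = sprintf("B%04d", 1:(2 * n)),
    sex = rep(c("female", "male"), each = n),
    n_mut = c(rpois(n, rate_f), rpois(n, rate_m)))
  bm <- burden_model(mk_burden(4, 2, 1000), scope = "X_only")
  expect_gt(bm$rate_ratio, 1.8); expect_lt(bm$rate_ratio, 2.2)
  expect_true(bm$ci95[1] < bm$rate_ratio && bm$rate_ratio < bm$ci95[2])

  covered <- vapply(1:100, function(i) {
    b <- burden_model(mk_burden(5, 5, 150))
    b$ci95[1] <= 1 && 1 <= b$ci95[2]
  }, logical(1))
  expect_gte(mean(covered), 0.9)

  expect_error(burden_model(mk_burden(4, 2, 5)[1:5, ]), "both sexes")
  # unit weights equal the unweighted fit
  b0 <- mk_burden(3, 2, 200)
  w1 <- tibble::tibble(patient_id = b0$patient_id, w = 1)
  expect_equal(burden_model(b0, w1)$rate_ratio, burden_model(b0)$rate_ratio)
})

test_that("burden scopes count the right chromosomes", {
  mut <- tibble::tibble(patient_id = c("P1", "P1", "P1", "P2"),
                        gene = c("XG1", "AG1", "YG1", "XG1"),
                        chrom = c("X", "7", "Y", "X"), pos = 1:4,
                        ref_allele = "A", alt_allele = "T",
                        var_class = "Missense_Mutation")
  cl <- toy_clinical()[1:2, ]
  cl$patient_id <- c("P1", "P2")
  expect_equal(sum(mutation_burden(mut, cl, "genome_minus_Y")$n_mut), 3)
  expect_equal(sum(mutation_burden(mut, cl, "X_only")$n_mut), 2)
  gs <- mutation_burden(mut, cl, "gene_set", gene_set = "XG1")
  expect_equal(gs$n_mut[gs$patient_id == "P2"], 1)
  # patients without qualifying mutations keep explicit zeros
  expect_equal(nrow(mutation_burden(mut[0, ], cl, "X_only")), 2)
})

test_that("logit-scale RMAF comparison finds female silencing and a flat null", {
  withr::local_seed(17)
  n <- 800
  rec <- tibble::tibble(
    patient_id = sprintf("L%04d", 1:n), gene = "G", chrom = "X", pos = 1:n,
    sex = rep(c("female", "male"), each = n / 2),
    cancer_type = rep(c("AA", "BB"), n / 2), total_reads = 50,
    rule = "pileup", selected = TRUE,
    rmaf = c(ifelse(runif(n / 2) < 0.5, 0, 1), rep(1, n / 2)))
  rec$status <- classify_rmaf(rec$rmaf)
  out <- rmaf_sex_compare(rec)
  expect_lt(out$estimate, 0)
  expect_lt(out$p_value, 1e-3)

  flat <- dplyr::mutate(rec, rmaf = 1, status = "EM")
  expect_equal(rmaf_sex_compare(flat)$estimate, 0)
})

test_that("gene-size/NEM correlation matches hand arithmetic and a null", {
  expect_equal(size_nem_correlation(c(1, 2, 3), c(1, 2, 3))$r, 1)
  # hand Pearson r for (1,2,4) vs (2,1,3): r = 0.6546537
  expect_equal(size_nem_correlation(c(1, 2, 4), c(2, 1, 3))$r,
               0.654653670708, tolerance = 1e-9)
  withr::local_seed(19)
  null_r <- size_nem_correlation(rlnorm(300, 8, 1), rpois(300, 3))$r
  expect_lt(abs(null_r), 0.15)
  expect_true(is.na(size_nem_correlation(rep(1, 5), rpois(5, 3))$r))
  expect_error(size_nem_correlation(1:2, 1:2), "at least 3")
})
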