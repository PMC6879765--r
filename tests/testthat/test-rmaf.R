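test_that("RMAF is the mutant-read quotient and classification is boundary-inclusive", {
  expect_equal(compute_rmaf(3, 7), 0.7)
  expect_equal(compute_rmaf(50, 0), 0)
  expect_equal(compute_rmaf(42, 58), 0.58)
  expect_true(is.na(compute_rmaf(0, 0)))
  expect_error(compute_rmaf(-1, 5), "non-negative")

  expect_equal(classify_rmaf(c(0.75, 0.20, 0.5, 0.21, 0.74, 1, 0)),
               c("EM", "NEM", "intermediate", "intermediate", "intermediate",
                 "EM", "NEM"))
  expect_error(classify_rmaf(1.2), "0, 1")
  expect_error(rmaf_thresholds(em_min = 0.1, nem_max = 0.2), "nem_max")
})

test_that("the low-coverage fallback follows expression, cohort size and z-score rules", {
  fx <- rmaf_rule_fixture()
  rt <- rmaf_table(fx$mutations, fx$pileups, fx$clinical, fx$counts)

  row_of <- function(pat, gene) dplyr::filter(rt, .data$patient_id == pat,
                                              .data$gene == gene)
  # gene with zero counts everywhere
  expect_equal(row_of("PF13", "GNEX")$rule, "not_expressed_gene")
  expect_equal(row_of("PF13", "GNEX")$status, "discarded")
  # expressed in exactly half the cohort: not a majority
  expect_equal(row_of("PM14", "GHALF")$rule, "not_expressed_gene")
  # knockdown sample: all other cohort members at CPM 1000, this one 0.
  # Hand z on log2(CPM+1): 19 samples at log2(1001), one at 0 ->
  # z = (0 - 19*log2(1001)/20) / sd = -4.25 <= -4
  a <- log2(1001); xs <- c(rep(a, 19), 0)
  expect_true((0 - mean(xs)) / sd(xs) <= -4)
  kd <- row_of("PF11", "GKD")
  expect_equal(kd$rule, "knockdown_assigned")
  expect_equal(kd$rmaf, 1)
  expect_equal(kd$status, "EM")
  # modestly low expression against a cohort with natural spread:
  # z stays above the cut
  base <- rep(c(900, 1000, 1100), length.out = 20)
  base[12] <- 800
  xs2 <- log2(base + 1)
  expect_true((xs2[12] - mean(xs2)) / sd(xs2) > -4)
  expect_equal(row_of("PM12", "GNOKD")$rule, "insufficient_info")
  expect_equal(row_of("PM12", "GNOKD")$status, "discarded")
  # a mutation with no pileup reads at all also takes the fallback
  expect_equal(row_of("PF15", "GEXP")$rule, "insufficient_info")
})

test_that("exactly 10 reads uses the direct quotient, fewer does not", {
  cl <- rmaf_rule_fixture()
  mut <- tibble::tibble(patient_id = c("PF01", "PF01"), gene = "GEXP",
                        chrom = "X", pos = c(11, 12),
                        ref_allele = "A", alt_allele = "T",
                        var_class = "Missense_Mutation")
  pu <- tibble::tibble(patient_id = c("PF01", "PF01"), chrom = "X",
                       pos = c(11, 12), ref_reads = c(4, 4),
                       alt_reads = c(6, 5))
  rt <- rmaf_table(mut, pu, cl$clinical, cl$counts)
  expect_equal(rt$rule[rt$pos == 11], "pileup")
  expect_equal(rt$rmaf[rt$pos == 11], 0.6)
  expect_false(rt$rule[rt$pos == 12] == "pileup")  # 9 reads -> fallback
})

test_that("gene-level resolution keeps the highest RMAF with positional tie-break", {
  rec <- tibble::tibble(
    patient_id = c("P", "P", "Q", "Q", "R"),
    gene = "G", pos = c(100, 200, 300, 250, 10),
    rmaf = c(0.1, 0.9, 0.5, 0.5, 0.3),
    status = c("NEM", "EM", "intermediate", "intermediate", "intermediate"))
  out <- resolve_gene_level(rec)
  expect_equal(out$pos[out$selected & out$patient_id == "P"], 200)
  expect_equal(out$pos[out$selected & out$patient_id == "Q"], 250)
  expect_true(out$selected[out$patient_id == "R"])  # single record is itself
  # all-discarded gene contributes nothing
  disc <- tibble::tibble(patient_id = "P", gene = "G", pos = 1,
                         rmaf = NA_real_, status = "discarded")
  expect_false(any(resolve_gene_level(disc)$selected))
})

test_that("RMAF summaries report zero-fractions and medians by group", {
  rec <- tibble::tibble(
    patient_id = paste0("P", 1:8), gene = paste0("G", 1:8), pos = 1:8,
    sex = rep(c("female", "male"), each = 4),
    rmaf = c(0, 0, 1, 1, 0, 0, 0, 0),
    status = c("NEM", "NEM", "EM", "EM", "NEM", "NEM", "NEM", "NEM"),
    selected = TRUE)
  sm <- rmaf_summary(rec)
  f <- sm[sm$sex == "female", ]
  expect_equal(f$frac_zero, 0.5)
  expect_equal(f$median_rmaf, 0.5)
  m <- sm[sm$sex == "male", ]
  expect_equal(m$frac_zero, 1)
  expect_equal(m$median_rmaf, 0)
})

test_that("increasing alt reads at fixed depth never moves a call toward NEM", {
  ranks <- c(NEM = 1, intermediate = 2, EM = 3)
  total <- 40
  st <- classify_rmaf(compute_rmaf(total - (0:total), 0:total))
  expect_true(all(diff(ranks[st]) >= 0))
})

test_that("deeply covered male mutations are never discarded", {
  co <- simulate_cohort(sim_config(n_per_group = 25, n_x_genes = 40,
                                   n_autosome_genes = 40,
                                   not_expressed_gene_fraction = 0,
                                   knockdown_prob = 0, seed = 5))
  mut <- filter_mutations(co$mutations, drop_y = TRUE)
  rt <- rmaf_table(mut, co$pileups, co$clinical, co$counts)
  deep_male <- dplyr::filter(rt, .data$sex == "male", .data$total_reads >= 10)
  expect_gt(nrow(deep_male), 100)
  expect_true(all(deep_male$status != "discarded"))
})

test_that("pipeline statuses equal the literal rule-by-rule oracle", {
  fx <- rmaf_rule_fixture()
  rt <- rmaf_table(fx$mutations, fx$pileups, fx$clinical, fx$counts)
  or <- oracle_rmaf(fx$mutations, fx$pileups, fx$clinical, fx$counts)
  j <- dplyr::inner_join(rt, or, by = c("patient_id", "gene", "pos"),
                         suffix = c("", ".oracle"))
  expect_equal(nrow(j), 200)
  expect_equal(j$status, j$status.oracle)
  expect_equal(j$rule, j$rule.oracle)
  expect_equal(j$rmaf, j$rmaf.oracle)
  expect_equal(j$selected, j$selected.oracle)
})
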