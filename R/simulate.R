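#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the simulated study design. Defaults emulate the
#' disparity-cancer setting the analysis is built for: sex-differential TP53
#' mutation probabilities and population incidence taken from the bundled
#' 13-cancer input table ([tp53_incidence_inputs()]), a roughly twofold
#' female excess of X-linked exome mutations (two X copies), X-inactivation
#' silencing half of the non-escape female X mutations, a 15% escape-gene
#' fraction expressing both copies, negative-binomial RNA read depth, a
#' small per-mutation knockdown probability (the mutation silences its own
#' gene in that sample), mild age/smoking confounding with sex, and
#' exponential survival with a hazard ratio for TP53-mutant disease.
#'
#' @param n_per_group Patients per cancer per sex (default 75).
#' @param cancers Tibble with `cancer_type`, `sex`, `tp53_mut_prob`,
#'   `rate_per_100k`; default derived from [tp53_incidence_inputs()].
#' @param x_mut_rate Named vector, mean X-chromosome somatic mutations per
#'   patient by sex; default `c(female = 4, male = 2)` (female twice male).
#' @param autosome_mut_rate Mean autosomal mutations per patient by sex;
#'   default `c(female = 60.9, male = 60)` (rate ratio 1.015, the near-parity
#'   whole-exome regime).
#' @param xi_silencing_prob Probability a non-escape female X mutation lies
#'   on the inactive copy (default 0.5, fully random inactivation).
#' @param escape_gene_fraction Fraction of X genes escaping inactivation
#'   (default 0.15).
#' @param escape_expression_fraction Fraction of an escape gene's mRNA
#'   arising from the mutated copy in a heterozygote (default 0.5).
#' @param expression_fraction Mutant-allele mRNA fraction for a male or
#'   active-copy female mutation (default 1.0: clonal tumour, one active
#'   copy per locus).
#' @param knockdown_prob Probability that an otherwise fully expressed
#'   mutation instead abolishes its gene's expression in that sample
#'   (default 0.02).
#' @param depth_mean,depth_dispersion Negative-binomial RNA pileup depth:
#'   mean and size (dispersion) parameters, defaults 50 and 5.
#' @param n_x_genes,n_autosome_genes Gene catalog sizes (defaults 300, 500).
#' @param string_set_size Number of X genes flagged as the designated
#'   p53-associated set (default 30).
#' @param not_expressed_gene_fraction Fraction of genes with no expression
#'   at all (default 0.05), exercising the discard-if-gene-silent rule.
#' @param silent_fraction Fraction of simulated mutations drawn with
#'   non-functional variant classes (default 0.1), exercising the class
#'   filter.
#' @param tp53_unknown_fraction Fraction of patients with unknown TP53
#'   status (default 0.03).
#' @param age_mean,age_sd Age distribution (defaults 63, 10).
#' @param covariate_effects List of sex-confounding effects:
#'   `age_shift_male` (years added to male mean age, default 2) and
#'   `smoking_logodds_male` (log-odds shift of ever-smoking for males,
#'   default 0.8).
#' @param counts_mean,counts_sdlog,counts_size Expression-count model:
#'   per-gene baselines are log-normal with median `counts_mean` and
#'   log-sd `counts_sdlog`; per-sample counts are negative binomial with
#'   size `counts_size` around the baseline.
#' @param survival_median_years Baseline (wild-type) median survival
#'   (default 5 years).
#' @param survival_hazard_ratio Hazard ratio, TP53-mutant vs wild type
#'   (default 1.6).
#' @param censor_horizon_years Administrative censoring horizon (default 14).
#' @param dropout_rate Annual random-censoring rate (default 0.05).
#' @param seed Integer seed; a fixed seed makes [simulate_cohort()] fully
#'   deterministic.
#' @return A list of class `xd_sim_config`.
#' @export
sim_config <- function(n_per_group = 75,
                       cancers = NULL,
                       x_mut_rate = c(female = 4, male = 2),
                       autosome_mut_rate = c(female = 60.9, male = 60),
                       xi_silencing_prob = 0.5,
                       escape_gene_fraction = 0.15,
                       escape_expression_fraction = 0.5,
                       expression_fraction = 1.0,
                       knockdown_prob = 0.02,
                       depth_mean = 50,
                       depth_dispersion = 5,
                       n_x_genes = 300,
                       n_autosome_genes = 500,
                       string_set_size = 30,
                       not_expressed_gene_fraction = 0.05,
                       silent_fraction = 0.1,
                       tp53_unknown_fraction = 0.03,
                       age_mean = 63, age_sd = 10,
                       covariate_effects = list(age_shift_male = 2,
                                                smoking_logodds_male = 0.8),
                       counts_mean = 200, counts_sdlog = 1, counts_size = 20,
                       survival_median_years = 5,
                       survival_hazard_ratio = 1.6,
                       censor_horizon_years = 14,
                       dropout_rate = 0.05,
                       seed = 1L) {
  if (is.null(cancers)) {
    inp <- tp53_incidence_inputs()
    cancers <- tibble::tibble(cancer_type = inp$cancer_type,
                              sex = inp$sex,
                              tp53_mut_prob = inp$n_mut / inp$n_total,
                              rate_per_100k = inp$rate_per_100k)
  }
  probs <- c(xi_silencing_prob, escape_gene_fraction,
             escape_expression_fraction, expression_fraction, knockdown_prob,
             not_expressed_gene_fraction, silent_fraction,
             tp53_unknown_fraction, cancers$tp53_mut_prob)
  if (any(probs < 0 | probs > 1)) abort("all probabilities must lie in [0, 1]")
  if (n_per_group < 1) abort("n_per_group must be at least 1")
  if (any(cancers$rate_per_100k < 0)) abort("incidence rates must be non-negative")
  if (any(c(x_mut_rate, autosome_mut_rate) < 0)) abort("mutation rates must be non-negative")
  if (depth_mean <= 0 || depth_dispersion <= 0) abort("depth distribution must be positive")
  if (survival_hazard_ratio <= 0) abort("survival_hazard_ratio must be positive")
  structure(list(
    n_per_group = as.integer(n_per_group), cancers = cancers,
    x_mut_rate = x_mut_rate, autosome_mut_rate = autosome_mut_rate,
    xi_silencing_prob = xi_silencing_prob,
    escape_gene_fraction = escape_gene_fraction,
    escape_expression_fraction = escape_expression_fraction,
    expression_fraction = expression_fraction,
    knockdown_prob = knockdown_prob,
    depth_mean = depth_mean, depth_dispersion = depth_dispersion,
    n_x_genes = as.integer(n_x_genes),
    n_autosome_genes = as.integer(n_autosome_genes),
    string_set_size = as.integer(string_set_size),
    not_expressed_gene_fraction = not_expressed_gene_fraction,
    silent_fraction = silent_fraction,
    tp53_unknown_fraction = tp53_unknown_fraction,
    age_mean = age_mean, age_sd = age_sd,
    covariate_effects = covariate_effects,
    counts_mean = counts_mean, counts_sdlog = counts_sdlog,
    counts_size = counts_size,
    survival_median_years = survival_median_years,
    survival_hazard_ratio = survival_hazard_ratio,
    censor_horizon_years = censor_horizon_years,
    dropout_rate = dropout_rate,
    seed = as.integer(seed)), class = "xd_sim_config")
}

# gene catalog: X genes with lengths, escape / designated-set / expressed
# flags, plus autosomal genes; gene coordinates are laid out end-to-end per
# chromosome so (chrom, pos) identifies the gene
make_gene_catalog <- function(config) {
  nx <- config$n_x_genes
  na <- config$n_autosome_genes
  x_len <- pmax(200L, as.integer(round(exp(rnorm(nx, log(3000), 0.8)))))
  a_len <- pmax(200L, as.integer(round(exp(rnorm(na, log(3000), 0.8)))))
  x_escape <- runif(nx) < config$escape_gene_fraction
  in_set <- seq_len(nx) %in% sample.int(nx, min(config$string_set_size, nx))
  expressed <- runif(nx + na) >= config$not_expressed_gene_fraction
  cat_x <- tibble::tibble(
    gene = sprintf("XG%03d", seq_len(nx)), chrom = "X",
    length = x_len,
    start = cumsum(c(1L, x_len[-nx] + 1000L)),
    is_escape = x_escape, is_string_set = in_set,
    is_expressed = expressed[seq_len(nx)])
  a_chrom <- as.character(sample(1:22, na, replace = TRUE))
  cat_a <- tibble::tibble(
    gene = sprintf("AG%03d", seq_len(na)), chrom = a_chrom,
    length = a_len, start = 0L,
    is_escape = FALSE, is_string_set = FALSE,
    is_expressed = expressed[nx + seq_len(na)])
  cat_a <- dplyr::group_by(cat_a, .data$chrom)
  cat_a <- dplyr::mutate(cat_a,
                         start = cumsum(c(1L, .data$length[-dplyr::n()] + 1000L)))
  dplyr::bind_rows(cat_x, dplyr::ungroup(cat_a))
}

# draw mutations for one compartment (X or autosomes): patients with a
# Poisson number of mutations placed on genes proportional to length
draw_mutations <- function(patients, sexes, rate_by_sex, catalog, config) {
  n_mut <- rpois(length(patients), rate_by_sex[sexes])
  idx <- rep.int(seq_along(patients), n_mut)
  total <- sum(n_mut)
  if (total == 0) {
    return(tibble::tibble(patient_id = character(), gene = character(),
                          chrom = character(), pos = integer(),
                          ref_allele = character(), alt_allele = character(),
                          var_class = character()))
  }
  g <- sample.int(nrow(catalog), total, replace = TRUE, prob = catalog$length)
  pos <- catalog$start[g] +
    as.integer(floor(runif(total) * catalog$length[g]))
  classes <- rmaf_variant_classes()
  class_wts <- c(0.08, 0.04, 0.08, 0.06, 0.55, 0.1, 0.04, 0.05)
  is_silent <- runif(total) < config$silent_fraction
  vc <- sample(classes, total, replace = TRUE, prob = class_wts)
  vc[is_silent] <- sample(c("Silent", "Intron", "IGR"), sum(is_silent),
                          replace = TRUE)
  nt <- c("A", "C", "G", "T")
  ref <- sample(nt, total, replace = TRUE)
  alt <- nt[(match(ref, nt) + sample.int(3, total, replace = TRUE)) %% 4 + 1]
  tibble::tibble(patient_id = patients[idx],
                 gene = catalog$gene[g], chrom = catalog$chrom[g], pos = pos,
                 ref_allele = ref, alt_allele = alt, var_class = vc)
}

#' Simulate RNA pileup counts for mutations with known expression states
#'
#' Read depth is negative binomial; the number of mutant-allele reads is
#' binomial given depth, with success probability fixed by the mutation's
#' true expression state: 0 for a silenced (inactive-copy) mutation, the
#' configured full-expression fraction for a male or active-copy female
#' mutation, the heterozygous fraction for an escape-gene mutation, and zero
#' total reads when the gene is not expressed at all (knockdown or silent
#' gene).
#'
#' @param truth Tibble with columns `patient_id`, `chrom`, `pos`, `state`
#'   (one of `"expressed"`, `"active_copy"`, `"escape_het"`, `"silenced"`,
#'   `"knockdown"`, `"gene_not_expressed"`), as produced by
#'   [simulate_cohort()].
#' @param config An `xd_sim_config`.
#' @return Pileup tibble (`patient_id`, `chrom`, `pos`, `ref_reads`,
#'   `alt_reads`, `total_reads`).
#' @export
simulate_pileups <- function(truth, config) {
  n <- nrow(truth)
  depth <- rnbinom(n, mu = config$depth_mean, size = config$depth_dispersion)
  depth[truth$state %in% c("knockdown", "gene_not_expressed")] <- 0L
  p <- dplyr::case_match(truth$state,
                         c("expressed", "active_copy") ~ config$expression_fraction,
                         "escape_het" ~ config$escape_expression_fraction,
                         .default = 0)
  alt <- rbinom(n, depth, p)
  tibble::tibble(patient_id = truth$patient_id, chrom = truth$chrom,
                 pos = truth$pos, ref_reads = as.integer(depth - alt),
                 alt_reads = as.integer(alt),
                 total_reads = as.integer(depth))
}

#' Emit the generator's population incidence table
#'
#' @param config An `xd_sim_config`.
#' @return Tibble `cancer_type`, `sex`, `rate_per_100k` in the schema
#'   [read_incidence()] accepts.
#' @export
make_incidence_table <- function(config) {
  if (any(config$cancers$rate_per_100k < 0)) abort("incidence rates must be non-negative")
  tibble::as_tibble(config$cancers[, c("cancer_type", "sex", "rate_per_100k")])
}

#' Simulate a full cohort bundle
#'
#' Generates every input the analysis pipeline consumes — clinical table,
#' somatic mutation list (X and autosomes), per-mutation RNA pileups,
#' gene-by-sample count matrix and population incidence table — plus a
#' ground-truth table recording each X mutation's simulated expression
#' state, so downstream classification can be scored against the truth.
#' Fully deterministic for a fixed `config$seed`.
#'
#' @param config An [sim_config()] object.
#' @return A list of class `xd_cohort` with elements `clinical`,
#'   `mutations`, `pileups`, `counts`, `incidence`, `gene_catalog`, `truth`
#'   and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "xd_sim_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  catalog <- make_gene_catalog(config)
  cat_x <- dplyr::filter(catalog, .data$chrom == "X")
  cat_a <- dplyr::filter(catalog, .data$chrom != "X")

  grid <- tidyr::expand_grid(config$cancers[, c("cancer_type", "sex")],
                             rep = seq_len(config$n_per_group))
  n_pat <- nrow(grid)
  if (n_pat == 0) abort("zero patients requested")
  eff <- config$covariate_effects
  male <- grid$sex == "male"
  clinical <- tibble::tibble(
    patient_id = sprintf("PT%05d", seq_len(n_pat)),
    sex = grid$sex,
    cancer_type = grid$cancer_type,
    age = round(rnorm(n_pat, config$age_mean +
                        (eff$age_shift_male %||% 0) * male, config$age_sd), 1),
    race = sample(c("white", "black", "asian", "other"), n_pat,
                  replace = TRUE, prob = c(0.70, 0.13, 0.12, 0.05)),
    smoking = ifelse(runif(n_pat) <
                       stats::plogis(stats::qlogis(0.35) +
                                       (eff$smoking_logodds_male %||% 0) * male),
                     "ever", "never"),
    stage = sample(c("I", "II", "III", "IV"), n_pat, replace = TRUE,
                   prob = c(0.30, 0.30, 0.25, 0.15)))
  key <- paste(grid$cancer_type, grid$sex)
  prob_map <- setNames(config$cancers$tp53_mut_prob,
                       paste(config$cancers$cancer_type, config$cancers$sex))
  mut53 <- rbinom(n_pat, 1, prob_map[key]) == 1
  clinical$tp53_status <- ifelse(mut53, "mutant", "wt")
  clinical$tp53_status[runif(n_pat) < config$tp53_unknown_fraction] <- "unknown"

  base_rate <- log(2) / (config$survival_median_years * 365)
  hazard <- base_rate * ifelse(clinical$tp53_status == "mutant",
                               config$survival_hazard_ratio, 1)
  t_event <- rexp(n_pat, hazard)
  t_drop <- rexp(n_pat, config$dropout_rate / 365)
  horizon <- config$censor_horizon_years * 365
  t_cens <- pmin(t_drop, horizon)
  clinical$os_time <- round(pmin(t_event, t_cens))
  clinical$os_event <- t_event <= t_cens

  mut_x <- draw_mutations(clinical$patient_id, clinical$sex,
                          config$x_mut_rate, cat_x, config)
  mut_x <- dplyr::distinct(mut_x, .data$patient_id, .data$chrom, .data$pos,
                           .keep_all = TRUE)
  mut_a <- draw_mutations(clinical$patient_id, clinical$sex,
                          config$autosome_mut_rate, cat_a, config)

  # true expression state per X mutation
  sex_of <- setNames(clinical$sex, clinical$patient_id)
  esc <- setNames(cat_x$is_escape, cat_x$gene)
  expr_gene <- setNames(catalog$is_expressed, catalog$gene)
  st <- character(nrow(mut_x))
  is_f <- sex_of[mut_x$patient_id] == "female"
  st[!is_f] <- "expressed"
  on_escape <- esc[mut_x$gene]
  st[is_f & on_escape] <- "escape_het"
  sil <- runif(nrow(mut_x)) < config$xi_silencing_prob
  st[is_f & !on_escape] <- ifelse(sil[is_f & !on_escape], "silenced",
                                  "active_copy")
  kd <- runif(nrow(mut_x)) < config$knockdown_prob
  st[st %in% c("expressed", "active_copy") & kd] <- "knockdown"
  st[!expr_gene[mut_x$gene]] <- "gene_not_expressed"
  truth <- tibble::tibble(mutation_id = paste(mut_x$patient_id, mut_x$chrom,
                                              mut_x$pos, sep = ":"),
                          patient_id = mut_x$patient_id,
                          gene = mut_x$gene, chrom = mut_x$chrom,
                          pos = mut_x$pos,
                          sex = unname(sex_of[mut_x$patient_id]),
                          var_class = mut_x$var_class,
                          state = st)

  pileups <- simulate_pileups(truth, config)

  genes <- catalog$gene
  lambda <- ifelse(catalog$is_expressed,
                   exp(rnorm(nrow(catalog), log(config$counts_mean),
                             config$counts_sdlog)), 0)
  counts <- matrix(rnbinom(length(genes) * n_pat,
                           mu = rep(lambda, times = n_pat),
                           size = config$counts_size),
                   nrow = length(genes), ncol = n_pat,
                   dimnames = list(genes, clinical$patient_id))
  kd_rows <- truth[truth$state == "knockdown", c("gene", "patient_id")]
  if (nrow(kd_rows) > 0) {
    counts[cbind(match(kd_rows$gene, genes),
                 match(kd_rows$patient_id, clinical$patient_id))] <- 0
  }

  structure(list(clinical = as_clinical(clinical),
                 mutations = dplyr::bind_rows(mut_x, mut_a),
                 pileups = pileups,
                 counts = counts,
                 incidence = make_incidence_table(config),
                 gene_catalog = catalog,
                 truth = truth,
                 config = config),
            class = "xd_cohort")
}

#' Ground-truth expression states of a simulated cohort
#'
#' @param cohort An `xd_cohort` from [simulate_cohort()].
#' @return Tibble with one row per simulated X mutation and its true state.
#' @export
truth_table <- function(cohort) {
  stopifnot(inherits(cohort, "xd_cohort"))
  cohort$truth
}

#' @export
print.xd_cohort <- function(x, ...) {
  cat("<xd_cohort> ", nrow(x$clinical), " patients, ",
      nrow(x$mutations), " mutations (",
      sum(x$mutations$chrom == "X"), " on X), ",
      nrow(x$counts), " genes x ", ncol(x$counts), " samples\n", sep = "")
  invisible(x)
}
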