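#' Thresholds for RMAF computation and classification
#'
#' @param em_min Minimum RMAF for an expressed mutation (EM), default 0.75
#'   (boundary inclusive).
#' @param nem_max Maximum RMAF for a non-expressed mutation (NEM), default
#'   0.20 (boundary inclusive).
#' @param min_reads Minimum pileup depth for a direct RMAF quotient, default
#'   10; strictly fewer reads routes the mutation to the expression-based
#'   fallback.
#' @param cpm_min CPM floor for the is-the-gene-expressed majority vote,
#'   default 5 (inclusive).
#' @param z_cut Knockdown z-score cut on log2(CPM+1), default -4: at or
#'   below it a low-coverage mutation is interpreted as silencing its gene
#'   and assigned RMAF 1.
#' @param min_cohort Minimum cohort size for a stable z-score, default 3.
#' @return List of class `xd_rmaf_thresholds`.
#' @export
rmaf_thresholds <- function(em_min = 0.75, nem_max = 0.20, min_reads = 10,
                            cpm_min = 5, z_cut = -4, min_cohort = 3) {
  if (!(nem_max >= 0 && nem_max < em_min && em_min <= 1)) {
    abort("need 0 <= nem_max < em_min <= 1")
  }
  structure(list(em_min = em_min, nem_max = nem_max, min_reads = min_reads,
                 cpm_min = cpm_min, z_cut = z_cut, min_cohort = min_cohort),
            class = "xd_rmaf_thresholds")
}

#' RNA-mutated allele frequency
#'
#' The mRNA analogue of the DNA variant allele frequency: the fraction of
#' mRNA reads piled up at a mutated genomic position that carry the mutant
#' allele.
#'
#' @param ref_reads,alt_reads Non-negative read counts (vectorised).
#' @return `alt_reads / (ref_reads + alt_reads)`; `NA` where the total is 0.
#' @export
compute_rmaf <- function(ref_reads, alt_reads) {
  if (any(ref_reads < 0 | alt_reads < 0, na.rm = TRUE)) {
    abort("read counts must be non-negative")
  }
  total <- ref_reads + alt_reads
  ifelse(total > 0, alt_reads / total, NA_real_)
}

#' Classify RMAF values into NEM / intermediate / EM
#'
#' Both boundaries are inclusive: RMAF at or below `nem_max` is a
#' non-expressed mutation, at or above `em_min` an expressed mutation,
#' strictly between them intermediate.
#'
#' @param rmaf Numeric vector in `[0, 1]` (NA allowed, returned as NA).
#' @param thresholds An [rmaf_thresholds()] object.
#' @return Character vector in `{"NEM", "intermediate", "EM"}`.
#' @export
classify_rmaf <- function(rmaf, thresholds = rmaf_thresholds()) {
  if (any(rmaf < 0 | rmaf > 1, na.rm = TRUE)) abort("rmaf must lie in [0, 1]")
  dplyr::case_when(is.na(rmaf) ~ NA_character_,
                   rmaf <= thresholds$nem_max ~ "NEM",
                   rmaf >= thresholds$em_min ~ "EM",
                   .default = "intermediate")
}

#' Keep one mutation per patient and gene
#'
#' When a sample carries multiple somatic mutations in the same gene, only
#' the one with the highest RMAF represents the gene; ties are broken by the
#' smallest genomic position so the result is order-independent. Discarded
#' records never represent a gene.
#'
#' @param records RMAF record tibble with at least `patient_id`, `gene`,
#'   `pos`, `rmaf`, `status`.
#' @return The same tibble with a logical `selected` column.
#' @export
resolve_gene_level <- function(records) {
  records <- dplyr::mutate(records, .row = dplyr::row_number())
  live <- dplyr::filter(records, .data$status != "discarded")
  live <- dplyr::arrange(live, dplyr::desc(.data$rmaf), .data$pos)
  pick <- live[!duplicated(live[, c("patient_id", "gene")]), ]
  records$selected <- records$.row %in% pick$.row
  dplyr::select(records, -".row")
}

# z-scores on log2(CPM + 1) for one gene across a cohort of samples;
# returns named vector for the requested samples (NA if sd is 0)
log_cpm_z <- function(cpm_row) {
  x <- log2(cpm_row + 1)
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(setNames(rep(NA_real_, length(x)), names(x)))
  (x - mean(x)) / s
}

#' Compute RMAF records for a cohort
#'
#' The full per-mutation pipeline. For each X-chromosome mutation (after
#' class filtering) the RNA pileup at its position is looked up; with at
#' least `min_reads` total reads RMAF is the direct quotient
#' `alt / (alt + ref)`. Below that, the low-coverage fallback runs inside
#' the sex-and-cancer-matched cohort: if the gene fails the 5-CPM majority
#' rule there, the mutation is discarded (`not_expressed_gene`); otherwise a
#' z-score of the sample's log2(CPM+1) against the cohort decides — at or
#' below `z_cut` the mutation is deemed to have knocked its gene down and is
#' assigned RMAF 1 (`knockdown_assigned`); above, it is discarded
#' (`insufficient_info`). A cohort smaller than `min_cohort` also discards
#' (`insufficient_info`: the z-score is unstable). Finally one mutation per
#' patient and gene is selected ([resolve_gene_level()]) and classified
#' ([classify_rmaf()]).
#'
#' @param mutations Mutation tibble (already class-filtered; rows off the
#'   target chromosome are dropped here).
#' @param pileups Pileup tibble (see [read_pileups()]); mutations without a
#'   pileup row are treated as having zero reads.
#' @param clinical Clinical tibble supplying sex and cancer type.
#' @param counts Raw count matrix (genes x samples) for the fallback rules;
#'   CPM-normalised internally.
#' @param thresholds An [rmaf_thresholds()] object.
#' @param chrom Chromosome restricted to, default `"X"`; `NULL` keeps all.
#' @return Tibble of class `xd_rmaf` with one row per mutation:
#'   `patient_id`, `gene`, `chrom`, `pos`, `sex`, `cancer_type`,
#'   `total_reads`, `rmaf` (NA when discarded), `rule` (`pileup`,
#'   `knockdown_assigned`, `not_expressed_gene`, `insufficient_info`),
#'   `status` (`NEM`, `intermediate`, `EM`, `discarded`) and `selected`
#'   (gene-level representative).
#' @export
rmaf_table <- function(mutations, pileups, clinical, counts,
                       thresholds = rmaf_thresholds(), chrom = "X") {
  mut <- tibble::as_tibble(mutations)
  keep_chrom <- chrom
  if (!is.null(keep_chrom)) mut <- dplyr::filter(mut, .data$chrom %in% keep_chrom)
  mut <- dplyr::inner_join(mut,
                           dplyr::select(clinical, "patient_id", "sex",
                                         "cancer_type"),
                           by = "patient_id")
  pu <- dplyr::select(tibble::as_tibble(pileups),
                      "patient_id", "chrom", "pos", "ref_reads", "alt_reads")
  mut <- dplyr::left_join(mut, pu, by = c("patient_id", "chrom", "pos"))
  mut$ref_reads[is.na(mut$ref_reads)] <- 0L
  mut$alt_reads[is.na(mut$alt_reads)] <- 0L
  mut$total_reads <- mut$ref_reads + mut$alt_reads

  cpm <- cpm_normalize(counts)

  direct <- mut$total_reads >= thresholds$min_reads
  mut$rmaf <- NA_real_
  mut$rule <- NA_character_
  mut$rmaf[direct] <- compute_rmaf(mut$ref_reads[direct], mut$alt_reads[direct])
  mut$rule[direct] <- "pileup"

  # fallback, grouped by (sex, cancer, gene) so cohort statistics are
  # computed once per group
  fb <- which(!direct)
  if (length(fb) > 0) {
    cohort_samples <- split(clinical$patient_id,
                            paste(clinical$sex, clinical$cancer_type))
    fb_tab <- mut[fb, c("gene", "sex", "cancer_type", "patient_id")]
    fb_key <- paste(fb_tab$sex, fb_tab$cancer_type, fb_tab$gene)
    for (grp in split(seq_along(fb), fb_key)) {
      i <- fb[grp]
      gene <- mut$gene[i[1]]
      smp <- intersect(cohort_samples[[paste(mut$sex[i[1]], mut$cancer_type[i[1]])]],
                       colnames(cpm))
      if (length(smp) == 0) {
        mut$rule[i] <- "insufficient_info"
        next
      }
      if (!gene %in% rownames(cpm)) {
        mut$rule[i] <- "not_expressed_gene"
        next
      }
      row <- cpm[gene, smp]
      if (mean(row >= thresholds$cpm_min) <= 0.5) {
        mut$rule[i] <- "not_expressed_gene"
        next
      }
      if (length(smp) < thresholds$min_cohort) {
        mut$rule[i] <- "insufficient_info"
        next
      }
      z <- log_cpm_z(row)[mut$patient_id[i]]
      kd <- !is.na(z) & z <= thresholds$z_cut
      mut$rmaf[i][kd] <- 1
      mut$rule[i][kd] <- "knockdown_assigned"
      mut$rule[i][!kd] <- "insufficient_info"
    }
  }

  mut$status <- classify_rmaf(mut$rmaf, thresholds)
  mut$status[is.na(mut$status)] <- "discarded"
  out <- resolve_gene_level(
    dplyr::select(mut, "patient_id", "gene", "chrom", "pos", "sex",
                  "cancer_type", "total_reads", "rmaf", "rule", "status"))
  class(out) <- c("xd_rmaf", class(out))
  out
}

#' Summarise RMAF records by group
#'
#' Reports, per group (default: sex), the number of gene-level mutation
#' records, how many have RMAF exactly zero versus positive, the
#' corresponding fractions, and the median RMAF — the shape of the
#' headline "fraction of mutations never seen in mRNA" comparison.
#'
#' @param records An `xd_rmaf` tibble; only selected, non-discarded records
#'   enter the summary.
#' @param by Grouping column name, default `"sex"`.
#' @return Tibble with `n`, `n_zero`, `n_pos`, `frac_zero`, `frac_pos`,
#'   `median_rmaf` per group.
#' @export
rmaf_summary <- function(records, by = "sex") {
  live <- dplyr::filter(records, .data$selected, .data$status != "discarded")
  if (nrow(live) == 0) abort("no classified records to summarise")
  dplyr::summarise(dplyr::group_by(live, dplyr::across(dplyr::all_of(by))),
                   n = dplyr::n(),
                   n_zero = sum(.data$rmaf == 0),
                   n_pos = sum(.data$rmaf > 0),
                   frac_zero = .data$n_zero / .data$n,
                   frac_pos = .data$n_pos / .data$n,
                   median_rmaf = median(.data$rmaf),
                   .groups = "drop")
}
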