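#' Variant classes retained for expression analysis
#'
#' The eight Oncotator-style variant classifications with plausible functional
#' impact on the transcript; all other classes (e.g. Silent, Intron, IGR) are
#' excluded before RMAF analysis.
#'
#' @return Character vector of the eight retained classes.
#' @export
rmaf_variant_classes <- function() {
  c("3'UTR", "5'UTR", "Frame_Shift_Del", "Frame_Shift_Ins",
    "Missense_Mutation", "Nonsense_Mutation", "Splice_Region", "Splice_Site")
}

#' Filter a somatic mutation table for expression analysis
#'
#' Applies three screens: (1) drop every mutation of any hypermutator patient
#' whose total somatic mutation count reaches `max_per_patient` (strictly
#' fewer than the cap are kept); (2) keep only variant classes in
#' `allowed_classes`; (3) optionally drop Y-chromosome records (the shared
#' allosome analysis excludes Y, which females lack). The hypermutator cap is
#' assessed on the patient's total somatic count before the class filter, so
#' the operation is idempotent.
#'
#' @param mutations Mutation tibble (see [read_mutations()]).
#' @param allowed_classes Variant classes to retain; defaults to
#'   [rmaf_variant_classes()].
#' @param max_per_patient Hypermutator cap, default 15000; patients with
#'   `>= max_per_patient` mutations are removed entirely.
#' @param drop_y Drop chromosome-Y records, default `FALSE`.
#' @return Filtered mutation tibble.
#' @export
filter_mutations <- function(mutations,
                             allowed_classes = rmaf_variant_classes(),
                             max_per_patient = 15000,
                             drop_y = FALSE) {
  mutations <- tibble::as_tibble(mutations)
  if (nrow(mutations) == 0) return(mutations)
  totals <- table(mutations$patient_id)
  hyper <- names(totals)[totals >= max_per_patient]
  out <- dplyr::filter(mutations,
                       !.data$patient_id %in% hyper,
                       .data$var_class %in% allowed_classes)
  if (drop_y) out <- dplyr::filter(out, .data$chrom != "Y")
  out
}

#' Convert raw counts to counts per million
#'
#' `cpm[g, s] = counts[g, s] / colsum(s) * 1e6`, so every sample column of
#' the result sums to one million.
#'
#' @param counts Non-negative numeric matrix, genes x samples.
#' @return CPM matrix of the same shape.
#' @export
cpm_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0, na.rm = TRUE)) abort("counts must be non-negative")
  lib <- colSums(counts)
  zero <- lib == 0
  if (any(zero)) {
    bad <- colnames(counts)[zero] %||% which(zero)
    abort(paste0("all-zero sample column(s): ", paste(bad, collapse = ", ")))
  }
  sweep(counts, 2, lib, "/") * 1e6
}

#' Identify genes passing the low-expression filter
#'
#' A gene is retained iff its CPM is at least `threshold` in strictly more
#' than half of the samples considered (the "majority of samples" rule, with
#' the 5-CPM boundary inclusive).
#'
#' @param cpm CPM matrix, genes x samples (see [cpm_normalize()]).
#' @param threshold Minimum CPM, default 5.
#' @param samples Optional character vector restricting the majority vote to
#'   a sample subset (e.g. a sex-and-cancer-matched cohort).
#' @return Character vector of retained gene names.
#' @export
filter_low_expression <- function(cpm, threshold = 5, samples = NULL) {
  if (length(cpm) == 0 || nrow(cpm) == 0 || ncol(cpm) == 0) {
    abort("empty expression matrix")
  }
  if (!is.null(samples)) {
    keep <- intersect(samples, colnames(cpm))
    if (length(keep) == 0) abort("none of the requested samples are in the matrix")
    cpm <- cpm[, keep, drop = FALSE]
  }
  frac <- rowMeans(cpm >= threshold)
  rownames(cpm)[frac > 0.5]
}
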