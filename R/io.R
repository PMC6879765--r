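#' Read a clinical table
#'
#' Loads per-patient clinical annotations from a tab-separated file. Patients
#' without a recognisable sex annotation are dropped (sex is the analysis
#' variable; a record without it cannot enter any comparison) and counted in
#' the load report attached as the `"load_report"` attribute.
#'
#' @param path Path to a TSV with header. Required columns: `patient_id`,
#'   `sex`, `cancer_type`. Recognised optional columns: `age`, `race`,
#'   `smoking`, `stage`, `tp53_status` (`wt`/`mutant`/`unknown`), `os_time`
#'   (days), `os_event` (0/1 or logical).
#' @return A tibble of patient records, one row per patient, with a
#'   `load_report` attribute (`n_read`, `n_dropped_missing_sex`).
#' @export
read_clinical <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  required <- c("patient_id", "sex", "cancer_type")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("clinical table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  as_clinical(raw)
}

#' Coerce a data frame to a validated clinical table
#'
#' @param df A data frame with at least `patient_id`, `sex`, `cancer_type`.
#' @return A validated clinical tibble; see [read_clinical()].
#' @export
as_clinical <- function(df) {
  df <- tibble::as_tibble(df)
  n_read <- nrow(df)
  sex_raw <- df$sex
  df$sex <- normalize_sex(df$sex)
  bad <- !is.na(sex_raw) & trimws(as.character(sex_raw)) != "" & is.na(df$sex)
  if (any(bad)) {
    warn(paste0(sum(bad), " row(s) with unrecognised sex token rejected: ",
                paste(unique(sex_raw[bad]), collapse = ", ")))
  }
  df <- dplyr::filter(df, !is.na(.data$sex))
  if (anyDuplicated(df$patient_id)) {
    abort("duplicated patient_id in clinical table")
  }
  df$age <- if ("age" %in% names(df)) suppressWarnings(as.numeric(df$age)) else NA_real_
  for (col in c("race", "smoking", "stage")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  df$tp53_status <- if ("tp53_status" %in% names(df)) {
    st <- tolower(as.character(df$tp53_status))
    st[is.na(st) | !st %in% c("wt", "mutant")] <- "unknown"
    st
  } else "unknown"
  df$os_time <- if ("os_time" %in% names(df)) suppressWarnings(as.numeric(df$os_time)) else NA_real_
  if (any(df$os_time < 0, na.rm = TRUE)) abort("negative os_time in clinical table")
  df$os_event <- if ("os_event" %in% names(df)) {
    ev <- tolower(as.character(df$os_event))
    dplyr::case_match(ev, c("true", "1") ~ TRUE, c("false", "0") ~ FALSE,
                      .default = NA)
  } else NA
  out <- dplyr::select(df, "patient_id", "sex", "cancer_type", "age", "race",
                       "smoking", "stage", "tp53_status", "os_time", "os_event")
  attr(out, "load_report") <- tibble::tibble(
    n_read = n_read,
    n_dropped_missing_sex = n_read - nrow(out)
  )
  out
}

#' Read a MAF-like somatic mutation table
#'
#' Accepts either MAF column names (`Hugo_Symbol`, `Chromosome`,
#' `Start_Position`, `Reference_Allele`, `Tumor_Seq_Allele2`,
#' `Variant_Classification`, `Tumor_Sample_Barcode`) or the package's own
#' lower-case names. Coordinates are 1-based inclusive (MAF convention).
#'
#' @param path Path to a TSV with header.
#' @return A tibble with columns `patient_id`, `gene`, `chrom`, `pos`,
#'   `ref_allele`, `alt_allele`, `var_class`.
#' @export
read_mutations <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  maf_map <- c(Hugo_Symbol = "gene", Chromosome = "chrom",
               Start_Position = "pos", Reference_Allele = "ref_allele",
               Tumor_Seq_Allele2 = "alt_allele",
               Variant_Classification = "var_class",
               Tumor_Sample_Barcode = "patient_id")
  hit <- intersect(names(maf_map), names(raw))
  names(raw)[match(hit, names(raw))] <- maf_map[hit]
  as_mutations(raw)
}

#' Coerce a data frame to a validated mutation table
#'
#' @param df Data frame with `patient_id`, `gene`, `chrom`, `pos`,
#'   `ref_allele`, `alt_allele`, `var_class`.
#' @return A validated tibble; see [read_mutations()].
#' @export
as_mutations <- function(df) {
  df <- tibble::as_tibble(df)
  required <- c("patient_id", "gene", "chrom", "pos", "ref_allele",
                "alt_allele", "var_class")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("mutation table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  df$chrom <- sub("^chr", "", as.character(df$chrom))
  if (!all(df$chrom %in% valid_chroms)) {
    abort(paste0("invalid chromosome name(s): ",
                 paste(unique(setdiff(df$chrom, valid_chroms)), collapse = ", ")))
  }
  df$pos <- as.integer(df$pos)
  if (any(is.na(df$pos)) || any(df$pos < 1)) abort("mutation pos must be an integer >= 1")
  if (any(is.na(df$var_class) | df$var_class == "")) abort("empty var_class")
  dplyr::select(df, dplyr::all_of(required))
}

#' Read per-mutation RNA pileup counts
#'
#' One row per (patient, genomic position): reference- and alternate-allele
#' supporting mRNA read counts from piling all overlapping reads at the
#' position of a DNA mutation call.
#'
#' @param path Path to a TSV with header: `patient_id`, `chrom`, `pos`,
#'   `ref_reads`, `alt_reads`.
#' @return A tibble with those columns plus `total_reads`.
#' @export
read_pileups <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  required <- c("patient_id", "chrom", "pos", "ref_reads", "alt_reads")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("pileup table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  df$chrom <- sub("^chr", "", df$chrom)
  df$pos <- as.integer(df$pos)
  df$ref_reads <- as.integer(df$ref_reads)
  df$alt_reads <- as.integer(df$alt_reads)
  if (any(df$ref_reads < 0 | df$alt_reads < 0, na.rm = TRUE)) {
    abort("negative read counts in pileup table")
  }
  df$total_reads <- df$ref_reads + df$alt_reads
  dplyr::select(df, dplyr::all_of(c(required, "total_reads")))
}

#' Read a gene-by-sample raw count matrix
#'
#' @param path Path to a TSV whose first column holds gene symbols and
#'   remaining columns one sample each, values raw read counts.
#' @return A numeric matrix (genes x samples) with dimnames.
#' @export
read_counts <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  if (any(m < 0, na.rm = TRUE)) abort("negative counts in expression matrix")
  m
}

#' Read a per-cancer, per-sex population incidence table
#'
#' @param path Path to a TSV with header: `cancer_type`, `sex`,
#'   `rate_per_100k` (cases per 100,000, e.g. age-adjusted registry rates).
#' @return A validated tibble.
#' @export
read_incidence <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  required <- c("cancer_type", "sex", "rate_per_100k")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("incidence table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  df$sex <- normalize_sex(df$sex)
  if (any(is.na(df$sex))) abort("unrecognised sex token in incidence table")
  df$rate_per_100k <- as.numeric(df$rate_per_100k)
  if (any(!is.finite(df$rate_per_100k)) || any(df$rate_per_100k < 0)) {
    abort("incidence rates must be finite and non-negative")
  }
  tibble::as_tibble(df[, required])
}

#' Write a cohort bundle to a directory of TSV files
#'
#' Emits `clinical.tsv`, `mutations.tsv`, `pileups.tsv`, `counts.tsv` and
#' `incidence.tsv` in the formats the corresponding readers accept, so that a
#' write/read round trip reproduces the bundle.
#'
#' @param cohort A cohort bundle as returned by [simulate_cohort()], or any
#'   list with elements `clinical`, `mutations`, `pileups`, `counts`,
#'   `incidence`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(cohort$clinical, file.path(dir, "clinical.tsv"))
  readr::write_tsv(cohort$mutations, file.path(dir, "mutations.tsv"))
  pu <- dplyr::select(cohort$pileups, "patient_id", "chrom", "pos",
                      "ref_reads", "alt_reads")
  readr::write_tsv(pu, file.path(dir, "pileups.tsv"))
  cm <- tibble::as_tibble(cohort$counts, rownames = "gene")
  readr::write_tsv(cm, file.path(dir, "counts.tsv"))
  readr::write_tsv(cohort$incidence, file.path(dir, "incidence.tsv"))
  invisible(dir)
}

#' Read a cohort bundle written by [write_cohort()]
#'
#' @param dir Directory containing the bundle TSV files.
#' @return A list with `clinical`, `mutations`, `pileups`, `counts`,
#'   `incidence`.
#' @export
read_cohort <- function(dir) {
  list(
    clinical = read_clinical(file.path(dir, "clinical.tsv")),
    mutations = read_mutations(file.path(dir, "mutations.tsv")),
    pileups = read_pileups(file.path(dir, "pileups.tsv")),
    counts = read_counts(file.path(dir, "counts.tsv")),
    incidence = read_incidence(file.path(dir, "incidence.tsv"))
  )
}
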