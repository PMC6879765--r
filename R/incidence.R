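#' Bundled registry incidence and cohort TP53 mutation counts
#'
#' Per-cancer, per-sex inputs for the incidence integration: US
#' population cancer incidence rates per 100,000 (SEER, age-adjusted
#' upstream) alongside TCGA cohort sizes and TP53-mutant patient counts for
#' 13 non-reproductive cancer types. For head and neck squamous carcinoma
#' the registry category is oral cavity and pharynx.
#'
#' @return Tibble with `cancer_type`, `sex`, `n_total`, `n_mut`,
#'   `rate_per_100k`.
#' @export
tp53_incidence_inputs <- function() {
  path <- system.file("extdata", "tp53_seer_tcga.tsv", package = "xdisparity",
                      mustWork = TRUE)
  df <- readr::read_tsv(path, show_col_types = FALSE)
  tibble::as_tibble(df)
}

#' Cohort mutation frequency
#'
#' @param n_mut Number of mutant patients (0 <= n_mut <= n_total).
#' @param n_total Cohort size (> 0).
#' @return `n_mut / n_total` at full precision (vectorised).
#' @export
mutation_frequency <- function(n_mut, n_total) {
  if (any(n_total <= 0)) abort("n_total must be positive")
  if (any(n_mut < 0 | n_mut > n_total)) abort("need 0 <= n_mut <= n_total")
  n_mut / n_total
}

#' Population rate of mutant cancer per 100,000
#'
#' Scales a population incidence rate by the cohort mutation frequency,
#' giving the projected per-100,000 frequency of cancer carrying the
#' mutation.
#'
#' @param seer_rate Incidence rate per 100,000 (>= 0).
#' @param mut_freq Mutation frequency in `[0, 1]`.
#' @return `seer_rate * mut_freq`, unrounded (vectorised).
#' @export
per100k <- function(seer_rate, mut_freq) {
  if (any(seer_rate < 0)) abort("seer_rate must be non-negative")
  seer_rate * mut_freq
}

#' Male/female disparity ratio
#'
#' Both arguments must be unrounded per-100,000 values: rounding the
#' intermediates first changes several printed ratios (e.g. a cancer whose
#' true ratio renders as 4.9 would render as 5.0 from 1-decimal inputs).
#'
#' @param male_per100k,female_per100k Unrounded per-100,000 mutant-cancer
#'   rates (female must be positive).
#' @return `male_per100k / female_per100k` (vectorised).
#' @export
mf_ratio <- function(male_per100k, female_per100k) {
  if (any(female_per100k <= 0)) abort("female per-100k rate must be positive for a defined ratio")
  male_per100k / female_per100k
}

#' Cancers eligible for the four-cell disparity analysis
#'
#' A cancer type qualifies iff each of the four groups — female mutant,
#' female wild-type, male mutant, male wild-type — contains at least
#' `min_cases` patients with known status.
#'
#' @param clinical Clinical tibble (see [read_clinical()]); patients with
#'   `tp53_status == "unknown"` are not counted.
#' @param min_cases Minimum per-cell count, default 5 (boundary inclusive).
#' @return Character vector of eligible cancer types.
#' @export
eligible_cancers <- function(clinical, min_cases = 5) {
  known <- dplyr::filter(clinical, .data$tp53_status %in% c("wt", "mutant"))
  cells <- dplyr::count(known, .data$cancer_type, .data$sex, .data$tp53_status)
  cells <- tidyr::complete(cells,
                           .data$cancer_type,
                           sex = sex_levels,
                           tp53_status = c("wt", "mutant"),
                           fill = list(n = 0L))
  ok <- dplyr::summarise(dplyr::group_by(cells, .data$cancer_type),
                         eligible = all(.data$n >= min_cases) & dplyr::n() == 4L,
                         .groups = "drop")
  sort(ok$cancer_type[ok$eligible])
}

#' Build the sex-disparity incidence table
#'
#' Integrates cohort mutation frequencies with population incidence rates:
#' for each cancer and sex, `per100k_mut = rate_per_100k * n_mut / n_total`,
#' and per cancer the male/female ratio of those unrounded rates. Rows are
#' ordered by descending ratio (female before male within a cancer).
#'
#' @param counts Tibble with `cancer_type`, `sex`, `n_total`, `n_mut` —
#'   either cohort-derived (see [cohort_tp53_counts()]) or taken from a
#'   published table.
#' @param incidence Tibble with `cancer_type`, `sex`, `rate_per_100k`
#'   (see [read_incidence()]).
#' @return Tibble with one row per cancer x sex: `cancer_type`, `sex`,
#'   `n_total`, `n_mut`, `mut_freq`, `rate_per_100k`, `per100k_mut`,
#'   `mf_ratio` (repeated within cancer), all at full precision.
#' @seealso [render_incidence_table()] for printed-precision rendering.
#' @export
build_incidence_table <- function(counts, incidence) {
  counts <- tibble::as_tibble(counts)
  need <- dplyr::distinct(counts, .data$cancer_type, .data$sex)
  have <- dplyr::distinct(incidence, .data$cancer_type, .data$sex)
  miss <- dplyr::anti_join(need, have, by = c("cancer_type", "sex"))
  if (nrow(miss) > 0) {
    abort(paste0("missing incidence row(s) for: ",
                 paste(paste(miss$cancer_type, miss$sex), collapse = "; ")))
  }
  tab <- dplyr::inner_join(counts, incidence, by = c("cancer_type", "sex"))
  tab$mut_freq <- mutation_frequency(tab$n_mut, tab$n_total)
  tab$per100k_mut <- per100k(tab$rate_per_100k, tab$mut_freq)
  wide <- tidyr::pivot_wider(
    dplyr::select(tab, "cancer_type", "sex", "per100k_mut"),
    names_from = "sex", values_from = "per100k_mut")
  wide$mf_ratio <- mf_ratio(wide$male, wide$female)
  tab <- dplyr::left_join(tab, dplyr::select(wide, "cancer_type", "mf_ratio"),
                          by = "cancer_type")
  tab <- dplyr::arrange(tab, dplyr::desc(.data$mf_ratio), .data$cancer_type,
                        .data$sex)
  dplyr::select(tab, "cancer_type", "sex", "n_total", "n_mut", "mut_freq",
                "rate_per_100k", "per100k_mut", "mf_ratio")
}

#' Per-cancer, per-sex TP53 mutation counts from a clinical table
#'
#' @param clinical Clinical tibble with known/unknown `tp53_status`.
#' @param cancers Optional cancer subset, e.g. from [eligible_cancers()].
#' @return Tibble with `cancer_type`, `sex`, `n_total`, `n_mut`, counting
#'   only patients with known TP53 status.
#' @export
cohort_tp53_counts <- function(clinical, cancers = NULL) {
  known <- dplyr::filter(clinical, .data$tp53_status %in% c("wt", "mutant"))
  if (!is.null(cancers)) known <- dplyr::filter(known, .data$cancer_type %in% cancers)
  dplyr::summarise(dplyr::group_by(known, .data$cancer_type, .data$sex),
                   n_total = dplyr::n(),
                   n_mut = sum(.data$tp53_status == "mutant"),
                   .groups = "drop")
}

#' Render an incidence table at report precision
#'
#' Rounds half away from zero at rendering only: mutation frequency to 2
#' decimals, per-100,000 rates and ratios to 1 decimal.
#'
#' @param table Output of [build_incidence_table()].
#' @return Tibble with rounded `mut_freq`, `per100k_mut`, `mf_ratio`.
#' @export
render_incidence_table <- function(table) {
  dplyr::mutate(table,
                mut_freq = round_half_up(.data$mut_freq, 2),
                per100k_mut = round_half_up(.data$per100k_mut, 1),
                mf_ratio = round_half_up(.data$mf_ratio, 1))
}
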