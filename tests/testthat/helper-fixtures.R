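# Shared fixture builders. Everything is constructed in code; the RMAF rule
# fixture keeps per-sample library sizes at exactly 1e6 counts (via a filler
# gene) so CPM values equal the raw counts laid out below.

toy_clinical <- function() {
  tibble::tibble(
    patient_id = paste0("P", 1:6),
    sex = c("female", "male", "female", "male", "female", "male"),
    cancer_type = "TST",
    age = c(50, 60, 55, 65, 70, 40),
    race = "white", smoking = c("never", "ever", "never", "ever", "never", "ever"),
    stage = "II", tp53_status = c("wt", "mutant", "wt", "mutant", "unknown", "wt"),
    os_time = c(100, 200, 300, 400, 500, 600),
    os_event = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE))
}

# 200-mutation cohort exercising every RMAF rule: direct quotients at the
# classification boundaries, the <10-read fallback through each of its three
# outcomes, the 5-CPM majority vote (including the exactly-50% failure and
# the inclusive CPM=5 boundary), the z <= -4 knockdown assignment, and the
# highest-RMAF-per-gene selection with positional tie-breaks.
rmaf_rule_fixture <- function() {
  n_per_sex <- 20
  pats_f <- sprintf("PF%02d", 1:n_per_sex)
  pats_m <- sprintf("PM%02d", 1:n_per_sex)
  patients <- c(pats_f, pats_m)
  clinical <- tibble::tibble(
    patient_id = patients,
    sex = rep(c("female", "male"), each = n_per_sex),
    cancer_type = "TST",
    age = 60, race = "white", smoking = "never", stage = "I",
    tp53_status = "wt", os_time = NA_real_, os_event = NA)

  genes <- c("GEXP", "GNEX", "GHALF", "GMAJ", "GKD", "GNOKD", "GMULTI")
  counts <- matrix(0, nrow = length(genes) + 1, ncol = length(patients),
                   dimnames = list(c(genes, "FILLER"), patients))
  counts["GEXP", ] <- 1000
  counts["GMULTI", ] <- 1000
  counts["GNEX", ] <- 0
  for (p in list(pats_f, pats_m)) {
    counts["GHALF", p[1:10]] <- 1000           # exactly 50%: majority fails
    counts["GMAJ", p[1:11]] <- 5               # 11/20 at the inclusive floor
    counts["GKD", p] <- 1000
    counts["GKD", p[11]] <- 0                  # the knockdown sample
    # natural spread so a modest dip stays above the z cut
    counts["GNOKD", p] <- rep(c(900, 1000, 1100), length.out = n_per_sex)
    counts["GNOKD", p[12]] <- 800
  }
  counts["FILLER", ] <- 1e6 - colSums(counts[genes, , drop = FALSE])

  row_id <- 0
  rows <- list()
  add <- function(pat, gene, pos, ref, alt) {
    row_id <<- row_id + 1
    rows[[row_id]] <<- tibble::tibble(patient_id = pat, gene = gene,
                                      chrom = "X", pos = pos,
                                      ref_reads = ref, alt_reads = alt)
  }

  # direct-path block: RMAF grid spanning both boundaries, two depths
  grid_rmaf <- c(0, 0.1, 0.2, 0.21, 0.5, 0.74, 0.75, 0.9, 1)
  pos <- 1000
  for (pat in c(pats_f[1:4], pats_m[1:4])) {
    for (total in c(10, 100)) {
      for (r in grid_rmaf) {
        pos <- pos + 10
        alt <- round(r * total)
        add(pat, "GEXP", pos, total - alt, alt)
      }
    }
  }

  # fallback block (total reads < 10), one rule per patient
  for (pats in list(pats_f, pats_m)) {
    add(pats[13], "GNEX", 50, 3, 2)      # gene never expressed -> discard
    add(pats[14], "GHALF", 60, 4, 4)     # 50% is not a majority -> discard
    add(pats[19], "GMAJ", 70, 2, 2)      # expressed at the 5-CPM floor; z mild
    add(pats[11], "GKD", 80, 4, 5)       # z <= -4 -> RMAF 1 (knockdown)
    add(pats[12], "GNOKD", 90, 1, 1)     # z > -4 -> discard
    add(pats[15], "GEXP", 95, 0, 0)      # no pileup reads at all
  }

  # gene-level resolution block on GMULTI
  for (pats in list(pats_f, pats_m)) {
    add(pats[16], "GMULTI", 100, 9, 1)   # 0.1
    add(pats[16], "GMULTI", 200, 1, 9)   # 0.9 -> selected
    add(pats[17], "GMULTI", 300, 5, 5)   # tie ...
    add(pats[17], "GMULTI", 250, 5, 5)   # ... smaller pos selected
    add(pats[18], "GMULTI", 400, 3, 2)   # <10 reads, z mild -> discarded
    add(pats[18], "GMULTI", 500, 7, 3)   # 0.3 -> selected by default
  }

  mut <- dplyr::bind_rows(rows)
  # pad with additional direct-path records up to exactly 200 mutations
  need <- 200 - nrow(mut)
  pad_pat <- rep(c(pats_f[5], pats_m[5]), length.out = need)
  for (i in seq_len(need)) {
    alt <- (i %% 21)
    add(pad_pat[i], "GEXP", 5000 + 10 * i, 20 - alt, alt)
  }
  mut <- dplyr::bind_rows(rows)
  stopifnot(nrow(mut) == 200)

  pileups <- dplyr::filter(
    dplyr::select(mut, "patient_id", "chrom", "pos", "ref_reads", "alt_reads"),
    !(.data$ref_reads == 0 & .data$alt_reads == 0))
  pileups$total_reads <- pileups$ref_reads + pileups$alt_reads
  mutations <- dplyr::mutate(
    dplyr::select(mut, "patient_id", "gene", "chrom", "pos"),
    ref_allele = "C", alt_allele = "T", var_class = "Missense_Mutation")
  list(clinical = clinical, mutations = mutations, pileups = pileups,
       counts = counts)
}
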