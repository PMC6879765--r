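# Literal re-derivation of the RMAF rules, one mutation at a time, written
# independently of the package pipeline (plain loops, its own CPM
# arithmetic). Used to check rule fidelity record by record.
oracle_rmaf <- function(mutations, pileups, clinical, counts,
                        em_min = 0.75, nem_max = 0.20, min_reads = 10,
                        cpm_min = 5, z_cut = -4, min_cohort = 3) {
  lib <- colSums(counts)
  cpm <- counts
  for (s in colnames(counts)) cpm[, s] <- counts[, s] / lib[s] * 1e6

  n <- nrow(mutations)
  rmaf <- rep(NA_real_, n); rule <- character(n); status <- character(n)
  total_v <- integer(n)
  for (i in seq_len(n)) {
    m <- mutations[i, ]
    if (m$chrom != "X") { status[i] <- "skip"; next }
    info <- clinical[clinical$patient_id == m$patient_id, ]
    hit <- pileups[pileups$patient_id == m$patient_id &
                     pileups$chrom == m$chrom & pileups$pos == m$pos, ]
    total <- if (nrow(hit) == 1) hit$ref_reads + hit$alt_reads else 0L
    total_v[i] <- total
    if (total >= min_reads) {
      rmaf[i] <- hit$alt_reads / total
      rule[i] <- "pileup"
    } else {
      cohort <- clinical$patient_id[clinical$sex == info$sex &
                                      clinical$cancer_type == info$cancer_type]
      cohort <- cohort[cohort %in% colnames(cpm)]
      if (length(cohort) == 0) {
        rule[i] <- "insufficient_info"
      } else if (!m$gene %in% rownames(cpm) ||
                 sum(cpm[m$gene, cohort] >= cpm_min) <= length(cohort) / 2) {
        rule[i] <- "not_expressed_gene"
      } else if (length(cohort) < min_cohort) {
        rule[i] <- "insufficient_info"
      } else {
        x <- log2(cpm[m$gene, cohort] + 1)
        s <- stats::sd(x)
        z <- if (is.finite(s) && s > 0) {
          (log2(cpm[m$gene, m$patient_id] + 1) - mean(x)) / s
        } else NA_real_
        if (!is.na(z) && z <= z_cut) {
          rmaf[i] <- 1
          rule[i] <- "knockdown_assigned"
        } else {
          rule[i] <- "insufficient_info"
        }
      }
    }
    status[i] <- if (is.na(rmaf[i])) "discarded"
      else if (rmaf[i] <= nem_max) "NEM"
      else if (rmaf[i] >= em_min) "EM"
      else "intermediate"
  }

  # highest RMAF per patient and gene, ties to the smallest position
  selected <- rep(FALSE, n)
  keys <- paste(mutations$patient_id, mutations$gene)
  for (k in unique(keys)) {
    idx <- which(keys == k & status != "discarded" & status != "skip")
    if (length(idx) == 0) next
    best <- idx[order(-rmaf[idx], mutations$pos[idx])][1]
    selected[best] <- TRUE
  }
  tibble::tibble(patient_id = mutations$patient_id, gene = mutations$gene,
                 pos = mutations$pos, total_reads = total_v, rmaf = rmaf,
                 rule = rule, status = status, selected = selected)
}
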