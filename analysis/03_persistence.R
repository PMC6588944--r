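#!/usr/bin/env Rscript
# Occurrence classes and persistent receptors: per-individual class
# summaries, memory/naive overlap, abundance and nucleotide-redundancy
# comparisons between occurrence extremes, and the high-abundance-only
# occupancy rerun (sampling-depth robustness check).

source(file.path("analysis", "00_config.R"))
cohort <- load_cohort()
Tn <- length(cohort$time_points)

for (id in names(cohort$series)) {
  ser <- cohort$series[[id]]
  prof <- occurrence_profile(ser)
  pers <- persistent_set(prof, Tn)
  summ <- occurrence_class_summary(ser, prof)
  write_table(summ$classes, sprintf("occurrence_classes_%s.tsv", id))
  write_table(summ$cumulative_abundance,
              sprintf("cumulative_abundance_%s.tsv", id))
  cat(sprintf("%s: %d/%d receptors persistent (%.2f%%), %.1f%%-%.1f%% of mass\n",
              id, length(pers), length(prof),
              100 * length(pers) / length(prof),
              100 * min(summ$cumulative_abundance[n_occ == Tn,
                                                  cumulative_abundance]),
              100 * max(summ$cumulative_abundance[n_occ == Tn,
                                                  cumulative_abundance])))
  cat(sprintf("  memory overlap of persistent receptors: %.3f\n",
              summ$classes[n_occ == Tn, memory_overlap_fraction]))

  for (metric in c("abundance", "nt_redundancy")) {
    mwu <- compare_occurrence_classes(ser, prof, metric)
    write_table(data.table(individual = id, metric = metric,
                           n_low = mwu$n1, n_high = mwu$n2, U = mwu$U,
                           p = mwu$p),
                sprintf("mwu_%s_%s.tsv", metric, id))
    extreme <- mwu[n1 == 1 & n2 == Tn]
    cat(sprintf("  %s, once vs persistent: U = %.0f, p = %.3g\n",
                metric, extreme$U, extreme$p))
  }

  # high-abundance-only occupancy: top receptors concentrate at n = T
  tops <- unique(unlist(lapply(ser$pbmc_samples, top_fraction, 0.01)))
  prof_hi <- prof[names(prof) %in% tops]
  occ <- data.table(n_occ = as.integer(names(table(prof_hi))),
                    unique_tcr_count = as.integer(table(prof_hi)))
  write_table(occ, sprintf("occurrence_classes_high_%s.tsv", id))
  cat(sprintf("  top-1%% receptors: mean occurrence %.2f (all: %.2f)\n",
              mean(prof_hi), mean(prof)))
}
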