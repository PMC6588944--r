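#!/usr/bin/env Rscript
# Publicness: receptors are binned by the fraction of an external cohort
# sharing them; persistence is cross-tabulated against publicness, and the
# excess of highly public receptors (> 70% of the cohort) among persistent
# receptors is tested.

source(file.path("analysis", "00_config.R"))
cohort <- load_cohort()
Tn <- length(cohort$time_points)

profiles <- lapply(cohort$series, occurrence_profile)

for (id in names(profiles)) {
  bins <- publicness_bins(names(profiles[[id]]), cohort$sharing)
  op <- occurrence_by_publicness(bins, profiles[[id]])
  write_table(op$histogram, sprintf("publicness_hist_%s.tsv", id))
  write_table(op$mean_share_by_occurrence,
              sprintf("publicness_mean_share_%s.tsv", id))
}

enr <- highly_public_enrichment(profiles, cohort$sharing, Tn,
                                n_perm = 10000, seed = SEED)
write_table(enr$counts, "publicness_enrichment_counts.tsv")
print(enr$counts)
cat(sprintf("once vs persistent highly-public counts: t = %.3f, p = %.4g\n",
            enr$t_statistic, enr$t_p))
write_table(enr$permutation, "publicness_enrichment_permutation.tsv")
print(enr$permutation)

mp <- most_public_report(cohort$sharing, profiles, Tn)
write_table(mp, "most_public_report.tsv")
cat(sprintf("%d receptors shared by > 90%% of the external cohort\n",
            nrow(mp)))
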