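#!/usr/bin/env Rscript
# Per-sample summary statistics, repertoire overlap (Jaccard), and
# abundance correlations between time points.

source(file.path("analysis", "00_config.R"))
cohort <- load_cohort()

all_samples <- unlist(lapply(cohort$series, function(ser)
  c(ser$pbmc_samples, ser$memory_samples, ser$naive_samples)),
  recursive = FALSE)

st <- summary_stats(all_samples)
write_table(st, "summary_stats.tsv")

jm <- jaccard_matrix(all_samples)
write_table(as.data.table(jm, keep.rownames = "sample"),
            "jaccard_matrix.tsv")

ind_of <- sub("/.*", "", rownames(jm))
comp_of <- sub(".*/", "", rownames(jm))
pb <- comp_of == "PBMC"
pairs <- which(upper.tri(jm), arr.ind = TRUE)
pairs <- pairs[pb[pairs[, 1]] & pb[pairs[, 2]], , drop = FALSE]
same <- ind_of[pairs[, 1]] == ind_of[pairs[, 2]]
jwb <- data.table(
  comparison = c("within_individual", "between_individual"),
  mean_jaccard = c(mean(jm[pairs[same, , drop = FALSE]]),
                   mean(jm[pairs[!same, , drop = FALSE]])))
write_table(jwb, "jaccard_within_between.tsv")
cat(sprintf("within-individual mean Jaccard %.4f, between %.4f\n",
            jwb$mean_jaccard[1], jwb$mean_jaccard[2]))

panels <- list()
for (ser in cohort$series) {
  id <- ser$individual_id
  pb <- ser$pbmc_samples
  combos <- list(month = c(1, 2), year = c(1, length(pb)))
  for (nm in names(combos)) {
    res <- shared_abundance_correlation(
      abundance_vector(pb[[combos[[nm]][1]]]),
      abundance_vector(pb[[combos[[nm]][2]]]), "spearman")
    panels[[length(panels) + 1]] <- data.table(
      individual = id, panel = nm, n_shared = res$n_shared,
      rho = res$coefficient, p = res$p)
  }
}
panels <- rbindlist(panels)
write_table(panels, "correlation_panels.tsv")
print(panels)

# rarefaction of the first library, demonstrating sampling saturation
s0 <- cohort$series[[1]]$pbmc_samples[[1]]
depths <- round(seq(0.1, 1, by = 0.1) * sum(s0$records$count))
rc <- rarefaction_curve(s0, depths, n_reps = 5, seed = SEED)
write_table(rc, "rarefaction_S01_t00.tsv")
cat(sprintf("rarefaction: %.0f unique at half depth vs %.0f at full\n",
            rc[depth == depths[5], mean_unique_tcrs],
            rc[depth == depths[10], mean_unique_tcrs]))
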