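#!/usr/bin/env Rscript
# Clonal cohorts: receptors repeatedly in the top 1% whose trajectories
# correlate above 0.95 form cliques; clique size is permutation-tested and
# members are screened for sequencing-error signatures.

source(file.path("analysis", "00_config.R"))
cohort <- load_cohort()

reports <- list()
for (id in names(cohort$series)) {
  ser <- cohort$series[[id]]
  for (method in c("spearman", "pearson")) {
    det <- detect_cohort(ser, method = method)
    if (length(det$members) < 2 || is.null(det$matrix)) {
      cat(sprintf("%s/%s: no cohort (%d candidates)\n", id, method,
                  length(det$candidates)))
      next
    }
    sig <- cohort_significance(ser, length(det$members), n_perm = 1000,
                               method = method,
                               seed = SEED + match(id, names(cohort$series)))
    mean_ab <- rowMeans(det$matrix$abundance)[det$members]
    flags <- flag_artifact_suspects(det$members, mean_ab)
    cat(sprintf("%s/%s: %d candidates, clique of %d, p = %.4g, %d flagged\n",
                id, method, length(det$candidates), length(det$members),
                sig$p, sum(flags$flagged)))
    reports[[length(reports) + 1]] <- cbind(
      data.table(individual = id, method = method,
                 n_candidates = length(det$candidates),
                 clique_size = length(det$members), p = sig$p),
      flags)
  }
}
write_table(rbindlist(reports), "cohort_reports.tsv")
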