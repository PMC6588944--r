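# Shared configuration for the numbered analysis scripts. Run every script
# from the repository root, in order; 01 writes the cohort that 02-06 read.

suppressMessages({
  library(tcrpersist)
  library(data.table)
})

SEED <- 20190625
DATA_DIR <- file.path("results", "data")
TABLE_DIR <- file.path("results", "tables")
dir.create(TABLE_DIR, recursive = TRUE, showWarnings = FALSE)

write_table <- function(dt, name) {
  path <- file.path(TABLE_DIR, name)
  fwrite(dt, path, sep = "\t")
  cat("  wrote", path, "\n")
}

# Rebuild the tcr_series objects from the TSVs written by 01_simulate.R —
# the same reading path an external immunoSEQ export would take.
load_cohort <- function() {
  cfg <- yaml::read_yaml(file.path(DATA_DIR, "sim_config.yaml"))
  ids <- sprintf("S%02d", seq_len(cfg$n_individuals))
  read_one <- function(id, tp, comp) {
    read_repertoire_tsv(
      file.path(DATA_DIR, sprintf("%s_t%02d_%s.tsv", id, as.integer(tp),
                                  comp)),
      id, tp, comp)
  }
  series <- lapply(ids, function(id) {
    tcr_series(
      lapply(cfg$time_points, read_one, id = id, comp = "PBMC"),
      lapply(cfg$sorted_time_points, read_one, id = id, comp = "memory"),
      lapply(cfg$sorted_time_points, read_one, id = id, comp = "naive"))
  })
  names(series) <- ids
  list(series = series,
       sharing = read_sharing_tsv(file.path(DATA_DIR, "sharing_table.tsv")),
       truth = fread(file.path(DATA_DIR, "truth_labels.tsv")),
       time_points = cfg$time_points, seed = cfg$seed)
}
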