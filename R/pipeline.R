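PIPELINE_DEFAULTS <- list(
  stats = list(top_fraction = 0.01, high_abundance_parallel = TRUE,
               rarefaction_depths = 0L),
  persistence = list(),
  network = list(d_max = 1L, same_vj = FALSE, n_perm = 10000L),
  cohort = list(fraction = 0.01, min_times = 2L, threshold = 0.95,
                inclusive = FALSE, n_perm = 1000L),
  public = list(high_threshold = 0.70, n_perm = 10000L,
                most_public_threshold = 0.90))

apply_block_defaults <- function(block, defaults, name) {
  block <- block %||% list()
  unknown <- setdiff(names(block), names(defaults))
  if (length(unknown) > 0)
    stop("validate_config: unknown key '", name, ".", unknown[1], "'")
  utils::modifyList(defaults, block)
}

#' Validate and resolve a pipeline configuration
#'
#' Reads a YAML run configuration, applies defaults (top fraction 0.01,
#' correlation threshold 0.95, network edit distance 1, 10,000 shuffles for
#' the connectivity and publicness permutation tests, 1000 for the cohort
#' test) and rejects unknown keys. A configuration names either a sample
#' `manifest` (per sample: `path`, `individual`, `time_point`,
#' `compartment`, plus an optional `sharing` file) or a `simulate` block of
#' [sim_config()] parameters — never both.
#'
#' @param path YAML file path.
#' @return a resolved `run_config` list.
#' @export
validate_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("manifest", "simulate", "sharing", "outdir", "seed",
             names(PIPELINE_DEFAULTS))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    stop("validate_config: unknown key '", unknown[1], "'")
  if (is.null(cfg$seed) || !is.numeric(cfg$seed))
    stop("validate_config: 'seed' (integer) is required")
  if (is.null(cfg$outdir) || !is.character(cfg$outdir))
    stop("validate_config: 'outdir' (string) is required")
  has_manifest <- !is.null(cfg$manifest)
  has_sim <- !is.null(cfg$simulate)
  if (has_manifest == has_sim)
    stop("validate_config: exactly one of 'manifest' or 'simulate' required")
  if (has_manifest) {
    for (entry in cfg$manifest) {
      for (field in c("path", "individual", "time_point", "compartment")) {
        if (is.null(entry[[field]]))
          stop("validate_config: manifest entry missing '", field, "'")
      }
      if (!file.exists(entry$path))
        stop("validate_config: manifest file not found: ", entry$path)
    }
    if (!is.null(cfg$sharing) && !file.exists(cfg$sharing))
      stop("validate_config: sharing file not found: ", cfg$sharing)
  } else {
    sim_known <- setdiff(names(formals(sim_config)), "seed")
    unknown_sim <- setdiff(names(cfg$simulate), sim_known)
    if (length(unknown_sim) > 0)
      stop("validate_config: unknown key 'simulate.", unknown_sim[1], "'")
  }
  for (blk in names(PIPELINE_DEFAULTS)) {
    cfg[[blk]] <- apply_block_defaults(cfg[[blk]], PIPELINE_DEFAULTS[[blk]],
                                       blk)
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

load_series_from_manifest <- function(manifest) {
  samples <- lapply(manifest, function(e) {
    read_repertoire_tsv(e$path, e$individual, e$time_point, e$compartment)
  })
  ids <- vapply(samples, function(s) s$individual_id, character(1))
  series <- lapply(unique(ids), function(id) {
    mine <- samples[ids == id]
    comp <- vapply(mine, function(s) s$compartment, character(1))
    tcr_series(mine[comp == "PBMC"], mine[comp == "memory"],
               mine[comp == "naive"])
  })
  stats::setNames(series, unique(ids))
}

write_tsv <- function(dt, dir, name) {
  data.table::fwrite(dt, file.path(dir, name), sep = "\t")
}

#' Run the full longitudinal repertoire analysis
#'
#' Orchestrates every stage on a validated configuration: per-sample summary
#' statistics, the all-sample Jaccard matrix with within- vs
#' between-individual means, abundance correlation panels, per-individual
#' occurrence profiles / persistent sets / occurrence-class summaries and
#' Mann-Whitney class comparisons, the CDR3 similarity network with
#' connectivity permutation test, clonal-cohort detection (both correlation
#' methods) with shuffled-label significance and artifact flags, publicness
#' binning and enrichment (when a sharing table is available), and an
#' optional high-abundance-only re-run of the persistence analysis. All
#' stochastic stages use seeds derived from the global seed plus the stage
#' name, so identical configurations give byte-identical numeric tables.
#'
#' @param config a [validate_config()] result (or equivalent list).
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  sharing <- NULL
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", {
      args <- config$simulate %||% list()
      args$seed <- derive_seed(config$seed, "simulate")
      cohort <- simulate_cohort(do.call(sim_config, args))
      write_tsv(truth_labels(cohort$truth), outdir, "truth_labels.tsv")
      cohort
    })
    series_list <- sim$series
    sharing <- sim$sharing
  } else {
    series_list <- stage("load", load_series_from_manifest(config$manifest))
    if (!is.null(config$sharing))
      sharing <- stage("load", read_sharing_tsv(config$sharing))
  }

  all_samples <- unlist(lapply(series_list, function(ser)
    c(ser$pbmc_samples, ser$memory_samples, ser$naive_samples)),
    recursive = FALSE)

  stage("stats", {
    write_tsv(summary_stats(all_samples), outdir, "summary_stats.tsv")
    jm <- jaccard_matrix(all_samples)
    write_tsv(data.table::as.data.table(jm, keep.rownames = "sample"),
              outdir, "jaccard_matrix.tsv")
    ind_of <- sub("/.*", "", rownames(jm))
    comp_of <- sub(".*/", "", rownames(jm))
    pb <- comp_of == "PBMC"
    pairs <- which(upper.tri(jm), arr.ind = TRUE)
    pairs <- pairs[pb[pairs[, 1]] & pb[pairs[, 2]], , drop = FALSE]
    same <- ind_of[pairs[, 1]] == ind_of[pairs[, 2]]
    write_tsv(data.table::data.table(
      comparison = c("within_individual", "between_individual"),
      mean_jaccard = c(mean(jm[pairs[same, , drop = FALSE]]),
                       if (any(!same)) mean(jm[pairs[!same, , drop = FALSE]])
                       else NA_real_)),
      outdir, "jaccard_within_between.tsv")
  })

  stage("correlations", {
    panels <- list()
    add_panel <- function(label, s1, s2) {
      res <- tryCatch(
        shared_abundance_correlation(abundance_vector(s1),
                                     abundance_vector(s2), "spearman"),
        error = function(e) NULL)
      if (!is.null(res))
        panels[[length(panels) + 1]] <<- data.table::data.table(
          panel = label, n_shared = res$n_shared, rho = res$coefficient,
          p = res$p)
    }
    for (ser in series_list) {
      id <- ser$individual_id
      pb <- ser$pbmc_samples
      if (length(pb) >= 2) add_panel(paste0(id, ":month"), pb[[1]], pb[[2]])
      if (length(pb) >= 3)
        add_panel(paste0(id, ":year"), pb[[1]], pb[[length(pb)]])
      if (length(ser$memory_samples) >= 2)
        add_panel(paste0(id, ":memory_month"), ser$memory_samples[[1]],
                  ser$memory_samples[[2]])
      if (length(ser$naive_samples) >= 2)
        add_panel(paste0(id, ":naive_month"), ser$naive_samples[[1]],
                  ser$naive_samples[[2]])
    }
    if (length(series_list) >= 2) {
      add_panel("cross_individual", series_list[[1]]$pbmc_samples[[1]],
                series_list[[2]]$pbmc_samples[[1]])
    }
    write_tsv(data.table::rbindlist(panels), outdir,
              "correlation_panels.tsv")
  })

  profiles <- list()
  for (ser in series_list) {
    id <- ser$individual_id
    Tn <- length(ser$pbmc_samples)

    prof <- stage("persistence", {
      prof <- occurrence_profile(ser)
      pers <- persistent_set(prof, Tn)
      summ <- occurrence_class_summary(ser, prof)
      write_tsv(data.table::data.table(tcr = names(prof),
                                       n_occ = as.integer(prof),
                                       persistent = names(prof) %in% pers),
                outdir, sprintf("occurrences_%s.tsv", id))
      write_tsv(summ$classes, outdir,
                sprintf("occurrence_classes_%s.tsv", id))
      write_tsv(summ$cumulative_abundance, outdir,
                sprintf("cumulative_abundance_%s.tsv", id))
      for (metric in c("abundance", "nt_redundancy")) {
        write_tsv(compare_occurrence_classes(ser, prof, metric), outdir,
                  sprintf("mwu_%s_%s.tsv", metric, id))
      }
      prof
    })
    profiles[[id]] <- prof

    if (isTRUE(config$stats$high_abundance_parallel)) {
      stage("persistence_high_abundance", {
        tops <- lapply(ser$pbmc_samples, top_fraction,
                       fraction = config$stats$top_fraction)
        occ_hi <- table(unlist(tops))
        prof_hi <- stats::setNames(as.integer(occ_hi), names(occ_hi))
        summ_hi_tab <- data.table::data.table(
          n_occ = as.integer(names(table(prof_hi))),
          unique_tcr_count = as.integer(table(prof_hi)))
        write_tsv(summ_hi_tab, outdir,
                  sprintf("occurrence_classes_high_%s.tsv", id))
      })
    }

    stage("network", {
      tcrs <- names(prof)
      g <- build_similarity_graph(tcrs, d_max = config$network$d_max,
                                  same_vj = config$network$same_vj)
      bins <- neighbor_decile_bins(g)
      pc <- persistence_by_connectivity(bins, prof)
      pt <- connectivity_permutation_test(
        bins, prof, n_perm = config$network$n_perm,
        seed = derive_seed(config$seed, "network", id))
      write_tsv(bins[, .(n_tcrs = .N), by = .(bin, bin_label)], outdir,
                sprintf("network_bins_%s.tsv", id))
      write_tsv(pc$histogram, outdir,
                sprintf("network_occurrence_hist_%s.tsv", id))
      write_tsv(data.table::data.table(
        individual_id = id, trend = pt$observed, p = pt$p,
        n_perm = pt$n_perm, d_max = config$network$d_max,
        same_vj = config$network$same_vj),
        outdir, sprintf("network_trend_%s.tsv", id))
    })

    stage("cohorts", {
      reports <- list()
      for (method in c("spearman", "pearson")) {
        det <- detect_cohort(ser, fraction = config$cohort$fraction,
                             min_times = config$cohort$min_times,
                             method = method,
                             threshold = config$cohort$threshold,
                             inclusive = config$cohort$inclusive)
        if (length(det$members) >= 2 && !is.null(det$matrix)) {
          sig <- cohort_significance(
            ser, length(det$members), n_perm = config$cohort$n_perm,
            seed = derive_seed(config$seed, "cohort", id, method),
            fraction = config$cohort$fraction,
            min_times = config$cohort$min_times, method = method,
            threshold = config$cohort$threshold,
            inclusive = config$cohort$inclusive)
          mean_ab <- rowMeans(det$matrix$abundance)[det$members]
          flags <- flag_artifact_suspects(det$members, mean_ab)
          rep_dt <- cbind(
            data.table::data.table(individual_id = id, method = method,
                                   clique_size = length(det$members),
                                   p = sig$p),
            flags,
            data.table::as.data.table(
              det$matrix$abundance[det$members, , drop = FALSE]))
          reports[[length(reports) + 1]] <- rep_dt
        } else {
          reports[[length(reports) + 1]] <- data.table::data.table(
            individual_id = id, method = method,
            clique_size = length(det$members), p = NA_real_)
        }
      }
      write_tsv(data.table::rbindlist(reports, fill = TRUE), outdir,
                sprintf("cohort_report_%s.tsv", id))
    })
  }

  if (!is.null(sharing)) {
    stage("publicness", {
      Tn <- length(series_list[[1]]$pbmc_samples)
      for (id in names(profiles)) {
        bins <- publicness_bins(names(profiles[[id]]), sharing)
        op <- occurrence_by_publicness(bins, profiles[[id]])
        write_tsv(op$histogram, outdir,
                  sprintf("publicness_hist_%s.tsv", id))
        write_tsv(op$mean_share_by_occurrence, outdir,
                  sprintf("publicness_mean_share_%s.tsv", id))
      }
      enr <- highly_public_enrichment(
        profiles, sharing, Tn,
        high_threshold = config$public$high_threshold,
        n_perm = config$public$n_perm,
        seed = derive_seed(config$seed, "public"))
      write_tsv(enr$counts, outdir, "publicness_enrichment_counts.tsv")
      write_tsv(data.table::data.table(
        t_statistic = enr$t_statistic, t_p = enr$t_p,
        undefined = isTRUE(enr$undefined)),
        outdir, "publicness_enrichment_test.tsv")
      if (!is.null(enr$permutation))
        write_tsv(enr$permutation, outdir,
                  "publicness_enrichment_permutation.tsv")
      write_tsv(most_public_report(
        sharing, profiles, Tn,
        top_fraction_threshold = config$public$most_public_threshold),
        outdir, "most_public_report.tsv")
    })
  }

  manifest <- list(seed = config$seed,
                   stats = config$stats, network = config$network,
                   cohort = config$cohort, public = config$public,
                   individuals = names(series_list),
                   generated = !is.null(config$simulate))
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}
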