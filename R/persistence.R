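#' Occurrence profile of a longitudinal series
#'
#' For every productive receptor observed in at least one PBMC sample of an
#' individual's series, the number of PBMC time points at which it was
#' detected (abundance > 0). Sorted memory/naive samples are excluded from
#' the count.
#'
#' @param series a [tcr_series()].
#' @return named integer vector: TCR key -> n time points observed,
#'   in \[1, T\].
#' @export
occurrence_profile <- function(series) {
  stopifnot(length(series$pbmc_samples) >= 1)
  keys <- unlist(lapply(series$pbmc_samples,
                        function(s) collapse_to_tcrs(s)$tcr),
                 use.names = FALSE)
  tab <- table(keys)
  stats::setNames(as.integer(tab), names(tab))
}

#' Persistent receptor set
#'
#' Receptors detected at every PBMC time point of the series: the
#' "persistent" subset. With a single time point every observed receptor is
#' trivially persistent.
#'
#' @param profile an [occurrence_profile()].
#' @param n_timepoints total number of PBMC time points T.
#' @return character vector of TCR keys.
#' @export
persistent_set <- function(profile, n_timepoints) {
  if (n_timepoints == 0) stop("persistent_set: n_timepoints must be >= 1")
  names(profile)[profile == n_timepoints]
}

#' Per-occurrence-class summary of a series
#'
#' Groups receptors by the number of time points n at which they occur and
#' summarises each class: unique receptor count; mean abundance (each
#' receptor's abundance averaged over the samples where it is PRESENT, then
#' averaged over class members); mean nucleotide redundancy (distinct CDR3
#' nucleotide sequences per receptor across the whole series); overlap with
#' the pooled memory and naive compartments (fraction of class members seen
#' in the union of the sorted samples; NA when no sorted samples exist); and
#' the cumulative abundance the class contributes to each PBMC sample
#' (summed receptor frequencies, denominator including nonproductive mass,
#' so the columns across classes sum to the sample's productive fraction).
#'
#' @param series a [tcr_series()].
#' @param profile an [occurrence_profile()] computed from `series`.
#' @return list with `classes` (data.table, one row per n) and
#'   `cumulative_abundance` (data.table: n x time point matrix, long form).
#' @export
occurrence_class_summary <- function(series, profile) {
  Tn <- length(series$pbmc_samples)
  per_sample <- lapply(series$pbmc_samples, collapse_to_tcrs)
  all_rec <- data.table::rbindlist(lapply(seq_len(Tn), function(i) {
    x <- per_sample[[i]][, .(tcr, abundance)]
    x[, time_point := as.numeric(series$pbmc_samples[[i]]$time_point)]
    x
  }))
  prof_dt <- data.table::data.table(tcr = names(profile),
                                    n_occ = as.integer(profile))
  all_rec <- merge(all_rec, prof_dt, by = "tcr")

  # nucleotide redundancy across the series: distinct nt lineages per receptor
  nt <- data.table::rbindlist(lapply(series$pbmc_samples, function(s) {
    r <- s$records[productive == TRUE]
    data.table::data.table(tcr = tcr_key(r$v_gene, r$amino_acid, r$j_gene),
                           cdr3_nt = r$cdr3_nt)
  }))
  nt_red <- nt[, .(nt_redundancy = data.table::uniqueN(cdr3_nt)), by = tcr]

  per_tcr <- all_rec[, .(mean_abundance = mean(abundance), n_occ = n_occ[1]),
                     by = tcr]
  per_tcr <- merge(per_tcr, nt_red, by = "tcr")

  mem_union <- if (length(series$memory_samples) > 0)
    unique(unlist(lapply(series$memory_samples,
                         function(s) collapse_to_tcrs(s)$tcr))) else NULL
  nai_union <- if (length(series$naive_samples) > 0)
    unique(unlist(lapply(series$naive_samples,
                         function(s) collapse_to_tcrs(s)$tcr))) else NULL

  classes <- per_tcr[, .(
    unique_tcr_count = .N,
    mean_abundance = mean(mean_abundance),
    mean_nt_redundancy = mean(nt_redundancy),
    memory_overlap_fraction = if (is.null(mem_union)) NA_real_
      else mean(tcr %in% mem_union),
    naive_overlap_fraction = if (is.null(nai_union)) NA_real_
      else mean(tcr %in% nai_union)
  ), by = .(n_occ)]
  data.table::setorder(classes, n_occ)

  cum <- all_rec[, .(cumulative_abundance = sum(abundance)),
                 by = .(n_occ, time_point)]
  data.table::setorder(cum, n_occ, time_point)
  list(classes = classes[], cumulative_abundance = cum[])
}

#' Compare occurrence classes with pairwise Mann-Whitney U tests
#'
#' For every pair of occurrence classes (n1 < n2), a two-sided Mann-Whitney
#' U test on the chosen per-receptor metric: mean abundance over the samples
#' where the receptor is present, or nucleotide redundancy across the
#' series. The reported U statistic follows the convention of the lower-n
#' class (the rank-sum-derived U of the first group); the normal
#' approximation with continuity correction is used for large classes and
#' the exact distribution for small tie-free ones.
#'
#' @param series a [tcr_series()].
#' @param profile an [occurrence_profile()] of `series`.
#' @param metric "abundance" or "nt_redundancy".
#' @return data.table with columns `n1`, `n2`, `n1_size`, `n2_size`,
#'   `U`, `p`.
#' @export
compare_occurrence_classes <- function(series, profile,
                                       metric = c("abundance",
                                                  "nt_redundancy")) {
  metric <- match.arg(metric)
  Tn <- length(series$pbmc_samples)
  per_sample <- lapply(series$pbmc_samples, collapse_to_tcrs)
  all_rec <- data.table::rbindlist(
    lapply(per_sample, function(x) x[, .(tcr, abundance)]))
  vals <- if (metric == "abundance") {
    all_rec[, .(value = mean(abundance)), by = tcr]
  } else {
    nt <- data.table::rbindlist(lapply(series$pbmc_samples, function(s) {
      r <- s$records[productive == TRUE]
      data.table::data.table(tcr = tcr_key(r$v_gene, r$amino_acid, r$j_gene),
                             cdr3_nt = r$cdr3_nt)
    }))
    nt[, .(value = as.numeric(data.table::uniqueN(cdr3_nt))), by = tcr]
  }
  vals[, n_occ := profile[tcr]]
  ns <- sort(unique(vals$n_occ))
  if (length(ns) < 2) stop("compare_occurrence_classes: fewer than 2 classes")
  out <- list()
  for (i in seq_len(length(ns) - 1)) {
    for (j in (i + 1):length(ns)) {
      x <- vals$value[vals$n_occ == ns[i]]
      y <- vals$value[vals$n_occ == ns[j]]
      wt <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))
      out[[length(out) + 1]] <- data.table::data.table(
        n1 = ns[i], n2 = ns[j], n1_size = length(x), n2_size = length(y),
        U = unname(wt$statistic), p = wt$p.value)
    }
  }
  data.table::rbindlist(out)
}
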