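#' Sharing table: receptor publicness in an external cohort
#'
#' Maps TCRbeta identities to the number of subjects, out of a reference
#' cohort of known size, in which each receptor was observed. Receptors
#' absent from the table look up as 0 (observed in no cohort subject).
#'
#' @param counts named integer vector: TCR key -> share count.
#' @param cohort_size number of subjects in the reference cohort.
#' @return object of class `sharing_table`.
#' @export
sharing_table <- function(counts, cohort_size) {
  stopifnot(cohort_size > 0)
  keys <- names(counts) %||% character(0)
  counts <- as.integer(counts)
  if (any(counts < 0 | counts > cohort_size))
    stop("share counts must lie in [0, cohort_size]")
  structure(list(counts = counts, keys = keys,
                 cohort_size = as.integer(cohort_size)),
            class = "sharing_table")
}

#' @export
print.sharing_table <- function(x, ...) {
  cat(sprintf("<sharing_table> %d receptors over a cohort of %d subjects\n",
              length(x$counts), x$cohort_size))
  invisible(x)
}

#' Share counts / fractions for a set of receptors
#'
#' @param sharing a [sharing_table()].
#' @param tcrs character vector of TCR keys.
#' @return `share_count`: integer vector (0 for receptors absent from the
#'   table); `share_fraction`: the counts divided by the cohort size.
#' @export
share_count <- function(sharing, tcrs) {
  hit <- match(tcrs, sharing$keys)
  out <- sharing$counts[hit]
  out[is.na(hit)] <- 0L
  out
}

#' @rdname share_count
#' @export
share_fraction <- function(sharing, tcrs) {
  share_count(sharing, tcrs) / sharing$cohort_size
}

#' Read / write a sharing table TSV
#'
#' Tab-delimited with columns `aminoAcid`, `vGeneName`, `jGeneName`,
#' `share_count`; the cohort size is carried in a `# cohort_size=N` header
#' comment line.
#'
#' @param path file path.
#' @return a [sharing_table()].
#' @export
read_sharing_tsv <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^# cohort_size=\\d+$", first))
    stop("sharing TSV must start with a '# cohort_size=N' header line")
  cohort_size <- as.integer(sub("^# cohort_size=", "", first))
  dt <- data.table::fread(path, sep = "\t", skip = 1)
  for (col in c("aminoAcid", "vGeneName", "jGeneName", "share_count")) {
    if (!col %in% names(dt)) stop("missing mandatory column: '", col, "'")
  }
  keys <- tcr_key(dt$vGeneName, dt$aminoAcid, dt$jGeneName)
  sharing_table(stats::setNames(dt$share_count, keys), cohort_size)
}

#' @rdname read_sharing_tsv
#' @param sharing a [sharing_table()].
#' @export
write_sharing_tsv <- function(sharing, path) {
  parts <- tcr_unkey(sharing$keys)
  dt <- data.table::data.table(
    aminoAcid = parts$cdr3_aa, vGeneName = parts$v_gene,
    jGeneName = parts$j_gene, share_count = sharing$counts)
  data.table::setorder(dt, vGeneName, aminoAcid, jGeneName)
  writeLines(sprintf("# cohort_size=%d", sharing$cohort_size), path)
  data.table::fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Bin receptors into publicness deciles
#'
#' A receptor shared by a fraction f of the cohort lands in decile bin
#' `min(floor(10 f), 9)` — so f = 1 is clamped into the "90-100%" bin.
#'
#' @param tcrs character vector of TCR keys.
#' @param sharing a [sharing_table()].
#' @return data.table `tcr`, `share_count`, `share_fraction`, `bin` (0..9),
#'   `bin_label`.
#' @export
publicness_bins <- function(tcrs, sharing) {
  tcrs <- unique(tcrs)
  f <- share_fraction(sharing, tcrs)
  bin <- pmin(as.integer(floor(10 * f)), 9L)
  data.table::data.table(tcr = tcrs, share_count = share_count(sharing, tcrs),
                         share_fraction = f, bin = bin,
                         bin_label = sprintf("%d-%d%%", bin * 10,
                                             (bin + 1) * 10))
}

#' Occurrence distributions by publicness bin
#'
#' Per publicness decile, the normalized distribution of the number of time
#' points at which member receptors occur; and, transposed, the mean share
#' fraction per occurrence class.
#'
#' @param bins a [publicness_bins()] table.
#' @param profile an [occurrence_profile()] covering the binned receptors.
#' @return list with `histogram` (data.table `bin`, `n_occ`, `fraction`)
#'   and `mean_share_by_occurrence` (data.table `n_occ`,
#'   `mean_share_fraction`).
#' @export
occurrence_by_publicness <- function(bins, profile) {
  missing <- setdiff(bins$tcr, names(profile))
  if (length(missing) > 0)
    stop("receptors missing from occurrence profile: ",
         paste(utils::head(missing, 5), collapse = ", "))
  dt <- data.table::data.table(bin = bins$bin,
                               share_fraction = bins$share_fraction,
                               n_occ = as.integer(profile[bins$tcr]))
  hist <- dt[, .N, by = .(bin, n_occ)]
  hist[, fraction := N / sum(N), by = bin]
  data.table::setorder(hist, bin, n_occ)
  by_occ <- dt[, .(mean_share_fraction = mean(share_fraction)), by = n_occ]
  data.table::setorder(by_occ, n_occ)
  list(histogram = hist[, .(bin, n_occ, fraction)],
       mean_share_by_occurrence = by_occ[])
}

#' Enrichment of highly public receptors among persistent receptors
#'
#' "Highly public" receptors are those shared by strictly more than
#' `high_threshold` of the reference cohort. Per individual, the number of
#' highly public receptors among (a) the persistent set and (b) the
#' receptors observed only once is counted. Across individuals an
#' independent two-sample t-test compares the once-observed counts against
#' the persistent counts (negative t means persistent receptors carry
#' more). In addition a per-individual permutation test shuffles the
#' occurrence counts across receptors and recounts highly public receptors
#' falling in the shuffled persistent set (add-one p).
#'
#' @param profiles named list of [occurrence_profile()]s, one per
#'   individual.
#' @param sharing a [sharing_table()].
#' @param n_timepoints total PBMC time points T (persistence cutoff).
#' @param high_threshold share-fraction threshold for "highly public"
#'   (strict).
#' @param n_perm permutation count per individual (study analyses use
#'   10,000).
#' @param seed integer seed.
#' @param smoothed also return, per individual, the randomized Monte Carlo
#'   p-value `p_smoothed = (G + U (1 + E)) / (1 + n_perm)` with G the count
#'   of permuted counts strictly above the observed one, E the count of
#'   ties and U uniform on (0, 1) — exactly uniform under the null despite
#'   the integer statistic, hence the right quantity for calibration
#'   audits; report `p` for inference.
#' @return list with `counts` (per-individual data.table), `t_statistic`,
#'   `t_p`, and `permutation` (per-individual observed count and p). When
#'   no receptor is highly public the enrichment is reported absent
#'   (`undefined = TRUE`).
#' @export
highly_public_enrichment <- function(profiles, sharing, n_timepoints,
                                     high_threshold = 0.70, n_perm = 10000,
                                     seed = 1, smoothed = FALSE) {
  ids <- names(profiles) %||% paste0("ind", seq_along(profiles))
  counts <- data.table::rbindlist(lapply(seq_along(profiles), function(i) {
    prof <- profiles[[i]]
    hp <- share_fraction(sharing, names(prof)) > high_threshold
    data.table::data.table(
      individual_id = ids[i],
      n_highly_public = sum(hp),
      persistent_highly_public = sum(hp & prof == n_timepoints),
      once_highly_public = sum(hp & prof == 1))
  }))
  if (sum(counts$n_highly_public) == 0) {
    return(list(counts = counts, undefined = TRUE,
                t_statistic = NA_real_, t_p = NA_real_, permutation = NULL))
  }
  tt <- if (length(profiles) >= 2) {
    x <- counts$once_highly_public
    y <- counts$persistent_highly_public
    if (stats::sd(c(x, y)) == 0) {
      # both groups constant and equal: no difference, trivially t = 0
      list(statistic = c(t = 0), p.value = 1)
    } else if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      # internally constant but unequal groups: zero pooled variance makes
      # the statistic unbounded; report the t-test as inapplicable (the
      # permutation test below still applies)
      list(statistic = c(t = NA_real_), p.value = NA_real_)
    } else {
      stats::t.test(x, y, var.equal = TRUE)
    }
  } else NULL
  perm <- data.table::rbindlist(lapply(seq_along(profiles), function(i) {
    prof <- profiles[[i]]
    hp <- share_fraction(sharing, names(prof)) > high_threshold
    obs <- sum(hp & prof == n_timepoints)
    with_seed(derive_seed(seed, "public-perm", ids[i]), {
      gt <- 0L; eq <- 0L
      n_vals <- as.integer(prof)
      for (b in seq_len(n_perm)) {
        cnt <- sum(hp & sample(n_vals) == n_timepoints)
        if (cnt > obs) gt <- gt + 1L else if (cnt == obs) eq <- eq + 1L
      }
      dt <- data.table::data.table(individual_id = ids[i], observed = obs,
                                   p = (1 + gt + eq) / (1 + n_perm))
      if (smoothed)
        dt[, p_smoothed := (gt + stats::runif(1) * (1 + eq)) / (1 + n_perm)]
      dt
    })
  }))
  list(counts = counts, undefined = FALSE,
       t_statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
       t_p = if (is.null(tt)) NA_real_ else tt$p.value,
       permutation = perm)
}

#' Most-public receptors and their persistence across individuals
#'
#' Lists receptors shared by strictly more than `top_fraction_threshold` of
#' the reference cohort and, for each individual, whether the receptor is
#' persistent (observed at all T time points) there. Sorted by descending
#' share count, ties broken lexicographically by key.
#'
#' @param sharing a [sharing_table()].
#' @param profiles named list of per-individual [occurrence_profile()]s.
#' @param n_timepoints total PBMC time points T.
#' @param top_fraction_threshold share-fraction cutoff (strict).
#' @return data.table with `tcr`, `share_count`, `share_fraction` and one
#'   `persistent_<individual>` logical column per profile.
#' @export
most_public_report <- function(sharing, profiles, n_timepoints,
                               top_fraction_threshold = 0.90) {
  f <- sharing$counts / sharing$cohort_size
  keep <- f > top_fraction_threshold
  out <- data.table::data.table(tcr = sharing$keys[keep],
                                share_count = sharing$counts[keep],
                                share_fraction = f[keep])
  ids <- names(profiles) %||% paste0("ind", seq_along(profiles))
  for (i in seq_along(profiles)) {
    prof <- profiles[[i]]
    col <- paste0("persistent_", ids[i])
    occ <- prof[out$tcr]
    out[, (col) := !is.na(occ) & occ == n_timepoints]
  }
  data.table::setorder(out, -share_count, tcr)
  out[]
}
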