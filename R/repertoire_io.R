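#' @import data.table
NULL

# Column aliases accepted for the template/read count in immunoSEQ-style
# exports; matched case-sensitively, first hit wins.
COUNT_ALIASES <- c("count (templates/reads)", "count", "templates")

UNRESOLVED_GENE <- c("", "unresolved", "NA")

#' Construct a repertoire sample from clone-level records
#'
#' One sequencing library: the clone records of one individual at one time
#' point in one cell compartment (PBMC, memory or naive). Duplicate clones —
#' identical (V gene, J gene, CDR3 nucleotide, CDR3 amino acid) — are
#' collapsed by summing counts. Relative frequencies are recomputed from
#' counts over ALL records, productive and nonproductive alike: nonproductive
#' rearrangements are part of the sequenced pool and stay in the denominator.
#'
#' A record is productive when its CDR3 amino-acid sequence is non-empty and
#' free of stop symbols (`*`) and both V and J genes are resolved.
#'
#' @param records data.frame with columns `amino_acid`, `v_gene`, `j_gene`,
#'   `count`, and optionally `cdr3_nt`.
#' @param individual_id subject label.
#' @param time_point ordinal time-point label (months since first draw).
#' @param compartment one of "PBMC", "memory", "naive".
#' @return an object of class `tcr_sample`.
#' @export
tcr_sample <- function(records, individual_id, time_point,
                       compartment = c("PBMC", "memory", "naive")) {
  compartment <- match.arg(compartment)
  rec <- data.table::as.data.table(records)
  if (!"cdr3_nt" %in% names(rec)) rec[, cdr3_nt := NA_character_]
  rec[, amino_acid := ifelse(is.na(amino_acid), "", amino_acid)]
  # Records without nucleotide information collapse at amino-acid resolution
  # (one lineage per receptor); a deterministic placeholder keeps the
  # (tcr, cdr3_nt) key unique and the writer round-trip stable.
  rec[, cdr3_nt := ifelse(is.na(cdr3_nt) | cdr3_nt == "",
                          paste0("<nt:", amino_acid, ">"), cdr3_nt)]
  bad <- which(is.na(rec$count) | rec$count < 0 | rec$count != round(rec$count))
  if (length(bad) > 0) {
    stop("negative or non-integer count at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  rec <- rec[, .(count = sum(count)),
             by = .(amino_acid, v_gene, j_gene, cdr3_nt)]
  total <- sum(rec$count)
  rec[, frequency := if (total > 0) count / total else 0]
  rec[, productive := amino_acid != "" &
        !grepl("*", amino_acid, fixed = TRUE) &
        !(is.na(v_gene) | v_gene %in% UNRESOLVED_GENE) &
        !(is.na(j_gene) | j_gene %in% UNRESOLVED_GENE)]
  data.table::setorder(rec, v_gene, amino_acid, j_gene, cdr3_nt)
  s <- structure(
    list(individual_id = as.character(individual_id),
         time_point = time_point,
         compartment = compartment,
         records = rec[]),
    class = "tcr_sample")
  validate_tcr_sample(s)
  s
}

validate_tcr_sample <- function(s, tol = 1e-6) {
  f <- sum(s$records$frequency)
  if (nrow(s$records) > 0 && abs(f - 1) > tol) {
    stop("sample frequencies sum to ", format(f), ", not 1 +/- ", tol)
  }
  invisible(s)
}

#' @export
print.tcr_sample <- function(x, ...) {
  cat(sprintf("<tcr_sample> %s / t=%s / %s: %d records (%d productive), %s templates\n",
              x$individual_id, as.character(x$time_point), x$compartment,
              nrow(x$records), sum(x$records$productive),
              format(sum(x$records$count), big.mark = ",")))
  invisible(x)
}

#' Read an immunoSEQ-style repertoire TSV
#'
#' Reads a tab-delimited clonotype export (plain or gzip-compressed) with
#' columns `aminoAcid`, `vGeneName`, `jGeneName`, an optional `nucleotide`
#' column and a template-count column (any of
#' `"count (templates/reads)"`, `"count"`, `"templates"`). Rows whose CDR3
#' contains a stop symbol or whose V/J gene is unresolved are retained and
#' flagged nonproductive. A `frequencyCount (%)` column, when present, is
#' ignored and frequencies are recomputed from counts; a discrepancy larger
#' than 0.1 percentage points triggers a warning.
#'
#' @param path file path (`.tsv` or `.tsv.gz`).
#' @param individual_id,time_point,compartment sample annotations, see
#'   [tcr_sample()].
#' @param count_aliases accepted count column names, first match wins.
#' @return a [tcr_sample()].
#' @export
read_repertoire_tsv <- function(path, individual_id, time_point,
                                compartment = "PBMC",
                                count_aliases = COUNT_ALIASES) {
  if (!file.exists(path)) stop("no such file: ", path)
  # fread needs an extra package for gz paths; route those through a
  # connection instead so compressed exports read everywhere
  raw <- if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con), add = TRUE)
    data.table::fread(text = paste(readLines(con), collapse = "\n"),
                      sep = "\t", header = TRUE,
                      colClasses = list(character = "aminoAcid"),
                      na.strings = c("NA", ""))
  } else {
    data.table::fread(path, sep = "\t", header = TRUE,
                      colClasses = list(character = "aminoAcid"),
                      na.strings = c("NA", ""))
  }
  for (col in c("aminoAcid", "vGeneName", "jGeneName")) {
    if (!col %in% names(raw)) {
      stop("missing mandatory column: '", col, "' in ", path)
    }
  }
  count_col <- intersect(count_aliases, names(raw))
  if (length(count_col) == 0) {
    stop("missing mandatory column: a count column (one of ",
         paste(sQuote(count_aliases), collapse = ", "), ") in ", path)
  }
  count_col <- count_col[1]
  rec <- data.table::data.table(
    amino_acid = as.character(raw$aminoAcid),
    v_gene = as.character(raw$vGeneName),
    j_gene = as.character(raw$jGeneName),
    cdr3_nt = if ("nucleotide" %in% names(raw)) as.character(raw$nucleotide)
              else NA_character_,
    count = raw[[count_col]])
  s <- tcr_sample(rec, individual_id, time_point, compartment)
  if ("frequencyCount (%)" %in% names(raw)) {
    chk <- data.table::data.table(
      amino_acid = ifelse(is.na(raw$aminoAcid), "", raw$aminoAcid),
      v_gene = as.character(raw$vGeneName), j_gene = as.character(raw$jGeneName),
      pct = raw[["frequencyCount (%)"]], count = raw[[count_col]])
    chk <- chk[, .(pct = sum(pct), count = sum(count)),
               by = .(amino_acid, v_gene, j_gene)]
    chk[, recomputed := 100 * count / sum(count)]
    off <- chk[abs(pct - recomputed) > 0.1]
    if (nrow(off) > 0) {
      warning(nrow(off), " row(s) in ", basename(path),
              " have 'frequencyCount (%)' off by > 0.1 percentage points",
              " from count-derived frequencies; counts are used")
    }
  }
  s
}

#' Write a repertoire sample as an immunoSEQ-style TSV
#'
#' Output is byte-stable for a given sample (records are kept in a canonical
#' sort order) and round-trips through [read_repertoire_tsv()] losslessly at
#' the record level.
#'
#' @param sample a [tcr_sample()].
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_repertoire_tsv <- function(sample, path) {
  rec <- sample$records
  out <- data.table::data.table(
    "aminoAcid" = rec$amino_acid,
    "vGeneName" = rec$v_gene,
    "jGeneName" = rec$j_gene,
    "nucleotide" = ifelse(startsWith(rec$cdr3_nt, "<nt:"), "", rec$cdr3_nt),
    "count (templates/reads)" = rec$count,
    "frequencyCount (%)" = 100 * rec$frequency)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE,
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Restrict a sample to its productive records
#'
#' Returns the productive records only, with frequencies UNCHANGED: the
#' denominator still includes nonproductive template counts, so productive
#' frequencies sum to the sample's productive fraction, not to 1.
#'
#' @param sample a [tcr_sample()].
#' @return a `tcr_sample` containing only productive records.
#' @export
productive_view <- function(sample) {
  out <- sample
  out$records <- sample$records[productive == TRUE]
  out$productive_only <- TRUE
  out
}

#' Collapse clone records to amino-acid-level receptors
#'
#' Aggregates the productive clone records of a sample to unique TCRbeta
#' identities (V gene, CDR3 amino acid, J gene). Several nucleotide
#' rearrangements can converge on one amino-acid receptor; their count is the
#' receptor's nucleotide redundancy, a signature of convergent recombination.
#'
#' @param sample a [tcr_sample()].
#' @return data.table with one row per TCRbeta: `tcr` (key), `v_gene`,
#'   `cdr3_aa`, `j_gene`, `abundance` (summed clone frequencies, denominator
#'   including nonproductive mass) and `nt_redundancy` (distinct CDR3
#'   nucleotide sequences).
#' @export
collapse_to_tcrs <- function(sample) {
  rec <- sample$records[productive == TRUE]
  out <- rec[, .(abundance = sum(frequency),
                 nt_redundancy = data.table::uniqueN(cdr3_nt)),
             by = .(v_gene, cdr3_aa = amino_acid, j_gene)]
  out[, tcr := tcr_key(v_gene, cdr3_aa, j_gene)]
  data.table::setcolorder(out, c("tcr", "v_gene", "cdr3_aa", "j_gene",
                                 "abundance", "nt_redundancy"))
  data.table::setorder(out, tcr)
  out[]
}

#' Abundance vector of a sample at receptor level
#'
#' @param sample a [tcr_sample()].
#' @return named numeric vector: TCR key -> relative abundance (fractions over
#'   the full template pool; they sum to the productive fraction).
#' @export
abundance_vector <- function(sample) {
  tab <- collapse_to_tcrs(sample)
  stats::setNames(tab$abundance, tab$tcr)
}

#' Assemble one individual's longitudinal series
#'
#' @param pbmc_samples list of PBMC [tcr_sample()]s; sorted by time point.
#' @param memory_samples,naive_samples optional lists of sorted-compartment
#'   samples.
#' @return an object of class `tcr_series`.
#' @export
tcr_series <- function(pbmc_samples, memory_samples = list(),
                       naive_samples = list()) {
  stopifnot(length(pbmc_samples) >= 1)
  ids <- unique(vapply(c(pbmc_samples, memory_samples, naive_samples),
                       function(s) s$individual_id, character(1)))
  if (length(ids) != 1) stop("all samples in a series must share individual_id")
  ord <- order(vapply(pbmc_samples, function(s) as.numeric(s$time_point),
                      numeric(1)))
  structure(list(individual_id = ids,
                 pbmc_samples = pbmc_samples[ord],
                 memory_samples = memory_samples,
                 naive_samples = naive_samples),
            class = "tcr_series")
}

#' @export
print.tcr_series <- function(x, ...) {
  cat(sprintf("<tcr_series> individual %s: %d PBMC, %d memory, %d naive samples\n",
              x$individual_id, length(x$pbmc_samples),
              length(x$memory_samples), length(x$naive_samples)))
  invisible(x)
}
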