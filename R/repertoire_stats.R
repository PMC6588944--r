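#' Jaccard index of two receptor sets
#'
#' Intersection over union of unique TCRbeta identities; the repertoire
#' overlap measure used throughout. Defined as 0 when both sets are empty.
#'
#' @param a,b character vectors of TCR keys (or anything set-like).
#' @return numeric in \[0, 1\].
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Pairwise Jaccard matrix over samples
#'
#' Computed over the productive TCRbeta identity sets of each sample
#' (abundance ignored). The qualitative signature of repertoire
#' individuality is a higher mean within-individual than between-individual
#' Jaccard.
#'
#' @param samples list of [tcr_sample()]s.
#' @return symmetric numeric matrix with unit diagonal; dimnames are
#'   "individual/t<time>/<compartment>" labels.
#' @export
jaccard_matrix <- function(samples) {
  stopifnot(length(samples) >= 2)
  sets <- lapply(samples, function(s) collapse_to_tcrs(s)$tcr)
  labels <- vapply(samples, function(s)
    sprintf("%s/t%s/%s", s$individual_id, as.character(s$time_point),
            s$compartment), character(1))
  n <- length(sets)
  m <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- jaccard_index(sets[[i]], sets[[j]])
    }
  }
  dimnames(m) <- list(labels, labels)
  m
}

#' Shannon diversity estimate
#'
#' The effective number of receptors, exp(H) with H the Shannon entropy
#' (natural log) of the abundance vector renormalized to sum 1 within the
#' productive set. A perfectly even repertoire of S receptors scores S; a
#' monoclonal one scores 1.
#'
#' @param v named numeric abundance vector (positive entries).
#' @return numeric >= 1.
#' @export
shannon_diversity <- function(v) {
  if (length(v) == 0) stop("shannon_diversity: empty abundance vector")
  p <- v / sum(v)
  exp(-sum(p * log(p)))
}

#' Repertoire clonality (1 - Pielou's evenness)
#'
#' 1 - H / ln(S) on the renormalized abundances: 0 for a perfectly even
#' repertoire, approaching 1 under extreme clonal dominance. For S = 1 the
#' evenness limit is taken as 1, giving clonality 0.
#'
#' @param v named numeric abundance vector (positive entries).
#' @return numeric in \[0, 1\].
#' @export
clonality <- function(v) {
  if (length(v) == 0) stop("clonality: empty abundance vector")
  s <- length(v)
  if (s == 1) return(0)
  p <- v / sum(v)
  h <- -sum(p * log(p))
  1 - h / log(s)
}

#' High-abundance receptor subset
#'
#' The ceiling(fraction * S) receptors of highest abundance in a sample
#' ("top 1%" at the default). Ties at the cutoff are broken by
#' lexicographic TCR key so the subset is deterministic.
#'
#' @param sample a [tcr_sample()].
#' @param fraction fraction of unique receptors to keep, in (0, 1\].
#' @return character vector of TCR keys.
#' @export
top_fraction <- function(sample, fraction = 0.01) {
  stopifnot(fraction > 0, fraction <= 1)
  tab <- collapse_to_tcrs(sample)
  s <- nrow(tab)
  if (s == 0) return(character(0))
  k <- ceiling(fraction * s)
  ord <- order(-tab$abundance, tab$tcr)
  tab$tcr[ord[seq_len(k)]]
}

#' Correlation of receptor abundances between two samples
#'
#' Computed over the intersection of receptor keys only (receptors shared by
#' the two samples); the number shared is reported alongside the
#' coefficient and the large-sample test p-value.
#'
#' @param a,b named abundance vectors.
#' @param method "spearman" or "pearson".
#' @return list with `n_shared`, `coefficient`, `p`.
#' @export
shared_abundance_correlation <- function(a, b,
                                         method = c("spearman", "pearson")) {
  method <- match.arg(method)
  shared <- intersect(names(a), names(b))
  if (length(shared) < 3)
    stop("shared_abundance_correlation: fewer than 3 shared receptors (",
         length(shared), ") - correlation undefined")
  ct <- suppressWarnings(
    stats::cor.test(a[shared], b[shared], method = method, exact = FALSE))
  list(n_shared = length(shared),
       coefficient = unname(ct$estimate),
       p = ct$p.value)
}

#' V and J gene usage of a sample
#'
#' For each V gene and each J gene separately: the fraction of unique
#' productive receptors using it and the fraction of total productive
#' abundance carried by it. Both fractions sum to 1 per segment type.
#'
#' @param sample a [tcr_sample()].
#' @return data.table with columns `segment` ("V"/"J"), `gene`,
#'   `unique_fraction`, `abundance_fraction`.
#' @export
vj_usage <- function(sample) {
  tab <- collapse_to_tcrs(sample)
  one <- function(genes, seg) {
    dt <- data.table::data.table(gene = genes, abundance = tab$abundance)
    out <- dt[, .(unique_fraction = .N / nrow(dt),
                  abundance_fraction = sum(abundance) / sum(dt$abundance)),
              by = gene]
    out[, segment := seg]
    out
  }
  res <- rbind(one(tab$v_gene, "V"), one(tab$j_gene, "J"))
  data.table::setcolorder(res, c("segment", "gene", "unique_fraction",
                                 "abundance_fraction"))
  data.table::setorder(res, segment, gene)
  res[]
}

#' CDR3 amino-acid length distribution
#'
#' @param tcrs character vector of TCR keys.
#' @param weights optional named abundance vector; when given, abundance
#'   mass (renormalized) is accumulated per length instead of counts.
#' @return data.table with columns `length` and `value` (count or mass).
#' @export
cdr3_length_distribution <- function(tcrs, weights = NULL) {
  tcrs <- unique(tcrs)
  if (length(tcrs) == 0)
    return(data.table::data.table(length = integer(0), value = numeric(0)))
  len <- nchar(tcr_cdr3(tcrs))
  w <- if (is.null(weights)) rep(1, length(tcrs))
       else unname(weights[tcrs] / sum(weights[tcrs]))
  dt <- data.table::data.table(length = len, value = w)
  out <- dt[, .(value = sum(value)), by = length]
  data.table::setorder(out, length)
  out[]
}

# Multivariate hypergeometric draw: k templates without replacement from
# category counts n (sequential conditional rhyper).
rmvhyper <- function(n, k) {
  out <- integer(length(n))
  rem <- sum(n)
  for (i in seq_along(n)) {
    if (k <= 0) break
    out[i] <- stats::rhyper(1, n[i], rem - n[i], k)
    k <- k - out[i]
    rem <- rem - n[i]
  }
  out
}

#' Rarefaction curve of unique receptors vs sequencing depth
#'
#' Subsamples templates without replacement (hypergeometric) and counts the
#' unique productive receptors recovered, averaged over replicates. At full
#' depth this equals the observed richness exactly. A saturated library
#' shows a flat curve near full depth.
#'
#' @param sample a [tcr_sample()].
#' @param depths template counts to rarefy to (each <= total templates).
#' @param n_reps subsample replicates per depth.
#' @param seed integer seed.
#' @return data.table with columns `depth`, `mean_unique_tcrs`.
#' @export
rarefaction_curve <- function(sample, depths, n_reps = 10, seed = 1) {
  total <- sum(sample$records$count)
  if (any(depths > total))
    stop("rarefaction_curve: depth exceeds total template count (", total, ")")
  rec <- sample$records
  # template -> receptor map at amino-acid level; nonproductive templates
  # occupy depth but never add a receptor
  tab <- rec[, .(count = sum(count), productive = productive[1]),
             by = .(v_gene, amino_acid, j_gene)]
  counts <- tab$count
  prod <- tab$productive
  with_seed(seed, {
    res <- vapply(depths, function(d) {
      mean(vapply(seq_len(n_reps), function(r) {
        drawn <- rmvhyper(counts, d)
        sum(drawn > 0 & prod)
      }, numeric(1)))
    }, numeric(1))
    data.table::data.table(depth = depths, mean_unique_tcrs = res)
  })
}

#' Per-sample summary statistics table
#'
#' One row per sample: template depth, productive fraction, unique
#' receptors, unique V and J genes, Shannon diversity and clonality.
#'
#' @param samples list of [tcr_sample()]s.
#' @return data.table.
#' @export
summary_stats <- function(samples) {
  data.table::rbindlist(lapply(samples, function(s) {
    tab <- collapse_to_tcrs(s)
    v <- stats::setNames(tab$abundance, tab$tcr)
    data.table::data.table(
      individual_id = s$individual_id,
      time_point = as.numeric(s$time_point),
      compartment = s$compartment,
      total_templates = sum(s$records$count),
      productive_fraction = sum(s$records$frequency[s$records$productive]),
      unique_tcrs = nrow(tab),
      unique_clones = sum(tab$nt_redundancy),
      unique_v_genes = data.table::uniqueN(tab$v_gene),
      unique_j_genes = data.table::uniqueN(tab$j_gene),
      shannon_diversity = if (nrow(tab) > 0) shannon_diversity(v) else NA_real_,
      clonality = if (nrow(tab) > 0) clonality(v) else NA_real_)
  }))
}
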