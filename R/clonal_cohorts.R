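#' Select expanded (recurrently high-abundance) receptors
#'
#' Receptors that rank in the top `fraction` by abundance in at least
#' `min_times` distinct PBMC samples of a series — likely expanded T cell
#' clones, and the candidate universe for trajectory-correlation analysis.
#'
#' @param series a [tcr_series()].
#' @param fraction per-sample high-abundance fraction (default top 1%).
#' @param min_times minimum number of samples in which a receptor must rank
#'   in the top fraction.
#' @return character vector of TCR keys.
#' @export
select_expanded <- function(series, fraction = 0.01, min_times = 2) {
  stopifnot(length(series$pbmc_samples) >= min_times)
  tops <- unlist(lapply(series$pbmc_samples, top_fraction,
                        fraction = fraction))
  tab <- table(tops)
  sort(names(tab)[tab >= min_times])
}

#' Trajectory matrix with median imputation
#'
#' Rows are candidate receptors, columns PBMC time points, entries relative
#' abundances. A receptor absent from a sample is imputed with that
#' sample's median receptor abundance — in a repertoire this deep, an
#' undetected receptor is about as abundant as a typical detected one, so
#' the median is a better fill than a pseudocount. The median is taken over
#' all productive receptors of the sample, and the imputation mask is kept.
#'
#' @param series a [tcr_series()].
#' @param candidates character vector of TCR keys, each observed at least
#'   once in the series.
#' @return object of class `trajectory_matrix`: `abundance` (matrix),
#'   `imputed` (logical mask), `medians` (per-sample medians),
#'   `time_points`.
#' @export
trajectory_matrix <- function(series, candidates) {
  Tn <- length(series$pbmc_samples)
  tabs <- lapply(series$pbmc_samples, collapse_to_tcrs)
  m <- matrix(NA_real_, nrow = length(candidates), ncol = Tn,
              dimnames = list(candidates, vapply(
                series$pbmc_samples,
                function(s) as.character(s$time_point), character(1))))
  medians <- numeric(Tn)
  for (t in seq_len(Tn)) {
    tab <- tabs[[t]]
    medians[t] <- stats::median(tab$abundance)
    hit <- match(candidates, tab$tcr)
    m[, t] <- tab$abundance[hit]
  }
  never <- rowSums(!is.na(m)) == 0
  if (any(never)) {
    stop("candidate(s) never observed in the series: ",
         paste(utils::head(candidates[never], 5), collapse = ", "))
  }
  imputed <- is.na(m)
  for (t in seq_len(Tn)) m[imputed[, t], t] <- medians[t]
  structure(list(abundance = m, imputed = imputed, medians = medians,
                 time_points = colnames(m)),
            class = "trajectory_matrix")
}

#' Correlation graph over receptor trajectories
#'
#' Receptors are nodes; an edge joins two receptors whose abundance
#' trajectories (across the T time points, imputed entries included)
#' correlate strictly above the threshold. Zero-variance rows are excluded
#' with a warning.
#'
#' @param m a [trajectory_matrix()].
#' @param method "spearman" or "pearson".
#' @param threshold correlation threshold (strict `>`; set
#'   `inclusive = TRUE` for `>=`).
#' @param inclusive use `>=` instead of `>`.
#' @return object of class `correlation_graph`: `nodes` (character),
#'   `adjacency` (logical matrix), `method`, `threshold`.
#' @export
correlation_graph <- function(m, method = c("spearman", "pearson"),
                              threshold = 0.95, inclusive = FALSE) {
  method <- match.arg(method)
  x <- m$abundance
  if (ncol(x) < 3) stop("correlation_graph: need at least 3 time points")
  v <- apply(x, 1, stats::sd)
  if (any(v == 0)) {
    warning("excluding ", sum(v == 0), " zero-variance trajectory row(s)")
    x <- x[v > 0, , drop = FALSE]
  }
  cm <- suppressWarnings(stats::cor(t(x), method = method))
  adj <- if (inclusive) cm >= threshold else cm > threshold
  diag(adj) <- FALSE
  adj[is.na(adj)] <- FALSE
  structure(list(nodes = rownames(x), adjacency = adj, method = method,
                 threshold = threshold),
            class = "correlation_graph")
}

#' Maximum clique of a correlation graph
#'
#' Exact maximum-cardinality clique (every member pairwise connected). Ties
#' among maximum cliques are broken deterministically by the
#' lexicographically smallest sorted member set; an edgeless graph yields
#' the single lexicographically smallest node; an empty graph the empty
#' set.
#'
#' @param g a [correlation_graph()] (or any list with `nodes` and a logical
#'   `adjacency` matrix).
#' @return character vector of member TCR keys (sorted).
#' @export
max_clique <- function(g) {
  nodes <- g$nodes
  if (length(nodes) == 0) return(character(0))
  if (length(nodes) == 1 || !any(g$adjacency)) return(sort(nodes)[1])
  ig <- igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected")
  cliques <- igraph::largest_cliques(ig)
  sets <- lapply(cliques, function(cl) sort(nodes[as.integer(cl)]))
  keys <- vapply(sets, paste, character(1), collapse = "\r")
  sets[[which.min(rank(keys, ties.method = "first"))]]
}

#' Full cohort detection on a series
#'
#' Candidate selection (top-fraction at least `min_times`), median-imputed
#' trajectory matrix, correlation graph, maximum clique — for one
#' correlation method.
#'
#' @inheritParams select_expanded
#' @inheritParams correlation_graph
#' @return list with `candidates`, `matrix`, `graph`, `members` (the
#'   maximum clique), `method`, `threshold`.
#' @export
detect_cohort <- function(series, fraction = 0.01, min_times = 2,
                          method = "spearman", threshold = 0.95,
                          inclusive = FALSE) {
  candidates <- select_expanded(series, fraction, min_times)
  if (length(candidates) < 2) {
    return(list(candidates = candidates, matrix = NULL, graph = NULL,
                members = candidates, method = method, threshold = threshold))
  }
  m <- trajectory_matrix(series, candidates)
  g <- suppressWarnings(correlation_graph(m, method, threshold, inclusive))
  list(candidates = candidates, matrix = m, graph = g,
       members = max_clique(g), method = method, threshold = threshold)
}

# One shuffled re-analysis: permute each candidate's values (and missing
# slots) independently across sample labels, re-impute with the per-sample
# medians, rebuild the correlation graph, return the max clique size.
shuffled_clique_size <- function(obs, imputed, medians, method, threshold,
                                 inclusive = FALSE) {
  Tn <- ncol(obs)
  x <- obs
  x[imputed] <- NA_real_
  for (r in seq_len(nrow(x))) x[r, ] <- x[r, sample.int(Tn)]
  for (t in seq_len(Tn)) x[is.na(x[, t]), t] <- medians[t]
  v <- apply(x, 1, stats::sd)
  x <- x[v > 0, , drop = FALSE]
  if (nrow(x) < 2) return(min(1L, nrow(obs)))
  cm <- suppressWarnings(stats::cor(t(x), method = method))
  adj <- if (inclusive) cm >= threshold else cm > threshold
  diag(adj) <- FALSE
  adj[is.na(adj)] <- FALSE
  if (!any(adj)) return(1L)
  ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::clique_num(ig)
}

#' Permutation significance of the observed cohort size
#'
#' Each shuffled dataset independently permutes every candidate receptor's
#' abundance values across the sample labels of its individual (destroying
#' cross-receptor correlation while preserving each trajectory's value
#' multiset), re-runs imputation, correlation-graph construction and
#' maximum-clique search, and records the clique size. The p-value is
#' (1 + #\{permuted size >= observed\}) / (1 + n_perm).
#'
#' @param series a [tcr_series()].
#' @param observed_clique_size clique size whose significance is tested.
#' @param n_perm number of shuffled datasets (study analyses use 1000).
#' @param seed integer seed.
#' @param smoothed also return the randomized Monte Carlo p-value
#'   `p_smoothed = (G + U (1 + E)) / (1 + n_perm)` with G the count of null
#'   sizes strictly above the observed one, E the count of ties and U
#'   uniform on (0, 1) — exactly uniform under the null despite the integer
#'   statistic, hence the right quantity for calibration audits; report `p`
#'   for inference.
#' @inheritParams detect_cohort
#' @return list with `p`, `observed`, `null_sizes` (and `p_smoothed` when
#'   requested).
#' @export
cohort_significance <- function(series, observed_clique_size, n_perm = 1000,
                                seed = 1, fraction = 0.01, min_times = 2,
                                method = "spearman", threshold = 0.95,
                                inclusive = FALSE, smoothed = FALSE) {
  stopifnot(n_perm >= 1)
  candidates <- select_expanded(series, fraction, min_times)
  if (length(candidates) < 2) {
    return(list(p = 1, observed = observed_clique_size,
                null_sizes = rep(1L, n_perm)))
  }
  m <- trajectory_matrix(series, candidates)
  with_seed(seed, {
    sizes <- vapply(seq_len(n_perm), function(b) {
      as.integer(shuffled_clique_size(m$abundance, m$imputed, m$medians,
                                      method, threshold, inclusive))
    }, integer(1))
    out <- list(p = (1 + sum(sizes >= observed_clique_size)) / (1 + n_perm),
                observed = observed_clique_size, null_sizes = sizes)
    if (smoothed) {
      gt <- sum(sizes > observed_clique_size)
      eq <- sum(sizes == observed_clique_size)
      out$p_smoothed <- (gt + stats::runif(1) * (1 + eq)) / (1 + n_perm)
    }
    out
  })
}

#' Flag cohort members suspicious of sequencing error
#'
#' A high-abundance receptor closely correlated with low-abundance,
#' sequence-similar receptors is the signature of residual sequencing
#' error. A member is flagged when its mean abundance is below
#' `abundance_ratio` of the cohort's most abundant member AND its CDR3 is
#' within `d_max` Levenshtein edits of that member's CDR3.
#'
#' @param members character vector of cohort member TCR keys.
#' @param abundances named numeric vector (or matrix rows) of member mean
#'   abundances; names must cover `members`.
#' @param abundance_ratio flag threshold relative to the dominant member.
#' @param d_max CDR3 edit-distance threshold for "similar sequence".
#' @return data.table with columns `tcr`, `mean_abundance`, `flagged`.
#' @export
flag_artifact_suspects <- function(members, abundances,
                                   abundance_ratio = 0.1, d_max = 2) {
  ab <- abundances[members]
  dominant <- members[which.max(ab)]
  dom_cdr3 <- tcr_cdr3(dominant)
  flagged <- rep(FALSE, length(members))
  low <- ab < abundance_ratio * max(ab)
  if (any(low)) {
    d <- levenshtein(tcr_cdr3(members[low]), dom_cdr3)
    flagged[low] <- d <= d_max
  }
  flagged[members == dominant] <- FALSE
  data.table::data.table(tcr = members, mean_abundance = unname(ab),
                         flagged = flagged)
}
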