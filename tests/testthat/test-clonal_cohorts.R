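# Constructed series with exact counts (no sampling noise): n_bg background
# receptors with independent lognormal trajectories plus an optional planted
# member group following one latent trajectory with member-specific noise of
# controlled amplitude.
make_cohort_series <- function(seed, n_members = 10, n_bg = 3000,
                               noise_over_latent_sd = 0.1) {
  set.seed(seed)
  tps <- c(0, 1, 2, 3, 5, 6, 7, 12)
  Tn <- length(tps)
  lat <- cumsum(rnorm(Tn, 0, 1)); lat <- lat - mean(lat)
  noise_sd <- sd(lat) * noise_over_latent_sd
  n <- n_bg + n_members
  aas <- random_strings(n, lens = 10:16)
  while (anyDuplicated(aas) > 0) {
    aas[duplicated(aas)] <- random_strings(sum(duplicated(aas)), lens = 10:16)
  }
  vs <- sprintf("TCRBV%02d-01", sample(1:30, n, replace = TRUE))
  js <- sprintf("TCRBJ01-0%d", sample(1:6, n, replace = TRUE))
  bg_base <- exp(rnorm(n_bg, 0, 2))
  # standardize each member's noise to exactly the target amplitude
  noise <- vapply(seq_len(n_members), function(m) {
    e <- rnorm(Tn); e <- e - mean(e)
    e * noise_sd / sd(e)
  }, numeric(Tn))
  member_scale <- as.numeric(quantile(bg_base, 0.999))
  samples <- lapply(seq_len(Tn), function(t) {
    bg_val <- bg_base * exp(rnorm(n_bg, 0, 0.5))
    mem_val <- exp(lat[t] + noise[t, ]) * member_scale
    cnt <- pmax(1L, as.integer(round(c(bg_val, mem_val) * 50)))
    tcr_sample(data.frame(amino_acid = aas, v_gene = vs, j_gene = js,
                          count = cnt, stringsAsFactors = FALSE),
               "X", tps[t], "PBMC")
  })
  members <- if (n_members > 0)
    tcr_key(vs[n_bg + seq_len(n_members)], aas[n_bg + seq_len(n_members)],
            js[n_bg + seq_len(n_members)]) else character(0)
  list(series = tcr_series(samples), members = members)
}

test_that("select_expanded counts top-fraction membership across samples", {
  ser <- make_fixture_series()
  # 2-3 receptors per sample: ceiling(0.5 * S) keeps the top 1-2
  cand <- select_expanded(ser, fraction = 0.5, min_times = 2)
  expect_true(fixture_keys()[["A"]] %in% cand)   # top in all three samples
  expect_false(fixture_keys()[["C"]] %in% cand)  # present once, never top
})

test_that("trajectory_matrix imputes with per-sample medians and keeps the mask", {
  ser <- make_fixture_series()
  k <- fixture_keys()
  m <- trajectory_matrix(ser, unname(k[c("A", "B")]))
  expect_equal(dim(m$abundance), c(2L, 3L))
  # sample medians over ALL productive receptor abundances
  expect_equal(m$medians, c(median(c(0.8, 0.2)), median(c(0.6, 0.3, 0.1)),
                            1.0), tolerance = 1e-12)
  # B is absent from the third sample -> imputed with that sample's median
  expect_true(m$imputed[k[["B"]], 3])
  expect_equal(m$abundance[k[["B"]], ], c(0.2, 0.3, 1.0), ignore_attr = TRUE)
  expect_false(any(m$imputed[k[["A"]], ]))
  expect_error(trajectory_matrix(ser, c(k[["A"]], "V|CNOPEF|J")),
               "never observed")
})

test_that("correlation_graph applies a strict threshold and drops flat rows", {
  m <- list(abundance = rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8),
                              c = c(4, 3, 2, 1), d = c(5, 5, 5, 5)),
            imputed = matrix(FALSE, 4, 4), medians = rep(0, 4),
            time_points = as.character(1:4))
  class(m) <- "trajectory_matrix"
  expect_warning(g <- correlation_graph(m, "pearson", threshold = 0.95),
                 "zero-variance")
  expect_setequal(g$nodes, c("a", "b", "c"))
  expect_true(g$adjacency["a", "b"])    # exactly collinear: r = 1 > 0.95
  expect_false(g$adjacency["a", "c"])   # r = -1
  # strict vs inclusive boundary at the threshold value
  g2 <- suppressWarnings(correlation_graph(m, "pearson", threshold = 1))
  expect_false(any(g2$adjacency))
  g3 <- suppressWarnings(correlation_graph(m, "pearson", threshold = 1,
                                           inclusive = TRUE))
  expect_true(g3$adjacency["a", "b"])
  expect_error(correlation_graph(list(abundance = m$abundance[, 1:2])),
               "3 time points")
})

test_that("max_clique matches exhaustive enumeration on random graphs", {
  set.seed(3)
  for (rep in 1:25) {
    n <- sample(2:12, 1)
    adj <- matrix(runif(n * n) < 0.4, n, n)
    adj <- adj | t(adj); diag(adj) <- FALSE
    g <- list(nodes = sprintf("n%02d", seq_len(n)), adjacency = adj)
    expect_equal(length(max_clique(g)), clique_brute(adj))
  }
})

test_that("max_clique breaks ties deterministically and handles edge cases", {
  expect_equal(max_clique(list(nodes = character(0),
                               adjacency = matrix(FALSE, 0, 0))),
               character(0))
  # edgeless: lexicographically smallest node
  adj <- matrix(FALSE, 3, 3)
  expect_equal(max_clique(list(nodes = c("c", "a", "b"), adjacency = adj)),
               "a")
  # two disjoint 2-cliques: {b, d} vs {a, c} -> lexicographically smaller set
  adj <- matrix(FALSE, 4, 4)
  nodes <- c("b", "d", "a", "c")
  adj[1, 2] <- adj[2, 1] <- TRUE  # b - d
  adj[3, 4] <- adj[4, 3] <- TRUE  # a - c
  expect_equal(max_clique(list(nodes = nodes, adjacency = adj)), c("a", "c"))
})

test_that("cohort detection recovers planted members when the common
           trajectory dominates clone noise 10:1 in amplitude", {
  # 20 seeds, T = 8; recovery counts membership in either correlation
  # method's reported clique (both methods are part of the detection output)
  recovered <- 0L; planted <- 0L
  for (seed in 1:20) {
    sm <- make_cohort_series(seed)
    ds <- detect_cohort(sm$series, method = "spearman")
    dp <- detect_cohort(sm$series, method = "pearson")
    hits <- sm$members %in% union(ds$members, dp$members)
    recovered <- recovered + sum(hits)
    planted <- planted + length(sm$members)
  }
  expect_gte(recovered / planted, 0.90)
})

test_that("cohort significance is small for planted and bounded below", {
  sm <- make_cohort_series(101)
  det <- detect_cohort(sm$series)
  expect_gte(length(det$members), 8)
  sig <- cohort_significance(sm$series, length(det$members), n_perm = 99,
                             seed = 1)
  expect_equal(sig$p, 1 / 100)          # add-one lower bound attained
  expect_gte(min(sig$null_sizes), 1)
  # a one-candidate series degrades gracefully
  ser1 <- make_fixture_series()
  sig1 <- cohort_significance(ser1, 1, n_perm = 9, fraction = 0.4,
                              min_times = 3)
  expect_equal(sig1$p, 1)
})

test_that("flag_artifact_suspects flags low-abundance sequence neighbors only", {
  members <- c(tcr_key("V1", "CASSLEETQYF", "J1"),   # dominant
               tcr_key("V2", "CASSLEETQYX", "J1"),   # 1 edit, low abundance
               tcr_key("V3", "CWWWWWWWWWF", "J1"),   # far, low abundance
               tcr_key("V4", "CASSLEETQYF", "J2"))   # same CDR3, high abundance
  ab <- stats::setNames(c(100, 5, 5, 60), members)
  fl <- flag_artifact_suspects(members, ab)
  expect_equal(fl$flagged, c(FALSE, TRUE, FALSE, FALSE))
})
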