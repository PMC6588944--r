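test_that("levenshtein reproduces worked distances", {
  expect_equal(levenshtein("CASSLEETQYF", "CASSLEETQYF"), 0L)
  expect_equal(levenshtein("CASSLEETQYF", "CASSPQETQYF"), 2L)  # two substitutions
  expect_equal(levenshtein("CASSLEETQYF", "CASSLETQYF"), 1L)   # one deletion
  expect_equal(levenshtein("", "CAF"), 3L)
  expect_equal(levenshtein(c("AB", "AB"), c("AB", "BA")), c(0L, 2L))
})

test_that("levenshtein agrees with an independent DP oracle", {
  set.seed(11)
  a <- random_strings(100)
  b <- random_strings(100)
  expect_equal(levenshtein(a, b),
               vapply(seq_along(a), function(i) as.integer(lev_dp(a[i], b[i])),
                      integer(1)))
})

graph_oracle_edges <- function(keys, d_max, same_vj = FALSE) {
  parts <- tcr_unkey(keys)
  n <- length(keys)
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- lev_dp(parts$cdr3_aa[i], parts$cdr3_aa[j])
      if (d > d_max) next
      if (same_vj && (parts$v_gene[i] != parts$v_gene[j] ||
                      parts$j_gene[i] != parts$j_gene[j])) next
      a <- min(keys[i], keys[j]); b <- max(keys[i], keys[j])
      out[[length(out) + 1]] <- data.frame(a = a, b = b, distance = d)
    }
  }
  if (length(out) == 0)
    return(data.frame(a = character(0), b = character(0),
                      distance = integer(0)))
  res <- do.call(rbind, out)
  res[order(res$a, res$b), ]
}

test_that("similarity graph equals the all-pairs oracle (incl. d_max 2)", {
  set.seed(42)
  for (rep in 1:5) {
    # biased pool: mutated variants of a few centers ensure edges exist
    centers <- random_strings(5, lens = 10:14)
    mut <- vapply(sample(centers, 20, replace = TRUE), function(s) {
      p <- sample(nchar(s), 1)
      substr(s, p, p) <- sample(LETTERS[1:20], 1)
      s
    }, character(1), USE.NAMES = FALSE)
    keys <- unique(tcr_key(sample(c("V1", "V2"), 25, TRUE),
                           c(centers, mut),
                           sample(c("J1", "J2"), 25, TRUE)))
    for (d_max in 1:2) {
      g <- build_similarity_graph(keys, d_max = d_max)
      ora <- graph_oracle_edges(keys, d_max)
      expect_equal(as.data.frame(g$edges), ora, ignore_attr = TRUE)
    }
    # same-V/J restriction agrees too
    g_vj <- build_similarity_graph(keys, d_max = 1, same_vj = TRUE)
    expect_equal(as.data.frame(g_vj$edges),
                 graph_oracle_edges(keys, 1, same_vj = TRUE),
                 ignore_attr = TRUE)
  }
})

test_that("identical CDR3 with different V/J is a distance-0 edge", {
  keys <- c(tcr_key("V1", "CASSLF", "J1"), tcr_key("V2", "CASSLF", "J1"),
            tcr_key("V1", "CASSMF", "J1"))
  g <- build_similarity_graph(keys, d_max = 0)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$distance, 0L)
  expect_setequal(c(g$edges$a, g$edges$b), keys[1:2])
})

test_that("degrees and decile bins follow the clamped formula", {
  # star: center within 1 edit of 4 leaves; leaves mutually at distance 2
  center <- "CASSAAAAAF"
  leaves <- vapply(1:4, function(i) {
    s <- center; substr(s, i + 1, i + 1) <- "W"; s
  }, character(1))
  keys <- tcr_key("V1", c(center, leaves), "J1")
  g <- build_similarity_graph(keys, d_max = 1)
  deg <- g$nodes$degree[match(keys, g$nodes$tcr)]
  expect_equal(deg, c(4L, 1L, 1L, 1L, 1L))
  bins <- neighbor_decile_bins(g)
  expect_equal(bins$bin[match(keys[1], bins$tcr)], 9L)          # max degree
  expect_equal(bins$bin[match(keys[2], bins$tcr)], 2L)          # floor(10/4)
  # edgeless graph: everything in bin 0
  g0 <- build_similarity_graph(tcr_key("V1", c("CAAAF", "CWWWWWWF"), "J1"), 1)
  expect_true(all(neighbor_decile_bins(g0)$bin == 0L))
})

test_that("persistence_by_connectivity validates input and normalizes bins", {
  ser <- make_fixture_series()
  prof <- occurrence_profile(ser)
  g <- build_similarity_graph(names(prof), d_max = 1)
  bins <- neighbor_decile_bins(g)
  pc <- persistence_by_connectivity(bins, prof)
  sums <- pc$histogram[, sum(fraction), by = bin]
  expect_equal(sums$V1, rep(1, nrow(sums)), tolerance = 1e-12)
  expect_equal(pc$trend, 0)  # degrees all zero -> degenerate trend is 0
  expect_error(persistence_by_connectivity(bins, prof[-1]),
               "missing from occurrence profile")
})

test_that("connectivity permutation p is bounded and detects planted coupling", {
  cfg <- sim_config(n_individuals = 1, pool_size = 3000, depth = 3e4,
                    seed = 91)
  sim <- simulate_cohort(cfg)
  prof <- occurrence_profile(sim$series[[1]])
  g <- build_similarity_graph(names(prof), d_max = 1)
  bins <- neighbor_decile_bins(g)
  pt <- connectivity_permutation_test(bins, prof, n_perm = 199, seed = 5)
  expect_gte(pt$p, 1 / 200)
  expect_lte(pt$p, 0.05)     # planted clusters of persistent receptors
  expect_gt(pt$observed, 0)
  # n_perm = 0 degrades to p = 1
  expect_equal(connectivity_permutation_test(bins, prof, n_perm = 0)$p, 1)
})
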