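test_that("shannon diversity and clonality reproduce closed forms", {
  # uniform repertoire: effective number = S, clonality = 0
  v <- rep(1 / 20, 20)
  expect_equal(shannon_diversity(v), 20, tolerance = 1e-10)
  expect_equal(clonality(v), 0, tolerance = 1e-10)
  # worked case (0.5, 0.25, 0.25): H = 1.5 ln 2, e^H = 2^1.5
  v <- c(0.5, 0.25, 0.25)
  expect_equal(shannon_diversity(v), 2^1.5, tolerance = 1e-10)
  expect_equal(clonality(v), 1 - 1.5 * log(2) / log(3), tolerance = 1e-10)
  # dominant clone: clonality near 1
  expect_equal(clonality(c(0.99, 0.01)),
               1 - (-0.99 * log(0.99) - 0.01 * log(0.01)) / log(2),
               tolerance = 1e-10)
  # single receptor: evenness limit -> clonality 0
  expect_equal(clonality(c(x = 1)), 0)
  # unnormalized input is renormalized
  expect_equal(shannon_diversity(c(2, 1, 1)), 2^1.5, tolerance = 1e-10)
})

test_that("jaccard index handles the standard and edge cases", {
  expect_equal(jaccard_index(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard_index(c("a"), c("a")), 1)
  expect_equal(jaccard_index(c("a"), c("b")), 0)
  expect_equal(jaccard_index(character(0), character(0)), 0)
  expect_equal(jaccard_index(c("a", "a", "b"), c("a", "b")), 1)  # set semantics
})

test_that("jaccard_matrix is symmetric with unit diagonal and labels", {
  s1 <- make_fixture_sample("P1", 0)
  s2 <- make_fixture_sample("P1", 1)
  ser <- make_fixture_series("P2")
  m <- jaccard_matrix(c(list(s1, s2), ser$pbmc_samples[1]))
  expect_equal(m, t(m))
  expect_equal(diag(m), rep(1, 3), ignore_attr = TRUE)
  expect_equal(m["P1/t0/PBMC", "P1/t1/PBMC"], 1)  # identical fixtures
  expect_equal(m["P1/t0/PBMC", "P2/t0/PBMC"], 0)  # disjoint receptor sets
})

test_that("top_fraction applies the ceiling rule with lexicographic ties", {
  aas <- sprintf("CASS%02dF", 1:10)
  s <- tcr_sample(data.frame(amino_acid = aas, v_gene = "TCRBV01-01",
                             j_gene = "TCRBJ01-01",
                             count = c(50, rep(10, 9))),
                  "P1", 0, "PBMC")
  # ceiling(0.01 * 10) = 1: the dominant receptor only
  expect_equal(top_fraction(s, 0.01),
               tcr_key("TCRBV01-01", "CASS01F", "TCRBJ01-01"))
  # ceiling(0.25 * 10) = 3: ties among the 10-count receptors broken by key
  top3 <- top_fraction(s, 0.25)
  expect_equal(top3, tcr_key("TCRBV01-01", c("CASS01F", "CASS02F", "CASS03F"),
                             "TCRBJ01-01"))
  expect_length(top_fraction(s, 1), 10)
})

test_that("shared_abundance_correlation uses shared keys only", {
  a <- c(x = 0.1, y = 0.2, z = 0.3, w = 0.4)
  b <- c(y = 0.1, z = 0.2, w = 0.3, q = 0.9)
  res <- shared_abundance_correlation(a, b, "spearman")
  expect_equal(res$n_shared, 3L)
  expect_equal(res$coefficient, 1)
  expect_error(shared_abundance_correlation(c(x = 1, y = 2), c(x = 1, y = 2)),
               "fewer than 3 shared")
})

test_that("vj_usage fractions sum to one per segment", {
  u <- vj_usage(make_fixture_sample())
  sums <- u[, .(uf = sum(unique_fraction), af = sum(abundance_fraction)),
            by = segment]
  expect_equal(sums$uf, c(1, 1), tolerance = 1e-12)
  expect_equal(sums$af, c(1, 1), tolerance = 1e-12)
})

test_that("cdr3_length_distribution counts and weights correctly", {
  keys <- tcr_key("V", c("CASSLF", "CASSMF", "CASSLONGF"), "J")
  d <- cdr3_length_distribution(keys)
  expect_equal(d[length == 6, value], 2)
  expect_equal(d[length == 9, value], 1)
  w <- stats::setNames(c(0.1, 0.1, 0.2), keys)
  dw <- cdr3_length_distribution(keys, w)
  expect_equal(dw[length == 6, value], 0.5, tolerance = 1e-12)
  expect_equal(sum(dw$value), 1, tolerance = 1e-12)
})

test_that("rarefaction is exact at full depth, 1 at depth 1, monotone", {
  s <- make_fixture_sample()
  total <- sum(s$records$count)
  rc <- rarefaction_curve(s, c(1, 20, 50, total), n_reps = 20, seed = 7)
  expect_equal(rc[depth == total, mean_unique_tcrs],
               nrow(collapse_to_tcrs(s)))
  expect_lte(rc[depth == 1, mean_unique_tcrs], 1)
  expect_true(all(diff(rc$mean_unique_tcrs) >= 0))
  expect_error(rarefaction_curve(s, total + 1), "exceeds total")
})

test_that("summary_stats reports the fixture's known values", {
  st <- summary_stats(list(make_fixture_sample()))
  expect_equal(st$total_templates, 100)
  expect_equal(st$productive_fraction, 0.9, tolerance = 1e-12)
  expect_equal(st$unique_tcrs, 3L)
  expect_equal(st$unique_clones, 4L)  # one receptor has two nt lineages
  v <- c(0.5, 0.3, 0.1) / 0.9
  expect_equal(st$shannon_diversity, exp(-sum(v * log(v))), tolerance = 1e-10)
})
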