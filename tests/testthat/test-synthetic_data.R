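test_that("sim_config validates its inputs", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(persistent_fraction = 1.5, seed = 1), "fractions")
  # infeasible: 0 < persistent_fraction * pool_size < 1
  expect_error(sim_config(pool_size = 50, persistent_fraction = 0.01,
                          seed = 1), "persistent_fraction")
  # persistent_fraction 0 is allowed and yields no persistent clone
  cfg0 <- sim_config(pool_size = 500, persistent_fraction = 0, depth = 1e3,
                     seed = 2)
  truth0 <- generate_truth(cfg0)
  expect_false("persistent" %in% truth_labels(truth0)$persistence_class)
})

test_that("generation is deterministic in the seed", {
  cfg <- sim_config(n_individuals = 1, pool_size = 500, depth = 2e3, seed = 9)
  t1 <- generate_truth(cfg)
  t2 <- generate_truth(cfg)
  expect_equal(truth_labels(t1), truth_labels(t2))
  s1 <- draw_sample(t1, "S01", 0, "PBMC", seed = 5)
  s2 <- draw_sample(t2, "S01", 0, "PBMC", seed = 5)
  expect_equal(s1$records, s2$records)
  # byte-identical TSVs; a different seed gives a different sample
  f1 <- tempfile(); f2 <- tempfile()
  write_repertoire_tsv(s1, f1); write_repertoire_tsv(s2, f2)
  expect_identical(readLines(f1), readLines(f2))
  s3 <- draw_sample(t1, "S01", 0, "PBMC", seed = 6)
  expect_false(identical(s1$records, s3$records))
})

test_that("samples respect depth, compartment membership and validity", {
  cfg <- sim_config(n_individuals = 1, pool_size = 500, depth = 2e3, seed = 31)
  truth <- generate_truth(cfg)
  s <- draw_sample(truth, "S01", 0, "PBMC", seed = 1)
  expect_equal(sum(s$records$count), cfg$depth)
  expect_equal(sum(s$records$frequency), 1, tolerance = 1e-9)
  lab <- truth_labels(truth)
  mem <- draw_sample(truth, "S01", 5, "memory", seed = 2)
  nai <- draw_sample(truth, "S01", 5, "naive", seed = 3)
  expect_true(all(collapse_to_tcrs(mem)$tcr %in% lab[memory_flag == TRUE, tcr]))
  expect_true(all(collapse_to_tcrs(nai)$tcr %in%
                    lab[memory_flag == FALSE, tcr]))
  expect_error(draw_sample(truth, "S09", 0, "PBMC", seed = 1), "individual")
  expect_error(draw_sample(truth, "S01", 99, "PBMC", seed = 1), "time point")
})

test_that("with the boost off, persistent and transient base abundances match", {
  # two-sample test non-significant at alpha = 0.001 over 20 seeds
  for (seed in 1:20) {
    cfg <- sim_config(n_individuals = 1, pool_size = 2000, depth = 1e3,
                      abundance_boost = 1, couple_publicness = FALSE,
                      n_cohort_groups = 0, seed = 600 + seed)
    lab <- truth_labels(generate_truth(cfg))
    p <- stats::wilcox.test(
      log(lab[persistence_class == "persistent", base_abundance]),
      log(lab[persistence_class == "transient", base_abundance]))$p.value
    expect_gt(p, 0.001)
  }
})

test_that("persistent receptors carry higher nucleotide redundancy", {
  cfg <- sim_config(n_individuals = 1, pool_size = 2000, depth = 1e3,
                    seed = 77)
  truth <- generate_truth(cfg)
  p <- truth$individuals[[1]]
  red <- lengths(p$nt_seqs)
  expect_gt(mean(red[p$persistence_class == "persistent"]),
            mean(red[p$persistence_class == "transient"]))
})

test_that("ground-truth sharing spans all publicness deciles", {
  cfg <- sim_config(n_individuals = 1, pool_size = 5000, depth = 1e3,
                    seed = 13)
  truth <- generate_truth(cfg)
  sh <- truth_sharing_table(truth)
  expect_true(all(sh$counts <= sh$cohort_size))
  shared <- sh$keys[sh$counts > 0]
  bins <- publicness_bins(shared, sh)
  expect_setequal(unique(bins$bin), 0:9)
})

test_that("reverse_translate yields nucleotide sequences coding the input", {
  aa <- c("CASSF", "MW")
  nt <- reverse_translate(aa)
  expect_equal(nchar(nt), 3L * nchar(aa))
  # independent back-translation via the standard genetic code
  codons <- substring(nt[1], seq(1, nchar(nt[1]), 3), seq(3, nchar(nt[1]), 3))
  map <- stats::setNames(
    rep(names(tcrpersist:::CODON_TABLE), lengths(tcrpersist:::CODON_TABLE)),
    unlist(tcrpersist:::CODON_TABLE))
  expect_equal(paste(map[codons], collapse = ""), aa[1])
})

test_that("simulate_cohort assembles the full study design", {
  cfg <- sim_config(n_individuals = 2, pool_size = 500, depth = 2e3,
                    seed = 21)
  sim <- simulate_cohort(cfg)
  expect_equal(names(sim$series), c("S01", "S02"))
  ser <- sim$series[[1]]
  expect_length(ser$pbmc_samples, 8)
  expect_length(ser$memory_samples, 3)
  expect_length(ser$naive_samples, 3)
  expect_s3_class(sim$sharing, "sharing_table")
})
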