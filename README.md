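# tcrpersist

Longitudinal T cell receptor β-chain (TCRβ) repertoire analysis:
identification and characterisation of **persistent receptors** — TCRβs
detected in peripheral blood at every sampled time point of an individual
followed over a year — and of the properties that travel with persistence:
high abundance, memory phenotype, convergent nucleotide recombination,
CDR3 similarity-network connectivity, synchronised clonal trajectories,
and sharing ("publicness") across unrelated individuals.

A TCRβ is identified by its V gene, CDR3 amino-acid sequence, and J gene;
several nucleotide-level clones can encode the same receptor, and that
redundancy is itself a readout. Persistent receptors are typically a few
percent (or less) of the unique receptors in a repertoire yet carry a large
share of sequencing reads, overlap the memory compartment almost completely,
and are strongly enriched among receptors shared by more than 70% of a large
external cohort.

## What the package provides

| Stage | Key functions |
|---|---|
| I/O for immunoSEQ-style clonotype TSVs | `read_repertoire_tsv()`, `write_cohort()`, `read_sharing_tsv()` |
| Repertoire statistics | `jaccard_matrix()`, `shannon_diversity()`, `clonality()`, `vj_usage()`, `rarefaction_curve()`, `top_fraction()` |
| Persistence | `occurrence_profile()`, `persistent_set()`, `occurrence_class_summary()`, `compare_occurrence_classes()` |
| CDR3 similarity network | `build_similarity_graph()`, `neighbor_decile_bins()`, `connectivity_permutation_test()` |
| Clonal cohorts | `detect_cohort()`, `cohort_significance()`, `flag_artifact_suspects()` |
| Publicness | `publicness_bins()`, `highly_public_enrichment()`, `most_public_report()` |
| Synthetic cohorts with ground truth | `sim_config()`, `simulate_cohort()`, `truth_labels()` |
| One-shot pipeline | `validate_config()`, `run_pipeline()` |

Every stage works offline: the synthetic generator produces a full
longitudinal cohort (8 PBMC time points over 12 months, memory/naive sorted
samples at months 5–7, an external sharing cohort of 778 individuals) with
known truth labels, so detectors can be validated without access-restricted
sequencing data.

## Worked example

Simulate a small two-individual cohort and find each individual's
persistent receptors (numbers below are the actual output for this seed):

```r
library(tcrpersist)
library(data.table)

cfg <- sim_config(n_individuals = 2, pool_size = 2000, depth = 20000,
                  seed = 42)
sim <- simulate_cohort(cfg)
ser <- sim$series[[1]]
Tn  <- length(cfg$time_points)   # 8 time points

prof <- occurrence_profile(ser)      # times seen across the 8 PBMC samples
pers <- persistent_set(prof, Tn)     # seen at every time point
length(prof)                         # 918 unique productive TCRbetas
length(pers)                         # 33 persistent (3.6% of unique)

occurrence_class_summary(ser, prof)$classes[
  , .(n_occ, unique_tcr_count, mean_abundance, memory_overlap_fraction)]
#>    n_occ unique_tcr_count mean_abundance memory_overlap_fraction
#> 1:     1              700       0.000572                   0.104
#> 2:     2               47       0.000422                   0.404
#> ...
#> 8:     8               33       0.022330                   1.000
```

The shape is the one seen in real longitudinal repertoires: once-seen
receptors dominate the unique-receptor count, but the 33 persistent
receptors have ~40× the mean relative abundance, make up 73% of month-0
reads, and every one of them appears in the sorted memory compartment.
Abundance separates the occurrence extremes decisively
(Mann–Whitney, once-seen vs persistent: p ≈ 8×10⁻¹⁷).

Connectivity and publicness travel with persistence:

```r
g    <- build_similarity_graph(names(prof), d_max = 1)  # CDR3 Levenshtein <= 1
bins <- neighbor_decile_bins(g)
connectivity_permutation_test(bins, prof, n_perm = 500, seed = 7)
#> trend 0.187 (Spearman degree vs occurrence), p = 0.002

profiles <- setNames(lapply(sim$series, occurrence_profile),
                     vapply(sim$series, `[[`, "", "individual_id"))
highly_public_enrichment(profiles, sim$sharing, Tn, n_perm = 500, seed = 11)$counts
#>    individual_id n_highly_public persistent_highly_public once_highly_public
#> 1:           S01               7                        6                  0
#> 2:           S02               7                        5                  1
```

Of the receptors shared by >70% of the external cohort, almost all sit in
the persistent class and almost none in the once-seen class (permutation
p = 0.002 for both individuals). Samples from the same individual also
overlap far more than samples from different individuals (mean Jaccard
0.211 within vs 0.022 between).

## Tests

```r
testthat::test_dir("tests/testthat", package = "tcrpersist",
                   load_package = "installed")
```

The suite covers exact closed-form statistics, brute-force oracles for the
Levenshtein graph and maximum-clique search, detector sensitivity/false
discovery against generator truth labels, uniformity of permutation
p-values under generator nulls (Kolmogorov–Smirnov), and byte-identical
reproducibility of pipeline outputs for a fixed seed.

See `vignettes/persistent-receptors.Rmd` for the methods write-up,
including the generator's design constraints and the caveats on its
default parameter scale.
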