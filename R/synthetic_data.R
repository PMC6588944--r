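AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Codon table for reverse-translating CDR3 amino-acid sequences into
# plausible nucleotide rearrangements (stop codons never emitted).
CODON_TABLE <- list(
  A = c("GCT", "GCC", "GCA", "GCG"), C = c("TGT", "TGC"),
  D = c("GAT", "GAC"), E = c("GAA", "GAG"),
  F = c("TTT", "TTC"), G = c("GGT", "GGC", "GGA", "GGG"),
  H = c("CAT", "CAC"), I = c("ATT", "ATC", "ATA"),
  K = c("AAA", "AAG"), L = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"),
  M = "ATG", N = c("AAT", "AAC"),
  P = c("CCT", "CCC", "CCA", "CCG"), Q = c("CAA", "CAG"),
  R = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"),
  S = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
  T = c("ACT", "ACC", "ACA", "ACG"), V = c("GTT", "GTC", "GTA", "GTG"),
  W = "TGG", Y = c("TAT", "TAC"))

# Vectorised random reverse translation: one random codon per residue.
reverse_translate <- function(aa_vec) {
  if (length(aa_vec) == 0) return(character(0))
  chars <- strsplit(aa_vec, "")
  lens <- lengths(chars)
  flat <- unlist(chars, use.names = FALSE)
  ncod <- lengths(CODON_TABLE)[flat]
  pick <- ceiling(stats::runif(length(flat)) * ncod)
  codons <- mapply(function(a, i) CODON_TABLE[[a]][i], flat, pick,
                   USE.NAMES = FALSE)
  dt <- data.table::data.table(codon = codons,
                               id = rep(seq_along(aa_vec), lens))
  dt[, .(nt = paste(codon, collapse = "")), by = id]$nt
}

# Random CDR3 amino-acid sequences: conserved C...F frame, random core.
random_cdr3 <- function(n, len_range = c(10L, 18L)) {
  if (n == 0) return(character(0))
  lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE,
                 prob = stats::dnorm(seq(len_range[1], len_range[2]),
                                     mean = 14, sd = 1.8))
  core_len <- lens - 2L
  flat <- sample(AA_ALPHABET, sum(core_len), replace = TRUE)
  dt <- data.table::data.table(ch = flat, id = rep(seq_len(n), core_len))
  core <- dt[, .(s = paste(ch, collapse = "")), by = id]$s
  paste0("C", core, "F")
}

V_GENES <- sprintf("TCRBV%02d-01", 1:30)
J_GENES <- sprintf("TCRBJ%02d-0%d", rep(1:2, c(6, 7)), c(1:6, 1:7))

#' Configuration for the synthetic longitudinal cohort generator
#'
#' Defaults emulate the design of a three-subject, eight-time-point PBMC
#' immunosequencing study with memory/naive sorts at three intermediate
#' months, heavy-tailed (log-normal) clone abundances, a persistent clone
#' subset with an abundance boost and elevated nucleotide redundancy, public
#' clones shared across individuals and with an external reference cohort,
#' a nonproductive read fraction, and multinomial blood-draw undersampling.
#'
#' @param n_individuals number of subjects.
#' @param time_points months of the PBMC draws.
#' @param sorted_time_points months at which memory/naive sorts exist.
#' @param pool_size clones per individual before sampling.
#' @param lognormal_sigma sdlog of base clone abundances.
#' @param persistent_fraction,intermittent_fraction fractions of the pool in
#'   the persistent / intermittent occurrence classes (remainder transient).
#' @param abundance_boost multiplicative abundance advantage of persistent
#'   clones over the base log-normal draw.
#' @param nt_lambda_persistent,nt_lambda_other Poisson rates for extra
#'   nucleotide rearrangements per receptor (redundancy = 1 + Poisson).
#' @param nonproductive_fraction expected fraction of templates from
#'   out-of-frame / stop-containing rearrangements.
#' @param depth templates per sequencing library.
#' @param cohort_size size of the external sharing cohort.
#' @param public_fraction fraction of each pool shared across individuals
#'   (and present in the external cohort with share counts spanning deciles).
#' @param couple_publicness if TRUE, a clone's chance of being persistent
#'   rises with its external share fraction (the planted publicness effect);
#'   FALSE decouples them (null configuration).
#' @param couple_connectivity if TRUE, persistent private clones are seeded
#'   in small sequence-similar clusters (1 substitution from a cluster
#'   center), planting the connectivity-persistence association; FALSE
#'   plants equally many clusters at class-independent random private
#'   clones, so sequence similarity exists but is decoupled from
#'   persistence (null configuration).
#' @param persistent_cluster_size cluster size for connectivity coupling.
#' @param p_memory named probabilities of carrying the memory flag per
#'   persistence class.
#' @param random_walk_sd sd of per-step log abundance multipliers. The
#'   default is kept small so that persistent clones 10x above the
#'   detection limit (10/depth) remain detectable at every time point:
#'   larger steps both dip individual trajectories below detection and
#'   inflate the per-sample denominator late in the series (the multiplier
#'   mean grows as exp(t sd^2 / 2)).
#' @param n_cohort_groups,cohort_group_size planted co-trajectory cohorts:
#'   groups of high-abundance persistent clones sharing one latent
#'   trajectory.
#' @param cohort_noise_sd sd of member-specific log noise around the latent
#'   cohort trajectory (latent steps have sd 1, so the default keeps the
#'   common signal far above the clone noise variance..
#' @param seed mandatory integer seed; all generation is deterministic in it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_individuals = 3,
                       time_points = c(0, 1, 2, 3, 5, 6, 7, 12),
                       sorted_time_points = c(5, 6, 7),
                       pool_size = 50000,
                       lognormal_sigma = 2.5,
                       persistent_fraction = 0.01,
                       intermittent_fraction = 0.2,
                       abundance_boost = 50,
                       nt_lambda_persistent = 0.5,
                       nt_lambda_other = 0.05,
                       nonproductive_fraction = 0.15,
                       depth = 1e5,
                       cohort_size = 778,
                       public_fraction = 0.05,
                       couple_publicness = TRUE,
                       couple_connectivity = TRUE,
                       persistent_cluster_size = 5,
                       p_memory = c(persistent = 0.98, intermittent = 0.6,
                                    transient = 0.4),
                       random_walk_sd = 0.15,
                       n_cohort_groups = 1,
                       cohort_group_size = 10,
                       cohort_noise_sd = 0.05,
                       seed) {
  if (missing(seed) || is.null(seed)) stop("sim_config: 'seed' is mandatory")
  cfg <- as.list(environment())
  fracs <- c(persistent_fraction, intermittent_fraction,
             nonproductive_fraction, public_fraction)
  if (any(fracs < 0 | fracs > 1)) stop("sim_config: fractions must lie in [0, 1]")
  if (persistent_fraction + intermittent_fraction > 1)
    stop("sim_config: persistent + intermittent fractions exceed 1")
  if (depth < 1) stop("sim_config: depth must be >= 1")
  if (persistent_fraction > 0 && persistent_fraction * pool_size < 1)
    stop("sim_config: infeasible - persistent_fraction x pool_size < 1")
  if (!all(sorted_time_points %in% time_points))
    stop("sim_config: sorted_time_points must be a subset of time_points")
  cfg$n_timepoints <- length(time_points)
  structure(cfg, class = "sim_config")
}

#' Generate a ground-truth clone pool for a synthetic cohort
#'
#' Deterministic in `config$seed`. Each individual receives a pool of clones
#' with log-normal base abundances, a persistence class (persistent clones
#' carry an abundance boost and a stochastically larger nucleotide
#' redundancy), a memory flag, a trajectory of per-time-point abundance
#' multipliers (persistent: geometric random walk, strictly positive
#' everywhere; intermittent: active on a contiguous window; transient: one
#' active time point), and an external-cohort share count. A configurable
#' subset of clones is shared across individuals with share counts spanning
#' all publicness deciles, and planted co-trajectory cohort groups share one
#' latent trajectory.
#'
#' @param config a [sim_config()].
#' @return an object of class `truth_pool`: per-individual truth tables plus
#'   nonproductive pools.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "truth"), {
    Tn <- config$n_timepoints
    n_pub <- round(config$public_fraction * config$pool_size)

    # Global public clones: identical receptor identity in every individual,
    # share fractions skewed private but spanning all deciles.
    pub <- data.table::data.table(
      cdr3_aa = random_cdr3(n_pub),
      v_gene = sample(V_GENES, n_pub, replace = TRUE),
      j_gene = sample(J_GENES, n_pub, replace = TRUE))
    share_frac <- stats::runif(n_pub)^3
    pub[, public_share_count := pmax(1L, as.integer(round(share_frac * config$cohort_size)))]

    individuals <- list()
    nonproductive <- list()
    for (ind in seq_len(config$n_individuals)) {
      ind_id <- sprintf("S%02d", ind)
      n_priv <- config$pool_size - n_pub
      priv <- data.table::data.table(
        cdr3_aa = random_cdr3(n_priv),
        v_gene = sample(V_GENES, n_priv, replace = TRUE),
        j_gene = sample(J_GENES, n_priv, replace = TRUE),
        public_share_count = 0L)
      pool <- rbind(pub[, .(cdr3_aa, v_gene, j_gene, public_share_count)], priv)
      pool[, is_public := c(rep(TRUE, n_pub), rep(FALSE, n_priv))]

      # Persistence classes; optionally coupled to publicness so that very
      # public clones are much likelier to be persistent.
      # persistent_fraction 0 always means no persistent clone, so the
      # publicness coupling only applies when the class is populated
      p_pers <- rep(config$persistent_fraction, nrow(pool))
      if (config$couple_publicness && n_pub > 0 &&
          config$persistent_fraction > 0) {
        f <- pool$public_share_count / config$cohort_size
        p_pers <- pmin(0.95, p_pers + 0.9 * f^2)
      }
      u <- stats::runif(nrow(pool))
      cls <- ifelse(u < p_pers, "persistent",
             ifelse(u < p_pers + config$intermittent_fraction, "intermittent",
                    "transient"))
      pool[, persistence_class := cls]

      # Connectivity structure: rewrite a set of PRIVATE CDR3s as clusters
      # of single-substitution variants around shared centers. Coupled, the
      # set is the persistent private clones (planting the
      # connectivity-persistence association); decoupled, an equally sized
      # set of private clones is drawn uniformly at random regardless of
      # class, so baseline sequence similarity exists but is independent of
      # persistence (the null configuration).
      {
        idx_pers <- which(pool$persistence_class == "persistent" &
                            !pool$is_public)
        idx <- if (config$couple_connectivity) idx_pers else {
          priv <- which(!pool$is_public)
          sort(sample(priv, min(length(idx_pers), length(priv))))
        }
        if (length(idx) >= 2 && config$persistent_cluster_size >= 2) {
          k <- config$persistent_cluster_size
          grp <- ceiling(seq_along(idx) / k)
          centers <- random_cdr3(max(grp))
          new_cdr3 <- vapply(seq_along(idx), function(i) {
            ctr <- centers[grp[i]]
            pos <- sample(2:(nchar(ctr) - 1), 1)   # keep the C...F frame
            sub <- sample(AA_ALPHABET, 1)
            paste0(substr(ctr, 1, pos - 1), sub,
                   substr(ctr, pos + 1, nchar(ctr)))
          }, character(1))
          pool[idx, cdr3_aa := new_cdr3]
        }
      }
      pool[, tcr := tcr_key(v_gene, cdr3_aa, j_gene)]
      pool <- unique(pool, by = "tcr")
      n <- nrow(pool)

      # Heavy-tailed base abundances; persistent clones boosted.
      ab <- stats::rlnorm(n, meanlog = 0, sdlog = config$lognormal_sigma)
      ab[pool$persistence_class == "persistent"] <-
        ab[pool$persistence_class == "persistent"] * config$abundance_boost
      pool[, base_abundance := ab / sum(ab)]

      # Nucleotide redundancy: persistent receptors accrue convergent
      # rearrangements at a higher rate.
      lam <- ifelse(pool$persistence_class == "persistent",
                    config$nt_lambda_persistent, config$nt_lambda_other)
      pool[, nt_redundancy := 1L + stats::rpois(n, lam)]

      pool[, memory_flag := stats::rbinom(n, 1,
             config$p_memory[persistence_class]) == 1]

      # Trajectories.
      traj <- matrix(0, nrow = n, ncol = Tn)
      is_pers <- pool$persistence_class == "persistent"
      n_pers <- sum(is_pers)
      if (n_pers > 0) {
        steps <- matrix(stats::rnorm(n_pers * Tn, 0, config$random_walk_sd),
                        n_pers, Tn)
        traj[is_pers, ] <- exp(t(apply(steps, 1, cumsum)))
      }
      is_int <- pool$persistence_class == "intermittent"
      for (i in which(is_int)) {
        k <- sample(2:max(2, Tn - 1), 1)
        start <- sample(seq_len(Tn - k + 1), 1)
        traj[i, start:(start + k - 1)] <-
          exp(cumsum(stats::rnorm(k, 0, config$random_walk_sd)))
      }
      is_tra <- pool$persistence_class == "transient"
      if (any(is_tra)) {
        t_on <- sample.int(Tn, sum(is_tra), replace = TRUE)
        traj[cbind(which(is_tra), t_on)] <- exp(stats::rnorm(sum(is_tra), 0, 0.5))
      }

      # Planted co-trajectory cohorts: high-abundance persistent clones that
      # follow one latent trajectory with small member-specific noise.
      pool[, cohort_group := 0L]
      if (config$n_cohort_groups > 0) {
        pers_idx <- which(is_pers)
        need <- config$n_cohort_groups * config$cohort_group_size
        if (length(pers_idx) >= need) {
          chosen <- sample(pers_idx, need)
          # high-abundance but not mass-dominating: park members around the
          # ~8th abundance rank so the shared latent trajectory survives
          # the relative-abundance normalization
          hi <- sort(pool$base_abundance, decreasing = TRUE)[min(8L, n)]
          for (g in seq_len(config$n_cohort_groups)) {
            mem <- chosen[((g - 1) * config$cohort_group_size + 1):
                          (g * config$cohort_group_size)]
            lsteps <- cumsum(stats::rnorm(Tn, 0, 1))
            latent <- exp(lsteps - mean(lsteps))  # geometric-mean centered
            for (i in mem) {
              traj[i, ] <- latent * exp(stats::rnorm(Tn, 0, config$cohort_noise_sd))
            }
            pool[mem, cohort_group := g]
            # lift members into the high-abundance (top 1%) range
            pool[mem, base_abundance := hi * stats::runif(length(mem), 0.9, 1.4)]
          }
          pool[, base_abundance := base_abundance / sum(base_abundance)]
        }
      }

      # Nucleotide rearrangements encoding each receptor, with Dirichlet
      # weights splitting the receptor's abundance across lineages.
      nt_all <- reverse_translate(rep(pool$cdr3_aa, pool$nt_redundancy))
      w_all <- stats::rgamma(length(nt_all), 1)
      nt_dt <- data.table::data.table(
        id = rep(seq_len(n), pool$nt_redundancy), nt = nt_all, w = w_all)
      nt_dt[, w := w / sum(w), by = id]
      idf <- factor(nt_dt$id, levels = seq_len(n))
      pool[, nt_seqs := split(nt_dt$nt, idf)]
      pool[, nt_weights := split(nt_dt$w, idf)]

      pool[, trajectory := lapply(seq_len(n), function(i) traj[i, ])]

      # Nonproductive pool: stop-containing CDR3s with heavy-tailed mass.
      n_np <- max(50L, round(0.04 * config$pool_size))
      np_aa <- random_cdr3(n_np)
      pos <- vapply(np_aa, function(s) sample(2:(nchar(s) - 1), 1), 1L)
      substr(np_aa, pos, pos) <- "*"
      np <- data.table::data.table(
        amino_acid = np_aa,
        v_gene = sample(V_GENES, n_np, replace = TRUE),
        j_gene = sample(J_GENES, n_np, replace = TRUE),
        cdr3_nt = reverse_translate(gsub("*", "W", np_aa, fixed = TRUE)),
        weight = stats::rlnorm(n_np, 0, config$lognormal_sigma))
      np[, weight := weight / sum(weight)]

      individuals[[ind_id]] <- pool[]
      nonproductive[[ind_id]] <- np[]
    }
    structure(list(config = config, individuals = individuals,
                   nonproductive = nonproductive),
              class = "truth_pool")
  })
}

#' @export
print.truth_pool <- function(x, ...) {
  cat(sprintf("<truth_pool> %d individuals x %d time points, ~%d clones each\n",
              length(x$individuals), x$config$n_timepoints,
              nrow(x$individuals[[1]])))
  invisible(x)
}

#' Ground-truth labels of a synthetic pool
#'
#' @param pool a [generate_truth()] result.
#' @return data.table with one row per (individual, receptor): persistence
#'   class, base abundance, memory flag, share count, cohort group.
#' @export
truth_labels <- function(pool) {
  data.table::rbindlist(lapply(names(pool$individuals), function(id) {
    p <- pool$individuals[[id]]
    data.table::data.table(individual_id = id, tcr = p$tcr,
                           v_gene = p$v_gene, cdr3_aa = p$cdr3_aa,
                           j_gene = p$j_gene,
                           persistence_class = p$persistence_class,
                           base_abundance = p$base_abundance,
                           memory_flag = p$memory_flag,
                           public_share_count = p$public_share_count,
                           cohort_group = p$cohort_group)
  }))
}

#' Draw one sequencing library from a truth pool
#'
#' Template counts are drawn multinomially from the trajectory-adjusted clone
#' abundances at the requested time point (blood-draw undersampling);
#' nonproductive templates are injected at the configured fraction. The
#' memory compartment draws only from memory-flagged clones, naive from the
#' complement.
#'
#' @param pool a [generate_truth()] result.
#' @param individual individual id (e.g. "S01").
#' @param time_point one of `config$time_points`.
#' @param compartment "PBMC", "memory" or "naive".
#' @param depth templates to draw (default `config$depth`).
#' @param seed integer seed; same seed, same sample.
#' @return a [tcr_sample()].
#' @export
draw_sample <- function(pool, individual, time_point,
                        compartment = c("PBMC", "memory", "naive"),
                        depth = NULL, seed) {
  compartment <- match.arg(compartment)
  if (!individual %in% names(pool$individuals))
    stop("unknown individual: ", individual)
  cfg <- pool$config
  t_idx <- match(time_point, cfg$time_points)
  if (is.na(t_idx)) stop("unknown time point: ", time_point)
  depth <- depth %||% cfg$depth
  p <- pool$individuals[[individual]]
  keep <- switch(compartment,
                 PBMC = rep(TRUE, nrow(p)),
                 memory = p$memory_flag,
                 naive = !p$memory_flag)
  p <- p[keep]
  traj_t <- vapply(p$trajectory, `[[`, numeric(1), t_idx)
  w <- p$base_abundance * traj_t
  if (sum(w) <= 0) stop("no clone mass in this compartment at this time point")

  with_seed(seed, {
    n_np <- stats::rbinom(1, depth, cfg$nonproductive_fraction)
    n_prod <- depth - n_np
    # expand receptors to nucleotide lineages
    reps <- lengths(p$nt_seqs)
    idx <- rep(seq_len(nrow(p)), reps)
    lw <- w[idx] * unlist(p$nt_weights, use.names = FALSE)
    counts <- stats::rmultinom(1, n_prod, lw)[, 1]
    sel <- counts > 0
    rec <- data.table::data.table(
      amino_acid = p$cdr3_aa[idx][sel],
      v_gene = p$v_gene[idx][sel],
      j_gene = p$j_gene[idx][sel],
      cdr3_nt = unlist(p$nt_seqs, use.names = FALSE)[sel],
      count = counts[sel])
    np <- pool$nonproductive[[individual]]
    np_counts <- stats::rmultinom(1, n_np, np$weight)[, 1]
    np_sel <- np_counts > 0
    if (any(np_sel)) {
      rec <- rbind(rec, data.table::data.table(
        amino_acid = np$amino_acid[np_sel],
        v_gene = np$v_gene[np_sel], j_gene = np$j_gene[np_sel],
        cdr3_nt = np$cdr3_nt[np_sel], count = np_counts[np_sel]))
    }
    tcr_sample(rec, individual, time_point, compartment)
  })
}

#' Expose ground-truth sharing as a sharing table
#'
#' @param pool a [generate_truth()] result.
#' @param cohort_size cohort size (default from the config).
#' @return a [sharing_table()] mapping every truth receptor to its share
#'   count in the external cohort.
#' @export
truth_sharing_table <- function(pool, cohort_size = NULL) {
  cohort_size <- cohort_size %||% pool$config$cohort_size
  lab <- truth_labels(pool)
  counts <- lab[, .(share_count = max(public_share_count)), by = tcr]
  sharing_table(stats::setNames(counts$share_count, counts$tcr), cohort_size)
}

#' Simulate a full longitudinal cohort
#'
#' Generates the truth pool and draws every library of the study design:
#' PBMC at each time point for each individual, plus memory and naive sorts
#' at the sorted time points. Per-sample seeds are derived deterministically
#' from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `truth` (the pool), `series` (named list of
#'   [tcr_series()] per individual), and `sharing` (a [sharing_table()]).
#' @export
simulate_cohort <- function(config) {
  truth <- generate_truth(config)
  series <- lapply(names(truth$individuals), function(ind) {
    pbmc <- lapply(config$time_points, function(tp) {
      draw_sample(truth, ind, tp, "PBMC",
                  seed = derive_seed(config$seed, "draw", ind, tp, "PBMC"))
    })
    mem <- lapply(config$sorted_time_points, function(tp) {
      draw_sample(truth, ind, tp, "memory",
                  seed = derive_seed(config$seed, "draw", ind, tp, "memory"))
    })
    nai <- lapply(config$sorted_time_points, function(tp) {
      draw_sample(truth, ind, tp, "naive",
                  seed = derive_seed(config$seed, "draw", ind, tp, "naive"))
    })
    tcr_series(pbmc, mem, nai)
  })
  names(series) <- names(truth$individuals)
  list(truth = truth, series = series,
       sharing = truth_sharing_table(truth))
}

#' Write a simulated cohort to disk
#'
#' Emits one repertoire TSV per library (the immunoSEQ-style dialect of
#' [write_repertoire_tsv()]), a sharing-table TSV, a truth-labels TSV, and
#' the generation parameters as YAML (seed included).
#'
#' @param sim a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ind in names(sim$series)) {
    ser <- sim$series[[ind]]
    for (s in c(ser$pbmc_samples, ser$memory_samples, ser$naive_samples)) {
      write_repertoire_tsv(s, file.path(dir, sprintf(
        "%s_t%02d_%s.tsv", ind, as.integer(s$time_point), s$compartment)))
    }
  }
  write_sharing_tsv(sim$sharing, file.path(dir, "sharing_table.tsv"))
  data.table::fwrite(truth_labels(sim$truth),
                     file.path(dir, "truth_labels.tsv"), sep = "\t")
  cfg <- sim$truth$config
  yaml::write_yaml(cfg[setdiff(names(cfg), "n_timepoints")],
                   file.path(dir, "sim_config.yaml"))
  invisible(dir)
}
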