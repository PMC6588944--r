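# Small hand-built fixtures shared across test files.

# A sample with known structure: 3 productive receptors (one with two
# nucleotide lineages), one stop-codon record, one unresolved-V record.
make_fixture_sample <- function(individual = "P1", time_point = 0,
                                compartment = "PBMC") {
  rec <- data.frame(
    amino_acid = c("CASSLEETQYF", "CASSLEETQYF", "CASSPQETQYF",
                   "CASRGGTDTQYF", "CASS*LF", "CASSIRSSYEQYF"),
    v_gene = c("TCRBV05-01", "TCRBV05-01", "TCRBV06-01",
               "TCRBV07-01", "TCRBV09-01", "unresolved"),
    j_gene = c("TCRBJ02-05", "TCRBJ02-05", "TCRBJ02-05",
               "TCRBJ02-03", "TCRBJ01-01", "TCRBJ02-07"),
    cdr3_nt = c("TGTGCCAGCAGCTTAGAAGAAACGCAGTATTTT",
                "TGCGCCAGCAGCTTAGAAGAAACGCAGTATTTT",  # synonymous variant
                "TGTGCCAGCAGCCCCCAGGAAACGCAGTATTTT",
                "", "", ""),
    count = c(40, 10, 30, 10, 5, 5),
    stringsAsFactors = FALSE)
  tcr_sample(rec, individual, time_point, compartment)
}

# A tiny longitudinal series with fully controlled occurrence patterns.
# Receptor A: present at all 3 time points; B: at 2; C: at 1.
make_fixture_series <- function(individual = "P1") {
  mk <- function(tp, aas, vs, js, counts) {
    tcr_sample(data.frame(amino_acid = aas, v_gene = vs, j_gene = js,
                          count = counts, stringsAsFactors = FALSE),
               individual, tp, "PBMC")
  }
  a <- c("CASSAAAAQYF", "TCRBV01-01", "TCRBJ01-01")
  b <- c("CASSBBBBQYF", "TCRBV02-01", "TCRBJ01-02")
  c_ <- c("CASSCCCCQYF", "TCRBV03-01", "TCRBJ01-03")
  s1 <- mk(0, c(a[1], b[1]), c(a[2], b[2]), c(a[3], b[3]), c(80, 20))
  s2 <- mk(1, c(a[1], b[1], c_[1]), c(a[2], b[2], c_[2]),
           c(a[3], b[3], c_[3]), c(60, 30, 10))
  s3 <- mk(2, a[1], a[2], a[3], 100)
  tcr_series(list(s1, s2, s3))
}

fixture_keys <- function() {
  c(A = tcr_key("TCRBV01-01", "CASSAAAAQYF", "TCRBJ01-01"),
    B = tcr_key("TCRBV02-01", "CASSBBBBQYF", "TCRBJ01-02"),
    C = tcr_key("TCRBV03-01", "CASSCCCCQYF", "TCRBJ01-03"))
}

# Reference Levenshtein distance via the textbook dynamic-programming
# matrix — an implementation independent of the package's.
lev_dp <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n; d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + (x[i] != y[j]))
    }
  }
  d[n + 1, m + 1]
}

# Exhaustive maximum-clique size by bitmask enumeration (n <= 20).
clique_brute <- function(adj) {
  n <- nrow(adj)
  if (n == 0) return(0L)
  masks <- 0:(2^n - 1)
  valid <- rep(TRUE, length(masks))
  bit <- bitwShiftL(1L, 0:(n - 1))
  adjm <- vapply(seq_len(n), function(i)
    sum(bit[adj[i, ] | seq_len(n) == i]), numeric(1))
  for (i in seq_len(n)) {
    has_i <- bitwAnd(masks, bit[i]) > 0
    ok <- bitwAnd(adjm[i], masks) == masks
    valid <- valid & (!has_i | ok)
  }
  popcount <- vapply(masks[valid], function(m) sum(bitwAnd(m, bit) > 0),
                     numeric(1))
  as.integer(max(popcount))
}

# Random CDR3-like strings for oracle tests.
random_strings <- function(n, lens = 8:20) {
  vapply(seq_len(n), function(i) {
    paste(sample(LETTERS[1:20], sample(lens, 1), replace = TRUE),
          collapse = "")
  }, character(1))
}
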