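#' Canonical TCRbeta identity key
#'
#' A TCRbeta is identified by the exact string triple (V gene, CDR3 amino-acid
#' sequence, J gene); gene labels are used verbatim, with no allele collapsing.
#' The key is the pipe-joined triple and is used wherever receptors are placed
#' in sets or used as map keys.
#'
#' @param v_gene,cdr3_aa,j_gene character vectors of equal length.
#' @return character vector of keys.
#' @export
tcr_key <- function(v_gene, cdr3_aa, j_gene) {
  paste(v_gene, cdr3_aa, j_gene, sep = "|")
}

#' Split TCR keys back into their components
#'
#' @param key character vector of keys produced by [tcr_key()].
#' @return data.table with columns `v_gene`, `cdr3_aa`, `j_gene`.
#' @export
tcr_unkey <- function(key) {
  parts <- data.table::tstrsplit(key, "|", fixed = TRUE)
  data.table::data.table(v_gene = parts[[1]], cdr3_aa = parts[[2]],
                         j_gene = parts[[3]])
}

#' Extract the CDR3 amino-acid sequence from TCR keys
#' @param key character vector of keys.
#' @return character vector of CDR3 sequences.
#' @export
tcr_cdr3 <- function(key) {
  tcr_unkey(key)$cdr3_aa
}

# Deterministic child seed from a base seed and a character/int tag.
# Keeps all derived seeds in [1, 2^31 - 2].
derive_seed <- function(seed, ...) {
  tags <- paste(c(...), collapse = "/")
  h <- 0
  for (cp in utf8ToInt(tags)) h <- (h * 131 + cp) %% 2147483587L
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147483587 + 1)
}

# Evaluate `code` under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
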