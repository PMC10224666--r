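# Independent brute-force oracles and small fixture builders.

# Exhaustive minimum-energy nested folding by recursive enumeration
# (no memoization, no shared code with the package DP). Position i is
# either unpaired or paired with some k > i + 3.
oracle_mfe <- function(seq) {
  s <- strsplit(chartr("Tt", "Uu", toupper(seq)), "")[[1]]
  e_pair <- function(a, b) {
    key <- paste0(a, b)
    if (key %in% c("GC", "CG")) return(-3)
    if (key %in% c("AU", "UA")) return(-2)
    if (key %in% c("GU", "UG")) return(-1)
    0
  }
  rec <- function(i, j) {
    if (j - i < 4) return(0)
    best <- rec(i + 1, j)
    for (k in (i + 4):j) {
      e <- e_pair(s[i], s[k])
      if (e < 0) {
        cand <- e + rec(i + 1, k - 1) + (if (k < j) rec(k + 1, j) else 0)
        if (cand < best) best <- cand
      }
    }
    best
  }
  n <- length(s)
  if (n < 2) 0 else rec(1, n)
}

# Brute-force best 15mer: explicit substring loop, independent of
# enumerate_oligomers().
oracle_best_15mer <- function(sequence, allele, predictor) {
  n <- nchar(sequence)
  best_rank <- Inf; best_off <- NA_integer_
  for (i in seq_len(n - 14L)) {
    r <- predict_ranks(predictor, substr(sequence, i, i + 14L), allele)
    if (r < best_rank) {
      best_rank <- r
      best_off <- i
    }
  }
  list(offset = best_off, rank = best_rank)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

random_peptide <- function(n) {
  paste(sample(aa_alphabet(), n, replace = TRUE), collapse = "")
}

# Synthetic scored-candidate table in the shape select_panel() expects:
# expressed, distinct mutations, distinct strong best ligands of both
# classes, descending composite.
make_scored_candidates <- function(n, rpkm = 50) {
  data.frame(
    id = sprintf("cand%03d", seq_len(n)),
    mutation_id = sprintf("mut%03d", seq_len(n)),
    expression_rpkm = rep(rpkm, n),
    best_ligand1 = sprintf("LIGONE%03d", seq_len(n)),
    best_rank1 = rep(0.1, n),
    best_ligand2 = sprintf("LIGTWOPEPTIDE%03d", seq_len(n)),
    best_rank2 = rep(0.5, n),
    composite = seq(0.99, 0.01, length.out = n),
    stringsAsFactors = FALSE)
}

# Uniform codon-usage table (every codon frequency 1).
uniform_codon_usage <- function() {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  codon_usage_table(stats::setNames(rep(1, length(sense)), sense))
}
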