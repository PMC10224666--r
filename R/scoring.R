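#' Scoring parameter defaults
#'
#' Tunable parameters of the four-factor score. `rank_midpoint` (r0, %rank
#' units) and `rank_slope` (k) shape the logistic mapping from the best
#' predictor %rank to a raw ligand probability; `expression_e50` (RPKM) is
#' the half-saturation constant of the expression factor;
#' `immunogenicity_tau` scales the physicochemical distance in the
#' immunogenicity map; `caller_weights` weight the somatic caller consensus.
#'
#' @param rank_midpoint Logistic midpoint r0 in %rank units (default 2).
#' @param rank_slope Logistic slope k (default 2 per %rank unit).
#' @param expression_e50 Expression half-saturation in RPKM (default 10).
#' @param immunogenicity_tau Distance scale tau (default 2).
#' @param caller_weights Named non-negative weights, one per configured
#'   caller; default equal weights over [default_callers()].
#' @param property_table 20 x 5 amino-acid property matrix (default
#'   [atchley_factors()]).
#' @return Named list of scoring parameters.
#' @export
scoring_params <- function(rank_midpoint = 2, rank_slope = 2,
                           expression_e50 = 10, immunogenicity_tau = 2,
                           caller_weights = NULL,
                           property_table = atchley_factors()) {
  if (is.null(caller_weights)) {
    caller_weights <- stats::setNames(rep(1, length(default_callers())),
                                      default_callers())
  }
  stopifnot(all(caller_weights >= 0), sum(caller_weights) > 0,
            !is.null(names(caller_weights)))
  list(rank_midpoint = rank_midpoint, rank_slope = rank_slope,
       expression_e50 = expression_e50,
       immunogenicity_tau = immunogenicity_tau,
       caller_weights = caller_weights, property_table = property_table)
}

#' Somatic probability from caller consensus
#'
#' Weighted consensus fraction of the configured somatic callers supporting
#' a variant: the sum of supporting-caller weights over the total weight.
#' With default equal weights over four callers, support by two callers
#' gives 0.5.
#'
#' @param callers_supporting Character vector of supporting caller names.
#' @param weights Named non-negative weights over the configured callers.
#' @return Somatic probability in \[0, 1\].
#' @export
somatic_probability <- function(callers_supporting,
                                weights = scoring_params()$caller_weights) {
  unknown <- setdiff(callers_supporting, names(weights))
  if (length(unknown) > 0) {
    stop("unknown caller(s): ", paste(unknown, collapse = ", "))
  }
  sum(weights[unique(callers_supporting)]) / sum(weights)
}

#' Purity-corrected cancer cell fraction
#'
#' Corrects an observed tumor VAF for tumor purity under a diploid,
#' copy-neutral model: a heterozygous variant present in all cancer cells
#' of a sample with purity p has expected VAF p/2, so
#' CCF = clamp(2 * vaf / purity, 0, 1).
#'
#' @param vaf Observed variant allele frequency in \[0, 1\].
#' @param purity Tumor purity in (0, 1\].
#' @return Estimated cancer cell fraction in \[0, 1\]. Vectorized over `vaf`.
#' @export
corrected_vaf <- function(vaf, purity) {
  if (length(purity) != 1 || is.na(purity) || purity <= 0 || purity > 1) {
    stop("purity must be a single value in (0, 1]")
  }
  if (any(vaf < 0 | vaf > 1)) stop("vaf must lie in [0, 1]")
  pmin(pmax(2 * vaf / purity, 0), 1)
}

#' Clonal probability
#'
#' Combines the purity-corrected cancer cell fraction with the somatic
#' probability as their product: a variant is a credible clonal target only
#' when it is both near-clonal and well supported.
#'
#' @param ccf Cancer cell fraction in \[0, 1\].
#' @param somatic_p Somatic probability in \[0, 1\].
#' @return Clonal probability in \[0, 1\].
#' @export
clonal_probability <- function(ccf, somatic_p) {
  stopifnot(all(ccf >= 0 & ccf <= 1), all(somatic_p >= 0 & somatic_p <= 1))
  ccf * somatic_p
}

# Best (lowest) rank over a set of alleles for a peptide set; ties broken
# by lowest offset, then lexicographic allele name.
.best_over_alleles <- function(oligomers, alleles, predictor) {
  if (nrow(oligomers) == 0 || length(alleles) == 0) {
    return(list(rank = Inf, oligomer = NA_character_,
                offset = NA_integer_, allele = NA_character_))
  }
  best <- list(rank = Inf, oligomer = NA_character_,
               offset = NA_integer_, allele = NA_character_)
  for (al in sort(alleles)) {
    r <- predict_ranks(predictor, oligomers$oligomer, al)
    i <- which.min(r)  # which.min takes the first (leftmost) minimum
    if (r[i] < best$rank) {
      best <- list(rank = r[i], oligomer = oligomers$oligomer[i],
                   offset = oligomers$offset[i], allele = al)
    }
  }
  best
}

#' MHC ligand probability of a neoepitope
#'
#' Scores every overlapping oligomer of the class-specific sizes (8-11 for
#' MHC-I, 15 for MHC-II) against every allele of that class, takes the best
#' (lowest) %rank r* per class, and calibrates it to a probability with a
#' logistic map p_raw = 1 / (1 + exp(k * (r* - r0))). Expression is
#' integrated as a saturating factor e / (e + E50), so an unexpressed
#' candidate has probability 0 regardless of predicted binding. The
#' combined ligand probability is the maximum of the two class
#' probabilities: either ligand class makes the candidate presentable.
#'
#' @param sequence Neoepitope amino-acid sequence.
#' @param alleles List with elements `mhc1` and `mhc2`, character vectors of
#'   allele names (either may be empty).
#' @param predictor A predictor object (see [predict_ranks()]).
#' @param expression_rpkm Non-negative expression value in RPKM.
#' @param params Scoring parameters from [scoring_params()].
#' @return List with `mhc1_p`, `mhc2_p`, `mhc_p`, and per class the best
#'   ligand (`best_ligand1`, `best_ligand2`), its rank (`best_rank1`,
#'   `best_rank2`), offset and allele.
#' @export
mhc_ligand_probability <- function(sequence, alleles, predictor,
                                   expression_rpkm,
                                   params = scoring_params()) {
  stopifnot(expression_rpkm >= 0)
  o1 <- enumerate_oligomers(sequence, 8:11)
  o2 <- enumerate_oligomers(sequence, 15)
  b1 <- .best_over_alleles(o1, alleles$mhc1, predictor)
  b2 <- .best_over_alleles(o2, alleles$mhc2, predictor)
  expr_f <- expression_rpkm / (expression_rpkm + params$expression_e50)
  cal <- function(r) {
    if (!is.finite(r)) return(0)
    1 / (1 + exp(params$rank_slope * (r - params$rank_midpoint)))
  }
  mhc1_p <- cal(b1$rank) * expr_f
  mhc2_p <- cal(b2$rank) * expr_f
  list(mhc1_p = mhc1_p, mhc2_p = mhc2_p, mhc_p = max(mhc1_p, mhc2_p),
       best_ligand1 = b1$oligomer, best_rank1 = b1$rank,
       best_offset1 = b1$offset, best_allele1 = b1$allele,
       best_ligand2 = b2$oligomer, best_rank2 = b2$rank,
       best_offset2 = b2$offset, best_allele2 = b2$allele)
}

#' Best-rank representative 15mer
#'
#' Scores all overlapping 15mers of a neoepitope against one MHC-II allele
#' and returns the 15mer with the minimal (best) %rank, which represents
#' the neoepitope in rank-based prioritization. Ties break leftmost.
#'
#' @param sequence Neoepitope sequence (length >= 15).
#' @param allele MHC-II allele name.
#' @param predictor A predictor object.
#' @return List with `peptide`, `offset` (1-based) and `rank`.
#' @export
best_rank_15mer <- function(sequence, allele, predictor) {
  if (nchar(sequence) < 15) {
    stop("sequence shorter than 15 residues: ", nchar(sequence))
  }
  o <- enumerate_oligomers(sequence, 15)
  r <- predict_ranks(predictor, o$oligomer, allele)
  i <- which.min(r)
  list(peptide = o$oligomer[i], offset = o$offset[i], rank = r[i])
}

#' Physicochemical property distance between peptide pair
#'
#' Summed Euclidean distance between the property vectors of aligned
#' residue pairs of the mutant and wild-type peptide. For a single
#' substitution this reduces to the distance between the two exchanged
#' residues; identical sequences score 0.
#'
#' @param neo_seq Mutant peptide.
#' @param wt_seq Wild-type peptide of equal length.
#' @param table 20 x 5 property matrix with canonical-AA rownames.
#' @return Non-negative distance.
#' @export
property_distance <- function(neo_seq, wt_seq,
                              table = atchley_factors()) {
  if (nchar(neo_seq) != nchar(wt_seq)) {
    stop("peptides differ in length: ", nchar(neo_seq), " vs ",
         nchar(wt_seq))
  }
  a <- strsplit(neo_seq, "")[[1]]
  b <- strsplit(wt_seq, "")[[1]]
  .assert_canonical_aa(neo_seq, "neoepitope")
  .assert_canonical_aa(wt_seq, "wild-type peptide")
  d <- table[a, , drop = FALSE] - table[b, , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

#' Immunogenicity probability from property distance
#'
#' Maps the non-negative property distance d to a probability with a
#' saturating exponential I = 1 - exp(-d / tau): chemically conservative
#' substitutions (small d) score near 0, drastic ones approach 1, and I is
#' strictly increasing in d.
#'
#' @param d Non-negative property distance.
#' @param tau Distance scale (default 2).
#' @return Immunogenicity probability in \[0, 1). Vectorized over `d`.
#' @export
immunogenicity_probability <- function(d, tau = 2) {
  stopifnot(all(d >= 0), tau > 0)
  1 - exp(-d / tau)
}

#' Composite prioritization score
#'
#' The product of the somatic, clonal, MHC ligand and immunogenicity
#' probabilities; candidates are ranked descending on it.
#'
#' @param somatic_p,clonal_p,mhc_p,immunogenicity_p Factors in \[0, 1\].
#' @return Composite score in \[0, 1\]. Vectorized.
#' @export
composite_score <- function(somatic_p, clonal_p, mhc_p, immunogenicity_p) {
  for (x in list(somatic_p, clonal_p, mhc_p, immunogenicity_p)) {
    if (any(x < 0 | x > 1)) stop("all score factors must lie in [0, 1]")
  }
  somatic_p * clonal_p * mhc_p * immunogenicity_p
}

#' Score neoepitope candidates with the four-factor model
#'
#' Computes, for every retained candidate, the somatic consensus
#' probability, the clonal probability from the purity-corrected VAF, the
#' expression-calibrated MHC ligand probability (both classes), the
#' physicochemical property distance and immunogenicity probability, and
#' the composite product score.
#'
#' @param candidates Candidate table from [extract_candidates()] (retained
#'   rows are scored; discarded rows are dropped).
#' @param purity Tumor purity in (0, 1].
#' @param alleles List with `mhc1` and `mhc2` allele name vectors.
#' @param predictor A predictor object.
#' @param params Scoring parameters from [scoring_params()].
#' @return The candidate table augmented with score columns
#'   (`somatic_p`, `ccf`, `clonal_p`, `mhc1_p`, `mhc2_p`, `mhc_p`,
#'   `best_ligand1`, `best_rank1`, `best_ligand2`, `best_rank2`,
#'   `property_d`, `immunogenicity_p`, `composite`).
#' @export
score_candidates <- function(candidates, purity, alleles, predictor,
                             params = scoring_params()) {
  cand <- candidates[candidates$retained, , drop = FALSE]
  n <- nrow(cand)
  num <- function() numeric(n)
  cand$somatic_p <- num(); cand$ccf <- num(); cand$clonal_p <- num()
  cand$mhc1_p <- num(); cand$mhc2_p <- num(); cand$mhc_p <- num()
  cand$best_ligand1 <- character(n); cand$best_rank1 <- num()
  cand$best_ligand2 <- character(n); cand$best_rank2 <- num()
  cand$property_d <- num(); cand$immunogenicity_p <- num()
  for (i in seq_len(n)) {
    cand$somatic_p[i] <- somatic_probability(cand$callers[[i]],
                                             params$caller_weights)
    cand$ccf[i] <- corrected_vaf(cand$vaf[i], purity)
    cand$clonal_p[i] <- clonal_probability(cand$ccf[i], cand$somatic_p[i])
    m <- mhc_ligand_probability(cand$sequence[i], alleles, predictor,
                                cand$expression_rpkm[i], params)
    cand$mhc1_p[i] <- m$mhc1_p; cand$mhc2_p[i] <- m$mhc2_p
    cand$mhc_p[i] <- m$mhc_p
    cand$best_ligand1[i] <- m$best_ligand1
    cand$best_rank1[i] <- m$best_rank1
    cand$best_ligand2[i] <- m$best_ligand2
    cand$best_rank2[i] <- m$best_rank2
    cand$property_d[i] <- property_distance(cand$sequence[i],
                                            cand$wt_sequence[i],
                                            params$property_table)
    cand$immunogenicity_p[i] <-
      immunogenicity_probability(cand$property_d[i],
                                 params$immunogenicity_tau)
  }
  cand$composite <- composite_score(cand$somatic_p, cand$clonal_p,
                                    cand$mhc_p, cand$immunogenicity_p)
  cand
}
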