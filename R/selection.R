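#' Panel selection configuration
#'
#' @param mode `"ct26"` (rank-by-best-MHC-II-%rank with a strict expression
#'   cutoff) or `"b16f10"` (rank by the composite four-factor score with
#'   exclusion rules).
#' @param panel_size Number of neoepitopes to select (default 5 in ct26
#'   mode, 13 in b16f10 mode).
#' @param expression_cutoff_rpkm Strict lower RPKM bound for ct26-mode
#'   eligibility (default 20; a candidate at exactly the cutoff is
#'   excluded).
#' @param ligand_threshold_mhc1 Best class-I %rank at or below which a
#'   candidate is called to contain a predicted MHC-I ligand (default 0.5,
#'   the conventional strong-binder cutoff).
#' @param ligand_threshold_mhc2 As above for class II (default 2.0, the
#'   conventional binder cutoff).
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(mode = c("b16f10", "ct26"), panel_size = NULL,
                             expression_cutoff_rpkm = 20,
                             ligand_threshold_mhc1 = 0.5,
                             ligand_threshold_mhc2 = 2.0) {
  mode <- match.arg(mode)
  if (is.null(panel_size)) panel_size <- if (mode == "ct26") 5L else 13L
  stopifnot(panel_size >= 1)
  structure(list(mode = mode, panel_size = as.integer(panel_size),
                 expression_cutoff_rpkm = expression_cutoff_rpkm,
                 ligand_threshold_mhc1 = ligand_threshold_mhc1,
                 ligand_threshold_mhc2 = ligand_threshold_mhc2),
            class = "selection_config")
}

#' Rank candidates by best MHC-II %rank (ct26 mode)
#'
#' Retains candidates with expression strictly above the RPKM cutoff, scores
#' the representative best 15mer per candidate against the class-II allele,
#' and sorts ascending by that %rank (best binder first). Ties break by
#' candidate id for a fully deterministic order.
#'
#' @param candidates Candidate table with `sequence` and `expression_rpkm`.
#' @param predictor A predictor object.
#' @param allele MHC-II allele name.
#' @param config A [selection_config()] (uses the expression cutoff).
#' @return The eligible candidates, ordered, with columns `best15`,
#'   `best15_offset` and `best15_rank` added.
#' @export
rank_ct26 <- function(candidates, predictor, allele,
                      config = selection_config("ct26")) {
  elig <- candidates[candidates$expression_rpkm >
                       config$expression_cutoff_rpkm, , drop = FALSE]
  n <- nrow(elig)
  elig$best15 <- character(n)
  elig$best15_offset <- integer(n)
  elig$best15_rank <- numeric(n)
  for (i in seq_len(n)) {
    b <- best_rank_15mer(elig$sequence[i], allele, predictor)
    elig$best15[i] <- b$peptide
    elig$best15_offset[i] <- b$offset
    elig$best15_rank[i] <- b$rank
  }
  elig[order(elig$best15_rank, elig$id), , drop = FALSE]
}

#' Rank candidates by composite score (b16f10 mode)
#'
#' Sorts descending by the composite four-factor score; ties break by
#' candidate id.
#'
#' @param scored Scored candidate table from [score_candidates()].
#' @return The table in prioritized order.
#' @export
rank_b16f10 <- function(scored) {
  scored[order(-scored$composite, scored$id), , drop = FALSE]
}

#' Select the vaccine panel with exclusion rules
#'
#' Walks the prioritized list from the top, selecting candidates until the
#' panel is full, skipping any candidate that violates one of four
#' exclusion criteria: (1) the candidate is not expressed (RPKM <= 0);
#' (2) it contains neither a predicted MHC-I nor a predicted MHC-II ligand
#' (best %rank above both class thresholds); (3) it arises from the same
#' mutation as an already-selected candidate; (4) both its best class-I and
#' best class-II ligands are sequence-identical to those of an
#' already-selected candidate. Every examined candidate is either selected
#' or annotated with its first failing criterion (exhaustive audit).
#'
#' @param ranked Prioritized candidate table carrying `expression_rpkm`,
#'   `mutation_id`, `best_ligand1`, `best_rank1`, `best_ligand2`,
#'   `best_rank2`.
#' @param config A [selection_config()].
#' @return List with `panel` (selected rows, in rank order) and `audit`
#'   (data.frame: `id`, `rank_position`, `decision`, `criterion` with NA for
#'   selected, `reason`).
#' @export
select_panel <- function(ranked, config = selection_config()) {
  n <- nrow(ranked)
  decision <- character(n); criterion <- rep(NA_integer_, n)
  reason <- rep(NA_character_, n)
  sel <- integer(0)
  sel_mut <- character(0)
  sel_lig <- character(0)  # paired best-ligand keys of selected candidates
  reasons <- c("not expressed",
               "no predicted MHC-I or MHC-II ligand",
               "same mutation as a previously selected neoepitope",
               "best MHC-I and MHC-II ligands match a previous selection")
  for (i in seq_len(n)) {
    if (length(sel) >= config$panel_size) {
      decision[i] <- "not examined"
      next
    }
    has_l1 <- is.finite(ranked$best_rank1[i]) &&
      ranked$best_rank1[i] <= config$ligand_threshold_mhc1
    has_l2 <- is.finite(ranked$best_rank2[i]) &&
      ranked$best_rank2[i] <= config$ligand_threshold_mhc2
    lig_key <- paste(ranked$best_ligand1[i], ranked$best_ligand2[i],
                     sep = "::")
    fail <- if (ranked$expression_rpkm[i] <= 0) 1L
      else if (!has_l1 && !has_l2) 2L
      else if (ranked$mutation_id[i] %in% sel_mut) 3L
      else if (lig_key %in% sel_lig) 4L
      else NA_integer_
    if (is.na(fail)) {
      decision[i] <- "selected"
      sel <- c(sel, i)
      sel_mut <- c(sel_mut, ranked$mutation_id[i])
      sel_lig <- c(sel_lig, lig_key)
    } else {
      decision[i] <- "excluded"
      criterion[i] <- fail
      reason[i] <- reasons[fail]
    }
  }
  audit <- data.frame(id = ranked$id, rank_position = seq_len(n),
                      decision = decision, criterion = criterion,
                      reason = reason, stringsAsFactors = FALSE)
  list(panel = ranked[sel, , drop = FALSE], audit = audit)
}

#' Write a selection result as a JSON audit report
#'
#' @param selection Result of [select_panel()].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_selection_report <- function(selection, path) {
  panel_cols <- intersect(c("id", "mutation_id", "sequence",
                            "expression_rpkm", "composite", "best15_rank"),
                          names(selection$panel))
  jsonlite::write_json(
    list(panel = selection$panel[, panel_cols, drop = FALSE],
         audit = selection$audit),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
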