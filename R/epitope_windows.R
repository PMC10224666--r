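#' Build a tumor-specific protein sequence
#'
#' Applies germline missense substitutions to the reference protein first,
#' then the somatic substitution, yielding the tumor-specific sequence the
#' neoepitope window is cut from. Proteins carrying any germline frameshift
#' or splice-class variant are rejected (their protein-level consequence is
#' not representable as a substitution), as are somatic variants whose
#' annotated wild-type residue does not match the (germline-applied)
#' protein.
#'
#' @param protein_seq Reference protein sequence (character scalar).
#' @param germline_variants Data.frame of germline variants on this protein
#'   (may have zero rows).
#' @param somatic_variant Single-row data.frame (or list) with the somatic
#'   variant: `pos`, `ref_aa`, `alt_aa`.
#' @return A list with `status` ("ok", "rejected" or "discarded"), `reason`
#'   (NA when ok), `tumor_seq` (germline+somatic applied) and `germline_seq`
#'   (germline-only, the wild-type counterpart the WT window is cut from).
#' @export
build_tumor_protein <- function(protein_seq, germline_variants,
                                somatic_variant) {
  L <- nchar(protein_seq)
  if (nrow(germline_variants) > 0 &&
      any(germline_variants$class %in% c("frameshift", "splice"))) {
    return(list(status = "rejected", reason = "germline frameshift/splice",
                tumor_seq = NA_character_, germline_seq = NA_character_))
  }
  germ <- protein_seq
  if (nrow(germline_variants) > 0) {
    for (i in seq_len(nrow(germline_variants))) {
      p <- germline_variants$pos[i]
      if (p > L) stop("germline variant position ", p,
                      " beyond protein length ", L)
      substr(germ, p, p) <- germline_variants$alt_aa[i]
    }
  }
  p <- somatic_variant$pos
  if (p > L) stop("somatic variant position ", p,
                  " beyond protein length ", L)
  if (substr(germ, p, p) != somatic_variant$ref_aa) {
    return(list(status = "discarded", reason = "wildtype mismatch",
                tumor_seq = NA_character_, germline_seq = germ))
  }
  tumor <- germ
  substr(tumor, p, p) <- somatic_variant$alt_aa
  list(status = "ok", reason = NA_character_,
       tumor_seq = tumor, germline_seq = germ)
}

#' Check the annotated wild-type residue against a protein
#'
#' A variant whose annotated reference amino acid is not found at the
#' annotated position is discarded (annotation/sequence mismatch), never
#' silently corrected.
#'
#' @param protein_seq Protein sequence.
#' @param variant List or single-row data.frame with `pos` and `ref_aa`.
#' @return A list with `pass` (logical) and `reason` (NA or
#'   "wildtype mismatch").
#' @export
check_wildtype <- function(protein_seq, variant) {
  p <- variant$pos
  if (p < 1 || p > nchar(protein_seq)) {
    stop("variant position ", p, " outside protein of length ",
         nchar(protein_seq))
  }
  if (substr(protein_seq, p, p) == variant$ref_aa) {
    list(pass = TRUE, reason = NA_character_)
  } else {
    list(pass = FALSE, reason = "wildtype mismatch")
  }
}

#' Extract the neoepitope window around a mutated residue
#'
#' Cuts the long extraction window: 14 residues of flank on each side of the
#' mutated position (a 29mer when both flanks are complete), clipped at the
#' protein ends. Windows shorter than 15 residues after clipping are
#' discarded.
#'
#' @param tumor_seq Tumor-specific protein sequence.
#' @param pos 1-based position of the mutated residue.
#' @return List with `window` (sequence), `mutant_index` (1-based position
#'   of the mutated residue within the window), `start`, `end` (1-based
#'   coordinates on the protein) and `retained` (FALSE when length < 15).
#' @export
extract_window <- function(tumor_seq, pos) {
  L <- nchar(tumor_seq)
  if (pos < 1 || pos > L) stop("pos ", pos, " outside protein of length ", L)
  start <- max(1L, pos - 14L)
  end <- min(L, pos + 14L)
  window <- substr(tumor_seq, start, end)
  list(window = window, mutant_index = pos - start + 1L,
       start = start, end = end, retained = nchar(window) >= 15L)
}

#' Truncate a full extraction window to the final neoepitope
#'
#' Full 29mer windows lose one residue from each terminus, giving the final
#' 27mer with the mutated residue at position 14. Windows already clipped by
#' a protein end (< 29 residues) pass through unchanged.
#'
#' @param window Window sequence from [extract_window()].
#' @param mutant_index 1-based mutated-residue index within `window`.
#' @return List with `sequence` and `mutant_index` after truncation.
#' @export
truncate_to_final <- function(window, mutant_index) {
  n <- nchar(window)
  if (n == 29L) {
    list(sequence = substr(window, 2L, 28L), mutant_index = mutant_index - 1L)
  } else {
    list(sequence = window, mutant_index = mutant_index)
  }
}

#' Enumerate overlapping oligomers
#'
#' All overlapping subsequences of the requested sizes, left to right. A
#' size exceeding the sequence length contributes no oligomers (not an
#' error), so class-specific size sets can be applied uniformly to short
#' candidates.
#'
#' @param sequence Amino-acid sequence.
#' @param sizes Integer vector of oligomer lengths.
#' @return Data.frame with columns `offset` (1-based), `size`, `oligomer`.
#' @export
enumerate_oligomers <- function(sequence, sizes) {
  L <- nchar(sequence)
  out <- lapply(sizes, function(k) {
    if (k > L) return(NULL)
    offs <- seq_len(L - k + 1L)
    data.frame(offset = offs, size = k,
               oligomer = substring(sequence, offs, offs + k - 1L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(offset = integer(0), size = integer(0),
                      oligomer = character(0), stringsAsFactors = FALSE)
  }
  out
}

#' Locate a minimal epitope within a neoepitope sequence
#'
#' Leftmost exact-substring search, used to map an experimentally defined
#' minimal epitope (e.g. an MHC-I 8-11mer) back onto the long neoepitope it
#' derives from.
#'
#' @param neoepitope Long neoepitope sequence.
#' @param minimal Minimal epitope sequence.
#' @return 1-based offset of the leftmost match, or `NA_integer_` if absent.
#' @export
locate_minimal_epitope <- function(neoepitope, minimal) {
  m <- regexpr(minimal, neoepitope, fixed = TRUE)
  if (m[1] == -1L) NA_integer_ else as.integer(m[1])
}

#' Extract neoepitope candidates from a proteome and variant table
#'
#' The full extraction stage: for every somatic variant, builds the
#' tumor-specific protein (germline missense applied first), validates the
#' annotated wild-type residue, cuts the extraction window with clipping and
#' the 15-residue discard rule, applies terminal truncation, and cuts the
#' matched wild-type window from the germline-applied protein at identical
#' coordinates. Somatic frameshift/splice variants are not representable as
#' substitutions and are recorded as discarded. Every somatic variant
#' yields exactly one row, retained or discarded with a reason (exhaustive
#' audit).
#'
#' @param proteome Data.frame from [read_fasta()] (`id`, `sequence`).
#' @param variants Data.frame from [read_variants()] (somatic and germline
#'   rows together).
#' @param expression Optional data.frame from [read_expression()]; RPKM is
#'   joined by protein id (absent ids get 0).
#' @return Data.frame of candidates: `id`, `protein_id`, `mutation_id`,
#'   `pos`, `ref_aa`, `alt_aa`, `sequence`, `wt_sequence`, `mutant_index`,
#'   `vaf`, `n_callers`, `expression_rpkm`, `retained`, `reason`; `callers`
#'   as a list-column.
#' @export
extract_candidates <- function(proteome, variants, expression = NULL) {
  seqs <- stats::setNames(proteome$sequence, proteome$id)
  rpkm <- if (is.null(expression)) NULL else
    stats::setNames(expression$rpkm, expression$id)
  som <- variants[variants$origin == "somatic", , drop = FALSE]
  germ <- variants[variants$origin == "germline", , drop = FALSE]
  rows <- vector("list", nrow(som))
  for (i in seq_len(nrow(som))) {
    v <- som[i, ]
    expr <- if (is.null(rpkm)) NA_real_ else
      unname(ifelse(is.na(rpkm[v$protein_id]), 0, rpkm[v$protein_id]))
    base <- data.frame(
      id = sprintf("%s_%d_%s%s", v$protein_id, v$pos, v$ref_aa, v$alt_aa),
      protein_id = v$protein_id,
      mutation_id = sprintf("%s:%d:%s>%s", v$protein_id, v$pos,
                            v$ref_aa, v$alt_aa),
      pos = v$pos, ref_aa = v$ref_aa, alt_aa = v$alt_aa,
      sequence = NA_character_, wt_sequence = NA_character_,
      mutant_index = NA_integer_, vaf = v$vaf, n_callers = v$n_callers,
      expression_rpkm = expr, retained = FALSE, reason = NA_character_,
      stringsAsFactors = FALSE)
    base$callers <- v$callers  # list-column carried through
    if (!v$protein_id %in% names(seqs)) {
      base$reason <- "unknown protein"
      rows[[i]] <- base
      next
    }
    if (v$class != "missense") {
      base$reason <- "somatic frameshift/splice"
      rows[[i]] <- base
      next
    }
    g <- germ[germ$protein_id == v$protein_id, , drop = FALSE]
    built <- build_tumor_protein(seqs[[v$protein_id]], g, v)
    if (built$status != "ok") {
      base$reason <- built$reason
      rows[[i]] <- base
      next
    }
    win <- extract_window(built$tumor_seq, v$pos)
    if (!win$retained) {
      base$reason <- "window shorter than 15"
      rows[[i]] <- base
      next
    }
    fin <- truncate_to_final(win$window, win$mutant_index)
    wt_win <- substr(built$germline_seq, win$start, win$end)
    wt_fin <- truncate_to_final(wt_win, win$mutant_index)
    base$sequence <- fin$sequence
    base$wt_sequence <- wt_fin$sequence
    base$mutant_index <- fin$mutant_index
    base$retained <- TRUE
    rows[[i]] <- base
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(id = character(0))
  }
  rownames(out) <- NULL
  out
}
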