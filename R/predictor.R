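#' Predictor adapter contract
#'
#' A predictor is any object for which [predict_ranks()] returns one finite,
#' non-negative percentile-rank-like score per peptide for a given MHC
#' allele, with the convention that LOWER means a stronger predicted ligand
#' (the "%rank" convention of the NetMHC family). Predictors must be
#' deterministic for fixed inputs. The package ships a deterministic mock
#' predictor for testing ([mock_predictor()]), a lookup-table predictor used
#' by the planted-recovery scenario ([table_predictor()]), and a thin
#' adapter over an external NetMHC-family command-line tool
#' ([netmhc_predictor()]).
#'
#' @param predictor A predictor object.
#' @param peptides Character vector of peptides.
#' @param allele Allele name (single string).
#' @return Numeric vector of scores, one per peptide; lower = stronger.
#' @export
predict_ranks <- function(predictor, peptides, allele) {
  UseMethod("predict_ranks")
}

#' @export
predict_ranks.function <- function(predictor, peptides, allele) {
  out <- predictor(peptides, allele)
  .validate_ranks(out, peptides)
}

.validate_ranks <- function(out, peptides) {
  if (length(out) != length(peptides) || any(!is.finite(out)) || any(out < 0)) {
    stop("predictor returned invalid scores (need one finite non-negative ",
         "value per peptide)")
  }
  as.numeric(out)
}

# Deterministic polynomial rolling hash of a string, in [0, 1).
.hash01 <- function(strings) {
  vapply(strings, function(s) {
    h <- 0
    for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 2147483647
    h / 2147483647
  }, numeric(1), USE.NAMES = FALSE)
}

#' Deterministic mock MHC predictor
#'
#' Maps each (peptide, allele) pair to a reproducible pseudo-random %rank in
#' (0, `max_rank`] via a string hash. No biology is modelled; the mock
#' exists so every pipeline stage that consumes predictor output can be
#' tested deterministically without an external neural predictor.
#'
#' @param max_rank Upper bound of emitted ranks (default 100, mimicking a
#'   percentile rank).
#' @return A predictor object.
#' @export
mock_predictor <- function(max_rank = 100) {
  structure(list(max_rank = max_rank), class = c("mock_predictor", "predictor"))
}

#' @export
predict_ranks.mock_predictor <- function(predictor, peptides, allele) {
  h <- .hash01(paste(peptides, allele, sep = "|"))
  .validate_ranks(h * predictor$max_rank, peptides)
}

#' Lookup-table MHC predictor
#'
#' Returns a configured rank for listed peptides and a default rank for all
#' others; allele-agnostic unless keys are given as `"peptide|allele"`.
#' Used by the planted-recovery scenario to make chosen peptides strong
#' predicted ligands by construction.
#'
#' @param ranks Named numeric vector: names are peptides (or
#'   `"peptide|allele"` keys), values are %rank scores.
#' @param default Rank for peptides not in the table (default 50).
#' @return A predictor object.
#' @export
table_predictor <- function(ranks, default = 50) {
  stopifnot(length(ranks) == 0 || !is.null(names(ranks)),
            all(is.finite(ranks)), all(ranks >= 0))
  structure(list(ranks = ranks, default = default),
            class = c("table_predictor", "predictor"))
}

#' @export
predict_ranks.table_predictor <- function(predictor, peptides, allele) {
  keyed <- paste(peptides, allele, sep = "|")
  out <- predictor$ranks[keyed]
  miss <- is.na(out)
  out[miss] <- predictor$ranks[peptides[miss]]
  out[is.na(out)] <- predictor$default
  .validate_ranks(unname(out), peptides)
}

#' External NetMHC-family command-line adapter
#'
#' Thin adapter around a NetMHC-family tool (e.g. NetMHCpan/NetMHCIIpan):
#' writes the peptides to a temporary file, invokes the tool with its
#' peptide-input flags, and extracts the %rank column from the tabular
#' output by header name. Requires the external binary on the PATH; the
#' test-suite uses the built-in mock instead.
#'
#' @param command Name or path of the external binary.
#' @param rank_column Header name of the %rank column (default "%Rank").
#' @param extra_args Additional command-line arguments.
#' @return A predictor object.
#' @export
netmhc_predictor <- function(command, rank_column = "%Rank",
                             extra_args = character(0)) {
  structure(list(command = command, rank_column = rank_column,
                 extra_args = extra_args),
            class = c("netmhc_predictor", "predictor"))
}

#' @export
predict_ranks.netmhc_predictor <- function(predictor, peptides, allele) {
  if (Sys.which(predictor$command) == "") {
    stop("external predictor binary not found: ", predictor$command)
  }
  pepfile <- tempfile(fileext = ".pep")
  on.exit(unlink(pepfile), add = TRUE)
  writeLines(peptides, pepfile)
  out <- suppressWarnings(system2(
    predictor$command,
    c("-p", shQuote(pepfile), "-a", shQuote(allele), predictor$extra_args),
    stdout = TRUE))
  .parse_netmhc_output(out, peptides, predictor$rank_column)
}

# Parses whitespace-delimited NetMHC-family stdout: finds the header line
# containing both "Peptide" and the rank column, then reads rank by column
# index from each data line.
.parse_netmhc_output <- function(lines, peptides, rank_column) {
  header_i <- grep("Peptide", lines)
  header_i <- header_i[grepl(rank_column, lines[header_i], fixed = TRUE)][1]
  if (is.na(header_i)) stop("could not locate predictor output header")
  header <- strsplit(trimws(lines[header_i]), "\\s+")[[1]]
  pep_col <- which(header == "Peptide")[1]
  rank_col <- which(header == rank_column)[1]
  ranks <- stats::setNames(rep(NA_real_, length(peptides)), peptides)
  for (ln in lines[-seq_len(header_i)]) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) >= max(pep_col, rank_col) && f[pep_col] %in% peptides) {
      val <- suppressWarnings(as.numeric(f[rank_col]))
      if (!is.na(val)) ranks[f[pep_col]] <- val
    }
  }
  if (any(is.na(ranks))) {
    stop("predictor output missing peptide(s): ",
         paste(utils::head(names(ranks)[is.na(ranks)], 3), collapse = ", "))
  }
  .validate_ranks(unname(ranks), peptides)
}
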