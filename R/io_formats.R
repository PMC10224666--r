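#' Default somatic-caller set
#'
#' Names of the four somatic variant callers whose per-variant support flags
#' the pipeline consumes. Caller names in variant tables are validated
#' against this set (or a user-supplied replacement).
#'
#' @return Character vector of caller names.
#' @export
default_callers <- function() {
  c("lofreq", "mutect2", "strelka", "snvsniffer")
}

#' Read protein sequences from FASTA
#'
#' Sequences are uppercased and a single terminal stop character (`*`) is
#' stripped. Any other non-canonical letter is an error naming the record.
#'
#' @param path Path to a protein FASTA file.
#' @return A data.frame with columns `id` and `sequence`, one row per record,
#'   in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)
  for (i in seq_along(seqs)) {
    if (is.na(ids[i]) || ids[i] == "") {
      stop("FASTA record ", i, " has an empty header")
    }
    if (nchar(seqs[i]) == 0) {
      stop("FASTA record '", ids[i], "' has an empty sequence")
    }
    bad <- setdiff(strsplit(seqs[i], "")[[1]], aa_alphabet())
    if (length(bad) > 0) {
      stop("FASTA record '", ids[i], "' contains non-canonical letters: ",
           paste(unique(bad), collapse = ", "))
    }
  }
  data.frame(id = unname(ids), sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param ids Character vector of record identifiers.
#' @param sequences Character vector of sequences (protein or DNA).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(ids, sequences, path) {
  stopifnot(length(ids) == length(sequences))
  set <- Biostrings::BStringSet(sequences)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

.variant_classes <- c("missense", "frameshift", "splice")
.variant_origins <- c("somatic", "germline")

#' Read a protein-level variant table
#'
#' The pipeline consumes variants at protein level in a minimal
#' tab-separated dialect with header columns `protein_id`, `pos` (1-based
#' amino-acid position), `ref_aa`, `alt_aa`, `class` (missense, frameshift
#' or splice), `origin` (somatic or germline), `vaf` (in \[0,1\]) and
#' `callers` (semicolon-joined subset of the configured caller names; may be
#' empty). Parsing is total: every row either yields a validated record or a
#' row-level error citing the file line.
#'
#' @param path Path to the tab-separated variant table.
#' @param callers Allowed caller names; defaults to [default_callers()].
#' @return A data.frame with the columns above, `callers` as a list-column of
#'   character vectors, plus `n_callers`.
#' @export
read_variants <- function(path, callers = default_callers()) {
  if (!file.exists(path)) stop("variant table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("protein_id", "pos", "ref_aa", "alt_aa", "class",
                "origin", "vaf", "callers")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("variant table missing columns: ", paste(missing, collapse = ", "))
  }
  n <- nrow(df)
  pos <- suppressWarnings(as.integer(df$pos))
  vaf <- suppressWarnings(as.numeric(df$vaf))
  caller_list <- vector("list", n)
  for (i in seq_len(n)) {
    line <- i + 1L  # header occupies line 1
    if (is.na(pos[i]) || pos[i] < 1) {
      stop("variant table line ", line, ": pos must be an integer >= 1, got '",
           df$pos[i], "'")
    }
    if (is.na(vaf[i]) || vaf[i] < 0 || vaf[i] > 1) {
      stop("variant table line ", line, ": vaf must lie in [0,1], got '",
           df$vaf[i], "'")
    }
    if (!df$class[i] %in% .variant_classes) {
      stop("variant table line ", line, ": unknown class '", df$class[i], "'")
    }
    if (!df$origin[i] %in% .variant_origins) {
      stop("variant table line ", line, ": unknown origin '", df$origin[i], "'")
    }
    if (df$class[i] == "missense" && df$ref_aa[i] == df$alt_aa[i]) {
      stop("variant table line ", line, ": missense ref_aa equals alt_aa ('",
           df$ref_aa[i], "')")
    }
    cl <- if (is.na(df$callers[i]) || df$callers[i] == "") character(0) else
      strsplit(df$callers[i], ";", fixed = TRUE)[[1]]
    unknown <- setdiff(cl, callers)
    if (length(unknown) > 0) {
      stop("variant table line ", line, ": unknown caller name(s): ",
           paste(unknown, collapse = ", "))
    }
    caller_list[[i]] <- cl
  }
  out <- data.frame(protein_id = df$protein_id, pos = pos,
                    ref_aa = df$ref_aa, alt_aa = df$alt_aa,
                    class = df$class, origin = df$origin, vaf = vaf,
                    stringsAsFactors = FALSE)
  out$callers <- caller_list
  out$n_callers <- vapply(caller_list, length, integer(1))
  out
}

#' Write a variant table in the package dialect
#'
#' @param variants Data.frame as returned by [read_variants()] or the
#'   synthetic generators (list-column `callers`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_variants <- function(variants, path) {
  out <- variants[, c("protein_id", "pos", "ref_aa", "alt_aa",
                      "class", "origin", "vaf")]
  out$callers <- vapply(variants$callers, paste, character(1), collapse = ";")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a transcript expression table
#'
#' Tab-separated with columns `id`, `rpkm` and (optionally) `rna_vaf`.
#'
#' @param path Path to the table.
#' @return Data.frame with columns `id`, `rpkm`, `rna_vaf`.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "rpkm") %in% names(df))) {
    stop("expression table must have columns 'id' and 'rpkm'")
  }
  if (is.null(df$rna_vaf)) df$rna_vaf <- NA_real_
  if (any(is.na(df$rpkm)) || any(df$rpkm < 0)) {
    stop("expression table: rpkm must be non-negative and complete")
  }
  df[, c("id", "rpkm", "rna_vaf")]
}

#' Write an expression table
#' @param expression Data.frame with columns `id`, `rpkm`, `rna_vaf`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(expression, path) {
  utils::write.table(expression, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a codon-usage table
#'
#' Expects a tab-separated file with columns `codon` (DNA alphabet, length 3)
#' and `frequency` (non-negative, any consistent scale such as counts or
#' per-thousand). All 61 sense codons must be present. Two derived
#' quantities are attached: per-amino-acid normalized sampling weights
#' (summing to 1 within each synonymous family) and the relative
#' adaptiveness w = frequency / max synonymous frequency used by the codon
#' adaptation index, which is 1 for each family's most frequent codon.
#'
#' @param path Path to the table.
#' @return An object of class `codon_usage_table`: data.frame with columns
#'   `codon`, `aa`, `frequency`, `weight`, `w`.
#' @export
read_codon_usage <- function(path) {
  if (!file.exists(path)) stop("codon usage table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("codon", "frequency") %in% names(df))) {
    stop("codon usage table must have columns 'codon' and 'frequency'")
  }
  codon_usage_table(stats::setNames(df$frequency, toupper(df$codon)))
}

#' Build a codon-usage table from a named frequency vector
#'
#' @param frequencies Named numeric vector, names are DNA codons.
#' @return An object of class `codon_usage_table`.
#' @export
codon_usage_table <- function(frequencies) {
  codons <- names(frequencies)
  if (is.null(codons) || any(!grepl("^[ACGT]{3}$", codons))) {
    stop("codon usage: names must be DNA codons of length 3")
  }
  if (anyDuplicated(codons)) stop("codon usage: duplicated codons")
  if (any(is.na(frequencies)) || any(frequencies < 0)) {
    stop("codon usage: frequencies must be non-negative")
  }
  gc <- genetic_code()
  sense <- names(gc)[gc != "*"]
  missing <- setdiff(sense, codons)
  if (length(missing) > 0) {
    stop("codon usage: missing sense codon(s): ",
         paste(missing, collapse = ", "))
  }
  df <- data.frame(codon = sense, aa = unname(gc[sense]),
                   frequency = unname(frequencies[sense]),
                   stringsAsFactors = FALSE)
  fam_sum <- tapply(df$frequency, df$aa, sum)
  fam_max <- tapply(df$frequency, df$aa, max)
  if (any(fam_max == 0)) {
    stop("codon usage: amino acid(s) with all-zero frequencies: ",
         paste(names(fam_max)[fam_max == 0], collapse = ", "))
  }
  # Zero-frequency families cannot happen past the check above; a uniform
  # fallback within a family is only needed if every codon had frequency 0.
  df$weight <- as.numeric(df$frequency / fam_sum[df$aa])
  df$w <- as.numeric(df$frequency / fam_max[df$aa])
  class(df) <- c("codon_usage_table", "data.frame")
  df
}

#' Representative mouse codon-usage table
#'
#' A representative mammalian (mouse-like) codon-usage table shipped with
#' the package, on a frequency-per-thousand scale. Used as the default for
#' reverse translation and CAI; replace with [read_codon_usage()] for a
#' different organism.
#'
#' @return An object of class `codon_usage_table`.
#' @export
default_codon_usage <- function() {
  path <- system.file("extdata", "codon_usage_mouse.tsv", package = "neovax")
  read_codon_usage(path)
}

#' @export
print.codon_usage_table <- function(x, ...) {
  cat("Codon usage table: 61 sense codons\n")
  cat("Most frequent codon per family has relative adaptiveness w = 1\n")
  NextMethod()
}

#' Write an optimized construct to FASTA plus a feature table
#'
#' @param construct A `dna_construct` as returned by [design_insert()] or
#'   [assemble_insert()].
#' @param path_fasta Output FASTA path for the insert sequence.
#' @param path_features Output path for the tab-separated feature table
#'   (columns `feature`, `start`, `end`; 1-based inclusive coordinates).
#' @return Invisibly, a list with both paths.
#' @export
write_construct <- function(construct, path_fasta, path_features) {
  stopifnot(inherits(construct, "dna_construct"))
  write_fasta(construct$id, construct$sequence, path_fasta)
  utils::write.table(construct$features[, c("feature", "start", "end")],
                     path_features, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(fasta = path_fasta, features = path_features))
}

#' Read a pipeline configuration file
#'
#' YAML configuration overriding pipeline defaults; unknown keys are an
#' error so typos do not silently fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @param defaults Named list of defaults to merge into.
#' @return Named list of configuration values.
#' @export
read_config <- function(path, defaults = list()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (length(defaults) > 0) {
    unknown <- setdiff(names(cfg), names(defaults))
    if (length(unknown) > 0) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    }
    defaults[names(cfg)] <- cfg
    return(defaults)
  }
  cfg
}
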