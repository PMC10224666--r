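#' Construct-design configuration
#'
#' Parameters of the multi-epitope DNA insert optimization. Defaults mirror
#' the procedure's published constants: a cohort of 10,000 candidate
#' inserts, dynamic CAI/GC thresholding retaining the top 1%, and final
#' selection of the survivor with the highest (least negative) RNA minimum
#' free energy.
#'
#' @param cohort_size Number of candidate constructs to generate.
#' @param survivor_fraction Fraction surviving the dynamic CAI/GC
#'   thresholding stage (default 0.01, i.e. 99% eliminated).
#' @param kozak Kozak consensus placed immediately before the start codon.
#' @param stop_codon Stop codon closing the coding region.
#' @param sites Named character vector of flanking restriction sites; first
#'   is placed 5', second 3'. Internal occurrences are screened as hazards.
#' @param linker_peptide Peptide linker between epitopes (default "GGS").
#' @param n_linker_variants Number of synonymous linker DNA variants drawn
#'   from by the assembler.
#' @param repeat_min_len Minimum exact direct-repeat length flagged as a
#'   hazard (nucleotides).
#' @param gc_window Target GC-content window (fractions) for the dynamic
#'   threshold score.
#' @param gc_penalty Score penalty per unit GC distance outside the window.
#' @param engine RNA folding engine: `"nussinov"` (built-in energy dynamic
#'   program) or `"rnafold"` (external ViennaRNA adapter).
#' @return An object of class `design_config`.
#' @export
design_config <- function(cohort_size = 10000L, survivor_fraction = 0.01,
                          kozak = "GCCACC", stop_codon = "TAA",
                          sites = c(nhei = "GCTAGC", xhoi = "CTCGAG"),
                          linker_peptide = "GGS", n_linker_variants = 4L,
                          repeat_min_len = 12L,
                          gc_window = c(0.40, 0.60), gc_penalty = 5,
                          engine = c("nussinov", "rnafold")) {
  stopifnot(cohort_size >= 1, survivor_fraction > 0, survivor_fraction <= 1,
            length(sites) == 2, repeat_min_len >= 2,
            gc_window[1] <= gc_window[2])
  engine <- match.arg(engine)
  structure(list(cohort_size = as.integer(cohort_size),
                 survivor_fraction = survivor_fraction, kozak = kozak,
                 stop_codon = stop_codon, sites = sites,
                 linker_peptide = linker_peptide,
                 n_linker_variants = as.integer(n_linker_variants),
                 repeat_min_len = as.integer(repeat_min_len),
                 gc_window = gc_window, gc_penalty = gc_penalty,
                 engine = engine),
            class = "design_config")
}

#' Reverse-translate a peptide by weighted codon sampling
#'
#' Each residue independently draws a synonymous codon with probability
#' proportional to its usage frequency, so the cohort explores
#' codon-usage-typical sequence space. Translating the result always
#' reproduces the peptide.
#'
#' @param peptide Amino-acid sequence (canonical letters).
#' @param codon_table A `codon_usage_table`.
#' @return DNA string of length `3 * nchar(peptide)`. Uses the current RNG
#'   stream (seed the caller for reproducibility).
#' @export
reverse_translate <- function(peptide, codon_table = default_codon_usage()) {
  .assert_canonical_aa(peptide, "peptide")
  aas <- strsplit(peptide, "")[[1]]
  out <- character(length(aas))
  for (aa in unique(aas)) {
    idx <- which(aas == aa)
    fam <- codon_table[codon_table$aa == aa, ]
    out[idx] <- if (nrow(fam) == 1) fam$codon else
      sample(fam$codon, length(idx), replace = TRUE, prob = fam$weight)
  }
  paste(out, collapse = "")
}

#' Build a maximally diverse synonymous linker set
#'
#' Enumerates all synonymous DNA encodings of the linker peptide and picks
#' `n_variants` of them by greedy max-min Hamming-distance selection,
#' seeded with the most-frequent-codon encoding. Drawing linkers from a
#' diverse set keeps repeated junctions from creating DNA repeats.
#'
#' @param linker_peptide Linker amino-acid sequence (default "GGS").
#' @param n_variants Number of DNA variants to select.
#' @param codon_table A `codon_usage_table`.
#' @return An object of class `linker_set`: list with `peptide` and
#'   `dna_variants`.
#' @export
build_linker_set <- function(linker_peptide = "GGS", n_variants = 4,
                             codon_table = default_codon_usage()) {
  .assert_canonical_aa(linker_peptide, "linker peptide")
  aas <- strsplit(linker_peptide, "")[[1]]
  fams <- lapply(aas, function(aa) codon_table$codon[codon_table$aa == aa])
  all_enc <- do.call(expand.grid,
                     c(rev(fams), stringsAsFactors = FALSE))[, rev(seq_along(fams)), drop = FALSE]
  all_enc <- apply(all_enc, 1, paste, collapse = "")
  if (n_variants > length(all_enc)) {
    stop("n_variants exceeds the ", length(all_enc),
         " synonymous encodings of '", linker_peptide, "'")
  }
  most_freq <- paste(vapply(aas, function(aa) {
    fam <- codon_table[codon_table$aa == aa, ]
    fam$codon[which.max(fam$frequency)]
  }, character(1)), collapse = "")
  ham <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  chosen <- most_freq
  pool <- setdiff(all_enc, most_freq)
  while (length(chosen) < n_variants) {
    dmin <- vapply(pool, function(p) {
      min(vapply(chosen, ham, numeric(1), a = p))
    }, numeric(1))
    # greedy max-min; ties broken lexicographically for determinism
    best <- pool[dmin == max(dmin)]
    nxt <- sort(best)[1]
    chosen <- c(chosen, nxt)
    pool <- setdiff(pool, nxt)
  }
  structure(list(peptide = linker_peptide, dna_variants = chosen),
            class = "linker_set")
}

#' Assemble a multi-epitope DNA insert
#'
#' Concatenates the epitope-coding segments with linker DNA drawn at random
#' per junction from the linker set, and adds the fixed features:
#' 5' restriction site, Kozak, start codon, stop codon, 3' restriction
#' site. Feature coordinates are recorded 1-based inclusive.
#'
#' @param epitope_dnas Character vector of epitope-coding DNA segments.
#' @param linker_set A [build_linker_set()] result.
#' @param config A [design_config()].
#' @param id Construct identifier.
#' @return An object of class `dna_construct`: list with `id`, `sequence`,
#'   `features` (data.frame), `coding` (start codon through last epitope),
#'   and metric slots (`cai`, `gc`, `mfe`, `hazards`) filled by later
#'   stages. Uses the current RNG stream for linker draws.
#' @export
assemble_insert <- function(epitope_dnas, linker_set,
                            config = design_config(), id = "construct") {
  k <- length(epitope_dnas)
  stopifnot(k >= 1)
  linkers <- if (k > 1) {
    sample(linker_set$dna_variants, k - 1L, replace = TRUE)
  } else character(0)
  feats <- list(); pos <- 1L
  add <- function(name, seqpart) {
    feats[[length(feats) + 1L]] <<- data.frame(
      feature = name, start = pos, end = pos + nchar(seqpart) - 1L,
      stringsAsFactors = FALSE)
    pos <<- pos + nchar(seqpart)
    seqpart
  }
  parts <- character(0)
  parts <- c(parts, add(paste0("site_5p_", names(config$sites)[1]),
                        config$sites[[1]]))
  parts <- c(parts, add("kozak", config$kozak))
  parts <- c(parts, add("start_codon", "ATG"))
  for (i in seq_len(k)) {
    parts <- c(parts, add(sprintf("epitope_%02d", i), epitope_dnas[i]))
    if (i < k) parts <- c(parts, add(sprintf("linker_%02d", i), linkers[i]))
  }
  parts <- c(parts, add("stop_codon", config$stop_codon))
  parts <- c(parts, add(paste0("site_3p_", names(config$sites)[2]),
                        config$sites[[2]]))
  features <- do.call(rbind, feats)
  seqn <- paste(parts, collapse = "")
  cds_start <- features$start[features$feature == "start_codon"]
  cds_end <- features$end[features$feature == "stop_codon"]
  structure(list(id = id, sequence = seqn, features = features,
                 coding = substr(seqn, cds_start + 3L, cds_end - 3L),
                 cai = NA_real_, gc = NA_real_, mfe = NA_real_,
                 hazards = character(0)),
            class = "dna_construct")
}

#' @export
print.dna_construct <- function(x, ...) {
  cat("DNA construct", x$id, "-", nchar(x$sequence), "nt\n")
  cat(sprintf("  CAI %.3f | GC %.3f | MFE %s | hazards: %s\n",
              x$cai, x$gc,
              ifelse(is.na(x$mfe), "unevaluated", sprintf("%.1f", x$mfe)),
              if (length(x$hazards) == 0) "none" else
                paste(x$hazards, collapse = ", ")))
  invisible(x)
}

#' Codon adaptation index
#'
#' Geometric mean of the relative adaptiveness w of each codon (Sharp & Li),
#' excluding codons with no synonymous choice (ATG, TGG) and stop codons,
#' which carry no optimization signal. 1.0 means every codon is its
#' family's most frequent.
#'
#' @param dna Coding DNA (length divisible by 3).
#' @param codon_table A `codon_usage_table`.
#' @return CAI in (0, 1].
#' @export
cai <- function(dna, codon_table = default_codon_usage()) {
  n <- nchar(dna)
  if (n == 0 || n %% 3 != 0) {
    stop("coding sequence length must be a positive multiple of 3, got ", n)
  }
  codons <- substring(dna, seq(1, n, 3), seq(3, n, 3))
  w <- stats::setNames(codon_table$w, codon_table$codon)
  keep <- !(codons %in% c("ATG", "TGG", "TAA", "TAG", "TGA"))
  codons <- codons[keep]
  if (length(codons) == 0) return(1)
  if (any(!codons %in% names(w))) {
    stop("non-sense codon in coding sequence: ",
         paste(unique(codons[!codons %in% names(w)]), collapse = ", "))
  }
  exp(mean(log(w[codons])))
}

#' GC content of a DNA sequence
#'
#' @param dna Non-empty DNA string.
#' @return Fraction of G and C bases in \[0, 1\].
#' @export
gc_content <- function(dna) {
  n <- nchar(dna)
  if (n == 0) stop("empty sequence")
  gc <- nchar(gsub("[^GCgc]", "", dna))
  gc / n
}

#' Screen a construct for sequence hazards
#'
#' Flags (i) exact direct repeats of at least `repeat_min_len` nucleotides
#' occurring two or more times, (ii) TATA-box-like motifs (TATAWAW),
#' (iii) premature polyadenylation signals (AATAAA / ATTAAA) on the coding
#' strand, and (iv) internal occurrences of the configured restriction
#' sites (outside their declared flanking positions).
#'
#' @param dna Insert sequence.
#' @param config A [design_config()].
#' @param features Optional feature table (to exempt the declared flanking
#'   site coordinates from the internal-site check).
#' @return Character vector of hazard flags (empty when clean): subset of
#'   `"repeat"`, `"tata"`, `"polya"`, `"internal_site"`.
#' @export
screen_hazards <- function(dna, config = design_config(), features = NULL) {
  flags <- character(0)
  n <- nchar(dna)
  k <- config$repeat_min_len
  if (n >= 2 * k) {
    kmers <- substring(dna, 1:(n - k + 1L), k:n)
    if (anyDuplicated(kmers) > 0) flags <- c(flags, "repeat")
  }
  if (grepl("TATA[AT]A[AT]", dna)) flags <- c(flags, "tata")
  if (grepl("AATAAA|ATTAAA", dna)) flags <- c(flags, "polya")
  declared <- integer(0)
  if (!is.null(features)) {
    site_rows <- grepl("^site_", features$feature)
    declared <- features$start[site_rows]
  }
  for (site in config$sites) {
    hits <- gregexpr(site, dna, fixed = TRUE)[[1]]
    hits <- hits[hits > 0]
    if (length(setdiff(hits, declared)) > 0) {
      flags <- c(flags, "internal_site")
      break
    }
  }
  flags
}

#' RNA minimum free energy
#'
#' Energy of the most stable nested secondary structure of the transcribed
#' insert. The built-in engine is a Nussinov-style dynamic program with
#' pair energies GC = -3, AU = -2, GU = -1 (arbitrary units) and a minimum
#' hairpin loop of 3 unpaired bases; it is exact for that energy model.
#' The `"rnafold"` engine shells out to ViennaRNA's RNAfold (full
#' thermodynamic model, kcal/mol) behind the same lower-is-more-structured
#' contract. T and U are interchangeable in the input.
#'
#' @param dna DNA or RNA sequence.
#' @param engine `"nussinov"` (default) or `"rnafold"`.
#' @return Minimum free energy, always <= 0.
#' @export
rna_mfe <- function(dna, engine = c("nussinov", "rnafold")) {
  engine <- match.arg(engine)
  if (nchar(dna) == 0) stop("empty sequence")
  if (engine == "nussinov") {
    .rna_mfe_nussinov(dna)
  } else {
    if (Sys.which("RNAfold") == "") stop("RNAfold binary not found on PATH")
    rna <- chartr("Tt", "Uu", dna)
    out <- system2("RNAfold", "--noPS", input = rna, stdout = TRUE)
    m <- regmatches(out[2], regexpr("\\(\\s*-?[0-9.]+\\s*\\)$", out[2]))
    if (length(m) == 0) stop("could not parse RNAfold output")
    as.numeric(gsub("[()\\s]", "", m, perl = TRUE))
  }
}

#' Generate a cohort of candidate inserts
#'
#' Draws `cohort_size` independent inserts for the peptide panel: each
#' epitope is reverse-translated by weighted codon sampling and assembled
#' with randomly drawn linker variants, then scored for CAI and GC content
#' and screened for sequence hazards. Hazard-flagged members are marked
#' ineligible for thresholding. RNA folding is deferred to the final
#' selection stage, where only the thresholding survivors are evaluated.
#'
#' @param panel_peptides Character vector of epitope peptides.
#' @param config A [design_config()].
#' @param codon_table A `codon_usage_table`.
#' @return List with `constructs` (list of `dna_construct`) and `summary`
#'   (data.frame: `id`, `cai`, `gc`, `eligible`, `hazards`). Uses the
#'   current RNG stream.
#' @export
generate_cohort <- function(panel_peptides, config = design_config(),
                            codon_table = default_codon_usage()) {
  stopifnot(length(panel_peptides) >= 1)
  for (p in panel_peptides) .assert_canonical_aa(p, "panel peptide")
  linker_set <- build_linker_set(config$linker_peptide,
                                 config$n_linker_variants, codon_table)
  N <- config$cohort_size
  k <- length(panel_peptides)
  # Synonymous linker variants share one length, so the feature layout is
  # identical across the cohort; one reference assembly provides the
  # template shared by all members.
  template <- assemble_insert(
    vapply(panel_peptides, reverse_translate, character(1),
           codon_table = codon_table, USE.NAMES = FALSE),
    linker_set, config, id = "template")
  # Batched weighted codon sampling over all epitope residues of the
  # whole cohort (one draw call per amino acid).
  concat <- paste(panel_peptides, collapse = "")
  aas <- strsplit(concat, "")[[1]]
  m <- length(aas)
  fam_pos <- split(seq_len(m), aas)
  codon_mat <- matrix(NA_character_, nrow = m, ncol = N)
  for (aa in names(fam_pos)) {
    fam <- codon_table[codon_table$aa == aa, ]
    idx <- fam_pos[[aa]]
    codon_mat[idx, ] <- if (nrow(fam) == 1) fam$codon else
      sample(fam$codon, length(idx) * N, replace = TRUE, prob = fam$weight)
  }
  link_mat <- if (k > 1) {
    matrix(sample(linker_set$dna_variants, (k - 1L) * N, replace = TRUE),
           nrow = k - 1L)
  } else matrix(character(0), nrow = 0, ncol = N)
  ep_end <- cumsum(nchar(panel_peptides))
  ep_start <- c(1L, utils::head(ep_end, -1) + 1L)
  prefix <- paste0(config$sites[[1]], config$kozak, "ATG")
  suffix <- paste0(config$stop_codon, config$sites[[2]])
  constructs <- vector("list", N)
  cai_v <- numeric(N); gc_v <- numeric(N); haz <- character(N)
  for (i in seq_len(N)) {
    segs <- character(2L * k - 1L)
    for (j in seq_len(k)) {
      segs[2L * j - 1L] <-
        paste(codon_mat[ep_start[j]:ep_end[j], i], collapse = "")
      if (j < k) segs[2L * j] <- link_mat[j, i]
    }
    coding <- paste(segs, collapse = "")
    seqn <- paste0(prefix, coding, suffix)
    hz <- screen_hazards(seqn, config, template$features)
    cons <- template
    cons$id <- sprintf("c%05d", i)
    cons$sequence <- seqn
    cons$coding <- coding
    cons$cai <- cai(coding, codon_table)
    cons$gc <- gc_content(seqn)
    cons$hazards <- hz
    constructs[[i]] <- cons
    cai_v[i] <- cons$cai; gc_v[i] <- cons$gc
    haz[i] <- paste(hz, collapse = ",")
  }
  summary <- data.frame(id = sprintf("c%05d", seq_len(N)),
                        cai = cai_v, gc = gc_v, eligible = haz == "",
                        hazards = haz, stringsAsFactors = FALSE)
  list(constructs = constructs, summary = summary)
}

# Dynamic-threshold ranking score: CAI penalized by the distance of the GC
# content from the target window (zero inside the window).
.threshold_score <- function(cai, gc, config) {
  gc_dist <- pmax(0, config$gc_window[1] - gc) +
    pmax(0, gc - config$gc_window[2])
  cai - config$gc_penalty * gc_dist
}

#' Apply dynamic CAI/GC thresholds to a cohort
#'
#' Ranks hazard-free cohort members by CAI penalized for GC content outside
#' the target window, and keeps the top `ceiling(survivor_fraction * N)` of
#' the cohort — thresholds are thus set by the cohort's own score
#' distribution rather than fixed cutoffs. At the defaults this eliminates
#' exactly 99% of the generated constructs.
#'
#' @param cohort Result of [generate_cohort()].
#' @param config A [design_config()].
#' @return List with `survivors` (list of `dna_construct`, best first),
#'   `survivor_ids`, and `n_eliminated`.
#' @export
apply_dynamic_thresholds <- function(cohort, config = design_config()) {
  s <- cohort$summary
  n_keep <- as.integer(ceiling(config$survivor_fraction * nrow(s)))
  elig <- which(s$eligible)
  if (length(elig) < n_keep) {
    stop("only ", length(elig), " hazard-free constructs but ",
         n_keep, " survivors requested; enlarge the cohort or relax screens")
  }
  sc <- .threshold_score(s$cai[elig], s$gc[elig], config)
  keep <- elig[order(-sc, s$id[elig])][seq_len(n_keep)]
  list(survivors = cohort$constructs[keep], survivor_ids = s$id[keep],
       n_eliminated = nrow(s) - n_keep)
}

#' Select the final construct by maximal RNA minimum free energy
#'
#' Folds each thresholding survivor and returns the one with the highest
#' (least negative) minimum free energy — the least structured transcript,
#' favoring translatability. Ties break by higher CAI, then id.
#'
#' @param survivors List of `dna_construct` (from
#'   [apply_dynamic_thresholds()]).
#' @param config A [design_config()] (folding engine).
#' @return The winning `dna_construct` with its `mfe` slot filled;
#'   attribute `"mfe_all"` holds every survivor's energy.
#' @export
select_final <- function(survivors, config = design_config()) {
  if (length(survivors) == 0) stop("no surviving constructs to select from")
  mfe <- vapply(survivors, function(cons) {
    rna_mfe(cons$sequence, config$engine)
  }, numeric(1))
  cai_v <- vapply(survivors, `[[`, numeric(1), "cai")
  ids <- vapply(survivors, `[[`, character(1), "id")
  best <- order(-mfe, -cai_v, ids)[1]
  out <- survivors[[best]]
  out$mfe <- mfe[best]
  attr(out, "mfe_all") <- stats::setNames(mfe, ids)
  out
}

#' Design an optimized multi-epitope DNA insert
#'
#' End-to-end insert optimization: generate the construct cohort by
#' weighted-codon reverse translation and random linker assembly, apply
#' the dynamic CAI/GC thresholds (eliminating 99% at defaults), fold the
#' survivors, and return the construct with the highest RNA minimum free
#' energy. One seed governs the whole run.
#'
#' @param panel_peptides Character vector of epitope peptides.
#' @param config A [design_config()].
#' @param codon_table A `codon_usage_table`.
#' @param seed Optional integer seed applied to the run's RNG stream.
#' @return List with `construct` (the final `dna_construct`) and `report`
#'   (generated / eliminated / survivor counts, metric distribution
#'   summaries, survivor energies).
#' @export
design_insert <- function(panel_peptides, config = design_config(),
                          codon_table = default_codon_usage(),
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cohort <- generate_cohort(panel_peptides, config, codon_table)
  thr <- apply_dynamic_thresholds(cohort, config)
  final <- select_final(thr$survivors, config)
  report <- list(
    n_generated = nrow(cohort$summary),
    n_hazard_flagged = sum(!cohort$summary$eligible),
    n_eliminated = thr$n_eliminated,
    n_survivors = length(thr$survivors),
    eliminated_percent = 100 * thr$n_eliminated / nrow(cohort$summary),
    cai_quartiles = stats::quantile(cohort$summary$cai,
                                    c(0.25, 0.5, 0.75)),
    gc_quartiles = stats::quantile(cohort$summary$gc, c(0.25, 0.5, 0.75)),
    survivor_mfe = attr(final, "mfe_all"),
    final_id = final$id, final_cai = final$cai, final_gc = final$gc,
    final_mfe = final$mfe)
  list(construct = final, report = report)
}

#' Write a cohort report as JSON
#'
#' @param report Report list from [design_insert()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_design_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
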