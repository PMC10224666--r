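#' Simulation configuration
#'
#' Parameters of the synthetic tumor/normal dataset generator. Defaults
#' describe a modest exome-scale slice realistic for a murine tumor line:
#' tumor purity 0.8, a mostly-clonal mutation spectrum, log-normal
#' expression centred near the 20-RPKM eligibility cutoff so both sides of
#' the filter are populated, and four somatic callers with high but
#' imperfect sensitivity.
#'
#' @param n_proteins Number of proteins in the synthetic proteome.
#' @param protein_length_range Length range (amino acids), inclusive.
#' @param n_somatic,n_germline Somatic / germline variant counts.
#' @param purity Tumor purity in (0, 1].
#' @param clonal_fraction Fraction of somatic variants that are clonal
#'   (cancer cell fraction 1); the rest draw CCF uniformly on (0, 1).
#' @param depth Sequencing depth for binomial VAF noise; `Inf` gives the
#'   noise-free infinite-depth limit.
#' @param caller_sensitivity Named per-caller detection probabilities.
#' @param germline_fs_fraction Fraction of germline variants that are
#'   frameshift/splice class (these knock out their protein downstream).
#' @param expression_log_mean,expression_log_sd Log-normal RPKM parameters
#'   (defaults log(20) and 1.2: median at the eligibility cutoff).
#' @param zero_expression_fraction Fraction of proteins with RPKM 0.
#' @param seed Integer seed; every generator derives its stream from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 40, protein_length_range = c(120, 500),
                       n_somatic = 60, n_germline = 15, purity = 0.8,
                       clonal_fraction = 0.6, depth = 200,
                       caller_sensitivity = c(lofreq = 0.9, mutect2 = 0.9,
                                              strelka = 0.85,
                                              snvsniffer = 0.8),
                       germline_fs_fraction = 0.1,
                       expression_log_mean = log(20),
                       expression_log_sd = 1.2,
                       zero_expression_fraction = 0.1,
                       seed = 1L) {
  stopifnot(n_proteins >= 1, all(protein_length_range >= 1),
            protein_length_range[1] <= protein_length_range[2],
            purity > 0, purity <= 1,
            clonal_fraction >= 0, clonal_fraction <= 1,
            all(caller_sensitivity >= 0 & caller_sensitivity <= 1),
            germline_fs_fraction >= 0, germline_fs_fraction <= 1,
            zero_expression_fraction >= 0, zero_expression_fraction <= 1,
            depth > 0)
  structure(list(n_proteins = n_proteins,
                 protein_length_range = protein_length_range,
                 n_somatic = n_somatic, n_germline = n_germline,
                 purity = purity, clonal_fraction = clonal_fraction,
                 depth = depth, caller_sensitivity = caller_sensitivity,
                 germline_fs_fraction = germline_fs_fraction,
                 expression_log_mean = expression_log_mean,
                 expression_log_sd = expression_log_sd,
                 zero_expression_fraction = zero_expression_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Runs expr under a substream seed derived from the global config seed, so
# each generator is reproducible on its own and in any call order.
.with_substream <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((seed * 1000L + offset) %% 2147483647L)
  force(expr)
}

#' Generate a synthetic proteome
#'
#' Proteins with i.i.d. uniform canonical amino acids, lengths uniform over
#' the configured range. Bit-reproducible under the config seed.
#'
#' @param config A [sim_config()].
#' @return Data.frame with `id`, `sequence` (the [read_fasta()] shape).
#' @export
gen_proteome <- function(config) {
  .with_substream(config$seed, 1L, {
    span <- seq(config$protein_length_range[1],
                config$protein_length_range[2])
    lens <- span[sample.int(length(span), config$n_proteins,
                            replace = TRUE)]
    seqs <- vapply(lens, function(L) {
      paste(sample(aa_alphabet(), L, replace = TRUE), collapse = "")
    }, character(1))
    data.frame(id = sprintf("SYNP%04d", seq_len(config$n_proteins)),
               sequence = seqs, stringsAsFactors = FALSE)
  })
}

#' Generate synthetic somatic and germline variants
#'
#' Somatic missense variants receive a true cancer cell fraction of 1
#' (clonal, with probability `clonal_fraction`) or uniform on (0, 1)
#' (subclonal). The expected VAF under the diploid copy-neutral model is
#' CCF x purity / 2; at finite depth the observed VAF adds binomial
#' sampling noise, at `depth = Inf` it is exact. Caller support is drawn
#' per caller from the configured sensitivities. Germline variants are
#' heterozygous (VAF 0.5), carry no somatic-caller support, and a
#' configured fraction is frameshift/splice class. Reference residues
#' always match the proteome.
#'
#' @param proteome Proteome from [gen_proteome()].
#' @param config A [sim_config()].
#' @return Variant data.frame in the [read_variants()] shape plus a
#'   `true_ccf` column (NA for germline); `callers` is a list-column.
#' @export
gen_variants <- function(proteome, config) {
  .with_substream(config$seed, 2L, {
    lens <- nchar(proteome$sequence)
    n_pos <- sum(lens)
    n_total <- config$n_somatic + config$n_germline
    if (n_total > n_pos) {
      stop("requested ", n_total, " variants but proteome has only ",
           n_pos, " positions")
    }
    # distinct (protein, position) pairs over the concatenated proteome
    flat <- sample(n_pos, n_total)
    cum <- cumsum(lens)
    prot_i <- findInterval(flat - 1L, c(0L, cum), rightmost.closed = TRUE)
    pos <- flat - c(0L, cum)[prot_i]
    origin <- rep(c("somatic", "germline"),
                  c(config$n_somatic, config$n_germline))
    ref <- substring(proteome$sequence[prot_i], pos, pos)
    alt <- vapply(ref, function(r) sample(setdiff(aa_alphabet(), r), 1),
                  character(1), USE.NAMES = FALSE)
    cls <- ifelse(origin == "germline" &
                    stats::runif(n_total) < config$germline_fs_fraction,
                  sample(c("frameshift", "splice"), n_total, replace = TRUE),
                  "missense")
    ccf <- ifelse(stats::runif(n_total) < config$clonal_fraction, 1,
                  stats::runif(n_total))
    ccf[origin == "germline"] <- NA_real_
    exp_vaf <- ifelse(origin == "germline", 0.5,
                      ccf * config$purity / 2)
    vaf <- if (is.infinite(config$depth)) exp_vaf else
      stats::rbinom(n_total, config$depth, exp_vaf) / config$depth
    callers <- lapply(seq_len(n_total), function(i) {
      if (origin[i] == "germline") return(character(0))
      s <- config$caller_sensitivity
      names(s)[stats::runif(length(s)) < s]
    })
    out <- data.frame(protein_id = proteome$id[prot_i], pos = pos,
                      ref_aa = ref, alt_aa = alt, class = cls,
                      origin = origin, vaf = vaf, true_ccf = ccf,
                      stringsAsFactors = FALSE)
    out$callers <- callers
    out$n_callers <- lengths(callers)
    out
  })
}

#' Generate a synthetic expression table
#'
#' Log-normal RPKM per protein with a configured zero-expression fraction;
#' the RNA VAF of a protein tracks the DNA VAF of its (first) somatic
#' variant with additive noise, clamped to \[0, 1\].
#'
#' @param proteome Proteome from [gen_proteome()].
#' @param config A [sim_config()].
#' @param variants Optional variant table (for RNA VAF coupling).
#' @return Data.frame with `id`, `rpkm`, `rna_vaf`.
#' @export
gen_expression <- function(proteome, config, variants = NULL) {
  .with_substream(config$seed, 3L, {
    n <- nrow(proteome)
    rpkm <- stats::rlnorm(n, config$expression_log_mean,
                          config$expression_log_sd)
    zero <- stats::runif(n) < config$zero_expression_fraction
    rpkm[zero] <- 0
    rna_vaf <- rep(NA_real_, n)
    if (!is.null(variants)) {
      som <- variants[variants$origin == "somatic", , drop = FALSE]
      first <- som[!duplicated(som$protein_id), , drop = FALSE]
      m <- match(proteome$id, first$protein_id)
      hit <- !is.na(m)
      rna_vaf[hit] <- pmin(pmax(first$vaf[m[hit]] +
                                  stats::rnorm(sum(hit), 0, 0.05), 0), 1)
    }
    data.frame(id = proteome$id, rpkm = rpkm, rna_vaf = rna_vaf,
               stringsAsFactors = FALSE)
  })
}

#' Generate a complete synthetic dataset
#'
#' @param config A [sim_config()].
#' @return List with `proteome`, `variants`, `expression`, `purity`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  proteome <- gen_proteome(config)
  variants <- gen_variants(proteome, config)
  expression <- gen_expression(proteome, config, variants)
  list(proteome = proteome, variants = variants, expression = expression,
       purity = config$purity)
}

#' Write a synthetic dataset in the pipeline's file dialects
#'
#' Emits `proteome.fasta`, `variants.tsv`, `expression.tsv` and
#' `config.yaml` (purity) into a directory so the pipeline can run
#' end-to-end from files.
#'
#' @param dataset List from [simulate_dataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, named vector of written paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(proteome = file.path(dir, "proteome.fasta"),
             variants = file.path(dir, "variants.tsv"),
             expression = file.path(dir, "expression.tsv"),
             config = file.path(dir, "config.yaml"))
  write_fasta(dataset$proteome$id, dataset$proteome$sequence,
              paths[["proteome"]])
  write_variants(dataset$variants, paths[["variants"]])
  write_expression(dataset$expression, paths[["expression"]])
  yaml::write_yaml(list(purity = dataset$purity), paths[["config"]])
  invisible(paths)
}

#' Generate a planted-recovery scenario
#'
#' Builds a dataset in which `k` planted somatic variants dominate every
#' factor of the composite score: they are clonal (observed VAF exactly
#' purity/2), supported by all four callers, highly expressed, and their
#' substitutions are chosen to maximize the physicochemical distance;
#' the returned lookup-table predictor assigns a strong %rank to every
#' oligomer of a planted neoepitope and a non-binding rank to everything
#' else. Decoy variants are subclonal, weakly supported and weakly
#' expressed. Used for end-to-end recovery testing: selection must return
#' exactly the planted identifiers.
#'
#' @param config A [sim_config()]; `n_somatic` counts decoys + planted.
#' @param k Number of planted variants (default 13).
#' @return List with the dataset fields of [simulate_dataset()] plus
#'   `predictor` and `planted_ids` (candidate ids of the planted set).
#' @export
gen_planted_scenario <- function(config = sim_config(), k = 13) {
  stopifnot(k >= 0, k <= config$n_somatic)
  proteome <- gen_proteome(config)
  variants <- gen_variants(proteome, config)
  expression <- gen_expression(proteome, config, variants)
  som_idx <- which(variants$origin == "somatic")
  # plant only where a full window and clean germline background exist
  germ_prot <- unique(variants$protein_id[variants$origin == "germline"])
  lens <- stats::setNames(nchar(proteome$sequence), proteome$id)
  ok <- som_idx[variants$pos[som_idx] > 14 &
                  variants$pos[som_idx] <=
                    lens[variants$protein_id[som_idx]] - 14 &
                  !variants$protein_id[som_idx] %in% germ_prot]
  ok <- ok[!duplicated(variants$protein_id[ok])]  # distinct proteins
  if (length(ok) < k) stop("proteome too small to plant ", k, " variants")
  planted <- .with_substream(config$seed, 4L, sample(ok, k))
  atch <- atchley_factors()
  dmat <- as.matrix(stats::dist(atch))
  for (i in planted) {
    ref <- variants$ref_aa[i]
    variants$alt_aa[i] <- names(which.max(dmat[ref, ]))
    variants$class[i] <- "missense"
    variants$true_ccf[i] <- 1
    variants$vaf[i] <- config$purity / 2
    variants$callers[[i]] <- names(config$caller_sensitivity)
    variants$n_callers[i] <- length(config$caller_sensitivity)
    expression$rpkm[expression$id == variants$protein_id[i]] <- 100
  }
  decoys <- setdiff(som_idx, planted)
  variants$vaf[decoys] <- pmin(variants$vaf[decoys], 0.3 * config$purity / 2)
  variants$true_ccf[decoys] <- pmin(variants$true_ccf[decoys], 0.3)
  for (i in decoys) {
    # conservative substitution (nearest property neighbor) and at most
    # three supporting callers, so decoys sit strictly below the planted
    # set on every factor
    ref <- variants$ref_aa[i]
    if (variants$class[i] == "missense") {
      variants$alt_aa[i] <- names(which.min(dmat[ref, -match(ref, colnames(dmat))]))
    }
    if (variants$n_callers[i] >= length(config$caller_sensitivity)) {
      variants$callers[[i]] <- variants$callers[[i]][-1]
      variants$n_callers[i] <- length(variants$callers[[i]])
    }
  }
  planted_ids <- sprintf("%s_%d_%s%s", variants$protein_id[planted],
                         variants$pos[planted], variants$ref_aa[planted],
                         variants$alt_aa[planted])
  # strong rank only for oligomers spanning a planted mutation (flank-only
  # oligomers are reference sequence that nearby decoy windows can share)
  cand <- extract_candidates(proteome, variants, expression)
  pl <- cand[cand$id %in% planted_ids, , drop = FALSE]
  oligos <- unlist(lapply(seq_len(nrow(pl)), function(j) {
    o <- enumerate_oligomers(pl$sequence[j], c(8:11, 15))
    mut <- pl$mutant_index[j]
    o$oligomer[o$offset <= mut & mut <= o$offset + o$size - 1L]
  }))
  predictor <- table_predictor(
    stats::setNames(rep(0.1, length(oligos)), oligos), default = 60)
  list(proteome = proteome, variants = variants, expression = expression,
       purity = config$purity, predictor = predictor,
       planted_ids = planted_ids)
}
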