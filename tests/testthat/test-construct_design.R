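test_that("reverse translation is faithful and respects codon weights", {
  tab <- default_codon_usage()
  expect_equal(reverse_translate("M", tab), "ATG")
  expect_equal(reverse_translate("W", tab), "TGG")
  set.seed(16)
  for (i in 1:10) {
    p <- random_peptide(25)
    dna <- reverse_translate(p, tab)
    expect_equal(neovax:::translate_dna(dna), p)
  }
  expect_error(reverse_translate("MXZ", tab), "non-canonical")
  # large-sample codon frequencies for G and S match the table weights
  set.seed(17)
  draws <- replicate(4000, reverse_translate("GS", tab))
  g_codon <- substr(draws, 1, 3)
  g_fam <- tab[tab$aa == "G", ]
  cs <- chisq.test(table(factor(g_codon, levels = g_fam$codon)),
                   p = g_fam$weight)
  expect_gt(cs$p.value, 0.001)
})

test_that("linker sets are synonymous, diverse, and deterministic", {
  tab <- default_codon_usage()
  ls <- build_linker_set("GGS", 4, tab)
  expect_length(ls$dna_variants, 4)
  for (v in ls$dna_variants) {
    expect_equal(neovax:::translate_dna(v), "GGS")
  }
  # seed choice: the single variant is the most-frequent-codon encoding
  expect_equal(build_linker_set("GGS", 1, tab)$dna_variants, "GGCGGCAGC")
  # pairwise distinct
  d <- outer(ls$dna_variants, ls$dna_variants, Vectorize(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }))
  expect_true(all(d[upper.tri(d)] >= 1))
  expect_identical(ls, build_linker_set("GGS", 4, tab))
  # GGS has 4 x 4 x 6 = 96 synonymous encodings
  expect_error(build_linker_set("GGS", 97, tab), "96")
})

test_that("assembled inserts have the declared layout and translate correctly", {
  tab <- default_codon_usage()
  ls <- build_linker_set("GGS", 4, tab)
  cfg <- design_config()
  set.seed(18)
  peps <- replicate(3, random_peptide(27))
  ep_dna <- vapply(peps, reverse_translate, character(1),
                   codon_table = tab, USE.NAMES = FALSE)
  cons <- assemble_insert(ep_dna, ls, cfg)
  expect_equal(sum(grepl("^linker", cons$features$feature)), 2)
  expect_equal(neovax:::translate_dna(cons$coding),
               paste(peps, collapse = "GGS"))
  expect_true(startsWith(cons$sequence, paste0(cfg$sites[[1]], cfg$kozak,
                                               "ATG")))
  expect_true(endsWith(cons$sequence, paste0(cfg$stop_codon,
                                             cfg$sites[[2]])))
  # single epitope: no linker features
  single <- assemble_insert(ep_dna[1], ls, cfg)
  expect_equal(sum(grepl("^linker", single$features$feature)), 0)
  # features tile contiguously
  f <- single$features[order(single$features$start), ]
  expect_true(all(f$start[-1] == utils::head(f$end, -1) + 1))
})

test_that("CAI is the geometric mean of relative adaptiveness with exclusions", {
  tab <- default_codon_usage()
  # all most-frequent synonymous codons: CAI exactly 1
  best <- vapply(split(tab, tab$aa), function(fam) {
    fam$codon[which.max(fam$frequency)]
  }, character(1))
  expect_equal(cai(paste(best, collapse = ""), tab), 1.0)
  # two-codon toy table: w = {1, 0.25} -> geometric mean 0.5
  freq <- stats::setNames(tab$frequency, tab$codon)
  freq["CTT"] <- 10; freq["CTG"] <- 40
  toy <- codon_usage_table(freq)
  expect_equal(cai("CTTCTG", toy), sqrt(0.25 * 1))
  # ATG carries no signal
  expect_equal(cai("CTTCTGATG", toy), cai("CTTCTG", toy))
  expect_error(cai("CTTC", tab), "multiple of 3")
})

test_that("GC content is the G+C fraction", {
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("ATAT"), 0.0)
  expect_error(gc_content(""), "empty")
})

test_that("hazard screen flags repeats, TATA boxes, poly-A signals, internal sites", {
  cfg <- design_config()
  expect_equal(screen_hazards(strrep("A", 30), cfg), "repeat")
  expect_equal(screen_hazards("GCATATAAATGC", cfg), "tata")
  expect_equal(screen_hazards("GCGCAATAAAGCGC", cfg), "polya")
  expect_equal(screen_hazards("GCGCATTAAAGCGC", cfg), "polya")
  # constructed negative: no motifs, no 12-nt repeat
  neg <- "GACGTTCAGCTGGACAAGGAGATCGTGAGCCTGTGGCGCTACCCGGACATCGAGCTGAAG"
  expect_length(screen_hazards(neg, cfg), 0)
  # internal restriction site is flagged; declared flanks are exempt
  with_site <- paste0("GACGTT", cfg$sites[[1]], "GACGTT")
  expect_equal(screen_hazards(with_site, cfg), "internal_site")
  feats <- data.frame(feature = "site_5p_nhei", start = 7L,
                      end = 12L, stringsAsFactors = FALSE)
  expect_length(screen_hazards(with_site, cfg, feats), 0)
})

test_that("built-in folding engine matches the brute-force enumeration oracle", {
  expect_equal(rna_mfe("AAAAAA"), 0)
  expect_equal(rna_mfe("GC"), 0)  # minimum loop forbids pairing
  expect_equal(rna_mfe("GGGAAACCC"), -9)  # three GC pairs
  set.seed(19)
  for (i in 1:60) {
    s <- random_dna(sample(2:12, 1))
    expect_equal(rna_mfe(s), oracle_mfe(s), info = s)
  }
})

test_that("folding is invariant to the DNA/RNA alphabet and never positive", {
  set.seed(20)
  for (i in 1:20) {
    s <- random_dna(sample(5:40, 1))
    dna <- chartr("U", "T", s)
    expect_equal(rna_mfe(s), rna_mfe(dna))
    expect_lte(rna_mfe(s), 0)
  }
})

test_that("cohorts have the configured size and all members translate to the panel", {
  set.seed(21)
  peps <- replicate(3, random_peptide(27))
  cfg <- design_config(cohort_size = 120)
  set.seed(22)
  co <- generate_cohort(peps, cfg)
  expect_equal(nrow(co$summary), 120)
  expect_length(co$constructs, 120)
  target <- paste(peps, collapse = cfg$linker_peptide)
  idx <- c(1, 60, 120)
  for (i in idx) {
    expect_equal(neovax:::translate_dna(co$constructs[[i]]$coding), target)
    expect_equal(co$constructs[[i]]$cai,
                 cai(co$constructs[[i]]$coding))
    expect_equal(co$constructs[[i]]$gc,
                 gc_content(co$constructs[[i]]$sequence))
  }
  # seed determinism
  set.seed(22)
  co2 <- generate_cohort(peps, cfg)
  expect_identical(co$summary, co2$summary)
})

test_that("dynamic thresholding keeps exactly the survivor fraction, best first", {
  set.seed(23)
  peps <- replicate(2, random_peptide(27))
  cfg <- design_config(cohort_size = 300)
  set.seed(24)
  co <- generate_cohort(peps, cfg)
  thr <- apply_dynamic_thresholds(co, cfg)
  expect_length(thr$survivors, ceiling(0.01 * 300))
  expect_equal(thr$n_eliminated, 300 - 3)
  # survivor threshold scores dominate all eligible non-survivors
  sc <- neovax:::.threshold_score(co$summary$cai, co$summary$gc, cfg)
  elig <- co$summary$eligible
  in_surv <- co$summary$id %in% thr$survivor_ids
  expect_gte(min(sc[in_surv]), max(sc[elig & !in_surv]))
  # no hazard-flagged construct survives
  expect_true(all(co$summary$eligible[in_surv]))
})

test_that("survivor fraction 1 keeps a hazard-free cohort whole", {
  cfg <- design_config(cohort_size = 30, survivor_fraction = 1)
  set.seed(25)
  co <- generate_cohort("MACDEF", cfg)
  expect_true(all(co$summary$eligible))
  thr <- apply_dynamic_thresholds(co, cfg)
  expect_length(thr$survivors, 30)
})

test_that("final selection takes the maximum MFE with CAI then id tie-breaks", {
  mk <- function(id, sequence, cai) {
    structure(list(id = id, sequence = sequence, cai = cai,
                   mfe = NA_real_), class = "dna_construct")
  }
  # energies: GGGAAACCC = -9, GGAAACCC = -6, AAAAAA = 0
  surv <- list(mk("x", "GGGAAACCC", 0.5), mk("y", "GGAAACCC", 0.5),
               mk("z", "AAAAAA", 0.5))
  pick <- select_final(surv, design_config())
  expect_equal(pick$id, "z")
  expect_equal(pick$mfe, 0)
  # CAI breaks MFE ties
  tie <- list(mk("a", "AAAAAA", 0.8), mk("b", "TTTTTT", 0.9))
  expect_equal(select_final(tie, design_config())$id, "b")
  # single survivor returns itself
  expect_equal(select_final(surv[1], design_config())$id, "x")
  expect_error(select_final(list(), design_config()), "no surviving")
})

test_that("end-to-end design is reproducible and audited", {
  set.seed(26)
  peps <- replicate(3, random_peptide(27))
  cfg <- design_config(cohort_size = 300)
  d1 <- design_insert(peps, cfg, seed = 99)
  d2 <- design_insert(peps, cfg, seed = 99)
  expect_identical(d1$construct$sequence, d2$construct$sequence)
  expect_equal(d1$report$n_generated, 300)
  expect_equal(d1$report$n_survivors, 3)
  expect_equal(d1$report$n_eliminated, 297)
  expect_equal(d1$report$final_mfe, max(d1$report$survivor_mfe))
  # the chosen construct translates to the panel and keeps clean flanks
  expect_equal(neovax:::translate_dna(d1$construct$coding),
               paste(peps, collapse = "GGS"))
  expect_length(d1$construct$hazards, 0)
  expect_gte(d1$report$final_cai, stats::median(d1$report$cai_quartiles[2]))
})
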