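test_that("tumor protein applies germline then somatic substitutions", {
  germ <- data.frame(protein_id = "p1", pos = 3L, ref_aa = "V",
                     alt_aa = "L", class = "missense", origin = "germline",
                     stringsAsFactors = FALSE)
  som <- list(pos = 2L, ref_aa = "K", alt_aa = "N")
  out <- build_tumor_protein("MKVA", germ, som)
  expect_equal(out$status, "ok")
  expect_equal(out$tumor_seq, "MNLA")
  expect_equal(out$germline_seq, "MKLA")
})

test_that("germline frameshift or splice variants reject the protein", {
  germ <- data.frame(protein_id = "p1", pos = 3L, ref_aa = "V",
                     alt_aa = "V", class = "splice", origin = "germline",
                     stringsAsFactors = FALSE)
  out <- build_tumor_protein("MKVA", germ, list(pos = 2L, ref_aa = "K",
                                                alt_aa = "N"))
  expect_equal(out$status, "rejected")
  expect_equal(out$reason, "germline frameshift/splice")
})

test_that("without germline variants only the somatic substitution applies", {
  none <- data.frame(protein_id = character(0), pos = integer(0),
                     ref_aa = character(0), alt_aa = character(0),
                     class = character(0), origin = character(0),
                     stringsAsFactors = FALSE)
  out <- build_tumor_protein("MKVA", none, list(pos = 2L, ref_aa = "K",
                                                alt_aa = "N"))
  expect_equal(out$tumor_seq, "MNVA")
  expect_equal(out$germline_seq, "MKVA")
  expect_error(build_tumor_protein("MKVA", none,
                                   list(pos = 9L, ref_aa = "K",
                                        alt_aa = "N")),
               "beyond protein length")
})

test_that("wild-type residue check discards annotation mismatches", {
  expect_true(check_wildtype("MKVA", list(pos = 2L, ref_aa = "K"))$pass)
  chk <- check_wildtype("MKVA", list(pos = 2L, ref_aa = "G"))
  expect_false(chk$pass)
  expect_equal(chk$reason, "wildtype mismatch")
  expect_error(check_wildtype("MKVA", list(pos = 5L, ref_aa = "K")),
               "outside protein")
})

test_that("window extraction centers full-flank variants at position 15", {
  set.seed(1)
  prot <- random_peptide(200)
  w <- extract_window(prot, 100L)
  expect_equal(nchar(w$window), 29)
  expect_equal(w$mutant_index, 15L)
  expect_equal(w$window, substr(prot, 86, 114))
  expect_true(w$retained)
})

test_that("window extraction clips at protein ends and discards short windows", {
  set.seed(2)
  prot <- random_peptide(200)
  w <- extract_window(prot, 1L)
  expect_equal(w$window, substr(prot, 1, 15))
  expect_equal(w$mutant_index, 1L)
  expect_true(w$retained)
  short <- extract_window(random_peptide(14), 7L)
  expect_false(short$retained)
  expect_lte(nchar(short$window), 14)
})

test_that("terminal truncation converts 29mers to 27mers, mutant 15 -> 14", {
  set.seed(3)
  w29 <- random_peptide(29)
  fin <- truncate_to_final(w29, 15L)
  expect_equal(nchar(fin$sequence), 27)
  expect_equal(fin$mutant_index, 14L)
  expect_equal(fin$sequence, substr(w29, 2, 28))
  # clipped windows pass through unchanged
  w20 <- random_peptide(20)
  expect_equal(truncate_to_final(w20, 3L),
               list(sequence = w20, mutant_index = 3L))
})

test_that("oligomer enumeration produces all overlapping windows in order", {
  set.seed(4)
  s27 <- random_peptide(27)
  o15 <- enumerate_oligomers(s27, 15)
  expect_equal(nrow(o15), 13)
  expect_equal(o15$offset, 1:13)
  o_cl1 <- enumerate_oligomers(s27, 8:11)
  expect_equal(nrow(o_cl1), 74)  # 20 + 19 + 18 + 17
  expect_true(all(o_cl1$oligomer ==
                    substring(s27, o_cl1$offset,
                              o_cl1$offset + o_cl1$size - 1)))
  expect_equal(enumerate_oligomers(s27, 27)$oligomer, s27)
  expect_equal(nrow(enumerate_oligomers(s27, 30)), 0)
})

test_that("minimal epitopes are located by leftmost exact match", {
  expect_equal(locate_minimal_epitope("QIETQQRKFKASRASILSEMKMLKEKR",
                                      "KFKASRASI"), 8L)
  expect_equal(locate_minimal_epitope("ELCRVCGDKASGFRYNVLSCEGCKGFF",
                                      "SGFRYNVL"), 11L)
  expect_true(is.na(locate_minimal_epitope("MKVAMKVA", "WWW")))
})

test_that("window extraction is symmetric under protein reversal", {
  set.seed(5)
  revstr <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  for (rep in 1:10) {
    L <- sample(20:80, 1)
    prot <- random_peptide(L)
    pos <- sample(L, 1)
    w <- extract_window(prot, pos)
    wr <- extract_window(revstr(prot), L - pos + 1L)
    expect_equal(wr$window, revstr(w$window))
    expect_equal(wr$mutant_index, nchar(w$window) - w$mutant_index + 1L)
  }
})

test_that("tiling a long protein yields retained window lengths 15 through 29", {
  set.seed(6)
  prot <- random_peptide(60)
  lens <- integer(0)
  for (pos in 1:60) {
    w <- extract_window(prot, pos)
    if (w$retained) lens <- c(lens, nchar(w$window))
  }
  expect_setequal(unique(lens), 15:29)
  expect_equal(min(lens), 15)
})

test_that("extract_candidates audits every somatic variant exactly once", {
  ds <- simulate_dataset(sim_config(seed = 21, n_somatic = 40,
                                    n_germline = 10))
  cand <- extract_candidates(ds$proteome, ds$variants, ds$expression)
  expect_equal(nrow(cand),
               sum(ds$variants$origin == "somatic"))
  expect_true(all(xor(cand$retained, !is.na(cand$reason))))
  ret <- cand[cand$retained, ]
  # mutated and wild-type residues sit at the mutant index
  expect_true(all(substr(ret$sequence, ret$mutant_index,
                         ret$mutant_index) == ret$alt_aa))
  expect_true(all(substr(ret$wt_sequence, ret$mutant_index,
                         ret$mutant_index) == ret$ref_aa))
  expect_true(all(nchar(ret$sequence) >= 15 & nchar(ret$sequence) <= 27))
  expect_true(all(nchar(ret$sequence) == nchar(ret$wt_sequence)))
  # mutant/wild-type pairs differ at exactly one position
  ndiff <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, ret$sequence, ret$wt_sequence)
  expect_true(all(ndiff == 1))
})

test_that("somatic frameshift and splice variants are recorded as discarded", {
  prot <- data.frame(id = "p1",
                     sequence = strrep("ACDEFGHIKLMNPQRSTVWY", 3),
                     stringsAsFactors = FALSE)
  v <- data.frame(protein_id = "p1", pos = 30L, ref_aa = "K", alt_aa = "E",
                  class = "frameshift", origin = "somatic", vaf = 0.3,
                  stringsAsFactors = FALSE)
  v$callers <- list("lofreq")
  v$n_callers <- 1L
  cand <- extract_candidates(prot, v)
  expect_false(cand$retained)
  expect_equal(cand$reason, "somatic frameshift/splice")
})
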