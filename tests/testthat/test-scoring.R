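test_that("somatic probability is the weighted caller-consensus fraction", {
  expect_equal(somatic_probability(character(0)), 0)
  expect_equal(somatic_probability(default_callers()), 1)
  expect_equal(somatic_probability(c("lofreq", "strelka")), 0.5)
  w <- c(lofreq = 3, mutect2 = 1, strelka = 1, snvsniffer = 1)
  expect_equal(somatic_probability("lofreq", w), 0.5)
  expect_error(somatic_probability("gatk"), "unknown caller")
})

test_that("purity correction recovers the cancer cell fraction with clamping", {
  expect_equal(corrected_vaf(0.5, 1.0), 1.0)
  expect_equal(corrected_vaf(0.25, 0.5), 1.0)
  expect_equal(corrected_vaf(0.05, 1.0), 0.1)
  expect_equal(corrected_vaf(0.9, 0.5), 1.0)  # clamped
  expect_error(corrected_vaf(0.2, 0), "purity")
  expect_error(corrected_vaf(1.2, 0.5), "vaf")
})

test_that("clonal probability is the CCF x somatic product, monotone in both", {
  expect_equal(clonal_probability(1, 1), 1)
  expect_equal(clonal_probability(0.7, 0), 0)
  expect_equal(clonal_probability(0.8, 0.5), 0.4)
  set.seed(8)
  a <- runif(20); b <- runif(20)
  expect_true(all(clonal_probability(a, b) <= clonal_probability(pmin(a + 0.1, 1), b)))
})

test_that("property distance is zero on identity, symmetric, and matches the table", {
  atch <- atchley_factors()
  expect_equal(property_distance("MKVA", "MKVA"), 0)
  set.seed(9)
  a <- random_peptide(12); b <- random_peptide(12)
  expect_equal(property_distance(a, b), property_distance(b, a))
  # single K -> N substitution reduces to one pairwise distance
  d_kn <- sqrt(sum((atch["K", ] - atch["N", ])^2))
  expect_equal(property_distance("AKA", "ANA"), d_kn)
  expect_error(property_distance("MK", "MKV"), "length")
})

test_that("immunogenicity map is 0 at 0, saturating, strictly increasing", {
  expect_equal(immunogenicity_probability(0), 0)
  expect_equal(immunogenicity_probability(2, tau = 2), 1 - exp(-1))
  expect_gt(immunogenicity_probability(1e6), 0.999999)
  d <- seq(0, 10, 0.5)
  expect_true(all(diff(immunogenicity_probability(d)) > 0))
})

test_that("composite score is the product of the four factors, in [0,1]", {
  expect_equal(composite_score(1, 1, 1, 1), 1)
  expect_equal(composite_score(0.3, 0, 0.9, 0.9), 0)
  expect_equal(composite_score(0.5, 0.5, 0.5, 0.5), 0.0625)
  expect_error(composite_score(1.2, 1, 1, 1), "\\[0, 1\\]")
  set.seed(10)
  for (i in 1:50) {
    f <- runif(4)
    cs <- composite_score(f[1], f[2], f[3], f[4])
    expect_equal(cs, prod(f))
    expect_true(cs >= 0 && cs <= 1)
    # monotone non-decreasing in each factor
    j <- sample(4, 1); g <- f; g[j] <- min(1, g[j] + runif(1))
    expect_gte(composite_score(g[1], g[2], g[3], g[4]), cs)
  }
})

test_that("MHC ligand probability calibrates the best rank and gates on expression", {
  set.seed(11)
  s <- random_peptide(27)
  alleles <- list(mhc1 = "al1", mhc2 = "al2")
  # unexpressed candidates have zero ligand probability
  m0 <- mhc_ligand_probability(s, alleles, mock_predictor(), 0)
  expect_equal(m0$mhc_p, 0)
  # a rank-0 oligomer with saturating expression hits the closed form
  strong <- substr(s, 3, 10)  # one 8mer
  pred <- table_predictor(stats::setNames(0, strong), default = 80)
  m <- mhc_ligand_probability(s, alleles, pred, 1e9)
  k <- scoring_params()$rank_slope; r0 <- scoring_params()$rank_midpoint
  expect_equal(m$mhc1_p, 1 / (1 + exp(k * (0 - r0))), tolerance = 1e-6)
  expect_equal(m$best_ligand1, strong)
  expect_equal(m$best_rank1, 0)
  expect_equal(m$mhc_p, max(m$mhc1_p, m$mhc2_p))
})

test_that("best rank across alleles equals the minimum over alleles", {
  set.seed(12)
  s <- random_peptide(27)
  pred <- mock_predictor()
  both <- mhc_ligand_probability(s, list(mhc1 = c("aA", "aB"),
                                         mhc2 = character(0)), pred, 50)
  single <- lapply(c("aA", "aB"), function(al) {
    mhc_ligand_probability(s, list(mhc1 = al, mhc2 = character(0)), pred, 50)
  })
  expect_equal(both$best_rank1, min(single[[1]]$best_rank1,
                                    single[[2]]$best_rank1))
})

test_that("best_rank_15mer agrees with a brute-force scan and breaks ties leftmost", {
  set.seed(13)
  pred <- mock_predictor()
  for (i in 1:10) {
    s <- random_peptide(sample(15:40, 1))
    b <- best_rank_15mer(s, "IAb", pred)
    o <- oracle_best_15mer(s, "IAb", pred)
    expect_equal(b$offset, o$offset)
    expect_equal(b$rank, o$rank)
    expect_equal(b$peptide, substr(s, b$offset, b$offset + 14))
  }
  s15 <- random_peptide(15)
  expect_equal(best_rank_15mer(s15, "IAb", pred)$peptide, s15)
  # all-equal ranks: leftmost window wins
  flat <- table_predictor(c(dummy = 1), default = 7)
  expect_equal(best_rank_15mer(random_peptide(27), "IAb", flat)$offset, 1L)
  expect_error(best_rank_15mer(random_peptide(14), "IAb", pred),
               "shorter than 15")
})

test_that("predictor adapters are deterministic and validated", {
  p <- mock_predictor()
  peps <- replicate(5, random_peptide(9))
  r1 <- predict_ranks(p, peps, "H2Kb")
  r2 <- predict_ranks(p, peps, "H2Kb")
  expect_identical(r1, r2)
  expect_true(all(r1 >= 0 & r1 <= 100))
  # allele changes the scores
  expect_false(identical(r1, predict_ranks(p, peps, "H2Db")))
  bad <- function(peptides, allele) rep(-1, length(peptides))
  expect_error(predict_ranks(bad, peps, "x"), "invalid scores")
})

test_that("score_candidates fills a coherent score vector per retained candidate", {
  ds <- simulate_dataset(sim_config(seed = 31, n_somatic = 25))
  cand <- extract_candidates(ds$proteome, ds$variants, ds$expression)
  sc <- score_candidates(cand, ds$purity,
                         list(mhc1 = "H2Kb", mhc2 = "IAb"),
                         mock_predictor())
  expect_equal(nrow(sc), sum(cand$retained))
  for (col in c("somatic_p", "clonal_p", "mhc_p", "immunogenicity_p",
                "composite")) {
    expect_true(all(sc[[col]] >= 0 & sc[[col]] <= 1), info = col)
  }
  expect_equal(sc$composite,
               sc$somatic_p * sc$clonal_p * sc$mhc_p * sc$immunogenicity_p)
  expect_equal(sc$clonal_p, sc$ccf * sc$somatic_p)
})
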