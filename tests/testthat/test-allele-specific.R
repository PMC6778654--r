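test_that("allele-specific transforms reproduce the reference cases", {
  # wild type is (1, 1) at any admixture
  cn <- allele_specific_cn(1, 0, 0.3)
  expect_equal(cn$cnA, 1)
  expect_equal(cn$cnB, 1)
  # clonal hemizygous deletion seen at 50% purity
  cn <- allele_specific_cn(2 / 3, log2(3 / 4), 0.5)
  expect_equal(cn$cnA, 1, tolerance = 1e-12)
  expect_equal(cn$cnB, 0, tolerance = 1e-12)
  expect_equal(log2_corr(0, 0), 0)
  expect_equal(log2_corr(log2(3 / 4), 0.5), -1)
  # signal implying zero tumor copies has no finite corrected logR
  expect_true(is.na(log2_corr(log2(0.2), 0.2)))
  expect_error(allele_specific_cn(0.5, 0, 1), class = "ascn_domain_error")
})

test_that("the major-allele expression equals its algebraic simplification", {
  grid <- expand.grid(beta = seq(0.01, 1, by = 0.01),
                      G = seq(0, 0.95, by = 0.05),
                      logRp = seq(-2, 2, by = 0.25))
  cn <- allele_specific_cn(grid$beta, grid$logRp, grid$G)
  simplified <- ((2 - grid$beta) * 2^grid$logRp - grid$G) / (1 - grid$G)
  expect_lt(max(abs(cn$cnA - simplified)), 1e-10)
  # and the total always satisfies cnA + cnB = 2 * 2^log2_corr
  lc <- log2_corr(grid$logRp, grid$G)
  ok <- !is.na(lc)
  expect_lt(max(abs(cn$cnA[ok] + cn$cnB[ok] - 2 * 2^lc[ok])), 1e-9)
})

test_that("the transform inverts the clonal forward model for integer states", {
  set.seed(13)
  for (i in 1:200) {
    a <- sample(0:6, 1)
    b <- sample(0:a, 1)
    if (a == 0 && b == 0) a <- b <- 1   # (0,0) has no finite logR
    G <- runif(1, 0, 0.9)
    sig <- expected_signal(a, b, 1, G, 0)
    cn <- allele_specific_cn(sig$beta.exp, sig$logR.exp, G)
    expect_lt(abs(cn$cnA - a), 1e-9)
    expect_lt(abs(cn$cnB - b), 1e-9)
  }
})

test_that("integer calls use a strict distance threshold and clamp axis noise", {
  expect_equal(integer_cn_calls(1.2), 1)
  expect_true(is.na(integer_cn_calls(1.5)))       # exactly at the threshold
  expect_equal(integer_cn_calls(c(2.9, 0.1)), c(3, 0))
  expect_equal(integer_cn_calls(-0.1), 0)          # small negatives are noise
  expect_true(is.na(integer_cn_calls(-0.6)))
  expect_equal(integer_cn_calls(1.8, allelic_imbalance_th = 0.3), 2)
  expect_true(is.na(integer_cn_calls(1.6, allelic_imbalance_th = 0.3)))
  expect_error(integer_cn_calls(1, allelic_imbalance_th = 0), class = "ascn_domain_error")
})

test_that("the allele-specific table recovers simulated states", {
  # CN-LOH at 20% admixture plus deletions and gains, all clonal
  states <- data.frame(cnA = c(1, 1, 2, 2, 2), cnB = c(1, 0, 0, 1, 2), clonality = 1)
  segs <- data.frame(chrom = paste0("chr", 1:5), start = 1, end = 3e6,
                     cnA = states$cnA, cnB = states$cnB, clonality = 1)
  sim <- simulate_tumor(tumor_model(segs, admixture = 0.2, coverage_tumor = 120,
                                    coverage_normal = 120),
                        seed = 17)
  bt <- compute_beta_table(sim$seg_tb, sim$pileup_tumor, sim$pileup_normal)
  pl <- compute_ploidy(bt)
  adm <- compute_dna_admixture(bt, pl)
  tb <- compute_allele_specific_scna_table(bt, pl, adm)
  expect_equal(tb$cnA.int, states$cnA)
  expect_equal(tb$cnB.int, states$cnB)
  loh <- which(states$cnA == 2 & states$cnB == 0)
  expect_equal(tb$log2.corr[loh], 0, tolerance = 0.15)
  expect_true(all(tb$cnA >= tb$cnB))
})

test_that("segments without beta keep the corrected logR only", {
  bt <- fake_beta_table(logR = c(0, -0.5), beta = c(0.98, NA))
  pl <- data.frame(sample = "fake1", ploidy = 2, logR.shift = 0)
  adm <- data.frame(sample = "fake1", adm = 0.2, adm.min = 0.15, adm.max = 0.25)
  tb <- compute_allele_specific_scna_table(bt, pl, adm)
  expect_true(is.na(tb$cnA[2]) && is.na(tb$cnB[2]))
  expect_false(is.na(tb$log2.corr[2]))
})
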