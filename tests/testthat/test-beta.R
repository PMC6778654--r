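test_that("fully balanced segments give beta 1 and pure deletions give beta 0", {
  est <- estimate_beta(rep(0.5, 50), rep(100, 50))
  expect_equal(est$beta, 1)
  expect_equal(est$nsnps, 50)
  expect_equal(est$cov, 100)
  est0 <- estimate_beta(rep(c(0, 1), 25), rep(100, 50))
  expect_equal(est0$beta, 0)
})

test_that("a 1:9 normal:deleted-tumor cell mixture yields beta near 2/11", {
  # AF modes at 1/11 and 10/11 are the signature of a clonal hemizygous
  # deletion at 10% admixture
  af <- rep(c(1 / 11, 10 / 11), each = 75)
  est <- estimate_beta(af, rep(220, 150))
  expect_equal(est$beta, 2 / 11, tolerance = 0.02)
})

test_that("beta estimates match the exhaustive-grid likelihood oracle", {
  set.seed(42)
  for (i in 1:12) {
    cov <- sample(10:30, 5, replace = TRUE)
    af <- rbinom(5, cov, sample(c(0.2, 0.5, 0.8), 5, replace = TRUE)) / cov
    est <- estimate_beta(af, cov)$beta
    orc <- oracle_beta_mle(af, cov, step = 1e-4)
    expect_lt(abs(est - orc), 1e-3)
  }
})

test_that("the folded likelihood is invariant under af mirroring", {
  set.seed(7)
  for (i in 1:5) {
    cov <- sample(30:80, 20, replace = TRUE)
    k <- rbinom(20, cov, 0.3)
    b1 <- estimate_beta(k / cov, cov)$beta
    b2 <- estimate_beta((cov - k) / cov, cov)$beta
    expect_equal(b1, b2, tolerance = 1e-9)
  }
})

test_that("beta estimation is insensitive to a global coverage rescaling", {
  # resampling at 4x coverage must not bias the estimator
  true_beta <- 0.4
  est_at_cov <- function(cov_mean, seed) {
    set.seed(seed)
    reps <- vapply(1:40, function(r) {
      cov <- rpois(60, cov_mean)
      p <- ifelse(runif(60) < 0.5, true_beta / 2, 1 - true_beta / 2)
      estimate_beta(rbinom(60, cov, p) / pmax(cov, 1), cov)$beta
    }, numeric(1))
    mean(reps)
  }
  expect_equal(est_at_cov(40, 11), true_beta, tolerance = 0.03)
  expect_equal(est_at_cov(160, 12), true_beta, tolerance = 0.03)
})

test_that("informative-SNP selection applies the heterozygosity window and intersection", {
  normal <- data.frame(chrom = "chr1", pos = c(10, 20, 30, 40),
                       af = c(0.5, 0.05, 0.75, 0.5), cov = 30)
  tumor <- data.frame(chrom = "chr1", pos = c(10, 20, 30, 99),
                      af = c(0.9, 0.5, 0.6, 0.5), cov = 40)
  snps <- select_informative_snps(normal, tumor)
  expect_equal(snps$pos, c(10, 30))  # 20 fails the window, 40/99 fail the intersection
  expect_warning(
    select_informative_snps(normal[2, , drop = FALSE], tumor),
    class = "ascn_no_informative_snps")
})

test_that("the beta table honors the SNP-count and coverage filters", {
  seg <- data.frame(sample = "s", chrom = "chr1",
                    start = c(1, 1001), end = c(1000, 2000), logR = 0)
  pos <- c(seq(10, 990, by = 10), 1005, 1010, 1015)   # 98 SNPs then 3 SNPs
  normal <- data.frame(chrom = "chr1", pos = pos, af = 0.5, cov = 60)
  tumor <- data.frame(chrom = "chr1", pos = pos, af = 0.5, cov = 60)
  bt <- compute_beta_table(seg, tumor, normal, min_required_snps = 10)
  expect_equal(nrow(bt), 2)
  expect_equal(bt$nsnps, c(99, 3))
  expect_false(is.na(bt$beta[1]))
  expect_true(is.na(bt$beta[2]))      # too few SNPs: reported but not estimated
  expect_true(bt$beta.min[1] <= bt$beta[1] && bt$beta[1] <= bt$beta.max[1])
  # matched normal on a diploid germline: n_beta near 1
  expect_equal(bt$n_beta[1], 1, tolerance = 0.05)
})

test_that("a diploid wild-type genome without admixture has beta near 1 everywhere", {
  model <- tumor_model(
    data.frame(chrom = paste0("chr", 1:6), start = 1, end = 2e6,
               cnA = 1, cnB = 1, clonality = 1),
    admixture = 0, coverage_tumor = 80, coverage_normal = 80)
  sim <- simulate_tumor(model, seed = 31)
  bt <- compute_beta_table(sim$seg_tb, sim$pileup_tumor, sim$pileup_normal)
  expect_true(all(!is.na(bt$beta)))
  expect_true(all(bt$beta >= 0.95))
})

test_that("segments with no overlapping informative SNP trigger a structured warning", {
  seg <- data.frame(chrom = "chr9", start = 1, end = 1000, logR = 0)
  pu <- data.frame(chrom = "chr1", pos = c(10, 20, 30), af = 0.5, cov = 50)
  expect_warning(
    bt <- compute_beta_table(seg, pu, pu),
    class = "ascn_no_segment_snps")
  expect_true(all(is.na(bt$beta)))
})

test_that("the beta-table summary formats counts and degenerate quantiles", {
  bt <- fake_beta_table(logR = rnorm(65, 0, 0.01), beta = c(rep(0.97, 49), rep(NA, 16)))
  s <- summarize_beta_table(bt)
  expect_equal(s$n_valid, 49)
  expect_equal(s$pct_valid, 75)
  expect_match(paste(capture.output(print(s)), collapse = "\n"),
               "valid beta: 49 \\(75%\\)")

  s0 <- summarize_beta_table(bt[0, , drop = FALSE])
  expect_true(all(is.na(s0$length_quantiles)))
  expect_match(paste(capture.output(print(s0)), collapse = "\n"), "undefined")

  s1 <- summarize_beta_table(bt[1, , drop = FALSE])
  expect_true(all(s1$nsnps_quantiles == bt$nsnps[1]))
})
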