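test_that("model validation rejects inconsistent specifications", {
  base <- data.frame(chrom = "chr1", start = 1, end = 1e6, cnA = 1, cnB = 1,
                     clonality = 1)
  expect_s3_class(tumor_model(base), "tumor_model")
  bad <- rbind(base, data.frame(chrom = "chr1", start = 5e5, end = 2e6,
                                cnA = 1, cnB = 0, clonality = 1))
  expect_error(tumor_model(bad), class = "ascn_model_error")
  expect_error(tumor_model(transform(base, cnB = 2)), class = "ascn_model_error")
  expect_error(tumor_model(base, admixture = 1), class = "ascn_model_error")
})

test_that("simulations are reproducible given the seed", {
  model <- scenario_model("diploid_clean")
  s1 <- simulate_tumor(model, seed = 3)
  s2 <- simulate_tumor(model, seed = 3)
  expect_identical(s1, s2)
  s3 <- simulate_tumor(model, seed = 4)
  expect_false(identical(s1$pileup_tumor, s3$pileup_tumor))
})

test_that("cell-mixture compositions reproduce the textbook beta values", {
  # one normal cell with nine tumor cells carrying a hemizygous deletion:
  # admixture 1/10, beta 2/11
  m1 <- tumor_model(data.frame(chrom = "chr1", start = 1, end = 2e6,
                               cnA = 1, cnB = 0, clonality = 1),
                    admixture = 1 / 10, coverage_tumor = 500,
                    coverage_normal = 500)
  sim1 <- simulate_tumor(m1, seed = 91)
  snps <- select_informative_snps(sim1$pileup_normal, sim1$pileup_tumor)
  expect_gt(nrow(snps), 100)
  expect_equal(estimate_beta(snps$af_tumor, snps$cov_tumor)$beta, 2 / 11,
               tolerance = 0.02)

  # same sample but the deletion present in only six of the nine tumor
  # cells: beta 8/14
  m2 <- tumor_model(data.frame(chrom = "chr1", start = 1, end = 2e6,
                               cnA = 1, cnB = 0, clonality = 2 / 3),
                    admixture = 1 / 10, coverage_tumor = 500,
                    coverage_normal = 500)
  sim2 <- simulate_tumor(m2, seed = 92)
  snps2 <- select_informative_snps(sim2$pileup_normal, sim2$pileup_tumor)
  expect_equal(estimate_beta(snps2$af_tumor, snps2$cov_tumor)$beta, 8 / 14,
               tolerance = 0.02)
})

test_that("tumor allelic fractions converge to the mixture modes", {
  # clonal hemizygous deletion at 50% admixture: AF modes 1/3 and 2/3,
  # folded mean beta 2/3
  m <- tumor_model(data.frame(chrom = "chr1", start = 1, end = 3e6,
                              cnA = 1, cnB = 0, clonality = 1),
                   admixture = 0.5, coverage_tumor = 2000, coverage_normal = 500)
  sim <- simulate_tumor(m, seed = 93)
  af <- sim$pileup_tumor$af
  folded <- ifelse(af > 0.5, 1 - af, af)
  expect_equal(mean(folded), 1 / 3, tolerance = 0.01)
  expect_equal(2 * mean(folded) / (mean(folded) + mean(1 - folded)), 2 / 3,
               tolerance = 0.01)
})

test_that("wild-type logR centers on zero in a diploid model without noise", {
  segs <- data.frame(chrom = paste0("chr", 1:4), start = 1, end = 1e6,
                     cnA = 1, cnB = 1, clonality = 1)
  m <- tumor_model(segs, admixture = 0.2, logr_noise_sd = 0)
  sim <- simulate_tumor(m, seed = 94)
  expect_true(all(abs(sim$seg_tb$logR) < 0.01))
  expect_equal(m$ploidy, 2)
})

test_that("the fixture suite reproduces its design ploidies and failure modes", {
  dir <- withr::local_tempdir()
  res <- make_fixture_suite(dir, seed = 5)
  expect_true(all(file.exists(file.path(dir, c(
    "diploid_clean_segments.tsv", "aneuploid_shifted_tumor_pileup.tsv",
    "subclonal_normal_pileup.tsv", "quiet_segments.tsv")))))

  # the shifted genome: wild-type shift -0.34, ploidy 2.53
  sim <- res$aneuploid_shifted
  expect_equal(sim$truth$ploidy, 2.53, tolerance = 0.005)
  bt <- compute_beta_table(read_segment_table(file.path(dir, "aneuploid_shifted_segments.tsv")),
                           read_pileup_table(file.path(dir, "aneuploid_shifted_tumor_pileup.tsv")),
                           read_pileup_table(file.path(dir, "aneuploid_shifted_normal_pileup.tsv")))
  pl <- compute_ploidy(bt)
  expect_equal(pl$ploidy, 2.53, tolerance = 0.05)

  # the diploid genome: shift near 0, ploidy near 2
  bt_d <- compute_beta_table(res$diploid_clean$seg_tb,
                             res$diploid_clean$pileup_tumor,
                             res$diploid_clean$pileup_normal)
  pl_d <- compute_ploidy(bt_d)
  expect_lt(abs(pl_d$logR.shift), 0.03)
  expect_equal(pl_d$ploidy, 2, tolerance = 0.05)
})
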