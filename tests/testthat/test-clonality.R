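test_that("the cell-mixture forward model reproduces the reference signals", {
  expect_equal(expected_signal(1, 0, 1, 0, 0),
               data.frame(beta.exp = 0, logR.exp = -1))
  s <- expected_signal(1, 0, 1, 0.5, 0)
  expect_equal(s$beta.exp, 2 / 3)
  expect_equal(s$logR.exp, log2(3 / 4))
  # clonal homozygous deletion in a pure sample: all signal vanishes
  s <- expected_signal(0, 0, 1, 0, 0)
  expect_equal(s$beta.exp, 1)
  expect_equal(s$logR.exp, -Inf)
  # balanced states have beta 1 regardless of clonality and admixture
  for (a in 1:4) {
    expect_equal(expected_signal(a, a, 0.7, 0.3, 0)$beta.exp, 1)
  }
  expect_error(expected_signal(1, 2, 1, 0, 0), class = "ascn_domain_error")
})

test_that("a half-clonal deletion in a pure sample fits clonality 0.5", {
  fit <- scna_clonality_fit(beta = 2 / 3, logRp = log2(3 / 4), admixture = 0)
  expect_true(fit$analysed)
  expect_equal(c(fit$cnA, fit$cnB), c(1, 0))
  expect_equal(fit$clonality, 0.5, tolerance = 1e-6)
})

test_that("the deletion closed form is monotone and exact at matched admixture", {
  G <- 0.3
  cl <- function(b) (1 - b / (2 - b)) / (1 - G)
  b_at_G <- expected_signal(1, 0, 1, G, 0)$beta.exp
  expect_equal(cl(b_at_G), 1, tolerance = 1e-12)
  bs <- seq(b_at_G, 0.95, length.out = 20)
  expect_true(all(diff(vapply(bs, cl, numeric(1))) < 0))
})

test_that("the state/clonality fit agrees with the exhaustive-grid oracle", {
  set.seed(55)
  for (i in 1:50) {
    a <- sample(0:4, 1); b <- if (a > 0) sample(0:min(a, 2), 1) else 0
    if (a == 1 && b == 1) a <- 2
    cl_true <- runif(1, 0.2, 1)
    G <- runif(1, 0, 0.6)
    sig <- expected_signal(a, b, cl_true, G, 0)
    beta <- min(1, max(0, sig$beta.exp + rnorm(1, 0, 0.02)))
    logRp <- sig$logR.exp + rnorm(1, 0, 0.05)
    if (!is.finite(logRp)) next
    fit <- scna_clonality_fit(beta, logRp, admixture = G, fit_tol = Inf)
    if (!fit$analysed) next   # the wild-type gate legitimately refuses
    orc <- oracle_clonality_fit(beta, logRp, G)
    # the returned optimum is at least as good as the brute-force optimum
    # under the selection objective (weighted residual + parsimony)
    obj <- function(aa, bb, cc) {
      s <- expected_signal(aa, bb, cc, G, 0)
      (s$beta.exp - beta)^2 + 0.25 * (s$logR.exp - logRp)^2 + 2e-3 * (aa + bb)
    }
    expect_lte(obj(fit$cnA, fit$cnB, fit$clonality), orc$value + 1e-6)
  }
})

test_that("clonality discretization follows the bound/threshold rules", {
  expect_equal(discretize_clonality(0.95, 0.90, 0.99), "clonal")
  expect_equal(discretize_clonality(0.5, 0.3, 0.7), "subclonal")
  expect_equal(discretize_clonality(0.9, 0.8, 0.95), "uncertain.clonal")
  expect_equal(discretize_clonality(0.8, 0.7, 0.9), "uncertain.subclonal")
  expect_equal(discretize_clonality(NA, NA, NA), "not.analysed")
  expect_equal(discretize_clonality(c(0.95, 0.5), c(0.90, 0.3), c(0.99, 0.7)),
               c("clonal", "subclonal"))
})

test_that("the SCNA clonality table classifies simulated clones and subclones", {
  sim <- simulate_tumor(scenario_model("subclonal"), seed = 71)
  res <- run_pipeline(sim)
  tb <- compute_scna_clonality_table(res$bt, res$pl, res$adm)
  truth <- sim$truth$segments
  clonal_del <- which(truth$cnB == 0 & truth$clonality == 1)
  sub_del <- which(truth$cnB == 0 & truth$clonality == 0.5)
  wt <- which(truth$cnA == 1 & truth$cnB == 1)
  expect_true(mean(tb$clonality[clonal_del] > 0.9) >= 0.8)
  expect_equal(mean(tb$clonality[sub_del]), 0.5, tolerance = 0.1)
  expect_true(all(tb$clonality.status[wt] == "not.analysed"))
  an <- !is.na(tb$clonality)
  expect_true(all(tb$clonality.min[an] <= tb$clonality[an] + 1e-9))
  expect_true(all(tb$clonality.max[an] >= tb$clonality[an] - 1e-9))
})

test_that("SNV VAF adjustment and clonality follow the dilution model", {
  expect_equal(snv_adjusted_vaf(0.5, 0, 2), 0.5)
  expect_equal(snv_adjusted_vaf(0.25, 0.5, 2), 0.5)
  expect_equal(snv_clonality(0.3, 0, 2, 1), 0.6)
  expect_equal(snv_clonality(1 / 3, 0, 3, 1), 1)
  expect_equal(snv_clonality(0, 0.3, 2, 1), 0)
  expect_equal(snv_expected_vaf(1, 0, 3, 1), 1 / 3)
  expect_equal(snv_expected_vaf(0.6, 0, 2, 1), 0.3)
  # linear in VAF; doubling multiplicity halves clonality
  expect_equal(snv_clonality(0.2, 0.3, 2, 1, cap = FALSE) * 2,
               snv_clonality(0.4, 0.3, 2, 1, cap = FALSE))
  expect_equal(snv_clonality(0.2, 0.3, 4, 2, cap = FALSE) * 2,
               snv_clonality(0.2, 0.3, 4, 1, cap = FALSE))
  expect_error(snv_clonality(0.3, 0, 2, 0), class = "ascn_domain_error")
})

test_that("SNV clonality recovers simulated mixtures and flags unmapped variants", {
  segs <- data.frame(chrom = paste0("chr", 1:6), start = 1, end = 2e6,
                     cnA = c(1, 1, 1, 1, 1, 1), cnB = c(1, 1, 1, 1, 0, 0),
                     clonality = 1)
  snvs <- data.frame(chrom = rep(c("chr1", "chr2", "chr3", "chr4"), each = 5),
                     pos = rep(seq(2e5, 1e6, length.out = 5), 4),
                     multiplicity = 1,
                     clonality = rep(c(1, 0.4), each = 10))
  model <- tumor_model(segs, admixture = 0.2, coverage_tumor = 500,
                       coverage_normal = 200, snvs = snvs)
  sim <- simulate_tumor(model, seed = 81)
  res <- run_pipeline(sim)
  snv_tb <- compute_snv_clonality_table(sim$snv_reads, res$bt, res$pl, res$adm)
  clonal <- which(sim$truth$snvs$clonality == 1)
  sub <- which(sim$truth$snvs$clonality == 0.4)
  expect_equal(mean(snv_tb$SNV.clonality[clonal]), 1, tolerance = 0.1)
  expect_equal(mean(snv_tb$SNV.clonality[sub]), 0.4, tolerance = 0.05)
  expect_true(all(snv_tb$SNV.clonality.status[clonal] %in%
                    c("clonal", "uncertain.clonal")))
  expect_true(all(snv_tb$t_af_corr >= 0 & snv_tb$t_af_corr <= 1.2, na.rm = TRUE))
  expect_equal(sum(snv_tb$excluded), 1)  # 5% upper tail of 20 variants

  # a variant outside every segment is not analysed
  stray <- sim$snv_reads[1, ]
  stray$chrom <- "chrX"
  out <- compute_snv_clonality_table(rbind(sim$snv_reads, stray),
                                     res$bt, res$pl, res$adm)
  expect_equal(out$SNV.clonality.status[nrow(out)], "not.analysed")

  # empty input gives an empty, well-formed output
  empty <- compute_snv_clonality_table(sim$snv_reads[0, ], res$bt, res$pl, res$adm)
  expect_equal(nrow(empty), 0)
  expect_true("SNV.clonality.status" %in% names(empty))
})
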