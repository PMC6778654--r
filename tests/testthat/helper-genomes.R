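# Simulated-genome builders shared by the recovery tests. All randomness is
# driven by the seed argument; callers fix seeds so runs are reproducible.

# A fabricated beta table (no pileups involved) for tests that exercise the
# sample-level estimators directly on known per-segment signal.
fake_beta_table <- function(logR, beta, nsnps = 200, cov = 100, n_beta = 1,
                            seg_len = 2e6, sample = "fake1") {
  n <- length(logR)
  start <- seq(1, by = seg_len, length.out = n)
  data.frame(sample = sample, chrom = "chr1", start = start,
             end = start + seg_len - 1, logR = logR,
             beta = beta, nsnps = rep_len(nsnps, n), cov = rep_len(cov, n),
             n_beta = rep_len(n_beta, n),
             beta.min = pmax(0, beta - 0.02), beta.max = pmin(1, beta + 0.02),
             stringsAsFactors = FALSE)
}

# Random tumor genome with guaranteed wild-type anchor segments and clonal
# hemizygous deletions, plus a variable mix of gains, CN-LOH and subclonal
# deletions. Admixture in [0.1, 0.7]; implied sample ploidy spans roughly
# 1.8 to 3.3 across genome types.
random_genome_model <- function(seed, seg_len = 8e5, n_chrom = 4, per_chrom = 6,
                                coverage = 150, logr_noise_sd = 0.05,
                                with_snvs = FALSE) {
  set.seed(seed)
  n <- n_chrom * per_chrom
  G <- runif(1, 0.1, 0.7)
  genome_type <- sample(c("loss", "balancedish", "gain"), 1)
  n_wt <- 9
  n_del <- 6
  extra <- switch(genome_type,
    loss = data.frame(cnA = c(1, 1, 1), cnB = c(0, 0, 0), clonality = 1),
    balancedish = data.frame(cnA = c(2, 2, 2), cnB = c(1, 0, 1), clonality = 1),
    gain = data.frame(cnA = c(2, 2, 3, 3), cnB = c(2, 1, 1, 2), clonality = 1))
  n_sub <- 3
  n_fill <- n - n_wt - n_del - nrow(extra) - n_sub
  fill_pool <- data.frame(cnA = c(2, 2, 2, 3), cnB = c(1, 0, 2, 1), clonality = 1)
  fill <- fill_pool[sample.int(nrow(fill_pool), n_fill, replace = TRUE), ]
  states <- rbind(
    data.frame(cnA = 1, cnB = 1, clonality = 1)[rep(1, n_wt), ],
    data.frame(cnA = 1, cnB = 0, clonality = 1)[rep(1, n_del), ],
    extra,
    data.frame(cnA = 1, cnB = 0, clonality = runif(n_sub, 0.35, 0.65)),
    fill)
  states <- states[sample.int(n), ]
  grid <- expand.grid(slot = seq_len(per_chrom), chrom = seq_len(n_chrom))
  segments <- data.frame(
    chrom = paste0("chr", grid$chrom),
    start = (grid$slot - 1) * seg_len + 1,
    end = grid$slot * seg_len,
    cnA = states$cnA, cnB = states$cnB, clonality = states$clonality,
    stringsAsFactors = FALSE)
  snvs <- NULL
  if (with_snvs) {
    # SNVs on wild-type and clonally deleted segments (multiplicity 1),
    # clonality either clonal or clearly subclonal
    host <- which(segments$cnA == 1 & segments$clonality == 1)
    host <- host[seq_len(min(12, length(host)))]
    snvs <- data.frame(
      chrom = segments$chrom[host],
      pos = floor((segments$start[host] + segments$end[host]) / 2),
      multiplicity = 1,
      clonality = rep(c(1, 0.4), length.out = length(host)))
  }
  tumor_model(segments, admixture = G, coverage_tumor = coverage,
              coverage_normal = coverage, logr_noise_sd = logr_noise_sd,
              snvs = snvs)
}

# Full pipeline on one simulated genome: beta table, ploidy, admixture.
run_pipeline <- function(sim, error_tb = default_error_table()) {
  bt <- compute_beta_table(sim$seg_tb, sim$pileup_tumor, sim$pileup_normal,
                           error_tb = error_tb)
  pl <- compute_ploidy(bt)
  adm <- compute_dna_admixture(bt, pl, error_tb = error_tb)
  list(bt = bt, pl = pl, adm = adm)
}
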