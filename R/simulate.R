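# Synthetic matched tumor/normal data with known ground truth.
#
# The generator realizes the same cell-mixture model the estimators invert:
# informative SNPs are placed uniformly at a fixed density, normal allelic
# fractions are Binomial(cov, 1/2), tumor allelic fractions follow the
# per-allele read contributions rA/rB of the aberrant state mixed at its
# clonality with wild type and admixed normal DNA, per-segment tumor
# coverage scales with (rA + rB)/2 relative to the genome-wide mean (which
# reproduces the mean-coverage normalization of logR and hence the
# wild-type shift of aneuploid genomes), and SNV read counts are binomial
# around the expected VAF of their clonality/multiplicity.

#' Specify a synthetic tumor
#'
#' @param segments data.frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{cnA}, \code{cnB} (integer allele copies of the
#'   aberrant state) and \code{clonality} (fraction of tumor cells carrying
#'   it; wild-type segments use cnA = cnB = 1 at any clonality). Segments
#'   must not overlap within a chromosome.
#' @param admixture fraction of non-tumor DNA G in [0, 1).
#' @param coverage_tumor,coverage_normal mean sequencing depths.
#' @param snp_density_per_kb informative SNPs per kb (0.33 matches the
#'   genome-wide density of common heterozygous polymorphisms).
#' @param logr_noise_sd Gaussian noise added to the per-segment logR.
#' @param snvs optional data.frame with columns \code{chrom}, \code{pos},
#'   \code{multiplicity}, \code{clonality} describing somatic SNVs.
#' @return object of class \code{tumor_model}; its \code{ploidy} element is
#'   the length-weighted mean total copy number of the sample relative to a
#'   diploid reference (the quantity the logR-shift equation estimates).
#' @export
tumor_model <- function(segments, admixture = 0.3,
                        coverage_tumor = 100, coverage_normal = 100,
                        snp_density_per_kb = 0.33, logr_noise_sd = 0.05,
                        snvs = NULL) {
  stopifnot(is.data.frame(segments))
  need <- c("chrom", "start", "end", "cnA", "cnB", "clonality")
  miss <- setdiff(need, names(segments))
  if (length(miss)) {
    ascn_stop("ascn_model_error", paste("segment spec lacks columns:", paste(miss, collapse = ", ")))
  }
  if (any(segments$end < segments$start)) {
    ascn_stop("ascn_model_error", "segment end < start")
  }
  if (any(segments$cnB > segments$cnA | segments$cnB < 0)) {
    ascn_stop("ascn_model_error", "allele copies must satisfy 0 <= cnB <= cnA")
  }
  if (any(segments$clonality < 0 | segments$clonality > 1)) {
    ascn_stop("ascn_model_error", "clonality must lie in [0, 1]")
  }
  if (admixture < 0 || admixture >= 1) {
    ascn_stop("ascn_model_error", "admixture must lie in [0, 1)")
  }
  if (snp_density_per_kb <= 0) ascn_stop("ascn_model_error", "snp density must be positive")
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)])) {
      ascn_stop("ascn_model_error", sprintf("overlapping segments on %s", ch))
    }
  }
  # per-allele relative contributions of each segment in the bulk sample
  G <- admixture
  rA <- G + (1 - G) * (segments$clonality * segments$cnA + 1 - segments$clonality)
  rB <- G + (1 - G) * (segments$clonality * segments$cnB + 1 - segments$clonality)
  len <- segments$end - segments$start + 1
  norm <- sum(len * (rA + rB) / 2) / sum(len)
  structure(list(segments = segments, admixture = admixture,
                 coverage_tumor = coverage_tumor, coverage_normal = coverage_normal,
                 snp_density_per_kb = snp_density_per_kb,
                 logr_noise_sd = logr_noise_sd, snvs = snvs,
                 rA = rA, rB = rB, mean_relative_coverage = norm,
                 ploidy = 2 * norm, logR_shift = -log2(norm)),
            class = "tumor_model")
}

#' @export
print.tumor_model <- function(x, ...) {
  cat(sprintf("tumor_model: %d segments, admixture %.3f, ploidy %.3f (shift %.3f)\n",
              nrow(x$segments), x$admixture, x$ploidy, x$logR_shift))
  invisible(x)
}

#' Simulate matched tumor/normal tables from a tumor model
#'
#' Generates the three analysis inputs (segment table with noisy logR,
#' tumor pileup, matched normal pileup) plus an SNV read-count table when
#' the model specifies SNVs, and a truth record with every simulated
#' quantity. Runs are reproducible: the same model and seed give identical
#' outputs.
#'
#' @param model a \code{\link{tumor_model}}.
#' @param seed integer RNG seed.
#' @param sample sample identifier stamped on the tables.
#' @return list with \code{seg_tb}, \code{pileup_tumor},
#'   \code{pileup_normal}, \code{snv_reads} (NULL when no SNVs are
#'   specified) and \code{truth}.
#' @export
simulate_tumor <- function(model, seed = 1L, sample = "sim1") {
  stopifnot(inherits(model, "tumor_model"))
  set.seed(seed)
  seg <- model$segments
  G <- model$admixture
  norm <- model$mean_relative_coverage
  nseg <- nrow(seg)
  len <- seg$end - seg$start + 1
  rel <- (model$rA + model$rB) / 2

  snp_chrom <- character(0); snp_pos <- numeric(0); snp_seg <- integer(0)
  for (i in seq_len(nseg)) {
    nsnp <- stats::rpois(1, len[i] / 1000 * model$snp_density_per_kb)
    if (nsnp == 0) next
    pos <- sort(sample.int(len[i], min(nsnp, len[i]))) + seg$start[i] - 1
    snp_chrom <- c(snp_chrom, rep(seg$chrom[i], length(pos)))
    snp_pos <- c(snp_pos, pos)
    snp_seg <- c(snp_seg, rep(i, length(pos)))
  }
  nsnp <- length(snp_pos)

  cov_n <- stats::rpois(nsnp, model$coverage_normal)
  af_n <- ifelse(cov_n > 0, stats::rbinom(nsnp, cov_n, 0.5) / pmax(cov_n, 1), 0)
  cov_t <- stats::rpois(nsnp, model$coverage_tumor * rel[snp_seg] / norm)
  # the alternative base sits on allele A or B with equal probability
  on_A <- stats::runif(nsnp) < 0.5
  tot <- model$rA[snp_seg] + model$rB[snp_seg]
  p_alt <- ifelse(tot > 0,
                  ifelse(on_A, model$rA[snp_seg], model$rB[snp_seg]) / tot, 0)
  af_t <- ifelse(cov_t > 0, stats::rbinom(nsnp, cov_t, p_alt) / pmax(cov_t, 1), 0)

  seg_tb <- data.frame(sample = sample, chrom = seg$chrom, start = seg$start,
                       end = seg$end,
                       logR = log2(rel / norm) + stats::rnorm(nseg, 0, model$logr_noise_sd),
                       stringsAsFactors = FALSE)
  pileup_normal <- data.frame(chrom = snp_chrom, pos = snp_pos, af = af_n,
                              cov = cov_n, stringsAsFactors = FALSE)
  pileup_tumor <- data.frame(chrom = snp_chrom, pos = snp_pos, af = af_t,
                             cov = cov_t, stringsAsFactors = FALSE)

  snv_reads <- NULL
  truth_snv <- NULL
  if (!is.null(model$snvs) && nrow(model$snvs) > 0) {
    sv <- model$snvs
    seg_of <- vapply(seq_len(nrow(sv)), function(i) {
      j <- which(seg$chrom == sv$chrom[i] & seg$start <= sv$pos[i] & seg$end >= sv$pos[i])
      if (length(j)) j[1] else NA_integer_
    }, integer(1))
    cnT_t <- ifelse(is.na(seg_of), 2,
                    seg$clonality[seg_of] * (seg$cnA[seg_of] + seg$cnB[seg_of]) +
                      (1 - seg$clonality[seg_of]) * 2)
    vaf_exp <- snv_expected_vaf(sv$clonality, G, cnT_t, sv$multiplicity)
    depth <- stats::rpois(nrow(sv), model$coverage_tumor *
                            ifelse(is.na(seg_of), 1, rel[seg_of]) / norm)
    alt <- stats::rbinom(nrow(sv), depth, clamp01(vaf_exp))
    snv_reads <- data.frame(sample = sample, chrom = sv$chrom, pos = sv$pos,
                            ref = "A", alt = "T",
                            rc_ref_tumor = depth - alt, rc_alt_tumor = alt,
                            stringsAsFactors = FALSE)
    truth_snv <- cbind(sv, vaf_expected = vaf_exp, cnT_tumor = cnT_t)
  }

  list(seg_tb = seg_tb, pileup_tumor = pileup_tumor, pileup_normal = pileup_normal,
       snv_reads = snv_reads,
       truth = list(admixture = G, ploidy = model$ploidy,
                    logR_shift = model$logR_shift, segments = seg,
                    snvs = truth_snv, seed = seed))
}

# Standard multi-chromosome layout used by the bundled scenario models:
# `states` rows are recycled across chromosomes of 10 Mb split into
# `per_chrom` segments.
.scenario_segments <- function(states, chrom_mb = 10, n_chrom = 6, per_chrom = 5) {
  seg_len <- chrom_mb * 1e6 / per_chrom
  grid <- expand.grid(slot = seq_len(per_chrom), chrom = seq_len(n_chrom))
  k <- nrow(states)
  idx <- ((seq_len(nrow(grid)) - 1) %% k) + 1
  data.frame(chrom = paste0("chr", grid$chrom),
             start = (grid$slot - 1) * seg_len + 1,
             end = grid$slot * seg_len,
             cnA = states$cnA[idx], cnB = states$cnB[idx],
             clonality = states$clonality[idx],
             stringsAsFactors = FALSE)
}

#' Bundled simulation scenarios
#'
#' Four reference tumor models exercising the qualitatively different
#' profiles the estimators must handle: \code{diploid_clean} (diploid,
#' moderate admixture, clonal hemizygous deletions), \code{aneuploid_shifted}
#' (53\% of the genome gained in a pure sample, wild-type logR shift -0.34,
#' ploidy 2.53), \code{subclonal} (clonal and subclonal deletions
#' coexisting) and \code{quiet} (no somatic copy-number aberration; the
#' admixture estimator must refuse).
#'
#' @param scenario one of \code{"diploid_clean"}, \code{"aneuploid_shifted"},
#'   \code{"subclonal"}, \code{"quiet"}.
#' @return a \code{\link{tumor_model}}.
#' @export
scenario_model <- function(scenario = c("diploid_clean", "aneuploid_shifted",
                                        "subclonal", "quiet")) {
  scenario <- match.arg(scenario)
  switch(scenario,
    diploid_clean = tumor_model(
      .scenario_segments(data.frame(cnA = c(1, 1, 1, 1, 2),
                                    cnB = c(1, 1, 1, 0, 1),
                                    clonality = 1)),
      admixture = 0.3, coverage_tumor = 120, coverage_normal = 100),
    aneuploid_shifted = {
      # 17 of 30 slots with one extra copy, 12 wild type, 1 hemizygous
      # deletion -> mean CN 76/30 = 2.533, wild-type shift
      # -log2(2.533/2) = -0.341
      states <- data.frame(
        cnA = c(rep(2, 17), rep(1, 12), 1),
        cnB = c(rep(1, 17), rep(1, 12), 0),
        clonality = 1)
      tumor_model(.scenario_segments(states), admixture = 0,
                  coverage_tumor = 125, coverage_normal = 117)
    },
    subclonal = tumor_model(
      .scenario_segments(data.frame(cnA = c(1, 1, 1, 1, 1),
                                    cnB = c(1, 1, 1, 0, 0),
                                    clonality = c(1, 1, 1, 1, 0.5))),
      admixture = 0.3, coverage_tumor = 150, coverage_normal = 120),
    quiet = tumor_model(
      .scenario_segments(data.frame(cnA = 1, cnB = 1, clonality = 1)),
      admixture = 0.3, coverage_tumor = 100, coverage_normal = 100)
  )
}

#' Write the standard fixture suite
#'
#' Simulates the four bundled scenarios (\code{\link{scenario_model}}) and
#' writes their tables as tab-separated files named
#' \code{<scenario>_{segments,tumor_pileup,normal_pileup}.tsv} (plus
#' \code{_snv_reads.tsv} where SNVs exist) under \code{out_dir}. All
#' fixtures are synthetic data with recorded truth.
#'
#' @param out_dir writable directory.
#' @param seed RNG seed shared by the four simulations.
#' @return invisibly, a named list of the simulation results.
#' @export
make_fixture_suite <- function(out_dir, seed = 1L) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  scen <- c("diploid_clean", "aneuploid_shifted", "subclonal", "quiet")
  res <- lapply(scen, function(s) {
    sim <- simulate_tumor(scenario_model(s), seed = seed, sample = s)
    write_tsv_table(sim$seg_tb, file.path(out_dir, paste0(s, "_segments.tsv")))
    write_tsv_table(sim$pileup_tumor, file.path(out_dir, paste0(s, "_tumor_pileup.tsv")))
    write_tsv_table(sim$pileup_normal, file.path(out_dir, paste0(s, "_normal_pileup.tsv")))
    if (!is.null(sim$snv_reads)) {
      write_tsv_table(sim$snv_reads, file.path(out_dir, paste0(s, "_snv_reads.tsv")))
    }
    sim
  })
  names(res) <- scen
  invisible(res)
}
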