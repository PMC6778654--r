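# Per-segment estimation of beta, the fraction of allelically neutral reads.
#
# At an informative SNP (heterozygous in the matched normal), the tumor
# allelic fraction concentrates at b/2 if the alternative base sits on the
# under-represented allele and at 1 - b/2 otherwise, where b is the fraction
# of neutral reads. Which allele carries the alternative base is unknown, so
# the likelihood folds the two cases into an equal-weight two-component
# binomial mixture and beta is its maximum-likelihood estimate.

# Log-likelihood of the folded mixture at a single beta value.
# k, n: alternative-read counts and depths at the informative SNPs.
.folded_loglik <- function(b, k, n) {
  la <- stats::dbinom(k, n, b / 2, log = TRUE)
  lb <- stats::dbinom(k, n, 1 - b / 2, log = TRUE)
  hi <- pmax(la, lb)
  lo <- pmin(la, lb)
  term <- ifelse(is.finite(hi), hi + log1p(exp(lo - hi)), -Inf)
  sum(term) - length(k) * log(2)
}

# Vectorized evaluation over a grid of beta values in (0, 1]; the b = 0
# column is handled by the scalar form (log(0) terms need dbinom's exact
# boundary behavior). Shared binomial coefficients factor out of the mixture.
.folded_loglik_grid <- function(k, n, grid) {
  stopifnot(length(grid) > 0)
  out <- numeric(length(grid))
  pos <- which(grid > 0)
  if (length(pos)) {
    lp <- log(grid[pos] / 2)      # log P(alt) when the alt base is depleted
    lq <- log1p(-grid[pos] / 2)   # log P(alt) when the alt base is retained
    A <- outer(k, lp) + outer(n - k, lq)
    B <- outer(k, lq) + outer(n - k, lp)
    hi <- pmax(A, B)
    out[pos] <- colSums(hi + log1p(exp(-abs(A - B)))) +
      sum(lchoose(n, k)) - length(k) * log(2)
  }
  zero <- which(grid == 0)
  if (length(zero)) out[zero] <- .folded_loglik(0, k, n)
  out
}

#' Estimate beta for one set of informative SNPs
#'
#' Maximizes the folded two-component binomial mixture likelihood over beta
#' in [0, 1]: a grid search (step \code{grid_step}) followed by a
#' golden-section refinement of the best grid cell. Alternative-read counts
#' are reconstructed as \code{round(af * cov)} because pileups store
#' fractions, not counts. SNPs with zero coverage contribute to the SNP
#' count and mean coverage but not to the likelihood.
#'
#' @param af allelic fractions of the informative SNPs (one per SNP).
#' @param cov read depths at the same SNPs.
#' @param grid_step grid resolution of the initial search.
#' @return list with \code{beta} (NA when no usable SNP is available),
#'   \code{nsnps} (number of informative SNPs) and \code{cov} (mean depth).
#' @export
estimate_beta <- function(af, cov, grid_step = 0.001) {
  nsnps <- length(af)
  mean_cov <- if (nsnps > 0) mean(cov) else NA_real_
  use <- which(cov > 0 & !is.na(af))
  if (nsnps == 0 || length(use) == 0) {
    return(list(beta = NA_real_, nsnps = nsnps, cov = mean_cov))
  }
  n <- as.numeric(round(cov[use]))
  k <- pmin(n, pmax(0, round(af[use] * cov[use])))
  grid <- seq(0, 1, by = grid_step)
  ll <- .folded_loglik_grid(k, n, grid)
  b0 <- grid[which.max(ll)]
  opt <- stats::optimize(function(b) .folded_loglik(b, k, n),
                         interval = c(max(0, b0 - grid_step), min(1, b0 + grid_step)),
                         maximum = TRUE, tol = 1e-6)
  beta <- if (opt$objective >= max(ll)) opt$maximum else b0
  list(beta = clamp01(beta), nsnps = nsnps, cov = mean_cov)
}

#' Select informative SNPs from matched pileups
#'
#' An informative SNP is heterozygous in the matched normal: it must be
#' present in both pileups and its normal allelic fraction must fall inside
#' \code{[min_af_het_snps, max_af_het_snps]}. Positions present in only one
#' pileup are dropped.
#'
#' @param pileup_normal,pileup_tumor pileup tables (see
#'   \code{\link{read_pileup_table}}).
#' @param min_af_het_snps,max_af_het_snps allelic-fraction window defining
#'   heterozygosity in the normal sample.
#' @return data.frame with columns \code{chrom}, \code{pos},
#'   \code{af_tumor}, \code{cov_tumor}, \code{af_normal}, \code{cov_normal},
#'   ordered by position.
#' @export
select_informative_snps <- function(pileup_normal, pileup_tumor,
                                    min_af_het_snps = 0.2, max_af_het_snps = 0.8) {
  nm <- data.frame(chrom = pileup_normal$chrom, pos = pileup_normal$pos,
                   af_normal = pileup_normal$af, cov_normal = pileup_normal$cov,
                   stringsAsFactors = FALSE)
  tm <- data.frame(chrom = pileup_tumor$chrom, pos = pileup_tumor$pos,
                   af_tumor = pileup_tumor$af, cov_tumor = pileup_tumor$cov,
                   stringsAsFactors = FALSE)
  mg <- merge(nm, tm, by = c("chrom", "pos"), sort = FALSE)
  keep <- mg$af_normal >= min_af_het_snps & mg$af_normal <= max_af_het_snps
  out <- mg[keep, c("chrom", "pos", "af_tumor", "cov_tumor", "af_normal", "cov_normal")]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) {
    ascn_warn("ascn_no_informative_snps",
              "no informative SNP found in the intersection of the two pileups")
  }
  out
}

# Map informative SNPs to segments (1-based inclusive on both sides).
.snps_by_segment <- function(seg_tb, snps) {
  if (nrow(snps) == 0) return(rep(list(integer(0)), nrow(seg_tb)))
  seg_gr <- GenomicRanges::GRanges(seg_tb$chrom, IRanges::IRanges(seg_tb$start, seg_tb$end))
  snp_gr <- GenomicRanges::GRanges(snps$chrom, IRanges::IRanges(snps$pos, snps$pos))
  # disjoint chromosome sets are legitimate here (handled by the structured
  # no-overlap warning downstream)
  hits <- suppressWarnings(as.data.frame(GenomicRanges::findOverlaps(snp_gr, seg_gr)))
  out <- rep(list(integer(0)), nrow(seg_tb))
  if (nrow(hits)) {
    sp <- split(hits$queryHits, hits$subjectHits)
    out[as.integer(names(sp))] <- sp
  }
  out
}

#' Compute the beta table for a segmented tumor profile
#'
#' Extends the input segment table with, for every segment: \code{beta}
#' (fraction of allelically neutral reads in the tumor), \code{nsnps}
#' (number of informative SNPs it contains), \code{cov} (their mean tumor
#' depth), \code{n_beta} (the same estimator applied to the matched normal
#' pileup; expected to be 1 except over germline copy-number variants) and
#' error bounds \code{beta.min}/\code{beta.max} from the beta error table.
#' \code{beta} and \code{n_beta} are reported only for segments with at
#' least \code{min_required_snps} informative SNPs and mean tumor coverage
#' of at least \code{min_coverage}; other segments keep their SNP count and
#' coverage but carry NA estimates.
#'
#' @param seg_tb segment table (see \code{\link{read_segment_table}}).
#' @param pileup_tumor,pileup_normal pileup tables for the tumor and its
#'   matched normal.
#' @param min_af_het_snps,max_af_het_snps normal allelic-fraction window
#'   defining informative SNPs.
#' @param min_required_snps minimum informative SNPs per segment.
#' @param min_coverage minimum mean tumor coverage at informative SNPs.
#' @param error_tb beta error table used for the bounds (see
#'   \code{\link{build_error_table}}); NULL skips the bounds.
#' @param threads number of worker processes for the per-segment estimates;
#'   results do not depend on the worker count.
#' @return the input table extended with beta-related columns, one row per
#'   input segment, in input order.
#' @export
compute_beta_table <- function(seg_tb, pileup_tumor, pileup_normal,
                               min_af_het_snps = 0.2, max_af_het_snps = 0.8,
                               min_required_snps = 10, min_coverage = 20,
                               error_tb = default_error_table(), threads = 1) {
  validate_segments(seg_tb)
  snps <- select_informative_snps(pileup_normal, pileup_tumor,
                                  min_af_het_snps, max_af_het_snps)
  by_seg <- .snps_by_segment(seg_tb, snps)
  if (nrow(seg_tb) > 0 && all(lengths(by_seg) == 0)) {
    ascn_warn("ascn_no_segment_snps",
              "no informative SNP overlaps any input segment; all beta values are undefined")
  }
  one <- function(idx) {
    et <- estimate_beta(snps$af_tumor[idx], snps$cov_tumor[idx])
    en <- estimate_beta(snps$af_normal[idx], snps$cov_normal[idx])
    c(beta = et$beta, nsnps = et$nsnps, cov = et$cov, n_beta = en$beta)
  }
  res <- if (threads > 1) {
    parallel::mclapply(by_seg, one, mc.cores = threads)
  } else {
    lapply(by_seg, one)
  }
  res <- do.call(rbind, res)
  out <- seg_tb
  out$beta <- res[, "beta"]
  out$nsnps <- as.integer(res[, "nsnps"])
  out$cov <- res[, "cov"]
  out$n_beta <- res[, "n_beta"]
  fail <- is.na(out$beta) | out$nsnps < min_required_snps |
    is.na(out$cov) | out$cov < min_coverage
  out$beta[fail] <- NA_real_
  out$n_beta[fail] <- NA_real_
  if (!is.null(error_tb)) {
    err <- lookup_beta_error(error_tb, out$nsnps, out$cov)
    out$beta.min <- clamp01(out$beta - err)
    out$beta.max <- clamp01(out$beta + err)
  } else {
    out$beta.min <- NA_real_
    out$beta.max <- NA_real_
  }
  out
}

#' Summarize a beta table
#'
#' Reports the number of processed segments, the number (and percentage)
#' with a valid beta estimate, and the 0/25/50/75/100\% quantiles of segment
#' length, mean informative-SNP coverage and informative-SNP count. These
#' are the standard sanity checks on a segmentation/pileup pair: many short
#' segments mean few informative SNPs, very long segments suggest
#' undersegmentation, and the SNP count per kb (about 0.33 for common
#' polymorphisms) gauges pileup completeness.
#'
#' @param beta_table output of \code{\link{compute_beta_table}}.
#' @return an object of class \code{beta_table_summary} with a print method.
#' @export
summarize_beta_table <- function(beta_table) {
  probs <- c(0, 0.25, 0.5, 0.75, 1)
  qt <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(stats::setNames(rep(NA_real_, 5), paste0(probs * 100, "%")))
    stats::quantile(x, probs = probs, names = TRUE)
  }
  n <- nrow(beta_table)
  nv <- sum(!is.na(beta_table$beta))
  structure(list(
    sample = sample_name(beta_table),
    n_segments = n,
    n_valid = nv,
    pct_valid = if (n > 0) round(100 * nv / n) else NA_real_,
    length_quantiles = qt(beta_table$end - beta_table$start + 1),
    coverage_quantiles = qt(beta_table$cov),
    nsnps_quantiles = qt(beta_table$nsnps)
  ), class = "beta_table_summary")
}

#' @export
print.beta_table_summary <- function(x, ...) {
  cat(sprintf("Computed beta table of sample \"%s\"\n", x$sample))
  cat(sprintf("Number of processed segments: %d\n", x$n_segments))
  cat(sprintf("Number of segments with valid beta: %d (%s%%)\n", x$n_valid,
              ifelse(is.na(x$pct_valid), "NA", x$pct_valid)))
  fmt <- function(title, q, digits = 4) {
    cat(title, "\n", sep = "")
    for (nm in names(q)) {
      v <- q[[nm]]
      cat(sprintf("  %s: %s\n", nm,
                  if (is.na(v)) "undefined" else format(v, digits = digits + 3)))
    }
  }
  fmt("Quantiles of input segment lengths:", x$length_quantiles)
  fmt("Quantiles of input segment coverage:", x$coverage_quantiles)
  fmt("Quantiles of number of informative SNPs per input segment:", x$nsnps_quantiles)
  invisible(x)
}
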