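# DNA admixture (fraction of non-tumor DNA, 1 - purity) via the local
# most-clonal-deletion approach. Each candidate hemizygous deletion yields
# an apparent admixture from its beta; subclonal deletions inflate that
# apparent value (reads from tumor cells lacking the deletion are
# indistinguishable from normal-cell reads), so the sample admixture is the
# mode of the lowest cluster of apparent values.

#' Apparent DNA admixture of a hemizygous deletion
#'
#' A clonal one-copy deletion in a sample with admixture G has
#' \code{beta = 2G / (1 + G)} (two neutral reads from the admixed diploid
#' cells for every active tumor read). Inverting gives the apparent
#' admixture \code{G = beta / (2 - beta)}: 0 for a pure clonal deletion,
#' 2/3 -> 0.5, and 1 when no aberrant signal remains.
#'
#' @param beta per-segment fraction of neutral reads, in [0, 1].
#' @return apparent admixture, same length as \code{beta}.
#' @export
apparent_admixture_from_beta <- function(beta) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    ascn_stop("ascn_domain_error", "beta must lie in [0, 1]")
  }
  beta / (2 - beta)
}

#' Estimate DNA admixture from candidate hemizygous deletions
#'
#' Candidate deletions are segments with defined beta below
#' \code{beta_limit_for_neutral_reads}, ploidy-adjusted logR
#' (\code{logRp = logR - shift}) in \code{[-1 - logr_slack, 0)}, adequate
#' SNP/coverage support and diploid matched-normal beta. For each candidate
#' the apparent admixture \code{G = beta / (2 - beta)} is computed and the
#' candidate is retained only if its logRp is consistent with a clonal
#' hemizygous deletion at that admixture,
#' \code{|logRp - log2((1 + G) / 2)| <= consistency_tol}. The sample
#' admixture is the leftmost qualifying mode of the retained apparent
#' values (density-smoothed, segment-length weighted); the bounds
#' re-evaluate the apparent admixture at beta -/+ the error-table
#' half-width of the supporting segments.
#'
#' A profile without retained deletions (e.g. all beta near 1 and logR near
#' 0) raises a classed estimation error: a copy-number-quiet tumor and a
#' fully admixed sample are indistinguishable, and callers must not default
#' silently.
#'
#' @param beta_table output of \code{\link{compute_beta_table}}.
#' @param ploidy_table output of \code{\link{compute_ploidy}}.
#' @param error_tb beta error table for the bounds.
#' @param min_coverage,min_required_snps segment filters.
#' @param beta_limit_for_neutral_reads segments with beta at or above this
#'   are treated as balanced, not as deletions.
#' @param logr_slack slack below logRp = -1 tolerated for candidate
#'   deletions (noise allowance).
#' @param consistency_tol maximum |logRp - expected logRp| for a candidate
#'   to be retained.
#' @param n_beta_limit minimum matched-normal beta (germline CNV guard).
#' @param min_mode_mass mass qualification threshold for candidate modes.
#' @return data.frame with columns \code{sample}, \code{adm},
#'   \code{adm.min}, \code{adm.max}; attribute \code{n_supporting} records
#'   the number of deletions behind the call.
#' @export
compute_dna_admixture <- function(beta_table, ploidy_table,
                                  error_tb = default_error_table(),
                                  min_coverage = 20, min_required_snps = 10,
                                  beta_limit_for_neutral_reads = 0.90,
                                  logr_slack = 0.2, consistency_tol = 0.25,
                                  n_beta_limit = 0.9, min_mode_mass = 0.2) {
  shift <- ploidy_table$logR.shift[1] %||% shift_from_ploidy(ploidy_table$ploidy[1])
  logRp <- beta_table$logR - shift
  cand <- !is.na(beta_table$beta) &
    beta_table$beta < beta_limit_for_neutral_reads &
    !is.na(beta_table$cov) & beta_table$cov >= min_coverage &
    beta_table$nsnps >= min_required_snps &
    !is.na(beta_table$n_beta) & beta_table$n_beta >= n_beta_limit &
    is.finite(logRp) & logRp >= -1 - logr_slack & logRp < 0
  tb <- beta_table[cand, , drop = FALSE]
  lp <- logRp[cand]
  if (nrow(tb) > 0) {
    g <- apparent_admixture_from_beta(tb$beta)
    consistent <- abs(lp - log2((1 + g) / 2)) <= consistency_tol
    tb <- tb[consistent, , drop = FALSE]
    g <- g[consistent]
  } else {
    g <- numeric(0)
  }
  if (nrow(tb) == 0) {
    ascn_stop("ascn_no_deletions",
              paste("no hemizygous deletion consistent with a clonal one-copy loss;",
                    "either the genome lacks somatic copy-number aberrations or the",
                    "sample is almost fully admixed, and the two cases cannot be",
                    "distinguished from (beta, logR) data"))
  }
  if (nrow(tb) <= 2) {
    adm <- min(g)
  } else {
    modes <- .weighted_modes(g, w = tb$end - tb$start + 1)
    qual <- modes$mass >= min_mode_mass * max(modes$mass)
    adm <- min(modes$loc[qual])
  }
  adm <- clamp01(adm)
  support <- which(abs(g - adm) <= 0.1)
  if (length(support) == 0) support <- which.min(abs(g - adm))
  err <- lookup_beta_error(error_tb, tb$nsnps[support], tb$cov[support])
  err[is.na(err)] <- 0
  g_lo <- apparent_admixture_from_beta(clamp01(tb$beta[support] - err))
  g_hi <- apparent_admixture_from_beta(clamp01(tb$beta[support] + err))
  out <- data.frame(sample = sample_name(beta_table),
                    adm = adm,
                    adm.min = clamp01(min(adm, stats::median(g_lo))),
                    adm.max = clamp01(max(adm, stats::median(g_hi))),
                    stringsAsFactors = FALSE)
  attr(out, "n_supporting") <- length(support)
  attr(out, "apparent_admixtures") <- g
  out
}
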