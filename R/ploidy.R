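# Sample ploidy from the logR displacement of allelically balanced
# wild-type segments. Because logR is normalized by the ratio of mean tumor
# to mean normal coverage, an aneuploid genome shifts the wild-type mode
# away from 0, and the shift encodes the average copy number:
# ploidy = 2 * 2^(-shift).

# Weighted-kernel-density mode finding shared by the ploidy and admixture
# estimators. Returns one row per local maximum with its location and the
# fraction of density mass attributed to it (grid points are assigned to
# the nearest peak, split at the valleys between consecutive peaks).
.weighted_modes <- function(x, w = NULL) {
  if (length(x) == 0) return(data.frame(loc = numeric(0), mass = numeric(0)))
  if (length(x) == 1 || length(unique(x)) == 1) {
    return(data.frame(loc = x[1], mass = 1))
  }
  if (is.null(w)) w <- rep(1, length(x))
  d <- stats::density(x, weights = w / sum(w), bw = "nrd0", n = 512)
  y <- d$y
  n <- length(y)
  interior <- which(diff(sign(diff(y))) == -2) + 1
  peaks <- interior
  if (y[1] > y[2]) peaks <- c(1, peaks)
  if (y[n] > y[n - 1]) peaks <- c(peaks, n)
  peaks <- sort(unique(peaks))
  if (length(peaks) == 0) peaks <- which.max(y)
  # valleys split the grid into one basin per peak
  cuts <- vapply(seq_len(length(peaks) - 1), function(i) {
    seg <- peaks[i]:peaks[i + 1]
    seg[which.min(y[seg])]
  }, numeric(1))
  bounds <- c(1, cuts, n)
  mass <- vapply(seq_along(peaks), function(i) {
    sum(y[bounds[i]:bounds[i + 1]])
  }, numeric(1))
  data.frame(loc = d$x[peaks], mass = mass / sum(y))
}

#' Estimate the wild-type logR shift
#'
#' Restricts the beta table to allelically balanced segments (defined beta
#' at or above \code{beta_limit_for_neutral_reads}, adequate coverage and
#' SNP support, matched-normal beta consistent with a diploid germline),
#' discards the lowest-logR fraction \code{max_homo_dels_fraction} as
#' putative homozygous deletions, and locates the wild-type mode of the
#' remaining logR values with a segment-length-weighted Gaussian kernel
#' density (Silverman bandwidth). Balanced states are CN 2, 4, ... and CN 2
#' has the smallest logR, so the shift is the leftmost local maximum whose
#' mass reaches \code{min_mode_mass} of the dominant mode's mass (the mass
#' qualification suppresses spurious noise modes).
#'
#' @param beta_table output of \code{\link{compute_beta_table}}.
#' @param beta_limit_for_neutral_reads minimum beta for a segment to count
#'   as allelically balanced (noise keeps real wild type below 1).
#' @param max_homo_dels_fraction fraction of eligible segments discarded
#'   from the low-logR tail; overestimating it is harmless.
#' @param min_coverage,min_required_snps segment filters.
#' @param n_beta_limit minimum matched-normal beta (guards against germline
#'   copy-number variants).
#' @param min_mode_mass mass qualification threshold for candidate modes,
#'   relative to the dominant mode.
#' @return the logR shift (log2 units), with attribute \code{n_segments}.
#' @export
compute_logR_shift <- function(beta_table,
                               beta_limit_for_neutral_reads = 0.90,
                               max_homo_dels_fraction = 0.05,
                               min_coverage = 20, min_required_snps = 10,
                               n_beta_limit = 0.9, min_mode_mass = 0.2) {
  ok <- !is.na(beta_table$beta) &
    beta_table$beta >= beta_limit_for_neutral_reads &
    !is.na(beta_table$cov) & beta_table$cov >= min_coverage &
    beta_table$nsnps >= min_required_snps &
    !is.na(beta_table$n_beta) & beta_table$n_beta >= n_beta_limit &
    is.finite(beta_table$logR)
  tb <- beta_table[ok, , drop = FALSE]
  if (nrow(tb) == 0) {
    ascn_stop("ascn_no_balanced_segments",
              paste("no allelically balanced segment passes the filters;",
                    "the profile cannot anchor a wild-type logR mode"))
  }
  ord <- order(tb$logR)
  drop_n <- floor(max_homo_dels_fraction * nrow(tb))
  keep <- ord[seq.int(drop_n + 1, nrow(tb))]
  tb <- tb[keep, , drop = FALSE]
  modes <- .weighted_modes(tb$logR, w = tb$end - tb$start + 1)
  qual <- modes$mass >= min_mode_mass * max(modes$mass)
  shift <- min(modes$loc[qual])
  attr(shift, "n_segments") <- nrow(tb)
  shift
}

#' Ploidy implied by a wild-type logR shift
#'
#' \code{ploidy = 2 * 2^(-shift)}: a shift of 0 corresponds to a diploid
#' genome, negative shifts to copy-number gain on average.
#' @param shift wild-type logR shift (log2 units).
#' @return average copies per cell.
#' @export
ploidy_from_shift <- function(shift) 2 * 2^(-shift)

#' Wild-type logR shift implied by a ploidy
#'
#' Inverse of \code{\link{ploidy_from_shift}}.
#' @param ploidy average copies per cell (> 0).
#' @return logR shift (log2 units).
#' @export
shift_from_ploidy <- function(ploidy) {
  if (any(ploidy <= 0)) ascn_stop("ascn_domain_error", "ploidy must be positive")
  -log2(ploidy / 2)
}

#' Estimate sample ploidy from a beta table
#'
#' Locates the wild-type logR shift (\code{\link{compute_logR_shift}}) and
#' converts it to ploidy. When two interpretations of a profile are
#' plausible (e.g. diploid-with-subclonality vs aneuploid; the shift
#' estimate is not identifiable from (beta, logR) data alone in such cases)
#' the diagnostic lattice plot of
#' \code{\link{check_ploidy_and_admixture}} should be inspected, and
#' \code{force_shift} allows the user to impose the alternative solution;
#' the estimator itself never switches interpretation silently.
#'
#' @param beta_table output of \code{\link{compute_beta_table}}.
#' @param force_shift optional user-imposed logR shift overriding the
#'   estimation.
#' @param ... further arguments passed to \code{\link{compute_logR_shift}}.
#' @return data.frame with columns \code{sample}, \code{ploidy},
#'   \code{logR.shift}. Ploidy is reported at full precision; round to two
#'   decimals for display.
#' @export
compute_ploidy <- function(beta_table, force_shift = NULL, ...) {
  shift <- if (!is.null(force_shift)) force_shift else compute_logR_shift(beta_table, ...)
  data.frame(sample = sample_name(beta_table),
             ploidy = ploidy_from_shift(as.numeric(shift)),
             logR.shift = as.numeric(shift),
             stringsAsFactors = FALSE)
}
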