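# Allele-specific copy number: transform (beta, logR) pairs into fractional
# and integer copies of the major and minor allele, given the sample ploidy
# (logR shift) and DNA admixture.
#
# With logRp the ploidy-adjusted logR and G the admixture, the two allele
# copy numbers are
#   cn_minor = (beta * 2^logRp - G) / (1 - G)
#   cn_major = ((2 - beta) * (beta * 2^logRp - G) + 2 G (1 - beta)) / ((1 - G) * beta)
# and the major-allele expression simplifies algebraically to
#   ((2 - beta) * 2^logRp - G) / (1 - G),
# which is the form used at beta = 0 where the full expression is 0/0.
# Maternal and paternal alleles are not distinguishable from bulk data, so
# the output is ordered as (major, minor) = (max, min).

#' Fractional allele-specific copy numbers from (beta, logRp)
#'
#' @param beta fraction of neutral reads, in (0, 1] (0 allowed; handled via
#'   the simplified major-allele form).
#' @param logRp ploidy-adjusted logR (logR minus the wild-type shift).
#' @param admixture DNA admixture G in [0, 1).
#' @return data.frame with columns \code{cnA} (major) and \code{cnB}
#'   (minor); \code{cnA + cnB = 2 * 2^log2_corr} by construction.
#' @export
allele_specific_cn <- function(beta, logRp, admixture) {
  if (any(admixture >= 1 | admixture < 0, na.rm = TRUE)) {
    ascn_stop("ascn_domain_error", "admixture must lie in [0, 1)")
  }
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    ascn_stop("ascn_domain_error", "beta must lie in [0, 1]")
  }
  t2 <- 2^logRp
  G <- admixture
  cnB <- (beta * t2 - G) / (1 - G)
  cnA <- ifelse(beta > 0,
                ((2 - beta) * (beta * t2 - G) + 2 * G * (1 - beta)) / ((1 - G) * beta),
                ((2 - beta) * t2 - G) / (1 - G))
  data.frame(cnA = pmax(cnA, cnB), cnB = pmin(cnA, cnB))
}

#' Purity/ploidy-corrected logR
#'
#' The logR a segment would display in a diploid, 100\% pure sample:
#' \code{log2((2 * 2^logRp - 2G) / (2 * (1 - G)))}. Consequently the total
#' fractional copy number satisfies \code{cnA + cnB = 2 * 2^log2_corr}.
#' Segments whose observed signal implies non-positive tumor copy number
#' (e.g. a clonal homozygous deletion, whose corrected logR diverges to
#' -Inf) return NA.
#'
#' @param logRp ploidy-adjusted logR.
#' @param admixture DNA admixture G in [0, 1).
#' @return corrected logR values; NA where undefined.
#' @export
log2_corr <- function(logRp, admixture) {
  if (any(admixture >= 1 | admixture < 0, na.rm = TRUE)) {
    ascn_stop("ascn_domain_error", "admixture must lie in [0, 1)")
  }
  arg <- (2 * 2^logRp - 2 * admixture) / (2 * (1 - admixture))
  out <- rep(NA_real_, length(arg))
  ok <- !is.na(arg) & arg > 0
  out[ok] <- log2(arg[ok])
  out
}

#' Integer allele-specific copy-number calls
#'
#' A fractional value is called to its nearest integer (rounding half away
#' from zero) only when it lies strictly within \code{allelic_imbalance_th}
#' of that integer; values at exactly the threshold (e.g. 1.5 with the
#' default 0.5) remain uncalled. Small negative values above -0.2 -
#' noise around the zero-copy axis - are clamped to 0 for the call only;
#' the fractional value is not modified.
#'
#' @param cn fractional copy numbers.
#' @param allelic_imbalance_th maximum distance to the integer, in (0, 1].
#' @return integer calls, NA where the distance test fails.
#' @export
integer_cn_calls <- function(cn, allelic_imbalance_th = 0.5) {
  if (allelic_imbalance_th <= 0 || allelic_imbalance_th > 1) {
    ascn_stop("ascn_domain_error", "allelic_imbalance_th must lie in (0, 1]")
  }
  x <- ifelse(!is.na(cn) & cn < 0 & cn > -0.2, 0, cn)
  r <- round_half_away(x)
  # negative copy numbers beyond the clamp window are never callable
  ifelse(!is.na(x) & x >= 0 & abs(x - r) < allelic_imbalance_th, r, NA_real_)
}

#' Compute the allele-specific copy-number table
#'
#' Extends a beta table with \code{log2.corr} (purity/ploidy-corrected
#' logR), fractional \code{cnA}/\code{cnB} (major/minor allele copies) and
#' integer calls \code{cnA.int}/\code{cnB.int}. Segments without a defined
#' beta keep their corrected logR - total copy number needs no allelic
#' signal - but carry NA allele-specific values.
#'
#' @param beta_table output of \code{\link{compute_beta_table}}.
#' @param ploidy_table output of \code{\link{compute_ploidy}}.
#' @param admixture_table output of \code{\link{compute_dna_admixture}}.
#' @param error_tb beta error table (kept for interface symmetry; the
#'   fractional transform itself is deterministic).
#' @param allelic_imbalance_th see \code{\link{integer_cn_calls}}.
#' @return the beta table extended with columns \code{log2.corr},
#'   \code{cnA}, \code{cnB}, \code{cnA.int}, \code{cnB.int}.
#' @export
compute_allele_specific_scna_table <- function(beta_table, ploidy_table, admixture_table,
                                               error_tb = default_error_table(),
                                               allelic_imbalance_th = 0.5) {
  G <- admixture_table$adm[1]
  if (is.na(G) || G >= 1) {
    ascn_stop("ascn_domain_error",
              "admixture of 1 (no tumor DNA) leaves allele-specific copy numbers undefined")
  }
  shift <- ploidy_table$logR.shift[1] %||% shift_from_ploidy(ploidy_table$ploidy[1])
  out <- beta_table
  logRp <- out$logR - shift
  out$log2.corr <- log2_corr(logRp, G)
  has_beta <- !is.na(out$beta)
  out$cnA <- NA_real_
  out$cnB <- NA_real_
  if (any(has_beta)) {
    cn <- allele_specific_cn(out$beta[has_beta], logRp[has_beta], G)
    out$cnA[has_beta] <- cn$cnA
    out$cnB[has_beta] <- cn$cnB
  }
  out$cnA.int <- integer_cn_calls(out$cnA, allelic_imbalance_th)
  out$cnB.int <- integer_cn_calls(out$cnB, allelic_imbalance_th)
  out
}
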