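# Clonality of single-nucleotide variants. The observed VAF of an SNV is
# diluted by admixed normal DNA and modulated by the local copy-number
# state: a variant present in a fraction cl of tumor cells on m copies per
# mutated cell shows
#   VAF = cl * m * (1 - G) / (2 G + (1 - G) * cnT)
# where cnT is the (fractional) total tumor copy number of the containing
# segment. Inverting gives the clonality; rescaling the VAF to a 100% pure
# sample gives the adjusted VAF t_af_corr.

#' Purity/copy-number adjusted VAF
#'
#' The VAF the variant would show in a 100\% pure sample with the same
#' copy state: \code{vaf * (2G + (1 - G) * cnT) / ((1 - G) * cnT)}.
#'
#' @param vaf observed variant allele fraction.
#' @param admixture DNA admixture G in [0, 1).
#' @param cnT total tumor copy number at the locus (> 0).
#' @return adjusted VAF; NA where the copy state leaves it undefined.
#' @export
snv_adjusted_vaf <- function(vaf, admixture, cnT) {
  denom <- (1 - admixture) * cnT
  ifelse(is.na(denom) | denom <= 0, NA_real_,
         vaf * (2 * admixture + (1 - admixture) * cnT) / denom)
}

#' SNV clonality from VAF
#'
#' Fraction of tumor cells harboring the variant, given the local total
#' copy number and the number of mutated copies per mutated cell
#' (multiplicity): \code{vaf * (2G + (1 - G) * cnT) / ((1 - G) * m)},
#' capped at 1.
#'
#' @param vaf observed variant allele fraction.
#' @param admixture DNA admixture G in [0, 1).
#' @param cnT total tumor copy number at the locus (> 0).
#' @param multiplicity mutated copies per mutated cell (integer >= 1).
#' @param cap cap the estimate at 1 (default TRUE; the raw value is useful
#'   for multiplicity selection).
#' @return clonality estimates.
#' @export
snv_clonality <- function(vaf, admixture, cnT, multiplicity = 1, cap = TRUE) {
  if (any(multiplicity < 1, na.rm = TRUE)) {
    ascn_stop("ascn_domain_error", "multiplicity must be at least 1")
  }
  denom <- (1 - admixture) * multiplicity
  cl <- ifelse(is.na(denom) | denom <= 0 | is.na(cnT) | cnT <= 0, NA_real_,
               vaf * (2 * admixture + (1 - admixture) * cnT) / denom)
  if (cap) pmin(cl, 1) else cl
}

#' Expected VAF of an SNV
#'
#' Inverse of \code{\link{snv_clonality}}: the VAF expected for a variant
#' of given clonality and multiplicity at a locus with total tumor copy
#' number \code{cnT} in a sample with admixture G.
#'
#' @param clonality fraction of tumor cells with the variant.
#' @param admixture DNA admixture G in [0, 1).
#' @param cnT total tumor copy number at the locus (> 0).
#' @param multiplicity mutated copies per mutated cell.
#' @return expected VAF.
#' @export
snv_expected_vaf <- function(clonality, admixture, cnT, multiplicity = 1) {
  clonality * multiplicity * (1 - admixture) / (2 * admixture + (1 - admixture) * cnT)
}

#' Compute the SNV clonality table
#'
#' Maps each SNV to the unique segment containing its position, derives the
#' local fractional total copy number \code{cnT = cnA + cnB} from the
#' allele-specific table, selects the multiplicity as the smallest integer
#' in \code{1..max(1, cnA.int)} whose implied clonality does not exceed
#' 1.05 (1 when the integer major-allele call is unavailable), and reports
#' the adjusted VAF, the capped clonality, bounds obtained at the admixture
#' bounds, and the discretized status. SNVs outside every segment, on
#' segments without allele-specific calls, or without coverage are
#' \code{not.analysed}. Variants whose adjusted VAF falls in the upper
#' \code{error_rate} tail of the sample's adjusted-VAF distribution are
#' flagged in the \code{excluded} column (likely copy-state or caller
#' artifacts); their estimates are reported but should not be trusted.
#'
#' @param snv_tb SNV read-count table (see \code{\link{read_snv_table}}).
#' @param beta_table output of \code{\link{compute_beta_table}}.
#' @param ploidy_table output of \code{\link{compute_ploidy}}.
#' @param admixture_table output of \code{\link{compute_dna_admixture}}.
#' @param error_tb beta error table passed through to the allele-specific
#'   step.
#' @param error_rate fraction of SNVs flagged from the upper adjusted-VAF
#'   tail.
#' @param clonality_threshold see \code{\link{discretize_clonality}}.
#' @return the SNV table extended with columns \code{cnA}, \code{cnB},
#'   \code{t_af_corr}, \code{multiplicity}, \code{SNV.clonality},
#'   \code{SNV.clonality.min}, \code{SNV.clonality.max},
#'   \code{SNV.clonality.status}, \code{excluded}.
#' @export
compute_snv_clonality_table <- function(snv_tb, beta_table, ploidy_table,
                                        admixture_table,
                                        error_tb = default_error_table(),
                                        error_rate = 0.05,
                                        clonality_threshold = 0.85) {
  out <- snv_tb
  n <- nrow(out)
  for (col in c("cnA", "cnB", "t_af_corr", "multiplicity", "SNV.clonality",
                "SNV.clonality.min", "SNV.clonality.max")) {
    out[[col]] <- rep(NA_real_, n)
  }
  if (n == 0) {
    out$SNV.clonality.status <- character(0)
    out$excluded <- logical(0)
    return(out)
  }
  ascn <- compute_allele_specific_scna_table(beta_table, ploidy_table, admixture_table,
                                             error_tb = error_tb)
  seg_gr <- GenomicRanges::GRanges(ascn$chrom, IRanges::IRanges(ascn$start, ascn$end))
  snv_gr <- GenomicRanges::GRanges(out$chrom, IRanges::IRanges(out$pos, out$pos))
  hits <- suppressWarnings(as.data.frame(GenomicRanges::findOverlaps(snv_gr, seg_gr)))
  hits <- hits[!duplicated(hits$queryHits), , drop = FALSE]  # unique containing segment
  G <- admixture_table$adm[1]
  G_min <- min(admixture_table$adm.min[1], 1 - 1e-9)
  G_max <- min(admixture_table$adm.max[1], 1 - 1e-9)
  depth <- out$rc_ref_tumor + out$rc_alt_tumor
  vaf <- ifelse(depth > 0, out$rc_alt_tumor / depth, NA_real_)
  seg_of <- rep(NA_integer_, n)
  seg_of[hits$queryHits] <- hits$subjectHits
  for (i in seq_len(n)) {
    j <- seg_of[i]
    if (is.na(j) || is.na(vaf[i])) next
    cnT <- ascn$cnA[j] + ascn$cnB[j]
    if (is.na(cnT) || cnT <= 0) next
    out$cnA[i] <- ascn$cnA[j]
    out$cnB[i] <- ascn$cnB[j]
    out$t_af_corr[i] <- snv_adjusted_vaf(vaf[i], G, cnT)
    m_max <- max(1, if (is.na(ascn$cnA.int[j])) 1 else ascn$cnA.int[j])
    m <- 1
    for (cand in seq_len(m_max)) {
      m <- cand
      if (snv_clonality(vaf[i], G, cnT, cand, cap = FALSE) <= 1.05) break
    }
    out$multiplicity[i] <- m
    out$SNV.clonality[i] <- snv_clonality(vaf[i], G, cnT, m)
    at_bounds <- c(snv_clonality(vaf[i], G_min, cnT, m),
                   snv_clonality(vaf[i], G_max, cnT, m))
    out$SNV.clonality.min[i] <- min(out$SNV.clonality[i], at_bounds, na.rm = TRUE)
    out$SNV.clonality.max[i] <- max(out$SNV.clonality[i], at_bounds, na.rm = TRUE)
  }
  out$SNV.clonality.status <- discretize_clonality(out$SNV.clonality,
                                                   out$SNV.clonality.min,
                                                   out$SNV.clonality.max,
                                                   clonality_threshold)
  out$excluded <- FALSE
  analysed <- which(!is.na(out$t_af_corr))
  if (length(analysed) > 0 && error_rate > 0) {
    cutoff <- stats::quantile(out$t_af_corr[analysed], probs = 1 - error_rate,
                              names = FALSE, type = 7)
    out$excluded[analysed] <- out$t_af_corr[analysed] > cutoff
  }
  out
}
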