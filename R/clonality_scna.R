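# Clonality of somatic copy-number aberrations.
#
# Cell-mixture forward model: a segment with integer allele-specific state
# (a, b) present in a fraction c of tumor cells, in a sample with admixture
# G, mixes three populations - normal cells (state (1,1)), tumor cells
# without the aberration (state (1,1)) and tumor cells with it (state
# (a, b)). The per-allele relative read contributions are
#   rA = G + (1 - G) * (c * a + 1 - c)
#   rB = G + (1 - G) * (c * b + 1 - c)
# giving beta = 2 * min(rA, rB) / (rA + rB) and
# logR = log2((rA + rB) / 2) + shift.

#' Expected (beta, logR) of an allele-specific state
#'
#' Forward model used by the clonality fit, the allele-specific round-trip
#' checks and the diagnostic lattice. With clonality 1 it reduces to the
#' clonal prediction inverted by \code{\link{allele_specific_cn}}.
#' A fully deleted locus (\code{rA + rB = 0}) maps to
#' \code{(beta, logR) = (1, -Inf)}.
#'
#' @param cnA,cnB integer allele copies of the aberrant state
#'   (\code{0 <= cnB <= cnA}).
#' @param clonality fraction of tumor cells carrying the state, in [0, 1].
#' @param admixture DNA admixture G in [0, 1].
#' @param logR_shift wild-type logR shift added to the expected logR.
#' @return data.frame with columns \code{beta.exp}, \code{logR.exp}.
#' @export
expected_signal <- function(cnA, cnB, clonality = 1, admixture = 0, logR_shift = 0) {
  if (any(cnB > cnA | cnB < 0, na.rm = TRUE)) {
    ascn_stop("ascn_domain_error", "allele copies must satisfy 0 <= cnB <= cnA")
  }
  if (any(clonality < 0 | clonality > 1, na.rm = TRUE)) {
    ascn_stop("ascn_domain_error", "clonality must lie in [0, 1]")
  }
  if (any(admixture < 0 | admixture > 1, na.rm = TRUE)) {
    ascn_stop("ascn_domain_error", "admixture must lie in [0, 1]")
  }
  rA <- admixture + (1 - admixture) * (clonality * cnA + 1 - clonality)
  rB <- admixture + (1 - admixture) * (clonality * cnB + 1 - clonality)
  tot <- rA + rB
  beta <- ifelse(tot > 0, 2 * pmin(rA, rB) / tot, 1)
  logR <- ifelse(tot > 0, log2(tot / 2) + logR_shift, -Inf)
  data.frame(beta.exp = beta, logR.exp = logR)
}

# Unchecked scalar version used inside optimization loops.
.exp_signal <- function(a, b, cl, G) {
  rA <- G + (1 - G) * (cl * a + 1 - cl)
  rB <- G + (1 - G) * (cl * b + 1 - cl)
  tot <- rA + rB
  if (tot <= 0) return(c(1, -Inf))
  c(2 * min(rA, rB) / tot, log2(tot / 2))
}

# Integer states enumerated by the fit, ordered so that ties resolve to the
# most parsimonious (smallest total, then smallest major) state. (1, 1) is
# excluded: at any clonality it is indistinguishable from wild type.
.candidate_states <- function(max_cn) {
  st <- expand.grid(cnA = 0:max_cn, cnB = 0:max_cn)
  st <- st[st$cnB <= st$cnA & !(st$cnA == 1 & st$cnB == 1), , drop = FALSE]
  st[order(st$cnA + st$cnB, st$cnA), , drop = FALSE]
}

#' Fit the clonality of one aberrant segment
#'
#' Enumerates integer allele-specific states (a, b) with
#' \code{0 <= b <= a <= max_cn}, excluding (1, 1), and for each minimizes
#' over clonality c in [0, 1] the squared signal distance
#' \code{(beta.exp - beta)^2 + logr_weight * (logR.exp - logRp)^2}. For
#' the hemizygous-deletion state (1, 0) the optimum has the closed form
#' \code{c = (1 - G') / (1 - G)} with \code{G' = beta / (2 - beta)} the
#' apparent admixture, which is used directly.
#'
#' Gains are exactly degenerate along the family with \code{(a - 1) * c}
#' constant - a clonal single-copy gain emits the same signal as a
#' half-clonal two-copy gain - so state selection adds a parsimony penalty
#' of \code{parsimony_penalty} per total copy to the squared residual: a
#' higher-copy state must earn its extra copies with a genuinely better
#' fit rather than by chasing noise. The reported residual is the
#' unpenalized weighted distance. Clonality bounds come from refitting the selected state at the
#' pessimistic corners (beta.min, admixture.max) and (beta.max,
#' admixture.min). Segments that look wild type (beta at or above
#' \code{beta_threshold} and |logRp| <= 0.1) or whose best residual
#' exceeds \code{fit_tol} are not analysed.
#'
#' @param beta,logRp observed segment signal (beta and ploidy-adjusted logR).
#' @param beta_min,beta_max error bounds on beta (default: no error).
#' @param admixture point estimate of DNA admixture G (< 1).
#' @param admixture_min,admixture_max bounds on G.
#' @param max_cn largest allele copy number enumerated.
#' @param beta_threshold beta at or above this marks a balanced segment.
#' @param logr_weight weight of the logR axis in the residual; logR noise
#'   exceeds beta noise, so the axis is down-weighted.
#' @param fit_tol maximum acceptable residual (Euclidean, weighted).
#' @param parsimony_penalty squared-residual penalty per total copy used
#'   during state selection.
#' @return list with \code{cnA}, \code{cnB}, \code{clonality},
#'   \code{clonality.min}, \code{clonality.max}, \code{residual} and
#'   \code{analysed}.
#' @export
scna_clonality_fit <- function(beta, logRp, beta_min = beta, beta_max = beta,
                               admixture, admixture_min = admixture,
                               admixture_max = admixture,
                               max_cn = 8, beta_threshold = 0.9,
                               logr_weight = 0.25, fit_tol = 0.05,
                               parsimony_penalty = 2e-3) {
  if (is.na(admixture) || admixture >= 1) {
    ascn_stop("ascn_domain_error", "admixture must be < 1 to fit clonality")
  }
  not_analysed <- list(cnA = NA_real_, cnB = NA_real_, clonality = NA_real_,
                       clonality.min = NA_real_, clonality.max = NA_real_,
                       residual = NA_real_, analysed = FALSE)
  if (is.na(beta) || !is.finite(logRp)) return(not_analysed)
  if (beta >= beta_threshold && abs(logRp) <= 0.1) return(not_analysed)

  states <- .candidate_states(max_cn)
  fit_state <- function(a, b, bt, G) {
    obj_vec <- function(cl) {   # weighted squared distance, vectorized in cl
      rA <- G + (1 - G) * (cl * a + 1 - cl)
      rB <- G + (1 - G) * (cl * b + 1 - cl)
      tot <- rA + rB
      be <- ifelse(tot > 0, 2 * pmin(rA, rB) / tot, 1)
      le <- ifelse(tot > 0, log2(tot / 2), -Inf)
      (be - bt)^2 + logr_weight * (le - logRp)^2
    }
    # the objective can be multimodal in c, so scan a coarse grid first and
    # refine the best cell locally
    cg <- seq(0, 1, by = 0.01)
    vg <- obj_vec(cg)
    i0 <- which.min(vg)
    opt <- stats::optimize(obj_vec,
                           interval = c(max(0, cg[i0] - 0.01), min(1, cg[i0] + 0.01)),
                           tol = 1e-7)
    cands <- rbind(c(opt$minimum, opt$objective), c(cg[i0], vg[i0]))
    if (a == 1 && b == 0) {
      # closed-form optimum of the deletion branch, exact when the logR is
      # consistent with the beta signal
      cl_cf <- clamp01((1 - bt / (2 - bt)) / (1 - G))
      cands <- rbind(cands, c(cl_cf, obj_vec(cl_cf)))
    }
    best <- which.min(cands[, 2])
    list(clonality = cands[best, 1], value = cands[best, 2])
  }
  fits <- lapply(seq_len(nrow(states)), function(i) {
    fit_state(states$cnA[i], states$cnB[i], beta, admixture)
  })
  vals <- vapply(fits, `[[`, numeric(1), "value")
  # states are parsimony-ordered, so exact ties also resolve to the
  # smallest total copy number
  best <- which.min(vals + parsimony_penalty * (states$cnA + states$cnB))
  a <- states$cnA[best]
  b <- states$cnB[best]
  cl <- fits[[best]]$clonality
  residual <- sqrt(vals[best])
  if (residual > fit_tol) return(not_analysed)
  cl_lo <- fit_state(a, b, clamp01(beta_min), min(admixture_max, 1 - 1e-9))$clonality
  cl_hi <- fit_state(a, b, clamp01(beta_max), max(admixture_min, 0))$clonality
  list(cnA = a, cnB = b, clonality = clamp01(cl),
       clonality.min = clamp01(min(cl, cl_lo, cl_hi)),
       clonality.max = clamp01(max(cl, cl_lo, cl_hi)),
       residual = residual, analysed = TRUE)
}

#' Discretize a clonality estimate
#'
#' Maps a clonality value with bounds to one of \code{clonal},
#' \code{uncertain.clonal}, \code{uncertain.subclonal}, \code{subclonal}:
#' a call is certain when the whole error interval falls on one side of the
#' threshold, and carries the \code{uncertain} prefix when the interval
#' straddles it (the side of the point estimate decides the suffix).
#'
#' @param clonality point estimates.
#' @param clonality_min,clonality_max error bounds.
#' @param clonality_threshold discretization threshold.
#' @return character vector of statuses (\code{not.analysed} where the
#'   estimate is missing).
#' @export
discretize_clonality <- function(clonality, clonality_min, clonality_max,
                                 clonality_threshold = 0.85) {
  th <- clonality_threshold
  ifelse(is.na(clonality), "not.analysed",
  ifelse(clonality_min >= th, "clonal",
  ifelse(clonality >= th, "uncertain.clonal",
  ifelse(clonality_max >= th, "uncertain.subclonal", "subclonal"))))
}

#' Compute the SCNA clonality table
#'
#' Runs \code{\link{scna_clonality_fit}} on every segment with a defined
#' beta and appends \code{clonality}, \code{clonality.min},
#' \code{clonality.max} and \code{clonality.status} to the allele-specific
#' table. Wild-type segments, segments without beta, and segments whose
#' signal does not fit any integer state within tolerance are reported as
#' \code{not.analysed}.
#'
#' @param beta_table output of \code{\link{compute_beta_table}}.
#' @param ploidy_table output of \code{\link{compute_ploidy}}.
#' @param admixture_table output of \code{\link{compute_dna_admixture}}.
#' @param error_tb beta error table used for the beta bounds when the beta
#'   table does not carry them.
#' @param clonality_threshold see \code{\link{discretize_clonality}}.
#' @param beta_threshold segments with beta at or above this and near-zero
#'   logRp are wild type.
#' @param max_cn largest allele copy number enumerated by the fit.
#' @param allelic_imbalance_th passed to the allele-specific step.
#' @return the allele-specific table extended with clonality columns.
#' @export
compute_scna_clonality_table <- function(beta_table, ploidy_table, admixture_table,
                                         error_tb = default_error_table(),
                                         clonality_threshold = 0.85,
                                         beta_threshold = 0.9, max_cn = 8,
                                         allelic_imbalance_th = 0.5) {
  out <- compute_allele_specific_scna_table(beta_table, ploidy_table, admixture_table,
                                            error_tb = error_tb,
                                            allelic_imbalance_th = allelic_imbalance_th)
  shift <- ploidy_table$logR.shift[1] %||% shift_from_ploidy(ploidy_table$ploidy[1])
  G <- admixture_table$adm[1]
  G_min <- admixture_table$adm.min[1] %||% G
  G_max <- admixture_table$adm.max[1] %||% G
  if (is.null(out$beta.min) || all(is.na(out$beta.min))) {
    err <- lookup_beta_error(error_tb, out$nsnps, out$cov)
    out$beta.min <- clamp01(out$beta - err)
    out$beta.max <- clamp01(out$beta + err)
  }
  n <- nrow(out)
  cl <- cl_min <- cl_max <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(out$beta[i])) next
    bmin <- out$beta.min[i]
    bmax <- out$beta.max[i]
    fit <- scna_clonality_fit(
      beta = out$beta[i], logRp = out$logR[i] - shift,
      beta_min = if (is.na(bmin)) out$beta[i] else bmin,
      beta_max = if (is.na(bmax)) out$beta[i] else bmax,
      admixture = G, admixture_min = G_min, admixture_max = G_max,
      max_cn = max_cn, beta_threshold = beta_threshold)
    if (fit$analysed) {
      cl[i] <- fit$clonality
      cl_min[i] <- fit$clonality.min
      cl_max[i] <- fit$clonality.max
    }
  }
  out$clonality <- cl
  out$clonality.min <- cl_min
  out$clonality.max <- cl_max
  out$clonality.status <- discretize_clonality(cl, cl_min, cl_max, clonality_threshold)
  out
}
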