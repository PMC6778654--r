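# Monte-Carlo calibration of the beta estimator: for each combination of
# informative-SNP count and coverage, the expected error half-width around
# the beta estimate at a stated confidence level. The half-width is the
# worst case over a grid of true beta values, so the bounds are conservative
# for any segment regardless of its underlying state.

.error_table_cache <- new.env(parent = emptyenv())

#' Build a beta error table by simulation
#'
#' For every pair (number of informative SNPs m, mean coverage c) the
#' builder simulates \code{reps} replicate segments for each true beta in
#' \code{beta_grid}: per-SNP depths are Poisson(c), the alternative base
#' lands on the depleted or retained allele with equal probability, and
#' alternative-read counts are binomial. Each replicate is passed through
#' \code{\link{estimate_beta}} and the table records, per (m, c), the
#' \code{confidence}-level quantile of the absolute estimation error,
#' maximized over \code{beta_grid}.
#'
#' @param nsnps_grid,cov_grid grids of informative-SNP counts and coverages.
#' @param beta_grid true beta values the error is maximized over.
#' @param reps Monte-Carlo replicates per (m, c, beta) cell (at least 100).
#' @param confidence quantile of |estimate - truth| reported as the error.
#' @param seed RNG seed; two builds with the same seed are identical.
#' @return data.frame with columns \code{nsnps}, \code{cov}, \code{error}
#'   and attributes recording the build parameters.
#' @export
build_error_table <- function(nsnps_grid, cov_grid, beta_grid = seq(0, 1, by = 0.25),
                              reps = 1000, confidence = 0.9, seed = 6106L) {
  if (length(nsnps_grid) == 0 || length(cov_grid) == 0 || length(beta_grid) == 0) {
    ascn_stop("ascn_config_error", "nsnps_grid, cov_grid and beta_grid must be non-empty")
  }
  if (reps < 100) ascn_stop("ascn_config_error", "reps must be at least 100")
  set.seed(seed)
  cells <- expand.grid(nsnps = sort(unique(nsnps_grid)), cov = sort(unique(cov_grid)))
  err <- vapply(seq_len(nrow(cells)), function(i) {
    m <- cells$nsnps[i]
    cv <- cells$cov[i]
    max(vapply(beta_grid, function(b) {
      est <- vapply(seq_len(reps), function(r) {
        depth <- pmax(1L, stats::rpois(m, cv))
        depleted <- stats::runif(m) < 0.5
        p <- ifelse(depleted, b / 2, 1 - b / 2)
        k <- stats::rbinom(m, depth, p)
        estimate_beta(k / depth, depth)$beta
      }, numeric(1))
      stats::quantile(abs(est - b), probs = confidence, names = FALSE)
    }, numeric(1)))
  }, numeric(1))
  out <- data.frame(nsnps = cells$nsnps, cov = cells$cov, error = err)
  attr(out, "confidence") <- confidence
  attr(out, "beta_grid") <- beta_grid
  attr(out, "reps") <- reps
  attr(out, "seed") <- seed
  out
}

#' Look up beta error half-widths
#'
#' Pairs (nsnps, cov) not present in the table are resolved to the nearest
#' available grid value independently in each dimension.
#'
#' @param error_tb error table from \code{\link{build_error_table}}.
#' @param nsnps,cov vectors of informative-SNP counts and mean coverages.
#' @return numeric vector of error half-widths (NA where inputs are NA).
#' @export
lookup_beta_error <- function(error_tb, nsnps, cov) {
  ns_vals <- sort(unique(error_tb$nsnps))
  cv_vals <- sort(unique(error_tb$cov))
  nearest <- function(vals, x) {
    vapply(x, function(v) {
      if (is.na(v)) return(NA_real_)
      vals[which.min(abs(vals - v))]
    }, numeric(1))
  }
  nn <- nearest(ns_vals, nsnps)
  cc <- nearest(cv_vals, cov)
  idx <- match(paste(nn, cc), paste(error_tb$nsnps, error_tb$cov))
  error_tb$error[idx]
}

#' Bundled beta error table
#'
#' Returns the precomputed error table shipped with the package
#' (\code{inst/extdata/beta_error_table.tsv}), generated by
#' \code{\link{build_error_table}} with the default confidence (0.9), 1000
#' replicates per cell and a fixed seed; the generating script is
#' \code{inst/extdata/beta_error_table_provenance.R}. Experiments far from
#' the calibrated grid (ultra-deep targeted panels, very low-pass
#' whole-genome) should rebuild an ad hoc table instead.
#'
#' @return data.frame with columns \code{nsnps}, \code{cov}, \code{error}.
#' @export
default_error_table <- function() {
  if (is.null(.error_table_cache$tb)) {
    path <- system.file("extdata", "beta_error_table.tsv", package = "ascnclone")
    if (!nzchar(path)) {
      ascn_stop("ascn_config_error", "bundled beta error table not found")
    }
    .error_table_cache$tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  .error_table_cache$tb
}
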