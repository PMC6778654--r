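# Diagnostic beta-vs-logR lattice: the expected position of every integer
# allele-specific state given the estimated ploidy (shift) and admixture,
# overlaid on the observed segments. Comparing observed clusters with the
# lattice is the standard sanity check on ploidy/admixture estimates and
# the way to surface alternative interpretations of ambiguous profiles.

#' Expected lattice of integer allele-specific states
#'
#' One point per state (cnA, cnB) with 0 <= cnB <= cnA <= max_cn, computed
#' with the clonal forward model (\code{\link{expected_signal}} at
#' clonality 1). The homozygous-deletion state (0, 0) sits at logR -Inf
#' when no admixture is present and is flagged as unplottable.
#'
#' @param admixture DNA admixture G.
#' @param logR_shift wild-type logR shift.
#' @param max_cn largest allele copy number in the lattice.
#' @return data.frame with columns \code{cnA}, \code{cnB}, \code{beta.exp},
#'   \code{logR.exp}, \code{label}, \code{plottable}.
#' @export
expected_lattice <- function(admixture, logR_shift = 0, max_cn = 6) {
  st <- expand.grid(cnB = 0:max_cn, cnA = 0:max_cn)
  st <- st[st$cnB <= st$cnA, c("cnA", "cnB")]
  rownames(st) <- NULL
  sig <- expected_signal(st$cnA, st$cnB, clonality = 1, admixture = admixture,
                         logR_shift = logR_shift)
  data.frame(st,
             beta.exp = sig$beta.exp,
             logR.exp = sig$logR.exp,
             label = sprintf("(%d,%d)", st$cnA, st$cnB),
             plottable = is.finite(sig$logR.exp),
             stringsAsFactors = FALSE)
}

#' Plot observed segments against the expected state lattice
#'
#' Scatter of (logR, beta) for every segment with a defined beta (gray
#' dots) with the expected positions of integer allele-specific states
#' overlaid (light-red circles, labelled), given the estimated ploidy and
#' admixture, which are reported in the title. The lattice used for the
#' overlay can also be written as a TSV so that the prediction is testable
#' without graphics.
#'
#' @param beta_table output of \code{\link{compute_beta_table}}.
#' @param ploidy_table output of \code{\link{compute_ploidy}}.
#' @param admixture_table output of \code{\link{compute_dna_admixture}}.
#' @param max_cn largest allele copy number in the lattice.
#' @param out_image optional path; the plot is saved there (format from the
#'   extension).
#' @param out_table optional path; the lattice data.frame is written there
#'   as TSV.
#' @return list with \code{plot} (a ggplot object) and \code{lattice} (the
#'   data.frame behind the overlay).
#' @export
check_ploidy_and_admixture <- function(beta_table, ploidy_table, admixture_table,
                                       max_cn = 6, out_image = NULL, out_table = NULL) {
  shift <- ploidy_table$logR.shift[1] %||% shift_from_ploidy(ploidy_table$ploidy[1])
  lat <- expected_lattice(admixture_table$adm[1], shift, max_cn)
  obs <- beta_table[!is.na(beta_table$beta) & is.finite(beta_table$logR), , drop = FALSE]
  if (nrow(obs) == 0) {
    ascn_warn("ascn_empty_plot", "no segment with a defined beta; plotting the lattice only")
  }
  p <- ggplot2::ggplot() +
    ggplot2::geom_point(data = obs,
                        ggplot2::aes(x = .data$logR, y = .data$beta),
                        color = "gray40", size = 1.5, alpha = 0.7) +
    ggplot2::geom_point(data = lat[lat$plottable, ],
                        ggplot2::aes(x = .data$logR.exp, y = .data$beta.exp),
                        shape = 21, color = "indianred1", fill = NA,
                        size = 6, stroke = 0.8) +
    ggplot2::geom_text(data = lat[lat$plottable, ],
                       ggplot2::aes(x = .data$logR.exp, y = .data$beta.exp,
                                    label = .data$label),
                       color = "indianred3", size = 2.2, vjust = -1.6) +
    ggplot2::labs(
      title = sprintf("%s: ploidy %.2f, admixture %.2f",
                      sample_name(beta_table), ploidy_table$ploidy[1],
                      admixture_table$adm[1]),
      x = "logR", y = "beta") +
    ggplot2::coord_cartesian(ylim = c(0, 1.05)) +
    ggplot2::theme_bw()
  if (!is.null(out_table)) write_tsv_table(lat, out_table)
  if (!is.null(out_image)) {
    ggplot2::ggsave(out_image, plot = p, width = 7, height = 5, dpi = 150)
  }
  list(plot = p, lattice = lat)
}
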