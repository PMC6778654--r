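# Reading, validation and writing of the three tab-separated input table
# dialects (segmented copy number, SNP pileups, SNV read counts) and of
# BED-compatible exports. All downstream modules consume the canonical
# column names produced here.

# Upstream segmentation tools (CBS wrappers, CNVkit, EXCAVATOR2, FACETS)
# disagree on column names; matching is case-insensitive over this synonym
# map and the first hit wins.
.column_synonyms <- list(
  sample       = c("sample", "sample.id", "sample_id", "id"),
  chrom        = c("chrom", "chr", "chromosome", "seqnames"),
  start        = c("start", "loc.start", "start.pos", "chromstart"),
  end          = c("end", "loc.end", "end.pos", "chromend"),
  logR         = c("logr", "log2", "seg.mean", "log2.ratio", "log2ratio"),
  pos          = c("pos", "position"),
  af           = c("af", "allelic.fraction", "allelic_fraction", "baf"),
  cov          = c("cov", "coverage", "depth", "rd"),
  ref          = c("ref", "ref_base", "reference"),
  alt          = c("alt", "alt_base", "alternative"),
  rc_ref_tumor = c("rc_ref_tumor", "ref.count", "t_ref_count"),
  rc_alt_tumor = c("rc_alt_tumor", "alt.count", "t_alt_count")
)

.resolve_column <- function(df, field, required = TRUE) {
  hit <- which(tolower(names(df)) %in% .column_synonyms[[field]])
  if (length(hit) == 0) {
    if (required) {
      ascn_stop("ascn_format_error",
                sprintf("required column '%s' not found (accepted names: %s)",
                        field, paste(.column_synonyms[[field]], collapse = ", ")),
                field = field)
    }
    return(NA_integer_)
  }
  hit[1]
}

.read_tsv <- function(path) {
  if (!file.exists(path)) {
    ascn_stop("ascn_io_error", sprintf("file not found: %s", path))
  }
  utils::read.delim(path, header = TRUE, sep = "\t", na.strings = c("-", "NA"),
                    check.names = FALSE, comment.char = "", stringsAsFactors = FALSE)
}

.as_numeric_checked <- function(x, field, allow_na = FALSE) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (allow_na) return(list(x = out, bad = bad))
  bad <- union(bad, which(is.na(x)))
  list(x = out, bad = sort(bad))
}

.row_error <- function(field, rows, what) {
  ascn_stop("ascn_validation_error",
            sprintf("%s in column '%s' at row(s): %s", what, field,
                    paste(utils::head(rows, 20), collapse = ", ")),
            field = field, rows = rows)
}

#' Read a segmented copy-number table
#'
#' Parses a tab-separated table of genomic segments with the shape produced
#' by segmentation algorithms such as Circular Binary Segmentation: one row
#' per segment with chromosome, start, end (1-based, inclusive) and the log2
#' tumor/normal normalized coverage ratio (logR). Column names are matched
#' case-insensitively against a synonym map (e.g. \code{chr}/\code{chrom},
#' \code{seg.mean}/\code{log2}/\code{logR}).
#'
#' @param path path to a tab-separated file with a header row.
#' @param sample sample identifier used when the table has no sample column.
#' @return a \code{data.frame} with columns \code{sample}, \code{chrom},
#'   \code{start}, \code{end}, \code{logR}, in file order.
#' @export
read_segment_table <- function(path, sample = NULL) {
  df <- .read_tsv(path)
  idx <- vapply(c("chrom", "start", "end", "logR"), function(f) .resolve_column(df, f), integer(1))
  sidx <- .resolve_column(df, "sample", required = FALSE)
  out <- data.frame(
    sample = if (!is.na(sidx)) as.character(df[[sidx]]) else rep(sample %||% "sample1", nrow(df)),
    chrom  = as.character(df[[idx[["chrom"]]]]),
    stringsAsFactors = FALSE
  )
  for (f in c("start", "end")) {
    chk <- .as_numeric_checked(df[[idx[[f]]]], f)
    if (length(chk$bad)) .row_error(f, chk$bad, "non-numeric coordinate")
    out[[f]] <- chk$x
  }
  chk <- .as_numeric_checked(df[[idx[["logR"]]]], "logR", allow_na = TRUE)
  if (length(chk$bad)) .row_error("logR", chk$bad, "non-numeric value")
  out$logR <- chk$x
  bad <- which(out$end < out$start)
  if (length(bad)) .row_error("end", bad, "end < start")
  key <- paste(out$sample, out$chrom, out$start, out$end)
  if (anyDuplicated(key)) {
    .row_error("chrom/start/end", which(duplicated(key)), "duplicated segment")
  }
  validate_segments(out)
  out
}

#' Validate an in-memory segment table
#'
#' Checks the invariants expected of a segment table (coordinates present,
#' \code{end >= start}, unique intervals within a sample).
#' @param seg_tb data.frame with columns chrom/start/end/logR (sample optional).
#' @return the input, invisibly, if valid.
#' @export
validate_segments <- function(seg_tb) {
  for (f in c("chrom", "start", "end", "logR")) {
    if (is.null(seg_tb[[f]])) {
      ascn_stop("ascn_format_error", sprintf("required column '%s' not found", f), field = f)
    }
  }
  bad <- which(seg_tb$end < seg_tb$start)
  if (length(bad)) .row_error("end", bad, "end < start")
  invisible(seg_tb)
}

#' Read a SNP pileup table
#'
#' Parses a tab-separated pileup over candidate SNP positions reporting, for
#' each position, the allelic fraction of the alternative base and the read
#' coverage. The format is compatible with the pileup output of allele-specific
#' expression/genotyping pileup tools run on a BAM file over a SNP VCF.
#'
#' Rows with an allelic fraction outside [0, 1] or negative coverage are
#' rejected with their row index; zero-coverage rows are accepted (depth
#' filtering happens downstream, not at I/O time).
#'
#' @param path path to a tab-separated file with a header row.
#' @return a \code{data.frame} with columns \code{chrom}, \code{pos},
#'   \code{af}, \code{cov}, in file order.
#' @export
read_pileup_table <- function(path) {
  df <- .read_tsv(path)
  idx <- vapply(c("chrom", "pos", "af", "cov"), function(f) .resolve_column(df, f), integer(1))
  out <- data.frame(chrom = as.character(df[[idx[["chrom"]]]]), stringsAsFactors = FALSE)
  for (f in c("pos", "af", "cov")) {
    chk <- .as_numeric_checked(df[[idx[[f]]]], f)
    if (length(chk$bad)) .row_error(f, chk$bad, "non-numeric value")
    out[[f]] <- chk$x
  }
  bad <- which(out$af < 0 | out$af > 1)
  if (length(bad)) .row_error("af", bad, "allelic fraction outside [0, 1]")
  bad <- which(out$cov < 0)
  if (length(bad)) .row_error("cov", bad, "negative coverage")
  key <- paste(out$chrom, out$pos)
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    ascn_stop("ascn_validation_error",
              sprintf("duplicated (chrom, pos) entries: %s",
                      paste(utils::head(dups, 10), collapse = "; ")),
              duplicates = dups)
  }
  out
}

#' Read an SNV read-count table
#'
#' Parses a tab-separated table of somatic single-nucleotide variants with
#' reference- and alternative-supporting tumor read counts
#' (\code{rc_ref_tumor}, \code{rc_alt_tumor}). Missing values may be encoded
#' as \code{"-"}.
#'
#' @param path path to a tab-separated file with a header row.
#' @param sample sample identifier used when the table has no sample column.
#' @return a \code{data.frame} with columns \code{sample}, \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}, \code{rc_ref_tumor},
#'   \code{rc_alt_tumor}.
#' @export
read_snv_table <- function(path, sample = NULL) {
  df <- .read_tsv(path)
  idx <- vapply(c("chrom", "pos", "rc_ref_tumor", "rc_alt_tumor"),
                function(f) .resolve_column(df, f), integer(1))
  sidx <- .resolve_column(df, "sample", required = FALSE)
  ridx <- .resolve_column(df, "ref", required = FALSE)
  aidx <- .resolve_column(df, "alt", required = FALSE)
  out <- data.frame(
    sample = if (!is.na(sidx)) as.character(df[[sidx]]) else rep(sample %||% "sample1", nrow(df)),
    chrom  = as.character(df[[idx[["chrom"]]]]),
    stringsAsFactors = FALSE
  )
  chk <- .as_numeric_checked(df[[idx[["pos"]]]], "pos")
  if (length(chk$bad)) .row_error("pos", chk$bad, "non-numeric value")
  out$pos <- chk$x
  out$ref <- if (!is.na(ridx)) as.character(df[[ridx]]) else NA_character_
  out$alt <- if (!is.na(aidx)) as.character(df[[aidx]]) else NA_character_
  for (f in c("rc_ref_tumor", "rc_alt_tumor")) {
    chk <- .as_numeric_checked(df[[idx[[f]]]], f, allow_na = TRUE)
    if (length(chk$bad)) .row_error(f, chk$bad, "non-numeric value")
    if (any(chk$x < 0, na.rm = TRUE)) .row_error(f, which(chk$x < 0), "negative read count")
    out[[f]] <- chk$x
  }
  out
}

#' Write a table as tab-separated text
#'
#' @param tb data.frame.
#' @param path output path.
#' @param na string used to encode missing values (empty by default; the
#'   clonality writers use \code{"-"}).
#' @return the path, invisibly.
#' @export
write_tsv_table <- function(tb, path, na = "") {
  utils::write.table(tb, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = na)
  invisible(path)
}

#' Export a per-segment table in BED-compatible coordinates
#'
#' Internal coordinates are 1-based and inclusive; BED uses 0-based,
#' half-open intervals, so starts are shifted by exactly -1 and ends are
#' left unchanged. All columns beyond chrom/start/end are appended after the
#' first three, which makes the output directly usable for gene-model
#' annotation with standard interval tools.
#'
#' @param tb data.frame carrying chrom/start/end columns (synonyms accepted).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_bed_compatible <- function(tb, path) {
  ci <- .resolve_column(tb, "chrom")
  si <- .resolve_column(tb, "start")
  ei <- .resolve_column(tb, "end")
  rest <- setdiff(seq_along(tb), c(ci, si, ei))
  out <- data.frame(chrom = tb[[ci]], start = tb[[si]] - 1, end = tb[[ei]],
                    stringsAsFactors = FALSE)
  for (j in rest) out[[names(tb)[j]]] <- tb[[j]]
  names(out)[1] <- "#chrom"
  utils::write.table(out, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}
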