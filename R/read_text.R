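# Reader/writer for the per-base methylation call table dialect:
# tab-separated, header row, columns
#   chrBase  chr  base  strand  coverage  freqC  freqT
# strand coded F/R (or +/-), freqC + freqT ~ 100 per row.

.TEXT_COLS <- c("chrBase", "chr", "base", "strand", "coverage",
                "freqC", "freqT")

#' Read a per-base methylation call table
#'
#' Parses the tab-separated per-cytosine dialect with columns
#' \code{chrBase, chr, base, strand, coverage, freqC, freqT}.  \code{freqC}
#' and \code{freqT} are the percent of reads calling the base methylated
#' (C) and unmethylated (T); they must sum to 100 within 0.05 per row
#' (rounding tolerance).  Counts are re-derived as
#' \code{n_meth = round(coverage * freqC / 100)} (half-up) and
#' \code{n_unmeth = coverage - n_meth}.  Strand letters F/R (forward /
#' reverse) and +/- are accepted; records come back sorted.
#'
#' No coverage filter is applied here; use \code{\link{filter_by_coverage}}
#' explicitly.
#'
#' @param path path to the table.
#' @param context methylation context of the calls (default \code{"CpG"}).
#' @param sample_id sample identifier; defaults to the file base name.
#' @param treatment integer group indicator (0 = control).
#' @return a \code{\link{methylome}} at base resolution.
#' @export
read_methylation_text <- function(path, context = "CpG",
                                  sample_id = NULL, treatment = 0L) {
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(nf) == 0L) stop("empty file (no header): ", path)
  bad <- which(nf != nf[1L])
  if (length(bad))
    stop(sprintf("malformed row in %s: line %d has %d fields, expected %d",
                 path, bad[1L], nf[bad[1L]], nf[1L]))
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE,
                           colClasses = c(chrBase = "character",
                                          chr = "character",
                                          strand = "character"))
  missing_cols <- setdiff(.TEXT_COLS, names(tab))
  if (length(missing_cols))
    stop("missing columns in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  if (!nrow(tab)) {
    empty <- data.frame(chrom = character(), start = integer(),
                        end = integer(), strand = character(),
                        n_meth = integer(), n_unmeth = integer())
    return(methylome(empty, sample_id, treatment, context, "base"))
  }
  freq_sum <- tab$freqC + tab$freqT
  off <- which(abs(freq_sum - 100) > 0.05)
  if (length(off))
    stop(sprintf(
      "freqC + freqT = %.2f (expected 100 +/- 0.05) at data row %d of %s",
      freq_sum[off[1L]], off[1L], path))
  strand <- c(F = "+", R = "-", "+" = "+", "-" = "-")[tab$strand]
  if (anyNA(strand))
    stop("unrecognized strand code in ", path, "; expected F/R or +/-")
  n_meth <- as.integer(.round_half_up(tab$coverage * tab$freqC / 100))
  df <- data.frame(chrom = tab$chr, start = tab$base, end = tab$base,
                   strand = unname(strand),
                   n_meth = n_meth,
                   n_unmeth = as.integer(tab$coverage) - n_meth)
  methylome(df, sample_id, treatment, context, "base")
}

#' Write a methylome in the per-base call table dialect
#'
#' Inverse of \code{\link{read_methylation_text}}: emits
#' \code{chrBase chr base strand coverage freqC freqT} with strand coded
#' F/R and frequencies rounded to two decimals.  Only base-resolution
#' methylomes can be serialized in this dialect.
#'
#' @param m a base-resolution \code{\link{methylome}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_methylation_text <- function(m, path) {
  if (m$resolution != "base")
    stop("only base-resolution methylomes can be written in this dialect")
  d <- m$data
  cov <- d$n_meth + d$n_unmeth
  freqC <- round(100 * d$n_meth / cov, 2)
  out <- data.frame(chrBase = paste(d$chrom, d$start, sep = "."),
                    chr = d$chrom, base = d$start,
                    strand = c("+" = "F", "-" = "R", "*" = "F")[d$strand],
                    coverage = cov, freqC = freqC,
                    freqT = round(100 - freqC, 2))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
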