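# Core data containers for per-sample methylation calls.

.VALID_STRANDS  <- c("+", "-", "*")
.VALID_CONTEXTS <- c("CpG", "CHG", "CHH")

# half-up rounding; base round() rounds half to even
.round_half_up <- function(x) floor(x + 0.5)

.unit_key <- function(df) {
  paste(df$chrom, df$start, df$end, df$strand, sep = "\r")
}

.order_units <- function(df) {
  order(df$chrom, df$start, df$end, df$strand, method = "radix")
}

#' Construct a sample methylome
#'
#' A methylome holds, for one sample, the bisulfite-sequencing methylation
#' calls at a set of genomic units: either single cytosines
#' (\code{resolution = "base"}, \code{start == end}) or summarized regions
#' (\code{resolution = "region"}).  Each unit carries the number of reads
#' supporting a methylated call (C read-outs, protected from bisulfite
#' conversion) and an unmethylated call (T read-outs).
#'
#' @param data data.frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{strand} (\code{+}, \code{-} or \code{*}),
#'   \code{n_meth}, \code{n_unmeth}; an optional \code{name} column is
#'   retained (region identity).  Coordinates are 1-based inclusive.
#' @param sample_id character scalar identifying the sample.
#' @param treatment integer group indicator; 0 denotes the control group.
#' @param context methylation context: \code{"CpG"}, \code{"CHG"} or
#'   \code{"CHH"}.
#' @param resolution \code{"base"} or \code{"region"}.
#'
#' @return An object of class \code{methylome}.  Records are sorted by
#'   (chrom, start, end, strand); duplicate unit keys are an error, as is
#'   any unit with zero total coverage.
#' @export
methylome <- function(data, sample_id, treatment = 0L,
                      context = c("CpG", "CHG", "CHH"),
                      resolution = c("base", "region")) {
  context    <- match.arg(context)
  resolution <- match.arg(resolution)
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  req <- c("chrom", "start", "end", "strand", "n_meth", "n_unmeth")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols))
    stop("methylome data is missing columns: ",
         paste(missing_cols, collapse = ", "))
  keep <- c(req, intersect("name", names(data)))
  data <- as.data.frame(data)[, keep, drop = FALSE]
  data$chrom  <- as.character(data$chrom)
  data$strand <- as.character(data$strand)
  data$start  <- as.integer(data$start)
  data$end    <- as.integer(data$end)
  data$n_meth   <- as.integer(data$n_meth)
  data$n_unmeth <- as.integer(data$n_unmeth)
  if (nrow(data)) {
    if (any(!nzchar(data$chrom)) || anyNA(data$chrom))
      stop("chrom must be non-empty")
    if (!all(data$strand %in% .VALID_STRANDS))
      stop("strand must be one of ", paste(.VALID_STRANDS, collapse = " "))
    if (any(data$start > data$end)) stop("start must be <= end")
    if (resolution == "base" && any(data$start != data$end))
      stop("base-resolution units must have start == end")
    if (any(data$n_meth < 0) || any(data$n_unmeth < 0))
      stop("negative call counts")
    if (any(data$n_meth + data$n_unmeth < 1L))
      stop("every unit must have coverage >= 1")
    data <- data[.order_units(data), , drop = FALSE]
    if (anyDuplicated(.unit_key(data)))
      stop("duplicate (chrom, start, end, strand) keys in sample ", sample_id)
    rownames(data) <- NULL
  }
  structure(
    list(sample_id = sample_id, treatment = as.integer(treatment),
         context = context, resolution = resolution, data = data),
    class = "methylome")
}

#' @export
print.methylome <- function(x, ...) {
  cat(sprintf("methylome: %s (treatment=%d, context=%s, resolution=%s)\n",
              x$sample_id, x$treatment, x$context, x$resolution))
  cat(sprintf("  %d units", nrow(x$data)))
  if (nrow(x$data)) {
    cov <- x$data$n_meth + x$data$n_unmeth
    cat(sprintf(", median coverage %.0f, mean methylation %.1f%%",
                stats::median(cov),
                mean(100 * x$data$n_meth / cov)))
  }
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.methylome <- function(x, ...) x$data

#' Number of units in a methylome
#' @param m a \code{methylome}
#' @export
n_units <- function(m) nrow(m$data)

#' Per-unit read coverage
#'
#' Coverage is the number of read-level calls retained at a unit:
#' \code{n_meth + n_unmeth}.
#' @param m a \code{methylome}
#' @return integer vector aligned to the unit order of \code{m}.
#' @export
unit_coverage <- function(m) m$data$n_meth + m$data$n_unmeth

#' Percent methylation from call counts
#'
#' The methylation level of a unit is the fraction of reads calling it
#' methylated, \code{100 * n_meth / (n_meth + n_unmeth)}, reported to two
#' decimals.
#'
#' @param n_meth,n_unmeth non-negative call counts (vectorized).
#' @return percent methylation in \code{[0, 100]}, rounded to two decimals.
#' @export
percent_methylation <- function(n_meth, n_unmeth) {
  cov <- n_meth + n_unmeth
  if (any(cov < 1)) stop("coverage must be >= 1 to compute percent methylation")
  round(100 * n_meth / cov, 2)
}

#' Coverage and base-quality filter policy
#'
#' Default thresholds for processing raw alignments and call tables: a unit
#' must be covered by at least \code{min_coverage} reads, and each read-level
#' call must have PHRED base quality at least \code{min_base_quality}.
#' Optionally, units whose coverage lies strictly above a high empirical
#' percentile of the sample's coverage distribution are discarded; this
#' guards against PCR duplication bias (clonal reads), which inflates a
#' secondary high-coverage mode.
#'
#' @param min_coverage minimum read coverage per unit (reads; default 10).
#' @param min_base_quality minimum PHRED base quality per call (default 20).
#' @param high_coverage_percentile optional percentile in (0, 100), e.g.
#'   99.9; \code{NULL} disables the upper cut.
#' @export
filter_policy <- function(min_coverage = 10L, min_base_quality = 20L,
                          high_coverage_percentile = NULL) {
  stopifnot(min_coverage >= 1)
  if (!is.null(high_coverage_percentile))
    stopifnot(high_coverage_percentile > 0, high_coverage_percentile < 100)
  structure(list(min_coverage = as.integer(min_coverage),
                 min_base_quality = as.integer(min_base_quality),
                 high_coverage_percentile = high_coverage_percentile),
            class = "filter_policy")
}

#' Filter a methylome by read coverage
#'
#' Removes units with coverage below \code{policy$min_coverage} and, when
#' \code{policy$high_coverage_percentile} is set, units with coverage
#' strictly above that empirical percentile of the sample's own coverage
#' distribution (ties at the percentile are retained).  Unit order is
#' preserved; filtering is idempotent.
#'
#' @param m a \code{methylome}
#' @param policy a \code{\link{filter_policy}}
#' @return the filtered \code{methylome} (possibly empty).
#' @export
filter_by_coverage <- function(m, policy = filter_policy()) {
  if (!inherits(m, "methylome")) stop("m must be a methylome")
  if (!n_units(m)) return(m)
  cov <- unit_coverage(m)
  keep <- cov >= policy$min_coverage
  if (!is.null(policy$high_coverage_percentile)) {
    cut <- stats::quantile(cov, policy$high_coverage_percentile / 100,
                           names = FALSE)
    keep <- keep & cov <= cut
  }
  m$data <- m$data[keep, , drop = FALSE]
  rownames(m$data) <- NULL
  m
}
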