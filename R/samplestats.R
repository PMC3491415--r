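# Descriptive statistics, sample-sample correlation, hierarchical
# clustering and PCA on commonly covered units.

.DIST_METHODS <- c("correlation", "euclidean", "maximum", "manhattan",
                   "canberra", "binary", "minkowski")
.LINKAGES <- c(ward = "ward.D2", single = "single", complete = "complete",
               average = "average")

.histogram <- function(x, breaks) {
  h <- graphics::hist(x, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  list(breaks = h$breaks, counts = h$counts, mids = h$mids)
}

.five_summary <- function(x) {
  q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
  c(min = q[1], q1 = q[2], median = q[3], mean = mean(x), q3 = q[4],
    max = q[5])
}

#' Histogram and summary of per-unit percent methylation
#'
#' In normal samples the distribution is typically bimodal: most
#' cytosines are either nearly unmethylated or nearly fully methylated.
#'
#' @param m a \code{\link{methylome}}.
#' @param bins number of equal-width bins over [0, 100].
#' @return list with \code{histogram} (breaks, counts, mids) and
#'   \code{summary} (min, quartiles, mean, max).
#' @export
methylation_stats <- function(m, bins = 20L) {
  pm <- percent_methylation(m$data$n_meth, m$data$n_unmeth)
  list(histogram = .histogram(pm, seq(0, 100, length.out = bins + 1L)),
       summary = .five_summary(pm))
}

#' Histogram and summary of per-unit read coverage
#'
#' A secondary high-coverage mode indicates PCR duplication bias (clonal
#' reads); see \code{\link{filter_policy}} for the corrective upper
#' percentile cut.
#'
#' @param m a \code{\link{methylome}}.
#' @param bins number of bins.
#' @param log10 bin on the log10 scale (useful for long-tailed coverage).
#' @return list with \code{histogram} and \code{summary} (on the original
#'   scale; breaks are log10-transformed when \code{log10 = TRUE}).
#' @export
coverage_stats <- function(m, bins = 20L, log10 = FALSE) {
  cov <- unit_coverage(m)
  x <- if (log10) base::log10(cov) else cov
  breaks <- if (length(unique(x)) == 1L)
    c(x[1L] - 0.5, x[1L] + 0.5)
  else seq(min(x), max(x), length.out = bins + 1L)
  list(histogram = .histogram(x, breaks),
       summary = .five_summary(cov), log10 = log10)
}

#' Pairwise sample correlation of percent-methylation profiles
#'
#' Correlations are computed on the complete-case percent matrix (units
#' covered in every sample).  A sample with zero variance yields NA
#' entries, reported with a warning rather than silently coerced.
#'
#' @param u a \code{united_methylome} with >= 2 samples and >= 3 units.
#' @param method \code{"pearson"}, \code{"kendall"} or \code{"spearman"}.
#' @return symmetric sample x sample correlation matrix with unit
#'   diagonal.
#' @export
correlation_matrix <- function(u, method = c("pearson", "kendall",
                                             "spearman")) {
  method <- match.arg(method)
  pm <- percent_matrix(u)
  if (ncol(pm) < 2L) stop("need at least 2 samples")
  if (nrow(pm) < 3L) stop("need at least 3 commonly covered units")
  flat <- which(apply(pm, 2L, stats::sd) == 0)
  cm <- suppressWarnings(stats::cor(pm, method = method))
  diag(cm) <- 1
  if (length(flat))
    warning("zero-variance sample(s), correlation undefined (NA): ",
            paste(colnames(pm)[flat], collapse = ", "))
  cm
}

#' Pairwise sample distances on percent-methylation profiles
#'
#' \code{"correlation"} distance is 1 - Pearson correlation; the others
#' are the usual geometric metrics on the percent profiles.
#'
#' @param u a \code{united_methylome}.
#' @param method one of \code{"correlation"}, \code{"euclidean"},
#'   \code{"maximum"}, \code{"manhattan"}, \code{"canberra"},
#'   \code{"binary"}, \code{"minkowski"}.
#' @param p Minkowski power.
#' @return a \code{dist} object over samples.
#' @export
sample_dist <- function(u, method = "correlation", p = 2) {
  if (!method %in% .DIST_METHODS)
    stop("unknown distance '", method, "'; valid: ",
         paste(.DIST_METHODS, collapse = ", "))
  pm <- percent_matrix(u)
  if (method == "correlation")
    stats::as.dist(1 - stats::cor(pm, method = "pearson"))
  else
    stats::dist(t(pm), method = method, p = p)
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of the samples' percent-methylation profiles.
#' Ward linkage uses the squared-distance update (\code{ward.D2}).
#'
#' @param u a \code{united_methylome} with >= 2 samples.
#' @param dist_method distance metric, see \code{\link{sample_dist}}.
#' @param linkage \code{"ward"}, \code{"single"}, \code{"complete"} or
#'   \code{"average"}.
#' @param p Minkowski power.
#' @return an \code{hclust} dendrogram with sample leaves.
#' @export
cluster_samples <- function(u, dist_method = "correlation",
                            linkage = "ward", p = 2) {
  if (!linkage %in% names(.LINKAGES))
    stop("unknown linkage '", linkage, "'; valid: ",
         paste(names(.LINKAGES), collapse = ", "))
  if (length(u$samples) < 2L) stop("need at least 2 samples")
  stats::hclust(sample_dist(u, dist_method, p),
                method = .LINKAGES[[linkage]])
}

#' Principal component analysis of samples
#'
#' PCA of the samples' percent-methylation profiles, with samples as
#' observations and commonly covered units as variables.  Components are
#' ordered by decreasing explained variance; each component's sign is
#' fixed so that its largest-magnitude loading is positive, making scores
#' reproducible across platforms.
#'
#' @param u a \code{united_methylome} with >= 2 samples and >= 2 units.
#' @param center,scale. passed to \code{\link[stats]{prcomp}}; defaults
#'   center = TRUE, scale. = FALSE.
#' @return list with \code{scores} (samples x components),
#'   \code{loadings} (units x components), \code{variance_fractions}
#'   (non-increasing, summing to 1) and \code{sdev}.
#' @export
pca_samples <- function(u, center = TRUE, scale. = FALSE) {
  pm <- percent_matrix(u)
  if (ncol(pm) < 2L) stop("need at least 2 samples")
  if (nrow(pm) < 2L) stop("need at least 2 commonly covered units")
  pc <- stats::prcomp(t(pm), center = center, scale. = scale.)
  flip <- apply(pc$rotation, 2L, function(v) {
    s <- sign(v[which.max(abs(v))]); if (s == 0) 1 else s
  })
  pc$rotation <- sweep(pc$rotation, 2L, flip, `*`)
  pc$x <- sweep(pc$x, 2L, flip, `*`)
  v <- pc$sdev^2
  list(scores = pc$x, loadings = pc$rotation,
       variance_fractions = v / sum(v), sdev = pc$sdev)
}
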