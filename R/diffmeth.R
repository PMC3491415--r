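# Per-unit differential methylation testing.
#
# The methylation proportion P_i of sample i at a unit is modeled on the
# logit scale as a function of the treatment indicator T_i,
#     log(P_i / (1 - P_i)) = b0 + b1 * T_i (+ covariate terms),
# with per-sample binomial counts (n_meth successes out of coverage).
# The null hypothesis b1 = 0 is tested by a likelihood-ratio chi-square
# (default) or Wald test.  With exactly one sample per group the exact
# conditional test on the pooled 2x2 table (Fisher) is used instead.

#' Model specification for differential methylation tests
#'
#' @param covariates optional data.frame of per-sample covariates
#'   (continuous or categorical), rows aligned to the samples; covariates
#'   enter the logistic model additively.
#' @param test \code{"likelihood_ratio"} (deviance chi-square, default)
#'   or \code{"wald"}.
#' @param correction q-value method: \code{"slim"} (sliding-linear-model
#'   pi0-scaled FDR, default) or \code{"bh"} (Benjamini-Hochberg).
#' @export
model_spec <- function(covariates = NULL,
                       test = c("likelihood_ratio", "wald"),
                       correction = c("slim", "bh")) {
  if (!is.null(covariates)) covariates <- as.data.frame(covariates)
  structure(list(covariates = covariates, test = match.arg(test),
                 correction = match.arg(correction)),
            class = "model_spec")
}

.check_groups <- function(treatment) {
  if (!any(treatment == 0L)) stop("no control samples (treatment == 0)")
  if (!any(treatment != 0L)) stop("no treatment samples (treatment != 0)")
}

.pooled_diff <- function(n_meth, n_unmeth, treatment) {
  trt <- treatment != 0L
  cov <- n_meth + n_unmeth
  100 * (sum(n_meth[trt]) / sum(cov[trt]) -
         sum(n_meth[!trt]) / sum(cov[!trt]))
}

# x * log(p / q) with the 0 * log(0) := 0 convention
.xlogr <- function(x, p, q) {
  out <- suppressWarnings(x * log(p / q))
  out[x == 0] <- 0
  out
}

#' Logistic-regression test for differential methylation at one unit
#'
#' Fits the binomial logistic model of per-sample methylated counts on the
#' treatment indicator (treatment entered as categorical with control
#' level 0 as reference) and tests whether all treatment coefficients are
#' zero.  The default likelihood-ratio statistic is referred to a
#' chi-square with df = number of treatment levels - 1; it stays finite
#' under complete separation (the fit is then flagged).  Covariates are
#' adjusted for by including them in both the null and full models.
#'
#' The reported methylation difference uses pooled group counts
#' (coverage-weighted), \code{100 * (sum m_T / sum cov_T - sum m_C / sum
#' cov_C)}, not the mean of per-sample percentages.
#'
#' @param n_meth,n_unmeth per-sample call counts (each sample coverage
#'   >= 1).
#' @param treatment integer group indicators; 0 = control, other values
#'   are treatment groups.
#' @param covariates optional per-sample covariate data.frame.
#' @param test \code{"likelihood_ratio"} or \code{"wald"}.
#' @return list with \code{pvalue}, \code{meth_diff} (percentage points,
#'   treatment - control), \code{beta1} (log odds ratio of the first
#'   treatment level vs control; +/-Inf under separation) and
#'   \code{flagged} (TRUE under complete separation of pooled
#'   proportions).
#' @export
logistic_test <- function(n_meth, n_unmeth, treatment, covariates = NULL,
                          test = c("likelihood_ratio", "wald")) {
  test <- match.arg(test)
  stopifnot(length(n_meth) == length(n_unmeth),
            length(n_meth) == length(treatment))
  cov <- n_meth + n_unmeth
  if (any(cov < 1)) stop("every sample must have coverage >= 1")
  .check_groups(treatment)
  grp <- factor(treatment, levels = sort(unique(treatment)))
  p_g <- tapply(n_meth, grp, sum) / tapply(cov, grp, sum)
  p_trt1 <- p_g[[2L]]; p_ctl <- p_g[[1L]]
  beta1 <- log(p_trt1 / (1 - p_trt1)) - log(p_ctl / (1 - p_ctl))
  flagged <- (p_ctl %in% c(0, 1)) && (p_trt1 %in% c(0, 1)) &&
    p_ctl != p_trt1

  if (is.null(covariates) && test == "likelihood_ratio") {
    p0 <- sum(n_meth) / sum(cov)
    pg <- p_g[as.integer(grp)]
    g2 <- 2 * sum(.xlogr(n_meth, pg, p0) +
                  .xlogr(n_unmeth, 1 - pg, 1 - p0))
    pvalue <- stats::pchisq(max(g2, 0), df = nlevels(grp) - 1L,
                            lower.tail = FALSE)
  } else {
    dat <- data.frame(.grp = grp)
    if (!is.null(covariates)) dat <- cbind(dat, covariates)
    y <- cbind(n_meth, n_unmeth)
    full <- suppressWarnings(
      stats::glm(y ~ ., family = stats::binomial(), data = dat))
    if (test == "likelihood_ratio") {
      null <- suppressWarnings(
        stats::glm(y ~ . - .grp, family = stats::binomial(), data = dat))
      stat <- max(null$deviance - full$deviance, 0)
      df <- null$df.residual - full$df.residual
      pvalue <- stats::pchisq(stat, df = df, lower.tail = FALSE)
    } else {
      cf <- grep("^\\.grp", names(stats::coef(full)))
      b <- stats::coef(full)[cf]
      V <- stats::vcov(full)[cf, cf, drop = FALSE]
      stat <- tryCatch(drop(t(b) %*% solve(V, b)), error = function(e) NA)
      pvalue <- if (is.finite(stat))
        stats::pchisq(stat, df = length(cf), lower.tail = FALSE)
      else 1
    }
  }
  list(pvalue = pvalue,
       meth_diff = .pooled_diff(n_meth, n_unmeth, treatment),
       beta1 = unname(beta1), flagged = flagged)
}

# two-sided exact p of a 2x2 table by the point-probability rule:
# condition on the margins; sum hypergeometric probabilities of all
# tables no more probable than the observed one (with a small relative
# guard against floating-point ties).
.fisher_p <- function(a, m1, m2, k) {
  lo <- max(0L, k - m2); hi <- min(m1, k)
  probs <- stats::dhyper(lo:hi, m1, m2, k)
  pobs <- probs[a - lo + 1L]
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

#' Fisher's exact test for a single treatment/control pair
#'
#' Compares the fraction of methylated calls in one treatment and one
#' control sample via the exact conditional (hypergeometric) distribution
#' of the 2x2 table, two-sided by the point-probability method.
#'
#' @param n_meth_t,n_unmeth_t treatment sample counts.
#' @param n_meth_c,n_unmeth_c control sample counts.
#' @return list with \code{pvalue} and \code{meth_diff} (treatment% -
#'   control%).
#' @export
fisher_test <- function(n_meth_t, n_unmeth_t, n_meth_c, n_unmeth_c) {
  m1 <- n_meth_t + n_unmeth_t
  m2 <- n_meth_c + n_unmeth_c
  if (any(c(n_meth_t, n_unmeth_t, n_meth_c, n_unmeth_c) < 0))
    stop("counts must be non-negative")
  if (m1 < 1 || m2 < 1) stop("both samples must have coverage >= 1")
  list(pvalue = .fisher_p(n_meth_t, m1, m2, n_meth_t + n_meth_c),
       meth_diff = 100 * (n_meth_t / m1 - n_meth_c / m2))
}

# vectorized likelihood-ratio chi-square over all units (no covariates)
.lrt_matrix <- function(n_meth, n_unmeth, treatment) {
  cov <- n_meth + n_unmeth
  grp <- factor(treatment, levels = sort(unique(treatment)))
  g2 <- 0
  sm_tot <- rowSums(n_meth); sc_tot <- rowSums(cov)
  p0 <- sm_tot / sc_tot
  ll_g <- function(sm, sc, p) {
    out <- numeric(length(sm))
    i <- sm > 0; out[i] <- sm[i] * log(p[i])
    j <- (sc - sm) > 0; out[j] <- out[j] + (sc - sm)[j] * log(1 - p[j])
    out
  }
  ll_full <- 0
  for (lev in levels(grp)) {
    cols <- which(grp == lev)
    sm <- rowSums(n_meth[, cols, drop = FALSE])
    sc <- rowSums(cov[, cols, drop = FALSE])
    ll_full <- ll_full + ll_g(sm, sc, sm / sc)
  }
  ll_null <- ll_g(sm_tot, sc_tot, p0)
  g2 <- pmax(2 * (ll_full - ll_null), 0)
  stats::pchisq(g2, df = nlevels(grp) - 1L, lower.tail = FALSE)
}

#' Per-unit differential methylation over a united methylome
#'
#' Dispatches the per-unit test by design: with one sample per group the
#' exact conditional test on the 2x2 table (\code{\link{fisher_test}}) is
#' used; with replicates in any group, the binomial logistic-regression
#' test (\code{\link{logistic_test}}).  P-values are corrected to
#' q-values with \code{\link{adjust_pvalues}}.  Results are returned in
#' unit order and are identical for any number of workers.
#'
#' @param u a \code{united_methylome} containing both a control
#'   (treatment 0) and at least one treatment group.
#' @param spec a \code{\link{model_spec}}.
#' @param workers number of parallel workers (forked; chunked by unit
#'   position and concatenated in order).
#' @return a \code{methyl_diff} data.frame with columns \code{chrom},
#'   \code{start}, \code{end}, \code{strand}, \code{pvalue},
#'   \code{qvalue}, \code{meth.diff}, \code{class} (all \code{"none"}
#'   until \code{\link{get_methyl_diff}} selects), with attributes
#'   \code{test} ("fisher" or "logistic") and \code{pi0}.
#' @export
calculate_diff_meth <- function(u, spec = model_spec(), workers = 1L) {
  stopifnot(inherits(u, "united_methylome"))
  trt <- u$treatments
  .check_groups(trt)
  n <- nrow(u$units)
  d <- u$units
  use_fisher <- length(trt) == 2L
  cov <- u$n_meth + u$n_unmeth

  # meth.diff from pooled group counts, vectorized
  t_cols <- which(trt != 0L); c_cols <- which(trt == 0L)
  meth.diff <- 100 *
    (rowSums(u$n_meth[, t_cols, drop = FALSE]) /
       rowSums(cov[, t_cols, drop = FALSE]) -
     rowSums(u$n_meth[, c_cols, drop = FALSE]) /
       rowSums(cov[, c_cols, drop = FALSE]))

  chunk_p <- function(rows) {
    nm <- u$n_meth[rows, , drop = FALSE]
    nu <- u$n_unmeth[rows, , drop = FALSE]
    if (use_fisher) {
      vapply(seq_along(rows), function(i)
        .fisher_p(nm[i, t_cols], nm[i, t_cols] + nu[i, t_cols],
                  nm[i, c_cols] + nu[i, c_cols],
                  nm[i, t_cols] + nm[i, c_cols]),
        0)
    } else if (is.null(spec$covariates) &&
               spec$test == "likelihood_ratio") {
      .lrt_matrix(nm, nu, trt)
    } else {
      vapply(seq_along(rows), function(i)
        logistic_test(nm[i, ], nu[i, ], trt, spec$covariates,
                      spec$test)$pvalue, 0)
    }
  }

  workers <- max(1L, as.integer(workers))
  if (n == 0L) {
    pvalue <- numeric(0)
  } else if (workers == 1L) {
    pvalue <- chunk_p(seq_len(n))
  } else {
    chunks <- split(seq_len(n),
                    cut(seq_len(n), breaks = min(workers, n),
                        labels = FALSE))
    res <- parallel::mclapply(chunks, chunk_p, mc.cores = workers)
    pvalue <- unlist(res, use.names = FALSE)
  }

  q <- adjust_pvalues(pvalue, spec$correction)
  out <- data.frame(chrom = d$chrom, start = d$start, end = d$end,
                    strand = d$strand, pvalue = pvalue,
                    qvalue = as.numeric(q),
                    meth.diff = meth.diff,
                    class = rep("none", n))
  class(out) <- c("methyl_diff", "data.frame")
  attr(out, "test") <- if (use_fisher) "fisher" else "logistic"
  attr(out, "pi0") <- attr(q, "pi0")
  attr(out, "correction") <- spec$correction
  out
}

#' Extract differentially methylated cytosines or regions
#'
#' Retains units with \code{qvalue < qvalue_cut} and absolute methylation
#' difference strictly greater than \code{diff_cut} percentage points
#' (both inequalities strict), optionally restricted to hypermethylated
#' (difference > 0, i.e. higher methylation than the control group) or
#' hypomethylated units.  Defaults: q < 0.01 and |difference| > 25.
#'
#' @param d a \code{methyl_diff} table.
#' @param qvalue_cut q-value threshold (default 0.01).
#' @param diff_cut methylation-difference threshold in percentage points
#'   (default 25).
#' @param type \code{"all"}, \code{"hyper"} or \code{"hypo"}.
#' @return the filtered \code{methyl_diff} with \code{class} set to
#'   \code{"hyper"} or \code{"hypo"}.
#' @export
get_methyl_diff <- function(d, qvalue_cut = 0.01, diff_cut = 25,
                            type = c("all", "hyper", "hypo")) {
  type <- match.arg(type)
  keep <- d$qvalue < qvalue_cut & abs(d$meth.diff) > diff_cut
  keep[is.na(keep)] <- FALSE
  if (type == "hyper") keep <- keep & d$meth.diff > 0
  if (type == "hypo")  keep <- keep & d$meth.diff < 0
  out <- d[keep, , drop = FALSE]
  out$class <- ifelse(out$meth.diff > 0, "hyper", "hypo")
  rownames(out) <- NULL
  out
}

#' Per-chromosome rates of differential methylation
#'
#' For each chromosome, the percentage of covered units called hyper- or
#' hypomethylated at the given cutoffs, plus a genome-wide row.
#'
#' @param d a \code{methyl_diff} table derived from \code{u}.
#' @param u the \code{united_methylome} the tests were run on.
#' @param qvalue_cut,diff_cut extraction cutoffs
#'   (\code{\link{get_methyl_diff}} defaults).
#' @return data.frame with columns \code{chrom}, \code{covered},
#'   \code{n_hyper}, \code{n_hypo}, \code{hyper_pct}, \code{hypo_pct};
#'   last row \code{chrom = "all"}.
#' @export
diff_per_chromosome <- function(d, u, qvalue_cut = 0.01, diff_cut = 25) {
  dm <- get_methyl_diff(d, qvalue_cut, diff_cut, "all")
  chroms <- sort(unique(u$units$chrom))
  covered <- as.integer(table(factor(u$units$chrom, levels = chroms)))
  n_hyper <- as.integer(table(factor(dm$chrom[dm$class == "hyper"],
                                     levels = chroms)))
  n_hypo  <- as.integer(table(factor(dm$chrom[dm$class == "hypo"],
                                     levels = chroms)))
  out <- data.frame(chrom = chroms, covered = covered,
                    n_hyper = n_hyper, n_hypo = n_hypo)
  out <- rbind(out, data.frame(chrom = "all", covered = sum(covered),
                               n_hyper = sum(n_hyper),
                               n_hypo = sum(n_hypo)))
  out$hyper_pct <- ifelse(out$covered > 0,
                          100 * out$n_hyper / out$covered, 0)
  out$hypo_pct  <- ifelse(out$covered > 0,
                          100 * out$n_hypo / out$covered, 0)
  out
}

#' Read a differential methylation table from TSV
#'
#' @param path a file written by \code{\link{write_diff_table}}.
#' @return a \code{methyl_diff} data.frame.
#' @export
read_diff_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("chrom", "start", "end", "strand", "pvalue", "qvalue",
           "meth.diff")
  missing_cols <- setdiff(req, names(d))
  if (length(missing_cols))
    stop("not a differential methylation table, missing: ",
         paste(missing_cols, collapse = ", "))
  if (!"class" %in% names(d)) d$class <- "none"
  class(d) <- c("methyl_diff", "data.frame")
  d
}

#' Serialize a differential methylation table as TSV
#'
#' @param d a \code{methyl_diff} table.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_diff_table <- function(d, path) {
  out <- as.data.frame(d)
  num <- vapply(out, is.numeric, TRUE) &
    !names(out) %in% c("start", "end")
  out[num] <- lapply(out[num], function(x)
    formatC(x, digits = 15, format = "g"))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
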