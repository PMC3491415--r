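# Multiple-testing correction: Benjamini-Hochberg FDR and the
# sliding-linear-model (SLIM) pi0-scaled variant.
#
# BH controls the FDR assuming all hypotheses may be null (pi0 = 1) and
# is therefore conservative when many units carry true signal.  SLIM
# first estimates pi0, the proportion of true nulls, from the shape of
# the p-value distribution: under the null p-values are uniform, so away
# from the signal-bearing left tail the empirical CDF grows linearly
# with slope ~ pi0.  The estimate rescales the BH q-values,
# q_slim = pi0_hat * q_bh, which is never more conservative than BH.

#' Estimate the proportion of true null hypotheses (pi0)
#'
#' Fits ordinary least-squares lines to the empirical CDF of the
#' p-values over a set of sliding windows placed in the upper part of
#' [0, 1] (where true signal contributes little mass); each window's
#' slope estimates the local null density, i.e. pi0.  The median of the
#' window slopes, clamped to [0, 1], is returned.  Degenerate inputs
#' (fewer than 20 p-values, or a non-finite fit) fall back to pi0 = 1,
#' which reduces SLIM to plain BH.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param window_starts left edges of the sliding windows.
#' @param window_width width of each window.
#' @param grid_step spacing of the CDF evaluation grid inside a window.
#' @return pi0 estimate in [0, 1].
#' @export
slim_pi0 <- function(p, window_starts = seq(0.3, 0.7, by = 0.05),
                     window_width = 0.2, grid_step = 0.01) {
  n <- length(p)
  if (n < 20L) return(1)
  Fn <- stats::ecdf(p)
  slopes <- vapply(window_starts, function(l) {
    xs <- seq(l, min(l + window_width, 1), by = grid_step)
    ys <- Fn(xs)
    stats::cov(xs, ys) / stats::var(xs)
  }, 0)
  pi0 <- stats::median(slopes)
  if (!is.finite(pi0)) return(1)
  min(1, max(0, pi0))
}

#' Convert p-values to q-values
#'
#' \code{"bh"} applies the Benjamini-Hochberg step-up procedure,
#' \code{q_(i) = min_(j >= i) (p_(j) * n / j)} capped at 1.
#' \code{"slim"} (default) additionally rescales by the estimated
#' proportion of true nulls: \code{q = pi0_hat * q_bh}, with
#' \code{pi0_hat} from \code{\link{slim_pi0}} clamped to [0, 1]; when the
#' estimate is degenerate the result equals BH.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param method \code{"slim"} or \code{"bh"}.
#' @return numeric vector of q-values with attributes \code{pi0} and
#'   \code{method}.
#' @export
adjust_pvalues <- function(p, method = c("slim", "bh")) {
  method <- match.arg(method)
  if (length(p) && (anyNA(p) || any(p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]")
  q_bh <- stats::p.adjust(p, method = "BH")
  if (method == "bh") {
    pi0 <- 1
    q <- q_bh
  } else {
    pi0 <- slim_pi0(p)
    q <- pmin(1, pi0 * q_bh)
  }
  attr(q, "pi0") <- pi0
  attr(q, "method") <- method
  q
}
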