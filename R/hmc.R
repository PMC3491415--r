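# 5-hydroxymethylcytosine adjustment.
#
# Conventional bisulfite sequencing cannot distinguish 5mC from 5hmC:
# both are protected from conversion, so the apparent methylation level
# is their sum.  Protocols that measure 5hmC directly (oxidative or
# TAB-based bisulfite variants) yield a matched per-base 5hmC level that
# can be subtracted to recover the true 5mC signal.

#' Adjust apparent 5mC levels for measured 5hmC
#'
#' On every base covered in both samples the adjusted methylation level
#' is \code{max(0, mc\% - hmc\%)}; counts are re-derived from the 5mC
#' sample's coverage, \code{n_meth = round(coverage * adjusted\% / 100)}
#' (half-up) and \code{n_unmeth = coverage - n_meth}, so coverage is
#' conserved per base.  Bases absent from the 5hmC sample pass through
#' unchanged (their count is reported in a message); bases covered only
#' in the 5hmC sample are ignored.  The operation is pure: applying it
#' twice subtracts twice.
#'
#' @param mc base-resolution \code{\link{methylome}} of apparent 5mC
#'   levels.
#' @param hmc matched base-resolution \code{methylome} of 5hmC levels
#'   (same context).
#' @return the adjusted 5mC \code{methylome}.
#' @export
adjust_mc_for_hmc <- function(mc, hmc) {
  if (mc$resolution != "base" || hmc$resolution != "base")
    stop("both samples must be at base resolution")
  if (mc$context != hmc$context)
    stop("5mC and 5hmC samples must share the methylation context")
  d <- mc$data
  if (!nrow(d)) return(mc)
  key_mc  <- paste(d$chrom, d$start, d$strand, sep = "\r")
  key_hmc <- paste(hmc$data$chrom, hmc$data$start, hmc$data$strand,
                   sep = "\r")
  idx <- match(key_mc, key_hmc)
  hit <- !is.na(idx)
  if (any(!hit))
    message(sum(!hit), " base(s) not covered in the 5hmC sample left",
            " unadjusted")
  if (any(hit)) {
    cov_mc <- d$n_meth[hit] + d$n_unmeth[hit]
    pct_mc <- 100 * d$n_meth[hit] / cov_mc
    h <- hmc$data[idx[hit], , drop = FALSE]
    pct_hmc <- 100 * h$n_meth / (h$n_meth + h$n_unmeth)
    adj <- pmax(0, pct_mc - pct_hmc)
    n_meth <- as.integer(.round_half_up(cov_mc * adj / 100))
    d$n_meth[hit]   <- n_meth
    d$n_unmeth[hit] <- cov_mc - n_meth
  }
  methylome(d, mc$sample_id, mc$treatment, mc$context, "base")
}
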