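# Synthetic data with known ground truth: methylomes, Bismark-style SAM
# alignments and feature sets.  Every generator is a pure function of its
# spec: the RNG kind is pinned and the previous RNG state is restored on
# exit, so a given seed reproduces the same output on any platform.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed",
                                          envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

#' Specification of a simulated methylation experiment
#'
#' The defaults emulate a typical RRBS setting: read coverage around 30x
#' per site (negative-binomial, so that most sites clear a 10x filter),
#' and a bimodal baseline methylation landscape in which 70% of sites
#' are nearly unmethylated, 20% nearly fully methylated, and the rest
#' intermediate.  An optional clonal spike multiplies the coverage of a
#' random subset of site/sample pairs, mimicking PCR duplication bias.
#' Differential signal is planted by shifting the treatment-group
#' methylation proportion of a fraction of sites by \code{effect_delta}
#' percentage points; affected sites are drawn among sites with enough
#' headroom to express the full shift (methylation gains concentrate at
#' lowly methylated sites, as in CpG-island hypermethylation).
#'
#' @param n_sites number of cytosine sites.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param n_control,n_treatment samples per group.
#' @param coverage_mean,coverage_dispersion negative-binomial coverage
#'   model (mean and size); coverage is clamped to >= 1.
#' @param clonal_fraction fraction of site/sample pairs whose coverage is
#'   multiplied by \code{clonal_factor} (PCR-duplication spike).
#' @param clonal_factor coverage multiplier of the clonal spike.
#' @param baseline \code{"bimodal"} (default) or \code{"uniform"}
#'   (proportions uniform on [0.1, 0.9]; useful for calibration studies
#'   away from the boundary).
#' @param effect_fraction fraction of sites with a planted group
#'   difference.
#' @param effect_delta planted difference in percentage points
#'   (treatment - control), in [-100, 100].
#' @param seed integer seed fixing the full output.
#' @export
sim_spec <- function(n_sites = 1000L,
                     chrom_lengths = c(chr1 = 5e5, chr2 = 5e5),
                     n_control = 4L, n_treatment = 4L,
                     coverage_mean = 30, coverage_dispersion = 8,
                     clonal_fraction = 0, clonal_factor = 10,
                     baseline = c("bimodal", "uniform"),
                     effect_fraction = 0, effect_delta = 0,
                     seed = 1L) {
  baseline <- match.arg(baseline)
  stopifnot(n_sites >= 1, length(chrom_lengths) >= 1,
            !is.null(names(chrom_lengths)),
            n_control >= 1, n_treatment >= 1, coverage_mean > 0,
            coverage_dispersion > 0,
            clonal_fraction >= 0, clonal_fraction <= 1,
            effect_fraction >= 0, effect_fraction <= 1,
            abs(effect_delta) <= 100)
  structure(as.list(environment()), class = "sim_spec")
}

.baseline_props <- function(n, baseline) {
  if (baseline == "uniform") return(stats::runif(n, 0.1, 0.9))
  mode <- sample(c("low", "high", "mid"), n, replace = TRUE,
                 prob = c(0.7, 0.2, 0.1))
  p <- numeric(n)
  p[mode == "low"]  <- stats::rbeta(sum(mode == "low"), 1, 30)
  p[mode == "high"] <- stats::rbeta(sum(mode == "high"), 30, 1)
  p[mode == "mid"]  <- stats::runif(sum(mode == "mid"), 0.1, 0.9)
  p
}

#' Simulate a set of sample methylomes with known ground truth
#'
#' Sites are placed uniformly at random on the specified chromosomes
#' (forward strand).  Per site and sample, coverage is drawn from the
#' spec's negative-binomial model (with optional clonal spike) and the
#' methylated count binomially from the site's group proportion.
#'
#' @param spec a \code{\link{sim_spec}}.
#' @return list with \code{samples} (list of \code{\link{methylome}}
#'   objects, controls first, treatment indicator set) and \code{truth}
#'   (per-site \code{chrom}, \code{start}, \code{p_control},
#'   \code{p_treatment}, \code{affected}).
#' @export
simulate_methylomes <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  .with_seed(spec$seed, {
    n <- spec$n_sites
    chroms <- names(spec$chrom_lengths)
    site_chrom <- sample(chroms, n, replace = TRUE,
                         prob = spec$chrom_lengths /
                           sum(spec$chrom_lengths))
    site_chrom <- site_chrom[order(site_chrom, method = "radix")]
    pos <- unlist(lapply(unique(site_chrom), function(ch) {
      k <- sum(site_chrom == ch)
      sort(sample.int(spec$chrom_lengths[[ch]], k))
    }), use.names = FALSE)

    p_ctl <- .baseline_props(n, spec$baseline)
    p_trt <- p_ctl
    affected <- rep(FALSE, n)
    if (spec$effect_fraction > 0 && spec$effect_delta != 0) {
      shifted <- p_ctl + spec$effect_delta / 100
      eligible <- which(shifted >= 0 & shifted <= 1)
      n_eff <- round(spec$effect_fraction * n)
      if (length(eligible) < n_eff)
        stop("not enough sites can express a shift of ",
             spec$effect_delta, " percentage points")
      idx <- sample(eligible, n_eff)
      affected[idx] <- TRUE
      p_trt[idx] <- shifted[idx]
    }

    ids <- c(paste0("ctrl_", seq_len(spec$n_control)),
             paste0("trt_", seq_len(spec$n_treatment)))
    treat <- c(rep(0L, spec$n_control), rep(1L, spec$n_treatment))
    samples <- vector("list", length(ids))
    for (j in seq_along(ids)) {
      cov <- pmax(1L, stats::rnbinom(n, size = spec$coverage_dispersion,
                                     mu = spec$coverage_mean))
      if (spec$clonal_fraction > 0) {
        clonal <- stats::runif(n) < spec$clonal_fraction
        cov[clonal] <- cov[clonal] * spec$clonal_factor
      }
      p <- if (treat[j] == 0L) p_ctl else p_trt
      n_meth <- stats::rbinom(n, cov, p)
      samples[[j]] <- methylome(
        data.frame(chrom = site_chrom, start = pos, end = pos,
                   strand = "+", n_meth = n_meth,
                   n_unmeth = cov - n_meth),
        sample_id = ids[j], treatment = treat[j])
    }
    list(samples = samples,
         truth = data.frame(chrom = site_chrom, start = pos,
                            p_control = p_ctl, p_treatment = p_trt,
                            affected = affected))
  })
}

#' Write a Bismark-style SAM file realizing specified per-site calls
#'
#' Emits one single-end read per requested call, each carrying an
#' XM-style methylation call string (\code{Z}/\code{z} for CpG,
#' \code{X}/\code{x} CHG, \code{H}/\code{h} CHH) and per-base qualities.
#' High-quality calls get PHRED \code{quality}; the optional
#' \code{n_meth_lowq}/\code{n_unmeth_lowq} columns add calls at
#' \code{low_quality}, which a reader at the default policy (quality >=
#' 20) must exclude.  Reads tile across offsets so the cytosine falls at
#' varying read positions.  Sites with strand \code{-} are written as
#' reverse-complement alignments (FLAG 16).
#'
#' @param path output SAM path.
#' @param sites data.frame with \code{chrom}, \code{pos}, \code{strand},
#'   \code{n_meth}, \code{n_unmeth} and optional \code{n_meth_lowq},
#'   \code{n_unmeth_lowq}.
#' @param chrom_lengths named lengths for the \code{@SQ} header; derived
#'   from the sites when omitted.
#' @param context methylation context of the calls.
#' @param read_length read length in bp.
#' @param quality,low_quality PHRED qualities of normal and low-quality
#'   calls.
#' @param n_unmapped number of additional unmapped reads to append.
#' @return list with \code{path} and \code{expected} (data.frame of the
#'   per-site counts a quality-filtering reader should recover).
#' @export
simulate_sam <- function(path, sites, chrom_lengths = NULL,
                         context = c("CpG", "CHG", "CHH"),
                         read_length = 10L, quality = 40L,
                         low_quality = 10L, n_unmapped = 0L) {
  context <- match.arg(context)
  chars <- .CONTEXT_CHARS[[context]]
  sites <- as.data.frame(sites)
  if (!"n_meth_lowq" %in% names(sites)) sites$n_meth_lowq <- 0L
  if (!"n_unmeth_lowq" %in% names(sites)) sites$n_unmeth_lowq <- 0L
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(sites$pos, sites$chrom, max) + read_length
    chrom_lengths <- stats::setNames(as.integer(chrom_lengths),
                                     names(chrom_lengths))
  }
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                      as.integer(chrom_lengths)))
  lines <- character(0)
  rid <- 0L
  for (s in seq_len(nrow(sites))) {
    st <- sites[s, ]
    calls <- c(rep(chars[1L], st$n_meth), rep(chars[2L], st$n_unmeth),
               rep(chars[1L], st$n_meth_lowq),
               rep(chars[2L], st$n_unmeth_lowq))
    qs <- c(rep(quality, st$n_meth + st$n_unmeth),
            rep(low_quality, st$n_meth_lowq + st$n_unmeth_lowq))
    for (i in seq_along(calls)) {
      rid <- rid + 1L
      offset <- (i - 1L) %% min(read_length, st$pos)
      start <- st$pos - offset
      L <- min(read_length,
               chrom_lengths[[st$chrom]] - start + 1L)
      xm <- rep(".", L); xm[offset + 1L] <- calls[i]
      sq <- rep("A", L)
      sq[offset + 1L] <- if (calls[i] == chars[1L]) "C" else "T"
      qual <- rep(rawToChar(as.raw(33L + quality)), L)
      qual[offset + 1L] <- rawToChar(as.raw(33L + qs[i]))
      flag <- if (st$strand == "-") 16L else 0L
      lines <- c(lines, paste(
        sprintf("read_%05d", rid), flag, st$chrom, start, 42L,
        paste0(L, "M"), "*", 0L, 0L,
        paste(sq, collapse = ""), paste(qual, collapse = ""),
        paste0("XM:Z:", paste(xm, collapse = "")),
        sep = "\t"))
    }
  }
  if (n_unmapped > 0L) {
    for (i in seq_len(n_unmapped)) {
      rid <- rid + 1L
      lines <- c(lines, paste(
        sprintf("read_%05d", rid), 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
        paste(rep("A", read_length), collapse = ""),
        paste(rep(rawToChar(as.raw(33L + quality)), read_length),
              collapse = ""),
        sep = "\t"))
    }
  }
  writeLines(c(header, lines), path)
  expected <- data.frame(chrom = sites$chrom, pos = sites$pos,
                         strand = sites$strand,
                         n_meth = as.integer(sites$n_meth),
                         n_unmeth = as.integer(sites$n_unmeth))
  list(path = path, expected = expected)
}

#' Simulate feature sets for annotation
#'
#' Draws non-degenerate TSS points (random strands), promoters (TSS +/-
#' 1 kb), exons, introns, CpG islands and custom regions on the given
#' chromosomes.  Interval lengths are uniform within kind-typical
#' ranges.
#'
#' @param chrom_lengths named vector of chromosome lengths.
#' @param n_tss,n_exons,n_introns,n_islands,n_custom counts per kind.
#' @param seed integer seed.
#' @return named list of \code{\link{feature_set}}s: \code{tss},
#'   \code{promoters}, \code{exons}, \code{introns}, \code{islands},
#'   \code{custom}.
#' @export
simulate_features <- function(chrom_lengths = c(chr1 = 5e5, chr2 = 5e5),
                              n_tss = 20L, n_exons = 30L,
                              n_introns = 30L, n_islands = 10L,
                              n_custom = 10L, seed = 1L) {
  .with_seed(seed, {
    rand_intervals <- function(k, len_min, len_max, prefix) {
      chrom <- sample(names(chrom_lengths), k, replace = TRUE)
      len <- sample.int(len_max - len_min + 1L, k, replace = TRUE) +
        len_min - 1L
      maxstart <- pmax(1L, chrom_lengths[chrom] - len)
      start <- vapply(maxstart, function(m) sample.int(m, 1L), 0L)
      data.frame(chrom = chrom, start = start, end = start + len - 1L,
                 strand = "*", name = paste0(prefix, seq_len(k)))
    }
    tss_df <- rand_intervals(n_tss, 1L, 1L, "gene")
    tss_df$strand <- sample(c("+", "-"), n_tss, replace = TRUE)
    tss <- feature_set(tss_df, "tss")
    list(tss = tss,
         promoters = promoters_from_tss(tss),
         exons = feature_set(rand_intervals(n_exons, 100L, 500L, "exon"),
                             "exon"),
         introns = feature_set(rand_intervals(n_introns, 200L, 2000L,
                                              "intron"), "intron"),
         islands = feature_set(rand_intervals(n_islands, 300L, 1500L,
                                              "cgi"), "cpg_island"),
         custom = feature_set(rand_intervals(n_custom, 500L, 5000L,
                                             "region"), "custom"))
  })
}
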