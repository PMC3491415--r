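# Joining samples on commonly covered units; summarizing base calls over
# tiling windows or predefined regions.

.methylome_gr <- function(data) {
  GenomicRanges::GRanges(
    seqnames = data$chrom,
    ranges = IRanges::IRanges(start = data$start, end = data$end),
    strand = "*")
}

#' Merge the two strands of each CpG dyad
#'
#' A CpG on the reverse strand reports the cytosine one base downstream of
#' its forward-strand partner.  Destranding shifts reverse-strand records
#' onto the forward-strand coordinate (start - 1) and sums the call counts
#' of the two strands, yielding one record per dyad on strand \code{+}.
#' Only meaningful for CpG-context, base-resolution methylomes.
#'
#' @param m a base-resolution CpG \code{\link{methylome}}.
#' @return the destranded \code{methylome}.
#' @export
destrand <- function(m) {
  if (m$context != "CpG" || m$resolution != "base")
    stop("destranding applies to CpG-context base-resolution methylomes")
  d <- m$data
  if (!nrow(d)) return(m)
  rev <- d$strand == "-"
  d$start[rev] <- d$start[rev] - 1L
  d$end[rev]   <- d$start[rev]
  key <- paste(d$chrom, d$start, sep = "\r")
  n_meth   <- rowsum(d$n_meth, key)
  n_unmeth <- rowsum(d$n_unmeth, key)
  parts <- strsplit(rownames(n_meth), "\r", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(parts, `[`, "", 1L),
    start = as.integer(vapply(parts, `[`, "", 2L)),
    strand = "+",
    n_meth = n_meth[, 1L], n_unmeth = n_unmeth[, 1L])
  out$end <- out$start
  methylome(out, m$sample_id, m$treatment, m$context, m$resolution)
}

#' Join samples on commonly covered units
#'
#' Builds the matrix-like container used by all cross-sample analyses:
#' only units covered in every sample are retained (complete-case join,
#' never imputed), and the per-sample (n_meth, n_unmeth) counts are
#' carried over unchanged.  All samples must share context and
#' resolution.
#'
#' @param samples list of \code{\link{methylome}} objects (at least one);
#'   sample ids must be unique.
#' @param destrand merge CpG dyad strands before joining (CpG base
#'   resolution only; default \code{FALSE}).
#' @return a \code{united_methylome}: unit table plus unit x sample count
#'   matrices and the aligned treatment vector.
#' @export
unite_methylomes <- function(samples, destrand = FALSE) {
  stopifnot(is.list(samples), length(samples) >= 1L)
  if (!all(vapply(samples, inherits, TRUE, "methylome")))
    stop("samples must be a list of methylome objects")
  ctx <- unique(vapply(samples, `[[`, "", "context"))
  res <- unique(vapply(samples, `[[`, "", "resolution"))
  if (length(ctx) > 1L)
    stop("samples have mixed contexts: ", paste(ctx, collapse = ", "))
  if (length(res) > 1L)
    stop("samples have mixed resolutions: ", paste(res, collapse = ", "))
  ids <- vapply(samples, `[[`, "", "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample ids")
  if (destrand) samples <- lapply(samples, bsmethkit::destrand)

  keys <- lapply(samples, function(s) .unit_key(s$data))
  common <- Reduce(intersect, keys)
  if (!length(common))
    warning("no units covered in all samples; united methylome is empty")
  ref <- samples[[1L]]$data
  ref <- ref[match(common, keys[[1L]]), c("chrom", "start", "end", "strand"),
             drop = FALSE]
  ord <- .order_units(ref)
  units <- ref[ord, , drop = FALSE]
  common <- common[ord]
  rownames(units) <- NULL
  n <- length(common); k <- length(samples)
  n_meth   <- matrix(0L, n, k, dimnames = list(NULL, ids))
  n_unmeth <- matrix(0L, n, k, dimnames = list(NULL, ids))
  for (j in seq_len(k)) {
    idx <- match(common, keys[[j]])
    n_meth[, j]   <- samples[[j]]$data$n_meth[idx]
    n_unmeth[, j] <- samples[[j]]$data$n_unmeth[idx]
  }
  structure(
    list(samples = ids,
         treatments = vapply(samples, `[[`, 0L, "treatment"),
         context = ctx, resolution = res,
         units = units, n_meth = n_meth, n_unmeth = n_unmeth),
    class = "united_methylome")
}

#' @export
print.united_methylome <- function(x, ...) {
  cat(sprintf("united_methylome: %d samples x %d units (%s, %s)\n",
              length(x$samples), nrow(x$units), x$context, x$resolution))
  cat("  samples:", paste(sprintf("%s[%d]", x$samples, x$treatments),
                          collapse = " "), "\n")
  invisible(x)
}

#' Percent-methylation matrix of a united methylome
#'
#' @param u a \code{united_methylome}.
#' @return numeric matrix (units x samples) of percent methylation values,
#'   two decimals; no missing cells by construction.
#' @export
percent_matrix <- function(u) {
  stopifnot(inherits(u, "united_methylome"))
  pm <- percent_methylation(u$n_meth, u$n_unmeth)
  dimnames(pm) <- list(NULL, u$samples)
  pm
}

#' Summarize base-level calls over tiling windows
#'
#' Lays windows of \code{window_size} bp per chromosome, anchored at
#' position 1 and stepping by \code{step_size}; each window's counts are
#' the sums over the covered cytosines it contains (strand-agnostic;
#' window strand \code{*}).  Windows containing fewer than
#' \code{min_bases} covered cytosines are omitted.  With
#' \code{step_size < window_size} windows overlap and bases contribute to
#' every window containing them.
#'
#' @param m a base-resolution \code{\link{methylome}}.
#' @param window_size window width in bp (default 1000).
#' @param step_size step between window starts in bp (default 1000).
#' @param min_bases minimum covered cytosines per retained window.
#' @return a region-resolution \code{methylome} of tile counts.
#' @export
tile_methylome <- function(m, window_size = 1000L, step_size = 1000L,
                           min_bases = 1L) {
  if (m$resolution != "base")
    stop("tile_methylome requires a base-resolution methylome")
  stopifnot(window_size >= 1, step_size >= 1, min_bases >= 1)
  d <- m$data
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_meth = integer(), n_unmeth = integer())
  if (!nrow(d))
    return(methylome(empty, m$sample_id, m$treatment, m$context, "region"))
  sp <- split(d$start, d$chrom)
  win <- do.call(rbind, lapply(names(sp), function(ch) {
    data.frame(chrom = ch,
               start = seq.int(1L, max(sp[[ch]]), by = step_size))
  }))
  win$end <- win$start + as.integer(window_size) - 1L
  gr_win  <- .methylome_gr(win)
  gr_base <- .methylome_gr(d)
  ov <- GenomicRanges::findOverlaps(gr_base, gr_win, ignore.strand = TRUE)
  if (!length(ov))
    return(methylome(empty, m$sample_id, m$treatment, m$context, "region"))
  wi <- S4Vectors::subjectHits(ov)
  bi <- S4Vectors::queryHits(ov)
  n_meth   <- rowsum(d$n_meth[bi], wi)
  n_unmeth <- rowsum(d$n_unmeth[bi], wi)
  n_bases  <- rowsum(rep(1L, length(bi)), wi)
  idx <- as.integer(rownames(n_meth))
  keep <- n_bases[, 1L] >= min_bases
  out <- data.frame(chrom = win$chrom[idx][keep],
                    start = win$start[idx][keep],
                    end = win$end[idx][keep],
                    strand = "*",
                    n_meth = n_meth[keep, 1L],
                    n_unmeth = n_unmeth[keep, 1L])
  methylome(out, m$sample_id, m$treatment, m$context, "region")
}

#' Summarize base-level calls over predefined regions
#'
#' Sums methylated/unmethylated counts over the covered cytosines falling
#' inside each region (1-based inclusive overlap, strand ignored).
#' Regions containing no covered cytosine are omitted; region names are
#' preserved.  A base inside two overlapping regions contributes to both.
#'
#' @param m a base-resolution \code{\link{methylome}}.
#' @param regions a \code{\link{feature_set}} (or data.frame with
#'   \code{chrom}, \code{start}, \code{end} and optionally \code{name}).
#' @return a region-resolution \code{methylome}.
#' @export
summarize_regions <- function(m, regions) {
  if (m$resolution != "base")
    stop("summarize_regions requires a base-resolution methylome")
  r <- as.data.frame(regions)
  d <- m$data
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_meth = integer(), n_unmeth = integer())
  if (!nrow(d) || !nrow(r))
    return(methylome(empty, m$sample_id, m$treatment, m$context, "region"))
  ov <- GenomicRanges::findOverlaps(.methylome_gr(d), .methylome_gr(r),
                                    ignore.strand = TRUE)
  if (!length(ov))
    return(methylome(empty, m$sample_id, m$treatment, m$context, "region"))
  ri <- S4Vectors::subjectHits(ov)
  bi <- S4Vectors::queryHits(ov)
  n_meth   <- rowsum(d$n_meth[bi], ri)
  n_unmeth <- rowsum(d$n_unmeth[bi], ri)
  idx <- as.integer(rownames(n_meth))
  out <- data.frame(chrom = r$chrom[idx], start = r$start[idx],
                    end = r$end[idx],
                    strand = if ("strand" %in% names(r))
                      r$strand[idx] else "*",
                    n_meth = n_meth[, 1L], n_unmeth = n_unmeth[, 1L])
  if ("name" %in% names(r)) out$name <- r$name[idx]
  methylome(out, m$sample_id, m$treatment, m$context, "region")
}
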