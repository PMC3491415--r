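# Bismark-style SAM ingestion: per-read methylation call strings (XM tag)
# are tallied into per-cytosine counts, applying base-quality and coverage
# filters.  Call string alphabet: Z/z = CpG meth/unmeth, X/x = CHG,
# H/h = CHH; '.' marks non-cytosine read bases.

.CONTEXT_CHARS <- list(CpG = c("Z", "z"), CHG = c("X", "x"),
                       CHH = c("H", "h"))

# Map each read base to its reference position (NA where the base does not
# consume reference: insertions, soft clips).  Supports M/=/X, I, D, N, S, H.
.cigar_ref_positions <- function(cigar, pos) {
  ops  <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
  len  <- as.integer(sub("[MIDNSHP=X]$", "", ops))
  what <- substring(ops, nchar(ops), nchar(ops))
  refpos <- integer(0)
  r <- pos
  for (i in seq_along(ops)) {
    w <- what[i]; l <- len[i]
    if (w %in% c("M", "=", "X")) {
      refpos <- c(refpos, seq.int(r, length.out = l)); r <- r + l
    } else if (w %in% c("I", "S")) {
      refpos <- c(refpos, rep(NA_integer_, l))
    } else if (w %in% c("D", "N")) {
      r <- r + l
    } # H, P consume neither read nor reported bases
  }
  refpos
}

#' Read methylation calls from a Bismark-style SAM alignment
#'
#' Each aligned read must carry a per-base methylation call string in its
#' \code{XM} tag (Z/z for CpG, X/x for CHG, H/h for CHH methylated /
#' unmethylated calls).  For every cytosine position in the requested
#' context, calls are counted across reads; a call is excluded when its
#' PHRED base quality is below \code{policy$min_base_quality}, and
#' positions whose remaining coverage is below \code{policy$min_coverage}
#' are dropped.  The strand of a record is the strand of the cytosine
#' (reverse-complement alignments report \code{-}).  Unmapped reads are
#' skipped and counted in a message; a mapped read without an \code{XM}
#' tag is an error naming the read.
#'
#' The counting is independent of read order in the file.
#'
#' @param path SAM file with \code{@SQ} header lines.
#' @param policy a \code{\link{filter_policy}}; defaults to coverage >= 10
#'   and base quality >= 20.
#' @param context \code{"CpG"}, \code{"CHG"} or \code{"CHH"}.
#' @param sample_id sample identifier; defaults to the file base name.
#' @param treatment integer group indicator (0 = control).
#' @return a \code{\link{methylome}} at base resolution.
#' @export
read_bismark_sam <- function(path, policy = filter_policy(),
                             context = c("CpG", "CHG", "CHH"),
                             sample_id = NULL, treatment = 0L) {
  context <- match.arg(context)
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  chars <- .CONTEXT_CHARS[[context]]

  bam <- Rsamtools::asBam(path, tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "qual"),
    tag = "XM")
  aln <- Rsamtools::scanBam(bam, param = param)[[1L]]

  n_reads <- length(aln$qname)
  if (!n_reads)
    return(methylome(
      data.frame(chrom = character(), start = integer(), end = integer(),
                 strand = character(), n_meth = integer(),
                 n_unmeth = integer()),
      sample_id, treatment, context, "base"))

  unmapped <- bitwAnd(aln$flag, 4L) > 0L
  if (any(unmapped))
    message(sum(unmapped), " unmapped read(s) skipped in ", path)

  xm    <- aln$tag$XM
  quals <- as.character(aln$qual)
  chrom_v <- strand_v <- character(0)
  pos_v <- integer(0)
  meth_v <- logical(0)
  for (i in seq_len(n_reads)) {
    if (unmapped[i]) next
    if (is.null(xm) || is.na(xm[i]))
      stop("read ", aln$qname[i], " has no XM methylation call string")
    calls <- strsplit(xm[i], "", fixed = TRUE)[[1L]]
    hit <- calls %in% chars
    if (!any(hit)) next
    refpos <- .cigar_ref_positions(aln$cigar[i], aln$pos[i])
    if (length(refpos) != length(calls))
      stop("read ", aln$qname[i],
           ": XM string length does not match the alignment")
    q <- utf8ToInt(quals[i]) - 33L
    keep <- hit & !is.na(refpos) & q >= policy$min_base_quality
    if (!any(keep)) next
    chrom_v  <- c(chrom_v, rep(as.character(aln$rname[i]), sum(keep)))
    pos_v    <- c(pos_v, refpos[keep])
    strand_v <- c(strand_v,
                  rep(if (bitwAnd(aln$flag[i], 16L) > 0L) "-" else "+",
                      sum(keep)))
    meth_v   <- c(meth_v, calls[keep] == chars[1L])
  }

  if (!length(pos_v))
    return(methylome(
      data.frame(chrom = character(), start = integer(), end = integer(),
                 strand = character(), n_meth = integer(),
                 n_unmeth = integer()),
      sample_id, treatment, context, "base"))

  key <- paste(chrom_v, pos_v, strand_v, sep = "\r")
  n_meth   <- rowsum(as.integer(meth_v), key)
  n_total  <- rowsum(rep(1L, length(key)), key)
  parts <- strsplit(rownames(n_meth), "\r", fixed = TRUE)
  df <- data.frame(
    chrom  = vapply(parts, `[`, "", 1L),
    start  = as.integer(vapply(parts, `[`, "", 2L)),
    strand = vapply(parts, `[`, "", 3L),
    n_meth = as.integer(n_meth[, 1L]),
    n_unmeth = as.integer(n_total[, 1L] - n_meth[, 1L]))
  df$end <- df$start
  df <- df[df$n_meth + df$n_unmeth >= policy$min_coverage, , drop = FALSE]
  methylome(df, sample_id, treatment, context, "base")
}
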