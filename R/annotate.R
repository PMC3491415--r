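# Genomic-context annotation of differential methylation events:
# nearest TSS, gene parts, CpG islands and shores, custom regions.
# All internal arithmetic is 1-based inclusive; BED input is converted
# on read.  Strand is ignored for overlap (a methylation event hits a
# feature on either strand); it only sets the sign of TSS distances.

.FEATURE_KINDS <- c("tss", "promoter", "exon", "intron", "cpg_island",
                    "custom")

#' Construct a strand-aware feature set
#'
#' @param data data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (1-based inclusive), optional \code{strand}
#'   (\code{+ - *}) and \code{name}.
#' @param kind one of \code{"tss"}, \code{"promoter"}, \code{"exon"},
#'   \code{"intron"}, \code{"cpg_island"}, \code{"custom"}.
#' @return a \code{feature_set} data.frame with attribute \code{kind}.
#' @export
feature_set <- function(data, kind = "custom") {
  if (!kind %in% .FEATURE_KINDS)
    stop("unknown feature kind '", kind, "'; valid: ",
         paste(.FEATURE_KINDS, collapse = ", "))
  data <- as.data.frame(data)
  stopifnot(all(c("chrom", "start", "end") %in% names(data)))
  if (!"strand" %in% names(data)) data$strand <- rep("*", nrow(data))
  if (!"name" %in% names(data))
    data$name <- if (nrow(data))
      paste0(kind, "_", seq_len(nrow(data))) else character(0)
  data$strand[!data$strand %in% c("+", "-")] <- "*"
  if (any(data$start > data$end)) stop("feature start must be <= end")
  if (any(data$start < 1)) stop("feature start must be >= 1")
  data <- data[, c("chrom", "start", "end", "strand", "name")]
  data$start <- as.integer(data$start); data$end <- as.integer(data$end)
  rownames(data) <- NULL
  structure(data, class = c("feature_set", "data.frame"), kind = kind)
}

#' Read a feature set from a BED file
#'
#' BED is 0-based half-open; coordinates are converted to the package's
#' 1-based inclusive convention on read.
#'
#' @param path BED file (3+ columns; name and strand used when present).
#' @param kind feature kind, see \code{\link{feature_set}}.
#' @return a \code{feature_set}.
#' @export
read_features <- function(path, kind = "custom") {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)))
  nm <- gr$name
  if (!is.null(nm) && !all(is.na(nm))) df$name <- nm
  feature_set(df, kind)
}

#' Write a feature set as BED
#'
#' @param fs a \code{feature_set}.
#' @param path output path (coordinates converted to 0-based half-open).
#' @return \code{path}, invisibly.
#' @export
write_features <- function(fs, path) {
  d <- as.data.frame(fs)
  out <- data.frame(d$chrom, d$start - 1L, d$end, d$name, 0L, d$strand)
  out[[6]][out[[6]] == "*"] <- "."
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Promoter intervals around transcription start sites
#'
#' The promoter of a gene is taken as a fixed window around its TSS
#' (default +/- 1000 bp), clipped at position 1.
#'
#' @param tss a \code{feature_set} of TSS points.
#' @param upstream,downstream extent in bp on each side of the TSS.
#' @return a promoter \code{feature_set}.
#' @export
promoters_from_tss <- function(tss, upstream = 1000L,
                               downstream = 1000L) {
  d <- as.data.frame(tss)
  minus <- d$strand == "-"
  start <- ifelse(minus, d$start - downstream, d$start - upstream)
  end   <- ifelse(minus, d$start + upstream, d$start + downstream)
  feature_set(data.frame(chrom = d$chrom, start = pmax(1L, start),
                         end = end, strand = d$strand, name = d$name),
              "promoter")
}

.events_df <- function(events) {
  d <- as.data.frame(events)
  stopifnot(all(c("chrom", "start", "end") %in% names(d)))
  d
}

# any-overlap of events against a feature data.frame (strand-blind)
.overlaps_any <- function(ev, fs) {
  if (is.null(fs) || !nrow(as.data.frame(fs)))
    return(rep(FALSE, nrow(ev)))
  ov <- GenomicRanges::findOverlaps(.methylome_gr(ev),
                                    .methylome_gr(as.data.frame(fs)),
                                    ignore.strand = TRUE)
  seq_len(nrow(ev)) %in% S4Vectors::queryHits(ov)
}

.annotation_summary <- function(assignments, labels) {
  counts <- table(factor(assignments$label, levels = labels))
  pct <- if (nrow(assignments))
    100 * as.numeric(counts) / nrow(assignments)
  else rep(0, length(labels))
  names(pct) <- labels
  structure(list(assignments = assignments, percentages = pct),
            class = "annotation_summary")
}

#' @export
print.annotation_summary <- function(x, ...) {
  cat("annotation of", nrow(x$assignments), "events:\n")
  for (l in names(x$percentages))
    cat(sprintf("  %-12s %6.2f%%\n", l, x$percentages[[l]]))
  invisible(x)
}

#' Signed distance from each event to its nearest TSS
#'
#' Distances are signed relative to the direction of transcription:
#' event position minus TSS position, with the sign flipped for TSS on
#' the minus strand, so that positive always means downstream of the
#' TSS.  The nearest TSS is chosen by absolute distance; ties are broken
#' by lowest TSS coordinate, then name.  Events on chromosomes absent
#' from the TSS set get NA with a message.
#'
#' @param events a \code{methyl_diff} table (or data.frame with
#'   \code{chrom}, \code{start}, \code{end}).
#' @param tss a non-empty \code{feature_set} of TSS points (strand
#'   meaningful).
#' @return data.frame with per-event \code{dist_to_tss} (signed bp) and
#'   \code{tss_name}.
#' @export
nearest_tss <- function(events, tss) {
  ev <- .events_df(events)
  td <- as.data.frame(tss)
  if (!nrow(td)) stop("TSS feature set is empty")
  td <- td[order(td$chrom, td$start, td$name, method = "radix"), ,
           drop = FALSE]
  out <- data.frame(dist_to_tss = rep(NA_real_, nrow(ev)),
                    tss_name = rep(NA_character_, nrow(ev)))
  missing_chrom <- 0L
  for (ch in unique(ev$chrom)) {
    ei <- which(ev$chrom == ch)
    ti <- which(td$chrom == ch)
    if (!length(ti)) { missing_chrom <- missing_chrom + length(ei); next }
    tpos <- td$start[ti]
    for (i in ei) {
      pos <- ev$start[i]
      dabs <- abs(pos - tpos)
      best <- which(dabs == min(dabs))[1L]  # sorted: lowest coord, then name
      j <- ti[best]
      d <- pos - td$start[j]
      if (td$strand[j] == "-") d <- -d
      out$dist_to_tss[i] <- d
      out$tss_name[i] <- td$name[j]
    }
  }
  if (missing_chrom)
    message(missing_chrom,
            " event(s) on chromosomes absent from the TSS set")
  cbind(ev[, c("chrom", "start", "end")], out)
}

#' Assign events to gene parts
#'
#' Each event receives exactly one label with precedence
#' promoter > exon > intron > intergenic (any-overlap, strand-blind), so
#' the category percentages always partition the event set.
#'
#' @param events event table (see \code{\link{nearest_tss}}).
#' @param promoters,exons,introns \code{feature_set}s (any may be empty).
#' @return an \code{annotation_summary}: per-event assignments and
#'   category percentages summing to 100.
#' @export
annotate_gene_parts <- function(events, promoters, exons, introns) {
  ev <- .events_df(events)
  label <- rep("intergenic", nrow(ev))
  label[.overlaps_any(ev, introns)]   <- "intron"
  label[.overlaps_any(ev, exons)]     <- "exon"
  label[.overlaps_any(ev, promoters)] <- "promoter"
  assignments <- cbind(ev[, c("chrom", "start", "end")], label = label)
  .annotation_summary(assignments,
                      c("promoter", "exon", "intron", "intergenic"))
}

#' CpG island shores
#'
#' Shores are the flanking zones adjacent to CpG islands (default 2 kb
#' on each side): \code{[start - flank, start - 1]} and
#' \code{[end + 1, end + flank]} per island, clipped at position 1.
#'
#' @param islands a CpG-island \code{feature_set}.
#' @param flank shore width in bp (default 2000).
#' @return a \code{feature_set} of shore intervals.
#' @export
cpg_shores <- function(islands, flank = 2000L) {
  d <- as.data.frame(islands)
  left <- data.frame(chrom = d$chrom, start = pmax(1L, d$start - flank),
                     end = d$start - 1L, strand = "*",
                     name = paste0(d$name, "_shore_left"))
  right <- data.frame(chrom = d$chrom, start = d$end + 1L,
                      end = d$end + flank, strand = "*",
                      name = paste0(d$name, "_shore_right"))
  sh <- rbind(left, right)
  sh <- sh[sh$start <= sh$end, , drop = FALSE]
  feature_set(sh, "custom")
}

#' Assign events to CpG islands, shores, or other
#'
#' Labels with precedence island > shore > other: an event inside an
#' island is always "island", even when it also lies within a shore of a
#' neighboring island.
#'
#' @param events event table.
#' @param islands a CpG-island \code{feature_set}.
#' @param shore_flank shore width in bp (default 2000).
#' @return an \code{annotation_summary} over labels island / shore /
#'   other.
#' @export
annotate_cpg <- function(events, islands, shore_flank = 2000L) {
  ev <- .events_df(events)
  label <- rep("other", nrow(ev))
  label[.overlaps_any(ev, cpg_shores(islands, shore_flank))] <- "shore"
  label[.overlaps_any(ev, islands)] <- "island"
  assignments <- cbind(ev[, c("chrom", "start", "end")], label = label)
  .annotation_summary(assignments, c("island", "shore", "other"))
}

#' Overlap of events with user-supplied regions
#'
#' @param events event table.
#' @param regions a \code{feature_set} of custom regions (enhancers,
#'   repeats, ...); may be empty.
#' @return an \code{annotation_summary} over labels inside / outside.
#' @export
annotate_custom <- function(events, regions) {
  ev <- .events_df(events)
  inside <- .overlaps_any(ev, regions)
  assignments <- cbind(ev[, c("chrom", "start", "end")],
                       label = ifelse(inside, "inside", "outside"))
  .annotation_summary(assignments, c("inside", "outside"))
}
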