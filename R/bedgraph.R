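# bedGraph export of differential methylation calls for genome browsers.

.bedgraph_block <- function(d, name) {
  header <- sprintf(
    "track type=bedGraph name=\"%s\" description=\"methylation difference (%%)\"",
    name)
  if (!nrow(d)) return(header)
  c(header,
    paste(d$chrom, d$start - 1L, d$end,
          format(d$meth.diff, scientific = FALSE, trim = TRUE)))
}

#' Write differential methylation calls as a bedGraph track
#'
#' Emits \code{chrom start0 end value} lines with 0-based half-open
#' coordinates (\code{start0 = start - 1}) and the methylation difference
#' in percentage points as the track value, preceded by a
#' \code{track type=bedGraph} header.  \code{track = "hyper"} or
#' \code{"hypo"} restricts to gains or losses relative to the control
#' group (written as separate track blocks when \code{"all"} is split by
#' sign via \code{split_by_sign}).
#'
#' @param d a \code{methyl_diff} table (or any data.frame with
#'   \code{chrom}, \code{start}, \code{end}, \code{meth.diff}).
#' @param path output file.
#' @param track \code{"all"}, \code{"hyper"} or \code{"hypo"}.
#' @param split_by_sign when \code{track = "all"}, write two track blocks
#'   (hyper then hypo) instead of one combined block.
#' @param name track name stem used in the header line.
#' @return \code{path}, invisibly.
#' @export
write_bedgraph <- function(d, path, track = c("all", "hyper", "hypo"),
                           split_by_sign = FALSE, name = "meth.diff") {
  track <- match.arg(track)
  d <- as.data.frame(d)
  hyper <- d[d$meth.diff > 0, , drop = FALSE]
  hypo  <- d[d$meth.diff < 0, , drop = FALSE]
  lines <- switch(track,
    hyper = .bedgraph_block(hyper, paste0(name, ".hyper")),
    hypo  = .bedgraph_block(hypo, paste0(name, ".hypo")),
    all   = if (split_by_sign)
      c(.bedgraph_block(hyper, paste0(name, ".hyper")),
        .bedgraph_block(hypo, paste0(name, ".hypo")))
    else .bedgraph_block(d, name))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
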