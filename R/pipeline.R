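# End-to-end workflow: import -> filter -> (tile | regions) -> unite ->
# sample statistics -> differential methylation -> extraction ->
# annotation -> export.

#' Configuration of an end-to-end run
#'
#' Bundles inputs and options for \code{\link{run_pipeline}}.  Every
#' default equals the package-wide defaults of the underlying functions
#' (coverage >= 10, base quality >= 20, q-value < 0.01, |difference| >
#' 25, shore flank 2000 bp).
#'
#' @param inputs character vector of per-base call tables (the
#'   \code{\link{read_methylation_text}} dialect), or a list of
#'   \code{\link{methylome}} objects.
#' @param sample_ids sample identifiers (defaults to file base names).
#' @param treatments integer treatment vector aligned to \code{inputs};
#'   0 = control.
#' @param context methylation context.
#' @param policy a \code{\link{filter_policy}}.
#' @param tiling \code{NULL} or \code{list(window_size, step_size,
#'   min_bases)} for tiling-window summarization.
#' @param regions \code{NULL}, a BED path or a \code{feature_set}:
#'   summarize over predefined regions instead of bases.
#' @param destrand merge CpG dyad strands before uniting.
#' @param spec a \code{\link{model_spec}}.
#' @param qvalue_cut,diff_cut DMC/DMR extraction cutoffs.
#' @param tss,islands,custom optional annotation inputs (BED path or
#'   \code{feature_set}).
#' @param shore_flank CpG shore width (bp).
#' @param promoter_flank promoter half-width around the TSS (bp).
#' @param out_dir output directory (created if absent).
#' @param workers parallel workers for the differential test.
#' @param seed integer seed recorded in the run summary.
#' @export
run_config <- function(inputs, treatments, sample_ids = NULL,
                       context = "CpG", policy = filter_policy(),
                       tiling = NULL, regions = NULL, destrand = FALSE,
                       spec = model_spec(), qvalue_cut = 0.01,
                       diff_cut = 25, tss = NULL, exons = NULL,
                       introns = NULL, islands = NULL,
                       custom = NULL, shore_flank = 2000L,
                       promoter_flank = 1000L, out_dir, workers = 1L,
                       seed = 1L) {
  if (length(treatments) != length(inputs))
    stop("treatments must have one entry per input")
  if (is.character(inputs) && is.null(sample_ids))
    sample_ids <- sub("\\.[^.]*$", "", basename(inputs))
  if (!is.null(tiling) && !is.null(regions))
    stop("choose tiling windows or predefined regions, not both")
  structure(as.list(environment()), class = "run_config")
}

.load_features <- function(x, kind) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "feature_set")) return(x)
  read_features(x, kind)
}

.write_united <- function(u, path) {
  out <- u$units
  for (j in seq_along(u$samples)) {
    out[[paste0("nMeth_", u$samples[j])]] <- u$n_meth[, j]
    out[[paste0("nUnmeth_", u$samples[j])]] <- u$n_unmeth[, j]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

.write_matrix <- function(m, path) {
  utils::write.table(
    data.frame(sample = rownames(m),
               formatC(m, digits = 15, format = "g"),
               check.names = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis workflow
#'
#' Executes import, filtering, optional regional summarization, the
#' complete-case join, sample statistics, differential methylation
#' testing, DMC/DMR extraction, optional annotation, and export.  All
#' tabular outputs and the JSON run summary are written under
#' \code{cfg$out_dir}; the summary records stage counts and the
#' parameters used, so a rerun with the same inputs and configuration
#' reproduces byte-identical files regardless of the worker count.
#' Stage progress goes to \code{message()}.
#'
#' @param cfg a \code{\link{run_config}}.
#' @return the run summary list, invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name) message("[bsmethkit] stage: ", name)

  stage("import")
  samples <- if (is.character(cfg$inputs)) {
    lapply(seq_along(cfg$inputs), function(i)
      read_methylation_text(cfg$inputs[i], context = cfg$context,
                            sample_id = cfg$sample_ids[i],
                            treatment = cfg$treatments[i]))
  } else {
    lapply(seq_along(cfg$inputs), function(i) {
      s <- cfg$inputs[[i]]
      s$treatment <- as.integer(cfg$treatments[i])
      s
    })
  }
  units_read <- vapply(samples, n_units, 0L)

  stage("filter")
  samples <- lapply(samples, filter_by_coverage, policy = cfg$policy)
  units_filtered <- vapply(samples, n_units, 0L)

  if (!is.null(cfg$tiling)) {
    stage("tile")
    samples <- lapply(samples, function(s)
      do.call(tile_methylome, c(list(m = s), cfg$tiling)))
  } else if (!is.null(cfg$regions)) {
    stage("regions")
    reg <- .load_features(cfg$regions, "custom")
    samples <- lapply(samples, summarize_regions, regions = reg)
  }

  stage("unite")
  u <- unite_methylomes(samples, destrand = cfg$destrand)
  if (!nrow(u$units))
    stop("unite: no units are covered in all samples after filtering; ",
         "lower min_coverage or use regional summarization")
  .write_united(u, file.path(cfg$out_dir, "united.tsv"))

  stage("stats")
  cm <- NULL
  if (length(u$samples) >= 2L && nrow(u$units) >= 3L) {
    cm <- correlation_matrix(u)
    .write_matrix(cm, file.path(cfg$out_dir, "correlation.tsv"))
  }

  stage("diff")
  d <- calculate_diff_meth(u, spec = cfg$spec, workers = cfg$workers)
  write_diff_table(d, file.path(cfg$out_dir, "diff.tsv"))

  stage("extract")
  dm <- get_methyl_diff(d, cfg$qvalue_cut, cfg$diff_cut, "all")
  write_diff_table(dm, file.path(cfg$out_dir, "dmc.tsv"))
  write_bedgraph(dm, file.path(cfg$out_dir, "dmc_hyper.bedgraph"),
                 track = "hyper")
  write_bedgraph(dm, file.path(cfg$out_dir, "dmc_hypo.bedgraph"),
                 track = "hypo")
  per_chr <- diff_per_chromosome(d, u, cfg$qvalue_cut, cfg$diff_cut)
  utils::write.table(per_chr,
                     file.path(cfg$out_dir, "per_chromosome.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  annotation <- list()
  tss <- .load_features(cfg$tss, "tss")
  islands <- .load_features(cfg$islands, "cpg_island")
  custom <- .load_features(cfg$custom, "custom")
  if (!is.null(tss) || !is.null(islands) || !is.null(custom))
    stage("annotate")
  if (!is.null(tss)) {
    nt <- nearest_tss(dm, tss)
    utils::write.table(nt, file.path(cfg$out_dir, "tss_distance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    empty_fs <- function(kind)
      feature_set(data.frame(chrom = character(), start = integer(),
                             end = integer()), kind)
    exons <- .load_features(cfg$exons, "exon")
    introns <- .load_features(cfg$introns, "intron")
    gp <- annotate_gene_parts(
      dm, promoters_from_tss(tss, cfg$promoter_flank,
                             cfg$promoter_flank),
      if (is.null(exons)) empty_fs("exon") else exons,
      if (is.null(introns)) empty_fs("intron") else introns)
    annotation$gene_parts <- as.list(gp$percentages)
  }
  if (!is.null(islands)) {
    cg <- annotate_cpg(dm, islands, cfg$shore_flank)
    annotation$cpg <- as.list(cg$percentages)
  }
  if (!is.null(custom)) {
    cu <- annotate_custom(dm, custom)
    annotation$custom <- as.list(cu$percentages)
  }

  stage("export")
  summary <- list(
    samples = as.list(stats::setNames(units_read, u$samples)),
    units_after_filter = as.list(stats::setNames(units_filtered,
                                                 u$samples)),
    treatments = cfg$treatments,
    resolution = u$resolution,
    united_units = nrow(u$units),
    test = attr(d, "test"),
    correction = attr(d, "correction"),
    pi0 = attr(d, "pi0"),
    n_dmc = nrow(dm),
    n_hyper = sum(dm$class == "hyper"),
    n_hypo = sum(dm$class == "hypo"),
    parameters = list(min_coverage = cfg$policy$min_coverage,
                      min_base_quality = cfg$policy$min_base_quality,
                      qvalue_cut = cfg$qvalue_cut,
                      diff_cut = cfg$diff_cut,
                      shore_flank = cfg$shore_flank,
                      seed = cfg$seed),
    annotation = annotation)
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}
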