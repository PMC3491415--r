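# Genomic-context annotation: TSS distances, gene parts, CpG islands
# and shores, custom regions.

events_at <- function(pos, chrom = "chr1") {
  data.frame(chrom = chrom, start = pos, end = pos)
}

test_that("nearest TSS distances are signed by transcription direction", {
  tss <- feature_set(data.frame(chrom = "chr1",
                                start = c(1000L, 2000L, 5000L),
                                end = c(1000L, 2000L, 5000L),
                                strand = c("+", "+", "-"),
                                name = c("gA", "gB", "gC")), "tss")
  nt <- nearest_tss(events_at(c(1500L, 1000L, 5400L, 4900L)), tss)
  # 1500 ties between TSS 1000 and 2000 -> lowest coordinate wins
  expect_equal(nt$dist_to_tss[1], 500)
  expect_equal(nt$tss_name[1], "gA")
  # event exactly at a TSS
  expect_equal(nt$dist_to_tss[2], 0)
  # minus-strand TSS: downstream is toward lower coordinates
  expect_equal(nt$dist_to_tss[3], -400)
  expect_equal(nt$dist_to_tss[4], 100)
  expect_equal(nt$tss_name[3], "gC")

  expect_message(
    miss <- nearest_tss(events_at(10L, chrom = "chrUn"), tss),
    "absent")
  expect_true(is.na(miss$dist_to_tss))
  expect_error(nearest_tss(events_at(1L), tss[0, ]), "empty")
})

test_that("tie-breaking prefers lowest coordinate then name", {
  tss <- feature_set(data.frame(chrom = "chr1", start = c(3000L, 3000L),
                                end = c(3000L, 3000L), strand = "+",
                                name = c("zeta", "alpha")), "tss")
  nt <- nearest_tss(events_at(3100L), tss)
  expect_equal(nt$tss_name, "alpha")
})

test_that("gene-part labels form a precedence-resolved partition", {
  promoters <- feature_set(data.frame(chrom = "chr1", start = 900L,
                                      end = 1100L), "promoter")
  exons <- feature_set(data.frame(chrom = "chr1",
                                  start = c(1000L, 3000L),
                                  end = c(1600L, 3500L)), "exon")
  introns <- feature_set(data.frame(chrom = "chr1", start = 1601L,
                                    end = 2999L), "intron")
  ann <- annotate_gene_parts(events_at(c(1050L, 1300L, 2000L, 9000L)),
                             promoters, exons, introns)
  expect_equal(ann$assignments$label,
               c("promoter", "exon", "intron", "intergenic"))
  expect_equal(sum(ann$percentages), 100)
  expect_equal(unname(ann$percentages), c(25, 25, 25, 25))
})

test_that("annotation percentages always sum to 100 on random data", {
  feats <- simulate_features(seed = 71)
  set.seed(72)
  ev <- events_at(sample.int(5e5, 300),
                  chrom = sample(c("chr1", "chr2"), 300, TRUE))
  gp <- annotate_gene_parts(ev, feats$promoters, feats$exons,
                            feats$introns)
  expect_equal(sum(gp$percentages), 100, tolerance = 0.1)
  expect_equal(nrow(gp$assignments), 300L)
  expect_true(all(table(gp$assignments$label) >= 0))  # one label each
  cg <- annotate_cpg(ev, feats$islands)
  expect_equal(sum(cg$percentages), 100, tolerance = 0.1)

  # invariance to feature ordering
  shuffle <- function(fs) feature_set(
    as.data.frame(fs)[sample(nrow(as.data.frame(fs))), ],
    attr(fs, "kind"))
  set.seed(73)
  gp2 <- annotate_gene_parts(ev, shuffle(feats$promoters),
                             shuffle(feats$exons), shuffle(feats$introns))
  expect_equal(gp$assignments, gp2$assignments)
})

test_that("CpG shore arithmetic matches the 2 kb flank definition", {
  islands <- feature_set(data.frame(chrom = "chr1", start = 10000L,
                                    end = 10500L, name = "cgi1"),
                         "cpg_island")
  sh <- as.data.frame(cpg_shores(islands))
  expect_equal(sh$start, c(8000L, 10501L))
  expect_equal(sh$end, c(9999L, 12500L))

  ann <- annotate_cpg(events_at(c(9500L, 10200L, 12500L, 12501L,
                                  8000L, 7999L)), islands)
  expect_equal(ann$assignments$label,
               c("shore", "island", "shore", "other", "shore", "other"))

  # shores never cover their own island
  ov <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(sh$chrom,
                           IRanges::IRanges(sh$start, sh$end)),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(10000, 10500)))
  expect_length(ov, 0L)

  # island precedence over a neighboring island's shore
  two <- feature_set(data.frame(chrom = "chr1",
                                start = c(10000L, 11000L),
                                end = c(10500L, 11400L)), "cpg_island")
  ann2 <- annotate_cpg(events_at(11200L), two)
  expect_equal(ann2$assignments$label, "island")

  # flank clipped at position 1
  near_edge <- feature_set(data.frame(chrom = "chr1", start = 500L,
                                      end = 900L), "cpg_island")
  sh2 <- as.data.frame(cpg_shores(near_edge))
  expect_equal(sh2$start[1], 1L)
})

test_that("custom-region overlap equals brute-force containment", {
  big <- feature_set(data.frame(chrom = "chr1", start = 1L,
                                end = 1000000L))
  all_in <- annotate_custom(events_at(c(5L, 500L)), big)
  expect_equal(unname(all_in$percentages["inside"]), 100)

  none <- annotate_custom(events_at(c(5L, 500L)), big[0, ])
  expect_equal(unname(none$percentages["inside"]), 0)

  feats <- simulate_features(seed = 74)
  set.seed(75)
  ev <- events_at(sample.int(5e5, 200),
                  chrom = sample(c("chr1", "chr2"), 200, TRUE))
  got <- annotate_custom(ev, feats$custom)
  rd <- as.data.frame(feats$custom)
  oracle <- vapply(seq_len(nrow(ev)), function(i)
    any(rd$chrom == ev$chrom[i] & rd$start <= ev$start[i] &
          rd$end >= ev$start[i]), TRUE)
  expect_equal(got$assignments$label,
               ifelse(oracle, "inside", "outside"))
})
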