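# Small in-code fixture builders shared across test files.

mk_methylome <- function(pos, n_meth, n_unmeth, chrom = "chr1",
                         strand = "+", sample_id = "s1",
                         treatment = 0L, resolution = "base",
                         end = pos) {
  methylome(data.frame(chrom = rep_len(chrom, length(pos)), start = pos,
                       end = end,
                       strand = rep_len(strand, length(pos)),
                       n_meth = n_meth, n_unmeth = n_unmeth),
            sample_id = sample_id, treatment = treatment,
            resolution = resolution)
}

example_calls_path <- function() {
  system.file("extdata", "example_cpg_calls.txt", package = "bsmethkit")
}

# exact two-sided point-probability p of a 2x2 table by direct
# enumeration over the conditional distribution, using log-binomial
# coefficients (independent of the dhyper-based implementation)
enum_fisher_p <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  lo <- max(0L, k - m2); hi <- min(m1, k)
  x <- lo:hi
  lp <- lchoose(m1, x) + lchoose(m2, k - x) - lchoose(m1 + m2, k)
  probs <- exp(lp)
  pobs <- probs[a - lo + 1L]
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# write a simulated sample set to text files in the Table-dialect
write_sim_inputs <- function(sim, dir) {
  vapply(sim$samples, function(s) {
    p <- file.path(dir, paste0(s$sample_id, ".txt"))
    write_methylation_text(s, p)
    p
  }, "")
}
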