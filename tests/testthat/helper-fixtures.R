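# Shared fixture builders for the test suite. All fixtures are built in
# code; file-based fixtures are written to tempdir() on the fly.

# standard study chromosome: 100 cM, centromere at 20% of the length
chrom100 <- function(...) chromosome_spec("1", 100, 20, ...)

cfg_haldane <- function() chiasma_config(interference = FALSE)
cfg_kosambi <- function() chiasma_config(interference = TRUE)

# a chiasma configuration that essentially never produces a chiasma,
# for exercising degenerate (zero-crossover) paths deterministically
cfg_none <- function() chiasma_config(interference = FALSE,
                                      mean_distance = 1e6)

# binomial 3-standard-error band check
expect_within_3se <- function(est, expected, n, extra = 0) {
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(est - expected), max(3 * se, extra))
}

# write a complete, consistent set of simulation input files; returns the
# parameter file path
write_sim_fixture <- function(dir = tempfile("simfix"), ploidy = 4,
                              mapfunction = "HALDANE", seed = 11,
                              n_offspring = 4) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(c("chromosome\tlength\tcentromere\tprefPairing\tquadrivalents",
               "1\t100\t20\t0.0\tNA",
               "2\t60\t30\t0.5\t0.5"),
             file.path(dir, "chrom.txt"))
  writeLines(c("marker\tchromosome\tposition",
               "M1\t1\t0", "M2\t1\t25", "M3\t1\t75", "M4\t2\t10",
               "M5\t2\t55"),
             file.path(dir, "map.txt"))
  ped <- c("name\tparent1\tparent2", "P1\tNA\tNA", "P2\tNA\tNA",
           paste0("F", seq_len(n_offspring), "\tP1\tP2"))
  writeLines(ped, file.path(dir, "ped.txt"))
  cols <- as.vector(t(outer(c("P1", "P2"), seq_len(ploidy), paste,
                            sep = "_")))
  allele_rows <- vapply(c("M1", "M2", "M3", "M4", "M5"), function(m) {
    paste(c(m, rep(c("A", "a"), length.out = length(cols))),
          collapse = "\t")
  }, character(1))
  writeLines(c(paste(c("marker", cols), collapse = "\t"), allele_rows),
             file.path(dir, "founder.txt"))
  pf <- file.path(dir, "params.txt")
  writeLines(c(paste("PLOIDY =", ploidy),
               paste("MAPFUNCTION =", mapfunction),
               "CHROMFILE = chrom.txt",
               "MAPFILE = map.txt",
               "PEDFILE = ped.txt",
               "FOUNDERFILE = founder.txt",
               paste0("OUTPUT = out/run"),
               paste("SEED =", seed)),
             pf)
  pf
}
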