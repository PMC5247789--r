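test_that("synthetic genomes honor the configuration and are
           seed-deterministic", {
  cfg <- synth_config(n_scaffolds = 10, scaffold_length = 1e6, seed = 5)
  g <- make_genome(cfg)
  expect_equal(nrow(g), 10L)
  expect_equal(genome_length(g), 1e7)
  expect_equal(make_genome(cfg), g)
  # a single paper-scale scaffold is allowed
  big <- synth_config(n_scaffolds = 1, scaffold_length = 246e6)
  expect_equal(genome_length(make_genome(big)), 246e6)
  expect_error(synth_config(n_scaffolds = 0), "n_scaffolds")
})

test_that("het sites form a Poisson process at the configured rate", {
  cfg <- synth_config(n_scaffolds = 5, scaffold_length = 2e6,
                      het_rate = 0.015, ibd_fraction = 0, seed = 11)
  g <- make_genome(cfg)
  st <- make_snp_table(g, cfg)
  n <- n_snps(st$snps)
  expected <- 0.015 * genome_length(g)
  sigma <- sqrt(expected * (1 - 0.015))
  expect_lt(abs(n - expected), 3 * sigma)
  expect_equal(nrow(st$tracts), 0L)
  # determinism under the seed
  st2 <- make_snp_table(g, cfg)
  expect_equal(st2$snps$scf1, st$snps$scf1)
  # degenerate rate
  cfg0 <- synth_config(n_scaffolds = 2, scaffold_length = 1e5,
                       het_rate = 0, seed = 1)
  expect_equal(n_snps(make_snp_table(make_genome(cfg0), cfg0)$snps), 0)
})

test_that("embedded tracts are SNP-free and cover the requested fraction", {
  cfg <- synth_config(n_scaffolds = 4, scaffold_length = 5e6,
                      het_rate = 0.015, ibd_fraction = 0.5,
                      ibd_tract_mean = 5e4, seed = 21)
  g <- make_genome(cfg)
  st <- make_snp_table(g, cfg)
  expect_gte(region_length(st$tracts), 0.5 * genome_length(g))
  for (i in seq_len(nrow(st$tracts))) {
    nm <- st$tracts$chrom[i]
    p <- st$snps[[nm]]
    inside <- p > st$tracts$start[i] & p <= st$tracts$end[i]
    expect_equal(sum(inside), 0L)
  }
  # impossible packing refuses rather than spinning
  cfg_bad <- synth_config(n_scaffolds = 1, scaffold_length = 1e5,
                          ibd_fraction = 0.99, ibd_tract_mean = 9e4,
                          seed = 3)
  expect_error(make_snp_table(make_genome(cfg_bad), cfg_bad), "too high")
})

test_that("segment detection recovers embedded tract interiors", {
  cfg <- synth_config(n_scaffolds = 3, scaffold_length = 3e6,
                      het_rate = 0.015, ibd_fraction = 0.2,
                      ibd_tract_mean = 4e4, seed = 31)
  g <- make_genome(cfg)
  st <- make_snp_table(g, cfg)
  segs <- max_snp_free_segments(st$snps, genome_regions(g))
  # every embedded tract sits inside one detected segment (boundaries
  # may extend into the flanking inter-SNP gaps)
  for (i in seq_len(nrow(st$tracts))) {
    nm <- st$tracts$chrom[i]
    sel <- segs$chrom == nm & segs$start <= st$tracts$start[i] &
      segs$end >= st$tracts$end[i]
    expect_equal(sum(sel), 1L)
  }
})

test_that("coverage track mixes diploid and half-depth windows", {
  cfg <- synth_config(n_scaffolds = 4, scaffold_length = 1e6,
                      depth_mean = 84, collapsed_fraction = 0.3,
                      seed = 41)
  g <- make_genome(cfg)
  cov <- make_coverage(g, cfg)
  coll <- unlist(attr(cov, "collapsed"), use.names = FALSE)
  d <- unlist(cov, use.names = FALSE)
  expect_equal(length(d), 4e4)
  frac <- mean(coll)
  expect_lt(abs(frac - 0.3), 0.05)
  expect_lt(abs(mean(d[!coll]) - 84), 1)
  expect_lt(abs(mean(d[coll]) - 42), 1)
  # determinism
  cov2 <- make_coverage(g, cfg)
  expect_equal(cov2$scf1, cov$scf1)
  # unimodal when nothing is collapsed
  cfg0 <- synth_config(n_scaffolds = 2, scaffold_length = 1e6,
                       collapsed_fraction = 0, seed = 42)
  cov0 <- make_coverage(make_genome(cfg0), cfg0)
  expect_false(any(unlist(attr(cov0, "collapsed"))))
})

test_that("a written dataset reads back into identical objects", {
  cfg <- synth_config(n_scaffolds = 3, scaffold_length = 2e5,
                      het_rate = 0.01, ibd_fraction = 0.1,
                      ibd_tract_mean = 1e4, seed = 51)
  dir <- withr::local_tempdir()
  paths <- write_synthetic_dataset(cfg, dir)
  g <- read_genome(paths$genome)
  expect_equal(genome_length(g), 6e5)
  snps <- read_het_snps(paths$vcf, g)
  ref <- make_snp_table(g, cfg)
  expect_equal(n_snps(snps), n_snps(ref$snps))
  expect_equal(snps$scf2, ref$snps$scf2)
  expect_equal(as.data.frame(read_bed(paths$tracts)),
               as.data.frame(ref$tracts))
  cov <- read_coverage(paths$depth, g)
  expect_equal(cov$scf1, make_coverage(g, cfg)$scf1)
})
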