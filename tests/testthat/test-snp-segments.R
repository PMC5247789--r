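test_that("closed-form SNP-free window probability", {
  expect_equal(expected_snp_free_fraction(0, 1000), 1)
  expect_equal(expected_snp_free_fraction(1, 1), 0)
  p500 <- expected_snp_free_fraction(0.015, 500)
  expect_equal(p500, (1 - 0.015)^500)
  expect_lt(p500, 0.01)  # long deserts cannot arise by chance
})

test_that("window fractions count exactly and ignore terminal stubs", {
  g <- genome("chr1", 1000)
  regions <- genome_regions(g)
  snps <- snp_table(list(chr1 = c(100, 900)), g)
  expect_equal(snp_free_window_fraction(snps, regions, 100), 0.8)
  # no SNPs: every window free
  none <- snp_table(list(), g)
  for (w in c(100, 333, 1000)) {
    expect_equal(snp_free_window_fraction(none, regions, w), 1.0)
  }
  # stub discarded: w = 300 tiles 3 windows over [0, 900); SNP at 950
  # lives in the stub and cannot dirty anything
  stub <- snp_table(list(chr1 = 950), g)
  expect_equal(snp_free_window_fraction(stub, regions, 300), 1.0)
  expect_error(snp_free_window_fraction(none, regions, 2000), "window")
})

test_that("window fractions match the Bernoulli closed form", {
  cfg <- synth_config(n_scaffolds = 5, scaffold_length = 2e6,
                      het_rate = 0.015, seed = 61)
  g <- make_genome(cfg)
  snps <- make_snp_table(g, cfg)$snps
  regions <- genome_regions(g)
  for (w in c(100, 500)) {
    n_win <- floor(1e7 / w)
    p <- expected_snp_free_fraction(0.015, w)
    sigma <- sqrt(p * (1 - p) / n_win)
    got <- snp_free_window_fraction(snps, regions, w)
    expect_lt(abs(got - p), 4 * sigma + 1e-4)
  }
  # non-increasing in window size over the standard ladder
  ws <- c(100, 200, 300, 400, 500, 1000, 2000, 5000, 10000)
  fr <- vapply(ws, function(w) snp_free_window_fraction(snps, regions, w),
               1.0)
  expect_true(all(diff(fr) <= 0))
})

test_that("maximal segments split exactly at het sites", {
  g <- genome("chr1", 100)
  regions <- genome_regions(g)
  snps <- snp_table(list(chr1 = 50), g)
  segs <- max_snp_free_segments(snps, regions)
  expect_equal(as.data.frame(segs),
               data.frame(chrom = "chr1", start = c(0, 50), end = c(49, 100)))
  # no SNPs: the whole region
  segs0 <- max_snp_free_segments(snp_table(list(), g), regions)
  expect_equal(segs0$start, 0)
  expect_equal(segs0$end, 100)
  # adjacent sites and region-edge sites yield no zero-length segments
  snps2 <- snp_table(list(chr1 = c(1, 50, 51, 100)), g)
  segs2 <- max_snp_free_segments(snps2, regions)
  expect_true(all(segs2$end > segs2$start))
  expect_equal(sum(segs2$end - segs2$start), 100 - 4)
})

test_that("segments match the per-base brute-force oracle", {
  set.seed(71)
  for (rep in 1:5) {
    g <- genome(c("a", "b"), c(5000, 3000))
    snps <- snp_table(list(a = sort(sample.int(5000, 40)),
                           b = sort(sample.int(3000, 5))), g)
    regions <- region_set(c("a", "a", "b"), c(0, 2100, 500),
                          c(2000, 5000, 2800))
    got <- max_snp_free_segments(snps, regions)
    want <- brute_force_segments(snps, regions)
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("segment lengths plus het sites conserve the analyzed length", {
  cfg <- synth_config(n_scaffolds = 3, scaffold_length = 1e6,
                      het_rate = 0.01, ibd_fraction = 0.3,
                      ibd_tract_mean = 3e4, seed = 81)
  g <- make_genome(cfg)
  snps <- make_snp_table(g, cfg)$snps
  regions <- region_set(rep(g$name, each = 2),
                        rep(c(0, 6e5), 3), rep(c(5e5, 1e6), 3))
  segs <- max_snp_free_segments(snps, regions)
  n_inside <- sum(vapply(g$name, function(nm) {
    p <- snps[[nm]]
    sum((p > 0 & p <= 5e5) | (p > 6e5 & p <= 1e6))
  }, 1.0))
  expect_equal(sum(segs$end - segs$start) + n_inside,
               region_length(regions))
})

test_that("segment summaries report fraction, median and longest", {
  segs <- region_set(rep("c", 3), c(0, 10000, 60000),
                     c(2000, 50000, 60500))
  analyzed <- region_set("c", 0, 1e5)
  st <- summarize_segments(segs, analyzed, min_len = 1000)
  expect_equal(st$median_len_ge_L, 21000)  # {2 kb, 40 kb} qualify
  expect_equal(st$fraction_ge_L, 42000 / 1e5)
  expect_equal(st$longest_len, 40000)
  expect_equal(st$n_segments, 3L)
  # no qualifying segment
  st0 <- summarize_segments(region_set("c", 0, 500), analyzed,
                            min_len = 1000)
  expect_equal(st0$fraction_ge_L, 0)
  expect_true(is.na(st0$median_len_ge_L))
  expect_error(summarize_segments(segs, analyzed, min_len = 0), "min_len")
  # denominator switch
  g <- genome("c", 2e5)
  st2 <- summarize_segments(segs, analyzed, min_len = 1000,
                            denominator = "genome", genome = g)
  expect_equal(st2$fraction_ge_L, 42000 / 2e5)
})

test_that("random placement at 1.5% leaves no long SNP-free segments", {
  cfg <- synth_config(n_scaffolds = 5, scaffold_length = 2e6, seed = 91)
  g <- make_genome(cfg)
  regions <- genome_regions(g)
  n <- round(0.015 * region_length(regions))
  set.seed(99)
  snps <- snpdesert:::random_snp_table(n, regions)
  st <- summarize_segments(max_snp_free_segments(snps, regions),
                           regions, min_len = 1000)
  expect_lt(st$fraction_ge_L, 1e-3)
})

test_that("the random null reproduces the closed form at all nine sizes", {
  cfg <- synth_config(n_scaffolds = 5, scaffold_length = 2e6, seed = 101)
  g <- make_genome(cfg)
  regions <- genome_regions(g)
  h <- 0.015
  n <- round(h * region_length(regions))
  ws <- c(100, 200, 300, 400, 500, 1000, 2000, 5000, 10000)
  fr <- random_null_simulate(n, regions, ws, seed = 103)
  for (i in seq_along(ws)) {
    p <- expected_snp_free_fraction(h, ws[i])
    n_win <- floor(1e7 / ws[i])
    sigma <- sqrt(max(p * (1 - p), 1e-12) / n_win)
    expect_lt(abs(fr[[i]] - p), 3 * sigma + 1e-4)
  }
  # degenerate bounds
  tiny <- region_set("s", 0, 200)
  expect_equal(unname(random_null_simulate(0, tiny, w_list = 100)),
               1.0)
  expect_equal(unname(random_null_simulate(200, tiny, w_list = 100)),
               0.0)
  expect_error(random_null_simulate(201, tiny, w_list = 100), "exceeds")
})
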