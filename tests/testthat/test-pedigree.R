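test_that("founder haplotypes carry Poisson variants and one block", {
  g <- toy_genome(2, 5e6)
  set.seed(201)
  pool <- founder_pool(g, 4, f = 0.007)
  for (l in 1:4) {
    n <- length(pool$variants[[l]])
    lambda <- 0.007 * 1e7
    expect_lt(abs(n - lambda), 3 * sqrt(lambda))
    expect_false(is.unsorted(pool$variants[[l]], strictly = TRUE))
  }
  hap <- founder_haplotype(pool, 2)
  expect_equal(hap$ends, 1e7)
  expect_equal(hap$labels, 2L)
  # determinism and the degenerate rate
  set.seed(201)
  pool2 <- founder_pool(g, 4, f = 0.007)
  expect_equal(pool2$variants, pool$variants)
  expect_equal(lengths(founder_pool(g, 2, f = 0)$variants), c(0L, 0L))
})

test_that("meiosis at r = 0 copies parental scaffolds verbatim", {
  g <- toy_genome(3, 1e6)
  set.seed(211)
  pool <- founder_pool(g, 2, f = 0.001)
  ind <- individual(founder_haplotype(pool, 1), founder_haplotype(pool, 2))
  picked <- matrix(NA, 5, 3)
  for (i in 1:5) {
    gam <- meiosis(ind, g, r = 0)
    # block boundaries only at scaffold edges; every scaffold is an
    # intact copy of one parental haplotype (independent assortment)
    expect_true(all(gam$ends %in% c(1e6, 2e6, 3e6)))
    expect_true(all(gam$labels %in% 1:2))
    lab_per_scaf <- gam$labels[findInterval(c(0, 1e6, 2e6), gam$ends) + 1L]
    picked[i, ] <- lab_per_scaf
  }
  # the coin is actually flipped: both parents appear across draws
  expect_setequal(unique(as.vector(picked)), 1:2)
})

test_that("crossover counts are Poisson at the cM/Mb rate", {
  g <- genome("s1", 1e8)  # one 100 Mb scaffold
  set.seed(221)
  pool <- founder_pool(g, 2, f = 0)
  ind <- individual(founder_haplotype(pool, 1), founder_haplotype(pool, 2))
  # with two distinct labels every effective crossover is a junction
  n_junc <- vapply(1:200, function(i) {
    length(meiosis(ind, g, r = 5)$ends) - 1L
  }, 1L)
  lambda <- 1e8 * 5e-8  # 5 expected crossovers
  expect_lt(abs(mean(n_junc) - lambda), 3 * sqrt(lambda / 200))
})

test_that("meiosis of two identical haplotypes is invariant", {
  g <- toy_genome(2, 1e6)
  set.seed(231)
  pool <- founder_pool(g, 1, f = 0.005)
  ind <- individual(founder_haplotype(pool, 1), founder_haplotype(pool, 1))
  gam <- meiosis(ind, g, r = 10)
  expect_equal(gam$labels, 1L)     # blocks merge back to one label
  expect_equal(gam$ends, 2e6)
})

test_that("het sites are the symmetric difference of founder variants", {
  g <- genome("s1", 1000)
  pool <- structure(list(genome = g, total = 1000, f = 0,
                         variants = list(c(10, 50, 300), c(50, 200))),
                    class = "founder_pool")
  ind <- individual(founder_haplotype(pool, 1), founder_haplotype(pool, 2))
  # shared position 50 is homozygous; the rest are het
  expect_equal(het_positions(ind, pool), c(10, 200, 300))
  st <- score_individual(ind, pool, min_len = 10)
  expect_equal(st$het_rate, 3 / 1000)
})

test_that("IBD stretches are always SNP-free", {
  g <- toy_genome(2, 2e6)
  set.seed(241)
  pool <- founder_pool(g, 4, f = 0.007)
  for (i in 1:3) {
    off <- snpdesert:::breed_offspring("full_sib", pool, r = 8)
    het <- het_positions(off, pool)
    ibd <- diploid_ibd_intervals(off, pool$total)
    if (nrow(ibd)) {
      idx <- findInterval(het - 1, ibd[, "start"])
      inside <- idx > 0 & (het - 1) < ibd[pmax(idx, 1L), "end"]
      expect_equal(sum(inside), 0L)
    }
  }
})

test_that("ancestry blocks tile the genome through any pedigree", {
  g <- toy_genome(3, 1e6)
  set.seed(251)
  pool <- founder_pool(g, 8, f = 0.007)
  off <- snpdesert:::breed_offspring("cousin", pool, r = 10)
  for (hap in list(off$hap1, off$hap2)) {
    expect_false(is.unsorted(hap$ends, strictly = TRUE))
    expect_equal(hap$ends[length(hap$ends)], 3e6)
    expect_true(all(hap$labels >= 1 & hap$labels <= 8))
    # merged representation: no two adjacent blocks share a label
    if (length(hap$labels) > 1L) {
      expect_true(all(diff(hap$labels) != 0))
    }
  }
})

test_that("mean autozygous fraction matches path-counting kinship", {
  g <- toy_genome(4, 1e7)  # 40 Mb
  reps <- 25
  for (sc in pedigree_scenarios()) {
    res <- run_pedigree(sc, g, reps = reps, seed = 261)
    oracle <- pedigree_oracle_F(sc)
    expect_equal(res$expected_F, oracle)
    se <- stats::sd(res$per_replicate$fraction_ge_L) / sqrt(reps)
    expect_lt(abs(res$mean_fraction_ge_L - oracle), 3 * se + 0.01)
  }
})

test_that("faster recombination shortens the qualifying segments", {
  g <- toy_genome(4, 1e7)
  meds <- vapply(c(1, 5, 10), function(r) {
    run_pedigree("full_sib", g, reps = 12, rec_rate = r,
                 seed = 300 + r)$pooled_median_len
  }, 1.0)
  expect_true(all(diff(meds) < 0))
})

test_that("unknown scenarios are rejected", {
  expect_error(run_pedigree("selfing", toy_genome(1, 1e6), reps = 1),
               "arg")
})
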