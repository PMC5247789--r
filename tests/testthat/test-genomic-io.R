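test_that("genome parsing handles TSV, .fai and malformed input", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t1000", "chr2\t500"), tsv)
  g <- read_genome(tsv)
  expect_s3_class(g, "genome")
  expect_equal(g$name, c("chr1", "chr2"))
  expect_equal(genome_length(g), 1500)

  fai <- withr::local_tempfile(fileext = ".fai")
  writeLines(c("s1\t2000\t10\t60\t61", "s2\t300\t2100\t60\t61"), fai)
  gf <- read_genome(fai)
  expect_equal(gf$length, c(2000, 300))

  empty <- withr::local_tempfile()
  file.create(empty)
  expect_error(read_genome(empty), "empty")
  expect_error(genome(c("a", "a"), c(10, 20)), "duplicate")
  expect_error(genome("a", 0), "positive")
})

test_that("heterozygous genotype filtering keeps only het SNVs", {
  g <- genome("chr1", 1000)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr1\t10\t.\tA\tT\t.\tPASS\t.\tGT\t0/1",
    "chr1\t20\t.\tC\tG\t.\tPASS\t.\tGT\t1/1",
    "chr1\t30\t.\tG\tA\t.\tPASS\t.\tGT\t0|1",
    "chr1\t40\t.\tT\tC\t.\tPASS\t.\tGT\t1|0",
    "chr1\t50\t.\tA\tT,C\t.\tPASS\t.\tGT\t1/2",
    "chr1\t60\t.\tA\tAT\t.\tPASS\t.\tGT\t0/1",
    "chr1\t70\t.\tA\tT\t.\tPASS\t.\tGT\t0/0"), vcf)
  snps <- read_het_snps(vcf, g)
  expect_equal(snps$chr1, c(10, 30, 40, 50))
  # indels count only on request
  snps2 <- read_het_snps(vcf, g, include_indels = TRUE)
  expect_equal(snps2$chr1, c(10, 30, 40, 50, 60))
})

test_that("VCF contract errors: multi-sample, unsorted, missing GT", {
  g <- genome("chr1", 1000)
  two <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "chr1\t10\t.\tA\tT\t.\tPASS\t.\tGT\t0/1\t0/0"), two)
  expect_error(read_het_snps(two, g), "sample")
  expect_equal(read_het_snps(two, g, sample = "S2")$chr1, numeric())
  expect_equal(read_het_snps(two, g, sample = "S1")$chr1, 10)

  unsorted <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr1\t30\t.\tA\tT\t.\tPASS\t.\tGT\t0/1",
    "chr1\t10\t.\tA\tT\t.\tPASS\t.\tGT\t0/1"), unsorted)
  expect_error(read_het_snps(unsorted, g), "sorted")

  nogt <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr1\t10\t.\tA\tT\t.\tPASS\t.\tGT\t./.",
    "chr1\t20\t.\tA\tT\t.\tPASS\t.\tGT\t0/1"), nogt)
  expect_warning(snps <- read_het_snps(nogt, g), "skipped")
  expect_equal(snps$chr1, 20)
})

test_that("region sets round-trip through BED without merging", {
  rs <- region_set(c("chr1", "chr1", "chr2"), c(0, 10, 5), c(10, 20, 50))
  bed <- withr::local_tempfile(fileext = ".bed")
  write_segments(rs, bed)
  lines <- readLines(bed)
  expect_length(lines, 3L)            # adjacent intervals stay distinct
  expect_equal(lines[1], "chr1\t0\t10")
  back <- read_bed(bed)
  expect_equal(as.data.frame(back), as.data.frame(rs))

  empty <- region_set()
  bed2 <- withr::local_tempfile(fileext = ".bed")
  write_segments(empty, bed2)
  expect_identical(readLines(bed2), character())
  expect_equal(nrow(read_bed(bed2)), 0L)
})

test_that("region_set validates and merge_regions collapses abutters", {
  expect_error(region_set("c", 5, 5), "start < end")
  expect_error(region_set(c("c", "c"), c(0, 5), c(10, 15)), "overlap")
  m <- merge_regions(region_set(c("c", "c", "c"), c(0, 10, 30),
                                c(10, 20, 40)))
  expect_equal(m$start, c(0, 30))
  expect_equal(m$end, c(20, 40))
})

test_that("1-based SNP positions map to [p-1, p) interval space", {
  # a segment split at site p must leave [start, p-1) and [p, end)
  g <- genome("chr1", 100)
  snps <- snp_table(list(chr1 = 50), g)
  segs <- max_snp_free_segments(snps, genome_regions(g))
  expect_equal(segs$start, c(0, 50))
  expect_equal(segs$end, c(49, 100))
})

test_that("SNP tables and coverage tracks round-trip through disk", {
  g <- genome(c("s1", "s2"), c(5000, 1250))
  snps <- snp_table(list(s1 = c(17, 200, 4999), s2 = c(3, 1250)), g)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_het_vcf(snps, vcf)
  back <- read_het_snps(vcf, g)
  expect_equal(back$s1, snps$s1)
  expect_equal(back$s2, snps$s2)

  trk <- coverage_track(list(s1 = rep(c(10, 20), 25), s2 = rep(30, 12)),
                        g, window_bp = 100)
  bg <- withr::local_tempfile(fileext = ".bedgraph")
  write_coverage(trk, bg)
  trk2 <- read_coverage(bg, g)
  expect_equal(trk2$s1, trk$s1)
  expect_equal(trk2$s2, trk$s2)
  expect_equal(attr(trk2, "window_bp"), 100)
  # terminal stub (1250 %% 100) is flagged, not stored
  expect_equal(attr(trk2, "stub_bp")[2], 50)
})
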