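#' Founder haplotype pool
#'
#' Samples `n` unrelated founder haplotypes over a genome.  Each
#' founder haplotype carries variants (relative to the reference) as a
#' homogeneous Poisson process at per-bp rate `f`, and consists of a
#' single ancestry block per scaffold with a fresh founder label.  Two
#' haplotypes drawn from the pool and paired make one diploid
#' individual whose heterozygosity is about `2 f (1 - f)` — with the
#' default `f = 0.007`, half of the 1.5% observed heterozygosity per
#' haplotype, pairing reproduces the observed rate.
#'
#' Positions are kept in a single concatenated ("global") 1-based
#' coordinate space; ancestry blocks are global 0-based half-open
#' intervals.  Splitting blocks at scaffold boundaries recovers the
#' per-scaffold tiling.
#'
#' @param g a [genome()].
#' @param n number of founder haplotypes (labels `1..n`).
#' @param f per-bp founder variant frequency (default 0.007).
#' @return A list of class `founder_pool`: `genome`, `total` (genome
#'   length), `f`, and `variants` (list of sorted global 1-based
#'   position vectors, one per label).
#' @export
founder_pool <- function(g, n, f = 0.007) {
  stopifnot(inherits(g, "genome"), n >= 1, f >= 0, f <= 1)
  total <- genome_length(g)
  variants <- lapply(seq_len(n), function(i) poisson_positions(total, f))
  structure(list(genome = g, total = total, f = f, variants = variants),
            class = "founder_pool")
}

#' Extract one founder haplotype from a pool
#'
#' @param pool a [founder_pool()].
#' @param label founder label in `1..length(pool$variants)`.
#' @return A `haplotype`: list with `ends` (global 0-based half-open
#'   block ends; starts are implicit), `labels` (founder label per
#'   block), and `muts` (two-column matrix of new-mutation positions
#'   and identities; empty for founders).
#' @export
founder_haplotype <- function(pool, label) {
  stopifnot(inherits(pool, "founder_pool"),
            label >= 1, label <= length(pool$variants))
  structure(list(ends = pool$total, labels = as.integer(label),
                 muts = cbind(pos = numeric(), id = numeric())),
            class = "haplotype")
}

#' Pair two haplotypes into a diploid individual
#' @param hap1,hap2 `haplotype` objects over the same genome.
#' @return A list of class `individual` with elements `hap1`, `hap2`.
#' @export
individual <- function(hap1, hap2) {
  stopifnot(inherits(hap1, "haplotype"), inherits(hap2, "haplotype"))
  structure(list(hap1 = hap1, hap2 = hap2), class = "individual")
}

#' Meiosis: recombine an individual's two haplotypes into one gamete
#'
#' Per scaffold, the crossover count is Poisson with mean
#' `length_bp * r * 1e-8` (1 cM/Mb = 1e-8 crossovers per bp per
#' meiosis), crossover positions are uniform, and the gamete alternates
#' between the two parental haplotypes starting from a fair-coin choice
#' made independently per scaffold (scaffolds assort independently).
#' Ancestry blocks and new-mutation lists are spliced accordingly; no
#' new mutations are introduced here (the pedigree simulations follow
#' the source model in omitting mutation, which is orders of magnitude
#' slower than the standing variation).
#'
#' @param ind an [individual()].
#' @param g the [genome()].
#' @param r recombination rate in cM/Mb (>= 0).
#' @return A `haplotype` gamete.
#' @export
meiosis <- function(ind, g, r) {
  stopifnot(inherits(ind, "individual"), inherits(g, "genome"), r >= 0)
  off <- cumsum(c(0, g$length))
  # per-scaffold crossovers and starting haplotype
  seg_start <- numeric(); seg_src <- integer()
  for (i in seq_len(nrow(g))) {
    L <- g$length[i]
    k <- stats::rpois(1L, L * r * 1e-8)
    xs <- if (k) sort(floor(stats::runif(k) * L)) + off[i] else numeric()
    src0 <- sample(0:1, 1L)
    seg_start <- c(seg_start, off[i], xs)
    seg_src <- c(seg_src, (src0 + seq(0L, length.out = k + 1L)) %% 2L)
  }
  seg_end <- c(seg_start[-1], off[length(off)])
  keep <- seg_end > seg_start
  splice_haplotypes(ind$hap1, ind$hap2,
                    seg_start[keep], seg_end[keep], seg_src[keep])
}

# Splice two haplotypes along [start, end) segments taken from source
# hap 0/1; merges adjacent same-label blocks.
splice_haplotypes <- function(h0, h1, seg_start, seg_end, seg_src) {
  ends <- numeric(); labels <- integer()
  mut_keep <- vector("list", length(seg_start))
  for (j in seq_along(seg_start)) {
    h <- if (seg_src[j] == 0L) h0 else h1
    a <- seg_start[j]; b <- seg_end[j]
    j1 <- findInterval(a, h$ends, left.open = FALSE) + 1L
    # h$ends[j1] is the first block end > a
    while (j1 <= length(h$ends) && h$ends[j1] <= a) j1 <- j1 + 1L
    blocks_e <- h$ends[j1:length(h$ends)]
    cut <- which(blocks_e >= b)[1L]
    e <- c(blocks_e[seq_len(cut - 1L)], b)
    l <- h$labels[j1 + seq_len(cut) - 1L]
    # append, merging across the junction when the label repeats
    if (length(labels) && labels[length(labels)] == l[1L]) {
      ends <- ends[-length(ends)]
      labels <- labels[-length(labels)]
    }
    ends <- c(ends, e); labels <- c(labels, l)
    mp <- h$muts
    if (nrow(mp)) {
      sel <- mp[, "pos"] > a & mp[, "pos"] <= b
      mut_keep[[j]] <- mp[sel, , drop = FALSE]
    }
  }
  muts <- do.call(rbind, c(list(cbind(pos = numeric(), id = numeric())),
                           mut_keep[!vapply(mut_keep, is.null, TRUE)]))
  structure(list(ends = ends, labels = labels, muts = muts),
            class = "haplotype")
}

#' Heterozygous positions of a diploid individual
#'
#' A site is heterozygous when the two haplotypes carry different
#' alleles there: founder variants contribute wherever the ancestry
#' labels of the two haplotypes differ (the symmetric difference of the
#' two founders' variants in that stretch — a variant present on both
#' founders at the same position is homozygous, as is any variant
#' inside an identical-by-descent stretch), and new mutations
#' contribute when their identity is present on exactly one haplotype.
#'
#' @param ind an [individual()].
#' @param pool the [founder_pool()] the ancestry labels refer to.
#' @return Sorted numeric vector of global 1-based heterozygous
#'   positions.
#' @export
het_positions <- function(ind, pool) {
  stopifnot(inherits(ind, "individual"), inherits(pool, "founder_pool"))
  v1 <- haplotype_variants(ind$hap1, pool)
  v2 <- haplotype_variants(ind$hap2, pool)
  het <- sym_diff_sorted(v1, v2)
  m1 <- ind$hap1$muts; m2 <- ind$hap2$muts
  if (nrow(m1) || nrow(m2)) {
    shared <- intersect(m1[, "id"], m2[, "id"])
    mut_pos <- c(m1[!m1[, "id"] %in% shared, "pos"],
                 m2[!m2[, "id"] %in% shared, "pos"])
    het <- sort(unique(c(het, mut_pos)))
  }
  het
}

# Founder variants carried by one haplotype, from its ancestry blocks.
haplotype_variants <- function(hap, pool) {
  starts <- c(0, hap$ends[-length(hap$ends)])
  out <- vector("list", length(pool$variants))
  for (l in unique(hap$labels)) {
    sel <- hap$labels == l
    s <- starts[sel]; e <- hap$ends[sel]
    p <- pool$variants[[l]]
    if (!length(p)) next
    idx <- findInterval(p - 1, s)
    keep <- idx > 0 & (p - 1) < e[pmax(idx, 1L)]
    out[[l]] <- p[keep]
  }
  v <- unlist(out, use.names = FALSE)
  if (is.integer(v)) sort(v, method = "radix") else sort(v)
}

# Symmetric difference of two sorted integer vectors.
sym_diff_sorted <- function(a, b) {
  s <- c(a, b)
  s <- if (is.integer(s)) sort(s, method = "radix") else sort(s)
  if (!length(s)) return(numeric())
  dup <- c(diff(s) == 0, FALSE) | c(FALSE, diff(s) == 0)
  s[!dup]
}

#' Score one diploid individual's SNP-free segments
#'
#' Converts the individual's heterozygous positions into a SNP table
#' and computes the maximal SNP-free segments and their summary over
#' the whole simulated genome — the same scoring applied to observed
#' SNP calls.
#'
#' @param ind an [individual()].
#' @param pool the [founder_pool()].
#' @param min_len qualifying-segment threshold in bp (default 1000).
#' @return A `segment_stats` list (see [summarize_segments()]) with an
#'   extra element `het_rate`.
#' @export
score_individual <- function(ind, pool, min_len = 1000) {
  g <- pool$genome
  snps <- snp_table_from_global(het_positions(ind, pool), g)
  analyzed <- genome_regions(g)
  segs <- max_snp_free_segments(snps, analyzed)
  stats <- summarize_segments(segs, analyzed, min_len = min_len)
  stats$het_rate <- n_snps(snps) / genome_length(g)
  stats
}
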