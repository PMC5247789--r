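#' Configuration for the synthetic-data generator
#'
#' Describes a synthetic diploid dataset with the statistical structure
#' the analysis assumes: heterozygous sites as a homogeneous Poisson
#' process at rate `het_rate` in "diverse" regions, interrupted by long
#' embedded SNP-free (identity-by-descent) tracts, and a window-depth
#' track mixing a diploid peak at `depth_mean` with a collapsed-haplotype
#' peak at half depth.
#'
#' @param n_scaffolds number of scaffolds.
#' @param scaffold_length scaffold length(s) in bp; recycled to
#'   `n_scaffolds`.
#' @param het_rate per-bp heterozygosity outside embedded tracts
#'   (default 0.015, the observed genome-wide value).
#' @param ibd_fraction fraction of the genome to embed as SNP-free
#'   tracts (default 0).
#' @param ibd_tract_mean mean embedded tract length in bp (exponential
#'   law, default 50,000).
#' @param depth_mean mean depth of the diploid peak (default 84).
#' @param collapsed_fraction fraction of windows drawn from the
#'   half-depth collapsed peak (default 0.3).
#' @param collapsed_tract_mean mean length (bp) of a contiguous
#'   collapsed stretch (default 10,000): collapsed windows arrive in
#'   runs, as real divergent regions do, while their overall window
#'   fraction stays at `collapsed_fraction`.
#' @param depth_size negative-binomial size (inverse overdispersion) of
#'   the per-window depth draw (default 80; larger is tighter).
#' @param window_bp depth window width (default 100).
#' @param seed integer seed; identical seeds give identical datasets.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_scaffolds = 10, scaffold_length = 1e6,
                         het_rate = 0.015, ibd_fraction = 0,
                         ibd_tract_mean = 5e4, depth_mean = 84,
                         collapsed_fraction = 0.3,
                         collapsed_tract_mean = 1e4, depth_size = 80,
                         window_bp = 100, seed = NULL) {
  stopifnot(n_scaffolds >= 1, all(scaffold_length >= 1),
            het_rate >= 0, het_rate <= 1,
            ibd_fraction >= 0, ibd_fraction < 1,
            ibd_tract_mean > 0, depth_mean > 0,
            collapsed_fraction >= 0, collapsed_fraction <= 1,
            collapsed_tract_mean >= window_bp, depth_size > 0,
            window_bp >= 1)
  structure(list(n_scaffolds = as.integer(n_scaffolds),
                 scaffold_length = rep_len(scaffold_length, n_scaffolds),
                 het_rate = het_rate, ibd_fraction = ibd_fraction,
                 ibd_tract_mean = ibd_tract_mean, depth_mean = depth_mean,
                 collapsed_fraction = collapsed_fraction,
                 collapsed_tract_mean = collapsed_tract_mean,
                 depth_size = depth_size, window_bp = window_bp,
                 seed = seed),
            class = "synth_config")
}

#' Generate a synthetic genome
#' @param config a [synth_config()].
#' @return A [genome()] named `scf1 ... scfN`.
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  genome(paste0("scf", seq_len(config$n_scaffolds)),
         config$scaffold_length)
}

# n sorted uniform draws on (0, 1], O(n) without sorting
# (normalized exponential spacings).
sorted_uniforms <- function(n) {
  if (n == 0L) return(numeric())
  e <- stats::rexp(n + 1L)
  (cumsum(e)[seq_len(n)]) / sum(e)
}

# Sorted unique integer positions in 1..L from a Poisson(L * rate)
# process; integer-rounding collisions are re-drawn (topped up).
poisson_positions <- function(L, rate) {
  n <- stats::rpois(1L, L * rate)
  if (n > L) n <- L
  if (n == 0L) return(numeric())
  pos <- ceiling(sorted_uniforms(n) * L)
  pos <- pos[c(TRUE, diff(pos) > 0)]  # already sorted; drop collisions
  while (length(pos) < n) {
    extra <- ceiling(stats::runif(n - length(pos)) * L)
    pos <- unique(sort(c(pos, extra)))
  }
  if (L <= .Machine$integer.max) as.integer(pos) else pos
}

#' Generate a synthetic SNP table with embedded SNP-free tracts
#'
#' Heterozygous sites are placed as a homogeneous Poisson process at
#' rate `het_rate` per bp, then erased inside embedded tracts.  Tracts
#' are drawn with exponential lengths (mean `ibd_tract_mean`, rounded,
#' minimum 1 bp) and rejection-placed without overlap until they cover
#' `ibd_fraction` of the genome.
#'
#' @param g a [genome()] (typically from [make_genome()]).
#' @param config a [synth_config()].
#' @return A list with elements `snps` (a [snp_table()]) and `tracts`
#'   (a [region_set()] of ground-truth embedded SNP-free tracts).
#' @export
make_snp_table <- function(g, config) {
  stopifnot(inherits(g, "genome"), inherits(config, "synth_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  tracts <- place_tracts(g, config)
  positions <- vector("list", nrow(g))
  names(positions) <- g$name
  for (i in seq_len(nrow(g))) {
    nm <- g$name[i]
    p <- poisson_positions(g$length[i], config$het_rate)
    tr <- regions_of(tracts, nm)
    if (nrow(tr) && length(p)) {
      idx <- findInterval(p - 1, tr[, "start"])
      inside <- idx > 0 & (p - 1) < tr[pmax(idx, 1L), "end"]
      p <- p[!inside]
    }
    positions[[nm]] <- p
  }
  list(snps = snp_table(positions, g), tracts = tracts)
}

# Rejection-place non-overlapping tracts covering ibd_fraction of the
# genome; tracts never span scaffold boundaries.
place_tracts <- function(g, config) {
  target <- config$ibd_fraction * genome_length(g)
  if (target == 0) return(region_set())
  chrom <- character(); start <- numeric(); end <- numeric()
  placed <- 0
  attempts <- 0L
  max_attempts <- 10000L + 200L * ceiling(target / config$ibd_tract_mean)
  while (placed < target) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("ibd_fraction ", config$ibd_fraction,
           " is too high to place non-overlapping tracts of mean ",
           config$ibd_tract_mean, " bp")
    }
    len <- max(1, round(stats::rexp(1L, 1 / config$ibd_tract_mean)))
    i <- sample.int(nrow(g), 1L, prob = g$length)
    L <- g$length[i]
    if (len > L) next
    s <- floor(stats::runif(1L) * (L - len + 1))
    e <- s + len
    sel <- chrom == g$name[i]
    if (any(sel & start < e & end > s)) next
    chrom <- c(chrom, g$name[i]); start <- c(start, s); end <- c(end, e)
    placed <- placed + len
  }
  region_set(chrom, start, end)
}

#' Generate a synthetic bimodal coverage track
#'
#' Each complete window is independently collapsed with probability
#' `collapsed_fraction`; depth is a negative-binomial draw with mean
#' `depth_mean` (diploid) or `depth_mean / 2` (collapsed) and size
#' `depth_size`.
#'
#' @param g a [genome()].
#' @param config a [synth_config()].
#' @return A [coverage_track()] with attribute `collapsed` (logical
#'   list marking which windows were drawn from the half-depth peak).
#' @export
make_coverage <- function(g, config) {
  stopifnot(inherits(g, "genome"), inherits(config, "synth_config"))
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  depths <- vector("list", nrow(g))
  collapsed <- vector("list", nrow(g))
  names(depths) <- names(collapsed) <- g$name
  for (i in seq_len(nrow(g))) {
    n <- floor(g$length[i] / config$window_bp)
    coll <- collapsed_run_states(n, config)
    mu <- ifelse(coll, config$depth_mean / 2, config$depth_mean)
    depths[[g$name[i]]] <- stats::rnbinom(n, size = config$depth_size,
                                          mu = mu)
    collapsed[[g$name[i]]] <- coll
  }
  out <- coverage_track(depths, g, config$window_bp)
  attr(out, "collapsed") <- collapsed
  out
}

# Alternating-run collapsed/diploid states for n windows: collapsed
# runs are geometric with mean collapsed_tract_mean / window_bp
# windows, diploid runs scaled so the stationary collapsed-window
# fraction equals collapsed_fraction.
collapsed_run_states <- function(n, config) {
  cf <- config$collapsed_fraction
  if (cf == 0) return(rep(FALSE, n))
  if (cf == 1) return(rep(TRUE, n))
  m_coll <- config$collapsed_tract_mean / config$window_bp
  m_dipl <- m_coll * (1 - cf) / cf
  out <- logical(0)
  state <- stats::runif(1L) < cf
  while (length(out) < n) {
    # alternating geometric run lengths, drawn in batches of 50 runs
    states <- rep(c(state, !state), length.out = 50L)
    k <- 1L + stats::rgeom(50L, pmin(1, 1 / ifelse(states, m_coll, m_dipl)))
    out <- c(out, rep(states, k))
    state <- !states[50L]
  }
  out[seq_len(n)]
}

#' Write a full synthetic dataset to disk
#'
#' Emits the file dialects the readers consume: genome TSV, single-sample
#' VCF of heterozygous sites, bedGraph depth track, BED of ground-truth
#' embedded tracts, and a JSON sidecar with the generator configuration
#' (seed included).
#'
#' @param config a [synth_config()]; give it a `seed` for
#'   reproducibility.
#' @param dir output directory (created if missing).
#' @return Named list of file paths (`genome`, `vcf`, `depth`, `tracts`,
#'   `meta`), invisibly.
#' @export
write_synthetic_dataset <- function(config, dir) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- make_genome(config)
  st <- make_snp_table(g, config)
  cov <- make_coverage(g, config)
  paths <- list(genome = file.path(dir, "genome.tsv"),
                vcf = file.path(dir, "het_snps.vcf"),
                depth = file.path(dir, "depth.bedgraph"),
                tracts = file.path(dir, "true_tracts.bed"),
                meta = file.path(dir, "synth_config.json"))
  write_genome(g, paths$genome)
  write_het_vcf(st$snps, paths$vcf)
  write_coverage(cov, paths$depth)
  write_segments(st$tracts, paths$tracts)
  jsonlite::write_json(config[!vapply(config, is.null, TRUE)],
                       paths$meta, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
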