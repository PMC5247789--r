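#' Expected SNP-free fraction of a window under random placement
#'
#' Under uniform random placement of heterozygous sites at per-bp rate
#' `h`, the probability that a `w`-bp window contains no site is
#' `(1 - h)^w`.  At the observed heterozygosity of 1.5% this drops
#' below 1% already for 500-bp windows, which is why long SNP-free
#' segments cannot arise by chance.
#'
#' @param h per-bp heterozygosity, in `[0, 1]`.
#' @param w window size in bp.
#' @return `(1 - h)^w`.
#' @examples
#' expected_snp_free_fraction(0.015, 500)  # ~5.2e-4
#' @export
expected_snp_free_fraction <- function(h, w) {
  stopifnot(h >= 0, h <= 1, w >= 0)
  (1 - h)^w
}

# For each kept SNP, the index of the analyzed region it falls in (NA
# if outside); q is the 0-based site coordinate p - 1.
.assign_regions <- function(q, starts, ends) {
  idx <- findInterval(q, starts)
  idx[idx > 0 & q >= ends[pmax(idx, 1L)]] <- NA_integer_
  idx[idx == 0L] <- NA_integer_
  idx
}

#' Fraction of SNP-free windows at one window size
#'
#' Tiles each analyzed region into consecutive `w`-bp windows starting
#' at the region start, discards the shorter terminal stub of each
#' region, and returns the fraction of windows containing zero
#' heterozygous sites.  Sites outside the analyzed regions are ignored.
#'
#' @param snps a [snp_table()].
#' @param regions a non-empty [region_set()] of analyzed regions.
#' @param w window size in bp (>= 1).
#' @return Numeric scalar in `[0, 1]`.
#' @export
snp_free_window_fraction <- function(snps, regions, w) {
  stopifnot(inherits(snps, "snp_table"), inherits(regions, "region_set"),
            w >= 1)
  if (nrow(regions) == 0L) stop("empty analyzed region set")
  total <- 0
  occupied <- 0
  for (nm in unique(regions$chrom)) {
    reg <- regions_of(regions, nm)
    nwin <- floor((reg[, "end"] - reg[, "start"]) / w)
    total <- total + sum(nwin)
    q <- snps[[nm]] - 1
    if (is.null(snps[[nm]]) || !length(q)) next
    idx <- .assign_regions(q, reg[, "start"], reg[, "end"])
    keep <- !is.na(idx)
    if (!any(keep)) next
    q <- q[keep]; idx <- idx[keep]
    win <- floor((q - reg[idx, "start"]) / w)
    ok <- win < nwin[idx]
    occupied <- occupied +
      length(unique((idx[ok] - 1) * (max(nwin) + 1) + win[ok]))
  }
  if (total == 0) stop("no complete ", w, " bp window fits in the regions")
  1 - occupied / total
}

#' Maximal SNP-free segments within analyzed regions
#'
#' Within each analyzed region, returns the maximal sub-intervals that
#' contain no heterozygous site.  Each het site excludes exactly its
#' own base pair (`[p - 1, p)`), so segment boundaries fall at region
#' edges or at het positions; zero-length segments produced by adjacent
#' sites or sites at region edges are dropped.  Segments never span
#' across gaps between analyzed regions: a coverage gap is absence of
#' evidence, not evidence of homozygosity.
#'
#' @param snps a [snp_table()].
#' @param regions a [region_set()] of analyzed regions.
#' @return A [region_set()] of SNP-free segments.
#' @export
max_snp_free_segments <- function(snps, regions) {
  stopifnot(inherits(snps, "snp_table"), inherits(regions, "region_set"))
  out_chrom <- character(); out_start <- numeric(); out_end <- numeric()
  for (nm in unique(regions$chrom)) {
    reg <- regions_of(regions, nm)
    S <- reg[, "start"]; E <- reg[, "end"]
    q <- snps[[nm]] - 1
    if (is.null(snps[[nm]])) q <- numeric()
    idx <- .assign_regions(q, S, E)
    keep <- !is.na(idx)
    q <- q[keep]; r <- idx[keep]
    # starts: every region start + the bp after every kept site;
    # ends: the first site of the region / the next site / region end.
    if (length(q)) {
      nxt_same <- c(r[-1] == r[-length(r)], FALSE)
      end_for_q <- ifelse(nxt_same, c(q[-1], NA), E[r])
    } else {
      end_for_q <- numeric()
    }
    first_q <- match(seq_along(S), r)
    end_for_S <- ifelse(is.na(first_q), E, q[first_q])
    starts <- c(S, q + 1)
    ends <- c(end_for_S, end_for_q)
    chroms <- rep(nm, length(starts))
    pos <- ends > starts
    out_chrom <- c(out_chrom, chroms[pos])
    out_start <- c(out_start, starts[pos])
    out_end <- c(out_end, ends[pos])
  }
  region_set(out_chrom, out_start, out_end)
}

#' Summary statistics of SNP-free segments
#'
#' @param segments a [region_set()] of SNP-free segments (from
#'   [max_snp_free_segments()]).
#' @param analyzed the [region_set()] the segments were computed over.
#' @param min_len segment length threshold L in bp (default 1000).
#' @param denominator `"analyzed"` (default) divides by the analyzed
#'   length — the self-consistent choice, and what the simulations
#'   produce; `"genome"` divides by the full assembly length (requires
#'   `genome`).
#' @param genome a [genome()], only needed for
#'   `denominator = "genome"`.
#' @return A list of class `segment_stats`: `n_segments`,
#'   `analyzed_bp`, `free_bp` (total segment length), `fraction_free`,
#'   `fraction_ge_L` (fraction of the denominator inside segments >=
#'   `min_len`), `median_len_ge_L` (`NA` when no segment qualifies),
#'   `longest_len`, `min_len`, and `lengths_ge_L` (the qualifying
#'   segment lengths, for pooling across replicates).
#' @export
summarize_segments <- function(segments, analyzed, min_len = 1000,
                               denominator = c("analyzed", "genome"),
                               genome = NULL) {
  stopifnot(inherits(segments, "region_set"),
            inherits(analyzed, "region_set"))
  if (min_len < 1) stop("min_len must be >= 1")
  denominator <- match.arg(denominator)
  denom <- if (denominator == "analyzed") region_length(analyzed) else {
    if (is.null(genome)) stop("denominator = \"genome\" needs `genome`")
    genome_length(genome)
  }
  lens <- segments$end - segments$start
  qual <- lens[lens >= min_len]
  structure(list(
    n_segments = length(lens),
    analyzed_bp = region_length(analyzed),
    free_bp = sum(lens),
    fraction_free = sum(lens) / denom,
    fraction_ge_L = sum(qual) / denom,
    median_len_ge_L = if (length(qual)) stats::median(qual) else NA_real_,
    longest_len = if (length(lens)) max(lens) else 0,
    min_len = min_len,
    lengths_ge_L = sort(qual)
  ), class = "segment_stats")
}

#' @export
print.segment_stats <- function(x, ...) {
  cat(sprintf(
    paste0("<segment_stats> %d segments over %s analyzed bp\n",
           "  fraction in segments >= %d bp: %.4f\n",
           "  median qualifying length: %s bp, longest: %s bp\n"),
    x$n_segments, format(x$analyzed_bp, big.mark = ","), x$min_len,
    x$fraction_ge_L,
    format(x$median_len_ge_L, big.mark = ","),
    format(x$longest_len, big.mark = ",")))
  invisible(x)
}

#' Random-placement null for the SNP-free window fractions
#'
#' Places `n_snps` heterozygous sites uniformly without replacement
#' over the positions of the analyzed regions and returns the SNP-free
#' window fraction at each requested window size — the control the
#' observed window fractions are compared against.
#'
#' @param n_snps number of sites to place (`<=` analyzed length).
#' @param analyzed a [region_set()] of analyzed regions.
#' @param w_list window sizes in bp (default the standard ladder 100,
#'   200, 300, 400, 500, 1000, 2000, 5000, 10000).
#' @param seed optional integer seed.
#' @return Named numeric vector, one SNP-free fraction per window size.
#' @export
random_null_simulate <- function(n_snps, analyzed,
                                 w_list = c(100, 200, 300, 400, 500,
                                            1000, 2000, 5000, 10000),
                                 seed = NULL) {
  stopifnot(inherits(analyzed, "region_set"), n_snps >= 0)
  total <- region_length(analyzed)
  if (n_snps > total) {
    stop("n_snps (", n_snps, ") exceeds analyzed positions (", total, ")")
  }
  if (!is.null(seed)) set.seed(seed)
  snps <- random_snp_table(n_snps, analyzed)
  out <- vapply(w_list, function(w)
    snp_free_window_fraction(snps, analyzed, w), 1.0)
  names(out) <- as.character(w_list)
  out
}

# Uniform-without-replacement site placement over a region set,
# returned as a snp_table on a genome spanning the regions' scaffolds.
random_snp_table <- function(n_snps, analyzed) {
  lens <- analyzed$end - analyzed$start
  cum <- cumsum(c(0, lens))
  total <- cum[length(cum)]
  draw <- sort(sample.int(total, n_snps))
  ridx <- findInterval(draw - 1, cum[-length(cum)])
  q <- analyzed$start[ridx] + (draw - 1 - cum[ridx])
  chroms <- unique(analyzed$chrom)
  scaf_len <- vapply(chroms, function(nm)
    max(analyzed$end[analyzed$chrom == nm]), 1.0)
  g <- genome(chroms, scaf_len)
  snp_table(split(q + 1, factor(analyzed$chrom[ridx], levels = chroms)), g)
}
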