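#' Fit the two-peak model of the window-depth distribution
#'
#' The depth histogram of an assembly from a heterozygous diploid shows
#' a main peak at the expected diploid coverage and a second peak near
#' half depth, produced by regions so divergent between the homologous
#' chromosomes that the two haplotypes assembled separately (so reads
#' from only one haplotype map there).  Peaks are located as local
#' maxima of a kernel-smoothed density (bandwidth = mean depth / 20);
#' the rightmost substantial mode is always the diploid one.  The
#' default diploid depth range is `[valley, diploid_mode + (diploid_mode
#' - valley)]`, where `valley` is the density minimum between the two
#' modes — symmetric about the mode, so the filter is unbiased.  With a
#' single detectable mode, `collapsed_mode` is `NA` and the range
#' brackets the mode at +/- 25%.
#'
#' @param track a [coverage_track()] with at least 1000 windows.
#' @param min_peak_height local maxima below this fraction of the
#'   tallest density peak are ignored (default 0.05).
#' @return A list of class `peak_model` with elements `diploid_mode`,
#'   `collapsed_mode` (`NA` if undetected), `diploid_range` (length-2
#'   numeric), and `bandwidth`.
#' @export
fit_coverage_peaks <- function(track, min_peak_height = 0.05) {
  stopifnot(inherits(track, "coverage_track"))
  x <- unlist(track, use.names = FALSE)
  if (length(x) < 1000L) {
    stop("need at least 1000 depth windows to fit the peak model")
  }
  if (all(x == 0)) stop("all-zero depth track")
  bw <- mean(x) / 20
  d <- stats::density(x, bw = bw, n = 1024L)
  y <- d$y
  is_max <- c(FALSE, y[2:(length(y) - 1)] > y[1:(length(y) - 2)] &
                y[2:(length(y) - 1)] >= y[3:length(y)], FALSE)
  peaks <- which(is_max & y >= min_peak_height * max(y))
  if (!length(peaks)) peaks <- which.max(y)
  diploid_i <- peaks[length(peaks)]
  diploid_mode <- d$x[diploid_i]
  left <- peaks[peaks < diploid_i]
  if (length(left)) {
    collapsed_i <- left[which.max(y[left])]
    collapsed_mode <- d$x[collapsed_i]
    between <- seq(collapsed_i, diploid_i)
    valley <- d$x[between[which.min(y[between])]]
    lo <- valley
  } else {
    collapsed_mode <- NA_real_
    lo <- 0.75 * diploid_mode
  }
  hi <- diploid_mode + (diploid_mode - lo)
  structure(list(diploid_mode = diploid_mode,
                 collapsed_mode = collapsed_mode,
                 diploid_range = c(lo, hi), bandwidth = bw),
            class = "peak_model")
}

#' @export
print.peak_model <- function(x, ...) {
  cat(sprintf(
    "<peak_model> diploid mode %.1f (range %.1f-%.1f), collapsed mode %s\n",
    x$diploid_mode, x$diploid_range[1], x$diploid_range[2],
    if (is.na(x$collapsed_mode)) "absent" else sprintf("%.1f",
                                                       x$collapsed_mode)))
  invisible(x)
}

#' Select the diploid-coverage regions of the genome
#'
#' Keeps the windows whose depth falls inside the diploid range and
#' merges runs of adjacent kept windows into maximal intervals.  The
#' filtering unit is the window, so interval bounds are multiples of
#' `window_bp`; terminal stubs shorter than one window are never
#' included.  Re-applying the selection to its own output is a no-op.
#'
#' @param track a [coverage_track()].
#' @param model a `peak_model` from [fit_coverage_peaks()], or a list
#'   with a `diploid_range` element (so an explicit `lo`/`hi` override
#'   can be passed as `list(diploid_range = c(lo, hi))`).
#' @param smooth_windows odd number of windows for a running-median
#'   smooth of the depth before thresholding (default 1 = raw
#'   windows).  Collapsed stretches span many consecutive windows, so
#'   a modest smooth (the observed-genome pipeline uses 5) removes
#'   single-window depth noise that would otherwise chop the analyzed
#'   regions into fragments, without hiding real collapsed tracts.
#' @return A [region_set()] of diploid-coverage regions.
#' @export
select_diploid_regions <- function(track, model, smooth_windows = 1) {
  stopifnot(inherits(track, "coverage_track"),
            smooth_windows >= 1, smooth_windows %% 2 == 1)
  rng <- model$diploid_range
  stopifnot(length(rng) == 2L, rng[1] < rng[2])
  g <- attr(track, "genome")
  w <- attr(track, "window_bp")
  chrom <- character(); start <- numeric(); end <- numeric()
  for (nm in g$name) {
    d <- track[[nm]]
    if (!length(d)) next
    if (smooth_windows > 1 && length(d) > smooth_windows) {
      d <- stats::runmed(d, smooth_windows, endrule = "median")
    }
    keep <- d >= rng[1] & d <= rng[2]
    r <- rle(keep)
    ends_w <- cumsum(r$lengths)
    starts_w <- ends_w - r$lengths
    sel <- r$values
    if (any(sel)) {
      chrom <- c(chrom, rep(nm, sum(sel)))
      start <- c(start, starts_w[sel] * w)
      end <- c(end, ends_w[sel] * w)
    }
  }
  region_set(chrom, start, end)
}

#' Length-weighted mean depth of a region set
#'
#' Averages window depths over all windows overlapping the regions,
#' weighting each window by its overlap length.  Used to check that
#' SNP-free segments are not read-mapping artifacts: genuine homozygous
#' tracts have at least the genome-average diploid coverage.
#'
#' @param track a [coverage_track()].
#' @param regions a non-empty [region_set()].
#' @return Numeric scalar, the length-weighted mean depth.
#' @export
mean_depth_of_regions <- function(track, regions) {
  stopifnot(inherits(track, "coverage_track"),
            inherits(regions, "region_set"))
  if (nrow(regions) == 0L) stop("empty region set")
  g <- attr(track, "genome")
  w <- attr(track, "window_bp")
  total_wt <- 0
  total_sum <- 0
  for (nm in unique(regions$chrom)) {
    d <- track[[nm]]
    if (is.null(d)) stop("region on unknown scaffold ", nm)
    reg <- regions_of(regions, nm)
    # clip to the complete-window span; stubs carry no depth estimate
    s <- pmin(reg[, "start"], length(d) * w)
    e <- pmin(reg[, "end"], length(d) * w)
    ok <- e > s
    s <- s[ok]; e <- e[ok]
    if (!length(s)) next
    kfirst <- floor(s / w)
    klast <- ceiling(e / w) - 1
    counts <- klast - kfirst + 1
    ks <- sequence(counts, from = kfirst, by = 1)
    reg_id <- rep(seq_along(s), counts)
    ov <- pmin(e[reg_id], (ks + 1) * w) - pmax(s[reg_id], ks * w)
    total_wt <- total_wt + sum(ov)
    total_sum <- total_sum + sum(ov * d[ks + 1])
  }
  if (total_wt == 0) stop("regions cover no complete depth window")
  total_sum / total_wt
}
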