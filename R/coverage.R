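#' Coverage track: mean read depth in fixed-width windows
#'
#' For each scaffold, mean depth over consecutive `window_bp` windows.
#' Only the `floor(length / window_bp)` complete windows are stored; a
#' shorter terminal stub (recorded in attribute `stub_bp`) is discarded
#' from all window statistics, mirroring how terminal sub-windows are
#' dropped from the SNP-free window counts.
#'
#' @param depths named list, one non-negative numeric vector per
#'   scaffold with `floor(length / window_bp)` entries.
#' @param g the [genome()].
#' @param window_bp window width in bp (default 100).
#' @return An object of class `coverage_track`: the depth list with
#'   attributes `genome`, `window_bp`, `stub_bp`.
#' @export
coverage_track <- function(depths, g, window_bp = 100) {
  stopifnot(inherits(g, "genome"), window_bp >= 1)
  out <- vector("list", nrow(g))
  names(out) <- g$name
  for (i in seq_len(nrow(g))) {
    nm <- g$name[i]
    n_expect <- floor(g$length[i] / window_bp)
    d <- depths[[nm]]
    if (is.null(d)) stop("no depth vector for scaffold ", nm)
    d <- as.numeric(d)
    if (length(d) != n_expect) {
      stop(sprintf("scaffold %s: expected %d complete windows, got %d",
                   nm, n_expect, length(d)))
    }
    if (any(!is.finite(d)) || any(d < 0)) {
      stop("depths must be finite and non-negative (scaffold ", nm, ")")
    }
    out[[nm]] <- d
  }
  structure(out, genome = g, window_bp = window_bp,
            stub_bp = g$length %% window_bp, class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s windows of %d bp, mean depth %.1f\n",
              format(sum(lengths(x)), big.mark = ","),
              attr(x, "window_bp"), mean(unlist(x, use.names = FALSE))))
  invisible(x)
}

#' Read a fixed-window depth track from a bedGraph or TSV file
#'
#' Expects 4 columns `chrom start end depth` (0-based half-open), one
#' line per consecutive window of constant width; the terminal stub
#' window, if present in the file, is dropped.
#'
#' @param path path to the bedGraph/TSV file (no header).
#' @param g the [genome()].
#' @param window_bp window width; inferred from the first line if `NULL`.
#' @return A [coverage_track()].
#' @export
read_coverage <- function(path, g, window_bp = NULL) {
  stopifnot(inherits(g, "genome"))
  if (!file.exists(path)) stop("depth file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 4L) stop("expected 4 columns: chrom start end depth")
  names(tab)[1:4] <- c("chrom", "start", "end", "depth")
  if (is.null(window_bp)) window_bp <- tab$end[1L] - tab$start[1L]
  depths <- vector("list", nrow(g))
  names(depths) <- g$name
  for (nm in g$name) {
    sub <- tab[tab$chrom == nm, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    L <- g$length[match(nm, g$name)]
    n <- floor(L / window_bp)
    keep <- sub$end - sub$start == window_bp &
      sub$start %% window_bp == 0 & sub$end <= n * window_bp
    sub <- sub[keep, , drop = FALSE]
    if (nrow(sub) != n || !all(sub$start == (seq_len(n) - 1) * window_bp)) {
      stop("depth track does not tile scaffold ", nm,
           " in consecutive ", window_bp, " bp windows")
    }
    depths[[nm]] <- sub$depth
  }
  coverage_track(depths, g, window_bp)
}

#' Write a coverage track as a bedGraph file
#' @param track a [coverage_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  g <- attr(track, "genome")
  w <- attr(track, "window_bp")
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in g$name) {
    d <- track[[nm]]
    if (!length(d)) next
    s <- (seq_along(d) - 1) * w
    writeLines(paste(nm, format(s, scientific = FALSE, trim = TRUE),
                     format(s + w, scientific = FALSE, trim = TRUE),
                     format(d, trim = TRUE), sep = "\t"), con)
  }
  invisible(path)
}
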