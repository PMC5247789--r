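#' Region set: sorted disjoint half-open genomic intervals
#'
#' A `region_set` is a data frame with columns `chrom`, `start`, `end`
#' holding 0-based half-open intervals `[start, end)`.  Intervals are
#' sorted by (`chrom` in first-appearance order, `start`) and must be
#' disjoint within a scaffold; abutting intervals are kept distinct
#' unless [merge_regions()] is applied.
#'
#' @param chrom character vector of scaffold names.
#' @param start,end numeric vectors, `0 <= start < end`.
#' @return An object of class `region_set`.
#' @examples
#' region_set("chr1", c(0, 200), c(100, 300))
#' @export
region_set <- function(chrom = character(), start = numeric(),
                       end = numeric()) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (length(chrom)) {
    if (any(start < 0) || any(end <= start)) {
      stop("regions must satisfy 0 <= start < end")
    }
    lev <- unique(chrom)
    key <- match(chrom, lev) * (max(end) + 1) + start
    if (is.unsorted(key)) {
      o <- order(key, method = "radix")
      chrom <- chrom[o]; start <- start[o]; end <- end[o]
    }
    same <- chrom[-1] == chrom[-length(chrom)]
    if (length(chrom) > 1L && any(same & start[-1] < end[-length(end)])) {
      stop("regions overlap within a scaffold")
    }
  }
  structure(data.frame(chrom = chrom, start = start, end = end,
                       stringsAsFactors = FALSE),
            class = c("region_set", "data.frame"))
}

#' Total length of a region set in bp
#' @param rs a [region_set()].
#' @return Numeric scalar.
#' @export
region_length <- function(rs) {
  stopifnot(inherits(rs, "region_set"))
  sum(rs$end - rs$start)
}

#' Merge abutting or overlapping intervals into maximal intervals
#' @param rs a [region_set()].
#' @return A [region_set()] with maximal disjoint, non-abutting intervals.
#' @export
merge_regions <- function(rs) {
  stopifnot(inherits(rs, "region_set"))
  if (nrow(rs) < 2L) return(rs)
  new_run <- c(TRUE, rs$chrom[-1] != rs$chrom[-nrow(rs)] |
                 rs$start[-1] > rs$end[-nrow(rs)])
  grp <- cumsum(new_run)
  region_set(chrom = rs$chrom[new_run],
             start = rs$start[new_run],
             end = as.numeric(tapply(rs$end, factor(grp, levels = unique(grp)),
                                     max)))
}

#' Write a region set as a 3-column BED file
#'
#' Intervals are written as-is, one line per interval, 0-based half-open;
#' no implicit merging.  An empty set produces an empty file.
#'
#' @param regions a [region_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(regions, path) {
  stopifnot(inherits(regions, "region_set"))
  if (nrow(regions) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  utils::write.table(
    data.frame(regions$chrom,
               format(regions$start, scientific = FALSE, trim = TRUE),
               format(regions$end, scientific = FALSE, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 3-column BED file into a region set
#' @param path path to a BED file (first three columns used).
#' @return A [region_set()].
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (file.size(path) == 0L) return(region_set())
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  region_set(tab[[1L]], as.numeric(tab[[2L]]), as.numeric(tab[[3L]]))
}

# Regions of one scaffold as a two-column matrix [start, end).
regions_of <- function(rs, chrom) {
  sel <- rs$chrom == chrom
  cbind(start = rs$start[sel], end = rs$end[sel])
}
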