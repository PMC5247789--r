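#' Genome: an ordered set of scaffolds with lengths
#'
#' A `genome` is a data frame with columns `name` (unique scaffold names,
#' in file order) and `length` (scaffold length in base pairs).  All
#' coordinates in this package are 0-based half-open internally; VCF
#' positions are 1-based at the file boundary, BED intervals 0-based
#' half-open.  A 1-based SNP position `p` corresponds to the 1-bp
#' interval `[p - 1, p)`.
#'
#' @param name character vector of scaffold names.
#' @param length integer-like vector of scaffold lengths (bp, >= 1).
#'
#' @return An object of class `genome` (a data frame with columns
#'   `name`, `length`).
#' @examples
#' g <- genome(c("chr1", "chr2"), c(1e6, 5e5))
#' genome_length(g)
#' @export
genome <- function(name, length) {
  name <- as.character(name)
  length <- as.numeric(length)
  if (length(name) == 0L) stop("a genome needs at least one scaffold")
  if (anyDuplicated(name)) stop("duplicate scaffold name: ",
                                name[duplicated(name)][1L])
  if (any(!is.finite(length)) || any(length < 1) ||
      any(length != floor(length))) {
    stop("scaffold lengths must be positive integers")
  }
  structure(data.frame(name = name, length = length,
                       stringsAsFactors = FALSE),
            class = c("genome", "data.frame"))
}

#' Read a genome from a FASTA index or a two-column TSV
#'
#' Accepts either a `samtools faidx` `.fai` file (name, length, offset,
#' linebases, linewidth; lengths taken from column 2) or a plain
#' two-column `name<TAB>length` table without header.
#'
#' @param path path to the `.fai` or TSV file.
#' @return A [genome()] with scaffolds in file order.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome file not found: ", path)
  if (file.size(path) == 0) stop("empty genome file: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("empty genome file: ", path)
  if (ncol(tab) < 2L) stop("expected at least two columns (name, length)")
  lens <- suppressWarnings(as.numeric(tab[[2L]]))
  if (any(is.na(lens))) stop("non-numeric scaffold length in ", path)
  genome(tab[[1L]], lens)
}

#' Write a genome as a two-column TSV
#'
#' @param g a [genome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(g, path) {
  stopifnot(inherits(g, "genome"))
  utils::write.table(data.frame(g$name, format(g$length, scientific = FALSE,
                                               trim = TRUE)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Total genome length in bp
#' @param g a [genome()].
#' @return Numeric scalar, sum of scaffold lengths.
#' @export
genome_length <- function(g) {
  stopifnot(inherits(g, "genome"))
  sum(g$length)
}

# Cumulative 0-based start offset of each scaffold in the concatenated
# (global) coordinate space used by the simulators.
scaffold_offsets <- function(g) {
  off <- cumsum(c(0, g$length))
  names(off) <- c(g$name, "")
  off
}

#' Region set covering every scaffold of a genome
#' @param g a [genome()].
#' @return A [region_set()] with one interval `[0, length)` per scaffold.
#' @export
genome_regions <- function(g) {
  stopifnot(inherits(g, "genome"))
  region_set(chrom = g$name, start = rep(0, nrow(g)), end = g$length)
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %d scaffold(s), %s bp total\n", nrow(x),
              format(genome_length(x), big.mark = ",", scientific = FALSE)))
  NextMethod()
}

# Split sorted global 1-based positions into a per-scaffold snp_table.
snp_table_from_global <- function(pos, g) {
  off <- cumsum(c(0, g$length))
  if (is.unsorted(pos)) pos <- sort(pos)
  idx <- findInterval(pos - 1, off[-length(off)], rightmost.closed = FALSE)
  # idx in 1..n_scaffolds because 0 <= pos-1 < total
  out <- vector("list", nrow(g))
  names(out) <- g$name
  loc <- pos - off[idx]
  byscaf <- split(loc, factor(idx, levels = seq_len(nrow(g))))
  for (i in seq_len(nrow(g))) out[[i]] <- as.numeric(byscaf[[i]])
  snp_table(out, g)
}
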