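# Independent oracles used across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force per-base SNP-free segments: materializes a logical mask
# per analyzed region and extracts runs.  Only for small instances.
brute_force_segments <- function(snps, regions) {
  chrom <- character(); start <- numeric(); end <- numeric()
  for (i in seq_len(nrow(regions))) {
    nm <- regions$chrom[i]
    s <- regions$start[i]; e <- regions$end[i]
    mask <- rep(TRUE, e - s)
    p <- snps[[nm]]
    p <- p[p - 1 >= s & p - 1 < e]
    mask[p - s] <- FALSE  # site p occupies [p-1, p), index p-1-s+1
    r <- rle(mask)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths
    sel <- r$values
    if (any(sel)) {
      chrom <- c(chrom, rep(nm, sum(sel)))
      start <- c(start, s + starts_i[sel])
      end <- c(end, s + ends_i[sel])
    }
  }
  region_set(chrom, start, end)
}

# Path-counting (tabular-method) kinship: pedigree is a data frame
# with columns id, sire, dam (NA for founders), ancestors listed
# before descendants.  Returns the full kinship matrix.
kinship_matrix <- function(ped) {
  n <- nrow(ped)
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    si <- match(ped$sire[i], ped$id)
    di <- match(ped$dam[i], ped$id)
    for (j in seq_len(i - 1L)) {
      kij <- if (is.na(si)) 0 else (K[si, j] + K[di, j]) / 2
      K[i, j] <- K[j, i] <- kij
    }
    Fi <- if (is.na(si)) 0 else K[si, di]
    K[i, i] <- (1 + Fi) / 2
  }
  K
}

# Inbreeding coefficient of the final offspring of each mating design,
# from an explicitly written-out pedigree (independent of the
# simulator's pedigree construction).
pedigree_oracle_F <- function(scenario) {
  ped <- switch(
    scenario,
    full_sib = data.frame(
      id = c("A", "B", "C", "D"),
      sire = c(NA, NA, "A", "A"),
      dam = c(NA, NA, "B", "B")),
    half_sib_unrelated = data.frame(
      id = c("A", "M1", "M2", "C", "D"),
      sire = c(NA, NA, NA, "A", "A"),
      dam = c(NA, NA, NA, "M1", "M2")),
    half_sib_related_mothers = data.frame(
      id = c("G1", "G2", "A", "M1", "M2", "C", "D"),
      sire = c(NA, NA, NA, "G1", "G1", "A", "A"),
      dam = c(NA, NA, NA, "G2", "G2", "M1", "M2")),
    cousin = data.frame(
      id = c("G1", "G2", "U1", "U2", "S1", "S2", "C", "D"),
      sire = c(NA, NA, NA, NA, "G1", "G1", "S1", "S2"),
      dam = c(NA, NA, NA, NA, "G2", "G2", "U1", "U2")),
    stop("unknown scenario"))
  K <- kinship_matrix(ped)
  # parents of the scored offspring are always the last two rows
  K[nrow(ped), nrow(ped) - 1L]
}

# Identity-by-descent intervals of a diploid individual: elementary
# intervals where the two haplotypes carry the same founder label.
diploid_ibd_intervals <- function(ind, total) {
  bnd <- sort(unique(c(0, ind$hap1$ends, ind$hap2$ends)))
  s <- bnd[-length(bnd)]
  lab1 <- ind$hap1$labels[findInterval(s, ind$hap1$ends) + 1L]
  lab2 <- ind$hap2$labels[findInterval(s, ind$hap2$ends) + 1L]
  same <- lab1 == lab2
  cbind(start = s[same], end = bnd[-1][same])
}

# Small deterministic genome used throughout.
toy_genome <- function(n = 3, len = 1e6) {
  genome(paste0("scf", seq_len(n)), rep(len, n))
}
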