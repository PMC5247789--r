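#' Close-relative inbreeding scenarios
#'
#' The four mating designs whose offspring the pedigree simulator
#' scores, with their path-counting inbreeding coefficients F (the
#' expected fraction of the offspring genome that is autozygous):
#'
#' * `full_sib` — brother x sister, children of two unrelated
#'   founders; F = 1/4.
#' * `half_sib_related_mothers` — half-siblings sharing one father,
#'   whose mothers are full sisters; F = 3/16.
#' * `half_sib_unrelated` — half-siblings sharing one father, with
#'   unrelated mothers; F = 1/8.
#' * `cousin` — first cousins (children of two full siblings married
#'   to unrelated spouses); F = 1/16.
#'
#' @name pedigree_scenarios
#' @return `pedigree_scenarios()` returns the scenario names.
#' @export
pedigree_scenarios <- function() {
  c("full_sib", "half_sib_related_mothers", "half_sib_unrelated", "cousin")
}

# Number of founder haplotypes each scenario needs.
.scenario_n_haps <- c(full_sib = 4L, half_sib_related_mothers = 6L,
                      half_sib_unrelated = 6L, cousin = 8L)

# Breed one offspring of the scenario from a pool of unrelated founder
# haplotypes; extra unrelated individuals (spouses, second mothers) are
# taken fresh from the pool.
breed_offspring <- function(scenario, pool, r) {
  g <- pool$genome
  fh <- function(i) founder_haplotype(pool, i)
  mate <- function(a, b) individual(meiosis(a, g, r), meiosis(b, g, r))
  switch(
    scenario,
    full_sib = {
      father <- individual(fh(1L), fh(2L))
      mother <- individual(fh(3L), fh(4L))
      mate(mate(father, mother), mate(father, mother))
    },
    half_sib_unrelated = {
      father <- individual(fh(1L), fh(2L))
      mother1 <- individual(fh(3L), fh(4L))
      mother2 <- individual(fh(5L), fh(6L))
      mate(mate(father, mother1), mate(father, mother2))
    },
    half_sib_related_mothers = {
      father <- individual(fh(1L), fh(2L))
      granddad <- individual(fh(3L), fh(4L))
      grandma <- individual(fh(5L), fh(6L))
      mother1 <- mate(granddad, grandma)
      mother2 <- mate(granddad, grandma)
      mate(mate(father, mother1), mate(father, mother2))
    },
    cousin = {
      granddad <- individual(fh(1L), fh(2L))
      grandma <- individual(fh(3L), fh(4L))
      sib1 <- mate(granddad, grandma)
      sib2 <- mate(granddad, grandma)
      spouse1 <- individual(fh(5L), fh(6L))
      spouse2 <- individual(fh(7L), fh(8L))
      mate(mate(sib1, spouse1), mate(sib2, spouse2))
    },
    stop("unknown pedigree scenario: ", scenario)
  )
}

#' Simulate offspring of close-relative inbreeding and score their
#' SNP-free segments
#'
#' For each replicate, fresh unrelated founder haplotypes are drawn
#' (variant density `f` per bp), the pedigree of the chosen scenario is
#' bred via Poisson-crossover [meiosis()], and the final offspring's
#' SNP-free segments (threshold `min_len`) are scored over the whole
#' simulated genome.  Unless fixed via `rec_rate`, each replicate draws
#' its recombination rate uniformly from 1-10 cM/Mb, the plausible
#' range for the species.  No mutations are introduced during the
#' pedigree: at ~1e-9 per bp per generation they are negligible next to
#' the standing variation.
#'
#' @param scenario one of [pedigree_scenarios()].
#' @param g a [genome()] (>= 10 Mb total recommended for stable
#'   statistics).
#' @param reps number of replicate pedigrees (default 100).
#' @param rec_rate recombination rate in cM/Mb; `NULL` (default) draws
#'   uniformly in `[1, 10]` per replicate.
#' @param f founder haplotype variant frequency per bp (default 0.007).
#' @param min_len qualifying-segment threshold in bp (default 1000).
#' @param seed optional integer seed (replicate i uses `seed + i - 1`).
#' @return A list of class `pedigree_result`: `scenario`,
#'   `per_replicate` (data frame with one row per replicate:
#'   `rec_rate`, `fraction_ge_L`, `median_len_ge_L`, `longest_len`,
#'   `het_rate`), `mean_fraction_ge_L`, `pooled_median_len`
#'   (median over all qualifying segments pooled across replicates),
#'   `pooled_lengths`, and `expected_F` (the path-counting inbreeding
#'   coefficient).
#' @export
run_pedigree <- function(scenario, g, reps = 100, rec_rate = NULL,
                         f = 0.007, min_len = 1000, seed = NULL) {
  scenario <- match.arg(scenario, pedigree_scenarios())
  stopifnot(inherits(g, "genome"), reps >= 1)
  expected_F <- c(full_sib = 1 / 4, half_sib_related_mothers = 3 / 16,
                  half_sib_unrelated = 1 / 8, cousin = 1 / 16)[[scenario]]
  rows <- vector("list", reps)
  pooled <- vector("list", reps)
  for (i in seq_len(reps)) {
    if (!is.null(seed)) set.seed(seed + i - 1L)
    r <- if (is.null(rec_rate)) stats::runif(1L, 1, 10) else rec_rate
    pool <- founder_pool(g, .scenario_n_haps[[scenario]], f)
    off <- breed_offspring(scenario, pool, r)
    st <- score_individual(off, pool, min_len = min_len)
    rows[[i]] <- data.frame(replicate = i, rec_rate = r,
                            fraction_ge_L = st$fraction_ge_L,
                            median_len_ge_L = st$median_len_ge_L,
                            longest_len = st$longest_len,
                            het_rate = st$het_rate)
    pooled[[i]] <- st$lengths_ge_L
  }
  per_replicate <- do.call(rbind, rows)
  pooled_lengths <- sort(unlist(pooled, use.names = FALSE))
  structure(list(
    scenario = scenario,
    per_replicate = per_replicate,
    mean_fraction_ge_L = mean(per_replicate$fraction_ge_L),
    pooled_median_len = if (length(pooled_lengths))
      stats::median(pooled_lengths) else NA_real_,
    pooled_lengths = pooled_lengths,
    expected_F = expected_F,
    min_len = min_len
  ), class = "pedigree_result")
}

#' @export
print.pedigree_result <- function(x, ...) {
  cat(sprintf(
    paste0("<pedigree_result> %s, %d replicates\n",
           "  mean fraction in SNP-free segments >= %d bp: %.4f",
           " (pedigree F = %.4f)\n",
           "  pooled median qualifying length: %s bp\n"),
    x$scenario, nrow(x$per_replicate), x$min_len,
    x$mean_fraction_ge_L, x$expected_F,
    format(round(x$pooled_median_len), big.mark = ",")))
  invisible(x)
}
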