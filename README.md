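# snpdesert

Homozygous-desert segment analysis and founder-history simulation for
diploid genomes.

## The problem

A sequenced diploid individual whose genome is heterozygous at rate *h*
should almost never show long stretches without heterozygous sites:
under uniform placement the chance that a *w*-bp window is SNP-free is
(1 − *h*)^*w*, which at *h* = 1.5% is below 1% already for *w* = 500 bp.
When a genome nevertheless carries a large fraction of its length in
SNP-free segments ≥ 1 kb ("homozygous deserts"), those segments are
identical-by-descent (IBD) tracts: both homologous copies descend from
the same recent ancestral haplotype.  The genome-wide desert fraction
estimates the inbreeding coefficient *F*, and the desert *length*
distribution dates the event — each generation of recombination cuts
IBD blocks, so a segment whose lineages pass through ~2*G* meioses has
expected genetic length 100/(2*G*) cM.

The motivating organism is the North American cabbage white butterfly
(*Pieris rapae*): ~1.5% heterozygosity overall, yet ~18% of the
assembly in SNP-free segments ≥ 1 kb with a median length of tens of
kb.  Two candidate explanations — recent close-relative inbreeding
versus descent from a handful of founders hundreds of generations ago —
predict similar desert *fractions* but desert *lengths* that differ by
an order of magnitude.  `snpdesert` implements everything needed to
make that comparison:

* **Observed-genome statistics** — coverage-based filtering of
  collapsed assembly regions (two-peak depth model), SNP-free window
  fractions over a standard window ladder, maximal SNP-free segments
  and their summary, and a random-placement null (closed form and
  simulation).
* **Pedigree simulator** — explicit Poisson-crossover meiosis over
  sparse founder haplotypes for four close-relative designs
  (full siblings *F* = 1/4, half-sibs with sister mothers 3/16,
  half-sibs 1/8, cousins 1/16).
* **Forward population simulator** — a compiled Wright–Fisher engine
  with recombination, infinite-sites mutation and 10-fold exponential
  growth from 2–4 founders to an effective-size cap, using
  ancestry-block arithmetic so a 246 Mb genome over 500 generations
  runs in minutes.
* **Synthetic-data generator** — genomes, het-SNP VCFs and bimodal
  depth tracks with known embedded IBD tracts, so the whole pipeline is
  testable without any external data.

The methods vignette (`vignettes/population-history.Rmd`) documents the
models, parameter choices and limitations in detail.

## Worked example

Simulate a small "observed" dataset (20 Mb, 18% embedded IBD tracts,
bimodal 84×/42× depth), run the observed-genome pipeline, and compare
both historical hypotheses at reduced scale:

```r
library(snpdesert)

cfg <- synth_config(n_scaffolds = 4, scaffold_length = 5e6,
                    het_rate = 0.015, ibd_fraction = 0.18,
                    ibd_tract_mean = 5e4, depth_mean = 84,
                    collapsed_fraction = 0.3, seed = 1)
paths <- write_synthetic_dataset(cfg, "demo")
res <- run_observed_pipeline(paths$vcf, paths$depth, paths$genome,
                             null_seed = 2)
print(res)
```

```
== observed-genome SNP-desert analysis ==
<peak_model> diploid mode 82.4 (range 57.5-107.4), collapsed mode 41.3
  analyzed (diploid-coverage) length: 14,223,500 bp, het rate 0.0123
<segment_stats> 172790 segments over 14,223,500 analyzed bp
  fraction in segments >= 1000 bp: 0.1778
  median qualifying length: 11,668 bp, longest: 101,403 bp
  mean depth analyzed 83.9, SNP-free segments 83.9
  SNP-free window fractions (observed / random null):
       100 bp: 0.3614 / 0.2898
       200 bp: 0.2183 / 0.0823
       ...
      1000 bp: 0.1745 / 0.0000
     10000 bp: 0.1461 / 0.0000
```

Reading the output: the depth histogram was resolved into a diploid
peak (82×) and a collapsed-haplotype peak (41×); analysis is restricted
to the 14.2 Mb of diploid-coverage windows.  17.8% of the analyzed
length lies in SNP-free segments ≥ 1 kb — recovering the 18% that the
generator embedded — while the random-placement null drops to zero
beyond 1 kb windows, so the deserts cannot be a sampling accident of a
1.2% het rate.

```r
g <- genome(paste0("scf", 1:5), rep(1e7, 5))
ped <- run_pedigree("full_sib", g, reps = 20, seed = 3)
pop <- simulate_population(
  pop_sim_params(g, n_founders = 3, generations = 200, ne_cap = 2000,
                 n_samples = 10, seed = 4))
run_hypothesis_comparison(
  observed = list(fraction_ge_L = res$stats$fraction_ge_L,
                  median_len_ge_L = res$stats$median_len_ge_L),
  pedigree_results = list(ped), popsim_results = list(pop))
```

```
== hypothesis comparison (fraction AND median must both match) ==
           scenario        hypothesis fraction median_bp
           full_sib recent_inbreeding   0.2400 2,134,021
 founders_3_gen_200      few_founders   0.2187    44,742
           observed          observed   0.1778    11,668
```

Both histories produce a large desert fraction, but sibling mating
leaves *megabase* deserts while a 3-founder population 200 generations
old leaves ~45 kb ones: only the founder history is compatible with an
observation of short, abundant deserts.

A thin command-line wrapper with the same functionality ships in
`inst/scripts/snpdesert.R` (subcommands `simulate-data`, `segments`,
`pedigree`, `popsim`).

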