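# hapsweep

Phylogeographic analysis of a selected haplotype in a recombining autosomal
region, built around the *SLC24A5* skin-pigmentation locus: the derived
allele of rs1426654 (A111T) is carried almost exclusively by one core
haplotype, C11, whose origin (a single crossover between two older
haplotypes, followed by the A111T mutation) and age can be reconstructed
from phased population panels.

The package is for population geneticists who want each stage of that kind
of analysis as a tested, reusable function:

* **I/O** — phased panels from VCF (`|`-phased), IMPUTE-style
  hap/legend/sample triples, or plain TSV matrices, recoded to
  0 = ancestral / 1 = derived / `NA` against a site annotation; writers
  round-trip bit-exactly.
* **LD blocks** — partition a region at recombination hotspots
  (rate > 5 cM/Mb, boundaries at run midpoints; secondary 0.8 cM/Mb
  boundaries opt-in) and measure block geometry.
* **Classification** — assign chromosomes to named haplotypes, ambiguity
  classes (`C6/C7`), or key-site residual classes (`Other-d`/`Other-a`),
  and tabulate by population.
* **Networks** — collapse a panel into haplotype classes, link them by a
  deterministic nearest-neighbour (minimum spanning) rule, root by
  ancestral alleles, and flag sites mutating on more than one edge — the
  signature of recombination under infinite sites.
* **Crossover reconstruction** — test whether a haplotype is a
  zero-mismatch single-crossover product of two parents, localise the
  breakpoint interval, scan candidate parent pairs, and emit the
  reciprocal product.
* **Molecular clock** — calibrate a per-site per-year rate from an
  outgroup alignment (gap-masked: `mu = D / (L_aln * 2 * T)`), convert the
  mean Hamming distance from the modal haplotype into years
  (`age = mean_diff / (mu * L)`), estimate effective sample sizes by
  duplication resampling, attach exact Garwood Poisson confidence limits,
  and correct for undetected rare variants via the power-weighted spectrum
  `sum(A_i / P_i)`.
* **Simulators** — star genealogies (sweep limit), infinite-sites mutation
  trees with persisting ancestors, single-crossover recombinants and
  frequency-table panels, each with a truth record, so the whole pipeline
  is testable offline.

## Worked example

Calibrate the clock from the published human–chimpanzee summary of the
C+D region, then date the common ancestor of the C11+D4 carriers from the
published chromosome and difference totals:

```r
library(hapsweep)

cal <- slc24a5_calibration()
mu  <- calibrate_rate(cal$d, cal$l_aln, cal$t_years)
mu
#> clock_calibration: 1227 substitutions / 125531 nt / 6e+06 y (2 lineages)
#>   -> mu = 8.145e-10 per site per year

L <- block_length(slc24a5_blocks(), c("C", "D"))   # 127419 nt
date_haplotype(1013, 822, 19, mu, L, correction_factor = 1.58)
#> age_estimate: 7.8 kya (95% CI 4.4-12.8) from 1013 chromosomes,
#>   822 differences, ESS 19
#>   undercount-corrected: 12.4 kya (7.0-20.2), factor 1.58
```

The point estimate reads as: 822 differences over 1013 chromosomes is a
mean of 0.81 mutations per lineage; at 8.145e-10 per site per year over
127,419 nt that is ~7,800 years to the founder, and correcting for
variants missed at low sequencing depth raises it to ~12,400 years.  The
interval uses an effective sample size of 19 (not 1013) because post-sweep
lineages are strongly correlated.

The haplotype network over the 11 published core haplotypes shows the
crossover footprint — exactly one site appears on two edges:

```r
defs  <- slc24a5_core_definitions()
panel <- simulate_classified_panel(
  defs, data.frame(label = names(defs$entries), population = "pool",
                   count = 1))
net <- build_network(panel, min_hap_freq = 0)
find_recurrent_sites(net)[, c("site", "n_edges")]
#>   site n_edges
#> 1   c1       2

derived_allele_share(slc24a5_hapmap_counts(), "C11", defs)
#> [1] 96.97885
```

`vignettes/haplotype-dating.Rmd` explains the model, the assumptions and
the design choices; `inst/cli/hapsweep.R` exposes the stages
(`classify`, `network`, `recomb-scan`, `date`, `calibrate`, `simulate`)
as a command-line tool driven by flat `key = value` configs.

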