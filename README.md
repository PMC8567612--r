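# achiasma

Tetrad segregation, mutation accumulation and recombination-signal
analysis for achiasmate yeast genomes.

## The problem

A handful of eukaryotes appear to complete meiosis without crossing
over. Demonstrating that from sequence data is an exercise in proving a
negative: it requires calling meiotic events across whole genomes of
dissected tetrads at marker-level resolution, showing that what few
events exist are gene conversions (non-crossovers) rather than
reciprocal exchanges, and corroborating the absence of recombination on
evolutionary timescales through tree concordance and linkage
disequilibrium. Because the interesting result is "zero events", the
analysis stack itself has to be validated against data with known
ground truth.

`achiasma` packages that stack for budding yeasts that mate within the
meiotic tetrad (e.g. *Saccharomycodes ludwigii*-like life cycles):

* **a ground-truth simulator** — hybrid parental genomes with
  compartmentalized divergence, meioses with configurable crossover
  (CO) and non-crossover (NCO) rates, sister / non-sister intratetrad
  matings, mutation-accumulation (MA) genealogies with configurable
  mutation rate, AT bias, Ts:Tv and mitotic loss of heterozygosity
  (LOH), and Poisson–binomial read-depth noise;
* **marker selection** — high-confidence discriminant SNPs between two
  parents from per-sample allele depths (single alternate allele,
  per-parent depth ≥ 10, majority-allele fraction > 0.9, opposite
  alleles);
* **tetrad event calling** — parental-origin assignment per spore,
  2:2 / 3:1 / 4:0 segregation classification, and CO / NCO /
  premeiotic-LOH calls with inner intervals and maximum tracts bounded
  by the closest flanking 2:2 markers;
* **MA-rate estimation** — line-exclusive single-nucleotide mutation
  filtering (depth > 10 everywhere, allele balance 0.4–0.6 for hets,
  zygosity classes by founder background), the base-substitutional
  rate μ_bs = m / (sites × ploidy × generations × lines) with the
  exact Poisson 95% CI (χ²(0.025, 2m)/2, χ²(0.975, 2m+2)/2),
  composition-weighted AT bias
  (m_GC→AT / N_GC) / (m_AT→GC / N_AT), equilibrium GC = 1/(1 + bias),
  Ts:Tv, and mitotic LOH tract detection with a per-generation rate;
* **tree concordance** — allele-sharing distances, BIONJ trees per
  chromosome and genome-wide, and five unrooted topological tree
  distances (Robinson–Foulds, path difference, quartet, matching
  split, maximum agreement subtree) normalized against the mean of
  1000 uniform random topology pairs;
* **LD decay** — genotype-correlation r² for all intra-chromosome SNP
  pairs, averaged per distance and smoothed with a moving average.

## Worked example

Simulate a hybrid cross with a high-divergence compartment (3.3% per
site) and a low-divergence background (0.2%), push it through marker
selection and event calling, and estimate an MA rate:

```r
library(achiasma)

g <- genome_spec(data.frame(name = c("chrA", "chrB"),
                            length = c(2e5, 1.5e5)))
prof <- divergence_profile(data.frame(
  chrom = c("chrA", "chrA", "chrB"),
  start = c(0, 1e5, 0), end = c(1e5, 2e5, 1.5e5),
  rate  = c(0.033, 0.002, 0.002)), g)
pp <- simulate_parent_pair(g, prof, seed = 11)
pp
#> Parental pair: 3852 discriminant SNPs over 2 chromosome(s)

markers <- select_markers(parent_calls(pp, mean_depth = 40, seed = 12))
tt <- simulate_tetrad(pp, meiosis_params(co_rate = 0, nco_rate = 1),
                      seed = 13)
om <- assign_origin(markers, spore_calls(tt, mean_depth = 30, seed = 14))
call_events(om, chrom_lengths = c(chrA = 2e5, chrB = 1.5e5))
#> Recombination events: 2 (0 CO, 2 NCO, 0 premeiotic LOH, 0 complex)
#>   chrom kind spores n_markers inner_start inner_end tract_start tract_end
#> 1  chrA  NCO      2        42       77971     79148       77914     79174
#> 2  chrB  NCO      4         5      133658    134814      133189    135610
```

An achiasmate meiosis (`co_rate = 0`) with one expected conversion per
chromosome yields two NCOs and no crossover: each names one converted
spore, its supporting markers (`n_markers`), the first/last converted
marker (`inner_*`) and the maximum tract between the closest flanking
2:2 markers (`tract_*`). Rates from published MA counts:

```r
estimate_rate(85, n_lines = 30, generations = ma_generations(97, 21),
              callable_sites = 0.93 * 12.5e6, ploidy = 1)
#> Base-substitutional mutation rate
#>   mu_bs = 1.2e-10 /site/generation (85 mutations, 30 lines x 2037
#>   generations, 11,625,000 sites x ploidy 1)
#>   Poisson 95% CI: 9.56e-11 - 1.48e-10

pooled_bias(c(2.92, 5.85, 2.63), weights = c(85, 48, 53))
#> $bias
#> [1] 3.593495        # GC→AT mutations ~3.6x more frequent per site
#> $equilibrium
#> [1] 0.2327501       # mutation-driven equilibrium GC ≈ 23.3%
```

The pooled equilibrium sits ~6.3 points below an observed GC of 29.6%,
quantifying how much of the composition mutation pressure alone cannot
explain.

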