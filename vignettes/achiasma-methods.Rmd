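---
title: "Models and methods behind achiasma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind achiasma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`achiasma` analyses whole-genome evidence for (or against) meiotic
crossing over in tetrad-forming yeasts. Because its central empirical
claim is an absence — zero crossovers — every analysis stage is paired
with a simulator that produces the same kind of data with known ground
truth. This vignette documents the models, the tunable parameters, the
numerical choices, and what the simulations do and do not establish
about real data.

## The meiosis model

A cross is represented by two phased parental haplotypes over a shared
chromosome set. Divergence between them is compartmentalized: each
chromosome is tiled by intervals with their own per-site SNP rate,
because real hybrid genomes mix highly divergent compartments (a few
percent per site) with nearly identical ones (~0.2%). SNP counts per
compartment are Binomial(length, rate) with positions uniform without
replacement, kept out of repeat-masked intervals by default since
marker sets are called against masked references.

One meiosis replicates each homolog into two chromatids and then:

* places Poisson(`co_rate`) crossover breakpoints per chromosome at
  continuous uniform positions; each crossover exchanges the distal
  segments of one chromatid of each homolog. Breakpoints fall between
  markers and are therefore reported as the flanking-marker interval —
  exactly the resolution real data have;
* places Poisson(`nco_rate`) gene-conversion tracts; tract lengths are
  uniform on 1–2 kb by default, the scale typical of budding-yeast
  conversion tracts, and the recipient chromatid and conversion
  direction are uniform because no asymmetry is established;
* segregates 2+2: meiosis I separates homolog centromeres into two
  cells (independent assortment across chromosomes), meiosis II splits
  sisters. Spores 1–2 always descend from one meiosis-I cell, spores
  3–4 from the other, which is what "non-sister" intratetrad mating
  refers to.

Chiasma and chromatid interference are not modelled (placements are
independent Poisson); `obligate_co` is implemented by rejection
sampling. These simplifications matter for event *spacing*, not for
whether an individual event is detectable, which is what the detection
tests exercise.

Every simulated event is recorded with exact coordinates, including a
`visible` flag: a crossover between two chromatids that already carry
identical parental labels distal to the breakpoint (a two-strand
double-crossover configuration) changes no marker and is unobservable
in principle, in simulation and in reality alike. Detection claims are
therefore made, and tested, for marker-visible events.

## Event calling

Origin assignment is definitional: a spore's call at a marker is P1 or
P2 when its allele equals the respective parental allele, missing
otherwise (no call, heterozygous call, depth below threshold, or a
third allele — counted and warned about). Event calling compresses
each chromosome's complete markers into runs of identical origin
vectors:

* a phase change between two 2:2 runs with exactly two spores
  switching (necessarily reciprocally) is a **CO**; the inner interval
  is the flanking marker pair, which coincides with the maximum tract;
* a 3:1/1:3 run flanked on both sides by the *same* 2:2 phase with one
  converted spore is an **NCO**; its maximum tract runs between the
  closest flanking 2:2 markers (chromosome bounds if none), so a
  single-marker conversion at position p with flanks at p−a and p+b has
  maximum tract length a+b;
* 4:0/0:4 runs are reported as **premeiotic LOH** and excluded from
  meiotic event counts — they pre-date meiosis (mitotic conversion
  during diploid growth);
* anything contradictory is flagged **COMPLEX** rather than dropped:
  conversion runs without a 2:2 flank on both sides, four spores
  switching at once, and reciprocal double switches restored within a
  single 2:2 marker (indistinguishable from a two-strand double event
  at that resolution; with ≥ 2 intervening markers two COs are
  reported).

`min_nco_markers` defaults to 1 because genuine single-marker NCOs
exist. Markers with any missing spore are excluded from event support
but do not break runs; a missing-data gap longer than `merge_distance`
(default 5 kb) splits the chromosome so that no event is ever called
across it. The Seg export is a minimal six-column TSV (chromosome,
position, four origin codes, `-` for missing) that round-trips
losslessly; it does not reproduce any particular legacy dialect
byte-for-byte.

The caller is verified against a brute-force enumerator that tests
every adjacent marker pair and every marker interval directly against
these definitions, and against simulated truth over 1000 tetrads in
the acceptance suite. Those assertions are conditioned on *resolvable*
configurations — events marker-visible and separated by at least two
markers from each other and from chromosome ends — since outside that
regime the definitions themselves become ambiguous (and the caller
flags rather than guesses).

## Mutation-accumulation model and estimators

MA lines accumulate Poisson(μ × callable sites × ploidy × generations)
mutations each. The AT bias is modelled as per-site rate heterogeneity:
GC bases mutate `at_bias` times faster per site than AT bases, with a
shared transition fraction ts_tv/(1 + ts_tv) and an even split of the
two transversion targets. A purely directional parameterization (same
per-site rate, biased outcomes) cannot reach a bias of 3.6 at Ts:Tv
1.2 — with a shared transition fraction the AT→GC probability is
bounded below by it — whereas rate heterogeneity recovers both the
composition-weighted bias and the Ts:Tv ratio in expectation, as the
generator tests verify. Heterozygous-diploid founders additionally
receive LOH tracts at `loh_rate` events per generation, each collapsing
the founder's heterozygous sites in the tract onto one haplotype.

The filters mirror standard MA practice: single alternate allele,
strictly more than 10 reads in every sample, the variant in exactly one
line, allele balance within 0.4–0.6 for heterozygous calls, zygosity
classes restricted to what the founder background can produce, and
het→hom changes screened against detected LOH tracts. One consequence
worth stating: at moderate depth (20–40×) the balance window itself
rejects a material fraction of *true* heterozygous mutations, because
Binomial(depth, 0.5) allele fractions stray outside 0.4–0.6 roughly a
fifth of the time. The filter is exact for haploid backgrounds at any
depth clearing the threshold, and for diploids in the high-depth limit;
the tests assert exactly that, and at moderate depth assert that losses
are confined to hets (no false positives). Real MA studies under-count
for the same reason.

The rate estimator divides the count by sites × ploidy × generations ×
lines; ploidy belongs in the denominator because a diploid cell
exposes twice the base pairs per generation (the verbal "per site"
description hides this, but the arithmetic of published diploid rates
requires it). The 95% CI is the exact Poisson interval,
χ²(0.025, 2m)/2 to χ²(0.975, 2m+2)/2, scaled by the same denominator —
not a normal approximation — and is tested against direct tail-sum
inversion. `callable_sites` is always an explicit argument: analyzed
genome fractions differ between genealogies and are not always
published, so the package never guesses one (the hybrid-diploid
genealogy of the motivating study is exactly such a case).

AT bias is the per-site flux ratio (m_GC→AT/N_GC)/(m_AT→GC/N_AT) over
the callable composition; GC- and AT-conserving substitutions do not
enter. Equilibrium GC is 1/(1 + bias). Pooling across genealogies is a
pair of count-weighted means — of the biases and of the equilibria
separately; pooling per-site fluxes first would give a slightly
different equilibrium, and the weighted-mean-of-equilibria convention
is the one that reproduces published pooled values. LOH detection is
run-length encoding of founder-heterozygous sites gone homozygous for
a single haplotype in one line, with `min_markers = 2` by default to
suppress single-site genotyping noise (configurable to 1); an event is
terminal when it reaches the first or last heterozygous site of its
chromosome.

## Tree concordance

Strain dissimilarity is an allele-sharing distance: sharing between
dosages g, h ∈ {0, 1, 2} is 1 − |g − h|/2, averaged over sites called
in both strains (hets count half). It is a documented stand-in for
SNP-array-style individual dissimilarity; exact published formulas
vary, and topology-level conclusions are asserted here only on
simulations. Trees are BIONJ (variance-weighted neighbour joining, via
`ape::bionj`), which recovers additive matrices exactly.

Five unrooted, purely topological distances are implemented:
Robinson–Foulds (splits in exactly one tree), path difference
(Euclidean distance of topological leaf-pair path lengths), quartet
(quartets resolved differently, via the four-point condition on
unit-branch-length path distances — exact for binary trees), matching
split (minimum-weight perfect matching between split sets under
symmetric-difference weight, unmatched splits paired with the trivial
split; solved by bitmask dynamic programming, exact up to ~16
nontrivial splits), and maximum agreement subtree distance (n minus
the largest agreeing leaf subset, computed exactly by a directed-edge
dynamic program over all edge rootings — O(n²) state pairs, practical
far beyond the 11-strain study scale). Branch lengths are ignored
throughout; two further weighted variants sometimes reported alongside
these are deliberately out of scope. All five are tested against
exhaustive oracles (split, quartet and leaf-subset enumeration) at
n ≤ 8 and against independent implementations where they exist.

Normalization divides a raw distance by the mean over `n_random`
(default 1000) independent pairs of topologies drawn uniformly over
unrooted binary labeled trees by sequential uniform leaf insertion
over the 2k−5 edges — the generator's uniformity is itself
chi-square-tested over all 15 five-taxon topologies. A normalized
distance of ~1 therefore means "as discordant as two random trees";
the concordance scan computes the normalizer once per strain set and
reuses it across chromosomes.

## LD decay

r² is the squared Pearson correlation of alternate-allele dosage
vectors across strains (het = 1, missing pairwise-deleted) — the
genotype-based estimator, chosen because unphased diploids preclude
haplotype-frequency r²; comparisons between strain groups are relative
and should use equal group sizes. All intra-chromosome pairs up to
`max_dist` (default 300 kb) are scored, averaged at each exact
distance, and smoothed with a centred moving average over 50 distance
points (both recorded in the output). Under a single shared genealogy
the curve is flat in distance — tested by a regression slope whose CI
covers zero, fitted on the raw per-distance means because the smoothed
series is autocorrelated — and under simulated recombination (sites
switching between two independent genealogies along the chromosome)
the smoothed curve decreases in distance (Spearman test).

## What the simulations do not establish

The generator emulates marker geometry, event structure, depth noise
and missingness, but not read-level artefacts: mapping bias, indels,
structural variation, aneuploidy, or two-spore diploid asci (all of
which occur in real strains of the motivating system) are out of
scope. Passing tests therefore validate the *analysis logic* at the
stated filters, not the upstream variant calling. Problem sizes in the
test and acceptance suites — 100-kb single-chromosome crosses with
~200 markers, 1000-tetrad detection sweeps, 100-replicate MA recovery
at μ = 5×10⁻⁹ over 1 Mb × 20 lines × 1000 generations, 11-strain tree
and LD groups — were chosen as the smallest scales at which the tested
properties are statistically meaningful; generator defaults themselves
(μ = 1.2×10⁻¹⁰, bias 2.92, Ts:Tv 1.2, 30 lines × 2037 generations,
3.3%/0.2% divergence compartments, GC 0.296) follow the study system
this package models.
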