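#' Generations elapsed in a bottleneck-propagated MA experiment
#'
#' Mutation-accumulation lines are propagated through single-cell
#' bottlenecks; each streak-to-colony cycle corresponds to a fixed
#' number of cell generations, so the experiment's total is simply
#' cycles times generations per cycle (e.g. 97 cycles of 21 generations
#' give 2037).
#'
#' @param cycles number of bottleneck cycles (>= 1).
#' @param per_cycle generations per cycle (> 0).
#' @return total number of generations.
#' @export
ma_generations <- function(cycles, per_cycle) {
  stopifnot(cycles >= 1, per_cycle > 0)
  cycles * per_cycle
}

#' Mutation-accumulation simulation parameters
#'
#' Defaults reproduce the haploid genealogy of the study system this
#' package models: 30 lines bottlenecked for 97 cycles of 21
#' generations, a base-substitutional rate of 1.2e-10 per site per
#' generation, AT bias 2.92 and Ts:Tv 1.2.
#'
#' @param mu per-site per-generation base-substitutional mutation rate.
#' @param at_bias ratio of the per-GC-site GC->AT rate to the
#'   per-AT-site AT->GC rate (>= 0).
#' @param ts_tv expected transition:transversion ratio (>= 0).
#' @param n_lines number of independent MA lines (>= 1).
#' @param generations generations per line (>= 1).
#' @param founder_zygosity \code{"homozygous-haploid"},
#'   \code{"homozygous-diploid"} or \code{"heterozygous-diploid"}.
#' @param loh_rate expected mitotic loss-of-heterozygosity events per
#'   generation per line (heterozygous founders only).
#' @param loh_length LOH tract-length model, as in
#'   \code{\link{meiosis_params}}.
#' @return an object of class \code{ma_params}.
#' @export
ma_params <- function(mu = 1.2e-10, at_bias = 2.92, ts_tv = 1.2,
                      n_lines = 30, generations = ma_generations(97, 21),
                      founder_zygosity = c("homozygous-haploid",
                                           "homozygous-diploid",
                                           "heterozygous-diploid"),
                      loh_rate = 0,
                      loh_length = list(family = "uniform",
                                        min = 1000, max = 15000)) {
  founder_zygosity <- match.arg(founder_zygosity)
  stopifnot(mu >= 0, at_bias >= 0, ts_tv >= 0, n_lines >= 1,
            generations >= 1, loh_rate >= 0)
  p <- list(mu = mu, at_bias = at_bias, ts_tv = ts_tv, n_lines = n_lines,
            generations = generations, founder_zygosity = founder_zygosity,
            loh_rate = loh_rate, loh_length = loh_length)
  class(p) <- "ma_params"
  p
}

ma_ploidy <- function(params)
  if (params$founder_zygosity == "homozygous-haploid") 1L else 2L

# draw n callable positions (uniform over unmasked sites)
sample_callable <- function(genome, n) {
  if (n == 0) return(data.frame(chrom = character(), pos = numeric()))
  ch <- genome$chromosomes
  unmasked <- vapply(seq_len(nrow(ch)), function(i) {
    m <- genome$masked[genome$masked$chrom == ch$name[i], , drop = FALSE]
    ch$length[i] - sum(m$end - m$start)
  }, 0)
  ci <- sample.int(nrow(ch), n, replace = TRUE, prob = unmasked)
  pos <- numeric(n)
  for (k in seq_len(n)) {
    repeat {
      p <- floor(stats::runif(1, 0, ch$length[ci[k]]))
      if (!in_mask(genome, ch$name[ci[k]], p)) break
    }
    pos[k] <- p
  }
  data.frame(chrom = ch$name[ci], pos = pos)
}

#' Simulate a mutation-accumulation genealogy with known mutations
#'
#' Per line, the number of single-nucleotide mutations is
#' Poisson(mu x callable sites x ploidy x generations). The AT bias is
#' realised as per-site rate heterogeneity between GC and AT source
#' bases (the GC:AT per-site rate ratio equals \code{at_bias}), with a
#' shared transition fraction \code{ts_tv/(1+ts_tv)} and an even split
#' of the two transversion targets, so that both the composition-
#' weighted bias and the Ts:Tv ratio are recovered in expectation.
#' Heterozygous-diploid founders additionally receive mitotic LOH
#' tracts at \code{loh_rate} events per generation, each collapsing the
#' founder's heterozygous sites in the tract onto one haplotype.
#'
#' @param genome a \code{\link{genome_spec}}.
#' @param params an \code{\link{ma_params}}.
#' @param het_map founder heterozygous-site map, required for
#'   heterozygous-diploid founders: a \code{\link{parental_pair}} (its
#'   SNPs are the founder's heterozygous sites) or a data.frame with
#'   columns \code{chrom}, \code{pos}, \code{a1}, \code{a2}.
#' @param seed integer seed, or \code{NULL}.
#' @return an object of class \code{ma_genealogy} with \code{$snms}
#'   (true line-exclusive mutations: line, chrom, pos, ref, alt, class,
#'   ts flag, zygosity change) and \code{$loh} (true LOH tracts: line,
#'   chrom, start, end, kept haplotype).
#' @export
simulate_ma_genealogy <- function(genome, params, het_map = NULL,
                                  seed = NULL) {
  stopifnot(inherits(genome, "genome_spec"), inherits(params, "ma_params"))
  if (!is.null(seed)) set.seed(seed)
  het <- params$founder_zygosity == "heterozygous-diploid"
  if (het) {
    if (inherits(het_map, "parental_pair")) het_map <- het_map$snps
    if (is.null(het_map) ||
        !all(c("chrom", "pos", "a1", "a2") %in% names(het_map)))
      stop("heterozygous-diploid founder requires a het_map ",
           "(parental_pair or chrom/pos/a1/a2 data.frame)")
  }
  ploidy <- ma_ploidy(params)
  C <- callable_sites(genome)
  gc <- genome$gc_content
  p_gc_source <- gc * params$at_bias / (gc * params$at_bias + (1 - gc))
  p_ts <- params$ts_tv / (1 + params$ts_tv)
  lam <- params$mu * C * ploidy * params$generations

  snms <- list(); lohs <- list()
  for (line in seq_len(params$n_lines)) {
    n <- stats::rpois(1, lam)
    if (n > 0) {
      sites <- sample_callable(genome, n)
      from_gc <- stats::runif(n) < p_gc_source
      is_ts <- stats::runif(n) < p_ts
      # transversions: half change the GC/AT class, half preserve it
      tv_change <- stats::runif(n) < 0.5
      ref <- ifelse(from_gc,
                    ifelse(stats::runif(n) < 0.5, "C", "G"),
                    ifelse(stats::runif(n) < 0.5, "A", "T"))
      alt <- character(n)
      alt[is_ts] <- c(A = "G", C = "T", G = "A", T = "C")[ref[is_ts]]
      ch <- !is_ts & tv_change
      alt[ch] <- c(A = "C", C = "A", G = "T", T = "G")[ref[ch]]
      pr <- !is_ts & !tv_change
      alt[pr] <- c(A = "T", C = "G", G = "C", T = "A")[ref[pr]]
      zyg <- if (ploidy == 1L) "hom>hom" else "hom>het"
      snms[[length(snms) + 1]] <- data.frame(
        line = line, chrom = sites$chrom, pos = sites$pos,
        ref = ref, alt = alt,
        class = mutation_class(ref, alt),
        ts = is_ts, zygosity_change = zyg)
    }
    if (het && params$loh_rate > 0) {
      n_loh <- stats::rpois(1, params$loh_rate * params$generations)
      if (n_loh > 0) {
        ch <- genome$chromosomes
        ci <- sample.int(nrow(ch), n_loh, replace = TRUE, prob = ch$length)
        for (k in seq_len(n_loh)) {
          len <- draw_tract_length(params$loh_length)
          x <- stats::runif(1, 0, ch$length[ci[k]])
          lohs[[length(lohs) + 1]] <- data.frame(
            line = line, chrom = ch$name[ci[k]],
            start = x, end = min(x + len, ch$length[ci[k]]),
            haplotype = sample(1:2, 1))
        }
      }
    }
  }
  snms <- if (length(snms)) do.call(rbind, snms) else
    data.frame(line = integer(), chrom = character(), pos = numeric(),
               ref = character(), alt = character(), class = character(),
               ts = logical(), zygosity_change = character())
  lohs <- if (length(lohs)) do.call(rbind, lohs) else
    data.frame(line = integer(), chrom = character(), start = numeric(),
               end = numeric(), haplotype = integer())
  rownames(snms) <- rownames(lohs) <- NULL
  g <- list(genome = genome, params = params, het_map = if (het) het_map,
            snms = snms, loh = lohs)
  class(g) <- "ma_genealogy"
  g
}

#' @export
print.ma_genealogy <- function(x, ...) {
  cat("MA genealogy: ", x$params$n_lines, " lines x ",
      x$params$generations, " generations (",
      x$params$founder_zygosity, ")\n", sep = "")
  cat("  true SNMs: ", nrow(x$snms), "; true LOH tracts: ",
      nrow(x$loh), "\n", sep = "")
  invisible(x)
}

#' Classify a substitution into the six unordered base-pair classes
#'
#' @param ref,alt single-character reference and alternate bases.
#' @return character vector among \code{"GC>AT"}, \code{"AT>GC"},
#'   \code{"GC>GC"}, \code{"AT>AT"}.
#' @export
mutation_class <- function(ref, alt) {
  gcset <- c("G", "C")
  from <- ifelse(ref %in% gcset, "GC", "AT")
  to <- ifelse(alt %in% gcset, "GC", "AT")
  paste0(from, ">", to)
}

#' Transition test for a substitution
#'
#' @param ref,alt single-character bases.
#' @return logical: \code{TRUE} for purine-purine or
#'   pyrimidine-pyrimidine changes.
#' @export
is_transition <- function(ref, alt) {
  pur <- c("A", "G")
  (ref %in% pur) == (alt %in% pur)
}

#' Simulate per-site sequencing depths and allele counts
#'
#' Plumbing for exercising depth and allele-balance filters: total
#' depth per site and sample is Poisson(\code{mean_depth}); alternate
#' reads are Binomial(depth, p) with p = 0, 0.5, 1 for
#' hom-ref/het/hom-alt genotypes, perturbed towards the other allele by
#' \code{error_rate}.
#'
#' @param genotypes sites x samples matrix of alternate-allele dosages
#'   (0, 1, 2; \code{NA} gives zero depth).
#' @param mean_depth mean sequencing depth (> 0).
#' @param error_rate per-read error probability.
#' @param seed integer seed, or \code{NULL}.
#' @return list with matrices \code{ref_depth} and \code{alt_depth}.
#' @export
simulate_depths <- function(genotypes, mean_depth, error_rate = 0,
                            seed = NULL) {
  stopifnot(mean_depth > 0, error_rate >= 0, error_rate <= 0.5)
  if (!is.null(seed)) set.seed(seed)
  g <- as.matrix(genotypes)
  dp <- matrix(stats::rpois(length(g), mean_depth), nrow = nrow(g))
  dp[is.na(g)] <- 0L
  p <- g / 2
  p <- p + error_rate * (1 - 2 * p)
  p[is.na(p)] <- 0
  alt <- matrix(stats::rbinom(length(g), as.vector(dp), as.vector(p)),
                nrow = nrow(g))
  dimnames(alt) <- dimnames(dp) <- dimnames(g)
  list(ref_depth = dp - alt, alt_depth = alt)
}
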