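#' Filter line-exclusive single-nucleotide mutations from MA calls
#'
#' Applies the standard MA-line filters: single alternate allele,
#' strictly more than \code{min_depth} reads in every sample, the
#' variant present in exactly one line (relative to the founder
#' genotype), heterozygous calls only within the allele-balance window,
#' and zygosity-change classes restricted to those a given founder
#' background can produce. Heterozygous-to-homozygous changes are
#' additionally screened against detected LOH tracts (those inside a
#' tract of the same line are excluded as LOH, not mutation).
#'
#' @param calls a \code{\link{site_calls}} with one sample per line.
#' @param founder founder alternate-allele dosage at every site of
#'   \code{calls} (vector, values 0/1/2).
#' @param background founder zygosity: \code{"homozygous-haploid"},
#'   \code{"homozygous-diploid"} or \code{"heterozygous-diploid"}.
#' @param min_depth strict lower bound on per-sample total depth
#'   (default 10: a site needs more than 10 reads everywhere).
#' @param balance allele-balance window (inclusive) for heterozygous
#'   calls, default \code{c(0.4, 0.6)}.
#' @param loh_events optional data.frame of LOH tracts (\code{line},
#'   \code{chrom}, \code{start}, \code{end}) used to screen het-to-hom
#'   changes, e.g. from \code{\link{detect_ma_loh}}.
#' @return data.frame of SNM records: \code{line}, \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt} (lost and gained allele),
#'   \code{class}, \code{ts}, \code{zygosity_change}.
#' @export
filter_snms <- function(calls, founder,
                        background = c("homozygous-haploid",
                                       "homozygous-diploid",
                                       "heterozygous-diploid"),
                        min_depth = 10, balance = c(0.4, 0.6),
                        loh_events = NULL) {
  stopifnot(inherits(calls, "site_calls"),
            length(founder) == nrow(calls$sites))
  background <- match.arg(background)
  nl <- n_samples(calls)
  single_alt <- !grepl(",", calls$sites$alt) & nzchar(calls$sites$alt)
  tot <- calls$ref_depth + calls$alt_depth
  depth_ok <- rowSums(tot > min_depth) == nl
  g <- calls$genotype
  diff <- !is.na(g) & g != founder
  exclusive <- rowSums(diff) == 1
  cand <- which(single_alt & depth_ok & exclusive)
  out <- list()
  for (i in cand) {
    line <- which(diff[i, ])
    d <- g[i, line]
    zyg <- if (founder[i] == 1) "het>hom"
      else if (d == 1) "hom>het" else "hom>hom"
    ok <- switch(background,
                 "homozygous-haploid" = zyg == "hom>hom",
                 "homozygous-diploid" = zyg %in% c("hom>het", "hom>hom"),
                 "heterozygous-diploid" = zyg %in% c("hom>het", "het>hom"))
    if (!ok) next
    if (d == 1) {
      ab <- calls$alt_depth[i, line] / tot[i, line]
      if (is.na(ab) || ab < balance[1] || ab > balance[2]) next
    }
    if (zyg == "het>hom" && !is.null(loh_events) && nrow(loh_events)) {
      hit <- loh_events$line == line &
        loh_events$chrom == calls$sites$chrom[i] &
        loh_events$start <= calls$sites$pos[i] &
        loh_events$end > calls$sites$pos[i]
      if (any(hit)) next
    }
    # lost -> gained allele defines the substitution direction
    from <- if (zyg == "het>hom" && d == 0) calls$sites$alt[i] else
      calls$sites$ref[i]
    to <- if (zyg == "het>hom" && d == 0) calls$sites$ref[i] else
      calls$sites$alt[i]
    out[[length(out) + 1]] <- data.frame(
      line = line, chrom = calls$sites$chrom[i],
      pos = calls$sites$pos[i], ref = from, alt = to,
      class = mutation_class(from, to), ts = is_transition(from, to),
      zygosity_change = zyg)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(line = integer(), chrom = character(), pos = numeric(),
               ref = character(), alt = character(), class = character(),
               ts = logical(), zygosity_change = character())
  rownames(res) <- NULL
  res
}

#' Base-substitutional mutation rate with exact Poisson 95% CI
#'
#' The rate is the total number of line-exclusive mutations divided by
#' callable sites x ploidy x generations x lines. The confidence
#' interval is the exact (chi-square) Poisson interval on the count,
#' scaled by the same denominator: low = chisq(0.025, 2n)/2, high =
#' chisq(0.975, 2n+2)/2. A zero count gives mu = 0 with a one-sided
#' upper bound.
#'
#' @param n_mut total line-exclusive mutation count (>= 0).
#' @param n_lines number of lines.
#' @param generations generations per line.
#' @param callable_sites analyzed (unmasked) genome size in bp. Always
#'   an explicit input: the analyzed fraction differs between
#'   genealogies and should not be guessed.
#' @param ploidy 1 or 2; the denominator counts base pairs per cell, so
#'   diploid genealogies use twice the callable sites.
#' @return an object of class \code{rate_estimate} with fields
#'   \code{mu}, \code{ci} (length 2), and the inputs.
#' @examples
#' estimate_rate(85, n_lines = 30, generations = 2037,
#'               callable_sites = 0.93 * 12.5e6, ploidy = 1)
#' @export
estimate_rate <- function(n_mut, n_lines, generations, callable_sites,
                          ploidy = 1) {
  stopifnot(n_mut >= 0, n_lines > 0, generations > 0,
            callable_sites > 0, ploidy %in% c(1, 2))
  denom <- callable_sites * ploidy * generations * n_lines
  mu <- n_mut / denom
  lo <- if (n_mut == 0) 0 else 0.5 * stats::qchisq(0.025, 2 * n_mut)
  hi <- 0.5 * stats::qchisq(0.975, 2 * n_mut + 2)
  est <- list(mu = mu, ci = c(lo, hi) / denom, n_mut = n_mut,
              n_lines = n_lines, generations = generations,
              callable_sites = callable_sites, ploidy = ploidy)
  class(est) <- "rate_estimate"
  est
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat("Base-substitutional mutation rate\n")
  cat("  mu_bs = ", format(x$mu, digits = 3), " /site/generation (",
      x$n_mut, " mutations, ", x$n_lines, " lines x ",
      x$generations, " generations, ",
      format(x$callable_sites, big.mark = ","), " sites x ploidy ",
      x$ploidy, ")\n", sep = "")
  cat("  Poisson 95% CI: ", format(x$ci[1], digits = 3), " - ",
      format(x$ci[2], digits = 3), "\n", sep = "")
  invisible(x)
}

#' Equilibrium GC content implied by an AT mutation bias
#'
#' Under mutation pressure alone, the genomic GC fraction equilibrates
#' where the per-genome GC->AT and AT->GC fluxes balance:
#' \code{1 / (1 + bias)}.
#'
#' @param bias composition-weighted AT bias (>= 0, possibly
#'   \code{Inf}).
#' @return the equilibrium GC fraction.
#' @examples
#' equilibrium_gc(2.92)  # 0.255
#' @export
equilibrium_gc <- function(bias) {
  stopifnot(all(bias >= 0))
  ifelse(is.infinite(bias), 0, 1 / (1 + bias))
}

#' Composition-weighted AT mutational bias and equilibrium GC
#'
#' The bias is the ratio of per-site rates, i.e. GC->AT counts per
#' callable GC base over AT->GC counts per callable AT base;
#' GC-conserving and AT-conserving substitutions do not enter.
#'
#' @param snms SNM records (from \code{\link{filter_snms}} or a
#'   simulated genealogy's \code{$snms}).
#' @param composition named vector with callable \code{n_gc} and
#'   \code{n_at} base counts (see \code{\link{base_composition}}), or a
#'   \code{\link{genome_spec}}.
#' @return an object of class \code{bias_estimate}: \code{bias},
#'   \code{equilibrium} (= \code{1/(1+bias)}), and the counts used. A
#'   zero AT->GC count yields an infinite bias and equilibrium 0.
#' @export
compute_at_bias <- function(snms, composition) {
  if (inherits(composition, "genome_spec"))
    composition <- base_composition(composition)
  stopifnot(all(c("n_gc", "n_at") %in% names(composition)),
            all(composition > 0))
  m_ga <- sum(snms$class == "GC>AT")
  m_ag <- sum(snms$class == "AT>GC")
  bias <- if (m_ag == 0) Inf else
    (m_ga / composition[["n_gc"]]) / (m_ag / composition[["n_at"]])
  est <- list(bias = bias, equilibrium = equilibrium_gc(bias),
              n_gc_to_at = m_ga, n_at_to_gc = m_ag, n_snms = nrow(snms),
              composition = composition)
  class(est) <- "bias_estimate"
  est
}

#' @export
print.bias_estimate <- function(x, ...) {
  cat("AT bias (composition-weighted): ", format(x$bias, digits = 3),
      "  [", x$n_gc_to_at, " GC>AT vs ", x$n_at_to_gc, " AT>GC]\n",
      sep = "")
  cat("Mutation-driven equilibrium GC: ",
      format(x$equilibrium, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Pool AT-bias estimates across genealogies
#'
#' Count-weighted means of the per-genealogy biases and of the
#' per-genealogy equilibrium GC values (two separate weighted means;
#' pooling per-site fluxes first would give a slightly different
#' equilibrium).
#'
#' @param biases numeric vector of per-genealogy biases, or a list of
#'   \code{bias_estimate} objects.
#' @param weights non-negative weights, conventionally the SNM counts;
#'   taken from the estimates when a list is given and weights are
#'   omitted.
#' @return a list with \code{bias} and \code{equilibrium}.
#' @examples
#' pooled_bias(c(2.92, 5.85, 2.63), weights = c(85, 48, 53))
#' @export
pooled_bias <- function(biases, weights = NULL) {
  if (is.list(biases) && inherits(biases[[1]], "bias_estimate")) {
    if (is.null(weights))
      weights <- vapply(biases, function(b) b$n_snms, 0)
    biases <- vapply(biases, function(b) b$bias, 0)
  }
  stopifnot(length(weights) == length(biases), all(weights >= 0),
            sum(weights) > 0)
  list(bias = sum(biases * weights) / sum(weights),
       equilibrium = sum(equilibrium_gc(biases) * weights) / sum(weights))
}

#' Transition:transversion ratio of a mutation set
#'
#' @param snms SNM records with a logical \code{ts} column.
#' @return count(transitions) / count(transversions); \code{Inf} when
#'   no transversion is present.
#' @export
ts_tv <- function(snms) {
  n_ts <- sum(snms$ts); n_tv <- sum(!snms$ts)
  if (n_tv == 0) Inf else n_ts / n_tv
}

#' Detect mitotic LOH tracts in MA lines of a heterozygous founder
#'
#' Scans founder-heterozygous sites for maximal runs, within one line,
#' that have become homozygous for the same haplotype. Runs of at least
#' \code{min_markers} sites are reported as events; an event is
#' terminal when it reaches the first or last heterozygous site of its
#' chromosome, interstitial otherwise.
#'
#' @param het_sites data.frame of founder heterozygous sites
#'   (\code{chrom}, \code{pos}), sorted.
#' @param genotypes het-sites x lines dosage matrix (1 = still
#'   heterozygous, 0/2 = homozygous for one or the other haplotype,
#'   \code{NA} ignored).
#' @param min_markers minimum sites per event (default 2, suppressing
#'   single-site genotyping noise; set to 1 to keep everything).
#' @param generations generations per line; when given, the genomic
#'   event rate per generation is returned.
#' @return an object of class \code{loh_scan}: \code{$events}
#'   (\code{line}, \code{chrom}, \code{start}, \code{end} half-open,
#'   \code{kind}, \code{n_markers}, \code{haplotype}) and \code{$rate}
#'   (events per generation, or \code{NA}).
#' @export
detect_ma_loh <- function(het_sites, genotypes, min_markers = 2,
                          generations = NULL) {
  genotypes <- as.matrix(genotypes)
  stopifnot(nrow(genotypes) == nrow(het_sites))
  ev <- list()
  for (cn in unique(het_sites$chrom)) {
    rows <- which(het_sites$chrom == cn)
    pos <- het_sites$pos[rows]
    for (line in seq_len(ncol(genotypes))) {
      gv <- genotypes[rows, line]
      state <- ifelse(is.na(gv), "na", ifelse(gv == 1, "het",
                                              ifelse(gv == 0, "hom1",
                                                     "hom2")))
      r <- rle(state)
      ends <- cumsum(r$lengths); starts <- c(1, utils::head(ends, -1) + 1)
      for (k in which(r$values %in% c("hom1", "hom2") &
                        r$lengths >= min_markers)) {
        terminal <- starts[k] == 1 || ends[k] == length(pos)
        ev[[length(ev) + 1]] <- data.frame(
          line = line, chrom = cn, start = pos[starts[k]],
          end = pos[ends[k]] + 1,
          kind = if (terminal) "terminal" else "interstitial",
          n_markers = r$lengths[k],
          haplotype = if (r$values[k] == "hom1") 1L else 2L)
      }
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(line = integer(), chrom = character(), start = numeric(),
               end = numeric(), kind = character(), n_markers = integer(),
               haplotype = integer())
  rownames(events) <- NULL
  rate <- if (is.null(generations)) NA_real_ else
    loh_rate(nrow(events), ncol(genotypes), generations)
  structure(list(events = events, rate = rate), class = "loh_scan")
}

#' @export
print.loh_scan <- function(x, ...) {
  cat("LOH scan: ", nrow(x$events), " event(s)",
      if (!is.na(x$rate)) paste0("; rate ", format(x$rate, digits = 3),
                                 " per generation"), "\n", sep = "")
  if (nrow(x$events)) print.data.frame(x$events)
  invisible(x)
}

#' Genomic LOH event rate per generation
#'
#' @param n_events total LOH events across lines.
#' @param n_lines number of lines.
#' @param generations generations per line.
#' @return events per generation: \code{n_events / (n_lines *
#'   generations)}.
#' @examples
#' loh_rate(22, 11, 2016)  # ~9.9e-4
#' @export
loh_rate <- function(n_events, n_lines, generations) {
  stopifnot(n_events >= 0, n_lines > 0, generations > 0)
  n_events / (n_lines * generations)
}
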