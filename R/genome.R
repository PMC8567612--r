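#' Genome specification
#'
#' Describes the genome over which all simulations operate: chromosome
#' names and lengths, the genomic GC content, and optional repeat-mask
#' intervals that are excluded from mutation calling ("callable" sites
#' are the unmasked ones).
#'
#' Coordinates are 0-based, half-open throughout the package; conversion
#' to 1-based happens only at VCF import/export.
#'
#' @param chromosomes data.frame with columns \code{name} (character)
#'   and \code{length} (bp, > 0), one row per chromosome.
#' @param gc_content genomic GC fraction in \[0, 1\]. Defaults to 0.296,
#'   the observed GC content of the unmasked fraction of an
#'   achiasmate-yeast genome of the scale this package targets.
#' @param masked optional data.frame of repeat-mask intervals with
#'   columns \code{chrom}, \code{start}, \code{end} (0-based half-open);
#'   intervals must lie within their chromosome and not overlap.
#' @return an object of class \code{genome_spec}.
#' @examples
#' g <- genome_spec(data.frame(name = "chrI", length = 1e6))
#' callable_sites(g)
#' @export
genome_spec <- function(chromosomes, gc_content = 0.296, masked = NULL) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length") %in% names(chromosomes)))
  chromosomes$name <- as.character(chromosomes$name)
  chromosomes$length <- as.numeric(chromosomes$length)
  if (anyDuplicated(chromosomes$name))
    stop("duplicated chromosome names")
  if (any(chromosomes$length <= 0))
    stop("chromosome lengths must be > 0")
  if (!is.numeric(gc_content) || gc_content < 0 || gc_content > 1)
    stop("gc_content must be a fraction in [0, 1]")
  if (is.null(masked)) {
    masked <- data.frame(chrom = character(), start = numeric(),
                         end = numeric())
  } else {
    stopifnot(all(c("chrom", "start", "end") %in% names(masked)))
    masked <- masked[order(masked$chrom, masked$start), , drop = FALSE]
    for (cn in unique(masked$chrom)) {
      len <- chromosomes$length[match(cn, chromosomes$name)]
      if (is.na(len)) stop("masked interval on unknown chromosome: ", cn)
      m <- masked[masked$chrom == cn, , drop = FALSE]
      if (any(m$start < 0) || any(m$end > len) || any(m$end <= m$start))
        stop("masked interval out of bounds on ", cn)
      if (nrow(m) > 1 && any(m$start[-1] < m$end[-nrow(m)]))
        stop("masked intervals overlap on ", cn)
    }
  }
  g <- list(chromosomes = chromosomes, gc_content = gc_content,
            masked = masked)
  class(g) <- "genome_spec"
  if (callable_sites(g) <= 0) stop("no callable sites left after masking")
  g
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("Genome: ", nrow(x$chromosomes), " chromosome(s), ",
      format(sum(x$chromosomes$length), big.mark = ","), " bp, GC ",
      x$gc_content, "\n", sep = "")
  cat("Masked: ", nrow(x$masked), " interval(s); callable sites: ",
      format(callable_sites(x), big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' Number of callable (unmasked) sites in a genome
#'
#' @param genome a \code{\link{genome_spec}}.
#' @return total chromosome length minus total masked length.
#' @export
callable_sites <- function(genome) {
  stopifnot(inherits(genome, "genome_spec"))
  sum(genome$chromosomes$length) -
    sum(genome$masked$end - genome$masked$start)
}

#' Counts of callable GC and AT bases implied by a genome's composition
#'
#' @param genome a \code{\link{genome_spec}}.
#' @return named numeric vector with elements \code{n_gc} and \code{n_at}.
#' @export
base_composition <- function(genome) {
  n <- callable_sites(genome)
  c(n_gc = n * genome$gc_content, n_at = n * (1 - genome$gc_content))
}

#' Divergence profile between two parental haplotypes
#'
#' Per-chromosome compartments, each with its own per-site divergence
#' rate. Real hybrid yeast genomes are compartmentalised: some
#' chromosomes (or chromosome arms) diverge at a few percent per site
#' while the rest of the genome is nearly identical; the profile lets a
#' simulated cross reproduce that heterogeneity.
#'
#' @param compartments data.frame with columns \code{chrom},
#'   \code{start}, \code{end} (0-based half-open) and \code{rate}
#'   (per-site divergence in \[0, 1\]). The compartments must tile every
#'   chromosome of \code{genome} exactly, without gaps or overlaps.
#' @param genome the \code{\link{genome_spec}} the profile applies to.
#' @return an object of class \code{divergence_profile}.
#' @export
divergence_profile <- function(compartments, genome) {
  stopifnot(inherits(genome, "genome_spec"),
            all(c("chrom", "start", "end", "rate") %in% names(compartments)))
  if (any(compartments$rate < 0 | compartments$rate > 1))
    stop("divergence rates must be in [0, 1]")
  compartments <- compartments[order(compartments$chrom, compartments$start),
                               , drop = FALSE]
  for (i in seq_len(nrow(genome$chromosomes))) {
    cn <- genome$chromosomes$name[i]
    len <- genome$chromosomes$length[i]
    m <- compartments[compartments$chrom == cn, , drop = FALSE]
    if (nrow(m) == 0) stop("chromosome not tiled: ", cn)
    ok <- m$start[1] == 0 && m$end[nrow(m)] == len &&
      (nrow(m) == 1 || all(m$start[-1] == m$end[-nrow(m)]))
    if (!ok) stop("compartments do not tile chromosome ", cn)
  }
  if (!all(compartments$chrom %in% genome$chromosomes$name))
    stop("compartment on unknown chromosome")
  p <- list(compartments = compartments)
  class(p) <- "divergence_profile"
  p
}

#' Uniform divergence profile covering a whole genome at one rate
#'
#' @param genome a \code{\link{genome_spec}}.
#' @param rate per-site divergence rate.
#' @return a \code{\link{divergence_profile}} with one compartment per
#'   chromosome.
#' @export
uniform_profile <- function(genome, rate) {
  divergence_profile(
    data.frame(chrom = genome$chromosomes$name, start = 0,
               end = genome$chromosomes$length, rate = rate),
    genome)
}

# TRUE for positions falling inside any masked interval of their chromosome
in_mask <- function(genome, chrom, pos) {
  m <- genome$masked[genome$masked$chrom == chrom, , drop = FALSE]
  if (nrow(m) == 0) return(rep(FALSE, length(pos)))
  hit <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(m))) hit <- hit | (pos >= m$start[i] & pos < m$end[i])
  hit
}
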