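#' Simulate a pair of divergent parental haplotypes
#'
#' Draws the discriminant-SNP universe of a hybrid cross. Within each
#' compartment of the divergence profile, the number of SNPs is
#' Binomial(compartment length, rate) and positions are sampled
#' uniformly without replacement; by default SNPs are kept out of
#' masked (repeat) intervals, mirroring how real marker sets are called
#' against repeat-masked references. Each SNP stores the two distinct
#' parental alleles.
#'
#' @param genome a \code{\link{genome_spec}}.
#' @param profile a \code{\link{divergence_profile}} tiling \code{genome}.
#' @param allow_masked if \code{TRUE}, SNPs may fall inside masked
#'   intervals (default \code{FALSE}).
#' @param seed integer seed for the simulation's random stream, or
#'   \code{NULL} to use the current stream.
#' @return an object of class \code{parental_pair}: the genome plus a
#'   sorted SNP table (\code{chrom}, \code{pos} 0-based, \code{a1},
#'   \code{a2}).
#' @examples
#' g <- genome_spec(data.frame(name = "chrI", length = 2e5))
#' pp <- simulate_parent_pair(g, uniform_profile(g, 0.02), seed = 1)
#' nrow(pp$snps)
#' @export
simulate_parent_pair <- function(genome, profile, allow_masked = FALSE,
                                 seed = NULL) {
  stopifnot(inherits(genome, "genome_spec"),
            inherits(profile, "divergence_profile"))
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  # base weights from genomic composition for the "reference" allele
  wt <- c(A = (1 - genome$gc_content) / 2, C = genome$gc_content / 2,
          G = genome$gc_content / 2, T = (1 - genome$gc_content) / 2)
  out <- list()
  comp <- profile$compartments
  for (i in seq_len(nrow(comp))) {
    len <- comp$end[i] - comp$start[i]
    n <- stats::rbinom(1, size = len, prob = comp$rate[i])
    if (n == 0) next
    pos <- comp$start[i] + sample.int(len, n) - 1
    if (!allow_masked) pos <- pos[!in_mask(genome, comp$chrom[i], pos)]
    if (length(pos) == 0) next
    a1 <- sample(bases, length(pos), replace = TRUE, prob = wt)
    a2 <- vapply(a1, function(b) sample(setdiff(bases, b), 1), "")
    out[[length(out) + 1]] <- data.frame(chrom = comp$chrom[i], pos = pos,
                                         a1 = a1, a2 = unname(a2))
  }
  snps <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), pos = numeric(),
               a1 = character(), a2 = character())
  snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
  rownames(snps) <- NULL
  pp <- list(genome = genome, snps = snps)
  class(pp) <- "parental_pair"
  pp
}

#' @export
print.parental_pair <- function(x, ...) {
  cat("Parental pair: ", nrow(x$snps), " discriminant SNPs over ",
      nrow(x$genome$chromosomes), " chromosome(s)\n", sep = "")
  invisible(x)
}
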