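#' Select high-confidence discriminant markers between two parents
#'
#' Filters a two-parent call set down to the marker universe used for
#' segregation analysis. A site is retained when it has exactly one
#' alternate allele, total depth of at least \code{min_depth} in each
#' parent, strictly more than \code{purity} of each parent's reads
#' supporting a single allele (reference or alternate), and the two
#' parents' majority alleles differ (discriminant). For low-coverage
#' crosses the same filter is conventionally re-run with
#' \code{min_depth = 3}.
#'
#' @param calls a \code{\link{site_calls}} with exactly two samples
#'   (the parents, in order).
#' @param min_depth minimum total reads per parent (inclusive;
#'   default 10).
#' @param purity strict lower bound on the majority-allele read
#'   fraction in each parent (default 0.9).
#' @return an object of class \code{marker_table}: a sorted data.frame
#'   (\code{chrom}, \code{pos} 0-based, \code{a1}, \code{a2}) with the
#'   thresholds recorded in attributes. An empty table (with a message)
#'   if nothing survives.
#' @examples
#' g <- genome_spec(data.frame(name = "chrI", length = 1e5))
#' pp <- simulate_parent_pair(g, uniform_profile(g, 0.01), seed = 1)
#' mt <- select_markers(parent_calls(pp, mean_depth = 40, seed = 2))
#' nrow(mt) == nrow(pp$snps)
#' @export
select_markers <- function(calls, min_depth = 10, purity = 0.9) {
  stopifnot(inherits(calls, "site_calls"))
  if (n_samples(calls) != 2)
    stop("marker selection needs exactly two parent samples, got ",
         n_samples(calls))
  single_alt <- !grepl(",", calls$sites$alt) & nzchar(calls$sites$alt)
  tot <- calls$ref_depth + calls$alt_depth
  depth_ok <- tot[, 1] >= min_depth & tot[, 2] >= min_depth
  maj <- pmax(calls$ref_depth, calls$alt_depth)
  pur_ok <- tot[, 1] > 0 & tot[, 2] > 0 &
    maj[, 1] / pmax(tot[, 1], 1) > purity &
    maj[, 2] / pmax(tot[, 2], 1) > purity
  allele_of <- function(j) ifelse(calls$alt_depth[, j] > calls$ref_depth[, j],
                                  calls$sites$alt, calls$sites$ref)
  a1 <- allele_of(1); a2 <- allele_of(2)
  keep <- single_alt & depth_ok & pur_ok & a1 != a2
  keep[is.na(keep)] <- FALSE
  mt <- data.frame(chrom = calls$sites$chrom[keep],
                   pos = calls$sites$pos[keep],
                   a1 = a1[keep], a2 = a2[keep])
  mt <- mt[order(mt$chrom, mt$pos), , drop = FALSE]
  rownames(mt) <- NULL
  if (nrow(mt) == 0)
    message("no sites survived marker filtering")
  structure(mt, class = c("marker_table", "data.frame"),
            min_depth = min_depth, purity = purity)
}

#' @export
print.marker_table <- function(x, ...) {
  cat("Marker table: ", nrow(x), " discriminant markers",
      " (min_depth = ", attr(x, "min_depth"),
      ", purity > ", attr(x, "purity"), ")\n", sep = "")
  if (nrow(x)) print.data.frame(utils::head(x, 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Write / read a marker table as TSV
#'
#' @param markers a \code{\link{marker_table}}.
#' @param file path.
#' @return \code{file} invisibly (writer); a \code{marker_table}
#'   (reader).
#' @export
write_markers <- function(markers, file) {
  utils::write.table(as.data.frame(markers), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_markers
#' @export
read_markers <- function(file) {
  mt <- utils::read.table(file, header = TRUE, sep = "\t",
                          colClasses = c("character", "numeric",
                                         "character", "character"))
  structure(mt, class = c("marker_table", "data.frame"),
            min_depth = NA, purity = NA)
}
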