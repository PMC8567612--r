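#' Per-sample variant calls at a set of sites
#'
#' The package's in-memory representation of a multi-sample variant
#' table: site metadata plus per-sample alternate-allele dosage and
#' read depths. Positions are 0-based internally (converted to 1-based
#' on VCF export/import).
#'
#' @param sites data.frame with columns \code{chrom}, \code{pos}
#'   (0-based), \code{ref}, \code{alt} (comma-separated if multiple
#'   alternates).
#' @param genotype sites x samples matrix of alternate-allele dosages
#'   (0, 1, 2, \code{NA}); column names are sample names.
#' @param ref_depth,alt_depth matrices of reference / alternate read
#'   counts, same shape as \code{genotype}.
#' @return an object of class \code{site_calls}.
#' @export
site_calls <- function(sites, genotype, ref_depth, alt_depth) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  genotype <- as.matrix(genotype)
  ref_depth <- as.matrix(ref_depth); alt_depth <- as.matrix(alt_depth)
  stopifnot(nrow(genotype) == nrow(sites),
            all(dim(ref_depth) == dim(genotype)),
            all(dim(alt_depth) == dim(genotype)),
            !is.null(colnames(genotype)))
  if (any(ref_depth < 0, na.rm = TRUE) || any(alt_depth < 0, na.rm = TRUE))
    stop("read depths must be >= 0")
  o <- order(sites$chrom, sites$pos)
  x <- list(sites = sites[o, , drop = FALSE],
            genotype = genotype[o, , drop = FALSE],
            ref_depth = ref_depth[o, , drop = FALSE],
            alt_depth = alt_depth[o, , drop = FALSE])
  rownames(x$sites) <- NULL
  class(x) <- "site_calls"
  x
}

#' @export
print.site_calls <- function(x, ...) {
  cat("Site calls: ", nrow(x$sites), " sites x ", ncol(x$genotype),
      " samples (", paste(colnames(x$genotype), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

n_samples <- function(calls) ncol(calls$genotype)

#' Build parent variant calls from a simulated parental pair
#'
#' Encodes the cross's SNP table as a two-sample call set (parent 1
#' homozygous reference, parent 2 homozygous alternate) with simulated
#' read depths, the input expected by \code{\link{select_markers}}.
#'
#' @param pair a \code{\link{parental_pair}}.
#' @param mean_depth,error_rate,seed passed to
#'   \code{\link{simulate_depths}}.
#' @param samples character vector of the two sample names.
#' @return a \code{\link{site_calls}} object.
#' @export
parent_calls <- function(pair, mean_depth = 30, error_rate = 0,
                         seed = NULL, samples = c("P1", "P2")) {
  stopifnot(inherits(pair, "parental_pair"), length(samples) == 2)
  sites <- data.frame(chrom = pair$snps$chrom, pos = pair$snps$pos,
                      ref = pair$snps$a1, alt = pair$snps$a2)
  g <- matrix(c(rep(0, nrow(sites)), rep(2, nrow(sites))), ncol = 2,
              dimnames = list(NULL, samples))
  d <- simulate_depths(g, mean_depth, error_rate, seed)
  site_calls(sites, g, d$ref_depth, d$alt_depth)
}

#' Build four-spore variant calls from a simulated tetrad
#'
#' @param truth a \code{\link{simulate_tetrad}} result.
#' @param mean_depth,error_rate,seed passed to
#'   \code{\link{simulate_depths}}.
#' @param missing_rate fraction of spore genotypes dropped at random
#'   (no-calls), to exercise missing-data handling.
#' @return a \code{\link{site_calls}} object with samples
#'   \code{spore1..spore4}.
#' @export
spore_calls <- function(truth, mean_depth = 30, error_rate = 0,
                        missing_rate = 0, seed = NULL) {
  stopifnot(inherits(truth, "tetrad_truth"))
  if (!is.null(seed)) set.seed(seed)
  snps <- truth$snps
  g <- matrix(NA_real_, nrow = nrow(snps), ncol = 4,
              dimnames = list(NULL, paste0("spore", 1:4)))
  for (cn in names(truth$origins)) {
    rows <- which(snps$chrom == cn)
    g[rows, ] <- t(ifelse(truth$origins[[cn]] == "P2", 2, 0))
  }
  if (missing_rate > 0)
    g[stats::runif(length(g)) < missing_rate] <- NA
  sites <- data.frame(chrom = snps$chrom, pos = snps$pos,
                      ref = snps$a1, alt = snps$a2)
  d <- simulate_depths(g, mean_depth, error_rate)
  site_calls(sites, g, d$ref_depth, d$alt_depth)
}

#' Build multi-line variant calls from a simulated MA genealogy
#'
#' Assembles the joint call table of all lines of a genealogy over the
#' union of founder heterozygous sites (heterozygous founders) and true
#' mutation sites, with simulated depths; the founder's dosages are
#' returned alongside, as \code{\link{filter_snms}} needs the
#' background genotype at every site.
#'
#' @param ma a \code{\link{simulate_ma_genealogy}} result.
#' @param mean_depth,error_rate,seed passed to
#'   \code{\link{simulate_depths}}.
#' @return list with elements \code{calls} (a \code{\link{site_calls}}
#'   with one sample per line, named \code{line1..lineN}) and
#'   \code{founder} (founder dosage vector aligned to the call sites).
#' @export
line_calls <- function(ma, mean_depth = 30, error_rate = 0, seed = NULL) {
  stopifnot(inherits(ma, "ma_genealogy"))
  if (!is.null(seed)) set.seed(seed)
  nl <- ma$params$n_lines
  het <- !is.null(ma$het_map)
  sites <- data.frame(chrom = character(), pos = numeric(),
                      ref = character(), alt = character())
  founder <- numeric(0)
  if (het) {
    sites <- data.frame(chrom = ma$het_map$chrom, pos = ma$het_map$pos,
                        ref = ma$het_map$a1, alt = ma$het_map$a2)
    founder <- rep(1, nrow(sites))
  }
  mut <- ma$snms
  if (nrow(mut)) {
    key <- paste(sites$chrom, sites$pos)
    new <- !(paste(mut$chrom, mut$pos) %in% key)
    mut <- mut[new, , drop = FALSE]          # rare collisions dropped
    sites <- rbind(sites, data.frame(chrom = mut$chrom, pos = mut$pos,
                                     ref = mut$ref, alt = mut$alt))
    founder <- c(founder, rep(0, nrow(mut)))
  }
  g <- matrix(rep(founder, nl), ncol = nl,
              dimnames = list(NULL, paste0("line", seq_len(nl))))
  key <- paste(sites$chrom, sites$pos)
  if (nrow(mut)) {
    idx <- match(paste(mut$chrom, mut$pos), key)
    g[cbind(idx, mut$line)] <-
      ifelse(mut$zygosity_change == "hom>hom", 2, 1)
  }
  if (het && nrow(ma$loh)) {
    for (i in seq_len(nrow(ma$loh))) {
      tr <- ma$loh[i, ]
      hit <- which(sites$chrom == tr$chrom & sites$pos >= tr$start &
                     sites$pos < tr$end & founder == 1)
      if (length(hit))
        g[hit, tr$line] <- if (tr$haplotype == 1) 0 else 2
    }
  }
  o <- order(sites$chrom, sites$pos)
  d <- simulate_depths(g, mean_depth, error_rate)
  list(calls = site_calls(sites, g, d$ref_depth, d$alt_depth)[],
       founder = founder[o])
}

# ---- VCF import/export (vcfR-backed) --------------------------------

#' Write a call set to VCF
#'
#' Exports a \code{\link{site_calls}} object as a multi-sample VCF with
#' GT and AD fields (positions converted to 1-based). Files ending in
#' \code{.gz} are written gzip-compressed.
#'
#' @param calls a \code{\link{site_calls}}.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
write_calls_vcf <- function(calls, file) {
  stopifnot(inherits(calls, "site_calls"))
  gt_code <- function(d) {
    ifelse(is.na(d), "./.", c("0/0", "0/1", "1/1")[d + 1])
  }
  body <- matrix("", nrow = nrow(calls$sites), ncol = n_samples(calls))
  for (j in seq_len(n_samples(calls)))
    body[, j] <- paste0(gt_code(calls$genotype[, j]), ":",
                        calls$ref_depth[, j], ",", calls$alt_depth[, j])
  fix <- cbind(CHROM = calls$sites$chrom,
               POS = format(calls$sites$pos + 1, scientific = FALSE,
                            trim = TRUE),
               ID = ".", REF = calls$sites$ref, ALT = calls$sites$alt,
               QUAL = ".", FILTER = "PASS", INFO = ".")
  header <- c("##fileformat=VCFv4.2",
              "##source=achiasma",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", "FORMAT",
                      colnames(calls$genotype)), collapse = "\t"))
  rows <- apply(cbind(fix, FORMAT = "GT:AD", body), 1, paste,
                collapse = "\t")
  con <- if (grepl("\\.gz$", file)) gzfile(file, "w") else file(file, "w")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(file)
}

#' Read a multi-sample VCF into a call set
#'
#' Parses a VCF (via \pkg{vcfR}) carrying GT and AD per sample into the
#' package's \code{\link{site_calls}} representation. Genotypes are
#' recoded as alternate-allele dosage; calls involving alleles beyond
#' the first alternate keep their dosage with respect to allele 1.
#'
#' @param file VCF path (optionally gzipped).
#' @param samples optional character vector restricting/ordering the
#'   samples.
#' @return a \code{\link{site_calls}} object.
#' @export
read_calls_vcf <- function(file, samples = NULL) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ad <- vcfR::extract.gt(v, element = "AD")
  if (!is.null(samples)) {
    gt <- gt[, samples, drop = FALSE]
    ad <- ad[, samples, drop = FALSE]
  }
  dos <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt),
                dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean %in% c("0/0", "0")] <- 0
  dos[clean %in% c("0/1", "1/0")] <- 1
  dos[clean %in% c("1/1", "1")] <- 2
  ref_d <- alt_d <- matrix(0L, nrow = nrow(gt), ncol = ncol(gt),
                           dimnames = dimnames(gt))
  split_ad <- function(x, k) {
    out <- suppressWarnings(
      as.integer(vapply(strsplit(ifelse(is.na(x), "0,0", x), ","),
                        function(p) if (length(p) >= k) p[k] else "0", "")))
    out[is.na(out)] <- 0L
    out
  }
  for (j in seq_len(ncol(ad))) {
    ref_d[, j] <- split_ad(ad[, j], 1L)
    alt_d[, j] <- split_ad(ad[, j], 2L)
  }
  sites <- data.frame(chrom = as.character(v@fix[, "CHROM"]),
                      pos = as.numeric(v@fix[, "POS"]) - 1,
                      ref = as.character(v@fix[, "REF"]),
                      alt = as.character(v@fix[, "ALT"]))
  site_calls(sites, dos, ref_d, alt_d)
}

#' Write recombination or LOH events as a BED-like table
#'
#' Columns: chrom, maximum-tract start and end (0-based half-open),
#' kind, spores, marker count, inner-interval start and end.
#'
#' @param events a data.frame of events as returned by
#'   \code{\link{call_events}}.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
write_events_bed <- function(events, file) {
  out <- data.frame(chrom = events$chrom,
                    start = events$tract_start, end = events$tract_end,
                    name = events$kind, spores = events$spores,
                    markerCount = events$n_markers,
                    innerStart = events$inner_start,
                    innerEnd = events$inner_end)
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(file)
}

# keep site_calls subsettable by site index
#' @export
`[.site_calls` <- function(x, i, ...) {
  if (missing(i)) return(x)
  site_calls(x$sites[i, , drop = FALSE],
             x$genotype[i, , drop = FALSE],
             x$ref_depth[i, , drop = FALSE],
             x$alt_depth[i, , drop = FALSE])
}
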