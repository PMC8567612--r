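#' Pairwise linkage disequilibrium r-squared between two sites
#'
#' The genotype-based estimator: squared Pearson correlation of the
#' alternate-allele dosage vectors across strains, over strains called
#' at both sites. Undefined (NA) when either site is monomorphic among
#' the shared strains.
#'
#' @param ga,gb dosage vectors of equal length.
#' @return r-squared in \[0, 1\], or \code{NA}.
#' @examples
#' pair_r2(c(0, 0, 2, 2), c(2, 2, 0, 0))  # complete (negative) LD: 1
#' @export
pair_r2 <- function(ga, gb) {
  if (length(ga) != length(gb)) stop("genotype vectors differ in length")
  ok <- !is.na(ga) & !is.na(gb)
  if (sum(ok) < 2) return(NA_real_)
  a <- ga[ok]; b <- gb[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' Linkage-disequilibrium decay curve
#'
#' Scores all intra-chromosome site pairs up to \code{max_dist} apart,
#' averages r-squared at each exact pair distance, and smooths the
#' resulting series along the distance axis with a centred moving
#' average of \code{window} distance points. Monomorphic or undefined
#' pairs are skipped.
#'
#' @param gm a \code{\link{genotype_matrix}} with sites sorted by
#'   position.
#' @param max_dist maximum pair distance in bp (default 300000).
#' @param window moving-average window in distance points (default 50).
#' @return an object of class \code{ld_curve}: data.frame
#'   (\code{distance}, \code{mean_r2}, \code{n_pairs},
#'   \code{smoothed_r2}) with the parameters in attributes; empty (with
#'   a message) if no pair qualifies.
#' @export
decay_curve <- function(gm, max_dist = 300000, window = 50) {
  stopifnot(inherits(gm, "genotype_matrix"), max_dist > 0, window >= 1)
  all_d <- list(); all_r <- list()
  for (cn in unique(gm$sites$chrom)) {
    cols <- which(gm$sites$chrom == cn)
    pos <- gm$sites$pos[cols]
    o <- order(pos); cols <- cols[o]; pos <- pos[o]
    ns <- length(cols)
    for (i in seq_len(max(ns - 1, 0))) {
      jmax <- findInterval(pos[i] + max_dist, pos)
      if (jmax <= i) next
      js <- (i + 1):jmax
      # columnwise squared Pearson correlation == pair_r2 per pair
      r2 <- suppressWarnings(as.vector(
        stats::cor(gm$geno[, cols[i]], gm$geno[, cols[js], drop = FALSE],
                   use = "pairwise.complete.obs")))^2
      ok <- !is.na(r2)
      if (any(ok)) {
        all_d[[length(all_d) + 1]] <- pos[js][ok] - pos[i]
        all_r[[length(all_r) + 1]] <- r2[ok]
      }
    }
  }
  dd <- unlist(all_d); rr <- unlist(all_r)
  if (length(dd)) {
    acc_s <- rowsum(rr, dd)
    acc_n <- as.integer(rowsum(rep(1, length(dd)), dd))
    acc_d <- as.numeric(rownames(acc_s))
    acc_s <- as.vector(acc_s)
  } else acc_d <- numeric(0)
  if (length(acc_d) == 0) {
    message("no qualifying site pairs; empty LD curve")
    out <- data.frame(distance = numeric(), mean_r2 = numeric(),
                      n_pairs = integer(), smoothed_r2 = numeric())
    return(structure(out, class = c("ld_curve", "data.frame"),
                     max_dist = max_dist, window = window))
  }
  o <- order(acc_d)
  out <- data.frame(distance = acc_d[o], mean_r2 = (acc_s / acc_n)[o],
                    n_pairs = acc_n[o])
  out$smoothed_r2 <- moving_average(out$mean_r2, window)
  structure(out, class = c("ld_curve", "data.frame"),
            max_dist = max_dist, window = window)
}

# centred moving average with shrinking windows at the edges
moving_average <- function(x, window) {
  n <- length(x)
  half <- floor(window / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' @export
print.ld_curve <- function(x, ...) {
  cat("LD decay curve: ", nrow(x), " distance points, ",
      sum(x$n_pairs), " site pairs (max distance ", attr(x, "max_dist"),
      " bp, window ", attr(x, "window"), ")\n", sep = "")
  invisible(x)
}

#' @export
plot.ld_curve <- function(x, ...) {
  plot(x$distance, x$mean_r2, pch = 16, cex = 0.4, col = "grey70",
       xlab = "distance (bp)", ylab = expression(r^2), ylim = c(0, 1),
       ...)
  graphics::lines(x$distance, x$smoothed_r2, col = "firebrick", lwd = 2)
  invisible(x)
}
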