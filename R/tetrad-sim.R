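#' Meiosis simulation parameters
#'
#' @param co_rate expected crossovers per chromosome per meiosis (>= 0).
#'   The achiasmate limit is \code{co_rate = 0}.
#' @param nco_rate expected non-crossover (gene-conversion) initiations
#'   per chromosome per meiosis (>= 0).
#' @param tract_length gene-conversion tract-length model: a list with
#'   \code{family} one of \code{"uniform"} (fields \code{min},
#'   \code{max}) or \code{"fixed"} (field \code{length}), in bp. The
#'   default, uniform on 1000-2000 bp, matches the typical 1-2 kb
#'   conversion tracts of budding yeasts.
#' @param obligate_co if \code{TRUE}, meioses with zero crossovers on a
#'   chromosome are rejected and redrawn (obligate-chiasma regime).
#' @return an object of class \code{meiosis_params}.
#' @export
meiosis_params <- function(co_rate = 0, nco_rate = 0,
                           tract_length = list(family = "uniform",
                                               min = 1000, max = 2000),
                           obligate_co = FALSE) {
  stopifnot(co_rate >= 0, nco_rate >= 0)
  fam <- match.arg(tract_length$family, c("uniform", "fixed"))
  if (fam == "uniform") {
    stopifnot(tract_length$min >= 1, tract_length$max >= tract_length$min)
  } else {
    stopifnot(tract_length$length >= 1)
  }
  if (obligate_co && co_rate == 0)
    stop("obligate_co requires co_rate > 0")
  p <- list(co_rate = co_rate, nco_rate = nco_rate,
            tract_length = tract_length, obligate_co = obligate_co)
  class(p) <- "meiosis_params"
  p
}

draw_tract_length <- function(spec, n = 1) {
  switch(spec$family,
         uniform = stats::runif(n, spec$min, spec$max),
         fixed = rep(spec$length, n))
}

#' Simulate one meiosis of a hybrid diploid into a four-spore tetrad
#'
#' Models one meiosis over the marker universe of a parental pair: each
#' homolog is replicated into two chromatids, Poisson(\code{co_rate})
#' crossover breakpoints per chromosome reciprocally exchange the
#' distal segments of one chromatid of each homolog, and
#' Poisson(\code{nco_rate}) gene-conversion tracts unidirectionally
#' overwrite a tract on one chromatid with the homologous sequence.
#' Chromatids then segregate 2+2: meiosis I separates the homolog
#' centromeres into two cells (independent assortment across
#' chromosomes), meiosis II splits sister chromatids, so spores 1 and 2
#' always descend from one meiosis-I cell and spores 3 and 4 from the
#' other.
#'
#' Crossover breakpoints are continuous positions between markers and
#' are reported as the flanking-marker interval; every generated event
#' is recorded with exact coordinates in \code{$events} as ground truth.
#'
#' @param pair a \code{\link{parental_pair}}.
#' @param params a \code{\link{meiosis_params}}.
#' @param seed integer seed, or \code{NULL}.
#' @return an object of class \code{tetrad_truth}: \code{$origins} is a
#'   list (per chromosome) of 4 x markers character matrices with
#'   entries \code{"P1"}/\code{"P2"} (rows = spores), \code{$events} a
#'   data.frame of true events (kind, breakpoints, tract, spores,
#'   supporting marker count and inner marker interval), and
#'   \code{$snps} the marker table of the pair.
#' @examples
#' g <- genome_spec(data.frame(name = "chrI", length = 1e5))
#' pp <- simulate_parent_pair(g, uniform_profile(g, 0.01), seed = 1)
#' tt <- simulate_tetrad(pp, meiosis_params(co_rate = 0), seed = 2)
#' nrow(tt$events)  # achiasmate: no events
#' @export
simulate_tetrad <- function(pair, params, seed = NULL) {
  stopifnot(inherits(pair, "parental_pair"),
            inherits(params, "meiosis_params"))
  if (!is.null(seed)) set.seed(seed)
  chroms <- pair$genome$chromosomes
  origins <- list()
  events <- list()
  for (ci in seq_len(nrow(chroms))) {
    cn <- chroms$name[ci]
    L <- chroms$length[ci]
    pos <- pair$snps$pos[pair$snps$chrom == cn]
    nm <- length(pos)
    # chromatids 1,2 carry the P1 homolog; 3,4 the P2 homolog
    O <- matrix(rep(c("P1", "P1", "P2", "P2"), each = nm),
                nrow = 4, byrow = TRUE)
    ev <- list()

    n_co <- stats::rpois(1, params$co_rate)
    if (params$obligate_co) while (n_co == 0) n_co <- stats::rpois(1, params$co_rate)
    if (n_co > 0) {
      xs <- sort(stats::runif(n_co, 0, L))
      for (x in xs) {
        a <- sample(1:2, 1)
        b <- sample(3:4, 1)
        right <- which(pos > x)
        if (length(right) && length(right) < nm) {
          # a swap between chromatids already carrying identical labels
          # distal to x (a two-strand double-CO configuration) changes
          # no marker and is unobservable in parental-origin space
          visible <- any(O[a, right] != O[b, right])
          tmp <- O[a, right]; O[a, right] <- O[b, right]; O[b, right] <- tmp
          i_left <- max(which(pos <= x))
          ev[[length(ev) + 1]] <- data.frame(
            chrom = cn, kind = "CO", breakpoint = x,
            tract_start = x, tract_end = x,
            chromatids = paste(a, b, sep = ","),
            inner_start = pos[i_left], inner_end = pos[i_left + 1],
            n_markers = 0, visible = visible)
        }
        # a breakpoint distal to all markers (or proximal to all) is
        # invisible to the marker universe and is not recorded
      }
    }

    n_nco <- stats::rpois(1, params$nco_rate)
    if (n_nco > 0) {
      for (k in seq_len(n_nco)) {
        len <- draw_tract_length(params$tract_length)
        x <- stats::runif(1, 0, L)
        tract <- c(x, min(x + len, L))
        recip <- sample(1:4, 1)
        donor <- if (recip <= 2) sample(3:4, 1) else sample(1:2, 1)
        idx <- which(pos >= tract[1] & pos < tract[2])
        changed <- idx[O[recip, idx] != O[donor, idx]]
        if (length(changed)) O[recip, changed] <- O[donor, changed]
        ev[[length(ev) + 1]] <- data.frame(
          chrom = cn, kind = "NCO", breakpoint = x,
          tract_start = tract[1], tract_end = tract[2],
          chromatids = as.character(recip),
          inner_start = if (length(changed)) pos[min(changed)] else NA_real_,
          inner_end = if (length(changed)) pos[max(changed)] else NA_real_,
          n_markers = length(changed), visible = length(changed) > 0)
      }
    }

    # meiosis I: homolog centromeres to the two cells; meiosis II: sisters
    # split. Spores 1,2 = cell one; 3,4 = cell two.
    cell_of_p1 <- sample(c(1L, 2L), 1)
    spore_sets <- if (cell_of_p1 == 1L) list(1:2, 3:4) else list(3:4, 1:2)
    sp <- integer(4)
    sp[1:2] <- sample(spore_sets[[1]])   # chromatids 1,2 -> spores
    sp[3:4] <- sample(spore_sets[[2]])   # chromatids 3,4 -> spores
    S <- matrix(NA_character_, nrow = 4, ncol = nm)
    S[sp, ] <- O
    rownames(S) <- paste0("spore", 1:4)
    origins[[cn]] <- S

    if (length(ev)) {
      ev <- do.call(rbind, ev)
      ev$spores <- vapply(strsplit(ev$chromatids, ","), function(ch)
        paste(sort(sp[as.integer(ch)]), collapse = ","), "")
      events[[length(events) + 1]] <- ev
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(chrom = character(), kind = character(),
               breakpoint = numeric(), tract_start = numeric(),
               tract_end = numeric(), chromatids = character(),
               inner_start = numeric(), inner_end = numeric(),
               n_markers = integer(), visible = logical(),
               spores = character())
  rownames(events) <- NULL
  tt <- list(origins = origins, events = events, snps = pair$snps,
             genome = pair$genome)
  class(tt) <- "tetrad_truth"
  tt
}

#' @export
print.tetrad_truth <- function(x, ...) {
  cat("Simulated tetrad: ", nrow(x$snps), " markers, ",
      sum(x$events$kind == "CO"), " CO / ",
      sum(x$events$kind == "NCO"), " NCO true events\n", sep = "")
  invisible(x)
}

#' Ground-truth origin matrix of a simulated tetrad
#'
#' Bypasses genotyping: converts a \code{\link{simulate_tetrad}}
#' result directly into the error-free \code{\link{origin_matrix}}
#' that a perfect variant-calling pipeline would produce.
#'
#' @param truth a \code{\link{simulate_tetrad}} result.
#' @return an \code{\link{origin_matrix}}.
#' @export
truth_origin_matrix <- function(truth) {
  stopifnot(inherits(truth, "tetrad_truth"))
  O <- matrix(NA_character_, nrow = nrow(truth$snps), ncol = 4,
              dimnames = list(NULL, paste0("spore", 1:4)))
  for (cn in names(truth$origins)) {
    rows <- which(truth$snps$chrom == cn)
    O[rows, ] <- t(truth$origins[[cn]])
  }
  origin_matrix(truth$snps, O)
}

#' Fuse two spores of a tetrad into a diploid (intratetrad mating)
#'
#' Non-sister mating pairs spores that were separated at meiosis I
#' (here: one of spores 1-2 with one of spores 3-4); sister mating
#' pairs spores from the same meiosis-I cell. In the achiasmate limit,
#' non-sister fusion restores heterozygosity at every marker, while
#' sister fusion yields complete homozygosity; crossovers erode the
#' former.
#'
#' @param truth a \code{\link{simulate_tetrad}} result.
#' @param mode \code{"non-sister"} or \code{"sister"}.
#' @param spores optional integer pair overriding the default choice
#'   (spores 1 and 3 for non-sister, 1 and 2 for sister); must respect
#'   \code{mode}.
#' @return data.frame with one row per marker: \code{chrom},
#'   \code{pos}, origins \code{o1}, \code{o2} of the two gametes and
#'   logical \code{het}.
#' @export
intratetrad_mate <- function(truth, mode = c("non-sister", "sister"),
                             spores = NULL) {
  stopifnot(inherits(truth, "tetrad_truth"))
  mode <- match.arg(mode)
  if (is.null(spores)) spores <- if (mode == "non-sister") c(1L, 3L) else c(1L, 2L)
  same_cell <- (all(spores <= 2) || all(spores >= 3))
  if (mode == "non-sister" && same_cell)
    stop("spores ", paste(spores, collapse = ","), " are meiosis-I sisters")
  if (mode == "sister" && !same_cell)
    stop("spores ", paste(spores, collapse = ","), " are not meiosis-I sisters")
  out <- lapply(names(truth$origins), function(cn) {
    S <- truth$origins[[cn]]
    pos <- truth$snps$pos[truth$snps$chrom == cn]
    data.frame(chrom = cn, pos = pos,
               o1 = S[spores[1], ], o2 = S[spores[2], ],
               het = S[spores[1], ] != S[spores[2], ])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
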