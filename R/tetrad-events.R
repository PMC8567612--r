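#' Parental-origin matrix of a tetrad
#'
#' @param markers data.frame with at least \code{chrom} and \code{pos}
#'   (a \code{\link{marker_table}} works).
#' @param origin markers x 4 character matrix with entries \code{"P1"},
#'   \code{"P2"} or \code{NA} (missing).
#' @return an object of class \code{origin_matrix}.
#' @export
origin_matrix <- function(markers, origin) {
  origin <- as.matrix(origin)
  stopifnot(nrow(origin) == nrow(markers), ncol(origin) == 4,
            all(origin %in% c("P1", "P2") | is.na(origin)))
  if (is.null(colnames(origin))) colnames(origin) <- paste0("spore", 1:4)
  o <- order(markers$chrom, markers$pos)
  x <- list(markers = data.frame(chrom = markers$chrom[o],
                                 pos = markers$pos[o]),
            origin = origin[o, , drop = FALSE])
  rownames(x$markers) <- NULL
  class(x) <- "origin_matrix"
  x
}

#' @export
print.origin_matrix <- function(x, ...) {
  pat <- classify_sites(x)
  cat("Origin matrix: ", nrow(x$markers), " markers x 4 spores\n",
      sep = "")
  print(table(pattern = pat$label))
  invisible(x)
}

#' Assign parental origin to each spore at each marker
#'
#' A spore's cell is \code{"P1"} when its called allele equals the
#' parent-1 allele of the marker, \code{"P2"} when it equals the
#' parent-2 allele, and missing otherwise (no call, heterozygous call,
#' depth below \code{min_depth}, or an allele matching neither parent
#' -- the last is counted and reported in a warning).
#'
#' @param markers a \code{\link{marker_table}} (or data.frame with
#'   \code{chrom}, \code{pos}, \code{a1}, \code{a2}).
#' @param spores a \code{\link{site_calls}} with exactly 4 samples
#'   covering (a subset of) the marker positions.
#' @param min_depth minimum total read depth for a spore call to be
#'   used (default 0: genotype calls taken at face value).
#' @return an \code{\link{origin_matrix}}.
#' @export
assign_origin <- function(markers, spores, min_depth = 0) {
  stopifnot(all(c("chrom", "pos", "a1", "a2") %in% names(markers)))
  if (n_samples(spores) != 4)
    stop("expected 4 spore samples, got ", n_samples(spores))
  mk <- paste(markers$chrom, markers$pos)
  sk <- paste(spores$sites$chrom, spores$sites$pos)
  hit <- match(mk, sk)
  O <- matrix(NA_character_, nrow = nrow(markers), ncol = 4,
              dimnames = list(NULL, colnames(spores$genotype)))
  n_foreign <- 0
  ok <- !is.na(hit)
  if (any(ok)) {
    g <- spores$genotype[hit[ok], , drop = FALSE]
    tot <- (spores$ref_depth + spores$alt_depth)[hit[ok], , drop = FALSE]
    ref <- spores$sites$ref[hit[ok]]; alt <- spores$sites$alt[hit[ok]]
    for (j in 1:4) {
      allele <- ifelse(is.na(g[, j]) | g[, j] == 1, NA_character_,
                       ifelse(g[, j] == 0, ref, alt))
      allele[tot[, j] < min_depth] <- NA_character_
      o <- ifelse(is.na(allele), NA_character_,
                  ifelse(allele == markers$a1[ok], "P1",
                         ifelse(allele == markers$a2[ok], "P2",
                                "foreign")))
      n_foreign <- n_foreign + sum(o == "foreign", na.rm = TRUE)
      o[!is.na(o) & o == "foreign"] <- NA_character_
      O[ok, j] <- o
    }
  }
  if (n_foreign > 0)
    warning(n_foreign, " spore call(s) matched neither parental allele; ",
            "set to missing")
  origin_matrix(markers, O)
}

#' Classify the segregation pattern at every marker
#'
#' @param origin an \code{\link{origin_matrix}}.
#' @return data.frame with per-marker parental counts \code{nP1},
#'   \code{nP2}, \code{nMissing} and a \code{label} among \code{"2:2"},
#'   \code{"3:1"}, \code{"1:3"}, \code{"4:0"}, \code{"0:4"},
#'   \code{"incomplete"}.
#' @export
classify_sites <- function(origin) {
  stopifnot(inherits(origin, "origin_matrix"))
  nP1 <- rowSums(origin$origin == "P1", na.rm = TRUE)
  nP2 <- rowSums(origin$origin == "P2", na.rm = TRUE)
  nmiss <- 4 - nP1 - nP2
  label <- ifelse(nmiss > 0, "incomplete",
                  paste(nP1, nP2, sep = ":"))
  data.frame(origin$markers, nP1 = nP1, nP2 = nP2, nMissing = nmiss,
             label = label)
}

# max-tract bounds from the closest flanking 2:2 complete markers;
# falls back to chromosome bounds (if known) or the marker span.
tract_bounds <- function(pos22, left_of, right_of, chrom_len, first_pos,
                         last_pos) {
  lo <- pos22[pos22 < left_of]
  hi <- pos22[pos22 > right_of]
  c(if (length(lo)) max(lo) else 0,
    if (length(hi)) min(hi) else if (!is.na(chrom_len)) chrom_len else last_pos)
}

#' Call crossover, non-crossover and premeiotic-LOH events
#'
#' Compresses each chromosome's complete markers (no missing spore)
#' into runs of identical origin vectors and interprets the run
#' structure:
#' \itemize{
#'   \item a phase change between two 2:2 runs in which exactly two
#'     spores switch origin, reciprocally, is a crossover (CO); any
#'     intervening conversion-pattern run is attached as a conversion
#'     annotation;
#'   \item a maximal 3:1/1:3 run of at least \code{min_nco_markers}
#'     markers, flanked on both sides by 2:2 runs of the same phase,
#'     with a single converted spore, is a non-crossover (NCO);
#'   \item 4:0/0:4 runs are reported as premeiotic LOH (they pre-date
#'     meiosis and are excluded from meiotic event counts);
#'   \item anything contradictory (an unflanked conversion run, four
#'     spores switching at once, or a reciprocal double switch restored
#'     within fewer than 2 markers) is flagged \code{COMPLEX}, never
#'     dropped.
#' }
#' Markers with missing cells do not support events and do not break
#' runs; however, if a stretch of missing data longer than
#' \code{merge_distance} separates two complete markers, the chromosome
#' is split there and events are never called across the gap. Maximum
#' tracts run between the closest flanking 2:2 markers (chromosome
#' bounds if none).
#'
#' @param origin an \code{\link{origin_matrix}}.
#' @param min_nco_markers minimum markers supporting an NCO (default 1;
#'   real single-marker NCOs exist, so the default keeps them).
#' @param merge_distance maximum missing-data span (bp) bridged within
#'   a run (default 5000).
#' @param chrom_lengths optional named vector of chromosome lengths
#'   used for tract bounds at chromosome ends.
#' @return an object of class \code{recomb_events}: a data.frame with
#'   columns \code{chrom}, \code{kind} (\code{CO}, \code{NCO},
#'   \code{PREMEIOTIC_LOH}, \code{COMPLEX}), \code{spores}
#'   (comma-separated spore indices), \code{n_markers},
#'   \code{inner_start}/\code{inner_end} (first and last supporting
#'   marker; for a clean CO the flanking markers), \code{tract_start}/
#'   \code{tract_end} (maximum tract, half-open) and \code{note}.
#' @export
call_events <- function(origin, min_nco_markers = 1, merge_distance = 5000,
                        chrom_lengths = NULL) {
  stopifnot(inherits(origin, "origin_matrix"))
  ev_out <- list()
  add <- function(chrom, kind, spores, n_markers, inner, tract, note = "") {
    ev_out[[length(ev_out) + 1]] <<- data.frame(
      chrom = chrom, kind = kind, spores = spores, n_markers = n_markers,
      inner_start = inner[1], inner_end = inner[2],
      tract_start = tract[1], tract_end = tract[2], note = note)
  }
  for (cn in unique(origin$markers$chrom)) {
    rows <- which(origin$markers$chrom == cn)
    M <- origin$origin[rows, , drop = FALSE]
    pos <- origin$markers$pos[rows]
    clen <- if (!is.null(chrom_lengths) && cn %in% names(chrom_lengths))
      chrom_lengths[[cn]] else NA_real_
    complete <- which(rowSums(is.na(M)) == 0)
    if (length(complete) < 1) next
    # split where a long missing-data gap separates complete markers
    blk <- cumsum(c(1, diff(complete) > 1 &
                      diff(pos[complete]) > merge_distance))
    for (b in unique(blk)) {
      cm <- complete[blk == b]
      # one character per spore so string positions index spores
      code <- ifelse(M[cm, , drop = FALSE] == "P1", "1", "2")
      sig <- apply(code, 1, paste, collapse = "")
      nP1 <- rowSums(M[cm, , drop = FALSE] == "P1")
      r <- rle(sig)
      K <- length(r$values)
      i1 <- cumsum(r$lengths)          # run end (index into cm)
      i0 <- c(1, utils::head(i1, -1) + 1)
      rl <- ifelse(nP1[i0] == 2, "22", ifelse(nP1[i0] %in% c(1, 3),
                                              "conv", "loh"))
      rsig <- r$values[seq_len(K)]
      pos_c <- pos[cm]
      pos22 <- pos_c[rep(rl == "22", r$lengths)]
      first_p <- pos_c[1]; last_p <- pos_c[length(pos_c)]
      idx22 <- which(rl == "22")

      # conversion & LOH runs
      consumed <- rep(FALSE, K)   # conv runs absorbed into CO events
      for (k in which(rl != "22")) {
        prev <- idx22[idx22 < k]; nxt <- idx22[idx22 > k]
        prev <- if (length(prev)) max(prev) else NA
        nxt <- if (length(nxt)) min(nxt) else NA
        inner <- c(pos_c[i0[k]], pos_c[i1[k]])
        tract <- tract_bounds(pos22, inner[1], inner[2], clen,
                              first_p, last_p)
        nm <- r$lengths[k]
        if (rl[k] == "loh") {
          add(cn, "PREMEIOTIC_LOH", "1,2,3,4", nm, inner, tract)
          next
        }
        if (is.na(prev) || is.na(nxt)) {
          add(cn, "COMPLEX", "", nm, inner, tract,
              "conversion run without flanking 2:2 on both sides")
          next
        }
        if (rsig[prev] == rsig[nxt]) {
          fl <- strsplit(rsig[prev], "")[[1]]
          cv <- strsplit(rsig[k], "")[[1]]
          diffs <- which(fl != cv)
          if (length(diffs) == 1 && nm >= min_nco_markers) {
            add(cn, "NCO", as.character(diffs), nm, inner, tract)
          } else if (length(diffs) != 1) {
            add(cn, "COMPLEX", paste(diffs, collapse = ","), nm, inner,
                tract, "multi-spore conversion between identical phases")
          }
        } else {
          consumed[k] <- TRUE   # attached to the CO at this boundary
        }
      }

      # crossovers: boundaries between consecutive 2:2 runs
      if (length(idx22) >= 2) {
        n22 <- length(idx22)
        sig22 <- rsig[idx22]
        changed <- sig22[-1] != sig22[-n22]
        # double-switch restoration: u -> v -> w with sig_u == sig_w
        skip <- rep(FALSE, n22 - 1)
        for (t in seq_len(n22 - 2)) {
          if (changed[t] && changed[t + 1] &&
              sig22[t] == sig22[t + 2] &&
              r$lengths[idx22[t + 1]] < 2) {
            u <- idx22[t]; w <- idx22[t + 2]
            add(cn, "COMPLEX", "", r$lengths[idx22[t + 1]],
                c(pos_c[i1[u]], pos_c[i0[w]]),
                c(pos_c[i1[u]], pos_c[i0[w]]),
                "reciprocal double switch within a single 2:2 marker")
            skip[t] <- skip[t + 1] <- TRUE
          }
        }
        for (t in which(changed & !skip)) {
          u <- idx22[t]; v <- idx22[t + 1]
          a <- strsplit(sig22[t], "")[[1]]
          bvec <- strsplit(sig22[t + 1], "")[[1]]
          diffs <- which(a != bvec)
          between <- seq_len(K) > u & seq_len(K) < v
          conv_n <- sum(r$lengths[between & rl != "22"])
          inner <- c(pos_c[i1[u]], pos_c[i0[v]])
          if (length(diffs) == 2) {
            note <- if (conv_n > 0) "with conversion tract" else ""
            add(cn, "CO", paste(diffs, collapse = ","), conv_n, inner,
                inner, note)
          } else {
            add(cn, "COMPLEX", paste(diffs, collapse = ","), conv_n,
                inner, inner, "more than two spores switch phase")
          }
        }
      }
    }
  }
  ev <- if (length(ev_out)) do.call(rbind, ev_out) else
    data.frame(chrom = character(), kind = character(),
               spores = character(), n_markers = integer(),
               inner_start = numeric(), inner_end = numeric(),
               tract_start = numeric(), tract_end = numeric(),
               note = character())
  rownames(ev) <- NULL
  structure(ev, class = c("recomb_events", "data.frame"))
}

#' @export
print.recomb_events <- function(x, ...) {
  cat("Recombination events: ", nrow(x), " (",
      sum(x$kind == "CO"), " CO, ", sum(x$kind == "NCO"), " NCO, ",
      sum(x$kind == "PREMEIOTIC_LOH"), " premeiotic LOH, ",
      sum(x$kind == "COMPLEX"), " complex)\n", sep = "")
  if (nrow(x)) print.data.frame(x)
  invisible(x)
}

#' Write / read a per-marker segregation (Seg) file
#'
#' Minimal six-column tab-delimited dialect: a header naming the four
#' spores, then one row per marker with chromosome, position and the
#' four origin codes (\code{P1}, \code{P2}, or \code{-} for missing).
#' Round-trips losslessly through \code{read_seg}.
#'
#' @param origin an \code{\link{origin_matrix}}.
#' @param file path.
#' @return \code{file} invisibly (writer); an \code{origin_matrix}
#'   (reader).
#' @export
write_seg <- function(origin, file) {
  stopifnot(inherits(origin, "origin_matrix"))
  O <- origin$origin
  O[is.na(O)] <- "-"
  out <- data.frame(chrom = origin$markers$chrom,
                    pos = origin$markers$pos, O, check.names = FALSE)
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_seg
#' @export
read_seg <- function(file) {
  x <- utils::read.table(file, header = TRUE, sep = "\t",
                         check.names = FALSE,
                         colClasses = c("character", "numeric",
                                        rep("character", 4)))
  O <- as.matrix(x[, 3:6])
  O[O == "-"] <- NA_character_
  origin_matrix(x[, 1:2], O)
}
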