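#' Strain-by-site genotype matrix
#'
#' @param geno strains x sites numeric matrix of alternate-allele
#'   dosages (0/1/2, \code{NA} missing), with strain row names.
#' @param sites data.frame with \code{chrom} and \code{pos} per column
#'   of \code{geno}.
#' @return an object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(geno, sites) {
  geno <- as.matrix(geno)
  stopifnot(!is.null(rownames(geno)), ncol(geno) == nrow(sites),
            all(c("chrom", "pos") %in% names(sites)))
  x <- list(geno = geno, sites = sites)
  class(x) <- "genotype_matrix"
  x
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix: ", nrow(x$geno), " strains x ", ncol(x$geno),
      " sites on ", length(unique(x$sites$chrom)), " chromosome(s)\n",
      sep = "")
  invisible(x)
}

#' Convert multi-strain site calls into a genotype matrix
#'
#' @param calls a \code{\link{site_calls}} (one sample per strain).
#' @return a \code{\link{genotype_matrix}} (sites transposed to
#'   columns).
#' @export
as_genotype_matrix <- function(calls) {
  stopifnot(inherits(calls, "site_calls"))
  genotype_matrix(t(calls$genotype), calls$sites)
}

#' Allele-sharing dissimilarity between strains
#'
#' Pairwise distance = 1 minus the mean per-site allele-sharing
#' fraction over sites non-missing in both strains, where sharing
#' between dosages g and h is \code{1 - |g - h|/2} (identical
#' homozygotes share 1, opposite homozygotes 0, het vs hom 0.5). This
#' is a documented allele-sharing stand-in for SNP-based individual
#' dissimilarity.
#'
#' @param gm a \code{\link{genotype_matrix}} with >= 2 strains.
#' @return symmetric strains x strains distance matrix with zero
#'   diagonal; an error if any pair shares no called site.
#' @export
snp_dissimilarity <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"), nrow(gm$geno) >= 2)
  g <- gm$geno
  ns <- nrow(g)
  D <- matrix(0, ns, ns, dimnames = list(rownames(g), rownames(g)))
  for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
    ok <- !is.na(g[i, ]) & !is.na(g[j, ])
    if (!any(ok)) stop("strains ", rownames(g)[i], " and ",
                       rownames(g)[j], " share no called site")
    D[i, j] <- D[j, i] <- mean(abs(g[i, ok] - g[j, ok]) / 2)
  }
  D
}

#' Build an unrooted tree from a distance matrix (BIONJ)
#'
#' Variance-weighted neighbour joining via \code{\link[ape]{bionj}};
#' deterministic given its input, and exact on additive matrices.
#'
#' @param d symmetric distance matrix (>= 4 taxa, complete).
#' @return an unrooted \code{phylo}.
#' @export
build_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 4) stop("tree building needs >= 4 taxa")
  if (any(is.na(d))) stop("incomplete distance matrix")
  ape::unroot(ape::bionj(stats::as.dist(d)))
}

# ---- internal tree machinery ---------------------------------------

# nontrivial splits as a logical matrix (rows = splits) over sorted labels
tree_splits <- function(tree) {
  labs <- sort(tree$tip.label)
  n <- length(labs)
  pp <- ape::prop.part(tree)
  out <- list()
  for (p in pp) {
    mem <- labs %in% tree$tip.label[p]
    if (min(sum(mem), n - sum(mem)) < 2) next
    if (!mem[1]) mem <- !mem           # canonical orientation
    out[[length(out) + 1]] <- mem
  }
  m <- if (length(out)) do.call(rbind, out) else
    matrix(logical(), 0, n)
  colnames(m) <- labs
  unique(m)
}

# topological (unit-branch-length) tip-tip distances, sorted-label order
tip_dist <- function(tree) {
  t2 <- tree
  t2$edge.length <- rep(1, nrow(t2$edge))
  n <- length(tree$tip.label)
  D <- ape::dist.nodes(t2)[seq_len(n), seq_len(n)]
  ord <- order(tree$tip.label)
  D <- D[ord, ord]
  dimnames(D) <- list(sort(tree$tip.label), sort(tree$tip.label))
  D
}

# quartet topology codes from a topological distance matrix:
# 1 = ab|cd, 2 = ac|bd, 3 = ad|bc (quads: 4-row index matrix)
quartet_codes <- function(D, quads) {
  s1 <- D[cbind(quads[1, ], quads[2, ])] + D[cbind(quads[3, ], quads[4, ])]
  s2 <- D[cbind(quads[1, ], quads[3, ])] + D[cbind(quads[2, ], quads[4, ])]
  s3 <- D[cbind(quads[1, ], quads[4, ])] + D[cbind(quads[2, ], quads[3, ])]
  code <- integer(ncol(quads))
  code[s1 < s2 & s1 < s3] <- 1L
  code[s2 < s1 & s2 < s3] <- 2L
  code[s3 < s1 & s3 < s2] <- 3L
  code        # 0 = unresolved (ties)
}

# minimum-cost assignment of rows to columns of a square cost matrix,
# bitmask DP (k <= ~16)
assignment_cost <- function(cost) {
  k <- nrow(cost)
  if (k == 0) return(0)
  if (k > 16) stop("assignment too large")
  f <- rep(Inf, 2^k); f[1] <- 0
  sets <- 0:(2^k - 1)
  pc <- vapply(sets, function(s) sum(bitwAnd(s, 2^(0:(k - 1))) > 0), 0)
  for (i in seq_len(k)) {
    fn <- rep(Inf, 2^k)
    from <- which(pc == i - 1) # 1-based into f (set value +1)
    for (j in seq_len(k)) {
      bit <- 2^(j - 1)
      free <- from[bitwAnd(sets[from], bit) == 0]
      tgt <- free + bit
      fn[tgt] <- pmin(fn[tgt], f[free] + cost[i, j])
    }
    f <- fn
  }
  f[2^k]
}

# unrooted maximum agreement subtree size via directed-edge DP
umast_size <- function(t1, t2) {
  labs <- sort(t1$tip.label)
  n <- length(labs)
  prep <- function(tree) {
    ne <- nrow(tree$edge)
    adj <- vector("list", max(tree$edge))
    for (r in seq_len(ne)) {
      a <- tree$edge[r, 1]; b <- tree$edge[r, 2]
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    }
    # directed edges (a -> b): subtree rooted at b, away from a
    de <- rbind(tree$edge, tree$edge[, 2:1])
    nd <- nrow(de)
    kids <- vector("list", nd); size <- integer(nd)
    lset <- vector("list", nd)  # logical over sorted labels
    idx_of <- new.env(hash = TRUE)
    for (r in seq_len(nd))
      assign(paste(de[r, 1], de[r, 2]), r, envir = idx_of)
    fill <- function(r) {
      if (size[r] > 0) return()
      b <- de[r, 2]
      if (b <= n) {
        size[r] <<- 1L
        lset[[r]] <<- labs == tree$tip.label[b]
      } else {
        ch <- setdiff(adj[[b]], de[r, 1])
        ck <- vapply(ch, function(x) get(paste(b, x), envir = idx_of), 0)
        for (c1 in ck) fill(c1)
        kids[[r]] <<- ck
        size[r] <<- sum(size[ck])
        ls <- lset[[ck[1]]]
        for (c1 in ck[-1]) ls <- ls | lset[[c1]]
        lset[[r]] <<- ls
      }
    }
    for (r in seq_len(nd)) fill(r)
    list(de = de, kids = kids, size = size, lset = lset,
         und = seq_len(ne), nd = nd)
  }
  P1 <- prep(t1); P2 <- prep(t2)
  M <- matrix(0L, P1$nd, P2$nd)
  o1 <- order(P1$size); o2 <- order(P2$size)
  for (i in o1) for (j in o2) {
    if (P1$size[i] == 1L) {
      M[i, j] <- as.integer(any(P1$lset[[i]] & P2$lset[[j]]))
    } else if (P2$size[j] == 1L) {
      M[i, j] <- as.integer(any(P1$lset[[i]] & P2$lset[[j]]))
    } else {
      k1 <- P1$kids[[i]]; k2 <- P2$kids[[j]]
      M[i, j] <- max(M[k1[1], k2[1]] + M[k1[2], k2[2]],
                     M[k1[1], k2[2]] + M[k1[2], k2[1]],
                     M[i, k2[1]], M[i, k2[2]],
                     M[k1[1], j], M[k1[2], j])
    }
  }
  ne1 <- P1$nd / 2; ne2 <- P2$nd / 2
  best <- 0L
  for (e1 in seq_len(ne1)) for (e2 in seq_len(ne2)) {
    f1 <- e1; r1 <- e1 + ne1      # the two directions of edge e1
    f2 <- e2; r2 <- e2 + ne2
    best <- max(best,
                M[f1, f2] + M[r1, r2],
                M[f1, r2] + M[r1, f2])
  }
  best
}

#' Topological distance between two unrooted trees
#'
#' Five unrooted, purely topological metrics (branch lengths are
#' ignored):
#' \describe{
#'   \item{RF}{Robinson-Foulds: number of nontrivial splits present in
#'     exactly one tree.}
#'   \item{PD}{path difference: Euclidean distance between the vectors
#'     of topological leaf-pair path lengths.}
#'   \item{Q}{quartet distance: number of leaf quartets resolved
#'     differently.}
#'   \item{MS}{matching split: minimum-weight perfect matching between
#'     the two split sets under symmetric-difference weight (splits
#'     left unmatched pair with the trivial split).}
#'   \item{MAS}{maximum agreement subtree distance: number of leaves
#'     that must be removed for the trees to agree.}
#' }
#'
#' @param t1,t2 unrooted \code{phylo} objects on the same leaf set.
#' @param metric one of \code{"RF"}, \code{"PD"}, \code{"Q"},
#'   \code{"MS"}, \code{"MAS"}.
#' @return the raw distance (0 for topologically identical trees).
#' @examples
#' t1 <- ape::read.tree(text = "((a,b),(c,d),e);")
#' t2 <- ape::read.tree(text = "((a,c),(b,d),e);")
#' tree_distance(t1, t2, "RF")
#' @export
tree_distance <- function(t1, t2, metric = c("RF", "PD", "Q", "MS", "MAS")) {
  metric <- match.arg(metric)
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  n <- length(t1$tip.label)
  switch(metric,
    RF = {
      s1 <- tree_splits(t1); s2 <- tree_splits(t2)
      k1 <- apply(s1, 1, paste, collapse = "")
      k2 <- apply(s2, 1, paste, collapse = "")
      sum(!(k1 %in% k2)) + sum(!(k2 %in% k1))
    },
    PD = {
      d <- tip_dist(t1) - tip_dist(t2)
      sqrt(sum(d[upper.tri(d)]^2))
    },
    Q = {
      quads <- utils::combn(n, 4)
      sum(quartet_codes(tip_dist(t1), quads) !=
            quartet_codes(tip_dist(t2), quads))
    },
    MS = {
      s1 <- tree_splits(t1); s2 <- tree_splits(t2)
      m1 <- nrow(s1); m2 <- nrow(s2); k <- max(m1, m2)
      if (k == 0) return(0)
      cost <- matrix(0, k, k)
      for (i in seq_len(k)) for (j in seq_len(k)) {
        if (i <= m1 && j <= m2) {
          h <- sum(s1[i, ] != s2[j, ])
          cost[i, j] <- min(h, n - h)
        } else if (i <= m1) {
          cost[i, j] <- min(sum(s1[i, ]), n - sum(s1[i, ]))
        } else if (j <= m2) {
          cost[i, j] <- min(sum(s2[j, ]), n - sum(s2[j, ]))
        }
      }
      assignment_cost(cost)
    },
    MAS = n - umast_size(t1, t2)
  )
}

#' Generate a topology uniform over unrooted binary labeled trees
#'
#' Sequential uniform leaf insertion: starting from the unique 3-leaf
#' tree, each further leaf subdivides an edge chosen uniformly among
#' the current 2k-3; this yields the uniform distribution over the
#' (2n-5)!! unrooted binary topologies.
#'
#' @param labels leaf labels (>= 3).
#' @return an unrooted \code{phylo} with unit branch lengths.
#' @export
random_topology <- function(labels) {
  n <- length(labels)
  stopifnot(n >= 3)
  # nodes: 1..n leaves (insertion order), n+1.. internal
  edges <- matrix(c(n + 1, 1, n + 1, 2, n + 1, 3), ncol = 2,
                  byrow = TRUE)
  nxt <- n + 2
  for (k in seq_len(n - 3) + 3) {
    e <- sample.int(nrow(edges), 1)
    a <- edges[e, 1]; b <- edges[e, 2]
    edges <- rbind(edges[-e, , drop = FALSE],
                   c(a, nxt), c(nxt, b), c(nxt, k))
    nxt <- nxt + 1
  }
  adj <- vector("list", nxt - 1)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  nk <- function(node, parent) {
    ch <- setdiff(adj[[node]], parent)
    if (length(ch) == 0) return(labels[node])
    paste0("(", paste(vapply(ch, nk, "", parent = node),
                      collapse = ","), ")")
  }
  tr <- ape::read.tree(text = paste0(nk(n + 1, 0), ";"))
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}

#' Random-pair mean of a tree metric (the normalizer)
#'
#' Mean distance over independent pairs of uniform random topologies
#' on the same leaf set; observed distances divided by this mean have
#' expectation 1 for random pairs.
#'
#' @param metric metric name (see \code{\link{tree_distance}}), or a
#'   vector of names.
#' @param labels leaf labels.
#' @param n_pairs number of random pairs (default 1000).
#' @param seed integer seed, or \code{NULL}.
#' @return named numeric vector of means, one per metric.
#' @export
random_pair_mean <- function(metric, labels, n_pairs = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tot <- stats::setNames(numeric(length(metric)), metric)
  for (p in seq_len(n_pairs)) {
    t1 <- random_topology(labels)
    t2 <- random_topology(labels)
    for (m in metric) tot[m] <- tot[m] + tree_distance(t1, t2, m)
  }
  tot / n_pairs
}

#' Normalize a raw tree distance against random tree pairs
#'
#' @param raw raw distance.
#' @param metric metric name.
#' @param labels leaf set of the compared trees.
#' @param n_pairs,seed passed to \code{\link{random_pair_mean}}.
#' @return \code{raw / } random-pair mean.
#' @export
normalize_distance <- function(raw, metric, labels, n_pairs = 1000,
                               seed = NULL) {
  raw / random_pair_mean(metric, labels, n_pairs, seed)[[metric]]
}

#' Tree concordance of each chromosome against the whole genome
#'
#' Builds the whole-genome allele-sharing BIONJ tree and one tree per
#' chromosome, and scores each chromosome tree against the genome tree
#' with all five topological metrics, normalized by the mean of random
#' tree pairs (shared across chromosomes). Chromosomes with fewer than
#' 4 informative (polymorphic, not all-missing) sites are skipped with
#' a message.
#'
#' @param gm a \code{\link{genotype_matrix}} (>= 4 strains).
#' @param n_random random pairs for the normalizer (default 1000).
#' @param seed integer seed for the normalizer.
#' @return an object of class \code{tree_distance_report}: a data.frame
#'   (chrom, metric, raw, random_mean, normalized) with the trees in
#'   attributes \code{genome_tree} and \code{chromosome_trees}.
#' @export
concordance_scan <- function(gm, n_random = 1000, seed = 1) {
  stopifnot(inherits(gm, "genotype_matrix"), nrow(gm$geno) >= 4)
  metrics <- c("MAS", "MS", "RF", "PD", "Q")
  genome_tree <- build_tree(snp_dissimilarity(gm))
  labels <- rownames(gm$geno)
  norm <- random_pair_mean(metrics, labels, n_random, seed)
  informative <- function(cols) {
    v <- apply(gm$geno[, cols, drop = FALSE], 2,
               function(x) length(unique(x[!is.na(x)])) > 1)
    sum(v)
  }
  rows <- list(); trees <- list()
  for (cn in unique(gm$sites$chrom)) {
    cols <- which(gm$sites$chrom == cn)
    if (informative(cols) < 4) {
      message("skipping ", cn, ": fewer than 4 informative sites")
      next
    }
    ct <- build_tree(snp_dissimilarity(
      genotype_matrix(gm$geno[, cols, drop = FALSE],
                      gm$sites[cols, , drop = FALSE])))
    trees[[cn]] <- ct
    for (m in metrics) {
      raw <- tree_distance(genome_tree, ct, m)
      rows[[length(rows) + 1]] <- data.frame(
        chrom = cn, metric = m, raw = raw, random_mean = norm[[m]],
        normalized = raw / norm[[m]])
    }
  }
  rep <- do.call(rbind, rows)
  rownames(rep) <- NULL
  structure(rep, class = c("tree_distance_report", "data.frame"),
            genome_tree = genome_tree, chromosome_trees = trees)
}

#' @export
print.tree_distance_report <- function(x, ...) {
  cat("Tree concordance (chromosome vs whole genome), normalized to",
      "random tree pairs:\n")
  w <- stats::reshape(as.data.frame(x)[, c("chrom", "metric", "normalized")],
                      direction = "wide", idvar = "chrom",
                      timevar = "metric")
  names(w) <- sub("normalized\\.", "", names(w))
  print.data.frame(w, row.names = FALSE, digits = 3)
  invisible(x)
}
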