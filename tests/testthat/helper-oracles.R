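# Independent oracles and fixture builders used across the suite.
# These deliberately re-derive quantities by enumeration / brute force,
# never by calling the implementation under test.

# ---- small fixture builders ----------------------------------------

toy_genome <- function(len = 1e5, name = "chrI", gc = 0.3, masked = NULL)
  genome_spec(data.frame(name = name, length = len), gc_content = gc,
              masked = masked)

# a site_calls table built by hand (one chromosome)
make_calls <- function(pos, ref, alt, genotype, ref_depth, alt_depth,
                       samples) {
  g <- matrix(genotype, ncol = length(samples),
              dimnames = list(NULL, samples))
  site_calls(data.frame(chrom = "chrI", pos = pos, ref = ref, alt = alt),
             g,
             matrix(ref_depth, ncol = length(samples)),
             matrix(alt_depth, ncol = length(samples)))
}

# an origin matrix built by hand from a character vector per spore
make_origin <- function(pos, ...) {
  sp <- list(...)
  stopifnot(length(sp) == 4)
  origin_matrix(data.frame(chrom = "chrI", pos = pos),
                do.call(cbind, sp))
}

# ---- brute-force segregation-event enumerator ----------------------
# Tests every adjacent marker pair / marker interval directly against
# the CO / NCO / LOH definitions. Assumes complete data (no missing).
oracle_events <- function(origin) {
  ev <- list()
  for (cn in unique(origin$markers$chrom)) {
    rows <- which(origin$markers$chrom == cn)
    M <- origin$origin[rows, , drop = FALSE]
    pos <- origin$markers$pos[rows]
    k <- nrow(M)
    nP1 <- rowSums(M == "P1")
    lab <- ifelse(nP1 == 2, "22", ifelse(nP1 %in% c(1, 3), "conv", "loh"))
    # CO: adjacent 2:2 markers whose vectors differ in exactly 2 spores
    for (i in seq_len(max(k - 1, 0))) {
      if (lab[i] == "22" && lab[i + 1] == "22") {
        d <- which(M[i, ] != M[i + 1, ])
        if (length(d) == 2)
          ev[[length(ev) + 1]] <- data.frame(
            chrom = cn, kind = "CO",
            spores = paste(d, collapse = ","),
            inner_start = pos[i], inner_end = pos[i + 1])
      }
    }
    # NCO: maximal conv runs with one converted spore, identical 2:2
    # vectors on both flanks
    i <- 1
    while (i <= k) {
      if (lab[i] == "conv") {
        j <- i
        while (j < k && lab[j + 1] == "conv" &&
                 all(M[j + 1, ] == M[i, ])) j <- j + 1
        if (i > 1 && j < k && lab[i - 1] == "22" && lab[j + 1] == "22" &&
              all(M[i - 1, ] == M[j + 1, ])) {
          d <- which(M[i, ] != M[i - 1, ])
          if (length(d) == 1)
            ev[[length(ev) + 1]] <- data.frame(
              chrom = cn, kind = "NCO", spores = as.character(d),
              inner_start = pos[i], inner_end = pos[j])
        }
        i <- j + 1
      } else if (lab[i] == "loh") {
        j <- i
        while (j < k && lab[j + 1] == "loh" &&
                 all(M[j + 1, ] == M[i, ])) j <- j + 1
        ev[[length(ev) + 1]] <- data.frame(
          chrom = cn, kind = "PREMEIOTIC_LOH", spores = "1,2,3,4",
          inner_start = pos[i], inner_end = pos[j])
        i <- j + 1
      } else i <- i + 1
    }
  }
  out <- if (length(ev)) do.call(rbind, ev) else
    data.frame(chrom = character(), kind = character(),
               spores = character(), inner_start = numeric(),
               inner_end = numeric())
  out[order(out$chrom, out$inner_start), , drop = FALSE]
}

# resolvable simulated tetrad: every true event is visible, supported,
# and events are separated by >= 2 complete 2:2 markers from each
# other and from chromosome ends (so every definition applies cleanly)
resolvable_tetrad <- function(truth) {
  ev <- truth$events
  if (nrow(ev) == 0) return(TRUE)
  if (any(!ev$visible)) return(FALSE)
  for (cn in unique(ev$chrom)) {
    pos <- truth$snps$pos[truth$snps$chrom == cn]
    e <- ev[ev$chrom == cn, , drop = FALSE]
    # marker-index span of each event
    lo <- vapply(seq_len(nrow(e)), function(i) {
      if (e$kind[i] == "CO") match(e$inner_start[i], pos)
      else match(e$inner_start[i], pos) - 1L  # NCO needs a 2:2 flank
    }, 0L)
    hi <- vapply(seq_len(nrow(e)), function(i) {
      if (e$kind[i] == "CO") match(e$inner_end[i], pos)
      else match(e$inner_end[i], pos) + 1L
    }, 0L)
    if (any(is.na(lo)) || any(is.na(hi))) return(FALSE)
    if (min(lo) < 2 || max(hi) > length(pos) - 1) return(FALSE)
    o <- order(lo)
    if (nrow(e) > 1 && any(lo[o][-1] - hi[o][-nrow(e)] < 2)) return(FALSE)
  }
  TRUE
}

# ---- tree oracles (exhaustive, n <= 8) ------------------------------

# induced quartet topology via ape::drop.tip on the actual tree
oracle_quartet <- function(tree, q) {
  t4 <- ape::drop.tip(tree, setdiff(tree$tip.label, q))
  pp <- ape::prop.part(t4)
  canon <- function(side) {
    # report the pair containing the alphabetically first quartet leaf
    if (!min(q) %in% side) side <- setdiff(q, side)
    paste(sort(side), collapse = "|")
  }
  for (p in pp) {
    side <- t4$tip.label[p]
    if (length(side) == 2) return(canon(side))
    other <- setdiff(q, side)
    if (length(other) == 2) return(canon(other))
  }
  "star"
}

oracle_quartet_distance <- function(t1, t2) {
  labs <- sort(t1$tip.label)
  qs <- utils::combn(labs, 4)
  sum(vapply(seq_len(ncol(qs)), function(i)
    oracle_quartet(t1, qs[, i]) != oracle_quartet(t2, qs[, i]), TRUE))
}

# splits via phangorn (independent of the package's prop.part path)
oracle_splits <- function(tree) {
  m <- as.matrix(phangorn::as.splits(tree))
  labs <- sort(colnames(m))
  m <- m[, labs, drop = FALSE]
  n <- ncol(m)
  keep <- pmin(rowSums(m), n - rowSums(m)) >= 2
  m <- m[keep, , drop = FALSE]
  flip <- m[, 1] == 0
  m[flip, ] <- 1 - m[flip, , drop = FALSE]
  unique(apply(m, 1, paste, collapse = ""))
}

oracle_rf <- function(t1, t2) {
  s1 <- oracle_splits(t1); s2 <- oracle_splits(t2)
  sum(!(s1 %in% s2)) + sum(!(s2 %in% s1))
}

# minimum-cost split matching by explicit permutation enumeration
oracle_ms <- function(t1, t2) {
  key_to_vec <- function(k) as.integer(strsplit(k, "")[[1]])
  s1 <- lapply(oracle_splits(t1), key_to_vec)
  s2 <- lapply(oracle_splits(t2), key_to_vec)
  n <- length(t1$tip.label)
  k <- max(length(s1), length(s2))
  if (k == 0) return(0)
  cost <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i <= length(s1) && j <= length(s2)) {
      h <- sum(s1[[i]] != s2[[j]])
      cost[i, j] <- min(h, n - h)
    } else if (i <= length(s1)) {
      cost[i, j] <- min(sum(s1[[i]]), n - sum(s1[[i]]))
    } else if (j <= length(s2)) {
      cost[i, j] <- min(sum(s2[[j]]), n - sum(s2[[j]]))
    }
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  min(vapply(perms(seq_len(k)), function(p)
    sum(cost[cbind(seq_len(k), p)]), 0))
}

# topologies-agree test on a leaf subset, via phangorn RF on pruned trees
agrees_on <- function(t1, t2, keep) {
  if (length(keep) <= 3) return(TRUE)
  p1 <- ape::drop.tip(t1, setdiff(t1$tip.label, keep))
  p2 <- ape::drop.tip(t2, setdiff(t2$tip.label, keep))
  phangorn::RF.dist(ape::unroot(p1), ape::unroot(p2)) == 0
}

# exhaustive maximum agreement subtree (largest-first subset search)
oracle_mas <- function(t1, t2) {
  labs <- t1$tip.label
  n <- length(labs)
  for (drop in 0:(n - 3)) {
    if (drop == 0) {
      if (agrees_on(t1, t2, labs)) return(0)
    } else {
      combs <- utils::combn(labs, drop)
      for (i in seq_len(ncol(combs)))
        if (agrees_on(t1, t2, setdiff(labs, combs[, i]))) return(drop)
    }
  }
  n - 3
}

# ---- exact Poisson CI oracle: invert tail sums directly ------------
oracle_poisson_ci <- function(n) {
  lo <- if (n == 0) 0 else
    stats::uniroot(function(l) 1 - stats::ppois(n - 1, l) - 0.025,
                   c(1e-9, 10 * n + 10), tol = 1e-10)$root
  hi <- stats::uniroot(function(l) stats::ppois(n, l) - 0.025,
                       c(1e-9, 10 * n + 50), tol = 1e-10)$root
  c(lo, hi)
}

# ---- clonal / recombining genotype simulators for LD & trees -------

# all sites drawn on one shared genealogy: LD structure independent of
# physical distance
sim_clonal_gm <- function(n_strains, n_sites, chrom_len = 1e6,
                          chroms = "chrI", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- random_topology(paste0("s", seq_len(n_strains)))
  parts <- ape::prop.part(tr)
  labs <- attr(parts, "labels")
  clades <- lapply(parts, function(p) labs[p])
  clades <- clades[vapply(clades, length, 0) < n_strains]
  clades <- c(clades, as.list(labs))   # singletons
  strains <- paste0("s", seq_len(n_strains))
  total <- n_sites * length(chroms)
  g <- matrix(0, n_strains, total, dimnames = list(strains, NULL))
  sites <- data.frame(chrom = rep(chroms, each = n_sites),
                      pos = as.vector(replicate(length(chroms),
                        sort(sample.int(chrom_len, n_sites)))))
  pick <- sample(length(clades), total, replace = TRUE)
  for (s in seq_len(total))
    g[clades[[pick[s]]], s] <- 2
  genotype_matrix(g, sites)
}

# two independent genealogies; each site assigned to one of them by a
# Markov switch process along the chromosome at rate rho per bp
sim_recombining_gm <- function(n_strains, n_sites, chrom_len = 1e6,
                               rho = 1e-4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gm1 <- sim_clonal_gm(n_strains, n_sites, chrom_len)
  gm2 <- sim_clonal_gm(n_strains, n_sites, chrom_len)
  pos <- sort(sample.int(chrom_len, n_sites))
  which_g <- integer(n_sites)
  which_g[1] <- sample(1:2, 1)
  for (s in 2:n_sites) {
    p_switch <- 1 - exp(-rho * (pos[s] - pos[s - 1]))
    which_g[s] <- if (stats::runif(1) < p_switch)
      3 - which_g[s - 1] else which_g[s - 1]
  }
  g <- matrix(0, n_strains, n_sites,
              dimnames = list(rownames(gm1$geno), NULL))
  g[, which_g == 1] <- gm1$geno[, which_g == 1]
  g[, which_g == 2] <- gm2$geno[, which_g == 2]
  genotype_matrix(g, data.frame(chrom = "chrI", pos = pos))
}
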