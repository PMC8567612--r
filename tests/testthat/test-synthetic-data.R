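test_that("genome and divergence-profile validation rejects bad input", {
  expect_error(genome_spec(data.frame(name = "c", length = 0)),
               "lengths")
  expect_error(genome_spec(data.frame(name = "c", length = 100),
                           gc_content = 1.5), "gc_content")
  expect_error(genome_spec(data.frame(name = "c", length = 100),
                           masked = data.frame(chrom = "c", start = 50,
                                               end = 120)),
               "out of bounds")
  expect_error(genome_spec(
    data.frame(name = "c", length = 100),
    masked = data.frame(chrom = "c", start = c(0, 5), end = c(10, 20))),
    "overlap")
  g <- toy_genome(1000)
  expect_error(divergence_profile(
    data.frame(chrom = "chrI", start = 0, end = 500, rate = 0.1), g),
    "tile")
  expect_error(uniform_profile(g, 1.2), "rates")
  gm <- genome_spec(data.frame(name = "c", length = 100),
                    masked = data.frame(chrom = "c", start = 10, end = 40))
  expect_equal(callable_sites(gm), 70)
})

test_that("parental SNP counts follow the compartment binomial model", {
  g <- toy_genome(1e6)
  # zero rate -> zero SNPs
  expect_equal(nrow(simulate_parent_pair(g, uniform_profile(g, 0),
                                         seed = 1)$snps), 0)
  # 1 Mb at 3.3%: count within 3 binomial SDs of 33,000
  sd33 <- sqrt(1e6 * 0.033 * 0.967)
  for (s in 1:3) {
    n <- nrow(simulate_parent_pair(g, uniform_profile(g, 0.033),
                                   seed = s)$snps)
    expect_lt(abs(n - 33000), 3 * sd33)
  }
  # determinism under a fixed seed
  a <- simulate_parent_pair(g, uniform_profile(g, 0.002), seed = 42)
  b <- simulate_parent_pair(g, uniform_profile(g, 0.002), seed = 42)
  expect_identical(a$snps, b$snps)
  # positions strictly increasing, alleles differ, mask respected
  gm <- genome_spec(data.frame(name = "chrI", length = 1e5),
                    masked = data.frame(chrom = "chrI", start = 2e4,
                                        end = 4e4))
  pp <- simulate_parent_pair(gm, uniform_profile(gm, 0.01), seed = 5)
  expect_true(all(diff(pp$snps$pos) > 0))
  expect_true(all(pp$snps$a1 != pp$snps$a2))
  expect_false(any(pp$snps$pos >= 2e4 & pp$snps$pos < 4e4))
  # compartmentalized divergence lands SNPs where the rate is
  g2 <- toy_genome(2e5)
  prof <- divergence_profile(
    data.frame(chrom = "chrI", start = c(0, 1e5), end = c(1e5, 2e5),
               rate = c(0.03, 0)), g2)
  pp2 <- simulate_parent_pair(g2, prof, seed = 6)
  expect_true(all(pp2$snps$pos < 1e5))
})

test_that("achiasmate meioses conserve 2:2 segregation at every marker", {
  g <- toy_genome(5e4)
  pp <- simulate_parent_pair(g, uniform_profile(g, 0.002), seed = 2)
  for (s in 1:50) {
    tt <- simulate_tetrad(pp, meiosis_params(), seed = s)
    S <- tt$origins[["chrI"]]
    expect_true(all(colSums(S == "P1") == 2))
    # each spore's origin vector is constant along the chromosome
    expect_true(all(apply(S, 1, function(r) length(unique(r)) == 1)))
  }
  expect_equal(nrow(simulate_tetrad(pp, meiosis_params(), seed = 1)$events), 0)
})

test_that("a single crossover switches exactly two spores reciprocally", {
  g <- toy_genome(5e4)
  pp <- simulate_parent_pair(g, uniform_profile(g, 0.002), seed = 2)
  found <- 0
  for (s in 1:80) {
    tt <- simulate_tetrad(pp, meiosis_params(co_rate = 1), seed = s)
    if (sum(tt$events$kind == "CO") != 1 || !all(tt$events$visible)) next
    found <- found + 1
    S <- tt$origins[["chrI"]]
    pos <- pp$snps$pos
    # exhaustive scan of all origin-vector transitions
    switches <- which(vapply(seq_len(ncol(S) - 1), function(i)
      any(S[, i] != S[, i + 1]), TRUE))
    expect_length(switches, 1)
    d <- which(S[, switches] != S[, switches + 1])
    expect_length(d, 2)
    expect_setequal(S[d, switches], c("P1", "P2"))          # reciprocal
    expect_setequal(S[d, switches + 1], c("P1", "P2"))
    expect_equal(pos[switches], tt$events$inner_start)
    expect_equal(pos[switches + 1], tt$events$inner_end)
    expect_equal(sort(unname(d)),
                 as.integer(strsplit(tt$events$spores, ",")[[1]]))
    expect_true(all(colSums(S == "P1") == 2))               # still 2:2
  }
  expect_gte(found, 20)
})

test_that("an NCO tract covering k markers segregates 3:1 there, 2:2 elsewhere", {
  g <- toy_genome(5e4)
  pp <- simulate_parent_pair(g, uniform_profile(g, 0.002), seed = 2)
  found <- 0
  for (s in 1:60) {
    tt <- simulate_tetrad(pp, meiosis_params(nco_rate = 1), seed = s)
    ev <- tt$events
    if (nrow(ev) != 1 || ev$kind != "NCO" || ev$n_markers == 0) next
    found <- found + 1
    S <- tt$origins[["chrI"]]
    pos <- pp$snps$pos
    in_tract <- pos >= ev$inner_start & pos <= ev$inner_end
    expect_true(all(colSums(S[, in_tract, drop = FALSE] == "P1") %in% c(1, 3)))
    expect_true(all(colSums(S[, !in_tract, drop = FALSE] == "P1") == 2))
    expect_equal(sum(in_tract), ev$n_markers)
  }
  expect_gte(found, 15)
})

test_that("intratetrad mating restores or erases heterozygosity as expected", {
  g <- toy_genome(5e4)
  pp <- simulate_parent_pair(g, uniform_profile(g, 0.002), seed = 2)
  tt <- simulate_tetrad(pp, meiosis_params(), seed = 9)
  expect_equal(mean(intratetrad_mate(tt, "non-sister")$het), 1)
  expect_equal(mean(intratetrad_mate(tt, "sister")$het), 0)
  expect_error(intratetrad_mate(tt, "non-sister", spores = c(1, 2)),
               "sisters")
  expect_error(intratetrad_mate(tt, "sister", spores = c(1, 3)),
               "not meiosis-I sisters")
  # heterozygous fraction is non-increasing in CO rate (on average)
  het_at <- function(co_rate) {
    mean(vapply(1:40, function(s) {
      t1 <- simulate_tetrad(pp, meiosis_params(co_rate = co_rate),
                            seed = 100 + s)
      sp <- sample(c(sample(1:2, 1), sample(3:4, 1)))
      mean(intratetrad_mate(t1, "non-sister", spores = sp)$het)
    }, 0))
  }
  set.seed(7)
  h <- c(het_at(0), het_at(1), het_at(4))
  expect_equal(h[1], 1)
  expect_true(all(diff(h) < 0))
})

test_that("one CO leaves the non-sister diploid homozygous only distal to it", {
  # enumerating the chromatid pairings by hand: with one CO, the two
  # recombinant chromatids always end in different meiosis-I cells, so
  # (i) pairing a recombinant with the untouched chromatid of the
  # other homolog is heterozygous proximal to the breakpoint and
  # homozygous distal, while (ii) pairing the two recombinants is
  # heterozygous everywhere
  g <- toy_genome(5e4)
  pp <- simulate_parent_pair(g, uniform_profile(g, 0.002), seed = 2)
  found <- 0
  for (s in 1:60) {
    tt <- simulate_tetrad(pp, meiosis_params(co_rate = 1), seed = 200 + s)
    if (sum(tt$events$kind == "CO") != 1 || !all(tt$events$visible)) next
    found <- found + 1
    ev <- tt$events
    co_spores <- as.integer(strsplit(ev$spores, ",")[[1]])
    sa <- co_spores[co_spores <= 2]
    sb <- co_spores[co_spores >= 3]
    sb_sib <- setdiff(3:4, sb)
    proximal <- function(d) d$pos <= ev$inner_start
    distal <- function(d) d$pos >= ev$inner_end
    d1 <- intratetrad_mate(tt, "non-sister", spores = c(sa, sb_sib))
    expect_true(all(d1$het[proximal(d1)]))
    expect_true(all(!d1$het[distal(d1)]))
    d2 <- intratetrad_mate(tt, "non-sister", spores = c(sa, sb))
    expect_true(all(d2$het))
  }
  expect_gte(found, 15)
})

test_that("MA mutation counts and spectra follow the configured model", {
  g <- toy_genome(1e6, gc = 0.5)
  # mu = 0 -> no mutations
  p0 <- ma_params(mu = 0, n_lines = 5, generations = 100)
  expect_equal(nrow(simulate_ma_genealogy(g, p0, seed = 1)$snms), 0)
  # closed-form Poisson mean: 10 lines x 2000 gen x 1 Mb x 1e-8 = 200
  p1 <- ma_params(mu = 1e-8, n_lines = 10, generations = 2000,
                  at_bias = 1, ts_tv = 1)
  tot <- nrow(simulate_ma_genealogy(g, p1, seed = 3)$snms)
  expect_lt(abs(tot - 200), 3 * sqrt(200))
  # at_bias = 1 on a 50% GC genome: GC->AT and AT->GC counts equal
  p2 <- ma_params(mu = 2e-7, n_lines = 10, generations = 1000,
                  at_bias = 1, ts_tv = 1)
  sn <- simulate_ma_genealogy(g, p2, seed = 4)$snms
  n_ga <- sum(sn$class == "GC>AT"); n_ag <- sum(sn$class == "AT>GC")
  expect_lt(abs(n_ga - n_ag) / sqrt(n_ga + n_ag), 4)
  # Ts:Tv recovered in expectation at the study-like setting
  p3 <- ma_params(mu = 2e-7, n_lines = 10, generations = 1000,
                  ts_tv = 1.2)
  sn3 <- simulate_ma_genealogy(g, p3, seed = 5)$snms
  expect_lt(abs(ts_tv(sn3) - 1.2), 0.15)
  expect_true(all(sn3$ts == is_transition(sn3$ref, sn3$alt)))
  # masked regions receive no mutations
  gm <- genome_spec(data.frame(name = "chrI", length = 1e6),
                    masked = data.frame(chrom = "chrI", start = 0,
                                        end = 5e5))
  snm <- simulate_ma_genealogy(gm, p2, seed = 6)$snms
  expect_true(all(snm$pos >= 5e5))
  # het founder requires a het map
  expect_error(
    simulate_ma_genealogy(g, ma_params(founder_zygosity =
                                         "heterozygous-diploid")),
    "het_map")
})

test_that("heterozygous founders accumulate LOH tracts at the set rate", {
  g <- toy_genome(1e6)
  pp <- simulate_parent_pair(g, uniform_profile(g, 0.01), seed = 1)
  pars <- ma_params(mu = 1e-9, n_lines = 20, generations = 500,
                    founder_zygosity = "heterozygous-diploid",
                    loh_rate = 2e-3)
  ma <- simulate_ma_genealogy(g, pars, het_map = pp, seed = 2)
  lam <- 2e-3 * 500 * 20
  expect_lt(abs(nrow(ma$loh) - lam), 3 * sqrt(lam))
  expect_true(all(ma$loh$end > ma$loh$start))
})

test_that("simulated depths follow the Poisson-binomial read model", {
  # het site at depth 1000 with no error: balance near 0.5
  g <- matrix(1, 1, 1, dimnames = list(NULL, "s"))
  d <- simulate_depths(g, mean_depth = 1000, error_rate = 0, seed = 1)
  tot <- d$ref_depth + d$alt_depth
  expect_lt(abs(d$alt_depth / tot - 0.5), 3 * sqrt(0.25 / tot))
  # hom sites with no error: alt fraction exactly 0 or 1
  g2 <- matrix(c(0, 2), 2, 1, dimnames = list(NULL, "s"))
  d2 <- simulate_depths(g2, 50, 0, seed = 2)
  expect_equal(unname(d2$alt_depth[1, 1]), 0L)
  expect_equal(unname(d2$ref_depth[2, 1]), 0L)
  # determinism: bitwise-identical tables under a fixed seed
  g3 <- matrix(sample(0:2, 300, TRUE), 100, 3,
               dimnames = list(NULL, c("a", "b", "c")))
  expect_identical(simulate_depths(g3, 30, 0.01, seed = 7),
                   simulate_depths(g3, 30, 0.01, seed = 7))
})
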