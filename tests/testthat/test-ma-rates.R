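test_that("SNM filtering enforces exclusivity, depth and balance boundaries", {
  # 3 lines, homozygous-diploid founder; depths set by hand
  mk <- function(g, rd, ad, founder = 0, alt = "G") {
    calls <- make_calls(10, "A", alt, g, rd, ad,
                        c("line1", "line2", "line3"))
    filter_snms(calls, founder, "homozygous-diploid")
  }
  # clean line-exclusive het with balance 0.5
  expect_equal(nrow(mk(c(1, 0, 0), c(15, 30, 30), c(15, 0, 0))), 1)
  # variant in two lines -> excluded
  expect_equal(nrow(mk(c(1, 1, 0), c(15, 15, 30), c(15, 15, 0))), 0)
  # depth exactly 10 in one sample -> excluded (strict "more than 10")
  expect_equal(nrow(mk(c(1, 0, 0), c(5, 30, 30), c(5, 0, 0))), 0)
  # balance 0.39 -> excluded; 0.40 -> retained
  expect_equal(nrow(mk(c(1, 0, 0), c(61, 30, 30), c(39, 0, 0))), 0)
  expect_equal(nrow(mk(c(1, 0, 0), c(60, 30, 30), c(40, 0, 0))), 1)
  # multi-allelic site -> excluded
  expect_equal(nrow(mk(c(1, 0, 0), c(15, 30, 30), c(15, 0, 0),
                       alt = "G,T")), 0)
  # haploid background rejects het calls, accepts hom-hom
  c1 <- make_calls(10, "A", "G", c(2, 0, 0), c(0, 30, 30), c(30, 0, 0),
                   c("line1", "line2", "line3"))
  r <- filter_snms(c1, 0, "homozygous-haploid")
  expect_equal(r$zygosity_change, "hom>hom")
  expect_equal(r$class, "AT>GC")
  c2 <- make_calls(10, "A", "G", c(1, 0, 0), c(15, 30, 30), c(15, 0, 0),
                   c("line1", "line2", "line3"))
  expect_equal(nrow(filter_snms(c2, 0, "homozygous-haploid")), 0)
  # het founder: het->hom inside a detected LOH tract is excluded
  c3 <- make_calls(10, "A", "G", c(2, 1, 1), c(0, 15, 15), c(30, 15, 15),
                   c("line1", "line2", "line3"))
  loh <- data.frame(line = 1, chrom = "chrI", start = 0, end = 100)
  expect_equal(nrow(filter_snms(c3, 1, "heterozygous-diploid")), 1)
  expect_equal(nrow(filter_snms(c3, 1, "heterozygous-diploid",
                                loh_events = loh)), 0)
  # het->hom direction: the gained allele defines the substitution
  r3 <- filter_snms(c3, 1, "heterozygous-diploid")
  expect_equal(r3$zygosity_change, "het>hom")
  expect_equal(r3$class, "AT>GC")  # A/G het fixed for G
})

test_that("error-free simulated genealogies are recovered exactly by the filter", {
  g <- toy_genome(5e5, gc = 0.3)
  # haploid background: every mutation is a hom>hom call, recovery is
  # exact at any depth clearing the threshold
  ph <- ma_params(mu = 2e-8, n_lines = 8, generations = 1000,
                  founder_zygosity = "homozygous-haploid")
  mah <- simulate_ma_genealogy(g, ph, seed = 20)
  lch <- line_calls(mah, mean_depth = 40, error_rate = 0, seed = 23)
  goth <- filter_snms(lch$calls, lch$founder, "homozygous-haploid")
  wanth <- mah$snms[order(mah$snms$chrom, mah$snms$pos), ]
  expect_equal(nrow(goth), nrow(wanth))
  expect_equal(goth$pos, wanth$pos)
  # diploid background: heterozygous mutations additionally face the
  # allele-balance window, which binomial read sampling at moderate
  # depth fails ~20% of the time; at high depth recovery is exact
  pars <- ma_params(mu = 2e-8, n_lines = 8, generations = 1000,
                    founder_zygosity = "homozygous-diploid")
  ma <- simulate_ma_genealogy(g, pars, seed = 21)
  lc <- line_calls(ma, mean_depth = 500, error_rate = 0, seed = 22)
  got <- filter_snms(lc$calls, lc$founder, "homozygous-diploid")
  want <- ma$snms[order(ma$snms$chrom, ma$snms$pos), ]
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$pos, want$pos)
  expect_equal(got$line, want$line)
  expect_equal(got$class, want$class)
  expect_equal(got$ts, want$ts)
  # at moderate depth the balance window only ever removes hets
  lc2 <- line_calls(ma, mean_depth = 30, error_rate = 0, seed = 24)
  got2 <- filter_snms(lc2$calls, lc2$founder, "homozygous-diploid")
  expect_true(all(paste(got2$chrom, got2$pos) %in%
                    paste(want$chrom, want$pos)))
})

test_that("rate estimation reproduces the haploid-genealogy arithmetic", {
  # 85 mutations, 30 lines, 2037 generations, 93% of a 12.5-Mb genome
  est <- estimate_rate(85, n_lines = 30, generations = 2037,
                       callable_sites = 0.93 * 12.5e6, ploidy = 1)
  expect_equal(est$mu, 1.20e-10, tolerance = 0.005)
  # generation bookkeeping: 97 cycles x 21 generations
  expect_equal(ma_generations(97, 21), 2037)
  # the diploid denominator doubles the callable sites
  est2 <- estimate_rate(48, 19, 1920, 1.16e7, ploidy = 2)
  expect_equal(est2$mu, 48 / (19 * 1920 * 2 * 1.16e7))
  # zero mutations: mu = 0 with a one-sided upper bound
  est0 <- estimate_rate(0, 10, 100, 1e6, 1)
  expect_equal(est0$mu, 0)
  expect_equal(est0$ci[1], 0)
  expect_gt(est0$ci[2], 0)
})

test_that("the exact Poisson CI matches direct tail-probability inversion", {
  for (n in c(5, 22, 85, 200)) {
    est <- estimate_rate(n, 1, 1, 1, 1)   # unit denominator: CI on counts
    expect_equal(est$ci, oracle_poisson_ci(n), tolerance = 1e-6)
  }
  # frozen ratios for n = 85: CI / point = (0.799, 1.237)
  est <- estimate_rate(85, 30, 2037, 1.16e7, 1)
  expect_equal(est$ci / est$mu, c(0.7988, 1.2365), tolerance = 1e-3)
  expect_true(est$ci[1] <= est$mu && est$mu <= est$ci[2])
})

test_that("AT bias, equilibrium GC and their pooling follow the flux model", {
  # printed per-genealogy biases reproduce the printed equilibria
  expect_equal(equilibrium_gc(2.92), 0.255, tolerance = 0.002)
  expect_equal(equilibrium_gc(5.85), 0.146, tolerance = 0.002)
  expect_equal(equilibrium_gc(2.63), 0.276, tolerance = 0.002)
  expect_equal(equilibrium_gc(1), 0.5)
  # count-weighted pooling
  pooled <- pooled_bias(c(2.92, 5.85, 2.63), weights = c(85, 48, 53))
  expect_equal(pooled$bias, 3.6, tolerance = 0.01)
  expect_equal(pooled$equilibrium, 0.233, tolerance = 0.002)
  expect_equal(pooled_bias(5.85, weights = 48)$bias, 5.85)
  # bias from counts is composition-weighted
  snms <- data.frame(class = c(rep("GC>AT", 30), rep("AT>GC", 20),
                               rep("GC>GC", 7)),
                     ts = TRUE)
  be <- compute_at_bias(snms, c(n_gc = 3e5, n_at = 7e5))
  expect_equal(be$bias, (30 / 3e5) / (20 / 7e5))
  expect_equal(be$equilibrium, 1 / (1 + be$bias))
  # zero opposite flux: infinite bias, equilibrium 0
  be0 <- compute_at_bias(data.frame(class = "GC>AT", ts = TRUE),
                         c(n_gc = 1e5, n_at = 1e5))
  expect_true(is.infinite(be0$bias))
  expect_equal(be0$equilibrium, 0)
  # simulated genealogy recovers the configured bias
  g <- toy_genome(1e6, gc = 0.3)
  ma <- simulate_ma_genealogy(
    g, ma_params(mu = 2e-7, n_lines = 10, generations = 1000,
                 at_bias = 3.6), seed = 30)
  be2 <- compute_at_bias(ma$snms, base_composition(g))
  expect_equal(be2$bias, 3.6, tolerance = 0.15)
})

test_that("Ts:Tv counting handles definitions and edge cases", {
  snms <- data.frame(ref = c("A", "C", "A"), alt = c("G", "T", "T"))
  snms$ts <- is_transition(snms$ref, snms$alt)
  expect_equal(ts_tv(snms), 2)
  expect_true(is.infinite(ts_tv(data.frame(ts = c(TRUE, TRUE)))))
  # sampled ratio concentrates near the configured value
  g <- toy_genome(1e6)
  ma <- simulate_ma_genealogy(
    g, ma_params(mu = 2e-7, n_lines = 10, generations = 1000,
                 ts_tv = 1.2), seed = 31)
  expect_equal(ts_tv(ma$snms), 1.2, tolerance = 0.12)
})

test_that("LOH detection matches a run-length oracle and classifies ends", {
  het <- data.frame(chrom = "chrI", pos = c(10, 20, 30, 40, 50, 60))
  # line1: interstitial tract over sites 20-40 (same haplotype);
  # line2: terminal tract at the chromosome start; line3: single site
  gmat <- cbind(line1 = c(1, 0, 0, 0, 1, 1),
                line2 = c(2, 2, 1, 1, 1, 1),
                line3 = c(1, 1, 1, 2, 1, 1))
  scan <- detect_ma_loh(het, gmat, min_markers = 2)
  expect_equal(nrow(scan$events), 2)
  e1 <- scan$events[scan$events$line == 1, ]
  expect_equal(c(e1$start, e1$end), c(20, 41))
  expect_equal(e1$kind, "interstitial")
  expect_equal(e1$n_markers, 3)
  e2 <- scan$events[scan$events$line == 2, ]
  expect_equal(e2$kind, "terminal")
  # min_markers = 1 picks up the single-site event
  expect_equal(nrow(detect_ma_loh(het, gmat, min_markers = 1)$events), 3)
  # a run mixing the two haplotypes is not one event
  gm2 <- cbind(line1 = c(1, 0, 2, 0, 1, 1))
  expect_equal(nrow(detect_ma_loh(het, gm2, min_markers = 2)$events), 0)
  # no homozygous runs -> no events, rate 0
  all_het <- cbind(line1 = rep(1, 6))
  s0 <- detect_ma_loh(het, all_het, generations = 100)
  expect_equal(nrow(s0$events), 0)
  expect_equal(s0$rate, 0)
  # headline rate arithmetic: 22 events, 11 lines, 2016 generations
  expect_equal(loh_rate(22, 11, 2016), 9.9e-4, tolerance = 0.005)
})

test_that("simulated LOH tracts are recovered with correct bounds", {
  g <- toy_genome(5e5)
  pp <- simulate_parent_pair(g, uniform_profile(g, 0.01), seed = 40)
  pars <- ma_params(mu = 0, n_lines = 6, generations = 500,
                    founder_zygosity = "heterozygous-diploid",
                    loh_rate = 2e-3,
                    loh_length = list(family = "uniform", min = 3000,
                                      max = 10000))
  ma <- simulate_ma_genealogy(g, pars, het_map = pp, seed = 41)
  lc <- line_calls(ma, mean_depth = 40, seed = 42)
  het_rows <- which(lc$founder == 1)
  scan <- detect_ma_loh(lc$calls$sites[het_rows, c("chrom", "pos")],
                        lc$calls$genotype[het_rows, ], min_markers = 2)
  # each true tract covering >= 2 het sites appears with exact bounds
  for (i in seq_len(nrow(ma$loh))) {
    tr <- ma$loh[i, ]
    covered <- pp$snps$pos[pp$snps$pos >= tr$start & pp$snps$pos < tr$end]
    if (length(covered) < 2) next
    hit <- scan$events[scan$events$line == tr$line &
                         scan$events$start == min(covered), ]
    expect_equal(nrow(hit), 1)
    expect_equal(hit$end, max(covered) + 1)
    expect_equal(hit$n_markers, length(covered))
  }
  expect_gt(nrow(ma$loh), 2)
})
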