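# Windowed diversity statistics, FST and the selection scans.

test_that("closed-form and boundary cases of the diversity statistics", {
  # monomorphic window: pi = theta_w = 0, D undefined
  p <- make_panel(matrix(0L, 5, 6))
  p$geno[, 1] <- 0L
  w <- data.frame(chrom = "Ca1", start = 0, end = 1000)
  st <- window_diversity(p, w)
  expect_equal(st$pi, 0)
  expect_equal(st$theta_w, 0)
  expect_true(is.na(st$tajima_d))
  expect_true(is.na(st$fuli_dstar))

  # n = 4 haplotypes, S = 3, L = 100: theta_w = 3 / (11/6) / 100
  g <- matrix(0L, 3, 2)
  g[1, 1] <- 2L; g[2, 2] <- 2L; g[3, 1] <- 1L; g[3, 2] <- 1L
  p2 <- make_panel(g, pos = c(10L, 20L, 30L))
  w2 <- data.frame(chrom = "Ca1", start = 0, end = 100)
  st2 <- window_diversity(p2, w2)
  expect_equal(st2$theta_w, 3 / (11 / 6) / 100, tolerance = 1e-9)
  expect_equal(st2$S, 3)

  # haploid sample size below 4 is rejected
  expect_error(window_diversity(make_panel(matrix(0L, 2, 1)), w), "4")
})

test_that("pi and theta_w are invariant to sample order and allele swap", {
  set.seed(31)
  g <- matrix(sample(c(0L, 1L, 2L, NA), 200 * 10, TRUE,
                     prob = c(0.5, 0.05, 0.4, 0.05)), 200, 10)
  p <- make_panel(g, pos = seq(0L, by = 40L, length.out = 200))
  w <- data.frame(chrom = "Ca1", start = 0, end = 8000)
  st <- window_diversity(p, w)
  p_perm <- p
  perm <- sample(10)
  p_perm$geno <- p$geno[, perm]
  p_perm$samples <- p$samples[perm, ]
  expect_equal(window_diversity(p_perm, w)$pi, st$pi)
  p_swap <- p
  p_swap$geno <- 2L - p$geno
  st_swap <- window_diversity(p_swap, w)
  expect_equal(st_swap$pi, st$pi)
  expect_equal(st_swap$theta_w, st$theta_w)
})

test_that("window statistics match the straight-from-formula oracle", {
  set.seed(17)
  for (rep in 1:10) {
    n <- 10
    g <- matrix(sample(c(0L, 1L, 2L, NA), 60 * n, TRUE,
                       prob = c(0.45, 0.1, 0.4, 0.05)), 60, n)
    p <- make_panel(g, pos = sort(sample(0:4999, 60)))
    w <- data.frame(chrom = "Ca1", start = 0, end = 5000)
    st <- window_diversity(p, w)
    o <- oracle_window_stats(g, 5000)
    expect_equal(st$pi, o$pi, tolerance = 1e-9)
    expect_equal(st$theta_w, o$theta_w, tolerance = 1e-9)
    expect_equal(st$S, o$S)
    expect_equal(st$eta1, o$eta1)
    expect_equal(st$tajima_d, o$tajima_d, tolerance = 1e-9)
    expect_equal(st$fuli_dstar, o$fuli_dstar, tolerance = 1e-9)
  }
})

test_that("FST matches hand computation and behaves at the extremes", {
  # identical frequencies -> ~0; fixed differences -> 1
  gA <- matrix(c(2L, 0L), 5, 4)
  gB <- gA
  pAB <- make_panel(cbind(gA, gB))
  w <- data.frame(chrom = "Ca1", start = 0, end = 1000)
  ids <- pAB$samples$sample
  f0 <- window_fst(pAB, w, ids[1:4], ids[5:8])
  # with frequencies forced identical, Hudson's within-group correction
  # makes the estimate slightly negative (order -1/(n-1)), never positive
  expect_lte(f0, 0)
  expect_gt(f0, -0.2)
  gA2 <- matrix(0L, 5, 4); gB2 <- matrix(2L, 5, 4)
  p2 <- make_panel(cbind(gA2, gB2))
  expect_equal(window_fst(p2, w, ids[1:4], ids[5:8]), 1)

  # 5-site toy window vs the per-site ratio-of-sums arithmetic
  set.seed(23)
  gA3 <- matrix(sample(c(0L, 2L), 5 * 6, TRUE, prob = c(0.9, 0.1)), 5, 6)
  gB3 <- matrix(sample(c(0L, 2L), 5 * 6, TRUE, prob = c(0.1, 0.9)), 5, 6)
  p3 <- make_panel(cbind(gA3, gB3))
  ids3 <- p3$samples$sample
  got <- window_fst(p3, w, ids3[1:6], ids3[7:12])
  expect_equal(got, oracle_fst(gA3, gB3), tolerance = 1e-9)

  expect_error(window_fst(p3, w, ids3[1], ids3[7:12]), "2 samples")
})

test_that("FST of a random split of one group is near zero", {
  cfg <- panel_config(chrom_lengths = c(Ca1 = 500000), n_samples = 20,
                      n_subpops = 1, selfing = 0, seed = 41)
  g <- simulate_genome(cfg)
  sim <- simulate_panel(g, cfg)
  ids <- sim$panel$samples$sample
  set.seed(1)
  half <- sample(ids, 10)
  w <- data.frame(chrom = "Ca1", start = 0, end = 500000)
  f <- window_fst(sim$panel, w, half, setdiff(ids, half))
  expect_lt(abs(f), 0.02)
})

test_that("neutral simulations satisfy the pi/theta_w and Tajima's D bands", {
  stats <- t(vapply(1:20, function(s) {
    cfg <- panel_config(chrom_lengths = c(Ca1 = 500000), n_samples = 20,
                        n_subpops = 1, selfing = 0, indel_fraction = 0,
                        theta = 0.002, seed = 9000 + s)
    g <- simulate_genome(cfg)
    sim <- simulate_panel(g, cfg)
    st <- window_diversity(sim$panel, make_windows(g, 10000))
    c(pi = stats::weighted.mean(st$pi, st$L),
      tw = stats::weighted.mean(st$theta_w, st$L),
      D = mean(st$tajima_d, na.rm = TRUE))
  }, numeric(3)))
  expect_gt(mean(stats[, "pi"]) / mean(stats[, "tw"]), 0.9)
  expect_lt(mean(stats[, "pi"]) / mean(stats[, "tw"]), 1.1)
  expect_lt(abs(mean(stats[, "D"])), 0.3)
})

test_that("differentiation scan handles forced and empty overlap", {
  st <- data.frame(chrom = "Ca1", start = (0:9) * 10000,
                   end = (1:10) * 10000)
  st$fst <- c(0.9, rep(0.1, 9))
  st$dpi <- c(0.5, rep(0.01, 9))
  r <- differentiation_scan(st, top_fraction = 0.1)
  expect_equal(nrow(r), 1)
  expect_equal(r$start, 0)
  expect_equal(r$class, "differentiation")

  st$fst <- c(0.9, rep(0.1, 9))
  st$dpi <- c(0.01, 0.5, rep(0.01, 8))   # disjoint top sets
  r2 <- differentiation_scan(st, top_fraction = 0.1)
  expect_equal(nrow(r2), 0)
  expect_error(differentiation_scan(st, top_fraction = 0), "top_fraction")
})

test_that("differentiation scan covers a planted subpopulation sweep", {
  cover <- vapply(1:5, function(s) {
    cfg <- panel_config(chrom_lengths = c(Ca1 = 2000000), n_samples = 20,
                        n_subpops = 2, divergence = 0.1,
                        admix_alpha = 0.05, selfing = 0,
                        indel_fraction = 0,
                        sweeps = data.frame(chrom = "Ca1", start = 900000,
                                            end = 1000000, factor = 0.05,
                                            subpop = 1),
                        seed = 600 + s)
    g <- simulate_genome(cfg)
    sim <- simulate_panel(g, cfg)
    grpA <- rownames(sim$truth$Q0)[sim$truth$Q0[, 1] > 0.5]
    grpB <- setdiff(sim$panel$samples$sample, grpA)
    st <- diversity_stats(sim$panel, make_windows(g, 10000), grpA, grpB)
    reg <- differentiation_scan(st, top_fraction = 0.10)
    if (!nrow(reg)) return(0)
    sum(pmax(0, pmin(reg$end, 1000000) - pmax(reg$start, 900000))) / 100000
  }, numeric(1))
  expect_gte(sum(cover >= 0.8), 4)
})

test_that("Tajima region scan finds planted sweeps and balancing regions", {
  hits_neg <- 0; hits_pos <- 0
  for (s in 1:5) {
    cfg <- panel_config(chrom_lengths = c(Ca1 = 2000000), n_samples = 20,
                        n_subpops = 1, selfing = 0, indel_fraction = 0,
                        sweeps = data.frame(chrom = "Ca1", start = 800000,
                                            end = 1000000, factor = 0.1,
                                            subpop = NA),
                        balancing = data.frame(chrom = "Ca1",
                                               start = 1400000,
                                               end = 1600000,
                                               strength = 0.9),
                        seed = 820 + s)
    g <- simulate_genome(cfg)
    sim <- simulate_panel(g, cfg)
    st <- window_diversity(sim$panel, make_windows(g, 10000))
    set.seed(1)
    neg <- tajima_region_scan(st, "negative", min_span = 150000)
    pos <- tajima_region_scan(st, "positive", min_span = 150000)
    if (nrow(neg) && any(pmin(neg$end, 1000000) -
                           pmax(neg$start, 800000) > 0))
      hits_neg <- hits_neg + 1
    if (nrow(pos) && any(pmin(pos$end, 1600000) -
                           pmax(pos$start, 1400000) > 0))
      hits_pos <- hits_pos + 1
    # mean D strictly negative inside the planted sweep
    inswp <- st$start >= 800000 & st$end <= 1000000
    expect_lt(mean(st$tajima_d[inswp], na.rm = TRUE), 0)
  }
  expect_gte(hits_neg, 4)
  expect_gte(hits_pos, 4)
})

test_that("the scan is calibrated on neutral panels", {
  n_regions <- vapply(1:10, function(s) {
    cfg <- panel_config(chrom_lengths = c(Ca1 = 1000000), n_samples = 20,
                        n_subpops = 1, selfing = 0, indel_fraction = 0,
                        seed = 4000 + s)
    g <- simulate_genome(cfg)
    sim <- simulate_panel(g, cfg)
    st <- window_diversity(sim$panel, make_windows(g, 10000))
    set.seed(1)
    nrow(tajima_region_scan(st, "negative", min_span = 150000))
  }, numeric(1))
  # far fewer significant regions than alpha x windows (0.05 x 100 = 5)
  expect_lte(mean(n_regions), 5)
})
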