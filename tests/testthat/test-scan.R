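test_that("window enumeration drops trailing partial windows", {
  cfg <- scan_config()
  w <- make_windows(data.frame(contig = "chr1", length = 250000), cfg)
  expect_equal(nrow(w), 8L)  # floor((250k - 100k)/20k) + 1
  expect_equal(w$start, seq(0, 140000, by = 20000))
  expect_equal(w$end, w$start + 100000)

  expect_warning(
    w0 <- make_windows(data.frame(contig = "chr1", length = 99999), cfg))
  expect_equal(nrow(w0), 0L)

  w1 <- make_windows(data.frame(contig = "chr1", length = 100000), cfg)
  expect_equal(nrow(w1), 1L)
  expect_equal(c(w1$start, w1$end), c(0, 100000))
})

test_that("window diversity equals the all-pairs chromosome oracle", {
  cfg <- scan_config(min_callable_sites = 1)

  # zero segregating sites
  gm0 <- make_gm(matrix(0L, 0, 9), pos = integer(), contig_len = 200000,
                 ref = character(), alt = character())
  expect_equal(window_pi(gm0, "highland", "chr1", 0, 100000, cfg), 0)

  # single site, 4 alt among 8 highland chromosomes, 100000 callable:
  # site pi = 2*4*4/(8*7) = 16/28
  geno <- matrix(0L, 1, 9)
  geno[1, 1:4] <- 1L   # the four highland samples het -> k = 4 of n = 8
  gm <- make_gm(geno, pos = 50L, contig_len = 100000)
  expect_equal(window_pi(gm, "highland", "chr1", 0, 100000, cfg),
               (16 / 28) / 100000)
  expect_equal(16 / 28, pi_allpairs(geno[1, 1:4]))

  # frequency-based estimator equals exhaustive pairwise comparison
  set.seed(7)
  for (i in 1:50) {
    g <- sample(0:2, 6, replace = TRUE)  # 12 chromosomes
    expect_equal(2 * sum(g) * (12 - sum(g)) / (12 * 11), pi_allpairs(g))
  }
  # including missing genotypes
  for (i in 1:30) {
    g <- sample(c(0:2, NA), 6, replace = TRUE)
    m <- matrix(g, 1)
    got <- altisweep:::site_pi(m)
    expect_equal(got, pi_allpairs(g))
  }
})

test_that("windowed F_ST matches the literal Weir-Cockerham transcription", {
  # fixed difference -> 1 (exact with balanced sizes, 1e-12 otherwise)
  scheme8 <- default_samples()[-9, ]
  gm_bal <- make_gm(matrix(c(rep(2L, 4), rep(0L, 4)), 1, 8), pos = 10L,
                    contig_len = 100000, scheme = scheme8)
  expect_identical(window_fst(gm_bal, "chr1", 0, 100000), 1)
  geno <- matrix(c(rep(2L, 4), rep(0L, 5)), 1, 9)
  gm <- make_gm(geno, pos = 10L, contig_len = 100000)
  expect_equal(window_fst(gm, "chr1", 0, 100000), 1, tolerance = 1e-12)

  # window of sites monomorphic across both classes is ineligible
  gmono <- make_gm(matrix(2L, 3, 9), contig_len = 100000)
  expect_true(is.na(window_fst(gmono, "chr1", 0, 100000)))

  # randomized windows, 4 highland vs 5 lowland diploids, with missingness
  set.seed(13)
  for (i in 1:60) {
    ns <- sample(5:50, 1)
    geno <- matrix(sample(0:2, ns * 9, replace = TRUE), ns, 9)
    if (i %% 3 == 0) geno[runif(length(geno)) < 0.1] <- NA_integer_
    gm <- make_gm(geno, pos = sort(sample.int(90000, ns)), contig_len = 100000)
    got <- window_fst(gm, "chr1", 0, 100000)
    # the window uses only sites with a called genotype in every sample
    complete <- rowSums(is.na(geno)) == 0L
    geno_c <- geno[complete, , drop = FALSE]
    want <- wc_fst_literal(geno_c[, 1:4, drop = FALSE],
                           geno_c[, 5:9, drop = FALSE])
    if (is.na(want)) expect_true(is.na(got)) else expect_equal(got, want,
                                                               tolerance = 1e-12)
  }
})

test_that("diversity ratio orientation marks highland diversity loss", {
  expect_equal(pi_ratio(0.001, 0.001), 1)
  expect_equal(pi_ratio(0.0001, 0.001), 10)
  expect_equal(pi_ratio(0.0001, 0.001, "target_over_contrast"), 0.1)
  expect_true(is.na(pi_ratio(0, 0.001)))
  expect_true(is.na(pi_ratio(0, 0, "target_over_contrast")))
})

test_that("empirical percentiles follow the average-rank convention", {
  expect_equal(empirical_percentiles(c(0.1, 0.2, 0.3, 0.4, 0.5)),
               c(20, 40, 60, 80, 100))
  n <- 7
  expect_equal(empirical_percentiles(rep(3.3, n)),
               rep((n + 1) / (2 * n) * 100, n))
  expect_equal(empirical_percentiles(42), 100)

  set.seed(17)
  for (i in 1:20) {
    v <- sample(round(rnorm(30), 1), 30, replace = TRUE)
    got <- empirical_percentiles(v)
    expect_equal(got, percentile_naive(v))
    # monotone, ties share a percentile
    o <- order(v)
    expect_true(all(diff(got[o]) >= 0))
  }
})

test_that("joint outlier flagging matches a naive double-sort oracle", {
  mk <- function(fst, ratio) {
    data.frame(contig = "chr1", start = seq_along(fst) * 1000,
               end = seq_along(fst) * 1000 + 500,
               fst = fst, pi_ratio = ratio, eligible = TRUE)
  }
  set.seed(19)
  w <- mk(runif(100), runif(100))
  out <- joint_outliers(w, scan_config(top_fraction = 0.05))
  expect_equal(sum(out$outlier), 5L)

  # a window in both marginal top-5% tails is flagged in both modes
  for (i in 1:10) {
    w <- mk(runif(60), runif(60))
    jp <- joint_outliers(w, scan_config(top_fraction = 0.05))
    # an empty marginal intersection is a legitimate (warned) outcome
    mi <- suppressWarnings(
      joint_outliers(w, scan_config(top_fraction = 0.05,
                                    outlier_mode = "marginal_intersection")))
    top_f <- rank(w$fst) > 57   # naive: top 3 of 60 by sorting
    top_r <- rank(w$pi_ratio) > 57
    both <- which(top_f & top_r)
    expect_true(all(mi$outlier[both]))
    expect_true(all(jp$outlier[both]))
    expect_equal(which(mi$outlier), both)
  }

  expect_warning(out0 <- joint_outliers(mk(rep(1, 10), rep(1, 10)),
                                        scan_config()))
  expect_equal(sum(out0$outlier), 0L)
})

test_that("region merging follows the 200-kb inclusive gap rule", {
  cfg <- scan_config()
  w2 <- data.frame(contig = "chr1", start = c(0, 280000),
                   end = c(100000, 380000))
  m <- merge_regions(w2, cfg)   # gap 180 kb < 200 kb
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(0, 380000))

  w3 <- data.frame(contig = "chr1", start = c(0, 400000),
                   end = c(100000, 500000))  # gap 300 kb
  expect_equal(nrow(merge_regions(w3, cfg)), 2L)

  w4 <- data.frame(contig = "chr1", start = c(0, 300000),
                   end = c(100000, 400000))  # gap exactly 200 kb
  expect_equal(nrow(merge_regions(w4, cfg)), 1L)

  # random window sets: disjoint, order-invariant, idempotent, oracle-equal
  set.seed(23)
  for (i in 1:25) {
    n <- sample(2:30, 1)
    starts <- sort(sample(seq(0, 5e6, by = 20000), n))
    w <- data.frame(contig = sample(c("chr1", "chr2"), n, replace = TRUE),
                    start = starts, end = starts + 100000)
    m1 <- merge_regions(w, cfg)
    m2 <- merge_regions(w[sample(n), ], cfg)
    expect_equal(m1[c("contig", "start", "end")], m2[c("contig", "start", "end")])
    again <- merge_regions(m1[c("contig", "start", "end")], cfg)
    expect_equal(again[c("contig", "start", "end")],
                 m1[c("contig", "start", "end")])
    for (ctg in unique(m1$contig)) {
      r <- m1[m1$contig == ctg, ]
      if (nrow(r) > 1) expect_true(all(r$start[-1] > r$end[-nrow(r)]))
    }
    oracle <- merge_regions_naive(w, cfg$merge_gap)
    oracle <- oracle[order(oracle$contig, oracle$start), ]
    expect_equal(m1$start, oracle$start)
    expect_equal(m1$end, oracle$end)
  }
})

test_that("gene-to-region assignment uses 1-bp overlap of gene spans", {
  mk_genes <- function(df) {
    gene_models(
      genes = data.frame(gene_id = df$id, name = df$id, source = "t",
                         contig = df$contig, strand = "+",
                         start = df$start, end = df$end),
      transcripts = data.frame(tx_id = paste0(df$id, ".1"), gene_id = df$id),
      exons = data.frame(tx_id = paste0(df$id, ".1"), contig = df$contig,
                         start = df$start, end = df$end),
      cds = data.frame(tx_id = character(), contig = character(),
                       start = integer(), end = integer())
    )
  }
  regions <- data.frame(contig = "chr1", start = 1000, end = 2000)
  g <- mk_genes(data.frame(id = c("IN", "EDGE", "OUT"), contig = "chr1",
                           start = c(1200, 500, 2500), end = c(1400, 1001, 3000)))
  got <- genes_in_regions(regions, g)
  expect_setequal(got[[1]], c("IN", "EDGE"))

  # brute-force overlap oracle on random intervals
  set.seed(29)
  for (i in 1:10) {
    nr <- 5; ng <- 40
    rs <- sort(sample(1:100000, nr)) ; re <- rs + sample(1000:20000, nr)
    gs <- sample(1:120000, ng); ge <- gs + sample(100:5000, ng)
    regions <- data.frame(contig = "chr1", start = rs, end = re)
    g <- mk_genes(data.frame(id = sprintf("G%02d", 1:ng), contig = "chr1",
                             start = gs, end = ge))
    got <- genes_in_regions(regions, g)
    for (r in seq_len(nr)) {
      want <- sort(sprintf("G%02d", which(gs < re[r] & ge > rs[r])))
      expect_equal(got[[r]], want)
    }
  }
})

test_that("sweep_scan returns a classed fit with methods", {
  cfg <- sim_config(genome_length = 4e6,
                    sweep_intervals = list(list("chr1", 1.8e6, 2.1e6)),
                    seed = 3)
  sim <- simulate_cohort(cfg)
  sc <- sweep_scan(sim$matrix)
  expect_s3_class(sc, "sweep_scan")
  expect_output(print(sc), "outlier regions")
  expect_output(print(summary(sc)), "F_ST")
  expect_gt(nrow(sc$regions), 0)
  # percentile fields absent (NA) on ineligible windows
  inel <- !sc$windows$eligible
  if (any(inel)) expect_true(all(is.na(sc$windows$pct_joint[inel])))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(sc))
})
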