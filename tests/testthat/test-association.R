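# scheme columns: TI09 TI32 QH11 QH16 | XJ24 XJ30 IM06 IM07 RKWL
pattern_gm <- function(...) {
  rows <- list(...)
  make_gm(do.call(rbind, rows))
}

test_that("highland pattern filter applies the Tibet/Qinghai/lowland rules", {
  gm <- pattern_gm(
    c(2, 2, 1, 2, 0, 0, 0, 0, 0),  # passes scan and strict
    c(2, 2, 0, 2, 0, 0, 0, 0, 0),  # Qinghai hom-ref -> fails both
    c(2, 2, 1, 1, 0, 0, 0, 1, 0),  # 4 hom-ref lowland, one het -> scan only
    c(2, 1, 1, 2, 0, 0, 0, 0, 0),  # Tibet het -> fails both
    c(2, 2, 2, 2, 0, 0, 0, 0, 2)   # lowland hom-alt -> fails both
  )
  expect_equal(pattern_filter(gm, "scan"), c(1L, 3L))
  expect_equal(pattern_filter(gm, "strict"), 1L)

  # missing genotypes never satisfy a requirement
  gm_na <- pattern_gm(c(2, NA, 1, 2, 0, 0, 0, 0, 0))
  expect_length(pattern_filter(gm_na, "scan"), 0L)

  # strict hits are always a subset of scan hits
  set.seed(47)
  for (i in 1:20) {
    g <- random_gm(50, miss = 0.05)
    expect_true(all(pattern_filter(g, "strict") %in% pattern_filter(g, "scan")))
  }

  no_tibet <- default_samples()
  no_tibet$subpop[no_tibet$subpop == "Tibet"] <- "Qinghai"
  gm_bad <- make_gm(matrix(0L, 2, 9), scheme = no_tibet)
  expect_error(pattern_filter(gm_bad), class = "altisweep_input_error")
})

test_that("allelic chi-square matches the textbook 2x2 formula", {
  # highland 16 alt / 0 ref vs lowland 0 alt / 20 ref (panel-like sizes):
  # chi2 = 36 * (16*20)^2 / (16*20*16*20) = 36
  scheme <- data.frame(
    sample_id = sprintf("S%02d", 1:18),
    subpop = rep(c("Tibet", "Xinjiang"), c(8, 10)))
  gm <- make_gm(matrix(c(rep(2L, 8), rep(0L, 10)), 1), scheme = scheme)
  r <- allelic_chisq(gm, 1)
  expect_identical(r$chi2, 36)
  expect_identical(r$freq_diff, 1)
  expect_equal(r$p, stats::pchisq(36, 1, lower.tail = FALSE))

  # equal frequencies -> chi2 0, p 1
  gm_eq <- make_gm(matrix(1L, 1, 9))
  r_eq <- allelic_chisq(gm_eq, 1)
  expect_equal(r_eq$chi2, 0)
  expect_equal(r_eq$p, 1)

  # random tables vs stats::chisq.test without correction
  set.seed(53)
  for (i in 1:40) {
    g <- random_gm(1, miss = 0.1)
    r <- allelic_chisq(gm = g, site = 1)
    tab <- r$table
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      expect_equal(r$chi2, 0)
    } else {
      want <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      expect_equal(r$chi2, unname(want$statistic), tolerance = 1e-10)
      expect_equal(r$p, want$p.value, tolerance = 1e-10)
    }
  }

  # invariance under allele relabelling
  g1 <- make_gm(matrix(c(2, 2, 1, 2, 0, 0, 1, 0, 0), 1))
  g2 <- make_gm(matrix(2L - c(2L, 2L, 1L, 2L, 0L, 0L, 1L, 0L, 0L), 1))
  expect_equal(allelic_chisq(g1, 1)$chi2, allelic_chisq(g2, 1)$chi2)
  expect_equal(allelic_chisq(g1, 1)$freq_diff, allelic_chisq(g2, 1)$freq_diff)
})

test_that("r-squared estimators agree with haplotype-frequency arithmetic", {
  # phased haplotype counts (AB, ab, Ab, aB) = (4, 4, 1, 1):
  # D = 0.4 - 0.25 = 0.15, r2 = 0.0225/0.0625 = 0.36
  expect_equal(r2_phased(4, 4, 1, 1), 0.36)

  # identical genotype columns -> r2 = 1 in every estimator
  g <- c(0L, 1L, 2L, 0L, 2L, 1L, 0L, 2L, 1L)
  expect_equal(r2_em(g, g), 1, tolerance = 1e-9)
  expect_equal(r2_composite(g, g), 1)

  # no double heterozygotes: EM equals direct phased counting
  set.seed(59)
  n_checked <- 0
  while (n_checked < 100) {
    g1 <- sample(0:2, 10, replace = TRUE)
    g2 <- sample(0:2, 10, replace = TRUE)
    if (any(g1 == 1 & g2 == 1)) next
    if (length(unique(g1)) == 1 || length(unique(g2)) == 1) next
    n_checked <- n_checked + 1
    # unambiguous haplotype reconstruction
    n_AB <- n_ab <- n_Ab <- n_aB <- 0
    for (k in seq_along(g1)) {
      a <- g1[k]; b <- g2[k]
      if (a == 1) {
        hapsA <- c(1, 0)
        hapsB <- c(b / 2, b / 2)
      } else if (b == 1) {
        hapsA <- c(a / 2, a / 2)
        hapsB <- c(1, 0)
      } else {
        hapsA <- c(a / 2, a / 2)
        hapsB <- c(b / 2, b / 2)
      }
      for (h in 1:2) {
        if (hapsA[h] == 1 && hapsB[h] == 1) n_AB <- n_AB + 1
        else if (hapsA[h] == 1) n_Ab <- n_Ab + 1
        else if (hapsB[h] == 1) n_aB <- n_aB + 1
        else n_ab <- n_ab + 1
      }
    }
    expect_equal(r2_em(g1, g2), r2_phased(n_AB, n_ab, n_Ab, n_aB),
                 tolerance = 1e-8)
  }

  # symmetry and allele-swap invariance
  set.seed(61)
  for (i in 1:30) {
    g1 <- sample(0:2, 12, replace = TRUE)
    g2 <- sample(0:2, 12, replace = TRUE)
    r_a <- r2_em(g1, g2); r_b <- r2_em(g2, g1)
    if (is.na(r_a)) {
      expect_true(is.na(r_b))
    } else {
      expect_equal(r_a, r_b, tolerance = 1e-8)
      expect_equal(r2_em(2L - g1, g2), r_a, tolerance = 1e-8)
    }
  }

  # monomorphic site -> undefined
  expect_true(is.na(r2_em(rep(0L, 9), g)))
  res <- pairwise_r2(make_gm(rbind(rep(0L, 9), g)), 1:2)
  expect_true(is.na(res$r2))
})

test_that("LD pruning removes linked SNPs and survives a post-audit", {
  # duplicated column: exactly one kept
  g <- c(0L, 1L, 2L, 0L, 2L, 1L, 0L, 2L, 1L)
  gm_dup <- make_gm(rbind(g, g))
  expect_length(ld_prune(gm_dup), 1L)

  # mutually independent columns all kept
  set.seed(67)
  repeat {
    gm_ind <- random_gm(6)
    pr <- pairwise_r2(gm_ind, 1:6, method = "composite")
    if (all(pr$r2 <= 0.2, na.rm = TRUE)) break
  }
  expect_length(ld_prune(gm_ind), 6L)

  # random matrices: exhaustive pair re-check among kept sites
  for (i in 1:5) {
    gm <- random_gm(60, miss = 0.05)
    kept <- ld_prune(gm, window_snps = 50, step_snps = 5, r2_threshold = 0.2)
    idx_all <- seq_len(nrow(gm$sites))
    starts <- seq(1, length(idx_all), by = 5)
    for (st in starts) {
      win <- intersect(idx_all[st:min(st + 49, length(idx_all))], kept)
      if (length(win) < 2) next
      pr <- pairwise_r2(gm, win, method = "composite")
      expect_true(all(is.na(pr$r2) | pr$r2 <= 0.2))
    }
  }
})

test_that("complete-LD groups are the r2 = 1 connected components", {
  g <- c(0L, 1L, 2L, 0L, 2L, 1L, 0L, 2L, 1L)
  gm3 <- make_gm(rbind(g, g, g))
  groups <- complete_ld_groups(pairwise_r2(gm3, 1:3))
  expect_equal(groups, list(1:3))

  # transitivity on complete data: chain a-b, b-c implies one group
  gm_chain <- make_gm(rbind(g, g, 2L - g))  # allele swap keeps r2 = 1
  grp <- complete_ld_groups(pairwise_r2(gm_chain, 1:3))
  expect_equal(grp, list(1:3))

  # with missing data, components follow the computed edge list; compare
  # against an independent graph-component oracle
  skip_if_not_installed("igraph")
  set.seed(71)
  for (i in 1:10) {
    gm <- random_gm(12, miss = 0.25)
    pr <- pairwise_r2(gm, seq_len(12))
    got <- complete_ld_groups(pr)
    edges <- pr[!is.na(pr$r2) & pr$r2 >= 1 - 1e-9, ]
    if (!nrow(edges)) {
      expect_equal(got, list())
    } else {
      gr <- igraph::graph_from_data_frame(
        edges[c("site_i", "site_j")], directed = FALSE)
      comp <- igraph::components(gr)
      want <- split(as.integer(names(comp$membership)), comp$membership)
      want <- lapply(unname(want), sort)
      want <- want[order(vapply(want, min, numeric(1)))]
      got_sorted <- got[order(vapply(got, min, numeric(1)))]
      expect_equal(got_sorted, want)
    }
  }
})
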