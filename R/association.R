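#' Highland genotype-pattern filter for candidate SNPs
#'
#' Scan mode (pattern observed in the nine-genome data): every Tibet sample
#' homozygous alternative; at least three lowland samples homozygous
#' reference with no lowland homozygous alternative; no Qinghai sample
#' homozygous reference. Strict mode (re-sequencing validation): as scan
#' mode, but every lowland sample must be homozygous reference. A missing
#' genotype never satisfies a requirement placed on its sample.
#'
#' @param gm a [geno_matrix]
#' @param mode `"scan"` or `"strict"`
#' @param min_lowland_homref scan-mode minimum count of lowland hom-ref
#'   samples
#' @return integer vector of passing site indices (rows of `gm$sites`)
#' @export
pattern_filter <- function(gm, mode = c("scan", "strict"),
                           min_lowland_homref = 3L) {
  mode <- match.arg(mode)
  ti <- samples_of_subpop(gm, "Tibet")
  qh <- samples_of_subpop(gm, "Qinghai")
  lo <- samples_of_class(gm, "lowland")
  if (!length(ti)) stop_input("scheme has no Tibet samples")

  g_ti <- gm$geno[, ti, drop = FALSE]
  g_qh <- gm$geno[, qh, drop = FALSE]
  g_lo <- gm$geno[, lo, drop = FALSE]

  tibet_ok <- rowSums(g_ti == 2L, na.rm = TRUE) == length(ti) &
    rowSums(is.na(g_ti)) == 0L
  qinghai_ok <- rowSums(g_qh == 0L, na.rm = TRUE) == 0L
  lowland_homref <- rowSums(g_lo == 0L, na.rm = TRUE)
  lowland_homalt <- rowSums(g_lo == 2L, na.rm = TRUE)

  pass <- if (mode == "scan") {
    tibet_ok & qinghai_ok &
      lowland_homref >= min_lowland_homref & lowland_homalt == 0L
  } else {
    tibet_ok & qinghai_ok &
      lowland_homref == length(lo) & rowSums(is.na(g_lo)) == 0L
  }
  which(pass)
}

#' Allelic chi-square association test at one site
#'
#' Builds the 2x2 highland-vs-lowland allele-count table (two alleles per
#' non-missing diploid genotype) and computes the Pearson chi-square without
#' continuity correction (1 df). Genotype counts per group are also returned.
#'
#' @param gm a [geno_matrix]
#' @param site row index into `gm$sites`
#' @return list: `site`, `chi2`, `p`, `freq_alt_high`, `freq_alt_low`,
#'   `freq_diff`, `table` (allele counts), `genotype_counts`
#' @export
allelic_chisq <- function(gm, site) {
  hi <- samples_of_class(gm, "highland")
  lo <- samples_of_class(gm, "lowland")
  g_hi <- gm$geno[site, hi]
  g_lo <- gm$geno[site, lo]
  if (all(is.na(g_hi)) || all(is.na(g_lo))) {
    stop_input("need at least one non-missing genotype per group at site ", site)
  }
  alt_hi <- sum(g_hi, na.rm = TRUE)
  tot_hi <- 2L * sum(!is.na(g_hi))
  alt_lo <- sum(g_lo, na.rm = TRUE)
  tot_lo <- 2L * sum(!is.na(g_lo))
  tab <- matrix(c(alt_hi, tot_hi - alt_hi, alt_lo, tot_lo - alt_lo),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("highland", "lowland"), c("alt", "ref")))
  chi2 <- pearson_chi2_2x2(tab)
  p <- if (chi2 == 0) 1 else stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  f_hi <- alt_hi / tot_hi
  f_lo <- alt_lo / tot_lo
  gt_counts <- rbind(
    highland = tabulate(g_hi + 1L, nbins = 3L),
    lowland = tabulate(g_lo + 1L, nbins = 3L)
  )
  colnames(gt_counts) <- c("hom_ref", "het", "hom_alt")
  list(site = site, chi2 = chi2, p = p,
       freq_alt_high = f_hi, freq_alt_low = f_lo,
       freq_diff = abs(f_hi - f_lo), table = tab, genotype_counts = gt_counts)
}

# Pearson chi-square of a 2x2 table without continuity correction;
# 0 when any margin is empty (monomorphic site / empty group)
pearson_chi2_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  if (denom == 0) return(0)
  n * (a * d - b * c)^2 / denom
}

#' Association tests over many sites
#'
#' @param gm a [geno_matrix]
#' @param sites integer site indices (default: all)
#' @param fisher also compute Fisher's exact p (useful when expected counts
#'   are below 5)
#' @return data.frame, one row per site
#' @export
association_table <- function(gm, sites = seq_len(nrow(gm$sites)),
                              fisher = FALSE) {
  rows <- lapply(sites, function(s) {
    r <- allelic_chisq(gm, s)
    out <- data.frame(
      contig = gm$sites$contig[s], pos = gm$sites$pos[s],
      chi2 = r$chi2, p = r$p, freq_alt_high = r$freq_alt_high,
      freq_alt_low = r$freq_alt_low, freq_diff = r$freq_diff,
      stringsAsFactors = FALSE)
    if (fisher) {
      out$p_fisher <- stats::fisher.test(r$table)$p.value
    }
    out
  })
  out <- do.call(rbind, rows)
  out$site <- sites
  out
}

# ---- r-squared estimators -------------------------------------------------

r2_from_hap_freq <- function(pAB, pA, pB) {
  D <- pAB - pA * pB
  den <- pA * (1 - pA) * pB * (1 - pB)
  if (den <= 0) return(NA_real_)
  D^2 / den
}

#' r-squared from phased haplotype counts
#'
#' @param n_AB,n_ab,n_Ab,n_aB haplotype counts
#' @return squared allelic correlation
#' @export
r2_phased <- function(n_AB, n_ab, n_Ab, n_aB) {
  n <- n_AB + n_ab + n_Ab + n_aB
  if (n == 0) return(NA_real_)
  pAB <- n_AB / n
  pA <- (n_AB + n_Ab) / n
  pB <- (n_AB + n_aB) / n
  r2_from_hap_freq(pAB, pA, pB)
}

#' r-squared from unphased genotypes by EM haplotype-frequency estimation
#'
#' Double heterozygotes are apportioned between the two phase resolutions at
#' each EM step; fixed-point iteration to `tol` or `max_iter` iterations.
#' Missing genotypes are excluded pairwise.
#'
#' @param g1,g2 genotype code vectors (0/1/2/NA) at the two sites
#' @param tol convergence tolerance on haplotype frequencies
#' @param max_iter iteration cap
#' @return squared allelic correlation, `NA` if either site is monomorphic
#'   among complete cases
#' @export
r2_em <- function(g1, g2, tol = 1e-10, max_iter = 1000L) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  n <- length(g1)
  if (n < 2) return(NA_real_)
  pA <- sum(g1) / (2 * n)   # allele A = alt at site 1
  pB <- sum(g2) / (2 * n)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(NA_real_)

  # known haplotype contributions; only (het, het) individuals are ambiguous
  n_dh <- sum(g1 == 1L & g2 == 1L)
  base <- c(AB = 0, Ab = 0, aB = 0, ab = 0)
  for (i in seq_len(n)) {
    a <- g1[i]; b <- g2[i]
    if (a == 1L && b == 1L) next
    # each individual contributes two haplotypes; for unambiguous genotypes
    # the split is determined by the allele counts
    if (a == 1L) {
      # one A and one a chromosome; B alleles are both the same (b != 1)
      base["AB"] <- base["AB"] + (b == 2L)
      base["Ab"] <- base["Ab"] + (b == 0L)
      base["aB"] <- base["aB"] + (b == 2L)
      base["ab"] <- base["ab"] + (b == 0L)
    } else if (b == 1L) {
      base["AB"] <- base["AB"] + (a == 2L)
      base["aB"] <- base["aB"] + (a == 0L)
      base["Ab"] <- base["Ab"] + (a == 2L)
      base["ab"] <- base["ab"] + (a == 0L)
    } else {
      base["AB"] <- base["AB"] + (a == 2L) * (b == 2L) * 2
      base["Ab"] <- base["Ab"] + (a == 2L) * (b == 0L) * 2
      base["aB"] <- base["aB"] + (a == 0L) * (b == 2L) * 2
      base["ab"] <- base["ab"] + (a == 0L) * (b == 0L) * 2
    }
  }
  total <- 2 * n
  # init at linkage equilibrium
  p <- c(AB = pA * pB, Ab = pA * (1 - pB), aB = (1 - pA) * pB,
         ab = (1 - pA) * (1 - pB))
  for (it in seq_len(max_iter)) {
    cis <- p["AB"] * p["ab"]
    trans <- p["Ab"] * p["aB"]
    w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    cnt <- base
    cnt["AB"] <- cnt["AB"] + n_dh * w
    cnt["ab"] <- cnt["ab"] + n_dh * w
    cnt["Ab"] <- cnt["Ab"] + n_dh * (1 - w)
    cnt["aB"] <- cnt["aB"] + n_dh * (1 - w)
    p_new <- cnt / total
    if (max(abs(p_new - p)) < tol) {
      p <- p_new
      break
    }
    p <- p_new
  }
  r2_from_hap_freq(p[["AB"]], pA, pB)
}

#' Composite genotypic r-squared
#'
#' Squared Pearson correlation of genotype dosages over complete cases.
#'
#' @param g1,g2 genotype code vectors (0/1/2/NA)
#' @return squared correlation, `NA` if either site is monomorphic
#' @export
r2_composite <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  if (length(g1) < 2) return(NA_real_)
  if (stats::sd(g1) == 0 || stats::sd(g2) == 0) return(NA_real_)
  stats::cor(g1, g2)^2
}

#' Pairwise r-squared over a site set
#'
#' @param gm a [geno_matrix]
#' @param sites integer site indices
#' @param method `"em"` (default), `"composite"`, or `"phased"` (requires no
#'   double heterozygotes; falls back to EM semantics otherwise since phase is
#'   then unambiguous)
#' @return data.frame (`site_i`, `site_j`, `r2`, `method`); monomorphic pairs
#'   carry `NA`
#' @export
pairwise_r2 <- function(gm, sites, method = c("em", "composite", "phased")) {
  method <- match.arg(method)
  if (length(sites) < 2) {
    return(data.frame(site_i = integer(), site_j = integer(),
                      r2 = numeric(), method = character()))
  }
  fn <- switch(method,
               em = r2_em,
               composite = r2_composite,
               phased = function(g1, g2) r2_em(g1, g2))
  pairs <- utils::combn(sites, 2)
  out <- data.frame(
    site_i = pairs[1, ], site_j = pairs[2, ],
    r2 = apply(pairs, 2, function(p) fn(gm$geno[p[1], ], gm$geno[p[2], ])),
    method = method, stringsAsFactors = FALSE)
  out
}

site_maf <- function(gm, s) {
  g <- gm$geno[s, ]
  n <- 2 * sum(!is.na(g))
  if (n == 0) return(0)
  p <- sum(g, na.rm = TRUE) / n
  min(p, 1 - p)
}

#' LD pruning of a genotype matrix
#'
#' Sliding windows of `window_snps` SNPs advanced by `step_snps`; within each
#' window, while any retained pair exceeds `r2_threshold`, the pair with the
#' largest r-squared is found and its lower-minor-allele-frequency member
#' removed (tie: the later position). The final kept set contains no
#' within-window pair above the threshold.
#'
#' @param gm a [geno_matrix]
#' @param window_snps,step_snps,r2_threshold pruning parameters
#' @param method r-squared estimator, see [pairwise_r2]
#' @return integer vector of kept site indices
#' @export
ld_prune <- function(gm, window_snps = 50L, step_snps = 5L,
                     r2_threshold = 0.2, method = "composite") {
  fn <- switch(method, em = r2_em, composite = r2_composite,
               stop_input("unsupported pruning method ", method))
  keep <- rep(TRUE, nrow(gm$sites))
  for (ctg in unique(gm$sites$contig)) {
    idx_all <- which(gm$sites$contig == ctg)
    if (length(idx_all) < 2) next
    starts <- seq(1L, length(idx_all), by = step_snps)
    for (st in starts) {
      win <- idx_all[st:min(st + window_snps - 1L, length(idx_all))]
      repeat {
        cur <- win[keep[win]]
        if (length(cur) < 2) break
        pr <- utils::combn(cur, 2)
        r2 <- apply(pr, 2, function(p) fn(gm$geno[p[1], ], gm$geno[p[2], ]))
        viol <- which(!is.na(r2) & r2 > r2_threshold)
        if (!length(viol)) break
        worst <- viol[which.max(r2[viol])]
        i <- pr[1, worst]; j <- pr[2, worst]
        mi <- site_maf(gm, i); mj <- site_maf(gm, j)
        drop <- if (mi < mj) i else if (mj < mi) j else {
          # tie: remove the later position
          if (gm$sites$pos[i] > gm$sites$pos[j]) i else j
        }
        keep[drop] <- FALSE
      }
    }
  }
  which(keep)
}

#' Complete-LD site groups
#'
#' Connected components of the graph whose edges are site pairs with
#' r-squared at least `1 - tol`; singleton components are omitted.
#'
#' @param ld_pairs data.frame as returned by [pairwise_r2]
#' @param tol tolerance below exactly 1
#' @return list of integer site-index vectors, each of size >= 2
#' @export
complete_ld_groups <- function(ld_pairs, tol = 1e-9) {
  edges <- ld_pairs[!is.na(ld_pairs$r2) & ld_pairs$r2 >= 1 - tol, , drop = FALSE]
  if (!nrow(edges)) return(list())
  nodes <- sort(unique(c(edges$site_i, edges$site_j)))
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(edges))) {
    a <- find(match(edges$site_i[k], nodes))
    b <- find(match(edges$site_j[k], nodes))
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_along(nodes), find, numeric(1))
  groups <- split(nodes, roots)
  groups <- groups[lengths(groups) >= 2]
  names(groups) <- NULL
  lapply(groups, sort)
}
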