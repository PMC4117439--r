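#' Scan configuration
#'
#' Defaults follow the standard sliding-window design for two-population sweep
#' scans: 100-kb windows advanced in 20-kb steps, top 5% of the joint
#' empirical percentile as outliers (top 1% reported alongside), and outlier
#' windows merged into regions when within 200 kb of each other.
#'
#' @param window_size window width in bp
#' @param step window increment in bp
#' @param top_fraction outlier tail fraction on the joint percentile
#' @param secondary_fraction stricter tail reported for reference (no effect
#'   on outlier calls)
#' @param merge_gap maximum gap (bp) between outlier windows merged into one
#'   region; the boundary gap itself merges (inclusive rule)
#' @param min_callable_sites windows with fewer callable positions are
#'   ineligible; default 10% of `window_size`
#' @param ratio_orientation `"contrast_over_target"` (default; lowland/highland,
#'   large values mark highland diversity loss) or `"target_over_contrast"`
#' @param outlier_mode `"joint_product"` (default) or `"marginal_intersection"`
#' @return a `scan_config` list
#' @export
scan_config <- function(window_size = 100000L, step = 20000L,
                        top_fraction = 0.05, secondary_fraction = 0.01,
                        merge_gap = 200000L,
                        min_callable_sites = NULL,
                        ratio_orientation = c("contrast_over_target",
                                              "target_over_contrast"),
                        outlier_mode = c("joint_product",
                                         "marginal_intersection")) {
  if (step <= 0 || step > window_size) stop_input("need 0 < step <= window_size")
  if (top_fraction <= 0 || top_fraction >= 1) stop_input("top_fraction must be in (0,1)")
  if (merge_gap < 0) stop_input("merge_gap must be >= 0")
  structure(list(
    window_size = as.integer(window_size), step = as.integer(step),
    top_fraction = top_fraction, secondary_fraction = secondary_fraction,
    merge_gap = as.numeric(merge_gap),
    min_callable_sites = as.integer(min_callable_sites %||% (window_size %/% 10L)),
    ratio_orientation = match.arg(ratio_orientation),
    outlier_mode = match.arg(outlier_mode)
  ), class = "scan_config")
}

#' Enumerate sliding windows over contigs
#'
#' Windows start at 0 and advance by `step`; trailing windows that would
#' extend past the contig end are dropped. Coordinates are 0-based half-open.
#'
#' @param contigs data.frame (`contig`, `length`)
#' @param config a [scan_config]
#' @return data.frame (`contig`, `start`, `end`)
#' @export
make_windows <- function(contigs, config = scan_config()) {
  out <- lapply(seq_len(nrow(contigs)), function(i) {
    L <- as.numeric(contigs$length[i])
    if (L < config$window_size) return(NULL)
    starts <- seq(0, L - config$window_size, by = config$step)
    data.frame(contig = contigs$contig[i], start = starts,
               end = starts + config$window_size, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out) || !nrow(out)) {
    warning("no contig is long enough for a single window")
    return(data.frame(contig = character(), start = numeric(), end = numeric()))
  }
  rownames(out) <- NULL
  out
}

# per-site nucleotide diversity from a genotype submatrix (rows = sites,
# columns = the population's samples): unbiased pairwise-difference estimator
# 2k(n-k)/(n(n-1)) over the non-missing chromosomes
site_pi <- function(geno_sub) {
  k <- rowSums(geno_sub, na.rm = TRUE)
  n <- 2L * rowSums(!is.na(geno_sub))
  out <- numeric(nrow(geno_sub))
  ok <- n >= 2
  out[ok] <- 2 * k[ok] * (n[ok] - k[ok]) / (n[ok] * (n[ok] - 1))
  out
}

#' Nucleotide diversity of one window
#'
#' Sum of per-site pairwise diversity over passing variant sites in the
#' window, divided by the window's callable-position count.
#'
#' @param gm a [geno_matrix]
#' @param population `"highland"` or `"lowland"`
#' @param contig,start,end window coordinates (0-based half-open)
#' @param config a [scan_config] (supplies `min_callable_sites`)
#' @return per-callable-site diversity, or `NA` for an ineligible window
#' @export
window_pi <- function(gm, population, contig, start, end,
                      config = scan_config()) {
  cols <- samples_of_class(gm, population)
  nc <- n_callable(gm, contig, start, end)
  if (nc < config$min_callable_sites) return(NA_real_)
  idx <- which(gm$sites$contig == contig & gm$sites$pos >= start &
                 gm$sites$pos < end & site_usable(gm))
  if (!length(idx)) return(0)
  sum(site_pi(gm$geno[idx, cols, drop = FALSE])) / nc
}

# windows use only sites passing the genome layer and, per the all-samples
# rule, passing the sample layer with an observed genotype in every sample
site_usable <- function(gm) {
  gm$site_pass & rowSums(is.na(gm$geno) | !gm$geno_pass) == 0L
}

# Weir-Cockerham (1984) two-level variance components for two populations at
# one site. p: alt frequencies, n: diploid sample sizes, h: observed
# heterozygote frequencies. Vectorized over sites.
wc_components <- function(p1, p2, n1, n2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  list(a = a, b = b, c = c)
}

#' Windowed Weir-Cockerham F_ST
#'
#' Per-site variance components are computed from the two altitude classes'
#' allele frequencies, sample sizes and observed heterozygosities; the window
#' estimate is the ratio of averages, sum(a)/sum(a+b+c), over sites with
#' defined components. Sites monomorphic across both classes contribute
#' nothing.
#'
#' @param gm a [geno_matrix]
#' @param contig,start,end window coordinates (0-based half-open)
#' @return windowed F_ST, or `NA` when no site is informative
#' @export
window_fst <- function(gm, contig, start, end) {
  idx <- which(gm$sites$contig == contig & gm$sites$pos >= start &
                 gm$sites$pos < end & site_usable(gm))
  if (!length(idx)) return(NA_real_)
  hi <- samples_of_class(gm, "highland")
  lo <- samples_of_class(gm, "lowland")
  g1 <- gm$geno[idx, hi, drop = FALSE]
  g2 <- gm$geno[idx, lo, drop = FALSE]
  comp <- wc_components_geno(g1, g2)
  num <- sum(comp$a, na.rm = TRUE)
  den <- sum(comp$a + comp$b + comp$c, na.rm = TRUE)
  if (!is.finite(den) || den == 0) return(NA_real_)
  num / den
}

# components from genotype submatrices; sites with <1 diploid per class or
# monomorphic across both classes get NA components
wc_components_geno <- function(g1, g2) {
  n1 <- rowSums(!is.na(g1))
  n2 <- rowSums(!is.na(g2))
  p1 <- rowSums(g1, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(g2, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(g1 == 1L, na.rm = TRUE) / n1
  h2 <- rowSums(g2 == 1L, na.rm = TRUE) / n2
  comp <- wc_components(p1, p2, n1, n2, h1, h2)
  bad <- n1 < 1 | n2 < 1 | (p1 == p2 & (p1 == 0 | p1 == 1))
  comp$a[bad] <- NA_real_
  comp$b[bad] <- NA_real_
  comp$c[bad] <- NA_real_
  comp
}

#' Diversity ratio of one window
#'
#' Default orientation returns lowland/highland diversity so that large
#' values mark diversity loss in the highland (sweep-target) population.
#'
#' @param pi_high,pi_low the two window diversities
#' @param orientation see [scan_config]
#' @return the ratio, or `NA` when the denominator is zero
#' @export
pi_ratio <- function(pi_high, pi_low,
                     orientation = c("contrast_over_target",
                                     "target_over_contrast")) {
  orientation <- match.arg(orientation)
  num <- if (orientation == "contrast_over_target") pi_low else pi_high
  den <- if (orientation == "contrast_over_target") pi_high else pi_low
  out <- ifelse(is.na(den) | den == 0, NA_real_, num / den)
  out
}

#' Empirical percentile transform
#'
#' Average rank divided by N, times 100; ascending, so the largest value maps
#' to 100 and ties share a percentile.
#'
#' @param values numeric vector (no NAs)
#' @return percentiles in (0, 100]
#' @export
empirical_percentiles <- function(values) {
  if (!length(values)) return(numeric())
  rank(values, ties.method = "average") / length(values) * 100
}

#' Flag joint-percentile outlier windows
#'
#' Computes the marginal empirical percentiles of F_ST and of the diversity
#' ratio over eligible windows, their product, and the percentile of the
#' product (the joint percentile). `joint_product` mode flags windows whose
#' joint percentile exceeds `100 * (1 - top_fraction)`; windows tied at the
#' boundary value share a percentile and are flagged together.
#' `marginal_intersection` mode requires both marginal percentiles in the top
#' tail. The minimal F_ST and ratio among flagged windows are returned as the
#' implied marginal thresholds.
#'
#' @param windows data.frame with columns `fst`, `pi_ratio` and logical
#'   `eligible`
#' @param config a [scan_config]
#' @return `windows` with percentile columns and logical `outlier` added, plus
#'   attributes `thresholds` (implied minima) and `n_flagged`
#' @export
joint_outliers <- function(windows, config = scan_config()) {
  w <- windows
  w$pct_fst <- NA_real_
  w$pct_dpi <- NA_real_
  w$pct_product <- NA_real_
  w$pct_joint <- NA_real_
  w$outlier <- FALSE
  el <- which(w$eligible)
  if (!length(el)) {
    warning("no eligible windows")
    attr(w, "thresholds") <- c(fst = NA_real_, pi_ratio = NA_real_)
    return(w)
  }
  w$pct_fst[el] <- empirical_percentiles(w$fst[el])
  w$pct_dpi[el] <- empirical_percentiles(w$pi_ratio[el])
  w$pct_product[el] <- w$pct_fst[el] * w$pct_dpi[el]
  w$pct_joint[el] <- empirical_percentiles(w$pct_product[el])
  cutoff <- 100 * (1 - config$top_fraction)
  if (config$outlier_mode == "joint_product") {
    w$outlier[el] <- w$pct_joint[el] > cutoff
  } else {
    w$outlier[el] <- w$pct_fst[el] > cutoff & w$pct_dpi[el] > cutoff
  }
  if (!any(w$outlier)) {
    warning("no outlier windows flagged (degenerate top tail)")
    attr(w, "thresholds") <- c(fst = NA_real_, pi_ratio = NA_real_)
  } else {
    attr(w, "thresholds") <- c(fst = min(w$fst[w$outlier]),
                               pi_ratio = min(w$pi_ratio[w$outlier]))
  }
  attr(w, "n_flagged") <- sum(w$outlier)
  w
}

#' Merge outlier windows into regions
#'
#' Same-contig outlier windows whose gap (next start minus previous end) is at
#' most `merge_gap` are joined, together with the intervening sequence.
#' Idempotent and invariant to input order.
#'
#' @param outlier_windows data.frame (`contig`, `start`, `end`), outlier
#'   windows only
#' @param config a [scan_config]
#' @return data.frame (`contig`, `start`, `end`, `n_windows`)
#' @export
merge_regions <- function(outlier_windows, config = scan_config()) {
  ow <- outlier_windows
  if (!nrow(ow)) {
    return(data.frame(contig = character(), start = numeric(),
                      end = numeric(), n_windows = integer()))
  }
  ow <- ow[order(ow$contig, ow$start, ow$end), , drop = FALSE]
  regions <- list()
  cur <- NULL
  for (i in seq_len(nrow(ow))) {
    row <- ow[i, ]
    if (!is.null(cur) && row$contig == cur$contig &&
        row$start - cur$end <= config$merge_gap) {
      cur$end <- max(cur$end, row$end)
      cur$n_windows <- cur$n_windows + 1L
    } else {
      if (!is.null(cur)) regions[[length(regions) + 1L]] <- cur
      cur <- data.frame(contig = row$contig, start = row$start, end = row$end,
                        n_windows = 1L, stringsAsFactors = FALSE)
    }
  }
  regions[[length(regions) + 1L]] <- cur
  out <- do.call(rbind, regions)
  rownames(out) <- NULL
  out
}

#' Genes overlapping outlier regions
#'
#' A gene is assigned to a region when its span overlaps the region by at
#' least 1 bp; each gene is listed once per region.
#'
#' @param regions data.frame (`contig`, `start`, `end`)
#' @param genes a `gene_models` object
#' @return list (per region) of gene-ID character vectors
#' @export
genes_in_regions <- function(regions, genes) {
  if (!nrow(regions)) return(list())
  gr_reg <- GenomicRanges::GRanges(
    regions$contig,
    IRanges::IRanges(start = regions$start + 1L, end = regions$end)
  )
  g <- genes$genes
  gr_gene <- GenomicRanges::GRanges(
    g$contig, IRanges::IRanges(start = g$start + 1L, end = g$end)
  )
  hits <- GenomicRanges::findOverlaps(gr_reg, gr_gene, minoverlap = 1L)
  out <- rep(list(character()), nrow(regions))
  for (q in unique(S4Vectors::queryHits(hits))) {
    ids <- g$gene_id[S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == q]]
    out[[q]] <- sort(unique(ids))
  }
  out
}

#' Two-population windowed selection scan
#'
#' The package's central fit: computes per-window F_ST (Weir-Cockerham, ratio
#' of averages), highland and lowland nucleotide diversity, their ratio, the
#' marginal empirical percentiles, the joint percentile product, outlier
#' flags, merged outlier regions and (when gene models are supplied) the genes
#' overlapping each region.
#'
#' @param gm a [geno_matrix]
#' @param genes optional `gene_models` object
#' @param config a [scan_config]
#' @return an object of class `sweep_scan` with components `windows` (one row
#'   per window with all statistics), `regions`, `region_genes`, `thresholds`
#'   (implied marginal minima among outliers), `config` and bookkeeping counts
#' @export
sweep_scan <- function(gm, genes = NULL, config = scan_config()) {
  win <- make_windows(gm$contigs, config)
  usable <- site_usable(gm)
  hi <- samples_of_class(gm, "highland")
  lo <- samples_of_class(gm, "lowland")
  if (!length(hi) || !length(lo)) {
    stop_input("scheme must contain both highland and lowland samples")
  }

  # per-site quantities, computed once
  s_pi_h <- site_pi(gm$geno[, hi, drop = FALSE])
  s_pi_l <- site_pi(gm$geno[, lo, drop = FALSE])
  comp <- wc_components_geno(gm$geno[, hi, drop = FALSE],
                             gm$geno[, lo, drop = FALSE])
  abc <- comp$a + comp$b + comp$c

  nw <- nrow(win)
  win$n_callable <- NA_integer_
  win$n_snps <- 0L
  win$fst <- NA_real_
  win$pi_high <- NA_real_
  win$pi_low <- NA_real_
  win$pi_ratio <- NA_real_

  for (ctg in unique(win$contig)) {
    widx <- which(win$contig == ctg)
    sidx <- which(gm$sites$contig == ctg & usable)
    pos <- gm$sites$pos[sidx]
    o <- order(pos)
    sidx <- sidx[o]; pos <- pos[o]
    for (wi in widx) {
      lo_i <- findInterval(win$start[wi] - 1L, pos) + 1L
      hi_i <- findInterval(win$end[wi] - 1L, pos)
      win$n_callable[wi] <- n_callable(gm, ctg, win$start[wi], win$end[wi])
      if (hi_i < lo_i) {
        if (win$n_callable[wi] >= config$min_callable_sites) {
          win$fst[wi] <- NA_real_
          win$pi_high[wi] <- 0
          win$pi_low[wi] <- 0
        }
        next
      }
      rows <- sidx[lo_i:hi_i]
      win$n_snps[wi] <- length(rows)
      if (win$n_callable[wi] < config$min_callable_sites) next
      win$pi_high[wi] <- sum(s_pi_h[rows]) / win$n_callable[wi]
      win$pi_low[wi] <- sum(s_pi_l[rows]) / win$n_callable[wi]
      den <- sum(abc[rows], na.rm = TRUE)
      if (is.finite(den) && den != 0) {
        win$fst[wi] <- sum(comp$a[rows], na.rm = TRUE) / den
      }
    }
  }
  win$pi_ratio <- pi_ratio(win$pi_high, win$pi_low,
                           orientation = config$ratio_orientation)
  win$eligible <- !is.na(win$fst) & !is.na(win$pi_ratio) &
    win$n_callable >= config$min_callable_sites

  win <- joint_outliers(win, config)
  thresholds <- attr(win, "thresholds")

  regions <- merge_regions(win[win$outlier, c("contig", "start", "end")], config)
  if (nrow(regions)) {
    # region-level max joint percentile over member windows
    regions$max_pct_joint <- vapply(seq_len(nrow(regions)), function(i) {
      m <- win$outlier & win$contig == regions$contig[i] &
        win$start >= regions$start[i] & win$end <= regions$end[i]
      max(win$pct_joint[m])
    }, numeric(1))
  }
  region_genes <- if (!is.null(genes)) genes_in_regions(regions, genes) else NULL

  structure(list(
    windows = win,
    regions = regions,
    region_genes = region_genes,
    thresholds = thresholds,
    config = config,
    n_windows = nw,
    n_eligible = sum(win$eligible),
    n_outlier = sum(win$outlier)
  ), class = "sweep_scan")
}

#' @export
print.sweep_scan <- function(x, ...) {
  cat("Two-population selective sweep scan\n")
  cat(sprintf("  windows: %d (%d eligible, %d ineligible)\n",
              x$n_windows, x$n_eligible, x$n_windows - x$n_eligible))
  cat(sprintf("  window %d kb / step %d kb, top fraction %.3g (%s mode)\n",
              x$config$window_size %/% 1000L, x$config$step %/% 1000L,
              x$config$top_fraction, x$config$outlier_mode))
  cat(sprintf("  outlier windows: %d; outlier regions: %d\n",
              x$n_outlier, nrow(x$regions)))
  if (!anyNA(x$thresholds)) {
    cat(sprintf("  implied marginal thresholds: F_ST > %.3f, diversity ratio > %.3f\n",
                x$thresholds[["fst"]], x$thresholds[["pi_ratio"]]))
  }
  if (!is.null(x$region_genes)) {
    cat("  genes in outlier regions:",
        length(unique(unlist(x$region_genes))), "\n")
  }
  invisible(x)
}

#' @export
summary.sweep_scan <- function(object, ...) {
  w <- object$windows[object$windows$eligible, ]
  out <- list(
    scan = object,
    fst = summary(w$fst),
    pi_ratio = summary(w$pi_ratio),
    pi_high = summary(w$pi_high),
    pi_low = summary(w$pi_low)
  )
  class(out) <- "summary.sweep_scan"
  out
}

#' @export
print.summary.sweep_scan <- function(x, ...) {
  print(x$scan)
  cat("\nEligible-window statistics:\n")
  cat("  F_ST:\n"); print(x$fst)
  cat("  diversity ratio:\n"); print(x$pi_ratio)
  invisible(x)
}

#' Genome-wide plot of the joint percentile
#'
#' Manhattan-style base-graphics plot of each window's joint percentile along
#' the genome, outlier windows highlighted.
#'
#' @param x a `sweep_scan` object
#' @param ... passed to [graphics::plot]
#' @export
plot.sweep_scan <- function(x, ...) {
  w <- x$windows[x$windows$eligible, ]
  if (!nrow(w)) {
    warning("nothing to plot: no eligible windows")
    return(invisible(x))
  }
  ctgs <- unique(w$contig)
  offset <- stats::setNames(cumsum(c(0, vapply(
    ctgs[-length(ctgs)],
    function(ctg) max(w$end[w$contig == ctg]), numeric(1)))), ctgs)
  xpos <- (w$start + w$end) / 2 + offset[w$contig]
  col <- ifelse(w$outlier, "firebrick", c("grey40", "grey70")[
    (match(w$contig, ctgs) %% 2L) + 1L])
  graphics::plot(xpos / 1e6, w$pct_joint, col = col, pch = 16, cex = 0.5,
                 xlab = "genome position (Mb)", ylab = "joint percentile (%)",
                 ...)
  graphics::abline(h = 100 * (1 - x$config$top_fraction), lty = 2)
  invisible(x)
}

#' Per-window statistics table
#'
#' @param scan a `sweep_scan` object
#' @param path output TSV path; coordinates are written 1-based inclusive
#' @return `path`, invisibly
#' @export
write_window_tsv <- function(scan, path) {
  w <- scan$windows
  out <- data.frame(contig = w$contig, start = w$start + 1L, end = w$end,
                    w[, !(names(w) %in% c("contig", "start", "end"))])
  write_tsv(out, path)
  invisible(path)
}

#' Outlier regions as BED
#'
#' @param scan a `sweep_scan` object
#' @param path output BED path (0-based half-open)
#' @return `path`, invisibly
#' @export
write_region_bed <- function(scan, path) {
  r <- scan$regions
  utils::write.table(
    data.frame(r$contig, format(r$start, scientific = FALSE, trim = TRUE),
               format(r$end, scientific = FALSE, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
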