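#' Simulation configuration for the two-population sweep simulator
#'
#' Defaults describe the study design the package targets: nine diploid
#' genomes in four subpopulations (2 Tibet + 2 Qinghai highland; 2 Xinjiang +
#' 3 InnerMongolia lowland), 20 Mb of sequence, background per-site
#' heterozygosity 0.001, and one 300-kb selective sweep in which highland
#' diversity is reduced to 5% of background and highland-lowland allele
#' frequency divergence is boosted by 0.3.
#'
#' @param genome_length total genome length in bp
#' @param n_contigs number of contigs (`chr1..chrN`), splitting the length evenly
#' @param theta expected per-site heterozygosity outside sweeps (0-1)
#' @param divergence Balding-Nichols F for the background between-population
#'   allele-frequency divergence (0-1)
#' @param sweep_intervals list of `(contig, start, end)` triples, 0-based
#'   half-open; must fall inside contig bounds and not overlap
#' @param sweep_diversity_factor multiplier (0-1) applied to highland
#'   heterozygosity inside sweeps
#' @param sweep_divergence_boost additive shift (0-1) of the highland
#'   alternative-allele frequency inside sweeps
#' @param samples data.frame (`sample_id`, `subpop`)
#' @param n_planted_causal number of highland-pattern causal SNPs to plant
#'   inside sweep intervals
#' @param gc_fraction GC content of the generated reference
#' @param titv transition/transversion ratio of the simulated mutation spectrum
#' @param missing_rate per-genotype missingness probability (0 by default)
#' @param seed integer seed; every simulator operation is deterministic given it
#' @return a `sim_config` list
#' @export
sim_config <- function(genome_length = 20e6,
                       n_contigs = 1L,
                       theta = 0.001,
                       divergence = 0.1,
                       sweep_intervals = list(list("chr1", 9850000L, 10150000L)),
                       sweep_diversity_factor = 0.05,
                       sweep_divergence_boost = 0.3,
                       samples = default_samples(),
                       n_planted_causal = 3L,
                       gc_fraction = 0.42,
                       titv = 2.3,
                       missing_rate = 0,
                       seed = 1L) {
  cfg <- list(
    genome_length = as.numeric(genome_length), n_contigs = as.integer(n_contigs),
    theta = theta, divergence = divergence,
    sweep_intervals = sweep_intervals,
    sweep_diversity_factor = sweep_diversity_factor,
    sweep_divergence_boost = sweep_divergence_boost,
    samples = as.data.frame(samples), n_planted_causal = as.integer(n_planted_causal),
    gc_fraction = gc_fraction, titv = titv, missing_rate = missing_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Default nine-sample cohort scheme
#'
#' Two Tibet, two Qinghai (highland), two Xinjiang and three InnerMongolia
#' (lowland) diploid samples.
#' @param panel if `TRUE`, return the 35-sample re-sequencing panel layout
#'   instead (10 Tibet, 8 Qinghai, 8 Xinjiang, 9 InnerMongolia)
#' @return data.frame (`sample_id`, `subpop`)
#' @export
default_samples <- function(panel = FALSE) {
  if (!panel) {
    return(data.frame(
      sample_id = c("TI09", "TI32", "QH11", "QH16",
                    "XJ24", "XJ30", "IM06", "IM07", "RKWL"),
      subpop = c("Tibet", "Tibet", "Qinghai", "Qinghai",
                 "Xinjiang", "Xinjiang", "InnerMongolia", "InnerMongolia",
                 "InnerMongolia"),
      stringsAsFactors = FALSE
    ))
  }
  counts <- c(Tibet = 10L, Qinghai = 8L, Xinjiang = 8L, InnerMongolia = 9L)
  pre <- c(Tibet = "TI", Qinghai = "QH", Xinjiang = "XJ", InnerMongolia = "IM")
  data.frame(
    sample_id = unlist(lapply(names(counts), function(p) {
      sprintf("%sP%02d", pre[[p]], seq_len(counts[[p]]))
    })),
    subpop = rep(names(counts), counts),
    stringsAsFactors = FALSE
  )
}

validate_sim_config <- function(cfg) {
  if (cfg$genome_length <= 0) stop_input("genome_length must be positive")
  if (!(cfg$theta > 0 && cfg$theta < 1)) stop_input("theta must be in (0,1)")
  if (cfg$sweep_diversity_factor < 0 || cfg$sweep_diversity_factor > 1) {
    stop_input("sweep_diversity_factor must be in [0,1]")
  }
  if (cfg$divergence < 0 || cfg$divergence >= 1) {
    stop_input("divergence must be in [0,1)")
  }
  bad <- setdiff(unique(cfg$samples$subpop), names(SUBPOP_CLASS))
  if (length(bad)) stop_input("unknown subpopulation(s): ", paste(bad, collapse = ", "))
  ctg <- contig_table(cfg)
  iv <- cfg$sweep_intervals
  if (length(iv)) {
    df <- sweep_df(cfg)
    for (i in seq_len(nrow(df))) {
      len <- ctg$length[match(df$contig[i], ctg$contig)]
      if (is.na(len)) stop_input("sweep interval on unknown contig ", df$contig[i])
      if (df$start[i] < 0 || df$end[i] > len || df$start[i] >= df$end[i]) {
        stop_input("sweep interval out of contig bounds: ", df$contig[i],
                   ":", df$start[i], "-", df$end[i])
      }
    }
    for (ctg_i in unique(df$contig)) {
      d <- df[df$contig == ctg_i, , drop = FALSE]
      d <- d[order(d$start), , drop = FALSE]
      if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])) {
        stop_input("sweep intervals overlap on ", ctg_i)
      }
    }
  }
  invisible(cfg)
}

contig_table <- function(cfg) {
  n <- cfg$n_contigs
  per <- floor(cfg$genome_length / n)
  len <- rep(per, n)
  len[n] <- cfg$genome_length - per * (n - 1)
  data.frame(contig = paste0("chr", seq_len(n)), length = len,
             stringsAsFactors = FALSE)
}

sweep_df <- function(cfg) {
  if (!length(cfg$sweep_intervals)) {
    return(data.frame(contig = character(), start = numeric(), end = numeric()))
  }
  do.call(rbind, lapply(cfg$sweep_intervals, function(x) {
    data.frame(contig = as.character(x[[1]]), start = as.numeric(x[[2]]),
               end = as.numeric(x[[3]]), stringsAsFactors = FALSE)
  }))
}

# E[2p(1-p)] for p ~ Uniform(0.05, 0.95); converts theta into a per-bp
# segregating-site density for the Poisson placement of sites
UNIF_MEAN_HET <- 0.365

#' Generate a random reference sequence
#'
#' @param length total length in bp
#' @param gc_fraction GC content in `[0,1]`
#' @param seed integer seed
#' @param n_contigs number of contigs to split the sequence into
#' @return list with `sequences` (named character vector) and `contigs`
#'   (data.frame `contig`, `length`)
#' @export
generate_reference <- function(length, gc_fraction = 0.42, seed = 1L,
                               n_contigs = 1L) {
  if (length <= 0) stop_input("length must be positive")
  if (gc_fraction < 0 || gc_fraction > 1) stop_input("gc_fraction must be in [0,1]")
  ctg <- contig_table(list(genome_length = length, n_contigs = as.integer(n_contigs)))
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seqs <- with_seed(seed, {
    vapply(ctg$length, function(L) {
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
    }, character(1))
  })
  names(seqs) <- ctg$contig
  list(sequences = seqs, contigs = ctg)
}

# shrink heterozygosity 2p(1-p) by `factor`, moving p toward its nearest
# fixation boundary (analytic sweep model; no haplotype copying)
shrink_het <- function(p, factor) {
  h <- 2 * p * (1 - p) * factor
  root <- sqrt(pmax(0, 1 - 2 * h))
  ifelse(p >= 0.5, (1 + root) / 2, (1 - root) / 2)
}

#' Simulate a two-population diploid cohort with a planted sweep
#'
#' Biallelic sites are placed by a Poisson process at the density implied by
#' `theta`; per-population alternative-allele frequencies follow a
#' Balding-Nichols draw around a shared ancestral frequency, with F set by
#' `divergence`. Inside sweep intervals the highland frequency is first
#' shifted toward fixation by `sweep_divergence_boost` and its heterozygosity
#' then shrunk by `sweep_diversity_factor`. Diploid genotypes are drawn under
#' within-population Hardy-Weinberg proportions. `n_planted_causal`
#' highland-pattern causal SNPs are planted at the sweep centre.
#'
#' @param config a [sim_config]
#' @param reference optional output of [generate_reference] consistent with
#'   `config`; when supplied, reference alleles are read from the sequence
#' @return list with elements `matrix` (a [geno_matrix]) and `truth`
#'   (a `sim_truth` record: sweep intervals, planted causal SNPs, realized
#'   per-window diversity, seed)
#' @export
simulate_cohort <- function(config, reference = NULL) {
  validate_sim_config(config)
  ctg <- contig_table(config)
  sw <- sweep_df(config)
  # within-population expected heterozygosity under the Balding-Nichols draw
  # is 2p(1-p)(1-F); the site density compensates so the cohort's realized
  # per-site heterozygosity targets theta
  density <- config$theta / (UNIF_MEAN_HET * (1 - config$divergence))

  sim <- with_seed(config$seed, {
    sites_list <- list()
    for (i in seq_len(nrow(ctg))) {
      L <- ctg$length[i]
      n_sites <- stats::rpois(1, L * density)
      n_sites <- min(n_sites, L)
      pos <- sort(sample.int(L, n_sites)) - 1L
      sites_list[[i]] <- data.frame(contig = ctg$contig[i], pos = pos,
                                    stringsAsFactors = FALSE)
    }
    sites <- do.call(rbind, sites_list)
    n <- nrow(sites)

    # ancestral and population frequencies (alternative allele)
    p_anc <- stats::runif(n, 0.05, 0.95)
    F <- config$divergence
    draw_pop <- function() {
      if (F <= 0) return(p_anc)
      a <- p_anc * (1 - F) / F
      b <- (1 - p_anc) * (1 - F) / F
      stats::rbeta(n, a, b)
    }
    p_high <- draw_pop()
    p_low <- draw_pop()

    in_sweep <- logical(n)
    if (nrow(sw)) {
      for (k in seq_len(nrow(sw))) {
        in_sweep <- in_sweep | (sites$contig == sw$contig[k] &
                                  sites$pos >= sw$start[k] & sites$pos < sw$end[k])
      }
    }
    if (any(in_sweep)) {
      pb <- pmin(1, p_high[in_sweep] + config$sweep_divergence_boost)
      p_high[in_sweep] <- shrink_het(pb, config$sweep_diversity_factor)
    }

    # alleles: ref from the reference sequence when given, else random;
    # alt drawn from a Ti/Tv mutation spectrum
    bases <- c("A", "C", "G", "T")
    if (!is.null(reference)) {
      ref <- character(n)
      for (ci in unique(sites$contig)) {
        idx <- which(sites$contig == ci)
        s <- reference$sequences[[ci]]
        ref[idx] <- substring(s, sites$pos[idx] + 1L, sites$pos[idx] + 1L)
      }
      ref[!ref %in% bases] <- sample(bases, sum(!ref %in% bases), replace = TRUE)
    } else {
      ref <- sample(bases, n, replace = TRUE)
    }
    transition <- c(A = "G", G = "A", C = "T", T = "C")
    p_ti <- config$titv / (config$titv + 1)
    is_ti <- stats::runif(n) < p_ti
    alt <- ifelse(is_ti, transition[ref], NA_character_)
    tv_choice <- stats::runif(n)
    for (b in bases) {
      idx <- which(!is_ti & ref == b)
      if (!length(idx)) next
      others <- setdiff(bases, c(b, transition[[b]]))
      alt[idx] <- ifelse(tv_choice[idx] < 0.5, others[1], others[2])
    }

    ns <- nrow(config$samples)
    geno <- matrix(NA_integer_, n, ns)
    cls <- unname(SUBPOP_CLASS[config$samples$subpop])
    for (j in seq_len(ns)) {
      p <- if (cls[j] == "highland") p_high else p_low
      geno[, j] <- stats::rbinom(n, 2L, p)
    }
    if (config$missing_rate > 0) {
      drop <- matrix(stats::runif(n * ns) < config$missing_rate, n, ns)
      geno[drop] <- NA_integer_
    }

    # keep only sites segregating in the cohort (observed alternative allele)
    alt_obs <- rowSums(geno, na.rm = TRUE) > 0
    list(sites = data.frame(contig = sites$contig, pos = sites$pos,
                            ref = unname(ref), alt = unname(alt),
                            stringsAsFactors = FALSE)[alt_obs, , drop = FALSE],
         geno = geno[alt_obs, , drop = FALSE])
  })

  gm <- geno_matrix(sim$sites, sim$geno, config$samples, ctg)

  truth <- structure(list(
    sweep_intervals = sw,
    causal_snps = data.frame(contig = character(), pos = integer(),
                             pattern = character(), stringsAsFactors = FALSE),
    realized = realized_diversity(gm, window = 100000L),
    seed = config$seed
  ), class = "sim_truth")

  if (config$n_planted_causal > 0 && nrow(sw)) {
    planted <- plant_causal_snps(gm, truth, config$n_planted_causal, "highland")
    gm <- planted$matrix
    truth <- planted$truth
  }
  list(matrix = gm, truth = truth)
}

# realized per-window diversity (non-overlapping windows), kept in the truth
# record so parameter-recovery tests can compare against what was generated
realized_diversity <- function(gm, window = 100000L) {
  out <- list()
  hi <- samples_of_class(gm, "highland")
  lo <- samples_of_class(gm, "lowland")
  for (i in seq_len(nrow(gm$contigs))) {
    ctg <- gm$contigs$contig[i]
    L <- gm$contigs$length[i]
    if (L < window) {
      starts <- 0
      window_i <- L
    } else {
      starts <- seq(0, L - window, by = window)
      window_i <- window
    }
    idx_ctg <- gm$sites$contig == ctg
    pos <- gm$sites$pos[idx_ctg]
    pi_h <- site_pi(gm$geno[idx_ctg, hi, drop = FALSE])
    pi_l <- site_pi(gm$geno[idx_ctg, lo, drop = FALSE])
    bin <- findInterval(pos, starts)
    agg <- function(v) {
      s <- tapply(v, factor(bin, levels = seq_along(starts)), sum)
      as.numeric(ifelse(is.na(s), 0, s)) / window_i
    }
    out[[ctg]] <- data.frame(contig = ctg, start = starts,
                             end = pmin(starts + window_i, L),
                             pi_high = agg(pi_h), pi_low = agg(pi_l),
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Plant causal SNPs matching a highland genotype pattern
#'
#' Overwrites genotypes at existing sites inside the sweep intervals so they
#' satisfy the named pattern: Tibet samples homozygous alternative, Qinghai
#' heterozygous or homozygous alternative, lowland homozygous reference
#' (pattern `"strict"`: every lowland sample; pattern `"highland"`: one lowland
#' heterozygote is allowed and planted when the cohort has at least four
#' lowland samples). Sites nearest the sweep-interval centres are chosen, so
#' the operation is deterministic without consuming random numbers.
#'
#' @param matrix a [geno_matrix]
#' @param truth the `sim_truth` record to update
#' @param n number of SNPs to plant
#' @param pattern `"highland"` (scan-mode pattern) or `"strict"`
#' @return list with updated `matrix` and `truth`
#' @export
plant_causal_snps <- function(matrix, truth, n, pattern = c("highland", "strict")) {
  pattern <- match.arg(pattern)
  gm <- matrix
  if (n == 0) return(list(matrix = gm, truth = truth))
  sw <- truth$sweep_intervals
  if (!nrow(sw)) stop_input("no sweep intervals to plant causal SNPs in")
  in_sweep <- logical(nrow(gm$sites))
  centre_dist <- rep(Inf, nrow(gm$sites))
  for (k in seq_len(nrow(sw))) {
    hit <- gm$sites$contig == sw$contig[k] &
      gm$sites$pos >= sw$start[k] & gm$sites$pos < sw$end[k]
    in_sweep <- in_sweep | hit
    mid <- (sw$start[k] + sw$end[k]) / 2
    centre_dist[hit] <- pmin(centre_dist[hit], abs(gm$sites$pos[hit] - mid))
  }
  already <- paste(gm$sites$contig, gm$sites$pos) %in%
    paste(truth$causal_snps$contig, truth$causal_snps$pos)
  avail <- which(in_sweep & !already)
  if (length(avail) < n) stop_input("not enough sites inside sweep intervals to plant ", n)
  pick <- avail[order(centre_dist[avail])][seq_len(n)]

  ti <- samples_of_subpop(gm, "Tibet")
  qh <- samples_of_subpop(gm, "Qinghai")
  lo <- samples_of_class(gm, "lowland")
  if (!length(ti)) stop_input("scheme has no Tibet samples")
  for (s in pick) {
    gm$geno[s, ti] <- 2L
    if (length(qh)) {
      gm$geno[s, qh] <- 2L
      gm$geno[s, qh[1]] <- 1L
    }
    gm$geno[s, lo] <- 0L
    if (pattern == "highland" && length(lo) >= 4) {
      gm$geno[s, lo[length(lo)]] <- 1L
    }
    gm$geno_pass[s, ] <- TRUE
  }
  gm$site_pass[pick] <- TRUE
  truth$causal_snps <- rbind(truth$causal_snps, data.frame(
    contig = gm$sites$contig[pick], pos = gm$sites$pos[pick],
    pattern = pattern, stringsAsFactors = FALSE
  ))
  truth$causal_snps <- truth$causal_snps[order(truth$causal_snps$contig,
                                               truth$causal_snps$pos), ]
  rownames(truth$causal_snps) <- NULL
  list(matrix = gm, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth: seed", x$seed, "\n")
  cat("  sweep intervals:", nrow(x$sweep_intervals), "\n")
  cat("  planted causal SNPs:", nrow(x$causal_snps), "\n")
  invisible(x)
}

#' Write the simulated fixture bundle to a directory
#'
#' Emits `cohort.vcf` (VCF v4.2, GT only), `reference.fa` (60-column FASTA),
#' `genes.gff3`, `populations.tsv` and `truth.json`.
#'
#' @param matrix a [geno_matrix]
#' @param reference output of [generate_reference]
#' @param genes a `gene_models` object (or `NULL` to skip)
#' @param truth a `sim_truth` record
#' @param out_dir output directory (created if needed)
#' @return named character vector of the written paths, invisibly
#' @export
write_fixture_bundle <- function(matrix, reference, genes, truth, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_input("cannot create output directory ", out_dir)
  }
  paths <- c(
    vcf = file.path(out_dir, "cohort.vcf"),
    fasta = file.path(out_dir, "reference.fa"),
    pop = file.path(out_dir, "populations.tsv"),
    truth = file.path(out_dir, "truth.json")
  )
  write_vcf_geno(matrix, paths[["vcf"]])
  write_fasta(reference$sequences, paths[["fasta"]])
  write_pop_tsv(matrix, paths[["pop"]])
  truth_json <- list(
    sweep_intervals = truth$sweep_intervals,
    causal_snps = truth$causal_snps,
    seed = truth$seed
  )
  jsonlite::write_json(truth_json, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  if (!is.null(genes)) {
    paths[["gff3"]] <- file.path(out_dir, "genes.gff3")
    write_gff3(genes, paths[["gff3"]])
  }
  invisible(paths)
}
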