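#' Detect CpG positions in a reference sequence
#'
#' Flags both the C and the G of every CG dinucleotide on the forward strand
#' (the mask is strand-symmetric: the reverse strand's CpGs are the same
#' positions).
#'
#' @param sequence a single sequence string over A/C/G/T/N
#' @return sorted integer vector of 0-based flagged positions
#' @export
detect_cpg_sites <- function(sequence) {
  hits <- gregexpr("CG", sequence, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(integer())
  sort(unique(c(hits - 1L, hits)))  # 0-based C and G positions
}

#' Filter configuration for the genotype QC chain
#'
#' The chain has two layers mirroring genome-level and sample-level filters:
#' genome-level stages mark whole sites (CpG overlap, per-site missingness),
#' sample-level stages mark individual genotypes (depth and quality bounds,
#' applied only when the matrix carries DP/GQ values).
#'
#' @param exclude_cpg drop sites overlapping CpG dinucleotides and remove those
#'   positions from callable totals
#' @param max_missing_fraction_per_site sites with a larger missing fraction
#'   are dropped (`NULL` disables the stage)
#' @param min_depth,max_depth per-genotype depth bounds (`NULL` disables)
#' @param min_genotype_quality per-genotype GQ bound (`NULL` disables)
#' @param aim_threshold diagnostic-allele fraction below which a sample is
#'   flagged as admixed by [ancestry_screen]
#' @return a `filter_config` list
#' @export
filter_config <- function(exclude_cpg = TRUE,
                          max_missing_fraction_per_site = NULL,
                          min_depth = NULL, max_depth = NULL,
                          min_genotype_quality = NULL,
                          aim_threshold = 0.90) {
  if (!is.null(min_depth) && !is.null(max_depth) && min_depth > max_depth) {
    stop_input("min_depth > max_depth")
  }
  if (!is.null(min_depth) && min_depth < 0) stop_input("depth bounds must be non-negative")
  if (aim_threshold <= 0 || aim_threshold > 1) stop_input("aim_threshold must be in (0,1]")
  structure(list(
    exclude_cpg = exclude_cpg,
    max_missing_fraction_per_site = max_missing_fraction_per_site,
    min_depth = min_depth, max_depth = max_depth,
    min_genotype_quality = min_genotype_quality,
    aim_threshold = aim_threshold
  ), class = "filter_config")
}

#' Apply the QC filter chain to a genotype matrix
#'
#' Updates the site-level and genotype-level pass masks and (for CpG
#' exclusion) the genome-wide excluded-position lists. The input matrix is not
#' modified; filtering is idempotent.
#'
#' @param gm a [geno_matrix]
#' @param config a [filter_config]
#' @param reference output of [generate_reference] (or a compatible list with
#'   `sequences`); required when `exclude_cpg` is on
#' @return list with `matrix` (filtered copy) and `report` (data.frame of
#'   per-stage removal counts)
#' @export
apply_filters <- function(gm, config = filter_config(), reference = NULL) {
  report <- data.frame(stage = character(), sites_removed = integer(),
                       genotypes_failed = integer(), stringsAsFactors = FALSE)
  add <- function(stage, sites = 0L, genos = 0L) {
    rbind(report, data.frame(stage = stage, sites_removed = as.integer(sites),
                             genotypes_failed = as.integer(genos),
                             stringsAsFactors = FALSE))
  }

  if (isTRUE(config$exclude_cpg)) {
    if (is.null(reference)) stop_input("exclude_cpg requires a reference")
    missing_ctg <- setdiff(unique(gm$sites$contig), names(reference$sequences))
    if (length(missing_ctg)) {
      stop_input("reference does not cover contig(s): ",
                 paste(missing_ctg, collapse = ", "))
    }
    newly <- logical(nrow(gm$sites))
    for (ctg in names(reference$sequences)) {
      cpg <- detect_cpg_sites(reference$sequences[[ctg]])
      gm$excluded[[ctg]] <- sort(unique(c(gm$excluded[[ctg]], cpg)))
      idx <- which(gm$sites$contig == ctg)
      hit <- gm$sites$pos[idx] %in% cpg
      newly[idx[hit]] <- TRUE
    }
    removed <- sum(newly & gm$site_pass)
    gm$site_pass[newly] <- FALSE
    report <- add("cpg_exclusion", sites = removed)
  }

  if (!is.null(config$min_depth) || !is.null(config$max_depth)) {
    if (!is.null(gm$dp)) {
      fail <- matrix(FALSE, nrow(gm$geno), ncol(gm$geno))
      if (!is.null(config$min_depth)) fail <- fail | (gm$dp < config$min_depth)
      if (!is.null(config$max_depth)) fail <- fail | (gm$dp > config$max_depth)
      fail[is.na(fail)] <- FALSE
      n_new <- sum(fail & gm$geno_pass)
      gm$geno_pass[fail] <- FALSE
      report <- add("depth_bounds", genos = n_new)
    } else {
      report <- add("depth_bounds_skipped_no_DP")
    }
  }

  if (!is.null(config$min_genotype_quality)) {
    if (!is.null(gm$gq)) {
      fail <- gm$gq < config$min_genotype_quality
      fail[is.na(fail)] <- FALSE
      n_new <- sum(fail & gm$geno_pass)
      gm$geno_pass[fail] <- FALSE
      report <- add("genotype_quality", genos = n_new)
    } else {
      report <- add("genotype_quality_skipped_no_GQ")
    }
  }

  if (!is.null(config$max_missing_fraction_per_site)) {
    miss_frac <- rowMeans(is.na(gm$geno) | !gm$geno_pass)
    fail <- miss_frac > config$max_missing_fraction_per_site
    removed <- sum(fail & gm$site_pass)
    gm$site_pass[fail] <- FALSE
    report <- add("site_missingness", sites = removed)
  }

  list(matrix = gm, report = report)
}

#' Merge per-sample variant sets, dropping incompletely called sites
#'
#' Takes the union of per-sample SNP sites, then removes every site that is
#' absent from at least one sample's callable set (default: its variant set,
#' i.e. a site must have been called in all samples to survive).
#'
#' @param variant_sets list (one per sample) of data.frames with columns
#'   `contig`, `pos` (plus any allele columns, carried through from the first
#'   set containing each site)
#' @param callable_sets optional list of data.frames (`contig`, `pos`) giving
#'   each sample's called sites; defaults to `variant_sets`
#' @return data.frame of retained sites, sorted and unique
#' @export
merge_drop_missing <- function(variant_sets, callable_sets = variant_sets) {
  if (length(variant_sets) < 2) stop_input("need at least two samples to merge")
  key <- function(df) paste(df$contig, df$pos)
  union_df <- do.call(rbind, lapply(variant_sets, function(df) {
    df[, intersect(c("contig", "pos", "ref", "alt"), names(df)), drop = FALSE]
  }))
  union_df <- union_df[!duplicated(key(union_df)), , drop = FALSE]
  keep <- rep(TRUE, nrow(union_df))
  for (cs in callable_sets) {
    keep <- keep & key(union_df) %in% key(cs)
  }
  out <- union_df[keep, , drop = FALSE]
  out <- out[order(out$contig, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# per-sample pass vector: site passes genome layer, genotype passes sample
# layer and is non-missing
sample_pass <- function(gm, j) {
  gm$site_pass & gm$geno_pass[, j] & !is.na(gm$geno[, j])
}

#' Per-sample heterozygosity
#'
#' Ratio of passed-filter heterozygous genotype calls to all passed-filter
#' sites for the sample — the denominator includes callable invariant
#' positions, not just variant sites.
#'
#' @param gm a [geno_matrix]
#' @param sample_id sample name
#' @return numeric ratio, or `NA` when no site passes
#' @export
heterozygosity <- function(gm, sample_id) {
  j <- match(sample_id, gm$scheme$sample_id)
  if (is.na(j)) stop_input("unknown sample ", sample_id)
  on_excluded <- site_on_excluded(gm)
  pass <- sample_pass(gm, j)
  denom <- total_callable(gm) - sum(!on_excluded & !pass)
  if (denom <= 0) return(NA_real_)
  sum(gm$geno[, j] == 1L & pass, na.rm = TRUE) / denom
}

is_transition <- function(ref, alt) {
  (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
}

#' Transition/transversion ratio
#'
#' Counted over passed variant sites where the selected sample carries at
#' least one alternative allele (each site counts once per sample). With
#' `sample_id = NULL` a site counts once if any sample carries the
#' alternative.
#'
#' @param gm a [geno_matrix]
#' @param sample_id sample name, or `NULL` for the cohort
#' @return Ti/Tv ratio; `NA` when there are no transversions
#' @export
titv <- function(gm, sample_id = NULL) {
  if (is.null(sample_id)) {
    carries <- rowSums(gm$geno * gm$geno_pass, na.rm = TRUE) > 0
    use <- gm$site_pass & carries
  } else {
    j <- match(sample_id, gm$scheme$sample_id)
    if (is.na(j)) stop_input("unknown sample ", sample_id)
    use <- sample_pass(gm, j) & !is.na(gm$geno[, j]) & gm$geno[, j] >= 1L
  }
  ti <- sum(use & is_transition(gm$sites$ref, gm$sites$alt))
  tv <- sum(use) - ti
  if (tv == 0) return(NA_real_)
  ti / tv
}

#' Per-class genotype concordance between two call sets
#'
#' For each genotype class of the first call set (hom-ref, het, hom-alt),
#' the fraction of sites where the second set agrees, over sites non-missing
#' in both.
#'
#' @param calls_a,calls_b integer genotype vectors (codes 0/1/2/NA) over the
#'   same sites
#' @return named numeric vector `c(hom_ref=, het=, hom_alt=)`; `NA` for an
#'   empty class
#' @export
genotype_concordance <- function(calls_a, calls_b) {
  if (length(calls_a) != length(calls_b)) stop_input("call vectors differ in length")
  both <- !is.na(calls_a) & !is.na(calls_b)
  out <- c(hom_ref = NA_real_, het = NA_real_, hom_alt = NA_real_)
  for (k in 0:2) {
    idx <- both & calls_a == k
    if (any(idx)) out[k + 1L] <- mean(calls_b[idx] == calls_a[idx])
  }
  out
}

#' Diagnostic-allele admixture screen
#'
#' For each sample, the fraction of observed alleles at ancestry-informative
#' marker sites that match the diagnostic (wolf) allele; samples below the
#' threshold are flagged as admixed.
#'
#' @param gm a [geno_matrix]
#' @param diagnostic_alleles data.frame with columns `contig`, `pos` (0-based)
#'   and `wolf_allele` (`"ref"` or `"alt"`)
#' @param threshold flagging threshold on the diagnostic fraction
#' @return data.frame (`sample_id`, `fraction`, `admixed`); `NA` fraction when
#'   a sample has no genotyped marker
#' @export
ancestry_screen <- function(gm, diagnostic_alleles, threshold = 0.90) {
  if (threshold <= 0 || threshold > 1) stop_input("threshold must be in (0,1]")
  key_m <- paste(gm$sites$contig, gm$sites$pos)
  idx <- match(paste(diagnostic_alleles$contig, diagnostic_alleles$pos), key_m)
  if (all(is.na(idx))) stop_input("no diagnostic marker overlaps the matrix sites")
  use <- !is.na(idx)
  idx <- idx[use]
  wolf_is_alt <- diagnostic_alleles$wolf_allele[use] == "alt"

  out <- data.frame(sample_id = gm$scheme$sample_id, fraction = NA_real_,
                    admixed = NA, stringsAsFactors = FALSE)
  for (j in seq_len(n_samples(gm))) {
    g <- gm$geno[idx, j]
    ok <- !is.na(g)
    if (!any(ok)) next
    carried <- sum(ifelse(wolf_is_alt[ok], g[ok], 2L - g[ok]))
    observed <- 2L * sum(ok)
    out$fraction[j] <- carried / observed
    out$admixed[j] <- out$fraction[j] < threshold
  }
  out
}

#' Per-sample QC summary
#'
#' @param gm a [geno_matrix]
#' @return data.frame with one row per sample: SNP count (sites where the
#'   sample carries an alternative allele and passes both mask layers),
#'   passed-site count, heterozygosity and Ti/Tv
#' @export
sample_qc_stats <- function(gm) {
  on_excluded <- site_on_excluded(gm)
  do.call(rbind, lapply(seq_len(n_samples(gm)), function(j) {
    pass <- sample_pass(gm, j)
    data.frame(
      sample_id = gm$scheme$sample_id[j],
      subpop = gm$scheme$subpop[j],
      n_snps = sum(pass & gm$geno[, j] >= 1L, na.rm = TRUE),
      n_passed_sites = total_callable(gm) - sum(!on_excluded & !pass),
      heterozygosity = heterozygosity(gm, gm$scheme$sample_id[j]),
      titv = titv(gm, gm$scheme$sample_id[j]),
      stringsAsFactors = FALSE
    )
  }))
}
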