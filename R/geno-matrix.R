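#' Diploid genotype matrix for a two-population cohort
#'
#' The central data container: biallelic SNP sites by samples, diploid genotype
#' codes, a sample-to-subpopulation scheme, and the two mask layers used by the
#' filtering framework — a per-site mask (genome-level filters) and a
#' per-genotype mask (sample-level filters). Positions are 0-based internally;
#' VCF output is 1-based.
#'
#' Genotype codes: 0 = homozygous reference, 1 = heterozygous, 2 = homozygous
#' alternative, `NA` = missing.
#'
#' @param sites data.frame with columns `contig`, `pos` (0-based), `ref`, `alt`
#' @param geno integer matrix, `nrow(sites)` x `n samples`, codes 0/1/2/NA
#' @param scheme data.frame with columns `sample_id`, `subpop`; subpopulations
#'   must be one of Tibet, Qinghai, Xinjiang, InnerMongolia (Tibet and Qinghai
#'   map to the highland class, the others to lowland)
#' @param contigs data.frame with columns `contig`, `length`
#' @param excluded optional named list (by contig) of sorted 0-based positions
#'   excluded genome-wide (e.g. CpG sites); these reduce callable-site counts
#' @return an object of class `geno_matrix`
#' @export
geno_matrix <- function(sites, geno, scheme, contigs, excluded = list()) {
  sites <- as.data.frame(sites)
  stopifnot(all(c("contig", "pos", "ref", "alt") %in% names(sites)))
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != nrow(sites)) {
    stop_input("geno has ", nrow(geno), " rows but sites has ", nrow(sites))
  }
  scheme <- as.data.frame(scheme)
  stopifnot(all(c("sample_id", "subpop") %in% names(scheme)))
  if (ncol(geno) != nrow(scheme)) {
    stop_input("geno has ", ncol(geno), " columns but scheme lists ",
               nrow(scheme), " samples")
  }
  bad <- setdiff(unique(scheme$subpop), names(SUBPOP_CLASS))
  if (length(bad)) stop_input("unknown subpopulation(s): ", paste(bad, collapse = ", "))
  scheme$class <- unname(SUBPOP_CLASS[scheme$subpop])
  colnames(geno) <- scheme$sample_id

  codes <- geno[!is.na(geno)]
  if (length(codes) && (any(codes < 0L) || any(codes > 2L))) {
    stop_input("genotype codes must be 0, 1, 2 or NA")
  }
  if (nrow(sites)) {
    if (any(sites$ref == sites$alt)) stop_input("ref and alt alleles must differ")
    if (!all(c(sites$ref, sites$alt) %in% c("A", "C", "G", "T"))) {
      stop_input("alleles must be A/C/G/T (biallelic SNPs only)")
    }
    o <- order(sites$contig, sites$pos)
    sites <- sites[o, , drop = FALSE]
    geno <- geno[o, , drop = FALSE]
    if (anyDuplicated(paste(sites$contig, sites$pos))) {
      stop_input("duplicate sites are not allowed")
    }
    rownames(sites) <- NULL
  }
  contigs <- as.data.frame(contigs)
  stopifnot(all(c("contig", "length") %in% names(contigs)))

  structure(list(
    sites = sites,
    geno = geno,
    scheme = scheme,
    contigs = contigs,
    site_pass = rep(TRUE, nrow(sites)),
    geno_pass = matrix(TRUE, nrow(sites), ncol(geno),
                       dimnames = list(NULL, colnames(geno))),
    excluded = excluded
  ), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$sites), "sites x", ncol(x$geno), "samples\n")
  tab <- table(x$scheme$class)
  cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  contigs:", nrow(x$contigs),
      sprintf("(%.1f Mb)", sum(as.numeric(x$contigs$length)) / 1e6), "\n")
  cat("  sites passing genome-level mask:", sum(x$site_pass), "\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) c(nrow(x$sites), ncol(x$geno))

n_samples <- function(gm) ncol(gm$geno)

samples_of_class <- function(gm, class) {
  which(gm$scheme$class == class)
}

samples_of_subpop <- function(gm, subpop) {
  which(gm$scheme$subpop == subpop)
}

#' Count callable positions of a window
#'
#' Callable positions are all reference positions minus genome-level excluded
#' positions (e.g. CpG sites). Interval is 0-based half-open.
#' @param gm a [geno_matrix]
#' @param contig contig name
#' @param start,end 0-based half-open bounds
#' @return integer count
#' @export
n_callable <- function(gm, contig, start, end) {
  width <- end - start
  ex <- gm$excluded[[contig]]
  if (is.null(ex) || !length(ex)) return(as.integer(width))
  as.integer(width - sum(ex >= start & ex < end))
}

total_callable <- function(gm) {
  sum(as.numeric(gm$contigs$length)) - sum(lengths(gm$excluded))
}

# flag marking variant rows that sit on genome-excluded positions (kept in the
# table for reporting but never double-counted against callable totals)
site_on_excluded <- function(gm) {
  if (!length(gm$excluded)) return(rep(FALSE, nrow(gm$sites)))
  out <- logical(nrow(gm$sites))
  for (ctg in unique(gm$sites$contig)) {
    ex <- gm$excluded[[ctg]]
    if (is.null(ex)) next
    idx <- which(gm$sites$contig == ctg)
    out[idx] <- gm$sites$pos[idx] %in% ex
  }
  out
}

subset_sites <- function(gm, keep) {
  gm$sites <- gm$sites[keep, , drop = FALSE]
  rownames(gm$sites) <- NULL
  gm$geno <- gm$geno[keep, , drop = FALSE]
  gm$site_pass <- gm$site_pass[keep]
  gm$geno_pass <- gm$geno_pass[keep, , drop = FALSE]
  if (!is.null(gm$dp)) gm$dp <- gm$dp[keep, , drop = FALSE]
  if (!is.null(gm$gq)) gm$gq <- gm$gq[keep, , drop = FALSE]
  gm
}

#' Write genotypes as a minimal VCF v4.2 (GT field only)
#'
#' @param gm a [geno_matrix]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_vcf_geno <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=altisweep",
    sprintf("##contig=<ID=%s,length=%d>", gm$contigs$contig, gm$contigs$length),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$scheme$sample_id), collapse = "\t")
  ), con)
  if (nrow(gm$sites)) {
    gt <- matrix(c("0/0", "0/1", "1/1")[gm$geno + 1L],
                 nrow(gm$geno), ncol(gm$geno))
    gt[is.na(gm$geno)] <- "./."
    lines <- paste(
      gm$sites$contig, gm$sites$pos + 1L, ".", gm$sites$ref, gm$sites$alt,
      ".", "PASS", ".", "GT",
      apply(gt, 1L, paste, collapse = "\t"),
      sep = "\t"
    )
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a VCF and a population map into a genotype matrix
#'
#' Only biallelic SNPs are retained; the GT field is decoded to 0/1/2/NA codes.
#' Contig lengths are taken from the VCF header when declared, otherwise from
#' the maximum observed position per contig.
#'
#' @param vcf_path VCF v4.2 file (plain text or gzipped)
#' @param pop_path two-column TSV (`sample_id`, `subpop`); ignored when `scheme`
#'   is supplied
#' @param scheme optional scheme data.frame in place of `pop_path`
#' @return a [geno_matrix]
#' @export
read_vcf_geno <- function(vcf_path, pop_path = NULL, scheme = NULL) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  snp <- fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  fix <- fix[snp, , drop = FALSE]
  gt_raw <- gt_raw[snp, , drop = FALSE]

  decode <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(NA_integer_, length(g))
    out[g %in% c("0/0")] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g %in% c("1/1")] <- 2L
    out
  }
  geno <- apply(gt_raw, 2L, decode)
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = nrow(fix))

  if (is.null(scheme)) {
    if (is.null(pop_path)) stop_input("either pop_path or scheme is required")
    scheme <- utils::read.table(pop_path, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  }
  scheme <- scheme[match(colnames(gt_raw), scheme$sample_id), , drop = FALSE]
  if (anyNA(scheme$sample_id)) {
    stop_input("population map does not cover all VCF samples")
  }

  meta <- v@meta
  ctg_lines <- grep("^##contig=", meta, value = TRUE)
  if (length(ctg_lines)) {
    ids <- sub('.*ID=([^,>]+).*', "\\1", ctg_lines)
    lens <- suppressWarnings(as.integer(sub('.*length=([0-9]+).*', "\\1", ctg_lines)))
    contigs <- data.frame(contig = ids, length = lens, stringsAsFactors = FALSE)
  } else {
    pos1 <- as.integer(fix$POS)
    contigs <- stats::aggregate(pos1, list(contig = fix$CHROM), max)
    names(contigs)[2] <- "length"
  }

  geno_matrix(
    sites = data.frame(contig = fix$CHROM, pos = as.integer(fix$POS) - 1L,
                       ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE),
    geno = geno, scheme = scheme, contigs = contigs
  )
}

#' Write the sample-to-subpopulation map as TSV
#' @param gm a [geno_matrix]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_pop_tsv <- function(gm, path) {
  write_tsv(gm$scheme[, c("sample_id", "subpop")], path)
  invisible(path)
}
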