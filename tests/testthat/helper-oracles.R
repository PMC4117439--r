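# Independent oracles used across the suite. Each is a deliberately naive,
# literal implementation kept separate from the package's vectorized code.

# literal per-site transcription of the Weir & Cockerham (1984) two-level
# variance components for r = 2 populations, scalar arithmetic throughout
wc_fst_literal <- function(g1, g2) {
  stopifnot(nrow(g1) == nrow(g2))
  num <- 0; den <- 0
  r <- 2
  for (s in seq_len(nrow(g1))) {
    x1 <- g1[s, ][!is.na(g1[s, ])]
    x2 <- g2[s, ][!is.na(g2[s, ])]
    n1 <- length(x1); n2 <- length(x2)
    if (n1 < 1 || n2 < 1) next
    p1 <- sum(x1) / (2 * n1)
    p2 <- sum(x2) / (2 * n2)
    if (p1 == p2 && (p1 == 0 || p1 == 1)) next  # monomorphic overall
    h1 <- sum(x1 == 1) / n1
    h2 <- sum(x2 == 1) / n2
    nbar <- (n1 + n2) / r
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) * (s2 - 1 / (nbar - 1) *
                          (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  if (den == 0) return(NA_real_)
  num / den
}

# explicit all-pairs chromosome comparison for per-site nucleotide diversity
pi_allpairs <- function(geno_row) {
  alleles <- integer()
  for (g in geno_row) {
    if (is.na(g)) next
    alleles <- c(alleles, switch(as.character(g),
                                 "0" = c(0L, 0L), "1" = c(0L, 1L), "2" = c(1L, 1L)))
  }
  n <- length(alleles)
  if (n < 2) return(0)
  diffs <- 0; pairs <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      pairs <- pairs + 1
      diffs <- diffs + (alleles[i] != alleles[j])
    }
  }
  diffs / pairs
}

# naive sort-based empirical percentile (average rank under ties)
percentile_naive <- function(v) {
  n <- length(v)
  out <- numeric(n)
  for (i in seq_len(n)) {
    below <- sum(v < v[i])
    ties <- sum(v == v[i])
    out[i] <- (below + (1 + ties) / 2) / n * 100
  }
  out
}

# brute-force gap-rule region merger
merge_regions_naive <- function(w, gap) {
  if (!nrow(w)) return(w)
  w <- w[order(w$contig, w$start), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(w))) {
    placed <- FALSE
    for (k in seq_along(out)) {
      if (out[[k]]$contig == w$contig[i] &&
          w$start[i] - out[[k]]$end <= gap && w$end[i] >= out[[k]]$start) {
        out[[k]]$start <- min(out[[k]]$start, w$start[i])
        out[[k]]$end <- max(out[[k]]$end, w$end[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) out[[length(out) + 1]] <- list(contig = w$contig[i],
                                                start = w$start[i],
                                                end = w$end[i])
  }
  do.call(rbind, lapply(out, as.data.frame))
}

# build a small in-memory cohort around an explicit genotype matrix
# (rows = sites); default scheme is the nine-sample design
make_gm <- function(geno, pos = NULL, scheme = altisweep::default_samples(),
                    contig_len = 1e6, ref = NULL, alt = NULL) {
  geno <- as.matrix(geno)
  n <- nrow(geno)
  if (is.null(pos)) pos <- seq(100L, by = 100L, length.out = n)
  if (is.null(ref)) ref <- rep("A", n)
  if (is.null(alt)) alt <- rep("G", n)
  altisweep::geno_matrix(
    sites = data.frame(contig = rep("chr1", n), pos = pos, ref = ref, alt = alt,
                       stringsAsFactors = FALSE),
    geno = geno, scheme = scheme,
    contigs = data.frame(contig = "chr1", length = contig_len)
  )
}

# random genotype matrix for property tests
random_gm <- function(n_sites, scheme = altisweep::default_samples(),
                      contig_len = NULL, miss = 0) {
  ns <- nrow(scheme)
  geno <- matrix(sample(0:2, n_sites * ns, replace = TRUE), n_sites, ns)
  if (miss > 0) geno[runif(length(geno)) < miss] <- NA_integer_
  if (is.null(contig_len)) contig_len <- n_sites * 100 + 1000
  pos <- sort(sample.int(contig_len - 10L, n_sites))
  make_gm(geno, pos = pos, scheme = scheme, contig_len = contig_len)
}

# exact upper-tail hypergeometric probability by combinatorial summation
hyper_upper_exact <- function(k, K, N, n) {
  sum(vapply(k:min(K, n), function(x) {
    choose(K, x) * choose(N - K, n - x) / choose(N, n)
  }, numeric(1)))
}

# single-exon gene whose CDS is ATG | codon | TAA, placed at 0-based
# position 10 on a 50-bp contig; used by the exhaustive codon-change checks
single_codon_gene <- function(codon, strand = "+") {
  coding <- paste0("ATG", codon, "TAA")
  genomic <- if (strand == "+") coding else altisweep:::revcomp(coding)
  seqs <- c(chr1 = paste0("AAAAACCCCC", genomic,
                          paste(rep("A", 31), collapse = "")))
  ref <- list(sequences = seqs,
              contigs = data.frame(contig = "chr1", length = nchar(seqs)))
  genes <- altisweep::gene_models(
    genes = data.frame(gene_id = "G1", name = "G1", source = "t",
                       contig = "chr1", strand = strand, start = 10L,
                       end = 10L + nchar(coding)),
    transcripts = data.frame(tx_id = "G1.1", gene_id = "G1"),
    exons = data.frame(tx_id = "G1.1", contig = "chr1", start = 10L,
                       end = 10L + nchar(coding)),
    cds = data.frame(tx_id = "G1.1", contig = "chr1", start = 10L,
                     end = 10L + nchar(coding))
  )
  list(ref = ref, genes = genes)
}
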