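test_that("ORF intactness names the first violated rule", {
  expect_true(orf_intact("ATGAAATAA")$intact)
  r1 <- orf_intact("ATGTGATAA")
  expect_false(r1$intact); expect_equal(r1$reason, "internal_stop_codon")
  r2 <- orf_intact("ATGAAAA")
  expect_false(r2$intact); expect_equal(r2$reason, "length_not_multiple_of_3")
  expect_false(orf_intact("TTGAAATAA")$intact)
  expect_false(orf_intact("ATGAAAAAA")$intact)
  expect_error(orf_intact(""), class = "altisweep_input_error")
})

# minimal single-exon gene on a hand-built reference
plus_gene_fixture <- function(cds_codon, strand = "+") {
  # CDS = ATG | codon | TAA starting at 0-based position 10
  coding <- paste0("ATG", cds_codon, "TAA")
  pad5 <- "AAAAACCCCC"
  pad3 <- paste(rep("A", 30), collapse = "")
  genomic <- if (strand == "+") coding else altisweep:::revcomp(coding)
  seqs <- c(chr1 = paste0(pad5, genomic, pad3))
  ref <- list(sequences = seqs,
              contigs = data.frame(contig = "chr1", length = nchar(seqs)))
  genes <- gene_models(
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

test_that("effect classification handles worked codon changes", {
  # TCT -> ACT at the first codon position: Ser -> Thr
  fx <- plus_gene_fixture("TCT")
  eff <- classify_effect("chr1", 13L, "T", "A", fx$genes, fx$ref)
  expect_equal(eff$category, "nonsynonymous")
  expect_equal(eff$aa_change, "S2T")

  # GCT -> GCC at the third position: synonymous
  fx2 <- plus_gene_fixture("GCT")
  eff2 <- classify_effect("chr1", 15L, "T", "C", fx2$genes, fx2$ref)
  expect_equal(eff2$category, "synonymous")

  # minus strand: transcript codon CAT -> CGT (H -> R); genomic change is the
  # complement at the middle codon position
  fx3 <- plus_gene_fixture("CAT", strand = "-")
  # genome holds revcomp("ATG CAT TAA") = TTAATGCAT; transcript codon 2 middle
  # base A sits at genomic position 10 + 4 (revcomp index): locate it directly
  genomic <- fx3$ref$sequences[["chr1"]]
  # transcript positions map to genomic 0-based (10 + 8) - cds_index
  # codon 2 middle base has cds_index 4 -> genomic pos 14
  eff3 <- classify_effect("chr1", 14L, substr(genomic, 15, 15), "C",
                          fx3$genes, fx3$ref)
  expect_equal(eff3$category, "nonsynonymous")
  expect_equal(eff3$aa_change, "H2R")

  # reference mismatch is a data error naming the position
  expect_error(classify_effect("chr1", 13L, "G", "A", fx$genes, fx$ref),
               class = "altisweep_data_error")
})

test_that("effect classification partitions simulated SNP sets", {
  ref <- generate_reference(40000, 0.4, seed = 31)
  gen <- generate_gene_models(ref, 6, seed = 31)
  cfg <- sim_config(genome_length = 40000, sweep_intervals = list(),
                    n_planted_causal = 0L, theta = 0.005, seed = 31)
  sim <- simulate_cohort(cfg, reference = gen$reference)
  eff <- classify_effects(sim$matrix, gen$genes, gen$reference)
  expect_equal(nrow(eff), nrow(sim$matrix$sites))
  expect_true(all(eff$category %in% c("synonymous", "nonsynonymous", "utr5",
                                      "utr3", "intron", "intergenic")))
  coding <- eff$category %in% c("synonymous", "nonsynonymous")
  expect_true(all(!is.na(eff$aa_change[coding])))
  expect_true(all(is.na(eff$aa_change[!coding])))
  # intron/UTR/CDS calls carry their gene
  expect_true(all(!is.na(eff$gene_id[eff$category != "intergenic"])))
})

test_that("catalog deduplication applies the name and exon-sharing rules", {
  mk <- function(prefix, starts, ends, name, source, contig = "chr1",
                 exon_breaks = NULL) {
    gid <- paste0(prefix, "_g")
    tid <- paste0(prefix, "_t")
    if (is.null(exon_breaks)) {
      ex <- data.frame(tx_id = tid, contig = contig, start = starts, end = ends)
    } else {
      ex <- data.frame(tx_id = tid, contig = contig,
                       start = exon_breaks$start, end = exon_breaks$end)
    }
    gene_models(
      genes = data.frame(gene_id = gid, name = name, source = source,
                         contig = contig, strand = "+",
                         start = min(ex$start), end = max(ex$end)),
      transcripts = data.frame(tx_id = tid, gene_id = gid),
      exons = ex,
      cds = data.frame(tx_id = character(), contig = character(),
                       start = integer(), end = integer())
    )
  }

  # identical span and name -> one gene
  a <- mk("a", 100, 500, "KDR", "ensembl")
  b <- mk("b", 100, 500, "kdr", "ncbi")
  m <- dedup_gene_catalog(a, b)
  expect_equal(nrow(m$catalog$genes), 1L)
  expect_equal(m$duplicates$reason, "name_match")

  # overlapping, dissimilar names, 2 of 5 exons shared (40%) -> kept separate
  ex_a <- list(start = c(100, 300, 500, 700, 900),
               end = c(200, 400, 600, 800, 1000))
  ex_b <- list(start = c(100, 300, 450, 650, 850),
               end = c(200, 400, 560, 760, 960))
  a2 <- mk("a2", NULL, NULL, "GENEA", "ensembl", exon_breaks = ex_a)
  b2 <- mk("b2", NULL, NULL, "GENEB", "ncbi", exon_breaks = ex_b)
  m2 <- dedup_gene_catalog(a2, b2)
  expect_equal(nrow(m2$catalog$genes), 2L)

  # 3 of 5 shared (60%) is not > 60% -> separate; 4 of 5 (80%) merges
  ex_b3 <- list(start = c(100, 300, 500, 650, 850),
                end = c(200, 400, 600, 760, 960))
  m3 <- dedup_gene_catalog(a2, mk("b3", NULL, NULL, "GENEC", "ncbi",
                                  exon_breaks = ex_b3))
  expect_equal(nrow(m3$catalog$genes), 2L)
  ex_b4 <- list(start = c(100, 300, 500, 700, 850),
                end = c(200, 400, 600, 800, 960))
  m4 <- dedup_gene_catalog(a2, mk("b4", NULL, NULL, "GENED", "ncbi",
                                  exon_breaks = ex_b4))
  expect_equal(nrow(m4$catalog$genes), 1L)
  expect_equal(m4$duplicates$reason, "exon_share")

  # symmetric merged gene count, planted duplicates recovered
  m_ab <- dedup_gene_catalog(a2, b2)
  m_ba <- dedup_gene_catalog(b2, a2)
  expect_equal(nrow(m_ab$catalog$genes), nrow(m_ba$catalog$genes))
})

test_that("alignment QC computes gap fraction and identity per row", {
  aln <- c(refrow = "MKTALLV", same = "MKTALLV", gappy = "-------",
           gapped = "MKT-LLV")
  qc <- alignment_qc(aln, "refrow")
  expect_equal(qc$gap_fraction[qc$sequence_id == "same"], 0)
  expect_equal(qc$identity[qc$sequence_id == "same"], 1)
  expect_true(qc$passed[qc$sequence_id == "same"])
  expect_false(qc$passed[qc$sequence_id == "gappy"])
  # one gap among 7 columns exceeds the 10% default gap threshold
  expect_equal(qc$gap_fraction[qc$sequence_id == "gapped"], 1 / 7)
  expect_false(qc$passed[qc$sequence_id == "gapped"])

  # random rows vs a column-scan oracle
  set.seed(37)
  for (i in 1:15) {
    L <- 40
    mkrow <- function() paste(sample(c(LETTERS[1:4], "-"), L, TRUE,
                                     prob = c(rep(0.22, 4), 0.12)), collapse = "")
    aln <- c(R = mkrow(), X = mkrow())
    qc <- alignment_qc(aln, "R", gap_threshold = 0.2, identity_threshold = 0.3)
    r <- strsplit(aln[["R"]], "")[[1]]; x <- strsplit(aln[["X"]], "")[[1]]
    both <- r != "-" & x != "-"
    expect_equal(qc$gap_fraction[2], sum(x == "-") / L)
    expect_equal(qc$identity[2],
                 if (any(both)) sum(x[both] == r[both]) / sum(both) else 0)
  }
  expect_error(alignment_qc(c(a = "AB", b = "ABC"), "a"),
               class = "altisweep_input_error")
})

test_that("hypergeometric enrichment matches exact combinatorics and BH rules", {
  universe <- sprintf("g%02d", 1:20)
  term_map <- data.frame(term_id = "T1", gene_id = universe[1:10])
  res <- enrich(universe[1:5], term_map, universe, min_genes = 5)
  expect_equal(res$p_raw, 252 / 15504, tolerance = 1e-12)
  expect_equal(res$p_raw, hyper_upper_exact(5, 10, 20, 5), tolerance = 1e-12)
  expect_true(res$reported)

  # k = 0 has upper-tail probability 1
  res0 <- enrich(universe[11:15],
                 data.frame(term_id = "T1", gene_id = universe[1:10]),
                 universe)
  expect_equal(res0$p_raw, 1)

  # a term with k = 4 is never reported, whatever its p-value
  res4 <- enrich(universe[1:4],
                 data.frame(term_id = "T1", gene_id = universe[1:4]),
                 universe)
  expect_lt(res4$p_bh, 0.01)
  expect_false(res4$reported)

  # BH is monotone in p_raw
  set.seed(43)
  tm <- do.call(rbind, lapply(1:12, function(t) {
    data.frame(term_id = paste0("T", t),
               gene_id = sample(universe, sample(3:12, 1)))
  }))
  res_m <- enrich(sample(universe, 8), tm, universe)
  expect_true(all(diff(res_m$p_bh[order(res_m$p_raw)]) >= -1e-15))

  expect_error(enrich(c("nope"), term_map, universe),
               class = "altisweep_input_error")
})
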