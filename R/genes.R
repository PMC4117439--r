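#' Gene model container
#'
#' Transcript-structured gene models with 0-based half-open internal
#' coordinates. `genes` carries one row per gene (span = union of its
#' transcripts), `transcripts` links transcripts to genes, `exons` and `cds`
#' carry the per-transcript intervals. UTRs are derivable as exonic sequence
#' outside the CDS.
#'
#' @param genes data.frame (`gene_id`, `name`, `source`, `contig`, `strand`,
#'   `start`, `end`)
#' @param transcripts data.frame (`tx_id`, `gene_id`)
#' @param exons data.frame (`tx_id`, `contig`, `start`, `end`)
#' @param cds data.frame (`tx_id`, `contig`, `start`, `end`)
#' @return an object of class `gene_models`
#' @export
gene_models <- function(genes, transcripts, exons, cds) {
  genes <- as.data.frame(genes)
  if (!"name" %in% names(genes)) genes$name <- genes$gene_id
  if (!"source" %in% names(genes)) genes$source <- "local"
  for (df_name in c("exons", "cds")) {
    df <- get(df_name)
    if (nrow(df) && any(df$start >= df$end)) {
      stop_input(df_name, " intervals must be non-empty (start < end)")
    }
  }
  exons <- exons[order(exons$tx_id, exons$start), , drop = FALSE]
  cds <- cds[order(cds$tx_id, cds$start), , drop = FALSE]
  # exons must not overlap within a transcript
  for (tx in unique(exons$tx_id)) {
    e <- exons[exons$tx_id == tx, , drop = FALSE]
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)])) {
      stop_input("overlapping exons in transcript ", tx)
    }
  }
  rownames(genes) <- rownames(transcripts) <- rownames(exons) <- rownames(cds) <- NULL
  structure(list(genes = genes, transcripts = as.data.frame(transcripts),
                 exons = exons, cds = cds),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,", nrow(x$transcripts),
      "transcripts\n")
  invisible(x)
}

#' Generate synthetic gene models on a reference
#'
#' Places non-overlapping multi-exon genes on both strands and patches the
#' reference sequence so every CDS is an intact open reading frame (ATG start,
#' single stop, length a multiple of 3, no internal stop). Deterministic
#' given the seed.
#'
#' @param reference output of [generate_reference]
#' @param n_genes number of genes to place
#' @param seed integer seed
#' @return list with `genes` (a [gene_models]) and `reference` (patched copy)
#' @export
generate_gene_models <- function(reference, n_genes, seed = 1L) {
  if (n_genes < 0) stop_input("n_genes must be >= 0")
  empty <- gene_models(
    genes = data.frame(gene_id = character(), name = character(),
                       source = character(), contig = character(),
                       strand = character(), start = integer(), end = integer(),
                       stringsAsFactors = FALSE),
    transcripts = data.frame(tx_id = character(), gene_id = character(),
                             stringsAsFactors = FALSE),
    exons = data.frame(tx_id = character(), contig = character(),
                       start = integer(), end = integer(), stringsAsFactors = FALSE),
    cds = data.frame(tx_id = character(), contig = character(),
                     start = integer(), end = integer(), stringsAsFactors = FALSE)
  )
  if (n_genes == 0) return(list(genes = empty, reference = reference))

  ctg <- reference$contigs
  slot_width <- 6000L  # bp of contig reserved per gene, incl. flanks
  capacity <- sum(pmax(0L, floor(ctg$length / slot_width)))
  if (capacity < n_genes) {
    stop_input("contig(s) too short to host ", n_genes, " genes: ",
               paste(ctg$contig, collapse = ", "))
  }

  with_seed(seed, {
    genes_l <- list(); tx_l <- list(); ex_l <- list(); cds_l <- list()
    seqs <- as.list(reference$sequences)
    placed <- 0L
    non_stop <- setdiff(names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE != "*"], "ATG")
    stops <- c("TAA", "TAG", "TGA")
    for (i in seq_len(nrow(ctg))) {
      n_here <- min(n_genes - placed, floor(ctg$length[i] / slot_width))
      if (n_here <= 0) next
      for (k in seq_len(n_here)) {
        placed <- placed + 1L
        gid <- sprintf("GENE%03d", placed)
        tid <- sprintf("TX%03d.1", placed)
        strand <- if (placed %% 2L == 0L) "-" else "+"
        slot0 <- (k - 1L) * slot_width + 500L  # gene's slot on this contig

        n_ex <- sample(1:3, 1)
        n_codons <- sample(40:120, 1)  # incl. start and stop
        coding <- paste0("ATG",
                         paste(sample(non_stop, n_codons - 2L, replace = TRUE),
                               collapse = ""),
                         sample(stops, 1))
        L <- nchar(coding)
        # split CDS across exons at codon-agnostic cut points
        cuts <- if (n_ex > 1) sort(sample(seq_len(L - 1L), n_ex - 1L)) else integer()
        piece_len <- diff(c(0L, cuts, L))
        utr5 <- sample(30:120, 1)
        utr3 <- sample(30:120, 1)
        introns <- if (n_ex > 1) sample(80:400, n_ex - 1L, replace = TRUE) else integer()

        # genomic (left-to-right) CDS piece lengths; transcript exon order is
        # reversed along the genome on the minus strand
        piece_g <- if (strand == "+") piece_len else rev(piece_len)
        exon_len <- piece_g
        if (strand == "+") {
          exon_len[1] <- exon_len[1] + utr5
          exon_len[n_ex] <- exon_len[n_ex] + utr3
        } else {
          exon_len[1] <- exon_len[1] + utr3   # 3'UTR is genomic-leftmost
          exon_len[n_ex] <- exon_len[n_ex] + utr5
        }

        gstart <- slot0
        ex_starts <- integer(n_ex); ex_ends <- integer(n_ex)
        pos <- gstart
        for (e in seq_len(n_ex)) {
          ex_starts[e] <- pos
          ex_ends[e] <- pos + exon_len[e]
          pos <- ex_ends[e] + if (e < n_ex) introns[e] else 0L
        }
        gend <- ex_ends[n_ex]
        cds_starts <- ex_starts; cds_ends <- ex_ends
        if (strand == "+") {
          cds_starts[1] <- cds_starts[1] + utr5
          cds_ends[n_ex] <- cds_ends[n_ex] - utr3
        } else {
          cds_starts[1] <- cds_starts[1] + utr3
          cds_ends[n_ex] <- cds_ends[n_ex] - utr5
        }
        stopifnot(all((cds_ends - cds_starts) == piece_g))

        # patch the sequence: the genomic concatenation of the CDS intervals
        # must read as the coding sequence (reverse complemented on -)
        s <- seqs[[ctg$contig[i]]]
        genomic_cds <- if (strand == "+") coding else revcomp(coding)
        off <- 0L
        for (e in seq_len(n_ex)) {
          frag <- substr(genomic_cds, off + 1L, off + piece_g[e])
          substr(s, cds_starts[e] + 1L, cds_ends[e]) <- frag
          off <- off + piece_g[e]
        }
        seqs[[ctg$contig[i]]] <- s

        genes_l[[placed]] <- data.frame(
          gene_id = gid, name = gid, source = "sim", contig = ctg$contig[i],
          strand = strand, start = gstart, end = gend, stringsAsFactors = FALSE)
        tx_l[[placed]] <- data.frame(tx_id = tid, gene_id = gid,
                                     stringsAsFactors = FALSE)
        ex_l[[placed]] <- data.frame(tx_id = tid, contig = ctg$contig[i],
                                     start = ex_starts, end = ex_ends,
                                     stringsAsFactors = FALSE)
        cds_l[[placed]] <- data.frame(tx_id = tid, contig = ctg$contig[i],
                                      start = cds_starts, end = cds_ends,
                                      stringsAsFactors = FALSE)
      }
      if (placed >= n_genes) break
    }
    reference$sequences <- unlist(seqs)
    list(
      genes = gene_models(do.call(rbind, genes_l), do.call(rbind, tx_l),
                          do.call(rbind, ex_l), do.call(rbind, cds_l)),
      reference = reference
    )
  })
}

#' Extract a transcript's CDS sequence
#'
#' Concatenates the CDS intervals in transcript orientation (reverse
#' complemented for minus-strand transcripts).
#'
#' @param genes a [gene_models]
#' @param tx_id transcript ID
#' @param reference output of [generate_reference]
#' @return character CDS sequence
#' @export
cds_sequence <- function(genes, tx_id, reference) {
  cds <- genes$cds[genes$cds$tx_id == tx_id, , drop = FALSE]
  if (!nrow(cds)) stop_input("transcript ", tx_id, " has no CDS")
  gid <- genes$transcripts$gene_id[genes$transcripts$tx_id == tx_id]
  strand <- genes$genes$strand[genes$genes$gene_id == gid]
  s <- reference$sequences[[cds$contig[1]]]
  pieces <- substring(s, cds$start + 1L, cds$end)
  seq <- paste(pieces, collapse = "")
  if (strand == "-") seq <- revcomp(seq)
  seq
}

#' Write gene models as GFF3
#'
#' @param genes a [gene_models]
#' @param path output path (1-based inclusive coordinates)
#' @return `path`, invisibly
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes$genes))) {
    g <- genes$genes[i, ]
    writeLines(sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                       g$contig, g$source, g$start + 1L, g$end, g$strand,
                       g$gene_id, g$name), con)
    txs <- genes$transcripts[genes$transcripts$gene_id == g$gene_id, , drop = FALSE]
    for (tid in txs$tx_id) {
      ex <- genes$exons[genes$exons$tx_id == tid, , drop = FALSE]
      cds <- genes$cds[genes$cds$tx_id == tid, , drop = FALSE]
      writeLines(sprintf("%s\t%s\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                         g$contig, g$source, min(ex$start) + 1L, max(ex$end),
                         g$strand, tid, g$gene_id), con)
      writeLines(sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                         ex$contig, g$source, ex$start + 1L, ex$end,
                         g$strand, tid), con)
      if (nrow(cds)) {
        # phase: bases to skip before the first complete codon of each piece
        lens <- cds$end - cds$start
        ord <- if (g$strand == "+") seq_len(nrow(cds)) else rev(seq_len(nrow(cds)))
        before <- cumsum(c(0L, lens[ord]))[seq_len(nrow(cds))]
        phase <- (3L - (before %% 3L)) %% 3L
        phase_g <- integer(nrow(cds)); phase_g[ord] <- phase
        writeLines(sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s",
                           cds$contig, g$source, cds$start + 1L, cds$end,
                           g$strand, phase_g, tid), con)
      }
    }
  }
  invisible(path)
}

#' Read gene models from GFF3 or GTF
#'
#' Uses the standard GFF/GTF importer and converts to the package's
#' 0-based-half-open [gene_models] container. Features without an mRNA parent
#' hierarchy are grouped by their transcript/Parent attribute.
#'
#' @param path GFF3 or GTF file
#' @param source source tag recorded on the genes
#' @return a [gene_models]
#' @export
read_gene_models <- function(path, source = NULL) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  typecol <- df$type

  is_gtf <- grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)
  if (is_gtf) {
    df$ID <- NA_character_
    df$Parent <- df$transcript_id
    gene_rows <- df[typecol == "transcript" | typecol == "gene", , drop = FALSE]
  }

  get_parent <- function(d) {
    if (is_gtf) return(d$Parent)
    vapply(d$Parent, function(p) if (length(p)) as.character(p[[1]]) else NA_character_,
           character(1))
  }

  g <- df[typecol == "gene", , drop = FALSE]
  tx <- df[typecol %in% c("mRNA", "transcript"), , drop = FALSE]
  ex <- df[typecol == "exon", , drop = FALSE]
  cds <- df[typecol == "CDS", , drop = FALSE]

  if (is_gtf) {
    if (!nrow(g)) {
      g <- tx[!duplicated(tx$gene_id), , drop = FALSE]
      g$ID <- g$gene_id
    } else {
      g$ID <- g$gene_id
    }
    tx$ID <- tx$transcript_id
    tx_parent <- tx$gene_id
    ex_parent <- ex$transcript_id
    cds_parent <- cds$transcript_id
  } else {
    tx_parent <- get_parent(tx)
    ex_parent <- get_parent(ex)
    cds_parent <- get_parent(cds)
  }

  name_col <- if ("Name" %in% names(g)) g$Name else g$ID
  genes_df <- data.frame(
    gene_id = g$ID, name = ifelse(is.na(name_col), g$ID, name_col),
    source = source %||% as.character(g$source),
    contig = g$seqnames, strand = g$strand,
    start = g$start - 1L, end = g$end, stringsAsFactors = FALSE)
  tx_df <- data.frame(tx_id = tx$ID, gene_id = tx_parent, stringsAsFactors = FALSE)
  ex_df <- data.frame(tx_id = ex_parent, contig = as.character(ex$seqnames),
                      start = ex$start - 1L, end = ex$end, stringsAsFactors = FALSE)
  cds_df <- data.frame(tx_id = cds_parent, contig = as.character(cds$seqnames),
                       start = cds$start - 1L, end = cds$end, stringsAsFactors = FALSE)
  gene_models(genes_df, tx_df, ex_df, cds_df)
}
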