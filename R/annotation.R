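#' Check a CDS for an intact open reading frame
#'
#' Intact means: starts with ATG, ends with a stop codon (TAA/TAG/TGA),
#' length is a multiple of 3 and there is no internal in-frame stop.
#'
#' @param cds_seq CDS nucleotide sequence (character scalar)
#' @return list with `intact` (logical) and `reason` (first violated rule, or
#'   `NA` when intact)
#' @export
orf_intact <- function(cds_seq) {
  if (!nchar(cds_seq)) stop_input("empty CDS sequence")
  s <- toupper(cds_seq)
  n <- nchar(s)
  fail <- function(reason) list(intact = FALSE, reason = reason)
  if (n %% 3L != 0L) return(fail("length_not_multiple_of_3"))
  if (substr(s, 1L, 3L) != "ATG") return(fail("no_start_codon"))
  codons <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
  stops <- GENETIC_CODE_TABLE[codons] == "*"
  stops[is.na(stops)] <- FALSE
  if (!stops[length(codons)]) return(fail("no_stop_codon"))
  if (any(stops[-length(codons)])) return(fail("internal_stop_codon"))
  list(intact = TRUE, reason = NA_character_)
}

#' Merge two gene catalogs, removing duplicated entries
#'
#' Genes from the two sources are considered duplicates when their spans
#' overlap on the same contig and either their names match (case-insensitive,
#' version suffixes stripped) or any pair of their transcripts shares more
#' than `exon_share_threshold` of its exons (identical coordinates, counted
#' against the transcript with fewer exons). The first catalog's entry is
#' kept; transcripts with exactly identical exon coordinates are deduplicated
#' and remaining transcripts of the dropped gene are attached as alternative
#' transcripts of the kept gene.
#'
#' @param set_a,set_b [gene_models] objects
#' @param exon_share_threshold fraction of shared exons above which two
#'   transcripts mark their genes as duplicates
#' @return list with `catalog` (merged [gene_models]) and `duplicates`
#'   (data.frame `kept_id`, `dropped_id`, `reason`)
#' @export
dedup_gene_catalog <- function(set_a, set_b, exon_share_threshold = 0.6) {
  norm_name <- function(x) tolower(sub("\\.[0-9]+$", "", x))
  exon_keys <- function(gm) {
    sapply(split(gm$exons, gm$exons$tx_id), function(e) {
      paste(e$contig, e$start, e$end, sep = ":", collapse = ";")
    })
  }
  exon_set <- function(gm, tx) {
    e <- gm$exons[gm$exons$tx_id == tx, , drop = FALSE]
    paste(e$contig, e$start, e$end, sep = ":")
  }
  tx_of_gene <- function(gm, gid) gm$transcripts$tx_id[gm$transcripts$gene_id == gid]

  dup <- data.frame(kept_id = character(), dropped_id = character(),
                    reason = character(), stringsAsFactors = FALSE)
  drop_b <- character()
  merge_into <- list()  # dropped B gene -> kept A gene

  for (i in seq_len(nrow(set_b$genes))) {
    gb <- set_b$genes[i, ]
    cand <- which(set_a$genes$contig == gb$contig &
                    set_a$genes$start < gb$end & set_a$genes$end > gb$start)
    for (j in cand) {
      ga <- set_a$genes[j, ]
      reason <- NULL
      if (norm_name(ga$name) == norm_name(gb$name)) {
        reason <- "name_match"
      } else {
        for (ta in tx_of_gene(set_a, ga$gene_id)) {
          ea <- exon_set(set_a, ta)
          for (tb in tx_of_gene(set_b, gb$gene_id)) {
            eb <- exon_set(set_b, tb)
            share <- length(intersect(ea, eb)) / min(length(ea), length(eb))
            if (share > exon_share_threshold) {
              reason <- "exon_share"
              break
            }
          }
          if (!is.null(reason)) break
        }
      }
      if (!is.null(reason)) {
        dup <- rbind(dup, data.frame(kept_id = ga$gene_id,
                                     dropped_id = gb$gene_id,
                                     reason = reason, stringsAsFactors = FALSE))
        drop_b <- c(drop_b, gb$gene_id)
        merge_into[[gb$gene_id]] <- ga$gene_id
        break
      }
    }
  }

  keep_b <- !(set_b$genes$gene_id %in% drop_b)
  genes <- rbind(set_a$genes, set_b$genes[keep_b, , drop = FALSE])

  # transcripts: all of A; B's transcripts reassigned (for dropped genes) or
  # kept, minus exact-exon duplicates of an already-present transcript
  keys_a <- exon_keys(set_a)
  reassigned <- vapply(set_b$transcripts$gene_id, function(g) {
    if (!is.null(merge_into[[g]])) merge_into[[g]] else g
  }, character(1))
  tx_b <- set_b$transcripts
  tx_b$gene_id <- unname(reassigned)
  keys_b <- exon_keys(set_b)
  dup_tx <- names(keys_b)[keys_b %in% keys_a]
  tx_b <- tx_b[!(tx_b$tx_id %in% dup_tx), , drop = FALSE]
  # transcripts of kept-separate B genes keep their own gene
  transcripts <- rbind(set_a$transcripts, tx_b)
  exons <- rbind(set_a$exons,
                 set_b$exons[set_b$exons$tx_id %in% tx_b$tx_id, , drop = FALSE])
  cds <- rbind(set_a$cds,
               set_b$cds[set_b$cds$tx_id %in% tx_b$tx_id, , drop = FALSE])
  # drop gene rows for B genes fully merged away
  genes <- genes[!(genes$gene_id %in% drop_b), , drop = FALSE]

  list(catalog = gene_models(genes, transcripts, exons, cds), duplicates = dup)
}

# ordered worst-first; classification keeps the highest-precedence category
# across overlapping transcripts
EFFECT_PRECEDENCE <- c("nonsynonymous", "synonymous", "utr5", "utr3",
                       "intron", "intergenic")

classify_one_tx <- function(pos, ref, alt, tx_id, genes, reference) {
  gid <- genes$transcripts$gene_id[genes$transcripts$tx_id == tx_id]
  strand <- genes$genes$strand[genes$genes$gene_id == gid]
  ex <- genes$exons[genes$exons$tx_id == tx_id, , drop = FALSE]
  cds <- genes$cds[genes$cds$tx_id == tx_id, , drop = FALSE]
  in_exon <- any(pos >= ex$start & pos < ex$end)
  if (!in_exon) {
    if (pos >= min(ex$start) && pos < max(ex$end)) {
      return(list(category = "intron", aa_change = NA_character_,
                  codon_change = NA_character_))
    }
    return(NULL)
  }
  in_cds_piece <- which(pos >= cds$start & pos < cds$end)
  if (!length(in_cds_piece)) {
    # UTR: side relative to the CDS in transcript orientation
    if (!nrow(cds)) {
      cat5 <- "utr5"  # non-coding transcript: treat exonic hit as 5' UTR class
      return(list(category = cat5, aa_change = NA_character_,
                  codon_change = NA_character_))
    }
    before_cds <- pos < min(cds$start)
    cat <- if ((strand == "+" && before_cds) || (strand == "-" && !before_cds)) {
      "utr5"
    } else "utr3"
    return(list(category = cat, aa_change = NA_character_,
                codon_change = NA_character_))
  }
  # coding: index of the base within the CDS in transcript orientation
  lens <- cds$end - cds$start
  if (strand == "+") {
    k <- in_cds_piece
    before <- if (k > 1) sum(lens[seq_len(k - 1L)]) else 0L
    cds_index <- before + (pos - cds$start[k])  # 0-based
  } else {
    k <- in_cds_piece
    after <- if (k < nrow(cds)) sum(lens[seq(k + 1L, nrow(cds))]) else 0L
    cds_index <- after + (cds$end[k] - 1L - pos)
  }
  codon_i <- cds_index %/% 3L       # 0-based codon index
  within <- cds_index %% 3L         # 0-based position within codon
  full_cds <- cds_sequence(genes, tx_id, reference)
  codon_ref <- substr(full_cds, codon_i * 3L + 1L, codon_i * 3L + 3L)
  base_ref_tx <- if (strand == "+") ref else unname(DNA_COMPLEMENT[ref])
  base_alt_tx <- if (strand == "+") alt else unname(DNA_COMPLEMENT[alt])
  if (substr(codon_ref, within + 1L, within + 1L) != base_ref_tx) {
    stop_data("reference allele mismatch at position ", pos,
              " in transcript ", tx_id)
  }
  codon_alt <- codon_ref
  substr(codon_alt, within + 1L, within + 1L) <- base_alt_tx
  aa_ref <- translate_codon(codon_ref)
  aa_alt <- translate_codon(codon_alt)
  cat <- if (aa_ref == aa_alt) "synonymous" else "nonsynonymous"
  list(category = cat,
       aa_change = paste0(aa_ref, codon_i + 1L, aa_alt),
       codon_change = paste0(codon_ref, ">", codon_alt))
}

#' Classify the functional effect of a SNP
#'
#' Strand-aware codon lookup against the reference: synonymous or
#' nonsynonymous inside CDS (with amino-acid change such as `S214T`), 5'/3'
#' UTR inside exons outside CDS, intron inside a transcript span otherwise,
#' intergenic outside all transcripts. Across overlapping transcripts the
#' worst consequence wins (nonsynonymous > synonymous > UTR > intron).
#'
#' @param contig,pos SNP location (`pos` 0-based)
#' @param ref,alt alleles; `ref` must match the reference base
#' @param genes a [gene_models]
#' @param reference output of [generate_reference]
#' @return list with `category`, `gene_id`, `aa_change`, `codon_change`
#' @export
classify_effect <- function(contig, pos, ref, alt, genes, reference) {
  base <- substr(reference$sequences[[contig]], pos + 1L, pos + 1L)
  if (!identical(base, ref)) {
    stop_data("reference mismatch at ", contig, ":", pos,
              " (reference has ", base, ", variant claims ", ref, ")")
  }
  hits <- list()
  gene_hit <- character()
  g_idx <- which(genes$genes$contig == contig & genes$genes$start <= pos &
                   genes$genes$end > pos)
  for (j in g_idx) {
    gid <- genes$genes$gene_id[j]
    for (tid in genes$transcripts$tx_id[genes$transcripts$gene_id == gid]) {
      res <- classify_one_tx(pos, ref, alt, tid, genes, reference)
      if (!is.null(res)) {
        res$gene_id <- gid
        hits[[length(hits) + 1L]] <- res
      }
    }
  }
  if (!length(hits)) {
    return(list(category = "intergenic", gene_id = NA_character_,
                aa_change = NA_character_, codon_change = NA_character_))
  }
  prec <- match(vapply(hits, `[[`, character(1), "category"), EFFECT_PRECEDENCE)
  best <- hits[[which.min(prec)]]
  list(category = best$category, gene_id = best$gene_id,
       aa_change = best$aa_change, codon_change = best$codon_change)
}

#' Classify every site of a genotype matrix
#'
#' @param gm a [geno_matrix]
#' @param genes a [gene_models]
#' @param reference output of [generate_reference]
#' @return data.frame: site columns plus `category`, `gene_id`, `aa_change`
#' @export
classify_effects <- function(gm, genes, reference) {
  res <- lapply(seq_len(nrow(gm$sites)), function(i) {
    s <- gm$sites[i, ]
    e <- classify_effect(s$contig, s$pos, s$ref, s$alt, genes, reference)
    data.frame(contig = s$contig, pos = s$pos, ref = s$ref, alt = s$alt,
               category = e$category, gene_id = e$gene_id,
               aa_change = e$aa_change, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Ortholog-alignment quality control
#'
#' Per-row gap fraction and identity to the reference row; rows with more
#' gaps than `gap_threshold` or identity below `identity_threshold` fail.
#' Identity is computed over columns where both rows are non-gap.
#'
#' @param alignment named character vector of equal-length aligned sequences
#'   (`-` for gaps)
#' @param reference_row name of the reference sequence in `alignment`
#' @param gap_threshold maximum tolerated gap fraction
#' @param identity_threshold minimum identity to the reference
#' @return data.frame (`sequence_id`, `gap_fraction`, `identity`, `passed`)
#' @export
alignment_qc <- function(alignment, reference_row,
                         gap_threshold = 0.10, identity_threshold = 0.60) {
  if (length(unique(nchar(alignment))) != 1L) {
    stop_input("ragged alignment: rows differ in length")
  }
  if (!reference_row %in% names(alignment)) {
    stop_input("reference row ", reference_row, " not in alignment")
  }
  ref <- strsplit(alignment[[reference_row]], "")[[1]]
  out <- lapply(names(alignment), function(nm) {
    row <- strsplit(alignment[[nm]], "")[[1]]
    gap_fraction <- mean(row == "-")
    both <- row != "-" & ref != "-"
    identity <- if (any(both)) mean(row[both] == ref[both]) else 0
    data.frame(sequence_id = nm, gap_fraction = gap_fraction,
               identity = identity,
               passed = gap_fraction <= gap_threshold &
                 identity >= identity_threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Gene-set enrichment by hypergeometric test
#'
#' Upper-tail hypergeometric p-value per term, Benjamini-Hochberg correction
#' across tested terms; a term is `reported` when it holds at least
#' `min_genes` selected genes and its corrected p-value is at most
#' `alpha`.
#'
#' @param selected character vector of selected gene IDs (subset of `universe`)
#' @param term_map data.frame (`term_id`, `gene_id`)
#' @param universe character vector of all gene IDs
#' @param min_genes reporting threshold on selected genes per term
#' @param alpha reporting threshold on the BH-corrected p-value
#' @return data.frame (`term_id`, `k`, `K`, `n`, `N`, `p_raw`, `p_bh`,
#'   `reported`), sorted by `p_raw`
#' @export
enrich <- function(selected, term_map, universe, min_genes = 5L, alpha = 0.05) {
  selected <- unique(selected)
  universe <- unique(universe)
  offenders <- setdiff(selected, universe)
  if (length(offenders)) {
    stop_input("selected genes not in universe: ",
               paste(offenders, collapse = ", "))
  }
  N <- length(universe)
  n <- length(selected)
  terms <- split(term_map$gene_id, term_map$term_id)
  rows <- lapply(names(terms), function(t) {
    genes_t <- intersect(unique(terms[[t]]), universe)
    K <- length(genes_t)
    if (!K) return(NULL)
    k <- length(intersect(genes_t, selected))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = t, k = k, K = K, n = n, N = N, p_raw = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop_input("no non-empty terms to test")
  out$p_bh <- stats::p.adjust(out$p_raw, method = "BH")
  out$reported <- out$k >= min_genes & out$p_bh <= alpha
  out <- out[order(out$p_raw), , drop = FALSE]
  rownames(out) <- NULL
  out
}
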