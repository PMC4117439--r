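#' Three-predictor consensus of external damaging verdicts
#'
#' Selects candidate rows called damaging by all three external effect
#' predictors, matched as the tools' categorical verdict codes:
#' PolyPhen2 `"PROBABLY DAMAGING"`/`"POSSIBLY DAMAGING"`, SIFT
#' `"AFFECT PROTEIN FUNCTION"`, MAPP `"Bad Amino Acids"`.
#'
#' @param candidates data.frame with columns `polyphen2`, `sift`, `mapp`
#' @return list: `consensus` (subset data.frame), `counts` (per-tool damaging
#'   counts and the intersection size)
#' @export
consensus_predictors <- function(candidates) {
  need <- c("polyphen2", "sift", "mapp")
  missing_cols <- setdiff(need, names(candidates))
  if (length(missing_cols)) {
    stop_input("missing predictor column(s): ", paste(missing_cols, collapse = ", "))
  }
  dam <- list(
    polyphen2 = candidates$polyphen2 %in% c("PROBABLY DAMAGING",
                                            "POSSIBLY DAMAGING"),
    sift = candidates$sift %in% "AFFECT PROTEIN FUNCTION",
    mapp = candidates$mapp %in% "Bad Amino Acids"
  )
  all3 <- dam$polyphen2 & dam$sift & dam$mapp
  list(
    consensus = candidates[all3, , drop = FALSE],
    counts = c(polyphen2 = sum(dam$polyphen2), sift = sum(dam$sift),
               mapp = sum(dam$mapp), consensus = sum(all3))
  )
}

#' Final candidate-SNP report
#'
#' One row per pattern-filter hit with the three selection criteria as flags:
#' (1) the SNP lies in an outlier region and its gene is in the a-priori gene
#' set, (2) it passes the genotype-pattern filter in the requested mode,
#' (3) association statistics; complete-LD group membership is annotated.
#'
#' @param gm a [geno_matrix]
#' @param scan a `sweep_scan` object
#' @param gene_set character vector of a-priori candidate gene IDs (`NULL`
#'   disables the gene-set criterion)
#' @param effects output of [classify_effects] (`NULL` skips gene/effect
#'   columns)
#' @param pattern_mode passed to [pattern_filter]
#' @return data.frame, one row per pattern hit, with criterion flags,
#'   association columns and `ld_group`
#' @export
candidate_report <- function(gm, scan, gene_set = NULL, effects = NULL,
                             pattern_mode = "scan") {
  hits <- pattern_filter(gm, mode = pattern_mode)
  if (!length(hits)) {
    return(data.frame(contig = character(), pos = integer(), site = integer(),
                      in_outlier_region = logical(), in_gene_set = logical(),
                      pattern_pass = logical(), chi2 = numeric(), p = numeric(),
                      freq_diff = numeric(), ld_group = integer(),
                      stringsAsFactors = FALSE))
  }
  assoc <- association_table(gm, hits)
  reg <- scan$regions
  in_region <- vapply(hits, function(s) {
    any(reg$contig == gm$sites$contig[s] & gm$sites$pos[s] >= reg$start &
          gm$sites$pos[s] < reg$end)
  }, logical(1))

  out <- data.frame(
    contig = gm$sites$contig[hits], pos = gm$sites$pos[hits], site = hits,
    in_outlier_region = in_region, pattern_pass = TRUE,
    chi2 = assoc$chi2, p = assoc$p, freq_diff = assoc$freq_diff,
    stringsAsFactors = FALSE)

  if (!is.null(effects)) {
    key <- paste(effects$contig, effects$pos)
    m <- match(paste(out$contig, out$pos), key)
    out$gene_id <- effects$gene_id[m]
    out$category <- effects$category[m]
    out$aa_change <- effects$aa_change[m]
  }
  out$in_gene_set <- if (!is.null(gene_set) && !is.null(out$gene_id)) {
    !is.na(out$gene_id) & out$gene_id %in% gene_set
  } else NA

  out$ld_group <- NA_integer_
  if (length(hits) >= 2) {
    groups <- complete_ld_groups(pairwise_r2(gm, hits, method = "em"))
    for (gi in seq_along(groups)) {
      out$ld_group[match(groups[[gi]], out$site)] <- gi
    }
  }
  out
}

#' Run the full pipeline on a simulated cohort
#'
#' simulate -> QC -> scan -> effect classification -> candidate filter ->
#' association/LD -> report, writing every stage table plus a JSON manifest
#' into `out_dir`. Re-running with the same configuration and seed reproduces
#' byte-identical tables.
#'
#' @param sim a [sim_config]
#' @param scan_cfg a [scan_config]
#' @param filter_cfg a [filter_config]
#' @param out_dir output directory
#' @param gene_set optional a-priori gene-ID vector; defaults to the genes
#'   overlapping the configured sweep intervals
#' @param n_genes genes to simulate for the annotation stage
#' @param pattern_mode candidate-filter mode
#' @return (invisibly) list with all stage objects and the manifest
#' @export
run_pipeline <- function(sim = sim_config(), scan_cfg = scan_config(),
                         filter_cfg = filter_config(),
                         out_dir, gene_set = NULL, n_genes = 20L,
                         pattern_mode = "scan") {
  if (missing(out_dir)) stop_input("out_dir is required")
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)) {
    stop_input("cannot create output directory ", out_dir)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(errorCondition(paste0("stage '", name, "' failed: ",
                                 conditionMessage(e)),
                          class = c("altisweep_stage_error", "error")))
    })
  }
  manifest <- list(tool = "altisweep",
                   version = as.character(utils::packageVersion("altisweep")),
                   seed = sim$seed, stages = list())

  ref <- stage("reference", generate_reference(sim$genome_length,
                                               sim$gc_fraction, seed = sim$seed,
                                               n_contigs = sim$n_contigs))
  gen <- stage("genes", generate_gene_models(ref, n_genes, seed = sim$seed + 1L))
  ref <- gen$reference
  cohort <- stage("simulate", simulate_cohort(sim, reference = ref))
  gm <- cohort$matrix
  truth <- cohort$truth
  manifest$stages$simulate <- list(n_sites = nrow(gm$sites),
                                   n_samples = ncol(gm$geno))

  qc <- stage("qc", apply_filters(gm, filter_cfg, ref))
  gm <- qc$matrix
  manifest$stages$qc <- list(report = qc$report,
                             n_sites_pass = sum(gm$site_pass))

  scan <- stage("scan", sweep_scan(gm, genes = gen$genes, config = scan_cfg))
  manifest$stages$scan <- list(n_windows = scan$n_windows,
                               n_eligible = scan$n_eligible,
                               n_outlier = scan$n_outlier,
                               n_regions = nrow(scan$regions))

  effects <- stage("annotate", classify_effects(gm, gen$genes, ref))
  manifest$stages$annotate <- as.list(table(effects$category))

  if (is.null(gene_set)) {
    sw <- truth$sweep_intervals
    g <- gen$genes$genes
    in_sweep <- vapply(seq_len(nrow(g)), function(i) {
      any(sw$contig == g$contig[i] & g$start[i] < sw$end & g$end[i] > sw$start)
    }, logical(1))
    gene_set <- g$gene_id[in_sweep]
  }

  report <- stage("report", candidate_report(gm, scan, gene_set = gene_set,
                                             effects = effects,
                                             pattern_mode = pattern_mode))
  manifest$stages$report <- list(n_candidates = nrow(report))

  paths <- c(
    windows = file.path(out_dir, "windows.tsv"),
    regions = file.path(out_dir, "regions.bed"),
    qc = file.path(out_dir, "sample_qc.tsv"),
    filter_report = file.path(out_dir, "filter_report.tsv"),
    effects = file.path(out_dir, "effects.tsv"),
    candidates = file.path(out_dir, "candidates.tsv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_window_tsv(scan, paths[["windows"]])
  write_region_bed(scan, paths[["regions"]])
  write_tsv(sample_qc_stats(gm), paths[["qc"]])
  write_tsv(qc$report, paths[["filter_report"]])
  write_tsv(effects, paths[["effects"]])
  write_tsv(report, paths[["candidates"]])
  manifest$outputs <- lapply(paths[names(paths) != "manifest"], function(p) {
    unname(tools::md5sum(p))
  })
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, force = TRUE)

  invisible(list(matrix = gm, truth = truth, reference = ref,
                 genes = gen$genes, scan = scan, effects = effects,
                 report = report, manifest = manifest, paths = paths))
}
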