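# End-to-end orchestration: completeness -> solitary calls -> truncation
# exclusion -> orthology -> partner-MTase transfer -> classification ->
# methyl-directed screen -> mobile-element neighborhood scan -> reports.

#' Run the full solitary-RE / separated-system pipeline
#'
#' Stage order follows the published procedure: incomplete systems with
#' intact RE genes are scanned for vicinity MTases, probable gene fragments
#' are excluded, BBH orthology is computed for REs and MTases, partner
#' MTases are transferred through orthologous complete systems, and every
#' solitary RE receives exactly one class. The methyl-directed screen and
#' the 20 kb mobile-element scan run on the results. Deterministic given
#' the inputs and `seed` (which drives only the bootstrap).
#'
#' @param cohort an `rm_cohort` (from [generate_cohort()] or
#'   [read_cohort()]), or a list with `genes`, `replicons` and optionally
#'   `sequences`, `mtase_ref`.
#' @param thresholds an [rm_thresholds()] list.
#' @param outdir optional directory: writes TSV/JSON artifacts.
#' @param seed RNG seed for the bootstrap stage.
#' @param screen run the Type IV methyl-directed screen (needs Type IIM/IV
#'   sequences in the cohort to do anything).
#' @return list of class `rm_result`: `systems`, `scans`, `solitary`,
#'   `classifications`, `putative_systems`, `re_pairs`, `mtase_pairs`,
#'   `re_groups`, `table1`, `table2`, `screen`, `mge`.
#' @export
run_pipeline <- function(cohort, thresholds = rm_thresholds(),
                         outdir = NULL, seed = 1L, screen = TRUE) {
  genes <- cohort$genes
  replicons <- cohort$replicons
  validate_cohort(genes, replicons)
  sequences <- cohort$sequences
  mtase_ref <- cohort$mtase_ref
  if (is.null(mtase_ref)) mtase_ref <- character()

  systems <- build_systems(genes)
  sysmap <- stats::setNames(systems$completeness,
                            paste(systems$genome_id, systems$system_id,
                                  sep = "\r"))
  syskey <- function(g) paste(g$genome_id, ifelse(is.na(g$system_id),
    paste0("solo:", g$gene_id), g$system_id), sep = "\r")

  # candidates: intact REs of Types I-III in incomplete systems
  re_rows <- genes[genes$role == "RE" & !genes$corrupted &
                     genes$rm_type %in% c("I", "II", "III"), , drop = FALSE]
  re_rows <- re_rows[!duplicated(re_rows$gene_id), , drop = FALSE]
  cand <- re_rows[sysmap[syskey(re_rows)] == "incomplete", , drop = FALSE]

  scans <- list()
  sol_flag <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    g <- cand[i, , drop = FALSE]
    seq_i <- if (!is.null(sequences)) sequences[[g$replicon_id]] else NULL
    sc <- scan_vicinity_for_mtases(g, genes, replicons, seq_i, mtase_ref,
                                   thresholds)
    scans[[g$gene_id]] <- sc
    sol_flag[i] <- call_solitary(g, sc)
  }
  solitary <- cand[sol_flag, , drop = FALSE]

  # truncation filter against REs of complete systems
  comp_res <- re_rows[sysmap[syskey(re_rows)] == "complete", , drop = FALSE]
  trunc <- stats::setNames(logical(nrow(solitary)), solitary$gene_id)
  trunc_evidence <- list()
  for (i in seq_len(nrow(solitary))) {
    tr <- is_probably_truncated(solitary[i, , drop = FALSE], comp_res,
                                thresholds)
    trunc[i] <- tr$truncated
    trunc_evidence[[solitary$gene_id[i]]] <- tr$evidence
  }

  re_pairs <- bbh_all(genes, "RE", thresholds)
  mtase_pairs <- bbh_all(genes, "MTase", thresholds)
  re_groups <- build_groups(re_pairs)
  in_pairs <- unique(c(re_pairs$gene_a, re_pairs$gene_b))

  cls_rows <- list(); put_rows <- list()
  for (i in seq_len(nrow(solitary))) {
    g <- solitary[i, , drop = FALSE]
    partners <- if (!trunc[i] && g$gene_id %in% in_pairs)
      find_partner_mtase(g, genes, replicons, systems, re_pairs,
                         mtase_pairs, thresholds)
    else find_partner_mtase(g, genes[0L, ], replicons, systems,
                            re_pairs[0L, ], mtase_pairs[0L, ], thresholds)
    if (nrow(partners)) put_rows[[g$gene_id]] <- partners
    cls_rows[[g$gene_id]] <- classify_solitary(
      g, trunc[i], g$gene_id %in% in_pairs, partners, scans[[g$gene_id]])
  }
  classifications <- if (length(cls_rows)) do.call(rbind, cls_rows) else
    data.frame(gene_id = character(), genome_id = character(),
               rm_type = character(), class = character(),
               evidence = character(), stringsAsFactors = FALSE)
  rownames(classifications) <- NULL
  putative <- if (length(put_rows)) do.call(rbind, put_rows) else
    find_partner_mtase(re_rows[0L, ], genes[0L, ], replicons, systems,
                       re_pairs[0L, ], mtase_pairs[0L, ], thresholds)
  rownames(putative) <- NULL

  table1 <- write_report(classifications)
  table2 <- summarize_groups(putative, re_groups, genes, systems)

  # methyl-directed screen: solitary REs vs Type IIM/IV REs
  screen_res <- NULL
  if (isTRUE(screen)) {
    mdir <- genes[genes$role == "RE" & !genes$corrupted &
                    genes$rm_type %in% c("IIM", "IV") &
                    nzchar(genes$protein_seq), , drop = FALSE]
    solp <- solitary[nzchar(solitary$protein_seq), , drop = FALSE]
    universe <- c(stats::setNames(solp$protein_seq, solp$gene_id),
                  stats::setNames(mdir$protein_seq, mdir$gene_id))
    categories <- c(stats::setNames(rep("solitary", nrow(solp)),
                                    solp$gene_id),
                    stats::setNames(rep("methyl_directed", nrow(mdir)),
                                    mdir$gene_id))
    if (length(universe) >= 2L) {
      hits <- search_hits(universe, universe, thresholds$typeiv_evalue,
                          thresholds)
      clusters <- cluster_by_identity(hits, names(universe), categories,
                                      thresholds)
      trees <- list()
      for (cid in unique(clusters$cluster_id[clusters$mixed %in% TRUE])) {
        mem <- clusters$gene_id[clusters$cluster_id == cid]
        if (length(mem) < 3L) next
        msa <- progressive_msa(universe[mem])
        bs <- bootstrap_support(msa, thresholds$bootstrap_reps, seed)
        trees[[cid]] <- list(msa = msa$aligned, tree = bs$tree,
                             support = bs$support)
      }
      screen_res <- list(hits = hits, clusters = clusters, trees = trees)
    } else {
      screen_res <- list(hits = NULL,
                         clusters = cluster_by_identity(
                           search_hits(character(), character(), 1,
                                       thresholds),
                           names(universe), categories, thresholds),
                         trees = list())
    }
  }

  # mobile-element neighborhood of separated systems
  sep <- putative[putative$status == "separated", , drop = FALSE]
  mge_scans <- list()
  for (id in unique(c(sep$re_gene, sep$mtase_gene))) {
    row <- genes[genes$gene_id == id, , drop = FALSE][1L, ]
    mge_scans[[id]] <- scan_mge(row, genes, replicons,
                                thresholds$neighborhood_bp)
  }
  mge <- list(scans = mge_scans,
              enrichment = mge_enrichment_summary(sep, mge_scans))

  res <- structure(list(
    systems = systems, scans = scans, solitary = solitary,
    truncation = trunc_evidence, classifications = classifications,
    putative_systems = putative, re_pairs = re_pairs,
    mtase_pairs = mtase_pairs, re_groups = re_groups,
    table1 = table1, table2 = table2, screen = screen_res, mge = mge),
    class = "rm_result")
  if (!is.null(outdir)) write_result_bundle(res, outdir)
  res
}

#' Serialize a pipeline result to a directory
#'
#' Writes the classification, putative-system, ortholog-pair/group and
#' summary tables as TSV plus a JSON manifest. Output is byte-identical
#' across runs with identical inputs and seed (no timestamps).
#'
#' @param res an `rm_result`.
#' @param outdir output directory.
#' @return invisibly `outdir`.
#' @export
write_result_bundle <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    df2 <- df
    lc <- vapply(df2, is.list, TRUE)
    df2[lc] <- lapply(df2[lc], vapply, paste, "", collapse = ",")
    write.table(df2, file.path(outdir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wt(res$classifications, "classifications.tsv")
  wt(res$putative_systems, "putative_systems.tsv")
  wt(res$re_pairs, "re_pairs.tsv")
  wt(res$mtase_pairs, "mtase_pairs.tsv")
  wt(res$re_groups, "re_groups.tsv")
  wt(res$table1, "table1.tsv")
  wt(res$table2, "table2.tsv")
  if (!is.null(res$screen)) wt(res$screen$clusters, "screen_clusters.tsv")
  newicks <- vapply(res$screen$trees, function(t)
    ape::write.tree(t$tree), "")
  manifest <- list(
    schema_version = "1.0",
    n_solitary = nrow(res$solitary),
    class_counts = as.list(table(res$classifications$class)),
    n_separated = sum(res$putative_systems$status == "separated"),
    mge_enrichment = res$mge$enrichment,
    screen_trees = as.list(newicks))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(outdir)
}

#' Compare pipeline classifications to a cohort's truth labels
#'
#' Computes per-class precision and recall of the classification against
#' the generator's planted labels. REs the truth marks `not_solitary`
#' count as negatives; a class absent from both truth and prediction has
#' precision = recall = 1 (vacuously perfect).
#'
#' @param classifications `classifications` from [run_pipeline()].
#' @param truth the `truth` element of an `rm_cohort`.
#' @return data.frame: `class`, `n_truth`, `n_pred`, `tp`, `precision`,
#'   `recall`.
#' @export
evaluate_against_truth <- function(classifications, truth) {
  tcl <- truth$classes
  rows <- lapply(SOLITARY_CLASSES, function(cl) {
    t_ids <- tcl$gene_id[tcl$class == cl]
    p_ids <- classifications$gene_id[classifications$class == cl]
    tp <- length(intersect(t_ids, p_ids))
    data.frame(class = cl, n_truth = length(t_ids), n_pred = length(p_ids),
               tp = tp,
               precision = if (length(p_ids)) tp / length(p_ids) else 1,
               recall = if (length(t_ids)) tp / length(t_ids) else 1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
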