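# Partner-MTase transfer through orthologous complete R-M systems, the
# >4 kb separated-system rule, and the final classification of solitary REs.

#' Predict partner MTases for a solitary RE via orthologous systems
#'
#' For each ortholog RE' of the solitary RE that belongs to a complete R-M
#' system with non-corrupted MTase M', the BBH ortholog M of M' in the
#' solitary RE's genome is looked up. Every non-corrupted M of the same R-M
#' type yields a putative R-M system (solitary RE, M); duplicates by M are
#' merged with pooled provenance. The system is `separated` when the
#' edge-to-edge RE-M distance exceeds `separated_bp` (4 kb) or the genes lie
#' on different replicons; co-located S-subunit genes (within the vicinity
#' window of M) are reported as cassette members for Type I partners.
#'
#' @param re one-row gene-record of the solitary RE.
#' @param genes,replicons cohort annotation.
#' @param systems output of [build_systems()].
#' @param re_pairs,mtase_pairs BBH pair tables from [bbh_all()] for roles
#'   RE and MTase.
#' @param thresholds an [rm_thresholds()] list.
#' @return data.frame of putative systems: `re_gene`, `mtase_gene`,
#'   `genome_id`, `rm_type`, `separation_bp` (may be `Inf`), `status`,
#'   `n_support`, `provenance` (semicolon-joined `genome:RE'+M'` records),
#'   `cassette_s_genes`.
#' @export
find_partner_mtase <- function(re, genes, replicons, systems,
                               re_pairs, mtase_pairs,
                               thresholds = rm_thresholds()) {
  empty <- data.frame(re_gene = character(), mtase_gene = character(),
                      genome_id = character(), rm_type = character(),
                      separation_bp = numeric(), status = character(),
                      n_support = integer(), provenance = character(),
                      cassette_s_genes = character(),
                      stringsAsFactors = FALSE)
  rid <- re$gene_id[1L]
  orth <- unique(c(re_pairs$gene_b[re_pairs$gene_a == rid],
                   re_pairs$gene_a[re_pairs$gene_b == rid]))
  if (!length(orth)) return(empty)
  gidx <- match(genes$gene_id, genes$gene_id)  # first-row lookup per gene id
  gene_row <- function(id) genes[genes$gene_id == id, , drop = FALSE][1L, ]
  support <- list()   # mtase gene id -> character vector of provenance
  for (rp in orth) {
    rp_row <- gene_row(rp)
    sysid <- rp_row$system_id
    if (is.na(sysid)) next
    sys <- systems[systems$system_id == sysid &
                     systems$genome_id == rp_row$genome_id, , drop = FALSE]
    if (!nrow(sys) || sys$completeness[1L] != "complete") next
    mem <- genes[genes$gene_id %in% sys$gene_ids[[1L]], , drop = FALSE]
    mprime <- mem[mem$role == "MTase" & !mem$corrupted, , drop = FALSE]
    for (mp in mprime$gene_id) {
      # BBH ortholog of M' in the solitary RE's genome
      cand <- c(mtase_pairs$gene_b[mtase_pairs$gene_a == mp],
                mtase_pairs$gene_a[mtase_pairs$gene_b == mp])
      for (m in cand) {
        m_row <- gene_row(m)
        if (m_row$genome_id != re$genome_id[1L]) next
        if (m_row$corrupted) next
        if (m_row$rm_type != re$rm_type[1L]) next
        tag <- sprintf("%s:%s+%s", rp_row$genome_id, rp, mp)
        support[[m]] <- c(support[[m]], tag)
      }
    }
  }
  if (!length(support)) return(empty)
  rows <- lapply(names(support), function(m) {
    m_row <- gene_row(m)
    d <- gene_distance(re, m_row, replicons)
    s_cass <- ""
    if (re$rm_type[1L] == "I") {
      rep_m <- replicons[replicons$replicon_id == m_row$replicon_id, ,
                         drop = FALSE]
      arcs <- vicinity_interval(m_row, thresholds$vicinity_bp, rep_m)
      sg <- genes[genes$genome_id == m_row$genome_id &
                    genes$replicon_id == m_row$replicon_id &
                    genes$role == "S_subunit" & !genes$corrupted, ,
                  drop = FALSE]
      if (nrow(sg)) {
        keep <- vapply(seq_len(nrow(sg)), function(i)
          overlaps_intervals(sg$start[i], sg$end[i], arcs), TRUE)
        s_cass <- paste(sort(unique(sg$gene_id[keep])), collapse = ",")
      }
    }
    data.frame(re_gene = rid, mtase_gene = m,
               genome_id = re$genome_id[1L], rm_type = re$rm_type[1L],
               separation_bp = d,
               status = if (d > thresholds$separated_bp) "separated"
                        else "ordinary",
               n_support = length(unique(support[[m]])),
               provenance = paste(sort(unique(support[[m]])),
                                  collapse = ";"),
               cassette_s_genes = s_cass, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res[order(res$mtase_gene), , drop = FALSE]
}

#' Classify one solitary RE
#'
#' Applies the fixed precedence: `probably_truncated` (fragments are
#' excluded before the MTase search), then `no_orthologs` (no BBH ortholog
#' anywhere, so the partner search cannot run), then
#' `separated_system_member` (at least one separated putative system), then
#' `corrupted_mtase_nearby` (a pseudo MTase within the 4 kb vicinity), and
#' finally `no_paired_mtase`. Classes are mutually exclusive, so per-class
#' counts always sum to the solitary total.
#'
#' @param re one-row gene-record.
#' @param truncated logical from [is_probably_truncated()].
#' @param has_orthologs logical: the RE occurs in at least one BBH pair.
#' @param partners data.frame from [find_partner_mtase()].
#' @param scan `rm_vicinity_scan` for the RE.
#' @return data.frame row: `gene_id`, `genome_id`, `rm_type`, `class`,
#'   `evidence`.
#' @export
classify_solitary <- function(re, truncated, has_orthologs, partners, scan) {
  cls <- if (isTRUE(truncated)) "probably_truncated"
    else if (!isTRUE(has_orthologs)) "no_orthologs"
    else if (nrow(partners) && any(partners$status == "separated"))
      "separated_system_member"
    else if (isTRUE(scan$has_corrupted_mtase)) "corrupted_mtase_nearby"
    else "no_paired_mtase"
  ev <- switch(cls,
    probably_truncated = "shorter by >=20% than a >20%-identity homolog",
    no_orthologs = "no BBH ortholog in any other genome",
    separated_system_member = paste("partner MTase(s):",
      paste(partners$mtase_gene[partners$status == "separated"],
            collapse = ",")),
    corrupted_mtase_nearby = "corrupted MTase within 4 kb vicinity",
    no_paired_mtase = "no partner MTase recovered")
  data.frame(gene_id = re$gene_id[1L], genome_id = re$genome_id[1L],
             rm_type = re$rm_type[1L], class = cls, evidence = ev,
             stringsAsFactors = FALSE)
}

#' Per-ortholog-group summary of putative separated R-M systems
#'
#' For each RE ortholog group containing at least one separated putative
#' system: the R-M type, the number of member systems (complete annotated
#' systems whose RE is in the group, plus the putative ones), how many were
#' annotated in the input, how many are separated, and how many distinct
#' solitary REs are involved. A group may list more separated systems than
#' solitary REs when one RE pairs with several MTase cassettes. Groups
#' without separated members are omitted.
#'
#' @param putative_systems row-bound [find_partner_mtase()] output.
#' @param groups RE ortholog groups from [build_groups()].
#' @param genes,systems cohort annotation and [build_systems()] output.
#' @return data.frame, one row per qualifying group.
#' @export
summarize_groups <- function(putative_systems, groups, genes, systems) {
  empty <- data.frame(group_id = character(), rm_type = character(),
                      n_systems = integer(), n_annotated = integer(),
                      n_separated = integer(), n_solitary_re = integer(),
                      stringsAsFactors = FALSE)
  sep <- putative_systems[putative_systems$status == "separated", ,
                          drop = FALSE]
  if (!nrow(sep)) return(empty)
  re_group <- stats::setNames(groups$group_id, groups$gene_id)
  sep$group_id <- re_group[sep$re_gene]
  sep <- sep[!is.na(sep$group_id), , drop = FALSE]
  if (!nrow(sep)) return(empty)
  # complete annotated systems whose RE falls in each group
  sys_complete <- systems[systems$completeness == "complete", , drop = FALSE]
  rows <- lapply(split(sep, sep$group_id), function(p) {
    gid <- p$group_id[1L]
    members <- groups$gene_id[groups$group_id == gid]
    ann <- sum(vapply(seq_len(nrow(sys_complete)), function(i)
      any(genes$gene_id[genes$gene_id %in% sys_complete$gene_ids[[i]] &
                          genes$role == "RE"] %in% members), TRUE))
    data.frame(group_id = gid, rm_type = p$rm_type[1L],
               n_systems = ann + nrow(p), n_annotated = ann,
               n_separated = nrow(p),
               n_solitary_re = length(unique(p$re_gene)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[order(res$group_id), , drop = FALSE]
}
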