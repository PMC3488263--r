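# Best-bidirectional-hit orthology with role-specific thresholds and
# single-linkage ortholog groups. Comparisons never cross R-M types: the
# published groups are type-homogeneous.

role_thresholds <- function(role, th) {
  switch(role,
    RE = list(identity = th$re_ortho_identity,
              coverage = th$re_ortho_coverage),
    MTase = list(identity = th$mtase_ortho_identity,
                 coverage = th$mtase_ortho_coverage),
    stop("orthology is defined for roles 'RE' and 'MTase'"))
}

#' Best hit of a query protein in a target genome
#'
#' Aligns the query against every target, keeps hits passing the role's
#' identity/coverage thresholds (coverage of the longer sequence), and
#' returns the top target by score, with ties broken by higher identity and
#' then lexicographically smallest subject id.
#'
#' @param query_seq amino-acid string.
#' @param targets named character vector of candidate proteins (same role
#'   and R-M type as the query).
#' @param role `"RE"` or `"MTase"`.
#' @param thresholds an [rm_thresholds()] list.
#' @return the winning target's name, or `NA_character_`.
#' @export
best_hit <- function(query_seq, targets, role,
                     thresholds = rm_thresholds()) {
  if (!length(targets)) return(NA_character_)
  rth <- role_thresholds(role, thresholds)
  hits <- search_hits(stats::setNames(query_seq, "!query"), targets,
                      evalue_max = Inf, thresholds = thresholds)
  hits <- hits[hit_meets(hits, rth$identity, rth$coverage, "longer"), ,
               drop = FALSE]
  if (!nrow(hits)) return(NA_character_)
  order_hits(hits)$subject_id[1L]
}

# internal: all-pairs hit table between two protein sets (named vectors)
cross_hits <- function(a, b, th) {
  out <- vector("list", length(b))
  for (j in seq_along(b))
    out[[j]] <- align_block(a, b[[j]], names(b)[j], th)
  do.call(rbind, out)
}

#' Best-bidirectional-hit ortholog pairs between two genomes
#'
#' For each R-M type present in both genomes, pairs (x in A, y in B) are
#' emitted iff y is x's best hit in B and x is y's best hit in A, both hits
#' passing the role's thresholds. Each gene appears in at most one pair per
#' partner genome by construction.
#'
#' @param genes full gene table (non-corrupted genes with proteins are used).
#' @param genome_a,genome_b genome ids (distinct).
#' @param role `"RE"` or `"MTase"`.
#' @param thresholds an [rm_thresholds()] list.
#' @return data.frame: `gene_a`, `gene_b`, `role`, `rm_type`, `identity_ab`,
#'   `identity_ba`, `score`.
#' @export
bbh_orthologs <- function(genes, genome_a, genome_b, role,
                          thresholds = rm_thresholds()) {
  stopifnot(genome_a != genome_b)
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      role = character(), rm_type = character(),
                      identity_ab = numeric(), identity_ba = numeric(),
                      score = numeric(), stringsAsFactors = FALSE)
  rth <- role_thresholds(role, thresholds)
  sel <- genes$role == role & !genes$corrupted & nzchar(genes$protein_seq)
  ga <- genes[sel & genes$genome_id == genome_a, , drop = FALSE]
  gb <- genes[sel & genes$genome_id == genome_b, , drop = FALSE]
  out <- list()
  for (ty in intersect(unique(ga$rm_type), unique(gb$rm_type))) {
    a <- stats::setNames(ga$protein_seq[ga$rm_type == ty],
                         ga$gene_id[ga$rm_type == ty])
    b <- stats::setNames(gb$protein_seq[gb$rm_type == ty],
                         gb$gene_id[gb$rm_type == ty])
    hits <- cross_hits(a, b, thresholds)
    hits <- hits[hit_meets(hits, rth$identity, rth$coverage, "longer"), ,
                 drop = FALSE]
    if (!nrow(hits)) next
    best_ab <- vapply(split(hits, hits$query_id),
                      function(h) order_hits(h)$subject_id[1L], "")
    # reverse direction: same alignments, roles of query/subject swapped
    rev <- hits
    rev$query_id <- hits$subject_id; rev$subject_id <- hits$query_id
    rev$coverage_query <- hits$coverage_subject
    rev$coverage_subject <- hits$coverage_query
    best_ba <- vapply(split(rev, rev$query_id),
                      function(h) order_hits(h)$subject_id[1L], "")
    for (x in names(best_ab)) {
      y <- best_ab[[x]]
      if (identical(best_ba[[y]], x)) {
        hab <- hits[hits$query_id == x & hits$subject_id == y, ]
        out[[length(out) + 1L]] <- data.frame(
          gene_a = x, gene_b = y, role = role, rm_type = ty,
          identity_ab = hab$identity[1L], identity_ba = hab$identity[1L],
          score = hab$score[1L], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$gene_a, res$gene_b), , drop = FALSE]
}

#' BBH ortholog pairs across all genome pairs of a cohort
#'
#' @inheritParams bbh_orthologs
#' @return row-bound [bbh_orthologs()] output over all unordered genome
#'   pairs (each pair computed once, `gene_a` from the lexicographically
#'   smaller genome).
#' @export
bbh_all <- function(genes, role, thresholds = rm_thresholds()) {
  gms <- sort(unique(genes$genome_id[genes$role == role &
                                       !genes$corrupted]))
  out <- list()
  if (length(gms) >= 2L)
    for (i in seq_len(length(gms) - 1L))
      for (j in seq((i + 1L), length(gms)))
        out[[length(out) + 1L]] <-
          bbh_orthologs(genes, gms[i], gms[j], role, thresholds)
  res <- do.call(rbind, out)
  if (is.null(res))
    bbh_orthologs(genes[0L, ], "a", "b", role, thresholds) else res
}

#' Ortholog groups from BBH pairs
#'
#' Single-linkage connected components of the pair graph. Proteins without
#' any pair are excluded (groups have two or more members by construction).
#'
#' @param pairs output of [bbh_all()] / [bbh_orthologs()].
#' @return data.frame: `group_id`, `role`, `rm_type`, `gene_id`.
#' @export
build_groups <- function(pairs) {
  empty <- data.frame(group_id = character(), role = character(),
                      rm_type = character(), gene_id = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(pairs)) return(empty)
  out <- list()
  for (key in unique(paste(pairs$role, pairs$rm_type, sep = "\r"))) {
    p <- pairs[paste(pairs$role, pairs$rm_type, sep = "\r") == key, ]
    g <- igraph::graph_from_data_frame(p[, c("gene_a", "gene_b")],
                                       directed = FALSE)
    comp <- igraph::components(g)
    memb <- igraph::membership(comp)
    out[[key]] <- data.frame(
      group_id = sprintf("%s_%s_g%03d", p$role[1L], p$rm_type[1L],
                         as.integer(memb)),
      role = p$role[1L], rm_type = p$rm_type[1L],
      gene_id = names(memb), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$group_id, res$gene_id), , drop = FALSE]
}
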