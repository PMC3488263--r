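# 20 kb mobile-genetic-element scan around the genes of separated systems.

#' Default MGE keyword classes
#'
#' Case-insensitive regexes applied to annotation product descriptions,
#' editable by the caller. Order matters: the first matching class wins.
#'
#' @return named character vector of regexes.
#' @export
default_mge_keywords <- function() {
  c(insertion_sequence = "insertion sequence|\\bIS[0-9]+",
    transposase = "transposase|transposon",
    integrase = "integrase|recombinase",
    phage_related = "phage|prophage")
}

#' Scan the neighborhood of a gene for mobile-genetic-element annotations
#'
#' Returns every annotated gene overlapping the `window_bp` (default 20 kb)
#' vicinity of the anchor whose product description matches one of the
#' keyword classes, sorted by edge-to-edge distance. Window boundaries are
#' handled like the vicinity rule: overlap by at least 1 bp counts.
#'
#' @param anchor_gene one-row gene-record.
#' @param genes annotation table (product descriptions consulted).
#' @param replicons replicon table.
#' @param window_bp window size in bp.
#' @param keyword_map named regex vector, see [default_mge_keywords()].
#' @return data.frame: `anchor_gene_id`, `mge_gene_id`, `category`,
#'   `distance_bp`, `product`.
#' @export
scan_mge <- function(anchor_gene, genes, replicons,
                     window_bp = rm_thresholds()$neighborhood_bp,
                     keyword_map = default_mge_keywords()) {
  empty <- data.frame(anchor_gene_id = character(), mge_gene_id = character(),
                      category = character(), distance_bp = numeric(),
                      product = character(), stringsAsFactors = FALSE)
  rep <- replicons[replicons$replicon_id == anchor_gene$replicon_id[1L], ,
                   drop = FALSE]
  arcs <- vicinity_interval(anchor_gene, window_bp, rep)
  nb <- genes[genes$replicon_id == anchor_gene$replicon_id[1L] &
                genes$gene_id != anchor_gene$gene_id[1L] &
                nzchar(genes$product), , drop = FALSE]
  if (!nrow(nb)) return(empty)
  inwin <- vapply(seq_len(nrow(nb)), function(i)
    overlaps_intervals(nb$start[i], nb$end[i], arcs), TRUE)
  nb <- nb[inwin, , drop = FALSE]
  if (!nrow(nb)) return(empty)
  cat <- rep(NA_character_, nrow(nb))
  for (k in names(keyword_map)) {
    hit <- is.na(cat) & grepl(keyword_map[[k]], nb$product,
                              ignore.case = TRUE)
    cat[hit] <- k
  }
  nb <- nb[!is.na(cat), , drop = FALSE]
  cat <- cat[!is.na(cat)]
  if (!nrow(nb)) return(empty)
  d <- vapply(seq_len(nrow(nb)), function(i)
    gene_distance(anchor_gene, nb[i, , drop = FALSE], replicons), 0)
  out <- data.frame(anchor_gene_id = anchor_gene$gene_id[1L],
                    mge_gene_id = nb$gene_id, category = cat,
                    distance_bp = d, product = nb$product,
                    stringsAsFactors = FALSE)
  out <- out[order(out$distance_bp, out$mge_gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of separated systems with a mobile element nearby
#'
#' A system counts when at least one MGE hit lies within the window of
#' either its RE or its MTase gene.
#'
#' @param separated_systems data.frame with columns `re_gene`, `mtase_gene`
#'   (one row per separated system).
#' @param scans named list mapping gene ids to [scan_mge()] results.
#' @return list: `n_systems`, `n_with_mge`, `fraction` (`NA` when there are
#'   no systems).
#' @export
mge_enrichment_summary <- function(separated_systems, scans) {
  n <- nrow(separated_systems)
  if (!n) return(list(n_systems = 0L, n_with_mge = 0L, fraction = NA_real_))
  has <- vapply(seq_len(n), function(i) {
    ids <- c(separated_systems$re_gene[i], separated_systems$mtase_gene[i])
    any(vapply(ids, function(id)
      !is.null(scans[[id]]) && nrow(scans[[id]]) > 0L, TRUE))
  }, TRUE)
  list(n_systems = n, n_with_mge = sum(has), fraction = mean(has))
}
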