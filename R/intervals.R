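# Interval arithmetic on linear and circular replicons.
# All intervals are 0-based half-open on the forward coordinate system.

#' Vicinity interval around a gene
#'
#' Expands a gene interval by `window_bp` on both sides. On linear replicons
#' the result is clipped to `[0, L)`; on circular replicons it wraps around
#' the origin and is returned as one or two arcs. The interval(s) always
#' cover the gene itself. Strand is ignored: the vicinity rule is
#' strand-agnostic.
#'
#' @param gene one-row gene-record data.frame.
#' @param window_bp positive window size in bp.
#' @param replicon one-row replicon table entry for the gene's replicon.
#' @return matrix with columns `start`, `end`: one row per arc.
#' @examples
#' rep <- replicon_records("chr", "g", 1e6L)
#' g <- gene_records("g", "chr", "re1", 10000L, 11000L, role = "RE")
#' vicinity_interval(g, 4000L, rep)   # [6000, 15000)
#' @export
vicinity_interval <- function(gene, window_bp, replicon) {
  stopifnot(window_bp > 0, nrow(gene) >= 1L)
  L <- replicon$length
  if (any(gene$start < 0L) || any(gene$end > L))
    stop("gene outside replicon bounds")
  s <- min(gene$start) - window_bp
  e <- max(gene$end) + window_bp
  if (replicon$topology == "linear") {
    m <- cbind(start = max(0L, s), end = min(L, e))
    return(m)
  }
  if (e - s >= L)   # window covers the whole circle
    return(cbind(start = 0L, end = L))
  s <- s %% L
  e <- e %% L
  if (e == 0L) e <- L
  if (s < e) cbind(start = s, end = e)
  else cbind(start = c(s, 0L), end = c(L, e))
}

# does [s,e) overlap any arc by >= 1 bp?
overlaps_intervals <- function(s, e, arcs) {
  any(pmax(s, arcs[, "start"]) < pmin(e, arcs[, "end"]))
}

#' Edge-to-edge distance between two genes of one genome
#'
#' Returns the bp gap between the nearest boundaries of the two genes: 0 if
#' they overlap, the shorter of the two arcs on circular replicons, and
#' `Inf` when the genes sit on different replicons of the genome (treated as
#' maximally separated).
#'
#' @param gene_x,gene_y one-row gene-record data.frames from one genome.
#' @param replicons replicon table.
#' @return numeric distance in bp, possibly `Inf`.
#' @export
gene_distance <- function(gene_x, gene_y, replicons) {
  if (gene_x$genome_id[1L] != gene_y$genome_id[1L])
    stop("gene_distance: genes belong to different genomes")
  if (gene_x$replicon_id[1L] != gene_y$replicon_id[1L]) return(Inf)
  rep <- replicons[replicons$replicon_id == gene_x$replicon_id[1L], ]
  s1 <- gene_x$start[1L]; e1 <- gene_x$end[1L]
  s2 <- gene_y$start[1L]; e2 <- gene_y$end[1L]
  if (max(s1, s2) < min(e1, e2)) return(0)
  if (rep$topology == "linear")
    return(if (s2 >= e1) s2 - e1 else s1 - e2)
  L <- rep$length
  d1 <- (s2 - e1) %% L   # forward gap x -> y
  d2 <- (s1 - e2) %% L   # forward gap y -> x
  min(d1, d2)
}

# extract the (possibly wrapped) vicinity nucleotide sequence; arcs are
# concatenated in circular order so the result is the contiguous region
extract_arcs <- function(seq, arcs) {
  paste0(vapply(seq_len(nrow(arcs)), function(i)
    substr(seq, arcs[i, "start"] + 1L, arcs[i, "end"]), ""), collapse = "")
}
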