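# Length-based filter for solitary REs that are probably gene fragments.

#' Is a solitary RE probably a truncated gene fragment?
#'
#' Homologs are REs from complete R-M systems whose alignment is
#' significant (`evalue < trunc_evalue`, the gate implicit in calling a hit
#' a homolog) with identity strictly above `trunc_homolog_identity` (20\%);
#' no coverage floor is applied. The solitary RE is flagged when it is
#' shorter by 20\% or more
#' than at least one homolog, i.e. `len(solitary) <= 0.8 * len(homolog)`
#' (boundary inclusive, reading "shorter by 20\% or more" literally).
#'
#' @param solitary_re one-row gene-record with a protein sequence.
#' @param complete_res gene-record data.frame of non-corrupted REs from
#'   complete systems (the comparison pool).
#' @param thresholds an [rm_thresholds()] list.
#' @return list: `truncated` (logical) and `evidence` (data.frame of the
#'   homologs considered: id, identity, lengths, length ratio, triggering).
#' @export
is_probably_truncated <- function(solitary_re, complete_res,
                                  thresholds = rm_thresholds()) {
  ev0 <- data.frame(homolog_id = character(), identity = numeric(),
                    len_solitary = integer(), len_homolog = integer(),
                    length_ratio = numeric(), triggers = logical(),
                    stringsAsFactors = FALSE)
  pool <- complete_res[complete_res$gene_id != solitary_re$gene_id[1L] &
                         nchar(complete_res$protein_seq) > 0L, , drop = FALSE]
  if (!nrow(pool))
    return(list(truncated = FALSE, evidence = ev0, note = "no homologs"))
  q <- solitary_re$protein_seq[1L]
  stopifnot(nzchar(q))
  hits <- search_hits(
    stats::setNames(q, solitary_re$gene_id[1L]),
    stats::setNames(pool$protein_seq, pool$gene_id),
    evalue_max = Inf, thresholds = thresholds)
  hits <- hits[hits$evalue < thresholds$trunc_evalue &
                 hits$identity > thresholds$trunc_homolog_identity, ,
               drop = FALSE]
  if (!nrow(hits))
    return(list(truncated = FALSE, evidence = ev0, note = "no homologs"))
  lq <- nchar(q)
  lh <- nchar(pool$protein_seq)[match(hits$subject_id, pool$gene_id)]
  ev <- data.frame(homolog_id = hits$subject_id, identity = hits$identity,
                   len_solitary = lq, len_homolog = lh,
                   length_ratio = lq / lh,
                   triggers = lq <= thresholds$trunc_length_fraction * lh,
                   stringsAsFactors = FALSE)
  list(truncated = any(ev$triggers),
       evidence = ev[order(-ev$triggers, -ev$identity), , drop = FALSE])
}
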