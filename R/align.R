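# Pairwise protein similarity: local alignment with BLOSUM62 and affine
# gaps (open 11, extend 1), approximating the BLASTp defaults the published
# procedure relied on. E-values use the Karlin-Altschul form
# E = K * m * n * exp(-lambda * S) with the standard gapped BLOSUM62 11/1
# parameters; this is an approximation to BLAST, not a bit-exact clone.

aa_check <- function(seqs, what = "sequence") {
  if (any(!nzchar(seqs))) stop(what, " must be a non-empty amino-acid string")
  bad <- grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), seqs)
  if (any(bad))
    stop("non-amino-acid characters in ", what, ": ",
         names(seqs)[bad][1L])
  invisible(TRUE)
}

blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

# align many queries against one subject in a single vectorized call
align_block <- function(queries, subject_seq, subject_id, th,
                        keep_alignment = FALSE) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(queries), Biostrings::AAString(subject_seq),
    type = "local", substitutionMatrix = blosum62(),
    gapOpening = th$gap_opening, gapExtension = th$gap_extension)
  nm <- Biostrings::nmatch(pa)
  nmm <- Biostrings::nmismatch(pa)
  qs <- BiocGenerics::start(Biostrings::pattern(pa))
  qe <- BiocGenerics::end(Biostrings::pattern(pa))
  ss <- BiocGenerics::start(Biostrings::subject(pa))
  se <- BiocGenerics::end(Biostrings::subject(pa))
  alw <- Biostrings::nchar(pa)   # alignment columns incl. gap columns
  qlen <- nchar(queries)
  slen <- nchar(subject_seq)
  sc <- BiocGenerics::score(pa)
  npairs <- nm + nmm
  ident <- ifelse(npairs > 0, nm / npairs, 0)
  cq <- (qe - qs + 1) / qlen
  cs <- (se - ss + 1) / slen
  longer <- pmax(qlen, slen)
  clong <- ifelse(qlen >= slen, cq, cs)
  ev <- th$karlin_k * qlen * slen * exp(-th$karlin_lambda * sc)
  out <- data.frame(
    query_id = if (!is.null(names(queries))) names(queries) else
      as.character(seq_along(queries)),
    subject_id = subject_id,
    identity = ident,
    # alternative convention (identical columns over the longer length),
    # stored so the coverage-convention choice is auditable
    identity_over_longer = nm / longer,
    coverage_query = cq, coverage_subject = cs, coverage_longer = clong,
    aln_length = alw, score = sc, evalue = ev,
    stringsAsFactors = FALSE
  )
  if (keep_alignment) {
    out$aligned_query <- as.character(Biostrings::pattern(pa))
    out$aligned_subject <- as.character(Biostrings::subject(pa))
  }
  out
}

#' Align two protein sequences
#'
#' Local Smith-Waterman-style alignment (BLOSUM62, affine gaps 11/1 by
#' default). Identity is the fraction of identical residue pairs among
#' aligned residue-pair columns (gap columns excluded); coverages are the
#' aligned span on each sequence divided by that sequence's length;
#' `coverage_longer` is the span on the longer sequence over its length.
#' Deterministic for fixed inputs and scoring parameters.
#'
#' @param seq_a,seq_b non-empty amino-acid strings.
#' @param id_a,id_b identifiers carried into the hit.
#' @param thresholds an [rm_thresholds()] list (scoring fields used).
#' @param keep_alignment also return the gapped aligned strings
#'   (`aligned_query`, `aligned_subject`), for auditing.
#' @return one-row data.frame (an AlignmentHit), or a zero-row data.frame if
#'   no positive-scoring local alignment exists.
#' @examples
#' align_pair("ACDEFGHIK", "ACDEFGHIR")$identity  # 8/9
#' @export
align_pair <- function(seq_a, seq_b, id_a = "a", id_b = "b",
                       thresholds = rm_thresholds(),
                       keep_alignment = FALSE) {
  aa_check(c(seq_a, seq_b))
  h <- align_block(stats::setNames(seq_a, id_a), seq_b, id_b, thresholds,
                   keep_alignment = keep_alignment)
  h[h$aln_length >= 1L & h$score > 0, , drop = FALSE]
}

#' All-vs-all similarity search
#'
#' Aligns every query against every subject and keeps the hits with
#' `evalue <= evalue_max` (one best local alignment per ordered pair).
#' Self-comparisons (same name) are skipped.
#'
#' @param queries,subjects named character vectors of protein sequences.
#' @param evalue_max E-value cutoff (> 0).
#' @param thresholds an [rm_thresholds()] list.
#' @return data.frame of AlignmentHits (possibly zero rows).
#' @export
search_hits <- function(queries, subjects, evalue_max,
                        thresholds = rm_thresholds()) {
  stopifnot(evalue_max > 0)
  empty <- align_pair("A", "A")[0L, ]
  if (!length(queries) || !length(subjects)) return(empty)
  aa_check(queries, "query"); aa_check(subjects, "subject")
  out <- vector("list", length(subjects))
  for (j in seq_along(subjects)) {
    qs <- queries[names(queries) != names(subjects)[j]]
    if (!length(qs)) next
    h <- align_block(qs, subjects[[j]], names(subjects)[j], thresholds)
    out[[j]] <- h[h$evalue <= evalue_max & h$score > 0 & h$aln_length >= 1L, ,
                  drop = FALSE]
  }
  res <- do.call(rbind, out)
  if (is.null(res)) empty else res[order(res$query_id, res$subject_id), ,
                                   drop = FALSE]
}

#' Identity/coverage threshold predicate
#'
#' `TRUE` iff `identity > identity_min` and the designated coverage(s)
#' `> coverage_min` — strict inequalities, matching rules written as ">".
#' `basis = "longer"` tests the coverage of the longer sequence, `"each"`
#' both sequences' coverages, `"query"` the query coverage only.
#'
#' @param hits AlignmentHit data.frame (vectorized over rows).
#' @param identity_min,coverage_min fractions in (0, 1].
#' @param basis `"longer"`, `"each"` or `"query"`.
#' @return logical vector.
#' @export
hit_meets <- function(hits, identity_min, coverage_min,
                      basis = c("longer", "each", "query")) {
  basis <- match.arg(basis)
  cov_ok <- switch(basis,
    longer = hits$coverage_longer > coverage_min,
    each = hits$coverage_query > coverage_min &
           hits$coverage_subject > coverage_min,
    query = hits$coverage_query > coverage_min)
  hits$identity > identity_min & cov_ok
}

# deterministic hit ordering: score desc, identity desc, subject_id asc
order_hits <- function(hits) {
  hits[order(-hits$score, -hits$identity, hits$subject_id), , drop = FALSE]
}
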